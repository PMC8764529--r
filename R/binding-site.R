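.WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD")
.METAL_ELEMENTS <- c("MG", "MN", "ZN", "CA", "NA", "FE")

## sp2 planar-group membership on the protein side. Returns a planar_group or
## NULL when the group is incomplete (e.g. chain terminus for a peptide amide).
.protein_pi_group <- function(atoms, i) {
  nm <- atoms$name[i]; rn <- atoms$res_num[i]; ch <- atoms$chain[i]
  res <- atoms$res_name[i]
  pick <- function(res_num, names) {
    sel <- atoms$chain == ch & atoms$res_num %in% res_num &
      !atoms$is_hetero
    sub <- atoms[sel, , drop = FALSE]
    m <- lapply(seq_along(names), function(k) {
      j <- which(sub$name == names[[k]]$name & sub$res_num == names[[k]]$res)
      if (length(j)) .coords(sub[j[1L], , drop = FALSE]) else NULL
    })
    if (any(vapply(m, is.null, logical(1L)))) return(NULL)
    do.call(rbind, m)
  }
  spec <- NULL; kind <- NULL
  if (res == "ASP" && nm %in% c("OD1", "OD2", "CG")) {
    spec <- list(list(name = "CB", res = rn), list(name = "CG", res = rn),
                 list(name = "OD1", res = rn), list(name = "OD2", res = rn))
    kind <- "carboxylate"
  } else if (res == "GLU" && nm %in% c("OE1", "OE2", "CD")) {
    spec <- list(list(name = "CG", res = rn), list(name = "CD", res = rn),
                 list(name = "OE1", res = rn), list(name = "OE2", res = rn))
    kind <- "carboxylate"
  } else if (nm == "N") {
    ## peptide amide of the preceding peptide bond: CA(i-1), C(i-1), O(i-1), N(i)
    spec <- list(list(name = "CA", res = rn - 1L), list(name = "C", res = rn - 1L),
                 list(name = "O", res = rn - 1L), list(name = "N", res = rn))
    kind <- "peptide_amide"
  } else if (nm == "O") {
    spec <- list(list(name = "CA", res = rn), list(name = "C", res = rn),
                 list(name = "O", res = rn), list(name = "N", res = rn + 1L))
    kind <- "peptide_amide"
  }
  if (is.null(spec)) return(NULL)
  pts <- pick(unique(vapply(spec, `[[`, numeric(1L), "res")), spec)
  if (is.null(pts)) return(NULL)
  fit_plane(pts, group_kind = kind)
}

.ligand_pi_group <- function(lig, atom_name, ligand_pi_groups) {
  for (kind in names(ligand_pi_groups)) {
    members <- ligand_pi_groups[[kind]]
    if (atom_name %in% members && all(members %in% lig$name)) {
      idx <- match(members, lig$name)
      return(fit_plane(.coords(lig[idx, , drop = FALSE]), group_kind = kind))
    }
  }
  NULL
}

#' Default ligand pi-group definitions
#'
#' Atom-name sets defining the sp2 planar groups of the toy ligands built by
#' [make_pocket()] and [make_ligand_pair()]: the carboxylate (two oxygens,
#' the carboxylate carbon and its attached carbon) and, for the GPPG-like
#' template, the guanine ring.
#'
#' @return Named list of character vectors of atom names.
#' @export
default_ligand_pi_groups <- function() {
  list(
    carboxylate = c("C1", "O1", "O2", "C2"),
    guanine_ring = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2G", "N2", "N3", "C4")
  )
}

#' Detect hydrogen bonds between a ligand and its protein environment
#'
#' Enumerates heavy-atom donor/acceptor pairs (N or O on both sides, one atom
#' in the ligand and one in protein or water) whose distance lies in
#' `[min_heavy_distance, max_heavy_distance]`. Hydrogens are ignored: the
#' deposited CofC structures are at a resolution without reliable hydrogen
#' positions, and no donor-H-acceptor angle criterion is applied. Instead,
#' whenever either side of the bond belongs to an sp2 pi-system (ligand
#' carboxylate or guanine ring, protein peptide amide or side-chain
#' carboxylate) the least-squares plane of that group is fitted and the
#' out-of-plane distance of the partner atom is recorded -- the geometric
#' quality statistic used throughout the package. When both sides are sp2 the
#' ligand-side group takes precedence.
#'
#' @param model A `structure_model`.
#' @param ligand List or vector with `chain`, `res_name`, `res_num`
#'   identifying the ligand (any element may be `NULL`/`NA` to match all).
#' @param max_heavy_distance,min_heavy_distance Donor-acceptor heavy-atom
#'   distance window in Angstrom (default 2.4--3.5).
#' @param ligand_pi_groups Named list of atom-name vectors defining ligand
#'   sp2 groups; see [default_ligand_pi_groups()].
#' @return A data frame of class `hbond_geometry` with one row per bond:
#'   partner identities, `heavy_distance`, `pi_kind`, `pi_side`,
#'   `pi_distance` (NA when neither side is sp2) and `partner_role`.
#' @export
detect_hbonds <- function(model, ligand,
                          max_heavy_distance = 3.5, min_heavy_distance = 2.4,
                          ligand_pi_groups = default_ligand_pi_groups()) {
  a <- model$atoms
  ligand <- as.list(ligand)
  sel <- rep(TRUE, nrow(a))
  if (!is.null(ligand$chain) && !is.na(ligand$chain)) sel <- sel & a$chain == ligand$chain
  if (!is.null(ligand$res_name) && !is.na(ligand$res_name)) sel <- sel & a$res_name == ligand$res_name
  if (!is.null(ligand$res_num) && !is.na(ligand$res_num)) sel <- sel & a$res_num == as.integer(ligand$res_num)
  if (!any(sel)) stop("ligand selector matched no atoms")
  lig <- a[sel, , drop = FALSE]
  env <- a[!sel, , drop = FALSE]

  lig_no <- lig[lig$element %in% c("N", "O"), , drop = FALSE]
  env_no <- env[env$element %in% c("N", "O"), , drop = FALSE]
  out <- list()
  if (nrow(lig_no) && nrow(env_no)) {
    lc <- .coords(lig_no); ec <- .coords(env_no)
    d2 <- outer(rowSums(lc^2), rowSums(ec^2), "+") - 2 * lc %*% t(ec)
    d <- sqrt(pmax(d2, 0))
    hits <- which(d >= min_heavy_distance & d <= max_heavy_distance, arr.ind = TRUE)
    if (nrow(hits)) {
      ord <- order(env_no$res_num[hits[, 2L]], env_no$name[hits[, 2L]],
                   lig_no$name[hits[, 1L]])
      hits <- hits[ord, , drop = FALSE]
      for (r in seq_len(nrow(hits))) {
        li <- hits[r, 1L]; ei <- hits[r, 2L]
        pg <- .ligand_pi_group(lig, lig_no$name[li], ligand_pi_groups)
        pi_side <- if (!is.null(pg)) "ligand" else NA_character_
        if (is.null(pg)) {
          ei_global <- which(a$serial == env_no$serial[ei] &
                               a$chain == env_no$chain[ei])[1L]
          pg <- .protein_pi_group(a, ei_global)
          if (!is.null(pg)) pi_side <- "protein"
        }
        partner_xyz <- if (identical(pi_side, "ligand")) ec[ei, ] else lc[li, ]
        ## donor/acceptor labelling heuristic on heavy atoms: N donates to O;
        ## between like elements the environment side is listed as donor
        lig_el <- lig_no$element[li]; env_el <- env_no$element[ei]
        env_is_donor <- !(lig_el == "N" && env_el == "O")
        role <- if (is.na(pi_side)) NA_character_ else {
          partner_is_env <- pi_side == "ligand"
          if (partner_is_env == env_is_donor) "donor_is_partner" else "acceptor_is_partner"
        }
        out[[length(out) + 1L]] <- data.frame(
          donor_atom = if (env_is_donor) env_no$name[ei] else lig_no$name[li],
          acceptor_atom = if (env_is_donor) lig_no$name[li] else env_no$name[ei],
          ligand_atom = lig_no$name[li],
          partner_chain = env_no$chain[ei],
          partner_res_name = env_no$res_name[ei],
          partner_res_num = env_no$res_num[ei],
          partner_atom = env_no$name[ei],
          ligand_chain = lig_no$chain[li],
          heavy_distance = d[li, ei],
          pi_kind = if (is.null(pg)) NA_character_ else pg$group_kind,
          pi_side = pi_side,
          pi_distance = if (is.null(pg)) NA_real_ else
            out_of_plane_distance(pg, partner_xyz),
          partner_role = role,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    donor_atom = character(), acceptor_atom = character(),
    ligand_atom = character(), partner_chain = character(),
    partner_res_name = character(), partner_res_num = integer(),
    partner_atom = character(), ligand_chain = character(),
    heavy_distance = numeric(), pi_kind = character(), pi_side = character(),
    pi_distance = numeric(), partner_role = character(),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("hbond_geometry", "data.frame")
  res
}

#' Mean out-of-pi-plane distortion of a hydrogen-bond set
#'
#' Arithmetic mean of the out-of-plane distances over the bonds that have a
#' fitted pi-group; bonds without one are excluded. A perfectly planar
#' hydrogen-bond geometry gives 0; larger values indicate strained sp2
#' hydrogen bonding.
#'
#' @param hbonds An `hbond_geometry` table from [detect_hbonds()].
#' @param pi_kind Optional filter (e.g. `"carboxylate"`) applied before
#'   averaging.
#' @return Mean distortion in Angstrom.
#' @export
average_pi_distortion <- function(hbonds, pi_kind = NULL) {
  x <- hbonds
  if (!is.null(pi_kind)) x <- x[!is.na(x$pi_kind) & x$pi_kind %in% pi_kind, , drop = FALSE]
  v <- x$pi_distance[!is.na(x$pi_distance)]
  if (!length(v)) stop("no hydrogen bonds with a pi-plane to average over")
  mean(v)
}

#' Protein-ligand contact table averaged over chains
#'
#' Reports every protein-atom/ligand-atom pair within `cutoff`, plus contacts
#' bridged by a water oxygen or a metal ion (protein atom within
#' `bridge_cutoff` of a bridge atom that is itself within `bridge_cutoff` of
#' a ligand atom). Distances are averaged over all chains containing the
#' ligand; a contact present in only some chains is averaged over the chains
#' where it occurs, with the per-chain values retained. For bridged contacts
#' the tabulated distance is from the protein atom to the bridging atom.
#'
#' @param model A `structure_model`.
#' @param ligand_res_name Three-letter ligand code.
#' @param cutoff Direct-contact cutoff in Angstrom (default 4.0).
#' @param bridge_cutoff Per-leg cutoff for water/metal bridges (default 3.5).
#' @return A data frame of class `contact_table`, sorted by
#'   (`protein_res_num`, `protein_atom`, `ligand_atom`), with `bridged_via`
#'   in `direct`/`water`/`magnesium`, `chains`, `per_chain_distances`
#'   (comma-separated, chain order) and `mean_distance`.
#' @export
contact_table <- function(model, ligand_res_name, cutoff = 4.0,
                          bridge_cutoff = 3.5) {
  a <- model$atoms
  lig_all <- a[a$res_name == ligand_res_name, , drop = FALSE]
  if (!nrow(lig_all)) stop("ligand '", ligand_res_name, "' not found in model")
  chains <- sort(unique(lig_all$chain))
  is_water <- a$res_name %in% .WATER_NAMES
  is_metal <- a$element %in% .METAL_ELEMENTS
  prot <- a[!a$is_hetero & !is_water & !is_metal, , drop = FALSE]
  rows <- list()
  for (ch in chains) {
    lig <- lig_all[lig_all$chain == ch, , drop = FALSE]
    pr <- prot[prot$chain == ch, , drop = FALSE]
    if (!nrow(pr)) next
    lc <- .coords(lig); pc <- .coords(pr)
    d <- sqrt(pmax(outer(rowSums(pc^2), rowSums(lc^2), "+") - 2 * pc %*% t(lc), 0))
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch,
        protein_res_name = pr$res_name[hit[, 1L]],
        protein_res_num = pr$res_num[hit[, 1L]],
        protein_atom = pr$name[hit[, 1L]],
        ligand_atom = lig$name[hit[, 2L]],
        bridged_via = "direct",
        distance = d[hit], stringsAsFactors = FALSE)
    }
    ## bridges: water O or metal in contact with both sides
    br <- a[(a$res_name %in% .WATER_NAMES & a$element == "O") |
              a$element %in% .METAL_ELEMENTS, , drop = FALSE]
    if (nrow(br)) {
      bc <- .coords(br)
      dbl <- sqrt(pmax(outer(rowSums(bc^2), rowSums(lc^2), "+") - 2 * bc %*% t(lc), 0))
      dbp <- sqrt(pmax(outer(rowSums(bc^2), rowSums(pc^2), "+") - 2 * bc %*% t(pc), 0))
      for (b in seq_len(nrow(br))) {
        ligs <- which(dbl[b, ] <= bridge_cutoff)
        prots <- which(dbp[b, ] <= bridge_cutoff)
        if (!length(ligs) || !length(prots)) next
        via <- if (br$element[b] %in% .METAL_ELEMENTS) "magnesium" else "water"
        grid <- expand.grid(p = prots, l = ligs)
        rows[[length(rows) + 1L]] <- data.frame(
          chain = ch,
          protein_res_name = pr$res_name[grid$p],
          protein_res_num = pr$res_num[grid$p],
          protein_atom = pr$name[grid$p],
          ligand_atom = lig$name[grid$l],
          bridged_via = via,
          distance = dbp[b, grid$p], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    res <- data.frame(protein_res_name = character(), protein_res_num = integer(),
                      protein_atom = character(), ligand_atom = character(),
                      bridged_via = character(), chains = character(),
                      per_chain_distances = character(), mean_distance = numeric(),
                      stringsAsFactors = FALSE)
    class(res) <- c("contact_table", "data.frame")
    return(res)
  }
  long <- do.call(rbind, rows)
  key <- paste(long$protein_res_num, long$protein_res_name, long$protein_atom,
               long$ligand_atom, long$bridged_via, sep = "\r")
  agg <- lapply(split(seq_len(nrow(long)), key), function(i) {
    i <- i[order(long$chain[i])]
    data.frame(
      protein_res_name = long$protein_res_name[i[1L]],
      protein_res_num = long$protein_res_num[i[1L]],
      protein_atom = long$protein_atom[i[1L]],
      ligand_atom = long$ligand_atom[i[1L]],
      bridged_via = long$bridged_via[i[1L]],
      chains = paste(long$chain[i], collapse = ","),
      per_chain_distances = paste(sprintf("%.9f", long$distance[i]), collapse = ","),
      mean_distance = mean(long$distance[i]),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, agg)
  res <- res[order(res$protein_res_num, res$protein_atom, res$ligand_atom,
                   res$bridged_via), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("contact_table", "data.frame")
  res
}

#' Audit metal-ion coordination shells
#'
#' Lists, for every ion of the requested element, all nitrogen/oxygen atoms
#' within the coordination cutoff, grouped by source (protein residue,
#' ligand, or water). In CofC the alpha- and beta-phosphates of the bound
#' guanylylated product are held by two magnesium ions positioned by three
#' aspartates, so the default element is magnesium.
#'
#' @param model A `structure_model`.
#' @param metal_element Element symbol (default `"MG"`).
#' @param coordination_cutoff Metal-to-O/N cutoff in Angstrom (default 2.6).
#' @return Data frame with one row per coordinating atom: metal identifiers,
#'   coordinating atom identifiers, `distance` and `source`
#'   (`protein`/`ligand`/`water`). Empty (zero rows) when the metal is
#'   absent.
#' @export
metal_coordination <- function(model, metal_element = "MG",
                               coordination_cutoff = 2.6) {
  a <- model$atoms
  metal_element <- toupper(metal_element)
  m <- a[a$element == metal_element, , drop = FALSE]
  empty <- data.frame(metal_serial = integer(), metal_chain = character(),
                      metal_res_num = integer(), chain = character(),
                      res_name = character(), res_num = integer(),
                      atom = character(), element = character(),
                      distance = numeric(), source = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(m)) return(empty)
  others <- a[a$element %in% c("N", "O"), , drop = FALSE]
  if (!nrow(others)) return(empty)
  mc <- .coords(m); oc <- .coords(others)
  d <- sqrt(pmax(outer(rowSums(mc^2), rowSums(oc^2), "+") - 2 * mc %*% t(oc), 0))
  hit <- which(d <= coordination_cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  src <- ifelse(others$res_name[hit[, 2L]] %in% .WATER_NAMES, "water",
                ifelse(others$is_hetero[hit[, 2L]], "ligand", "protein"))
  res <- data.frame(
    metal_serial = m$serial[hit[, 1L]],
    metal_chain = m$chain[hit[, 1L]],
    metal_res_num = m$res_num[hit[, 1L]],
    chain = others$chain[hit[, 2L]],
    res_name = others$res_name[hit[, 2L]],
    res_num = others$res_num[hit[, 2L]],
    atom = others$name[hit[, 2L]],
    element = others$element[hit[, 2L]],
    distance = d[hit],
    source = src, stringsAsFactors = FALSE)
  res <- res[order(res$metal_serial, res$res_num, res$atom), , drop = FALSE]
  rownames(res) <- NULL
  res
}
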