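#' Build an idealised carboxylate ligand
#'
#' A planar sp2 carboxylate (C1 with oxygens O1/O2 at 1.25 A, attached
#' carbon C2 at 1.52 A) in the z = 0 plane, centred on C1 at the origin.
#' Chemistry realism is not the goal; exact geometric ground truth is.
#'
#' @param res_name Ligand code (default `"CBX"`).
#' @param chain Chain identifier.
#' @param res_num Residue number.
#' @return Atom table (data frame).
#' @export
make_carboxylate_ligand <- function(res_name = "CBX", chain = "A", res_num = 500L) {
  data.frame(
    name = c("C1", "O1", "O2", "C2"),
    chain = chain, res_name = res_name, res_num = res_num,
    x = c(0, 0.625, 0.625, -1.52),
    y = c(0, 1.0825, -1.0825, 0),
    z = 0,
    element = c("C", "O", "O", "C"),
    is_hetero = TRUE, stringsAsFactors = FALSE)
}

#' Build an idealised GPPG-like ligand
#'
#' A toy guanylylated glycerate: planar guanine ring, a ribose stub, two
#' tetrahedral phosphates (P-O 1.6 A) and a glycerate whose carboxylate
#' (C1/O1/O2/C2) lies in a plane. Atom names follow
#' [default_ligand_pi_groups()] so pi-group detection works out of the box.
#'
#' @inheritParams make_carboxylate_ligand
#' @return Atom table (data frame).
#' @export
make_gppg_ligand <- function(res_name = "GPG", chain = "A", res_num = 500L) {
  carb <- make_carboxylate_ligand(res_name, chain, res_num)
  ## glycerate C3 and bridging oxygen off C2
  glyc <- data.frame(
    name = c("C3", "O3", "O1P"),
    chain = chain, res_name = res_name, res_num = res_num,
    x = c(-2.2, -2.2, -3.0), y = c(1.25, -0.8, 1.3), z = c(0.6, -0.5, 1.6),
    element = c("C", "O", "O"), is_hetero = TRUE, stringsAsFactors = FALSE)
  tet <- function(center, names, r = 1.6) {
    dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    out <- data.frame(
      name = c("P", "OT1", "OT2", "OT3", "OT4"),
      chain = chain, res_name = res_name, res_num = res_num,
      x = c(center[1L], center[1L] + r * dirs[, 1L]),
      y = c(center[2L], center[2L] + r * dirs[, 2L]),
      z = c(center[3L], center[3L] + r * dirs[, 3L]),
      element = c("P", rep("O", 4L)), is_hetero = TRUE, stringsAsFactors = FALSE)
    out <- out[seq_along(names), , drop = FALSE]
    out$name <- names
    out
  }
  pa <- tet(c(-4.2, 1.6, 2.4), c("PA", "O2P", "O3P", "OAB"))
  pb <- tet(c(-6.0, 2.2, 3.4), c("PB", "O4P", "O5P", "O5R"))
  ribose <- data.frame(
    name = c("C5R", "C4R", "O4R", "C1R"),
    chain = chain, res_name = res_name, res_num = res_num,
    x = c(-7.6, -8.6, -9.0, -9.9), y = c(2.8, 2.0, 0.8, 0.9),
    z = c(3.0, 2.2, 2.6, 2.0),
    element = c("C", "C", "O", "C"), is_hetero = TRUE, stringsAsFactors = FALSE)
  ## planar guanine: ring atoms on a circle in a tilted plane through C1R
  ring_names <- c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2G", "N2", "N3", "C4")
  th <- seq(0, 2 * pi, length.out = length(ring_names) + 1L)[seq_along(ring_names)]
  e1 <- c(1, 0, 0); e2 <- c(0, cos(pi / 6), sin(pi / 6))  # tilted ring plane
  ctr <- c(-11.3, 0.6, 1.6)
  ring <- data.frame(
    name = ring_names, chain = chain, res_name = res_name, res_num = res_num,
    x = ctr[1L] + 1.7 * (cos(th) * e1[1L] + sin(th) * e2[1L]),
    y = ctr[2L] + 1.7 * (cos(th) * e1[2L] + sin(th) * e2[2L]),
    z = ctr[3L] + 1.7 * (cos(th) * e1[3L] + sin(th) * e2[3L]),
    element = substr(ring_names, 1L, 1L), is_hetero = TRUE,
    stringsAsFactors = FALSE)
  ring$element[ring$name == "O6"] <- "O"
  rbind(carb, glyc, pa, pb, ribose, ring)
}

#' Generate a synthetic binding pocket with planted geometric truth
#'
#' Places a planar ligand (carboxylate-only or GPPG-like), then hydrogen-bond
#' donor atoms at exactly the requested out-of-pi-plane offsets and in-range
#' donor-acceptor distances, and magnesium ions with octahedral water
#' shells. The pocket is duplicated across chains with seeded Gaussian
#' jitter. A truth table records every planted hydrogen bond (donor
#' residue, target oxygen, distance, offset) and metal shell.
#'
#' @param n_donors Number of planted donors (recycled over the carboxylate
#'   oxygens).
#' @param planted_pi_offsets Out-of-plane offsets in Angstrom, recycled to
#'   `n_donors`.
#' @param ligand_template `"carboxylate"` or `"gppg"`.
#' @param n_metals Number of Mg ions with 6-water octahedral shells.
#' @param chains Number of chains (jittered copies).
#' @param jitter_sd Per-coordinate Gaussian jitter (Angstrom) applied to
#'   chains after the first.
#' @param donor_distance Heavy-atom donor-acceptor distance (default 2.9).
#' @param seed Mandatory integer seed.
#' @return List with `model` (a `structure_model`) and `truth` (list with
#'   `hbonds` data frame, `metals` data frame, and the generator settings).
#' @export
make_pocket <- function(n_donors = 3L, planted_pi_offsets = c(0.5, 1.0, 1.5),
                        ligand_template = c("carboxylate", "gppg"),
                        n_metals = 0L, chains = 1L, jitter_sd = 0,
                        donor_distance = 2.9, seed) {
  if (missing(seed)) stop("seed is mandatory")
  ligand_template <- match.arg(ligand_template)
  offsets <- rep(planted_pi_offsets, length.out = n_donors)
  if (any(offsets < 0)) stop("offsets must be >= 0")
  if (any(offsets >= donor_distance)) {
    stop("infeasible spec: offset >= donor-acceptor distance")
  }
  set.seed(seed)
  lig <- if (ligand_template == "carboxylate") make_carboxylate_ligand()
         else make_gppg_ligand()
  ## carboxylate plane is z = 0 by construction; donors fan out in-plane from
  ## the two oxygens, alternating, each on its own azimuth to stay separated
  base_atoms <- list(lig)
  truth_h <- list()
  if (n_donors > 0L) {
    for (k in seq_len(n_donors)) {
      ox <- if (k %% 2L == 1L) c(0.625, 1.0825, 0) else c(0.625, -1.0825, 0)
      side <- if (k %% 2L == 1L) 1 else -1
      az <- (30 + 25 * ((k - 1L) %/% 2L)) * pi / 180
      inplane <- sqrt(donor_distance^2 - offsets[k]^2)
      pos <- ox + c(inplane * cos(az), side * inplane * sin(az), offsets[k])
      base_atoms[[length(base_atoms) + 1L]] <- data.frame(
        name = "NZ", chain = "A", res_name = "LYS", res_num = 100L + k,
        x = pos[1L], y = pos[2L], z = pos[3L], element = "N",
        is_hetero = FALSE, stringsAsFactors = FALSE)
      truth_h[[k]] <- data.frame(
        donor_res_num = 100L + k, target_oxygen = if (side > 0) "O1" else "O2",
        distance = donor_distance, pi_offset = offsets[k],
        stringsAsFactors = FALSE)
    }
  }
  truth_m <- list()
  if (n_metals > 0L) {
    for (j in seq_len(n_metals)) {
      ctr <- c(8 + 6 * j, 5, 3)
      base_atoms[[length(base_atoms) + 1L]] <- data.frame(
        name = "MG", chain = "A", res_name = "MG", res_num = 200L + j,
        x = ctr[1L], y = ctr[2L], z = ctr[3L], element = "MG",
        is_hetero = TRUE, stringsAsFactors = FALSE)
      oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1)) * 2.1
      base_atoms[[length(base_atoms) + 1L]] <- data.frame(
        name = "O", chain = "A", res_name = "HOH",
        res_num = 300L + 10L * j + seq_len(6L),
        x = ctr[1L] + oct[, 1L], y = ctr[2L] + oct[, 2L], z = ctr[3L] + oct[, 3L],
        element = "O", is_hetero = TRUE, stringsAsFactors = FALSE)
      truth_m[[j]] <- data.frame(metal_res_num = 200L + j, n_coordinating = 6L,
                                 shell_distance = 2.1, stringsAsFactors = FALSE)
    }
  }
  one_chain <- do.call(rbind, base_atoms)
  all_chains <- lapply(seq_len(chains), function(ci) {
    ch <- one_chain
    ch$chain <- LETTERS[ci]
    if (ci > 1L) {
      ch$x <- ch$x + 60 * (ci - 1L) + stats::rnorm(nrow(ch), 0, jitter_sd)
      ch$y <- ch$y + stats::rnorm(nrow(ch), 0, jitter_sd)
      ch$z <- ch$z + stats::rnorm(nrow(ch), 0, jitter_sd)
    }
    ch
  })
  atoms <- do.call(rbind, all_chains)
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(atoms, title = "synthetic binding pocket")
  list(model = model,
       truth = list(
         hbonds = if (length(truth_h)) do.call(rbind, truth_h) else NULL,
         metals = if (length(truth_m)) do.call(rbind, truth_m) else NULL,
         ligand_res_name = lig$res_name[1L],
         ligand_res_num = lig$res_num[1L],
         offsets = offsets, chains = chains, jitter_sd = jitter_sd,
         donor_distance = donor_distance, seed = seed))
}

#' Generate a ligand pose pair related by a known carboxylate-axis rotation
#'
#' Rotates a copy of the base ligand by exactly `rotation_deg` about the
#' line through its two named carboxylate oxygens, recording the true angle
#' and the per-atom displacements (chord lengths).
#'
#' @param base Atom table of the base ligand (default an idealised GPPG-like
#'   ligand).
#' @param rotation_deg Rotation angle in degrees.
#' @param axis_oxygens Names of the two axis oxygens.
#' @return List with `lig_a`, `lig_b` and `truth` (angle, axis, per-atom
#'   displacement table with each atom's distance from the axis).
#' @export
make_ligand_pair <- function(base = make_gppg_ligand(), rotation_deg = 36,
                             axis_oxygens = c("O1", "O2")) {
  i1 <- match(axis_oxygens[1L], base$name)
  i2 <- match(axis_oxygens[2L], base$name)
  if (is.na(i1) || is.na(i2)) stop("axis oxygens not found in base ligand")
  p1 <- c(base$x[i1], base$y[i1], base$z[i1])
  p2 <- c(base$x[i2], base$y[i2], base$z[i2])
  if (sqrt(sum((p2 - p1)^2)) < 1e-9) stop("axis oxygens coincide")
  axis <- .unit(p2 - p1)
  co <- .coords(base)
  rot <- .rotate_about_axis(co, axis, rotation_deg * pi / 180, origin = p1)
  lig_b <- base
  lig_b$x <- rot[, 1L]; lig_b$y <- rot[, 2L]; lig_b$z <- rot[, 3L]
  off <- sweep(co, 2L, p1)
  r_axis <- sqrt(rowSums((off - (off %*% axis) %*% t(axis))^2))
  disp <- sqrt(rowSums((rot - co)^2))
  list(lig_a = base, lig_b = lig_b,
       truth = list(angle_deg = abs(rotation_deg) %% 360,
                    axis = axis,
                    displacements = data.frame(name = base$name,
                                               distance_from_axis = r_axis,
                                               displacement = disp,
                                               stringsAsFactors = FALSE)))
}

#' Generate a homolog set with a planted diagnostic residue
#'
#' Mutates a random reference sequence at `substitution_rate` everywhere
#' except the diagnostic position, forces that position to the planted
#' label, and introduces seeded deletions plus shared insertion columns so
#' the true alignment has a non-trivial gap pattern. Truth labels follow
#' the serine/threonine tolerance rule.
#'
#' @param reference_length Residues in the reference.
#' @param n_homologs Number of homolog rows (reference excluded).
#' @param substitution_rate Per-site substitution probability in [0, 1).
#' @param diagnostic_position 1-based ungapped position in the reference.
#' @param planted_labels Residues planted at the diagnostic position, one
#'   per homolog (recycled); use `"-"` to plant a deletion.
#' @param gap_rate Per-site deletion probability for homologs.
#' @param n_insert_columns Insertion columns (gap in the reference).
#' @param seed Mandatory integer seed.
#' @return List with `records` (ungapped data frame incl. the reference),
#'   `alignment` (a `multiple_alignment`, the true alignment) and `truth`
#'   (planted labels and expected calls).
#' @export
make_homolog_set <- function(reference_length = 120L, n_homologs = 8L,
                             substitution_rate = 0.05,
                             diagnostic_position = 60L,
                             planted_labels = c("S", "T", "G", "A"),
                             gap_rate = 0.02, n_insert_columns = 2L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (diagnostic_position < 1L || diagnostic_position > reference_length) {
    stop("diagnostic position outside the reference")
  }
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  ref <- sample(aa, reference_length, replace = TRUE)
  ref[diagnostic_position] <- "S"
  labels <- rep(planted_labels, length.out = n_homologs)
  rows <- matrix("-", nrow = n_homologs + 1L, ncol = reference_length)
  rows[1L, ] <- ref
  for (h in seq_len(n_homologs)) {
    s <- ref
    mut <- stats::runif(reference_length) < substitution_rate
    mut[diagnostic_position] <- FALSE
    s[mut] <- vapply(which(mut), function(i) sample(setdiff(aa, s[i]), 1L),
                     character(1L))
    del <- stats::runif(reference_length) < gap_rate
    del[diagnostic_position] <- FALSE
    s[del] <- "-"
    s[diagnostic_position] <- labels[h]
    rows[h + 1L, ] <- s
  }
  ## shared insertion columns: residues in a random subset of homologs,
  ## gaps in the reference (and the rest)
  if (n_insert_columns > 0L) {
    at <- sort(sample(seq_len(reference_length - 1L), n_insert_columns))
    for (k in rev(seq_along(at))) {
      newcol <- rep("-", n_homologs + 1L)
      carriers <- 1L + sample(seq_len(n_homologs),
                              max(1L, stats::rbinom(1L, n_homologs, 0.4)))
      newcol[carriers] <- sample(aa, length(carriers), replace = TRUE)
      rows <- cbind(rows[, seq_len(at[k]), drop = FALSE], newcol,
                    rows[, seq(at[k] + 1L, ncol(rows)), drop = FALSE])
    }
  }
  ids <- c("REF", sprintf("HOM%02d", seq_len(n_homologs)))
  rowstr <- apply(rows, 1L, paste, collapse = "")
  aln <- structure(list(ids = ids, rows = unname(rowstr), length = ncol(rows)),
                   class = "multiple_alignment")
  records <- data.frame(id = ids, description = "",
                        residues = gsub("-", "", rowstr, fixed = TRUE),
                        stringsAsFactors = FALSE)
  expected <- ifelse(labels %in% c("S", "T"), "tolerant",
                     ifelse(labels == "-", "indeterminate", "non_tolerant"))
  list(records = records, alignment = aln,
       truth = list(labels = labels,
                    expected_calls = c("tolerant", expected),
                    diagnostic_position = diagnostic_position,
                    seed = seed))
}

#' Simulate a combined CofC/D assay run with known rates
#'
#' For each replicate and reaction time, emits one Gaussian chromatographic
#' peak per product species whose area equals
#' `true_rate * min(t, saturation_after) * (1 + noise)`, with multiplicative
#' Gaussian noise of coefficient of variation `noise_cv`. Output follows the
#' [read_chromatograms()] CSV schema; the truth records the rates and the
#' expected relative turnover.
#'
#' @param true_rates Named vector of product-formation rates (normalised
#'   AUC per minute), named by product species.
#' @param time_points Reaction times in minutes.
#' @param saturation_after Time (min) after which product formation is flat
#'   (default 20, the end of the linear range).
#' @param peak_rt Named vector of retention times per species (defaults
#'   spread 1 min apart).
#' @param peak_width Gaussian peak sigma in minutes.
#' @param mz Named vector of m/z per species (defaults supplied).
#' @param noise_cv Coefficient of variation of the multiplicative area
#'   noise.
#' @param n_replicates Number of replicates.
#' @param n_scan_points Retention-time samples per peak.
#' @param seed Mandatory integer seed.
#' @return List with `chromatograms` (a `chromatogram_set`) and `truth`
#'   (rates, expected turnover percentages, spec).
#' @export
make_assay_run <- function(true_rates = c("3PG-F420-0" = 0.65,
                                          "F420-0" = 0.265,
                                          "DF420-0" = 0.085),
                           time_points = c(0, 5, 10, 15, 20),
                           saturation_after = 20,
                           peak_rt = NULL, peak_width = 0.08,
                           mz = NULL, noise_cv = 0,
                           n_replicates = 3L, n_scan_points = 41L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(true_rates < 0)) stop("rates must be >= 0")
  if (any(time_points < 0)) stop("time points must be >= 0")
  set.seed(seed)
  species <- names(true_rates)
  if (is.null(peak_rt)) peak_rt <- stats::setNames(2 + seq_along(species), species)
  if (is.null(mz)) mz <- stats::setNames(600 + 20 * seq_along(species), species)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    for (tt in time_points) {
      for (sp in species) {
        area <- true_rates[[sp]] * min(tt, saturation_after)
        if (noise_cv > 0 && area > 0) {
          area <- area * max(1 + stats::rnorm(1L, 0, noise_cv), 0)
        }
        rt <- seq(peak_rt[[sp]] - 4 * peak_width, peak_rt[[sp]] + 4 * peak_width,
                  length.out = n_scan_points)
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = sprintf("R%d", r), reaction_time_min = tt, species = sp,
          rt_min = rt, mz = mz[[sp]],
          intensity = area * stats::dnorm(rt, peak_rt[[sp]], peak_width),
          stringsAsFactors = FALSE)
      }
    }
  }
  chroms <- read_chromatograms(do.call(rbind, rows))
  expected <- 100 * true_rates / sum(true_rates)
  list(chromatograms = chroms,
       truth = list(true_rates = true_rates, expected_turnover_pct = expected,
                    saturation_after = saturation_after, noise_cv = noise_cv,
                    n_replicates = n_replicates, seed = seed))
}

#' Simulate nano-DSF melting curves with known parameters
#'
#' Evaluates the forward model of [dsf_signal()] on a temperature grid for
#' each ligand concentration and adds Gaussian signal noise.
#'
#' @param model An `unfolding_model` holding the true parameters.
#' @param ligand_concs Ligand concentrations in M (should include 0).
#' @param temperatures Temperature grid in K.
#' @param noise_sd Additive Gaussian noise SD in signal units.
#' @param seed Mandatory integer seed.
#' @return List with `curves` (data frame: `ligand_conc`, `temperature_K`,
#'   `signal`) and `truth` (the model).
#' @export
make_dsf_curves <- function(model, ligand_concs = c(0, 2e-6, 10e-6, 50e-6),
                            temperatures = seq(293, 363, by = 1),
                            noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  curves <- do.call(rbind, lapply(ligand_concs, function(L) {
    data.frame(ligand_conc = L, temperature_K = temperatures,
               signal = dsf_signal(model, temperatures, L) +
                 stats::rnorm(length(temperatures), 0, noise_sd))
  }))
  list(curves = curves, truth = list(model = model, noise_sd = noise_sd,
                                     seed = seed))
}
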