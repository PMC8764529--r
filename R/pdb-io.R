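#' Read a PDB-format coordinate file
#'
#' Parses fixed-column `ATOM`/`HETATM` records into an atom table. Only the
#' first `MODEL` of a multi-model file is kept. Alternate locations are
#' resolved deterministically: for each `(chain, res_num, insertion_code,
#' name)` the conformer with the highest occupancy wins, ties broken by
#' alt-loc letter (`A` before `B`).
#'
#' @param x Path to a PDB file, or a character vector of PDB-format lines
#'   (a single string containing newlines is also accepted).
#' @param keep_alt Keep all alternate locations instead of resolving them.
#' @return A `structure_model`: a list with `atoms` (data frame with columns
#'   `serial`, `name`, `alt_loc`, `chain`, `res_name`, `res_num`,
#'   `insertion_code`, `x`, `y`, `z`, `occupancy`, `element`, `is_hetero`),
#'   `title` and `source_id`.
#' @examples
#' lines <- c(
#'   "ATOM      1  N   GLY A   1       1.000   2.000   3.000  1.00  0.00           N",
#'   "END")
#' m <- read_pdb(lines)
#' m$atoms$x
#' @seealso [write_pdb()]
#' @export
read_pdb <- function(x, keep_alt = FALSE) {
  lines <- .as_pdb_lines(x)
  rec <- substr(lines, 1L, 6L)

  ## first MODEL only
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) >= 2L) {
    endmdl <- which(trimws(rec) == "ENDMDL")
    stop_at <- if (length(endmdl)) endmdl[1L] else model_starts[2L]
    keep <- seq_len(length(lines)) < stop_at
    lines <- lines[keep]
    rec <- rec[keep]
  }

  title <- paste(trimws(substr(lines[rec == "TITLE "], 11L, 80L)), collapse = " ")
  hdr <- lines[rec == "HEADER"]
  source_id <- if (length(hdr)) trimws(substr(hdr[1L], 63L, 66L)) else ""

  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(idx)) stop("no ATOM or HETATM records found (empty structure)")
  al <- lines[idx]

  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    blank <- which(!nzchar(trimws(s)))
    if (what %in% c("x", "y", "z")) bad <- sort(unique(c(bad, blank)))
    if (length(bad)) {
      stop(sprintf("malformed %s field in PDB record at line %d: '%s'",
                   what, idx[bad[1L]], trimws(al[bad[1L]])))
    }
    v
  }

  atoms <- data.frame(
    serial = num(substr(al, 7L, 11L), "serial"),
    name = trimws(substr(al, 13L, 16L)),
    alt_loc = trimws(substr(al, 17L, 17L)),
    res_name = trimws(substr(al, 18L, 20L)),
    chain = trimws(substr(al, 22L, 22L)),
    res_num = num(substr(al, 23L, 26L), "residue number"),
    insertion_code = trimws(substr(al, 27L, 27L)),
    x = num(substr(al, 31L, 38L), "x"),
    y = num(substr(al, 39L, 46L), "y"),
    z = num(substr(al, 47L, 54L), "z"),
    occupancy = num(substr(al, 55L, 60L), "occupancy"),
    element = trimws(substr(al, 77L, 78L)),
    is_hetero = substr(al, 1L, 6L) == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$serial[is.na(atoms$serial)] <- seq_along(atoms$serial)[is.na(atoms$serial)]

  ## element fallback from the atom name (first alphabetic character; two-letter
  ## symbols like MG/FE/ZN occupy columns 13-14 of the name field)
  miss <- !nzchar(atoms$element)
  if (any(miss)) {
    raw <- substr(al[miss], 13L, 16L)
    two <- toupper(trimws(substr(raw, 1L, 2L)))
    guess <- ifelse(two %in% c("MG", "FE", "ZN", "MN", "NA", "CL", "CA", "BR"),
                    two, substr(gsub("[^A-Za-z]", "", trimws(raw)), 1L, 1L))
    atoms$element[miss] <- toupper(guess)
  }
  atoms$element <- .normalize_element(atoms$element)

  if (!keep_alt && any(nzchar(atoms$alt_loc))) {
    key <- paste(atoms$chain, atoms$res_num, atoms$insertion_code, atoms$name,
                 sep = "\r")
    ## highest occupancy first, alt-loc letter as deterministic tie-break
    ord <- order(key, -atoms$occupancy, atoms$alt_loc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$res_num,
                                     atoms$insertion_code, atoms$name,
                                     sep = "\r")), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  rownames(atoms) <- NULL

  dup <- duplicated(paste(atoms$chain, atoms$res_num, atoms$insertion_code,
                          atoms$name, atoms$alt_loc, sep = "\r"))
  if (any(dup)) {
    stop(sprintf("duplicate atom identity (chain %s, residue %s%d, atom %s)",
                 atoms$chain[dup][1L], atoms$res_name[dup][1L],
                 atoms$res_num[dup][1L], atoms$name[dup][1L]))
  }

  structure(list(atoms = atoms, title = title, source_id = source_id),
            class = "structure_model")
}

.as_pdb_lines <- function(x) {
  if (is.character(x) && length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  }
  if (!is.character(x)) stop("expected a file path or character lines")
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

.normalize_element <- function(e) {
  e <- toupper(trimws(e))
  known2 <- c("MG", "FE", "ZN", "MN", "NA", "CL", "CA", "BR", "SE", "CU", "NI", "CO")
  ifelse(nchar(e) == 2L & !(e %in% known2), substr(e, 1L, 1L), e)
}

#' Build a structure model from an atom table
#'
#' Convenience constructor used by the synthetic generators and tests.
#'
#' @param atoms Data frame with at least `name`, `chain`, `res_name`,
#'   `res_num`, `x`, `y`, `z`; missing bookkeeping columns are filled with
#'   defaults.
#' @param title,source_id Optional metadata strings.
#' @return A `structure_model`.
#' @export
structure_model <- function(atoms, title = "", source_id = "") {
  needed <- c("name", "chain", "res_name", "res_num", "x", "y", "z")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$alt_loc)) atoms$alt_loc <- ""
  if (is.null(atoms$insertion_code)) atoms$insertion_code <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$element)) {
    atoms$element <- .normalize_element(substr(gsub("[0-9']", "", atoms$name), 1L, 2L))
  }
  if (is.null(atoms$is_hetero)) atoms$is_hetero <- FALSE
  atoms <- atoms[, c("serial", "name", "alt_loc", "res_name", "chain",
                     "res_num", "insertion_code", "x", "y", "z",
                     "occupancy", "element", "is_hetero")]
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)), all(is.finite(atoms$z)))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title, source_id = source_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d chain(s)%s\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  het <- table(x$atoms$res_name[x$atoms$is_hetero])
  if (length(het)) {
    cat("hetero:", paste(sprintf("%s x%d", names(het), as.integer(het)),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a structure model in PDB format
#'
#' Emits fixed-column `ATOM`/`HETATM` records with coordinates to three
#' decimals, so `read_pdb(write_pdb(m))` reproduces coordinates to within
#' 5e-4 Angstrom.
#'
#' @param model A `structure_model`.
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Invisibly (if `path` given) or visibly, a character vector of
#'   PDB lines.
#' @export
write_pdb <- function(model, path = NULL) {
  a <- model$atoms
  if (!nrow(a)) stop("refusing to write an empty structure")
  if (any(nchar(a$name) > 4L)) {
    stop("atom name longer than 4 characters: ",
         a$name[nchar(a$name) > 4L][1L])
  }
  ## short names start in column 14 by convention; 4-char names in column 13
  nm <- ifelse(nchar(a$name) >= 4L, a$name, sprintf(" %-3s", a$name))
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$is_hetero, "HETATM", "ATOM"),
    as.integer(a$serial) %% 100000L, nm, a$alt_loc, a$res_name, a$chain,
    as.integer(a$res_num), a$insertion_code, a$x, a$y, a$z, a$occupancy, 0,
    a$element)
  out <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Select atoms of one residue or ligand
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier, or `NULL` for any chain.
#' @param res_name Residue/ligand three-letter code, or `NULL`.
#' @param res_num Residue number, or `NULL`.
#' @return The matching rows of the atom table.
#' @export
select_atoms <- function(model, chain = NULL, res_name = NULL, res_num = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain == chain
  if (!is.null(res_name)) keep <- keep & a$res_name == res_name
  if (!is.null(res_num)) keep <- keep & a$res_num == res_num
  a[keep, , drop = FALSE]
}

.coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}
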