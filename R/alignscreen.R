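#' Read protein sequences from FASTA
#'
#' @param x File path or character vector of FASTA text.
#' @return Data frame with columns `id` (first whitespace-delimited header
#'   token), `description` (remainder of the header) and `residues`
#'   (uppercase, ungapped).
#' @export
read_fasta <- function(x) {
  txt <- .as_text_lines(x)
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  ss <- Biostrings::readBStringSet(tf)
  if (!length(ss)) stop("no FASTA records found")
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  res <- toupper(as.character(ss))
  res <- gsub("*", "", res, fixed = TRUE)
  if (any(grepl("[-.]", res))) {
    stop("gapped record '", id[grepl("[-.]", res)][1L],
         "': use read_alignment() for aligned input")
  }
  if (any(!nzchar(res))) stop("empty sequence for record ", id[!nzchar(res)][1L])
  data.frame(id = id, description = desc, residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param records Data frame with `id`, optional `description`, and
#'   `residues` (gapped rows are allowed for aligned FASTA output).
#' @param path Optional output file.
#' @param width Line-wrap width.
#' @return Character vector of FASTA lines (invisibly when `path` is given).
#' @export
write_fasta <- function(records, path = NULL, width = 60L) {
  hdr <- paste0(">", records$id,
                ifelse(nzchar(records$description %||% ""),
                       paste0(" ", records$description), ""))
  body <- vapply(records$residues, function(s) {
    paste(substring(s, seq(1L, nchar(s), width),
                    pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s))),
          collapse = "\n")
  }, character(1L))
  out <- unlist(strsplit(paste0(hdr, "\n", body), "\n"), use.names = FALSE)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.as_text_lines <- function(x) {
  if (is.character(x) && length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  }
  out <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  if (is.null(out)) character(0) else out
}

#' Read a multiple alignment (aligned FASTA or Clustal)
#'
#' `.` gap characters are normalised to `-`. All rows must have equal
#' length; a ragged alignment is an error naming the offending row.
#'
#' @param x File path or character vector.
#' @return A `multiple_alignment`: list with `ids`, `rows` (gapped,
#'   uppercase character vector) and `length` (number of columns).
#' @export
read_alignment <- function(x) {
  txt <- .as_text_lines(x)
  first <- txt[nzchar(trimws(txt))][1L]
  if (is.na(first)) stop("empty alignment input")
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) {
    body <- txt[-match(first, txt)]
    body <- body[nzchar(trimws(body))]
    body <- body[!grepl("^\\s", body)]           # drop conservation lines
    ids <- character(); rows <- list()
    for (ln in body) {
      parts <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(parts) < 2L) next
      id <- parts[1L]; seg <- gsub("[0-9]", "", parts[2L])
      if (!(id %in% ids)) { ids <- c(ids, id); rows[[id]] <- "" }
      rows[[id]] <- paste0(rows[[id]], seg)
    }
    rowv <- toupper(unlist(rows[ids], use.names = FALSE))
  } else {
    rec <- read_fasta_gapped(txt)
    ids <- rec$id
    rowv <- rec$residues
  }
  rowv <- gsub(".", "-", rowv, fixed = TRUE)
  lens <- nchar(rowv)
  if (length(unique(lens)) != 1L) {
    bad <- ids[which(lens != lens[1L])[1L]]
    stop("ragged alignment: row '", bad, "' has length ",
         lens[ids == bad][1L], " but row '", ids[1L], "' has ", lens[1L])
  }
  structure(list(ids = ids, rows = rowv, length = lens[1L]),
            class = "multiple_alignment")
}

## FASTA reader that keeps gap characters (readBStringSet would too, but the
## record-level validation of read_fasta strips/forbids them)
read_fasta_gapped <- function(txt) {
  txt <- .as_text_lines(txt)
  hd <- grep("^>", txt)
  if (!length(hd)) stop("no FASTA records found")
  ends <- c(hd[-1L] - 1L, length(txt))
  id <- sub("\\s.*$", "", sub("^>", "", txt[hd]))
  residues <- vapply(seq_along(hd), function(i) {
    toupper(gsub("\\s", "", paste(txt[(hd[i] + 1L):ends[i]], collapse = "")))
  }, character(1L))
  data.frame(id = id, residues = residues, stringsAsFactors = FALSE)
}

#' Needleman-Wunsch global alignment
#'
#' Optimal global alignment under a linear gap penalty, with deterministic
#' tie-breaking during traceback (diagonal preferred over up, up over left).
#'
#' @param a,b Sequences as strings, or single-row data frames with a
#'   `residues` column.
#' @param match,mismatch,gap Scores (defaults +1 / 0 / -1; identity rather
#'   than homology detection is the purpose, so no substitution matrix).
#' @return List with `a_aligned`, `b_aligned` (gapped strings) and `score`.
#' @export
global_align <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  sa <- if (is.data.frame(a)) a$residues[1L] else a
  sb <- if (is.data.frame(b)) b$residues[1L] else b
  va <- strsplit(toupper(sa), "")[[1L]]
  vb <- strsplit(toupper(sb), "")[[1L]]
  n <- length(va); m <- length(vb)
  if (!n || !m) stop("sequences must be non-empty")
  F <- matrix(0, n + 1L, m + 1L)
  F[, 1L] <- gap * (0:n)
  F[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(vb == va[i], match, mismatch)
    prev <- F[i, ]
    cur <- numeric(m + 1L)
    cur[1L] <- gap * i
    for (j in seq_len(m)) {
      cur[j + 1L] <- max(prev[j] + sub[j], prev[j + 1L] + gap, cur[j] + gap)
    }
    F[i + 1L, ] <- cur
  }
  ## traceback, diagonal > up > left on ties
  i <- n; j <- m; ra <- character(); rb <- character()
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        F[i + 1L, j + 1L] == F[i, j] + (if (va[i] == vb[j]) match else mismatch)) {
      ra <- c(va[i], ra); rb <- c(vb[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && F[i + 1L, j + 1L] == F[i, j + 1L] + gap) {
      ra <- c(va[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(vb[j], rb); j <- j - 1L
    }
  }
  list(a_aligned = paste(ra, collapse = ""),
       b_aligned = paste(rb, collapse = ""),
       score = F[n + 1L, m + 1L])
}

#' Percent identity of two aligned (gapped) rows
#'
#' Identity is counted over columns where at least one row has a residue:
#' 100 x (identical residue pairs) / (columns with >= 1 residue). Columns
#' that are gaps in both rows are ignored.
#'
#' @param aligned_a,aligned_b Equal-length gapped strings.
#' @return Percentage in [0, 100].
#' @export
percent_identity <- function(aligned_a, aligned_b) {
  va <- strsplit(toupper(aligned_a), "")[[1L]]
  vb <- strsplit(toupper(aligned_b), "")[[1L]]
  if (length(va) != length(vb)) stop("aligned rows differ in length")
  ga <- va == "-"; gb <- vb == "-"
  denom <- sum(!(ga & gb))
  if (!denom) stop("identity undefined: no columns with residues")
  100 * sum(!ga & !gb & va == vb) / denom
}

#' Map a reference residue number to its alignment column
#'
#' Finds the alignment column occupied by the `residue_number`-th residue of
#' the (gapped) reference row, so that positions defined on a protein (e.g.
#' the specificity-linked serine of a CofC) can be located in any alignment
#' regardless of its gap pattern.
#'
#' @param aln A `multiple_alignment`.
#' @param reference_id Row identifier.
#' @param residue_number 1-based position in the ungapped reference.
#' @return List with `reference_id`, `residue_number`, `column` (1-based)
#'   and `reference_residue` (for sanity-checking against the expected
#'   amino acid).
#' @export
map_residue_to_column <- function(aln, reference_id, residue_number) {
  k <- match(reference_id, aln$ids)
  if (is.na(k)) stop("reference id '", reference_id, "' not in alignment")
  v <- strsplit(aln$rows[k], "")[[1L]]
  nongap <- v != "-"
  if (residue_number < 1L || residue_number > sum(nongap)) {
    stop("residue number ", residue_number, " out of range (reference has ",
         sum(nongap), " residues)")
  }
  col <- which(cumsum(nongap) == residue_number & nongap)[1L]
  list(reference_id = reference_id, residue_number = as.integer(residue_number),
       column = as.integer(col), reference_residue = v[col])
}

#' Classify homologs by a diagnostic alignment column
#'
#' Applies the serine/threonine rule at the given column: rows carrying a
#' tolerated residue there are called `tolerant` (predicted to accept
#' 3-phosphoglycerate), rows with a gap are `indeterminate`, all others
#' `non_tolerant`.
#'
#' @param aln A `multiple_alignment`.
#' @param column 1-based alignment column.
#' @param tolerated Character vector of tolerated residues (default
#'   `c("S", "T")`).
#' @return Data frame with `sequence_id`, `column_residue` and `call`; the
#'   call counts are attached as attribute `summary`.
#' @export
classify_diagnostic <- function(aln, column, tolerated = c("S", "T")) {
  if (column < 1L || column > aln$length) {
    stop("column ", column, " out of range 1..", aln$length)
  }
  res <- toupper(substr(aln$rows, column, column))
  call <- ifelse(res == "-", "indeterminate",
                 ifelse(res %in% toupper(tolerated), "tolerant", "non_tolerant"))
  out <- data.frame(sequence_id = aln$ids, column_residue = res, call = call,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- table(factor(call, levels = c("tolerant", "non_tolerant",
                                                        "indeterminate")))
  out
}
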