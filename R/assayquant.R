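#' Read combined CofC/D assay chromatograms from CSV
#'
#' Expects long format with one intensity reading per row and columns
#' `replicate`, `reaction_time_min`, `species`, `rt_min`, `mz`, `intensity`.
#' Rows are validated and sorted by retention time within each trace.
#'
#' @param x File path, character vector of CSV text, or a data frame already
#'   in the schema.
#' @return A `chromatogram_set`: the validated data frame with that class
#'   attached.
#' @export
read_chromatograms <- function(x) {
  df <- if (is.data.frame(x)) {
    x
  } else {
    txt <- .as_text_lines(x)
    utils::read.csv(text = paste(txt, collapse = "\n"), stringsAsFactors = FALSE)
  }
  needed <- c("replicate", "reaction_time_min", "species", "rt_min", "mz", "intensity")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("chromatogram CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(df$intensity))) stop("non-finite intensity values")
  if (any(df$intensity < 0)) stop("negative intensity values")
  if (any(df$reaction_time_min < 0)) stop("negative reaction times")
  df <- df[order(df$replicate, df$reaction_time_min, df$species, df$rt_min), ,
           drop = FALSE]
  key <- paste(df$replicate, df$reaction_time_min, df$species, sep = "\r")
  dup <- unlist(lapply(split(df$rt_min, key), function(rt) c(FALSE, diff(rt) <= 0)))
  if (any(dup)) stop("retention times are not strictly increasing within a trace")
  rownames(df) <- NULL
  class(df) <- c("chromatogram_set", "data.frame")
  df
}

#' Write a chromatogram set as CSV
#'
#' @param chroms A `chromatogram_set`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_chromatograms <- function(chroms, path) {
  utils::write.csv(as.data.frame(chroms), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract an ion chromatogram (XIC)
#'
#' Filters one trace to the points whose m/z lies within
#' `mz_target +/- mz_tol`, the standard first step of LC-MS quantification.
#'
#' @param chroms A `chromatogram_set`.
#' @param species Product species name (e.g. `"3PG-F420-0"`).
#' @param mz_target Target m/z; `NULL` keeps all m/z values of the species.
#' @param mz_tol Tolerance in m/z units.
#' @param replicate,reaction_time_min Optional trace selectors.
#' @return An `xic_trace` data frame (`rt_min`, `intensity`, `mz`, plus the
#'   selector columns). An empty trace (with a warning) when no point
#'   survives the m/z filter.
#' @export
extract_xic <- function(chroms, species, mz_target = NULL, mz_tol = 0.01,
                        replicate = NULL, reaction_time_min = NULL) {
  df <- as.data.frame(chroms)
  keep <- df$species == species
  if (!any(keep)) stop("species '", species, "' not present")
  if (!is.null(replicate)) keep <- keep & df$replicate == replicate
  if (!is.null(reaction_time_min)) keep <- keep & df$reaction_time_min == reaction_time_min
  df <- df[keep, , drop = FALSE]
  if (!is.null(mz_target)) {
    df <- df[abs(df$mz - mz_target) <= mz_tol, , drop = FALSE]
  }
  if (!nrow(df)) warning("empty XIC: no points within m/z window for ", species)
  df <- df[order(df$replicate, df$reaction_time_min, df$rt_min), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("xic_trace", "data.frame")
  df
}

#' Integrate a chromatographic peak (area under the curve)
#'
#' Trapezoidal integral of intensity over retention time within a window,
#' after optionally subtracting the straight line through the two window
#' edges (a simple linear baseline; the default).
#'
#' @param xic An `xic_trace` or any data frame with `rt_min` and
#'   `intensity` for a single trace.
#' @param rt_window Numeric length-2 `(lo, hi)` in minutes; `NULL` uses the
#'   full trace.
#' @param baseline `"linear"` (default) or `"none"`.
#' @return Area (intensity x minutes); negative baseline-corrected areas are
#'   floored at 0.
#' @export
integrate_peak <- function(xic, rt_window = NULL, baseline = c("linear", "none")) {
  baseline <- match.arg(baseline)
  rt <- xic$rt_min; y <- xic$intensity
  if (!is.null(rt_window)) {
    keep <- rt >= rt_window[1L] & rt <= rt_window[2L]
    rt <- rt[keep]; y <- y[keep]
  }
  if (length(rt) < 2L) stop("peak integration needs at least 2 points in the window")
  o <- order(rt); rt <- rt[o]; y <- y[o]
  if (baseline == "linear") {
    n <- length(rt)
    slope <- (y[n] - y[1L]) / (rt[n] - rt[1L])
    y <- y - (y[1L] + slope * (rt - rt[1L]))
  }
  area <- sum(diff(rt) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  max(area, 0)
}

#' Normalise peak areas
#'
#' @param raw_areas Named numeric vector of areas per species.
#' @param mode `"total"` divides by the sum over all species; `"reference"`
#'   divides by the area of `reference_species` (e.g. the FO core, supplied
#'   at fixed concentration in the combined assay).
#' @param reference_species Species name used by mode `"reference"`.
#' @return Named numeric vector of normalised areas with attribute `mode`.
#' @export
normalize_area <- function(raw_areas, mode = c("total", "reference"),
                           reference_species = "FO") {
  mode <- match.arg(mode)
  if (!length(raw_areas) || all(raw_areas <= 0)) {
    stop("normalisation needs at least one positive area")
  }
  denom <- if (mode == "total") {
    sum(raw_areas)
  } else {
    if (!reference_species %in% names(raw_areas)) {
      stop("reference species '", reference_species, "' absent from areas")
    }
    raw_areas[[reference_species]]
  }
  if (denom <= 0) stop("zero normalisation denominator")
  out <- raw_areas / denom
  attr(out, "mode") <- mode
  out
}

#' Fit a product-formation rate on the linear time range
#'
#' Ordinary least-squares line through (reaction time, normalised area)
#' points inside the window, inclusive at both ends. The combined CofC/D
#' assay is linear over 0--20 min, the default window.
#'
#' @param times,areas Numeric vectors (minutes; normalised AUC).
#' @param window Length-2 time window in minutes (default `c(0, 20)`).
#' @return List with `slope` (per minute), `intercept`, `r_squared`,
#'   `n_points` and `window`.
#' @export
fit_linear_rate <- function(times, areas, window = c(0, 20)) {
  keep <- times >= window[1L] & times <= window[2L]
  t <- times[keep]; yv <- areas[keep]
  if (length(unique(t)) < 2L) {
    stop("rate fit needs >= 2 distinct time points inside the window")
  }
  fit <- stats::lm(yv ~ t)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((yv - mean(yv))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n_points = length(t), window = window)
}

#' Default substrate-to-product species map of the combined CofC/D assay
#'
#' 3-phosphoglycerate yields 3PG-F420-0, 2-phospholactate yields F420-0 and
#' phosphoenolpyruvate yields DF420-0, so each substrate's turnover is read
#' off the formation rate of its product.
#'
#' @return Named character vector `substrate -> product species`.
#' @export
default_substrate_map <- function() {
  c("3-PG" = "3PG-F420-0", "2-PL" = "F420-0", "PEP" = "DF420-0")
}

#' Relative-turnover profile across replicates
#'
#' Converts per-replicate product-formation rates into relative turnover
#' percentages (each substrate's rate as a share of the summed rates in that
#' replicate) and summarises across replicates with the arithmetic mean and
#' the sample (n-1) standard deviation. Negative rates are clamped to zero
#' with a warning before shares are formed.
#'
#' @param rates_per_replicate List (one element per replicate) of named
#'   numeric vectors of slopes, named by product species or by substrate.
#' @param substrate_map Named vector mapping substrate to product species;
#'   rate names matching a product species are relabelled to its substrate.
#' @return A `specificity_profile` data frame: `substrate`,
#'   `mean_turnover_pct`, `sd_turnover_pct`, `n_replicates`. Per-replicate
#'   percentages are attached as attribute `per_replicate`.
#' @export
specificity_profile <- function(rates_per_replicate,
                                substrate_map = default_substrate_map()) {
  if (!length(rates_per_replicate)) stop("no replicates supplied")
  shares <- lapply(rates_per_replicate, function(k) {
    nm <- names(k)
    hit <- match(nm, substrate_map)
    nm[!is.na(hit)] <- names(substrate_map)[hit[!is.na(hit)]]
    names(k) <- nm
    if (any(k < 0)) {
      warning("negative rate(s) clamped to zero before turnover computation")
      k[k < 0] <- 0
    }
    if (sum(k) <= 0) stop("all rates are zero in a replicate: turnover undefined")
    100 * k / sum(k)
  })
  subs <- names(shares[[1L]])
  if (!all(vapply(shares, function(s) identical(sort(names(s)), sort(subs)),
                  logical(1L)))) {
    stop("replicates disagree on substrate names")
  }
  mat <- do.call(rbind, lapply(shares, function(s) s[subs]))
  out <- data.frame(
    substrate = subs,
    mean_turnover_pct = colMeans(mat),
    sd_turnover_pct = if (nrow(mat) > 1L) apply(mat, 2L, stats::sd) else 0,
    n_replicates = nrow(mat),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "per_replicate") <- mat
  class(out) <- c("specificity_profile", "data.frame")
  out
}

#' Full assay quantification pipeline: XIC -> AUC -> rate -> turnover
#'
#' Runs the complete combined CofC/D quantification chain on a chromatogram
#' set: per replicate, species and reaction time an XIC is extracted and
#' integrated; areas are normalised (mode `"total"` rescales each replicate
#' by its summed product signal, mode `"reference"` divides each time point
#' by the FO reference trace, mode `"none"` keeps raw areas -- relative
#' turnover is invariant to the choice); a rate is fitted on the linear
#' window; and the rates are converted into a relative-turnover profile.
#'
#' @param chroms A `chromatogram_set`.
#' @param window Linear time range in minutes (default `c(0, 20)`).
#' @param normalize `"total"`, `"reference"` or `"none"`.
#' @param substrate_map Substrate-to-product map (see
#'   [default_substrate_map()]).
#' @param mz_targets Optional named vector of target m/z per species (with
#'   `mz_tol`) applied during XIC extraction.
#' @param mz_tol m/z tolerance.
#' @param baseline Peak-baseline mode passed to [integrate_peak()].
#' @param reference_species Reference species for mode `"reference"`.
#' @return List with `profile` (a `specificity_profile`), `rates` (list per
#'   replicate), `time_courses` (data frame of normalised areas) and
#'   `normalize` (the mode used).
#' @export
quantify_assay <- function(chroms, window = c(0, 20),
                           normalize = c("total", "reference", "none"),
                           substrate_map = default_substrate_map(),
                           mz_targets = NULL, mz_tol = 0.01,
                           baseline = "linear",
                           reference_species = "FO") {
  normalize <- match.arg(normalize)
  df <- as.data.frame(chroms)
  product_species <- unname(substrate_map)
  reps <- sort(unique(df$replicate))
  tc <- list()
  for (r in reps) {
    sub <- df[df$replicate == r, , drop = FALSE]
    times <- sort(unique(sub$reaction_time_min))
    for (tt in times) {
      species_here <- sort(unique(sub$species[sub$reaction_time_min == tt]))
      areas <- vapply(species_here, function(sp) {
        x <- extract_xic(chroms, sp, replicate = r, reaction_time_min = tt,
                         mz_target = if (!is.null(mz_targets)) mz_targets[[sp]] else NULL,
                         mz_tol = mz_tol)
        if (nrow(x) < 2L) return(0)
        integrate_peak(x, baseline = baseline)
      }, numeric(1L))
      if (normalize == "reference") {
        areas <- normalize_area(areas, "reference",
                                reference_species = reference_species)
      }
      tc[[length(tc) + 1L]] <- data.frame(
        replicate = r, reaction_time_min = tt,
        species = names(areas), area = as.numeric(areas),
        stringsAsFactors = FALSE)
    }
  }
  tc <- do.call(rbind, tc)
  if (normalize == "total") {
    ## per-replicate scale factor: summed product signal over the whole run,
    ## preserving linearity in time
    for (r in reps) {
      i <- tc$replicate == r
      s <- sum(tc$area[i & tc$species %in% product_species])
      if (s <= 0) stop("zero total product signal in replicate ", r)
      tc$area[i] <- tc$area[i] / s
    }
  }
  rates <- lapply(reps, function(r) {
    sub <- tc[tc$replicate == r & tc$species %in% product_species, , drop = FALSE]
    vapply(split(sub, sub$species), function(ss) {
      fit_linear_rate(ss$reaction_time_min, ss$area, window = window)$slope
    }, numeric(1L))
  })
  names(rates) <- reps
  list(profile = specificity_profile(rates, substrate_map = substrate_map),
       rates = rates, time_courses = tc, normalize = normalize)
}
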