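#' @name dsf_model
#' @title Two-state thermal unfolding with ligand linkage
#'
#' @description
#' The package models nano-DSF melting curves with a two-state (native /
#' unfolded) equilibrium and van 't Hoff energetics with zero heat-capacity
#' change: `dG_u(T) = dH_u * (1 - T / T_m)` with `T_m` the apo midpoint (K)
#' and `dH_u` the unfolding enthalpy at `T_m` (kJ/mol). A ligand at
#' concentration `L` (assumed in large excess, free ~ total) that binds only
#' the native state with dissociation constant `K_D` stabilises it by the
#' linkage term `R*T*log(1 + L/K_D)`, so the apparent unfolding free energy
#' is `dG_app = dG_u + R*T*log(1 + L/K_D)` and the unfolded fraction is
#' `f_u = 1 / (1 + exp(dG_app / (R*T)))`.
#'
#' When a fraction `phi` of the protein co-purifies loaded with a tightly
#' bound product (as CofC does with GPPG), the population is a mixture: the
#' loaded subpopulation is stabilised through its own constant `K_D_GPPG` by
#' the product released on unfolding (approximated as `phi *
#' protein_conc`), while the remaining `1 - phi` responds to the titrated
#' ligand. The observed `f_u` is the `phi`-weighted mixture.
NULL

.R_GAS <- 8.314  # J / mol / K

#' Construct an unfolding model parameter set
#'
#' @param T_m Apo melting midpoint in K.
#' @param dH_u Unfolding enthalpy at `T_m` in kJ/mol.
#' @param K_D Dissociation constant of the titrated ligand (M).
#' @param K_D_GPPG Dissociation constant of the co-purified product (M), or
#'   `NA` when `phi = 0`.
#' @param phi Fraction of protein pre-loaded with product, in [0, 1].
#' @param protein_conc Protein concentration (M), used to approximate the
#'   free product concentration as `phi * protein_conc`.
#' @param baselines Optional list with `a_N`, `b_N`, `a_U`, `b_U` (native /
#'   unfolded signal intercepts and per-K slopes) for signal simulation.
#' @return An `unfolding_model` list.
#' @export
unfolding_model <- function(T_m, dH_u, K_D = Inf, K_D_GPPG = NA, phi = 0,
                            protein_conc = 10e-6,
                            baselines = list(a_N = 1, b_N = -0.002,
                                             a_U = 2, b_U = -0.001)) {
  if (T_m <= 0 || dH_u <= 0) stop("T_m and dH_u must be positive")
  if (!is.infinite(K_D) && K_D <= 0) stop("K_D must be positive")
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  if (phi > 0 && (is.na(K_D_GPPG) || K_D_GPPG <= 0)) {
    stop("phi > 0 requires a positive K_D_GPPG")
  }
  structure(list(T_m = T_m, dH_u = dH_u, K_D = K_D, K_D_GPPG = K_D_GPPG,
                 phi = phi, protein_conc = protein_conc, baselines = baselines),
            class = "unfolding_model")
}

#' Unfolded fraction at a temperature and ligand concentration
#'
#' Evaluates the two-state linkage model (see [dsf_model]). At `T = T_m`
#' with no ligand and `phi = 0` this is exactly 0.5.
#'
#' @param model An `unfolding_model`.
#' @param T Temperature(s) in K.
#' @param ligand_conc Titrated ligand concentration in M.
#' @return `f_u` in [0, 1], vectorised over `T`.
#' @export
unfolded_fraction <- function(model, T, ligand_conc = 0) {
  if (any(T <= 0)) stop("temperatures must be positive (K)")
  if (ligand_conc < 0) stop("ligand concentration must be >= 0")
  fu_one <- function(link_conc, kd) {
    dG <- model$dH_u * 1000 * (1 - T / model$T_m) +
      .R_GAS * T * log1p(if (is.infinite(kd)) 0 else link_conc / kd)
    1 / (1 + exp(dG / (.R_GAS * T)))
  }
  free_pop <- fu_one(ligand_conc, model$K_D)
  if (model$phi <= 0) return(free_pop)
  loaded <- fu_one(model$phi * model$protein_conc, model$K_D_GPPG)
  (1 - model$phi) * free_pop + model$phi * loaded
}

#' Predicted nano-DSF signal
#'
#' Native and unfolded baselines (linear in temperature) mixed by the
#' unfolded fraction.
#'
#' @inheritParams unfolded_fraction
#' @return Signal values, vectorised over `T`.
#' @export
dsf_signal <- function(model, T, ligand_conc = 0) {
  b <- model$baselines
  fu <- unfolded_fraction(model, T, ligand_conc)
  (1 - fu) * (b$a_N + b$b_N * T) + fu * (b$a_U + b$b_U * T)
}

#' Apparent melting temperature of a curve
#'
#' Temperature at which the model's unfolded fraction crosses 0.5, located
#' by root bisection.
#'
#' @inheritParams unfolded_fraction
#' @param interval Search interval in K.
#' @return Apparent T_m in K.
#' @export
apparent_tm <- function(model, ligand_conc = 0, interval = c(250, 420)) {
  stats::uniroot(function(T) unfolded_fraction(model, T, ligand_conc) - 0.5,
                 interval = interval, tol = 1e-10)$root
}

.pack_params <- function(T_m, dH_u, log10_KD, base_mat) {
  c(T_m, dH_u, log10_KD, as.numeric(base_mat))
}

.melting_residuals <- function(p, curves, phi, K_D_GPPG, protein_conc) {
  n_curves <- length(curves)
  T_m <- p[1L]; dH_u <- p[2L]; KD <- 10^p[3L]
  if (T_m <= 0 || dH_u <= 0) return(rep(1e6, sum(vapply(curves, nrow, 1L))))
  bases <- matrix(p[-(1:3)], nrow = n_curves, ncol = 4L)
  unlist(lapply(seq_len(n_curves), function(i) {
    cv <- curves[[i]]
    m <- unfolding_model(T_m, dH_u, K_D = KD, K_D_GPPG = K_D_GPPG, phi = phi,
                         protein_conc = protein_conc,
                         baselines = list(a_N = bases[i, 1L], b_N = bases[i, 2L],
                                          a_U = bases[i, 3L], b_U = bases[i, 4L]))
    dsf_signal(m, cv$temperature_K, cv$ligand_conc[1L]) - cv$signal
  }), use.names = FALSE)
}

.init_baselines <- function(cv) {
  n <- nrow(cv)
  lo <- cv[seq_len(max(3L, floor(n * 0.15))), ]
  hi <- cv[seq(n - max(3L, floor(n * 0.15)) + 1L, n), ]
  cn <- stats::coef(stats::lm(signal ~ temperature_K, lo))
  cu <- stats::coef(stats::lm(signal ~ temperature_K, hi))
  c(cn[1L], cn[2L], cu[1L], cu[2L])
}

.guess_tm <- function(cv) {
  ## steepest-slope temperature of the apo (or lowest-ligand) curve
  d <- diff(cv$signal) / diff(cv$temperature_K)
  mid <- (utils::head(cv$temperature_K, -1L) + utils::tail(cv$temperature_K, -1L)) / 2
  mid[which.max(abs(d))]
}

#' Fit shared unfolding thermodynamics and K_D across a ligand titration
#'
#' Nonlinear least squares (Levenberg-Marquardt) over all melting curves of
#' a ligand series jointly: shared `T_m`, `dH_u` and `K_D` (fitted as
#' log10), per-curve linear baselines. Initialisation is data driven
#' (steepest-slope T_m, edge-fit baselines) with multistart over `T_m +/-
#' 10 K` and log-spaced `K_D`; the best run by residual sum of squares is
#' returned with asymptotic standard errors and 95% confidence intervals.
#'
#' @param curves Data frame with columns `ligand_conc` (M),
#'   `temperature_K` (or `temperature_C`) and `signal`, or a list of such
#'   per-curve data frames.
#' @param fix_phi Fraction of pre-loaded protein, fixed during the fit
#'   (default 0).
#' @param K_D_GPPG Product dissociation constant used when `fix_phi > 0`.
#' @param protein_conc Protein concentration (M).
#' @param n_starts Number of multistart initialisations (default 8).
#' @param seed Seed for the multistart draw.
#' @return A `melting_fit`: list with `estimates` (data frame of `T_m`,
#'   `dH_u`, `K_D` with `se`, `ci_lo`, `ci_hi`), `baselines`, `rss`,
#'   `converged`, `kd_identifiable` (FALSE when only apo curves were
#'   supplied) and `n_curves`.
#' @export
fit_melting <- function(curves, fix_phi = 0, K_D_GPPG = NA,
                        protein_conc = 10e-6, n_starts = 8L, seed = 1L) {
  curves <- .split_curves(curves)
  if (length(curves) < 1L) stop("no curves supplied")
  concs <- vapply(curves, function(cv) cv$ligand_conc[1L], numeric(1L))
  kd_identifiable <- any(concs > 0)
  if (length(curves) >= 3L && !0 %in% concs) {
    warning("no apo (ligand_conc = 0) curve supplied; T_m is extrapolated")
  }
  flat <- vapply(curves, function(cv) {
    stats::sd(cv$signal) < 1e-12 || diff(range(cv$signal)) <
      0.05 * max(abs(cv$signal), 1e-12)
  }, logical(1L))
  if (all(flat)) stop("no melting transition detected: curves are flat")

  apo_idx <- which.min(concs)
  tm0 <- .guess_tm(curves[[apo_idx]])
  base0 <- t(vapply(curves, .init_baselines, numeric(4L)))
  set.seed(seed)
  tms <- tm0 + stats::runif(n_starts, -10, 10); tms[1L] <- tm0
  kds <- 10^stats::runif(n_starts, -7, -3); kds[1L] <- 1e-5
  best <- NULL
  for (s in seq_len(n_starts)) {
    p0 <- .pack_params(tms[s], 300, log10(kds[s]), base0)
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = .melting_residuals, curves = curves,
                         phi = fix_phi, K_D_GPPG = K_D_GPPG,
                         protein_conc = protein_conc,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("melting fit failed for every start")
  fit <- best$fit
  p <- fit$par
  ## asymptotic covariance from the Jacobian
  se <- rep(NA_real_, 3L)
  cov_ok <- tryCatch({
    h <- fit$hessian
    dof <- max(length(fit$fvec) - length(p), 1L)
    cv <- solve(h) * best$rss / dof * 2  # hessian = 2 J'J for nls.lm
    se <- sqrt(pmax(diag(cv)[1:3], 0))
    TRUE
  }, error = function(e) FALSE)
  est <- data.frame(
    parameter = c("T_m", "dH_u", "K_D"),
    estimate = c(p[1L], p[2L], 10^p[3L]),
    se = c(se[1L], se[2L], if (cov_ok) log(10) * 10^p[3L] * se[3L] else NA),
    stringsAsFactors = FALSE)
  est$ci_lo <- est$estimate - 1.96 * est$se
  est$ci_hi <- est$estimate + 1.96 * est$se
  if (!kd_identifiable) est[est$parameter == "K_D", c("estimate", "se", "ci_lo", "ci_hi")] <- NA
  structure(list(
    estimates = est,
    baselines = matrix(p[-(1:3)], nrow = length(curves), ncol = 4L,
                       dimnames = list(NULL, c("a_N", "b_N", "a_U", "b_U"))),
    rss = best$rss,
    converged = fit$info %in% 1:4,
    kd_identifiable = kd_identifiable,
    n_curves = length(curves)
  ), class = "melting_fit")
}

.split_curves <- function(curves) {
  if (is.data.frame(curves)) {
    if (!"temperature_K" %in% names(curves) && "temperature_C" %in% names(curves)) {
      curves$temperature_K <- curves$temperature_C + 273.15
    }
    needed <- c("ligand_conc", "temperature_K", "signal")
    miss <- setdiff(needed, names(curves))
    if (length(miss)) stop("curve data lacks column(s): ", paste(miss, collapse = ", "))
    curves <- lapply(split(curves, curves$ligand_conc),
                     function(cv) cv[order(cv$temperature_K), , drop = FALSE])
  }
  lapply(curves, function(cv) {
    if (any(diff(cv$temperature_K) <= 0)) stop("temperatures must be strictly increasing")
    if (nrow(cv) < 10L) stop("each melting curve needs >= 10 points")
    cv
  })
}

#' Feasible (K_D,GTP, K_D,GPPG) combinations on a grid
#'
#' When a fraction of the protein co-purifies with tightly bound product,
#' the titration data constrain only combinations of the two dissociation
#' constants. For every grid point `(phi, K_D_GTP, K_D_GPPG)` the remaining
#' parameters (`T_m`, `dH_u`, per-curve baselines) are refitted and the RSS
#' recorded; the feasible set contains the points with
#' `RSS <= min(RSS) * (1 + threshold)` (so it always includes the argmin).
#'
#' @param curves As in [fit_melting()].
#' @param phi_grid,kd_gtp_grid,kd_gppg_grid Numeric grids (M for the K_Ds).
#' @param threshold Relative RSS slack defining feasibility (default 0.05).
#' @param protein_conc Protein concentration (M).
#' @return Data frame with `phi`, `kd_gtp`, `kd_gppg`, `rss`, `feasible`,
#'   carrying the refit minimum as attribute `min_rss`.
#' @export
kd_feasibility_grid <- function(curves, phi_grid, kd_gtp_grid, kd_gppg_grid,
                                threshold = 0.05, protein_conc = 10e-6) {
  if (!length(phi_grid) || !length(kd_gtp_grid) || !length(kd_gppg_grid)) {
    stop("grids must be non-empty")
  }
  curves <- .split_curves(curves)
  base0 <- t(vapply(curves, .init_baselines, numeric(4L)))
  tm0 <- .guess_tm(curves[[which.min(vapply(curves, function(cv) cv$ligand_conc[1L],
                                            numeric(1L)))]])
  grid <- expand.grid(phi = phi_grid, kd_gtp = kd_gtp_grid,
                      kd_gppg = kd_gppg_grid, KEEP.OUT.ATTRS = FALSE)
  resid_fixed <- function(p, phi, kd_gtp, kd_gppg) {
    .melting_residuals(c(p[1L], p[2L], log10(kd_gtp), p[-(1:2)]),
                       curves, phi, kd_gppg, protein_conc)
  }
  grid$rss <- vapply(seq_len(nrow(grid)), function(i) {
    p0 <- c(tm0, 300, as.numeric(base0))
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fixed, phi = grid$phi[i],
                         kd_gtp = grid$kd_gtp[i], kd_gppg = grid$kd_gppg[i],
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) Inf else sum(fit$fvec^2)
  }, numeric(1L))
  min_rss <- min(grid$rss)
  grid$feasible <- grid$rss <= min_rss * (1 + threshold)
  attr(grid, "min_rss") <- min_rss
  grid
}
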