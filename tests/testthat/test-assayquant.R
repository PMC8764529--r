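test_that("chromatogram CSV schema is validated and sorted on load", {
  csv <- c("replicate,reaction_time_min,species,rt_min,mz,intensity",
           "R1,5,F420-0,2.0,620,10",
           "R1,5,F420-0,1.5,620,4")
  ch <- read_chromatograms(csv)
  expect_s3_class(ch, "chromatogram_set")
  expect_equal(ch$rt_min, c(1.5, 2.0))   # sorted on load
  expect_error(read_chromatograms(csv[1:2][-1]), "lacks column")
  bad <- c(csv[1], "R1,5,F420-0,2.0,620,-3")
  expect_error(read_chromatograms(bad), "negative intensity")
})

test_that("generated runs round-trip through CSV", {
  run <- make_assay_run(noise_cv = 0.05, n_replicates = 2, seed = 12)
  tf <- tempfile(fileext = ".csv")
  write_chromatograms(run$chromatograms, tf)
  back <- read_chromatograms(tf)
  expect_equal(nrow(back), nrow(run$chromatograms))
  expect_equal(back$intensity, run$chromatograms$intensity, tolerance = 1e-9)
  expect_equal(back$species, run$chromatograms$species)
})

test_that("XIC extraction filters by m/z window exactly", {
  df <- data.frame(replicate = "R1", reaction_time_min = 5,
                   species = "F420-0",
                   rt_min = seq(1, 2, by = 0.1),
                   mz = rep(c(620.00, 620.02, 621.5), length.out = 11),
                   intensity = 1)
  ch <- read_chromatograms(df)
  x <- extract_xic(ch, "F420-0", mz_target = 620.00, mz_tol = 0.025)
  expect_equal(nrow(x), sum(abs(df$mz - 620) <= 0.025))
  expect_warning(x0 <- extract_xic(ch, "F420-0", mz_target = 640, mz_tol = 0),
                 "empty XIC")
  expect_equal(nrow(x0), 0L)
  expect_error(extract_xic(ch, "nope"), "not present")
})

test_that("peak integration matches closed forms", {
  ## constant intensity 10 over 2 minutes, no baseline correction
  flat <- data.frame(rt_min = seq(0, 2, by = 0.1), intensity = 10)
  expect_equal(integrate_peak(flat, baseline = "none"), 20, tolerance = 1e-12)
  ## the default linear baseline removes a constant offset entirely
  expect_equal(integrate_peak(flat), 0, tolerance = 1e-12)

  ## symmetric triangle, height 6, base 4 -> area 12
  tri <- data.frame(rt_min = c(0, 2, 4), intensity = c(0, 6, 0))
  expect_equal(integrate_peak(tri, baseline = "none"), 12, tolerance = 1e-12)

  expect_error(integrate_peak(flat[1, , drop = FALSE]), "at least 2")
})

test_that("noisy Gaussian peaks integrate to within 1% of the fine-grid truth", {
  set.seed(33)
  area_true <- 7.5; mu <- 2; sig <- 0.08
  rt <- seq(mu - 4 * sig, mu + 4 * sig, length.out = 61)
  y <- area_true * dnorm(rt, mu, sig) * (1 + rnorm(61, 0, 0.005))
  got <- integrate_peak(data.frame(rt_min = rt, intensity = y), baseline = "none")
  fine <- seq(mu - 4 * sig, mu + 4 * sig, length.out = 20001)
  truth <- sum(diff(fine) * (head(area_true * dnorm(fine, mu, sig), -1) +
                               tail(area_true * dnorm(fine, mu, sig), -1)) / 2)
  expect_lt(abs(got - truth) / truth, 0.01)
})

test_that("integration error vanishes as sampling density grows", {
  errs <- vapply(c(11, 41, 161), function(np) {
    rt <- seq(1.6, 2.4, length.out = np)
    got <- integrate_peak(data.frame(rt_min = rt,
                                     intensity = dnorm(rt, 2, 0.08)),
                          baseline = "none")
    abs(got - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("area normalisation modes behave and are scale invariant", {
  areas <- c(A = 3, B = 1)
  expect_equal(as.numeric(normalize_area(areas, "total")), c(0.75, 0.25))
  ref <- c(A = 1, FO = 2)
  expect_equal(normalize_area(ref, "reference")[["A"]], 0.5)
  scaled <- normalize_area(areas * 17, "total")
  expect_equal(as.numeric(scaled), c(0.75, 0.25))
  expect_error(normalize_area(c(A = 0, B = 0)), "positive area")
  expect_error(normalize_area(areas, "reference", reference_species = "FO"),
               "absent")
})

test_that("rate fits reproduce closed-form OLS inside the window", {
  f <- fit_linear_rate(c(0, 10, 20), c(0, 10, 20))
  expect_equal(f$slope, 1)
  expect_equal(f$r_squared, 1)
  expect_equal(fit_linear_rate(c(0, 5, 10), c(4, 4, 4))$slope, 0)

  set.seed(34)
  t <- seq(0, 20, by = 2.5)
  y <- 0.8 * t + rnorm(length(t), 0, 0.05)
  f2 <- fit_linear_rate(t, y)
  beta <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  expect_equal(f2$slope, beta, tolerance = 1e-12)
  ## points outside the window are excluded
  t3 <- c(t, 30); y3 <- c(y, 100)
  expect_equal(fit_linear_rate(t3, y3, window = c(0, 20))$slope, beta,
               tolerance = 1e-12)
  expect_error(fit_linear_rate(c(3, 3), c(1, 2)), "distinct time points")
})

test_that("turnover shares sum to 100 and collapse correctly", {
  pr <- specificity_profile(list(c(a = 3, b = 1)),
                            substrate_map = c(a = "a", b = "b"))
  expect_equal(pr$mean_turnover_pct, c(75, 25))
  expect_equal(pr$sd_turnover_pct, c(0, 0))
  pr3 <- specificity_profile(list(c(a = 2, b = 2, c = 2)),
                             substrate_map = c(a = "a", b = "b", c = "c"))
  expect_equal(pr3$mean_turnover_pct, rep(100 / 3, 3))
  expect_warning(
    prn <- specificity_profile(list(c(a = -1, b = 1)),
                               substrate_map = c(a = "a", b = "b")),
    "clamped")
  expect_equal(prn$mean_turnover_pct, c(0, 100))
  expect_error(specificity_profile(list(c(a = 0, b = 0)),
                                   substrate_map = c(a = "a", b = "b")),
               "undefined")
})

test_that("noiseless end-to-end pipeline recovers generator ratios exactly", {
  run <- make_assay_run(noise_cv = 0, seed = 35)
  q <- quantify_assay(run$chromatograms)
  got <- setNames(q$profile$mean_turnover_pct, q$profile$substrate)
  truth <- run$truth$expected_turnover_pct
  names(truth) <- names(default_substrate_map())[
    match(names(truth), default_substrate_map())]
  expect_lt(max(abs(got[names(truth)] - truth)), 0.1)
  expect_equal(sum(got), 100, tolerance = 1e-6)
  per <- attr(q$profile, "per_replicate")
  expect_equal(unname(rowSums(per)), rep(100, nrow(per)), tolerance = 1e-6)
})

test_that("turnover is invariant under rescaling all traces", {
  run <- make_assay_run(noise_cv = 0.03, seed = 36)
  q1 <- quantify_assay(run$chromatograms)
  scaled <- run$chromatograms
  scaled$intensity <- scaled$intensity * 37.5
  q2 <- quantify_assay(read_chromatograms(as.data.frame(scaled)))
  expect_equal(q2$profile$mean_turnover_pct, q1$profile$mean_turnover_pct,
               tolerance = 1e-9)
})

test_that("saturation beyond 20 min does not disturb the windowed fit", {
  run_sat <- make_assay_run(time_points = c(0, 5, 10, 15, 20, 30, 40),
                            saturation_after = 20, noise_cv = 0, seed = 37)
  run_lin <- make_assay_run(time_points = c(0, 5, 10, 15, 20),
                            saturation_after = 20, noise_cv = 0, seed = 37)
  q_sat <- quantify_assay(run_sat$chromatograms, window = c(0, 20))
  q_lin <- quantify_assay(run_lin$chromatograms, window = c(0, 20))
  expect_equal(q_sat$profile$mean_turnover_pct, q_lin$profile$mean_turnover_pct,
               tolerance = 1e-9)
})

test_that("reference-mode normalisation leaves turnover unchanged", {
  rates <- c("3PG-F420-0" = 0.5, "F420-0" = 0.3, "DF420-0" = 0.2, "FO" = 0)
  run <- make_assay_run(true_rates = rates, noise_cv = 0, seed = 38)
  ## give FO a constant (time-independent) area as the fixed-input reference
  ch <- as.data.frame(run$chromatograms)
  ch$intensity[ch$species == "FO"] <-
    dnorm(ch$rt_min[ch$species == "FO"], 6, 0.08) * 5
  ch <- read_chromatograms(ch)
  q_tot <- quantify_assay(ch, normalize = "total")
  q_ref <- quantify_assay(ch, normalize = "reference", reference_species = "FO")
  expect_equal(q_ref$profile$mean_turnover_pct, q_tot$profile$mean_turnover_pct,
               tolerance = 1e-6)
})
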