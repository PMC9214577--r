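test_that("spectral error closed forms and invariances", {
  Rm <- matrix(runif(44, 1e-6, 1e-3), 22, 2)
  expect_identical(spectral_error(Rm, Rm), 0)
  expect_equal(spectral_error(1.1 * Rm, Rm), 0.1)
  # invariant under a common positive spectral rescaling
  s <- runif(22, 0.5, 2)
  expect_equal(spectral_error(1.2 * Rm * s, Rm * s), 0.2)
  expect_error(spectral_error(Rm[1:10, ], Rm), "shapes")
  expect_error(spectral_error(Rm, -Rm), "positive")
})

test_that("fit targets validate their detector subsets", {
  R <- matrix(runif(22 * 6, 1e-6, 1e-3), 22, 6,
              dimnames = list(NULL, paste0("d", 1:6)))
  wl <- fit_wavelengths_default()
  expect_identical(length(wl), 22L)
  expect_true(all(wl >= 700 & wl <= 880))
  # density below 780 nm is about twice that above
  expect_gt(sum(wl < 780) / sum(wl >= 780), 1.4)
  tg <- fit_target(wl, R, 1:4, 5:6)
  expect_s3_class(tg, "fit_target")
  expect_error(fit_target(wl, R, 1:4, 4:6), "disjoint")
  expect_error(fit_target(wl, R, 1:4, 7), "not present")
})

test_that("calibration recovers affine distortions and rejects degeneracy", {
  set.seed(9)
  wl <- 22
  sim <- lapply(1:6, function(i) matrix(runif(wl * 3, 1e-5, 1e-3), wl, 3))
  # identity pairs: calibrated equals raw
  cal <- calibrate_spectra(sim, sim, sim[[1]])
  expect_equal(cal$target, sim[[1]], tolerance = 1e-10)
  # pairs (x, 2x): calibrated doubles the raw target
  twice <- lapply(sim, function(m) 2 * m)
  cal2 <- calibrate_spectra(sim, twice, sim[[1]])
  expect_equal(cal2$target, 2 * sim[[1]], tolerance = 1e-10)
  # affine distortion + noise round-trip: measured = (sim - b) / a with noise
  a <- c(2.0, 0.5, 1.3); b <- c(1e-5, -2e-5, 5e-6)
  meas <- lapply(sim, function(m) {
    sweep(sweep(m, 2, b, "-"), 2, a, "/") * matrix(rnorm(wl * 3, 1, 0.01),
                                                   wl, 3)
  })
  cal3 <- calibrate_spectra(meas, sim, meas[[1]])
  expect_equal(cal3$coef$slope, a, tolerance = 0.05)
  expect_equal(cal3$target, sim[[1]], tolerance = 0.05)
  # replicate averaging
  cal4 <- calibrate_spectra(sim, sim, list(sim[[1]], 3 * sim[[1]]))
  expect_equal(cal4$target, 2 * sim[[1]], tolerance = 1e-10)
  # degenerate phantoms
  flat <- lapply(sim, function(m) {m[] <- 1; m})
  expect_error(calibrate_spectra(flat, sim, sim[[1]]), "degenerate")
})

test_that("parameter vector and tissue parameters are mutually inverse", {
  spec <- param_spec()
  set.seed(2)
  v <- stats::setNames(runif(nrow(spec), spec$lo, spec$hi), spec$name)
  p <- vector_to_params(v)
  expect_equal(params_to_vector(p), v)
  expect_equal(p$scalp$A, v[["scalp_musp800"]] * 800^v[["scalp_K"]])
})

test_that("OP matrices from parameter vectors match the reference spectra path", {
  lib <- fx_lib()
  wl <- fit_wavelengths_default()
  v <- params_to_vector(tissue_params())
  cd <- headfit:::chrom_design(lib, wl)
  op <- headfit:::op_matrix_from_vector(v, cd, c("scalp", "skull", "csf", "gm"))
  ops_ref <- params_to_op_spectra(tissue_params(), lib, wl)
  for (cmp in c("scalp", "skull", "csf", "gm")) {
    ref <- ops_ref[ops_ref$compartment == cmp, ]
    expect_equal(unname(op[, paste0("mua_", cmp)]), ref$mua, tolerance = 1e-10)
    expect_equal(unname(op[, paste0("musp_", cmp)]), ref$musp,
                 tolerance = 1e-10)
  }
})

test_that("initial pools are feasible, deterministic, and self-retrieving", {
  lib <- fx_lib()
  wl <- fit_wavelengths_default()
  comps <- c("scalp", "skull", "gm")
  cd <- headfit:::chrom_design(lib, wl)
  fake_forward <- function(op) {
    # smooth positive synthetic forward: enough for pool mechanics
    R <- exp(-2 - op[, "mua_scalp"] * 3 - op[, "mua_gm"] * 2 -
               0.02 * op[, "musp_scalp"]) %o% c(1, 0.1, 0.01)
    colnames(R) <- c("d1", "d2", "d3")
    R
  }
  pool1 <- build_initial_pool(fake_forward, lib, wl, comps, n = 50, seed = 6)
  pool2 <- build_initial_pool(fake_forward, lib, wl, comps, n = 50, seed = 6)
  expect_identical(pool1$params, pool2$params)
  ridx <- headfit:::ranges_index(comps)
  for (i in seq_len(50)) {
    op <- headfit:::op_matrix_from_vector(pool1$params[i, ], cd, comps)
    expect_identical(headfit:::range_penalty(op, ridx), 0)
  }
  # a pool-generated target is retrieved with zero spectral error
  target_R <- pool1$spectra[17, , ]
  errs <- vapply(seq_len(50), function(i) {
    spectral_error(pool1$spectra[i, , ], target_R)
  }, numeric(1))
  expect_identical(which.min(errs), 17L)
  expect_identical(min(errs), 0)
})

test_that("two-stage solution selection reproduces the decision diagram", {
  mk <- function(err_fit, err_tie) {
    out <- tibble::tibble(
      start = seq_along(err_fit), pool_index = seq_along(err_fit),
      params = replicate(length(err_fit), list(NULL)),
      error_fit = err_fit, error_tiebreak = err_tie,
      penalty = 0, iterations = 10L, converged = TRUE, feasible = TRUE)
    out <- out[order(out$error_fit), ]
    out$rank <- seq_len(nrow(out))
    class(out) <- c("fit_result_set", class(out))
    out
  }
  # one result dominating both stages -> unique solution
  s1 <- select_solutions(mk(c(0.05, 0.09, 0.10), c(0.04, 0.05, 0.06)))
  expect_false(s1$multiplicity)
  expect_identical(nrow(s1$solutions), 1L)
  # two results tied within 2% at both stages -> multiple solutions
  s2 <- select_solutions(mk(c(0.050, 0.060, 0.120), c(0.040, 0.045, 0.030)))
  expect_true(s2$multiplicity)
  expect_identical(nrow(s2$solutions), 2L)
  expect_identical(s2$n_stage1, 2L)
  # stage 2 disambiguates a stage-1 tie
  s3 <- select_solutions(mk(c(0.050, 0.060, 0.065), c(0.020, 0.080, 0.090)))
  expect_false(s3$multiplicity)
  expect_identical(s3$n_stage1, 3L)
  # threshold zero keeps exact minima only
  s4 <- select_solutions(mk(c(0.05, 0.05 + 1e-9, 0.2), c(0.01, 0.02, 0.03)),
                         threshold = 0)
  expect_identical(nrow(s4$solutions), 1L)
  # no tie-breaker detectors: stage 2 skipped with a warning
  expect_warning(
    s5 <- select_solutions(mk(c(0.05, 0.06), c(NA_real_, NA_real_))),
    "stage 2 skipped")
  expect_identical(nrow(s5$solutions), 2L)
})

test_that("the detector-combination scan keeps the largest usable combination", {
  set.seed(19)
  comps <- c("scalp", "skull", "gm")
  n <- 1500
  X <- cbind(matrix(runif(n * 3, 0.05, 0.5), n, 3),
             matrix(runif(n * 3, 5, 35), n, 3))
  colnames(X) <- c(paste0("mua_", comps), paste0("musp_", comps))
  R <- exp(-3 - 2 * X[, 1] - X[, 3] - 0.05 * X[, 4] - 0.02 * X[, 6]) %o%
    c(1, 0.3, 0.1, 0.03)
  colnames(R) <- paste0("d", 1:4)
  ts <- tibble::as_tibble(cbind(X, R))
  ts$split <- sample(c("train", "val", "test"), n, TRUE, c(0.75, 0.1, 0.15))
  attr(ts, "compartments") <- comps
  surr <- train_surrogate(ts, hidden = c(16, 16), epochs = 60, seed = 2)
  forward <- surrogate_forward(surr)
  lib <- fx_lib()
  wl <- fit_wavelengths_default()
  pool <- build_initial_pool(forward, lib, wl, comps, n = 120, seed = 6)
  # target generated by the surrogate itself, then the 3 cm channel corrupted
  # with an oscillating distortion no smooth parameter change can absorb
  R_t <- pool$spectra[11, , ]
  colnames(R_t) <- paste0("d", 1:4)
  R_t[, "d4"] <- R_t[, "d4"] * exp(1.2 * sin(seq_len(nrow(R_t))))
  tg <- fit_target(wl, R_t, 1:4, integer(0))
  scan <- scan_detector_combinations(tg, forward, pool, lib,
                                     combinations = list(1:2, 1:3, 1:4),
                                     threshold = 0.15, n_starts = 5,
                                     max_iter = 150)
  expect_identical(scan$detectors, c("12", "123", "1234"))
  expect_true(scan$selected[scan$detectors == "123"])
  expect_false(scan$selected[scan$detectors == "1234"])
  expect_gt(scan$best_error[3], 0.15)
  expect_lt(scan$best_error[2], 0.15)
  expect_s3_class(attr(scan, "fits"), "fit_result_set")
})
test_that("analytic objective gradients match finite differences", {
  set.seed(11)
  comps <- c("scalp", "skull", "gm")
  n <- 1200
  X <- cbind(matrix(runif(n * 3, 0.05, 0.5), n, 3),
             matrix(runif(n * 3, 5, 35), n, 3))
  colnames(X) <- c(paste0("mua_", comps), paste0("musp_", comps))
  R <- exp(-3 - 2 * X[, 1] - X[, 3] - 0.05 * X[, 4]) %o% c(1, 0.3, 0.1)
  colnames(R) <- paste0("d", 1:3)
  ts <- tibble::as_tibble(cbind(X, R))
  ts$split <- sample(c("train", "val", "test"), n, TRUE, c(0.75, 0.1, 0.15))
  attr(ts, "compartments") <- comps
  surr <- train_surrogate(ts, hidden = c(16, 16), epochs = 40, seed = 2)
  fwd <- surrogate_forward(surr)
  wg <- attr(fwd, "with_grad")
  lib <- fx_lib()
  wl <- fit_wavelengths_default()
  cd <- headfit:::chrom_design(lib, wl)
  ridx <- headfit:::ranges_index(comps)
  spec <- param_spec()
  set.seed(3)
  v0 <- stats::setNames(runif(nrow(spec), spec$lo, spec$hi), spec$name)
  Rm <- spectra_from_vector(v0 * 0.98 + spec$lo * 0.02, fwd, comps, cd = cd)[, 1:2]
  fval <- function(v) {
    op <- headfit:::op_matrix_from_vector(v, cd, comps)
    R <- fwd(op)
    spectral_error(R[, 1:2], Rm) + 50 * headfit:::range_penalty(op, ridx)
  }
  # analytic gradient assembled the way the fitter does it
  op <- headfit:::op_matrix_from_vector(v0, cd, comps)
  fw <- wg(op)
  ratio <- fw$R[, 1:2] / Rm - 1
  err <- sqrt(mean(ratio^2))
  dE <- matrix(0, nrow(fw$R), ncol(fw$R))
  dE[, 1:2] <- ratio / (Rm * err * 2 * nrow(fw$R))
  dop <- fw$vjp(dE)
  colnames(dop) <- colnames(op)
  dP <- dop * 0
  for (q in names(ridx)) {
    r <- ridx[[q]]
    xq <- op[, q]
    dP[, q] <- 2 * (pmax((xq - r[2]) / r[3], 0) -
                    pmax((r[1] - xq) / r[3], 0)) / (r[3] * nrow(op))
  }
  ga <- headfit:::param_grad_from_op(v0, cd, comps, dop + 50 * dP)
  gn <- vapply(spec$name, function(nm) {
    h <- max(1e-6 * abs(v0[[nm]]), 1e-10)
    up <- v0; up[nm] <- up[nm] + h
    dn <- v0; dn[nm] <- dn[nm] - h
    (fval(up) - fval(dn)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(ga[spec$name]), unname(gn),
               tolerance = 1e-5)
})
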