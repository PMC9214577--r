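# a cheap smooth synthetic forward: positive, wavelength-independent given
# OPs; sufficient for the mechanics exercised here
fake_forward4 <- function(op) {
  R <- exp(-2 - 3 * op[, "mua_scalp"] - 2 * op[, "mua_gm"] -
             0.03 * op[, "musp_scalp"]) %o% c(1, 0.2, 0.05, 0.01)
  colnames(R) <- paste0("d", 1:4)
  R
}

test_that("test-spectra bookkeeping matches the study design", {
  lib <- fx_lib()
  wl <- fit_wavelengths_default()
  ts <- generate_test_spectra(fake_forward4, lib, wl, c("scalp", "skull", "gm"),
                              noise = noise_model(rep(5, 4)),
                              n_param = 15, n_noise = 14, seed = 2)
  expect_identical(nrow(ts$sets), 15L)
  expect_identical(nrow(ts$replicates), 15L * 14L)  # 210 noisy spectra
  # zero noise reproduces the noiseless spectra exactly
  ts0 <- generate_test_spectra(fake_forward4, lib, wl, c("scalp", "skull", "gm"),
                               noise = noise_model(rep(0, 4)),
                               n_param = 2, n_noise = 3, seed = 2)
  expect_equal(ts0$replicates$spectra[[1]], ts0$sets$clean[[1]])
  # determinism
  ts2 <- generate_test_spectra(fake_forward4, lib, wl, c("scalp", "skull", "gm"),
                               noise = noise_model(rep(5, 4)),
                               n_param = 15, n_noise = 14, seed = 2)
  expect_identical(ts$replicates$spectra[[7]], ts2$replicates$spectra[[7]])
})

test_that("noise replicates reproduce the per-detector CV", {
  lib <- fx_lib()
  wl <- fit_wavelengths_default()
  cv <- c(3.0, 4.2, 5.1, 12.1)
  ts <- generate_test_spectra(fake_forward4, lib, wl, c("scalp", "skull", "gm"),
                              noise = noise_model(cv),
                              n_param = 1, n_noise = 500, seed = 3)
  clean <- ts$sets$clean[[1]]
  for (j in c(1, 4)) {
    fac <- vapply(ts$replicates$spectra, function(m) m[5, j] / clean[5, j],
                  numeric(1))
    sample_cv <- stats::sd(fac) / mean(fac)
    # 3 sigma of the CV estimator at n = 500
    expect_lt(abs(sample_cv - cv[j] / 100), 3 * cv[j] / 100 / sqrt(2 * 499))
  }
})

test_that("confidence intervals behave like empirical quantiles", {
  lib <- fx_lib()
  wl <- fit_wavelengths_default()
  comps <- c("scalp", "skull", "gm")
  cd <- headfit:::chrom_design(lib, wl)
  truth <- params_to_vector(tissue_params())
  truth_op <- headfit:::op_matrix_from_vector(truth, cd, comps)
  # zero-error fits: all intervals collapse to [0, 0]
  fits0 <- tibble::tibble(params = replicate(12, list(truth)),
                          truth_op = replicate(12, list(truth_op)))
  ed0 <- compile_confidence_intervals(fits0, lib, wl, comps)
  expect_true(all(abs(ed0$intervals$lo) < 1e-9))
  expect_true(all(abs(ed0$intervals$hi) < 1e-9))
  # musp800 scaled by (1 + e), e ~ N(0, sigma): musp errors are exactly 100 e
  set.seed(8)
  sigma <- 0.05
  e <- rnorm(400, 0, sigma)
  fits <- tibble::tibble(
    params = lapply(e, function(ei) {
      v <- truth
      v[c("scalp_musp800", "skull_musp800", "gm_musp800")] <-
        v[c("scalp_musp800", "skull_musp800", "gm_musp800")] * (1 + ei)
      v
    }),
    truth_op = replicate(400, list(truth_op)))
  ed <- compile_confidence_intervals(fits, lib, wl, comps)
  ci68 <- ed$intervals[ed$intervals$level == 0.68 &
                       ed$intervals$op == "musp_gm", ]
  expect_equal(ci68$hi, 100 * sigma, tolerance = 0.15 * 100 * sigma)
  expect_equal(ci68$lo, -100 * sigma, tolerance = 0.15 * 100 * sigma)
  # nesting: the 68% interval sits inside the 95% one
  for (opn in unique(ed$intervals$op)) {
    i68 <- ed$intervals[ed$intervals$level == 0.68 & ed$intervals$op == opn, ]
    i95 <- ed$intervals[ed$intervals$level == 0.95 & ed$intervals$op == opn, ]
    expect_gte(i68$lo, i95$lo)
    expect_lte(i68$hi, i95$hi)
  }
  expect_warning(compile_confidence_intervals(fits[1:3, ], lib, wl, comps),
                 "fewer than 10")
})

test_that("sensitivity analysis reflects probing depth", {
  # forward built on the recorded head-model photon paths: reflectance at any
  # absorption via the Beer-Lambert rescaling (scattering held fixed)
  r <- fx_head_wmc()
  forward <- function(op) {
    mua <- cbind(scalp = op[, "mua_scalp"], skull = op[, "mua_skull"],
                 csf = op[, "mua_csf"], gm = op[, "mua_gm"],
                 wm = op[, "mua_gm"] / 2)
    wmc_reflectance(r, mua)
  }
  base <- c(mua_scalp = 0.25, mua_skull = 0.15, mua_csf = 0.04,
            mua_gm = 0.2, musp_scalp = 15, musp_skull = 16, musp_gm = 9)
  sens <- sensitivity_analysis(forward, base,
                               ops = c("mua_scalp", "mua_gm"))
  s <- function(opn, det) sens$sensitivity[sens$op == opn &
                                           sens$detector == det]
  # the shortest separation sees scalp, not gray matter
  expect_gt(abs(s("mua_scalp", "d1")), abs(s("mua_gm", "d1")))
  # gray-matter sensitivity grows with separation
  expect_gt(abs(s("mua_gm", "d6")) / max(abs(s("mua_gm", "d1")), 1e-12), 1)
  expect_error(sensitivity_analysis(forward, base, perturbation = 0),
               "positive")
})

test_that("rank validation normalizes and orders fabricated fits correctly", {
  lib <- fx_lib()
  wl <- fit_wavelengths_default()
  comps <- c("scalp", "skull", "gm")
  truth <- params_to_vector(tissue_params())
  # fabricate result sets where rank order equals OP-error order
  mk_target <- function(scales) {
    out <- tibble::tibble(
      start = seq_along(scales),
      params = lapply(scales, function(s) {
        v <- truth
        v[c("scalp_musp800", "skull_musp800", "gm_musp800")] <-
          v[c("scalp_musp800", "skull_musp800", "gm_musp800")] * s
        v
      }),
      error_fit = seq_along(scales) / 100,
      rank = seq_along(scales))
    class(out) <- c("fit_result_set", class(out))
    out
  }
  fits <- lapply(1:5, function(i) mk_target(1 + 0.02 * (1:6) + 0.001 * i))
  truths <- replicate(5, truth, simplify = FALSE)
  rv <- rank_validation(fits, truths, lib, wl, comps)
  med <- vapply(split(rv$norm_op_error, rv$rank), stats::median, numeric(1))
  expect_true(all(diff(med) > 0))
  # min-max property: each target contributes exactly one 0 and one 1
  for (tg in unique(rv$target)) {
    v <- rv$norm_op_error[rv$target == tg]
    expect_identical(sum(v == 0), 1L)
    expect_identical(sum(v == 1), 1L)
  }
  # degenerate target (constant errors) is skipped with a message
  fits_deg <- c(fits, list(mk_target(rep(1.1, 6))))
  truths_deg <- replicate(6, truth, simplify = FALSE)
  expect_message(rv2 <- rank_validation(fits_deg, truths_deg, lib, wl, comps),
                 "skipped")
  expect_identical(sort(unique(rv2$target)), 1:5)
})
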