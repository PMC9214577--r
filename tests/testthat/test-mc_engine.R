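test_that("identical RNG configuration reproduces photon records bit-exactly", {
  m <- fx_head_model(); p <- fx_head_probe()
  a <- run_white_mc(m, p, fx_head_musp(), n_photons = 2e4, seed = 3)
  b <- run_white_mc(m, p, fx_head_musp(), n_photons = 2e4, seed = 3)
  expect_identical(a$records, b$records)
  c <- run_white_mc(m, p, fx_head_musp(), n_photons = 2e4, seed = 4)
  expect_false(identical(a$records, c$records))
  # different seeds agree within binomial error at a well-populated detector
  n1 <- a$per_det$n_raw[1]; n2 <- c$per_det$n_raw[1]
  expect_lt(abs(n1 - n2), 6 * sqrt(n1))
})

test_that("every launched photon is accounted for exactly once", {
  r <- fx_head_wmc()
  audit <- with(r$counts, n_specular + n_escaped_top + n_escaped_other +
                  n_terminated + n_detected)
  expect_identical(audit, r$n_total)
  # and with the pathlength roulette disabled
  r2 <- run_white_mc(fx_head_model(), fx_head_probe(), fx_head_musp(),
                     n_photons = 1e4, seed = 9,
                     roulette = c(start_cm = Inf, step_cm = 15,
                                  survival = 0.5))
  audit2 <- with(r2$counts, n_specular + n_escaped_top + n_escaped_other +
                   n_terminated + n_detected)
  expect_identical(audit2, r2$n_total)
})

test_that("energy is conserved: a non-absorbing half-space returns all light", {
  # all photons either come back out of the top or are terminated by the cap;
  # side/bottom escape is made negligible by the model extent
  r <- fx_homog_wmc()
  frac_top <- (r$counts$n_escaped_top + r$counts$n_detected) / r$n_total
  frac_lost <- (r$counts$n_terminated + r$counts$n_escaped_other) / r$n_total
  expect_gt(frac_top + frac_lost + r$counts$n_specular / r$n_total, 0.999)
  expect_gt(frac_top, 0.80)
})

test_that("launch specular fraction matches the normal-incidence Fresnel coefficient", {
  # pencil beam: incidence is exactly normal, n 1.457 -> 1.4
  r <- fx_homog_wmc()
  R0 <- ((1.457 - 1.4) / (1.457 + 1.4))^2
  n <- r$n_total
  expect_lt(abs(r$counts$n_specular - n * R0), 4 * sqrt(n * R0))
})

test_that("stored exit angles respect the acceptance cone", {
  m <- fx_head_model(); p <- fx_head_probe()
  r <- run_white_mc(m, p, fx_head_musp(), n_photons = 6e4, seed = 5,
                    acceptance_na = 0.12)
  expect_gt(nrow(r$records), 0)
  expect_true(all(r$records[, "exit_angle"] <= asin(0.12 / 1.457) + 1e-12))
  # the all-angle run keeps wider angles
  rall <- fx_head_wmc()
  expect_gt(max(rall$records[, "exit_angle"]), asin(0.12 / 1.457))
})

test_that("absorbing run with zero absorption equals the white detection fraction", {
  m <- fx_head_model(); p <- fx_head_probe()
  w <- run_white_mc(m, p, fx_head_musp(), n_photons = 2e4, seed = 21)
  a <- run_absorbing_mc(m, p,
                        mua = c(scalp = 0, skull = 0, csf = 0, gm = 0, wm = 0),
                        musp = fx_head_musp(), n_photons = 2e4, seed = 21)
  expect_equal(a$reflectance, w$per_det$sum_w / w$n_total)
})

test_that("reflectance is monotone non-increasing in any compartment absorption", {
  r <- fx_head_wmc()
  base <- c(scalp = 0.2, skull = 0.1, csf = 0.03, gm = 0.15, wm = 0.075)
  sweep_mua <- function(cmp, values) {
    M <- matrix(rep(base, each = length(values)), ncol = 5,
                dimnames = list(NULL, names(base)))
    M[, cmp] <- values
    wmc_reflectance(r, M)
  }
  for (cmp in c("scalp", "skull", "gm")) {
    R <- sweep_mua(cmp, seq(0.05, 0.45, length.out = 9))
    expect_true(all(diff(R[, "d2"]) <= 0))
    expect_true(all(diff(R[, "d4"]) <= 0))
  }
})

test_that("low-scattering CSF acts as a light channel", {
  # absorption-weighted partial pathlengths at head-like absorption: photons
  # detected at 2-3 cm travel farther inside a mu_s' = 1 CSF layer than
  # inside a mu_s' = 10 replacement
  m <- fx_head_model(); p <- fx_head_probe()
  musp_lo <- fx_head_musp(); musp_lo["csf"] <- 1
  musp_hi <- fx_head_musp(); musp_hi["csf"] <- 10
  lo <- run_white_mc(m, p, musp_lo, n_photons = 1.2e5, seed = 31)
  hi <- run_white_mc(m, p, musp_hi, n_photons = 1.2e5, seed = 31)
  mua <- c(scalp = 0.2, skull = 0.12, csf = 0.03, gm = 0.18, wm = 0.09)
  for (det in c(3, 4)) {
    pl_lo <- mean_partial_pathlength(lo, mua, detector = det)
    pl_hi <- mean_partial_pathlength(hi, mua, detector = det)
    expect_gt(pl_lo[["csf"]], pl_hi[["csf"]])
  }
})

test_that("partial pathlengths behave physically", {
  r <- fx_head_wmc()
  mua0 <- c(scalp = 0, skull = 0, csf = 0, gm = 0, wm = 0)
  # zero absorption: the weighted mean reduces to the plain weighted average
  rec <- r$records[r$records[, "det"] == 2, ]
  manual <- colSums(rec[, paste0("pl_", c("scalp", "skull", "csf", "gm",
                                          "wm"))] * rec[, "w0"]) /
    sum(rec[, "w0"])
  expect_equal(unname(mean_partial_pathlength(r, mua0, 2)), unname(manual))
  # gray-matter pathlength grows with separation (depth sensitivity)
  pl_gm <- vapply(c(1, 3, 4), function(d) {
    mean_partial_pathlength(r, mua0, d)[["gm"]]
  }, numeric(1))
  expect_true(all(diff(pl_gm) > 0))
  expect_error(mean_partial_pathlength(r, mua0, 99), "no detected photons")
})

test_that("a detector with no photons warns instead of failing", {
  m <- build_slab_model(c(scalp = Inf), dims_vox = c(60L, 60L, 30L))
  p <- place_probe(m, sds_cm = c(0.8, 2.5), anchor_mm = c(27.9, 27.9))
  expect_warning(
    run_absorbing_mc(m, p, mua = c(scalp = 0.6, skull = 0.4, csf = 0.1,
                                   gm = 0.5, wm = 0.25),
                     musp = fx_musp10(), n_photons = 200, seed = 2),
    "zero detected photons")
})

test_that("record thinning preserves weighted sums unbiasedly", {
  r <- fx_head_wmc()
  thin <- thin_records(r, 500, seed = 1)
  expect_true(all(table(thin$records[, "det"]) <= 500))
  R_full <- wmc_reflectance(r, c(scalp = 0.2, skull = 0.1, csf = 0.03,
                                 gm = 0.15, wm = 0.075))
  R_thin <- wmc_reflectance(thin, c(scalp = 0.2, skull = 0.1, csf = 0.03,
                                    gm = 0.15, wm = 0.075))
  expect_equal(as.vector(R_thin[, "d1"]), as.vector(R_full[, "d1"]),
               tolerance = 0.15)
})
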