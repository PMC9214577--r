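test_that("grid bookkeeping matches the published construction", {
  expect_identical(n_combinations(musp_grid()), 2808)
  desk <- musp_grid(list(scalp = c(5, 20, 35), skull = c(5, 20, 35),
                         csf = c(1, 3.7), gm = c(5, 35)))
  expect_identical(n_combinations(desk), 36)
  expect_error(musp_grid(list(scalp = c(10, 5))), "strictly increasing")
  combos <- grid_combinations(desk)
  expect_identical(nrow(combos), 36L)
  expect_identical(names(combos),
                   c("musp_scalp", "musp_skull", "musp_csf", "musp_gm"))
})

test_that("Beer-Lambert rescaling has its closed-form limits", {
  # mua = 0 recovers the detection fraction exactly
  r <- fx_head_wmc()
  R0 <- wmc_reflectance(r, c(scalp = 0, skull = 0, csf = 0, gm = 0, wm = 0))
  expect_equal(as.vector(R0), r$per_det$sum_w / r$n_total)
  # single photon, 1 cm in scalp, mua_scalp = 0.3 -> exp(-0.3)/N
  one <- fake_wmc(fake_records(1, matrix(c(1, 0, 0, 0, 0), 1)), n_total = 50)
  R <- wmc_reflectance(one, c(scalp = 0.3, skull = 1, csf = 1, gm = 1, wm = 1))
  expect_equal(as.vector(R), c(exp(-0.3) / 50, 0))
  expect_error(wmc_reflectance(one, c(scalp = -0.1, skull = 0, csf = 0,
                                      gm = 0, wm = 0)), "non-negative")
  expect_error(wmc_reflectance(one, c(scalp = 0.3)), "columns")
})

test_that("log-reflectance is non-increasing and convex along each absorption axis", {
  r <- fx_head_wmc()
  for (cmp in c("scalp", "skull", "gm")) {
    mu <- seq(0.05, 0.5, length.out = 12)
    M <- matrix(0.1, length(mu), 5,
                dimnames = list(NULL, c("scalp", "skull", "csf", "gm", "wm")))
    M[, cmp] <- mu
    lR <- log(wmc_reflectance(r, M)[, "d2"])
    expect_true(all(diff(lR) < 0))
    expect_true(all(diff(diff(lR)) > -1e-8))  # convex up to numerical noise
  }
})

test_that("lookup-table construction is deterministic and sized by its grid", {
  m <- build_slab_model(c(scalp = Inf), dims_vox = c(60L, 60L, 30L))
  p <- place_probe(m, sds_cm = c(0.8, 1.5), anchor_mm = c(27.9, 27.9))
  g <- musp_grid(list(scalp = c(8, 20, 32)))
  lut1 <- build_lookup_table(m, p, g, n_photons = 4000, seed = 11)
  lut2 <- build_lookup_table(m, p, g, n_photons = 4000, seed = 11)
  expect_identical(length(lut1$entries), 3L)
  expect_identical(lut1$entries[[2]]$records, lut2$entries[[2]]$records)
})

test_that("interpolation reproduces stored nodes exactly and inherits monotonicity", {
  lut <- fx_phantom_lut()
  mua <- c(scalp = 0.25, skull = 0.12, csf = 0.05, gm = 0.15, wm = 0.075)
  k <- 7
  node_val <- wmc_reflectance(lut$entries[[k]], mua)
  interp <- interpolate_reflectance(lut, grid_combinations(lut$grid)[k, ], mua)
  expect_equal(as.vector(interp), as.vector(node_val), tolerance = 1e-12)
  # outside the hull: refused
  expect_error(interpolate_reflectance(
    lut, c(musp_scalp = 40, musp_skull = 20, musp_gm = 20), mua), "hull")
  # monotone decreasing in scalp absorption at a fixed off-node query
  q <- tibble::tibble(musp_scalp = 18, musp_skull = 14, musp_gm = 22)
  vals <- vapply(seq(0.1, 0.5, length.out = 6), function(ma) {
    mm <- mua; mm["scalp"] <- ma
    interpolate_reflectance(lut, q, mm)[, "d2"]
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("NA conversion fits, clips, and applies as specified", {
  set.seed(1)
  # constant-ratio synthetic pairs: intercept-only model recovers the ratio
  pairs <- tibble::tibble(
    ratio = rep(0.4, 40), log_R = rnorm(40), log_N = rnorm(40),
    mua_scalp = runif(40), mua_skull = runif(40),
    musp_scalp = 20, musp_skull = 20)
  pairs$ratio <- 0.4
  m <- fit_na_conversion(pairs)
  expect_equal(as.numeric(predict_na_ratio(m, pairs[1:5, ])), rep(0.4, 5),
               tolerance = 1e-8)
  expect_equal(apply_na_conversion(m, c(2, 3), pairs[1:2, ]),
               0.4 * c(2, 3), tolerance = 1e-8)
  expect_error(apply_na_conversion(m, c(-1, 2), pairs[1:2, ]), "positive")
  # predictions outside (0, 1] are clipped and counted
  pairs2 <- pairs
  pairs2$ratio <- pmin(pmax(2 * pairs2$log_R, 1e-3), 2)  # force wild fit
  m2 <- fit_na_conversion(pairs2)
  far <- pairs2[1:40, ]; far$log_R <- far$log_R + 10
  r <- predict_na_ratio(m2, far)
  expect_true(all(r > 0 & r <= 1))
  expect_gt(attr(r, "n_clipped"), 0)
  expect_error(fit_na_conversion(pairs[1:10, ]), "at least 30")
})

test_that("NA conversion agrees with direct low-NA simulation within MC noise", {
  m <- fx_head_model(); p <- fx_head_probe()
  musp <- fx_head_musp()
  high <- run_white_mc(m, p, musp, n_photons = 2e5, seed = 61,
                       acceptance_na = 1.0)
  low <- run_white_mc(m, p, musp, n_photons = 2e5, seed = 62,
                      acceptance_na = 0.12)
  set.seed(5)
  mua <- headfit:::sample_mua(40, c("scalp", "skull", "csf", "gm"))
  pairs <- na_conversion_pairs(high, low, mua, musp, detectors = 1:2)
  fit <- fit_na_conversion(pairs)
  expect_gt(fit$r_squared, 0.3)
  # held-out absorption sets: converted reflectance tracks the direct low-NA
  # simulation to within the combined Monte Carlo noise at the near detector
  mua_new <- headfit:::sample_mua(25, c("scalp", "skull", "csf", "gm"))
  Rh <- wmc_reflectance(high, mua_new)
  direct <- wmc_reflectance(low, mua_new, se = TRUE)
  feats <- tibble::tibble(
    log_R = log(Rh[, "d1"]), log_N = log(high$per_det$n_raw[1]),
    mua_scalp = mua_new[, "scalp"], mua_skull = mua_new[, "skull"],
    musp_scalp = musp[["scalp"]], musp_skull = musp[["skull"]])
  conv <- apply_na_conversion(fit, Rh[, "d1"], feats)
  rel_noise <- stats::median(direct$se[, "d1"] / direct$R[, "d1"]) +
    fit$residual_cv
  expect_lt(stats::median(abs(conv / direct$R[, "d1"] - 1)), 3 * rel_noise)
})

test_that("training-set bookkeeping is exact at both scales", {
  expect_identical(training_set_size(musp_grid(), 3000, 3000), 17424000)
  desk <- musp_grid(list(scalp = c(5, 20, 35), skull = c(5, 20, 35),
                         csf = c(1, 3.7), gm = c(5, 35)))
  expect_identical(training_set_size(desk, 100, 50), 8600)
})

test_that("generated training rows honor composition, splits, and determinism", {
  lut <- fx_phantom_lut()
  ts1 <- generate_training_set(lut, n_mua = 40, n_musp_extra = 10, seed = 3)
  ts2 <- generate_training_set(lut, n_mua = 40, n_musp_extra = 10, seed = 3)
  expect_equal(as.data.frame(ts1), as.data.frame(ts2))
  expected <- training_set_size(lut$grid, 40, 10)
  expect_lte(nrow(ts1), expected)
  expect_gte(nrow(ts1), 0.90 * expected)   # only non-positive rows drop
  split <- table(ts1$split)
  n <- nrow(ts1)
  expect_equal(as.numeric(split[c("train", "val", "test")]) / n,
               c(0.75, 0.10, 0.15), tolerance = 4 / n)
  expect_true(all(as.matrix(ts1[grep("^d", names(ts1))]) > 0))
  # white-matter coupling in the sampled absorption
  expect_error(generate_training_set(lut, n_mua = 0), "n_mua")
})

test_that("interpolated and surrogate forwards agree over random in-hull queries", {
  st <- fx_phantom()
  lut <- st$lut
  set.seed(44)
  n <- 100
  q <- headfit:::sample_musp(n, lut$grid)
  mua <- headfit:::sample_mua(n, names(lut$grid$nodes))
  interp <- interpolate_reflectance(lut, q, mua)
  op <- cbind(mua[, names(lut$grid$nodes)], as.matrix(q))
  colnames(op) <- c(paste0("mua_", names(lut$grid$nodes)), names(q))
  surr <- predict_reflectance(st$surrogate, op)
  # agreement within the surrogate's own validation error, per detector
  for (j in seq_len(ncol(surr))) {
    rel <- surr[, j] / interp[, j] - 1
    tol <- max(3 * st$surrogate$test_rms_pct[j] / 100, 0.05)
    expect_lt(stats::median(abs(rel)), tol)
  }
})
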