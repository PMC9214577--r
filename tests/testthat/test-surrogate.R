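# synthetic log-linear training set: exactly representable reflectance model,
# so surrogate error is pure optimization error
synthetic_training <- function(n = 4000, ndet = 3, seed = 2, bscale = 0.2) {
  set.seed(seed)
  comps <- c("scalp", "skull", "gm")
  X <- cbind(matrix(runif(n * 3, 0.05, 0.5), n, 3),
             matrix(runif(n * 3, 5, 35), n, 3))
  colnames(X) <- c(paste0("mua_", comps), paste0("musp_", comps))
  B <- matrix(c(-8, -2, -1, 0.02, 0.01, 0.005,
                -10, -4, -2, 0.03, 0.02, 0.01,
                -12, -5, -4, 0.02, 0.03, 0.02), 6, ndet)
  R <- exp(matrix(rep(c(-3, -5, -7), each = n), n, ndet) +
           scale(X) %*% (B * bscale))
  colnames(R) <- paste0("d", seq_len(ndet))
  out <- tibble::as_tibble(cbind(X, R))
  out$split <- sample(rep(c("train", "val", "test"), headfit:::round_split(
    n, c(train = 0.75, val = 0.10, test = 0.15))))
  attr(out, "compartments") <- comps
  out
}

test_that("the surrogate learns an exactly representable forward map to <1%", {
  ts <- synthetic_training(bscale = 0.1)
  m <- train_surrogate(ts, hidden = c(16, 16), epochs = 1000, lr = 1e-2,
                       patience = 150, seed = 1)
  expect_true(all(m$test_rms_pct < 1))
})

test_that("training is reproducible under a fixed seed", {
  ts <- synthetic_training(n = 1500)
  m1 <- train_surrogate(ts, hidden = c(16, 16), epochs = 30, seed = 4)
  m2 <- train_surrogate(ts, hidden = c(16, 16), epochs = 30, seed = 4)
  expect_identical(m1$test_rms_pct, m2$test_rms_pct)
  expect_identical(m1$net$W, m2$net$W)
})

test_that("a constant target is predicted as that constant everywhere", {
  ts <- synthetic_training(n = 1200)
  for (d in grep("^d", names(ts), value = TRUE)) ts[[d]] <- 3.7e-4
  m <- train_surrogate(ts, hidden = c(8, 8), epochs = 150, seed = 3)
  p <- predict_reflectance(m, ts[sample(nrow(ts), 50), m$in_cols])
  expect_equal(as.vector(p), rep(3.7e-4, 150), tolerance = 1e-3)
})

test_that("batched prediction equals elementwise prediction", {
  ts <- synthetic_training(n = 1500)
  m <- train_surrogate(ts, hidden = c(16, 16), epochs = 30, seed = 4)
  X <- ts[1:100, m$in_cols]
  batched <- predict_reflectance(m, X)
  singles <- t(vapply(seq_len(100), function(i) {
    predict_reflectance(m, unlist(X[i, ]))[1, ]
  }, numeric(length(m$out_cols))))
  expect_equal(batched, singles, tolerance = 1e-12)
  expect_error(predict_reflectance(m, c(mua_scalp = NaN)), "non-finite")
})

test_that("JSON serialization round-trips predictions bit-exactly", {
  ts <- synthetic_training(n = 1500)
  m <- train_surrogate(ts, hidden = c(16, 16), epochs = 30, seed = 4)
  path <- file.path(tempdir(), "surrogate.json")
  write_surrogate(m, path)
  m2 <- read_surrogate(path)
  X <- ts[1:50, m$in_cols]
  expect_identical(predict_reflectance(m, X), predict_reflectance(m2, X))
})

test_that("tidy and glance summarize the trained model", {
  ts <- synthetic_training(n = 1500)
  m <- train_surrogate(ts, hidden = c(16, 16), epochs = 30, seed = 4)
  td <- tidy(m)
  expect_identical(td$detector, m$out_cols)
  g <- glance(m)
  expect_identical(g$layers, "6-16-16-3")
  expect_true(is.finite(g$mean_test_rms_pct))
})

test_that("surrogate throughput supports the inverse loop", {
  ts <- synthetic_training(n = 1500)
  m <- train_surrogate(ts, hidden = c(64, 64), epochs = 20, seed = 4)
  X <- as.matrix(ts[sample(nrow(ts), 1000, replace = TRUE), m$in_cols])
  t0 <- proc.time()
  for (i in 1:20) predict_reflectance(m, X)
  dt <- (proc.time() - t0)[3]
  expect_gt(20 * 1000 / dt, 1e4)  # >= 10^4 queries per second
})

test_that("the phantom surrogate reproduces direct Monte Carlo within 10% across SDS", {
  st <- fx_phantom()
  model <- build_slab_model(c(scalp = 4, skull = 6, gm = Inf),
                            dims_vox = c(96L, 96L, 64L))
  probe <- place_probe(model, sds_cm = c(0.8, 1.5, 2.12, 3),
                       anchor_mm = c(44.64, 44.64))
  params <- list(
    tissue_params(),
    tissue_params(scalp = list(tHB = 9e-5, A = 2.5e4),
                  gm = list(tHB = 5e-5, A = 1.1e4)),
    tissue_params(skull = list(tHB = 6e-5, StO2 = 0.8),
                  gm = list(A = 5.8e3, K = 0.9)))
  val <- validate_surrogate(st$surrogate, model, probe, params,
                            wavelengths = c(720, 800, 870),
                            n_photons = 8e4,
                            annulus_halfwidth_cm = c(0.15, 0.2, 0.3, 0.5))
  expect_identical(nrow(val), 4L)
  expect_true(all(is.finite(val$rms_pct)))
  # at the suite's photon budget the 3 cm channel is shot-noise limited
  # (its lookup nodes carry ~10% statistical error); the nearer channels
  # must reproduce direct MC closely and the overall mean stay bounded
  expect_true(all(val$rms_pct[val$sds_cm <= 1.6] < 10))
  expect_lt(mean(val$rms_pct), 20)
})
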