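# Shared fixtures, built lazily and memoized for the whole test run. The
# expensive ones (Monte Carlo runs, the phantom pipeline) are reused across
# test files to keep the suite inside a sane time budget.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_lib <- function() fixture("lib", chromophore_library)

# homogeneous semi-infinite medium (all scalp), wide enough for SDS 4.5 cm
# radial scoring
fx_homog_model <- function() fixture("homog_model", function() {
  build_slab_model(c(scalp = Inf), dims_vox = c(140L, 140L, 64L))
})

fx_homog_probe <- function() fixture("homog_probe", function() {
  place_probe(fx_homog_model(), anchor_mm = c(65.1, 65.1))
})

# the oracle pair for the white-MC equivalence and diffusion checks:
# musp' = 10 1/cm everywhere
fx_musp10 <- function() {
  c(scalp = 10, skull = 10, csf = 10, gm = 10, wm = 10)
}

fx_homog_annulus <- function() c(0.15, 0.15, 0.2, 0.2, 0.25, 0.25)

fx_homog_wmc <- function() fixture("homog_wmc", function() {
  run_white_mc(fx_homog_model(), fx_homog_probe(), fx_musp10(),
               n_photons = 8e5, seed = 42, source_mode = "pencil",
               annulus_halfwidth_cm = fx_homog_annulus())
})

# four-layer head slab (scalp/skull/CSF/GM over WM) with a mid-range white run
fx_head_model <- function() fixture("head_model", function() {
  build_slab_model(c(scalp = 5, skull = 7, csf = 2, gm = 4, wm = Inf),
                   dims_vox = c(118L, 118L, 64L))
})

fx_head_probe <- function() fixture("head_probe", function() {
  place_probe(fx_head_model(), anchor_mm = c(54.9, 54.9))
})

fx_head_musp <- function() {
  c(scalp = 15, skull = 16, csf = 2.4, gm = 9, wm = 27)
}

fx_head_wmc <- function() fixture("head_wmc", function() {
  run_white_mc(fx_head_model(), fx_head_probe(), fx_head_musp(),
               n_photons = 2e5, seed = 7)
})

# hand-constructed white-MC result with known records, for closed-form checks
fake_wmc <- function(records, n_total, sds = c(0.8, 1.5)) {
  per_det <- tibble::tibble(
    id = seq_along(sds), sds_cm = sds,
    n_raw = vapply(seq_along(sds),
                   function(i) sum(records[, "det"] == i), numeric(1)),
    sum_w = vapply(seq_along(sds), function(i) {
      sum(records[records[, "det"] == i, "w0"])
    }, numeric(1)),
    sum_w2 = 0)
  structure(list(records = records, n_total = n_total, per_det = per_det,
                 counts = list(), musp = NULL, acceptance_na = 1, seed = 0,
                 detect = "discrete", mode = "white"),
            class = "wmc_result")
}

fake_records <- function(det, pl, w0 = 1) {
  m <- cbind(det = det, pl, exit_angle = 0, w0 = w0, wdet = 1)
  colnames(m) <- c("det", "pl_scalp", "pl_skull", "pl_csf", "pl_gm", "pl_wm",
                   "exit_angle", "w0", "wdet")
  m
}

# small three-layer lookup table for interpolation / training-set tests
fx_phantom_lut <- function() fixture("phantom_lut", function() {
  m <- build_slab_model(dims_vox = c(90L, 90L, 48L))
  p <- place_probe(m, anchor_mm = c(41.85, 41.85),
                   sds_cm = c(0.8, 1.5, 2.12, 3))
  g <- musp_grid(list(scalp = c(5, 20, 35), skull = c(5, 20, 35),
                      gm = c(5, 20, 35)))
  build_lookup_table(m, p, g, n_photons = 2.5e4, seed = 17,
                     annulus_halfwidth_cm = c(0.15, 0.2, 0.3, 0.4))
})

# the full desk-scale phantom pipeline (lookup table -> surrogate -> absorbing
# MC targets -> multi-start fit); shared by the recovery, self-consistency,
# ranking, and sensitivity tests
fx_phantom <- function() fixture("phantom", function() {
  phantom_recovery_study(seed = 5, verbose = FALSE)
})

# diffusion-approximation reflectance of a semi-infinite medium (per unit
# area), dipole source with extrapolated boundary; the classical closed form
# used as an independent oracle
diffusion_reflectance <- function(mua, musp, rho_cm, n_rel = 1.4 / 1.457) {
  mut <- mua + musp
  z0 <- 1 / mut
  D <- 1 / (3 * mut)
  mueff <- sqrt(mua / D)
  # effective internal reflection coefficient from Fresnel moments
  th <- seq(0, pi / 2, length.out = 2001)
  fres <- vapply(th, function(a) {
    ci <- cos(a)
    st2 <- (n_rel * sin(a))^2
    if (st2 >= 1) return(1)
    ct <- sqrt(1 - st2)
    rs <- (n_rel * ci - ct) / (n_rel * ci + ct)
    rp <- (n_rel * ct - ci) / (n_rel * ct + ci)
    0.5 * (rs^2 + rp^2)
  }, numeric(1))
  # note n_rel here is n_inside / n_outside viewed from inside
  rphi <- 2 * pracma_trapz(th, fres * sin(th) * cos(th))
  rj <- 3 * pracma_trapz(th, fres * sin(th) * cos(th)^2)
  reff <- (rphi + rj) / (2 - rphi + rj)
  zb <- 2 * D * (1 + reff) / (1 - reff)
  r1 <- sqrt(z0^2 + rho_cm^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho_cm^2)
  (1 / (4 * pi)) * (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
                    (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2)
}

pracma_trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
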