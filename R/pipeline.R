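# End-to-end phantom recovery study: the package's own validation loop.
# Simulate a layered slab with known optical properties using the direct
# absorbing Monte Carlo engine, then recover those properties with the
# lookup-table / surrogate forward model and multi-start curve fitting.

#' Build a flat layered slab model with arbitrary compartments
#'
#' Lighter-weight companion of [build_synthetic_head()] for phantom work: a
#' flat stack of named layers; the last named compartment fills the remaining
#' depth.
#'
#' @param layers_mm named thicknesses in mm, names among `scalp`, `skull`,
#'   `csf`, `gm`, `wm`, `sinus`; use `Inf` (or omit depth) for the last layer.
#' @param dims_vox voxels along (x, y, z).
#' @param voxel_mm voxel edge (mm).
#' @return a `voxel_head_model` (flat surface).
#' @export
build_slab_model <- function(layers_mm = c(scalp = 5, skull = 7, gm = Inf),
                             dims_vox = c(118L, 118L, 64L), voxel_mm = 0.93) {
  stopifnot(all(names(layers_mm) %in% names(HEAD_LABELS)),
            all(layers_mm > 0))
  nx <- dims_vox[1]; ny <- dims_vox[2]; nz <- dims_vox[3]
  zc <- (seq_len(nz) - 0.5) * voxel_mm
  edges <- cumsum(layers_mm)
  lab_z <- integer(nz)
  for (li in seq_along(layers_mm)) {
    code <- HEAD_LABELS[[names(layers_mm)[li]]]
    lower <- if (li == 1) 0 else edges[li - 1]
    lab_z[zc > lower & zc <= edges[li]] <- code
  }
  deepest <- if (any(is.finite(edges))) max(edges[is.finite(edges)]) else 0
  lab_z[zc > deepest] <- HEAD_LABELS[[names(layers_mm)[length(layers_mm)]]]
  labels <- array(rep(lab_z, each = nx * ny), dim = c(nx, ny, nz))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_mm = voxel_mm,
                 surface = list(type = "flat"),
                 label_map = HEAD_LABELS, layers_mm = layers_mm,
                 provenance = list(generator = "build_slab_model",
                                   histogram = table(labels))),
            class = "voxel_head_model")
}

#' Simulate multidistance target spectra with the absorbing Monte Carlo engine
#'
#' One direct absorbing-MC run per wavelength at the optical properties
#' derived from `truth`, the ground-truth generator for recovery studies.
#'
#' @param model,probe geometry.
#' @param truth a [tissue_params()] ground truth.
#' @param lib a [chromophore_library()].
#' @param wavelengths nm.
#' @param n_photons photons per wavelength.
#' @param seed base seed (wavelength i uses `seed + i`).
#' @param ... passed to [run_absorbing_mc()].
#' @return list: `reflectance` (wavelength x detector matrix), `se`, `op`
#'   (truth OP spectra tibble).
#' @export
simulate_target_spectra <- function(model, probe, truth, lib, wavelengths,
                                    n_photons = 2e5, seed = 100L, ...) {
  ops <- params_to_op_spectra(truth, lib, wavelengths)
  ndet <- nrow(probe$detectors)
  R <- matrix(NA_real_, length(wavelengths), ndet,
              dimnames = list(NULL, paste0("d", probe$detectors$id)))
  SE <- R
  for (i in seq_along(wavelengths)) {
    row <- ops[ops$wavelength_nm == wavelengths[i], ]
    mua <- stats::setNames(row$mua[match(COMPARTMENTS, row$compartment)],
                           COMPARTMENTS)
    musp <- stats::setNames(row$musp[match(COMPARTMENTS, row$compartment)],
                            COMPARTMENTS)
    res <- run_absorbing_mc(model, probe, mua, musp, n_photons = n_photons,
                            seed = seed + i, ...)
    R[i, ] <- res$reflectance
    SE[i, ] <- res$se
  }
  list(reflectance = R, se = SE, op = ops)
}

#' Layered-phantom recovery study
#'
#' The full inverse pipeline exercised end to end on a three-layer slab with
#' known optical properties: build the slab, construct the scattering lookup
#' table with white Monte Carlo, generate surrogate training data through the
#' Beer-Lambert rescaling and spline interpolation, train the surrogate, then
#' simulate target spectra with the independent absorbing-MC engine and
#' recover the layer properties by multi-start constrained fitting. Returns
#' per-OP relative errors of the selected solution against the ground truth.
#'
#' All randomness derives from `seed`. Scale knobs trade accuracy against run
#' time; the defaults run a desk-scale study in a few minutes.
#'
#' @param truth ground-truth [tissue_params()].
#' @param layers_mm slab layers (`scalp`, `skull`, `gm` by default).
#' @param wavelengths fit wavelengths.
#' @param grid scattering [musp_grid()] over the slab compartments.
#' @param sds_cm source-detector separations simulated and fitted.
#' @param annulus_halfwidth_cm radial scoring half-widths, one per detector.
#' @param n_photons_node white-MC photons per lookup node.
#' @param n_photons_target absorbing-MC photons per target wavelength.
#' @param n_mua,n_musp_extra training-set composition.
#' @param hidden,epochs surrogate architecture and budget.
#' @param pool_n initial-pool size.
#' @param n_starts,max_iter fitting control.
#' @param fit_detectors,tiebreak_detectors detector split.
#' @param seed master seed.
#' @param lib chromophore library.
#' @param dims_vox,voxel_mm slab discretization.
#' @param verbose progress messages.
#' @return list of class `phantom_study`: `errors` tibble (op, truth, fitted,
#'   rel_error_pct), `max_abs_error_pct`, plus the fitted objects
#'   (`surrogate`, `fits`, `solution`, `target`).
#' @export
phantom_recovery_study <- function(
    truth = tissue_params(),
    layers_mm = c(scalp = 4, skull = 6, gm = Inf),
    wavelengths = fit_wavelengths_default(),
    grid = musp_grid(list(scalp = c(5, 15, 25, 35),
                          skull = c(5, 20, 35),
                          gm = c(5, 20, 35))),
    sds_cm = c(0.8, 1.5, 2.12, 3),
    annulus_halfwidth_cm = c(0.15, 0.2, 0.3, 0.5),
    n_photons_node = 7e4, n_photons_target = 6e4,
    n_mua = 250, n_musp_extra = 150,
    hidden = c(64, 64), epochs = 150,
    pool_n = 1200, n_starts = 20, max_iter = 500,
    fit_detectors = 1:4, tiebreak_detectors = integer(0),
    seed = 1L, lib = chromophore_library(),
    dims_vox = c(96L, 96L, 64L), voxel_mm = 0.93,
    verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  model <- build_slab_model(layers_mm, dims_vox, voxel_mm)
  ext <- dims_vox[1:2] * voxel_mm
  probe <- place_probe(model, sds_cm = sds_cm,
                       anchor_mm = c(ext[1] / 2, ext[2] / 2))

  say("building lookup table (%d nodes x %g photons)...",
      n_combinations(grid), n_photons_node)
  lut <- build_lookup_table(model, probe, grid, n_photons = n_photons_node,
                            seed = seed,
                            annulus_halfwidth_cm = annulus_halfwidth_cm)
  say("generating training data (%d rows)...",
      training_set_size(grid, n_mua, n_musp_extra))
  train <- generate_training_set(lut, n_mua = n_mua,
                                 n_musp_extra = n_musp_extra,
                                 seed = seed + 1)
  say("training surrogate...")
  surr <- train_surrogate(train, hidden = hidden, epochs = epochs,
                          seed = seed + 2)
  forward <- surrogate_forward(surr)

  say("simulating target spectra (absorbing MC, %g photons/wavelength)...",
      n_photons_target)
  tgt <- simulate_target_spectra(model, probe, truth, lib, wavelengths,
                                 n_photons = n_photons_target,
                                 seed = seed + 1000,
                                 annulus_halfwidth_cm = annulus_halfwidth_cm)
  target <- fit_target(wavelengths, tgt$reflectance, fit_detectors,
                       tiebreak_detectors)

  say("building initial pool (%d) and fitting (%d starts)...",
      pool_n, n_starts)
  comps <- names(grid$nodes)
  pool <- build_initial_pool(forward, lib, wavelengths, comps,
                             n = pool_n, seed = seed + 3)
  fits <- fit_multistart(target, forward, pool, lib, n_starts = n_starts,
                         max_iter = max_iter)
  sol <- if (length(tiebreak_detectors)) select_solutions(fits)
         else suppressWarnings(select_solutions(fits))
  best <- sol$solutions$params[[1]]

  cd <- chrom_design(lib, wavelengths)
  truth_v <- params_to_vector(truth)
  truth_op <- op_matrix_from_vector(truth_v, cd, comps)
  fitted_op <- op_matrix_from_vector(best, cd, comps)
  op_cols <- colnames(truth_op)
  errors <- tibble::tibble(
    op = op_cols,
    truth = colMeans(truth_op),
    fitted = colMeans(fitted_op),
    rel_error_pct = vapply(op_cols, function(cn) {
      mean((fitted_op[, cn] - truth_op[, cn]) / truth_op[, cn]) * 100
    }, numeric(1)))

  structure(list(
    errors = errors,
    max_abs_error_pct = max(abs(errors$rel_error_pct)),
    surrogate = surr, lut = lut, pool = pool, fits = fits, solution = sol,
    target = target, target_se = tgt$se, truth = truth, model_dims = dims_vox,
    n_photons_node = n_photons_node, n_photons_target = n_photons_target,
    seed = seed
  ), class = "phantom_study")
}

#' Validate a surrogate against direct high-photon Monte Carlo
#'
#' For each supplied tissue-parameter set, runs fresh white Monte Carlo
#' simulations at the parameter set's wavelength-specific scattering, rescales
#' to its absorption through the Beer-Lambert law, and compares against the
#' surrogate's prediction: per-SDS RMS percent error across parameter sets and
#' wavelengths, the error measure used to qualify a surrogate before it
#' enters the inverse loop.
#'
#' @param surrogate a [train_surrogate()] model.
#' @param model,probe the geometry the surrogate was trained for.
#' @param params_list list of [tissue_params()] ground truths (>= 3 for a
#'   meaningful estimate).
#' @param wavelengths wavelengths at which to compare.
#' @param lib chromophore library.
#' @param n_photons photons per direct run.
#' @param seed base seed.
#' @param ... passed to [run_white_mc()] (detection settings should match the
#'   lookup-table construction).
#' @return tibble (detector, sds_cm, rms_pct), plus attribute `"pairs"` with
#'   the per-point comparison.
#' @export
validate_surrogate <- function(surrogate, model, probe, params_list,
                               wavelengths, lib = chromophore_library(),
                               n_photons = 2e5, seed = 9000L, ...) {
  comps <- surrogate$compartments
  cd <- chrom_design(lib, wavelengths)
  pairs <- purrr::map_dfr(seq_along(params_list), function(i) {
    v <- params_to_vector(params_list[[i]])
    op <- op_matrix_from_vector(v, cd, comps)
    pred <- predict_reflectance(surrogate, op)
    ops <- params_to_op_spectra(params_list[[i]], lib, wavelengths)
    purrr::map_dfr(seq_along(wavelengths), function(k) {
      row <- ops[ops$wavelength_nm == wavelengths[k], ]
      mua <- stats::setNames(row$mua[match(COMPARTMENTS, row$compartment)],
                             COMPARTMENTS)
      musp <- stats::setNames(row$musp[match(COMPARTMENTS, row$compartment)],
                              COMPARTMENTS)
      w <- run_white_mc(model, probe, musp, n_photons = n_photons,
                        seed = seed + 100 * i + k, ...)
      tibble::tibble(set = i, wavelength_nm = wavelengths[k],
                     detector = colnames(pred),
                     sds_cm = probe$detectors$sds_cm,
                     mc = as.vector(wmc_reflectance(w, mua)),
                     surrogate = pred[k, ])
    })
  })
  out <- dplyr::summarise(
    dplyr::group_by(pairs, .data$detector, .data$sds_cm),
    rms_pct = sqrt(mean((.data$surrogate / .data$mc - 1)^2)) * 100,
    .groups = "drop")
  attr(out, "pairs") <- pairs
  out
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("Phantom recovery study: max |OP error| = %.1f%%\n",
              x$max_abs_error_pct))
  print(x$errors)
  invisible(x)
}
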