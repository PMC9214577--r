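# R-side interface to the compiled voxel Monte Carlo engine.

COMPARTMENTS <- c("scalp", "skull", "csf", "gm", "wm")

# per-label optical vectors indexed by label code 0..6
label_optics <- function(model, musp, mua = NULL, g = 0.9) {
  musp <- musp[COMPARTMENTS]
  if (anyNA(musp)) stop("musp must name scalp, skull, csf, gm, wm", call. = FALSE)
  if (is.null(mua)) mua <- stats::setNames(rep(0, 5), COMPARTMENTS)
  mua <- mua[COMPARTMENTS]
  if (anyNA(mua)) stop("mua must name scalp, skull, csf, gm, wm", call. = FALSE)
  list(
    mus = c(0, unname(musp) / (1 - g), 0),        # outer, tissues, sinus
    g   = c(0, rep(g, 5), 0),
    n   = c(1.457, rep(1.4, 5), 1.0),
    mua = c(0, unname(mua), 0)
  )
}

mc_call <- function(model, probe, optics, absorbing, n_photons, acceptance_na,
                    seed, detect, annulus_halfwidth_cm, path_cap_cm,
                    source_mode, record_paths, weight_floor = 1e-5,
                    roulette = c(start_cm = 35, step_cm = 15, survival = 0.5)) {
  detect <- match.arg(detect, c("radial", "discrete"))
  if (detect == "radial" && model$surface$type != "flat") {
    stop("radial detection assumes a laterally invariant flat model; ",
         "use detect = \"discrete\" for curved surfaces", call. = FALSE)
  }
  source_mode <- match.arg(source_mode, c("disc", "pencil"))
  d <- probe$detectors
  det_info <- cbind(d$x_mm / 10, d$y_mm / 10, d$z_mm / 10,
                    d$nx, d$ny, d$nz, d$radius_mm / 10, d$sds_cm)
  src_pos <- probe$source$pos_mm / 10
  src_normal_in <- -probe$source$normal
  src_radius <- if (source_mode == "pencil") 0 else probe$source$radius_mm / 10
  src_na <- if (source_mode == "pencil") 0 else probe$source$na
  .mc_run_cpp(as.integer(model$labels), dim(model$labels),
              model$voxel_mm / 10,
              optics$mus, optics$g, optics$n, optics$mua, absorbing,
              src_pos, src_normal_in, src_radius, src_na, probe$n_fiber,
              det_info, acceptance_na,
              if (detect == "radial") 1L else 0L,
              rep_len(annulus_halfwidth_cm, nrow(d)),
              n_photons, seed, path_cap_cm,
              -log(weight_floor),
              model$surface$type == "flat", record_paths,
              roulette[["start_cm"]], roulette[["step_cm"]],
              roulette[["survival"]])
}

#' Run a white Monte Carlo simulation
#'
#' Launches photons with all absorption set to zero and records, for every
#' photon accepted by a detector, its pathlength in each tissue compartment.
#' Reflectance for any absorption combination is recovered afterwards with
#' [wmc_reflectance()] via the microscopic Beer-Lambert law, which is what
#' makes one scattering-only simulation reusable across the whole absorption
#' range.
#'
#' Detection modes: `"discrete"` tests each exiting photon against the literal
#' detector footprints and acceptance cones; `"radial"` (flat models only)
#' exploits lateral invariance by scoring the exit displacement from the
#' launch point into an annulus around each source-detector separation, with
#' the statistical weight `w0 = r_det^2 / (4 * sds * halfwidth)` that converts
#' annulus counts to detector-footprint counts. Radial scoring raises the
#' effective photon economy by orders of magnitude and is the default for
#' slab work.
#'
#' @param model a [build_synthetic_head()] model (or any voxel head model).
#' @param probe a [place_probe()] layout.
#' @param musp named transport scattering (1/cm) for `scalp`, `skull`, `csf`,
#'   `gm`, `wm`.
#' @param n_photons photons to launch.
#' @param acceptance_na detector numerical aperture; `>= 1` accepts all exit
#'   angles (the lookup-table acceleration mode).
#' @param seed integer; photons use counter-based streams derived from it, so
#'   results are bit-reproducible.
#' @param detect `"radial"` or `"discrete"`.
#' @param annulus_halfwidth_cm half-width of the radial scoring annulus (cm);
#'   the effective half-width is `max(detector radius, this)`.
#' @param path_cap_cm photons are terminated once their cumulative pathlength
#'   exceeds this cap; at the smallest tissue absorption of interest the
#'   discarded tail carries negligible Beer-Lambert weight.
#' @param source_mode `"disc"` (the fiber bundle footprint and launch NA) or
#'   `"pencil"` (point, normal incidence; used by oracle tests).
#' @param g anisotropy factor of all tissues.
#' @param record_paths keep per-photon pathlength records (required for
#'   [wmc_reflectance()]).
#' @param roulette pathlength roulette: beyond `start_cm` of cumulative path,
#'   photons survive checkpoints every `step_cm` with probability `survival`
#'   and carry the compensating `1/survival` statistical weight. Unbiased;
#'   set `start_cm = Inf` to disable (used by the energy-audit oracle).
#' @return object of class `wmc_result`.
#' @export
run_white_mc <- function(model, probe, musp, n_photons = 1e5,
                         acceptance_na = 1.0, seed = 1L,
                         detect = c("radial", "discrete"),
                         annulus_halfwidth_cm = 0.15, path_cap_cm = 150,
                         source_mode = c("disc", "pencil"), g = 0.9,
                         record_paths = TRUE,
                         roulette = c(start_cm = 35, step_cm = 15,
                                      survival = 0.5)) {
  stopifnot(n_photons >= 1)
  optics <- label_optics(model, musp, g = g)
  raw <- mc_call(model, probe, optics, absorbing = FALSE, n_photons,
                 acceptance_na, seed, detect, annulus_halfwidth_cm,
                 path_cap_cm, source_mode, record_paths, roulette = roulette)
  structure(list(
    records = raw$records,
    n_total = raw$n_total,
    per_det = tibble::tibble(
      id = probe$detectors$id, sds_cm = probe$detectors$sds_cm,
      n_raw = raw$det_raw, sum_w = raw$det_sum_w, sum_w2 = raw$det_sum_w2),
    counts = raw[c("n_specular", "n_escaped_top", "n_escaped_other",
                   "n_terminated", "n_detected")],
    musp = musp, g = g, acceptance_na = acceptance_na, seed = seed,
    detect = match.arg(detect), path_cap_cm = path_cap_cm,
    mode = "white"
  ), class = "wmc_result")
}

#' @export
print.wmc_result <- function(x, ...) {
  cat(sprintf("White MC: %g photons, NA=%g, %s detection, seed %d\n",
              x$n_total, x$acceptance_na, x$detect, x$seed))
  print(x$per_det)
  invisible(x)
}

#' Run a direct absorbing Monte Carlo simulation
#'
#' Same transport as [run_white_mc()] but each photon carries a continuous
#' Beer-Lambert weight `exp(-mua * s)` accumulated along its path (with
#' Russian-roulette termination once the weight falls below `weight_floor`),
#' and the per-detector reflectance is the summed detected weight over the
#' number launched. This is the direct oracle that the white-MC rescaling must
#' reproduce.
#'
#' @inheritParams run_white_mc
#' @param mua named absorption (1/cm) for `scalp`, `skull`, `csf`, `gm`, `wm`.
#' @param weight_floor roulette threshold on the Beer-Lambert weight.
#' @return tibble (id, sds_cm, reflectance, se, n_raw) with attribute
#'   `counts`; `se` is the Monte Carlo standard error of the reflectance.
#' @export
run_absorbing_mc <- function(model, probe, mua, musp, n_photons = 1e5,
                             acceptance_na = 1.0, seed = 1L,
                             detect = c("radial", "discrete"),
                             annulus_halfwidth_cm = 0.15, path_cap_cm = 150,
                             source_mode = c("disc", "pencil"), g = 0.9,
                             weight_floor = 1e-5,
                             roulette = c(start_cm = 35, step_cm = 15,
                                          survival = 0.5)) {
  stopifnot(n_photons >= 1, all(mua >= 0))
  optics <- label_optics(model, musp, mua = mua, g = g)
  raw <- mc_call(model, probe, optics, absorbing = TRUE, n_photons,
                 acceptance_na, seed, detect, annulus_halfwidth_cm,
                 path_cap_cm, source_mode, record_paths = FALSE,
                 weight_floor = weight_floor, roulette = roulette)
  n <- raw$n_total
  out <- tibble::tibble(
    id = probe$detectors$id, sds_cm = probe$detectors$sds_cm,
    reflectance = raw$det_sum_w / n,
    se = sqrt(pmax(raw$det_sum_w2 / n - (raw$det_sum_w / n)^2, 0) / n),
    n_raw = raw$det_raw)
  if (any(out$n_raw == 0)) {
    warning("zero detected photons at detector(s) ",
            paste(out$id[out$n_raw == 0], collapse = ", "), call. = FALSE)
  }
  attr(out, "counts") <- raw[c("n_specular", "n_escaped_top",
                               "n_escaped_other", "n_terminated",
                               "n_detected")]
  attr(out, "n_total") <- n
  out
}

#' Absorption-weighted mean partial pathlengths
#'
#' For one detector, the mean pathlength of detected photons in each tissue
#' compartment, weighted by their Beer-Lambert attenuation at the supplied
#' absorption. This equals the negative derivative of log-reflectance with
#' respect to that compartment's absorption, the quantity that converts
#' intensity changes into chromophore concentration changes.
#'
#' @param result a [run_white_mc()] result with path records.
#' @param mua named absorption (1/cm) per compartment; zeros give the
#'   unweighted mean.
#' @param detector detector id.
#' @return named numeric, mean pathlength (cm) per compartment.
#' @export
mean_partial_pathlength <- function(result, mua, detector) {
  stopifnot(inherits(result, "wmc_result"))
  rec <- result$records[result$records[, "det"] == detector, , drop = FALSE]
  if (nrow(rec) == 0) stop("no detected photons at detector ", detector,
                           call. = FALSE)
  pl <- rec[, paste0("pl_", COMPARTMENTS), drop = FALSE]
  mua <- mua[COMPARTMENTS]
  if (anyNA(mua)) stop("mua must name all five compartments", call. = FALSE)
  w <- rec[, "w0"] * exp(-as.vector(pl %*% unname(mua)))
  stats::setNames(as.vector(colSums(pl * w) / sum(w)), COMPARTMENTS)
}

#' Thin the photon records of a white MC result
#'
#' Uniformly subsamples each detector's records to at most `max_per_detector`,
#' scaling the statistical weights so all weighted sums stay unbiased. Useful
#' to bound the cost of repeated Beer-Lambert rescaling over large lookup
#' tables.
#'
#' @param result a `wmc_result`.
#' @param max_per_detector record cap per detector.
#' @param seed RNG seed for the subsample.
#' @return a `wmc_result` with thinned records (aggregate statistics in
#'   `per_det` are recomputed from the thinned records).
#' @export
thin_records <- function(result, max_per_detector, seed = 1L) {
  set.seed(seed)
  rec <- result$records
  keep <- unlist(lapply(unique(rec[, "det"]), function(dd) {
    idx <- which(rec[, "det"] == dd)
    if (length(idx) <= max_per_detector) return(idx)
    s <- sample(idx, max_per_detector)
    rec[s, "w0"] <<- rec[s, "w0"] * length(idx) / max_per_detector
    s
  }))
  result$records <- rec[sort(keep), , drop = FALSE]
  for (i in seq_len(nrow(result$per_det))) {
    ri <- result$records[result$records[, "det"] == result$per_det$id[i], ,
                         drop = FALSE]
    result$per_det$sum_w[i] <- sum(ri[, "w0"] * ri[, "wdet"])
    result$per_det$sum_w2[i] <- sum((ri[, "w0"] * ri[, "wdet"])^2)
  }
  result
}
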