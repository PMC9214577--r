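# Uncertainty quantification: noisy synthetic test spectra, error
# distributions with empirical confidence intervals, detector sensitivity,
# and validation of the spectral-error ranking.

#' Per-detector noise model of the instrument
#'
#' Multiplicative reflectance noise with a coefficient of variation per
#' source-detector separation; the defaults are the values estimated from
#' repeated in-vivo forehead measurements at the six separations.
#'
#' @param cv_pct CVs in percent, one per detector.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(cv_pct = c(3.0, 4.2, 5.1, 5.2, 5.4, 12.1)) {
  stopifnot(all(cv_pct >= 0))
  structure(list(cv = cv_pct / 100), class = "noise_model")
}

# mean-one lognormal factors with the requested CV
lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Generate noisy synthetic test spectra
#'
#' Draws `n_param` tissue-parameter sets uniformly inside the bounds (subject
#' to the optical-property range constraint), simulates their noiseless
#' spectra with the forward model, and attaches `n_noise` noisy replicates per
#' set: independent mean-one lognormal factors per detector and wavelength
#' with the per-detector CVs of `noise` (optionally a shared factor across
#' wavelengths, emulating coupling drift). At the published scale,
#' 15 parameter sets x 14 noise sets give 210 noisy spectra per subject.
#'
#' @param forward forward function (see [spectra_from_vector()]).
#' @param lib a [chromophore_library()].
#' @param wavelengths fit wavelengths.
#' @param compartments forward-model compartments.
#' @param noise a [noise_model()].
#' @param n_param parameter sets.
#' @param n_noise noisy replicates per set (a noiseless copy is always kept).
#' @param correlated share one noise factor across wavelengths per detector.
#' @param seed RNG seed.
#' @return object of class `test_spectra_set`: tibble `sets` (one row per
#'   parameter set: truth vector, truth OP matrix, noiseless spectra) and
#'   tibble `replicates` (set, replicate, spectra matrix list-column).
#' @export
generate_test_spectra <- function(forward, lib, wavelengths, compartments,
                                  noise = noise_model(), n_param = 15,
                                  n_noise = 14, correlated = FALSE,
                                  seed = 1L) {
  stopifnot(n_param >= 1, n_noise >= 0)
  pool <- build_initial_pool(forward, lib, wavelengths, compartments,
                             n = max(n_param, 20), seed = seed)
  cd <- chrom_design(lib, wavelengths)
  set.seed(seed + 1)
  sets <- tibble::tibble(
    set = seq_len(n_param),
    truth = lapply(seq_len(n_param), function(i) pool$params[i, ]),
    op = lapply(seq_len(n_param), function(i) {
      op_matrix_from_vector(pool$params[i, ], cd, compartments)
    }),
    clean = lapply(seq_len(n_param), function(i) {
      pool$spectra[i, , , drop = TRUE]
    }))
  ndet <- dim(pool$spectra)[3]
  nwl <- length(wavelengths)
  if (length(noise$cv) < ndet) stop("noise model has too few detectors",
                                    call. = FALSE)
  replicates <- purrr::map_dfr(seq_len(n_param), function(i) {
    reps <- lapply(seq_len(n_noise), function(r) {
      fac <- vapply(seq_len(ndet), function(j) {
        if (correlated) rep(lognormal_factors(1, noise$cv[j]), nwl)
        else lognormal_factors(nwl, noise$cv[j])
      }, numeric(nwl))
      sets$clean[[i]] * fac
    })
    tibble::tibble(set = i, replicate = seq_len(n_noise), spectra = reps)
  })
  structure(list(sets = sets, replicates = replicates,
                 wavelengths = wavelengths, compartments = compartments,
                 noise = noise, seed = seed),
            class = "test_spectra_set")
}

#' @export
print.test_spectra_set <- function(x, ...) {
  cat(sprintf("Test spectra: %d parameter sets x %d noisy replicates (+1 noiseless each)\n",
              nrow(x$sets), max(x$replicates$replicate, 0)))
  invisible(x)
}

# relative OP errors (%) of a fitted parameter vector against a truth OP
# matrix, averaged over the fit wavelengths, one value per OP column
op_relative_errors <- function(v, truth_op, cd, compartments) {
  est <- op_matrix_from_vector(v, cd, compartments)
  cols <- colnames(truth_op)
  cols <- cols[!grepl("csf", cols)]  # CSF is fixed, never fitted
  vapply(cols, function(cn) {
    mean((est[, cn] - truth_op[, cn]) / truth_op[, cn]) * 100
  }, numeric(1))
}

#' Compile error distributions and confidence intervals
#'
#' Pools relative errors of each fitted optical property across many fits
#' (multiple solutions enter as separate data points), and reports empirical
#' central intervals: the 68% interval is the 16th--84th percentile range of
#' the pooled errors, the 95% interval the 2.5th--97.5th.
#'
#' @param fits tibble with list-columns `params` (fitted vectors) and `truth_op`
#'   (matching truth OP matrices); see [fit_test_spectra()].
#' @param lib a [chromophore_library()].
#' @param wavelengths fit wavelengths.
#' @param compartments forward-model compartments.
#' @param levels confidence levels.
#' @return object of class `error_distribution`: tibble `samples` (long) and
#'   tibble `intervals` (op, level, lo, hi).
#' @export
compile_confidence_intervals <- function(fits, lib, wavelengths, compartments,
                                         levels = c(0.68, 0.95)) {
  stopifnot(nrow(fits) >= 1)
  if (nrow(fits) < 10) {
    warning("fewer than 10 fits; intervals will be unstable", call. = FALSE)
  }
  cd <- chrom_design(lib, wavelengths)
  samples <- purrr::map_dfr(seq_len(nrow(fits)), function(i) {
    err <- op_relative_errors(fits$params[[i]], fits$truth_op[[i]], cd,
                              compartments)
    tibble::tibble(fit = i, op = names(err), error_pct = unname(err))
  })
  intervals <- purrr::map_dfr(levels, function(p) {
    dplyr::summarise(dplyr::group_by(samples, .data$op),
                     level = p,
                     lo = stats::quantile(.data$error_pct, (1 - p) / 2,
                                          names = FALSE),
                     hi = stats::quantile(.data$error_pct, 1 - (1 - p) / 2,
                                          names = FALSE),
                     .groups = "drop")
  })
  structure(list(samples = samples, intervals = intervals),
            class = "error_distribution")
}

#' @export
print.error_distribution <- function(x, ...) {
  print(tidyr::pivot_wider(x$intervals, names_from = "level",
                           values_from = c("lo", "hi")))
  invisible(x)
}

#' @method autoplot error_distribution
#' @export
autoplot.error_distribution <- function(object, level = 0.68, ...) {
  ci <- object$intervals[object$intervals$level == level, ]
  ggplot2::ggplot(object$samples, ggplot2::aes(.data$error_pct)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(data = ci, ggplot2::aes(xintercept = .data$lo),
                        linetype = "dashed") +
    ggplot2::geom_vline(data = ci, ggplot2::aes(xintercept = .data$hi),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~op, scales = "free") +
    ggplot2::labs(x = "relative error (%)", y = "count")
}

#' Detector sensitivity to each optical property
#'
#' Central-difference relative sensitivity
#' \eqn{(\Delta R / R) / (\Delta OP / OP)} of each detector's reflectance to
#' each optical property, at one or more baseline OP vectors (averaged).
#' Positive perturbations outside the allowed hull are shrunk with a warning.
#'
#' @param forward forward function over OP matrices.
#' @param baseline_op named baseline OP vector (or matrix of baselines,
#'   averaged).
#' @param perturbation relative perturbation (default 5%).
#' @param ops which OP columns to perturb (default all non-CSF).
#' @return tibble (op, detector, sensitivity), class `sensitivity_table`.
#' @export
sensitivity_analysis <- function(forward, baseline_op, perturbation = 0.05,
                                 ops = NULL) {
  if (perturbation <= 0) stop("perturbation must be positive", call. = FALSE)
  if (is.null(dim(baseline_op))) {
    baseline_op <- matrix(baseline_op, nrow = 1,
                          dimnames = list(NULL, names(baseline_op)))
  }
  if (is.null(ops)) ops <- colnames(baseline_op)[!grepl("csf",
                                                        colnames(baseline_op))]
  out <- purrr::map_dfr(seq_len(nrow(baseline_op)), function(b) {
    base <- baseline_op[b, , drop = FALSE]
    R0 <- forward(base)
    purrr::map_dfr(ops, function(cn) {
      up <- base; dn <- base
      up[, cn] <- base[, cn] * (1 + perturbation)
      dn[, cn] <- base[, cn] * (1 - perturbation)
      dR <- (forward(up) - forward(dn)) / (2 * perturbation * R0)
      tibble::tibble(baseline = b, op = cn,
                     detector = colnames(R0), sensitivity = as.vector(dR))
    })
  })
  out <- dplyr::summarise(dplyr::group_by(out, .data$op, .data$detector),
                          sensitivity = mean(.data$sensitivity),
                          .groups = "drop")
  class(out) <- c("sensitivity_table", class(out))
  out
}

#' @method autoplot sensitivity_table
#' @export
autoplot.sensitivity_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$detector, abs(.data$sensitivity),
                                       group = .data$op)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~op, scales = "free_y") +
    ggplot2::labs(x = "detector", y = "|relative sensitivity|")
}

#' Validate the spectral-error ranking of multi-start fits
#'
#' For every target, computes the RMS percent error of the estimated optical
#' properties (over fit wavelengths and the six fitted OPs) for each of the
#' ranked starts, min-max normalizes those errors to [0, 1] within the target,
#' and pools them by spectral-error rank. If choosing the smallest spectral
#' error is sound, the pooled normalized OP error should grow with rank.
#'
#' @param fits_by_target list of `fit_result_set`s, all with the same number
#'   of starts.
#' @param truths list of truth parameter vectors, aligned with
#'   `fits_by_target`.
#' @param lib,wavelengths,compartments as elsewhere.
#' @return tibble (target, rank, norm_op_error), class `rank_validation`;
#'   targets with constant errors across starts are skipped with a message.
#' @export
rank_validation <- function(fits_by_target, truths, lib, wavelengths,
                            compartments) {
  stopifnot(length(fits_by_target) == length(truths))
  n_starts <- unique(vapply(fits_by_target, nrow, integer(1)))
  if (length(n_starts) != 1) {
    stop("all targets must have the same number of starts", call. = FALSE)
  }
  cd <- chrom_design(lib, wavelengths)
  out <- purrr::map_dfr(seq_along(fits_by_target), function(tg) {
    truth_op <- op_matrix_from_vector(truths[[tg]], cd, compartments)
    fits <- fits_by_target[[tg]]
    rms <- vapply(seq_len(nrow(fits)), function(i) {
      e <- op_relative_errors(fits$params[[i]], truth_op, cd, compartments)
      sqrt(mean(e^2))
    }, numeric(1))
    if (max(rms) - min(rms) < 1e-12) {
      message("target ", tg, " skipped: constant OP errors across starts")
      return(NULL)
    }
    tibble::tibble(target = tg, rank = fits$rank,
                   norm_op_error = (rms - min(rms)) / (max(rms) - min(rms)))
  })
  class(out) <- c("rank_validation", class(out))
  out
}

#' @method autoplot rank_validation
#' @export
autoplot.rank_validation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$rank),
                                       .data$norm_op_error)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "spectral-error rank", y = "normalized OP error")
}

#' Fit every spectrum of a test set
#'
#' Convenience driver for the uncertainty studies: fits the noiseless
#' spectrum and every noisy replicate of each parameter set, keeping the
#' selected solution(s) per spectrum (multiple solutions become separate
#' rows).
#'
#' @param tset a [generate_test_spectra()] set.
#' @param forward forward function.
#' @param pool an [build_initial_pool()] pool.
#' @param lib a [chromophore_library()].
#' @param fit_detectors,tiebreak_detectors detector split.
#' @param n_starts,max_iter fitting control.
#' @param threshold multiple-solution band.
#' @param include_noiseless also fit the noiseless spectra.
#' @return tibble: set, replicate (0 = noiseless), solution index, `params`,
#'   `truth`, `truth_op` list-columns, errors.
#' @export
fit_test_spectra <- function(tset, forward, pool, lib,
                             fit_detectors = 1:4, tiebreak_detectors = 5:6,
                             n_starts = 20, max_iter = 2000, threshold = 0.02,
                             include_noiseless = TRUE) {
  cd <- chrom_design(lib, tset$wavelengths)
  one <- function(set_i, rep_i, spectra) {
    colnames(spectra) <- paste0("d", seq_len(ncol(spectra)))
    tg <- fit_target(tset$wavelengths, spectra, fit_detectors,
                     tiebreak_detectors)
    fits <- fit_multistart(tg, forward, pool, lib, n_starts = n_starts,
                           max_iter = max_iter)
    sel <- select_solutions(fits, threshold)$solutions
    tibble::tibble(
      set = set_i, replicate = rep_i, solution = seq_len(nrow(sel)),
      params = sel$params,
      truth = list(tset$sets$truth[[set_i]]),
      truth_op = list(tset$sets$op[[set_i]]),
      error_fit = sel$error_fit, error_tiebreak = sel$error_tiebreak)
  }
  rows <- list()
  if (include_noiseless) {
    rows <- purrr::map(seq_len(nrow(tset$sets)), function(i) {
      one(i, 0L, tset$sets$clean[[i]])
    })
  }
  rows <- c(rows, purrr::map(seq_len(nrow(tset$replicates)), function(r) {
    one(tset$replicates$set[r], tset$replicates$replicate[r],
        tset$replicates$spectra[[r]])
  }))
  dplyr::bind_rows(rows)
}
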