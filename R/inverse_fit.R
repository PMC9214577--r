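# Inverse problem: multi-start constrained curve fitting of multidistance
# reflectance spectra in tissue-parameter space, plus calibration and
# multiple-solution selection.

#' RMS percent spectral error
#'
#' \deqn{E = \sqrt{\sum_d \sum_i (R_s(d,i)/R_m(d,i) - 1)^2 / (n_d n_\lambda)}}
#' over the selected detectors, the objective minimized by the fit. The ratio
#' form makes it invariant to any common positive rescaling of both spectra.
#'
#' @param Rs simulated reflectance, matrix wavelength x detector.
#' @param Rm measured (calibrated) reflectance, same shape, strictly positive.
#' @param detectors column indices (or names) to include; default all.
#' @return scalar error (0.1 means 10%).
#' @export
spectral_error <- function(Rs, Rm, detectors = NULL) {
  Rs <- as.matrix(Rs); Rm <- as.matrix(Rm)
  if (!all(dim(Rs) == dim(Rm))) stop("Rs and Rm shapes differ", call. = FALSE)
  if (!is.null(detectors)) {
    Rs <- Rs[, detectors, drop = FALSE]
    Rm <- Rm[, detectors, drop = FALSE]
  }
  if (any(Rm <= 0)) stop("measured reflectance must be strictly positive",
                         call. = FALSE)
  sqrt(mean((Rs / Rm - 1)^2))
}

#' Default fitting wavelengths
#'
#' 22 wavelengths between 700 and 880 nm, sampled twice as densely below
#' 780 nm where the hemoglobin spectra carry most of their contrast.
#'
#' @return numeric vector of 22 wavelengths (nm).
#' @export
fit_wavelengths_default <- function() {
  c(seq(700, 780, length.out = 14), seq(780, 880, length.out = 9)[-1])
}

#' Assemble a fitting target
#'
#' @param wavelengths nm, matching the rows of `reflectance`.
#' @param reflectance calibrated reflectance matrix (wavelength x detector),
#'   columns named `d1`, `d2`, ...
#' @param fit_detectors detector ids used inside the objective.
#' @param tiebreak_detectors detector ids held out for the multiple-solution
#'   stage; must be disjoint from `fit_detectors`.
#' @return object of class `fit_target`.
#' @export
fit_target <- function(wavelengths, reflectance,
                       fit_detectors = 1:4, tiebreak_detectors = 5:6) {
  reflectance <- as.matrix(reflectance)
  stopifnot(length(wavelengths) == nrow(reflectance),
            all(reflectance > 0))
  if (length(intersect(fit_detectors, tiebreak_detectors))) {
    stop("fitting and tie-breaker detector subsets must be disjoint",
         call. = FALSE)
  }
  det_ids <- as.integer(sub("^d", "", colnames(reflectance)))
  if (anyNA(det_ids)) det_ids <- seq_len(ncol(reflectance))
  missing <- setdiff(c(fit_detectors, tiebreak_detectors), det_ids)
  if (length(missing)) stop("detectors not present in target: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  structure(list(wavelengths = wavelengths, reflectance = reflectance,
                 det_ids = det_ids, fit_detectors = fit_detectors,
                 tiebreak_detectors = tiebreak_detectors),
            class = "fit_target")
}

det_cols <- function(target, ids) match(ids, target$det_ids)

# ---- calibration ------------------------------------------------------------

#' Calibrate measured spectra to absolute reflectance
#'
#' Fits, per detector, a linear regression of simulated absolute reflectance
#' on measured counts over a set of homogeneous calibration phantoms, then
#' applies it to the raw target spectra. Multiple raw replicates are averaged
#' after calibration.
#'
#' @param measured list of measured phantom matrices (wavelength x detector).
#' @param simulated list of matched simulated absolute-reflectance matrices.
#' @param raw_target one raw matrix, or a list of replicate matrices.
#' @return list of class `calibration` with the calibrated target matrix
#'   (`target`), the per-detector coefficients (`coef`), and the fitted `lm`s.
#' @export
calibrate_spectra <- function(measured, simulated, raw_target) {
  stopifnot(length(measured) == length(simulated), length(measured) >= 2)
  ndet <- ncol(measured[[1]])
  meas <- do.call(rbind, measured)
  sim <- do.call(rbind, simulated)
  fits <- lapply(seq_len(ndet), function(j) {
    if (stats::sd(meas[, j]) == 0) {
      stop("degenerate calibration: identical phantom intensities at detector ",
           j, call. = FALSE)
    }
    stats::lm(y ~ x, data = data.frame(x = meas[, j], y = sim[, j]))
  })
  coefs <- tibble::tibble(
    detector = seq_len(ndet),
    intercept = vapply(fits, function(f) stats::coef(f)[1], numeric(1)),
    slope = vapply(fits, function(f) stats::coef(f)[2], numeric(1)))
  if (any(coefs$slope <= 0)) {
    stop("calibration mapping must be increasing (non-positive slope)",
         call. = FALSE)
  }
  apply_cal <- function(m) {
    out <- m
    for (j in seq_len(ndet)) out[, j] <- coefs$intercept[j] +
        coefs$slope[j] * m[, j]
    out
  }
  if (!is.list(raw_target)) raw_target <- list(raw_target)
  cal <- lapply(raw_target, apply_cal)
  target <- Reduce(`+`, cal) / length(cal)
  structure(list(target = target, coef = coefs, fits = fits),
            class = "calibration")
}

# ---- parameter space --------------------------------------------------------

#' Free-parameter layout of the spectral fit
#'
#' The fit works in tissue-parameter space: per fitted tissue, total
#' hemoglobin `tHB` (M), saturation `StO2`, scattering at 800 nm `musp800`
#' (1/cm) and scattering power `K`, plus the scalp melanin fraction.
#' `musp800`/`K` replace the power-law amplitude `A = musp800 * 800^K`, which
#' keeps all parameters on comparable, physically bounded scales.
#'
#' @return tibble: `name`, `tissue`, `lo`, `hi`.
#' @export
param_spec <- function() {
  tibble::tribble(
    ~name,            ~tissue, ~lo,    ~hi,
    "scalp_tHB",      "scalp", 5e-6,   2e-4,
    "scalp_StO2",     "scalp", 0,      1,
    "scalp_Cmelanin", "scalp", 0,      0.003,
    "scalp_musp800",  "scalp", 5,      35,
    "scalp_K",        "scalp", 0.1,    3,
    "skull_tHB",      "skull", 5e-6,   2e-4,
    "skull_StO2",     "skull", 0,      1,
    "skull_musp800",  "skull", 5,      35,
    "skull_K",        "skull", 0.1,    3,
    "gm_tHB",         "gm",    5e-6,   2e-4,
    "gm_StO2",        "gm",    0,      1,
    "gm_musp800",     "gm",    5,      35,
    "gm_K",           "gm",    0.1,    3
  )
}

#' Convert between the fit vector and [tissue_params()]
#'
#' @param v named numeric in [param_spec()] order.
#' @return a `tissue_params` object (or the vector, for the inverse).
#' @export
vector_to_params <- function(v) {
  tissue_params(
    scalp = list(tHB = v[["scalp_tHB"]], StO2 = v[["scalp_StO2"]],
                 Cmelanin = v[["scalp_Cmelanin"]],
                 A = v[["scalp_musp800"]] * 800^v[["scalp_K"]],
                 K = v[["scalp_K"]]),
    skull = list(tHB = v[["skull_tHB"]], StO2 = v[["skull_StO2"]],
                 A = v[["skull_musp800"]] * 800^v[["skull_K"]],
                 K = v[["skull_K"]]),
    gm = list(tHB = v[["gm_tHB"]], StO2 = v[["gm_StO2"]],
              A = v[["gm_musp800"]] * 800^v[["gm_K"]],
              K = v[["gm_K"]]))
}

#' @rdname vector_to_params
#' @param params a `tissue_params` object.
#' @export
params_to_vector <- function(params) {
  c(scalp_tHB = params$scalp$tHB, scalp_StO2 = params$scalp$StO2,
    scalp_Cmelanin = params$scalp$Cmelanin,
    scalp_musp800 = params$scalp$A * 800^(-params$scalp$K),
    scalp_K = params$scalp$K,
    skull_tHB = params$skull$tHB, skull_StO2 = params$skull$StO2,
    skull_musp800 = params$skull$A * 800^(-params$skull$K),
    skull_K = params$skull$K,
    gm_tHB = params$gm$tHB, gm_StO2 = params$gm$StO2,
    gm_musp800 = params$gm$A * 800^(-params$gm$K),
    gm_K = params$gm$K)
}

# precomputed chromophore design at the fit wavelengths; makes each objective
# evaluation a handful of vector operations
chrom_design <- function(lib, wavelengths) {
  sp <- interp_chromophores(lib, wavelengths)
  list(wl = wavelengths,
       eps_HbO = sp$eps_HbO, eps_Hb = sp$eps_Hb,
       water = sp$mua_water, collagen = sp$mua_collagen,
       melanin = sp$mua_melanin,
       mua_csf = sp$mua_CSF, musp_csf = sp$musp_CSF,
       pow = log(wavelengths / 800))
}

# OP matrix (wavelength rows; mua_*/musp_* columns for `compartments`) from a
# parameter vector
op_matrix_from_vector <- function(v, cd, compartments) {
  hb <- function(tHB, StO2) 2.303 * (cd$eps_HbO * StO2 +
                                     cd$eps_Hb * (1 - StO2)) * tHB
  cols <- list()
  cols$mua_scalp <- hb(v[["scalp_tHB"]], v[["scalp_StO2"]]) +
    0.75 * cd$water + 0.02 * cd$collagen + v[["scalp_Cmelanin"]] * cd$melanin
  cols$mua_skull <- hb(v[["skull_tHB"]], v[["skull_StO2"]])
  cols$mua_gm <- hb(v[["gm_tHB"]], v[["gm_StO2"]]) + 0.75 * cd$water
  cols$musp_scalp <- v[["scalp_musp800"]] * exp(-v[["scalp_K"]] * cd$pow)
  cols$musp_skull <- v[["skull_musp800"]] * exp(-v[["skull_K"]] * cd$pow)
  cols$musp_gm <- v[["gm_musp800"]] * exp(-v[["gm_K"]] * cd$pow)
  if ("csf" %in% compartments) {
    cols$mua_csf <- cd$mua_csf
    cols$musp_csf <- cd$musp_csf
  }
  want <- c(paste0("mua_", compartments), paste0("musp_", compartments))
  out <- do.call(cbind, cols[want])
  colnames(out) <- want
  out
}

# chain rule from an OP-matrix gradient back to the 13 fit parameters
param_grad_from_op <- function(v, cd, compartments, dE_dop) {
  g <- stats::setNames(numeric(nrow(param_spec())), param_spec()$name)
  for (tis in c("scalp", "skull", "gm")) {
    if (!(tis %in% compartments)) next
    ca <- dE_dop[, paste0("mua_", tis)]
    cs <- dE_dop[, paste0("musp_", tis)]
    St <- v[[paste0(tis, "_StO2")]]
    tH <- v[[paste0(tis, "_tHB")]]
    m8 <- v[[paste0(tis, "_musp800")]]
    K <- v[[paste0(tis, "_K")]]
    mix <- cd$eps_HbO * St + cd$eps_Hb * (1 - St)
    g[paste0(tis, "_tHB")] <- sum(ca * 2.303 * mix)
    g[paste0(tis, "_StO2")] <- sum(ca * 2.303 * (cd$eps_HbO - cd$eps_Hb) * tH)
    decay <- exp(-K * cd$pow)
    g[paste0(tis, "_musp800")] <- sum(cs * decay)
    g[paste0(tis, "_K")] <- sum(cs * m8 * decay * (-cd$pow))
  }
  if ("scalp" %in% compartments) {
    g["scalp_Cmelanin"] <- sum(dE_dop[, "mua_scalp"] * cd$melanin)
  }
  g
}

# smooth quadratic hinge on Table 1 range violations of the derived OPs; the
# nonlinear constraint of the fit, returned in units comparable to the
# spectral error
range_penalty <- function(op, ranges_idx) {
  pen <- 0
  for (q in names(ranges_idx)) {
    r <- ranges_idx[[q]]
    x <- op[, q]
    pen <- pen + sum(pmax((r[1] - x) / r[3], 0)^2 +
                     pmax((x - r[2]) / r[3], 0)^2)
  }
  pen / nrow(op)
}

ranges_index <- function(compartments, ranges = op_ranges()) {
  out <- list()
  for (cmp in setdiff(compartments, "csf")) {
    r <- ranges[ranges$compartment == cmp, ]
    out[[paste0("mua_", cmp)]] <- c(r$mua_min, r$mua_max,
                                    r$mua_max - r$mua_min)
    out[[paste0("musp_", cmp)]] <- c(r$musp_min, r$musp_max,
                                     r$musp_max - r$musp_min)
  }
  out
}

#' Simulate spectra for a parameter vector through a forward model
#'
#' @param v named parameter vector ([param_spec()] order).
#' @param forward function mapping an OP matrix (`mua_*`, `musp_*` columns) to
#'   a reflectance matrix; e.g. `function(op) predict_reflectance(model, op)`.
#' @param cd a `chrom_design` (internal) or a [chromophore_library()] plus
#'   `wavelengths`.
#' @param compartments compartments the forward model expects.
#' @param lib,wavelengths used when `cd` is not supplied.
#' @return reflectance matrix (wavelength x detector).
#' @export
spectra_from_vector <- function(v, forward, compartments,
                                cd = NULL, lib = NULL, wavelengths = NULL) {
  if (is.null(cd)) cd <- chrom_design(lib, wavelengths)
  forward(op_matrix_from_vector(v, cd, compartments))
}

# ---- initial pool -----------------------------------------------------------

#' Pre-simulated pool of candidate starting parameters
#'
#' Uniform parameter draws inside the box bounds, rejected when the derived
#' optical properties leave the allowed ranges at any fit wavelength, with
#' spectra precomputed once through the forward model. A fit ranks the pool
#' against its target and takes the best members as starting values.
#'
#' @param forward forward function (see [spectra_from_vector()]).
#' @param lib a [chromophore_library()].
#' @param wavelengths fit wavelengths.
#' @param compartments forward-model compartments.
#' @param n pool size.
#' @param seed RNG seed.
#' @param max_tries rejection-sampling cap per accepted member.
#' @return object of class `initial_pool`: parameter matrix and spectra array.
#' @export
build_initial_pool <- function(forward, lib, wavelengths, compartments,
                               n = 5000, seed = 1L, max_tries = 50) {
  stopifnot(n >= 20)
  set.seed(seed)
  spec <- param_spec()
  cd <- chrom_design(lib, wavelengths)
  ridx <- ranges_index(compartments)
  P <- matrix(NA_real_, n, nrow(spec), dimnames = list(NULL, spec$name))
  spectra <- NULL
  accepted <- 0
  tries <- 0
  while (accepted < n) {
    tries <- tries + 1
    if (tries > max_tries * n) {
      stop("rejection sampling failed to fill the pool", call. = FALSE)
    }
    v <- stats::setNames(stats::runif(nrow(spec), spec$lo, spec$hi), spec$name)
    op <- op_matrix_from_vector(v, cd, compartments)
    if (range_penalty(op, ridx) > 0) next
    accepted <- accepted + 1
    P[accepted, ] <- v
    R <- forward(op)
    if (is.null(spectra)) {
      spectra <- array(NA_real_, c(n, nrow(R), ncol(R)),
                       dimnames = list(NULL, NULL, colnames(R)))
    }
    spectra[accepted, , ] <- R
  }
  structure(list(params = P, spectra = spectra, wavelengths = wavelengths,
                 compartments = compartments, seed = seed),
            class = "initial_pool")
}

# ---- multi-start fitting ----------------------------------------------------

#' Multi-start constrained spectral fit
#'
#' Ranks the pre-simulated pool by spectral error against the target on the
#' fitted detectors, takes the best `n_starts` members as initial values, and
#' minimizes the spectral error from each with a bound-constrained
#' quasi-Newton (L-BFGS-B) search in unit-scaled parameter space, adding a
#' smooth quadratic hinge penalty that keeps the derived optical properties
#' inside their allowed ranges. Results come back sorted by fitted-detector
#' error, each with the held-out tie-breaker error.
#'
#' @param target a [fit_target()].
#' @param forward forward function (see [spectra_from_vector()]).
#' @param pool a [build_initial_pool()] pool (matching wavelengths).
#' @param lib a [chromophore_library()].
#' @param n_starts fits per target.
#' @param max_iter L-BFGS-B iteration cap.
#' @param penalty_weight weight of the range penalty in the objective.
#' @return tibble of class `fit_result_set`: one row per start with the
#'   fitted parameter vector (list column `params`), `error_fit`,
#'   `error_tiebreak`, iterations, convergence and feasibility flags.
#' @export
fit_multistart <- function(target, forward, pool, lib, n_starts = 20,
                           max_iter = 2000, penalty_weight = 200) {
  stopifnot(inherits(target, "fit_target"), inherits(pool, "initial_pool"),
            nrow(pool$params) >= n_starts)
  if (!isTRUE(all.equal(pool$wavelengths, target$wavelengths))) {
    stop("pool and target wavelengths differ", call. = FALSE)
  }
  spec <- param_spec()
  cd <- chrom_design(lib, target$wavelengths)
  ridx <- ranges_index(pool$compartments)
  fit_idx <- det_cols(target, target$fit_detectors)
  tie_idx <- det_cols(target, target$tiebreak_detectors)
  Rm_fit <- target$reflectance[, fit_idx, drop = FALSE]
  Rm_tie <- target$reflectance[, tie_idx, drop = FALSE]

  # rank pool members on the fitted detectors
  pool_err <- vapply(seq_len(nrow(pool$params)), function(i) {
    spectral_error(pool$spectra[i, , fit_idx, drop = TRUE], Rm_fit)
  }, numeric(1))
  starts <- order(pool_err)[seq_len(n_starts)]

  lo <- spec$lo; hi <- spec$hi; span <- hi - lo
  to_unit <- function(v) (v - lo) / span
  from_unit <- function(x) stats::setNames(lo + x * span, spec$name)
  with_grad <- attr(forward, "with_grad")

  objective <- function(x) {
    v <- from_unit(x)
    op <- op_matrix_from_vector(v, cd, pool$compartments)
    R <- forward(op)
    spectral_error(R[, fit_idx, drop = FALSE], Rm_fit) +
      penalty_weight * range_penalty(op, ridx)
  }

  # analytic value + gradient (memoized: L-BFGS-B asks for both at each x)
  memo <- new.env(parent = emptyenv())
  eval_both <- function(x) {
    key <- paste(x, collapse = ",")
    if (identical(memo$key, key)) return(memo$val)
    v <- from_unit(x)
    op <- op_matrix_from_vector(v, cd, pool$compartments)
    fw <- with_grad(op)
    R <- fw$R
    nwl <- nrow(R); ndf <- length(fit_idx)
    ratio <- R[, fit_idx, drop = FALSE] / Rm_fit - 1
    err <- sqrt(mean(ratio^2))
    dE_dR <- matrix(0, nwl, ncol(R))
    dE_dR[, fit_idx] <- ratio / (Rm_fit * max(err, 1e-12) * ndf * nwl)
    dE_dop <- fw$vjp(dE_dR)
    colnames(dE_dop) <- colnames(op)
    # penalty and its gradient on the OP matrix
    pen <- 0
    dP_dop <- dE_dop * 0
    for (q in names(ridx)) {
      r <- ridx[[q]]
      xq <- op[, q]
      lo_h <- pmax((r[1] - xq) / r[3], 0)
      hi_h <- pmax((xq - r[2]) / r[3], 0)
      pen <- pen + sum(lo_h^2 + hi_h^2)
      dP_dop[, q] <- 2 * (hi_h - lo_h) / r[3]
    }
    pen <- pen / nwl
    dP_dop <- dP_dop / nwl
    g_op <- dE_dop + penalty_weight * dP_dop
    g <- param_grad_from_op(v, cd, pool$compartments, g_op)
    memo$key <- key
    memo$val <- list(value = err + penalty_weight * pen,
                     gradient = unname(g[spec$name] * span))
    memo$val
  }

  results <- purrr::map_dfr(seq_along(starts), function(si) {
    x0 <- to_unit(pool$params[starts[si], ])
    opt <- if (!is.null(with_grad)) {
      stats::optim(x0, function(x) eval_both(x)$value,
                   function(x) eval_both(x)$gradient,
                   method = "L-BFGS-B",
                   lower = rep(0, length(x0)), upper = rep(1, length(x0)),
                   control = list(maxit = max_iter, factr = 1e8))
    } else {
      stats::optim(x0, objective, method = "L-BFGS-B",
                   lower = rep(0, length(x0)), upper = rep(1, length(x0)),
                   control = list(maxit = max_iter, factr = 1e8))
    }
    v <- from_unit(opt$par)
    op <- op_matrix_from_vector(v, cd, pool$compartments)
    R <- forward(op)
    tibble::tibble(
      start = si, pool_index = starts[si],
      params = list(v),
      error_fit = spectral_error(R[, fit_idx, drop = FALSE], Rm_fit),
      error_tiebreak = if (length(tie_idx))
        spectral_error(R[, tie_idx, drop = FALSE], Rm_tie) else NA_real_,
      penalty = range_penalty(op, ridx),
      iterations = opt$counts[["function"]],
      converged = opt$convergence == 0,
      feasible = range_penalty(op, ridx) == 0)
  })
  results <- results[order(results$error_fit), ]
  results$rank <- seq_len(nrow(results))
  class(results) <- c("fit_result_set", class(results))
  attr(results, "target") <- target
  attr(results, "compartments") <- pool$compartments
  results
}

#' @method tidy fit_result_set
#' @export
tidy.fit_result_set <- function(x, ...) {
  dplyr::bind_cols(
    x[c("rank", "start", "error_fit", "error_tiebreak", "converged",
        "feasible")],
    purrr::map_dfr(x$params, ~ tibble::as_tibble(as.list(.x))))
}

#' @method glance fit_result_set
#' @export
glance.fit_result_set <- function(x, ...) {
  tibble::tibble(n_starts = nrow(x),
                 best_error_fit = min(x$error_fit),
                 best_error_tiebreak = x$error_tiebreak[which.min(x$error_fit)],
                 n_converged = sum(x$converged),
                 n_feasible = sum(x$feasible))
}

# ---- multiple-solution selection --------------------------------------------

#' Two-stage multiple-solution selection
#'
#' Measurement noise makes fits whose spectral errors differ by less than the
#' instrument noise level (2%) indistinguishable. Stage 1 keeps results whose
#' fitted-detector error lies within `threshold` (absolute, in error units) of
#' the minimum; stage 2 re-ranks the survivors on the tie-breaker detectors
#' that were excluded from the fit and keeps those within `threshold` of that
#' stage's minimum. Two or more final survivors are flagged as multiple
#' solutions.
#'
#' @param results a [fit_multistart()] result set.
#' @param threshold absolute spectral-error band (default 0.02, the 2% system
#'   noise level).
#' @return object of class `solution_set`: surviving rows, `multiplicity`
#'   flag, the stage-1 survivor count, and the threshold.
#' @export
select_solutions <- function(results, threshold = 0.02) {
  stopifnot(nrow(results) >= 1, threshold >= 0)
  stage1 <- results[results$error_fit <= min(results$error_fit) + threshold, ]
  if (all(is.na(stage1$error_tiebreak))) {
    warning("no tie-breaker detectors configured; stage 2 skipped",
            call. = FALSE)
    survivors <- stage1
  } else {
    survivors <- stage1[stage1$error_tiebreak <=
                          min(stage1$error_tiebreak) + threshold, ]
  }
  structure(list(solutions = survivors,
                 multiplicity = nrow(survivors) >= 2,
                 n_stage1 = nrow(stage1),
                 threshold = threshold),
            class = "solution_set")
}

#' @export
print.solution_set <- function(x, ...) {
  cat(sprintf(
    "Solution set: %d survivor(s) of %d stage-1 candidates (threshold %.3g)%s\n",
    nrow(x$solutions), x$n_stage1, x$threshold,
    if (x$multiplicity) " -- MULTIPLE SOLUTIONS" else ""))
  print(x$solutions[c("rank", "error_fit", "error_tiebreak")])
  invisible(x)
}

#' Scan detector combinations and pick the most informative usable one
#'
#' In-vivo targets sometimes cannot be fitted well on every detector at once
#' (local inhomogeneities under single fibers). This driver fits each
#' configured detector combination and selects the combination that uses the
#' most detectors while keeping the best fitted-detector spectral error below
#' `threshold`.
#'
#' @param target a [fit_target()]; its detector subsets are overridden per
#'   combination (detectors outside the combination serve as tie-breakers).
#' @param forward,pool,lib,n_starts,max_iter as in [fit_multistart()].
#' @param combinations list of integer vectors of detector ids.
#' @param threshold maximum acceptable best spectral error (default 0.15).
#' @return tibble (one row per combination: detectors, n_detectors,
#'   best_error, selected) with the chosen combination's `fit_result_set` in
#'   attribute `"fits"`.
#' @export
scan_detector_combinations <- function(target, forward, pool, lib,
                                       combinations, threshold = 0.15,
                                       n_starts = 20, max_iter = 2000) {
  all_ids <- target$det_ids
  rows <- purrr::map(combinations, function(combo) {
    tg <- fit_target(target$wavelengths, target$reflectance,
                     fit_detectors = combo,
                     tiebreak_detectors = setdiff(all_ids, combo))
    fits <- fit_multistart(tg, forward, pool, lib, n_starts = n_starts,
                           max_iter = max_iter)
    list(summary = tibble::tibble(
           detectors = paste(combo, collapse = ""),
           n_detectors = length(combo),
           best_error = min(fits$error_fit)),
         fits = fits)
  })
  out <- dplyr::bind_rows(purrr::map(rows, "summary"))
  ok <- out$best_error < threshold
  out$selected <- FALSE
  if (any(ok)) {
    pick <- which(ok)[order(-out$n_detectors[ok], out$best_error[ok])[1]]
    out$selected[pick] <- TRUE
    attr(out, "fits") <- rows[[pick]]$fits
  }
  out
}

#' Spectra overlay for a fitted result
#'
#' @param object a `fit_result_set`.
#' @param forward,lib the forward model and chromophore library used in the
#'   fit.
#' @param rank which result to plot (default the best).
#' @param ... unused.
#' @return a ggplot: measured vs fitted spectra per detector.
#' @method autoplot fit_result_set
#' @export
autoplot.fit_result_set <- function(object, forward, lib, rank = 1, ...) {
  target <- attr(object, "target")
  comps <- attr(object, "compartments")
  v <- object$params[[which(object$rank == rank)]]
  R <- spectra_from_vector(v, forward, comps, lib = lib,
                           wavelengths = target$wavelengths)
  df <- dplyr::bind_rows(
    tidyr::pivot_longer(
      dplyr::mutate(tibble::as_tibble(target$reflectance),
                    wavelength = target$wavelengths, kind = "measured"),
      dplyr::starts_with("d"), names_to = "detector", values_to = "R"),
    tidyr::pivot_longer(
      dplyr::mutate(tibble::as_tibble(R),
                    wavelength = target$wavelengths, kind = "fitted"),
      dplyr::starts_with("d"), names_to = "detector", values_to = "R"))
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$R,
                                   linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~detector, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance",
                  title = sprintf("rank %d fit, spectral error %.3g",
                                  rank, object$error_fit[object$rank == rank]))
}
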