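# Lookup table over transport scattering combinations, microscopic
# Beer-Lambert rescaling, NA conversion, interpolation, and training-set
# generation for the surrogate forward model.

#' Transport scattering grid for the lookup table
#'
#' Node lists of \eqn{\mu_s'} per varied compartment. The default reproduces
#' the published table construction: 13 scalp, 9 skull, 4 CSF, and 6 gray
#' matter nodes spanning their allowed ranges, 2808 combinations in all.
#' White matter is never a grid axis; its scattering is coupled to gray
#' matter.
#'
#' @param nodes named list of strictly increasing node vectors (1/cm); names
#'   must be a subset of `scalp`, `skull`, `csf`, `gm`.
#' @return object of class `musp_grid`.
#' @export
musp_grid <- function(nodes = list(
                        scalp = seq(5, 35, by = 2.5),
                        skull = seq(5, 35, by = 3.75),
                        csf   = seq(1, 3.7, by = 0.9),
                        gm    = seq(5, 35, by = 6))) {
  stopifnot(length(nodes) >= 1,
            all(names(nodes) %in% c("scalp", "skull", "csf", "gm")))
  for (nm in names(nodes)) {
    if (any(diff(nodes[[nm]]) <= 0)) {
      stop("grid nodes for ", nm, " must be strictly increasing", call. = FALSE)
    }
  }
  structure(list(nodes = nodes), class = "musp_grid")
}

#' Number of scattering combinations in a grid
#' @param grid a [musp_grid()].
#' @return integer product of the per-compartment node counts.
#' @export
n_combinations <- function(grid) {
  prod(vapply(grid$nodes, length, integer(1)))
}

#' All grid combinations as a tibble
#' @param grid a [musp_grid()].
#' @return tibble, one row per combination, columns `musp_<compartment>`.
#' @export
grid_combinations <- function(grid) {
  combos <- expand.grid(grid$nodes, KEEP.OUT.ATTRS = FALSE)
  names(combos) <- paste0("musp_", names(grid$nodes))
  # first axis varies slowest, matching the tensor order of the interpolation
  # weights
  combos <- combos[do.call(order, as.list(combos)), , drop = FALSE]
  rownames(combos) <- NULL
  tibble::as_tibble(combos)
}

#' Reflectance from white-MC records at arbitrary absorption
#'
#' The microscopic Beer-Lambert rescaling: for each detector,
#' \deqn{R = \frac{1}{N_{total}} \sum_i w_i\, e^{-\sum_l \mu_{a,l}
#'   PL(i,l)},}
#' summing the attenuated statistical weight of every detected photon over its
#' per-compartment pathlengths. One scattering-only simulation therefore
#' yields reflectance for any absorption combination.
#'
#' @param result a [run_white_mc()] result with path records.
#' @param mua named numeric (one absorption set, names `scalp`, `skull`,
#'   `csf`, `gm`, `wm`) or a matrix with those columns (one row per set).
#' @param se also return the Monte Carlo standard error.
#' @return matrix `n_sets x n_detectors` of reflectance (detectors in probe
#'   order); with `se = TRUE`, a list `(R, se)` of two such matrices.
#' @export
wmc_reflectance <- function(result, mua, se = FALSE) {
  stopifnot(inherits(result, "wmc_result"))
  if (is.null(dim(mua))) mua <- matrix(mua, nrow = 1,
                                       dimnames = list(NULL, names(mua)))
  if (!all(COMPARTMENTS %in% colnames(mua))) {
    stop("mua must have columns ", paste(COMPARTMENTS, collapse = ", "),
         call. = FALSE)
  }
  if (any(mua < 0)) stop("mua must be non-negative", call. = FALSE)
  mua <- mua[, COMPARTMENTS, drop = FALSE]
  ids <- result$per_det$id
  R <- matrix(0, nrow(mua), length(ids))
  V <- if (se) matrix(0, nrow(mua), length(ids)) else NULL
  rec_det <- result$records[, "det"]
  for (j in seq_along(ids)) {
    rows <- rec_det == ids[j]
    if (!any(rows)) next
    pl <- result$records[rows, paste0("pl_", COMPARTMENTS), drop = FALSE]
    w0 <- result$records[rows, "w0"]
    E <- exp(-pl %*% t(mua))          # n_rec x n_sets
    R[, j] <- as.vector(crossprod(E, w0)) / result$n_total
    if (se) V[, j] <- sqrt(as.vector(crossprod(E^2, w0^2))) / result$n_total
  }
  colnames(R) <- paste0("d", ids)
  if (se) { colnames(V) <- colnames(R); list(R = R, se = V) } else R
}

#' Build the scattering lookup table
#'
#' Runs one white Monte Carlo simulation per grid combination and stores the
#' photon path records, so reflectance at any absorption follows from
#' [wmc_reflectance()]. Compartments that are not grid axes keep the values in
#' `fixed_musp`; white-matter scattering is always coupled to 3x the gray
#' matter value.
#'
#' @param model,probe geometry, as for [run_white_mc()].
#' @param grid a [musp_grid()].
#' @param n_photons photons per grid node.
#' @param acceptance_na detector NA for the build (default 1.0, the
#'   all-angles acceleration; convert afterwards with the NA model).
#' @param seed base seed; node k runs with `seed + k`.
#' @param fixed_musp values for compartments absent from the grid (white
#'   matter defaults to the gray-matter coupling).
#' @param max_records_per_detector thin stored records per node to this count
#'   (weights rescaled; keeps later rescaling affordable).
#' @param progress print one line per node.
#' @param ... passed to [run_white_mc()].
#' @return object of class `lookup_table`.
#' @export
build_lookup_table <- function(model, probe, grid, n_photons = 1e5,
                               acceptance_na = 1.0, seed = 1L,
                               fixed_musp = c(scalp = 15, skull = 16,
                                              csf = 2.4, gm = 9),
                               max_records_per_detector = 12000,
                               progress = FALSE, ...) {
  combos <- grid_combinations(grid)
  entries <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    musp <- full_musp(combos[k, ], fixed_musp)
    res <- run_white_mc(model, probe, musp, n_photons = n_photons,
                        acceptance_na = acceptance_na, seed = seed + k, ...)
    if (max_records_per_detector < Inf) {
      res <- thin_records(res, max_records_per_detector, seed = seed + k)
    }
    res$records <- res$records[, c("det", paste0("pl_", COMPARTMENTS), "w0"),
                               drop = FALSE]
    entries[[k]] <- res
    if (progress) {
      message(sprintf("node %d/%d: musp (%s), %d records", k, nrow(combos),
                      paste(signif(unlist(combos[k, ]), 3), collapse = ", "),
                      nrow(res$records)))
    }
  }
  structure(list(grid = grid, combos = combos, entries = entries,
                 detectors = probe$detectors, n_photons = n_photons,
                 acceptance_na = acceptance_na, seed = seed,
                 fixed_musp = fixed_musp),
            class = "lookup_table")
}

# expand a grid-combination row into the full named musp vector, applying the
# white-matter coupling musp_wm = 3 * musp_gm
full_musp <- function(combo_row, fixed_musp) {
  musp <- stats::setNames(rep(NA_real_, 5), COMPARTMENTS)
  for (cmp in COMPARTMENTS) {
    cn <- paste0("musp_", cmp)
    if (cn %in% names(combo_row)) musp[cmp] <- as.numeric(combo_row[[cn]])
  }
  for (cmp in names(fixed_musp)) {
    if (is.na(musp[cmp]) && !is.na(fixed_musp[[cmp]])) {
      musp[cmp] <- fixed_musp[[cmp]]
    }
  }
  if (is.na(musp["wm"])) musp["wm"] <- 3 * musp[["gm"]]
  if (is.na(musp["csf"])) musp["csf"] <- 2.4
  if (anyNA(musp)) stop("incomplete musp specification", call. = FALSE)
  musp
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf("Lookup table: %d entries (%s), %g photons/node, NA=%g\n",
              length(x$entries),
              paste(names(x$grid$nodes),
                    vapply(x$grid$nodes, length, integer(1)),
                    sep = "=", collapse = " x "),
              x$n_photons, x$acceptance_na))
  invisible(x)
}

#' Reflectance at every lookup-table node for given absorption sets
#'
#' @param table a [build_lookup_table()] table.
#' @param mua matrix of absorption sets (columns `scalp`, `skull`, `csf`,
#'   `gm`, `wm`), or a named vector for one set.
#' @return array `n_nodes x n_sets x n_detectors`.
#' @export
lut_node_reflectance <- function(table, mua) {
  if (is.null(dim(mua))) mua <- matrix(mua, nrow = 1,
                                       dimnames = list(NULL, names(mua)))
  ndet <- nrow(table$detectors)
  out <- array(0, c(length(table$entries), nrow(mua), ndet))
  for (k in seq_along(table$entries)) {
    out[k, , ] <- wmc_reflectance(table$entries[[k]], mua)
  }
  out
}

# cardinal (basis) weights of separable cubic-spline interpolation on the
# grid: returns an n_query x n_nodes matrix W such that interpolated values
# are W %*% node_values, node order matching grid_combinations()
lut_interp_weights <- function(grid, query) {
  axes <- names(grid$nodes)
  qcols <- paste0("musp_", axes)
  if (!all(qcols %in% colnames(query))) {
    stop("query must have columns ", paste(qcols, collapse = ", "),
         call. = FALSE)
  }
  for (a in axes) {
    x <- query[[paste0("musp_", a)]]
    rng <- range(grid$nodes[[a]])
    if (any(x < rng[1] - 1e-9) || any(x > rng[2] + 1e-9)) {
      stop(sprintf("query musp_%s outside grid hull [%g, %g]; no extrapolation",
                   a, rng[1], rng[2]), call. = FALSE)
    }
  }
  axis_w <- lapply(axes, function(a) {
    nodes <- grid$nodes[[a]]
    q <- query[[paste0("musp_", a)]]
    if (length(nodes) == 1) return(matrix(1, length(q), 1))
    w <- vapply(seq_along(nodes), function(i) {
      e <- rep(0, length(nodes)); e[i] <- 1
      if (length(nodes) >= 3) {
        stats::splinefun(nodes, e, method = "fmm")(q)
      } else {
        stats::approx(nodes, e, xout = q)$y
      }
    }, numeric(length(q)))
    matrix(w, nrow = length(q))
  })
  # tensor product, first axis varying slowest to match grid_combinations()
  nq <- nrow(query)
  W <- matrix(1, nq, 1)
  for (aw in axis_w) {
    W <- W[, rep(seq_len(ncol(W)), each = ncol(aw)), drop = FALSE] *
      aw[, rep(seq_len(ncol(aw)), times = ncol(W)), drop = FALSE]
  }
  W
}

#' Interpolated reflectance inside the lookup-table hull
#'
#' Evaluates the Beer-Lambert rescaled reflectance at every grid node for the
#' requested absorption, then interpolates log-reflectance across the
#' scattering axes with separable cubic splines (log scale because
#' reflectance spans decades across source-detector separations). Queries at a
#' grid node reproduce the stored node value exactly; queries outside the
#' hull are an error.
#'
#' @param table a [build_lookup_table()] table.
#' @param musp_combo named \eqn{\mu_s'} for the grid compartments (vector for
#'   one query, or a tibble/matrix with columns `musp_<compartment>`).
#' @param mua_combo named absorption vector (or matrix, one row per query; a
#'   single row is recycled across scattering queries).
#' @return matrix `n_queries x n_detectors`.
#' @export
interpolate_reflectance <- function(table, musp_combo, mua_combo) {
  if (is.null(dim(musp_combo))) {
    musp_combo <- tibble::as_tibble(as.list(musp_combo))
    names(musp_combo) <- ifelse(grepl("^musp_", names(musp_combo)),
                                names(musp_combo),
                                paste0("musp_", names(musp_combo)))
  }
  musp_combo <- tibble::as_tibble(musp_combo)
  if (is.null(dim(mua_combo))) mua_combo <- matrix(
    mua_combo, nrow = 1, dimnames = list(NULL, names(mua_combo)))
  nq <- nrow(musp_combo)
  if (nrow(mua_combo) == 1 && nq > 1) {
    mua_combo <- mua_combo[rep(1, nq), , drop = FALSE]
  }
  stopifnot(nrow(mua_combo) == nq)
  W <- lut_interp_weights(table$grid, musp_combo)
  ndet <- nrow(table$detectors)
  nodeR <- lut_node_reflectance(table, mua_combo)  # nodes x nq x ndet
  out <- matrix(NA_real_, nq, ndet)
  for (j in seq_len(ndet)) {
    logR <- log(pmax(nodeR[, , j, drop = FALSE][, , 1, drop = TRUE], 1e-300))
    if (nq == 1) logR <- matrix(logR, ncol = 1)
    out[, j] <- exp(rowSums(W * t(logR)))
  }
  colnames(out) <- paste0("d", table$detectors$id)
  out
}

# ---- NA conversion -----------------------------------------------------------

#' Fit the NA-conversion regression
#'
#' Simulating with all-angle acceptance (NA = 1) collects far more photons
#' than the physical NA = 0.12 fibers; this linear regression converts
#' all-angle reflectance to fiber reflectance. The response is the
#' low-NA / high-NA reflectance ratio; the six features are the logarithm of
#' the high-NA reflectance, the logarithm of the high-NA detected photon
#' count, and the scalp/skull absorption and transport scattering, pooled
#' across detectors.
#'
#' @param pairs tibble with columns `ratio`, `log_R`, `log_N`, `mua_scalp`,
#'   `mua_skull`, `musp_scalp`, `musp_skull` (see [na_conversion_pairs()]).
#' @return object of class `na_conversion_model` wrapping the `lm` fit with
#'   R-squared and residual coefficient of variation.
#' @export
fit_na_conversion <- function(pairs) {
  need <- c("ratio", "log_R", "log_N", "mua_scalp", "mua_skull",
            "musp_scalp", "musp_skull")
  stopifnot(all(need %in% names(pairs)))
  if (nrow(pairs) < 30) {
    stop("need at least 30 paired observations to fit the NA conversion",
         call. = FALSE)
  }
  X <- as.matrix(pairs[setdiff(need, "ratio")])
  keep_feat <- apply(X, 2, function(col) stats::sd(col) > 0)
  form <- stats::as.formula(paste(
    "ratio ~", if (any(keep_feat)) paste(colnames(X)[keep_feat],
                                         collapse = " + ") else "1"))
  fit <- stats::lm(form, data = pairs)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient NA-conversion design; collinear features: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  res <- stats::residuals(fit)
  structure(list(fit = fit,
                 r_squared = summary(fit)$r.squared,
                 residual_cv = stats::sd(res) / mean(pairs$ratio),
                 n = nrow(pairs)),
            class = "na_conversion_model")
}

#' Build the paired high/low-NA observations for [fit_na_conversion()]
#'
#' For each pair of white MC runs (same geometry and scattering, all-angle vs
#' fiber NA) and each sampled absorption set, computes both reflectances via
#' [wmc_reflectance()] and assembles the feature rows.
#'
#' @param high,low `wmc_result`s at NA = 1 and at the fiber NA.
#' @param mua_samples matrix of absorption sets (columns `scalp`...`wm`).
#' @param musp named full scattering vector of the runs.
#' @param detectors detector ids to include (default all).
#' @return tibble of feature/response rows, detectors with zero counts
#'   dropped.
#' @export
na_conversion_pairs <- function(high, low, mua_samples, musp,
                                detectors = NULL) {
  if (is.null(detectors)) detectors <- high$per_det$id
  Rh <- wmc_reflectance(high, mua_samples)
  Rl <- wmc_reflectance(low, mua_samples)
  n_raw <- stats::setNames(high$per_det$n_raw, paste0("d", high$per_det$id))
  purrr::map_dfr(detectors, function(dd) {
    cn <- paste0("d", dd)
    ok <- Rh[, cn] > 0 & Rl[, cn] > 0
    tibble::tibble(
      detector = dd,
      ratio = Rl[ok, cn] / Rh[ok, cn],
      log_R = log(Rh[ok, cn]),
      log_N = log(n_raw[[cn]]),
      mua_scalp = mua_samples[ok, "scalp"],
      mua_skull = mua_samples[ok, "skull"],
      musp_scalp = musp[["scalp"]],
      musp_skull = musp[["skull"]])
  })
}

#' Predict the low-NA/high-NA ratio
#'
#' @param model a [fit_na_conversion()] model.
#' @param features tibble with the six feature columns.
#' @return numeric ratios, clipped into (0, 1]; clipping events are counted in
#'   attribute `n_clipped`.
#' @export
predict_na_ratio <- function(model, features) {
  r <- stats::predict(model$fit, newdata = features)
  n_clip <- sum(r <= 0 | r > 1)
  r <- pmin(pmax(r, 1e-6), 1)
  attr(r, "n_clipped") <- n_clip
  r
}

#' Convert all-angle reflectance to fiber-NA reflectance
#'
#' @param model a [fit_na_conversion()] model.
#' @param reflectance positive high-NA reflectance values.
#' @param features feature tibble aligned with `reflectance`.
#' @return converted reflectance.
#' @export
apply_na_conversion <- function(model, reflectance, features) {
  if (any(reflectance <= 0)) {
    stop("reflectance must be positive", call. = FALSE)
  }
  reflectance * as.numeric(predict_na_ratio(model, features))
}

#' @export
print.na_conversion_model <- function(x, ...) {
  cat(sprintf("NA-conversion model: n=%d, R^2=%.3f, residual CV=%.3g\n",
              x$n, x$r_squared, x$residual_cv))
  invisible(x)
}

# ---- training set ------------------------------------------------------------

#' Size of a training set without generating it
#'
#' The generator produces one row per (scattering combination, absorption
#' combination); scattering combinations are the grid nodes plus the extra
#' interpolated combinations. At the published scale -- the 2808-node grid,
#' 3000 interpolated scattering combinations, 3000 absorption combinations --
#' this is (2808 + 3000) x 3000 = 17,424,000 rows.
#'
#' @param grid a [musp_grid()].
#' @param n_mua absorption combinations.
#' @param n_musp_extra interpolated scattering combinations.
#' @return row count (double, exact).
#' @export
training_set_size <- function(grid, n_mua = 3000, n_musp_extra = 3000) {
  stopifnot(n_mua >= 1, n_musp_extra >= 0)
  (n_combinations(grid) + n_musp_extra) * n_mua
}

# uniform draws of mua per varied compartment within the allowed ranges, with
# the white-matter coupling mua_wm = mua_gm / 2
sample_mua <- function(n, compartments, ranges = op_ranges()) {
  out <- matrix(NA_real_, n, 5, dimnames = list(NULL, COMPARTMENTS))
  for (cmp in COMPARTMENTS) {
    r <- ranges[ranges$compartment == cmp, ]
    out[, cmp] <- stats::runif(n, r$mua_min, r$mua_max)
  }
  out[, "wm"] <- out[, "gm"] / 2
  fixed <- setdiff(COMPARTMENTS, c(compartments, "wm"))
  for (cmp in fixed) {
    r <- ranges[ranges$compartment == cmp, ]
    out[, cmp] <- (r$mua_min + r$mua_max) / 2
  }
  out
}

sample_musp <- function(n, grid) {
  out <- purrr::map(grid$nodes, function(nodes) {
    stats::runif(n, min(nodes), max(nodes))
  })
  names(out) <- paste0("musp_", names(grid$nodes))
  tibble::as_tibble(out)
}

#' Generate surrogate training data from a lookup table
#'
#' Rows pair a scattering combination (every grid node plus `n_musp_extra`
#' random in-hull combinations reached by spline interpolation) with `n_mua`
#' random absorption combinations drawn uniformly inside the allowed ranges
#' (white matter coupled to gray matter). Reflectance comes from the
#' Beer-Lambert rescaling of the stored records, optionally NA-converted.
#' Rows are tagged `train` / `val` / `test` in 75/10/15 proportions.
#'
#' @param table a [build_lookup_table()] table.
#' @param n_mua absorption combinations.
#' @param n_musp_extra interpolated scattering combinations.
#' @param na_model optional [fit_na_conversion()] model applied to all rows.
#' @param ranges an [op_ranges()] table.
#' @param seed RNG seed (draws and split assignment).
#' @param split train/val/test fractions, summing to 1.
#' @return tibble with `musp_*`, `mua_*` inputs, `d*` reflectance columns and
#'   a `split` tag; class `training_set`.
#' @export
generate_training_set <- function(table, n_mua = 300, n_musp_extra = 150,
                                  na_model = NULL, ranges = op_ranges(),
                                  seed = 1L,
                                  split = c(train = 0.75, val = 0.10,
                                            test = 0.15)) {
  stopifnot(n_mua >= 1, n_musp_extra >= 0,
            abs(sum(split) - 1) < 1e-8)
  set.seed(seed)
  comps <- names(table$grid$nodes)
  mua <- sample_mua(n_mua, comps, ranges)
  node_combos <- table$combos
  extra <- sample_musp(n_musp_extra, table$grid)
  ndet <- nrow(table$detectors)
  det_cols <- paste0("d", table$detectors$id)

  # node rows: Eq. (5) at each stored node
  nodeR <- lut_node_reflectance(table, mua)          # nodes x n_mua x ndet
  node_rows <- purrr::map_dfr(seq_len(nrow(node_combos)), function(k) {
    R <- matrix(nodeR[k, , ], nrow = n_mua)
    colnames(R) <- det_cols
    dplyr::bind_cols(
      node_combos[rep(k, n_mua), , drop = FALSE],
      tibble::as_tibble(mua[, comps, drop = FALSE],
                        .name_repair = ~ paste0("mua_", comps)),
      tibble::as_tibble(R))
  })

  extra_rows <- NULL
  if (n_musp_extra > 0) {
    W <- lut_interp_weights(table$grid, extra)        # n_extra x nodes
    extra_rows <- purrr::map_dfr(seq_len(n_musp_extra), function(q) {
      # interpolate log R across scattering axes for all mua at once
      R <- vapply(seq_len(ndet), function(j) {
        logR <- log(pmax(matrix(nodeR[, , j], ncol = n_mua), 1e-300))
        exp(as.vector(W[q, , drop = FALSE] %*% logR))
      }, numeric(n_mua))
      colnames(R) <- det_cols
      dplyr::bind_cols(
        extra[rep(q, n_mua), , drop = FALSE],
        tibble::as_tibble(mua[, comps, drop = FALSE],
                          .name_repair = ~ paste0("mua_", comps)),
        tibble::as_tibble(R))
    })
  }
  out <- dplyr::bind_rows(node_rows, extra_rows)

  if (!is.null(na_model)) {
    for (j in seq_len(ndet)) {
      cn <- det_cols[j]
      feats <- tibble::tibble(
        log_R = log(pmax(out[[cn]], 1e-300)),
        log_N = log(max(mean(vapply(table$entries,
          function(e) e$per_det$n_raw[j], numeric(1))), 1)),
        mua_scalp = out$mua_scalp, mua_skull = out$mua_skull,
        musp_scalp = out$musp_scalp, musp_skull = out$musp_skull)
      pos <- out[[cn]] > 0
      out[[cn]][pos] <- apply_na_conversion(na_model, out[[cn]][pos],
                                            feats[pos, ])
    }
  }

  keep <- rowSums(as.matrix(out[det_cols]) <= 0) == 0
  out <- out[keep, , drop = FALSE]
  n <- nrow(out)
  tags <- sample(rep(c("train", "val", "test"),
                     times = round_split(n, split)))
  out$split <- tags
  class(out) <- c("training_set", class(out))
  attr(out, "detectors") <- table$detectors
  attr(out, "compartments") <- comps
  attr(out, "seed") <- seed
  out
}

# largest-remainder apportionment of n rows into the split fractions
round_split <- function(n, split) {
  raw <- n * split
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_frac <- order(raw - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  base
}
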