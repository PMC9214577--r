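# Feedforward surrogate forward model: optical properties of the varied
# compartments -> log reflectance at the detectors. A small fully connected
# network trained on lookup-table data replaces Monte Carlo inside the
# inverse loop; at the published scale the hidden layers are 850/550/300/150,
# at desk scale two layers of 64 suffice.

mlp_init <- function(sizes, seed) {
  set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    # Glorot-scaled tanh initialization
    s <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -s, s),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(net, X, keep = FALSE) {
  L <- length(net$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1]] <- if (l < L) tanh(Z) else Z
  }
  if (keep) A else A[[L + 1]]
}

mlp_grad <- function(net, A, resid) {
  # resid = dLoss/dOutput at the linear output layer
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- resid
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta) / nrow(delta)
    gb[[l]] <- colMeans(delta)
    if (l > 1) delta <- (delta %*% t(net$W[[l]])) * (1 - A[[l]]^2)
  }
  list(W = gW, b = gb)
}

#' Train the surrogate forward model
#'
#' Fits a fully connected network with tanh hidden layers and a linear output
#' to predict log-reflectance at every detector from the optical-property
#' vector (absorption and transport scattering of each varied compartment).
#' Inputs and targets are z-scored on the training split; optimization is
#' minibatch Adam on the mean squared error with early stopping on the
#' validation split. The tanh nonlinearity keeps the learned forward map
#' smooth, which the gradient-based fitter relies on.
#'
#' @param data a [generate_training_set()] tibble (or any tibble with
#'   `mua_*` / `musp_*` inputs, `d*` reflectance columns and a `split` tag).
#' @param hidden hidden-layer widths.
#' @param epochs maximum training epochs.
#' @param batch minibatch size.
#' @param lr Adam step size.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed seed for initialization and shuffling.
#' @param verbose print per-epoch losses.
#' @return object of class `surrogate_model` with per-detector RMS percent
#'   error on the held-out test split.
#' @export
train_surrogate <- function(data, hidden = c(64, 64), epochs = 200,
                            batch = 1024, lr = 2e-3, patience = 20,
                            seed = 1L, verbose = FALSE) {
  comps <- attr(data, "compartments")
  if (is.null(comps)) {
    comps <- sub("^mua_", "", grep("^mua_", names(data), value = TRUE))
  }
  in_cols <- c(paste0("mua_", comps), paste0("musp_", comps))
  out_cols <- grep("^d[0-9]+$", names(data), value = TRUE)
  stopifnot(length(out_cols) >= 1, all(in_cols %in% names(data)))
  tr <- data$split == "train"
  if (!any(tr)) stop("empty training split", call. = FALSE)

  X <- as.matrix(data[in_cols]); Y <- log(as.matrix(data[out_cols]))
  mu_x <- colMeans(X[tr, , drop = FALSE])
  sd_x <- pmax(apply(X[tr, , drop = FALSE], 2, stats::sd), 1e-12)
  mu_y <- colMeans(Y[tr, , drop = FALSE])
  sd_y <- pmax(apply(Y[tr, , drop = FALSE], 2, stats::sd), 1e-12)
  Xs <- sweep(sweep(X, 2, mu_x), 2, sd_x, "/")
  Ys <- sweep(sweep(Y, 2, mu_y), 2, sd_y, "/")

  sizes <- c(ncol(X), hidden, ncol(Y))
  net <- mlp_init(sizes, seed)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0

  itr <- which(tr); ival <- which(data$split == "val")
  if (!length(ival)) ival <- itr
  best <- list(loss = Inf, net = net, epoch = 0)
  set.seed(seed + 1)
  for (ep in seq_len(epochs)) {
    ord <- sample(itr)
    for (start in seq(1, length(ord), by = batch)) {
      idx <- ord[start:min(start + batch - 1, length(ord))]
      A <- mlp_forward(net, Xs[idx, , drop = FALSE], keep = TRUE)
      resid <- 2 * (A[[length(A)]] - Ys[idx, , drop = FALSE])
      g <- mlp_grad(net, A, resid)
      t <- t + 1
      for (l in seq_along(net$W)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
        corr <- sqrt(1 - b2^t) / (1 - b1^t)
        net$W[[l]] <- net$W[[l]] - lr * corr * mW[[l]] / (sqrt(vW[[l]]) + eps)
        net$b[[l]] <- net$b[[l]] - lr * corr * mb[[l]] / (sqrt(vb[[l]]) + eps)
      }
      if (any(!is.finite(net$W[[1]]))) {
        stop("training diverged (non-finite weights); last good epoch ",
             best$epoch, call. = FALSE)
      }
    }
    val_loss <- mean((mlp_forward(net, Xs[ival, , drop = FALSE]) -
                      Ys[ival, , drop = FALSE])^2)
    if (verbose) message(sprintf("epoch %d: val MSE %.5f", ep, val_loss))
    if (val_loss < best$loss - 1e-7) {
      best <- list(loss = val_loss, net = net, epoch = ep)
    } else if (ep - best$epoch >= patience) break
  }

  model <- structure(list(
    net = best$net, sizes = sizes,
    in_cols = in_cols, out_cols = out_cols, compartments = comps,
    mu_x = mu_x, sd_x = sd_x, mu_y = mu_y, sd_y = sd_y,
    seed = seed, epochs_run = best$epoch, val_loss = best$loss
  ), class = "surrogate_model")

  ite <- which(data$split == "test")
  if (length(ite)) {
    pred <- predict_reflectance(model, data[ite, in_cols])
    truth <- as.matrix(data[ite, out_cols])
    model$test_rms_pct <- sqrt(colMeans((pred / truth - 1)^2)) * 100
  }
  model
}

#' Predict reflectance with the surrogate
#'
#' Vectorized forward pass: thousands of optical-property vectors per call.
#' Outputs are parameterized on the log scale, so predictions are strictly
#' positive. Inputs outside the allowed ranges trigger a warning (the
#' optimizer probes boundaries) but are evaluated.
#'
#' @param model a [train_surrogate()] model.
#' @param op named numeric vector, matrix, or tibble with the model's input
#'   columns (`mua_*`, `musp_*`).
#' @param warn_outside warn when inputs fall outside the training ranges.
#' @return matrix `n x n_detectors` of reflectance.
#' @export
predict_reflectance <- function(model, op, warn_outside = FALSE) {
  if (is.null(dim(op))) op <- matrix(op, nrow = 1,
                                     dimnames = list(NULL, names(op)))
  if (any(!is.finite(as.matrix(tibble::as_tibble(op))))) {
    stop("non-finite optical properties", call. = FALSE)
  }
  op <- as.matrix(tibble::as_tibble(op)[, model$in_cols, drop = FALSE])
  if (warn_outside) {
    lo <- model$mu_x - 4 * model$sd_x; hi <- model$mu_x + 4 * model$sd_x
    if (any(sweep(op, 2, lo) < 0) || any(sweep(op, 2, hi) > 0)) {
      warning("optical properties far outside the training range",
              call. = FALSE)
    }
  }
  Xs <- sweep(sweep(op, 2, model$mu_x), 2, model$sd_x, "/")
  Ys <- mlp_forward(model$net, Xs)
  R <- exp(sweep(sweep(Ys, 2, model$sd_y, "*"), 2, model$mu_y, "+"))
  colnames(R) <- model$out_cols
  R
}

#' Forward function with gradient support
#'
#' Wraps a surrogate as the forward function consumed by the fitter, attaching
#' a vector-Jacobian product so the optimizer can use analytic gradients: one
#' forward pass plus one backward pass per objective evaluation instead of a
#' finite-difference sweep over all parameters.
#'
#' @param model a [train_surrogate()] model.
#' @return function `op -> reflectance matrix`, with attribute `with_grad`: a
#'   function returning `list(R, vjp)` where `vjp(dE_dR)` maps a gradient with
#'   respect to reflectance back to a gradient with respect to the OP matrix.
#' @export
surrogate_forward <- function(model) {
  f <- function(op) predict_reflectance(model, op)
  attr(f, "with_grad") <- function(op) {
    op <- as.matrix(tibble::as_tibble(op)[, model$in_cols, drop = FALSE])
    Xs <- sweep(sweep(op, 2, model$mu_x), 2, model$sd_x, "/")
    A <- mlp_forward(model$net, Xs, keep = TRUE)
    L <- length(model$net$W)
    R <- exp(sweep(sweep(A[[L + 1]], 2, model$sd_y, "*"), 2, model$mu_y, "+"))
    colnames(R) <- model$out_cols
    vjp <- function(dE_dR) {
      # dE/dy (normalized outputs), then back through the tanh stack
      delta <- dE_dR * R * matrix(model$sd_y, nrow(R), ncol(R), byrow = TRUE)
      for (l in rev(seq_len(L))) {
        if (l < L) delta <- delta * (1 - A[[l + 1]]^2)
        delta <- delta %*% t(model$net$W[[l]])
      }
      sweep(delta, 2, model$sd_x, "/")  # to raw OP units
    }
    list(R = R, vjp = vjp)
  }
  f
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("Surrogate forward model: %s, trained %d epochs (val MSE %.2e)\n",
              paste(x$sizes, collapse = "-"), x$epochs_run, x$val_loss))
  if (!is.null(x$test_rms_pct)) {
    cat("  test RMS % error:",
        paste(sprintf("%s=%.1f", names(x$test_rms_pct), x$test_rms_pct),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy surrogate_model
#' @export
tidy.surrogate_model <- function(x, ...) {
  tibble::tibble(detector = x$out_cols,
                 test_rms_pct = if (is.null(x$test_rms_pct)) NA_real_
                                else unname(x$test_rms_pct))
}

#' @method glance surrogate_model
#' @export
glance.surrogate_model <- function(x, ...) {
  tibble::tibble(layers = paste(x$sizes, collapse = "-"),
                 epochs = x$epochs_run, val_mse = x$val_loss,
                 mean_test_rms_pct = if (is.null(x$test_rms_pct)) NA_real_
                                     else mean(x$test_rms_pct))
}

#' Serialize / restore a surrogate model as JSON
#'
#' Plain-text round trip that preserves predictions bit-exactly (weights are
#' written with full precision).
#'
#' @param model a `surrogate_model`.
#' @param path file path.
#' @return `path` (write) / the model (read).
#' @export
write_surrogate <- function(model, path) {
  # doubles are serialized as %.17g strings: 17 significant digits round-trip
  # IEEE doubles exactly, so restored models predict bit-identically
  num <- function(x) sprintf("%.17g", x)
  payload <- list(
    sizes = model$sizes, in_cols = model$in_cols, out_cols = model$out_cols,
    compartments = model$compartments,
    W = lapply(model$net$W, function(w) list(dim = dim(w),
                                             x = num(as.vector(w)))),
    b = lapply(model$net$b, num),
    mu_x = num(model$mu_x), sd_x = num(model$sd_x),
    mu_y = num(model$mu_y), sd_y = num(model$sd_y),
    col_names = list(x = model$in_cols, y = model$out_cols),
    seed = model$seed, epochs_run = model$epochs_run,
    val_loss = model$val_loss,
    test_rms_pct = if (is.null(model$test_rms_pct)) NULL
                   else num(model$test_rms_pct))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  net <- list(
    W = lapply(p$W, function(w) {
      d <- as.integer(unlist(w$dim))
      matrix(as.numeric(unlist(w$x)), d[1], d[2])
    }),
    b = lapply(p$b, function(bb) as.numeric(unlist(bb))))
  in_cols <- unlist(p$in_cols)
  out_cols <- unlist(p$out_cols)
  num <- function(x, names = NULL) {
    stats::setNames(as.numeric(unlist(x)), names)
  }
  structure(list(
    net = net, sizes = as.integer(unlist(p$sizes)),
    in_cols = in_cols, out_cols = out_cols,
    compartments = unlist(p$compartments),
    mu_x = num(p$mu_x, in_cols), sd_x = num(p$sd_x, in_cols),
    mu_y = num(p$mu_y, out_cols), sd_y = num(p$sd_y, out_cols),
    seed = p$seed, epochs_run = p$epochs_run, val_loss = p$val_loss,
    test_rms_pct = if (is.null(p$test_rms_pct)) NULL
                   else num(p$test_rms_pct, out_cols)
  ), class = "surrogate_model")
}
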