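# Forward surrogate networks: small fully connected feed-forward regressors
# (tanh hidden layers, linear output) trained by full-batch Adam on MSE.
# BPNN1 maps (c, phi, t, m, n, l) -> compressive modulus C11; BPNN2 maps the
# same inputs -> shear modulus C44. Directional moduli come from querying the
# networks on axis-permuted cell counts, so single-output networks suffice.

input_cols <- c("c", "phi", "t", "m", "n", "l")

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    W <- list(); b <- list()
    for (k in seq_len(length(sizes) - 1L)) {
      s <- sqrt(6 / (sizes[k] + sizes[k + 1L]))
      W[[k]] <- matrix(stats::runif(sizes[k] * sizes[k + 1L], -s, s),
                       sizes[k], sizes[k + 1L])
      b[[k]] <- numeric(sizes[k + 1L])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, X) {
  nl <- length(par$W)
  H <- vector("list", nl + 1L)
  H[[1L]] <- X
  for (k in seq_len(nl - 1L))
    H[[k + 1L]] <- tanh(sweep(H[[k]] %*% par$W[[k]], 2L, par$b[[k]], `+`))
  H[[nl + 1L]] <- sweep(H[[nl]] %*% par$W[[nl]], 2L, par$b[[nl]], `+`)
  H
}

# Gradient of mean squared error wrt all weights, full batch.
mlp_grad <- function(par, H, y) {
  nl <- length(par$W)
  n <- length(y)
  gW <- vector("list", nl); gb <- vector("list", nl)
  delta <- 2 * (H[[nl + 1L]] - y) / n        # d(MSE)/d(yhat), n x 1
  for (k in nl:1) {
    gW[[k]] <- crossprod(H[[k]], delta)
    gb[[k]] <- colSums(delta)
    if (k > 1L)
      delta <- (delta %*% t(par$W[[k]])) * (1 - H[[k]]^2)  # tanh'
  }
  list(W = gW, b = gb)
}

#' Train a forward surrogate network
#'
#' Fits a fully connected network with `hidden` tanh layers and a linear
#' output to one modulus label, minimizing mean squared error on standardized
#' inputs and labels with full-batch Adam. A fraction of the training split is
#' held out for early stopping: training keeps the weights with the lowest
#' held-out MSE and stops once it has not improved for `patience` epochs.
#' Training is deterministic for a fixed seed.
#'
#' @param ds a split `tpms_dataset` (see [split_dataset()]).
#' @param target `"compressive"` (the `C11` label, BPNN1) or `"shear"`
#'   (the `C44` label, BPNN2).
#' @param hidden hidden-layer widths; default `c(48, 48)`, the architecture
#'   selected by [architecture_search()] on the full protocol.
#' @param epochs maximum training epochs.
#' @param seed RNG seed for initialization and the validation split.
#' @param lr Adam learning rate.
#' @param val_fraction fraction of the training split held out for early
#'   stopping.
#' @param patience early-stopping patience in epochs.
#' @param l2 decoupled weight-decay coefficient on the weights (not biases).
#' @param overfit_tol fail the run if final test MSE exceeds `overfit_tol`
#'   times the training MSE (an overfitting guard; `Inf` disables). Only
#'   checked when the dataset has a test split.
#' @return A `bpnn` model: weights, normalizers, and training metadata.
#' @export
train_bpnn <- function(ds, target = c("compressive", "shear"),
                       hidden = c(48, 48), epochs = 3000, seed = 1,
                       lr = 0.01, val_fraction = 0.15, patience = 300,
                       l2 = 0, overfit_tol = 3) {
  stopifnot(inherits(ds, "tpms_dataset"))
  target <- match.arg(target)
  if (length(ds$train) < 50L) stop_cfg("need at least 50 training records, have %d",
                                       length(ds$train))
  label <- if (target == "compressive") "C11" else "C44"
  rec <- ds$records
  X <- as.matrix(rec[ds$train, input_cols])
  y <- rec[[label]][ds$train]
  xm <- colMeans(X); xs <- apply(X, 2L, stats::sd); xs[xs == 0] <- 1
  ym <- mean(y); ys <- stats::sd(y); if (ys == 0) ys <- 1
  Xs <- sweep(sweep(X, 2L, xm), 2L, xs, `/`)
  ysc <- (y - ym) / ys
  nfit <- nrow(Xs)
  nval <- max(1L, round(val_fraction * nfit))
  val_idx <- with_seed(derive_seed(seed, "valsplit"), sample.int(nfit, nval))
  fit_idx <- setdiff(seq_len(nfit), val_idx)
  Xf <- Xs[fit_idx, , drop = FALSE]; yf <- ysc[fit_idx]
  Xv <- Xs[val_idx, , drop = FALSE]; yv <- ysc[val_idx]

  sizes <- c(ncol(Xs), hidden, 1L)
  par <- mlp_init(sizes, seed)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; epsad <- 1e-8
  best <- list(par = par, val = Inf, epoch = 0L)
  stall <- 0L
  for (ep in seq_len(epochs)) {
    H <- mlp_forward(par, Xf)
    if (!is.finite(sum(H[[length(H)]])))
      stop_cfg("non-finite loss at epoch %d (lr = %g); training aborted", ep, lr)
    g <- mlp_grad(par, H, yf)
    for (k in seq_along(par$W)) {
      mW[[k]] <- b1 * mW[[k]] + (1 - b1) * g$W[[k]]
      vW[[k]] <- b2 * vW[[k]] + (1 - b2) * g$W[[k]]^2
      mb[[k]] <- b1 * mb[[k]] + (1 - b1) * g$b[[k]]
      vb[[k]] <- b2 * vb[[k]] + (1 - b2) * g$b[[k]]^2
      mhW <- mW[[k]] / (1 - b1^ep); vhW <- vW[[k]] / (1 - b2^ep)
      mhb <- mb[[k]] / (1 - b1^ep); vhb <- vb[[k]] / (1 - b2^ep)
      par$W[[k]] <- par$W[[k]] - lr * (mhW / (sqrt(vhW) + epsad) + l2 * par$W[[k]])
      par$b[[k]] <- par$b[[k]] - lr * mhb / (sqrt(vhb) + epsad)
    }
    pv <- mlp_forward(par, Xv)
    vmse <- mean((pv[[length(pv)]] - yv)^2)
    if (vmse < best$val - 1e-12) {
      best <- list(par = par, val = vmse, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  par <- best$par
  model <- structure(
    list(W = par$W, b = par$b, sizes = sizes, activation = "tanh",
         norm = list(xm = xm, xs = xs, ym = ym, ys = ys),
         target = target, label = label,
         meta = list(seed = seed, epochs_run = ep, best_epoch = best$epoch,
                     hidden = hidden, lr = lr, R = ds$provenance$R,
                     ranges = list(min = apply(X, 2, min), max = apply(X, 2, max)))),
    class = "bpnn")
  tr_pred <- predict(model, X)
  model$meta$train_mse <- mean((tr_pred - y)^2)
  if (length(ds$test) > 0L) {
    Xt <- as.matrix(rec[ds$test, input_cols])
    yt <- rec[[label]][ds$test]
    te_pred <- predict(model, Xt)
    model$meta$test_mse <- mean((te_pred - yt)^2)
    ratio <- model$meta$test_mse / max(model$meta$train_mse, 1e-12)
    model$meta$overfit_ratio <- ratio
    if (is.finite(overfit_tol) && ratio > overfit_tol)
      stop_cfg("overfitting gate tripped: test MSE / train MSE = %.2f > %g",
               ratio, overfit_tol)
  }
  model
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("BPNN surrogate (%s -> %s): layers %s, tanh/linear\n",
              paste(input_cols, collapse = ","), x$label,
              paste(x$sizes, collapse = "-")))
  cat(sprintf("  train MSE %.3g GPa^2%s, best epoch %d\n",
              x$meta$train_mse,
              if (!is.null(x$meta$test_mse))
                sprintf(", test MSE %.3g GPa^2", x$meta$test_mse) else "",
              x$meta$best_epoch))
  invisible(x)
}

# Coerce predict input to a numeric matrix with the canonical 6 columns.
as_input_matrix <- function(newdata) {
  if (inherits(newdata, "tpms_config")) newdata <- list(newdata)
  if (is.list(newdata) && length(newdata) > 0 &&
      inherits(newdata[[1]], "tpms_config")) {
    newdata <- do.call(rbind, lapply(newdata, function(cf) {
      if (is.null(cf$t)) stop_cfg("config has no calibrated t; run calibrate_t first")
      c(cf$c, cf$phi, cf$t, cf$m, cf$n, cf$l)
    }))
    colnames(newdata) <- input_cols
  }
  X <- as.matrix(as.data.frame(newdata)[, input_cols])
  storage.mode(X) <- "double"
  X
}

#' Predict a modulus from design parameters
#'
#' Pure function of the model and the inputs; vectorized over rows. Inputs far
#' outside the training ranges are flagged via the `"extrapolated"` attribute.
#'
#' @param object a `bpnn` model.
#' @param newdata a [tpms_config()], a list of them, or a matrix/data frame
#'   with columns `c, phi, t, m, n, l`.
#' @param ... unused.
#' @return Numeric vector of predicted moduli (GPa).
#' @export
predict.bpnn <- function(object, newdata, ...) {
  X <- as_input_matrix(newdata)
  Xs <- sweep(sweep(X, 2L, object$norm$xm), 2L, object$norm$xs, `/`)
  H <- mlp_forward(object, Xs)
  out <- as.vector(H[[length(H)]]) * object$norm$ys + object$norm$ym
  rng <- object$meta$ranges
  if (!is.null(rng)) {
    span <- pmax(rng$max - rng$min, 1e-9)
    outside <- sweep(X, 2L, rng$min) < -0.25 * rep(span, each = nrow(X)) |
               sweep(X, 2L, rng$max) > 0.25 * rep(span, each = nrow(X))
    if (any(outside)) attr(out, "extrapolated") <- unname(which(rowSums(outside) > 0))
  }
  out
}

#' Evaluate a surrogate on a dataset split
#'
#' @param model a `bpnn`.
#' @param ds a split `tpms_dataset`.
#' @param split `"test"` or `"train"`.
#' @return An `eval_report`: `mape` (%), `mse` (GPa^2), per-sample relative
#'   errors (%), and the count of zero-label samples excluded from MAPE.
#' @export
evaluate_bpnn <- function(model, ds, split = c("test", "train")) {
  split <- match.arg(split)
  idx <- ds[[split]]
  if (length(idx) == 0L) stop_cfg("empty %s split", split)
  X <- as.matrix(ds$records[idx, input_cols])
  y <- ds$records[[model$label]][idx]
  pred <- as.vector(predict(model, X))
  nonzero <- y != 0
  rel <- abs(pred[nonzero] - y[nonzero]) / abs(y[nonzero]) * 100
  structure(list(mape = mean(rel), mse = mean((pred - y)^2),
                 rel_errors = rel, split = split,
                 n = length(idx), n_zero_excluded = sum(!nonzero)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s split (n = %d): MAPE %.2f%%, MSE %.4g GPa^2%s\n",
              x$split, x$n, x$mape, x$mse,
              if (x$n_zero_excluded > 0)
                sprintf(" (%d zero labels excluded)", x$n_zero_excluded) else ""))
  invisible(x)
}

#' Select the network architecture by test MAPE
#'
#' Trains one candidate per grid row with identical splits and seed and
#' returns the candidate with the lowest test MAPE together with the full
#' table.
#'
#' @param ds a split `tpms_dataset`.
#' @param grid data frame with columns `layers` and `width`.
#' @param target label to fit, see [train_bpnn()].
#' @param seed RNG seed shared by all candidates.
#' @param epochs,patience training controls (smaller than the defaults keeps a
#'   grid search affordable).
#' @return List with `best` (row of `grid`), `table` (grid plus `mape`,
#'   `train_mse`, `test_mse`), and `models`.
#' @export
architecture_search <- function(ds, grid = expand.grid(layers = 1:2,
                                                       width = c(16L, 48L)),
                                target = "compressive", seed = 1,
                                epochs = 1500, patience = 150) {
  if (nrow(grid) == 0L) stop_cfg("empty architecture grid")
  res <- vector("list", nrow(grid))
  mape <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hidden <- rep(grid$width[i], grid$layers[i])
    m <- train_bpnn(ds, target = target, hidden = hidden, epochs = epochs,
                    seed = seed, patience = patience, overfit_tol = Inf)
    res[[i]] <- m
    mape[i] <- evaluate_bpnn(m, ds, "test")$mape
  }
  tab <- cbind(grid,
               mape = mape,
               train_mse = vapply(res, function(m) m$meta$train_mse, 0),
               test_mse = vapply(res, function(m) m$meta$test_mse %||% NA_real_, 0))
  best_i <- which.min(mape)
  list(best = grid[best_i, , drop = FALSE], best_index = best_i,
       table = tab, models = res)
}

#' Save / load a surrogate as portable JSON
#'
#' Weights are written at full precision so a load/predict round trip is
#' bit-identical.
#'
#' @param model a `bpnn`.
#' @param path file path.
#' @return `path` (save) or a `bpnn` (load).
#' @export
save_bpnn <- function(model, path) {
  stopifnot(inherits(model, "bpnn"))
  # weights, biases and normalizers are stored as %.17g strings: 17
  # significant digits round-trip an IEEE double exactly, which plain JSON
  # number formatting does not guarantee
  num <- function(x) sprintf("%.17g", as.vector(x))
  payload <- list(schema = "tpmsdesign-bpnn-1",
                  sizes = model$sizes, activation = model$activation,
                  target = model$target, label = model$label,
                  # column-major flattening; reshaped from `sizes` on load
                  W = lapply(model$W, num),
                  b = lapply(model$b, num),
                  norm = lapply(model$norm, num),
                  meta = model$meta)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_bpnn
#' @export
load_bpnn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "tpmsdesign-bpnn-1"))
    stop_cfg("unrecognized model schema in %s", path)
  sizes <- as.integer(p$sizes)
  W <- lapply(seq_len(length(sizes) - 1L), function(k) {
    matrix(as.numeric(unlist(p$W[[k]])), sizes[k], sizes[k + 1L])
  })
  b <- lapply(seq_len(length(sizes) - 1L), function(k) as.numeric(p$b[[k]]))
  norm <- lapply(p$norm, function(x) as.numeric(unlist(x)))
  structure(list(W = W, b = b, sizes = sizes, activation = p$activation,
                 norm = norm, target = p$target, label = p$label,
                 meta = p$meta),
            class = "bpnn")
}
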