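#' Training control for the feedforward network
#'
#' @param maxit maximum optimizer iterations (full-batch BFGS).
#' @param reltol relative convergence tolerance on the loss.
#' @param init_range half-width of the uniform weight initialization.
#' @return a list of class `fnn_control`.
#' @export
fnn_control <- function(maxit = 200, reltol = 1e-9, init_range = 0.5) {
  structure(list(maxit = maxit, reltol = reltol, init_range = init_range),
            class = "fnn_control")
}

unpack_par <- function(par, p, m, q) {
  i <- 0
  W1 <- matrix(par[i + seq_len(p * m)], p, m); i <- i + p * m
  b1 <- par[i + seq_len(m)]; i <- i + m
  W2 <- matrix(par[i + seq_len(m * q)], m, q); i <- i + m * q
  b2 <- par[i + seq_len(q)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

#' Train a one-hidden-layer feedforward network
#'
#' A small regression network: linear input layer, `n_hidden` tanh units,
#' linear outputs, minimizing the mean squared error jointly over all output
#' factors. Optimization is full-batch BFGS with analytic gradients, so
#' training is a deterministic function of (seed, data, control): the same
#' replicate seed always reproduces bit-identical weights, which is what
#' makes seeded replicate training and resumable scans possible. Inputs are
#' expected in normalized space.
#'
#' @param windows a `window_set` with normalized `X`, `Y`.
#' @param n_hidden hidden units, `>= 1`.
#' @param seed replicate seed controlling weight initialization.
#' @param control an [fnn_control()].
#' @return an object of class `fnn`: weights, condition
#'   (`subset`, `n_hidden`, `seed`), input/output names, and a training log
#'   (`epochs`, `final_loss`, `convergence`).
#' @export
fnn_train <- function(windows, n_hidden, seed, control = fnn_control()) {
  stopifnot(inherits(windows, "window_set"), n_hidden >= 1)
  X <- windows$X; Y <- windows$Y
  if (nrow(X) < 10) stop("need at least 10 training samples", call. = FALSE)
  p <- ncol(X); q <- ncol(Y); m <- as.integer(n_hidden); n <- nrow(X)
  set.seed(seed)
  par0 <- stats::runif(p * m + m + m * q + q, -control$init_range, control$init_range)
  loss <- function(par) {
    w <- unpack_par(par, p, m, q)
    H <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
    E <- sweep(H %*% w$W2, 2, w$b2, "+") - Y
    mean(E * E)
  }
  grad <- function(par) {
    w <- unpack_par(par, p, m, q)
    H <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
    E <- sweep(H %*% w$W2, 2, w$b2, "+") - Y
    dO <- 2 * E / (n * q)
    dH <- (dO %*% t(w$W2)) * (1 - H * H)
    c(as.vector(crossprod(X, dH)), colSums(dH),
      as.vector(crossprod(H, dO)), colSums(dO))
  }
  fit <- stats::optim(par0, loss, grad, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  if (!is.finite(fit$value))
    stop(sprintf("training diverged (non-finite loss) after %d evaluations",
                 fit$counts[["function"]]), call. = FALSE)
  w <- unpack_par(fit$par, p, m, q)
  structure(list(weights = w,
                 condition = list(subset = windows$subset, n_hidden = m,
                                  seed = seed),
                 input_names = colnames(X), output_names = colnames(Y),
                 W = windows$W, h = windows$h,
                 log = list(epochs = fit$counts[["function"]],
                            final_loss = fit$value,
                            convergence = fit$convergence)),
            class = "fnn")
}

#' Predict with a trained network
#'
#' Predictions are returned in normalized space; de-normalization is an
#' explicit caller step. The window factor order must match the model's -
#' a mismatch is an error, never a silent reordering.
#'
#' @param object an `fnn`.
#' @param windows a `window_set` whose `X` columns match the model's inputs.
#' @param ... unused.
#' @return numeric matrix, one row per sample, columns = output factors.
#' @export
predict.fnn <- function(object, windows, ...) {
  X <- if (inherits(windows, "window_set")) windows$X else windows
  if (!identical(colnames(X), object$input_names))
    stop("window factor set/order does not match the model's inputs",
         call. = FALSE)
  w <- object$weights
  H <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
  out <- sweep(H %*% w$W2, 2, w$b2, "+")
  colnames(out) <- object$output_names
  out
}

#' @export
print.fnn <- function(x, ...) {
  cat(sprintf("fnn: %d inputs -> %d tanh hidden -> %d outputs\n",
              length(x$input_names), x$condition$n_hidden,
              length(x$output_names)))
  cat(sprintf("  subset: {%s}; seed %d; final training MSE %.4g (%d evals)\n",
              paste(x$condition$subset, collapse = ", ") ,
              x$condition$seed, x$log$final_loss, x$log$epochs))
  invisible(x)
}

#' @export
coef.fnn <- function(object, ...) object$weights

#' @export
summary.fnn <- function(object, ...) {
  s <- list(n_par = length(unlist(object$weights)),
            condition = object$condition, log = object$log)
  class(s) <- "summary.fnn"
  s
}

#' @export
print.summary.fnn <- function(x, ...) {
  cat(sprintf("fnn with %d parameters; n_hidden=%d; seed=%d\n",
              x$n_par, x$condition$n_hidden, x$condition$seed))
  cat(sprintf("final loss %.6g; convergence code %d\n",
              x$log$final_loss, x$log$convergence))
  invisible(x)
}

#' Serialize / restore a trained network as portable JSON
#'
#' @param model an `fnn`.
#' @param path file path.
#' @export
write_fnn <- function(model, path) {
  stopifnot(inherits(model, "fnn"))
  obj <- list(weights = lapply(model$weights, function(w)
    if (is.matrix(w)) list(dim = dim(w), data = as.vector(w)) else
      list(dim = length(w), data = as.vector(w))),
    condition = model$condition, input_names = model$input_names,
    output_names = model$output_names, W = model$W, h = model$h,
    log = model$log)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fnn
#' @param path file path.
#' @export
read_fnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- obj$weights
  model <- list(weights = list(W1 = matrix(w$W1$data, w$W1$dim[1], w$W1$dim[2]),
                               b1 = as.numeric(w$b1$data),
                               W2 = matrix(w$W2$data, w$W2$dim[1], w$W2$dim[2]),
                               b2 = as.numeric(w$b2$data)),
                condition = list(subset = as.character(obj$condition$subset %||% character(0)),
                                 n_hidden = obj$condition$n_hidden,
                                 seed = obj$condition$seed),
                input_names = obj$input_names, output_names = obj$output_names,
                W = obj$W, h = obj$h, log = obj$log)
  class(model) <- "fnn"
  model
}
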