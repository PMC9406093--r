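#' Mean absolute error
#'
#' `MAE = mean(|y - y_hat|)`, the training and validation metric of the
#' drift predictor.
#'
#' @param actual,predicted equal-length non-empty numeric vectors.
#' @return Non-negative scalar.
#' @examples
#' mae(c(1, 2, 3), c(1.1, 1.8, 3.3))  # 0.2
#' @export
mae <- function(actual, predicted) {
  if (length(actual) == 0L || length(actual) != length(predicted)) {
    stop("actual and predicted must be non-empty and of equal length",
         call. = FALSE)
  }
  mean(abs(actual - predicted))
}

#' Drift trace with chronological train/test split
#'
#' A post-attachment settling series: times (seconds), normalized signal,
#' and a chronological split — the canonical recording has 31 samples at
#' 2 s intervals over 60 s, split 26 train / 5 test.
#'
#' @param t sample times in seconds, strictly increasing.
#' @param y normalized signal values, same length, finite.
#' @param n_train number of leading samples in the training set (default
#'   26; the rest are the test set).
#' @return Object of class `drift_trace` with `t`, `y`, `train_idx`,
#'   `test_idx`.
#' @export
drift_trace <- function(t, y, n_train = 26L) {
  if (length(t) != length(y)) stop("t and y lengths differ", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(t))) {
    stop("drift trace must be finite", call. = FALSE)
  }
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  n_train <- as.integer(n_train)
  if (n_train < 2L || n_train >= length(t)) {
    stop("n_train must leave at least one test sample", call. = FALSE)
  }
  structure(list(t = as.numeric(t), y = as.numeric(y),
                 train_idx = seq_len(n_train),
                 test_idx = seq(n_train + 1L, length(t))),
            class = "drift_trace")
}

#' Feedforward-network specification for drift prediction
#'
#' The drift predictor is a multi-layer perceptron regressing the
#' normalized signal on scaled time: five hidden layers of 128, 256, 128,
#' 64 and 16 units, sigmoid activation on the first hidden layer and ReLU
#' on the rest, linear output, trained for 200 epochs by AdaGrad on the
#' MAE loss with batch size 64 (full batch for the 26-sample training
#' set).
#'
#' @param hidden_units hidden-layer widths.
#' @param activations per-hidden-layer activations (`"sigmoid"` or
#'   `"relu"`).
#' Because the MAE objective is non-smooth, the fitted parameters are the
#' averaged iterates over the trailing `average_tail` fraction of epochs —
#' the estimator subgradient-method guarantees apply to — rather than the
#' last iterate, and the AdaGrad accumulator starts at
#' `accumulator_init > 0` so the first update is not a full-step sign kick.
#'
#' @param epochs training epochs (> 0).
#' @param batch_size minibatch size.
#' @param learning_rate AdaGrad base step size.
#' @param accumulator_init initial value of the AdaGrad squared-gradient
#'   accumulator.
#' @param average_tail fraction of trailing epochs whose parameter iterates
#'   are averaged into the returned model (0 = use the last iterate).
#' @param seed RNG seed for weight initialization and batch shuffling.
#' @return Object of class `mlp_spec`.
#' @export
mlp_spec <- function(hidden_units = c(128L, 256L, 128L, 64L, 16L),
                     activations = c("sigmoid", "relu", "relu", "relu",
                                     "relu"),
                     epochs = 200L, batch_size = 64L, learning_rate = 0.02,
                     accumulator_init = 0.1, average_tail = 0.5,
                     seed = 7L) {
  if (length(hidden_units) != length(activations)) {
    stop("one activation per hidden layer", call. = FALSE)
  }
  if (!all(activations %in% c("sigmoid", "relu"))) {
    stop("activations must be 'sigmoid' or 'relu'", call. = FALSE)
  }
  if (epochs < 1L) stop("epochs must be > 0", call. = FALSE)
  if (accumulator_init < 0) stop("accumulator_init must be >= 0", call. = FALSE)
  if (average_tail < 0 || average_tail > 1) {
    stop("average_tail must be in [0, 1]", call. = FALSE)
  }
  structure(list(hidden_units = as.integer(hidden_units),
                 activations = activations, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 accumulator_init = accumulator_init,
                 average_tail = average_tail, seed = as.integer(seed)),
            class = "mlp_spec")
}

# initialize weights: uniform with fan-in scaling, seeded
mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]
      s <- sqrt(6 / fan_in)
      list(W = matrix(stats::runif(fan_in * sizes[l + 1L], -s, s),
                      nrow = fan_in),
           b = rep(0, sizes[l + 1L]))
    })
  })
}

mlp_forward <- function(params, X, activations) {
  a <- X
  acts <- list(a)
  n_layers <- length(params)
  for (l in seq_len(n_layers)) {
    z <- a %*% params[[l]]$W + matrix(params[[l]]$b, nrow = nrow(a),
                                      ncol = length(params[[l]]$b),
                                      byrow = TRUE)
    a <- if (l == n_layers) z
         else if (activations[l] == "sigmoid") sigmoid(z)
         else relu(z)
    acts[[l + 1L]] <- a
  }
  acts
}

#' Fit the drift network and predict the full trace
#'
#' Trains the [mlp_spec()] network on the training split of a
#' [drift_trace()] — time min-max scaled to `[0, 1]` over the whole trace,
#' target min-max scaled over the training split — minimizing MAE with
#' AdaGrad, and returns predictions over all samples with train and test
#' MAE. Deterministic under the spec seed.
#'
#' @param trace a [drift_trace()].
#' @param spec an [mlp_spec()].
#' @return List of class `drift_fit`: `predictions` (full trace, original
#'   scale), `train_mae`, `test_mae`, `history` (per-epoch training MAE on
#'   the original scale).
#' @export
drift_fit_predict <- function(trace, spec = mlp_spec()) {
  stopifnot(inherits(trace, "drift_trace"), inherits(spec, "mlp_spec"))
  t_scaled <- (trace$t - min(trace$t)) / diff(range(trace$t))
  X_all <- matrix(t_scaled, ncol = 1)
  X <- X_all[trace$train_idx, , drop = FALSE]
  y_raw <- trace$y[trace$train_idx]
  y0 <- min(y_raw)
  y_span <- diff(range(y_raw))
  if (y_span == 0) y_span <- 1
  y <- (y_raw - y0) / y_span
  sizes <- c(1L, spec$hidden_units, 1L)
  params <- mlp_init(sizes, spec$seed)
  grads_sq <- lapply(params, function(p) {
    list(W = matrix(spec$accumulator_init, nrow(p$W), ncol(p$W)),
         b = rep(spec$accumulator_init, length(p$b)))
  })
  lr <- spec$learning_rate
  eps <- 1e-8
  n <- nrow(X)
  history <- numeric(spec$epochs)
  avg_start <- if (spec$average_tail > 0) {
    max(1L, ceiling(spec$epochs * (1 - spec$average_tail)))
  } else spec$epochs + 1L
  avg <- NULL
  n_avg <- 0L

  with_seed(spec$seed + 1L, {
    for (epoch in seq_len(spec$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = spec$batch_size)
      for (s in starts) {
        batch <- idx[s:min(s + spec$batch_size - 1L, n)]
        acts <- mlp_forward(params, X[batch, , drop = FALSE],
                            spec$activations)
        pred <- acts[[length(acts)]][, 1]
        # MAE loss (sub)gradient at the output
        delta <- matrix(sign(pred - y[batch]) / length(batch), ncol = 1)
        for (l in rev(seq_along(params))) {
          a_prev <- acts[[l]]
          gW <- crossprod(a_prev, delta)
          gb <- colSums(delta)
          if (l > 1L) {
            da <- delta %*% t(params[[l]]$W)
            a_cur <- acts[[l]]
            delta <- if (spec$activations[l - 1L] == "sigmoid") {
              da * a_cur * (1 - a_cur)
            } else {
              da * (a_cur > 0)
            }
          }
          grads_sq[[l]]$W <- grads_sq[[l]]$W + gW^2
          grads_sq[[l]]$b <- grads_sq[[l]]$b + gb^2
          params[[l]]$W <- params[[l]]$W -
            lr * gW / (sqrt(grads_sq[[l]]$W) + eps)
          params[[l]]$b <- params[[l]]$b -
            lr * gb / (sqrt(grads_sq[[l]]$b) + eps)
        }
      }
      acts <- mlp_forward(params, X, spec$activations)
      history[epoch] <- mae(y_raw, acts[[length(acts)]][, 1] * y_span + y0)
      if (epoch >= avg_start) {
        n_avg <- n_avg + 1L
        if (is.null(avg)) {
          avg <- params
        } else {
          avg <- mapply(function(a, p) {
            list(W = a$W + (p$W - a$W) / n_avg,
                 b = a$b + (p$b - a$b) / n_avg)
          }, avg, params, SIMPLIFY = FALSE)
        }
      }
    }
  })

  final <- if (is.null(avg)) params else avg
  pred_all <- mlp_forward(final, X_all, spec$activations)
  pred_all <- pred_all[[length(pred_all)]][, 1] * y_span + y0
  structure(list(
    predictions = pred_all,
    train_mae = mae(trace$y[trace$train_idx], pred_all[trace$train_idx]),
    test_mae = mae(trace$y[trace$test_idx], pred_all[trace$test_idx]),
    history = history),
    class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, ...) {
  cat(sprintf("<drift_fit> train MAE %.4f, test MAE %.4f (%d epochs)\n",
              x$train_mae, x$test_mae, length(x$history)))
  invisible(x)
}

#' Exponential least-squares baseline for the drift trace
#'
#' Fits `y = c0 + A * exp(-t / tau)` to the training split by nonlinear
#' least squares (with a log-linear start and an `optim()` fallback) and
#' reports its test MAE — the parametric baseline the network predictor is
#' compared against.
#'
#' @param trace a [drift_trace()].
#' @return List with `coef` (c0, A, tau), `predictions`, `train_mae`,
#'   `test_mae`.
#' @export
fit_exponential_decay <- function(trace) {
  stopifnot(inherits(trace, "drift_trace"))
  t_tr <- trace$t[trace$train_idx]
  y_tr <- trace$y[trace$train_idx]
  c0_0 <- min(y_tr)
  resid0 <- pmax(y_tr - c0_0 + 1e-6, 1e-6)
  lf <- stats::lm(log(resid0) ~ t_tr)
  start <- list(c0 = c0_0, A = exp(unname(stats::coef(lf)[1])),
                tau = max(-1 / unname(stats::coef(lf)[2]), 1))
  fit <- tryCatch(
    stats::nls(y_tr ~ c0 + A * exp(-t_tr / tau), start = start,
               # scaleOffset makes the convergence test valid for
               # zero-residual (noise-free) traces
               control = stats::nls.control(maxiter = 200, scaleOffset = 1,
                                            warnOnly = TRUE)),
    error = function(e) NULL)
  co <- if (!is.null(fit)) as.list(stats::coef(fit)) else {
    obj <- function(p) sum((y_tr - (p[1] + p[2] * exp(-t_tr / p[3])))^2)
    op <- stats::optim(unlist(start), obj)
    as.list(stats::setNames(op$par, c("c0", "A", "tau")))
  }
  pred <- co$c0 + co$A * exp(-trace$t / co$tau)
  list(coef = co, predictions = pred,
       train_mae = mae(y_tr, pred[trace$train_idx]),
       test_mae = mae(trace$y[trace$test_idx], pred[trace$test_idx]))
}
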