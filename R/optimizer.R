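# Optimizers over flat parameter vectors.
#
# The default is a bounded variant of Adam: per-parameter adaptive step
# sizes are clipped into a band that starts wide and pinches onto a final
# learning rate as training proceeds, combining Adam's fast early progress
# with SGD-like late-stage behavior.

#' Training configuration
#'
#' @param batch_size Mini-batch size (default 8).
#' @param learning_rate Base learning rate (default 1e-4).
#' @param final_lr Asymptotic (SGD-phase) learning rate of the bounded
#'   optimizer (default 0.01).
#' @param max_epochs Training epochs; the returned parameters are those of
#'   the epoch with the lowest validation loss, so there is no early stop.
#' @param optimizer `"adabound"`, `"adam"` or `"sgd"`.
#' @param beta1,beta2 Exponential decay of the first/second gradient
#'   moments.
#' @param gamma Bound-convergence speed: the step-size band is
#'   `[final_lr * (1 - 1/(gamma * t + 1)), final_lr * (1 + 1/(gamma * t))]`
#'   at step t.
#' @param eps Numerical floor inside the adaptive denominator.
#' @param augment Apply the augmentation plan during training (prediction
#'   passes never augment).
#' @param seed Seed controlling shuffling and augmentation draws.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 8, learning_rate = 1e-4,
                         final_lr = 0.01, max_epochs = 50,
                         optimizer = c("adabound", "adam", "sgd"),
                         beta1 = 0.9, beta2 = 0.999, gamma = 1e-3,
                         eps = 1e-8, augment = TRUE, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stop_if_not(batch_size >= 1, "batch_size must be >= 1")
  stop_if_not(learning_rate > 0 && final_lr > 0, "learning rates must be positive")
  stop_if_not(max_epochs >= 1, "max_epochs must be >= 1")
  stop_if_not(beta1 >= 0 && beta1 < 1 && beta2 >= 0 && beta2 < 1,
              "beta1/beta2 must lie in [0, 1)")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, final_lr = final_lr,
                 max_epochs = as.integer(max_epochs), optimizer = optimizer,
                 beta1 = beta1, beta2 = beta2, gamma = gamma, eps = eps,
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize optimizer state
#'
#' @param n_par Number of parameters.
#' @return An `optimizer_state`: step counter `t` and first/second moment
#'   accumulators `m`, `v`.
#' @export
optimizer_init <- function(n_par) {
  structure(list(t = 0L, m = numeric(n_par), v = numeric(n_par)),
            class = "optimizer_state")
}

#' One optimizer step with dynamically bounded learning rates
#'
#' Updates the exponential moving averages of the gradient and squared
#' gradient, computes the bias-corrected adaptive step size per parameter,
#' clips it into the band `[final_lr * (1 - 1/(gamma t + 1)),
#' final_lr * (1 + 1/(gamma t))]`, and applies it to the first moment.
#' As t grows the band pinches onto `final_lr`, so the update converges to
#' SGD with a momentum-averaged gradient at rate `final_lr`.
#' `optimizer = "adam"` skips the clipping; `"sgd"` uses the raw gradient
#' at `learning_rate`.
#'
#' @param par Flat parameter vector.
#' @param grad Gradient of the batch loss at `par` (finite).
#' @param state An `optimizer_state`.
#' @param cfg A [train_config()].
#' @return List with updated `par` and `state`.
#' @export
adabound_step <- function(par, grad, state, cfg) {
  stop_if_not(length(par) == length(grad) && length(par) == length(state$m),
              "par/grad/state shapes disagree")
  if (!all(is.finite(grad))) {
    bad <- which(!is.finite(grad))[1]
    stop(sprintf("non-finite gradient at flat parameter index %d", bad),
         call. = FALSE)
  }
  if (cfg$optimizer == "sgd") {
    state$t <- state$t + 1L
    return(list(par = par - cfg$learning_rate * grad, state = state))
  }
  t <- state$t + 1L
  m <- cfg$beta1 * state$m + (1 - cfg$beta1) * grad
  v <- cfg$beta2 * state$v + (1 - cfg$beta2) * grad^2
  step <- cfg$learning_rate * sqrt(1 - cfg$beta2^t) / (1 - cfg$beta1^t)
  eta <- step / (sqrt(v) + cfg$eps)
  if (cfg$optimizer == "adabound") {
    lb <- cfg$final_lr * (1 - 1 / (cfg$gamma * t + 1))
    ub <- cfg$final_lr * (1 + 1 / (cfg$gamma * t))
    eta <- pmin(pmax(eta, lb), ub)
  }
  state$t <- t
  state$m <- m
  state$v <- v
  list(par = par - eta * m, state = state)
}
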