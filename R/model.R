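# Modality-specific 1D convolutional classifiers.
#
# Each model is n_conv_blocks x (same-padded conv -> ReLU -> max-pool)
# followed by one sigmoid-activated fully connected unit.  Block counts are
# fixed per modality (7 for the accelerometer/gait/voice stacks, 6 for the
# coordinate stack); widths, kernel, pooling and input length are tunable.
# Parameters live in one flat vector; forward/backward run in compiled code.

mod_block_counts <- c(tap_accel = 7L, tap_coord = 6L, gait = 7L, voice = 7L)

#' Specify a 1D convolutional classifier
#'
#' @param modality One of `"tap_accel"` (7 blocks, default input 2500 x 3),
#'   `"tap_coord"` (6 blocks, default input 800 x 3: x, y, timestamp),
#'   `"gait"` (7 blocks, 2500 x 3) or `"voice"` (7 blocks, 1 channel;
#'   default input 40000 with pool width 4).
#' @param input_len Temporal input length; after all pooling stages the
#'   temporal extent must stay >= 1.
#' @param filters Integer vector of per-block filter counts (length equals
#'   the modality's block count).  Default: doubling from `base_filters`,
#'   capped at `max_filters`.
#' @param base_filters,max_filters Used to build the default `filters`.
#' @param kernel_size Convolution kernel width (default 9).
#' @param pool_size Max-pool width/stride (default 2; 4 for voice).
#' @param seed Seed for parameter initialization.
#' @return A `model_spec` object.
#' @export
model_spec <- function(modality = c("tap_accel", "tap_coord", "gait", "voice"),
                       input_len = NULL, filters = NULL,
                       base_filters = 8, max_filters = 128,
                       kernel_size = 9, pool_size = NULL, seed = 1L) {
  modality <- match.arg(modality)
  n_blocks <- mod_block_counts[[modality]]
  input_len <- input_len %||%
    switch(modality, tap_accel = 2500L, tap_coord = 800L, gait = 2500L,
           voice = 40000L)
  pool_size <- pool_size %||% if (modality == "voice") 4L else 2L
  channels <- if (modality == "voice") 1L else 3L
  filters <- filters %||%
    pmin(base_filters * 2^(seq_len(n_blocks) - 1), max_filters)
  stop_if_not(length(filters) == n_blocks,
              "%s needs exactly %d per-block filter counts", modality, n_blocks)
  stop_if_not(all(filters >= 1) && kernel_size >= 1 && pool_size >= 2,
              "filters/kernel/pool sizes out of range")
  L <- as.integer(input_len)
  lens <- integer(n_blocks)
  for (b in seq_len(n_blocks)) {
    stop_if_not(L >= pool_size,
                "temporal extent collapses below 1 at block %d (len %d, pool %d)",
                b, L, as.integer(pool_size))
    L <- L %/% pool_size
    lens[b] <- L
  }
  structure(list(modality = modality, input_len = as.integer(input_len),
                 channels = channels, n_conv_blocks = n_blocks,
                 filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 block_out_lens = lens, flat_dim = filters[n_blocks] * L,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %d blocks, input %d x %d, kernel %d, pool %d\n",
              x$modality, x$n_conv_blocks, x$channels, x$input_len,
              x$kernel_size, x$pool_size))
  cat(sprintf("  filters: %s; flat dim %d\n",
              paste(x$filters, collapse = "/"), x$flat_dim))
  invisible(x)
}

#' Build (initialize) a model from a spec
#'
#' He-style initialization for the convolution kernels (sd
#' sqrt(2 / fan_in)), zero biases, and a small random fully connected
#' layer, all drawn under `spec$seed` so two builds with the same seed are
#' identical.
#'
#' @param spec A [model_spec()].
#' @return A `pd_model`: list with `spec`, flat parameter vector `par`, and
#'   `normalization` (set at training time, defaults to the modality's
#'   plan default).
#' @export
build_model <- function(spec) {
  stop_if_not(inherits(spec, "model_spec"), "spec must be a model_spec")
  n_par <- cnn_par_length(spec)
  par <- with_seed(spec$seed, {
    p <- numeric(n_par)
    off <- 0L
    cin <- spec$channels
    for (b in seq_len(spec$n_conv_blocks)) {
      f <- spec$filters[b]
      nw <- f * cin * spec$kernel_size
      p[off + seq_len(nw)] <- rnorm(nw, 0, sqrt(2 / (cin * spec$kernel_size)))
      off <- off + nw + f           # biases stay zero
      cin <- f
    }
    p[off + seq_len(spec$flat_dim)] <- rnorm(spec$flat_dim, 0,
                                             sqrt(1 / spec$flat_dim))
    p
  })
  structure(list(spec = spec, par = par,
                 normalization = augment_plan(spec$modality)$normalization),
            class = "pd_model")
}

#' @export
print.pd_model <- function(x, ...) {
  cat(sprintf("<pd_model> %s, %d parameters, %s normalization\n",
              x$spec$modality, length(x$par), x$normalization))
  invisible(x)
}

#' Binary cross-entropy loss
#'
#' The per-item loss `-p * log(p_hat) - (1 - p) * log(1 - p_hat)` with
#' predictions clipped to `[eps, 1 - eps]`.  The batch loss used in
#' training is the mean over items.
#'
#' @param p Binary ground-truth labels (0/1), any length.
#' @param p_hat Predicted probabilities, same length.
#' @param eps Clipping constant (default 1e-7).
#' @return Elementwise non-negative losses.
#' @examples
#' binary_cross_entropy(0, 0.5)   # log(2)
#' @export
binary_cross_entropy <- function(p, p_hat, eps = 1e-7) {
  stop_if_not(all(p %in% c(0, 1)), "labels must be 0 or 1")
  stop_if_not(length(p) == length(p_hat), "labels and predictions differ in length")
  q <- pmin(pmax(p_hat, eps), 1 - eps)
  -p * log(q) - (1 - p) * log(1 - q)
}

# Score a cube of pre-normalized inputs. Internal.
model_forward <- function(model, x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  cnn_predict_scores(model$par, x, model$spec)
}
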