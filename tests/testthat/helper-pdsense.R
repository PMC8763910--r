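# Shared fixtures: all synthetic, built in code at test time.

# A small, fast tapping-only cohort configuration: 5-s records so encoded
# inputs stay short.
fast_tap_config <- function(n = 60, prevalence = 0.25,
                            records_pd_mean = 8, records_ctrl_mean = 4, ...) {
  cohort_config(n_individuals = n, prevalence = prevalence,
                modalities = "tapping",
                records_pd_mean = records_pd_mean,
                records_ctrl_mean = records_ctrl_mean,
                tap_duration_mean = 5, tap_duration_sd = 0.05,
                tap_duration_range = c(4.8, 5.2), ...)
}

# Reduced-width coordinate model matching 5-s records (~40 taps).
tiny_coord_spec <- function(seed = 1, input_len = 64)
  model_spec("tap_coord", input_len = input_len,
             filters = c(4, 8, 16, 16, 16, 16), seed = seed)

# Pure-R forward pass, independent of the compiled path; used as an oracle.
r_cnn_forward <- function(model, x) {
  spec <- model$spec
  par <- model$par
  off <- 0
  cin <- spec$channels
  cur <- x
  for (b in seq_len(spec$n_conv_blocks)) {
    f <- spec$filters[b]
    k <- spec$kernel_size
    W <- array(par[off + seq_len(f * cin * k)], dim = c(f, cin, k))
    off <- off + f * cin * k
    bias <- par[off + seq_len(f)]
    off <- off + f
    L <- ncol(cur)
    pl <- (k - 1) %/% 2
    xp <- cbind(matrix(0, cin, pl), cur, matrix(0, cin, k - 1 - pl))
    y <- matrix(0, f, L)
    for (j in seq_len(k))
      y <- y + matrix(W[, , j], nrow = f) %*% xp[, j:(j + L - 1), drop = FALSE]
    y <- y + bias
    y[y < 0] <- 0
    Lo <- L %/% spec$pool_size
    pooled <- matrix(0, f, Lo)
    for (i in seq_len(Lo))
      pooled[, i] <- apply(y[, ((i - 1) * spec$pool_size + 1):
                               (i * spec$pool_size), drop = FALSE], 1, max)
    cur <- pooled
    cin <- f
  }
  wfc <- par[off + seq_len(spec$flat_dim)]
  z <- sum(wfc * as.vector(cur)) + par[off + spec$flat_dim + 1]
  1 / (1 + exp(-z))
}

# Brute-force AUC: count concordant positive/negative pairs, ties at 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

with_seed_local <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# A bare individual for record-level simulators.
fake_ind <- function(severity) list(id = "x", severity = severity)

# Estimate mean inter-tap interval of a simulated tapping record.
mean_iti <- function(pair) mean(diff(pair$events$events$t))

# Zero-crossing period-perturbation oracle for vocal jitter: estimate the
# coefficient of variation of periods between rising zero crossings.
zc_jitter <- function(series) {
  v <- series$values[1, ]
  up <- which(v[-length(v)] < 0 & v[-1] >= 0)
  periods <- diff(up) / series$sample_rate
  periods <- periods[periods > 0.5 * median(periods) &
                       periods < 1.5 * median(periods)]
  sd(periods) / mean(periods)
}

# Peak frequency of a detrended channel by periodogram.
peak_freq <- function(series, channel = 3) {
  v <- series$values[channel, ] - mean(series$values[channel, ])
  n <- length(v)
  p <- Mod(fft(v))[2:(n %/% 2)]^2
  freq <- (seq_len(n %/% 2 - 1)) * series$sample_rate / n
  freq[which.max(p)]
}
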