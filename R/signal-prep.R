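# Batch-wise normalization and augmentation operators.
#
# During training, normalization and augmentation are applied to each batch
# separately (batch-local statistics), which avoids leaking global data
# statistics across the train/test boundary.  The operator order is fixed:
# normalize -> time scale -> rotate -> magnitude scale.

#' Assemble a training batch
#'
#' @param items List of channels x input_len numeric matrices (equal shape).
#' @param labels Binary vector (0/1), one per item.
#' @param meta Data frame with one row per item; must contain
#'   `individual_id` and `record_id`, and — if boundary normalization will
#'   be used — `bound_x0`, `bound_y0`, `bound_x1`, `bound_y1` (the union
#'   bounding box of the two target buttons).
#' @return A `pd_batch`: list with `x` (channels x len x n array), `labels`,
#'   `meta`.
#' @export
as_batch <- function(items, labels, meta) {
  stop_if_not(length(items) >= 1, "batch must contain at least one item")
  dims <- vapply(items, dim, integer(2))
  stop_if_not(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
              "all batch items must share one channels x input_len shape")
  stop_if_not(all(labels %in% c(0, 1)), "labels must be 0/1")
  stop_if_not(length(labels) == length(items) && nrow(meta) == length(items),
              "labels and meta must have one entry per item")
  x <- array(unlist(items, use.names = FALSE),
             dim = c(dims[1, 1], dims[2, 1], length(items)))
  structure(list(x = x, labels = as.numeric(labels), meta = meta),
            class = "pd_batch")
}

#' Batch-local normalization
#'
#' Normalizes a batch with statistics computed on that batch alone.
#' `zscore` centers and scales each channel to batch mean 0 and (population)
#' standard deviation 1; a zero-variance channel keeps a unit divisor with a
#' warning.  `center` subtracts the per-channel batch mean (for coordinate
#' batches this also centers the timestamp channel).  `boundary`
#' re-expresses the coordinate channels (1 = x, 2 = y) relative to the
#' per-item target-button bounding box: subtract the box origin, divide by
#' its extent; the timestamp channel is left untouched.
#'
#' @param batch A `pd_batch` (see [as_batch()]).
#' @param method One of `"zscore"`, `"center"`, `"boundary"`, `"none"`.
#' @return The normalized `pd_batch`.
#' @export
normalize_batch <- function(batch,
                            method = c("zscore", "center", "boundary", "none")) {
  method <- match.arg(method)
  if (method == "none") return(batch)
  x <- batch$x
  nc <- dim(x)[1]
  if (method == "zscore") {
    for (c_ in seq_len(nc)) {
      v <- x[c_, , ]
      m <- mean(v)
      s <- sqrt(mean((v - m)^2))
      if (s < 1e-12) {
        warning(sprintf("zero-variance channel %d under zscore; using unit divisor",
                        c_))
        s <- 1
      }
      x[c_, , ] <- (v - m) / s
    }
  } else if (method == "center") {
    for (c_ in seq_len(nc)) x[c_, , ] <- x[c_, , ] - mean(x[c_, , ])
  } else { # boundary
    need <- c("bound_x0", "bound_y0", "bound_x1", "bound_y1")
    stop_if_not(all(need %in% names(batch$meta)),
                "boundary normalization requires button bounds in batch meta")
    stop_if_not(nc >= 2, "boundary normalization needs x and y channels")
    for (i in seq_len(dim(x)[3])) {
      b <- batch$meta[i, need]
      x[1, , i] <- (x[1, , i] - b$bound_x0) / (b$bound_x1 - b$bound_x0)
      x[2, , i] <- (x[2, , i] - b$bound_y0) / (b$bound_y1 - b$bound_y0)
    }
  }
  batch$x <- x
  batch
}

#' Time-scale a multichannel series by resampling
#'
#' Resamples each channel onto `round(coeff * L)` points by 1-D linear
#' interpolation on the index grid, preserving both endpoints.  `coeff = 1`
#' is the identity.
#'
#' @param series Numeric channels x L matrix (L >= 2).
#' @param coeff Positive scaling coefficient.
#' @return channels x round(coeff * L) matrix.
#' @export
time_scale <- function(series, coeff) {
  stop_if_not(is.matrix(series) && ncol(series) >= 2,
              "series must be a channels x L matrix with L >= 2")
  stop_if_not(is.numeric(coeff) && length(coeff) == 1 && coeff > 0,
              "coeff must be a single positive number")
  L <- ncol(series)
  Lnew <- round(coeff * L)
  if (Lnew == L && coeff == 1) return(series)
  stop_if_not(Lnew >= 2, "scaled length would fall below 2")
  xout <- seq(1, L, length.out = Lnew)
  out <- matrix(0, nrow(series), Lnew)
  for (c_ in seq_len(nrow(series)))
    out[c_, ] <- approx(seq_len(L), series[c_, ], xout = xout)$y
  out
}

#' Per-channel magnitude scaling
#'
#' @param series Numeric channels x L matrix.
#' @param coeffs One finite coefficient per channel.
#' @return The series with channel i multiplied by `coeffs[i]`.
#' @export
magnitude_scale <- function(series, coeffs) {
  stop_if_not(is.matrix(series), "series must be a channels x L matrix")
  stop_if_not(length(coeffs) == nrow(series) && all(is.finite(coeffs)),
              "need one finite coefficient per channel")
  series * coeffs
}

# Rotation matrix from the unit quaternion (cos(a/2), sin(a/2) * axis).
quat_rotation_matrix <- function(axis, angle) {
  w <- cos(angle / 2)
  v <- sin(angle / 2) * axis
  x <- v[1]; y <- v[2]; z <- v[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Rotate a 3-channel series with a quaternion rotation
#'
#' Rotates every time-sample 3-vector by the quaternion
#' `(cos(angle/2), sin(angle/2) * axis)`.  The rotation is an isometry:
#' per-sample Euclidean norms are preserved to machine precision.
#'
#' @param series Numeric 3 x L matrix.
#' @param axis Unit 3-vector (|axis| = 1 within 1e-9).
#' @param angle Rotation angle in radians.
#' @return The rotated 3 x L matrix.
#' @export
rotate3d <- function(series, axis, angle) {
  stop_if_not(is.matrix(series) && nrow(series) == 3,
              "series must be a 3 x L matrix")
  stop_if_not(length(axis) == 3 && abs(sqrt(sum(axis^2)) - 1) <= 1e-9,
              "axis must be a unit 3-vector")
  quat_rotation_matrix(axis, angle) %*% series
}

#' Rotate a 2-channel point set about its centroid
#'
#' Centers the points on their centroid, applies a planar rotation, and
#' restores the centroid, so the operator commutes with centering
#' normalization.
#'
#' @param points Numeric 2 x L matrix.
#' @param angle Rotation angle in radians.
#' @return The rotated 2 x L matrix (centroid unchanged).
#' @export
rotate2d <- function(points, angle) {
  stop_if_not(is.matrix(points) && nrow(points) == 2,
              "points must be a 2 x L matrix")
  ctr <- rowMeans(points)
  R <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)),
              nrow = 2, byrow = TRUE)
  R %*% (points - ctr) + ctr
}

#' Fit a series to a fixed temporal length
#'
#' Series shorter than `target_len` are right-padded with zeros (the
#' neutral element of centered data); longer series keep their first
#' `target_len` columns.  Idempotent.
#'
#' @param series Numeric channels x L matrix (non-empty).
#' @param target_len Positive integer.
#' @return channels x target_len matrix.
#' @export
fit_length <- function(series, target_len) {
  stop_if_not(is.matrix(series) && ncol(series) >= 1 && nrow(series) >= 1,
              "series must be a non-empty channels x L matrix")
  stop_if_not(target_len >= 1, "target_len must be positive")
  L <- ncol(series)
  if (L == target_len) return(series)
  if (L > target_len) return(series[, seq_len(target_len), drop = FALSE])
  cbind(series, matrix(0, nrow(series), target_len - L))
}

#' Augmentation plan
#'
#' Declares the normalization method and the random-augmentation ranges
#' applied, in a fixed order (normalize, time scale, rotate, magnitude
#' scale), to every training batch.  Modality defaults follow the
#' best-performing stacks: accelerometer modalities use z-score
#' normalization plus quaternion rotation over the full circle; the
#' coordinate model uses centering (of coordinates and timestamps) with 2D
#' rotation disabled — rotating tap positions degrades the signal, and
#' boundary normalization is likewise retained only for ablations; voice
#' uses z-score with time and magnitude scaling only.
#'
#' @param modality One of `"tap_accel"`, `"tap_coord"`, `"gait"`, `"voice"`,
#'   or NULL to set every field explicitly.
#' @param normalization `"zscore"`, `"center"`, `"boundary"` or `"none"`.
#' @param time_scale_range,magnitude_range Numeric `(low, high)` with
#'   `low <= high`; coefficients are drawn uniformly.  Defaults (0.8, 1.2).
#' @param rotation3d_range Radian interval for the 3D rotation angle (axis
#'   uniform on the unit sphere), or NULL to disable.
#' @param rotation2d_range Radian interval for the planar rotation of the
#'   coordinate channels, or NULL (default) to disable.
#' @return An `augment_plan` object.
#' @export
augment_plan <- function(modality = NULL,
                         normalization = NULL,
                         time_scale_range = c(0.8, 1.2),
                         magnitude_range = c(0.8, 1.2),
                         rotation3d_range = NULL,
                         rotation2d_range = NULL) {
  if (!is.null(modality)) {
    modality <- match.arg(modality, c("tap_accel", "tap_coord", "gait", "voice"))
    if (is.null(normalization))
      normalization <- if (modality == "tap_coord") "center" else "zscore"
    if (is.null(rotation3d_range) && modality %in% c("tap_accel", "gait"))
      rotation3d_range <- c(0, 2 * pi)
  }
  normalization <- match.arg(normalization %||% "zscore",
                             c("zscore", "center", "boundary", "none"))
  chk_range <- function(r, nm) {
    if (is.null(r)) return(invisible())
    stop_if_not(length(r) == 2 && r[1] <= r[2],
                "%s must be c(low, high) with low <= high", nm)
  }
  chk_range(time_scale_range, "time_scale_range")
  chk_range(magnitude_range, "magnitude_range")
  chk_range(rotation3d_range, "rotation3d_range")
  chk_range(rotation2d_range, "rotation2d_range")
  stop_if_not(time_scale_range[1] > 0, "time-scale coefficients must be positive")
  structure(list(normalization = normalization,
                 time_scale_range = time_scale_range,
                 magnitude_range = magnitude_range,
                 rotation3d_range = rotation3d_range,
                 rotation2d_range = rotation2d_range,
                 order = c("normalize", "time_scale", "rotate",
                           "magnitude_scale")),
            class = "augment_plan")
}

#' Apply an augmentation plan to a training batch
#'
#' Normalizes the batch with batch-local statistics, then draws, per item,
#' a time-scale coefficient, a rotation (3D quaternion rotation for
#' 3-channel sensor batches if enabled; planar rotation of the first two
#' channels if enabled) and per-channel magnitude coefficients, all uniform
#' on the plan ranges.  Time-scaled items are re-fit to the batch input
#' length.  Labels and metadata pass through untouched.  Draws from the
#' current RNG stream.
#'
#' @param batch A `pd_batch`.
#' @param plan An [augment_plan()].
#' @return The augmented `pd_batch`.
#' @export
augment_batch <- function(batch, plan) {
  stop_if_not(inherits(plan, "augment_plan"), "plan must be an augment_plan")
  batch <- normalize_batch(batch, plan$normalization)
  x <- batch$x
  d <- dim(x)
  for (i in seq_len(d[3])) {
    item <- x[, , i, drop = TRUE]
    if (d[1] == 1) item <- matrix(item, nrow = 1)
    coeff <- runif(1, plan$time_scale_range[1], plan$time_scale_range[2])
    item <- fit_length(time_scale(item, coeff), d[2])
    if (!is.null(plan$rotation3d_range) && d[1] == 3) {
      axis <- rnorm(3)
      axis <- axis / sqrt(sum(axis^2))
      ang <- runif(1, plan$rotation3d_range[1], plan$rotation3d_range[2])
      item <- rotate3d(item, axis, ang)
    }
    if (!is.null(plan$rotation2d_range) && d[1] >= 2) {
      ang <- runif(1, plan$rotation2d_range[1], plan$rotation2d_range[2])
      item[1:2, ] <- rotate2d(item[1:2, , drop = FALSE], ang)
    }
    mags <- runif(d[1], plan$magnitude_range[1], plan$magnitude_range[2])
    x[, , i] <- magnitude_scale(item, mags)
  }
  batch$x <- x
  batch
}
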