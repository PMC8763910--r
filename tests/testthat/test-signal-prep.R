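make_test_batch <- function(n = 4, channels = 3, len = 20, seed = 1) {
  set.seed(seed)
  items <- replicate(n, matrix(rnorm(channels * len), channels), simplify = FALSE)
  as_batch(items, labels = rep(c(0, 1), length.out = n),
           meta = data.frame(individual_id = paste0("i", seq_len(n)),
                             record_id = paste0("r", seq_len(n))))
}

test_that("zscore normalization yields per-channel batch moments (0, 1)", {
  b <- normalize_batch(make_test_batch(), "zscore")
  for (c_ in 1:3) {
    v <- b$x[c_, , ]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  }
})

test_that("centering zeroes a constant channel and the batch mean", {
  b <- make_test_batch()
  b$x[2, , ] <- 5
  out <- normalize_batch(b, "center")
  expect_true(all(out$x[2, , ] == 0))
  expect_lt(abs(mean(out$x[1, , ])), 1e-12)
})

test_that("zero-variance channel under zscore keeps a unit divisor with warning", {
  b <- make_test_batch()
  b$x[1, , ] <- 3
  expect_warning(out <- normalize_batch(b, "zscore"), "zero-variance")
  expect_true(all(out$x[1, , ] == 0))  # (3 - 3) / 1
})

test_that("boundary normalization maps the button-box origin to (0, 0)", {
  items <- list(rbind(x = c(40, 280, 160), y = c(290, 380, 335),
                      t = c(0, 1, 2)))
  meta <- data.frame(individual_id = "i1", record_id = "r1",
                     bound_x0 = 40, bound_y0 = 290, bound_x1 = 280,
                     bound_y1 = 380)
  b <- as_batch(items, labels = 1, meta = meta)
  out <- normalize_batch(b, "boundary")
  expect_equal(out$x[1:2, 1, 1], c(0, 0))
  expect_equal(out$x[1:2, 2, 1], c(1, 1))
  expect_equal(out$x[3, , 1], c(0, 1, 2))  # timestamps untouched
  b$meta <- b$meta[, 1:2]
  expect_error(normalize_batch(b, "boundary"), "bounds")
})

test_that("normalization is batch-local (no global statistics)", {
  b1 <- make_test_batch(seed = 1)
  b2 <- make_test_batch(seed = 2)
  n1 <- normalize_batch(b1, "zscore")$x[1, 1, 1]
  # moving item 1 of b1 into b2's company changes its normalized value
  mixed <- b2
  mixed$x[, , 1] <- b1$x[, , 1]
  nm <- normalize_batch(mixed, "zscore")$x[1, 1, 1]
  expect_false(isTRUE(all.equal(n1, nm)))
})

test_that("time_scale obeys the length law and the identity case", {
  m <- matrix(rnorm(3 * 2000), 3)
  expect_identical(time_scale(m, 1), m)
  expect_equal(ncol(time_scale(m, 1.2)), 2400)
  expect_equal(ncol(time_scale(m, 0.8)), 1600)
  expect_error(time_scale(m, 0), "positive")
  expect_error(time_scale(m[, 1, drop = FALSE], 1.5), "L >= 2")
})

test_that("time_scale matches the analytic resampling of a pure sine", {
  L <- 1000
  idx <- seq_len(L)
  f <- function(i) sin(2 * pi * 3 * (i - 1) / (L - 1))
  m <- rbind(f(idx))
  out <- time_scale(m, 0.8)
  Lnew <- ncol(out)
  xout <- seq(1, L, length.out = Lnew)
  # oracle: exact linear interpolation between the two bracketing samples
  lo <- pmin(floor(xout), L - 1)
  w <- xout - lo
  oracle <- (1 - w) * f(lo) + w * f(lo + 1)
  expect_lt(sqrt(mean((out[1, ] - oracle)^2)), 1e-6)
  expect_equal(out[1, 1], m[1, 1])
  expect_equal(out[1, Lnew], m[1, L])
})

test_that("magnitude_scale scales channels exactly", {
  m <- matrix(rnorm(3 * 50), 3)
  expect_identical(magnitude_scale(m, c(1, 1, 1)), m)
  expect_equal(magnitude_scale(m, c(2, 2, 2)), 2 * m)
  cf <- c(0.5, 1.3, -2)
  out <- magnitude_scale(m, cf)
  expect_equal(apply(out, 1, sd), abs(cf) * apply(m, 1, sd))
  expect_error(magnitude_scale(m, c(1, 2)), "coefficient")
})

test_that("rotate3d matches closed forms and an independent matrix oracle", {
  m <- matrix(c(1, 0, 0), 3, 5)
  expect_equal(rotate3d(m, c(0, 0, 1), 0), m)
  out <- rotate3d(m, c(0, 0, 1), pi)
  expect_equal(out, matrix(c(-1, 0, 0), 3, 5), tolerance = 1e-12)
  # Rodrigues-formula oracle, built independently of the quaternion path
  rodrigues <- function(axis, angle) {
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, byrow = TRUE)
    diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  }
  set.seed(4)
  for (i in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0, 2 * pi)
    x <- matrix(rnorm(3 * 7), 3)
    expect_lt(max(abs(rotate3d(x, ax, ang) - rodrigues(ax, ang) %*% x)), 1e-9)
  }
  expect_error(rotate3d(m, c(1, 1, 0), 0.3), "unit")
})

test_that("rotations are isometries on per-sample norms", {
  set.seed(6)
  x <- matrix(rnorm(3 * 40), 3)
  for (i in 1:10) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    out <- rotate3d(x, ax, runif(1, 0, 2 * pi))
    expect_lt(max(abs(sqrt(colSums(out^2)) - sqrt(colSums(x^2)))), 1e-9)
  }
  p <- matrix(rnorm(2 * 30), 2)
  pc <- p - rowMeans(p)
  for (a in runif(10, -pi, pi)) {
    out <- rotate2d(pc, a)
    expect_lt(max(abs(sqrt(colSums((out - rowMeans(out))^2)) -
                        sqrt(colSums(pc^2)))), 1e-9)
  }
})

test_that("rotate2d closed form and centroid preservation", {
  p <- matrix(c(1, 0), 2, 1)
  expect_equal(rotate2d(p, 0), p)
  pc <- matrix(c(1, 0, -1, 0), 2)  # centered pair
  out <- rotate2d(pc, pi / 2)
  expect_equal(out[, 1], c(0, 1), tolerance = 1e-12)
  set.seed(8)
  q <- matrix(rnorm(2 * 9) + 5, 2)
  expect_equal(rowMeans(rotate2d(q, 1.1)), rowMeans(q))
})

test_that("fit_length pads, truncates, and is idempotent", {
  m <- matrix(rnorm(3 * 2000), 3)
  out <- fit_length(m, 2500)
  expect_equal(dim(out), c(3, 2500))
  expect_true(all(out[, 2001:2500] == 0))
  expect_identical(out[, 1:2000], m)
  m2 <- matrix(rnorm(3 * 3000), 3)
  expect_identical(fit_length(m2, 2500), m2[, 1:2500])
  expect_identical(fit_length(fit_length(m, 2500), 2500),
                   fit_length(m, 2500))
})

test_that("augment_batch: degenerate plan is pure normalization, seeded draws reproduce", {
  b <- make_test_batch(n = 3, len = 32)
  plan_id <- augment_plan(normalization = "zscore",
                          time_scale_range = c(1, 1),
                          magnitude_range = c(1, 1))
  set.seed(5)
  out <- augment_batch(b, plan_id)
  expect_equal(out$x, normalize_batch(b, "zscore")$x, tolerance = 1e-12)
  plan <- augment_plan("tap_accel")
  a1 <- with_seed_local(42, augment_batch(b, plan))
  a2 <- with_seed_local(42, augment_batch(b, plan))
  expect_identical(a1$x, a2$x)
  expect_identical(a1$labels, b$labels)
  expect_identical(a1$meta, b$meta)
})

test_that("time-scale coefficients are uniform on (0.8, 1.2)", {
  # probe: a linear ramp lets the drawn coefficient be recovered from the
  # slope of the resampled output, independent of the RNG internals
  L <- 1000
  ramp <- matrix(seq_len(L), 1)
  b <- as_batch(list(ramp), labels = 1,
                meta = data.frame(individual_id = "i", record_id = "r"))
  plan <- augment_plan(normalization = "none", magnitude_range = c(1, 1))
  set.seed(12)
  coeffs <- replicate(1000, {
    out <- augment_batch(b, plan)$x[1, , 1]
    slope <- out[2] - out[1]
    round((L - 1) / slope + 1) / L
  })
  ks <- suppressWarnings(stats::ks.test(coeffs, "punif", 0.8, 1.2))
  expect_gt(ks$p.value, 0.001)
  expect_gt(min(coeffs), 0.79)
  expect_lt(max(coeffs), 1.21)
})
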