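test_that("binary cross-entropy matches closed forms and a high-precision oracle", {
  eps <- 1e-7
  expect_lt(binary_cross_entropy(1, 1 - eps), 1e-6)
  expect_equal(binary_cross_entropy(0, 0.5), -log(0.5))
  # -log(1/4) computed symbolically: 2 * log(2)
  expect_equal(binary_cross_entropy(1, 0.25), 2 * log(2), tolerance = 1e-10)
  expect_equal(binary_cross_entropy(c(1, 0), c(0.9, 0.1)),
               c(-log(0.9), -log(0.9)))
  expect_error(binary_cross_entropy(0.5, 0.5), "labels")
})

test_that("architecture contract: stage counts, channels, output lengths", {
  sa <- model_spec("tap_accel")
  expect_equal(sa$n_conv_blocks, 7)
  expect_equal(sa$input_len, 2500)
  expect_equal(sa$channels, 3)
  expect_length(sa$filters, 7)
  sc <- model_spec("tap_coord")
  expect_equal(sc$n_conv_blocks, 6)
  expect_equal(sc$input_len, 800)
  expect_equal(sc$channels, 3)
  sv <- model_spec("voice")
  expect_equal(sv$channels, 1)
  expect_equal(sv$n_conv_blocks, 7)
  # pooling halves (floor) at each stage
  expect_equal(sa$block_out_lens,
               Reduce(function(L, b) L %/% 2, 1:7, accumulate = TRUE,
                      init = 2500)[-1])
  expect_gte(min(sa$block_out_lens), 1)
  # collapse below 1 is rejected
  expect_error(model_spec("tap_accel", input_len = 64), "collapses")
})

test_that("parameter layout: one weight + bias set per block plus the FC head", {
  spec <- tiny_coord_spec()
  k <- spec$kernel_size
  fs <- spec$filters
  cin <- c(3, fs[-length(fs)])
  expected <- sum(fs * cin * k + fs) + spec$flat_dim + 1
  m <- build_model(spec)
  expect_length(m$par, expected)
})

test_that("builds are seeded: same seed identical, different seed not", {
  a <- build_model(tiny_coord_spec(seed = 9))
  b <- build_model(tiny_coord_spec(seed = 9))
  d <- build_model(tiny_coord_spec(seed = 10))
  expect_identical(a$par, b$par)
  expect_false(identical(a$par, d$par))
})

test_that("forward pass matches an independent pure-R implementation", {
  for (spec in list(tiny_coord_spec(seed = 2, input_len = 96),
                    model_spec("voice", input_len = 256,
                               filters = c(2, 3, 2, 2, 2, 2, 2),
                               kernel_size = 5, pool_size = 2, seed = 3))) {
    m <- build_model(spec)
    set.seed(spec$seed)
    x <- matrix(rnorm(spec$channels * spec$input_len), spec$channels)
    got <- pdsense:::model_forward(m, x)
    want <- r_cnn_forward(m, x)
    expect_equal(got, want, tolerance = 1e-12)
    expect_gt(got, 0)
    expect_lt(got, 1)
  }
})

test_that("zero input still yields a finite score in (0, 1)", {
  m <- build_model(model_spec("tap_accel", filters = rep(2, 7),
                              input_len = 640, seed = 1))
  s <- pdsense:::model_forward(m, matrix(0, 3, 640))
  expect_true(is.finite(s) && s > 0 && s < 1)
})

test_that("analytic gradients match central finite differences", {
  spec <- model_spec("tap_coord", input_len = 64, filters = rep(2, 6),
                     kernel_size = 3, seed = 5)
  m <- build_model(spec)
  set.seed(7)
  x <- array(rnorm(3 * 64 * 5), dim = c(3, 64, 5))
  y <- c(1, 0, 1, 1, 0)
  g <- pdsense:::cnn_batch_grad(m$par, x, y, spec)
  expect_equal(g$loss,
               mean(binary_cross_entropy(y,
                 pdsense:::cnn_predict_scores(m$par, x, spec))),
               tolerance = 1e-6)
  f <- function(p) pdsense:::cnn_batch_grad(p, x, y, spec)$loss
  idx <- sort(sample(length(m$par), 40))
  h <- 1e-6
  for (k in idx) {
    p1 <- m$par; p1[k] <- p1[k] + h
    p2 <- m$par; p2[k] <- p2[k] - h
    expect_lt(abs((f(p1) - f(p2)) / (2 * h) - g$grad[k]), 1e-6)
  }
})

test_that("bounded optimizer: hand-computed step, SGD limit, zero gradient", {
  cfg <- train_config(learning_rate = 1e-2, final_lr = 0.1, gamma = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
  st <- optimizer_init(1)
  # hand-set moments via two manual computations
  g <- 0.5
  out <- adabound_step(1, g, st, cfg)
  m1 <- 0.1 * g
  v1 <- 0.001 * g^2
  step1 <- 1e-2 * sqrt(1 - 0.999) / (1 - 0.9)
  eta1 <- step1 / (sqrt(v1) + 1e-8)
  lb1 <- 0.1 * (1 - 1 / (1e-3 + 1))
  ub1 <- 0.1 * (1 + 1 / 1e-3)
  eta1 <- min(max(eta1, lb1), ub1)
  expect_equal(out$par, 1 - eta1 * m1, tolerance = 1e-12)
  expect_equal(out$state$t, 1L)
  # pinched bounds: the update is momentum-SGD at final_lr
  st2 <- list(t = 10000000L, m = 0.3, v = 4)
  out2 <- adabound_step(2, 0.1, st2, cfg)
  m2 <- 0.9 * 0.3 + 0.1 * 0.1
  expect_equal(out2$par, 2 - cfg$final_lr * m2, tolerance = 1e-5)
  # zero gradient from a fresh state leaves parameters unchanged
  out3 <- adabound_step(c(1, 2), c(0, 0), optimizer_init(2), cfg)
  expect_identical(out3$par, c(1, 2))
  expect_error(adabound_step(1, NaN, optimizer_init(1), cfg), "non-finite")
})

test_that("training learns separable data and is deterministic", {
  cfg <- fast_tap_config(n = 40)
  co <- simulate_cohort(cfg, 31)
  spec <- tiny_coord_spec(seed = 4)
  rs <- encode_records(co, "tap_coord", spec$input_len)
  ids <- unique(rs$meta$individual_id)
  lab <- co$individuals$pd_label[match(ids, co$individuals$id)]
  fit_ids <- c(ids[lab == 1][1:4], ids[lab == 0][1:12])
  val_ids <- c(ids[lab == 1][5:7], ids[lab == 0][13:24])
  tc <- train_config(max_epochs = 10, seed = 2)
  res <- train_model(build_model(spec), subset_records(rs, fit_ids),
                     subset_records(rs, val_ids), tc)
  expect_lt(res$trace$train_loss[nrow(res$trace)], res$trace$train_loss[1])
  expect_equal(res$best_epoch, which.min(res$trace$val_loss))
  expect_true(all(res$trace$train_loss >= 0))
  res2 <- train_model(build_model(spec), subset_records(rs, fit_ids),
                      subset_records(rs, val_ids), tc)
  expect_identical(res$trace, res2$trace)
  expect_identical(res$model$par, res2$model$par)
  # train/validation individual overlap is rejected
  expect_error(train_model(build_model(spec), subset_records(rs, fit_ids),
                           subset_records(rs, c(val_ids, fit_ids[1])), tc),
               "overlap")
})

test_that("prediction is deterministic, in (0, 1), one score per record", {
  cfg <- fast_tap_config(n = 12)
  co <- simulate_cohort(cfg, 17)
  spec <- tiny_coord_spec(seed = 6)
  rs <- encode_records(co, "tap_coord", spec$input_len)
  m <- build_model(spec)
  p1 <- predict_records(m, rs)
  p2 <- predict_records(m, rs)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), length(rs$y))
  expect_true(all(p1$score > 0 & p1$score < 1))
  # modality mismatch rejected
  rs2 <- rs
  rs2$modality <- "gait"
  expect_error(predict_records(m, rs2), "modality")
})
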