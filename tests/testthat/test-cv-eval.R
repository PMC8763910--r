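fake_cohort <- function(n, prevalence = 0.3, seed = 1) {
  set.seed(seed)
  list(individuals = data.frame(
    id = sprintf("i%03d", seq_len(n)),
    pd_label = rbinom(n, 1, prevalence), stringsAsFactors = FALSE))
}

test_that("split plans are disjoint, covering, seeded, and class-balanced", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(8:40, 1)
    co <- fake_cohort(n, runif(1, 0.15, 0.5), seed = rep)
    if (sum(co$individuals$pd_label) < 3 ||
        sum(1 - co$individuals$pd_label) < 3) next
    plan <- make_splits(co, n_splits = 3, master_seed = rep)
    for (sp in plan$splits) {
      expect_length(intersect(sp$train, sp$test), 0)
      expect_setequal(c(sp$train, sp$test), co$individuals$id)
      expect_setequal(c(sp$train_fit, sp$train_val), sp$train)
      expect_length(intersect(sp$train_fit, sp$train_val), 0)
      lab <- setNames(co$individuals$pd_label, co$individuals$id)
      expect_equal(sort(unique(lab[sp$test])), c(0, 1))
      expect_equal(sort(unique(lab[sp$train_fit])), c(0, 1))
      expect_equal(sort(unique(lab[sp$train_val])), c(0, 1))
    }
  }
})

test_that("split sizes follow the test fraction; plans reproduce under a seed", {
  co <- fake_cohort(40, 0.4, seed = 3)
  plan <- make_splits(co, n_splits = 5, test_fraction = 0.25, master_seed = 7)
  for (sp in plan$splits) expect_equal(length(sp$test), 10)
  plan2 <- make_splits(co, n_splits = 5, test_fraction = 0.25, master_seed = 7)
  expect_identical(plan, plan2)
  co4 <- list(individuals = data.frame(id = c("a", "b", "c", "d"),
                                       pd_label = c(1, 1, 0, 0)))
  # 4 individuals cannot place both classes in both training halves, so the
  # sub-split falls back with a warning, but sizes still follow the fraction
  w <- capture_warnings(
    p4 <- make_splits(co4, n_splits = 2, test_fraction = 0.25, master_seed = 1))
  expect_match(w, "train/validation halves", all = TRUE)
  for (sp in p4$splits) {
    expect_length(sp$test, 1)
    expect_length(sp$train, 3)
  }
  expect_error(make_splits(list(individuals = data.frame(
    id = c("a", "b", "c"), pd_label = c(1, 0, 0))), 2), "at least 4")
})

test_that("kfold mode partitions individuals into disjoint test folds", {
  co <- fake_cohort(30, 0.4, seed = 5)
  plan <- make_splits(co, n_splits = 3, master_seed = 2, method = "kfold")
  tests <- unlist(lapply(plan$splits, `[[`, "test"))
  expect_setequal(tests, co$individuals$id)
  expect_equal(length(tests), 30)  # each individual tested exactly once
})

test_that("AUC equals the pairwise-concordance oracle on small tables", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # force occasional ties
    got <- compute_metrics(scores, labels)$auc
    expect_equal(got, brute_auc(scores, labels), tolerance = 1e-12)
  }
  expect_equal(compute_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0))$auc, 1)
  expect_equal(compute_metrics(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(compute_metrics(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUPRC matches a direct threshold-enumeration oracle", {
  brute_auprc <- function(scores, labels) {
    ths <- sort(unique(scores), decreasing = TRUE)
    rec <- vapply(ths, function(t) sum(labels == 1 & scores >= t) /
                    sum(labels == 1), numeric(1))
    prec <- vapply(ths, function(t) sum(labels == 1 & scores >= t) /
                     sum(scores >= t), numeric(1))
    sum(diff(c(0, rec)) * prec)
  }
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(5:14, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), sample(1:3, 1))
    expect_equal(compute_metrics(scores, labels)$auprc,
                 brute_auprc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC and AUPRC agree with an established reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  for (rep in 1:10) {
    n <- 50
    labels <- c(0, 1, rbinom(n - 2, 1, 0.35))
    scores <- round(runif(n), 2)
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(compute_metrics(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant to duplicating every negative individual", {
  set.seed(17)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.4)
  labels[1:2] <- c(0, 1)
  dup <- c(scores, scores[labels == 0])
  dlab <- c(labels, rep(0, sum(labels == 0)))
  expect_equal(compute_metrics(scores, labels)$auc,
               compute_metrics(dup, dlab)$auc, tolerance = 1e-12)
})

test_that("pulling collapses records correctly and max dominates mean", {
  tab <- data.frame(
    individual_id = c("a", "a", "a", "b"),
    record_id = c("r1", "r2", "r3", "r4"),
    model_id = "tap_coord",
    score = c(0.2, 0.9, 0.5, 0.4), label = c(1, 1, 1, 0))
  mx <- pull_scores(tab, "max")
  mn <- pull_scores(tab, "mean")
  expect_equal(mx$pulled_score[mx$individual_id == "a"], 0.9)
  expect_equal(mn$pulled_score[mn$individual_id == "a"], mean(c(0.2, 0.9, 0.5)))
  # single-record individual: max == mean
  expect_equal(mx$pulled_score[mx$individual_id == "b"],
               mn$pulled_score[mn$individual_id == "b"])
  expect_true(all(mx$pulled_score >= mn$pulled_score))
  set.seed(19)
  big <- data.frame(individual_id = rep(sprintf("i%02d", 1:20),
                                        times = sample(1:6, 20, TRUE)))
  big$record_id <- sprintf("r%03d", seq_len(nrow(big)))
  big$model_id <- "m"
  big$score <- runif(nrow(big))
  big$label <- as.numeric(substr(big$individual_id, 2, 3) <= "08")
  mx <- pull_scores(big, "max")
  mn <- pull_scores(big, "mean")
  expect_true(all(mx$pulled_score >= mn$pulled_score))
})

test_that("cross-split record scores are averaged before pulling", {
  tab <- data.frame(
    individual_id = c("a", "a", "a"),
    record_id = c("r1", "r1", "r2"),
    model_id = "m",
    score = c(0.2, 0.6, 0.9), label = 1,
    split_id = c(1, 2, 1))
  rec <- average_record_scores(tab)
  expect_equal(rec$score[rec$record_id == "r1"], 0.4)  # mean of 2 splits
  expect_equal(rec$n_splits[rec$record_id == "r1"], 2L)
  mx <- pull_scores(tab, "max")
  expect_equal(mx$pulled_score, 0.9)
  mn <- pull_scores(tab, "mean")
  expect_equal(mn$pulled_score, mean(c(0.4, 0.9)))
})

test_that("run_cv never scores an individual its model trained on", {
  cfg <- fast_tap_config(n = 30)
  co <- simulate_cohort(cfg, 41)
  spec <- tiny_coord_spec(seed = 3)
  plan <- make_splits(co, n_splits = 3, master_seed = 5)
  tab <- run_cv(co, spec, train_config(max_epochs = 2, seed = 1), plan)
  for (s in unique(tab$split_id)) {
    sp <- plan$splits[[s]]
    rows <- tab[tab$split_id == s, ]
    expect_length(intersect(rows$individual_id, sp$train), 0)
    expect_true(all(rows$individual_id %in% sp$test))
    # every test record of the modality is scored
    n_expected <- sum(vapply(cohort_records(co, "tap_coord"),
                             function(r) r$individual_id %in% sp$test,
                             logical(1)))
    expect_equal(nrow(rows), n_expected)
  }
  # determinism of the whole cv pass
  tab2 <- run_cv(co, spec, train_config(max_epochs = 2, seed = 1), plan)
  expect_identical(tab$score, tab2$score)
})

test_that("a 1-split plan equals a single train/test run", {
  cfg <- fast_tap_config(n = 24)
  co <- simulate_cohort(cfg, 43)
  spec <- tiny_coord_spec(seed = 8)
  plan <- make_splits(co, n_splits = 1, master_seed = 9)
  tcfg <- train_config(max_epochs = 3, seed = 4)
  tab <- run_cv(co, spec, tcfg, plan)
  sp <- plan$splits[[1]]
  rs <- encode_records(co, "tap_coord", spec$input_len)
  spec1 <- spec
  spec1$seed <- pdsense:::mix_seed(spec$seed, 101, 1)
  cfg1 <- tcfg
  cfg1$seed <- pdsense:::mix_seed(tcfg$seed, 211, 1)
  fitted <- train_model(build_model(spec1), subset_records(rs, sp$train_fit),
                        subset_records(rs, sp$train_val), cfg1)
  manual <- predict_records(fitted$model, subset_records(rs, sp$test))
  expect_equal(tab$score, manual$score)
})

test_that("subgroup metrics conserve counts and flag single-class strata", {
  cfg <- cohort_config(n_individuals = 200, modalities = character(0))
  co <- simulate_cohort(cfg, 51)
  set.seed(3)
  scores <- data.frame(individual_id = co$individuals$id,
                       pulled_score = runif(200) + 0.3 * co$individuals$pd_label,
                       label = co$individuals$pd_label)
  sg <- subgroup_metrics(scores, co)
  for (k in unique(sg$key)) {
    sub <- sg[sg$key == k, ]
    expect_equal(sum(sub$n_pos), sum(scores$label == 1))
    expect_equal(sum(sub$n_neg), sum(scores$label == 0))
  }
  expect_true(all(is.na(sg$auc[!sg$defined])))
  expect_true(all(!is.na(sg$auc[sg$defined])))
  expect_error(subgroup_metrics(scores, co, keys = "shoe_size"), "unknown")
})
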