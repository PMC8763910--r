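# Individual-level repeated splits and the cross-validation driver.
#
# Because individuals contribute many records, all partitioning happens at
# the individual level: no person's records ever appear on both sides of a
# split, which would otherwise leak identity features and inflate
# performance.

#' Build an individual-level split plan
#'
#' Draws `n_splits` independent random train/test partitions at the
#' individual level (75/25 by default); within each split's training side,
#' a seeded half/half train/validation sub-split, also by individual.
#' Splits whose test set or training halves miss a class are redrawn with
#' a fresh sub-seed (bounded retries).  `method = "kfold"` instead
#' partitions individuals into `n_splits` disjoint folds, each serving as
#' the test set once.
#'
#' @param cohort A `pd_cohort` (or any list with an `individuals` data
#'   frame carrying `id` and `pd_label`).
#' @param n_splits Number of splits (default 5).
#' @param test_fraction Fraction of individuals in each test set (default
#'   0.25; ignored for kfold).
#' @param master_seed Integer seed; the plan is a pure function of
#'   (cohort, arguments, master_seed).
#' @param method `"monte_carlo"` (default) or `"kfold"`.
#' @return A `split_plan`: list of splits, each with `train_fit`,
#'   `train_val`, `train` (their union) and `test` id vectors.
#' @export
make_splits <- function(cohort, n_splits = 5, test_fraction = 0.25,
                        master_seed = 1L,
                        method = c("monte_carlo", "kfold")) {
  method <- match.arg(method)
  ind <- cohort$individuals
  stop_if_not(nrow(ind) >= 4, "need at least 4 individuals to split")
  stop_if_not(test_fraction > 0 && test_fraction < 1,
              "test_fraction must lie in (0, 1)")
  labels <- setNames(ind$pd_label, ind$id)
  ids <- ind$id

  both_classes <- function(v) length(unique(labels[v])) == 2
  # Seeded half/half sub-split of the training individuals; retries to put
  # both classes in both halves, returns NULL if no attempt succeeds.
  halve <- function(train_ids, seed, strict = TRUE) {
    last <- NULL
    for (attempt in 0:99) {
      h <- with_seed(mix_seed(seed, 17, attempt), sample(train_ids))
      k <- ceiling(length(h) / 2)
      last <- list(fit = sort(h[seq_len(k)]), val = sort(h[-seq_len(k)]))
      if (both_classes(last$fit) && both_classes(last$val)) return(last)
    }
    if (strict) NULL else last
  }

  splits <- vector("list", n_splits)
  if (method == "monte_carlo") {
    n_test <- max(1L, round(test_fraction * length(ids)))
    stop_if_not(n_test <= length(ids) - 2,
                "test_fraction leaves too few training individuals")
    for (s in seq_len(n_splits)) {
      done <- FALSE
      fallback <- NULL
      for (attempt in 0:99) {
        test <- with_seed(mix_seed(master_seed, s, attempt),
                          sort(sample(ids, n_test)))
        train <- sort(setdiff(ids, test))
        # a 1-individual test set cannot hold both classes; exempt it
        if ((n_test >= 2 && !both_classes(test)) || !both_classes(train)) next
        hv <- halve(train, mix_seed(master_seed, s, attempt))
        if (is.null(hv)) {
          if (is.null(fallback))
            fallback <- list(train = train, test = test, attempt = attempt)
          next
        }
        splits[[s]] <- list(train = train, train_fit = hv$fit,
                            train_val = hv$val, test = test)
        done <- TRUE
        break
      }
      if (!done && !is.null(fallback)) {
        warning("could not place both classes in both train/validation ",
                "halves; using an unconstrained sub-split for split ", s)
        hv <- halve(fallback$train,
                    mix_seed(master_seed, s, fallback$attempt), strict = FALSE)
        splits[[s]] <- list(train = fallback$train, train_fit = hv$fit,
                            train_val = hv$val, test = fallback$test)
        done <- TRUE
      }
      if (!done)
        stop("cohort too small to place both classes in every split",
             call. = FALSE)
    }
  } else {
    perm <- with_seed(mix_seed(master_seed, 23), sample(ids))
    fold <- rep(seq_len(n_splits), length.out = length(perm))
    for (s in seq_len(n_splits)) {
      test <- sort(perm[fold == s])
      train <- sort(setdiff(ids, test))
      stop_if_not(both_classes(test) && both_classes(train),
                  "kfold split %d misses a class; use monte_carlo or reseed", s)
      hv <- halve(train, mix_seed(master_seed, s))
      if (is.null(hv)) {
        warning("could not place both classes in both train/validation ",
                "halves; using an unconstrained sub-split for split ", s)
        hv <- halve(train, mix_seed(master_seed, s), strict = FALSE)
      }
      splits[[s]] <- list(train = train, train_fit = hv$fit,
                          train_val = hv$val, test = test)
    }
  }
  structure(list(splits = splits, n_splits = as.integer(n_splits),
                 test_fraction = test_fraction,
                 master_seed = as.integer(master_seed), method = method),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d %s splits, test fraction %.2f, seed %d\n",
              x$n_splits, x$method, x$test_fraction, x$master_seed))
  invisible(x)
}

#' Run individual-level cross-validation for one modality
#'
#' For every split: builds a freshly initialized model, trains it on the
#' split's train-fit half with best-epoch selection on its validation
#' half, and scores the split's test records.  Only test-side predictions
#' enter the returned table, so every score comes from a model whose
#' training never saw that individual.
#'
#' @param cohort A `pd_cohort`.
#' @param spec A [model_spec()].
#' @param cfg A [train_config()].
#' @param plan A [split_plan] from [make_splits()].
#' @param augment An optional [augment_plan()] override.
#' @param return_models Attach the per-split trained models as attribute
#'   `"models"` (default FALSE).
#' @return A prediction table (`individual_id`, `record_id`, `model_id`,
#'   `split_id`, `score`, `label`) with the plan attached as attribute
#'   `"plan"`.
#' @export
run_cv <- function(cohort, spec, cfg = train_config(), plan, augment = NULL,
                   return_models = FALSE) {
  stop_if_not(inherits(plan, "split_plan"), "plan must come from make_splits()")
  rs <- encode_records(cohort, spec$modality, spec$input_len)
  all_ids <- unique(rs$meta$individual_id)
  out <- vector("list", plan$n_splits)
  models <- if (return_models) vector("list", plan$n_splits)
  for (s in seq_len(plan$n_splits)) {
    sp <- plan$splits[[s]]
    spec_s <- spec
    spec_s$seed <- mix_seed(spec$seed, 101, s)
    cfg_s <- cfg
    cfg_s$seed <- mix_seed(cfg$seed, 211, s)
    model <- build_model(spec_s)
    fit_ids <- intersect(sp$train_fit, all_ids)
    val_ids <- intersect(sp$train_val, all_ids)
    test_ids <- intersect(sp$test, all_ids)
    fitted <- train_model(model, subset_records(rs, fit_ids),
                          subset_records(rs, val_ids), cfg_s, augment)
    tab <- predict_records(fitted$model, subset_records(rs, test_ids))
    tab$split_id <- s
    out[[s]] <- tab
    if (return_models) models[[s]] <- fitted$model
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "plan") <- plan
  if (return_models) attr(res, "models") <- models
  res
}

#' Average each record's scores across the splits that tested it
#'
#' Under repeated random splits a record lands in a variable number of
#' test sets; its cross-split scores are averaged into one record score
#' before pulling.
#'
#' @param table A prediction table from [run_cv()].
#' @return Record-level data frame with one row per (record, model):
#'   `individual_id`, `record_id`, `model_id`, `score` (cross-split mean),
#'   `n_splits`, `label`.
#' @export
average_record_scores <- function(table) {
  stop_if_not(nrow(table) >= 1, "empty prediction table")
  key <- interaction(table$record_id, table$model_id, drop = TRUE)
  first <- !duplicated(key)
  out <- table[first, c("individual_id", "record_id", "model_id", "label")]
  out$score <- as.numeric(tapply(table$score, key, mean)[as.character(key[first])])
  out$n_splits <- as.integer(tapply(table$score, key, length)[as.character(key[first])])
  out <- out[order(out$individual_id, out$record_id), ]
  rownames(out) <- NULL
  out[, c("individual_id", "record_id", "model_id", "score", "n_splits",
          "label")]
}

#' Pull record scores to individual scores
#'
#' Collapses a multi-record individual's record scores to one score by
#' taking the maximum or the mean.  Cross-split scores of each record are
#' averaged first.  Maximum pulling captures episodic peak abnormalities
#' and tends to separate PD individuals better when their record scores
#' fluctuate.
#'
#' @param table A prediction table ([run_cv()]) or a record-level table
#'   from [average_record_scores()].
#' @param method `"max"` or `"mean"`.
#' @return An individual score table: `individual_id`, `pulled_score`,
#'   `label`, `pulling_method`.
#' @export
pull_scores <- function(table, method = c("max", "mean")) {
  method <- match.arg(method)
  stop_if_not(nrow(table) >= 1, "empty prediction table")
  if (!is.null(table$split_id)) table <- average_record_scores(table)
  agg <- if (method == "max") tapply(table$score, table$individual_id, max)
         else tapply(table$score, table$individual_id, mean)
  lab <- tapply(table$label, table$individual_id, `[`, 1)
  out <- data.frame(individual_id = names(agg),
                    pulled_score = as.numeric(agg),
                    label = as.numeric(lab[names(agg)]),
                    pulling_method = method,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$individual_id), ]
}
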