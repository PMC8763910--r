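# Threshold-free evaluation metrics.

#' ROC and precision-recall summary for a score vector
#'
#' AUC is computed by the midrank (Mann-Whitney) formula: the probability
#' that a uniformly random positive outranks a uniformly random negative,
#' with ties counted 1/2.  Being rank-based, it is unaffected by the
#' baseline class ratio.  AUPRC is the step-wise integral of the
#' precision-recall curve over distinct score thresholds.
#'
#' @param scores Numeric scores (higher = more PD-like), or an individual
#'   score table from [pull_scores()] (its `pulled_score`/`label` columns
#'   are used and `labels` may be omitted).
#' @param labels Binary labels (0/1) aligned with `scores`.
#' @param level `"record"` or `"individual"` (annotation only).
#' @param subgroup Optional demographic stratum annotation.
#' @return A `metric_result`: list with `auc`, `auprc`, `n_pos`, `n_neg`,
#'   `level`, `subgroup`.
#' @examples
#' compute_metrics(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc  # 1
#' @export
compute_metrics <- function(scores, labels = NULL,
                            level = c("individual", "record"),
                            subgroup = NA_character_) {
  level <- match.arg(level)
  if (is.data.frame(scores)) {
    labels <- scores$label
    scores <- scores$pulled_score %||% scores$score
  }
  stop_if_not(length(scores) == length(labels) && length(scores) >= 2,
              "scores and labels must align (length >= 2)")
  stop_if_not(all(labels %in% c(0, 1)), "labels must be 0/1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  stop_if_not(n_pos >= 1 && n_neg >= 1,
              "both classes must be present to compute AUC")
  r <- rank(scores)                       # midranks
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last_of_tie]
  fp <- fp[last_of_tie]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  auprc <- sum(diff(c(0, recall)) * precision)

  structure(list(auc = auc, auprc = auprc, n_pos = n_pos, n_neg = n_neg,
                 level = level, subgroup = subgroup),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<metric_result> AUC %.4f, AUPRC %.4f (%d pos / %d neg, %s%s)\n",
              x$auc, x$auprc, x$n_pos, x$n_neg, x$level,
              if (is.na(x$subgroup)) "" else paste0(", ", x$subgroup)))
  invisible(x)
}

age_bins <- function(age) {
  cut(age, breaks = c(-Inf, 35, 50, 65, Inf),
      labels = c("<=35", "35-50", "50-65", ">65"))
}

#' Per-demographic-stratum metrics
#'
#' Splits an individual score table by gender, smoking status and age bins
#' (<=35, 35-50, 50-65, >65) and computes AUC/AUPRC per stratum.  Strata
#' that retain only one class are reported with NA metrics and
#' `defined = FALSE` rather than dropped.
#'
#' @param scores An individual score table ([pull_scores()]).
#' @param cohort The `pd_cohort` supplying demographics.
#' @param keys Subset of `c("gender", "smoke", "age")`.
#' @return Data frame with one row per stratum: `key`, `stratum`, `auc`,
#'   `auprc`, `n_pos`, `n_neg`, `defined`.
#' @export
subgroup_metrics <- function(scores, cohort, keys = c("gender", "smoke", "age")) {
  stop_if_not(all(keys %in% c("gender", "smoke", "age")),
              "unknown demographic key")
  ind <- cohort$individuals
  m <- match(scores$individual_id, ind$id)
  stop_if_not(!anyNA(m), "score table contains unknown individuals")
  rows <- list()
  for (k in keys) {
    strat <- if (k == "age") age_bins(ind$age[m]) else ind[[k]][m]
    for (lev in unique(as.character(strat))) {
      sel <- which(as.character(strat) == lev)
      np <- sum(scores$label[sel] == 1)
      nn <- sum(scores$label[sel] == 0)
      if (np >= 1 && nn >= 1 && length(sel) >= 2) {
        mr <- compute_metrics(scores$pulled_score[sel], scores$label[sel],
                              level = "individual", subgroup = lev)
        rows[[length(rows) + 1]] <- data.frame(
          key = k, stratum = lev, auc = mr$auc, auprc = mr$auprc,
          n_pos = np, n_neg = nn, defined = TRUE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          key = k, stratum = lev, auc = NA_real_, auprc = NA_real_,
          n_pos = np, n_neg = nn, defined = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-split individual-level AUCs
#'
#' Pulls each split's test-side record scores to individual scores and
#' computes one AUC per split — the headline cross-validated performance
#' is their mean and spread.
#'
#' @param table A prediction table from [run_cv()].
#' @param method Pulling method, `"max"` or `"mean"`.
#' @return Numeric vector of AUCs, one per split.
#' @export
split_aucs <- function(table, method = c("max", "mean")) {
  method <- match.arg(method)
  vapply(sort(unique(table$split_id)), function(s) {
    sub <- table[table$split_id == s, ]
    compute_metrics(pull_scores(sub, method))$auc
  }, numeric(1))
}
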