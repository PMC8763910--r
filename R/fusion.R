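# Late fusion of per-modality individual scores and comparison against
# self-reported symptom ratings.

#' Fuse per-modality individual scores by averaging
#'
#' Joins two or more individual score tables on their shared individuals
#' (inner join; individuals missing any component modality are excluded
#' and counted) and averages the pulled scores with equal weights into one
#' assembled score.  Metrics are computed for every component and for the
#' fusion on the intersection cohort.
#'
#' @param tables Named list of >= 2 individual score tables
#'   ([pull_scores()]).
#' @return A `fusion_result`: list with `components`, `table` (per-
#'   individual component and fused scores), `metrics` (per component and
#'   `"fused"`), `n_intersection`, `n_excluded`.
#' @export
ensemble_scores <- function(tables) {
  stop_if_not(is.list(tables) && length(tables) >= 2,
              "need at least two component score tables")
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("model", seq_along(tables))
  ids <- Reduce(intersect, lapply(tables, `[[`, "individual_id"))
  stop_if_not(length(ids) >= 2, "component tables share no individuals")
  n_excluded <- length(unique(unlist(lapply(tables, `[[`, "individual_id")))) -
    length(ids)
  ids <- sort(ids)
  comp <- vapply(tables, function(tb)
    tb$pulled_score[match(ids, tb$individual_id)], numeric(length(ids)))
  comp <- matrix(comp, nrow = length(ids),
                 dimnames = list(NULL, names(tables)))
  lab <- tables[[1]]$label[match(ids, tables[[1]]$individual_id)]
  for (tb in tables[-1])
    stop_if_not(identical(as.numeric(tb$label[match(ids, tb$individual_id)]),
                          as.numeric(lab)),
                "component tables disagree on labels")
  fused <- rowMeans(comp)
  tab <- data.frame(individual_id = ids, comp, fused = fused, label = lab,
                    stringsAsFactors = FALSE, check.names = FALSE)
  metrics <- c(
    lapply(seq_along(tables), function(j)
      compute_metrics(comp[, j], lab, level = "individual")),
    list(compute_metrics(fused, lab, level = "individual")))
  names(metrics) <- c(names(tables), "fused")
  structure(list(components = names(tables), table = tab, metrics = metrics,
                 fusion_rule = "mean",
                 n_intersection = length(ids), n_excluded = n_excluded),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %s on %d shared individuals (%d excluded)\n",
              paste(x$components, collapse = " + "), x$n_intersection,
              x$n_excluded))
  for (nm in names(x$metrics))
    cat(sprintf("  %-12s AUC %.4f  AUPRC %.4f\n", nm, x$metrics[[nm]]$auc,
                x$metrics[[nm]]$auprc))
  invisible(x)
}

#' Compare model scores with self-reported symptom ratings
#'
#' Restricted to individuals with self-report scores, computes the Pearson
#' correlation of the model score with the total and part-2 symptom
#' scores, and the AUCs of the total score, the part-2 score and the model
#' score against the PD label.
#'
#' @param model_scores An individual score table ([pull_scores()] or the
#'   fused table of [ensemble_scores()] with `fused` renamed to
#'   `pulled_score`).
#' @param cohort The `pd_cohort` supplying `updrs_total`, `updrs_part2`
#'   and labels.
#' @return A `self_report_comparison`: list with `pearson_r_total`,
#'   `pearson_r_part2`, `auc_updrs_total`, `auc_updrs_part2`, `auc_model`,
#'   `n`.
#' @export
compare_self_report <- function(model_scores, cohort) {
  ind <- cohort$individuals
  m <- match(model_scores$individual_id, ind$id)
  stop_if_not(!anyNA(m), "score table contains unknown individuals")
  keep <- which(!is.na(ind$updrs_total[m]))
  stop_if_not(length(keep) >= 6, "too few individuals with self-reports")
  score <- model_scores$pulled_score[keep]
  label <- model_scores$label[keep]
  total <- ind$updrs_total[m][keep]
  part2 <- ind$updrs_part2[m][keep]
  stop_if_not(sum(label == 1) >= 3 && sum(label == 0) >= 3,
              "need >= 3 individuals with self-reports per class")
  stop_if_not(sd(score) > 0 && sd(total) > 0 && sd(part2) > 0,
              "degenerate variance in scores or self-reports")
  structure(list(
    pearson_r_total = cor(score, total),
    pearson_r_part2 = cor(score, part2),
    auc_updrs_total = compute_metrics(total, label)$auc,
    auc_updrs_part2 = compute_metrics(part2, label)$auc,
    auc_model = compute_metrics(score, label)$auc,
    n = length(keep)), class = "self_report_comparison")
}

#' @export
print.self_report_comparison <- function(x, ...) {
  cat(sprintf("<self_report_comparison> n = %d\n", x$n))
  cat(sprintf("  AUC: model %.4f | total score %.4f | part 2 %.4f\n",
              x$auc_model, x$auc_updrs_total, x$auc_updrs_part2))
  cat(sprintf("  Pearson r: model vs total %.4f, vs part 2 %.4f\n",
              x$pearson_r_total, x$pearson_r_part2))
  invisible(x)
}

#' Benchmark table across models
#'
#' Summarizes per-split individual-level AUCs per model (mean and sd,
#' sorted descending by mean) and reports descriptive two-sided t-tests
#' between consecutive rows.  Components may be prediction tables from
#' [run_cv()] (per-split AUCs are computed with the chosen pulling) or
#' numeric vectors of per-split AUCs (e.g. for fused assemblies).
#'
#' @param results Named list of prediction tables and/or numeric AUC
#'   vectors.
#' @param pulling Pulling method applied to prediction tables.
#' @return A `benchmark_table` data frame: `model`, `n_splits`,
#'   `auc_mean`, `auc_sd`, `p_vs_next`; per-split AUCs attached as
#'   attribute `"per_split"`.
#' @export
benchmark_table <- function(results, pulling = c("max", "mean")) {
  pulling <- match.arg(pulling)
  stop_if_not(is.list(results) && length(results) >= 1 && !is.null(names(results)),
              "results must be a named list")
  per_split <- lapply(results, function(r) {
    if (is.data.frame(r)) split_aucs(r, pulling) else as.numeric(r)
  })
  out <- data.frame(
    model = names(per_split),
    n_splits = vapply(per_split, length, integer(1)),
    auc_mean = vapply(per_split, mean, numeric(1)),
    auc_sd = vapply(per_split, function(v)
      if (length(v) > 1) sd(v) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$auc_mean), ]
  rownames(out) <- NULL
  out$p_vs_next <- NA_real_
  if (nrow(out) > 1) {
    for (i in seq_len(nrow(out) - 1)) {
      a <- per_split[[out$model[i]]]
      b <- per_split[[out$model[i + 1]]]
      if (length(a) > 1 && length(b) > 1 && (sd(a) > 0 || sd(b) > 0))
        out$p_vs_next[i] <- t.test(a, b)$p.value
    }
  }
  attr(out, "per_split") <- per_split[out$model]
  class(out) <- c("benchmark_table", "data.frame")
  out
}
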