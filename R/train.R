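# Training loop with best-epoch selection on validation loss.

#' Train a convolutional classifier
#'
#' Iterates epochs of augmented mini-batches over the training records,
#' evaluates the un-augmented validation loss after every epoch, and
#' returns the parameters of the epoch that minimizes it (no early stop;
#' best-epoch selection guards against overfitting).  Normalization and
#' augmentation are batch-local and applied during training only;
#' validation and prediction passes normalize each record on its own
#' statistics, making them deterministic.
#'
#' Training and validation sets must come from disjoint individuals.
#'
#' @param model A [build_model()] result.
#' @param train_set,val_set `record_set`s (see [encode_records()],
#'   [subset_records()]).
#' @param cfg A [train_config()].
#' @param plan An [augment_plan()]; defaults to the modality's standard
#'   plan.
#' @return List with `model` (parameters at the best epoch, normalization
#'   recorded for prediction), `trace` (per-epoch train/validation loss)
#'   and `best_epoch`.
#' @export
train_model <- function(model, train_set, val_set, cfg = train_config(),
                        plan = NULL) {
  stop_if_not(inherits(model, "pd_model"), "model must be a pd_model")
  stop_if_not(inherits(train_set, "record_set") && inherits(val_set, "record_set"),
              "train_set/val_set must be record_sets")
  stop_if_not(length(train_set$y) >= 1 && length(val_set$y) >= 1,
              "empty training or validation set")
  overlap <- intersect(unique(train_set$meta$individual_id),
                       unique(val_set$meta$individual_id))
  stop_if_not(length(overlap) == 0,
              "training and validation individuals overlap (e.g. %s)",
              overlap[1])
  plan <- plan %||% augment_plan(model$spec$modality)
  model$normalization <- plan$normalization
  spec <- model$spec
  stop_if_not(dim(train_set$x)[2] == spec$input_len,
              "records are not fit to the model input length")

  par <- model$par
  state <- optimizer_init(length(par))
  n <- length(train_set$y)
  val_x <- normalize_set(val_set, plan$normalization)

  trace <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
  best_par <- par
  best_val <- Inf
  best_epoch <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    epoch_loss <- 0
    n_batches <- 0L
    with_seed(mix_seed(cfg$seed, 7919, epoch), {
      idx <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      for (s in starts) {
        ids <- idx[s:min(s + cfg$batch_size - 1, n)]
        batch <- structure(list(
          x = train_set$x[, , ids, drop = FALSE],
          labels = train_set$y[ids],
          meta = train_set$meta[ids, , drop = FALSE]), class = "pd_batch")
        batch <- if (cfg$augment) augment_batch(batch, plan)
                 else normalize_batch(batch, plan$normalization)
        g <- cnn_batch_grad(par, batch$x, batch$labels, spec)
        upd <- adabound_step(par, g$grad, state, cfg)
        par <- upd$par
        state <- upd$state
        epoch_loss <- epoch_loss + g$loss
        n_batches <- n_batches + 1L
      }
    })
    val_scores <- cnn_predict_scores(par, val_x, spec)
    val_loss <- mean(binary_cross_entropy(val_set$y, val_scores))
    trace <- rbind(trace, data.frame(epoch = epoch,
                                     train_loss = epoch_loss / n_batches,
                                     val_loss = val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss
      best_par <- par
      best_epoch <- epoch
    }
  }
  model$par <- best_par
  list(model = model, trace = trace, best_epoch = best_epoch)
}

#' Score records with a trained model
#'
#' Deterministic prediction pass: each record is normalized on its own
#' statistics (no augmentation) and scored by the model's sigmoid output.
#'
#' @param model A `pd_model` (typically `train_model(...)$model`).
#' @param rs A `record_set` of the model's modality, fit to its input
#'   length.
#' @return A prediction table: data frame with `individual_id`,
#'   `record_id`, `model_id`, `score` in (0, 1) and `label`.
#' @export
predict_records <- function(model, rs) {
  stop_if_not(inherits(model, "pd_model"), "model must be a pd_model")
  stop_if_not(inherits(rs, "record_set"), "rs must be a record_set")
  stop_if_not(rs$modality == model$spec$modality,
              "record modality %s does not match model modality %s",
              rs$modality, model$spec$modality)
  stop_if_not(dim(rs$x)[2] == model$spec$input_len,
              "records are not fit to the model input length")
  x <- normalize_set(rs, model$normalization)
  scores <- cnn_predict_scores(model$par, x, model$spec)
  data.frame(individual_id = rs$meta$individual_id,
             record_id = rs$meta$record_id,
             model_id = model$spec$modality,
             score = as.numeric(scores), label = rs$y,
             stringsAsFactors = FALSE, row.names = NULL)
}
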