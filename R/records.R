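# Encoding cohort records into fixed-length model inputs.

encode_one_record <- function(rec, modality, input_len) {
  m <- switch(modality,
    tap_coord = {
      ev <- rec$events$events
      rbind(ev$x, ev$y, ev$t)     # channels: x, y, timestamp
    },
    rec$series$values)
  fit_length(m, input_len)
}

#' Encode cohort records as a fixed-length input set
#'
#' Converts every record of one model modality into a channels x
#' input_len matrix (tap events become a 3-channel x/y/timestamp event
#' sequence; waveforms are used as-is), zero-padded or tail-truncated to
#' the model input length, and stacks them with labels and metadata.
#'
#' @param cohort A `pd_cohort`.
#' @param modality Model modality (see [cohort_records()]).
#' @param input_len Target temporal length.
#' @return A `record_set`: list with `x` (channels x input_len x n array),
#'   `y` (labels), `meta` (individual_id, record_id, plus target-button
#'   bounds for coordinate records), `modality`, `input_len`.
#' @export
encode_records <- function(cohort, modality, input_len) {
  recs <- cohort_records(cohort, modality)
  stop_if_not(length(recs) >= 1, "cohort holds no %s records", modality)
  recs <- recs[order(names(recs))]
  labels <- setNames(cohort$individuals$pd_label, cohort$individuals$id)
  mats <- lapply(recs, encode_one_record, modality = modality,
                 input_len = input_len)
  meta <- data.frame(
    individual_id = vapply(recs, `[[`, "", "individual_id"),
    record_id = vapply(recs, `[[`, "", "record_id"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (modality == "tap_coord") {
    bb <- t(vapply(recs, function(r) button_bounds(r$events$buttons),
                   numeric(4)))
    meta$bound_x0 <- bb[, 1]; meta$bound_y0 <- bb[, 2]
    meta$bound_x1 <- bb[, 3]; meta$bound_y1 <- bb[, 4]
  }
  nc <- nrow(mats[[1]])
  x <- array(unlist(mats, use.names = FALSE),
             dim = c(nc, input_len, length(mats)))
  structure(list(x = x, y = as.numeric(labels[meta$individual_id]),
                 meta = meta, modality = modality,
                 input_len = as.integer(input_len)),
            class = "record_set")
}

#' Subset a record set by individual ids
#'
#' @param rs A `record_set`.
#' @param ids Individual ids to keep.
#' @return The subsetted `record_set`.
#' @export
subset_records <- function(rs, ids) {
  keep <- which(rs$meta$individual_id %in% ids)
  stop_if_not(length(keep) >= 1, "no records left after subsetting")
  rs$x <- rs$x[, , keep, drop = FALSE]
  rs$y <- rs$y[keep]
  rs$meta <- rs$meta[keep, , drop = FALSE]
  rownames(rs$meta) <- NULL
  rs
}

# Per-record normalization for prediction passes: same semantics as the
# batch-local operators with a batch of one, hence deterministic and a pure
# function of the record.
normalize_item <- function(mat, method, bounds = NULL) {
  if (method == "none") return(mat)
  if (method == "zscore") {
    for (c_ in seq_len(nrow(mat))) {
      m <- mean(mat[c_, ])
      s <- sqrt(mean((mat[c_, ] - m)^2))
      mat[c_, ] <- (mat[c_, ] - m) / max(s, 1e-12)
    }
  } else if (method == "center") {
    mat <- mat - rowMeans(mat)
  } else {
    stop_if_not(!is.null(bounds), "boundary normalization needs button bounds")
    mat[1, ] <- (mat[1, ] - bounds[1]) / (bounds[3] - bounds[1])
    mat[2, ] <- (mat[2, ] - bounds[2]) / (bounds[4] - bounds[2])
  }
  mat
}

# Normalize every record of a set for prediction; returns the cube.
normalize_set <- function(rs, method) {
  x <- rs$x
  has_bounds <- all(c("bound_x0", "bound_y0", "bound_x1", "bound_y1") %in%
                      names(rs$meta))
  for (i in seq_len(dim(x)[3])) {
    b <- if (has_bounds)
      as.numeric(rs$meta[i, c("bound_x0", "bound_y0", "bound_x1", "bound_y1")])
    x[, , i] <- normalize_item(matrix(x[, , i], nrow = dim(x)[1]), method, b)
  }
  x
}
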