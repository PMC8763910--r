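# On-disk formats.
#
# Sensor records use a line-delimited structured-text dialect inspired by
# the mPower export layout (the portal's exact schema is not public):
# '#key=value' header lines, then '@section' payload blocks with one
# tab-separated sample or event per line.  Voice records are standard
# uncompressed PCM16 mono WAV files with a '#key=value' sidecar
# ('<path>.meta').  This module is the single place a reader for the real
# portal layout would plug in.

RECORD_SCHEMA <- "pdsense-record-v1"

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write a sensor record to disk
#'
#' Tapping records store the accelerometer stream (`@accel`: t, x, y, z
#' rows) and the tap-event sequence (`@taps`: t, x, y rows) with the
#' target-button rectangles in the header; gait records store the
#' accelerometer stream; voice records are written as PCM16 mono WAV with
#' a text sidecar.  Numeric payloads are printed with 17 significant
#' digits, so text round-trips are exact; WAV payloads round-trip at the
#' stored 16-bit precision.
#'
#' @param rec A cohort record (element of `pd_cohort$records`).
#' @param path Output path (use a `.wav` suffix for voice).
#' @param overwrite Overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_record <- function(rec, path, overwrite = FALSE) {
  stop_if_not(overwrite || !file.exists(path),
              "refusing to overwrite %s (set overwrite = TRUE)", path)
  if (rec$modality == "voice") {
    write_wav(rec$series$values[1, ], rec$series$sample_rate, path)
    meta <- c(sprintf("#schema=%s", RECORD_SCHEMA),
              sprintf("#individual_id=%s", rec$individual_id),
              sprintf("#record_id=%s", rec$record_id),
              "#modality=voice",
              sprintf("#duration=%s", fmt_num(rec$duration)),
              sprintf("#sample_rate=%s", fmt_num(rec$series$sample_rate)))
    writeLines(meta, paste0(path, ".meta"))
    return(invisible(path))
  }
  lines <- c(sprintf("#schema=%s", RECORD_SCHEMA),
             sprintf("#individual_id=%s", rec$individual_id),
             sprintf("#record_id=%s", rec$record_id),
             sprintf("#modality=%s", rec$modality),
             sprintf("#duration=%s", fmt_num(rec$duration)),
             sprintf("#sample_rate=%s", fmt_num(rec$series$sample_rate)))
  if (rec$modality == "tapping") {
    ev <- rec$events
    lines <- c(lines,
               sprintf("#screen=%sx%s", fmt_num(ev$screen[[1]]),
                       fmt_num(ev$screen[[2]])),
               sprintf("#buttons=%s;%s",
                       paste(fmt_num(ev$buttons[[1]]), collapse = ","),
                       paste(fmt_num(ev$buttons[[2]]), collapse = ",")))
  }
  v <- rec$series$values
  tt <- (seq_len(ncol(v)) - 1) / rec$series$sample_rate
  lines <- c(lines, "@accel",
             paste(fmt_num(tt), fmt_num(v[1, ]), fmt_num(v[2, ]),
                   fmt_num(v[3, ]), sep = "\t"))
  if (rec$modality == "tapping") {
    e <- rec$events$events
    lines <- c(lines, "@taps",
               paste(fmt_num(e$t), fmt_num(e$x), fmt_num(e$y), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

parse_header <- function(lines, path) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2)
  stop_if_not(length(bad) == 0, "%s: malformed header line %d", path,
              if (length(bad)) bad[1] else 0L)
  setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
}

parse_rows <- function(lines, idx, n_fields, path) {
  if (!length(idx)) return(matrix(numeric(0), ncol = n_fields))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  stop_if_not(length(bad) == 0, "%s: line %d has %d fields (expected %d)",
              path, idx[bad[1]], lengths(parts)[bad[1]], n_fields)
  m <- matrix(as.numeric(unlist(parts)), ncol = n_fields, byrow = TRUE)
  stop_if_not(!anyNA(m), "%s: non-numeric payload near line %d", path, idx[1])
  m
}

#' Read a sensor record written by [write_record()]
#'
#' Validates the schema version, payload/modality agreement, timestamp
#' ordering (non-decreasing accelerometer samples, strictly increasing
#' taps) and the minimum of two tap events; malformed lines are reported
#' with their line number.
#'
#' @param path Path to a record file (text, or `.wav` with its sidecar).
#' @return A cohort record object.
#' @export
read_record <- function(path) {
  stop_if_not(file.exists(path), "no such record file: %s", path)
  if (grepl("\\.wav$", path)) {
    meta_path <- paste0(path, ".meta")
    stop_if_not(file.exists(meta_path), "missing voice sidecar %s", meta_path)
    h <- parse_header(readLines(meta_path), meta_path)
    stop_if_not(identical(h[["schema"]], RECORD_SCHEMA),
                "%s: unknown schema version '%s'", meta_path, h[["schema"]])
    wav <- read_wav(path)
    return(list(individual_id = h[["individual_id"]],
                record_id = h[["record_id"]], modality = "voice",
                duration = as.numeric(h[["duration"]]),
                series = sensor_series(matrix(wav$samples, nrow = 1),
                                       wav$sample_rate, "voice")))
  }
  lines <- readLines(path)
  h <- parse_header(lines, path)
  stop_if_not(identical(h[["schema"]], RECORD_SCHEMA),
              "%s: unknown schema version '%s'", path, h[["schema"]])
  modality <- h[["modality"]]
  stop_if_not(modality %in% c("tapping", "gait"),
              "%s: unsupported modality '%s' in text container", path, modality)
  sec <- ifelse(grepl("^@", lines), lines, NA)
  sec <- zoo_na_locf(sec)
  accel_idx <- which(sec == "@accel" & !grepl("^[#@]", lines))
  acc <- parse_rows(lines, accel_idx, 4L, path)
  stop_if_not(nrow(acc) >= 2, "%s: accelerometer payload missing", path)
  stop_if_not(all(diff(acc[, 1]) >= 0),
              "%s: accelerometer timestamps decrease", path)
  rate <- as.numeric(h[["sample_rate"]])
  rec <- list(individual_id = h[["individual_id"]],
              record_id = h[["record_id"]], modality = modality,
              duration = as.numeric(h[["duration"]]),
              series = sensor_series(t(acc[, 2:4]), rate,
                                     if (modality == "tapping") "tap_accel"
                                     else "gait"))
  if (modality == "tapping") {
    taps_idx <- which(sec == "@taps" & !grepl("^[#@]", lines))
    tp <- parse_rows(lines, taps_idx, 3L, path)
    stop_if_not(nrow(tp) >= 2, "%s: fewer than 2 tap events", path)
    stop_if_not(all(diff(tp[, 1]) > 0),
                "%s: tap timestamps must strictly increase", path)
    buttons <- lapply(strsplit(h[["buttons"]], ";", fixed = TRUE)[[1]],
                      function(s) as.numeric(strsplit(s, ",")[[1]]))
    screen <- as.numeric(strsplit(h[["screen"]], "x", fixed = TRUE)[[1]])
    rec$events <- tap_events(data.frame(t = tp[, 1], x = tp[, 2], y = tp[, 3]),
                             buttons, screen, as.numeric(h[["duration"]]))
  }
  rec
}

# last-observation-carried-forward for section markers (no zoo dependency)
zoo_na_locf <- function(x) {
  ok <- !is.na(x)
  idx <- cumsum(ok)
  out <- rep(NA_character_, length(x))
  out[idx > 0] <- x[ok][idx[idx > 0]]
  out
}

# --- minimal PCM16 mono WAV ------------------------------------------------

write_wav <- function(samples, sample_rate, path) {
  s <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_data <- length(s) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_data), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")    # PCM
  writeBin(1L, con, size = 2, endian = "little")    # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")    # block align
  writeBin(16L, con, size = 2, endian = "little")   # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_data, con, size = 4, endian = "little")
  writeBin(s, con, size = 2, endian = "little")
  invisible(path)
}

read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  stop_if_not(identical(readChar(con, 4), "RIFF"), "%s: not a RIFF file", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  stop_if_not(identical(readChar(con, 4), "WAVE"), "%s: not a WAV file", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop(path, ": no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      stop_if_not(fmt[1] == 1L && fmt[2] == 1L,
                  "%s: only PCM mono WAV is supported", path)
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = sz - 8))
    } else if (id == "data") {
      s <- readBin(con, integer(), n = sz / 2, size = 2, endian = "little")
      stop_if_not(!is.null(sample_rate), "%s: data chunk before fmt", path)
      return(list(samples = s / 32767, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, "raw", n = sz))
    }
  }
}

# --- cohort directories ----------------------------------------------------

#' Write a cohort to a directory
#'
#' Lays out `individuals.tsv`, `config.yaml` (generator configuration plus
#' seed, from which the cohort is fully reproducible) and one record file
#' per record under `records/`.
#'
#' @param cohort A `pd_cohort`.
#' @param dir Output directory (created if missing).
#' @param overwrite Overwrite existing record files?
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  dir.create(file.path(dir, "records"), recursive = TRUE, showWarnings = FALSE)
  write.table(cohort$individuals, file.path(dir, "individuals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(cohort$config)
  # named vectors must go out as maps or yaml drops the names
  for (nm in c("screen", "gender_probs", "smoke_probs"))
    cfg[[nm]] <- as.list(cfg[[nm]])
  yaml::write_yaml(list(schema = RECORD_SCHEMA, seed = cohort$seed,
                        config = cfg), file.path(dir, "config.yaml"))
  for (rec in cohort$records) {
    ext <- if (rec$modality == "voice") ".wav" else ".txt"
    write_record(rec, file.path(dir, "records", paste0(rec$record_id, ext)),
                 overwrite = overwrite)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `pd_cohort`.
#' @export
read_cohort <- function(dir) {
  stop_if_not(file.exists(file.path(dir, "individuals.tsv")),
              "%s is not a cohort directory", dir)
  ind <- read.table(file.path(dir, "individuals.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  stop_if_not(identical(meta$schema, RECORD_SCHEMA),
              "%s: unknown cohort schema", dir)
  cfg_args <- meta$config
  cfg_args$screen <- unlist(cfg_args$screen)
  cfg_args$gender_probs <- unlist(cfg_args$gender_probs)
  cfg_args$smoke_probs <- unlist(cfg_args$smoke_probs)
  config <- do.call(cohort_config, cfg_args)
  files <- sort(list.files(file.path(dir, "records"),
                           pattern = "\\.(txt|wav)$", full.names = TRUE))
  records <- lapply(files, read_record)
  names(records) <- vapply(records, `[[`, "", "record_id")
  structure(list(individuals = ind, records = records, config = config,
                 seed = as.integer(meta$seed)),
            class = "pd_cohort")
}

# --- prediction tables -----------------------------------------------------

#' Export a prediction or score table
#'
#' Writes tab-separated text with a stable header and deterministic row
#' order (individual id, then record id where present).
#'
#' @param table A prediction table or individual score table.
#' @param path Output path.
#' @param overwrite Overwrite an existing file?
#' @return `path`, invisibly.
#' @export
export_predictions <- function(table, path, overwrite = FALSE) {
  stop_if_not(overwrite || !file.exists(path),
              "refusing to overwrite %s (set overwrite = TRUE)", path)
  keys <- intersect(c("individual_id", "record_id", "split_id", "model_id"),
                    names(table))
  ord <- do.call(order, unname(table[keys]))
  write.table(table[ord, , drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a table written by [export_predictions()]
#'
#' @param path Path to the tab-separated table.
#' @return A data frame.
#' @export
read_predictions <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
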