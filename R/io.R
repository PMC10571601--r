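# Serialization: recordings and datasets as flat little-endian float32
# arrays with a JSON metadata sidecar (events included); calibration stats,
# models and logs as JSON/JSONL text.

write_bin_array <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4, endian = "little")
}

read_bin_array <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "numeric", n = n, size = 4, endian = "little")
}

#' Write / read a raw recording
#'
#' Stores `<stem>.bin` (channels x samples float32, column-major) and
#' `<stem>.json` (sampling rate, channel ids, events).
#'
#' @param rec An [ecog_recording()].
#' @param stem Path stem (without extension).
#' @return `write_recording` returns `stem` invisibly; `read_recording`
#'   returns the recording.
#' @export
write_recording <- function(rec, stem) {
  write_bin_array(rec$data, paste0(stem, ".bin"))
  meta <- list(n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               fs = rec$fs, channel_ids = rec$channel_ids,
               events = rec$events)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  d <- matrix(read_bin_array(paste0(stem, ".bin"),
                             meta$n_channels * meta$n_samples),
              meta$n_channels, meta$n_samples)
  ev <- if (length(meta$events)) {
    data.frame(type = meta$events$type, t = meta$events$t)
  } else {
    data.frame(type = character(), t = numeric())
  }
  ecog_recording(d, meta$fs, meta$channel_ids, ev)
}

#' Write / read calibration statistics as JSON
#'
#' @param stats A [compute_calibration_stats()] result.
#' @param path Output `.json` path.
#' @export
write_calibration_stats <- function(stats, path) {
  jsonlite::write_json(list(mean = stats$mean, sd = stats$sd,
                            bin_freqs_hz = stats$bin_freqs_hz,
                            n_windows = stats$n_windows, fs = stats$fs,
                            n_channels = stats$n_channels),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibration_stats
#' @export
read_calibration_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = x$mean, sd = x$sd, bin_freqs_hz = x$bin_freqs_hz,
                 n_windows = x$n_windows, fs = x$fs,
                 n_channels = x$n_channels),
            class = "calibration_stats")
}

#' Write / read a trained model
#'
#' Weights as float64 binary, configuration and shapes as JSON.
#'
#' @param model A `click_model`.
#' @param stem Path stem (without extension).
#' @export
write_model <- function(model, stem) {
  par <- c("W", "U", "b", "W1", "b1", "W2", "b2")
  flat <- unlist(lapply(model[par], as.numeric))
  con <- file(paste0(stem, ".bin"), "wb")
  writeBin(flat, con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(list(config = unclass(model$config),
                            trained = model$trained),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_model
#' @export
read_model <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  cfg <- do.call(model_config, meta$config[names(formals(model_config))])
  model <- build_model(cfg)
  par <- c("W", "U", "b", "W1", "b1", "W2", "b2")
  n_tot <- sum(vapply(model[par], length, 0L))
  con <- file(paste0(stem, ".bin"), "rb")
  flat <- readBin(con, "numeric", n = n_tot, size = 8, endian = "little")
  close(con)
  pos <- 0
  for (p in par) {
    k <- length(model[[p]])
    v <- flat[(pos + 1):(pos + k)]
    model[[p]] <- if (is.matrix(model[[p]])) {
      matrix(v, nrow(model[[p]]), ncol(model[[p]]))
    } else v
    pos <- pos + k
  }
  model$trained <- isTRUE(meta$trained)
  model
}

#' Write an event log as JSONL
#'
#' One event per line: `{"type": ..., "t": ..., "assignment": ...}` for
#' every grasp onset and click.
#'
#' @param log An assigned [click_event_log()].
#' @param path Output path.
#' @export
write_event_log <- function(log, path) {
  a <- log$assignments
  lines <- c(
    vapply(seq_along(log$grasp_onsets), function(i) {
      jsonlite::toJSON(list(type = "grasp_onset", t = log$grasp_onsets[i],
                            assignment = if (is.null(a)) NA else a$onset[i]),
                       auto_unbox = TRUE, digits = NA)
    }, ""),
    vapply(seq_along(log$detections), function(i) {
      jsonlite::toJSON(list(type = "click", t = log$detections[i],
                            t_onscreen = log$onscreen_clicks[i],
                            assignment = if (is.null(a)) NA else a$click[i]),
                       auto_unbox = TRUE, digits = NA)
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}
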