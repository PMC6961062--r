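# Full-workflow driver: config parsing and the end-to-end analysis run
# (read -> preprocess -> spectra/peaks -> coherence -> spectrograms) with a
# reproducibility manifest.

config_defaults <- function() {
  list(fs = NULL,
       acc_band = c(2, 30), emg_band = c(20, 300), filter_order = 3,
       smooth_cutoff = 30, peak_band = c(3, 18),
       coherence_window_s = 1, coherence_window_samples = NULL,
       coherence_alpha = 0.05, coherence_taper = 0.1,
       coherence_pairs = NULL, spectrogram_window = NULL,
       out_dir = ".")
}

parse_config_value <- function(x) {
  x <- trimws(x)
  parts <- trimws(strsplit(x, ",")[[1L]])
  nums <- suppressWarnings(as.numeric(parts))
  if (!anyNA(nums)) {
    if (length(nums) == 1L) nums[[1L]] else nums
  } else {
    x
  }
}

#' Read a flat key = value analysis configuration
#'
#' One `key = value` pair per line; `#` starts a comment; numeric values
#' and comma-separated numeric vectors are parsed as numbers. Channel
#' mapping lines take the form `channel.<column> = <name>:<role>[:<limb>]`.
#' All defaults are the standard tremor-protocol values (ACC band 2–30 Hz,
#' EMG band 20–300 Hz, order-3 Butterworth, 3–18 Hz peak band, 1 s
#' coherence windows at alpha 0.05 with taper fraction 0.1). Unknown keys
#' are rejected.
#'
#' @param path Path to the config file.
#' @return An `analysis_config` list.
#' @export
read_analysis_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  cfg <- config_defaults()
  channels <- NULL
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(sprintf("Config line is not `key = value`: %s", trimws(ln)),
            class = "tremorkit_config_error")
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (grepl("^channel\\.[0-9]+$", key)) {
      col <- as.integer(sub("^channel\\.", "", key))
      fields <- trimws(strsplit(val, ":")[[1L]])
      if (length(fields) < 2L) {
        abort(sprintf("Channel mapping needs `name:role[:limb]`: %s", val),
              class = "tremorkit_config_error")
      }
      limb <- if (length(fields) >= 3L) fields[[3L]] else "none"
      channels <- dplyr::bind_rows(
        channels, channel_spec(fields[[1L]], fields[[2L]], col, limb))
    } else if (key %in% names(cfg)) {
      cfg[[key]] <- if (key %in% c("out_dir", "coherence_pairs")) val
                    else parse_config_value(val)
    } else {
      abort(sprintf("Unknown config key: %s", key),
            class = "tremorkit_config_error")
    }
  }
  if (is.null(cfg$fs)) {
    abort("Config must set `fs` (the sampling rate is never inferred).",
          class = "tremorkit_config_error")
  }
  cfg$channels <- if (is.null(channels)) default_montage() else channels
  structure(cfg, class = "analysis_config")
}

default_coherence_pairs <- function(channels) {
  # within each limb: ACC against every EMG channel
  pairs <- list()
  for (lb in unique(channels$limb)) {
    sub <- channels[channels$limb == lb, ]
    acc <- sub$name[sub$role == "ACC"]
    emg <- sub$name[sub$role == "EMG"]
    for (a in acc) for (e in emg) pairs[[length(pairs) + 1L]] <- c(a, e)
  }
  pairs
}

parse_coherence_pairs <- function(spec) {
  lapply(strsplit(spec, ";")[[1L]], function(p) trimws(strsplit(p, "~")[[1L]]))
}

run_stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
          class = "tremorkit_stage_error", parent = e)
  })
}

#' Run the full tremor analysis workflow on a recording file
#'
#' Reads the text recording, preprocesses every channel by role, and writes
#' per-channel power spectra (`spectra.csv`), tremor-band peak frequencies
#' (`peaks.json`), the requested pairwise coherences of preprocessed channels
#' (`coherence_<x>_<y>.csv` plus `coherence_summary.json` with L and the
#' 95% confidence limit), per-channel spectrograms (`spectrogram_<ch>.csv`)
#' and a run manifest (`manifest.json`: config echo, package and R
#' versions, channel count). Any stage error propagates with the stage
#' named. Outputs are deterministic for identical input and config.
#'
#' @param recording_path Path to the plain-text recording.
#' @param config An `analysis_config` from [read_analysis_config()], or a
#'   list of overrides (at minimum `fs`).
#' @param out_dir Output directory (created if missing); overrides the
#'   config's `out_dir`.
#' @return Invisibly, a list with the result tibbles and written paths.
#' @export
run_full_analysis <- function(recording_path, config, out_dir = NULL) {
  if (!inherits(config, "analysis_config")) {
    base <- config_defaults()
    base[names(config)] <- config
    if (is.null(base$channels)) base$channels <- default_montage()
    config <- structure(base, class = "analysis_config")
  }
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rec <- run_stage("read", read_recording(recording_path, config$channels,
                                          fs = config$fs))
  pre <- run_stage("preprocess", preprocess_recording(
    rec, acc_band = config$acc_band, emg_band = config$emg_band,
    order = config$filter_order, smooth_cutoff = config$smooth_cutoff))

  spectra <- run_stage("spectrum", recording_spectra(pre))
  peaks <- run_stage("peaks", peak_frequencies(spectra, config$peak_band))
  write_table(spectra, file.path(out_dir, "spectra.csv"), "csv")
  write_table(peaks, file.path(out_dir, "peaks.json"), "json")

  pairs <- if (!is.null(config$coherence_pairs)) {
    parse_coherence_pairs(config$coherence_pairs)
  } else {
    default_coherence_pairs(rec_channels(rec))
  }
  coh_summaries <- list()
  for (pr in pairs) {
    if (pr[[1L]] == pr[[2L]]) {
      message(sprintf("note: coherence of channel '%s' with itself is identically 1",
                      pr[[1L]]))
    }
    co <- run_stage(sprintf("coherence %s~%s", pr[[1L]], pr[[2L]]),
                    coherence_between(pre, pr[[1L]], pr[[2L]],
                                      window_s = config$coherence_window_s,
                                      window_samples = config$coherence_window_samples,
                                      alpha = config$coherence_alpha,
                                      p = config$coherence_taper))
    fname <- sprintf("coherence_%s_%s.csv", pr[[1L]], pr[[2L]])
    write_table(co, file.path(out_dir, fname), "csv")
    coh_summaries[[paste(pr, collapse = "~")]] <-
      list(L = attr(co, "L"), confidence_limit = attr(co, "confidence_limit"),
           window_samples = attr(co, "window_samples"), file = fname)
  }
  if (length(coh_summaries)) {
    jsonlite::write_json(coh_summaries,
                         file.path(out_dir, "coherence_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  sg_paths <- character(0)
  for (nm in rec_channels(rec)$name) {
    w <- config$spectrogram_window %||% pow2_window(config$fs)
    sg <- run_stage(sprintf("spectrogram %s", nm),
                    spectrogram(pre[[nm]], config$fs, window_samples = w,
                                channel = nm))
    pth <- file.path(out_dir, sprintf("spectrogram_%s.csv", nm))
    write_table(sg, pth, "csv")
    sg_paths <- c(sg_paths, pth)
  }

  manifest <- list(
    recording = recording_path,
    n_channels = nrow(rec_channels(rec)),
    n_samples = nrow(rec),
    fs = config$fs,
    config = unclass(config)[setdiff(names(config), "channels")],
    channels = rec_channels(rec),
    n_spectra = length(unique(spectra$channel)),
    n_peaks = nrow(peaks),
    package = list(name = "tremorkit",
                   version = as.character(utils::packageVersion("tremorkit")),
                   r_version = R.version.string)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(recording = rec, preprocessed = pre, spectra = spectra,
                 peaks = peaks, coherence = coh_summaries, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
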