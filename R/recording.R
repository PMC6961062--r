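#' Describe one channel of a tremor recording
#'
#' A channel specification maps a column of a plain-text recording file onto
#' a named, role-tagged channel. Roles drive preprocessing: `"ACC"` channels
#' (accelerometry) are band-limited to the tremor band, `"EMG"` channels
#' (surface electromyography) are band-limited, rectified and smoothed.
#'
#' @param name Short channel label, e.g. `"R-ACC"` or `"R-ECR"`.
#' @param role Either `"ACC"` or `"EMG"`.
#' @param column 1-based column index of the channel in the source file.
#' @param limb `"left"`, `"right"` or `"none"`.
#'
#' @return A one-row tibble with columns `name`, `role`, `column`, `limb`.
#' @examples
#' channel_spec("R-ACC", "ACC", 1, "right")
#' @export
channel_spec <- function(name, role, column, limb = "none") {
  role <- match.arg(role, c("ACC", "EMG"))
  limb <- match.arg(limb, c("left", "right", "none"))
  column <- as.integer(column)
  if (is.na(column) || column < 1L) {
    abort("`column` must be a positive column index.", class = "tremorkit_spec_error")
  }
  tibble::tibble(name = name, role = role, column = column, limb = limb)
}

#' Standard six-channel tremor montage
#'
#' The conventional upper-limb tremor study layout: per limb, one wrist
#' accelerometer plus surface EMG over the antagonist forearm muscles
#' (extensor and flexor carpi radialis), giving six channels in the column
#' order L-ACC, L-ECR, L-FCR, R-ACC, R-ECR, R-FCR.
#'
#' @return A six-row channel-spec tibble.
#' @export
default_montage <- function() {
  dplyr::bind_rows(
    channel_spec("L-ACC", "ACC", 1, "left"),
    channel_spec("L-ECR", "EMG", 2, "left"),
    channel_spec("L-FCR", "EMG", 3, "left"),
    channel_spec("R-ACC", "ACC", 4, "right"),
    channel_spec("R-ECR", "EMG", 5, "right"),
    channel_spec("R-FCR", "EMG", 6, "right")
  )
}

validate_channel_specs <- function(channels) {
  needed <- c("name", "role", "column", "limb")
  if (!is.data.frame(channels) || !all(needed %in% names(channels))) {
    abort("`channels` must be a channel-spec tibble (see `channel_spec()`).",
          class = "tremorkit_spec_error")
  }
  if (anyDuplicated(channels$column)) {
    abort("Channel column indices must be unique.", class = "tremorkit_spec_error")
  }
  if (anyDuplicated(channels$name)) {
    abort("Channel names must be unique.", class = "tremorkit_spec_error")
  }
  if (!all(channels$role %in% c("ACC", "EMG"))) {
    abort("Channel roles must be 'ACC' or 'EMG'.", class = "tremorkit_spec_error")
  }
  invisible(channels)
}

#' Construct a tremor recording
#'
#' A recording is a tibble of samples in channel columns, carrying the
#' sampling rate and the channel specifications as attributes. All analysis
#' verbs in the package take this object first, so calls chain with the pipe.
#'
#' @param samples Numeric matrix or data frame, one column per channel, rows
#'   in temporal order. Amplitude units are whatever the acquisition system
#'   produced (ACC acceleration units, EMG voltage units).
#' @param fs Sampling rate in Hz (> 0); never inferred from the data.
#' @param channels Channel-spec tibble; `column` here indexes `samples`.
#'
#' @return A `tremor_recording` tibble with one column per channel (named
#'   after the specs) plus attributes `fs` and `channels`.
#' @export
recording <- function(samples, fs, channels = default_montage()) {
  validate_channel_specs(channels)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive sampling rate in Hz.",
          class = "tremorkit_spec_error")
  }
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 2L) {
    abort("A recording needs at least 2 samples.",
          class = "tremorkit_insufficient_data")
  }
  if (max(channels$column) > ncol(samples)) {
    abort(sprintf("Channel spec refers to column %d but the data has %d column(s).",
                  max(channels$column), ncol(samples)),
          class = "tremorkit_spec_error")
  }
  mat <- samples[, channels$column, drop = FALSE]
  if (!all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    abort(sprintf("Non-finite sample at row %d, channel '%s'.",
                  bad[[1L]], channels$name[[bad[[2L]]]]),
          class = "tremorkit_parse_error")
  }
  colnames(mat) <- channels$name
  out <- tibble::as_tibble(mat)
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "channels") <- channels
  class(out) <- c("tremor_recording", class(out))
  out
}

#' @export
print.tremor_recording <- function(x, ...) {
  ch <- rec_channels(x)
  cat(sprintf("<tremor_recording> %d samples x %d channels, fs = %g Hz (%.3f s)\n",
              nrow(x), nrow(ch), rec_fs(x), nrow(x) / rec_fs(x)))
  cat("channels:", paste0(ch$name, " [", ch$role, "]", collapse = ", "), "\n")
  NextMethod()
}

#' Sampling rate and channel table of a recording
#'
#' @param rec A `tremor_recording`.
#' @return `rec_fs()` the sampling rate in Hz; `rec_channels()` the
#'   channel-spec tibble; `rec_duration()` the duration in seconds.
#' @export
rec_fs <- function(rec) attr(rec, "fs")

#' @rdname rec_fs
#' @export
rec_channels <- function(rec) attr(rec, "channels")

#' @rdname rec_fs
#' @export
rec_duration <- function(rec) nrow(rec) / rec_fs(rec)

sniff_delimiter <- function(line) {
  # precedence: tab > comma > semicolon > whitespace runs
  if (grepl("\t", line)) return("\t")
  if (grepl(",", line)) return(",")
  if (grepl(";", line)) return(";")
  "[[:space:]]+"
}

tokenize_lines <- function(lines, delim) {
  lines <- sub("^[[:space:]]+", "", sub("[[:space:]]+$", "", lines))
  strsplit(lines, delim)
}

#' Read a plain-text multi-channel tremor recording
#'
#' Reads a delimited numeric text file (the universal interchange format for
#' electrophysiological exports) into a [recording()]. The delimiter is
#' auto-detected from the first data line with precedence tab, comma,
#' semicolon, then whitespace runs. Exactly one optional leading header line
#' of non-numeric tokens is tolerated; any later non-numeric token is a hard
#' parse error (missing values are never imputed — downstream spectral
#' estimators assume contiguous sampling).
#'
#' @param path Path to the text file.
#' @param channels Channel-spec tibble mapping file columns to channels.
#' @param fs Sampling rate in Hz, supplied by the user (files carry none).
#'
#' @return A `tremor_recording`.
#' @examples
#' \donttest{
#' rec <- simulate_recording(tremor_sim_params(duration_s = 2, seed = 1))
#' path <- tempfile(fileext = ".txt")
#' write_recording(rec, path)
#' rec2 <- read_recording(path, default_montage(), fs = 1000)
#' }
#' @export
read_recording <- function(path, channels = default_montage(), fs) {
  validate_channel_specs(channels)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "tremorkit_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort("File contains no data rows.", class = "tremorkit_insufficient_data")
  }
  delim <- sniff_delimiter(lines[[1L]])
  toks <- tokenize_lines(lines, delim)
  first <- suppressWarnings(as.numeric(toks[[1L]]))
  skip <- 0L
  if (anyNA(first)) {           # single optional header line
    skip <- 1L
    toks <- toks[-1L]
  }
  if (length(toks) < 2L) {
    abort("Fewer than 2 data rows.", class = "tremorkit_insufficient_data")
  }
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[[1L]])[1L]
    abort(sprintf("Ragged row at line %d: %d tokens, expected %d.",
                  bad + skip, ncols[[bad]], ncols[[1L]]),
          class = "tremorkit_parse_error")
  }
  if (max(channels$column) > ncols[[1L]]) {
    abort(sprintf("Channel spec refers to column %d but the file has %d column(s).",
                  max(channels$column), ncols[[1L]]),
          class = "tremorkit_spec_error")
  }
  vals <- suppressWarnings(as.numeric(unlist(toks, use.names = FALSE)))
  if (anyNA(vals)) {
    flat <- which(is.na(vals))[1L] - 1L
    row <- flat %/% ncols[[1L]] + 1L
    col <- flat %% ncols[[1L]] + 1L
    abort(sprintf("Non-numeric token at line %d, column %d.", row + skip, col),
          class = "tremorkit_parse_error")
  }
  mat <- matrix(vals, ncol = ncols[[1L]], byrow = TRUE)
  recording(mat, fs = fs, channels = channels)
}

#' Write a recording back to the plain-text interchange format
#'
#' Columns are written in channel-spec column order so that the same spec
#' re-reads the file (the writer dogfoods the reader's contract).
#'
#' @param rec A `tremor_recording`.
#' @param path Output path.
#' @param delim Delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, delim = "\t") {
  ch <- rec_channels(rec)
  mat <- matrix(0, nrow(rec), max(ch$column))
  for (i in seq_len(nrow(ch))) mat[, ch$column[[i]]] <- rec[[ch$name[[i]]]]
  utils::write.table(format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = delim, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a result table to CSV or JSON
#'
#' Numeric columns round-trip losslessly (>= 15 significant digits). CSV
#' output has a header row; JSON output is an array of records.
#'
#' @param rows A data frame of records.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("csv", "json")) {
  format <- match.arg(format)
  rows <- tibble::as_tibble(rows)
  if (format == "csv") {
    readr::write_csv(rows, path)
  } else {
    jsonlite::write_json(rows, path, digits = NA, dataframe = "rows", na = "null")
  }
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`.
#' @return A tibble.
#' @export
read_table_result <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
}
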