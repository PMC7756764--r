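#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed 16-bit PCM audio, the interchange
#' format of the pipeline. Samples are rescaled to `[-1, 1]` by dividing by
#' 32767.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `waveform` (numeric matrix, samples x channels, in
#'   `[-1, 1]`), `sample_rate` (Hz), and `bit_depth`.
#' @seealso [write_wav()], [standardize_audio()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) abort(sprintf("audio file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))

  read_id <- function() rawToChar(readBin(con, "raw", 4L))
  read_u32 <- function() readBin(con, "integer", 1L, size = 4L, endian = "little")

  if (!identical(read_id(), "RIFF")) abort(sprintf("not a RIFF file: %s", path))
  read_u32() # overall size, unused
  if (!identical(read_id(), "WAVE")) abort(sprintf("not a WAVE file: %s", path))

  fmt <- NULL
  samples <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4L)
    if (length(id_raw) < 4L) break
    id <- rawToChar(id_raw)
    size <- read_u32()
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size + size %% 2L)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bit_depth    = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) abort(sprintf("malformed WAV (data before fmt): %s", path))
      if (fmt$audio_format != 1L) {
        abort(sprintf("unsupported WAV encoding (format tag %d); only PCM is supported", fmt$audio_format))
      }
      if (fmt$bit_depth != 16L) {
        abort(sprintf("unsupported bit depth %d; only 16-bit PCM is supported", fmt$bit_depth))
      }
      n <- size %/% 2L
      samples <- readBin(con, "integer", n, size = 2L, signed = TRUE, endian = "little")
      if (length(samples) < n) abort(sprintf("truncated WAV data chunk: %s", path))
      if (size %% 2L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) abort(sprintf("no data chunk found in WAV: %s", path))

  wave <- matrix(samples / 32767, ncol = fmt$n_channels, byrow = TRUE)
  list(waveform = wave, sample_rate = fmt$sample_rate, bit_depth = fmt$bit_depth)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param waveform Numeric vector of amplitudes in `[-1, 1]` (values outside
#'   are clipped).
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, sample_rate, path) {
  stopifnot(is.numeric(waveform), length(sample_rate) == 1L, sample_rate > 0)
  x <- pmin(1, pmax(-1, as.double(waveform)))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")

  writeChar("RIFF", con, eos = NULL); w_u32(36L + n_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_u32(16L)
  w_u16(1L)                      # PCM
  w_u16(1L)                      # mono
  w_u32(sample_rate)
  w_u32(sample_rate * 2L)        # byte rate
  w_u16(2L)                      # block align
  w_u16(16L)                     # bit depth
  writeChar("data", con, eos = NULL); w_u32(n_bytes)
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

# Fourier-domain resampling: brickwall band limitation followed by exact
# reconstruction on the new sampling grid. Amplitude-preserving; output length
# round(n * to / from).
fft_resample <- function(x, from_rate, to_rate) {
  n <- length(x)
  m <- as.integer(round(n * to_rate / from_rate))
  if (m == n) return(x)
  if (n < 2L || m < 1L) return(rep(0, max(m, 0L)))
  X <- fft(x)
  Y <- complex(length.out = m)
  nk <- min(n, m)
  kh <- (nk - 1L) %/% 2L # strictly positive bins kept per side
  Y[1:(kh + 1L)] <- X[1:(kh + 1L)]
  if (kh >= 1L) Y[(m - kh + 1L):m] <- X[(n - kh + 1L):n]
  Re(fft(Y, inverse = TRUE)) / n
}

#' Standardize a waveform to the pipeline's canonical format
#'
#' Mixes multi-channel audio to mono (channel average) and resamples to the
#' canonical 22,050 Hz rate. Resampling is Fourier-domain (band-limited
#' spectral truncation), which is exact for band-limited content; the duration
#' is preserved to within one sample period. Already-standard input passes
#' through unchanged, so the operation is idempotent.
#'
#' @param waveform Numeric vector (mono) or matrix (samples x channels).
#' @param sample_rate Input sampling rate in Hz.
#' @param target_rate Target rate in Hz; default 22,050.
#' @return A list with `waveform` (numeric vector in `[-1, 1]`) and
#'   `sample_rate` (`target_rate`).
#' @export
standardize_audio <- function(waveform, sample_rate, target_rate = 22050L) {
  stopifnot(sample_rate > 0, target_rate > 0)
  x <- if (is.matrix(waveform)) rowMeans(waveform) else as.double(waveform)
  if (sample_rate != target_rate) {
    x <- fft_resample(x, sample_rate, target_rate)
    x <- pmin(1, pmax(-1, x)) # brickwall filtering can overshoot slightly
  }
  list(waveform = x, sample_rate = as.integer(target_rate))
}

#' Construct an audio session
#'
#' Bundles one session's standardized waveform, metadata, and (optionally) its
#' per-second occurrence labels. Labels follow second-by-second partial
#' interval coding: second `k` covers the half-open sample interval
#' `[k * sr, (k + 1) * sr)` (0-based) and is marked 1 if the behavior occurred
#' during any fraction of it. Samples beyond the last full second carry no
#' label and are ignored by feature extraction.
#'
#' @param waveform Numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (22,050 after standardization).
#' @param participant_id,session_id Identifier strings.
#' @param condition `"music"` or `"no_music"`.
#' @param labels Optional integer vector in `{0, 1}`, one value per full
#'   second of audio.
#' @return An object of class `audio_session`.
#' @export
audio_session <- function(waveform, sample_rate, participant_id, session_id,
                          condition = c("no_music", "music"), labels = NULL) {
  condition <- match.arg(condition)
  stopifnot(is.numeric(waveform), length(sample_rate) == 1L, sample_rate > 0)
  n_sec <- floor(length(waveform) / sample_rate)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n_sec) {
      abort(sprintf(
        "label count (%d) does not match full seconds of audio (%d)",
        length(labels), n_sec
      ))
    }
    check_binary(labels)
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      session_id = as.character(session_id),
      waveform = as.double(waveform),
      sample_rate = as.integer(sample_rate),
      condition = condition,
      labels = labels
    ),
    class = "audio_session"
  )
}

#' @export
print.audio_session <- function(x, ...) {
  secs <- floor(length(x$waveform) / x$sample_rate)
  cat(sprintf(
    "<audio_session> %s/%s: %.1f s @ %d Hz, %s, %s\n",
    x$participant_id, x$session_id, length(x$waveform) / x$sample_rate,
    x$sample_rate, x$condition,
    if (is.null(x$labels)) "unlabelled"
    else sprintf("%d/%d s labelled positive", sum(x$labels), secs)
  ))
  invisible(x)
}

#' Number of full seconds in a session
#' @param session An [audio_session()].
#' @return Integer count of whole seconds (trailing partial second dropped).
#' @export
session_seconds <- function(session) {
  stopifnot(inherits(session, "audio_session"))
  as.integer(floor(length(session$waveform) / session$sample_rate))
}

#' Load and standardize one session from disk
#'
#' Reads a PCM WAV file, standardizes it to 22,050 Hz mono, optionally reads
#' the per-second label file, and validates label count against the number of
#' full seconds.
#'
#' @param audio_path Path to a PCM WAV file.
#' @param label_path Optional path to a label CSV (see [write_labels()]).
#' @param participant_id,session_id Identifiers; `session_id` defaults to the
#'   audio file name without extension.
#' @param condition `"music"` or `"no_music"`.
#' @return An [audio_session()].
#' @export
load_session <- function(audio_path, label_path = NULL,
                         participant_id = "unknown",
                         session_id = NULL,
                         condition = c("no_music", "music")) {
  condition <- match.arg(condition)
  if (is.null(session_id)) {
    session_id <- sub("\\.[^.]+$", "", basename(audio_path))
  }
  raw <- read_wav(audio_path)
  std <- standardize_audio(raw$waveform, raw$sample_rate)
  labels <- if (!is.null(label_path) && !is.na(label_path) && nzchar(label_path)) {
    read_labels(label_path)
  }
  audio_session(std$waveform, std$sample_rate, participant_id, session_id,
                condition = condition, labels = labels)
}

#' Read a per-second label file
#'
#' @param path CSV with columns `second_index` (0-based) and `label` (0/1).
#' @return Integer vector of labels ordered by second index.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("label file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    second_index = readr::col_integer(),
    label = readr::col_double()
  ))
  if (!all(c("second_index", "label") %in% names(df))) {
    abort(sprintf("label file %s must have columns second_index,label", path))
  }
  check_binary(df$label, what = sprintf("labels in %s", path))
  if (nrow(df) && !identical(sort(df$second_index), 0:(nrow(df) - 1L))) {
    abort(sprintf("label file %s must index seconds 0..n-1 exactly once", path))
  }
  as.integer(df$label[order(df$second_index)])
}

#' Write per-second labels to a CSV file
#'
#' One record per full second, `second_index,label`, 0-based. Round-trips
#' exactly through [read_labels()] / [load_session()].
#'
#' @param session An [audio_session()] with labels, or a bare 0/1 vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(session, path) {
  labels <- if (inherits(session, "audio_session")) {
    if (is.null(session$labels)) abort("session has no labels to write")
    session$labels
  } else {
    check_binary(as.integer(session))
  }
  df <- tibble::tibble(
    second_index = seq_along(labels) - 1L,
    label = as.integer(labels)
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' Load and validate a dataset manifest
#'
#' A manifest is a CSV associating sessions with participants and condition:
#' columns `participant_id`, `session_id`, `audio_path`, `label_path`,
#' `condition` (music / no_music), `duration_seconds`.
#'
#' @param path Manifest CSV path.
#' @param check_paths If `TRUE` (default), verify every referenced audio and
#'   label file exists; set `FALSE` for metadata-only manifests.
#' @return A validated tibble of class `dataset_manifest`.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    session_id = readr::col_character(),
    audio_path = readr::col_character(),
    label_path = readr::col_character(),
    condition = readr::col_character(),
    duration_seconds = readr::col_double()
  ))
  as_manifest(df, check_paths = check_paths, base_dir = dirname(path))
}

#' Validate a data frame as a dataset manifest
#'
#' @param df Data frame with the manifest columns (see [load_manifest()]).
#' @param check_paths Verify referenced files exist.
#' @param base_dir Directory relative paths are resolved against.
#' @return A tibble of class `dataset_manifest`.
#' @export
as_manifest <- function(df, check_paths = FALSE, base_dir = ".") {
  required <- c("participant_id", "session_id", "condition", "duration_seconds")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(sprintf("manifest is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (!"audio_path" %in% names(df)) df$audio_path <- NA_character_
  if (!"label_path" %in% names(df)) df$label_path <- NA_character_
  df <- tibble::as_tibble(df)

  dup <- duplicated(df[c("participant_id", "session_id")])
  if (any(dup)) {
    abort(sprintf(
      "duplicate (participant_id, session_id) pair(s): %s",
      paste(unique(paste(df$participant_id[dup], df$session_id[dup], sep = "/")), collapse = ", ")
    ))
  }
  bad_cond <- setdiff(unique(df$condition), c("music", "no_music"))
  if (length(bad_cond)) {
    abort(sprintf("condition must be music or no_music; found: %s", paste(bad_cond, collapse = ", ")))
  }
  if (nrow(df) && any(df$duration_seconds <= 0)) abort("duration_seconds must be positive")

  if (check_paths && nrow(df)) {
    resolve <- function(p) ifelse(is.na(p) | p == "" | grepl("^/", p), p, file.path(base_dir, p))
    paths <- c(resolve(df$audio_path), resolve(df$label_path))
    paths <- paths[!is.na(paths) & nzchar(paths)]
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files)) {
      abort(sprintf("manifest references missing file(s): %s", paste(missing_files, collapse = ", ")))
    }
  }
  class(df) <- c("dataset_manifest", class(tibble::tibble()))
  df
}

#' Summarize a manifest by participant
#'
#' Per-participant session counts and durations, split by music condition —
#' the standard dataset description table for this kind of study.
#'
#' @param manifest A `dataset_manifest` tibble.
#' @return A tibble with one row per participant: `n_sessions`,
#'   `total_seconds`, `music_seconds`, `no_music_seconds`.
#' @export
manifest_summary <- function(manifest) {
  manifest |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      total_seconds = sum(.data$duration_seconds),
      music_seconds = sum(.data$duration_seconds[.data$condition == "music"]),
      no_music_seconds = sum(.data$duration_seconds[.data$condition == "no_music"]),
      .groups = "drop"
    )
}
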