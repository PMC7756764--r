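#' Feature extraction configuration
#'
#' Each full second of audio is cut into non-overlapping 0.1-s frames and each
#' frame summarized by `n_coefficients` log mel-filterbank energies, giving
#' `frames_per_second * n_coefficients` features per second (260 under the
#' defaults: 10 frames x 26 coefficients).
#'
#' @param window_length Frame length in seconds (default 0.1).
#' @param step Frame step in seconds; equal to `window_length` by default so
#'   frames tile the second without overlap.
#' @param n_coefficients Number of mel filters / coefficients per frame (26).
#' @param fft_size FFT length in samples; frames are zero-padded to it.
#'   Default 4096, the next power of two above the 2,205-sample frame at
#'   22,050 Hz, so no frame samples are truncated.
#' @param mel_low,mel_high Filterbank edge frequencies in Hz; `mel_high`
#'   defaults to the Nyquist frequency at extraction time when `NULL`.
#' @param pre_emphasis First-order pre-emphasis coefficient applied to the
#'   waveform before framing (`y[t] = x[t] - coef * x[t-1]`); 0 disables.
#' @param log_floor Energies are clipped at this positive constant before the
#'   log so silence maps to a finite value.
#' @param cepstral If `TRUE`, apply an orthonormal DCT-II to the log energies
#'   (true cepstral coefficients); default `FALSE` returns log filterbank
#'   energies directly.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(window_length = 0.1, step = window_length,
                           n_coefficients = 26L, fft_size = 4096L,
                           mel_low = 0, mel_high = NULL,
                           pre_emphasis = 0.97, log_floor = 1e-10,
                           cepstral = FALSE) {
  stopifnot(
    window_length > 0, step > 0, n_coefficients >= 1L,
    fft_size >= 2L, mel_low >= 0, log_floor > 0,
    pre_emphasis >= 0, pre_emphasis < 1
  )
  structure(
    list(
      window_length = window_length, step = step,
      n_coefficients = as.integer(n_coefficients),
      fft_size = as.integer(fft_size),
      mel_low = mel_low, mel_high = mel_high,
      pre_emphasis = pre_emphasis, log_floor = log_floor,
      cepstral = isTRUE(cepstral)
    ),
    class = "feature_config"
  )
}

#' Mel scale conversions
#'
#' `hz_to_mel(f) = 2595 * log10(1 + f / 700)` and its inverse.
#'
#' @param hz,mel Frequencies in Hz / mel.
#' @return Numeric vector.
#' @export
hz_to_mel <- function(hz) 2595 * log10(1 + hz / 700)

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(mel) 700 * (10^(mel / 2595) - 1)

#' Triangular mel filterbank
#'
#' Builds `n_filters` triangular filters whose peaks are equally spaced on the
#' mel scale between `low` and `high`, evaluated on the non-negative FFT bins
#' of an `fft_size`-point transform. Adjacent filters overlap: each filter
#' rises from the previous filter's peak bin and falls to the next one's.
#'
#' @param n_filters Number of filters.
#' @param sample_rate Sampling rate in Hz.
#' @param fft_size FFT length in samples.
#' @param low,high Edge frequencies in Hz; `high` defaults to Nyquist.
#' @return Matrix `n_filters x (fft_size / 2 + 1)` of non-negative weights,
#'   with the peak bin index of each filter in attribute `"center_bins"` and
#'   the mel-spaced peak frequencies (Hz) in `"center_hz"`.
#' @export
mel_filterbank <- function(n_filters, sample_rate, fft_size,
                           low = 0, high = NULL) {
  high <- high %||% (sample_rate / 2)
  if (low < 0 || low >= high) abort("need 0 <= low < high")
  if (high > sample_rate / 2 + 1e-9) {
    abort(sprintf("high (%g Hz) exceeds Nyquist (%g Hz)", high, sample_rate / 2))
  }
  n_bins <- fft_size %/% 2L + 1L
  pts_mel <- seq(hz_to_mel(low), hz_to_mel(high), length.out = n_filters + 2L)
  pts_hz <- mel_to_hz(pts_mel)
  # bin index of each edge/peak point (0-based bins, python_speech_features style)
  bins <- floor((fft_size + 1L) * pts_hz / sample_rate)
  if (any(diff(bins) < 1)) {
    abort(sprintf(
      "fft_size %d gives too few bins to separate %d mel filters; increase fft_size or reduce n_filters",
      fft_size, n_filters
    ))
  }
  fb <- matrix(0, n_filters, n_bins)
  for (j in seq_len(n_filters)) {
    l <- bins[j]; c <- bins[j + 1L]; r <- bins[j + 2L]
    up <- l:c
    fb[j, up + 1L] <- (up - l) / (c - l)
    down <- c:r
    fb[j, down + 1L] <- (r - down) / (r - c)
  }
  attr(fb, "center_bins") <- bins[2:(n_filters + 1L)]
  attr(fb, "center_hz") <- pts_hz[2:(n_filters + 1L)]
  fb
}

# Orthonormal DCT-II matrix (k x n), for optional cepstral output.
dct_matrix <- function(k, n) {
  m <- outer(0:(k - 1L), 0:(n - 1L), function(i, j) cos(pi * i * (2 * j + 1) / (2 * n)))
  m * sqrt(2 / n) * ifelse(seq_len(k) == 1L, 1 / sqrt(2), 1)
}

#' Extract per-second features from a session
#'
#' Converts a standardized session waveform into the per-second feature matrix
#' fed to the classifier: each full second contributes one row built from its
#' 10 non-overlapping 0.1-s frames, each frame summarized by 26 log
#' mel-filterbank energies (260 columns under the defaults). Frames within a
#' row are laid out in temporal order, coefficients contiguous within a frame.
#'
#' @param session An [audio_session()] (or a bare numeric waveform, assumed at
#'   22,050 Hz).
#' @param config A [feature_config()].
#' @return Numeric matrix, `full_seconds x features_per_second`; 0 rows for
#'   sessions shorter than one second. Attribute `"config"` carries the
#'   configuration used.
#' @export
extract_features <- function(session, config = feature_config()) {
  if (inherits(session, "audio_session")) {
    if (session$sample_rate != 22050L) {
      abort(sprintf(
        "session sample rate is %d Hz; standardize to 22050 Hz first (see standardize_audio)",
        session$sample_rate
      ))
    }
    x <- session$waveform
    sr <- session$sample_rate
  } else {
    x <- as.double(session)
    sr <- 22050L
  }
  frame_len <- as.integer(round(config$window_length * sr))
  step_len <- as.integer(round(config$step * sr))
  frames_per_sec <- as.integer(floor((sr - frame_len) / step_len) + 1L)
  n_feat <- frames_per_sec * config$n_coefficients
  n_sec <- floor(length(x) / sr)
  if (n_sec == 0L) {
    out <- matrix(numeric(0), 0L, n_feat)
    attr(out, "config") <- config
    return(out)
  }
  if (config$fft_size < frame_len) {
    abort(sprintf("fft_size (%d) is smaller than the frame length (%d samples)",
                  config$fft_size, frame_len))
  }

  x <- x[seq_len(n_sec * sr)] # drop trailing partial second
  if (config$pre_emphasis > 0) {
    x <- c(x[1L], x[-1L] - config$pre_emphasis * x[-length(x)])
  }

  fb <- mel_filterbank(config$n_coefficients, sr, config$fft_size,
                       low = config$mel_low,
                       high = config$mel_high %||% (sr / 2))
  dct <- if (config$cepstral) dct_matrix(config$n_coefficients, config$n_coefficients)

  n_bins <- config$fft_size %/% 2L + 1L
  out <- matrix(NA_real_, n_sec, n_feat)
  block <- 64L # seconds per FFT batch, bounds the workspace

  sec0 <- 1L
  while (sec0 <= n_sec) {
    sec1 <- min(n_sec, sec0 + block - 1L)
    secs <- sec0:sec1
    # frame start sample (1-based) for every frame of every second in block
    starts <- as.vector(outer(
      (seq_len(frames_per_sec) - 1L) * step_len,
      (secs - 1L) * sr,
      "+"
    )) + 1L
    fr <- matrix(0, config$fft_size, length(starts))
    idx <- outer(0:(frame_len - 1L), starts, "+")
    fr[seq_len(frame_len), ] <- x[idx]
    spec <- stats::mvfft(fr)[seq_len(n_bins), , drop = FALSE]
    power <- (Mod(spec)^2) / config$fft_size
    energies <- fb %*% power                     # n_coefficients x frames
    coef <- log(pmax(energies, config$log_floor))
    if (!is.null(dct)) coef <- dct %*% coef
    out[secs, ] <- matrix(as.vector(coef), nrow = length(secs), byrow = TRUE)
    sec0 <- sec1 + 1L
  }
  attr(out, "config") <- config
  out
}
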