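# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: agreement statistics are recomputed from the raw
# 2x2 contingency, resampling is checked against direct windowed-sinc
# interpolation, and correlations against the covariance formula.

oracle_accuracy <- function(pred, obs) {
  agree <- 0L
  for (i in seq_along(pred)) if (pred[i] == obs[i]) agree <- agree + 1L
  agree / length(pred)
}

oracle_kappa <- function(pred, obs) {
  n <- length(pred)
  a <- b <- c_ <- d <- 0L
  for (i in seq_len(n)) {
    if (obs[i] == 1 && pred[i] == 1) a <- a + 1L
    else if (obs[i] == 1 && pred[i] == 0) b <- b + 1L
    else if (obs[i] == 0 && pred[i] == 1) c_ <- c_ + 1L
    else d <- d + 1L
  }
  p_o <- (a + d) / n
  p_e <- ((a + b) / n) * ((a + c_) / n) + ((c_ + d) / n) * ((b + d) / n)
  if (p_e >= 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Windowed-sinc interpolation of x (sampled at from_rate) onto the target
# grid; O(n * m) but only used on tiny fixtures.
oracle_sinc_resample <- function(x, from_rate, to_rate, half_width = 64L) {
  n <- length(x)
  m <- round(n * to_rate / from_rate)
  t_src <- (seq_len(n) - 1L) / from_rate
  out <- numeric(m)
  cutoff <- min(from_rate, to_rate) / 2
  for (j in seq_len(m)) {
    t <- (j - 1L) / to_rate
    centre <- t * from_rate + 1
    lo <- max(1L, floor(centre) - half_width)
    hi <- min(n, ceiling(centre) + half_width)
    idx <- lo:hi
    u <- (t - t_src[idx]) * 2 * cutoff
    w <- ifelse(u == 0, 1, sin(pi * u) / (pi * u))
    # Hann taper over the truncated kernel support
    taper <- 0.5 + 0.5 * cos(pi * (idx - centre) / (half_width + 1))
    out[j] <- sum(x[idx] * w * taper) * (2 * cutoff / from_rate)
  }
  out
}

# tiny labelled fixture session: silence with a fixed tone burst
make_fixture_session <- function(seconds = 3L, sr = 22050L, labels = NULL) {
  x <- numeric(seconds * sr)
  x[(sr + 1):(2 * sr)] <- 0.4 * sin(2 * pi * 500 * (0:(sr - 1)) / sr)
  audio_session(x, sr, "Pf", "sfix", labels = labels)
}
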