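check_pair <- function(predicted, observed, allow_empty = FALSE) {
  if (length(predicted) != length(observed)) {
    abort(sprintf("length mismatch: predicted has %d values, observed has %d",
                  length(predicted), length(observed)))
  }
  if (!allow_empty && length(predicted) == 0L) abort("vectors must be non-empty")
  invisible(NULL)
}

#' Second-by-second accuracy
#'
#' Number of seconds on which the prediction and the observation agree,
#' divided by the total number of seconds.
#'
#' @param predicted,observed Binary vectors of equal nonzero length.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(predicted, observed) {
  check_pair(predicted, observed)
  check_binary(predicted, "predicted"); check_binary(observed, "observed")
  mean(predicted == observed)
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` computed from the 2x2
#' contingency of the two vectors. Kappa controls for agreement expected by
#' chance, which matters here because most seconds are negatives: a rater
#' that marks nothing still scores high accuracy but kappa 0. When both
#' raters are constant and identical, `p_e = 1` and kappa is undefined;
#' `NA` is returned rather than an arbitrary substitute so such sessions can
#' be excluded (with counts surfaced) from downstream aggregation.
#'
#' @param predicted,observed Binary vectors of equal nonzero length.
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohens_kappa <- function(predicted, observed) {
  check_pair(predicted, observed)
  check_binary(predicted, "predicted"); check_binary(observed, "observed")
  n <- length(predicted)
  a <- sum(predicted == 1 & observed == 1)
  b <- sum(predicted == 0 & observed == 1)
  c_ <- sum(predicted == 1 & observed == 0)
  d <- sum(predicted == 0 & observed == 0)
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  if (p_e >= 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Engagement percentage
#'
#' Percent of a session's seconds labelled as occurrence: the session-level
#' duration measure (e.g. 3 occurrences in 1,000 s is 0.3).
#'
#' @param labels Binary vector of nonzero length.
#' @return Percent in `[0, 100]`.
#' @export
engagement <- function(labels) {
  if (length(labels) == 0L) abort("labels must be non-empty")
  check_binary(labels)
  100 * mean(labels)
}

#' Session-by-session correlation
#'
#' Pearson product-moment correlation between model-computed and observed
#' engagement percentages across sessions — the headline validity measure,
#' with 0.80 the conventional "strong" benchmark. `NA` when either vector is
#' constant. A Spearman option is available but Pearson is the default.
#'
#' @param predicted_percents,observed_percents Numeric vectors, one value per
#'   session, equal length `>= 2`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
session_correlation <- function(predicted_percents, observed_percents,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_pair(predicted_percents, observed_percents)
  if (length(predicted_percents) < 2L) abort("need at least 2 sessions")
  if (sd(predicted_percents) == 0 || sd(observed_percents) == 0) return(NA_real_)
  cor(predicted_percents, observed_percents, method = method)
}

#' Correlation between per-session kappa and engagement
#'
#' Diagnostic for kappa deflation: sessions with low engagement mechanically
#' yield low kappa even when the absolute engagement error is tiny (an
#' observer marking 0.3% of seconds against an all-negative prediction scores
#' kappa 0), so per-session kappa correlates positively with engagement under
#' a detector whose error rate is constant. Sessions with undefined kappa are
#' excluded; their count is attached as attribute `"n_excluded"`.
#'
#' @param per_session Tibble with columns `kappa` and `observed_engagement`
#'   (as produced by [summarize_agreement()]), or a list of such rows.
#' @param method Correlation method, default Pearson.
#' @return Correlation, or `NA` (with a diagnostic message attribute) when
#'   fewer than 2 usable sessions or zero variance.
#' @export
kappa_engagement_correlation <- function(per_session, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  df <- tibble::as_tibble(per_session)
  stopifnot(all(c("kappa", "observed_engagement") %in% names(df)))
  usable <- !is.na(df$kappa)
  n_excluded <- sum(!usable)
  df <- df[usable, ]
  out <- if (nrow(df) < 2L || sd(df$kappa) == 0 || sd(df$observed_engagement) == 0) {
    NA_real_
  } else {
    cor(df$kappa, df$observed_engagement, method = method)
  }
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Summarize agreement between predictions and observations
#'
#' Computes the full agreement picture for a set of sessions: pooled accuracy
#' and kappa over the concatenation of all test seconds, per-session results
#' (engagement percentages, accuracy, kappa), the session-by-session
#' engagement correlation, and the kappa-vs-engagement diagnostic
#' correlation. Pooled kappa is the kappa of the concatenated vectors, which
#' is not the mean of per-session kappas — low-engagement sessions deflate
#' the latter but not the former.
#'
#' @param predicted_by_session,observed_by_session Named lists of binary
#'   vectors, one element per session, with identical names and element
#'   lengths.
#' @return An object of class `agreement_summary`: list with
#'   `pooled_accuracy`, `pooled_kappa`, `session_correlation`,
#'   `kappa_engagement_correlation`, `n_kappa_undefined`, and `per_session`
#'   (tibble).
#' @export
summarize_agreement <- function(predicted_by_session, observed_by_session) {
  if (length(predicted_by_session) == 0L) abort("no sessions to summarize")
  kp <- names(predicted_by_session); ko <- names(observed_by_session)
  if (is.null(kp) || is.null(ko)) abort("session lists must be named")
  if (!setequal(kp, ko)) {
    abort(sprintf(
      "session keys differ; only in predicted: %s; only in observed: %s",
      paste(setdiff(kp, ko), collapse = ", ") %|e|% "-",
      paste(setdiff(ko, kp), collapse = ", ") %|e|% "-"
    ))
  }
  keys <- kp
  per_session <- purrr::map_dfr(keys, function(k) {
    p <- predicted_by_session[[k]]; o <- observed_by_session[[k]]
    check_pair(p, o)
    tibble::tibble(
      session_id = k,
      n_seconds = length(o),
      observed_engagement = engagement(o),
      predicted_engagement = engagement(p),
      accuracy = accuracy(p, o),
      kappa = cohens_kappa(p, o)
    )
  })
  pooled_p <- unlist(predicted_by_session[keys], use.names = FALSE)
  pooled_o <- unlist(observed_by_session[keys], use.names = FALSE)
  ke <- kappa_engagement_correlation(per_session)
  structure(
    list(
      pooled_accuracy = accuracy(pooled_p, pooled_o),
      pooled_kappa = cohens_kappa(pooled_p, pooled_o),
      session_correlation = if (length(keys) >= 2L) {
        session_correlation(per_session$predicted_engagement,
                            per_session$observed_engagement)
      } else NA_real_,
      kappa_engagement_correlation = as.numeric(ke),
      n_kappa_undefined = attr(ke, "n_excluded"),
      per_session = per_session
    ),
    class = "agreement_summary"
  )
}

`%|e|%` <- function(x, y) if (nzchar(x)) x else y

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(
    "<agreement_summary> %d session(s), %d s: accuracy %.3f, kappa %s, correlation %s\n",
    nrow(x$per_session), sum(x$per_session$n_seconds), x$pooled_accuracy,
    formatC(x$pooled_kappa, digits = 3, format = "f"),
    formatC(x$session_correlation, digits = 3, format = "f")
  ))
  invisible(x)
}

#' @export
#' @rdname summarize_agreement
#' @param x An `agreement_summary`.
#' @param ... Unused.
tidy.agreement_summary <- function(x, ...) x$per_session

#' @export
#' @rdname summarize_agreement
glance.agreement_summary <- function(x, ...) {
  tibble::tibble(
    n_sessions = nrow(x$per_session),
    n_seconds = sum(x$per_session$n_seconds),
    pooled_accuracy = x$pooled_accuracy,
    pooled_kappa = x$pooled_kappa,
    session_correlation = x$session_correlation,
    kappa_engagement_correlation = x$kappa_engagement_correlation,
    n_kappa_undefined = x$n_kappa_undefined
  )
}

#' Simulate a degraded detector over observed labels
#'
#' Applies a fixed per-second miss rate (false negatives) and false-alarm
#' rate to a ground-truth label vector, emulating a detector whose per-second
#' error rates do not depend on session engagement. Used to demonstrate the
#' kappa-deflation phenomenon.
#'
#' @param labels Binary ground-truth vector.
#' @param miss_rate Probability a positive second is predicted 0.
#' @param false_alarm_rate Probability a negative second is predicted 1.
#' @param seed Integer seed.
#' @return Integer vector of simulated predictions.
#' @export
simulate_detector <- function(labels, miss_rate = 0.3, false_alarm_rate = 0.02,
                              seed = 1L) {
  check_binary(labels)
  stopifnot(miss_rate >= 0, miss_rate <= 1, false_alarm_rate >= 0, false_alarm_rate <= 1)
  withr::with_seed(seed, {
    u <- runif(length(labels))
    ifelse(labels == 1, as.integer(u >= miss_rate), as.integer(u < false_alarm_rate))
  })
}
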