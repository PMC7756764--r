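#' Plot a training log
#'
#' Training loss and validation kappa per epoch, with the selected best epoch
#' marked.
#'
#' @param object A `trained_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trained_model <- function(object, ...) {
  if (is.null(object$training_log)) abort("model has no training log yet")
  df <- object$training_log |>
    tidyr::pivot_longer(c("train_loss", "val_kappa"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training loss and validation kappa",
                  subtitle = "dashed line: restored best-kappa epoch") +
    ggplot2::theme_minimal()
}

#' Plot predicted against observed engagement
#'
#' One point per session; the identity line marks perfect session-level
#' agreement.
#'
#' @param object An `agreement_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_session,
                  ggplot2::aes(x = .data$observed_engagement,
                               y = .data$predicted_engagement)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed engagement (%)", y = "predicted engagement (%)") +
    ggplot2::theme_minimal()
}

#' Plot protocol results
#'
#' `type = "correlation"` shows the session-by-session engagement scatter per
#' participant (the headline validity view); `type = "kappa_engagement"`
#' shows per-session kappa against observed engagement, the diagnostic for
#' kappa deflation in low-engagement sessions.
#'
#' @param object A `protocol_result`.
#' @param type Which view to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protocol_result <- function(object,
                                     type = c("correlation", "kappa_engagement"),
                                     ...) {
  type <- match.arg(type)
  ps <- object$per_session
  if (type == "correlation") {
    ggplot2::ggplot(ps, ggplot2::aes(x = .data$observed_engagement,
                                     y = .data$predicted_engagement)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
      ggplot2::geom_point() +
      ggplot2::facet_wrap(ggplot2::vars(.data$test_participant)) +
      ggplot2::labs(
        x = "observed engagement (%)", y = "predicted engagement (%)",
        title = sprintf("%s analysis: session-by-session engagement", object$analysis)
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(dplyr::filter(ps, !is.na(.data$kappa)),
                    ggplot2::aes(x = .data$observed_engagement, y = .data$kappa)) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "grey40") +
      ggplot2::facet_wrap(ggplot2::vars(.data$test_participant)) +
      ggplot2::labs(
        x = "observed engagement (%)", y = "per-session kappa",
        title = "Kappa deflation: per-session kappa vs engagement"
      ) +
      ggplot2::theme_minimal()
  }
}
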