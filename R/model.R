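#' Classifier configuration
#'
#' Configuration of the per-second classifier: a fully connected network with
#' a single 128-neuron hidden layer mapping the 260 per-second features to one
#' occurrence probability. Training minimizes class-weighted binary
#' cross-entropy with the Adam optimizer, applies dropout to the input and
#' hidden layers, and stops early when Cohen's kappa on the validation seconds
#' has not improved for `patience` consecutive epochs.
#'
#' @param n_input Number of input features per second (260).
#' @param n_hidden Hidden layer width (128).
#' @param dropout_rate Fraction of units randomly dropped in the input and
#'   hidden layers during training (0.2).
#' @param learning_rate Adam base step size (0.001, the canonical default).
#' @param patience Consecutive non-improving epochs tolerated before stopping
#'   (10).
#' @param batch_size Seconds per mini-batch (256).
#' @param max_epochs Hard cap on training epochs (500), a safety net on top of
#'   early stopping.
#' @param decision_threshold Probability at or above which a second is
#'   classified as an occurrence (0.5; ties go to 1).
#' @param seed Integer seed controlling initialization, batch shuffling, and
#'   dropout masks.
#' @param class_weighting `"inverse_prevalence"` weights each class by
#'   `n / (2 * n_class)` so the weighted class masses are equal (the
#'   correction for datasets with far more silence than stereotypy);
#'   `"none"` disables it.
#' @param restore_best If `TRUE` (default), return the parameters from the
#'   best-validation-kappa epoch rather than the last epoch.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_input = 260L, n_hidden = 128L, dropout_rate = 0.2,
                         learning_rate = 0.001, patience = 10L,
                         batch_size = 256L, max_epochs = 500L,
                         decision_threshold = 0.5, seed = 1L,
                         class_weighting = c("inverse_prevalence", "none"),
                         restore_best = TRUE) {
  class_weighting <- match.arg(class_weighting)
  if (n_input < 1L || n_hidden < 1L) abort("n_input and n_hidden must be >= 1")
  stopifnot(
    dropout_rate >= 0, dropout_rate < 1, patience >= 1L,
    decision_threshold > 0, decision_threshold < 1,
    batch_size >= 1L, max_epochs >= 1L, learning_rate > 0
  )
  structure(
    list(
      n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
      dropout_rate = dropout_rate, learning_rate = learning_rate,
      patience = as.integer(patience), batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs),
      decision_threshold = decision_threshold, seed = as.integer(seed),
      class_weighting = class_weighting, restore_best = isTRUE(restore_best)
    ),
    class = "model_config"
  )
}

#' Initialize an untrained network
#'
#' Weights are drawn uniformly on the Glorot interval
#' `[-sqrt(6 / (fan_in + fan_out)), +sqrt(6 / (fan_in + fan_out))]`, seeded by
#' `config$seed`; biases start at zero.
#'
#' @param config A [model_config()].
#' @return A list of class `trained_model` with `trained = FALSE`.
#' @export
init_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  withr::with_seed(config$seed, {
    l1 <- sqrt(6 / (config$n_input + config$n_hidden))
    l2 <- sqrt(6 / (config$n_hidden + 1))
    W1 <- matrix(runif(config$n_input * config$n_hidden, -l1, l1),
                 config$n_input, config$n_hidden)
    W2 <- matrix(runif(config$n_hidden, -l2, l2), config$n_hidden, 1L)
  })
  structure(
    list(
      W1 = W1, b1 = numeric(config$n_hidden), W2 = W2, b2 = 0,
      hidden_activation = "relu", output_activation = "sigmoid",
      config = config, trained = FALSE, training_log = NULL, best_epoch = NA_integer_
    ),
    class = "trained_model"
  )
}

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -500), 500)))

#' Forward pass: per-second occurrence probabilities
#'
#' Runs features through the network. With `training = TRUE`, inverted
#' dropout masks (rate `config$dropout_rate`) are applied to the input and
#' hidden layers, as during training; the inference path
#' (`training = FALSE`) is deterministic and needs no rescaling.
#'
#' @param model A `trained_model` (see [init_model()], [train_network()]).
#' @param features Numeric matrix, seconds x `n_input`.
#' @param training Apply dropout masks.
#' @param seed Optional seed for the dropout masks when `training = TRUE`.
#' @return Numeric vector of probabilities in `(0, 1)`, one per row.
#' @export
forward_pass <- function(model, features, training = FALSE, seed = NULL) {
  stopifnot(inherits(model, "trained_model"))
  features <- as.matrix(features)
  if (ncol(features) != nrow(model$W1)) {
    abort(sprintf("feature width mismatch: expected %d columns, got %d",
                  nrow(model$W1), ncol(features)))
  }
  run <- function() {
    X <- features
    rate <- model$config$dropout_rate
    if (training && rate > 0) {
      X <- X * (matrix(runif(length(X)), nrow(X)) >= rate) / (1 - rate)
    }
    H <- pmax(sweep(X %*% model$W1, 2L, model$b1, "+"), 0)
    if (training && rate > 0) {
      H <- H * (matrix(runif(length(H)), nrow(H)) >= rate) / (1 - rate)
    }
    as.vector(sigmoid(H %*% model$W2 + model$b2))
  }
  if (training && !is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Balancing weights for a binary label vector
#'
#' Under `"inverse_prevalence"` each class is weighted by
#' `n / (2 * n_class)`, so the total weighted mass of positive and negative
#' seconds is equal — the correction applied to the loss because sessions
#' contain far more silence than stereotypy.
#'
#' @param labels Binary vector (0/1).
#' @param scheme `"inverse_prevalence"` or `"none"`.
#' @return Named numeric vector `c(positive = , negative = )`.
#' @export
class_weights <- function(labels, scheme = c("inverse_prevalence", "none")) {
  scheme <- match.arg(scheme)
  if (length(labels) == 0L) abort("labels must be non-empty")
  check_binary(labels)
  if (scheme == "none") return(c(positive = 1, negative = 1))
  n <- length(labels)
  n_pos <- sum(labels == 1)
  n_neg <- n - n_pos
  if (n_pos == 0L || n_neg == 0L) {
    abort("cannot balance a one-class label set; merge more data before training")
  }
  c(positive = n / (2 * n_pos), negative = n / (2 * n_neg))
}

#' Train the per-second classifier
#'
#' Mini-batch gradient descent on class-weighted binary cross-entropy with the
#' Adam optimizer (beta1 = 0.9, beta2 = 0.999, eps = 1e-8). After every epoch,
#' Cohen's kappa of the thresholded predictions on the pooled validation
#' seconds is computed; training stops once kappa has not improved for
#' `config$patience` consecutive epochs (or at `config$max_epochs`), and the
#' parameters from the earliest best-kappa epoch are restored.
#'
#' @param train_features,val_features Numeric matrices, seconds x `n_input`.
#' @param train_labels,val_labels Binary vectors matching the feature rows;
#'   training labels must contain both classes.
#' @param config A [model_config()].
#' @return A `trained_model` with `training_log` (tibble: epoch, train_loss,
#'   val_kappa) and `best_epoch`.
#' @export
train_network <- function(train_features, train_labels,
                          val_features, val_labels,
                          config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  X <- as.matrix(train_features); y <- as.numeric(train_labels)
  Xv <- as.matrix(val_features); yv <- as.integer(val_labels)
  if (nrow(X) == 0L || nrow(Xv) == 0L) abort("training and validation sets must be non-empty")
  if (nrow(X) != length(y)) abort("train feature rows and label count differ")
  if (nrow(Xv) != length(yv)) abort("validation feature rows and label count differ")
  check_binary(y); check_binary(yv)
  if (ncol(X) != config$n_input) {
    abort(sprintf("feature width mismatch: expected %d columns, got %d",
                  config$n_input, ncol(X)))
  }
  cw <- class_weights(y, config$class_weighting) # errors on one-class input
  w_all <- ifelse(y == 1, cw[["positive"]], cw[["negative"]])

  model <- init_model(config)
  W1 <- model$W1; b1 <- model$b1; W2 <- model$W2; b2 <- model$b2
  adam <- list(
    m = list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = 0),
    v = list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = 0)
  )
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  rate <- config$dropout_rate
  step <- 0L

  n <- nrow(X)
  bs <- min(config$batch_size, n)
  log_epoch <- integer(0); log_loss <- numeric(0); log_kappa <- numeric(0)
  best_kappa <- -Inf; best_epoch <- NA_integer_; best_params <- NULL
  since_best <- 0L

  withr::with_seed(derive_seed(config$seed, 1L), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      n_batches <- ceiling(n / bs)
      for (b in seq_len(n_batches)) {
        idx <- ord[((b - 1L) * bs + 1L):min(b * bs, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]; wb <- w_all[idx]
        m <- length(idx)
        if (rate > 0) {
          Xb <- Xb * (matrix(runif(length(Xb)), m) >= rate) / (1 - rate)
        }
        Z1 <- sweep(Xb %*% W1, 2L, b1, "+")
        H <- pmax(Z1, 0)
        Hd <- H
        mask_h <- NULL
        if (rate > 0) {
          mask_h <- (matrix(runif(length(H)), m) >= rate) / (1 - rate)
          Hd <- H * mask_h
        }
        p <- as.vector(sigmoid(Hd %*% W2 + b2))
        pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        loss <- mean(wb * -(yb * log(pc) + (1 - yb) * log(1 - pc)))
        if (!is.finite(loss)) abort(sprintf("non-finite loss at epoch %d", epoch))
        epoch_loss <- epoch_loss + loss * m

        dz2 <- matrix(wb * (p - yb) / m, ncol = 1L)
        gW2 <- crossprod(Hd, dz2)
        gb2 <- sum(dz2)
        dH <- (dz2 %*% t(W2)) * (Z1 > 0)
        if (!is.null(mask_h)) dH <- dH * mask_h
        gW1 <- crossprod(Xb, dH)
        gb1 <- colSums(dH)

        step <- step + 1L
        upd <- function(name, g) {
          adam$m[[name]] <<- beta1 * adam$m[[name]] + (1 - beta1) * g
          adam$v[[name]] <<- beta2 * adam$v[[name]] + (1 - beta2) * g^2
          mh <- adam$m[[name]] / (1 - beta1^step)
          vh <- adam$v[[name]] / (1 - beta2^step)
          lr * mh / (sqrt(vh) + eps)
        }
        W1 <- W1 - upd("W1", gW1)
        b1 <- b1 - upd("b1", gb1)
        W2 <- W2 - upd("W2", gW2)
        b2 <- b2 - upd("b2", gb2)
      }

      model$W1 <- W1; model$b1 <- b1; model$W2 <- W2; model$b2 <- b2
      pv <- forward_pass(model, Xv)
      kv <- cohens_kappa(as.integer(pv >= config$decision_threshold), yv)
      kv_cmp <- if (is.na(kv)) -Inf else kv

      log_epoch <- c(log_epoch, epoch)
      log_loss <- c(log_loss, epoch_loss / n)
      log_kappa <- c(log_kappa, if (is.na(kv)) NA_real_ else kv)

      if (kv_cmp > best_kappa) {
        best_kappa <- kv_cmp
        best_epoch <- epoch
        best_params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
  })

  if (is.na(best_epoch)) { # every epoch had undefined validation kappa
    best_epoch <- 1L
    best_params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  if (config$restore_best) {
    model$W1 <- best_params$W1; model$b1 <- best_params$b1
    model$W2 <- best_params$W2; model$b2 <- best_params$b2
  }
  model$trained <- TRUE
  model$best_epoch <- best_epoch
  model$training_log <- tibble::tibble(
    epoch = log_epoch, train_loss = log_loss, val_kappa = log_kappa
  )
  model
}

#' Per-second binary predictions
#'
#' @param model A trained model.
#' @param features Numeric matrix, seconds x `n_input`.
#' @param threshold Probability threshold; defaults to the model's configured
#'   decision threshold. A second is labelled 1 iff its probability is `>=`
#'   the threshold (ties go to 1).
#' @return Integer vector of 0/1 labels.
#' @export
predict_labels <- function(model, features, threshold = model$config$decision_threshold) {
  p <- forward_pass(model, features, training = FALSE)
  as.integer(p >= threshold)
}

#' @export
#' @param object A `trained_model`.
#' @param newdata Feature matrix.
#' @param type `"prob"` for probabilities, `"label"` for thresholded 0/1.
#' @param ... Unused.
#' @rdname predict_labels
predict.trained_model <- function(object, newdata, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  if (type == "prob") forward_pass(object, newdata) else predict_labels(object, newdata)
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> %d-%d-1 network (%s/%s), %s\n",
    x$config$n_input, x$config$n_hidden, x$hidden_activation, x$output_activation,
    if (x$trained) {
      sprintf("trained %d epochs, best epoch %d (val kappa %.3f)",
              nrow(x$training_log), x$best_epoch,
              x$training_log$val_kappa[x$best_epoch])
    } else "untrained"
  ))
  invisible(x)
}

#' Tidy the training log of a fitted classifier
#'
#' @param x A `trained_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`, `val_kappa`.
#' @export
tidy.trained_model <- function(x, ...) {
  if (is.null(x$training_log)) {
    return(tibble::tibble(epoch = integer(0), train_loss = numeric(0), val_kappa = numeric(0)))
  }
  x$training_log
}

#' One-row summary of a fitted classifier
#'
#' @param x A `trained_model`.
#' @param ... Unused.
#' @return Tibble with `n_epochs`, `best_epoch`, `best_val_kappa`,
#'   `n_parameters`.
#' @export
glance.trained_model <- function(x, ...) {
  tibble::tibble(
    n_epochs = if (is.null(x$training_log)) 0L else nrow(x$training_log),
    best_epoch = x$best_epoch,
    best_val_kappa = if (is.null(x$training_log)) NA_real_
                     else x$training_log$val_kappa[x$best_epoch],
    n_parameters = length(x$W1) + length(x$b1) + length(x$W2) + 1L
  )
}
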