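session_table <- function(x) {
  # minimal session metadata table (participant_id, session_id, condition,
  # duration_seconds) from a manifest or feature corpus
  if (inherits(x, "feature_corpus")) {
    tibble::tibble(
      participant_id = x$participant_id, session_id = x$session_id,
      condition = x$condition, duration_seconds = x$n_seconds
    )
  } else {
    tibble::as_tibble(x)[c("participant_id", "session_id", "condition", "duration_seconds")]
  }
}

apply_music_filter <- function(sessions, music_filter) {
  if (music_filter == "no_music_only") {
    sessions <- dplyr::filter(sessions, .data$condition == "no_music")
  }
  sessions
}

sess_ref <- function(sessions) sessions[c("participant_id", "session_id")]

#' Between-participant leave-one-out split plans
#'
#' One rotation per participant: that participant's sessions form the test
#' set, the cyclic-successor participant's sessions the validation set, and
#' the remaining participants the training set. Over all rotations each
#' participant appears in the test set exactly once and in the validation set
#' exactly once, never both in the same rotation.
#'
#' @param manifest A `dataset_manifest` or `feature_corpus`.
#' @param music_filter `"all"` or `"no_music_only"` (drops music-condition
#'   sessions everywhere before splitting).
#' @return A tibble of class `split_plan`, one row per rotation, with
#'   list-columns `train`, `validation`, `test` of (participant_id,
#'   session_id) references.
#' @export
between_splits <- function(manifest, music_filter = c("all", "no_music_only")) {
  music_filter <- match.arg(music_filter)
  sessions <- apply_music_filter(session_table(manifest), music_filter)
  participants <- unique(sessions$participant_id)
  p <- length(participants)
  if (p < 3L) abort(sprintf("between-participant analysis needs >= 3 participants, got %d", p))
  plans <- purrr::map_dfr(seq_len(p), function(i) {
    test_p <- participants[i]
    val_p <- participants[i %% p + 1L]
    train_p <- setdiff(participants, c(test_p, val_p))
    tibble::tibble(
      analysis = "between", rotation_id = i,
      test_participant = test_p, music_filter = music_filter,
      train = list(sess_ref(sessions[sessions$participant_id %in% train_p, ])),
      validation = list(sess_ref(sessions[sessions$participant_id == val_p, ])),
      test = list(sess_ref(sessions[sessions$participant_id == test_p, ])),
      extra_train_seconds = list(NULL)
    )
  })
  class(plans) <- c("split_plan", class(tibble::tibble()))
  plans
}

# shared core of the within / hybrid per-session rotations
focal_rotations <- function(sessions, focal, val_fraction, seed, analysis) {
  own <- sessions[sessions$participant_id == focal, ]
  n <- nrow(own)
  if (n < 3L) {
    abort(sprintf(
      "%s analysis needs >= 3 sessions for participant %s (got %d) to form nonempty train and validation sets",
      analysis, focal, n
    ))
  }
  purrr::map_dfr(seq_len(n), function(i) {
    rest <- own[-i, ]
    ord <- withr::with_seed(derive_seed(seed, i), sample.int(nrow(rest)))
    n_val <- max(1L, round(val_fraction * nrow(rest)))
    n_val <- min(n_val, nrow(rest) - 1L) # keep train nonempty
    val_idx <- ord[seq_len(n_val)]
    tibble::tibble(
      analysis = analysis, rotation_id = i,
      test_participant = focal, music_filter = "all",
      train = list(sess_ref(rest[-val_idx, ])),
      validation = list(sess_ref(rest[val_idx, ])),
      test = list(sess_ref(own[i, ])),
      extra_train_seconds = list(NULL)
    )
  })
}

#' Within-participant leave-one-session-out split plans
#'
#' One rotation per session of the focal participant: that session is the
#' test set and the remaining sessions are shuffled (seeded) and divided into
#' training (83%) and validation (17%) sessions, with at least one validation
#' session guaranteed (`max(1, round(0.17 * n))`).
#'
#' @param manifest A `dataset_manifest` or `feature_corpus` (may contain
#'   other participants; they are ignored).
#' @param participant Focal participant id; may be omitted when the manifest
#'   holds a single participant.
#' @param train_fraction Fraction of remaining sessions used for training
#'   (default 0.83).
#' @param seed Integer seed for the per-rotation shuffles.
#' @return A `split_plan` tibble, one row per session.
#' @export
within_splits <- function(manifest, participant = NULL, train_fraction = 0.83,
                          seed = 1L) {
  sessions <- session_table(manifest)
  if (is.null(participant)) {
    participant <- unique(sessions$participant_id)
    if (length(participant) != 1L) {
      abort("manifest holds several participants; name the focal one via `participant`")
    }
  }
  plans <- focal_rotations(sessions, participant, 1 - train_fraction, seed, "within")
  class(plans) <- c("split_plan", class(tibble::tibble()))
  plans
}

#' Hybrid split plans: within-participant rotations with between-participant
#' augmentation
#'
#' As [within_splits()] but with a 67/33 train/validation division of the
#' focal participant's remaining sessions, and with the training set
#' augmented by individual seconds sampled uniformly at random (without
#' replacement, seeded) from all other participants' sessions pooled — as
#' many as the within-participant training set contains, so the final
#' training set is 50% within-participant. Validation stays purely
#' within-participant. If the other-participant pool is smaller than
#' required, sampling falls back to with-replacement with a warning.
#'
#' @param manifest A `dataset_manifest` or `feature_corpus`.
#' @param participant Focal participant id.
#' @param train_fraction Within-participant training fraction (default 0.67).
#' @param seed Integer seed.
#' @return A `split_plan` tibble with populated `extra_train_seconds`
#'   list-column (tibbles of participant_id, session_id, second_index).
#' @export
hybrid_splits <- function(manifest, participant, train_fraction = 0.67, seed = 1L) {
  sessions <- session_table(manifest)
  others <- sessions[sessions$participant_id != participant, ]
  if (nrow(others) == 0L) abort("hybrid analysis needs at least one other participant")
  plans <- focal_rotations(sessions, participant, 1 - train_fraction, seed, "hybrid")
  pool <- others |>
    dplyr::mutate(.n_sec = as.integer(floor(.data$duration_seconds))) |>
    tidyr::uncount(.data$.n_sec, .id = "second_index") |>
    dplyr::mutate(second_index = .data$second_index - 1L) |>
    dplyr::select("participant_id", "session_id", "second_index")
  plans$extra_train_seconds <- purrr::map(seq_len(nrow(plans)), function(i) {
    tr <- plans$train[[i]]
    n_within <- sum(sessions$duration_seconds[
      paste(sessions$participant_id, sessions$session_id) %in%
        paste(tr$participant_id, tr$session_id)
    ])
    replace <- nrow(pool) < n_within
    if (replace) {
      warn(sprintf(
        "other-participant pool (%d s) smaller than within-participant training set (%d s); sampling with replacement",
        nrow(pool), n_within
      ))
    }
    idx <- withr::with_seed(derive_seed(seed, c(1000L, i)),
                            sample.int(nrow(pool), n_within, replace = replace))
    pool[idx, ]
  })
  class(plans) <- c("split_plan", class(tibble::tibble()))
  plans
}

# --- protocol runner ---------------------------------------------------------

stack_sessions <- function(fc, refs) {
  key <- paste(fc$participant_id, fc$session_id)
  want <- paste(refs$participant_id, refs$session_id)
  rows <- match(want, key)
  if (anyNA(rows)) {
    abort(sprintf("sessions missing from corpus: %s",
                  paste(want[is.na(rows)], collapse = ", ")))
  }
  list(
    X = do.call(rbind, fc$features[rows]),
    y = unlist(fc$labels[rows], use.names = FALSE),
    rows = rows
  )
}

run_rotation <- function(fc, plan_row, model_cfg) {
  tr <- stack_sessions(fc, plan_row$train[[1L]])
  X_train <- tr$X; y_train <- tr$y
  extra <- plan_row$extra_train_seconds[[1L]]
  if (!is.null(extra) && nrow(extra)) {
    key <- paste(fc$participant_id, fc$session_id)
    rows <- match(paste(extra$participant_id, extra$session_id), key)
    X_extra <- do.call(rbind, purrr::map2(rows, extra$second_index,
                                          function(r, s) fc$features[[r]][s + 1L, , drop = FALSE]))
    y_extra <- purrr::map2_int(rows, extra$second_index,
                               function(r, s) fc$labels[[r]][s + 1L])
    X_train <- rbind(X_train, X_extra)
    y_train <- c(y_train, y_extra)
  }
  va <- stack_sessions(fc, plan_row$validation[[1L]])
  model <- train_network(X_train, y_train, va$X, va$y, model_cfg)

  te_refs <- plan_row$test[[1L]]
  key <- paste(fc$participant_id, fc$session_id)
  te_rows <- match(paste(te_refs$participant_id, te_refs$session_id), key)
  preds <- tibble::tibble(
    session_id = fc$session_id[te_rows],
    predicted = purrr::map(te_rows, function(r) predict_labels(model, fc$features[[r]])),
    observed = purrr::map(te_rows, function(r) as.integer(fc$labels[[r]]))
  )
  list(predictions = preds, training_log = model$training_log,
       best_epoch = model$best_epoch)
}

#' Run a full analysis protocol over a corpus
#'
#' For every rotation of the chosen analysis design: extract the plan's
#' training / validation / test seconds, compute class weights on the
#' training labels, train the classifier with kappa-based early stopping on
#' the validation seconds, predict the test seconds, and evaluate agreement.
#' Per-participant aggregates follow the analysis design: the
#' between-participant analysis yields one test unit per participant; the
#' within and hybrid analyses yield one unit per session and report
#' per-participant means across sessions, plus the session-by-session
#' engagement correlation across that participant's test sessions.
#'
#' @param corpus A `feature_corpus` (see [corpus_features()]), `corpus_plan`,
#'   or `dataset_manifest`; the latter two are featurized first.
#' @param analysis `"between"`, `"within"`, or `"hybrid"`.
#' @param model_cfg A [model_config()]; its seed is re-derived per rotation
#'   from `seed`.
#' @param config A [feature_config()] used if `corpus` must be featurized.
#' @param music_filter `"all"` or `"no_music_only"`; the music-exclusion
#'   variant applies to the between-participant analysis only and is ignored
#'   (with a warning) elsewhere.
#' @param seed Top-level integer seed; every rotation derives its own seed
#'   from it.
#' @return An object of class `protocol_result` with `per_session` (every
#'   test-session result), `aggregate` (per-participant summary), `analysis`,
#'   and `seed`.
#' @export
run_protocol <- function(corpus, analysis = c("between", "within", "hybrid"),
                         model_cfg = model_config(), config = feature_config(),
                         music_filter = c("all", "no_music_only"), seed = 1L) {
  analysis <- match.arg(analysis)
  music_filter <- match.arg(music_filter)
  if (!inherits(corpus, "feature_corpus")) corpus <- corpus_features(corpus, config)
  if (music_filter == "no_music_only" && analysis != "between") {
    warn("music exclusion applies to the between-participant analysis only; ignoring")
    music_filter <- "all"
  }

  plans <- switch(analysis,
    between = between_splits(corpus, music_filter),
    within = ,
    hybrid = {
      participants <- unique(corpus$participant_id)
      purrr::imap_dfr(participants, function(p, i) {
        pl <- if (analysis == "within") {
          within_splits(corpus, p, seed = derive_seed(seed, c(7L, i)))
        } else {
          hybrid_splits(corpus, p, seed = derive_seed(seed, c(7L, i)))
        }
        pl$rotation_id <- pl$rotation_id + 1000L * i # unique across participants
        pl
      })
    }
  )

  results <- purrr::map(seq_len(nrow(plans)), function(i) {
    cfg <- model_cfg
    cfg$seed <- derive_seed(seed, c(13L, i))
    tryCatch(
      run_rotation(corpus, plans[i, ], cfg),
      error = function(e) {
        abort(sprintf("rotation %d (test %s) failed: %s",
                      plans$rotation_id[i], plans$test_participant[i],
                      conditionMessage(e)))
      }
    )
  })

  preds <- purrr::map_dfr(seq_along(results), function(i) {
    results[[i]]$predictions |>
      dplyr::mutate(
        rotation_id = plans$rotation_id[i],
        test_participant = plans$test_participant[i],
        .before = 1L
      )
  })

  per_session <- preds |>
    dplyr::mutate(
      n_seconds = purrr::map_int(.data$observed, length),
      observed_engagement = purrr::map_dbl(.data$observed, engagement),
      predicted_engagement = purrr::map_dbl(.data$predicted, engagement),
      accuracy = purrr::map2_dbl(.data$predicted, .data$observed, accuracy),
      kappa = purrr::map2_dbl(.data$predicted, .data$observed, cohens_kappa)
    ) |>
    dplyr::select(-"predicted", -"observed")

  # per-participant aggregation: pooled measures over the participant's
  # concatenated test seconds, per-session means, and the session-level
  # correlations; identical machinery for all three analyses since each
  # test session occurs exactly once per participant
  aggregate <- purrr::map_dfr(unique(preds$test_participant), function(p) {
    rows <- preds[preds$test_participant == p, ]
    ps <- per_session[per_session$test_participant == p, ]
    pooled_p <- unlist(rows$predicted, use.names = FALSE)
    pooled_o <- unlist(rows$observed, use.names = FALSE)
    ke <- kappa_engagement_correlation(ps)
    tibble::tibble(
      participant_id = p,
      n_sessions = nrow(rows),
      accuracy = mean(ps$accuracy),
      accuracy_pooled = accuracy(pooled_p, pooled_o),
      kappa_mean = mean(ps$kappa, na.rm = TRUE),
      kappa_pooled = cohens_kappa(pooled_p, pooled_o),
      session_correlation = if (nrow(ps) >= 2L) {
        session_correlation(ps$predicted_engagement, ps$observed_engagement)
      } else NA_real_,
      kappa_engagement_correlation = as.numeric(ke),
      n_kappa_undefined = attr(ke, "n_excluded")
    )
  })

  training <- tibble::tibble(
    rotation_id = plans$rotation_id,
    test_participant = plans$test_participant,
    best_epoch = purrr::map_int(results, "best_epoch"),
    training_log = purrr::map(results, "training_log")
  )

  structure(
    list(
      analysis = analysis, music_filter = music_filter, seed = as.integer(seed),
      plans = plans, per_session = per_session, aggregate = aggregate,
      training = training
    ),
    class = "protocol_result"
  )
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s analysis (%s), seed %d: %d rotation(s), %d participant(s)\n",
              x$analysis, x$music_filter, x$seed, nrow(x$plans), nrow(x$aggregate)))
  print(x$aggregate)
  invisible(x)
}

#' Per-participant results of a protocol run
#'
#' @param x A `protocol_result`.
#' @param ... Unused.
#' @return The per-participant aggregate tibble: accuracy, kappa (pooled over
#'   the participant's concatenated test seconds), mean per-session kappa,
#'   session-by-session correlation, and the kappa-vs-engagement diagnostic.
#' @export
tidy.protocol_result <- function(x, ...) x$aggregate

#' One-row summary of a protocol run
#'
#' @param x A `protocol_result`.
#' @param ... Unused.
#' @return Tibble with participant counts and the headline aggregate
#'   measures, including how many participants reach the 0.80
#'   session-by-session correlation benchmark.
#' @export
glance.protocol_result <- function(x, ...) {
  a <- x$aggregate
  tibble::tibble(
    analysis = x$analysis,
    n_participants = nrow(a),
    n_test_sessions = sum(a$n_sessions),
    mean_accuracy = mean(a$accuracy_pooled),
    mean_kappa = mean(a$kappa_pooled, na.rm = TRUE),
    mean_correlation = mean(a$session_correlation, na.rm = TRUE),
    n_correlation_ge_80 = sum(a$session_correlation >= 0.8, na.rm = TRUE),
    n_kappa_ge_50 = sum(a$kappa_pooled >= 0.5, na.rm = TRUE)
  )
}
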