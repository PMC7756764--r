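# small synthetic manifests for split-plan checks (no audio needed)
toy_manifest <- function(n_participants, sessions_each, duration = 100L) {
  as_manifest(tidyr::expand_grid(
    participant_id = paste0("P", seq_len(n_participants)),
    session_id = sprintf("s%02d", seq_len(sessions_each))
  ) |>
    dplyr::mutate(
      audio_path = NA_character_, label_path = NA_character_,
      condition = rep_len(c("no_music", "music"), dplyr::n()),
      duration_seconds = duration
    ))
}

test_that("between-participant rotations form a test/validation permutation pair", {
  m <- toy_manifest(8, 5)
  plans <- between_splits(m)
  expect_equal(nrow(plans), 8L)
  for (i in seq_len(nrow(plans))) {
    parts <- function(x) unique(x$participant_id)
    expect_length(parts(plans$train[[i]]), 6L)
    expect_length(parts(plans$validation[[i]]), 1L)
    expect_length(parts(plans$test[[i]]), 1L)
    # no overlap inside a rotation
    expect_length(intersect(parts(plans$train[[i]]),
                            c(parts(plans$validation[[i]]), parts(plans$test[[i]]))), 0L)
    expect_false(parts(plans$validation[[i]]) == parts(plans$test[[i]]))
  }
  test_ps <- purrr::map_chr(plans$test, ~ unique(.x$participant_id))
  val_ps <- purrr::map_chr(plans$validation, ~ unique(.x$participant_id))
  expect_setequal(test_ps, paste0("P", 1:8))
  expect_setequal(val_ps, paste0("P", 1:8)) # each validates exactly once

  small <- between_splits(toy_manifest(3, 2))
  expect_equal(nrow(small), 3L)
  expect_error(between_splits(toy_manifest(2, 4)), ">= 3 participants")
})

test_that("music exclusion drops music sessions everywhere before splitting", {
  m <- toy_manifest(4, 6)
  plans <- between_splits(m, music_filter = "no_music_only")
  all_sessions <- dplyr::bind_rows(plans$train, plans$validation, plans$test)
  key <- paste(m$participant_id, m$session_id)
  conditions <- m$condition[match(paste(all_sessions$participant_id,
                                        all_sessions$session_id), key)]
  expect_true(all(conditions == "no_music"))
})

test_that("within-participant rotations split 83/17 with nonempty validation", {
  m <- toy_manifest(1, 12)
  plans <- within_splits(m, seed = 3)
  expect_equal(nrow(plans), 12L)
  for (i in seq_len(nrow(plans))) {
    expect_equal(nrow(plans$test[[i]]), 1L)
    expect_equal(nrow(plans$train[[i]]), 9L)       # 11 remaining, round(0.17*11)=2 validation
    expect_equal(nrow(plans$validation[[i]]), 2L)
    ids <- c(plans$test[[i]]$session_id, plans$train[[i]]$session_id,
             plans$validation[[i]]$session_id)
    expect_equal(sort(ids), sort(m$session_id)) # disjoint and exhaustive
  }
  # every session is the test session exactly once
  expect_setequal(purrr::map_chr(plans$test, "session_id"), m$session_id)

  tiny <- within_splits(toy_manifest(1, 3), seed = 1)
  for (i in 1:3) {
    expect_equal(nrow(tiny$train[[i]]), 1L)
    expect_equal(nrow(tiny$validation[[i]]), 1L)
  }
  expect_error(within_splits(toy_manifest(1, 2)), ">= 3 sessions")
})

test_that("hybrid training sets are half within-participant, exactly", {
  m <- toy_manifest(4, 6, duration = 50L)
  plans <- hybrid_splits(m, "P2", seed = 9)
  expect_equal(nrow(plans), 6L)
  for (i in seq_len(nrow(plans))) {
    n_within <- sum(m$duration_seconds[paste(m$participant_id, m$session_id) %in%
      paste(plans$train[[i]]$participant_id, plans$train[[i]]$session_id)])
    extra <- plans$extra_train_seconds[[i]]
    expect_equal(nrow(extra), n_within) # 50% +/- 0 by construction
    expect_true(all(extra$participant_id != "P2"))
    expect_true(all(extra$second_index >= 0 & extra$second_index < 50))
    # without replacement: no duplicated second reference
    expect_false(any(duplicated(extra)))
    # validation stays purely within-participant
    expect_true(all(plans$validation[[i]]$participant_id == "P2"))
  }
  # determinism of the sampled second sets
  plans2 <- hybrid_splits(m, "P2", seed = 9)
  expect_identical(plans$extra_train_seconds, plans2$extra_train_seconds)
  expect_false(identical(
    plans$extra_train_seconds,
    hybrid_splits(m, "P2", seed = 10)$extra_train_seconds
  ))
})

test_that("hybrid sampling with a single data-rich other participant uses it alone", {
  m <- toy_manifest(2, 6, duration = 400L)
  plans <- hybrid_splits(m, "P1", seed = 2)
  expect_true(all(purrr::map_lgl(plans$extra_train_seconds,
                                 ~ all(.x$participant_id == "P2"))))
})

test_that("hybrid falls back to replacement sampling when the pool is too small", {
  m <- toy_manifest(2, 8, duration = 60L)
  # focal has 7x60 = 420 s of potential training data; other pool = 8x60 = 480
  # shrink the other participant to force replacement
  m$duration_seconds[m$participant_id == "P2"] <- 20L
  warnings <- capture_warnings(plans <- hybrid_splits(m, "P1", seed = 4))
  expect_true(length(warnings) > 0 && all(grepl("replacement", warnings)))
  expect_true(any(duplicated(plans$extra_train_seconds[[1]])))
})

test_that("no test second leaks into train or validation of its rotation", {
  cp <- generate_corpus(3, 4, session_duration = 40, seed = 77)
  fc <- suppressWarnings(corpus_features(cp))
  for (analysis in c("between", "within", "hybrid")) {
    plans <- switch(analysis,
      between = between_splits(fc),
      within = within_splits(fc, "P1", seed = 1),
      hybrid = hybrid_splits(fc, "P1", seed = 1)
    )
    for (i in seq_len(nrow(plans))) {
      test_keys <- paste(plans$test[[i]]$participant_id, plans$test[[i]]$session_id)
      other <- dplyr::bind_rows(plans$train[[i]], plans$validation[[i]],
                                plans$extra_train_seconds[[i]])
      expect_length(intersect(test_keys,
                              paste(other$participant_id, other$session_id)), 0L)
    }
  }
})

test_that("run_protocol yields the designed number of units and aggregates", {
  cp <- generate_corpus(3, 4, session_duration = 40, seed = 5)
  fc <- suppressWarnings(corpus_features(cp))
  cfg <- model_config(patience = 3L, max_epochs = 30L)

  between <- run_protocol(fc, "between", model_cfg = cfg, seed = 5)
  expect_equal(nrow(between$aggregate), 3L)            # one unit per participant
  expect_equal(nrow(between$per_session), 12L)         # every session tested once
  expect_setequal(between$aggregate$participant_id, paste0("P", 1:3))

  within <- run_protocol(fc, "within", model_cfg = cfg, seed = 5)
  expect_equal(nrow(within$per_session), 12L)          # one unit per session
  expect_equal(within$aggregate$n_sessions, rep(4L, 3))
  # reported value is the mean across that participant's rotations
  p1 <- within$per_session[within$per_session$test_participant == "P1", ]
  expect_equal(within$aggregate$accuracy[within$aggregate$participant_id == "P1"],
               mean(p1$accuracy))

  expect_warning(run_protocol(fc, "within", model_cfg = cfg,
                              music_filter = "no_music_only", seed = 5),
                 "between-participant analysis only")

  g <- glance(between)
  expect_named(g, c("analysis", "n_participants", "n_test_sessions",
                    "mean_accuracy", "mean_kappa", "mean_correlation",
                    "n_correlation_ge_80", "n_kappa_ge_50"))
})

test_that("protocol runs are reproducible end-to-end under one seed", {
  cp <- generate_corpus(3, 3, session_duration = 30, seed = 8)
  fc <- suppressWarnings(corpus_features(cp))
  cfg <- model_config(patience = 2L, max_epochs = 15L)
  r1 <- run_protocol(fc, "between", model_cfg = cfg, seed = 4)
  r2 <- run_protocol(fc, "between", model_cfg = cfg, seed = 4)
  expect_identical(r1$per_session, r2$per_session)
  expect_identical(r1$aggregate, r2$aggregate)
  expect_identical(r1$training$training_log, r2$training$training_log)
})
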