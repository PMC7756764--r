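test_that("vocal events are seeded, harmonic, and spectrally placed", {
  p <- vocal_profile("P1", f0_low = 200, f0_high = 300, formant_center = 1000)
  e1 <- synth_vocal_event(p, 0.5, seed = 4)
  e2 <- synth_vocal_event(p, 0.5, seed = 4)
  expect_identical(e1, e2)
  expect_false(identical(e1, synth_vocal_event(p, 0.5, seed = 5)))

  # FFT peak-pick oracle: fundamental lies inside the profile's f0 range
  for (s in 1:5) {
    ev <- synth_vocal_event(p, 1.0, seed = s)
    spec <- abs(fft(ev))[1:(length(ev) %/% 2)]
    freqs <- (seq_along(spec) - 1) * 22050 / length(ev)
    # lowest prominent spectral peak = fundamental
    cand <- freqs[spec > 0.3 * max(spec)]
    f0 <- min(cand[cand > 50])
    expect_gte(f0, p$f0_low * 0.95)
    expect_lte(f0, p$f0_high * 1.05)
  }

  # zero harmonics above the fundamental: energy concentrated at one peak
  pure <- vocal_profile("P1", f0_low = 200, f0_high = 300, harmonic_count = 0L,
                        formant_center = 250)
  ev <- synth_vocal_event(pure, 1.0, seed = 9)
  spec <- abs(fft(ev))[1:(length(ev) %/% 2)]
  peak_band <- sum(spec[spec > 0.05 * max(spec)]^2)
  expect_gt(peak_band / sum(spec^2), 0.98)
})

test_that("event placement respects targets including zero", {
  p <- default_profiles(1)
  expect_equal(nrow(place_events(100, 0, p, seed = 1)), 0L)
  expect_identical(place_events(200, 30, p, seed = 2),
                   place_events(200, 30, p, seed = 2))
  ev <- place_events(200, 30, p, seed = 2)
  expect_true(all(ev$onset >= 0 & ev$onset < 200))
  expect_true(all(ev$onset + ev$duration <= 200 + 1e-9))
  # events do not overlap (renewal construction)
  if (nrow(ev) > 1) expect_true(all(diff(ev$onset) > ev$duration[-nrow(ev)] - 1e-9))
})

test_that("realized engagement tracks the target for 300-s sessions", {
  p <- default_profiles(1)
  for (tgt in c(10, 25, 40, 60)) {
    realized <- sapply(1:5, function(s) {
      100 * mean(events_to_labels(place_events(300, tgt, p, seed = 1000 + s), 300))
    })
    expect_lt(abs(mean(realized) - tgt), 5)   # unbiased across seeds
    expect_true(all(abs(realized - tgt) < 10)) # and individually close
  }
})

test_that("labels follow the partial-interval rule exactly", {
  ev <- tibble::tibble(onset = 2.4, duration = 0.2) # spans 2.4-2.6 s
  expect_equal(events_to_labels(ev, 4), c(0L, 0L, 1L, 0L))
  ev2 <- tibble::tibble(onset = c(0.9, 2.0), duration = c(0.2, 1.0))
  expect_equal(events_to_labels(ev2, 4), c(1L, 1L, 1L, 0L)) # 0.9-1.1 touches 0 and 1
  # boundary case: event ending exactly on a second boundary does not spill over
  ev3 <- tibble::tibble(onset = 1.0, duration = 1.0)
  expect_equal(events_to_labels(ev3, 3), c(0L, 1L, 0L))
})

test_that("synthesized sessions carry ground-truth labels and sane audio", {
  p <- default_profiles(2)[1, ]
  spec <- session_spec(40, "no_music", target_engagement = 30)
  s <- synth_session(p, spec, seed = 3, session_id = "t1")
  expect_s3_class(s, "audio_session")
  expect_equal(session_seconds(s), 40L)
  expect_length(s$labels, 40L)
  expect_true(all(abs(s$waveform) <= 1))
  expect_equal(attr(s, "realized_engagement"), 100 * mean(s$labels))
  # determinism
  s2 <- synth_session(p, spec, seed = 3, session_id = "t1")
  expect_identical(s$waveform, s2$waveform)
  expect_identical(s$labels, s2$labels)

  # zero target: pure noise, all labels zero
  s0 <- synth_session(p, session_spec(30, "no_music", target_engagement = 0), seed = 4)
  expect_equal(sum(s0$labels), 0L)
  expect_lt(sqrt(mean(s0$waveform^2)), 0.1) # noise floor only

  # music condition raises signal energy relative to plain noise
  sm <- synth_session(p, session_spec(30, "music", target_engagement = 0), seed = 4)
  expect_gt(sqrt(mean(sm$waveform^2)), sqrt(mean(s0$waveform^2)))
})

test_that("corpus plans enumerate sessions, stay distinct, and reproduce", {
  cp <- generate_corpus(8, 10, session_duration = 120, seed = 6)
  expect_equal(nrow(cp$sessions), 80L)
  expect_equal(dplyr::n_distinct(cp$sessions$participant_id), 8L)
  # profiles pairwise distinct in (f0 range, formant)
  key <- paste(cp$profiles$f0_low, cp$profiles$f0_high, cp$profiles$formant_center)
  expect_false(any(duplicated(key)))
  # same top-level seed: identical realized audio
  cp2 <- generate_corpus(8, 10, session_duration = 120, seed = 6)
  s1 <- realize_session(cp, "P3", "s02")
  s2 <- realize_session(cp2, "P3", "s02")
  expect_identical(s1$waveform, s2$waveform)
  expect_identical(s1$labels, s2$labels)
  expect_error(realize_session(cp, "P9", "s01"), "not in corpus plan")
})

test_that("written corpora round-trip through the manifest loader", {
  dir <- withr::local_tempdir()
  cp <- generate_corpus(2, 3, session_duration = 30,
                        schedule = tibble::tibble(
                          condition = c("no_music", "music", "no_music"),
                          target_engagement = c(30, 10, 50)
                        ),
                        seed = 12)
  manifest <- write_corpus(cp, dir)
  expect_equal(nrow(manifest), 6L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  # reload one session from disk: labels identical, audio within quantization
  s_mem <- realize_session(cp, "P1", "s01")
  s_disk <- load_session(file.path(dir, "P1_s01.wav"),
                         file.path(dir, "P1_s01_labels.csv"),
                         participant_id = "P1", condition = "no_music")
  expect_identical(s_disk$labels, s_mem$labels)
  expect_lt(max(abs(s_disk$waveform - s_mem$waveform)), 1 / 32767)
  expect_error(write_corpus(cp, dir), "refusing to overwrite")

  # feature corpora from plan and from disk agree up to PCM quantization
  fc_mem <- corpus_features(cp)
  fc_disk <- corpus_features(load_manifest(file.path(dir, "manifest.csv")),
                             base_dir = dir)
  expect_equal(fc_mem$n_seconds, fc_disk$n_seconds)
  expect_identical(fc_mem$labels, fc_disk$labels)
  expect_equal(fc_mem$features[[1]], fc_disk$features[[1]], tolerance = 0.05)
})

test_that("music overlay makes within-participant detection no easier", {
  # same events and SNR, music on vs off; a fixed small classifier should do
  # at least as well without music (trend over a few seeds, not per-seed)
  p <- default_profiles(1)
  deltas <- sapply(1:3, function(seed) {
    kappas <- sapply(c("no_music", "music"), function(cond) {
      sessions <- lapply(1:4, function(i) {
        synth_session(p, session_spec(30, cond, target_engagement = 35),
                      seed = derive_seed(seed, i), session_id = paste0("s", i))
      })
      feats <- lapply(sessions, extract_features)
      labs <- lapply(sessions, function(s) s$labels)
      cfg <- model_config(patience = 3L, max_epochs = 25L, seed = seed)
      m <- train_network(do.call(rbind, feats[1:2]), unlist(labs[1:2]),
                         feats[[3]], labs[[3]], cfg)
      k <- cohens_kappa(predict_labels(m, feats[[4]]), labs[[4]])
      if (is.na(k)) 0 else k
    })
    kappas[["no_music"]] - kappas[["music"]]
  })
  expect_gte(mean(deltas), 0)
})
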