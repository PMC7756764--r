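#' Vocal profile of a synthetic participant
#'
#' Parameters of one participant's simulated vocal events: a harmonic stack
#' at a fundamental drawn from `f0_range`, band-emphasized near
#' `formant_center`, with log-normally distributed event durations. Distinct
#' profiles across participants emulate the heterogeneity of real vocal
#' stereotypy (humming, monosyllables, word repetitions differ in pitch,
#' timbre, and event length).
#'
#' @param participant_id Identifier string.
#' @param f0_low,f0_high Fundamental frequency range in Hz, within (50, 1000).
#' @param harmonic_count Number of harmonics above the fundamental.
#' @param formant_center Spectral emphasis center in Hz.
#' @param event_meanlog,event_sdlog Log-normal parameters of event duration in
#'   seconds; the median `exp(event_meanlog)` must lie in `[0.3, 3]` s.
#' @param amplitude_db Event RMS relative to the background noise RMS, in dB.
#' @return A one-row tibble of class `vocal_profile`.
#' @export
vocal_profile <- function(participant_id, f0_low = 150, f0_high = 400,
                          harmonic_count = 10L, formant_center = 1200,
                          event_meanlog = log(0.8), event_sdlog = 0.4,
                          amplitude_db = 15) {
  stopifnot(
    f0_low > 50, f0_high < 1000, f0_low < f0_high,
    harmonic_count >= 0L, formant_center > 0,
    exp(event_meanlog) >= 0.3, exp(event_meanlog) <= 3, event_sdlog >= 0
  )
  out <- tibble::tibble(
    participant_id = as.character(participant_id),
    f0_low = f0_low, f0_high = f0_high,
    harmonic_count = as.integer(harmonic_count),
    formant_center = formant_center,
    event_meanlog = event_meanlog, event_sdlog = event_sdlog,
    amplitude_db = amplitude_db
  )
  class(out) <- c("vocal_profile", class(out))
  out
}

#' Default spread of distinct vocal profiles
#'
#' Produces `n` pairwise-distinct profiles with fundamentals, formant centers,
#' and event-duration statistics spread across plausible child-vocalization
#' ranges, so participants are acoustically distinguishable.
#'
#' @param n Number of participants.
#' @param amplitude_db Event-to-background level in dB applied to every
#'   profile (default +15).
#' @return A tibble with one `vocal_profile` row per participant
#'   (`participant_id` values `"P1" ... "Pn"`).
#' @export
default_profiles <- function(n = 8L, amplitude_db = 15) {
  stopifnot(n >= 1L)
  purrr::map_dfr(seq_len(n), function(i) {
    f0_low <- if (n == 1L) 160 else 110 + (i - 1) * 220 / (n - 1)
    vocal_profile(
      participant_id = paste0("P", i),
      f0_low = f0_low, f0_high = f0_low + 90,
      harmonic_count = 8L + (i - 1L) %% 5L,
      formant_center = if (n == 1L) 1200 else 600 + (i - 1) * 2200 / (n - 1),
      event_meanlog = log(if (n == 1L) 0.8 else 0.5 + (i - 1) * 0.9 / (n - 1)),
      event_sdlog = 0.4,
      amplitude_db = amplitude_db
    )
  })
}

#' Session specification for the generator
#'
#' @param duration Session length in seconds (`>= 30`; default 120).
#' @param condition `"music"` or `"no_music"`.
#' @param target_engagement Target percent of seconds containing an event, in
#'   `[0, 80]`.
#' @param noise_floor Background (pink noise) RMS in dB full scale (RMS 1.0 =
#'   0 dB); default -30.
#' @param music_gain Music RMS relative to the noise RMS in dB (music
#'   condition only); default +5.
#' @param music_pattern_seed Seed fixing the music's note pattern. Treatment
#'   sessions play a child's preferred music, so the same pattern recurs
#'   across a participant's sessions; set one value per participant (as
#'   [generate_corpus()] does) to emulate that. `NULL` derives it from the
#'   session seed, giving session-unique music.
#' @return A list of class `session_spec`.
#' @export
session_spec <- function(duration = 120, condition = c("no_music", "music"),
                         target_engagement = 30, noise_floor = -30,
                         music_gain = 5, music_pattern_seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(duration >= 30, target_engagement >= 0, target_engagement <= 80)
  structure(
    list(
      duration = duration, condition = condition,
      target_engagement = target_engagement,
      noise_floor = noise_floor, music_gain = music_gain,
      music_pattern_seed = music_pattern_seed
    ),
    class = "session_spec"
  )
}

#' Place vocal events by a calibrated renewal process
#'
#' Events with log-normal durations alternate with exponential gaps whose
#' mean is calibrated so the expected fraction of *labelled* seconds matches
#' `target_engagement`. Under partial-interval coding a second stays
#' unlabelled only if it falls entirely inside a gap, which for a stationary
#' alternating renewal process with exponential gaps (mean `g`) and mean
#' event duration `E[d]` has probability `g * exp(-1/g) / (E[d] + g)`; the
#' gap mean solving `1 - that = target` is found by root-finding, so the
#' calibration stays accurate even at high duty cycles where events crowd
#' into shared seconds.
#'
#' @param duration Session length in seconds.
#' @param target_engagement Target percent of labelled seconds.
#' @param profile A [vocal_profile()] row (supplies duration statistics).
#' @param seed Integer seed.
#' @return Tibble with columns `onset` and `duration` (seconds); zero rows
#'   when the target is 0.
#' @export
place_events <- function(duration, target_engagement, profile, seed = 1L) {
  stopifnot(duration > 0, target_engagement >= 0, target_engagement <= 100)
  if (target_engagement == 0) {
    return(tibble::tibble(onset = numeric(0), duration = numeric(0)))
  }
  ed <- exp(profile$event_meanlog + profile$event_sdlog^2 / 2)
  f <- target_engagement / 100
  # expected unlabelled fraction g*exp(-1/g)/(ed+g) must equal 1 - f
  resid <- function(g) g * exp(-1 / g) - (1 - f) * (ed + g)
  gap_mean <- if (resid(0.05) >= 0) 0.05 else {
    stats::uniroot(resid, c(0.05, 1e6), tol = 1e-9)$root
  }
  withr::with_seed(seed, {
    onsets <- numeric(0); durs <- numeric(0)
    t <- rexp(1L, 1 / gap_mean) * 0.5 # shorter lead-in than steady-state gaps
    while (t < duration) {
      d <- rlnorm(1L, profile$event_meanlog, profile$event_sdlog)
      d <- min(d, duration - t)
      onsets <- c(onsets, t); durs <- c(durs, d)
      t <- t + d + rexp(1L, 1 / gap_mean)
    }
  })
  tibble::tibble(onset = onsets, duration = durs)
}

#' Per-second labels implied by a set of events
#'
#' Partial-interval rule: second `k` (0-based, covering `[k, k + 1)` s) is
#' labelled 1 iff any event overlaps it for any fraction of the second.
#'
#' @param events Tibble with `onset` and `duration` columns (seconds).
#' @param n_seconds Number of whole seconds in the session.
#' @return Integer 0/1 vector of length `n_seconds`.
#' @export
events_to_labels <- function(events, n_seconds) {
  labels <- integer(n_seconds)
  for (i in seq_len(nrow(events))) {
    s <- events$onset[i]; e <- s + events$duration[i]
    if (e <= s) next
    first <- floor(s)
    last <- min(ceiling(e) - 1, n_seconds - 1)
    if (first > n_seconds - 1) next
    labels[(first:last) + 1L] <- 1L
  }
  labels
}

# Pink (1/f) background noise, unit RMS: white noise shaped by the standard
# third-order IIR approximation.
pink_noise <- function(n) {
  w <- rnorm(n + 500L)
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(-2.494956002, 2.017265875, -0.522189400)
  ma <- stats::filter(w, b, method = "convolution", sides = 1L)
  ma[is.na(ma)] <- 0
  x <- as.numeric(stats::filter(ma, -a, method = "recursive"))
  x <- x[(length(x) - n + 1L):length(x)] # drop filter warm-up
  x / sqrt(mean(x^2))
}

#' Synthesize one vocal event waveform
#'
#' A harmonic stack at a fundamental drawn uniformly from the profile's f0
#' range, with slow random vibrato, harmonic amplitudes emphasized near the
#' profile's formant center, and a raised-cosine attack/decay envelope.
#' Output has unit RMS (scaled by the caller).
#'
#' @param profile A [vocal_profile()] row.
#' @param duration Event duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return Numeric waveform vector of length `round(duration * sample_rate)`.
#' @export
synth_vocal_event <- function(profile, duration, sample_rate = 22050L, seed = 1L) {
  stopifnot(duration > 0)
  n <- max(8L, as.integer(round(duration * sample_rate)))
  withr::with_seed(seed, {
    f0 <- runif(1L, profile$f0_low, profile$f0_high)
    vib_rate <- runif(1L, 4, 7)
    vib_depth <- runif(1L, 0.01, 0.04)
    vib_phase <- runif(1L, 0, 2 * pi)
    t <- (seq_len(n) - 1L) / sample_rate
    inst_f <- f0 * (1 + vib_depth * sin(2 * pi * vib_rate * t + vib_phase))
    phase <- 2 * pi * cumsum(inst_f) / sample_rate
    h_max <- profile$harmonic_count + 1L
    phases <- runif(h_max, 0, 2 * pi)
    x <- numeric(n)
    for (h in seq_len(h_max)) {
      amp <- exp(-0.5 * ((h * f0 - profile$formant_center) / 700)^2) + 0.25 / h
      x <- x + amp * sin(h * phase + phases[h])
    }
  })
  ramp <- max(4L, min(as.integer(0.03 * sample_rate), n %/% 4L))
  env <- rep(1, n)
  up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
  env[seq_len(ramp)] <- up
  env[(n - ramp + 1L):n] <- rev(up)
  x <- x * env
  x / sqrt(mean(x^2))
}

# Music surrogate: several harmonic voices with periodic note onsets (no real
# recordings needed). The note pattern — voice count, pitches, octave — is
# drawn from `pattern_seed`, kept constant across a participant's sessions to
# emulate the same preferred music recurring in every treatment session;
# `seed` varies only the session's starting point in the pattern and the
# note phases. Unit RMS.
synth_music <- function(duration, sample_rate = 22050L, seed = 1L,
                        pattern_seed = seed) {
  n <- as.integer(round(duration * sample_rate))
  pentatonic <- c(220.0, 246.9, 293.7, 329.6, 392.0, 440.0, 493.9, 587.3)
  withr::with_seed(pattern_seed, {
    n_voices <- sample(3:5, 1L)
    octave <- sample(c(0.5, 1, 2), 1L)
    patterns <- lapply(seq_len(n_voices), function(v) {
      sample(pentatonic, 4L, replace = TRUE) * octave
    })
  })
  withr::with_seed(seed, {
    start_note <- sample.int(4L, 1L) - 1L # where in the pattern this session starts
    phase0 <- runif(1L, 0, 2 * pi)
  })
  x <- numeric(n)
  note_len <- as.integer(0.45 * sample_rate)
  onset_step <- 0.5 # seconds between note onsets
  decay <- exp(-3 * seq_len(note_len) / note_len)
  for (v in seq_len(n_voices)) {
    pattern <- patterns[[v]]
    offset <- (v - 1L) * onset_step / n_voices
    k <- 0L
    repeat {
      t0 <- offset + k * onset_step
      i0 <- as.integer(round(t0 * sample_rate))
      if (i0 >= n) break
      f <- pattern[((k + start_note) %% length(pattern)) + 1L]
      len <- min(note_len, n - i0)
      tt <- seq_len(len) / sample_rate
      note <- (sin(2 * pi * f * tt + phase0) + 0.5 * sin(4 * pi * f * tt + phase0) +
                 0.25 * sin(6 * pi * f * tt + phase0)) * decay[seq_len(len)]
      x[(i0 + 1L):(i0 + len)] <- x[(i0 + 1L):(i0 + len)] + note
      k <- k + 1L
    }
  }
  x / sqrt(mean(x^2))
}

#' Synthesize a labelled session
#'
#' Background pink noise at `noise_floor`, vocal events placed by
#' [place_events()] and scaled `amplitude_db` above the noise RMS, optionally
#' an overlaid music surrogate at `music_gain` above the noise, and
#' ground-truth partial-interval labels derived from the exact event times.
#'
#' @param profile A [vocal_profile()] row.
#' @param spec A [session_spec()].
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed; all randomness derives from it.
#' @param participant_id,session_id Identifiers for the resulting session;
#'   default to the profile's participant and `"s1"`.
#' @return An [audio_session()] with labels; the realized engagement percent
#'   is attached as attribute `"realized_engagement"`.
#' @export
synth_session <- function(profile, spec, sample_rate = 22050L, seed = 1L,
                          participant_id = profile$participant_id,
                          session_id = "s1") {
  stopifnot(inherits(spec, "session_spec"))
  n <- as.integer(round(spec$duration * sample_rate))
  n_sec <- as.integer(floor(spec$duration))

  events <- place_events(spec$duration, spec$target_engagement, profile,
                         seed = derive_seed(seed, 1L))
  labels <- events_to_labels(events, n_sec)
  if (spec$target_engagement > 0 && nrow(events) == 0L) {
    warn(sprintf(
      "no events could be placed for target engagement %.1f%%; realized engagement is 0",
      spec$target_engagement
    ))
  }

  noise_rms <- db_to_amp(spec$noise_floor)
  x <- withr::with_seed(derive_seed(seed, 2L), pink_noise(n)) * noise_rms

  event_rms <- noise_rms * db_to_amp(profile$amplitude_db)
  for (i in seq_len(nrow(events))) {
    ev <- synth_vocal_event(profile, events$duration[i], sample_rate,
                            seed = derive_seed(seed, 10L + i))
    i0 <- as.integer(round(events$onset[i] * sample_rate))
    len <- min(length(ev), n - i0)
    if (len <= 0L) next
    x[(i0 + 1L):(i0 + len)] <- x[(i0 + 1L):(i0 + len)] + ev[seq_len(len)] * event_rms
  }

  if (spec$condition == "music") {
    mus <- synth_music(spec$duration, sample_rate, seed = derive_seed(seed, 3L),
                       pattern_seed = spec$music_pattern_seed %||% derive_seed(seed, 4L))
    x <- x + mus * noise_rms * db_to_amp(spec$music_gain)
  }

  x <- pmin(1, pmax(-1, x))
  out <- audio_session(x, sample_rate, participant_id, session_id,
                       condition = spec$condition, labels = labels)
  attr(out, "realized_engagement") <- if (n_sec > 0) 100 * mean(labels) else NA_real_
  out
}

#' Default per-session engagement schedule
#'
#' Mixes higher-engagement no-music sessions (emulating baseline) with
#' low-engagement music sessions (emulating noncontingent-music treatment),
#' including near-zero-engagement sessions that exercise the kappa-deflation
#' regime.
#'
#' @param n Sessions per participant.
#' @return Tibble with columns `condition` and `target_engagement`.
#' @export
default_engagement_schedule <- function(n = 10L) {
  stopifnot(n >= 1L)
  n_nm <- ceiling(n / 2)
  n_m <- n - n_nm
  nm <- tibble::tibble(
    condition = "no_music",
    target_engagement = if (n_nm == 1L) 45 else seq(20, 65, length.out = n_nm)
  )
  m <- if (n_m > 0L) {
    tibble::tibble(
      condition = "music",
      target_engagement = if (n_m == 1L) 5 else seq(0.5, 16, length.out = n_m)
    )
  }
  dplyr::bind_rows(nm, m)
}

#' Generate a synthetic corpus plan
#'
#' Builds the deterministic plan for a labelled corpus: one distinct
#' [vocal_profile()] per participant and, per participant, the sessions of
#' `schedule` with a derived per-session seed. Sessions are synthesized
#' lazily — [realize_session()] reconstructs any session's audio and labels
#' bit-identically from the plan, [write_corpus()] materializes WAV/CSV files,
#' and [corpus_features()] streams straight to the feature representation.
#'
#' @param n_participants,sessions_per_participant Corpus dimensions.
#' @param session_duration Seconds per session (default 120).
#' @param schedule Per-session `condition` / `target_engagement` tibble (one
#'   row per session of each participant); defaults to
#'   [default_engagement_schedule()].
#' @param profiles Profile tibble; defaults to [default_profiles()] at
#'   +15 dB event level.
#' @param noise_floor,music_gain Session acoustics (see [session_spec()]).
#' @param seed Top-level integer seed; per-session seeds derive from it.
#' @return A list of class `corpus_plan` with `profiles`, `sessions` (tibble:
#'   participant_id, session_id, condition, target_engagement,
#'   duration_seconds, session_seed), `sample_rate`, and `seed`.
#' @export
generate_corpus <- function(n_participants = 8L, sessions_per_participant = 10L,
                            session_duration = 120,
                            schedule = default_engagement_schedule(sessions_per_participant),
                            profiles = default_profiles(n_participants),
                            noise_floor = -30, music_gain = 5, seed = 1L) {
  stopifnot(n_participants >= 1L, sessions_per_participant >= 1L,
            nrow(schedule) == sessions_per_participant,
            nrow(profiles) == n_participants)
  sessions <- tidyr::expand_grid(
    participant_id = profiles$participant_id,
    session_index = seq_len(sessions_per_participant)
  ) |>
    dplyr::mutate(
      session_id = sprintf("s%02d", .data$session_index),
      condition = schedule$condition[.data$session_index],
      target_engagement = schedule$target_engagement[.data$session_index],
      duration_seconds = session_duration,
      session_seed = purrr::map2_int(
        match(.data$participant_id, profiles$participant_id),
        .data$session_index,
        function(p, s) derive_seed(seed, c(p, s))
      ),
      # one music pattern per participant: preferred music recurs across
      # that child's treatment sessions
      music_pattern_seed = purrr::map_int(
        match(.data$participant_id, profiles$participant_id),
        function(p) derive_seed(seed, c(p, 0L))
      )
    ) |>
    dplyr::select(-"session_index")
  structure(
    list(
      profiles = profiles, sessions = sessions,
      sample_rate = 22050L, noise_floor = noise_floor, music_gain = music_gain,
      seed = as.integer(seed)
    ),
    class = "corpus_plan"
  )
}

#' @export
print.corpus_plan <- function(x, ...) {
  cat(sprintf(
    "<corpus_plan> %d participant(s) x %d session(s), %g s each (seed %d)\n",
    nrow(x$profiles), nrow(x$sessions) / nrow(x$profiles),
    x$sessions$duration_seconds[1], x$seed
  ))
  invisible(x)
}

#' Reconstruct one session of a corpus plan
#'
#' @param corpus A `corpus_plan` from [generate_corpus()].
#' @param participant_id,session_id Which session to synthesize.
#' @return The [audio_session()], bit-identical across calls.
#' @export
realize_session <- function(corpus, participant_id, session_id) {
  stopifnot(inherits(corpus, "corpus_plan"))
  row <- corpus$sessions |>
    dplyr::filter(.data$participant_id == !!participant_id,
                  .data$session_id == !!session_id)
  if (nrow(row) != 1L) {
    abort(sprintf("session %s/%s not in corpus plan", participant_id, session_id))
  }
  profile <- corpus$profiles[corpus$profiles$participant_id == participant_id, ]
  spec <- session_spec(
    duration = row$duration_seconds, condition = row$condition,
    target_engagement = row$target_engagement,
    noise_floor = corpus$noise_floor, music_gain = corpus$music_gain,
    music_pattern_seed = row$music_pattern_seed
  )
  synth_session(profile, spec, corpus$sample_rate, seed = row$session_seed,
                participant_id = participant_id, session_id = session_id)
}

#' Materialize a corpus plan as WAV, label, and manifest files
#'
#' Writes `<participant>_<session>.wav` and `..._labels.csv` per session plus
#' `manifest.csv`, the standard on-disk exchange format of the pipeline.
#'
#' @param corpus A `corpus_plan`.
#' @param dir Output directory (created if needed); must not already contain
#'   a manifest.
#' @return The validated `dataset_manifest` tibble, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "corpus_plan"))
  if (file.exists(file.path(dir, "manifest.csv"))) {
    abort(sprintf("%s already contains a manifest.csv; refusing to overwrite", dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::pmap_dfr(corpus$sessions, function(participant_id, session_id,
                                                    condition, duration_seconds, ...) {
    sess <- realize_session(corpus, participant_id, session_id)
    stem <- sprintf("%s_%s", participant_id, session_id)
    wav <- file.path(dir, paste0(stem, ".wav"))
    lab <- file.path(dir, paste0(stem, "_labels.csv"))
    write_wav(sess$waveform, sess$sample_rate, wav)
    write_labels(sess, lab)
    tibble::tibble(
      participant_id = participant_id, session_id = session_id,
      audio_path = basename(wav), label_path = basename(lab),
      condition = condition, duration_seconds = duration_seconds
    )
  })
  readr::write_csv(rows, file.path(dir, "manifest.csv"))
  invisible(load_manifest(file.path(dir, "manifest.csv")))
}

#' Per-second feature representation of a whole corpus
#'
#' Streams each session (synthesized from a `corpus_plan`, or loaded from the
#' files of a `dataset_manifest`) through [extract_features()], keeping only
#' the feature matrix and labels so memory stays bounded by one session's
#' audio.
#'
#' @param corpus A `corpus_plan` or a `dataset_manifest`.
#' @param config A [feature_config()].
#' @param base_dir Directory manifest paths are resolved against (manifest
#'   input only).
#' @return A tibble of class `feature_corpus`: one row per session with
#'   `participant_id`, `session_id`, `condition`, `n_seconds`, and
#'   list-columns `features` (seconds x 260 matrix) and `labels`.
#' @export
corpus_features <- function(corpus, config = feature_config(), base_dir = ".") {
  if (inherits(corpus, "corpus_plan")) {
    rows <- corpus$sessions
    get_session <- function(i) realize_session(corpus, rows$participant_id[i], rows$session_id[i])
  } else if (inherits(corpus, "dataset_manifest")) {
    rows <- corpus
    get_session <- function(i) {
      resolve <- function(p) if (grepl("^/", p)) p else file.path(base_dir, p)
      load_session(resolve(rows$audio_path[i]),
                   label_path = if (!is.na(rows$label_path[i])) resolve(rows$label_path[i]),
                   participant_id = rows$participant_id[i],
                   session_id = rows$session_id[i],
                   condition = rows$condition[i])
    }
  } else {
    abort("corpus must be a corpus_plan or dataset_manifest")
  }
  out <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    sess <- get_session(i)
    feats <- extract_features(sess, config)
    tibble::tibble(
      participant_id = rows$participant_id[i],
      session_id = rows$session_id[i],
      condition = rows$condition[i],
      n_seconds = nrow(feats),
      features = list(feats),
      labels = list(sess$labels)
    )
  })
  class(out) <- c("feature_corpus", class(tibble::tibble()))
  out
}
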