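#' Reference dataset description
#'
#' Per-participant session counts and durations of the published reference
#' dataset of home-recorded sessions from eight children: 142 sessions,
#' 99,564 s in total, of which 25,887 s were recorded with noncontingent
#' music playing and 73,677 s without. Used to validate manifest aggregation
#' and as a realistic template for dataset-level bookkeeping.
#'
#' @return A tibble with one row per participant: `participant_id`,
#'   `n_sessions`, `total_seconds`, `music_seconds`, `no_music_seconds`.
#' @export
reference_dataset <- function() {
  tibble::tribble(
    ~participant_id, ~n_sessions, ~total_seconds, ~music_seconds, ~no_music_seconds,
    "P1", 38L, 27448, 719,  26729,
    "P2",  6L,  4015, 2044,  1971,
    "P3", 30L, 20756, 3685, 17071,
    "P4", 10L,  6909, 2729,  4180,
    "P5", 25L, 17461, 4357, 13104,
    "P6", 11L,  7533, 4750,  2783,
    "P7", 10L,  7091, 2783,  4308,
    "P8", 12L,  8351, 4820,  3531
  )
}

# Spread `total` seconds over `k` sessions as evenly as possible in whole
# seconds.
split_even <- function(total, k) {
  if (k == 0L) return(integer(0))
  base <- total %/% k
  rem <- total - base * k
  base + c(rep(1L, rem), rep(0L, k - rem))
}

#' Metadata-only manifest matching the reference dataset
#'
#' Expands [reference_dataset()] into per-session manifest rows. The
#' published description gives only per-participant totals, so the
#' within-participant allocation of seconds to sessions is synthetic: the
#' number of music sessions per participant is chosen proportional to the
#' participant's music share (at least one per nonzero condition), and each
#' condition's seconds are spread evenly over its sessions. Participant and
#' condition aggregates reproduce the published totals exactly.
#'
#' @return A `dataset_manifest` tibble (no audio or label paths).
#' @export
reference_manifest <- function() {
  ref <- reference_dataset()
  rows <- purrr::pmap_dfr(ref, function(participant_id, n_sessions, total_seconds,
                                        music_seconds, no_music_seconds) {
    k_m <- if (music_seconds == 0) 0L else
      min(n_sessions - (no_music_seconds > 0),
          max(1L, round(n_sessions * music_seconds / total_seconds)))
    k_w <- n_sessions - k_m
    durs <- c(split_even(music_seconds, k_m), split_even(no_music_seconds, k_w))
    tibble::tibble(
      participant_id = participant_id,
      session_id = sprintf("s%02d", seq_len(n_sessions)),
      audio_path = NA_character_,
      label_path = NA_character_,
      condition = rep(c("music", "no_music"), c(k_m, k_w)),
      duration_seconds = durs
    )
  })
  as_manifest(rows)
}
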