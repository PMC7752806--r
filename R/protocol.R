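#' Stimulus and trace timing configuration
#'
#' Bundles the physical stimulus parameters and the per-trial sampling window
#' used throughout the pipeline. Defaults follow the delay conditioning
#' protocol this package models: a 500-ms, 1200-Hz pure tone conditioned
#' stimulus (CS) that co-terminates with a 50-ms corneal air-puff
#' unconditional stimulus (US) on reinforced trials, a 15-30 s inter-trial
#' interval, and EMG sampled at 1000 Hz over a 3000-ms window per trial.
#'
#' @param cs_duration_ms CS duration in milliseconds.
#' @param cs_frequency_hz CS tone frequency in Hz (metadata only).
#' @param cs_level_db CS sound level in dB (metadata only).
#' @param us_duration_ms US duration in milliseconds.
#' @param us_pressure_psi US air-puff pressure in psi (metadata only).
#' @param iti_min_s,iti_max_s Bounds of the uniform inter-trial interval, in
#'   seconds.
#' @param sample_rate_hz EMG sampling rate in Hz.
#' @param trace_duration_ms Length of the per-trial sampling window in
#'   milliseconds.
#' @param cs_onset_ms CS onset position within the trace, in milliseconds.
#'   Must leave at least 250 ms of pre-stimulus baseline.
#'
#' @return An object of class `stimulus_config` (a named list).
#' @examples
#' cfg <- stimulus_config()
#' cfg$cs_duration_ms
#' @export
stimulus_config <- function(cs_duration_ms = 500,
                            cs_frequency_hz = 1200,
                            cs_level_db = 82,
                            us_duration_ms = 50,
                            us_pressure_psi = 5,
                            iti_min_s = 15,
                            iti_max_s = 30,
                            sample_rate_hz = 1000,
                            trace_duration_ms = 3000,
                            cs_onset_ms = 1000) {
  cfg <- list(
    cs_duration_ms = cs_duration_ms,
    cs_frequency_hz = cs_frequency_hz,
    cs_level_db = cs_level_db,
    us_duration_ms = us_duration_ms,
    us_pressure_psi = us_pressure_psi,
    iti_min_s = iti_min_s,
    iti_max_s = iti_max_s,
    sample_rate_hz = sample_rate_hz,
    trace_duration_ms = trace_duration_ms,
    cs_onset_ms = cs_onset_ms
  )
  if (!(cs_duration_ms > us_duration_ms && us_duration_ms > 0)) {
    stop("cs_duration_ms must exceed us_duration_ms, both positive")
  }
  if (iti_min_s > iti_max_s) stop("iti_min_s must not exceed iti_max_s")
  if (cs_onset_ms + cs_duration_ms >= trace_duration_ms) {
    stop("CS must end before the trace does")
  }
  if (cs_onset_ms < 250) stop("cs_onset_ms must leave >= 250 ms of baseline")
  structure(cfg, class = "stimulus_config")
}

#' US onset for a reinforced trial
#'
#' On CS+ trials the US co-terminates with the CS, so the US starts
#' `cs_duration - us_duration` after CS onset (450 ms at defaults).
#'
#' @param config A [stimulus_config()].
#' @return US onset in ms within the trace.
#' @keywords internal
us_onset_for_cs_plus <- function(config) {
  config$cs_onset_ms + config$cs_duration_ms - config$us_duration_ms
}

# Acquisition trial counts by week: Week 1 has 60 trials (30 CS+, 30 CS-)
# preceded by 3 US-alone habituation trials; Week 2 has 30 trials, no
# US-alone exposures.
week_plan <- function(week) {
  week <- as.integer(week)
  if (!week %in% c(1L, 2L)) stop("week must be 1 or 2")
  if (week == 1L) {
    list(n_us_alone = 3L, n_cs_plus = 30L, n_cs_minus = 30L)
  } else {
    list(n_us_alone = 0L, n_cs_plus = 15L, n_cs_minus = 15L)
  }
}

#' Generate a pseudorandom conditioning session schedule
#'
#' Builds a Week 1 or Week 2 session under the 50% partial reinforcement
#' schedule. Week 1 consists of 3 US-alone exposures (UR calibration)
#' followed by 60 acquisition trials (30 CS+, 30 CS-); Week 2 consists of 30
#' acquisition trials (15 CS+, 15 CS-) with no US-alone exposures. Trial
#' order within the acquisition block is pseudorandom under the constraint
#' that no more than 3 trials of the same type occur in succession, sampled
#' uniformly over admissible orderings by rejection sampling (shuffle, reject
#' on a run longer than 3).
#'
#' @param week 1 or 2.
#' @param config A [stimulus_config()].
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @return A `session_schedule`: a data frame with one row per trial and
#'   columns `trial_index`, `kind` (`"CS_PLUS"`, `"CS_MINUS"`, `"US_ALONE"`),
#'   `phase` (`"habituation"` or `"acquisition"`), `iti_s`, `cs_onset_ms`,
#'   `us_onset_ms` (`NA` where the stimulus is absent), plus `week` and
#'   `seed` attributes.
#' @examples
#' sch <- generate_schedule(1, seed = 7)
#' table(sch$kind)
#' max_run_length(sch)
#' @export
generate_schedule <- function(week, config = stimulus_config(), seed) {
  plan <- week_plan(week)
  rng <- local_rng(seed)
  kinds <- c(rep("CS_PLUS", plan$n_cs_plus), rep("CS_MINUS", plan$n_cs_minus))
  acq <- sample_constrained_sequence(kinds, max_run = 3L)
  all_kinds <- c(rep("US_ALONE", plan$n_us_alone), acq)
  n <- length(all_kinds)
  iti <- sample_iti(config, n = n)
  cs_onset <- ifelse(all_kinds == "US_ALONE", NA_integer_,
                     as.integer(config$cs_onset_ms))
  us_onset <- rep(NA_integer_, n)
  us_onset[all_kinds == "CS_PLUS"] <- as.integer(us_onset_for_cs_plus(config))
  # US-alone exposures are delivered at the same in-trace latency as the
  # paired US so UR scoring windows line up across trial types.
  us_onset[all_kinds == "US_ALONE"] <- as.integer(us_onset_for_cs_plus(config))
  sched <- data.frame(
    trial_index = seq_len(n),
    kind = all_kinds,
    phase = ifelse(all_kinds == "US_ALONE", "habituation", "acquisition"),
    iti_s = iti,
    cs_onset_ms = cs_onset,
    us_onset_ms = us_onset,
    stringsAsFactors = FALSE
  )
  structure(sched,
            week = as.integer(week), seed = as.integer(seed),
            config = config,
            class = c("session_schedule", "data.frame"))
}

# Uniform sampling over orderings of a trial-kind multiset subject to a
# maximum same-kind run length, by rejection: shuffle, reject on a long run.
# Rejection preserves uniformity over the admissible set.
sample_constrained_sequence <- function(kinds, max_run = 3L) {
  repeat {
    perm <- sample(kinds)
    if (max_kind_run(perm) <= max_run) return(perm)
  }
}

# longest run of equal values in a character vector
max_kind_run <- function(kinds) {
  if (length(kinds) == 0L) return(0L)
  max(rle(kinds)$lengths)
}

#' Longest same-type run among acquisition trials
#'
#' Validates the sequencing constraint: generated schedules never contain
#' more than 3 consecutive CS+ or CS- acquisition trials. Habituation
#' (US-alone) trials are excluded.
#'
#' @param schedule A `session_schedule` (or any data frame with `kind` and
#'   `phase` columns).
#' @return Integer run length.
#' @export
max_run_length <- function(schedule) {
  if (nrow(schedule) == 0L) stop("schedule is empty")
  acq <- schedule$kind[schedule$phase == "acquisition"]
  max_kind_run(acq)
}

#' Draw inter-trial intervals
#'
#' Uniform over `[iti_min_s, iti_max_s]` (15-30 s at defaults).
#'
#' @param config A [stimulus_config()].
#' @param n Number of draws.
#' @return Numeric vector of ITIs in seconds.
#' @export
sample_iti <- function(config = stimulus_config(), n = 1) {
  stats::runif(n, min = config$iti_min_s, max = config$iti_max_s)
}

#' Write / read a schedule as CSV
#'
#' The on-disk format has columns
#' `trial_index,kind,iti_s,cs_onset_ms,us_onset_ms`; absent stimulus onsets
#' are empty cells and onset times are integer milliseconds.
#'
#' @param schedule A `session_schedule`.
#' @param file Path to write to / read from.
#' @return `read_schedule()` returns a data frame with the same columns plus
#'   a reconstructed `phase` column.
#' @export
write_schedule <- function(schedule, file) {
  out <- schedule[, c("trial_index", "kind", "iti_s",
                      "cs_onset_ms", "us_onset_ms")]
  utils::write.csv(out, file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(file) {
  sched <- utils::read.csv(file, stringsAsFactors = FALSE,
                           colClasses = c(trial_index = "integer",
                                          kind = "character",
                                          iti_s = "numeric",
                                          cs_onset_ms = "integer",
                                          us_onset_ms = "integer"))
  sched$phase <- ifelse(sched$kind == "US_ALONE", "habituation", "acquisition")
  sched
}

# Seed scoping: run code under a given seed without disturbing the caller's
# RNG state. Returns invisibly; used at the top of every seeded generator.
local_rng <- function(seed) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      # restore on exit of the *caller*; the old state is embedded by value
      do.call(on.exit, list(bquote(assign(".Random.seed", .(old),
                                          envir = globalenv())), add = TRUE),
              envir = parent.frame())
    } else {
      do.call(on.exit, list(quote(rm(".Random.seed", envir = globalenv())),
                            add = TRUE),
              envir = parent.frame())
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
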