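#' Latent learning profile
#'
#' Parametric stand-in for the acquisition curves of the three learning
#' phenotypes (High learners respond at high rates from early in training,
#' Mid learners acquire gradually, Low learners barely acquire under the 50%
#' partial reinforcement schedule). Within a week the per-block CR
#' probability follows saturating growth
#' `p(t) = p_start + (p_asymptote - p_start) * (1 - exp(-rate * t))`;
#' Week 2 restarts from `retention` times the Week-1 final value and grows
#' toward the same asymptote.
#'
#' @param name Profile label (`"HIGH"`, `"MID"`, `"LOW"`, or custom).
#' @param p_start Starting CR probability.
#' @param p_asymptote Asymptotic CR probability (`>= p_start`).
#' @param rate Per-block growth constant (`>= 0`).
#' @param retention Multiplier on the Week-1 final probability giving the
#'   Week-2 starting probability; in `[0, 1.2]`.
#' @return An object of class `learning_profile`.
#' @export
learning_profile <- function(name, p_start, p_asymptote, rate, retention = 1) {
  if (!(p_start >= 0 && p_start <= p_asymptote && p_asymptote <= 1)) {
    stop("need 0 <= p_start <= p_asymptote <= 1")
  }
  if (rate < 0) stop("rate must be >= 0")
  if (retention < 0 || retention > 1.2) stop("retention must be in [0, 1.2]")
  structure(list(name = name, p_start = p_start, p_asymptote = p_asymptote,
                 rate = rate, retention = retention),
            class = "learning_profile")
}

#' Default learning profiles
#'
#' Stand-in parameter sets chosen so the three simulated group curves
#' qualitatively reproduce the published phenotypes: HIGH responds at a high
#' rate from the first block and plateaus near 65%, MID rises gradually
#' toward ~45%, LOW stays nearly flat around 15%. These are modelling
#' defaults, not measured values, and are fully configurable.
#'
#' @return Named list of [learning_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    HIGH = learning_profile("HIGH", p_start = 0.45, p_asymptote = 0.65,
                            rate = 1.5, retention = 1.0),
    MID = learning_profile("MID", p_start = 0.08, p_asymptote = 0.50,
                           rate = 0.35, retention = 0.9),
    LOW = learning_profile("LOW", p_start = 0.08, p_asymptote = 0.15,
                           rate = 0.4, retention = 1.0)
  )
}

#' Per-block CR probability for a profile
#'
#' Week 1 evaluates the saturating-growth curve at `t = block` (blocks 1-6).
#' Week 2 starts exactly at `retention * p_week1(6)` in its first block and
#' relaxes toward the asymptote at the same rate (blocks 1-3); if retention
#' places the start above the asymptote the probability is held constant
#' rather than decaying, so the within-week curve is always monotone
#' non-decreasing. Values are clipped to `[0, 1]`.
#'
#' @param profile A [learning_profile()].
#' @param week 1 or 2.
#' @param block Block number (1-6 for Week 1, 1-3 for Week 2).
#' @return CR probability.
#' @export
cr_probability <- function(profile, week, block) {
  week <- as.integer(week)
  n_blocks <- if (week == 1L) 6L else if (week == 2L) 3L else
    stop("week must be 1 or 2")
  if (any(block < 1L | block > n_blocks)) {
    stop(sprintf("block out of range 1..%d for week %d", n_blocks, week))
  }
  grow <- function(p0, t) {
    p0 + (profile$p_asymptote - p0) * (1 - exp(-profile$rate * t))
  }
  p <- if (week == 1L) {
    grow(profile$p_start, block)
  } else {
    q0 <- min(1, profile$retention * grow(profile$p_start, 6))
    if (q0 >= profile$p_asymptote) rep(q0, length(block)) else
      grow(q0, block - 1)
  }
  pmin(pmax(p, 0), 1)
}

#' EMG noise and blink-burst parameters
#'
#' Controls the synthetic EMG generator. The baseline is band-limited
#' (1-30 Hz) Gaussian noise of SD `sigma_b` on the envelope scale. Blink
#' bursts are smooth unimodal Gaussian envelopes with width parameter (SD)
#' drawn uniformly from `[width_min_ms, width_max_ms]` and peak amplitudes
#' drawn log-normally; the CR amplitude median (0.8) sits 4x above the 0.2
#' detection threshold. CR peak latency is uniform in
#' `[cr_lat_min_ms, cr_lat_max_ms]` after CS onset (well inside the scoring
#' window); the UR burst begins `[ur_lat_min_ms, ur_lat_max_ms]` after US
#' onset. Spontaneous blinks occur at Poisson rate `spont_rate` per trial and
#' are placed outside the CR window unless `spont_in_cr_window = TRUE`
#' (useful for stressing false-positive handling).
#'
#' `mode = "envelope"` synthesises the post-preprocessing rectified-envelope
#' signal directly (traces are flagged `prefiltered` so the detector skips
#' its band-pass); `mode = "raw"` multiplies the burst envelopes by a 15-Hz
#' carrier to mimic band-passed oscillatory EMG, which the detector must
#' rectify and smooth itself.
#'
#' @param sigma_b Baseline noise SD (envelope units).
#' @param cr_amp_meanlog,cr_amp_sdlog Log-normal parameters of CR peak
#'   amplitude.
#' @param ur_amp_meanlog,ur_amp_sdlog Log-normal parameters of UR peak
#'   amplitude.
#' @param width_min_ms,width_max_ms Burst envelope width (Gaussian SD) range.
#' @param cr_lat_min_ms,cr_lat_max_ms CR peak latency range after CS onset.
#' @param ur_lat_min_ms,ur_lat_max_ms UR burst-onset latency range after US
#'   onset.
#' @param spont_rate Mean spontaneous blinks per trial.
#' @param spont_in_cr_window Allow spontaneous blinks inside the CR window.
#' @param mode `"envelope"` or `"raw"`.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(sigma_b = 0.05,
                         cr_amp_meanlog = log(0.8), cr_amp_sdlog = 0.3,
                         ur_amp_meanlog = log(1.2), ur_amp_sdlog = 0.3,
                         width_min_ms = 30, width_max_ms = 60,
                         cr_lat_min_ms = 120, cr_lat_max_ms = 400,
                         ur_lat_min_ms = 25, ur_lat_max_ms = 60,
                         spont_rate = 0.05, spont_in_cr_window = FALSE,
                         mode = c("envelope", "raw")) {
  mode <- match.arg(mode)
  structure(list(sigma_b = sigma_b,
                 cr_amp_meanlog = cr_amp_meanlog, cr_amp_sdlog = cr_amp_sdlog,
                 ur_amp_meanlog = ur_amp_meanlog, ur_amp_sdlog = ur_amp_sdlog,
                 width_min_ms = width_min_ms, width_max_ms = width_max_ms,
                 cr_lat_min_ms = cr_lat_min_ms, cr_lat_max_ms = cr_lat_max_ms,
                 ur_lat_min_ms = ur_lat_min_ms, ur_lat_max_ms = ur_lat_max_ms,
                 spont_rate = spont_rate,
                 spont_in_cr_window = spont_in_cr_window,
                 mode = mode), class = "noise_params")
}

# Gaussian burst envelope evaluated on sample grid t (ms)
burst_envelope <- function(t_ms, peak_ms, width_ms, amplitude) {
  amplitude * exp(-(t_ms - peak_ms)^2 / (2 * width_ms^2))
}

# band-limited baseline noise with envelope-scale SD sigma_b
baseline_noise <- function(n, sample_rate_hz, sigma_b) {
  z <- bandpass_1_30(stats::rnorm(n), sample_rate_hz)
  s <- stats::sd(z)
  if (s == 0) return(rep(0, n))
  z * (sigma_b / s)
}

#' Simulate one trial's EMG trace
#'
#' Band-limited baseline noise, plus a UR burst after the US on every trial
#' with a US, plus (iff `cr_draw` and the trial has a CS) a CR burst whose
#' peak falls inside the CR scoring window, plus occasional spontaneous
#' blinks. Uses the current RNG stream; seed at a higher level.
#'
#' @param trial One `session_schedule` row.
#' @param cr_draw Logical: does this trial express a conditioned response?
#' @param config A [stimulus_config()].
#' @param noise A [noise_params()].
#' @return Numeric trace of `trace_duration_ms * sample_rate_hz / 1000`
#'   samples with attributes `prefiltered` (TRUE in envelope mode) and
#'   `sample_rate_hz`.
#' @export
simulate_trial_emg <- function(trial, cr_draw, config = stimulus_config(),
                               noise = noise_params()) {
  fs <- config$sample_rate_hz
  n <- round(config$trace_duration_ms * fs / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / fs
  env <- numeric(n)

  add_burst <- function(env, peak_ms, amp) {
    w <- stats::runif(1, noise$width_min_ms, noise$width_max_ms)
    env + burst_envelope(t_ms, peak_ms, w, amp)
  }

  has_cs <- !is.na(trial$cs_onset_ms)
  has_us <- !is.na(trial$us_onset_ms)
  if (has_us) {
    lat <- stats::runif(1, noise$ur_lat_min_ms, noise$ur_lat_max_ms)
    w <- stats::runif(1, noise$width_min_ms, noise$width_max_ms)
    amp <- stats::rlnorm(1, noise$ur_amp_meanlog, noise$ur_amp_sdlog)
    # burst onset (~2 SD before its peak) begins `lat` ms after the US
    env <- env + burst_envelope(t_ms, trial$us_onset_ms + lat + 2 * w, w, amp)
  }
  if (isTRUE(cr_draw) && has_cs) {
    lat <- stats::runif(1, noise$cr_lat_min_ms, noise$cr_lat_max_ms)
    amp <- stats::rlnorm(1, noise$cr_amp_meanlog, noise$cr_amp_sdlog)
    env <- add_burst(env, trial$cs_onset_ms + lat, amp)
  }
  n_spont <- stats::rpois(1, noise$spont_rate)
  if (n_spont > 0) {
    cr_lo <- if (has_cs) trial$cs_onset_ms + 80 else Inf
    cr_hi <- if (has_cs) trial$cs_onset_ms + 450 else -Inf
    for (s in seq_len(n_spont)) {
      repeat {
        peak <- stats::runif(1, 100, config$trace_duration_ms - 100)
        ok <- noise$spont_in_cr_window || peak < cr_lo || peak > cr_hi
        if (ok) break
      }
      amp <- stats::rlnorm(1, noise$cr_amp_meanlog, noise$cr_amp_sdlog)
      env <- add_burst(env, peak, amp)
    }
  }
  if (noise$mode == "raw") {
    carrier <- sin(2 * pi * 15 * t_ms / 1000)
    trace <- env * carrier + baseline_noise(n, fs, noise$sigma_b)
    prefiltered <- FALSE
  } else {
    trace <- env + baseline_noise(n, fs, noise$sigma_b)
    prefiltered <- TRUE
  }
  structure(trace, prefiltered = prefiltered, sample_rate_hz = fs,
            class = c("emg_trace", "numeric"))
}

# largest-remainder apportionment of n among proportions p
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Default cohort composition
#'
#' Group proportions of the modelled 54-subject cohort:
#' PTSD-/mTBI- 8, PTSD-/mTBI+ 21, PTSD+/mTBI- 12, PTSD+/mTBI+ 13.
#' @return Named numeric vector of proportions summing to 1.
#' @export
default_composition <- function() {
  c("PTSD-/mTBI-" = 8, "PTSD-/mTBI+" = 21,
    "PTSD+/mTBI-" = 12, "PTSD+/mTBI+" = 13) / 54
}

#' Default latent-profile mix by PTSD status
#'
#' Conditional profile probabilities chosen so that the HIGH cluster is
#' enriched for PTSD+ subjects (about 71% of HIGH learners PTSD+) while LOW
#' learners are predominantly PTSD-, mirroring the published subtype
#' composition.
#' @return List with elements `ptsd_pos` and `ptsd_neg`, each a named
#'   probability vector over HIGH/MID/LOW.
#' @export
default_profile_mix <- function() {
  list(
    ptsd_pos = c(HIGH = 10, MID = 7, LOW = 8) / 25,
    ptsd_neg = c(HIGH = 4, MID = 6, LOW = 19) / 29
  )
}

#' Default questionnaire-score distributions by group
#'
#' Group-level total-score means and SDs for PCL-5, PHQ-8 and AMBI, plus age
#' and sex composition, matching the demographic table of the modelled
#' cohort. Totals are drawn from normals truncated to the instrument range;
#' PCL-5 draws are additionally truncated on the diagnostic side of the
#' cut-off (33) so that generated group labels and scored flags agree.
#' @return Named list keyed by group label.
#' @export
default_questionnaire_params <- function() {
  list(
    "PTSD-/mTBI-" = list(pcl = c(10.00, 6.63), phq = c(7.50, 4.31),
                         ambi = c(16.63, 6.68), age = c(46, 11.50),
                         p_male = 6 / 8),
    "PTSD-/mTBI+" = list(pcl = c(19.19, 8.52), phq = c(5.57, 3.81),
                         ambi = c(16.91, 5.70), age = c(51, 10.00),
                         p_male = 18 / 21),
    "PTSD+/mTBI-" = list(pcl = c(47.67, 11.24), phq = c(14.92, 7.13),
                         ambi = c(20.25, 6.37), age = c(50, 10.50),
                         p_male = 10 / 12),
    "PTSD+/mTBI+" = list(pcl = c(51.46, 9.70), phq = c(12.46, 4.37),
                         ambi = c(22.08, 6.86), age = c(45, 12.00),
                         p_male = 9 / 13)
  )
}

# one draw from N(mean, sd) truncated to [lo, hi] via inverse CDF
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (lo >= hi) stop("invalid truncation bounds")
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) {
    stop("truncation interval has negligible mass: infeasible parameters")
  }
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# distribute integer total over k items with per-item maximum item_max,
# by repeated uniform increments over non-saturated items
decompose_total <- function(total, k, item_max) {
  if (total < 0 || total > k * item_max) {
    stop("total outside instrument range: infeasible")
  }
  items <- integer(k)
  for (u in seq_len(total)) {
    open <- which(items < item_max)
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    items[pick] <- items[pick] + 1L
  }
  items
}

# deterministic per-subject child seed from a master seed
subject_seed <- function(seed, i) {
  (as.integer(seed) + i * 10007L) %% 2147483587L
}

#' Sample a synthetic cohort
#'
#' Generates `n` subjects with PTSD/mTBI group labels (fixed largest-
#' remainder apportionment of `composition`), age, sex, item-level
#' questionnaire responses whose group totals follow the configured
#' mean/SD targets, a concussion screen consistent with the mTBI label, and
#' a latent learning profile drawn from `profile_mix` conditional on PTSD
#' status. Each subject is generated from a deterministic child seed of
#' `seed`, so enlarging the cohort never reshuffles existing subjects.
#'
#' @param n Cohort size.
#' @param composition Named group proportions (see [default_composition()]).
#' @param profile_mix Profile mix by PTSD status
#'   (see [default_profile_mix()]).
#' @param q_params Questionnaire distributions
#'   (see [default_questionnaire_params()]).
#' @param seed Master seed.
#' @return Data frame, one row per subject: `subject_id`, `group`, `age`,
#'   `sex`, `latent_profile`, `ptsd_group`, `mtbi_group`, `tbi_event`,
#'   `tbi_aoc`, `tbi_loc_min`, and item columns `pcl01..pcl20`,
#'   `phq01..phq08`, `ambi01..ambi16`.
#' @export
sample_cohort <- function(n = 54,
                          composition = default_composition(),
                          profile_mix = default_profile_mix(),
                          q_params = default_questionnaire_params(),
                          seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (abs(sum(composition) - 1) > 1e-8) stop("composition must sum to 1")
  counts <- apportion(n, composition)
  groups <- rep(names(composition), counts)
  rows <- lapply(seq_len(n), function(i) {
    local_rng(subject_seed(seed, i))
    g <- groups[i]
    qp <- q_params[[g]]
    ptsd <- grepl("PTSD\\+", g)
    mtbi <- grepl("mTBI\\+", g)
    pcl_bounds <- if (ptsd) c(33, 80) else c(0, 32)
    pcl_total <- round(rtrunc_norm(1, qp$pcl[1], qp$pcl[2],
                                   pcl_bounds[1], pcl_bounds[2]))
    phq_total <- round(rtrunc_norm(1, qp$phq[1], qp$phq[2], 0, 24))
    ambi_total <- round(rtrunc_norm(1, qp$ambi[1], qp$ambi[2], 0, 32))
    age <- round(rtrunc_norm(1, qp$age[1], qp$age[2], 18, 65))
    sex <- if (stats::runif(1) < qp$p_male) "M" else "F"
    mix <- if (ptsd) profile_mix$ptsd_pos else profile_mix$ptsd_neg
    prof <- sample(names(mix), 1, prob = mix)
    if (mtbi) {
      tbi_event <- TRUE
      tbi_aoc <- TRUE
      tbi_loc <- if (stats::runif(1) < 0.5) NA_real_ else
        round(stats::runif(1, 1, 20), 1)
    } else {
      tbi_event <- stats::runif(1) < 0.3
      tbi_aoc <- FALSE
      tbi_loc <- NA_real_
    }
    pcl_items <- decompose_total(pcl_total, 20, 4)
    phq_items <- decompose_total(phq_total, 8, 3)
    ambi_items <- decompose_total(ambi_total, 16, 2)
    row <- data.frame(
      subject_id = sprintf("S%03d", i),
      group = g, age = age, sex = sex, latent_profile = prof,
      ptsd_group = ptsd, mtbi_group = mtbi,
      tbi_event = tbi_event, tbi_aoc = tbi_aoc, tbi_loc_min = tbi_loc,
      stringsAsFactors = FALSE
    )
    row[sprintf("pcl%02d", 1:20)] <- as.list(pcl_items)
    row[sprintf("phq%02d", 1:8)] <- as.list(phq_items)
    row[sprintf("ambi%02d", 1:16)] <- as.list(ambi_items)
    row
  })
  do.call(rbind, rows)
}

#' Simulate one subject's session
#'
#' Generates the week's schedule, draws per-trial CR expression from the
#' subject's learning-profile block probabilities, and (optionally)
#' synthesises per-trial EMG traces.
#'
#' @param profile A [learning_profile()].
#' @param week 1 or 2.
#' @param config A [stimulus_config()].
#' @param noise A [noise_params()].
#' @param seed Seed for this subject-session.
#' @param generate_traces Synthesise EMG (`TRUE`) or return CR draws only.
#' @return List: `schedule`, `truth` (data frame `trial_index, kind, block,
#'   p_cr, cr_draw`), `traces` (list or `NULL`).
#' @export
simulate_subject_session <- function(profile, week,
                                     config = stimulus_config(),
                                     noise = noise_params(),
                                     seed = 1,
                                     generate_traces = TRUE) {
  schedule <- generate_schedule(week, config, seed = seed)
  local_rng(seed + 1L)
  acq <- schedule$phase == "acquisition"
  block <- integer(nrow(schedule))
  block[acq] <- (seq_len(sum(acq)) - 1L) %/% 10L + 1L
  p_cr <- rep(NA_real_, nrow(schedule))
  p_cr[acq] <- cr_probability(profile, week, block[acq])
  cr_draw <- rep(FALSE, nrow(schedule))
  cr_draw[acq] <- stats::runif(sum(acq)) < p_cr[acq]
  truth <- data.frame(trial_index = schedule$trial_index,
                      kind = schedule$kind, block = ifelse(acq, block, NA),
                      p_cr = p_cr, cr_draw = cr_draw,
                      stringsAsFactors = FALSE)
  traces <- NULL
  if (generate_traces) {
    traces <- lapply(seq_len(nrow(schedule)), function(i) {
      simulate_trial_emg(schedule[i, ], cr_draw[i], config, noise)
    })
  }
  list(schedule = schedule, truth = truth, traces = traces)
}

#' Simulate the full study for a cohort
#'
#' Runs [simulate_subject_session()] for Week 1 and Week 2 for every subject,
#' returning schedules, traces and the ground-truth table of per-trial CR
#' draws (retained for parameter-recovery tests). For large cohorts consider
#' `generate_traces = FALSE` (truth table only) or the streaming pipeline in
#' [run_study()], which discards traces after detection.
#'
#' @param cohort A cohort data frame from [sample_cohort()].
#' @param config A [stimulus_config()].
#' @param noise A [noise_params()].
#' @param seed Master seed.
#' @param profiles Named list of [learning_profile()]s resolving
#'   `cohort$latent_profile`.
#' @param generate_traces Synthesise EMG traces.
#' @return List with `sessions` (per subject id: `week1`, `week2` session
#'   lists) and `truth` (long data frame over subjects, weeks, trials).
#' @export
simulate_study <- function(cohort, config = stimulus_config(),
                           noise = noise_params(), seed = 1,
                           profiles = default_profiles(),
                           generate_traces = TRUE) {
  sessions <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    prof <- profiles[[cohort$latent_profile[i]]]
    if (is.null(prof)) stop("unknown latent profile: ",
                            cohort$latent_profile[i])
    s1 <- simulate_subject_session(prof, 1, config, noise,
                                   seed = subject_seed(seed, i * 2L),
                                   generate_traces = generate_traces)
    s2 <- simulate_subject_session(prof, 2, config, noise,
                                   seed = subject_seed(seed, i * 2L + 1L),
                                   generate_traces = generate_traces)
    sessions[[id]] <- list(week1 = s1, week2 = s2)
    for (wk in 1:2) {
      tr <- (if (wk == 1) s1 else s2)$truth
      tr$subject_id <- id
      tr$week <- wk
      truth_rows[[length(truth_rows) + 1L]] <- tr
    }
  }
  truth <- do.call(rbind, truth_rows)
  list(sessions = sessions, truth = truth)
}

#' Write / read cohort tables
#'
#' One row per subject with item-level questionnaire columns; the CSV round-
#' trips through [score_subjects()].
#' @param cohort Cohort data frame.
#' @param file Path.
#' @export
write_cohort <- function(cohort, file) {
  utils::write.csv(cohort, file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Write / read per-subject traces as long-format CSV
#'
#' Plain-text trace container: columns `trial_index, sample_index,
#' amplitude`, one file per subject-session, with the `prefiltered` flag and
#' sample rate stored in a JSON sidecar (`<file>.json`).
#' @param traces List of traces (one per trial).
#' @param file CSV path.
#' @export
write_traces <- function(traces, file) {
  long <- do.call(rbind, lapply(seq_along(traces), function(i) {
    data.frame(trial_index = i, sample_index = seq_along(traces[[i]]),
               amplitude = as.numeric(traces[[i]]))
  }))
  utils::write.csv(long, file, row.names = FALSE)
  meta <- list(prefiltered = isTRUE(attr(traces[[1]], "prefiltered")),
               sample_rate_hz = attr(traces[[1]], "sample_rate_hz") %||% 1000)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_traces
#' @export
read_traces <- function(file) {
  long <- utils::read.csv(file)
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  lapply(split(long$amplitude, long$trial_index), function(x) {
    structure(as.numeric(x), prefiltered = isTRUE(meta$prefiltered),
              sample_rate_hz = meta$sample_rate_hz,
              class = c("emg_trace", "numeric"))
  })
}
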