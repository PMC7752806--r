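#' Study run configuration
#'
#' Bundles every knob of an end-to-end run: the master seed, cohort size and
#' composition, stimulus/trace timing, EMG noise model, detector settings,
#' sphericity policy, and clustering options. A run is reproducible from its
#' config alone; [run_study()] serialises the config with every output
#' manifest.
#'
#' @param seed Master seed.
#' @param n Cohort size.
#' @param composition Group proportions (see [default_composition()]).
#' @param profiles Learning profiles (see [default_profiles()]).
#' @param profile_mix Profile mix by PTSD status.
#' @param stim A [stimulus_config()].
#' @param noise A [noise_params()].
#' @param detection A [detection_config()].
#' @param sphericity Greenhouse-Geisser policy for [mixed_rm_ancova()].
#' @param k_range Candidate cluster counts.
#' @param generate_traces Simulate EMG and run detection (`TRUE`), or score
#'   planted CR draws directly (`FALSE`; detection-free mode used for fast
#'   statistical calibration studies).
#' @param outdir Optional output directory for artifacts.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, n = 54,
                       composition = default_composition(),
                       profiles = default_profiles(),
                       profile_mix = default_profile_mix(),
                       stim = stimulus_config(),
                       noise = noise_params(),
                       detection = detection_config(),
                       sphericity = "mauchly",
                       k_range = 2:8,
                       generate_traces = TRUE,
                       outdir = NULL) {
  structure(list(seed = seed, n = n, composition = composition,
                 profiles = profiles, profile_mix = profile_mix,
                 stim = stim, noise = noise, detection = detection,
                 sphericity = sphericity, k_range = k_range,
                 generate_traces = generate_traces, outdir = outdir),
            class = "run_config")
}

#' Run the full study pipeline
#'
#' Executes the complete analysis chain: simulate a cohort -> synthesise and
#' detect per-trial EMG (streamed subject-by-subject, traces discarded after
#' detection) -> blockwise CR scoring -> questionnaire scoring -> mixed
#' repeated-measures ANCOVAs for Week 1 (2 x 2 x 6) and Week 2 (2 x 2 x 3)
#' with age as covariate, plus the post-hoc PTSD comparisons within mTBI
#' strata -> behavioural subtyping (all-blocks majority-rule solution and the
#' Week-2-only three-group solution) with profile-wise symptom comparisons.
#' When `config$outdir` is set, all artifacts plus a manifest (seed, config
#' hash, stage log) are written there.
#'
#' @param config A [run_config()].
#' @return List of class `study_run`: `cohort`, `scored`, `series`, `truth`,
#'   `ancova` (`week1`, `week2`), `posthoc`, `subtype` (`all`, `week2`),
#'   `comparison` (`all`, `week2`), `log`, `manifest`.
#' @export
run_study <- function(config = run_config()) {
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate", {
    sample_cohort(config$n, config$composition, config$profile_mix,
                  seed = config$seed)
  })
  say("simulate: cohort of %d subjects (%s)", nrow(cohort),
      paste(names(table(cohort$group)), table(cohort$group),
            sep = "=", collapse = ", "))

  results <- stage("detect", {
    out <- list()
    for (i in seq_len(nrow(cohort))) {
      id <- cohort$subject_id[i]
      prof <- config$profiles[[cohort$latent_profile[i]]]
      res <- list()
      for (wk in 1:2) {
        ss <- simulate_subject_session(
          prof, wk, config$stim, config$noise,
          seed = subject_seed(config$seed, i * 2L + (wk - 1L)),
          generate_traces = config$generate_traces)
        if (config$generate_traces) {
          det <- detect_session(ss$traces, ss$schedule, config$detection,
                                config$stim)
        } else {
          # detection-free mode: planted CR draws stand in for detector calls
          det <- data.frame(trial_index = ss$schedule$trial_index,
                            kind = ss$schedule$kind,
                            phase = ss$schedule$phase,
                            cr_present = ifelse(
                              ss$schedule$phase == "acquisition",
                              ss$truth$cr_draw, NA),
                            stringsAsFactors = FALSE)
        }
        det$subject_id <- id
        det$week <- wk
        res[[paste0("week", wk)]] <- det
      }
      out[[id]] <- res
    }
    out
  })
  n_cr <- sum(vapply(results, function(r) {
    sum(r$week1$cr_present, na.rm = TRUE) + sum(r$week2$cr_present, na.rm = TRUE)
  }, numeric(1)))
  say("detect: %d trials scored, %d CRs detected",
      sum(vapply(results, function(r) nrow(r$week1) + nrow(r$week2), 1)), n_cr)

  series <- stage("score", assemble_learning_matrix(results))
  if (length(attr(series, "excluded")) > 0) {
    say("score: excluded %d subjects with incomplete sessions",
        length(attr(series, "excluded")))
  }
  say("score: learning matrix %d x %d", nrow(series), ncol(series))

  scored <- stage("questionnaires", score_subjects(cohort))
  scored <- scored[match(rownames(series), scored$subject_id), ]
  say("questionnaires: %d PTSD+, %d mTBI+, %d BI",
      sum(scored$ptsd_positive), sum(scored$mtbi_positive),
      sum(scored$bi_positive))

  between <- data.frame(ptsd = scored$ptsd_positive,
                        mtbi = scored$mtbi_positive)
  ancova <- stage("stats", {
    list(
      week1 = mixed_rm_ancova(series[, 1:6], between, scored$age,
                              sphericity = config$sphericity),
      week2 = mixed_rm_ancova(series[, 7:9], between, scored$age,
                              sphericity = config$sphericity)
    )
  })
  say("stats: week1 PTSD p=%.3f, week2 PTSD p=%.3f",
      ancova$week1$p[ancova$week1$effect == "ptsd"],
      ancova$week2$p[ancova$week2$effect == "ptsd"])

  posthoc <- stage("posthoc", {
    w2 <- rowMeans(series[, 7:9])
    tests <- list()
    for (m in c(FALSE, TRUE)) {
      sel <- scored$mtbi_positive == m
      x <- w2[sel & scored$ptsd_positive]
      y <- w2[sel & !scored$ptsd_positive]
      tests[[if (m) "mtbi_pos" else "mtbi_neg"]] <-
        if (length(x) >= 2 && length(y) >= 2) two_sample_t(x, y) else NULL
    }
    ps <- vapply(Filter(Negate(is.null), tests), function(t) t$p, numeric(1))
    list(tests = tests, p_bonferroni = bonferroni_adjust(ps))
  })

  subtype <- stage("subtype", {
    list(all = subtype_cohort(series, "all", config$k_range),
         week2 = subtype_cohort(series, "week2"))
  })
  say("subtype: all-blocks k=%d (%s); week2 k=%d", subtype$all$k,
      paste(names(table(subtype$all$profile)), table(subtype$all$profile),
            sep = "=", collapse = ", "), subtype$week2$k)

  comparison <- stage("compare", {
    list(all = compare_profiles(subtype$all$profile, scored),
         week2 = compare_profiles(subtype$week2$profile, scored))
  })

  truth <- NULL  # regenerate on demand via simulate_study(); traces streamed
  manifest <- list(seed = config$seed, n = config$n,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   config_hash = config_hash(config), log = log)
  run <- structure(list(cohort = cohort, scored = scored, series = series,
                        results = results, ancova = ancova, posthoc = posthoc,
                        subtype = subtype, comparison = comparison,
                        log = log, manifest = manifest),
                   class = "study_run")
  if (!is.null(config$outdir)) write_run(run, config)
  run
}

# stable hash of the config: md5 of its deparsed, deterministic serialisation
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "outdir")]), tmp)
  unname(tools::md5sum(tmp))
}

# write all run artifacts under config$outdir
write_run <- function(run, config) {
  dir <- config$outdir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(run$cohort, file.path(dir, "cohort.csv"))
  utils::write.csv(run$scored, file.path(dir, "scored_subjects.csv"),
                   row.names = FALSE)
  series_df <- data.frame(subject_id = rownames(run$series), run$series,
                          row.names = NULL)
  utils::write.csv(series_df, file.path(dir, "learning_series.csv"),
                   row.names = FALSE)
  for (wk in c("week1", "week2")) {
    utils::write.csv(as.data.frame(run$ancova[[wk]]),
                     file.path(dir, paste0("ancova_", wk, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(week1 = as.list(as.data.frame(run$ancova$week1)),
         week2 = as.list(as.data.frame(run$ancova$week2)),
         mauchly_week1 = unclass(attr(run$ancova$week1, "mauchly")),
         mauchly_week2 = unclass(attr(run$ancova$week2, "mauchly"))),
    file.path(dir, "ancova.json"), auto_unbox = TRUE, digits = NA)
  labels_df <- data.frame(subject_id = rownames(run$series),
                          profile_all = run$subtype$all$profile,
                          profile_week2 = run$subtype$week2$profile,
                          row.names = NULL)
  utils::write.csv(labels_df, file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  if (!is.null(run$subtype$all$panel)) {
    utils::write.csv(
      data.frame(index = names(run$subtype$all$panel$votes),
                 k = as.integer(run$subtype$all$panel$votes)),
      file.path(dir, "index_votes.csv"), row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
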