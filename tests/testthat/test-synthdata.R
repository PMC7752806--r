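test_that("cr_probability follows saturating growth with retention", {
  flat <- learning_profile("LOW", 0.2, 0.2, rate = 1)
  expect_equal(cr_probability(flat, 1, 1:6), rep(0.2, 6))
  expect_equal(cr_probability(flat, 2, 1:3), rep(0.2, 3))

  fast <- learning_profile("HIGH", 0.1, 0.7, rate = 1e6)
  expect_equal(cr_probability(fast, 1, 1:6), rep(0.7, 6), tolerance = 1e-12)

  high <- default_profiles()$HIGH
  p1 <- cr_probability(high, 1, 1:6)
  expect_true(all(diff(p1) >= 0))
  p2 <- cr_probability(high, 2, 1:3)
  expect_true(all(diff(p2) >= 0))
  # week 2 starts at retention x week-1 final value
  expect_equal(p2[1], high$retention * p1[6], tolerance = 1e-12)

  # retention above the asymptote holds constant, never decays
  bounce <- learning_profile("X", 0.3, 0.5, rate = 2, retention = 1.2)
  pb <- cr_probability(bounce, 2, 1:3)
  expect_true(all(diff(pb) >= 0))
  expect_error(cr_probability(high, 1, 7), "range")
  expect_error(cr_probability(high, 2, 4), "range")
  expect_error(learning_profile("bad", 0.5, 0.4, 1), "p_start")
})

test_that("silent traces stay silent and expressed CRs are detectable", {
  minus <- make_trial("CS_MINUS")
  quiet <- noise_params(sigma_b = 1e-12, spont_rate = 0)
  set.seed(4)
  tr <- simulate_trial_emg(minus, cr_draw = FALSE, noise = quiet)
  expect_lt(max(abs(tr)), 1e-6)
  expect_false(classify_cr(preprocess_emg(tr), minus)$cr_present)

  plus <- make_trial("CS_PLUS")
  hits <- replicate(300, {
    tr <- simulate_trial_emg(plus, TRUE)
    classify_cr(preprocess_emg(tr), plus)$cr_present
  })
  expect_gte(mean(hits), 0.95)

  # unexpressed CS+ trials still show a UR after 450 ms but no CR
  stats <- replicate(300, {
    tr <- simulate_trial_emg(plus, FALSE)
    env <- preprocess_emg(tr)
    c(cr = classify_cr(env, plus)$cr_present,
      ur = classify_ur(env, plus)$ur_present)
  })
  expect_lte(mean(stats["cr", ]), 0.05)
  expect_gte(mean(stats["ur", ]), 0.95)
})

test_that("raw oscillatory mode is handled through the detector band-pass", {
  plus <- make_trial("CS_PLUS")
  set.seed(12)
  raw <- noise_params(mode = "raw")
  tr <- simulate_trial_emg(plus, TRUE, noise = raw)
  expect_false(isTRUE(attr(tr, "prefiltered")))
  hits <- replicate(150, {
    tr <- simulate_trial_emg(plus, TRUE, noise = raw)
    classify_cr(preprocess_emg(tr), plus)$cr_present
  })
  expect_gte(mean(hits), 0.9)
})

test_that("baseline noise power is concentrated in 1-30 Hz", {
  set.seed(8)
  minus <- make_trial("CS_MINUS")
  quiet <- noise_params(spont_rate = 0)
  long <- unlist(lapply(1:100, function(i) {
    as.numeric(simulate_trial_emg(minus, FALSE, noise = quiet))
  }))
  sp <- stats::spec.pgram(stats::ts(long, frequency = 1000), plot = FALSE,
                          taper = 0)
  in_band <- sp$freq >= 1 & sp$freq <= 30
  expect_gt(sum(sp$spec[in_band]) / sum(sp$spec), 0.95)
})

test_that("sampled cohorts match the configured group structure", {
  cohort <- sample_cohort(n = 54, seed = 3)
  expect_equal(nrow(cohort), 54L)
  expect_equal(as.integer(table(cohort$group)[c(
    "PTSD-/mTBI-", "PTSD-/mTBI+", "PTSD+/mTBI-", "PTSD+/mTBI+")]),
    c(8L, 21L, 12L, 13L))
  expect_true(all(cohort$age >= 18 & cohort$age <= 65))
  # scored flags agree with generative groups by construction
  scored <- score_subjects(cohort)
  expect_equal(scored$ptsd_positive, cohort$ptsd_group)
  expect_equal(scored$mtbi_positive, cohort$mtbi_group)
  # determinism and extensibility: first subjects unchanged by growth
  c2 <- sample_cohort(n = 54, seed = 3)
  expect_identical(cohort, c2)
})

test_that("questionnaire totals track their target distributions", {
  one_group <- c("PTSD-/mTBI-" = 1)
  set.seed(10)
  cohort <- sample_cohort(n = 120, composition = one_group, seed = 10)
  scored <- score_subjects(cohort)
  # truncation to [0, 32] shifts the mean slightly; allow 3 SE around the
  # truncated-normal mean rather than the raw 10.00
  m <- 10; s <- 6.63
  a <- (0 - m) / s; b <- (32 - m) / s
  tn_mean <- m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  se <- s / sqrt(120)
  expect_lt(abs(mean(scored$pcl_total) - tn_mean), 3 * se)
  expect_true(all(scored$pcl_total <= 32))
})

test_that("item decomposition respects ranges and recovers totals", {
  set.seed(6)
  for (t in c(0, 17, 80)) {
    items <- blinkcr:::decompose_total(t, 20, 4)
    expect_equal(sum(items), t)
    expect_true(all(items >= 0 & items <= 4))
  }
  expect_error(blinkcr:::decompose_total(81, 20, 4), "infeasible")
})

test_that("study simulation plants recoverable CR probabilities", {
  cohort <- sample_cohort(n = 6, seed = 21)
  sim <- simulate_study(cohort, seed = 21, generate_traces = FALSE)
  expect_identical(
    sim$truth,
    simulate_study(cohort, seed = 21, generate_traces = FALSE)$truth)
  acq <- sim$truth[sim$truth$kind != "US_ALONE", ]
  expect_true(all(!is.na(acq$p_cr)))
  expect_true(all(is.na(sim$truth$block[sim$truth$kind == "US_ALONE"])))

  zero <- learning_profile("LOW", 0, 0, 1)
  cz <- cohort[1, , drop = FALSE]
  simz <- simulate_study(cz, seed = 5, profiles = list(LOW = zero, MID = zero,
                                                       HIGH = zero),
                         generate_traces = FALSE)
  expect_false(any(simz$truth$cr_draw))
})

test_that("detected block CR% recovers planted probabilities (closed loop)", {
  set.seed(33)
  profiles <- default_profiles()
  planted <- c()
  detected <- c()
  for (i in 1:30) {
    prof <- profiles[[sample(names(profiles), 1)]]
    wk <- sample(1:2, 1)
    ss <- simulate_subject_session(prof, wk, seed = 7000 + i)
    det <- detect_session(ss$traces, ss$schedule)
    acq <- det[det$phase == "acquisition", ]
    pct <- block_cr_percent(acq)
    blocks <- seq_along(pct)
    planted <- c(planted, 100 * cr_probability(prof, wk, blocks))
    detected <- c(detected, pct)
  }
  fit <- lm(detected ~ planted)
  expect_gt(coef(fit)[2], 0.9)
  expect_lt(coef(fit)[2], 1.1)
  expect_lt(abs(coef(fit)[1]), 5)
})

test_that("trace containers round-trip through CSV", {
  plus <- make_trial("CS_PLUS")
  set.seed(2)
  traces <- lapply(1:3, function(i) simulate_trial_emg(plus, TRUE))
  f <- tempfile(fileext = ".csv")
  write_traces(traces, f)
  back <- read_traces(f)
  expect_equal(length(back), 3L)
  expect_equal(as.numeric(back[[2]]), as.numeric(traces[[2]]))
  expect_true(isTRUE(attr(back[[1]], "prefiltered")))
  unlink(c(f, paste0(f, ".json")))
})
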