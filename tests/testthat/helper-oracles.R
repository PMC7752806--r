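# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most literal method available, sharing no code
# with the package internals they check.

# a clean Gaussian-envelope test trace (no noise) with optional bumps
bump_envelope <- function(n = 3000, peaks_ms = numeric(0), amps = numeric(0),
                          widths_ms = numeric(0)) {
  t_ms <- seq_len(n) - 1
  env <- numeric(n)
  for (i in seq_along(peaks_ms)) {
    env <- env + amps[i] * exp(-(t_ms - peaks_ms[i])^2 / (2 * widths_ms[i]^2))
  }
  env
}

# one CS+ / CS- / US-alone trial row with default timing
make_trial <- function(kind) {
  data.frame(
    trial_index = 1L, kind = kind,
    phase = if (kind == "US_ALONE") "habituation" else "acquisition",
    iti_s = 20,
    cs_onset_ms = if (kind == "US_ALONE") NA_integer_ else 1000L,
    us_onset_ms = if (kind == "CS_MINUS") NA_integer_ else 1450L,
    stringsAsFactors = FALSE
  )
}

# Literal reference CR detector: scan every sample of the half-open window,
# apply the three criteria at each local maximum, exactly as written out.
brute_force_cr <- function(envelope, trial, config = detection_config()) {
  cs <- trial$cs_onset_ms
  w_end <- if (trial$kind == "CS_PLUS") trial$us_onset_ms else cs + 450
  base_idx <- (cs - 250 + 1):cs  # samples at 1 kHz; onset sample excluded
  bmean <- mean(envelope[base_idx])
  bsd <- sd(envelope[base_idx])
  lo <- cs + config$cr_window_start_ms + 1   # 1-based index of window start
  hi <- w_end                                 # last index before w_end
  for (i in lo:hi) {
    left <- if (i == 1) -Inf else envelope[i - 1]
    right <- if (i == length(envelope)) -Inf else envelope[i + 1]
    if (!(envelope[i] > left && envelope[i] >= right)) next
    amp <- envelope[i]
    s_f <- (amp - envelope[i - 25]) / 25
    s_b <- (envelope[i + 25] - amp) / 25
    ok <- amp > config$amplitude_threshold &&
      amp > bmean + config$baseline_k * bsd &&
      min(s_f, abs(s_b)) >= config$min_slope
    if (ok) return(TRUE)
  }
  FALSE
}

# Brute-force complete-linkage agglomeration for tiny n: merge the pair of
# clusters with the smallest maximum pairwise distance, recording the
# partition at every k.
brute_force_complete_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- max(D[clusters[[i]], clusters[[j]], drop = FALSE])
      if (d < best[1]) best <- c(d, i, j)
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
    labs <- integer(n)
    for (g in seq_along(clusters)) labs[clusters[[g]]] <- g
    partitions[[length(clusters)]] <- labs
  }
  partitions
}

# partitions equal up to label renaming (same co-membership relation)
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# Classical balanced two-between-factor mixed ANOVA sums of squares computed
# from cell means (no covariate). Y: subjects x k; a, b: factor vectors.
balanced_mixed_anova_oracle <- function(Y, a, b) {
  n <- nrow(Y)
  k <- ncol(Y)
  grand <- mean(Y)
  subj_mean <- rowMeans(Y)
  cell <- interaction(a, b)
  n_c <- table(cell)[1]
  mean_a <- tapply(subj_mean, a, mean)
  mean_b <- tapply(subj_mean, b, mean)
  mean_ab <- tapply(subj_mean, cell, mean)
  ss_a <- k * 2 * n_c * sum((mean_a - grand)^2)
  ss_b <- k * 2 * n_c * sum((mean_b - grand)^2)
  ss_cells <- k * n_c * sum((mean_ab - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_berr <- k * sum((subj_mean - ave(subj_mean, cell))^2)
  col_mean <- colMeans(Y)
  ss_block <- n * sum((col_mean - grand)^2)
  # cell-by-block means
  cb <- matrix(0, nlevels(cell), k)
  for (ci in seq_len(nlevels(cell))) {
    cb[ci, ] <- colMeans(Y[cell == levels(cell)[ci], , drop = FALSE])
  }
  a_of_cell <- tapply(as.character(a), cell, function(x) x[1])
  b_of_cell <- tapply(as.character(b), cell, function(x) x[1])
  ab_mean <- matrix(0, nlevels(cell), k)
  for (ci in seq_len(nlevels(cell))) {
    ab_mean[ci, ] <- mean_ab[levels(cell)[ci]] + col_mean - grand
  }
  a_block <- rowsum(cb, a_of_cell) / 2  # mean over b within each a level
  b_block <- rowsum(cb, b_of_cell) / 2
  ss_a_block <- 2 * n_c * sum((sweep(sweep(a_block, 1, mean_a), 2,
                                     col_mean) + grand)^2)
  ss_b_block <- 2 * n_c * sum((sweep(sweep(b_block, 1, mean_b), 2,
                                     col_mean) + grand)^2)
  ss_cells_block <- n_c * sum((cb - ab_mean)^2)
  ss_ab_block <- ss_cells_block - ss_a_block - ss_b_block
  ss_total <- sum((Y - grand)^2)
  ss_werr <- ss_total - ss_a - ss_b - ss_ab - ss_berr -
    ss_block - ss_a_block - ss_b_block - ss_ab_block
  df_berr <- n - nlevels(cell)
  df_werr <- (k - 1) * df_berr
  list(
    F_a = unname((ss_a / 1) / (ss_berr / df_berr)),
    F_b = unname((ss_b / 1) / (ss_berr / df_berr)),
    F_ab = unname((ss_ab / 1) / (ss_berr / df_berr)),
    F_block = unname((ss_block / (k - 1)) / (ss_werr / df_werr)),
    F_a_block = unname((ss_a_block / (k - 1)) / (ss_werr / df_werr)),
    F_b_block = unname((ss_b_block / (k - 1)) / (ss_werr / df_werr)),
    F_ab_block = unname((ss_ab_block / (k - 1)) / (ss_werr / df_werr))
  )
}

# Gaussian-noise learning matrix with three planted profiles (constructed
# separation), for planted-partition recovery checks
planted_learning_matrix <- function(n_per = c(14, 15, 25), sd_within = 10,
                                    means = c(HIGH = 80, MID = 45, LOW = 10)) {
  labs <- rep(names(means), n_per)
  X <- t(vapply(labs, function(l) rnorm(9, means[[l]], sd_within),
                numeric(9)))
  colnames(X) <- c(paste0("w1b", 1:6), paste0("w2b", 1:3))
  rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  list(X = X, labels = labs)
}
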