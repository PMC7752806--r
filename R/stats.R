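#' Orthonormal within-subject contrast matrix
#'
#' Helmert-type contrasts orthonormalised so that the k columns of the
#' repeated measures are projected onto k-1 orthonormal directions, each
#' orthogonal to the unit vector. Used by the sphericity statistics and the
#' within-subject sums of squares.
#'
#' @param k Number of within-subject levels.
#' @return k x (k-1) matrix with orthonormal columns.
#' @keywords internal
orthonormal_contrasts <- function(k) {
  M <- stats::contr.helmert(k)
  sweep(M, 2, sqrt(colSums(M^2)), "/")
}

# residual cross-product matrix of the contrast-projected data, and its
# error degrees of freedom, given a between-subject design matrix X
contrast_covariance <- function(Y, X = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  k <- ncol(Y)
  if (k < 2L) stop("need at least 2 within-subject levels")
  if (is.null(X)) X <- matrix(1, n, 1)
  if (n <= ncol(X) + k - 1L) stop("insufficient subjects for k levels")
  M <- orthonormal_contrasts(k)
  Yw <- Y %*% M
  qr_x <- qr(X)
  E <- qr.resid(qr_x, Yw)
  n_e <- n - qr_x$rank
  list(S = crossprod(E) / n_e, n_e = n_e, k = k)
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance matrix of the orthonormal within-subject
#' contrasts is proportional to the identity.
#' `W = det(S) / (tr(S)/(k-1))^(k-1)` on the contrast covariance `S`
#' estimated from residuals of the between-subject model, with the usual
#' chi-square approximation. With k = 2 there is a single contrast and
#' sphericity holds trivially (W = 1, p = 1).
#'
#' @param Y Subjects x k matrix of repeated measures.
#' @param X Optional between-subject design matrix (defaults to an
#'   intercept); residual df are reduced accordingly.
#' @return List of class `mauchly_result`: `W`, `chi_sq`, `df`, `p`.
#' @export
mauchly_test <- function(Y, X = NULL) {
  cc <- contrast_covariance(Y, X)
  k <- cc$k
  d <- k - 1L
  df <- as.integer(k * d / 2 - 1)
  if (k == 2L) {
    return(structure(list(W = 1, chi_sq = 0, df = 0L, p = 1),
                     class = "mauchly_result"))
  }
  S <- cc$S
  W <- det(S) / (sum(diag(S)) / d)^d
  W <- min(max(W, .Machine$double.xmin), 1)
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * cc$n_e)
  chi_sq <- -rho * cc$n_e * log(W)
  p <- stats::pchisq(chi_sq, df, lower.tail = FALSE)
  structure(list(W = W, chi_sq = chi_sq, df = df, p = p),
            class = "mauchly_result")
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity estimate `(tr S)^2 / ((k-1) tr(S^2))` on the contrast
#' covariance, clipped to its theoretical range `[1/(k-1), 1]`. Used to
#' shrink repeated-measures degrees of freedom when sphericity is violated.
#'
#' @inheritParams mauchly_test
#' @return Numeric epsilon.
#' @export
gg_epsilon <- function(Y, X = NULL) {
  cc <- contrast_covariance(Y, X)
  d <- cc$k - 1L
  S <- cc$S
  eps <- sum(diag(S))^2 / (d * sum(S * S))
  min(max(eps, 1 / d), 1)
}

# Type III sums of squares for every term of a between-subject model with
# sum-to-zero factor coding. Returns per-term SS/df plus residual SS/df.
# y may be a matrix; SS are then summed across columns (used for the
# within-subject strata).
type3_ss <- function(y, X, assign, labels) {
  y <- as.matrix(y)
  fit_rss <- function(Xm) {
    qr_x <- qr(Xm)
    sum(qr.resid(qr_x, y)^2)
  }
  rss_full <- fit_rss(X)
  terms_idx <- sort(unique(assign[assign > 0]))
  ss <- vapply(terms_idx, function(t) {
    fit_rss(X[, assign != t, drop = FALSE]) - rss_full
  }, numeric(1))
  df <- vapply(terms_idx, function(t) sum(assign == t), numeric(1))
  # the intercept's SS is used for the within-subject main effect stratum
  ss0 <- fit_rss(X[, assign != 0, drop = FALSE]) - rss_full
  list(labels = labels[terms_idx], ss = ss, df = df,
       ss_intercept = ss0, rss = rss_full,
       df_resid = nrow(y) - qr(X)$rank)
}

#' Mixed repeated-measures ANCOVA
#'
#' Fits the classical univariate mixed-design analysis: between-subject
#' factors (crossed, sum-to-zero coded, Type III sums of squares) and an
#' optional mean-centered continuous covariate are tested against the
#' between-subject error; the repeated-measures factor and its interactions
#' with every between term are tested against the subject-by-measure error
#' stratum, with Greenhouse-Geisser corrected degrees of freedom reported for
#' every within effect. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` within each stratum.
#'
#' The covariate enters the between-subject model only; its interaction with
#' the repeated factor appears as a `block:<covariate>` row in the within
#' stratum (part of the standard decomposition) but the error term is not
#' reduced further. With n subjects, two between factors and one covariate
#' the between-error df is n - 5, and the within-error df is (k-1)(n - 5).
#'
#' @param Y Subjects x k matrix of repeated measures (block CR percentages).
#' @param between Data frame of between-subject factors (columns coerced to
#'   factors), e.g. PTSD and mTBI flags.
#' @param covariate Optional numeric covariate (e.g. age); mean-centered
#'   internally.
#' @param sphericity `"mauchly"` applies the Greenhouse-Geisser correction
#'   when Mauchly's test rejects at `alpha`; `"always"` / `"never"` force it.
#' @param alpha Mauchly decision level.
#' @return Data frame of class `rm_ancova` with one row per effect:
#'   `effect, stratum, ss, df_num, df_den, F, p_uncorrected, gg_epsilon,
#'   df_num_gg, df_den_gg, p_gg, p, partial_eta_sq`; `p` is the policy-chosen
#'   p-value. Attributes: `mauchly` (the [mauchly_test()] result),
#'   `gg_applied`, `error_ss`.
#' @export
mixed_rm_ancova <- function(Y, between, covariate = NULL,
                            sphericity = c("mauchly", "always", "never"),
                            alpha = 0.05) {
  sphericity <- match.arg(sphericity)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  k <- ncol(Y)
  if (k < 2L) stop("need at least 2 repeated measures")
  between <- as.data.frame(between)
  for (nm in names(between)) between[[nm]] <- factor(between[[nm]])
  if (any(vapply(between, nlevels, 1L) < 2L)) {
    stop("each between factor needs at least 2 observed levels")
  }
  cells <- interaction(between, drop = FALSE)
  if (any(table(cells) < 2L)) {
    stop("design-deficient: every between-subject cell needs >= 2 subjects")
  }
  dat <- between
  rhs <- paste(names(between), collapse = " * ")
  if (!is.null(covariate)) {
    if (stats::sd(covariate) == 0) stop("covariate is constant (rank-deficient)")
    dat$.cov <- as.numeric(covariate) - mean(covariate)
    rhs <- paste(".cov", rhs, sep = " + ")
  }
  mf <- stats::model.frame(stats::as.formula(paste("~", rhs)), dat)
  contr <- lapply(between, function(x) "contr.sum")
  X <- stats::model.matrix(attr(mf, "terms"), mf,
                           contrasts.arg = contr)
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(mf), "term.labels")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient between-subject design")
  p_par <- ncol(X)
  if (n <= p_par) stop("insufficient subjects for the between design")

  # between stratum: projection of each subject onto the constant direction
  yb <- rowMeans(Y) * sqrt(k)
  bt <- type3_ss(yb, X, assign, labels)
  # within stratum: orthonormal contrast projections
  M <- orthonormal_contrasts(k)
  Yw <- Y %*% M
  wt <- type3_ss(Yw, X, assign, labels)

  # at toy scale (n_e < k - 1) the contrast covariance is singular and
  # sphericity cannot be estimated; fall back to uncorrected df
  eps <- tryCatch(gg_epsilon(Y, X), error = function(e) NA_real_)
  mau <- tryCatch(mauchly_test(Y, X), error = function(e) {
    structure(list(W = NA_real_, chi_sq = NA_real_, df = NA_integer_,
                   p = NA_real_), class = "mauchly_result")
  })
  if (is.na(eps)) {
    warning("too few subjects to estimate sphericity; uncorrected df used")
    eps <- 1
  }
  gg_applied <- switch(sphericity,
                       always = TRUE, never = FALSE,
                       mauchly = k > 2L && !is.na(mau$p) && mau$p < alpha)

  mk_rows <- function(effect, stratum, ss, df_num, ss_err, df_err, e) {
    ms_err <- ss_err / df_err
    F <- (ss / df_num) / ms_err
    p_unc <- stats::pf(F, df_num, df_err, lower.tail = FALSE)
    p_gg <- stats::pf(F, df_num * e, df_err * e, lower.tail = FALSE)
    data.frame(effect = effect, stratum = stratum, ss = ss,
               df_num = df_num, df_den = df_err, F = F,
               p_uncorrected = p_unc,
               gg_epsilon = if (stratum == "within") e else NA_real_,
               df_num_gg = if (stratum == "within") df_num * e else NA_real_,
               df_den_gg = if (stratum == "within") df_err * e else NA_real_,
               p_gg = if (stratum == "within") p_gg else NA_real_,
               p = if (stratum == "within" && gg_applied) p_gg else p_unc,
               partial_eta_sq = ss / (ss + ss_err),
               stringsAsFactors = FALSE)
  }

  rows <- list()
  cov_first <- !is.null(covariate)
  for (i in seq_along(bt$labels)) {
    eff <- if (bt$labels[i] == ".cov") "age" else bt$labels[i]
    rows[[length(rows) + 1L]] <-
      mk_rows(eff, "between", bt$ss[i], bt$df[i], bt$rss, bt$df_resid, 1)
  }
  rows[[length(rows) + 1L]] <-
    mk_rows("block", "within", wt$ss_intercept, k - 1L,
            wt$rss, (k - 1L) * wt$df_resid, eps)
  for (i in seq_along(wt$labels)) {
    eff <- if (wt$labels[i] == ".cov") "block:age" else
      paste0("block:", wt$labels[i])
    rows[[length(rows) + 1L]] <-
      mk_rows(eff, "within", wt$ss[i], wt$df[i] * (k - 1L),
              wt$rss, (k - 1L) * wt$df_resid, eps)
  }
  out <- do.call(rbind, rows)
  structure(out, mauchly = mau, gg_applied = gg_applied,
            error_ss = c(between = bt$rss, within = wt$rss),
            class = c("rm_ancova", "data.frame"))
}

#' Bonferroni adjustment
#'
#' `p -> min(1, p * m)`.
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param m Number of comparisons (defaults to `length(pvals)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  pmin(1, pvals * m)
}

#' Helmert contrasts over three ordered groups
#'
#' For groups ordered (Low, Mid, High): contrast 1 compares Low against the
#' mean of Mid and High (weights 1, -1/2, -1/2); contrast 2 compares Mid
#' against High (weights 0, 1, -1). Each contrast is tested as a linear
#' contrast on the pooled one-way ANOVA error term with N - 3 df.
#'
#' @param values Numeric outcome.
#' @param groups Factor (or coercible) with exactly 3 levels in the order
#'   Low, Mid, High.
#' @return Data frame with one row per contrast: `contrast, estimate, se, t,
#'   df, p`.
#' @export
helmert_contrasts <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 3L) stop("exactly 3 ordered groups required")
  ns <- table(groups)
  if (any(ns < 2L)) stop("each group needs n >= 2")
  means <- tapply(values, groups, mean)
  N <- length(values)
  sse <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  df <- N - 3L
  mse <- sse / df
  W <- rbind(c(1, -0.5, -0.5), c(0, 1, -1))
  rownames(W) <- c("first_vs_rest", "second_vs_third")
  out <- lapply(rownames(W), function(cn) {
    w <- W[cn, ]
    est <- sum(w * means)
    se <- sqrt(mse * sum(w^2 / as.numeric(ns)))
    t <- est / se
    data.frame(contrast = cn, estimate = est, se = se, t = t, df = df,
               p = 2 * stats::pt(-abs(t), df), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance and `n1 + n2 - 2` df (the convention
#' matching integer published df), two-sided.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return List: `t`, `df`, `p`, `mean_diff`.
#' @export
two_sample_t <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each sample needs n >= 2")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean(x) - mean(y)) / se
  df <- n1 + n2 - 2L
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_diff = mean(x) - mean(y))
}

#' One-way ANOVA with partial eta squared
#'
#' @param values Numeric outcome.
#' @param groups Grouping factor (>= 2 groups, each n >= 2).
#' @return List: `F`, `df1`, `df2`, `p`, `partial_eta_sq`, `group_means`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs n >= 2")
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- table(groups)
  ssb <- sum(as.numeric(ns) * (means - grand)^2)
  ssw <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE),
       partial_eta_sq = ssb / (ssb + ssw),
       group_means = means)
}
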