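#' Squared Euclidean distance matrix
#'
#' `D[i, j] = sum_b (X[i, b] - X[j, b])^2`, the dissimilarity used for the
#' learning-series clustering. Inputs are raw block CR percentages; no
#' standardisation is applied since all columns share units.
#'
#' @param X Numeric matrix (subjects x blocks), no missing values.
#' @return Symmetric matrix with zero diagonal.
#' @export
sq_euclidean_matrix <- function(X) {
  if (anyNA(X)) stop("missing values in the learning matrix")
  as.matrix(stats::dist(X, method = "euclidean"))^2
}

#' Complete-linkage agglomerative clustering
#'
#' Furthest-neighbour agglomeration on a precomputed dissimilarity matrix:
#' the distance between two clusters is the maximum pairwise member
#' dissimilarity. Returns the full merge tree; heights are non-decreasing
#' along the merge sequence (complete linkage is monotone).
#'
#' @param D Dissimilarity matrix (e.g. [sq_euclidean_matrix()] output) or
#'   `dist` object, n >= 2.
#' @return An `hclust` merge tree.
#' @export
complete_linkage <- function(D) {
  d <- stats::as.dist(D)
  if (attr(d, "Size") < 2L) stop("need at least 2 subjects")
  stats::hclust(d, method = "complete")
}

#' Cut a merge tree into k clusters
#'
#' @param tree An `hclust` tree from [complete_linkage()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer cluster labels.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k out of range")
  stats::cutree(tree, k = k)
}

# ---- internal cluster validity indices ------------------------------------
# All indices operate on the raw data X (Euclidean geometry) and a label
# vector. W/B denote pooled within/between-cluster sums of squares.

cluster_ss <- function(X, labels) {
  X <- as.matrix(X)
  grand <- colMeans(X)
  tss <- sum(sweep(X, 2, grand)^2)
  wss <- 0
  for (g in unique(labels)) {
    Xi <- X[labels == g, , drop = FALSE]
    wss <- wss + sum(sweep(Xi, 2, colMeans(Xi))^2)
  }
  list(wss = wss, bss = tss - wss, tss = tss)
}

index_calinski_harabasz <- function(X, labels) {
  n <- nrow(X)
  k <- length(unique(labels))
  ss <- cluster_ss(X, labels)
  (ss$bss / (k - 1)) / (ss$wss / (n - k))
}

index_silhouette <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(D)
  ks <- unique(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(ks[ks != labels[i]],
                    function(g) mean(D[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

index_dunn <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  ks <- unique(labels)
  diam <- max(vapply(ks, function(g) {
    d <- D[labels == g, labels == g, drop = FALSE]
    if (length(d) == 1L) 0 else max(d)
  }, numeric(1)))
  sep <- Inf
  for (i in seq_along(ks)) for (j in seq_along(ks)) {
    if (i < j) {
      sep <- min(sep, min(D[labels == ks[i], labels == ks[j], drop = FALSE]))
    }
  }
  if (diam == 0) Inf else sep / diam
}

index_davies_bouldin <- function(X, labels) {
  X <- as.matrix(X)
  ks <- sort(unique(labels))
  cent <- t(vapply(ks, function(g) colMeans(X[labels == g, , drop = FALSE]),
                   numeric(ncol(X))))
  scatter <- vapply(seq_along(ks), function(i) {
    Xi <- X[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xi, 2, cent[i, ])^2)))
  }, numeric(1))
  r <- vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) {
      m <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      (scatter[i] + scatter[j]) / m
    }, numeric(1)))
  }, numeric(1))
  mean(r)
}

index_c <- function(X, labels) {
  D <- stats::dist(X)
  d <- as.numeric(D)
  pair_within <- as.numeric(stats::dist(as.numeric(factor(labels)))) == 0
  nw <- sum(pair_within)
  if (nw == 0L) return(NA_real_)
  s <- sum(d[pair_within])
  ds <- sort(d)
  s_min <- sum(ds[seq_len(nw)])
  s_max <- sum(ds[seq(length(ds) - nw + 1L, length(ds))])
  if (s_max == s_min) return(0)
  (s - s_min) / (s_max - s_min)
}

index_mcclain_rao <- function(X, labels) {
  d <- as.numeric(stats::dist(X))
  pair_within <- as.numeric(stats::dist(as.numeric(factor(labels)))) == 0
  nw <- sum(pair_within)
  nb <- sum(!pair_within)
  if (nw == 0L || nb == 0L) return(NA_real_)
  (sum(d[pair_within]) / nw) / (sum(d[!pair_within]) / nb)
}

index_point_biserial <- function(X, labels) {
  d <- as.numeric(stats::dist(X))
  pair_within <- as.numeric(stats::dist(as.numeric(factor(labels)))) == 0
  nw <- sum(pair_within)
  nb <- sum(!pair_within)
  nt <- nw + nb
  if (nw == 0L || nb == 0L) return(NA_real_)
  sd_all <- stats::sd(d) * sqrt((nt - 1) / nt)
  (mean(d[!pair_within]) - mean(d[pair_within])) *
    sqrt(nw * nb / nt^2) / sd_all
}

index_ball_hall <- function(X, labels) {
  cluster_ss(X, labels)$wss / length(unique(labels))
}

index_ratkowsky_lance <- function(X, labels) {
  X <- as.matrix(X)
  k <- length(unique(labels))
  grand <- colMeans(X)
  ratios <- vapply(seq_len(ncol(X)), function(j) {
    tssj <- sum((X[, j] - grand[j])^2)
    wssj <- sum(vapply(unique(labels), function(g) {
      xj <- X[labels == g, j]
      sum((xj - mean(xj))^2)
    }, numeric(1)))
    if (tssj == 0) 0 else sqrt((tssj - wssj) / tssj)
  }, numeric(1))
  mean(ratios) / sqrt(k)
}

#' Evaluate the validity-index panel over candidate cluster counts
#'
#' Computes ten internal cluster-validity indices for each candidate k and
#' lets each index vote for its preferred k according to its own optimality
#' rule: maximised (Calinski-Harabasz, silhouette, Dunn, point-biserial,
#' Ratkowsky-Lance), minimised (Davies-Bouldin, C-index, McClain-Rao), or
#' largest change between successive k (Ball-Hall, Hartigan). The selected
#' cluster count is the plurality winner of these votes (see
#' [majority_rule_k()]); the panel is reported in full so results are
#' auditable.
#'
#' @param X Learning matrix (subjects x blocks).
#' @param k_range Candidate cluster counts, within `[2, n - 1]`.
#' @param tree Optional precomputed [complete_linkage()] tree of
#'   [sq_euclidean_matrix()]`(X)`.
#' @return List of class `validity_panel`: `votes` (named integer, one per
#'   index), `values` (index x k matrix), `k_range`.
#' @export
validity_indices <- function(X, k_range = 2:8, tree = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > n - 1L) {
    stop("k_range must lie within [2, n-1]")
  }
  if (is.null(tree)) tree <- complete_linkage(sq_euclidean_matrix(X))
  k_eval <- sort(unique(c(k_range, max(k_range) + 1L)))
  k_eval <- k_eval[k_eval <= n - 1L]
  labels_by_k <- lapply(k_eval, function(k) cut_tree(tree, k))
  names(labels_by_k) <- k_eval

  simple <- list(
    calinski_harabasz = list(fn = index_calinski_harabasz, rule = "max"),
    silhouette = list(fn = index_silhouette, rule = "max"),
    dunn = list(fn = index_dunn, rule = "max"),
    davies_bouldin = list(fn = index_davies_bouldin, rule = "min"),
    c_index = list(fn = index_c, rule = "min"),
    mcclain_rao = list(fn = index_mcclain_rao, rule = "min"),
    point_biserial = list(fn = index_point_biserial, rule = "max"),
    ratkowsky_lance = list(fn = index_ratkowsky_lance, rule = "max")
  )

  values <- matrix(NA_real_, nrow = length(simple) + 2L,
                   ncol = length(k_range),
                   dimnames = list(c(names(simple), "ball_hall", "hartigan"),
                                   k_range))
  votes <- integer(0)
  for (nm in names(simple)) {
    v <- vapply(as.character(k_range), function(kk) {
      labs <- labels_by_k[[kk]]
      if (length(unique(labs)) < 2L) return(NA_real_)
      simple[[nm]]$fn(X, labs)
    }, numeric(1))
    values[nm, ] <- v
    if (all(is.na(v))) {
      warning("index ", nm, " produced no valid value; vote skipped")
      next
    }
    pick <- if (simple[[nm]]$rule == "max") which.max(v) else which.min(v)
    votes[nm] <- k_range[pick]
  }

  # elbow-style indices need W at neighbouring k
  wss_k <- vapply(as.character(k_eval), function(kk) {
    cluster_ss(X, labels_by_k[[kk]])$wss
  }, numeric(1))
  wss_1 <- cluster_ss(X, rep(1L, n))$wss
  wss_at <- function(k) {
    if (k == 1L) wss_1 else wss_k[as.character(k)]
  }
  bh <- vapply(k_range, function(k) wss_at(k) / k, numeric(1))
  values["ball_hall", ] <- bh
  bh_prev <- vapply(k_range - 1L, function(k) wss_at(k) / max(k, 1L),
                    numeric(1))
  votes["ball_hall"] <- k_range[which.max(bh_prev - bh)]
  hart <- vapply(k_range, function(k) {
    w1 <- wss_at(k)
    w2 <- wss_at(k + 1L)
    if (is.na(w2) || w2 == 0) return(NA_real_)
    (w1 / w2 - 1) * (n - k - 1)
  }, numeric(1))
  values["hartigan", ] <- hart
  hart_prev <- vapply(k_range - 1L, function(k) {
    if (k < 1L) return(NA_real_)
    w1 <- wss_at(k)
    w2 <- wss_at(k + 1L)
    if (is.na(w2) || w2 == 0) return(NA_real_)
    (w1 / w2 - 1) * (n - k - 1)
  }, numeric(1))
  diffs <- hart_prev - hart
  if (all(is.na(diffs))) {
    warning("hartigan index produced no valid value; vote skipped")
  } else {
    votes["hartigan"] <- k_range[which.max(diffs)]
  }

  structure(list(votes = votes, values = values, k_range = k_range),
            class = "validity_panel")
}

#' Majority-rule selection of the cluster count
#'
#' The k preferred by the plurality of validity-index votes; ties are broken
#' toward the smaller k (parsimony).
#'
#' @param votes Integer vector of per-index preferred k (the `votes` element
#'   of [validity_indices()], or a bare vector).
#' @return Selected k.
#' @export
majority_rule_k <- function(votes) {
  if (inherits(votes, "validity_panel")) votes <- votes$votes
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0L) stop("no valid votes")
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}

#' Name clusters by learning proficiency
#'
#' Ranks clusters by grand-mean CR percentage: with k = 3 the names are
#' HIGH, MID, LOW in descending order; other k fall back to RANK1..RANKk.
#' Ties in cluster means are broken by cluster id and flagged with a
#' warning.
#'
#' @param X Learning matrix.
#' @param labels Integer cluster labels.
#' @return Character vector of per-subject profile names, with a `map`
#'   attribute (cluster id -> name) and `cluster_means` attribute.
#' @export
label_profiles <- function(X, labels) {
  ks <- sort(unique(labels))
  means <- vapply(ks, function(g) mean(X[labels == g, , drop = FALSE]),
                  numeric(1))
  if (anyDuplicated(round(means, 12))) {
    warning("tied cluster means; ranking ties broken by cluster id")
  }
  ord <- order(means, decreasing = TRUE)
  nm <- if (length(ks) == 3L) c("HIGH", "MID", "LOW") else
    paste0("RANK", seq_along(ks))
  map <- stats::setNames(nm, ks[ord])
  out <- unname(map[as.character(labels)])
  structure(out, map = map,
            cluster_means = stats::setNames(means[ord], nm))
}

#' Cluster a cohort's learning series into behavioural subtypes
#'
#' Complete-linkage clustering on squared Euclidean distances between
#' learning series. With `inputs = "all"` the series are all nine blocks and
#' the cluster count is selected by majority rule over the validity-index
#' panel; with `inputs = "week2"` only the three Week-2 blocks enter and a
#' three-group solution is specified a priori (mirroring the design where
#' the reduced-input analysis fixes k = 3 for comparability).
#'
#' @param series Learning matrix with columns `w1b1..w1b6, w2b1..w2b3` (see
#'   [assemble_learning_matrix()]).
#' @param inputs `"all"` or `"week2"`.
#' @param k_range Candidate cluster counts for majority-rule selection.
#' @param k Override the cluster count (skips the vote).
#' @return List of class `cluster_solution`: `k`, `labels`, `profile`
#'   (per-subject names), `tree`, `panel` (or `NULL` when k was specified),
#'   `inputs`, `X`.
#' @export
subtype_cohort <- function(series, inputs = c("all", "week2"),
                           k_range = 2:8, k = NULL) {
  inputs <- match.arg(inputs)
  X <- as.matrix(series)
  if (inputs == "week2") {
    X <- X[, c("w2b1", "w2b2", "w2b3"), drop = FALSE]
    if (is.null(k)) k <- 3L
  }
  tree <- complete_linkage(sq_euclidean_matrix(X))
  panel <- NULL
  if (is.null(k)) {
    k_range <- k_range[k_range <= nrow(X) - 1L]
    panel <- validity_indices(X, k_range, tree)
    k <- majority_rule_k(panel)
  }
  labels <- cut_tree(tree, k)
  profile <- label_profiles(X, labels)
  structure(list(k = k, labels = labels, profile = profile, tree = tree,
                 panel = panel, inputs = inputs, X = X),
            class = "cluster_solution")
}

#' Compare psychological measures across learning profiles
#'
#' One-way ANOVAs (with partial eta squared) on PCL-5 total and cluster
#' B/C/D/E scores, PHQ-8 total and AMBI total across the learning profiles,
#' Helmert contrasts over the ordered profiles (Low vs the more proficient
#' groups; Mid vs High) for each measure, and PTSD+/MDD+/BI proportions per
#' profile.
#'
#' @param profile Per-subject profile names ([label_profiles()] output), in
#'   the same subject order as `scored`.
#' @param scored Scored-subject data frame ([score_subjects()] output).
#' @return List of class `profile_comparison`: `anova` (data frame per
#'   measure), `contrasts` (data frame per measure x contrast),
#'   `proportions` (profile x flag), `n` (per-profile counts).
#' @export
compare_profiles <- function(profile, scored) {
  stopifnot(length(profile) == nrow(scored))
  lv <- intersect(c("LOW", "MID", "HIGH"), unique(profile))
  grp <- factor(profile, levels = if (length(lv) == length(unique(profile)))
    lv else sort(unique(profile)))
  measures <- c(pcl_total = "pcl_total", cluster_b = "pcl_cluster_b",
                cluster_c = "pcl_cluster_c", cluster_d = "pcl_cluster_d",
                cluster_e = "pcl_cluster_e", phq_total = "phq_total",
                ambi_total = "ambi_total")
  degenerate <- names(which(table(grp) < 2L))
  an <- lapply(names(measures), function(m) {
    a <- tryCatch(one_way_anova(scored[[measures[m]]], grp),
                  error = function(e) NULL)
    if (is.null(a)) {
      data.frame(measure = m, F = NA_real_, df1 = NA_integer_,
                 df2 = NA_integer_, p = NA_real_,
                 partial_eta_sq = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(measure = m, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p,
                 partial_eta_sq = a$partial_eta_sq, stringsAsFactors = FALSE)
    }
  })
  an <- do.call(rbind, an)
  cons <- NULL
  if (nlevels(grp) == 3L && all(table(grp) >= 2L)) {
    cons <- do.call(rbind, lapply(names(measures), function(m) {
      hc <- helmert_contrasts(scored[[measures[m]]], grp)
      hc$measure <- m
      hc
    }))
  }
  flags <- c(ptsd_positive = "ptsd_positive",
             mdd_positive = "mdd_aggregate_positive",
             bi_positive = "bi_positive")
  props <- t(vapply(levels(grp), function(g) {
    vapply(flags, function(fl) mean(scored[[fl]][grp == g]), numeric(1))
  }, numeric(length(flags))))
  if (length(degenerate) > 0L) {
    message("degenerate profiles (n < 2): ",
            paste(degenerate, collapse = ", "))
  }
  structure(list(anova = an, contrasts = cons, proportions = props,
                 n = table(grp), degenerate = degenerate),
            class = "profile_comparison")
}
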