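test_that("squared Euclidean distances match the double-loop definition", {
  X <- rbind(rep(0, 9), rep(10, 9))
  D <- sq_euclidean_matrix(X)
  expect_equal(D[1, 2], 900)
  expect_equal(unname(diag(D)), rep(0, 2))
  set.seed(1)
  X2 <- matrix(rnorm(5 * 9), 5, 9)
  D2 <- sq_euclidean_matrix(X2)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(D2[i, j], sum((X2[i, ] - X2[j, ])^2), tolerance = 1e-9)
  }
  expect_error(sq_euclidean_matrix(rbind(c(1, NA), c(0, 0))), "missing")
})

test_that("complete linkage reproduces hand-traced merges", {
  D2 <- matrix(c(0, 4, 4, 0), 2, 2)
  t2 <- complete_linkage(D2)
  expect_equal(as.numeric(t2$height), 4)

  # 1-D points {0, 1, 10} on squared distances: merge {0,1} at 1, then all
  # at squared distance 100
  X <- matrix(c(0, 1, 10), ncol = 1)
  tr <- complete_linkage(sq_euclidean_matrix(X))
  expect_equal(tr$height, c(1, 100))
  labs <- cut_tree(tr, 2)
  expect_true(same_partition(labs, c(1, 1, 2)))
  expect_equal(length(unique(cut_tree(tr, 1))), 1L)
  expect_equal(length(unique(cut_tree(tr, 3))), 3L)
  expect_error(cut_tree(tr, 0), "range")
  expect_true(all(diff(tr$height) >= 0))
})

test_that("linkage partitions match the brute-force oracle for n <= 7", {
  set.seed(21)
  for (n in 4:7) {
    for (rep_i in 1:10) {
      X <- matrix(rnorm(n * 3), n, 3)
      D <- sq_euclidean_matrix(X)
      tree <- complete_linkage(D)
      parts <- brute_force_complete_linkage(D)
      for (k in 1:n) {
        expect_true(same_partition(cut_tree(tree, k), parts[[k]]),
                    label = sprintf("n=%d rep=%d k=%d", n, rep_i, k))
      }
    }
  }
})

test_that("permuting subjects permutes labels identically", {
  set.seed(5)
  X <- planted_learning_matrix()$X
  perm <- sample(nrow(X))
  l1 <- cut_tree(complete_linkage(sq_euclidean_matrix(X)), 3)
  l2 <- cut_tree(complete_linkage(sq_euclidean_matrix(X[perm, ])), 3)
  expect_true(same_partition(l1[perm], l2))
})

test_that("rescaling the learning matrix changes no partition", {
  set.seed(6)
  X <- matrix(rnorm(20 * 9, 40, 15), 20, 9)
  t1 <- complete_linkage(sq_euclidean_matrix(X))
  t2 <- complete_linkage(sq_euclidean_matrix(X * 3.7))
  for (k in 2:6) {
    expect_true(same_partition(cut_tree(t1, k), cut_tree(t2, k)))
  }
})

test_that("validity indices agree on two well-separated clouds", {
  set.seed(7)
  X <- rbind(matrix(rnorm(20 * 9, 0, 1), 20, 9),
             matrix(rnorm(20 * 9, 10, 1), 20, 9))
  panel <- validity_indices(X, k_range = 2:6)
  expect_true(all(panel$votes == 2))
  expect_equal(majority_rule_k(panel), 2L)
})

test_that("index values match closed forms on constructed instances", {
  # Calinski-Harabasz on a hand-computable 1-D instance
  X <- matrix(c(0, 2, 10, 12), ncol = 1)
  labels <- c(1, 1, 2, 2)
  ssw <- 2 + 2          # each cluster: (0-1)^2+(2-1)^2 etc.
  ssb <- 2 * (1 - 6)^2 + 2 * (11 - 6)^2
  ch_ref <- (ssb / 1) / (ssw / 2)
  expect_equal(blinkcr:::index_calinski_harabasz(X, labels), ch_ref,
               tolerance = 1e-9)
  # silhouette of a perfect partition (zero within-cluster distances)
  Xp <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  expect_equal(blinkcr:::index_silhouette(Xp, rep(1:2, each = 3)), 1)
  # silhouette cross-check against the cluster package
  skip_if_not_installed("cluster")
  set.seed(8)
  Xs <- matrix(rnorm(30), 15, 2)
  ls <- rep(1:3, each = 5)
  sil <- cluster::silhouette(ls, dist(Xs))
  expect_equal(blinkcr:::index_silhouette(Xs, ls),
               mean(sil[, "sil_width"]), tolerance = 1e-9)
})

test_that("majority rule takes the plurality and breaks ties downward", {
  expect_equal(majority_rule_k(c(2L, rep(3L, 5), 4L, 4L)), 3L)
  expect_equal(majority_rule_k(c(2L, 2L, 2L, 3L, 3L, 3L)), 2L)
  expect_equal(majority_rule_k(c(a = 4L)), 4L)
  expect_error(majority_rule_k(integer(0)), "votes")
})

test_that("profiles are named by descending mean CR%", {
  X <- rbind(matrix(60, 4, 9), matrix(35, 4, 9), matrix(10, 4, 9))
  labels <- rep(c(2, 3, 1), each = 4)
  prof <- label_profiles(X, labels)
  expect_equal(unique(prof[1:4]), "HIGH")
  expect_equal(unique(prof[5:8]), "MID")
  expect_equal(unique(prof[9:12]), "LOW")
  means <- attr(prof, "cluster_means")
  expect_equal(unname(means), c(60, 35, 10))
  expect_warning(label_profiles(rbind(matrix(5, 2, 9), matrix(5, 2, 9)),
                                rep(1:2, each = 2)), "tied")
  # k != 3 falls back to rank names
  p2 <- label_profiles(X[1:8, ], rep(1:2, each = 4))
  expect_true(all(p2 %in% c("RANK1", "RANK2")))
})

test_that("planted three-profile cohorts are recovered", {
  skip_if_not_installed("mclust")
  set.seed(9)
  hits <- replicate(20, {
    pl <- planted_learning_matrix()
    sol <- subtype_cohort(pl$X, "all")
    mclust::adjustedRandIndex(sol$profile, pl$labels) >= 0.8
  })
  expect_gte(mean(hits), 0.9)
})

test_that("week-2-only subtyping uses three groups on three blocks", {
  set.seed(10)
  pl <- planted_learning_matrix()
  sol <- subtype_cohort(pl$X, "week2")
  expect_equal(sol$k, 3L)
  expect_equal(ncol(sol$X), 3L)
  expect_null(sol$panel)
  expect_equal(sort(unique(sol$profile)), c("HIGH", "LOW", "MID"))
})

test_that("profile comparisons produce the full report", {
  set.seed(11)
  pl <- planted_learning_matrix()
  cohort <- sample_cohort(n = nrow(pl$X), seed = 11)
  scored <- score_subjects(cohort)
  cmp <- compare_profiles(pl$labels, scored)
  expect_equal(nrow(cmp$anova), 7L)
  expect_true(all(c("pcl_total", "phq_total", "ambi_total") %in%
                    cmp$anova$measure))
  expect_equal(nrow(cmp$contrasts), 14L)
  expect_equal(sum(cmp$n), nrow(scored))
  expect_true(all(cmp$proportions >= 0 & cmp$proportions <= 1))
  # degenerate singleton profile is reported, not fatal
  labs2 <- c(rep("A", 1), rep("B", nrow(scored) - 1))
  expect_message(cmp2 <- compare_profiles(labs2, scored), "degenerate")
  expect_equal(cmp2$degenerate, "A")
  expect_true(all(is.na(cmp2$anova$F)))
})

test_that("identical score distributions yield mostly null comparisons", {
  set.seed(12)
  n_sig <- replicate(40, {
    labs <- sample(rep(c("LOW", "MID", "HIGH"), c(18, 18, 18)))
    y <- rnorm(54, 20, 8)
    one_way_anova(y, labs)$p < 0.05
  })
  expect_gte(mean(!n_sig), 0.9)
})
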