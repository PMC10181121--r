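test_that("PCA ordering finds a planted dominant-variance feature", {
  m <- load_montage("emotiv14")
  cat14 <- feature_catalog(m)
  set.seed(13)
  n <- 120
  latent <- rnorm(n)
  X <- matrix(rnorm(n * 112), n)
  # the latent factor loads strongest on PS:T7 and weakly on the rest of
  # the group, so after per-column z-scoring the first PC is the latent
  # direction and PS:T7 carries the largest absolute loading
  X[, 1:14] <- 0.3 * latent + X[, 1:14]
  X[, 5] <- 10 * latent + rnorm(n, sd = 0.1)   # PS:T7 dominates
  tab <- manual_table(X, rep(c("A", "B"), each = n / 2), cat14)
  ord <- pca_order(tab, "PS")
  expect_equal(ord$features[1], "PS:T7")
  expect_equal(unname(ord$P["PS:T7"]), 14L)
  expect_equal(sort(unname(ord$P)), 1:14)   # a permutation of 1..f_j
})

test_that("duplicated columns occupy adjacent PCA ranks", {
  m <- tiny_montage()
  ct <- feature_catalog(m)   # 3 PS + 1 AI + 3 PLV
  set.seed(14)
  X <- matrix(rnorm(50 * 7), 50)
  X[, 6] <- X[, 5]           # duplicate two PLV columns
  tab <- manual_table(X, rep(c("A", "B"), 25), ct)
  ord <- pca_order(tab, "PLV")
  pos <- match(ct$name[ct$group == "PLV"][1:2], ord$features)
  expect_equal(abs(diff(pos)), 1L)
})

test_that("zero-variance columns are dropped to the lowest positions", {
  m <- load_montage("emotiv14")
  cat14 <- feature_catalog(m)
  set.seed(15)
  X <- matrix(rnorm(60 * 112), 60)
  X[, 2] <- 7                      # PS:F7 constant
  tab <- manual_table(X, rep(c("A", "B"), 30), cat14)
  expect_warning(ord <- pca_order(tab, "PS"), "zero-variance")
  expect_equal(ord$features[14], "PS:F7")
  expect_equal(unname(ord$P["PS:F7"]), 1L)
})

test_that("explained-variance curves behave like the covariance says", {
  m <- load_montage("emotiv14")
  cat14 <- feature_catalog(m)
  # rank-1 group: first ratio is 1
  set.seed(16)
  base <- rnorm(80)
  X <- matrix(rnorm(80 * 112), 80)
  X[, 1:14] <- outer(base, runif(14, 0.5, 2))
  tab <- manual_table(X, rep(c("A", "B"), 40), cat14)
  ev <- explained_variance_curve(tab, "PS")
  expect_equal(ev[1], 1, tolerance = 1e-9)
  expect_equal(ev[length(ev)], 1, tolerance = 1e-9)
  expect_true(all(diff(ev) >= -1e-12))

  # isotropic noise: first ratio ~ 1/d on average (50 seeds)
  first <- replicate(50, {
    Xi <- matrix(rnorm(60 * 112), 60)
    ti <- manual_table(Xi, rep(c("A", "B"), 30), cat14)
    explained_variance_curve(ti, "AI")[1]
  })
  expect_equal(mean(first), 1 / 7, tolerance = 0.25)

  # planted 3-factor structure in the 14 PS columns: >= 0.9 by 3 PCs
  F3 <- matrix(rnorm(80 * 3), 80)
  load <- matrix(rnorm(3 * 14), 3)
  X3 <- matrix(rnorm(80 * 112), 80)
  X3[, 1:14] <- F3 %*% load + matrix(rnorm(80 * 14, sd = 0.2), 80)
  t3 <- manual_table(X3, rep(c("A", "B"), 40), cat14)
  expect_gte(explained_variance_curve(t3, "PS")[3], 0.9)
})

test_that("vectorized signed-rank p-values equal stats::wilcox.test", {
  set.seed(17)
  for (case in 1:30) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (case %% 3 == 0) {  # force ties and zero differences
      x <- round(x); y <- round(y)
      y[1] <- x[1]
    }
    d <- matrix(x - y, ncol = 1)
    if (all(d == 0)) next
    mine <- eegchsel:::signed_rank_p(d)
    ref <- suppressWarnings(
      wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE))$p.value
    expect_equal(unname(mine), ref, tolerance = 1e-12)
  }
})

test_that("Wilcoxon ordering runs all C(n,2) pairwise tests", {
  m <- pair_montage()
  ct <- feature_catalog(m)
  set.seed(18)
  subj <- rep(sprintf("S%02d", 1:13), each = 4)
  X <- matrix(rnorm(52 * 4), 52)
  tab <- manual_table(X, subj, ct)
  ord <- wilcoxon_order(tab, "PS")
  expect_equal(ord$diagnostics$n_tests, 78L)   # 13 choose 2
})

test_that("Wilcoxon ordering recovers a planted between-subject shift", {
  m <- load_montage("emotiv14")
  cat14 <- feature_catalog(m)
  set.seed(19)
  subj <- rep(sprintf("S%02d", 1:6), each = 10)
  X <- matrix(rnorm(60 * 112), 60)
  X[, 8] <- X[, 8] + 5 * as.integer(factor(subj))   # PS:O2 shifts
  tab <- manual_table(X, subj, cat14)
  ord <- wilcoxon_order(tab, "PS")
  expect_equal(ord$features[1], "PS:O2")
})

test_that("two-subject Wilcoxon ordering equals the single test", {
  m <- load_montage("emotiv14")
  cat14 <- feature_catalog(m)
  set.seed(20)
  subj <- rep(c("A", "B"), each = 12)
  X <- matrix(rnorm(24 * 112), 24)
  tab <- manual_table(X, subj, cat14)
  ord <- wilcoxon_order(tab, "PS")
  p <- eegchsel:::signed_rank_p(X[1:12, 1:14] - X[13:24, 1:14])
  expected <- cat14$name[cat14$group == "PS"][order(rank(p, ties.method = "first"))]
  expect_equal(ord$features, expected)
})

test_that("Wilcoxon ordering is invariant to subject relabelling", {
  m <- tiny_montage()
  ct <- feature_catalog(m)
  set.seed(22)
  subj <- rep(sprintf("S%d", 1:5), each = 8)
  X <- matrix(rnorm(40 * 7), 40)
  X[, 1] <- X[, 1] + 3 * as.integer(factor(subj))
  tab <- manual_table(X, subj, ct)
  relab <- c(S1 = "Q4", S2 = "Q1", S3 = "Q5", S4 = "Q2", S5 = "Q3")
  tab2 <- manual_table(X, unname(relab[subj]), ct)
  expect_equal(wilcoxon_order(tab, "PS")$features,
               wilcoxon_order(tab2, "PS")$features)
})

test_that("feature weights follow k * P / f exactly", {
  expect_equal(feature_weight(2, 11, 14), 11 / 7)
  expect_equal(feature_weight(1, 5, 7), 5 / 7)
  expect_equal(feature_weight(1.2, 91, 91), 1.2)
  for (k in c(0.5, 1, 2, 7)) for (f in c(1, 3, 10))
    expect_equal(feature_weight(k, f, f), k)
  expect_error(feature_weight(2, 15, 14), "out of range")
  expect_error(feature_weight(2, 0, 14), "out of range")
  expect_error(feature_weight(-1, 3, 14), "positive")
})

test_that("channel scores equal a brute-force oracle on random montages", {
  set.seed(23)
  for (case in 1:100) {
    mont <- random_montage(sample(1:3, 1), sample(0:2, 1))
    ct <- feature_catalog(mont)
    ks <- scoring_config(k_PS = runif(1, 0.5, 3),
                         k_AI = runif(1, 0.5, 3),
                         k_PLV = runif(1, 0.5, 3))
    # random hand-assigned orderings per group
    groups <- unique(ct$group)
    ords <- lapply(groups, function(g) {
      feats <- sample(ct$name[ct$group == g])
      eegchsel:::new_feature_ordering(g, feats, "manual", list())
    })
    rk <- score_channels(ords, ct, ks)
    # oracle: direct sum over every feature mentioning the channel
    P_all <- do.call(c, unname(lapply(ords, `[[`, "P")))
    k_of <- c(PS = ks$k_PS, AI = ks$k_AI, PLV = ks$k_PLV)
    oracle <- sapply(mont$channels, function(cc) {
      tot <- 0
      for (r in seq_len(nrow(ct))) {
        if (identical(ct$ch1[r], cc) ||
            (!is.na(ct$ch2[r]) && identical(ct$ch2[r], cc))) {
          f <- sum(ct$group == ct$group[r])
          tot <- tot + k_of[[ct$group[r]]] * P_all[[ct$name[r]]] / f
        }
      }
      tot
    })
    got <- coef(rk)[names(oracle)]
    expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
    # score equals the sum of its group breakdown exactly
    expect_equal(rk$table$score,
                 rk$table$score_PS + rk$table$score_AI + rk$table$score_PLV)
  }
})

test_that("scaling every k scales scores but not the order", {
  tab <- quick_table(31, n_subjects = 3, duration_s = 12)
  r1 <- rank_channels(tab, "pca", scoring_config(2, 1, 1.2))
  r2 <- rank_channels(tab, "pca", scoring_config(4, 2, 2.4))
  expect_equal(r2$table$score, 2 * r1$table$score, tolerance = 1e-12)
  expect_equal(r2$table$channel, r1$table$channel)
})

test_that("a single-channel montage scores k_PS exactly", {
  m1 <- montage("one", "Cz")
  ct <- feature_catalog(m1)
  ords <- list(eegchsel:::new_feature_ordering("PS", "PS:Cz", "manual",
                                               list()))
  rk <- score_channels(ords, ct, scoring_config())
  expect_equal(rk$table$score, 2)
})

test_that("exchangeable channels get near-equal scores as rows grow", {
  # no mirror pairs and a full PLV clique: all three channels exchangeable
  m <- montage("iso3", c("Ca", "Cb", "Cc"),
               positions = cbind(0:2, 0:2),
               mirror_pairs = matrix(character(0), 0, 2))
  ct <- feature_catalog(m)   # 3 PS + 3 PLV
  set.seed(24)
  scores <- replicate(30, {
    X <- matrix(rnorm(60 * 6), 60)
    tab <- manual_table(X, rep(c("A", "B"), 30), ct)
    coef(rank_channels(tab, "pca"))[c("Ca", "Cb", "Cc")]
  })
  per_seed_spread <- median(apply(scores, 2L, function(s) max(s) - min(s)))
  mean_scores <- rowMeans(scores)
  # expected scores equal: averaging over seeds shrinks the spread well
  # below the typical single-run spread
  expect_lt(max(mean_scores) - min(mean_scores), per_seed_spread / 2)
})
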