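test_that("common-peak alignment finds exactly the shared peaks", {
  set.seed(3)
  shared_rt <- seq(2, 24, by = 1)          # 23 seeded common peaks
  lists <- lapply(1:18, function(b) {
    extra_rt <- runif(3, 26, 35) + b       # batch-unique extras
    data.frame(rt = c(shared_rt + rnorm(23, 0, 0.01), extra_rt),
               area = runif(26, 50, 500))
  })
  names(lists) <- paste0("S", 1:18)
  tab <- align_common_peaks(lists)
  expect_equal(sum(tab$common), 23L)
  expect_equal(nrow(tab$areas), 18L)
  expect_true(all(tab$areas[, tab$common] > 0))

  # one batch: every peak is trivially common
  solo <- align_common_peaks(lists[1])
  expect_true(all(solo$common))
  # disjoint retention times: no common peaks
  two <- align_common_peaks(list(S1 = data.frame(rt = c(1, 2), area = c(1, 1)),
                                 S2 = data.frame(rt = c(5, 6), area = c(1, 1))))
  expect_equal(sum(two$common), 0L)
  # ambiguous duplicate within a batch is resolved and logged
  expect_message(
    align_common_peaks(list(S1 = data.frame(rt = c(1.00, 1.01, 3),
                                            area = c(5, 9, 2)),
                            S2 = data.frame(rt = c(1.005, 3.01),
                                            area = c(4, 2)))),
    "keeping the nearest")
})

test_that("fingerprint similarity is the congruence coefficient", {
  x <- rbind(S1 = c(1, 2, 3, 4), S2 = c(2, 4, 6, 8), S3 = c(4, 3, 2, 1))
  tab <- peak_table(x)
  rep_mean <- fingerprint_similarity(tab)
  ref <- colMeans(x)
  for (b in rownames(x)) {
    expect_equal(unname(rep_mean$similarity[b]),
                 sum(x[b, ] * ref) / sqrt(sum(x[b, ]^2) * sum(ref^2)),
                 tolerance = 1e-12)
  }
  # a batch identical (up to scale) to the reference scores 1
  repS1 <- fingerprint_similarity(tab, reference = "S1")
  expect_equal(unname(repS1$similarity["S1"]), 1)
  expect_equal(unname(repS1$similarity["S2"]), 1)  # scale invariance
  # orthogonal vectors score 0
  orth <- peak_table(rbind(S1 = c(1, 0), S2 = c(0, 1)))
  expect_equal(unname(fingerprint_similarity(orth, "S1")$similarity["S2"]), 0)
  expect_error(fingerprint_similarity(peak_table(rbind(S1 = c(0, 0),
                                                       S2 = c(1, 1))), "S1"),
               "all zero")
})

test_that("autoscaling centres, scales, drops constants and inverts", {
  set.seed(4)
  x <- matrix(rexp(60, 0.01), 10, 6,
              dimnames = list(paste0("S", 1:10), paste0("P", 1:6)))
  sc <- autoscale(x)
  expect_true(all(abs(colMeans(sc)) < 1e-12))
  expect_true(all(abs(apply(sc, 2, sd) - 1) < 1e-12))
  expect_equal(unscale(sc), x)
  xc <- cbind(x, Pc = 7)
  expect_warning(sc2 <- autoscale(xc), "constant")
  expect_false("Pc" %in% colnames(sc2))
})

test_that("HCA recovers duplicates first and honours k", {
  x <- rbind(S1 = c(1, 2, 3), S2 = c(1, 2, 3), S3 = c(9, 1, 0),
             S4 = c(8, 2, 1))
  h <- hca(x, k = 2, scale = FALSE)
  expect_equal(h$hclust$merge[1, ], c(-1, -2))  # identical rows merge first
  expect_equal(unname(h$clusters["S1"]), unname(h$clusters["S2"]))
  expect_false(unname(h$clusters["S1"]) == unname(h$clusters["S3"]))
  hk <- hca(x, k = 4, scale = FALSE)
  expect_equal(length(unique(hk$clusters)), 4L)
  expect_error(hca(x, k = 9, scale = FALSE), "exceeds")
})

test_that("PCA matches a direct eigendecomposition and flags rank-1 data", {
  set.seed(5)
  x <- autoscale(matrix(rnorm(18 * 7), 18, 7))
  res <- pca(x)
  ev <- eigen(stats::cov(x))$values
  expect_equal(res$explained_variance_fraction, ev[seq_len(ncol(res$scores))] /
                 sum(ev), tolerance = 1e-9)
  expect_equal(sum(res$explained_variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(res$explained_variance_fraction) <= 1e-12))
  # deterministic sign: the dominant loading of each component is positive
  for (j in seq_len(ncol(res$loadings))) {
    expect_gte(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  }
  # rank-1 matrix: PC1 explains everything
  r1 <- outer(rnorm(6), rnorm(4))
  res1 <- pca(r1, n_components = 1)
  expect_equal(res1$explained_variance_fraction, 1, tolerance = 1e-9)
  expect_error(pca(x, n_components = 20), "exceeds")
})

test_that("OPLS-DA separates constructed classes, collapses under label
           permutation, and satisfies the VIP identity", {
  set.seed(6)
  n <- 18; p <- 12
  grp <- factor(rep(c("A", "B"), each = 9))
  X <- matrix(rnorm(n * p), n, p)
  X[grp == "B", 1:4] <- X[grp == "B", 1:4] + 3   # separable structure
  colnames(X) <- paste0("P", 1:p)
  Xs <- autoscale(X)
  fit <- oplsda(Xs, grp)
  expect_gt(fit$Q2, 0.9)
  expect_gte(fit$R2Y, fit$Q2)
  expect_equal(sum(fit$vip^2), p, tolerance = 1e-9)
  expect_true(all(names(sort(fit$vip, decreasing = TRUE))[1:4] %in%
                    paste0("P", 1:4)))
  # label permutation destroys predictivity
  q2_perm <- replicate(30, oplsda(Xs, sample(grp), cv_folds = 7)$Q2)
  expect_lt(stats::median(q2_perm), 0.2)
  expect_gt(fit$Q2, max(q2_perm))
  expect_error(oplsda(Xs, factor(rep("A", n))), "2 classes")
})

test_that("with zero orthogonal components OPLS-DA equals an independent
           one-component PLS oracle", {
  set.seed(8)
  for (rep in 1:5) {
    X <- autoscale(matrix(rnorm(16 * 9), 16, 9))
    grp <- factor(rep(c("A", "B"), each = 8))
    fit0 <- oplsda(X, grp, n_orthogonal = 0L, cv_folds = 4)
    q2_oracle <- oracle_pls1_q2(X, as.numeric(grp == "B"), cv_folds = 4)
    expect_equal(fit0$Q2, q2_oracle, tolerance = 1e-9)
  }
})

test_that("vip_select thresholds and orders the VIP scores", {
  set.seed(9)
  X <- autoscale(matrix(rnorm(12 * 6), 12, 6))
  fit <- oplsda(X, factor(rep(c("A", "B"), 6)))
  sel <- vip_select(fit, 0.5)
  expect_true(all(sel > 0.5))
  expect_true(all(diff(sel) <= 0))
  expect_length(vip_select(fit, max(fit$vip) + 1), 0L)
})

test_that("the planted three-group structure is recovered by HCA, PCA and
           VIP in at least 95 % of seeds", {
  n_seeds <- 100
  ok_hca <- ok_pca <- ok_vip <- 0
  for (sd in seq_len(n_seeds)) {
    gen <- generate_peak_tables(synthetic_design(seed = sd))
    truth <- gen$truth
    cl <- hca(gen$table, k = 3)$clusters
    ok_hca <- ok_hca + (length(unique(paste(cl, truth$groups))) == 3)
    sc <- pca(autoscale(gen$table), n_components = 2)$scores
    ok_pca <- ok_pca + (oracle_silhouette(dist(sc), truth$groups) > 0)
    sel <- truth$groups %in% c("II", "III")
    fit <- oplsda(autoscale(gen$table$areas[sel, ]), truth$groups[sel])
    top8 <- names(sort(fit$vip, decreasing = TRUE))[1:8]
    ok_vip <- ok_vip + (setequal(top8, truth$planted_markers) &&
                          all(fit$vip[truth$planted_markers] > 1))
  }
  expect_gte(ok_hca / n_seeds, 0.95)
  expect_gte(ok_pca / n_seeds, 0.95)
  expect_gte(ok_vip / n_seeds, 0.95)
})
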