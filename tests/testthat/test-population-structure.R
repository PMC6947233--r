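test_that("allele-sharing similarity matches the brute-force count", {
  g <- rbind(rep(0L, 10), rep(2L, 10), rep(1L, 10))
  s <- ibs_similarity(tiny_ds(g))
  expect_equal(s[1, 1], 1)
  expect_equal(s[1, 2], 0)       # opposite homozygotes everywhere
  expect_equal(s[1, 3], 0.5)
  set.seed(7)
  g2 <- matrix(sample(c(0:2, NA), 5 * 20, TRUE, prob = c(.3, .3, .3, .1)),
               nrow = 5)
  s2 <- ibs_similarity(tiny_ds(g2))
  expect_equal(unname(s2), oracle_ibs(g2), tolerance = 1e-12)
  expect_true(isSymmetric(s2))
})

test_that("PCoA reconstructs distances and handles the equilateral case", {
  # three points with equal pairwise dissimilarity
  s <- matrix(0.5, 3, 3); diag(s) <- 1
  p <- pcoa(s)
  pos <- p$eigenvalues[p$eigenvalues > 1e-9]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  expect_equal(sum(abs(p$eigenvalues[3])), 0, tolerance = 1e-9)

  # similarity from real coordinates: embedding must reproduce distances
  set.seed(8)
  X <- matrix(rnorm(12 * 3), 12, 3)
  d2 <- as.matrix(dist(X))^2
  s2 <- 1 - d2 / 2
  p2 <- pcoa(s2)
  drec <- as.matrix(dist(p2$coordinates))
  expect_equal(drec, sqrt(d2), tolerance = 1e-8, ignore_attr = TRUE)
  # column means are zero and variance fractions are proper
  expect_lt(max(abs(colMeans(p2$coordinates))), 1e-10)
  expect_equal(sum(p2$variance_explained), 1, tolerance = 1e-12)
  expect_error(pcoa(matrix(c(1, 0.2, 0.4, 1), 2, 2)), "symmetric")
})

test_that("PCoA agrees with classical MDS as an independent route", {
  set.seed(9)
  X <- matrix(rnorm(10 * 4), 10, 4)
  d2 <- as.matrix(dist(X))^2
  s <- 1 - d2 / 2
  p <- pcoa(s)
  ref <- stats::cmdscale(sqrt(d2), k = 4, eig = TRUE)
  expect_equal(p$eigenvalues[1:4], ref$eig[1:4], tolerance = 1e-8)
  expect_equal(abs(p$coordinates[, 1]), abs(ref$points[, 1]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("two drifted populations separate on the first PCoA axis", {
  sim <- small_sweep_sim()
  kept <- ld_prune(sim$genotypes, qc_config())
  pruned <- sim$genotypes
  pruned <- divscan:::subset_markers(pruned,
                                     pruned$markers$marker_id %in% kept)
  p <- pcoa(ibs_similarity(pruned))
  pop <- sim$genotypes$samples$true_pop
  a1 <- p$coordinates[, 1]
  gap <- abs(mean(a1[pop == "SJ"]) - mean(a1[pop == "NS"]))
  pooled <- sqrt((var(a1[pop == "SJ"]) + var(a1[pop == "NS"])) / 2)
  expect_gt(gap, 2 * pooled)
})

test_that("BIC selects the generative number of clusters", {
  set.seed(10)
  one <- matrix(rnorm(150 * 200), 150, 200)
  b1 <- find_clusters_bic(one, k_range = 1:4, seed = 2)
  expect_equal(b1$best_k, 1)
  two <- rbind(matrix(rnorm(75 * 200), 75, 200),
               matrix(rnorm(75 * 200, mean = 1), 75, 200))
  b2 <- find_clusters_bic(two, k_range = 1:4, seed = 2)
  expect_equal(b2$best_k, 2)
  expect_equal(length(b2$assignments), 150)
  # deterministic under a fixed seed
  b2b <- find_clusters_bic(two, k_range = 1:4, seed = 2)
  expect_identical(b2$table, b2b$table)
  expect_error(find_clusters_bic(one, k_range = 1:200),
               "below the sample count")
})

test_that("DAPC posteriors normalize and separable groups self-assign", {
  set.seed(11)
  X <- rbind(matrix(rnorm(40 * 50), 40, 50),
             matrix(rnorm(40 * 50, mean = 3), 40, 50))
  labels <- rep(c("A", "B"), each = 40)
  fit <- dapc_fit(X, labels, n_pcs = 10)
  expect_equal(rowSums(fit$posterior), rep(1, 80), tolerance = 1e-12)
  expect_equal(fit$self_assignment, 1)
  expect_equal(ncol(fit$discriminant_loadings), 1)  # g - 1 axes
  # held-out prediction works on the same marker space
  pr <- predict(fit, X[c(1, 80), , drop = FALSE])
  expect_equal(pr$assign, c("A", "B"))
  expect_error(dapc_fit(X, labels, n_pcs = 100), "rank")
})

test_that("DAPC agrees with an independent discriminant implementation", {
  skip_if_not_installed("MASS")
  set.seed(12)
  X <- rbind(matrix(rnorm(30 * 40), 30, 40),
             matrix(rnorm(30 * 40, mean = 1.5), 30, 40))
  labels <- factor(rep(c("A", "B"), each = 30))
  fit <- dapc_fit(X, labels, n_pcs = 8)
  pcs <- prcomp(scale(X, scale = FALSE), center = FALSE, rank. = 8)$x
  ref <- MASS::lda(pcs, grouping = labels)
  ref_assign <- as.character(predict(ref)$class)
  expect_gt(mean(fit$assign == ref_assign), 0.97)
})

test_that("permuted labels destroy DAPC information", {
  set.seed(13)
  X <- rbind(matrix(rnorm(50 * 60), 50, 60),
             matrix(rnorm(50 * 60, mean = 2), 50, 60))
  perm <- sample(rep(c("A", "B"), each = 50))
  fit <- dapc_fit(X, perm, n_pcs = 10)
  # mean posterior for the labelled group is near 1/g on permuted labels
  post_true <- mean(fit$posterior[cbind(seq_len(100),
                                        match(perm, fit$levels))])
  expect_lt(abs(post_true - 0.5), 0.15)
})

test_that("cross-validation scores PC counts and breaks ties by RMSE", {
  set.seed(14)
  X <- rbind(matrix(rnorm(40 * 50), 40, 50),
             matrix(rnorm(40 * 50, mean = 4), 40, 50))
  labels <- rep(c("A", "B"), each = 40)
  cv <- dapc_crossvalidate(X, labels, pcs_grid = c(5, 10), reps = 8, seed = 3)
  expect_equal(nrow(cv$table), 2)
  expect_true(all(cv$table$reps == 8))
  expect_equal(cv$table$mean_assignment, c(1, 1))
  expect_equal(cv$table$rmse, c(0, 0))
  # labels independent of data: held-out assignment near chance
  perm <- sample(labels)
  cvn <- dapc_crossvalidate(X, perm, pcs_grid = 5, reps = 15, seed = 4)
  expect_lt(abs(cvn$table$mean_assignment - 0.5), 0.2)
})
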