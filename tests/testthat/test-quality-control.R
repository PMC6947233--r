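test_that("call-rate filter removes strictly below the boundary", {
  g <- matrix(0L, nrow = 10, ncol = 3)
  g[1, 2] <- NA            # 9/10 called: retained at 0.90
  g[1:2, 3] <- NA          # 8/10 called: removed
  out <- call_rate_filter(tiny_ds(g), 0.90)
  expect_equal(out$removed, "m3")
  expect_equal(colnames(out$dataset$genotypes), c("m1", "m2"))
})

test_that("call-rate filter agrees with per-column counting on random missingness", {
  set.seed(1)
  g <- matrix(sample(c(0:2, NA), 50 * 40, TRUE, prob = c(.3, .3, .3, .1)),
              nrow = 50)
  ds <- tiny_ds(g)
  out <- call_rate_filter(ds, 0.9)
  keep_oracle <- vapply(seq_len(ncol(g)), function(j)
    sum(!is.na(g[, j])) / nrow(g) >= 0.9, logical(1))
  expect_equal(colnames(out$dataset$genotypes),
               ds$markers$marker_id[keep_oracle])
})

test_that("MAF filter computes frequency from called genotypes only", {
  # dosages [0,0,1,2]: p = 3/8, MAF 0.375 -> retained
  g <- cbind(c(0L, 0L, 1L, 2L), c(0L, 0L, 0L, 0L), c(NA, 1L, 1L, NA))
  out <- maf_filter(tiny_ds(g), 0.01)
  expect_true("m1" %in% colnames(out$dataset$genotypes))
  expect_true("m2" %in% out$removed)       # monomorphic
  expect_true("m3" %in% colnames(out$dataset$genotypes))  # MAF 0.5 of called
  expect_warning(maf_filter(tiny_ds(matrix(NA_integer_, 4, 1))), "no called")
})

test_that("MAF filter matches direct allele counting across a frequency sweep", {
  set.seed(2)
  g <- vapply(seq(0, 0.5, length.out = 60), function(p)
    rbinom(80, 2, p), integer(80))
  out <- maf_filter(tiny_ds(g), 0.05)
  maf_oracle <- apply(g, 2, function(col) {
    p <- sum(col) / (2 * length(col))
    min(p, 1 - p)
  })
  expect_equal(colnames(out$dataset$genotypes),
               tiny_markers(60)$marker_id[maf_oracle >= 0.05])
})

test_that("Hardy-Weinberg exact test matches enumeration", {
  expect_equal(hwe_exact_test(30, 0, 0), 1)
  expect_equal(hwe_exact_test(50, 0, 50), oracle_hwe(50, 0, 50))
  # all configurations with total <= 10, exhaustively
  for (n in 1:10) {
    for (a in 0:n) for (b in 0:(n - a)) {
      c_ <- n - a - b
      expect_equal(hwe_exact_test(a, b, c_), oracle_hwe(a, b, c_),
                   tolerance = 1e-12,
                   info = sprintf("counts (%d,%d,%d)", a, b, c_))
    }
  }
  expect_error(hwe_exact_test(-1, 2, 3), "negative")
})

test_that("hwe_filter removes only markers below alpha", {
  set.seed(3)
  g <- cbind(rbinom(100, 2, 0.4),                       # in HWE
             c(rep(0L, 50), rep(2L, 50)))               # no hets at p=0.5
  out <- hwe_filter(tiny_ds(g), 1e-4)
  expect_equal(out$removed, "m2")
  expect_lt(out$p[2], 1e-10)
})

test_that("genotype r-squared handles degenerate and missing input", {
  x <- c(0, 1, 2, 1, 0, 2)
  expect_equal(ld_r2(x, x), 1)
  expect_equal(ld_r2(x, rep(1, 6)), 0)
  expect_true(is.na(ld_r2(c(0, NA, NA, NA, NA, 1), c(NA, 1, 1, 1, 1, NA))))
  expect_error(ld_r2(x, x[-1]), "length")
  set.seed(4)
  for (i in 1:100) {
    a <- sample(c(0:2, NA), 30, TRUE, prob = c(.3, .3, .3, .1))
    b <- sample(c(0:2, NA), 30, TRUE, prob = c(.3, .3, .3, .1))
    got <- ld_r2(a, b)
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) next
    expect_equal(got, oracle_r2(a, b), tolerance = 1e-12)
  }
})

test_that("LD pruning drops one of each highly correlated pair", {
  set.seed(5)
  base <- rbinom(60, 2, 0.5)
  g <- cbind(base, base, rbinom(60, 2, 0.5))
  kept <- ld_prune(tiny_ds(g), qc_config(ld_window = 3, ld_step = 1))
  expect_length(intersect(kept, c("m1", "m2")), 1)
  expect_true("m3" %in% kept)
  # independent columns: nothing removed
  g2 <- vapply(1:10, function(i) rbinom(200, 2, 0.5), integer(200))
  expect_length(ld_prune(tiny_ds(g2), qc_config(ld_window = 5, ld_step = 2)), 10)
})

test_that("pruned panels contain no offending pair within any window", {
  set.seed(6)
  # correlated chain of 200 SNPs on one chromosome
  n <- 80; m <- 200
  g <- matrix(0L, n, m)
  g[, 1] <- rbinom(n, 2, 0.5)
  for (j in 2:m) {
    flip <- rbinom(n, 1, 0.2)
    g[, j] <- ifelse(flip == 1, rbinom(n, 2, 0.5), g[, j - 1])
  }
  cfg <- qc_config(ld_window = 20, ld_step = 5, ld_r2_max = 0.5)
  ds <- tiny_ds(g)
  kept <- ld_prune(ds, cfg)
  keep_idx <- which(ds$markers$marker_id %in% kept)
  # post-hoc verification with the documented window enumeration
  for (s in seq(1, m - 1, by = cfg$ld_step)) {
    w <- intersect(s:min(s + cfg$ld_window - 1, m), keep_idx)
    if (length(w) < 2) next
    for (i in seq_along(w)[-length(w)]) {
      for (j in (i + 1):length(w)) {
        r2 <- ld_r2(g[, w[i]], g[, w[j]])
        expect_lte(r2, cfg$ld_r2_max + 1e-12)
      }
    }
  }
  # the lower-MAF member is the victim
  base <- sample(c(rep(0L, 30), rep(1L, 30), rep(2L, 20)))   # p = 0.4375
  rare <- base
  rare[sample(which(base == 2L), 8)] <- 1L                   # p = 0.3875
  g3 <- cbind(base, rare)
  expect_gt(ld_r2(g3[, 1], g3[, 2]), 0.5)
  kept3 <- ld_prune(tiny_ds(g3), qc_config(ld_window = 2, ld_step = 1))
  expect_equal(kept3, "m1")
})

test_that("the QC pipeline reports per-stage attrition that sums", {
  sim <- small_null_sim()
  out <- run_qc(sim$genotypes)
  rep <- out$report
  expect_equal(rep$n_in - sum(rep$stages$removed), rep$n_out)
  expect_equal(rep$stages$retained[3], ncol(out$dataset$genotypes))
  # order: call rate then MAF then HWE; ids attributed once
  all_removed <- unlist(rep$removed_ids)
  expect_equal(anyDuplicated(all_removed), 0L)
  f <- tempfile(fileext = ".tsv")
  write_qc_report(rep, f)
  expect_equal(nrow(utils::read.table(f, header = TRUE)), 3)
})
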