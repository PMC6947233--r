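test_that("haplotype filtering yields a complete matrix by the two-step rule", {
  H <- rbind(c(0L, 1L, 0L, 1L),
             c(0L, NA, 0L, 1L),   # rule 1: row dropped
             c(1L, 1L, NA, 0L),   # rule 1: row dropped
             c(1L, 0L, 1L, 0L))
  hs <- tiny_hs(H)
  out <- filter_haplotypes(hs)
  expect_equal(nrow(out$haplotypes), 2)
  expect_equal(ncol(out$haplotypes), 4)
  # with a tolerated per-row missing fraction, rule 2 removes the marker
  # still missing in a surviving row
  H2 <- rbind(c(0L, NA, 0L, 1L, 0L, 1L, 0L, 1L),
              c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L),
              c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L),
              c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L))
  out2 <- filter_haplotypes(tiny_hs(H2), max_row_missing = 0.2)
  expect_equal(nrow(out2$haplotypes), 4)        # 1/8 missing tolerated
  expect_false("m2" %in% colnames(out2$haplotypes))
  expect_equal(sum(is.na(out2$haplotypes)), 0)
  set.seed(31)
  H3 <- matrix(sample(c(0L, 1L, NA), 20 * 30, TRUE, prob = c(.485, .485, .03)), 20)
  out3 <- filter_haplotypes(tiny_hs(H3), max_row_missing = 0.1)
  expect_equal(sum(is.na(out3$haplotypes)), 0)
})

test_that("EHHS decay matches pair counting and is non-increasing", {
  # 4 haplotypes monomorphic at the core, splitting {2,2} at the next SNP
  H <- rbind(c(0L, 0L, 0L), c(0L, 0L, 1L), c(0L, 1L, 0L), c(0L, 1L, 1L))
  hs <- tiny_hs(H)
  d <- ehhs_decay(hs, core = 1, cutoff = 0)
  right <- d$decay[d$decay$side == "right", ]
  expect_equal(right$ehhs[1], 1 / 3)      # {2,2} classes: 2 of 6 pairs
  expect_equal(right$ehhs[2], 0)          # all four prefixes distinct

  # identical haplotypes: EHHS stays 1 to the chromosome end
  Hsame <- matrix(rep(c(0L, 1L, 0L, 1L, 1L), each = 6), nrow = 6)
  dsame <- ehhs_decay(tiny_hs(Hsame), core = 3)
  expect_true(all(dsame$decay$ehhs == 1))
  expect_equal(unname(dsame$reason), c("chrom_end", "chrom_end"))

  set.seed(32)
  for (rep in 1:25) {
    H <- random_haps(12, 15, seed = 100 + rep)
    hs <- tiny_hs(H)
    core <- sample(2:14, 1)
    d <- ehhs_decay(hs, core, cutoff = 0.01)
    expect_true(all(diff(d$decay$ehhs[d$decay$side == "right"]) <= 1e-12))
    expect_true(all(diff(rev(d$decay$ehhs[d$decay$side == "left"])) <= 1e-12))
    for (side in c("left", "right")) {
      seg <- d$decay[d$decay$side == side, ]
      for (k in seq_len(nrow(seg))) {
        x <- match(seg$pos_bp[k], hs$markers$pos_bp)
        expect_equal(seg$ehhs[k], oracle_ehhs(H, core, x), tolerance = 1e-12)
      }
    }
  }
})

test_that("decay truncation honours gaps and the extension cap", {
  H <- random_haps(8, 20, seed = 5)
  mk <- tiny_markers(20, spacing = 1000L)
  mk$pos_bp[15:20] <- mk$pos_bp[15:20] + 5e5   # 500 kb gap after marker 14
  ids <- paste0("s", 1:4)
  hs <- haplotype_set(H, rep(ids, each = 2), mk,
                      pop_of = stats::setNames(rep("P1", 4), ids))
  d <- ehhs_decay(hs, core = 10, cutoff = 0, max_gap_bp = 2e5)
  expect_equal(unname(d$reason["right"]), "gap")
  expect_lte(max(d$decay$pos_bp), mk$pos_bp[14])
  d2 <- ehhs_decay(hs, core = 10, cutoff = 0, max_gap_bp = 1e7,
                   max_extend_bp = 3000)
  expect_equal(unname(d2$reason["right"]), "max_extend")
  expect_true(all(abs(d2$decay$pos_bp - d2$core_pos) <= 3000))
})

test_that("iES integration is the trapezoid rule over both flanks", {
  # EHHS == 1 over a 10 kb right flank, empty left flank
  mk <- tiny_markers(3)
  mk$pos_bp <- c(1L, 5001L, 10001L)
  ids <- c("a", "b")
  hs <- haplotype_set(cbind(c(0L,0L,1L,1L), c(0L,0L,1L,1L), c(0L,0L,1L,1L)),
                      rep(ids, each = 2), mk,
                      pop_of = stats::setNames(rep("P1", 2), ids))
  d <- ehhs_decay(hs, core = 1)
  expect_equal(integrate_ies(d), 10000)
  set.seed(33)
  for (rep in 1:30) {
    H <- random_haps(10, 12, seed = 200 + rep)
    hs <- tiny_hs(H)
    d <- ehhs_decay(hs, core = 6, cutoff = 0.01)
    seg_r <- d$decay[d$decay$side %in% c("core", "right"), ]
    seg_l <- d$decay[d$decay$side %in% c("core", "left"), ]
    want <- oracle_trapezoid(seg_r$pos_bp, seg_r$ehhs) +
      oracle_trapezoid(rev(-seg_l$pos_bp), rev(seg_l$ehhs))
    expect_equal(integrate_ies(d), want, tolerance = 1e-9)
  }
})

test_that("the C++ scan integral equals the R-level decay integral", {
  H <- random_haps(14, 40, seed = 77)
  hs <- tiny_hs(H)
  sc <- divscan:::.ies_scan_cpp(hs$haplotypes, as.numeric(hs$markers$pos_bp),
                                0.05, 2e5, FALSE, 2.5e6)
  for (core in c(2, 10, 20, 39)) {
    d <- ehhs_decay(hs, core)
    if (any(d$reason %in% c("chrom_end"))) next
    expect_equal(unname(sc[core, "ies"]), integrate_ies(d), tolerance = 1e-9,
                 info = paste("core", core))
  }
})

test_that("the cross-population log-ratio is antisymmetric and zero at parity", {
  H <- random_haps(16, 30, seed = 42)
  ids <- paste0("s", 1:8)
  pops <- stats::setNames(rep(c("P1", "P2"), each = 4), ids)
  # identical haplotype sets in both populations
  Hdup <- rbind(H[1:8, ], H[1:8, ])
  hs <- haplotype_set(Hdup, rep(ids, each = 2), tiny_markers(30),
                      pop_of = pops)
  expect_equal(xpehh(hs, 15, "P1", "P2"), 0, tolerance = 1e-12)
  hs2 <- haplotype_set(H, rep(ids, each = 2), tiny_markers(30), pop_of = pops)
  ab <- xpehh(hs2, 15, "P1", "P2")
  ba <- xpehh(hs2, 15, "P2", "P1")
  expect_equal(ab, -ba, tolerance = 1e-12)
})

test_that("standardization normalizes, is affine-invariant and idempotent", {
  set.seed(34)
  x <- rnorm(500, 3, 7); x[c(5, 10)] <- NA
  z <- standardize_scores(x)
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_equal(z, standardize_scores(10 * x - 4), tolerance = 1e-12)
  expect_equal(z, standardize_scores(z), tolerance = 1e-12)
  want <- (x - mean(x, na.rm = TRUE)) / sqrt(sum((x - mean(x, na.rm = TRUE))^2,
                                                 na.rm = TRUE) / (498 - 1))
  expect_equal(z, want, tolerance = 1e-12)
  expect_error(standardize_scores(rep(2, 5)), "zero standard deviation")
})

test_that("the Gaussian p-transform behaves as a two-sided -log10 p", {
  expect_equal(p_xpehh(0), 0)
  zs <- c(0.3, 1, 2.5, 5, 10)
  expect_equal(p_xpehh(zs), p_xpehh(-zs))
  expect_equal(p_xpehh(1.959964), -log10(0.05), tolerance = 1e-4)
  expect_equal(p_xpehh(1), -log10(2 * pnorm(-1)), tolerance = 1e-12)
  # cap guards overflow at extreme scores
  expect_equal(p_xpehh(60), 300)
  expect_equal(p_xpehh(60, max_p = 50), 50)
})

test_that("Benjamini-Hochberg adjustment matches the step-up definition", {
  one <- bh_fdr(-log10(0.03))
  expect_equal(one$q, 0.03)
  worked <- bh_fdr(-log10(c(0.001, 0.01, 0.02, 0.8)))
  expect_equal(worked$q, c(0.004, 0.02, 0.8 / 30, 0.8), tolerance = 1e-12)
  expect_equal(sum(worked$significant), 3)
  set.seed(35)
  for (rep in 1:20) {
    p <- runif(40)^2
    got <- bh_fdr(-log10(p))$q
    expect_equal(got, oracle_bh(p), tolerance = 1e-9)
  }
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("a planted sweep drives the scan in the configured direction", {
  sim <- small_sweep_sim()
  hs <- filter_haplotypes(sim$haplotypes)
  xp <- xpehh_scan(hs, pop_a = "NS", pop_b = "SJ")
  d <- xp$snps
  near <- d$chrom == sim$truth$chrom &
    abs(d$pos_bp - sim$truth$pos_bp) < 2e6
  # selection in SJ pushes the score negative around the sweep
  expect_lt(mean(d$z[near], na.rm = TRUE), mean(d$z[!near], na.rm = TRUE))
  expect_true(all(d$direction[!is.na(d$z) & d$z > 0] == "NS"))
  expect_true(all(d$direction[!is.na(d$z) & d$z < 0] == "SJ"))
  # swapping the populations flips the scores exactly
  xp2 <- xpehh_scan(hs, pop_a = "SJ", pop_b = "NS")
  expect_equal(xp2$snps$raw, -d$raw, tolerance = 1e-12)
})

test_that("null simulations yield no extreme scores or discoveries", {
  sim <- small_null_sim()
  hs <- filter_haplotypes(sim$haplotypes)
  xp <- xpehh_scan(hs)
  expect_lte(mean(abs(xp$snps$z) >= 4, na.rm = TRUE), 1e-3)
  expect_lte(sum(xp$snps$significant), 1)
})
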