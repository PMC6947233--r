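test_that("region construction pads, clamps and merges inclusively", {
  one <- build_regions(data.frame(chrom = "19", pos_bp = 41709599), 250000)
  expect_equal(one$start_bp, 41459599)
  expect_equal(one$end_bp, 41959599)
  expect_equal(one$length_kb, 500L)

  two <- build_regions(data.frame(chrom = "1", pos_bp = c(100000, 300000)),
                       250000)
  expect_equal(nrow(two), 1)
  expect_equal(two$start_bp, 1)        # clamped at 1
  expect_equal(two$end_bp, 550000)
  expect_equal(two$n_snps, 2)

  none <- build_regions(data.frame(chrom = character(), pos_bp = integer()))
  expect_equal(nrow(none), 0)

  # separate chromosomes and directions never merge
  mix <- build_regions(data.frame(chrom = c("1", "1", "2"),
                                  pos_bp = c(1e6, 1.2e6, 1e6),
                                  direction = c("SJ", "NS", "SJ")), 250000)
  expect_equal(nrow(mix), 3)
})

test_that("region merging is idempotent", {
  set.seed(41)
  snps <- data.frame(chrom = sample(c("1", "2"), 40, TRUE),
                     pos_bp = sample.int(5e6, 40))
  r1 <- build_regions(snps, 250000)
  # feeding the duplicated SNP set changes nothing about the intervals
  r2 <- build_regions(rbind(snps, snps), 250000)
  expect_equal(r1[c("chrom", "start_bp", "end_bp")],
               r2[c("chrom", "start_bp", "end_bp")])
  # and no two merged regions on a chromosome overlap or touch
  for (ch in unique(r1$chrom)) {
    rr <- r1[r1$chrom == ch, ]
    if (nrow(rr) > 1)
      expect_true(all(rr$start_bp[-1] > rr$end_bp[-nrow(rr)] + 1))
  }
})

test_that("published region coordinates reproduce their printed lengths", {
  expect_equal(region_length_kb(10891925, 11400093), 508L)
  expect_equal(region_length_kb(27935550, 31789708), 3854L)
  expect_equal(region_length_kb(5277465, 5984107), 707L)
  expect_equal(region_length_kb(40592555, 43510660), 2918L)
  expect_equal(region_length_kb(100, 100), 0L)
  expect_error(region_length_kb(200, 100), "end_bp")
})

test_that("concordance flags regions containing significant F_ST SNPs", {
  regions <- build_regions(data.frame(chrom = c("7", "12"),
                                      pos_bp = c(9e7, 1.2e7),
                                      direction = "SJ"), 250000)
  fst <- structure(list(snps = data.frame(
    marker_id = c("a", "b", "c"), chrom = c("7", "7", "12"),
    pos_bp = c(9e7 + 1000, 9e7 + 2000, 5e7),
    fst = c(0.16, 0.12, 0.4),
    significant = c(TRUE, TRUE, TRUE))), class = "fst_scan")
  out <- concordance(regions, fst)
  # regions come back sorted by chromosome label, "12" before "7"
  expect_equal(out$concordant[out$chrom == "7"], TRUE)
  expect_equal(out$concordant[out$chrom == "12"], FALSE)
  expect_equal(out$max_fst_overlap[out$chrom == "7"], 0.16)
  expect_true(is.na(out$max_fst_overlap[out$chrom == "12"]))
  expect_equal(unname(attr(out, "rate")["SJ"]), 0.5)
  # empty region set passes through
  expect_equal(nrow(concordance(build_regions(
    data.frame(chrom = character(), pos_bp = integer())), fst)), 0)
})

write_test_gff3 <- function(genes, path, junk = FALSE) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s;biotype=%s",
                     genes$chrom, genes$start, genes$end, genes$id, genes$id,
                     genes$biotype))
  if (junk) lines <- append(lines, "broken line without tabs", after = 1)
  writeLines(lines, path)
  path
}

test_that("gene annotation lists overlapping genes with inclusive bounds", {
  genes <- data.frame(chrom = "1", start = c(1000, 3001), end = c(2000, 4000),
                      id = c("g1", "g2"), biotype = c("protein_coding", "lncRNA"))
  gff <- write_test_gff3(genes, tempfile(fileext = ".gff3"))
  regions <- data.frame(chrom = "1", start_bp = 1500, end_bp = 3000)
  ann <- annotate_genes(regions, gff)
  expect_equal(ann$genes$gene_id, "g1")       # 3001 starts past the region
  expect_equal(unname(ann$biotype_tally["protein_coding"]), 1L)

  gff2 <- write_test_gff3(genes, tempfile(fileext = ".gff3"), junk = TRUE)
  expect_warning(ann2 <- annotate_genes(regions, gff2), "malformed")
  expect_equal(ann2$genes$gene_id, "g1")
  expect_error(annotate_genes(regions, gff2, strict = TRUE), "malformed")
})

test_that("gene-region overlap matches a quadratic oracle", {
  set.seed(42)
  genes <- data.frame(chrom = sample(c("1", "2"), 60, TRUE),
                      start = sample.int(1e6, 60))
  genes$end <- genes$start + sample.int(5e4, 60)
  genes$id <- paste0("g", seq_len(60))
  genes$biotype <- sample(c("protein_coding", "lncRNA", "snoRNA"), 60, TRUE)
  gff <- write_test_gff3(genes, tempfile(fileext = ".gff3"))
  regions <- data.frame(chrom = sample(c("1", "2"), 10, TRUE),
                        start_bp = sample.int(9e5, 10))
  regions$end_bp <- regions$start_bp + 1e5
  ann <- annotate_genes(regions, gff)
  want <- oracle_overlaps(
    data.frame(chrom = regions$chrom, start = regions$start_bp,
               end = regions$end_bp),
    data.frame(chrom = genes$chrom, start = genes$start, end = genes$end))
  got <- ann$genes[order(ann$genes$region, ann$genes$gene_id), ]
  want_ids <- genes$id[want[, 2]]
  ord <- order(want[, 1], want_ids)
  expect_equal(got$region, want[ord, 1])
  expect_equal(got$gene_id, want_ids[ord])
})

test_that("hypergeometric enrichment follows the tail-sum definition", {
  bg <- paste0("g", 1:20000)
  hits <- bg[1:100]
  terms <- list(none = bg[19000:19099],
                ten = c(bg[1:5], bg[200:294]),
                all = hits)
  out <- enrichment_test(hits, bg, terms)
  expect_equal(out$fold[out$term == "none"], 0)
  expect_equal(out$p[out$term == "none"], 1)
  expect_equal(out$fold[out$term == "ten"], 10)
  expect_equal(out$p[out$term == "ten"],
               oracle_hyper_tail(5, 100, 20000, 100), tolerance = 1e-12)
  expect_equal(out$fold[out$term == "all"], 20000 / 100)
  expect_error(enrichment_test("zz", bg, terms), "subset")
  expect_error(enrichment_test(hits, character(), terms), "empty")
  withq <- enrichment_test(hits, bg, terms, adjust = TRUE)
  expect_equal(withq$q, p.adjust(withq$p, "BH"))
})

test_that("random term maps give uniform enrichment p-values", {
  set.seed(43)
  bg <- paste0("g", 1:2000)
  hits <- sample(bg, 100)
  terms <- lapply(seq_len(400), function(i) sample(bg, 50))
  names(terms) <- paste0("t", seq_len(400))
  out <- enrichment_test(hits, bg, terms)
  # discrete p-values are stochastically >= uniform; KS should not reject
  # uniformity strongly from above
  ks <- suppressWarnings(ks.test(out$p, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("QTL overlap reports exactly the intersecting intervals", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t999\t2000\tQTL_growth", "2\t0\t500\tQTL_jump"), bed)
  regions <- data.frame(chrom = c("1", "1", "2"),
                        start_bp = c(1500, 5000, 400),
                        end_bp = c(1800, 6000, 450))
  out <- qtl_overlap(regions, bed)
  expect_equal(out$region, c(1L, 3L))
  expect_equal(out$qtl_label, c("QTL_growth", "QTL_jump"))
  # BED half-open: interval (999,2000] in 1-based inclusive is 1000..2000
  expect_equal(out$qtl_start[1], 1000)
})

test_that("BED export converts 1-based inclusive to half-open", {
  r <- build_regions(data.frame(chrom = "5", pos_bp = 1e6), 1000)
  f <- tempfile(fileext = ".bed")
  write_regions_bed(r, f)
  got <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(as.integer(got[2]), r$start_bp - 1L)
  expect_equal(as.integer(got[3]), r$end_bp)
})
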