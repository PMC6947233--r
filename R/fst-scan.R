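#' Per-group allele frequencies
#'
#' Alt-allele frequency among called genotypes in each of the two groups.
#' Markers with no called genotype in a whole group are flagged and excluded
#' from the scan.
#'
#' @param ds a `genotype_dataset`.
#' @param labels group factor per sample; defaults to `ds$samples$group`.
#' @return List with per-group frequency vectors `p`, called-sample counts
#'   `n_called`, and `excluded` marker ids.
#' @export
group_allele_freqs <- function(ds, labels = NULL) {
  if (is.null(labels)) labels <- ds$samples$group
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2)
    stop("exactly two groups required, got ", nlevels(labels))
  out_p <- list(); out_n <- list()
  for (lv in levels(labels)) {
    g <- ds$genotypes[labels == lv, , drop = FALSE]
    out_n[[lv]] <- colSums(!is.na(g))
    out_p[[lv]] <- alt_freq(g)
  }
  excl <- out_n[[1]] == 0 | out_n[[2]] == 0
  list(p = out_p, n_called = out_n,
       excluded = ds$markers$marker_id[excl])
}

#' Nei's fixation index for a biallelic marker
#'
#' With the unweighted mean frequency `pbar = (p1 + p2) / 2`, total expected
#' heterozygosity `H_T = 2 pbar (1 - pbar)` and mean subpopulation expected
#' heterozygosity `H_S = (2 p1 (1 - p1) + 2 p2 (1 - p2)) / 2`, the statistic
#' is `(H_T - H_S) / H_T`. Markers monomorphic in both groups (`H_T = 0`)
#' return 0, and negative values (possible only through rounding, as the
#' unweighted form is algebraically non-negative) are clamped to 0. No
#' small-sample bias correction is applied.
#'
#' @param p1,p2 alt-allele frequencies in the two groups (vectors allowed).
#' @return F_ST value(s) in `[0, 1]`.
#' @export
nei_fst <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  fst <- ifelse(ht > 0, (ht - hs) / ht, 0)
  pmin(1, pmax(0, fst))
}

#' Empirical outlier threshold
#'
#' Returns the value separating the top `top_fraction` of the distribution:
#' the k-th largest value with `k = ceiling(top_fraction * n)`. The
#' significant set is `{x >= threshold}`, so tied values at the threshold are
#' all included. If every value is equal the whole vector is significant
#' (degenerate case, warned).
#'
#' @param x numeric vector (e.g. per-SNP F_ST values).
#' @param top_fraction upper tail mass (default 0.001, the top 0.1 percent).
#' @return The threshold value.
#' @export
empirical_threshold <- function(x, top_fraction = 0.001) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty vector")
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must be in (0, 1)")
  if (max(x) == min(x))
    warning("all values equal; every marker meets the threshold")
  k <- ceiling(top_fraction * length(x))
  sort(x, decreasing = TRUE)[k]
}

#' Qualitative interpretation of an F_ST value
#'
#' Bands: below 0.05 little differentiation, 0.05 up to (but excluding) 0.15
#' moderate, 0.15 through 0.25 large, and above 0.25 very large.
#'
#' @param fst value(s) in `[0, 1]`.
#' @return Factor with levels little/moderate/large/very_large.
#' @export
classify_wright <- function(fst) {
  if (any(fst < 0 | fst > 1, na.rm = TRUE)) stop("fst must lie in [0, 1]")
  cut(fst, breaks = c(-Inf, 0.05, 0.15, 0.25, Inf), right = FALSE,
      labels = c("little", "moderate", "large", "very_large")) ->
    out
  # 0.25 itself still counts as large (right-open cut puts it in very_large)
  out[!is.na(fst) & fst == 0.25] <- "large"
  out
}

#' Genome-wide per-SNP F_ST scan
#'
#' Computes [nei_fst()] between two predefined groups for every marker,
#' flags the empirical top `top_fraction` as potential signatures of
#' selection (ties at the threshold included), and summarises the
#' distribution. Markers uncalled in a whole group are excluded from both
#' the scan and the quantile denominator.
#'
#' @inheritParams group_allele_freqs
#' @param top_fraction outlier tail (default 0.001).
#' @return Object of class `fst_scan`: per-SNP data.frame (`marker_id`,
#'   `chrom`, `pos_bp`, `fst`, `significant`), `threshold`, `summary` and
#'   `excluded` ids.
#' @export
fst_scan <- function(ds, labels = NULL, top_fraction = 0.001) {
  fr <- group_allele_freqs(ds, labels)
  fst <- nei_fst(fr$p[[1]], fr$p[[2]])
  excl <- ds$markers$marker_id %in% fr$excluded
  fst[excl] <- NA_real_
  thr <- empirical_threshold(fst, top_fraction)
  df <- data.frame(marker_id = ds$markers$marker_id,
                   chrom = ds$markers$chrom, pos_bp = ds$markers$pos_bp,
                   fst = fst,
                   significant = !is.na(fst) & fst >= thr,
                   stringsAsFactors = FALSE)
  structure(list(snps = df, threshold = thr,
                 summary = c(mean = mean(fst, na.rm = TRUE),
                             sd = stats::sd(fst, na.rm = TRUE)),
                 excluded = fr$excluded, top_fraction = top_fraction),
            class = "fst_scan")
}

#' @export
#' @method print fst_scan
print.fst_scan <- function(x, ...) {
  cat(sprintf("F_ST scan: %d markers, mean %.4f (sd %.4f)\n",
              nrow(x$snps), x$summary["mean"], x$summary["sd"]))
  cat(sprintf("  top %.2f%% threshold %.4f -> %d significant SNP(s)\n",
              100 * x$top_fraction, x$threshold, sum(x$snps$significant)))
  invisible(x)
}

#' @export
#' @param x an `fst_scan`.
#' @param ... passed to [graphics::plot()].
#' @rdname fst_scan
#' @method plot fst_scan
plot.fst_scan <- function(x, ...) {
  df <- x$snps[!is.na(x$snps$fst), ]
  chrom <- factor(df$chrom, levels = unique(df$chrom))
  offs <- c(0, cumsum(tapply(df$pos_bp, chrom, max)))
  xpos <- df$pos_bp + offs[as.integer(chrom)]
  graphics::plot(xpos, df$fst, pch = 16, cex = 0.4,
                 col = as.integer(chrom) %% 2 + 1,
                 xlab = "genome position", ylab = "F_ST", ...)
  graphics::abline(h = x$threshold, lty = 3, col = "deeppink")
  invisible(x)
}

#' Write a per-SNP F_ST track as TSV
#'
#' @param scan an `fst_scan`.
#' @param path output TSV path.
#' @export
write_fst_tsv <- function(scan, path) {
  utils::write.table(scan$snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
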