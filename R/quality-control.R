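#' Marker quality-control configuration
#'
#' Bundles the QC thresholds applied before the scans: minimum per-marker
#' call rate 0.90, minimum minor allele frequency 0.01, Hardy-Weinberg exact
#' p-value floor 1e-4, and the LD-pruning scheme (windows of 50 SNPs moved by
#' 5 SNPs, r-squared ceiling 0.5) used only ahead of the structure analyses.
#'
#' @param min_call_rate markers called in fewer than this fraction of samples
#'   are removed (boundary retained).
#' @param min_maf markers with minor allele frequency strictly below this are
#'   removed.
#' @param hwe_alpha markers with an exact Hardy-Weinberg p-value strictly
#'   below this are removed.
#' @param ld_window,ld_step,ld_r2_max sliding-window LD pruning parameters
#'   (SNP counts and squared-correlation ceiling).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_call_rate = 0.90, min_maf = 0.01, hwe_alpha = 1e-4,
                      ld_window = 50L, ld_step = 5L, ld_r2_max = 0.5) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5,
            hwe_alpha > 0, hwe_alpha < 1,
            ld_window >= 2, ld_step >= 1, ld_step <= ld_window,
            ld_r2_max > 0, ld_r2_max <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, ld_window = as.integer(ld_window),
                 ld_step = as.integer(ld_step), ld_r2_max = ld_r2_max),
            class = "qc_config")
}

#' Per-marker call-rate filter
#'
#' Removes markers genotyped in strictly fewer than `min_call_rate` of the
#' samples; a marker exactly at the boundary is retained.
#'
#' @param ds a `genotype_dataset`.
#' @param min_call_rate minimum fraction of called genotypes.
#' @return List with `dataset` (filtered) and `removed` (marker ids).
#' @export
call_rate_filter <- function(ds, min_call_rate = 0.90) {
  cr <- colMeans(!is.na(ds$genotypes))
  drop <- cr < min_call_rate
  list(dataset = subset_markers(ds, !drop),
       removed = ds$markers$marker_id[drop])
}

# alt-allele frequency per marker from called genotypes
alt_freq <- function(g) {
  called <- colSums(!is.na(g))
  ifelse(called > 0, colSums(g, na.rm = TRUE) / (2 * called), NA_real_)
}

#' Minor-allele-frequency filter
#'
#' MAF is `min(p, 1 - p)` with `p` the alt-allele frequency among called
#' genotypes. Markers with MAF strictly below `min_maf` are removed; a marker
#' with no called genotypes is removed with a warning.
#'
#' @inheritParams call_rate_filter
#' @param min_maf minimum minor allele frequency.
#' @return List with `dataset` and `removed`.
#' @export
maf_filter <- function(ds, min_maf = 0.01) {
  p <- alt_freq(ds$genotypes)
  if (anyNA(p))
    warning(sum(is.na(p)), " marker(s) with no called genotypes removed")
  maf <- pmin(p, 1 - p)
  drop <- is.na(maf) | maf < min_maf
  list(dataset = subset_markers(ds, !drop),
       removed = ds$markers$marker_id[drop])
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts no more probable
#' than the observed one. Stable at low counts, unlike the chi-squared
#' approximation.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (min(n_AA, n_Aa, n_aa) < 0) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required")
  n_a <- 2 * n_aa + n_Aa              # minor-or-not doesn't matter: symmetric
  rare <- min(n_a, 2 * n - n_a)
  obs_het <- n_Aa
  # heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  if (length(hets) == 1) return(1)
  # unnormalized probabilities by recurrence:
  # P(h+2)/P(h) = [ (rare-h)(2n-rare-h) ] / [ (h+2)(h+1)/4 * 4 ] simplified
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    lp[i] <- lp[i - 1] +
      log(rare - h) + log(2 * n - rare - h) -
      log(h + 2) - log(h + 1)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(obs_het, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

#' Hardy-Weinberg filter over a dataset
#'
#' Applies [hwe_exact_test()] to every marker (whole cohort, called genotypes
#' only) and removes markers with p strictly below `alpha`.
#'
#' @inheritParams call_rate_filter
#' @param alpha significance floor (default 1e-4).
#' @return List with `dataset`, `removed`, and the vector of `p` values.
#' @export
hwe_filter <- function(ds, alpha = 1e-4) {
  g <- ds$genotypes
  n2 <- colSums(g == 2L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n0 <- colSums(g == 0L, na.rm = TRUE)
  p <- vapply(seq_len(ncol(g)), function(j) {
    if (n0[j] + n1[j] + n2[j] == 0) return(NA_real_)
    hwe_exact_test(n0[j], n1[j], n2[j])
  }, numeric(1))
  drop <- !is.na(p) & p < alpha
  list(dataset = subset_markers(ds, !drop),
       removed = ds$markers$marker_id[drop], p = p)
}

#' Squared genotype correlation between two markers
#'
#' Squared Pearson correlation of dosage vectors over pairwise-complete
#' samples. Returns 0 when either vector is constant, and `NA` when fewer
#' than two complete pairs remain.
#'
#' @param g1,g2 dosage vectors of equal length (`NA` = missing).
#' @return r-squared in `[0, 1]`, 0 for constant input, or `NA`.
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Sliding-window LD pruning
#'
#' Slides a window of `ld_window` SNPs advanced by `ld_step` SNPs along each
#' chromosome (windows never cross chromosome boundaries). Within a window,
#' while any retained pair has r-squared above `ld_r2_max`, the member with
#' the lower MAF is removed (ties: the marker later in map order), keeping
#' the more informative marker deterministically.
#'
#' @inheritParams call_rate_filter
#' @param cfg a [qc_config()].
#' @return Character vector of retained marker ids.
#' @export
ld_prune <- function(ds, cfg = qc_config()) {
  g <- ds$genotypes
  mk <- ds$markers
  p <- alt_freq(g)
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, ncol(g))
  for (ch in unique(mk$chrom)) {
    cols <- which(mk$chrom == ch)
    m_ch <- length(cols)
    starts <- seq(1L, max(1L, m_ch - 1L), by = cfg$ld_step)
    for (s in starts) {
      w <- cols[s:min(s + cfg$ld_window - 1L, m_ch)]
      w <- w[keep[w]]
      if (length(w) < 2) next
      cc <- suppressWarnings(stats::cor(g[, w, drop = FALSE],
                                        use = "pairwise.complete.obs"))
      r2 <- cc^2
      r2[is.na(r2)] <- 0
      diag(r2) <- 0
      alive <- rep(TRUE, length(w))
      repeat {
        off <- which(r2 > cfg$ld_r2_max & outer(alive, alive, "&"),
                     arr.ind = TRUE)
        off <- off[off[, 1] < off[, 2], , drop = FALSE]
        if (nrow(off) == 0) break
        i <- off[1, 1]; j <- off[1, 2]
        mi <- maf[w[i]]; mj <- maf[w[j]]
        victim <- if (isTRUE(mi < mj)) i else if (isTRUE(mj < mi)) j else j
        alive[victim] <- FALSE
      }
      keep[w[!alive]] <- FALSE
    }
  }
  ds$markers$marker_id[keep]
}

#' Run the marker QC pipeline
#'
#' Applies the filters in order: call rate, MAF, Hardy-Weinberg. Each marker
#' is attributed to the first filter it fails. LD pruning is *not* part of
#' this pipeline: it is applied separately (see [ld_prune()]) only ahead of
#' the structure analyses, while the selection scans use the full post-QC
#' panel.
#'
#' @inheritParams call_rate_filter
#' @param cfg a [qc_config()].
#' @return List with `dataset` (post-QC) and `report` (class `qc_report`).
#' @export
run_qc <- function(ds, cfg = qc_config()) {
  n_in <- ncol(ds$genotypes)
  st1 <- call_rate_filter(ds, cfg$min_call_rate)
  st2 <- maf_filter(st1$dataset, cfg$min_maf)
  st3 <- hwe_filter(st2$dataset, cfg$hwe_alpha)
  report <- structure(
    list(stages = data.frame(
      stage = c("call_rate", "maf", "hwe"),
      removed = c(length(st1$removed), length(st2$removed),
                  length(st3$removed)),
      retained = c(ncol(st1$dataset$genotypes), ncol(st2$dataset$genotypes),
                   ncol(st3$dataset$genotypes)),
      stringsAsFactors = FALSE),
      n_in = n_in, n_out = ncol(st3$dataset$genotypes),
      samples_retained = nrow(ds$genotypes),
      removed_ids = list(call_rate = st1$removed, maf = st2$removed,
                         hwe = st3$removed)),
    class = "qc_report")
  list(dataset = st3$dataset, report = report)
}

#' @export
#' @method print qc_report
print.qc_report <- function(x, ...) {
  cat("marker QC:", x$n_in, "in ->", x$n_out, "retained;",
      x$samples_retained, "samples\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report a `qc_report`.
#' @param path output TSV path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report$stages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
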