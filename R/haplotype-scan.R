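#' Filter haplotypes and markers to a complete matrix
#'
#' Two-step rule: first drop haplotype rows whose missing fraction exceeds
#' `max_row_missing` (with the default 0, any missing call removes the row),
#' then drop markers still missing in any surviving row. The result is a
#' complete 0/1 matrix (a sample may be left with a single haplotype row).
#'
#' @param hs a `haplotype_set`.
#' @param max_row_missing largest tolerated fraction of missing calls per
#'   haplotype row (default 0).
#' @return A complete `haplotype_set`.
#' @export
filter_haplotypes <- function(hs, max_row_missing = 0) {
  H <- hs$haplotypes
  keep_row <- rowMeans(is.na(H)) <= max_row_missing
  H <- H[keep_row, , drop = FALSE]
  keep_col <- colSums(is.na(H)) == 0
  if (!nrow(H) || !sum(keep_col)) stop("filtering left no complete data")
  haplotype_set(H[, keep_col, drop = FALSE], hs$carrier[keep_row],
                hs$markers[keep_col, , drop = FALSE], hs$pop_of)
}

reason_labels <- c("cutoff", "gap", "chrom_end", "max_extend")

#' Site-EHH decay around a core marker
#'
#' The site (allele-agnostic) extended haplotype homozygosity at flank
#' marker x is the number of haplotype pairs identical over every marker in
#' `[core..x]` divided by the number of pairs identical at the core site, so
#' it equals 1 at the core and is non-increasing outward. The decay is
#' walked in both directions until it falls below `cutoff` (the first
#' below-cutoff marker is not included), an inter-marker gap exceeds
#' `max_gap_bp`, or the chromosome end is reached; the stop reason is
#' recorded per flank.
#'
#' @param hs a complete `haplotype_set` (see [filter_haplotypes()]).
#' @param core marker id or column index of the core SNP.
#' @param pop population label; `NULL` uses all haplotypes.
#' @param cutoff EHHS floor ending the walk (default 0.05).
#' @param max_gap_bp largest tolerated inter-marker gap (default 200 kb).
#' @param max_extend_bp farthest distance the decay is followed from the
#'   core (default 2.5 Mb); caps the integration support the way selection
#'   scans conventionally bound extended-haplotype integrals.
#' @return Object of class `ehh_decay`: data.frame `(pos_bp, side, ehhs)`
#'   including the core row, plus per-flank stop reasons.
#' @export
ehhs_decay <- function(hs, core, pop = NULL, cutoff = 0.05,
                       max_gap_bp = 2e5, max_extend_bp = 2.5e6) {
  mk <- hs$markers
  if (is.character(core)) core <- match(core, mk$marker_id)
  if (is.na(core) || core < 1 || core > nrow(mk)) stop("core marker not found")
  rows <- if (is.null(pop)) seq_len(nrow(hs$haplotypes)) else pop_rows(hs, pop)
  if (length(rows) < 2) stop("need at least two haplotypes")
  chrom <- mk$chrom[core]
  cols <- which(mk$chrom == chrom)
  H <- hs$haplotypes[rows, cols, drop = FALSE]
  if (anyNA(H)) stop("haplotypes contain missing values; filter first")
  pos <- as.numeric(mk$pos_bp[cols])
  c0 <- match(core, cols) - 1L
  left <- .ehhs_flank_cpp(H, c0, -1L, cutoff, max_gap_bp, pos, max_extend_bp)
  right <- .ehhs_flank_cpp(H, c0, 1L, cutoff, max_gap_bp, pos, max_extend_bp)
  df <- rbind(
    data.frame(pos_bp = rev(pos[left$idx + 1L]),
               side = rep("left", length(left$idx)),
               ehhs = rev(left$ehhs)),
    data.frame(pos_bp = pos[c0 + 1L], side = "core", ehhs = 1),
    data.frame(pos_bp = pos[right$idx + 1L],
               side = rep("right", length(right$idx)),
               ehhs = right$ehhs))
  structure(list(decay = df, core_pos = pos[c0 + 1L], chrom = chrom,
                 reason = c(left = reason_labels[left$reason + 1L],
                            right = reason_labels[right$reason + 1L])),
            class = "ehh_decay")
}

#' @export
#' @method print ehh_decay
print.ehh_decay <- function(x, ...) {
  cat("EHHS decay at", x$chrom, ":", x$core_pos, "-",
      nrow(x$decay) - 1, "flank point(s); stop:",
      paste(names(x$reason), x$reason, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Integrated EHHS (iES)
#'
#' Trapezoidal integral of the EHHS decay against physical distance (bp),
#' summed over both flanks from the core to each truncation point. A
#' zero-length support gives 0.
#'
#' @param decay an `ehh_decay`.
#' @return iES in base pairs.
#' @export
integrate_ies <- function(decay) {
  df <- decay$decay
  total <- 0
  for (s in c("left", "right")) {
    seg <- df[df$side == s, , drop = FALSE]
    x <- c(decay$core_pos, seg$pos_bp[order(abs(seg$pos_bp - decay$core_pos))])
    e <- c(1, seg$ehhs[order(abs(seg$pos_bp - decay$core_pos))])
    if (length(x) > 1)
      total <- total + sum(abs(diff(x)) * (utils::head(e, -1) + e[-1]) / 2)
  }
  total
}

#' Cross-population EHH log-ratio at one core
#'
#' `ln(iES_popA / iES_popB)` at a single core marker; positive values point
#' to longer haplotype homozygosity (hence putative selection) in `pop_a`.
#'
#' @inheritParams ehhs_decay
#' @param pop_a,pop_b population labels (numerator, denominator).
#' @return The raw (unstandardized) log-ratio, or `NA` when either
#'   population's iES is zero.
#' @export
xpehh <- function(hs, core, pop_a, pop_b, cutoff = 0.05, max_gap_bp = 2e5,
                  max_extend_bp = 2.5e6) {
  ia <- integrate_ies(ehhs_decay(hs, core, pop_a, cutoff, max_gap_bp,
                                 max_extend_bp))
  ib <- integrate_ies(ehhs_decay(hs, core, pop_b, cutoff, max_gap_bp,
                                 max_extend_bp))
  if (ia <= 0 || ib <= 0) return(NA_real_)
  log(ia / ib)
}

#' Genome-wide standardization
#'
#' Centres and scales to unit variance over non-missing values (no allele
#' frequency binning). Idempotent on already-standardized input.
#'
#' @param x numeric vector with at least two distinct non-missing values.
#' @return z-scores with mean 0 and SD 1.
#' @export
standardize_scores <- function(x) {
  if (sum(!is.na(x)) < 2) stop("need at least two values")
  s <- stats::sd(x, na.rm = TRUE)
  if (s == 0) stop("zero standard deviation")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Gaussian two-sided p-transform of a standardized score
#'
#' `-log10(1 - 2 |Phi(z) - 0.5|)`, i.e. the two-sided normal tail
#' probability of `z` on a -log10 scale; 0 at `z = 0` and symmetric in the
#' sign of `z`. Values are capped at `max_p` to guard overflow for extreme
#' scores (computed in log space, so the cap only binds beyond
#' `|z| ~ 37`).
#'
#' @param z standardized score(s).
#' @param max_p cap on the returned -log10 p (default 300).
#' @return -log10 two-sided p-value(s), in `[0, max_p]`.
#' @export
p_xpehh <- function(z, max_p = 300) {
  lp <- stats::pnorm(-abs(z), log.p = TRUE) + log(2)   # log two-sided p
  pmin(pmax(-lp / log(10), 0), max_p)
}

#' Benjamini-Hochberg FDR on -log10 p-values
#'
#' Converts the -log10 scale back to probabilities, applies the step-up
#' Benjamini-Hochberg adjustment (with monotonicity enforcement), and flags
#' values with adjusted p at or below `q_level`.
#'
#' @param p_log10 vector of -log10 p-values (`NA` allowed).
#' @param q_level FDR level (default 0.05).
#' @return List with `q` (adjusted p, probability scale) and `significant`.
#' @export
bh_fdr <- function(p_log10, q_level = 0.05) {
  if (!length(p_log10)) stop("empty input")
  p <- 10^(-p_log10)
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = !is.na(q) & q <= q_level)
}

#' Cross-population haplotype scan
#'
#' Computes iES per core SNP in each population (site-EHH decay truncated at
#' `cutoff` or `max_gap_bp`), the raw log-ratio
#' `ln(iES_popA / iES_popB)`, the genome-wide standardized score z, the
#' Gaussian two-sided -log10 p, and Benjamini-Hochberg adjusted q-values.
#' With the reference labelling `pop_a = "NS"`, `pop_b = "SJ"`, positive z
#' points to selection in NS and negative z to selection in SJ. Cores whose
#' decay hits a chromosome end before dropping below `cutoff` in either
#' population are excluded from standardization by default; an alternative
#' fixed `|z| >= z_rule` flag is also reported.
#'
#' @param hs a complete `haplotype_set` with population labels.
#' @param pop_a,pop_b population labels (numerator, denominator).
#' @param cutoff,max_gap_bp,max_extend_bp decay truncation controls (see
#'   [ehhs_decay()]).
#' @param fdr FDR level for the primary significance call (default 0.05).
#' @param exclude_chrom_end drop chromosome-end-truncated cores (default
#'   `TRUE`).
#' @param z_rule threshold for the alternative fixed-|z| flag (default 4).
#' @return Object of class `xpehh_scan`: per-SNP data.frame (`marker_id`,
#'   `chrom`, `pos_bp`, `raw`, `z`, `p_log10`, `q`, `direction`,
#'   `significant`, `significant_z`), plus counts of excluded cores.
#' @export
xpehh_scan <- function(hs, pop_a = "NS", pop_b = "SJ", cutoff = 0.05,
                       max_gap_bp = 2e5, max_extend_bp = 2.5e6, fdr = 0.05,
                       exclude_chrom_end = TRUE, z_rule = 4) {
  mk <- hs$markers
  if (anyNA(hs$haplotypes)) stop("haplotypes contain missing values; filter first")
  ra <- pop_rows(hs, pop_a); rb <- pop_rows(hs, pop_b)
  if (length(ra) < 2 || length(rb) < 2)
    stop("both populations need at least two haplotypes")
  m <- nrow(mk)
  ies_a <- ies_b <- rep(NA_real_, m)
  end_flag <- rep(FALSE, m)
  for (ch in unique(mk$chrom)) {
    cols <- which(mk$chrom == ch)
    pos <- as.numeric(mk$pos_bp[cols])
    sa <- .ies_scan_cpp(hs$haplotypes[ra, cols, drop = FALSE], pos,
                        cutoff, max_gap_bp, exclude_chrom_end, max_extend_bp)
    sb <- .ies_scan_cpp(hs$haplotypes[rb, cols, drop = FALSE], pos,
                        cutoff, max_gap_bp, exclude_chrom_end, max_extend_bp)
    ies_a[cols] <- sa[, "ies"]
    ies_b[cols] <- sb[, "ies"]
    ends <- sa[, "reason_left"] == 2 | sa[, "reason_right"] == 2 |
      sb[, "reason_left"] == 2 | sb[, "reason_right"] == 2
    end_flag[cols] <- !is.na(ends) & ends
  }
  raw <- ifelse(!is.na(ies_a) & !is.na(ies_b) & ies_a > 0 & ies_b > 0,
                log(ies_a / ies_b), NA_real_)
  n_end_excluded <- 0L
  if (exclude_chrom_end) {
    n_end_excluded <- sum(end_flag)
    raw[end_flag] <- NA_real_
  }
  z <- standardize_scores(raw)
  p <- p_xpehh(z)
  adj <- bh_fdr(p, fdr)
  df <- data.frame(marker_id = mk$marker_id, chrom = mk$chrom,
                   pos_bp = mk$pos_bp, ies_a = ies_a, ies_b = ies_b,
                   raw = raw, z = z, p_log10 = p, q = adj$q,
                   direction = ifelse(is.na(z), NA_character_,
                                      ifelse(z > 0, pop_a, pop_b)),
                   significant = adj$significant,
                   significant_z = !is.na(z) & abs(z) >= z_rule,
                   stringsAsFactors = FALSE)
  structure(list(snps = df, pop_a = pop_a, pop_b = pop_b, fdr = fdr,
                 cutoff = cutoff, max_gap_bp = max_gap_bp,
                 max_extend_bp = max_extend_bp,
                 n_end_excluded = n_end_excluded),
            class = "xpehh_scan")
}

#' @export
#' @method print xpehh_scan
print.xpehh_scan <- function(x, ...) {
  ok <- !is.na(x$snps$z)
  cat(sprintf("XPEHH scan (%s vs %s): %d cores scored, %d excluded at chromosome ends\n",
              x$pop_a, x$pop_b, sum(ok), x$n_end_excluded))
  cat(sprintf("  BH-FDR %.2f: %d significant; |z|>=4 rule: %d\n", x$fdr,
              sum(x$snps$significant), sum(x$snps$significant_z)))
  invisible(x)
}

#' @export
#' @param x an `xpehh_scan`.
#' @param what plot the standardized score (`"z"`) or `-log10 p` (`"p"`).
#' @param ... passed to [graphics::plot()].
#' @rdname xpehh_scan
#' @method plot xpehh_scan
plot.xpehh_scan <- function(x, what = c("z", "p"), ...) {
  what <- match.arg(what)
  df <- x$snps[!is.na(x$snps$z), ]
  chrom <- factor(df$chrom, levels = unique(df$chrom))
  offs <- c(0, cumsum(tapply(df$pos_bp, chrom, max)))
  xp <- df$pos_bp + offs[as.integer(chrom)]
  y <- if (what == "z") df$z else df$p_log10
  graphics::plot(xp, y, pch = 16, cex = 0.4,
                 col = as.integer(chrom) %% 2 + 1, xlab = "genome position",
                 ylab = if (what == "z") "XPEHH (z)" else "-log10 p", ...)
  if (what == "z") graphics::abline(h = c(-4, 4), lty = 3)
  invisible(x)
}

#' Write a per-SNP XPEHH track as TSV
#'
#' @param scan an `xpehh_scan`.
#' @param path output TSV path.
#' @export
write_xpehh_tsv <- function(scan, path) {
  utils::write.table(scan$snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
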