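#' Run the full divergence-scan pipeline
#'
#' Orchestrates the analysis end to end: marker QC; LD-pruned population
#' structure (PCoA, BIC cluster inference, DAPC with optional
#' cross-validated PC retention); the per-SNP F_ST scan and the
#' cross-population haplotype (XPEHH) scan on the full post-QC panel;
#' candidate-region construction with F_ST/XPEHH concordance; and optional
#' gene/QTL annotation. Inputs may be in-memory objects or file paths (PLINK
#' prefix, phased VCF, sample TSV). All outputs are regenerable from the
#' inputs plus `seed`.
#'
#' @param genotypes a `genotype_dataset` or a PLINK path prefix.
#' @param haplotypes a `haplotype_set` or a phased-VCF path.
#' @param samples optional sample data.frame (or TSV path) with `sample_id`
#'   and `ebv_jump`; groups are assigned by [assign_groups()]. When absent,
#'   the haplotype set's population labels are used.
#' @param gff3,qtl_bed optional annotation inputs.
#' @param qc a [qc_config()].
#' @param k_range,n_pcs_kept BIC clustering controls.
#' @param pcs_grid,cv_reps when `pcs_grid` is non-`NULL`, the DAPC PC count
#'   is chosen by [dapc_crossvalidate()] with `cv_reps` replicates;
#'   otherwise `n_pcs_dapc` is used directly.
#' @param n_pcs_dapc PCs retained by DAPC when no grid is given.
#' @param top_fraction,fdr,pad_bp,ehh_cutoff,max_gap_bp,max_extend_bp scan
#'   and region parameters.
#' @param pop_a,pop_b XPEHH numerator/denominator population labels.
#' @param do_structure run the PCoA/DAPC stage (default `TRUE`).
#' @param out_dir write TSV outputs and a run log there when non-`NULL`.
#' @param seed seed for the stochastic stages (K-means restarts,
#'   cross-validation splits).
#' @return Object of class `divscan_report` collecting every stage result.
#' @export
run_scan <- function(genotypes, haplotypes, samples = NULL, gff3 = NULL,
                     qtl_bed = NULL, qc = qc_config(), k_range = 1:5,
                     n_pcs_kept = NULL, pcs_grid = NULL, cv_reps = 30,
                     n_pcs_dapc = 10, top_fraction = 0.001, fdr = 0.05,
                     pad_bp = 250000, ehh_cutoff = 0.05, max_gap_bp = 2e5,
                     max_extend_bp = 2.5e6,
                     pop_a = "NS", pop_b = "SJ", do_structure = TRUE,
                     out_dir = NULL, seed = 1) {
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  if (is.character(genotypes)) genotypes <- read_plink(genotypes)
  if (is.character(haplotypes)) haplotypes <- read_phased_vcf(haplotypes)
  if (is.character(samples)) samples <- read_sample_table(samples)

  if (!is.null(samples)) {
    samples <- assign_groups(samples)
    idx <- match(genotypes$samples$sample_id, samples$sample_id)
    if (anyNA(idx)) stop("sample table does not cover all genotyped samples")
    genotypes$samples <- cbind(genotypes$samples[
      setdiff(names(genotypes$samples), names(samples))],
      samples[idx, , drop = FALSE])
    labels <- genotypes$samples$group
  } else if (!is.null(haplotypes$pop_of)) {
    labels <- factor(haplotypes$pop_of[genotypes$samples$sample_id])
    genotypes$samples$group <- labels
  } else stop("no sample table and no population labels on the haplotypes")
  say("groups: %s", paste(names(table(labels)), table(labels),
                          sep = "=", collapse = ", "))
  if (is.null(haplotypes$pop_of))
    haplotypes$pop_of <- stats::setNames(as.character(labels),
                                         genotypes$samples$sample_id)

  qc_res <- run_qc(genotypes, qc)
  ds <- qc_res$dataset
  say("QC: %d -> %d markers", qc_res$report$n_in, qc_res$report$n_out)

  structure_res <- NULL
  if (do_structure) {
    pruned_ids <- ld_prune(ds, qc)
    pruned <- subset_markers(ds, ds$markers$marker_id %in% pruned_ids)
    say("LD pruning for structure: %d -> %d markers", qc_res$report$n_out,
        length(pruned_ids))
    pc <- pcoa(ibs_similarity(pruned))
    bic <- find_clusters_bic(pruned, k_range = k_range,
                             n_pcs_kept = n_pcs_kept, seed = seed)
    say("BIC best K = %d", bic$best_k)
    cv <- NULL
    n_pcs <- n_pcs_dapc
    if (!is.null(pcs_grid)) {
      cv <- dapc_crossvalidate(pruned, labels, pcs_grid, reps = cv_reps,
                               seed = seed)
      n_pcs <- cv$chosen_n_pcs
      say("cross-validation chose %d PCs", n_pcs)
    }
    dapc <- dapc_fit(pruned, labels, n_pcs)
    say("DAPC self-assignment: %.1f%%", 100 * dapc$self_assignment)
    structure_res <- list(pcoa = pc, bic = bic, cv = cv, dapc = dapc,
                          pruned_ids = pruned_ids)
  }

  fst <- fst_scan(ds, labels, top_fraction)
  say("F_ST: mean %.4f, threshold %.4f, %d significant",
      fst$summary["mean"], fst$threshold, sum(fst$snps$significant))

  hs <- filter_haplotypes(haplotypes)
  keep <- hs$markers$marker_id %in% ds$markers$marker_id
  hs <- haplotype_set(hs$haplotypes[, keep, drop = FALSE], hs$carrier,
                      hs$markers[keep, , drop = FALSE], hs$pop_of)
  xp <- xpehh_scan(hs, pop_a = pop_a, pop_b = pop_b, cutoff = ehh_cutoff,
                   max_gap_bp = max_gap_bp, max_extend_bp = max_extend_bp,
                   fdr = fdr)
  say("XPEHH: %d significant at FDR %.2f", sum(xp$snps$significant), fdr)

  sig <- xp$snps[xp$snps$significant, , drop = FALSE]
  regions <- build_regions(sig, pad_bp = pad_bp)
  regions <- concordance(regions, fst)
  say("regions: %d built, %d concordant", nrow(regions),
      sum(regions$concordant))

  annotation <- NULL
  if (!is.null(gff3) && nrow(regions)) {
    annotation <- annotate_genes(regions, gff3)
    say("genes overlapping regions: %d", nrow(annotation$genes))
  }
  qtl <- NULL
  if (!is.null(qtl_bed) && nrow(regions)) qtl <- qtl_overlap(regions, qtl_bed)

  group_summary <- NULL
  ebv_cols <- intersect(c("ebv_jump", "ebv_dressage"),
                        names(genotypes$samples))
  if (length(ebv_cols)) {
    lv <- levels(factor(labels))
    group_summary <- do.call(rbind, lapply(lv, function(g) {
      d <- genotypes$samples[labels == g, ebv_cols, drop = FALSE]
      data.frame(group = g, trait = ebv_cols,
                 n = nrow(d),
                 mean = vapply(d, mean, 0, na.rm = TRUE),
                 sd = vapply(d, stats::sd, 0, na.rm = TRUE),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }

  report <- structure(list(
    qc = qc_res$report, structure = structure_res, fst = fst, xpehh = xp,
    regions = regions, annotation = annotation, qtl = qtl,
    group_summary = group_summary, labels = labels, seed = seed,
    params = list(qc = qc, top_fraction = top_fraction, fdr = fdr,
                  pad_bp = pad_bp, ehh_cutoff = ehh_cutoff,
                  max_gap_bp = max_gap_bp, max_extend_bp = max_extend_bp,
                  pop_a = pop_a, pop_b = pop_b),
    log = log_lines), class = "divscan_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
#' @method print divscan_report
print.divscan_report <- function(x, ...) {
  cat("divergence-scan report\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Write all report tables to a directory
#'
#' Emits the QC report, structure tables (coordinates, eigenvalues, BIC, CV,
#' membership posteriors), the per-SNP F_ST and XPEHH tracks, candidate
#' regions (TSV and BED), gene/QTL annotations, the group summary, and a run
#' log with the effective parameters and seed.
#'
#' @param report a `divscan_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_qc_report(report$qc, file.path(out_dir, "qc_report.tsv"))
  if (!is.null(report$structure)) {
    st <- report$structure
    w(data.frame(sample_id = rownames(st$pcoa$coordinates),
                 st$pcoa$coordinates[, seq_len(min(10, ncol(st$pcoa$coordinates)))]),
      "pcoa_coordinates.tsv")
    w(data.frame(axis = seq_along(st$pcoa$variance_explained),
                 variance_explained = st$pcoa$variance_explained),
      "pcoa_variance.tsv")
    w(st$bic$table, "bic_table.tsv")
    if (!is.null(st$cv)) w(st$cv$table, "dapc_cv.tsv")
    w(data.frame(sample_id = rownames(st$dapc$posterior),
                 st$dapc$posterior, assigned = st$dapc$assign),
      "dapc_membership.tsv")
  }
  write_fst_tsv(report$fst, file.path(out_dir, "fst_snps.tsv"))
  write_xpehh_tsv(report$xpehh, file.path(out_dir, "xpehh_snps.tsv"))
  w(as.data.frame(report$regions), "regions.tsv")
  if (nrow(report$regions))
    write_regions_bed(report$regions, file.path(out_dir, "regions.bed"))
  if (!is.null(report$annotation)) w(report$annotation$genes, "region_genes.tsv")
  if (!is.null(report$qtl)) w(report$qtl, "qtl_overlap.tsv")
  if (!is.null(report$group_summary)) w(report$group_summary,
                                        "group_summary.tsv")
  writeLines(c(report$log,
               paste0("seed: ", report$seed),
               paste0("params: ", paste(names(unlist(report$params)),
                                        unlist(report$params), sep = "=",
                                        collapse = " "))),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Demonstration run on simulated data
#'
#' Simulates a cohort with one planted sweep, writes the fixtures to disk,
#' and runs the full pipeline from those files — a smoke test of every
#' reader and stage from a single seed.
#'
#' @param seed simulation and analysis seed.
#' @param dir working directory (default a temporary one).
#' @param ... passed on to [sim_config()].
#' @return The `divscan_report`, with the simulation attached as attribute
#'   `"sim"`.
#' @export
run_demo <- function(seed = 1, dir = tempfile("divscan_demo"), ...) {
  cfg <- sim_config(seed = seed, ...)
  cfg$sweeps <- data.frame(chrom = as.character(ceiling(cfg$n_chrom / 2)),
                           pos_bp = round(cfg$chrom_len_bp / 2), s = 0.1,
                           target_pop = "SJ", stringsAsFactors = FALSE)
  sim <- simulate_divergence(cfg)
  paths <- write_fixtures(sim, dir)
  report <- run_scan(genotypes = sub("\\.bed$", "", paths[["bed"]]),
                     haplotypes = paths[["vcf"]],
                     samples = paths[["samples"]],
                     out_dir = file.path(dir, "out"), seed = seed)
  attr(report, "sim") <- sim
  report
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [run_scan()] (input
#' paths under `genotypes`, `haplotypes`, `samples`, `gff3`, `qtl_bed`; QC
#' thresholds under `qc:`; scan options at the top level) and runs the
#' pipeline.
#'
#' @param path YAML config file.
#' @return The `divscan_report`.
#' @export
run_scan_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$qc)) cfg$qc <- do.call(qc_config, cfg$qc)
  for (f in c("genotypes", "haplotypes", "samples", "gff3", "qtl_bed")) {
    if (!is.null(cfg[[f]]) && f %in% c("gff3", "qtl_bed", "samples") &&
        !file.exists(cfg[[f]]))
      stop("configured file does not exist: ", cfg[[f]])
  }
  do.call(run_scan, cfg)
}
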