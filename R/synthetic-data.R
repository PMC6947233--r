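#' Simulation configuration
#'
#' Parameters of the forward Wright-Fisher generator of two diverging
#' diploid subpopulations. The defaults emulate a sport-horse-like cohort
#' at desk scale: two groups of 190 diploids, 5 chromosomes of 2,000 SNPs
#' over 25 Mb each, recombination at 1 cM/Mb, a burn-in to build linkage
#' disequilibrium, and 50 generations of post-split drift. Pseudo breeding
#' values are drawn per group from the bimodal mixture N(125, 13.4) /
#' N(77, 11.3) on the EBV scale (population mean 100).
#'
#' @param n_pop diploid individuals per subpopulation.
#' @param n_chrom number of chromosomes.
#' @param m_snps markers per chromosome.
#' @param chrom_len_bp chromosome length in bp.
#' @param recomb_rate per-bp, per-generation crossover rate.
#' @param split_generations generations of independent drift after the split.
#' @param burn_in random-mating generations before the split (builds LD).
#' @param n_anc diploid size of the ancestral (pre-split) population. The
#'   default is larger than `n_pop` because two recently specialized
#'   subgroups descend from a base population with far more breeding
#'   animals than either subgroup.
#' @param ancestral_maf_dist Beta(a, b) parameters of ancestral site
#'   frequencies; the default Beta(2, 2) mimics the common-variant spectrum
#'   of a genotyping array.
#' @param sweeps data.frame with columns `chrom`, `pos_bp`, `s`,
#'   `target_pop`, or `NULL` for pure drift. Each sweep allele starts at
#'   `sweep_init_freq` in the ancestral pool (standing variation) and is
#'   driven by genic selection (fitness 1, 1+s, 1+2s) in its target
#'   population only.
#' @param sweep_init_freq standing frequency of each sweep allele at the
#'   split (default 0.05).
#' @param missing_rate genotype missingness rate (haplotypes stay complete,
#'   as after statistical phasing).
#' @param pop_labels labels of the two subpopulations.
#' @param ebv_mean,ebv_sd per-population pseudo-EBV means and SDs.
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pop = 190, n_chrom = 5, m_snps = 2000,
                       chrom_len_bp = 2.5e7, recomb_rate = 1e-8,
                       split_generations = 50, burn_in = 100, n_anc = 500,
                       ancestral_maf_dist = c(2, 2), sweeps = NULL,
                       sweep_init_freq = 0.05, missing_rate = 0.002,
                       pop_labels = c("SJ", "NS"),
                       ebv_mean = c(SJ = 125, NS = 77),
                       ebv_sd = c(SJ = 13.4, NS = 11.3), seed = 1) {
  stopifnot(n_pop >= 2, n_chrom >= 1, m_snps >= 2, chrom_len_bp > m_snps,
            recomb_rate >= 0, split_generations >= 0, burn_in >= 0,
            n_anc >= 2,
            length(ancestral_maf_dist) == 2, all(ancestral_maf_dist > 0),
            sweep_init_freq > 0, sweep_init_freq < 1,
            missing_rate >= 0, missing_rate < 1, length(pop_labels) == 2)
  if (!is.null(sweeps)) {
    sweeps <- as.data.frame(sweeps, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "pos_bp", "s", "target_pop") %in% names(sweeps)),
              all(sweeps$pos_bp >= 1), all(sweeps$pos_bp <= chrom_len_bp),
              all(sweeps$s >= 0), all(sweeps$target_pop %in% pop_labels))
  }
  structure(list(n_pop = n_pop, n_chrom = n_chrom, m_snps = m_snps,
                 chrom_len_bp = chrom_len_bp, recomb_rate = recomb_rate,
                 split_generations = split_generations, burn_in = burn_in,
                 n_anc = n_anc,
                 ancestral_maf_dist = ancestral_maf_dist, sweeps = sweeps,
                 sweep_init_freq = sweep_init_freq,
                 missing_rate = missing_rate, pop_labels = pop_labels,
                 ebv_mean = ebv_mean, ebv_sd = ebv_sd, seed = seed),
            class = "sim_config")
}

# evolve one population for T generations; selection on sweep columns
evolve_pop <- function(H, n_gen, cfg, chrom_start, chrom_end, pos, lens,
                       sweep_cols = integer(), sweep_s = numeric()) {
  n <- ncol(H) / 2
  for (g in seq_len(n_gen)) {
    w <- rep(1, n)
    for (k in seq_along(sweep_cols)) {
      hap <- H[sweep_cols[k], ]
      dos <- hap[seq(1, 2 * n, 2)] + hap[seq(2, 2 * n, 2)]
      w <- w * (1 + sweep_s[k] * dos)
    }
    H <- .wf_next_gen_cpp(H, chrom_start, chrom_end, pos, lens,
                          cfg$recomb_rate, w, n)
  }
  H
}

#' Simulate two diverging subpopulations
#'
#' Forward-in-time generator: an ancestral pool with site frequencies from
#' Beta(a, b) and independent sites runs `burn_in` generations of random
#' mating with recombination (inducing LD and drift), optionally seeds each
#' configured sweep allele at `sweep_init_freq` as standing variation, then
#' splits into two populations that drift independently for
#' `split_generations` generations, with genic selection (1, 1+s, 1+2s) on
#' each sweep in its target population. A sweep allele lost to drift is
#' retried up to `retry_cap` times and reported if still lost. Genotype
#' missingness is applied at `missing_rate`; haplotypes stay complete.
#'
#' @param cfg a [sim_config()].
#' @param retry_cap retries per population when a sweep allele is lost.
#' @return List of class `divscan_sim` with `haplotypes` (a
#'   [haplotype_set()]), `genotypes` (a [genotype_dataset()] including
#'   pseudo-EBVs and EBV-derived groups in the sample table), `truth`
#'   (data.frame: one row per sweep, with realized final frequencies), and
#'   the `config`.
#' @export
simulate_divergence <- function(cfg = sim_config(), retry_cap = 10) {
  set.seed(cfg$seed)
  m_tot <- cfg$n_chrom * cfg$m_snps
  chroms <- as.character(seq_len(cfg$n_chrom))
  pos_list <- lapply(seq_len(cfg$n_chrom), function(ch)
    sort(sample.int(cfg$chrom_len_bp - 1L, cfg$m_snps)))
  markers <- data.frame(
    marker_id = unlist(lapply(seq_len(cfg$n_chrom), function(ch)
      sprintf("snp%s_%d", chroms[ch], seq_len(cfg$m_snps)))),
    chrom = rep(chroms, each = cfg$m_snps),
    pos_bp = unlist(pos_list),
    allele_ref = "A", allele_alt = "B", stringsAsFactors = FALSE)
  pos <- as.numeric(markers$pos_bp)
  chrom_start <- as.integer(seq(0, m_tot - 1, by = cfg$m_snps))
  chrom_end <- as.integer(chrom_start + cfg$m_snps - 1L)
  lens <- rep(as.numeric(cfg$chrom_len_bp), cfg$n_chrom)

  n <- cfg$n_pop
  na <- cfg$n_anc
  p0 <- stats::rbeta(m_tot, cfg$ancestral_maf_dist[1], cfg$ancestral_maf_dist[2])
  # marker-major orientation (markers x haplotypes) through the forward pass
  H <- matrix(stats::rbinom(2L * na * m_tot, 1L, p0), nrow = m_tot)
  storage.mode(H) <- "integer"
  if (cfg$burn_in > 0)
    H <- evolve_pop(H, cfg$burn_in, cfg, chrom_start, chrom_end, pos, lens)

  sweep_cols <- integer(0); sweep_s <- numeric(0); sweep_target <- character(0)
  if (!is.null(cfg$sweeps) && nrow(cfg$sweeps)) {
    for (k in seq_len(nrow(cfg$sweeps))) {
      ch <- as.character(cfg$sweeps$chrom[k])
      cand <- which(markers$chrom == ch)
      if (!length(cand)) stop("sweep chromosome not in the map: ", ch)
      col <- cand[which.min(abs(markers$pos_bp[cand] - cfg$sweeps$pos_bp[k]))]
      sweep_cols <- c(sweep_cols, col)
      sweep_s <- c(sweep_s, cfg$sweeps$s[k])
      sweep_target <- c(sweep_target, cfg$sweeps$target_pop[k])
      # plant the allele as single-origin standing variation: every carrier
      # receives an identity-by-descent copy of one origin haplotype around
      # the site, eroded by recombination. Segment lengths are exponential
      # with rate age * recomb_rate, where the allele age is the neutral
      # expectation E[age | freq f] = -4N f ln(f) / (1 - f) generations --
      # derived from the configuration, not a free parameter.
      f0 <- cfg$sweep_init_freq
      n_copies <- max(1L, round(2 * na * f0))
      age <- max(1, -4 * na * f0 * log(f0) / (1 - f0))
      seg_rate <- age * cfg$recomb_rate
      chrom_cols <- which(markers$chrom == ch)
      cpos <- markers$pos_bp[chrom_cols]
      origin <- sample.int(2 * na, 1)
      carriers <- unique(c(origin,
                           sample(setdiff(seq_len(2 * na), origin),
                                  n_copies - 1L)))
      for (cr in carriers) {
        if (cr == origin) next
        lo <- markers$pos_bp[col] - stats::rexp(1, seg_rate)
        hi <- markers$pos_bp[col] + stats::rexp(1, seg_rate)
        seg <- chrom_cols[cpos >= lo & cpos <= hi]
        H[seg, cr] <- H[seg, origin]
      }
      colvals <- integer(2 * na)
      colvals[carriers] <- 1L
      H[col, ] <- colvals
    }
  }

  pops <- list()
  for (p in seq_along(cfg$pop_labels)) {
    lab <- cfg$pop_labels[p]
    mine <- which(sweep_target == lab)
    for (attempt in seq_len(retry_cap + 1)) {
      Hp <- .wf_next_gen_cpp(H, chrom_start, chrom_end, pos, lens,
                             cfg$recomb_rate, rep(1, na), n)
      Hp <- evolve_pop(Hp, cfg$split_generations, cfg, chrom_start,
                       chrom_end, pos, lens, sweep_cols[mine], sweep_s[mine])
      lost <- length(mine) && any(rowSums(Hp[sweep_cols[mine], , drop = FALSE]) == 0)
      if (!lost) break
    }
    pops[[lab]] <- list(H = Hp, retries = attempt - 1L,
                        lost = if (length(mine))
                          rowSums(Hp[sweep_cols[mine], , drop = FALSE]) == 0
                        else logical(0))
  }

  sample_ids <- unlist(lapply(cfg$pop_labels, function(l)
    sprintf("%s_%03d", l, seq_len(n))))
  pop_of <- stats::setNames(rep(cfg$pop_labels, each = n), sample_ids)
  Hall <- t(do.call(cbind, lapply(pops, `[[`, "H")))
  carrier <- rep(sample_ids, each = 2)
  hs <- haplotype_set(Hall, carrier, markers, pop_of = pop_of)

  g <- Hall[seq(1, nrow(Hall), 2), , drop = FALSE] +
    Hall[seq(2, nrow(Hall), 2), , drop = FALSE]
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(g)) < cfg$missing_rate
    g[mask] <- NA_integer_
  }
  ebv <- make_pseudo_ebvs(rep(cfg$pop_labels, each = n),
                          mean_sj = cfg$ebv_mean[[1]], sd_sj = cfg$ebv_sd[[1]],
                          mean_ns = cfg$ebv_mean[[2]], sd_ns = cfg$ebv_sd[[2]])
  samples <- assign_groups(data.frame(sample_id = sample_ids,
                                      true_pop = rep(cfg$pop_labels, each = n),
                                      ebv_jump = ebv,
                                      stringsAsFactors = FALSE))
  ds <- genotype_dataset(g, markers, samples)

  truth <- if (length(sweep_cols)) {
    freq <- vapply(cfg$pop_labels, function(l)
      rowMeans(pops[[l]]$H[sweep_cols, , drop = FALSE]), numeric(length(sweep_cols)))
    freq <- matrix(freq, nrow = length(sweep_cols),
                   dimnames = list(NULL, cfg$pop_labels))
    data.frame(marker_id = markers$marker_id[sweep_cols],
               chrom = markers$chrom[sweep_cols],
               pos_bp = markers$pos_bp[sweep_cols], s = sweep_s,
               target_pop = sweep_target,
               freq_pop1 = freq[, 1], freq_pop2 = freq[, 2],
               lost = vapply(seq_along(sweep_cols), function(k) {
                 tp <- sweep_target[k]
                 mine <- which(sweep_target == tp)
                 isTRUE(pops[[tp]]$lost[match(k, mine)])
               }, logical(1)),
               retries = vapply(sweep_target, function(tp)
                 pops[[tp]]$retries, integer(1)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(marker_id = character(), chrom = character(),
               pos_bp = integer(), s = numeric(), target_pop = character(),
               freq_pop1 = numeric(), freq_pop2 = numeric(),
               lost = logical(), retries = integer())
  }
  structure(list(haplotypes = hs, genotypes = ds, truth = truth,
                 config = cfg), class = "divscan_sim")
}

#' @export
#' @method print divscan_sim
print.divscan_sim <- function(x, ...) {
  cfg <- x$config
  cat("simulated cohort:", 2 * cfg$n_pop, "diploids (",
      paste(cfg$pop_labels, collapse = "/"), "),",
      cfg$n_chrom, "x", cfg$m_snps, "SNPs, T =", cfg$split_generations, "\n")
  if (nrow(x$truth)) {
    cat("  sweeps:\n")
    print(x$truth[, c("chrom", "pos_bp", "s", "target_pop", "freq_pop1",
                      "freq_pop2", "lost")], row.names = FALSE)
  } else cat("  pure drift (no sweeps)\n")
  invisible(x)
}

#' Draw pseudo breeding values for a labelled cohort
#'
#' Gaussian per-group draws on the EBV scale (population mean 100),
#' producing the bimodal distribution used to split a cohort into SJ and NS
#' groups. With the defaults, [assign_groups()] at threshold 100 recovers
#' the generating label for every sample whose draw lands on the correct
#' side of 100.
#'
#' @param labels character vector of group labels (`"SJ"`/`"NS"`).
#' @param mean_sj,sd_sj,mean_ns,sd_ns group means and SDs.
#' @param seed optional seed (uses the ambient RNG stream when `NULL`).
#' @return Numeric vector of EBVs, one per label.
#' @export
make_pseudo_ebvs <- function(labels, mean_sj = 125, sd_sj = 13.4,
                             mean_ns = 77, sd_ns = 11.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  mu <- ifelse(labels == "SJ", mean_sj, mean_ns)
  sdv <- ifelse(labels == "SJ", sd_sj, sd_ns)
  stats::rnorm(length(labels), mu, sdv)
}

#' Write a simulated cohort as analysis-ready fixtures
#'
#' Emits the exact formats the readers consume: a PLINK binary triple, a
#' phased VCF, a headered sample TSV and a ground-truth JSON recording the
#' configured sweeps.
#'
#' @param sim a `divscan_sim` from [simulate_divergence()].
#' @param dir output directory (created if needed).
#' @param prefix file name stem (default `"cohort"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(sim, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, prefix)
  write_plink(sim$genotypes, stem)
  write_phased_vcf(sim$haplotypes, paste0(stem, ".vcf"))
  write_sample_table(sim$genotypes$samples, paste0(stem, "_samples.tsv"))
  jsonlite::write_json(list(config = sim$config[setdiff(names(sim$config),
                                                        "sweeps")],
                            sweeps = sim$truth),
                       paste0(stem, "_truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(bed = paste0(stem, ".bed"), bim = paste0(stem, ".bim"),
              fam = paste0(stem, ".fam"), vcf = paste0(stem, ".vcf"),
              samples = paste0(stem, "_samples.tsv"),
              truth = paste0(stem, "_truth.json")))
}
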