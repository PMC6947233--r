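#' Shared data containers
#'
#' The package moves genotype and haplotype data through two light S3
#' containers. A `genotype_dataset` holds an n-samples x m-markers matrix of
#' alt-allele dosages (0, 1, 2 or `NA` for missing) together with a marker map
#' and a sample table. A `haplotype_set` holds a 2n x m binary matrix of
#' phased haplotypes (0 = reference allele, 1 = alternate allele), two rows
#' per individual, with a carrier map and per-sample population labels.
#'
#' Positions are 1-based base pairs and must be strictly increasing within a
#' chromosome; marker ids must be unique. The missing-genotype sentinel is
#' `NA`, never 0.
#'
#' @param genotypes integer matrix of alt-allele dosages, samples in rows.
#' @param markers data.frame with columns `marker_id`, `chrom`, `pos_bp`,
#'   `allele_ref`, `allele_alt`.
#' @param samples data.frame with at least a `sample_id` column; typically
#'   also `ebv_jump`, `group`, `tb_fraction`.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, markers, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  markers <- validate_marker_map(markers)
  if (nrow(genotypes) != nrow(samples))
    stop("genotype rows (", nrow(genotypes), ") do not match samples (",
         nrow(samples), ")")
  if (ncol(genotypes) != nrow(markers))
    stop("genotype columns (", ncol(genotypes), ") do not match markers (",
         nrow(markers), ")")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id")
  dimnames(genotypes) <- list(samples$sample_id, markers$marker_id)
  structure(list(genotypes = genotypes, markers = markers, samples = samples),
            class = "genotype_dataset")
}

validate_marker_map <- function(markers) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "pos_bp")
  miss <- setdiff(need, names(markers))
  if (length(miss)) stop("marker map lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(markers$allele_ref)) markers$allele_ref <- "A"
  if (is.null(markers$allele_alt)) markers$allele_alt <- "B"
  markers$chrom <- as.character(markers$chrom)
  markers$pos_bp <- as.integer(markers$pos_bp)
  if (any(markers$pos_bp < 1L)) stop("pos_bp must be >= 1")
  if (anyDuplicated(markers$marker_id)) stop("duplicated marker_id")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos_bp[markers$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  markers
}

#' @rdname genotype_dataset
#' @param haplotypes 2n x m binary matrix (`NA` allowed before filtering).
#' @param carrier character vector mapping each haplotype row to a sample id;
#'   rows 2i-1 and 2i carry the two haplotypes of sample i.
#' @param pop_of named character vector (or factor) giving the population of
#'   each sample; may be `NULL` when labels are attached later.
#' @export
haplotype_set <- function(haplotypes, carrier, markers, pop_of = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  markers <- validate_marker_map(markers)
  if (ncol(haplotypes) != nrow(markers))
    stop("haplotype columns do not match markers")
  if (length(carrier) != nrow(haplotypes))
    stop("carrier must map every haplotype row")
  bad <- haplotypes[!is.na(haplotypes)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("haplotypes must be 0, 1 or NA")
  cnt <- table(carrier)
  if (any(cnt > 2L)) stop("more than two haplotypes for a sample")
  if (!is.null(pop_of)) {
    pop_of <- stats::setNames(as.character(pop_of), names(pop_of))
    miss <- setdiff(unique(carrier), names(pop_of))
    if (length(miss))
      stop("pop_of lacks labels for ", length(miss), " sample(s)")
  }
  rownames(haplotypes) <- paste0(carrier, "_h", stats::ave(seq_along(carrier),
                                                           carrier, FUN = seq_along))
  colnames(haplotypes) <- markers$marker_id
  structure(list(haplotypes = haplotypes, carrier = as.character(carrier),
                 markers = markers, pop_of = pop_of),
            class = "haplotype_set")
}

#' @export
#' @method print genotype_dataset
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$genotypes), "samples x",
      ncol(x$genotypes), "markers on",
      length(unique(x$markers$chrom)), "chromosome(s)\n")
  mr <- mean(is.na(x$genotypes))
  cat(sprintf("  missing dosages: %.2f%%\n", 100 * mr))
  invisible(x)
}

#' @export
#' @method print haplotype_set
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", nrow(x$haplotypes), "haplotypes (",
      length(unique(x$carrier)), "samples ) x", ncol(x$haplotypes), "markers\n")
  if (!is.null(x$pop_of)) {
    tb <- table(x$pop_of[unique(x$carrier)])
    cat("  populations:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# internal: keep a subset of markers (by column index) consistently
subset_markers <- function(ds, keep) {
  genotype_dataset(ds$genotypes[, keep, drop = FALSE],
                   ds$markers[keep, , drop = FALSE], ds$samples)
}

# internal: rows of the haplotype matrix belonging to one population
pop_rows <- function(hs, pop) {
  if (is.null(hs$pop_of)) stop("haplotype_set has no population labels")
  which(hs$pop_of[hs$carrier] == pop)
}
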