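#' Read a PLINK 1 binary triple
#'
#' Reads `.bed`/`.bim`/`.fam` files (SNP-major `.bed`) into a
#' [genotype_dataset()]. Dosages count copies of the `.bim` allele-1 (A1),
#' which is taken as the alternate allele, so downstream frequency-based
#' statistics are invariant to allele labelling. The PLINK missing code maps
#' to `NA`.
#'
#' @param path_prefix path without extension; the three members must exist.
#' @return A `genotype_dataset`.
#' @export
read_plink <- function(path_prefix) {
  paths <- paste0(path_prefix, c(".bed", ".bim", ".fam"))
  ok <- file.exists(paths)
  if (!all(ok))
    stop("missing PLINK file member(s): ", paste(paths[!ok], collapse = ", "))
  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "marker_id", "cm", "pos_bp",
                                         "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "sample_id", "sire_id",
                                         "dam_id", "sex", "pheno"))
  m <- nrow(bim); n <- nrow(fam)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic number)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bytes_per_snp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m)
    stop(".bed size does not match ", n, " samples x ", m, " markers")
  codes <- plink_decode_table()  # 256 x 4 matrix of A1 dosages
  geno <- codes[as.integer(body) + 1L, , drop = FALSE]
  geno <- matrix(t(geno), nrow = 4L * bytes_per_snp, ncol = m)[1:n, , drop = FALSE]
  markers <- data.frame(marker_id = bim$marker_id, chrom = bim$chrom,
                        pos_bp = bim$pos_bp, allele_ref = bim$a2,
                        allele_alt = bim$a1, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = fam$sample_id, fid = fam$fid,
                        sire_id = fam$sire_id, dam_id = fam$dam_id,
                        sex = fam$sex, stringsAsFactors = FALSE)
  genotype_dataset(geno, markers, samples)
}

# 2-bit PLINK codes (per byte, low bits first):
# 00 hom A1 -> 2, 01 missing -> NA, 10 het -> 1, 11 hom A2 -> 0
plink_decode_table <- function() {
  two_bit <- c(2L, NA_integer_, 1L, 0L)
  b <- 0:255
  cbind(two_bit[bitwAnd(b, 3L) + 1L],
        two_bit[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
        two_bit[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
        two_bit[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L])
}

#' Write a PLINK 1 binary triple
#'
#' Inverse of [read_plink()]: A1 is the alternate allele, A2 the reference.
#'
#' @param ds a `genotype_dataset`.
#' @inheritParams read_plink
#' @return `path_prefix`, invisibly.
#' @export
write_plink <- function(ds, path_prefix) {
  g <- ds$genotypes
  n <- nrow(g); m <- ncol(g)
  code <- matrix(3L, nrow = n, ncol = m)     # hom ref
  code[!is.na(g) & g == 2L] <- 0L            # hom alt (A1)
  code[!is.na(g) & g == 1L] <- 2L            # het
  code[is.na(g)] <- 1L                       # missing
  bytes_per_snp <- ceiling(n / 4)
  pad <- 4L * bytes_per_snp - n
  if (pad > 0) code <- rbind(code, matrix(3L, pad, m))
  idx <- seq(1L, nrow(code), by = 4L)
  bytes <- code[idx, , drop = FALSE] +
    4L * code[idx + 1L, , drop = FALSE] +
    16L * code[idx + 2L, , drop = FALSE] +
    64L * code[idx + 3L, , drop = FALSE]
  con <- file(paste0(path_prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  mk <- ds$markers
  utils::write.table(data.frame(mk$chrom, mk$marker_id, 0, mk$pos_bp,
                                mk$allele_alt, mk$allele_ref),
                     paste0(path_prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sm <- ds$samples
  fam <- data.frame(fid = if (is.null(sm$fid)) sm$sample_id else sm$fid,
                    iid = sm$sample_id,
                    sire = if (is.null(sm$sire_id)) 0 else sm$sire_id,
                    dam = if (is.null(sm$dam_id)) 0 else sm$dam_id,
                    sex = if (is.null(sm$sex)) 0 else sm$sex,
                    pheno = -9)
  utils::write.table(fam, paste0(path_prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path_prefix)
}

#' Read phased haplotypes from a VCF
#'
#' Consumes a VCF whose GT fields are phased (`"|"` separator, as produced by
#' statistical phasing) and returns a [haplotype_set()]. Only biallelic
#' records are accepted. In strict mode (default) an unphased or
#' multi-allelic record is an error; in lenient mode such records are skipped
#' with a warning.
#'
#' @param path VCF file (plain or gzipped).
#' @param pop_of optional named vector of population labels per sample.
#' @param strict reject (`TRUE`) or skip (`FALSE`) non-conforming records.
#' @return A `haplotype_set`.
#' @export
read_phased_vcf <- function(path, pop_of = NULL, strict = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  unphased <- apply(gt, 1, function(r) any(grepl("/", r, fixed = TRUE)))
  bad <- multi | unphased
  if (any(bad)) {
    if (strict)
      stop(sum(multi), " multi-allelic and ", sum(unphased),
           " unphased record(s) in strict mode")
    warning("skipping ", sum(bad), " multi-allelic/unphased record(s)")
    fix <- fix[!bad, , drop = FALSE]
    gt <- gt[!bad, , drop = FALSE]
  }
  m <- nrow(gt); samples <- colnames(gt); n <- length(samples)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  to_int <- function(x) {
    out <- suppressWarnings(as.integer(x))
    out[x == "."] <- NA_integer_
    out
  }
  H <- matrix(NA_integer_, nrow = 2 * n, ncol = m)
  H[seq(1, 2 * n, by = 2), ] <- t(matrix(to_int(a1), nrow = m))
  H[seq(2, 2 * n, by = 2), ] <- t(matrix(to_int(a2), nrow = m))
  markers <- data.frame(marker_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                           paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                                           fix[, "ID"]),
                        chrom = fix[, "CHROM"],
                        pos_bp = as.integer(fix[, "POS"]),
                        allele_ref = fix[, "REF"], allele_alt = fix[, "ALT"],
                        stringsAsFactors = FALSE)
  haplotype_set(H, rep(samples, each = 2), markers, pop_of = pop_of)
}

#' Write phased haplotypes to a VCF
#'
#' @param hs a `haplotype_set` (missing calls become `.` in the GT field).
#' @param path output file path (plain text VCF v4.2).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(hs, path) {
  mk <- hs$markers
  samples <- unique(hs$carrier)
  H <- hs$haplotypes
  chrom_max <- tapply(mk$pos_bp, mk$chrom, max)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=divscan",
           paste0("##contig=<ID=", names(chrom_max), ",length=",
                  as.integer(chrom_max) + 1L, ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  hv <- ifelse(is.na(H), ".", as.character(H))
  i1 <- match(samples, hs$carrier)                 # first haplotype row
  i2 <- nrow(H) - match(samples, rev(hs$carrier)) + 1L  # second
  gt_cols <- vapply(seq_along(samples), function(k) {
    paste0(hv[i1[k], ], "|", hv[i2[k], ])
  }, character(ncol(H)))
  gt_cols <- matrix(gt_cols, nrow = ncol(H))
  body <- cbind(mk$chrom, mk$pos_bp, mk$marker_id, mk$allele_ref,
                mk$allele_alt, ".", "PASS", ".", "GT", gt_cols)
  writeLines(c(hdr, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read / write the sample table
#'
#' Headered TSV with columns `sample_id`, `ebv_jump` and optionally
#' `ebv_dressage`, `sire_id`, `dam_id`, `tb_flag`.
#'
#' @param path TSV file.
#' @return A data.frame.
#' @export
read_sample_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_sample_table
#' @param samples data.frame to write.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign samples to subpopulations by breeding value
#'
#' Samples with an EBV for the focal discipline strictly above `threshold`
#' (scale mean 100) are labelled `SJ`, all others `NS`; a sample with an EBV
#' exactly at the threshold goes to `NS` so the partition is total. Samples
#' with a missing EBV are labelled `unassigned` with a warning.
#'
#' @param samples data.frame with an `ebv_jump` column.
#' @param threshold EBV cut point (default 100, the population mean).
#' @return `samples` with a `group` factor added; group counts are attached
#'   as attribute `"counts"`.
#' @export
assign_groups <- function(samples, threshold = 100) {
  if (is.null(samples$ebv_jump)) stop("samples lack an ebv_jump column")
  grp <- ifelse(samples$ebv_jump > threshold, "SJ", "NS")
  if (anyNA(grp)) {
    warning(sum(is.na(grp)), " sample(s) without EBV left unassigned")
    grp[is.na(grp)] <- "unassigned"
  }
  samples$group <- factor(grp, levels = c("SJ", "NS", "unassigned"))
  attr(samples, "counts") <- table(samples$group)
  samples
}

#' Pedigree-based blood fraction
#'
#' Computes the fraction of an individual's genome expected to derive from a
#' flagged ancestral group (e.g. Thoroughbred), from a pedigree truncated at
#' `generations` meioses. Every ancestral path contributes `(1/2)^d` at the
#' first flagged ancestor it meets at depth `d <= generations`; descent stops
#' there, so the result lies in `[0, 1]`. Unknown parents contribute 0.
#'
#' @param sample_id individual to score.
#' @param pedigree data.frame with columns `id`, `sire_id`, `dam_id`
#'   (`NA` or `"0"` for unknown parents).
#' @param flagged character vector of flagged ancestor ids.
#' @param generations pedigree depth (default 4).
#' @return Fraction in `[0, 1]`.
#' @export
blood_fraction <- function(sample_id, pedigree, flagged, generations = 4) {
  if (generations < 1) stop("generations must be >= 1")
  ped <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  need <- c("id", "sire_id", "dam_id")
  if (!all(need %in% names(ped)))
    stop("pedigree needs columns id, sire_id, dam_id")
  sire <- stats::setNames(as.character(ped$sire_id), ped$id)
  dam <- stats::setNames(as.character(ped$dam_id), ped$id)
  flagged <- as.character(flagged)
  unknown <- function(x) is.na(x) || x == "0" || x == ""
  rec <- function(id, depth, seen) {
    if (unknown(id) || depth > generations) return(0)
    if (id %in% seen) stop("pedigree cycle detected at ", id)
    if (id %in% flagged) return(0.5 ^ depth)
    seen <- c(seen, id)
    rec(sire[id], depth + 1, seen) + rec(dam[id], depth + 1, seen)
  }
  rec(sire[sample_id], 1, sample_id) + rec(dam[sample_id], 1, sample_id)
}
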