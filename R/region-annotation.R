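#' Build candidate regions around significant SNPs
#'
#' Each significant SNP expands to `[pos - pad_bp, pos + pad_bp]` (clamped at
#' 1); overlapping or touching windows on the same chromosome (and, when a
#' `direction` column is present, with the same direction) merge into one
#' region. Coordinates are 1-based inclusive. Merging is idempotent.
#'
#' @param snps data.frame with `chrom` and `pos_bp` columns (e.g. the
#'   significant rows of an [xpehh_scan()]); optional `marker_id`,
#'   `direction` and `q` columns feed region provenance.
#' @param pad_bp half-width of the window around each SNP (default 250 kb).
#' @return data.frame of class `candidate_regions`: `chrom`, `start_bp`,
#'   `end_bp`, `length_kb`, `direction`, `n_snps`, `min_q`, `source_snps`.
#' @export
build_regions <- function(snps, pad_bp = 250000) {
  if (!nrow(snps)) {
    out <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), length_kb = integer(),
                      direction = character(), n_snps = integer(),
                      min_q = numeric(), source_snps = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("candidate_regions", "data.frame")
    return(out)
  }
  if (is.null(snps$direction)) snps$direction <- NA_character_
  if (is.null(snps$q)) snps$q <- NA_real_
  if (is.null(snps$marker_id))
    snps$marker_id <- paste0(snps$chrom, "_", snps$pos_bp)
  key <- paste(snps$chrom, snps$direction, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(snps)), key), function(idx) {
    ss <- snps[idx, , drop = FALSE]
    ss <- ss[order(ss$pos_bp), , drop = FALSE]
    ir <- IRanges::IRanges(start = pmax(1, ss$pos_bp - pad_bp),
                           end = ss$pos_bp + pad_bp)
    merged <- IRanges::reduce(ir)
    hit <- IRanges::findOverlaps(ir, merged)
    grpof <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    data.frame(
      chrom = ss$chrom[1],
      start_bp = IRanges::start(merged),
      end_bp = IRanges::end(merged),
      direction = ss$direction[1],
      n_snps = as.integer(table(factor(grpof, levels = seq_along(merged)))),
      min_q = as.numeric(tapply(ss$q, grpof, function(v)
        if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))),
      source_snps = as.character(tapply(ss$marker_id, grpof, paste,
                                        collapse = ",")),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  out$length_kb <- region_length_kb(out$start_bp, out$end_bp)
  out <- out[, c("chrom", "start_bp", "end_bp", "length_kb", "direction",
                 "n_snps", "min_q", "source_snps")]
  class(out) <- c("candidate_regions", "data.frame")
  out
}

#' Region length in kilobases
#'
#' `round((end_bp - start_bp) / 1000)`, matching how published region tables
#' report interval lengths.
#'
#' @param start_bp,end_bp 1-based inclusive region bounds (vectors allowed).
#' @return Integer length in kb.
#' @export
region_length_kb <- function(start_bp, end_bp) {
  if (any(end_bp < start_bp)) stop("end_bp must be >= start_bp")
  as.integer(round((end_bp - start_bp) / 1000))
}

#' Concordance of haplotype-scan regions with the F_ST scan
#'
#' A region is concordant when at least one F_ST-significant SNP lies within
#' `[start_bp, end_bp]` on the same chromosome; the highest significant F_ST
#' inside is reported (`NA` otherwise). The concordance rate per direction is
#' attached as attribute `"rate"`.
#'
#' @param regions a `candidate_regions` data.frame.
#' @param fst_result an [fst_scan()] result over the same marker map.
#' @return `regions` with `concordant` and `max_fst_overlap` columns added.
#' @export
concordance <- function(regions, fst_result) {
  sig <- fst_result$snps[fst_result$snps$significant, , drop = FALSE]
  regions$concordant <- rep(FALSE, nrow(regions))
  regions$max_fst_overlap <- rep(NA_real_, nrow(regions))
  for (i in seq_len(nrow(regions))) {
    hit <- sig$chrom == regions$chrom[i] &
      sig$pos_bp >= regions$start_bp[i] & sig$pos_bp <= regions$end_bp[i]
    if (any(hit)) {
      regions$concordant[i] <- TRUE
      regions$max_fst_overlap[i] <- max(sig$fst[hit])
    }
  }
  rate <- tapply(regions$concordant, regions$direction, mean)
  attr(regions, "rate") <- rate
  regions
}

# read a GFF3 leniently: drop malformed lines (wrong field count) first
read_gff3_genes <- function(gff3, strict = FALSE) {
  lines <- readLines(gff3)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nf != 9)) {
    if (strict) stop(sum(nf != 9), " malformed GFF3 line(s)")
    warning("skipping ", sum(nf != 9), " malformed GFF3 line(s)")
  }
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp))
  writeLines(c(lines[startsWith(lines, "#")], body[nf == 9]), tmp)
  gr <- rtracklayer::import(tmp, format = "gff3")
  gr[tolower(as.character(gr$type)) == "gene"]
}

#' Annotate candidate regions with genes from a GFF3
#'
#' Lists every gene whose span intersects a region (any overlap, inclusive
#' coordinates) and tallies gene biotypes. Malformed GFF3 lines are skipped
#' with a warning in lenient mode and are an error in strict mode.
#'
#' @param regions a `candidate_regions` data.frame.
#' @param gff3 path to a GFF3 file with `gene` features carrying a
#'   `biotype`/`gene_biotype` attribute.
#' @param strict fail on malformed lines instead of skipping them.
#' @return List with `genes` (per-region data.frame: region index, gene id,
#'   symbol, biotype, coordinates) and `biotype_tally`.
#' @export
annotate_genes <- function(regions, gff3, strict = FALSE) {
  genes <- read_gff3_genes(gff3, strict)
  biotype <- genes$biotype
  if (is.null(biotype)) biotype <- genes$gene_biotype
  if (is.null(biotype)) biotype <- rep(NA_character_, length(genes))
  gene_id <- genes$ID
  if (is.null(gene_id)) gene_id <- genes$gene_id
  symbol <- genes$Name
  if (is.null(symbol)) symbol <- gene_id
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start_bp,
                                                regions$end_bp))
  hits <- GenomicRanges::findOverlaps(rg, genes)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  out <- data.frame(region = qi,
                    chrom = as.character(GenomicRanges::seqnames(genes))[si],
                    gene_id = as.character(gene_id)[si],
                    symbol = as.character(symbol)[si],
                    biotype = as.character(biotype)[si],
                    start = GenomicRanges::start(genes)[si],
                    end = GenomicRanges::end(genes)[si],
                    strand = as.character(GenomicRanges::strand(genes))[si],
                    stringsAsFactors = FALSE)
  list(genes = out, biotype_tally = table(out$biotype))
}

#' Hypergeometric term-enrichment test
#'
#' For a term with `K` genes in a background of `N`, of which `k` fall among
#' the `n` hit genes: fold enrichment is `(k/n)/(K/N)` and the p-value is the
#' hypergeometric upper tail `P(X >= k)`. Raw p-values are reported by
#' default (mirroring database over-representation reports); an optional
#' Benjamini-Hochberg column can be added.
#'
#' @param hit_genes character vector of hit gene ids (subset of background).
#' @param background character vector of all testable gene ids.
#' @param term_map named list mapping term -> character vector of gene ids.
#' @param adjust add a BH-adjusted column (default `FALSE`).
#' @return data.frame with `term`, `K`, `k`, `fold`, `p` (and `q`).
#' @export
enrichment_test <- function(hit_genes, background, term_map, adjust = FALSE) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  hit_genes <- unique(hit_genes)
  if (!all(hit_genes %in% background))
    stop("hit_genes must be a subset of background")
  N <- length(background); n <- length(hit_genes)
  rows <- lapply(names(term_map), function(tm) {
    tg <- intersect(unique(term_map[[tm]]), background)
    K <- length(tg)
    k <- length(intersect(tg, hit_genes))
    fold <- if (k == 0) 0 else (k / n) / (K / N)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, K = K, k = k, fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Overlap candidate regions with user-supplied QTL intervals
#'
#' @param regions a `candidate_regions` data.frame.
#' @param qtl_bed path to a BED file (0-based half-open; the `name` column
#'   labels each interval).
#' @return data.frame with one row per (region, overlapping QTL) pair.
#' @export
qtl_overlap <- function(regions, qtl_bed) {
  qtl <- rtracklayer::import(qtl_bed, format = "bed")
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start_bp,
                                                regions$end_bp))
  hits <- GenomicRanges::findOverlaps(rg, qtl)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  nm <- qtl$name
  if (is.null(nm)) nm <- rep(NA_character_, length(qtl))
  data.frame(region = qi, chrom = regions$chrom[qi],
             region_start = regions$start_bp[qi],
             region_end = regions$end_bp[qi],
             qtl_label = as.character(nm)[si],
             qtl_start = GenomicRanges::start(qtl)[si],
             qtl_end = GenomicRanges::end(qtl)[si],
             stringsAsFactors = FALSE)
}

#' Export candidate regions as BED
#'
#' Internal 1-based inclusive coordinates convert to BED's 0-based
#' half-open convention.
#'
#' @param regions a `candidate_regions` data.frame.
#' @param path output BED path.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, regions$start_bp - 1L, regions$end_bp,
                   ifelse(is.na(regions$direction), ".", regions$direction))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
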