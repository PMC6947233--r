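# Independent brute-force oracles. Each re-derives its quantity from the
# definition with naive loops, sharing no code with the implementation.

# two-sided exact Hardy-Weinberg p-value by full enumeration over all
# heterozygote counts compatible with the allele counts
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logpr <- vapply(hets, function(h) {
    naa <- (n_a - h) / 2
    nAA <- n - naa - h
    # P(h | allele counts) proportional to 2^h / (nAA! h! naa!)
    h * log(2) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa)
  }, numeric(1))
  # normalize explicitly (the combinatorial constants cancel)
  pr <- exp(logpr - max(logpr))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

# squared Pearson correlation from the textbook formula
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  if (sxx == 0 || syy == 0) return(0)
  (sxy / sqrt(sxx * syy))^2
}

# Nei fixation index from the definition, scalar
oracle_fst <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  if (ht == 0) return(0)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  max(0, min(1, (ht - hs) / ht))
}

# EHHS at a single flank marker by O(n^2) pairwise comparison
oracle_ehhs <- function(H, core, x) {
  n <- nrow(H)
  rng <- if (x >= core) core:x else x:core
  den <- 0; num <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (H[i, core] == H[j, core]) {
        den <- den + 1
        if (all(H[i, rng] == H[j, rng])) num <- num + 1
      }
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# trapezoid rule written out longhand
oracle_trapezoid <- function(x, y) {
  area <- 0
  for (i in seq_len(length(x) - 1))
    area <- area + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  area
}

# Benjamini-Hochberg from the step-up definition, O(m^2)
oracle_bh <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- sum(p <= p[i])            # rank with ties
    # smallest alpha at which p_i is rejected: min over j >= rank of p_(j)*m/j
    cand <- vapply(seq_len(m), function(j) {
      pj <- sort(p)[j]
      if (pj >= p[i]) pj * m / j else Inf
    }, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  adj
}

# allele-sharing similarity by explicit double loop
oracle_ibs <- function(g) {
  n <- nrow(g)
  s <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      s[i, j] <- s[j, i] <- 1 - sum(abs(g[i, ok] - g[j, ok])) / (2 * sum(ok))
    }
  }
  s
}

# blood fraction by exhaustive enumeration of ancestral paths: each path
# stops at the first flagged ancestor it meets
oracle_blood_fraction <- function(id, ped, flagged, generations) {
  sire <- stats::setNames(as.character(ped$sire_id), ped$id)
  dam <- stats::setNames(as.character(ped$dam_id), ped$id)
  total <- 0
  walk <- function(a, depth) {
    if (is.na(a) || a == "0" || a == "" || depth > generations) return()
    if (a %in% flagged) {
      total <<- total + 0.5^depth
      return()
    }
    walk(sire[a], depth + 1)
    walk(dam[a], depth + 1)
  }
  walk(sire[id], 1)
  walk(dam[id], 1)
  total
}

# inclusive-coordinate interval overlap by quadratic search
oracle_overlaps <- function(regions, features) {
  hits <- NULL
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(features))) {
      if (regions$chrom[i] == features$chrom[j] &&
          regions$start[i] <= features$end[j] &&
          features$start[j] <= regions$end[i])
        hits <- rbind(hits, c(i, j))
    }
  }
  hits
}

# hypergeometric upper tail by explicit summation
oracle_hyper_tail <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(x)
    exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)), numeric(1)))
}
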