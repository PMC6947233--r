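#' Allele-sharing identity-by-state similarity
#'
#' For samples i and j, `s_ij = 1 - sum_m |g_im - g_jm| / (2 * m_complete)`
#' averaged over markers called in both samples. Identical genotype rows give
#' 1, opposite homozygotes at every marker give 0. The diagonal is 1.
#'
#' @param ds a `genotype_dataset` (typically post-QC and LD-pruned).
#' @return Symmetric n x n similarity matrix with unit diagonal.
#' @export
ibs_similarity <- function(ds) {
  g <- ds$genotypes
  m <- ncol(g)
  shared <- crossprod(t(!is.na(g)) * 1)   # complete pairs per sample pair
  if (any(shared == 0))
    stop("sample pair(s) share no called markers")
  # dist() rescales the available-marker sum by m / m_avail, so dividing by
  # 2m recovers the mean over complete markers
  d <- as.matrix(stats::dist(g, method = "manhattan"))
  s <- 1 - d / (2 * m)
  diag(s) <- 1
  dimnames(s) <- list(ds$samples$sample_id, ds$samples$sample_id)
  s
}

#' Principal coordinates analysis of a similarity matrix
#'
#' Converts similarities to squared Euclidean distances `D2 = 2 (1 - s)`,
#' applies Gower double-centering `B = -1/2 J D2 J` with
#' `J = I - 11'/n`, and eigendecomposes `B`. Coordinates are eigenvectors
#' scaled by the square roots of the positive eigenvalues; negative
#' eigenvalues are dropped (not shifted) and excluded from the
#' variance-explained denominator.
#'
#' @param similarity symmetric matrix with unit diagonal (e.g. from
#'   [ibs_similarity()]).
#' @return Object of class `pcoa_result` with `eigenvalues` (all, descending),
#'   `coordinates` (n x k, positive axes only) and `variance_explained`.
#' @export
pcoa <- function(similarity) {
  s <- as.matrix(similarity)
  if (!isSymmetric(s, tol = 1e-8)) stop("similarity matrix is not symmetric")
  n <- nrow(s)
  d2 <- 2 * (1 - s)
  diag(d2) <- 0
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * ctr %*% d2 %*% ctr
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(s)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(eigenvalues = e$values,
                 coordinates = coords,
                 variance_explained = e$values[pos] / sum(e$values[pos])),
            class = "pcoa_result")
}

#' @export
#' @method print pcoa_result
print.pcoa_result <- function(x, ...) {
  k <- min(3, length(x$variance_explained))
  cat("PCoA:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "positive axes\n")
  cat("  variance explained:",
      paste(sprintf("%.2f%%", 100 * x$variance_explained[1:k]), collapse = ", "),
      "...\n")
  invisible(x)
}

#' @export
#' @param x a `pcoa_result`.
#' @param groups optional factor colouring the points.
#' @param ... passed to [graphics::plot()].
#' @rdname pcoa
#' @method plot pcoa_result
plot.pcoa_result <- function(x, groups = NULL, ...) {
  ve <- x$variance_explained
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(x$coordinates[, 1], x$coordinates[, 2], col = col,
                 xlab = sprintf("Axis 1 (%.1f%%)", 100 * ve[1]),
                 ylab = sprintf("Axis 2 (%.1f%%)", 100 * ve[2]), ...)
  invisible(x)
}

# centered, mean-imputed dosage matrix and its principal component scores
pc_scores <- function(g, n_pcs) {
  mu <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]
  gc <- sweep(g, 2, colMeans(g))
  p <- stats::prcomp(gc, center = FALSE, rank. = n_pcs)
  k <- min(n_pcs, ncol(p$rotation))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       rotation = p$rotation[, seq_len(k), drop = FALSE],
       col_means = colMeans(g), impute = mu, sdev = p$sdev)
}

#' Choose the number of genetic clusters by BIC
#'
#' Runs K-means (multiple restarts under a fixed seed) on the top principal
#' components of the centred dosage matrix for each candidate K, and scores
#' each solution with `BIC(K) = n log(WSS_K / n) + K log(n)`. The returned
#' table flags the argmin.
#'
#' @param ds a `genotype_dataset` (or numeric dosage matrix).
#' @param k_range candidate cluster counts (default `1:5`).
#' @param n_pcs_kept principal components fed to K-means; the default
#'   `min(100, n - 2)` retains many PCs, which is what keeps the criterion
#'   from splitting unstructured noise.
#' @param n_start K-means restarts per K.
#' @param seed RNG seed making the table deterministic.
#' @return Object of class `bic_table`: data.frame `(k, wss, bic)`, `best_k`
#'   and the `assignments` for the best K.
#' @export
find_clusters_bic <- function(ds, k_range = 1:5, n_pcs_kept = NULL,
                              n_start = 10, seed = 1) {
  g <- if (inherits(ds, "genotype_dataset")) ds$genotypes else as.matrix(ds)
  n <- nrow(g)
  if (is.null(n_pcs_kept)) n_pcs_kept <- min(100L, n - 2L, ncol(g))
  if (max(k_range) >= n) stop("largest K must be below the sample count")
  if (n_pcs_kept > min(n - 1, ncol(g)))
    stop("n_pcs_kept exceeds the available rank")
  sc <- pc_scores(g, n_pcs_kept)$scores
  set.seed(seed)
  rows <- lapply(sort(k_range), function(k) {
    if (k == 1) {
      wss <- sum(sweep(sc, 2, colMeans(sc))^2)
      cl <- rep(1L, n)
    } else {
      km <- stats::kmeans(sc, centers = k, nstart = n_start, iter.max = 100)
      wss <- km$tot.withinss
      cl <- km$cluster
    }
    list(k = k, wss = wss, bic = n * log(wss / n) + k * log(n), cl = cl)
  })
  tab <- data.frame(k = vapply(rows, `[[`, 0, "k"),
                    wss = vapply(rows, `[[`, 0, "wss"),
                    bic = vapply(rows, `[[`, 0, "bic"))
  best <- which.min(tab$bic)
  structure(list(table = tab, best_k = tab$k[best],
                 assignments = rows[[best]]$cl),
            class = "bic_table")
}

#' @export
#' @method print bic_table
print.bic_table <- function(x, ...) {
  cat("K-means BIC (best K =", x$best_k, ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Discriminant analysis of principal components
#'
#' PCA on the centred (mean-imputed) dosage matrix, followed by linear
#' discriminant axes maximising the between/within variance ratio on the
#' retained PCs. Membership posteriors use Gaussian class-conditional
#' densities with the pooled within-group covariance on the discriminant
#' axes and class-proportion priors.
#'
#' @param ds a `genotype_dataset` or numeric dosage matrix.
#' @param labels group factor, one entry per sample (>= 2 groups, each with
#'   >= 2 members).
#' @param n_pcs number of principal components retained before the
#'   discriminant step.
#' @return Object of class `dapc_model` with loadings, centroids, posteriors
#'   and self-assignment; see [predict.dapc_model()] for new data.
#' @export
dapc_fit <- function(ds, labels, n_pcs) {
  g <- if (inherits(ds, "genotype_dataset")) ds$genotypes else as.matrix(ds)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two groups")
  if (any(table(labels) < 2)) stop("every group needs at least two members")
  n <- nrow(g); glev <- levels(labels); ng <- nlevels(labels)
  if (n_pcs > min(n - ng, ncol(g)))
    stop("n_pcs exceeds the available rank (max ", min(n - ng, ncol(g)), ")")
  pca <- pc_scores(g, n_pcs)
  sc <- pca$scores
  # within- and between-group scatter on the retained PCs
  mu <- colMeans(sc)
  W <- matrix(0, n_pcs, n_pcs); B <- matrix(0, n_pcs, n_pcs)
  for (lv in glev) {
    xi <- sc[labels == lv, , drop = FALSE]
    mg <- colMeans(xi)
    W <- W + crossprod(sweep(xi, 2, mg))
    B <- B + nrow(xi) * tcrossprod(mg - mu)
  }
  W <- W / (n - ng)
  ew <- eigen((W + t(W)) / 2, symmetric = TRUE)
  if (min(ew$values) <= max(ew$values) * 1e-10)
    stop("within-group covariance is singular; reduce n_pcs")
  Wmh <- ew$vectors %*% diag(1 / sqrt(ew$values), n_pcs) %*% t(ew$vectors)
  eb <- eigen(Wmh %*% B %*% Wmh, symmetric = TRUE)
  naxes <- ng - 1
  disc <- Wmh %*% eb$vectors[, seq_len(naxes), drop = FALSE]
  colnames(disc) <- paste0("LD", seq_len(naxes))
  z <- sc %*% disc
  centroids <- do.call(rbind, lapply(glev, function(lv)
    colMeans(z[labels == lv, , drop = FALSE])))
  rownames(centroids) <- glev
  pooled <- matrix(0, naxes, naxes)
  for (lv in glev) {
    zi <- z[labels == lv, , drop = FALSE]
    pooled <- pooled + crossprod(sweep(zi, 2, colMeans(zi)))
  }
  pooled <- pooled / (n - ng)
  model <- structure(list(
    n_pcs_retained = n_pcs,
    impute = pca$impute, col_means = pca$col_means,
    pc_loadings = pca$rotation, discriminant_loadings = disc,
    centroids = centroids, pooled_cov = pooled,
    priors = as.numeric(table(labels)) / n, levels = glev,
    var_explained_pcs = sum(pca$sdev[seq_len(n_pcs)]^2) / sum(pca$sdev^2)),
    class = "dapc_model")
  pr <- predict(model, g)
  model$posterior <- pr$posterior
  model$assign <- pr$assign
  model$self_assignment <- mean(pr$assign == as.character(labels))
  model$labels <- labels
  model
}

#' Predict group membership from a fitted DAPC model
#'
#' @param object a `dapc_model`.
#' @param newdata `genotype_dataset` or dosage matrix over the same markers
#'   used at fit time.
#' @param ... unused.
#' @return List with `assign` (character) and `posterior` (n x g matrix,
#'   rows summing to 1).
#' @export
#' @method predict dapc_model
predict.dapc_model <- function(object, newdata, ...) {
  g <- if (inherits(newdata, "genotype_dataset")) newdata$genotypes
       else as.matrix(newdata)
  if (ncol(g) != nrow(object$pc_loadings))
    stop("newdata markers do not match the fitted model")
  for (j in seq_len(ncol(g)))
    if (anyNA(g[, j])) g[is.na(g[, j]), j] <- object$impute[j]
  gc <- sweep(g, 2, object$col_means)
  z <- gc %*% object$pc_loadings %*% object$discriminant_loadings
  ic <- solve(object$pooled_cov)
  logdet <- determinant(object$pooled_cov, logarithm = TRUE)$modulus
  ll <- vapply(seq_along(object$levels), function(k) {
    dz <- sweep(z, 2, object$centroids[k, ])
    -0.5 * rowSums((dz %*% ic) * dz) - 0.5 * logdet + log(object$priors[k])
  }, numeric(nrow(z)))
  ll <- matrix(ll, nrow = nrow(z))
  ll <- ll - apply(ll, 1, max)
  post <- exp(ll) / rowSums(exp(ll))
  colnames(post) <- object$levels
  rownames(post) <- rownames(g)
  list(assign = object$levels[max.col(post, ties.method = "first")],
       posterior = post)
}

#' @export
#' @method print dapc_model
print.dapc_model <- function(x, ...) {
  cat("DAPC:", x$n_pcs_retained, "PCs retained (",
      sprintf("%.1f%%", 100 * x$var_explained_pcs), "of variance ),",
      length(x$levels), "groups\n")
  cat(sprintf("  self-assignment: %.1f%%\n", 100 * x$self_assignment))
  invisible(x)
}

#' Cross-validated choice of retained PCs for DAPC
#'
#' Repeats stratified 90/10 train/validation splits and, for each candidate
#' PC count, reports the mean proportion of held-out samples assigned to
#' their true group and `RMSE = sqrt(mean((1 - proportion_correct)^2))`. The
#' chosen PC count maximises mean assignment, with ties broken by lower RMSE.
#'
#' @inheritParams dapc_fit
#' @param pcs_grid candidate PC counts.
#' @param reps number of random splits per grid value (default 30).
#' @param train_frac training fraction (default 0.9, stratified by group).
#' @param seed RNG seed.
#' @return Object of class `dapc_cv`: table `(n_pcs, mean_assignment, rmse,
#'   reps)` and `chosen_n_pcs`.
#' @export
dapc_crossvalidate <- function(ds, labels, pcs_grid, reps = 30,
                               train_frac = 0.9, seed = 1) {
  g <- if (inherits(ds, "genotype_dataset")) ds$genotypes else as.matrix(ds)
  labels <- factor(labels)
  set.seed(seed)
  acc <- matrix(NA_real_, nrow = reps, ncol = length(pcs_grid))
  for (r in seq_len(reps)) {
    tr <- unlist(lapply(levels(labels), function(lv) {
      idx <- which(labels == lv)
      sample(idx, max(1, round(train_frac * length(idx))))
    }))
    if (length(unique(labels[tr])) < nlevels(labels))
      stop("a group is absent from a training fold")
    te <- setdiff(seq_len(nrow(g)), tr)
    for (ci in seq_along(pcs_grid)) {
      np <- pcs_grid[ci]
      fit <- try(dapc_fit(g[tr, , drop = FALSE], labels[tr], np),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      pr <- predict(fit, g[te, , drop = FALSE])
      acc[r, ci] <- mean(pr$assign == as.character(labels[te]))
    }
  }
  tab <- data.frame(n_pcs = pcs_grid,
                    mean_assignment = colMeans(acc, na.rm = TRUE),
                    rmse = apply(acc, 2, function(a)
                      sqrt(mean((1 - a)^2, na.rm = TRUE))),
                    reps = colSums(!is.na(acc)))
  ord <- order(-tab$mean_assignment, tab$rmse)
  structure(list(table = tab, chosen_n_pcs = tab$n_pcs[ord[1]]),
            class = "dapc_cv")
}

#' @export
#' @method print dapc_cv
print.dapc_cv <- function(x, ...) {
  cat("DAPC cross-validation (chosen n_pcs =", x$chosen_n_pcs, ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
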