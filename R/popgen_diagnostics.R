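#' Principal component analysis of standardised dosages
#'
#' Columns are centred by `2p` and scaled by `sqrt(2p(1-p))` (frequencies
#' from the analysis set; zero-variance SNPs are dropped with a warning).
#' Eigenvalues come from the individual-by-individual covariance
#' `W W' / m`; scores are the projections of the standardised rows onto the
#' top-k right singular vectors, i.e. `score_k = sqrt(m * lambda_k) u_k`.
#' Score signs are fixed so the largest-magnitude loading of each
#' component is positive.
#'
#' @param g a complete (imputed) [geno_matrix()] or plain dosage matrix.
#' @param k number of components to return.
#' @return A list of class `pca_result`: `eigenvalues` (descending),
#'   `scores` (n x k, named rows), `varprop` (variance-explained
#'   fractions, eigenvalue / trace).
#' @export
compute_pca <- function(g, k = 10) {
  d <- if (inherits(g, "geno_matrix")) g$dosages else as.matrix(g)
  if (anyNA(d)) stop("PCA needs a complete matrix; run mean_impute() first")
  n <- nrow(d)
  p <- colMeans(d) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all SNPs are monomorphic; PCA undefined")
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance SNPs dropped before PCA")
    d <- d[, keep, drop = FALSE]
    p <- p[keep]
  }
  m <- ncol(d)
  k <- min(k, n, m)
  W <- sweep(d, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  C <- tcrossprod(W) / m
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lambda[seq_len(k)] * m), k, k)
  # deterministic sign: largest |entry| positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(eigenvalues = lambda, scores = scores,
                 varprop = lambda / sum(lambda)), class = "pca_result")
}

#' Silhouette of line labels on the leading principal components
#'
#' Mean silhouette width of the line grouping in (PC1, PC2) space — the
#' quantitative stand-in for "the lines separate on the PCA plot".
#'
#' @param pca a [compute_pca()] result.
#' @param line_labels line label per individual, in score row order or
#'   named by id.
#' @param k number of leading components to use.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
line_silhouette <- function(pca, line_labels, k = 2) {
  sc <- pca$scores[, seq_len(min(k, ncol(pca$scores))), drop = FALSE]
  if (!is.null(names(line_labels))) line_labels <- line_labels[rownames(sc)]
  cl <- as.integer(factor(line_labels))
  sil <- cluster::silhouette(cl, stats::dist(sc))
  mean(sil[, "sil_width"])
}

#' Pairwise linkage disequilibrium r2
#'
#' Composite (genotypic) r2: the squared Pearson correlation of dosage
#' vectors, appropriate for unphased data. Only within-chromosome pairs
#' within `max_distance_bp` are computed. Pairs involving a monomorphic
#' SNP have undefined correlation and are skipped (counted in the
#' `n_skipped` attribute).
#'
#' @param g a complete [geno_matrix()].
#' @param max_distance_bp maximum inter-SNP distance in base pairs.
#' @return data.frame (`snp1`, `snp2`, `chromosome`, `distance_bp`, `r2`)
#'   with attribute `n_skipped`.
#' @export
pairwise_ld_r2 <- function(g, max_distance_bp = 1e6) {
  stopifnot(inherits(g, "geno_matrix"))
  d <- g$dosages
  if (anyNA(d)) stop("LD needs a complete matrix; run mean_impute() first")
  map <- g$map
  out <- list()
  n_skipped <- 0L
  for (cc in unique(map$chromosome)) {
    idx <- which(map$chromosome == cc)
    if (length(idx) < 2) next
    idx <- idx[order(map$position[idx])]
    pos <- map$position[idx]
    sds <- apply(d[, idx, drop = FALSE], 2, sd)
    poly <- sds > 0
    suppressWarnings(cm <- cor(d[, idx, drop = FALSE]))
    for (a in seq_along(idx)[-length(idx)]) {
      b <- which(pos > pos[a] & pos - pos[a] <= max_distance_bp)
      b <- b[b > a]
      if (!length(b)) next
      usable <- poly[a] & poly[b]
      n_skipped <- n_skipped + sum(!usable)
      b <- b[usable]
      if (!length(b)) next
      out[[length(out) + 1L]] <- data.frame(
        snp1 = map$snp_id[idx[a]], snp2 = map$snp_id[idx[b]],
        chromosome = cc, distance_bp = pos[b] - pos[a],
        r2 = cm[a, b]^2, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(snp1 = character(0), snp2 = character(0),
               chromosome = character(0), distance_bp = numeric(0),
               r2 = numeric(0))
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' LD-based effective population size via Sved's relation
#'
#' SNP pairs are binned by distance; base-pair distance maps to
#' recombination fraction c through Haldane's function at `cm_per_mb`
#' (default 1 cM/Mb). Per bin, the mean r2 is adjusted for finite sample
#' size (`r2' = mean r2 - 1/n`) and inverted through Sved's formula
#' `E[r2'] = 1 / (alpha + 4 Ne c)`, giving
#' `Ne(t) = (1/(4c)) (1/r2' - alpha)` at `t = 1/(2c)` generations ago.
#' Bins where the adjusted r2 gives a non-positive Ne are flagged unusable
#' rather than fatal.
#'
#' @param ld data.frame from [pairwise_ld_r2()].
#' @param n_individuals sample size used for the r2 estimates.
#' @param bins numeric vector of distance-bin breaks (bp), or a single
#'   integer number of equal-width bins.
#' @param alpha Sved's mutation/adjustment constant (default 2).
#' @param cm_per_mb genetic map density used for bp-to-Morgan conversion.
#' @return data.frame of class `ne_trajectory`: per bin mean distance,
#'   `c`, `t_generations`, `mean_r2`, `adj_r2`, `ne`, `usable`.
#' @export
estimate_ne <- function(ld, n_individuals, bins = 10, alpha = 2,
                        cm_per_mb = 1) {
  if (!nrow(ld)) stop("no LD estimates supplied")
  if (length(bins) == 1L) {
    bins <- seq(min(ld$distance_bp), max(ld$distance_bp),
                length.out = bins + 1L)
    bins[1] <- bins[1] - 1
  }
  bin_id <- cut(ld$distance_bp, bins)
  res <- list()
  for (b in levels(bin_id)) {
    sel <- bin_id == b
    if (!any(sel)) next
    d_mean <- mean(ld$distance_bp[sel])
    morgans <- d_mean * cm_per_mb * 1e-8
    cfrac <- 0.5 * (1 - exp(-2 * morgans))
    r2_mean <- mean(ld$r2[sel])
    r2_adj <- r2_mean - 1 / n_individuals
    ne <- if (r2_adj > 0) (1 / (4 * cfrac)) * (1 / r2_adj - alpha) else NA_real_
    res[[length(res) + 1L]] <- data.frame(
      bin = b, n_pairs = sum(sel), mean_distance_bp = d_mean, c = cfrac,
      t_generations = 1 / (2 * cfrac), mean_r2 = r2_mean, adj_r2 = r2_adj,
      ne = ne, usable = is.finite(ne) && ne > 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("ne_trajectory", "data.frame")
  out
}
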