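#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = (M - P)(M - P)' / (2 * sum p_k (1 - p_k))` with `M` the n x m
#' dosage matrix and the k-th column of `P` equal to `2 p_k`. Coded-allele
#' frequencies `p_k` are computed from the supplied analysis set unless
#' given explicitly (e.g. to centre validation animals with reference
#' frequencies).
#'
#' @param g a complete [geno_matrix()] or dosage matrix.
#' @param p optional vector of coded-allele frequencies.
#' @return A symmetric n x n matrix with individual ids as dimnames and
#'   attribute `kind = "G"`.
#' @export
compute_G <- function(g, p = NULL) {
  M <- if (inherits(g, "geno_matrix")) g$dosages else as.matrix(g)
  if (anyNA(M)) stop("G needs complete dosages; run mean_impute() first")
  if (ncol(M) < 2) stop("need at least two SNPs")
  if (is.null(p)) p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic: zero VanRaden denominator")
  Z <- sweep(M, 2, 2 * p, "-")
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  attr(G, "kind") <- "G"
  G
}

#' Pedigree (numerator) relationship matrix by the tabular method
#'
#' Requires an ancestors-first pedigree. Recursion:
#' `A_ii = 1 + 0.5 A_{sire,dam}`; `A_ij = 0.5 (A_{j,sire(i)} + A_{j,dam(i)})`
#' for `j` earlier than `i`; unknown parents contribute 0.
#'
#' @param pedigree a sorted `pedigree_table` (see [read_pedigree()]).
#' @return A symmetric matrix over all pedigree ids, attribute
#'   `kind = "A"`.
#' @export
compute_A <- function(pedigree) {
  n <- nrow(pedigree)
  ids <- pedigree$id
  idx <- setNames(seq_len(n), ids)
  si <- unname(idx[pedigree$sire])
  di <- unname(idx[pedigree$dam])
  if (any(!is.na(si) & si >= seq_len(n)) ||
      any(!is.na(di) & di >= seq_len(n))) {
    stop("pedigree is not sorted ancestors-first; use read_pedigree()/as_pedigree()")
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (!is.na(s)) A[j, s] else 0
      row_d <- if (!is.na(d)) A[j, d] else 0
      A[j, i] <- A[i, j] <- 0.5 * (row_s + row_d)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  attr(A, "kind") <- "A"
  A
}

#' Extract the genotyped block of A
#'
#' @param A pedigree relationship matrix from [compute_A()].
#' @param genotyped_ids ids of genotyped individuals (subset of the
#'   pedigree ids) in the desired order.
#' @return The principal submatrix `A22`, attribute `kind = "A22"`.
#' @export
extract_A22 <- function(A, genotyped_ids) {
  missing_ids <- setdiff(genotyped_ids, rownames(A))
  if (length(missing_ids)) {
    stop("genotyped ids not in pedigree: ",
         paste(head(missing_ids, 5), collapse = ", "))
  }
  A22 <- A[genotyped_ids, genotyped_ids, drop = FALSE]
  attr(A22, "kind") <- "A22"
  A22
}

#' Tune G to the A22 scale and blend
#'
#' First rescales G with scalars (a, b) so that the mean diagonal and mean
#' off-diagonal of `a G + b 11'` match those of `A22` (puts the genomic
#' and pedigree relationships on a compatible base), then blends:
#' `G_b = (1 - w) G_tuned + w A22`. Blending with `w > 0` guarantees
#' invertibility when `A22` is positive definite.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationships of the same individuals, same order.
#' @param blend_weight blending weight `w` in `[0, 1]` (default 0.05).
#' @param tune logical; set `FALSE` to skip the (a, b) rescaling.
#' @return Blended matrix, attribute `kind = "G_blended"`.
#' @export
tune_and_blend_G <- function(G, A22, blend_weight = 0.05, tune = TRUE) {
  if (!identical(dim(G), dim(A22))) stop("G and A22 dimensions differ")
  if (!is.null(rownames(G)) && !is.null(rownames(A22)) &&
      !identical(rownames(G), rownames(A22))) {
    stop("G and A22 id order differs")
  }
  n <- nrow(G)
  if (tune && n > 1) {
    off <- row(G) != col(G)
    # a * mean + b matched for diagonal and off-diagonal means
    dG <- mean(diag(G)); oG <- mean(G[off])
    dA <- mean(diag(A22)); oA <- mean(A22[off])
    det2 <- dG - oG
    if (abs(det2) < 1e-12) stop("singular tuning system: G has equal diagonal and off-diagonal means")
    a <- (dA - oA) / det2
    b <- dA - a * dG
    G <- a * G + b
  }
  Gb <- (1 - blend_weight) * G + blend_weight * A22
  dimnames(Gb) <- dimnames(A22)
  attr(Gb, "kind") <- "G_blended"
  Gb
}

#' Inverse of the single-step (H) relationship matrix
#'
#' Standard construction with unit weights:
#' `H^-1 = A^-1 + [[0, 0], [0, G_b^-1 - A22^-1]]`, the non-zero block on
#' the genotyped individuals. The corresponding H combines pedigree
#' relationships with genomic relationships among (and propagated to
#' relatives of) the genotyped animals.
#'
#' @param A full pedigree relationship matrix.
#' @param A22 genotyped block of `A` (same order as `G_blended`).
#' @param G_blended blended genomic matrix from [tune_and_blend_G()].
#' @param genotyped_ids ids (rows of `A22`/`G_blended`) marking the
#'   genotyped block within `A`.
#' @return `H^-1` over all pedigree ids, attribute `kind = "H_inverse"`.
#' @export
compute_H_inverse <- function(A, A22, G_blended, genotyped_ids) {
  ids <- rownames(A)
  if (!all(genotyped_ids %in% ids)) stop("genotyped ids not in A")
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("matrix A is singular: ", conditionMessage(e)))
  Hinv <- Ainv
  if (length(genotyped_ids)) {
    Gi <- tryCatch(solve(G_blended), error = function(e)
      stop("matrix G_blended is singular: ", conditionMessage(e)))
    A22i <- tryCatch(solve(A22), error = function(e)
      stop("matrix A22 is singular: ", conditionMessage(e)))
    gi <- match(genotyped_ids, ids)
    Hinv[gi, gi] <- Hinv[gi, gi] + Gi - A22i
  }
  dimnames(Hinv) <- dimnames(A)
  attr(Hinv, "kind") <- "H_inverse"
  Hinv
}
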