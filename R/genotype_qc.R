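#' Quality-control thresholds
#'
#' Defaults follow the standard chip-QC rule set for this kind of study:
#' individuals with genotype call rate below 0.9 are excluded, and within
#' each line SNPs with call rate below 0.9 or minor allele frequency below
#' 0.05 are excluded.
#'
#' @param min_individual_call_rate,min_snp_call_rate,min_maf thresholds in
#'   `[0, 1]`. Exclusion is strict (`< threshold` fails), so ties at the
#'   threshold pass.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_individual_call_rate = 0.9,
                          min_snp_call_rate = 0.9,
                          min_maf = 0.05) {
  vals <- c(min_individual_call_rate, min_snp_call_rate, min_maf)
  if (any(vals < 0) || any(vals > 1)) stop("thresholds must be in [0, 1]")
  structure(list(min_individual_call_rate = min_individual_call_rate,
                 min_snp_call_rate = min_snp_call_rate,
                 min_maf = min_maf), class = "qc_thresholds")
}

#' Per-individual genotype call rate
#'
#' @param g a [geno_matrix()].
#' @return Named numeric vector: fraction of non-missing calls per
#'   individual.
#' @export
individual_call_rate <- function(g) {
  stopifnot(inherits(g, "geno_matrix"), ncol(g$dosages) >= 1)
  rowMeans(!is.na(g$dosages))
}

#' Per-SNP call rate
#'
#' @param g a [geno_matrix()].
#' @return Named numeric vector: fraction of non-missing calls per SNP.
#' @export
snp_call_rate <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  colMeans(!is.na(g$dosages))
}

#' Per-SNP minor allele frequency
#'
#' Computed on non-missing dosages: `p` = mean dosage / 2,
#' MAF = `min(p, 1 - p)`. SNPs with no non-missing call get `NA` (they fail
#' the call-rate filter first).
#'
#' @param g a [geno_matrix()].
#' @return Named numeric vector in `[0, 0.5]`.
#' @export
snp_maf <- function(g) {
  p <- allele_freq(g)
  pmin(p, 1 - p)
}

#' Apply per-line genotype quality control
#'
#' Filter order follows the per-population QC design: individuals with a
#' low overall call rate are removed first; then, within each line, SNPs
#' failing the per-line call-rate or per-line MAF threshold are removed.
#' A SNP survives a line if and only if it passes both criteria within
#' that line, so the surviving SNP sets differ between lines.
#'
#' @param g a [geno_matrix()] covering all individuals.
#' @param thresholds a [qc_thresholds()].
#' @param line_labels named character vector (or vector in `g` id order)
#'   assigning each individual to a line.
#' @return A list with `per_line` (named list of filtered `geno_matrix`
#'   objects) and `report` (a `qc_report` list: removed individuals with
#'   reasons, per-line SNP removal counts per criterion, per-line
#'   surviving counts).
#' @export
apply_qc <- function(g, thresholds = qc_thresholds(), line_labels) {
  stopifnot(inherits(g, "geno_matrix"))
  ids <- rownames(g$dosages)
  if (!is.null(names(line_labels))) {
    if (!all(ids %in% names(line_labels))) {
      stop("line_labels do not cover all individuals")
    }
    line_labels <- line_labels[ids]
  } else if (length(line_labels) != length(ids)) {
    stop("line_labels must cover all individuals")
  }
  line_labels <- as.character(line_labels)

  icr <- individual_call_rate(g)
  drop_ind <- ids[icr < thresholds$min_individual_call_rate]
  keep_ind <- setdiff(ids, drop_ind)
  removed_individuals <- data.frame(
    id = drop_ind, reason = rep("call_rate", length(drop_ind)),
    call_rate = unname(icr[drop_ind]), stringsAsFactors = FALSE)

  per_line <- list()
  snp_counts <- list()
  for (l in unique(line_labels)) {
    l_ids <- intersect(keep_ind, ids[line_labels == l])
    if (!length(l_ids)) {
      stop("line ", l, " has no individuals left after the call-rate filter")
    }
    gl <- subset_geno(g, individuals = l_ids)
    cr <- snp_call_rate(gl)
    maf <- snp_maf(gl)
    fail_cr <- cr < thresholds$min_snp_call_rate
    fail_maf <- !is.na(maf) & maf < thresholds$min_maf
    fail_maf[is.na(maf)] <- TRUE   # frequency undefined: no calls at all
    keep <- !fail_cr & !fail_maf
    if (!any(keep)) stop("line ", l, " has no SNPs left after QC")
    per_line[[l]] <- subset_geno(gl, snps = which(keep))
    snp_counts[[l]] <- data.frame(
      line = l, n_input = length(keep),
      removed_call_rate = sum(fail_cr),
      removed_maf = sum(fail_maf & !fail_cr),
      surviving = sum(keep), stringsAsFactors = FALSE)
  }
  snp_summary <- do.call(rbind, snp_counts)
  rownames(snp_summary) <- NULL
  shared <- Reduce(intersect, lapply(per_line, function(x) x$map$snp_id))
  report <- structure(list(removed_individuals = removed_individuals,
                           snp_summary = snp_summary,
                           intersection_size = length(shared)),
                      class = "qc_report")
  list(per_line = per_line, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", nrow(x$removed_individuals), "individuals removed\n")
  print(x$snp_summary)
  cat("SNPs shared by all lines:", x$intersection_size, "\n")
  invisible(x)
}

#' Combine per-line matrices over the shared SNP set
#'
#' For combined-reference analyses, the SNP set is the intersection of the
#' per-line surviving sets (the conservative choice: every retained SNP
#' passed QC in every member line) and individuals are concatenated. The
#' fixed coded-allele convention guarantees dosages mean the same thing in
#' every line.
#'
#' @param per_line named list of `geno_matrix` objects (>= 2).
#' @return A combined [geno_matrix()].
#' @export
intersect_snp_sets <- function(per_line) {
  if (length(per_line) < 2) stop("need at least two lines to combine")
  shared <- Reduce(intersect, lapply(per_line, function(x) x$map$snp_id))
  if (!length(shared)) stop("no SNPs shared by all lines")
  mats <- lapply(per_line, function(x) subset_geno(x, snps = shared))
  dos <- do.call(rbind, lapply(mats, function(x) x$dosages))
  geno_matrix(dos, rownames(dos), mats[[1]]$map)
}

#' Mean-impute missing dosages
#'
#' Each missing entry is replaced by that SNP's mean dosage in the
#' analysis set; observed entries are unchanged, so per-SNP means are
#' preserved.
#'
#' @param g a [geno_matrix()] (post-QC; every SNP needs at least one
#'   observed call).
#' @return A complete [geno_matrix()] (dosages may be fractional).
#' @export
mean_impute <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  d <- g$dosages
  if (!anyNA(d)) return(g)
  mu <- colMeans(d, na.rm = TRUE)
  if (anyNA(mu)) {
    stop("SNPs with no observed calls cannot be imputed: ",
         paste(head(g$map$snp_id[is.na(mu)], 5), collapse = ", "))
  }
  na_idx <- which(is.na(d), arr.ind = TRUE)
  d[na_idx] <- mu[na_idx[, 2]]
  out <- g
  out$dosages <- d
  out
}
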