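#' Construct a genotype matrix object
#'
#' The central genotype container: an individuals-by-SNP dosage matrix
#' (counts of the coded allele, `NA` = missing call) plus a SNP map.
#' The coded allele of every SNP is fixed at creation time and is never
#' re-inferred from allele frequencies, so dosages keep the same meaning
#' when the matrix is subset to individual lines.
#'
#' @param dosages numeric matrix, individuals in rows, SNPs in columns;
#'   entries 0, 1, 2 or `NA`.
#' @param individual_ids character vector of unique individual ids
#'   (defaults to `rownames(dosages)`).
#' @param map data.frame with columns `snp_id`, `chromosome`, `position`,
#'   `allele_a`, `allele_b`, `coded_allele`. Positions are 1-based;
#'   chromosomes are autosomal labels.
#'
#' @return An object of class `geno_matrix`: a list with elements
#'   `dosages` (named matrix) and `map`.
#' @export
geno_matrix <- function(dosages, individual_ids = rownames(dosages), map) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(individual_ids)) {
    stop("individual ids are required (rownames or `individual_ids`)")
  }
  individual_ids <- as.character(individual_ids)
  if (nrow(dosages) != length(individual_ids)) {
    stop("row count does not match number of individual ids")
  }
  if (anyDuplicated(individual_ids)) {
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  }
  map <- validate_snp_map(map)
  if (ncol(dosages) != nrow(map)) {
    stop("column count (", ncol(dosages), ") does not match map rows (",
         nrow(map), ")")
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  rownames(dosages) <- individual_ids
  colnames(dosages) <- map$snp_id
  structure(list(dosages = dosages, map = map), class = "geno_matrix")
}

validate_snp_map <- function(map) {
  required <- c("snp_id", "chromosome", "position",
                "allele_a", "allele_b", "coded_allele")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols)) {
    stop("SNP map is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$snp_id <- as.character(map$snp_id)
  map$chromosome <- as.character(map$chromosome)
  if (anyDuplicated(map$snp_id)) {
    stop("duplicate snp ids: ",
         paste(unique(map$snp_id[duplicated(map$snp_id)]), collapse = ", "))
  }
  if (any(map$position <= 0)) stop("SNP positions must be positive (1-based)")
  if (any(map$allele_a == map$allele_b)) {
    stop("allele_a and allele_b must differ for every SNP")
  }
  if (!all(map$coded_allele == map$allele_a | map$coded_allele == map$allele_b)) {
    stop("coded_allele must be one of allele_a / allele_b")
  }
  # autosomes only: reject sex-chromosome labels
  sex_labels <- c("X", "Y", "XY", "MT", "M", "23", "24", "25", "26")
  if (any(toupper(map$chromosome) %in% sex_labels)) {
    stop("non-autosomal chromosome labels present; autosomes only are supported")
  }
  rownames(map) <- NULL
  map
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosages), "individuals x", ncol(x$dosages),
      "SNPs;", sum(is.na(x$dosages)), "missing calls\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param g a [geno_matrix()].
#' @param individuals character ids or index vector (optional).
#' @param snps character snp ids or index vector (optional).
#' @return A `geno_matrix` restricted to the requested rows/columns, in the
#'   requested order.
#' @export
subset_geno <- function(g, individuals = NULL, snps = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  d <- g$dosages
  map <- g$map
  if (!is.null(individuals)) {
    if (is.character(individuals)) {
      missing_ids <- setdiff(individuals, rownames(d))
      if (length(missing_ids)) {
        stop("unknown individual ids: ", paste(head(missing_ids, 5), collapse = ", "))
      }
    }
    d <- d[individuals, , drop = FALSE]
  }
  if (!is.null(snps)) {
    if (is.character(snps)) {
      missing_snps <- setdiff(snps, map$snp_id)
      if (length(missing_snps)) {
        stop("unknown snp ids: ", paste(head(missing_snps, 5), collapse = ", "))
      }
      idx <- match(snps, map$snp_id)
    } else {
      idx <- snps
    }
    d <- d[, idx, drop = FALSE]
    map <- map[idx, , drop = FALSE]
    rownames(map) <- NULL
  }
  # built directly (not via the constructor) so imputed fractional
  # dosages survive subsetting
  structure(list(dosages = d, map = map), class = "geno_matrix")
}

#' Coded-allele frequencies of a genotype matrix
#'
#' @param g a [geno_matrix()] or plain dosage matrix.
#' @return numeric vector `p`, one frequency per SNP, computed on
#'   non-missing dosages.
#' @export
allele_freq <- function(g) {
  d <- if (inherits(g, "geno_matrix")) g$dosages else g
  colMeans(d, na.rm = TRUE) / 2
}
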