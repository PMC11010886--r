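# shared fixtures and independent oracles

# small genotype matrix with explicit map
toy_geno <- function(dosages, ids = NULL, chrom = NULL, pos = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  map <- data.frame(snp_id = paste0("s", seq_len(m)),
                    chromosome = as.character(chrom), position = pos,
                    allele_a = "A", allele_b = "G", coded_allele = "G",
                    stringsAsFactors = FALSE)
  geno_matrix(dosages, ids, map)
}

# HWE genotypes at given frequencies (independent individuals)
hwe_geno <- function(n, p, ids = paste0("i", seq_len(n))) {
  m <- length(p)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  toy_geno(d, ids = ids)
}

# Hudson FST estimator for two populations (ratio of averages)
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# recursive-coancestry oracle for the numerator relationship matrix,
# independent of the tabular implementation
kinship_oracle <- function(pedigree) {
  n <- nrow(pedigree)
  idx <- stats::setNames(seq_len(n), pedigree$id)
  si <- unname(idx[pedigree$sire]); di <- unname(idx[pedigree$dam])
  phi <- matrix(NA_real_, n, n)
  k <- function(i, j) {
    if (is.na(phi[i, j])) {
      val <- if (i == j) {
        0.5 * (1 + (if (!is.na(si[i]) && !is.na(di[i])) k(si[i], di[i]) else 0))
      } else {
        a <- max(i, j); b <- min(i, j)   # a is the younger (later) one
        s <- si[a]; d <- di[a]
        0.5 * ((if (!is.na(s)) k(s, b) else 0) +
                 (if (!is.na(d)) k(d, b) else 0))
      }
      phi[i, j] <<- val; phi[j, i] <<- val
    }
    phi[i, j]
  }
  A <- matrix(0, n, n, dimnames = list(pedigree$id, pedigree$id))
  for (i in seq_len(n)) for (j in seq_len(i)) A[i, j] <- A[j, i] <- 2 * k(i, j)
  A
}

# naive dense mixed-model-equation solve at a fixed variance ratio,
# requiring an invertible K
naive_mme <- function(y, X, K, lambda) {
  n <- length(y)
  Ki <- solve(K)
  C <- rbind(cbind(crossprod(X), t(X)),
             cbind(X, diag(n) + Ki * lambda))
  sol <- solve(C, c(crossprod(X, y), y))
  list(b = sol[seq_len(ncol(X))], u = sol[-seq_len(ncol(X))])
}

# GLS/BLUP closed form that tolerates a singular K
naive_blup <- function(y, X, K, s2u, s2e) {
  V <- s2u * K + s2e * diag(length(y))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2u * K %*% Vi %*% (y - X %*% b)
  list(b = drop(b), u = drop(u))
}

# marker-architecture simulation for sampler tests: n_qtl causal loci
# among m SNPs, heritability h2, sex fixed effect
sim_marker_data <- function(n, m, h2, seed, n_qtl = m) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  M <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
              dimnames = list(paste0("i", seq_len(n)),
                              paste0("s", seq_len(m))))
  eff <- numeric(m)
  qtl <- sort(sample.int(m, n_qtl))
  eff[qtl] <- rnorm(n_qtl)
  tbv_raw <- drop(scale(M, scale = FALSE) %*% eff)
  eff <- eff * sqrt(h2 / var(tbv_raw))
  tbv <- tbv_raw * sqrt(h2 / var(tbv_raw))
  sex <- rep(c("male", "female"), length.out = n)
  y <- 10 + 0.5 * (sex == "male") + tbv + rnorm(n, 0, sqrt(1 - h2))
  list(M = M, eff = eff, tbv = tbv, y = y, sex = sex,
       X = fixed_effects_design(sex), qtl = qtl)
}

# reduced study configuration used across tests
test_config <- function(seed = 1, ...) {
  sim_config(n_per_line = c(small = 60, medium = 100, large = 200),
             n_snps = 2000, n_qtl = 200, seed = seed, ...)
}
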