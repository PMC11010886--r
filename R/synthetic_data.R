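#' Configuration for the synthetic three-line study
#'
#' Defines the conditions of the simulated multi-line pig study: three
#' lines with divergent allele frequencies (Balding-Nichols drift from a
#' common base population), discrete-generation pedigrees with
#' non-genotyped ancestors, gene-dropped genotypes and two heritable
#' growth traits (age100 in days, bf100 in mm) with a sex fixed effect.
#'
#' Line sizes default to the 295 / 500 / 1500 composition of the
#' small / medium / large (Danish / Canadian / American role) lines; tests
#' use a reduced 60 / 100 / 200 configuration.
#'
#' @param n_per_line named counts of genotyped study animals per line,
#'   names `small`, `medium`, `large`.
#' @param n_snps number of autosomal SNPs.
#' @param n_chromosomes number of autosomes the SNPs are spread over.
#' @param chr_length_bp autosome length in base pairs (uniform SNP
#'   placement).
#' @param n_qtl number of causal loci per trait (drawn among the SNPs).
#' @param divergence_fst Balding-Nichols drift parameter in (0, 1)
#'   controlling between-line allele-frequency divergence.
#' @param h2 named per-trait narrow-sense heritabilities in (0, 1).
#' @param trait_mean,trait_sd named per-trait phenotypic means and
#'   standard deviations on the corrected scale (days / mm).
#' @param sex_effect named per-trait additive effect of being male, in
#'   trait units.
#' @param n_generations pedigree depth (>= 1); the youngest generation
#'   holds the genotyped study animals.
#' @param genotyped_fraction fraction of all pedigree individuals that are
#'   genotyped, in (0, 1]; ancestors make up the remainder and carry
#'   phenotypes only (the single-step GBLUP use case). With 1 the pedigree
#'   collapses to a single genotyped founder generation.
#' @param missing_rate fraction of genotype calls set to missing in the
#'   written/returned study genotypes.
#' @param ld_mode logical; if `TRUE`, gametes are formed by copying
#'   parental haplotypes in blocks with Haldane recombination
#'   probabilities (1 cM/Mb), creating linkage disequilibrium that decays
#'   with distance. If `FALSE` (default) loci segregate independently,
#'   which keeps Mendelian oracles exact.
#' @param seed master RNG seed; stages draw from fixed per-stage
#'   substreams so they are independently reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_line = c(small = 295, medium = 500, large = 1500),
                       n_snps = 30000,
                       n_chromosomes = 18,
                       chr_length_bp = 1.5e8,
                       n_qtl = 300,
                       divergence_fst = 0.1,
                       h2 = c(age100 = 0.4, bf100 = 0.5),
                       trait_mean = c(age100 = 160, bf100 = 12),
                       trait_sd = c(age100 = 8, bf100 = 2),
                       sex_effect = c(age100 = -5, bf100 = -1.2),
                       n_generations = 3,
                       genotyped_fraction = 0.75,
                       missing_rate = 0.01,
                       ld_mode = FALSE,
                       seed = 1) {
  if (length(n_per_line) != 3L || is.null(names(n_per_line)) ||
      !setequal(names(n_per_line), c("small", "medium", "large"))) {
    stop("n_per_line must be a named vector with names small, medium, large")
  }
  if (any(n_per_line < 4)) stop("each line needs at least 4 study animals")
  if (n_qtl > n_snps) stop("n_qtl must not exceed n_snps")
  if (divergence_fst <= 0 || divergence_fst >= 1) {
    stop("divergence_fst must be in (0, 1)")
  }
  if (any(h2 <= 0) || any(h2 >= 1)) stop("h2 must be in (0, 1)")
  if (genotyped_fraction <= 0 || genotyped_fraction > 1) {
    stop("genotyped_fraction must be in (0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (n_generations < 1) stop("n_generations must be >= 1")
  traits <- c("age100", "bf100")
  for (v in list(h2, trait_mean, trait_sd, sex_effect)) {
    if (!all(traits %in% names(v))) {
      stop("per-trait parameters need names age100 and bf100")
    }
  }
  structure(list(n_per_line = n_per_line[c("small", "medium", "large")],
                 n_snps = n_snps, n_chromosomes = n_chromosomes,
                 chr_length_bp = chr_length_bp, n_qtl = n_qtl,
                 divergence_fst = divergence_fst, h2 = h2[traits],
                 trait_mean = trait_mean[traits], trait_sd = trait_sd[traits],
                 sex_effect = sex_effect[traits],
                 n_generations = n_generations,
                 genotyped_fraction = genotyped_fraction,
                 missing_rate = missing_rate, ld_mode = ld_mode,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# fixed per-stage substream offsets so each stage is independently
# reproducible from the master seed
stage_seed <- function(config, stage) {
  offsets <- c(freqs = 101L, pedigree = 211L, genedrop = 307L,
               phenotypes = 401L, missing = 503L)
  (config$seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Draw per-line allele frequencies under Balding-Nichols drift
#'
#' Each line's frequency at SNP k is drawn from a Beta distribution with
#' mean `base_freqs[k]` and variance `fst * p * (1 - p)`, then clipped to
#' `[0.001, 0.999]`. As `fst` approaches 0 the line frequencies converge
#' to the base frequencies.
#'
#' @param base_freqs base-population frequencies (recommended in
#'   `[0.05, 0.95]`).
#' @param fst drift parameter in (0, 1).
#' @param n_lines number of lines.
#' @param seed RNG seed.
#' @return Matrix `length(base_freqs)` x `n_lines`.
#' @export
draw_line_frequencies <- function(base_freqs, fst, n_lines = 3, seed = 1) {
  if (fst <= 0 || fst >= 1) stop("fst must be in (0, 1)")
  if (any(base_freqs <= 0) || any(base_freqs >= 1)) {
    stop("base frequencies must be in (0, 1)")
  }
  set.seed(seed)
  m <- length(base_freqs)
  k <- (1 - fst) / fst
  out <- matrix(0, m, n_lines)
  for (l in seq_len(n_lines)) {
    out[, l] <- rbeta(m, base_freqs * k, (1 - base_freqs) * k)
  }
  pmin(pmax(out, 0.001), 0.999)
}

#' Simulate discrete-generation pedigrees for the three lines
#'
#' Each line gets `n_generations` discrete generations with no cross-line
#' matings (the three lines share no ancestors). The youngest generation
#' holds the `n_per_line` genotyped study animals; ancestor generations
#' (sized so genotyped animals are `genotyped_fraction` of the pedigree)
#' are phenotyped but not genotyped. Every non-founder draws one sire and
#' one dam uniformly from the previous generation of its own line.
#'
#' @param config a [sim_config()].
#' @param gen_sizes optional list (one element per line, names
#'   `small`/`medium`/`large`) of explicit per-generation sizes, overriding
#'   the default allocation; the last element of each vector is the study
#'   generation.
#' @return A `pedigree_table` with extra columns `line`, `sex`,
#'   `generation` and logical `genotyped`, sorted ancestors-first.
#' @export
simulate_pedigree <- function(config, gen_sizes = NULL) {
  set.seed(stage_seed(config, "pedigree"))
  lines <- names(config$n_per_line)
  records <- list()
  for (l in lines) {
    n_study <- config$n_per_line[[l]]
    if (is.null(gen_sizes)) {
      G <- config$n_generations
      n_anc_total <- round(n_study * (1 / config$genotyped_fraction - 1))
      if (n_anc_total == 0L || G == 1L) {
        sizes <- n_study
      } else {
        n_anc_gen <- max(4L, floor(n_anc_total / (G - 1)))
        sizes <- c(rep(n_anc_gen, G - 1), n_study)
      }
    } else {
      sizes <- gen_sizes[[l]]
    }
    if (length(sizes) > 1 && any(sizes[-length(sizes)] < 4)) {
      stop("line ", l, ": fewer than 2 candidate parents per sex in some ",
           "generation (ancestor generations need >= 4 individuals)")
    }
    prev_males <- prev_females <- character(0)
    for (g in seq_along(sizes)) {
      n_g <- sizes[g]
      ids <- sprintf("%s_g%d_%04d", l, g, seq_len(n_g))
      sex <- rep(c("male", "female"), length.out = n_g)
      if (g == 1L) {
        sire <- dam <- rep(NA_character_, n_g)
      } else {
        sire <- sample(prev_males, n_g, replace = TRUE)
        dam <- sample(prev_females, n_g, replace = TRUE)
      }
      records[[length(records) + 1L]] <- data.frame(
        id = ids, sire = sire, dam = dam, line = l, sex = sex,
        generation = g, genotyped = g == length(sizes),
        stringsAsFactors = FALSE)
      prev_males <- ids[sex == "male"]
      prev_females <- ids[sex == "female"]
    }
  }
  pd <- do.call(rbind, records)
  # generations were emitted ancestors-first within line, so the order is
  # already topological; run it through as_pedigree for the cycle check
  sorted <- as_pedigree(pd[, c("id", "sire", "dam")])
  pd <- pd[match(sorted$id, pd$id), , drop = FALSE]
  rownames(pd) <- NULL
  class(pd) <- c("pedigree_table", "data.frame")
  pd
}

#' Build the SNP map used by the generator
#'
#' SNPs are placed uniformly at random along equally sized autosomes and
#' sorted by position. Alleles are A (non-coded) and B-strand G (coded).
#'
#' @param config a [sim_config()].
#' @return A SNP map data.frame as required by [geno_matrix()].
#' @keywords internal
simulate_map <- function(config) {
  m <- config$n_snps
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), m))
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(config$chr_length_bp, length(idx)))
  }
  data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
             chromosome = as.character(chrom), position = pos,
             allele_a = "A", allele_b = "G", coded_allele = "G",
             stringsAsFactors = FALSE)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotype alleles are drawn Bernoulli(line frequency); each
#' offspring receives one gamete per parent. By default loci segregate
#' independently (exact Mendelian oracles); in LD mode the gamete copies
#' parental haplotypes in blocks, switching between the two parental
#' haplotypes at each SNP interval with the Haldane recombination
#' probability at 1 cM/Mb.
#'
#' @param pedigree a sorted `pedigree_table` with a `line` column.
#' @param line_freqs matrix SNPs x lines of coded-allele frequencies,
#'   columns named by line.
#' @param map SNP map (needed in LD mode for chromosome/position).
#' @param seed RNG seed.
#' @param ld_mode logical, see [sim_config()].
#' @return A [geno_matrix()] covering every pedigree individual.
#' @export
gene_drop <- function(pedigree, line_freqs, map, seed = 1, ld_mode = FALSE) {
  if (!"line" %in% names(pedigree)) stop("pedigree needs a `line` column")
  if (is.null(colnames(line_freqs)) ||
      !all(pedigree$line %in% colnames(line_freqs))) {
    stop("line_freqs must have one named column per pedigree line")
  }
  set.seed(seed)
  n <- nrow(pedigree)
  m <- nrow(line_freqs)
  idx <- setNames(seq_len(n), pedigree$id)
  si <- idx[pedigree$sire]
  di <- idx[pedigree$dam]
  if (any(!is.na(pedigree$sire) & is.na(si)) ||
      any(!is.na(pedigree$dam) & is.na(di))) {
    stop("pedigree references unknown parent ids")
  }
  hap1 <- matrix(0L, n, m)
  hap2 <- matrix(0L, n, m)

  # per-interval recombination probabilities (0.5 across chromosome breaks)
  if (ld_mode) {
    d_bp <- diff(map$position)
    rprob <- 0.5 * (1 - exp(-2 * d_bp * 1e-8))
    rprob[map$chromosome[-1] != map$chromosome[-m]] <- 0.5
  }

  make_gamete <- function(p) {
    if (!ld_mode) {
      pick <- rbinom(m, 1L, 0.5)
    } else {
      switches <- rbinom(m - 1L, 1L, rprob)
      pick <- (rbinom(1L, 1L, 0.5) + cumsum(c(0L, switches))) %% 2L
    }
    ifelse(pick == 0L, hap1[p, ], hap2[p, ])
  }

  for (i in seq_len(n)) {
    if (is.na(si[i]) && is.na(di[i])) {
      p <- line_freqs[, pedigree$line[i]]
      hap1[i, ] <- rbinom(m, 1L, p)
      hap2[i, ] <- rbinom(m, 1L, p)
    } else if (!is.na(si[i]) && !is.na(di[i])) {
      hap1[i, ] <- make_gamete(si[i])
      hap2[i, ] <- make_gamete(di[i])
    } else {
      stop("individual ", pedigree$id[i], " has exactly one known parent; ",
           "gene dropping needs both or neither")
    }
  }
  geno_matrix(hap1 + hap2, pedigree$id, map)
}

#' Simulate the two corrected growth traits and their raw measurements
#'
#' For each trait, `n_qtl` causal SNPs get standard-normal effects rescaled
#' so that true breeding values explain `h2` of the (sex-adjusted)
#' phenotypic variance; the corrected phenotype is
#' intercept + sex effect + TBV + residual. Raw measurements
#' (`measured_age`, `measured_weight`, `measured_backfat`) are then
#' back-computed by inverting the 100 kg correction formulas at a weight
#' near 100 kg, so that [apply_corrections()] reproduces the simulated
#' corrected traits exactly.
#'
#' @param g a [geno_matrix()] covering every individual to phenotype.
#' @param pedigree `pedigree_table` with `sex` and `line` for the same
#'   individuals.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return A list with `phenotypes` (a `pheno_table` of raw measurements)
#'   and `truth` (data.frame `id`, `tbv_age100`, `tbv_bf100`, plus QTL
#'   effects as attributes `qtl_age100`, `qtl_bf100`).
#' @export
simulate_phenotypes <- function(g, pedigree, config, seed = 1) {
  set.seed(seed)
  stopifnot(identical(rownames(g$dosages), pedigree$id))
  M <- g$dosages
  if (anyNA(M)) stop("simulate_phenotypes needs complete genotypes")
  n <- nrow(M)
  sexm <- as.numeric(pedigree$sex == "male")
  traits <- c("age100", "bf100")
  corrected <- matrix(0, n, 2, dimnames = list(pedigree$id, traits))
  tbv <- matrix(0, n, 2, dimnames = list(pedigree$id, traits))
  qtl <- list()
  for (t in traits) {
    h2 <- config$h2[[t]]
    v_target <- config$trait_sd[[t]]^2
    qtl_idx <- sort(sample.int(ncol(M), config$n_qtl))
    eff <- rnorm(config$n_qtl)
    raw <- drop(M[, qtl_idx, drop = FALSE] %*% eff)
    v_raw <- var(raw)
    if (v_raw <= 0) stop("degenerate QTL genotypes; increase n_snps or MAF")
    eff <- eff * sqrt(h2 * v_target / v_raw)
    tbv[, t] <- drop(M[, qtl_idx, drop = FALSE] %*% eff)
    resid <- rnorm(n, 0, sqrt((1 - h2) * v_target))
    corrected[, t] <- config$trait_mean[[t]] + config$sex_effect[[t]] * sexm +
      (tbv[, t] - mean(tbv[, t])) + resid
    qtl[[t]] <- data.frame(snp_id = g$map$snp_id[qtl_idx], effect = eff,
                           stringsAsFactors = FALSE)
  }
  if (any(corrected[, "bf100"] <= 0)) {
    corrected[, "bf100"] <- pmax(corrected[, "bf100"], 0.5)
  }

  # invert the endpoint corrections at a measurement weight near 100 kg
  w <- pmin(pmax(rnorm(n, 100, 5), 88), 112)
  coeff <- correction_constants$cf_coeff[pedigree$sex]
  measured_age <- corrected[, "age100"] / (1 + (100 - w) / (w * coeff))
  num <- correction_constants$bf_num[pedigree$sex]
  slope <- correction_constants$bf_slope[pedigree$sex]
  measured_backfat <- corrected[, "bf100"] * (num + slope * (w - 100)) / num

  ph <- data.frame(id = pedigree$id, sex = pedigree$sex, line = pedigree$line,
                   measured_age = unname(measured_age),
                   measured_weight = unname(w),
                   measured_backfat = unname(measured_backfat),
                   stringsAsFactors = FALSE)
  class(ph) <- c("pheno_table", "data.frame")
  truth <- data.frame(id = pedigree$id, tbv_age100 = unname(tbv[, "age100"]),
                      tbv_bf100 = unname(tbv[, "bf100"]),
                      stringsAsFactors = FALSE)
  attr(truth, "qtl_age100") <- qtl[["age100"]]
  attr(truth, "qtl_bf100") <- qtl[["bf100"]]
  list(phenotypes = ph, truth = truth)
}

#' Simulate a complete three-line study in memory
#'
#' Runs every generator stage (line frequencies, pedigree, gene drop,
#' phenotypes, missing-call masking) from the per-stage substreams of the
#' master seed.
#'
#' @param config a [sim_config()].
#' @return A list with `config`, `map`, `line_freqs`, `pedigree`,
#'   `geno_all` (complete genotypes, all pedigree individuals), `geno`
#'   (genotyped study animals only, with missing calls), `phenotypes`
#'   (raw measurements for all pedigree individuals) and `truth`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "freqs"))
  base_freqs <- runif(config$n_snps, 0.05, 0.95)
  line_freqs <- draw_line_frequencies(base_freqs, config$divergence_fst,
                                      n_lines = 3,
                                      seed = stage_seed(config, "freqs") + 1L)
  colnames(line_freqs) <- names(config$n_per_line)
  map <- simulate_map(config)
  pedigree <- simulate_pedigree(config)
  geno_all <- gene_drop(pedigree, line_freqs, map,
                        seed = stage_seed(config, "genedrop"),
                        ld_mode = config$ld_mode)
  sim <- simulate_phenotypes(geno_all, pedigree, config,
                             seed = stage_seed(config, "phenotypes"))
  geno <- subset_geno(geno_all, individuals = pedigree$id[pedigree$genotyped])
  if (config$missing_rate > 0) {
    set.seed(stage_seed(config, "missing"))
    d <- geno$dosages
    mask <- matrix(runif(length(d)) < config$missing_rate, nrow(d), ncol(d))
    d[mask] <- NA_real_
    geno <- geno_matrix(d, rownames(geno$dosages), geno$map)
  }
  list(config = config, map = map, line_freqs = line_freqs,
       pedigree = pedigree, geno_all = geno_all, geno = geno,
       phenotypes = sim$phenotypes, truth = sim$truth)
}

#' Generate a synthetic study and write it to disk
#'
#' Writes the file set consumed by the pipeline: `genotypes.ped` /
#' `genotypes.map` (+ allele sidecar) for the genotyped study animals,
#' `phenotypes.csv` (raw measurements for every pedigree individual),
#' `pedigree.csv`, and `truth.csv` with the simulated true breeding
#' values.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the [simulate_study()] list with an added `paths`
#'   element.
#' @export
generate_study <- function(config, out_dir) {
  study <- simulate_study(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(ped = file.path(out_dir, "genotypes.ped"),
                map = file.path(out_dir, "genotypes.map"),
                phenotypes = file.path(out_dir, "phenotypes.csv"),
                pedigree = file.path(out_dir, "pedigree.csv"),
                truth = file.path(out_dir, "truth.csv"))
  write_ped_map(study$geno, paths$ped, paths$map)
  write.csv(as.data.frame(study$phenotypes), paths$phenotypes,
            row.names = FALSE)
  pd <- as.data.frame(study$pedigree)[, c("id", "sire", "dam")]
  pd$sire[is.na(pd$sire)] <- "0"
  pd$dam[is.na(pd$dam)] <- "0"
  write.csv(pd, paths$pedigree, row.names = FALSE)
  write.csv(study$truth, paths$truth, row.names = FALSE)
  study$paths <- paths
  invisible(study)
}
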