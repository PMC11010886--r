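test_that("Balding-Nichols line frequencies have the requested moments", {
  set.seed(3)
  base <- runif(10000, 0.1, 0.9)
  # near-zero drift: line frequencies converge to the base
  lf0 <- draw_line_frequencies(base, 1e-5, n_lines = 2, seed = 5)
  expect_lt(max(abs(lf0 - base)), 0.05)
  # fst = 0.1: across-line variance ~ fst * p(1-p) within 10%
  fst <- 0.1
  lf <- draw_line_frequencies(base, fst, n_lines = 40, seed = 6)
  v_emp <- apply(lf, 1, var)
  ratio <- mean(v_emp) / mean(fst * base * (1 - base))
  expect_lt(abs(ratio - 1), 0.1)
  expect_error(draw_line_frequencies(base, 0), "fst")
})

test_that("Hudson estimator recovers the drift FST between two lines", {
  set.seed(9)
  base <- runif(10000, 0.1, 0.9)
  lf <- draw_line_frequencies(base, 0.1, n_lines = 2, seed = 10)
  n <- 400
  g1 <- hwe_geno(n, lf[, 1]); g2 <- hwe_geno(n, lf[, 2])
  fst_hat <- hudson_fst(allele_freq(g1), allele_freq(g2), n, n)
  expect_lt(abs(fst_hat - 0.1), 0.02)
})

test_that("simulated pedigrees have line-contained discrete generations", {
  cfg <- test_config(seed = 2)
  ped <- simulate_pedigree(cfg)
  expect_s3_class(ped, "pedigree_table")     # passed the cycle check
  # every non-founder's parents are in the previous generation, same line
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  nf <- which(!is.na(ped$sire))
  expect_gt(length(nf), 0)
  expect_true(all(ped$generation[idx[ped$sire[nf]]] ==
                    ped$generation[nf] - 1))
  expect_true(all(ped$line[idx[ped$sire[nf]]] == ped$line[nf]))
  expect_true(all(ped$line[idx[ped$dam[nf]]] == ped$line[nf]))
  # 2 generations, 4 founders, 4 offspring: all offspring from founders
  cfg2 <- sim_config(n_per_line = c(small = 4, medium = 4, large = 4),
                     n_snps = 10, n_qtl = 2, n_generations = 2,
                     genotyped_fraction = 0.5, seed = 4)
  ped2 <- simulate_pedigree(cfg2)
  sm <- ped2[ped2$line == "small", ]
  expect_true(all(is.na(sm$sire[sm$generation == 1])))
  expect_true(all(sm$sire[sm$generation == 2] %in%
                    sm$id[sm$generation == 1]))
})

test_that("A matrix is block-diagonal across lines (no shared ancestry)", {
  cfg <- sim_config(n_per_line = c(small = 8, medium = 8, large = 8),
                    n_snps = 10, n_qtl = 2, n_generations = 3,
                    genotyped_fraction = 0.5, seed = 5)
  ped <- simulate_pedigree(cfg)
  A <- compute_A(ped)
  for (l1 in c("small", "medium")) {
    for (l2 in setdiff(c("medium", "large"), l1)) {
      block <- A[ped$id[ped$line == l1], ped$id[ped$line == l2]]
      expect_equal(max(abs(block)), 0)
    }
  }
})

test_that("gene dropping obeys Mendelian certainty and expectation", {
  # founder at frequency ~1 is homozygous for the coded allele
  ped <- as_pedigree(data.frame(id = c("f1", "f2", "k"),
                                sire = c("0", "0", "f1"),
                                dam = c("0", "0", "f2")))
  ped$line <- "small"
  lf <- matrix(0.999, 50, 1, dimnames = list(NULL, "small"))
  map <- data.frame(snp_id = paste0("s", 1:50), chromosome = "1",
                    position = 1:50 * 1000, allele_a = "A", allele_b = "G",
                    coded_allele = "G")
  g <- gene_drop(ped, lf, map, seed = 1)
  # parents (2,2) at nearly every locus -> offspring 2 wherever parents are 2
  both2 <- g$dosages["f1", ] == 2 & g$dosages["f2", ] == 2
  expect_true(all(g$dosages["k", both2] == 2))
  expect_gt(mean(g$dosages == 2), 0.95)

  # full sibs: mean genomic relationship ~ 0.5 (G centred at true freqs)
  set.seed(8)
  n_fam <- 120
  recs <- do.call(rbind, lapply(seq_len(n_fam), function(i) {
    data.frame(id = sprintf(c("s%03d", "d%03d", "c%03da", "c%03db"), i),
               sire = c("0", "0", sprintf("s%03d", i), sprintf("s%03d", i)),
               dam = c("0", "0", sprintf("d%03d", i), sprintf("d%03d", i)))
  }))
  ped2 <- as_pedigree(recs)
  ped2$line <- "small"
  m <- 2000
  p_true <- runif(m, 0.2, 0.8)
  lf2 <- matrix(p_true, m, 1, dimnames = list(NULL, "small"))
  map2 <- data.frame(snp_id = paste0("s", 1:m), chromosome = "1",
                     position = 1:m * 1000, allele_a = "A", allele_b = "G",
                     coded_allele = "G")
  g2 <- gene_drop(ped2, lf2, map2, seed = 9)
  G <- compute_G(g2, p = p_true)
  sib_rel <- vapply(seq_len(n_fam), function(i) {
    G[sprintf("c%03da", i), sprintf("c%03db", i)]
  }, numeric(1))
  expect_lt(abs(mean(sib_rel) - 0.5), 0.05)
})

test_that("phenotype simulation partitions variance as configured", {
  # h2 ~ 0.99: phenotype ~ TBV with slope 1
  cfg <- sim_config(n_per_line = c(small = 200, medium = 4, large = 4),
                    n_snps = 800, n_qtl = 100,
                    h2 = c(age100 = 0.99, bf100 = 0.99),
                    n_generations = 1, genotyped_fraction = 1,
                    missing_rate = 0, seed = 21)
  st <- simulate_study(cfg)
  ph <- apply_corrections(st$phenotypes)
  sm <- ph$line == "small"
  fit <- lm(ph$age100[sm] ~ st$truth$tbv_age100[sm] +
              (ph$sex[sm] == "male"))
  expect_lt(abs(coef(fit)[2] - 1), 0.1)
  expect_gt(summary(fit)$r.squared, 0.95)

  # zero sex effect: sex means equal within sampling error
  cfg0 <- test_config(seed = 22, sex_effect = c(age100 = 0, bf100 = 0))
  st0 <- simulate_study(cfg0)
  ph0 <- apply_corrections(st0$phenotypes)
  dd <- abs(mean(ph0$age100[ph0$sex == "male"]) -
              mean(ph0$age100[ph0$sex == "female"]))
  expect_lt(dd, 3 * sd(ph0$age100) / sqrt(nrow(ph0) / 4))

  # determinism
  st1 <- simulate_study(test_config(seed = 23))
  st2 <- simulate_study(test_config(seed = 23))
  expect_identical(st1$geno$dosages, st2$geno$dosages)
  expect_identical(st1$phenotypes, st2$phenotypes)
  expect_identical(st1$truth, st2$truth)
})

test_that("TBV bookkeeping and realized heritability match the config", {
  cfg <- test_config(seed = 1)
  st <- simulate_study(cfg)
  for (tr in c("age100", "bf100")) {
    q <- attr(st$truth, paste0("qtl_", tr))
    idx <- match(q$snp_id, st$map$snp_id)
    tbv <- drop(st$geno_all$dosages[, idx] %*% q$effect)
    expect_equal(unname(tbv), st$truth[[paste0("tbv_", tr)]])
    # realized h2 (sex-adjusted phenotypic variance) within 0.05
    ph <- apply_corrections(st$phenotypes)
    y <- ph[[tr]] - cfg$sex_effect[[tr]] * (ph$sex == "male")
    expect_lt(abs(var(tbv) / var(y) - cfg$h2[[tr]]), 0.05)
  }
})

test_that("pedigree and genomic relationships agree at high marker density", {
  cfg <- sim_config(n_per_line = c(small = 60, medium = 4, large = 4),
                    n_snps = 5000, n_qtl = 50, n_generations = 3,
                    genotyped_fraction = 0.75, missing_rate = 0, seed = 31)
  st <- simulate_study(cfg)
  ped <- st$pedigree[st$pedigree$line == "small", ]
  A <- compute_A(st$pedigree)[ped$id, ped$id]
  p_true <- st$line_freqs[, "small"]
  G <- compute_G(subset_geno(st$geno_all, individuals = ped$id), p = p_true)
  nf <- ped$id[!is.na(ped$sire)]
  diffs <- abs(A[nf, nf] - G[nf, nf])
  expect_lt(mean(diffs[upper.tri(diffs)]), 0.05)
})

test_that("generate_study writes a readable, consistent file set", {
  tmp <- withr::local_tempdir()
  cfg <- test_config(seed = 2)
  st <- generate_study(cfg, tmp)
  # 360 genotyped study animals in the reduced configuration
  g <- read_ped_map(st$paths$ped, st$paths$map)
  expect_equal(nrow(g$dosages), 360)
  expect_equal(g$dosages, st$geno$dosages)
  ph <- read_phenotypes(st$paths$phenotypes)
  expect_setequal(ph$id, st$pedigree$id)
  pd <- read_pedigree(st$paths$pedigree)
  expect_setequal(pd$id, st$pedigree$id)
  truth <- read.csv(st$paths$truth)
  expect_equal(nrow(truth), nrow(st$pedigree))

  # genotyped_fraction = 1: every pedigree member genotyped
  cfg1 <- sim_config(n_per_line = c(small = 10, medium = 10, large = 10),
                     n_snps = 50, n_qtl = 5, genotyped_fraction = 1,
                     missing_rate = 0, seed = 3)
  st1 <- simulate_study(cfg1)
  expect_setequal(rownames(st1$geno$dosages), st1$pedigree$id)
})
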