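test_that("BayesA shrinks to zero on null data and is seed-deterministic", {
  set.seed(41)
  M <- matrix(rbinom(50 * 30, 2, 0.5), 50, 30,
              dimnames = list(paste0("i", 1:50), paste0("s", 1:30)))
  st <- mcmc_settings(n_iter = 1500, burn_in = 300, thin = 3, seed = 5)
  fit <- fit_bayesA(rep(0, 50), matrix(1, 50, 1), M, st)
  expect_lt(max(abs(fit$effects)), 1e-3)
  expect_lt(max(abs(fit$gebv)), 0.05)

  dat <- sim_marker_data(80, 40, 0.5, 42)
  f1 <- fit_bayesA(dat$y, dat$X, dat$M, st)
  f2 <- fit_bayesA(dat$y, dat$X, dat$M, st)
  expect_identical(f1$effects, f2$effects)
  expect_identical(f1$sigma_e_chain, f2$sigma_e_chain)
  # residual-variance chain passes a basic stationarity sanity check
  ch <- f1$sigma_e_chain
  expect_false(all(diff(ch) > 0) || all(diff(ch) < 0))
  expect_gt(f1$ess_sigma_e, 10)
})

test_that("BayesA recovers dense marker effects on simulated data", {
  dat <- sim_marker_data(200, 100, 0.7, 43)
  st <- mcmc_settings(n_iter = 3000, burn_in = 600, thin = 3, seed = 7,
                      h2_prior = 0.7)
  fit <- fit_bayesA(dat$y, dat$X, dat$M, st)
  expect_gt(cor(fit$effects, dat$eff), 0.4)
  expect_gt(cor(fit$gebv, dat$tbv), 0.6)
})

test_that("BayesB with zero null fraction reproduces BayesA exactly", {
  dat <- sim_marker_data(100, 60, 0.5, 44)
  stA <- mcmc_settings(n_iter = 1500, burn_in = 300, thin = 3, seed = 9)
  stB <- stA; stB$pi_null <- 0
  fa <- fit_bayesA(dat$y, dat$X, dat$M, stA)
  fb <- fit_bayesB(dat$y, dat$X, dat$M, stB)
  # identical Gibbs chains, so far beyond the 0.98 GEBV-correlation bar
  expect_equal(fa$effects, fb$effects)
  expect_gt(cor(fa$gebv, fb$gebv), 0.98)
})

test_that("BayesB concentrates inclusion on true QTLs and respects the prior under the null", {
  dat <- sim_marker_data(300, 200, 0.6, 45, n_qtl = 5)
  st <- mcmc_settings(n_iter = 3000, burn_in = 600, thin = 3, seed = 11,
                      pi_null = 0.95)
  fit <- fit_bayesB(dat$y, dat$X, dat$M, st)
  expect_gt(mean(fit$incl_freq[dat$qtl]),
            mean(fit$incl_freq[-dat$qtl]))
  # null-effect data with pi_null = 0.999: almost nothing included
  set.seed(46)
  y0 <- rnorm(300)
  st0 <- mcmc_settings(n_iter = 1500, burn_in = 300, thin = 3, seed = 13,
                       pi_null = 0.999)
  fit0 <- fit_bayesB(y0, dat$X, dat$M, st0)
  expect_lt(mean(fit0$incl_freq), 0.05)
})

test_that("BayesC with full inclusion and fixed variances matches closed-form ridge", {
  dat <- sim_marker_data(100, 50, 0.5, 47)
  s2m <- 0.02; s2e <- 0.6
  st <- mcmc_settings(n_iter = 4000, burn_in = 800, thin = 2, seed = 15,
                      pi_null = 0, fix_sigma_e = s2e, fix_sigma_m = s2m)
  fit <- fit_bayesC(dat$y, dat$X, dat$M, st)
  Mc <- sweep(dat$M, 2, colMeans(dat$M))
  lam <- s2e / s2m
  X <- dat$X
  C <- rbind(cbind(crossprod(X), crossprod(X, Mc)),
             cbind(crossprod(Mc, X), crossprod(Mc) + diag(lam, 50)))
  sol <- solve(C, c(crossprod(X, dat$y), crossprod(Mc, dat$y)))
  ridge_gebv <- drop(Mc %*% sol[-(1:2)])
  expect_gt(cor(fit$gebv, ridge_gebv), 0.99)
})

test_that("a monomorphic marker's effect posterior falls back to its prior", {
  dat <- sim_marker_data(80, 30, 0.5, 48)
  dat$M[, 7] <- 2   # centred column becomes all zero
  st <- mcmc_settings(n_iter = 2000, burn_in = 400, thin = 2, seed = 17,
                      pi_null = 0.8)
  fit <- fit_bayesC(dat$y, dat$X, dat$M, st)
  # no likelihood contribution: inclusion frequency stays at the prior
  expect_lt(abs(fit$incl_freq[7] - 0.2), 0.05)
  expect_lt(abs(fit$effects[7]), 0.1)
})

test_that("GBLUP solves the mixed-model equations at a fixed variance ratio", {
  set.seed(51)
  n <- 30
  p0 <- runif(300, 0.2, 0.8)
  g <- hwe_geno(n, p0)
  G <- compute_G(g, p = p0)   # external frequencies keep G full rank
  y <- rnorm(n); X <- cbind(1, rbinom(n, 1, 0.5))
  fit <- fit_gblup(setNames(y, rownames(G)), X, G,
                   start_values = c(1, 2), fix_variances = TRUE)
  oracle <- naive_mme(y, X, G, lambda = 2)
  expect_lt(max(abs(fit$gebv - oracle$u)), 1e-8)
  expect_lt(max(abs(fit$b - oracle$b)), 1e-8)
  # singular (internally centred) G against the GLS/BLUP closed form
  G2 <- compute_G(g)
  fit2 <- fit_gblup(setNames(y, rownames(G)), X, G2,
                    start_values = c(1.3, 0.7), fix_variances = TRUE)
  oracle2 <- naive_blup(y, X, G2, 1.3, 0.7)
  expect_lt(max(abs(fit2$gebv - oracle2$u)), 1e-8)
})

test_that("GBLUP with identity G shrinks centred phenotypes exactly", {
  set.seed(52)
  n <- 120
  y <- rnorm(n)
  G <- diag(n); dimnames(G) <- list(paste0("i", 1:n), paste0("i", 1:n))
  s2g <- 0.7; s2e <- 0.3
  fit <- fit_gblup(setNames(y, rownames(G)), matrix(1, n, 1), G,
                   start_values = c(s2g, s2e), fix_variances = TRUE)
  expect_equal(unname(fit$gebv), (y - mean(y)) * s2g / (s2g + s2e),
               tolerance = 1e-8)
})

test_that("EM-REML log-likelihood increases monotonically and recovers h2", {
  set.seed(53)
  n <- 300; m <- 800
  p0 <- runif(m, 0.1, 0.9)
  g <- hwe_geno(n, p0)
  G <- compute_G(g)
  eff <- rnorm(m)
  tbv <- drop(sweep(g$dosages, 2, 2 * p0) %*% eff)
  tbv <- tbv * sqrt(0.5 / var(tbv))
  y <- 5 + tbv + rnorm(n, 0, sqrt(0.5))
  fit <- fit_gblup(setNames(y, rownames(G)), matrix(1, n, 1), G)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_lt(abs(fit$h2 - 0.5), 0.15)
  expect_true(fit$converged)
})

test_that("ssGBLUP degenerates to pedigree BLUP and to GBLUP at the limits", {
  ped <- as_pedigree(data.frame(id = c("a", "b", "c", "d", "e", "f"),
                                sire = c("0", "0", "a", "a", "c", "c"),
                                dam = c("0", "0", "b", "b", "d", "d")))
  A <- compute_A(ped)
  set.seed(54)
  y <- setNames(rnorm(6), ped$id)
  X <- matrix(1, 6, 1)
  # no genotyped individuals: H^-1 = A^-1, i.e. pedigree BLUP
  Hinv <- compute_H_inverse(A, A[0, 0], A[0, 0], character(0))
  f_ped <- fit_ssgblup(y, X, Hinv, start_values = c(1, 1),
                       fix_variances = TRUE)
  oracle <- naive_mme(unname(y), X, A, lambda = 1)
  expect_lt(max(abs(f_ped$gebv - oracle$u)), 1e-8)

  # everyone genotyped, blending and tuning off: matches GBLUP
  p0 <- runif(400, 0.2, 0.8)
  g <- hwe_geno(6, p0, ids = ped$id)
  G <- compute_G(g, p = p0)
  A22 <- extract_A22(A, ped$id)
  Gb <- tune_and_blend_G(G, A22, blend_weight = 0, tune = FALSE)
  Hinv2 <- compute_H_inverse(A, A22, Gb, ped$id)
  f_ss <- fit_ssgblup(y, X, Hinv2, start_values = c(1, 0.8),
                      fix_variances = TRUE)
  f_gb <- fit_gblup(y, X, G, start_values = c(1, 0.8), fix_variances = TRUE)
  expect_lt(max(abs(f_ss$gebv - f_gb$gebv)), 1e-6)
})

test_that("ssGBLUP propagates information to non-genotyped relatives", {
  cfg <- sim_config(n_per_line = c(small = 80, medium = 4, large = 4),
                    n_snps = 1000, n_qtl = 100, n_generations = 3,
                    genotyped_fraction = 0.5, missing_rate = 0, seed = 55)
  st <- simulate_study(cfg)
  ped <- st$pedigree[st$pedigree$line == "small", ]
  class(ped) <- c("pedigree_table", "data.frame")
  gen_ids <- ped$id[ped$genotyped]
  A <- compute_A(ped)
  A22 <- extract_A22(A, gen_ids)
  G <- compute_G(subset_geno(st$geno_all, individuals = gen_ids))
  Gb <- tune_and_blend_G(G, A22, 0.05)
  Hinv <- compute_H_inverse(A, A22, Gb, gen_ids)
  ph <- apply_corrections(st$phenotypes)
  y <- setNames(ph$age100, ph$id)[ped$id]
  X <- fixed_effects_design(setNames(ph$sex, ph$id)[ped$id])
  fit <- suppressWarnings(
    fit_ssgblup(y, X, Hinv, max_iter = 100, tol = 1e-5))
  anc <- ped$id[!ped$genotyped]
  tbv <- setNames(st$truth$tbv_age100, st$truth$id)
  expect_gt(cor(fit$gebv[anc], tbv[anc]), 0)
})

test_that("validation prediction is consistent with training GEBVs", {
  dat <- sim_marker_data(90, 40, 0.5, 56)
  st <- mcmc_settings(n_iter = 1500, burn_in = 300, thin = 3, seed = 19)
  fit <- fit_bayesA(dat$y, dat$X, dat$M, st)
  # a validation individual identical to a training one gets the same GEBV
  pred <- predict_validation(fit, dat$M[c(3, 10), , drop = FALSE])
  expect_equal(unname(pred), unname(fit$gebv[c(3, 10)]))
  # zero-effect fit predicts zero
  fit0 <- fit
  fit0$effects <- rep(0, length(fit0$effects))
  expect_equal(unname(predict_validation(fit0, dat$M[1:5, ])), rep(0, 5))
  # SNP-set mismatch is an error
  expect_error(predict_validation(fit, dat$M[, 1:10]), "SNP set")
})

test_that("marker-based and relationship-based GEBVs coincide (RR-BLUP / GBLUP)", {
  set.seed(57)
  n <- 60; m <- 150
  p0 <- runif(m, 0.2, 0.8)
  g <- hwe_geno(n, p0)
  M <- g$dosages
  y <- rnorm(n) + drop(scale(M[, 1:10], scale = FALSE) %*% rnorm(10, 0, .2))
  X <- matrix(1, n, 1)
  p_hat <- colMeans(M) / 2
  Mc <- sweep(M, 2, 2 * p_hat)
  cdenom <- 2 * sum(p_hat * (1 - p_hat))
  G <- compute_G(g)
  s2m <- 0.004; s2e <- 0.9
  s2g <- s2m * cdenom
  # marker route: joint ridge MME
  lam <- s2e / s2m
  C <- rbind(cbind(crossprod(X), crossprod(X, Mc)),
             cbind(crossprod(Mc, X), crossprod(Mc) + diag(lam, m)))
  sol <- solve(C, c(crossprod(X, y), crossprod(Mc, y)))
  gebv_marker <- drop(Mc %*% sol[-1])
  # relationship route
  fit <- fit_gblup(setNames(y, rownames(M)), X, G,
                   start_values = c(s2g, s2e), fix_variances = TRUE)
  expect_lt(max(abs(gebv_marker - fit$gebv)), 1e-6)
})
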