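#' MCMC settings for the Bayesian whole-genome regressions
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in discarded iterations (< `n_iter`).
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed RNG seed (samplers are deterministic given the seed).
#' @param df prior degrees of freedom `v` of the scaled-inverse-chi-square
#'   marker-variance prior.
#' @param h2_prior prior heritability used to derive the prior scale `S`
#'   (see Details).
#' @param pi_null prior null fraction: the prior probability that a marker
#'   has no effect. BayesA corresponds to `pi_null = 0`; in the BayesC
#'   convention where the mixture parameter is the inclusion probability,
#'   that probability is `1 - pi_null`.
#' @param fix_sigma_e,fix_sigma_m optional fixed values for the residual
#'   and (BayesC) common marker variance; `NULL` = sampled.
#'
#' @details The marker-variance prior scale is derived from `h2_prior` by
#' the standard rule `S = var(y) * h2_prior * (v - 2) /
#' (v * (1 - pi_null) * 2 * sum(p(1-p)))`, so that the implied genetic
#' variance matches `h2_prior * var(y)` a priori. The residual scale is
#' set analogously from `1 - h2_prior`.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 20000, burn_in = 4000, thin = 10,
                          seed = 42, df = 4.2, h2_prior = 0.5,
                          pi_null = 0.95,
                          fix_sigma_e = NULL, fix_sigma_m = NULL) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (pi_null < 0 || pi_null >= 1) stop("pi_null must be in [0, 1)")
  if (df <= 2) stop("prior df must exceed 2 (finite prior mean)")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 df = df, h2_prior = h2_prior, pi_null = pi_null,
                 fix_sigma_e = fix_sigma_e, fix_sigma_m = fix_sigma_m),
            class = "mcmc_settings")
}

#' Build the fixed-effects design matrix (overall mean + sex)
#'
#' @param sex character vector of `male`/`female`.
#' @return A full-column-rank design matrix with an intercept and, when
#'   both sexes are present, a male indicator.
#' @export
fixed_effects_design <- function(sex) {
  n <- length(sex)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (length(unique(sex)) > 1L) {
    X <- cbind(X, male = as.numeric(sex == "male"))
  }
  X
}

run_bayes <- function(y, X, M, model, settings) {
  if (any(!is.finite(y))) stop("non-finite phenotypes")
  stopifnot(nrow(X) == length(y), nrow(M) == length(y))
  model_code <- match(model, c("bayesA", "bayesB", "bayesC")) - 1L
  pi_null <- if (model == "bayesA") 0 else settings$pi_null

  p_train <- colMeans(M) / 2
  Mc <- sweep(M, 2, 2 * p_train, "-")
  sumpq <- 2 * sum(p_train * (1 - p_train))
  vy <- var(y)
  v <- settings$df
  S <- if (vy > 0 && sumpq > 0) {
    vy * settings$h2_prior * (v - 2) / (v * (1 - pi_null) * sumpq)
  } else 1e-8
  ve <- settings$df
  Se <- if (vy > 0) vy * (1 - settings$h2_prior) * (ve - 2) / ve else 1e-8

  set.seed(settings$seed)
  res <- gibbs_sampler_cpp(
    as.numeric(y), X, Mc, model_code,
    settings$n_iter, settings$burn_in, settings$thin,
    v, S, pi_null, ve, Se,
    !is.null(settings$fix_sigma_e),
    if (is.null(settings$fix_sigma_e)) 0 else settings$fix_sigma_e,
    !is.null(settings$fix_sigma_m),
    if (is.null(settings$fix_sigma_m)) 0 else settings$fix_sigma_m)

  gebv <- drop(Mc %*% res$g_mean)
  names(gebv) <- rownames(M)
  structure(list(model = model, gebv = gebv,
                 effects = drop(res$g_mean), b = drop(res$b_mean),
                 incl_freq = drop(res$incl_freq),
                 p_train = p_train, snp_ids = colnames(M),
                 sigma2_e = res$sigma_e_mean,
                 sigma2_marker = res$sigma_m_mean,
                 sigma_e_chain = drop(res$sigma_e_chain),
                 ess_sigma_e = ess(drop(res$sigma_e_chain)),
                 train_ids = rownames(M), settings = settings),
            class = "gebv_fit")
}

#' Fit BayesA by single-site Gibbs sampling
#'
#' All markers have an effect; each marker effect has its own variance
#' with a scaled-inverse-chi-square prior (df `v`, scale `S`), updated
#' from its full conditional `(S v + g_i^2) / chisq(v + 1)`. Genotypes are
#' centred by twice the training allele frequency; GEBV = centred dosages
#' times posterior-mean effects.
#'
#' @param y phenotype vector (corrected trait).
#' @param X fixed-effects design matrix (see [fixed_effects_design()]).
#' @param M dosage matrix (individuals x SNPs, training individuals).
#' @param settings an [mcmc_settings()].
#' @return A `gebv_fit` with GEBVs, posterior-mean marker effects,
#'   variance components and the kept residual-variance chain.
#' @export
fit_bayesA <- function(y, X, M, settings = mcmc_settings()) {
  run_bayes(y, X, M, "bayesA", settings)
}

#' Fit BayesB by single-site Gibbs sampling
#'
#' Point-mass mixture: a marker has no effect with prior probability
#' `pi_null`, otherwise its own scaled-inverse-chi-square variance as in
#' BayesA. The indicator is sampled from the marginal likelihood ratio
#' with the effect integrated out, then the effect is drawn conditional on
#' inclusion. `pi_null = 0` reduces BayesB to BayesA.
#'
#' @inheritParams fit_bayesA
#' @return A `gebv_fit`; `incl_freq` holds per-marker posterior inclusion
#'   frequencies.
#' @export
fit_bayesB <- function(y, X, M, settings = mcmc_settings()) {
  run_bayes(y, X, M, "bayesB", settings)
}

#' Fit BayesC by single-site Gibbs sampling
#'
#' Point-mass mixture with one common variance shared by all included
#' markers, sampled from its scaled-inverse-chi-square full conditional;
#' genotype codes are centred (-2p / 1-2p / 2-2p). The residual is
#' homoskedastic (identity weight matrix).
#'
#' @inheritParams fit_bayesA
#' @return A `gebv_fit`.
#' @export
fit_bayesC <- function(y, X, M, settings = mcmc_settings()) {
  run_bayes(y, X, M, "bayesC", settings)
}

#' Fit GBLUP with EM-REML variance components
#'
#' Mixed model `y = X b + g + e`, `g ~ N(0, G sigma2_g)`,
#' `e ~ N(0, I sigma2_e)`. Individuals with `NA` phenotypes are excluded
#' from the likelihood; their GEBVs are predicted through their genomic
#' relationships with the training animals
#' (`g_new = G[new, train] G[train, train]^-1 g_train`, computed on the
#' non-null eigenspace of G so a singular G is handled). Variance
#' components are estimated by EM-REML (monotone REML log-likelihood)
#' unless `fix_variances` is set.
#'
#' @param y phenotype vector over the rows of `G` (`NA` = not phenotyped /
#'   masked).
#' @param X fixed-effects design matrix over the rows of `G`.
#' @param G genomic relationship matrix from [compute_G()].
#' @param start_values optional `c(sigma2_g, sigma2_e)` starting (or
#'   fixed) values.
#' @param fix_variances if `TRUE`, skip REML and solve the mixed-model
#'   equations at `start_values`.
#' @param max_iter,tol EM-REML iteration cap and relative-change
#'   tolerance.
#' @return A `gebv_fit` with GEBVs for every row of `G`, variance
#'   components, heritability estimate and the REML log-likelihood trace.
#' @export
fit_gblup <- function(y, X, G, start_values = NULL, fix_variances = FALSE,
                      max_iter = 500, tol = 1e-6) {
  ids <- rownames(G)
  obs <- which(!is.na(y))
  if (length(obs) < 3) stop("need at least 3 phenotyped individuals")
  yo <- y[obs]
  Xo <- as.matrix(X)[obs, , drop = FALSE]
  Xo <- Xo[, qr(Xo)$pivot[seq_len(qr(Xo)$rank)], drop = FALSE]
  Gtt <- G[obs, obs, drop = FALSE]
  eg <- eigen((Gtt + t(Gtt)) / 2, symmetric = TRUE)
  r <- sum(eg$values > max(eg$values) * 1e-8)
  if (r == 0) stop("G has no positive eigenvalues on the training set")
  U <- eg$vectors[, seq_len(r), drop = FALSE]
  d <- eg$values[seq_len(r)]

  fit <- em_reml_engine(yo, Xo, Z = U, Kinv = diag(1 / d, r),
                        sigma2_u = start_values[1],
                        sigma2_e = start_values[2],
                        fix_variances = fix_variances,
                        max_iter = max_iter, tol = tol)
  if (!fix_variances && !fit$converged) {
    warning("EM-REML did not reach tolerance ", tol, " in ", max_iter,
            " iterations")
  }
  g_train <- drop(U %*% fit$uhat)
  wg <- drop(U %*% (fit$uhat / d))              # G_tt^- g_train
  gebv <- drop(G[, obs, drop = FALSE] %*% wg)
  gebv[obs] <- g_train
  names(gebv) <- ids
  structure(list(model = "gblup", gebv = gebv, b = fit$bhat,
                 sigma2_g = fit$sigma2_u, sigma2_e = fit$sigma2_e,
                 h2 = fit$sigma2_u / (fit$sigma2_u + fit$sigma2_e),
                 loglik_trace = fit$loglik_trace,
                 iterations = fit$iterations, converged = fit$converged,
                 train_ids = ids[obs]),
            class = "gebv_fit")
}

#' Fit single-step GBLUP (ssGBLUP) with EM-REML variance components
#'
#' Mixed model over every pedigree individual,
#' `y = X b + Z a + e`, `a ~ N(0, H sigma2_a)`, with the pedigree-genomic
#' H matrix supplied through its inverse (see [compute_H_inverse()]).
#' `Z` is the incidence of phenotyped individuals; genotyped and
#' non-genotyped animals are evaluated jointly, so phenotype information
#' flows through the pedigree.
#'
#' @param y phenotype vector over the rows of `H_inverse` (`NA` = not
#'   phenotyped / masked).
#' @param X fixed-effects design matrix over the rows of `H_inverse`.
#' @param H_inverse inverse relationship matrix over all pedigree ids.
#' @param start_values,fix_variances,max_iter,tol as in [fit_gblup()].
#' @return A `gebv_fit` with breeding values for every pedigree
#'   individual.
#' @export
fit_ssgblup <- function(y, X, H_inverse, start_values = NULL,
                        fix_variances = FALSE, max_iter = 500, tol = 1e-6) {
  ids <- rownames(H_inverse)
  q <- nrow(H_inverse)
  obs <- which(!is.na(y))
  if (length(obs) < 3) stop("need at least 3 phenotyped individuals")
  yo <- y[obs]
  Xo <- as.matrix(X)[obs, , drop = FALSE]
  Xo <- Xo[, qr(Xo)$pivot[seq_len(qr(Xo)$rank)], drop = FALSE]
  Z <- matrix(0, length(obs), q)
  Z[cbind(seq_along(obs), obs)] <- 1

  fit <- em_reml_engine(yo, Xo, Z = Z, Kinv = (H_inverse + t(H_inverse)) / 2,
                        sigma2_u = start_values[1],
                        sigma2_e = start_values[2],
                        fix_variances = fix_variances,
                        max_iter = max_iter, tol = tol)
  if (!fix_variances && !fit$converged) {
    warning("EM-REML did not reach tolerance ", tol, " in ", max_iter,
            " iterations")
  }
  gebv <- fit$uhat
  names(gebv) <- ids
  structure(list(model = "ssgblup", gebv = gebv, b = fit$bhat,
                 sigma2_a = fit$sigma2_u, sigma2_e = fit$sigma2_e,
                 h2 = fit$sigma2_u / (fit$sigma2_u + fit$sigma2_e),
                 loglik_trace = fit$loglik_trace,
                 iterations = fit$iterations, converged = fit$converged,
                 train_ids = ids[obs]),
            class = "gebv_fit")
}

#' Predict GEBVs for validation individuals
#'
#' Marker models compute centred-dosage-times-effects products using the
#' training-set centring frequencies over the training SNP set; matrix
#' models (GBLUP/ssGBLUP) read the breeding values already estimated for
#' the requested ids.
#'
#' @param fit a `gebv_fit`.
#' @param newdata for marker models, a [geno_matrix()] or dosage matrix
#'   over the training SNP set; for matrix models, a character vector of
#'   ids present in the fitted relationship structure.
#' @return Named numeric vector of GEBVs.
#' @export
predict_validation <- function(fit, newdata) {
  stopifnot(inherits(fit, "gebv_fit"))
  if (fit$model %in% c("bayesA", "bayesB", "bayesC")) {
    M <- if (inherits(newdata, "geno_matrix")) newdata$dosages else
      as.matrix(newdata)
    if (!identical(colnames(M), fit$snp_ids)) {
      stop("validation SNP set does not match the training SNP set")
    }
    if (anyNA(M)) stop("validation dosages must be complete")
    Mc <- sweep(M, 2, 2 * fit$p_train, "-")
    out <- drop(Mc %*% fit$effects)
    names(out) <- rownames(M)
    out
  } else {
    missing_ids <- setdiff(newdata, names(fit$gebv))
    if (length(missing_ids)) {
      stop("ids absent from the fitted relationship structure: ",
           paste(head(missing_ids, 5), collapse = ", "))
    }
    fit$gebv[newdata]
  }
}

#' @export
print.gebv_fit <- function(x, ...) {
  cat("gebv_fit:", x$model, "-", length(x$gebv), "breeding values\n")
  invisible(x)
}

# effective sample size from the initial-positive-sequence of
# autocorrelations
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(as.numeric(n))
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  neg <- which(ac < 0)
  if (length(neg)) ac <- ac[seq_len(neg[1] - 1)]
  max(1, n / (1 + 2 * sum(ac)))
}
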