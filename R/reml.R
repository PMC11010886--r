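# EM-REML engine for the single-random-effect mixed model
#   y = X b + Z u + e,  u ~ N(0, K sigma2_u),  e ~ N(0, I sigma2_e)
# parameterised by Kinv (positive definite). Uses Henderson's EM-REML
# updates on the mixed-model equations:
#   sigma2_u <- (u' Kinv u + sigma2_e * tr(Kinv Cuu)) / q
#   sigma2_e <- (y'y - b'X'y - u'Z'y) / (n - p)
# where Cuu is the random-effect block of the inverse MME coefficient
# matrix. After absorbing the fixed effects, Cuu = (S + alpha Kinv)^-1
# with S = Z' Px Z and alpha = sigma2_e / sigma2_u, so a single
# generalised eigendecomposition makes every iteration O(q^2).

em_reml_engine <- function(y, X, Z, Kinv,
                           sigma2_u = NULL, sigma2_e = NULL,
                           fix_variances = FALSE,
                           max_iter = 500, tol = 1e-6) {
  n <- length(y)
  X <- as.matrix(X); Z <- as.matrix(Z)
  p <- ncol(X); q <- ncol(Z)
  if (any(!is.finite(y))) stop("non-finite phenotypes")
  if (n < p) stop("fewer observations than fixed-effect columns")
  vy <- var(y)
  if (is.null(sigma2_u)) sigma2_u <- max(vy / 2, 1e-8)
  if (is.null(sigma2_e)) sigma2_e <- max(vy / 2, 1e-8)

  XtX <- crossprod(X)
  XtXinv <- solve(XtX)
  Xty <- crossprod(X, y)
  ZtX <- crossprod(Z, X)
  Zty <- crossprod(Z, y)
  yty <- sum(y^2)
  S <- crossprod(Z) - ZtX %*% XtXinv %*% t(ZtX)
  Zpy <- Zty - ZtX %*% XtXinv %*% Xty

  Ru <- chol(Kinv)                      # Kinv = Ru' Ru
  Lh <- backsolve(Ru, diag(q))          # Ru^-1
  Ms <- crossprod(t(crossprod(Lh, S)), Lh)  # Lh' S Lh
  Ms <- (Ms + t(Ms)) / 2
  es <- eigen(Ms, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  Tmat <- Lh %*% es$vectors
  w <- drop(crossprod(Tmat, Zpy))

  # pieces for the REML log-likelihood
  Mz <- crossprod(t(crossprod(Lh, crossprod(Z))), Lh)
  Mz <- (Mz + t(Mz)) / 2
  ez <- eigen(Mz, symmetric = TRUE)
  mu <- pmax(ez$values, 0)
  Fz <- crossprod(ez$vectors, crossprod(Lh, ZtX))
  logdetK <- -2 * sum(log(diag(Ru)))

  solve_at <- function(alpha) {
    dinv <- 1 / (lam + alpha)
    a <- w * dinv                       # uhat in the rotated basis
    uhat <- drop(Tmat %*% a)
    bhat <- drop(XtXinv %*% (Xty - t(ZtX) %*% uhat))
    sse <- yty - sum(bhat * Xty) - sum(uhat * Zty)
    list(uhat = uhat, bhat = bhat, sse = max(sse, 1e-12),
         uKu = sum(a^2),                # u' Kinv u
         dinv = dinv)
  }

  reml_ll <- function(s2u, s2e, sse) {
    gamma <- s2u / s2e
    logdetV <- n * log(s2e) + sum(log1p(gamma * mu))
    wts <- 1 / (1 / gamma + mu)
    XVX <- (XtX - crossprod(Fz, Fz * wts)) / s2e
    ld_xvx <- determinant(XVX, logarithm = TRUE)$modulus
    -0.5 * (logdetV + as.numeric(ld_xvx) + sse / s2e)
  }

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    alpha <- sigma2_e / sigma2_u
    sol <- solve_at(alpha)
    ll_trace <- c(ll_trace, reml_ll(sigma2_u, sigma2_e, sol$sse))
    if (fix_variances) { converged <- TRUE; break }
    trKC <- sum(sol$dinv)
    s2u_new <- (sol$uKu + sigma2_e * trKC) / q
    s2e_new <- sol$sse / (n - p)
    delta <- max(abs(s2u_new - sigma2_u) / (sigma2_u + 1e-12),
                 abs(s2e_new - sigma2_e) / (sigma2_e + 1e-12))
    sigma2_u <- max(s2u_new, 1e-12)
    sigma2_e <- max(s2e_new, 1e-12)
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # final solve and log-likelihood at the converged parameters
  alpha <- sigma2_e / sigma2_u
  sol <- solve_at(alpha)
  ll_trace <- c(ll_trace, reml_ll(sigma2_u, sigma2_e, sol$sse))

  list(bhat = sol$bhat, uhat = sol$uhat,
       sigma2_u = sigma2_u, sigma2_e = sigma2_e,
       loglik_trace = ll_trace, iterations = iter, converged = converged)
}
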