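# Profiled-likelihood engine for the variance-component models underlying
# the spline and differential-expression fits.
#
# Model: y = X beta + sum_g Z_g u_g + e, with u_g ~ N(0, sigma2 * gamma_g I)
# independent across blocks and e ~ N(0, sigma2 I). For fixed variance
# ratios gamma the GLS beta and sigma2 have closed forms, so only the
# log-ratios theta_g = log(gamma_g) are optimised numerically. All matrix
# work is done on q x q cross-products (q = total random-effect columns)
# via the Woodbury identity, so the cost per likelihood evaluation is
# O(q^3) regardless of the number of observations.

# Cross-products shared by every theta evaluation.
lmm_precompute <- function(y, X, Zlist) {
  Z <- if (length(Zlist)) do.call(cbind, Zlist) else
    matrix(0, length(y), 0)
  blocks <- rep.int(seq_along(Zlist),
                    vapply(Zlist, ncol, integer(1)))
  list(n = length(y), p = ncol(X),
       X = X, Z = Z, blocks = blocks,
       XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y * y),
       ZtZ = crossprod(Z), ZtX = crossprod(Z, X), Zty = crossprod(Z, y))
}

# Profiled quantities at a given theta (log variance ratios, one per block).
# reml switches the variance-denominator and adds the fixed-effect
# determinant term. Returns NULL when the system is numerically singular.
lmm_profile <- function(pc, theta, reml = FALSE) {
  gamma <- exp(theta)
  sg <- sqrt(gamma)[pc$blocks]          # per-column scale
  q <- length(sg)
  if (q > 0) {
    M <- pc$ZtZ * tcrossprod(sg)        # sg_i sg_j ZtZ_ij
    diag(M) <- diag(M) + 1
    L <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(L)) return(NULL)
    logdetV <- 2 * sum(log(diag(L)))
    Bt <- pc$ZtX * sg                   # row-scaled
    ct <- pc$Zty * sg
    MiB <- backsolve(L, forwardsolve(t(L), Bt))
    Mic <- backsolve(L, forwardsolve(t(L), ct))
    XtViX <- pc$XtX - crossprod(Bt, MiB)
    XtViy <- pc$Xty - crossprod(Bt, Mic)
    ytViy <- pc$yty - sum(ct * Mic)
  } else {
    logdetV <- 0
    XtViX <- pc$XtX; XtViy <- pc$Xty; ytViy <- pc$yty
  }
  R <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  beta <- backsolve(R, forwardsolve(t(R), XtViy))
  rss <- max(ytViy - sum(beta * XtViy), 1e-300)
  n <- pc$n; p <- pc$p
  if (reml) {
    sigma2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) + logdetV +
                    2 * sum(log(diag(R))))
  } else {
    sigma2 <- rss / n
    ll <- -0.5 * (n * (log(2 * pi * sigma2) + 1) + logdetV)
  }
  list(beta = drop(beta), sigma2 = sigma2, loglik = ll,
       gamma = gamma, theta = theta)
}

# BLUPs of the random effects at the fitted (theta, beta).
lmm_blup <- function(pc, fit) {
  if (!length(pc$blocks)) return(numeric(0))
  gamma_col <- fit$gamma[pc$blocks]
  sg <- sqrt(gamma_col)
  d <- drop(pc$Zty - pc$ZtX %*% fit$beta)    # Z'r
  M <- pc$ZtZ * tcrossprod(sg)
  diag(M) <- diag(M) + 1
  ZtVir <- d - (pc$ZtZ %*% (sg * solve(M, sg * d)))
  drop(gamma_col * ZtVir)
}

#' Fit a Gaussian linear mixed model with independent random-effect blocks
#'
#' Workhorse behind the spline and differential-expression fits: estimates
#' `y = X beta + sum_g Z_g u_g + e` where each block of random
#' coefficients `u_g` is i.i.d. `N(0, sigma2 * gamma_g)`. The variance
#' ratios `gamma_g` are profiled out of the (restricted) likelihood and
#' optimised on the log scale; `beta`, `sigma2` and the BLUPs `u_g` follow
#' in closed form. With no random blocks this reduces to ordinary least
#' squares.
#'
#' @param y numeric response vector (no missing values).
#' @param X fixed-effect design matrix.
#' @param Zlist list of random-effect design matrices, one per block.
#' @param method `"ML"` or `"REML"`. Likelihood-ratio comparisons across
#'   models with different fixed effects require `"ML"`.
#' @param theta_init optional starting log variance ratios.
#' @param maxit maximum optimiser iterations.
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @return list with `beta`, `sigma2`, `gamma` (variance ratios),
#'   `var_components` (`sigma2 * gamma`), `u` (list of BLUP vectors per
#'   block), `loglik`, `method`, `converged`, `n`.
#' @export
fit_lmm <- function(y, X, Zlist = list(), method = c("ML", "REML"),
                    theta_init = NULL, maxit = 200, reltol = 1e-8) {
  method <- match.arg(method)
  reml <- method == "REML"
  keep <- !is.na(y)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  Zlist <- lapply(Zlist, function(Z) Z[keep, , drop = FALSE])
  pc <- lmm_precompute(y, X, Zlist)
  G <- length(Zlist)
  converged <- TRUE
  if (G == 0) {
    fit <- lmm_profile(pc, numeric(0), reml = reml)
    if (is.null(fit)) stop("singular fixed-effect design")
  } else {
    blocks <- as.integer(pc$blocks)
    obj <- function(th)
      lmm_negdev_cpp(th, pc$ZtZ, pc$ZtX, drop(pc$Zty), pc$XtX,
                     drop(pc$Xty), pc$yty, pc$n, blocks, reml)
    th0 <- if (is.null(theta_init)) rep(0, G) else theta_init
    if (G == 1) {
      op <- stats::optimize(obj, interval = c(-30, 15), tol = 1e-7)
      th_hat <- op$minimum
    } else {
      op <- stats::optim(th0, obj, method = "Nelder-Mead",
                         control = list(maxit = maxit * 10,
                                        reltol = reltol))
      th_hat <- op$par
      converged <- op$convergence == 0
    }
    th_hat <- pmin(pmax(th_hat, -30), 15)
    fit <- lmm_profile(pc, th_hat, reml = reml)
    if (is.null(fit)) stop("variance-component fit is singular")
  }
  u_all <- lmm_blup(pc, fit)
  u <- split(u_all, pc$blocks)
  names(u) <- names(Zlist)[as.integer(names(u))]
  names(fit$gamma) <- names(Zlist)
  list(beta = fit$beta, sigma2 = fit$sigma2, gamma = fit$gamma,
       var_components = fit$sigma2 * fit$gamma, u = u,
       loglik = fit$loglik, method = method, converged = converged,
       n = pc$n)
}

# Gaussian OLS fit with its ML log-likelihood; the class-0 model.
ols_fit <- function(y, X) {
  keep <- !is.na(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  qr_ <- qr(X)
  beta <- qr.coef(qr_, y)
  res <- y - drop(X %*% beta)
  n <- length(y)
  sigma2 <- sum(res^2) / n
  ll <- -0.5 * n * (log(2 * pi * max(sigma2, 1e-300)) + 1)
  list(beta = beta, sigma2 = sigma2, gamma = numeric(0),
       var_components = numeric(0), u = list(), loglik = ll,
       method = "ML", converged = TRUE, n = n)
}
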