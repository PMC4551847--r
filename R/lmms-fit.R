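# The four nested models fitted per molecule, in increasing complexity:
#   0 LIN  - straight line, ordinary least squares
#   1 SPL  - penalized truncated-line spline: intercept + slope fixed,
#            spline coefficients u_k i.i.d. N(0, sigma_u2) random effects
#   2 SSI  - SPL plus a subject-specific random intercept U_i
#   3 SSIS - SPL plus subject-specific random intercept and slope
#            (independent, diagonal covariance)
lmms_class_names <- c("0" = "LIN", "1" = "SPL", "2" = "SSI", "3" = "SSIS")

lmms_designs <- function(profile, basis) {
  t <- profile$time
  X <- cbind(intercept = 1, time = t)
  Zs <- truncated_line_basis(t, basis)
  subj <- factor(profile$subject)
  # per-subject indicator columns (model.matrix chokes on 1 level)
  Zi <- 1 * outer(as.character(subj), levels(subj), "==")
  list(X = X, Zspline = Zs, Zint = Zi, Zslope = Zi * t,
       subjects = levels(subj))
}

#' Fit one LMMS model class to a molecule profile
#'
#' @param profile data.frame with columns `subject`, `time`, `value` (one
#'   row per observation; missing values allowed and dropped).
#' @param model_class 0 (LIN), 1 (SPL), 2 (SSI) or 3 (SSIS); see Details.
#' @param basis a [spline_basis()]; defaults to one built from the
#'   profile's observed times.
#'
#' @details The spline coefficients are random effects, which makes the
#' spline penalized: the implied ridge penalty is
#' `lambda = sigma_eps2 / sigma_u2`, chosen by the data through the
#' likelihood rather than by a tuning parameter. Variance components are
#' reported under REML; the marginal log-likelihood stored in `loglik_ml`
#' is always the ML value so that likelihood-ratio comparisons between
#' classes (and later between fixed-effect structures) are valid.
#'
#' @return object of class `lmms_fit`: list with `model_class`, `beta0`,
#'   `beta1`, `u` (predicted spline coefficients, length 0 for LIN),
#'   `subject_effects`, `sigma_eps2`, `sigma_u2`, `sigma_U2`,
#'   `sigma_a02`, `sigma_a12` (NA where not in the model), `loglik_ml`,
#'   `basis`, `n_obs`, `converged`.
#' @export
fit_lmms <- function(profile, model_class, basis = NULL) {
  stopifnot(model_class %in% 0:3)
  profile <- profile[!is.na(profile$value), , drop = FALSE]
  if (is.null(basis)) basis <- spline_basis(profile$time)
  d <- lmms_designs(profile, basis)
  y <- profile$value
  n_subj <- length(d$subjects)
  if (model_class >= 2 && n_subj < 2)
    stop("model class ", model_class, " needs at least 2 subjects")
  if (model_class == 3) {
    multi <- table(profile$subject) >= 2
    if (sum(multi) < 2)
      stop("model class 3 needs >= 2 observations for >= 2 subjects")
  }
  Zlist <- switch(as.character(model_class),
    "0" = list(),
    "1" = list(u = d$Zspline),
    "2" = list(u = d$Zspline, U = d$Zint),
    "3" = list(u = d$Zspline, a0 = d$Zint, a1 = d$Zslope))
  if (model_class == 0) {
    ml <- ols_fit(y, d$X)
    rep_fit <- ml
  } else {
    ml <- fit_lmm(y, d$X, Zlist, method = "ML")
    if (model_class >= 2) {
      # second start from the nested class's optimum with the new block
      # switched off; keeps the ML log-likelihoods monotone across the
      # nested classes even when the cold start stalls
      prev <- fit_lmms(profile, model_class - 1L, basis)
      g <- function(x) log(max(x, 1e-12))
      th_warm <- if (model_class == 2)
        c(g(prev$sigma_u2 / prev$sigma_eps2), -20)
      else
        c(g(prev$sigma_u2 / prev$sigma_eps2),
          g(prev$sigma_U2 / prev$sigma_eps2), -20)
      ml2 <- fit_lmm(y, d$X, Zlist, method = "ML", theta_init = th_warm)
      if (ml2$loglik > ml$loglik) ml <- ml2
    }
    rep_fit <- fit_lmm(y, d$X, Zlist, method = "REML",
                       theta_init = log(pmax(ml$gamma, 1e-12)))
  }
  vc <- rep_fit$var_components
  subj_eff <- NULL
  if (model_class == 2) subj_eff <- rep_fit$u$U
  if (model_class == 3)
    subj_eff <- cbind(intercept = rep_fit$u$a0, slope = rep_fit$u$a1)
  structure(list(
    model_class = model_class,
    beta0 = unname(rep_fit$beta[1]), beta1 = unname(rep_fit$beta[2]),
    u = if (model_class >= 1) unname(rep_fit$u$u) else numeric(0),
    subject_effects = subj_eff,
    sigma_eps2 = rep_fit$sigma2,
    sigma_u2 = if (model_class >= 1) unname(vc["u"]) else NA_real_,
    sigma_U2 = if (model_class == 2) unname(vc["U"]) else NA_real_,
    sigma_a02 = if (model_class == 3) unname(vc["a0"]) else NA_real_,
    sigma_a12 = if (model_class == 3) unname(vc["a1"]) else NA_real_,
    loglik_ml = ml$loglik, basis = basis, n_obs = length(y),
    converged = ml$converged && rep_fit$converged),
    class = "lmms_fit")
}

#' @export
print.lmms_fit <- function(x, ...) {
  cat("LMMS fit, model class", x$model_class,
      paste0("(", lmms_class_names[as.character(x$model_class)], ")"), "\n")
  cat(sprintf("  beta0 = %.4g, beta1 = %.4g, %d knot(s), n = %d\n",
              x$beta0, x$beta1, length(x$basis$knots), x$n_obs))
  cat(sprintf("  loglik (ML) = %.4f, sigma_eps2 = %.4g\n",
              x$loglik_ml, x$sigma_eps2))
  invisible(x)
}

#' Population curve of a fitted LMMS model
#'
#' Evaluates `f(t) = beta0 + beta1 t + sum_k u_k (t - kappa_k)_+`, the
#' fitted mean trajectory: continuous, piecewise linear with breakpoints
#' only at the knots, and linear beyond the last knot.
#'
#' @param fit an `lmms_fit`.
#' @param times numeric vector of evaluation times.
#' @return numeric vector `f(times)`.
#' @export
predict_curve <- function(fit, times) {
  f <- fit$beta0 + fit$beta1 * times
  if (length(fit$u))
    f <- f + drop(truncated_line_basis(times, fit$basis) %*% fit$u)
  f
}

#' Derivative of the fitted population curve
#'
#' The rate-of-change profile: `f'(t) = beta1 + sum_k u_k [t >= kappa_k]`,
#' piecewise constant between knots. For a LIN fit the derivative is the
#' constant slope estimate.
#'
#' @inheritParams predict_curve
#' @return numeric vector `f'(times)`.
#' @export
lmms_derivative <- function(fit, times) {
  fp <- rep(fit$beta1, length(times))
  if (length(fit$u)) {
    ind <- outer(times, fit$basis$knots, ">=")
    fp <- fp + drop(ind %*% fit$u)
  }
  fp
}

#' Serial model selection for one molecule
#'
#' Fits the four nested models in order and promotes to the more complex
#' model only when a likelihood-ratio test (ML log-likelihoods,
#' chi-squared reference with 1 degree of freedom per step, no boundary
#' correction) rejects the simpler one at level `alpha`. Selection stops
#' at the first non-promotion. A non-converged candidate is treated as a
#' non-promotion with a warning.
#'
#' @param profile data.frame with `subject`, `time`, `value`.
#' @param basis a [spline_basis()] (default built from the profile).
#' @param alpha promotion level of each likelihood-ratio test.
#' @return list with `fit` (the chosen `lmms_fit`) and `steps`
#'   (data.frame of attempted promotions: null/alt class, statistic, df,
#'   p-value, promoted flag).
#' @export
select_lmms <- function(profile, basis = NULL, alpha = 0.05) {
  profile <- profile[!is.na(profile$value), , drop = FALSE]
  if (is.null(basis)) basis <- spline_basis(profile$time)
  n_subj <- length(unique(profile$subject))
  multi <- sum(table(profile$subject) >= 2)
  max_class <- if (n_subj < 2) 1 else if (multi < 2) 2 else 3

  current <- fit_lmms(profile, 0, basis)
  steps <- NULL
  for (cand in seq_len(max_class)) {
    alt <- tryCatch(fit_lmms(profile, cand, basis),
                    error = function(e) NULL)
    if (is.null(alt) || !alt$converged) {
      warning("class ", cand, " fit unavailable or not converged; ",
              "keeping class ", current$model_class)
      break
    }
    stat <- max(0, 2 * (alt$loglik_ml - current$loglik_ml))
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    promoted <- p < alpha
    steps <- rbind(steps, data.frame(
      null_class = current$model_class, alt_class = cand,
      statistic = stat, df = 1, p = p, promoted = promoted))
    if (!promoted) break
    current <- alt
  }
  list(fit = current, steps = steps)
}

#' Model every molecule of an experiment
#'
#' Runs [select_lmms()] per molecule and evaluates the selected population
#' curves (and optionally their derivatives) on a common time grid.
#'
#' @param exp a [tc_experiment()] (a filtered experiment is recommended).
#' @param alpha promotion level for the serial selection.
#' @param grid evaluation times; defaults to the sorted distinct observed
#'   times.
#' @param derivative also return the derivative matrix.
#' @return list with `curves` (molecules x grid matrix), `derivatives`
#'   (or `NULL`), `selection` (per-molecule results), `class_counts`
#'   (table over LIN/SPL/SSI/SSIS), and `failed` (molecule ids whose fit
#'   failed, dropped from the output).
#' @export
lmms_model_all <- function(exp, alpha = 0.05, grid = NULL,
                           derivative = FALSE) {
  if (is.null(grid)) grid <- sort(unique(exp$time))
  basis <- spline_basis(exp$time)
  ids <- rownames(exp$values)
  sel <- vector("list", length(ids)); names(sel) <- ids
  failed <- character(0)
  for (m in ids) {
    pr <- data.frame(subject = exp$subject, time = exp$time,
                     value = exp$values[m, ])
    res <- tryCatch(select_lmms(pr, basis, alpha), error = function(e) e)
    if (inherits(res, "error")) {
      warning("model selection failed for ", m, ": ",
              conditionMessage(res))
      failed <- c(failed, m)
    } else sel[[m]] <- res
  }
  ok <- setdiff(ids, failed)
  curves <- t(vapply(ok, function(m) predict_curve(sel[[m]]$fit, grid),
                     numeric(length(grid))))
  derivs <- if (derivative)
    t(vapply(ok, function(m) lmms_derivative(sel[[m]]$fit, grid),
             numeric(length(grid))))
  colnames(curves) <- grid
  if (!is.null(derivs)) colnames(derivs) <- grid
  classes <- vapply(sel[ok], function(s) s$fit$model_class, numeric(1))
  counts <- table(factor(lmms_class_names[as.character(classes)],
                         levels = lmms_class_names))
  list(curves = curves, derivatives = derivs, selection = sel[ok],
       class_counts = counts, grid = grid, failed = failed)
}
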