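# Trajectory-level differential expression: nested-model likelihood ratio
# tests built on the spline mixed model. The full mean curve for a subject
# in group r is
#   f_r(t) = beta0 + beta1 t + sum_k u_k (t-kappa_k)_+
#            + alpha_0r + alpha_1r t + sum_k v_rk (t-kappa_k)_+   (r >= 2)
# with the common spline u and the per-group offset splines v_r penalized
# (random coefficients), plus an optional subject-level random structure.

#' @keywords internal
de_random_structure <- function(profile, random) {
  if (random == "auto") {
    multi <- any(table(profile$subject) >= 2)
    random <- if (multi) "intercept" else "none"
  }
  random
}

# Design matrices for one effect's full and null models.
# spline_df = "random": penalized spline blocks count 1 df (their variance
# component) in the LRT; "fixed": spline columns enter the fixed design
# and count K df per block.
de_designs <- function(profile, effect, basis,
                       random = c("auto", "none", "intercept",
                                  "intercept_slope"),
                       spline_df = c("random", "fixed")) {
  random <- de_random_structure(profile, match.arg(random))
  spline_df <- match.arg(spline_df)
  t <- profile$time
  Zs <- truncated_line_basis(t, basis)
  K <- ncol(Zs)
  subj <- factor(profile$subject)
  Zi <- stats::model.matrix(~ subj - 1)
  subj_blocks <- switch(random,
    none = list(),
    intercept = list(U = Zi),
    intercept_slope = list(a0 = Zi, a1 = Zi * t))

  grp <- NULL
  if (effect %in% c("group", "interaction")) {
    if (is.null(profile$group)) stop("effect '", effect,
                                     "' needs a group annotation")
    grp <- factor(profile$group)
    R <- nlevels(grp)
    if (R < 2) stop("effect '", effect, "' needs >= 2 groups")
    Hi <- stats::model.matrix(~ grp)[, -1, drop = FALSE]  # indicators r>=2
  }

  spl_fixed <- spline_df == "fixed"
  with_spline <- function(X, Zlist, mat, name) {
    if (spl_fixed) list(X = cbind(X, mat), Zlist = Zlist)
    else list(X = X, Zlist = c(Zlist, stats::setNames(list(mat), name)))
  }

  if (effect == "time") {
    full <- with_spline(cbind(intercept = 1, time = t), subj_blocks,
                        Zs, "u")
    null <- list(X = cbind(intercept = rep(1, length(t))),
                 Zlist = subj_blocks)
    df <- if (spl_fixed) 1 + K else 2
  } else if (effect == "group") {
    # literal reading: the common curve keeps its spline part but neither
    # model carries the linear slope (alpha_1 = 0 and beta1 = 0)
    base <- with_spline(cbind(intercept = rep(1, length(t))),
                        subj_blocks, Zs, "u")
    full <- list(X = cbind(base$X, Hi), Zlist = base$Zlist)
    null <- base
    df <- ncol(Hi)
  } else if (effect == "interaction") {
    base_X <- cbind(intercept = 1, time = t, Hi)
    base <- with_spline(base_X, subj_blocks, Zs, "u")
    vmats <- lapply(seq_len(ncol(Hi)), function(r) Zs * Hi[, r])
    names(vmats) <- paste0("v", seq_len(ncol(Hi)) + 1)
    full <- list(X = cbind(base$X, Hi * t), Zlist = base$Zlist)
    if (spl_fixed) full$X <- cbind(full$X, do.call(cbind, vmats))
    else full$Zlist <- c(full$Zlist, vmats)
    null <- base
    df <- if (spl_fixed) ncol(Hi) * (1 + K) else ncol(Hi) * 2
  } else stop("unknown effect: ", effect)
  list(full = full, null = null, df = df, random = random)
}

de_fit <- function(y, des, theta_init = NULL) {
  if (length(des$Zlist) == 0) ols_fit(y, des$X)
  else fit_lmm(y, des$X, des$Zlist, method = "ML",
               theta_init = theta_init)
}

# warm start for the full model: shared random blocks start at the null
# fit's variance ratios, blocks unique to the full model start near zero.
# At that point the full model's likelihood already matches the null's
# (its extra structure is switched off), so the optimiser can only gain
# and the nesting inequality loglik_full >= loglik_null is preserved.
de_full_start <- function(des, f_null) {
  nm <- names(des$full$Zlist)
  if (!length(nm)) return(NULL)
  th <- rep(-8, length(nm))
  null_nm <- names(des$null$Zlist)
  for (i in seq_along(null_nm)) {
    j <- match(null_nm[i], nm)
    if (!is.na(j)) th[j] <- log(max(f_null$gamma[i], 1e-12))
  }
  th
}

#' Likelihood-ratio test of one effect on one molecule profile
#'
#' Compares the full and null mean structures for the requested effect
#' (see the module header) by an ML likelihood-ratio test against a
#' chi-squared reference:
#' \describe{
#'   \item{time}{full: common curve; null: intercept only. df = 2 by
#'     default (slope + the spline variance component).}
#'   \item{group}{full: common spline + group intercept offsets; null:
#'     without the offsets. No linear slope in either model. df = R - 1.}
#'   \item{interaction}{full: group-specific intercepts, slopes and
#'     offset splines; null: common curve shape + group intercepts only.
#'     df = (R - 1) * 2 by default.}
#' }
#' Any subject-level random structure is shared by both models.
#'
#' @param profile data.frame with `subject`, `time`, `value` and (for
#'   group/interaction) `group`.
#' @param effect `"time"`, `"group"` or `"interaction"`.
#' @param basis a [spline_basis()]; default built from the profile times.
#' @param random subject-level random structure: `"auto"` (intercept when
#'   any subject has repeated measures, else none), `"none"`,
#'   `"intercept"`, `"intercept_slope"`.
#' @param spline_df `"random"` (penalized spline blocks count 1 df) or
#'   `"fixed"` (spline coefficients as fixed effects, K df per block).
#' @return one-row data.frame: `effect`, `statistic`, `df`, `p`,
#'   `loglik_full`, `loglik_null`, `converged`.
#' @export
lmmsde_test <- function(profile, effect = c("time", "group", "interaction"),
                        basis = NULL, random = "auto",
                        spline_df = "random") {
  effect <- match.arg(effect)
  profile <- profile[!is.na(profile$value), , drop = FALSE]
  if (effect == "time" && length(unique(profile$time)) < 2)
    stop("time test needs >= 2 distinct times")
  if (is.null(basis)) basis <- spline_basis(profile$time)
  des <- de_designs(profile, effect, basis, random, spline_df)
  f_null <- tryCatch(de_fit(profile$value, des$null),
                     error = function(e) NULL)
  f_full <- if (is.null(f_null)) NULL else
    tryCatch(de_fit(profile$value, des$full,
                    theta_init = de_full_start(des, f_null)),
             error = function(e) NULL)
  if (!is.null(f_full) && !is.null(f_null) &&
      f_full$loglik < f_null$loglik) {
    # rare optimiser miss: restart the full model from the boundary point
    # where its extra blocks are switched off and it nests the null
    th <- de_full_start(des, f_null)
    th[!(names(des$full$Zlist) %in% names(des$null$Zlist))] <- -30
    f_full <- tryCatch(de_fit(profile$value, des$full, theta_init = th),
                       error = function(e) f_full)
  }
  ok <- !is.null(f_full) && !is.null(f_null) &&
    f_full$converged && f_null$converged
  if (ok) {
    stat <- max(0, 2 * (f_full$loglik - f_null$loglik))
    p <- stats::pchisq(stat, df = des$df, lower.tail = FALSE)
  } else {
    stat <- NA_real_; p <- NA_real_
  }
  data.frame(effect = effect, statistic = stat, df = des$df, p = p,
             loglik_full = if (is.null(f_full)) NA_real_ else f_full$loglik,
             loglik_null = if (is.null(f_null)) NA_real_ else f_null$loglik,
             converged = ok, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment with missing values
#'
#' Step-up FDR adjustment; missing p-values (e.g. non-converged fits) are
#' excluded from the procedure and reinserted as missing, so they do not
#' count towards the number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return adjusted p-values, same length and order, capped at 1.
#' @export
adjust_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Differential-expression pipeline over an experiment
#'
#' Runs the requested effect tests for every molecule, with an optional
#' preceding filtering stage (the per-condition rule of
#' [filter_experiment()]), and adjusts p-values within each effect across
#' molecules by Benjamini-Hochberg.
#'
#' @param exp a [tc_experiment()]; a group annotation is required when
#'   `group` or `interaction` effects are requested.
#' @param effects subset of `c("time", "group", "interaction")`.
#' @param random,spline_df passed to [lmmsde_test()].
#' @param alpha_fdr significance level on the adjusted p-values.
#' @param filter_first run [filter_experiment()] (per-group when grouped)
#'   before testing.
#' @param seed seed for the filtering classification.
#' @return data.frame with one row per molecule x effect: `molecule`,
#'   `effect`, `statistic`, `df`, `p`, `adj_p`, `significant`.
#' @export
lmmsde <- function(exp, effects = c("time", "group", "interaction"),
                   random = "auto", spline_df = "random",
                   alpha_fdr = 0.05, filter_first = FALSE, seed = 1L) {
  effects <- unique(effects)
  if (length(effects) == 0) stop("no effects requested")
  bad <- setdiff(effects, c("time", "group", "interaction"))
  if (length(bad)) stop("unknown effect(s): ", paste(bad, collapse = ", "))
  if (any(effects %in% c("group", "interaction")) && is.null(exp$group))
    stop("group/interaction effects need a group annotation")
  if (filter_first)
    exp <- filter_experiment(exp, per_group = !is.null(exp$group),
                             seed = seed)$experiment
  basis <- spline_basis(exp$time)
  ids <- rownames(exp$values)
  res <- lapply(effects, function(eff) {
    rows <- lapply(ids, function(m) {
      pr <- data.frame(subject = exp$subject, time = exp$time,
                       value = exp$values[m, ],
                       stringsAsFactors = FALSE)
      if (!is.null(exp$group)) pr$group <- exp$group
      cbind(molecule = m,
            lmmsde_test(pr, eff, basis, random, spline_df))
    })
    tab <- do.call(rbind, rows)
    tab$adj_p <- adjust_bh(tab$p)
    tab$significant <- !is.na(tab$adj_p) & tab$adj_p < alpha_fdr
    tab
  })
  do.call(rbind, res)
}
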