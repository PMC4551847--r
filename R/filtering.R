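#' Per-molecule filter statistics
#'
#' For each molecule computes three standard deviations and the two filter
#' ratios used to separate informative from noise-only profiles:
#' \itemize{
#'   \item `sT`: mean over time points of the SD across subjects measured
#'     at that time;
#'   \item `sI`: mean over subjects of the SD across that subject's time
#'     points;
#'   \item `sM`: the overall SD of the profile;
#'   \item `RT = sT / sM` and `RI = 1 - sI / sM`.
#' }
#' A profile of pure noise has per-time SDs close to the overall SD, so
#' `RT` near 1; a genuine signal over time inflates `sM` relative to `sT`,
#' pushing `RT` below 1. Missing cells are excluded from every sum with
#' denominators reduced accordingly; a time point or subject with fewer
#' than 2 present values contributes nothing to the respective mean, and a
#' constant profile (`sM` = 0) is flagged `degenerate`.
#'
#' @param exp a [tc_experiment()]; subjects are expected to share the same
#'   sampled time points, with at least three present values per time point
#'   for the ratios to be well behaved.
#' @return data.frame with one row per molecule: `molecule`, `sT`, `sI`,
#'   `sM`, `RT`, `RI`, `missing_fraction`, and a `label` column initialised
#'   to `"unclassified"`, `"degenerate"` or `"excluded_missing"` (the last
#'   only set later by [filter_experiment()]).
#' @export
filter_statistics <- function(exp) {
  v <- exp$values
  time_f <- factor(exp$time)
  subj_f <- factor(exp$subject)

  # mean of SDs taken within the columns of each index set, skipping NA
  # and skipping sets with < 2 present values
  mean_group_sd <- function(y, f) {
    sds <- tapply(y, f, function(z) {
      z <- z[!is.na(z)]
      if (length(z) < 2) NA_real_ else stats::sd(z)
    })
    if (all(is.na(sds))) NA_real_ else mean(sds, na.rm = TRUE)
  }

  n_mol <- nrow(v)
  sT <- sI <- sM <- rep(NA_real_, n_mol)
  for (m in seq_len(n_mol)) {
    y <- v[m, ]
    pres <- y[!is.na(y)]
    if (length(pres) >= 2) sM[m] <- stats::sd(pres)
    sT[m] <- mean_group_sd(y, time_f)
    sI[m] <- mean_group_sd(y, subj_f)
  }
  miss <- rowMeans(is.na(v))
  defined <- !is.na(sM) & sM > 0 & !is.na(sT) & !is.na(sI)
  RT <- ifelse(defined, sT / sM, NA_real_)
  RI <- ifelse(defined, 1 - sI / sM, NA_real_)
  data.frame(
    molecule = rownames(v), sT = sT, sI = sI, sM = sM,
    RT = RT, RI = RI, missing_fraction = miss,
    label = ifelse(defined, "unclassified", "degenerate"),
    stringsAsFactors = FALSE)
}

#' Classify molecules as informative vs non-informative
#'
#' Fits a 2-component model-based (Gaussian mixture) clustering on the
#' `(RT, RI)` points via \pkg{mclust} and labels the component with the
#' larger mean `RT` (ties broken by larger mean `RI`) as non-informative:
#' noise-only profiles sit near `RT` = 1 while signal pushes `RT` down.
#' Molecules with undefined ratios keep their `degenerate` label (a
#' constant profile carries no temporal signal and is treated as
#' non-informative downstream).
#'
#' @param stats data.frame from [filter_statistics()].
#' @param seed integer seed for the (stochastic) mixture initialisation.
#' @return `stats` with `label` filled in as `"informative"` /
#'   `"noninformative"` (or untouched degenerate rows). If the mixture fit
#'   fails or collapses (e.g. all points identical) all classifiable
#'   molecules are labelled informative and a warning is raised.
#' @export
classify_informative <- function(stats, seed = 1L) {
  ok <- stats$label == "unclassified" & !is.na(stats$RT) & !is.na(stats$RI)
  pts <- cbind(RT = stats$RT[ok], RI = stats$RI[ok])
  fallback <- function(msg) {
    warning("model-based classification fell back to all-informative: ", msg)
    stats$label[ok] <- "informative"
    stats
  }
  if (sum(ok) < 2) return(fallback("fewer than 2 classifiable molecules"))
  if (all(abs(pts[, 1] - pts[1, 1]) < 1e-12) &&
      all(abs(pts[, 2] - pts[1, 2]) < 1e-12))
    return(fallback("all filter-ratio points identical"))
  fit <- withr_seed(seed, {
    tryCatch(
      suppressWarnings(mclust::Mclust(pts, G = 2, verbose = FALSE)),
      error = function(e) NULL)
  })
  if (is.null(fit) || is.null(fit$classification) ||
      length(unique(fit$classification)) < 2)
    return(fallback("mixture fit degenerate or not converged"))
  mu <- fit$parameters$mean  # 2 x G
  noisy <- which.max(mu["RT", ] + 1e-9 * mu["RI", ])
  stats$label[ok] <- ifelse(fit$classification == noisy,
                            "noninformative", "informative")
  stats
}

# evaluate expr with a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Filter a time-course experiment
#'
#' Applies the full quality-control stage: molecules with more than
#' `max_missing` missing cells are removed first; the remaining molecules
#' are classified by [filter_statistics()] + [classify_informative()].
#' With `per_group = TRUE` (on a grouped experiment) statistics and
#' classification are run within each group level and a molecule is
#' removed only if found non-informative in every level, so profiles that
#' are flat within one condition but differ between conditions survive.
#'
#' @param exp a [tc_experiment()].
#' @param per_group classify within each group level (requires a group
#'   annotation) rather than pooled.
#' @param max_missing maximal tolerated missing fraction (default 0.5).
#' @param seed seed passed to [classify_informative()].
#' @return list with `experiment` (the retained molecules) and `report`
#'   (per-molecule statistics for all input molecules, including the
#'   removed ones; for `per_group` runs one block per level plus a
#'   `retained` summary column in `combined`).
#' @export
filter_experiment <- function(exp, per_group = FALSE, max_missing = 0.5,
                              seed = 1L) {
  miss <- rowMeans(is.na(exp$values))
  too_missing <- miss > max_missing

  classify_one <- function(e) {
    st <- filter_statistics(e)
    st$label[too_missing] <- "excluded_missing"
    classify_informative(st, seed = seed)
  }

  if (per_group) {
    if (is.null(exp$group)) stop("per_group filtering needs a group annotation")
    parts <- split_by_group(exp)
    reports <- lapply(parts, classify_one)
    lab_mat <- vapply(reports, function(r) r$label, character(nrow(exp$values)))
    informative_any <- apply(lab_mat, 1, function(l) any(l == "informative"))
    retained <- !too_missing & informative_any
    combined <- reports[[1]][, "molecule", drop = FALSE]
    combined$retained <- retained
    report <- list(per_group = reports, combined = combined)
  } else {
    report <- classify_one(exp)
    retained <- !too_missing & report$label == "informative"
  }
  if (!any(retained))
    warning("no molecules survive filtering; returning an empty experiment")
  list(experiment = exp[retained, ], report = report)
}
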