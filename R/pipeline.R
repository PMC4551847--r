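# Composite workflow: filter -> model -> (de | cluster), each stage
# reading the previous stage's tab-separated artifacts, so stages can
# also be run independently from the command line.

#' Assemble a run configuration
#'
#' @param matrix_path,sheet_path input expression matrix and sample sheet
#'   (tab-separated; see [read_experiment()]).
#' @param out_dir output directory (created if absent).
#' @param stages ordered subset of `c("filter", "model", "de",
#'   "cluster")`.
#' @param per_group,max_missing filtering parameters.
#' @param alpha serial-selection promotion level.
#' @param effects,random,fdr differential-expression parameters.
#' @param algorithms,k_range,metric clustering parameters.
#' @param derivative cluster the derivative profiles instead of the
#'   fitted curves.
#' @param seed master seed; per-stage seeds derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(matrix_path, sheet_path, out_dir = ".",
                       stages = c("filter", "model", "de"),
                       per_group = TRUE, max_missing = 0.5,
                       alpha = 0.05, effects = "time", random = "auto",
                       fdr = 0.05,
                       algorithms = c("hierarchical", "kmeans", "pam",
                                      "som", "model_based"),
                       k_range = 2:9, metric = "euclidean",
                       derivative = FALSE, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the configured pipeline
#'
#' Executes the configured stages in order. Every stage writes its
#' tab-separated artifacts into `out_dir`; the resolved configuration is
#' written alongside them (`run_config.txt`). With a fixed seed the
#' output files are byte-identical across invocations.
#'
#' @param config a [run_config()].
#' @return invisibly, a character vector of the written file paths.
#' @export
run_pipeline <- function(config) {
  cf <- config
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  exp <- read_experiment(cf$matrix_path, cf$sheet_path, quiet = TRUE)
  dump <- vapply(cf, function(v) paste(format(v), collapse = ","),
                 character(1))
  paths <- c(paths, write_tsv(
    data.frame(parameter = names(dump), value = unname(dump)),
    file.path(cf$out_dir, "run_config.txt")))

  if ("filter" %in% cf$stages) {
    fl <- filter_experiment(exp,
                            per_group = cf$per_group &&
                              !is.null(exp$group),
                            max_missing = cf$max_missing, seed = cf$seed)
    rep_df <- if (is.data.frame(fl$report)) fl$report else {
      merged <- fl$report$per_group[[1]]
      merged$retained <- fl$report$combined$retained
      merged
    }
    paths <- c(paths,
               write_tsv(rep_df, file.path(cf$out_dir,
                                           "filter_report.tsv")))
    exp <- fl$experiment
    write_experiment(exp, file.path(cf$out_dir, "filtered_matrix.tsv"),
                     file.path(cf$out_dir, "filtered_samples.tsv"))
    paths <- c(paths, file.path(cf$out_dir, "filtered_matrix.tsv"),
               file.path(cf$out_dir, "filtered_samples.tsv"))
  }

  modelled <- NULL
  if ("model" %in% cf$stages || "cluster" %in% cf$stages) {
    modelled <- lmms_model_all(exp, alpha = cf$alpha,
                               derivative = cf$derivative)
    curves_df <- data.frame(molecule = rownames(modelled$curves),
                            modelled$curves, check.names = FALSE)
    paths <- c(paths, write_tsv(curves_df,
                                file.path(cf$out_dir, "curves.tsv")))
    cls <- vapply(modelled$selection,
                  function(s) s$fit$model_class, numeric(1))
    paths <- c(paths, write_tsv(
      data.frame(molecule = names(cls), model_class = cls,
                 model = lmms_class_names[as.character(cls)]),
      file.path(cf$out_dir, "model_report.tsv")))
    if (cf$derivative) {
      dv <- data.frame(molecule = rownames(modelled$derivatives),
                       modelled$derivatives, check.names = FALSE)
      paths <- c(paths, write_tsv(dv, file.path(cf$out_dir,
                                                "derivatives.tsv")))
    }
  }

  if ("de" %in% cf$stages) {
    de <- lmmsde(exp, effects = cf$effects, random = cf$random,
                 alpha_fdr = cf$fdr, seed = cf$seed)
    paths <- c(paths, write_tsv(de, file.path(cf$out_dir, "de.tsv")))
  }

  if ("cluster" %in% cf$stages) {
    mat <- if (cf$derivative) modelled$derivatives else modelled$curves
    sel <- select_clustering(mat, algorithms = cf$algorithms,
                             k_range = cf$k_range, metric = cf$metric,
                             seed = cf$seed)
    paths <- c(paths, write_tsv(
      data.frame(molecule = names(sel$best$assignments),
                 cluster = sel$best$assignments,
                 algorithm = sel$best$algorithm, k = sel$best$k),
      file.path(cf$out_dir, "cluster_assignments.tsv")))
    paths <- c(paths, write_tsv(sel$grid,
                                file.path(cf$out_dir, "cluster_dunn.tsv")))
  }
  invisible(paths)
}
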