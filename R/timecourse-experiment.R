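#' Time-course expression experiment
#'
#' Container for a molecules x samples matrix of (log-scale) intensities
#' together with per-sample annotations: the subject (or biological
#' replicate) each sample was taken from, the sampling time, and an
#' optional treatment group. Missing values are stored as `NA` and are
#' skipped by every downstream computation.
#'
#' @param values numeric matrix, molecules in rows, samples in columns.
#'   Row names are molecule ids, column names sample ids (generated when
#'   absent).
#' @param subject character vector, one subject id per sample.
#' @param time numeric vector of finite sampling times, one per sample.
#' @param group optional factor/character vector of group labels, one per
#'   sample; must be constant within subject.
#'
#' @return An object of class `tc_experiment`: a list with elements
#'   `values`, `subject`, `time`, `group` (or `NULL`).
#' @export
#' @examples
#' vals <- matrix(rnorm(12), 2, 6,
#'                dimnames = list(c("m1", "m2"), paste0("s", 1:6)))
#' exp <- tc_experiment(vals,
#'                      subject = rep(c("a", "b"), each = 3),
#'                      time = rep(c(0, 1, 2), 2))
tc_experiment <- function(values, subject, time, group = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("molecule_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  subject <- as.character(subject)
  time <- as.numeric(time)
  if (!is.null(group)) group <- as.character(group)
  obj <- structure(
    list(values = values, subject = subject, time = time, group = group),
    class = "tc_experiment")
  validate_tc_experiment(obj)
  obj
}

validate_tc_experiment <- function(x) {
  v <- x$values
  ns <- ncol(v)
  if (length(x$subject) != ns)
    stop("subject annotation length (", length(x$subject),
         ") does not match sample count (", ns, ")")
  if (length(x$time) != ns)
    stop("time annotation length (", length(x$time),
         ") does not match sample count (", ns, ")")
  if (anyNA(x$subject)) stop("every sample needs a subject")
  if (any(!is.finite(x$time)))
    stop("every sample needs a finite numeric time")
  if (length(unique(x$time)) < 2)
    stop("need at least 2 distinct time values")
  if (anyDuplicated(rownames(v)))
    stop("duplicated molecule ids: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  if (!is.null(x$group)) {
    if (length(x$group) != ns)
      stop("group annotation length does not match sample count")
    if (anyNA(x$group)) stop("group labels must not be missing")
    bad <- tapply(x$group, x$subject, function(g) length(unique(g)) > 1)
    if (any(bad))
      stop("group label not constant within subject(s): ",
           paste(names(bad)[bad], collapse = ", "))
  }
  invisible(x)
}

#' @export
print.tc_experiment <- function(x, ...) {
  cat("Time-course experiment:", nrow(x$values), "molecules x",
      ncol(x$values), "samples\n")
  cat("  subjects:", length(unique(x$subject)),
      " distinct times:", length(unique(x$time)), "\n")
  if (!is.null(x$group))
    cat("  groups:", paste(names(table(x$group)), table(x$group),
                           sep = "=", collapse = ", "), "\n")
  nm <- sum(is.na(x$values))
  if (nm > 0)
    cat("  missing cells:", nm,
        sprintf("(%.1f%%)", 100 * nm / length(x$values)), "\n")
  invisible(x)
}

#' @export
dim.tc_experiment <- function(x) dim(x$values)

#' Number of molecules / samples
#' @param x a `tc_experiment`
#' @return integer count
#' @export
n_molecules <- function(x) nrow(x$values)

#' @rdname n_molecules
#' @export
n_samples <- function(x) ncol(x$values)

#' Subset an experiment
#'
#' @param x a `tc_experiment`
#' @param i molecule index (row) selector
#' @param j sample index (column) selector
#' @param ... ignored
#' @return a `tc_experiment` restricted to the selected molecules/samples
#' @export
`[.tc_experiment` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  tc_experiment(v, subject = x$subject[j], time = x$time[j],
                group = if (!is.null(x$group)) x$group[j])
}

#' Read a time-course experiment from delimited text
#'
#' Reads an expression matrix (first column molecule ids, header of sample
#' ids) and a sample sheet with columns `sample`, `subject`, `time` and
#' optionally `group`. Empty cells and the literal "NA" denote missing
#' values. Columns of the matrix are reordered to match the sheet.
#'
#' @param matrix_path path to the delimited expression matrix.
#' @param sheet_path path to the delimited sample sheet.
#' @param sep field separator; default `"\t"`, use `","` for CSV.
#' @param quiet suppress the note about how many missing cells were read.
#' @return a [tc_experiment()]
#' @export
read_experiment <- function(matrix_path, sheet_path, sep = "\t",
                            quiet = FALSE) {
  mat <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           row.names = 1, check.names = FALSE,
                           na.strings = c("NA", ""),
                           stringsAsFactors = FALSE)
  sheet <- utils::read.table(sheet_path, header = TRUE, sep = sep,
                             na.strings = c("NA", ""),
                             check.names = FALSE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  need <- c("sample", "subject", "time")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns sample/subject/time; found: ",
         paste(names(sheet), collapse = ", "))
  only_mat <- setdiff(colnames(mat), sheet$sample)
  only_sheet <- setdiff(sheet$sample, colnames(mat))
  if (length(only_mat) || length(only_sheet))
    stop("matrix columns and sample sheet disagree.",
         if (length(only_mat))
           paste0(" Only in matrix: ", paste(only_mat, collapse = ", "), "."),
         if (length(only_sheet))
           paste0(" Only in sheet: ", paste(only_sheet, collapse = ", "), "."))
  mat <- as.matrix(mat[, sheet$sample, drop = FALSE])
  tt <- suppressWarnings(as.numeric(sheet$time))
  if (anyNA(tt))
    stop("non-numeric time value(s) in sample sheet: ",
         paste(unique(sheet$time[is.na(tt)]), collapse = ", "))
  if (!quiet && anyNA(mat))
    message(sum(is.na(mat)), " missing cell(s) read from ", matrix_path)
  tc_experiment(mat, subject = sheet$subject, time = tt,
                group = if ("group" %in% names(sheet)) sheet$group)
}

#' Write a time-course experiment as delimited text
#'
#' Inverse of [read_experiment()]: writes the matrix and the sample sheet
#' in the layout that function reads back, with `NA` for missing cells.
#'
#' @param exp a `tc_experiment`
#' @param matrix_path,sheet_path output paths.
#' @param sep field separator.
#' @return invisibly, the two paths.
#' @export
write_experiment <- function(exp, matrix_path, sheet_path, sep = "\t") {
  df <- data.frame(molecule = rownames(exp$values), exp$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  sheet <- data.frame(sample = colnames(exp$values), subject = exp$subject,
                      time = exp$time, stringsAsFactors = FALSE)
  if (!is.null(exp$group)) sheet$group <- exp$group
  utils::write.table(sheet, sheet_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, sheet_path))
}

#' Split an experiment by group level
#'
#' Partitions the samples by the group annotation; the molecule set is
#' unchanged in every part. Used by the per-condition filtering rule.
#'
#' @param exp a grouped `tc_experiment`
#' @return named list of `tc_experiment`, one per group level
#' @export
split_by_group <- function(exp) {
  if (is.null(exp$group))
    stop("experiment has no group annotation")
  lv <- unique(exp$group)
  out <- lapply(lv, function(g) exp[, exp$group == g])
  names(out) <- lv
  out
}
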