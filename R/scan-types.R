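# Domain types for parcellated BOLD data: parent scans, task annotations,
# and the task scans extracted from them.
#
# Conventions (fixed, also documented in the CLI help): matrices are oriented
# rows = regions, columns = time points; time indices are 0-based and task
# intervals are half-open [start, end).

#' Construct a task annotation
#'
#' An ordered list of labeled, non-overlapping, half-open time intervals
#' `[start, end)` over the columns of a parent scan. Cue and rest periods are
#' simply absent from the list: only the task blocks to be extracted are
#' annotated.
#'
#' @param start integer vector of 0-based interval starts.
#' @param end integer vector of exclusive interval ends.
#' @param label character vector of non-empty task labels.
#' @return An object of class `task_annotation`: a data.frame with columns
#'   `start`, `end`, `label`, sorted by `start`.
#' @examples
#' task_annotation(c(0, 5), c(5, 10), c("A", "B"))
#' @export
task_annotation <- function(start, end, label) {
  if (length(start) != length(end) || length(start) != length(label)) {
    abort("start, end and label must have equal length")
  }
  if (length(start) == 0) abort("annotation must contain at least one interval")
  start <- as.integer(start)
  end <- as.integer(end)
  label <- as.character(label)
  if (any(is.na(start)) || any(is.na(end))) abort("interval bounds must be integers")
  if (any(!nzchar(label)) || any(is.na(label))) abort("interval labels must be non-empty")
  if (any(start < 0)) abort("interval starts must be >= 0")
  if (any(end - start < 2)) abort("each interval must have length >= 2")
  o <- order(start)
  start <- start[o]; end <- end[o]; label <- label[o]
  if (length(start) > 1 && any(start[-1] < end[-length(end)])) {
    i <- which(start[-1] < end[-length(end)])[1]
    abort("annotation intervals overlap: [%d,%d) '%s' and [%d,%d) '%s'",
          start[i], end[i], label[i], start[i + 1], end[i + 1], label[i + 1])
  }
  structure(data.frame(start = start, end = end, label = label,
                       stringsAsFactors = FALSE),
            class = c("task_annotation", "data.frame"))
}

#' Construct a parent scan
#'
#' A parent scan is one full fMRI session: an `m x n` matrix of
#' region-averaged BOLD values (rows = regions, columns = time points)
#' together with a subject identifier and a [task_annotation()] marking the
#' task blocks it contains.
#'
#' @param data numeric matrix, regions x time.
#' @param subject_id subject identifier (string).
#' @param annotation a [task_annotation()] whose intervals lie within
#'   `[0, ncol(data))`.
#' @param session_id session identifier, e.g. `"test"` or `"retest"`.
#' @return An object of class `parent_scan`.
#' @examples
#' ann <- task_annotation(c(0, 5), c(5, 10), c("A", "B"))
#' ps <- parent_scan(matrix(rnorm(30), 3, 10), "sub-01", ann)
#' @export
parent_scan <- function(data, subject_id, annotation, session_id = "test") {
  check_finite_matrix(data, "parent scan data")
  if (nrow(data) < 2 || ncol(data) < 2) {
    abort("parent scan must have at least 2 regions and 2 time points")
  }
  if (!inherits(annotation, "task_annotation")) {
    abort("annotation must be a task_annotation")
  }
  if (any(annotation$end > ncol(data))) {
    bad <- annotation[annotation$end > ncol(data), ][1, ]
    abort("interval [%d,%d) '%s' exceeds scan length n=%d",
          bad$start, bad$end, bad$label, ncol(data))
  }
  structure(list(data = data,
                 subject_id = as.character(subject_id),
                 annotation = annotation,
                 session_id = as.character(session_id)),
            class = "parent_scan")
}

#' @export
print.parent_scan <- function(x, ...) {
  cat(sprintf("<parent_scan> subject %s (%s): %d regions x %d time points, %d task intervals\n",
              x$subject_id, x$session_id, nrow(x$data), ncol(x$data),
              nrow(x$annotation)))
  invisible(x)
}

#' @export
print.task_scan <- function(x, ...) {
  cat(sprintf("<task_scan> subject %s, task '%s': %d regions x %d time points\n",
              x$subject_id, x$task_label, nrow(x$data), ncol(x$data)))
  invisible(x)
}

new_task_scan <- function(data, subject_id, task_label, parent_ref) {
  structure(list(data = data, subject_id = subject_id,
                 task_label = task_label, parent_ref = parent_ref),
            class = "task_scan")
}

#' Extract task scans from a parent scan
#'
#' Slices out one task scan per annotated interval, in annotation order. Each
#' task scan is the contiguous column block `[start, end)` of the parent's
#' matrix and carries the parent's subject id plus the interval label.
#'
#' Extraction is the *last* pipeline step: when de-individualization is
#' wanted, the parent is de-meaned and whitened first (see
#' [preprocess_parent()]) and task scans are extracted from the whitened
#' matrix.
#'
#' @param parent a [parent_scan()] (or [preprocess_parent()] output).
#' @return list of `task_scan` objects, one per interval.
#' @examples
#' ann <- task_annotation(c(0, 5), c(5, 10), c("A", "B"))
#' ps <- parent_scan(matrix(rnorm(30), 3, 10), "sub-01", ann)
#' length(extract_task_scans(ps))
#' @export
extract_task_scans <- function(parent) {
  if (!inherits(parent, c("parent_scan", "whitened_parent_scan"))) {
    abort("parent must be a parent_scan or whitened_parent_scan")
  }
  ann <- parent$annotation
  if (is.null(ann) || nrow(ann) == 0) abort("no task intervals in annotation")
  ref <- paste0(parent$subject_id, ":", parent$session_id)
  lapply(seq_len(nrow(ann)), function(i) {
    cols <- (ann$start[i] + 1L):ann$end[i]   # 0-based half-open -> R columns
    new_task_scan(parent$data[, cols, drop = FALSE], parent$subject_id,
                  ann$label[i], ref)
  })
}
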