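# Text I/O: parcellated time-series matrices (TSV/CSV), JSON task
# annotations, and TSV distance matrices. All formats are plain text so
# fixtures and outputs stay portable and diffable.

detect_sep <- function(line) if (grepl("\t", line)) "\t" else ","

#' Read a parcellated time-series matrix
#'
#' Reads delimited numeric text (TSV or CSV, auto-detected) with rows =
#' regions and columns = time points. A single header row of time indices is
#' tolerated and auto-detected by testing whether the first cell is numeric.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_timeseries_matrix <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty matrix file: %s", path)
  sep <- detect_sep(lines[[1]])
  first <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[[1]])))
  if (has_header) lines <- lines[-1]
  rows <- strsplit(lines, sep, fixed = TRUE)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1) abort("ragged rows in %s: %s columns", path,
                                paste(ncols, collapse = "/"))
  out <- matrix(NA_real_, length(rows), ncols)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      abort("non-numeric cell at row %d, column %d of %s ('%s')",
            i, j, path, rows[[i]][j])
    }
    out[i, ] <- v
  }
  out
}

#' Write a parcellated time-series matrix
#'
#' Full-precision TSV companion to [read_timeseries_matrix()]; round-trips
#' bit-identically.
#'
#' @param x numeric matrix (regions x time).
#' @param path file path.
#' @export
write_timeseries_matrix <- function(x, path) {
  check_finite_matrix(x, "time-series matrix")
  lines <- apply(x, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a task annotation from JSON
#'
#' The sidecar is a JSON array of objects `{"start":, "end":, "label":}` with
#' 0-based half-open intervals.
#'
#' @param path file path.
#' @return a [task_annotation()].
#' @export
read_task_annotation <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.data.frame(rec) || !all(c("start", "end", "label") %in% names(rec))) {
    abort("annotation %s must be a JSON array of {start, end, label} records", path)
  }
  task_annotation(rec$start, rec$end, rec$label)
}

#' Write a task annotation to JSON
#'
#' @param annotation a [task_annotation()].
#' @param path file path.
#' @export
write_task_annotation <- function(annotation, path) {
  if (!inherits(annotation, "task_annotation")) abort("not a task_annotation")
  jsonlite::write_json(as.data.frame(unclass(annotation)), path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parent scan from matrix + annotation files
#'
#' @param matrix_path delimited numeric text, rows = regions, columns = time.
#' @param annotation_path JSON annotation sidecar (see
#'   [read_task_annotation()]).
#' @param subject_id subject identifier.
#' @param session_id session identifier.
#' @return a validated [parent_scan()].
#' @export
read_parent_scan <- function(matrix_path, annotation_path, subject_id,
                             session_id = "test") {
  data <- read_timeseries_matrix(matrix_path)
  ann <- read_task_annotation(annotation_path)
  parent_scan(data, subject_id, ann, session_id)
}

#' Write a parent scan
#'
#' Emits `<stem>.tsv` (matrix) and `<stem>.json` (annotation).
#'
#' @param parent a [parent_scan()].
#' @param stem output path stem without extension.
#' @return character vector of the two paths written, invisibly.
#' @export
write_parent_scan <- function(parent, stem) {
  if (!inherits(parent, "parent_scan")) abort("not a parent_scan")
  mp <- paste0(stem, ".tsv"); ap <- paste0(stem, ".json")
  write_timeseries_matrix(parent$data, mp)
  write_task_annotation(parent$annotation, ap)
  invisible(c(mp, ap))
}

#' Construct a distance matrix object
#'
#' A symmetric, nonnegative, zero-diagonal matrix of pairwise dissimilarities
#' over identified objects. The triangle inequality is deliberately *not*
#' part of the contract: the dM dissimilarity can violate it.
#'
#' @param values numeric N x N matrix.
#' @param object_ids character vector of N identifiers.
#' @param metric_name name of the generating metric.
#' @return an object of class `distance_matrix`.
#' @export
distance_matrix <- function(values, object_ids, metric_name = "unknown") {
  check_finite_matrix(values, "distance matrix")
  if (!is_square(values)) abort("distance matrix must be square")
  n <- nrow(values)
  if (length(object_ids) != n) abort("need %d object ids, got %d", n, length(object_ids))
  if (max_abs(values - t(values)) > 1e-8 * max(1, max_abs(values))) {
    abort("distance matrix is not symmetric")
  }
  if (any(diag(values) != 0)) abort("distance matrix diagonal must be zero")
  if (any(values < 0)) abort("distance matrix entries must be >= 0")
  values <- sym(values)
  dimnames(values) <- list(object_ids, object_ids)
  structure(list(values = values, object_ids = as.character(object_ids),
                 metric_name = metric_name),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d x %d, metric '%s'\n",
              nrow(x$values), ncol(x$values), x$metric_name))
  invisible(x)
}

#' Write a distance matrix to TSV
#'
#' Header row and first column carry the object ids; values are printed at
#' full precision so [read_distance_matrix()] round-trips bit-identically.
#'
#' @param D a [distance_matrix()].
#' @param path file path.
#' @export
write_distance_matrix <- function(D, path) {
  if (!inherits(D, "distance_matrix")) abort("not a distance_matrix")
  n <- length(D$object_ids)
  head <- paste(c("id", D$object_ids), collapse = "\t")
  body <- vapply(seq_len(n), function(i) {
    paste(c(D$object_ids[i], sprintf("%.17g", D$values[i, ])), collapse = "\t")
  }, "")
  writeLines(c(head, body), path)
  invisible(path)
}

#' Read a distance matrix from TSV
#'
#' @param path file written by [write_distance_matrix()].
#' @param metric_name metric name to record on the result.
#' @return a [distance_matrix()].
#' @export
read_distance_matrix <- function(path, metric_name = "unknown") {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  ids <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]][-1]
  n <- length(ids)
  vals <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    cells <- strsplit(lines[[i + 1]], "\t", fixed = TRUE)[[1]]
    vals[i, ] <- as.numeric(cells[-1])
  }
  distance_matrix(vals, ids, metric_name)
}
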