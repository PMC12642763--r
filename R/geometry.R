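# Distances between scans and connectomes.
#
# Three routes, each sensitive to a different kind of structure:
#   * frobenius_raw  — entrywise distance between task scans; dominated by
#     per-subject BOLD offsets, so it clusters scans by individual;
#   * bures_connectome — Bures distance between Pearson correlation
#     connectomes; sensitive to inter-region correlation structure, again a
#     subject fingerprint, but immune to mean/scale differences;
#   * dM — Frobenius distance between task scans extracted from de-meaned,
#     whitened parents; individual structure removed, task signal remains.
#     dM can break the triangle inequality and is a dissimilarity, not a
#     metric.

#' Functional connectome of a task scan
#'
#' Region-against-region Pearson correlation (default) or sample covariance
#' of a task scan's rows.
#'
#' @param scan a `task_scan`, or a bare numeric matrix (regions x time).
#' @param kind `"correlation"` (default) or `"covariance"`.
#' @return an object of class `connectome`: list with `matrix`, `kind`,
#'   `subject_id`, `task_label`.
#' @export
connectome <- function(scan, kind = c("correlation", "covariance")) {
  kind <- match.arg(kind)
  data <- if (inherits(scan, "task_scan")) scan$data else scan
  check_finite_matrix(data, "task scan data")
  if (ncol(data) < 3) abort("need at least 3 time points for a connectome")
  if (kind == "correlation") {
    sds <- apply(data, 1, stats::sd)
    if (any(sds == 0)) {
      abort("region %d has constant signal; correlation undefined",
            which(sds == 0)[1])
    }
    mat <- sym(unname(stats::cor(t(data))))
    diag(mat) <- 1
  } else {
    mat <- covariance_of_rows(data)
  }
  structure(list(matrix = mat, kind = kind,
                 subject_id = if (inherits(scan, "task_scan")) scan$subject_id else NA_character_,
                 task_label = if (inherits(scan, "task_scan")) scan$task_label else NA_character_),
            class = "connectome")
}

#' @rdname connectome
#' @export
correlation_connectome <- function(scan) connectome(scan, "correlation")

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d x %d %s matrix (subject %s, task %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$kind, x$subject_id, x$task_label))
  invisible(x)
}

conn_matrix <- function(x) if (inherits(x, "connectome")) x$matrix else x

#' Symmetric PSD matrix square root
#'
#' Eigendecomposition-based principal square root; eigenvalues that are
#' negative by roundoff (within `tol * max(eigenvalue)`) are clamped to 0,
#' genuinely negative eigenvalues are an error.
#'
#' @param A symmetric PSD matrix.
#' @param tol relative tolerance for accepting small negative eigenvalues.
#' @return symmetric PSD matrix `R` with `R %*% R = A`.
#' @export
psd_sqrt <- function(A, tol = 1e-8) {
  A <- conn_matrix(A)
  check_finite_matrix(A, "input")
  if (!is_square(A)) abort("input must be square")
  if (max_abs(A - t(A)) > 1e-8 * max(1, max_abs(A))) abort("input must be symmetric")
  ee <- eigen(sym(A), symmetric = TRUE)
  lmax <- max(ee$values, 0)
  if (min(ee$values) < -tol * max(lmax, 1)) {
    abort("input not PSD: eigenvalue %g", min(ee$values))
  }
  lam <- pmax(ee$values, 0)
  sym(ee$vectors %*% (t(ee$vectors) * sqrt(lam)))
}

# tr (A^{1/2} B A^{1/2})^{1/2} given sqrt_A precomputed: the shared kernel of
# fidelity and the Bures distance (equals sqrt of fidelity).
root_fidelity <- function(sqrt_A, B, tol = 1e-8) {
  M <- sym(sqrt_A %*% B %*% sqrt_A)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sum(sqrt(pmax(ev, 0)))
}

check_same_size <- function(A, B) {
  if (!identical(dim(A), dim(B))) {
    abort("size mismatch: %dx%d vs %dx%d", nrow(A), ncol(A), nrow(B), ncol(B))
  }
}

#' Fidelity between two PSD matrices
#'
#' `F(A, B) = (tr (A^{1/2} B A^{1/2})^{1/2})^2`, the similarity functional
#' underlying the Bures distance; symmetric in its arguments and equal to
#' `(tr A)^2` when `B = A`.
#'
#' @param A,B symmetric PSD matrices (or `connectome` objects) of equal size.
#' @return nonnegative scalar.
#' @export
fidelity <- function(A, B) {
  A <- conn_matrix(A); B <- conn_matrix(B)
  check_same_size(A, B)
  root_fidelity(psd_sqrt(A), B)^2
}

#' Bures distance between two PSD matrices
#'
#' The geodesic distance on the manifold of PSD matrices,
#' `dB(A, B) = sqrt( tr A + tr B - 2 sqrt(F(A, B)) )` with `F` the
#' [fidelity()]. Applied to functional connectomes it measures how
#' distinguishable two scans are by their inter-region correlation pattern.
#' A radicand that is slightly negative from roundoff (when `A` is very close
#' to `B`) is clamped to 0 so that `dB(A, A) == 0` exactly.
#'
#' @inheritParams fidelity
#' @return nonnegative scalar; a true metric on PSD matrices.
#' @export
bures_distance <- function(A, B) {
  A <- conn_matrix(A); B <- conn_matrix(B)
  check_same_size(A, B)
  rf <- root_fidelity(psd_sqrt(A), B)
  bures_from_parts(sum(diag(A)), sum(diag(B)), rf)
}

# dB from traces and tr(A^{1/2}BA^{1/2})^{1/2}; radicands within eigensolver
# roundoff of zero (relative to the trace scale) are clamped so that
# dB(A, A) == 0 exactly
bures_from_parts <- function(tr_a, tr_b, rf) {
  rad <- tr_a + tr_b - 2 * rf
  if (rad < 1e-12 * (tr_a + tr_b)) return(0)
  sqrt(rad)
}

#' Frobenius distance between two matrices
#'
#' `dF(A, B) = ||A - B||_F`, the entrywise Euclidean distance; the natural
#' extension of the Euclidean distance to matrices and a true metric. It is
#' sensitive to constant offsets: shifting every entry of one argument by `c`
#' yields `dF = sqrt(m*n) * |c|`.
#'
#' @param A,B numeric matrices (or `task_scan`s) of identical shape.
#' @return nonnegative scalar.
#' @export
frobenius_distance <- function(A, B) {
  if (inherits(A, "task_scan")) A <- A$data
  if (inherits(B, "task_scan")) B <- B$data
  check_same_size(A, B)
  sqrt(sum((A - B)^2))
}

#' dM dissimilarity between two task scans
#'
#' De-means and whitens each parent scan, extracts the indexed task scans
#' from the *whitened* parents, and returns their Frobenius distance. This is
#' the de-individualized comparison: per-region offsets and inter-region
#' correlation structure (both subject fingerprints) are removed before the
#' distance is taken, so what remains is predominantly task signal.
#'
#' dM is symmetric and zero on identical arguments but may violate the
#' triangle inequality — it is a dissimilarity, not a metric.
#'
#' @param parent1,parent2 [parent_scan()] objects.
#' @param idx1,idx2 1-based annotation interval indices selecting the task
#'   scan within each parent.
#' @param ridge ridge passed to [whiten()].
#' @param truncate if `TRUE`, task scans of unequal length are truncated to
#'   the shorter length (from the start of each block) with a warning;
#'   if `FALSE` (default) unequal lengths are an error.
#' @return nonnegative scalar.
#' @export
dM_distance <- function(parent1, parent2, idx1, idx2, ridge = 0,
                        truncate = FALSE) {
  w1 <- preprocess_parent(parent1, ridge = ridge)
  w2 <- preprocess_parent(parent2, ridge = ridge)
  t1 <- extract_task_scans(w1)[[idx1]]
  t2 <- extract_task_scans(w2)[[idx2]]
  d1 <- t1$data; d2 <- t2$data
  if (ncol(d1) != ncol(d2)) {
    if (!truncate) {
      abort(paste("task scans have unequal lengths (%d vs %d);",
                  "set truncate = TRUE to compare the common prefix"),
            ncol(d1), ncol(d2))
    }
    L <- min(ncol(d1), ncol(d2))
    warning(sprintf("truncating task scans to %d common time points", L))
    d1 <- d1[, seq_len(L), drop = FALSE]
    d2 <- d2[, seq_len(L), drop = FALSE]
  }
  frobenius_distance(d1, d2)
}

task_scan_lengths <- function(scans) vapply(scans, function(s) ncol(s$data), 0L)

truncate_scans <- function(scans) {
  Ls <- task_scan_lengths(scans)
  L <- min(Ls)
  if (any(Ls != L)) {
    warning(sprintf("task scans have unequal lengths; truncating all to %d time points", L))
    scans <- lapply(scans, function(s) {
      s$data <- s$data[, seq_len(L), drop = FALSE]; s
    })
  }
  scans
}

scan_ids <- function(scans) {
  ids <- vapply(scans, function(s) paste0(s$subject_id, ":", s$task_label), "")
  if (anyDuplicated(ids)) ids <- paste0(ids, "#", seq_along(ids))
  ids
}

#' Pairwise distance matrix over a collection of scans
#'
#' Assembles the symmetric distance matrix for one of the three pipeline
#' metrics.
#'
#' * `"frobenius_raw"` — `objects` is a list of `task_scan`s (or matrices);
#'   entries are Frobenius distances between the raw scans.
#' * `"bures_connectome"` — `objects` is a list of `task_scan`s; each is
#'   first mapped to a connectome (Pearson correlation by default) and
#'   entries are Bures distances. The PSD square root of each connectome is
#'   computed once, not once per pair.
#' * `"dM"` — `objects` is a list of [parent_scan()]s; each parent is
#'   de-meaned and whitened *once*, its task scans are extracted from the
#'   whitened matrix, and entries are Frobenius distances between all
#'   extracted task scans (in parent order, then annotation order).
#'
#' @param objects list of scans (see above).
#' @param metric one of `"frobenius_raw"`, `"bures_connectome"`, `"dM"`.
#' @param ridge ridge for whitening (dM only).
#' @param kind connectome kind for the Bures route.
#' @return a [distance_matrix()]; object ids are `subject:task` (suffixed
#'   with an index if duplicated).
#' @export
pairwise_distances <- function(objects,
                               metric = c("frobenius_raw", "bures_connectome", "dM"),
                               ridge = 0,
                               kind = c("correlation", "covariance")) {
  metric <- match.arg(metric)
  kind <- match.arg(kind)
  if (length(objects) < 2) abort("need at least 2 objects")

  if (metric == "dM") {
    if (!all(vapply(objects, inherits, TRUE, what = "parent_scan"))) {
      abort("for metric 'dM', objects must be a list of parent_scan")
    }
    whitened <- lapply(objects, preprocess_parent, ridge = ridge)
    scans <- truncate_scans(unlist(lapply(whitened, extract_task_scans),
                                   recursive = FALSE))
    mats <- lapply(scans, `[[`, "data")
    ids <- scan_ids(scans)
    dist_fun <- frobenius_distance
  } else if (metric == "frobenius_raw") {
    scans <- objects
    if (all(vapply(scans, inherits, TRUE, what = "task_scan"))) {
      scans <- truncate_scans(scans)
      ids <- scan_ids(scans)
      mats <- lapply(scans, `[[`, "data")
    } else {
      mats <- scans
      ids <- paste0("obj", seq_along(mats))
    }
    dist_fun <- frobenius_distance
  } else {
    conns <- lapply(objects, connectome, kind = kind)
    ids <- vapply(conns, function(cn) paste0(cn$subject_id, ":", cn$task_label), "")
    if (anyDuplicated(ids) || anyNA(ids)) ids <- paste0("obj", seq_along(conns))
    mats <- lapply(conns, `[[`, "matrix")
    roots <- lapply(mats, psd_sqrt)
    traces <- vapply(mats, function(m) sum(diag(m)), 0)
    dist_fun <- NULL
  }

  n <- length(mats)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- if (metric == "bures_connectome") {
        bures_from_parts(traces[i], traces[j], root_fidelity(roots[[i]], mats[[j]]))
      } else {
        dist_fun(mats[[i]], mats[[j]])
      }
    }
  }
  distance_matrix(D, ids, metric)
}
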