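# Two-stage de-individualization of parent scans:
#   1. standardization: subtract each region's mean over the whole session
#      (removes the subject-specific per-region BOLD offsets);
#   2. Mahalanobis (ZCA) whitening against W = cov of the de-meaned rows
#      (erases inter-region correlation structure and fixes every region's
#      standard deviation at 1).
# Both steps act on the *whole parent scan*; task scans are extracted
# afterwards, so all task blocks from one session share one transform.

#' Remove each row's mean
#'
#' @param S numeric matrix (regions x time).
#' @return matrix of the same shape whose rows have mean 0.
#' @examples
#' demean_rows(matrix(1:3, 1))
#' @export
demean_rows <- function(S) {
  check_finite_matrix(S, "input")
  if (ncol(S) < 1 || nrow(S) < 1) abort("input matrix is empty")
  S - rowMeans(S)
}

#' Covariance of the rows of a matrix
#'
#' Treats each row (region) as a variable observed at `n` time points and
#' returns the `m x m` sample covariance (1/(n-1) normalizer). For de-meaned
#' BOLD data this is the covariance-based functional connectome.
#'
#' @param S numeric matrix (m regions x n time points), n >= 2.
#' @return symmetric PSD `m x m` matrix.
#' @export
covariance_of_rows <- function(S) {
  check_finite_matrix(S, "input")
  if (ncol(S) < 2) abort("need at least 2 time points to estimate covariance")
  sym(unname(stats::cov(t(S))))
}

#' Mahalanobis-whiten a de-meaned parent scan
#'
#' Computes `Sw = (W + ridge*I)^{-1/2} S` with `W = cov` of the rows of `S`
#' and the symmetric PSD inverse square root taken by eigendecomposition.
#' With `ridge = 0` and full-rank `W`, the rows of the output have identity
#' covariance (the whitening contract) and hence unit standard deviation and
#' an identity Pearson correlation connectome.
#'
#' Eigenvalues are clamped at a relative floor of `1e-12 * max(eigenvalue)`
#' before inversion; an ill-conditioned `W` (condition number beyond
#' `condition_threshold`) is a hard error rather than a silent
#' regularization, because silent ridging would change dM values
#' irreproducibly.
#'
#' @param S numeric matrix (m x n), typically the output of [demean_rows()];
#'   `m <= n - 1` is recommended so that `W` has full rank.
#' @param ridge nonnegative ridge added to the diagonal of `W` before
#'   inversion (default 0).
#' @param condition_threshold condition-number limit beyond which whitening
#'   refuses to proceed (default 1e12).
#' @return list with elements `data` (the whitened matrix), `ridge_used`,
#'   and `whitener` (the `m x m` inverse square root applied).
#' @export
whiten <- function(S, ridge = 0, condition_threshold = 1e12) {
  check_finite_matrix(S, "input")
  if (ridge < 0) abort("ridge must be >= 0")
  W <- covariance_of_rows(S) + diag(ridge, nrow(S))
  ee <- eigen(sym(W), symmetric = TRUE)
  lam <- ee$values
  lmax <- max(lam, 0)
  if (lmax <= 0 || min(lam) <= 0 || lmax / min(lam) > condition_threshold) {
    abort(paste("covariance is numerically singular (condition number > %g);",
                "increase the ridge or use more time points (need n > m)"),
          condition_threshold)
  }
  lam <- pmax(lam, 1e-12 * lmax)
  inv_sqrt <- ee$vectors %*% (t(ee$vectors) * (1 / sqrt(lam)))
  list(data = inv_sqrt %*% S, ridge_used = ridge, whitener = inv_sqrt)
}

#' De-mean and whiten a parent scan
#'
#' Applies the full de-individualization transform ([demean_rows()] then
#' [whiten()]) to a parent scan's matrix. The annotation is carried through
#' unchanged so that task scans are extracted *after* whitening via
#' [extract_task_scans()].
#'
#' @param parent a [parent_scan()].
#' @inheritParams whiten
#' @return an object of class `whitened_parent_scan` with fields `data`,
#'   `subject_id`, `annotation`, `session_id`, `ridge_used`.
#' @examples
#' ann <- task_annotation(0, 10, "A")
#' ps <- parent_scan(matrix(rnorm(40), 4, 10), "s1", ann)
#' w <- preprocess_parent(ps)
#' max(abs(covariance_of_rows(w$data) - diag(4)))  # ~ 0
#' @export
preprocess_parent <- function(parent, ridge = 0, condition_threshold = 1e12) {
  if (!inherits(parent, "parent_scan")) abort("parent must be a parent_scan")
  wres <- whiten(demean_rows(parent$data), ridge = ridge,
                 condition_threshold = condition_threshold)
  structure(list(data = wres$data,
                 subject_id = parent$subject_id,
                 annotation = parent$annotation,
                 session_id = parent$session_id,
                 ridge_used = wres$ridge_used),
            class = "whitened_parent_scan")
}

#' @export
print.whitened_parent_scan <- function(x, ...) {
  cat(sprintf("<whitened_parent_scan> subject %s (%s): %d x %d, ridge %g\n",
              x$subject_id, x$session_id, nrow(x$data), ncol(x$data),
              x$ridge_used))
  invisible(x)
}
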