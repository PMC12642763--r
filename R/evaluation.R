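# Clustering of embedded coordinates and partition-based scoring.
#
# ARS and AMI judge data *partitioning*, not label alignment: both are
# chance-adjusted (expected value 0 under random labelings) and normalized
# (maximum 1, attained exactly when the two partitions coincide), so they
# are the right scores for an unsupervised pipeline whose cluster ids carry
# no intrinsic meaning.

coords_of <- function(X) {
  if (inherits(X, "embedding_result")) X$coordinates else as.matrix(X)
}

# squared Euclidean distances from each row of X to each row of C
cross_dist2 <- function(X, C) {
  outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- cross_dist2(X, X[centers[1], , drop = FALSE])[, 1]
  for (j in seq_len(k - 1)) {
    d2 <- pmax(d2, 0)
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = probs)
    d2 <- pmin(d2, cross_dist2(X, X[centers[j + 1], , drop = FALSE])[, 1])
  }
  X[centers, , drop = FALSE]
}

lloyd <- function(X, centers, iter_max = 100L) {
  k <- nrow(centers)
  n <- nrow(X)
  assign <- integer(n)
  for (it in seq_len(iter_max)) {
    d2 <- pmax(cross_dist2(X, centers), 0)
    new_assign <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters with the worst-fit points
    empty <- setdiff(seq_len(k), unique(new_assign))
    if (length(empty) > 0) {
      worst <- order(d2[cbind(seq_len(n), new_assign)], decreasing = TRUE)
      for (e in seq_along(empty)) new_assign[worst[e]] <- empty[e]
    }
    if (identical(new_assign, assign) && it > 1) break
    assign <- new_assign
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[assign == j, , drop = FALSE])
    }
  }
  d2 <- pmax(cross_dist2(X, centers), 0)
  list(labels = assign, centers = centers,
       inertia = sum(d2[cbind(seq_len(n), assign)]))
}

#' k-means clustering with k-means++ initialization
#'
#' Lloyd's algorithm, best inertia over `n_restarts` seeded k-means++
#' initializations. Deterministic for a fixed seed; the caller's RNG state
#' is untouched.
#'
#' @param X numeric `N x d` coordinate matrix or an `embedding_result`.
#' @param k number of clusters, `1 <= k <= N`.
#' @param seed integer seed.
#' @param n_restarts number of independent initializations (default 10).
#' @return object of class `clustering_result`: list with `labels` (1-based
#'   cluster ids), `k`, `inertia`, `seed`, `n_restarts`.
#' @export
cluster_kmeans <- function(X, k, seed = 0L, n_restarts = 10L) {
  X <- coords_of(X)
  n <- nrow(X)
  if (k < 1 || k > n) abort("k must be in [1, %d], got %s", n, k)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(derive_seed(seed, "kmeans", r), {
      lloyd(X, kmeanspp_init(X, k))
    })
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(list(labels = best$labels, k = as.integer(k),
                 inertia = best$inertia, seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> k = %d, inertia = %.4g, %d non-empty clusters\n",
              x$k, x$inertia, length(unique(x$labels))))
  invisible(x)
}

#' Contingency table of two labelings
#'
#' @param truth,pred label vectors of equal length.
#' @return list with `counts` (r x c integer matrix), `row_marginals`,
#'   `col_marginals`, `n`.
#' @export
contingency_table <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    abort("label vectors differ in length (%d vs %d)", length(truth), length(pred))
  }
  if (length(truth) < 2) abort("need at least 2 labeled objects")
  counts <- unname(table(factor(truth), factor(pred)))
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts))
  list(counts = counts,
       row_marginals = as.integer(rowSums(counts)),
       col_marginals = as.integer(colSums(counts)),
       n = as.integer(sum(counts)))
}

choose2 <- function(x) x * (x - 1) / 2

#' Adjusted Rand score
#'
#' Chance-adjusted pair-counting agreement between two partitions:
#' `(Index - E[Index]) / (MaxIndex - E[Index])` on the contingency table.
#' Equals 1 iff the partitions are identical and has expected value 0 for
#' random labelings; invariant to relabeling either argument.
#'
#' @param truth,pred label vectors of equal length (any atomic type).
#' @return scalar `<= 1`.
#' @export
adjusted_rand_score <- function(truth, pred) {
  ct <- contingency_table(truth, pred)
  idx <- sum(choose2(ct$counts))
  a <- sum(choose2(ct$row_marginals))
  b <- sum(choose2(ct$col_marginals))
  expected <- a * b / choose2(ct$n)
  maximum <- (a + b) / 2
  if (maximum == expected) return(1)   # both partitions trivial and identical
  (idx - expected) / (maximum - expected)
}

entropy_of <- function(marginals, n) {
  p <- marginals[marginals > 0] / n
  -sum(p * log(p))
}

mutual_information <- function(ct) {
  n <- ct$n
  mi <- 0
  for (i in seq_along(ct$row_marginals)) {
    for (j in seq_along(ct$col_marginals)) {
      nij <- ct$counts[i, j]
      if (nij > 0) {
        mi <- mi + nij / n * log(n * nij / (ct$row_marginals[i] * ct$col_marginals[j]))
      }
    }
  }
  mi
}

# E[MI] under the permutation (hypergeometric) model, log-space factorials
expected_mutual_information <- function(ct) {
  n <- ct$n
  a <- ct$row_marginals
  b <- ct$col_marginals
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lfactorial(a[i]) + lfactorial(b[j]) +
          lfactorial(n - a[i]) + lfactorial(n - b[j]) -
          lfactorial(n) - lfactorial(nij) - lfactorial(a[i] - nij) -
          lfactorial(b[j] - nij) - lfactorial(n - a[i] - b[j] + nij)
        emi <- emi + nij / n * log(n * nij / (a[i] * b[j])) * exp(lp)
      }
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' `AMI = (MI - E[MI]) / (norm(H(truth), H(pred)) - E[MI])` with the expected
#' mutual information taken under the permutation (hypergeometric) model.
#' The normalizer is the arithmetic mean of the entropies by default (the
#' modern convention), configurable to the maximum. Natural-log base
#' throughout (the base cancels in the ratio).
#'
#' Degenerate case: when both partitions are single-cluster the score is 1
#' if they are identical as partitions (they necessarily are) — more
#' generally, a zero denominator returns 1 for identical partitions and 0
#' otherwise.
#'
#' @inheritParams adjusted_rand_score
#' @param normalizer `"arithmetic"` (default) or `"max"` entropy
#'   normalization.
#' @return scalar `<= 1`.
#' @export
adjusted_mutual_information <- function(truth, pred,
                                        normalizer = c("arithmetic", "max")) {
  normalizer <- match.arg(normalizer)
  ct <- contingency_table(truth, pred)
  h_true <- entropy_of(ct$row_marginals, ct$n)
  h_pred <- entropy_of(ct$col_marginals, ct$n)
  mi <- mutual_information(ct)
  emi <- expected_mutual_information(ct)
  norm <- if (normalizer == "arithmetic") mean(c(h_true, h_pred)) else max(h_true, h_pred)
  denom <- norm - emi
  if (abs(denom) < 1e-14) {
    same <- identical(partition_signature(truth), partition_signature(pred))
    return(if (same) 1 else 0)
  }
  (mi - emi) / denom
}

# canonical form of a partition: cluster ids renumbered by first appearance
partition_signature <- function(labels) {
  match(labels, unique(labels))
}

#' Score an embedding's clustering against subject and task labels
#'
#' Runs k-means twice on the embedded coordinates — once with `k_subject`
#' clusters scored against the subject labels, once with `k_task` clusters
#' scored against the task labels — and reports AMI and ARS for each.
#' Clustering is meant to run on the higher-dimensional (e.g. 20-d)
#' embedding used for quantitative evaluation, not on a 2-d visualization.
#'
#' @param coords `embedding_result` or `N x d` matrix.
#' @param subject_labels,task_labels ground-truth label vectors of length N.
#' @param seed RNG seed for k-means.
#' @param k_subject clusters for the subject run (default: number of unique
#'   subject labels).
#' @param k_task clusters for the task run (default: number of unique task
#'   labels).
#' @param n_restarts k-means restarts.
#' @return data.frame with rows `AMI`, `ARS` and columns `task`, `subject`.
#' @export
evaluate_embedding <- function(coords, subject_labels, task_labels, seed = 0L,
                               k_subject = NULL, k_task = NULL,
                               n_restarts = 10L) {
  X <- coords_of(coords)
  n <- nrow(X)
  if (length(subject_labels) != n || length(task_labels) != n) {
    abort("label vectors must have length %d", n)
  }
  if (is.null(k_subject)) k_subject <- length(unique(subject_labels))
  if (is.null(k_task)) k_task <- length(unique(task_labels))
  cl_subj <- cluster_kmeans(X, k_subject, seed = derive_seed(seed, "subject"),
                            n_restarts = n_restarts)
  cl_task <- cluster_kmeans(X, k_task, seed = derive_seed(seed, "task"),
                            n_restarts = n_restarts)
  out <- data.frame(
    task = c(adjusted_mutual_information(task_labels, cl_task$labels),
             adjusted_rand_score(task_labels, cl_task$labels)),
    subject = c(adjusted_mutual_information(subject_labels, cl_subj$labels),
                adjusted_rand_score(subject_labels, cl_subj$labels)),
    row.names = c("AMI", "ARS"))
  out
}
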