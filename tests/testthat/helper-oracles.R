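# Independent oracles used by the unit and acceptance tests. Each is a
# deliberately naive, literal implementation kept separate from the package
# code paths it checks.

# Brute-force Floyd-Warshall over an explicit edge list: O(N^3) triple loop.
fw_oracle <- function(n, edges) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]; w <- edges$weight[r]
    D[i, j] <- min(D[i, j], w)
    D[j, i] <- min(D[j, i], w)
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Pair-counting adjusted Rand index: enumerate all object pairs and count
# co-assignments, then use the closed form on the four pair counts.
ars_pair_oracle <- function(truth, pred) {
  n <- length(truth)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- truth[i] == truth[j]
      sp <- pred[i] == pred[j]
      if (st && sp) n11 <- n11 + 1
      else if (!st && !sp) n00 <- n00 + 1
      else if (st && !sp) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / denom
}

# Direct expected-mutual-information summation under the permutation model,
# with the hypergeometric pmf delegated to stats::dhyper (independent of the
# package's log-factorial route).
emi_oracle <- function(truth, pred) {
  tab <- table(truth, pred)
  a <- rowSums(tab); b <- colSums(tab); n <- sum(tab)
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      for (nij in seq.int(max(1, a[i] + b[j] - n), min(a[i], b[j]))) {
        if (nij < max(1, a[i] + b[j] - n)) next
        p <- stats::dhyper(nij, a[i], n - a[i], b[j])
        emi <- emi + nij / n * log(n * nij / (a[i] * b[j])) * p
      }
    }
  }
  unname(emi)
}

ami_oracle <- function(truth, pred) {
  tab <- table(truth, pred)
  n <- sum(tab)
  joint <- tab / n
  pr <- rowSums(joint); pc <- colSums(joint)
  mi <- 0
  for (i in seq_along(pr)) {
    for (j in seq_along(pc)) {
      if (joint[i, j] > 0) mi <- mi + joint[i, j] * log(joint[i, j] / (pr[i] * pc[j]))
    }
  }
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  emi <- emi_oracle(truth, pred)
  denom <- mean(c(h(pr), h(pc))) - emi
  if (abs(denom) < 1e-14) {
    return(if (identical(match(truth, unique(truth)), match(pred, unique(pred)))) 1 else 0)
  }
  unname((mi - emi) / denom)
}

# All set partitions of n objects as label vectors (restricted growth strings).
partitions_of <- function(n) {
  out <- list()
  grow <- function(labels, k) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (v in seq_len(k + 1)) grow(c(labels, v), max(k, v))
  }
  grow(integer(0), 0L)
  out
}

# Random symmetric positive definite matrix with eigenvalues in [lo, hi].
random_spd <- function(m, lo = 0.5, hi = 2) {
  Q <- qr.Q(qr(matrix(rnorm(m * m), m, m)))
  Q %*% (t(Q) * runif(m, lo, hi))
}

random_correlation <- function(m) {
  stats::cov2cor(random_spd(m))
}

# Small well-formed parent scan fixture.
make_parent <- function(m = 4, L = 10, n_tasks = 2, subject = "s1",
                        labels = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- L * n_tasks
  if (is.null(labels)) labels <- LETTERS[seq_len(n_tasks)]
  starts <- (seq_len(n_tasks) - 1) * L
  parent_scan(matrix(rnorm(m * n), m, n), subject,
              task_annotation(starts, starts + L, labels))
}
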