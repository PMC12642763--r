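# Isomap: kNN graph on a precomputed distance matrix, graph geodesics,
# double-centered Gram matrix, spectral embedding. The geodesic step uses
# repeated Dijkstra (via igraph) — identical output to Floyd–Warshall for
# nonnegative weights, but scales to large N; the test suite checks it
# against a brute-force cubic oracle.

dist_values <- function(D) {
  if (inherits(D, "distance_matrix")) D$values else {
    check_finite_matrix(D, "distance matrix")
    D
  }
}

#' k-nearest-neighbour graph of a distance matrix
#'
#' For each node, edges to its `k` smallest-distance neighbours (self
#' excluded, ties broken by lower index); the edge set is then symmetrized
#' by union, which maximizes connectivity.
#'
#' @param D a [distance_matrix()] or plain symmetric matrix.
#' @param k neighbourhood size, `1 <= k <= N-1`.
#' @return object of class `neighbor_graph`: list with `n_nodes`, `edges`
#'   (data.frame `i`, `j`, `weight` with `i < j`), `k`.
#' @export
knn_graph <- function(D, k) {
  V <- dist_values(D)
  n <- nrow(V)
  if (k < 1 || k > n - 1) abort("k must be in [1, %d], got %s", n - 1, k)
  pairs <- matrix(0L, 0, 2)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nb <- others[order(V[i, others], others)][seq_len(k)]
    pairs <- rbind(pairs, cbind(pmin(i, nb), pmax(i, nb)))
  }
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  structure(list(n_nodes = n,
                 edges = data.frame(i = pairs[, 1], j = pairs[, 2],
                                    weight = V[pairs]),
                 k = as.integer(k)),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d nodes, %d undirected edges (k = %d)\n",
              x$n_nodes, nrow(x$edges), x$k))
  invisible(x)
}

as_igraph <- function(G) {
  igraph::graph_from_edgelist(as.matrix(G$edges[, c("i", "j")]), directed = FALSE)
}

#' Geodesic (shortest-path) distances through a neighbour graph
#'
#' Direct neighbours keep their input distance; all other pairs get the
#' shortest-path distance through the graph. A disconnected graph is an
#' error (no silent subsetting): the message reports component sizes and
#' advises a larger `k`.
#'
#' @param G a [knn_graph()] result.
#' @param D the distance matrix the graph was built from.
#' @return symmetric `N x N` matrix of graph geodesics.
#' @export
geodesic_distances <- function(G, D) {
  V <- dist_values(D)
  if (!inherits(G, "neighbor_graph")) abort("G must be a neighbor_graph")
  if (G$n_nodes != nrow(V)) abort("graph and distance matrix disagree on N")
  g <- as_igraph(G)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    abort("neighbour graph is disconnected (component sizes %s); increase k",
          paste(sort(comp$csize, decreasing = TRUE), collapse = ", "))
  }
  Dh <- igraph::distances(g, weights = G$edges$weight, algorithm = "dijkstra")
  dimnames(Dh) <- NULL
  # contract: direct edges carry the raw distance even if a
  # multi-hop path through a non-metric input would be shorter
  idx <- as.matrix(G$edges[, c("i", "j")])
  Dh[idx] <- G$edges$weight
  Dh[idx[, 2:1, drop = FALSE]] <- G$edges$weight
  sym(Dh)
}

#' Spectral embedding of a geodesic distance matrix (classical MDS step)
#'
#' Forms the double-centered Gram matrix `B = -1/2 * J D^2 J` with
#' `J = I - (1/N) 11'` (squaring elementwise), eigendecomposes it, and
#' returns coordinates `X = V_d Lambda_d^{1/2}` for the top `d` nonnegative
#' eigenvalues. If fewer than `d` eigenvalues are nonnegative, fewer columns
#' are returned with a warning.
#'
#' @param D_hat symmetric zero-diagonal matrix (typically
#'   [geodesic_distances()] output).
#' @param d target dimension, `1 <= d <= N-1`.
#' @param backend label stored on the result.
#' @return object of class `embedding_result`: list with `coordinates`
#'   (N x d'), `eigenvalues` (length d', descending), `d`, `backend`.
#' @export
isomap_embed <- function(D_hat, d, backend = "isomap") {
  V <- dist_values(D_hat)
  n <- nrow(V)
  if (d < 1 || d > n - 1) abort("d must be in [1, %d]", n - 1)
  if (max_abs(V - t(V)) > 1e-8 * max(1, max_abs(V))) abort("D_hat must be symmetric")
  B <- V^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  B <- sym(-0.5 * B)
  ee <- eigen(B, symmetric = TRUE)
  # nonnegative eigenpairs only; eigenvalues below 1e-12 * lambda_max are
  # numerical zeros (e.g. the centering null direction) and are excluded so
  # the retained dimension count is deterministic
  keep <- which(ee$values >= 1e-12 * max(ee$values, 0) & ee$values >= 0)
  keep <- keep[seq_len(min(d, length(keep)))]
  if (length(keep) < d) {
    warning(sprintf("only %d nonnegative eigenvalues available; returning %d dimensions",
                    length(keep), length(keep)))
  }
  lam <- ee$values[keep]
  X <- ee$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam), length(keep))
  structure(list(coordinates = X, eigenvalues = lam,
                 d = length(keep), backend = backend),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d points in %d dimensions (%s)\n",
              nrow(x$coordinates), x$d, x$backend))
  invisible(x)
}

#' Embed a distance matrix in low dimension
#'
#' The `"isomap"` backend chains [knn_graph()], [geodesic_distances()] and
#' [isomap_embed()]. With `k = N - 1` the graph is complete and the result
#' reduces to classical MDS of `D`. The `"umap"` backend delegates to the
#' external \pkg{uwot} implementation (never reimplemented here), feeding
#' `D` as a precomputed distance matrix under a fixed seed; if \pkg{uwot} is
#' not installed this is an error, never a silent fallback.
#'
#' @param D a [distance_matrix()] or plain symmetric matrix.
#' @param k neighbourhood size (default 10).
#' @param d embedding dimension (default 2 for plots; use 20 for
#'   clustering).
#' @param backend `"isomap"` (default) or `"umap"`.
#' @param seed RNG seed (umap backend only; isomap is deterministic).
#' @return an `embedding_result`.
#' @export
embed_distances <- function(D, k = 10, d = 2, backend = c("isomap", "umap"),
                            seed = 0L) {
  backend <- match.arg(backend)
  V <- dist_values(D)
  if (backend == "isomap") {
    G <- knn_graph(V, k)
    isomap_embed(geodesic_distances(G, V), d)
  } else {
    if (!requireNamespace("uwot", quietly = TRUE)) {
      abort("backend 'umap' requires the 'uwot' package, which is not installed")
    }
    X <- with_seed(seed, uwot::umap(stats::as.dist(V), n_neighbors = k,
                                    n_components = d))
    structure(list(coordinates = X, eigenvalues = rep(NA_real_, d),
                   d = d, backend = "umap"),
              class = "embedding_result")
  }
}
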