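# Isomap: kNN graph, graph geodesics, spectral embedding.

dist_from_points <- function(P) {
  unname(as.matrix(stats::dist(P)))
}

test_that("knn_graph: saturation, hand-enumerated neighbours, degeneracies", {
  # 4 collinear points at 0, 1, 2, 10 with k = 1:
  # neighbour lists are 1->2, 2->1 (tie to lower index over 3), 3->2, 4->3;
  # union edges {1-2, 2-3, 3-4}, connected only via symmetrization
  D <- dist_from_points(c(0, 1, 2, 10))
  G <- knn_graph(D, 1)
  expect_equal(G$edges$i, c(1L, 2L, 3L))
  expect_equal(G$edges$j, c(2L, 3L, 4L))
  expect_equal(G$edges$weight, c(1, 1, 8))

  # k = N - 1 gives the complete graph
  Gc <- knn_graph(D, 3)
  expect_identical(nrow(Gc$edges), 6L)

  # duplicated points are mutual nearest neighbours, no self-edges
  Dd <- dist_from_points(c(0, 0, 5))
  Gd <- knn_graph(Dd, 1)
  expect_true(any(Gd$edges$i == 1 & Gd$edges$j == 2))
  expect_true(all(Gd$edges$i != Gd$edges$j))

  expect_error(knn_graph(D, 0), "k must be")
  expect_error(knn_graph(D, 4), "k must be")
})

test_that("geodesic_distances: direct edges, two-hop paths, disconnection error", {
  # complete graph: geodesics equal the input distances
  withr::local_seed(1)
  P <- matrix(rnorm(12), 6, 2)
  D <- dist_from_points(P)
  G <- knn_graph(D, 5)
  expect_equal(geodesic_distances(G, D), unname(D), tolerance = 1e-12)

  # path graph 0-1-2 with unit edges: D_hat[1,3] = 2
  Dp <- dist_from_points(c(0, 1, 2))
  Gp <- knn_graph(Dp, 1)
  Dh <- geodesic_distances(Gp, Dp)
  expect_equal(Dh[1, 3], 2)

  # two far-apart pairs with k = 1 stay disconnected: error names components
  Dfar <- dist_from_points(c(0, 1, 100, 101))
  expect_error(geodesic_distances(knn_graph(Dfar, 1), Dfar),
               "disconnected.*2, 2.*increase k")
})

test_that("geodesics match the brute-force Floyd-Warshall oracle", {
  withr::local_seed(2)
  for (rep in 1:15) {
    n <- sample(5:25, 1)
    P <- matrix(rnorm(2 * n), n, 2)
    D <- dist_from_points(P)
    k <- sample(2:(n - 1), 1)
    G <- knn_graph(D, k)
    if (igraph::components(
          igraph::graph_from_edgelist(as.matrix(G$edges[, 1:2]),
                                      directed = FALSE))$no > 1) next
    expect_equal(geodesic_distances(G, D), fw_oracle(n, G$edges),
                 tolerance = 1e-12)
  }
})

test_that("isomap_embed recovers closed-form and exact-MDS configurations", {
  # 3 collinear points at 0, 1, 2: 1-d coordinates (-1, 0, 1) up to sign
  D <- dist_from_points(c(0, 1, 2))
  emb <- isomap_embed(D, 1)
  x <- emb$coordinates[, 1]
  if (x[1] > x[3]) x <- -x
  expect_equal(x, c(-1, 0, 1), tolerance = 1e-10)

  # points already in R^2, complete graph: embedded distances reproduce the
  # input exactly (classical MDS exactness)
  withr::local_seed(3)
  P <- matrix(rnorm(20), 10, 2)
  D <- dist_from_points(P)
  emb2 <- isomap_embed(D, 2)
  expect_equal(dist_from_points(emb2$coordinates), unname(D),
               tolerance = 1e-8)

  # degenerate all-zero input embeds at the origin
  z <- isomap_embed(matrix(0, 4, 4), 2)
  expect_equal(max(abs(z$coordinates)), 0)

  # eigenvalues are nonnegative and sorted descending
  expect_true(all(diff(emb2$eigenvalues) <= 1e-12))
  expect_true(all(emb2$eigenvalues >= 0))
})

test_that("with k = N-1 the embedding equals classical MDS (cmdscale oracle)", {
  withr::local_seed(4)
  P <- matrix(rnorm(36), 12, 3)
  D <- dist_from_points(P)
  emb <- embed_distances(D, k = 11, d = 3)
  ref <- stats::cmdscale(D, k = 3)
  # align column signs before comparing
  for (c_ in 1:3) {
    if (sum(emb$coordinates[, c_] * ref[, c_]) < 0) ref[, c_] <- -ref[, c_]
  }
  expect_equal(emb$coordinates, unname(ref), tolerance = 1e-8)
})

test_that("grid configurations embed with geodesic-faithful distances", {
  grid <- as.matrix(expand.grid(x = 0:5, y = 0:5))
  D <- dist_from_points(grid)
  # k = 8 so diagonal neighbours enter the graph; with k = 4 the geodesics
  # are Manhattan distances, which no 2-d Euclidean embedding tracks at 0.99
  G <- knn_graph(D, 8)
  Dh <- geodesic_distances(G, D)
  emb <- isomap_embed(Dh, 2)
  d_emb <- dist_from_points(emb$coordinates)
  expect_gt(stats::cor(d_emb[upper.tri(d_emb)], Dh[upper.tri(Dh)]), 0.99)
})

test_that("embedding respects object permutation up to rigid motion", {
  withr::local_seed(5)
  P <- matrix(rnorm(30), 15, 2)
  D <- dist_from_points(P)
  emb <- embed_distances(D, k = 6, d = 2)
  perm <- sample(15)
  embp <- embed_distances(D[perm, perm], k = 6, d = 2)
  d1 <- dist_from_points(emb$coordinates)[perm, perm]
  d2 <- dist_from_points(embp$coordinates)
  expect_equal(d2, d1, tolerance = 1e-8)
})

test_that("embed_distances is deterministic and reduces to isomap_embed", {
  withr::local_seed(6)
  P <- matrix(rnorm(6), 3, 2)
  D <- dist_from_points(P)
  e1 <- embed_distances(D, k = 2, d = 2)
  e2 <- embed_distances(D, k = 2, d = 2)
  expect_identical(e1$coordinates, e2$coordinates)
  # N = 3, k = 2: complete graph, equals direct spectral embedding of D
  expect_equal(e1$coordinates, isomap_embed(D, 2)$coordinates)

  if (requireNamespace("uwot", quietly = TRUE)) {
    u1 <- embed_distances(dist_from_points(matrix(rnorm(40), 20, 2)),
                          k = 5, d = 2, backend = "umap", seed = 1)
    expect_identical(dim(u1$coordinates), c(20L, 2L))
  } else {
    expect_error(embed_distances(D, k = 2, d = 2, backend = "umap"),
                 "uwot")
  }
})

test_that("requesting more dimensions than nonnegative eigenvalues warns", {
  # triangle-violating configuration: Gram eigenvalues 4.5, 0.5, ~0, -1.5,
  # so only 2 usable dimensions exist
  D <- matrix(1, 4, 4); diag(D) <- 0; D[1, 2] <- D[2, 1] <- 3
  expect_warning(emb <- isomap_embed(D, 3), "nonnegative eigenvalues")
  expect_identical(emb$d, 2L)
})
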