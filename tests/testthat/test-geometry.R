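# Distances: connectomes, fidelity/Bures, Frobenius, dM, pairwise assembly.

test_that("correlation connectome: affine invariance and brute-force Pearson", {
  r <- c(1, 3, 2, 5, 4, 7)
  T1 <- rbind(r, 2 * r + 5)
  expect_equal(connectome(T1)$matrix, matrix(1, 2, 2))
  expect_equal(connectome(rbind(r, -r))$matrix,
               matrix(c(1, -1, -1, 1), 2))

  withr::local_seed(1)
  X <- matrix(rnorm(4 * 100), 4, 100)
  C <- connectome(X)$matrix
  L <- ncol(X)
  for (i in 1:4) {
    for (j in 1:4) {
      xi <- X[i, ] - mean(X[i, ]); xj <- X[j, ] - mean(X[j, ])
      expect_equal(C[i, j],
                   sum(xi * xj) / (stats::sd(X[i, ]) * stats::sd(X[j, ]) * (L - 1)),
                   tolerance = 1e-12)
    }
  }

  X[2, ] <- 7
  expect_error(connectome(X), "region 2")

  # covariance kind stays available behind the flag
  expect_equal(connectome(T1, kind = "covariance")$matrix,
               covariance_of_rows(T1))
})

test_that("psd_sqrt: closed forms, multiply-back, PSD guard", {
  expect_equal(psd_sqrt(diag(c(4, 9))), diag(c(2, 3)))
  expect_equal(psd_sqrt(diag(3)), diag(3))
  withr::local_seed(2)
  A <- random_spd(6)
  R <- psd_sqrt(A)
  expect_equal(R, t(R))
  expect_lt(norm(R %*% R - A, "F") / norm(A, "F"), 1e-8)
  expect_error(psd_sqrt(diag(c(1, -0.5))), "not PSD")
  # tiny negative roundoff eigenvalues are clamped, not rejected
  expect_silent(psd_sqrt(A - 1e-14 * diag(6)))
})

test_that("fidelity matches self-, commuting- and 2x2 analytic oracles", {
  expect_equal(fidelity(diag(3), diag(3)), 9)
  withr::local_seed(3)
  A <- random_spd(5)
  expect_equal(fidelity(A, A), sum(diag(A))^2, tolerance = 1e-8)

  # commuting diagonal closed form (sum sqrt(a_i b_i))^2
  expect_equal(fidelity(diag(c(1, 4)), diag(c(4, 1))), 16)
  for (rep in 1:20) {
    a <- runif(4, 0.1, 3); b <- runif(4, 0.1, 3)
    expect_equal(fidelity(diag(a), diag(b)), sum(sqrt(a * b))^2,
                 tolerance = 1e-8)
  }

  # independent 2x2 analytic oracle: F = tr(AB) + 2 sqrt(det(AB))
  for (rep in 1:50) {
    A <- random_spd(2); B <- random_spd(2)
    expect_equal(fidelity(A, B),
                 sum(diag(A %*% B)) + 2 * sqrt(det(A %*% B)),
                 tolerance = 1e-8)
    expect_equal(fidelity(A, B), fidelity(B, A), tolerance = 1e-8)
  }
  expect_error(fidelity(diag(2), diag(3)), "size mismatch")
})

test_that("Bures distance: identity, diagonal closed form, correlation trace identity", {
  withr::local_seed(4)
  A <- random_spd(5)
  expect_identical(bures_distance(A, A), 0)
  expect_equal(bures_distance(diag(c(1, 1)), diag(c(4, 1))), 1)
  for (rep in 1:20) {
    a <- runif(3, 0.1, 3); b <- runif(3, 0.1, 3)
    expect_equal(bures_distance(diag(a), diag(b)),
                 sqrt(sum((sqrt(a) - sqrt(b))^2)), tolerance = 1e-8)
  }
  # for correlation matrices (trace m): dB^2 = 2m - 2 sqrt(F)
  for (rep in 1:10) {
    m <- 4
    A <- random_correlation(m); B <- random_correlation(m)
    expect_equal(bures_distance(A, B)^2, 2 * m - 2 * sqrt(fidelity(A, B)),
                 tolerance = 1e-8)
  }
})

test_that("Bures metric axioms hold on random SPD samples", {
  withr::local_seed(5)
  for (rep in 1:30) {
    A <- random_spd(4); B <- random_spd(4); C <- random_spd(4)
    dab <- bures_distance(A, B)
    dba <- bures_distance(B, A)
    expect_gte(dab, 0)
    expect_lt(abs(dab - dba), 1e-10)
    expect_lte(dab, bures_distance(A, C) + bures_distance(C, B) + 1e-10)
  }
})

test_that("Frobenius distance closed forms and shift sensitivity", {
  A <- matrix(c(1, 3, 2, 4), 2)
  expect_identical(frobenius_distance(A, A), 0)
  expect_equal(frobenius_distance(A, matrix(c(1, 3, 2, 0), 2)), 4)
  # constant shift c on an m x n matrix gives sqrt(m n) |c|
  expect_equal(frobenius_distance(A, A + 1), 2)
  withr::local_seed(6)
  X <- matrix(rnorm(12), 3, 4)
  expect_equal(frobenius_distance(X, X + 2.5), sqrt(12) * 2.5)
  expect_error(frobenius_distance(X, t(X)), "size mismatch")
})

test_that("dM: identity, row-offset invariance, contrast with raw Frobenius", {
  withr::local_seed(7)
  ps <- make_parent(m = 6, L = 25, n_tasks = 2)
  expect_lt(dM_distance(ps, ps, 1, 1), 1e-10)
  expect_gt(dM_distance(ps, ps, 1, 2), 0)
  expect_equal(dM_distance(ps, ps, 1, 2), dM_distance(ps, ps, 2, 1))

  # distinct per-region constant offsets (the subject-mean phenomenon) are
  # removed exactly by de-meaning
  ps2 <- ps
  ps2$data <- ps$data + rnorm(6, sd = 50)
  expect_lt(abs(dM_distance(ps, ps2, 1, 1)), 1e-6)
  expect_lt(abs(dM_distance(ps, ps2, 1, 2) - dM_distance(ps, ps, 1, 2)), 1e-6)

  # identical task signal, different subject correlation structure: dM is
  # small relative to the raw Frobenius distance
  cfg1 <- cohort_config(n_subjects = 2, n_tasks = 4, m_regions = 12,
                        timepoints_per_task = 30, task_signal_strength = 5,
                        seed = 11)
  p1 <- generate_parent_scan(cfg1, 1)
  p2 <- generate_parent_scan(cfg1, 2)
  raw1 <- extract_task_scans(p1)[[1]]$data
  raw2 <- extract_task_scans(p2)[[1]]$data
  expect_lt(dM_distance(p1, p2, 1, 1) / frobenius_distance(raw1, raw2), 1)

  # unequal task lengths surface as an error unless truncation is requested
  ann <- task_annotation(c(0, 10), c(10, 30), c("A", "B"))
  pu <- parent_scan(matrix(rnorm(6 * 30), 6, 30), "s2", ann)
  expect_error(dM_distance(pu, pu, 1, 2), "truncate")
  expect_warning(d <- dM_distance(pu, pu, 1, 2, truncate = TRUE), "truncating")
  expect_gt(d, 0)
})

test_that("pairwise_distances agrees entrywise with direct metric calls", {
  withr::local_seed(8)
  cfg <- cohort_config(n_subjects = 2, n_tasks = 3, m_regions = 8,
                       timepoints_per_task = 20, seed = 3)
  parents <- list(generate_parent_scan(cfg, 1), generate_parent_scan(cfg, 2))
  scans <- unlist(lapply(parents, extract_task_scans), recursive = FALSE)

  Df <- pairwise_distances(scans, "frobenius_raw")
  Db <- pairwise_distances(scans, "bures_connectome")
  n <- length(scans)
  expect_identical(dim(Df$values), c(n, n))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      expect_identical(Df$values[i, j],
                       frobenius_distance(scans[[i]], scans[[j]]))
      expect_identical(Db$values[i, j],
                       bures_distance(connectome(scans[[i]]),
                                      connectome(scans[[j]])))
    }
  }

  # dM route: whitening once per parent equals the per-pair definition
  Dm <- pairwise_distances(parents, "dM")
  expect_equal(Dm$values[1, 4], dM_distance(parents[[1]], parents[[2]], 1, 1),
               tolerance = 1e-10)
  expect_equal(Dm$values[2, 6], dM_distance(parents[[1]], parents[[2]], 2, 3),
               tolerance = 1e-10)

  # N = 2 reduces to the direct call; identical objects give a zero matrix
  D2 <- pairwise_distances(scans[1:2], "frobenius_raw")
  expect_identical(D2$values[1, 2], frobenius_distance(scans[[1]], scans[[2]]))
  same <- list(scans[[1]], scans[[1]], scans[[1]])
  expect_true(all(pairwise_distances(same, "frobenius_raw")$values == 0))
  # Bures on identical connectomes is zero up to eigensolver roundoff
  expect_lt(max(pairwise_distances(same, "bures_connectome")$values), 1e-6)
})

test_that("scale invariances: connectome and Bures ignore per-row affine rescaling", {
  withr::local_seed(9)
  X <- matrix(rnorm(5 * 60), 5, 60)
  a <- runif(5, 0.5, 3); b <- rnorm(5, sd = 10)
  Y <- X * a + b
  expect_equal(connectome(Y)$matrix, connectome(X)$matrix, tolerance = 1e-12)
  Z <- matrix(rnorm(5 * 60), 5, 60)
  expect_lt(abs(bures_distance(connectome(Y), connectome(Z)) -
                bures_distance(connectome(X), connectome(Z))), 1e-10)
})
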