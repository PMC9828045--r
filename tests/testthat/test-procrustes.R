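test_that("rigidly transformed copies of one shape align to distance zero", {
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.3, 0.3, 1))
  rot90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  arr <- array(NA_real_, c(2, 4, 3))
  arr[1, , ] <- base
  arr[2, , ] <- 2 * base %*% rot90 + 5
  al <- gpa(landmark_dataset(arr))
  expect_lt(max(abs(al$coords[1, , ] - al$coords[2, , ])), 1e-9)
  # sqrt(1 - g^2) loses half the working precision near g = 1
  expect_lt(procrustes_distance(arr[1, , ], arr[2, , ]), 1e-6)
  expect_equal(unname(al$centroid_sizes[2] / al$centroid_sizes[1]), 2)
})

test_that("a single specimen is returned centred at unit centroid size", {
  ds <- random_dataset(1, 6, seed = 2)
  al <- gpa(ds)
  expect_lt(max(abs(colMeans(al$coords[1, , ]))), 1e-12)
  expect_equal(sum(al$coords[1, , ]^2), 1)
  expect_equal(unname(al$centroid_sizes[1]),
               centroid_size(ds$coords[1, , ]))
})

test_that("GPA is invariant to arbitrary rigid transformation and scaling of inputs", {
  ds <- random_dataset(7, 6, seed = 5)
  al1 <- gpa(ds)
  set.seed(99)
  arr2 <- ds$coords
  for (i in 1:7) {
    Q <- svd(matrix(stats::rnorm(9), 3))$u
    if (det(Q) < 0) Q[, 3] <- -Q[, 3]
    arr2[i, , ] <- sweep(ds$coords[i, , ] %*% Q * stats::runif(1, 0.2, 5),
                         2, stats::rnorm(3, sd = 10), "+")
  }
  al2 <- gpa(landmark_dataset(arr2))
  expect_lt(max(abs(al1$coords - al2$coords)), 1e-8)
})

test_that("full Procrustes distances match an independent rotation-search oracle", {
  set.seed(7)
  configs <- replicate(10, matrix(stats::rnorm(15), 5, 3), simplify = FALSE)
  for (i in 1:4) for (j in (i + 1):5) {
    d_pkg <- procrustes_distance(configs[[i]], configs[[j]])
    d_orc <- opa_distance_oracle(configs[[i]], configs[[j]])
    expect_lt(abs(d_pkg - d_orc), 1e-6)
  }
})

test_that("degenerate and rank-deficient configurations are rejected", {
  arr <- array(0, c(2, 4, 3))
  arr[1, , ] <- matrix(stats::rnorm(12), 4)
  expect_error(gpa(landmark_dataset(arr)), "degenerate")
})

test_that("a mirror-symmetric configuration has zero asymmetric component", {
  tpl <- small_template()
  P <- nrow(tpl$coords)
  arr <- array(NA_real_, c(4, P, 3))
  for (i in 1:4) arr[i, , ] <- tpl$coords * (0.8 + 0.1 * i)
  ds <- landmark_dataset(arr, landmarks = rownames(tpl$coords))
  dec <- symmetry_decompose(gpa(ds), tpl$pairing)
  expect_lt(max(abs(dec$asymmetric)), 1e-8)
  expect_lt(max(abs(dec$coords - dec$symmetric)), 1e-8)
})

test_that("a configuration and its mirrored-relabelled copy share the symmetric component", {
  tpl <- small_template()
  lms <- rownames(tpl$coords)
  P <- length(lms)
  set.seed(21)
  conf <- tpl$coords + matrix(stats::rnorm(P * 3, sd = 0.05), P)
  # reflect y and swap left/right labels
  perm <- seq_len(P); names(perm) <- lms
  li <- match(tpl$pairing$paired[, 1], lms)
  ri <- match(tpl$pairing$paired[, 2], lms)
  perm[li] <- ri; perm[ri] <- li
  mirr <- conf; mirr[, 2] <- -mirr[, 2]; mirr <- mirr[perm, ]
  filler <- tpl$coords + matrix(stats::rnorm(P * 3, sd = 0.05), P)
  arr <- array(NA_real_, c(3, P, 3))
  arr[1, , ] <- conf; arr[2, , ] <- mirr; arr[3, , ] <- filler
  dec <- symmetry_decompose(gpa(landmark_dataset(arr, landmarks = lms)),
                            tpl$pairing)
  expect_lt(max(abs(dec$symmetric[1, , ] - dec$symmetric[2, , ])), 1e-8)
})

test_that("symmetric and asymmetric sums of squares partition the total", {
  tpl <- small_template()
  P <- nrow(tpl$coords)
  set.seed(31)
  arr <- array(rep(t(tpl$coords), each = 6), c(6, P, 3)) +
    array(stats::rnorm(6 * P * 3, sd = 0.05), c(6, P, 3))
  dec <- symmetry_decompose(gpa(landmark_dataset(arr,
                                                 landmarks = rownames(tpl$coords))),
                            tpl$pairing)
  refl <- attr(dec, "reflected")
  # per specimen pair {original, reflection}: SS about the grand mean splits
  # exactly into symmetric-component SS and asymmetry SS
  mu <- dec$mean_shape
  for (i in 1:6) {
    tot <- sum((dec$coords[i, , ] - mu)^2) + sum((refl[i, , ] - mu)^2)
    parts <- 2 * sum((dec$symmetric[i, , ] - mu)^2) +
      sum((dec$coords[i, , ] - dec$symmetric[i, , ])^2) +
      sum((refl[i, , ] - dec$symmetric[i, , ])^2)
    expect_equal(tot, parts, tolerance = 1e-12)
  }
})

test_that("noise-free allometric shape attains the minimum attainable p-value", {
  tr <- simulate_tree(10, height = 5, seed = 4)
  set.seed(4)
  cs <- exp(stats::rnorm(10, 0, 0.5))
  b <- stats::rnorm(18)
  X <- outer(log(cs), b) + matrix(2, 10, 18)
  rownames(X) <- tr$tip.label
  sh <- shapes_from_matrix(X, centroid_sizes = stats::setNames(cs,
                                                               tr$tip.label))
  res <- phylo_allometry_test(sh, tr, n_perm = 99, seed = 8)
  expect_equal(res$p_value, 1 / 100)
  expect_gt(res$effect_fraction, 0.999)
  res999 <- phylo_allometry_test(sh, tr, n_perm = 999, seed = 8)
  expect_equal(res999$p_value, 0.001)
})

test_that("size-independent shape is usually non-significant under the allometry test", {
  tr <- simulate_tree(12, height = 5, seed = 6)
  C <- species_covariance(tr, "BM")$matrix
  L <- t(chol(C))
  ps <- vapply(1:20, function(rep) {
    set.seed(100 + rep)
    X <- L %*% matrix(stats::rnorm(12 * 15), 12)
    rownames(X) <- tr$tip.label
    cs <- exp(stats::rnorm(12, 0, 0.4))
    sh <- shapes_from_matrix(X, centroid_sizes = stats::setNames(cs,
                                                                 tr$tip.label))
    phylo_allometry_test(sh, tr, n_perm = 99, seed = rep)$p_value
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.5)
})

test_that("tip/specimen mismatches and low permutation counts are flagged", {
  tr <- simulate_tree(5, seed = 1)
  X <- matrix(stats::rnorm(5 * 12), 5)
  rownames(X) <- c(tr$tip.label[-5], "intruder")
  sh <- shapes_from_matrix(X, centroid_sizes = stats::setNames(rep(1, 5),
                                                               rownames(X)))
  expect_error(phylo_allometry_test(sh, tr), "intruder")
  rownames(X) <- tr$tip.label
  sh2 <- shapes_from_matrix(X, centroid_sizes = stats::setNames(rep(1, 5),
                                                                rownames(X)))
  res <- phylo_allometry_test(sh2, tr, n_perm = 49, seed = 1)
  expect_match(res$warning, "n_perm")
})
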