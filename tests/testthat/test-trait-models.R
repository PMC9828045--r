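# shared simulation helpers for this file
sim_matrix_normal <- function(C, R, seed) {
  set.seed(seed)
  Y <- t(chol(C)) %*% matrix(stats::rnorm(nrow(C) * nrow(R)), nrow(C)) %*%
    chol(R)
  rownames(Y) <- rownames(C)
  Y
}
rand_spd <- function(q, seed) {
  set.seed(seed)
  crossprod(matrix(stats::rnorm(q * q), q)) / q + diag(q) * 0.5
}

tr38 <- simulate_tree(38, 11.5, seed = 1)

test_that("early burst with rate fixed at zero reproduces the BM fit", {
  Y <- sim_matrix_normal(species_covariance(tr38, "BM")$matrix,
                         rand_spd(8, 1), seed = 2)
  fb <- fit_trait_model(Y, tr38, "BM")
  fe <- fit_trait_model(Y, tr38, "EB", fixed_theta = 0)
  expect_equal(fe$log_lik, fb$log_lik, tolerance = 1e-6)
  expect_equal(fe$gamma, fb$gamma)
  expect_equal(fe$gic, fb$gic + 2, tolerance = 1e-6)  # one extra parameter
})

test_that("constant data are rejected rather than fitted degenerately", {
  Y <- matrix(1.5, 38, 6, dimnames = list(tr38$tip.label, NULL))
  expect_error(fit_trait_model(Y, tr38, "BM"), "zero variation")
})

test_that("shrinkage degrees of freedom interpolate between full and diagonal", {
  Y <- sim_matrix_normal(species_covariance(tr38, "BM")$matrix,
                         rand_spd(6, 3), seed = 4)
  q <- 6
  f1 <- fit_trait_model(Y, tr38, "BM", gamma_grid = 1)
  expect_equal(f1$df, q + q)                       # diagonal covariance
  f0 <- fit_trait_model(Y, tr38, "BM", gamma_grid = 1e-12)
  expect_equal(f0$df, q * (q + 1) / 2 + q, tolerance = 1e-6)
  fo <- fit_trait_model(Y, tr38, "OU", gamma_grid = 1)
  expect_equal(fo$df, 1 + q + q)
  expect_equal(gic(fo), -2 * fo$log_lik + 2 * fo$df)
})

test_that("the selected fit is at least as good as the diagonal fallback", {
  for (seed in 1:5) {
    Y <- sim_matrix_normal(species_covariance(tr38, "BM")$matrix,
                           rand_spd(10, seed + 10), seed = seed + 20)
    f <- fit_trait_model(Y, tr38, "BM")
    fdiag <- fit_trait_model(Y, tr38, "BM", gamma_grid = 1)
    expect_gte(f$cv, fdiag$cv - 1e-9)
    expect_gte(f$log_lik, fdiag$log_lik - 1e-9)
  }
})

test_that("whitened residuals of BM simulations recover the trait covariance", {
  tr <- simulate_tree(200, height = 1, seed = 5)
  C <- species_covariance(tr, "BM")$matrix
  W <- solve(t(chol(C)))
  R <- matrix(0.3, 10, 10); diag(R) <- 1
  errs <- vapply(1:20, function(rep) {
    Y <- sim_matrix_normal(C, R, seed = 800 + rep)
    Z <- W %*% Y
    norm(crossprod(Z) / 200 - R, "F") / norm(R, "F")
  }, numeric(1))
  expect_lt(max(errs), 0.3)
})

test_that("phylogenetic half-life arithmetic and monotonicity", {
  expect_equal(phylo_half_life(log(2), 1), 1)
  a <- seq(0.2, 5, by = 0.4)
  th <- vapply(a, phylo_half_life, height_myr = 11.5, numeric(1))
  expect_true(all(diff(th) < 0))                      # decreasing in alpha
  expect_equal(phylo_half_life(1.5, 23), 2 * phylo_half_life(1.5, 11.5))
  expect_error(phylo_half_life(0, 11.5), "BM")
  expect_error(phylo_half_life(-1, 11.5), "BM")
})

test_that("model support over trees handles single and repeated trees", {
  Y <- sim_matrix_normal(species_covariance(tr38, "BM")$matrix,
                         rand_spd(6, 7), seed = 8)
  ms1 <- model_support_over_trees(Y, list(tr38))
  expect_equal(sum(ms1$table$preferred_pct), 100)
  expect_equal(sort(ms1$table$preferred_pct), c(0, 0, 100))
  expect_equal(ms1$n_trees, 1L)
  ms10 <- model_support_over_trees(Y, rep(list(tr38), 5))
  expect_equal(unname(ms10$table$gic_2sd), rep(0, 3))
  expect_equal(ms10$table$preferred_pct, ms1$table$preferred_pct)
})

test_that("strongly constrained simulations prefer OU across perturbed trees", {
  utr <- tr38; utr$edge.length <- utr$edge.length / 11.5
  C <- species_covariance(utr, "OU", 2)$matrix
  rownames(C) <- colnames(C) <- tr38$tip.label
  Y <- sim_matrix_normal(C, rand_spd(20, 9), seed = 10)
  ms <- model_support_over_trees(Y, simulate_tree_set(tr38, 5, seed = 11))
  tab <- ms$table
  expect_gt(tab$preferred_pct[tab$model == "OU"], 50)
  alpha_bar <- tab$param_mean[tab$model == "OU"]
  expect_gt(alpha_bar, 0.5); expect_lt(alpha_bar, 8)
})

test_that("rate comparison is exact on its diagonal and detects a 4-fold ratio", {
  part <- module_partition("two", list(M1 = paste0("lm", 1:5),
                                       M2 = paste0("lm", 6:10)))
  C <- species_covariance(tr38, "BM")$matrix
  hits <- vapply(1:20, function(rep) {
    set.seed(900 + rep)
    X <- t(chol(C)) %*% matrix(stats::rnorm(38 * 30), 38)
    X[, 16:30] <- 2 * X[, 16:30]        # module 2 at 4x the rate
    rownames(X) <- tr38$tip.label
    rc <- multi_module_rates(shapes_from_matrix(X), part, tr38,
                             n_sim = 99, seed = rep)
    expect_equal(unname(diag(rc$pairwise_ratio)), c(1, 1))
    expect_equal(unname(diag(rc$pairwise_p)), c(1, 1))
    rc$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("rate-ratio p-values are calibrated under equal rates", {
  part <- module_partition("two", list(M1 = paste0("lm", 1:5),
                                       M2 = paste0("lm", 6:10)))
  C <- species_covariance(tr38, "BM")$matrix
  ps <- vapply(1:20, function(rep) {
    set.seed(1000 + rep)
    X <- t(chol(C)) %*% matrix(stats::rnorm(38 * 30), 38)
    rownames(X) <- tr38$tip.label
    multi_module_rates(shapes_from_matrix(X), part, tr38, n_sim = 99,
                       seed = rep)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.85)
  expect_gt(stats::sd(ps), 0.05)
})

test_that("disparity is zero for identical specimens and scales quadratically", {
  part <- module_partition("two", list(M1 = paste0("lm", 1:3),
                                       M2 = paste0("lm", 4:6)))
  X0 <- matrix(rep(stats::rnorm(18), each = 5), 5, 18)
  d0 <- module_disparity(shapes_from_matrix(X0), part)
  expect_equal(unname(d0$disparity), c(0, 0))
  set.seed(26)
  X <- X0 + matrix(stats::rnorm(90), 5)
  d1 <- module_disparity(shapes_from_matrix(X), part)
  mu <- colMeans(X)
  X2 <- sweep(X, 2, mu) * 2
  X2 <- sweep(X2, 2, mu, "+")
  d2 <- module_disparity(shapes_from_matrix(X2), part)
  expect_equal(d2$disparity, 4 * d1$disparity, tolerance = 1e-12)
})

test_that("disparity matches a hand-computed Procrustes variance", {
  part <- module_partition("two", list(M1 = paste0("lm", 1:2),
                                       M2 = paste0("lm", 3:6)))
  set.seed(27)
  X <- matrix(stats::rnorm(3 * 18), 3)
  d <- module_disparity(shapes_from_matrix(X), part)
  D <- sweep(X, 2, colMeans(X))
  expect_equal(unname(d$disparity["M1"]), sum(D[, 1:6]^2) / 3 / 2)
  expect_equal(unname(d$disparity["M2"]), sum(D[, 7:18]^2) / 3 / 4)
  expect_true(all(d$pairwise_p >= 0 & d$pairwise_p <= 1, na.rm = TRUE))
})
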