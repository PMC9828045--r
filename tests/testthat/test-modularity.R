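test_that("CR matches a hand-computed block-norm oracle on a toy covariance", {
  set.seed(12)
  M <- matrix(stats::rnorm(144), 12)
  S <- crossprod(M) / 12          # 4 landmarks x 3 coords
  a <- factor(c("A", "A", "B", "B"))
  cr_pkg <- covariance_ratio(S, a)
  # oracle: direct block arithmetic
  S0 <- S; diag(S0) <- 0
  idx <- function(l) (3 * (l - 1) + 1):(3 * l)
  blocks <- list(A = c(idx(1), idx(2)), B = c(idx(3), idx(4)))
  s12 <- sum(S0[blocks$A, blocks$B]^2)
  s11 <- sum(S0[blocks$A, blocks$A]^2)
  s22 <- sum(S0[blocks$B, blocks$B]^2)
  expect_equal(as.numeric(cr_pkg), sqrt(s12 / sqrt(s11 * s22)),
               tolerance = 1e-12)
})

test_that("zero between-module covariance gives CR = 0 and equicorrelation gives CR near 1", {
  # block-diagonal: no between-module covariance at all
  set.seed(13)
  S <- matrix(0, 12, 12)
  S[1:6, 1:6] <- crossprod(matrix(stats::rnorm(36), 6))
  S[7:12, 7:12] <- crossprod(matrix(stats::rnorm(36), 6))
  expect_equal(as.numeric(covariance_ratio(S, factor(c(1, 1, 2, 2)))), 0)
  # exchangeable data: all off-diagonal covariances equal
  P <- 8
  Sigma <- matrix(0.4, 3 * P, 3 * P); diag(Sigma) <- 1
  set.seed(14)
  X <- matrix(stats::rnorm(500 * 3 * P), 500) %*% chol(Sigma)
  cr <- covariance_ratio(stats::cov(X), factor(rep(1:2, each = 4)))
  expect_lt(abs(as.numeric(cr) - 1), 0.05)
})

test_that("a single-landmark module with no within-covariance is an error", {
  S <- diag(12)   # 4 landmarks, diagonal covariance
  expect_error(covariance_ratio(S, factor(c(1, 2, 2, 2))), "denominator")
})

test_that("the permutation test detects independent landmark blocks", {
  a <- rep(c("A", "B"), each = 6)
  hits <- vapply(1:20, function(rep) {
    X <- block_matrix(38, a, rho_within = 0.6, rho_between = 0,
                      seed = 600 + rep)
    part <- module_partition("gen", split(paste0("lm", 1:12), a))
    r <- cr_permutation_test(shapes_from_matrix(X), part, n_perm = 99,
                             seed = rep)
    r$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("an observed CR below every permutation draw attains the floor p-value", {
  a <- rep(c("A", "B"), each = 6)
  X <- block_matrix(200, a, rho_within = 0.9, rho_between = 0, seed = 15)
  part <- module_partition("gen", split(paste0("lm", 1:12), a))
  r <- cr_permutation_test(shapes_from_matrix(X), part, n_perm = 999,
                           seed = 16)
  expect_equal(r$p_value, 0.001)
  expect_lt(r$z_cr, -3)
  expect_length(r$null_distribution, 999L)
})

test_that("exchangeable data give calibrated p-values and small effect sizes", {
  a <- rep(c("A", "B"), each = 4)
  part <- module_partition("null", split(paste0("lm", 1:8), a))
  res <- lapply(1:20, function(rep) {
    X <- block_matrix(30, a, rho_within = 0.4, rho_between = 0.4,
                      seed = 700 + rep)
    cr_permutation_test(shapes_from_matrix(X), part, n_perm = 199,
                        seed = rep)
  })
  ps <- vapply(res, function(r) r$p_value, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.85)
  expect_gt(stats::sd(ps), 0.05)
  expect_lt(stats::median(abs(vapply(res, function(r) r$z_cr, numeric(1)))), 2)
})

test_that("phylogenetically corrected CR uses the evolutionary covariance", {
  tr <- simulate_tree(20, seed = 17)
  a <- rep(c("A", "B"), each = 4)
  part <- module_partition("gen", split(paste0("lm", 1:8), a))
  X <- block_matrix(20, a, rho_within = 0.7, rho_between = 0.1, seed = 18)
  rownames(X) <- tr$tip.label
  r <- cr_permutation_test(shapes_from_matrix(X), part, n_perm = 99,
                           seed = 19, tree = tr)
  expect_true(r$corrected)
  expect_true(is.finite(r$cr))
  rownames(X)[1] <- "nope"
  expect_error(cr_permutation_test(shapes_from_matrix(X), part,
                                   n_perm = 99, seed = 19, tree = tr),
               "mismatch")
})

test_that("CR rankings are invariant to input order and refuse mixed corrections", {
  a <- rep(c("A", "B"), each = 4)
  part <- module_partition("gen", split(paste0("lm", 1:8), a))
  part2 <- module_partition("alt",
                            split(paste0("lm", 1:8), rep(c("A", "B"), 4)))
  X <- block_matrix(30, a, rho_within = 0.6, rho_between = 0.1, seed = 20)
  r1 <- cr_permutation_test(shapes_from_matrix(X), part, n_perm = 99, seed = 1)
  r2 <- cr_permutation_test(shapes_from_matrix(X), part2, n_perm = 99, seed = 1)
  cmpa <- compare_cr(list(r1, r2))
  cmpb <- compare_cr(list(r2, r1))
  expect_equal(cmpa$table, cmpb$table)
  expect_equal(cmpa$z_diff["gen", "alt"], -cmpa$z_diff["alt", "gen"])
  expect_equal(unname(diag(cmpa$z_diff)), c(0, 0))
  r3 <- r2; r3$corrected <- TRUE
  expect_error(compare_cr(list(r1, r3)), "mix")
})

test_that("landmark congruence is 1 for identical and 0 for orthogonal displacements", {
  set.seed(22)
  n <- 12
  d1 <- scale(matrix(stats::rnorm(3 * n), n), scale = FALSE)  # centred
  orth <- cbind(-d1[, 2], d1[, 1], 0)         # orthogonal to d1 rowwise
  X <- cbind(d1, d1, orth, matrix(stats::rnorm(3 * n), n))
  lc <- landmark_correlations(X)
  expect_equal(lc$matrix[1, 2], 1)
  expect_lt(lc$matrix[1, 3], 1e-12)
  expect_equal(diag(lc$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(lc$matrix >= 0 & lc$matrix <= 1))
})

test_that("congruence values match a direct per-pair loop oracle", {
  set.seed(23)
  X <- matrix(stats::rnorm(5 * 9), 5)   # 5 specimens x 3 landmarks
  lc <- landmark_correlations(X)$matrix
  D <- sweep(X, 2, colMeans(X))
  for (l in 1:2) for (m in (l + 1):3) {
    num <- 0; dl <- 0; dm <- 0
    for (s in 1:5) {
      vl <- D[s, (3 * l - 2):(3 * l)]; vm <- D[s, (3 * m - 2):(3 * m)]
      num <- num + sum(vl * vm); dl <- dl + sum(vl^2); dm <- dm + sum(vm^2)
    }
    expect_equal(lc[l, m], abs(num) / sqrt(dl * dm), tolerance = 1e-12)
  }
})

test_that("a landmark with zero deviation is named in the error", {
  X <- matrix(stats::rnorm(5 * 12), 5)
  X[, 4:6] <- 1   # landmark 2 never moves
  expect_error(landmark_correlations(X, landmarks = paste0("lm", 1:4)),
               "lm2")
})

test_that("likelihoods are monotone over nested parameterization schemes", {
  tpl <- small_template()
  ledger <- builtin_ledger(tpl$organs)
  schemes <- enumerate_schemes(ledger)
  a <- as.character(partition_assignment(ledger[["H6*"]],
                                         rownames(tpl$coords)))
  X <- block_matrix(40, a, rho_within = 0.5, rho_between = 0.15, seed = 24)
  lc <- landmark_correlations(X, landmarks = rownames(tpl$coords))
  fits <- emmli_fit(lc, schemes)
  tab <- fits$table
  ml <- function(id) tab$MaxL[tab$scheme == id]
  for (h in c("H2", "H2*", "H5", "H5*", "H6", "H6*")) {
    expect_gte(ml(paste0(h, "-d")), ml(paste0(h, "-b")) - 1e-9)
    expect_gte(ml(paste0(h, "-d")), ml(paste0(h, "-c")) - 1e-9)
    expect_gte(ml(paste0(h, "-b")), ml(paste0(h, "-a")) - 1e-9)
    expect_gte(ml(paste0(h, "-c")), ml(paste0(h, "-a")) - 1e-9)
    expect_gte(ml(paste0(h, "-a")), ml("null") - 1e-9)
  }
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_true(all(tab$dAICc >= 0))
  expect_equal(tab$K, vapply(schemes, scheme_k,
                             landmarks = rownames(tpl$coords), 1L),
               ignore_attr = TRUE)
})

test_that("the AICc correction requires enough landmark pairs and effective rows", {
  expect_error(aicc(10, 6, 6), "positive")
  expect_error(aicc(10, 5, 6), "positive")
  expect_equal(aicc(10, 2, 100), -20 + 4 + 12 / 97)
  R <- diag(4); R[upper.tri(R)] <- R[lower.tri(R)] <- 0.3
  rownames(R) <- colnames(R) <- letters[1:4]
  part <- module_partition("tiny", list(M1 = c("a", "b"), M2 = c("c", "d")))
  schemes <- enumerate_schemes(list(tiny = part))
  expect_error(emmli_fit(R, schemes, n_eff = 4), "n_eff")
})

test_that("integration estimates recover the generating correlations", {
  tpl <- small_template()
  ledger <- builtin_ledger(tpl$organs)
  schemes <- enumerate_schemes(ledger)
  lms <- rownames(tpl$coords)
  a <- as.character(partition_assignment(ledger[["H6*"]], lms))
  X <- block_matrix(200, a, rho_within = 0.5, rho_between = 0.15, seed = 25)
  lc <- landmark_correlations(X, landmarks = lms)
  fits <- emmli_fit(lc, schemes)
  rep_tab <- integration_report(fits, scheme_id = "H6*-d")
  within <- rep_tab$rho[rep_tab$type == "within"]
  between <- rep_tab$rho[rep_tab$type == "between"]
  expect_true(all(within > 0.4 & within < 0.6))
  expect_true(all(between > 0.05 & between < 0.25))
  expect_gt(min(within), max(between))
})
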