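#' Covariance ratio (CR) of a partitioned landmark covariance matrix
#'
#' The CR statistic quantifies the independence of modules: for two modules
#' with covariance blocks `S11`, `S22` (within) and `S12` (between),
#' `CR = sqrt( ||S12||_F^2 / sqrt(||S11o||_F^2 ||S22o||_F^2) )` where the
#' `o` superscript denotes the within block with its diagonal zeroed. Values
#' near 0 indicate independent modules; values near 1 match a structureless
#' covariance. For more than two modules the arithmetic mean of all pairwise
#' CRs is returned.
#'
#' @param cov a `3P x 3P` covariance matrix whose columns are
#'   landmark-contiguous 3-column blocks (see [shape_matrix()]).
#' @param partition a [module_partition()] with at least 2 modules, or a
#'   module-assignment factor of length P.
#' @param landmarks landmark labels ordering the blocks (needed when
#'   `partition` is a `module_partition`).
#' @return the CR statistic (scalar); pairwise CRs are attached as
#'   attribute `"pairwise"`.
#' @export
covariance_ratio <- function(cov, partition, landmarks = NULL) {
  P <- ncol(cov) / 3L
  if (P != floor(P)) stop("covariance must have 3P columns")
  a <- partition_to_factor(partition, landmarks, P)
  B <- landmark_block_norms(cov)
  cr_from_blocks(B, a)
}

partition_to_factor <- function(partition, landmarks, P) {
  if (inherits(partition, "module_partition")) {
    if (is.null(landmarks)) stop("`landmarks` required with a module_partition")
    a <- partition_assignment(partition, landmarks)
  } else {
    a <- as.factor(partition)
  }
  if (length(a) != P)
    stop("module assignment length does not match landmark count")
  if (nlevels(droplevels(a)) < 2L) stop("at least 2 modules required")
  droplevels(a)
}

# B[l, m] = squared Frobenius norm of the 3x3 covariance block of landmarks
# l and m, computed on the covariance with its diagonal zeroed (the diagonal
# only affects within-module norms, as required by the CR definition).
landmark_block_norms <- function(cov) {
  P <- ncol(cov) / 3L
  S0 <- cov; diag(S0) <- 0
  E <- S0^2
  G <- matrix(0, 3L * P, P)
  G[cbind(seq_len(3L * P), rep(seq_len(P), each = 3))] <- 1
  crossprod(G, E %*% G)
}

cr_from_blocks <- function(B, a) {
  k <- nlevels(a)
  M <- matrix(0, nrow(B), k)
  M[cbind(seq_len(nrow(B)), as.integer(a))] <- 1
  T <- crossprod(M, B %*% M)
  pw <- matrix(NA_real_, k, k, dimnames = list(levels(a), levels(a)))
  vals <- c()
  for (g in seq_len(k - 1)) for (h in (g + 1):k) {
    den <- sqrt(T[g, g] * T[h, h])
    if (den <= 0)
      stop("zero within-module covariance for module ", levels(a)[g],
           " or ", levels(a)[h], " (CR denominator is 0)")
    pw[g, h] <- pw[h, g] <- sqrt(T[g, h] / den)
    vals <- c(vals, pw[g, h])
  }
  structure(mean(vals), pairwise = pw)
}

#' CR permutation test of a modularity hypothesis
#'
#' The observed CR is compared against a null distribution generated by
#' randomly reassigning whole landmarks (each landmark's three coordinates
#' move together) to modules, preserving module sizes. Significantly low CR
#' indicates modularity. The p-value counts null values less than or equal
#' to the observed one, with the observed value included, so the floor is
#' `1/(n_perm + 1)` (0.001 at 999 permutations). The effect size `z_cr`
#' standardizes the observed CR against the permutation distribution; more
#' negative values indicate a stronger modular signal.
#'
#' When `tree` is supplied the covariance is the evolutionary (BM) species
#' covariance of the shape coordinates — GLS-root-centred residuals whitened
#' by the phylogenetic covariance — giving the phylogenetically corrected
#' version of the test.
#'
#' @param shapes an `aligned_shapes` object (symmetric component used when
#'   present), a [landmark_dataset()], or an `S x 3P` shape matrix.
#' @param partition a [module_partition()].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param tree optional `ape::phylo` tree for phylogenetic correction.
#' @param landmarks landmark labels (required when `shapes` is a bare
#'   matrix).
#' @return an object of class `cr_result` with `cr`, `p_value`, `z_cr`,
#'   `null_distribution`, `corrected`, `n_permutations`, `hypothesis` and
#'   `pairwise` CRs.
#' @export
cr_permutation_test <- function(shapes, partition, n_perm = 999L, seed = 1L,
                                tree = NULL, landmarks = NULL) {
  if (is.matrix(shapes)) {
    X <- shapes
    if (is.null(landmarks)) stop("`landmarks` required with a bare matrix")
  } else {
    X <- shape_matrix(shapes)
    landmarks <- if (inherits(shapes, "landmark_dataset")) shapes$landmarks
                 else shapes$landmarks
  }
  if (nrow(X) < 4L) stop("at least 4 specimens required")
  warn <- NULL
  if (n_perm < 99L) warn <- "n_perm < 99: p-value resolution is poor"
  if (!is.null(tree)) {
    if (!setequal(rownames(X), tree$tip.label))
      stop("tip/specimen mismatch between shapes and tree")
    S <- evolutionary_covariance(tree, X)
  } else {
    S <- stats::cov(X)
  }
  a <- partition_to_factor(partition, landmarks, ncol(X) / 3L)
  B <- landmark_block_norms(S)
  obs <- cr_from_blocks(B, a)
  pairwise <- attr(obs, "pairwise")
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    as.numeric(cr_from_blocks(B, a[sample.int(length(a))])), numeric(1))
  p <- (1 + sum(null <= obs)) / (n_perm + 1)
  sdn <- stats::sd(null)
  if (!is.finite(sdn) || sdn == 0)
    stop("degenerate permutation distribution (sd = 0): z_cr undefined")
  structure(list(cr = as.numeric(obs), p_value = p,
                 z_cr = (as.numeric(obs) - mean(null)) / sdn,
                 null_distribution = null, corrected = !is.null(tree),
                 n_permutations = n_perm,
                 hypothesis = if (inherits(partition, "module_partition"))
                   partition$name else NA_character_,
                 pairwise = pairwise, warning = warn),
            class = "cr_result")
}

#' @export
print.cr_result <- function(x, ...) {
  cat(sprintf("CR test%s [%s]: CR = %.3f, p = %.4g, Z_CR = %.2f (%d perms)\n",
              if (x$corrected) " (phylogenetically corrected)" else "",
              x$hypothesis, x$cr, x$p_value, x$z_cr, x$n_permutations))
  invisible(x)
}

#' Rank CR results by effect size
#'
#' Orders hypotheses by `z_cr` (most negative = strongest modular signal)
#' and reports pairwise effect-size differences `z_i - z_j` with a
#' two-sample normal comparison (each `z` treated as a standard-normal
#' deviate of its own permutation distribution, so the difference has
#' variance 2). All results must come from the same dataset, permutation
#' count and correction mode.
#'
#' @param results a list of `cr_result` objects.
#' @return a list of class `cr_comparison` with `table` (hypotheses sorted
#'   by `z_cr`), `z_diff` and `p_diff` matrices.
#' @export
compare_cr <- function(results) {
  if (length(unique(vapply(results, function(r) r$corrected, TRUE))) != 1L)
    stop("cannot mix corrected and uncorrected CR results")
  if (length(unique(vapply(results, function(r) r$n_permutations, 1))) != 1L)
    stop("all results must use the same number of permutations")
  nm <- vapply(results, function(r) r$hypothesis, "")
  z <- vapply(results, function(r) r$z_cr, numeric(1))
  cr <- vapply(results, function(r) r$cr, numeric(1))
  p <- vapply(results, function(r) r$p_value, numeric(1))
  ord <- order(z)
  tab <- data.frame(hypothesis = nm[ord], cr = cr[ord], p_value = p[ord],
                    z_cr = z[ord], row.names = NULL)
  zd <- outer(z, z, "-"); dimnames(zd) <- list(nm, nm)
  pd <- 2 * stats::pnorm(-abs(zd) / sqrt(2)); dimnames(pd) <- dimnames(zd)
  structure(list(table = tab, z_diff = zd, p_diff = pd),
            class = "cr_comparison")
}

#' Landmark correlation matrix (vector congruence)
#'
#' For each pair of landmarks, the absolute congruence of their per-specimen
#' 3D displacement vectors:
#' `r_lm = |sum_s d_ls . d_ms| / sqrt(sum_s ||d_ls||^2 sum_s ||d_ms||^2)`,
#' where `d_ls` is specimen s's deviation of landmark l from the mean shape.
#' With a tree, rows are phylogenetic independent contrasts of the 3P
#' coordinate columns instead of specimen deviations (contrasts are already
#' centred), giving the phylogenetically corrected matrix with `N - 1`
#' effective rows.
#'
#' @param shapes an `aligned_shapes` object, [landmark_dataset()], array or
#'   `S x 3P` matrix.
#' @param tree optional `ape::phylo` tree for phylogenetic correction.
#' @param landmarks landmark labels (required for a bare matrix).
#' @return a list of class `landmark_correlations` with `matrix` (`P x P`,
#'   unit diagonal, entries in `[0, 1]`), `n_rows_used` and `corrected`.
#' @export
landmark_correlations <- function(shapes, tree = NULL, landmarks = NULL) {
  if (is.matrix(shapes)) {
    X <- shapes
    if (is.null(landmarks)) landmarks <- paste0("lm", seq_len(ncol(shapes) / 3))
  } else {
    X <- shape_matrix(shapes)
    landmarks <- shapes$landmarks %||% dimnames(shapes)[[2]]
  }
  if (!is.null(tree)) {
    D <- independent_contrasts(tree, X)
  } else {
    if (nrow(X) < 5L) stop("at least 5 specimens required")
    D <- sweep(X, 2, colMeans(X))
  }
  P <- ncol(X) / 3L
  full <- crossprod(D)
  A <- matrix(0, P, P)
  for (k in 1:3) {
    idx <- seq(k, by = 3L, length.out = P)
    A <- A + full[idx, idx]
  }
  d <- diag(A)
  if (any(d < 1e-20)) {
    bad <- landmarks[which(d < 1e-20)]
    stop("landmark(s) with zero total deviation: ",
         paste(bad, collapse = ", "))
  }
  r <- abs(A) / sqrt(outer(d, d))
  r[r > 1] <- 1
  diag(r) <- 1
  dimnames(r) <- list(landmarks, landmarks)
  structure(list(matrix = r, n_rows_used = nrow(D),
                 corrected = !is.null(tree)),
            class = "landmark_correlations")
}

#' Small-sample corrected AIC from a maximum log-likelihood
#'
#' `AICc = -2 MaxL + 2K + 2K(K+1)/(n - K - 1)` with `n` the number of
#' unordered landmark pairs entering the correlation likelihood.
#'
#' @param max_l maximum log-likelihood.
#' @param k number of model parameters.
#' @param n sample size (landmark pairs, `P(P-1)/2`).
#' @return the AICc value.
#' @export
aicc <- function(max_l, k, n) {
  if (n - k - 1 <= 0) stop("n - K - 1 must be positive for the AICc correction")
  -2 * max_l + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Maximum-likelihood comparison of modularity hypotheses
#'
#' Fits every parameterization scheme to a landmark correlation matrix.
#' Correlations are Fisher z-transformed (`z = atanh(min(r, 1 - 1e-9))`);
#' within each rho set the maximum-likelihood estimate is the mean in z
#' space (`rho_hat = tanh(mean z)`), and the log-likelihood sums normal
#' densities of the pair z values around their set mean with standard
#' deviation `1/sqrt(n_eff - 3)`, the classical Fisher-z sampling error.
#' Models are compared by AICc with sample size `P(P-1)/2` pairs; Akaike
#' weights give model posterior probabilities.
#'
#' @param corr a [landmark_correlations()] result or a bare `P x P`
#'   correlation matrix.
#' @param schemes a list of parameterization schemes from
#'   [enumerate_schemes()].
#' @param n_eff number of rows used to build the correlation matrix
#'   (specimens, or `N - 1` contrasts for the corrected matrix); defaults
#'   to the value recorded in `corr`.
#' @return a list of class `emmli_fits`: `table` (one row per scheme with
#'   `MaxL`, `K`, `AICc`, `dAICc`, `weight`), `rho` (named list of
#'   rho-set estimates per scheme) and `best` (id of the AICc-best scheme).
#' @export
emmli_fit <- function(corr, schemes, n_eff = NULL) {
  if (inherits(corr, "landmark_correlations")) {
    if (is.null(n_eff)) n_eff <- corr$n_rows_used
    R <- corr$matrix
  } else {
    R <- corr
    if (is.null(n_eff)) stop("`n_eff` required with a bare matrix")
  }
  if (n_eff < 5L) stop("n_eff must be at least 5")
  landmarks <- rownames(R) %||% paste0("lm", seq_len(nrow(R)))
  P <- nrow(R)
  n_pairs <- P * (P - 1) / 2
  r <- R[upper.tri(R)]
  z <- atanh(pmin(r, 1 - 1e-9))
  sdz <- 1 / sqrt(n_eff - 3)
  rows <- list(); rho <- list()
  for (sc in schemes) {
    sets <- scheme_pair_sets(sc, landmarks)
    zbar <- tapply(z, sets, mean)
    ll <- sum(stats::dnorm(z, mean = zbar[as.integer(sets)], sd = sdz,
                           log = TRUE))
    K <- nlevels(sets) + 1L
    rows[[sc$id]] <- data.frame(scheme = sc$id,
                                hypothesis = if (is.null(sc$partition))
                                  "null" else sc$partition$name,
                                letter = sc$letter,
                                n_modules = if (is.null(sc$partition)) 1L
                                  else length(sc$partition$modules),
                                MaxL = ll, K = K,
                                AICc = aicc(ll, K, n_pairs))
    rho[[sc$id]] <- tanh(zbar)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$dAICc <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$dAICc / 2)
  tab$weight <- w / sum(w)
  structure(list(table = tab, rho = rho,
                 best = tab$scheme[which.min(tab$AICc)],
                 n_eff = n_eff, n_pairs = n_pairs),
            class = "emmli_fits")
}

#' @export
print.emmli_fits <- function(x, ...) {
  cat(sprintf("modularity model selection: %d schemes, best = %s\n",
              nrow(x$table), x$best))
  best <- x$table[order(x$table$AICc)[seq_len(min(5, nrow(x$table)))], ]
  print(best, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Within/between-module integration report
#'
#' Tabulates the maximum-likelihood correlation (integration) estimates of
#' the best-fitting scheme, split into within-module and between-module-pair
#' coefficients; raw and phylogenetically corrected fits can be shown side
#' by side.
#'
#' @param fit an `emmli_fits` object (raw data).
#' @param fit_corrected optional `emmli_fits` from the phylogenetically
#'   corrected correlation matrix.
#' @param scheme_id scheme to report (default: `fit$best`).
#' @return a data frame with columns `type` (`within`/`between`), `unit`
#'   (module or module pair), `rho` and optionally `rho_corrected`.
#' @export
integration_report <- function(fit, fit_corrected = NULL, scheme_id = NULL) {
  if (is.null(scheme_id)) scheme_id <- fit$best
  rho <- fit$rho[[scheme_id]]
  if (is.null(rho)) stop("scheme ", scheme_id, " not found in fit")
  lab <- names(rho)
  type <- ifelse(grepl("^within", lab), "within",
                 ifelse(grepl("^between", lab), "between", lab))
  unit <- sub("^(within|between):?", "", lab)
  unit[unit == ""] <- "(pooled)"
  out <- data.frame(type = type, unit = unit, rho = as.numeric(rho),
                    row.names = NULL)
  if (!is.null(fit_corrected)) {
    rho2 <- fit_corrected$rho[[scheme_id]]
    if (is.null(rho2)) stop("scheme ", scheme_id, " not found in corrected fit")
    out$rho_corrected <- as.numeric(rho2[lab])
  }
  out[order(out$type, decreasing = TRUE), , drop = FALSE]
}
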