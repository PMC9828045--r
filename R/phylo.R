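#' Species covariance matrix under a trait-evolution model
#'
#' Expected covariance among tip values of a single trait evolving on the
#' tree with unit rate, under Brownian motion (BM), a single-optimum
#' Ornstein-Uhlenbeck process (OU, fixed root at the optimum), or an
#' early-burst model (EB, exponentially time-decaying rate).
#'
#' For tips i, j with shared root-to-MRCA time `t_ij` and patristic distance
#' `d_ij`:
#' * BM: `C_ij = t_ij`
#' * OU: `C_ij = exp(-alpha d_ij) (1 - exp(-2 alpha t_ij)) / (2 alpha)`
#' * EB: `C_ij = (exp(r t_ij) - 1) / r`, with the `r -> 0` limit `t_ij`
#'   taken analytically when `|r| < 1e-8`.
#'
#' The trait rate enters downstream through the trait covariance matrix R,
#' so `parameter` is the single model-specific parameter (`alpha` or `r`).
#'
#' @param tree an `ape::phylo` tree (rooted, branch lengths required).
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param parameter `alpha >= 0` for OU, any real `r` for EB (with
#'   `|r| * height <= 50`); ignored for BM.
#' @param stationary logical; if `TRUE` the stationary OU covariance
#'   `exp(-alpha d_ij) / (2 alpha)` is used instead of the fixed-root form.
#' @return a list with `matrix` (N x N, tip labels as dimnames), `model`
#'   and `parameter`.
#' @export
species_covariance <- function(tree, model = c("BM", "OU", "EB"),
                               parameter = 0, stationary = FALSE) {
  model <- match.arg(model)
  validate_tree(tree)
  tshared <- ape::vcv(tree)           # shared root-to-MRCA path lengths
  h <- tree_height(tree)
  C <- switch(model,
    BM = tshared,
    OU = {
      if (parameter < 0) stop("OU requires alpha >= 0")
      if (!ape::is.ultrametric(tree, tol = 1e-6 * max(h, 1)))
        stop("OU covariance requires an ultrametric tree")
      if (parameter == 0) tshared else {
        d <- outer(diag(tshared), diag(tshared), "+") - 2 * tshared
        if (stationary)
          exp(-parameter * d) / (2 * parameter)
        else
          exp(-parameter * d) * (1 - exp(-2 * parameter * tshared)) /
            (2 * parameter)
      }
    },
    EB = {
      if (abs(parameter) * h > 50)
        stop("|r| * height must be <= 50")
      if (abs(parameter) < 1e-8) tshared
      else (exp(parameter * tshared) - 1) / parameter
    })
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * sum(diag(C)))
    stop("species covariance is not positive semi-definite")
  list(matrix = C, model = model, parameter = parameter)
}

#' Phylogenetic independent contrasts of a trait matrix
#'
#' Standardized contrasts (Felsenstein's pruning recursion, as implemented
#' in `ape::pic`) applied column-wise to an `N x q` trait matrix.
#' Multifurcations are resolved arbitrarily with zero-length branches.
#'
#' @param tree an `ape::phylo` tree.
#' @param X numeric `N x q` matrix, rownames matching tip labels (or rows in
#'   tip-label order).
#' @return an `(N-1) x q` matrix of standardized contrasts.
#' @export
independent_contrasts <- function(tree, X) {
  X <- as.matrix(X)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  if (!is.null(rownames(X))) {
    if (!setequal(rownames(X), tree$tip.label))
      stop("rownames of X do not match tree tip labels")
    X <- X[tree$tip.label, , drop = FALSE]
  } else if (nrow(X) != length(tree$tip.label)) {
    stop("X must have one row per tip")
  }
  out <- tryCatch(
    apply(X, 2, function(col) ape::pic(stats::setNames(col, tree$tip.label),
                                       tree)),
    error = function(e) stop("contrast computation failed (possibly a ",
                             "zero-length terminal pair): ",
                             conditionMessage(e)))
  matrix(out, nrow = length(tree$tip.label) - 1L, ncol = ncol(X),
         dimnames = list(NULL, colnames(X)))
}

#' GLS estimate of the root state
#'
#' The generalized-least-squares root (phylogenetic mean) under a BM species
#' covariance C: `a = (1' C^-1 1)^-1 1' C^-1 X`.
#'
#' @param tree an `ape::phylo` tree.
#' @param X numeric `N x q` matrix, rownames matching tip labels.
#' @return a length-q vector.
#' @export
gls_root <- function(tree, X) {
  X <- as.matrix(X)
  C <- species_covariance(tree, "BM")$matrix
  if (!is.null(rownames(X))) {
    if (!setequal(rownames(X), rownames(C)))
      stop("rownames of X do not match tree tip labels")
    X <- X[rownames(C), , drop = FALSE]
  }
  Ci <- tryCatch(solve(C), error = function(e)
    stop("singular species covariance matrix"))
  one <- rep(1, nrow(C))
  drop((t(one) %*% Ci %*% X) / drop(t(one) %*% Ci %*% one))
}

# Symmetric inverse square root of a positive-definite matrix via its
# eigendecomposition; eigenvalues below tol * max are rejected.
mat_inv_sqrt <- function(C, tol = 1e-12) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < tol * max(e$values))
    stop("matrix is numerically singular")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# Evolutionary (BM) covariance of traits among species: residuals from the
# GLS root, whitened by C^-1, with denominator N - 1.
evolutionary_covariance <- function(tree, X) {
  X <- as.matrix(X)
  C <- species_covariance(tree, "BM")$matrix
  if (!is.null(rownames(X))) X <- X[rownames(C), , drop = FALSE]
  a <- gls_root(tree, X)
  R <- sweep(X, 2, a)
  crossprod(R, solve(C, R)) / (nrow(X) - 1)
}
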