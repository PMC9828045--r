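#' Penalized-likelihood fit of a multivariate trait-evolution model
#'
#' Fits BM, single-optimum OU or early-burst (EB) evolution of an `N x q`
#' coordinate block (q may exceed N) on a phylogeny. The root state is
#' profiled out by GLS; for a candidate model parameter theta (`alpha` for
#' OU, `r` for EB, none for BM) the data are whitened by
#' `C(theta)^(-1/2)`, and the trait covariance R is estimated by linear
#' shrinkage of the whitened sample covariance toward its diagonal,
#' `R(gamma) = (1 - gamma) S + gamma diag(S)`. The pair `(theta, gamma)` is
#' chosen to maximize the leave-one-species-out cross-validated predictive
#' log-density: each species is predicted from all others through the
#' conditional Gaussian implied by `C(theta)` (so a misspecified theta
#' degrades the held-out predictions), with R estimated from the remaining
#' species. The reported log-likelihood is the matrix-normal likelihood at
#' the optimum (including the `q log|C|` term, so values are comparable
#' across theta and models).
#'
#' `alpha` and `r` are parameterized per unit tree height internally (the
#' tree is rescaled to height 1 before fitting) and converted through the
#' original height for reporting, so an OU fit with `alpha = 1.33` on an
#' 11.5-Myr tree has phylogenetic half-life `ln 2 / 1.33 * 11.5 = 5.99` Myr.
#'
#' @param module_data numeric `N x q` matrix of (module) coordinates,
#'   rownames matching tip labels.
#' @param tree an `ape::phylo` tree (ultrametric required for OU).
#' @param model `"BM"`, `"OU"` or `"EB"`.
#' @param gamma_grid shrinkage intensities searched (in `(0, 1]`; 0 is
#'   excluded because the sample covariance is singular when `q >= N`).
#' @param theta_grid optional parameter grid (per unit tree height);
#'   defaults to a log-spaced grid on `[0.01, 50]` for OU and a signed
#'   log-spaced grid on `[-10, 10]` for EB.
#' @param fixed_theta optional fixed model parameter (per unit height);
#'   bypasses the theta search (e.g. `fixed_theta = 0` makes EB identical
#'   to BM).
#' @return an object of class `trait_model_fit` with elements `model`,
#'   `alpha`/`r` (per unit height), `gamma`, `trait_cov` (shrunken R),
#'   `log_lik`, `df`, `gic`, `cv`, `t_half` (Myr, OU only), `tree_height`,
#'   `n`, `q` and `boundary` (TRUE if theta was selected at a grid edge).
#' @export
fit_trait_model <- function(module_data, tree, model = c("BM", "OU", "EB"),
                            gamma_grid = c(0.01, 0.05, 0.1, 0.2, 0.4, 0.7, 1),
                            theta_grid = NULL, fixed_theta = NULL) {
  model <- match.arg(model)
  Y <- as.matrix(module_data)
  if (!is.null(rownames(Y))) {
    if (!setequal(rownames(Y), tree$tip.label))
      stop("rownames of module_data do not match tree tip labels")
    Y <- Y[tree$tip.label, , drop = FALSE]
  } else if (nrow(Y) != length(tree$tip.label)) {
    stop("module_data must have one row per tip")
  }
  v <- apply(Y, 2, stats::var)
  if (max(v) < 1e-24)
    stop("module data have (numerically) zero variation; nothing to fit")
  # structurally constant columns (e.g. the mirrored coordinate of midline
  # landmarks in a symmetric component) carry no information and would make
  # every covariance singular; the model is fitted on the remaining columns
  keep <- v > 1e-12 * max(v)
  n_dropped <- sum(!keep)
  Y <- Y[, keep, drop = FALSE]
  N <- nrow(Y); q <- ncol(Y)
  h <- tree_height(tree)
  utree <- tree
  utree$edge.length <- utree$edge.length / h   # unit height
  if (is.null(theta_grid)) {
    theta_grid <- switch(model,
      BM = 0,
      OU = exp(seq(log(0.01), log(50), length.out = 16)),
      # positive r capped at 2/height: on an ultrametric tree an
      # accelerating-rates model with r = 2*alpha is exactly the fixed-root
      # OU covariance (ACDC equivalence), so larger r would duplicate OU
      EB = c(-exp(seq(log(10), log(0.01), length.out = 8)),
             exp(seq(log(0.01), log(2), length.out = 6))))
  }
  if (!is.null(fixed_theta)) theta_grid <- fixed_theta
  if (model == "BM") theta_grid <- 0
  best <- NULL
  for (theta in theta_grid) {
    C <- species_covariance(utree, model, theta)$matrix
    eC <- sym_eigen(C)
    if (is.null(eC) || min(eC$values) < 1e-12 * max(eC$values)) next
    W <- eC$vectors %*% (t(eC$vectors) / sqrt(eC$values))
    Pm <- eC$vectors %*% (t(eC$vectors) / eC$values)   # C^-1
    logdetC <- sum(log(eC$values))
    Ci1 <- Pm %*% rep(1, N)
    a <- drop(crossprod(Ci1, Y)) / sum(Ci1)
    Yc <- sweep(Y, 2, a)
    Z <- W %*% Yc
    G <- crossprod(Z)
    # leave-one-species-out conditional residuals and variances:
    # y_i | y_-i ~ N(mu_i, v_i R) with v_i = 1/P_ii and
    # y_i - mu_i = (P Yc)_i / P_ii (precision-matrix identities)
    pii <- diag(Pm)
    Etil <- (Pm %*% Yc) / sqrt(pii)        # residuals / sqrt(v_i)
    logv <- -log(pii)
    for (gamma in gamma_grid) {
      cv <- loo_gaussian_score(Z, G, gamma, Etil, logv)
      if (is.null(best) || cv > best$cv)
        best <- list(theta = theta, gamma = gamma, cv = cv, Z = Z, G = G,
                     logdetC = logdetC, root = a)
    }
  }
  if (is.null(best)) stop("no admissible model parameter value found")
  S <- best$G / N
  R <- shrink_cov(S, best$gamma)
  eR <- eigen(R, symmetric = TRUE)
  if (min(eR$values) <= 0) stop("shrunken trait covariance is not positive definite")
  log_lik <- -0.5 * (N * q * log(2 * pi) + q * best$logdetC +
                     N * sum(log(eR$values)) +
                     sum(diag(solve(R, best$G))))
  n_modelpar <- if (model == "BM") 0L else 1L
  df <- n_modelpar + q + (1 - best$gamma) * q * (q + 1) / 2 + best$gamma * q
  boundary <- if (model == "BM" || !is.null(fixed_theta)) FALSE
    else best$theta %in% range(theta_grid)
  fit <- structure(list(
    model = model,
    alpha = if (model == "OU") best$theta else NA_real_,
    r = if (model == "EB") best$theta else NA_real_,
    gamma = best$gamma,
    trait_cov = R,
    root = best$root,
    log_lik = log_lik,
    df = df,
    gic = -2 * log_lik + 2 * df,
    cv = best$cv,
    t_half = if (model == "OU" && best$theta > 0)
      phylo_half_life(best$theta, h) else NA_real_,
    tree_height = h, n = N, q = q, n_dropped = n_dropped,
    boundary = boundary), class = "trait_model_fit")
  fit
}

#' @export
print.trait_model_fit <- function(x, ...) {
  par <- switch(x$model, BM = "",
                OU = sprintf(", alpha = %.3g (t1/2 = %.2f Myr)", x$alpha,
                             x$t_half),
                EB = sprintf(", r = %.3g", x$r))
  cat(sprintf("%s fit (N = %d, q = %d)%s: logLik = %.2f, gamma = %.2g, GIC = %.2f%s\n",
              x$model, x$n, x$q, par, x$log_lik, x$gamma, x$gic,
              if (x$boundary) " [parameter at grid boundary]" else ""))
  invisible(x)
}

# Leave-one-species-out cross-validated predictive log density. Row i of
# Etil holds the conditional residual of species i given all others,
# divided by sqrt of its conditional variance v_i (logv = log v_i); the
# trait covariance for the prediction is the shrunken crossprod of the
# whitened rows excluding species i.
loo_gaussian_score <- function(Z, G, gamma, Etil, logv) {
  N <- nrow(Z); q <- ncol(Z)
  total <- 0
  for (i in seq_len(N)) {
    Si <- (G - tcrossprod(Z[i, ])) / (N - 1)
    Ri <- shrink_cov(Si, gamma)
    ch <- tryCatch(chol(Ri), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    v <- backsolve(ch, Etil[i, ], transpose = TRUE)
    total <- total - 0.5 * (q * log(2 * pi) + q * logv[i] +
                            2 * sum(log(diag(ch))) + sum(v^2))
  }
  total
}

# Symmetric eigendecomposition with an SVD fallback (dsyevr can fail on
# matrices with tightly clustered tiny eigenvalues); NULL if both fail.
sym_eigen <- function(C) {
  e <- tryCatch(eigen(C, symmetric = TRUE), error = function(err) NULL)
  if (!is.null(e)) return(e)
  s <- tryCatch(svd(C), error = function(err) NULL)
  if (is.null(s)) return(NULL)
  list(values = s$d, vectors = s$u)
}

shrink_cov <- function(S, gamma) {
  R <- (1 - gamma) * S
  diag(R) <- diag(R) + gamma * diag(S)
  R
}

#' Generalized information criterion of a trait-model fit
#'
#' `GIC = -2 logLik + 2 df`, where the model degrees of freedom count the
#' evolutionary parameter (0 for BM, 1 for OU or EB), the q root states,
#' and the effective covariance degrees of freedom of the shrunken R,
#' interpolated between the full `q(q+1)/2` (no shrinkage) and the diagonal
#' `q` (full shrinkage): `df_R = (1 - gamma) q(q+1)/2 + gamma q`. Lower is
#' better.
#'
#' @param fit a `trait_model_fit`.
#' @return the GIC value.
#' @export
gic <- function(fit) {
  if (!inherits(fit, "trait_model_fit")) stop("`fit` must be a trait_model_fit")
  fit$gic
}

#' Phylogenetic half-life of an OU process
#'
#' The expected time to cover half the distance from the ancestral state to
#' the optimum: `t_1/2 = ln 2 / alpha`. With `alpha` expressed per unit
#' tree height, multiplication by the height in Myr yields the half-life in
#' Myr; values well below the tree height indicate a strong constraint.
#'
#' @param alpha OU rate-of-adaptation parameter (per unit tree height),
#'   must be positive.
#' @param height_myr tree height in Myr.
#' @return half-life in Myr.
#' @export
phylo_half_life <- function(alpha, height_myr) {
  if (alpha <= 0) stop("alpha must be positive (alpha = 0: OU collapses to BM)")
  if (height_myr <= 0) stop("height_myr must be positive")
  log(2) / alpha * height_myr
}

#' Trait-model support across a set of trees
#'
#' Fits every model on every tree and summarizes the GIC distribution per
#' model (mean and 2 SD) along with the percentage of trees on which each
#' model attains the lowest GIC. Ties go to the earlier model in the fixed
#' order BM, EB, OU. Trees on which any fit fails are excluded with a
#' warning and `n_trees` decremented.
#'
#' @param module_data numeric `N x q` matrix, rownames matching tip labels.
#' @param trees a list of `ape::phylo` trees sharing the tip set.
#' @param models character vector of models to fit.
#' @param ... passed to [fit_trait_model()].
#' @return a list of class `model_support_summary` with `table` (per model:
#'   `gic_mean`, `gic_2sd`, `preferred_pct`, mean parameter estimate),
#'   `gic` (tree x model matrix) and `n_trees`.
#' @export
model_support_over_trees <- function(module_data, trees,
                                     models = c("BM", "EB", "OU"), ...) {
  models <- match.arg(models, c("BM", "EB", "OU"), several.ok = TRUE)
  models <- c("BM", "EB", "OU")[c("BM", "EB", "OU") %in% models]
  if (!length(trees)) stop("at least one tree is required")
  tips <- sort(trees[[1]]$tip.label)
  for (tr in trees) if (!identical(sort(tr$tip.label), tips))
    stop("all trees must share the same tip set")
  gics <- matrix(NA_real_, length(trees), length(models),
                 dimnames = list(NULL, models))
  pars <- matrix(NA_real_, length(trees), length(models),
                 dimnames = list(NULL, models))
  ok <- rep(TRUE, length(trees))
  for (i in seq_along(trees)) {
    for (m in models) {
      f <- tryCatch(fit_trait_model(module_data, trees[[i]], m, ...),
                    error = function(e) NULL)
      if (is.null(f)) { ok[i] <- FALSE; break }
      gics[i, m] <- f$gic
      pars[i, m] <- switch(m, BM = NA_real_, OU = f$alpha, EB = f$r)
    }
  }
  if (!all(ok)) {
    warning(sum(!ok), " tree(s) excluded due to fit failures")
    gics <- gics[ok, , drop = FALSE]
    pars <- pars[ok, , drop = FALSE]
  }
  if (!nrow(gics)) stop("all trees failed to fit")
  pref <- models[apply(gics, 1, which.min)]   # which.min takes first on ties
  tab <- data.frame(
    model = models,
    gic_mean = colMeans(gics),
    gic_2sd = 2 * apply(gics, 2, stats::sd),
    preferred_pct = 100 * vapply(models, function(m) mean(pref == m),
                                 numeric(1)),
    param_mean = colMeans(pars),
    param_2sd = 2 * apply(pars, 2, stats::sd),
    row.names = NULL)
  structure(list(table = tab, gic = gics, n_trees = nrow(gics)),
            class = "model_support_summary")
}

#' @export
print.model_support_summary <- function(x, ...) {
  cat(sprintf("model support over %d tree(s):\n", x$n_trees))
  print(x$table, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Multivariate net rates of shape evolution per module
#'
#' Per module m, the net rate is
#' `sigma2_mult_m = sum_i ||y_i,m||^2 / (N p_m)`, where the `y_i` are the
#' BM-whitened, GLS-root-centred shape coordinates restricted to module m
#' and `p_m` its landmark count (per-landmark standardization makes modules
#' of different size comparable). The observed statistic is the max/min
#' rate ratio; its null distribution is generated by simulating BM data on
#' the tree under a common-rate pooled covariance (the estimated
#' evolutionary correlation structure with every coordinate's variance set
#' to the pooled mean), with the observed statistic included in the null
#' set. Pairwise ratios are tested against their own simulated nulls.
#'
#' @param shapes an `aligned_shapes` object (symmetric component used when
#'   present) or `S x 3P` matrix with tip-label rownames.
#' @param partition a [module_partition()].
#' @param tree an `ape::phylo` tree.
#' @param n_sim number of BM simulations for the null.
#' @param seed integer seed.
#' @param landmarks landmark labels (required for a bare matrix).
#' @return a list of class `rate_comparison` with `rates` (named per-module
#'   sigma2_mult), `observed_ratio`, `p_value`, `pairwise_p`, `n_sim`.
#' @export
multi_module_rates <- function(shapes, partition, tree, n_sim = 999L,
                               seed = 1L, landmarks = NULL) {
  if (is.matrix(shapes)) {
    X <- shapes
    if (is.null(landmarks)) stop("`landmarks` required with a bare matrix")
  } else {
    X <- shape_matrix(shapes)
    landmarks <- shapes$landmarks
  }
  a <- partition_assignment(partition, landmarks)
  if (any(table(a) == 0L)) stop("empty module")
  if (!setequal(rownames(X), tree$tip.label))
    stop("tip/specimen mismatch between shapes and tree")
  X <- X[tree$tip.label, , drop = FALSE]
  N <- nrow(X)
  C <- species_covariance(tree, "BM")$matrix
  W <- mat_inv_sqrt(C)
  col_mod <- rep(as.character(a), each = 3L)
  p_m <- table(a)
  rate_of <- function(M) {  # M: whitened, centred S x 3P matrix
    ss <- colSums(M^2)
    agg <- tapply(ss, col_mod, sum)[levels(a)]
    stats::setNames(as.numeric(agg) / (N * as.numeric(p_m[levels(a)])),
                    levels(a))
  }
  whiten <- function(Y) {
    Ci1 <- solve(C, rep(1, N))
    root <- drop(crossprod(Ci1, Y)) / sum(Ci1)
    W %*% sweep(Y, 2, root)
  }
  Z <- whiten(X)
  rates <- rate_of(Z)
  obs <- max(rates) / min(rates)
  k <- nlevels(a)
  obs_pw <- matrix(1, k, k, dimnames = list(levels(a), levels(a)))
  for (g in seq_len(k)) for (h in seq_len(k))
    obs_pw[g, h] <- max(rates[g], rates[h]) / min(rates[g], rates[h])
  # common-rate null covariance: estimated correlations, pooled variance
  Shat <- crossprod(Z) / (N - 1)
  vbar <- mean(diag(Shat))
  Rnull <- vbar * stats::cov2cor(Shat)
  eR <- eigen(Rnull, symmetric = TRUE)
  Rhalf <- eR$vectors %*% (t(eR$vectors) * sqrt(pmax(eR$values, 0)))
  Lc <- t(chol(C))
  set.seed(seed)
  null_ratio <- numeric(n_sim)
  null_pw <- array(NA_real_, c(n_sim, k, k))
  for (b in seq_len(n_sim)) {
    Yb <- Lc %*% matrix(stats::rnorm(N * ncol(X)), N) %*% Rhalf
    rownames(Yb) <- tree$tip.label
    rb <- rate_of(whiten(Yb))
    null_ratio[b] <- max(rb) / min(rb)
    for (g in seq_len(k)) for (h in seq_len(k))
      null_pw[b, g, h] <- max(rb[g], rb[h]) / min(rb[g], rb[h])
  }
  p <- (1 + sum(null_ratio >= obs)) / (n_sim + 1)
  pw_p <- matrix(1, k, k, dimnames = dimnames(obs_pw))
  for (g in seq_len(k)) for (h in seq_len(k)) {
    if (g == h) next
    pw_p[g, h] <- (1 + sum(null_pw[, g, h] >= obs_pw[g, h])) / (n_sim + 1)
  }
  structure(list(rates = rates, observed_ratio = obs, p_value = p,
                 pairwise_ratio = obs_pw, pairwise_p = pw_p, n_sim = n_sim),
            class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat("multivariate rate comparison (sigma2_mult per module):\n")
  print(signif(x$rates, 4))
  cat(sprintf("max/min ratio = %.3f, p = %.4g (%d simulations)\n",
              x$observed_ratio, x$p_value, x$n_sim))
  invisible(x)
}

#' Per-module morphological disparity (Procrustes variance)
#'
#' Disparity of module m is the Procrustes variance of its landmarks,
#' standardized by landmark count:
#' `(sum_i ||x_i,m - xbar_m||^2 / N) / p_m`. Pairwise differences are
#' evaluated by treating each species' per-landmark-standardized squared
#' deviation as a replicate observation in a one-way layout and applying
#' Tukey's HSD with multiplicity-adjusted p-values.
#'
#' @param shapes an `aligned_shapes` object (symmetric component used when
#'   present) or `S x 3P` matrix.
#' @param partition a [module_partition()].
#' @param landmarks landmark labels (required for a bare matrix).
#' @return a list of class `disparity_result` with `disparity` (named
#'   vector), `pairwise_p` (Tukey-adjusted), and `per_specimen` (the
#'   replicate observations).
#' @export
module_disparity <- function(shapes, partition, landmarks = NULL) {
  if (is.matrix(shapes)) {
    X <- shapes
    if (is.null(landmarks)) stop("`landmarks` required with a bare matrix")
  } else {
    X <- shape_matrix(shapes)
    landmarks <- shapes$landmarks
  }
  if (nrow(X) < 3L) stop("at least 3 specimens required")
  a <- partition_assignment(partition, landmarks)
  col_mod <- rep(as.character(a), each = 3L)
  D <- sweep(X, 2, colMeans(X))
  p_m <- table(a)
  per_spec <- sapply(levels(a), function(m)
    rowSums(D[, col_mod == m, drop = FALSE]^2) / as.numeric(p_m[m]))
  disparity <- colMeans(per_spec)
  long <- data.frame(dev = as.vector(per_spec),
                     module = factor(rep(levels(a), each = nrow(X)),
                                     levels = levels(a)))
  k <- nlevels(a)
  pw <- matrix(NA_real_, k, k, dimnames = list(levels(a), levels(a)))
  if (k >= 2L && stats::var(long$dev) > 0) {
    tk <- stats::TukeyHSD(stats::aov(dev ~ module, data = long))$module
    for (rn in rownames(tk)) {
      gh <- strsplit(rn, "-", fixed = TRUE)[[1]]
      pw[gh[1], gh[2]] <- pw[gh[2], gh[1]] <- tk[rn, "p adj"]
    }
  }
  diag(pw) <- 1
  structure(list(disparity = disparity, pairwise_p = pw,
                 per_specimen = per_spec),
            class = "disparity_result")
}

#' @export
print.disparity_result <- function(x, ...) {
  cat("per-module disparity (Procrustes variance / landmark count):\n")
  print(signif(x$disparity, 4))
  invisible(x)
}
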