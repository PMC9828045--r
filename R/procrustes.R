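#' Generalized Procrustes Analysis (GPA)
#'
#' Iterative superimposition separating shape from size, position and
#' orientation: each configuration is centred, scaled to unit centroid size,
#' and rotated (proper rotations only, determinant +1) onto the iteratively
#' re-estimated mean shape, which is itself re-standardized to unit centroid
#' size each round. Iteration stops when the mean shape changes by less than
#' `tol` (root sum of squares).
#'
#' @param dataset a [landmark_dataset()] with `S >= 1` specimens.
#' @param tol convergence tolerance on the change in mean shape.
#' @param max_iter maximum number of alignment rounds.
#' @return an object of class `aligned_shapes` with elements `coords`
#'   (aligned `S x P x 3` array), `mean_shape` (`P x 3`), `centroid_sizes`
#'   (original sizes), and empty `symmetric`/`asymmetric` slots filled by
#'   [symmetry_decompose()].
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100L) {
  co <- dataset$coords
  S <- dim(co)[1]; P <- dim(co)[2]
  sizes <- numeric(S)
  X <- vector("list", S)
  for (i in seq_len(S)) {
    m <- co[i, , ]
    m <- sweep(m, 2, colMeans(m))
    cs <- sqrt(sum(m^2))
    if (cs < 1e-12)
      stop("degenerate (all-coincident) configuration for specimen ",
           dataset$specimens[i])
    if (qr(m)$rank < 2L)
      stop("rank-deficient configuration for specimen ", dataset$specimens[i])
    sizes[i] <- cs
    X[[i]] <- m / cs
  }
  if (S == 1L) {
    arr <- array(X[[1]], c(1, P, 3))
    return(new_aligned_shapes(arr, X[[1]], sizes, dataset))
  }
  mshape <- X[[1]]
  delta <- Inf
  for (it in seq_len(max_iter)) {
    X <- lapply(X, rotate_onto, target = mshape)
    new_mean <- Reduce(`+`, X) / S
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mshape)^2))
    mshape <- new_mean
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf("GPA did not converge in %d iterations (last delta = %.3g)",
                 max_iter, delta))
  # canonical orientation: principal axes of the mean shape with a
  # deterministic sign convention, so the alignment is invariant to
  # arbitrary pre-rotation of the inputs
  R <- principal_axes_rotation(mshape)
  mshape <- mshape %*% R
  arr <- array(NA_real_, c(S, P, 3))
  for (i in seq_len(S)) arr[i, , ] <- X[[i]] %*% R
  new_aligned_shapes(arr, mshape, sizes, dataset)
}

# Proper rotation onto the principal axes of a centred P x 3 configuration;
# axis signs fixed by the third moment along each axis (generically
# nonzero), with the last axis flipped if needed to keep det = +1.
principal_axes_rotation <- function(m) {
  V <- svd(m)$v
  for (j in 1:2) {
    s <- sum((m %*% V[, j])^3)
    if (s == 0) s <- V[which.max(abs(V[, j])), j]
    if (s < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

new_aligned_shapes <- function(arr, mshape, sizes, dataset) {
  dimnames(arr) <- list(dataset$specimens, dataset$landmarks,
                        c("x", "y", "z"))
  rownames(mshape) <- dataset$landmarks
  structure(list(coords = arr, mean_shape = mshape,
                 centroid_sizes = stats::setNames(sizes, dataset$specimens),
                 symmetric = NULL, asymmetric = NULL,
                 specimens = dataset$specimens,
                 landmarks = dataset$landmarks),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf("aligned_shapes: %d specimens x %d landmarks%s\n",
              dim(x$coords)[1], dim(x$coords)[2],
              if (!is.null(x$symmetric)) ", symmetry-decomposed" else ""))
  invisible(x)
}

# Optimal proper rotation of X onto target (both centred): the rotation R
# maximizing trace(R' X' M), with det(R) = +1 enforced so reflections are
# never fitted.
rotate_onto <- function(X, target) {
  s <- svd(crossprod(X, target))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  X %*% R
}

#' Full Procrustes distance between two configurations
#'
#' Both configurations are centred and scaled to unit centroid size; the
#' distance is then minimized over proper rotations and a scaling of the
#' first onto the second, giving `sqrt(1 - g^2)` where `g` is the (sign
#' corrected) sum of singular values of the cross-product matrix.
#'
#' @param A,B `P x 3` coordinate matrices.
#' @return a scalar in `[0, 1]`.
#' @export
procrustes_distance <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); A <- A / sqrt(sum(A^2))
  B <- sweep(B, 2, colMeans(B)); B <- B / sqrt(sum(B^2))
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  g <- sum(s$d * c(1, 1, d))
  sqrt(max(0, 1 - g^2))
}

#' Object-symmetry decomposition of aligned shapes
#'
#' Implements the standard object-symmetry protocol: for each specimen a
#' reflected-and-relabelled copy is constructed (mirror across the
#' midsagittal plane by negating one axis, swap left/right landmark labels,
#' midline landmarks fixed), a joint GPA is run over the `2S` originals and
#' reflections, and the symmetric component of each specimen is the average
#' of its two aligned copies. The asymmetric component is the remainder, so
#' symmetric + asymmetric reconstructs each aligned configuration exactly.
#'
#' @param aligned an `aligned_shapes` object from [gpa()], or a
#'   [landmark_dataset()] (aligned internally).
#' @param pairing a [symmetry_pairing()] covering all landmarks.
#' @param axis the mirrored coordinate axis (default 2 = y, i.e. the
#'   left-right axis of a configuration whose midsagittal plane is x-z).
#' @param tol,max_iter passed to the joint GPA.
#' @return an `aligned_shapes` object whose `coords` are the jointly aligned
#'   originals and whose `symmetric`/`asymmetric` components are filled;
#'   the aligned reflections are kept in attribute `"reflected"`.
#' @export
symmetry_decompose <- function(aligned, pairing, axis = 2L,
                               tol = 1e-10, max_iter = 100L) {
  if (inherits(aligned, "landmark_dataset")) aligned <- gpa(aligned, tol, max_iter)
  if (!inherits(aligned, "aligned_shapes"))
    stop("`aligned` must be aligned_shapes or landmark_dataset")
  landmarks <- aligned$landmarks
  validate_pairing(pairing, landmarks)
  S <- dim(aligned$coords)[1]; P <- length(landmarks)
  # row permutation: left <-> right, midline fixed
  perm <- seq_len(P); names(perm) <- landmarks
  li <- match(pairing$paired[, 1], landmarks)
  ri <- match(pairing$paired[, 2], landmarks)
  perm[li] <- ri; perm[ri] <- li
  reflect <- function(m) {
    m[, axis] <- -m[, axis]
    m[perm, , drop = FALSE]
  }
  big <- array(NA_real_, c(2L * S, P, 3))
  for (i in seq_len(S)) {
    big[i, , ] <- aligned$coords[i, , ]
    big[S + i, , ] <- reflect(aligned$coords[i, , ])
  }
  joint <- landmark_dataset(big,
                            specimens = c(aligned$specimens,
                                          paste0(aligned$specimens, "__refl")),
                            landmarks = landmarks)
  jal <- gpa(joint, tol = tol, max_iter = max_iter)
  orig <- jal$coords[seq_len(S), , , drop = FALSE]
  refl <- jal$coords[S + seq_len(S), , , drop = FALSE]
  sym <- (orig + refl) / 2
  asym <- orig - sym
  dimnames(orig) <- dimnames(sym) <- dimnames(asym) <-
    list(aligned$specimens, landmarks, c("x", "y", "z"))
  out <- structure(list(coords = orig, mean_shape = jal$mean_shape,
                        centroid_sizes = aligned$centroid_sizes,
                        symmetric = sym, asymmetric = asym,
                        specimens = aligned$specimens,
                        landmarks = landmarks),
                   class = "aligned_shapes")
  attr(out, "reflected") <- refl
  out
}

#' Extract the flat shape matrix from aligned shapes
#'
#' Columns are landmark-contiguous 3-column blocks (x, y, z of landmark 1,
#' then landmark 2, ...), the layout assumed by every downstream covariance
#' computation.
#'
#' @param x an `aligned_shapes` object, a [landmark_dataset()], or an
#'   `S x P x 3` array.
#' @param component `"auto"` (symmetric if available, else full aligned),
#'   `"symmetric"`, `"asymmetric"` or `"full"`.
#' @return an `S x 3P` numeric matrix with specimen rownames.
#' @export
shape_matrix <- function(x, component = c("auto", "symmetric", "asymmetric",
                                          "full")) {
  component <- match.arg(component)
  if (inherits(x, "landmark_dataset")) x <- x$coords
  if (is.array(x) && length(dim(x)) == 3L) {
    arr <- x
  } else if (inherits(x, "aligned_shapes")) {
    arr <- switch(component,
      auto = if (!is.null(x$symmetric)) x$symmetric else x$coords,
      symmetric = x$symmetric %||% stop("no symmetric component present"),
      asymmetric = x$asymmetric %||% stop("no asymmetric component present"),
      full = x$coords)
  } else stop("cannot extract a shape matrix from this object")
  S <- dim(arr)[1]; P <- dim(arr)[2]
  M <- matrix(aperm(arr, c(1, 3, 2)), S, 3L * P)
  rownames(M) <- dimnames(arr)[[1]]
  lm <- dimnames(arr)[[2]] %||% paste0("lm", seq_len(P))
  colnames(M) <- paste(rep(lm, each = 3), rep(c("x", "y", "z"), P), sep = ".")
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phylogenetic regression of shape on size (evolutionary allometry)
#'
#' Generalized least squares regression of the `S x 3P` shape matrix on log
#' centroid size under a Brownian-motion species covariance, with
#' significance assessed by randomized residual permutation (RRPP): the
#' residuals of the reduced (intercept-only) phylogenetic model are permuted
#' across species and the explained sum of squares recomputed. The reported
#' p-value includes the observed statistic in the null set, so the smallest
#' attainable value is `1 / (n_perm + 1)`.
#'
#' @param shapes an `aligned_shapes` object with centroid sizes recorded.
#' @param tree an `ape::phylo` tree whose tip labels match the specimens.
#' @param n_perm number of residual permutations (values below 99 are
#'   allowed but recorded as a warning in the result).
#' @param seed integer seed for the permutations.
#' @return a list of class `allometry_result` with `effect_fraction`
#'   (fraction of phylogenetically transformed shape variance explained by
#'   log size), `p_value`, `n_permutations` and `warning` (character or
#'   `NULL`).
#' @export
phylo_allometry_test <- function(shapes, tree, n_perm = 999L, seed = 1L) {
  if (is.null(shapes$centroid_sizes))
    stop("shapes must carry centroid sizes")
  specs <- shapes$specimens
  if (!setequal(specs, tree$tip.label))
    stop("tip/specimen mismatch: only in tree: ",
         paste(setdiff(tree$tip.label, specs), collapse = ", "),
         "; only in data: ", paste(setdiff(specs, tree$tip.label),
                                   collapse = ", "))
  warn <- NULL
  if (n_perm < 99L) warn <- "n_perm < 99: p-value resolution is poor"
  Y <- shape_matrix(shapes)
  x <- log(shapes$centroid_sizes)
  C <- species_covariance(tree, "BM")$matrix[specs, specs]
  W <- mat_inv_sqrt(C)
  Yt <- W %*% Y
  Xr <- W %*% matrix(1, length(specs), 1)          # reduced: intercept
  Xf <- W %*% cbind(1, x)                          # full: + log size
  rss <- function(X, Y) {
    Q <- qr(X)
    sum((Y - X %*% qr.coef(Q, Y))^2)
  }
  fit_r <- qr(Xr)
  fitted_r <- Xr %*% qr.coef(fit_r, Yt)
  resid_r <- Yt - fitted_r
  ss_tot <- sum(resid_r^2)
  ss_obs <- ss_tot - rss(Xf, Yt)
  set.seed(seed)
  ss_null <- vapply(seq_len(n_perm), function(i) {
    Yp <- fitted_r + resid_r[sample.int(nrow(resid_r)), , drop = FALSE]
    rr <- sum((Yp - Xr %*% qr.coef(fit_r, Yp))^2)
    rr - rss(Xf, Yp)
  }, numeric(1))
  p <- (1 + sum(ss_null >= ss_obs)) / (n_perm + 1)
  structure(list(effect_fraction = ss_obs / ss_tot, p_value = p,
                 n_permutations = n_perm, warning = warn),
            class = "allometry_result")
}

#' @export
print.allometry_result <- function(x, ...) {
  cat(sprintf(
    "phylogenetic allometry: %.1f%% of shape variance explained by log size, p = %.4g (%d permutations)\n",
    100 * x$effect_fraction, x$p_value, x$n_permutations))
  if (!is.null(x$warning)) cat("warning:", x$warning, "\n")
  invisible(x)
}
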