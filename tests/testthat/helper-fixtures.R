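# Shared fixture builders. Everything is generated in code; no data files.

# a small flower template (20 landmarks) for fast tests
small_template <- function(seed = 1L) {
  make_template(c(sepal = 6, petal = 4, labellum = 4, column = 4,
                  column_foot = 2), seed = seed)
}

# random landmark dataset (no structure)
random_dataset <- function(S, P, seed = 1L, scale = 1) {
  set.seed(seed)
  landmark_dataset(array(stats::rnorm(S * P * 3, sd = scale), c(S, P, 3)))
}

# S x 3P coordinate matrix with block-correlated landmark deviations:
# Kronecker structure Omega x I3, unit variances, iid rows.
block_matrix <- function(S, assignment, rho_within, rho_between, seed = 1L,
                         sd = 1) {
  P <- length(assignment)
  Omega <- matrix(rho_between, P, P)
  for (m in unique(assignment)) {
    idx <- which(assignment == m)
    Omega[idx, idx] <- rho_within
  }
  diag(Omega) <- 1
  set.seed(seed)
  X <- matrix(stats::rnorm(S * 3 * P), S) %*% (chol(Omega) %x% diag(3)) * sd
  rownames(X) <- paste0("s", seq_len(S))
  X
}

# independent full-Procrustes-distance oracle: numerical minimization over
# Euler angles and scale (multiple starts), never touching the package's
# closed-form SVD route
opa_distance_oracle <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); A <- A / sqrt(sum(A^2))
  B <- sweep(B, 2, colMeans(B)); B <- B / sqrt(sum(B^2))
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rx %*% Ry %*% Rz
  }
  # scale parameterized on the log so only positive scalings (no
  # reflections) are reachable, matching the proper-rotation convention
  obj <- function(par) sum((exp(par[4]) * A %*% rotmat(par[1:3]) - B)^2)
  best <- Inf
  for (s in 1:12) {
    set.seed(s)
    st <- c(stats::runif(3, -pi, pi), 0)
    o <- stats::optim(st, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  sqrt(max(0, best))
}

# brute-force shared-path-length (BM covariance) oracle: explicit root-to-tip
# path enumeration on the edge list, independent of ape::vcv
bm_vcv_oracle <- function(tree) {
  N <- length(tree$tip.label)
  root <- N + 1L
  # path of edges from root to each tip
  parent_of <- function(node) {
    e <- which(tree$edge[, 2] == node)
    if (!length(e)) NULL else e
  }
  paths <- lapply(seq_len(N), function(tip) {
    edges <- integer()
    node <- tip
    repeat {
      e <- parent_of(node)
      if (is.null(e)) break
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  })
  C <- matrix(0, N, N, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    shared <- intersect(paths[[i]], paths[[j]])
    C[i, j] <- sum(tree$edge.length[shared])
  }
  C
}

# aligned_shapes stand-in built directly from a coordinate matrix (flat
# S x 3P, landmark-contiguous) with given centroid sizes
shapes_from_matrix <- function(X, centroid_sizes = NULL,
                               landmarks = NULL) {
  S <- nrow(X); P <- ncol(X) / 3
  if (is.null(landmarks)) landmarks <- paste0("lm", seq_len(P))
  arr <- aperm(array(t(X), c(3, P, S)), c(3, 2, 1))
  dimnames(arr) <- list(rownames(X), landmarks, c("x", "y", "z"))
  structure(list(coords = arr, mean_shape = NULL,
                 centroid_sizes = centroid_sizes,
                 symmetric = NULL, asymmetric = NULL,
                 specimens = rownames(X), landmarks = landmarks),
            class = "aligned_shapes")
}
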