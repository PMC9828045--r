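#' Construct a landmark dataset
#'
#' A landmark dataset holds the raw or aligned 3D coordinates of `P` landmarks
#' digitized on each of `S` specimens (one specimen per species in a
#' macroevolutionary setting), together with unique specimen and landmark
#' labels. Coordinates are treated as unitless.
#'
#' @param coords numeric array of dimension `S x P x 3` (no `NA`/`Inf`).
#' @param specimens character vector of `S` unique specimen labels.
#'   Defaults to `dimnames(coords)[[1]]`.
#' @param landmarks character vector of `P` unique landmark labels.
#'   Defaults to `dimnames(coords)[[2]]`.
#' @param aligned logical; `TRUE` only for Procrustes-aligned data, in which
#'   case each configuration must be centred at the origin and
#'   `centroid_sizes` must be supplied.
#' @param centroid_sizes optional numeric vector of original centroid sizes.
#' @return an object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(coords, specimens = NULL, landmarks = NULL,
                             aligned = FALSE, centroid_sizes = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("`coords` must be an S x P x 3 array")
  if (any(!is.finite(coords)))
    stop("landmark coordinates contain NA/NaN/Inf values")
  S <- dim(coords)[1]; P <- dim(coords)[2]
  if (P < 4L) stop("at least 4 landmarks are required (P >= 4)")
  if (is.null(specimens)) specimens <- dimnames(coords)[[1]]
  if (is.null(landmarks)) landmarks <- dimnames(coords)[[2]]
  if (is.null(specimens)) specimens <- paste0("spec", seq_len(S))
  if (is.null(landmarks)) landmarks <- paste0("lm", seq_len(P))
  if (anyDuplicated(specimens)) stop("specimen labels must be unique")
  if (anyDuplicated(landmarks)) stop("landmark labels must be unique")
  if (length(specimens) != S || length(landmarks) != P)
    stop("label lengths do not match coordinate dimensions")
  dimnames(coords) <- list(specimens, landmarks, c("x", "y", "z"))
  if (aligned) {
    cent <- apply(coords, 1, function(m) max(abs(colMeans(m))))
    if (any(cent > 1e-8))
      stop("aligned datasets must have centroids at the origin (|centroid| < 1e-8)")
    if (is.null(centroid_sizes))
      stop("aligned datasets must record centroid sizes")
  }
  if (!is.null(centroid_sizes)) {
    if (length(centroid_sizes) != S || any(centroid_sizes <= 0))
      stop("`centroid_sizes` must be S positive values")
  }
  structure(list(coords = coords, specimens = specimens,
                 landmarks = landmarks, aligned = aligned,
                 centroid_sizes = centroid_sizes),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(sprintf("landmark_dataset: %d specimens x %d landmarks (3D)%s\n",
              length(x$specimens), length(x$landmarks),
              if (x$aligned) ", aligned" else ""))
  invisible(x)
}

#' @export
dim.landmark_dataset <- function(x) dim(x$coords)

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid; the standard size measure in geometric morphometrics.
#'
#' @param x a `P x 3` coordinate matrix.
#' @return a positive scalar.
#' @export
centroid_size <- function(x) {
  cen <- colMeans(x)
  sqrt(sum(sweep(x, 2, cen)^2))
}

#' Read a landmark dataset from file
#'
#' Two dialects are supported: a long-format CSV with columns
#' `specimen,landmark,x,y,z` (the canonical interchange format: labels are
#' explicit, so landmark identity never depends on row position), and TPS
#' with `LM3=P` coordinate blocks followed by an `ID=` line per specimen
#' (read for interoperability with digitising software).
#'
#' @param path path to the file.
#' @param format `"csv_long"` or `"tps"`.
#' @return a [landmark_dataset()]. Specimen and landmark ordering follows
#'   first appearance in the file.
#' @export
read_landmarks <- function(path, format = c("csv_long", "tps")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv_long") read_landmarks_csv(path) else read_landmarks_tps(path)
}

read_landmarks_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "landmark", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("csv_long file must have columns specimen,landmark,x,y,z")
  if (anyDuplicated(d[, c("specimen", "landmark")]))
    stop("duplicate (specimen, landmark) rows in ", path)
  specimens <- unique(d$specimen)
  landmarks <- unique(d$landmark)
  S <- length(specimens); P <- length(landmarks)
  coords <- array(NA_real_, c(S, P, 3),
                  dimnames = list(specimens, landmarks, c("x", "y", "z")))
  si <- match(d$specimen, specimens); li <- match(d$landmark, landmarks)
  coords[cbind(si, li, 1L)] <- d$x
  coords[cbind(si, li, 2L)] <- d$y
  coords[cbind(si, li, 3L)] <- d$z
  if (any(is.na(coords))) {
    miss <- which(is.na(coords[, , 1, drop = FALSE]), arr.ind = TRUE)
    stop(sprintf("ragged landmark data: specimen '%s' is missing landmark '%s'",
                 specimens[miss[1, 1]], landmarks[miss[1, 2]]))
  }
  landmark_dataset(coords, specimens, landmarks)
}

read_landmarks_tps <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3?=", lines)
  if (!length(starts)) stop("no LM= blocks found in TPS file ", path)
  configs <- list()
  for (s in starts) {
    p <- as.integer(sub("^LM3?=", "", lines[s]))
    block <- lines[(s + 1):(s + p)]
    xyz <- do.call(rbind, lapply(strsplit(block, "[ \t]+"), as.numeric))
    if (ncol(xyz) != 3L) stop("TPS block at line ", s, " is not 3D")
    idl <- lines[s + p + 1]
    if (!grepl("^ID=", idl)) stop("missing ID= line after block at line ", s)
    configs[[sub("^ID=", "", idl)]] <- xyz
  }
  pn <- vapply(configs, nrow, 1L)
  if (length(unique(pn)) != 1L)
    stop(sprintf("ragged landmark counts: specimen '%s' has %d landmarks, expected %d",
                 names(configs)[which(pn != pn[1])[1]],
                 pn[which(pn != pn[1])[1]], pn[1]))
  S <- length(configs); P <- pn[1]
  coords <- array(NA_real_, c(S, P, 3))
  for (i in seq_len(S)) coords[i, , ] <- configs[[i]]
  landmark_dataset(coords, names(configs), paste0("lm", seq_len(P)))
}

#' Write a landmark dataset
#'
#' @param dataset a [landmark_dataset()].
#' @param path output file path.
#' @param format `"csv_long"` or `"tps"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(dataset, path, format = c("csv_long", "tps")) {
  format <- match.arg(format)
  co <- dataset$coords
  if (format == "csv_long") {
    S <- dim(co)[1]; P <- dim(co)[2]
    fmt <- function(v) sub("^(-?\\d+)$", "\\1", sprintf("%.17g", v))
    d <- data.frame(
      specimen = rep(dataset$specimens, each = P),
      landmark = rep(dataset$landmarks, times = S),
      x = fmt(as.vector(t(co[, , 1]))),
      y = fmt(as.vector(t(co[, , 2]))),
      z = fmt(as.vector(t(co[, , 3]))))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_along(dataset$specimens)) {
      writeLines(sprintf("LM3=%d", dim(co)[2]), con)
      m <- co[i, , ]
      writeLines(apply(m, 1, function(r)
        paste(sprintf("%.17g", r), collapse = " ")), con)
      writeLines(paste0("ID=", dataset$specimens[i]), con)
    }
  }
  invisible(path)
}

#' Read a phylogeny from a Newick file
#'
#' The tree must be rooted with branch lengths (in Myr for a time-calibrated
#' chronogram). The returned `phylo` object (ape) is used downstream for
#' species covariance matrices and independent contrasts.
#'
#' @param path path to a Newick file (the first tree is used).
#' @return an `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  validate_tree(tr)
}

#' Read a set of phylogenies from a Newick file
#'
#' @param path path to a Newick file containing one or more trees.
#' @return a list of `ape::phylo` trees.
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- list(tr)
  lapply(tr, validate_tree)
}

validate_tree <- function(tr) {
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge))
    stop("tree has missing branch lengths")
  if (any(tr$edge.length < 0)) stop("tree has negative branch lengths")
  tr
}

#' Height of a rooted tree
#'
#' Maximum root-to-tip path length.
#'
#' @param tree an `ape::phylo` tree.
#' @return a positive scalar.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' Prune a tree to a subset of tips
#'
#' @param tree an `ape::phylo` tree.
#' @param tips character vector of tip labels to keep.
#' @return the pruned tree; path lengths among retained tips are conserved.
#' @export
prune_tree <- function(tree, tips) {
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss))
    stop("tips absent from tree: ", paste(miss, collapse = ", "))
  ape::keep.tip(tree, tips)
}

#' Construct a bilateral symmetry pairing
#'
#' Declares which landmarks form mirrored left/right pairs and which lie on
#' the midsagittal plane. Together the pairs and midline landmarks must cover
#' every landmark exactly once; this is what allows a reflected-and-relabelled
#' copy of each configuration to be built during symmetry decomposition.
#'
#' @param paired two-column character matrix (or list of length-2 vectors);
#'   column 1 = left labels, column 2 = right labels.
#' @param midline character vector of midline landmark labels.
#' @param landmarks character vector of all landmark labels to validate
#'   coverage against (optional at construction; validated again at use).
#' @return an object of class `symmetry_pairing`.
#' @export
symmetry_pairing <- function(paired, midline, landmarks = NULL) {
  if (is.list(paired)) paired <- do.call(rbind, paired)
  if (length(paired) && (!is.matrix(paired) || ncol(paired) != 2L))
    stop("`paired` must be a 2-column matrix of left/right labels")
  paired <- matrix(as.character(paired), ncol = 2,
                   dimnames = list(NULL, c("left", "right")))
  midline <- as.character(midline)
  all_lab <- c(paired, midline)
  if (anyDuplicated(all_lab))
    stop("landmark(s) appear in more than one pairing role: ",
         paste(unique(all_lab[duplicated(all_lab)]), collapse = ", "))
  obj <- structure(list(paired = paired, midline = midline),
                   class = "symmetry_pairing")
  if (!is.null(landmarks)) validate_pairing(obj, landmarks)
  obj
}

#' Validate a pairing against a landmark set
#'
#' Checks that pairs plus midline cover every landmark exactly once.
#'
#' @param pairing a [symmetry_pairing()].
#' @param landmarks character vector of landmark labels.
#' @return the pairing, invisibly; errors on gaps or unknown labels.
#' @export
validate_pairing <- function(pairing, landmarks) {
  covered <- c(pairing$paired, pairing$midline)
  miss <- setdiff(landmarks, covered)
  extra <- setdiff(covered, landmarks)
  if (length(miss))
    stop("pairing does not cover landmark(s): ", paste(miss, collapse = ", "))
  if (length(extra))
    stop("pairing refers to unknown landmark(s): ", paste(extra, collapse = ", "))
  invisible(pairing)
}

#' Read or write a symmetry pairing (YAML)
#'
#' The file holds `paired:` (a list of `[left, right]` label pairs) and
#' `midline:` (a list of labels).
#'
#' @param path file path.
#' @return for reading, a [symmetry_pairing()].
#' @export
read_symmetry_pairing <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  symmetry_pairing(y$paired, unlist(y$midline))
}

#' @rdname read_symmetry_pairing
#' @param pairing a [symmetry_pairing()] to write.
#' @export
write_symmetry_pairing <- function(pairing, path) {
  y <- list(paired = lapply(seq_len(nrow(pairing$paired)),
                            function(i) as.vector(pairing$paired[i, ])),
            midline = as.list(pairing$midline))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read a hypothesis ledger (YAML)
#'
#' The ledger maps each named modularity hypothesis to its modules and each
#' module to the landmark labels it contains, e.g.
#' ```
#' hypotheses:
#'   "H6*":
#'     category: development
#'     modules:
#'       M1: [sepA1, sepA2, ...]
#'       M2: [...]
#' ```
#' Every hypothesis is validated to be a set partition of `landmarks`
#' (if given): each landmark assigned to exactly one module.
#'
#' @param path file path.
#' @param landmarks optional character vector of landmark labels the
#'   partitions must cover.
#' @return a named list of [module_partition()] objects.
#' @export
read_hypothesis_ledger <- function(path, landmarks = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  hs <- y$hypotheses
  if (is.null(hs)) stop("ledger file must contain a top-level `hypotheses:` map")
  out <- lapply(names(hs), function(nm) {
    h <- hs[[nm]]
    module_partition(name = nm,
                     modules = lapply(h$modules, unlist),
                     category = if (is.null(h$category)) "unspecified" else h$category,
                     landmarks = landmarks)
  })
  names(out) <- names(hs)
  out
}

#' Write a hypothesis ledger (YAML)
#'
#' @param ledger a named list of [module_partition()] objects.
#' @param path file path.
#' @export
write_hypothesis_ledger <- function(ledger, path) {
  y <- list(hypotheses = lapply(ledger, function(h)
    list(category = h$category,
         modules = lapply(h$modules, as.list))))
  names(y$hypotheses) <- vapply(ledger, function(h) h$name, "")
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' @param x a data frame.
#' @param path output path.
#' @export
write_result_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
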