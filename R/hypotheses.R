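#' Construct a modularity hypothesis (module partition)
#'
#' A modularity hypothesis assigns every landmark to exactly one module.
#' Modules must be disjoint, non-empty, and jointly exhaustive over the
#' landmark set the hypothesis is applied to.
#'
#' @param name hypothesis label, e.g. `"H6*"`.
#' @param modules named list; each element is a character vector of landmark
#'   labels belonging to that module (module labels `M1`, `M2`, ... keep
#'   output tables aligned across hypotheses).
#' @param category one of `"efficiency"`, `"attraction"`, `"development"`,
#'   `"null"`, or `"unspecified"`.
#' @param landmarks optional full landmark set to validate exhaustiveness
#'   against.
#' @return an object of class `module_partition`.
#' @export
module_partition <- function(name, modules, category = "unspecified",
                             landmarks = NULL) {
  if (is.null(names(modules)) || any(!nzchar(names(modules))))
    stop("modules must be named")
  if (any(lengths(modules) == 0L))
    stop("hypothesis ", name, ": empty module")
  modules <- lapply(modules, as.character)
  all_lm <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(all_lm))
    stop("hypothesis ", name, ": landmark(s) assigned to two modules: ",
         paste(unique(all_lm[duplicated(all_lm)]), collapse = ", "))
  obj <- structure(list(name = name, category = category, modules = modules),
                   class = "module_partition")
  if (!is.null(landmarks)) validate_partition(obj, landmarks)
  obj
}

#' Validate a partition against a landmark set
#'
#' Checks that the modules are jointly exhaustive over `landmarks` and
#' contain no unknown labels (disjointness is enforced at construction).
#'
#' @param partition a [module_partition()].
#' @param landmarks character vector of landmark labels.
#' @return the partition, invisibly; errors name the hypothesis and the
#'   offending landmark(s).
#' @export
validate_partition <- function(partition, landmarks) {
  assigned <- unlist(partition$modules, use.names = FALSE)
  miss <- setdiff(landmarks, assigned)
  extra <- setdiff(assigned, landmarks)
  if (length(miss))
    stop("hypothesis ", partition$name, ": unassigned landmark(s): ",
         paste(miss, collapse = ", "))
  if (length(extra))
    stop("hypothesis ", partition$name, ": unknown landmark(s): ",
         paste(extra, collapse = ", "))
  invisible(partition)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition '%s' (%s): %d modules [%s]\n",
              x$name, x$category, length(x$modules),
              paste(sprintf("%s:%d", names(x$modules), lengths(x$modules)),
                    collapse = ", ")))
  invisible(x)
}

#' Module assignment as a factor over landmark labels
#'
#' @param partition a [module_partition()].
#' @param landmarks character vector giving the landmark ordering.
#' @return a factor of length `length(landmarks)` with module labels as
#'   levels (in module order).
#' @export
partition_assignment <- function(partition, landmarks) {
  validate_partition(partition, landmarks)
  a <- rep(NA_character_, length(landmarks))
  for (m in names(partition$modules))
    a[landmarks %in% partition$modules[[m]]] <- m
  factor(a, levels = names(partition$modules))
}

#' Built-in ledger of flower modularity hypotheses
#'
#' Generates the standard ten competing hypotheses of flower evolutionary
#' modularity for a zygomorphic orchid flower, from a per-landmark organ
#' annotation. Organs are `sepal`, `petal` (lateral petals), `labellum`,
#' `column` (column-part, i.e. excluding the foot) and `column_foot`.
#'
#' The six base hypotheses fall into three categories:
#' * efficiency — H1: labellum + column (with foot) vs. the rest;
#'   H2: sepals + lateral petals / labellum / column; H3: sepals vs.
#'   lateral petals + labellum + column;
#' * attraction — H4: column vs. the attractive remainder;
#' * development — H5: the classic whorl-based split (sepals / petal whorl
#'   including labellum / column); H6: sepals / lateral petals / labellum /
#'   column, reflecting separate developmental-genetic control of the
#'   labellum.
#'
#' Each hypothesis that separates labellum and column (H2, H4, H5, H6) gets a
#' starred counterpart (H2*, H4*, H5*, H6*) generated programmatically by
#' moving the `column_foot` landmarks (the attachment point of the labellum
#' ligament and the internal rim of the foot) into the labellum-bearing
#' module, encoding the hypothesis that the foot covaries with the hinged
#' labellum rather than with the rest of the column.
#'
#' @param organs named character vector: names are landmark labels, values
#'   are organ annotations as above.
#' @return a named list of 10 [module_partition()] objects
#'   (H1, H2, H2*, H3, H4, H4*, H5, H5*, H6, H6*).
#' @export
builtin_ledger <- function(organs) {
  valid <- c("sepal", "petal", "labellum", "column", "column_foot")
  if (is.null(names(organs)) || any(!nzchar(names(organs))))
    stop("`organs` must be a named vector (names = landmark labels)")
  bad <- setdiff(unique(organs), valid)
  if (length(bad))
    stop("unknown organ annotation(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(valid, collapse = "/"), ")")
  if (any(is.na(organs)))
    stop("missing organ annotation for landmark(s): ",
         paste(names(organs)[is.na(organs)], collapse = ", "))
  lm_of <- function(...) names(organs)[organs %in% c(...)]
  S <- lm_of("sepal"); P <- lm_of("petal"); L <- lm_of("labellum")
  C <- lm_of("column"); F <- lm_of("column_foot")
  if (!length(S) || !length(P) || !length(L) || !length(C))
    stop("each of sepal/petal/labellum/column must have at least one landmark")
  mk <- function(name, category, ...) {
    mods <- list(...)
    names(mods) <- paste0("M", seq_along(mods))
    module_partition(name, mods, category, landmarks = names(organs))
  }
  ledger <- list(
    "H1"  = mk("H1", "efficiency", c(S, P), c(L, C, F)),
    "H2"  = mk("H2", "efficiency", c(S, P), L, c(C, F)),
    "H2*" = mk("H2*", "efficiency", c(S, P), c(L, F), C),
    "H3"  = mk("H3", "efficiency", S, c(P, L, C, F)),
    "H4"  = mk("H4", "attraction", c(S, P, L), c(C, F)),
    "H4*" = mk("H4*", "attraction", c(S, P, L, F), C),
    "H5"  = mk("H5", "development", S, c(P, L), c(C, F)),
    "H5*" = mk("H5*", "development", S, c(P, L, F), C),
    "H6"  = mk("H6", "development", S, P, L, c(C, F)),
    "H6*" = mk("H6*", "development", S, P, c(L, F), C)
  )
  ledger
}

#' Enumerate correlation parameterization schemes over a hypothesis ledger
#'
#' For each modularity hypothesis, the within- and between-module landmark
#' correlations can be modelled with shared or separate coefficients:
#' * `a` — one shared within-module rho and one shared between-module rho;
#' * `b` — separate within-module rhos, shared between;
#' * `c` — shared within, separate rho per module pair;
#' * `d` — separate within-module and separate between-pair rhos.
#'
#' Two-module hypotheses admit only `a` and `b` (with a single module pair,
#' `c` and `d` duplicate them). A null scheme (one rho over all landmark
#' pairs, i.e. no modularity) is appended.
#'
#' @param ledger a list of [module_partition()] objects.
#' @return a list of scheme objects (class `parameterization_scheme`), one
#'   per hypothesis/letter combination, plus the null scheme (id `"null"`).
#'   Each carries `id`, `partition` and `letter`.
#' @export
enumerate_schemes <- function(ledger) {
  out <- list()
  for (h in ledger) {
    k <- length(h$modules)
    if (k < 2L)
      stop("hypothesis ", h$name, " has fewer than 2 modules")
    letters_used <- if (k == 2L) c("a", "b") else c("a", "b", "c", "d")
    for (lt in letters_used) {
      id <- paste0(h$name, "-", lt)
      out[[id]] <- structure(list(id = id, partition = h, letter = lt),
                             class = "parameterization_scheme")
    }
  }
  out[["null"]] <- structure(
    list(id = "null",
         partition = NULL,
         letter = "null"),
    class = "parameterization_scheme")
  out
}

#' Rho-set labels for every unordered landmark pair under a scheme
#'
#' Pairs are enumerated in upper-triangle column-major order (the order of
#' `m[upper.tri(m)]` for a `P x P` matrix), the convention used throughout
#' the likelihood fitting.
#'
#' @param scheme a `parameterization_scheme`.
#' @param landmarks character vector giving the landmark ordering.
#' @return a factor of length `P(P-1)/2`; its levels are the rho sets, each
#'   carrying one free correlation parameter.
#' @export
scheme_pair_sets <- function(scheme, landmarks) {
  P <- length(landmarks)
  ut <- which(upper.tri(diag(P)), arr.ind = TRUE)  # column-major order
  if (scheme$letter == "null")
    return(factor(rep("all", nrow(ut))))
  a <- partition_assignment(scheme$partition, landmarks)
  ai <- as.character(a[ut[, 1]]); aj <- as.character(a[ut[, 2]])
  within <- ai == aj
  pairlab <- ifelse(within, ai,
                    paste(pmin(ai, aj), pmax(ai, aj), sep = "-"))
  lab <- switch(scheme$letter,
    a = ifelse(within, "within", "between"),
    b = ifelse(within, paste0("within:", pairlab), "between"),
    c = ifelse(within, "within", paste0("between:", pairlab)),
    d = ifelse(within, paste0("within:", pairlab),
               paste0("between:", pairlab)))
  factor(lab)
}

#' Number of free parameters of a scheme
#'
#' One parameter per rho set plus one, matching the model-size convention of
#' the AICc comparisons (so the null scheme has K = 2 and the fully separate
#' scheme of a 4-module hypothesis has K = 4 + 6 + 1 = 11).
#'
#' @param scheme a `parameterization_scheme`.
#' @param landmarks landmark ordering (used to enumerate pairs).
#' @return integer K.
#' @export
scheme_k <- function(scheme, landmarks) {
  nlevels(scheme_pair_sets(scheme, landmarks)) + 1L
}
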