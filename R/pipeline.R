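#' Run the full evolutionary-modularity study workflow
#'
#' Executes the analysis stages in their canonical order: Procrustes
#' superimposition, object-symmetry decomposition, phylogenetic allometry
#' check, CR permutation tests of every hypothesis (raw and
#' phylogenetically corrected), maximum-likelihood modularity model
#' selection (raw and corrected), the integration report under the winning
#' hypothesis, per-module trait-model fitting with GIC support (optionally
#' over a set of trees), multivariate rate comparison and per-module
#' disparity. The module set passed to the trait-model stage is taken from
#' the AICc-best hypothesis unless `trait_hypothesis` overrides it (the
#' winning hypothesis may reasonably be fixed by inspecting CR, effect
#' sizes and the likelihood ranking together rather than AICc alone).
#'
#' Effect sizes in the CR table follow the convention of being reported
#' only for hypotheses whose CR is significant (`NA` otherwise).
#'
#' @param landmarks a [landmark_dataset()] or path to a landmark file.
#' @param tree an `ape::phylo` tree or path to a Newick file.
#' @param ledger a named list of [module_partition()] objects or path to a
#'   ledger YAML.
#' @param pairing a [symmetry_pairing()] or path to a pairing YAML.
#' @param n_perm permutations for the CR tests (>= 99).
#' @param seed master seed; stage seeds are derived deterministically.
#' @param allometry_correction if `TRUE` and the allometry test is run,
#'   size-residual shapes are used downstream. Off by default (the expected
#'   case for these data is a nonsignificant allometric effect, and no
#'   correction is then applied).
#' @param trait_hypothesis optional hypothesis name to use for the
#'   trait-model stage instead of the AICc winner.
#' @param trees optional list of trees (or path to a multi-tree Newick) for
#'   the model-support-over-trees summary; defaults to the single `tree`.
#' @param models trait models to fit per module.
#' @param n_sim_rates simulations for the rate-comparison null.
#' @param landmark_format format of the landmark file when `landmarks` is a
#'   path.
#' @param out_dir optional directory; when given, TSV tables and a JSON
#'   report are written there.
#' @return a list of class `study_report`.
#' @export
run_study <- function(landmarks, tree, ledger, pairing,
                      n_perm = 999L, seed = 1L,
                      allometry_correction = FALSE,
                      trait_hypothesis = NULL, trees = NULL,
                      models = c("BM", "EB", "OU"), n_sim_rates = 999L,
                      landmark_format = "csv_long", out_dir = NULL) {
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks,
                                                           landmark_format)
  if (is.character(tree)) tree <- read_tree(tree)
  if (is.character(pairing)) pairing <- read_symmetry_pairing(pairing)
  if (is.character(ledger)) ledger <- read_hypothesis_ledger(ledger)
  if (is.character(trees)) trees <- read_trees(trees)
  if (is.null(trees)) trees <- list(tree)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  validate_pairing(pairing, landmarks$landmarks)
  for (h in ledger) validate_partition(h, landmarks$landmarks)
  miss <- symdiff_labels(landmarks$specimens, tree$tip.label)
  if (length(miss))
    stop("specimen/tip mismatch: ", paste(miss, collapse = ", "))

  stage <- function(nm) message("[morphomod] stage: ", nm)
  stage("Procrustes superimposition + symmetry decomposition")
  shapes <- symmetry_decompose(gpa(landmarks), pairing)

  stage("phylogenetic allometry")
  allom <- phylo_allometry_test(shapes, tree, n_perm = n_perm,
                                seed = seed + 1L)
  if (allometry_correction && allom$p_value < 0.05) {
    stage("allometric size correction (residual shapes)")
    X <- shape_matrix(shapes)
    x <- log(shapes$centroid_sizes)
    fit <- stats::lm.fit(cbind(1, x), X)
    Xr <- sweep(fit$residuals, 2, colMeans(X), "+")
    arr <- aperm(array(t(Xr), c(3, length(shapes$landmarks), nrow(Xr))),
                 c(3, 2, 1))
    dimnames(arr) <- dimnames(shapes$symmetric)
    shapes$symmetric <- arr
  }

  stage(sprintf("CR permutation tests (%d hypotheses x %d permutations)",
                length(ledger), n_perm))
  cr_raw <- lapply(ledger, function(h)
    cr_permutation_test(shapes, h, n_perm = n_perm, seed = seed + 2L))
  cr_corr <- lapply(ledger, function(h)
    cr_permutation_test(shapes, h, n_perm = n_perm, seed = seed + 3L,
                        tree = tree))
  cr_table <- data.frame(
    hypothesis = vapply(ledger, function(h) h$name, ""),
    category = vapply(ledger, function(h) h$category, ""),
    cr = vapply(cr_raw, function(r) r$cr, 1),
    p = vapply(cr_raw, function(r) r$p_value, 1),
    z_cr = ifelse(vapply(cr_raw, function(r) r$p_value, 1) < 0.05,
                  vapply(cr_raw, function(r) r$z_cr, 1), NA_real_),
    cr_corrected = vapply(cr_corr, function(r) r$cr, 1),
    p_corrected = vapply(cr_corr, function(r) r$p_value, 1),
    z_cr_corrected = ifelse(vapply(cr_corr, function(r) r$p_value, 1) < 0.05,
                            vapply(cr_corr, function(r) r$z_cr, 1), NA_real_),
    row.names = NULL)

  stage("modularity model selection (maximum likelihood)")
  schemes <- enumerate_schemes(ledger)
  corr_raw <- landmark_correlations(shapes)
  corr_phy <- landmark_correlations(shapes, tree = tree)
  emmli_raw <- emmli_fit(corr_raw, schemes)
  emmli_corr <- emmli_fit(corr_phy, schemes)
  best_scheme <- emmli_raw$best
  best_hyp <- emmli_raw$table$hypothesis[emmli_raw$table$scheme == best_scheme]
  integ <- integration_report(emmli_raw, emmli_corr,
                              scheme_id = if (best_scheme == "null") NULL
                              else best_scheme)

  fit_hyp_name <- trait_hypothesis %||% best_hyp
  if (fit_hyp_name == "null")
    stop("the null model won the model selection; no module structure to fit")
  fit_hyp <- ledger[[fit_hyp_name]]
  if (is.null(fit_hyp)) stop("unknown hypothesis: ", fit_hyp_name)

  stage(sprintf("trait-model fitting per module of %s over %d tree(s)",
                fit_hyp_name, length(trees)))
  X <- shape_matrix(shapes)
  a <- partition_assignment(fit_hyp, shapes$landmarks)
  col_mod <- rep(as.character(a), each = 3L)
  support <- lapply(stats::setNames(levels(a), levels(a)), function(m)
    model_support_over_trees(X[, col_mod == m, drop = FALSE], trees,
                             models = models))
  support_table <- do.call(rbind, lapply(levels(a), function(m) {
    tb <- support[[m]]$table
    best_m <- tb$model[which.max(tb$preferred_pct)]
    th <- vapply(seq_len(nrow(tb)), function(i) {
      if (tb$model[i] == "OU" && isTRUE(tb$param_mean[i] > 0))
        phylo_half_life(tb$param_mean[i], tree_height(tree))
      else NA_real_
    }, numeric(1))
    data.frame(module = m, tb, t_half = th, best = tb$model == best_m)
  }))

  stage("multivariate rate comparison")
  rates <- multi_module_rates(shapes, fit_hyp, tree, n_sim = n_sim_rates,
                              seed = seed + 4L)

  stage("per-module disparity")
  disp <- module_disparity(shapes, fit_hyp)

  report <- structure(list(
    allometry = allom,
    cr_table = cr_table,
    cr_raw = cr_raw, cr_corrected = cr_corr,
    emmli = emmli_raw, emmli_corrected = emmli_corr,
    best_scheme = best_scheme, best_hypothesis = best_hyp,
    integration = integ,
    trait_hypothesis = fit_hyp_name,
    model_support = support, model_support_table = support_table,
    rates = rates, disparity = disp,
    provenance = list(seed = seed, n_perm = n_perm,
                      n_trees = length(trees),
                      n_sim_rates = n_sim_rates,
                      n_specimens = length(shapes$specimens),
                      n_landmarks = length(shapes$landmarks),
                      allometry_correction = allometry_correction,
                      package_version = as.character(
                        utils::packageVersion("morphomod")))),
    class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

symdiff_labels <- function(a, b) c(setdiff(a, b), setdiff(b, a))

#' @export
print.study_report <- function(x, ...) {
  cat("== evolutionary modularity study report ==\n")
  cat(sprintf("allometry: %.1f%% variance, p = %.3g\n",
              100 * x$allometry$effect_fraction, x$allometry$p_value))
  cat("\nCR tests (raw / phylogenetically corrected):\n")
  print(x$cr_table, row.names = FALSE, digits = 3)
  cat(sprintf("\nbest modularity model: %s (hypothesis %s)\n",
              x$best_scheme, x$best_hypothesis))
  cat("\nintegration coefficients:\n")
  print(x$integration, row.names = FALSE, digits = 2)
  cat(sprintf("\ntrait models per module of %s:\n", x$trait_hypothesis))
  print(x$model_support_table, row.names = FALSE, digits = 4)
  cat("\n"); print(x$rates); cat("\n"); print(x$disparity)
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits TSV tables mirroring the standard result layout (CR tests,
#' modularity model selection, integration coefficients, trait-model
#' support, rates, disparity) plus a machine-readable JSON report.
#'
#' @param report a `study_report` from [run_study()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_result_table(report$cr_table, file.path(out_dir, "cr_tests.tsv"))
  write_result_table(report$emmli$table,
                     file.path(out_dir, "modularity_models.tsv"))
  write_result_table(report$emmli_corrected$table,
                     file.path(out_dir, "modularity_models_corrected.tsv"))
  write_result_table(report$integration,
                     file.path(out_dir, "integration.tsv"))
  write_result_table(report$model_support_table,
                     file.path(out_dir, "trait_models.tsv"))
  json <- list(
    allometry = report$allometry[c("effect_fraction", "p_value",
                                   "n_permutations")],
    cr = report$cr_table,
    best_scheme = report$best_scheme,
    best_hypothesis = report$best_hypothesis,
    modularity_models = report$emmli$table,
    modularity_models_corrected = report$emmli_corrected$table,
    integration = report$integration,
    trait_hypothesis = report$trait_hypothesis,
    trait_models = report$model_support_table,
    rates = list(sigma2_mult = as.list(report$rates$rates),
                 observed_ratio = report$rates$observed_ratio,
                 p_value = report$rates$p_value),
    disparity = as.list(report$disparity$disparity),
    disparity_pairwise_p = report$disparity$pairwise_p,
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
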