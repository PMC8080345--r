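## End-to-end study workflow: read/align/slide/symmetrize, morphospace,
## hypothesis tests, discrimination, fossil classification, exports.

#' Run the full morphometric study workflow
#'
#' Executes the complete chain on a set of modern reference configurations
#' and (optionally) unknown/subfossil configurations:
#' superimposition ([gpa()]) with mirroring of left elements,
#' semilandmark sliding, bilateral symmetrization, PCA morphospace,
#' Procrustes ANOVA of shape on genus and log size with RRPP, pairwise
#' genus shape tests, centroid-size ANOVA with Tukey HSD, multivariate
#' phylogenetic signal on species-mean shapes (when a tree is supplied),
#' CVA with leave-one-out cross-validation, and classification of the
#' unknowns with typicality and posterior probabilities. When `out_dir`
#' is given every result surface is written as TSV plus a JSON run
#' manifest that suffices to re-run identically.
#'
#' @param modern list of [configuration()]s (or a TPS/CSV file path) —
#'   the modern reference sample, left and right elements paired by
#'   `specimen_id`.
#' @param fossils optional list of unknown [configuration()]s (or file
#'   path).
#' @param tree optional `phylo` tree (or Newick path) whose tips match
#'   the species labels.
#' @param scheme the [landmark_scheme()]; required for sliding.
#' @param group_field metadata column defining the reference groups.
#' @param n_perm permutations for ANOVA / pairwise / K_mult.
#' @param seed RNG seed used for every stochastic stage.
#' @param pc_variance cumulative-variance threshold for PC retention in
#'   the CVA.
#' @param typicality `"chisq"` or `"f"` (see
#'   [typicality_probability()]).
#' @param sliding_cycles maximum semilandmark sliding cycles.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return object of class `study_result`: list with `alignment`,
#'   `symmetric`, `pca`, `shape_anova`, `pairwise`, `size_anova`,
#'   `signal` (or `NULL`), `cva`, `loo`, `classification` (or `NULL`),
#'   and the run `manifest`.
#' @export
run_study <- function(modern, fossils = list(), tree = NULL, scheme = NULL,
                      group_field = "genus", n_perm = 999, seed = 1,
                      pc_variance = 0.90,
                      typicality = c("chisq", "f"), sliding_cycles = 5,
                      out_dir = NULL) {
  typicality <- match.arg(typicality)
  stage <- "read inputs"
  result <- tryCatch({
    if (is.character(modern)) modern <- read_any_landmarks(modern, scheme)
    if (is.character(fossils)) fossils <- read_any_landmarks(fossils, scheme)
    if (is.character(tree)) tree <- read_newick(tree)

    stage <- "generalized Procrustes alignment"
    aligned <- gpa(modern, scheme = scheme)
    stage <- "semilandmark sliding"
    if (!is.null(scheme)) {
      aligned <- slide_semilandmarks(aligned, max_cycles = sliding_cycles)
    }
    stage <- "bilateral symmetrization"
    sym <- symmetrize_pairs(aligned)

    stage <- "principal component analysis"
    space <- shape_pca(sym)

    stage <- "Procrustes ANOVA"
    shape_anova <- procrustes_anova(sym, group_field = group_field,
                                    n_perm = n_perm, seed = seed)
    stage <- "pairwise shape tests"
    pw <- pairwise_group_tests(sym, group_field = group_field,
                               n_perm = n_perm, seed = seed)
    stage <- "centroid size ANOVA"
    size_res <- size_anova_tukey(sym, group_field = group_field)

    signal <- NULL
    if (!is.null(tree)) {
      stage <- "phylogenetic signal"
      y <- t(apply(sym$shapes, 1, vec_shape))
      sp_means <- rowsum(y, sym$meta$species) /
        as.vector(table(sym$meta$species))
      signal <- kmult(sp_means, tree, n_perm = max(n_perm, 2), seed = seed)
    }

    stage <- "canonical variate analysis"
    cva <- cva_fit(space, group_field = group_field,
                   pc_variance = pc_variance)
    stage <- "cross-validation"
    loo <- loo_crossvalidate(cva)

    classification <- NULL
    if (length(fossils) > 0) {
      stage <- "classification of unknowns"
      classification <- predict(cva, fossils, typicality = typicality)
    }

    manifest <- list(
      n_modern = length(modern), n_unknowns = length(fossils),
      group_field = group_field, n_perm = n_perm, seed = seed,
      pc_variance = pc_variance, retained_pcs = cva$k,
      typicality = typicality, sliding_cycles = sliding_cycles,
      gpa_tol = 1e-10, sliding_tol = 1e-6,
      has_tree = !is.null(tree))
    structure(list(alignment = aligned, symmetric = sym, pca = space,
                   shape_anova = shape_anova, pairwise = pw,
                   size_anova = size_res, signal = signal, cva = cva,
                   loo = loo, classification = classification,
                   manifest = manifest),
              class = "study_result")
  }, error = function(e) {
    stop("study failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) write_study_outputs(result, out_dir)
  result
}

read_any_landmarks <- function(path, scheme) {
  if (grepl("\\.tps$", path, ignore.case = TRUE)) read_tps(path, scheme)
  else read_landmark_table(path, scheme,
                           sep = if (grepl("\\.tsv$", path)) "\t" else ",")
}

# write every result surface as TSV + a JSON manifest
write_study_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", row.names = FALSE,
    quote = FALSE)
  sc <- data.frame(specimen_id = result$symmetric$meta$specimen_id,
                   result$symmetric$meta[c("species", "genus")],
                   cs = result$symmetric$cs,
                   result$pca$scores, check.names = FALSE)
  w(sc, "scores.tsv")
  w(summary(result$pca), "variance_table.tsv")
  w(result$shape_anova$table, "procrustes_anova.tsv")
  w(result$pairwise, "pairwise_tests.tsv")
  w(result$size_anova$anova, "size_anova.tsv")
  w(result$size_anova$tukey, "size_tukey.tsv")
  w(result$size_anova$group_stats, "size_group_stats.tsv")
  if (!is.null(result$signal))
    w(data.frame(K_mult = result$signal$K, p = result$signal$p_value,
                 n_perm = result$signal$n_perm), "phylogenetic_signal.tsv")
  w(data.frame(specimen_id = rownames(result$cva$scores),
               group = result$cva$groups, result$cva$scores,
               check.names = FALSE), "cv_scores.tsv")
  if (!is.null(result$classification))
    w(as.data.frame(result$classification), "classification_report.tsv")
  # landmark-level warps at the observed extremes of PC1/PC2
  for (ax in 1:2) {
    rng <- range(result$pca$scores[, ax])
    warps <- rbind(
      data.frame(axis = ax, extreme = "min", landmark_id = seq_len(
        nrow(result$pca$mean_shape)),
        shape_at_score(result$pca, ax, rng[1])),
      data.frame(axis = ax, extreme = "max", landmark_id = seq_len(
        nrow(result$pca$mean_shape)),
        shape_at_score(result$pca, ax, rng[2])))
    names(warps)[4:6] <- c("x", "y", "z")
    w(warps, sprintf("warp_PC%d_extremes.tsv", ax))
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat("Morphometric study result\n=========================\n")
  print(x$alignment)
  print(x$pca)
  print(x$shape_anova)
  if (!is.null(x$signal)) print(x$signal)
  print(x$cva)
  print(x$loo)
  if (!is.null(x$classification)) print(x$classification)
  invisible(x)
}

#' Morphospace scatter plots
#'
#' PC1/PC2 (or CV1/CV2) scatter with group convex hulls; unknowns, when
#' supplied, are overplotted as filled red circles.
#'
#' @param x a [shape_pca()] or [cva_fit()].
#' @param groups group labels (defaults to the genus metadata).
#' @param unknowns optional score matrix of projected unknowns.
#' @param axes which two axes to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.shape_pca <- function(x, groups = x$meta$genus, unknowns = NULL,
                           axes = c(1, 2), ...) {
  morpho_scatter(x$scores[, axes, drop = FALSE], groups, unknowns,
                 sprintf("PC%d (%.1f%%)", axes,
                         100 * x$variance_fractions[axes]), ...)
}

#' @rdname plot.shape_pca
#' @export
plot.cva_fit <- function(x, groups = x$groups, unknowns = NULL,
                         axes = c(1, 2), ...) {
  morpho_scatter(x$scores[, axes, drop = FALSE], groups, unknowns,
                 sprintf("CV%d (%.1f%%)", axes,
                         100 * x$among_group_fractions[axes]), ...)
}

morpho_scatter <- function(sc, groups, unknowns, labs, ...) {
  groups <- factor(groups)
  pal <- grDevices::hcl.colors(max(3, nlevels(groups)), "Dark 3")
  all_pts <- if (is.null(unknowns)) sc else
    rbind(sc, unknowns[, 1:2, drop = FALSE])
  graphics::plot(all_pts, type = "n", xlab = labs[1], ylab = labs[2], ...)
  for (g in seq_len(nlevels(groups))) {
    pts <- sc[groups == levels(groups)[g], , drop = FALSE]
    if (nrow(pts) >= 3) {
      h <- grDevices::chull(pts)
      graphics::polygon(pts[h, ], border = pal[g], col = NA)
    }
    graphics::points(pts, pch = 19, col = pal[g])
  }
  if (!is.null(unknowns))
    graphics::points(unknowns[, 1:2, drop = FALSE], pch = 21, bg = "red")
  graphics::legend("topright", legend = levels(groups), col =
                     pal[seq_len(nlevels(groups))], pch = 19, cex = 0.8)
  invisible(sc)
}
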