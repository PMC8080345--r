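## Canonical variate analysis and group assignment of unknowns:
## Mahalanobis distances, typicality and posterior probabilities,
## leave-one-out cross-validation.

# symmetric inverse square root of a positive definite matrix
inv_sqrt <- function(w) {
  e <- eigen(w, symmetric = TRUE)
  if (min(e$values) <= max(e$values) * 1e-10)
    stop("singular within-group covariance; retain fewer PCs")
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

#' Number of leading PCs reaching a cumulative variance threshold
#'
#' The default "reduced set of PC scores" for CVA: the smallest number of
#' leading axes whose cumulative variance fraction reaches `threshold`,
#' capped at `n - g - 1` so the pooled within-group covariance stays
#' invertible.
#'
#' @param space a [shape_pca()].
#' @param groups group labels for the training specimens.
#' @param threshold cumulative variance fraction (default 0.90).
#' @return an integer number of axes.
#' @export
retained_pcs <- function(space, groups, threshold = 0.90) {
  k <- which(cumsum(space$variance_fractions) >= threshold)[1]
  if (is.na(k)) k <- length(space$variance_fractions)
  cap <- nrow(space$scores) - length(unique(groups)) - 1
  max(1L, min(k, cap))
}

#' Canonical variate analysis on retained PC scores
#'
#' Solves the generalized eigenproblem of the between-group covariance
#' against the pooled within-group covariance `W`. The returned transform
#' spans the full retained-PC space, scaled so the pooled within-group
#' covariance of transformed scores is the identity (whitening); the first
#' `min(G-1, k)` columns are the canonical axes with positive among-group
#' eigenvalue. Squared Euclidean distance across the full transformed
#' space equals Mahalanobis distance in PC space — the property used for
#' typicality and posterior probabilities.
#'
#' @param x either a [shape_pca()] (retained axes chosen via
#'   [retained_pcs()]) or an N x k score matrix.
#' @param groups group labels (length N); taken from
#'   `x$meta[[group_field]]` when `x` is a `shape_pca`.
#' @param group_field metadata column naming the groups (default
#'   `"genus"`).
#' @param pc_variance cumulative-variance threshold for PC retention.
#' @param k override the number of retained PCs.
#' @return object of class `cva_fit`: group means, pooled `W` and its
#'   inverse, full whitening `transform` (k x k), canonical `eigenvalues`,
#'   `n_axes`, training CV `scores`, `among_group_fractions`, group sizes,
#'   and (when built from a `shape_pca`) the morphospace needed to project
#'   unknowns.
#' @export
cva_fit <- function(x, groups = NULL, group_field = "genus",
                    pc_variance = 0.90, k = NULL) {
  space <- NULL
  if (inherits(x, "shape_pca")) {
    space <- x
    if (is.null(groups)) groups <- space$meta[[group_field]]
    if (is.null(k)) k <- retained_pcs(space, groups, pc_variance)
    scores <- space$scores[, seq_len(k), drop = FALSE]
  } else {
    scores <- as.matrix(x)
    if (is.null(groups)) stop("groups required with a score matrix")
    k <- ncol(scores)
  }
  groups <- factor(groups)
  n <- nrow(scores); g <- nlevels(groups)
  if (g < 2) stop("need at least two groups")
  if (k > n - g)
    stop("too many retained axes (k = ", k, " > N - G = ", n - g,
         "): within-group covariance singular")
  means <- rowsum(scores, groups) / as.vector(table(groups))
  centred <- scores - means[groups, , drop = FALSE]
  w <- crossprod(centred) / (n - g)
  grand <- colMeans(scores)
  md <- sweep(means, 2, grand)
  b <- crossprod(md * sqrt(as.vector(table(groups)))) / (g - 1)
  wis <- inv_sqrt(w)
  e <- eigen(wis %*% b %*% wis, symmetric = TRUE)
  transform <- wis %*% e$vectors
  n_axes <- min(g - 1, k)
  colnames(transform) <- paste0("CV", seq_len(k))
  cv_scores <- sweep(scores, 2, grand) %*% transform
  eig <- pmax(e$values, 0)
  structure(list(means = means, grand_mean = grand, W = w,
                 W_inv = wis %*% wis, transform = transform,
                 eigenvalues = eig[seq_len(n_axes)], n_axes = n_axes,
                 among_group_fractions =
                   eig[seq_len(n_axes)] / sum(eig[seq_len(n_axes)]),
                 scores = cv_scores, pc_scores = scores, groups = groups,
                 group_sizes = as.vector(table(groups)), k = k,
                 group_field = group_field, space = space),
            class = "cva_fit")
}

#' @export
print.cva_fit <- function(x, ...) {
  cat(sprintf(
    "Canonical variate analysis: %d specimens, %d groups, %d retained PCs, %d CV axes\n",
    nrow(x$scores), nlevels(x$groups), x$k, x$n_axes))
  cat("  among-group variance fractions:",
      paste(sprintf("CV%d %.1f%%", seq_len(x$n_axes),
                    100 * x$among_group_fractions), collapse = ", "), "\n")
  invisible(x)
}

#' Mahalanobis squared distance to a group mean
#'
#' `D^2 = (x - mu_g)' W^-1 (x - mu_g)` with `W` the pooled within-group
#' covariance on the retained PCs; identical to the squared Euclidean
#' distance in the full whitened CV space.
#'
#' @param model a [cva_fit()].
#' @param point score vector in retained-PC space (length `model$k`).
#' @param group group label.
#' @return non-negative scalar.
#' @export
mahalanobis_d2 <- function(model, point, group) {
  point <- as.numeric(point)
  if (length(point) != model$k)
    stop("point has length ", length(point), ", model expects ", model$k)
  d <- point - model$means[as.character(group), ]
  drop(t(d) %*% model$W_inv %*% d)
}

#' Typicality probability of group membership
#'
#' The probability that a genuine member of the group lies at least as far
#' from the group mean as the observed specimen — an absolute test of
#' membership (unlike the posterior, which is only relative). Default is
#' the chi-square upper tail on `D^2` with df equal to the dimension of
#' the discriminant space (the retained PCs, across which `D^2` is
#' computed). The `"f"` variant applies the small-sample correction
#' `((m - k + 1) n_g / (k m (n_g + 1))) D^2 ~ F(k, m - k + 1)`, with `m`
#' the pooled within-group df.
#'
#' @inheritParams mahalanobis_d2
#' @param method `"chisq"` (default) or `"f"`.
#' @return probability in `[0, 1]`.
#' @export
typicality_probability <- function(model, point, group,
                                   method = c("chisq", "f")) {
  method <- match.arg(method)
  d2 <- mahalanobis_d2(model, point, group)
  k <- model$k
  if (method == "chisq")
    return(stats::pchisq(d2, df = k, lower.tail = FALSE))
  m <- nrow(model$scores) - nlevels(model$groups)
  ng <- model$group_sizes[match(as.character(group), levels(model$groups))]
  fstat <- d2 * (m - k + 1) * ng / (k * m * (ng + 1))
  stats::pf(fstat, k, m - k + 1, lower.tail = FALSE)
}

#' Posterior probabilities of group membership
#'
#' `P(g | x) = pi_g exp(-D^2_g / 2) / sum_h pi_h exp(-D^2_h / 2)` with
#' equal priors by default, computed with max-subtraction for numerical
#' stability. Posteriors always sum to one; they express relative support
#' among the candidate groups regardless of absolute fit.
#'
#' @inheritParams mahalanobis_d2
#' @param priors optional prior probabilities per group (recycled /
#'   normalized); default equal.
#' @return named probability vector over groups summing to 1.
#' @export
posterior_probability <- function(model, point, priors = NULL) {
  lv <- levels(model$groups)
  if (is.null(priors)) priors <- rep(1 / length(lv), length(lv))
  priors <- priors / sum(priors)
  d2 <- vapply(lv, function(g) mahalanobis_d2(model, point, g), 0)
  lo <- -d2 / 2 + log(priors)
  lo <- lo - max(lo)
  w <- exp(lo)
  stats::setNames(w / sum(w), lv)
}

#' Leave-one-out cross-validation of group assignment
#'
#' Each specimen is held out in turn; group means and the pooled
#' within-group covariance are re-estimated from the remainder and the
#' specimen assigned to the group with the smallest Mahalanobis `D^2`.
#'
#' @param scores N x k score matrix, or a [cva_fit()] (its stored training
#'   scores and groups are used).
#' @param groups group labels (ignored when `scores` is a `cva_fit`).
#' @return object of class `loo_cv`: `accuracy` (fraction correct),
#'   `confusion` (true x assigned table) and per-specimen `assigned`.
#' @export
loo_crossvalidate <- function(scores, groups = NULL) {
  if (inherits(scores, "cva_fit")) {
    groups <- scores$groups
    scores <- scores$pc_scores
  }
  scores <- as.matrix(scores)
  groups <- factor(groups)
  if (any(table(groups) < 2))
    stop("every group needs >= 2 members for leave-one-out")
  n <- nrow(scores)
  lv <- levels(groups)
  assigned <- character(n)
  for (i in seq_len(n)) {
    tr <- scores[-i, , drop = FALSE]
    gr <- droplevels(groups[-i])
    means <- rowsum(tr, gr) / as.vector(table(gr))
    centred <- tr - means[gr, , drop = FALSE]
    winv <- solve(crossprod(centred) / (nrow(tr) - nlevels(gr)))
    d2 <- apply(means, 1, function(mu) {
      d <- scores[i, ] - mu
      drop(t(d) %*% winv %*% d)
    })
    assigned[i] <- names(which.min(d2))
  }
  assigned <- factor(assigned, levels = lv)
  structure(list(accuracy = mean(assigned == groups),
                 confusion = table(true = groups, assigned = assigned),
                 assigned = assigned),
            class = "loo_cv")
}

#' @export
print.loo_cv <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation accuracy: %.1f%%\n",
              100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Classify unknown specimens against the reference groups
#'
#' The full assignment pipeline: each unknown is mirrored if left-sided,
#' superimposed and slid against the fixed training consensus, projected
#' onto the retained PCs, and compared to every reference group by
#' Procrustes distance to the group mean shape and by Mahalanobis `D^2`
#' (equivalently, across all CV axes), from which typicality and posterior
#' probabilities are derived. A typicality call requires the best
#' typicality to exceed `typicality_threshold`; specimens failing it are
#' flagged as having no clear affinity. Projection errors are reported
#' per specimen; remaining specimens are still classified.
#'
#' @param object a [cva_fit()] built from a [shape_pca()].
#' @param newdata a [configuration()] or list of them (the unknowns).
#' @param typicality one of `"chisq"`, `"f"` — see
#'   [typicality_probability()].
#' @param priors optional posterior priors, see [posterior_probability()].
#' @param typicality_threshold minimum best typicality for a positive
#'   call (default 0.20).
#' @param ... unused.
#' @return object of class `classification_report`: a data.frame with one
#'   row per unknown and, per group, Procrustes distance, `D^2`,
#'   typicality and posterior columns, plus the best-group calls under
#'   each criterion.
#' @export
predict.cva_fit <- function(object, newdata, typicality = c("chisq", "f"),
                            priors = NULL, typicality_threshold = 0.20,
                            ...) {
  typicality <- match.arg(typicality)
  if (is.null(object$space))
    stop("this cva_fit was built from raw scores; projection of raw ",
         "configurations needs one built from a shape_pca")
  if (inherits(newdata, "configuration")) newdata <- list(newdata)
  lv <- levels(object$groups)
  space <- object$space
  # group mean shapes, reconstructed losslessly from the full morphospace
  mean_vec <- vec_shape(space$mean_shape)
  group_shape <- lapply(lv, function(g) {
    sc <- colMeans(space$scores[object$groups == g, , drop = FALSE])
    unvec_shape(mean_vec + as.vector(space$eigenvectors %*% sc))
  })
  names(group_shape) <- lv
  rows <- list(); errors <- character(0)
  for (cf in newdata) {
    res <- tryCatch({
      pc <- predict(space, cf)[1, seq_len(object$k)]
      d2 <- vapply(lv, function(g) mahalanobis_d2(object, pc, g), 0)
      typ <- vapply(lv, function(g)
        typicality_probability(object, pc, g, typicality), 0)
      post <- posterior_probability(object, pc, priors)
      coords <- cf$coords
      if (identical(cf$side, "left")) coords[, 1] <- -coords[, 1]
      al <- align_to_consensus(coords, space$consensus, space$scheme)
      pd <- vapply(group_shape, function(m)
        procrustes_distance(al, m, align = FALSE), 0)
      best_t <- lv[which.max(typ)]
      row <- data.frame(specimen_id = cf$specimen_id, t(pd), t(d2),
                        t(typ), t(post),
                        typicality_call = if (max(typ) > typicality_threshold)
                          best_t else "none",
                        posterior_call = lv[which.max(post)],
                        check.names = FALSE)
      names(row)[1 + seq_along(lv)] <- paste0("procD_", lv)
      names(row)[1 + length(lv) + seq_along(lv)] <- paste0("D2_", lv)
      names(row)[1 + 2 * length(lv) + seq_along(lv)] <- paste0("typ_", lv)
      names(row)[1 + 3 * length(lv) + seq_along(lv)] <- paste0("post_", lv)
      row
    }, error = function(e) {
      errors <<- c(errors, paste0(cf$specimen_id, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, errors = errors, groups = lv,
            typicality_threshold = typicality_threshold,
            typicality_method = typicality,
            class = c("classification_report", "data.frame"))
}

#' @export
print.classification_report <- function(x, digits = 3, ...) {
  lv <- attr(x, "groups")
  cat(sprintf(
    "Classification of %d unknown specimen(s) against %d reference groups (%s typicality)\n",
    nrow(x), length(lv), attr(x, "typicality_method")))
  show <- x[c("specimen_id", paste0("typ_", lv), paste0("post_", lv),
              "typicality_call", "posterior_call")]
  num <- vapply(show, is.numeric, TRUE)
  show[num] <- lapply(show[num], round, digits)
  print(as.data.frame(show), row.names = FALSE)
  if (length(attr(x, "errors")))
    cat("Skipped (projection errors):\n ",
        paste(attr(x, "errors"), collapse = "\n  "), "\n")
  invisible(x)
}
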