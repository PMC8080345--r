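## Shape morphospace: PCA of Procrustes coordinates, projection of new
## specimens, shapes along axes, BM ancestral states for phylomorphospaces.

# vectorize a K x 3 shape as (x1,y1,z1,x2,y2,z2,...) and back
vec_shape <- function(s) as.vector(t(s))
unvec_shape <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Principal component analysis of Procrustes shape coordinates
#'
#' Eigendecomposition of the covariance (divisor N-1) of the vectorized
#' aligned shapes about their mean. At most `min(N-1, 3K-7)` components
#' carry variance after superimposition removes 7 degrees of freedom
#' (translation, rotation, scale). Eigenvector signs are fixed so the
#' largest-magnitude loading on each axis is positive.
#'
#' @param dataset a [gpa()] fit (typically slid and symmetrized).
#' @return an object of class `shape_pca`: `mean_shape` (K x 3),
#'   `eigenvectors` (3K x m, orthonormal columns), `eigenvalues` (m,
#'   descending), `scores` (N x m, named PC1..PCm), `variance_fractions`,
#'   plus the training `consensus`, `scheme` and `meta` needed to project
#'   unknowns.
#' @seealso [predict.shape_pca()], [shape_at_score()]
#' @export
shape_pca <- function(dataset) {
  n <- dim(dataset$shapes)[1]
  if (n < 3) stop("PCA needs at least 3 specimens")
  x <- t(apply(dataset$shapes, 1, vec_shape))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  keep <- which(eig > max(eig) * 1e-12)
  eig <- eig[keep]
  rot <- pc$rotation[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- sweep(x, 2, pc$center) %*% rot
  colnames(scores) <- colnames(rot) <- paste0("PC", seq_len(ncol(rot)))
  structure(list(mean_shape = unvec_shape(pc$center),
                 eigenvectors = rot, eigenvalues = eig,
                 scores = scores,
                 variance_fractions = eig / sum(eig),
                 consensus = dataset$consensus,
                 scheme = dataset$scheme,
                 meta = dataset$meta),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  m <- min(4, length(x$eigenvalues))
  cat(sprintf("Shape PCA: %d specimens, %d non-degenerate axes\n",
              nrow(x$scores), length(x$eigenvalues)))
  cat("  variance fractions:",
      paste(sprintf("%s %.1f%%", names(x$variance_fractions)[1:m] <-
                      paste0("PC", 1:m),
                    100 * x$variance_fractions[1:m]), collapse = ", "),
      sprintf("(first %d: %.1f%%)\n", m,
              100 * sum(x$variance_fractions[1:m])))
  invisible(x)
}

#' @export
summary.shape_pca <- function(object, ...) {
  df <- data.frame(axis = colnames(object$scores),
                   eigenvalue = object$eigenvalues,
                   variance_pct = 100 * object$variance_fractions,
                   cumulative_pct = 100 * cumsum(object$variance_fractions))
  rownames(df) <- NULL
  df
}

# align one raw configuration against a fixed consensus: centre, unit CS,
# optimal rotation, then (optionally) slide semilandmarks against the
# consensus, re-normalizing after each slide
align_to_consensus <- function(coords, consensus, scheme = NULL,
                               slide = TRUE, cycles = 5) {
  x <- center_shape(coords)
  x <- x / sqrt(sum(x^2))
  x <- x %*% solve_rotation(x, consensus)
  if (slide && !is.null(scheme) && length(scheme$curves) > 0) {
    nb <- curve_neighbours(scheme)
    for (cy in seq_len(cycles)) {
      x <- slide_one(x, consensus, nb)
      x <- center_shape(x)
      x <- x / sqrt(sum(x^2))
      x <- x %*% solve_rotation(x, consensus)
    }
  }
  x
}

#' Project new specimens into an existing shape morphospace
#'
#' Unknown configurations are superimposed on the fixed training consensus
#' (unit centroid size, optimal rotation), their semilandmarks slid
#' against that consensus — the reference morphospace never moves — and the
#' centred vectorized shape is multiplied by the stored eigenvectors.
#' Mirroring of left elements is applied first, matching the training
#' alignment. Training specimens reproduce their stored scores.
#'
#' @param object a [shape_pca()].
#' @param newdata a [configuration()], a list of them, or a K x 3 matrix.
#' @param slide slide semilandmarks against the consensus (default `TRUE`).
#' @param align superimpose on the consensus before projecting (default
#'   `TRUE`); set `FALSE` only when the input is already expressed in the
#'   training frame (centred, unit centroid size, optimally rotated), in
#'   which case projection is the bare matrix multiplication with the
#'   eigenvectors.
#' @param ... unused.
#' @return a matrix of scores (one row per specimen, PC1..PCm).
#' @export
predict.shape_pca <- function(object, newdata, slide = TRUE, align = TRUE,
                              ...) {
  if (inherits(newdata, "configuration")) newdata <- list(newdata)
  if (is.matrix(newdata)) newdata <- list(list(coords = newdata, side = "unknown"))
  k <- nrow(object$mean_shape)
  scores <- matrix(NA_real_, length(newdata), ncol(object$eigenvectors))
  colnames(scores) <- colnames(object$eigenvectors)
  rownames(scores) <- vapply(seq_along(newdata), function(i) {
    cf <- newdata[[i]]
    if (!is.null(cf$specimen_id)) cf$specimen_id else paste0("unknown", i)
  }, "")
  for (i in seq_along(newdata)) {
    cf <- newdata[[i]]
    coords <- cf$coords
    if (nrow(coords) != k)
      stop("specimen ", rownames(scores)[i], ": ", nrow(coords),
           " landmarks, morphospace expects ", k)
    if (identical(cf$side, "left")) coords[, 1] <- -coords[, 1]
    x <- if (align)
      align_to_consensus(coords, object$consensus, object$scheme, slide)
    else coords
    scores[i, ] <- (vec_shape(x) - vec_shape(object$mean_shape)) %*%
      object$eigenvectors
  }
  scores
}

#' Shape at a position along a principal axis
#'
#' Reconstructs the landmark configuration `mean + value * eigenvector`,
#' the shape the morphospace model implies at a given score. Used for
#' axis-extreme warp visualizations.
#'
#' @param space a [shape_pca()].
#' @param axis axis index (1 = PC1).
#' @param value score along that axis.
#' @return a K x 3 shape matrix.
#' @export
shape_at_score <- function(space, axis, value) {
  if (axis < 1 || axis > ncol(space$eigenvectors))
    stop("axis out of range")
  unvec_shape(vec_shape(space$mean_shape) +
                value * space$eigenvectors[, axis])
}

#' Brownian-motion ancestral states for a phylomorphospace
#'
#' Maximum-likelihood ancestral estimates (equivalent to branch-length
#' weighted squared-change parsimony) of per-species shape scores at every
#' internal node, computed independently per axis via [phytools::fastAnc()].
#' The root estimate is the phylogenetically weighted mean of the tips.
#'
#' @param scores matrix of species scores (rownames = species, one row per
#'   tip) — typically within-species means of PC scores.
#' @param tree a rooted `phylo` tree with branch lengths whose tip labels
#'   match `rownames(scores)`.
#' @return object of class `ancestral_states`: list with `nodes` (matrix
#'   of internal-node estimates, rownames = node numbers), `tips` (the
#'   input scores ordered as the tree's tips) and `tree`.
#' @export
ancestral_states <- function(scores, tree) {
  if (is.null(dim(scores))) scores <- cbind(score = scores)
  missing_sp <- setdiff(tree$tip.label, rownames(scores))
  if (length(missing_sp))
    stop("tips without score data: ", paste(missing_sp, collapse = ", "))
  scores <- scores[tree$tip.label, , drop = FALSE]
  nodes <- vapply(seq_len(ncol(scores)), function(j) {
    x <- scores[, j]
    names(x) <- tree$tip.label
    unname(phytools::fastAnc(tree, x))
  }, numeric(tree$Nnode))
  if (is.null(dim(nodes))) nodes <- matrix(nodes, nrow = tree$Nnode)
  colnames(nodes) <- colnames(scores)
  rownames(nodes) <- as.character(ape::Ntip(tree) + seq_len(tree$Nnode))
  structure(list(nodes = nodes, tips = scores, tree = tree),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(sprintf("Ancestral state estimates at %d internal nodes (%d axes)\n",
              nrow(x$nodes), ncol(x$nodes)))
  cat("  root:", paste(signif(x$nodes[1, ], 4), collapse = ", "), "\n")
  invisible(x)
}

#' Phylomorphospace plot
#'
#' PC1/PC2 scatter of species means with tree branches drawn through the
#' estimated ancestral positions.
#'
#' @param x an [ancestral_states()] object (needs >= 2 axes).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ancestral_states <- function(x, ...) {
  if (ncol(x$tips) < 2) stop("need at least two axes to plot")
  all_pts <- rbind(x$tips[, 1:2], x$nodes[, 1:2])
  ntip <- nrow(x$tips)
  graphics::plot(all_pts, type = "n",
                 xlab = colnames(x$tips)[1], ylab = colnames(x$tips)[2], ...)
  coords_of <- function(node) {
    if (node <= ntip) x$tips[x$tree$tip.label[node], 1:2]
    else x$nodes[as.character(node), 1:2]
  }
  for (e in seq_len(nrow(x$tree$edge))) {
    a <- coords_of(x$tree$edge[e, 1])
    b <- coords_of(x$tree$edge[e, 2])
    graphics::segments(a[1], a[2], b[1], b[2], col = "grey50")
  }
  graphics::points(x$nodes[, 1:2], pch = 21, bg = "white", cex = 0.7)
  graphics::points(x$tips[, 1:2], pch = 19)
  graphics::text(x$tips[, 1:2], labels = rownames(x$tips),
                 pos = 3, cex = 0.7)
  invisible(x)
}
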