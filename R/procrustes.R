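## Procrustes superimposition: centroid size, OPA, GPA, mirroring.
## Shapes are K x 3 matrices; aligned datasets store an N x K x 3 array.

center_shape <- function(x) sweep(x, 2, colMeans(x))

#' Centroid size of a configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of all landmarks from their centroid. Invariant
#' to translation and rotation; scales linearly with the configuration.
#'
#' @param x a [configuration()] or a K x 3 coordinate matrix.
#' @return a positive scalar.
#' @export
centroid_size <- function(x) {
  if (inherits(x, "configuration")) x <- x$coords
  cs <- sqrt(sum(center_shape(x)^2))
  if (cs <= 0) stop("degenerate configuration: all landmarks coincident")
  cs
}

# optimal proper rotation Q minimizing ||A Q - B||_F (Kabsch);
# improper (reflection) allowed on request
solve_rotation <- function(a, b, allow_reflection = FALSE) {
  s <- svd(crossprod(a, b))
  q <- s$u %*% t(s$v)
  if (!allow_reflection && det(q) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    q <- u %*% t(s$v)
  }
  q
}

#' Ordinary (pairwise) Procrustes alignment
#'
#' Least-squares superimposition of one configuration onto a target:
#' removes translation, optionally scale, and rotation. The returned
#' rotation is proper (determinant +1) unless `allow_reflection = TRUE`.
#'
#' @param moving,target K x 3 matrices with equal K.
#' @param scale if `TRUE` (default) the least-squares optimal scale is
#'   applied to `moving`.
#' @param allow_reflection permit an improper rotation when it fits better.
#' @return list with `aligned` (K x 3, in the target's frame), `rotation`
#'   (3 x 3), `scale`, and `residual` — the Procrustes distance
#'   `sqrt(sum((aligned - target)^2))`.
#' @export
opa_align <- function(moving, target, scale = TRUE, allow_reflection = FALSE) {
  if (inherits(moving, "configuration")) moving <- moving$coords
  if (inherits(target, "configuration")) target <- target$coords
  if (nrow(moving) != nrow(target))
    stop("landmark count mismatch: ", nrow(moving), " vs ", nrow(target))
  a <- center_shape(moving)
  b <- center_shape(target)
  q <- solve_rotation(a, b, allow_reflection)
  s <- if (scale) sum((a %*% q) * b) / sum(a * a) else 1
  aligned <- s * (a %*% q)
  res <- sqrt(sum((aligned - b)^2))
  aligned <- sweep(aligned, 2, colMeans(target), `+`)
  list(aligned = aligned, rotation = q, scale = s, residual = res)
}

#' Procrustes distance between two shapes
#'
#' Square root of the summed squared differences between corresponding
#' landmarks. With `align = TRUE` the shapes are first scaled to unit
#' centroid size and optimally superimposed (full Procrustes distance);
#' otherwise they are compared as given.
#'
#' @param x,y K x 3 matrices.
#' @param align superimpose before measuring (default `TRUE`).
#' @return a non-negative scalar.
#' @export
procrustes_distance <- function(x, y, align = TRUE) {
  if (inherits(x, "configuration")) x <- x$coords
  if (inherits(y, "configuration")) y <- y$coords
  if (!align) return(sqrt(sum((x - y)^2)))
  a <- center_shape(x); a <- a / sqrt(sum(a^2))
  b <- center_shape(y); b <- b / sqrt(sum(b^2))
  q <- solve_rotation(a, b)
  sqrt(sum((a %*% q - b)^2))
}

#' Mirror a configuration across the plane x = 0
#'
#' Left elements are reflected so that left and right become directly
#' comparable ("mirroring of left coordinates"). The scheme is assumed
#' side-symmetric, so landmark ids are unchanged. Mirroring is an
#' involution and leaves centroid size untouched.
#'
#' @param config a [configuration()].
#' @return the mirrored [configuration()], side relabelled `"right"` when
#'   the input was a left element.
#' @export
mirror_configuration <- function(config) {
  if (config$side == "right")
    warning("mirroring a right-side configuration")
  coords <- config$coords
  coords[, 1] <- -coords[, 1]
  out <- config
  out$coords <- coords
  out$side <- if (config$side == "left") "right" else config$side
  out
}

# core GPA loop on a list of K x 3 matrices; returns unit-CS aligned shapes
# plus consensus (unit CS) and iteration count
gpa_core <- function(shapes, tol = 1e-10, max_iter = 100) {
  shapes <- lapply(shapes, function(x) {
    x <- center_shape(x)
    x / sqrt(sum(x^2))
  })
  consensus <- shapes[[1]]
  for (it in seq_len(max_iter)) {
    shapes <- lapply(shapes, function(x) x %*% solve_rotation(x, consensus))
    new_cons <- Reduce(`+`, shapes) / length(shapes)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol)
      return(list(shapes = shapes, consensus = consensus, iterations = it))
  }
  stop("GPA did not converge in ", max_iter,
       " iterations (last consensus RMS change ", signif(delta, 3), ")")
}

#' Generalized Procrustes analysis of a set of configurations
#'
#' Iteratively centres every configuration, scales it to unit centroid
#' size, rotates it to the current consensus, and re-estimates the
#' consensus (the normalized mean shape) until the consensus stabilises.
#' Centroid sizes are recorded before scaling. Left-side elements can be
#' mirrored first so both sides share one orientation.
#'
#' @param configs list of [configuration()]s on a common scheme.
#' @param scheme optional [landmark_scheme()] carried into the result (and
#'   required later for semilandmark sliding).
#' @param mirror_left mirror left-side configurations before alignment
#'   (default `TRUE`).
#' @param tol convergence tolerance on the consensus root-mean-square
#'   change per iteration.
#' @param max_iter iteration cap.
#' @return an object of class `gpa`: list with `shapes` (N x K x 3 array of
#'   Procrustes shape coordinates, unit centroid size), `cs` (N centroid
#'   sizes), `consensus` (K x 3 mean shape), `meta` (specimen metadata
#'   data.frame), `scheme`, `iterations`, and bookkeeping flags.
#' @seealso [slide_semilandmarks()], [symmetrize_pairs()], [shape_pca()]
#' @export
gpa <- function(configs, scheme = NULL, mirror_left = TRUE,
                tol = 1e-10, max_iter = 100) {
  if (length(configs) < 2) stop("GPA needs at least two configurations")
  k <- nrow(configs[[1]]$coords)
  if (!all(vapply(configs, function(cf) nrow(cf$coords), 0L) == k))
    stop("configurations differ in landmark count")
  meta <- config_metadata(configs)
  if (mirror_left) {
    is_left <- meta$side == "left"
    configs[is_left] <- lapply(configs[is_left], mirror_configuration)
    meta$mirrored <- is_left
  } else meta$mirrored <- FALSE
  cs <- vapply(configs, centroid_size, 0)
  fit <- gpa_core(lapply(configs, `[[`, "coords"), tol, max_iter)
  shapes <- array(NA_real_, c(length(configs), k, 3),
                  dimnames = list(meta$specimen_id, NULL, c("x", "y", "z")))
  for (i in seq_along(fit$shapes)) shapes[i, , ] <- fit$shapes[[i]]
  structure(list(shapes = shapes, cs = cs, consensus = fit$consensus,
                 meta = meta, scheme = scheme, iterations = fit$iterations,
                 slid = FALSE, symmetrized = FALSE,
                 sliding_iterations_used = 0L),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf(
    "Generalized Procrustes fit: %d configurations, %d landmarks (3D)\n",
    dim(x$shapes)[1], dim(x$shapes)[2]))
  cat(sprintf("  converged in %d iteration(s); semilandmarks %s; %s\n",
              x$iterations,
              if (x$slid) sprintf("slid (%d cycle(s))",
                                  x$sliding_iterations_used) else "not slid",
              if (x$symmetrized) "bilateral symmetric component" else
                "per-element shapes"))
  cat(sprintf("  centroid size: %.4g - %.4g (median %.4g)\n",
              min(x$cs), max(x$cs), stats::median(x$cs)))
  invisible(x)
}

#' @export
summary.gpa <- function(object, ...) {
  print(object)
  d <- apply(object$shapes, 1, function(s)
    sqrt(sum((s - object$consensus)^2)))
  cat(sprintf("  Procrustes distance to consensus: mean %.4g, max %.4g\n",
              mean(d), max(d)))
  invisible(object)
}

# rebuild the shapes array from a list of matrices (internal)
shapes_to_array <- function(lst, template) {
  out <- template
  for (i in seq_along(lst)) out[i, , ] <- lst[[i]]
  out
}
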