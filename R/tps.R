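#' Thin-plate spline warp between two landmark sets in 3D
#'
#' Fits the 3D thin-plate spline interpolant (radial kernel U(r) = r, plus
#' an affine part) mapping each source landmark exactly onto its target,
#' and evaluates it at arbitrary query points. Affine deformations are
#' reproduced exactly (the non-affine warp component is zero), which is the
#' property that makes the TPS the standard visualization of shape change
#' between a reference and a target configuration.
#'
#' @param source,target K x 3 matrices, K >= 5, in one-to-one
#'   correspondence.
#' @param query M x 3 matrix of points to warp (defaults to `source`, i.e.
#'   the warped landmarks themselves).
#' @return M x 3 matrix of warped query points.
#' @export
tps_warp <- function(source, target, query = source) {
  source <- as.matrix(source); target <- as.matrix(target)
  query <- as.matrix(query)
  k <- nrow(source)
  if (k < 5) stop("3D TPS needs at least 5 landmarks")
  if (nrow(target) != k) stop("source/target landmark count mismatch")
  kernel <- as.matrix(stats::dist(source))      # U(r) = r in 3D
  p <- cbind(1, source)
  lhs <- rbind(cbind(kernel, p), cbind(t(p), matrix(0, 4, 4)))
  rhs <- rbind(target, matrix(0, 4, 3))
  coefs <- tryCatch(solve(lhs, rhs), error = function(e)
    stop("singular TPS system (degenerate source landmarks); ",
         "jitter the source configuration slightly"))
  coefs <- coefs + solve(lhs, rhs - lhs %*% coefs)  # iterative refinement
  w <- coefs[1:k, , drop = FALSE]
  a <- coefs[(k + 1):(k + 4), , drop = FALSE]
  # distances query -> source landmarks, computed dimension-wise to avoid
  # cancellation when a query point coincides with a landmark
  u <- sqrt(outer(query[, 1], source[, 1], `-`)^2 +
              outer(query[, 2], source[, 2], `-`)^2 +
              outer(query[, 3], source[, 3], `-`)^2)
  cbind(1, query) %*% a + u %*% w
}
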