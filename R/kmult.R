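#' Multivariate phylogenetic signal K_mult
#'
#' The multivariate generalization of Blomberg's K: the ratio of the
#' observed level of phylogenetic structure in a multivariate trait to the
#' level expected under Brownian motion on the given tree. With tree
#' covariance `C` (shared path lengths), data `Y` (one row per tip) and
#' phylogenetically weighted mean `a = (1'C^-1 1)^-1 (1'C^-1 Y)`,
#'
#' `K = [ tr((Y-1a)'(Y-1a)) / tr((Y-1a)' C^-1 (Y-1a)) ] /
#'      [ (tr(C) - n / (1'C^-1 1)) / (n-1) ]`
#'
#' so that K has expectation 1 under Brownian motion, exceeds 1 when
#' relatives resemble each other more than BM predicts, and falls below 1
#' when they resemble each other less. With a single trait column this is
#' exactly Blomberg's K. Significance is assessed by permuting data across
#' the tips of the phylogeny; the observed value is included among the
#' `n_perm` iterations.
#'
#' @param species_shapes matrix of per-species trait values (rownames =
#'   species; e.g. species-mean vectorized Procrustes coordinates or PC
#'   scores), or a named vector for the univariate case.
#' @param tree a rooted `phylo` tree with branch lengths; tip labels must
#'   match the rownames.
#' @param n_perm permutation iterations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return object of class `kmult`: list with `K`, `p_value`, `n_perm`,
#'   `phylo_mean` (the weighted mean `a`) and `C`.
#' @export
kmult <- function(species_shapes, tree, n_perm = 1000, seed = NULL) {
  if (is.null(dim(species_shapes)))
    species_shapes <- cbind(trait = species_shapes)
  y <- as.matrix(species_shapes)
  if (is.null(rownames(y))) stop("species_shapes needs species rownames")
  missing_sp <- setdiff(tree$tip.label, rownames(y))
  if (length(missing_sp))
    stop("tips without data: ", paste(missing_sp, collapse = ", "))
  y <- y[tree$tip.label, , drop = FALSE]
  if (sum(apply(y, 2, stats::var)) == 0)
    stop("zero-variance data across tips: K undefined")
  cmat <- ape::vcv(tree)
  n <- nrow(y)
  cinv <- solve(cmat)
  ones <- matrix(1, n, 1)
  denom_norm <- (sum(diag(cmat)) - n / sum(cinv)) / (n - 1)
  k_stat <- function(yy) {
    a <- crossprod(ones, cinv %*% yy) / sum(cinv)
    r <- yy - ones %*% a
    (sum(r * r) / sum(r * (cinv %*% r))) / denom_norm
  }
  k_obs <- k_stat(y)
  if (!is.null(seed)) set.seed(seed)
  k_perm <- c(k_obs, vapply(seq_len(n_perm - 1), function(b)
    k_stat(y[sample.int(n), , drop = FALSE]), 0))
  a_obs <- crossprod(ones, cinv %*% y) / sum(cinv)
  structure(list(K = unname(k_obs), p_value = mean(k_perm >= k_obs),
                 n_perm = n_perm, phylo_mean = drop(a_obs), C = cmat),
            class = "kmult")
}

#' @export
print.kmult <- function(x, ...) {
  cat(sprintf("Multivariate phylogenetic signal: K_mult = %.3f, p = %.4g (%d permutations)\n",
              x$K, x$p_value, x$n_perm))
  invisible(x)
}
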