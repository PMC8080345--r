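## Bilateral symmetrization (matching symmetry): one symmetric-component
## shape per individual from its mirrored-left and right elements.

#' Symmetrize paired bilateral elements
#'
#' Collapses the aligned left (already mirrored during [gpa()]) and right
#' elements of each individual into their symmetric component: the
#' Procrustes mean of the two aligned shapes (the second side is optimally
#' rotated onto the first before averaging; the average is rescaled to
#' unit centroid size). Individuals represented by a single element pass
#' through unchanged and are flagged `paired = FALSE`. The per-individual
#' centroid size is the mean of the side centroid sizes. The reduced
#' dataset is re-aligned so the stored consensus is again the Procrustes
#' mean of its shapes.
#'
#' @param dataset a [gpa()] fit whose `meta$specimen_id` links paired
#'   elements.
#' @return a new `gpa` object with one shape per individual and
#'   `symmetrized = TRUE`; `meta` gains a logical `paired` column.
#' @export
symmetrize_pairs <- function(dataset) {
  ids <- dataset$meta$specimen_id
  groups <- split(seq_along(ids), ids)
  sizes <- lengths(groups)
  if (any(sizes > 2))
    stop("more than two elements for individual(s): ",
         paste(names(groups)[sizes > 2], collapse = ", "))
  groups <- groups[unique(ids)]  # preserve input order
  shapes <- vector("list", length(groups))
  cs <- numeric(length(groups))
  paired <- logical(length(groups))
  meta_rows <- integer(length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    meta_rows[g] <- idx[1]
    cs[g] <- mean(dataset$cs[idx])
    if (length(idx) == 2) {
      a <- dataset$shapes[idx[1], , ]
      b <- dataset$shapes[idx[2], , ]
      b <- b %*% solve_rotation(b, a)
      m <- (a + b) / 2
      shapes[[g]] <- m / sqrt(sum(center_shape(m)^2))
      paired[g] <- TRUE
    } else {
      shapes[[g]] <- dataset$shapes[idx[1], , ]
      paired[g] <- FALSE
    }
  }
  fit <- gpa_core(shapes)
  k <- dim(dataset$shapes)[2]
  meta <- dataset$meta[meta_rows, , drop = FALSE]
  meta$side <- NULL
  meta$paired <- paired
  rownames(meta) <- NULL
  arr <- array(NA_real_, c(length(groups), k, 3),
               dimnames = list(meta$specimen_id, NULL, c("x", "y", "z")))
  out <- dataset
  out$shapes <- shapes_to_array(fit$shapes, arr)
  out$cs <- cs
  out$consensus <- fit$consensus
  out$meta <- meta
  out$symmetrized <- TRUE
  out
}
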