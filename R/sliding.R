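## Sliding semilandmarks: minimized Procrustes distance criterion.
##
## Each semilandmark may move along its local curve tangent, estimated by
## central finite difference on its flanking curve neighbours (one-sided at
## curve ends). The least-squares optimal step towards the consensus has
## the closed form s = t . (y - x) for unit tangent t; it is clipped to
## half the distance to the nearest neighbour so the along-curve ordering
## can never invert. Sliding alternates with GPA re-alignment.

# neighbour table for a scheme: for each semilandmark id, the ids of the
# previous and next point along its curve
curve_neighbours <- function(scheme) {
  out <- list()
  for (cv in scheme$curves) {
    seq_ids <- c(cv$start, cv$semis, cv$end)
    for (j in seq_along(cv$semis)) {
      id <- cv$semis[j]
      out[[as.character(id)]] <- c(prev = seq_ids[j], nxt = seq_ids[j + 2])
    }
  }
  out
}

# slide one shape towards a fixed target; returns the displaced shape
slide_one <- function(x, target, nb) {
  for (id_chr in names(nb)) {
    id <- as.integer(id_chr)
    p <- x[nb[[id_chr]]["prev"], ]
    q <- x[nb[[id_chr]]["nxt"], ]
    tg <- q - p
    len <- sqrt(sum(tg^2))
    if (len < .Machine$double.eps) next
    tg <- tg / len
    s <- sum(tg * (target[id, ] - x[id, ]))
    bound <- 0.5 * min(sqrt(sum((x[id, ] - p)^2)), sqrt(sum((q - x[id, ])^2)))
    s <- max(-bound, min(bound, s))
    x[id, ] <- x[id, ] + s * tg
  }
  x
}

#' Optimize semilandmark positions by the Procrustes distance criterion
#'
#' Slides each semilandmark along its local curve tangent towards the
#' consensus, by the step that minimizes the Procrustes distance of the
#' specimen to the consensus, then re-runs the generalized Procrustes
#' alignment; the consensus is re-estimated every cycle. Fixed landmarks
#' never move, and each step is bounded to half the distance to the
#' nearest curve neighbour so points cannot leapfrog.
#'
#' @param dataset a [gpa()] fit.
#' @param scheme [landmark_scheme()] declaring the curves; defaults to the
#'   scheme stored in `dataset`.
#' @param max_cycles maximum slide/re-align cycles (default 5).
#' @param tol stop when the summed Procrustes distance to the consensus
#'   changes by less than this between cycles.
#' @param target optional fixed K x 3 target shape; when supplied the
#'   consensus is NOT re-estimated and every specimen is slid and aligned
#'   against this fixed reference (used when projecting unknowns into an
#'   existing morphospace).
#' @return the updated `gpa` object with `slid = TRUE`.
#' @export
slide_semilandmarks <- function(dataset, scheme = dataset$scheme,
                                max_cycles = 5, tol = 1e-6, target = NULL) {
  if (is.null(scheme)) stop("no landmark scheme available for sliding")
  if (length(scheme$curves) == 0) return(dataset)
  nb <- curve_neighbours(scheme)
  for (id_chr in names(nb)) {
    ids <- nb[[id_chr]]
    if (any(ids < 1 | ids > scheme$total))
      stop("semilandmark ", id_chr, " has out-of-scheme neighbours")
  }
  n <- dim(dataset$shapes)[1]
  shapes <- lapply(seq_len(n), function(i) dataset$shapes[i, , ])
  fixed_target <- !is.null(target)
  consensus <- if (fixed_target) target else dataset$consensus
  total_d <- sum(vapply(shapes, function(s)
    sqrt(sum((s - consensus)^2)), 0))
  cycles <- 0L
  for (cy in seq_len(max_cycles)) {
    shapes <- lapply(shapes, slide_one, target = consensus, nb = nb)
    if (fixed_target) {
      shapes <- lapply(shapes, function(x) {
        x <- center_shape(x)
        x <- x / sqrt(sum(x^2))
        x %*% solve_rotation(x, consensus)
      })
    } else {
      fit <- gpa_core(shapes)
      shapes <- fit$shapes
      consensus <- fit$consensus
    }
    new_total <- sum(vapply(shapes, function(s)
      sqrt(sum((s - consensus)^2)), 0))
    cycles <- cy
    if (abs(total_d - new_total) < tol) {
      total_d <- new_total
      break
    }
    total_d <- new_total
  }
  dataset$shapes <- shapes_to_array(shapes, dataset$shapes)
  dataset$consensus <- consensus
  dataset$slid <- TRUE
  dataset$sliding_iterations_used <- cycles
  dataset
}
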