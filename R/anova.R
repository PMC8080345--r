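## Procrustes ANOVA with residual-randomization permutation (RRPP),
## pairwise mean-shape tests, and centroid-size ANOVA with Tukey HSD.

# sequential (type-I) sums of squares of Y on a list of nested model
# matrices; returns per-term SS plus residual SS of the full model.
# Fitting is by QR projection; SS are summed squared residual distances
# across all shape dimensions.
sequential_ss <- function(y, design_list) {
  rss <- vapply(design_list, function(x) {
    q <- qr.Q(qr(x))
    sum((y - q %*% crossprod(q, y))^2)
  }, 0)
  list(term_ss = rss[-length(rss)] - rss[-1],
       residual_ss = rss[length(rss)],
       reduced_rss = rss)
}

# build the sequential design matrices for shape ~ genus * log(CS)
build_designs <- function(group, logsize, terms) {
  n <- length(group)
  designs <- list(matrix(1, n, 1))
  labels <- character(0)
  x <- designs[[1]]
  if ("group" %in% terms) {
    mm <- stats::model.matrix(~g, data.frame(g = group))
    x <- mm
    designs <- c(designs, list(x))
    labels <- c(labels, "group")
  }
  if ("size" %in% terms) {
    x <- cbind(x, size = logsize)
    designs <- c(designs, list(x))
    labels <- c(labels, "size")
  }
  if ("interaction" %in% terms) {
    mm <- stats::model.matrix(~g * s, data.frame(g = group, s = logsize))
    inter <- mm[, grepl(":", colnames(mm)), drop = FALSE]
    x <- cbind(x, inter)
    designs <- c(designs, list(x))
    labels <- c(labels, "group:size")
  }
  for (d in designs) {
    if (qr(d)$rank < ncol(d))
      stop("collinear model terms (design matrix rank deficient)")
  }
  list(designs = designs, labels = labels)
}

#' Procrustes ANOVA of shape on group and size
#'
#' Linear model on the vectorized Procrustes shape coordinates,
#' `shape ~ group * log(CS)`, with sequential (type-I) sums of squares
#' computed as summed squared residual distances, and significance
#' assessed by residual randomization (RRPP): for each term, the residuals
#' of its reduced model are permuted, added back to the reduced-model
#' fit, and the term's F statistic recomputed;
#' `p = (number of permuted F >= observed + 1) / (n_perm + 1)`.
#'
#' @param dataset a [gpa()] fit (typically symmetrized), or a list with
#'   elements `shapes`/`scores` and metadata — see Details.
#' @param group_field metadata column defining groups (default `"genus"`).
#' @param terms which terms to fit, in order: subset of
#'   `c("group", "size", "interaction")`.
#' @param log_size use log centroid size as the allometry covariate
#'   (default `TRUE`; set `FALSE` for raw CS).
#' @param n_perm number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return object of class `procrustes_anova`: a data.frame `table` with
#'   columns `term, df, SS, MS, F, Rsq, p` (residual and total rows
#'   appended), plus `n_perm`.
#' @export
procrustes_anova <- function(dataset, group_field = "genus",
                             terms = c("group", "size", "interaction"),
                             log_size = TRUE, n_perm = 999, seed = NULL) {
  y <- t(apply(dataset$shapes, 1, vec_shape))
  group <- factor(dataset$meta[[group_field]])
  if (any(table(group) < 2))
    stop("singleton group(s): ",
         paste(names(which(table(group) < 2)), collapse = ", "))
  logsize <- if (log_size) log(dataset$cs) else dataset$cs
  bd <- build_designs(group, logsize, terms)
  n <- nrow(y)
  y_c <- sweep(y, 2, colMeans(y))
  ss_total <- sum(y_c^2)
  obs <- sequential_ss(y, bd$designs)
  df_term <- vapply(bd$designs, ncol, 0L)
  df_term <- df_term[-1] - df_term[-length(df_term)]
  df_res <- n - ncol(bd$designs[[length(bd$designs)]])
  ms_term <- obs$term_ss / df_term
  ms_res <- obs$residual_ss / df_res
  f_obs <- ms_term / ms_res
  # RRPP: permute reduced-model residuals per term
  if (!is.null(seed)) set.seed(seed)
  p <- rep(NA_real_, length(f_obs))
  if (n_perm > 0) {
    count_ge <- numeric(length(f_obs))
    qlist <- lapply(bd$designs, function(x) qr.Q(qr(x)))
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      for (t in seq_along(f_obs)) {
        qr_red <- qlist[[t]]
        fit_red <- qr_red %*% crossprod(qr_red, y)
        y_star <- fit_red + (y - fit_red)[idx, , drop = FALSE]
        q_full <- qlist[[t + 1]]
        rss_red <- sum((y_star - qr_red %*% crossprod(qr_red, y_star))^2)
        rss_full <- sum((y_star - q_full %*% crossprod(q_full, y_star))^2)
        q_last <- qlist[[length(qlist)]]
        rss_last <- sum((y_star - q_last %*% crossprod(q_last, y_star))^2)
        f_star <- ((rss_red - rss_full) / df_term[t]) / (rss_last / df_res)
        if (f_star >= f_obs[t]) count_ge[t] <- count_ge[t] + 1
      }
    }
    p <- (count_ge + 1) / (n_perm + 1)
  }
  tab <- data.frame(
    term = c(bd$labels, "residual", "total"),
    df = c(df_term, df_res, n - 1),
    SS = c(obs$term_ss, obs$residual_ss, ss_total),
    MS = c(ms_term, ms_res, NA),
    F = c(f_obs, NA, NA),
    Rsq = c(obs$term_ss / ss_total, obs$residual_ss / ss_total, 1),
    p = c(p, NA, NA))
  structure(list(table = tab, n_perm = n_perm, group_field = group_field,
                 log_size = log_size),
            class = "procrustes_anova")
}

#' @export
print.procrustes_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Procrustes ANOVA (sequential SS, %d RRPP permutations)\n",
              x$n_perm))
  tab <- x$table
  tab$SS <- signif(tab$SS, digits); tab$MS <- signif(tab$MS, digits)
  tab$F <- signif(tab$F, digits); tab$Rsq <- signif(tab$Rsq, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Pairwise mean-shape difference tests between groups
#'
#' For every pair of groups the statistic is the Procrustes distance
#' between the group mean shapes; the null distribution is built by
#' permuting group labels. Raw p-values are reported (no multiplicity
#' correction), `p = (number of permuted distances >= observed + 1) /
#' (n_perm + 1)`.
#'
#' @inheritParams procrustes_anova
#' @return data.frame with columns `group1, group2, distance, p`.
#' @export
pairwise_group_tests <- function(dataset, group_field = "genus",
                                 n_perm = 999, seed = NULL) {
  y <- t(apply(dataset$shapes, 1, vec_shape))
  group <- factor(dataset$meta[[group_field]])
  if (any(table(group) < 2)) stop("singleton group(s)")
  if (!is.null(seed)) set.seed(seed)
  lv <- levels(group)
  pairs <- utils::combn(lv, 2)
  mean_dist <- function(g) {
    means <- rowsum(y, g) / as.vector(table(g))
    as.matrix(stats::dist(means))
  }
  d_obs <- mean_dist(group)
  count <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (b in seq_len(n_perm)) {
    d_star <- mean_dist(sample(group))
    count <- count + (d_star >= d_obs)
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             distance = d_obs[t(pairs)],
             p = (count[t(pairs)] + 1) / (n_perm + 1))
}

#' One-way ANOVA of centroid size with Tukey HSD post-hoc tests
#'
#' Classical one-way ANOVA of centroid size on group, Tukey's honestly
#' significant difference comparisons via the studentized-range
#' distribution, and per-group mean and standard deviation of centroid
#' size.
#'
#' @inheritParams procrustes_anova
#' @return object of class `size_anova`: list with `anova` (the
#'   [stats::aov()] summary data.frame), `tukey` (data.frame of pairwise
#'   comparisons), and `group_stats` (mean, sd, n per group).
#' @export
size_anova_tukey <- function(dataset, group_field = "genus") {
  group <- factor(dataset$meta[[group_field]])
  if (nlevels(group) < 2 || any(table(group) < 2))
    stop("need >= 2 groups with >= 2 members each")
  cs <- dataset$cs
  if (all(vapply(split(cs, group), stats::var, 0) == 0))
    stop("zero pooled within-group variance")
  fit <- stats::aov(cs ~ group)
  hsd <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(hsd), hsd, row.names = NULL)
  names(tukey) <- c("comparison", "diff", "lwr", "upr", "p_adj")
  gs <- data.frame(group = levels(group),
                   mean = as.vector(tapply(cs, group, mean)),
                   sd = as.vector(tapply(cs, group, stats::sd)),
                   n = as.vector(table(group)))
  a <- summary(fit)[[1]]
  structure(list(anova = data.frame(term = trimws(rownames(a)), a,
                                    row.names = NULL, check.names = FALSE),
                 tukey = tukey, group_stats = gs),
            class = "size_anova")
}

#' @export
print.size_anova <- function(x, ...) {
  cat("One-way ANOVA of centroid size\n")
  print(x$anova, row.names = FALSE)
  cat("\nGroup centroid size (mean ± sd):\n")
  gs <- x$group_stats
  cat(paste(sprintf("  %s: %.0f ± %.1f (n=%d)",
                    gs$group, gs$mean, gs$sd, gs$n), collapse = "\n"), "\n")
  cat("\nTukey HSD:\n")
  print(x$tukey, row.names = FALSE)
  invisible(x)
}
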