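two_group_scores <- function(n = 20, sep = 10, sd_within = 1, p = 3,
                             seed = 90) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n * p, 0, sd_within), 2 * n, p)
  x[(n + 1):(2 * n), 1] <- x[(n + 1):(2 * n), 1] + sep
  list(scores = x, groups = rep(c("A", "B"), each = n))
}

test_that("CVA has the defining whitening property and closed-form separation", {
  # two 1-D groups with means 0 and m and within-sd s separate by m/s
  set.seed(91)
  m <- 3; s <- 0.5; n <- 400
  x <- cbind(c(rnorm(n, 0, s), rnorm(n, m, s)))
  g <- rep(c("A", "B"), each = n)
  fit <- cva_fit(x, g)
  expect_equal(fit$n_axes, 1L)
  gap <- abs(diff(tapply(fit$scores[, 1], g, mean)))
  # sample-pooled sd estimates s; separation on the CV scale is m_hat/s_hat
  mu <- tapply(x[, 1], g, mean)
  s_hat <- sqrt(sum((x[, 1] - mu[g])^2) / (2 * n - 2))
  expect_equal(gap, abs(diff(mu)) / s_hat, tolerance = 1e-9)
  # multivariate: pooled within-group covariance of CV scores = identity
  tg <- two_group_scores(n = 30, sep = 4, p = 4)
  fit2 <- cva_fit(tg$scores, tg$groups)
  cvs <- fit2$scores
  centred <- cvs - rowsum(cvs, tg$groups)[tg$groups, ] /
    as.vector(table(tg$groups))[1]
  w_cv <- crossprod(centred) / (nrow(cvs) - 2)
  expect_equal(w_cv, diag(4), tolerance = 1e-6, ignore_attr = TRUE)
  # exactly min(G-1, k) axes with positive among-group eigenvalue
  expect_equal(fit2$n_axes, 1L)
  expect_true(all(fit2$eigenvalues > 0))
  expect_error(cva_fit(tg$scores[c(1, 31), ], c("A", "B")), "singular|k = ")
})

test_that("Mahalanobis D^2 equals its direct-algebra and CV-space forms", {
  set.seed(92)
  n <- 15
  x <- rbind(matrix(rnorm(n * 3), n, 3),
             matrix(rnorm(n * 3, 2), n, 3),
             matrix(rnorm(n * 3, -2), n, 3))
  g <- rep(c("A", "B", "C"), each = n)
  fit <- cva_fit(x, g)
  pt <- c(0.5, -1, 2)
  for (gr in c("A", "B", "C")) {
    d2 <- mahalanobis_d2(fit, pt, gr)
    # direct inverse computation
    mu <- colMeans(x[g == gr, ])
    centred <- x - rowsum(x, g)[g, ] / n
    w <- crossprod(centred) / (3 * n - 3)
    oracle <- drop(t(pt - mu) %*% solve(w) %*% (pt - mu))
    expect_equal(d2, oracle, tolerance = 1e-10)
    # squared Euclidean distance across the full CV space
    cv_pt <- (pt - fit$grand_mean) %*% fit$transform
    cv_mu <- (mu - fit$grand_mean) %*% fit$transform
    expect_equal(d2, sum((cv_pt - cv_mu)^2), tolerance = 1e-8)
  }
  # zero at the mean, one at unit offset under identity W
  expect_equal(mahalanobis_d2(fit, colMeans(x[g == "A", ]), "A"), 0,
               tolerance = 1e-12)
  expect_error(mahalanobis_d2(fit, c(1, 2), "A"), "length")
})

test_that("typicality follows the chi-square law and decreases in D^2", {
  tg <- two_group_scores(n = 30, sep = 5, p = 2)
  fit <- cva_fit(tg$scores, tg$groups)
  mu_a <- fit$means["A", ]
  expect_equal(typicality_probability(fit, mu_a, "A"), 1)
  # df = 2, D^2 = 5.991 (the 0.95 chi-square quantile) -> 0.05
  # construct a point at exactly that D^2 from the mean along W^{1/2} e1
  e <- eigen(fit$W, symmetric = TRUE)
  dir1 <- e$vectors[, 1] * sqrt(e$values[1])
  pt <- mu_a + sqrt(5.991) * dir1
  d2 <- mahalanobis_d2(fit, pt, "A")
  expect_equal(d2, 5.991, tolerance = 1e-9)
  expect_equal(typicality_probability(fit, pt, "A"),
               pchisq(5.991, 2, lower.tail = FALSE), tolerance = 1e-12)
  pt95 <- mu_a + sqrt(qchisq(0.95, 2)) * dir1
  expect_equal(typicality_probability(fit, pt95, "A"), 0.05,
               tolerance = 1e-9)
  # monotone decreasing in D^2
  ds <- seq(0, 4, by = 0.5)
  typ <- vapply(ds, function(d)
    typicality_probability(fit, mu_a + d * dir1, "A"), 0)
  expect_true(all(diff(typ) < 0))
  # small-sample F variant is close to chi-square but not identical
  tf <- typicality_probability(fit, pt, "A", method = "f")
  expect_gt(tf, 0.02)
  expect_false(isTRUE(all.equal(tf, 0.05, tolerance = 1e-6)))
})

test_that("posteriors normalize, favour the nearest group, and match closed form", {
  set.seed(93)
  x <- rbind(matrix(rnorm(20, 0, 1), 10, 2),
             matrix(rnorm(20, 4, 1), 10, 2))
  g <- rep(c("A", "B"), each = 10)
  fit <- cva_fit(x, g)
  # equidistant point: posterior 1/G each
  mid <- (fit$means["A", ] + fit$means["B", ]) / 2
  post_mid <- posterior_probability(fit, mid)
  expect_equal(sum(post_mid), 1, tolerance = 1e-9)
  expect_equal(unname(post_mid), c(0.5, 0.5), tolerance = 1e-9)
  # direct formula: D^2 of 1 vs 4 -> (0.8176, 0.1824)
  expect_equal(exp(-1 / 2) / (exp(-1 / 2) + exp(-4 / 2)), 0.8176,
               tolerance = 1e-4)
  # argmax posterior always equals minimal-D^2 group
  for (i in 1:20) {
    pt <- rnorm(2, 2, 3)
    post <- posterior_probability(fit, pt)
    d2 <- vapply(c("A", "B"), function(gr) mahalanobis_d2(fit, pt, gr), 0)
    expect_equal(names(which.max(post)), names(which.min(d2)))
    expect_equal(sum(post), 1, tolerance = 1e-9)
  }
  # dominance: D^2 gap of 20 -> posterior > 0.999
  pt_a <- fit$means["A", ]
  d2b <- mahalanobis_d2(fit, pt_a, "B")
  expect_gt(d2b, 20)
  expect_gt(posterior_probability(fit, pt_a)["A"], 0.999)
})

test_that("LOO cross-validation separates clusters and respects bookkeeping", {
  tg <- two_group_scores(n = 20, sep = 10, sd_within = 1, p = 3)
  cv <- loo_crossvalidate(tg$scores, tg$groups)
  expect_equal(cv$accuracy, 1)
  expect_equal(as.vector(rowSums(cv$confusion)), c(20L, 20L))
  # permuted labels, balanced two groups: accuracy near chance
  set.seed(94)
  perm <- sample(tg$groups)
  cv0 <- loo_crossvalidate(tg$scores, perm)
  expect_lt(abs(cv0$accuracy - 0.5), 0.2)
  expect_error(loo_crossvalidate(tg$scores[1:3, ], c("A", "A", "B")),
               ">= 2")
})

test_that("unknown classification runs the full projection pipeline", {
  sim <- simulate_dataset(simulation_config(seed = 27))
  res <- run_study(sim$modern, fossils = sim$fossils,
                   scheme = sim$config$scheme, n_perm = 9, seed = 2)
  rep <- res$classification
  expect_equal(nrow(rep), 11L)
  lv <- attr(rep, "groups")
  expect_length(lv, 5L)
  post <- as.matrix(rep[paste0("post_", lv)])
  expect_equal(unname(rowSums(post)), rep(1, 11), tolerance = 1e-9)
  typ <- as.matrix(rep[paste0("typ_", lv)])
  expect_true(all(typ >= 0 & typ <= 1))
  expect_true(all(as.matrix(rep[paste0("D2_", lv)]) >= 0))
  # a training specimen fed back as an unknown: confidently self-assigned
  tr_cf <- sim$modern[[1]]
  self <- predict(res$cva, tr_cf)
  expect_equal(self$posterior_call, tr_cf$genus)
  expect_gt(max(as.matrix(self[paste0("typ_", lv)])), 0.05)
  # an unknown far outside all groups: typicality collapses everywhere,
  # posteriors still normalize, report flags no clear affinity
  far <- tr_cf
  far$coords <- far$coords + 40 * abs(far$coords)
  far$specimen_id <- "way_out"
  out <- predict(res$cva, far)
  expect_true(all(as.matrix(out[paste0("typ_", lv)]) < 0.05))
  expect_equal(out$typicality_call, "none")
  expect_equal(sum(as.matrix(out[paste0("post_", lv)])), 1,
               tolerance = 1e-9)
})
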