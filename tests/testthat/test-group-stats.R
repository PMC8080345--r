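make_group_dataset <- function(n_per = 3, offset = 0.3, noise = 0,
                               k = 6, seed = 60) {
  set.seed(seed)
  base <- random_coords(k, seed = seed)
  delta <- matrix(0, k, 3)
  delta[1, 1] <- offset
  shapes <- c(lapply(seq_len(n_per), function(i)
    base + matrix(rnorm(3 * k, 0, noise), k, 3)),
    lapply(seq_len(n_per), function(i)
      base + delta + matrix(rnorm(3 * k, 0, noise), k, 3)))
  fake_dataset(shapes,
               data.frame(specimen_id = paste0("s", seq_len(2 * n_per)),
                          genus = rep(c("A", "B"), each = n_per)),
               cs = exp(rnorm(2 * n_per, 7, 0.1)))
}

test_that("sequential SS matches direct residual summation via lm", {
  ds <- make_group_dataset(n_per = 3, offset = 0.2, noise = 0.05)
  res <- procrustes_anova(ds, terms = c("group", "size"), n_perm = 0)
  y <- dataset_matrix(ds)
  g <- factor(ds$meta$genus)
  s <- log(ds$cs)
  rss <- function(fit) sum(residuals(fit)^2)
  r0 <- rss(lm(y ~ 1))
  r1 <- rss(lm(y ~ g))
  r2 <- rss(lm(y ~ g + s))
  tab <- res$table
  expect_equal(tab$SS[tab$term == "group"], r0 - r1, tolerance = 1e-9)
  expect_equal(tab$SS[tab$term == "size"], r1 - r2, tolerance = 1e-9)
  expect_equal(tab$SS[tab$term == "residual"], r2, tolerance = 1e-9)
  # SS decomposition: terms + residual = total
  expect_equal(sum(tab$SS[tab$term %in% c("group", "size", "residual")]),
               tab$SS[tab$term == "total"], tolerance = 1e-9)
  expect_true(all(tab$Rsq >= 0 & tab$Rsq <= 1))
})

test_that("zero-noise group offset gives R^2 = 1 and zero residual", {
  ds <- make_group_dataset(n_per = 3, offset = 0.4, noise = 0)
  res <- procrustes_anova(ds, terms = "group", n_perm = 19, seed = 1)
  tab <- res$table
  expect_equal(tab$Rsq[tab$term == "group"], 1, tolerance = 1e-9)
  expect_equal(tab$SS[tab$term == "residual"], 0, tolerance = 1e-12)
  expect_equal(tab$p[tab$term == "group"], 1 / 20)
})

test_that("R^2 is invariant to rigid motion of the raw configurations", {
  sim <- simulate_dataset(simulation_config(seed = 23))
  cfs <- sim$modern
  f1 <- symmetrize_pairs(gpa(cfs, scheme = sim$config$scheme))
  q <- random_rotation(5)
  cfs2 <- lapply(cfs, function(cf) {
    cf$coords <- cf$coords %*% q + 100
    cf
  })
  f2 <- symmetrize_pairs(gpa(cfs2, scheme = sim$config$scheme))
  a1 <- procrustes_anova(f1, n_perm = 0)
  a2 <- procrustes_anova(f2, n_perm = 0)
  expect_equal(a1$table$Rsq, a2$table$Rsq, tolerance = 1e-9)
})

test_that("permutation p-values are reproducible and properly bounded", {
  ds <- make_group_dataset(n_per = 5, offset = 0.05, noise = 0.05)
  a1 <- procrustes_anova(ds, terms = "group", n_perm = 99, seed = 7)
  a2 <- procrustes_anova(ds, terms = "group", n_perm = 99, seed = 7)
  expect_identical(a1$table$p, a2$table$p)
  p <- a1$table$p[1]
  expect_gte(p, 1 / 100)
  expect_lte(p, 1)
  expect_error(procrustes_anova(fake_dataset(
    list(random_coords(5), random_coords(5, 2), random_coords(5, 3)),
    data.frame(specimen_id = c("a", "b", "c"),
               genus = c("A", "A", "B"))), terms = "group"), "singleton")
})

test_that("pairwise tests are symmetric, calibrated, and saturate when separated", {
  # extreme separation: p at the permutation floor for every pair
  set.seed(71)
  k <- 6
  shapes <- c(lapply(1:4, function(i) random_coords(k, 80) +
                       matrix(rnorm(3 * k, 0, 0.01), k, 3)),
              lapply(1:4, function(i) random_coords(k, 81) +
                       matrix(rnorm(3 * k, 0, 0.01), k, 3)))
  ds <- fake_dataset(shapes, data.frame(specimen_id = paste0("s", 1:8),
                                        genus = rep(c("A", "B"), each = 4)))
  pw <- pairwise_group_tests(ds, n_perm = 49, seed = 2)
  expect_equal(pw$p, 1 / 50)
  # distance symmetry: recompute with relabelled groups
  ds2 <- ds
  ds2$meta$genus <- rep(c("B", "A"), each = 4)
  pw2 <- pairwise_group_tests(ds2, n_perm = 9, seed = 2)
  expect_equal(pw$distance, pw2$distance, tolerance = 1e-12)
  # identical groups: distances at the noise scale, p not extreme
  set.seed(72)
  shapes0 <- lapply(1:12, function(i) random_coords(k, 90) +
                      matrix(rnorm(3 * k, 0, 0.05), k, 3))
  ds0 <- fake_dataset(shapes0,
                      data.frame(specimen_id = paste0("n", 1:12),
                                 genus = rep(c("A", "B"), 6)))
  pw0 <- pairwise_group_tests(ds0, n_perm = 199, seed = 3)
  expect_gt(pw0$p, 0.05)
})

test_that("size ANOVA reproduces the hand-computed F and Tukey layout", {
  ds <- fake_dataset(lapply(1:6, function(i) random_coords(5, i)),
                     data.frame(specimen_id = paste0("s", 1:6),
                                genus = rep(c("A", "B"), each = 3)),
                     cs = c(1, 2, 3, 4, 5, 6))
  res <- size_anova_tukey(ds)
  # SSB = 13.5 on 1 df, SSW = 4 on 4 df -> F = 13.5
  expect_equal(res$anova$`F value`[1], 13.5, tolerance = 1e-9)
  expect_equal(res$anova$Df, c(1, 4))
  expect_equal(res$group_stats$mean, c(2, 5))
  expect_equal(res$group_stats$sd, c(1, 1))
  # Tukey p agrees with the studentized-range oracle
  q_obs <- abs(5 - 2) / sqrt(1 / 3)   # pooled MSW = 1, n = 3 per group
  expect_equal(res$tukey$p_adj, ptukey(q_obs, 2, 4, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_error(size_anova_tukey(fake_dataset(
    lapply(1:4, function(i) random_coords(5, i)),
    data.frame(specimen_id = paste0("s", 1:4),
               genus = rep(c("A", "B"), each = 2)),
    cs = c(1, 1, 2, 2))), "zero pooled")
})

test_that("univariate K_mult equals an independently coded Blomberg's K", {
  skip_if_not_installed("picante")
  tr <- ape::read.tree(
    text = "(((A:1,B:1):1,(C:0.5,D:1.5):1.2):0.3,E:2);")
  set.seed(8)
  x <- setNames(rnorm(5), tr$tip.label)
  k1 <- kmult(x, tr, n_perm = 2, seed = 1)$K
  k2 <- as.numeric(picante::Kcalc(x[tr$tip.label], tr))
  expect_equal(k1, k2, tolerance = 1e-9)
})

test_that("K_mult is invariant to branch-length rescaling and errors on flat data", {
  tr <- default_tree()
  set.seed(9)
  y <- matrix(rnorm(13 * 6), 13, dimnames = list(tr$tip.label, NULL))
  k1 <- kmult(y, tr, n_perm = 2, seed = 1)$K
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 37
  k2 <- kmult(y, tr2, n_perm = 2, seed = 1)$K
  expect_equal(k1, k2, tolerance = 1e-9)
  expect_error(kmult(matrix(1, 13, 4,
                            dimnames = list(tr$tip.label, NULL)), tr),
               "zero-variance")
  expect_error(kmult(y[1:10, ], tr), "without data")
})

test_that("white noise on an imbalanced tree yields K below 1", {
  # fully pectinate (comb) tree concentrates shared history; iid data
  # carry none of it, pushing K down
  tr <- ape::read.tree(text = paste0(
    "(((((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,F:5):1,G:6):1,H:7);"))
  set.seed(10)
  ks <- replicate(60, kmult(
    matrix(rnorm(8 * 4), 8, dimnames = list(tr$tip.label, NULL)),
    tr, n_perm = 2)$K)
  expect_lt(mean(ks), 1)
})
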