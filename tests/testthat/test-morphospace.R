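test_that("PCA recovers rank-1 structure and reconstructs losslessly", {
  k <- 10
  mean_s <- random_coords(k, seed = 40)
  v <- random_coords(k, seed = 41)
  v <- v / sqrt(sum(v^2))
  shapes <- lapply(seq(-2, 2, length.out = 5), function(t) mean_s + t * v)
  ds <- fake_dataset(shapes, data.frame(specimen_id = paste0("s", 1:5)))
  sp <- shape_pca(ds)
  expect_equal(length(sp$eigenvalues), 1L)
  expect_equal(sp$variance_fractions[[1]], 1)
  # full reconstruction: mean + scores %*% t(eigenvectors)
  x <- dataset_matrix(ds)
  recon <- matrix(rep(as.vector(t(sp$mean_shape)), 5), 5, byrow = TRUE) +
    sp$scores %*% t(sp$eigenvectors)
  expect_equal(recon, x, tolerance = 1e-9, ignore_attr = TRUE)
  # orthonormal eigenvectors, mean-zero scores
  g <- crossprod(sp$eigenvectors)
  expect_equal(g, diag(ncol(g)), tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(sp$scores))), 1e-9)
  expect_error(shape_pca(fake_dataset(shapes[1:2],
                                      data.frame(specimen_id = c("a", "b")))),
               "at least 3")
})

test_that("eigenvalues conserve total variance and stay ordered", {
  set.seed(42)
  shapes <- lapply(1:20, function(i) random_coords(8, seed = 100 + i))
  ds <- fake_dataset(shapes, data.frame(specimen_id = paste0("s", 1:20)))
  sp <- shape_pca(ds)
  x <- dataset_matrix(ds)
  total_var <- sum(apply(x, 2, var))
  expect_equal(sum(sp$eigenvalues), total_var, tolerance = 1e-9)
  expect_true(all(diff(sp$eigenvalues) <= 1e-12))
  expect_true(all(diff(sp$variance_fractions) <= 1e-12))
  expect_lte(length(sp$eigenvalues), 19)
})

test_that("leading eigenvalue matches the two-cluster analytic covariance", {
  # two point masses at +/- d/2 plus isotropic noise: leading eigenvalue
  # of the covariance is |d|^2/4 + sigma^2 (analytic oracle)
  set.seed(43)
  p <- 15
  d <- rnorm(p)
  d <- 2 * d / sqrt(sum(d^2))   # |d| = 2
  sigma <- 0.1
  n <- 200
  x <- matrix(rnorm(n * p, 0, sigma), n, p) +
    outer(rep(c(-0.5, 0.5), each = n / 2), d)
  ev <- eigen(cov(x), symmetric = TRUE, only.values = TRUE)$values
  expected <- sum(d^2) / 4 + sigma^2
  expect_lt(abs(ev[1] - expected) / expected, 0.05)
})

test_that("projection of new specimens is consistent with training scores", {
  sim <- simulate_dataset(simulation_config(seed = 19))
  fit <- slide_semilandmarks(gpa(sim$modern, scheme = sim$config$scheme))
  sym <- symmetrize_pairs(fit)
  sp <- shape_pca(sym)
  # a training specimen's aligned shape projects onto its stored scores
  # (already centred, unit CS and optimally rotated, so re-alignment is
  # idempotent)
  tr_shape <- sym$shapes[5, , ]
  sc <- predict(sp, tr_shape, slide = FALSE)
  expect_equal(as.vector(sc), as.vector(sp$scores[5, ]), tolerance = 1e-8)
  # the training mean projects to the exact zero vector, and the
  # (renormalized) consensus to within its distance from the mean, which
  # is bounded by the total Procrustes variance
  expect_lt(max(abs(predict(sp, sp$mean_shape, align = FALSE))), 1e-10)
  sc0 <- predict(sp, sp$consensus, slide = FALSE)
  expect_lt(max(abs(sc0)), sum(sp$eigenvalues))
  # constructed inverse problem: mean + 2 * PC1 projects to (2, 0, ...)
  target <- shape_at_score(sp, 1, 2)
  sc2 <- predict(sp, target, align = FALSE)
  expect_equal(sc2[1, 1], 2, tolerance = 1e-6)
  expect_lt(max(abs(sc2[1, -1])), 1e-6)
  # full alignment is invariant to the unknown's rigid frame and scale
  sc2a <- predict(sp, target, slide = FALSE)
  moved <- 3.3 * target %*% random_rotation(77) + 10
  sc3 <- predict(sp, moved, slide = FALSE)
  expect_equal(as.vector(sc3), as.vector(sc2a), tolerance = 1e-8)
  expect_error(predict(sp, random_coords(7, seed = 1)), "landmarks")
})

test_that("shape_at_score and projection are an inverse pair", {
  shapes <- lapply(1:6, function(i)
    base_template() + matrix(rnorm(165, 0, 0.03), 55, 3))
  ds <- fake_dataset(shapes, data.frame(specimen_id = paste0("s", 1:6)))
  ds$consensus <- ds$consensus /
    sqrt(sum(sweep(ds$consensus, 2, colMeans(ds$consensus))^2))
  sp <- shape_pca(ds)
  expect_equal(shape_at_score(sp, 2, 0), sp$mean_shape)
  # most-negative PC1 specimen: rank-1 reconstruction comparison
  i_min <- which.min(sp$scores[, 1])
  rec <- shape_at_score(sp, 1, min(sp$scores[, 1]))
  oracle <- diplomorph:::unvec_shape(
    as.vector(t(sp$mean_shape)) + sp$scores[i_min, 1] * sp$eigenvectors[, 1])
  expect_equal(rec, oracle, tolerance = 1e-12)
  expect_error(shape_at_score(sp, 99, 1), "axis")
})

test_that("ancestral states obey closed-form Brownian expectations", {
  # equal branches: midpoint
  t1 <- ape::read.tree(text = "(A:1,B:1);")
  a1 <- ancestral_states(c(A = 0, B = 2), t1)
  expect_equal(unname(a1$nodes[1, 1]), 1)
  # unequal branches: inverse-branch-length weighting
  t2 <- ape::read.tree(text = "(A:1,B:3);")
  a2 <- ancestral_states(c(A = 0, B = 2), t2)
  expect_equal(unname(a2$nodes[1, 1]), (0 / 1 + 2 / 3) / (1 / 1 + 1 / 3),
               tolerance = 1e-9)
  # the same value maximizes the Brownian likelihood (numerical check):
  # root x minimizes (x-a)^2/la + (x-b)^2/lb
  opt <- optimize(function(x) (x - 0)^2 / 1 + (x - 2)^2 / 3, c(-5, 5),
                  tol = 1e-10)
  expect_equal(unname(a2$nodes[1, 1]), opt$minimum, tolerance = 1e-6)
  # star tree: arithmetic mean
  t3 <- ape::read.tree(text = "(A:1,B:1,C:1);")
  a3 <- ancestral_states(c(A = 1, B = 2, C = 6), t3)
  expect_equal(unname(a3$nodes[1, 1]), 3, tolerance = 1e-9)
  expect_error(ancestral_states(c(A = 0, B = 1), default_tree()),
               "without")
})

test_that("TPS warp interpolates exactly and reproduces affine maps", {
  src <- random_coords(12, seed = 50)
  # identity
  expect_equal(tps_warp(src, src, random_coords(20, seed = 51)),
               random_coords(20, seed = 51), tolerance = 1e-9)
  # exact interpolation of landmarks
  tgt <- src + random_coords(12, seed = 52) * 0.3
  expect_equal(tps_warp(src, tgt, src), tgt, tolerance = 1e-9)
  # affine exactness on arbitrary query points
  aff <- matrix(c(1.2, 0.1, -0.3, 0, 0.9, 0.2, 0.4, -0.1, 1.1), 3)
  b <- c(1, -2, 0.5)
  tgt_aff <- src %*% aff + matrix(b, 12, 3, byrow = TRUE)
  q <- random_coords(30, seed = 53)
  expect_equal(tps_warp(src, tgt_aff, q),
               q %*% aff + matrix(b, 30, 3, byrow = TRUE),
               tolerance = 1e-8)
  expect_error(tps_warp(src[1:4, ], src[1:4, ]), "at least 5")
})
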