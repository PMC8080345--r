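# Shared fixtures and independent oracles for the suite.

# tiny scheme: 3 fixed landmarks, one curve of 3 semilandmarks
tiny_scheme <- function() {
  landmark_scheme(3L, list(list(start = 1L, semis = 4:6, end = 2L)))
}

# deterministic non-degenerate K x 3 configuration
random_coords <- function(k, seed = 1, scale = 1) {
  set.seed(seed)
  matrix(rnorm(3 * k), k, 3) * scale
}

rotation_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# independent OPA oracle: minimize the scaled residual over rotations by
# Euler-angle grid search plus Nelder-Mead refinement (no SVD involved)
oracle_opa_residual <- function(moving, target) {
  a <- sweep(moving, 2, colMeans(moving))
  b <- sweep(target, 2, colMeans(target))
  resid_at <- function(ang) {
    rz1 <- rotation_z(ang[1])
    rx <- rbind(c(1, 0, 0),
                c(0, cos(ang[2]), -sin(ang[2])),
                c(0, sin(ang[2]), cos(ang[2])))
    rz2 <- rotation_z(ang[3])
    q <- rz1 %*% rx %*% rz2
    aq <- a %*% q
    # optimal non-negative scale (negative scale would smuggle in the
    # improper transform -Q)
    s <- max(sum(aq * b) / sum(a * a), 0)
    sqrt(sum((s * aq - b)^2))
  }
  grid <- expand.grid(a1 = seq(0, 2 * pi, length.out = 19)[-19],
                      a2 = seq(0, pi, length.out = 10),
                      a3 = seq(0, 2 * pi, length.out = 19)[-19])
  vals <- apply(grid, 1, resid_at)
  starts <- order(vals)[1:8]
  min(vapply(starts, function(i)
    optim(as.numeric(grid[i, ]), resid_at, method = "Nelder-Mead",
          control = list(reltol = 1e-14, maxit = 5000))$value, 0))
}

# minimal aligned-dataset stand-in for the statistics modules: shapes are
# taken as given (already "aligned"), metadata supplied directly
fake_dataset <- function(shapes_list, meta, cs = NULL) {
  k <- nrow(shapes_list[[1]])
  arr <- array(NA_real_, c(length(shapes_list), k, 3))
  for (i in seq_along(shapes_list)) arr[i, , ] <- shapes_list[[i]]
  list(shapes = arr, cs = if (is.null(cs)) rep(1, length(shapes_list)) else cs,
       consensus = Reduce(`+`, shapes_list) / length(shapes_list),
       meta = meta, scheme = NULL)
}

# vectorized-shape matrix of a dataset (same layout the package uses)
dataset_matrix <- function(dataset) {
  t(apply(dataset$shapes, 1, function(s) as.vector(t(s))))
}
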