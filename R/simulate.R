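## Synthetic-data generator: landmark datasets with the statistical
## structure the analysis chain assumes — among-genus shape divergence
## evolved by Brownian motion on a species tree, within-species noise, a
## weak allometric size-shape component, bilateral pairs with small
## left-right asymmetry, and unpaired "fossil" elements of unknown
## affinity — emitted in random rigid frames so superimposition has real
## work to do.

#' Default species phylogeny for the synthetic study
#'
#' A rooted, ultrametric 13-tip tree over 5 genera (3 + 1 + 2 + 3 + 4
#' species), root depth 15, mimicking a two-clade radiation in which one
#' clade holds two of the genera and the other three.
#' @return an `ape::phylo` tree.
#' @export
default_tree <- function() {
  txt <- paste0(
    "((((Woodworthia_sp1:2,Woodworthia_sp2:2):2,",
    "(Woodworthia_sp3:3,Woodworthia_sp4:3):1):6,",
    "Hoplodactylus_duvaucelii:10):5,",
    "((Dactylocnemis_sp1:3,(Dactylocnemis_sp2:2,Dactylocnemis_sp3:2):1):8,",
    "((Mokopirirakau_sp1:4,Mokopirirakau_sp2:4):5,",
    "(Naultinus_sp1:3,(Naultinus_sp2:2,Naultinus_sp3:2):1):6):2):4);")
  validate_phylogeny(ape::read.tree(text = txt))
}

#' Template base shape for the default scheme
#'
#' A deterministic, non-degenerate 3D template: the four curve anchors and
#' forty semilandmarks lie on a closed undulating loop (an ellipse with a
#' dorsoventral wave), the remaining fixed landmarks sit off the loop and
#' in the interior. Landmarks follow [default_scheme()] ids.
#' @param scheme a [landmark_scheme()]; only the default layout is
#'   supported.
#' @return a K x 3 matrix.
#' @export
base_template <- function(scheme = default_scheme()) {
  loop <- function(th) cbind(2 * cos(th), sin(th), 0.4 * sin(2 * th))
  coords <- matrix(NA_real_, scheme$total, 3)
  anchors <- c(1, 4, 8, 12)
  anchor_th <- c(0, pi / 2, pi, 3 * pi / 2)
  coords[anchors, ] <- loop(anchor_th)
  # off-loop fixed landmarks (ridges, processes, interior points)
  off <- rbind(c(1.7, 1.0, 0.9), c(0.9, 1.4, -0.4),      # 2, 3
               c(-0.8, 1.3, 0.7), c(-1.6, 0.9, -0.5), c(-2.1, 0.3, 0.6),
               c(-1.5, -0.9, 0.8), c(-0.7, -1.4, -0.6),  # 9, 10
               c(0.8, -1.3, 0.5),                         # 11
               c(0.5, 0.2, 1.1), c(-0.5, -0.1, -1.0), c(0.1, -0.4, 0.8))
  coords[c(2, 3, 5, 6, 7, 9, 10, 11, 13, 14, 15), ] <- off
  for (i in seq_along(scheme$curves)) {
    cv <- scheme$curves[[i]]
    th <- seq(anchor_th[i], anchor_th[i] + pi / 2,
              length.out = length(cv$semis) + 2)
    coords[cv$semis, ] <- loop(th[-c(1, length(th))])
  }
  coords
}

# fixed allometric shape direction: dorsoventral deepening, orthogonalized
# against uniform scaling (which superimposition would remove anyway)
allometry_direction <- function(base) {
  centred <- center_shape(base)
  v_scale <- as.vector(t(centred))
  v_scale <- v_scale / sqrt(sum(v_scale^2))
  d <- as.vector(t(cbind(0 * centred[, 1], 0 * centred[, 2], centred[, 3])))
  d <- d - sum(d * v_scale) * v_scale
  d / sqrt(sum(d^2))
}

#' Simulation configuration for the synthetic study
#'
#' Defaults emulate the study design the package targets: 13 species in 5
#' genera, 43 modern individuals with paired left/right elements (86
#' configurations), 11 unpaired subfossil elements, genus-level shape
#' divergence evolved by Brownian motion on [default_tree()], isotropic
#' within-species landmark noise, a weak allometric component (about 7% of
#' symmetric shape variance at the default coefficient), small left-right
#' asymmetry, and genus centroid-size distributions of
#' 1690±228.1, 968±100.9, 1198±142.9, 1241±115.6 and 1093±104.0 CT units.
#'
#' @param scheme landmark scheme (default [default_scheme()]).
#' @param tree species tree; genus of each species is the tip-label
#'   prefix before the first underscore.
#' @param n_per_species named integer vector of individuals per species
#'   (default sums to 43).
#' @param bm_rate Brownian per-coordinate shape variance per unit branch
#'   length.
#' @param within_sd per-coordinate within-species shape standard
#'   deviation.
#' @param asymmetry_sd per-coordinate left-right asymmetry sd.
#' @param tangent_jitter_sd optional extra semilandmark jitter directed
#'   along curve tangents (gives sliding realistic work; default 0).
#' @param allometry_coefficient shape displacement along the fixed
#'   allometric direction per unit deviation of log centroid size from the
#'   genus mean.
#' @param size_means,size_sds named per-genus centroid-size mean and sd.
#' @param n_fossils number of unpaired subfossil elements.
#' @param fossil_from_genus genus whose shape distribution generates the
#'   fossils.
#' @param fossil_size_mean,fossil_size_sd fossil centroid-size
#'   distribution (fossils run larger than the modern sample).
#' @param fossil_offset optional 3K shape offset added to every fossil
#'   (e.g. to place fossils outside all reference groups); default none.
#' @param seed RNG seed.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(
    scheme = default_scheme(), tree = default_tree(),
    n_per_species = NULL,
    bm_rate = 4e-4, within_sd = 0.05, asymmetry_sd = 0.02,
    tangent_jitter_sd = 0,
    allometry_coefficient = 2.05,
    size_means = c(Dactylocnemis = 1198, Hoplodactylus = 1690,
                   Mokopirirakau = 1241, Naultinus = 1093,
                   Woodworthia = 968),
    size_sds = c(Dactylocnemis = 142.9, Hoplodactylus = 228.1,
                 Mokopirirakau = 115.6, Naultinus = 104.0,
                 Woodworthia = 100.9),
    n_fossils = 11, fossil_from_genus = "Hoplodactylus",
    fossil_size_mean = 1900, fossil_size_sd = 200,
    fossil_offset = NULL, seed = 42) {
  if (is.null(n_per_species)) {
    n_per_species <- c(
      Woodworthia_sp1 = 3, Woodworthia_sp2 = 3, Woodworthia_sp3 = 3,
      Woodworthia_sp4 = 3, Hoplodactylus_duvaucelii = 7,
      Dactylocnemis_sp1 = 3, Dactylocnemis_sp2 = 3, Dactylocnemis_sp3 = 3,
      Mokopirirakau_sp1 = 4, Mokopirirakau_sp2 = 4,
      Naultinus_sp1 = 3, Naultinus_sp2 = 2, Naultinus_sp3 = 2)
  }
  stopifnot(all(tree$tip.label %in% names(n_per_species)),
            bm_rate >= 0, within_sd >= 0, asymmetry_sd >= 0,
            tangent_jitter_sd >= 0)
  structure(list(scheme = scheme, tree = tree,
                 n_per_species = n_per_species, bm_rate = bm_rate,
                 within_sd = within_sd, asymmetry_sd = asymmetry_sd,
                 tangent_jitter_sd = tangent_jitter_sd,
                 allometry_coefficient = allometry_coefficient,
                 size_means = size_means, size_sds = size_sds,
                 n_fossils = n_fossils,
                 fossil_from_genus = fossil_from_genus,
                 fossil_size_mean = fossil_size_mean,
                 fossil_size_sd = fossil_size_sd,
                 fossil_offset = fossil_offset, seed = seed),
            class = "simulation_config")
}

#' Evolve species mean shapes by Brownian motion on a tree
#'
#' Independent Brownian increments per coordinate along every branch; each
#' tip inherits the root (base) shape plus the summed increments along its
#' path, so a tip coordinate has variance `bm_rate` times its root-to-tip
#' length and two tips covary by `bm_rate` times their shared path length.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param base_shape K x 3 root shape.
#' @param bm_rate per-coordinate variance per unit branch length.
#' @param seed optional RNG seed.
#' @return named list of K x 3 species mean shapes (one per tip).
#' @export
simulate_bm_shapes <- function(tree, base_shape, bm_rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(base_shape)
  ntip <- ape::Ntip(tree)
  node_vals <- matrix(NA_real_, ntip + tree$Nnode, p)
  root <- ntip + 1L
  node_vals[root, ] <- as.vector(base_shape)
  # edges in preorder so parents are filled before children
  for (e in order(tree$edge[, 1])) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    node_vals[child, ] <- node_vals[par, ] +
      stats::rnorm(p, 0, sqrt(bm_rate * len))
  }
  out <- lapply(seq_len(ntip), function(i)
    matrix(node_vals[i, ], nrow(base_shape), 3))
  names(out) <- tree$tip.label
  out
}

# random proper rotation (Haar-ish via QR) and translation
random_rigid <- function(x, trans_scale = 5) {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(x %*% q, 2, stats::rnorm(3, 0, trans_scale * mean(abs(x))), `+`)
}

#' Simulate a full bilateral landmark study
#'
#' Generates modern individuals (paired left and right elements) and
#' unpaired subfossil elements under a [simulation_config()]. Each
#' individual is its species Brownian mean plus isotropic within-species
#' noise plus the allometric displacement
#' `allometry_coefficient * (log CS - genus mean log CS)` along the fixed
#' allometric direction; the right element adds the individual's
#' asymmetry vector and the left subtracts it before mirroring. Every
#' element is rescaled to its drawn centroid size and emitted in a random
#' rigid frame.
#'
#' @param config a [simulation_config()].
#' @return list with `modern` (list of [configuration()]s,
#'   2 x individuals), `fossils` (unpaired subfossil configurations,
#'   species/genus unset), `truth` (data.frame of the fossils' generating
#'   species/genus), `species_shapes`, and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  set.seed(config$seed)
  scheme <- config$scheme
  base <- base_template(scheme)
  k <- scheme$total
  u_allo <- allometry_direction(base)
  species_shapes <- simulate_bm_shapes(config$tree, base, config$bm_rate)
  genus_of <- function(sp) sub("_.*", "", sp)
  nb <- if (config$tangent_jitter_sd > 0) curve_neighbours(scheme) else NULL

  make_individual <- function(sp, cs) {
    gen <- genus_of(sp)
    shp <- species_shapes[[sp]] +
      matrix(stats::rnorm(3 * k, 0, config$within_sd), k, 3)
    dev <- log(cs) - log(config$size_means[[gen]])
    shp <- shp + config$allometry_coefficient * dev *
      matrix(u_allo, k, 3, byrow = TRUE)
    if (!is.null(nb)) {
      for (id_chr in names(nb)) {
        id <- as.integer(id_chr)
        tg <- shp[nb[[id_chr]]["nxt"], ] - shp[nb[[id_chr]]["prev"], ]
        tg <- tg / sqrt(sum(tg^2))
        shp[id, ] <- shp[id, ] +
          stats::rnorm(1, 0, config$tangent_jitter_sd) * tg
      }
    }
    shp
  }
  emit <- function(shp, cs) {
    shp <- center_shape(shp)
    random_rigid(shp * (cs / sqrt(sum(shp^2))))
  }

  modern <- list()
  idx <- 0L
  for (sp in names(config$n_per_species)) {
    gen <- genus_of(sp)
    for (j in seq_len(config$n_per_species[[sp]])) {
      idx <- idx + 1L
      id <- sprintf("mod%02d", idx)
      cs <- max(stats::rnorm(1, config$size_means[[gen]],
                             config$size_sds[[gen]]),
                0.3 * config$size_means[[gen]])
      ind <- make_individual(sp, cs)
      asym <- matrix(stats::rnorm(3 * k, 0, config$asymmetry_sd), k, 3)
      right <- emit(ind + asym, cs)
      left <- emit(ind - asym, cs)
      left[, 1] <- -left[, 1]
      modern[[length(modern) + 1L]] <- configuration(
        right, id, species = sp, genus = gen, side = "right")
      modern[[length(modern) + 1L]] <- configuration(
        left, id, species = sp, genus = gen, side = "left")
    }
  }

  fossil_species <- names(config$n_per_species)[
    genus_of(names(config$n_per_species)) == config$fossil_from_genus]
  fossils <- list()
  truth <- data.frame(specimen_id = character(0), species = character(0),
                      genus = character(0))
  for (f in seq_len(config$n_fossils)) {
    sp <- sample(fossil_species, 1)
    id <- sprintf("fossil%s", LETTERS[f])
    cs <- max(stats::rnorm(1, config$fossil_size_mean,
                           config$fossil_size_sd),
              0.3 * config$fossil_size_mean)
    shp <- make_individual(sp, cs)
    if (!is.null(config$fossil_offset))
      shp <- shp + matrix(config$fossil_offset, k, 3, byrow = TRUE)
    side <- if (f %% 2 == 0) "left" else "right"
    coords <- emit(shp, cs)
    if (side == "left") coords[, 1] <- -coords[, 1]
    fossils[[f]] <- configuration(coords, id, side = side,
                                  era = "subfossil")
    truth <- rbind(truth, data.frame(specimen_id = id, species = sp,
                                     genus = config$fossil_from_genus))
  }
  list(modern = modern, fossils = fossils, truth = truth,
       species_shapes = species_shapes, config = config)
}
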