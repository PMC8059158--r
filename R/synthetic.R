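# Synthetic-study generator: complete fake comparative studies (tree,
# specimen-level landmark configurations, ecology tables, truth record) so
# every stage of the pipeline is testable without any specimen downloads.

#' Deterministic ellipsoid landmark template
#'
#' A cranium-sized stand-in template: K points spread over an elongate
#' ellipsoid by the Fibonacci spiral, scaled to unit centroid size. The
#' first `n_fixed` points are fixed landmarks and the next `n_curve` are
#' curve semilandmarks; the remaining patch semilandmarks are split into a
#' facial patch (anterior half, largest x) and a neurocranial patch
#' (posterior half). Purely geometric: it is not an anatomical model.
#'
#' @param n_fixed,n_curve,n_patch landmark counts by role.
#' @return list: `coords` (K x 3, unit centroid size), `roles`, `subsets`.
#' @export
skull_template <- function(n_fixed = 46L, n_curve = 191L, n_patch = 144L) {
  k <- n_fixed + n_curve + n_patch
  i <- seq_len(k)
  z <- 1 - 2 * (i - 0.5) / k
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  pts <- cbind(1.6 * z, 1.0 * r * cos(golden * i), 0.8 * r * sin(golden * i))
  pts <- pts / centroid_size(pts)
  roles <- c(rep("fixed", n_fixed), rep("curve_semilandmark", n_curve),
             rep("patch_semilandmark", n_patch))
  subsets <- rep("other", k)
  patch_idx <- which(roles == "patch_semilandmark")
  ord <- patch_idx[order(pts[patch_idx, 1L], decreasing = TRUE)]
  half <- floor(length(patch_idx) / 2)
  subsets[ord[seq_len(half)]] <- "facial"
  subsets[ord[half + seq_len(half)]] <- "neurocranial"
  list(coords = pts, roles = roles, subsets = subsets)
}

#' Define a synthetic study scenario
#'
#' Bundles every knob of the generator. The defaults emulate the structure
#' of a specimen-level cranial-shape study: 57 species with four specimens
#' each, a 381-point template (46 fixed, 191 curve and 144 patch
#' semilandmarks; 72-point facial and neurocranial patches), species means
#' evolving by multivariate Brownian motion on a unit-depth pure-birth
#' tree, an optional convergent regime pulling a focal tip set toward a
#' shared phenotype, allometric size effects, and a prey/predator mass
#' ratio tied to the first latent shape axis.
#'
#' @param n_species number of species.
#' @param n_specimens_per_species specimens digitized per species.
#' @param p_latent number of latent shape traits.
#' @param rate_matrix p x p BM rate matrix (default identity).
#' @param n_focal size of the focal (convergent-regime) species set; the
#'   last `n_focal` species are the focal set, the first of them playing the
#'   focal "unknown" downstream.
#' @param convergence_weight w in [0, 1]: each focal species mean is blended
#'   `(1 - w) * own + w * target` with a shared drawn target; w = 0 recovers
#'   pure Brownian motion.
#' @param template landmark template (see [skull_template()]); unit
#'   centroid size.
#' @param deform_scale landmark displacement per unit latent trait, as a
#'   fraction of centroid size.
#' @param specimen_noise_sd per-coordinate digitizing/individual noise, unit
#'   centroid-size frame.
#' @param base_size mean centroid size in mm.
#' @param allometry_slope b: specimen centroid size is
#'   `base_size * exp(b * latent_1)`.
#' @param ecology_effect a: species log prey/predator ratio is
#'   `log(0.45) + a * latent_1 + noise`, so the class boundary sits at
#'   latent_1 = 0.
#' @param ecology_noise_sd noise sd on the log ratio.
#' @param seed integer; every random draw of the study flows from it.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_species = 57L,
                               n_specimens_per_species = 4L,
                               p_latent = 4L,
                               rate_matrix = diag(p_latent),
                               n_focal = 3L,
                               convergence_weight = 0,
                               template = skull_template(),
                               deform_scale = 0.05,
                               specimen_noise_sd = 0.001,
                               base_size = 100,
                               allometry_slope = 0.3,
                               ecology_effect = 1,
                               ecology_noise_sd = 0.3,
                               seed = 1L) {
  if (convergence_weight < 0 || convergence_weight > 1) {
    stop("convergence_weight must lie in [0, 1]")
  }
  stopifnot(n_species >= 4L, n_specimens_per_species >= 1L,
            nrow(rate_matrix) == p_latent)
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic scenario:", x$n_species, "species x",
      x$n_specimens_per_species, "specimens,",
      nrow(x$template$coords), "landmarks, w =", x$convergence_weight,
      "( seed", x$seed, ")\n")
  invisible(x)
}

#' Simulate a complete synthetic study
#'
#' Draws the tree, evolves latent species means by Brownian motion, applies
#' the convergent regime to the focal set, maps latents to landmarks through
#' a seeded orthonormal deformation basis, re-embeds each specimen with
#' Gaussian coordinate noise, a random rotation/translation, and an
#' allometric size factor (so Procrustes alignment has real work to undo),
#' and derives a matching ecology table. All randomness flows from the
#' scenario seed; the same scenario reproduces the same study bit for bit.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list of class `synthetic_study`: `tree`, `configs` (list of
#'   [landmark_config]), `ecology` (an `ecology_table`), `raw_ecology`,
#'   `truth` (species latents, focal flags, target phenotype), `scenario`.
#' @export
simulate_study <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  ns <- scenario$n_species
  p <- scenario$p_latent
  tree <- simulate_tree(ns)
  species <- tree$tip.label

  model <- structure(list(rate_matrix = scenario$rate_matrix,
                          root_state = rep(0, p)),
                     class = "bm_model")
  latents <- matrix(simulate_bm(tree, model, n_sims = 1L)[1L, , ], ns, p,
                    dimnames = list(species, paste0("latent", seq_len(p))))

  focal <- tail(species, scenario$n_focal)
  w <- scenario$convergence_weight
  target <- drop(psd_sqrt(scenario$rate_matrix) %*% stats::rnorm(p))
  if (w > 0) {
    for (sp in focal) latents[sp, ] <- (1 - w) * latents[sp, ] + w * target
  }

  # seeded orthonormal latent -> landmark map
  k <- nrow(scenario$template$coords)
  B <- qr.Q(qr(matrix(stats::rnorm(3L * k * p), 3L * k, p)))  # (3K) x p
  basis <- t(B) * scenario$deform_scale                        # p x 3K

  configs <- list()
  for (s in seq_len(ns)) {
    mean_flat <- as.vector(t(scenario$template$coords)) + latents[s, ] %*% basis
    for (j in seq_len(scenario$n_specimens_per_species)) {
      flat <- mean_flat + stats::rnorm(3L * k, sd = scenario$specimen_noise_sd)
      coords <- matrix(flat, k, 3L, byrow = TRUE)
      size <- scenario$base_size *
        exp(scenario$allometry_slope * latents[s, 1L])
      coords <- coords * size
      coords <- coords %*% random_rotation() +
        matrix(stats::rnorm(3L, sd = 10), k, 3L, byrow = TRUE)
      configs[[length(configs) + 1L]] <- landmark_config(
        coords,
        specimen_id = sprintf("%s__%02d", species[s], j),
        species_id = species[s],
        sex = if (j %% 2L) "f" else "m",
        roles = scenario$template$roles,
        subsets = scenario$template$subsets)
    }
  }

  ln_ratio <- log(PREY_RATIO_CUT) + scenario$ecology_effect * latents[, 1L] +
    stats::rnorm(ns, sd = scenario$ecology_noise_sd)
  body_mass <- exp(stats::rnorm(ns, log(10), 0.8))
  pack_size <- ifelse(stats::runif(ns) < 0.1, sample(2:8, ns, replace = TRUE), 1L)
  vert <- stats::runif(ns, 0.3, 0.95)
  invert <- (1 - vert) * stats::runif(ns, 0.5, 1)
  raw_ecology <- data.frame(
    species = species,
    body_mass = body_mass,
    prey_mass = exp(ln_ratio) * pack_size * body_mass,
    pack_size = pack_size,
    vertebrates = vert,
    invertebrates = invert,
    fruit = pmax(0, 1 - vert - invert),
    stringsAsFactors = FALSE)
  ecology <- build_ecology(raw_ecology)

  truth <- data.frame(species = species, latents,
                      ln_prey_ratio = ln_ratio,
                      focal = species %in% focal,
                      stringsAsFactors = FALSE)
  attr(truth, "target") <- target
  structure(
    list(tree = tree, configs = configs, ecology = ecology,
         raw_ecology = raw_ecology, truth = truth, focal = focal,
         scenario = scenario),
    class = "synthetic_study")
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", length(x$tree$tip.label), "species,",
      length(x$configs), "specimens | focal:",
      paste(x$focal, collapse = ", "), "\n")
  invisible(x)
}

#' Miniature deterministic study for tests and examples
#'
#' 8 species x 3 specimens x 20 landmarks (4 fixed, 4 curve, 12 patch; 6
#' facial + 6 neurocranial), with both prey-size classes populated.
#' Deterministic: repeated calls return the identical study.
#'
#' @param convergence_weight optional convergent-regime strength.
#' @param seed scenario seed (fixed default for reproducibility).
#' @return a `synthetic_study`.
#' @export
fixture_small <- function(convergence_weight = 0, seed = 42L) {
  simulate_study(synthetic_scenario(
    n_species = 8L, n_specimens_per_species = 3L, p_latent = 3L,
    rate_matrix = diag(3L), n_focal = 2L,
    convergence_weight = convergence_weight,
    template = skull_template(n_fixed = 4L, n_curve = 4L, n_patch = 12L),
    seed = seed))
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Landmarks as TPS, tree as Newick, ecology and subset map as CSV, truth
#' record as CSV.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    landmarks = file.path(dir, "landmarks.tps"),
    tree = file.path(dir, "tree.nwk"),
    ecology = file.path(dir, "ecology.csv"),
    subset_map = file.path(dir, "subset_map.csv"),
    truth = file.path(dir, "truth.csv"))
  write_landmarks(study$configs, paths$landmarks, format = "tps")
  ape::write.tree(study$tree, paths$tree)
  utils::write.csv(study$raw_ecology, paths$ecology, row.names = FALSE)
  tpl <- study$configs[[1L]]
  utils::write.csv(
    data.frame(landmark_index = seq_along(tpl$subsets) - 1L,
               subset = tpl$subsets, role = tpl$roles),
    paths$subset_map, row.names = FALSE)
  utils::write.csv(study$truth, paths$truth, row.names = FALSE)
  paths
}
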