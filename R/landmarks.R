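# Landmark configurations, TPS/CSV I/O, and generalized Procrustes alignment.

#' Construct a single landmark configuration
#'
#' Bundles one specimen's K x 3 landmark coordinates with its identifiers and
#' per-landmark annotations. Roles distinguish fixed landmarks from curve and
#' patch semilandmarks (only semilandmarks are ever slid); subsets carve the
#' configuration into the facial and neurocranial patches analysed as
#' separate datasets.
#'
#' @param coords numeric K x 3 matrix of landmark coordinates (mm).
#' @param specimen_id,species_id character scalars; preserved verbatim.
#' @param sex character scalar, `"unknown"` if not recorded.
#' @param roles length-K character vector in
#'   `c("fixed", "curve_semilandmark", "patch_semilandmark")`.
#' @param subsets length-K character vector in
#'   `c("facial", "neurocranial", "other")`.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(coords, specimen_id, species_id,
                            sex = "unknown",
                            roles = rep("fixed", nrow(coords)),
                            subsets = rep("other", nrow(coords))) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) {
    stop("coords must be a K x 3 matrix, got ", ncol(coords), " columns")
  }
  if (!all(is.finite(coords))) {
    stop("non-finite coordinate in specimen '", specimen_id, "'")
  }
  if (length(roles) != nrow(coords) || length(subsets) != nrow(coords)) {
    stop("roles/subsets length must equal the landmark count")
  }
  bad_role <- setdiff(roles, c("fixed", "curve_semilandmark", "patch_semilandmark"))
  if (length(bad_role)) stop("unknown landmark role: ", bad_role[1])
  bad_sub <- setdiff(subsets, c("facial", "neurocranial", "other"))
  if (length(bad_sub)) stop("unknown landmark subset: ", bad_sub[1])
  structure(
    list(specimen_id = as.character(specimen_id),
         species_id = as.character(species_id),
         sex = as.character(sex),
         coords = unname(coords),
         roles = as.character(roles),
         subsets = as.character(subsets)),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration: specimen", x$specimen_id,
      "| species", x$species_id, "\n")
  cat("  ", nrow(x$coords), "landmarks (",
      sum(x$roles == "fixed"), "fixed,",
      sum(x$roles == "curve_semilandmark"), "curve,",
      sum(x$roles == "patch_semilandmark"), "patch )\n")
  invisible(x)
}

check_equal_k <- function(configs) {
  ks <- vapply(configs, function(cf) nrow(cf$coords), integer(1))
  if (length(unique(ks)) > 1L) {
    off <- which(ks != ks[1])[1]
    stop("landmark count mismatch: specimen '", configs[[off]]$specimen_id,
         "' has ", ks[off], " landmarks, expected ", ks[1])
  }
  ks[1]
}

#' Read landmark configurations from TPS or wide CSV files
#'
#' TPS records are `LM3=<K>` followed by K whitespace-separated `x y z` rows
#' and an `ID=` line. IDs of the form `species__specimen` are split into the
#' two identifiers; otherwise supply `species_map`. The wide CSV layout has
#' columns `specimen, species, sex, x1, y1, z1, x2, ...`.
#'
#' @param path file to read.
#' @param format `"tps"` or `"csv"`; guessed from the extension by default.
#' @param subset_map optional data frame with columns `landmark_index`
#'   (0-based) and `subset`, optionally `role`, attached to every specimen.
#' @param species_map optional named character vector, specimen id -> species id.
#' @return list of [landmark_config] objects, one per specimen.
#' @export
read_landmarks <- function(path, format = c("auto", "tps", "csv"),
                           subset_map = NULL, species_map = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  configs <- if (format == "tps") {
    read_landmarks_tps(path, species_map)
  } else {
    read_landmarks_csv(path)
  }
  check_equal_k(configs)
  if (!is.null(subset_map)) {
    configs <- lapply(configs, apply_subset_map, subset_map = subset_map)
  }
  configs
}

read_landmarks_tps <- function(path, species_map = NULL) {
  lines <- readLines(path)
  configs <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM3?=", ln)) stop("expected LM3= record at line ", i, " of ", path)
    k <- as.integer(sub("^LM3?=", "", ln))
    if (i + k > length(lines)) stop("truncated TPS record starting at line ", i)
    coords <- matrix(NA_real_, k, 3L)
    for (j in seq_len(k)) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + j]), "\\s+")[[1]]))
      if (length(vals) != 3L || anyNA(vals)) {
        stop("non-numeric or incomplete coordinate at line ", i + j, " of ", path)
      }
      coords[j, ] <- vals
    }
    i <- i + k + 1L
    id <- NA_character_
    while (i <= length(lines) && !grepl("^LM3?=", trimws(lines[i]))) {
      if (grepl("^ID=", trimws(lines[i]))) id <- sub("^ID=", "", trimws(lines[i]))
      i <- i + 1L
    }
    if (is.na(id)) stop("TPS record without ID= line in ", path)
    if (grepl("__", id, fixed = TRUE)) {
      parts <- strsplit(id, "__", fixed = TRUE)[[1]]
      species <- parts[1]
      specimen <- id
    } else {
      specimen <- id
      species <- if (!is.null(species_map) && specimen %in% names(species_map)) {
        species_map[[specimen]]
      } else {
        specimen
      }
    }
    configs[[length(configs) + 1L]] <-
      landmark_config(coords, specimen_id = specimen, species_id = species)
  }
  if (!length(configs)) stop("no landmark records found in ", path)
  configs
}

read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("specimen", "species", "sex"), names(df))
  if (!all(c("specimen", "species") %in% meta_cols)) {
    stop("CSV must have 'specimen' and 'species' columns")
  }
  coord_cols <- setdiff(names(df), meta_cols)
  k3 <- length(coord_cols)
  if (k3 %% 3L != 0L) stop("coordinate columns not a multiple of 3 in ", path)
  lapply(seq_len(nrow(df)), function(r) {
    vals <- suppressWarnings(as.numeric(df[r, coord_cols]))
    if (anyNA(vals)) {
      bad <- coord_cols[which(is.na(vals))[1]]
      stop("missing or non-numeric coordinate in row ", r,
           " (specimen '", df$specimen[r], "', column '", bad, "')")
    }
    landmark_config(matrix(vals, ncol = 3L, byrow = TRUE),
                    specimen_id = df$specimen[r],
                    species_id = df$species[r],
                    sex = if ("sex" %in% meta_cols) df$sex[r] else "unknown")
  })
}

apply_subset_map <- function(config, subset_map) {
  k <- nrow(config$coords)
  idx <- subset_map$landmark_index + 1L  # files use 0-based indices
  if (any(idx < 1L | idx > k)) stop("subset map index out of range (0-based, K = ", k, ")")
  subsets <- config$subsets
  subsets[idx] <- as.character(subset_map$subset)
  config$subsets <- subsets
  if (!is.null(subset_map$role)) {
    roles <- config$roles
    roles[idx] <- as.character(subset_map$role)
    config$roles <- roles
  }
  landmark_config(config$coords, config$specimen_id, config$species_id,
                  sex = config$sex, roles = config$roles, subsets = config$subsets)
}

#' Write landmark configurations to TPS or wide CSV
#'
#' Inverse of [read_landmarks()]; TPS IDs are written as
#' `species__specimen` so species assignments round-trip.
#'
#' @inheritParams read_landmarks
#' @param configs list of [landmark_config] objects.
#' @export
write_landmarks <- function(configs, path, format = c("auto", "tps", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  }
  if (format == "tps") {
    out <- unlist(lapply(configs, function(cf) {
      id <- if (startsWith(cf$specimen_id, paste0(cf$species_id, "__"))) {
        cf$specimen_id
      } else {
        paste0(cf$species_id, "__", cf$specimen_id)
      }
      c(paste0("LM3=", nrow(cf$coords)),
        apply(cf$coords, 1, function(r) paste(format(r, digits = 17), collapse = " ")),
        paste0("ID=", id))
    }))
    writeLines(out, path)
  } else {
    k <- check_equal_k(configs)
    mat <- t(vapply(configs, function(cf) as.vector(t(cf$coords)), numeric(3L * k)))
    colnames(mat) <- paste0(rep(c("x", "y", "z"), k), rep(seq_len(k), each = 3L))
    df <- data.frame(specimen = vapply(configs, `[[`, "", "specimen_id"),
                     species = vapply(configs, `[[`, "", "species_id"),
                     sex = vapply(configs, `[[`, "", "sex"),
                     mat, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all landmarks to their
#' centroid; the size variable removed by Procrustes superimposition.
#'
#' @param config a [landmark_config] or a bare K x 3 coordinate matrix.
#' @return positive scalar (0, with a warning, for fully degenerate
#'   configurations in which all points coincide).
#' @export
centroid_size <- function(config) {
  x <- if (inherits(config, "landmark_config")) config$coords else as.matrix(config)
  if (nrow(x) < 1L) stop("configuration has no landmarks")
  centered <- sweep(x, 2L, colMeans(x))
  cs <- sqrt(sum(centered^2))
  if (cs == 0) warning("degenerate configuration: all landmarks coincide")
  cs
}

# det-corrected orthogonal rotation of x onto target (both centred);
# reflections are excluded so biological shapes cannot mirror.
rotate_onto <- function(x, target) {
  s <- svd(crossprod(target, x))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$v %*% diag(c(1, 1, d)[seq_along(s$d)]) %*% t(s$u)
  x %*% rot
}

center_scale <- function(x) {
  x <- sweep(x, 2L, colMeans(x))
  x / sqrt(sum(x^2))
}

#' Generalized Procrustes alignment
#'
#' Iteratively removes translation, scale, and rotation from a set of
#' landmark configurations: each configuration is centred, scaled to unit
#' centroid size, and rotated onto the running consensus by the
#' determinant-corrected orthogonal solution (no reflections); the consensus
#' is the coordinate-wise mean, itself re-centred and re-scaled each round.
#' Iteration stops when the consensus moves less than `tol` (root summed
#' squared change).
#'
#' With `slide_semilandmarks = TRUE`, curve and patch semilandmarks are slid
#' in their locally estimated tangent planes to minimize thin-plate-spline
#' bending energy against the consensus before each rotation round.
#'
#' @param configs list of [landmark_config] objects with identical K.
#' @param slide_semilandmarks logical; default `FALSE`.
#' @param tol convergence tolerance on consensus change.
#' @param max_iter iteration cap; exceeding it is an error that reports the
#'   last change norm.
#' @return An object of class `aligned_shapes`: list with `pcoords`
#'   (N x K x 3 array), `csize`, `ln_csize`, `mean_shape`, `specimen_ids`,
#'   `species_ids`, `roles`, `subsets`, `iterations`.
#' @export
gpa_align <- function(configs, slide_semilandmarks = FALSE,
                      tol = 1e-8, max_iter = 100L) {
  n <- length(configs)
  if (n < 2L) stop("need at least 2 configurations")
  k <- check_equal_k(configs)
  csize <- vapply(configs, centroid_size, numeric(1))
  arr <- array(NA_real_, c(n, k, 3L))
  for (i in seq_len(n)) arr[i, , ] <- center_scale(configs[[i]]$coords)

  roles <- configs[[1]]$roles
  sliders <- which(roles %in% c("curve_semilandmark", "patch_semilandmark"))
  consensus <- arr[1, , ]
  iter <- 0L
  change <- Inf
  repeat {
    iter <- iter + 1L
    if (slide_semilandmarks && length(sliders) && iter > 1L) {
      for (i in seq_len(n)) {
        arr[i, , ] <- center_scale(
          slide_to_consensus(arr[i, , ], consensus, sliders))
      }
    }
    for (i in seq_len(n)) arr[i, , ] <- rotate_onto(arr[i, , ], consensus)
    new_consensus <- center_scale(apply(arr, c(2L, 3L), mean))
    change <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (change < tol) break
    if (iter >= max_iter) {
      stop("GPA failed to converge in ", max_iter,
           " iterations (last consensus change ", format(change), ")")
    }
  }
  # the exported mean shape is the plain coordinate-wise mean of the aligned
  # configurations (the unit-size rescaling is internal to the iteration)
  consensus <- apply(arr, c(2L, 3L), mean)
  structure(
    list(pcoords = arr,
         csize = csize,
         ln_csize = log(csize),
         mean_shape = consensus,
         specimen_ids = vapply(configs, `[[`, "", "specimen_id"),
         species_ids = vapply(configs, `[[`, "", "species_id"),
         roles = roles,
         subsets = configs[[1]]$subsets,
         iterations = iter),
    class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat("Procrustes-aligned shapes:", dim(x$pcoords)[1], "specimens x",
      dim(x$pcoords)[2], "landmarks (3D)\n")
  cat("  species:", length(unique(x$species_ids)),
      "| GPA iterations:", x$iterations, "\n")
  invisible(x)
}

# Thin-plate-spline bending-energy matrix for a 3D reference configuration.
# 3D kernel U(r) = -r; returns the K x K upper-left block of L^{-1}.
bending_energy_matrix <- function(ref) {
  k <- nrow(ref)
  r <- as.matrix(stats::dist(ref))
  K <- -r
  P <- cbind(1, ref)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  Linv <- solve(L + diag(1e-12, k + 4L))
  Linv[seq_len(k), seq_len(k), drop = FALSE]
}

# Local tangent plane per sliding landmark, estimated from the plane of its
# nearest neighbours on the consensus (the two leading local PCs).
tangent_planes <- function(consensus, sliders, n_neighbors = 8L) {
  d <- as.matrix(stats::dist(consensus))
  lapply(sliders, function(j) {
    nb <- order(d[j, ])[seq_len(min(n_neighbors + 1L, nrow(consensus)))]
    local <- sweep(consensus[nb, , drop = FALSE], 2L,
                   colMeans(consensus[nb, , drop = FALSE]))
    sv <- svd(local)
    sv$v[, 1:2, drop = FALSE]
  })
}

# Slide semilandmarks of one configuration within their tangent planes to
# minimize TPS bending energy relative to the consensus.
slide_to_consensus <- function(x, consensus, sliders) {
  k <- nrow(consensus)
  Be <- bending_energy_matrix(consensus)
  E <- kronecker(diag(3L), Be)          # coords stacked axis-major: (x.., y.., z..)
  planes <- tangent_planes(consensus, sliders)
  q <- 2L * length(sliders)
  U <- matrix(0, 3L * k, q)
  for (s in seq_along(sliders)) {
    j <- sliders[s]
    for (axis in 1:3) {
      U[(axis - 1L) * k + j, 2L * s - 1L] <- planes[[s]][axis, 1L]
      U[(axis - 1L) * k + j, 2L * s] <- planes[[s]][axis, 2L]
    }
  }
  y <- as.vector(x - consensus)         # column-major (x.., y.., z..)
  UtE <- crossprod(U, E)
  t_hat <- tryCatch(
    solve(UtE %*% U + diag(1e-10, q), -UtE %*% y),
    error = function(e) rep(0, q))
  x + matrix(U %*% t_hat, k, 3L)
}

#' Extract (and optionally re-align) a landmark subset
#'
#' Carves out the facial or neurocranial patch of an aligned dataset. By
#' default the subset is re-superimposed on its own, so each patch defines
#' its own shape space; with `realign = FALSE` the coordinates are carried
#' over unchanged from the full-configuration alignment.
#'
#' @param aligned an `aligned_shapes` object.
#' @param subset `"total"`, `"facial"`, or `"neurocranial"`.
#' @param realign logical, default `TRUE`.
#' @return An `aligned_shapes` object over the subset's landmarks.
#' @export
subset_shapes <- function(aligned, subset = c("total", "facial", "neurocranial"),
                          realign = TRUE) {
  subset <- match.arg(subset)
  if (subset == "total") return(aligned)
  keep <- which(aligned$subsets == subset)
  if (!length(keep)) stop("no landmarks labelled '", subset, "'")
  n <- dim(aligned$pcoords)[1]
  configs <- lapply(seq_len(n), function(i) {
    landmark_config(aligned$pcoords[i, keep, , drop = FALSE][1, , ],
                    specimen_id = aligned$specimen_ids[i],
                    species_id = aligned$species_ids[i],
                    roles = aligned$roles[keep],
                    subsets = aligned$subsets[keep])
  })
  if (realign) {
    out <- gpa_align(configs)
    # patch centroid sizes are measured in the original units, not the
    # unit-size frame of the full alignment
    out
  } else {
    arr <- aligned$pcoords[, keep, , drop = FALSE]
    structure(
      list(pcoords = arr,
           csize = vapply(configs, centroid_size, numeric(1)),
           ln_csize = log(vapply(configs, centroid_size, numeric(1))),
           mean_shape = apply(arr, c(2L, 3L), mean),
           specimen_ids = aligned$specimen_ids,
           species_ids = aligned$species_ids,
           roles = aligned$roles[keep],
           subsets = aligned$subsets[keep],
           iterations = aligned$iterations),
      class = "aligned_shapes")
  }
}

#' Species mean shapes from aligned coordinates
#'
#' Coordinate-wise arithmetic mean of each species' Procrustes coordinates
#' (no re-superimposition of the means). When a tree is supplied the output
#' rows follow the tree's tip order.
#'
#' @param aligned an `aligned_shapes` object.
#' @param tree optional `phylo` tree whose tip order fixes the row order.
#' @return list with `means` (S x K x 3 array, species in dimnames),
#'   `ln_csize` (per-species mean log centroid size), `species`.
#' @export
species_mean_shapes <- function(aligned, tree = NULL) {
  species <- aligned$species_ids
  uniq <- unique(species)
  if (!is.null(tree)) {
    missing_sp <- setdiff(tree$tip.label, uniq)
    if (length(missing_sp)) {
      stop("tree tips absent from the data: ", paste(missing_sp, collapse = ", "))
    }
    dropped <- setdiff(uniq, tree$tip.label)
    if (length(dropped)) {
      warning("species not in tree dropped: ", paste(dropped, collapse = ", "))
    }
    uniq <- tree$tip.label
  }
  k <- dim(aligned$pcoords)[2]
  means <- array(NA_real_, c(length(uniq), k, 3L), dimnames = list(uniq, NULL, NULL))
  lncs <- numeric(length(uniq))
  for (s in seq_along(uniq)) {
    rows <- which(species == uniq[s])
    means[s, , ] <- apply(aligned$pcoords[rows, , , drop = FALSE], c(2L, 3L), mean)
    lncs[s] <- mean(aligned$ln_csize[rows])
  }
  names(lncs) <- uniq
  list(means = means, ln_csize = lncs, species = uniq)
}

#' Export aligned shapes as a wide CSV
#'
#' @param aligned an `aligned_shapes` object.
#' @param path output file.
#' @export
write_aligned <- function(aligned, path) {
  n <- dim(aligned$pcoords)[1]
  k <- dim(aligned$pcoords)[2]
  mat <- t(vapply(seq_len(n), function(i) as.vector(t(aligned$pcoords[i, , ])),
                  numeric(3L * k)))
  colnames(mat) <- paste0(rep(c("x", "y", "z"), k), rep(seq_len(k), each = 3L))
  df <- data.frame(specimen = aligned$specimen_ids, species = aligned$species_ids,
                   csize = aligned$csize, mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
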