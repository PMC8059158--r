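# Ordination of aligned shapes: PCA of Procrustes coordinates, axis
# bookkeeping, PC-selection rules, phylomorphospace projection.

# N x 3K matrix of vectorized configurations (x1 y1 z1 x2 ...)
flatten_shapes <- function(arr) {
  n <- dim(arr)[1]
  k <- dim(arr)[2]
  out <- t(vapply(seq_len(n), function(i) as.vector(t(arr[i, , ])), numeric(3L * k)))
  rownames(out) <- dimnames(arr)[[1]]
  out
}

#' Principal component analysis of aligned shapes
#'
#' Eigen-decomposition of the covariance of the vectorized Procrustes
#' coordinates about their mean, at either the specimen or the species-mean
#' level. Axes are ordered by decreasing eigenvalue; the sign of each axis is
#' fixed so its largest-magnitude loading is positive, making scores
#' reproducible across platforms. Null axes (eigenvalue below 1e-12 of the
#' total) are dropped, so the retained percentages sum to 100.
#'
#' @param aligned an `aligned_shapes` object.
#' @param level `"specimen"` or `"species_mean"`.
#' @return object of class `shape_space`: `scores` (N x m, rownames are
#'   specimen or species ids), `eigenvalues`, `pct_variance`, `loadings`
#'   (m x 3K), `reference_mean` (K x 3), `level`.
#' @export
pca <- function(aligned, level = c("specimen", "species_mean")) {
  level <- match.arg(level)
  if (level == "specimen") {
    X <- flatten_shapes(aligned$pcoords)
    rownames(X) <- aligned$specimen_ids
  } else {
    sm <- species_mean_shapes(aligned)
    X <- flatten_shapes(sm$means)
  }
  if (nrow(X) < 3L) stop("need at least 3 configurations for PCA")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  pc <- stats::prcomp(Xc, center = FALSE)
  ev <- pc$sdev^2
  keep <- which(ev > 1e-12 * sum(ev))
  ev <- ev[keep]
  rot <- pc$rotation[, keep, drop = FALSE]
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2L, flip, `*`)
  scores <- Xc %*% rot
  colnames(scores) <- paste0("PC", seq_along(ev))
  k <- dim(aligned$pcoords)[2]
  structure(
    list(scores = scores,
         eigenvalues = ev,
         pct_variance = 100 * ev / sum(ev),
         loadings = t(rot),
         reference_mean = matrix(ctr, k, 3L, byrow = TRUE),
         level = level),
    class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat("Shape space (", x$level, " level): ", nrow(x$scores), " points x ",
      length(x$eigenvalues), " axes\n", sep = "")
  cat("  PC1-PC3 variance: ",
      paste0(sprintf("%.1f%%", x$pct_variance[seq_len(min(3, length(x$pct_variance)))]),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select PC axes above a variance threshold
#'
#' Indices of axes explaining at least `threshold_pct` percent of the total
#' shape variance, in axis order. The analyses use 1 (candidate clustering,
#' CVA, convergence tests) and 5 (ecology screens) as the two conventional
#' thresholds; ties at the boundary are retained.
#'
#' @param space a `shape_space` object.
#' @param threshold_pct percentage in (0, 100).
#' @return integer vector of axis indices (possibly empty).
#' @export
select_pcs <- function(space, threshold_pct = 1) {
  stopifnot(threshold_pct > 0, threshold_pct < 100)
  which(space$pct_variance >= threshold_pct)
}

#' Phylomorphospace node coordinates
#'
#' Positions of a phylogeny's nodes in a PC plane: tips at their species-mean
#' scores, internal nodes at the ML Brownian-motion ancestral reconstruction
#' of those scores, plus the tree's edge list for plotting.
#'
#' @param space a species-mean level `shape_space` (score rownames must match
#'   tree tips).
#' @param tree rooted [ape::phylo].
#' @param axes which two axes to project (default 1:2).
#' @return list with `nodes` (data frame: node_id, label, two score columns)
#'   and `edges` (parent/child node ids).
#' @export
phylomorphospace_coords <- function(space, tree, axes = c(1L, 2L)) {
  scores <- space$scores
  absent <- setdiff(tree$tip.label, rownames(scores))
  if (length(absent)) {
    stop("no scores for tree tips: ", paste(absent, collapse = ", "))
  }
  axes <- axes[axes <= ncol(scores)]
  tipsc <- scores[tree$tip.label, axes, drop = FALSE]
  anc <- ancestral_states(tree, scores[tree$tip.label, , drop = FALSE])
  n <- length(tree$tip.label)
  nodes <- data.frame(
    node_id = c(seq_len(n), n + seq_len(tree$Nnode)),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)))
  coords <- rbind(tipsc, anc[, axes, drop = FALSE])
  colnames(coords) <- colnames(scores)[axes]
  nodes <- cbind(nodes, as.data.frame(coords, row.names = NULL))
  list(nodes = nodes,
       edges = data.frame(parent = tree$edge[, 1], child = tree$edge[, 2]))
}

#' Write a shape space (scores + variance table) to CSV files
#'
#' @param space a `shape_space`.
#' @param scores_path,variance_path output files (either may be `NULL`).
#' @export
write_shape_space <- function(space, scores_path = NULL, variance_path = NULL) {
  if (!is.null(scores_path)) {
    utils::write.csv(data.frame(id = rownames(space$scores), space$scores,
                                check.names = FALSE),
                     scores_path, row.names = FALSE)
  }
  if (!is.null(variance_path)) {
    utils::write.csv(data.frame(axis = seq_along(space$eigenvalues),
                                eigenvalue = space$eigenvalues,
                                pct_variance = space$pct_variance),
                     variance_path, row.names = FALSE)
  }
  invisible(space)
}
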