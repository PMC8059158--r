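# Tree I/O and Brownian-motion machinery: phylogenetic covariance, ML
# ancestral states, rate estimation from contrasts, and multivariate BM
# simulation. Trees are ape "phylo" objects throughout.

#' Read a rooted, branch-length tree from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] adding the structural checks the
#' downstream comparative machinery relies on: rootedness, complete branch
#' lengths, unique tip labels. Polytomies are permitted and retained.
#'
#' @param path Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    stop("missing branch length on the edge to node ", tree$edge[bad, 2])
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label: ", tree$tip.label[duplicated(tree$tip.label)][1])
  }
  # a basal polytomy (e.g. a star tree) is still rooted for BM purposes;
  # require only a single root node
  n <- length(tree$tip.label)
  parents <- unique(tree$edge[, 1])
  roots <- setdiff(parents, tree$edge[, 2])
  if (length(roots) != 1L) stop("tree must have a single root")
  invisible(tree)
}

# Zero-length branches break the GLS machinery; nudge them to a negligible
# fraction of tree depth (warned once per call).
regularize_tree <- function(tree) {
  if (any(tree$edge.length == 0)) {
    eps <- 1e-8 * max(ape::node.depth.edgelength(tree))
    if (eps == 0) eps <- 1e-8
    warning("zero-length branches replaced by ", format(eps))
    tree$edge.length[tree$edge.length == 0] <- eps
  }
  tree
}

#' Phylogenetic covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j (the
#' expected trait covariance under unit-rate Brownian motion); the diagonal
#' holds root-to-tip depths.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @return n x n matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_tree(tree)
  ape::vcv.phylo(tree)
}

# Shared path lengths between every pair of nodes (tips + internals),
# from pairwise patristic distances and node depths.
full_shared_paths <- function(tree) {
  d <- ape::dist.nodes(tree)
  depth <- ape::node.depth.edgelength(tree)
  (outer(depth, depth, "+") - d) / 2
}

# Linear map A (internal nodes x tips) such that A %*% X gives the ML (GLS)
# Brownian-motion ancestral states at every internal node. Precomputable per
# tree, so repeated reconstructions (e.g. inside simulation nulls) are a
# single matrix product.
anc_state_map <- function(tree) {
  tree <- regularize_tree(tree)
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  shared <- full_shared_paths(tree)
  Ctt <- shared[seq_len(n), seq_len(n), drop = FALSE]
  Cat <- shared[n + seq_len(nn), seq_len(n), drop = FALSE]
  Ctt_inv_1 <- solve(Ctt, rep(1, n))
  w_root <- Ctt_inv_1 / sum(Ctt_inv_1)        # GLS root weights
  M <- Cat %*% solve(Ctt)
  A <- M + (1 - rowSums(M)) %*% t(w_root)
  rownames(A) <- as.character(n + seq_len(nn))
  colnames(A) <- tree$tip.label
  A
}

#' Maximum-likelihood Brownian-motion ancestral states
#'
#' GLS reconstruction at every internal node, equivalent to the
#' branch-length-weighted squared-change-parsimony solution. Handles
#' polytomies natively; zero-length branches are epsilon-regularized with a
#' warning.
#'
#' @param tree rooted [ape::phylo].
#' @param tip_values n x p matrix, rows in tree tip order (or rownames
#'   matching tip labels, in which case rows are re-ordered).
#' @return matrix (internal nodes x p); rownames are ape node numbers, the
#'   root first.
#' @export
ancestral_states <- function(tree, tip_values) {
  tip_values <- align_tip_rows(tree, tip_values)
  A <- anc_state_map(tree)
  A %*% tip_values
}

align_tip_rows <- function(tree, tip_values) {
  tip_values <- as.matrix(tip_values)
  n <- length(tree$tip.label)
  if (nrow(tip_values) != n) {
    stop("tip_values has ", nrow(tip_values), " rows but the tree has ", n, " tips")
  }
  if (!is.null(rownames(tip_values))) {
    missing_sp <- setdiff(tree$tip.label, rownames(tip_values))
    if (length(missing_sp)) {
      stop("tip_values rows missing for: ", paste(missing_sp, collapse = ", "))
    }
    tip_values <- tip_values[tree$tip.label, , drop = FALSE]
  } else {
    rownames(tip_values) <- tree$tip.label
  }
  tip_values
}

#' Estimate a multivariate Brownian-motion model from tip data
#'
#' The per-unit-time trait covariance (rate matrix) is the average outer
#' product of the phylogenetically independent contrasts; the root state is
#' the GLS estimate. R may be rank-deficient when traits outnumber
#' contrasts; this is flagged, not an error.
#'
#' @param tree rooted [ape::phylo], n >= 3 tips.
#' @param tip_values n x p matrix in tip order.
#' @return object of class `bm_model`: list with `rate_matrix` (p x p),
#'   `root_state` (length p), `rank_deficient` flag.
#' @export
estimate_bm_rate <- function(tree, tip_values) {
  validate_tree(tree)
  tree <- regularize_tree(tree)
  tip_values <- align_tip_rows(tree, tip_values)
  n <- nrow(tip_values)
  if (n < 3L) stop("need at least 3 tips to estimate a rate")
  tree_di <- ape::multi2di(tree)  # pic requires binary; zero-length resolution
  tree_di$edge.length[tree_di$edge.length == 0] <-
    1e-8 * max(ape::node.depth.edgelength(tree_di))
  U <- apply(tip_values, 2L, function(x) {
    ape::pic(stats::setNames(x, rownames(tip_values)), tree_di)
  })
  U <- matrix(U, ncol = ncol(tip_values))
  R <- crossprod(U) / nrow(U)
  C <- phylo_covariance(tree)
  Cinv1 <- solve(C, rep(1, n))
  root <- drop(crossprod(tip_values, Cinv1) / sum(Cinv1))
  structure(
    list(rate_matrix = (R + t(R)) / 2,
         root_state = root,
         rank_deficient = qr(R)$rank < ncol(R)),
    class = "bm_model")
}

#' @export
print.bm_model <- function(x, ...) {
  cat("Brownian-motion model:", ncol(x$rate_matrix), "traits",
      if (x$rank_deficient) "(rank-deficient rate matrix)" else "", "\n")
  invisible(x)
}

# symmetric PSD square root; errors on clearly negative eigenvalues
psd_sqrt <- function(R, tol = 1e-10) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (any(e$values < -tol * max(abs(e$values), 1))) {
    stop("rate matrix is not positive semidefinite")
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate multivariate Brownian motion along a tree
#'
#' Independent Gaussian increments per branch with covariance
#' `branch length x R`, accumulated root-to-tip. Simulations consume the RNG
#' stream sequentially, so the first k draws of an `n_sims` run reproduce a
#' k-sim run under the same seed.
#'
#' @param tree rooted [ape::phylo].
#' @param model a `bm_model` (or list with `rate_matrix`, `root_state`).
#' @param n_sims number of replicate datasets.
#' @param seed optional integer seed (RNG untouched when `NULL`).
#' @param include_nodes if `TRUE` also return realized internal-node states.
#' @return `n_sims x n x p` array of tip values (tip labels on dim 2); with
#'   `include_nodes`, an attribute `node_states` (`n_sims x Nnode x p`).
#' @export
simulate_bm <- function(tree, model, n_sims = 1L, seed = NULL,
                        include_nodes = FALSE) {
  validate_tree(tree)
  R <- as.matrix(model$rate_matrix)
  p <- ncol(R)
  L <- psd_sqrt(R)
  root_state <- rep_len(model$root_state, p)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  tree_pre <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  edge <- tree_pre$edge
  elen <- tree_pre$edge.length
  root <- n + 1L
  out <- array(NA_real_, c(n_sims, n, p), dimnames = list(NULL, tree$tip.label, NULL))
  nodes <- if (include_nodes) {
    array(NA_real_, c(n_sims, tree$Nnode, p),
          dimnames = list(NULL, as.character(n + seq_len(tree$Nnode)), NULL))
  }
  states <- matrix(0, n + tree$Nnode, p)
  for (s in seq_len(n_sims)) {
    incr <- (matrix(stats::rnorm(nrow(edge) * p), nrow(edge), p) %*% L) * sqrt(elen)
    states[root, ] <- root_state
    for (e in seq_len(nrow(edge))) {
      states[edge[e, 2L], ] <- states[edge[e, 1L], ] + incr[e, ]
    }
    out[s, , ] <- states[seq_len(n), ]
    if (include_nodes) nodes[s, , ] <- states[n + seq_len(tree$Nnode), ]
  }
  if (include_nodes) attr(out, "node_states") <- nodes
  out
}

#' Simulate a pure-birth tree rescaled to unit depth
#'
#' @param n_species tip count.
#' @param seed optional seed.
#' @return ultrametric [ape::phylo] with tips `sp01, sp02, ...` and root
#'   depth 1.
#' @export
simulate_tree <- function(n_species, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}
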