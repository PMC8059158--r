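# Tests of phenotypic convergence: UPGMA candidate selection, distance-based
# C1-C4 metrics with a Brownian-motion simulation null, the phenotypic
# vector-angle (theta) test with a tip-state shuffling null, BH false
# discovery control, and the maximal-convergence decision rule.

#' UPGMA candidate selection for convergence testing
#'
#' Average-linkage hierarchical clustering of species on their mean PC
#' scores (Euclidean distances). The candidate set for a focal species is
#' its largest phenogram cluster that still excludes the majority of
#' species: following the focal species up the merge sequence, the cluster
#' after its last merge containing at most half of all species. A phenetic
#' "group of similar species" that has absorbed most of the tree no longer
#' screens anything, so the rule stops before that happens. A fixed cut
#' height can be supplied instead. Ties in the distance matrix are resolved
#' by [stats::hclust()]'s ordering (lowest index first).
#'
#' @param scores species x PC matrix (rownames are species), typically the
#'   axes retained above 1% variance.
#' @param focal focal species id.
#' @param cut_height optional fixed dendrogram cut height.
#' @return object of class `candidate_set`: `focal`, `candidates` (cluster
#'   members other than the focal), `members`, `linkage` (the `hclust`
#'   object), `height` of the defining merge.
#' @export
upgma_candidates <- function(scores, focal, cut_height = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 3L) stop("need at least 3 species")
  if (!focal %in% rownames(scores)) stop("focal species '", focal, "' not in scores")
  hc <- stats::hclust(stats::dist(scores), method = "average")
  labs <- rownames(scores)
  if (!is.null(cut_height)) {
    grp <- stats::cutree(hc, h = cut_height)
    members <- labs[grp == grp[match(focal, labs)]]
    height <- cut_height
  } else {
    # follow the focal leaf up the merge sequence
    focal_leaf <- match(focal, labs)
    cluster_of <- -focal_leaf          # hclust encodes leaves as negatives
    merges <- integer(0)
    for (m in seq_len(nrow(hc$merge))) {
      if (cluster_of %in% hc$merge[m, ]) {
        merges <- c(merges, m)
        cluster_of <- m
      }
    }
    sizes <- vapply(merges, function(m) length(cluster_leaves(hc$merge, m)),
                    integer(1))
    small_enough <- which(sizes <= max(2L, floor(nrow(scores) / 2)))
    target <- if (length(small_enough)) {
      merges[small_enough[length(small_enough)]]
    } else {
      merges[1L]
    }
    members <- labs[cluster_leaves(hc$merge, target)]
    height <- hc$height[target]
  }
  structure(
    list(focal = focal,
         candidates = setdiff(members, focal),
         members = members,
         linkage = hc,
         height = height),
    class = "candidate_set")
}

cluster_leaves <- function(merge, m) {
  row <- merge[m, ]
  unlist(lapply(row, function(x) if (x < 0) -x else cluster_leaves(merge, x)))
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("UPGMA candidate set for", x$focal, "(cluster height",
      format(x$height, digits = 4), "):\n ",
      paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}

#' Export a UPGMA dendrogram as Newick
#' @param cand a `candidate_set`.
#' @param path output file.
#' @export
write_dendrogram <- function(cand, path) {
  ape::write.tree(ape::as.phylo(cand$linkage), path)
  invisible(path)
}

# Per-pair geometry reused across simulation nulls: node paths from the MRCA
# to both tips, the tree-edge indices along those paths, and the edge indices
# of the clade descending from the MRCA.
pair_geometry <- function(tree, pair) {
  tips <- match(pair, tree$tip.label)
  if (anyNA(tips)) stop("species not in tree: ", pair[is.na(tips)][1])
  if (tips[1] == tips[2]) stop("a species cannot be tested against itself")
  mrca <- ape::getMRCA(tree, tips)
  path1 <- ape::nodepath(tree, mrca, tips[1])
  path2 <- ape::nodepath(tree, mrca, tips[2])
  n <- length(tree$tip.label)
  clade_nodes <- clade_descendants(tree, mrca)
  path_edge_idx <- function(path) {
    if (length(path) < 2L) return(integer(0))
    vapply(seq_len(length(path) - 1L), function(i) {
      which(tree$edge[, 1] == path[i] & tree$edge[, 2] == path[i + 1L])
    }, integer(1))
  }
  list(tips = tips, mrca = mrca, path1 = path1, path2 = path2,
       path_edges = c(path_edge_idx(path1), path_edge_idx(path2)),
       clade_edges = which(tree$edge[, 1] %in% c(mrca, clade_nodes)),
       n_tips = n)
}

clade_descendants <- function(tree, node) {
  out <- integer(0)
  frontier <- node
  while (length(frontier)) {
    kids <- tree$edge[tree$edge[, 1] %in% frontier, 2]
    out <- c(out, kids)
    frontier <- kids[kids > length(tree$tip.label)]
  }
  out
}

# Phenotypes of every node (tips then internals, ape numbering) and the
# per-edge phenotypic change magnitudes; computed once per dataset and
# shared by all pairs.
node_pheno_all <- function(tree, tip_mat, anc_mat) {
  ph <- rbind(unname(tip_mat), unname(anc_mat))
  list(ph = ph,
       edge_change = sqrt(rowSums(
         (ph[tree$edge[, 2L], , drop = FALSE] -
          ph[tree$edge[, 1L], , drop = FALSE])^2)))
}

c_metrics_eval <- function(geom, npa) {
  P1 <- npa$ph[geom$path1, , drop = FALSE]
  P2 <- npa$ph[geom$path2, , drop = FALSE]
  d_tip <- sqrt(sum((P1[nrow(P1), ] - P2[nrow(P2), ])^2))
  cross <- outer(rowSums(P1^2), rowSums(P2^2), "+") - 2 * tcrossprod(P1, P2)
  # the tip pair is itself enumerated, so D_max >= D_tip holds exactly;
  # guard against last-bit float noise between the two computations
  d_max <- max(sqrt(max(pmax(cross, 0))), d_tip)
  l_lineage <- sum(npa$edge_change[geom$path_edges])
  l_clade <- sum(npa$edge_change[geom$clade_edges])
  c1 <- if (d_max > 0) 1 - d_tip / d_max else 0
  c2 <- d_max - d_tip
  c(C1 = c1, C2 = c2,
    C3 = if (l_lineage > 0) c2 / l_lineage else 0,
    C4 = if (l_clade > 0) c2 / l_clade else 0,
    D_tip = d_tip, D_max = d_max,
    L_tot_lineage = l_lineage, L_tot_clade = l_clade)
}

#' Distance-based convergence metrics C1-C4
#'
#' Quantify how much of the maximal phenotypic distance ever separating two
#' lineages has been closed by the time of their tips. With D_tip the
#' Euclidean distance between the two tip phenotypes and D_max the maximum
#' distance over all node pairs (ancestors or tips) drawn one from each
#' lineage path MRCA -> tip: C1 = 1 - D_tip/D_max (0 = as different as the
#' lineages ever were, 1 = complete convergence), C2 = D_max - D_tip (raw
#' magnitude), C3 = C2 scaled by the total phenotypic change along both
#' lineage paths, and C4 = C2 scaled by the total change over every branch
#' of the clade descending from the MRCA. Ancestral phenotypes are ML
#' Brownian-motion reconstructions unless exact node states are injected.
#'
#' @param tree rooted [ape::phylo].
#' @param tip_values n x p species-mean trait matrix (e.g. selected PC
#'   scores), rownames matched to tips.
#' @param pair character vector of the two species.
#' @param node_states optional matrix of internal-node phenotypes (rownames
#'   are ape node numbers) bypassing reconstruction.
#' @return named vector: C1..C4, D_tip, D_max, L_tot_lineage, L_tot_clade.
#' @export
c_metrics <- function(tree, tip_values, pair, node_states = NULL) {
  validate_tree(tree)
  tip_mat <- align_tip_rows(tree, tip_values)
  geom <- pair_geometry(tree, pair)
  anc <- if (is.null(node_states)) {
    ancestral_states(tree, tip_mat)
  } else {
    ns <- as.matrix(node_states)
    if (!is.null(rownames(ns))) {
      ns[as.character(length(tree$tip.label) + seq_len(tree$Nnode)), ,
         drop = FALSE]
    } else ns
  }
  c_metrics_eval(geom, node_pheno_all(tree, tip_mat, anc))
}

#' Simulation significance of the C1-C4 metrics
#'
#' The null distribution of each metric comes from Brownian-motion evolution
#' on the same tree: the rate matrix and root state are estimated from the
#' observed data (independent contrasts / GLS), `n_sims` datasets are
#' simulated, and each metric is recomputed per simulation; p-values are the
#' +1-corrected fraction of simulations reaching at least the observed value.
#'
#' @inheritParams c_metrics
#' @param n_sims simulated datasets (>= 100).
#' @param seed optional integer seed.
#' @return object of class `c_signif`: `observed`, `p_values`, `n_sims`.
#' @export
c_significance <- function(tree, tip_values, pair, n_sims = 1000L, seed = NULL) {
  if (n_sims < 100L) stop("n_sims must be at least 100")
  validate_tree(tree)
  tip_mat <- align_tip_rows(tree, tip_values)
  model <- estimate_bm_rate(tree, tip_mat)
  if (all(model$rate_matrix == 0)) {
    stop("estimated rate matrix is all zero; data carry no variation")
  }
  geom <- pair_geometry(tree, pair)
  A <- anc_state_map(tree)
  obs <- c_metrics_eval(geom, node_pheno_all(tree, tip_mat, A %*% tip_mat))
  sims <- simulate_bm(tree, model, n_sims = n_sims, seed = seed)
  metrics <- c("C1", "C2", "C3", "C4")
  exceed <- stats::setNames(numeric(4), metrics)
  for (s in seq_len(n_sims)) {
    ts <- matrix(sims[s, , ], nrow = dim(sims)[2])
    val <- c_metrics_eval(geom, node_pheno_all(tree, ts, A %*% ts))
    exceed <- exceed + (val[metrics] >= obs[metrics])
  }
  structure(
    list(observed = obs, p_values = (exceed + 1) / (n_sims + 1),
         n_sims = n_sims),
    class = "c_signif")
}

#' @export
print.c_signif <- function(x, ...) {
  cat(sprintf("C1 = %.3f (p = %.4g), C2 = %.3g (p = %.4g)  [%d BM simulations]\n",
              x$observed["C1"], x$p_values["C1"],
              x$observed["C2"], x$p_values["C2"], x$n_sims))
  invisible(x)
}

# angle between two phenotypic vectors, in degrees
vector_angle <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    stop("zero-length phenotypic vector: a tip equals its reconstructed MRCA state")
  }
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

# anc rows are internal nodes in ape numbering order (root = n_tips + 1)
theta_for_tips <- function(mrca_mat, tips, tip_mat, anc, dnode, n_tips) {
  pairs <- utils::combn(tips, 2L)
  th <- tt <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    mrca <- mrca_mat[i1, i2]
    a <- anc[mrca - n_tips, ]
    th[j] <- vector_angle(tip_mat[i1, ] - a, tip_mat[i2, ] - a)
    tt[j] <- th[j] / dnode[i1, i2]
  }
  c(theta = mean(th), theta_time = mean(tt))
}

#' Phenotypic vector-angle test of convergence
#'
#' For each species in a putatively convergent group, the phenotypic vector
#' is its tip phenotype minus the ML-reconstructed phenotype of the pair's
#' most recent common ancestor; theta is the angle between the two vectors
#' (mean over pairs for groups larger than two), and theta_time divides it
#' by the patristic distance between the species through the MRCA. Angles
#' near 0 mean the lineages evolved toward similar phenotypes; ~90 degrees
#' means dissimilarity. The null shuffles the convergent "state" across the
#' tree's tips: each of `n_shuffles` draws picks a random tip set of the
#' same size and recomputes the mean angle; the one-sided p-value is the
#' +1-corrected fraction of shuffles with an angle at most the observed.
#'
#' @inheritParams c_metrics
#' @param group character vector (>= 2) of species carrying the state.
#' @param n_shuffles random reassignments of the state.
#' @param seed optional seed.
#' @return object of class `theta_result`: `theta` (degrees), `theta_time`
#'   (degrees per unit branch length), `p`, `n_shuffles`.
#' @export
theta_convergence <- function(tree, tip_values, group, n_shuffles = 1000L,
                              seed = NULL) {
  validate_tree(tree)
  tip_mat <- align_tip_rows(tree, tip_values)
  if (length(group) < 2L) stop("need at least 2 species in the state group")
  tips <- match(group, tree$tip.label)
  if (anyNA(tips)) stop("species not in tree: ", group[is.na(tips)][1])
  anc <- ancestral_states(tree, tip_mat)
  n <- length(tree$tip.label)
  dnode <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  mrca_mat <- unname(ape::mrca(tree))
  obs <- theta_for_tips(mrca_mat, tips, tip_mat, anc, dnode, n)
  if (!is.null(seed)) set.seed(seed)
  at_most <- 0L
  for (s in seq_len(n_shuffles)) {
    null <- theta_for_tips(mrca_mat, sample.int(n, length(tips)), tip_mat,
                           anc, dnode, n)
    if (null["theta"] <= obs["theta"]) at_most <- at_most + 1L
  }
  structure(
    list(theta = unname(obs["theta"]), theta_time = unname(obs["theta_time"]),
         p = (at_most + 1) / (n_shuffles + 1), n_shuffles = n_shuffles),
    class = "theta_result")
}

#' @export
print.theta_result <- function(x, ...) {
  cat(sprintf("theta = %.1f deg (%.2f deg per unit time), p = %.4g [%d shuffles]\n",
              x$theta, x$theta_time, x$p, x$n_shuffles))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery control
#'
#' Step-up adjustment of a family of p-values; a test is significant when
#' its adjusted p-value is at most `alpha`.
#'
#' @param p_values numeric vector in [0, 1].
#' @param alpha target false discovery rate (the analyses use 0.10).
#' @return list with `adjusted` and logical `significant`, in input order.
#' @export
bh_fdr <- function(p_values, alpha = 0.10) {
  if (!length(p_values)) {
    return(list(adjusted = numeric(0), significant = logical(0)))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, significant = !is.na(adjusted) & adjusted <= alpha)
}

#' Maximal-convergence decision rule
#'
#' Combines the two convergence tests across the three shape datasets.
#' Within each (dataset x method) family the p-values are BH-adjusted at
#' `alpha`; a species is maximally convergent when it is significant under
#' BOTH methods in the total-cranium dataset AND under both methods in at
#' least one patch dataset (facial or neurocranial). Candidates missing any
#' dataset are excluded with a warning.
#'
#' @param results data frame with columns `species`, `dataset` (one of
#'   `"total"`, `"facial"`, `"neurocranial"`), `p_C1`, `p_theta` (and,
#'   optionally, the statistics themselves, which are carried through).
#' @param alpha false discovery rate, default 0.10.
#' @return data frame of class `convergence_call`: one row per species with
#'   per-dataset significance flags, adjusted p-values, and
#'   `maximal_convergent`.
#' @export
maximal_convergence_call <- function(results, alpha = 0.10) {
  req <- c("species", "dataset", "p_C1", "p_theta")
  miss <- setdiff(req, names(results))
  if (length(miss)) stop("results missing columns: ", paste(miss, collapse = ", "))
  datasets <- c("total", "facial", "neurocranial")
  if (!nrow(results)) {
    empty <- data.frame(species = character(0), both_total = logical(0),
                        both_facial = logical(0), both_neurocranial = logical(0),
                        maximal_convergent = logical(0))
    class(empty) <- c("convergence_call", "data.frame")
    return(empty)
  }
  have <- table(results$species, factor(results$dataset, levels = datasets))
  complete <- rownames(have)[apply(have >= 1L, 1L, all)]
  dropped <- setdiff(unique(results$species), complete)
  if (length(dropped)) {
    warning("candidates missing a dataset, excluded: ",
            paste(dropped, collapse = ", "))
  }
  results <- results[results$species %in% complete, , drop = FALSE]
  results$sig_C1 <- NA
  results$adj_p_C1 <- NA_real_
  results$sig_theta <- NA
  results$adj_p_theta <- NA_real_
  for (ds in datasets) {
    idx <- which(results$dataset == ds)
    for (method in c("C1", "theta")) {
      fdr <- bh_fdr(results[[paste0("p_", method)]][idx], alpha)
      results[[paste0("adj_p_", method)]][idx] <- fdr$adjusted
      results[[paste0("sig_", method)]][idx] <- fdr$significant
    }
  }
  per_species <- lapply(complete, function(sp) {
    r <- results[results$species == sp, ]
    both <- vapply(datasets, function(ds) {
      rr <- r[r$dataset == ds, ][1L, ]
      isTRUE(rr$sig_C1) && isTRUE(rr$sig_theta)
    }, logical(1))
    data.frame(species = sp,
               both_total = both[["total"]],
               both_facial = both[["facial"]],
               both_neurocranial = both[["neurocranial"]],
               maximal_convergent = both[["total"]] &&
                 (both[["facial"]] || both[["neurocranial"]]))
  })
  call_tab <- do.call(rbind, per_species)
  attr(call_tab, "detail") <- results
  class(call_tab) <- c("convergence_call", "data.frame")
  call_tab
}

#' @export
print.convergence_call <- function(x, ...) {
  maximal <- x$species[x$maximal_convergent]
  cat("Maximal-convergence call over", nrow(x), "candidates\n")
  cat("  maximally convergent:",
      if (length(maximal)) paste(maximal, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
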