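# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Sum of squared distances to the centroid via the pairwise-distance
# identity, computed with an explicit double loop.
brute_centroid_size <- function(coords) {
  k <- nrow(coords)
  acc <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      acc <- acc + sum((coords[i, ] - coords[j, ])^2)
    }
  }
  sqrt(acc / (2 * k))
}

# Closed-form 2D ordinary Procrustes alignment of centred, unit-size
# configurations: optimal rotation angle and residual distance.
opa_2d <- function(a, b) {
  num <- sum(a[, 1] * b[, 2] - a[, 2] * b[, 1])
  den <- sum(a[, 1] * b[, 1] + a[, 2] * b[, 2])
  ang <- atan2(num, den)
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L)
  list(angle = ang, aligned = b %*% rot,
       distance = sqrt(sum((a - b %*% rot)^2)))
}

# Literal transcription of Blomberg's univariate K statistic.
blomberg_k <- function(tree, x) {
  x <- x[tree$tip.label]
  C <- ape::vcv.phylo(tree)
  Cinv <- solve(C)
  n <- length(x)
  one <- rep(1, n)
  a <- as.numeric((t(one) %*% Cinv %*% x) / (t(one) %*% Cinv %*% one))
  mse0 <- as.numeric(t(x - a) %*% (x - a)) / (n - 1)
  mse <- as.numeric(t(x - a) %*% Cinv %*% (x - a)) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  (mse0 / mse) / expected
}

# Brute-force C1-C4 by explicit enumeration, walking the edge matrix
# directly (no shared path machinery with the package).
brute_c_metrics <- function(tree, tip_values, pair, node_states) {
  n <- length(tree$tip.label)
  pheno <- function(node) {
    if (node <= n) tip_values[node, ] else node_states[as.character(node), ]
  }
  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  path_to_root <- function(node) {
    path <- node
    while (length(parent_of(node))) {
      node <- parent_of(node)
      path <- c(path, node)
    }
    path
  }
  t1 <- match(pair[1], tree$tip.label)
  t2 <- match(pair[2], tree$tip.label)
  p1 <- path_to_root(t1)
  p2 <- path_to_root(t2)
  mrca <- p1[p1 %in% p2][1]
  p1 <- p1[seq_len(which(p1 == mrca))]
  p2 <- p2[seq_len(which(p2 == mrca))]
  d_tip <- sqrt(sum((pheno(t1) - pheno(t2))^2))
  d_max <- 0
  for (u in p1) {
    for (v in p2) {
      d_max <- max(d_max, sqrt(sum((pheno(u) - pheno(v))^2)))
    }
  }
  lineage <- 0
  for (path in list(p1, p2)) {
    for (i in seq_len(length(path) - 1)) {
      lineage <- lineage + sqrt(sum((pheno(path[i]) - pheno(path[i + 1]))^2))
    }
  }
  in_clade <- function(node) mrca %in% path_to_root(node)
  clade <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child != mrca && in_clade(child)) {
      clade <- clade + sqrt(sum((pheno(child) - pheno(tree$edge[e, 1]))^2))
    }
  }
  c2 <- d_max - d_tip
  c(C1 = 1 - d_tip / d_max, C2 = c2, C3 = c2 / lineage, C4 = c2 / clade,
    D_tip = d_tip, D_max = d_max, L_tot_lineage = lineage, L_tot_clade = clade)
}

# Step-up BH by its definition.
bh_by_hand <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  passed <- which(p[ord] <= seq_len(m) / m * alpha)
  sig <- rep(FALSE, m)
  if (length(passed)) sig[ord[seq_len(max(passed))]] <- TRUE
  sig
}

# random tree + node states for enumeration checks
random_injected_case <- function(n_tips, p, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_tips)
  tree$tip.label <- sprintf("t%02d", seq_len(n_tips))
  tips <- matrix(rnorm(n_tips * p), n_tips, p,
                 dimnames = list(tree$tip.label, NULL))
  nodes <- matrix(rnorm(tree$Nnode * p), tree$Nnode, p,
                  dimnames = list(as.character(n_tips + seq_len(tree$Nnode)), NULL))
  list(tree = tree, tips = tips, nodes = nodes)
}
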