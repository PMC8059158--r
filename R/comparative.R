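# Phylogenetically informed inference on multivariate shape: Kmult
# phylogenetic signal and distance-based PGLS with residual-randomization
# permutation inference.

# inverse square root of a symmetric PD matrix
inv_sqrt_mat <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(e$values) < 1e-12 * max(e$values)) {
    stop("phylogenetic covariance is numerically singular; check branch lengths")
  }
  e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
}

gls_mean <- function(C, Y) {
  Cinv1 <- solve(C, rep(1, nrow(Y)))
  drop(crossprod(Y, Cinv1)) / sum(Cinv1)
}

#' Multivariate phylogenetic signal (Kmult)
#'
#' Ratio of the observed to the Brownian-motion-expected phylogenetic
#' structuring of multivariate data: the observed part is the summed squared
#' Euclidean distance of the tip data to the phylogenetically weighted mean
#' over the same quantity after whitening by the phylogenetic covariance;
#' the expectation is the analytic trace-based value for the tree. Reduces
#' exactly to Blomberg's K for a single trait; approximately 1 under
#' Brownian motion. Significance by permutation of the tip rows.
#'
#' @param tree rooted [ape::phylo].
#' @param tip_values n x p matrix (rownames matched to tips when present).
#' @param n_perm permutations for the p-value (0 skips the test).
#' @param seed optional integer seed.
#' @return object of class `physignal_result`: `K_mult`, `p`, `n_perm`.
#' @export
k_mult <- function(tree, tip_values, n_perm = 999L, seed = NULL) {
  validate_tree(tree)
  Y <- align_tip_rows(tree, tip_values)
  n <- nrow(Y)
  if (n < 4L) stop("need at least 4 tips")
  C <- phylo_covariance(tree)
  Cinv <- solve(C)
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  stat <- function(Y) {
    a <- gls_mean(C, Y)
    resid <- sweep(Y, 2L, a)
    num <- sum(resid^2)
    den <- sum(resid * (Cinv %*% resid))
    (num / den) / expected
  }
  K_obs <- stat(Y)
  p <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    K_null <- replicate(n_perm, stat(Y[sample.int(n), , drop = FALSE]))
    p <- (sum(K_null >= K_obs) + 1) / (n_perm + 1)
  }
  structure(list(K_mult = K_obs, p = p, n_perm = n_perm),
            class = "physignal_result")
}

#' @export
print.physignal_result <- function(x, ...) {
  cat(sprintf("Kmult = %.4f, p = %s (%d permutations)\n",
              x$K_mult, format.pval(x$p), x$n_perm))
  invisible(x)
}

#' Distance-based phylogenetic generalized least squares
#'
#' Fits a (possibly highly multivariate) response to a single predictor
#' under Brownian-motion residual covariance: both sides are whitened by the
#' inverse square root of the phylogenetic covariance and sums of squares
#' are decomposed in that space, giving R-squared and a pseudo-F that are
#' well defined even when traits far outnumber tips. Inference is by
#' residual randomization: reduced-model (intercept-only) residuals are
#' permuted in the whitened space and the pseudo-F recomputed; the effect
#' size Z is the standardized position of the observed F in that null.
#' With an identity covariance (star tree, unit depths) the fit reduces to
#' ordinary least squares.
#'
#' @param tree rooted [ape::phylo].
#' @param response n x p matrix (e.g. Procrustes coordinates or log centroid
#'   size), rownames matched to tips.
#' @param predictor named numeric vector or factor over the same species.
#' @param n_perm number of residual permutations.
#' @param seed optional seed.
#' @param exclude species to drop from both tree and data before fitting
#'   (e.g. a focal species of unknown ecology).
#' @return object of class `pgls_result`: `R2`, `F`, `Z`, `p`,
#'   `df` (model, residual), `n`.
#' @export
pgls_fit <- function(tree, response, predictor, n_perm = 999L, seed = NULL,
                     exclude = NULL) {
  validate_tree(tree)
  response <- as.matrix(response)
  if (is.null(rownames(response))) rownames(response) <- tree$tip.label
  if (!is.null(exclude)) {
    exclude <- intersect(exclude, tree$tip.label)
    if (length(exclude) >= length(tree$tip.label) - 2L) {
      stop("exclusion leaves too few species")
    }
    tree <- ape::drop.tip(tree, exclude)
  }
  keep <- tree$tip.label
  Y <- response[keep, , drop = FALSE]
  x <- predictor[keep]
  if (anyNA(x)) {
    stop("predictor undefined for: ",
         paste(keep[is.na(x)], collapse = ", "))
  }
  if (is.character(x)) x <- factor(x)
  if (is.factor(x)) {
    x <- droplevels(x)
    small <- table(x) < 2L
    if (any(small)) {
      stop("factor level with fewer than 2 species: ",
           paste(names(which(small)), collapse = ", "))
    }
  }
  n <- length(keep)
  X <- stats::model.matrix(~x, data = data.frame(x = x))
  C <- phylo_covariance(tree)
  P <- inv_sqrt_mat(C)
  Yw <- P %*% Y
  Xw <- P %*% X
  ones_w <- P %*% rep(1, n)

  qr_red <- qr(ones_w)
  qr_full <- qr(Xw)
  fit_red <- qr.fitted(qr_red, Yw)
  e_red <- Yw - fit_red
  ss_total <- sum(e_red^2)
  df_model <- ncol(X) - 1L
  df_resid <- n - ncol(X)
  f_stat <- function(Yw_perm) {
    ss_resid <- sum(qr.resid(qr_full, Yw_perm)^2)
    ss_model <- sum(qr.resid(qr_red, Yw_perm)^2) - ss_resid
    (ss_model / df_model) / (ss_resid / df_resid)
  }
  ss_resid_obs <- sum(qr.resid(qr_full, Yw)^2)
  R2 <- (ss_total - ss_resid_obs) / ss_total
  F_obs <- f_stat(Yw)
  p <- NA_real_
  Z <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    F_null <- replicate(n_perm, {
      f_stat(fit_red + e_red[sample.int(n), , drop = FALSE])
    })
    p <- (sum(F_null >= F_obs) + 1) / (n_perm + 1)
    Z <- (F_obs - mean(F_null)) / stats::sd(F_null)
  }
  structure(
    list(R2 = R2, F = F_obs, Z = Z, p = p,
         df = c(model = df_model, residual = df_resid), n = n),
    class = "pgls_result")
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf("PGLS (n = %d): R2 = %.3f, F(%d,%d) = %.3f, Z = %.3f, p = %s\n",
              x$n, x$R2, x$df[1], x$df[2], x$F, x$Z, format.pval(x$p)))
  invisible(x)
}
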