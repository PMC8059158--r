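# Ecology table construction (prey/predator mass ratios, diet categories),
# canonical-variates discrimination of relative prey size with leave-one-out
# validation, and per-PC nonparametric ecology screens.

#' Relative prey-size class boundary
#'
#' Prey averaging more than this fraction of predator body mass (per hunter,
#' after pack-size division) defines the large-prey class; the value comes
#' from the energetic-constraint model of prey-size choice in carnivores.
#' It is the single source of the threshold everywhere in the package.
#' @export
PREY_RATIO_CUT <- 0.45

# diet fraction column -> fine-category stem
DIET_STEMS <- c(vertebrates = "carnivore", invertebrates = "insectivore",
                fruit = "frugivore", plants = "herbivore", other = "generalist")

#' Build the species ecology table
#'
#' From raw masses, pack sizes and diet-composition fractions, derives the
#' per-capita prey/predator mass ratio (mean prey mass divided by pack size,
#' over predator mass), its natural log, the small/large prey-size class at
#' the 45% boundary, and fine- and coarse-grained diet categories. The fine
#' label is the main (> 50% biomass) food source, hyphenated with a
#' secondary source contributing 20-50%; the coarse label is carnivorous
#' (>= 50% vertebrates), insectivorous (>= 50% invertebrates), or generalist.
#'
#' @param raw data frame with columns `species`, `body_mass` (kg),
#'   `prey_mass` (kg), `pack_size` (>= 1; 1 for solitary hunters), and any of
#'   the diet-fraction columns `vertebrates`, `invertebrates`, `fruit`,
#'   `plants`, `other` (each in 0..1).
#' @param prey_ratio_cut class boundary, default [PREY_RATIO_CUT].
#' @return data frame of class `ecology_table` with columns `species`,
#'   `body_mass`, `prey_mass`, `pack_size`, `prey_ratio`, `ln_prey_ratio`,
#'   `size_class`, `diet_fine`, `diet_coarse`, `diet_missing`.
#' @export
build_ecology <- function(raw, prey_ratio_cut = PREY_RATIO_CUT) {
  req <- c("species", "body_mass", "prey_mass", "pack_size")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("ecology table missing columns: ", paste(miss, collapse = ", "))
  if (any(raw$body_mass <= 0, na.rm = TRUE) || any(raw$prey_mass <= 0, na.rm = TRUE)) {
    stop("body and prey masses must be positive")
  }
  if (any(raw$pack_size < 1, na.rm = TRUE)) stop("pack_size must be >= 1")
  frac_cols <- intersect(names(DIET_STEMS), names(raw))
  fr <- as.matrix(raw[, frac_cols, drop = FALSE])
  if (length(fr) && any(fr < 0 | fr > 1, na.rm = TRUE)) {
    stop("diet fractions must lie in [0, 1]")
  }
  ratio <- (raw$prey_mass / raw$pack_size) / raw$body_mass
  out <- data.frame(
    species = as.character(raw$species),
    body_mass = raw$body_mass,
    prey_mass = raw$prey_mass,
    pack_size = raw$pack_size,
    prey_ratio = ratio,
    ln_prey_ratio = log(ratio),
    size_class = ifelse(ratio > prey_ratio_cut, "large", "small"),
    stringsAsFactors = FALSE)
  fine <- coarse <- rep(NA_character_, nrow(raw))
  missing_diet <- rep(TRUE, nrow(raw))
  if (length(frac_cols)) {
    for (i in seq_len(nrow(raw))) {
      f <- fr[i, ]
      if (anyNA(f)) next
      missing_diet[i] <- FALSE
      ord <- order(f, decreasing = TRUE)
      stems <- DIET_STEMS[frac_cols]
      if (f[ord[1]] > 0.5) {
        fine[i] <- stems[ord[1]]
        if (length(f) > 1L && f[ord[2]] >= 0.2 && f[ord[2]] < 0.5) {
          fine[i] <- paste0(stems[ord[1]], "/", stems[ord[2]])
        }
      } else {
        fine[i] <- "generalist"
      }
      v <- if ("vertebrates" %in% frac_cols) f[["vertebrates"]] else 0
      iv <- if ("invertebrates" %in% frac_cols) f[["invertebrates"]] else 0
      coarse[i] <- if (v >= 0.5) "carnivorous"
                   else if (iv >= 0.5) "insectivorous"
                   else "generalist"
    }
  }
  out$diet_fine <- fine
  out$diet_coarse <- coarse
  out$diet_missing <- missing_diet
  class(out) <- c("ecology_table", "data.frame")
  out
}

# pooled within-group covariance and group means of a 2+-group sample
pooled_within <- function(X, g) {
  g <- factor(g)
  means <- do.call(rbind, lapply(levels(g), function(l) colMeans(X[g == l, , drop = FALSE])))
  rownames(means) <- levels(g)
  W <- matrix(0, ncol(X), ncol(X))
  for (l in levels(g)) {
    Xl <- X[g == l, , drop = FALSE]
    W <- W + crossprod(sweep(Xl, 2L, colMeans(Xl)))
  }
  list(W = W / (nrow(X) - nlevels(g)), means = means)
}

classify_mahalanobis <- function(X, means, Winv) {
  d2 <- vapply(seq_len(nrow(means)), function(gi) {
    d <- sweep(X, 2L, means[gi, ])
    rowSums((d %*% Winv) * d)
  }, numeric(nrow(X)))
  d2 <- matrix(d2, nrow = nrow(X))
  lik <- exp(-(d2 - apply(d2, 1L, min)) / 2)   # equal priors
  post <- lik / rowSums(lik)
  colnames(post) <- rownames(means)
  list(assigned = rownames(means)[apply(d2, 1L, which.min)], posterior = post)
}

#' Canonical-variates discrimination of prey-size classes
#'
#' Two-group canonical variates (linear discriminant) analysis on selected
#' PC scores: the canonical axis is the leading eigenvector of the
#' within-group-inverse times between-group scatter; specimens are assigned
#' by Mahalanobis distance to the group means with equal priors, with
#' posteriors from normalized Gaussian likelihoods. Known specimens are
#' cross-validated by leave-one-out jackknife (full refit per held-out
#' specimen); unknowns are scored against the fit to all knowns.
#'
#' @param scores specimen x PC matrix (rownames are specimen ids), already
#'   restricted to the selected axes.
#' @param classes named character/factor of known classes; specimens absent
#'   from `names(classes)` (or listed in `unknown`) are treated as unknowns.
#' @param unknown character vector of specimen ids to assign, never train on.
#' @param strata optional named vector (e.g. infraclass per specimen) for
#'   stratified percent-correct reporting.
#' @return object of class `cva_result`.
#' @export
cva_discriminate <- function(scores, classes, unknown = NULL, strata = NULL) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores))) stop("scores must have specimen rownames")
  known_ids <- setdiff(intersect(rownames(scores), names(classes)), unknown)
  g <- factor(as.character(classes[known_ids]))
  if (nlevels(g) != 2L) stop("exactly two classes required, got ", nlevels(g))
  if (any(table(g) < 2L)) stop("each class needs at least 2 known specimens")
  X <- scores[known_ids, , drop = FALSE]

  fit_cva <- function(X, g) {
    pw <- pooled_within(X, g)
    Winv <- tryCatch(solve(pw$W), error = function(e) {
      stop("singular within-group scatter; use fewer PC axes", call. = FALSE)
    })
    axis <- drop(Winv %*% (pw$means[1L, ] - pw$means[2L, ]))
    axis <- axis / sqrt(sum(axis^2))
    list(means = pw$means, Winv = Winv, axis = axis)
  }
  fit <- fit_cva(X, g)
  cls <- classify_mahalanobis(X, fit$means, fit$Winv)

  jack <- character(length(known_ids))
  for (i in seq_along(known_ids)) {
    gi <- droplevels(g[-i])
    if (nlevels(gi) < 2L) stop("jackknife removed the last member of a class")
    f <- fit_cva(X[-i, , drop = FALSE], gi)
    jack[i] <- classify_mahalanobis(X[i, , drop = FALSE], f$means, f$Winv)$assigned
  }
  confusion <- table(truth = g, assigned = factor(jack, levels = levels(g)))
  pct_correct <- 100 * sum(diag(confusion)) / sum(confusion)
  pct_by_stratum <- NULL
  if (!is.null(strata)) {
    st <- as.character(strata[known_ids])
    pct_by_stratum <- vapply(split(seq_along(known_ids), st), function(idx) {
      100 * mean(jack[idx] == as.character(g)[idx])
    }, numeric(1))
  }
  unknown_tab <- NULL
  unknown <- intersect(unknown, rownames(scores))
  if (length(unknown)) {
    u <- classify_mahalanobis(scores[unknown, , drop = FALSE], fit$means, fit$Winv)
    unknown_tab <- data.frame(specimen = unknown, assigned = u$assigned,
                              posterior = apply(u$posterior, 1L, max),
                              u$posterior, check.names = FALSE)
  }
  structure(
    list(canonical_axis = fit$axis,
         group_means = fit$means,
         cv_scores = drop(scores %*% fit$axis),
         assignments = data.frame(specimen = known_ids,
                                  truth = as.character(g),
                                  assigned = cls$assigned,
                                  jackknife = jack,
                                  posterior = apply(cls$posterior, 1L, max)),
         confusion = confusion,
         pct_correct = pct_correct,
         pct_correct_resubstitution =
           100 * mean(cls$assigned == as.character(g)),
         pct_by_stratum = pct_by_stratum,
         unknown_assignments = unknown_tab),
    class = "cva_result")
}

#' @export
print.cva_result <- function(x, ...) {
  cat(sprintf("CVA: %d known specimens, jackknife %% correct = %.1f\n",
              nrow(x$assignments), x$pct_correct))
  if (!is.null(x$unknown_assignments)) {
    for (i in seq_len(nrow(x$unknown_assignments))) {
      cat(sprintf("  unknown %s -> %s (post. prob. %.3f)\n",
                  x$unknown_assignments$specimen[i],
                  x$unknown_assignments$assigned[i],
                  x$unknown_assignments$posterior[i]))
    }
  }
  invisible(x)
}

#' Per-PC nonparametric ecology screens
#'
#' For each supplied PC axis: a Wilcoxon rank-sum test of scores between the
#' small- and large-prey classes (exact for small samples, normal
#' approximation with tie correction otherwise) and a Spearman rank
#' correlation of scores against the log prey/predator mass ratio. Species
#' subsets (e.g. placental-only) are screened by passing a filter.
#'
#' @param scores species x PC matrix (rownames are species).
#' @param ln_ratio named numeric, log prey/predator ratio per species.
#' @param classes named character, `"small"`/`"large"` per species.
#' @param species optional subset of species to screen.
#' @return data frame: `pc`, `wilcoxon_p`, `spearman_rho`, `spearman_p`,
#'   `note` (flags constant axes).
#' @export
pc_ecology_screen <- function(scores, ln_ratio, classes, species = NULL) {
  scores <- as.matrix(scores)
  ids <- rownames(scores)
  if (!is.null(species)) ids <- intersect(ids, species)
  ids <- intersect(ids, intersect(names(ln_ratio), names(classes)))
  X <- scores[ids, , drop = FALSE]
  r <- ln_ratio[ids]
  cl <- factor(as.character(classes[ids]))
  if (nlevels(cl) == 2L && any(table(cl) < 4L)) {
    warning("fewer than 4 species in a size class; rank-sum p-values unstable")
  }
  n <- length(ids)
  out <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (stats::sd(x) == 0) {
      return(data.frame(pc = j, wilcoxon_p = NA_real_, spearman_rho = NA_real_,
                        spearman_p = NA_real_, note = "constant axis"))
    }
    wp <- if (nlevels(cl) == 2L) {
      stats::wilcox.test(x ~ cl, exact = n <= 20)$p.value
    } else NA_real_
    ct <- suppressWarnings(
      stats::cor.test(x, r, method = "spearman", exact = FALSE))
    data.frame(pc = j, wilcoxon_p = wp, spearman_rho = unname(ct$estimate),
               spearman_p = ct$p.value, note = "")
  })
  do.call(rbind, out)
}
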