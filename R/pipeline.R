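# Config-driven orchestration of the full analysis: GPA -> subsets -> PCA ->
# signal/PGLS -> CVA -> ecology screens -> UPGMA candidates -> convergence
# tests -> BH -> maximal-convergence call, with deterministic seeding and
# table-shaped CSV outputs.

#' Assemble a pipeline configuration
#'
#' Every printed constant of the analysis is a named option with its
#' conventional value as default: PC retention above 1% of shape variance
#' (5% for the ecology screens), the 45% prey/predator mass-ratio class
#' boundary, FDR alpha 0.10, and 1000 permutations / simulations / shuffles.
#'
#' @param landmarks,tree,ecology,subset_map input file paths (a pre-built
#'   `synthetic_study` may be passed to [run_pipeline()] instead).
#' @param focal_species the focal "unknown" species.
#' @param pc_variance_pct,pc_screen_pct,prey_ratio_cut,alpha thresholds.
#' @param n_perm,n_sims,n_shuffles resampling counts.
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @param output_dir where the report bundle is written (`NULL` = nowhere).
#' @param slide_semilandmarks forwarded to [gpa_align()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(landmarks = NULL, tree = NULL, ecology = NULL,
                            subset_map = NULL, focal_species,
                            pc_variance_pct = 1.0, pc_screen_pct = 5.0,
                            prey_ratio_cut = PREY_RATIO_CUT, alpha = 0.10,
                            n_perm = 1000L, n_sims = 1000L, n_shuffles = 1000L,
                            seed = 1L, output_dir = NULL,
                            slide_semilandmarks = FALSE) {
  stopifnot(pc_variance_pct > 0, pc_variance_pct < 100,
            prey_ratio_cut > 0, prey_ratio_cut < 1,
            alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative input paths
#' are resolved against the file's directory.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("landmarks", "tree", "ecology", "subset_map")) {
    if (!is.null(y[[key]]) && !grepl("^/", y[[key]])) {
      y[[key]] <- file.path(base, y[[key]])
    }
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

derive_seeds <- function(seed) {
  base <- as.integer(seed) %% 1000000L
  list(kmult = base * 13L + 1L, pgls = base * 13L + 2L,
       csig = base * 13L + 3L, theta = base * 13L + 4L)
}

#' Run the full shape-ecology-convergence pipeline
#'
#' Executes, in order: landmark reading, Procrustes alignment, subset
#' extraction (total / facial / neurocranial, each re-superimposed), PCA at
#' specimen and species-mean level, phylogenetic signal and PGLS models,
#' prey-size CVA with the focal species held out as the unknown, per-PC
#' ecology screens, UPGMA candidate selection on the total dataset,
#' pairwise C1-C4 and theta convergence tests of every candidate against
#' the focal species in all three datasets, BH adjustment, and the
#' maximal-convergence decision rule. Re-running with the same inputs and
#' seed reproduces the bundle bit for bit.
#'
#' @param config a `pipeline_config`.
#' @param study optional in-memory `synthetic_study` used instead of the
#'   config's input paths.
#' @return list of class `pipeline_report`: `signal` (per-dataset Kmult +
#'   PGLS table), `cva` (per-dataset percent-correct and focal assignment),
#'   `screens`, `candidates`, `convergence` (per pair per dataset),
#'   `call` (the maximal-convergence table), `spaces`, `config`.
#' @export
run_pipeline <- function(config, study = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed)

  if (is.null(study)) {
    configs <- stage("read_landmarks", {
      sm <- utils::read.csv(config$subset_map)
      read_landmarks(config$landmarks, subset_map = sm)
    })
    tree <- stage("read_tree", read_newick(config$tree))
    ecology <- stage("read_ecology",
                     build_ecology(utils::read.csv(config$ecology),
                                   prey_ratio_cut = config$prey_ratio_cut))
  } else {
    configs <- study$configs
    tree <- study$tree
    ecology <- stage("read_ecology",
                     build_ecology(study$raw_ecology,
                                   prey_ratio_cut = config$prey_ratio_cut))
  }
  focal <- config$focal_species
  species_in_data <- unique(vapply(configs, `[[`, "", "species_id"))
  if (!focal %in% species_in_data) {
    stop("focal species '", focal, "' absent from the landmark data")
  }
  unknown_eco <- setdiff(species_in_data, c(ecology$species, focal))
  if (length(unknown_eco)) {
    stop("species missing from the ecology table: ",
         paste(unknown_eco, collapse = ", "))
  }
  tree <- stage("prune_tree", {
    extra <- setdiff(tree$tip.label, species_in_data)
    if (length(extra)) tree <- ape::drop.tip(tree, extra)
    validate_tree(tree)
    tree
  })

  aligned <- stage("gpa", gpa_align(configs,
                                    slide_semilandmarks = config$slide_semilandmarks))
  datasets <- stage("subsets", list(
    total = aligned,
    facial = subset_shapes(aligned, "facial"),
    neurocranial = subset_shapes(aligned, "neurocranial")))

  spaces <- stage("pca", lapply(datasets, function(d) {
    list(specimen = pca(d, "specimen"), species = pca(d, "species_mean"))
  }))

  eco_ratio <- stats::setNames(ecology$ln_prey_ratio, ecology$species)
  eco_class <- stats::setNames(ecology$size_class, ecology$species)
  eco_coarse <- stats::setNames(ecology$diet_coarse, ecology$species)

  signal <- stage("signal_pgls", {
    rows <- list()
    for (ds in names(datasets)) {
      sm <- species_mean_shapes(datasets[[ds]], tree = tree)
      Y <- flatten_shapes(sm$means)
      lncs <- sm$ln_csize
      ks <- k_mult(tree, Y, n_perm = config$n_perm, seed = seeds$kmult)
      fits <- list(
        `Pcoords ~ ln(Csize)` = list(resp = Y, pred = lncs, excl = NULL),
        `Pcoords ~ prey/predator mass ratio` =
          list(resp = Y, pred = eco_ratio, excl = focal),
        `Pcoords ~ dietary category (coarse)` =
          list(resp = Y, pred = eco_coarse, excl = focal),
        `ln(Csize) ~ prey/predator mass ratio` =
          list(resp = cbind(lncs), pred = eco_ratio, excl = focal),
        `ln(Csize) ~ dietary category (coarse)` =
          list(resp = cbind(lncs), pred = eco_coarse, excl = focal))
      for (fn in names(fits)) {
        f <- fits[[fn]]
        fit <- tryCatch(
          pgls_fit(tree, f$resp, f$pred, n_perm = config$n_perm,
                   seed = seeds$pgls, exclude = f$excl),
          error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = ds, test = fn,
          K_mult = NA_real_,
          df = if (is.null(fit)) NA_character_ else
            paste(fit$df, collapse = ","),
          R2 = if (is.null(fit)) NA_real_ else fit$R2,
          F = if (is.null(fit)) NA_real_ else fit$F,
          Z = if (is.null(fit)) NA_real_ else fit$Z,
          p = if (is.null(fit)) NA_real_ else fit$p,
          note = if (is.null(fit)) "not estimable" else "")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds, test = "Kmult", K_mult = ks$K_mult, df = NA_character_,
        R2 = NA_real_, F = NA_real_, Z = NA_real_, p = ks$p, note = "")
    }
    tab <- do.call(rbind, rows)
    fdr <- bh_fdr(tab$p, config$alpha)
    tab$adj_p <- fdr$adjusted
    tab$significant <- fdr$significant
    tab
  })

  cva <- stage("cva", {
    spec_species <- stats::setNames(aligned$species_ids, aligned$specimen_ids)
    out <- list()
    for (ds in names(datasets)) {
      sp <- spaces[[ds]]$specimen
      sel <- select_pcs(sp, config$pc_variance_pct)
      scores <- sp$scores[, sel, drop = FALSE]
      cls <- eco_class[spec_species[rownames(scores)]]
      names(cls) <- rownames(scores)
      unknown <- rownames(scores)[spec_species[rownames(scores)] == focal]
      cls <- cls[!names(cls) %in% unknown & !is.na(cls)]
      out[[ds]] <- cva_discriminate(scores, cls, unknown = unknown)
    }
    out
  })

  screens <- stage("screens", {
    out <- list()
    for (ds in names(datasets)) {
      sp <- spaces[[ds]]$species
      sel <- select_pcs(sp, config$pc_screen_pct)
      scr <- pc_ecology_screen(
        sp$scores[, sel, drop = FALSE], eco_ratio, eco_class,
        species = setdiff(rownames(sp$scores), focal))
      scr$pc <- sel[scr$pc]
      scr$dataset <- ds
      out[[ds]] <- scr
    }
    do.call(rbind, out)
  })

  candidates <- stage("upgma", {
    sp <- spaces$total$species
    sel <- select_pcs(sp, config$pc_variance_pct)
    upgma_candidates(sp$scores[, sel, drop = FALSE], focal)
  })

  convergence <- stage("convergence", {
    tabs <- lapply(names(datasets), function(ds) {
      sp <- spaces[[ds]]$species
      sel <- select_pcs(sp, config$pc_variance_pct)
      tab <- convergence_screen(
        tree, sp$scores[, sel, drop = FALSE], focal, candidates$candidates,
        n_sims = config$n_sims, n_shuffles = config$n_shuffles,
        seed_sims = seeds$csig, seed_shuffles = seeds$theta)
      tab$dataset <- ds
      tab
    })
    do.call(rbind, tabs)
  })

  call_tab <- stage("maximal_call",
                    maximal_convergence_call(convergence, alpha = config$alpha))

  report <- structure(
    list(signal = signal, cva = cva, screens = screens,
         candidates = candidates, convergence = convergence,
         call = call_tab, spaces = spaces, tree = tree, ecology = ecology,
         config = config),
    class = "pipeline_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Pairwise convergence tests of candidates against a focal species
#'
#' Runs the C1-C4 simulation test and the theta shuffling test for every
#' (focal, candidate) pair on one trait dataset. One Brownian-motion null
#' (rate estimated from the supplied scores) and one set of random tip-pair
#' draws are shared across the pairs of the dataset; this is statistically
#' identical to simulating per pair and keeps large candidate sets cheap.
#'
#' @param tree rooted [ape::phylo] over the score rows.
#' @param scores species x trait matrix (selected PC axes).
#' @param focal focal species.
#' @param candidates character vector of candidate species.
#' @param n_sims,n_shuffles null sizes.
#' @param seed_sims,seed_shuffles integer seeds for the two nulls.
#' @return data frame: species, C1..C4, p_C1..p_C4, theta, theta_time,
#'   p_theta.
#' @export
convergence_screen <- function(tree, scores, focal, candidates,
                               n_sims = 1000L, n_shuffles = 1000L,
                               seed_sims = NULL, seed_shuffles = NULL) {
  if (!length(candidates)) {
    return(data.frame(species = character(0), C1 = numeric(0), C2 = numeric(0),
                      C3 = numeric(0), C4 = numeric(0), D_tip = numeric(0),
                      D_max = numeric(0), L_tot_lineage = numeric(0),
                      L_tot_clade = numeric(0), p_C1 = numeric(0),
                      p_C2 = numeric(0), p_C3 = numeric(0), p_C4 = numeric(0),
                      theta = numeric(0), theta_time = numeric(0),
                      p_theta = numeric(0)))
  }
  scores <- align_tip_rows(tree, scores)
  model <- estimate_bm_rate(tree, scores)
  A <- anc_state_map(tree)
  anc_obs <- A %*% scores
  n <- length(tree$tip.label)
  geoms <- lapply(candidates, function(sp) pair_geometry(tree, c(focal, sp)))
  metrics <- c("C1", "C2", "C3", "C4")
  npa_obs <- node_pheno_all(tree, scores, anc_obs)
  obs <- t(vapply(geoms, function(g) c_metrics_eval(g, npa_obs), numeric(8L)))
  exceed <- matrix(0, length(candidates), 4L,
                   dimnames = list(candidates, metrics))
  sims <- simulate_bm(tree, model, n_sims = n_sims, seed = seed_sims)
  for (s in seq_len(n_sims)) {
    ts <- matrix(sims[s, , ], nrow = n)
    npa_s <- node_pheno_all(tree, ts, A %*% ts)
    for (g in seq_along(geoms)) {
      val <- c_metrics_eval(geoms[[g]], npa_s)
      exceed[g, ] <- exceed[g, ] + (val[metrics] >= obs[g, metrics])
    }
  }
  p_c <- (exceed + 1) / (n_sims + 1)

  dnode <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  mrca_mat <- unname(ape::mrca(tree))
  th_obs <- t(vapply(candidates, function(sp) {
    theta_for_tips(mrca_mat, match(c(focal, sp), tree$tip.label),
                   scores, anc_obs, dnode, n)
  }, numeric(2L)))
  if (!is.null(seed_shuffles)) set.seed(seed_shuffles)
  null_theta <- vapply(seq_len(n_shuffles), function(s) {
    theta_for_tips(mrca_mat, sample.int(n, 2L), scores, anc_obs,
                   dnode, n)[["theta"]]
  }, numeric(1))
  p_theta <- vapply(th_obs[, 1L], function(t0) {
    (sum(null_theta <= t0) + 1) / (n_shuffles + 1)
  }, numeric(1))

  data.frame(species = candidates,
             obs,
             p_C1 = p_c[, "C1"], p_C2 = p_c[, "C2"],
             p_C3 = p_c[, "C3"], p_C4 = p_c[, "C4"],
             theta = th_obs[, 1L], theta_time = th_obs[, 2L],
             p_theta = p_theta,
             row.names = NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report | focal:", x$config$focal_species, "\n")
  cat("  candidates:", length(x$candidates$candidates),
      "| maximally convergent:",
      paste(x$call$species[x$call$maximal_convergent], collapse = ", "), "\n")
  for (ds in names(x$cva)) {
    cat(sprintf("  CVA %s: %.1f%% jackknife correct\n", ds,
                x$cva[[ds]]$pct_correct))
  }
  invisible(x)
}

#' Write the report bundle as CSV tables plus a run log
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$signal, file.path(dir, "signal_pgls.csv"),
                   row.names = FALSE)
  cva_tab <- do.call(rbind, lapply(names(report$cva), function(ds) {
    cv <- report$cva[[ds]]
    data.frame(dataset = ds,
               pct_correct = cv$pct_correct,
               pct_correct_resubstitution = cv$pct_correct_resubstitution,
               focal_assigned = if (!is.null(cv$unknown_assignments))
                 paste(unique(cv$unknown_assignments$assigned), collapse = ";")
               else NA_character_)
  }))
  utils::write.csv(cva_tab, file.path(dir, "cva_summary.csv"), row.names = FALSE)
  utils::write.csv(report$screens, file.path(dir, "pc_ecology_screens.csv"),
                   row.names = FALSE)
  utils::write.csv(report$convergence, file.path(dir, "convergence_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$call),
                   file.path(dir, "maximal_convergence.csv"), row.names = FALSE)
  writeLines(c(
    paste("morphoconv", as.character(utils::packageVersion("morphoconv"))),
    paste("R", getRversion()),
    paste("seed", report$config$seed),
    paste("stage seeds:",
          paste(names(derive_seeds(report$config$seed)),
                unlist(derive_seeds(report$config$seed)),
                sep = "=", collapse = " ")),
    paste("focal", report$config$focal_species),
    paste("candidates", paste(report$candidates$candidates, collapse = ","))),
    file.path(dir, "run_log.txt"))
  write_dendrogram(report$candidates, file.path(dir, "upgma_dendrogram.nwk"))
  invisible(dir)
}
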