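# UPGMA candidates, C1-C4 metrics, theta test, BH, and the decision rule.

six_tip_tree <- function() {
  ape::read.tree(text = "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,(t5:1,t6:1):2);")
}

test_that("UPGMA reproduces a hand-agglomerated worked example", {
  # collinear points 0, 1, 4, 10: hand agglomeration gives merges
  # {a,b}@1, {ab,c}@3.5, {abc,d}@25/3
  scores <- matrix(c(0, 1, 4, 10), 4, 1,
                   dimnames = list(c("a", "b", "c", "d"), NULL))
  cand <- upgma_candidates(scores, focal = "a")
  hc <- cand$linkage
  expect_equal(hc$height, c(1, 3.5, 25 / 3), tolerance = 1e-12)
  # largest focal cluster holding at most half the species: {a,b}
  expect_identical(sort(cand$members), c("a", "b"))
  expect_identical(cand$candidates, "b")

  # coincident species merge first at height zero
  sc2 <- matrix(c(0, 0, 5, 9), 4, 1,
                dimnames = list(c("a", "b", "c", "d"), NULL))
  expect_equal(upgma_candidates(sc2, "c")$linkage$height[1], 0)

  # equidistant points: all merge heights equal, any order valid
  eq <- diag(3) * sqrt(2) / 2
  rownames(eq) <- c("a", "b", "c")
  h <- upgma_candidates(eq, "a")$linkage$height
  expect_equal(h[1], 1, tolerance = 1e-12)

  expect_error(upgma_candidates(scores, "nope"), "focal")
})

test_that("fixed-height cuts select the focal cluster at that height", {
  scores <- matrix(c(0, 1, 4, 10), 4, 1,
                   dimnames = list(c("a", "b", "c", "d"), NULL))
  cand <- upgma_candidates(scores, "a", cut_height = 2)
  expect_identical(sort(cand$members), c("a", "b"))
})

test_that("C1 hits its analytic bounds under injected node states", {
  tree <- six_tip_tree()
  n <- 6L
  nodes <- as.character(n + seq_len(tree$Nnode))
  tips <- matrix(0, n, 2, dimnames = list(tree$tip.label, NULL))
  anc <- matrix(rnorm(tree$Nnode * 2, mean = 5), tree$Nnode, 2,
                dimnames = list(nodes, NULL))

  # identical tip phenotypes, distinct ancestors: complete convergence
  tips["t1", ] <- c(1, 1)
  tips["t4", ] <- c(1, 1)
  m <- c_metrics(tree, tips, c("t1", "t4"), node_states = anc)
  expect_equal(unname(m["C1"]), 1, tolerance = 1e-12)
  expect_equal(unname(m["D_tip"]), 0)

  # tips realizing the maximal cross-lineage distance: zero convergence
  tips["t1", ] <- c(-50, 0)
  tips["t4", ] <- c(50, 0)
  m0 <- c_metrics(tree, tips, c("t1", "t4"), node_states = anc)
  expect_equal(unname(m0["C1"]), 0, tolerance = 1e-12)
  expect_equal(unname(m0["D_tip"]), unname(m0["D_max"]))

  expect_error(c_metrics(tree, tips, c("t1", "t1")), "itself")
})

test_that("c_metrics equals brute-force node-pair enumeration on random trees", {
  for (seed in 1:25) {
    case <- random_injected_case(6, 3, seed)
    pair <- sample(case$tree$tip.label, 2)
    ours <- c_metrics(case$tree, case$tips, pair, node_states = case$nodes)
    oracle <- brute_c_metrics(case$tree, case$tips, pair, case$nodes)
    expect_equal(ours, oracle[names(ours)], tolerance = 1e-12)
  }
})

test_that("C-metric identities and ranges hold with reconstructed ancestors", {
  set.seed(77)
  tree <- simulate_tree(10)
  model <- structure(list(rate_matrix = diag(3), root_state = rep(0, 3)),
                     class = "bm_model")
  for (s in 1:10) {
    Y <- matrix(simulate_bm(tree, model, n_sims = 1)[1, , ], 10, 3,
                dimnames = list(tree$tip.label, NULL))
    pair <- sample(tree$tip.label, 2)
    m <- c_metrics(tree, Y, pair)
    expect_gte(m[["C1"]], 0); expect_lte(m[["C1"]], 1)
    expect_gte(m[["C2"]], 0)
    expect_equal(m[["C1"]], 1 - m[["D_tip"]] / m[["D_max"]], tolerance = 1e-12)
    expect_equal(m[["C2"]], m[["D_max"]] - m[["D_tip"]], tolerance = 1e-12)
    expect_equal(m[["C3"]], m[["C2"]] / m[["L_tot_lineage"]], tolerance = 1e-12)
    expect_equal(m[["C4"]], m[["C2"]] / m[["L_tot_clade"]], tolerance = 1e-12)
    expect_gte(m[["D_max"]], m[["D_tip"]])
    expect_gte(m[["L_tot_clade"]], m[["L_tot_lineage"]] - 1e-12)
  }
})

test_that("c_significance is seeded, +1-corrected, and sane at the extremes", {
  set.seed(13)
  tree <- simulate_tree(12)
  model <- structure(list(rate_matrix = diag(2), root_state = c(0, 0)),
                     class = "bm_model")
  Y <- matrix(simulate_bm(tree, model, n_sims = 1, seed = 5)[1, , ], 12, 2,
              dimnames = list(tree$tip.label, NULL))
  a <- c_significance(tree, Y, c("sp01", "sp07"), n_sims = 100, seed = 9)
  b <- c_significance(tree, Y, c("sp01", "sp07"), n_sims = 100, seed = 9)
  expect_identical(a$p_values, b$p_values)
  expect_true(all(a$p_values > 0 & a$p_values <= 1))
  expect_error(c_significance(tree, Y, c("sp01", "sp07"), n_sims = 10),
               "at least 100")
  expect_error(c_significance(tree, Y * 0, c("sp01", "sp07"), n_sims = 100),
               "no variation")

  # anti-converged tips: observed C1 near 0, null easily exceeds it
  Y2 <- Y
  Y2["sp01", ] <- c(-40, 0)
  Y2["sp07", ] <- c(40, 0)
  far <- c_significance(tree, Y2, c("sp01", "sp07"), n_sims = 100, seed = 2)
  expect_lt(far$observed[["C1"]], 0.05)
  expect_gt(far$p_values[["C1"]], 0.5)
})

test_that("phenotypic angles match analytic values", {
  va <- morphoconv:::vector_angle
  expect_equal(va(c(1, 0), c(1, 1)), 45, tolerance = 1e-12)
  expect_equal(va(c(2, 0), c(6, 0)), 0, tolerance = 1e-12)
  expect_equal(va(c(1, 0), c(0, -3)), 90, tolerance = 1e-12)
  expect_equal(va(c(1, 2), c(-1, -2)), 180, tolerance = 1e-6)
  expect_error(va(c(0, 0), c(1, 1)), "zero-length")
})

test_that("theta test is rotation-invariant and flags identical cherries", {
  set.seed(14)
  tree <- simulate_tree(12)
  model <- structure(list(rate_matrix = diag(3), root_state = rep(0, 3)),
                     class = "bm_model")
  Y <- matrix(simulate_bm(tree, model, n_sims = 1, seed = 6)[1, , ], 12, 3,
              dimnames = list(tree$tip.label, NULL))
  t1 <- theta_convergence(tree, Y, c("sp02", "sp09"), n_shuffles = 99, seed = 3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  YQ <- Y %*% Q
  rownames(YQ) <- rownames(Y)
  t2 <- theta_convergence(tree, YQ, c("sp02", "sp09"), n_shuffles = 99, seed = 3)
  expect_equal(t1$theta, t2$theta, tolerance = 1e-9)
  expect_equal(t1$theta_time, t2$theta_time, tolerance = 1e-9)
  expect_identical(t1$p, t2$p)
  expect_gte(t1$theta, 0); expect_lte(t1$theta, 180)

  # two identical tips collapse onto their MRCA reconstruction on a 2-tip tree
  two <- ape::read.tree(text = "(A:1,B:1);")
  same <- matrix(1, 2, 2, dimnames = list(c("A", "B"), NULL))
  expect_error(theta_convergence(two, same, c("A", "B"), n_shuffles = 10),
               "zero-length")
})

test_that("BH matches the step-up definition and its hand example", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), alpha = 0.10)
  expect_identical(out$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_fdr(rep(1, 5), 0.10)$significant, rep(FALSE, 5))
  expect_identical(bh_fdr(0.05, 0.10)$significant, TRUE)
  empty <- bh_fdr(numeric(0), 0.10)
  expect_length(empty$significant, 0L)

  set.seed(15)
  for (r in 1:20) {
    p <- runif(sample(3:30, 1))
    expect_identical(bh_fdr(p, 0.10)$significant, bh_by_hand(p, 0.10))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the maximal-convergence rule needs both methods in total plus one patch", {
  mk <- function(sp, ds, p1, pt) {
    data.frame(species = sp, dataset = ds, p_C1 = p1, p_theta = pt)
  }
  tab <- rbind(
    mk("everywhere", c("total", "facial", "neurocranial"),
       c(0.001, 0.001, 0.001), c(0.001, 0.001, 0.001)),
    mk("nowhere", c("total", "facial", "neurocranial"),
       c(1, 1, 1), c(1, 1, 1)),
    mk("patch_only", c("total", "facial", "neurocranial"),
       c(1, 0.001, 0.001), c(1, 0.001, 0.001)),
    mk("one_method", c("total", "facial", "neurocranial"),
       c(0.001, 0.001, 0.001), c(1, 1, 1)))
  call <- maximal_convergence_call(tab, alpha = 0.10)
  expect_identical(call$species[call$maximal_convergent], "everywhere")

  all_null <- tab
  all_null$p_C1 <- 1
  all_null$p_theta <- 1
  expect_false(any(maximal_convergence_call(all_null)$maximal_convergent))

  incomplete <- tab[tab$species != "nowhere" | tab$dataset != "facial", ]
  expect_warning(call2 <- maximal_convergence_call(incomplete), "nowhere")
  expect_false("nowhere" %in% call2$species)
})

test_that("lowering a p-value never shrinks the maximal set", {
  set.seed(16)
  for (r in 1:15) {
    sp <- paste0("s", 1:6)
    tab <- expand.grid(species = sp,
                       dataset = c("total", "facial", "neurocranial"),
                       stringsAsFactors = FALSE)
    tab$p_C1 <- runif(nrow(tab))
    tab$p_theta <- runif(nrow(tab))
    before <- maximal_convergence_call(tab, alpha = 0.10)
    set_before <- before$species[before$maximal_convergent]
    i <- sample(nrow(tab), 1)
    tab$p_C1[i] <- tab$p_C1[i] / 10
    after <- maximal_convergence_call(tab, alpha = 0.10)
    expect_true(all(set_before %in% after$species[after$maximal_convergent]))
  }
})
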