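# Landmark I/O, centroid size, and generalized Procrustes alignment.

make_config <- function(coords, id = "s1", sp = "spA", ...) {
  landmark_config(coords, specimen_id = id, species_id = sp, ...)
}

random_config <- function(k, seed, id = "s1", sp = "spA") {
  set.seed(seed)
  make_config(matrix(rnorm(3 * k), k, 3), id = id, sp = sp)
}

test_that("TPS files preserve specimen counts and round-trip bit-identically", {
  set.seed(11)
  configs <- lapply(1:8, function(i) {
    make_config(matrix(rnorm(180), 60, 3), id = sprintf("sp%02d__%02d", i, i),
                sp = sprintf("sp%02d", i))
  })
  path <- withr::local_tempfile(fileext = ".tps")
  write_landmarks(configs, path)
  back <- read_landmarks(path)
  expect_length(back, 8L)
  for (i in 1:8) {
    expect_identical(back[[i]]$coords, configs[[i]]$coords)
    expect_identical(back[[i]]$specimen_id, configs[[i]]$specimen_id)
    expect_identical(back[[i]]$species_id, configs[[i]]$species_id)
  }

  small <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM3=2", "0 0 0", "1 1 1", "ID=a__1",
               "LM3=2", "2 2 2", "3 3 3", "ID=b__1"), small)
  expect_length(read_landmarks(small), 2L)
})

test_that("malformed landmark files fail loudly, naming the offender", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen,species,x1,y1,z1,x2,y2,z2",
               "s1,spA,0,0,0,1,1,1",
               "s2,spB,0,0,,1,1,1"), path)
  expect_error(read_landmarks(path), "s2")

  tps <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM3=2", "0 0 0", "1 1 x", "ID=a"), tps)
  expect_error(read_landmarks(tps), "line 3")

  mixed <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM3=2", "0 0 0", "1 1 1", "ID=a__1",
               "LM3=3", "0 0 0", "1 1 1", "2 2 2", "ID=bad__1"), mixed)
  expect_error(read_landmarks(mixed), "bad__1")
})

test_that("subset maps attach 0-based subset and role labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen,species,x1,y1,z1,x2,y2,z2,x3,y3,z3",
               "s1,spA,0,0,0,1,1,1,2,0,1"), path)
  sm <- data.frame(landmark_index = c(0L, 2L),
                   subset = c("facial", "neurocranial"),
                   role = c("patch_semilandmark", "patch_semilandmark"))
  cfg <- read_landmarks(path, subset_map = sm)[[1]]
  expect_identical(cfg$subsets, c("facial", "other", "neurocranial"))
  expect_identical(cfg$roles[1], "patch_semilandmark")
})

test_that("centroid size matches the analytic value, scales linearly, and agrees with brute force", {
  square <- matrix(c(0.5, 0.5, 0, 0.5, -0.5, 0, -0.5, 0.5, 0, -0.5, -0.5, 0),
                   4, 3, byrow = TRUE)
  expect_equal(centroid_size(square), sqrt(2), tolerance = 1e-12)

  cfg <- random_config(20, seed = 3)
  expect_equal(centroid_size(make_config(cfg$coords * 3.7)),
               3.7 * centroid_size(cfg), tolerance = 1e-12)
  expect_equal(centroid_size(cfg), brute_centroid_size(cfg$coords),
               tolerance = 1e-12)
  expect_warning(centroid_size(matrix(1, 5, 3)), "degenerate")
})

test_that("GPA removes translation, rotation and scaling to numerical precision", {
  a <- random_config(15, seed = 5, id = "a")
  rot <- morphoconv:::random_rotation()
  b_coords <- 2.5 * a$coords %*% rot + matrix(c(3, -1, 7), 15, 3, byrow = TRUE)
  b <- make_config(b_coords, id = "b")
  al <- gpa_align(list(a, b))
  expect_lt(sqrt(mean((al$pcoords[1, , ] - al$pcoords[2, , ])^2)), 1e-8)

  # identical configurations have zero Procrustes distance
  al2 <- gpa_align(list(a, make_config(a$coords, id = "a2")))
  expect_lt(sqrt(sum((al2$pcoords[1, , ] - al2$pcoords[2, , ])^2)), 1e-12)
})

test_that("aligned shapes satisfy the unit-size, centred invariants", {
  configs <- lapply(1:6, function(i) random_config(12, seed = 20 + i,
                                                   id = paste0("s", i)))
  al <- gpa_align(configs)
  for (i in 1:6) {
    expect_lt(max(abs(colSums(al$pcoords[i, , ]))), 1e-9)
    expect_lt(abs(1 - centroid_size(al$pcoords[i, , ])), 1e-9)
  }
  expect_equal(al$mean_shape, apply(al$pcoords, c(2, 3), mean),
               tolerance = 1e-6)
  expect_equal(al$csize, vapply(configs, centroid_size, numeric(1)))
})

test_that("two-specimen GPA matches the closed-form planar Procrustes solution", {
  # planar triangles embedded in 3D; rotation solved by hand in 2D
  t1 <- cbind(matrix(c(0, 0, 2, 0, 1, 2), 3, 2, byrow = TRUE), 0)
  t2 <- cbind(matrix(c(0.2, -0.1, 1.8, 0.4, 0.8, 2.2), 3, 2, byrow = TRUE), 0)
  c1 <- morphoconv:::center_scale(t1)
  c2 <- morphoconv:::center_scale(t2)
  oracle <- opa_2d(c1[, 1:2], c2[, 1:2])
  al <- gpa_align(list(make_config(t1, id = "a"), make_config(t2, id = "b")))
  gpa_dist <- sqrt(sum((al$pcoords[1, , ] - al$pcoords[2, , ])^2))
  expect_equal(gpa_dist, oracle$distance, tolerance = 1e-10)
})

test_that("GPA output is invariant to similarity transforms of any input specimen", {
  configs <- lapply(1:5, function(i) random_config(10, seed = 40 + i,
                                                   id = paste0("s", i)))
  ref <- gpa_align(configs)
  set.seed(99)
  perturbed <- configs
  rot <- morphoconv:::random_rotation()
  perturbed[[3]] <- make_config(
    0.3 * configs[[3]]$coords %*% rot + matrix(rnorm(3, sd = 5), 10, 3,
                                               byrow = TRUE),
    id = "s3")
  out <- gpa_align(perturbed)
  expect_lt(max(abs(out$pcoords - ref$pcoords)), 1e-8)
})

test_that("GPA descent is monotone in summed squared distance to the consensus", {
  configs <- lapply(1:7, function(i) random_config(9, seed = 60 + i,
                                                   id = paste0("s", i)))
  # re-run alignment manually, tracking the objective across iterations
  arr <- array(NA_real_, c(7, 9, 3))
  for (i in 1:7) arr[i, , ] <- morphoconv:::center_scale(configs[[i]]$coords)
  consensus <- arr[1, , ]
  objective <- c()
  for (iter in 1:10) {
    for (i in 1:7) arr[i, , ] <- morphoconv:::rotate_onto(arr[i, , ], consensus)
    objective <- c(objective, sum(sweep(arr, c(2, 3), consensus)^2))
    consensus <- morphoconv:::center_scale(apply(arr, c(2, 3), mean))
  }
  expect_true(all(diff(objective) < 1e-10))
})

test_that("semilandmark sliding reduces bending energy against the consensus", {
  tpl <- skull_template(n_fixed = 6L, n_curve = 6L, n_patch = 12L)
  set.seed(8)
  configs <- lapply(1:4, function(i) {
    make_config(tpl$coords + matrix(rnorm(72, sd = 0.01), 24, 3),
                id = paste0("s", i), roles = tpl$roles, subsets = tpl$subsets)
  })
  plain <- gpa_align(configs)
  slid <- gpa_align(configs, slide_semilandmarks = TRUE)
  be <- morphoconv:::bending_energy_matrix(plain$mean_shape)
  bending <- function(al) {
    sum(vapply(1:4, function(i) {
      d <- al$pcoords[i, , ] - al$mean_shape
      sum(diag(t(d) %*% be %*% d))
    }, numeric(1)))
  }
  expect_lt(bending(slid), bending(plain))
})

test_that("subsets partition the landmarks and realigned patches are re-standardized", {
  fx <- fixture_small()
  al <- gpa_align(fx$configs)
  expect_setequal(unique(al$subsets), c("other", "facial", "neurocranial"))
  expect_identical(subset_shapes(al, "total"), al)
  fa <- subset_shapes(al, "facial")
  expect_equal(dim(fa$pcoords)[2], sum(al$subsets == "facial"))
  for (i in seq_len(dim(fa$pcoords)[1])) {
    expect_lt(abs(1 - centroid_size(fa$pcoords[i, , ])), 1e-9)
  }
  carried <- subset_shapes(al, "neurocranial", realign = FALSE)
  keep <- which(al$subsets == "neurocranial")
  expect_equal(carried$pcoords[2, , ], al$pcoords[2, keep, ])
  al$subsets <- rep("other", length(al$subsets))
  expect_error(subset_shapes(al, "facial"), "no landmarks")
})

test_that("species means are exact coordinate-wise means in tree tip order", {
  fx <- fixture_small()
  al <- gpa_align(fx$configs)
  sm <- species_mean_shapes(al, tree = fx$tree)
  expect_identical(sm$species, fx$tree$tip.label)
  sp <- fx$tree$tip.label[4]
  rows <- which(al$species_ids == sp)
  brute <- Reduce(`+`, lapply(rows, function(r) al$pcoords[r, , ])) / length(rows)
  expect_equal(sm$means[sp, , ], brute, tolerance = 1e-12)

  # mirrored pair about a mean recovers the mean exactly
  base <- random_config(8, seed = 77)$coords
  delta <- matrix(rnorm(24, sd = 0.01), 8, 3)
  al2 <- list(pcoords = array(c(base + delta, base - delta), c(2, 8, 3)),
              ln_csize = c(0, 0),
              species_ids = c("m", "m"), specimen_ids = c("a", "b"))
  # note: bypasses alignment on purpose; means are plain arithmetic
  arr <- array(NA_real_, c(2, 8, 3))
  arr[1, , ] <- base + delta
  arr[2, , ] <- base - delta
  al2$pcoords <- arr
  class(al2) <- "aligned_shapes"
  sm2 <- species_mean_shapes(al2)
  expect_equal(sm2$means["m", , ], base, tolerance = 1e-12)
})
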