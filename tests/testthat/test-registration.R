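test_that("rigid transforms validate, compose and invert", {
  expect_error(rigid_transform(matrix(2 * diag(3), 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "rigid")
  set.seed(3)
  for (i in 1:10) {
    tr <- random_rigid()
    id <- compose_transform(tr, invert_transform(tr))
    expect_lt(max(abs(id$rotation - diag(3))), 1e-9)
    expect_lt(max(abs(id$translation)), 1e-9)
    expect_lt(max(abs(crossprod(tr$rotation) - diag(3))), 1e-9)
    expect_lt(abs(det(tr$rotation) - 1), 1e-9)
  }
})

test_that("composition applied once equals sequential application", {
  set.seed(4)
  t1 <- random_rigid(); t2 <- random_rigid()
  p <- matrix(rnorm(30), 10, 3)
  seq2 <- apply_transform(apply_transform(p, t1), t2)
  once <- apply_transform(p, compose_transform(t2, t1))
  expect_lt(max(abs(seq2 - once)), 1e-9)
})

test_that("horn_align recovers exact transforms and rejects degeneracy", {
  set.seed(5)
  p <- matrix(rnorm(18), 6, 3)
  expect_equal(horn_align(p, p)$rotation, diag(3), tolerance = 1e-9)
  tr <- axis_angle_transform(c(0, 0, 1), 90, c(1, 2, 3))
  q <- apply_transform(p, tr)
  h <- horn_align(q, p)
  expect_lt(max(abs(h$rotation - tr$rotation)), 1e-9)
  expect_lt(max(abs(h$translation - tr$translation)), 1e-9)
  # residual zero by construction
  expect_lt(max(abs(apply_transform(p, h) - q)), 1e-9)
  expect_error(horn_align(p[1:2, ], p[1:2, ]), "at least 3")
  expect_error(horn_align(p, p[1:3, ]), "counts differ")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(horn_align(line, line + 1), "collinear")
})

test_that("horn_align attains a lower objective than random search", {
  set.seed(6)
  p <- matrix(rnorm(18), 6, 3)
  tr <- random_rigid()
  q <- apply_transform(p, tr) + matrix(rnorm(18, 0, 0.3), 6, 3)
  h <- horn_align(q, p)
  obj <- function(t2) sum((apply_transform(p, t2) - q)^2)
  best_random <- min(vapply(seq_len(10000), function(i) obj(random_rigid()),
                            1))
  expect_lte(obj(h), best_random)
})

test_that("prominent-vertex pick respects direction and tie-breaking", {
  s <- icosphere(1, 3)
  top <- pick_prominent_vertex(s, c(0, 0, 1))
  expect_gt(s$vertices[top, 3], 0.99)
  # equivariance: transforming the mesh and the direction consistently
  # picks the same anatomical point
  tr <- axis_angle_transform(c(1, 1, 0), 40, c(3, -2, 1))
  s2 <- apply_transform(s, tr)
  top2 <- pick_prominent_vertex(s2, as.vector(tr$rotation %*% c(0, 0, 1)))
  expect_equal(top2, top)
  # flat-top mesh: ties broken by lowest index
  flat <- triangle_mesh(rbind(c(0, 0, 1), c(1, 0, 1), c(0, 1, 1),
                              c(0, 0, 0)),
                        rbind(c(1, 2, 3), c(1, 4, 2), c(2, 4, 3),
                              c(1, 3, 4)))
  expect_equal(pick_prominent_vertex(flat, c(0, 0, 1)), 1L)
})

test_that("select_region obeys its radius and matches the cap fraction", {
  s <- icosphere(1, 4)
  seed <- pick_prominent_vertex(s, c(0, 0, 1))
  expect_error(select_region(s, seed, 0), "radius")
  expect_error(select_region(s, 0, 1), "seed")
  expect_warning(only_seed <- select_region(s, seed, 1e-9), "only the seed")
  expect_equal(only_seed$index, seed)
  all_sel <- select_region(s, seed, 3)
  expect_equal(length(all_sel$index), nrow(s$vertices))
  # Euclidean chord 0.5 on the unit sphere: cap fraction (1 - cos t)/2
  # with cos t = 1 - 2 (0.25)^2
  sel <- select_region(s, seed, 0.5)
  frac <- length(sel$index) / nrow(s$vertices)
  expect_lt(abs(frac / 0.0625 - 1), 0.15)
  # all selected points within the radius of the seed
  d <- sqrt(rowSums(sweep(sel$points, 2, s$vertices[seed, ])^2))
  expect_lte(max(d), 0.5 + 1e-12)
})

test_that("icp on identical clouds returns identity immediately", {
  s <- icosphere(2, 2)
  out <- icp_register(s$vertices, s$vertices)
  expect_lt(rotation_angle(out$transform), 1e-8)
  expect_lt(max(abs(out$transform$translation)), 1e-10)
  expect_lte(out$iterations, 2)
  expect_error(icp_register(s$vertices[0, , drop = FALSE], s$vertices),
               "empty")
})

test_that("icp RMS trace is non-increasing", {
  set.seed(8)
  m <- make_condyle_mesh(small_phantom_spec())
  for (seed in 1:3) {
    p <- perturb_replicate(m, 8, 4, 0.05, seed = seed)
    out <- icp_register(m$vertices, p$mesh$vertices, max_iter = 40,
                        max_points = 1500)
    expect_true(all(diff(out$rms) <= 1e-9))
  }
})

test_that("the semiautomatic chain recovers a clean 5 deg / 2 mm offset", {
  m <- make_condyle_mesh(small_phantom_spec())
  p <- perturb_replicate(m, 5, 2, 0, seed = 21)
  reg <- register_meshes(m, p$mesh)
  err <- pose_error(reg$transform, p$transform,
                    anchor = colMeans(m$vertices))
  expect_lt(err$rotation_deg, 0.1)
  expect_lt(err$translation_mm, 0.05)
})

test_that("registration never changes S or V", {
  m <- make_condyle_mesh(small_phantom_spec())
  p <- perturb_replicate(m, 10, 6, 0, seed = 2)
  reg <- register_meshes(m, p$mesh)
  aligned <- apply_transform(p$mesh, reg$transform)
  expect_lt(abs(surface_area(aligned) / surface_area(p$mesh) - 1), 1e-9)
  expect_lt(abs(mesh_volume(aligned) / mesh_volume(p$mesh) - 1), 1e-9)
})

test_that("pose files round-trip through plain text", {
  tr <- axis_angle_transform(c(1, 2, 3), 33, c(0.5, -4, 2))
  path <- withr::local_tempfile(fileext = ".txt")
  write_pose(tr, path)
  tr2 <- read_pose(path)
  expect_lt(max(abs(tr2$rotation - tr$rotation)), 1e-12)
  expect_lt(max(abs(tr2$translation - tr$translation)), 1e-12)
})

test_that("landmark files are parsed as named positions", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ANS 0 70 -3.5", "notch_L 25 -9 -3.5", "notch_R -25 -9 -3.5"),
             path)
  lm <- read_landmarks(path)
  expect_named(lm, c("ANS", "notch_L", "notch_R"))
  expect_equal(lm$notch_R, c(-25, -9, -3.5))
})
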