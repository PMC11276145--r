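test_that("cut planes satisfy their geometric invariants", {
  pl <- build_cut_planes(c(0, 100, 0), c(50, 0, 0), c(-50, 0, 0))
  expect_lt(abs(sum(pl$plane_A$normal * pl$plane_B$normal)), 1e-9)
  # plane A contains all three landmarks
  for (p in pl$landmarks)
    expect_lt(abs(sum((p - pl$plane_A$point) * pl$plane_A$normal)), 1e-9)
  # plane B contains both notch points
  for (p in pl$landmarks[c("notch_L", "notch_R")])
    expect_lt(abs(sum((p - pl$plane_B$point) * pl$plane_B$normal)), 1e-9)
  expect_error(build_cut_planes(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
})

test_that("swapping the notch points leaves the planes unchanged", {
  pl1 <- build_cut_planes(c(3, 80, 2), c(42, -5, -1), c(-38, -6, -2))
  pl2 <- build_cut_planes(c(3, 80, 2), c(-38, -6, -2), c(42, -5, -1))
  expect_equal(pl1$plane_A, pl2$plane_A, tolerance = 1e-12)
  expect_equal(pl1$plane_B, pl2$plane_B, tolerance = 1e-12)
})

test_that("planes transform equivariantly with the landmarks", {
  set.seed(11)
  pl <- build_cut_planes(c(0, 70, -3.5), c(25, -9, -3.5), c(-25, -9, -3.5))
  tr <- random_rigid()
  pl2 <- transform_planes(pl, tr)
  for (nm in c("plane_A", "plane_B")) {
    want_n <- as.vector(tr$rotation %*% pl[[nm]]$normal)
    got_n <- pl2[[nm]]$normal
    expect_lt(min(max(abs(got_n - want_n)), max(abs(got_n + want_n))),
              1e-9)
    want_p <- as.vector(tr$rotation %*% pl[[nm]]$point) + tr$translation
    # transformed point lies on the transformed plane
    expect_lt(abs(sum((want_p - pl2[[nm]]$point) * pl2[[nm]]$normal)), 1e-9)
  }
})

test_that("a plane through the centre halves a sphere", {
  s <- icosphere(1, 4)
  cut <- clip_halfspace(s, c(0, 0, 0), c(0, 0, 1))
  expect_true(is_watertight(cut))
  expect_lt(abs(mesh_volume(cut) / (mesh_volume(s) / 2) - 1), 0.005)
  expect_lt(abs(mesh_volume(cut) / (2 / 3 * pi) - 1), 0.005)
  expect_gt(attr(cut, "cap_area"), 0)
  expect_lt(abs(attr(cut, "cap_area") / pi - 1), 0.005)
})

test_that("cut_head keeps the head side, caps, and warns on misses", {
  s <- icosphere(1, 3)
  # plane B far from the mesh: only plane A cuts
  pl <- build_cut_planes(c(0, 5, 0), c(10, -30, 0), c(-10, -30, 0))
  expect_warning(cut <- cut_head(s, pl, keep_point = c(0, 0, 1)),
                 "does not intersect")
  expect_true(is_watertight(cut))
  expect_lte(mesh_volume(cut), mesh_volume(s))
  expect_lt(abs(mesh_volume(cut) / (2 / 3 * pi) - 1), 0.01)
  # both planes entirely outside: mesh passes through unchanged, one
  # warning per missing plane
  pl_far <- build_cut_planes(c(0, 5, -20), c(10, -30, -20), c(-10, -30, -20))
  w <- testthat::capture_warnings(
    same <- cut_head(s, pl_far, keep_point = c(0, 0, 1)))
  expect_length(w, 2)
  expect_match(w, "does not intersect", all = TRUE)
  expect_equal(mesh_volume(same), mesh_volume(s))
})

test_that("cutting an ellipsoid phantom matches the analytic cap volume", {
  a <- 8; b <- 6; cc <- 5; z0 <- 1.5
  sp <- phantom_spec(semi_axes = c(a, b, cc), neck_length = 0,
                     asymmetry = 0, lateral_offset = 0, pitch = 0.2)
  m <- make_condyle_mesh(sp)
  pl <- build_cut_planes(c(0, 50, z0), c(30, -20, z0), c(-30, -20, z0))
  cut <- suppressWarnings(cut_head(m, pl, keep_point = c(0, 0, cc)))
  expect_true(is_watertight(cut))
  expect_lt(abs(mesh_volume(cut) / ellipsoid_cap_volume(a, b, cc, z0) - 1),
            0.02)
})

test_that("cutting commutes with rigid motion", {
  m <- make_condyle_mesh(small_phantom_spec())
  pl <- build_cut_planes(c(0, 50, -2), c(30, -15, -2), c(-30, -15, -2))
  tr <- axis_angle_transform(c(0.3, 1, 0.2), 25, c(4, -7, 2))
  keep <- m$vertices[pick_prominent_vertex(m), ]
  c1 <- apply_transform(
    suppressWarnings(cut_head(m, pl, keep_point = keep)), tr)
  c2 <- suppressWarnings(cut_head(apply_transform(m, tr),
                                  transform_planes(pl, tr),
                                  keep_point = apply_transform(
                                    matrix(keep, 1), tr)))
  expect_equal(nrow(c1$vertices), nrow(c2$vertices))
  expect_lt(max(abs(c1$vertices - c2$vertices)), 1e-6)
  expect_lt(abs(mesh_volume(c1) - mesh_volume(c2)), 1e-6)
})

test_that("cut keeps the largest component when the mesh splits", {
  # dumbbell: two spheres joined by nothing - a plane cut through the
  # larger sphere leaves two components after clipping the bridge region
  a <- icosphere(2, 3)
  b <- icosphere(1, 3, center = c(6, 0, 0))
  both <- triangle_mesh(rbind(a$vertices, b$vertices),
                        rbind(a$faces, b$faces + nrow(a$vertices)))
  pl <- build_cut_planes(c(0, 20, -0.5), c(30, -10, -0.5), c(-30, -10, -0.5))
  w <- testthat::capture_warnings(
    cut <- cut_head(both, pl, keep_point = c(0, 0, 2)))
  expect_match(w, "components", all = FALSE)
  expect_true(is_watertight(cut))
  # the larger sphere's upper part is kept
  expect_gt(mesh_volume(cut), mesh_volume(b))
})
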