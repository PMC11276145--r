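test_that("phantom specs validate their parameters", {
  expect_error(phantom_spec(semi_axes = c(-1, 2, 3)), "positive")
  expect_error(phantom_spec(neck_radius = 0), "neck")
  expect_error(phantom_spec(pitch = 0), "pitch")
  expect_error(make_condyle_pair(phantom_spec(side = "right"),
                                 phantom_spec(side = "right")),
               "side")
})

test_that("phantom generation is deterministic and watertight", {
  sp <- small_phantom_spec()
  m1 <- make_condyle_mesh(sp)
  m2 <- make_condyle_mesh(sp)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
  expect_true(is_watertight(m1))
  expect_gt(condylometry:::signed_volume(m1), 0)
})

test_that("sphere-degenerate spec matches the closed-form volume", {
  r <- 6.2035  # 4/3 pi r^3 ~ 1000 mm^3
  sp <- phantom_spec(semi_axes = c(r, r, r), neck_length = 0,
                     asymmetry = 0, lateral_offset = 0, pitch = 0.25)
  m <- make_condyle_mesh(sp)
  ref <- attr(m, "reference")
  expect_equal(ref$V, 4 / 3 * pi * r^3, tolerance = 1e-12)
  expect_equal(ref$S, 4 * pi * r^2, tolerance = 1e-9)
  expect_lt(abs(mesh_volume(m) / ref$V - 1), 0.01)
  expect_lt(abs(surface_area(m) / ref$S - 1), 0.01)
})

test_that("mirrored specs give exact mirror images with equal S and V", {
  pair <- make_condyle_pair(small_phantom_spec("left"),
                            small_phantom_spec("right"))
  sl <- surface_area(pair$left); sr <- surface_area(pair$right)
  vl <- mesh_volume(pair$left); vr <- mesh_volume(pair$right)
  expect_lt(abs(sl / sr - 1), 1e-9)
  expect_lt(abs(vl / vr - 1), 1e-9)
  # exact mirror about x = 0
  mirrored <- pair$left$vertices
  mirrored[, 1] <- -mirrored[, 1]
  expect_identical(sort(mirrored[, 1]), sort(pair$right$vertices[, 1]))
})

test_that("default phantom volume lies in the adult condylar range", {
  m <- make_condyle_mesh(phantom_spec(side = "right"))
  # range spanned by reported condylar volumes, mean +/- 3 SD
  expect_gt(mesh_volume(m), 1222.89 - 3 * 69.46)
  expect_lt(mesh_volume(m), 1507.73 + 3 * 55.12)
})

test_that("voxelization reproduces volume and is seed-deterministic", {
  s <- icosphere(6.2035, 3)
  noiseless <- modality_model("cbct_like", boundary_noise_sd = 0,
                              intensity_noise_sd = 0)
  v <- voxelize(s, noiseless, seed = 7)
  expect_identical(v$polarity, "bone_bright")
  m <- threshold_bone(v, 500)
  expect_lt(abs(mask_volume(m) / mesh_volume(s) - 1), 0.02)
  v2 <- voxelize(s, noiseless, seed = 7)
  expect_identical(v$intensities, v2$intensities)
  noisy <- modality_model("cbct_like")
  expect_false(identical(voxelize(s, noisy, seed = 1)$intensities,
                         voxelize(s, noisy, seed = 2)$intensities))
  expect_error(modality_model("cbct_like", voxel_size = c(0, 1, 1)),
               "voxel_size")
})

test_that("modality invariants hold", {
  expect_error(modality_model("cbct_like", polarity = "bone_dark"))
  expect_error(modality_model("cbct_like", erosion_bias = 0.2))
  expect_error(modality_model("mri_like", polarity = "bone_bright"))
  mri <- modality_model("mri_like")
  expect_identical(mri$polarity, "bone_dark")
  expect_gte(mri$erosion_bias, 0)
})

test_that("erosion bias shrinks the segmented volume by ~ delta * S", {
  r <- 8
  s <- icosphere(r, 3)
  delta <- 0.4
  mri <- modality_model("mri_like", erosion_bias = delta,
                        boundary_noise_sd = 0, intensity_noise_sd = 0)
  v <- voxelize(s, mri, seed = 3)
  mesh2 <- segment_volume(v)
  # offset-sphere oracle: eroded volume = 4/3 pi (r - delta)^3
  expected <- 4 / 3 * pi * (r - delta)^3
  expect_lt(abs(mesh_volume(mesh2) / expected - 1), 0.02)
  # first-order shell check: deficit ~ delta * S
  deficit <- mesh_volume(s) - mesh_volume(mesh2)
  expect_lt(abs(deficit / (delta * 4 * pi * r^2) - 1), 0.1)
})

test_that("voxel volume converges to the analytic volume as h shrinks", {
  s <- icosphere(5, 3)
  errs <- vapply(c(1.6, 0.4), function(h) {
    v <- voxelize(s, modality_model("cbct_like", voxel_size = rep(h, 3),
                                    boundary_noise_sd = 0,
                                    intensity_noise_sd = 0), seed = 1)
    abs(mask_volume(threshold_bone(v, 500)) / mesh_volume(s) - 1)
  }, 1)
  expect_lt(errs[2], 0.02)
  expect_lt(errs[2], errs[1] + 0.01)  # no divergence with refinement
})

test_that("perturb_replicate returns the exact transform it applied", {
  m <- icosphere(3, 2)
  z <- perturb_replicate(m, 0, 0, 0, seed = 1)
  expect_equal(z$transform$rotation, diag(3))
  expect_equal(z$transform$translation, c(0, 0, 0))
  expect_identical(z$mesh$vertices, m$vertices)

  p <- perturb_replicate(m, 10, 5, 0, seed = 11)
  back <- apply_transform(p$mesh, invert_transform(p$transform))
  expect_lt(max(abs(back$vertices - m$vertices)), 1e-9)
  expect_lte(rotation_angle(p$transform), 10)
  expect_lte(sqrt(sum(p$transform$translation^2)), 5)
})

test_that("vertex noise magnitude matches the chi distribution mean", {
  m <- icosphere(3, 4)  # many vertices for a tight Monte-Carlo estimate
  sd <- 0.1
  p <- perturb_replicate(m, 0, 0, vertex_noise_sd = sd, seed = 5)
  disp <- sqrt(rowSums((p$mesh$vertices - m$vertices)^2))
  # |N3(0, sd)| has mean sd * sqrt(8/pi)
  expect_lt(abs(mean(disp) / (sd * sqrt(8 / pi)) - 1), 0.02)
})
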