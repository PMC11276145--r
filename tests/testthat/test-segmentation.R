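make_volume <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxel_volume(arr, spacing = spacing, origin = origin)
}

test_that("align_origin zeroes the origin and records the shift", {
  v <- make_volume(array(0, c(4, 4, 4)), origin = c(5, 5, 5))
  v2 <- align_origin(v)
  expect_equal(v2$origin, c(0, 0, 0))
  expect_equal(attr(v2, "origin_shift"), c(5, 5, 5))
  v3 <- align_origin(v2)
  expect_identical(v3$intensities, v2$intensities)
  expect_equal(v3$origin, c(0, 0, 0))
})

test_that("mesh extracted before vs after align_origin differs by the shift", {
  s <- icosphere(4, 2)
  v <- voxelize(s, modality_model("cbct_like", boundary_noise_sd = 0,
                                  intensity_noise_sd = 0), seed = 1)
  m_before <- extract_mesh(fill_holes(threshold_bone(v, 500)))
  v0 <- align_origin(v)
  m_after <- extract_mesh(fill_holes(threshold_bone(v0, 500)))
  shifted <- sweep(m_after$vertices, 2, -attr(v0, "origin_shift"))
  expect_lt(max(abs(shifted - m_before$vertices)), 1e-9)
})

test_that("thresholding selects the requested band and is monotone", {
  arr <- array(seq(0, 1000, length.out = 27), c(3, 3, 3))
  v <- make_volume(arr)
  expect_error(threshold_bone(v, 10, 5), "lo")
  full <- threshold_bone(v, -Inf, Inf)
  expect_true(all(full$mask))
  expect_warning(m0 <- threshold_bone(v, 2000, 3000), "no voxels")
  expect_false(any(m0$mask))
  expect_true(m0$provenance$empty)
  # monotone: enlarging the band never removes voxels
  m1 <- threshold_bone(v, 400, 600)
  m2 <- threshold_bone(v, 300, 700)
  expect_true(all(m2$mask[m1$mask]))
})

test_that("seeded_select keeps only components reachable from seeds", {
  arr <- array(0, c(12, 6, 6))
  arr[2:4, 2:4, 2:4] <- 1000   # component A
  arr[8:10, 2:4, 2:4] <- 1000  # component B
  v <- make_volume(arr)
  m <- threshold_bone(v, 500)
  selA <- seeded_select(m, c(3, 3, 3))
  expect_equal(sum(selA$mask), 27)
  expect_true(all(which(selA$mask, arr.ind = TRUE)[, 1] <= 4))
  # a seed in each component keeps everything
  both <- seeded_select(m, rbind(c(3, 3, 3), c(9, 3, 3)))
  expect_identical(both$mask, m$mask)
  # idempotence
  again <- seeded_select(selA, c(3, 3, 3))
  expect_identical(again$mask, selA$mask)
  expect_error(seeded_select(m, c(50, 1, 1)), "outside")
  expect_warning(ignored <- seeded_select(m, rbind(c(1, 1, 1), c(3, 3, 3))),
                 "ignored")
  expect_equal(sum(ignored$mask), 27)
})

test_that("seeded_select agrees with a brute-force BFS oracle", {
  set.seed(99)
  arr <- array(stats::runif(10 * 10 * 10) > 0.6, c(10, 10, 10))
  v <- make_volume(array(as.numeric(arr) * 1000, dim(arr)))
  m <- threshold_bone(v, 500)
  seeds <- which(arr, arr.ind = TRUE)[1:3, , drop = FALSE]
  got <- seeded_select(m, seeds)
  want <- bfs_fill_oracle(arr, seeds, 26L)
  expect_identical(got$mask, want)
})

test_that("fill_holes closes cavities by exactly their voxel count", {
  arr <- array(0, c(10, 10, 10))
  arr[2:9, 2:9, 2:9] <- 1000
  arr[4:6, 4:6, 4:6] <- 0      # cavity of 27 voxels
  arr[8, 8, 8] <- 0            # second cavity of 1 voxel
  v <- make_volume(arr)
  m <- threshold_bone(v, 500)
  before <- sum(m$mask)
  filled <- fill_holes(m)
  expect_equal(sum(filled$mask), before + 27 + 1)
  # solid mask unchanged; idempotent
  again <- fill_holes(filled)
  expect_identical(again$mask, filled$mask)
  # hollow sphere shell becomes a solid ball
  g <- seq(-6, 6, by = 0.5)
  gr <- expand.grid(x = g, y = g, z = g)
  r <- sqrt(gr$x^2 + gr$y^2 + gr$z^2)
  shell <- array(as.numeric(r >= 4 & r <= 5) * 1000,
                 c(length(g), length(g), length(g)))
  sm <- fill_holes(threshold_bone(make_volume(shell), 500))
  inside_count <- sum(r <= 5)
  expect_equal(sum(sm$mask), inside_count)
})

test_that("extract_mesh produces watertight outward surfaces in world mm", {
  empty_mask <- suppressWarnings(threshold_bone(
    make_volume(array(0, c(3, 3, 3))), 500, 600))
  expect_error(extract_mesh(empty_mask), "empty")
  # single voxel: documented convention gives half the cell volume
  arr <- array(0, c(3, 3, 3)); arr[2, 2, 2] <- 1000
  m <- extract_mesh(threshold_bone(make_volume(arr), 500))
  expect_true(is_watertight(m))
  expect_equal(mesh_volume(m), 0.5)
  # sphere mask r = 10 mm at 0.4 mm spacing
  g <- (seq_len(55) - 28) * 0.4
  gr <- expand.grid(x = g, y = g, z = g)
  mask <- array((gr$x^2 + gr$y^2 + gr$z^2) <= 100, c(55, 55, 55))
  sv <- make_volume(array(as.numeric(mask) * 1000, dim(mask)),
                    spacing = c(0.4, 0.4, 0.4),
                    origin = c(-10.8, -10.8, -10.8))
  ms <- extract_mesh(threshold_bone(sv, 500))
  expect_true(is_watertight(ms))
  expect_gt(condylometry:::signed_volume(ms), 0)
  expect_lt(abs(mesh_volume(ms) / 4188.79 - 1), 0.02)
  # independent marching-cubes reference (scikit-image, same mask):
  # 4168.096 mm^3; tetrahedral decomposition agrees closely
  expect_lt(abs(mesh_volume(ms) / 4168.096 - 1), 0.005)
})

test_that("segmentation round-trip recovers the phantom volume within 3%", {
  m <- make_condyle_mesh(small_phantom_spec())
  v <- voxelize(m, modality_model("cbct_like", boundary_noise_sd = 0,
                                  intensity_noise_sd = 0), seed = 1)
  m2 <- segment_volume(v)
  expect_true(is_watertight(m2))
  expect_lt(abs(mesh_volume(m2) / mesh_volume(m) - 1), 0.03)
})

test_that("NIfTI volume IO round-trips data and geometry", {
  s <- icosphere(3, 2)
  v <- voxelize(s, modality_model("cbct_like"), seed = 1)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path, polarity = v$polarity)
  expect_equal(dim(v2$intensities), dim(v$intensities))
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-4)
  expect_equal(as.vector(v2$intensities), as.vector(v$intensities),
               tolerance = 1e-5)
})
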