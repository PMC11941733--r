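test_that("threshold segmentation selects the closed intensity interval", {
  spec <- anatomy_spec(neck_radius = 11, max_radius = 25.5)
  ph <- generate_phantom_volume(spec, 1, noise_sd = 0)
  m <- threshold_segment(ph, 0.5)
  expect_equal(mask_volume(m), lumen_volume_analytic(spec), tolerance = 0.02)
  expect_warning(threshold_segment(ph, 99), "empty")
  # boundary inclusivity: voxels exactly at lo are retained
  v <- voxel_volume(array(c(0, 0.5, 1, 0.49, 1, 0, 0.5, 1), c(2, 2, 2)), 1)
  sel <- threshold_segment(v, lo = 0.5, hi = 1)
  expect_identical(sum(sel$voxels), 5L)
  expect_error(threshold_segment(v, 1, 0.5), "lo < hi")
})

test_that("largest_component keeps the lumen, drops noise islands", {
  spec <- small_spec()
  ph <- generate_phantom_volume(spec, 1, noise_sd = 0)
  m <- threshold_segment(ph, 0.5)
  vox <- m$voxels
  # plant 50 single-voxel islands, none 26-adjacent to the lumen
  set.seed(42)
  d <- dim(vox)
  dil <- vox
  sh <- function(a, axis, by) {
    idx <- lapply(d, seq_len)
    n <- d[axis]
    idx[[axis]] <- pmin(pmax(seq_len(n) + by, 1), n)
    do.call(`[`, c(list(a), idx))
  }
  for (ax in 1:3) dil <- dil | sh(dil, ax, 1) | sh(dil, ax, -1)
  candidates <- which(!dil)
  isl <- sample(candidates, 50)
  vox[isl] <- TRUE
  lc <- largest_component(segmentation_mask(vox, m$spacing, m$origin), 26)
  expect_identical(lc$voxels, m$voxels)
  # already-connected mask: identity
  expect_identical(largest_component(m, 6)$voxels, m$voxels)
  # two equal components: deterministic lowest-index tie-break
  a <- array(FALSE, c(5, 5, 5)); a[1, 1, 1] <- TRUE; a[5, 5, 5] <- TRUE
  t1 <- largest_component(segmentation_mask(a, 1), 6)
  expect_true(t1$voxels[1, 1, 1]); expect_false(t1$voxels[5, 5, 5])
  expect_error(largest_component(segmentation_mask(array(FALSE, c(2, 2, 2)), 1)),
               "empty")
})

test_that("extract_surface recovers sphere area, volume and topology", {
  m <- ball_mask(15, 40, 1)
  s <- extract_surface(m)
  expect_equal(surface_area(s), 4 * pi * 15^2, tolerance = 0.03)
  expect_equal(mesh_volume(s), 4 / 3 * pi * 15^3, tolerance = 0.02)
  expect_equal(euler_characteristic(s), 2) # closed, genus 0
  expect_length(boundary_loops(s), 0)
  expect_true(all(triangle_normals(s)$areas > 0))
})

test_that("single interior voxel yields a small closed surface", {
  sv <- array(FALSE, c(3, 3, 3)); sv[2, 2, 2] <- TRUE
  s <- extract_surface(segmentation_mask(sv, 1), presmooth = FALSE)
  expect_equal(euler_characteristic(s), 2)
  vol <- mesh_volume(s)
  expect_gt(vol, 0)
  expect_lte(vol, 1) # bounded by the voxel volume (isosurface cuts corners)
})

test_that("mask touching the grid boundary is flagged as open", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 2:3, 2:3] <- TRUE # touches x-min face
  s <- extract_surface(segmentation_mask(a, 1), presmooth = FALSE)
  expect_match(s$provenance, "open")
  expect_gt(length(boundary_loops(s)), 0)
})

test_that("phantom-derived lumen surface has tube topology after clipping", {
  spec <- small_spec()
  ph <- generate_phantom_volume(spec, 1, noise_sd = 0)
  s <- extract_surface(largest_component(threshold_segment(ph, 0.5)))
  expect_equal(euler_characteristic(s), 2) # capped tube = sphere
  clipped <- aortafem:::clip_surface_z(s, 3, spec$total_length - 3)
  expect_equal(euler_characteristic(clipped), 0) # open tube = annulus
  expect_length(boundary_loops(clipped), 2)
})

test_that("Taubin smoothing denoises without shrinking", {
  s <- extract_surface(ball_mask(15, 40, 1))
  expect_identical(smooth_surface(s, 0)$vertices, s$vertices)
  set.seed(1)
  noisy <- s
  r0 <- sqrt(rowSums(s$vertices^2))
  noisy$vertices <- s$vertices * (1 + rnorm(nrow(s$vertices), 0, 0.5) / r0)
  rms <- function(m) sqrt(mean((sqrt(rowSums(m$vertices^2)) - 15)^2))
  sm <- smooth_surface(noisy, 50)
  expect_lt(rms(sm), 0.5 * rms(noisy))
  expect_identical(nrow(sm$vertices), nrow(noisy$vertices))
  # volume preservation on the clean sphere (the motivation for Taubin
  # over plain Laplacian)
  v0 <- mesh_volume(s)
  expect_equal(mesh_volume(smooth_surface(s, 100)), v0, tolerance = 0.02)
})

test_that("reconstruction stages are deterministic", {
  spec <- small_spec(seed = 5)
  run <- function() {
    ph <- generate_phantom_volume(spec, 1.5, noise_sd = 0.1, seed = 5)
    s <- extract_surface(largest_component(threshold_segment(ph, 0.5)))
    smooth_surface(s, 10)$vertices
  }
  expect_identical(run(), run())
})
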