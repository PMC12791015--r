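vol_of <- function(arr, vs = 3) volume_grid(arr, vs, "density_bright")

test_that("slab_average is a dimension-preserving running mean along z", {
  arr <- array(rnorm(4 * 3 * 5), c(4, 3, 5))
  v <- vol_of(arr)
  expect_identical(slab_average(v, 1)$data, arr)

  const <- vol_of(array(7, c(3, 3, 6)))
  expect_equal(slab_average(const, 4)$data, const$data)

  # hand-derived: column (0,0,4,0), width 2 -> windows (z, z+1), last shrinks
  col <- vol_of(array(c(0, 0, 4, 0), c(1, 1, 4)))
  expect_equal(as.numeric(slab_average(col, 2)$data), c(0, 2, 2, 0))

  expect_error(slab_average(col, 0), "width")
  expect_error(slab_average(col, 5), "width")
  expect_identical(dim(slab_average(v, 5)$data), dim(arr))
})

test_that("decimate_z collapses non-overlapping windows", {
  arr <- array(rep(1:6, each = 4), c(2, 2, 6))
  dec <- decimate_z(vol_of(arr), 2)
  expect_identical(dim(dec$data), c(2L, 2L, 3L))
  expect_equal(as.numeric(dec$data[1, 1, ]), c(1.5, 3.5, 5.5))
})

test_that("normalize_unit_interval maps range onto [0,1]", {
  expect_equal(sort(unique(as.numeric(
    normalize_unit_interval(vol_of(array(c(0, 2), c(2, 1, 1))))$data))),
    c(0, 1))
  expect_equal(sort(unique(as.numeric(
    normalize_unit_interval(vol_of(array(c(-1, 0, 1), c(3, 1, 1))))$data))),
    c(0, 0.5, 1))
  v01 <- vol_of(array(c(0, 0.25, 1, 0.5), c(4, 1, 1)))
  expect_equal(normalize_unit_interval(v01)$data, v01$data)
  expect_error(normalize_unit_interval(vol_of(array(3, c(2, 2, 2)))),
               "degenerate")
})

test_that("high_intensity_mask thresholds at mean + k*SD globally", {
  arr <- array(0, c(3, 3, 3)); arr[2, 2, 2] <- 1
  m <- high_intensity_mask(vol_of(arr), 3.3)
  # direct arithmetic: mean 1/27, sample SD ~0.192, threshold ~0.67 < 1
  expect_identical(which(m), which(arr == 1))
  expect_equal(sum(m), 1L)

  expect_error(high_intensity_mask(vol_of(array(1, c(2, 2, 2))), 3.3),
               "degenerate|constant")
  noisy <- vol_of(array(rnorm(1000), c(10, 10, 10)))
  expect_equal(sum(high_intensity_mask(noisy, 1e6)), 0L)
  dark <- volume_grid(arr, 3, "density_dark")
  expect_error(high_intensity_mask(dark, 3.3), "density_bright")
})

test_that("label_components respects the chosen neighborhood", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE        # share only a corner
  expect_length(label_components(m, 26), 1L)
  expect_length(label_components(m, 6), 2L)
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 1] <- TRUE      # share an edge
  expect_length(label_components(m2, 18), 1L)
  expect_length(label_components(m2, 6), 2L)

  single <- array(FALSE, c(3, 3, 3)); single[2, 1, 3] <- TRUE
  comps <- label_components(single, 26)
  expect_length(comps, 1L)
  expect_identical(lengths(comps), 1L)

  block <- array(FALSE, c(5, 5, 5)); block[2:3, 2:3, 2:3] <- TRUE
  for (conn in c(6, 18, 26)) {
    comps <- label_components(block, conn)
    expect_length(comps, 1L)
    expect_identical(lengths(comps), 8L)
  }
  expect_length(label_components(array(FALSE, c(3, 3, 3))), 0L)

  # deterministic ordering by ascending minimum linear index
  m3 <- array(FALSE, c(6, 6, 6))
  m3[5:6, 5:6, 5:6] <- TRUE; m3[1:2, 1, 1] <- TRUE
  comps <- label_components(m3, 26)
  expect_identical(vapply(comps, min, numeric(1)),
                   sort(vapply(comps, min, numeric(1))))
  expect_equal(min(comps[[1]]), 1)
})

test_that("singleton removal and size gating filter components", {
  fake <- function(n) as.integer(seq_len(n))
  comps <- list(fake(1), fake(5), fake(1), fake(44))
  expect_identical(lengths(remove_singletons(comps)), c(5L, 44L))
  expect_length(remove_singletons(list()), 0L)
  big <- list(fake(2), fake(3))
  expect_identical(remove_singletons(big), big)

  sized <- lapply(c(39, 40, 53, 55, 56), fake)
  expect_identical(lengths(size_gate(sized, 40, 55)), c(40L, 53L, 55L))
  expect_identical(size_gate(sized, 1, .Machine$integer.max), sized)
  expect_length(size_gate(list(), 40, 55), 0L)

  # order independence with singleton removal when min >= 2
  expect_identical(size_gate(remove_singletons(comps), 2, 50),
                   remove_singletons(size_gate(comps, 2, 50)))
})

test_that("theoretical_voxel_count uses the volume-ratio definition", {
  expect_identical(theoretical_voxel_count(7, 3), 53)    # 1.4-nm gold @ 3 Å
  expect_identical(theoretical_voxel_count(0, 3), 0)
  expect_identical(theoretical_voxel_count(7, 7), 4)     # (4/3)*pi ~ 4.19
  expect_error(theoretical_voxel_count(7, 0), "voxel")
  expect_identical(derive_size_gate(7, 3), c(40, 55))    # reference gate
})

test_that("pixel_span rounds the physical diameter to pixels", {
  expect_identical(pixel_span(14, 1.068), 13)
  expect_identical(pixel_span(14, 14), 1)
  expect_identical(pixel_span(50, 3), 17)
})

test_that("component_centroid uses the voxel-center convention", {
  dims <- c(5, 5, 5)
  lin <- function(i, j, k) (k - 1) * 25 + (j - 1) * 5 + i   # 1-based
  # single voxel with 0-based index (1,1,1) -> (4.5, 4.5, 4.5) Å at 3 Å
  expect_equal(component_centroid(lin(2, 2, 2), dims, 3), c(4.5, 4.5, 4.5))
  # symmetric pair -> midpoint
  expect_equal(component_centroid(c(lin(1, 1, 1), lin(3, 1, 1)), dims, 3),
               c(4.5, 1.5, 1.5))
  # 2x2x2 block -> block center
  blk <- as.integer(outer(outer(2:3, (2:3 - 1) * 5, "+"), (2:3 - 1) * 25, "+"))
  expect_equal(component_centroid(blk, dims, 3), c(6, 6, 6))
  # origin shifts the result
  expect_equal(component_centroid(lin(2, 2, 2), dims, 3, origin = c(10, 0, -3)),
               c(14.5, 4.5, 1.5))
})

test_that("resample_block_mean averages factor^3 blocks", {
  arr <- array(seq_len(4 * 4 * 4), c(4, 4, 4))
  v <- volume_grid(arr, 1.5, "density_bright")
  r <- resample_block_mean(v, 2)
  expect_identical(dim(r$data), c(2L, 2L, 2L))
  expect_equal(r$voxel_size, 3)
  expect_equal(r$data[1, 1, 1], mean(arr[1:2, 1:2, 1:2]))
  expect_equal(r$data[2, 2, 2], mean(arr[3:4, 3:4, 3:4]))
  expect_identical(resample_block_mean(v, 1), v)
})

test_that("detect_gold recovers noiseless simulated gold exactly", {
  cfg <- tiny_sim_config(seed = 7, noise_sd = 0, n_particles = 5,
                         n_unbound_gold = 1)
  sim <- simulate_tomogram(cfg)
  det <- detect_gold(sim$volume, tiny_detect_params())
  m <- match_detections(sim$truth$gold_positions, det, tol_A = 3)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_lt(max(m$centroid_err_A), 3)   # within one working voxel

  # a 200-voxel bright blob is gated out as gallium/ice/membrane
  arr <- array(0, c(32, 32, 32))
  arr[10:15, 10:15, 10:15] <- 10       # 216 voxels
  blob <- detect_gold(vol_of(arr), detection_params(slab_width = 1))
  expect_equal(nrow(blob), 0L)
})

test_that("detect_gold is affine-invariant and monotone in k_sd", {
  cfg <- tiny_sim_config(seed = 9, noise_sd = 1, n_particles = 4)
  sim <- simulate_tomogram(cfg)
  p <- tiny_detect_params(noisy = TRUE)
  det <- detect_gold(sim$volume, p)

  scaled <- sim$volume
  scaled$data <- 17 * scaled$data - 120
  det2 <- detect_gold(scaled, p)
  expect_equal(as.data.frame(det), as.data.frame(det2), tolerance = 1e-9)

  n_by_k <- vapply(c(2, 3.3, 5, 8), function(k) {
    pk <- detection_params(k_sd = k, slab_width = p$slab_width,
                           min_voxels = 1, max_voxels = .Machine$integer.max,
                           remove_singletons = FALSE)
    nrow(detect_gold(sim$volume, pk))
  }, numeric(1))
  expect_true(all(diff(n_by_k) <= 0))
})

test_that("detect_gold resamples finer grids to the working pixel size", {
  cfg <- tiny_sim_config(seed = 12, noise_sd = 0, n_particles = 3,
                         n_unbound_gold = 0, dims = c(192, 192, 192),
                         voxel_size = 1.5)
  sim <- simulate_tomogram(cfg)
  # block-mean partial-volume voxels inflate blobs past the binary-raster
  # size, so the gate is widened for resampled input
  p <- detection_params(slab_width = 1, min_voxels = 27, max_voxels = 133)
  det <- detect_gold(sim$volume, p)
  m <- match_detections(sim$truth$gold_positions, det, tol_A = 3)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  # non-integer ratio is rejected
  odd <- volume_grid(sim$volume$data, 1.3, "density_bright")
  expect_error(detect_gold(odd, tiny_detect_params()), "integer factor")
})

test_that("pure-noise volumes yield no detections at k_sd = 3.3", {
  set.seed(2024)
  noise <- vol_of(array(rnorm(64^3, 0, 1), c(64, 64, 64)))
  det <- detect_gold(noise, detection_params(slab_width = 1, min_voxels = 40,
                                             max_voxels = 55))
  expect_equal(nrow(det), 0L)
  # even before the gate, supra-threshold noise is singletons/small pairs
  mask <- high_intensity_mask(normalize_unit_interval(noise), 3.3)
  comps <- remove_singletons(label_components(mask, 26))
  expect_true(all(lengths(comps) < 40))
})
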