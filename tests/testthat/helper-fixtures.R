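# Shared fixtures: small simulated worlds that render and detect in seconds.
# Geometry is shrunk (small particles, short tethers) so boxes stay tiny;
# amplitude ratios keep the realistic ordering noise ~ particle << gold.

tiny_sim_config <- function(seed = 1, noise_sd = 0, n_particles = 5,
                            n_unbound_gold = 1, labeled_fraction = 1,
                            dims = c(112, 112, 112), voxel_size = 3, ...) {
  simulation_config(
    dims = dims, voxel_size = voxel_size,
    n_particles = n_particles, particle_radius = 25,
    particle_amplitude = 1, gold_amplitude = 10,
    tag_offset = c(0, 0, 30),
    labeled_fraction = labeled_fraction,
    tether_mean = 20, tether_sd = 5, tether_max = 40,
    gold_radius = 7, gold_coat_thickness = 5,   # shrunk-scale coat
    n_unbound_gold = n_unbound_gold,
    noise_sd = noise_sd, min_separation = 60, seed = seed, ...)
}

# detection params suited to the tiny worlds: no slab smoothing needed for
# noiseless isotropic volumes; a 3-slice slab plus a widened gate for noisy
# ones (smoothing inflates gold components along z past the 53-voxel
# theoretical size)
tiny_detect_params <- function(noisy = FALSE) {
  v <- theoretical_voxel_count(7, 3)
  if (noisy) {
    detection_params(slab_width = 3, min_voxels = round(0.5 * v),
                     max_voxels = round(3 * v))
  } else {
    detection_params(slab_width = 1, min_voxels = round(0.5 * v),
                     max_voxels = round(1.7 * v))
  }
}

# geometry-only world at realistic ribosome scale and cytoplasmic dilution;
# dims are virtual (never rasterized)
geometry_sim_config <- function(seed, labeled_fraction, n_particles = 500) {
  n_bound <- round(labeled_fraction * n_particles)
  simulation_config(
    dims = c(1500, 1500, 1500), voxel_size = 3,
    n_particles = n_particles, particle_radius = 110,
    tag_offset = c(0, 0, 129),
    labeled_fraction = labeled_fraction,
    tether_mean = 51, tether_sd = 19, tether_max = 100,
    gold_radius = 7,
    n_unbound_gold = round(0.15 / 0.85 * n_bound),  # ~15% of gold unbound
    noise_sd = 0, min_separation = 242, seed = seed)
}

# match detections against truth gold positions: a detection is a true
# positive when within tol_A of some truth gold
match_detections <- function(truth_golds, detections, tol_A = 3) {
  det <- as.matrix(as.data.frame(detections)[, c("x", "y", "z")])
  d_truth <- min_pairwise_distances(truth_golds, det) * 10
  d_det <- min_pairwise_distances(det, truth_golds) * 10
  list(recall = mean(d_truth <= tol_A),
       precision = mean(d_det <= tol_A),
       centroid_err_A = d_truth[d_truth <= tol_A])
}

expect_volume_equal <- function(a, b, tolerance = 1e-6) {
  expect_equal(dim(a$data), dim(b$data))
  expect_equal(a$voxel_size, b$voxel_size, tolerance = tolerance)
  expect_equal(a$data, b$data, tolerance = tolerance, ignore_attr = TRUE)
}
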