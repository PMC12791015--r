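#' Configuration for the synthetic tomogram generator
#'
#' Collects every knob of the simulated world.  Defaults emulate ribosome-scale
#' particles tagged at a surface site 12.9 nm from the center, labeled with
#' 1.4-nm gold through a flexible tether whose tag-to-gold distance is a
#' Gaussian (mean 51 Å, sd 19 Å) truncated to (0, 100 Å] — matching the
#' Gaussian summaries observed for this chemistry and the adopted 10 nm
#' maximum extended tether distance.  Amplitudes reflect gold being far denser
#' than biological material.
#'
#' @param dims volume dimensions in voxels, length 3.
#' @param voxel_size Å per voxel (default 3, the working pixel size of
#'   whole-tomogram detection).
#' @param n_particles number of macromolecules.
#' @param particle_radius macromolecule radius, Å (default 110, 80S ribosome
#'   scale).
#' @param particle_amplitude intensity of particle voxels.
#' @param tag_offset tag-site position in the particle frame, Å (default
#'   `c(0, 0, 129)`).
#' @param labeled_fraction fraction of particles carrying one gold, in
#'   \[0, 1\].
#' @param tether_mean,tether_sd,tether_max tag-to-gold distance distribution:
#'   Gaussian(mean, sd) truncated to `[tether_min, tether_max]`, Å.
#' @param tether_min lower truncation of the tether draw, Å.  Defaults to
#'   `gold_radius + gold_coat_thickness`: the gold *center* can never come
#'   closer to the tag than its own coated radius.
#' @param gold_radius gold sphere radius, Å (7 for 1.4-nm gold; 25 for 5-nm).
#' @param gold_coat_thickness steric shell of the dextran coat around the
#'   gold, Å (default 18, half the ~3.6 nm diameter of 10 kDa dextran); no
#'   macromolecule surface comes closer than this to the gold surface.
#' @param gold_amplitude intensity of gold voxels; must exceed
#'   `particle_amplitude`.
#' @param n_unbound_gold free gold spheres at uniform random positions.
#' @param noise_sd SD of additive white Gaussian noise.
#' @param min_separation minimum center-to-center particle distance, Å.
#' @param seed RNG seed; the full (volume, truth) pair is a deterministic
#'   function of the config including the seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(dims = c(160, 160, 160),
                              voxel_size = 3,
                              n_particles = 10,
                              particle_radius = 110,
                              particle_amplitude = 1,
                              tag_offset = c(0, 0, 129),
                              labeled_fraction = 0.7,
                              tether_mean = 51,
                              tether_sd = 19,
                              tether_max = 100,
                              gold_radius = 7,
                              gold_coat_thickness = 18,
                              tether_min = gold_radius + gold_coat_thickness,
                              gold_amplitude = 5,
                              n_unbound_gold = 2,
                              noise_sd = 0.2,
                              min_separation = 2.2 * particle_radius,
                              seed = 1) {
  cfg <- list(dims = as.integer(dims), voxel_size = voxel_size,
              n_particles = as.integer(n_particles),
              particle_radius = particle_radius,
              particle_amplitude = particle_amplitude,
              tag_offset = as.numeric(tag_offset),
              labeled_fraction = labeled_fraction,
              tether_mean = tether_mean, tether_sd = tether_sd,
              tether_max = tether_max, tether_min = tether_min,
              gold_radius = gold_radius,
              gold_coat_thickness = gold_coat_thickness,
              gold_amplitude = gold_amplitude,
              n_unbound_gold = as.integer(n_unbound_gold),
              noise_sd = noise_sd, min_separation = min_separation,
              seed = as.integer(seed))
  if (length(cfg$dims) != 3L || any(cfg$dims < 1L)) stop("bad dims")
  if (cfg$labeled_fraction < 0 || cfg$labeled_fraction > 1)
    stop("labeled_fraction must be in [0, 1]")
  if (!(cfg$gold_amplitude > cfg$particle_amplitude) ||
      cfg$particle_amplitude <= 0)
    stop("need gold_amplitude > particle_amplitude > 0")
  if (cfg$tether_max <= 0 || cfg$tether_sd < 0 ||
      cfg$tether_min < 0 || cfg$tether_min >= cfg$tether_max)
    stop("bad tether parameters")
  class(cfg) <- "simulation_config"
  cfg
}

#' Draw ground-truth particle/gold geometry (no rasterization)
#'
#' Generates the geometric ground truth of the simulated world: particle
#' centers (uniform, rejection-sampled to `min_separation`, kept far enough
#' from the faces that any tethered gold stays inside), uniform random ZYZ
#' orientations, tag sites at `center + R %*% tag_offset`, one gold per
#' labeled particle at `tag_site + L * u` with `L` from the truncated
#' Gaussian tether distribution and `u` isotropic, and unbound golds at
#' uniform positions.  Exactly `round(labeled_fraction * n_particles)` golds
#' are bound.  Usable on domains far too large to rasterize; rendering is a
#' separate step ([simulate_tomogram()]).
#'
#' @param config a [simulation_config()].
#' @return list of class `simulation_truth`: `particles` (a
#'   [particle_table()]), `tag_sites` (n x 3, Å), `gold_positions` (m x 3, Å),
#'   `bound_flags`, `bound_particle_ids` (NA for unbound gold),
#'   `tether_lengths` (Å, bound golds only), `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  with(config, {
    box <- dims * voxel_size
    margin <- particle_radius +
      (if (labeled_fraction > 0)
         sqrt(sum(tag_offset^2)) + tether_max + gold_radius else 0)
    lo <- rep(margin, 3); hi <- box - margin
    if (any(hi <= lo))
      stop("volume too small for particle_radius + tether margin")

    centers <- matrix(NA_real_, n_particles, 3)
    budget <- 200L * n_particles
    placed <- 0L
    while (placed < n_particles && budget > 0L) {
      p <- lo + stats::runif(3) * (hi - lo)
      ok <- placed == 0L ||
        min(rowSums((centers[seq_len(placed), , drop = FALSE] -
                       matrix(p, placed, 3, byrow = TRUE))^2)) >=
          min_separation^2
      if (ok) { placed <- placed + 1L; centers[placed, ] <- p }
      budget <- budget - 1L
    }
    if (placed < n_particles)
      stop(sprintf(
        "placement failed: %d of %d particles after retry budget; enlarge dims or lower min_separation",
        placed, n_particles))

    # uniform orientations: rot, psi uniform on [0,360), cos(tilt) uniform
    rot <- stats::runif(n_particles, 0, 360)
    tilt <- acos(stats::runif(n_particles, -1, 1)) * 180 / pi
    psi <- stats::runif(n_particles, 0, 360)
    particles <- particle_table(
      data.frame(id = seq_len(n_particles),
                 x = centers[, 1], y = centers[, 2], z = centers[, 3],
                 rot = rot, tilt = tilt, psi = psi),
      pixel_size_of_source = voxel_size,
      provenance = sprintf("simulate_truth(seed=%d)", seed))

    tag_sites <- t(vapply(seq_len(n_particles), function(i) {
      centers[i, ] + as.numeric(
        euler_zyz_matrix(rot[i], tilt[i], psi[i]) %*% tag_offset)
    }, numeric(3)))

    n_bound <- round(labeled_fraction * n_particles)
    bound_ids <- if (n_bound > 0)
      sort(sample.int(n_particles, n_bound)) else integer()
    tether_lengths <- rtruncnorm_interval(n_bound, tether_mean, tether_sd,
                                          tether_min, tether_max)
    # excluded volume: the dextran-coated gold cannot penetrate any
    # particle (the tether cannot thread through a macromolecule and the
    # coat is sterically solid), and gold beads keep 4 radii apart.  Only
    # the direction is redrawn, so the tether-length marginal stays the
    # stated truncated Gaussian.
    clearance <- particle_radius + gold_radius + gold_coat_thickness
    gold_b <- matrix(numeric(), 0, 3)
    if (n_bound > 0) {
      gold_b <- matrix(NA_real_, n_bound, 3)
      for (b in seq_len(n_bound)) {
        pid <- bound_ids[b]
        found <- FALSE
        for (round in 1:50) {
          # in a crowded neighborhood a short tether may have no clear
          # direction at all; redraw the length (still the stated truncated
          # Gaussian) and try again -- conditioning on local feasibility
          if (round > 1)
            tether_lengths[b] <- rtruncnorm_interval(1, tether_mean,
                                                     tether_sd, tether_min,
                                                     tether_max)
          for (try in 1:200) {
            u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
            g <- tag_sites[pid, ] + u * tether_lengths[b]
            clear_particles <-
              min(rowSums(sweep(centers, 2, g)^2)) >= clearance^2
            prev <- gold_b[seq_len(b - 1L), , drop = FALSE]
            clear_gold <- !nrow(prev) ||
              min(rowSums(sweep(prev, 2, g)^2)) >= (4 * gold_radius)^2
            if (clear_particles && clear_gold) { found <- TRUE; break }
          }
          if (found) break
        }
        if (!found)
          stop("tether geometry infeasible for particle ", pid)
        gold_b[b, ] <- g
      }
    }

    gold_u <- matrix(numeric(), 0, 3)
    if (n_unbound_gold > 0) {
      gold_u <- matrix(NA_real_, n_unbound_gold, 3)
      for (b in seq_len(n_unbound_gold)) {
        for (try in 1:1000) {
          g <- gold_radius + stats::runif(3) * (box - 2 * gold_radius)
          far_particles <- !nrow(centers) ||
            min(rowSums(sweep(centers, 2, g)^2)) >= clearance^2
          prev <- rbind(gold_b, gold_u[seq_len(b - 1L), , drop = FALSE])
          far_gold <- !nrow(prev) ||
            min(rowSums(sweep(prev, 2, g)^2)) >= (4 * gold_radius)^2
          if (far_particles && far_gold) break
          if (try == 1000) stop("unbound-gold placement failed")
        }
        gold_u[b, ] <- g
      }
    }

    structure(list(
      particles = particles,
      tag_sites = tag_sites,
      gold_positions = rbind(gold_b, gold_u),
      bound_flags = c(rep(TRUE, n_bound), rep(FALSE, n_unbound_gold)),
      bound_particle_ids = c(bound_ids, rep(NA_integer_, n_unbound_gold)),
      tether_lengths = tether_lengths,
      config = config), class = "simulation_truth")
  })
}

# truncated-Gaussian draw on [lower, upper], by rejection
rtruncnorm_interval <- function(n, mean, sd, lower, upper) {
  if (n == 0) return(numeric())
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Mean of the truncated tether distribution
#'
#' Closed-form mean of a Gaussian(mean, sd) truncated to `[lower, upper]` —
#' the truncation-corrected expectation of drawn tether lengths, used as the
#' reference in distance-recovery checks.
#'
#' @param mean,sd,upper,lower distribution parameters, Å.
#' @return expected tether length, Å.
#' @export
truncated_tether_mean <- function(mean, sd, upper, lower = 0) {
  a <- (lower - mean) / sd; b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' Render a synthetic tomogram with ground truth
#'
#' Draws the geometry with [simulate_truth()] and rasterizes it: particles as
#' solid spheres of `particle_amplitude`, gold as solid spheres of
#' `gold_amplitude` (a voxel belongs to a sphere when its *center* lies
#' within the radius; overlaps keep the maximum amplitude, so gold is never
#' shadowed), plus additive white Gaussian noise.  The result uses the
#' bright-density convention.  Bit-identical output for identical config.
#'
#' @param config a [simulation_config()].
#' @return list with `volume` (a [volume_grid()]) and `truth`
#'   (the [simulate_truth()] result).
#' @export
simulate_tomogram <- function(config) {
  truth <- simulate_truth(config)   # seeds the RNG; noise drawn after
  cfg <- config
  arr <- array(0, cfg$dims)
  pos <- particle_positions(truth$particles)
  for (i in seq_len(nrow(pos)))
    arr <- rasterize_sphere(arr, pos[i, ], cfg$particle_radius,
                            cfg$particle_amplitude, cfg$voxel_size)
  gp <- truth$gold_positions
  for (i in seq_len(nrow(gp)))
    arr <- rasterize_sphere(arr, gp[i, ], cfg$gold_radius,
                            cfg$gold_amplitude, cfg$voxel_size)
  if (cfg$noise_sd > 0)
    arr <- arr + stats::rnorm(length(arr), 0, cfg$noise_sd)
  list(volume = volume_grid(arr, cfg$voxel_size, "density_bright"),
       truth = truth)
}

# set voxels whose centers fall inside the sphere to max(current, amplitude);
# restricted to the sphere's bounding box, clipped at the volume faces
rasterize_sphere <- function(arr, center, radius, amplitude, voxel_size) {
  d <- dim(arr)
  rng <- lapply(1:3, function(ax) {
    i0 <- floor((center[ax] - radius) / voxel_size - 0.5) + 1
    i1 <- ceiling((center[ax] + radius) / voxel_size - 0.5) + 1
    max(1, i0):min(d[ax], i1)
  })
  if (any(lengths(rng) == 0)) return(arr)
  cx <- (rng[[1]] - 0.5) * voxel_size - center[1]
  cy <- (rng[[2]] - 0.5) * voxel_size - center[2]
  cz <- (rng[[3]] - 0.5) * voxel_size - center[3]
  inside <- outer(outer(cx^2, cy^2, "+"), cz^2, "+") <= radius^2
  sub <- arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  sub[inside] <- pmax(sub[inside], amplitude)
  arr[rng[[1]], rng[[2]], rng[[3]]] <- sub
  arr
}

#' Extract subtomogram boxes around particles
#'
#' Cuts an even-sided cube centered on each particle position (the voxel
#' containing the position becomes output voxel `box/2`, 0-based).  Boxes
#' that extend past the volume are padded with the volume mean and flagged
#' with attribute `padded = TRUE`.
#'
#' @param vol a [volume_grid()].
#' @param particles a [particle_table()] (positions in Å).
#' @param box box side in voxels; must be even.
#' @return list of `volume_grid` boxes, voxel size inherited; each carries a
#'   `padded` attribute.
#' @export
extract_subtomograms <- function(vol, particles, box) {
  stopifnot(inherits(vol, "volume_grid"), inherits(particles, "particle_table"))
  if (box %% 2 != 0 || box < 2) stop("box must be even and >= 2")
  d <- dim(vol$data)
  fill <- mean(vol$data)
  pos <- particle_positions(particles)
  half <- box %/% 2
  lapply(seq_len(nrow(pos)), function(i) {
    c0 <- floor((pos[i, ] - vol$origin) / vol$voxel_size)  # 0-based voxel
    lo <- c0 - half + 1       # 1-based start; c0 lands at output index half
    hi <- lo + box - 1
    sub <- array(fill, c(box, box, box))
    slo <- pmax(lo, 1); shi <- pmin(hi, d)
    padded <- any(lo < 1) || any(hi > d)
    if (all(slo <= shi)) {
      sub[(slo[1] - lo[1] + 1):(shi[1] - lo[1] + 1),
          (slo[2] - lo[2] + 1):(shi[2] - lo[2] + 1),
          (slo[3] - lo[3] + 1):(shi[3] - lo[3] + 1)] <-
        vol$data[slo[1]:shi[1], slo[2]:shi[2], slo[3]:shi[3]]
    }
    out <- volume_grid(sub, vol$voxel_size, vol$contrast,
                       origin = vol$origin + (lo - 1) * vol$voxel_size)
    attr(out, "padded") <- padded
    out
  })
}

#' Write simulation truth as CSV
#'
#' One row per gold: `gold_id, x_A, y_A, z_A, bound, bound_particle_id,
#' tether_length_A`.  Companion to the particle table written with
#' [write_particles()].
#'
#' @param truth a [simulate_truth()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  g <- truth$gold_positions
  n_b <- sum(truth$bound_flags)
  df <- data.frame(gold_id = seq_len(nrow(g)),
                   x_A = g[, 1], y_A = g[, 2], z_A = g[, 3],
                   bound = truth$bound_flags,
                   bound_particle_id = truth$bound_particle_ids,
                   tether_length_A = c(truth$tether_lengths,
                                       rep(NA_real_, nrow(g) - n_b)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
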