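#' ZYZ intrinsic rotation matrix
#'
#' Builds the rotation matrix `R = Rz(rot) %*% Ry(tilt) %*% Rz(psi)` for
#' intrinsic ZYZ Euler angles in degrees — the convention used throughout the
#' package for particle orientations (shared with the common
#' subtomogram-averaging STAR dialect).  A vector `v` fixed in the particle
#' frame maps to `R %*% v` in the tomogram frame.
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_zyz_matrix <- function(rot, tilt, psi) {
  stopifnot(is.finite(rot), is.finite(tilt), is.finite(psi))
  d2r <- pi / 180
  rz <- function(a) {
    ca <- cos(a); sa <- sin(a)
    matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    ca <- cos(a); sa <- sin(a)
    matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
  }
  rz(rot * d2r) %*% ry(tilt * d2r) %*% rz(psi * d2r)
}

#' Re-center particle coordinates on the tag site
#'
#' Moves each particle position from the macromolecule center to the position
#' of a site fixed in the particle frame (e.g. the C-terminus of the tagged
#' ribosomal protein L29, 12.9 nm from the ribosome center): each position
#' becomes `position + R(euler) %*% offset`.  Orientations are untouched, and
#' the displacement norm equals `|offset|` for every record (rotations
#' preserve length).
#'
#' @param particles a [particle_table()] with orientations.
#' @param offset length-3 vector, Å, in the particle frame.  Default
#'   `c(0, 0, 129)`: the 12.9 nm center-to-L29 distance placed on the particle
#'   z-axis.
#' @return A `particle_table` with updated positions.
#' @export
recenter_to_tag_site <- function(particles, offset = c(0, 0, 129)) {
  stopifnot(inherits(particles, "particle_table"), length(offset) == 3)
  df <- as.data.frame(particles)
  if (!all(is.finite(as.matrix(df[, c("rot", "tilt", "psi")]))))
    stop("missing or non-finite Euler angles")
  shift <- t(vapply(seq_len(nrow(df)), function(i) {
    as.numeric(euler_zyz_matrix(df$rot[i], df$tilt[i], df$psi[i]) %*% offset)
  }, numeric(3)))
  df$x <- df$x + shift[, 1]
  df$y <- df$y + shift[, 2]
  df$z <- df$z + shift[, 3]
  particle_table(df,
                 pixel_size_of_source = attr(particles, "pixel_size_of_source"),
                 provenance = paste0(attr(particles, "provenance"),
                                     " | re-centered to tag site"))
}

#' Minimum pairwise distances from sites to gold positions
#'
#' For each target site, the minimum Euclidean distance to any gold center —
#' the matrix-minimum statistic that defines the gold-to-target distance
#' distribution.  Inputs are Å; output is nm (conversion at the API boundary
#' only).
#'
#' @param sites n x 3 matrix of tag-site positions, Å.
#' @param golds m x 3 matrix of gold centers, Å.
#' @return numeric vector of length n, nm.
#' @export
min_pairwise_distances <- function(sites, golds) {
  sites <- as_coord_matrix(sites, "sites")
  golds <- as_coord_matrix(golds, "golds")
  if (nrow(golds) == 0L)
    stop("no gold positions: minimum distances are undefined")
  # squared-distance matrix via the expansion |s-g|^2 = |s|^2 + |g|^2 - 2 s.g
  s2 <- rowSums(sites^2)
  g2 <- rowSums(golds^2)
  d2 <- outer(s2, g2, "+") - 2 * tcrossprod(sites, golds)
  sqrt(pmax(apply(d2, 1, min), 0)) / 10
}

as_coord_matrix <- function(x, what) {
  if (inherits(x, "particle_table")) x <- particle_positions(x)
  if (inherits(x, "gold_detections")) x <- as.matrix(x[, c("x", "y", "z")])
  x <- as.matrix(x)
  if (length(x) == 3L) x <- matrix(as.numeric(x), 1, 3)
  if (ncol(x) != 3L) stop(sprintf("`%s` must be an n x 3 matrix (Å)", what))
  if (nrow(x) == 0L) stop(sprintf("`%s` is empty", what))
  storage.mode(x) <- "double"
  x
}

#' Worm-like-chain RMS end-to-end distance
#'
#' Root-mean-square end-to-end distance of a semi-flexible polymer with
#' contour length `L` and persistence length `l_p`:
#' `sqrt(2 l_p L (1 - (l_p/L)(1 - exp(-L/l_p))))`.  Used to bound the reach of
#' the disordered residues tethering the tag site to the label.
#'
#' @param contour contour length L, Å (> 0).
#' @param persistence persistence length l_p, Å (> 0).
#' @return RMS end-to-end distance, Å.
#' @export
wlc_rms_end_to_end <- function(contour, persistence) {
  if (any(contour <= 0) || any(persistence <= 0))
    stop("contour and persistence lengths must be positive")
  L <- contour; lp <- persistence
  sqrt(2 * lp * L * (1 - (lp / L) * (1 - exp(-L / lp))))
}

#' Tether model for the tag-to-gold linker
#'
#' Describes the physical linker between the tagged site and the gold center:
#' disordered residues (worm-like chain), plus rigid contributions from the
#' dextran coat and the covalent ligand.  `max_distance` is the adopted
#' maximum extended tag-to-gold distance used as the bound/unbound cutoff
#' (default 100 Å = 10 nm).
#'
#' @param n_flexible_residues number of disordered residues in the tether.
#' @param contour_per_residue contour length per residue, Å (default 3.8).
#' @param persistence_length persistence length of the disordered chain, Å
#'   (default 4.0, typical for unstructured polypeptide).
#' @param rigid_extension rigid dextran + ligand contribution, Å (default
#'   36 + 22: a 10 kDa dextran of ~3.6 nm diameter plus a ~22 Å ligand).
#' @param max_distance adopted maximum extended distance, Å; default 100.
#' @return A list of class `tether_model`.
#' @export
tether_model <- function(n_flexible_residues = 10,
                         contour_per_residue = 3.8,
                         persistence_length = 4.0,
                         rigid_extension = 36 + 22,
                         max_distance = 100) {
  stopifnot(n_flexible_residues >= 0, contour_per_residue > 0,
            persistence_length > 0, rigid_extension > 0)
  if (!is.null(max_distance)) {
    L <- max(n_flexible_residues * contour_per_residue, 1e-9)
    if (max_distance < wlc_rms_end_to_end(L, persistence_length))
      stop("max_distance below the WLC rms end-to-end distance of the chain")
  }
  structure(list(n_flexible_residues = n_flexible_residues,
                 contour_per_residue = contour_per_residue,
                 persistence_length = persistence_length,
                 rigid_extension = rigid_extension,
                 max_distance = max_distance),
            class = "tether_model")
}

#' Maximum tether distance
#'
#' The adopted `max_distance` of the model if set; otherwise the
#' full-extension bound `n_residues * contour_per_residue + rigid_extension`.
#'
#' @param model a [tether_model()].
#' @return distance in Å.
#' @export
max_tether_distance <- function(model) {
  stopifnot(inherits(model, "tether_model"))
  if (!is.null(model$max_distance)) return(model$max_distance)
  model$n_flexible_residues * model$contour_per_residue + model$rigid_extension
}

#' Classify particles as gold-bound by distance cutoff
#'
#' @param distances vector of minimum gold distances, nm.
#' @param cutoff_nm bound/unbound cutoff, nm (default 10, the adopted maximum
#'   extended tether distance).
#' @return logical vector, `TRUE` = bound (distance <= cutoff).
#' @export
classify_bound <- function(distances, cutoff_nm = 10) {
  stopifnot(is.numeric(distances), length(cutoff_nm) == 1)
  distances <= cutoff_nm
}

#' Labeling efficiency
#'
#' The single-molecule labeling-efficiency statistic:
#' `N_labeled / (N_labeled + N_unlabeled)`.
#'
#' @param n_labeled,n_unlabeled non-negative counts; the sum must be positive.
#' @return A list of class `efficiency_result` with `n_labeled`,
#'   `n_unlabeled` and `efficiency`.
#' @examples
#' labeling_efficiency(9567, 13748 - 9567)$efficiency  # 0.695...
#' @export
labeling_efficiency <- function(n_labeled, n_unlabeled) {
  stopifnot(n_labeled >= 0, n_unlabeled >= 0)
  n <- n_labeled + n_unlabeled
  if (n <= 0) stop("zero denominator: need at least one particle")
  structure(list(n_labeled = as.integer(n_labeled),
                 n_unlabeled = as.integer(n_unlabeled),
                 efficiency = n_labeled / n),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("labeling efficiency %d/%d = %.3f\n",
              x$n_labeled, x$n_labeled + x$n_unlabeled, x$efficiency))
  invisible(x)
}

#' Summary of a minimum-distance distribution
#'
#' Sample mean and SD (n-1 denominator) of the per-particle minimum
#' gold distances, in nm.
#'
#' @param distances numeric vector, nm; length >= 2.
#' @return A list of class `distance_summary`: `per_particle_min_distance`,
#'   `mean`, `sd`, `n`.
#' @export
distance_summary <- function(distances) {
  stopifnot(is.numeric(distances))
  if (length(distances) < 2L)
    stop("need at least two distances for a sample SD")
  structure(list(per_particle_min_distance = distances,
                 mean = mean(distances),
                 sd = stats::sd(distances),
                 n = length(distances)),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("min-distance distribution: mean %.2f nm, sd %.2f nm, n = %d\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Gold-to-target efficiency pipeline
#'
#' Composes the distance geometry into the labeling-efficiency estimate:
#' per-site minimum distance to any gold, bound/unbound classification at the
#' tether cutoff, the efficiency statistic, and the fraction of golds with no
#' tag site within the cutoff (unbound gold).  Assignment is nearest-neighbor
#' without exclusivity; set `exclusive = TRUE` for a greedy one-to-one
#' matching (closest pairs first, each gold used once).
#'
#' @param tag_sites n x 3 matrix or `particle_table`, Å.
#' @param detections m x 3 matrix, `gold_detections` data frame, Å.
#' @param cutoff_nm bound cutoff, nm (default 10).
#' @param exclusive use greedy one-to-one gold-site assignment.
#' @return list with `summary` ([distance_summary()] of bound particles'
#'   distances), `efficiency` ([labeling_efficiency()]),
#'   `unbound_gold_fraction`, and the per-site `distances` (nm) and `bound`
#'   flags.
#' @export
efficiency_pipeline <- function(tag_sites, detections, cutoff_nm = 10,
                                exclusive = FALSE) {
  sites <- as_coord_matrix(tag_sites, "tag_sites")
  golds <- as_coord_matrix(detections, "detections")
  if (exclusive) {
    d_nm <- greedy_min_distances(sites, golds, cutoff_nm)
  } else {
    d_nm <- min_pairwise_distances(sites, golds)
  }
  bound <- classify_bound(d_nm, cutoff_nm)
  eff <- labeling_efficiency(sum(bound), sum(!bound))
  # unbound gold: golds with no site within cutoff
  gold_min <- min_pairwise_distances(golds, sites)
  unbound_gold <- mean(gold_min > cutoff_nm)
  summ <- if (sum(bound) >= 2L) distance_summary(d_nm[bound]) else NULL
  list(summary = summ, efficiency = eff,
       unbound_gold_fraction = unbound_gold,
       distances = d_nm, bound = bound)
}

# greedy one-to-one matching: repeatedly take the globally closest
# (site, gold) pair within cutoff; unmatched sites keep their matrix minimum
greedy_min_distances <- function(sites, golds, cutoff_nm) {
  s2 <- rowSums(sites^2); g2 <- rowSums(golds^2)
  d <- sqrt(pmax(outer(s2, g2, "+") - 2 * tcrossprod(sites, golds), 0)) / 10
  out <- apply(d, 1, min)
  ord <- order(d)
  used_s <- logical(nrow(sites)); used_g <- logical(nrow(golds))
  for (k in ord) {
    if (d[k] > cutoff_nm) break
    i <- (k - 1) %% nrow(sites) + 1
    j <- (k - 1) %/% nrow(sites) + 1
    if (used_s[i] || used_g[j]) next
    used_s[i] <- TRUE; used_g[j] <- TRUE
    out[i] <- d[i, j]
  }
  out[!used_s & out <= cutoff_nm] <- cutoff_nm + 1  # gold taken elsewhere
  out
}
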