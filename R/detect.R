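#' Parameters for whole-tomogram gold detection
#'
#' Defaults correspond to 1.4-nm gold detected on a 3 Å/px grid: intensity
#' threshold at mean + 3.3 SD, 26-connected components, singleton removal,
#' and a voxel-count gate of \[40, 55\] bracketing the 53-voxel theoretical
#' volume of a 7 Å sphere on that grid (components larger than the gate are
#' gallium, ice or membrane; the lower bound absorbs grid-sampling
#' undersampling).  For other gold/grid combinations use
#' [derive_size_gate()].
#'
#' @param k_sd threshold multiplier on the global SD (default 3.3).
#' @param slab_width z-slices in the running-mean window (default 10).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_voxels,max_voxels component-size gate (defaults 40 and 55).
#' @param remove_singletons drop size-1 components before gating (default
#'   TRUE).
#' @param working_pixel_size detection grid, Å (default 3); volumes on a
#'   finer grid are block-mean resampled to it.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(k_sd = 3.3, slab_width = 10, connectivity = 26,
                             min_voxels = 40, max_voxels = 55,
                             remove_singletons = TRUE,
                             working_pixel_size = 3) {
  stopifnot(k_sd > 0, slab_width >= 1,
            connectivity %in% c(6L, 18L, 26L),
            min_voxels >= 1, min_voxels <= max_voxels,
            working_pixel_size > 0)
  structure(list(k_sd = k_sd, slab_width = as.integer(slab_width),
                 connectivity = as.integer(connectivity),
                 min_voxels = as.integer(min_voxels),
                 max_voxels = as.integer(max_voxels),
                 remove_singletons = isTRUE(remove_singletons),
                 working_pixel_size = working_pixel_size),
            class = "detection_params")
}

#' Size gate derived from the theoretical sphere volume
#'
#' For gold/grid combinations other than the 7 Å / 3 Å default, scales the
#' reference \[40, 55\] gate by its ratios to the 53-voxel theoretical count:
#' `[round(0.75 V), round(1.04 V)]` with `V = theoretical_voxel_count(radius,
#' voxel)`.  A declared heuristic, not a measured calibration.
#'
#' @param radius gold radius, Å.
#' @param voxel grid spacing, Å.
#' @return integer vector `c(min_voxels, max_voxels)`.
#' @export
derive_size_gate <- function(radius, voxel) {
  v <- theoretical_voxel_count(radius, voxel)
  c(round(0.75 * v), round(1.04 * v))
}

#' Running-mean slab average along z
#'
#' Averages each z-slice with its neighbors in a centered window of `width`
#' slices (for even widths the extra slice goes above; edge windows shrink).
#' Dimension-preserving, so centroid z-coordinates stay in the source frame —
#' this is the running-mean reading of "averaged over ten slices", not
#' decimation (see [decimate_z()] for that alternative).
#'
#' @param vol a [volume_grid()].
#' @param width window width in slices, `1 <= width <= dim z`.
#' @return a `volume_grid` of identical dimensions.
#' @export
slab_average <- function(vol, width) {
  stopifnot(inherits(vol, "volume_grid"))
  nz <- dim(vol$data)[3]
  if (width < 1 || width > nz)
    stop(sprintf("width must be in [1, %d]", nz))
  width <- as.integer(width)
  if (width == 1L) return(vol)
  lo_off <- (width - 1L) %/% 2L     # slices below the center
  hi_off <- width - 1L - lo_off     # slices above
  # cumulative sum over z of the per-voxel columns
  d <- dim(vol$data)
  flat <- matrix(vol$data, d[1] * d[2], d[3])
  cs <- matrix(0, d[1] * d[2], d[3] + 1L)
  for (z in seq_len(d[3])) cs[, z + 1L] <- cs[, z] + flat[, z]
  out <- matrix(0, d[1] * d[2], d[3])
  for (z in seq_len(d[3])) {
    a <- max(1L, z - lo_off); b <- min(d[3], z + hi_off)
    out[, z] <- (cs[, b + 1] - cs[, a]) / (b - a + 1)
  }
  dim(out) <- d
  volume_grid(out, vol$voxel_size, vol$contrast, vol$origin)
}

#' Decimating z-average
#'
#' Alternative reading of slab averaging: non-overlapping windows of `width`
#' slices collapse to single slices, dividing the z-dimension by `width`.
#' The returned grid keeps the x/y voxel size; z-coordinates of downstream
#' centroids must be multiplied back by `width` to return to the source
#' frame, which is why [detect_gold()] uses [slab_average()] by default.
#'
#' @inheritParams slab_average
#' @return a `volume_grid` with `floor(nz / width)` z-slices.
#' @export
decimate_z <- function(vol, width) {
  stopifnot(inherits(vol, "volume_grid"))
  d <- dim(vol$data)
  if (width < 1 || width > d[3]) stop("bad width")
  width <- as.integer(width)
  nzo <- d[3] %/% width
  a <- vol$data[, , seq_len(nzo * width), drop = FALSE]
  dim(a) <- c(d[1] * d[2], width, nzo)
  out <- apply(a, c(1, 3), mean)
  dim(out) <- c(d[1], d[2], nzo)
  volume_grid(out, vol$voxel_size, vol$contrast, vol$origin)
}

#' Normalize intensities onto \[0, 1\]
#'
#' Affine map of the intensity range onto the unit interval (min to 0, max
#' to 1).  Errors on constant volumes, whose range is degenerate.
#'
#' @param vol a [volume_grid()].
#' @return a `volume_grid` with intensities in \[0, 1\].
#' @export
normalize_unit_interval <- function(vol) {
  stopifnot(inherits(vol, "volume_grid"))
  lo <- min(vol$data); hi <- max(vol$data)
  if (hi <= lo) stop("degenerate range: constant volume cannot be normalized")
  vol$data <- (vol$data - lo) / (hi - lo)
  vol
}

#' Threshold high-intensity voxels
#'
#' Binary mask of voxels whose intensity exceeds `mean + k_sd * SD`, with the
#' mean and (sample) SD computed globally over the whole volume.  Requires
#' bright-density contrast.
#'
#' @param vol a [volume_grid()] with `contrast == "density_bright"`.
#' @param k_sd threshold multiplier.
#' @return logical 3D array.
#' @export
high_intensity_mask <- function(vol, k_sd = 3.3) {
  require_bright(vol, "high_intensity_mask")
  mu <- mean(vol$data)
  sg <- stats::sd(vol$data)
  if (sg == 0) stop("degenerate SD: constant volume")
  vol$data > mu + k_sd * sg
}

#' Label connected components of a binary mask
#'
#' Groups true voxels into maximal connected sets under a 6-, 18- or
#' 26-neighborhood.  Component ids are deterministic: ascending minimum
#' linear (column-major) voxel index.  Works on the sparse set of true
#' voxels, so cost scales with mask size, not volume size.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return list of integer vectors of linear voxel indices, one per
#'   component; empty list for an empty mask.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3,
            connectivity %in% c(6, 18, 26))
  idx <- which(mask)
  if (!length(idx)) return(list())
  d <- dim(mask)
  ai <- arrayInd(idx, d)
  off <- neighbor_offsets(connectivity)
  # union-find over mask voxels
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(off))) {
    ni <- ai[, 1] + off[r, 1]
    nj <- ai[, 2] + off[r, 2]
    nk <- ai[, 3] + off[r, 3]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    if (!any(ok)) next
    nlin <- (nk[ok] - 1) * d[1] * d[2] + (nj[ok] - 1) * d[1] + ni[ok]
    m <- match(nlin, idx)
    hit <- which(!is.na(m))
    src <- which(ok)[hit]
    dst <- m[hit]
    for (t in seq_along(hit)) {
      a <- find(src[t]); b <- find(dst[t])
      if (a != b) parent[a] <- b
    }
  }
  root <- vapply(seq_along(idx), find, integer(1))
  comps <- split(idx, root)
  comps <- unname(comps[order(vapply(comps, min, numeric(1)))])
  lapply(comps, as.integer)
}

# positive-direction half of the neighborhood (the symmetric half suffices
# for pairwise unions)
neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6)  g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  if (connectivity == 18) g <- g[rowSums(abs(g)) <= 2, , drop = FALSE]
  # keep lexicographically positive half
  pos <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  g[pos, , drop = FALSE]
}

#' Drop single-voxel components
#'
#' Unpaired above-threshold voxels are background; remove them.  Order is
#' preserved.
#'
#' @param components list of components from [label_components()].
#' @return filtered list.
#' @export
remove_singletons <- function(components) {
  components[lengths(components) >= 2L]
}

#' Keep components within a voxel-count gate
#'
#' @param components list of components.
#' @param min_voxels,max_voxels inclusive bounds on component size.
#' @return filtered list, order preserved.
#' @export
size_gate <- function(components, min_voxels, max_voxels) {
  stopifnot(min_voxels <= max_voxels)
  n <- lengths(components)
  components[n >= min_voxels & n <= max_voxels]
}

#' Theoretical voxel count of a sphere on a grid
#'
#' The volume-ratio count `round((4/3) pi r^3 / s^3)`: the number of voxels a
#' sphere of radius `r` occupies on a grid of spacing `s`, by volume.  This
#' definition — not a lattice center-in-sphere enumeration, which depends on
#' where the sphere sits on the grid (48-60 voxels for r = 7 Å, s = 3 Å) —
#' gives the reference 53 voxels for 1.4-nm gold on a 3 Å grid that anchors
#' the default size gate.
#'
#' @param radius sphere radius, Å (>= 0).
#' @param voxel grid spacing, Å (> 0).
#' @return integer voxel count.
#' @examples
#' theoretical_voxel_count(7, 3)  # 53
#' @export
theoretical_voxel_count <- function(radius, voxel) {
  if (voxel <= 0) stop("voxel must be > 0")
  if (radius < 0) stop("radius must be >= 0")
  round((4 / 3) * pi * radius^3 / voxel^3)
}

#' Pixels spanned by a physical diameter
#'
#' `round(diameter / pixel)`: e.g. a 14 Å gold moiety spans ~13 pixels at
#' 1.068 Å/px.
#'
#' @param diameter physical extent, Å.
#' @param pixel pixel size, Å.
#' @return integer pixel count.
#' @export
pixel_span <- function(diameter, pixel) {
  stopifnot(diameter >= 0, pixel > 0)
  round(diameter / pixel)
}

#' Centroid of a component in physical coordinates
#'
#' Unweighted mean of the member voxel centers, converted to Å with the
#' voxel-center convention (0-based index i sits at `(i + 0.5) * voxel_size +
#' origin`).
#'
#' @param component integer vector of linear voxel indices.
#' @param dims dimensions of the volume the indices refer to.
#' @param voxel_size Å per voxel.
#' @param origin length-3 origin, Å.
#' @return length-3 position, Å.
#' @export
component_centroid <- function(component, dims, voxel_size,
                               origin = c(0, 0, 0)) {
  ai <- arrayInd(component, dims)     # 1-based
  colMeans((ai - 0.5) * voxel_size) + origin
}

#' Block-mean resampling to a coarser grid
#'
#' Averages `factor^3` blocks of voxels (the integer ratio of target to
#' source voxel size), trimming any remainder.  Used to bring fine
#' reconstructions onto the 3 Å working grid before detection.
#'
#' @param vol a [volume_grid()].
#' @param factor integer downsampling factor per axis.
#' @return a `volume_grid` with voxel size `factor * voxel_size`.
#' @export
resample_block_mean <- function(vol, factor) {
  stopifnot(inherits(vol, "volume_grid"))
  factor <- as.integer(round(factor))
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1L) return(vol)
  d <- dim(vol$data)
  nd <- d %/% factor
  if (any(nd < 1)) stop("volume smaller than one block")
  a <- vol$data[seq_len(nd[1] * factor),
                seq_len(nd[2] * factor),
                seq_len(nd[3] * factor), drop = FALSE]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(factor^3, prod(nd))
  out <- colMeans(a)
  dim(out) <- nd
  volume_grid(out, vol$voxel_size * factor, vol$contrast, vol$origin)
}

#' Whole-tomogram gold detection
#'
#' The full detection chain: (optional) block-mean resampling to the working
#' pixel size, slab averaging along z, normalization to \[0, 1\],
#' thresholding at mean + `k_sd` SD, connected-component labeling, singleton
#' removal, voxel-count gating, and centroid extraction.  One detection per
#' surviving component, ordered by component id (ascending minimum voxel
#' index).  The result is invariant to affine rescaling of the input
#' intensities, and raising `k_sd` never increases the number of detections.
#'
#' @param vol a [volume_grid()] with `contrast == "density_bright"`.
#' @param params a [detection_params()].
#' @return data frame of class `gold_detections` with columns
#'   `component_id`, `x`, `y`, `z` (centroid, Å), `voxel_count`,
#'   `peak_intensity` (on the normalized scale).
#' @export
detect_gold <- function(vol, params = detection_params()) {
  require_bright(vol, "detect_gold")
  stopifnot(inherits(params, "detection_params"))
  if (abs(vol$voxel_size - params$working_pixel_size) >
      1e-6 * params$working_pixel_size) {
    f <- params$working_pixel_size / vol$voxel_size
    if (abs(f - round(f)) > 1e-6)
      stop(sprintf(
        "voxel size %g Å is not an integer factor of the working pixel size %g Å",
        vol$voxel_size, params$working_pixel_size))
    vol <- resample_block_mean(vol, round(f))
  }
  vol <- slab_average(vol, min(params$slab_width, dim(vol$data)[3]))
  vol <- normalize_unit_interval(vol)
  mask <- high_intensity_mask(vol, params$k_sd)
  comps <- label_components(mask, params$connectivity)
  if (params$remove_singletons) comps <- remove_singletons(comps)
  comps <- size_gate(comps, params$min_voxels, params$max_voxels)
  d <- dim(vol$data)
  if (!length(comps)) {
    out <- data.frame(component_id = integer(), x = numeric(),
                      y = numeric(), z = numeric(),
                      voxel_count = integer(), peak_intensity = numeric())
  } else {
    cent <- t(vapply(comps, component_centroid, numeric(3),
                     dims = d, voxel_size = vol$voxel_size,
                     origin = vol$origin))
    out <- data.frame(component_id = seq_along(comps),
                      x = cent[, 1], y = cent[, 2], z = cent[, 3],
                      voxel_count = lengths(comps),
                      peak_intensity = vapply(comps, function(ix)
                        max(vol$data[ix]), numeric(1)))
  }
  class(out) <- c("gold_detections", "data.frame")
  out
}

#' Write detections as CSV
#'
#' Columns `component_id, x_A, y_A, z_A, voxel_count, peak_intensity`.
#'
#' @param detections a [detect_gold()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  stopifnot(inherits(detections, "gold_detections"))
  df <- as.data.frame(detections)
  names(df) <- c("component_id", "x_A", "y_A", "z_A", "voxel_count",
                 "peak_intensity")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read detections from CSV
#' @param path CSV written by [write_detections()].
#' @return a `gold_detections` data frame.
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path)
  need <- c("component_id", "x_A", "y_A", "z_A", "voxel_count",
            "peak_intensity")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  out <- data.frame(component_id = df$component_id,
                    x = df$x_A, y = df$y_A, z = df$z_A,
                    voxel_count = df$voxel_count,
                    peak_intensity = df$peak_intensity)
  class(out) <- c("gold_detections", "data.frame")
  out
}
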