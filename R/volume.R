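#' 3D intensity volume with physical metadata
#'
#' A `volume_grid` is the carrier for tomograms and subtomograms: a 3D numeric
#' array plus the physical voxel size (Å, isotropic), an explicit contrast
#' convention, and a physical origin.  The contrast field records whether dense
#' material maps to high values (`"density_bright"`) or low values
#' (`"density_dark"`, the conventional cryo-EM black-on-white display).  Every
#' intensity-thresholding operation in this package requires
#' `density_bright` input and refuses `density_dark` rather than silently
#' inverting — sign errors are the dominant failure mode in tomogram intensity
#' analysis, so the conversion is always explicit via [invert_contrast()].
#'
#' The voxel with (0-based) index `(i, j, k)` has its *center* at physical
#' position `(i + 0.5, j + 0.5, k + 0.5) * voxel_size + origin` in Å.  All
#' geometry in the package (rasterization, centroids, subtomogram extraction)
#' uses this voxel-center convention.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param voxel_size isotropic voxel size in Å; must be > 0.
#' @param contrast `"density_bright"` or `"density_dark"`.
#' @param origin physical position of the corner of voxel (0,0,0), Å; length-3.
#' @return An object of class `volume_grid`.
#' @examples
#' v <- volume_grid(array(0, c(8, 8, 8)), voxel_size = 3,
#'                  contrast = "density_bright")
#' dim(v$data)
#' @export
volume_grid <- function(data, voxel_size,
                        contrast = c("density_bright", "density_dark"),
                        origin = c(0, 0, 0)) {
  contrast <- match.arg(contrast)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be a single positive finite number (Å)")
  if (any(dim(data) < 1L))
    stop("all three dimensions must be >= 1")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be a finite 3-vector (Å)")
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         contrast = contrast, origin = as.numeric(origin)),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d voxels @ %g Å/voxel, %s\n",
              d[1], d[2], d[3], x$voxel_size, x$contrast))
  cat(sprintf("  intensity range [%g, %g], origin (%g, %g, %g) Å\n",
              min(x$data), max(x$data),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Explicitly flip the contrast convention of a volume
#'
#' Negates the intensities and toggles the `contrast` field, so that density
#' maps to the opposite end of the scale.  This is the only sanctioned way to
#' move between the cryo-EM display convention (`density_dark`) and the
#' analysis convention (`density_bright`) that the detection and randomization
#' operators require.
#'
#' @param vol a [volume_grid()].
#' @return A `volume_grid` with `data = -data` and the opposite contrast label.
#' @export
invert_contrast <- function(vol) {
  stopifnot(inherits(vol, "volume_grid"))
  vol$data <- -vol$data
  vol$contrast <- if (vol$contrast == "density_bright") "density_dark"
                  else "density_bright"
  vol
}

# internal: fail unless the volume is density_bright
require_bright <- function(vol, what) {
  if (!inherits(vol, "volume_grid")) stop("expected a volume_grid")
  if (vol$contrast != "density_bright")
    stop(sprintf(paste0(
      "%s requires contrast == \"density_bright\" (dense objects = high ",
      "values); got \"density_dark\". Convert explicitly with ",
      "invert_contrast()."), what))
  invisible(vol)
}

# internal: physical coordinates (Å) of voxel centers along one axis
voxel_centers <- function(n, voxel_size, origin1) {
  (seq_len(n) - 0.5) * voxel_size + origin1
}
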