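#' Molecule count from molar concentration and volume
#'
#' Avogadro's number times moles: `6.02214076e23 * molar * volume`.
#'
#' @param molar concentration, mol/L.
#' @param volume sample volume, L.
#' @return molecule count (numeric; exact for the given inputs).
#' @export
molecules_from_concentration <- function(molar, volume) {
  stopifnot(molar >= 0, volume >= 0)
  6.02214076e23 * molar * volume
}

#' Fit a fluorescence calibration line
#'
#' Ordinary least squares of intensity on molecule count, from a dilution
#' series of the fluorescent nanogold probe.
#'
#' @param molecules abscissae: molecule counts (>= 2 distinct values).
#' @param intensity ordinates: fluorescence intensities.
#' @return list of class `calibration_curve`: `slope` (intensity per
#'   molecule), `intercept`, `r_squared`.
#' @export
fit_calibration <- function(molecules, intensity) {
  stopifnot(length(molecules) == length(intensity), length(molecules) >= 2)
  if (length(unique(molecules)) < 2)
    stop("need at least 2 distinct molecule counts to fit a line")
  fit <- stats::lm(intensity ~ molecules)
  ss_tot <- sum((intensity - mean(intensity))^2)
  r2 <- if (ss_tot == 0) 1
        else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "calibration_curve")
}

#' Invert a calibration curve to molecules per cell
#'
#' Subtracts the background fluorescence of probe-free cells, inverts the
#' linear calibration, and normalizes by the cell count.  Negative estimates
#' (measured below background + intercept) are reported as 0 with a warning —
#' molecule counts are non-negative.
#'
#' @param curve a [fit_calibration()] result.
#' @param measured_intensity bulk fluorescence of the treated cells.
#' @param background fluorescence of probe-free cells.
#' @param n_cells number of cells in the measured sample (>= 1).
#' @return molecules per cell.
#' @export
invert_calibration <- function(curve, measured_intensity, background = 0,
                               n_cells = 1) {
  stopifnot(inherits(curve, "calibration_curve"), n_cells >= 1)
  if (curve$slope == 0) stop("zero slope: calibration cannot be inverted")
  est <- ((measured_intensity - background) - curve$intercept) /
    curve$slope / n_cells
  if (est < 0) {
    warning("negative molecule estimate clipped to 0")
    est <- 0
  }
  est
}

#' Extrapolate a subvolume count to a whole cell
#'
#' `count * cell_volume / subvolume`, the proportionality used to scale
#' particle counts from an imaged subvolume to a full cell volume.
#'
#' @param count_in_subvolume particles counted in the imaged subvolume.
#' @param subvolume imaged volume, um^3 (> 0).
#' @param cell_volume whole-cell volume, um^3 (> 0).
#' @return estimated count per cell.
#' @export
extrapolate_copies <- function(count_in_subvolume, subvolume, cell_volume) {
  stopifnot(subvolume > 0, cell_volume > 0, count_in_subvolume >= 0)
  count_in_subvolume * cell_volume / subvolume
}

#' Per-group size statistics with a separability flag
#'
#' Sample mean, SD and n of particle diameters per group (e.g. nominal
#' 1.4-nm vs 5-nm gold), plus a separability flag for a pair of groups:
#' distributions are declared separable when the mean gap exceeds twice the
#' sum of the SDs, `|mu1 - mu2| > 2 (s1 + s2)` — a conservative reading of
#' "clearly separated" for multiplexed label sizes.
#'
#' @param diameters numeric vector, nm.
#' @param groups group labels, same length.
#' @return list with `stats` (data frame: group, mean, sd, n) and
#'   `separable` (logical for exactly 2 groups, `NA` otherwise).
#' @export
size_distribution_stats <- function(diameters, groups) {
  stopifnot(length(diameters) == length(groups))
  sp <- split(diameters, groups)
  st <- data.frame(group = names(sp),
                   mean = vapply(sp, mean, numeric(1)),
                   sd = vapply(sp, stats::sd, numeric(1)),
                   n = lengths(sp), row.names = NULL)
  separable <- if (nrow(st) == 2) {
    abs(st$mean[1] - st$mean[2]) > 2 * (st$sd[1] + st$sd[2])
  } else NA
  list(stats = st, separable = separable)
}
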