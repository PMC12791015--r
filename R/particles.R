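#' Particle table: positions and orientations of picked macromolecules
#'
#' A `particle_table` is a data frame with one row per picked particle and
#' columns `id` (unique integer), `x`, `y`, `z` (position in Å — the particle
#' center, or the tag site after [recenter_to_tag_site()]) and `rot`, `tilt`,
#' `psi` (ZYZ intrinsic Euler angles, degrees).  The pixel size of the source
#' coordinate file and a free-text provenance string travel as attributes.
#'
#' @param df data frame with columns `id, x, y, z, rot, tilt, psi` (Å and
#'   degrees).  `id` may be omitted; sequential ids are assigned.
#' @param pixel_size_of_source pixel size (Å) of the file the coordinates came
#'   from; 1 for tables born in Å.
#' @param provenance free-text description of where the table came from.
#' @return A data frame of class `particle_table`.
#' @export
particle_table <- function(df, pixel_size_of_source = 1,
                           provenance = "constructed in R") {
  need <- c("x", "y", "z", "rot", "tilt", "psi")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0L) stop("no particles: table must be non-empty")
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  df <- df[, c("id", need)]
  for (cl in names(df))
    if (!is.numeric(df[[cl]])) stop("non-numeric column: ", cl)
  if (anyDuplicated(df$id)) stop("particle ids must be unique")
  if (!all(is.finite(as.matrix(df[, c("rot", "tilt", "psi")]))))
    stop("non-finite Euler angles")
  structure(df,
            pixel_size_of_source = pixel_size_of_source,
            provenance = provenance,
            class = c("particle_table", "data.frame"))
}

#' Positions of a particle table as an n x 3 matrix (Å)
#' @param particles a [particle_table()].
#' @return numeric matrix with columns x, y, z.
#' @export
particle_positions <- function(particles) {
  as.matrix(as.data.frame(particles)[, c("x", "y", "z")])
}

#' Read a particle table from STAR or CSV
#'
#' Two dialects are supported.  `csv`: columns
#' `id,x_A,y_A,z_A,rot_deg,tilt_deg,psi_deg`, coordinates already in Å.
#' `star`: a particle loop with `_rlnCoordinateX/Y/Z` in *pixels* of the
#' declared `pixel_size` plus `_rlnAngleRot/Tilt/Psi` in degrees (the common
#' subtomogram-averaging dialect); coordinates are converted to Å on read.
#' Angles are ZYZ intrinsic in both dialects.
#'
#' @param path input file.
#' @param dialect `"star"` or `"csv"`.
#' @param pixel_size Å per pixel of the STAR coordinates (required for
#'   `"star"`, ignored for `"csv"`).
#' @return A [particle_table()].
#' @export
read_particles <- function(path, dialect = c("csv", "star"), pixel_size = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (dialect == "csv") {
    df <- utils::read.csv(path)
    need <- c("x_A", "y_A", "z_A", "rot_deg", "tilt_deg", "psi_deg")
    if (!all(need %in% names(df)))
      stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
    if (nrow(df) == 0L) stop("no particles in ", path)
    out <- data.frame(x = df$x_A, y = df$y_A, z = df$z_A,
                      rot = df$rot_deg, tilt = df$tilt_deg, psi = df$psi_deg)
    if ("id" %in% names(df)) out$id <- df$id
    particle_table(out, pixel_size_of_source = 1,
                   provenance = paste("csv:", path))
  } else {
    if (is.null(pixel_size) || pixel_size <= 0)
      stop("`pixel_size` (Å/px) is required for STAR input")
    loop <- read_star_loop(path)
    cmap <- c(x = "rlnCoordinateX", y = "rlnCoordinateY", z = "rlnCoordinateZ",
              rot = "rlnAngleRot", tilt = "rlnAngleTilt", psi = "rlnAnglePsi")
    miss <- cmap[!cmap %in% names(loop)]
    if (length(miss))
      stop("missing STAR columns: ", paste0("_", miss, collapse = ", "))
    if (nrow(loop) == 0L) stop("no particles in ", path)
    out <- data.frame(
      x = loop$rlnCoordinateX * pixel_size,
      y = loop$rlnCoordinateY * pixel_size,
      z = loop$rlnCoordinateZ * pixel_size,
      rot = loop$rlnAngleRot, tilt = loop$rlnAngleTilt, psi = loop$rlnAnglePsi)
    particle_table(out, pixel_size_of_source = pixel_size,
                   provenance = paste("star:", path))
  }
}

#' Write a particle table to STAR or CSV
#'
#' Inverse of [read_particles()]: the CSV dialect writes Å directly; the STAR
#' dialect divides coordinates by `pixel_size` to emit pixels, and documents
#' the ZYZ intrinsic angle convention in a comment line.  Round-trips to the
#' written precision (6 decimals).
#'
#' @inheritParams read_particles
#' @param particles a [particle_table()].
#' @return `path`, invisibly.
#' @export
write_particles <- function(particles, path, dialect = c("csv", "star"),
                            pixel_size = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(particles, "particle_table"))
  df <- as.data.frame(particles)
  if (dialect == "csv") {
    out <- data.frame(id = df$id,
                      x_A = df$x, y_A = df$y, z_A = df$z,
                      rot_deg = df$rot, tilt_deg = df$tilt, psi_deg = df$psi)
    utils::write.csv(format(out, digits = 12, trim = TRUE), path,
                     row.names = FALSE, quote = FALSE)
  } else {
    if (is.null(pixel_size) || pixel_size <= 0)
      stop("`pixel_size` (Å/px) is required for STAR output")
    tags <- c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
              "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi")
    m <- cbind(df$x, df$y, df$z, df$rot, df$tilt, df$psi)
    m[, 1:3] <- m[, 1:3] / pixel_size
    lines <- c(
      "# ZYZ intrinsic Euler angles (rot, tilt, psi), degrees;",
      sprintf("# coordinates in pixels of %g A/px", pixel_size),
      "", "data_particles", "", "loop_",
      sprintf("_%s #%d", tags, seq_along(tags)),
      apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")))
    writeLines(lines, path)
  }
  invisible(path)
}

# internal: minimal STAR loop reader (first loop_ block in the file)
read_star_loop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[!startsWith(lines, "#")]
  li <- which(lines == "loop_")
  if (!length(li)) stop("no loop_ block in STAR file")
  i <- li[1] + 1L
  tags <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tags <- c(tags, sub("^_", "", sub("\\s+#\\d+$", "", lines[i])))
    i <- i + 1L
  }
  rows <- character()
  while (i <= length(lines) && nzchar(lines[i]) &&
         !startsWith(lines[i], "data_")) {
    rows <- c(rows, lines[i]); i <- i + 1L
  }
  if (!length(rows)) return(stats::setNames(
    as.data.frame(matrix(numeric(), 0, length(tags))), tags))
  m <- do.call(rbind, strsplit(rows, "\\s+"))
  if (ncol(m) != length(tags)) stop("malformed STAR loop: column mismatch")
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- tags
  for (cl in names(df)) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (!anyNA(v)) df[[cl]] <- v
  }
  bad <- vapply(df, function(v) !is.numeric(v), logical(1))
  if (any(bad)) stop("non-numeric fields in STAR columns: ",
                     paste(names(df)[bad], collapse = ", "))
  df
}
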