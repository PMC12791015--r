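#' Read an MRC2014 volume
#'
#' Minimal reader for the MRC2014 single-volume format (modes 0, 1 and 2;
#' little-endian).  The voxel size is taken from the header cell dimensions
#' divided by the sampling (`CELLA / M`), and must be isotropic: volumes with
#' unequal voxel sizes along the three axes are rejected, because every
#' downstream operator assumes an isotropic grid.
#'
#' @param path path to an existing `.mrc` file.
#' @param contrast contrast convention to record on the returned volume.
#'   Defaults to `"density_dark"`, the convention of raw cryo-EM
#'   reconstructions (dense material = dark); override for maps already in
#'   bright-density form.
#' @return A [volume_grid()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, contrast = c("density_dark", "density_bright")) {
  contrast <- match.arg(contrast)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))

  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_raw <- readBin(con, "raw", n = 1024)

  machst <- hdr_raw[213:216]  # word 54
  if (!(machst[1] %in% as.raw(c(0x44, 0x00)))) {
    # 0x44 = little-endian stamp; 0x00 tolerated (some writers omit MACHST)
    stop("unsupported MRC byte order (big-endian MACHST stamp)")
  }
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  m <- hdr_int[8:10]
  cella <- hdr_num[11:13]
  origin <- hdr_num[50:52]
  if (any(c(nx, ny, nz) < 1) || any(m < 1))
    stop("corrupt MRC header: non-positive dimensions")

  vs <- cella / m
  if (any(vs <= 0)) vs <- c(1, 1, 1)  # headers with zero cell: unit voxels
  if (max(vs) - min(vs) > 1e-4 * max(vs))
    stop(sprintf(
      "anisotropic voxel size (%.4g, %.4g, %.4g) Å: only isotropic grids are supported",
      vs[1], vs[2], vs[3]))

  nvox <- as.numeric(nx) * ny * nz
  seek(con, 1024 + hdr_int[24])  # skip extended header (NSYMBT bytes)
  dat <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1,
                             signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    stop(sprintf("unsupported MRC mode %d (supported: 0, 1, 2)", mode))
  )
  if (length(dat) != nvox) stop("truncated MRC data block")
  dim(dat) <- c(nx, ny, nz)  # MRC fast axis = x, matching R column-major
  volume_grid(dat, voxel_size = vs[1], contrast = contrast, origin = origin)
}

#' Write a volume as MRC2014
#'
#' Writes 32-bit float (mode 2) MRC2014 with the voxel size encoded in the
#' cell dimensions and the origin in the ORIGIN header words.  Round-trips
#' bit-exactly with [read_volume()] at float32 precision.
#'
#' @param vol a [volume_grid()] with finite data.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  if (!all(is.finite(vol$data)))
    stop("non-finite values in volume data; refusing to write")
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))

  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")

  wi(c(d, 2L))                  # NX NY NZ MODE
  wi(c(0L, 0L, 0L))             # NXSTART..
  wi(d)                         # MX MY MZ
  wf(d * vol$voxel_size)        # CELLA (Å)
  wf(c(90, 90, 90))             # CELLB
  wi(c(1L, 2L, 3L))             # MAPC MAPR MAPS
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))  # DMIN DMAX DMEAN
  wi(c(1L, 0L))                 # ISPG NSYMBT
  wi(rep(0L, 3))                # EXTRA words 25-27 (EXTTYP blank)
  wi(20140L)                    # NVERSION
  wi(rep(0L, 21))               # EXTRA words 29-49
  wf(vol$origin)                # ORIGIN (Å)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(vol$data))       # RMS
  wi(1L)                        # NLABL
  lab <- charToRaw(format("tomogold volume", width = 80))
  writeBin(lab, con)
  writeBin(raw(800 - length(lab)), con)
  wf(vol$data)
  invisible(path)
}
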