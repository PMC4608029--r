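# Density volumes and MRC input/output.
#
# Coordinate convention, used everywhere in the package: a volume is a 3D
# array indexed [i, j, k] (R's 1-based indexing); the centre of voxel
# (i, j, k) sits at  origin + (c(i, j, k) - 1) * voxel_size  in Angstroms,
# with isotropic voxel_size. The first array index is x, the second y, the
# third z.

#' Create a density volume
#'
#' A `density_volume` is a 3D scalar grid with an isotropic voxel size and a
#' physical origin, holding synthetic or experimental cryo-ET density.
#'
#' @param data A 3D numeric array.
#' @param voxel_size Voxel edge length in Angstroms (> 0).
#' @param origin Physical position (Angstroms) of the centre of voxel
#'   `[1, 1, 1]`; length-3 numeric.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("`data` must be a 3D array")
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0) {
    stop("`voxel_size` must be a single positive number")
  }
  if (length(origin) != 3 || any(!is.finite(origin))) {
    stop("`origin` must be a finite length-3 numeric")
  }
  if (any(!is.finite(data))) stop("volume values must be finite")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_volume")
}

#' @export
dim.density_volume <- function(x) dim(x$data)

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_volume> %d x %d x %d voxels @ %.3f A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  origin: (%.1f, %.1f, %.1f) A   range: [%.3g, %.3g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Interpolate density at physical positions
#'
#' Trilinear interpolation of a density volume at arbitrary points given in
#' Angstroms. Points outside the grid yield `NA`.
#'
#' @param volume A [density_volume].
#' @param points Data frame with x/y/z columns or n x 3 matrix of positions
#'   in Angstroms.
#' @return Numeric vector of interpolated densities.
#' @export
interp_density <- function(volume, points) {
  stopifnot(inherits(volume, "density_volume"))
  p <- as_points_matrix(points)
  idx <- sweep(p, 2, volume$origin, "-") / volume$voxel_size
  # pass the array directly: Rcpp wraps it without copying
  cpp_trilinear(volume$data, dim(volume$data), idx)
}

# like as_curve_matrix but without the >= 3 vertex requirement
as_points_matrix <- function(points) {
  if (is.matrix(points)) m <- points
  else m <- cbind(points$x, points$y, points$z)
  storage.mode(m) <- "double"
  m
}

# physical coordinates of every voxel centre along one axis
axis_coords <- function(volume, axis) {
  volume$origin[axis] + (seq_len(dim(volume$data)[axis]) - 1) * volume$voxel_size
}

# ---------------------------------------------------------------------------
# MRC (MRC2014) mode-2 input/output. Minimal, little-endian, single volume.
# Voxel size is carried in the cell dimensions (CELLA / MX etc.); the
# physical origin in the ORIGIN words (49-51, 0-based) of the header.

#' Read an MRC density map (mode 2, 32-bit float)
#'
#' @param path Path to an MRC file.
#' @return A [density_volume]. Axis order follows the file's column/row/
#'   section order, which this writer always emits as x, y, z.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024) stop("corrupt MRC header: file shorter than 1024 bytes")
  ints <- readBin(hdr_raw, "integer", n = 256, size = 4, endian = "little")
  flts <- readBin(hdr_raw, "double", n = 256, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]
  mode <- ints[4]
  if (mode != 2) stop(sprintf("unsupported MRC mode %d (only mode 2 float32)", mode))
  if (any(c(nx, ny, nz) < 1) || any(c(nx, ny, nz) > 1e5)) {
    stop("corrupt MRC header: implausible dimensions")
  }
  mx <- ints[8]; my <- ints[9]; mz <- ints[10]
  cella <- flts[11:13]
  vx <- cella / c(mx, my, mz)
  if (any(!is.finite(vx)) || any(vx <= 0)) {
    stop("corrupt MRC header: non-positive voxel size")
  }
  if (max(vx) - min(vx) > 1e-4 * max(vx)) {
    stop("anisotropic voxel sizes are not supported")
  }
  origin <- flts[50:52]
  nvox <- as.double(nx) * ny * nz
  dat <- readBin(con, "double", n = nvox, size = 4, endian = "little")
  if (length(dat) < nvox) {
    stop(sprintf("truncated MRC file: expected %.0f voxels, read %d", nvox,
                 length(dat)))
  }
  density_volume(array(dat, dim = c(nx, ny, nz)), voxel_size = mean(vx),
                 origin = origin)
}

#' Write a density volume as MRC (mode 2)
#'
#' Round-trips with [read_mrc()]: grid values are preserved to float32
#' precision bit-exactly, voxel size and origin to float precision.
#'
#' @param volume A [density_volume].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(volume, path) {
  stopifnot(inherits(volume, "density_volume"))
  d <- dim(volume$data)
  ints <- integer(256)
  flts <- numeric(256)
  ints[1:3] <- d
  ints[4] <- 2L
  ints[5:7] <- 0L                       # nxstart/nystart/nzstart
  ints[8:10] <- d                       # mx/my/mz
  flts[11:13] <- d * volume$voxel_size  # cell dimensions (A)
  flts[14:16] <- 90                     # cell angles
  ints[17:19] <- 1:3                    # axis order: columns=x, rows=y, sections=z
  flts[20] <- min(volume$data)
  flts[21] <- max(volume$data)
  flts[22] <- mean(volume$data)
  ints[23] <- 1L                        # ISPG = 1: 3D volume
  ints[24] <- 0L                        # no extended header
  flts[50:52] <- volume$origin
  flts[55] <- stats::sd(as.numeric(volume$data))

  hdr <- raw(1024)
  for (w in seq_len(256)) {
    bytes <- if (w %in% c(11:16, 20:22, 50:52, 55)) {
      writeBin(flts[w], raw(), size = 4, endian = "little")
    } else {
      writeBin(ints[w], raw(), size = 4, endian = "little")
    }
    hdr[(4 * (w - 1) + 1):(4 * w)] <- bytes
  }
  hdr[209:212] <- as.raw(c(0x4d, 0x41, 0x50, 0x20))  # "MAP " (word 53)
  hdr[213:216] <- as.raw(c(0x44, 0x44, 0x00, 0x00))  # little-endian stamp

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.numeric(volume$data), con, size = 4, endian = "little")
  invisible(path)
}
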