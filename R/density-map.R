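#' Density map object
#'
#' A 3D scalar grid with an isotropic voxel size (Angstrom) and an origin:
#' the Angstrom offset of the centre of voxel (0,0,0). Grids are stored as
#' numeric arrays with `dim = c(nx, ny, nz)`, x fastest. Protein and
#' membrane density is negative ("dark"), background near zero.
#'
#' @param grid numeric 3D array, at least 2 voxels along each axis, all
#'   values finite.
#' @param voxel_size voxel edge length in Angstrom, > 0.
#' @param origin numeric length-3, Angstrom position of the centre of voxel
#'   (0,0,0).
#' @return an object of class `density_map`.
#' @export
#' @examples
#' m <- density_map(array(0, c(4, 4, 4)), voxel_size = 3.8)
#' dim(m$grid)
density_map <- function(grid, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(grid) || length(dim(grid)) != 3)
    abort("`grid` must be a 3D array")
  if (any(dim(grid) < 2)) abort("`grid` must have at least 2 voxels per axis")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    abort("`voxel_size` must be a single positive number (Angstrom)")
  if (length(origin) != 3 || any(!is.finite(origin)))
    abort("`origin` must be a finite length-3 vector (Angstrom)")
  if (any(!is.finite(grid))) abort("`grid` contains non-finite values")
  storage.mode(grid) <- "double"
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_map> %d x %d x %d voxels, %.3f A/voxel, origin (%g, %g, %g) A\n",
              d[1], d[2], d[3], x$voxel_size, x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$grid), max(x$grid), mean(x$grid)))
  invisible(x)
}

is_density_map <- function(x) inherits(x, "density_map")

#' Convert between Angstrom positions and voxel coordinates
#'
#' A position `p` (Angstrom) corresponds to the continuous 0-based voxel
#' coordinate `(p - origin) / voxel_size`; voxel index `i` has its centre at
#' `i * voxel_size + origin`.
#'
#' @param map a [density_map()].
#' @param pos matrix (n x 3) or length-3 vector of Angstrom positions.
#' @return matrix of continuous 0-based voxel coordinates.
#' @export
map_to_voxel <- function(map, pos) {
  pos <- rbind_pos(pos)
  sweep(pos, 2, map$origin) / map$voxel_size
}

#' @rdname map_to_voxel
#' @param vox matrix (n x 3) of 0-based voxel coordinates.
#' @export
voxel_to_map <- function(map, vox) {
  vox <- rbind_pos(vox)
  sweep(vox * map$voxel_size, 2, map$origin, `+`)
}

rbind_pos <- function(pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  if (ncol(pos) != 3) abort("positions must have 3 columns")
  storage.mode(pos) <- "double"
  pos
}

# ---- MRC 2014 I/O -----------------------------------------------------------

#' Read an MRC density map
#'
#' Reads MRC/MRC2014 files of mode 0 (int8), 1 (int16) or 2 (float32).
#' The voxel size is taken from the cell dimensions divided by the grid
#' sampling, the origin from the ORIGIN header words. Only isotropic voxel
#' sizes are supported (tolerance 1e-3 A).
#'
#' @param path file path.
#' @return a [density_map()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024) abort("MRC format error: truncated header")
  endian <- "little"
  machst <- as.integer(hdr_raw[213:214])
  if (machst[1] == 0x11) endian <- "big"
  int_at <- function(w) readBin(hdr_raw[(4 * (w - 1) + 1):(4 * w)], "integer",
                                size = 4, endian = endian)
  flt_at <- function(w) readBin(hdr_raw[(4 * (w - 1) + 1):(4 * w)], "numeric",
                                size = 4, endian = endian)
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  mx <- int_at(8); my <- int_at(9); mz <- int_at(10)
  cella <- c(flt_at(11), flt_at(12), flt_at(13))
  nsymbt <- int_at(24)
  origin <- c(flt_at(50), flt_at(51), flt_at(52))
  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 1e5))
    abort(sprintf("MRC format error: bad dimensions NX/NY/NZ = %d/%d/%d", nx, ny, nz))
  if (!mode %in% c(0L, 1L, 2L))
    abort(sprintf("MRC format error: unsupported MODE = %d (modes 0/1/2 supported)", mode))
  if (mx <= 0 || my <= 0 || mz <= 0)
    abort("MRC format error: non-positive sampling MX/MY/MZ")
  vs <- cella / c(mx, my, mz)
  if (any(vs <= 0)) abort("MRC format error: non-positive CELLA voxel size")
  if (max(vs) - min(vs) > 1e-3)
    abort("MRC format error: anisotropic voxel size not supported")
  if (nsymbt > 0) {
    skip <- readBin(con, "raw", n = nsymbt)
    if (length(skip) < nsymbt) abort("MRC format error: truncated extended header")
  }
  n <- as.double(nx) * ny * nz
  sz <- c(`0` = 1L, `1` = 2L, `2` = 4L)[as.character(mode)]
  what <- if (mode == 2L) "numeric" else "integer"
  data <- readBin(con, what, n = n, size = sz, endian = endian,
                  signed = TRUE)
  if (length(data) < n) abort("MRC format error: truncated data block")
  grid <- array(as.double(data), dim = c(nx, ny, nz))
  density_map(grid, voxel_size = mean(vs), origin = origin)
}

#' Write a density map as MRC mode 2
#'
#' Writes little-endian MRC2014, mode 2 (float32), with the voxel size
#' recorded through the cell dimensions and the origin in the ORIGIN words.
#'
#' @param map a [density_map()]; refuses to write non-finite values.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  if (!is_density_map(map)) abort("`map` must be a density_map")
  if (any(!is.finite(map$grid))) abort("refusing to write non-finite map values")
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                  # NX NY NZ
  wi(2L)                                 # MODE
  wi(c(0L, 0L, 0L))                      # NXSTART..
  wi(d)                                  # MX MY MZ
  wf(d * map$voxel_size)                 # CELLA
  wf(c(90, 90, 90))                      # CELLB
  wi(c(1L, 2L, 3L))                      # MAPC MAPR MAPS
  wf(c(min(map$grid), max(map$grid), mean(map$grid)))  # DMIN DMAX DMEAN
  wi(c(0L, 0L))                          # ISPG NSYMBT
  wi(rep(0L, 25))                        # EXTRA (words 26-50 start at 25 here)
  # words 50-52 are ORIGIN: we have written 49 words so far
  wf(map$origin)                         # ORIGIN x y z
  writeBin(charToRaw("MAP "), con)       # word 53
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(map$grid))                       # RMS
  wi(1L)                                 # NLABL
  lab <- sprintf("%-80s", "subtomo density map")
  writeBin(charToRaw(lab), con)
  writeBin(raw(800 - 80), con)
  writeBin(as.numeric(map$grid), con, size = 4, endian = "little")
  invisible(path)
}
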