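#' Particle table
#'
#' The motive-list analogue threading picking, alignment, averaging and the
#' geometry statistics: one row per particle with its position (Angstrom),
#' orientation (intrinsic Z-Y-Z Euler angles, degrees, template frame into
#' tomogram frame), cross-correlation score and class label. `cc` and
#' `class` may be `NA` ("unset") until the relevant stage has run.
#'
#' @param x a data frame with columns `x`, `y`, `z` and optionally `id`,
#'   `phi`, `theta`, `psi`, `cc`, `class`. Missing orientation columns
#'   default to 0; missing `id` to the row number.
#' @return a tibble with class `particle_table` and the canonical column
#'   set `id, x, y, z, phi, theta, psi, cc, class`, Euler angles
#'   normalized to canonical ranges.
#' @export
#' @examples
#' particle_table(data.frame(x = 0, y = 0, z = 100, theta = 370))
particle_table <- function(x) {
  x <- as_tibble(x)
  need <- c("x", "y", "z")
  miss <- setdiff(need, names(x))
  if (length(miss))
    abort(paste0("particle table lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  n <- nrow(x)
  if (!"id" %in% names(x)) x$id <- seq_len(n)
  for (col in c("phi", "theta", "psi")) if (!col %in% names(x)) x[[col]] <- 0
  if (!"cc" %in% names(x)) x$cc <- NA_real_
  if (!"class" %in% names(x)) x$class <- NA_integer_
  if (anyDuplicated(x$id)) abort("particle ids must be unique")
  if (n && any(!is.finite(as.matrix(x[, c("x", "y", "z")]))))
    abort("particle positions must be finite")
  if (n) {
    eul <- normalize_euler(x$phi, x$theta, x$psi)
    x$phi <- eul[, "phi"]; x$theta <- eul[, "theta"]; x$psi <- eul[, "psi"]
    bad <- !is.na(x$cc) & (x$cc < -1 - 1e-9 | x$cc > 1 + 1e-9)
    if (any(bad)) abort("cc scores must lie in [-1, 1]")
  }
  out <- x[, c("id", "x", "y", "z", "phi", "theta", "psi", "cc", "class")]
  out$id <- as.integer(out$id)
  out$class <- as.integer(out$class)
  class(out) <- c("particle_table", class(out))
  out
}

is_particle_table <- function(x) inherits(x, "particle_table")

as_particle_table <- function(x) {
  if (is_particle_table(x)) x else particle_table(x)
}

#' Read / write particle tables
#'
#' Tab-separated text with a header line naming the canonical columns
#' `id x y z phi theta psi cc class`; unset `cc`/`class` round-trip as
#' `NA`. Positions in Angstrom, angles in degrees.
#'
#' @param path file path.
#' @return [read_particles()] returns a [particle_table()];
#'   [write_particles()] returns `path` invisibly.
#' @export
read_particles <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "numeric", check.names = TRUE)
  need <- c("id", "x", "y", "z", "phi", "theta", "psi", "cc", "class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste0("particle table schema error: missing column(s) ",
                 paste(miss, collapse = ", ")))
  particle_table(df)
}

#' @rdname read_particles
#' @param particles a [particle_table()].
#' @export
write_particles <- function(particles, path) {
  particles <- as_particle_table(particles)
  df <- as.data.frame(particles)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

positions_matrix <- function(particles) {
  as.matrix(particles[, c("x", "y", "z")])
}

particle_rotations <- function(particles) {
  lapply(seq_len(nrow(particles)), function(i)
    euler_to_matrix(particles$phi[i], particles$theta[i], particles$psi[i]))
}
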