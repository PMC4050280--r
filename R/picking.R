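# Particle picking: bin + smooth, thresholded local-minima detection,
# membrane-proximity filtering, membrane-normal orientation initialization.

#' Bin and Gaussian-filter a tomogram
#'
#' Block-mean binning by `bin_factor` followed by Gaussian smoothing with
#' `gaussian_sigma` (in binned voxels, applied in Fourier space). If
#' `bin_factor` does not divide a dimension the map is padded with its
#' mean value up to the next multiple before binning (documented
#' pad-and-crop rule). The origin is kept consistent in Angstrom: the
#' first binned voxel centre is the mean of the centres it covers.
#'
#' @param map a [density_map()].
#' @param bin_factor integer >= 1.
#' @param gaussian_sigma smoothing SD in (binned) voxels; 0 disables.
#' @return a [density_map()] with `voxel_size * bin_factor`.
#' @export
preprocess <- function(map, bin_factor = 4, gaussian_sigma = 2) {
  stopifnot(is_density_map(map))
  bin_factor <- as.integer(bin_factor)
  if (is.na(bin_factor) || bin_factor < 1)
    abort("`bin_factor` must be an integer >= 1")
  if (gaussian_sigma < 0) abort("`gaussian_sigma` must be >= 0")
  g <- map$grid
  d <- dim(g)
  b <- bin_factor
  if (b > 1) {
    dpad <- ceiling(d / b) * b
    if (any(dpad != d)) {
      gp <- array(mean(g), dpad)
      gp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- g
      g <- gp
      d <- dpad
    }
    n1 <- d[1] / b; n2 <- d[2] / b; n3 <- d[3] / b
    dim(g) <- c(b, n1, b, n2, b, n3)
    g <- aperm(g, c(1, 3, 5, 2, 4, 6))
    dim(g) <- c(b^3, n1 * n2 * n3)
    g <- array(colMeans(g), c(n1, n2, n3))
  }
  out <- density_map(g, map$voxel_size * b,
                     map$origin + (b - 1) / 2 * map$voxel_size)
  if (gaussian_sigma > 0) out <- gaussian_filter(out, gaussian_sigma)
  out
}

#' Gaussian-filter a map in Fourier space
#' @param map a [density_map()].
#' @param sigma real-space SD in voxels.
#' @return filtered [density_map()].
#' @export
gaussian_filter <- function(map, sigma) {
  d <- dim(map$grid)
  att <- lapply(d, function(n) exp(-2 * pi^2 * sigma^2 * fft_freq(n)^2))
  F <- fft(map$grid)
  F <- F * outer(outer(att[[1]], att[[2]]), att[[3]])
  density_map(array(Re(fft(F, inverse = TRUE)) / prod(d), d),
              map$voxel_size, map$origin)
}

#' Detect thresholded local minima
#'
#' Strict minima over the 26-neighbourhood whose value is below
#' `mean - k_sd * SD`, with the statistics taken over the whole map.
#' The one-voxel border is excluded (incomplete neighbourhood). Results
#' are ordered by ascending linear voxel index, which makes ties and
#' output order deterministic.
#'
#' @param map a [density_map()] (typically from [preprocess()]).
#' @param k_sd threshold depth in SD units (default 2).
#' @return n x 3 matrix of positions in Angstrom (voxel centres); zero
#'   rows for a constant map.
#' @export
detect_minima <- function(map, k_sd = 2) {
  stopifnot(is_density_map(map))
  g <- map$grid
  s <- sd(g)
  if (s == 0) return(matrix(numeric(), 0, 3,
                            dimnames = list(NULL, c("x", "y", "z"))))
  thr <- mean(g) - k_sd * s
  ijk <- cpp_local_minima(g, dim(g), thr)
  pos <- voxel_to_map(map, ijk)
  colnames(pos) <- c("x", "y", "z")
  pos
}

#' Keep positions near a vesicle membrane
#'
#' Retains positions whose unsigned radial distance to the nearest
#' vesicle surface is at most `d_max`.
#'
#' @param positions n x 3 Angstrom matrix.
#' @param vesicles a [vesicle_model()] or list of them (must be non-empty).
#' @param d_max maximum membrane distance, Angstrom (default 150).
#' @return the retained subset of `positions`.
#' @export
filter_membrane_proximity <- function(positions, vesicles, d_max = 150) {
  if (d_max < 0) abort("`d_max` must be >= 0")
  positions <- rbind_pos(positions)
  if (!nrow(positions)) return(positions)
  md <- membrane_distance(positions, vesicles)
  positions[md$dist <= d_max, , drop = FALSE]
}

#' Initialize orientations normal to the membrane
#'
#' Each position is assigned to its nearest vesicle; the orientation
#' rotates the template +z axis onto the outward radial unit vector at
#' the position, with in-plane spin set to 0 by convention.
#'
#' @param positions n x 3 Angstrom matrix.
#' @param vesicles a [vesicle_model()] or list of them.
#' @return a [particle_table()] with initialized orientations.
#' @export
init_orientations <- function(positions, vesicles) {
  positions <- rbind_pos(positions)
  vesicles <- as_vesicle_list(vesicles)
  md <- membrane_distance(positions, vesicles)
  eul <- matrix(0, nrow(positions), 3)
  for (i in seq_len(nrow(positions))) {
    v <- vesicles[[md$vesicle[i]]]
    rad <- positions[i, ] - v$centre
    if (sqrt(sum(rad^2)) < 1e-9)
      abort(sprintf("position %d lies at a vesicle centre: normal undefined", i))
    eul[i, ] <- z_axis_to_direction(rad)
  }
  particle_table(tibble(
    id = seq_len(nrow(positions)),
    x = positions[, 1], y = positions[, 2], z = positions[, 3],
    phi = eul[, 1], theta = eul[, 2], psi = eul[, 3]))
}

#' Collapse duplicate picks
#'
#' Greedy non-maximum suppression on particle positions: particles are
#' visited in decreasing cc order (`NA` cc last, then by id) and kept only
#' if at least `min_dist` from every previously kept particle. Used after
#' alignment, when duplicate picks of one molecule have converged to the
#' same refined position.
#'
#' @param particles a [particle_table()].
#' @param min_dist suppression radius, Angstrom.
#' @return the retained [particle_table()] rows.
#' @export
deduplicate_particles <- function(particles, min_dist) {
  particles <- as_particle_table(particles)
  if (nrow(particles) < 2) return(particles)
  ord <- order(-ifelse(is.na(particles$cc), -Inf, particles$cc), particles$id)
  pos <- positions_matrix(particles)[ord, , drop = FALSE]
  keep <- logical(length(ord))
  kept <- matrix(numeric(), 0, 3)
  for (i in seq_along(ord)) {
    if (!nrow(kept) ||
        all(rowSums(sweep(kept, 2, pos[i, ])^2) >= min_dist^2)) {
      keep[i] <- TRUE
      kept <- rbind(kept, pos[i, ])
    }
  }
  out <- particles[sort(ord[keep]), , drop = FALSE]
  class(out) <- class(particles)
  out
}

#' Pick particles from a tomogram
#'
#' Convenience chain: [preprocess()] (bin + smooth), [detect_minima()],
#' [filter_membrane_proximity()], [init_orientations()]. Positions are
#' reported in unbinned Angstrom coordinates.
#'
#' @param tomogram a [density_map()].
#' @param vesicles a [vesicle_model()] or list of them.
#' @param bin_factor,gaussian_sigma see [preprocess()].
#' @param k_sd see [detect_minima()].
#' @param d_max see [filter_membrane_proximity()].
#' @return a [particle_table()] of candidate particles.
#' @export
pick_particles <- function(tomogram, vesicles, bin_factor = 2,
                           gaussian_sigma = 0.5, k_sd = 2, d_max = 150) {
  small <- preprocess(tomogram, bin_factor, gaussian_sigma)
  pos <- detect_minima(small, k_sd)
  pos <- filter_membrane_proximity(pos, vesicles, d_max)
  if (!nrow(pos)) abort("no particles picked: empty detection after filtering")
  init_orientations(pos, vesicles)
}
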