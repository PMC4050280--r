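# Synthetic vesicle-tomogram generator: the ground-truthed stand-in for the
# raw tomograms. A tomogram here is a dark (negative) membrane shell plus
# dark elongated protein phantoms anchored on the sphere, degraded by the
# Fourier missing wedge and additive Gaussian noise.

#' Build an elongated protein phantom
#'
#' The phantom is a distal ellipsoidal head (cross-section `head_axes`)
#' on a proximal cylindrical tail, aligned with the template +z axis:
#' the tail tip (membrane anchor) at `z = -length/2`, the head apex at
#' `z = +length/2` relative to the box centre. Voxels store the negative
#' occupancy fraction (2x supersampled), so density is <= 0 ("dark").
#'
#' With the defaults (`length` 130 A, head 60 x 40 A, head length
#' 0.4 * length, `tail_radius` 10 A) the solid volume is about 90,000 A^3,
#' matching the displacement volume of an ~87 kDa ectodomain monomer.
#'
#' @param length total extent along +z, Angstrom.
#' @param head_axes length-2, full cross-section axes (a, b) of the head
#'   ellipsoid, Angstrom.
#' @param tail_radius radius of the tail cylinder, Angstrom.
#' @param voxel_size Angstrom per voxel.
#' @param head_length axial extent of the head ellipsoid (defaults to
#'   0.4 * length).
#' @return an object of class `protein_template`: the phantom
#'   [density_map()] (`$map`, box centred on Angstrom (0,0,0)), the
#'   long-axis unit vector (`$axis`, always +z), `$length`, `$head_axes`,
#'   `$tail_radius`, `$head_length`, the z offset of the density centroid
#'   (`$centroid_z`) and of the membrane anchor (`$anchor_z`), both in
#'   Angstrom relative to the box centre.
#' @export
make_protein_template <- function(length = 130, head_axes = c(60, 40),
                                  tail_radius = 10, voxel_size = 7.6,
                                  head_length = 0.4 * length) {
  if (!is.finite(length) || length <= 0) abort("`length` must be positive")
  if (any(!is.finite(head_axes)) || any(head_axes <= 0) ||
      length(head_axes) != 2)
    abort("`head_axes` must be two positive numbers")
  if (!is.finite(tail_radius) || tail_radius <= 0)
    abort("`tail_radius` must be positive")
  if (!is.finite(voxel_size) || voxel_size <= 0)
    abort("`voxel_size` must be positive")
  if (head_length >= length) abort("`length` must exceed the head extent")
  if (min(length, head_axes, 2 * tail_radius) <= 2 * voxel_size)
    abort("all phantom dimensions must exceed 2 voxels")
  a <- head_axes[1] / 2; b <- head_axes[2] / 2; h <- head_length / 2
  half_len <- length / 2
  side <- max(length, head_axes) + 4 * voxel_size
  n <- as.integer(ceiling(side / voxel_size))
  if (n %% 2 == 0) n <- n + 1L   # odd box: centre voxel on the axis
  origin <- -((n - 1) / 2) * voxel_size
  # 2x supersampled occupancy; subsample centres at voxel centre +/- vs/4
  sub <- as.numeric(outer(c(-0.25, 0.25) * voxel_size,
                          ((seq_len(n) - 1) - (n - 1) / 2) * voxel_size, `+`))
  inside <- function(x, y, z) {
    head_c <- half_len - h
    in_head <- ((x / a)^2 + (y / b)^2 + ((z - head_c) / h)^2) <= 1
    in_tail <- (x^2 + y^2) <= tail_radius^2 & z >= -half_len & z <= head_c
    in_head | in_tail
  }
  occ <- array(0, c(n, n, n))
  for (dz in 1:2) for (dy in 1:2) for (dx in 1:2) {
    xs <- sub[seq(dx, by = 2, length.out = n)]
    ys <- sub[seq(dy, by = 2, length.out = n)]
    zs <- sub[seq(dz, by = 2, length.out = n)]
    X <- array(rep(xs, times = n * n), c(n, n, n))
    Y <- array(rep(rep(ys, each = n), times = n), c(n, n, n))
    Z <- array(rep(zs, each = n * n), c(n, n, n))
    occ <- occ + inside(X, Y, Z)
  }
  grid <- -occ / 8
  map <- density_map(grid, voxel_size, origin = rep(origin, 3))
  w <- -grid
  zc <- sum(w * array(rep(((seq_len(n) - 1) + origin / voxel_size),
                          each = n * n), c(n, n, n))) * voxel_size / sum(w)
  structure(list(map = map, axis = c(0, 0, 1), length = length,
                 head_axes = head_axes, tail_radius = tail_radius,
                 head_length = head_length, centroid_z = zc,
                 anchor_z = -half_len),
            class = "protein_template")
}

#' @export
print.protein_template <- function(x, ...) {
  cat(sprintf(paste0("<protein_template> length %g A, head %g x %g A, tail ",
                     "radius %g A, %d^3 voxels at %.2f A\n"),
              x$length, x$head_axes[1], x$head_axes[2], x$tail_radius,
              dim(x$map$grid)[1], x$map$voxel_size))
  invisible(x)
}

#' Solid volume of a phantom (A^3)
#'
#' Sum of occupancy times voxel volume; for a clean phantom this matches
#' the analytic ellipsoid + cylinder volume.
#' @param template a `protein_template`.
#' @return volume in cubic Angstrom.
#' @export
template_volume <- function(template) {
  sum(-template$map$grid) * template$map$voxel_size^3
}

#' Place particles on a vesicle surface
#'
#' Anchor points are drawn uniformly on the sphere by rejection sampling
#' under a hard-core constraint on particle *centres*. Each particle's
#' long axis is the outward membrane normal at its anchor, tilted by an
#' angle drawn from a Gaussian truncated to `[0, 90)` degrees about a
#' uniformly random tangent direction (azimuth), so tilt is evenly
#' distributed in all radial directions. The particle centre (the position
#' recorded in the table) sits `anchor_offset` Angstrom along the axis
#' from the anchor.
#'
#' @param vesicle a [vesicle_model()].
#' @param n number of particles (>= 1).
#' @param min_centre_dist hard-core centre-to-centre distance, Angstrom.
#' @param tilt_mean,tilt_sd tilt distribution parameters, degrees.
#' @param seed integer RNG seed (applied with `set.seed`).
#' @param anchor_offset distance from anchor to particle centre along the
#'   axis (half the template length), Angstrom.
#' @param surface_offset radial offset of the anchor sphere from the
#'   vesicle radius, Angstrom. An ectodomain protrudes from the outer
#'   membrane leaflet, so pipelines pass half the membrane thickness;
#'   the default 0 anchors directly on the model sphere.
#' @param max_attempts rejection-sampling cap per particle; exceeding it
#'   raises a capacity error reporting the achieved count.
#' @return an object of class `scene_truth`: `$vesicles` (list),
#'   `$particles` (a [particle_table()] with ground-truth poses) and
#'   `$truth` (tibble: `id`, `tilt`, `azimuth` in degrees, anchor
#'   coordinates `ax, ay, az` in Angstrom).
#' @export
place_particles <- function(vesicle, n, min_centre_dist = 100,
                            tilt_mean = 33, tilt_sd = 17, seed = 1,
                            anchor_offset = 65, surface_offset = 0,
                            max_attempts = 10000) {
  stopifnot(inherits(vesicle, "vesicle_model"))
  if (!is.finite(n) || n < 1) abort("`n` must be >= 1")
  if (min_centre_dist < 0) abort("`min_centre_dist` must be >= 0")
  if (tilt_sd < 0) abort("`tilt_sd` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  centres <- matrix(NA_real_, n, 3)
  anchors <- matrix(NA_real_, n, 3)
  eulers <- matrix(NA_real_, n, 3)
  tilts <- numeric(n); azs <- numeric(n)
  r <- vesicle$radius + surface_offset; c0 <- vesicle$centre
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      v <- rnorm(3)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) next
      nrm <- v / nv
      anchor <- c0 + r * nrm
      tilt <- draw_truncated_tilt(tilt_mean, tilt_sd)
      az <- runif(1, 0, 360)
      Rn <- euler_to_matrix(z_axis_to_direction(nrm)[1],
                            z_axis_to_direction(nrm)[2], 0)
      Rp <- Rn %*% euler_to_matrix(az, tilt, 0)
      u <- Rp %*% c(0, 0, 1)
      centre <- anchor + anchor_offset * as.numeric(u)
      ok <- TRUE
      if (i > 1 && min_centre_dist > 0) {
        prev <- centres[seq_len(i - 1), , drop = FALSE]
        d2 <- rowSums(sweep(prev, 2, centre)^2)
        ok <- all(d2 >= min_centre_dist^2)
      }
      if (ok) {
        centres[i, ] <- centre
        anchors[i, ] <- anchor
        eulers[i, ] <- matrix_to_euler(Rp)
        tilts[i] <- tilt; azs[i] <- az
        placed <- TRUE
        break
      }
    }
    if (!placed)
      abort(sprintf(paste0("packing capacity error: placed %d of %d ",
                           "particles (hard-core %g A on radius %g A)"),
                    i - 1L, n, min_centre_dist, r))
  }
  particles <- particle_table(tibble(
    id = seq_len(n), x = centres[, 1], y = centres[, 2], z = centres[, 3],
    phi = eulers[, 1], theta = eulers[, 2], psi = eulers[, 3]))
  structure(list(
    vesicles = list(vesicle),
    particles = particles,
    truth = tibble(id = seq_len(n), tilt = tilts, azimuth = azs,
                   ax = anchors[, 1], ay = anchors[, 2], az = anchors[, 3])),
    class = "scene_truth")
}

draw_truncated_tilt <- function(mean, sd) {
  if (sd == 0) return(max(0, min(mean, 90 - 1e-9)))
  repeat {
    t <- rnorm(1, mean, sd)
    if (t >= 0 && t < 90) return(t)
  }
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d particles on %d vesicle(s)\n",
              nrow(x$particles), length(x$vesicles)))
  invisible(x)
}

#' Render a scene into a tomogram
#'
#' The map is the sum of a dark spherical-shell bilayer per vesicle and
#' the protein phantom resampled (trilinear) at each particle's pose.
#' Background is 0 and all features are negative.
#'
#' @param scene a `scene_truth` from [place_particles()].
#' @param template a `protein_template`.
#' @param membrane_thickness shell thickness, Angstrom.
#' @param box_dim integer length-3 (or scalar) box size in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param origin Angstrom position of the centre of voxel (0,0,0);
#'   defaults to centring the first vesicle in the box.
#' @param membrane_value shell density (negative).
#' @return a [density_map()].
#' @export
render_tomogram <- function(scene, template, membrane_thickness = 50,
                            box_dim = 256, voxel_size = 7.6, origin = NULL,
                            membrane_value = -1) {
  stopifnot(inherits(scene, "scene_truth"),
            inherits(template, "protein_template"))
  box_dim <- as.integer(rep_len(box_dim, 3))
  if (is.null(origin))
    origin <- scene$vesicles[[1]]$centre - (box_dim - 1) / 2 * voxel_size
  grid <- array(0, box_dim)
  dimv <- dim(grid)
  # membrane shells
  for (v in scene$vesicles) {
    cvox <- (v$centre - origin) / voxel_size
    cpp_add_shell(grid, dimv, cvox, v$radius / voxel_size,
                  (membrane_thickness / 2) / voxel_size, membrane_value, 2L)
  }
  # particles
  p <- scene$particles
  if (nrow(p)) {
    pos_vox <- sweep(positions_matrix(p), 2, origin) / voxel_size
    out_of_box <- which(apply(pos_vox, 1, function(q)
      any(q < 0 | q > dimv - 1)))
    if (length(out_of_box))
      abort(paste0("particle placement error: outside box, ids ",
                   paste(p$id[out_of_box], collapse = ", ")))
    tmap <- template$map
    pmat <- positions_matrix(p)
    for (i in seq_len(nrow(p))) {
      R <- euler_to_matrix(p$phi[i], p$theta[i], p$psi[i])
      # target voxel v -> template voxel: (R'((v*vs + origin) - p) - o_t)/vs_t
      M <- t(R) * (voxel_size / tmap$voxel_size)
      tvec <- (as.numeric(t(R) %*% (origin - pmat[i, ])) - tmap$origin) /
        tmap$voxel_size
      cpp_add_rotated(grid, dimv, tmap$grid, dim(tmap$grid), M, tvec, 1)
    }
  }
  density_map(grid, voxel_size, origin)
}

#' Apply the tomographic missing wedge
#'
#' Zeroes Fourier coefficients outside the angular range sampled by the
#' tilt series: with tilt axis y and the beam along z, a coefficient at
#' in-plane/axial frequency `(k_perp, k_z)` is retained iff the angle
#' `atan(k_z / k_perp)` (folded to (-90, 90]) lies within
#' `[tilt_min, tilt_max]`. The DC component is always retained and the
#' output is real-valued. Applying the mask twice equals applying it once.
#'
#' @param map a [density_map()].
#' @param geometry a [tilt_geometry()].
#' @return a [density_map()].
#' @export
apply_missing_wedge <- function(map, geometry) {
  stopifnot(is_density_map(map), inherits(geometry, "tilt_geometry"))
  d <- dim(map$grid)
  kz <- fft_freq(d[3])
  kperp <- if (geometry$tilt_axis == "y") fft_freq(d[1]) else fft_freq(d[2])
  ang <- atan2(outer(rep(1, length(kperp)), kz),
               outer(kperp, rep(1, length(kz)))) * 180 / pi
  ang <- 90 - ((90 - ang) %% 180)          # fold to (-90, 90]
  # coefficients with k_perp = k_z = 0 (the tilt-axis line incl. DC) fold to
  # angle 0 and are retained whenever the range includes 0
  keep2d <- ang >= geometry$tilt_min & ang <= geometry$tilt_max
  F <- fft(map$grid)
  for (k in seq_len(d[3])) {
    bad <- !keep2d[, k]
    if (!any(bad)) next
    if (geometry$tilt_axis == "y") F[bad, , k] <- 0 else F[, bad, k] <- 0
  }
  out <- Re(fft(F, inverse = TRUE)) / prod(d)
  density_map(array(out, d), map$voxel_size, map$origin)
}

fft_freq <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / n
}

#' Add white Gaussian noise at a target SNR
#'
#' Noise variance is `var(signal over the nonzero-signal support) / snr`;
#' the noise field covers the whole map and is reproducible given `seed`.
#' `snr = Inf` returns the input unchanged.
#'
#' @param map a [density_map()].
#' @param snr target signal-to-noise variance ratio, > 0.
#' @param seed integer RNG seed.
#' @return a [density_map()].
#' @export
add_noise <- function(map, snr, seed = 1) {
  stopifnot(is_density_map(map))
  if (!is.numeric(snr) || length(snr) != 1 || is.na(snr) || snr <= 0)
    abort("`snr` must be a positive number")
  if (!is.finite(snr)) return(map)
  support <- map$grid != 0
  if (!any(support)) abort("map has no nonzero signal support")
  sigma <- sqrt(var(map$grid[support]) / snr)
  if (!is.null(seed)) set.seed(seed)
  noisy <- map$grid + array(rnorm(length(map$grid), 0, sigma), dim(map$grid))
  density_map(noisy, map$voxel_size, map$origin)
}
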