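# Post-averaging geometry: tilt statistics against the membrane normal,
# nearest-neighbour spacing, back-plotting, volume-based thresholding,
# extent measurement and landmark-membrane histograms.

#' Tilt of particle axes to the membrane normal
#'
#' For each particle the long axis is `u = R z` (its rotated template
#' axis). The membrane anchor is found by tracing the axis from the
#' particle centre toward the membrane: the nearest intersection of the
#' line `p - t u` (t >= 0) with the assigned vesicle sphere, falling back
#' to the radially closest surface point when the line misses. The tilt
#' is the angle between `u` and the outward normal at that anchor; the
#' azimuth is the direction of the axis's tangential component in the
#' local tangent basis. Azimuth uniformity is summarised with a Rayleigh
#' test.
#'
#' @param particles a [particle_table()] with orientations.
#' @param vesicles a [vesicle_model()] or list of them.
#' @param axis the long-axis direction in the template/reference frame
#'   (default +z). After reference-free refinement the common frame's
#'   in-plane gauge is arbitrary, so pass the axis estimated from the
#'   final average (e.g. the leading principal axis from
#'   [measure_extents()]) to make the statistics gauge-independent.
#' @return a `tilt_stats` object: tibble with `id`, `tilt`, `azimuth`
#'   (degrees), `vesicle`, and attributes `mean`, `sd`,
#'   `rayleigh_statistic`, `rayleigh_p`.
#' @export
tilt_statistics <- function(particles, vesicles, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  particles <- as_particle_table(particles)
  vesicles <- as_vesicle_list(vesicles)
  if (!nrow(particles)) abort("no particles")
  pos <- positions_matrix(particles)
  assign <- membrane_distance(pos, vesicles)$vesicle
  tilt <- numeric(nrow(particles)); azim <- numeric(nrow(particles))
  for (i in seq_len(nrow(particles))) {
    v <- vesicles[[assign[i]]]
    p <- pos[i, ]
    dvec <- p - v$centre
    dn <- sqrt(sum(dvec^2))
    if (dn < 1e-9) abort(sprintf("particle %d at a vesicle centre", particles$id[i]))
    R <- euler_to_matrix(particles$phi[i], particles$theta[i],
                         particles$psi[i])
    u <- as.numeric(R %*% axis)
    du <- sum(dvec * u)
    disc <- du^2 - (dn^2 - v$radius^2)
    anchor_n <- if (disc >= 0 && dn >= v$radius) {
      t0 <- du - sqrt(disc)
      (dvec - t0 * u) / sqrt(sum((dvec - t0 * u)^2))
    } else dvec / dn
    ct <- max(-1, min(1, sum(u * anchor_n)))
    tilt[i] <- acos(ct) * 180 / pi
    Rn <- euler_to_matrix(z_axis_to_direction(anchor_n)[1],
                          z_axis_to_direction(anchor_n)[2], 0)
    e1 <- Rn[, 1]; e2 <- Rn[, 2]
    azim[i] <- (atan2(sum(u * e2), sum(u * e1)) * 180 / pi) %% 360
  }
  ray <- rayleigh_test(azim * pi / 180)
  out <- tibble(id = particles$id, tilt = tilt, azimuth = azim,
                vesicle = assign)
  structure(out, class = c("tilt_stats", class(out)),
            mean = mean(tilt), sd = sd(tilt),
            rayleigh_statistic = ray$statistic, rayleigh_p = ray$p.value)
}

#' @export
glance.tilt_stats <- function(x, ...) {
  tibble(n = nrow(x), mean_tilt = attr(x, "mean"), sd_tilt = attr(x, "sd"),
         rayleigh_statistic = attr(x, "rayleigh_statistic"),
         rayleigh_p = attr(x, "rayleigh_p"))
}

rayleigh_test <- function(theta) {
  n <- length(theta)
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  Z <- n * rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(statistic = Z, p.value = max(0, min(1, p)))
}

#' Estimate the reference-frame long axis from membrane normals
#'
#' Reference-free refinement leaves the common frame's in-plane gauge
#' arbitrary, so the template-frame direction of the particle long axis
#' must be estimated before tilt statistics. Because tilt azimuths are
#' uniform around the membrane normal, the pull-backs of the outward
#' normals into each particle's template frame scatter symmetrically
#' about the long-axis direction; their mean direction is therefore a
#' consistent, orientation-blind estimator of it, with error of order
#' `sd(sin(tilt)) / sqrt(n)`.
#'
#' @param particles an aligned [particle_table()].
#' @param vesicles a [vesicle_model()] or list of them.
#' @return unit 3-vector (template frame).
#' @export
estimate_reference_axis <- function(particles, vesicles) {
  particles <- as_particle_table(particles)
  vesicles <- as_vesicle_list(vesicles)
  pos <- positions_matrix(particles)
  assign <- membrane_distance(pos, vesicles)$vesicle
  acc <- c(0, 0, 0)
  for (i in seq_len(nrow(particles))) {
    v <- vesicles[[assign[i]]]
    n <- pos[i, ] - v$centre
    nn <- sqrt(sum(n^2))
    if (nn < 1e-9) next
    R <- euler_to_matrix(particles$phi[i], particles$theta[i],
                         particles$psi[i])
    acc <- acc + as.numeric(t(R) %*% (n / nn))
  }
  na <- sqrt(sum(acc^2))
  if (na < 1e-9) abort("axis estimate degenerate: normals cancel")
  acc / na
}

particle_anchors <- function(particles, vesicles, axis = c(0, 0, 1)) {
  # trace each particle's axis toward the membrane; nearest sphere
  # intersection, falling back to the radially closest surface point
  particles <- as_particle_table(particles)
  vesicles <- as_vesicle_list(vesicles)
  pos <- positions_matrix(particles)
  assign <- membrane_distance(pos, vesicles)$vesicle
  t(vapply(seq_len(nrow(particles)), function(i) {
    v <- vesicles[[assign[i]]]
    p <- pos[i, ]
    dvec <- p - v$centre
    dn <- sqrt(sum(dvec^2))
    R <- euler_to_matrix(particles$phi[i], particles$theta[i],
                         particles$psi[i])
    u <- as.numeric(R %*% axis)
    du <- sum(dvec * u)
    disc <- du^2 - (dn^2 - v$radius^2)
    if (disc >= 0 && dn >= v$radius) p - (du - sqrt(disc)) * u
    else v$centre + v$radius * dvec / dn
  }, numeric(3)))
}

#' Collapse picks that share a membrane anchor
#'
#' A single-pass membrane protein has one anchor point; two aligned
#' picks whose traced anchors fall within `min_dist` of each other are
#' duplicate detections of the same molecule (typically offset along the
#' axially featureless tail), and only the higher-scoring one is kept.
#' Anchor-space suppression separates duplicates from genuine
#' neighbours, whose anchors respect the packing distance.
#'
#' @param particles an aligned [particle_table()].
#' @param vesicles a [vesicle_model()] or list of them.
#' @param axis template-frame long-axis direction (see
#'   [estimate_reference_axis()]).
#' @param min_dist anchor suppression radius, Angstrom.
#' @return the retained [particle_table()] rows.
#' @export
deduplicate_by_anchor <- function(particles, vesicles, axis = c(0, 0, 1),
                                  min_dist = 60) {
  particles <- as_particle_table(particles)
  if (nrow(particles) < 2) return(particles)
  anchors <- particle_anchors(particles, vesicles, axis)
  ord <- order(-ifelse(is.na(particles$cc), -Inf, particles$cc),
               particles$id)
  keep <- logical(nrow(particles))
  kept <- matrix(numeric(), 0, 3)
  for (i in ord) {
    if (!nrow(kept) ||
        all(rowSums(sweep(kept, 2, anchors[i, ])^2) >= min_dist^2)) {
      keep[i] <- TRUE
      kept <- rbind(kept, anchors[i, ])
    }
  }
  out <- particles[keep, , drop = FALSE]
  class(out) <- class(particles)
  out
}

#' Nearest-neighbour centre distances
#'
#' Euclidean centre-to-centre distance from each particle to its nearest
#' neighbour.
#'
#' @param particles a [particle_table()] with >= 2 rows.
#' @return an `nn_stats` tibble with `id` and `nn_dist` (Angstrom) and
#'   attributes `min`, `mean`, `median`.
#' @export
nn_distances <- function(particles) {
  particles <- as_particle_table(particles)
  if (nrow(particles) < 2) abort("need at least 2 particles")
  D <- as.matrix(stats::dist(positions_matrix(particles)))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  out <- tibble(id = particles$id, nn_dist = unname(nn))
  structure(out, class = c("nn_stats", class(out)),
            min = min(nn), mean = mean(nn), median = stats::median(nn))
}

#' @export
glance.nn_stats <- function(x, ...) {
  tibble(n = nrow(x), min = attr(x, "min"), mean = attr(x, "mean"),
         median = attr(x, "median"))
}

#' Plot the averaged structure back into the tomogram frame
#'
#' Composite map: the membrane map plus the averaged particle map
#' resampled at every particle pose (sum; dark convention).
#'
#' @param average_map the averaged particle [density_map()] (box centred
#'   on its own origin, as returned by [average_particles()]).
#' @param membrane_map a [density_map()] in the tomogram frame providing
#'   dims, voxel size, origin and the membrane density (may be a zero
#'   map).
#' @param particles a [particle_table()] with final poses.
#' @return a [density_map()] with the membrane map's geometry.
#' @export
backplot <- function(average_map, membrane_map, particles) {
  stopifnot(is_density_map(average_map), is_density_map(membrane_map))
  particles <- as_particle_table(particles)
  grid <- membrane_map$grid + 0   # fresh copy: the C++ adder is in-place
  d <- dim(grid)
  vs <- membrane_map$voxel_size
  if (nrow(particles)) {
    pos_vox <- map_to_voxel(membrane_map, positions_matrix(particles))
    bad <- which(apply(pos_vox, 1, function(q) any(q < 0 | q > d - 1)))
    if (length(bad))
      abort(paste0("placement outside dims for ids ",
                   paste(particles$id[bad], collapse = ", ")))
    am <- average_map
    cb_t <- -am$origin / am$voxel_size   # template-frame centre voxel
    pmat <- positions_matrix(particles)
    for (i in seq_len(nrow(particles))) {
      R <- euler_to_matrix(particles$phi[i], particles$theta[i],
                           particles$psi[i])
      M <- t(R) * (vs / am$voxel_size)
      tvec <- (as.numeric(t(R) %*% (membrane_map$origin - pmat[i, ])) -
                 am$origin) / am$voxel_size
      cpp_add_rotated(grid, d, am$grid, dim(am$grid), M, tvec, 1)
    }
  }
  density_map(grid, vs, membrane_map$origin)
}

#' Iso-level enclosing a target volume
#'
#' Finds the density level such that the volume of voxels at or below it
#' (dark convention) matches `target_volume` to within half a voxel
#' volume. Implemented by direct selection on the sorted voxel values.
#'
#' @param map a [density_map()].
#' @param target_volume target volume in cubic Angstrom, in
#'   `(0, box volume)`.
#' @return the iso-level, with attribute `achieved_volume` (A^3).
#' @export
threshold_by_volume <- function(map, target_volume) {
  stopifnot(is_density_map(map))
  vv <- map$voxel_size^3
  nvox <- length(map$grid)
  if (!is.finite(target_volume) || target_volume <= 0 ||
      target_volume >= nvox * vv)
    abort("`target_volume` unreachable: outside (0, box volume)")
  k <- round(target_volume / vv)
  if (k < 1) abort("`target_volume` smaller than one voxel")
  v <- sort(as.numeric(map$grid), partial = k)[seq_len(k)]
  level <- v[k]
  achieved <- sum(map$grid <= level) * vv
  structure(level, achieved_volume = achieved)
}

#' Extents of the thresholded density
#'
#' Selects voxels at or below `iso_level`, takes the largest 26-connected
#' component, and measures extents along its principal axes (max minus
#' min voxel-centre projection plus one voxel for the voxel extent). The
#' longest extent is the length; the two cross-section axes are
#' evaluated over the distal half of the component (the half further
#' along `distal_axis`) when a membrane reference direction is supplied.
#'
#' @param map a [density_map()].
#' @param iso_level density level (dark convention: select `<= level`).
#' @param distal_axis optional length-3 direction pointing away from the
#'   membrane (e.g. `c(0, 0, 1)` for a membrane-normal average); when
#'   given, cross axes are measured over the distal ("head") half.
#' @param head_fraction fraction of the length counted as the head.
#' @return list with `length` (Angstrom), `cross_axes` (descending,
#'   Angstrom), `axes` (3x3, columns = principal axes) and `n_voxels`.
#' @export
measure_extents <- function(map, iso_level, distal_axis = NULL,
                            head_fraction = 0.5) {
  stopifnot(is_density_map(map))
  sel <- map$grid <= iso_level
  if (!any(sel)) abort("empty selection at this iso-level")
  lab <- cpp_label_components(sel, dim(map$grid))
  tab <- tabulate(lab[lab > 0])
  main <- which.max(tab)
  idx <- which(lab == main)
  xyz <- voxel_to_map(map, arrayInd(idx, dim(map$grid)) - 1L)
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  axes <- ev$vectors[, order(ev$values, decreasing = TRUE), drop = FALSE]
  proj <- xc %*% axes
  ext <- apply(proj, 2, function(p) diff(range(p))) + map$voxel_size
  if (!is.null(distal_axis)) {
    if (sum(axes[, 1] * distal_axis) < 0) {
      axes[, 1] <- -axes[, 1]
      proj[, 1] <- -proj[, 1]
    }
    cutoff <- max(proj[, 1]) - head_fraction * diff(range(proj[, 1]))
    head <- proj[, 1] >= cutoff
    cross <- sort(apply(proj[head, 2:3, drop = FALSE], 2,
                        function(p) diff(range(p))) + map$voxel_size,
                  decreasing = TRUE)
  } else {
    cross <- sort(ext[2:3], decreasing = TRUE)
  }
  list(length = ext[1], cross_axes = cross, axes = axes,
       n_voxels = length(idx))
}

#' Landmark-to-membrane distance histograms
#'
#' Transforms template-frame landmark points by every particle pose and
#' histograms their unsigned radial distance to the assigned vesicle
#' membrane.
#'
#' @param particles a [particle_table()].
#' @param landmarks k x 3 matrix of template-frame points (Angstrom,
#'   relative to the template box centre).
#' @param vesicles a [vesicle_model()] or list of them.
#' @param bin_width histogram bin width, Angstrom (default 5).
#' @return list with `distances` (tibble: `landmark`, `id`, `dist`) and
#'   `histogram` (tibble: `landmark`, `mid`, `count`).
#' @export
landmark_membrane_histogram <- function(particles, landmarks, vesicles,
                                        bin_width = 5) {
  particles <- as_particle_table(particles)
  landmarks <- rbind_pos(landmarks)
  vesicles <- as_vesicle_list(vesicles)
  if (!nrow(particles)) abort("no particles")
  pos <- positions_matrix(particles)
  assign <- membrane_distance(pos, vesicles)$vesicle
  rows <- vector("list", nrow(landmarks))
  for (l in seq_len(nrow(landmarks))) {
    d <- numeric(nrow(particles))
    for (i in seq_len(nrow(particles))) {
      R <- euler_to_matrix(particles$phi[i], particles$theta[i],
                           particles$psi[i])
      q <- pos[i, ] + as.numeric(R %*% landmarks[l, ])
      v <- vesicles[[assign[i]]]
      d[i] <- abs(sqrt(sum((q - v$centre)^2)) - v$radius)
    }
    rows[[l]] <- tibble(landmark = l, id = particles$id, dist = d)
  }
  distances <- bind_rows(rows)
  histogram <- distances |>
    mutate(mid = (floor(.data$dist / bin_width) + 0.5) * bin_width) |>
    dplyr::count(.data$landmark, .data$mid, name = "count")
  list(distances = distances, histogram = histogram)
}
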