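# Sub-volume extraction, constrained iterative alignment, above-mean cc
# selection, even/odd gold-standard averaging, FSC, resolution, FSC-matched
# low-pass filtering and PCA classification.

#' Alignment schedule
#'
#' One row per refinement iteration: angular search half-range and step
#' (degrees), shift half-range (Angstrom), low-pass cutoff (1/Angstrom)
#' applied to the reference, and whether the mask is applied. Invariants:
#' step <= half-range, cutoffs non-decreasing, half-ranges non-increasing.
#'
#' @param half_range,step,shift,lowpass,mask equal-length vectors
#'   (scalars recycled).
#' @return a tibble of class `alignment_schedule`.
#' @export
alignment_schedule <- function(half_range, step, shift, lowpass, mask) {
  n <- max(length(half_range), length(step), length(shift),
           length(lowpass), length(mask))
  s <- tibble(half_range = rep_len(half_range, n), step = rep_len(step, n),
              shift = rep_len(shift, n), lowpass = rep_len(lowpass, n),
              mask = rep_len(mask, n))
  if (any(s$step > s$half_range + 1e-9))
    abort("schedule invalid: step exceeds half-range")
  if (any(diff(s$lowpass) < -1e-12, na.rm = TRUE))
    abort("schedule invalid: low-pass cutoffs must be non-decreasing")
  if (any(diff(s$half_range) > 1e-12))
    abort("schedule invalid: half-ranges must be non-increasing")
  class(s) <- c("alignment_schedule", class(s))
  s
}

#' Default masked refinement schedule
#'
#' Six iterations with successively finer angular sampling (half-ranges
#' 30, 20, 15, 10, 6, 4 degrees; steps a third of the half-range) and a
#' low-pass cutoff rising linearly from 1/4 to 3/4 of Nyquist. The first
#' iteration additionally sweeps the full in-plane spin (see
#' [align_particles()]), since picking leaves the spin unconstrained.
#'
#' @param voxel_size Angstrom per voxel (sets Nyquist).
#' @param n_iter number of iterations.
#' @return an `alignment_schedule`.
#' @export
default_schedule <- function(voxel_size, n_iter = 6) {
  half <- c(30, 20, 15, 10, 6, 4)[seq_len(min(n_iter, 6))]
  if (n_iter > 6) half <- c(half, rep(4, n_iter - 6))
  nyq <- 1 / (2 * voxel_size)
  alignment_schedule(half_range = half, step = half / 3,
                     shift = voxel_size,
                     lowpass = seq(0.25 * nyq, 0.75 * nyq,
                                   length.out = length(half)),
                     mask = TRUE)
}

#' Unmasked picking-refinement schedule
#'
#' Five equal iterations at coarse angular sampling with the mask off,
#' used to refine positions and orientations against the global average
#' of all picked sub-volumes before particle selection.
#'
#' @param voxel_size Angstrom per voxel.
#' @param n_iter number of iterations.
#' @return an `alignment_schedule`.
#' @export
stage_a_schedule <- function(voxel_size, n_iter = 5) {
  nyq <- 1 / (2 * voxel_size)
  alignment_schedule(half_range = rep(30, n_iter), step = 15,
                     shift = voxel_size, lowpass = 0.5 * nyq, mask = FALSE)
}

#' Extract an axis-aligned sub-volume
#'
#' Crops a cubic box centred on a particle position. Integer-voxel
#' positions relocate content exactly; sub-voxel offsets are handled by
#' trilinear interpolation. With `pad = TRUE` out-of-bounds voxels are
#' filled with the map mean, otherwise any overlap with the boundary is
#' an error.
#'
#' @param tomogram a [density_map()].
#' @param centre length-3 Angstrom position (box centre).
#' @param box_size box edge in voxels.
#' @param pad logical; pad with the map mean instead of erroring.
#' @param fill padding value; defaults to the map mean (callers in hot
#'   loops pass a precomputed value).
#' @return a [density_map()] of dim `box_size^3` whose origin places the
#'   box centre at `centre`.
#' @export
extract_subvolume <- function(tomogram, centre, box_size, pad = FALSE,
                              fill = NULL) {
  stopifnot(is_density_map(tomogram))
  d <- dim(tomogram$grid)
  if (box_size > min(d)) abort("`box_size` exceeds the tomogram dimensions")
  vc <- as.numeric(map_to_voxel(tomogram, centre))
  half <- (box_size - 1) / 2
  if (!pad && (any(vc - half < -1e-9) || any(vc + half > d - 1 + 1e-9)))
    abort("sub-volume box exceeds the tomogram bounds (padding disabled)")
  if (is.null(fill)) fill <- mean(tomogram$grid)
  off <- vc - half
  if (max(abs(off - round(off))) < 1e-9) {
    # integer-voxel crop, no interpolation
    g <- fill_crop(tomogram$grid, round(off), box_size, fill)
  } else {
    g <- cpp_resample(tomogram$grid, d, rep(box_size, 3L), diag(3),
                      off, fill)
  }
  density_map(g, tomogram$voxel_size,
              origin = as.numeric(centre) - half * tomogram$voxel_size)
}

fill_crop <- function(grid, i0, box, fill) {
  d <- dim(grid)
  g <- array(fill, rep(box, 3))
  src <- lapply(1:3, function(a) {
    s <- max(0, i0[a]):min(d[a] - 1, i0[a] + box - 1)
    if (!length(s) || s[1] > s[length(s)]) integer() else s
  })
  if (any(!lengths(src))) return(g)
  dst <- lapply(1:3, function(a) src[[a]] - i0[a] + 1)
  g[dst[[1]], dst[[2]], dst[[3]]] <-
    grid[src[[1]] + 1, src[[2]] + 1, src[[3]] + 1]
  g
}

#' Cross-correlation of a sub-volume against a posed reference
#'
#' Normalized about-the-mean correlation over masked voxels between the
#' sub-volume and the reference rotated by `rotation` (Z-Y-Z Euler,
#' degrees) and shifted by `shift` (Angstrom), both applied about the box
#' centre.
#'
#' @param subvolume,reference [density_map()]s of equal dims.
#' @param rotation length-3 Euler triplet, degrees.
#' @param shift length-3 Angstrom shift.
#' @param mask optional array of weights in `[0, 1]` (same dims).
#' @return correlation in `[-1, 1]`.
#' @export
cc_score <- function(subvolume, reference, rotation = c(0, 0, 0),
                     shift = c(0, 0, 0), mask = NULL) {
  stopifnot(is_density_map(subvolume), is_density_map(reference))
  d <- dim(subvolume$grid)
  if (!all(d == dim(reference$grid))) abort("dims differ")
  R <- euler_to_matrix(rotation[1], rotation[2], rotation[3])
  cb <- (d - 1) / 2
  sv <- shift / reference$voxel_size
  # posed ref: out(y) = ref(R^-1 (y - cb - shift) + cb)
  M <- t(R)
  tv <- cb - as.numeric(M %*% (cb + sv))
  rg <- cpp_resample(reference$grid, d, d, M, tv, mean(reference$grid))
  w <- if (is.null(mask)) rep(1, length(rg)) else {
    if (!all(dim(mask) == d)) abort("mask dims differ")
    as.numeric(mask)
  }
  cc <- cpp_masked_cc(as.numeric(subvolume$grid), as.numeric(rg), w)
  if (is.na(cc)) abort("undefined score: zero variance under the mask")
  cc
}

#' Soft membrane-excluding alignment mask
#'
#' A soft ball about the box centre (cosine edge), truncated below
#' `z_min` to exclude the membrane slab. The ball must contain the whole
#' particle at any tilt — a centred rod of half-length L/2 needs
#' `radius >= L/2` — while its radius excludes neighbouring particles;
#' the z truncation removes the membrane, which otherwise dominates the
#' correlation and locks orientations to the membrane normal.
#'
#' @param box_size box edge, voxels.
#' @param voxel_size Angstrom per voxel.
#' @param radius ball radius, Angstrom.
#' @param z_min,z_max kept z range about the box centre, Angstrom.
#' @param soft_edge cosine edge width, Angstrom.
#' @param margin voxels at the box border forced to zero (shift head-room).
#' @return numeric array of weights in `[0, 1]`.
#' @export
alignment_mask <- function(box_size, voxel_size, radius = 66,
                           z_min = -70, z_max = 70, soft_edge = 8,
                           margin = 2) {
  ax <- (seq_len(box_size) - 1 - (box_size - 1) / 2) * voxel_size
  r3d <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  edge <- function(d) ifelse(d <= 0, 1,
                             ifelse(d >= soft_edge, 0,
                                    0.5 * (1 + cos(pi * d / soft_edge))))
  wr <- edge(r3d - radius)
  wz <- edge(pmax(z_min - ax, ax - z_max))
  m <- wr * rep(wz, each = box_size^2)
  dim(m) <- rep(box_size, 3)
  if (margin > 0) {
    idx <- c(seq_len(margin), box_size - seq_len(margin) + 1)
    m[idx, , ] <- 0; m[, idx, ] <- 0; m[, , idx] <- 0
  }
  m
}

delta_rotation_grid <- function(half_range, step, spin_half = NULL,
                                spin_step = NULL) {
  a <- sort(unique(c(0, seq(-half_range, half_range, by = step))))
  spin <- if (is.null(spin_half)) a else
    sort(unique(c(0, seq(-spin_half, spin_half, by = spin_step))))
  g <- expand.grid(dpsi = spin, dtheta = a, dphi = a)
  # identity first, then scan order: deterministic tie-breaking
  id <- which(g$dphi == 0 & g$dtheta == 0 & g$dpsi == 0)
  g <- rbind(g[id, ], g[-id, ])
  lapply(seq_len(nrow(g)), function(i)
    euler_to_matrix(g$dphi[i], g$dtheta[i], g$dpsi[i]))
}

shift_grid <- function(max_shift_vox) {
  s <- -max_shift_vox:max_shift_vox
  g <- expand.grid(sx = s, sy = s, sz = s)
  id <- which(g$sx == 0 & g$sy == 0 & g$sz == 0)
  as.matrix(rbind(g[id, ], g[-id, ]))
}

#' Iterative constrained alignment of particles
#'
#' Per iteration: the reference is low-pass filtered at the scheduled
#' cutoff; each particle's sub-volume is extracted at its current
#' position, rotated into its current template frame, and compared
#' against the reference over a grid of delta rotations (Z-Y-Z, within
#' the scheduled half-range) and integer-voxel shifts; the best pose is
#' adopted and its cc recorded; then the reference is re-computed as the
#' average of all particles at their updated poses. Grid search only, ties
#' resolved to the first candidate in scan order (identity first).
#'
#' When `spin_sweep = TRUE` the first masked iteration extends the spin
#' (psi) search to the full circle, because membrane-normal
#' initialization leaves the in-plane spin unconstrained.
#'
#' @param particles a [particle_table()] with initial poses.
#' @param tomogram the [density_map()] the particles live in.
#' @param schedule an [alignment_schedule()].
#' @param box_size sub-volume box edge, voxels.
#' @param reference optional starting reference [density_map()]
#'   (`box_size^3`); default: the average of the particles at their
#'   current poses.
#' @param mask optional mask array (used on iterations with
#'   `schedule$mask`); default [alignment_mask()] geometry.
#' @param spin_sweep sweep full in-plane spin on the first masked
#'   iteration.
#' @param update_reference re-compute the reference from the updated
#'   poses after each iteration (the reference-free default); `FALSE`
#'   keeps the supplied reference fixed.
#' @param max_total_shift cap (Angstrom) on the total displacement of
#'   any particle from its starting position; shift candidates beyond
#'   it are not explored. Prevents positional random walk on
#'   low-contrast data. `Inf` disables.
#' @param membrane_exclude,membrane_band when set, the vesicle membrane
#'   band is suppressed (replaced by the local mean) both in the scored
#'   sub-volumes and in the rebuilt references, so the correlation is
#'   driven by the particle and not by the membrane slab.
#' @param wedge optional [tilt_geometry()]. When given, masked
#'   iterations score rotations in Fourier space over each particle's
#'   sampled region only (the missing wedge rotated into its current
#'   frame is excluded from both volumes), which removes the systematic
#'   orientation bias that scoring wedge-filtered data against an
#'   unfiltered reference would cause; shifts are then refined in real
#'   space at the best rotation.
#' @param verbose emit per-iteration log lines via `message()`.
#' @return the updated [particle_table()] with attributes `run_log`
#'   (tibble: iteration, mean_cc) and `reference` (the final average).
#' @export
align_particles <- function(particles, tomogram, schedule,
                            box_size = 24, reference = NULL, mask = NULL,
                            spin_sweep = FALSE, update_reference = TRUE,
                            max_total_shift = 20, membrane_exclude = NULL,
                            membrane_band = 56, wedge = NULL,
                            verbose = FALSE) {
  particles <- as_particle_table(particles)
  if (!nrow(particles)) abort("empty particle set")
  stopifnot(is_density_map(tomogram))
  vs <- tomogram$voxel_size
  d <- rep(box_size, 3L)
  orig_pos <- positions_matrix(particles)
  tomo_mean <- mean(tomogram$grid)
  if (is.null(reference))
    reference <- average_particles(particles, tomogram, box_size,
                                   membrane_exclude, membrane_band)
  if (is.null(mask))
    mask <- alignment_mask(box_size, vs)
  vlist_excl <- if (is.null(membrane_exclude)) NULL else
    as_vesicle_list(membrane_exclude)
  box_offsets <- if (is.null(membrane_exclude)) NULL else
    membrane_box_offsets(box_size, vs)
  ones <- array(1, d)
  ones[c(1, 2, box_size - 1, box_size), , ] <- 0
  ones[, c(1, 2, box_size - 1, box_size), ] <- 0
  ones[, , c(1, 2, box_size - 1, box_size)] <- 0
  log <- NULL
  cb <- (d - 1) / 2
  first_masked <- which(schedule$mask)[1]
  kmat <- NULL
  if (!is.null(wedge)) {
    kx <- fft_freq(box_size)
    kmat <- rbind(rep(kx, times = box_size^2),
                  rep(rep(kx, each = box_size), times = box_size),
                  rep(kx, each = box_size^2))
    kfreq <- sqrt(colSums(kmat^2)) / vs        # 1/Angstrom
  }
  for (it in seq_len(nrow(schedule))) {
    refF <- lowpass_filter(reference, schedule$lowpass[it])
    sweep_spin <- isTRUE(spin_sweep) && !is.na(first_masked) &&
      it == first_masked
    deltas <- if (sweep_spin)
      delta_rotation_grid(schedule$half_range[it],
                          max(schedule$step[it], schedule$half_range[it] / 2),
                          spin_half = 180 - 1e-9, spin_step = 30)
    else delta_rotation_grid(schedule$half_range[it], schedule$step[it])
    nrot <- length(deltas)
    refs <- array(0, c(d, nrot))
    for (r in seq_len(nrot)) {
      D <- deltas[[r]]
      M <- t(D)
      refs[, , , r] <- cpp_resample(refF$grid, d, d, M,
                                    cb - as.numeric(M %*% cb),
                                    mean(refF$grid))
    }
    w <- if (schedule$mask[it]) mask else ones
    midx <- which(w > 0)
    mijk <- arrayInd(midx, d) - 1L
    mw <- as.numeric(w[midx])
    sh_vox <- max(1L, as.integer(round(schedule$shift[it] / vs)))
    shifts <- shift_grid(sh_vox)
    if (any(mijk < sh_vox) || any(mijk > box_size - 1 - sh_vox))
      abort("mask margin smaller than the shift search range")
    # wedge-compensated scoring on masked refinement iterations (the
    # coarse spin-sweep iteration uses the real-space path: its rotation
    # set is an order of magnitude larger and its role is only to seed
    # the in-plane spin)
    use_wedge <- !is.null(wedge) && schedule$mask[it] && !sweep_spin
    if (use_wedge) {
      wa <- array(w, d)
      keep_base <- is.finite(schedule$lowpass[it]) &
        (kfreq <= max(schedule$lowpass[it], 4 / (box_size * vs)))
      if (!any(keep_base)) keep_base <- kfreq <= 0.5 / vs
      keep_base[1] <- FALSE        # exclude DC: about-the-mean
      ball <- which(keep_base)
      kmat_ball <- kmat[, ball, drop = FALSE]
      # references restricted to the low-pass ball: cache-friendly scoring
      Frefs <- vapply(seq_len(nrot), function(r)
        as.vector(fft(refs[, , , r] * wa))[ball],
        complex(length(ball)))
    }
    rgm <- if (use_wedge) NULL else
      matrix(refs, box_size^3, nrot)[midx, , drop = FALSE]
    pmat <- positions_matrix(particles)
    new_eul <- matrix(0, nrow(particles), 3)
    new_pos <- pmat
    ccs <- numeric(nrow(particles))
    for (i in seq_len(nrow(particles))) {
      Rp <- euler_to_matrix(particles$phi[i], particles$theta[i],
                            particles$psi[i])
      sub <- extract_subvolume(tomogram, pmat[i, ], box_size, pad = TRUE,
                               fill = tomo_mean)
      if (!is.null(box_offsets))
        sub$grid <- suppress_membrane(sub$grid, pmat[i, ], box_offsets,
                                      vlist_excl, membrane_band)
      subrot <- cpp_resample(sub$grid, d, d, Rp,
                             cb - as.numeric(Rp %*% cb), mean(sub$grid))
      sh_i <- shifts
      if (is.finite(max_total_shift)) {
        disp <- sweep(shifts %*% t(Rp) * vs, 2,
                      pmat[i, ] - orig_pos[i, ], `+`)
        ok <- sqrt(rowSums(disp^2)) <= max_total_shift
        ok[1] <- TRUE   # zero shift always allowed
        sh_i <- shifts[ok, , drop = FALSE]
      }
      if (use_wedge) {
        Fsub <- as.vector(fft(array(subrot, d) * wa))[ball]
        ktom <- Rp %*% kmat_ball
        kperp <- if (wedge$tilt_axis == "y") ktom[1, ] else ktom[2, ]
        ang <- atan2(ktom[3, ], kperp) * 180 / pi
        ang <- 90 - ((90 - ang) %% 180)
        keep_i <- which(ang >= wedge$tilt_min & ang <= wedge$tilt_max) - 1L
        ccs_rot <- cpp_wedge_cc(Fsub, Frefs, nrot, keep_i)
        irot <- which.max(ccs_rot)
        cc_rec <- ccs_rot[irot]
      } else {
        best <- cpp_search_poses(subrot, rgm, d, mijk, mw, sh_i)
        irot <- best$rot
        cc_rec <- best$cc
      }
      # shift search at the chosen rotation, with per-axis parabolic
      # sub-voxel refinement of the correlation peak
      ccs_sh <- cpp_cc_shift_grid(subrot, refs[, , , irot],
                                  d, mijk, mw, sh_i)
      ib <- which.max(ccs_sh)
      base <- as.numeric(sh_i[ib, ])
      key <- paste(sh_i[, 1], sh_i[, 2], sh_i[, 3])
      frac <- c(0, 0, 0)
      for (ax in 1:3) {
        lo <- base; lo[ax] <- lo[ax] - 1
        hi <- base; hi[ax] <- hi[ax] + 1
        ilo <- match(paste(lo[1], lo[2], lo[3]), key)
        ihi <- match(paste(hi[1], hi[2], hi[3]), key)
        if (!is.na(ilo) && !is.na(ihi)) {
          den <- ccs_sh[ilo] - 2 * ccs_sh[ib] + ccs_sh[ihi]
          if (is.finite(den) && den < -1e-12)
            frac[ax] <- max(-0.5, min(0.5,
                                      0.5 * (ccs_sh[ilo] - ccs_sh[ihi]) / den))
        }
      }
      Rn <- Rp %*% deltas[[irot]]
      new_eul[i, ] <- matrix_to_euler(Rn)
      new_pos[i, ] <- pmat[i, ] + as.numeric(Rp %*% ((base + frac) * vs))
      ccs[i] <- cc_rec
    }
    particles$phi <- new_eul[, 1]; particles$theta <- new_eul[, 2]
    particles$psi <- new_eul[, 3]
    particles$x <- new_pos[, 1]; particles$y <- new_pos[, 2]
    particles$z <- new_pos[, 3]
    particles$cc <- ccs
    if (update_reference || it == nrow(schedule))
      reference <- average_particles(particles, tomogram, box_size,
                                     membrane_exclude, membrane_band)
    log <- bind_rows(log, tibble(iteration = it, mean_cc = mean(ccs),
                                 n_rotations = nrot))
    if (verbose)
      message(sprintf("iter %d: mean cc %.4f (%d rotations)", it,
                      mean(ccs), nrot))
  }
  attr(particles, "run_log") <- log
  attr(particles, "reference") <- reference
  particles
}

#' Re-centre particles on their average's structural midpoint
#'
#' Picking centres boxes on the local density minimum (the phantom's
#' density centroid), not on the geometric middle of the molecule. This
#' thresholds the current average (at `mean - k_sd * SD`), takes the
#' largest 26-connected component, and shifts every particle by the
#' offset of the component's bounding-box midpoint from the box centre
#' (rotated into the tomogram frame), so the molecule is centred in its
#' box for masked refinement and extent measurement.
#'
#' @param particles a [particle_table()].
#' @param tomogram the source [density_map()].
#' @param box_size box edge, voxels.
#' @param k_sd threshold depth for the component selection.
#' @param membrane_exclude,membrane_band forwarded to
#'   [average_particles()].
#' @return the shifted [particle_table()], with attribute `offset`
#'   (Angstrom, template frame).
#' @export
recentre_particles <- function(particles, tomogram, box_size = 24,
                               k_sd = 2, membrane_exclude = NULL,
                               membrane_band = 56) {
  particles <- as_particle_table(particles)
  avg <- average_particles(particles, tomogram, box_size,
                           membrane_exclude, membrane_band)
  g <- avg$grid
  thr <- mean(g) - k_sd * sd(g)
  sel <- g <= thr
  if (!any(sel)) return(structure(particles, offset = c(0, 0, 0)))
  lab <- cpp_label_components(sel, dim(g))
  main <- which.max(tabulate(lab[lab > 0]))
  ijk <- arrayInd(which(lab == main), dim(g)) - 1L
  mid_vox <- (apply(ijk, 2, min) + apply(ijk, 2, max)) / 2
  offset <- (mid_vox - (box_size - 1) / 2) * avg$voxel_size
  pmat <- positions_matrix(particles)
  for (i in seq_len(nrow(particles))) {
    R <- euler_to_matrix(particles$phi[i], particles$theta[i],
                         particles$psi[i])
    pmat[i, ] <- pmat[i, ] + as.numeric(R %*% offset)
  }
  particles$x <- pmat[, 1]; particles$y <- pmat[, 2]; particles$z <- pmat[, 3]
  structure(particles, offset = offset)
}

#' Rigid alignment of one map onto another
#'
#' Grid search (coarse, then one refinement pass at a third of the
#' step) over Z-Y-Z rotations and integer-voxel shifts maximizing the
#' masked about-the-mean correlation of `map_b` posed onto `map_a`.
#' Used to register independently refined half-set averages, whose
#' frames condense to arbitrary in-plane gauges, before computing their
#' FSC.
#'
#' @param map_a,map_b [density_map()]s of equal dims.
#' @param mask optional weight array.
#' @param theta_max maximum tilt explored, degrees.
#' @param step coarse angular step, degrees.
#' @param shift_vox integer shift half-range, voxels.
#' @return list with `map` (the posed `map_b`), `rotation`, `shift_vox`,
#'   `cc`.
#' @export
align_maps <- function(map_a, map_b, mask = NULL, theta_max = 40,
                       step = 15, shift_vox = 1) {
  d <- dim(map_a$grid)
  if (!all(d == dim(map_b$grid))) abort("dims differ")
  w <- if (is.null(mask)) array(1, d) else mask
  sh <- expand.grid(sx = -shift_vox:shift_vox, sy = -shift_vox:shift_vox,
                    sz = -shift_vox:shift_vox)
  eval_pose <- function(e) {
    best <- list(cc = -2)
    R <- euler_to_matrix(e[1], e[2], e[3])
    cb <- (d - 1) / 2
    M <- t(R)
    for (s in seq_len(nrow(sh))) {
      sv <- as.numeric(sh[s, ])
      tv <- cb - as.numeric(M %*% (cb + sv))
      rg <- cpp_resample(map_b$grid, d, d, M, tv, mean(map_b$grid))
      cc <- cpp_masked_cc(as.numeric(map_a$grid), as.numeric(rg),
                          as.numeric(w))
      if (!is.na(cc) && cc > best$cc)
        best <- list(cc = cc, rotation = e, shift = sv, grid = rg)
    }
    best
  }
  grid1 <- expand.grid(phi = seq(-180, 165, by = step),
                       theta = seq(0, theta_max, by = step),
                       psi = seq(-180, 165, by = step))
  best <- list(cc = -2)
  for (i in seq_len(nrow(grid1))) {
    e <- as.numeric(grid1[i, ])
    R <- euler_to_matrix(e[1], e[2], e[3])
    cb <- (d - 1) / 2
    M <- t(R)
    tv <- cb - as.numeric(M %*% cb)
    rg <- cpp_resample(map_b$grid, d, d, M, tv, mean(map_b$grid))
    cc <- cpp_masked_cc(as.numeric(map_a$grid), as.numeric(rg),
                        as.numeric(w))
    if (!is.na(cc) && cc > best$cc) best <- list(cc = cc, rotation = e)
  }
  # refine rotation at a third of the step (no shift), then shifts once
  fine <- expand.grid(dphi = seq(-step, step, by = step / 3),
                      dtheta = seq(-step, step, by = step / 3),
                      dpsi = seq(-step, step, by = step / 3))
  R0 <- euler_to_matrix(best$rotation[1], best$rotation[2], best$rotation[3])
  cb <- (d - 1) / 2
  best_rot <- best$rotation
  best_cc <- best$cc
  for (i in seq_len(nrow(fine))) {
    e0 <- matrix_to_euler(R0 %*% euler_to_matrix(fine$dphi[i],
                                                 fine$dtheta[i],
                                                 fine$dpsi[i]))
    M <- t(euler_to_matrix(e0[1], e0[2], e0[3]))
    rg <- cpp_resample(map_b$grid, d, d, M, cb - as.numeric(M %*% cb),
                       mean(map_b$grid))
    cc <- cpp_masked_cc(as.numeric(map_a$grid), as.numeric(rg),
                        as.numeric(w))
    if (!is.na(cc) && cc > best_cc) { best_cc <- cc; best_rot <- e0 }
  }
  best2 <- eval_pose(as.numeric(best_rot))
  list(map = density_map(array(best2$grid, d), map_b$voxel_size,
                         map_b$origin),
       rotation = best2$rotation, shift_vox = best2$shift, cc = best2$cc)
}

#' Select particles scoring above the mean cc
#'
#' Retains records whose cc is strictly greater than the arithmetic mean
#' cc; equal-scoring sets therefore retain nothing. All cc must be set.
#'
#' @param particles a [particle_table()] with cc scores.
#' @return the retained [particle_table()].
#' @export
select_above_mean <- function(particles) {
  particles <- as_particle_table(particles)
  if (any(is.na(particles$cc))) abort("all cc scores must be set")
  out <- particles[particles$cc > mean(particles$cc), , drop = FALSE]
  class(out) <- class(particles)
  out
}

#' Split a particle table by index parity
#'
#' Partition by the parity of the 0-based record index: the `even` table
#' takes indices 0, 2, 4, ... (and so is the larger half of an odd-sized
#' table), `odd` the rest.
#'
#' @param particles a [particle_table()].
#' @return list with elements `even` and `odd`.
#' @export
split_even_odd <- function(particles) {
  particles <- as_particle_table(particles)
  n <- nrow(particles)
  ev <- seq_len(n) %% 2 == 1   # 0-based even
  even <- particles[ev, , drop = FALSE]
  odd <- particles[!ev, , drop = FALSE]
  class(even) <- class(particles); class(odd) <- class(particles)
  list(even = even, odd = odd)
}

membrane_box_offsets <- function(box_size, voxel_size) {
  cb <- (box_size - 1) / 2
  ax <- ((0:(box_size - 1)) - cb) * voxel_size
  as.matrix(expand.grid(x = ax, y = ax, z = ax))
}

suppress_membrane <- function(grid, centre, box_offsets, vlist, band) {
  near <- FALSE
  for (v in vlist) {
    dx <- box_offsets[, 1] + centre[1] - v$centre[1]
    dy <- box_offsets[, 2] + centre[2] - v$centre[2]
    dz <- box_offsets[, 3] + centre[3] - v$centre[3]
    rr <- sqrt(dx * dx + dy * dy + dz * dz)
    near <- near | abs(rr - v$radius) <= band / 2
  }
  if (any(near)) grid[near] <- mean(grid[!near])
  grid
}

#' Average particles into a reference frame
#'
#' Each sub-volume is extracted at its particle's position, rotated into
#' the common template frame by the inverse pose (trilinear), and the
#' voxel-wise mean is returned. With `membrane_exclude` set, voxels
#' within `membrane_band / 2` of a vesicle surface are replaced by the
#' sub-volume mean before rotation, so the (otherwise coherent)
#' membrane slab does not contaminate the particle average — the
#' averaging-side counterpart of masking out the membrane.
#'
#' @param particles a [particle_table()] (>= 1 row).
#' @param tomogram the source [density_map()].
#' @param box_size box edge, voxels.
#' @param membrane_exclude optional [vesicle_model()] (or list) whose
#'   membrane band is suppressed.
#' @param membrane_band excluded band thickness, Angstrom.
#' @return a [density_map()] centred on Angstrom (0,0,0).
#' @export
average_particles <- function(particles, tomogram, box_size = 24,
                              membrane_exclude = NULL,
                              membrane_band = 56) {
  particles <- as_particle_table(particles)
  if (!nrow(particles)) abort("cannot average an empty particle set")
  vs <- tomogram$voxel_size
  d <- rep(box_size, 3L)
  cb <- (d - 1) / 2
  acc <- array(0, d)
  tomo_mean <- mean(tomogram$grid)
  pmat <- positions_matrix(particles)
  box_offsets <- NULL
  if (!is.null(membrane_exclude)) {
    vlist <- as_vesicle_list(membrane_exclude)
    box_offsets <- membrane_box_offsets(box_size, vs)
  }
  for (i in seq_len(nrow(particles))) {
    Rp <- euler_to_matrix(particles$phi[i], particles$theta[i],
                          particles$psi[i])
    sub <- extract_subvolume(tomogram, pmat[i, ], box_size, pad = TRUE,
                             fill = tomo_mean)
    if (!is.null(box_offsets))
      sub$grid <- suppress_membrane(sub$grid, pmat[i, ], box_offsets,
                                    vlist, membrane_band)
    acc <- acc + cpp_resample(sub$grid, d, d, Rp,
                              cb - as.numeric(Rp %*% cb), mean(sub$grid))
  }
  density_map(acc / nrow(particles), vs,
              origin = -cb * vs)
}

#' Fourier shell correlation between two maps
#'
#' Normalized complex correlation per concentric Fourier shell of width
#' one Fourier voxel. Requires equal dims and voxel size.
#'
#' @param map_a,map_b [density_map()]s.
#' @return an `fsc_curve`: tibble with `frequency` (1/Angstrom, shell
#'   centres, ascending to Nyquist) and `fsc`.
#' @export
compute_fsc <- function(map_a, map_b) {
  stopifnot(is_density_map(map_a), is_density_map(map_b))
  d <- dim(map_a$grid)
  if (!all(d == dim(map_b$grid))) abort("FSC: dims differ")
  if (abs(map_a$voxel_size - map_b$voxel_size) > 1e-9)
    abort("FSC: voxel sizes differ")
  A <- fft(map_a$grid)
  B <- fft(map_b$grid)
  n <- d[1]
  kx <- fft_freq(d[1]) * d[1]
  ky <- fft_freq(d[2]) * d[2] * (d[1] / d[2])
  kz <- fft_freq(d[3]) * d[3] * (d[1] / d[3])
  r2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  shell <- round(sqrt(r2))
  nmax <- floor(n / 2)
  keep <- shell <= nmax
  sh <- as.integer(shell[keep]) + 1L
  ab <- Re(A[keep] * Conj(B[keep]))
  aa <- Mod(A[keep])^2
  bb <- Mod(B[keep])^2
  num <- as.numeric(rowsum(ab, sh))
  da <- as.numeric(rowsum(aa, sh))
  db <- as.numeric(rowsum(bb, sh))
  fsc <- ifelse(da > 0 & db > 0, num / sqrt(da * db), 0)
  curve <- tibble(frequency = (0:nmax) / (n * map_a$voxel_size), fsc = fsc)
  class(curve) <- c("fsc_curve", class(curve))
  curve
}

#' Resolution at an FSC threshold
#'
#' Reciprocal of the frequency of the first downward crossing of the
#' threshold, linearly interpolated between shells. If the curve never
#' crosses, the Nyquist resolution is returned with attribute
#' `crossed = FALSE`.
#'
#' @param curve an `fsc_curve` (or tibble with `frequency`, `fsc`).
#' @param threshold correlation threshold in (0, 1), e.g. 0.143 or 0.5.
#' @return resolution in Angstrom, with attribute `crossed`.
#' @export
resolution_at <- function(curve, threshold) {
  if (!nrow(curve)) abort("empty FSC curve")
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0,1)")
  f <- curve$frequency; v <- curve$fsc
  for (i in seq_len(length(v) - 1)) {
    if (v[i] >= threshold && v[i + 1] < threshold) {
      t <- (v[i] - threshold) / (v[i] - v[i + 1])
      fc <- f[i] + t * (f[i + 1] - f[i])
      return(structure(1 / fc, crossed = TRUE))
    }
  }
  structure(1 / f[length(f)], crossed = FALSE)
}

#' Sharp-edged low-pass filter
#'
#' Fourier amplitudes beyond `cutoff` (1/Angstrom) are attenuated with a
#' narrow cosine edge (10% of the cutoff) to limit ringing.
#'
#' @param map a [density_map()].
#' @param cutoff spatial frequency in 1/Angstrom; `Inf` returns the map.
#' @return a [density_map()].
#' @export
lowpass_filter <- function(map, cutoff) {
  if (!is.finite(cutoff)) return(map)
  d <- dim(map$grid)
  fx <- fft_freq(d[1]) / map$voxel_size
  fy <- fft_freq(d[2]) / map$voxel_size
  fz <- fft_freq(d[3]) / map$voxel_size
  r <- sqrt(outer(outer(fx^2, fy^2, `+`), fz^2, `+`))
  edge <- 0.1 * cutoff
  w <- ifelse(r <= cutoff, 1,
              ifelse(r >= cutoff + edge, 0,
                     0.5 * (1 + cos(pi * (r - cutoff) / edge))))
  F <- fft(map$grid) * w
  density_map(array(Re(fft(F, inverse = TRUE)) / prod(d), d),
              map$voxel_size, map$origin)
}

#' Gaussian low-pass matched to an FSC curve
#'
#' Least-squares fit of `G(f) = exp(-f^2 / (2 sigma_f^2))` to the FSC
#' values, then multiplication of the Fourier amplitudes by `G`. An
#' essentially flat curve (all FSC > 0.99) leaves the map unchanged
#' (the `sigma_f -> Inf` limit); a non-decaying curve that cannot be fit
#' is an error.
#'
#' @param map a [density_map()].
#' @param curve an `fsc_curve` defined to Nyquist.
#' @return the filtered [density_map()], with attribute `sigma_f`
#'   (1/Angstrom).
#' @export
lowpass_by_fsc <- function(map, curve) {
  stopifnot(is_density_map(map))
  f <- curve$frequency; v <- pmax(pmin(curve$fsc, 1), 0)
  if (all(v > 0.99)) return(structure(map, sigma_f = Inf))
  if (stats::cov(f, v) >= 0)
    abort(paste0("FSC curve does not decay (non-negative trend over ",
                 "frequency): cannot fit a Gaussian width"))
  nyq <- max(f)
  sse <- function(s) sum((exp(-f^2 / (2 * s^2)) - v)^2)
  opt <- optimise(sse, c(nyq / 200, 20 * nyq))
  sig <- opt$minimum
  d <- dim(map$grid)
  fx <- fft_freq(d[1]) / map$voxel_size
  fy <- fft_freq(d[2]) / map$voxel_size
  fz <- fft_freq(d[3]) / map$voxel_size
  r2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  G <- exp(-r2 / (2 * sig^2))
  F <- fft(map$grid) * G
  out <- density_map(array(Re(fft(F, inverse = TRUE)) / prod(d), d),
                     map$voxel_size, map$origin)
  structure(out, sigma_f = sig)
}

#' PCA classification of aligned sub-volumes
#'
#' Principal components of the masked voxel vectors followed by k-means
#' on the leading component scores, with a fixed seed.
#'
#' @param subvolumes list of [density_map()]s aligned to a common frame
#'   (equal dims).
#' @param mask optional weight/selection array (voxels with weight > 0
#'   enter the analysis).
#' @param n_components number of leading components used for clustering
#'   (capped at `min(n - 1, n_voxels)`).
#' @param k_classes number of k-means classes.
#' @param seed RNG seed for k-means.
#' @return list with `labels` (integer per sub-volume), `counts`
#'   (per-class table) and `variance_explained`.
#' @export
pca_classify <- function(subvolumes, mask = NULL, n_components = 5,
                         k_classes = 2, seed = 1) {
  n <- length(subvolumes)
  if (k_classes > n) abort("`k_classes` exceeds the number of sub-volumes")
  d <- dim(subvolumes[[1]]$grid)
  sel <- if (is.null(mask)) rep(TRUE, prod(d)) else as.numeric(mask) > 0
  X <- t(vapply(subvolumes, function(m) as.numeric(m$grid)[sel],
                numeric(sum(sel))))
  if (all(apply(X, 2, var) < 1e-30))
    abort("degenerate variance: sub-volumes are identical, nothing to classify")
  n_components <- min(n_components, n - 1, ncol(X))
  p <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  set.seed(seed)
  km <- kmeans(p$x[, seq_len(n_components), drop = FALSE], k_classes,
               nstart = 10)
  list(labels = as.integer(km$cluster),
       counts = table(km$cluster),
       variance_explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(n_components)])
}
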