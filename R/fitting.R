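# Fitting atomic models into EM density: density synthesis, rigid-body
# search, hinge-restricted flexible refinement, domain-rotation comparison,
# residue-pair distances, and bilayer placement.

#' Synthesize a density map from an atomic model
#'
#' Each atom is rendered as a 3D Gaussian of real-space SD
#' `resolution / (2 pi sqrt(2))`, scaled by its atomic mass and negated
#' (dark convention, matching the EM maps in this package).
#'
#' @param model an `atomic_model`.
#' @param resolution nominal resolution in Angstrom (>= 2 * voxel_size).
#' @param voxel_size Angstrom per voxel.
#' @param box_dim optional integer length-3 box size in voxels; default
#'   encloses the model plus 4 SD of padding.
#' @param origin optional Angstrom origin (centre of voxel (0,0,0));
#'   default centres the model in the box.
#' @return a [density_map()].
#' @export
model_to_map <- function(model, resolution, voxel_size, box_dim = NULL,
                         origin = NULL) {
  if (!is_atomic_model(model)) model <- atomic_model(model)
  if (!nrow(model)) abort("empty model")
  if (resolution < 2 * voxel_size)
    abort("`resolution` must be at least 2 * voxel_size (Nyquist bound)")
  sigma <- resolution / (2 * pi * sqrt(2))
  xyz <- model_coords(model)
  pad <- 4 * sigma + voxel_size
  if (is.null(box_dim)) {
    span <- apply(xyz, 2, function(v) diff(range(v))) + 2 * pad
    box_dim <- as.integer(ceiling(span / voxel_size)) + 1L
  } else box_dim <- as.integer(rep_len(box_dim, 3))
  if (is.null(origin))
    origin <- colMeans(apply(xyz, 2, range)) - (box_dim - 1) / 2 * voxel_size
  pos_vox <- sweep(xyz, 2, origin) / voxel_size
  g <- cpp_splat_gaussians(box_dim, pos_vox, -atom_masses(model),
                           sigma / voxel_size)
  density_map(g, voxel_size, origin)
}

footprint_mask <- function(synth_grid, fraction = 0.1) {
  lo <- min(synth_grid)
  if (lo >= 0) abort("degenerate footprint: synthesized map has no density")
  synth_grid <= fraction * lo
}

#' Cross-correlation of a model against a map
#'
#' About-the-mean correlation between the experimental map and the
#' model-synthesized density, over the model's footprint (voxels whose
#' synthesized density is at most 10% of its minimum, i.e. at least 10%
#' of the peak depth).
#'
#' @param map the experimental [density_map()].
#' @param model an `atomic_model` already posed in map coordinates.
#' @param resolution synthesis resolution, Angstrom.
#' @return CCC in `[-1, 1]`.
#' @export
model_map_ccc <- function(map, model, resolution) {
  synth <- model_to_map(model, resolution, map$voxel_size,
                        box_dim = dim(map$grid), origin = map$origin)
  fp <- footprint_mask(synth$grid)
  if (sum(fp) < 8) abort("degenerate footprint: model outside the map?")
  cc <- cpp_masked_cc(as.numeric(map$grid), as.numeric(synth$grid),
                      as.numeric(fp))
  if (is.na(cc)) abort("degenerate footprint: zero variance under footprint")
  cc
}

#' Rigid-body fit of a model into a map
#'
#' Exhaustive grid search over Z-Y-Z rotation offsets (about the model
#' centroid) and translations around the initial pose, maximizing the
#' footprint-masked CCC of [model_map_ccc()]. Zero search ranges evaluate
#' the initial pose only. Ties keep the first candidate in scan order
#' (identity first).
#'
#' @param model an `atomic_model` (in map coordinates at its initial
#'   pose).
#' @param map the target [density_map()].
#' @param resolution synthesis resolution, Angstrom.
#' @param rotation,shift initial pose: Euler triplet (degrees) and
#'   translation (Angstrom) applied to `model` about its centroid before
#'   the search.
#' @param ang_range,ang_step angular search half-range and step, degrees.
#' @param shift_range,shift_step translation half-range and step,
#'   Angstrom.
#' @return a `fit_result`: list with `rotation` (Euler, deg), `shift`
#'   (Angstrom), `ccc`, `model` (the posed `atomic_model`) and
#'   `n_evaluated`.
#' @export
rigid_fit <- function(model, map, resolution, rotation = c(0, 0, 0),
                      shift = c(0, 0, 0), ang_range = 0, ang_step = 5,
                      shift_range = 0, shift_step = 4) {
  if (!is_atomic_model(model)) model <- atomic_model(model)
  centre <- colMeans(model_coords(model))
  angs <- if (ang_range > 0) sort_zero_first(seq(-ang_range, ang_range,
                                                 by = ang_step)) else 0
  shs <- if (shift_range > 0) sort_zero_first(seq(-shift_range, shift_range,
                                                  by = shift_step)) else 0
  R0 <- euler_to_matrix(rotation[1], rotation[2], rotation[3])
  best <- list(ccc = -2)
  n_eval <- 0L
  for (dphi in angs) for (dth in angs) for (dpsi in angs) {
    R <- R0 %*% euler_to_matrix(dphi, dth, dpsi)
    rotated <- transform_model(model, R, c(0, 0, 0), centre)
    for (sx in shs) for (sy in shs) for (sz in shs) {
      cand <- rotated
      tot_shift <- shift + c(sx, sy, sz)
      cand$x <- cand$x + tot_shift[1]
      cand$y <- cand$y + tot_shift[2]
      cand$z <- cand$z + tot_shift[3]
      ccc <- model_map_ccc(map, cand, resolution)
      n_eval <- n_eval + 1L
      if (ccc > best$ccc) {
        eul <- matrix_to_euler(R)
        best <- list(rotation = eul, shift = tot_shift, ccc = ccc,
                     model = cand)
      }
    }
  }
  structure(c(best, list(n_evaluated = n_eval)), class = "fit_result")
}

sort_zero_first <- function(v) {
  v <- sort(unique(c(0, v)))
  c(0, v[v != 0])
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> ccc %.4f, rotation (%.1f, %.1f, %.1f) deg, shift (%.1f, %.1f, %.1f) A\n",
              x$ccc, x$rotation[1], x$rotation[2], x$rotation[3],
              x$shift[1], x$shift[2], x$shift[3]))
  if (!is.null(x$hinge_rotations))
    cat(sprintf("  hinge rotations: I-II %.1f deg, I-III %.1f deg\n",
                x$hinge_rotations[1], x$hinge_rotations[2]))
  invisible(x)
}

#' @export
glance.fit_result <- function(x, ...) {
  tibble(ccc = x$ccc,
         hinge12 = if (is.null(x$hinge_rotations)) NA_real_ else x$hinge_rotations[1],
         hinge13 = if (is.null(x$hinge_rotations)) NA_real_ else x$hinge_rotations[2])
}

hinge_pivot <- function(model, residues) {
  atoms <- domain_atoms(model, residues, backbone_only = TRUE)
  if (!nrow(atoms)) atoms <- domain_atoms(model, residues)
  if (!nrow(atoms)) abort("hinge residues not found in model")
  colMeans(model_coords(atoms))
}

#' Hinge-restricted flexible fit
#'
#' Starting from a rigid-body pose, alternately rotates domains II and
#' III as rigid bodies about their hinge pivot points (the backbone
#' midpoint of the hinge residues) to maximize the footprint-masked CCC,
#' with domain I (plus any membrane-proximal region) fixed. Hinge
#' residues follow their moving domain. Each of the `n_iterations`
#' rounds searches a rotation-vector grid that shrinks by half, so the
#' final angular resolution is `angle_step / 2^(n_iterations-1)`. The
#' identity is always a candidate, hence the final CCC is never below
#' the rigid-fit CCC.
#'
#' @param model the rigid-fit posed `atomic_model` (e.g. `$model` of a
#'   [rigid_fit()] result).
#' @param domains a [domain_assignment()].
#' @param map the target [density_map()].
#' @param resolution synthesis resolution, Angstrom.
#' @param n_iterations refinement rounds (default 4).
#' @param angle_range initial rotation-vector half-range per axis,
#'   degrees; 0 disables all movement (returns the rigid pose).
#' @param angle_step initial grid step, degrees.
#' @return a `fit_result` with `ccc`, `hinge_rotations` (degrees, total
#'   axis-angle magnitude for II and III), and the fitted `model`.
#' @export
hinge_flexible_fit <- function(model, domains, map, resolution,
                               n_iterations = 4, angle_range = 24,
                               angle_step = 8) {
  if (!inherits(domains, "domain_assignment"))
    abort("`domains` must be a domain_assignment")
  if (!is_atomic_model(model)) model <- atomic_model(model)
  pivots <- list(hinge_pivot(model, domains$hinge12),
                 hinge_pivot(model, domains$hinge13))
  moving <- list(c(domains$domain2, domains$hinge12),
                 c(domains$domain3, domains$hinge13))
  Racc <- list(diag(3), diag(3))
  cur <- model
  ccc <- model_map_ccc(map, cur, resolution)
  rng <- angle_range; stp <- angle_step
  for (it in seq_len(n_iterations)) {
    for (dmn in 1:2) {
      if (rng <= 0) next
      sel <- cur$residue_number %in% moving[[dmn]]
      if (!any(sel)) abort(sprintf("domain %s has no atoms", c("II", "III")[dmn]))
      grid <- sort_zero_first(seq(-rng, rng, by = stp))
      base_xyz <- model_coords(cur)[sel, , drop = FALSE]
      best <- list(ccc = ccc, R = diag(3))
      for (rx in grid) for (ry in grid) for (rz in grid) {
        vec <- c(rx, ry, rz)
        ang <- sqrt(sum(vec^2))
        R <- if (ang < 1e-12) diag(3) else axis_angle_to_matrix(vec, ang)
        cand <- cur
        xyz <- sweep(base_xyz, 2, pivots[[dmn]])
        xyz <- sweep(xyz %*% t(R), 2, pivots[[dmn]], `+`)
        cand$x[sel] <- xyz[, 1]; cand$y[sel] <- xyz[, 2]
        cand$z[sel] <- xyz[, 3]
        cc <- model_map_ccc(map, cand, resolution)
        if (cc > best$ccc) best <- list(ccc = cc, R = R, model = cand)
      }
      if (!is.null(best$model)) {
        cur <- best$model
        ccc <- best$ccc
        Racc[[dmn]] <- best$R %*% Racc[[dmn]]
      }
    }
    rng <- rng / 2; stp <- stp / 2
  }
  structure(list(
    rotation = c(phi = 0, theta = 0, psi = 0), shift = c(0, 0, 0),
    ccc = ccc,
    hinge_rotations = c(hinge12 = rotation_axis_angle(Racc[[1]])$angle,
                        hinge13 = rotation_axis_angle(Racc[[2]])$angle),
    model = cur), class = "fit_result")
}

kabsch <- function(P, Q) {
  # rotation R with Q ~ P %*% t(R) after centering (maps P onto Q)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Rotation of one domain between two models
#'
#' Superposes `model_b` onto `model_a` by least squares over the backbone
#' atoms of `fixed_domain`, then computes the optimal rotation carrying
#' the `moving_domain` of `model_a` onto that of (superposed) `model_b`;
#' returns its axis-angle magnitude in degrees. Atoms are matched by
#' (chain, residue number, atom name) over backbone atoms (N, CA, C, O).
#'
#' @param model_a,model_b `atomic_model`s sharing residue numbering.
#' @param fixed_domain,moving_domain integer vectors of residue numbers.
#' @return rotation angle in degrees.
#' @export
domain_rotation_between <- function(model_a, model_b, fixed_domain,
                                    moving_domain) {
  pair <- function(dom) {
    a <- domain_atoms(model_a, dom, backbone_only = TRUE)
    b <- domain_atoms(model_b, dom, backbone_only = TRUE)
    key <- function(m) paste(m$chain, m$residue_number, m$atom_name)
    common <- intersect(key(a), key(b))
    if (length(common) < 3)
      abort("fewer than 3 common backbone atoms in a domain")
    list(a = model_coords(a[match(common, key(a)), ]),
         b = model_coords(b[match(common, key(b)), ]))
  }
  fx <- pair(fixed_domain)
  # superpose b onto a over the fixed domain
  ca <- colMeans(fx$a); cb <- colMeans(fx$b)
  Rfix <- kabsch(sweep(fx$b, 2, cb), sweep(fx$a, 2, ca))
  mv <- pair(moving_domain)
  mv$b <- sweep(sweep(mv$b, 2, cb) %*% t(Rfix), 2, ca, `+`)
  cma <- colMeans(mv$a); cmb <- colMeans(mv$b)
  Rmov <- kabsch(sweep(mv$a, 2, cma), sweep(mv$b, 2, cmb))
  rotation_axis_angle(Rmov)$angle
}

#' Minimum distance between two residues' atom sets
#'
#' Minimum pairwise distance between named atom sets of two residues;
#' defaults probe a Glu-Lys salt bridge (side-chain carboxylate oxygens
#' vs the side-chain nitrogen).
#'
#' @param model an `atomic_model`.
#' @param chain_a,number_a,chain_b,number_b residue addresses.
#' @param atoms_a,atoms_b atom-name sets.
#' @return distance in Angstrom.
#' @export
residue_pair_distance <- function(model, chain_a, number_a, chain_b,
                                  number_b, atoms_a = c("OE1", "OE2"),
                                  atoms_b = "NZ") {
  pick <- function(ch, no, at, label) {
    m <- model[model$chain == ch & model$residue_number == no &
                 model$atom_name %in% at, , drop = FALSE]
    if (!nrow(m))
      abort(sprintf("residue %s%d: no atoms among {%s}", ch, no,
                    paste(at, collapse = ", ")))
    model_coords(m)
  }
  A <- pick(chain_a, number_a, atoms_a)
  B <- pick(chain_b, number_b, atoms_b)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Locate a lipid bilayer in the membrane band of a map
#'
#' Computes the radial mean-density profile around the vesicle centre
#' within `window`, requires two distinct dips (leaflets), and refines a
#' two-Gaussian (plus constant) least-squares fit to report the two
#' leaflet peak radii and their separation.
#'
#' @param map a [density_map()].
#' @param vesicle a [vesicle_model()] giving the centre (its radius
#'   centres the default window).
#' @param window length-2 radial window in Angstrom; default
#'   `radius + c(-80, 80)`.
#' @param dr radial bin width, Angstrom (default half a voxel).
#' @return list with `peak_radii` (ascending), `separation`,
#'   `amplitudes`, and the `profile` tibble (`r`, `density`).
#' @export
place_bilayer <- function(map, vesicle, window = NULL, dr = NULL) {
  stopifnot(is_density_map(map), inherits(vesicle, "vesicle_model"))
  if (is.null(window)) window <- vesicle$radius + c(-80, 80)
  if (is.null(dr)) dr <- map$voxel_size / 2
  prof <- radial_profile(map, vesicle$centre, window[1], window[2], dr)
  v <- prof$density
  n <- length(v)
  if (n < 7) abort("radial window too narrow")
  # local dips below the profile mean
  dips <- which(v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] <= v[3:n] &
                  v[2:(n - 1)] < mean(v)) + 1
  if (length(dips) > 1) dips <- dips[order(v[dips])]
  # enforce separation of at least 3 bins between the two dips
  if (length(dips) >= 2) {
    keep <- c(dips[1], dips[abs(dips - dips[1]) >= 3][1])
    dips <- keep[!is.na(keep)]
  }
  if (length(dips) < 2)
    abort("no bilayer: fewer than two distinct dips in the radial profile")
  p0 <- c(r1 = prof$r[min(dips)], r2 = prof$r[max(dips)],
          a1 = v[min(dips)] - max(v), a2 = v[max(dips)] - max(v),
          w = 4 * dr, c = max(v))
  fn <- function(p) {
    g <- p["c"] + p["a1"] * exp(-(prof$r - p["r1"])^2 / (2 * p["w"]^2)) +
      p["a2"] * exp(-(prof$r - p["r2"])^2 / (2 * p["w"]^2))
    sum((g - v)^2)
  }
  opt <- stats::optim(p0, fn, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  r12 <- sort(c(opt$par["r1"], opt$par["r2"]))
  list(peak_radii = unname(r12), separation = unname(diff(r12)),
       amplitudes = unname(c(opt$par["a1"], opt$par["a2"])),
       profile = prof)
}

#' Radial mean-density profile
#'
#' Mean map value in concentric shells around a centre.
#'
#' @param map a [density_map()].
#' @param centre Angstrom centre.
#' @param rmin,rmax radial range, Angstrom.
#' @param dr bin width, Angstrom.
#' @return tibble with `r` (bin centres) and `density`.
#' @export
radial_profile <- function(map, centre, rmin, rmax, dr) {
  d <- dim(map$grid)
  cx <- (0:(d[1] - 1)) * map$voxel_size + map$origin[1] - centre[1]
  cy <- (0:(d[2] - 1)) * map$voxel_size + map$origin[2] - centre[2]
  cz <- (0:(d[3] - 1)) * map$voxel_size + map$origin[3] - centre[3]
  r <- sqrt(outer(outer(cx^2, cy^2, `+`), cz^2, `+`))
  sel <- r >= rmin & r <= rmax
  bin <- floor((r[sel] - rmin) / dr)
  dens <- as.numeric(rowsum(as.numeric(map$grid[sel]), bin))
  cnt <- as.numeric(rowsum(rep(1, sum(sel)), bin))
  bins <- sort(unique(bin))
  tibble(r = rmin + (bins + 0.5) * dr, density = dens / cnt)
}
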