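# Shared fixture builders. Everything is generated in code; sizes are kept
# small so each builder runs in well under a second unless noted.

random_map <- function(n = 16, seed = 1, voxel_size = 4) {
  set.seed(seed)
  density_map(array(rnorm(n^3), c(n, n, n)), voxel_size)
}

small_template <- function(voxel_size = 7.6) {
  make_protein_template(length = 130, head_axes = c(60, 40),
                        tail_radius = 10, voxel_size = voxel_size)
}

# a modest scene + tomogram for pipeline-level tests
small_scene <- function(n = 60, radius = 400, seed = 11, snr = Inf,
                        tilt_mean = 33, tilt_sd = 17, box = 152) {
  ves <- vesicle_model(c(0, 0, 0), radius)
  scene <- place_particles(ves, n, min_centre_dist = 100,
                           tilt_mean = tilt_mean, tilt_sd = tilt_sd,
                           seed = seed, anchor_offset = 65)
  tmpl <- small_template()
  tomo <- render_tomogram(scene, tmpl, membrane_thickness = 50,
                          box_dim = box, voxel_size = 7.6)
  list(vesicle = ves, scene = scene, template = tmpl, tomogram = tomo)
}

# brute-force 26-neighbourhood minima scan (triple loop oracle)
brute_minima <- function(map, k_sd = 2) {
  g <- map$grid
  d <- dim(g)
  thr <- mean(g) - k_sd * sd(g)
  hits <- NULL
  for (k in 2:(d[3] - 1)) for (j in 2:(d[2] - 1)) for (i in 2:(d[1] - 1)) {
    v <- g[i, j, k]
    if (!(v < thr)) next
    nb <- g[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)]
    if (sum(v < nb) == 26) hits <- rbind(hits, c(i, j, k) - 1)
  }
  if (is.null(hits)) return(matrix(numeric(), 0, 3))
  voxel_to_map(map, hits)
}

# direct-sum FSC oracle on small maps
brute_fsc <- function(a, b) {
  A <- fft(a$grid); B <- fft(b$grid)
  d <- dim(a$grid); n <- d[1]
  idx <- function(m) { f <- c(0:floor((m - 1) / 2), -(ceiling((m - 1) / 2):1)); f }
  nmax <- floor(n / 2)
  num <- den_a <- den_b <- rep(0, nmax + 1)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    r <- round(sqrt(idx(d[1])[i]^2 + idx(d[2])[j]^2 + idx(d[3])[k]^2))
    if (r > nmax) next
    s <- r + 1
    num[s] <- num[s] + Re(A[i, j, k] * Conj(B[i, j, k]))
    den_a[s] <- den_a[s] + Mod(A[i, j, k])^2
    den_b[s] <- den_b[s] + Mod(B[i, j, k])^2
  }
  num / sqrt(den_a * den_b)
}

# toy two-domain-plus-core atomic model: three blobs of CA/backbone atoms
# around given centres, residues numbered per domain
toy_model <- function(seed = 1) {
  set.seed(seed)
  mk_dom <- function(centre, res_range, spread = 12) {
    n <- length(res_range)
    tibble::tibble(
      atom_name = rep(c("N", "CA", "C", "O"), n),
      residue_name = "ALA",
      residue_number = rep(res_range, each = 4),
      chain = "A",
      x = centre[1] + rnorm(4 * n, 0, spread),
      y = centre[2] + rnorm(4 * n, 0, spread),
      z = centre[3] + rnorm(4 * n, 0, spread))
  }
  atomic_model(dplyr::bind_rows(
    mk_dom(c(0, 0, 0), 1:20),        # domain I
    mk_dom(c(34, 0, 0), 31:50),      # domain II
    mk_dom(c(0, 34, 0), 61:80)))     # domain III
}

toy_domains <- function() {
  domain_assignment(domain1 = 1:20, domain2 = 31:50, domain3 = 61:80,
                    hinge12 = 21:30, hinge13 = 51:60)
}

# toy model including hinge residues (between the domain blobs)
toy_model_with_hinges <- function(seed = 1) {
  m <- toy_model(seed)
  hinge <- function(res_range, from, to) {
    n <- length(res_range)
    fr <- seq(0.3, 0.7, length.out = n)
    tibble::tibble(
      atom_name = "CA", residue_name = "GLY",
      residue_number = res_range, chain = "A",
      x = from[1] + fr * (to[1] - from[1]),
      y = from[2] + fr * (to[2] - from[2]),
      z = from[3] + fr * (to[3] - from[3]))
  }
  atomic_model(dplyr::bind_rows(
    tibble::as_tibble(m)[, c("atom_name", "residue_name", "residue_number",
                             "chain", "x", "y", "z")],
    hinge(21:30, c(0, 0, 0), c(34, 0, 0)),
    hinge(51:60, c(0, 0, 0), c(0, 34, 0))))
}

# Synthetic stand-in for the deposited pre/post-conformation protomer pair:
# a toy three-domain model whose "fitted" state carries a 3.8 A Glu245-Lys400
# contact, and whose "crystal" state derives from it by known hinge rotations
# of -16 deg (domain II, axis (0,1,1)) and -19 deg (domain III, axis (0,0,-1)),
# opening the pair to ~12.5 A. Labelled synthetic: it stands in for reference
# structures that are not shipped with the package.
synthetic_conformer_pair <- function() {
  set.seed(42)
  mk_dom <- function(centre, res_range, spread = 10) {
    n <- length(res_range)
    tibble::tibble(atom_name = rep(c("N", "CA", "C", "O"), n),
                   residue_name = "ALA",
                   residue_number = rep(res_range, each = 4), chain = "A",
                   x = centre[1] + rnorm(4 * n, 0, spread),
                   y = centre[2] + rnorm(4 * n, 0, spread),
                   z = centre[3] + rnorm(4 * n, 0, spread))
  }
  hinge <- function(res, from, to) {
    fr <- seq(0.3, 0.7, length.out = length(res))
    tibble::tibble(atom_name = "CA", residue_name = "GLY",
                   residue_number = res, chain = "A",
                   x = from[1] + fr * (to[1] - from[1]),
                   y = from[2] + fr * (to[2] - from[2]),
                   z = from[3] + fr * (to[3] - from[3]))
  }
  glu <- tibble::tibble(atom_name = c("CA", "CB", "OE1", "OE2"),
                        residue_name = "GLU", residue_number = 245,
                        chain = "A", x = c(26, 27, 28, 28.5),
                        y = c(20, 22, 24, 23), z = c(0, 1, 2, 3.5))
  lys <- tibble::tibble(atom_name = c("CA", "NZ"), residue_name = "LYS",
                        residue_number = 400, chain = "A",
                        x = c(20, 30), y = c(28, 26.4), z = c(0, 4.3))
  fitted <- atomic_model(dplyr::bind_rows(
    mk_dom(c(0, 0, 0), 1:40), mk_dom(c(40, 12, 0), 242:280),
    mk_dom(c(12, 40, 0), 382:420),
    hinge(230:241, c(0, 0, 0), c(40, 12, 0)),
    hinge(370:381, c(0, 0, 0), c(12, 40, 0)), glu, lys))
  doms <- list(d1 = 1:40, d2 = 242:280, d3 = 382:420,
               h12 = 230:241, h13 = 370:381)
  p12 <- subtomo:::hinge_pivot(fitted, doms$h12)
  p13 <- subtomo:::hinge_pivot(fitted, doms$h13)
  rot_about <- function(model, residues, pivot, axis, ang) {
    sel <- model$residue_number %in% residues
    R <- axis_angle_to_matrix(axis, ang)
    xyz <- as.matrix(model[sel, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, `+`)
    model$x[sel] <- xyz[, 1]; model$y[sel] <- xyz[, 2]
    model$z[sel] <- xyz[, 3]
    model
  }
  crystal <- rot_about(fitted, c(doms$d2, 245, doms$h12), p12, c(0, 1, 1), -16)
  crystal <- rot_about(crystal, c(doms$d3, 400, doms$h13), p13, c(0, 0, -1), -19)
  list(fitted = fitted, crystal = crystal, domains = doms)
}

# shared acceptance-scale pipeline runs, computed once per test session
acceptance_cache <- local({
  env <- new.env()
  function(name, builder) {
    if (is.null(env[[name]])) env[[name]] <- builder()
    env[[name]]
  }
})

run_acceptance_pipeline <- function(cfg) {
  sim <- stage_simulate(cfg)
  pick <- stage_pick(sim$tomogram, cfg)
  align <- stage_align(pick$particles, sim$tomogram, cfg, pick$vesicle,
                       wedge = sim$geometry)
  stats <- stage_stats(align, pick$vesicle, sim$tomogram, cfg)
  list(sim = sim, pick = pick, align = align, stats = stats)
}
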