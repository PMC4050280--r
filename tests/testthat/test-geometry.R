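test_that("tilt statistics recover planted angles exactly", {
  ves <- vesicle_model(c(0, 0, 0), 500)
  # all particles exactly radial: zero tilt
  s0 <- place_particles(ves, 40, min_centre_dist = 100, tilt_mean = 0,
                        tilt_sd = 0, seed = 3)
  t0 <- tilt_statistics(s0$particles, ves)
  expect_equal(attr(t0, "mean"), 0, tolerance = 1e-6)
  expect_equal(attr(t0, "sd"), 0, tolerance = 1e-6)
  # planted known tilts recovered to < 0.5 degree
  s1 <- place_particles(ves, 200, min_centre_dist = 100, tilt_mean = 33,
                        tilt_sd = 17, seed = 4)
  t1 <- tilt_statistics(s1$particles, ves)
  expect_lt(max(abs(t1$tilt - s1$truth$tilt)), 0.5)
  # azimuths are recovered too
  dif <- (t1$azimuth - s1$truth$azimuth + 180) %% 360 - 180
  expect_lt(max(abs(dif)), 0.5)
  expect_error(
    tilt_statistics(particle_table(tibble::tibble(x = 0, y = 0, z = 0)),
                    ves), "centre")
})

test_that("uniform azimuths pass the Rayleigh test in most runs", {
  set.seed(91)
  rejections <- 0
  for (i in 1:100) {
    az <- runif(150, 0, 2 * pi)
    p <- subtomo:::rayleigh_test(az)$p.value
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 10)
  # a concentrated sample is firmly rejected
  conc <- subtomo:::rayleigh_test(rnorm(150, 1, 0.2))
  expect_lt(conc$p.value, 1e-6)
})

test_that("nearest-neighbour distances equal the exhaustive oracle", {
  two <- particle_table(tibble::tibble(id = 1:2, x = c(0, 100), y = 0, z = 0))
  nn2 <- nn_distances(two)
  expect_equal(nn2$nn_dist, c(100, 100))
  # hard-core scene: reported minimum >= the exclusion distance
  ves <- vesicle_model(c(0, 0, 0), 600)
  s <- place_particles(ves, 300, min_centre_dist = 100, seed = 7)
  nns <- nn_distances(s$particles)
  expect_gte(attr(nns, "min"), 100)
  # O(n^2) double-loop oracle, n = 500
  set.seed(8)
  pts <- particle_table(tibble::tibble(id = 1:500,
                                       x = runif(500, 0, 900),
                                       y = runif(500, 0, 900),
                                       z = runif(500, 0, 900)))
  got <- nn_distances(pts)
  p <- as.matrix(pts[, c("x", "y", "z")])
  want <- sapply(seq_len(500), function(i) {
    best <- Inf
    for (j in seq_len(500)) if (j != i)
      best <- min(best, sqrt(sum((p[i, ] - p[j, ])^2)))
    best
  })
  expect_equal(got$nn_dist, want, tolerance = 1e-12)
  expect_error(nn_distances(two[1, ]), "at least 2")
})

test_that("back-plotting composites the average at every pose", {
  tmpl <- small_template()
  vs <- 7.6
  box <- 64
  membrane <- density_map(array(0, rep(box, 3)), vs,
                          rep(-(box - 1) / 2 * vs, 3))
  avg <- extract_subvolume(
    density_map({g <- array(0, rep(box, 3))
                 cpp_add_rotated(g, dim(g), tmpl$map$grid, dim(tmpl$map$grid),
                                 diag(3),
                                 (membrane$origin - tmpl$map$origin) / vs, 1)
                 g}, vs, membrane$origin), c(0, 0, 0), 24)
  # single particle at the centre with identity pose: interior equals avg
  pt <- particle_table(tibble::tibble(id = 1, x = 0, y = 0, z = 0))
  comp <- backplot(avg, membrane, pt)
  inner <- extract_subvolume(comp, c(0, 0, 0), 24)
  expect_equal(inner$grid, avg$grid, tolerance = 0.15)
  # empty particle table: membrane-only composite
  comp0 <- backplot(avg, membrane, pt[0, ])
  expect_identical(comp0$grid, membrane$grid)
  # out-of-bounds placement errors with the offending id
  far <- particle_table(tibble::tibble(id = 7, x = 1e5, y = 0, z = 0))
  expect_error(backplot(avg, membrane, far), "7")
})

test_that("back-plot of a truth-posed scene matches the tomogram", {
  sc <- small_scene(n = 40, radius = 400, seed = 17, box = 144)
  vs <- 7.6
  membrane <- density_map(array(0, dim(sc$tomogram$grid)), vs,
                          sc$tomogram$origin)
  cpp_add_shell(membrane$grid, dim(membrane$grid),
                as.numeric(map_to_voxel(membrane, c(0, 0, 0))),
                400 / vs, 25 / vs, -1, 2L)
  avg <- extract_subvolume(
    density_map({g <- array(0, dim(sc$tomogram$grid))
                 cpp_add_rotated(g, dim(g), sc$template$map$grid,
                                 dim(sc$template$map$grid), diag(3),
                                 (sc$tomogram$origin - sc$template$map$origin) / vs, 1)
                 g}, vs, sc$tomogram$origin), c(0, 0, 0), 24)
  comp <- backplot(avg, membrane, sc$scene$particles)
  expect_gt(cor(as.numeric(comp$grid), as.numeric(sc$tomogram$grid)), 0.9)
})

test_that("volume thresholding encloses the requested volume", {
  # solid dark sphere of radius 27.5 A: level encloses the analytic volume
  vs <- 2
  n <- 48
  ax <- (0:(n - 1) - (n - 1) / 2) * vs
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  grid <- array(ifelse(r <= 27.5, -1, 0) * (1 - r / 80), dim(r))
  m <- density_map(array(grid, dim(r)), vs)
  target <- 4 / 3 * pi * 27.5^3   # ~87,100 A^3
  lev <- threshold_by_volume(m, target)
  expect_lt(abs(attr(lev, "achieved_volume") - target) / target, 0.02)
  expect_lte(max(r[m$grid <= as.numeric(lev)]), 27.5 + vs)
  # unreachable target errors
  expect_error(threshold_by_volume(m, n^3 * vs^3 + 1), "unreachable")
  # enclosed volume is monotone in the target
  t1 <- threshold_by_volume(m, 20000)
  t2 <- threshold_by_volume(m, 60000)
  expect_lte(attr(t1, "achieved_volume"), attr(t2, "achieved_volume"))
})

test_that("extent measurement recovers the phantom dimensions", {
  tmpl <- small_template()
  pad <- 31
  g <- array(0, rep(pad, 3))
  d <- dim(tmpl$map$grid)
  o <- (pad - d[1]) %/% 2
  g[o + 1:d[1], o + 1:d[2], o + 1:d[3]] <- tmpl$map$grid
  m <- density_map(g, tmpl$map$voxel_size,
                   rep(-(pad - 1) / 2 * tmpl$map$voxel_size, 3))
  iso <- threshold_by_volume(m, 87000)
  ext <- measure_extents(m, as.numeric(iso), distal_axis = c(0, 0, 1))
  expect_lt(abs(ext$length - 130), 2 * 7.6)
  expect_lt(abs(ext$cross_axes[1] - 60), 2 * 7.6)
  expect_lt(abs(ext$cross_axes[2] - 40), 2 * 7.6)
  # a sphere has three equal extents
  vs <- 4; n <- 32
  ax <- (0:(n - 1) - (n - 1) / 2) * vs
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  sph <- density_map(array(ifelse(r <= 40, -1, 0), dim(r)), vs)
  es <- measure_extents(sph, -0.5)
  expect_lt(diff(range(c(es$length, es$cross_axes))), vs + 1e-9)
  expect_error(measure_extents(sph, -2), "empty")
})

test_that("landmark-membrane histograms equal direct recomputation", {
  ves <- vesicle_model(c(0, 0, 0), 900)
  s <- place_particles(ves, 500, min_centre_dist = 80, tilt_mean = 0,
                       tilt_sd = 0, seed = 9, anchor_offset = 65)
  # anchor landmark (template frame z = -65): distance 0 for all
  res <- landmark_membrane_histogram(s$particles, rbind(c(0, 0, -65)), ves)
  expect_lt(max(res$distances$dist), 1e-6)
  # head-apex landmark at +65: radial particles put it 130 A out
  res2 <- landmark_membrane_histogram(s$particles, rbind(c(0, 0, 65)), ves)
  expect_equal(res2$distances$dist, rep(130, 500), tolerance = 1e-6)
  # tilted scene: equals per-particle brute force
  st <- place_particles(ves, 500, min_centre_dist = 80, tilt_mean = 33,
                        tilt_sd = 17, seed = 10)
  lm <- rbind(c(10, -6, 30), c(0, 0, 65))
  got <- landmark_membrane_histogram(st$particles, lm, ves, bin_width = 5)
  p <- st$particles
  for (l in 1:2) {
    want <- sapply(seq_len(nrow(p)), function(i) {
      R <- euler_to_matrix(p$phi[i], p$theta[i], p$psi[i])
      q <- c(p$x[i], p$y[i], p$z[i]) + as.numeric(R %*% lm[l, ])
      abs(sqrt(sum(q^2)) - 900)
    })
    expect_equal(got$distances$dist[got$distances$landmark == l], want,
                 tolerance = 1e-9)
  }
  # histogram counts add up
  expect_equal(sum(got$histogram$count), 2 * 500)
})
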