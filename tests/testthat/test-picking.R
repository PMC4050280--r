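test_that("preprocess bins by block mean and rescales the geometry", {
  m <- random_map(128, seed = 2, voxel_size = 3.8)
  b <- preprocess(m, bin_factor = 4, gaussian_sigma = 0)
  expect_equal(dim(b$grid), c(32, 32, 32))
  expect_equal(b$voxel_size, 15.2)
  # global mean preserved by block-mean binning
  expect_equal(mean(b$grid), mean(m$grid), tolerance = 1e-12)
  # binned voxel 0 centre = mean of the original centres it covers
  expect_equal(b$origin, m$origin + 1.5 * 3.8)
  # identity case
  id <- preprocess(m, bin_factor = 1, gaussian_sigma = 0)
  expect_equal(id$grid, m$grid)
  expect_error(preprocess(m, bin_factor = 0), "integer")
})

test_that("detect_minima finds exactly the planted wells", {
  g <- array(0, c(32, 32, 32))
  set.seed(7)
  pts <- cbind(sample(3:30, 10), sample(3:30, 10), sample(3:30, 10))
  pts <- pts[!duplicated(pts), , drop = FALSE][1:10, ]
  for (r in 1:10) g[pts[r, 1], pts[r, 2], pts[r, 3]] <- -1
  m <- density_map(g, 4)
  hits <- detect_minima(m, k_sd = 2)
  expect_equal(nrow(hits), 10)
  want <- voxel_to_map(m, pts - 1)
  expect_equal(hits[order(hits[, 1], hits[, 2], hits[, 3]), ],
               want[order(want[, 1], want[, 2], want[, 3]), ],
               ignore_attr = TRUE)
  # constant map: zero detections, not an error
  expect_equal(nrow(detect_minima(density_map(array(1, c(8, 8, 8)), 1))), 0)
})

test_that("detect_minima equals the exhaustive triple-loop scan", {
  for (seed in c(1, 2)) {
    m <- random_map(32, seed = seed)
    got <- detect_minima(m, k_sd = 2)
    want <- brute_minima(m, k_sd = 2)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                 want[order(want[, 1], want[, 2], want[, 3]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("membrane proximity filter keeps points within d_max of a shell", {
  ves <- vesicle_model(c(0, 0, 0), 300)
  pts <- rbind(c(0, 0, 300 + 140),   # kept
               c(0, 0, 300 + 160),   # rejected
               c(0, 300, 0),         # on the surface: kept
               c(0, 0, 120))         # deep inside: rejected
  kept <- filter_membrane_proximity(pts, ves, d_max = 150)
  expect_equal(nrow(kept), 2)
  expect_true(any(abs(kept[, 3] - 440) < 1e-9))
  expect_true(any(abs(kept[, 2] - 300) < 1e-9))
  expect_error(filter_membrane_proximity(pts, list(), 150), "non-empty")

  # brute-force oracle on 1000 random points, two vesicles
  set.seed(31)
  vlist <- list(vesicle_model(c(0, 0, 0), 250),
                vesicle_model(c(400, 0, 0), 150))
  p <- matrix(runif(3000, -400, 700), ncol = 3)
  kept2 <- filter_membrane_proximity(p, vlist, d_max = 100)
  direct <- sapply(seq_len(nrow(p)), function(i) {
    d1 <- abs(sqrt(sum(p[i, ]^2)) - 250)
    d2 <- abs(sqrt(sum((p[i, ] - c(400, 0, 0))^2)) - 150)
    min(d1, d2) <= 100
  })
  expect_equal(nrow(kept2), sum(direct))
})

test_that("initial orientations are the outward membrane normals", {
  ves <- vesicle_model(c(0, 0, 0), 200)
  pt <- init_orientations(rbind(c(0, 0, 260)), ves)
  expect_equal(unname(c(pt$phi, pt$theta, pt$psi)), c(0, 0, 0),
               tolerance = 1e-9)
  set.seed(13)
  pos <- matrix(rnorm(300), ncol = 3)
  pos <- pos / sqrt(rowSums(pos^2)) * runif(100, 180, 260)
  pt <- init_orientations(pos, ves)
  for (i in seq_len(nrow(pt))) {
    R <- euler_to_matrix(pt$phi[i], pt$theta[i], pt$psi[i])
    u <- as.numeric(R %*% c(0, 0, 1))
    n <- pos[i, ] / sqrt(sum(pos[i, ]^2))
    expect_gt(sum(u * n), 1 - 1e-6)
  }
  expect_error(init_orientations(rbind(c(0, 0, 0)), ves), "centre")
})

test_that("orientation init matches ground truth on an untilted scene", {
  ves <- vesicle_model(c(0, 0, 0), 400)
  s <- place_particles(ves, 30, min_centre_dist = 120, tilt_mean = 0,
                       tilt_sd = 0, seed = 5, anchor_offset = 65)
  pos <- as.matrix(s$particles[, c("x", "y", "z")])
  init <- init_orientations(pos, ves)
  # the long axis must match; the in-plane spin is a convention (psi = 0
  # for the initializer, arbitrary in the generator)
  for (i in 1:30) {
    Rt <- euler_to_matrix(s$particles$phi[i], s$particles$theta[i],
                          s$particles$psi[i])
    Ri <- euler_to_matrix(init$phi[i], init$theta[i], init$psi[i])
    ax_t <- as.numeric(Rt %*% c(0, 0, 1))
    ax_i <- as.numeric(Ri %*% c(0, 0, 1))
    expect_lt(acos(min(1, sum(ax_t * ax_i))) * 180 / pi, 1)
  }
})

test_that("sphere fitting recovers exact and noisy spheres", {
  set.seed(17)
  dirs <- matrix(rnorm(1500), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  exact <- sweep(dirs * 320, 2, c(5, -8, 12), `+`)
  v <- fit_vesicle_sphere(exact)
  expect_equal(v$radius, 320, tolerance = 1e-9)
  expect_equal(v$centre, c(5, -8, 12), tolerance = 1e-9)
  noisy <- exact + matrix(rnorm(1500, 0, 2), ncol = 3)
  v2 <- fit_vesicle_sphere(noisy)
  expect_lt(abs(v2$radius - 320), 1)
  expect_error(fit_vesicle_sphere(dirs[1:3, ]), "4 points")
  flat <- cbind(runif(20), runif(20), 0)
  expect_error(fit_vesicle_sphere(flat), "coplanar|degenerate")
})

test_that("sphere fitting from a rendered map recovers the vesicle", {
  sc <- small_scene(n = 40, radius = 400, seed = 19)
  v <- fit_vesicle_sphere(sc$tomogram)
  expect_lt(abs(v$radius - 400), 12)
  expect_lt(sqrt(sum(v$centre^2)), 10)
})

test_that("picking recovers planted particles on a noiseless scene", {
  sc <- small_scene(n = 60, radius = 400, seed = 23)
  picked <- pick_particles(sc$tomogram, sc$vesicle, bin_factor = 2,
                           gaussian_sigma = 0.5, k_sd = 2, d_max = 150)
  # expected pick location: the density centroid of the phantom
  truth <- as.matrix(sc$scene$particles[, c("x", "y", "z")])
  cz <- sc$template$centroid_z
  expect_centres <- t(sapply(seq_len(nrow(truth)), function(i) {
    R <- euler_to_matrix(sc$scene$particles$phi[i],
                         sc$scene$particles$theta[i],
                         sc$scene$particles$psi[i])
    truth[i, ] + as.numeric(R %*% c(0, 0, cz))
  }))
  pp <- as.matrix(picked[, c("x", "y", "z")])
  binned_voxel <- 2 * 7.6
  hit <- sapply(seq_len(nrow(expect_centres)), function(i) {
    min(sqrt(rowSums(sweep(pp, 2, expect_centres[i, ])^2)))
  })
  expect_gte(mean(hit <= 1.8 * binned_voxel), 0.95)
})

test_that("duplicate picks collapse to the highest-scoring particle", {
  pt <- particle_table(tibble::tibble(
    id = 1:4, x = c(0, 5, 200, 203), y = 0, z = 0,
    cc = c(0.9, 0.5, 0.2, 0.7)))
  out <- deduplicate_particles(pt, min_dist = 50)
  expect_equal(out$id, c(1L, 4L))
})
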