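test_that("sub-volume extraction relocates and round-trips content", {
  m <- random_map(32, seed = 4, voxel_size = 2)
  # integer-voxel crop (odd box: integer corner): exact relocation
  centre <- voxel_to_map(m, c(15, 15, 15))
  sub <- extract_subvolume(m, centre, 9)
  expect_identical(sub$grid, m$grid[12:20, 12:20, 12:20])
  # sub-voxel shift there and back on a band-limited map: interior agrees
  # to interpolation error
  ms <- gaussian_filter(m, 1.5)
  d <- c(0.4, -0.3, 0.2) * m$voxel_size
  s1 <- extract_subvolume(ms, centre + d, 13, pad = TRUE)
  s2 <- extract_subvolume(s1, centre, 9, pad = TRUE)
  expect_lt(max(abs(s2$grid[3:7, 3:7, 3:7] -
                      extract_subvolume(ms, centre, 9)$grid[3:7, 3:7, 3:7])),
            0.1 * diff(range(ms$grid)))
  # bounds
  expect_error(extract_subvolume(m, voxel_to_map(m, c(1, 15, 15)), 9),
               "bounds")
  expect_error(extract_subvolume(m, centre, 64), "exceeds")
})

test_that("cc_score matches the direct correlation formula", {
  a <- random_map(16, seed = 5)
  b <- random_map(16, seed = 6)
  expect_equal(cc_score(a, a), 1.0, tolerance = 1e-12)
  neg <- a; neg$grid <- -neg$grid
  expect_equal(cc_score(a, neg), -1.0, tolerance = 1e-12)
  got <- cc_score(a, b)
  want <- cor(as.numeric(a$grid), as.numeric(b$grid))
  expect_equal(got, want, tolerance = 1e-12)
  # weighted version against direct weighted computation
  set.seed(8)
  w <- array(runif(16^3), rep(16, 3))
  got_w <- cc_score(a, b, mask = w)
  wm <- function(x) sum(w * x) / sum(w)
  av <- a$grid - wm(a$grid); bv <- b$grid - wm(b$grid)
  want_w <- sum(w * av * bv) / sqrt(sum(w * av^2) * sum(w * bv^2))
  expect_equal(got_w, want_w, tolerance = 1e-12)
  # zero-variance region errors
  flat <- density_map(array(1, rep(16, 3)), 4)
  expect_error(cc_score(a, flat), "zero variance")
})

test_that("above-mean selection is strict and matches recomputation", {
  pt <- particle_table(tibble::tibble(id = 1:4, x = 0, y = 0, z = 1:4,
                                      cc = c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(nrow(select_above_mean(pt)), 2)
  eq <- particle_table(tibble::tibble(id = 1:3, x = 0, y = 0, z = 1:3,
                                      cc = 0.5))
  expect_equal(nrow(select_above_mean(eq)), 0)
  # oracle on a 1973-score vector (the picked-particle count scale)
  set.seed(41)
  cc <- runif(1973, -0.2, 0.9)
  big <- particle_table(tibble::tibble(id = seq_along(cc), x = 0, y = 0,
                                       z = seq_along(cc), cc = cc))
  expect_equal(nrow(select_above_mean(big)), sum(cc > mean(cc)))
  nacc <- particle_table(tibble::tibble(id = 1:2, x = 0, y = 0, z = 1:2,
                                        cc = c(0.5, NA)))
  expect_error(select_above_mean(nacc), "cc")
})

test_that("even/odd split partitions by 0-based index parity", {
  mk <- function(n) particle_table(tibble::tibble(id = seq_len(n), x = 0,
                                                  y = 0, z = seq_len(n)))
  s801 <- split_even_odd(mk(801))
  expect_equal(nrow(s801$even), 401)
  expect_equal(nrow(s801$odd), 400)
  expect_equal(s801$even$id[1:3], c(1L, 3L, 5L))
  s2 <- split_even_odd(mk(2))
  expect_equal(c(nrow(s2$even), nrow(s2$odd)), c(1L, 1L))
  s0 <- split_even_odd(mk(0)[0, ])
  expect_equal(c(nrow(s0$even), nrow(s0$odd)), c(0L, 0L))
})

test_that("averaging identical planted copies recovers the template", {
  tmpl <- small_template()
  box <- 96; vs <- 7.6
  grid <- array(0, rep(box, 3)); orig <- rep(-(box - 1) / 2 * vs, 3)
  set.seed(9)
  spots <- rbind(c(-220, -220, 0), c(220, -220, 0), c(-220, 220, 0),
                 c(220, 220, 0), c(0, 0, -220), c(0, 0, 220))
  poses <- lapply(1:6, function(i)
    list(eul = c(runif(1, -180, 180), runif(1, 0, 60), runif(1, -180, 180)),
         pos = spots[i, ] + runif(3, -10, 10)))
  for (p in poses) {
    R <- euler_to_matrix(p$eul[1], p$eul[2], p$eul[3])
    tv <- (as.numeric(t(R) %*% (orig - p$pos)) - tmpl$map$origin) / vs
    cpp_add_rotated(grid, dim(grid), tmpl$map$grid, dim(tmpl$map$grid),
                    t(R) , tv, 1)
  }
  tomo <- density_map(grid, vs, orig)
  pt <- particle_table(tibble::tibble(
    id = 1:6,
    x = sapply(poses, function(p) p$pos[1]),
    y = sapply(poses, function(p) p$pos[2]),
    z = sapply(poses, function(p) p$pos[3]),
    phi = sapply(poses, function(p) p$eul[1]),
    theta = sapply(poses, function(p) p$eul[2]),
    psi = sapply(poses, function(p) p$eul[3])))
  avg <- average_particles(pt, tomo, 24)
  # compare to the template resampled into the same box
  ref <- extract_subvolume(
    density_map({g <- array(0, rep(box, 3))
                 cpp_add_rotated(g, dim(g), tmpl$map$grid, dim(tmpl$map$grid),
                                 diag(3), (orig - tmpl$map$origin) / vs, 1)
                 g}, vs, orig), c(0, 0, 0), 24)
  expect_gt(cor(as.numeric(avg$grid), as.numeric(ref$grid)), 0.98)
  # single particle: returns that (rotated) sub-volume
  one <- average_particles(pt[1, ], tomo, 24)
  expect_gt(cor(as.numeric(one$grid), as.numeric(ref$grid)), 0.95)
  expect_error(average_particles(pt[0, ], tomo, 24), "empty")
})

test_that("SNR of an average of N noisy copies grows as sqrt(N)", {
  tmpl <- small_template()
  vs <- tmpl$map$voxel_size
  box <- 24
  base <- extract_subvolume(
    density_map({g <- array(0, rep(64, 3))
                 o <- rep(-(64 - 1) / 2 * vs, 3)
                 cpp_add_rotated(g, dim(g), tmpl$map$grid, dim(tmpl$map$grid),
                                 diag(3), (o - tmpl$map$origin) / vs, 1)
                 g}, vs, rep(-(64 - 1) / 2 * vs, 3)), c(0, 0, 0), box)
  sig <- base$grid
  set.seed(77)
  ns <- c(2, 4, 8, 16, 32)
  snrs <- sapply(ns, function(n) {
    avg <- Reduce(`+`, lapply(seq_len(n), function(i)
      sig + array(rnorm(length(sig), 0, 1), dim(sig)))) / n
    sd(sig) / sd(avg - sig)
  })
  fit <- coef(lm(log(snrs) ~ log(ns)))
  expect_lt(abs(fit[2] - 0.5), 0.1)
})

test_that("alignment recovers a planted pose perturbation", {
  tmpl <- small_template()
  vs <- 7.6; box <- 64
  true_eul <- c(25, 40, -60); true_pos <- c(12, -9, 5)
  grid <- array(0, rep(box, 3)); orig <- rep(-(box - 1) / 2 * vs, 3)
  R <- euler_to_matrix(true_eul[1], true_eul[2], true_eul[3])
  tv <- (as.numeric(t(R) %*% (orig - true_pos)) - tmpl$map$origin) / vs
  cpp_add_rotated(grid, dim(grid), tmpl$map$grid, dim(tmpl$map$grid),
                  t(R), tv, 1)
  tomo <- density_map(grid, vs, orig)
  g2 <- array(0, rep(box, 3))
  cpp_add_rotated(g2, dim(g2), tmpl$map$grid, dim(tmpl$map$grid), diag(3),
                  (orig - tmpl$map$origin) / vs, 1)
  ref <- extract_subvolume(density_map(g2, vs, orig), c(0, 0, 0), 24)
  init <- particle_table(tibble::tibble(
    id = 1, x = true_pos[1] - 8, y = true_pos[2] + 6, z = true_pos[3] - 5,
    phi = true_eul[1] + 10, theta = true_eul[2] - 12, psi = true_eul[3] + 8))
  sched <- alignment_schedule(half_range = c(15, 10, 5, 2),
                              step = c(5, 10 / 3, 5 / 3, 2 / 3),
                              shift = vs, lowpass = Inf, mask = FALSE)
  out <- align_particles(init, tomo, sched, box_size = 24, reference = ref,
                         update_reference = FALSE)
  Rr <- euler_to_matrix(out$phi, out$theta, out$psi)
  expect_lt(rotation_angle_between(R, Rr), 2 / 3 + 1)   # final step + slack
  expect_lt(sqrt(sum((c(out$x, out$y, out$z) - true_pos)^2)), vs)
  expect_gt(out$cc, 0.95)
  # aligning the reference against itself: identity pose, cc ~ 1
  self <- particle_table(tibble::tibble(id = 1, x = 0, y = 0, z = 0))
  sched1 <- alignment_schedule(half_range = 10, step = 5, shift = vs,
                               lowpass = Inf, mask = FALSE)
  out2 <- align_particles(self, tomo, sched1, box_size = 24,
                          reference = extract_subvolume(tomo, c(0, 0, 0), 24),
                          update_reference = FALSE, max_total_shift = 0.1)
  expect_equal(c(out2$phi, out2$theta, out2$psi), c(0, 0, 0),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_gt(out2$cc, 0.999)
  expect_error(align_particles(init[0, ], tomo, sched, box_size = 24),
               "empty")
})

test_that("mean cc is non-decreasing on a benign fixed-cutoff run", {
  sc <- small_scene(n = 25, radius = 300, seed = 31, box = 112)
  init <- init_orientations(as.matrix(sc$scene$particles[, c("x", "y", "z")]),
                            sc$vesicle)
  sched <- alignment_schedule(half_range = c(20, 15, 10), step = c(20, 15, 10) / 3,
                              shift = 7.6, lowpass = 1 / 30, mask = TRUE)
  out <- align_particles(init, sc$tomogram, sched, box_size = 24,
                         membrane_exclude = sc$vesicle)
  log <- attr(out, "run_log")
  expect_true(all(diff(log$mean_cc) > -0.02))
})

test_that("FSC behaves on identical, independent and oracle inputs", {
  m <- random_map(32, seed = 12)
  self <- compute_fsc(m, m)
  expect_true(all(abs(self$fsc - 1) < 1e-9))
  expect_equal(self$fsc[1], 1)
  # independent white noise decorrelates beyond the first shells
  a <- random_map(64, seed = 13); b <- random_map(64, seed = 14)
  f <- compute_fsc(a, b)
  expect_lt(max(abs(f$fsc[-(1:4)])), 0.1)
  # brute-force double-sum oracle at 16^3
  x <- random_map(16, seed = 15); y <- random_map(16, seed = 16)
  got <- compute_fsc(x, y)
  want <- brute_fsc(x, y)
  expect_equal(got$fsc, want, tolerance = 1e-10)
  expect_error(compute_fsc(m, a), "dims")
})

test_that("resolution_at interpolates the first downward crossing", {
  curve <- tibble::tibble(frequency = c(0, 0.01, 0.02, 0.03),
                          fsc = c(1, 0.9, 0.5, 0.1))
  r <- resolution_at(curve, 0.5)
  expect_equal(as.numeric(r), 50)
  expect_true(attr(r, "crossed"))
  # 0.5 crossing frequency <= 0.143 crossing frequency (36 A >= 22 A ordering)
  set.seed(19)
  for (i in 1:10) {
    v <- sort(runif(20, 0, 1), decreasing = TRUE)
    cv <- tibble::tibble(frequency = seq(0, 0.065, length.out = 20), fsc = v)
    r05 <- resolution_at(cv, 0.5); r0143 <- resolution_at(cv, 0.143)
    expect_gte(as.numeric(r05), as.numeric(r0143) - 1e-9)
  }
  ones <- tibble::tibble(frequency = seq(0, 0.065, length.out = 20), fsc = 1)
  rn <- resolution_at(ones, 0.5)
  expect_false(attr(rn, "crossed"))
  expect_equal(as.numeric(rn), 1 / 0.065, tolerance = 1e-9)
  expect_error(resolution_at(ones[0, ], 0.5), "empty")
  expect_error(resolution_at(ones, 1.5), "threshold")
})

test_that("FSC-matched Gaussian low-pass has the fitted width", {
  vs <- 4
  # flat curve: unchanged
  m <- random_map(32, seed = 21, voxel_size = vs)
  flat <- tibble::tibble(frequency = (0:16) / (32 * vs), fsc = 1)
  expect_identical(lowpass_by_fsc(m, flat)$grid, m$grid)
  # impulse -> gaussian blob of predicted width
  sigf <- 0.02
  freq <- (0:16) / (32 * vs)
  curve <- tibble::tibble(frequency = freq, fsc = exp(-freq^2 / (2 * sigf^2)))
  imp <- density_map(array(0, rep(32, 3)), vs)
  imp$grid[17, 17, 17] <- 1
  out <- lowpass_by_fsc(imp, curve)
  expect_equal(attr(out, "sigma_f"), sigf, tolerance = 0.02)
  # real-space SD of the blob = 1/(2 pi sigma_f)
  ax <- (0:31 - 16) * vs
  xg <- array(rep(ax, times = 32 * 32), rep(32, 3))
  sd_real <- sqrt(sum(out$grid * xg^2) / sum(out$grid))
  expect_lt(abs(sd_real - 1 / (2 * pi * sigf)) / (1 / (2 * pi * sigf)), 0.05)
  # output power spectrum ratio matches G^2
  m2 <- random_map(32, seed = 22, voxel_size = vs)
  out2 <- lowpass_by_fsc(m2, curve)
  F_in <- fft(m2$grid); F_out <- fft(out2$grid)
  shell <- compute_fsc(m2, m2) # reuse shell freqs
  ratio <- Mod(F_out[2:10, 1, 1])^2 / Mod(F_in[2:10, 1, 1])^2
  fr <- (1:9) / (32 * vs)
  expect_equal(ratio, exp(-fr^2 / attr(out2, "sigma_f")^2), tolerance = 1e-6)
  # non-decaying curve errors
  rising <- tibble::tibble(frequency = freq, fsc = seq(0.2, 0.9, length.out = 17))
  expect_error(lowpass_by_fsc(m, rising), "decay")
})

test_that("PCA classification separates two planted variants", {
  tmpl <- small_template()
  sub1 <- tmpl$map$grid
  sub2 <- tmpl$map$grid + 0.6 * tmpl$map$grid[, , c(2:dim(tmpl$map$grid)[3], 1)]
  set.seed(33)
  vols <- c(
    lapply(1:50, function(i)
      density_map(sub1 + array(rnorm(length(sub1), 0, 0.08), dim(sub1)), 7.6)),
    lapply(1:50, function(i)
      density_map(sub2 + array(rnorm(length(sub2), 0, 0.08), dim(sub2)), 7.6)))
  res <- pca_classify(vols, n_components = 3, k_classes = 2, seed = 2)
  truth <- rep(1:2, each = 50)
  purity <- max(mean(res$labels == truth), mean(res$labels == 3 - truth))
  expect_gte(purity, 0.9)
  expect_equal(sum(res$counts), 100)
  # identical inputs: degenerate
  same <- lapply(1:5, function(i) density_map(sub1, 7.6))
  expect_error(pca_classify(same, k_classes = 2), "degenerate")
  # rank bound on components
  few <- lapply(1:4, function(i)
    density_map(sub1 + array(rnorm(length(sub1), 0, 0.1), dim(sub1)), 7.6))
  res2 <- pca_classify(few, n_components = 10, k_classes = 2, seed = 1)
  expect_lte(length(res2$variance_explained), 3)
  expect_error(pca_classify(few, k_classes = 9), "exceeds")
})

test_that("schedule invariants are enforced", {
  expect_error(alignment_schedule(10, 20, 4, 0.1, TRUE), "step")
  expect_error(alignment_schedule(c(10, 10), c(3, 3), 4, c(0.2, 0.1), TRUE),
               "non-decreasing")
  expect_error(alignment_schedule(c(10, 20), 3, 4, 0.1, TRUE),
               "non-increasing")
  s <- default_schedule(7.6)
  expect_equal(nrow(s), 6)
  expect_equal(s$half_range, c(30, 20, 15, 10, 6, 4))
  expect_equal(s$step, s$half_range / 3)
})
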