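test_that("model density synthesis is localized and mass-linear", {
  one <- atomic_model(tibble::tibble(atom_name = "CA", residue_name = "ALA",
                                     residue_number = 1, chain = "A",
                                     x = 3.2, y = -1.1, z = 7.7))
  m <- model_to_map(one, resolution = 10, voxel_size = 2)
  idx <- arrayInd(which.min(m$grid), dim(m$grid)) - 1
  peak <- voxel_to_map(m, idx)
  expect_lt(sqrt(sum((peak - c(3.2, -1.1, 7.7))^2)), sqrt(3) * 1.01)
  expect_lte(max(m$grid), 0)
  # doubling the model doubles the integral
  mod <- toy_model(3)
  m1 <- model_to_map(mod, 12, 3)
  dbl <- atomic_model(dplyr::bind_rows(tibble::as_tibble(mod)[, -1],
                                       tibble::as_tibble(mod)[, -1]))
  m2 <- model_to_map(dbl, 12, 3, box_dim = dim(m1$grid), origin = m1$origin)
  expect_equal(sum(m2$grid), 2 * sum(m1$grid), tolerance = 1e-6)
  # resolution below the Nyquist bound is refused
  expect_error(model_to_map(mod, 3, 2), "Nyquist")
})

test_that("rigid fit recovers identity and planted rotations", {
  mod <- toy_model(4)
  target <- model_to_map(mod, 14, 4)
  # self-fit at identity
  self <- rigid_fit(mod, target, resolution = 14)
  expect_gt(self$ccc, 0.99)
  # planted 10-degree rotation recovered within one step
  centre <- colMeans(as.matrix(mod[, c("x", "y", "z")]))
  R10 <- euler_to_matrix(0, 10, 0)
  rotated <- subtomo:::transform_model(mod, R10, c(0, 0, 0), centre)
  target2 <- model_to_map(rotated, 14, 4, box_dim = dim(target$grid),
                          origin = target$origin)
  fit <- rigid_fit(mod, target2, resolution = 14, ang_range = 15,
                   ang_step = 5)
  Rf <- euler_to_matrix(fit$rotation[1], fit$rotation[2], fit$rotation[3])
  expect_lt(rotation_angle_between(R10, Rf), 5 + 1e-6)
  expect_gt(fit$ccc, 0.95)
  # zero ranges: evaluates exactly the initial pose
  z <- rigid_fit(mod, target2, resolution = 14)
  expect_equal(z$n_evaluated, 1L)
  expect_equal(unname(z$rotation), c(0, 0, 0))
})

test_that("hinge-restricted flexible fit recovers constructed rotations", {
  mod <- toy_model_with_hinges(5)
  doms <- toy_domains()
  # construct a target with known domain rotations about the hinge pivots
  p12 <- subtomo:::hinge_pivot(mod, doms$hinge12)
  p13 <- subtomo:::hinge_pivot(mod, doms$hinge13)
  bend <- function(model, residues, pivot, axis, angle) {
    sel <- model$residue_number %in% residues
    R <- axis_angle_to_matrix(axis, angle)
    xyz <- as.matrix(model[sel, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, `+`)
    model$x[sel] <- xyz[, 1]; model$y[sel] <- xyz[, 2]
    model$z[sel] <- xyz[, 3]
    model
  }
  bent <- bend(mod, c(doms$domain2, doms$hinge12), p12, c(0, 0, 1), 16)
  bent <- bend(bent, c(doms$domain3, doms$hinge13), p13, c(1, 0, 0), 19)
  target <- model_to_map(bent, 14, 4)
  fit <- hinge_flexible_fit(mod, doms, target, resolution = 14,
                            n_iterations = 4)
  expect_gt(fit$ccc, 0.99)
  expect_lt(abs(fit$hinge_rotations["hinge12"] - 16), 2)
  expect_lt(abs(fit$hinge_rotations["hinge13"] - 19), 2)
  # zero allowed range reproduces the rigid pose
  frozen <- hinge_flexible_fit(mod, doms, target, resolution = 14,
                               angle_range = 0)
  expect_equal(frozen$ccc, model_map_ccc(target, mod, 14), tolerance = 1e-12)
  expect_equal(unname(frozen$hinge_rotations), c(0, 0))
})

test_that("flexible fit never scores below the rigid fit", {
  doms <- toy_domains()
  for (seed in c(2, 6)) {
    mod <- toy_model_with_hinges(seed)
    set.seed(seed + 100)
    # an imperfect target: the model bent by random small hinge motions
    p12 <- subtomo:::hinge_pivot(mod, doms$hinge12)
    sel <- mod$residue_number %in% c(doms$domain2, doms$hinge12)
    R <- axis_angle_to_matrix(rnorm(3), runif(1, 5, 20))
    xyz <- as.matrix(mod[sel, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2, p12) %*% t(R), 2, p12, `+`)
    tgt_model <- mod
    tgt_model$x[sel] <- xyz[, 1]; tgt_model$y[sel] <- xyz[, 2]
    tgt_model$z[sel] <- xyz[, 3]
    target <- model_to_map(tgt_model, 16, 4)
    rigid_ccc <- model_map_ccc(target, mod, 16)
    flex <- hinge_flexible_fit(mod, doms, target, resolution = 16,
                               n_iterations = 2, angle_range = 12,
                               angle_step = 6)
    expect_gte(flex$ccc, rigid_ccc - 1e-12)
  }
})

test_that("domain rotation between conformers is measured exactly", {
  mod <- toy_model(7)
  expect_equal(domain_rotation_between(mod, mod, 1:20, 31:50), 0,
               tolerance = 1e-6)
  # constructed 25-degree rotation of the moving domain
  R25 <- axis_angle_to_matrix(c(1, 2, 0.5), 25)
  sel <- mod$residue_number %in% 31:50
  pivot <- c(10, -4, 2)
  b <- mod
  xyz <- as.matrix(mod[sel, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, pivot) %*% t(R25), 2, pivot, `+`)
  b$x[sel] <- xyz[, 1]; b$y[sel] <- xyz[, 2]; b$z[sel] <- xyz[, 3]
  got <- domain_rotation_between(mod, b, 1:20, 31:50)
  expect_equal(got, 25, tolerance = 0.1)
  # symmetry
  expect_equal(domain_rotation_between(b, mod, 1:20, 31:50), got,
               tolerance = 1e-6)
  # invariance under a global rigid motion of one model
  Rg <- euler_to_matrix(40, 70, -10)
  bg <- subtomo:::transform_model(b, Rg, c(30, -20, 12))
  expect_equal(domain_rotation_between(mod, bg, 1:20, 31:50), got,
               tolerance = 1e-6)
  expect_error(domain_rotation_between(mod, b, 1:20, 200:210), "3 common")
})

test_that("residue pair distances take the atom-set minimum", {
  mk <- function(resno, name, atoms, pos) {
    tibble::tibble(atom_name = atoms, residue_name = name,
                   residue_number = resno, chain = "A",
                   x = pos[, 1], y = pos[, 2], z = pos[, 3])
  }
  model <- atomic_model(dplyr::bind_rows(
    mk(245, "GLU", c("CA", "OE1", "OE2"),
       rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))),
    mk(400, "LYS", c("CA", "NZ"),
       rbind(c(20, 0, 0), c(8, 0, 0)))))
  expect_equal(residue_pair_distance(model, "A", 245, "A", 400), 5)
  # brute-force oracle over all pairs
  A <- as.matrix(model[model$atom_name %in% c("OE1", "OE2"), c("x", "y", "z")])
  B <- as.matrix(model[model$atom_name == "NZ", c("x", "y", "z")])
  want <- min(apply(A, 1, function(a)
    apply(B, 1, function(b) sqrt(sum((a - b)^2)))))
  expect_equal(residue_pair_distance(model, "A", 245, "A", 400), want)
  # overlapping sets from the same residue give 0
  expect_equal(residue_pair_distance(model, "A", 245, "A", 245,
                                     atoms_a = "OE1", atoms_b = "OE1"), 0)
  expect_error(residue_pair_distance(model, "A", 999, "A", 400), "999")
})

test_that("bilayer placement finds two leaflet dips", {
  # construct a map with two concentric dark shells (leaflets)
  vs <- 4; n <- 72
  ves <- vesicle_model(c(0, 0, 0), 100)
  g <- array(0, rep(n, 3))
  cpp_add_shell(g, dim(g), rep((n - 1) / 2, 3), 80 / vs, 4 / vs, -1, 2L)
  cpp_add_shell(g, dim(g), rep((n - 1) / 2, 3), 120 / vs, 4 / vs, -1, 2L)
  m <- density_map(g, vs, rep(-(n - 1) / 2 * vs, 3))
  res <- place_bilayer(m, ves, window = c(40, 160))
  expect_lt(abs(res$peak_radii[1] - 80), 2)
  expect_lt(abs(res$peak_radii[2] - 120), 2)
  expect_lt(abs(res$separation - 40), 3)
  # symmetric construction recovers equal amplitudes
  expect_lt(abs(diff(abs(res$amplitudes))) / max(abs(res$amplitudes)), 0.2)
  # a single shell is a no-bilayer error
  g1 <- array(0, rep(n, 3))
  cpp_add_shell(g1, dim(g1), rep((n - 1) / 2, 3), 100 / vs, 4 / vs, -1, 2L)
  m1 <- density_map(g1, vs, rep(-(n - 1) / 2 * vs, 3))
  expect_error(place_bilayer(m1, ves, window = c(40, 160)), "no bilayer")
})
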