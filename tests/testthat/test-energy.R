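# finite-difference agreement expected for every analytic gradient
FD_TOL <- 1e-5

test_that("harmonic restraint energies vanish at equilibrium and match hand values", {
  s <- point_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0)))
  k <- atom_keys(s)
  pairs <- data.frame(a = k[1], b = k[2], d_ref = 3, d_eq = 3)
  at_eq <- den_energy(s, pairs)
  expect_equal(at_eq$energy, 0)
  expect_equal(max(abs(at_eq$gradient)), 0)
  # one pair, d = 3, d_eq = 2, k = 0.01 -> 0.01 * 1^2
  pairs$d_eq <- 2
  expect_equal(den_energy(s, pairs)$energy, 0.01)
  # one triplet at 90 deg with equilibrium 100 deg, k = 0.01 -> 1.0
  ang <- data.frame(vertex = k[1], tail1 = k[2], tail2 = k[3],
                    theta_ref = 90, theta_eq = 100)
  expect_equal(dan_energy(s, ang)$energy, 1.0)
  ang$theta_eq <- 90
  expect_equal(dan_energy(s, ang)$energy, 0)
})

test_that("restraint gradients match central finite differences", {
  truth <- helix_fixture(7)
  n <- nrow(truth)
  rs <- generate_restraints(truth, truth, selection_params(seed = 5))
  pairs <- rs$pairs[1:20, ]
  angles <- rs$angles[1:20, ]
  s <- set_coords(truth, coords(truth) +
                  0.4 * with_seed_local(8, matrix(rnorm(3 * n), n, 3)))
  g_den <- den_energy(s, pairs)$gradient
  expect_lt(max_rel_err(fd_gradient(function(x)
    den_energy(x, pairs)$energy, s), g_den), FD_TOL)
  g_dan <- dan_energy(s, angles)$gradient
  expect_lt(max_rel_err(fd_gradient(function(x)
    dan_energy(x, angles)$energy, s), g_dan), FD_TOL)
})

test_that("DCN energy is additive in DEN and DAN and scales with w_dcn", {
  truth <- helix_fixture(6)
  rs <- generate_restraints(truth, truth, selection_params(seed = 1))
  s <- set_coords(truth, coords(truth) +
                  0.3 * with_seed_local(2, matrix(rnorm(3 * nrow(truth)),
                                                  nrow(truth), 3)))
  p <- deformation_params(w_dcn = 30)
  dc <- dcn_energy(s, rs, p)
  expect_equal(dc$energy,
               den_energy(s, rs$pairs)$energy + dan_energy(s, rs$angles)$energy)
  expect_equal(dc$gradient,
               30 * (den_energy(s, rs$pairs)$gradient +
                     dan_energy(s, rs$angles)$gradient))
  # zero weight contributes nothing regardless of geometry
  p0 <- deformation_params(w_dcn = 0)
  tt <- total_target(s, rs, NULL, make_topology(truth), p0)
  expect_equal(tt$e_dcn, 0)
  # empty restraint set
  rs0 <- rs; rs0$pairs <- rs$pairs[0, ]; rs0$angles <- rs$angles[0, ]
  expect_equal(dcn_energy(s, rs0, p)$energy, 0)
})

test_that("stereochemical terms vanish at ideal geometry and gradients verify", {
  truth <- helix_fixture(7)
  topo <- make_topology(truth)
  st <- stereo_energy(truth, topo)
  expect_lt(st$e_bond, 1e-10)
  expect_lt(st$e_angle, 1e-10)
  # nonbonded beyond the scaled radii sum contributes nothing: two bonded
  # dimers 8 A apart
  far <- point_structure(rbind(c(0, 0, 0), c(1.5, 0, 0), c(8, 0, 0),
                               c(9.5, 0, 0)), resno = c(1, 1, 5, 5))
  expect_equal(stereo_energy(far, make_topology(far, ideal = "model"))$e_rep,
               0)
  s <- set_coords(truth, coords(truth) +
                  0.3 * with_seed_local(3, matrix(rnorm(3 * nrow(truth)),
                                                  nrow(truth), 3)))
  for (vs in c(1, 0.75)) {
    g <- stereo_energy(s, topo, vs)$gradient
    expect_lt(max_rel_err(fd_gradient(function(x)
      stereo_energy(x, topo, vs)$energy, s), g), FD_TOL)
  }
})

test_that("structure factors reproduce analytic point-scatterer results", {
  hkl <- rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0), c(0, 1, 0), c(0, 0, 2),
               c(1, 1, 0), c(2, 1, 3), c(5, 0, 0), c(0, 3, 1), c(4, 0, 0))
  refl <- reflection_set(c(10, 10, 10), hkl, rep(1, 10),
                         c(rep(FALSE, 8), TRUE, TRUE), 2)
  one <- point_structure(c(1.7, 2.9, 0.3), elesy = "H")
  expect_equal(Mod(calc_structure_factors(one, refl, 0)), rep(1, 10))
  # two unit scatterers at fractional 0 and 0.5 along x: |F| = 2 for even
  # h, 0 for odd h
  two <- point_structure(rbind(c(0, 0, 0), c(5, 0, 0)), elesy = "H")
  f <- calc_structure_factors(two, refl, 0)
  expect_equal(Mod(f[1:3]), c(0, 2, 0))
  expect_equal(Mod(f[10]), 2)
  # periodic wrap: shifting an atom by a full cell edge changes nothing
  shifted <- point_structure(c(1.7 + 10, 2.9, 0.3 - 20), elesy = "H")
  expect_equal(calc_structure_factors(shifted, refl, 5),
               calc_structure_factors(one, refl, 5))
})

test_that("direct summation agrees with an FFT density oracle", {
  ngrid <- 16L; cell <- c(8, 8, 8)
  with_seed_local(12, {
    frac_idx <- matrix(sample(0:(ngrid - 1), 60, replace = TRUE), 20, 3)
  })
  xyz <- frac_idx * (cell[1] / ngrid)
  elems <- rep(c("C", "N", "O", "S"), 5)
  s <- point_structure(xyz, elesy = elems)
  hkl <- as.matrix(expand.grid(h = -3:3, k = -3:3, l = 0:3))
  hkl <- hkl[!(hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] == 0), ]
  hkl <- hkl[hkl[, 3] > 0 | (hkl[, 3] == 0 & (hkl[, 2] > 0 |
             (hkl[, 2] == 0 & hkl[, 1] > 0))), ]
  free <- rep(FALSE, nrow(hkl)); free[1:20] <- TRUE
  refl <- reflection_set(cell, hkl, rep(1, nrow(hkl)), free, 1.2)
  z <- c(C = 6, N = 7, O = 8, S = 16)[elems]
  for (b in c(0, 15)) {
    got <- calc_structure_factors(s, refl, b)
    want <- oracle_sf_fft(frac_idx, z, ngrid, cell, hkl, b)
    expect_lt(max(Mod(got - want)) / max(Mod(want)), 1e-4)
  }
})

test_that("amplitude target is zero on self-consistent data and scale-invariant", {
  truth <- helix_fixture(6)
  refl <- tiny_reflections(truth, d_min = 3.5, b = 12)
  # F_obs computed from the same coordinates at the same B
  f_self <- Mod(calc_structure_factors(truth, refl, 12))
  refl_self <- reflection_set(refl$cell, refl$hkl, f_self, refl$free,
                              refl$d_min)
  e <- exp_energy(truth, refl_self, 12)
  expect_lt(e$energy, 1e-14 * sum(f_self^2))
  expect_equal(e$scale, 1, tolerance = 1e-10)
  # doubling all amplitudes doubles the scale, not the minimum location
  refl2 <- reflection_set(refl$cell, refl$hkl, 2 * f_self, refl$free,
                          refl$d_min)
  s_off <- set_coords(truth, coords(truth) +
                      0.2 * with_seed_local(4, matrix(rnorm(3 * nrow(truth)),
                                                      nrow(truth), 3)))
  e1 <- exp_energy(s_off, refl_self, 12)
  e2 <- exp_energy(s_off, refl2, 12)
  expect_equal(e2$scale, 2 * e1$scale, tolerance = 1e-12)
  expect_equal(e2$energy, 4 * e1$energy, tolerance = 1e-10)
  expect_equal(e2$gradient, 4 * e1$gradient, tolerance = 1e-10)
  # degenerate data
  refl0 <- refl_self; refl0$f_obs[] <- 0
  expect_error(exp_energy(truth, refl0, 12), "scale undefined")
})

test_that("amplitude-target gradient matches finite differences", {
  truth <- helix_fixture(5)  # 20 atoms
  refl <- tiny_reflections(truth, d_min = 3.5)
  s <- set_coords(truth, coords(truth) +
                  0.3 * with_seed_local(5, matrix(rnorm(3 * nrow(truth)),
                                                  nrow(truth), 3)))
  g <- exp_energy(s, refl, 10)$gradient
  expect_lt(max_rel_err(fd_gradient(function(x)
    exp_energy(x, refl, 10)$energy, s), g), FD_TOL)
})

test_that("free reflections never contribute to the working-set target", {
  truth <- helix_fixture(6)
  refl <- tiny_reflections(truth, d_min = 3.5)
  s <- perturb_structure(truth, 1.0, seed = 3)
  e1 <- exp_energy(s, refl, 10)
  # corrupting every free amplitude leaves energy and gradient unchanged
  refl_bad <- refl; refl_bad$f_obs[refl_bad$free] <- 999
  e2 <- exp_energy(s, refl_bad, 10)
  expect_equal(e1$energy, e2$energy)
  expect_equal(e1$gradient, e2$gradient)
  # r_work is free-set independent too
  r1 <- r_factors(s, refl, 10)
  expect_equal(r1$r_work, r_factors(s, refl_bad, 10)$r_work)
})

test_that("R factors separate the data fit of good, perturbed and random models", {
  truth <- helix_fixture(8)
  refl <- tiny_reflections(truth, d_min = 3.0, b = 15)
  rf <- r_factors(truth, refl, 15)
  expect_lt(rf$r_work, 0.01)
  expect_lt(rf$r_free, 0.02)
  # scrambled coordinates plateau near the random-model R
  box <- apply(coords(truth), 2, range)
  rand <- set_coords(truth, with_seed_local(6, apply(box, 2, function(r)
    runif(nrow(truth), r[1], r[2]))))
  expect_gt(r_factors(rand, refl, 15)$r_free, 0.4)
  expect_error(r_factors(truth, reflection_set(
    refl$cell, refl$hkl, refl$f_obs, rep(c(TRUE, FALSE),
    c(3, length(refl$free) - 3)), refl$d_min), 15), NA)
})

test_that("total target composes its terms and its gradient verifies", {
  truth <- helix_fixture(5)
  topo <- make_topology(truth)
  rs <- generate_restraints(truth, truth, selection_params(seed = 2))
  refl <- tiny_reflections(truth, d_min = 3.5)
  s <- set_coords(truth, coords(truth) +
                  0.25 * with_seed_local(7, matrix(rnorm(3 * nrow(truth)),
                                                   nrow(truth), 3)))
  p <- deformation_params(w_dcn = 20, w_a = 0.4)
  tt <- total_target(s, rs, refl, topo, p, b_overall = 10, vdw_scale = 0.8)
  expect_equal(tt$energy,
               stereo_energy(s, topo, 0.8)$energy +
               0.4 * exp_energy(s, refl, 10)$energy +
               20 * dcn_energy(s, rs, p)$energy)
  expect_lt(max_rel_err(fd_gradient(function(x)
    total_target(x, rs, refl, topo, p, 10, 0.8)$energy, s), tt$gradient),
    FD_TOL)
  # w_a = 0, w_dcn = 0 reduces to the stereochemical energy alone
  p0 <- deformation_params(w_dcn = 0, w_a = 0)
  expect_equal(total_target(s, rs, refl, topo, p0, 10, 0.8)$energy,
               stereo_energy(s, topo, 0.8)$energy)
})

test_that("internal-coordinate energies are rigid-motion invariant", {
  truth <- helix_fixture(6)
  topo <- make_topology(truth)
  rs <- generate_restraints(truth, truth, selection_params(seed = 3))
  s <- perturb_structure(truth, 1.2, seed = 9)
  p <- deformation_params(w_dcn = 10)
  base_dcn <- dcn_energy(s, rs, p)$energy
  base_st <- stereo_energy(s, topo)$energy
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  for (i in 1:3) {
    shift <- with_seed_local(20 + i, rnorm(3, sd = 5))
    moved <- set_coords(s, sweep(coords(s) %*% rot, 2, shift, "+"))
    expect_equal(dcn_energy(moved, rs, p)$energy, base_dcn,
                 tolerance = 1e-9)
    expect_equal(stereo_energy(moved, topo)$energy, base_st,
                 tolerance = 1e-9)
  }
})

test_that("reflection files round-trip in both dialects", {
  truth <- helix_fixture(6)
  refl <- tiny_reflections(truth, d_min = 3.5)
  f <- withr::local_tempfile(fileext = ".txt")
  write_reflections(refl, f)
  back <- read_reflections(f)
  expect_equal(back$cell, refl$cell, tolerance = 1e-6)
  expect_equal(back$hkl, refl$hkl)
  expect_equal(back$f_obs, refl$f_obs, tolerance = 1e-6)
  expect_equal(back$free, refl$free)
  # CSV dialect
  fcsv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(sprintf("# cell %f %f %f dmin %f", refl$cell[1], refl$cell[2],
                       refl$cell[3], refl$d_min),
               sprintf("%d,%d,%d,%g,%d", refl$hkl[, 1], refl$hkl[, 2],
                       refl$hkl[, 3], refl$f_obs, as.integer(refl$free))),
             fcsv)
  back2 <- read_reflections(fcsv)
  expect_equal(back2$f_obs, refl$f_obs, tolerance = 1e-6)
  expect_error(read_reflections(withr::local_tempfile(lines = "1 2 3")),
               "header")
})
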