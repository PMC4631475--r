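test_that("cross-chain and collinear triplets are excluded", {
  # two chains: every triplet mixes chains -> empty
  s2 <- structure_from_atoms(c("A", "A", "B"), c(1, 2, 1), "ALA",
                             c("CA", "CA", "CA"),
                             rbind(c(0, 0, 0), c(3, 0, 2), c(0, 3, 1)))
  corr <- match_atoms(s2, s2)
  expect_equal(nrow(enumerate_dan_candidates(s2, corr)), 0)
  # collinear same-chain atoms: vertex angle 180 fails the angle band
  s3 <- point_structure(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)))
  expect_equal(nrow(enumerate_dan_candidates(s3, match_atoms(s3, s3))), 0)
})

test_that("DAN enumeration equals the brute-force triple-loop oracle", {
  p <- selection_params(cutoff = 6, max_residue_separation = 3)
  for (mode in c("directional", "arbitrary")) {
    for (n_res in c(5, 6, 7)) {  # 20 to 28 atoms
      s <- helix_fixture(n_res)
      corr <- match_atoms(s, s)
      pm <- p; pm$mode <- mode
      got <- enumerate_dan_candidates(s, corr, pm)
      want <- oracle_dan(s, corr$reference, p$cutoff,
                         p$max_residue_separation, p$angle_min,
                         p$angle_max, mode == "directional")
      expect_equal(sort(paste(got$vertex, got$tail1, got$tail2)), want,
                   info = paste(mode, n_res))
    }
  }
})

test_that("DAN candidates satisfy the admissibility criteria post hoc", {
  s <- helix_fixture(10)
  corr <- match_atoms(s, s)
  p <- selection_params(cutoff = 8, max_residue_separation = 4)
  cand <- enumerate_dan_candidates(s, corr, p)
  expect_gt(nrow(cand), 0)
  for (i in seq_len(nrow(cand))) {
    v <- cand$vertex[i]; t1 <- cand$tail1[i]; t2 <- cand$tail2[i]
    expect_lte(atom_distance(s, v, t1), p$cutoff)
    expect_lte(atom_distance(s, v, t2), p$cutoff)
    res_of <- function(k) as.integer(strsplit(k, "/")[[1]][2])
    expect_lte(abs(res_of(v) - res_of(t1)), p$max_residue_separation)
    expect_lte(abs(res_of(v) - res_of(t2)), p$max_residue_separation)
    a <- atom_angle(s, v, t1, t2)
    expect_gte(a, p$angle_min); expect_lte(a, p$angle_max)
    expect_equal(cand$theta_ref[i], a)
  }
  # tails canonically ordered by serial
  srl <- function(k) match(k, atom_keys(s))
  expect_true(all(srl(cand$tail1) < srl(cand$tail2)))
  # directional vertices precede both tails
  expect_true(all(srl(cand$vertex) < srl(cand$tail1)))
})

test_that("directional-mode enumeration is a subset of arbitrary mode", {
  s <- helix_fixture(8)
  corr <- match_atoms(s, s)
  dir_ <- enumerate_dan_candidates(s, corr,
                                   selection_params(mode = "directional"))
  arb <- enumerate_dan_candidates(s, corr,
                                  selection_params(mode = "arbitrary"))
  tag <- function(d) paste(d$vertex, d$tail1, d$tail2)
  expect_true(all(tag(dir_) %in% tag(arb)))
  expect_gt(nrow(arb), nrow(dir_))
})

test_that("DEN enumeration applies cutoff/separation and matches the oracle", {
  far <- point_structure(rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_equal(nrow(enumerate_den_candidates(far, match_atoms(far, far))), 0)
  near <- point_structure(rbind(c(0, 0, 0), c(5, 0, 0)), resno = c(1, 2))
  expect_equal(nrow(enumerate_den_candidates(near, match_atoms(near, near))),
               1)
  s <- helix_fixture(8)
  corr <- match_atoms(s, s)
  p <- selection_params(cutoff = 7, max_residue_separation = 4)
  got <- enumerate_den_candidates(s, corr, p)
  want <- oracle_den(s, corr$reference, 7, 4)
  expect_equal(sort(paste(got$a, got$b)), want)
  d <- vapply(seq_len(nrow(got)), function(i)
    atom_distance(s, got$a[i], got$b[i]), numeric(1))
  expect_equal(got$d_ref, d)
})

test_that("restraint selection is seeded, exact-count, and pool-limited", {
  s <- helix_fixture(12)
  corr <- match_atoms(s, s)
  cand <- enumerate_dan_candidates(s, corr, selection_params())
  expect_gt(nrow(cand), 100)
  p <- selection_params(seed = 7)
  sel1 <- select_restraints(cand, 100, p)
  sel2 <- select_restraints(cand, 100, p)
  expect_equal(nrow(sel1), 100)
  expect_identical(sel1, sel2)
  # restraint_multiple scales the draw
  p2 <- selection_params(seed = 7, restraint_multiple = 0.5)
  expect_equal(nrow(select_restraints(cand, 100, p2)), 50)
  # pool exhaustion: entire pool plus a warning
  small <- cand[1:50, ]
  expect_warning(all50 <- select_restraints(small, 100, p), "pool")
  expect_equal(nrow(all50), 50)
  # different seeds give different selections nearly always
  draws <- vapply(1:20, function(sd) {
    psd <- selection_params(seed = sd)
    paste(select_restraints(cand, 30, psd)$vertex, collapse = ",")
  }, character(1))
  expect_gt(length(unique(draws)), 18)
})

test_that("with multiple 1 the angle count equals the atom count", {
  s <- helix_fixture(10)
  rs <- generate_restraints(s, s, selection_params(seed = 2))
  expect_equal(nrow(rs$angles), nrow(s))
  expect_equal(nrow(rs$pairs), nrow(s))
})

test_that("equilibria initialize from the starting structure", {
  truth <- helix_fixture(8)
  start <- perturb_structure(truth, 1.5, seed = 4)
  rs <- generate_restraints(start, truth, selection_params(seed = 1),
                            starting = start)
  # reference values from truth, equilibria from start
  for (i in with_seed_local(1, sample(nrow(rs$pairs), 5))) {
    expect_equal(rs$pairs$d_ref[i],
                 atom_distance(truth, rs$pairs$a[i], rs$pairs$b[i]))
    expect_equal(rs$pairs$d_eq[i],
                 atom_distance(start, rs$pairs$a[i], rs$pairs$b[i]))
  }
  for (i in with_seed_local(2, sample(nrow(rs$angles), 5))) {
    expect_equal(rs$angles$theta_ref[i],
                 atom_angle(truth, rs$angles$vertex[i], rs$angles$tail1[i],
                            rs$angles$tail2[i]))
    expect_equal(rs$angles$theta_eq[i],
                 atom_angle(start, rs$angles$vertex[i], rs$angles$tail1[i],
                            rs$angles$tail2[i]))
  }
  # starting == reference: equilibria equal reference values
  rs2 <- generate_restraints(truth, truth, selection_params(seed = 1))
  expect_equal(rs2$pairs$d_eq, rs2$pairs$d_ref)
  expect_equal(rs2$angles$theta_eq, rs2$angles$theta_ref)
  # empty set passes through unchanged
  empty <- rs; empty$pairs <- rs$pairs[0, ]; empty$angles <- rs$angles[0, ]
  expect_equal(nrow(init_equilibria(empty, start)$pairs), 0)
  # unresolvable atom names the restraint kind
  tiny <- point_structure(c(0, 0, 0), elety = "CA")
  expect_error(init_equilibria(rs, tiny), "pair restraint")
})

test_that("restraint files round-trip losslessly with vertex listed first", {
  truth <- helix_fixture(8)
  start <- perturb_structure(truth, 1.0, seed = 2)
  rs <- generate_restraints(start, truth, selection_params(seed = 3),
                            starting = start)
  f <- withr::local_tempfile(fileext = ".txt")
  write_restraints(rs, f)
  back <- read_restraints(f, rs$params)
  expect_equal(back$pairs, rs$pairs, tolerance = 1e-6)
  expect_equal(back$angles, rs$angles, tolerance = 1e-6)
  # ANGL records list vertex, then first tail, then second tail
  angl <- grep("^ANGL", readLines(f), value = TRUE)
  first_key <- vapply(strsplit(angl, "\\s+"), function(x)
    paste(x[2], x[3], x[4], sep = "/"), character(1))
  expect_equal(first_key, rs$angles$vertex)
  # unknown tags and malformed lines are rejected with a line number
  writeLines(c("PAIR A 1 CA A 2 CA 3.0 3.0", "BOGUS x"), f)
  expect_error(read_restraints(f), "unknown restraint tag")
  writeLines("ANGL A 1 CA A 2 CA 100.0 100.0", f)
  expect_error(read_restraints(f), "line 1")
})

test_that("restraint selection is byte-identical under a fixed seed", {
  truth <- helix_fixture(10)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_restraints(generate_restraints(truth, truth,
                                       selection_params(seed = 9)), f1)
  write_restraints(generate_restraints(truth, truth,
                                       selection_params(seed = 9)), f2)
  expect_identical(readLines(f1), readLines(f2))
})
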