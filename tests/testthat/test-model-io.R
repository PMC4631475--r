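test_that("PDB files parse into ordered atom records", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "REMARK test",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 20.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 20.00           C",
    "ATOM      3  C   ALA A   2      10.747   5.227  -4.308  1.00 20.00           C",
    "TER", "END"), f)
  s <- read_pdb(f)
  expect_s3_class(s, "dcn_structure")
  expect_equal(nrow(s), 3)
  expect_equal(s$serial, 1:3)
  expect_equal(s$x, c(11.104, 11.639, 10.747))
  expect_equal(s$resno, c(1L, 1L, 2L))
  expect_equal(atom_keys(s), c("A/1/N", "A/1/CA", "A/2/C"))
})

test_that("alternate locations other than blank/'A' are skipped", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 20.00           N",
    "ATOM      2  CA AALA A   1      11.639   6.071  -5.147  0.50 20.00           C",
    "ATOM      3  CA BALA A   1      11.700   6.100  -5.100  0.50 20.00           C",
    "END"), f)
  s <- read_pdb(f)
  # hand count: 3 records, one altLoc-B duplicate -> 2 atoms, 'A' retained
  expect_equal(nrow(s), 2)
  expect_equal(s$x[s$elety == "CA"], 11.639)
})

test_that("hydrogens are dropped by default but kept on request", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 20.00           N",
    "ATOM      2  H   ALA A   1       1.000   0.000   0.000  1.00 20.00           H",
    "END"), f)
  expect_equal(nrow(read_pdb(f)), 1)
  expect_equal(nrow(read_pdb(f, keep_hydrogens = TRUE)), 2)
})

test_that("malformed and degenerate PDB inputs raise informative errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(read_pdb(f), "empty structure")
  writeLines(c("ATOM      1  N   ALA A   1      11.104"), f)
  expect_error(read_pdb(f), "line 1")
  writeLines(c(
    "ATOM      1  N   ALA A   1A     11.104   6.134  -6.504  1.00 20.00           N"),
    f)
  expect_error(read_pdb(f), "insertion code")
  expect_error(read_pdb(file.path(tempdir(), "no-such-file.pdb")),
               "no such file")
})

test_that("write_pdb emits fixed columns, renumbers serials, and round-trips", {
  s1 <- point_structure(c(1, 2, 3), elety = "CA")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s1, f)
  line <- grep("^ATOM", readLines(f), value = TRUE)
  expect_match(line, "   1.000   2.000   3.000", fixed = TRUE)

  s <- helix_fixture(5)
  s$serial <- s$serial + 100L  # arbitrary serials are renumbered on write
  write_pdb(s, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^ATOM", lines)), nrow(s))
  expect_equal(lines[length(lines)], "END")
  back <- read_pdb(f)
  expect_equal(back$serial, seq_len(nrow(s)))
  expect_equal(atom_keys(back), atom_keys(s))
  expect_equal(coords(back), coords(s), tolerance = 1e-3)
  # coordinates are exact to the format's 3 decimals
  expect_true(max(abs(coords(back) - round(coords(s), 3))) < 1e-9)
})

test_that("write_pdb rejects overflowing coordinates and empty structures", {
  s <- point_structure(c(10000, 0, 0))
  expect_error(write_pdb(s, tempfile()), "10000")
  s2 <- helix_fixture(5)
  expect_error(write_pdb(s2[0, ], tempfile()), "zero atoms")
})

test_that("match_atoms returns shared keys in target order", {
  s <- helix_fixture(6)
  corr <- match_atoms(s, s)
  expect_equal(nrow(corr), nrow(s))
  expect_equal(corr$target, atom_keys(s))

  ref <- s[s$resno != 3, ]  # reference missing one residue
  class(ref) <- class(s)
  corr2 <- match_atoms(s, ref)
  expect_equal(nrow(corr2), nrow(s) - 4)
  expect_false(any(grepl("^A/3/", corr2$target)))
})

test_that("match_atoms equals brute-force key intersection on disjoint subsets", {
  s <- helix_fixture(25)  # 100 atoms
  keep <- sort(with_seed_local(11, sample(nrow(s), 80)))
  ref <- s[keep, ]
  class(ref) <- class(s)
  corr <- match_atoms(s, ref)
  # oracle: plain set intersection
  expect_equal(sort(corr$target),
               sort(intersect(atom_keys(s), atom_keys(ref))))
  expect_equal(nrow(corr), 80)
  # order follows target serial order
  expect_equal(corr$target,
               atom_keys(s)[atom_keys(s) %in% atom_keys(ref)])
})

test_that("match_atoms with no shared keys errors; key_map bridges numbering", {
  a <- point_structure(c(0, 0, 0), resno = 1, elety = "CA")
  b <- point_structure(c(0, 0, 0), resno = 9, elety = "CA")
  expect_error(match_atoms(a, b), "no atom correspondence")
  km <- data.frame(target = "A/1/CA", reference = "A/9/CA")
  corr <- match_atoms(a, b, key_map = km)
  expect_equal(corr$reference, "A/9/CA")
})

test_that("distances and angles match direct arithmetic", {
  s <- point_structure(rbind(c(0, 0, 0), c(3, 4, 0), c(1, 0, 0), c(0, 1, 0),
                             c(1, 1, 0), c(-2, 0, 0)))
  k <- atom_keys(s)
  expect_equal(atom_distance(s, k[1], k[2]), 5)
  expect_equal(atom_distance(s, k[1], k[1]), 0)
  expect_equal(atom_angle(s, k[1], k[3], k[4]), 90)
  expect_equal(atom_angle(s, k[1], k[3], k[6]), 180)
  expect_equal(atom_angle(s, k[1], k[3], k[5]), 45)
  # symmetry properties
  expect_equal(atom_distance(s, k[2], k[1]), atom_distance(s, k[1], k[2]))
  expect_equal(atom_angle(s, k[1], k[4], k[3]), atom_angle(s, k[1], k[3], k[4]))
  # random pairs against independent recomputation from raw coordinates
  xyz <- coords(helix_fixture(6))
  s2 <- helix_fixture(6)
  idx <- with_seed_local(5, replicate(10, sample(nrow(s2), 2)))
  for (c_i in seq_len(ncol(idx))) {
    i <- idx[1, c_i]; j <- idx[2, c_i]
    expect_equal(atom_distance(s2, atom_keys(s2)[i], atom_keys(s2)[j]),
                 sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  }
  expect_error(atom_distance(s, "A/99/ZZ", k[1]), "cannot resolve")
  expect_error(atom_angle(s, k[1], k[1], k[2]), "degenerate")
})
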