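# Fixtures and independent oracles shared across the test files.

with_seed_local <- function(seed, expr) withr::with_seed(seed, expr)

# small backbone helix built by the package's generator
helix_fixture <- function(n_res = 7, seed = 1) {
  make_true_structure(scenario_spec(n_residues = n_res, seed = seed))
}

# structure with atoms at arbitrary coordinates, one residue per atom
point_structure <- function(xyz, chain = "A", resno = NULL, elety = NULL,
                            elesy = "C") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(elety)) elety <- sprintf("X%d", seq_len(n))
  structure_from_atoms(chain, resno, "ALA", elety, xyz, elesy = elesy)
}

# central finite-difference gradient of fn(structure) -> scalar
fd_gradient <- function(fn, s, h = 1e-5) {
  xyz <- coords(s)
  g <- xyz * 0
  for (i in seq_len(nrow(xyz))) {
    for (k in 1:3) {
      xp <- xyz; xp[i, k] <- xp[i, k] + h
      xm <- xyz; xm[i, k] <- xm[i, k] - h
      g[i, k] <- (fn(set_coords(s, xp)) - fn(set_coords(s, xm))) / (2 * h)
    }
  }
  g
}

max_rel_err <- function(got, want) {
  max(abs(got - want)) / max(abs(want))
}

# Brute-force triple-loop DAN enumeration oracle, independent of the
# package kernel: plain R loops applying the admissibility criteria.
oracle_dan <- function(s, keys, cutoff, max_sep, amin, amax, directional) {
  rows <- sort(match(keys, atom_keys(s)))
  xyz <- coords(s)
  out <- list()
  ang <- function(v, a, b) {
    u <- xyz[a, ] - xyz[v, ]; w <- xyz[b, ] - xyz[v, ]
    acos(pmin(1, pmax(-1, sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) * 180 / pi
  }
  d <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  for (i in rows) for (j in rows) for (k in rows) {
    if (!(i < j && j < k)) next
    if (length(unique(s$chain[c(i, j, k)])) != 1) next
    verts <- if (directional) list(c(i, j, k))
             else list(c(i, j, k), c(j, i, k), c(k, i, j))
    for (vt in verts) {
      v <- vt[1]; t1 <- vt[2]; t2 <- vt[3]
      if (abs(s$resno[v] - s$resno[t1]) > max_sep) next
      if (abs(s$resno[v] - s$resno[t2]) > max_sep) next
      if (d(v, t1) > cutoff || d(v, t2) > cutoff) next
      a <- ang(v, t1, t2)
      if (a < amin || a > amax) next
      out[[length(out) + 1]] <- c(v, t1, t2)
    }
  }
  if (!length(out)) return(character(0))
  m <- do.call(rbind, out)
  keysv <- atom_keys(s)
  sort(paste(keysv[m[, 1]], keysv[m[, 2]], keysv[m[, 3]]))
}

# Brute-force DEN pair enumeration oracle.
oracle_den <- function(s, keys, cutoff, max_sep) {
  rows <- sort(match(keys, atom_keys(s)))
  xyz <- coords(s)
  out <- list()
  for (i in rows) for (j in rows) {
    if (i >= j) next
    if (s$chain[i] != s$chain[j]) next
    if (abs(s$resno[i] - s$resno[j]) > max_sep) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) > cutoff) next
    out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(character(0))
  m <- do.call(rbind, out)
  keysv <- atom_keys(s)
  sort(paste(keysv[m[, 1]], keysv[m[, 2]]))
}

# FFT-based structure-factor oracle: atoms snapped to an N^3 grid give an
# exact discrete density whose DFT equals the direct sum; the overall-B
# damping multiplies both identically.
oracle_sf_fft <- function(frac_idx, z, ngrid, cell, hkl, b) {
  rho <- array(0, dim = c(ngrid, ngrid, ngrid))
  for (a in seq_len(nrow(frac_idx))) {
    i <- frac_idx[a, ] %% ngrid + 1
    rho[i[1], i[2], i[3]] <- rho[i[1], i[2], i[3]] + z[a]
  }
  Fg <- Conj(fft(rho))  # our convention uses exp(+2 pi i h.x)
  d2inv <- (hkl[, 1] / cell[1])^2 + (hkl[, 2] / cell[2])^2 +
    (hkl[, 3] / cell[3])^2
  damp <- exp(-b * d2inv / 4)
  idx <- (hkl %% ngrid) + 1
  vapply(seq_len(nrow(hkl)), function(r)
    Fg[idx[r, 1], idx[r, 2], idx[r, 3]], complex(1)) * damp
}

# small reflection fixture around a structure
tiny_reflections <- function(s, d_min = 3, margin = 6, b = 10, seed = 1,
                             free_fraction = 0.15) {
  simulate_reflections(s, scenario_spec(
    n_residues = 5, d_min = d_min, cell_margin = margin, b_data = b,
    free_fraction = free_fraction, seed = seed))
}

# quick low-cost protocol for determinism/behaviour tests
short_protocol <- function(seed = 1, macrocycles = 2) {
  protocol_config(t_start = 300, t_step = 100, macrocycles = macrocycles,
                  relax_macrocycles = 1, final_zero_w_macrocycles = 1,
                  seed = seed)
}
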