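# Synthetic fixtures: a "true" backbone structure, a perturbed
# homology-like starting/reference model with a controllable RMSD from
# truth, and complete low-resolution amplitude data computed from the true
# structure with a randomly flagged free set.

#' Scenario specification for synthetic data
#'
#' @param n_residues residues per chain (>= 5).
#' @param chain_count number of chains.
#' @param geometry backbone conformation: `"helix"`, `"extended"`, or
#'   `"mixed"` (helical first half, extended second half).
#' @param perturbation_rmsd target all-atom RMSD (A) between the true
#'   structure and the starting model; the achieved RMSD is kept within
#'   20% of this value.
#' @param d_min resolution limit of the simulated amplitudes (A).
#' @param free_fraction fraction of reflections flagged free.
#' @param cell_margin padding (A) added to the model extent when sizing
#'   the P1 box.
#' @param b_data overall isotropic B (A^2) applied when simulating
#'   amplitudes.
#' @param noise_sigma optional multiplicative Gaussian amplitude noise
#'   (relative sigma; 0 = noise-free).
#' @param seed integer seed; scenario generation is fully deterministic
#'   given the seed.
#' @return list of class `dcn_scenario_spec`.
#' @export
scenario_spec <- function(n_residues = 30, chain_count = 1,
                          geometry = c("helix", "extended", "mixed"),
                          perturbation_rmsd = 3.0, d_min = 4.0,
                          free_fraction = 0.1, cell_margin = 10,
                          b_data = 20, noise_sigma = 0, seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 5, chain_count >= 1, perturbation_rmsd >= 0,
            d_min > 1, free_fraction > 0, free_fraction < 0.5,
            cell_margin >= 0, b_data >= 0, noise_sigma >= 0)
  sp <- list(n_residues = as.integer(n_residues),
             chain_count = as.integer(chain_count), geometry = geometry,
             perturbation_rmsd = perturbation_rmsd, d_min = d_min,
             free_fraction = free_fraction, cell_margin = cell_margin,
             b_data = b_data, noise_sigma = noise_sigma,
             seed = as.integer(seed))
  class(sp) <- "dcn_scenario_spec"
  sp
}

# backbone torsions per conformation (phi, psi in degrees)
CONF_TORSIONS <- list(helix = c(phi = -57, psi = -47),
                      extended = c(phi = -139, psi = 135))

# Place atom D given positions A, B, C, the bond length |C-D|, the angle
# B-C-D (deg) and the torsion A-B-C-D (deg).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- -torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- ab - sum(ab * bc) * bc
  n <- n / sqrt(sum(n^2))
  m <- c(bc[2] * n[3] - bc[3] * n[2], bc[3] * n[1] - bc[1] * n[3],
         bc[1] * n[2] - bc[2] * n[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * (-n) + d2[3] * m
}

build_backbone <- function(n_res, geometry) {
  phi_psi <- function(i) {
    g <- if (geometry == "mixed") {
      if (i <= n_res / 2) "helix" else "extended"
    } else geometry
    CONF_TORSIONS[[g]]
  }
  bl <- IDEAL_BONDS; ba <- IDEAL_ANGLES
  # first residue seeded in the xy-plane
  N1 <- c(0, 0, 0)
  CA1 <- c(bl["N-CA"], 0, 0)
  th <- ba["N-CA-C"] * pi / 180
  C1 <- CA1 + bl["CA-C"] * c(-cos(th), sin(th), 0)
  atoms <- list()
  prevN <- N1; prevCA <- CA1; prevC <- C1
  for (i in seq_len(n_res)) {
    tor <- phi_psi(i)
    if (i == 1) {
      Ni <- N1; CAi <- CA1; Ci <- C1
    } else {
      Ni <- place_atom(prevN, prevCA, prevC, bl["C-N"], ba["CA-C-N"],
                       tor_prev["psi"])
      CAi <- place_atom(prevCA, prevC, Ni, bl["N-CA"], ba["C-N-CA"], 180)
      Ci <- place_atom(prevC, Ni, CAi, bl["CA-C"], ba["N-CA-C"], tor["phi"])
    }
    # carbonyl O from the psi torsion (O trans to the next N)
    Oi <- place_atom(Ni, CAi, Ci, bl["C-O"], ba["CA-C-O"],
                     tor["psi"] + 180)
    atoms[[i]] <- rbind(N = Ni, CA = CAi, C = Ci, O = Oi)
    prevN <- Ni; prevCA <- CAi; prevC <- Ci
    tor_prev <- tor
  }
  do.call(rbind, atoms)
}

# rotate to principal axes so the bounding box is tight and axis-aligned
orient_principal <- function(xyz) {
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  sv <- svd(xc)
  rot <- sv$v
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]
  # longest axis last (z), deterministic ordering by singular value
  xc %*% rot[, order(sv$d)]
}

#' Generate a synthetic true structure
#'
#' Poly-alanine-like backbone (N, CA, C, O per residue) built from ideal
#' bond lengths, bond angles and conformation-specific torsions, oriented
#' along its principal axes.  Multiple chains are laid side by side.
#' Deterministic given the spec.
#'
#' @param spec a `dcn_scenario_spec`.
#' @return a `dcn_structure`.
#' @export
make_true_structure <- function(spec = scenario_spec()) {
  per_chain <- orient_principal(build_backbone(spec$n_residues,
                                               spec$geometry))
  blocks <- lapply(seq_len(spec$chain_count), function(k) {
    sweep(per_chain, 2, c(15 * (k - 1), 0, 0), "+")
  })
  xyz <- do.call(rbind, blocks)
  n_res <- spec$n_residues
  structure_from_atoms(
    chain = rep(LETTERS[seq_len(spec$chain_count)], each = 4 * n_res),
    resno = rep(rep(seq_len(n_res), each = 4), spec$chain_count),
    resid = "ALA",
    elety = rep(c("N", "CA", "C", "O"), n_res * spec$chain_count),
    xyz = xyz,
    elesy = rep(c("N", "C", "C", "O"), n_res * spec$chain_count),
    b = spec$b_data)
}

#' Perturb a structure toward a homology-model-like starting model
#'
#' Applies a smooth correlated displacement field (a few low-frequency
#' sinusoidal modes along the chain plus a small white-noise residual),
#' rescaled so the all-atom RMSD to the input is within 20% of
#' `target_rmsd`, then re-idealizes stereochemistry by a short tethered
#' minimization against the stereochemical energy.
#'
#' @param truth a `dcn_structure`.
#' @param target_rmsd target all-atom RMSD (A); 0 returns `truth`
#'   unchanged.
#' @param seed integer seed for the displacement field.
#' @return a `dcn_structure` with the same atom keys as `truth`.
#' @export
perturb_structure <- function(truth, target_rmsd, seed = 1L) {
  if (target_rmsd == 0) return(truth)
  n <- nrow(truth)
  xyz0 <- coords(truth)
  disp <- with_seed(seed, {
    d <- matrix(0, n, 3)
    for (ch in unique(truth$chain)) {
      rows <- which(truth$chain == ch)
      t <- seq(0, 1, length.out = length(rows))
      for (axis in 1:3) {
        v <- 0.1 * rnorm(length(rows))
        for (m in 1:3)
          v <- v + (rnorm(1) / m) * sin(pi * m * t + runif(1, 0, 2 * pi))
        d[rows, axis] <- v
      }
    }
    d
  })
  topo <- make_topology(truth)
  target <- target_rmsd
  sc <- target / sqrt(mean(rowSums(disp^2)))
  out_xyz <- xyz0
  for (iter in 1:4) {
    moved <- xyz0 + sc * disp
    out_xyz <- idealize_coords(moved, topo, tether = 10)
    ach <- sqrt(mean(rowSums((out_xyz - xyz0)^2)))
    if (abs(ach - target) <= 0.2 * target) break
    sc <- sc * target / ach
  }
  set_coords(truth, out_xyz)
}

# short L-BFGS minimization of stereo energy + harmonic tether to `ref`
idealize_coords <- function(ref, topo, tether = 10, maxit = 80) {
  n <- nrow(ref)
  fn <- function(v) {
    x <- matrix(v, n, 3)
    st <- cpp_stereo_energy_grad(x, topo, 1.0)
    st$energy + tether * sum((x - ref)^2)
  }
  gr <- function(v) {
    x <- matrix(v, n, 3)
    st <- cpp_stereo_energy_grad(x, topo, 1.0)
    as.numeric(st$gradient + 2 * tether * (x - ref))
  }
  res <- stats::optim(as.numeric(ref), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  matrix(res$par, n, 3)
}

#' Simulate amplitude data from a structure
#'
#' Encloses the model in an orthogonal P1 box (extent plus
#' `cell_margin`), enumerates every Friedel-unique integer `(h,k,l)` with
#' `d >= d_min` (excluding the origin), computes `F_obs = |F_calc|` from
#' the structure at `b_data`, optionally applies multiplicative Gaussian
#' noise, and flags a random free set.  Deterministic given the spec seed.
#'
#' @param truth a `dcn_structure`.
#' @param spec a `dcn_scenario_spec`.
#' @return a `dcn_reflections`.
#' @export
simulate_reflections <- function(truth, spec = scenario_spec()) {
  xyz <- coords(truth)
  cell <- apply(xyz, 2, function(v) diff(range(v))) + spec$cell_margin
  hmax <- floor(cell / spec$d_min)
  g <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                   l = 0:hmax[3], KEEP.OUT.ATTRS = FALSE)
  # Friedel-unique hemisphere: l > 0, or l = 0 & k > 0, or l = k = 0 & h > 0
  keep <- g$l > 0 | (g$l == 0 & g$k > 0) | (g$l == 0 & g$k == 0 & g$h > 0)
  g <- g[keep, , drop = FALSE]
  hkl <- as.matrix(g)
  inside <- (hkl[, 1] / cell[1])^2 + (hkl[, 2] / cell[2])^2 +
    (hkl[, 3] / cell[3])^2 <= 1 / spec$d_min^2 + 1e-12
  hkl <- hkl[inside, , drop = FALSE]
  m <- nrow(hkl)
  if (m < 50)
    stop("only ", m, " reflections inside the resolution sphere; ",
         "use a larger cell or a finer d_min", call. = FALSE)
  f <- Mod(cpp_structure_factors(xyz, cell, hkl, electron_counts(truth),
                                 spec$b_data))
  with_seed(derive_seed(spec$seed, 7L), {
    if (spec$noise_sigma > 0)
      f <- pmax(f * (1 + spec$noise_sigma * rnorm(m)), 0)
    free <- logical(m)
    free[sample.int(m, round(spec$free_fraction * m))] <- TRUE
  })
  reflection_set(cell, hkl, f, free, spec$d_min)
}

#' Compose a full synthetic scenario
#'
#' Generates the true structure, the perturbed starting model (which by
#' default also serves as the restraint reference) and the simulated
#' reflection data.  With `dir` set, writes `truth.pdb`, `start.pdb`,
#' `refl.txt` and a JSON manifest.
#'
#' @param spec a `dcn_scenario_spec`.
#' @param dir optional output directory.
#' @return list of class `dcn_scenario` with `truth`, `start_model`,
#'   `reflections`, `spec`, `achieved_rmsd`.
#' @export
make_scenario <- function(spec = scenario_spec(), dir = NULL) {
  truth <- make_true_structure(spec)
  start <- perturb_structure(truth, spec$perturbation_rmsd,
                             seed = derive_seed(spec$seed, 3L))
  refl <- simulate_reflections(truth, spec)
  sc <- list(truth = truth, start_model = start, reflections = refl,
             spec = spec,
             achieved_rmsd = rmsd(truth, start, superpose = FALSE))
  class(sc) <- "dcn_scenario"
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_pdb(truth, file.path(dir, "truth.pdb"))
    write_pdb(start, file.path(dir, "start.pdb"))
    write_reflections(refl, file.path(dir, "refl.txt"))
    manifest <- c(unclass(spec),
                  list(achieved_rmsd = sc$achieved_rmsd,
                       n_reflections = length(refl$f_obs),
                       n_free = sum(refl$free)))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  sc
}

#' @export
print.dcn_scenario <- function(x, ...) {
  cat(sprintf(
    "dcn_scenario: %d res x %d chain (%s), start RMSD %.2f A, %d reflections to %.1f A\n",
    x$spec$n_residues, x$spec$chain_count, x$spec$geometry,
    x$achieved_rmsd, length(x$reflections$f_obs), x$spec$d_min))
  invisible(x)
}

# ---- model-quality metrics ---------------------------------------------------

# Kabsch superposition of xyz (n x 3) onto ref (n x 3); returns rotated and
# translated xyz.
kabsch_fit <- function(xyz, ref) {
  cx <- colMeans(xyz); cr <- colMeans(ref)
  a <- sweep(xyz, 2, cx); b <- sweep(ref, 2, cr)
  sv <- svd(crossprod(a, b))
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(a %*% t(rot), 2, cr, "+")
}

#' All-atom RMSD between two structures
#'
#' Computed over the shared atom keys, optionally after optimal
#' (least-squares) superposition.
#'
#' @param s1,s2 `dcn_structure` objects.
#' @param superpose superpose `s2` onto `s1` first (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(s1, s2, superpose = TRUE) {
  corr <- match_atoms(s1, s2)
  x1 <- coords(s1)[key_index(s1, corr$target), , drop = FALSE]
  x2 <- coords(s2)[key_index(s2, corr$reference), , drop = FALSE]
  if (superpose) x2 <- kabsch_fit(x2, x1)
  sqrt(mean(rowSums((x1 - x2)^2)))
}

#' Fraction of CA atoms within 1 A of the reference
#'
#' A GDT-like model-quality score: after optimal superposition on all
#' shared atoms, the fraction of shared CA atoms whose deviation is below
#' `cutoff`.
#'
#' @param model,truth `dcn_structure` objects.
#' @param cutoff deviation cutoff in A (default 1).
#' @return fraction in \[0, 1\].
#' @export
gdt_score <- function(model, truth, cutoff = 1) {
  corr <- match_atoms(truth, model)
  i1 <- key_index(truth, corr$target)
  i2 <- key_index(model, corr$reference)
  x1 <- coords(truth)[i1, , drop = FALSE]
  x2 <- kabsch_fit(coords(model)[i2, , drop = FALSE], x1)
  is_ca <- truth$elety[i1] == "CA"
  if (!any(is_ca)) stop("no CA atoms shared", call. = FALSE)
  mean(sqrt(rowSums((x1[is_ca, , drop = FALSE] -
                     x2[is_ca, , drop = FALSE])^2)) < cutoff)
}
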