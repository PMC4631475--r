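# Refinement target:  E = E_stereo + w_a * E_exp + w_dcn * E_DCN
# where E_DCN = k * sum_i (d_i - d_eq_i)^2  +  k * sum_j (theta_j - theta_eq_j)^2
# (distances in Angstrom, angles in degrees, k = 0.01 for both sums) and
# E_exp is a least-squares amplitude residual with a closed-form scale.

#' Deformation and weighting parameters
#'
#' Parameters governing how restraint equilibria deform and how the three
#' target-function terms are weighted.
#'
#' `gamma` and `mu` set the mixing of reference versus current geometry in
#' the equilibrium updates for distances and angles respectively (1 = pull
#' fully toward the reference, 0 = track the current model).  `kappa` and
#' `phi` are the per-update rates of change of the equilibria.  `w_dcn`
#' weights the combined restraint energy; `w_a` weights the diffraction
#' term (`NULL` = determined automatically from the gradient-norm ratio at
#' the start of a refinement).  `k` is the spring constant applied to both
#' the distance (A^-2) and angle (deg^-2) sums; `k_pair`/`k_angle` override
#' it separately.
#'
#' @param gamma,mu fractions in \[0, 1\].
#' @param kappa,phi fractions in \[0, 1\].
#' @param w_dcn nonnegative restraint weight.
#' @param k spring constant (default 0.01).
#' @param k_pair,k_angle separate overrides for the pair/angle sums.
#' @param w_a nonnegative data weight, or `NULL` for automatic.
#' @return list of class `dcn_deformation_params`.
#' @export
deformation_params <- function(gamma = 0.6, mu = 0.6, kappa = 0.1, phi = 0.1,
                               w_dcn = 30, k = 0.01, k_pair = k,
                               k_angle = k, w_a = NULL) {
  stopifnot(gamma >= 0, gamma <= 1, mu >= 0, mu <= 1,
            kappa >= 0, kappa <= 1, phi >= 0, phi <= 1,
            w_dcn >= 0, k > 0, k_pair > 0, k_angle > 0,
            is.null(w_a) || w_a >= 0)
  p <- list(gamma = gamma, mu = mu, kappa = kappa, phi = phi,
            w_dcn = w_dcn, k = k, k_pair = k_pair, k_angle = k_angle,
            w_a = w_a)
  class(p) <- "dcn_deformation_params"
  p
}

# restraint keys -> 0-based row indices for the kernels
pair_indices <- function(s, pairs)
  list(a = key_index(s, pairs$a, "pair restraint") - 1L,
       b = key_index(s, pairs$b, "pair restraint") - 1L)

angle_indices <- function(s, angles)
  list(v = key_index(s, angles$vertex, "angle restraint") - 1L,
       t1 = key_index(s, angles$tail1, "angle restraint") - 1L,
       t2 = key_index(s, angles$tail2, "angle restraint") - 1L)

#' Deformable elastic network (pair) energy
#'
#' `E = k * sum_i (d_i - d_eq_i)^2` over all pair restraints, with the
#' exact analytic gradient.  A coincident pair (zero distance) contributes
#' zero energy and gradient, with a warning.
#'
#' @param s a `dcn_structure` supplying coordinates.
#' @param pairs pair-restraint data.frame (columns `a`, `b`, `d_eq`).
#' @param k spring constant (A^-2).
#' @return list with `energy` and `gradient` (n x 3 matrix).
#' @export
den_energy <- function(s, pairs, k = 0.01) {
  if (NROW(pairs) == 0L)
    return(list(energy = 0, gradient = matrix(0, nrow(s), 3)))
  i <- pair_indices(s, pairs)
  res <- cpp_den_energy_grad(coords(s), i$a, i$b, pairs$d_eq, k)
  if (res$n_degenerate > 0)
    warning(res$n_degenerate,
            " coincident pair(s) contribute zero energy and gradient",
            call. = FALSE)
  list(energy = res$energy, gradient = res$gradient)
}

#' Deformable angular network (triplet) energy
#'
#' `E = k * sum_j (theta_j - theta_eq_j)^2` with angles in degrees, with
#' the analytic gradient (numerically guarded near 0/180 degrees).  A
#' degenerate triplet (zero-length arm) contributes zero, with a warning.
#'
#' @param s a `dcn_structure`.
#' @param angles angle-restraint data.frame (columns `vertex`, `tail1`,
#'   `tail2`, `theta_eq`).
#' @param k spring constant (deg^-2).
#' @return list with `energy` and `gradient`.
#' @export
dan_energy <- function(s, angles, k = 0.01) {
  if (NROW(angles) == 0L)
    return(list(energy = 0, gradient = matrix(0, nrow(s), 3)))
  i <- angle_indices(s, angles)
  res <- cpp_dan_energy_grad(coords(s), i$v, i$t1, i$t2, angles$theta_eq, k)
  if (res$n_degenerate > 0)
    warning(res$n_degenerate,
            " degenerate angle triplet(s) contribute zero energy and gradient",
            call. = FALSE)
  list(energy = res$energy, gradient = res$gradient)
}

#' Combined DCN restraint energy
#'
#' The deformable complex network energy is the sum of the pair (DEN) and
#' angle (DAN) harmonic energies; its contribution to the refinement target
#' is `w_dcn * E_DCN`.
#'
#' @param s a `dcn_structure`.
#' @param rs a `dcn_restraint_set`.
#' @param p `dcn_deformation_params` (uses `w_dcn`, `k_pair`, `k_angle`).
#' @return list with `energy` (unweighted `E_DCN`), `gradient` (of
#'   `w_dcn * E_DCN`), and components `e_den`, `e_dan`.
#' @export
dcn_energy <- function(s, rs, p = deformation_params()) {
  den <- den_energy(s, rs$pairs, p$k_pair)
  dan <- dan_energy(s, rs$angles, p$k_angle)
  list(energy = den$energy + dan$energy,
       e_den = den$energy, e_dan = dan$energy,
       gradient = p$w_dcn * (den$gradient + dan$gradient))
}

#' Simplified stereochemical energy
#'
#' Harmonic bonds, harmonic bond angles (radians internally) and a quartic
#' soft-sphere repulsion `k_rep * (r_min - d)^4` acting on nonbonded pairs
#' closer than the scaled sum of their element radii.
#'
#' @param s a `dcn_structure`.
#' @param topo a topology from [make_topology()].
#' @param vdw_scale scale factor applied to the repulsion radii (the
#'   annealing protocol uses 0.75 early and 1 late).
#' @return list with `energy`, components `e_bond`, `e_angle`, `e_rep`,
#'   and `gradient`.
#' @export
stereo_energy <- function(s, topo, vdw_scale = 1) {
  stopifnot(inherits(topo, "dcn_topology"), vdw_scale > 0, vdw_scale <= 1)
  res <- cpp_stereo_energy_grad(coords(s), topo, vdw_scale)
  res[c("energy", "e_bond", "e_angle", "e_rep", "gradient")]
}

# ---- Reflection data ---------------------------------------------------------

#' Construct a reflection set
#'
#' Amplitude data in a P1 box: Miller indices, observed amplitudes and the
#' cross-validation (free) flags.
#'
#' @param cell numeric length-3 box edge lengths (A).
#' @param hkl integer matrix (m x 3) of Miller indices, unique, without
#'   (0,0,0).
#' @param f_obs nonnegative amplitudes.
#' @param free logical free-set flags (fraction strictly between 0 and 0.5).
#' @param d_min resolution limit (A); every reflection must satisfy
#'   `d >= d_min`.
#' @return list of class `dcn_reflections`.
#' @export
reflection_set <- function(cell, hkl, f_obs, free, d_min) {
  hkl <- matrix(as.integer(hkl), ncol = 3)
  stopifnot(length(cell) == 3, all(cell > 0), nrow(hkl) == length(f_obs),
            length(free) == length(f_obs), d_min > 0)
  if (any(f_obs < 0)) stop("negative amplitude(s)", call. = FALSE)
  if (anyDuplicated(hkl)) stop("duplicate Miller indices", call. = FALSE)
  if (any(rowSums(hkl == 0L) == 3L)) stop("(0,0,0) is not a reflection",
                                          call. = FALSE)
  d <- reflection_d(cell, hkl)
  if (any(d < d_min * (1 - 1e-9)))
    stop("reflection(s) beyond the stated resolution limit d_min",
         call. = FALSE)
  fr <- mean(free)
  if (fr <= 0 || fr >= 0.5)
    stop("free-set fraction must lie strictly between 0 and 0.5 (got ",
         signif(fr, 3), ")", call. = FALSE)
  r <- list(cell = as.numeric(cell), hkl = hkl, f_obs = as.numeric(f_obs),
            free = as.logical(free), d_min = d_min)
  class(r) <- "dcn_reflections"
  r
}

# d-spacing of each reflection in an orthogonal P1 cell
reflection_d <- function(cell, hkl) {
  1 / sqrt((hkl[, 1] / cell[1])^2 + (hkl[, 2] / cell[2])^2 +
           (hkl[, 3] / cell[3])^2)
}

#' @export
print.dcn_reflections <- function(x, ...) {
  cat(sprintf(
    "dcn_reflections: %d reflections to %.2f A, cell %.1f x %.1f x %.1f A, %d free (%.1f%%)\n",
    length(x$f_obs), x$d_min, x$cell[1], x$cell[2], x$cell[3],
    sum(x$free), 100 * mean(x$free)))
  invisible(x)
}

#' Write reflections to a text file
#'
#' Format: a header line `# cell <a> <b> <c> dmin <d>` followed by one
#' whitespace-delimited record `h k l Fobs free` per reflection
#' (`free` is 0/1).
#'
#' @param refl a `dcn_reflections`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_reflections <- function(refl, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# cell %.6f %.6f %.6f dmin %.6f",
                     refl$cell[1], refl$cell[2], refl$cell[3], refl$d_min),
             con)
  writeLines(sprintf("%d %d %d %.8g %d", refl$hkl[, 1], refl$hkl[, 2],
                     refl$hkl[, 3], refl$f_obs, as.integer(refl$free)), con)
  invisible(path)
}

#' Read reflections from a text file
#'
#' Accepts the whitespace-delimited format of [write_reflections()] and a
#' CSV dialect (`h,k,l,Fobs,free` records with the same `# cell ... dmin
#' ...` header).
#'
#' @param path input path.
#' @return a `dcn_reflections`.
#' @export
read_reflections <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#\\s*cell\\b", lines, value = TRUE)
  if (length(hdr) == 0)
    stop("missing '# cell a b c dmin d' header in ", path, call. = FALSE)
  toks <- strsplit(trimws(hdr[1]), "[[:space:],]+")[[1]]
  nums <- suppressWarnings(as.numeric(toks))
  nums <- nums[!is.na(nums)]
  if (length(nums) < 4) stop("malformed reflection header", call. = FALSE)
  cell <- nums[1:3]; d_min <- nums[4]
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  sep <- if (any(grepl(",", body[1], fixed = TRUE))) "," else ""
  tab <- utils::read.table(text = body, sep = sep, header = FALSE,
                           strip.white = TRUE)
  if (ncol(tab) != 5)
    stop("expected 5 columns (h k l Fobs free) in ", path, call. = FALSE)
  reflection_set(cell, as.matrix(tab[, 1:3]), tab[, 4],
                 as.logical(tab[, 5]), d_min)
}

# ---- Data term ---------------------------------------------------------------

ELECTRON_COUNTS <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15, SE = 34,
                     FE = 26, ZN = 30, MG = 12, CA = 20, MN = 25)

electron_counts <- function(s) {
  z <- ELECTRON_COUNTS[toupper(s$elesy)]
  z[is.na(z)] <- 6
  unname(z)
}

#' Structure factors by direct summation
#'
#' `F(h) = sum_atoms z exp(-B s^2 / 4) exp(2 pi i h . x_frac)` in an
#' orthogonal P1 cell, with `z` the element electron count.  Atoms outside
#' the cell wrap periodically (the phase is unchanged by integer-cell
#' translations).
#'
#' @param s a `dcn_structure`.
#' @param refl a `dcn_reflections` (supplies cell and indices).
#' @param b_overall overall isotropic B (A^2).
#' @return complex vector of calculated structure factors, one per
#'   reflection.
#' @export
calc_structure_factors <- function(s, refl, b_overall = 0) {
  cpp_structure_factors(coords(s), refl$cell, refl$hkl, electron_counts(s),
                        b_overall)
}

#' Least-squares amplitude target
#'
#' `E = sum_work (F_obs - s |F_calc|)^2` with `s` the closed-form optimal
#' linear scale over the working set.  Free reflections never contribute to
#' the energy or the gradient.
#'
#' @param s a `dcn_structure`.
#' @param refl a `dcn_reflections`.
#' @param b_overall overall isotropic B (A^2).
#' @return list with `energy`, `gradient`, `scale`.
#' @export
exp_energy <- function(s, refl, b_overall = 0) {
  work <- !refl$free
  if (!any(work)) stop("working set is empty", call. = FALSE)
  if (all(refl$f_obs[work] == 0))
    stop("all working F_obs are zero; amplitude scale undefined",
         call. = FALSE)
  res <- cpp_exp_energy_grad(coords(s), refl$cell, refl$hkl,
                             electron_counts(s), b_overall, refl$f_obs,
                             work, TRUE)
  res[c("energy", "gradient", "scale")]
}

#' R factors over the working and free sets
#'
#' `R = sum |F_obs - s |F_calc|| / sum F_obs` per set, with the linear
#' scale `s` fitted on the working set only.
#'
#' @param s a `dcn_structure`.
#' @param refl a `dcn_reflections`.
#' @param b_overall overall isotropic B (A^2).
#' @return list with `r_work`, `r_free`, `scale`.
#' @export
r_factors <- function(s, refl, b_overall = 0) {
  if (!any(refl$free)) stop("free set is empty", call. = FALSE)
  if (!any(!refl$free)) stop("working set is empty", call. = FALSE)
  fc <- Mod(calc_structure_factors(s, refl, b_overall))
  r_factors_from_amplitudes(refl$f_obs, fc, refl$free)
}

r_factors_from_amplitudes <- function(fobs, fc, free) {
  work <- !free
  den <- sum(fc[work]^2)
  sc <- if (den > 0) sum(fobs[work] * fc[work]) / den else 0
  list(r_work = sum(abs(fobs[work] - sc * fc[work])) / sum(fobs[work]),
       r_free = sum(abs(fobs[free] - sc * fc[free])) / sum(fobs[free]),
       scale = sc)
}

#' Total refinement target
#'
#' `E = E_stereo + w_a * E_exp + w_dcn * E_DCN` with the summed analytic
#' gradient.
#'
#' @param s a `dcn_structure`.
#' @param rs a `dcn_restraint_set` (may hold zero restraints).
#' @param refl a `dcn_reflections`, or `NULL` to omit the data term.
#' @param topo a `dcn_topology`.
#' @param p `dcn_deformation_params`; `p$w_a` must be numeric here
#'   (automatic weighting is resolved by [run_refinement()]).
#' @param b_overall overall isotropic B (A^2).
#' @param vdw_scale repulsion radius scale.
#' @return list with `energy`, `gradient`, and the component energies.
#' @export
total_target <- function(s, rs, refl, topo, p = deformation_params(),
                         b_overall = 0, vdw_scale = 1) {
  st <- stereo_energy(s, topo, vdw_scale)
  w_a <- if (is.null(p$w_a)) 0 else p$w_a
  ex <- if (!is.null(refl) && w_a > 0) exp_energy(s, refl, b_overall)
        else list(energy = 0, gradient = 0, scale = NA_real_)
  dc <- if (p$w_dcn > 0) dcn_energy(s, rs, p)
        else list(energy = 0, e_den = 0, e_dan = 0, gradient = 0)
  list(energy = st$energy + w_a * ex$energy + p$w_dcn * dc$energy,
       gradient = st$gradient + w_a * ex$gradient + dc$gradient,
       e_stereo = st$energy, e_exp = ex$energy, e_dcn = dc$energy,
       e_den = dc$e_den, e_dan = dc$e_dan, scale = ex$scale)
}
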