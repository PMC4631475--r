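# Simulated-annealing refinement with deformable-equilibrium updates.
#
# Temperature starts at t_start and drops by t_step after every microcycle
# of steps_per_microcycle dynamics steps; one sweep from t_start down to
# t_step is a macrocycle.  Restraint equilibria update once per microcycle.
# During the first relax_macrocycles the update rates kappa/phi are zero;
# repulsion radii are scaled down except in the last two macrocycles; the
# DCN weight is zeroed in the last final_zero_w_macrocycles.

# Internal unit system: unit atomic masses; Boltzmann constant KB maps the
# kelvin scale of the schedule onto the energy scale of the force field;
# FS_TO_DT maps the femtosecond time step onto integrator units.  Both are
# calibrated so that the default protocol is stable on backbone models
# with the default force constants.
KB <- 0.001
FS_TO_DT <- 0.002
FORCE_CAP <- 1e4

#' Annealing protocol configuration
#'
#' Defaults: a 3000 K start cooled by 50 K per six-step microcycle (60
#' microcycles per macrocycle), eight macrocycles, equilibrium-update rates
#' kappa/phi of 0 for the first three macrocycles and 0.1 afterwards,
#' repulsion radii at 75% except in the last two macrocycles, and the DCN
#' weight zeroed in the last two macrocycles.
#'
#' @param t_start starting temperature (K).
#' @param t_step temperature drop per microcycle (K); must divide
#'   `t_start`.
#' @param steps_per_microcycle dynamics steps per microcycle.
#' @param macrocycles number of annealing sweeps.
#' @param relax_macrocycles initial macrocycles with kappa = phi = 0.
#' @param final_zero_w_macrocycles trailing macrocycles with the DCN
#'   weight forced to zero.
#' @param kappa_phi_value the kappa/phi value used after relaxation.
#' @param vdw_scale_early repulsion-radius scale outside the last two
#'   macrocycles.
#' @param timestep dynamics time step (fs).
#' @param seed integer seed for velocity assignment.
#' @return list of class `dcn_protocol_config`.
#' @export
protocol_config <- function(t_start = 3000, t_step = 50,
                            steps_per_microcycle = 6, macrocycles = 8,
                            relax_macrocycles = 3,
                            final_zero_w_macrocycles = 2,
                            kappa_phi_value = 0.1, vdw_scale_early = 0.75,
                            timestep = 4, seed = 1L) {
  stopifnot(t_start > 0, t_step > 0, t_start %% t_step == 0,
            steps_per_microcycle >= 1, macrocycles >= 1,
            relax_macrocycles >= 0, final_zero_w_macrocycles >= 0,
            relax_macrocycles + final_zero_w_macrocycles <= macrocycles,
            kappa_phi_value >= 0, kappa_phi_value <= 1,
            vdw_scale_early > 0, vdw_scale_early <= 1, timestep > 0)
  cfg <- list(t_start = t_start, t_step = t_step,
              steps_per_microcycle = as.integer(steps_per_microcycle),
              macrocycles = as.integer(macrocycles),
              relax_macrocycles = as.integer(relax_macrocycles),
              final_zero_w_macrocycles = as.integer(final_zero_w_macrocycles),
              kappa_phi_value = kappa_phi_value,
              vdw_scale_early = vdw_scale_early,
              timestep = timestep, seed = as.integer(seed))
  class(cfg) <- "dcn_protocol_config"
  cfg
}

#' Microcycle temperature schedule
#'
#' Per macrocycle the temperatures are `t_start, t_start - t_step, ...,
#' t_step`, repeated for every macrocycle.
#'
#' @param cfg a `dcn_protocol_config`.
#' @return data.frame with columns `macrocycle`, `microcycle`,
#'   `temperature`.
#' @export
anneal_schedule <- function(cfg = protocol_config()) {
  temps <- seq(cfg$t_start, cfg$t_step, by = -cfg$t_step)
  data.frame(macrocycle = rep(seq_len(cfg$macrocycles), each = length(temps)),
             microcycle = rep(seq_along(temps), cfg$macrocycles),
             temperature = rep(temps, cfg$macrocycles))
}

#' Update restraint equilibria toward reference/current geometry
#'
#' Convex-combination update applied once per microcycle:
#' `d_eq <- (1 - kappa) d_eq + kappa * (gamma * d_ref + (1 - gamma) * d_now)`
#' and analogously for angles with `phi`/`mu`, where `d_now`/`theta_now`
#' are measured in the current coordinates.  With `kappa = phi = 0` the
#' equilibria are unchanged; with `gamma = 1` repeated updates converge
#' geometrically to the reference values, with `gamma = 0` they track the
#' current model.
#'
#' @param rs a `dcn_restraint_set`.
#' @param s a `dcn_structure` with the current coordinates.
#' @param p `dcn_deformation_params`.
#' @return the updated restraint set.
#' @export
update_equilibria <- function(rs, s, p = deformation_params()) {
  stopifnot(inherits(rs, "dcn_restraint_set"))
  if (p$kappa == 0 && p$phi == 0) return(rs)
  xyz <- coords(s)
  if (nrow(rs$pairs) && p$kappa > 0) {
    i <- pair_indices(s, rs$pairs)
    d_now <- measure_pair_distances(xyz, i$a + 1L, i$b + 1L)
    ok <- d_now > 1e-9
    if (any(!ok))
      warning(sum(!ok), " degenerate pair(s) skipped in equilibrium update",
              call. = FALSE)
    tgt <- p$gamma * rs$pairs$d_ref + (1 - p$gamma) * d_now
    rs$pairs$d_eq[ok] <- (1 - p$kappa) * rs$pairs$d_eq[ok] +
      p$kappa * tgt[ok]
  }
  if (nrow(rs$angles) && p$phi > 0) {
    i <- angle_indices(s, rs$angles)
    m <- measure_triplet_angles(xyz, i$v + 1L, i$t1 + 1L, i$t2 + 1L)
    ok <- m$ok
    if (any(!ok))
      warning(sum(!ok),
              " degenerate triplet(s) skipped in equilibrium update",
              call. = FALSE)
    tgt <- p$mu * rs$angles$theta_ref + (1 - p$mu) * m$theta
    rs$angles$theta_eq[ok] <- (1 - p$phi) * rs$angles$theta_eq[ok] +
      p$phi * tgt[ok]
  }
  rs
}

measure_pair_distances <- function(xyz, ia, ib) {
  sqrt(rowSums((xyz[ia, , drop = FALSE] - xyz[ib, , drop = FALSE])^2))
}

measure_triplet_angles <- function(xyz, iv, i1, i2) {
  u <- xyz[i1, , drop = FALSE] - xyz[iv, , drop = FALSE]
  w <- xyz[i2, , drop = FALSE] - xyz[iv, , drop = FALSE]
  nu <- sqrt(rowSums(u^2)); nw <- sqrt(rowSums(w^2))
  ok <- nu > 1e-9 & nw > 1e-9
  cs <- rowSums(u * w) / pmax(nu * nw, 1e-300)
  cs <- pmin(1, pmax(-1, cs))
  list(theta = acos(cs) * 180 / pi, ok = ok)
}

# internal: restraints resolved to 0-based indices for the kernel
dcn_kernel_args <- function(s, rs) {
  if (nrow(rs$pairs)) {
    ip <- pair_indices(s, rs$pairs)
  } else ip <- list(a = integer(0), b = integer(0))
  if (nrow(rs$angles)) {
    ia <- angle_indices(s, rs$angles)
  } else ia <- list(v = integer(0), t1 = integer(0), t2 = integer(0))
  list(pair_a = ip$a, pair_b = ip$b, d_eq = as.numeric(rs$pairs$d_eq),
       ang_v = ia$v, ang_t1 = ia$t1, ang_t2 = ia$t2,
       theta_eq = as.numeric(rs$angles$theta_eq))
}

# 1-D scan for the overall isotropic B minimizing R_work
scan_b_overall <- function(s, refl, b_grid = seq(0, 100, by = 5)) {
  fc0 <- Mod(calc_structure_factors(s, refl, 0))
  d <- reflection_d(refl$cell, refl$hkl)
  s2 <- 1 / d^2
  rw <- vapply(b_grid, function(b) {
    fc <- fc0 * exp(-b * s2 / 4)
    r_factors_from_amplitudes(refl$f_obs, fc, refl$free)$r_work
  }, numeric(1))
  b_grid[which.min(rw)]
}

#' Run one simulated-annealing refinement
#'
#' Cartesian velocity-Verlet dynamics against the total target, with
#' Maxwell-Boltzmann velocity assignment at the start of each macrocycle,
#' per-microcycle velocity rescaling to the schedule temperature, and
#' equilibrium updates once per microcycle.  The protocol schedule follows
#' `cfg` (see [protocol_config()]); equilibrium updates are suspended
#' whenever the DCN weight is zero (they would no longer affect the
#' target).  The returned structure is the final dynamics frame.
#'
#' @param start starting `dcn_structure`.
#' @param rs a `dcn_restraint_set` with initialized equilibria.
#' @param refl a `dcn_reflections`.
#' @param topo a `dcn_topology`, or `NULL` to build one from `start`.
#' @param p `dcn_deformation_params`; `p$w_a = NULL` triggers automatic
#'   data weighting from the gradient-norm ratio at the start.
#' @param cfg a `dcn_protocol_config`.
#' @param b_overall overall isotropic B (A^2), or `NULL` to select it by a
#'   1-D scan against R_work at the start of every macrocycle.
#' @return list of class `dcn_refinement_result` with `final_structure`,
#'   `r_work`, `r_free`, `trace` (one row per macrocycle), `w_a`,
#'   `b_overall`, `seed`, `params`.
#' @export
run_refinement <- function(start, rs, refl, topo = NULL,
                           p = deformation_params(),
                           cfg = protocol_config(), b_overall = NULL) {
  if (is.null(topo)) topo <- make_topology(start)
  stopifnot(inherits(rs, "dcn_restraint_set"),
            inherits(refl, "dcn_reflections"))
  n <- nrow(start)
  xyz <- coords(start)
  z <- electron_counts(start)
  scan_b <- is.null(b_overall)
  b_now <- if (scan_b) scan_b_overall(start, refl) else b_overall
  xray <- list(cell = refl$cell, hkl = refl$hkl, z = z, fobs = refl$f_obs,
               work = !refl$free, b_overall = b_now)

  # automatic data weight: balance the stereochemical and data gradients
  w_a <- p$w_a
  if (is.null(w_a)) {
    gs <- stereo_energy(start, topo, cfg$vdw_scale_early)$gradient
    ge <- exp_energy(start, refl, b_now)$gradient
    rms <- function(m) sqrt(mean(m^2))
    w_a <- if (rms(ge) > 0) rms(gs) / rms(ge) else 1
  }

  temps <- seq(cfg$t_start, cfg$t_step, by = -cfg$t_step)
  dt <- cfg$timestep * FS_TO_DT
  trace <- vector("list", cfg$macrocycles)
  s_now <- start

  with_seed(cfg$seed, {
    for (mc in seq_len(cfg$macrocycles)) {
      kp <- if (mc <= cfg$relax_macrocycles) 0 else cfg$kappa_phi_value
      vdw <- if (mc > cfg$macrocycles - 2) 1 else cfg$vdw_scale_early
      w <- if (mc > cfg$macrocycles - cfg$final_zero_w_macrocycles) 0
           else p$w_dcn
      if (scan_b) {
        b_now <- scan_b_overall(s_now, refl)
        xray$b_overall <- b_now
      }
      vel <- matrix(rnorm(3 * n), n, 3) * sqrt(KB * temps[1])
      dcn_args <- dcn_kernel_args(s_now, rs)
      p_mc <- p; p_mc$kappa <- kp; p_mc$phi <- kp
      for (im in seq_along(temps)) {
        # rescale kinetic energy to the schedule temperature
        ke <- 0.5 * sum(vel^2)
        target <- 1.5 * n * KB * temps[im]
        if (ke > 0) vel <- vel * sqrt(target / ke)
        seg <- cpp_md_segment(coords(s_now), vel, cfg$steps_per_microcycle,
                              dt, topo, vdw, xray, w_a, dcn_args, w,
                              p$k_pair, p$k_angle, FORCE_CAP)
        if (!seg$ok)
          stop(sprintf(
            "refinement blew up (non-finite energy) at macrocycle %d, microcycle %d",
            mc, im), call. = FALSE)
        s_now <- set_coords(s_now, seg$xyz)
        vel <- seg$vel
        if (w > 0 && kp > 0) {
          rs <- update_equilibria(rs, s_now, p_mc)
          dcn_args$d_eq <- as.numeric(rs$pairs$d_eq)
          dcn_args$theta_eq <- as.numeric(rs$angles$theta_eq)
        }
      }
      rf <- r_factors(s_now, refl, b_now)
      trace[[mc]] <- data.frame(
        macrocycle = mc, r_work = rf$r_work, r_free = rf$r_free,
        e_stereo = seg$e_stereo, e_exp = seg$e_exp,
        e_den = seg$e_den, e_dan = seg$e_dan,
        w_dcn = w, kappa_phi = kp, vdw_scale = vdw, b_overall = b_now)
    }
  })

  trace <- do.call(rbind, trace)
  rf <- r_factors(s_now, refl, b_now)
  out <- list(final_structure = s_now, r_work = rf$r_work,
              r_free = rf$r_free, trace = trace, w_a = w_a,
              b_overall = b_now, seed = cfg$seed, params = p,
              restraints = rs)
  class(out) <- "dcn_refinement_result"
  out
}

#' @export
print.dcn_refinement_result <- function(x, ...) {
  cat(sprintf(
    "dcn_refinement_result: R_work %.4f, R_free %.4f after %d macrocycles (seed %d)\n",
    x$r_work, x$r_free, nrow(x$trace), x$seed))
  invisible(x)
}
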