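# Three-dimensional grid search over (gamma, w_dcn, mu), seeded repeats at
# each point, winner by lowest R_free.

#' Grid-search specification
#'
#' Defaults reproduce the canonical 180-point grid — six values of gamma,
#' five of w_dcn, six of mu — with ten refinement repeats per point using
#' the integer seeds 1 to 10.
#'
#' @param gamma_values,mu_values mixing fractions in \[0, 1\].
#' @param w_values DCN weights (nonnegative).
#' @param seeds unique integer seeds; each seed re-randomizes both the
#'   restraint selection and the velocity assignment.
#' @return list of class `dcn_grid_spec`.
#' @export
grid_spec <- function(gamma_values = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                      w_values = c(3, 10, 30, 100, 300),
                      mu_values = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                      seeds = 1:10) {
  stopifnot(length(gamma_values) > 0, length(w_values) > 0,
            length(mu_values) > 0, length(seeds) > 0,
            !anyDuplicated(seeds),
            all(gamma_values >= 0 & gamma_values <= 1),
            all(mu_values >= 0 & mu_values <= 1), all(w_values >= 0))
  sp <- list(gamma_values = gamma_values, w_values = w_values,
             mu_values = mu_values, seeds = as.integer(seeds))
  class(sp) <- "dcn_grid_spec"
  sp
}

#' Enumerate grid points
#'
#' Cartesian product of the three value lists in deterministic order:
#' gamma outermost, w_dcn middle, mu innermost.
#'
#' @param spec a `dcn_grid_spec`.
#' @return data.frame with columns `gamma`, `w_dcn`, `mu` and a `point`
#'   index.
#' @export
grid_points <- function(spec = grid_spec()) {
  g <- expand.grid(mu = spec$mu_values, w_dcn = spec$w_values,
                   gamma = spec$gamma_values, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("gamma", "w_dcn", "mu")]
  g$point <- seq_len(nrow(g))
  rownames(g) <- NULL
  g
}

#' Run the grid search
#'
#' For every grid point and every seed, regenerates the restraint
#' selection with that seed, runs a full refinement, and records
#' `(point, seed, r_work, r_free, status)`.  The per-point winner and the
#' global winner are the runs with the lowest `r_free`; ties break to the
#' lower `w_dcn`, then earlier enumeration order, then lower seed.
#' Individual run failures are recorded as `status = "failed"` and the
#' search continues.
#'
#' If `progress_file` is given, completed rows are appended to it as the
#' search proceeds and are skipped on restart, making long searches
#' resumable; the winning refinement is re-run (deterministically) if its
#' structure is not in memory.
#'
#' @param start starting `dcn_structure` (also the default reference).
#' @param reference reference `dcn_structure` supplying restraint
#'   geometry.
#' @param refl a `dcn_reflections`.
#' @param spec a `dcn_grid_spec`.
#' @param topo optional `dcn_topology` (built from `start` if `NULL`).
#' @param selection base `dcn_selection_params` (its seed is overridden
#'   per run).
#' @param cfg base `dcn_protocol_config` (its seed is overridden per run).
#' @param p_base base `dcn_deformation_params` (gamma, w_dcn, mu are
#'   overridden per point).
#' @param b_overall passed to [run_refinement()].
#' @param progress_file optional CSV path for resumable progress.
#' @param n_workers number of worker processes (forked via the parallel
#'   package); results are identical to serial execution.
#' @return list of class `dcn_grid_result` with `table` (all runs),
#'   `per_point` (best run per point), `best` (winning parameters/seed),
#'   and `best_result` (the winning `dcn_refinement_result`).
#' @export
run_grid <- function(start, reference, refl, spec = grid_spec(),
                     topo = NULL, selection = selection_params(),
                     cfg = protocol_config(), p_base = deformation_params(),
                     b_overall = NULL, progress_file = NULL, n_workers = 1) {
  if (is.null(topo)) topo <- make_topology(start)
  pts <- grid_points(spec)
  runs <- merge(pts, data.frame(seed = spec$seeds))
  runs <- runs[order(runs$point, runs$seed), ]
  rownames(runs) <- NULL

  done <- NULL
  if (!is.null(progress_file) && file.exists(progress_file)) {
    done <- utils::read.csv(progress_file, stringsAsFactors = FALSE)
  }

  one_run <- function(i) {
    row <- runs[i, ]
    res <- tryCatch(
      run_grid_single(start, reference, refl, topo, selection, cfg, p_base,
                      row$gamma, row$w_dcn, row$mu, row$seed, b_overall),
      error = function(e) e)
    if (inherits(res, "error")) {
      list(r_work = NA_real_, r_free = NA_real_, status = "failed",
           result = NULL, message = conditionMessage(res))
    } else {
      list(r_work = res$r_work, r_free = res$r_free, status = "ok",
           result = res, message = "")
    }
  }

  todo <- seq_len(nrow(runs))
  if (!is.null(done) && nrow(done)) {
    key <- paste(runs$point, runs$seed)
    todo <- todo[!(key %in% paste(done$point, done$seed))]
  }
  results <- vector("list", nrow(runs))
  if (length(todo)) {
    if (n_workers > 1 && .Platform$OS.type == "unix") {
      computed <- parallel::mclapply(todo, one_run, mc.cores = n_workers,
                                     mc.preschedule = TRUE)
    } else {
      computed <- lapply(todo, one_run)
    }
    results[todo] <- computed
  }

  tab <- runs
  tab$r_work <- NA_real_; tab$r_free <- NA_real_; tab$status <- "done_prior"
  for (i in seq_len(nrow(tab))) {
    if (!is.null(results[[i]])) {
      tab$r_work[i] <- results[[i]]$r_work
      tab$r_free[i] <- results[[i]]$r_free
      tab$status[i] <- results[[i]]$status
    }
  }
  if (!is.null(done) && nrow(done)) {
    m <- match(paste(done$point, done$seed), paste(tab$point, tab$seed))
    ok <- !is.na(m)
    tab$r_work[m[ok]] <- done$r_work[ok]
    tab$r_free[m[ok]] <- done$r_free[ok]
    tab$status[m[ok]] <- done$status[ok]
  }
  if (!is.null(progress_file))
    utils::write.csv(tab[, c("point", "gamma", "w_dcn", "mu", "seed",
                             "r_work", "r_free", "status")],
                     progress_file, row.names = FALSE)
  if (all(is.na(tab$r_free)))
    stop("all grid-search runs failed", call. = FALSE)

  # winner: lowest r_free; ties -> lower w_dcn, then point order, then seed
  ord <- order(tab$r_free, tab$w_dcn, tab$point, tab$seed, na.last = TRUE)
  best_row <- tab[ord[1], ]
  per_point <- do.call(rbind, lapply(split(tab, tab$point), function(g) {
    o <- order(g$r_free, g$w_dcn, g$point, g$seed, na.last = TRUE)
    g[o[1], ]
  }))
  rownames(per_point) <- NULL

  i_best <- which(tab$point == best_row$point & tab$seed == best_row$seed)
  best_result <- if (!is.null(results[[i_best]]) &&
                     !is.null(results[[i_best]]$result)) {
    results[[i_best]]$result
  } else {
    run_grid_single(start, reference, refl, topo, selection, cfg, p_base,
                    best_row$gamma, best_row$w_dcn, best_row$mu,
                    best_row$seed, b_overall)
  }

  out <- list(table = tab, per_point = per_point,
              best = best_row[, c("point", "gamma", "w_dcn", "mu", "seed",
                                  "r_work", "r_free")],
              best_result = best_result, spec = spec)
  class(out) <- "dcn_grid_result"
  out
}

run_grid_single <- function(start, reference, refl, topo, selection, cfg,
                            p_base, gamma, w_dcn, mu, seed, b_overall) {
  sel <- selection; sel$seed <- as.integer(seed)
  rs <- generate_restraints(start, reference, sel, starting = start)
  p <- p_base; p$gamma <- gamma; p$w_dcn <- w_dcn; p$mu <- mu
  run_cfg <- cfg; run_cfg$seed <- as.integer(seed)
  run_refinement(start, rs, refl, topo = topo, p = p, cfg = run_cfg,
                 b_overall = b_overall)
}

#' @export
print.dcn_grid_result <- function(x, ...) {
  cat(sprintf(
    "dcn_grid_result: %d runs (%d failed); best R_free %.4f at gamma=%.2f w_dcn=%g mu=%.2f (seed %d)\n",
    nrow(x$table), sum(x$table$status == "failed"), x$best$r_free,
    x$best$gamma, x$best$w_dcn, x$best$mu, x$best$seed))
  invisible(x)
}
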