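# Deformable restraint generation.
#
# DEN: harmonic distance restraints between randomly chosen atom pairs.
# DAN: harmonic restraints on the vertex angle of randomly chosen atom
#      triplets.  A triplet is admissible when
#        (i)   all three atoms lie in one polypeptide chain,
#        (ii)  both tails are within a cutoff distance of the vertex,
#        (iii) each tail is no more than a maximum number of residues from
#              the vertex, and
#        (iv)  the vertex angle lies inside a band (default 60-120 deg).
# Both networks are drawn from the reference structure and restricted to
# atoms present in both target and reference.

#' Selection parameters for restraint generation
#'
#' Defaults follow common practice for reference-model restraints: a 15 A
#' cutoff, at most ten residues between vertex and tail, a 60-120 degree
#' vertex-angle band, and one restraint per atom of the target structure.
#'
#' @param cutoff distance cutoff in A for pairs and for vertex-tail
#'   distances.
#' @param max_residue_separation maximum `|resno(vertex) - resno(tail)|`
#'   (applied to each tail independently, and to the two atoms of a pair).
#' @param angle_min,angle_max admissible vertex-angle band in degrees.
#' @param restraint_multiple number of restraints drawn from each candidate
#'   pool, as a multiple of the number of target atoms.
#' @param mode `"directional"` (vertex serial must precede both tail
#'   serials) or `"arbitrary"` (any vertex assignment passing the criteria).
#' @param seed integer seed controlling the random draw.
#' @return A list of class `dcn_selection_params`.
#' @export
selection_params <- function(cutoff = 15, max_residue_separation = 10,
                             angle_min = 60, angle_max = 120,
                             restraint_multiple = 1,
                             mode = c("directional", "arbitrary"),
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(cutoff > 0, max_residue_separation >= 0,
            angle_min > 0, angle_min < angle_max, angle_max < 180,
            restraint_multiple > 0)
  p <- list(cutoff = cutoff,
            max_residue_separation = as.integer(max_residue_separation),
            angle_min = angle_min, angle_max = angle_max,
            restraint_multiple = restraint_multiple,
            mode = mode, seed = as.integer(seed))
  class(p) <- "dcn_selection_params"
  p
}

# Waters never carry restraints; HETATM ligands may (if matched).
WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

restraint_eligible <- function(s) {
  atom_keys(s)[!(s$resid %in% WATER_RESNAMES)]
}

# Rows of `reference` usable for restraints, in serial order.
eligible_rows <- function(reference, corr) {
  ok <- restraint_eligible(reference)
  idx <- key_index(reference, corr$reference, "correspondence")
  sort(idx[atom_keys(reference)[idx] %in% ok])
}

#' Enumerate candidate angle (DAN) restraints
#'
#' Applies admissibility criteria (i)-(iv) to all atom triplets of the
#' reference structure whose atoms are matched in the correspondence.
#' Geometry (vertex-tail distances and the vertex angle) is measured in the
#' reference structure, which is the model the restraints encode.  Tails are
#' canonically ordered (`serial(tail1) < serial(tail2)`); in directional
#' mode only triplets whose vertex serial precedes both tail serials are
#' kept, in arbitrary mode every admissible vertex assignment is kept.
#'
#' @param reference a `dcn_structure`.
#' @param corr correspondence from [match_atoms()].
#' @param p `dcn_selection_params`.
#' @return data.frame with columns `vertex`, `tail1`, `tail2` (keys),
#'   `theta_ref`, `theta_eq` (degrees); possibly zero rows.
#' @export
enumerate_dan_candidates <- function(reference, corr, p = selection_params()) {
  stopifnot(nrow(corr) > 0)
  rows <- eligible_rows(reference, corr)
  res <- cpp_enumerate_dan(coords(reference), as.integer(rows) - 1L,
                           reference$serial,
                           match(reference$chain, unique(reference$chain)),
                           reference$resno,
                           p$cutoff, p$max_residue_separation,
                           p$angle_min, p$angle_max,
                           p$mode == "directional")
  k <- atom_keys(reference)
  out <- data.frame(vertex = k[res$vertex], tail1 = k[res$tail1],
                    tail2 = k[res$tail2],
                    theta_ref = res$theta, theta_eq = res$theta,
                    stringsAsFactors = FALSE)
  out
}

#' Enumerate candidate pair (DEN) restraints
#'
#' All same-chain atom pairs matched in the correspondence whose reference
#' distance is within the cutoff and whose residue separation is within the
#' maximum, unordered-unique (first atom has the lower serial).
#'
#' @inheritParams enumerate_dan_candidates
#' @return data.frame with columns `a`, `b` (keys), `d_ref`, `d_eq` (A).
#' @export
enumerate_den_candidates <- function(reference, corr, p = selection_params()) {
  stopifnot(nrow(corr) > 0)
  rows <- eligible_rows(reference, corr)
  res <- cpp_enumerate_den(coords(reference), as.integer(rows) - 1L,
                           match(reference$chain, unique(reference$chain)),
                           reference$resno,
                           p$cutoff, p$max_residue_separation)
  k <- atom_keys(reference)
  data.frame(a = k[res$a], b = k[res$b], d_ref = res$d, d_eq = res$d,
             stringsAsFactors = FALSE)
}

#' Randomly select restraints from a candidate pool
#'
#' Draws `round(restraint_multiple * n_atoms)` candidates uniformly without
#' replacement.  The pool is sorted canonically before sampling so a given
#' seed yields the same selection regardless of enumeration order.  If the
#' pool is smaller than the request the whole pool is returned with a
#' warning.
#'
#' @param candidates data.frame from an `enumerate_*` function.
#' @param n_atoms number of atoms in the target structure.
#' @param p `dcn_selection_params` (uses `restraint_multiple` and `seed`).
#' @return the selected subset of `candidates`.
#' @export
select_restraints <- function(candidates, n_atoms, p = selection_params()) {
  stopifnot(nrow(candidates) > 0)
  keycols <- intersect(c("vertex", "tail1", "tail2", "a", "b"),
                       names(candidates))
  ord <- do.call(order, candidates[keycols])
  candidates <- candidates[ord, , drop = FALSE]
  n_req <- round(p$restraint_multiple * n_atoms)
  if (nrow(candidates) < n_req) {
    warning(sprintf("candidate pool (%d) smaller than requested %d restraints;
 using entire pool", nrow(candidates), n_req), call. = FALSE)
    rownames(candidates) <- NULL
    return(candidates)
  }
  sel <- with_seed(p$seed, sample.int(nrow(candidates), n_req))
  out <- candidates[sort(sel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a full DCN restraint set
#'
#' Convenience driver: matches atoms, enumerates DEN pair and DAN triplet
#' candidates in the reference structure, randomly selects
#' `restraint_multiple * n_atoms` of each (independent streams derived from
#' `p$seed`), and initialises equilibrium values from the starting
#' structure.
#'
#' @param target structure being refined.
#' @param reference structure supplying restraint geometry.
#' @param p `dcn_selection_params`.
#' @param starting structure supplying initial equilibrium values
#'   (default: the target).
#' @param key_map optional key mapping passed to [match_atoms()].
#' @return A `dcn_restraint_set`: list with elements `pairs`, `angles`,
#'   `params`, `seed`.
#' @export
generate_restraints <- function(target, reference, p = selection_params(),
                                starting = target, key_map = NULL) {
  corr <- match_atoms(target, reference, key_map)
  den <- enumerate_den_candidates(reference, corr, p)
  dan <- enumerate_dan_candidates(reference, corr, p)
  n_atoms <- nrow(target)
  # independent sub-streams for the two pools, both derived from p$seed
  p_den <- p; p_den$seed <- derive_seed(p$seed, 1L)
  p_dan <- p; p_dan$seed <- derive_seed(p$seed, 2L)
  rs <- list(pairs = select_restraints(den, n_atoms, p_den),
             angles = select_restraints(dan, n_atoms, p_dan),
             params = p, seed = p$seed)
  class(rs) <- "dcn_restraint_set"
  init_equilibria(rs, starting)
}

#' @export
print.dcn_restraint_set <- function(x, ...) {
  cat(sprintf("dcn_restraint_set: %d pair (DEN) + %d angle (DAN) restraints, seed %d\n",
              nrow(x$pairs), nrow(x$angles), x$seed))
  invisible(x)
}

#' Initialise restraint equilibrium values from a starting structure
#'
#' Sets every pair's `d_eq` and every triplet's `theta_eq` to the value
#' measured in `starting`; reference values are untouched.  When the
#' starting structure is the reference itself, equilibria equal reference
#' values.
#'
#' @param rs a `dcn_restraint_set`.
#' @param starting a `dcn_structure` resolving all restrained atoms.
#' @return the updated restraint set.
#' @export
init_equilibria <- function(rs, starting) {
  stopifnot(inherits(rs, "dcn_restraint_set"))
  xyz <- coords(starting)
  if (nrow(rs$pairs)) {
    ia <- key_index(starting, rs$pairs$a, "pair restraint")
    ib <- key_index(starting, rs$pairs$b, "pair restraint")
    rs$pairs$d_eq <- sqrt(rowSums((xyz[ia, , drop = FALSE] -
                                   xyz[ib, , drop = FALSE])^2))
  }
  if (nrow(rs$angles)) {
    iv <- key_index(starting, rs$angles$vertex, "angle restraint")
    i1 <- key_index(starting, rs$angles$tail1, "angle restraint")
    i2 <- key_index(starting, rs$angles$tail2, "angle restraint")
    rs$angles$theta_eq <- vapply(seq_along(iv), function(j)
      angle_deg(xyz[iv[j], ], xyz[i1[j], ], xyz[i2[j], ]), numeric(1))
  }
  rs
}

# ---- Restraint file format ---------------------------------------------------
#
# One record per line:
#   PAIR chain resno name chain resno name d_ref d_eq
#   ANGL chain resno name chain resno name chain resno name theta_ref theta_eq
# ANGL lists the triplet in the order vertex, first tail, second tail.

split_key <- function(k) {
  parts <- strsplit(k, "/", fixed = TRUE)
  do.call(rbind, parts)
}

#' Write a restraint set to a text file
#'
#' @param rs a `dcn_restraint_set`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_restraints <- function(rs, path) {
  stopifnot(inherits(rs, "dcn_restraint_set"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# dcn restraints seed=%d mode=%s", rs$seed,
                     rs$params$mode), con)
  if (nrow(rs$pairs)) {
    a <- split_key(rs$pairs$a); b <- split_key(rs$pairs$b)
    writeLines(sprintf("PAIR %s %s %s %s %s %s %.6f %.6f",
                       a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3],
                       rs$pairs$d_ref, rs$pairs$d_eq), con)
  }
  if (nrow(rs$angles)) {
    v <- split_key(rs$angles$vertex)
    t1 <- split_key(rs$angles$tail1); t2 <- split_key(rs$angles$tail2)
    writeLines(sprintf("ANGL %s %s %s %s %s %s %s %s %s %.6f %.6f",
                       v[, 1], v[, 2], v[, 3], t1[, 1], t1[, 2], t1[, 3],
                       t2[, 1], t2[, 2], t2[, 3],
                       rs$angles$theta_ref, rs$angles$theta_eq), con)
  }
  invisible(path)
}

#' Read a restraint set from a text file
#'
#' @param path file written by [write_restraints()].
#' @param params optional `dcn_selection_params` to attach.
#' @return a `dcn_restraint_set`.
#' @export
read_restraints <- function(path, params = selection_params()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  pairs <- list(); angles <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (f[1] == "PAIR") {
      if (length(f) != 9)
        stop("malformed PAIR record at line ", i, call. = FALSE)
      pairs[[length(pairs) + 1L]] <- data.frame(
        a = paste(f[2], f[3], f[4], sep = "/"),
        b = paste(f[5], f[6], f[7], sep = "/"),
        d_ref = as.numeric(f[8]), d_eq = as.numeric(f[9]),
        stringsAsFactors = FALSE)
    } else if (f[1] == "ANGL") {
      if (length(f) != 12)
        stop("malformed ANGL record at line ", i, call. = FALSE)
      angles[[length(angles) + 1L]] <- data.frame(
        vertex = paste(f[2], f[3], f[4], sep = "/"),
        tail1 = paste(f[5], f[6], f[7], sep = "/"),
        tail2 = paste(f[8], f[9], f[10], sep = "/"),
        theta_ref = as.numeric(f[11]), theta_eq = as.numeric(f[12]),
        stringsAsFactors = FALSE)
    } else {
      stop("unknown restraint tag '", f[1], "' at line ", i, call. = FALSE)
    }
  }
  empty_pairs <- data.frame(a = character(), b = character(),
                            d_ref = numeric(), d_eq = numeric(),
                            stringsAsFactors = FALSE)
  empty_angles <- data.frame(vertex = character(), tail1 = character(),
                             tail2 = character(), theta_ref = numeric(),
                             theta_eq = numeric(), stringsAsFactors = FALSE)
  rs <- list(pairs = if (length(pairs)) do.call(rbind, pairs) else empty_pairs,
             angles = if (length(angles)) do.call(rbind, angles)
                      else empty_angles,
             params = params, seed = params$seed)
  class(rs) <- "dcn_restraint_set"
  rs
}

# ---- seeded randomness -------------------------------------------------------

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-stream seed (kept below 2^31).
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 11 * as.numeric(stream)) %% 2147483629)
}
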