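# Minimal stereochemical topology for backbone models: harmonic bonds and
# bond angles plus a repulsion-only nonbonded term.  Ideal values come from
# a small internal dictionary of standard backbone geometry, falling back
# to the geometry observed in the supplied model for anything unknown.

# standard backbone geometry (lengths in A, angles in degrees); the same
# constants drive the synthetic-structure builder, so an unperturbed
# synthetic model is exactly at the stereochemical minimum.
IDEAL_BONDS <- c("N-CA" = 1.458, "CA-C" = 1.525, "C-O" = 1.231,
                 "C-N" = 1.329, "CA-CB" = 1.521)
IDEAL_ANGLES <- c("N-CA-C" = 111.2, "CA-C-O" = 120.8, "CA-C-N" = 116.2,
                  "O-C-N" = 123.0, "C-N-CA" = 121.7,
                  "N-CA-CB" = 110.4, "C-CA-CB" = 110.5)
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Build a stereochemical topology for a structure
#'
#' Connectivity is derived from backbone atom names (N-CA, CA-C, C-O,
#' CA-CB within a residue; C-N between consecutive residues of one chain)
#' plus distance-based detection (`< 1.9` A) for any remaining covalent
#' contacts.  Bond angles are every pair of bonds sharing an atom.  Ideal
#' values come from a standard backbone dictionary where known, otherwise
#' from the supplied structure.  Nonbonded repulsion acts on all pairs
#' separated by more than three bonds (1-2, 1-3 and 1-4 excluded: those
#' distances are fixed, or nearly fixed, by the covalent terms), with
#' per-element van der Waals radii.
#'
#' @param s a `dcn_structure` (typically the starting model).
#' @param k_bond,k_angle,k_rep force constants (energy / A^2,
#'   energy / rad^2, energy / A^4).
#' @param repel_radius_scale base factor applied to the van der Waals
#'   radii sum of every nonbonded pair.  Repulsion-only terms
#'   conventionally use radii below the full van der Waals values so that
#'   legitimate close contacts (hydrogen bonds, helix carbonyl stacking)
#'   are not penalized; the annealing protocol's `vdw_scale` multiplies
#'   this base factor.
#' @param ideal `"table"` to prefer the standard dictionary, `"model"` to
#'   take every ideal value from the geometry of `s`.
#' @return list of class `dcn_topology` holding 0-based index vectors and
#'   ideal values for the kernels.
#' @export
make_topology <- function(s, k_bond = 300, k_angle = 80, k_rep = 50,
                          ideal = c("table", "model"),
                          repel_radius_scale = 0.9) {
  ideal <- match.arg(ideal)
  n <- nrow(s)
  xyz <- coords(s)
  name <- trimws(s$elety)

  bi <- integer(0); bj <- integer(0)
  add_bond <- function(i, j) {
    if (length(i)) { bi <<- c(bi, i); bj <<- c(bj, j) }
  }
  # named backbone connectivity
  row_of <- function(atname, chain, resno) {
    idx <- match(paste(chain, resno, atname, sep = "/"), atom_keys(s))
    idx
  }
  res_tab <- unique(s[, c("chain", "resno")])
  for (pair in list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("CA", "CB"))) {
    i <- row_of(pair[1], res_tab$chain, res_tab$resno)
    j <- row_of(pair[2], res_tab$chain, res_tab$resno)
    ok <- !is.na(i) & !is.na(j)
    add_bond(i[ok], j[ok])
  }
  # peptide bond between consecutive residues of the same chain
  i <- row_of("C", res_tab$chain, res_tab$resno)
  j <- row_of("N", res_tab$chain, res_tab$resno + 1L)
  ok <- !is.na(i) & !is.na(j)
  add_bond(i[ok], j[ok])

  # distance-based detection for atoms not covered by the named rules
  have <- paste(pmin(bi, bj), pmax(bi, bj))
  covered <- unique(c(bi, bj))
  loose <- setdiff(seq_len(n), covered)
  if (length(loose)) {
    for (i in loose) {
      d2 <- colSums((t(xyz) - xyz[i, ])^2)
      near <- which(d2 > 1e-6 & d2 < 1.9^2 & s$chain == s$chain[i])
      for (j in near) {
        tag <- paste(min(i, j), max(i, j))
        if (!(tag %in% have)) { add_bond(i, j); have <- c(have, tag) }
      }
    }
  }
  if (length(bi) == 0) stop("no bonds detected; cannot build a topology",
                            call. = FALSE)

  blen_obs <- sqrt(rowSums((xyz[bi, , drop = FALSE] -
                            xyz[bj, , drop = FALSE])^2))
  btag <- paste(name[bi], name[bj], sep = "-")
  btag2 <- paste(name[bj], name[bi], sep = "-")
  blen <- if (ideal == "model") blen_obs else {
    v <- IDEAL_BONDS[btag]
    v[is.na(v)] <- IDEAL_BONDS[btag2][is.na(v)]
    v[is.na(v)] <- blen_obs[is.na(v)]
    unname(v)
  }

  # bond angles: neighbours of each atom, all pairs
  nb <- vector("list", n)
  for (r in seq_along(bi)) {
    nb[[bi[r]]] <- c(nb[[bi[r]]], bj[r])
    nb[[bj[r]]] <- c(nb[[bj[r]]], bi[r])
  }
  av <- integer(0); a1 <- integer(0); a2 <- integer(0)
  for (v in seq_len(n)) {
    ng <- sort(unique(nb[[v]]))
    if (length(ng) >= 2) {
      cmb <- utils::combn(ng, 2)
      av <- c(av, rep(v, ncol(cmb))); a1 <- c(a1, cmb[1, ])
      a2 <- c(a2, cmb[2, ])
    }
  }
  ang_obs <- vapply(seq_along(av), function(r)
    angle_deg(xyz[av[r], ], xyz[a1[r], ], xyz[a2[r], ]), numeric(1))
  atag <- paste(name[a1], name[av], name[a2], sep = "-")
  atag2 <- paste(name[a2], name[av], name[a1], sep = "-")
  adeg <- if (ideal == "model") ang_obs else {
    v <- IDEAL_ANGLES[atag]
    v[is.na(v)] <- IDEAL_ANGLES[atag2][is.na(v)]
    v[is.na(v)] <- ang_obs[is.na(v)]
    unname(v)
  }

  # nonbonded pairs: everything except 1-2, 1-3 and 1-4 (whose distances
  # are fixed, or nearly fixed, by the covalent terms)
  excl <- new.env(hash = TRUE)
  mark <- function(i, j) assign(paste(min(i, j), max(i, j)), TRUE,
                                envir = excl)
  for (r in seq_along(bi)) mark(bi[r], bj[r])
  for (r in seq_along(av)) mark(a1[r], a2[r])
  for (r in seq_along(bi)) {
    for (i2 in setdiff(nb[[bi[r]]], bj[r]))
      for (j2 in setdiff(nb[[bj[r]]], bi[r]))
        if (i2 != j2) mark(i2, j2)
  }
  radius <- VDW_RADII[toupper(s$elesy)]
  radius[is.na(radius)] <- 1.70
  ni <- integer(0); nj <- integer(0)
  cmb <- utils::combn(n, 2)
  tags <- paste(cmb[1, ], cmb[2, ])
  keep <- !vapply(tags, exists, logical(1), envir = excl, inherits = FALSE)
  ni <- cmb[1, keep]; nj <- cmb[2, keep]

  topo <- list(
    bond_i = as.integer(bi - 1L), bond_j = as.integer(bj - 1L),
    bond_len = as.numeric(blen), k_bond = k_bond,
    angle_v = as.integer(av - 1L), angle_i = as.integer(a1 - 1L),
    angle_j = as.integer(a2 - 1L), angle_rad = as.numeric(adeg) * pi / 180,
    k_angle = k_angle,
    nb_i = as.integer(ni - 1L), nb_j = as.integer(nj - 1L),
    nb_rsum = as.numeric(repel_radius_scale * (radius[ni] + radius[nj])),
    k_rep = k_rep,
    n_atoms = n)
  class(topo) <- c("dcn_topology", "list")
  topo
}

#' @export
print.dcn_topology <- function(x, ...) {
  cat(sprintf("dcn_topology: %d bonds, %d angles, %d nonbonded pairs (%d atoms)\n",
              length(x$bond_i), length(x$angle_v), length(x$nb_i),
              x$n_atoms))
  invisible(x)
}
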