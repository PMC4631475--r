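#' @useDynLib dcnrefine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif optim median setNames
#' @importFrom utils read.table write.table head
NULL

# ---- Structure container -----------------------------------------------------
#
# A structure is a data.frame (class "dcn_structure") with one row per atom:
#   serial  integer, strictly increasing in file order
#   chain   single character chain identifier
#   resno   integer residue number (1-based, PDB convention)
#   resid   3-letter residue name
#   elety   atom name (PDB atom-name field, e.g. "CA", "OD1")
#   elesy   element symbol ("C", "N", ...)
#   x,y,z   orthogonal coordinates in Angstrom
#   b       isotropic B factor (A^2)
#   o       occupancy
# Atoms are identified throughout by the key (chain, resno, elety).

#' Construct a structure object from per-atom vectors
#'
#' Low-level constructor for the atom table used throughout the package.
#' Most users will obtain structures from [read_pdb()] or
#' [make_true_structure()] instead.
#'
#' @param chain chain identifiers (single characters).
#' @param resno integer residue numbers.
#' @param resid 3-letter residue names.
#' @param elety atom names.
#' @param xyz numeric matrix with one row per atom and columns x, y, z (A).
#' @param elesy element symbols; derived from the first letter of `elety`
#'   when missing.
#' @param b,o B factors (A^2) and occupancies, recycled.
#' @param serial atom serial numbers; defaults to `1:n`.
#' @return An object of class `dcn_structure`.
#' @export
structure_from_atoms <- function(chain, resno, resid, elety, xyz,
                                 elesy = NULL, b = 0, o = 1, serial = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  if (is.null(elesy)) elesy <- substr(gsub("[0-9]", "", elety), 1, 1)
  if (is.null(serial)) serial <- seq_len(n)
  s <- data.frame(
    serial = as.integer(serial),
    chain = rep_len(as.character(chain), n),
    resno = rep_len(as.integer(resno), n),
    resid = rep_len(as.character(resid), n),
    elety = rep_len(as.character(elety), n),
    elesy = rep_len(as.character(elesy), n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = rep_len(as.numeric(b), n),
    o = rep_len(as.numeric(o), n),
    stringsAsFactors = FALSE
  )
  class(s) <- c("dcn_structure", "data.frame")
  validate_structure(s)
  s
}

validate_structure <- function(s) {
  if (nrow(s) == 0L) stop("structure contains zero atoms", call. = FALSE)
  if (!all(is.finite(c(s$x, s$y, s$z))))
    stop("structure contains non-finite coordinates", call. = FALSE)
  k <- atom_keys(s)
  if (anyDuplicated(k))
    stop("duplicate atom key(s): ",
         paste(unique(k[duplicated(k)])[1:min(3, sum(duplicated(k)))],
               collapse = ", "), call. = FALSE)
  if (any(diff(s$serial) <= 0))
    stop("atom serial numbers must strictly increase", call. = FALSE)
  invisible(s)
}

#' Atom keys of a structure
#'
#' Returns the `(chain, resno, atom name)` identity key of every atom as a
#' character vector `"chain/resno/name"`, in atom order.
#'
#' @param s a `dcn_structure`.
#' @return character vector of keys.
#' @export
atom_keys <- function(s) paste(s$chain, s$resno, s$elety, sep = "/")

#' Coordinate matrix of a structure
#'
#' @param s a `dcn_structure`.
#' @return numeric n x 3 matrix of coordinates (A).
#' @export
coords <- function(s) cbind(x = s$x, y = s$y, z = s$z)

#' Replace the coordinates of a structure
#'
#' @param s a `dcn_structure`.
#' @param xyz numeric n x 3 matrix.
#' @return `s` with new coordinates.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s), ncol(xyz) == 3)
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}

# Resolve keys to row indices; error (naming the key) if any are missing.
key_index <- function(s, keys, what = "atom") {
  idx <- match(keys, atom_keys(s))
  if (anyNA(idx))
    stop("cannot resolve ", what, " key(s): ",
         paste(head(keys[is.na(idx)], 3), collapse = ", "), call. = FALSE)
  idx
}

#' @export
print.dcn_structure <- function(x, ...) {
  cat(sprintf("dcn_structure: %d atoms, %d chain(s), residues %d..%d\n",
              nrow(x), length(unique(x$chain)), min(x$resno), max(x$resno)))
  invisible(x)
}

# ---- PDB input/output --------------------------------------------------------

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (fixed-column PDB layout).  Alternate-location
#' indicators other than blank or `'A'` are skipped.  Records carrying
#' insertion codes are rejected: the package identifies atoms by
#' `(chain, residue number, atom name)` and has no ordering for inserted
#' residues.  Hydrogens are dropped by default, following the convention of
#' restrained refinement at low resolution.
#'
#' @param path path to a PDB file.
#' @param keep_hydrogens keep element-H atoms (default `FALSE`).
#' @return A `dcn_structure`.
#' @export
read_pdb <- function(path, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("empty structure: no ATOM/HETATM records in ", path,
                          call. = FALSE)
  bad <- which(is_atom & nchar(lines) < 54)
  if (length(bad))
    stop("malformed ATOM/HETATM record at line ", bad[1],
         " (too short for coordinate columns)", call. = FALSE)
  ins <- which(is_atom & substr(lines, 27, 27) != " ")
  if (length(ins))
    stop("insertion code at line ", ins[1],
         ": insertion codes are not supported; renumber the model",
         call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = TRUE,
                                     multi = FALSE)),
    error = function(e) stop("malformed PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  a <- pdb$atom
  keep <- rep(TRUE, nrow(a))
  elesy <- trimws(a$elesy)
  noel <- is.na(elesy) | elesy == ""
  elesy[noel] <- substr(gsub("[^A-Za-z]", "", a$elety[noel]), 1, 1)
  if (!keep_hydrogens) keep <- keep & !(toupper(elesy) %in% c("H", "D"))
  a <- a[keep, , drop = FALSE]
  elesy <- elesy[keep]
  if (nrow(a) == 0L)
    stop("empty structure: no non-hydrogen atoms in ", path, call. = FALSE)
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- " "
  s <- data.frame(
    serial = as.integer(a$eleno),
    chain = chain, resno = as.integer(a$resno), resid = a$resid,
    elety = a$elety, elesy = toupper(elesy),
    x = a$x, y = a$y, z = a$z,
    b = ifelse(is.na(a$b), 0, a$b), o = ifelse(is.na(a$o), 1, a$o),
    stringsAsFactors = FALSE
  )
  # bio3d preserves file order; re-serialise if the file's serials repeat
  # (e.g. >99999-atom overflow) so the strict-increase invariant holds.
  if (any(diff(s$serial) <= 0)) s$serial <- seq_len(nrow(s))
  class(s) <- c("dcn_structure", "data.frame")
  validate_structure(s)
  s
}

#' Write a structure to a PDB file
#'
#' Standard fixed-column ATOM records with coordinates at 3 decimals and
#' serial numbers renumbered 1..N, followed by TER/END.
#'
#' @param s a `dcn_structure`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(s, path) {
  validate_structure(s)
  xyz <- coords(s)
  if (any(abs(xyz) >= 10000))
    stop("coordinate magnitude >= 10000 A cannot be written in PDB ",
         "fixed columns", call. = FALSE)
  n <- nrow(s)
  # PDB atom-name column convention: names of 1-3 characters whose element
  # symbol is one letter start in column 14.
  name <- vapply(s$elety, function(e) {
    if (nchar(e) >= 4) substr(e, 1, 4) else sprintf(" %-3s", e)
  }, character(1))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n), name, s$resid, s$chain, s$resno,
    xyz[, 1], xyz[, 2], xyz[, 3], s$o, s$b, s$elesy)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

# ---- Correspondence and geometry --------------------------------------------

#' Match atoms between a target and a reference structure
#'
#' Restraints may only involve atoms present in both the target and the
#' reference structure.  Atoms are matched by identical
#' `(chain, residue number, atom name)` keys; the reference is assumed to be
#' renumbered onto the target's scheme (as produced by molecular replacement
#' of per-chain homology models).  For mismatched numbering supply
#' `key_map`, a two-column table of corresponding keys.
#'
#' @param target,reference `dcn_structure` objects.
#' @param key_map optional data.frame/matrix with columns `target`,
#'   `reference` giving explicit key pairs (`"chain/resno/name"` form).
#' @return A data.frame of class `dcn_correspondence` with columns
#'   `target`, `reference` (keys), in target serial order.
#' @export
match_atoms <- function(target, reference, key_map = NULL) {
  tk <- atom_keys(target)
  rk <- atom_keys(reference)
  if (is.null(key_map)) {
    shared <- tk[tk %in% rk]
    out <- data.frame(target = shared, reference = shared,
                      stringsAsFactors = FALSE)
  } else {
    key_map <- as.data.frame(key_map, stringsAsFactors = FALSE)
    stopifnot(all(c("target", "reference") %in% names(key_map)))
    if (anyDuplicated(key_map$target) || anyDuplicated(key_map$reference))
      stop("key_map must be one-to-one", call. = FALSE)
    ok <- key_map$target %in% tk & key_map$reference %in% rk
    out <- key_map[ok, c("target", "reference"), drop = FALSE]
    out <- out[order(match(out$target, tk)), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (nrow(out) == 0L)
    stop("no atom correspondence between target and reference ",
         "(no shared (chain, resno, atom name) keys)", call. = FALSE)
  class(out) <- c("dcn_correspondence", "data.frame")
  out
}

#' Distance between two atoms
#'
#' @param s a `dcn_structure`.
#' @param a,b atom keys (`"chain/resno/name"`).
#' @return Euclidean distance in Angstrom.
#' @export
atom_distance <- function(s, a, b) {
  i <- key_index(s, c(a, b))
  xyz <- coords(s)
  sqrt(sum((xyz[i[1], ] - xyz[i[2], ])^2))
}

#' Vertex angle spanned by three atoms
#'
#' The angle at `vertex` between the vectors vertex->tail1 and
#' vertex->tail2.
#'
#' @param s a `dcn_structure`.
#' @param vertex,tail1,tail2 atom keys.
#' @return angle in degrees, in \[0, 180\].
#' @export
atom_angle <- function(s, vertex, tail1, tail2) {
  i <- key_index(s, c(vertex, tail1, tail2))
  xyz <- coords(s)
  angle_deg(xyz[i[1], ], xyz[i[2], ], xyz[i[3], ])
}

# vertex v, tails t1/t2 as coordinate triples
angle_deg <- function(v, t1, t2) {
  u <- t1 - v; w <- t2 - v
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0)
    stop("degenerate angle: zero-length arm at vertex", call. = FALSE)
  cs <- sum(u * w) / (nu * nw)
  cs <- min(1, max(-1, cs))
  acos(cs) * 180 / pi
}
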