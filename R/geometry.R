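# Geometry module: structure parsing, bond perception and measurement of the
# keto-enol fragment bond lengths i-v.

# Covalent radii in Angstrom (Cordero-type single-bond values), frozen here so
# bond perception never depends on an external lookup.  Carbon uses the sp3
# value; for the conjugated rings handled here the 1.2 tolerance factor
# absorbs the difference.
COVALENT_RADII <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05,
  Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Fe = 1.32, Cu = 1.32, Zn = 1.22,
  Se = 1.20, Br = 1.20, I = 1.39
)

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe"
)

#' Construct a 3D molecule
#'
#' A minimal container for an optimized 3D geometry: element symbols,
#' Cartesian coordinates in Angstrom, and an (optionally empty) list of
#' covalent bonds.  Bonds can be supplied from an SDF connection table or
#' perceived from distances with \code{\link{perceive_bonds}}.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param bonds two-column integer matrix of 1-based atom index pairs, or
#'   NULL for no connectivity yet.
#' @param name free-text identifier.
#' @return An object of class \code{molecule3d} with fields \code{elements},
#'   \code{coords}, \code{bonds} and \code{name}.
#' @export
molecule3d <- function(elements, coords, bonds = NULL, name = "") {
  coords <- as.matrix(coords)
  if (length(elements) < 1L) stop2("a molecule needs at least one atom")
  if (nrow(coords) != length(elements) || ncol(coords) != 3L)
    stop2("coords must be a %d x 3 matrix", length(elements))
  if (any(!is.finite(coords))) stop2("all coordinates must be finite")
  bad <- setdiff(unique(elements), ELEMENT_SYMBOLS)
  if (length(bad))
    stop2("unknown element symbol(s): %s", paste(bad, collapse = ", "))
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2L)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  n <- length(elements)
  if (nrow(bonds)) {
    if (any(bonds < 1L | bonds > n)) stop2("bond index out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop2("self-bonds are not allowed")
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (anyDuplicated(key)) stop2("duplicate bonds are not allowed")
  }
  structure(list(elements = as.character(elements), coords = coords,
                 bonds = bonds, name = as.character(name)),
            class = "molecule3d")
}

#' @export
print.molecule3d <- function(x, ...) {
  cat(sprintf("<molecule3d> %s: %d atoms, %d bonds\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              length(x$elements), nrow(x$bonds)))
  invisible(x)
}

#' Read an XYZ structure file
#'
#' Parses the plain xmol dialect: atom count, comment line, then one
#' "symbol x y z" line per atom (coordinates in Angstrom).  The comment line
#' becomes the molecule name; connectivity is left empty for later
#' perception.
#'
#' @param path path to an XYZ file.
#' @return A \code{\link{molecule3d}} with no bonds.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) < 1L) stop2("%s: empty file (line 1)", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L)
    stop2("%s: malformed atom count on line 1: '%s'", path, lines[1])
  if (length(lines) != n + 2L)
    stop2("%s: header declares %d atoms but file has %d atom lines",
          path, n, max(length(lines) - 2L, 0L))
  name <- trimws(lines[2])
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L)
      stop2("%s: expected 'symbol x y z' on line %d", path, ln)
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop2("%s: non-numeric coordinate on line %d", path, ln)
    if (!(tok[1] %in% ELEMENT_SYMBOLS))
      stop2("%s: unknown element symbol '%s' on line %d", path, tok[1], ln)
    elements[i] <- tok[1]
    coords[i, ] <- xyz
  }
  molecule3d(elements, coords, name = name)
}

#' Read an SDF/MOL file (V2000)
#'
#' Parses one or more MOL V2000 records (separated by \code{$$$$}) and
#' returns their geometries with bonds taken from the connection table.
#' Bond orders are recorded in an extra column of \code{bonds} but treated
#' as advisory; fragment perception relies on distances and element types.
#'
#' @param path path to an SDF or MOL file.
#' @return A list of \code{\link{molecule3d}} objects, one per record.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(0L, head(trimws(lines), -1) == "$$$$")))
  recs <- Filter(function(r) any(nzchar(trimws(r))), recs)
  if (!length(recs)) stop2("%s: no MOL records found", path)
  lapply(recs, parse_mol_record, path = path)
}

parse_mol_record <- function(rec, path) {
  rec <- rec[trimws(rec) != "$$$$"]
  if (length(rec) < 4L) stop2("%s: truncated MOL record", path)
  counts <- rec[4]
  if (grepl("V3000", counts))
    stop2("%s: V3000 connection tables are not supported (V2000 only)", path)
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds))
    stop2("%s: malformed counts line '%s'", path, counts)
  if (length(rec) < 4L + natoms + nbonds)
    stop2("%s: truncated MOL record (declares %d atoms, %d bonds)",
          path, natoms, nbonds)
  elements <- character(natoms)
  coords <- matrix(NA_real_, natoms, 3L)
  for (i in seq_len(natoms)) {
    al <- rec[4L + i]
    xyz <- suppressWarnings(as.numeric(c(substr(al, 1, 10),
                                         substr(al, 11, 20),
                                         substr(al, 21, 30))))
    sym <- trimws(substr(al, 31, 34))
    if (anyNA(xyz) || !nzchar(sym)) {
      # fall back to whitespace tokens for loosely formatted files
      tok <- strsplit(trimws(al), "\\s+")[[1]]
      if (length(tok) < 4L) stop2("%s: malformed atom line %d", path, i)
      xyz <- suppressWarnings(as.numeric(tok[1:3]))
      sym <- tok[4]
      if (anyNA(xyz)) stop2("%s: malformed atom line %d", path, i)
    }
    elements[i] <- sym
    coords[i, ] <- xyz
  }
  bonds <- matrix(integer(0), ncol = 3L)
  for (i in seq_len(nbonds)) {
    bl <- rec[4L + natoms + i]
    a <- suppressWarnings(as.integer(substr(bl, 1, 3)))
    b <- suppressWarnings(as.integer(substr(bl, 4, 6)))
    o <- suppressWarnings(as.integer(substr(bl, 7, 9)))
    if (is.na(a) || is.na(b)) {
      tok <- suppressWarnings(as.integer(strsplit(trimws(bl), "\\s+")[[1]]))
      if (length(tok) < 2L || anyNA(tok[1:2]))
        stop2("%s: malformed bond line %d", path, i)
      a <- tok[1]; b <- tok[2]; o <- if (length(tok) >= 3L) tok[3] else 1L
    }
    if (a < 1L || b < 1L || a > natoms || b > natoms)
      stop2("%s: bond line %d references atom %d (atoms are 1..%d)",
            path, i, min(a, b), natoms)
    bonds <- rbind(bonds, c(a, b, if (is.na(o)) 1L else o))
  }
  name <- trimws(rec[1])
  mol <- molecule3d(elements, coords, bonds = bonds[, 1:2, drop = FALSE],
                    name = name)
  if (nrow(bonds)) attr(mol$bonds, "order") <- bonds[, 3]
  mol
}

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance does not exceed
#' \code{tolerance} times the sum of their covalent radii (bundled
#' Cordero-type table).  Any existing bond list is replaced.
#'
#' @param mol a \code{\link{molecule3d}}.
#' @param tolerance unitless factor in \code{[1.0, 1.5]}; default 1.2.
#' @return The molecule with \code{bonds} populated.
#' @export
perceive_bonds <- function(mol, tolerance = 1.2) {
  stopifnot(inherits(mol, "molecule3d"))
  if (tolerance < 1.0 || tolerance > 1.5)
    stop2("tolerance must lie in [1.0, 1.5]")
  missing_r <- setdiff(unique(mol$elements), names(COVALENT_RADII))
  if (length(missing_r))
    stop2("no covalent radius tabulated for element(s): %s",
          paste(missing_r, collapse = ", "))
  n <- length(mol$elements)
  radii <- COVALENT_RADII[mol$elements]
  d <- as.matrix(dist(mol$coords))
  cutoff <- tolerance * outer(radii, radii, "+")
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  mol$bonds <- matrix(as.integer(hit), ncol = 2L,
                      dimnames = NULL)[order(hit[, 1], hit[, 2]), ,
                                       drop = FALSE]
  mol
}

#' Measure a bond length
#'
#' Euclidean distance between two atoms, in Angstrom.
#'
#' @param mol a \code{\link{molecule3d}}.
#' @param i,j 1-based atom indices, distinct.
#' @return Length in Angstrom.
#' @export
bond_length <- function(mol, i, j) {
  stopifnot(inherits(mol, "molecule3d"))
  n <- length(mol$elements)
  if (any(c(i, j) < 1L) || any(c(i, j) > n))
    stop2("atom index out of range (molecule has %d atoms)", n)
  if (i == j) stop2("bond_length requires two distinct atoms")
  sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
}

# Signed dihedral a-b-c-d in degrees, in (-180, 180].
dihedral_deg <- function(coords, a, b, c, d) {
  b1 <- coords[b, ] - coords[a, ]
  b2 <- coords[c, ] - coords[b, ]
  b3 <- coords[d, ] - coords[c, ]
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

neighbors_of <- function(bonds, i) {
  c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
}

#' Locate the cyclic keto-enol fragment
#'
#' Searches a bonded molecule for the enolized 1,3-dione motif: a 5- or
#' 6-membered ring carrying the path C3(=O_keto)-C2=C1(-O_enol-H), with the
#' keto oxygen exocyclic and the enol oxygen bearing exactly one hydrogen.
#' The C1=C2 double bond (bond iii) is identified as the shorter of the two
#' ring bonds at C1.  The O-H orientation is classified from the
#' C2-C1-O_enol-H torsion: syn for |torsion| <= 90 degrees, anti otherwise.
#'
#' When several candidate fragments exist (e.g. triketones with two
#' conceivable enolization sites), the one with the shortest O-H bond is
#' returned, a warning is emitted, and all candidates are recorded in the
#' \code{candidates} attribute.
#'
#' @param mol a \code{\link{molecule3d}} with bonds populated.
#' @return An object of class \code{keto_enol_fragment} with 1-based atom
#'   indices \code{idx_H}, \code{idx_O_enol}, \code{idx_C1}, \code{idx_C2},
#'   \code{idx_C3}, \code{idx_O_keto}, plus \code{ring_size},
#'   \code{torsion_deg} and \code{conformer} ("syn" or "anti").
#' @export
detect_keto_enol_fragment <- function(mol) {
  stopifnot(inherits(mol, "molecule3d"))
  if (!nrow(mol$bonds))
    stop2("molecule has no bonds; run perceive_bonds() first")
  el <- mol$elements
  bonds <- mol$bonds
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(el) - igraph::vcount(g)))

  candidates <- list()
  saw_bare_enol_o <- FALSE

  for (o_enol in which(el == "O")) {
    nb <- neighbors_of(bonds, o_enol)
    h_nb <- nb[el[nb] == "H"]
    c_nb <- nb[el[nb] == "C"]
    if (length(c_nb) != 1L) next
    if (length(h_nb) != 1L) {
      # a ring-attached O lacking its hydroxyl H: remember for the error
      if (length(h_nb) == 0L && length(nb) == 1L) saw_bare_enol_o <- TRUE
      next
    }
    c1 <- c_nb
    ring_nb <- setdiff(neighbors_of(bonds, c1), o_enol)
    ring_nb <- ring_nb[el[ring_nb] == "C"]
    if (!length(ring_nb)) next
    # bond iii is the shorter ring bond at C1
    ord <- order(vapply(ring_nb, function(j) bond_length(mol, c1, j), 0))
    for (c2 in ring_nb[ord]) {
      c3_cands <- setdiff(neighbors_of(bonds, c2), c1)
      c3_cands <- c3_cands[el[c3_cands] == "C"]
      for (c3 in c3_cands) {
        o_keto <- NA_integer_
        for (ok in neighbors_of(bonds, c3)) {
          if (el[ok] == "O" && ok != o_enol &&
              length(neighbors_of(bonds, ok)) == 1L) {
            o_keto <- ok
            break
          }
        }
        if (is.na(o_keto)) next
        ring_size <- ring_containing(g, c1, c2, c3,
                                     forbid = c(o_enol, o_keto, h_nb))
        if (is.na(ring_size)) next
        tors <- dihedral_deg(mol$coords, c2, c1, o_enol, h_nb)
        candidates[[length(candidates) + 1L]] <- structure(
          list(ring_size = ring_size, idx_H = h_nb, idx_O_enol = o_enol,
               idx_C1 = c1, idx_C2 = c2, idx_C3 = c3, idx_O_keto = o_keto,
               torsion_deg = tors,
               conformer = if (abs(tors) > 90) "anti" else "syn"),
          class = "keto_enol_fragment")
        break  # one C3 per (O_enol, C2) is enough
      }
      if (length(candidates) &&
          candidates[[length(candidates)]]$idx_C1 == c1) break
    }
  }

  if (!length(candidates)) {
    if (saw_bare_enol_o)
      stop2(paste("no hydroxyl H: a candidate enol oxygen carries no",
                  "hydrogen (heavy-atom-only input?)"))
    stop2("no keto-enol fragment found")
  }
  r_oh <- vapply(candidates,
                 function(f) bond_length(mol, f$idx_O_enol, f$idx_H), 0)
  if (length(candidates) > 1L)
    warning(sprintf(
      "%d candidate keto-enol fragments found; returning the one with the shortest O-H bond",
      length(candidates)), call. = FALSE)
  best <- candidates[[which.min(r_oh)]]
  attr(best, "n_candidates") <- length(candidates)
  attr(best, "candidates") <- candidates
  best
}

# Size (5 or 6) of a ring through c1-c2-c3 avoiding `forbid`, or NA.
# A ring of size n closes c3 -> c1 with n-2 edges outside the c2 vertex.
ring_containing <- function(g, c1, c2, c3, forbid) {
  # vertex ids shift after deletion, so address vertices by name
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g2 <- igraph::delete_vertices(g, as.character(c(c2, forbid)))
  if (!as.character(c1) %in% igraph::V(g2)$name ||
      !as.character(c3) %in% igraph::V(g2)$name) return(NA_integer_)
  paths <- igraph::all_simple_paths(g2, from = as.character(c3),
                                    to = as.character(c1), cutoff = 4)
  if (!length(paths)) return(NA_integer_)
  sizes <- vapply(paths, function(p) length(p) + 1L, 0L)  # ring = path + C2
  sizes <- sizes[sizes %in% c(5L, 6L)]
  if (!length(sizes)) return(NA_integer_)
  min(sizes)
}

#' @export
print.keto_enol_fragment <- function(x, ...) {
  cat(sprintf(
    "<keto_enol_fragment> ring %d, %s (torsion %.1f deg); O-H %d-%d, C1 %d, C2 %d, C3 %d, O_keto %d\n",
    x$ring_size, x$conformer, x$torsion_deg, x$idx_O_enol, x$idx_H,
    x$idx_C1, x$idx_C2, x$idx_C3, x$idx_O_keto))
  invisible(x)
}

#' Measure the five diagnostic bond lengths
#'
#' Given a located fragment, measures bonds i-v: i = O_enol-H,
#' ii = C1-O_enol, iii = C1=C2, iv = C2-C3, v = C3=O_keto.
#'
#' @param mol a \code{\link{molecule3d}}.
#' @param frag a \code{keto_enol_fragment} whose indices are valid in
#'   \code{mol}.
#' @return A \code{bond_feature_vector}: named numeric of length 5 with
#'   names \code{r_OH}, \code{r_CO}, \code{r_CC_double}, \code{r_CC_single},
#'   \code{r_CO_double} (Angstrom).
#' @export
extract_features <- function(mol, frag) {
  stopifnot(inherits(mol, "molecule3d"), inherits(frag, "keto_enol_fragment"))
  v <- c(
    r_OH        = bond_length(mol, frag$idx_O_enol, frag$idx_H),
    r_CO        = bond_length(mol, frag$idx_C1, frag$idx_O_enol),
    r_CC_double = bond_length(mol, frag$idx_C1, frag$idx_C2),
    r_CC_single = bond_length(mol, frag$idx_C2, frag$idx_C3),
    r_CO_double = bond_length(mol, frag$idx_C3, frag$idx_O_keto)
  )
  validate_feature_vector(v)
}

#' Validate a bond feature vector
#'
#' Checks the five lengths lie in the physically plausible window
#' (0.5, 3.0) Angstrom and that the O-H bond is shorter than the C-O bond,
#' as in any valid enol fragment.
#'
#' @param v named numeric of length 5 (see \code{\link{extract_features}}).
#' @return The vector, classed \code{bond_feature_vector}.
#' @export
validate_feature_vector <- function(v) {
  v <- v[FEATURE_COLUMNS]
  check_numeric_vector(unname(v), "feature vector")
  if (any(v <= LENGTH_RANGE[1]) || any(v >= LENGTH_RANGE[2]))
    stop2("bond length outside the (%.1f, %.1f) Angstrom window",
          LENGTH_RANGE[1], LENGTH_RANGE[2])
  if (v[["r_OH"]] >= v[["r_CO"]])
    stop2("invalid fragment: O-H (%.3f) not shorter than C-O (%.3f)",
          v[["r_OH"]], v[["r_CO"]])
  names(v) <- FEATURE_COLUMNS
  class(v) <- c("bond_feature_vector", "numeric")
  v
}
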