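#' Lightweight molecular graph
#'
#' Internal molecule container used throughout the package: an atom table
#' (element, Cartesian coordinates in Angstrom, formal charge) plus a bond
#' table (1-based atom indices, bond order). Structures read from SDF or
#' SMILES, and structures built by the synthetic-library generator, are all
#' normalized to this form.
#'
#' @param atoms data.frame with columns `elem`, `x`, `y`, `z`, `charge`.
#' @param bonds data.frame with columns `a1`, `a2`, `order`.
#' @param id molecule identifier string.
#' @return An object of class `molgraph`.
#' @keywords internal
#' @export
molgraph <- function(atoms, bonds, id = "mol") {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  atoms$elem <- as.character(atoms$elem)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (nrow(bonds) == 0) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  structure(
    list(atoms = atoms, bonds = bonds, id = id),
    class = "molgraph"
  )
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf(
    "<molgraph %s: %d atoms (%d heavy), %d bonds, charge %+d>\n",
    x$id, nrow(x$atoms), sum(x$atoms$elem != "H"), nrow(x$bonds),
    sum(x$atoms$charge)
  ))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

heavy_idx <- function(mol) which(mol$atoms$elem != "H")

coords <- function(mol, idx = NULL) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

set_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

mol_weight <- function(mol) {
  m <- ATOMIC_MASS[mol$atoms$elem]
  m[is.na(m)] <- 0
  sum(m)
}

#' Adjacency list of a molgraph (1-based neighbour indices per atom)
#' @noRd
adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

bond_order_matrix <- function(mol) {
  n <- n_atoms(mol)
  m <- matrix(0L, n, n)
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]; o <- mol$bonds$order[i]
    m[a, b] <- o; m[b, a] <- o
  }
  m
}

#' Topological (bond-count) distances between all atom pairs by BFS
#' @noRd
bond_distances <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

#' Smallest rings (size <= max_size) via per-edge BFS
#'
#' For each bond, the shortest path between its endpoints in the graph with
#' that bond removed closes the smallest ring through the bond. Returns a
#' de-duplicated list of atom-index vectors.
#' @noRd
find_rings <- function(mol, max_size = 7) {
  nb <- adjacency(mol)
  rings <- list()
  seen <- character()
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    # BFS from a to b avoiding the direct edge
    prev <- rep(NA_integer_, n_atoms(mol))
    prev[a] <- a
    queue <- a
    found <- FALSE
    while (length(queue) && !found) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) {
        if (v == a && w == b) next
        if (is.na(prev[w])) {
          prev[w] <- v
          if (w == b) { found <- TRUE; break }
          queue <- c(queue, w)
        }
      }
    }
    if (!found) next
    path <- b
    v <- b
    while (v != a) { v <- prev[v]; path <- c(path, v) }
    if (length(path) > max_size) next
    key <- paste(sort(path), collapse = "-")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1]] <- path
    }
  }
  rings
}

#' Aromatic ring perception
#'
#' A 5- or 6-membered ring is taken as aromatic when every ring atom is
#' C/N/O/S, is not sp3 (each ring carbon takes part in at least one double
#' or aromatic bond), and the ring is near-planar. This approximate Hueckel
#' rule covers the benzene / pyridine / five-membered heteroaromatic
#' chemistry this package works with.
#' @noRd
aromatic_rings <- function(mol) {
  bo <- bond_order_matrix(mol)
  rings <- find_rings(mol, max_size = 6)
  keep <- list()
  for (ring in rings) {
    if (!(length(ring) %in% c(5L, 6L))) next
    elems <- mol$atoms$elem[ring]
    if (!all(elems %in% c("C", "N", "O", "S"))) next
    ok <- TRUE
    for (a in ring) {
      if (mol$atoms$elem[a] == "C") {
        # ring carbon must carry a double (order 2) or aromatic (4) bond
        if (!any(bo[a, ] %in% c(2L, 4L))) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    # planarity: ring atoms within 0.35 A of their best-fit plane
    xyz <- coords(mol, ring)
    cen <- colMeans(xyz)
    sv <- svd(sweep(xyz, 2, cen))
    normal <- sv$v[, 3]
    dev <- abs(sweep(xyz, 2, cen) %*% normal)
    if (max(dev) > 0.35) next
    keep[[length(keep) + 1]] <- ring
  }
  keep
}

#' Count of hydrogens attached to an atom
#' @noRd
h_count <- function(mol, idx, adj = adjacency(mol)) {
  sum(mol$atoms$elem[adj[[idx]]] == "H")
}

#' Convert a ChemmineR SDF object to molgraph
#'
#' @param sdf a `ChemmineR::SDF` object (one molecule, explicit hydrogens
#'   where needed downstream).
#' @param id molecule id; defaults to the SDF title.
#' @return a [molgraph()].
#' @keywords internal
#' @export
sdf_to_molgraph <- function(sdf, id = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elems <- sub("_.*$", "", rownames(ab))
  atoms <- data.frame(
    elem = elems,
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    charge = 0L,
    stringsAsFactors = FALSE
  )
  # SDF charge column (V3 in ChemmineR atom block) uses the old 1..7 codes
  if (ncol(ab) >= 5) {
    code <- ab[, 5]
    chg <- integer(length(code))
    chg[code == 1] <- 3L; chg[code == 2] <- 2L; chg[code == 3] <- 1L
    chg[code == 5] <- -1L; chg[code == 6] <- -2L; chg[code == 7] <- -3L
    atoms$charge <- chg
  }
  bonds <- data.frame(
    a1 = as.integer(bb[, 1]),
    a2 = as.integer(bb[, 2]),
    order = as.integer(bb[, 3])
  )
  rownames(atoms) <- NULL
  molgraph(atoms, bonds, id = id %||% ChemmineR::sdfid(sdf))
}

#' Convert a molgraph (optionally with extra data fields) to a ChemmineR SDF
#' @keywords internal
#' @export
molgraph_to_sdf <- function(mol, data = character()) {
  n <- n_atoms(mol)
  ab <- cbind(
    C1 = mol$atoms$x, C2 = mol$atoms$y, C3 = mol$atoms$z,
    C5 = 0, C6 = charge_to_sdf_code(mol$atoms$charge),
    C7 = 0, C8 = 0, C9 = 0, C10 = 0, C11 = 0, C12 = 0,
    C13 = 0, C14 = 0, C15 = 0, C16 = 0
  )
  rownames(ab) <- paste(mol$atoms$elem, seq_len(n), sep = "_")
  nb <- nrow(mol$bonds)
  bb <- cbind(
    C1 = mol$bonds$a1, C2 = mol$bonds$a2, C3 = mol$bonds$order,
    C4 = 0, C5 = 0, C6 = 0, C7 = 0
  )
  rownames(bb) <- paste0("bnd_", seq_len(max(nb, 0)))
  header <- c(
    Molecule_Name = mol$id, Source = "pharmqsar",
    Comment = "",
    Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  )
  sdf <- new("SDF", header = header, atomblock = ab, bondblock = bb,
             datablock = data)
  sdf
}

charge_to_sdf_code <- function(chg) {
  code <- integer(length(chg))
  code[chg == 3] <- 1L; code[chg == 2] <- 2L; code[chg == 1] <- 3L
  code[chg == -1] <- 5L; code[chg == -2] <- 6L; code[chg == -3] <- 7L
  code
}

#' Parse SMILES into molgraphs with explicit hydrogens and 3D coordinates
#'
#' Thin wrapper over ChemmineR/Open Babel: SMILES are parsed, hydrogens made
#' explicit and a single low-energy 3D geometry generated.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional ids (defaults to names or seq).
#' @return list of [molgraph()] objects.
#' @export
smiles_to_molgraph <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- names(smiles) %||% as.character(seq_along(smiles))
  names(smiles) <- ids
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  # 3D embedding can fail for degenerate (single-heavy-atom) inputs; fall
  # back to the parser's layout in that case
  sdf3d <- tryCatch(suppressWarnings(ChemmineR::generate3DCoords(sdfset)),
                    error = function(e) sdfset)
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    out[[i]] <- sdf_to_molgraph(sdf3d[[i]], id = ids[i])
  }
  names(out) <- ids
  out
}
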