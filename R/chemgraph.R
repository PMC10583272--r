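# Graph primitives shared by the naming, template and linking machinery.

#' Convert a MolecularGraph to an igraph object
#'
#' Vertices are named by atom serial; bond order is kept as an edge
#' attribute.
#'
#' @param g A [MolecularGraph-class].
#' @return An undirected igraph graph.
#' @keywords internal
asIgraph <- function(g) {
  ig <- igraph::make_empty_graph(n = 0, directed = FALSE)
  ig <- igraph::add_vertices(ig, nAtoms(g),
                             name = as.character(atoms(g)$serial))
  bd <- bonds(g)
  if (nrow(bd)) {
    ig <- igraph::add_edges(ig, rbind(match(bd$a, atoms(g)$serial),
                                      match(bd$b, atoms(g)$serial)))
    igraph::E(ig)$order <- bd$order
  }
  ig
}

# adjacency list keyed by serial (character); values integer serial vectors
.adjacency <- function(g) {
  ser <- atoms(g)$serial
  adj <- setNames(vector("list", length(ser)), as.character(ser))
  for (i in seq_along(ser)) adj[[i]] <- integer()
  bd <- bonds(g)
  if (nrow(bd)) {
    for (i in seq_len(nrow(bd))) {
      a <- as.character(bd$a[i]); b <- as.character(bd$b[i])
      adj[[a]] <- c(adj[[a]], bd$b[i])
      adj[[b]] <- c(adj[[b]], bd$a[i])
    }
  }
  adj
}

#' Restrict a graph to a subset of atoms
#'
#' Keeps the listed serials and all bonds among them; serials are
#' preserved.
#'
#' @param g A [MolecularGraph-class].
#' @param serials Integer vector of atom serials to keep.
#' @return A [MolecularGraph-class].
#' @export
subgraphBySerial <- function(g, serials) {
  at <- atoms(g)[atoms(g)$serial %in% serials, , drop = FALSE]
  bd <- bonds(g)
  bd <- bd[bd$a %in% serials & bd$b %in% serials, , drop = FALSE]
  rownames(at) <- rownames(bd) <- NULL
  new("MolecularGraph", atoms = at, bonds = bd, netCharge = g@netCharge)
}

#' Heavy-atom subgraph
#'
#' Drops hydrogens and pseudoatoms, keeping all bonds among the remaining
#' atoms.  Original serials are preserved.  CIP duplicate atoms (which are
#' heavy by construction) are kept.
#'
#' @param g A [MolecularGraph-class].
#' @return A [MolecularGraph-class] containing only heavy, non-pseudo atoms.
#' @export
#' @examples
#' gm <- makeFixture(fixtureSpec("methane"))
#' nAtoms(heavyAtomSubgraph(gm))  # 1
heavyAtomSubgraph <- function(g) {
  at <- atoms(g)
  keep <- at$serial[toupper(at$element) != "H" & !at$isPseudo]
  subgraphBySerial(g, keep)
}

#' Expand unsaturated bonds with CIP duplicate atoms
#'
#' For every bond of integer order k > 1, adds k - 1 duplicate ("phantom")
#' leaf atoms on each end, each carrying the element of the atom across the
#' bond, as required by the Cahn-Ingold-Prelog rules.  Aromatic bonds
#' (order 1.5) are handled per atom: each atom involved in at least one
#' aromatic bond gains exactly `aromaticDuplicates` duplicate leaves whose
#' element is the highest-atomic-number partner across its aromatic bonds
#' (a Kekule-structure-free convention; a benzene carbon gains one
#' duplicate C).
#'
#' @param g A heavy-atom [MolecularGraph-class] with bond orders set.
#' @param aromaticDuplicates integer; duplicates added per aromatic atom
#'   (default 1; 0 disables aromatic duplication).
#' @return A [MolecularGraph-class] with duplicate atoms appended; the
#'   original atoms and bonds are unchanged.
#' @export
expandUnsaturation <- function(g, aromaticDuplicates = 1L) {
  at <- atoms(g)
  bd <- bonds(g)
  if (nrow(bd) && !all(bd$order %in% c(1, 1.5, 2, 3))) {
    bad <- which(!bd$order %in% c(1, 1.5, 2, 3))[1]
    stop(sprintf("unknown bond order %s on bond %d-%d",
                 bd$order[bad], bd$a[bad], bd$b[bad]))
  }
  elem <- setNames(at$element, as.character(at$serial))
  nextSerial <- if (nrow(at)) max(at$serial) + 1L else 1L
  newAtoms <- list(); newBonds <- list()
  addDup <- function(host, element) {
    a <- data.frame(serial = nextSerial, name = paste0("DU", nextSerial),
                    element = element, x = at$x[at$serial == host],
                    y = at$y[at$serial == host], z = at$z[at$serial == host],
                    isPseudo = FALSE, isDuplicate = TRUE, charge = NA_real_)
    newAtoms[[length(newAtoms) + 1L]] <<- a
    newBonds[[length(newBonds) + 1L]] <<-
      data.frame(a = host, b = nextSerial, order = 1)
    nextSerial <<- nextSerial + 1L
  }
  if (nrow(bd)) {
    intBonds <- bd[bd$order %in% c(2, 3), , drop = FALSE]
    if (nrow(intBonds)) {
      for (i in seq_len(nrow(intBonds))) {
        k <- intBonds$order[i]
        for (rep in seq_len(k - 1)) {
          addDup(intBonds$a[i], elem[[as.character(intBonds$b[i])]])
          addDup(intBonds$b[i], elem[[as.character(intBonds$a[i])]])
        }
      }
    }
    arBonds <- bd[bd$order == 1.5, , drop = FALSE]
    if (nrow(arBonds) && aromaticDuplicates > 0) {
      arAtoms <- sort(unique(c(arBonds$a, arBonds$b)))
      for (s in arAtoms) {
        partners <- c(arBonds$b[arBonds$a == s], arBonds$a[arBonds$b == s])
        pz <- atomicNumber(elem[as.character(partners)])
        best <- elem[[as.character(partners[which.max(pz)])]]
        for (rep in seq_len(aromaticDuplicates)) addDup(s, best)
      }
    }
  }
  if (length(newAtoms)) {
    at2 <- rbind(at[, names(newAtoms[[1]])], do.call(rbind, newAtoms))
    extra <- setdiff(names(at), names(newAtoms[[1]]))
    for (cn in extra) at2[[cn]] <- c(at[[cn]], rep(NA, length(newAtoms)))
    bd2 <- rbind(bd, do.call(rbind, newBonds))
    rownames(at2) <- rownames(bd2) <- NULL
    new("MolecularGraph", atoms = at2, bonds = bd2, netCharge = g@netCharge)
  } else {
    g
  }
}

#' Bond distances from a source atom
#'
#' Breadth-first shortest path lengths, in bonds, from `source` to every
#' reachable atom.  Unreachable atoms are absent from the result.
#'
#' @param g A [MolecularGraph-class].
#' @param source Atom serial to measure from.
#' @return Named integer vector (names are atom serials) of bond counts;
#'   the source maps to 0.
#' @export
bondDistances <- function(g, source) {
  if (!source %in% atoms(g)$serial)
    stop("unknown source serial: ", source)
  ig <- asIgraph(g)
  d <- igraph::distances(ig, v = as.character(source))[1, ]
  d <- d[is.finite(d)]
  setNames(as.integer(d), names(d))
}

#' Chirality sign from four positions
#'
#' Sign of the determinant of the 4x4 matrix whose rows are the
#' homogeneous coordinates (x, y, z, 1) of, in order: the two atoms being
#' compared (`pHigh`, `pLow`), the central atom (standing in for the
#' fourth, lowest-priority substituent), and the anchor atom of highest
#' priority in the bottom row.  Swapping `pHigh` and `pLow` flips the
#' sign; so does reflecting all four positions.
#'
#' @param pHigh,pLow Numeric(3) coordinates of the two atoms under
#'   comparison.
#' @param center Numeric(3) coordinates of the central (stereo) atom.
#' @param anchor Numeric(3) coordinates of the highest-priority neighbour
#'   (the atom preceding the branch point).
#' @param tol Relative degeneracy tolerance: an error is raised when
#'   |det| < `tol` times the product of the three edge lengths from the
#'   centre.
#' @return `+1` or `-1`.
#' @export
chiralitySign <- function(pHigh, pLow, center, anchor, tol = 1e-9) {
  m <- rbind(c(pHigh, 1), c(pLow, 1), c(center, 1), c(anchor, 1))
  d <- det(m)
  scale <- prod(pmax(sqrt(sum((pHigh - center)^2)), 1e-12),
                pmax(sqrt(sum((pLow - center)^2)), 1e-12),
                pmax(sqrt(sum((anchor - center)^2)), 1e-12))
  if (abs(d) < tol * scale)
    stop("degenerate geometry: near-zero chirality determinant")
  if (d > 0) 1 else -1
}

# All backbone motifs N-C(.)-C(=O) in a graph (hydrogens may be present).
# Returns a list of named integer vectors (n, ca, c, o).  The CA candidate
# must be carbon, bonded to a nitrogen and to a carbon carrying a carbonyl
# oxygen: double-bonded, or - for inputs whose bond orders default to 1
# (PDB CONECT) - a terminal oxygen without hydrogens.  No hydrogen count
# is imposed on CA so that alpha-methylated residues are found too.
.findBackboneMotifs <- function(g) {
  at <- atoms(g)
  bd <- bonds(g)
  adj <- .adjacency(g)
  elemOf <- setNames(toupper(at$element), as.character(at$serial))
  real <- setNames(!at$isDuplicate & !at$isPseudo, as.character(at$serial))
  orderOf <- function(a, b) {
    hit <- (bd$a == a & bd$b == b) | (bd$a == b & bd$b == a)
    bd$order[hit][1]
  }
  carbonylO <- function(cc, o) {
    if (orderOf(cc, o) >= 2) return(TRUE)
    nb <- adj[[as.character(o)]]
    nb <- nb[real[as.character(nb)]]
    all(nb %in% cc)   # terminal O, no hydrogens and no other heavy atom
  }
  motifs <- list()
  heavy <- function(s) s[real[as.character(s)] &
                         elemOf[as.character(s)] != "H"]
  for (ca in at$serial[elemOf[as.character(at$serial)] == "C" &
                       !at$isDuplicate & !at$isPseudo]) {
    nb <- heavy(adj[[as.character(ca)]])
    ns <- nb[elemOf[as.character(nb)] == "N"]
    cs <- nb[elemOf[as.character(nb)] == "C"]
    if (!length(ns) || !length(cs)) next
    for (cc in cs) {
      onb <- heavy(adj[[as.character(cc)]])
      os <- onb[elemOf[as.character(onb)] == "O"]
      dblO <- os[vapply(os, function(o) carbonylO(cc, o), logical(1))]
      if (!length(dblO)) next
      for (nn in ns) {
        motifs[[length(motifs) + 1L]] <-
          c(n = nn, ca = ca, c = cc, o = dblO[1])
      }
    }
  }
  motifs
}

#' Locate an amino-acid backbone
#'
#' Finds the backbone atoms N, CA, C, O of a residue.  When an atom named
#' "CA" is present, name-based lookup takes precedence (inputs derived
#' from topology builders or the CCD carry names); otherwise the
#' N-C(.)-C(=O) motif is matched on the bond graph.
#'
#' @param g A [MolecularGraph-class] with explicit bonds.
#' @param residue Optional 1-based index selecting among multiple motifs
#'   (in order of CA serial) when the graph holds more than one residue.
#' @return Named integer vector with elements `n`, `ca`, `c`, `o`.
#' @export
findBackbone <- function(g, residue = NULL) {
  at <- atoms(g)
  byName <- at$serial[toupper(trimws(at$name)) == "CA" & !at$isDuplicate]
  motifs <- .findBackboneMotifs(g)
  if (!length(motifs))
    stop("no backbone motif N-C-C(=O) found")
  if (length(byName) >= 1) {
    named <- Filter(function(m) m[["ca"]] %in% byName, motifs)
    if (length(named)) motifs <- named
  }
  # collapse motifs sharing a CA (multiple N or O matches)
  cas <- vapply(motifs, `[[`, integer(1), "ca")
  motifs <- motifs[!duplicated(cas)]
  if (length(motifs) > 1 && is.null(residue))
    stop("multiple backbone motifs found (", length(motifs),
         "); supply `residue` to select one")
  if (is.null(residue)) residue <- 1L
  if (residue > length(motifs))
    stop("residue index out of range: ", residue)
  motifs <- motifs[order(vapply(motifs, `[[`, integer(1), "ca"))]
  motifs[[residue]]
}
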