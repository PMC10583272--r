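# IUPAC/IUBMB-conformant side-chain atom naming.
#
# Heavy atoms are labelled by their bond distance from the alpha carbon
# (Greek letter, transliterated to Roman characters in files) plus a chain
# identifier assigned by Cahn-Ingold-Prelog priority, with a geometric
# determinant tie-break for prochiral tetrahedral centres.

#' Default Greek-to-Roman transliteration table
#'
#' One Roman character per Greek letter, alpha through omega:
#' A B G D E Z H Q I K L M V X O P R S T U F C Y W.
#'
#' @return Character vector of length 24.
#' @export
defaultTransliteration <- function() {
  c("A", "B", "G", "D", "E", "Z", "H", "Q", "I", "K", "L", "M",
    "V", "X", "O", "P", "R", "S", "T", "U", "F", "C", "Y", "W")
}

#' Positional label for a bond distance from the alpha carbon
#'
#' Position 1 (the alpha carbon itself, distance 0) carries the alpha
#' label; the first side-chain atom (distance 1) is beta, and so on
#' through omega (distance 23).  From position 25 (distance 24) the
#' alphabet repeats as two-letter codes (alpha-alpha, alpha-beta, ...,
#' omega-omega), giving a total label space of 600 positions.
#'
#' @param distance Integer vector of bond distances from CA, in 1..599.
#' @param table Transliteration table, see [defaultTransliteration()].
#' @return Character vector of labels.
#' @export
#' @examples
#' positionLabel(1)   # "B"
#' positionLabel(14)  # "O"
#' positionLabel(24)  # "AA"
positionLabel <- function(distance, table = defaultTransliteration()) {
  stopifnot(length(table) == 24)
  if (any(distance < 1 | distance > 599))
    stop("distance must be between 1 and 599")
  distance <- as.integer(distance)
  out <- character(length(distance))
  single <- distance <= 23
  out[single] <- table[distance[single] + 1L]
  if (any(!single)) {
    idx <- distance[!single] - 24L
    out[!single] <- paste0(table[idx %/% 24L + 1L], table[idx %% 24L + 1L])
  }
  out
}

#' The full ordered label sequence
#'
#' @param table Transliteration table.
#' @return Character vector of all 600 position labels, the alpha position
#'   first.
#' @export
positionLabels <- function(table = defaultTransliteration()) {
  c(table[1], positionLabel(1:599, table))
}

# ---- hierarchical-digraph sphere machinery -------------------------------

# Sphere sequence of atomic-number multisets rooted at `root`, with
# `exclude` treated as the root's predecessor.  The graph is expected to be
# the expanded heavy graph (CIP duplicates present as leaves).  Ring
# closures are handled with hierarchical-digraph semantics: a neighbour
# already on the path from the root becomes a phantom leaf carrying its
# atomic number.  Returns a list: element d+1 holds the sorted (decreasing)
# atomic numbers at depth d (depth 0 = the root itself).
.cipSpheres <- function(adj, zOf, isDup, root, exclude) {
  rootKey <- as.character(root)
  spheres <- list(zOf[[rootKey]])
  # frontier nodes: atom serial, index of parent node in `pathAtoms` store
  nodeAtom <- c(root)
  nodeParent <- c(0L)
  frontier <- 1L
  depth <- 0L
  excludeOf <- c(exclude)   # per-node: atom not to re-enter directly
  while (length(frontier)) {
    nextAtoms <- integer(); nextParents <- integer()
    nextExclude <- integer(); zs <- integer()
    for (ni in frontier) {
      a <- nodeAtom[ni]
      if (isDup[[as.character(a)]]) next  # duplicates never expand
      nbrs <- adj[[as.character(a)]]
      nbrs <- nbrs[nbrs != excludeOf[ni]]
      if (!length(nbrs)) next
      # ancestors of this node (atoms on path back to root)
      anc <- integer(); cur <- ni
      while (cur != 0L) { anc <- c(anc, nodeAtom[cur]); cur <- nodeParent[cur] }
      anc <- c(anc, exclude)
      for (nb in nbrs) {
        zs <- c(zs, zOf[[as.character(nb)]])
        closing <- nb %in% anc
        nodeAtom <- c(nodeAtom, nb)
        nodeParent <- c(nodeParent, ni)
        # ring-closure neighbours become phantom leaves: mark them so they
        # are skipped on the next expansion by excluding every neighbour
        excludeOf <- c(excludeOf, if (closing) -1L else a)
        if (!closing) {
          nextAtoms <- c(nextAtoms, length(nodeAtom))
        }
      }
    }
    if (!length(zs)) break
    depth <- depth + 1L
    spheres[[depth + 1L]] <- sort(zs, decreasing = TRUE)
    frontier <- nextAtoms
  }
  spheres
}

# Lexicographic comparison of two sphere sequences.  Shorter spheres are
# padded with phantom atomic number 0.  Returns list(cmp, depth): cmp < 0
# if `a` has priority, > 0 if `b` has, 0 on exhaustion-equal; depth is the
# sphere index (0-based) of the first difference.
.compareSpheres <- function(a, b) {
  nd <- max(length(a), length(b))
  for (d in seq_len(nd)) {
    va <- if (d <= length(a)) a[[d]] else integer()
    vb <- if (d <= length(b)) b[[d]] else integer()
    n <- max(length(va), length(vb))
    if (!n) next
    va <- c(va, rep(0L, n - length(va)))
    vb <- c(vb, rep(0L, n - length(vb)))
    diff <- which(va != vb)
    if (length(diff)) {
      i <- diff[1]
      return(list(cmp = if (va[i] > vb[i]) -1L else 1L, depth = d - 1L))
    }
  }
  list(cmp = 0L, depth = NA_integer_)
}

#' CIP priority comparison of two branches
#'
#' Compares the branches rooted at atoms `a` and `b` (sharing predecessor
#' `exclude`) by expanding bond spheres of atomic numbers over the
#' hierarchical digraph: the atoms themselves first, then all atoms one
#' bond away, and so on.  Returns `"a_first"`, `"b_first"`, or `"tie"`
#' when every sphere exhausts equal.
#'
#' @param g Expanded heavy [MolecularGraph-class] (see
#'   [expandUnsaturation()]).
#' @param a,b Atom serials of the branch roots.
#' @param exclude Serial of the shared predecessor.
#' @return `"a_first"`, `"b_first"` or `"tie"`.
#' @export
cipCompare <- function(g, a, b, exclude) {
  at <- atoms(g)
  adj <- .adjacency(g)
  zOf <- as.list(setNames(atomicNumber(at$element), as.character(at$serial)))
  isDup <- as.list(setNames(at$isDuplicate, as.character(at$serial)))
  sa <- .cipSpheres(adj, zOf, isDup, a, exclude)
  sb <- .cipSpheres(adj, zOf, isDup, b, exclude)
  r <- .compareSpheres(sa, sb)
  if (r$cmp < 0) "a_first" else if (r$cmp > 0) "b_first" else "tie"
}

# ---- chain assignment ----------------------------------------------------

# Canonical geometric order for chemically arbitrary choices: atoms are
# ranked by their sorted squared-distance profile to every real atom of
# the molecule (rounded to 1e-6), a key invariant under atom permutation,
# rigid motion and reflection.  Exactly symmetric profiles keep input
# order.  Returns an ordering permutation of `serials`.
.geomRank <- function(serials, allXYZ) {
  keys <- lapply(serials, function(s) {
    x <- allXYZ[as.character(s), ]
    sort(round(rowSums(sweep(allXYZ, 2, x)^2), 6))
  })
  n <- length(serials)
  ord <- seq_len(n)
  cmp <- function(i, j) {
    a <- keys[[i]]; b <- keys[[j]]
    m <- min(length(a), length(b))
    d <- which(a[seq_len(m)] != b[seq_len(m)])
    if (length(d)) return(sign(a[d[1]] - b[d[1]]))
    sign(length(a) - length(b))
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (cmp(ord[i], ord[j]) > 0) { t <- ord[i]; ord[i] <- ord[j]; ord[j] <- t }
  }
  ord
}

# Rank sibling branches of `parent`.  Returns list(order, resolvedBy,
# tieEvents, audit).  `ctx` carries adj/zOf/isDup/coords/tetra of the
# expanded graph plus the original input order of atoms.
.rankSiblings <- function(kids, parent, anchor, ctx) {
  audit <- character()
  if (length(kids) == 1L)
    return(list(order = kids,
                resolvedBy = setNames("atomic-number", kids),
                tieEvents = list(), audit = audit))
  kids <- kids[order(match(kids, ctx$inputOrder))]
  seqs <- lapply(kids, function(k)
    .cipSpheres(ctx$adj, ctx$zOf, ctx$isDup, k, parent))
  names(seqs) <- as.character(kids)
  n <- length(kids)
  cmp <- matrix(0L, n, n); dep <- matrix(NA_integer_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- .compareSpheres(seqs[[i]], seqs[[j]])
    cmp[i, j] <- r$cmp; cmp[j, i] <- -r$cmp
    dep[i, j] <- dep[j, i] <- r$depth
  }
  # stable sort by pairwise comparator (ties keep input order for now)
  ord <- seq_len(n)
  ord <- ord[order(vapply(seq_len(n), function(i) sum(cmp[i, ] > 0), 0L) -
              vapply(seq_len(n), function(i) sum(cmp[i, ] < 0), 0L))]
  resolvedBy <- setNames(rep("sphere-comparison", n), as.character(kids))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    dd <- dep[i, others]
    dd <- dd[!is.na(dd)]
    if (length(dd) && min(dd) == 0L)
      resolvedBy[i] <- "atomic-number"
  }
  tieEvents <- list()
  # walk ranked list, resolving tie groups
  i <- 1L
  finalOrder <- integer()
  while (i <= n) {
    grp <- ord[i]
    j <- i + 1L
    while (j <= n && cmp[ord[i], ord[j]] == 0L) { grp <- c(grp, ord[j]); j <- j + 1L }
    if (length(grp) >= 2L) {
      gk <- kids[grp]
      if (length(grp) == 2L && isTRUE(ctx$tetra[[as.character(parent)]]) &&
          !is.na(anchor)) {
        s <- tryCatch(
          chiralitySign(ctx$coords[[as.character(gk[1])]],
                        ctx$coords[[as.character(gk[2])]],
                        ctx$coords[[as.character(parent)]],
                        ctx$coords[[as.character(anchor)]]),
          error = function(e) NA)
        if (!is.na(s)) {
          if (s < 0) gk <- rev(gk)
          resolvedBy[as.character(gk)] <- "geometric"
          audit <- c(audit, sprintf(
            "branch at %d: tie between %s resolved geometrically (det sign %+d)",
            parent, paste(kids[grp], collapse = "/"), s))
        } else {
          gk <- gk[.geomRank(gk, ctx$allXYZ)]
          resolvedBy[as.character(gk)] <- "arbitrary"
          audit <- c(audit, sprintf(
            "branch at %d: planar tie between %s left arbitrary (distance-profile order)",
            parent, paste(gk, collapse = "/")))
        }
      } else {
        gk <- gk[.geomRank(gk, ctx$allXYZ)]
        resolvedBy[as.character(gk)] <- "arbitrary"
        audit <- c(audit, sprintf(
          "branch at %d: %d identical chains (%s), identity arbitrary",
          parent, length(grp), paste(gk, collapse = "/")))
      }
      tieEvents[[length(tieEvents) + 1L]] <-
        list(parent = parent, kids = gk,
             how = resolvedBy[[as.character(gk[1])]])
      finalOrder <- c(finalOrder, gk)
    } else {
      finalOrder <- c(finalOrder, kids[grp])
    }
    i <- j
  }
  list(order = finalOrder,
       resolvedBy = resolvedBy[as.character(finalOrder)],
       tieEvents = tieEvents, audit = audit)
}

#' Assign distance shells and CIP chain identifiers to a side chain
#'
#' Implements the incremental one-pass assignment: chains are initiated at
#' the atoms bonded to the alpha carbon and extended shell by shell in
#' order of bond distance, previously assigned atoms being revisited in
#' priority order at each increment.  Branch priority follows the CIP
#' atomic-number/sphere rules; ties between exactly two identical branches
#' at a tetrahedral atom are resolved geometrically via the chirality
#' determinant (three identical branches stay arbitrary).  An atom joining
#' two chains (ring closure) receives the lower chain identifier.  A final
#' symmetry re-pass renumbers chains born inside CIP-identical sibling
#' subtrees into consecutive blocks ordered by parent-chain priority, so
#' that duplicated rings carry consecutive chain numbers.
#'
#' @param g Full [MolecularGraph-class] of a single residue (hydrogens
#'   present; they are ignored here but used to detect tetrahedral
#'   centres).
#' @param backbone Named serial vector from [findBackbone()].
#' @param aromaticDuplicates Passed to [expandUnsaturation()].
#' @return A [ChainAssignment-class].
#' @export
assignChains <- function(g, backbone, aromaticDuplicates = 1L) {
  ca <- backbone[["ca"]]; bbN <- backbone[["n"]]; bbC <- backbone[["c"]]
  heavy <- heavyAtomSubgraph(g)
  reach <- bondDistances(heavy, ca)
  if (!all(atoms(heavy)$serial %in% as.integer(names(reach))))
    stop("disconnected heavy atom(s): ",
         paste(setdiff(atoms(heavy)$serial, as.integer(names(reach))),
               collapse = ", "))
  # side-chain distances: paths may not run through backbone N or C'
  pruned <- subgraphBySerial(heavy,
                             setdiff(atoms(heavy)$serial, c(bbN, bbC)))
  dist <- bondDistances(pruned, ca)
  dist <- dist[dist > 0]
  if (!length(dist)) stop("side chain is empty")
  sideSerials <- as.integer(names(dist))
  distOf <- setNames(as.integer(dist), names(dist))

  exp <- expandUnsaturation(heavy, aromaticDuplicates)
  atx <- atoms(exp)
  ctx <- list(
    adj = .adjacency(exp),
    zOf = as.list(setNames(atomicNumber(atx$element),
                           as.character(atx$serial))),
    isDup = as.list(setNames(atx$isDuplicate, as.character(atx$serial))),
    coords = setNames(lapply(seq_len(nrow(atx)), function(i)
      c(atx$x[i], atx$y[i], atx$z[i])), as.character(atx$serial)),
    inputOrder = atoms(g)$serial,
    allXYZ = local({
      real <- atoms(g)[!atoms(g)$isDuplicate & !atoms(g)$isPseudo, ,
                       drop = FALSE]
      m <- as.matrix(real[, c("x", "y", "z")])
      rownames(m) <- as.character(real$serial)
      m
    })
  )
  # tetrahedral: four neighbours counting hydrogens, in the input graph
  degFull <- table(factor(c(bonds(g)$a, bonds(g)$b),
                          levels = atoms(g)$serial))
  psd <- atoms(g)$serial[atoms(g)$isPseudo | atoms(g)$isDuplicate]
  if (length(psd)) {  # pseudoatom bonds do not count towards geometry
    bg <- bonds(g)
    keep <- !(bg$a %in% psd | bg$b %in% psd)
    degFull <- table(factor(c(bg$a[keep], bg$b[keep]),
                            levels = atoms(g)$serial))
  }
  ctx$tetra <- as.list(setNames(degFull == 4L, atoms(g)$serial))

  chain <- setNames(rep(NA_integer_, length(sideSerials)),
                    as.character(sideSerials))
  parentOf <- chain
  resolvedBy <- setNames(rep(NA_character_, length(sideSerials)),
                         as.character(sideSerials))
  nextChain <- 1L
  audit <- character()
  tieEvents <- list()

  shellAdj <- .adjacency(pruned)
  maxD <- max(distOf)
  for (d in 0:(maxD - 1L)) {
    parents <- if (d == 0L) ca else
      sideSerials[distOf[as.character(sideSerials)] == d]
    if (d > 0L)
      parents <- parents[order(chain[as.character(parents)])]
    for (p in parents) {
      kids <- shellAdj[[as.character(p)]]
      kids <- kids[kids %in% sideSerials &
                   distOf[as.character(kids)] == d + 1L]
      if (!length(kids)) next
      anchor <- if (d == 0L) bbN else parentOf[[as.character(p)]]
      rk <- .rankSiblings(kids, p, anchor, ctx)
      audit <- c(audit, rk$audit)
      tieEvents <- c(tieEvents, rk$tieEvents)
      for (i in seq_along(rk$order)) {
        k <- rk$order[i]; kk <- as.character(k)
        cand <- if (d == 0L) {
          nextChain + i - 1L   # chains initiated at CA: 1..k in rank order
        } else if (i == 1L) chain[[as.character(p)]] else NA_integer_
        if (is.na(chain[[kk]])) {
          if (is.na(cand)) { cand <- nextChain; nextChain <- nextChain + 1L }
          chain[[kk]] <- cand
          parentOf[[kk]] <- p
          resolvedBy[[kk]] <- rk$resolvedBy[[kk]]
        } else {
          # ring-joining atom: lower of current and would-be chain id
          if (!is.na(cand) && cand < chain[[kk]]) {
            audit <- c(audit, sprintf(
              "ring join at %d: chain %d lowered to %d", k, chain[[kk]], cand))
            chain[[kk]] <- cand
          } else {
            audit <- c(audit, sprintf(
              "ring join at %d: keeps chain %d", k, chain[[kk]]))
          }
          resolvedBy[[kk]] <- "ring-join"
        }
      }
      if (d == 0L) nextChain <- nextChain + length(rk$order)
    }
  }

  # compress chain ids to 1..K (joins can orphan a freshly allocated id)
  used <- sort(unique(chain))
  chain[] <- match(chain, used)

  # symmetry re-pass: chains born inside CIP-identical sibling subtrees are
  # renumbered as consecutive blocks in parent-priority order
  inSubtree <- function(x, root) {
    cur <- x
    repeat {
      if (cur == root) return(TRUE)
      cur <- parentOf[[as.character(cur)]]
      if (is.na(cur) || cur == ca) return(FALSE)
      if (!as.character(cur) %in% names(parentOf)) return(FALSE)
    }
  }
  for (ev in tieEvents) {
    chainIds <- sort(unique(chain))
    births <- vapply(chainIds, function(cc) {
      members <- as.integer(names(chain)[chain == cc])
      members[which.min(distOf[as.character(members)])]
    }, integer(1))
    copies <- lapply(ev$kids, function(k)
      sideSerials[vapply(sideSerials, inSubtree, logical(1), root = k)])
    chainLists <- lapply(copies, function(cp) chainIds[births %in% cp])
    u <- sort(unlist(chainLists))
    if (length(u) < 2L) next
    newIds <- u
    perm <- setNames(u, u)
    pos <- 1L
    for (cl in chainLists) {
      if (!length(cl)) next
      perm[as.character(cl)] <- newIds[pos:(pos + length(cl) - 1L)]
      pos <- pos + length(cl)
    }
    if (!all(perm == as.integer(names(perm)))) {
      audit <- c(audit, sprintf(
        "symmetry re-pass at branch %d: chains [%s] -> [%s]",
        ev$parent, paste(names(perm), collapse = ","),
        paste(perm, collapse = ",")))
      hit <- chain %in% u
      chain[hit] <- perm[as.character(chain[hit])]
    }
  }

  tb <- data.frame(serial = sideSerials,
                   distance = unname(distOf[as.character(sideSerials)]),
                   chain = unname(chain[as.character(sideSerials)]),
                   resolvedBy = unname(resolvedBy[as.character(sideSerials)]),
                   stringsAsFactors = FALSE)
  tb <- tb[order(tb$distance, tb$chain), ]
  rownames(tb) <- NULL
  new("ChainAssignment", table = tb, audit = audit, caSerial = as.integer(ca))
}

# ---- name generation -----------------------------------------------------

# Number a set of hydrogens on one heavy atom.  Returns the integer
# suffixes in the hydrogens' input order ('' for a lone hydrogen).
.numberHydrogens <- function(hSerials, center, anchor, tetrahedralC, coords,
                             allXYZ, audit = NULL) {
  nh <- length(hSerials)
  if (nh == 1L) return(list(suffix = "", audit = audit))
  geomSuffix <- function(labels) {
    suf <- character(nh)
    suf[.geomRank(hSerials, allXYZ)] <- labels
    suf
  }
  if (nh == 2L && tetrahedralC && !is.na(anchor)) {
    s <- tryCatch(
      chiralitySign(coords[[as.character(hSerials[1])]],
                    coords[[as.character(hSerials[2])]],
                    coords[[as.character(center)]],
                    coords[[as.character(anchor)]]),
      error = function(e) NA)
    if (!is.na(s)) {
      suf <- if (s > 0) c("2", "3") else c("3", "2")
      return(list(suffix = suf,
                  audit = c(audit, sprintf(
                    "methylene at %s: H numbers by determinant sign %+d",
                    center, s))))
    }
    audit <- c(audit, sprintf(
      "methylene at %s: degenerate geometry, H numbers arbitrary", center))
    return(list(suffix = geomSuffix(c("2", "3")), audit = audit))
  }
  if (nh == 2L) return(list(suffix = geomSuffix(c("1", "2")),
                            audit = audit))
  list(suffix = geomSuffix(as.character(seq_len(nh))), audit = audit)
}

#' Generate atom names from a chain assignment
#'
#' Heavy side-chain names are element symbol + positional label + chain
#' number, except that a chain-1 atom which is the sole heavy occupant of
#' its distance shell carries no number (with `stickySuffix = TRUE` the
#' number is retained downstream of any branch that is still open).
#' Hydrogens take H + the parent's positional part; the two hydrogens of a
#' tetrahedral methylene are numbered 2/3 by the geometric rule, methyl
#' hydrogens 1/2/3 in input order.  Pseudoatoms (Q + positional part) are
#' emitted for multi-hydrogen groups and arbitrary-symmetric aromatic CH
#' pairs.
#'
#' @param assignment A [ChainAssignment-class].
#' @param g The full input [MolecularGraph-class].
#' @param table Transliteration table.
#' @param stickySuffix Keep the chain-1 number after an upstream branch
#'   (so e.g. a lone delta methyl downstream of a beta branch is numbered).
#' @param pseudo Emit pseudoatom names.
#' @return A [NamingResult-class] covering the side-chain atoms (heavy and
#'   hydrogen) only; [renameResidue()] adds backbone and terminal atoms.
#' @export
nameAtoms <- function(assignment, g, table = defaultTransliteration(),
                      stickySuffix = FALSE, pseudo = TRUE) {
  tb <- assignment@table
  at <- atoms(g)
  coords <- setNames(lapply(seq_len(nrow(at)), function(i)
    c(at$x[i], at$y[i], at$z[i])), as.character(at$serial))
  realAt <- at[!at$isDuplicate & !at$isPseudo, , drop = FALSE]
  allXYZ <- as.matrix(realAt[, c("x", "y", "z")])
  rownames(allXYZ) <- as.character(realAt$serial)
  adj <- .adjacency(g)
  elemOf <- setNames(toupper(at$element), as.character(at$serial))
  isH <- setNames(elemOf == "H" & !at$isPseudo & !at$isDuplicate,
                  as.character(at$serial))
  audit <- assignment@audit
  heavyNames <- character(nrow(tb))
  occupancy <- table(tb$distance)
  joined <- setNames(tb$resolvedBy == "ring-join", as.character(tb$serial))
  for (i in seq_len(nrow(tb))) {
    d <- tb$distance[i]; cc <- tb$chain[i]
    lab <- positionLabel(d, table)
    sole <- occupancy[[as.character(d)]] == 1L
    omit <- cc == 1L && sole
    if (omit && stickySuffix && !joined[[as.character(tb$serial[i])]]) {
      prev <- tb$distance == d - 1L
      if (d > 1L && sum(prev) >= 2L) omit <- FALSE
    }
    heavyNames[i] <- paste0(elemOf[[as.character(tb$serial[i])]], lab,
                            if (!omit) cc else "")
  }
  map <- data.frame(serial = tb$serial,
                    oldName = at$name[match(tb$serial, at$serial)],
                    newName = heavyNames, kind = "sidechain",
                    stringsAsFactors = FALSE)
  # hydrogens
  parentOfChain <- setNames(rep(NA_integer_, nrow(tb)),
                            as.character(tb$serial))
  for (i in seq_len(nrow(tb))) {
    nb <- adj[[as.character(tb$serial[i])]]
    cand <- nb[nb %in% c(tb$serial[tb$distance == tb$distance[i] - 1L],
                         assignment@caSerial)]
    parentOfChain[i] <- if (length(cand)) cand[1] else NA_integer_
  }
  degFull <- vapply(as.character(at$serial), function(s)
    length(adj[[s]]), integer(1))
  hRows <- list(); qRows <- list()
  for (i in seq_len(nrow(tb))) {
    s <- tb$serial[i]
    hs <- adj[[as.character(s)]]
    hs <- hs[isH[as.character(hs)]]
    if (!length(hs)) next
    hs <- hs[order(match(hs, at$serial))]
    posPart <- substring(heavyNames[i],
                         nchar(elemOf[[as.character(s)]]) + 1L)
    tet <- elemOf[[as.character(s)]] == "C" &&
      degFull[[as.character(s)]] == 4L
    nm <- .numberHydrogens(hs, s, parentOfChain[[as.character(s)]],
                           tet, coords, allXYZ, audit)
    audit <- nm$audit
    hRows[[length(hRows) + 1L]] <- data.frame(
      serial = hs, oldName = at$name[match(hs, at$serial)],
      newName = paste0("H", posPart, nm$suffix), kind = "hydrogen",
      stringsAsFactors = FALSE)
    if (pseudo && length(hs) >= 2L) {
      qRows[[length(qRows) + 1L]] <- data.frame(
        name = paste0("Q", posPart), parentSerial = s,
        members = paste(paste0("H", posPart, nm$suffix), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  # aromatic/arbitrary symmetric CH pairs: one pseudoatom across the pair
  if (pseudo) {
    arb <- tb[tb$resolvedBy == "arbitrary", , drop = FALSE]
    if (nrow(arb)) {
      for (d in unique(arb$distance)) {
        grp <- arb[arb$distance == d, , drop = FALSE]
        if (nrow(grp) == 2L) {
          nh <- vapply(grp$serial, function(s) {
            hh <- adj[[as.character(s)]]; sum(isH[as.character(hh)])
          }, integer(1))
          if (all(nh == 1L)) {
            lab <- positionLabel(d, table)
            qRows[[length(qRows) + 1L]] <- data.frame(
              name = paste0("Q", lab), parentSerial = grp$serial[1],
              members = paste0("H", lab, grp$chain, collapse = ","),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(hRows)) map <- rbind(map, do.call(rbind, hRows))
  qdf <- if (length(qRows)) unique(do.call(rbind, qRows)) else
    data.frame(name = character(), parentSerial = integer(),
               members = character(), stringsAsFactors = FALSE)
  if (anyDuplicated(map$newName)) {
    dups <- unique(map$newName[duplicated(map$newName)])
    stop("atom name collision after all rules: ",
         paste(dups, collapse = ", "), "\naudit:\n",
         paste(audit, collapse = "\n"))
  }
  new("NamingResult", map = map, pseudoatoms = qdf, audit = audit)
}

# Names for atoms hanging off the backbone N (N-methyl etc.) and the
# carboxyl end.  Returns rows to append to the map.
.nameTerminalAtoms <- function(g, backbone, adj, elemOf, isH, taken, audit,
                               allXYZ) {
  rows <- list()
  at <- atoms(g)
  bbN <- backbone[["n"]]; ca <- backbone[["ca"]]
  bbC <- backbone[["c"]]; bbO <- backbone[["o"]]
  note <- function(x) audit <<- c(audit, x)
  # N substituents -----------------------------------------------------
  nsub <- adj[[as.character(bbN)]]
  nsub <- nsub[!nsub %in% c(ca) & !isH[as.character(nsub)]]
  cnCount <- 0L
  for (s in nsub) {
    hs <- adj[[as.character(s)]]
    hsOnly <- all(isH[as.character(setdiff(hs, bbN))])
    if (elemOf[[as.character(s)]] == "C" && hsOnly && cnCount == 0L) {
      nm <- "CN"; cnCount <- cnCount + 1L    # CCD N-methyl convention
      rows[[length(rows) + 1L]] <- data.frame(
        serial = s, oldName = at$name[at$serial == s], newName = nm,
        kind = "terminal", stringsAsFactors = FALSE)
      hss <- setdiff(hs, bbN)
      if (length(hss) > 1L) hss <- hss[.geomRank(hss, allXYZ)]
      for (k in seq_along(hss))
        rows[[length(rows) + 1L]] <- data.frame(
          serial = hss[k], oldName = at$name[at$serial == hss[k]],
          newName = paste0("HN", k), kind = "terminal",
          stringsAsFactors = FALSE)
    } else {
      # generic terminal-substituent scheme for larger R' groups
      comp <- .componentBeyond(g, bbN, s)
      idx <- 0L
      for (cs in comp) {
        idx <- idx + 1L
        nm <- paste0(elemOf[[as.character(cs)]], "N", idx)
        while (nm %in% taken) { idx <- idx + 1L
          nm <- paste0(elemOf[[as.character(cs)]], "N", idx) }
        taken <- c(taken, nm)
        rows[[length(rows) + 1L]] <- data.frame(
          serial = cs, oldName = at$name[at$serial == cs], newName = nm,
          kind = "terminal", stringsAsFactors = FALSE)
      }
      note(sprintf("N-terminal substituent at %d named generically", s))
    }
  }
  # carboxyl end --------------------------------------------------------
  csub <- adj[[as.character(bbC)]]
  csub <- csub[!csub %in% c(ca, bbO) & !isH[as.character(csub)]]
  oxt <- 0L; tIdx <- 0L
  for (s in csub) {
    if (elemOf[[as.character(s)]] == "O" && oxt == 0L) {
      oxt <- oxt + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        serial = s, oldName = at$name[at$serial == s], newName = "OXT",
        kind = "terminal", stringsAsFactors = FALSE)
      hs <- adj[[as.character(s)]]
      hs <- hs[isH[as.character(hs)]]
      if (length(hs))
        rows[[length(rows) + 1L]] <- data.frame(
          serial = hs[1], oldName = at$name[at$serial == hs[1]],
          newName = "HXT", kind = "terminal", stringsAsFactors = FALSE)
    } else {
      comp <- .componentBeyond(g, bbC, s)
      for (cs in comp) {
        tIdx <- tIdx + 1L
        nm <- paste0(elemOf[[as.character(cs)]], "T", tIdx)
        rows[[length(rows) + 1L]] <- data.frame(
          serial = cs, oldName = at$name[at$serial == cs], newName = nm,
          kind = "terminal", stringsAsFactors = FALSE)
      }
      note(sprintf("C-terminal substituent at %d named generically", s))
    }
  }
  list(rows = rows, audit = audit)
}

# atoms in the connected component containing `start` once `cut` is removed
.componentBeyond <- function(g, cut, start) {
  keep <- setdiff(atoms(g)$serial, cut)
  sub <- subgraphBySerial(g, keep)
  comp <- bondDistances(sub, start)
  as.integer(names(comp))
}

#' Rename a residue to IUPAC-conformant atom names
#'
#' Orchestrates the full pipeline: heavy-atom reduction, CIP duplicate
#' expansion, backbone location, chain assignment and name generation.
#' Backbone atoms receive the fixed names N, H (or H1/H2/H3 on a free
#' amine), CA, HA (HA2/HA3 for glycine-like residues), C, O, plus OXT/HXT
#' for a carboxyl terminus; an N-methyl carbon is named CN with HN1-HN3
#' (CCD convention).  Deterministic for a fixed input.
#'
#' @param g A single-residue [MolecularGraph-class] with backbone present.
#' @param residue Optional residue selector passed to [findBackbone()].
#' @param table Transliteration table.
#' @param stickySuffix,pseudo See [nameAtoms()].
#' @param amideH Name to give a single backbone amide hydrogen ("H" for
#'   CCD-facing output; "HN" for CNS-facing output).
#' @return A [NamingResult-class] mapping every input atom.
#' @export
#' @examples
#' cys <- makeFixture(fixtureSpec("CYS"))
#' res <- renameResidue(cys)
#' subset(nameMap(res), kind == "sidechain")$newName  # "CB" "SG"
renameResidue <- function(g, residue = NULL,
                          table = defaultTransliteration(),
                          stickySuffix = FALSE, pseudo = TRUE,
                          amideH = "H") {
  backbone <- findBackbone(g, residue)
  at <- atoms(g)
  adj <- .adjacency(g)
  elemOf <- setNames(toupper(at$element), as.character(at$serial))
  isH <- setNames(elemOf == "H" & !at$isPseudo & !at$isDuplicate,
                  as.character(at$serial))
  coords <- setNames(lapply(seq_len(nrow(at)), function(i)
    c(at$x[i], at$y[i], at$z[i])), as.character(at$serial))
  realAt <- at[!at$isDuplicate & !at$isPseudo, , drop = FALSE]
  allXYZ <- as.matrix(realAt[, c("x", "y", "z")])
  rownames(allXYZ) <- as.character(realAt$serial)

  # side chain (may legitimately be empty: glycine)
  emptySide <- FALSE
  res <- tryCatch(assignChains(g, backbone),
                  error = function(e) {
                    if (grepl("side chain is empty", conditionMessage(e))) {
                      emptySide <<- TRUE; NULL
                    } else stop(e)
                  })
  if (is.null(res)) {
    map <- data.frame(serial = integer(), oldName = character(),
                      newName = character(), kind = character(),
                      stringsAsFactors = FALSE)
    qdf <- data.frame(name = character(), parentSerial = integer(),
                      members = character(), stringsAsFactors = FALSE)
    audit <- "no side-chain heavy atoms"
  } else {
    nr <- nameAtoms(res, g, table = table, stickySuffix = stickySuffix,
                    pseudo = pseudo)
    map <- nr@map; qdf <- nr@pseudoatoms; audit <- nr@audit
  }

  addRow <- function(serial, newName, kind) {
    map <<- rbind(map, data.frame(
      serial = serial, oldName = at$name[at$serial == serial],
      newName = newName, kind = kind, stringsAsFactors = FALSE))
  }
  bb <- backbone
  addRow(bb[["n"]], "N", "backbone")
  addRow(bb[["ca"]], "CA", "backbone")
  addRow(bb[["c"]], "C", "backbone")
  addRow(bb[["o"]], "O", "backbone")
  # amide / amine hydrogens
  nh <- adj[[as.character(bb[["n"]])]]
  nh <- nh[isH[as.character(nh)]]
  if (length(nh) > 1L) nh <- nh[.geomRank(nh, allXYZ)]
  if (length(nh) == 1L) addRow(nh, amideH, "backbone")
  else for (k in seq_along(nh)) addRow(nh[k], paste0("H", k), "backbone")
  # alpha hydrogens
  ha <- adj[[as.character(bb[["ca"]])]]
  ha <- ha[isH[as.character(ha)]]
  if (length(ha) == 1L) addRow(ha, "HA", "backbone")
  else if (length(ha) == 2L) {
    nm <- .numberHydrogens(ha, bb[["ca"]], bb[["n"]], TRUE, coords,
                           allXYZ, audit)
    audit <- nm$audit
    for (k in seq_along(ha)) addRow(ha[k], paste0("HA", nm$suffix[k]),
                                    "backbone")
  }
  tm <- .nameTerminalAtoms(g, bb, adj, elemOf, isH, map$newName, audit,
                           allXYZ)
  audit <- tm$audit
  if (length(tm$rows)) map <- rbind(map, do.call(rbind, tm$rows))
  # any pseudoatoms present in the input keep their names (audited)
  psd <- at$serial[at$isPseudo]
  for (s in setdiff(psd, map$serial)) {
    addRow(s, at$name[at$serial == s], "pseudo")
    audit <- c(audit, sprintf("input pseudoatom %d kept its name", s))
  }
  missing <- setdiff(at$serial[!at$isDuplicate], map$serial)
  if (length(missing))
    stop("atoms left unnamed: ", paste(missing, collapse = ", "))
  rownames(map) <- NULL
  if (anyDuplicated(map$newName)) {
    dups <- unique(map$newName[duplicated(map$newName)])
    stop("atom name collision after all rules: ",
         paste(dups, collapse = ", "), "\naudit:\n",
         paste(audit, collapse = "\n"))
  }
  new("NamingResult", map = map, pseudoatoms = qdf, audit = audit)
}
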