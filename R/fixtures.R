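# Programmatic generation of every test input: canonical and non-canonical
# residues, capped peptide templates, extended link templates and random
# side chains, all with idealised internal-coordinate geometry (tetrahedral
# 109.47 deg frames, element-pair bond lengths).  No chemistry toolkit is
# involved; determinism is guaranteed for a fixed recipe and seed.

# ---- idealised geometry --------------------------------------------------

.BOND_LENGTHS <- list(
  "C C"  = c(`1` = 1.53, `1.5` = 1.40, `2` = 1.33, `3` = 1.20),
  "C N"  = c(`1` = 1.47, `1.5` = 1.34, `2` = 1.28),
  "C O"  = c(`1` = 1.43, `2` = 1.23),
  "C S"  = c(`1` = 1.81),
  "S S"  = c(`1` = 2.04),
  "N N"  = c(`1` = 1.45),
  "N O"  = c(`1` = 1.40),
  "O O"  = c(`1` = 1.48),
  "C H"  = c(`1` = 1.09),
  "N H"  = c(`1` = 1.01),
  "O H"  = c(`1` = 0.96),
  "S H"  = c(`1` = 1.34),
  "C CL" = c(`1` = 1.79)
)

.bondLength <- function(e1, e2, order = 1) {
  key <- paste(sort(c(toupper(e1), toupper(e2))), collapse = " ")
  tab <- .BOND_LENGTHS[[key]]
  if (is.null(tab)) return(1.5)
  v <- tab[as.character(order)]
  if (is.na(v)) tab[[1]] else unname(v)
}

.idealDirs <- function(type) {
  switch(type,
    tet = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
      sqrt(3),
    trig = rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
                 c(-0.5, -sqrt(3) / 2, 0)),
    linear = rbind(c(1, 0, 0), c(-1, 0, 0)))
}

# rotation R with R %*% p_i ~ q_i for row vectors of P, Q (Kabsch)
.kabsch <- function(P, Q) {
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

# Deterministic 3D embedding of a bonded graph: breadth-first from `root`,
# children placed on ideal tetrahedral/trigonal/linear directions aligned
# to the already-placed neighbours.
.embedGraph <- function(atomsDf, bondsDf, root) {
  n <- nrow(atomsDf)
  ser <- atomsDf$serial
  key <- as.character(ser)
  pseudo <- atomsDf$serial[atomsDf$isPseudo]
  pseudoBonds <- bondsDf$a %in% pseudo | bondsDf$b %in% pseudo
  pseudoDf <- bondsDf[pseudoBonds, , drop = FALSE]
  bondsDf <- bondsDf[!pseudoBonds, , drop = FALSE]
  adj <- setNames(vector("list", n), key)
  ordAt <- setNames(vector("list", n), key)
  for (i in seq_len(nrow(bondsDf))) {
    a <- as.character(bondsDf$a[i]); b <- as.character(bondsDf$b[i])
    adj[[a]] <- c(adj[[a]], bondsDf$b[i]); adj[[b]] <- c(adj[[b]], bondsDf$a[i])
    ordAt[[a]] <- c(ordAt[[a]], bondsDf$order[i])
    ordAt[[b]] <- c(ordAt[[b]], bondsDf$order[i])
  }
  pos <- matrix(NA_real_, n, 3, dimnames = list(key, NULL))
  pos[as.character(root), ] <- 0
  queue <- root
  first <- TRUE
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    pk <- as.character(p)
    nbrs <- adj[[pk]]
    placed <- nbrs[!is.na(pos[as.character(nbrs), 1])]
    unplaced <- setdiff(nbrs, placed)
    unplaced <- unplaced[order(match(unplaced, ser))]
    if (!length(unplaced)) next
    orders <- ordAt[[pk]]
    type <- if (any(orders == 3) ||
                (sum(orders == 2) >= 2 && length(nbrs) <= 2)) "linear"
            else if (any(orders %in% c(2, 1.5))) "trig" else "tet"
    ideal <- .idealDirs(type)
    need <- length(placed) + length(unplaced)
    if (need > nrow(ideal)) ideal <- .idealDirs("tet")
    if (need > nrow(ideal))
      stop("cannot embed atom with more than 4 neighbours")
    k <- length(placed)
    if (k == 0) {
      R <- diag(3)
    } else {
      P <- ideal[seq_len(k), , drop = FALSE]
      Q <- t(vapply(placed, function(nb) {
        v <- pos[as.character(nb), ] - pos[pk, ]
        v / sqrt(sum(v^2))
      }, numeric(3)))
      R <- .kabsch(P, Q)
    }
    free <- ideal[(k + 1):(k + length(unplaced)), , drop = FALSE]
    for (j in seq_along(unplaced)) {
      ch <- unplaced[j]
      dirv <- as.numeric(R %*% free[j, ])
      bo <- ordAt[[pk]][match(ch, adj[[pk]])]
      bl <- .bondLength(atomsDf$element[match(p, ser)],
                        atomsDf$element[match(ch, ser)], bo)
      pos[as.character(ch), ] <- pos[pk, ] + bl * dirv
      queue <- c(queue, ch)
    }
    first <- FALSE
  }
  if (anyNA(pos[!atomsDf$isPseudo, 1]))
    stop("embedding failed: disconnected atoms")
  # pseudoatoms sit on their bonded partner, slightly offset
  for (i in seq_len(nrow(pseudoDf))) {
    p <- pseudoDf$a[i]; q <- pseudoDf$b[i]
    if (p %in% pseudo) { tmp <- p; p <- q; q <- tmp }
    pos[as.character(q), ] <- pos[as.character(p), ] + c(0.1, 0.1, 0.1)
  }
  pos[is.na(pos)] <- 0
  pos
}

# ---- molecule builder ----------------------------------------------------

.molBuilder <- function() {
  env <- new.env(parent = emptyenv())
  env$atoms <- list(); env$bonds <- list(); env$serial <- 0L
  env$add <- function(name, element, parent = NULL, order = 1,
                      nH = 0L, pseudo = FALSE) {
    env$serial <- env$serial + 1L
    s <- env$serial
    env$atoms[[s]] <- data.frame(serial = s, name = name, element = element,
                                 isPseudo = pseudo, stringsAsFactors = FALSE)
    if (!is.null(parent)) env$bond(parent, s, order)
    if (nH > 0)
      for (k in seq_len(nH))
        env$add(paste0("H", name, if (nH > 1) k else ""), "H", s)
    s
  }
  env$bond <- function(a, b, order = 1)
    env$bonds[[length(env$bonds) + 1L]] <-
      data.frame(a = a, b = b, order = order)
  env$build <- function(root = 1L, netCharge = NA) {
    at <- do.call(rbind, env$atoms)
    bd <- do.call(rbind, env$bonds)
    pos <- .embedGraph(cbind(at, x = 0, y = 0, z = 0), bd, root)
    at$x <- pos[as.character(at$serial), 1]
    at$y <- pos[as.character(at$serial), 2]
    at$z <- pos[as.character(at$serial), 3]
    makeMolecularGraph(at, bd, netCharge)
  }
  env
}

# ---- residue side-chain recipes -----------------------------------------

# "NAME ELEMENT PARENT ORDER NH"; PARENT "CA" roots the side chain.
# Ring-closure bonds listed separately.  Atom names are the standard
# IUPAC/BMRB heavy-atom names (these also seed the reference table tests).
.RESDEFS <- list(
  ALA = list(side = c("CB C CA 1 3")),
  ARG = list(side = c("CB C CA 1 2", "CG C CB 1 2", "CD C CG 1 2",
                      "NE N CD 1 1", "CZ C NE 1 0", "NH1 N CZ 2 2",
                      "NH2 N CZ 1 2")),
  ASN = list(side = c("CB C CA 1 2", "CG C CB 1 0", "OD1 O CG 2 0",
                      "ND2 N CG 1 2")),
  ASP = list(side = c("CB C CA 1 2", "CG C CB 1 0", "OD1 O CG 2 0",
                      "OD2 O CG 1 1")),
  CYS = list(side = c("CB C CA 1 2", "SG S CB 1 1")),
  GLN = list(side = c("CB C CA 1 2", "CG C CB 1 2", "CD C CG 1 0",
                      "OE1 O CD 2 0", "NE2 N CD 1 2")),
  GLU = list(side = c("CB C CA 1 2", "CG C CB 1 2", "CD C CG 1 0",
                      "OE1 O CD 2 0", "OE2 O CD 1 1")),
  GLY = list(side = character()),
  HIS = list(side = c("CB C CA 1 2", "CG C CB 1 0", "ND1 N CG 1.5 1",
                      "CD2 C CG 1.5 1", "CE1 C ND1 1.5 1",
                      "NE2 N CD2 1.5 1"),
             rings = c("CE1 NE2 1.5")),
  ILE = list(side = c("CB C CA 1 1", "CG1 C CB 1 2", "CG2 C CB 1 3",
                      "CD1 C CG1 1 3")),
  LEU = list(side = c("CB C CA 1 2", "CG C CB 1 1", "CD1 C CG 1 3",
                      "CD2 C CG 1 3")),
  LYS = list(side = c("CB C CA 1 2", "CG C CB 1 2", "CD C CG 1 2",
                      "CE C CD 1 2", "NZ N CE 1 3")),
  MET = list(side = c("CB C CA 1 2", "CG C CB 1 2", "SD S CG 1 0",
                      "CE C SD 1 3")),
  PHE = list(side = c("CB C CA 1 2", "CG C CB 1 0", "CD1 C CG 1.5 1",
                      "CD2 C CG 1.5 1", "CE1 C CD1 1.5 1",
                      "CE2 C CD2 1.5 1", "CZ C CE1 1.5 1"),
             rings = c("CZ CE2 1.5")),
  PRO = list(side = c("CB C CA 1 2", "CG C CB 1 2", "CD C CG 1 2"),
             nToSide = "CD", freeNH = 1L),
  SER = list(side = c("CB C CA 1 2", "OG O CB 1 1")),
  THR = list(side = c("CB C CA 1 1", "OG1 O CB 1 1", "CG2 C CB 1 3")),
  TRP = list(side = c("CB C CA 1 2", "CG C CB 1 0", "CD1 C CG 1.5 1",
                      "CD2 C CG 1.5 0", "NE1 N CD1 1.5 1",
                      "CE2 C CD2 1.5 0", "CE3 C CD2 1.5 1",
                      "CZ2 C CE2 1.5 1", "CZ3 C CE3 1.5 1",
                      "CH2 C CZ2 1.5 1"),
             rings = c("NE1 CE2 1.5", "CH2 CZ3 1.5")),
  TYR = list(side = c("CB C CA 1 2", "CG C CB 1 0", "CD1 C CG 1.5 1",
                      "CD2 C CG 1.5 1", "CE1 C CD1 1.5 1",
                      "CE2 C CD2 1.5 1", "CZ C CE1 1.5 0",
                      "OH O CZ 1 1"),
             rings = c("CZ CE2 1.5")),
  VAL = list(side = c("CB C CA 1 1", "CG1 C CB 1 3", "CG2 C CB 1 3")),
  # non-canonical residues used throughout the worked examples
  ORN = list(side = c("CB C CA 1 2", "CG C CB 1 2", "CD C CG 1 2",
                      "NE N CD 1 2")),
  AIB = list(side = c("CB1 C CA 1 3", "CB2 C CA 1 3"), noHA = TRUE),
  SAR = list(side = character(), nMethyl = TRUE),
  # toys exercising specific priority rules
  OVC = list(side = c("CB C CA 1 1", "CG1 C CB 1 2", "OD1 O CG1 1 1",
                      "CG2 C CB 1 2", "CD2 C CG2 1 3")),
  DPH = list(side = c("CB C CA 1 1",
                      "CG C CB 1 0", "CD1 C CG 1.5 1", "CD2 C CG 1.5 1",
                      "CE1 C CD1 1.5 1", "CE2 C CD2 1.5 1",
                      "CZ C CE1 1.5 1",
                      "CG' C CB 1 0", "CD1' C CG' 1.5 1",
                      "CD2' C CG' 1.5 1", "CE1' C CD1' 1.5 1",
                      "CE2' C CD2' 1.5 1", "CZ' C CE1' 1.5 1"),
             rings = c("CZ CE2 1.5", "CZ' CE2' 1.5")),
  NAP = list(side = c("CB C CA 1 2", "CG C CB 1 0", "CD1 C CG 1.5 1",
                      "CD2 C CG 1.5 0", "CE1 C CD1 1.5 1",
                      "CE2 C CD2 1.5 0", "CE3 C CD2 1.5 1",
                      "CZ1 C CE1 1.5 1", "CZ2 C CE2 1.5 1",
                      "CZ3 C CE3 1.5 1", "CH2 C CZ2 1.5 1"),
             rings = c("CZ1 CE2 1.5", "CH2 CZ3 1.5"))
)

.RES_ALIASES <- c(
  alanine = "ALA", arginine = "ARG", asparagine = "ASN", aspartate = "ASP",
  cysteine = "CYS", glutamine = "GLN", glutamate = "GLU", glycine = "GLY",
  histidine = "HIS", isoleucine = "ILE", leucine = "LEU", lysine = "LYS",
  methionine = "MET", phenylalanine = "PHE", proline = "PRO",
  serine = "SER", threonine = "THR", tryptophan = "TRP", tyrosine = "TYR",
  valine = "VAL", ornithine = "ORN", sarcosine = "SAR"
)

.CANONICAL20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# Add one residue (backbone + side chain) to a builder.  Returns serials of
# n, ca, c.  nTerm: "free" (amine H's), "amide" (single H, preceded by a
# peptide bond), cTerm: "acid" (O + OXT-H) or "peptide" (C left open).
.addResidue <- function(b, code, nTerm = "free", cTerm = "acid") {
  def <- .RESDEFS[[code]]
  if (is.null(def)) stop("unknown residue recipe: ", code)
  nMe <- isTRUE(def$nMethyl)
  freeNH <- if (!is.null(def$freeNH)) def$freeNH else 2L
  nH <- if (nTerm == "amide") {
    if (nMe || !is.null(def$nToSide)) 0L else 1L
  } else {
    if (nMe) max(0L, freeNH - 1L) else freeNH
  }
  n <- b$add("N", "N", nH = nH)
  if (nMe) b$add("CN", "C", parent = n, nH = 3L)
  ca <- b$add("CA", "C", parent = n, nH = if (isTRUE(def$noHA)) 0L else 1L)
  serials <- list(N = n, CA = ca)
  for (ln in def$side) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    serials[[f[1]]] <- b$add(f[1], f[2], parent = serials[[f[3]]],
                             order = as.numeric(f[4]),
                             nH = as.integer(f[5]))
  }
  if (!is.null(def$rings))
    for (rn in def$rings) {
      f <- strsplit(trimws(rn), "\\s+")[[1]]
      b$bond(serials[[f[1]]], serials[[f[2]]], as.numeric(f[3]))
    }
  if (!is.null(def$nToSide)) b$bond(n, serials[[def$nToSide]], 1)
  cc <- b$add("C", "C", parent = ca)
  b$add("O", "O", parent = cc, order = 2)
  if (cTerm == "acid") b$add("OXT", "O", parent = cc, nH = 1L)
  list(n = n, ca = ca, c = cc)
}

.addAceCap <- function(b) {   # CH3-C(=O)-, returns carbonyl C serial
  ch3 <- b$add("CH3", "C", nH = 3L)
  cc <- b$add("C", "C", parent = ch3)
  b$add("O", "O", parent = cc, order = 2)
  cc
}

.addNMeCap <- function(b, prevC) {  # -N(H)-CH3
  n <- b$add("N", "N", parent = prevC, nH = 1L)
  b$add("CH3", "C", parent = n, nH = 3L)
  n
}

# ---- public fixture interface -------------------------------------------

#' Describe a fixture recipe
#'
#' @param recipe Recipe name; see [listFixtureRecipes()].
#' @param seed Integer seed (random recipes only).
#' @param nHeavy Side-chain heavy-atom budget for `random-tree`.
#' @param mirror Reflect all coordinates (x -> -x), producing the
#'   enantiomer.
#' @return A `FixtureSpec` (list with class attribute).
#' @export
fixtureSpec <- function(recipe, seed = 1L, nHeavy = NULL, mirror = FALSE) {
  structure(list(recipe = recipe, seed = as.integer(seed),
                 nHeavy = nHeavy, mirror = mirror),
            class = "FixtureSpec")
}

#' Available fixture recipes
#'
#' @return Character vector of recipe names understood by [makeFixture()].
#' @export
listFixtureRecipes <- function() {
  base <- names(.RESDEFS)
  c(base, paste0("capped-", base), paste0("nterm-", base),
    paste0("cterm-", base),
    "methane", "ethene", "ethanol", "benzene", "cys-extended",
    "random-tree")
}

#' Build a fixture molecular graph
#'
#' Recipes cover the 20 canonical residues (three-letter codes, standalone
#' with free termini), ornithine/Aib/sarcosine, capped templates
#' (`capped-X` = Ace-Ala-X-Ala-NMe, `nterm-X` = X-Ala-NMe, `cterm-X` =
#' Ace-Ala-X), priority toys (`OVC` the O-vs-C branch, `DPH` the
#' diphenyl symmetric branch, `NAP` a fused aromatic), the extended
#' cysteine for disulfide linking (`cys-extended`), small molecules, and
#' seeded random side chains (`random-tree`).  The same spec always yields
#' the identical graph.
#'
#' @param spec A [fixtureSpec()] or a recipe name.
#' @return A [MolecularGraph-class].
#' @export
#' @examples
#' makeFixture(fixtureSpec("capped-ornithine"))
makeFixture <- function(spec) {
  if (is.character(spec)) spec <- fixtureSpec(spec)
  recipe <- spec$recipe
  lower <- tolower(recipe)
  resolveCode <- function(x) {
    x <- tolower(x)
    if (toupper(x) %in% names(.RESDEFS)) toupper(x)
    else if (x %in% names(.RES_ALIASES)) .RES_ALIASES[[x]]
    else stop("unknown residue recipe: ", x)
  }
  g <-
    if (toupper(recipe) %in% names(.RESDEFS) ||
        lower %in% names(.RES_ALIASES)) {
      b <- .molBuilder()
      .addResidue(b, resolveCode(recipe))
      b$build()
    } else if (grepl("^(capped|nterm|cterm)-", lower)) {
      kind <- sub("-.*$", "", lower)
      code <- resolveCode(sub("^[a-z]+-", "", lower))
      b <- .molBuilder()
      if (kind %in% c("capped", "cterm")) {
        ace <- .addAceCap(b)
        ala1 <- .addResidue(b, "ALA", nTerm = "amide", cTerm = "peptide")
        b$bond(ace, ala1$n)
        x <- .addResidue(b, code, nTerm = "amide",
                         cTerm = if (kind == "capped") "peptide" else "acid")
        b$bond(ala1$c, x$n)
        if (kind == "capped") {
          ala2 <- .addResidue(b, "ALA", nTerm = "amide", cTerm = "peptide")
          b$bond(x$c, ala2$n)
          .addNMeCap(b, ala2$c)
        }
      } else {  # nterm: X-Ala-NMe
        x <- .addResidue(b, code, nTerm = "free", cTerm = "peptide")
        ala <- .addResidue(b, "ALA", nTerm = "amide", cTerm = "peptide")
        b$bond(x$c, ala$n)
        .addNMeCap(b, ala$c)
      }
      b$build()
    } else if (lower == "methane") {
      b <- .molBuilder(); b$add("C1", "C", nH = 4L); b$build()
    } else if (lower == "ethene") {
      b <- .molBuilder()
      c1 <- b$add("C1", "C", nH = 2L)
      b$add("C2", "C", parent = c1, order = 2, nH = 2L)
      b$build()
    } else if (lower == "ethanol") {
      b <- .molBuilder()
      c1 <- b$add("C1", "C", nH = 3L)
      c2 <- b$add("C2", "C", parent = c1, nH = 2L)
      b$add("O1", "O", parent = c2, nH = 1L)
      b$build()
    } else if (lower == "benzene") {
      b <- .molBuilder()
      cs <- integer(6)
      cs[1] <- b$add("C1", "C", nH = 1L)
      for (i in 2:6) cs[i] <- b$add(paste0("C", i), "C", parent = cs[i - 1],
                                    order = 1.5, nH = 1L)
      b$bond(cs[6], cs[1], 1.5)
      b$build()
    } else if (lower == "cys-extended") {
      .cysExtendedGraph()
    } else if (lower == "random-tree") {
      .randomSideChain(spec$seed, if (is.null(spec$nHeavy)) 12L
                       else spec$nHeavy)
    } else stop("unknown recipe: ", recipe)
  if (isTRUE(spec$mirror)) g <- mirrorGraph(g)
  g
}

# Extended cysteine: Calpha-Cbeta-Sgamma plus the image of the partner
# side chain (Sgamma'-Cbeta', systematically named SD / CE) beyond the
# linking bond, with pseudoatoms QB (own methylene) and QE (extension).
.cysExtendedGraph <- function() {
  b <- .molBuilder()
  n <- b$add("N", "N", nH = 1L)
  ca <- b$add("CA", "C", parent = n, nH = 1L)
  cb <- b$add("CB", "C", parent = ca, nH = 2L)
  sg <- b$add("SG", "S", parent = cb)
  sd <- b$add("SD", "S", parent = sg)       # partner Sgamma'
  ce <- b$add("CE", "C", parent = sd, nH = 2L)  # partner Cbeta'
  cc <- b$add("C", "C", parent = ca)
  b$add("O", "O", parent = cc, order = 2)
  b$add("QB", "C", parent = cb, pseudo = TRUE)
  b$add("QE", "C", parent = ce, pseudo = TRUE)
  b$build()
}

#' Mirror a graph (x -> -x)
#'
#' @param g A [MolecularGraph-class].
#' @return The reflected graph.
#' @export
mirrorGraph <- function(g) {
  at <- atoms(g)
  at$x <- -at$x
  new("MolecularGraph", atoms = at, bonds = bonds(g), netCharge = g@netCharge)
}

#' Randomly permute atom order and serial labels
#'
#' @param g A [MolecularGraph-class].
#' @param seed Integer seed.
#' @return List with elements `graph` (the permuted graph) and `serialMap`
#'   (named integer vector: old serial -> new serial).
#' @export
permuteAtoms <- function(g, seed = 1L) {
  at <- atoms(g); bd <- bonds(g)
  n <- nrow(at)
  perm <- .withSeed(seed, sample.int(n))        # new row order
  lab <- .withSeed(seed + 1L, sample.int(n))    # new serial labels
  serialMap <- setNames(lab, as.character(at$serial))
  at2 <- at[perm, , drop = FALSE]
  at2$serial <- unname(serialMap[as.character(at2$serial)])
  bd2 <- bd
  bd2$a <- unname(serialMap[as.character(bd$a)])
  bd2$b <- unname(serialMap[as.character(bd$b)])
  rownames(at2) <- rownames(bd2) <- NULL
  list(graph = new("MolecularGraph", atoms = at2, bonds = bd2,
                   netCharge = g@netCharge),
       serialMap = serialMap)
}

# run expr with a local RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.MAX_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L)

# Random valence-respecting side-chain tree on a standard backbone.
.randomSideChain <- function(seed, nHeavy = 12L) {
  .withSeed(seed, {
    b <- .molBuilder()
    n <- b$add("N", "N", nH = 2L)
    ca <- b$add("CA", "C", parent = n, nH = 1L)
    elems <- c("C", "C", "C", "C", "C", "C", "C", "N", "N", "O", "S")
    heavies <- integer()
    parents <- integer()
    elemOf <- character()
    used <- integer()   # bonds used per side atom
    cb <- b$add("SC1", "C", parent = ca)
    heavies <- c(heavies, cb); parents <- c(parents, ca)
    elemOf <- c(elemOf, "C"); used <- c(used, 1L)
    nSide <- max(1L, min(nHeavy, 18L))
    while (length(heavies) < nSide) {
      open <- which(used < .MAX_VALENCE[elemOf])
      if (!length(open)) break
      pi <- if (length(open) == 1L) open else sample(open, 1L)
      el <- sample(elems, 1L)
      s <- b$add(paste0("S", el, length(heavies) + 1L), el,
                 parent = heavies[pi])
      used[pi] <- used[pi] + 1L
      heavies <- c(heavies, s); parents <- c(parents, heavies[pi])
      elemOf <- c(elemOf, el); used <- c(used, 1L)
    }
    # occasionally upgrade a C-C or C-O tree bond to a double bond
    for (i in seq_along(heavies)) {
      if (parents[i] %in% heavies) {
        j <- match(parents[i], heavies)
        if (elemOf[i] %in% c("C", "O") && elemOf[j] == "C" &&
            used[i] < .MAX_VALENCE[elemOf[i]] &&
            used[j] < .MAX_VALENCE[elemOf[j]] &&
            stats::runif(1) < 0.15) {
          for (bi in seq_along(b$bonds)) {
            bb <- b$bonds[[bi]]
            if ((bb$a == parents[i] && bb$b == heavies[i]) ||
                (bb$a == heavies[i] && bb$b == parents[i])) {
              b$bonds[[bi]]$order <- 2
              used[i] <- used[i] + 1L; used[j] <- used[j] + 1L
              break
            }
          }
        }
      }
    }
    # fill remaining valence with hydrogens
    for (i in seq_along(heavies)) {
      free <- .MAX_VALENCE[elemOf[i]] - used[i]
      if (free > 0) for (k in seq_len(free)) {
        b$add(paste0("HS", i, k), "H", parent = heavies[i])
      }
    }
    cc <- b$add("C", "C", parent = ca)
    b$add("O", "O", parent = cc, order = 2)
    b$add("OXT", "O", parent = cc, nH = 1L)
    b$build()
  })
}

# ---- extended templates for the linker ----------------------------------

#' Extended residue library templates for link fixtures
#'
#' `"CYSX"`: the extended cysteine template (side chain CB-SG plus the
#' partner image SD-CE beyond the linking bond, pseudoatoms QB and QE).
#' `"VAN5"`/`"VAN7"`: toy templates for the third vancomycin side-chain
#' link, residue 5 carrying extension atoms CG1/CE1/CZ3/CZ4 beyond its
#' linking atom CD1 and residue 7 carrying synthetic extension atoms
#' CE6/CZ5/CH1/CH2 beyond its linking atom CG3 (the residue-5 extension
#' names follow the published mapping; the residue-7 ones are synthetic).
#'
#' @param which "CYSX", "VAN5" or "VAN7".
#' @return A [ResidueTemplate-class].
#' @export
makeExtendedTemplate <- function(which = c("CYSX", "VAN5", "VAN7")) {
  which <- match.arg(which)
  if (which == "CYSX")
    return(graphToTemplate(.cysExtendedGraph(), "CYSX"))
  b <- .molBuilder()
  n <- b$add("N", "N", nH = 1L)
  ca <- b$add("CA", "C", parent = n, nH = 1L)
  if (which == "VAN5") {
    cb <- b$add("CB", "C", parent = ca, nH = 1L)
    cg <- b$add("CG", "C", parent = cb, nH = 1L)
    cb2 <- b$add("CB2", "C", parent = cg, nH = 3L)
    cd1 <- b$add("CD1", "C", parent = cg, nH = 0L)     # linking atom
    cg1 <- b$add("CG1", "C", parent = cd1, nH = 1L)    # extension
    ce1 <- b$add("CE1", "C", parent = cg1, nH = 1L)
    b$add("CZ3", "C", parent = ce1, nH = 1L)
    b$add("CZ4", "C", parent = ce1, nH = 1L)
  } else {
    cb <- b$add("CB", "C", parent = ca, nH = 1L)
    cd1 <- b$add("CD1", "C", parent = cb, nH = 1L)
    ce3 <- b$add("CE3", "C", parent = cd1, nH = 1L)
    ce5 <- b$add("CE5", "C", parent = ce3, nH = 1L)
    cg3 <- b$add("CG3", "C", parent = ce5, nH = 0L)    # linking atom
    ce6 <- b$add("CE6", "C", parent = cg3, nH = 1L)    # synthetic extension
    cz5 <- b$add("CZ5", "C", parent = ce6, nH = 1L)
    b$add("CH1", "C", parent = cz5, nH = 1L)
    b$add("CH2", "C", parent = cz5, nH = 1L)
  }
  cc <- b$add("C", "C", parent = ca)
  b$add("O", "O", parent = cc, order = 2)
  graphToTemplate(b$build(), which)
}

#' Packaged reference nomenclature for the canonical residues
#'
#' Standard IUPAC/BMRB heavy-atom side-chain names for the 20 canonical
#' amino acids, plus the documented list of deviations produced by the
#' literal sole-occupant rule (a chain-1 atom alone in its distance shell
#' carries no chain number, so e.g. the isoleucine delta methyl is emitted
#' as CD where common usage is CD1).
#'
#' @return List with elements `names` (named list: residue -> character
#'   vector of heavy side-chain names) and `deviations` (data.frame
#'   `residue`, `reference`, `emitted`).
#' @export
referenceNomenclature <- function() {
  f <- system.file("extdata", "canonical_sidechain_names.tsv",
                   package = "ncAAlib", mustWork = TRUE)
  lines <- readLines(f)[-1]
  parts <- strsplit(lines, "\t")
  nm <- lapply(parts, function(p)
    if (length(p) < 2 || !nzchar(p[2])) character()
    else strsplit(p[2], ",")[[1]])
  names(nm) <- vapply(parts, `[`, character(1), 1)
  dev <- utils::read.table(
    system.file("extdata", "sole_occupant_deviations.tsv",
                package = "ncAAlib", mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  list(names = nm, deviations = dev)
}
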