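# Recognition of capped peptide submission templates and excision of the
# central group of interest.
#
# The general template is Ace-Ala-X-Ala-NMe (internal residue); X-Ala-NMe
# and Ace-Ala-X mark N- and C-terminal residues.  X is whatever sits in the
# marked position - it need not be a canonical amino acid, only enterable
# into a peptide chain via peptide bonds (N-substitution is tolerated).

# hydrogens attached to any of `serials`
.attachedHydrogens <- function(g, serials) {
  at <- atoms(g)
  adj <- .adjacency(g)
  isH <- setNames(toupper(at$element) == "H" & !at$isPseudo,
                  as.character(at$serial))
  unlist(lapply(serials, function(s) {
    nb <- adj[[as.character(s)]]
    nb[isH[as.character(nb)]]
  }))
}

# methyl test: carbon whose only heavy neighbours are `allowed`
.isMethyl <- function(g, s, allowed) {
  at <- atoms(g)
  adj <- .adjacency(g)
  if (toupper(at$element[at$serial == s]) != "C") return(FALSE)
  nb <- adj[[as.character(s)]]
  heavyNb <- nb[toupper(at$element[match(nb, at$serial)]) != "H"]
  all(heavyNb %in% allowed)
}

#' Classify a capped peptide template
#'
#' Identifies peptide-bond backbone motifs, matches the acetyl (Ace) and
#' N-methyl-amide (NMe) caps and the flanking alanines, and determines
#' which template form the molecule represents: `internal`
#' (Ace-Ala-X-Ala-NMe), `n_terminal` (X-Ala-NMe), `c_terminal`
#' (Ace-Ala-X) or `not_template`.
#'
#' @param g A [MolecularGraph-class] with explicit bonds and hydrogens.
#' @return A [TemplateClassification-class].
#' @export
#' @examples
#' cls <- classifyTemplate(makeFixture("capped-ornithine"))
#' cls@kind  # "internal"
classifyTemplate <- function(g) {
  notTemplate <- new("TemplateClassification", kind = "not_template",
                     capAtoms = list(), xAtoms = integer(),
                     backbone = integer(), attachments = integer())
  heavy <- heavyAtomSubgraph(g)
  motifs <- .findBackboneMotifs(g)
  if (!length(motifs)) return(notTemplate)
  cas <- vapply(motifs, `[[`, integer(1), "ca")
  motifs <- motifs[!duplicated(cas)]
  at <- atoms(g)
  adjH <- .adjacency(heavy)
  elemOf <- setNames(toupper(atoms(heavy)$element),
                     as.character(atoms(heavy)$serial))
  bondedTo <- function(a, b) b %in% adjH[[as.character(a)]]

  # order motifs along the chain by peptide bonds C(i) - N(j)
  n <- length(motifs)
  nextOf <- rep(NA_integer_, n)
  prevOf <- rep(NA_integer_, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && bondedTo(motifs[[i]][["c"]], motifs[[j]][["n"]])) {
      nextOf[i] <- j; prevOf[j] <- i
    }
  }
  if (n > 1 && (sum(is.na(prevOf)) != 1 || sum(is.na(nextOf)) != 1))
    return(notTemplate)   # not a single linear peptide
  ordIdx <- which(is.na(prevOf))[1]
  ord <- ordIdx
  while (!is.na(nextOf[ord[length(ord)]])) ord <- c(ord, nextOf[ord[length(ord)]])
  if (length(ord) != n) return(notTemplate)
  motifs <- motifs[ord]

  firstN <- motifs[[1]][["n"]]; lastC <- motifs[[n]][["c"]]
  allCa <- vapply(motifs, `[[`, integer(1), "ca")

  # Ace cap: CH3-C(=O)- on the first residue's nitrogen
  aceAtoms <- integer()
  for (nb in adjH[[as.character(firstN)]]) {
    if (nb %in% allCa || elemOf[[as.character(nb)]] != "C") next
    onb <- adjH[[as.character(nb)]]
    os <- onb[elemOf[as.character(onb)] == "O"]
    me <- onb[vapply(onb, function(s) .isMethyl(heavy, s, nb), logical(1))]
    if (length(os) && length(me)) {
      aceAtoms <- c(nb, os[1], me[1])
      break
    }
  }
  # NMe cap: -N(H)-CH3 on the last residue's carbonyl carbon
  nmeAtoms <- integer()
  for (nb in adjH[[as.character(lastC)]]) {
    if (elemOf[[as.character(nb)]] != "N") next
    if (nb %in% vapply(motifs, `[[`, integer(1), "n")) next
    me <- adjH[[as.character(nb)]]
    me <- me[vapply(me, function(s) .isMethyl(heavy, s, nb), logical(1))]
    if (length(me)) { nmeAtoms <- c(nb, me[1]); break }
  }

  # per-residue atom sets: backbone + side chain reachable from CA
  resAtoms <- lapply(seq_len(n), function(i) {
    m <- motifs[[i]]
    blocked <- c(m[["n"]], m[["c"]])
    pruned <- subgraphBySerial(heavy,
                               setdiff(atoms(heavy)$serial, blocked))
    side <- as.integer(names(bondDistances(pruned, m[["ca"]])))
    bbO <- adjH[[as.character(m[["c"]])]]
    bbO <- bbO[elemOf[as.character(bbO)] == "O"]
    unique(c(m, side, bbO))
  })
  isAla <- vapply(seq_len(n), function(i) {
    m <- motifs[[i]]
    side <- setdiff(resAtoms[[i]],
                    c(m, adjH[[as.character(m[["c"]])]]))
    length(side) == 1L && .isMethyl(heavy, side[1], m[["ca"]])
  }, logical(1))

  hasAce <- length(aceAtoms) > 0
  hasNme <- length(nmeAtoms) > 0
  kind <- NULL; xIdx <- NULL; caps <- list()
  if (n == 3 && hasAce && hasNme && isAla[1] && isAla[3]) {
    kind <- "internal"; xIdx <- 2L
    caps <- list(ace = aceAtoms, ala_n = resAtoms[[1]],
                 ala_c = resAtoms[[3]], nme = nmeAtoms)
  } else if (n == 2 && !hasAce && hasNme && isAla[2]) {
    kind <- "n_terminal"; xIdx <- 1L
    caps <- list(ala_c = resAtoms[[2]], nme = nmeAtoms)
  } else if (n == 2 && hasAce && !hasNme && isAla[1]) {
    kind <- "c_terminal"; xIdx <- 2L
    caps <- list(ace = aceAtoms, ala_n = resAtoms[[1]])
  } else if (n >= 4 && hasAce && hasNme && isAla[1] && isAla[n]) {
    stop("ambiguous template: ", n - 2,
         " candidate X residues between the flanking alanines")
  } else {
    return(notTemplate)
  }

  # grow cap sets to include their hydrogens
  caps <- lapply(caps, function(s)
    as.integer(unique(c(s, .attachedHydrogens(g, s)))))
  capAll <- unique(unlist(caps))
  xAtoms <- setdiff(at$serial[!at$isPseudo], capAll)
  m <- motifs[[xIdx]]
  attachments <- integer()
  if (kind %in% c("internal", "c_terminal"))
    attachments <- c(attachments, n_side = m[["n"]])
  if (kind %in% c("internal", "n_terminal"))
    attachments <- c(attachments, c_side = m[["c"]])
  new("TemplateClassification", kind = kind, capAtoms = caps,
      xAtoms = as.integer(sort(xAtoms)),
      backbone = vapply(c("n", "ca", "c", "o"), function(k) m[[k]],
                        integer(1)),
      attachments = attachments)
}

#' Excise the group of interest from a recognised template
#'
#' Cuts the severed peptide bonds, keeps X's own atoms (terminal variants
#' keep their terminal groups), names the backbone N, H, CA, HA, C, O and
#' runs the side-chain renamer.  Attachment points (where peptide bonds
#' were severed) are recorded in the `attachments` attribute of the
#' returned graph.
#'
#' @param g The template [MolecularGraph-class].
#' @param cls Its [TemplateClassification-class].
#' @param amideH Name for a single backbone amide hydrogen ("H" for
#'   CCD-facing output, "HN" for CNS-facing output).
#' @return List with elements `graph` (the excised residue, atom names
#'   replaced by the new names) and `naming` (the [NamingResult-class]).
#' @export
exciseResidue <- function(g, cls, amideH = "H") {
  if (cls@kind == "not_template")
    stop("not a recognised template; nothing to excise")
  ex <- subgraphBySerial(g, cls@xAtoms)
  naming <- renameResidue(ex, amideH = amideH)
  at <- atoms(ex)
  idx <- match(at$serial, naming@map$serial)
  at$name <- ifelse(is.na(idx), at$name, naming@map$newName[idx])
  out <- new("MolecularGraph", atoms = at, bonds = bonds(ex),
             netCharge = ex@netCharge)
  attr(out, "attachments") <- cls@attachments
  list(graph = out, naming = naming)
}
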