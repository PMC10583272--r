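#' @import methods
#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

# Atomic numbers for the elements this package expects to meet in amino acids
# and their modifications.  Extend here if an exotic element is needed.
.ATOMIC_NUMBERS <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, NA. = 11L, MG = 12L,
  P = 15L, S = 16L, CL = 17L, K = 19L, CA. = 20L, FE = 26L, ZN = 30L,
  SE = 34L, BR = 35L, I = 53L
)

#' Atomic number of an element symbol
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Integer vector of atomic numbers.
#' @keywords internal
atomicNumber <- function(element) {
  key <- toupper(element)
  # Na and Ca clash with R's NA / the alpha-carbon shorthand; stored dotted.
  key[key == "NA"] <- "NA."
  key[key == "CA"] <- "CA."
  z <- .ATOMIC_NUMBERS[key]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  }
  unname(z)
}

.validElement <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  key[key == "CA"] <- "CA."
  key %in% names(.ATOMIC_NUMBERS)
}

#' MolecularGraph: atoms plus explicit bonds
#'
#' The substrate of every algorithm in the package: a small molecule or
#' residue with explicit hydrogens and explicit bonds.  Atoms live in a
#' data.frame with columns `serial` (unique positive integer), `name`,
#' `element`, `x`, `y`, `z` (Angstrom), `isPseudo` (CYANA Q-atoms),
#' `isDuplicate` (CIP phantom duplicates introduced for unsaturated bonds)
#' and `charge` (elementary charges, may be `NA`).  Bonds are a data.frame
#' with columns `a`, `b` (atom serials) and `order` (1, 2, 3, or 1.5 for
#' aromatic).
#'
#' @slot atoms data.frame of atoms.
#' @slot bonds data.frame of bonds.
#' @slot netCharge integer net charge of the molecule (may be `NA`).
#' @export
setClass("MolecularGraph",
  representation(atoms = "data.frame", bonds = "data.frame",
                 netCharge = "numeric"),
  prototype(netCharge = NA_real_)
)

setValidity("MolecularGraph", function(object) {
  at <- object@atoms
  bd <- object@bonds
  msgs <- character()
  need <- c("serial", "name", "element", "x", "y", "z",
            "isPseudo", "isDuplicate", "charge")
  if (!all(need %in% names(at)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(at$serial))
    msgs <- c(msgs, "atom serials must be unique")
  if (any(at$serial <= 0))
    msgs <- c(msgs, "atom serials must be positive")
  if (!all(.validElement(at$element[!at$isPseudo])))
    msgs <- c(msgs, "invalid element symbol among non-pseudo atoms")
  if (nrow(bd)) {
    if (!all(c("a", "b", "order") %in% names(bd)))
      return("bonds must have columns a, b, order")
    if (any(bd$a == bd$b))
      msgs <- c(msgs, "bond endpoints must differ")
    if (!all(c(bd$a, bd$b) %in% at$serial))
      msgs <- c(msgs, "bond references unknown atom serial")
    key <- paste(pmin(bd$a, bd$b), pmax(bd$a, bd$b))
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate bond for an unordered atom pair")
    if (!all(bd$order %in% c(1, 1.5, 2, 3)))
      msgs <- c(msgs, "bond order must be 1, 1.5 (aromatic), 2 or 3")
    deg <- table(factor(c(bd$a, bd$b), levels = at$serial))
    if (any(at$isDuplicate & deg != 1L))
      msgs <- c(msgs, "duplicate atoms must have exactly one bond")
    isH <- toupper(at$element) == "H" & !at$isDuplicate & !at$isPseudo
    if (any(isH & deg > 1L))
      msgs <- c(msgs, "hydrogens must have degree 1")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a MolecularGraph
#'
#' @param atoms data.frame with at least `serial`, `element`, `x`, `y`, `z`.
#'   Missing optional columns (`name`, `isPseudo`, `isDuplicate`, `charge`)
#'   are filled with defaults.
#' @param bonds data.frame with columns `a`, `b` and optionally `order`
#'   (default 1).
#' @param netCharge integer net charge; `NA` when unknown.
#' @return A [MolecularGraph-class] object.
#' @export
#' @examples
#' g <- makeMolecularGraph(
#'   data.frame(serial = 1:2, element = c("C", "O"),
#'              x = c(0, 1.23), y = 0, z = 0),
#'   data.frame(a = 1, b = 2, order = 2))
#' nAtoms(g)
makeMolecularGraph <- function(atoms, bonds = data.frame(), netCharge = NA) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$name)) atoms$name <- paste0(atoms$element, atoms$serial)
  if (is.null(atoms$isPseudo)) atoms$isPseudo <- FALSE
  if (is.null(atoms$isDuplicate)) atoms$isDuplicate <- FALSE
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  atoms$serial <- as.integer(atoms$serial)
  cols <- c("serial", "name", "element", "x", "y", "z",
            "isPseudo", "isDuplicate", "charge")
  atoms <- atoms[, c(cols, setdiff(names(atoms), cols)), drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    if (is.null(bonds$order)) bonds$order <- 1
    bonds$a <- as.integer(bonds$a)
    bonds$b <- as.integer(bonds$b)
    bonds$order <- as.numeric(bonds$order)
    rownames(bonds) <- NULL
  } else {
    bonds <- data.frame(a = integer(), b = integer(), order = numeric())
  }
  new("MolecularGraph", atoms = atoms, bonds = bonds,
      netCharge = as.numeric(netCharge))
}

#' @rdname MolecularGraph-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname MolecularGraph-accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname MolecularGraph-accessors
#' @export
setGeneric("netCharge", function(x) standardGeneric("netCharge"))
#' @rdname MolecularGraph-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname MolecularGraph-accessors
#' @export
setGeneric("nBonds", function(x) standardGeneric("nBonds"))

#' Accessors for MolecularGraph
#'
#' `atoms()` and `bonds()` return the underlying data.frames; `netCharge()`
#' the declared net charge; `nAtoms()`/`nBonds()` the counts.
#'
#' @param x A [MolecularGraph-class].
#' @name MolecularGraph-accessors
#' @aliases atoms bonds netCharge nAtoms nBonds
NULL

#' @rdname MolecularGraph-accessors
setMethod("atoms", "MolecularGraph", function(x) x@atoms)
#' @rdname MolecularGraph-accessors
setMethod("bonds", "MolecularGraph", function(x) x@bonds)
#' @rdname MolecularGraph-accessors
setMethod("netCharge", "MolecularGraph", function(x) x@netCharge)
#' @rdname MolecularGraph-accessors
setMethod("nAtoms", "MolecularGraph", function(x) nrow(x@atoms))
#' @rdname MolecularGraph-accessors
setMethod("nBonds", "MolecularGraph", function(x) nrow(x@bonds))

setMethod("show", "MolecularGraph", function(object) {
  at <- object@atoms
  cat("MolecularGraph with", nrow(at), "atoms and",
      nrow(object@bonds), "bonds\n")
  tab <- table(at$element[!at$isDuplicate & !at$isPseudo])
  cat("  formula:", paste0(names(tab), tab, collapse = " "), "\n")
  if (any(at$isDuplicate))
    cat("  CIP duplicate atoms:", sum(at$isDuplicate), "\n")
  if (any(at$isPseudo))
    cat("  pseudoatoms:", sum(at$isPseudo), "\n")
  if (!is.na(object@netCharge))
    cat("  net charge:", object@netCharge, "\n")
  invisible(NULL)
})

#' ChainAssignment: per-atom distance and chain identifier
#'
#' Result of [assignChains()]: one row per side-chain heavy atom with its
#' bond distance from the alpha carbon, the CIP chain identifier (1 =
#' highest priority) and how the priority decision was made
#' (`atomic-number`, `sphere-comparison`, `geometric`, `ring-join` or
#' `arbitrary`).
#'
#' @slot table data.frame with columns `serial`, `distance`, `chain`,
#'   `resolvedBy`.
#' @slot audit character vector; human-readable trail of priority decisions.
#' @slot caSerial serial of the alpha carbon the distances refer to.
#' @export
setClass("ChainAssignment",
  representation(table = "data.frame", audit = "character",
                 caSerial = "integer"))

setValidity("ChainAssignment", function(object) {
  tb <- object@table
  need <- c("serial", "distance", "chain", "resolvedBy")
  if (!all(need %in% names(tb)))
    return(paste("table needs columns", paste(need, collapse = ", ")))
  if (nrow(tb) && any(tb$distance < 1)) return("distances must be >= 1")
  if (nrow(tb) && any(tb$chain < 1)) return("chain ids must be >= 1")
  TRUE
})

setMethod("show", "ChainAssignment", function(object) {
  cat("ChainAssignment for", nrow(object@table), "side-chain heavy atoms\n")
  if (nrow(object@table)) {
    cat("  chains:", max(object@table$chain),
        " max distance:", max(object@table$distance), "\n")
  }
  invisible(NULL)
})

#' NamingResult: mapping from input atoms to IUPAC-conformant names
#'
#' @slot map data.frame with columns `serial`, `oldName`, `newName`, `kind`
#'   (`backbone`, `sidechain`, `hydrogen`, `terminal`).
#' @slot pseudoatoms data.frame with columns `name`, `parentSerial`,
#'   `members` (comma-separated hydrogen names the Q-atom represents).
#' @slot audit character; trail of the priority/numbering decisions.
#' @export
setClass("NamingResult",
  representation(map = "data.frame", pseudoatoms = "data.frame",
                 audit = "character"))

setValidity("NamingResult", function(object) {
  m <- object@map
  if (!all(c("serial", "oldName", "newName", "kind") %in% names(m)))
    return("map needs columns serial, oldName, newName, kind")
  if (anyDuplicated(m$newName))
    return("new atom names must be unique within the residue")
  TRUE
})

setMethod("show", "NamingResult", function(object) {
  cat("NamingResult:", nrow(object@map), "atoms named")
  if (nrow(object@pseudoatoms))
    cat(",", nrow(object@pseudoatoms), "pseudoatoms")
  cat("\n")
  invisible(NULL)
})

#' @rdname NamingResult-accessors
#' @export
setGeneric("nameMap", function(x) standardGeneric("nameMap"))
#' Accessors for NamingResult
#' @param x A [NamingResult-class].
#' @name NamingResult-accessors
#' @rdname NamingResult-accessors
setMethod("nameMap", "NamingResult", function(x) x@map)

#' ResidueTemplate: one parsed CYANA residue library entry
#'
#' Preserves every input byte so that writing an unmodified entry
#' reproduces the input exactly.  Atom records are additionally parsed
#' into fields so that the linker can retype atoms in place.
#'
#' @slot name residue code (e.g. "CYSX").
#' @slot headerLine the raw RESIDUE header line.
#' @slot angleLines raw dihedral-angle lines, in order.
#' @slot atomTable data.frame with columns `serial`, `name`, `type`,
#'   `x`, `y`, `z`, `bonded` (list of integer vectors), `raw` (the exact
#'   input line), `typeStart`, `typeEnd` (character positions of the type
#'   field within `raw`).
#' @slot headerCounts integer vector of the counts as read from the header.
#' @export
setClass("ResidueTemplate",
  representation(name = "character", headerLine = "character",
                 angleLines = "character", atomTable = "data.frame",
                 headerCounts = "integer"))

setValidity("ResidueTemplate", function(object) {
  tb <- object@atomTable
  need <- c("serial", "name", "type", "x", "y", "z", "bonded", "raw",
            "typeStart", "typeEnd")
  if (!all(need %in% names(tb)))
    return(paste("atomTable needs columns", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$name))
    return("atom names must be unique within a template entry")
  refs <- unlist(tb$bonded)
  refs <- refs[refs != 0]
  if (length(refs) && !all(refs %in% tb$serial))
    return("bonded-serial list references an atom outside the entry")
  TRUE
})

setMethod("show", "ResidueTemplate", function(object) {
  cat("ResidueTemplate", object@name, "-", nrow(object@atomTable), "atoms,",
      length(object@angleLines), "angle records\n")
  invisible(NULL)
})

#' @rdname ResidueTemplate-accessors
#' @export
setGeneric("templateName", function(x) standardGeneric("templateName"))
#' @rdname ResidueTemplate-accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' Accessors for ResidueTemplate
#' @param x A [ResidueTemplate-class].
#' @name ResidueTemplate-accessors
#' @rdname ResidueTemplate-accessors
setMethod("templateName", "ResidueTemplate", function(x) x@name)
#' @rdname ResidueTemplate-accessors
setMethod("atomTable", "ResidueTemplate", function(x) x@atomTable)

#' TemplateClassification: recognised capped-template form
#'
#' @slot kind one of `internal`, `n_terminal`, `c_terminal`, `not_template`.
#' @slot capAtoms named list of integer serial vectors (`ace`, `nme`,
#'   `ala_n`, `ala_c`) for the caps and flanking alanines present.
#' @slot xAtoms integer serials of the group of interest X, including its
#'   backbone.
#' @slot backbone named integer vector (n, ca, c, o) of X's backbone serials.
#' @slot attachments named integer vector of X atoms where peptide bonds
#'   were severed.
#' @export
setClass("TemplateClassification",
  representation(kind = "character", capAtoms = "list", xAtoms = "integer",
                 backbone = "integer", attachments = "integer"))

setMethod("show", "TemplateClassification", function(object) {
  cat("TemplateClassification:", object@kind, "\n")
  if (object@kind != "not_template")
    cat("  X group:", length(object@xAtoms), "atoms; caps/flanks:",
        paste(names(object@capAtoms), collapse = ", "), "\n")
  invisible(NULL)
})

#' LinkSpec: user description of a side-chain link
#'
#' @slot templateA,templateB the two extended [ResidueTemplate-class]s.
#' @slot resIndexA,resIndexB residue positions in the intended sequence.
#' @slot linkingBond character(2): the linking-bond atom name in template A
#'   and in template B (real atoms).
#' @slot overlapPairs data.frame with columns `templateSide` ("A" or "B"),
#'   `extAtom` (extension atom name on that side), `realAtom` (the
#'   corresponding real atom name in the other template).
#' @export
setClass("LinkSpec",
  representation(templateA = "ResidueTemplate", templateB = "ResidueTemplate",
                 resIndexA = "integer", resIndexB = "integer",
                 linkingBond = "character", overlapPairs = "data.frame"))

setMethod("show", "LinkSpec", function(object) {
  cat("LinkSpec:", object@templateA@name, "(res", object@resIndexA, ") -",
      object@templateB@name, "(res", object@resIndexB, ") via",
      paste(object@linkingBond, collapse = "-"), ";",
      nrow(object@overlapPairs), "overlap pairs\n")
  invisible(NULL)
})

#' LinkResult: modified templates, restraints and link statement
#'
#' @slot templateA,templateB the retyped templates (extension atoms and
#'   their hydrogens carry the DUMMY type; pseudoatoms untouched).
#' @slot restraints data.frame of upper-distance restraints with columns
#'   `resI`, `resnameI`, `atomI`, `resJ`, `resnameJ`, `atomJ`, `limit`,
#'   `weight`.
#' @slot statement named list: `atomI`, `resI`, `atomJ`, `resJ`, `dialect`.
#' @slot dummyRegistry data.frame of all DUMMY-retyped atoms with columns
#'   `resIndex`, `resname`, `atom` (used by [finalizeStructure()]).
#' @export
setClass("LinkResult",
  representation(templateA = "ResidueTemplate", templateB = "ResidueTemplate",
                 restraints = "data.frame", statement = "list",
                 dummyRegistry = "data.frame"))

setValidity("LinkResult", function(object) {
  r <- object@restraints
  if (nrow(r) && any(r$limit <= 0)) return("restraint limits must be > 0")
  if (nrow(r) && any(r$weight <= 0)) return("restraint weights must be > 0")
  TRUE
})

setMethod("show", "LinkResult", function(object) {
  cat("LinkResult:", nrow(object@restraints), "restraints,",
      nrow(object@dummyRegistry), "DUMMY atoms, link",
      object@statement$atomI, object@statement$resI, "-",
      object@statement$atomJ, object@statement$resJ, "\n")
  invisible(NULL)
})

#' @rdname LinkResult-accessors
#' @export
setGeneric("restraints", function(x) standardGeneric("restraints"))
#' @rdname LinkResult-accessors
#' @export
setGeneric("linkStatement", function(x) standardGeneric("linkStatement"))
#' @rdname LinkResult-accessors
#' @export
setGeneric("dummyRegistry", function(x) standardGeneric("dummyRegistry"))
#' Accessors for LinkResult
#' @param x A [LinkResult-class].
#' @name LinkResult-accessors
#' @rdname LinkResult-accessors
setMethod("restraints", "LinkResult", function(x) x@restraints)
#' @rdname LinkResult-accessors
setMethod("linkStatement", "LinkResult", function(x) x@statement)
#' @rdname LinkResult-accessors
setMethod("dummyRegistry", "LinkResult", function(x) x@dummyRegistry)

#' CnsBuildingBlock: a CNS-compatible residue description
#'
#' @slot resname residue code.
#' @slot atoms data.frame with columns `name`, `type`, `charge`,
#'   `isBackbone`.
#' @slot bondTerms,angleTerms,dihedralTerms,improperTerms data.frames of
#'   bonded terms over atom names with a `params` list column.
#' @slot typeParams data.frame of per-type non-bonded parameters with
#'   columns `type`, `eps`, `sigma`.
#' @slot netCharge declared net charge (e).
#' @export
setClass("CnsBuildingBlock",
  representation(resname = "character", atoms = "data.frame",
                 bondTerms = "data.frame", angleTerms = "data.frame",
                 dihedralTerms = "data.frame", improperTerms = "data.frame",
                 typeParams = "data.frame", netCharge = "numeric"))

setValidity("CnsBuildingBlock", function(object) {
  if (!all(c("name", "type", "charge", "isBackbone") %in%
           names(object@atoms)))
    return("atoms needs columns name, type, charge, isBackbone")
  if (!is.na(object@netCharge) &&
      abs(sum(object@atoms$charge) - object@netCharge) > 1e-6)
    return("atom charges must sum to the declared net charge within 1e-6 e")
  TRUE
})

setMethod("show", "CnsBuildingBlock", function(object) {
  cat("CnsBuildingBlock", object@resname, "-", nrow(object@atoms), "atoms (",
      sum(object@atoms$isBackbone), "retained backbone ), net charge",
      object@netCharge, "\n")
  invisible(NULL)
})
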