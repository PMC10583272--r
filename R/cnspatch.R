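# CNS building-block patching: retain the standard atom types and
# parameters for the protein-backbone atoms (N, HN, CA, HA, CB, O), mint
# fresh atom types for everything else, and absorb any residual charge
# into the non-backbone atom of largest charge magnitude so that the net
# charge is conserved when the standard backbone charges replace the
# input ones.

.CNS_BACKBONE <- c("N", "HN", "CA", "HA", "CB", "O")

#' Read a residue topology description (YAML/JSON)
#'
#' Schema: `resname`, `net_charge`, `atoms` (list of `name`, `type`,
#' `charge`), optional `bonds`/`angles`/`dihedrals`/`impropers` (lists of
#' atom-name vectors with an optional `params` numeric vector) and
#' optional `types` (list of `type`, `eps`, `sigma`).
#'
#' @param path YAML or JSON file.
#' @return Topology list in the layout accepted by [buildCnsPatch()].
#' @export
readCnsTopology <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  terms <- function(key, arity) {
    xs <- raw[[key]]
    if (is.null(xs)) return(data.frame(atoms = I(list()),
                                       params = I(list())))
    data.frame(
      atoms = I(lapply(xs, function(t) as.character(t$atoms))),
      params = I(lapply(xs, function(t)
        if (is.null(t$params)) numeric() else as.numeric(t$params))))
  }
  list(
    resname = raw$resname,
    netCharge = as.numeric(raw$net_charge),
    atoms = data.frame(
      name = vapply(raw$atoms, function(a) a$name, character(1)),
      type = vapply(raw$atoms, function(a) a$type, character(1)),
      charge = vapply(raw$atoms, function(a) as.numeric(a$charge),
                      numeric(1)),
      stringsAsFactors = FALSE),
    bonds = terms("bonds", 2), angles = terms("angles", 3),
    dihedrals = terms("dihedrals", 4), impropers = terms("impropers", 4),
    types = if (is.null(raw$types))
      data.frame(type = character(), eps = numeric(), sigma = numeric())
    else data.frame(
      type = vapply(raw$types, function(t) t$type, character(1)),
      eps = vapply(raw$types, function(t) as.numeric(t$eps), numeric(1)),
      sigma = vapply(raw$types, function(t) as.numeric(t$sigma),
                     numeric(1)),
      stringsAsFactors = FALSE))
}

#' Read a standard-backbone charge table
#'
#' Tab-separated columns `atom`, `type`, `charge` for the six retained
#' backbone atoms.  A synthetic example ships in
#' `inst/extdata/cns_backbone_charges_synthetic.tsv`.
#'
#' @param path TSV file.
#' @return data.frame with columns `atom`, `type`, `charge`.
#' @export
readBackboneCharges <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Build a CNS-compatible building block
#'
#' Backbone atoms keep the standard types and charges supplied in
#' `backboneCharges`; every other atom receives a fresh type name.  The
#' residual charge, `netCharge` minus the sum of standard backbone charges
#' and input non-backbone charges, is added to the non-backbone atom with
#' the largest charge magnitude (ties broken by atom-name order), so the
#' output charges sum exactly to the declared net charge.
#'
#' @param topology Topology list (see [readCnsTopology()]): `resname`,
#'   `atoms` data.frame (`name`, `type`, `charge`), bonded-term tables and
#'   a `types` non-bonded parameter table.
#' @param backboneCharges data.frame `atom`/`type`/`charge` for the
#'   standard backbone atoms.
#' @param netCharge Declared net charge (e); defaults to
#'   `topology$netCharge`.
#' @param retainC Also retain the carbonyl C as a standard backbone atom
#'   (the default retained set is N, HN, CA, HA, CB, O).
#' @param requireBackbone Error when a retained-backbone atom is missing;
#'   set `FALSE` for backbone-modified residues (only the atoms present
#'   are retained).
#' @return A [CnsBuildingBlock-class].
#' @export
buildCnsPatch <- function(topology, backboneCharges,
                          netCharge = topology$netCharge,
                          retainC = FALSE, requireBackbone = TRUE) {
  atoms <- topology$atoms
  backboneNames <- c(.CNS_BACKBONE, if (retainC) "C")
  missing <- setdiff(backboneNames, atoms$name)
  if (length(missing)) {
    if (requireBackbone)
      stop("missing backbone atom(s): ", paste(missing, collapse = ", "),
           "; backbone-modified residues need requireBackbone = FALSE ",
           "and manual linkage statements")
    backboneNames <- setdiff(backboneNames, missing)
  }
  isBB <- atoms$name %in% backboneNames
  if (!any(!isBB))
    stop("no absorber: every atom is a retained backbone atom")
  bbIdx <- match(atoms$name[isBB], backboneCharges$atom)
  if (anyNA(bbIdx))
    stop("backbone charge table lacks atom(s): ",
         paste(atoms$name[isBB][is.na(bbIdx)], collapse = ", "))
  out <- atoms
  out$isBackbone <- isBB
  out$type[isBB] <- backboneCharges$type[bbIdx]
  inputCharge <- atoms$charge
  out$charge[isBB] <- backboneCharges$charge[bbIdx]
  # fresh type names for everything else: one per distinct input type
  prefix <- toupper(substr(topology$resname, 1, 2))
  oldTypes <- unique(atoms$type[!isBB])
  newTypes <- setNames(sprintf("%s%d", prefix, seq_along(oldTypes)),
                       oldTypes)
  out$type[!isBB] <- unname(newTypes[atoms$type[!isBB]])
  # residual charge absorption
  residual <- netCharge - (sum(out$charge[isBB]) + sum(inputCharge[!isBB]))
  if (abs(residual) > 1e-12) {
    cand <- which(!isBB)
    mag <- abs(inputCharge[cand])
    best <- cand[order(-mag, atoms$name[cand])][1]
    out$charge[best] <- out$charge[best] + residual
  }
  types <- topology$types
  types <- types[types$type %in% oldTypes, , drop = FALSE]
  types$type <- unname(newTypes[types$type])
  new("CnsBuildingBlock", resname = topology$resname,
      atoms = out[, c("name", "type", "charge", "isBackbone")],
      bondTerms = topology$bonds, angleTerms = topology$angles,
      dihedralTerms = topology$dihedrals, improperTerms = topology$impropers,
      typeParams = types, netCharge = as.numeric(netCharge))
}

#' Resolve atom-type name clashes across building blocks
#'
#' Type names that appear in more than one block with identical non-bonded
#' parameters are merged silently; identical names with differing
#' parameters are renamed with a deterministic numeric suffix (`_2`,
#' `_3`, ...) in later blocks.  A report of every rename is returned.
#'
#' @param blocks List of [CnsBuildingBlock-class]s.
#' @return List with elements `blocks` (the resolved list) and `report`
#'   (data.frame `block`, `oldType`, `newType`).
#' @export
resolveTypeClashes <- function(blocks) {
  if (!length(blocks)) stop("need at least one building block")
  seen <- list()   # type name -> params of first definition
  report <- list()
  allNames <- unique(unlist(lapply(blocks, function(b) b@typeParams$type)))
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    tp <- b@typeParams
    for (i in seq_len(nrow(tp))) {
      ty <- tp$type[i]
      pars <- c(tp$eps[i], tp$sigma[i])
      if (is.null(seen[[ty]])) {
        seen[[ty]] <- pars
      } else if (max(abs(seen[[ty]] - pars)) <= 1e-9) {
        # parameter-identical duplicate: merge silently
      } else {
        k <- 2L
        repeat {
          cand <- sprintf("%s_%d", ty, k)
          if (is.null(seen[[cand]]) && !cand %in% allNames) break
          if (!is.null(seen[[cand]]) &&
              max(abs(seen[[cand]] - pars)) <= 1e-9) break
          k <- k + 1L
        }
        report[[length(report) + 1L]] <-
          data.frame(block = bi, oldType = ty, newType = cand,
                     stringsAsFactors = FALSE)
        b@atoms$type[b@atoms$type == ty] <- cand
        tp$type[i] <- cand
        if (is.null(seen[[cand]])) seen[[cand]] <- pars
      }
    }
    b@typeParams <- tp
    blocks[[bi]] <- b
  }
  list(blocks = blocks,
       report = if (length(report)) do.call(rbind, report) else
         data.frame(block = integer(), oldType = character(),
                    newType = character(), stringsAsFactors = FALSE))
}

#' Serialise a building block as CNS topology text
#'
#' @param block A [CnsBuildingBlock-class].
#' @param path Output path (`NULL` returns the lines).
#' @return Invisibly, the lines.
#' @export
writeCnsTopology <- function(block, path = NULL) {
  at <- block@atoms
  lines <- c(sprintf("RESIdue %s", block@resname), "  GROUP")
  lines <- c(lines, vapply(seq_len(nrow(at)), function(i)
    sprintf("    ATOM %-5s TYPE=%-8s CHARge=%8.4f END",
            at$name[i], at$type[i], at$charge[i]), character(1)))
  term <- function(df, kw) {
    if (!nrow(df)) return(character())
    vapply(seq_len(nrow(df)), function(i)
      paste0("  ", kw, " ", paste(sprintf("%-5s", df$atoms[[i]]),
                                  collapse = " ")), character(1))
  }
  lines <- c(lines,
             term(block@bondTerms, "BOND"),
             term(block@angleTerms, "ANGLe"),
             term(block@dihedralTerms, "DIHEdral"),
             term(block@improperTerms, "IMPRoper"),
             "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Serialise building-block parameters as CNS parameter text
#'
#' Bonded terms are written with their parameter vectors (over atom
#' types); non-bonded lines carry the per-type eps/sigma pairs.
#'
#' @param block A [CnsBuildingBlock-class].
#' @param path Output path (`NULL` returns the lines).
#' @return Invisibly, the lines.
#' @export
writeCnsParameters <- function(block, path = NULL) {
  typeOf <- setNames(block@atoms$type, block@atoms$name)
  term <- function(df, kw) {
    if (!nrow(df)) return(character())
    vapply(seq_len(nrow(df)), function(i) {
      tys <- unname(typeOf[df$atoms[[i]]])
      pars <- df$params[[i]]
      paste0(kw, " ", paste(sprintf("%-8s", tys), collapse = " "),
             if (length(pars)) paste0(" ", paste(sprintf("%.4f", pars),
                                                 collapse = " ")))
    }, character(1))
  }
  tp <- block@typeParams
  nb <- if (nrow(tp)) vapply(seq_len(nrow(tp)), function(i)
    sprintf("NONBonded %-8s %.6f %.6f %.6f %.6f", tp$type[i],
            tp$eps[i], tp$sigma[i], tp$eps[i], tp$sigma[i]),
    character(1)) else character()
  lines <- c(term(block@bondTerms, "BOND"),
             term(block@angleTerms, "ANGLe"),
             term(block@dihedralTerms, "DIHEdral"),
             term(block@improperTerms, "IMPRoper"),
             nb)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
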