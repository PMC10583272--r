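# Side-chain linking for torsion-angle structure calculation: two extended
# residue templates (each reaching at least one atom beyond the linking
# bond) are turned into link-ready templates by retyping the extension
# atoms as DUMMY, plus short upper-distance restraints pulling each
# template's extension onto the partner's real atoms, plus the link
# statement that removes the repulsion between the two linking atoms.

# element guess for template atoms (no element column in .lib entries)
.templateElement <- function(name) .elementFromPdb("", name)

# adjacency within a template from the bonded-serial lists
.templateAdjacency <- function(template) {
  tb <- template@atomTable
  adj <- setNames(vector("list", nrow(tb)), as.character(tb$serial))
  for (i in seq_len(nrow(tb))) {
    for (b in tb$bonded[[i]]) {
      if (b == 0) next
      adj[[as.character(tb$serial[i])]] <-
        unique(c(adj[[as.character(tb$serial[i])]], b))
      adj[[as.character(b)]] <-
        unique(c(adj[[as.character(b)]], tb$serial[i]))
    }
  }
  adj
}

# atoms beyond the linking atom, away from the backbone: the connected
# components, after removing the linking atom, that do not contain the
# backbone anchor (atom named CA, falling back to the first atom).
.extensionAtoms <- function(template, linkingAtom) {
  tb <- template@atomTable
  li <- match(linkingAtom, tb$name)
  if (is.na(li))
    stop("linking atom '", linkingAtom, "' not found in template '",
         template@name, "'")
  anchor <- if ("CA" %in% tb$name) tb$serial[match("CA", tb$name)]
            else tb$serial[1]
  adj <- .templateAdjacency(template)
  linkSerial <- tb$serial[li]
  visited <- c(linkSerial)
  reach <- function(start) {
    comp <- start; queue <- start
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[as.character(cur)]]) {
        if (nb %in% comp || nb == linkSerial) next
        comp <- c(comp, nb); queue <- c(queue, nb)
      }
    }
    comp
  }
  backboneComp <- reach(anchor)
  ext <- integer()
  for (nb in adj[[as.character(linkSerial)]]) {
    if (nb %in% backboneComp || nb %in% ext) next
    ext <- c(ext, reach(nb))
  }
  tb$name[match(sort(unique(ext)), tb$serial)]
}

#' Construct a link specification
#'
#' @param templateA,templateB Extended [ResidueTemplate-class]s (the same
#'   template may be supplied twice, e.g. for a disulfide).
#' @param resIndexA,resIndexB Residue positions in the intended sequence.
#' @param linkingBond Character(2): linking-bond atom name in template A
#'   and in template B.
#' @param overlapA,overlapB Named character vectors mapping each extension
#'   atom name (in A resp. B) to the corresponding real atom name in the
#'   other template.
#' @return A [LinkSpec-class].
#' @export
makeLinkSpec <- function(templateA, templateB, resIndexA, resIndexB,
                         linkingBond, overlapA, overlapB) {
  pairs <- rbind(
    data.frame(templateSide = "A", extAtom = names(overlapA),
               realAtom = unname(overlapA), stringsAsFactors = FALSE),
    data.frame(templateSide = "B", extAtom = names(overlapB),
               realAtom = unname(overlapB), stringsAsFactors = FALSE))
  new("LinkSpec", templateA = templateA, templateB = templateB,
      resIndexA = as.integer(resIndexA), resIndexB = as.integer(resIndexB),
      linkingBond = as.character(linkingBond), overlapPairs = pairs)
}

#' Generate link-ready templates, restraints and the link statement
#'
#' In each template the atoms beyond the linking bond - and the hydrogens
#' attached to them - are retyped with the DUMMY code (pseudoatom records
#' are never altered).  One upper-distance restraint is written per mapped
#' overlap pair, with the configured limit and weight, plus a link
#' statement naming the two linking-bond atoms.  Atom names, coordinates
#' and connectivity are untouched: only type codes change, so re-running
#' the operation on its own output is a no-op.
#'
#' @param spec A [LinkSpec-class].
#' @param limit Upper-distance limit in Angstrom (must be > 0).
#' @param weight Restraint weight.
#' @param dummyType,pseudoType Type codes for DUMMY retyping and for
#'   pseudoatom detection.
#' @param dialect Link-statement dialect keyword.
#' @param hydrogenRestraints Also restrain the retyped extension hydrogens
#'   onto the hydrogens of the mapped real atoms (paired in name order).
#' @return A [LinkResult-class].
#' @export
linkTemplates <- function(spec, limit = 0.04, weight = 10,
                          dummyType = "DUMMY", pseudoType = "PSEUD",
                          dialect = "link", hydrogenRestraints = FALSE) {
  if (limit <= 0) stop("the upper-distance limit must be larger than 0")
  sides <- list(
    A = list(tmpl = spec@templateA, res = spec@resIndexA,
             link = spec@linkingBond[1],
             other = spec@templateB, otherRes = spec@resIndexB),
    B = list(tmpl = spec@templateB, res = spec@resIndexB,
             link = spec@linkingBond[2],
             other = spec@templateA, otherRes = spec@resIndexA))
  outTmpl <- list()
  restraints <- list()
  registry <- list()
  for (sd in names(sides)) {
    s <- sides[[sd]]
    tb <- s$tmpl@atomTable
    pairs <- spec@overlapPairs[spec@overlapPairs$templateSide == sd, ,
                               drop = FALSE]
    ext <- .extensionAtoms(s$tmpl, s$link)
    if (!length(ext))
      stop("template '", s$tmpl@name, "' has no extension beyond the ",
           "linking bond at ", s$link)
    isPseudoAtom <- setNames(tb$type == pseudoType, tb$name)
    elem <- setNames(vapply(tb$name, .templateElement, character(1)),
                     tb$name)
    extHeavy <- ext[!isPseudoAtom[ext] & elem[ext] != "H"]
    extH <- ext[!isPseudoAtom[ext] & elem[ext] == "H"]
    bad <- setdiff(pairs$extAtom, tb$name)
    if (length(bad))
      stop("overlap pair names atom(s) absent from template '",
           s$tmpl@name, "': ", paste(bad, collapse = ", "))
    badReal <- setdiff(pairs$realAtom, s$other@atomTable$name)
    if (length(badReal))
      stop("overlap pair names atom(s) absent from partner template '",
           s$other@name, "': ", paste(badReal, collapse = ", "))
    unmapped <- setdiff(extHeavy, pairs$extAtom)
    if (length(unmapped))
      stop("extension atom(s) of template '", s$tmpl@name,
           "' left unmapped: ", paste(unmapped, collapse = ", "))
    notExt <- setdiff(pairs$extAtom, ext)
    if (length(notExt))
      stop("mapped atom(s) are not in the extension of template '",
           s$tmpl@name, "': ", paste(notExt, collapse = ", "))
    retype <- ext[!isPseudoAtom[ext]]
    outTmpl[[sd]] <- setAtomType(s$tmpl, retype, dummyType)
    registry[[sd]] <- data.frame(resIndex = s$res, resname = s$tmpl@name,
                                 atom = retype, stringsAsFactors = FALSE)
    restraints[[sd]] <- data.frame(
      resI = s$res, resnameI = s$tmpl@name, atomI = pairs$extAtom,
      resJ = s$otherRes, resnameJ = s$other@name, atomJ = pairs$realAtom,
      limit = limit, weight = weight, stringsAsFactors = FALSE)
    if (hydrogenRestraints && length(extH)) {
      oadj <- .templateAdjacency(s$other)
      otb <- s$other@atomTable
      oelem <- setNames(vapply(otb$name, .templateElement, character(1)),
                        otb$name)
      madj <- .templateAdjacency(s$tmpl)
      hrows <- list()
      for (pi in seq_len(nrow(pairs))) {
        extNb <- madj[[as.character(tb$serial[match(pairs$extAtom[pi],
                                                    tb$name)])]]
        myH <- sort(tb$name[match(extNb, tb$serial)][
          elem[tb$name[match(extNb, tb$serial)]] == "H"])
        realNb <- oadj[[as.character(otb$serial[match(pairs$realAtom[pi],
                                                      otb$name)])]]
        otherH <- sort(otb$name[match(realNb, otb$serial)][
          oelem[otb$name[match(realNb, otb$serial)]] == "H"])
        k <- min(length(myH), length(otherH))
        if (k > 0)
          hrows[[length(hrows) + 1L]] <- data.frame(
            resI = s$res, resnameI = s$tmpl@name, atomI = myH[seq_len(k)],
            resJ = s$otherRes, resnameJ = s$other@name,
            atomJ = otherH[seq_len(k)], limit = limit, weight = weight,
            stringsAsFactors = FALSE)
      }
      if (length(hrows))
        restraints[[paste0(sd, "H")]] <- do.call(rbind, hrows)
    }
  }
  stmt <- list(atomI = spec@linkingBond[1], resI = spec@resIndexA,
               atomJ = spec@linkingBond[2], resJ = spec@resIndexB,
               dialect = dialect)
  res <- do.call(rbind, unname(restraints))
  rownames(res) <- NULL
  new("LinkResult", templateA = outTmpl$A, templateB = outTmpl$B,
      restraints = res, statement = stmt,
      dummyRegistry = do.call(rbind, unname(registry)))
}

#' Strip DUMMY atoms from calculated structures and rename residues
#'
#' Post-calculation clean-up: every DUMMY-typed atom listed in the
#' registry is deleted from every model of a PDB, residue codes are
#' renamed (e.g. CYSX to CYS), and atom serials are repacked.  With an
#' empty registry and an empty rename map the lines pass through
#' byte-identically.
#'
#' @param pdbLines Character vector of PDB lines (possibly multi-model).
#' @param registry data.frame with columns `resIndex`, `resname`, `atom`
#'   (see [dummyRegistry()]).
#' @param rename Named character vector: old residue code -> new code.
#' @return Character vector of the edited PDB lines.
#' @export
finalizeStructure <- function(pdbLines, registry = NULL, rename = c()) {
  if ((is.null(registry) || nrow(registry) == 0) && !length(rename))
    return(pdbLines)
  isAtom <- startsWith(pdbLines, "ATOM") | startsWith(pdbLines, "HETATM")
  aname <- trimws(substr(pdbLines, 13, 16))
  rname <- trimws(substr(pdbLines, 18, 21))
  rno <- suppressWarnings(as.integer(substr(pdbLines, 23, 26)))
  drop <- rep(FALSE, length(pdbLines))
  if (!is.null(registry) && nrow(registry)) {
    for (i in seq_len(nrow(registry))) {
      hit <- isAtom & aname == registry$atom[i] &
        rname == registry$resname[i] & rno == registry$resIndex[i]
      if (!any(hit, na.rm = TRUE))
        stop("registry atom absent from the models: ", registry$atom[i],
             " of ", registry$resname[i], " ", registry$resIndex[i])
      drop <- drop | (hit %in% TRUE)
    }
  }
  out <- pdbLines[!drop]
  if (length(rename)) {
    isAtom2 <- startsWith(out, "ATOM") | startsWith(out, "HETATM")
    rn2 <- trimws(substr(out, 18, 21))
    for (old in names(rename)) {
      hit <- isAtom2 & rn2 == old
      if (any(hit))
        substr(out[hit], 18, 21) <- sprintf("%-4s", rename[[old]])
    }
  }
  # repack atom serials, restarting in each model
  isAtom3 <- startsWith(out, "ATOM") | startsWith(out, "HETATM")
  serial <- 0L
  for (i in seq_along(out)) {
    if (startsWith(out[i], "MODEL")) serial <- 0L
    if (isAtom3[i]) {
      serial <- serial + 1L
      substr(out[i], 7, 11) <- sprintf("%5d", serial)
    }
  }
  out
}
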