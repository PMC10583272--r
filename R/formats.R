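# File dialects: PDB (CONECT-bearing), Mol2, CYANA residue library (.lib),
# CYANA upper-distance restraints (.upl), sequence-file link directive and
# CCD-style component CIF.
#
# The .lib reader keeps every input byte: unmodified entries re-serialise
# exactly; the only editing operation offered is in-place substitution of
# the atom-type column.

.TWO_LETTER_ELEMENTS <- c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "SI")

# element from a PDB atom name / element column
.elementFromPdb <- function(elemCol, name) {
  e <- toupper(trimws(elemCol))
  if (nzchar(e)) return(e)
  nm <- toupper(gsub("[^A-Za-z].*$", "", trimws(name)))
  if (nchar(nm) >= 2 && substr(nm, 1, 2) %in% .TWO_LETTER_ELEMENTS)
    return(substr(nm, 1, 2))
  substr(nm, 1, 1)
}

# typical valences used only for the missing-hydrogen heuristic
.TYPICAL_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, SE = 2)

.checkHydrogens <- function(g) {
  at <- atoms(g); bd <- bonds(g)
  ok <- TRUE
  if (nrow(bd)) {
    val <- setNames(rep(0, nrow(at)), as.character(at$serial))
    for (i in seq_len(nrow(bd))) {
      o <- if (bd$order[i] == 1.5) 1.5 else bd$order[i]
      val[as.character(bd$a[i])] <- val[as.character(bd$a[i])] + o
      val[as.character(bd$b[i])] <- val[as.character(bd$b[i])] + o
    }
    heavy <- toupper(at$element) %in% names(.TYPICAL_VALENCE)
    expect <- .TYPICAL_VALENCE[toupper(at$element[heavy])]
    # order-1-only connectivity (PDB CONECT) cannot distinguish an
    # unsaturated atom from one missing a hydrogen: allow one unit of slack
    slack <- if (all(bd$order == 1)) 1.5 else 0.5
    short <- val[as.character(at$serial[heavy])] < expect - slack
    if (any(short)) {
      ok <- FALSE
      warning("heavy-atom valence check failed for atom(s) ",
              paste(at$serial[heavy][short], collapse = ", "),
              "; input may be missing hydrogens", call. = FALSE)
    }
  }
  ok
}

#' Read a structure file into a MolecularGraph
#'
#' PDB input must carry CONECT records (bond orders default to 1); Mol2
#' input provides bond orders (aromatic bonds become order 1.5).  A
#' heavy-atom valence check warns when hydrogens appear to be missing and
#' records the outcome in the `hydrogensComplete` attribute of the result.
#'
#' @param path File path.
#' @param format "pdb" or "mol2" (default: guessed from the extension).
#' @return A [MolecularGraph-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mol2")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  g <- if (format == "pdb") .readPdbGraph(path) else .readMol2Graph(path)
  attr(g, "hydrogensComplete") <- .checkHydrogens(g)
  g
}

.readPdbGraph <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  lines <- readLines(path)
  conect <- lines[startsWith(lines, "CONECT")]
  if (!length(conect))
    stop("no connectivity: PDB input must carry CONECT records")
  elements <- vapply(seq_len(nrow(at)), function(i)
    .elementFromPdb(if ("elesy" %in% names(at)) at$elesy[i] else "",
                    at$elety[i]), character(1))
  atomsDf <- data.frame(serial = as.integer(at$eleno),
                        name = trimws(at$elety), element = elements,
                        x = at$x, y = at$y, z = at$z,
                        stringsAsFactors = FALSE)
  pairs <- list()
  for (ln in conect) {
    f <- as.integer(substring(ln, seq(7, 27, 5), seq(11, 31, 5)))
    f <- f[!is.na(f)]
    if (length(f) >= 2)
      for (b in f[-1]) pairs[[length(pairs) + 1L]] <- c(f[1], b)
  }
  bd <- unique(do.call(rbind, lapply(pairs, function(p)
    data.frame(a = min(p), b = max(p), order = 1))))
  makeMolecularGraph(atomsDf, bd)
}

.readMol2Graph <- function(path) {
  m <- bio3d::read.mol2(path)
  at <- m$atom
  elements <- toupper(sub("\\..*$", "", at$elety))
  atomsDf <- data.frame(serial = as.integer(at$eleno),
                        name = trimws(at$elena), element = elements,
                        x = at$x, y = at$y, z = at$z,
                        charge = if ("charge" %in% names(at)) at$charge
                                 else NA_real_,
                        stringsAsFactors = FALSE)
  bd <- m$bond
  orderMap <- function(tp) {
    tp <- tolower(trimws(as.character(tp)))
    vapply(tp, function(t) switch(t, "1" = 1, "2" = 2, "3" = 3,
                                  "ar" = 1.5, "am" = 1, "un" = 1, 1),
           numeric(1))
  }
  bondsDf <- data.frame(a = as.integer(bd$origin),
                        b = as.integer(bd$target),
                        order = orderMap(bd$type))
  makeMolecularGraph(atomsDf, bondsDf)
}

#' Write a MolecularGraph as a CONECT-bearing PDB file
#'
#' @param g A [MolecularGraph-class] (pseudoatoms and CIP duplicates are
#'   skipped).
#' @param path Output path.
#' @param resname,resno Residue code and number for the ATOM records.
#' @return Invisibly, the path.
#' @export
writeStructurePdb <- function(g, path, resname = "LIG", resno = 1L) {
  at <- atoms(g)
  at <- at[!at$isPseudo & !at$isDuplicate, , drop = FALSE]
  ser <- setNames(seq_len(nrow(at)), as.character(at$serial))
  fmtName <- function(nm, el) {
    # atom name column 13-16; single-letter elements start in column 14
    if (nchar(el) == 1 && nchar(nm) <= 3) sprintf(" %-3s", nm)
    else sprintf("%-4s", substr(nm, 1, 4))
  }
  lines <- vapply(seq_len(nrow(at)), function(i) {
    sprintf("ATOM  %5d %s %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            ser[[as.character(at$serial[i])]],
            fmtName(at$name[i], at$element[i]), resname, resno,
            at$x[i], at$y[i], at$z[i], toupper(at$element[i]))
  }, character(1))
  bd <- bonds(g)
  bd <- bd[bd$a %in% at$serial & bd$b %in% at$serial, , drop = FALSE]
  nbrs <- split(c(bd$b, bd$a), c(bd$a, bd$b))
  clines <- unlist(lapply(names(nbrs), function(s) {
    ns <- sort(ser[as.character(nbrs[[s]])])
    chunks <- split(ns, ceiling(seq_along(ns) / 4))
    vapply(chunks, function(ch)
      paste0("CONECT", sprintf("%5d", ser[[s]]),
             paste(sprintf("%5d", ch), collapse = "")), character(1))
  }))
  writeLines(c(lines, clines, "END"), path)
  invisible(path)
}

# ---- CYANA residue library ----------------------------------------------

# Tokenise a line, returning value + character start/end positions.
.tokenise <- function(line) {
  m <- gregexpr("\\S+", line)[[1]]
  if (m[1] == -1) return(data.frame(tok = character(), start = integer(),
                                    end = integer()))
  data.frame(tok = regmatches(line, gregexpr("\\S+", line))[[1]],
             start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L,
             stringsAsFactors = FALSE)
}

#' Read a CYANA residue library file
#'
#' The dialect: each entry starts with a `RESIDUE <name> <nAngles>
#' <nAtoms> ...` header, followed by `nAngles` dihedral-angle lines and
#' `nAtoms` atom lines of the form `serial name type q x y z bonded...`.
#' Every raw line is preserved so that [writeLib()] reproduces untouched
#' entries byte for byte.
#'
#' @param path File path.
#' @return A list of [ResidueTemplate-class] objects, named by residue code.
#' @export
readLib <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  heads <- which(grepl("^\\s*RESIDUE\\s", lines))
  if (!length(heads)) stop("no RESIDUE header found in ", path)
  out <- list()
  for (hi in seq_along(heads)) {
    h <- heads[hi]
    pre <- if (hi == 1 && h > 1) lines[seq_len(h - 1)] else
      if (hi > 1) {
        prevEnd <- attr(out[[hi - 1]], "lastLine")
        if (h - 1 >= prevEnd + 1) lines[(prevEnd + 1):(h - 1)] else character()
      } else character()
    tk <- .tokenise(lines[h])
    if (nrow(tk) < 4)
      stop("malformed RESIDUE header at line ", h)
    name <- tk$tok[2]
    counts <- suppressWarnings(as.integer(tk$tok[3:nrow(tk)]))
    if (anyNA(counts[1:2]))
      stop("malformed RESIDUE header counts at line ", h)
    nAngles <- counts[1]; nAtomRecords <- counts[2]
    need <- h + nAngles + nAtomRecords
    if (need > length(lines))
      stop("truncated entry '", name, "': expected records through line ",
           need, " but file ends at line ", length(lines))
    angleLines <- if (nAngles) lines[(h + 1):(h + nAngles)] else character()
    atomLines <- if (nAtomRecords)
      lines[(h + nAngles + 1):(h + nAngles + nAtomRecords)] else character()
    rows <- lapply(seq_along(atomLines), function(i) {
      ln <- atomLines[i]
      t2 <- .tokenise(ln)
      if (nrow(t2) < 7)
        stop("malformed atom record at line ", h + nAngles + i,
             " of entry '", name, "'")
      serial <- suppressWarnings(as.integer(t2$tok[1]))
      xyz <- suppressWarnings(as.numeric(t2$tok[5:7]))
      if (is.na(serial) || anyNA(xyz))
        stop("unparseable atom record at line ", h + nAngles + i)
      bonded <- if (nrow(t2) > 7)
        suppressWarnings(as.integer(t2$tok[8:nrow(t2)])) else integer()
      data.frame(serial = serial, name = t2$tok[2], type = t2$tok[3],
                 x = xyz[1], y = xyz[2], z = xyz[3],
                 bonded = I(list(bonded[!is.na(bonded)])),
                 raw = ln, typeStart = t2$start[3], typeEnd = t2$end[3],
                 stringsAsFactors = FALSE)
    })
    atomTable <- do.call(rbind, rows)
    if (is.null(atomTable))
      atomTable <- data.frame(serial = integer(), name = character(),
                              type = character(), x = numeric(),
                              y = numeric(), z = numeric(),
                              bonded = I(list()), raw = character(),
                              typeStart = integer(), typeEnd = integer())
    tmpl <- new("ResidueTemplate", name = name, headerLine = lines[h],
                angleLines = angleLines, atomTable = atomTable,
                headerCounts = counts[!is.na(counts)])
    attr(tmpl, "preLines") <- pre
    attr(tmpl, "lastLine") <- need
    out[[hi]] <- tmpl
  }
  names(out) <- vapply(out, function(t) t@name, character(1))
  out
}

#' Serialise residue templates to a CYANA library file
#'
#' @param templates A [ResidueTemplate-class] or list thereof.
#' @param path Output path (`NULL` returns the lines invisibly).
#' @return Invisibly, the character vector written.
#' @export
writeLib <- function(templates, path = NULL) {
  if (is(templates, "ResidueTemplate")) templates <- list(templates)
  lines <- unlist(lapply(templates, function(t) {
    pre <- attr(t, "preLines")
    c(if (!is.null(pre)) pre, t@headerLine, t@angleLines, t@atomTable$raw)
  }))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Substitute the atom-type code of named atoms, in place
#'
#' Edits only the type-code column of the raw atom records; when the new
#' code is shorter than the old one it is padded with spaces so that the
#' remaining bytes of the line are untouched.
#'
#' @param template A [ResidueTemplate-class].
#' @param atomNames Character vector of atom names to retype.
#' @param newType Replacement type-code string.
#' @return The modified [ResidueTemplate-class].
#' @export
setAtomType <- function(template, atomNames, newType) {
  tb <- template@atomTable
  idx <- match(atomNames, tb$name)
  if (anyNA(idx))
    stop("atom(s) not in template '", template@name, "': ",
         paste(atomNames[is.na(idx)], collapse = ", "))
  for (i in idx) {
    old <- tb$type[i]
    if (identical(old, newType)) next
    width <- max(nchar(newType), nchar(old))
    padded <- formatC(newType, width = -width)
    raw <- tb$raw[i]
    tb$raw[i] <- paste0(substr(raw, 1, tb$typeStart[i] - 1L), padded,
                        substring(raw, tb$typeEnd[i] + 1L))
    tb$type[i] <- newType
    tb$typeEnd[i] <- tb$typeStart[i] + nchar(padded) - 1L
  }
  template@atomTable <- tb
  template
}

#' Convert a MolecularGraph to a residue library template
#'
#' Renders the graph as a library entry (no dihedral-angle records) using
#' element-based default type codes; pseudoatoms get the PSEUDO code.
#' Useful for building extended link templates programmatically.
#'
#' @param g A [MolecularGraph-class]; atom names are used as-is.
#' @param name Residue code for the entry.
#' @param typeMap Named character vector mapping element symbol to type
#'   code; elements missing from the map fall back to `<EL>_ALI`.
#' @param pseudoType Type code for pseudoatoms.
#' @return A [ResidueTemplate-class].
#' @export
graphToTemplate <- function(g, name,
                            typeMap = c(C = "C_ALI", H = "H_ALI",
                                        N = "N_AMI", O = "O_BYL",
                                        S = "S_RED"),
                            pseudoType = "PSEUD") {
  at <- atoms(g)
  at <- at[!at$isDuplicate, , drop = FALSE]
  ser <- setNames(seq_len(nrow(at)), as.character(at$serial))
  adj <- .adjacency(g)
  rows <- lapply(seq_len(nrow(at)), function(i) {
    el <- toupper(at$element[i])
    type <- if (at$isPseudo[i]) pseudoType
            else if (el %in% names(typeMap)) typeMap[[el]]
            else paste0(el, "_ALI")
    bnd <- sort(unname(ser[as.character(
      intersect(adj[[as.character(at$serial[i])]], at$serial))]))
    raw <- sprintf("%5d %-5s %-6s %8.4f %9.3f %9.3f %9.3f %s",
                   i, at$name[i], type, 0,
                   at$x[i], at$y[i], at$z[i],
                   paste(sprintf("%5d", if (length(bnd)) bnd else 0L),
                         collapse = ""))
    tk <- .tokenise(raw)
    data.frame(serial = i, name = at$name[i], type = type,
               x = at$x[i], y = at$y[i], z = at$z[i],
               bonded = I(list(bnd)), raw = raw,
               typeStart = tk$start[3], typeEnd = tk$end[3],
               stringsAsFactors = FALSE)
  })
  atomTable <- do.call(rbind, rows)
  header <- sprintf("RESIDUE %-5s %4d %4d %4d %4d", name, 0L,
                    nrow(atomTable), 1L, nrow(atomTable))
  new("ResidueTemplate", name = name, headerLine = header,
      angleLines = character(), atomTable = atomTable,
      headerCounts = c(0L, nrow(atomTable), 1L, nrow(atomTable)))
}

# ---- restraints and link statements --------------------------------------

#' Write upper-distance restraints (.upl)
#'
#' Fixed-width columns: residue index, residue name, atom name (twice),
#' the distance limit with two decimals, and the weight either as a bare
#' trailing numeric column (default) or as a `weight := w` option.
#'
#' @param restraints data.frame with columns `resI`, `resnameI`, `atomI`,
#'   `resJ`, `resnameJ`, `atomJ`, `limit`, `weight`.
#' @param path Output path.
#' @param weightStyle "column" (bare trailing numeric) or "option"
#'   (`weight := w`).
#' @return Invisibly, the lines written.
#' @export
writeUpl <- function(restraints, path, weightStyle = c("column", "option")) {
  weightStyle <- match.arg(weightStyle)
  if (nrow(restraints) && any(restraints$limit <= 0))
    stop("upper-distance limits must be larger than 0")
  lines <- if (!nrow(restraints)) character() else
    vapply(seq_len(nrow(restraints)), function(i) {
      r <- restraints[i, ]
      base <- sprintf("%4d %-5s %-5s %4d %-5s %-5s %8.2f",
                      r$resI, r$resnameI, r$atomI,
                      r$resJ, r$resnameJ, r$atomJ, r$limit)
      if (weightStyle == "column")
        paste0(base, sprintf(" %8.2f", r$weight))
      else paste0(base, sprintf("  weight := %.2f", r$weight))
    }, character(1))
  writeLines(lines, path)
  invisible(lines)
}

#' Read a .upl file written with the bare-column weight style
#'
#' @param path File path.
#' @return data.frame in the layout accepted by [writeUpl()].
#' @export
readUpl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(resI = integer(), resnameI = character(),
                      atomI = character(), resJ = integer(),
                      resnameJ = character(), atomJ = character(),
                      limit = numeric(), weight = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(lines, function(ln) {
    tk <- .tokenise(ln)$tok
    if (length(tk) < 7) stop("malformed restraint line: ", ln)
    data.frame(resI = as.integer(tk[1]), resnameI = tk[2], atomI = tk[3],
               resJ = as.integer(tk[4]), resnameJ = tk[5], atomJ = tk[6],
               limit = as.numeric(tk[7]),
               weight = if (length(tk) >= 8) as.numeric(tk[8]) else 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a sequence-file link statement
#'
#' Produces the directive that removes the repulsion term between the two
#' linking-bond atoms.  The exact syntax is dialect-dependent; the default
#' dialect writes `link <atomI> <resI> <atomJ> <resJ>`.
#'
#' @param stmt Named list with `atomI`, `resI`, `atomJ`, `resJ` and
#'   optionally `dialect`.
#' @param path Output path (`NULL` returns the line).
#' @return Invisibly, the line written.
#' @export
writeLinkStatement <- function(stmt, path = NULL) {
  dialect <- if (!is.null(stmt$dialect)) stmt$dialect else "link"
  line <- sprintf("%s %s %d %s %d", dialect, stmt$atomI,
                  as.integer(stmt$resI), stmt$atomJ, as.integer(stmt$resJ))
  if (!is.null(path)) writeLines(line, path)
  invisible(line)
}

# ---- component CIF -------------------------------------------------------

.CIF_BOND_ORDER <- c(`1` = "SING", `2` = "DOUB", `3` = "TRIP",
                     `1.5` = "AROM")

#' Write an excised residue as a CCD-style chemical component
#'
#' Emits `_chem_comp_atom` (name, element, model coordinates) and
#' `_chem_comp_bond` (names, order) loops.  The backbone atoms must be
#' named N, CA, C, O.
#'
#' @param residue A [MolecularGraph-class] whose atom names are the final
#'   (renamed) names.
#' @param path Output path.
#' @param compId Component identifier (default "UNL").
#' @return Invisibly, the path.
#' @export
writeComponentCif <- function(residue, path, compId = "UNL") {
  at <- atoms(residue)
  at <- at[!at$isPseudo & !at$isDuplicate, , drop = FALSE]
  if (any(is.na(at$name) | !nzchar(trimws(at$name))))
    stop("unnamed atoms: run the renamer before writing a component")
  if (!all(c("N", "CA", "C", "O") %in% trimws(at$name)))
    stop("residue missing backbone atoms N, CA, C, O")
  nameOf <- setNames(trimws(at$name), as.character(at$serial))
  hdr <- c(sprintf("data_%s", compId), "#",
           sprintf("_chem_comp.id %s", compId),
           sprintf("_chem_comp.type \"L-PEPTIDE LINKING\""), "#",
           "loop_", "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
           "_chem_comp_atom.type_symbol", "_chem_comp_atom.model_Cartn_x",
           "_chem_comp_atom.model_Cartn_y", "_chem_comp_atom.model_Cartn_z")
  atomLoop <- vapply(seq_len(nrow(at)), function(i)
    sprintf("%s %-5s %-2s %9.3f %9.3f %9.3f", compId, at$name[i],
            toupper(at$element[i]), at$x[i], at$y[i], at$z[i]),
    character(1))
  bd <- bonds(residue)
  bd <- bd[bd$a %in% at$serial & bd$b %in% at$serial, , drop = FALSE]
  bondHdr <- c("#", "loop_", "_chem_comp_bond.comp_id",
               "_chem_comp_bond.atom_id_1", "_chem_comp_bond.atom_id_2",
               "_chem_comp_bond.value_order")
  bondLoop <- if (nrow(bd)) vapply(seq_len(nrow(bd)), function(i)
    sprintf("%s %-5s %-5s %s", compId, nameOf[[as.character(bd$a[i])]],
            nameOf[[as.character(bd$b[i])]],
            .CIF_BOND_ORDER[[as.character(bd$order[i])]]), character(1))
    else character()
  writeLines(c(hdr, atomLoop, bondHdr, bondLoop, "#"), path)
  invisible(path)
}
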