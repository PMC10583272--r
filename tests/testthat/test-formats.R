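test_that("structure readers resolve elements, bonds and hydrogens", {
  f <- tempfile(fileext = ".mol2")
  writeLines(ethanolMol2Lines(), f)
  g <- readStructure(f)
  expect_equal(nAtoms(g), 9L)
  expect_equal(nBonds(g), 8L)
  expect_equal(sum(atoms(g)$element == "O"), 1L)
  expect_true(attr(g, "hydrogensComplete"))

  p <- tempfile(fileext = ".pdb")
  cys <- makeFixture("CYS")
  writeStructurePdb(cys, p, resname = "CYS")
  g2 <- readStructure(p)
  expect_equal(nAtoms(g2), nAtoms(cys))
  expect_equal(nBonds(g2), nBonds(cys))
  # renaming the re-read graph reproduces the side-chain names
  expect_setequal(subset(nameMap(renameResidue(g2)),
                         kind == "sidechain")$newName, c("CB", "SG"))

  # PDB without CONECT is a hard error
  noc <- readLines(p)
  writeLines(noc[!startsWith(noc, "CONECT")], p)
  expect_error(readStructure(p), "no connectivity")

  # stripped hydrogens trip the valence check
  p2 <- tempfile(fileext = ".pdb")
  writeStructurePdb(heavyAtomSubgraph(cys), p2, resname = "CYS")
  expect_warning(g3 <- readStructure(p2), "missing hydrogens")
  expect_false(attr(g3, "hydrogensComplete"))
})

test_that("library entries round-trip byte-identically", {
  tmpl <- makeExtendedTemplate("CYSX")
  f <- tempfile(fileext = ".lib")
  writeLib(tmpl, f)
  ref <- readLines(f)
  lib <- readLib(f)
  expect_named(lib, "CYSX")
  f2 <- tempfile(fileext = ".lib")
  writeLib(lib, f2)
  expect_identical(readLines(f2), ref)

  # pseudoatom records carry the PSEUDO type code
  tb <- atomTable(lib$CYSX)
  expect_setequal(tb$name[tb$type == "PSEUD"], c("QB", "QE"))

  # multiple entries round-trip too
  f3 <- tempfile(fileext = ".lib")
  writeLib(list(makeExtendedTemplate("VAN5"), makeExtendedTemplate("VAN7")),
           f3)
  lib3 <- readLib(f3)
  expect_named(lib3, c("VAN5", "VAN7"))
  f4 <- tempfile(fileext = ".lib")
  writeLib(lib3, f4)
  expect_identical(readLines(f4), readLines(f3))

  # truncation errors carry a line number
  writeLines(ref[1:4], f)
  expect_error(readLib(f), "line")
})

test_that("restraint and link-statement writers use the documented layout", {
  r <- data.frame(resI = 3L, resnameI = "CYSX", atomI = "SD",
                  resJ = 12L, resnameJ = "CYSX", atomJ = "SG",
                  limit = 0.04, weight = 10)
  f <- tempfile(fileext = ".upl")
  lines <- writeUpl(r, f)
  expect_match(lines, "0\\.04")
  expect_match(lines, "10")
  back <- readUpl(f)
  expect_equal(back$limit, r$limit)
  expect_equal(back$weight, r$weight)

  # option-style weight
  writeUpl(r, f, weightStyle = "option")
  expect_match(readLines(f), "weight := 10")

  # empty list -> empty file
  writeUpl(r[0, ], f)
  expect_equal(length(readLines(f)), 0L)

  # a limit of zero is rejected
  r0 <- r; r0$limit <- 0
  expect_error(writeUpl(r0, f), "larger than 0")

  s <- writeLinkStatement(list(atomI = "SG", resI = 3, atomJ = "SG",
                               resJ = 12))
  expect_equal(s, "link SG 3 SG 12")
})

test_that("component CIF writer emits CCD-style atom and bond loops", {
  tpl <- makeFixture("capped-ALA")
  ex <- exciseResidue(tpl, classifyTemplate(tpl))
  f <- tempfile(fileext = ".cif")
  writeComponentCif(ex$graph, f, compId = "ALA")
  lines <- readLines(f)
  expect_true(any(startsWith(lines, "data_ALA")))
  expect_true(any(grepl("_chem_comp_atom.atom_id", lines)))
  expect_true(any(grepl("_chem_comp_bond.value_order", lines)))
  expect_true(any(grepl("ALA CA", lines)))
  for (nm in c("N", "CA", "C", "O", "CB"))
    expect_true(any(grepl(paste0("^ALA ", nm, " "), lines)), info = nm)

  # cross-module consistency: excised ornithine names match the renamer
  torn <- makeFixture("capped-ornithine")
  exo <- exciseResidue(torn, classifyTemplate(torn))
  f2 <- tempfile(fileext = ".cif")
  writeComponentCif(exo$graph, f2, compId = "ORN")
  cif <- readLines(f2)
  for (nm in c("CB", "CG", "CD", "NE"))
    expect_true(any(grepl(paste0("^ORN ", nm, " "), cif)), info = nm)

  # unnamed atoms / missing backbone are rejected
  expect_error(writeComponentCif(makeFixture("ethanol"), f),
               "backbone|unnamed")
})

test_that("atom-type substitution touches only the type column", {
  tmpl <- makeExtendedTemplate("CYSX")
  mod <- setAtomType(tmpl, c("SD", "CE"), "DUMMY")
  raw0 <- tmpl@atomTable$raw
  raw1 <- mod@atomTable$raw
  changed <- which(raw0 != raw1)
  expect_equal(mod@atomTable$name[changed], c("SD", "CE"))
  for (i in changed) {
    st <- tmpl@atomTable$typeStart[i]
    en <- max(tmpl@atomTable$typeEnd[i], mod@atomTable$typeEnd[i])
    expect_identical(substr(raw0[i], 1, st - 1), substr(raw1[i], 1, st - 1))
    expect_identical(substring(raw0[i], en + 1), substring(raw1[i], en + 1))
  }
  expect_error(setAtomType(tmpl, "NOPE", "DUMMY"), "not in template")
})
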