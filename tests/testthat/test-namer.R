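test_that("position labels follow the transliterated Greek scheme", {
  expect_equal(positionLabel(1), "B")
  expect_equal(positionLabel(2), "G")
  expect_equal(positionLabel(14), "O")
  expect_equal(positionLabel(23), "W")
  expect_equal(positionLabel(24), "AA")
  expect_equal(positionLabel(599), "WW")
  expect_error(positionLabel(0), "between 1 and 599")
  expect_error(positionLabel(600), "between 1 and 599")
  labs <- positionLabels()
  expect_equal(length(labs), 600L)
  expect_equal(anyDuplicated(labs), 0L)   # bijective
  expect_equal(labs[1], "A")
  expect_equal(min(which(nchar(labs) == 2)), 25L)
})

test_that("CIP comparison ranks heavier and deeper-substituted branches first", {
  # O-branch beats C-branch at the same distance (atomic number first)
  ovc <- makeFixture("OVC")
  bb <- findBackbone(ovc)
  ex <- expandUnsaturation(heavyAtomSubgraph(ovc))
  at <- atoms(ovc)
  s <- function(nm) at$serial[at$name == nm]
  # -CH2-OH vs -CH2-CH3 resolves at sphere 2 in favour of the OH branch
  expect_equal(cipCompare(ex, s("CG1"), s("CG2"), s("CB")), "a_first")
  expect_equal(cipCompare(ex, s("CG2"), s("CG1"), s("CB")), "b_first")

  # valine's two methyls are an exact tie
  val <- makeFixture("VAL")
  atv <- atoms(val)
  exv <- expandUnsaturation(heavyAtomSubgraph(val))
  sv <- function(nm) atv$serial[atv$name == nm]
  expect_equal(cipCompare(exv, sv("CG1"), sv("CG2"), sv("CB")), "tie")
})

test_that("chain assignment handles rings, branches and symmetry", {
  # phenylalanine: ring closure joins chains 1 and 2 and takes chain 1
  phe <- makeFixture("PHE")
  a <- assignChains(phe, findBackbone(phe))
  at <- atoms(phe)
  tb <- a@table
  czRow <- tb[tb$serial == at$serial[at$name == "CZ"], ]
  expect_equal(czRow$distance, 5L)
  expect_equal(czRow$chain, 1L)
  expect_equal(czRow$resolvedBy, "ring-join")

  # valine: methyls resolved geometrically; mirror swaps them
  val <- makeFixture("VAL")
  tv <- assignChains(val, findBackbone(val))@table
  g12 <- tv[tv$distance == 2, ]
  expect_setequal(g12$chain, c(1L, 2L))
  expect_true(all(g12$resolvedBy == "geometric"))
  tm <- assignChains(mirrorGraph(val), findBackbone(val))@table
  m12 <- tm[tm$distance == 2, ]
  expect_equal(m12$chain[order(m12$serial)],
               rev(g12$chain[order(g12$serial)]))

  # duplicated phenyl rings get consecutive chain blocks after the
  # symmetry re-pass: {1,2} and {3,4}, never {1,3}/{2,4}
  dph <- makeFixture("DPH")
  td <- assignChains(dph, findBackbone(dph))@table
  d3 <- sort(td$chain[td$distance == 3])
  expect_equal(d3, 1:4)
  # each ring's two chains are consecutive
  joins <- td[td$resolvedBy == "ring-join", ]
  expect_equal(sort(joins$chain), c(1L, 3L))

  # disconnected atom errors
  iso <- makeFixture("CYS")
  at2 <- rbind(atoms(iso),
               data.frame(serial = 99L, name = "XX", element = "C",
                          x = 9, y = 9, z = 9, isPseudo = FALSE,
                          isDuplicate = FALSE, charge = NA_real_))
  expect_error(assignChains(new("MolecularGraph", atoms = at2,
                                bonds = bonds(iso), netCharge = NA_real_),
                            findBackbone(iso)),
               "disconnected")
})

test_that("name generation applies the sole-occupant and hydrogen rules", {
  cys <- renameResidue(makeFixture("CYS"))
  side <- subset(nameMap(cys), kind == "sidechain")
  expect_setequal(side$newName, c("CB", "SG"))
  hyd <- subset(nameMap(cys), kind == "hydrogen")
  expect_setequal(hyd$newName, c("HB2", "HB3", "HG"))

  ser <- renameResidue(makeFixture("SER"))
  expect_true("OG" %in% nameMap(ser)$newName)   # sole occupant, no number

  # two-occupant shells keep their numbers
  thr <- renameResidue(makeFixture("THR"))
  expect_true(all(c("OG1", "CG2") %in% nameMap(thr)$newName))

  # cysteine beta hydrogens flip when all coordinates are mirrored
  g <- makeFixture("CYS")
  n1 <- nameVec(renameResidue(g))
  n2 <- nameVec(renameResidue(mirrorGraph(g)))
  flipped <- names(n1)[n1 != n2]
  expect_setequal(unname(n1[flipped]), c("HB2", "HB3"))

  # pseudoatom names cover multi-hydrogen groups
  ile <- renameResidue(makeFixture("ILE"))
  expect_true(all(c("QG2", "QD") %in% ile@pseudoatoms$name))

  # sticky-suffix option keeps the chain number downstream of a branch
  ileS <- renameResidue(makeFixture("ILE"), stickySuffix = TRUE)
  expect_true("CD1" %in% nameMap(ileS)$newName)
  expect_false("CD1" %in% nameMap(ile)$newName)
  # ... but not after a ring join (phenylalanine zeta carbon stays CZ)
  pheS <- renameResidue(makeFixture("PHE"), stickySuffix = TRUE)
  expect_true("CZ" %in% nameMap(pheS)$newName)
})

test_that("the full renamer matches published nomenclature and is invariant", {
  ref <- referenceNomenclature()
  geomResidues <- c("VAL", "LEU")   # heavy branches decided by geometry
  for (code in names(ref$names)) {
    g <- makeFixture(code)
    r <- renameResidue(g)
    got <- subset(nameMap(r), kind == "sidechain")
    expect_equal(anyDuplicated(nameMap(r)$newName), 0L, info = code)
    expected <- ref$names[[code]]
    dev <- subset(ref$deviations, residue == code)
    for (i in seq_len(nrow(dev)))
      expected[expected == dev$reference[i]] <- dev$emitted[i]
    expect_setequal(got$newName, expected)
    if (!code %in% geomResidues && length(expected)) {
      at <- atoms(g)
      byFixtureName <- setNames(got$newName,
                                at$name[match(got$serial, at$serial)])
      # per-atom identity with the reference table (fixture names are the
      # reference names), after the deviation mapping
      for (nm in names(byFixtureName)) {
        want <- nm
        hit <- dev$reference == nm
        if (any(hit)) want <- dev$emitted[hit][1]
        expect_equal(unname(byFixtureName[[nm]]), want, info = code)
      }
    }
  }

  # ornithine: CB, CG, CD, NE plus numbered methylene hydrogens
  orn <- renameResidue(makeFixture("ORN"))
  expect_setequal(subset(nameMap(orn), kind == "sidechain")$newName,
                  c("CB", "CG", "CD", "NE"))
  expect_true(all(c("HB2", "HB3", "HG2", "HG3", "HD2", "HD3") %in%
                  nameMap(orn)$newName))

  # permutation invariance of the complete naming
  for (code in c("ALA", "TRP", "ILE", "GLY")) {
    g <- makeFixture(code)
    n1 <- nameMap(renameResidue(g))
    for (s in 1:10) {
      p <- permuteAtoms(g, s)
      n2 <- nameVec(renameResidue(p$graph))
      m1 <- setNames(n1$newName, p$serialMap[as.character(n1$serial)])
      m1 <- m1[order(as.integer(names(m1)))]
      expect_identical(unname(m1), unname(n2), info = paste(code, s))
    }
  }

  # rigid-motion invariance
  for (code in c("VAL", "TRP")) {
    g <- makeFixture(code)
    n1 <- nameVec(renameResidue(g))
    for (s in 1:5)
      expect_identical(nameVec(renameResidue(rigidMotion(g, s))), n1,
                       info = paste(code, s))
  }

  # d-amino acid: heavy names unchanged, prochiral H numbers swapped
  for (code in c("CYS", "ORN", "LYS")) {
    g <- makeFixture(code)
    n1 <- nameVec(renameResidue(g))
    n2 <- nameVec(renameResidue(mirrorGraph(g)))
    changed <- names(n1)[n1 != n2]
    expect_true(all(grepl("^H", n1[changed])), info = code)
    expect_setequal(unname(n1[changed]), unname(n2[changed]))
  }
})

test_that("renamer agrees with the brute-force CIP oracle", {
  ref <- referenceNomenclature()
  corpus <- c(setdiff(names(ref$names), "GLY"),
              "ORN", "AIB", "OVC", "DPH", "NAP")
  for (code in corpus) {
    g <- makeFixture(code)
    bb <- findBackbone(g)
    a1 <- assignChains(g, bb)@table
    a2 <- bruteForceCip(g, bb)@table
    expect_identical(a1[, c("serial", "distance", "chain")],
                     a2[, c("serial", "distance", "chain")], info = code)
  }
  for (s in 1:200) {
    g <- makeFixture(fixtureSpec("random-tree", seed = s,
                                 nHeavy = 3 + (s %% 14)))
    bb <- findBackbone(g)
    a1 <- assignChains(g, bb)@table
    a2 <- bruteForceCip(g, bb)@table
    expect_identical(a1[, c("serial", "distance", "chain")],
                     a2[, c("serial", "distance", "chain")],
                     info = paste("seed", s))
  }
})
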