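test_that("heavy-atom subgraph strips hydrogens and keeps serials", {
  g <- makeFixture("methane")
  h <- heavyAtomSubgraph(g)
  expect_equal(nAtoms(h), 1L)
  expect_equal(atoms(h)$element, "C")

  cys <- makeFixture("CYS")
  hc <- heavyAtomSubgraph(cys)
  expect_true(all(toupper(atoms(hc)$element) != "H"))
  expect_true(all(atoms(hc)$serial %in% atoms(cys)$serial))
  # the side chain reduces to the chain CA-CB-SG
  bb <- findBackbone(cys)
  d <- bondDistances(subgraphBySerial(hc,
         setdiff(atoms(hc)$serial, c(bb[["n"]], bb[["c"]]))), bb[["ca"]])
  expect_equal(sort(unname(d)), c(0L, 1L, 2L))

  eth <- makeFixture("ethene")
  he <- heavyAtomSubgraph(eth)
  expect_equal(nAtoms(he), 2L)
  expect_equal(bonds(he)$order, 2)
})

test_that("unsaturation expansion adds duplicate leaves on both ends", {
  eth <- heavyAtomSubgraph(makeFixture("ethene"))
  ex <- expandUnsaturation(eth)
  expect_equal(nAtoms(ex), 4L)
  dups <- atoms(ex)[atoms(ex)$isDuplicate, ]
  expect_equal(nrow(dups), 2L)
  expect_equal(unique(dups$element), "C")
  # duplicates are leaves
  deg <- table(factor(c(bonds(ex)$a, bonds(ex)$b),
                      levels = atoms(ex)$serial))
  expect_true(all(deg[as.character(dups$serial)] == 1L))

  # carbonyl: C gains an O duplicate, O gains a C duplicate
  b <- makeMolecularGraph(
    data.frame(serial = 1:2, element = c("C", "O"),
               x = c(0, 1.23), y = 0, z = 0),
    data.frame(a = 1, b = 2, order = 2))
  ec <- expandUnsaturation(b)
  dd <- atoms(ec)[atoms(ec)$isDuplicate, ]
  hostOf <- vapply(dd$serial, function(s) {
    bd <- bonds(ec); c(bd$a[bd$b == s], bd$b[bd$a == s])
  }, integer(1))
  expect_equal(dd$element[hostOf == 1], "O")
  expect_equal(dd$element[hostOf == 2], "C")

  # benzene: exactly one duplicate C per ring carbon (Kekule-free)
  bz <- heavyAtomSubgraph(makeFixture("benzene"))
  eb <- expandUnsaturation(bz)
  expect_equal(sum(atoms(eb)$isDuplicate), 6L)
  expect_equal(unique(atoms(eb)$element[atoms(eb)$isDuplicate]), "C")

  # expansion never changes distances between original atoms
  phe <- heavyAtomSubgraph(makeFixture("PHE"))
  ep <- expandUnsaturation(phe)
  d0 <- bondDistances(phe, atoms(phe)$serial[1])
  d1 <- bondDistances(ep, atoms(phe)$serial[1])
  expect_equal(d0, d1[names(d0)])

  bad <- makeMolecularGraph(
    data.frame(serial = 1:2, element = c("C", "C"), x = c(0, 1), y = 0,
               z = 0),
    data.frame(a = 1, b = 2, order = 1))
  bad@bonds$order <- 4
  expect_error(expandUnsaturation(bad), "unknown bond order")
})

test_that("bond distances are BFS shortest paths", {
  chain <- makeMolecularGraph(
    data.frame(serial = 1:3, element = "C", x = 0:2, y = 0, z = 0),
    data.frame(a = 1:2, b = 2:3))
  expect_equal(bondDistances(chain, 1),
               c(`1` = 0L, `2` = 1L, `3` = 2L))
  expect_error(bondDistances(chain, 99), "unknown source")

  # phenylalanine ring-closure carbon sits 5 bonds from CA
  phe <- makeFixture("PHE")
  bb <- findBackbone(phe)
  cz <- atoms(phe)$serial[atoms(phe)$name == "CZ"]
  d <- bondDistances(heavyAtomSubgraph(phe), bb[["ca"]])
  expect_equal(unname(d[as.character(cz)]), 5L)

  # disconnected atoms are absent
  iso <- makeMolecularGraph(
    data.frame(serial = 1:3, element = "C", x = 0:2, y = 0, z = 0),
    data.frame(a = 1, b = 2))
  expect_false("3" %in% names(bondDistances(iso, 1)))

  # invariance under permutation
  g <- makeFixture("TRP")
  p <- permuteAtoms(g, 7)
  d1 <- bondDistances(g, bb <- findBackbone(g)[["ca"]])
  d2 <- bondDistances(p$graph, p$serialMap[[as.character(bb)]])
  expect_equal(unname(sort(d1)), unname(sort(d2)))
})

test_that("chirality sign follows the determinant convention", {
  # canonical row order on a unit tetrahedron
  s <- chiralitySign(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0), c(0, 0, 1))
  expect_true(s %in% c(-1, 1))
  # swapping the compared atoms flips the sign
  expect_equal(chiralitySign(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0),
                             c(0, 0, 1)), -s)
  # mirroring flips the sign
  expect_equal(chiralitySign(c(-1, 0, 0), c(0, 1, 0), c(0, 0, 0),
                             c(0, 0, 1)), -s)
  # invariant under rigid motion (random rotations + translations)
  for (seed in 1:20) {
    set.seed(seed)
    th <- runif(1, 0, 2 * pi); ax <- c(0, 0, 1)
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
    t0 <- runif(3, -10, 10)
    mv <- function(p) as.numeric(R %*% p + t0)
    expect_equal(chiralitySign(mv(c(1, 0, 0)), mv(c(0, 1, 0)),
                               mv(c(0, 0, 0)), mv(c(0, 0, 1))), s)
  }
  # coplanar points are degenerate
  expect_error(chiralitySign(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0),
                             c(1, 1, 0)), "degenerate")
})

test_that("backbone location works by name and by subgraph match", {
  gly <- makeFixture("GLY")
  bb <- findBackbone(gly)
  at <- atoms(gly)
  expect_equal(at$name[match(bb, at$serial)], c("N", "CA", "C", "O"))

  # scrambled names, same bonds: identical result
  ala <- makeFixture("ALA")
  bb1 <- findBackbone(ala)
  at2 <- atoms(ala); at2$name <- paste0("X", seq_len(nrow(at2)))
  scr <- makeMolecularGraph(at2, bonds(ala))
  expect_equal(unname(findBackbone(scr)), unname(bb1))

  expect_error(findBackbone(makeFixture("ethanol")), "no backbone motif")
  # ambiguity without a residue selector
  expect_error(findBackbone(makeFixture("capped-ALA")), "multiple")
  expect_silent(findBackbone(makeFixture("capped-ALA"), residue = 2))
})
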