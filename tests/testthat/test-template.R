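test_that("capped templates are classified by their cap pattern", {
  cls <- classifyTemplate(makeFixture("capped-ornithine"))
  expect_equal(cls@kind, "internal")
  expect_setequal(names(cls@capAtoms), c("ace", "ala_n", "ala_c", "nme"))

  expect_equal(classifyTemplate(makeFixture("nterm-ALA"))@kind,
               "n_terminal")
  expect_equal(classifyTemplate(makeFixture("cterm-GLU"))@kind,
               "c_terminal")
  # a free residue is not a template
  expect_equal(classifyTemplate(makeFixture("ALA"))@kind, "not_template")
  expect_equal(classifyTemplate(makeFixture("ethanol"))@kind,
               "not_template")

  # caps and X partition the molecule
  g <- makeFixture("capped-TRP")
  cls2 <- classifyTemplate(g)
  all2 <- c(unlist(cls2@capAtoms), cls2@xAtoms)
  expect_setequal(all2, atoms(g)$serial)
  expect_equal(anyDuplicated(all2), 0L)

  # invariant under atom permutation
  p <- permuteAtoms(g, 11)
  cls3 <- classifyTemplate(p$graph)
  expect_equal(cls3@kind, "internal")
  expect_setequal(cls3@xAtoms,
                  unname(p$serialMap[as.character(cls2@xAtoms)]))
})

test_that("excision produces a named residue with attachment points", {
  g <- makeFixture("capped-ALA")
  ex <- exciseResidue(g, classifyTemplate(g))
  nm <- atoms(ex$graph)$name
  expect_setequal(nm, c("N", "H", "CA", "HA", "CB", "HB1", "HB2", "HB3",
                        "C", "O"))
  expect_equal(length(attr(ex$graph, "attachments")), 2L)

  # C-terminal template keeps both carboxyl oxygens, one attachment
  gc <- makeFixture("cterm-GLU")
  exc <- exciseResidue(gc, classifyTemplate(gc))
  expect_true(all(c("O", "OXT") %in% atoms(exc$graph)$name))
  expect_equal(names(attr(exc$graph, "attachments")), "n_side")

  # N-methylated X (sarcosine): no amide H, N keeps its methyl as CN
  gs <- makeFixture("capped-SAR")
  exs <- exciseResidue(gs, classifyTemplate(gs))
  nms <- atoms(exs$graph)$name
  expect_true("CN" %in% nms)
  expect_false("H" %in% nms)
  expect_true(all(c("HN1", "HN2", "HN3") %in% nms))

  # excised atoms plus caps reassemble the input
  cls <- classifyTemplate(g)
  expect_setequal(c(unlist(cls@capAtoms), atoms(ex$graph)$serial),
                  atoms(g)$serial)

  expect_error(exciseResidue(g, classifyTemplate(makeFixture("ALA"))),
               "not a recognised template")
})
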