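test_that("CNS patching retains the backbone and conserves charge", {
  bb <- cnsBackboneTable()
  topo <- cnsToyTopology(netCharge = 0)
  blk <- buildCnsPatch(topo, bb)
  a <- blk@atoms
  # the printed retained list: N, HN, CA, HA, CB, O - carbonyl C excluded
  expect_setequal(a$name[a$isBackbone], c("N", "HN", "CA", "HA", "CB", "O"))
  expect_equal(a$type[a$name == "N"], bb$type[bb$atom == "N"])
  expect_equal(a$charge[a$name == "HN"], bb$charge[bb$atom == "HN"])
  # fresh types for all other atoms, unique vs the input types
  expect_false(any(a$type[!a$isBackbone] %in% topo$atoms$type))
  # charge conservation to 1e-6 e
  expect_lt(abs(sum(a$charge) - 0), 1e-6)

  # retainC flag includes the carbonyl carbon
  blkC <- buildCnsPatch(topo, bb, retainC = TRUE)
  expect_true("C" %in% blkC@atoms$name[blkC@atoms$isBackbone])
  expect_lt(abs(sum(blkC@atoms$charge) - 0), 1e-6)
})

test_that("residual charge goes to the largest-magnitude non-backbone atom", {
  bb <- cnsBackboneTable()
  # residual exactly zero: charges pass through unchanged
  ch0 <- c(N = -0.57, HN = 0.37, CA = 0.07, HA = 0.09, CB = -0.18,
           O = -0.51, C = 0.46, CG = -0.30, CD = 0.10, NE = 0.47)
  topo0 <- cnsToyTopology(netCharge = sum(ch0), charges = ch0)
  blk0 <- buildCnsPatch(topo0, bb)
  nb <- !blk0@atoms$isBackbone
  expect_equal(blk0@atoms$charge[nb], unname(ch0[blk0@atoms$name[nb]]))

  # known residual lands on the atom of largest |charge| (arithmetic
  # oracle: absorber charge = input charge + residual)
  topo <- cnsToyTopology(netCharge = 0.05)
  blk <- buildCnsPatch(topo, bb)
  bbSum <- sum(bb$charge[match(c("N", "HN", "CA", "HA", "CB", "O"),
                               bb$atom)])
  nbIn <- topo$atoms$charge[!topo$atoms$name %in%
                            c("N", "HN", "CA", "HA", "CB", "O")]
  residual <- 0.05 - (bbSum + sum(nbIn))
  # largest |q| non-backbone atom in the toy is C at +0.46
  expect_equal(blk@atoms$charge[blk@atoms$name == "C"], 0.46 + residual,
               tolerance = 1e-9)
  expect_lt(abs(sum(blk@atoms$charge) - 0.05), 1e-6)

  # glycine-like residue with nothing outside the backbone: no absorber
  topoG <- cnsToyTopology()
  topoG$atoms <- topoG$atoms[topoG$atoms$name %in%
                             c("N", "HN", "CA", "HA", "CB", "O"), ]
  expect_error(buildCnsPatch(topoG, bb), "no absorber")

  # missing backbone atom errors unless explicitly tolerated
  topoM <- cnsToyTopology()
  topoM$atoms <- topoM$atoms[topoM$atoms$name != "HN", ]
  expect_error(buildCnsPatch(topoM, bb), "missing backbone")
  blkM <- buildCnsPatch(topoM, bb, requireBackbone = FALSE)
  expect_false("HN" %in% blkM@atoms$name)
  expect_lt(abs(sum(blkM@atoms$charge) - topoM$netCharge), 1e-6)
})

test_that("type clashes are renamed deterministically, duplicates merged", {
  bb <- cnsBackboneTable()
  b1 <- buildCnsPatch(cnsToyTopology(), bb)
  # identical parameters: merged silently
  rc0 <- resolveTypeClashes(list(b1, b1))
  expect_equal(nrow(rc0$report), 0L)

  # same name, different Lennard-Jones parameters: second renamed
  b2 <- b1
  b2@typeParams$eps[1] <- b2@typeParams$eps[1] + 0.05
  rc1 <- resolveTypeClashes(list(b1, b2))
  expect_equal(nrow(rc1$report), 1L)
  expect_equal(rc1$report$block, 2L)
  expect_match(rc1$report$newType, "_2$")
  # renaming propagates to the atoms and never changes parameters
  renamed <- rc1$report$newType
  expect_true(renamed %in% rc1$blocks[[2]]@typeParams$type)
  expect_true(renamed %in% rc1$blocks[[2]]@atoms$type)
  expect_equal(sort(rc1$blocks[[2]]@typeParams$eps),
               sort(b2@typeParams$eps))

  # three-way clash: two renames, all final names unique
  b3 <- b1
  b3@typeParams$eps[1] <- b3@typeParams$eps[1] + 0.10
  rc2 <- resolveTypeClashes(list(b1, b2, b3))
  expect_equal(nrow(rc2$report), 2L)
  finalTypes <- mapply(function(blk, i)
    paste(i, blk@typeParams$type), rc2$blocks, seq_along(rc2$blocks))
  allT <- unlist(lapply(rc2$blocks, function(b) b@typeParams$type))
  byName <- split(unlist(lapply(rc2$blocks, function(b)
    paste(b@typeParams$eps, b@typeParams$sigma))), allT)
  expect_true(all(vapply(byName, function(x)
    length(unique(x)) == 1L, logical(1))))
})

test_that("topology and parameter writers serialise the block", {
  blk <- buildCnsPatch(cnsToyTopology(), cnsBackboneTable())
  top <- writeCnsTopology(blk)
  expect_match(top[1], "^RESIdue ORX")
  expect_true(any(grepl("ATOM N *TYPE=NH1", top)))
  expect_true(any(grepl("^  BOND", top)))
  par <- writeCnsParameters(blk)
  expect_true(any(grepl("^NONBonded", par)))
  expect_true(any(grepl("^BOND", par)))

  # round trip through the YAML reader
  f <- tempfile(fileext = ".yaml")
  topo <- cnsToyTopology()
  yaml::write_yaml(list(
    resname = topo$resname, net_charge = topo$netCharge,
    atoms = lapply(seq_len(nrow(topo$atoms)), function(i)
      list(name = topo$atoms$name[i], type = topo$atoms$type[i],
           charge = topo$atoms$charge[i])),
    bonds = list(list(atoms = c("N", "CA"), params = c(300, 1.45))),
    types = list(list(type = "CT", eps = 0.1, sigma = 3.4))), f)
  topo2 <- readCnsTopology(f)
  expect_equal(topo2$atoms$charge, topo$atoms$charge)
  blk2 <- buildCnsPatch(topo2, cnsBackboneTable())
  expect_lt(abs(sum(blk2@atoms$charge) - topo$netCharge), 1e-6)
})
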