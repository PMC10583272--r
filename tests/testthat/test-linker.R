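test_that("disulfide linking retypes extensions and writes 4 restraints", {
  res <- linkTemplates(cysLinkSpec())
  r <- restraints(res)
  expect_equal(nrow(r), 4L)
  expect_true(all(r$limit == 0.04))
  expect_true(all(r$weight == 10))
  # each direction restrains the extension onto the partner's real atoms
  expect_setequal(paste(r$resI, r$atomI, r$resJ, r$atomJ),
                  c("3 SD 12 SG", "3 CE 12 CB",
                    "12 SD 3 SG", "12 CE 3 CB"))
  # extension heavy atoms and their hydrogens are DUMMY in both outputs
  for (tmpl in list(res@templateA, res@templateB)) {
    tb <- atomTable(tmpl)
    expect_setequal(tb$name[tb$type == "DUMMY"],
                    c("SD", "CE", "HCE1", "HCE2"))
    # pseudoatoms untouched
    expect_setequal(tb$name[tb$type == "PSEUD"], c("QB", "QE"))
  }
  # link statement names the linking-bond atoms only
  st <- linkStatement(res)
  expect_equal(st$atomI, "SG"); expect_equal(st$atomJ, "SG")
  expect_equal(st$resI, 3L); expect_equal(st$resJ, 12L)

  # serialised templates differ from the input only in the type column
  tb0 <- atomTable(makeExtendedTemplate("CYSX"))
  tb1 <- atomTable(res@templateA)
  changed <- which(tb0$raw != tb1$raw)
  expect_setequal(tb0$name[changed], c("SD", "CE", "HCE1", "HCE2"))
  for (i in changed) {
    st <- tb0$typeStart[i]
    en <- max(tb0$typeEnd[i], tb1$typeEnd[i])
    expect_identical(substr(tb0$raw[i], 1, st - 1),
                     substr(tb1$raw[i], 1, st - 1))
    expect_identical(substring(tb0$raw[i], en + 1),
                     substring(tb1$raw[i], en + 1))
  }

  # idempotent: re-linking the output changes nothing
  spec2 <- makeLinkSpec(res@templateA, res@templateB, 3L, 12L,
                        c("SG", "SG"), c(SD = "SG", CE = "CB"),
                        c(SD = "SG", CE = "CB"))
  res2 <- linkTemplates(spec2)
  expect_identical(res2@templateA@atomTable$raw,
                   res@templateA@atomTable$raw)

  # configurable limit/weight; zero limit rejected
  res3 <- linkTemplates(cysLinkSpec(), limit = 0.1, weight = 5)
  expect_true(all(restraints(res3)$limit == 0.1))
  expect_true(all(restraints(res3)$weight == 5))
  expect_error(linkTemplates(cysLinkSpec(), limit = 0), "larger than 0")
})

test_that("the vancomycin link-3 mapping yields one restraint per pair per direction", {
  v5 <- makeExtendedTemplate("VAN5")
  v7 <- makeExtendedTemplate("VAN7")
  spec <- makeLinkSpec(v5, v7, 5L, 7L, c("CD1", "CG3"),
    overlapA = c(CG1 = "CE5", CE1 = "CE3", CZ3 = "CD1", CZ4 = "CB"),
    overlapB = c(CE6 = "CD1", CZ5 = "CG", CH1 = "CB2", CH2 = "CB"))
  res <- linkTemplates(spec)
  expect_equal(nrow(restraints(res)), 8L)
  expect_true(all(restraints(res)$limit == 0.04))
  a <- subset(restraints(res), resI == 5)
  expect_setequal(paste(a$atomI, a$atomJ),
                  c("CG1 CE5", "CE1 CE3", "CZ3 CD1", "CZ4 CB"))

  # errors: unmapped extension atom, unknown overlap atom
  expect_error(linkTemplates(makeLinkSpec(v5, v7, 5L, 7L, c("CD1", "CG3"),
    c(CG1 = "CE5", CE1 = "CE3", CZ3 = "CD1"),
    c(CE6 = "CD1", CZ5 = "CG", CH1 = "CB2", CH2 = "CB"))),
    "CZ4")
  expect_error(linkTemplates(makeLinkSpec(v5, v7, 5L, 7L, c("CD1", "CG3"),
    c(CG1 = "CE5", CE1 = "CE3", CZ3 = "CD1", NOPE = "CB"),
    c(CE6 = "CD1", CZ5 = "CG", CH1 = "CB2", CH2 = "CB"))),
    "NOPE")
})

test_that("hydrogen restraints are optional and off by default", {
  res <- linkTemplates(cysLinkSpec())
  expect_false(any(grepl("^H", restraints(res)$atomI)))
  resH <- linkTemplates(cysLinkSpec(), hydrogenRestraints = TRUE)
  expect_gt(nrow(restraints(resH)), nrow(restraints(res)))
  hr <- subset(restraints(resH), grepl("^H", atomI))
  expect_true(all(grepl("^H", hr$atomJ)))
})

test_that("finalisation strips DUMMY atoms and renames residues", {
  lines <- cysxModelLines(nModels = 2, resno = 3)
  reg <- data.frame(resIndex = 3, resname = "CYSX",
                    atom = c("SD", "CE", "HCE1", "HCE2"),
                    stringsAsFactors = FALSE)
  out <- finalizeStructure(lines, reg, c(CYSX = "CYS"))
  nAtomsIn <- sum(startsWith(lines, "ATOM"))
  nAtomsOut <- sum(startsWith(out, "ATOM"))
  expect_equal(nAtomsIn - nAtomsOut, 8L)   # 4 atoms in each of 2 models
  expect_false(any(grepl("CYSX", out)))
  expect_true(any(grepl("CYS ", out)))
  # serials repacked per model: strictly 1..n in each model
  per <- split(out[startsWith(out, "ATOM")],
               cumsum(startsWith(out, "MODEL"))[startsWith(out, "ATOM")])
  for (m in per) {
    ser <- as.integer(substr(m, 7, 11))
    expect_equal(ser, seq_along(ser))
  }

  # byte-preserving pass-through
  expect_identical(finalizeStructure(lines, NULL, c()), lines)

  # registry referencing an absent atom errors
  regBad <- data.frame(resIndex = 3, resname = "CYSX", atom = "ZZ9")
  expect_error(finalizeStructure(lines, regBad), "absent")
})
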