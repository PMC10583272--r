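# Shared helpers: small file fixtures built in code.

ethanolMol2Lines <- function() {
  c("@<TRIPOS>MOLECULE", "ethanol", " 9 8 1 0 0", "SMALL", "NO_CHARGES", "",
    "@<TRIPOS>ATOM",
    "  1 C1  0.000 0.000 0.000 C.3 1 ETH 0.0",
    "  2 C2  1.530 0.000 0.000 C.3 1 ETH 0.0",
    "  3 O1  2.000 1.350 0.000 O.3 1 ETH 0.0",
    "  4 H1 -0.400 1.000 0.000 H 1 ETH 0.0",
    "  5 H2 -0.400 -0.500 0.870 H 1 ETH 0.0",
    "  6 H3 -0.400 -0.500 -0.870 H 1 ETH 0.0",
    "  7 H4  1.900 -0.500 0.870 H 1 ETH 0.0",
    "  8 H5  1.900 -0.500 -0.870 H 1 ETH 0.0",
    "  9 H6  2.960 1.350 0.000 H 1 ETH 0.0",
    "@<TRIPOS>BOND",
    "  1 1 2 1", "  2 2 3 1", "  3 1 4 1", "  4 1 5 1", "  5 1 6 1",
    "  6 2 7 1", "  7 2 8 1", "  8 3 9 1")
}

# standalone-residue fixture written as a CONECT-bearing PDB
writeResiduePdb <- function(code, path, resname = toupper(code)) {
  writeStructurePdb(makeFixture(code), path, resname = resname)
  path
}

# toy CNS residue topology (ornithine-like, six retained backbone atoms)
cnsToyTopology <- function(netCharge = 0,
                           charges = c(N = -0.5, HN = 0.35, CA = 0.05,
                                       HA = 0.09, CB = -0.1, O = -0.45,
                                       C = 0.46, CG = -0.30, CD = 0.10,
                                       NE = 0.30)) {
  list(resname = "ORX", netCharge = netCharge,
       atoms = data.frame(name = names(charges),
                          type = c("NX", "HX", "CX", "HX", "CX", "OX",
                                   "CX", "CT", "CT", "NT")[
                                     seq_along(charges)],
                          charge = unname(charges),
                          stringsAsFactors = FALSE),
       bonds = data.frame(atoms = I(list(c("N", "CA"), c("CA", "CB"))),
                          params = I(list(c(300, 1.45), c(310, 1.53)))),
       angles = data.frame(atoms = I(list(c("N", "CA", "CB"))),
                           params = I(list(c(50, 110)))),
       dihedrals = data.frame(atoms = I(list()), params = I(list())),
       impropers = data.frame(atoms = I(list()), params = I(list())),
       types = data.frame(type = c("CT", "NT"), eps = c(0.1, 0.2),
                          sigma = c(3.4, 3.1), stringsAsFactors = FALSE))
}

cnsBackboneTable <- function() {
  readBackboneCharges(system.file("extdata",
                                  "cns_backbone_charges_synthetic.tsv",
                                  package = "ncAAlib"))
}

# standard disulfide link spec over the extended cysteine template
cysLinkSpec <- function(resA = 3L, resB = 12L) {
  tmpl <- makeExtendedTemplate("CYSX")
  makeLinkSpec(tmpl, tmpl, resA, resB, c("SG", "SG"),
               overlapA = c(SD = "SG", CE = "CB"),
               overlapB = c(SD = "SG", CE = "CB"))
}

# multi-model PDB of the extended cysteine, residue codes CYSX
cysxModelLines <- function(nModels = 2, resno = 3) {
  f <- tempfile(fileext = ".pdb")
  writeStructurePdb(makeFixture("cys-extended"), f, resname = "CYSX",
                    resno = resno)
  body <- readLines(f)
  body <- body[body != "END"]
  unlist(lapply(seq_len(nModels), function(m)
    c(sprintf("MODEL %8d", m), body, "ENDMDL")))
}

# name map as a comparable old-serial -> name vector
nameVec <- function(naming) {
  m <- nameMap(naming)
  setNames(m$newName, as.character(m$serial))[
    order(as.integer(m$serial))]
}

rigidMotion <- function(g, seed) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3)
  Rz <- matrix(c(cos(th[2]), sin(th[2]), 0,
                 -sin(th[2]), cos(th[2]), 0, 0, 0, 1), 3)
  at <- atoms(g)
  m <- as.matrix(at[, c("x", "y", "z")]) %*% (Rx %*% Rz)
  at$x <- m[, 1] + stats::runif(1, -5, 5)
  at$y <- m[, 2] + stats::runif(1, -5, 5)
  at$z <- m[, 3] + stats::runif(1, -5, 5)
  new("MolecularGraph", atoms = at, bonds = bonds(g),
      netCharge = g@netCharge)
}
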