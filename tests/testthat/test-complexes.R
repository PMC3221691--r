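test_that("PDB writing and reading round-trips a toy complex", {
  cx <- genToyComplex(activePosePattern(), seed = 3, poseId = "ref")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeComplexPDB(cx, path)
  back <- readComplex(path)
  expect_identical(sort(residueIds(back)), sort(residueIds(cx)))
  expect_identical(nrow(residueAtoms(back)), nrow(residueAtoms(cx)))
  expect_identical(sum(atoms(ligand(back))$element != "H"),
                   sum(atoms(ligand(cx))$element != "H"))
  # coordinates preserved to PDB precision (1e-3 A)
  expect_lt(max(abs(as.matrix(residueAtoms(back)[, c("x", "y", "z")]) -
                    as.matrix(residueAtoms(cx)[, c("x", "y", "z")]))), 1e-3)
})

test_that("a PDB without HETATM ligand records errors", {
  cx <- genToyComplex(emptyPattern(), seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeComplexPDB(cx, path)
  lines <- readLines(path)
  writeLines(grep("^HETATM", lines, value = TRUE, invert = TRUE), path)
  expect_error(readComplex(path), "no ligand")
})

test_that("contacts use a strict cutoff and match brute force", {
  # constructed two-atom geometry: 3.9 in, 4.0 out
  lig <- mkMol("probe", "C", 4, coords = matrix(c(0, 0, 0), 1))
  res <- data.frame(resname = c("GLY", "GLY"), resno = c(1L, 2L),
                    chain = "A", atom = c("CA", "CA"), element = "C",
                    x = c(3.9, 4.0), y = 0, z = 0)
  cx <- new("ComplexStructure", residues = res, ligand = lig, poseId = "p")
  ct <- findContacts(cx)
  expect_identical(nrow(ct), 1L)
  expect_identical(ct$residue, "GLY:1")
  expect_equal(ct$distance, 3.9)
  # oracle equality on a full toy complex
  cxA <- genToyComplex(activePosePattern(), seed = 5)
  expect_identical(nrow(findContacts(cxA)), oracleContacts(cxA))
})

test_that("interaction detection reproduces constructed geometries", {
  # Arg NH 2.9 A from a ligand carbonyl O: hydrogen bond
  lig <- fixAcetone()
  oPos <- conformers(lig)[[1]]$coords[4, ]
  arg <- PhoreScreen:::.SIDECHAIN_FRAGS$ARG
  xyz <- sweep(arg$coords, 2, oPos + c(0, 2.9, 0) - arg$coords[2, ], `+`)
  res <- data.frame(resname = "ARG", resno = 144L, chain = "A",
                    atom = names(arg$atoms), element = unname(arg$atoms),
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  cx <- new("ComplexStructure", residues = res, ligand = lig, poseId = "hb")
  inter <- detectInteractions(cx)
  expect_true(any(inter$type == "HBOND" & inter$residue == "ARG:144"))

  # Glu carboxylate 3.5 A from a guanidinium: charged interaction
  gu <- assignProtonation(fixGuanidine())
  glu <- PhoreScreen:::.SIDECHAIN_FRAGS$GLU
  gCtr <- colMeans(conformers(gu)[[1]]$coords)
  xyz <- sweep(glu$coords, 2, gCtr + c(0, 3.5, 0), `+`)
  res <- data.frame(resname = "GLU", resno = 119L, chain = "A",
                    atom = names(glu$atoms), element = unname(glu$atoms),
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  cx2 <- new("ComplexStructure", residues = res, ligand = gu, poseId = "sb")
  expect_true(any(detectInteractions(cx2)$type == "CHARGED"))

  # Arg guanidinium 4.5 A above a benzene plane: pi-cation
  arg2 <- sweep(arg$coords, 2, c(0, 0, 4.5), `+`)
  res3 <- data.frame(resname = "ARG", resno = 307L, chain = "A",
                     atom = names(arg$atoms), element = unname(arg$atoms),
                     x = arg2[, 1], y = arg2[, 2], z = arg2[, 3])
  cx3 <- new("ComplexStructure", residues = res3, ligand = fixBenzene(),
             poseId = "pc")
  expect_true(any(detectInteractions(cx3)$type == "PICATION"))
})

test_that("fingerprints match the requested pattern and detections", {
  # far ligand: zero vector
  cx0 <- genToyComplex(emptyPattern(), seed = 6)
  fp0 <- interactionFingerprint(cx0)
  expect_identical(sum(fingerprintBits(fp0)), 0L)
  lig <- ligand(cx0)
  rxyz <- as.matrix(residueAtoms(cx0)[, c("x", "y", "z")])
  lxyz <- conformers(lig)[[1]]$coords
  expect_gte(min(as.matrix(pracma::distmat(rxyz, lxyz))), 5)

  # active-pattern pose: exactly the requested bits
  cxA <- genToyComplex(activePosePattern(), seed = 7, poseId = "act")
  fpA <- interactionFingerprint(cxA)
  on <- which(fingerprintBits(fpA) == 1L)
  got <- paste(indexMap(fpA)$residue[on], indexMap(fpA)$channel[on])
  expect_setequal(got, c("GLU:119 CHARGED", "CYS:137 HBOND", "ARG:144 PI",
                         "ARG:307 HBOND", "ARG:307 PI"))

  # two-path consistency: bits recomputed from detectInteractions agree
  inter <- detectInteractions(cxA)
  chan <- c(HBOND = "HBOND", CHARGED = "CHARGED", PIPI = "PI",
            PICATION = "PI")
  manual <- unique(paste(inter$residue, chan[inter$type]))
  expect_setequal(got, manual)

  # every set bit implies a heavy-atom contact under 4 A
  contacts <- findContacts(cxA)
  expect_true(all(indexMap(fpA)$residue[on] %in% contacts$residue))

  expect_error(interactionFingerprint(cxA, c("GLY:1")), "not in the complex")
})

test_that("Hamming distance matches the stated examples and the metric axioms", {
  pad <- function(x) c(x, rep(0L, 27 - length(x)))
  expect_equal(hammingDistance(mkIfp(pad(c(1, 0, 1, 0))),
                               mkIfp(pad(c(1, 1, 1, 1)))), 2 / 27)
  a <- mkIfp(rep(c(1L, 0L), c(13, 14)))
  expect_equal(hammingDistance(a, a), 0)
  b <- mkIfp(rep(c(0L, 1L), c(13, 14)))
  expect_equal(hammingDistance(a, b), 1)  # complementary vectors
  set.seed(17)
  for (i in 1:200) {
    x <- randomIfp("x"); y <- randomIfp("y"); z <- randomIfp("z")
    dxy <- hammingDistance(x, y)
    expect_equal(dxy, hammingDistance(y, x))
    expect_gte(dxy, 0); expect_lte(dxy, 1)
    expect_lte(dxy, hammingDistance(x, z) + hammingDistance(z, y) + 1e-12)
    expect_equal(hammingDistance(x, x), 0)
  }
  other <- new("InteractionFingerprint", bits = c(0L, 1L),
               indexMap = data.frame(residue = c("A:1", "A:1"),
                                     channel = c("HBOND", "CHARGED")),
               poseId = "short")
  expect_error(hammingDistance(a, other), "index maps differ")
})

test_that("pose clustering reproduces distances and planted structure", {
  # two groups of identical vectors: zero within-group merge heights and
  # two pure subtrees
  g1 <- lapply(1:3, function(i) mkIfp(rep(c(1L, 0L), c(5, 22)),
                                      sprintf("a%d", i)))
  g2 <- lapply(1:3, function(i) mkIfp(rep(c(0L, 1L), c(22, 5)),
                                      sprintf("b%d", i)))
  tree <- clusterPoses(c(g1, g2))
  expect_equal(sort(tree$height)[1:4], rep(0, 4))
  labels <- setNames(rep(c(TRUE, FALSE), each = 3),
                     c(sprintf("a%d", 1:3), sprintf("b%d", 1:3)))
  expect_equal(subtreePurity(tree, labels)$purity, 1)

  # condensed distance matrix equals the brute-force oracle
  set.seed(23)
  fps <- lapply(1:6, function(i) randomIfp(sprintf("r%d", i)))
  m <- oracleHammingMatrix(fps)
  tree2 <- clusterPoses(fps)
  d <- matrix(0, 6, 6)
  for (i in 1:5) for (j in (i + 1):6)
    d[i, j] <- d[j, i] <- hammingDistance(fps[[i]], fps[[j]])
  expect_equal(d, m, tolerance = 1e-12)

  expect_error(clusterPoses(fps[1]), "at least 2")
})

test_that("pose filters pass or fail exactly per the three constraints", {
  passPose <- genToyComplex(activePosePattern(), seed = 31, poseId = "ok")
  noGlu <- activePosePattern()
  noGlu <- noGlu[noGlu$type != "CHARGED", , drop = FALSE]
  failC1 <- genToyComplex(noGlu, seed = 32, poseId = "noglu")
  onePi <- data.frame(type = c("CHARGED", "HBOND", "PI"),
                      residue = c("GLU:119", "ARG:144", "ARG:307"))
  failC3 <- genToyComplex(onePi, seed = 33, poseId = "onepi")
  report <- applyPoseFilters(list(passPose, failC1, failC3))
  expect_identical(report$passed, c(TRUE, FALSE, FALSE))
  expect_match(report$reason[2], "constraint 1")
  expect_match(report$reason[3], "constraint 3")
  # a rule referencing an absent residue is a configuration error
  expect_error(applyPoseFilters(list(passPose),
                                defaultPoseRules(glu = "GLU:999")),
               "GLU:999")
})

test_that("ligand RMSD handles identity, translation and symmetry", {
  cx <- genToyComplex(activePosePattern(), seed = 35, poseId = "r")
  expect_equal(ligandRmsd(cx, cx), 0)
  moved <- cx
  moved@ligand <- transformMolecule(ligand(cx), t = c(1, 0, 0))
  expect_equal(ligandRmsd(moved, cx), 1, tolerance = 1e-9)
  # benzene rotated 60 degrees in place is automorphic: RMSD 0
  base <- genToyComplex(emptyPattern(), seed = 36)
  base@ligand <- fixBenzene()
  th <- pi / 3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rot <- base
  rot@ligand <- transformMolecule(fixBenzene(), R = R)
  expect_lt(ligandRmsd(rot, base), 1e-9)
  # mismatched topologies cannot be compared
  bad <- base; bad@ligand <- fixButane()
  expect_error(ligandRmsd(bad, base), "heavy-atom counts differ")
})

test_that("contact recovery fractions equal set arithmetic on oracles", {
  ref <- genToyComplex(activePosePattern(), seed = 37, poseId = "ref")
  expect_equal(contactRecovery(ref, ref)$contactRecovery, 1)
  expect_equal(contactRecovery(ref, ref)$residueRecovery, 1)
  far <- ref
  far@ligand <- transformMolecule(ligand(ref), t = c(80, 0, 0))
  rec <- contactRecovery(far, ref)
  expect_equal(rec$contactRecovery, 0)
  expect_equal(rec$residueRecovery, 0)
  # perturbed pose: fractions equal manual set arithmetic
  pert <- ref
  pert@ligand <- transformMolecule(ligand(ref), t = c(1.2, 0.4, 0))
  rec2 <- contactRecovery(pert, ref)
  cRef <- findContacts(ref); cPert <- findContacts(pert)
  keyR <- paste(cRef$residue, cRef$resAtom, cRef$ligAtom)
  keyP <- paste(cPert$residue, cPert$resAtom, cPert$ligAtom)
  expect_equal(rec2$contactRecovery,
               length(intersect(keyR, keyP)) / length(keyR))
  expect_equal(rec2$residueRecovery,
               length(intersect(unique(cRef$residue),
                                unique(cPert$residue))) /
                 length(unique(cRef$residue)))
  # a reference without contacts has undefined recovery
  empty <- genToyComplex(emptyPattern(), seed = 38)
  expect_error(contactRecovery(empty, empty), "no contacts")
})

test_that("detections are invariant under global rigid motion", {
  cx <- genToyComplex(activePosePattern(), seed = 39, poseId = "inv")
  fp0 <- fingerprintBits(interactionFingerprint(cx))
  set.seed(40)
  for (i in 1:10) {
    moved <- transformComplex(cx, R = PhoreScreen:::.randomRotation(),
                              t = stats::rnorm(3, sd = 10))
    expect_identical(fingerprintBits(interactionFingerprint(moved)), fp0)
    expect_lt(abs(ligandRmsd(moved, moved)), 1e-9)
  }
})
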