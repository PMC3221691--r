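test_that("SDF writing and reading round-trips atoms, bonds and charges", {
  model <- fourFeatureModel()
  mols <- genActives(model, 3, noise = 0.1, seed = 11)
  path <- withr::local_tempfile(fileext = ".sdf")
  writeMoleculesSDF(mols, path)
  back <- readMolecules(path, "sdf")
  expect_length(back, 3)
  expect_equal(vapply(back, molId, character(1)),
               vapply(mols, molId, character(1)))  # order preserved
  for (i in seq_along(mols)) {
    expect_identical(nrow(atoms(back[[i]])), nrow(atoms(mols[[i]])))
    expect_identical(nrow(bonds(back[[i]])), nrow(bonds(mols[[i]])))
    expect_identical(atoms(back[[i]])$charge, atoms(mols[[i]])$charge)
    expect_equal(ic50(back[[i]]), ic50(mols[[i]]), tolerance = 1e-8)
  }
  # independent parser oracle: ChemmineR reads the same structure back
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  expect_length(sdfset, 3)
  for (i in seq_along(mols)) {
    expect_identical(nrow(ChemmineR::atomblock(sdfset[[i]])),
                     nrow(atoms(mols[[i]])))
    expect_identical(nrow(ChemmineR::bondblock(sdfset[[i]])),
                     nrow(bonds(mols[[i]])))
  }
})

test_that("corrupt SDF records are skipped with a warning, valid ones kept", {
  model <- fourFeatureModel()
  mols <- genActives(model, 2, noise = 0.1, seed = 12)
  path <- withr::local_tempfile(fileext = ".sdf")
  writeMoleculesSDF(mols, path)
  lines <- readLines(path)
  corrupt <- c("broken", "", "", "  x  y  0  0", "M  END", "$$$$")
  splitAt <- grep("^\\$\\$\\$\\$", lines)[1]
  writeLines(c(lines[1:splitAt], corrupt, lines[(splitAt + 1):length(lines)]),
             path)
  expect_warning(back <- readMolecules(path, "sdf"), "skipping SDF record")
  expect_length(back, 2)
})

test_that("reading a missing file or an empty SDF errors", {
  expect_error(readMolecules("no-such-file.sdf", "sdf"), "no such file")
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines("junk", path)
  expect_error(suppressWarnings(readMolecules(path, "sdf")),
               "no valid molecule")
})

test_that("SMILES benzene parses to six aromatic carbons", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines("C1=CC=CC=C1 benzene", path)
  mols <- readMolecules(path, "smiles")
  expect_length(mols, 1)
  a <- atoms(mols[[1]])
  expect_identical(sum(a$element == "C" & a$aromatic), 6L)
})

test_that("rule-based protonation sets the documented charges at pH 7.5", {
  expect_identical(sum(atoms(assignProtonation(fixAceticAcid()))$charge), -1L)
  gu <- assignProtonation(fixGuanidine())
  expect_identical(sum(atoms(gu)$charge), 1L)
  # the guanidinium group as a whole carries the +1
  grp <- PhoreScreen:::.positiveGroups(gu)
  expect_length(grp, 1)
  expect_setequal(grp[[1]], 1:4)
  # no ionizable group: unchanged
  expect_identical(sum(atoms(assignProtonation(fixBenzene()))$charge), 0L)
  # outside the pKa windows nothing moves
  expect_identical(sum(atoms(assignProtonation(fixAceticAcid(), pH = 2))$charge), 0L)
})

test_that("computed properties match hand enumeration of the rule set", {
  p <- computeProperties(fixEthanol())
  expect_equal(unname(p[c("hbd", "hba", "rotatable", "formal_charge")]),
               c(1, 1, 0, 0))
  expect_equal(unname(p["mw"]), 46.069, tolerance = 1e-3)
  pb <- computeProperties(fixBenzene())
  expect_equal(unname(pb[c("hbd", "hba", "rotatable")]), c(0, 0, 0))
  expect_equal(unname(computeProperties(fixButane())["rotatable"]), 1)
  # amide C-N is not rotatable: N-methylacetamide has 0 rotatable bonds
  amide <- mkMol("nma", c("C", "C", "O", "N", "C"), c(3, 0, 0, 1, 3),
                 a1 = c(1, 2, 2, 4), a2 = c(2, 3, 4, 5),
                 order = c(1, 2, 1, 1))
  expect_equal(unname(computeProperties(amide)["rotatable"]), 0)
  # amide N is neither acceptor nor ionizable but still a donor
  expect_equal(unname(computeProperties(amide)[c("hbd", "hba")]), c(1, 1))
})

test_that("properties are conformer-independent", {
  bu <- generateConformers(fixButane(), nMax = 5, window = 20, seed = 3)
  p1 <- computeProperties(bu)
  bu2 <- bu
  bu2@conformers <- rev(bu2@conformers)
  expect_identical(p1, computeProperties(bu2))
})

test_that("conformer generation respects count, window, order and seed", {
  bu <- generateConformers(fixButane(), nMax = 10, window = 20, seed = 42)
  e <- vapply(conformers(bu), `[[`, numeric(1), "energy")
  expect_true(length(e) >= 1 && length(e) <= 10)
  expect_false(is.unsorted(e))
  expect_lte(max(e) - min(e), 20)
  expect_equal(e[1], min(e))  # window is referenced to the minimum
  bu2 <- generateConformers(fixButane(), nMax = 10, window = 20, seed = 42)
  expect_identical(lapply(conformers(bu), `[[`, "coords"),
                   lapply(conformers(bu2), `[[`, "coords"))
  # rigid ring: exactly one conformer
  expect_identical(nConformers(
    generateConformers(fixBenzene(), nMax = 50, window = 20, seed = 1)), 1L)
  # no starting geometry: generation error naming the molecule
  naked <- fixButane(); naked@conformers <- list()
  expect_error(generateConformers(naked, seed = 1), "butane")
})

test_that("feature perception follows the declared rule set", {
  fb <- perceiveFeatures(fixBenzene())
  expect_identical(fb$kind, "AROMATIC")
  expect_equal(c(fb$x, fb$y, fb$z), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sqrt(fb$dx^2 + fb$dy^2 + fb$dz^2), 1, tolerance = 1e-6)

  gu <- assignProtonation(fixGuanidine())
  fg <- perceiveFeatures(gu)
  expect_gte(sum(fg$kind == "POS_IONIZABLE"), 1)
  expect_gte(sum(fg$kind == "HBD"), 2)

  fa <- perceiveFeatures(fixAcetone())
  expect_identical(sum(fa$kind == "HBA"), 1L)
  expect_identical(sum(fa$kind == "HBD"), 0L)
  # the acceptor sits on the carbonyl oxygen with a C=O direction
  hba <- fa[fa$kind == "HBA", ]
  expect_equal(c(hba$x, hba$y, hba$z),
               conformers(fixAcetone())[[1]]$coords[4, ], tolerance = 1e-9)
  expect_false(anyNA(c(hba$dx, hba$dy, hba$dz)))

  # hydrophobic: butane is one 4-carbon fragment, ethanol has none
  expect_identical(perceiveFeatures(fixButane())$kind, "HYDROPHOBIC")
  expect_false("HYDROPHOBIC" %in% perceiveFeatures(fixEthanol())$kind)
})

test_that("feature perception is invariant under rigid motion", {
  model <- fourFeatureModel()
  mol <- genActives(model, 1, noise = 0.2, seed = 21)[[1]]
  f1 <- perceiveFeatures(mol)
  set.seed(99)
  for (rep in 1:5) {
    R <- PhoreScreen:::.randomRotation()
    t <- stats::rnorm(3, sd = 5)
    f2 <- perceiveFeatures(transformMolecule(mol, R = R, t = t))
    expect_identical(f1$kind, f2$kind)
    d1 <- stats::dist(as.matrix(f1[, c("x", "y", "z")]))
    d2 <- stats::dist(as.matrix(f2[, c("x", "y", "z")]))
    expect_lt(max(abs(d1 - d2)), 1e-6)
  }
})

test_that("property table CSV has the documented columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- writePropertyTable(list(fixEthanol(), fixBenzene()), path)
  back <- read.csv(path)
  expect_identical(names(back), c("id", "mw", "logp", "hbd", "hba",
                                  "rotatable", "formal_charge"))
  expect_identical(back$id, c("ethanol", "benzene"))
})
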