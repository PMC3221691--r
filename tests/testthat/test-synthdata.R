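test_that("generated actives embed the model and carry active IC50s", {
  model <- fourFeatureModel()
  acts <- genActives(model, 10, noise = 0.2, seed = 7)
  expect_length(acts, 10)
  fits <- vapply(acts, function(m) fitValueOf(mapLigand(model, m)),
                 numeric(1))
  expect_true(all(fits > 0))
  expect_true(all(fits > 4 * (1 - (0.2 / 1.6)^2) - 1e-9))  # jitter bound
  expect_true(all(vapply(acts, ic50, numeric(1)) < 0.05))
  # zero noise: every molecule maps with fit = k
  perfect <- genActives(model, 3, noise = 0, seed = 7)
  for (m in perfect)
    expect_equal(fitValueOf(mapLigand(model, m)), 4, tolerance = 1e-9)
})

test_that("generators are pure functions of the seed", {
  model <- fourFeatureModel()
  p1 <- withr::local_tempfile(fileext = ".sdf")
  p2 <- withr::local_tempfile(fileext = ".sdf")
  writeMoleculesSDF(genActives(model, 4, noise = 0.2, seed = 9), p1)
  writeMoleculesSDF(genActives(model, 4, noise = 0.2, seed = 9), p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical output
  d1 <- genDecoys(model, 3, seed = 9)
  d2 <- genDecoys(model, 3, seed = 9)
  expect_identical(lapply(d1, function(m) conformers(m)[[1]]$coords),
                   lapply(d2, function(m) conformers(m)[[1]]$coords))
})

test_that("decoys are property-matched but do not map to the model", {
  model <- fourFeatureModel()
  acts <- genActives(model, 12, noise = 0.2, seed = 13)
  stats <- referenceStats(acts)
  dec <- genDecoys(model, 25, seed = 13, stats = stats)
  expect_length(propertyFilter(dec, stats, kSd = 4, chargeRule = FALSE), 25)
  mapped <- sum(!vapply(dec, function(m) is.null(mapLigand(model, m)),
                        logical(1)))
  expect_lt(mapped / 25, 0.1)
  expect_length(genDecoys(model, 0, seed = 13), 0)
})

test_that("toy complexes realize exactly the requested interaction vector", {
  pat <- data.frame(type = c("CHARGED", "HBOND", "PI"),
                    residue = c("GLU:119", "ARG:144", "ARG:307"))
  cx <- genToyComplex(pat, seed = 15, poseId = "t")
  fp <- interactionFingerprint(cx)
  on <- which(fingerprintBits(fp) == 1L)
  expect_setequal(paste(indexMap(fp)$residue[on], indexMap(fp)$channel[on]),
                  c("GLU:119 CHARGED", "ARG:144 HBOND", "ARG:307 PI"))
  # unsupported combinations fail loudly
  expect_error(genToyComplex(data.frame(type = "CHARGED",
                                        residue = "ARG:144"), seed = 1),
               "acidic")
  expect_error(genToyComplex(data.frame(type = "HBOND",
                                        residue = "BAD:1"), seed = 1),
               "outside the site")
})

test_that("pose sets separate into pure subtrees under clustering", {
  ps <- genPoseSet(12, 12, flipProb = 0.05, seed = 19)
  expect_length(ps$poses, 24)
  fps <- lapply(ps$poses, interactionFingerprint)
  tree <- clusterPoses(fps)
  expect_gte(subtreePurity(tree, ps$labels)$purity, 0.9)
})
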