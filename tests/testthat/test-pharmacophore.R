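test_that("fit value follows the displacement formula and its bounds", {
  expect_identical(fitValue(rep(0, 4), rep(1.6, 4)), 4)
  expect_equal(fitValue(c(1.6, 0, 0, 0), rep(1.6, 4)), 3)
  expect_equal(fitValue(0.5, 1), 0.75)
  # monotone non-increasing in each displacement, bounded in [0, k]
  r <- rep(1.6, 4)
  prev <- Inf
  for (d in seq(0, 2, by = 0.1)) {
    v <- fitValue(c(d, 0.3, 0.3, 0.3), r)
    expect_lte(v, prev)
    expect_gte(v, 0); expect_lte(v, 4)
    prev <- v
  }
  expect_error(fitValue(c(-0.1), 1))
})

test_that("a ligand replicating the model geometry maps with maximal fit", {
  model <- fourFeatureModel()
  res <- mapLigand(model, exactLigand(model))
  expect_s4_class(res, "MappingResult")
  expect_equal(fitValueOf(res), 4, tolerance = 1e-9)
  expect_true(all(res@displacements < 1e-6))
})

test_that("a ligand missing a required kind cannot map with zero omissions", {
  model <- fourFeatureModel()  # requires POS_IONIZABLE
  expect_null(mapLigand(model, fixBenzene()))
  expect_null(mapLigand(model, fixButane()))
})

test_that("mapping equals exhaustive assignment enumeration (oracle)", {
  model <- fourFeatureModel()
  set.seed(7)
  for (seed in c(31, 32, 33)) {
    mol <- genActives(model, 1, noise = 0.4, seed = seed)[[1]]
    got <- mapLigand(model, mol)
    want <- oracleMapFit(model, mol)
    expect_false(is.null(got))
    expect_equal(fitValueOf(got), want, tolerance = 1e-6)
  }
  # and for a molecule that does not map, both return nothing
  dec <- genDecoys(model, 1, seed = 5)[[1]]
  expect_null(mapLigand(model, dec))
  expect_null(oracleMapFit(model, dec))
})

test_that("mapping is invariant under rigid motion of the conformer", {
  model <- fourFeatureModel()
  mol <- genActives(model, 1, noise = 0.3, seed = 41)[[1]]
  f0 <- fitValueOf(mapLigand(model, mol))
  set.seed(5)
  for (rep in 1:5) {
    moved <- transformMolecule(mol, R = PhoreScreen:::.randomRotation(),
                               t = stats::rnorm(3, sd = 8))
    expect_lt(abs(fitValueOf(mapLigand(model, moved)) - f0), 1e-6)
  }
})

test_that("references sharing a planted arrangement yield the planted model", {
  model <- fourFeatureModel()
  refs <- genActives(model, 3, noise = 0.2, seed = 7)
  models <- buildCommonFeatureModel(refs, kRange = 4)
  expect_gt(length(models), 0)
  expect_lte(length(models), 10)
  top <- models[[1]]
  expect_setequal(features(top)$kind,
                  c("HBA", "POS_IONIZABLE", "AROMATIC", "HYDROPHOBIC"))
  # every emitted model respects the minimum interfeature distance
  for (m in models) {
    ctr <- as.matrix(features(m)[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(ctr)); diag(d) <- Inf
    expect_gte(min(d), m@minInterfeatureDistance - 1e-9)
  }
  # model size cannot exceed the smallest reference's feature count
  minFeats <- min(vapply(refs, function(m) nrow(perceiveFeatures(m)),
                         integer(1)))
  expect_lte(nrow(features(models[[1]])), minFeats)
  # each reference maps back onto the model it defined (recovery property)
  for (r in refs) {
    res <- mapLigand(models[[1]], r)
    expect_false(is.null(res))
    expect_gte(fitValueOf(res), 4 * (1 - (0.4 / 1.6)^2) - 1e-6)
  }
})

test_that("references with disjoint feature kinds give no common model", {
  expect_message(
    models <- buildCommonFeatureModel(list(fixButane(), fixBenzene()),
                                      kRange = 2),
    "no common feature subset")
  expect_length(models, 0)
})

test_that("pharmacophore model JSON round-trips bit-exactly", {
  model <- newPharmacophoreModel(
    kinds = c("HBA", "AROMATIC", "HYDROPHOBIC"),
    centers = rbind(c(0.123456789, -2, 3), c(4, 5.5, -6), c(1, 1, 9)),
    tolerance = c(1.6, 2.0, 1.0),
    directions = rbind(c(0, 0, 1), rep(NA_real_, 3), rep(NA_real_, 3)),
    maxOmitted = 1L)
  path <- withr::local_tempfile(fileext = ".json")
  writePharmacophoreModel(model, path)
  back <- readPharmacophoreModel(path)
  expect_identical(features(back), features(model))
  expect_identical(back@maxOmitted, model@maxOmitted)
  expect_identical(back@minInterfeatureDistance,
                   model@minInterfeatureDistance)
})

test_that("model validity enforces the minimum interfeature distance", {
  expect_error(newPharmacophoreModel(
    kinds = c("HBA", "HBD"), centers = rbind(c(0, 0, 0), c(0.5, 0, 0))),
    "interfeature")
})
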