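test_that("property filter applies the +/- kSD window and the charge rule", {
  model <- fourFeatureModel()
  acts <- genActives(model, 8, noise = 0.2, seed = 51)
  stats <- referenceStats(acts)
  expect_length(propertyFilter(acts, stats), 8)  # actives pass their own window

  # a molecule at the reference means with charge 0 is retained
  center <- acts[[1]]
  expect_length(propertyFilter(list(center), stats, chargeRule = FALSE), 1)

  # formal charge -1 is rejected by the charge rule
  anion <- assignProtonation(fixAceticAcid())
  expect_length(propertyFilter(list(anion), stats, chargeRule = TRUE), 0)

  # a property 5 SD out is rejected at kSd = 4: bolt a long alkane on
  huge <- genActives(model, 1, noise = 0.2, seed = 52)[[1]]
  mwSd <- max(stats["mw", "sd"], 1)
  extraC <- ceiling((stats["mw", "mean"] + 5 * mwSd) / 12)
  big <- mkMol("whale", rep("C", extraC), rep(2, extraC),
               a1 = seq_len(extraC - 1), a2 = 2:extraC,
               order = rep(1L, extraC - 1))
  expect_length(propertyFilter(list(big), stats, kSd = 4), 0)

  # idempotent, order preserving, output subset of input
  once <- propertyFilter(acts, stats)
  twice <- propertyFilter(once, stats)
  expect_identical(vapply(once, molId, character(1)),
                   vapply(twice, molId, character(1)))
})

test_that("decoy sampling is seeded, size-checked and window-safe", {
  model <- fourFeatureModel()
  acts <- genActives(model, 6, noise = 0.2, seed = 61)
  pool <- genDecoys(model, 30, seed = 61, stats = referenceStats(acts))
  d1 <- buildDecoySet(acts, pool, 10, seed = 3)
  d2 <- buildDecoySet(acts, pool, 10, seed = 3)
  expect_identical(vapply(d1, molId, character(1)),
                   vapply(d2, molId, character(1)))
  expect_length(buildDecoySet(acts, pool, 0, seed = 3), 0)
  expect_error(buildDecoySet(acts, pool, 1000, seed = 3), "smaller than")
  stats <- referenceStats(acts)
  expect_length(propertyFilter(d1, stats, chargeRule = FALSE), 10)
})

test_that("screening ranks by fit, excludes unmapped, ignores input order", {
  model <- fourFeatureModel()
  refs <- genActives(model, 3, noise = 0.2, seed = 71)
  alkanes <- list(fixButane(), fixEthanol())
  hits <- screenLibrary(model, c(refs, alkanes))
  expect_identical(nrow(hits), 3L)  # feature-poor molecules drop out
  expect_true(all(hits$fit > 4 * (1 - (0.4 / 1.6)^2)))
  expect_false(is.unsorted(-hits$fit))
  hits2 <- screenLibrary(model, rev(c(refs, alkanes)))
  expect_identical(hits, hits2)
  expect_identical(nrow(screenLibrary(model, alkanes)), 0L)
})

test_that("ROC enrichment reproduces the hand-swept example", {
  hits <- data.frame(id = c("a1", "a2", "d1", "d2"),
                     fit = c(3.0, 2.9, 2.0, 1.0))
  enr <- rocEnrichment(hits, activeIds = c("a1", "a2"))
  expect_equal(auc(enr), 1.0)
  expect_equal(fullRecallCutoff(enr), 2.9)
  p <- rocPoints(enr)
  expect_false(is.unsorted(p$fpr))
  expect_false(is.unsorted(p$tpr))
  expect_equal(utils::tail(p$tpr, 1), 1)
  expect_equal(utils::tail(p$fpr, 1), 1)
})

test_that("ROC limiting cases: ties give AUC 0.5, zero actives error", {
  tied <- data.frame(id = c("a1", "a2", "d1", "d2"), fit = rep(2, 4))
  expect_equal(auc(rocEnrichment(tied, c("a1", "a2"))), 0.5)
  expect_error(rocEnrichment(tied, character(0)), "zero actives")
  expect_error(rocEnrichment(tied, tied$id), "decoy")
})

test_that("AUC is invariant to monotone transforms and matches pROC", {
  set.seed(13)
  hits <- data.frame(id = sprintf("m%02d", 1:40),
                     fit = round(stats::runif(40, 0, 4), 2))
  activeIds <- sprintf("m%02d", sample(40, 15))
  e1 <- rocEnrichment(hits, activeIds)
  hits2 <- hits; hits2$fit <- 2 * hits2$fit + 1  # monotone transform
  e2 <- rocEnrichment(hits2, activeIds)
  expect_equal(auc(e1), auc(e2), tolerance = 1e-12)
  want <- as.numeric(pROC::auc(pROC::roc(
    response = hits$id %in% activeIds, predictor = hits$fit,
    quiet = TRUE, direction = "<")))
  expect_equal(auc(e1), want, tolerance = 1e-9)
})

test_that("unscored molecules enter the ROC as not retrieved", {
  hits <- data.frame(id = c("a1", "d1"), fit = c(3, 1))
  enr <- rocEnrichment(hits, activeIds = c("a1", "a2"),
                       allIds = c("a1", "a2", "d1", "d2"))
  rk <- rankedScores(enr)
  expect_identical(rk$fit[rk$id == "a2"], -Inf)
  expect_identical(fullRecallCutoff(enr), -Inf)
})

test_that("Tanimoto follows SA/(SA+SB+SC) with the documented conventions", {
  bf <- function(bits) new("BitFingerprint", bits = as.integer(sort(bits)),
                           length = 16L, params = list())
  expect_equal(tanimoto(bf(c(1, 5, 9)), bf(c(1, 5, 9))), 1.0)
  expect_equal(tanimoto(bf(c(1, 2)), bf(c(3, 4))), 0.0)
  expect_equal(tanimoto(bf(c(1, 2, 3)), bf(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(bf(integer(0)), bf(integer(0))), 0)  # convention
  a <- bf(c(2, 4, 8)); b <- bf(c(2, 9))
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  long <- new("BitFingerprint", bits = 1L, length = 32L, params = list())
  expect_error(tanimoto(a, long), "lengths differ")
})

test_that("similarity matrix agrees with scalar Tanimoto and conventions", {
  model <- fourFeatureModel()
  mols <- genActives(model, 2, noise = 0.2, seed = 81)
  m <- similarityMatrix(mols, mols)
  expect_equal(unname(diag(m)), c(1, 1))
  fp <- lapply(mols, pathFingerprint)
  expect_equal(m[1, 2], tanimoto(fp[[1]], fp[[2]]))
  expect_equal(m[2, 1], m[1, 2])
  # structurally unrelated sets stay far below the 0.85 similarity rule
  unrelated <- similarityMatrix(list(fixBenzene()), list(fixButane()))
  expect_lt(max(unrelated), 0.85)
})
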