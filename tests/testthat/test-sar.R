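test_that("activity classification uses strict IC50 thresholds", {
  expect_identical(classifyActivity(0.01), "active")
  expect_identical(classifyActivity(2), "inactive")
  expect_identical(classifyActivity(0.5), "excluded")
  # boundary values fall in neither stated interval
  expect_identical(classifyActivity(c(0.05, 1.0)), c("excluded", "excluded"))
  expect_error(classifyActivity(-1), "positive")
  expect_error(classifyActivity(0), "positive")
})

test_that("matched pairs are found exactly at single-difference positions", {
  tpl <- defaultScaffold()
  gp <- genMatchedPairs(tpl, rule = list(D = c("AROMATIC", "HBA")),
                        nPairs = 4, seed = 91)
  pairs <- findMatchedPairs(gp$actives, gp$inactives, tpl)
  # every generated pair differs at exactly one position, so each active
  # matches at least its own partner
  expect_gte(nrow(pairs), 4)
  expect_true(all(pairs$position == "D"))
  expect_true(all(pairs$substituent_active != pairs$substituent_inactive))
})

test_that("two-position differences and identical molecules give no pair", {
  tpl <- defaultScaffold()
  subsA <- c(A1 = "methyl", D = "methoxyphenyl", L2 = "propyl", Q = "none")
  subsB <- c(A1 = "ethyl", D = "phenyl", L2 = "propyl", Q = "none")
  mA <- PhoreScreen:::.buildScaffoldMolecule("a", tpl, subsA, ic50 = 0.01)
  mB <- PhoreScreen:::.buildScaffoldMolecule("b", tpl, subsB, ic50 = 5)
  expect_identical(nrow(findMatchedPairs(list(mA), list(mB), tpl)), 0L)
  mA2 <- mA; mA2@ic50 <- 5
  expect_identical(nrow(findMatchedPairs(list(mA), list(mA2), tpl)), 0L)
})

test_that("molecules not matching the core are skipped with a message", {
  tpl <- defaultScaffold()
  gp <- genMatchedPairs(tpl, nPairs = 1, seed = 92)
  expect_message(
    pairs <- findMatchedPairs(c(gp$actives, list(fixButane())),
                              gp$inactives, tpl),
    "does not match the scaffold core")
  expect_gte(nrow(pairs), 1)
})

test_that("scaffold decomposition partitions the heavy atoms", {
  tpl <- defaultScaffold()
  subs <- c(A1 = "phenyl", D = "methoxyphenyl", L2 = "methyl", Q = "ethyl")
  m <- PhoreScreen:::.buildScaffoldMolecule("m", tpl, subs, ic50 = 0.01)
  d <- PhoreScreen:::.decompose(tpl, m)
  heavy <- which(atoms(m)$element != "H")
  covered <- sort(unname(c(d$mapping, unlist(d$substituents))))
  expect_identical(covered, heavy)  # core + substituents = whole graph
  expect_identical(length(d$substituents$D), 8L)   # methoxyphenyl
  expect_identical(length(d$substituents$L2), 1L)  # methyl
})

test_that("planted per-position rules are recovered exactly", {
  tpl <- defaultScaffold()
  gp <- genMatchedPairs(tpl, rule = list(D = c("AROMATIC", "HBA")),
                        nPairs = 13, seed = 7)
  pairs <- findMatchedPairs(gp$actives, gp$inactives, tpl)
  expect_gte(nrow(pairs), 13)
  report <- positionFeatureRules(pairs)
  expect_identical(report$D$required, c("AROMATIC", "HBA"))
  expect_gte(length(report$D$evidence), 1)  # evidence pair ids present

  gp2 <- genMatchedPairs(tpl, rule = list(Q = "HBD"), nPairs = 5, seed = 8)
  pairs2 <- findMatchedPairs(gp2$actives, gp2$inactives, tpl)
  report2 <- positionFeatureRules(pairs2)
  expect_true("HBD" %in% report2$Q$required)
})

test_that("pairs with no systematic delta are flagged 'no rule'", {
  pairs <- data.frame(
    active = c("a1", "a2"), inactive = c("i1", "i2"),
    position = "L2",
    substituent_active = c("x", "y"), substituent_inactive = c("y", "x"),
    kinds_active = c("AROMATIC", ""), kinds_inactive = c("", "AROMATIC"),
    gained = c("AROMATIC", ""), lost = c("", "AROMATIC"))
  report <- positionFeatureRules(pairs)
  expect_identical(report$L2$rule, "no rule")
})

test_that("generated pairs differ at exactly one position by construction", {
  tpl <- defaultScaffold()
  gp <- genMatchedPairs(tpl, nPairs = 6, seed = 93)
  for (i in seq_len(6)) {
    dA <- PhoreScreen:::.decompose(tpl, gp$actives[[i]])
    dI <- PhoreScreen:::.decompose(tpl, gp$inactives[[i]])
    differs <- vapply(names(dA$substituents), function(lbl)
      !PhoreScreen:::.substituentsIsomorphic(
        gp$actives[[i]], dA$substituents[[lbl]],
        gp$inactives[[i]], dI$substituents[[lbl]]), logical(1))
    expect_identical(sum(differs), 1L)
  }
  # IC50 annotations fall on the correct sides of the thresholds
  expect_true(all(vapply(gp$actives, ic50, numeric(1)) < 0.05))
  expect_true(all(vapply(gp$inactives, ic50, numeric(1)) > 1))
})
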