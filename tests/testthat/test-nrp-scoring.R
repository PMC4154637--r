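test_that("baseline probabilities follow additive smoothing and the degenerate rule", {
  f4 <- monomerFrequencyTable(c(ala = 3, gly = 1, ser = 0, val = 0))
  expect_equal(baselineProbability("ala", f4), 0.5)     # (3+1)/(4+4)
  expect_equal(baselineProbability("ser", f4), 0.125)   # (0+1)/(4+4)
  f20 <- uniformFreq20()
  expect_equal(baselineProbability(c("thr", "ser"), f20), 0.05)  # 1/20
  expect_equal(baselineProbability(c("ala", "ser"), f4), 0.25)   # 1/4
  expect_error(baselineProbability("orn", f4), "outside the alphabet")
  # probabilities over the alphabet sum to one
  expect_equal(sum(vapply(monomerAlphabet(f4), baselineProbability,
                          numeric(1), freq = f4)), 1)
})

test_that("match values average the channels and take the best candidate", {
  pBoth <- specificityPrediction(svmLarge = c("val", "ile", "leu"),
                                 svmThree = c("val", "ile", "leu", "ala"),
                                 stachMatch = "val", stachIdentity = 0.7)
  expect_equal(matchValue("val", pBoth), 0.6)   # mean(0.5, 0.7)
  pNone <- specificityPrediction(svmSingle = "gly", svmSmall = "gly",
                                 svmLarge = "gly", svmThree = "gly",
                                 stachMatch = "gly", stachIdentity = 1)
  expect_equal(matchValue("val", pNone), 0)
  pLeu <- fullPred("leu")
  expect_equal(matchValue(c("ile", "leu"), pLeu), 1)
  # absent channels: the remaining channel stands alone
  expect_equal(matchValue("thr", specificityPrediction(
    stachMatch = "thr", stachIdentity = 0.8)), 0.8)
  expect_equal(matchValue("thr", specificityPrediction(
    svmSmall = "thr", svmLarge = "thr", svmThree = "thr")), 0.75)
  # innermost matching tier wins
  pTier <- specificityPrediction(svmSingle = "val",
                                 svmSmall = c("val", "ile"),
                                 svmLarge = c("val", "ile", "leu"),
                                 svmThree = c("val", "ile", "leu", "abu"))
  expect_equal(vapply(c("val", "ile", "leu", "abu", "gly"), matchValue,
                      numeric(1), prediction = pTier),
               c(val = 1, ile = 0.75, leu = 0.5, abu = 0.25, gly = 0))
})

test_that("the position score reproduces its closed-form values and limits", {
  p <- scoringParams()
  expect_equal(positionScore(1, 0.05, p), 2.986282, tolerance = 1e-6)
  expect_equal(positionScore(0, 0.05, p), log(0.01 / 1.01))
  expect_equal(positionScore(0, 0.5, p), -4.615121, tolerance = 1e-6)
  # c = 0 is baseline-neutral, exactly
  expect_identical(positionScore(c(0, 0.3, 1), 0.07,
                                 scoringParams(c = 0)), c(0, 0, 0))
  # strictly increasing in the match value for c > 0
  grid <- seq(0, 1, by = 0.05)
  s <- positionScore(grid, 0.05, p)
  expect_true(all(diff(s) > 0))
  # eta-invariant at match 0 and 1, non-increasing in eta between
  for (iB in c(0, 1))
    expect_equal(positionScore(iB, 0.05, scoringParams(eta = 5)),
                 positionScore(iB, 0.05, scoringParams(eta = 1)))
  for (iB in c(0.25, 0.5, 0.9)) {
    byEta <- vapply(c(1, 2, 4, 8), function(e)
      positionScore(iB, 0.05, scoringParams(eta = e)), numeric(1))
    expect_true(all(diff(byEta) < 0))
  }
  expect_error(positionScore(0.5, 0, p), "\\(0, 1\\)")
  expect_error(positionScore(1.2, 0.5, p), "\\[0, 1\\]")
})

test_that("assembly-line configurations permute genes, not modules", {
  e2 <- bgcEntry("two", list(g1 = lapply(c("ala", "gly"), fullPred),
                             g2 = lapply(c("ser", "thr", "val"), fullPred)))
  ords <- enumerateOrderings(e2)
  expect_equal(length(ords), 2L)
  expect_false(attr(ords, "capped"))
  expect_equal(ords[[1]]$moduleIdx, 1:5)          # g1 then g2
  expect_equal(ords[[2]]$moduleIdx, c(3:5, 1:2))  # g2 then g1
  expect_equal(length(enumerateOrderings(perfectEntry("one", c("ala")))), 1L)
  e4 <- bgcEntry("four", setNames(lapply(1:4, function(i)
    list(fullPred("ala"))), paste0("g", 1:4)))
  expect_equal(length(enumerateOrderings(e4)), 24L)
  # deterministic truncation: the capped list is a prefix
  capped <- enumerateOrderings(e4, cap = 7)
  expect_true(attr(capped, "capped"))
  expect_equal(lapply(capped, `[[`, "genePerm"),
               lapply(enumerateOrderings(e4)[1:7], `[[`, "genePerm"))
})

test_that("scorer equals the exhaustive oracle on random small clusters", {
  freq <- defaultFrequencyTable()
  alpha <- monomerAlphabet(freq)
  set.seed(11)
  for (i in 1:40) {
    entry <- randomSmallEntry(sprintf("r%02d", i), alpha)
    tag <- randomTestTag(sample(2:5, 1L), alpha)
    params <- scoringParams(orientationMode =
                              sample(c("both", "forward"), 1L))
    got <- scoreTagAgainstBgc(tag, entry, freq, params)
    want <- oracleScore(tag, entry, freq, params)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    if (is.finite(want$S)) {
      expect_equal(got$alignment$moduleIdx, want$alignment$moduleIdx)
      expect_equal(got$alignment$orientation, want$alignment$orientation)
      expect_equal(got$alignment$offset, want$alignment$offset)
      expect_equal(got$colinearity, want$colinearity)
    }
  }
})

test_that("perfect-match scores are additive position by position", {
  freq <- uniformFreq20()
  p <- scoringParams()
  term <- positionScore(1, 0.05, p)
  monomers <- c("val", "ala", "leu", "ser", "gly", "thr", "ile", "phe")
  for (L in 2:8) {
    entry <- perfectEntry("add", monomers[1:L])
    tag <- sequenceTag(monomers[1:L], alphabet = monomerAlphabet(freq))
    expect_equal(scoreTagAgainstBgc(tag, entry, freq, p)$S, L * term,
                 tolerance = 1e-12)
  }
  # complete mismatch: every position at the floor term
  wrongTag <- sequenceTag(rep("trp", 4), alphabet = monomerAlphabet(freq))
  entry <- perfectEntry("miss", monomers[1:4])
  expect_equal(scoreTagAgainstBgc(wrongTag, entry, freq, p)$S,
               4 * log(0.01 / 1.01), tolerance = 1e-12)
})

test_that("orientation handling: both-mode symmetry, forward-mode asymmetry", {
  freq <- defaultFrequencyTable()
  alpha <- monomerAlphabet(freq)
  set.seed(5)
  for (i in 1:10) {
    entry <- randomSmallEntry(sprintf("o%02d", i), alpha)
    tag <- randomTestTag(3, alpha)
    both <- scoringParams(orientationMode = "both")
    expect_equal(scoreTagAgainstBgc(tag, entry, freq, both)$S,
                 scoreTagAgainstBgc(reverseTag(tag), entry, freq, both)$S,
                 tolerance = 1e-12)
  }
  # a forward-only scorer can miss a reversed-tag match
  entry <- perfectEntry("dir", c("val", "ala", "gly"))
  revTag <- sequenceTag(c("gly", "ala", "val"), alphabet = alpha)
  fwd <- scoreTagAgainstBgc(revTag, entry, freq,
                            scoringParams(orientationMode = "forward"))
  both <- scoreTagAgainstBgc(revTag, entry, freq,
                             scoringParams(orientationMode = "both"))
  expect_lt(fwd$S, both$S)
  expect_equal(both$alignment$orientation, "reversed")
})

test_that("colinearity counts native-consecutive forward pairs", {
  freq <- uniformFreq20()
  entry <- perfectEntry("col", c("val", "ala", "leu", "ser"))
  tag <- sequenceTag(c("val", "ala", "leu", "ser"),
                     alphabet = monomerAlphabet(freq))
  res <- scoreTagAgainstBgc(tag, entry, freq, scoringParams())
  expect_equal(res$colinearity, 1)
  # reversed alignment within one gene: no ascending pair
  revd <- scoreTagAgainstBgc(reverseTag(tag), entry, freq, scoringParams())
  expect_equal(revd$alignment$orientation, "reversed")
  expect_equal(colinearityIndex(revd$alignment), 0)
  # permuted gene boundary: 1 of 2 adjacent pairs native-consecutive
  expect_equal(colinearityIndex(list(geneIds = c("gB", "gA", "gA"),
                                     ordinals = c(0L, 0L, 1L))), 0.5)
  expect_equal(colinearityIndex(list(geneIds = "g", ordinals = 0L)), 1)
})

test_that("ranking sorts by score, shares tied ranks, and handles sentinels", {
  freq <- uniformFreq20()
  alpha <- monomerAlphabet(freq)
  tag <- sequenceTag(c("val", "ala", "leu", "ser"), alphabet = alpha)
  twin1 <- perfectEntry("twinA", c("val", "ala", "leu", "ser"))
  twin2 <- perfectEntry("twinB", c("val", "ala", "leu", "ser"))
  lone <- perfectEntry("loser", c("gly", "gly", "gly", "gly"))
  short <- perfectEntry("tooShort", c("val", "ala"))  # tag overhangs
  db <- bgcDatabase(list(lone, twin2, short, twin1))
  res <- rankBgcs(tag, db, freq = freq)
  expect_equal(res$clusterId, c("twinA", "twinB", "loser", "tooShort"))
  expect_equal(res$rank, c(1L, 1L, 3L, 4L))
  expect_equal(res$score[4], -Inf)
  expect_true(is.na(res$colinearity[4]))
  # a database of one ranks its entry first regardless of score
  solo <- rankBgcs(tag, bgcDatabase(list(lone)), freq = freq)
  expect_equal(solo$rank, 1L)
  expect_error(rankBgcs(tag, bgcDatabase(list()), freq = freq), "empty")
  # ties with different colinearity do not share a rank
  g2 <- bgcEntry("split", list(gA = lapply(c("val", "ala"), fullPred),
                               gB = lapply(c("leu", "ser"), fullPred)))
  res2 <- rankBgcs(tag, bgcDatabase(list(twin1, g2)), freq = freq)
  expect_equal(res2$clusterId, c("twinA", "split"))
  expect_equal(res2$score[1], res2$score[2], tolerance = 1e-12)
  expect_equal(res2$rank, c(1L, 2L))
  # baseline neutrality: c = 0 zeroes every finite score
  res0 <- rankBgcs(tag, db, freq = freq, params = scoringParams(c = 0))
  expect_true(all(res0$score[is.finite(res0$score)] == 0))
})
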