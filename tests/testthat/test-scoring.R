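kb <- buildDefaultKB()

test_that("cytogenetic lesions match their named categories", {
  m <- matchLesions(kb, list(aberration("translocation", "t(4;14)")))
  expect_identical(vapply(m$matches, `[[`, character(1), "category"),
                   "t(4;14)")
  m <- matchLesions(kb, list(aberration("translocation", "t(8;14)")))
  expect_identical(m$matches[[1]]$category, "Secondary t(8;14)")
  m <- matchLesions(kb, list(aberration("deletion", "del(13q)"),
                             aberration("deletion", "del(13)")))
  expect_identical(vapply(m$matches, `[[`, character(1), "category"),
                   "Del(13/13q)")
  expect_length(m$matches[[1]]$supporting, 2L)
})

test_that("any hyperdiploid trisomy matches Hyperdiploidy, de-duplicated", {
  m <- matchLesions(kb, list(
    aberration("trisomy", 3, method = "karyotype"),
    aberration("trisomy", 9, method = "karyotype"),
    aberration("trisomy", 15, method = "karyotype")))
  expect_length(m$matches, 1L)
  expect_identical(m$matches[[1]]$category, "Hyperdiploidy")
  expect_length(m$matches[[1]]$supporting, 3L)
  # a trisomy outside the hyperdiploid set stays unmatched, not dropped
  m2 <- matchLesions(kb, list(aberration("trisomy", 8, method = "karyotype")))
  expect_length(m2$matches, 0L)
  expect_length(m2$unmatched, 1L)
})

test_that("dual-listed genes resolve by detection mechanism", {
  # sequence mutation in MMSET hits the functional Epigenetic category,
  # never the chromosomal t(4;14) category
  m <- matchLesions(kb, list(
    aberration("mutation", gene = "MMSET", consequence = "nonsynonymous")))
  expect_identical(vapply(m$matches, `[[`, character(1), "category"),
                   "Epigenetic")
  m <- matchLesions(kb, list(
    aberration("mutation", gene = "TP53", consequence = "nonsynonymous")))
  expect_identical(m$matches[[1]]$category, "DNA repair")
  m <- matchLesions(kb, list(
    aberration("mutation", gene = "BRAF", consequence = "nonsynonymous")))
  expect_identical(m$matches[[1]]$category, "Proliferation")
  # synonymous mutations are routed to the filtered side list
  m <- matchLesions(kb, list(
    aberration("mutation", gene = "BRAF", consequence = "synonymous")))
  expect_length(m$matches, 0L)
  expect_length(m$filtered, 1L)
  # unknown gene goes to the unmatched side list
  m <- matchLesions(kb, list(
    aberration("mutation", gene = "ZZZ3", consequence = "nonsynonymous")))
  expect_length(m$unmatched, 1L)
})

test_that("RAG score is the exact mean of matched group weights", {
  score <- function(abs) computeRagScore(matchLesions(kb, abs)$matches)
  # both red
  expect_identical(score(list(aberration("deletion", "del(17p)"),
                              aberration("gain", "+1q"))), 3)
  # single green
  expect_identical(score(list(aberration("trisomy", 9, method = "karyotype"))), 1)
  # red + amber + green -> mean(3, 2, 1) = 2
  expect_identical(score(list(aberration("deletion", "del(17p)"),
                              aberration("translocation", "t(4;14)"),
                              aberration("trisomy", 5, method = "karyotype"))), 2)
  # empty match set has no score
  expect_identical(computeRagScore(list()), NA_real_)
})

test_that("score is invariant to order and assay redundancy, exact vs oracle", {
  allCats <- categories(kb)
  weights <- vapply(allCats, function(x)
    c(red = 3, amber = 2, green = 1)[[x@group]], numeric(1))
  # oracle equivalence on every subset of size <= 3 (exhaustive)
  for (k in 1:3) {
    idx <- utils::combn(length(allCats), k)
    for (j in seq_len(ncol(idx))) {
      abs <- lapply(allCats[idx[, j]], lesionFor)
      got <- computeRagScore(matchLesions(kb, abs)$matches)
      expect_equal(got, mean(weights[idx[, j]]))
    }
  }
  # permutation invariance and duplicate-evidence invariance
  set.seed(42)
  for (rep in 1:25) {
    pick <- sample(length(allCats), sample(1:8, 1))
    abs <- lapply(allCats[pick], lesionFor)
    s1 <- computeRagScore(matchLesions(kb, abs)$matches)
    s2 <- computeRagScore(matchLesions(kb, abs[sample(length(abs))])$matches)
    expect_identical(s1, s2)
    # a second supporting aberration for a matched category changes nothing
    s3 <- computeRagScore(matchLesions(kb, c(abs, abs[1]))$matches)
    expect_identical(s1, s3)
    expect_true(s1 >= min(weights[pick]) && s1 <= max(weights[pick]))
  }
})

test_that("adding a green lesion to an all-red set dilutes the score", {
  reds <- list(aberration("deletion", "del(17p)"), aberration("gain", "+1q"),
               aberration("translocation", "t(14;16)"))
  s_red <- computeRagScore(matchLesions(kb, reds)$matches)
  s_mix <- computeRagScore(matchLesions(
    kb, c(reds, list(aberration("trisomy", 9, method = "karyotype"))))$matches)
  expect_identical(s_red, 3)
  expect_lt(s_mix, s_red)
})

test_that("triple enumeration agrees with literal subset enumeration", {
  # 9-category sub-model: every one of the 511 non-empty subsets scored
  # literally, compared against the count-triple enumeration
  sub <- new("RagKnowledgeBase",
             categories = categories(kb)[c(1:5, 7, 14, 17, 22)],
             version = "sub", provenance = "")
  w <- vapply(categories(sub), function(x)
    c(red = 3, amber = 2, green = 1)[[x@group]], numeric(1))
  literal <- vapply(seq_len(2^9 - 1), function(mask) {
    pick <- which(bitwAnd(mask, bitwShiftL(1L, 0:8)) != 0L)
    mean(w[pick])
  }, numeric(1))
  rng <- scoreRange(sub)
  expect_identical(rng$nSubsets, 511)
  expect_identical(rng$min, min(literal))
  expect_identical(rng$max, max(literal))
  expect_setequal(round(rng$classes$score, 12), round(unique(literal), 12))
})

test_that("risk bands follow the half-open boundary convention", {
  expect_identical(classifyRisk(3.0), "high")
  expect_identical(classifyRisk(1.2), "low")
  expect_identical(classifyRisk(2.0), "high_intermediate")
  expect_identical(classifyRisk(c(1.0, 1.4999, 1.5, 1.9999, 2.4999, 2.5)),
                   c("low", "low", "low_intermediate", "low_intermediate",
                     "high_intermediate", "high"))
  expect_error(classifyRisk(0.5), class = "rag_validation_error")
  expect_error(classifyRisk(3.01), class = "rag_validation_error")
  expect_error(classifyRisk(NA_real_), class = "rag_validation_error")
})

test_that("ISS staging reproduces the staging table and its footnote", {
  expect_identical(issStage(3.0, 3.6), "I")
  expect_identical(issStage(6.0, 4.0), "III")
  expect_identical(issStage(3.0, 3.0), "II")  # low beta2m, low albumin
  expect_identical(issStage(4.0, 4.5), "II")  # mid beta2m, any albumin
  expect_identical(issStage(3.5, 4.5), "II")  # boundary: 3.5 is not < 3.5
  expect_identical(issStage(5.5, 4.5), "III") # boundary: >= 5.5
  expect_error(issStage(-1, 4), class = "rag_validation_error")
  expect_error(issStage(3, Inf), class = "rag_validation_error")
})

test_that("every point of a dense clinical grid maps to exactly one stage", {
  grid <- expand.grid(beta2m = seq(0, 10, by = 0.1),
                      albumin = seq(0, 6, by = 0.1))
  st <- issStage(grid$beta2m, grid$albumin)
  expect_true(all(st %in% c("I", "II", "III")))
  expect_setequal(unique(st), c("I", "II", "III"))
})

test_that("ultrahigh risk needs ISS II/III and more than one adverse lesion", {
  res <- function(abs) scoreAberrations(kb, abs)
  twoAdverse <- list(aberration("gain", "+1q"),
                     aberration("deletion", "del(17p)"))
  r <- combinedReport(res(twoAdverse), iss = "II")
  expect_identical(r@adverseCount, 2L)
  expect_true(r@ultrahigh)
  r <- combinedReport(res(list(aberration("deletion", "del(17p)"))), iss = "III")
  expect_identical(r@adverseCount, 1L)
  expect_false(r@ultrahigh)
  threeAdverse <- c(twoAdverse, list(aberration("translocation", "t(14;16)")))
  r <- combinedReport(res(threeAdverse), iss = "I")
  expect_identical(r@adverseCount, 3L)
  expect_false(r@ultrahigh)
  # no clinical data -> unstaged, never ultrahigh
  r <- combinedReport(res(twoAdverse))
  expect_true(is.na(r@stage))
  expect_false(r@ultrahigh)
  # staging can be derived from raw biochemistry
  r <- combinedReport(res(twoAdverse), beta2m = 6.1, albumin = 4)
  expect_identical(r@stage, "III")
  expect_true(r@ultrahigh)
})

test_that("trajectories report per-interval deltas and category turnover", {
  s0 <- ragSample("PT", list(aberration("trisomy", 9, method = "karyotype")),
                  timepoint = 0)
  s1 <- ragSample("PT", list(aberration("trisomy", 9, method = "karyotype"),
                             aberration("deletion", "del(17p)")),
                  timepoint = 1)
  traj <- scoreTrajectory(list(s1, s0), kb)  # unordered input
  expect_identical(traj$timepoint, c(0, 1))
  expect_identical(traj$score, c(1, 2))
  expect_identical(traj$delta, c(NA_real_, 1))
  expect_identical(traj$new_categories, c("", "Del(17p)"))
  expect_identical(traj$lost_categories, c("", ""))

  single <- scoreTrajectory(list(s0), kb)
  expect_identical(nrow(single), 1L)
  expect_identical(single$delta, NA_real_)

  same <- scoreTrajectory(list(s0, ragSample("PT", aberrations(s0),
                                             timepoint = 2)), kb)
  expect_identical(same$delta, c(NA_real_, 0))

  dup <- ragSample("PT", list(), timepoint = 0)
  expect_error(scoreTrajectory(list(s0, dup), kb),
               "duplicate", class = "rag_validation_error")
})

test_that("scoreSample binds lesions to clinical staging in one call", {
  s <- ragSample("S9", list(aberration("gain", "+1q"),
                            aberration("deletion", "del(17p)")),
                 beta2m = 5.9, albumin = 4.1)
  rep <- scoreSample(kb, s)
  expect_identical(ragScore(rep), 3)
  expect_identical(riskBand(rep), "high")
  expect_identical(rep@stage, "III")
  expect_true(rep@ultrahigh)
})
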