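test_that("fixture generation is fully determined by the seed", {
  a <- makeToyModel(seed = 1); b <- makeToyModel(seed = 1)
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$model@gpr, b$model@gpr)
  expect_identical(as.matrix(a$model@S), as.matrix(b$model@S))
  c <- makeToyModel(seed = 2)
  expect_false(identical(a$model@gpr, c$model@gpr))
})

test_that("rule composition follows the requested fractions", {
  fx <- makeToyModel(seed = 3, isozymeFraction = 0, complexFraction = 0)
  internal <- grepl("^(CHN|BRN)", fx$model@reactionIds)
  expect_true(all(lengths(lapply(fx$model@gpr[internal], parseGeneRule)) == 1))
  expect_true(all(lengths(unlist(lapply(fx$model@gpr[internal],
                                        parseGeneRule),
                          recursive = FALSE)) == 1))
  fx2 <- makeToyModel(seed = 3, isozymeFraction = 1, complexFraction = 0)
  nAlt <- lengths(lapply(fx2$model@gpr[grepl("^(CHN|BRN)",
                                             fx2$model@reactionIds)],
                         parseGeneRule))
  expect_true(all(nAlt >= 2))
})

test_that("generated models carry a feasible nonzero objective", {
  for (seed in 1:5)
    expect_gt(fba(makeToyModel(seed = seed)$model)$objective, 1e-6)
})

test_that("the Calvin fixture is carbon- and phosphate-balanced", {
  m <- makeCalvinFixture()
  carbon <- c(co2 = 1, rubp = 5, pga = 3, bpg = 3, gap = 3, dhap = 3,
              fbp = 6, f6p = 6, e4p = 4, sbp = 7, s7p = 7, x5p = 5,
              r5p = 5, ru5p = 5, atp = 10, adp = 10, pi = 0, nadh = 21,
              nad = 21, h2o = 0)
  phos <- c(co2 = 0, rubp = 2, pga = 1, bpg = 2, gap = 1, dhap = 1,
            fbp = 2, f6p = 1, e4p = 1, sbp = 2, s7p = 1, x5p = 1,
            r5p = 1, ru5p = 1, atp = 3, adp = 2, pi = 1, nadh = 2,
            nad = 2, h2o = 0)
  internal <- c("RBC", "PGK", "GAPDH", "TPI", "FBA", "FBPase", "TKT1",
                "SBA", "SBPase", "TKT2", "RPE", "RPI", "PRK")
  S <- as.matrix(m@S); rownames(S) <- m@metaboliteIds
  for (rx in internal) {
    col <- S[, match(rx, m@reactionIds)]
    expect_equal(sum(col * carbon[m@metaboliteIds]), 0, label = paste(rx, "C"))
    expect_equal(sum(col * phos[m@metaboliteIds]), 0, label = paste(rx, "P"))
  }
})

test_that("Calvin FBA costs are 9 ATP and 6 NADH per triose exported", {
  m <- makeCalvinFixture()
  k <- match("EX_gap", m@reactionIds)
  m@lb[k] <- 1; m@ub[k] <- 1
  expect_equal(fba(m, "ATPS", sense = "min")$objective, 9, tolerance = 1e-6)
  expect_equal(fba(m, "NADHS", sense = "min")$objective, 6, tolerance = 1e-6)
})

test_that("synthetic transcriptomes track their generating proteomes", {
  fx <- makeToyModel(seed = 4)
  pcm <- buildPCModel(fx$model, fx$proteins, P = 10)
  tr <- makeSyntheticTranscriptomes(pcm, 3, sigma = 0, nanFraction = 0,
                                    seed = 5)
  expect_equal(tr$T, tr$pTrue)
  # multiplicative lognormal noise: per-gene log-ratios within +-3 sigma
  # for (nearly) all genes
  tr2 <- makeSyntheticTranscriptomes(pcm, 5, sigma = 0.2, nanFraction = 0,
                                     seed = 6)
  pos <- tr2$pTrue > 0
  ratios <- log(tr2$T[pos] / tr2$pTrue[pos])
  expect_gte(mean(abs(ratios) <= 3 * 0.2), 0.99)
  # missingness close to the requested rate
  tr3 <- makeSyntheticTranscriptomes(pcm, 20, sigma = 0.2, nanFraction = 0.2,
                                     seed = 7)
  expect_gt(mean(is.na(tr3$T)), 0.08)
  expect_lt(mean(is.na(tr3$T)), 0.35)
})

test_that("fixtures re-enter the pipeline through the public readers only", {
  dir <- withr::local_tempdir()
  writeFixtures(dir, kind = "timecourse", seed = 2, nSamples = 2, P = 10)
  m1 <- readMetabolicModel(file.path(dir, "toy.xml"))
  m2 <- readMetabolicModel(file.path(dir, "toy.json"))
  expect_identical(m1@reactionIds, m2@reactionIds)
  prot <- readProteinFasta(file.path(dir, "toy.faa"))
  pcm <- buildPCModel(m1, prot, P = 10)
  t <- alignTranscripts(pcm, readTranscripts(
    file.path(dir, "transcripts_s01.tsv")))
  fit <- fitProteome(pcm, scaleTranscriptome(t, pcm@d, pcm@P))
  expect_solved(fit)
})
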