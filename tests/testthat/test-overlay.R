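test_that("transcriptome scaling hits the budget and is scale invariant", {
  d <- c(0.05, 0.10); P <- 150
  t <- c(1, 1)
  ts <- scaleTranscriptome(t, d, P)
  expect_equal(ts, c(1000, 1000))       # 150 / 0.15
  expect_equal(sum(ts * d), P)
  expect_equal(scaleTranscriptome(2 * t, d, P), ts)  # scale invariance
  tsOK <- scaleTranscriptome(ts, d, P)
  expect_equal(tsOK, ts)                # already scaled -> unchanged
  tna <- c(10, NA)
  tsna <- scaleTranscriptome(tna, d, P)
  expect_equal(sum(tsna * d, na.rm = TRUE), P)
  expect_true(is.na(tsna[2]))
  expect_error(scaleTranscriptome(c(0, 0), d, P), "positive")
})

test_that("weights emphasise low and absent expression", {
  w <- buildWeights(c(4, 0, NA, 0.5))
  expect_equal(unname(w), c(0.25, 1, 0, 2))
})

test_that("a transcriptome generated from a feasible proteome is recovered", {
  fx <- makeToyModel(seed = 6)
  pcm <- buildPCModel(fx$model, fx$proteins, P = 10)
  tr <- makeSyntheticTranscriptomes(pcm, 1, sigma = 0, nanFraction = 0,
                                    seed = 3)
  t <- scaleTranscriptome(tr$T[1, ], pcm@d, pcm@P)
  fit <- fitProteome(pcm, t)
  expect_solved(fit)
  expect_lt(fit@objective, 1e-6)
  expect_equal(unname(fit@pFit), unname(t), tolerance = 1e-4)
})

test_that("an over-budget target is projected onto the budget plane (KKT)", {
  # 2-protein model, only the budget couples p; analytic weighted
  # least-squares projection: p_i = t_i - lambda d_i / (2 w_i)
  S <- Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2), x = c(1, -1),
                            dims = c(1, 2))
  m <- newMetabolicModel(c("IN", "R1"), "a", c("g1", "g2"), S,
                         lb = c(0, 0), ub = c(10, 10),
                         gpr = c("", "g1 or g2"))
  prot <- data.frame(geneId = c("g1", "g2"), mw = c(0.05, 0.10))
  pcm <- buildPCModel(m, prot, P = 10)
  t <- c(g1 = 150, g2 = 60)                    # t'd = 13.5 > P
  w <- c(1, 1)
  fit <- fitProteome(pcm, t, w = w)
  expect_solved(fit)
  d <- unname(pcm@d)
  lambda <- 2 * (sum(t * d) - 10) / sum(d^2 / w)
  pStar <- unname(t) - lambda * d / (2 * w)
  expect_equal(unname(fit@pFit), pStar, tolerance = 1e-4)
  expect_equal(sum(fit@pFit * d), 10, tolerance = 1e-6)
  expect_gt(fit@objective, 0)
  # all-zero weights: objective is empty
  fit0 <- fitProteome(pcm, t, w = c(0, 0))
  expect_equal(fit0@objective, 0, tolerance = 1e-8)
})

test_that("contextualisation applies slack bounds per measurement status", {
  fx <- makeToyModel(seed = 6)
  pcm <- buildPCModel(fx$model, fx$proteins, P = 10)
  tr <- makeSyntheticTranscriptomes(pcm, 1, sigma = 0.1, nanFraction = 0.2,
                                    seed = 4)
  t <- scaleTranscriptome(tr$T[1, ], pcm@d, pcm@P)
  fit <- fitProteome(pcm, t)
  ctx <- contextualize(pcm, fit, s = 0.02)
  cons <- pcflux:::contextConstraints(ctx)
  meas <- ctx@measured
  expect_equal(cons$lb[cons$ip][meas], 0.98 * ctx@pFit[meas])
  expect_equal(cons$ub[cons$ip][meas], ctx@pFit[meas])
  expect_equal(cons$lb[cons$ip][!meas], rep(0, sum(!meas)))
  expect_equal(cons$ub[cons$ip][!meas], pcm@pUb[!meas])
  # s = 0 pins measured proteins exactly
  ctx0 <- contextualize(pcm, fit, s = 0)
  cons0 <- pcflux:::contextConstraints(ctx0)
  expect_equal(cons0$lb[cons0$ip][meas], ctx0@pFit[meas])
  expect_error(contextualize(pcm, fit, s = 1), "slack")
  expect_error(contextualize(pcm, fit, s = -0.1), "slack")
  # the fitted proteome is a feasibility witness
  expect_solved(pcFBA(ctx))
})

test_that("fit objective is non-increasing as the budget grows", {
  fx <- makeToyModel(seed = 7)
  tGen <- buildPCModel(fx$model, fx$proteins, P = 10)
  tr <- makeSyntheticTranscriptomes(tGen, 1, sigma = 0.3, nanFraction = 0,
                                    seed = 5)
  objs <- vapply(c(2, 5, 10, 20), function(P) {
    pcm <- buildPCModel(fx$model, fx$proteins, P = P)
    t <- scaleTranscriptome(tr$T[1, ], pcm@d, 2)  # same absolute target
    fitProteome(pcm, t)@objective
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-6))
})

test_that("the optimum is insensitive to slack within a reasonable range", {
  fx <- makeToyModel(seed = 8)
  pcm <- buildPCModel(fx$model, fx$proteins, P = 10)
  tr <- makeSyntheticTranscriptomes(pcm, 1, sigma = 0.2, nanFraction = 0,
                                    seed = 6)
  t <- scaleTranscriptome(tr$T[1, ], pcm@d, pcm@P)
  fit <- fitProteome(pcm, t)
  opts <- vapply(c(0.01, 0.02, 0.05), function(s)
    pcFBA(contextualize(pcm, fit, s = s))$objective, numeric(1))
  expect_lt(max(opts) - min(opts), 0.05 * max(abs(opts)))
})
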