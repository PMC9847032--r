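makeCtx <- function(seed = 1, P = 10, sigma = 0, nanFraction = 0) {
  fx <- makeToyModel(seed = seed)
  pcm <- buildPCModel(fx$model, fx$proteins, P = P)
  tr <- makeSyntheticTranscriptomes(pcm, 1, sigma = sigma,
                                    nanFraction = nanFraction, seed = seed)
  t <- scaleTranscriptome(tr$T[1, ], pcm@d, pcm@P)
  contextualize(pcm, fitProteome(pcm, t), s = 0.02)
}

test_that("flux intervals at fraction zero equal plain variability", {
  fx <- makeToyModel(seed = 12)
  pcm <- buildPCModel(fx$model, fx$proteins, P = 1e6)  # vacuous constraints
  fv <- pcFVA(pcm, "EX", fractions = 0)
  oracle <- bruteFVA(fx$model@S, fx$model@lb, fx$model@ub)
  expect_equal(fv$vmin, oracle$vmin, tolerance = 1e-5)
  expect_equal(fv$vmax, oracle$vmax, tolerance = 1e-5)
})

test_that("a full-optimum cut collapses a unique pathway to a point", {
  fx <- chainFixture()
  fv <- pcFVA(fx$pcm, "EX_b", fractions = c(0, 1))
  at1 <- fv[fv$fraction == 1, ]
  expect_equal(at1$vmin, at1$vmax, tolerance = 1e-4)
  expect_equal(at1$vmax, rep(702, 3), tolerance = 1e-3)
})

test_that("intervals are nested across increasing optimum fractions", {
  for (seed in c(1, 3, 5)) {
    ctx <- makeCtx(seed = seed, sigma = 0.2)
    fv <- pcFVA(ctx, "EX", fractions = c(0, 0.5, 0.9, 0.99))
    expect_true(all(fv$status == "optimal"), label = sprintf("seed %d", seed))
    for (d in split(fv, fv$reaction)) {
      d <- d[order(d$fraction), ]
      expect_true(all(diff(d$vmin) >= -1e-5), label = d$reaction[1])
      expect_true(all(diff(d$vmax) <= 1e-5), label = d$reaction[1])
    }
  }
})

test_that("classification thresholds reproduce the stated rules", {
  # constructed flux/transcript series with known Spearman rho
  S <- Matrix::sparseMatrix(i = 1, j = 1, x = -1, dims = c(1, 3))
  S[1, 2] <- 1; S[1, 3] <- 0
  m <- newMetabolicModel(c("R1", "R2", "R3"), "a", c("g1", "g2"), S,
                         lb = rep(0, 3), ub = rep(10, 3),
                         gpr = c("g1", "g2", ""))
  mkFVA <- function(vmax) {
    data.frame(reaction = c("R1", "R2", "R3"), fraction = 0,
               vmin = 0, vmax = vmax, status = "optimal")
  }
  # R1: rho = 1 with its transcripts; R2: perfectly anti-correlated
  n <- 8
  fvas <- lapply(seq_len(n), function(s) mkFVA(c(s, n - s, 1)))
  ts <- lapply(seq_len(n), function(s) c(g1 = s * 2, g2 = s * 3))
  cls <- classifyReactions(fvas, ts, m)
  expect_identical(cls$class[cls$reaction == "R1"], "expression_dependent")
  expect_equal(cls$rho[cls$reaction == "R1"], 1)
  expect_identical(cls$class[cls$reaction == "R2"], "expression_independent")
  expect_equal(cls$rho[cls$reaction == "R2"], -1)
  # spontaneous reactions are always expression-independent
  expect_identical(cls$class[cls$reaction == "R3"], "expression_independent")
  expect_true(is.na(cls$rho[cls$reaction == "R3"]))

  # rho = 0.9 and rho = -0.25 series hit the stated classes
  x <- c(1, 2, 3, 4, 5)
  y9 <- c(1, 2, 3, 5, 4)      # rho = 0.9
  stopifnot(abs(cor(x, y9, method = "spearman") - 0.9) < 1e-9)
  fvas2 <- lapply(seq_along(x), function(s) mkFVA(c(y9[s], 0, 0)))
  ts2 <- lapply(seq_along(x), function(s) c(g1 = x[s], g2 = 1))
  cls2 <- classifyReactions(fvas2, ts2, m)
  expect_identical(cls2$class[1], "expression_dependent")
  y25 <- c(3, 5, 1, 4, 2)
  rho25 <- cor(x, y25, method = "spearman")
  fvas3 <- lapply(seq_along(x), function(s) mkFVA(c(y25[s], 0, 0)))
  cls3 <- classifyReactions(fvas3, ts2, m)
  expect_equal(cls3$rho[1], rho25)
  expect_identical(cls3$class[1], "expression_independent")
})

test_that("classification is invariant to monotone transcript rescaling", {
  S <- Matrix::sparseMatrix(i = 1, j = 1, x = -1, dims = c(1, 1))
  m <- newMetabolicModel("R1", "a", "g1", S, lb = 0, ub = 10, gpr = "g1")
  mkFVA <- function(vmax) data.frame(reaction = "R1", fraction = 0,
                                     vmin = 0, vmax = vmax, status = "optimal")
  fvas <- lapply(c(2, 5, 3, 9, 7), function(v) mkFVA(v))
  ts <- lapply(c(1, 4, 2, 8, 6), function(v) c(g1 = v))
  base <- classifyReactions(fvas, ts, m)
  resc <- classifyReactions(fvas, lapply(ts, function(t) t^3 * 100 + 1), m)
  expect_equal(base$rho, resc$rho)
  expect_identical(base$class, resc$class)
})

test_that("consistency metrics and outlier ratios follow the definitions", {
  t <- c(a = 10, b = 20, c = 30, d = 40)
  r0 <- consistencyReport(t, t)
  expect_equal(r0@r2, 1); expect_equal(r0@r2Star, 1)
  expect_identical(r0@outliers, character(0))
  # one gene at exactly 3x is an outlier (inclusive), not a far outlier
  p1 <- t; p1["b"] <- 60
  r1 <- consistencyReport(p1, t)
  expect_identical(r1@outliers, "b")
  expect_identical(r1@farOutliers, character(0))
  # zero against positive is infinitely inconsistent
  p2 <- t; p2["c"] <- 0
  r2 <- consistencyReport(p2, t)
  expect_true("c" %in% r2@farOutliers)
  # symmetric: under-prediction counts the same as over-prediction
  p3 <- t; p3["d"] <- t["d"] / 10
  expect_true("d" %in% consistencyReport(p3, t)@farOutliers)
  # NA transcripts and (0,0) pairs are excluded
  r4 <- consistencyReport(c(t, e = 5, f = 0), c(t, e = NA, f = 0))
  expect_identical(r4@nPairs, 4L)
  expect_error(consistencyReport(c(1), c(1)), "2 usable")
})

test_that("matched pairs beat shuffled pairs on correlated data", {
  set.seed(31)
  wins <- 0L
  for (i in 1:100) {
    p <- 10^stats::runif(30, 0, 2)
    t <- p * exp(0.3 * stats::rnorm(30))
    names(p) <- names(t) <- paste0("g", 1:30)
    r2m <- consistencyReport(p, t)@r2
    r2s <- consistencyReport(sample(unname(p)), unname(t))@r2
    if (r2m >= r2s) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("persistent far outliers are counted and ordered", {
  mkRep <- function(far) pcflux:::.s4("ConsistencyReport", r2 = 1,
                                      r2Star = 1, outliers = far,
                                      farOutliers = far, nPairs = 10L)
  reps <- c(lapply(1:9, function(i) mkRep("gA")),
            lapply(1:8, function(i) mkRep(c("gB", "gA"))))
  out <- flagPersistentOutliers(reps, minSamples = 8)
  expect_identical(out$gene, c("gA", "gB"))
  expect_identical(out$count, c(17L, 8L))
  expect_identical(nrow(flagPersistentOutliers(reps, minSamples = 20)), 0L)
  # 7 of 16 does not reach an 8-sample threshold
  reps2 <- c(lapply(1:7, function(i) mkRep("gC")),
             lapply(1:9, function(i) mkRep(character(0))))
  expect_identical(nrow(flagPersistentOutliers(reps2, minSamples = 8)), 0L)
})
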