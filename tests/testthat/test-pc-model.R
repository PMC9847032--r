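test_that("complex enumeration deduplicates globally and routes via B", {
  S <- Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2), x = c(-1, -1),
                            dims = c(1, 2))
  m <- newMetabolicModel(c("R1", "R2"), "a", c("g1", "g2", "g3"), S,
                         lb = c(0, 0), ub = c(10, 10),
                         gpr = c("g1", "g1"))
  p <- data.frame(geneId = c("g1", "g2", "g3"), mw = c(0.05, 0.02, 0.03))
  ce <- enumerateComplexes(m, p)
  expect_identical(length(ce$complexes@complexIds), 1L)
  expect_identical(nrow(ce$enzymes@B), 2L)
  expect_equal(Matrix::colSums(ce$enzymes@B), c(`g1` = 2))

  m2 <- newMetabolicModel("R1", "a",  c("g1", "g2", "g3"),
                          Matrix::sparseMatrix(i = 1, j = 1, x = -1,
                                               dims = c(1, 1)),
                          lb = 0, ub = 10, gpr = "(g1 and g2) or g3")
  ce2 <- enumerateComplexes(m2, p)
  expect_setequal(ce2$complexes@complexIds, c("g1+g2", "g3"))
  expect_equal(sum(ce2$enzymes@B[1, ]), 2)
  expect_equal(ce2$complexes@mw[match("g1+g2", ce2$complexes@complexIds)],
               0.07)
})

test_that("curation overrides subunit copy numbers", {
  S <- Matrix::sparseMatrix(i = 1, j = 1, x = -1, dims = c(1, 1))
  m <- newMetabolicModel("R1", "a", c("g1", "g2"), S, lb = 0, ub = 10,
                         gpr = "g1 and g2")
  p <- data.frame(geneId = c("g1", "g2"), mw = c(0.05, 0.02))
  cur <- data.frame(complex = "g1+g2", gene = "g1", copies = 2)
  ce <- enumerateComplexes(m, p, curation = cur)
  expect_equal(ce$complexes@C["g1", "g1+g2"], 2)
  expect_equal(ce$complexes@mw, 2 * 0.05 + 0.02)
  badCur <- data.frame(complex = "g1+g2", gene = "gX", copies = 2)
  expect_error(enumerateComplexes(m, p, curation = badCur), "gX")
})

test_that("initial rate ratios follow the mass^(3/4) surface scaling", {
  mk <- function(mw) {
    C <- Matrix::sparseMatrix(i = seq_along(mw), j = seq_along(mw),
                              x = 1, dims = c(length(mw), length(mw)))
    pcflux:::.s4("ComplexSet", complexIds = paste0("c", seq_along(mw)),
                 C = pcflux:::.as_dgc(C), mw = mw)
  }
  expect_equal(estimateROri(mk(c(2, 2, 2))), c(1, 1, 1))
  # X = (81, 1): pre-normalisation ratios (81/41)^.75, (1/41)^.75
  r <- estimateROri(mk(c(81, 1)))
  pre <- c((81 / 41)^0.75, (1 / 41)^0.75)
  expect_equal(r, pre / mean(pre), tolerance = 1e-12)
  expect_equal(mean(r), 1, tolerance = 1e-12)
  # uniform rescaling of masses cancels
  expect_equal(estimateROri(mk(c(81, 1) * 7)), r)
  expect_error(estimateROri(mk(c(1, 0))), "mass")
})

test_that("proteome budget scales the total fraction by modelled share", {
  t <- c(1, 1); d <- c(0.05, 0.05)
  expect_equal(estimateProteomeBudget(t, d, t, d), 600)
  # modelled fraction 0.25 -> 150
  expect_equal(estimateProteomeBudget(c(4, 4), c(0.05, 0.05), c(1, 1),
                                      c(0.05, 0.05)), 150)
  # half NaN, measured fraction 0.1 -> 600 * 0.1 * 2
  tcp <- rep(1, 10); dcp <- rep(0.1, 10)
  tm <- c(0.2, NA); dm <- c(0.5, 0.5)
  expect_equal(estimateProteomeBudget(tcp, dcp, tm, dm), 600 * 0.1 * 2)
  expect_error(estimateProteomeBudget(t, d, c(NA_real_, NA_real_), d), "missing")
})

test_that("single-enzyme chain optimum equals the closed form kappa*P/d", {
  fx <- chainFixture(d1 = 0.05, P = 150)
  sol <- pcFBA(fx$pcm, "EX_b")
  kappa <- 65 * 3600e-6
  expect_solved(sol)
  expect_equal(sol$objective, kappa * 150 / 0.05, tolerance = 1e-5)
  expect_equal(unname(sol$p["g1"]), 3000, tolerance = 1e-4)
  # zero budget blocks all enzymatic flux
  fx0 <- chainFixture(P = 0)
  expect_equal(pcFBA(fx0$pcm, "EX_b")$objective, 0, tolerance = 1e-6)
})

test_that("spontaneous reactions keep their original bounds", {
  fx <- chainFixture()
  cons <- pcflux:::pcConstraints(fx$pcm)
  iv <- cons$iv
  expect_equal(cons$lb[iv], fx$model@lb)
  expect_equal(cons$ub[iv], fx$model@ub)
  # no enzyme rows reference EX_a / EX_b
  expect_identical(fx$pcm@enzymes@rxnIds, "R1")
})

test_that("relaxing the proteome budget recovers plain FBA", {
  for (seed in 1:8) {
    fx <- makeToyModel(seed = seed)
    ref <- fba(fx$model)$objective
    pcm <- buildPCModel(fx$model, fx$proteins, P = 1e7)
    got <- pcFBA(pcm)$objective
    expect_equal(got, ref, tolerance = 1e-6, label = sprintf("seed %d", seed))
  }
})

test_that("PC-FBA optimum is monotone in the proteome budget", {
  fx <- makeToyModel(seed = 2)
  vals <- vapply(c(0.5, 1, 2, 5, 10, 50),
                 function(P) pcFBA(buildPCModel(fx$model, fx$proteins,
                                                P = P))$objective,
                 numeric(1))
  expect_true(all(diff(vals) >= -1e-6))
})

test_that("feasible points respect budget and subunit availability", {
  fx <- makeToyModel(seed = 4)
  pcm <- buildPCModel(fx$model, fx$proteins, P = 5)
  sol <- pcFBA(pcm)
  expect_solved(sol)
  expect_lte(sum(sol$p * pcm@d), pcm@P + 1e-6)
  slackCx <- sol$p - as.numeric(pcm@complexes@C %*% sol$x)
  expect_true(all(slackCx >= -1e-6))  # excess protein allowed, deficit not
  expect_true(all(sol$p >= -1e-8) && all(sol$x >= -1e-8) &&
              all(sol$eFor >= -1e-8) && all(sol$eRev >= -1e-8))
})

test_that("flipping a reaction's direction convention leaves the optimum", {
  fx <- chainFixture()
  m <- fx$model
  k <- match("R1", m@reactionIds)
  m2 <- m
  m2@S[, k] <- -m@S[, k]
  oldLb <- m@lb[k]; oldUb <- m@ub[k]
  m2@lb[k] <- -oldUb; m2@ub[k] <- -oldLb
  pcm2 <- buildPCModel(m2, fx$proteins, P = 150)
  expect_equal(pcFBA(pcm2, "EX_b")$objective,
               pcFBA(fx$pcm, "EX_b")$objective, tolerance = 1e-5)
})

test_that("Calvin PC model reproduces pathway ATP and NADH costs", {
  m <- makeCalvinFixture()
  k <- match("EX_gap", m@reactionIds)
  m@lb[k] <- 1; m@ub[k] <- 1
  pcm <- buildPCModel(m, makeCalvinProteins(), P = 1000)
  expect_equal(pcFBA(pcm, "ATPS", sense = "min")$objective, 9,
               tolerance = 1e-5)
  expect_equal(pcFBA(pcm, "NADHS", sense = "min")$objective, 6,
               tolerance = 1e-5)
})

test_that("proteome allocation fractions sum to one and split evenly", {
  fx <- chainFixture()
  sol <- pcFBA(fx$pcm, "EX_b")
  al <- proteomeAllocation(fx$pcm, sol$p)
  expect_equal(sum(al$fraction), 1, tolerance = 1e-9)
  expect_identical(al$subsystem, "(unassigned)")
  # all-zero proteome -> empty table
  empty <- proteomeAllocation(fx$pcm, stats::setNames(0, "g1"))
  expect_identical(nrow(empty), 0L)
  # two equal-mass proteins in different subsystems -> 0.5 / 0.5
  fx2 <- makeToyModel(seed = 9, isozymeFraction = 0, complexFraction = 0)
  pcm2 <- buildPCModel(fx2$model, fx2$proteins, P = 10)
  p <- stats::setNames(rep(0, length(geneIds(pcm2))), geneIds(pcm2))
  g1 <- pcflux:::.gpr_genes(fx2$model@gpr[match("CHN01", fx2$model@reactionIds)])
  g2 <- pcflux:::.gpr_genes(fx2$model@gpr[grep("BRN", fx2$model@reactionIds)[1]])
  if (!identical(g1, g2)) {
    p[g1] <- 1 / pcm2@d[g1]; p[g2] <- 1 / pcm2@d[g2]
    al2 <- proteomeAllocation(pcm2, p)
    expect_equal(sort(al2$fraction), c(0.5, 0.5), tolerance = 1e-6)
  }
})
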