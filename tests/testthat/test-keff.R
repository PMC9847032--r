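test_that("well-separated expression blobs are recovered by clustering", {
  set.seed(21)
  ng <- 40L
  centers <- matrix(10^stats::runif(4 * ng, 0, 3), 4)
  T <- centers[rep(1:4, each = 3), ] * exp(0.01 * stats::rnorm(12 * ng))
  rownames(T) <- sprintf("s%02d", 1:12)
  cl <- clusterSamples(T, 4)
  # oracle: exhaustive scoring — members of the same blob must co-cluster
  blob <- rep(1:4, each = 3)
  agree <- outer(cl$membership, cl$membership, "==") ==
    outer(blob, blob, "==")
  expect_true(all(agree))
  expect_identical(dim(cl$means), c(4L, ng))
})

test_that("clustering edge cases behave deterministically", {
  T <- matrix(stats::runif(15, 1, 10), 5,
              dimnames = list(paste0("s", 1:5), NULL))
  expect_identical(clusterSamples(T, 5)$membership, 1:5)
  expect_error(clusterSamples(T, 0), "at least 1")
  expect_error(clusterSamples(T, 6), "exceeds")
  # identical samples split by tie-break: group means must be identical
  Tid <- matrix(rep(c(1, 2, 3), each = 4), 4)
  cl <- clusterSamples(Tid, 2)
  expect_identical(sort(unique(cl$membership)), 1:2)
  expect_equal(cl$means[1, ], cl$means[2, ])
})

test_that("the free mask follows the group-mean abundance rule", {
  C <- pcflux:::.as_dgc(Matrix::sparseMatrix(i = 1:3, j = 1:3, x = 1,
                                             dims = c(3, 3)))
  gm <- rbind(c(10, 5, 0.1), c(8, 9, 0.2))  # means 5.03, 5.73
  expect_identical(buildFreeMask(gm, C), c(TRUE, TRUE, FALSE))
  # uniform transcriptome: >= is inclusive, all complexes free
  expect_identical(buildFreeMask(rbind(c(2, 2, 2)), C), rep(TRUE, 3))
  # subunit below every group mean -> fixed
  expect_identical(buildFreeMask(rbind(c(10, 0.1, 20)), C),
                   c(FALSE, FALSE, TRUE))
})

test_that("data generated at the initial rate constants keep r unchanged", {
  kf <- makeKeffFixture()
  gms <- lapply(kf$demands, function(q)
    buildPCModel(applyDemands(kf$model, q), kf$proteins, P = kf$P))
  pcm <- gms[[1]]
  # transcriptomes = minimal proteomes generated AT rOri
  kappa <- pcm@rates@kappa
  gm0 <- t(vapply(kf$demands, function(q)
    c(gA = q[["EX1"]] / kappa, gB = q[["EX2"]] / kappa,
      gC = q[["EX3"]] / kappa), c(gA = 0, gB = 0, gC = 0)))
  resid <- solveKeffNCQP(pcm, gm0, freeMask = c(TRUE, TRUE, FALSE),
                         groupModels = gms, method = "alternating",
                         nStarts = 1)
  expect_equal(resid$r, pcm@rates@rOri, tolerance = 1e-3)
  expect_lt(resid$objective, resid$objectiveInitial + 1e-9)
})

test_that("a perturbed rate vector is recovered from noiseless groups", {
  kf <- makeKeffFixture()
  gms <- lapply(kf$demands, function(q)
    buildPCModel(applyDemands(kf$model, q), kf$proteins, P = kf$P))
  res <- solveKeffNCQP(gms[[1]], kf$groupMeans, groupModels = gms,
                       method = "alternating", nStarts = 2, seed = 1)
  expect_equal(unname(res$r), unname(kf$rTrue), tolerance = 0.01)
  expect_lt(res$objective, 1e-4)
  # hard constraint assertions
  expect_equal(mean(res$r), 1, tolerance = 1e-9)
  expect_identical(res$r[!res$freeMask], res$rOri[!res$freeMask])
  expect_true(all(res$r >= 0.1 * res$rOri - 1e-9) &&
              all(res$r <= 1.9 * res$rOri + 1e-9))
  # only free complexes moved
  expect_lte(sum(abs(res$r - res$rOri) > 1e-9), sum(res$freeMask))
})

test_that("perturbing a mask-fixed complex leaves its ratio at the start", {
  kf <- makeKeffFixture()
  gms <- lapply(kf$demands, function(q)
    buildPCModel(applyDemands(kf$model, q), kf$proteins, P = kf$P))
  # data generated with the fixed complex (gC) perturbed: r stays put
  kappa <- gms[[1]]@rates@kappa
  gmPert <- t(vapply(kf$demands, function(q)
    c(gA = q[["EX1"]] / (kappa * kf$rTrue[1]),
      gB = q[["EX2"]] / (kappa * kf$rTrue[2]),
      gC = q[["EX3"]] / (kappa * 1.5)), c(gA = 0, gB = 0, gC = 0)))
  res <- suppressWarnings(
    solveKeffNCQP(gms[[1]], gmPert, freeMask = c(TRUE, TRUE, FALSE),
                  groupModels = gms, method = "alternating", nStarts = 1))
  expect_identical(res$r[3], res$rOri[3])
})
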