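# Shared in-code fixtures and independent oracles.

# single-enzyme linear chain EX_a -> R1(g1) -> EX_b; closed-form PC optimum
# is kappa * P / d for the budget-limited enzyme
chainFixture <- function(d1 = 0.05, P = 150) {
  S <- Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 2, 2, 3),
                            x = c(1, -1, 1, -1), dims = c(2, 3))
  model <- newMetabolicModel(c("EX_a", "R1", "EX_b"), c("a", "b"), "g1", S,
                             lb = c(0, 0, 0), ub = c(1e5, 1e5, 1e5),
                             obj = c(0, 0, 1), gpr = c("", "g1", ""))
  proteins <- data.frame(geneId = "g1", sequence = "X", mw = d1)
  list(model = model, proteins = proteins,
       pcm = buildPCModel(model, proteins, P = P))
}

# truth-table oracle: minimal satisfying gene sets of a GPR by exhaustive
# enumeration (independent of the package's parser)
minimalSatSets <- function(rule, genes) {
  expr <- gsub("\\band\\b", "&", rule, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  pe <- parse(text = expr)[[1]]
  sat <- list()
  ng <- length(genes)
  for (mask in 0:(2^ng - 1)) {
    on <- genes[bitwAnd(mask, 2^(seq_len(ng) - 1)) > 0]
    env <- as.list(stats::setNames(genes %in% on, genes))
    if (isTRUE(eval(pe, env))) sat[[length(sat) + 1L]] <- sort(on)
  }
  keep <- vapply(seq_along(sat), function(i)
    !any(vapply(seq_along(sat), function(j)
      j != i && length(sat[[j]]) < length(sat[[i]]) &&
        all(sat[[j]] %in% sat[[i]]), logical(1))), logical(1))
  out <- unique(sat[keep])
  out[order(vapply(out, paste, "", collapse = "\r"))]
}

# random GPR generator (depth-limited, valid gene identifiers)
randomRule <- function(genes, depth = 0) {
  if (depth >= 4 || stats::runif(1) < 0.4) return(sample(genes, 1))
  op <- sample(c(" and ", " or "), 1)
  left <- randomRule(genes, depth + 1)
  right <- randomRule(genes, depth + 1)
  if (stats::runif(1) < 0.5) paste0("(", left, op, right, ")")
  else paste0(left, op, right)
}

# brute-force FVA oracle: vertex enumeration of {S v = 0, lb <= v <= ub}
# for small bounded networks
bruteFVA <- function(S, lb, ub) {
  S <- as.matrix(S)
  nr <- ncol(S)
  rk <- qr(S)$rank
  nfree <- nr - rk
  verts <- list()
  combs <- utils::combn(nr, nfree, simplify = FALSE)
  for (fixedIdx in combs) {
    freeIdx <- setdiff(seq_len(nr), fixedIdx)
    Sf <- S[, freeIdx, drop = FALSE]
    if (qr(Sf)$rank < rk) next
    grid <- expand.grid(rep(list(c(1, 2)), nfree))
    for (gi in seq_len(nrow(grid))) {
      vfix <- ifelse(unlist(grid[gi, ]) == 1, lb[fixedIdx], ub[fixedIdx])
      rhs <- -as.numeric(S[, fixedIdx, drop = FALSE] %*% vfix)
      vfree <- tryCatch(qr.solve(Sf, rhs), error = function(e) NULL)
      if (is.null(vfree)) next
      v <- numeric(nr); v[fixedIdx] <- vfix; v[freeIdx] <- vfree
      if (max(abs(S %*% v)) < 1e-8 &&
          all(v >= lb - 1e-8) && all(v <= ub + 1e-8))
        verts[[length(verts) + 1L]] <- v
    }
  }
  V <- do.call(rbind, verts)
  list(vmin = apply(V, 2, min), vmax = apply(V, 2, max))
}

expect_solved <- function(res) {
  st <- if (is.list(res)) res$status else res@status
  expect_identical(st, "optimal")
}

# a context model whose production is capped by one known protein
bottleneckContext <- function() {
  # a -> b via R1 (gene g1); b export is the product; g2 is idle capacity
  S <- Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 2, 2, 3),
                            x = c(1, -1, 1, -1), dims = c(2, 3))
  m <- newMetabolicModel(c("SRC", "R1", "EX_b"), c("a", "b"),
                         c("g1", "g2"), S, lb = c(0, 0, 0),
                         ub = c(1000, 1000, 1000), obj = c(0, 0, 1),
                         gpr = c("", "g1", ""))
  prot <- data.frame(geneId = c("g1", "g2"), mw = c(0.05, 0.05))
  pcm <- buildPCModel(m, prot, P = 1)   # generous relative to the fit below
  # measured proteome caps R1 at half of what the budget would allow
  pHalf <- 0.5 * pcm@P / 0.05
  fit <- pcflux:::.s4("FitResult",
                      pFit = c(g1 = pHalf, g2 = 0),
                      objective = 0, status = "optimal",
                      measured = c(TRUE, TRUE), solution = list())
  contextualize(pcm, fit, s = 0.02)
}
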