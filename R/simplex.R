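# Dense bounded-variable two-phase simplex with Bland's rule.
#
# Fallback for linear programs whose degenerate optimal faces defeat the
# interior-point method: exact at vertices and guaranteed to terminate.
# Operates on the equality standard form produced by ipSolve's
# preprocessing:  min c'z  s.t.  A z = b,  l <= z <= u.

.splx_tol <- 1e-9

.splx_phase <- function(cost, Afull, lfull, ufull, x, basis, nbLower,
                        nmax, maxit) {
  m <- nrow(Afull)
  for (it in seq_len(maxit)) {
    B <- Afull[, basis, drop = FALSE]
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv)) return(list(status = "singular"))
    y <- as.numeric(crossprod(Binv, cost[basis]))
    nonbasic <- setdiff(seq_len(nmax), basis)
    d <- cost[nonbasic] -
      as.numeric(crossprod(Afull[, nonbasic, drop = FALSE], y))
    atLo <- nbLower[nonbasic]
    elig <- (!is.na(atLo) & atLo & d < -.splx_tol) |
            (!is.na(atLo) & !atLo & d > .splx_tol) |
            (is.na(atLo) & abs(d) > .splx_tol)
    if (!any(elig))
      return(list(status = "optimal", x = x, basis = basis,
                  nbLower = nbLower))
    j <- min(nonbasic[elig])                     # Bland's rule
    dj <- d[match(j, nonbasic)]
    up <- if (is.na(nbLower[j])) dj < -.splx_tol else isTRUE(nbLower[j])
    dirj <- if (up) 1 else -1
    w <- as.numeric(Binv %*% Afull[, j])         # basics move by -dirj*step*w

    stepEnter <- if (up) ufull[j] - x[j] else x[j] - lfull[j]
    if (!is.finite(stepEnter)) stepEnter <- Inf
    sBasic <- rep(Inf, m)
    toLower <- rep(NA, m)
    for (kk in seq_len(m)) {
      bk <- basis[kk]
      delta <- -dirj * w[kk]
      if (delta < -.splx_tol && is.finite(lfull[bk])) {
        sBasic[kk] <- (x[bk] - lfull[bk]) / (-delta)
        toLower[kk] <- TRUE
      } else if (delta > .splx_tol && is.finite(ufull[bk])) {
        sBasic[kk] <- (ufull[bk] - x[bk]) / delta
        toLower[kk] <- FALSE
      }
    }
    sBasic <- pmax(sBasic, 0)
    step <- min(stepEnter, min(sBasic))
    if (!is.finite(step)) return(list(status = "unbounded"))

    x[j] <- x[j] + dirj * step
    x[basis] <- x[basis] - dirj * step * w
    if (min(sBasic) <= stepEnter + .splx_tol &&
        any(sBasic <= step + .splx_tol)) {
      cand <- which(sBasic <= step + .splx_tol)
      kk <- cand[which.min(basis[cand])]         # Bland on leaving too
      bk <- basis[kk]
      x[bk] <- if (toLower[kk]) lfull[bk] else ufull[bk]
      nbLower[bk] <- toLower[kk]
      basis[kk] <- j
    } else {
      nbLower[j] <- !isTRUE(nbLower[j])          # bound flip
    }
  }
  list(status = "maxit")
}

.splx_solve <- function(c, A, b, l, u, maxit = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) return(NULL)
  if (is.null(maxit)) maxit <- 2000L + 200L * (n + m)

  # structural variables start at the bound nearest zero (0 when free)
  start <- ifelse(is.finite(l) & is.finite(u),
                  ifelse(abs(l) <= abs(u), l, u),
                  ifelse(is.finite(l), pmax(l, 0) * 0 + l,
                         ifelse(is.finite(u), pmin(u, 0) * 0 + u, 0)))
  resid <- b - as.numeric(A %*% start)
  sgn <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m))
  lfull <- c(l, rep(0, m)); ufull <- c(u, rep(Inf, m))
  x <- c(start, abs(resid))
  basis <- n + seq_len(m)
  nbLower <- ifelse(is.finite(l) & is.finite(u), abs(l) <= abs(u),
                    ifelse(is.finite(l), TRUE,
                           ifelse(is.finite(u), FALSE, NA)))
  nbLower <- c(nbLower, rep(TRUE, m))

  c1 <- c(rep(0, n), rep(1, m))
  p1 <- .splx_phase(c1, Afull, lfull, ufull, x, basis, nbLower,
                    nmax = n + m, maxit = maxit)
  if (p1$status != "optimal") return(list(status = p1$status))
  if (sum(p1$x[n + seq_len(m)]) > 1e-7 * (1 + max(abs(b), 0)))
    return(list(status = "infeasible"))

  # artificials are pinned to zero for phase 2 (they may linger in the
  # basis at value zero)
  ufull[n + seq_len(m)] <- 0
  p2 <- .splx_phase(c(c, rep(0, m)), Afull, lfull, ufull, p1$x, p1$basis,
                    p1$nbLower, nmax = n + m, maxit = maxit)
  if (p2$status != "optimal") return(list(status = p2$status))
  z <- p2$x[seq_len(n)]
  list(status = "optimal", x = z, objective = sum(c * z))
}
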