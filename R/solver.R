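# Sparse primal-dual interior-point solver for linear programs and convex
# quadratic programs with a diagonal Hessian:
#
#     min  0.5 * x' diag(q) x + c' x
#     s.t. rlb <= A x <= rub        (row/range constraints)
#          lb  <=  x  <= ub         (variable bounds, +-Inf allowed)
#
# Every optimisation in the package (FBA, PC-FBA, FVA, proteome-fitting QP,
# debottlenecking LP) reduces to this form.  Mehrotra predictor-corrector on
# the normal equations; the diagonal Hessian keeps the reduced system
# A H^-1 A', which is factored with Matrix's sparse Cholesky.

#' @importFrom Matrix sparseMatrix Diagonal crossprod t Cholesky solve drop0
NULL

.ip_tol <- 1e-9

# robust coercion to general numeric CsparseMatrix (dgCMatrix)
.as_dgc <- function(M) {
  M <- Matrix::Matrix(M, sparse = TRUE)
  methods::as(methods::as(methods::as(M, "CsparseMatrix"),
                          "generalMatrix"), "dMatrix")
}

# Assemble the standard-form problem: all rows become A x - s = 0 with the
# range as bounds on the slack s, then variables fixed by equal bounds are
# eliminated.  Returns NULL mapping when trivially solvable.
ipSolve <- function(c, A = NULL, rlb = numeric(0), rub = numeric(0),
                    lb, ub, qdiag = NULL,
                    maxit = 600L, tol = .ip_tol) {
  n <- length(c)
  stopifnot(length(lb) == n, length(ub) == n)
  if (is.null(qdiag)) qdiag <- numeric(n)
  if (is.null(A)) A <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                            x = numeric(0), dims = c(0L, n))
  A <- .as_dgc(A)
  m <- nrow(A)
  stopifnot(length(rlb) == m, length(rub) == m)
  if (any(lb > ub + 1e-12) || any(rlb > rub + 1e-12))
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))

  # augment with slacks: [A -I] z = 0, slack bounds = row ranges
  if (m > 0L) {
    Aeq <- cbind(A, -Matrix::Diagonal(m))
    zlb <- c(lb, rlb); zub <- c(ub, rub)
    zc <- c(c, numeric(m)); zq <- c(qdiag, numeric(m))
  } else {
    Aeq <- A; zlb <- lb; zub <- ub; zc <- c; zq <- qdiag
  }
  beq <- numeric(m)
  ntot <- n + m

  # eliminate (effectively) fixed variables: intervals negligibly narrow
  # at the problem's own bound scale collapse to their midpoint
  bsc <- max(abs(zlb[is.finite(zlb)]), abs(zub[is.finite(zub)]), 1)
  fixed <- is.finite(zlb) & is.finite(zub) & (zub - zlb) < 1e-9 * bsc
  xfull <- numeric(ntot)
  xfull[fixed] <- (zlb[fixed] + zub[fixed]) / 2
  if (any(fixed)) {
    beq <- beq - as.numeric(Aeq[, fixed, drop = FALSE] %*% xfull[fixed])
    keep <- which(!fixed)
  } else keep <- seq_len(ntot)

  if (length(keep) == 0L) {
    ok <- m == 0L || max(abs(beq)) < 1e-7
    xs <- xfull[seq_len(n)]
    return(list(status = if (ok) "optimal" else "infeasible", x = xs,
                objective = sum(c * xs) + 0.5 * sum(qdiag * xs^2)))
  }

  res <- .ip_core(q = zq[keep], cc = zc[keep] + zq[keep] * 0,
                  A = Aeq[, keep, drop = FALSE], b = beq,
                  l = zlb[keep], u = zub[keep], maxit = maxit, tol = tol,
                  cfix = sum(zc[fixed] * xfull[fixed]) +
                         0.5 * sum(zq[fixed] * xfull[fixed]^2))
  xfull[keep] <- res$x
  x <- xfull[seq_len(n)]
  out <- list(status = res$status, x = x,
              objective = sum(c * x) + 0.5 * sum(qdiag * x^2))
  # pure LPs the interior-point method could not finish (degenerate active
  # sets) fall back to an exact bounded-variable simplex on the same
  # standard form
  if (out$status %in% c("suboptimal", "numerical", "maxit", "infeasible") &&
      !any(qdiag > 0) && ntot <= 2000L) {
    sx <- .splx_solve(zc[keep], Aeq[, keep, drop = FALSE], beq,
                      zlb[keep], zub[keep])
    if (!is.null(sx) && sx$status == "optimal") {
      xfull[keep] <- sx$x
      x <- xfull[seq_len(n)]
      out <- list(status = "optimal", x = x, objective = sum(c * x))
    } else if (!is.null(sx) && sx$status %in% c("infeasible", "unbounded")) {
      out$status <- sx$status
    }
  }
  out
}

# core Mehrotra predictor-corrector; A is m x n sparse, q >= 0 diagonal
.ip_core <- function(q, cc, A, b, l, u, maxit, tol, cfix = 0) {
  m <- nrow(A); n <- ncol(A)
  At <- Matrix::t(A)
  hasL <- is.finite(l); hasU <- is.finite(u)
  ncomp <- sum(hasL) + sum(hasU)
  isQP <- any(q > 0)

  # start strictly interior, near zero where the bounds allow
  off <- pmin(1, ifelse(hasL & hasU, (u - l) / 2, 1))
  x <- pmin(pmax(0, ifelse(hasL, l + off, -Inf)), ifelse(hasU, u - off, Inf))
  zl <- ifelse(hasL, 1, 0); zu <- ifelse(hasU, 1, 0)
  y <- numeric(m)
  bigM <- 1e12
  objscale <- 1 + max(abs(cc), 0)

  step <- function(v, dv, mask) {
    i <- mask & (dv < 0)
    if (!any(i)) return(1)
    min(1, min(-v[i] / dv[i]))
  }

  status <- "maxit"
  objPrev <- Inf; stall <- 0L; resets <- 0L
  for (it in seq_len(maxit)) {
    sl <- ifelse(hasL, pmax(x - l, 1e-14 * (1 + abs(l))), 1)
    su <- ifelse(hasU, pmax(u - x, 1e-14 * (1 + abs(u))), 1)
    rd <- q * x + cc - as.numeric(At %*% y) - zl + zu
    rp <- b - as.numeric(A %*% x)
    mu <- if (ncomp > 0)
      (sum((sl * zl)[hasL]) + sum((su * zu)[hasU])) / ncomp else 0

    pres <- if (m > 0) max(abs(rp)) / (1 + max(abs(b), 0)) else 0
    dres <- max(abs(rd)) / objscale
    if (pres < tol * 10 && dres < tol * 10 && mu < tol) { status <- "optimal"; break }
    # degenerate active sets can leave a few clamped complementarity pairs
    # stuck; accept on stationary residual-feasible iterates
    objNow <- sum(cc * x) + 0.5 * sum(q * x^2)
    stall <- if (abs(objNow - objPrev) <= 1e-10 * (1 + abs(objNow)))
      stall + 1L else 0L
    objPrev <- objNow
    if (stall >= 15L && pres < 1e-8 && dres < 1e-6) { status <- "optimal"; break }
    if (stall >= 15L && pres >= 1e-8 && resets < 3L) {
      # stalled while primal-infeasible: re-centre and reset the duals
      resets <- resets + 1L; stall <- 0L
      offr <- 0.1 * pmin(1, ifelse(hasL & hasU, (u - l) / 2, 1))
      x <- pmin(pmax(x, ifelse(hasL, l + offr, -Inf)),
                ifelse(hasU, u - offr, Inf))
      zl <- ifelse(hasL, 1, 0); zu <- ifelse(hasU, 1, 0); y <- numeric(m)
      next
    }

    # divergence heuristics
    obj <- sum(cc * x) + 0.5 * sum(q * x^2)
    if (max(abs(x)) > bigM) {
      status <- if (obj < -1e6 * objscale) "unbounded" else "infeasible"; break
    }
    if (max(abs(y), abs(zl), abs(zu)) > 1e16) { status <- "infeasible"; break }

    H <- q + ifelse(hasL, zl / sl, 0) + ifelse(hasU, zu / su, 0)
    H <- pmax(H, 1e-10)
    Hinv <- 1 / H

    ch <- NULL
    if (m > 0) {
      M0 <- Matrix::forceSymmetric(A %*% (Hinv * At))
      dM <- pmax(Matrix::diag(M0), 1e-8)
      reg <- 1e-12
      for (tryk in 1:6) {
        ch <- tryCatch(
          Matrix::Cholesky(methods::as(M0 + Matrix::Diagonal(m, reg * dM),
                                       "dsCMatrix"), LDL = FALSE, perm = TRUE),
          error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(ch)) break
        reg <- reg * 1e3
      }
      if (is.null(ch)) { status <- "numerical"; break }
    }

    solve_dir <- function(rcl, rcu) {
      rhat <- rd - ifelse(hasL, rcl / sl, 0) + ifelse(hasU, rcu / su, 0)
      if (m > 0) {
        rhs <- rp + as.numeric(A %*% (Hinv * rhat))
        dy <- as.numeric(Matrix::solve(ch, rhs))
        dx <- Hinv * (as.numeric(At %*% dy) - rhat)
      } else {
        dy <- numeric(0)
        dx <- -Hinv * rhat
      }
      dzl <- ifelse(hasL, (rcl - zl * dx) / sl, 0)
      dzu <- ifelse(hasU, (rcu + zu * dx) / su, 0)
      list(dx = dx, dy = dy, dzl = dzl, dzu = dzu)
    }

    # affine (predictor)
    aff <- solve_dir(rcl = ifelse(hasL, -sl * zl, 0),
                     rcu = ifelse(hasU, -su * zu, 0))
    aP <- min(step(sl, aff$dx, hasL), step(su, -aff$dx, hasU))
    aD <- min(step(zl, aff$dzl, hasL), step(zu, aff$dzu, hasU))
    if (ncomp > 0) {
      mu_aff <- (sum(((sl + aP * aff$dx) * (zl + aD * aff$dzl))[hasL]) +
                 sum(((su - aP * aff$dx) * (zu + aD * aff$dzu))[hasU])) / ncomp
      sigma <- max(min((mu_aff / max(mu, 1e-300))^3, 1), 0)
    } else sigma <- 0

    # corrector
    dir <- solve_dir(
      rcl = ifelse(hasL, sigma * mu - sl * zl - aff$dx * aff$dzl, 0),
      rcu = ifelse(hasU, sigma * mu - su * zu + aff$dx * aff$dzu, 0))
    gP <- 0.9995 * min(step(sl, dir$dx, hasL), step(su, -dir$dx, hasU))
    gD <- 0.9995 * min(step(zl, dir$dzl, hasL), step(zu, dir$dzu, hasU))
    if (isQP) gP <- gD <- min(gP, gD)

    x <- x + gP * dir$dx
    x <- pmax(x, ifelse(hasL, l + 1e-13 * (1 + abs(l)), -Inf))
    x <- pmin(x, ifelse(hasU, u - 1e-13 * (1 + abs(u)), Inf))
    y <- y + gD * dir$dy
    zl <- pmax(zl + gD * dir$dzl, ifelse(hasL, 1e-300, 0))
    zu <- pmax(zu + gD * dir$dzu, ifelse(hasU, 1e-300, 0))
    # centrality safeguard: cap complementarity products that run away
    if (ncomp > 0 && mu > 0) {
      slN <- ifelse(hasL, pmax(x - l, 1e-12), 1)
      suN <- ifelse(hasU, pmax(u - x, 1e-12), 1)
      zl <- ifelse(hasL, pmin(zl, 1e4 * mu / slN), zl)
      zu <- ifelse(hasU, pmin(zu, 1e4 * mu / suN), zu)
    }
  }

  if (status == "maxit") {
    # classify the failure by what is still violated
    rp <- b - as.numeric(A %*% x)
    pres <- if (m > 0) max(abs(rp)) / (1 + max(abs(b), 0)) else 0
    obj <- sum(cc * x) + 0.5 * sum(q * x^2)
    status <- if (pres > 1e-6) "infeasible"
      else if (obj < -1e8 * objscale) "unbounded"
      else "suboptimal"
  }
  list(status = status, x = x, objective = sum(cc * x) + 0.5 * sum(q * x^2) + cfix)
}

# Lexicographic solve: minimise objectives[[1]] exactly, then break ties by
# the later objectives.  The primary optimum comes from a dedicated solve;
# the canonical point from one combined solve in which each later objective
# enters with a weight small enough (1e-5 per level, rescaled to the
# problem's magnitudes) not to move the optimal vertex of the level above —
# a perturbation-based lexicographic scheme that avoids the degenerate
# near-equality rows of sequential objective fixing.  Each objective is
# list(c = cost vector).  Returns the point plus `primary`, the exact
# first-stage optimum.
ipSolveLex <- function(objectives, A, rlb, rub, lb, ub, lambda = 1e-5) {
  stopifnot(length(objectives) >= 1)
  sol1 <- ipSolve(objectives[[1]]$c, A, rlb, rub, lb, ub)
  if (sol1$status != "optimal" || length(objectives) == 1L)
    return(c(sol1, list(primary = sol1$objective)))
  scale1 <- 1 + abs(sol1$objective)
  ccomb <- objectives[[1]]$c
  for (k in 2:length(objectives)) {
    ck <- objectives[[k]]$c
    sk <- 1 + abs(sum(ck * sol1$x))
    ccomb <- ccomb + lambda^(k - 1) * (scale1 / sk) * ck
  }
  sol <- ipSolve(ccomb, A, rlb, rub, lb, ub)
  ok <- sol$status == "optimal" &&
    sum(objectives[[1]]$c * sol$x) <=
      sol1$objective + 1e-6 * scale1
  if (!ok) sol <- sol1
  list(status = "optimal", x = sol$x,
       objective = sum(objectives[[1]]$c * sol$x),
       primary = sol1$objective)
}
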