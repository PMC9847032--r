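# System-level calibration of effective rate constants across samples.
#
# The calibration problem is bilinear: per-group PC-model blocks share the
# rate-constant ratio vector r, which multiplies the complex concentrations
# inside the enzyme-balance constraint.  Two solution strategies are
# provided: a value-function decomposition ("bilinear": deterministic
# multi-start bounded quasi-Newton over the free components of r, each
# evaluation solving the per-group convex QPs exactly) and a block-coordinate
# "alternating" heuristic (fix r -> per-group convex QP; fix complex levels
# -> joint convex QP over proteomes, enzymes and the free r).

#' Cluster transcriptome samples
#'
#' Agglomerative hierarchical clustering of samples on log10(x+1)
#' abundances with correlation distance and average linkage; the tree is
#' cut at k clusters.  Group means are per-gene, missing-value-aware.
#'
#' @param T samples x genes abundance matrix (NA = unmeasured)
#' @param k number of groups, \code{1 <= k <= nrow(T)}
#' @return list with \code{membership} (integer per sample) and
#'   \code{means} (k x genes matrix of group mean abundances)
#' @export
clusterSamples <- function(T, k) {
  if (k < 1) stop("k must be at least 1")
  ns <- nrow(T)
  if (k > ns) stop("k exceeds the number of samples")
  if (all(colSums(!is.na(T)) == 0)) stop("no non-missing column in T")
  lt <- log10(T + 1)
  if (k == ns) {
    membership <- seq_len(ns)
  } else if (k == 1L) {
    membership <- rep(1L, ns)
  } else {
    cc <- suppressWarnings(stats::cor(t(lt), use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    membership <- stats::cutree(hc, k = k)
  }
  means <- t(vapply(seq_len(k), function(g) {
    sub <- T[membership == g, , drop = FALSE]
    colMeans(sub, na.rm = TRUE)
  }, numeric(ncol(T))))
  means[!is.finite(means)] <- NA_real_
  dimnames(means) <- list(paste0("group", seq_len(k)), colnames(T))
  list(membership = membership, means = means)
}

#' Mark complexes whose rate constant may be calibrated
#'
#' A complex is free if at least one of its subunits is, in at least one
#' sample group, at or above that group's mean abundance over measured
#' modelled genes; complexes whose subunits are all below every group mean
#' keep their initial rate constant.
#'
#' @param groupMeans groups x genes abundance matrix (NA = unmeasured)
#' @param C subunit copy-number matrix (genes x complexes)
#' @return logical vector per complex
#' @export
buildFreeMask <- function(groupMeans, C) {
  nc <- ncol(C)
  if (nc == 0L) return(logical(0))
  tavg <- apply(groupMeans, 1, mean, na.rm = TRUE)
  high <- sapply(seq_len(nrow(groupMeans)), function(k) {
    v <- groupMeans[k, ]
    !is.na(v) & v >= tavg[k]
  })
  anyHigh <- rowSums(high, na.rm = TRUE) > 0   # per gene
  as.logical(Matrix::colSums(C[anyHigh, , drop = FALSE] > 0) > 0)
}

#' Replace the rate-constant ratios of a PC-model
#' @param pcm a \linkS4class{PCModel}
#' @param r replacement per-complex ratio vector
#' @return the model with \code{rates@r} set to \code{r}
#' @export
withRates <- function(pcm, r) {
  pcm@rates@r <- r
  pcm
}

# objective of the per-group convex fits at a given r (Inf if any infeasible)
.keff_phi <- function(pcms, tlist, wlist, r) {
  tot <- 0
  fits <- vector("list", length(tlist))
  for (k in seq_along(tlist)) {
    f <- fitProteome(withRates(pcms[[k]], r), tlist[[k]], w = wlist[[k]])
    if (f@status != "optimal") return(list(value = Inf, fits = NULL))
    tot <- tot + f@objective
    fits[[k]] <- f
  }
  list(value = tot, fits = fits)
}

# project free components onto { sum = target, lo <= r <= hi }
.keff_project <- function(rf, lo, hi, target) {
  for (it in 1:100) {
    freeIdx <- which(rf > lo + 1e-12 & rf < hi - 1e-12)
    resid <- target - sum(rf)
    if (abs(resid) < 1e-12) break
    if (!length(freeIdx)) { rf <- rf + resid / length(rf); break }
    rf[freeIdx] <- rf[freeIdx] + resid / length(freeIdx)
    rf <- pmin(pmax(rf, lo), hi)
  }
  rf
}

#' Calibrate rate-constant ratios across sample groups
#'
#' Finds the single ratio vector r that best fits all sample groups at
#' once: minimises \eqn{\sum_k \sum_j w'_j (p^k_j - t^k_j)^2} over
#' per-group PC-model blocks and the shared r, subject to the per-group
#' PC constraints, \eqn{mean(r) = 1}, and
#' \eqn{0.1 r^{ori}_i \le r_i \le 1.9 r^{ori}_i} for free complexes
#' (\eqn{r_i = r^{ori}_i} otherwise).  Weights are binary: 0 for
#' unmeasured genes, 1 otherwise.
#'
#' @param pcm a \linkS4class{PCModel} (with \code{rates@rOri} as the
#'   starting ratios)
#' @param groupMeans groups x genes abundance matrix of group-mean
#'   transcriptomes (unscaled; scaling to the budget is applied here)
#' @param freeMask logical per complex; default from
#'   \code{\link{buildFreeMask}}
#' @param groupModels optional list of per-group \linkS4class{PCModel}
#'   variants (e.g. condition-specific uptake or demand bounds); they must
#'   share the base model's genes, complexes, rates and budget.  Default:
#'   \code{pcm} for every group.
#' @param method \code{"alternating"} (block-coordinate heuristic) or
#'   \code{"bilinear"} (value-function decomposition of the bilinear
#'   program)
#' @param lower,upper multiplier bounds on free ratios, default 0.1 and 1.9
#' @param nStarts random restarts (first start is always rOri), default 3
#' @param seed integer seed for the restarts
#' @param maxit maximum alternating iterations, default 50
#' @param reltol relative objective-improvement stopping tolerance
#' @return list with \code{r}, \code{rOri}, \code{freeMask},
#'   \code{objective}, \code{objectiveInitial}, per-group \code{fits} at
#'   the returned r, \code{method}, \code{heuristic} flag and
#'   \code{status}
#' @export
solveKeffNCQP <- function(pcm, groupMeans, freeMask = NULL,
                          groupModels = NULL,
                          method = c("alternating", "bilinear"),
                          lower = 0.1, upper = 1.9,
                          nStarts = 3L, seed = 1L, maxit = 50L,
                          reltol = 1e-6) {
  method <- match.arg(method)
  rOri <- pcm@rates@rOri
  nc <- length(rOri)
  if (is.null(freeMask)) freeMask <- buildFreeMask(groupMeans, pcm@complexes@C)
  stopifnot(length(freeMask) == nc)

  genes <- pcm@model@geneIds
  nGroups <- nrow(groupMeans)
  pcms <- if (is.null(groupModels)) rep(list(pcm), nGroups) else groupModels
  stopifnot(length(pcms) == nGroups)
  tlist <- lapply(seq_len(nrow(groupMeans)), function(k) {
    tk <- groupMeans[k, genes]
    scaleTranscriptome(tk, pcm@d, pcm@P)
  })
  wlist <- lapply(tlist, function(tk) ifelse(is.na(tk), 0, 1))

  free <- which(freeMask)
  nf <- length(free)
  lo <- lower * rOri[free]; hi <- upper * rOri[free]
  target <- nc * 1 - sum(rOri[!freeMask])  # sum of free components

  init <- .keff_phi(pcms, tlist, wlist, rOri)
  if (!is.finite(init$value))
    stop("PC-model infeasible at the initial rate constants")

  if (nf == 0L) {
    return(list(r = rOri, rOri = rOri, freeMask = freeMask,
                objective = init$value, objectiveInitial = init$value,
                fits = init$fits, method = method, heuristic = FALSE,
                status = "optimal"))
  }
  if (target < sum(lo) - 1e-9 || target > sum(hi) + 1e-9)
    stop("mean(r) = 1 is incompatible with the free-ratio bounds")

  mkR <- function(rf) { r <- rOri; r[free] <- rf; r }
  starts <- list(rOri[free])
  if (nStarts > 1L) {
    set.seed(seed)
    for (s in 2:nStarts)
      starts[[s]] <- .keff_project(stats::runif(nf, lo, hi), lo, hi, target)
  }

  bestVal <- init$value; bestRf <- rOri[free]; converged <- TRUE
  bestConverged <- TRUE
  for (st in starts) {
    res <- if (method == "alternating")
      .keff_alternating(pcms, tlist, wlist, rOri, free, lo, hi, target,
                        st, maxit, reltol)
    else
      .keff_bilinear(pcms, tlist, wlist, rOri, free, lo, hi, target, st)
    if (res$value < bestVal - 1e-12) {
      bestVal <- res$value; bestRf <- res$rf
      bestConverged <- res$converged
    }
  }

  rf <- .keff_project(pmin(pmax(bestRf, lo), hi), lo, hi, target)
  r <- mkR(rf)
  stopifnot(abs(mean(r) - 1) < 1e-9,
            all(r[free] >= lo - 1e-9), all(r[free] <= hi + 1e-9))
  final <- .keff_phi(pcms, tlist, wlist, r)
  status <- if (final$value <= init$value + 1e-9) "optimal" else "suboptimal"
  if (method == "alternating" && !bestConverged) {
    warning("alternating calibration did not converge; returning best incumbent")
    status <- "incumbent"
  }
  list(r = r, rOri = rOri, freeMask = freeMask,
       objective = final$value, objectiveInitial = init$value,
       fits = final$fits, method = method,
       heuristic = method == "alternating", status = status)
}

.keff_alternating <- function(pcms, tlist, wlist, rOri, free, lo, hi, target,
                              rf0, maxit, reltol) {
  rf <- rf0
  prev <- Inf; converged <- FALSE
  bestVal <- Inf; bestRf <- rf
  for (it in seq_len(maxit)) {
    phi <- .keff_phi(pcms, tlist, wlist, .mk_r(rOri, free, rf))
    if (!is.finite(phi$value)) break
    if (phi$value < bestVal) { bestVal <- phi$value; bestRf <- rf }
    if (is.finite(prev) && prev - phi$value < reltol * (1 + abs(prev))) {
      converged <- TRUE; break
    }
    prev <- phi$value
    xs <- lapply(phi$fits, function(f) f@solution$x)
    rfNew <- .keff_joint_qp(pcms, tlist, wlist, rOri, free, lo, hi, target,
                            xs)
    if (is.null(rfNew)) break
    rf <- rfNew
  }
  list(value = bestVal, rf = bestRf, converged = converged)
}

.mk_r <- function(rOri, free, rf) { r <- rOri; r[free] <- rf; r }

# joint convex QP over all groups with complex levels fixed: variables are
# per-group (v, p, ef, er) plus the free components of r
.keff_joint_qp <- function(pcms, tlist, wlist, rOri, free, lo, hi, target, xs) {
  pcm <- pcms[[1]]
  model <- pcm@model
  nr <- length(model@reactionIds); ng <- length(model@geneIds)
  ne <- length(pcm@enzymes@rxnIds); nc <- length(rOri)
  nf <- length(free)
  Q <- length(tlist)
  per <- nr + ng + 2L * ne
  ntot <- Q * per + nf
  irf <- Q * per + seq_len(nf)
  kappa <- pcm@rates@kappa
  enzIdx <- match(pcm@enzymes@rxnIds, model@reactionIds)
  B <- pcm@enzymes@B
  Bsum <- Matrix::summary(B)

  tri_i <- list(); tri_j <- list(); tri_x <- list()
  rlb <- list(); rub <- list()
  lb <- numeric(ntot); ub <- numeric(ntot)
  qdiag <- numeric(ntot); cc <- numeric(ntot)
  roff <- 0L
  add <- function(i, j, x) {
    tri_i[[length(tri_i) + 1L]] <<- i
    tri_j[[length(tri_j) + 1L]] <<- j
    tri_x[[length(tri_x) + 1L]] <<- x
  }
  nm <- nrow(model@S)

  for (k in seq_len(Q)) {
    mk <- pcms[[k]]@model
    Ssum <- Matrix::summary(.as_dgc(mk@S))
    off <- (k - 1L) * per
    iv <- off + seq_len(nr); ip <- off + nr + seq_len(ng)
    ief <- off + nr + ng + seq_len(ne); ier <- off + nr + ng + ne + seq_len(ne)
    xk <- xs[[k]]
    # S v = 0
    add(roff + Ssum$i, iv[Ssum$j], Ssum$x)
    rlb[[length(rlb) + 1L]] <- rep(0, nm); rub[[length(rub) + 1L]] <- rep(0, nm)
    roff <- roff + nm
    # ef + er - B diag(x) r = rhs_fixed
    add(roff + seq_len(ne), ief, rep(1, ne))
    add(roff + seq_len(ne), ier, rep(1, ne))
    sel <- Bsum$j %in% free
    if (any(sel)) {
      jfree <- match(Bsum$j[sel], free)
      add(roff + Bsum$i[sel], irf[jfree], -Bsum$x[sel] * xk[Bsum$j[sel]])
    }
    fixedPart <- if (nf == nc) rep(0, ne) else
      as.numeric(B[, -free, drop = FALSE] %*% (rOri[-free] * xk[-free]))
    rlb[[length(rlb) + 1L]] <- fixedPart; rub[[length(rub) + 1L]] <- fixedPart
    roff <- roff + ne
    # v - kappa ef <= 0 ; v + kappa er >= 0
    add(roff + seq_len(ne), iv[enzIdx], rep(1, ne))
    add(roff + seq_len(ne), ief, rep(-kappa, ne))
    rlb[[length(rlb) + 1L]] <- rep(-Inf, ne); rub[[length(rub) + 1L]] <- rep(0, ne)
    roff <- roff + ne
    add(roff + seq_len(ne), iv[enzIdx], rep(1, ne))
    add(roff + seq_len(ne), ier, rep(kappa, ne))
    rlb[[length(rlb) + 1L]] <- rep(0, ne); rub[[length(rub) + 1L]] <- rep(Inf, ne)
    roff <- roff + ne
    # d' p <= P
    add(rep(roff + 1L, ng), ip, unname(pcm@d))
    rlb[[length(rlb) + 1L]] <- -Inf; rub[[length(rub) + 1L]] <- pcm@P
    roff <- roff + 1L

    lb[iv] <- mk@lb; ub[iv] <- mk@ub
    cxk <- as.numeric(pcm@complexes@C %*% xk)
    lb[ip] <- pmax(0, cxk); ub[ip] <- pcm@pUb
    lb[c(ief, ier)] <- 0; ub[c(ief, ier)] <- Inf

    tk <- ifelse(is.na(tlist[[k]]), 0, tlist[[k]])
    qdiag[ip] <- 2 * wlist[[k]]
    cc[ip] <- -2 * wlist[[k]] * tk
  }
  # sum of free r = target
  add(rep(roff + 1L, nf), irf, rep(1, nf))
  rlb[[length(rlb) + 1L]] <- target; rub[[length(rub) + 1L]] <- target
  roff <- roff + 1L
  lb[irf] <- lo; ub[irf] <- hi

  A <- Matrix::sparseMatrix(i = unlist(tri_i), j = unlist(tri_j),
                            x = unlist(tri_x), dims = c(roff, ntot))
  sol <- ipSolve(cc, A = A, rlb = unlist(rlb), rub = unlist(rub),
                 lb = lb, ub = ub, qdiag = qdiag)
  if (sol$status != "optimal") return(NULL)
  sol$x[irf]
}

.keff_bilinear <- function(pcms, tlist, wlist, rOri, free, lo, hi, target,
                           rf0) {
  nf <- length(free)
  phiOf <- function(rf) {
    rf <- pmin(pmax(rf, lo), hi)
    .keff_phi(pcms, tlist, wlist, .mk_r(rOri, free, rf))$value
  }
  # finite surrogate with memoisation: extreme r can make a group QP
  # infeasible, and line searches revisit points
  cache <- new.env(parent = emptyenv())
  phiFin <- function(rf) {
    key <- paste(round(rf, 9), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- phiOf(rf)
    out <- if (is.finite(v)) v else 1e8 * (1 + sum((rf - rf0)^2))
    cache[[key]] <- out
    out
  }
  if (nf == 1L) {
    rf <- min(max(target, lo), hi)
    return(list(value = phiOf(rf), rf = rf, converged = TRUE))
  }
  # reduce by the mean constraint: theta are the first nf-1 free components
  fobj <- function(theta) {
    last <- target - sum(theta)
    pen <- (max(0, lo[nf] - last) + max(0, last - hi[nf]))^2
    phiFin(c(theta, min(max(last, lo[nf]), hi[nf]))) + 1e4 * pen
  }
  th0 <- rf0[-nf]
  opt <- stats::optim(th0, fobj, method = "L-BFGS-B",
                      lower = lo[-nf], upper = hi[-nf],
                      control = list(maxit = 200, factr = 1e4,
                                     ndeps = rep(1e-5, nf - 1L)))
  last <- min(max(target - sum(opt$par), lo[nf]), hi[nf])
  rf <- .keff_project(c(opt$par, last), lo, hi, target)
  list(value = phiOf(rf), rf = rf, converged = opt$convergence == 0)
}
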