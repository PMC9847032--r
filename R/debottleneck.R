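# Protein-overexpression debottlenecking: distribute a limited total
# overexpression allowance across proteins to maximise a production flux.

#' Find optimal protein-overexpression targets
#'
#' Relaxes the context-specific protein upper bounds from \eqn{p'_j} to
#' \eqn{p'_j + \epsilon_j} for measured genes, with a shared budget
#' \eqn{\sum_j \epsilon_j \le E}, and maximises the production objective by
#' LP.  Among alternate optima a canonical sparse answer is returned by
#' lexicographically minimising \eqn{\sum \epsilon} and then the proteome
#' mass \eqn{p^T d} at the fixed optimum.
#'
#' @param ctx a \linkS4class{ContextModel}
#' @param objective production reaction id
#' @param E overexpression budget (nmol/gDW), \eqn{E \ge 0}
#' @return a \linkS4class{DebottleneckResult}; \code{fold} is
#'   \eqn{(p'_j + \epsilon_j)/p'_j} (Inf where the fitted protein is 0 but
#'   \eqn{\epsilon_j > 0})
#' @export
debottleneck <- function(ctx, objective, E) {
  if (!is.numeric(E) || length(E) != 1L || is.na(E) || E < 0)
    stop("overexpression budget E must be a single non-negative number")
  pcm <- ctx@pcm
  cc <- .objective_coef(pcm@model, objective)
  cons <- contextConstraints(ctx)
  meas <- which(ctx@measured)
  nEps <- length(meas)
  n0 <- cons$ntot

  # append epsilon variables: p_j - eps_j <= pFit_j replaces p_j <= pFit_j
  A <- cbind(cons$A, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                          x = numeric(0),
                                          dims = c(nrow(cons$A), nEps)))
  lb <- c(cons$lb, rep(0, nEps)); ub <- c(cons$ub, rep(Inf, nEps))
  ub[cons$ip[meas]] <- Inf  # replaced by the row constraint below
  rows <- Matrix::sparseMatrix(
    i = c(seq_len(nEps), seq_len(nEps), rep(nEps + 1L, nEps)),
    j = c(cons$ip[meas], n0 + seq_len(nEps), n0 + seq_len(nEps)),
    x = c(rep(1, nEps), rep(-1, nEps), rep(1, nEps)),
    dims = c(nEps + 1L, n0 + nEps))
  A <- rbind(A, rows)
  rlb <- c(cons$rlb, rep(-Inf, nEps), -Inf)
  rub <- c(cons$rub, ctx@pFit[meas], E)

  c1 <- numeric(n0 + nEps); c1[cons$iv] <- -cc
  c2 <- numeric(n0 + nEps); c2[n0 + seq_len(nEps)] <- 1
  c3 <- numeric(n0 + nEps); c3[cons$ip] <- unname(pcm@d)
  sol <- ipSolveLex(list(list(c = c1), list(c = c2), list(c = c3)),
                    A = A, rlb = rlb, rub = rub, lb = lb, ub = ub)

  genes <- pcm@model@geneIds[meas]
  eps <- stats::setNames(pmax(sol$x[n0 + seq_len(nEps)], 0), genes)
  eps[eps < 1e-9 * (1 + E)] <- 0
  pf <- ctx@pFit[meas]
  fold <- ifelse(pf > 0, (pf + eps) / pf, ifelse(eps > 0, Inf, 1))
  .s4("DebottleneckResult", epsilon = eps, E = E,
               objectiveValue = if (sol$status == "optimal") -sol$primary
                                else NA_real_,
               fold = stats::setNames(fold, genes), status = sol$status)
}

#' Select an overexpression budget from the optimum-vs-E curve
#'
#' Computes the production optimum along a grid of budgets and returns the
#' point where the curve has reached its final constant slope: no single
#' protein is blocking the objective beyond that budget.  Concretely, the
#' slopes of consecutive grid intervals are scanned for the last run in
#' which they agree within \code{tol} (relative); E* is the first grid
#' point after that run starts.  A curve that is flat everywhere returns
#' the first grid point.
#'
#' @param ctx a \linkS4class{ContextModel}
#' @param objective production reaction id
#' @param EGrid increasing budget grid with at least 3 points
#' @param tol relative slope-stability tolerance, default 0.01
#' @return list with \code{EStar}, the curve data.frame (\code{E},
#'   \code{objective}), and \code{stable} (FALSE if the slope never
#'   stabilises, in which case the largest E is returned with a warning)
#' @export
selectBudget <- function(ctx, objective, EGrid, tol = 0.01) {
  EGrid <- sort(unique(as.numeric(EGrid)))
  if (length(EGrid) < 3L) stop("EGrid needs at least 3 points")
  vals <- vapply(EGrid, function(E)
    debottleneck(ctx, objective, E)@objectiveValue, numeric(1))
  curve <- data.frame(E = EGrid, objective = vals)
  if (max(vals) - min(vals) < 1e-9 * (1 + abs(max(vals))))
    return(list(EStar = EGrid[1], curve = curve, stable = TRUE))
  slopes <- diff(vals) / diff(EGrid)
  K <- length(slopes)
  sc <- max(abs(slopes), 1e-12)
  j <- K
  for (i in rev(seq_len(K))) {
    if (abs(slopes[i] - slopes[K]) <= tol * sc) j <- i else break
  }
  if (j >= K) {  # no stable tail of >= 2 intervals
    warning("optimum-vs-E slope never stabilises on the grid; returning max E")
    return(list(EStar = EGrid[length(EGrid)], curve = curve, stable = FALSE))
  }
  list(EStar = EGrid[j + 1L], curve = curve, stable = TRUE)
}
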