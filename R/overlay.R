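# Overlaying a transcriptome sample onto the PC-model by convex QP, and
# contextualisation of the protein bounds around the fitted proteome.

#' Scale a transcript vector to the proteome budget
#'
#' Multiplies the whole vector by one scalar so that
#' \eqn{\sum_{j\,measured} t_j d_j = P}, putting transcript abundances on
#' the same magnitude as protein concentrations (nmol/gDW).
#'
#' @param t transcript vector aligned to model genes (NA = unmeasured)
#' @param d per-gene protein mass (mg/nmol)
#' @param P proteome budget (mg/gDW)
#' @return the rescaled vector (NAs preserved)
#' @export
scaleTranscriptome <- function(t, d, P) {
  tot <- sum(t * d, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0)
    stop("total transcript mass is not positive; cannot scale")
  t * (P / tot)
}

#' Fitting weights for the proteome QP
#'
#' Inverse-abundance weights emphasise lowly and un-transcribed genes:
#' \eqn{w_j = 1/t_j} for \eqn{t_j > 0}, \eqn{w_j = 1} for \eqn{t_j = 0},
#' and \eqn{w_j = 0} for unmeasured (NA) genes, which removes them from the
#' objective entirely.
#'
#' @param t scaled transcript vector (NA = unmeasured)
#' @return weight vector of the same length
#' @export
buildWeights <- function(t) {
  stats::setNames(ifelse(is.na(t), 0, ifelse(t > 0, 1 / t, 1)), names(t))
}

#' Fit the PC-model proteome to a transcriptome sample
#'
#' Solves the convex quadratic program
#' \deqn{\min_{v,p,x,e} \sum_j w_j (p_j - t_j)^2}
#' subject to the full PC-model constraint system, i.e. the proteome vector
#' closest (in weighted least squares) to the measured transcriptome that
#' still supports a feasible metabolic state.
#'
#' @param pcm a \linkS4class{PCModel}
#' @param t transcript vector aligned to model genes, normally scaled by
#'   \code{\link{scaleTranscriptome}} (NA = unmeasured)
#' @param w weights; default \code{\link{buildWeights}(t)}
#' @return a \linkS4class{FitResult}
#' @export
fitProteome <- function(pcm, t, w = NULL) {
  genes <- pcm@model@geneIds
  stopifnot(length(t) == length(genes))
  if (is.null(w)) w <- buildWeights(t)
  stopifnot(length(w) == length(genes))
  measured <- !is.na(t)
  t0 <- ifelse(measured, t, 0)

  cons <- pcConstraints(pcm)
  qdiag <- numeric(cons$ntot); cc <- numeric(cons$ntot)
  qdiag[cons$ip] <- 2 * w
  cc[cons$ip] <- -2 * w * t0
  sol <- ipSolve(cc, A = cons$A, rlb = cons$rlb, rub = cons$rub,
                 lb = cons$lb, ub = cons$ub, qdiag = qdiag)
  objective <- if (sol$status == "optimal")
    max(sol$objective + sum(w * t0^2), 0) else NA_real_
  pt <- .pc_solution(sol, cons, pcm, objValue = objective)
  .s4("FitResult",
               pFit = pt$p, objective = objective, status = sol$status,
               measured = unname(measured),
               solution = pt[c("fluxes", "x", "eFor", "eRev")])
}

#' Contextualise a PC-model around a fitted proteome
#'
#' Replaces the generic protein bounds with sample-specific ones: measured
#' genes are confined to \eqn{(1-s)p'_j \le p_j \le p'_j} around the fitted
#' value; unmeasured genes keep \eqn{0 \le p_j \le p^{ub}_j}.  The small
#' slack \code{s} leaves budget headroom for unmeasured proteins and keeps
#' downstream LPs well-posed.
#'
#' @param pcm the \linkS4class{PCModel} that was fitted
#' @param fit a \linkS4class{FitResult} from \code{\link{fitProteome}}
#' @param s relative slack in [0, 1); default 0.02
#' @return a \linkS4class{ContextModel}
#' @export
contextualize <- function(pcm, fit, s = 0.02) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s >= 1)
    stop("slack s must be a single number in [0, 1)")
  .s4("ContextModel", pcm = pcm, pFit = unname(fit@pFit),
               slack = s, measured = fit@measured)
}

# constraint system of a contextualised PC-model
contextConstraints <- function(ctx, epsUpper = FALSE) {
  pcm <- ctx@pcm
  ng <- length(pcm@model@geneIds)
  pLb <- ifelse(ctx@measured, (1 - ctx@slack) * ctx@pFit, 0)
  pUp <- ifelse(ctx@measured, ctx@pFit, pcm@pUb)
  cons <- pcConstraints(pcm, pLb = pLb, pUbOverride = pUp)
  cons$measured <- ctx@measured
  cons
}
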