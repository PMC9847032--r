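# Unbiased network analysis: PC-FVA at graded optimum fractions, Spearman
# classification of reactions by expression dependence, and
# transcriptome-consistency diagnostics.

#' Protein-constrained flux variability analysis
#'
#' For each optimum fraction f, the objective flux is constrained to at
#' least f times its optimum and every reaction flux is minimised and
#' maximised.  Fraction 0 applies no objective cut (plain variability).
#' Intervals at a higher fraction are always nested inside those at a lower
#' one.
#'
#' @param ctx a \linkS4class{ContextModel} or \linkS4class{PCModel}
#' @param objective reaction id whose optimum anchors the cuts
#' @param fractions optimum fractions, default \code{c(0, 0.5, 0.9, 0.99)}
#' @param reactions reaction ids to scan (default all)
#' @return data.frame with columns \code{reaction}, \code{fraction},
#'   \code{vmin}, \code{vmax}, \code{status}
#' @export
pcFVA <- function(ctx, objective, fractions = c(0, 0.5, 0.9, 0.99),
                  reactions = NULL) {
  cons <- if (methods::is(ctx, "ContextModel")) contextConstraints(ctx)
          else pcConstraints(ctx)
  pc <- if (methods::is(ctx, "ContextModel")) ctx@pcm else ctx
  model <- pc@model
  if (is.null(reactions)) reactions <- model@reactionIds
  ridx <- match(reactions, model@reactionIds)
  if (anyNA(ridx)) stop("unknown reaction id(s): ",
                        paste(reactions[is.na(ridx)], collapse = ", "))
  cc <- .objective_coef(model, objective)
  cobj <- numeric(cons$ntot); cobj[cons$iv] <- -cc
  base <- ipSolve(cobj, A = cons$A, rlb = cons$rlb, rub = cons$rub,
                  lb = cons$lb, ub = cons$ub)
  if (base$status != "optimal")
    stop("objective optimisation failed: ", base$status)
  opt <- -base$objective

  objIdx <- which(cc != 0)
  singleObj <- length(objIdx) == 1L && cc[objIdx] == 1
  objRow <- Matrix::sparseMatrix(i = rep(1L, length(objIdx)),
                                 j = cons$iv[objIdx],
                                 x = cc[objIdx], dims = c(1L, cons$ntot))
  out <- vector("list", length(fractions))
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    A2 <- cons$A; rlb2 <- cons$rlb; rub2 <- cons$rub
    lb2 <- cons$lb
    if (f > 0) {
      thr <- opt - (1 - f) * abs(opt) - 1e-9 * (1 + abs(opt))
      if (singleObj) {
        # single-reaction objective: the cut is a tightened flux bound
        lb2[cons$iv[objIdx]] <- max(lb2[cons$iv[objIdx]], thr)
      } else {
        A2 <- rbind(cons$A, objRow); rlb2 <- c(cons$rlb, thr)
        rub2 <- c(cons$rub, Inf)
      }
    }
    vmin <- vmax <- rep(NA_real_, length(ridx))
    stat <- character(length(ridx))
    for (q in seq_along(ridx)) {
      cq <- numeric(cons$ntot); cq[cons$iv[ridx[q]]] <- 1
      lo <- ipSolve(cq, A = A2, rlb = rlb2, rub = rub2,
                    lb = lb2, ub = cons$ub)
      hi <- ipSolve(-cq, A = A2, rlb = rlb2, rub = rub2,
                    lb = lb2, ub = cons$ub)
      if (lo$status == "optimal" && hi$status == "optimal") {
        vmin[q] <- lo$objective; vmax[q] <- -hi$objective
        if (vmin[q] > vmax[q]) { tmp <- vmin[q]; vmin[q] <- vmax[q]; vmax[q] <- tmp }
        stat[q] <- "optimal"
      } else stat[q] <- paste(lo$status, hi$status, sep = "/")
    }
    out[[fi]] <- data.frame(reaction = reactions, fraction = f,
                            vmin = vmin, vmax = vmax, status = stat)
  }
  do.call(rbind, out)
}

#' Classify reactions by expression dependence
#'
#' Correlates, across samples, each reaction's maximal PC-FVA flux with the
#' total transcript abundance of its associated genes (Spearman rank,
#' average ranks on ties).  Classes: \eqn{\rho \ge 0.8} expression-dependent,
#' \eqn{0.5 \le \rho < 0.8} expression-correlated, otherwise
#' expression-independent.  Spontaneous reactions and constant series (rho
#' undefined) are expression-independent; the latter are flagged.
#'
#' @param fvaList list of per-sample FVA tables from \code{\link{pcFVA}}
#' @param transcriptList list of per-sample transcript vectors aligned to
#'   model genes (NA contributes 0 to a reaction's transcript sum)
#' @param model the \linkS4class{MetabolicModel}
#' @param fraction which FVA fraction's vmax to use, default 0
#' @return data.frame with columns \code{reaction}, \code{rho},
#'   \code{class}, \code{flag}
#' @export
classifyReactions <- function(fvaList, transcriptList, model, fraction = 0) {
  stopifnot(length(fvaList) == length(transcriptList))
  if (length(fvaList) < 3L)
    stop("at least 3 samples are needed for Spearman classification")
  nr <- length(model@reactionIds)
  vmaxMat <- matrix(sapply(fvaList, function(tab) {
    sub <- tab[tab$fraction == fraction, ]
    stats::setNames(sub$vmax, sub$reaction)[model@reactionIds]
  }), nrow = nr)
  tsum <- sapply(transcriptList, function(t) {
    t0 <- ifelse(is.na(t), 0, t)
    vapply(model@gpr, function(rule) {
      g <- .gpr_genes(rule)
      if (!length(g)) return(NA_real_)
      sum(t0[match(g, model@geneIds)])
    }, numeric(1))
  })
  tsum <- matrix(tsum, nrow = nr)
  rho <- rep(NA_real_, length(model@reactionIds))
  cls <- rep("expression_independent", length(model@reactionIds))
  flag <- rep(FALSE, length(model@reactionIds))
  for (k in seq_along(model@reactionIds)) {
    if (!nzchar(model@gpr[k])) next  # spontaneous
    xs <- vmaxMat[k, ]; ys <- tsum[k, ]
    if (anyNA(xs)) { flag[k] <- TRUE; next }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) { flag[k] <- TRUE; next }
    r <- stats::cor(xs, ys, method = "spearman")
    rho[k] <- r
    cls[k] <- if (r >= 0.8) "expression_dependent"
      else if (r >= 0.5) "expression_correlated"
      else "expression_independent"
  }
  data.frame(reaction = model@reactionIds, rho = rho, class = cls,
             flag = flag)
}

#' Consistency between fitted proteome and transcriptome
#'
#' Compares a fitted proteome with the scaled transcript vector it was
#' fitted to.  \code{r2} is the coefficient of determination
#' \eqn{1 - SS_{res}/SS_{tot}} on raw pairs; \code{r2Star} the same on
#' log10-transformed pairs restricted to strictly positive values.  A
#' gene's inconsistency ratio is \eqn{\max(p/t, t/p)} (Inf when exactly one
#' of the two is zero; (0,0) pairs are excluded); ratios of at least 3 are
#' outliers and at least 10 far outliers.
#'
#' @param pFit named fitted proteome
#' @param t scaled transcript vector aligned to the same genes (NA genes
#'   are excluded)
#' @return a \linkS4class{ConsistencyReport}
#' @export
consistencyReport <- function(pFit, t) {
  stopifnot(length(pFit) == length(t))
  genes <- if (!is.null(names(pFit))) names(pFit) else as.character(seq_along(pFit))
  use <- !is.na(t) & !(pFit == 0 & t == 0)
  p <- pFit[use]; tv <- t[use]; genes <- genes[use]
  if (sum(use) < 2L) stop("fewer than 2 usable gene pairs")
  r2 <- 1 - sum((p - tv)^2) / sum((tv - mean(tv))^2)
  pos <- p > 0 & tv > 0
  r2Star <- if (sum(pos) >= 2L) {
    lp <- log10(p[pos]); lt <- log10(tv[pos])
    1 - sum((lp - lt)^2) / sum((lt - mean(lt))^2)
  } else NA_real_
  ratio <- ifelse(p > 0 & tv > 0, pmax(p / tv, tv / p), Inf)
  .s4("ConsistencyReport",
               r2 = r2, r2Star = r2Star,
               outliers = genes[ratio >= 3],
               farOutliers = genes[ratio >= 10],
               nPairs = as.integer(sum(use)))
}

#' Flag genes that are persistent far outliers
#'
#' @param reports list of \linkS4class{ConsistencyReport} objects (one per
#'   sample)
#' @param minSamples minimum number of samples a gene must be a far outlier
#'   in
#' @return data.frame with columns \code{gene}, \code{count}, sorted by
#'   count (descending) then gene id
#' @export
flagPersistentOutliers <- function(reports, minSamples) {
  stopifnot(length(reports) >= 1L)
  counts <- table(unlist(lapply(reports, function(r) r@farOutliers)))
  counts <- counts[counts >= minSamples]
  if (!length(counts))
    return(data.frame(gene = character(0), count = integer(0)))
  out <- data.frame(gene = names(counts), count = as.integer(counts))
  out[order(-out$count, out$gene), , drop = FALSE]
}
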