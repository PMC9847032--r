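# PC-model assembly: complex/enzyme enumeration, rate-constant
# initialisation, proteome-budget estimation and the constraint system.

#' Enumerate enzyme complexes and enzymes from gene rules
#'
#' Parses every reaction's GPR into its minimal satisfying gene sets
#' (complexes), deduplicates complexes globally across reactions, and builds
#' the enzyme routing: one forward/reverse enzyme pair per gene-associated
#' reaction, with the Boolean matrix B sending each complex to every
#' reaction it can catalyse.  A complex shared by k reactions appears once
#' in C and k times in B, so isozyme sharing is a real resource trade-off.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param proteins data.frame from \code{\link{readProteinFasta}} (or with
#'   columns \code{geneId}, \code{mw}) giving subunit masses
#' @param curation optional data.frame with columns \code{complex} (subunit
#'   gene ids joined by \code{"+"}), \code{gene}, \code{copies} overriding
#'   subunit copy numbers of listed complexes
#' @return list with a \linkS4class{ComplexSet}, an \linkS4class{EnzymeSet},
#'   and \code{d}, the per-gene mass vector (mg/nmol) in model gene order
#' @export
enumerateComplexes <- function(model, proteins, curation = NULL) {
  genes <- model@geneIds
  d <- .gene_masses(model, proteins)

  disjByRxn <- lapply(model@gpr, parseGeneRule)
  enz <- which(lengths(disjByRxn) > 0L)

  key <- function(g) paste(g, collapse = "+")
  allKeys <- unique(unlist(lapply(disjByRxn[enz],
                                  function(ds) vapply(ds, key, ""))))
  copies <- lapply(allKeys, function(k) {
    g <- strsplit(k, "+", fixed = TRUE)[[1]]
    stats::setNames(rep(1, length(g)), g)
  })
  names(copies) <- allKeys

  if (!is.null(curation) && nrow(curation)) {
    for (i in seq_len(nrow(curation))) {
      ck <- key(sort(strsplit(curation$complex[i], "+", fixed = TRUE)[[1]]))
      if (!ck %in% allKeys) next
      g <- curation$gene[i]
      if (!g %in% names(copies[[ck]]))
        stop("curation row ", i, ": gene '", g,
             "' is not a subunit of complex '", ck, "'")
      if (!g %in% genes) stop("curation row ", i, ": unknown gene '", g, "'")
      copies[[ck]][g] <- as.numeric(curation$copies[i])
    }
  }

  nc <- length(allKeys)
  ci <- unlist(lapply(copies, function(cp) match(names(cp), genes)))
  cj <- rep(seq_len(nc), lengths(copies))
  cx <- unlist(copies, use.names = FALSE)
  C <- Matrix::sparseMatrix(i = ci, j = cj, x = cx,
                            dims = c(length(genes), nc),
                            dimnames = list(genes, allKeys))
  mw <- as.numeric(Matrix::crossprod(C, d))

  bi <- list(); bj <- list()
  for (q in seq_along(enz)) {
    ks <- vapply(disjByRxn[[enz[q]]], key, "")
    bi[[q]] <- rep(q, length(ks)); bj[[q]] <- match(ks, allKeys)
  }
  B <- Matrix::sparseMatrix(i = unlist(bi), j = unlist(bj), x = 1,
                            dims = c(length(enz), nc),
                            dimnames = list(model@reactionIds[enz], allKeys))
  list(complexes = .s4("ComplexSet", complexIds = allKeys,
                                C = .as_dgc(C), mw = mw),
       enzymes = .s4("EnzymeSet", rxnIds = model@reactionIds[enz],
                              B = .as_dgc(B)),
       d = d)
}

.gene_masses <- function(model, proteins) {
  idx <- match(model@geneIds, proteins$geneId)
  if (anyNA(idx))
    stop("no protein sequence/mass for model gene(s): ",
         paste(model@geneIds[is.na(idx)], collapse = ", "))
  stats::setNames(proteins$mw[idx], model@geneIds)
}

#' Initialise rate-constant ratios from complex masses
#'
#' Larger complexes present more catalytic surface; the initial ratio scales
#' with complex mass to the 3/4 power (the surface-area-to-mass scaling),
#' \eqn{r^{ori}_i = (X_i / \bar X)^{3/4}} with \eqn{X = C^T d}, then the
#' vector is renormalised to mean exactly 1 so the calibration constraint
#' \eqn{mean(r) = 1} holds at initialisation.
#'
#' @param complexes a \linkS4class{ComplexSet}
#' @return numeric vector \code{rOri} with \code{mean(rOri) == 1}
#' @export
estimateROri <- function(complexes) {
  X <- complexes@mw
  if (length(X) == 0L) return(numeric(0))
  if (any(X <= 0)) stop("complex with non-positive mass: ",
                        complexes@complexIds[which(X <= 0)[1]])
  r <- (X / mean(X))^0.75
  r / mean(r)
}

#' Estimate the proteome budget from transcriptome coverage
#'
#' Scales a total cellular proteome mass fraction (600 mg/gDW by default)
#' by the modelled fraction of the transcriptome mass:
#' \deqn{P = 600 \cdot \frac{t^T d}{t_{cp}^T d_{cp}} \cdot
#'   \frac{length(t)}{length(t) - \#NaN(t)},}
#' where \eqn{t, d} cover the modelled genes (missing measurements NaN) and
#' \eqn{t_{cp}, d_{cp}} the complete transcriptome.
#'
#' @param tcp,dcp complete transcript-abundance and mass vectors
#' @param t,d modelled transcript-abundance (NA = unmeasured) and mass
#'   vectors aligned to model genes
#' @param totalFraction total proteome weight fraction (mg/gDW)
#' @return proteome budget P (mg/gDW)
#' @export
estimateProteomeBudget <- function(tcp, dcp, t, d, totalFraction = 600) {
  if (all(is.na(t))) stop("all modelled transcripts are missing")
  denom <- sum(tcp * dcp, na.rm = TRUE)
  if (!is.finite(denom) || denom <= 0)
    stop("non-positive complete transcriptome mass")
  nNaN <- sum(is.na(t))
  frac <- sum(t * d, na.rm = TRUE) / denom
  totalFraction * frac * length(t) / (length(t) - nNaN)
}

#' Construct a RateConstants object
#' @param rOri initial per-complex ratios (mean 1)
#' @param keffAvg basal rate constant, 1/s
#' @param kappa unit coupling; default \code{keffAvg * 3600e-6}
#' @param r current ratios (default \code{rOri})
#' @return a \linkS4class{RateConstants}
#' @export
newRateConstants <- function(rOri, keffAvg = 65, kappa = keffAvg * 3600e-6,
                             r = rOri) {
  .s4("RateConstants", r = r, rOri = rOri,
               keffAvg = keffAvg, kappa = kappa)
}

#' Build a protein-constrained model
#'
#' Augments a metabolic model with protein, complex and enzyme variables
#' under a proteome mass budget.  Enzymatic-reaction fluxes are capped by
#' \eqn{\kappa e} in both directions, intersected with (never loosening) the
#' original flux bounds; spontaneous reactions keep their bounds untouched.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param proteins protein table from \code{\link{readProteinFasta}}
#' @param P proteome budget (mg/gDW)
#' @param keffAvg basal effective rate constant (1/s), default 65
#' @param kappa unit coupling (mmol/gDW/h per nmol/gDW), default
#'   \code{keffAvg * 3600e-6}
#' @param pUb per-protein upper bound; default \code{P / min(d)} (no single
#'   protein can exceed the whole budget)
#' @param curation optional complex-stoichiometry curation table, see
#'   \code{\link{enumerateComplexes}}
#' @return a \linkS4class{PCModel}
#' @export
buildPCModel <- function(model, proteins, P, keffAvg = 65,
                         kappa = keffAvg * 3600e-6, pUb = NULL,
                         curation = NULL) {
  ce <- enumerateComplexes(model, proteins, curation)
  rOri <- estimateROri(ce$complexes)
  rates <- newRateConstants(rOri, keffAvg = keffAvg, kappa = kappa)
  newPCModel(model, ce$complexes, ce$enzymes, rates, ce$d, P, pUb)
}

#' Assemble a PCModel from prepared components
#' @param model,complexes,enzymes,rates,d model components
#' @param P proteome budget (mg/gDW)
#' @param pUb per-protein upper bound (scalar or per-gene vector); default
#'   \code{P / min(d)}
#' @return a \linkS4class{PCModel}
#' @export
newPCModel <- function(model, complexes, enzymes, rates, d, P, pUb = NULL) {
  if (is.null(pUb)) pUb <- P / min(d)
  if (length(pUb) == 1L) pUb <- rep(pUb, length(model@geneIds))
  .s4("PCModel", model = model, complexes = complexes,
               enzymes = enzymes, rates = rates,
               d = stats::setNames(as.numeric(d), model@geneIds),
               P = P, pUb = as.numeric(pUb))
}

# ---- constraint assembly ----------------------------------------------------

# Linear constraint system of a PCModel over variables (v, p, x, ef, er).
# Returns A, row ranges, variable bounds and index blocks.  pLb/pUbOverride
# substitute the protein bounds (used by contextualised models).
pcConstraints <- function(pcm, pLb = NULL, pUbOverride = NULL) {
  model <- pcm@model
  nr <- length(model@reactionIds); ng <- length(model@geneIds)
  nc <- length(pcm@complexes@complexIds); ne <- length(pcm@enzymes@rxnIds)
  iv <- seq_len(nr); ip <- nr + seq_len(ng); ix <- nr + ng + seq_len(nc)
  ief <- nr + ng + nc + seq_len(ne); ier <- nr + ng + nc + ne + seq_len(ne)
  ntot <- nr + ng + nc + 2L * ne
  kappa <- pcm@rates@kappa
  enzIdx <- match(pcm@enzymes@rxnIds, model@reactionIds)

  blocks <- list()
  addBlock <- function(M, cols) {
    s <- Matrix::summary(.as_dgc(M))
    list(i = s$i, j = cols[s$j], x = s$x, n = nrow(M))
  }

  rows <- list(
    # S v = 0
    list(addBlock(model@S, iv)),
    # C x - p <= 0
    list(addBlock(pcm@complexes@C, ix),
         list(i = seq_len(ng), j = ip, x = rep(-1, ng), n = ng)),
    # ef + er - B diag(r) x = 0
    if (ne > 0) list(
      list(i = seq_len(ne), j = ief, x = rep(1, ne), n = ne),
      list(i = seq_len(ne), j = ier, x = rep(1, ne), n = ne),
      addBlock(pcm@enzymes@B %*% Matrix::Diagonal(nc, -pcm@rates@r), ix)),
    # v - kappa ef <= 0
    if (ne > 0) list(
      list(i = seq_len(ne), j = iv[enzIdx], x = rep(1, ne), n = ne),
      list(i = seq_len(ne), j = ief, x = rep(-kappa, ne), n = ne)),
    # v + kappa er >= 0
    if (ne > 0) list(
      list(i = seq_len(ne), j = iv[enzIdx], x = rep(1, ne), n = ne),
      list(i = seq_len(ne), j = ier, x = rep(kappa, ne), n = ne)),
    # d' p <= P
    list(list(i = rep(1L, ng), j = ip, x = unname(pcm@d), n = 1L)))

  nrows <- c(nrow(model@S), ng, if (ne > 0) c(ne, ne, ne) else NULL, 1L)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  off <- cumsum(c(0L, utils::head(nrows, -1L)))
  tri <- do.call(rbind, unlist(lapply(seq_along(rows), function(b)
    lapply(rows[[b]], function(bl)
      data.frame(i = bl$i + off[b], j = bl$j, x = bl$x))), recursive = FALSE))
  A <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                            dims = c(sum(nrows), ntot))

  rlb <- c(rep(0, nrow(model@S)), rep(-Inf, ng),
           if (ne > 0) c(rep(0, ne), rep(-Inf, ne), rep(0, ne)) else NULL,
           -Inf)
  rub <- c(rep(0, nrow(model@S)), rep(0, ng),
           if (ne > 0) c(rep(0, ne), rep(0, ne), rep(Inf, ne)) else NULL,
           pcm@P)

  plb <- if (is.null(pLb)) rep(0, ng) else pLb
  pub <- if (is.null(pUbOverride)) pcm@pUb else pUbOverride
  lb <- c(model@lb, plb, rep(0, nc), rep(0, 2L * ne))
  ub <- c(model@ub, pub, rep(Inf, nc), rep(Inf, 2L * ne))

  list(A = A, rlb = rlb, rub = rub, lb = lb, ub = ub,
       iv = iv, ip = ip, ix = ix, ief = ief, ier = ier, ntot = ntot,
       enzIdx = enzIdx)
}

.objective_coef <- function(model, objective) {
  nr <- length(model@reactionIds)
  if (is.null(objective)) {
    if (all(model@obj == 0)) stop("model has no objective")
    return(model@obj)
  }
  idx <- match(objective, model@reactionIds)
  if (is.na(idx)) stop("unknown objective reaction '", objective, "'")
  cc <- numeric(nr); cc[idx] <- 1
  cc
}

#' Flux balance analysis
#'
#' Solves the linear program \eqn{\max c^T v} s.t. \eqn{S v = 0},
#' \eqn{lb \le v \le ub}.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param objective reaction id (default: the model's objective coefficients)
#' @param sense \code{"max"} or \code{"min"}
#' @return list with \code{objective}, named \code{fluxes}, \code{status}
#' @export
fba <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  cc <- .objective_coef(model, objective)
  sgn <- if (sense == "max") -1 else 1
  nm <- length(model@metaboliteIds)
  sol <- ipSolve(sgn * cc, A = model@S, rlb = rep(0, nm), rub = rep(0, nm),
                 lb = model@lb, ub = model@ub)
  list(objective = if (sol$status == "optimal") sgn * sol$objective else NA_real_,
       fluxes = stats::setNames(sol$x, model@reactionIds),
       status = sol$status)
}

#' Protein-constrained flux balance analysis
#'
#' Maximises (or minimises) a reaction flux over the PC-model constraint
#' system.  To return a reproducible point among alternate optima, the
#' proteome mass \eqn{p^T d} is lexicographically minimised at the fixed
#' optimum.
#'
#' @param pcm a \linkS4class{PCModel} or \linkS4class{ContextModel}
#' @param objective reaction id (default: base-model objective)
#' @param sense \code{"max"} or \code{"min"}
#' @return list with \code{objective}, \code{status}, and named blocks
#'   \code{fluxes}, \code{p}, \code{x}, \code{eFor}, \code{eRev}
#' @export
pcFBA <- function(pcm, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  cons <- if (methods::is(pcm, "ContextModel")) contextConstraints(pcm)
          else pcConstraints(pcm)
  pc <- if (methods::is(pcm, "ContextModel")) pcm@pcm else pcm
  cc <- .objective_coef(pc@model, objective)
  sgn <- if (sense == "max") -1 else 1
  c1 <- numeric(cons$ntot); c1[cons$iv] <- sgn * cc
  c2 <- numeric(cons$ntot); c2[cons$ip] <- unname(pc@d)
  sol <- ipSolveLex(list(list(c = c1), list(c = c2)),
                    A = cons$A, rlb = cons$rlb, rub = cons$rub,
                    lb = cons$lb, ub = cons$ub)
  .pc_solution(sol, cons, pc, objValue = if (sol$status == "optimal")
    sgn * sol$primary else NA_real_)
}

.pc_solution <- function(sol, cons, pc, objValue) {
  model <- pc@model
  list(objective = objValue, status = sol$status,
       fluxes = stats::setNames(sol$x[cons$iv], model@reactionIds),
       p = stats::setNames(sol$x[cons$ip], model@geneIds),
       x = stats::setNames(sol$x[cons$ix], pc@complexes@complexIds),
       eFor = stats::setNames(sol$x[cons$ief], pc@enzymes@rxnIds),
       eRev = stats::setNames(sol$x[cons$ier], pc@enzymes@rxnIds))
}

#' Proteome allocation by subsystem
#'
#' Aggregates per-protein mass \eqn{p_j d_j} of a PC-FBA (or fitted)
#' solution into subsystem mass fractions.  A protein serving complexes in
#' several subsystems has its mass split equally among them.
#'
#' @param pcm the \linkS4class{PCModel} the solution belongs to
#' @param p named proteome vector (nmol/gDW)
#' @return data.frame with columns \code{subsystem}, \code{mass} (mg/gDW)
#'   and \code{fraction} (sums to 1 over proteins with p > 0); empty for an
#'   all-zero proteome
#' @export
proteomeAllocation <- function(pcm, p) {
  model <- pcm@model
  genes <- model@geneIds
  mass <- unname(p[genes]) * unname(pcm@d)
  subsOf <- function(g) {
    gi <- match(g, genes)
    cplx <- which(pcm@complexes@C[gi, ] > 0)
    if (!length(cplx)) return("(none)")
    rxns <- pcm@enzymes@rxnIds[which(Matrix::rowSums(
      pcm@enzymes@B[, cplx, drop = FALSE]) > 0)]
    ss <- unique(model@subsystem[match(rxns, model@reactionIds)])
    ss[!nzchar(ss)] <- "(unassigned)"
    unique(ss)
  }
  acc <- list()
  for (gi in which(mass > 0)) {
    ss <- subsOf(genes[gi])
    for (s in ss) acc[[s]] <- (if (is.null(acc[[s]])) 0 else acc[[s]]) +
        mass[gi] / length(ss)
  }
  if (!length(acc))
    return(data.frame(subsystem = character(0), mass = numeric(0),
                      fraction = numeric(0)))
  out <- data.frame(subsystem = names(acc), mass = unlist(acc),
                    row.names = NULL)
  out$fraction <- out$mass / sum(out$mass)
  out[order(-out$fraction), ]
}
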