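#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

# new() with slot values supplied afterwards: initialize() on classes with
# Matrix-typed slots trips over a stale class-definition cache in some
# builds, while direct slot assignment is safe.
.s4 <- function(.klass, ...) {
  obj <- methods::new(.klass)
  args <- list(...)
  for (nm in names(args)) methods::slot(obj, nm) <- args[[nm]]
  methods::validObject(obj)
  obj
}

#' Class MetabolicModel
#'
#' A constraint-based (stoichiometric) metabolic model: the sparse
#' stoichiometric matrix \eqn{S} (metabolites x reactions), per-reaction flux
#' bounds in mmol/gDW/h, linear objective coefficients, gene-protein-reaction
#' rules and subsystem labels.  Feasible flux vectors satisfy
#' \eqn{S v = 0,\ lb \le v \le ub}.
#'
#' @slot modelId model identifier
#' @slot reactionIds,metaboliteIds,geneIds identifier vectors
#' @slot S sparse stoichiometric matrix, metabolites x reactions
#' @slot lb,ub flux bounds (mmol/gDW/h)
#' @slot obj objective coefficient per reaction
#' @slot gpr Boolean gene rule string per reaction ("" = spontaneous)
#' @slot subsystem subsystem label per reaction (may be "")
#' @export
setClass("MetabolicModel", representation(
  modelId = "character",
  reactionIds = "character", metaboliteIds = "character",
  geneIds = "character",
  S = "ANY", lb = "numeric", ub = "numeric", obj = "numeric",
  gpr = "character", subsystem = "character"))

setValidity("MetabolicModel", function(object) {
  nr <- length(object@reactionIds); nm <- length(object@metaboliteIds)
  msgs <- character(0)
  if (!methods::is(object@S, "dgCMatrix"))
    return("S must be a dgCMatrix sparse matrix")
  if (!identical(dim(object@S), c(nm, nr)))
    msgs <- c(msgs, "dim(S) must be (metabolites x reactions)")
  for (f in c("lb", "ub", "obj", "gpr", "subsystem"))
    if (length(slot(object, f)) != nr)
      msgs <- c(msgs, sprintf("length(%s) must equal number of reactions", f))
  if (length(object@lb) == nr && length(object@ub) == nr &&
      any(object@lb > object@ub))
    msgs <- c(msgs, "lb must not exceed ub")
  if (anyDuplicated(object@reactionIds)) msgs <- c(msgs, "duplicate reaction ids")
  if (anyDuplicated(object@metaboliteIds)) msgs <- c(msgs, "duplicate metabolite ids")
  used <- unique(unlist(lapply(object@gpr, .gpr_genes)))
  if (length(setdiff(used, object@geneIds)))
    msgs <- c(msgs, paste("gpr references unknown genes:",
                          paste(setdiff(used, object@geneIds), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Class ComplexSet
#'
#' The deduplicated enzyme complexes of a model: subunit copy-number matrix
#' \eqn{C} (genes x complexes) and per-complex molecular mass
#' \eqn{X = C^T d} in mg/nmol.
#' @slot complexIds canonical complex identifiers
#' @slot C sparse subunit copy-number matrix, genes x complexes
#' @slot mw complex molecular mass (mg/nmol)
#' @export
setClass("ComplexSet", representation(
  complexIds = "character", C = "ANY", mw = "numeric"))

setValidity("ComplexSet", function(object) {
  nc <- length(object@complexIds)
  if (!methods::is(object@C, "dgCMatrix"))
    return("C must be a dgCMatrix sparse matrix")
  if (ncol(object@C) != nc) return("ncol(C) must equal number of complexes")
  if (length(object@mw) != nc) return("length(mw) must equal number of complexes")
  if (nc > 0 && any(Matrix::colSums(object@C > 0) < 1))
    return("every complex needs at least one subunit")
  if (length(object@C@x) && any(object@C@x < 0))
    return("subunit copy numbers must be positive")
  TRUE
})

#' Class EnzymeSet
#'
#' One forward/reverse enzyme pair per enzymatic (gene-associated) reaction,
#' and the Boolean routing matrix \eqn{B} (enzymatic reactions x complexes)
#' mapping each complex to every reaction it can catalyse.  Spontaneous
#' reactions carry no enzyme.
#' @slot rxnIds ids of the enzymatic reactions, in model order
#' @slot B sparse Boolean matrix, enzymatic reactions x complexes
#' @export
setClass("EnzymeSet", representation(rxnIds = "character", B = "ANY"))

setValidity("EnzymeSet", function(object) {
  if (!methods::is(object@B, "dgCMatrix"))
    return("B must be a dgCMatrix sparse matrix")
  if (nrow(object@B) != length(object@rxnIds))
    return("nrow(B) must equal number of enzymatic reactions")
  if (length(object@B@x) && !all(object@B@x %in% c(0, 1)))
    return("B must be Boolean")
  TRUE
})

#' Class RateConstants
#'
#' Effective catalytic rate constants: the dimensionless per-complex ratio
#' vector \code{r} (so \eqn{K_{eff,i} = r_i K_{eff}^{avg}}), its
#' mass-scaled initial value \code{rOri} (normalised to mean 1), the basal
#' rate constant \code{keffAvg} in 1/s, and the unit-coupling factor
#' \code{kappa = keffAvg * 3600 * 1e-6} converting enzyme nmol/gDW into flux
#' capacity mmol/gDW/h.
#' @slot r,rOri per-complex rate-constant ratios
#' @slot keffAvg basal rate constant (1/s)
#' @slot kappa flux capacity per enzyme unit (mmol/gDW/h per nmol/gDW)
#' @export
setClass("RateConstants", representation(
  r = "numeric", rOri = "numeric", keffAvg = "numeric", kappa = "numeric"))

setValidity("RateConstants", function(object) {
  if (length(object@r) != length(object@rOri))
    return("r and rOri must have equal length")
  if (any(object@r <= 0)) return("r must be positive")
  if (length(object@rOri) && abs(mean(object@rOri) - 1) > 1e-9)
    return("mean(rOri) must be 1")
  if (abs(object@kappa - object@keffAvg * 3600e-6) > 1e-9 * object@kappa)
    return("kappa must equal keffAvg * 3600e-6")
  TRUE
})

#' Class PCModel
#'
#' A protein-constrained metabolic model.  On top of the base model's flux
#' variables \eqn{v} it carries protein concentrations \eqn{p} (nmol/gDW),
#' complex concentrations \eqn{x}, and forward/reverse enzyme concentrations
#' \eqn{e_{for}, e_{rev}}, constrained by
#' \deqn{S v = 0;\quad C x \le p;\quad e_{for} + e_{rev} = B\,diag(r)\,x;}
#' \deqn{-\kappa e_{rev} \le v_{enz} \le \kappa e_{for};\quad 0 \le p \le
#'   p^{ub};\quad p^T d \le P.}
#'
#' @slot model the base \linkS4class{MetabolicModel}
#' @slot complexes a \linkS4class{ComplexSet}
#' @slot enzymes an \linkS4class{EnzymeSet}
#' @slot rates a \linkS4class{RateConstants}
#' @slot d per-gene protein molecular mass (mg/nmol), in gene order
#' @slot P proteome budget (mg/gDW)
#' @slot pUb per-protein upper bound (nmol/gDW)
#' @export
setClass("PCModel", representation(
  model = "MetabolicModel", complexes = "ComplexSet", enzymes = "EnzymeSet",
  rates = "RateConstants", d = "numeric", P = "numeric", pUb = "numeric"))

setValidity("PCModel", function(object) {
  ng <- length(object@model@geneIds)
  if (length(object@d) != ng) return("length(d) must equal number of genes")
  if (any(object@d <= 0)) return("protein masses must be positive")
  if (nrow(object@complexes@C) != ng) return("nrow(C) must equal number of genes")
  if (ncol(object@enzymes@B) != length(object@complexes@complexIds))
    return("ncol(B) must equal number of complexes")
  if (length(object@rates@r) != length(object@complexes@complexIds))
    return("length(r) must equal number of complexes")
  if (length(object@pUb) != ng) return("length(pUb) must equal number of genes")
  if (object@P < 0) return("proteome budget must be non-negative")
  TRUE
})

#' Class FitResult
#'
#' Result of fitting the PC-model proteome to one transcriptome sample by
#' convex QP: the fitted proteome \code{pFit} (nmol/gDW), the weighted
#' squared deviation attained, the solver status, and the full solution
#' point.  \code{measured} marks genes with a (non-missing) transcript
#' measurement.
#' @slot pFit named fitted proteome (nmol/gDW)
#' @slot objective weighted squared deviation at the optimum
#' @slot status solver status string
#' @slot measured logical per gene, TRUE where the transcript was measured
#' @slot solution list with flux/complex/enzyme blocks of the optimum
#' @export
setClass("FitResult", representation(
  pFit = "numeric", objective = "numeric", status = "character",
  measured = "logical", solution = "list"))

#' Class ContextModel
#'
#' A context-specific PC-model: protein bounds are tied to a fitted proteome
#' \code{pFit} with relative slack \code{s} (measured genes:
#' \eqn{(1-s) p'_j \le p_j \le p'_j}; unmeasured genes keep
#' \eqn{0 \le p_j \le p^{ub}_j}).
#' @slot pcm the underlying \linkS4class{PCModel}
#' @slot pFit named fitted proteome
#' @slot slack relative slack s in [0, 1)
#' @slot measured logical per gene
#' @export
setClass("ContextModel", representation(
  pcm = "PCModel", pFit = "numeric", slack = "numeric", measured = "logical"))

setValidity("ContextModel", function(object) {
  ng <- length(object@pcm@model@geneIds)
  if (length(object@pFit) != ng) return("length(pFit) must equal number of genes")
  if (length(object@measured) != ng) return("length(measured) must equal number of genes")
  if (object@slack < 0 || object@slack >= 1) return("slack must be in [0, 1)")
  TRUE
})

#' Class ConsistencyReport
#'
#' Agreement between a fitted proteome and the scaled transcriptome it was
#' fitted to: coefficient of determination on raw pairs (\code{r2}) and on
#' log10-transformed positive pairs (\code{r2Star}), plus outlier genes whose
#' symmetric ratio \eqn{\max(p/t, t/p)} is at least 3 (\code{outliers}) or 10
#' (\code{farOutliers}).
#' @slot r2,r2Star coefficients of determination
#' @slot outliers,farOutliers gene id vectors
#' @slot nPairs number of usable gene pairs
#' @export
setClass("ConsistencyReport", representation(
  r2 = "numeric", r2Star = "numeric",
  outliers = "character", farOutliers = "character", nPairs = "integer"))

setValidity("ConsistencyReport", function(object) {
  if (!all(object@farOutliers %in% object@outliers))
    return("farOutliers must be a subset of outliers")
  TRUE
})

#' Class DebottleneckResult
#'
#' Optimal protein-overexpression allowances: per-protein \eqn{\epsilon}
#' (nmol/gDW, non-zero only for measured genes), the budget E, the production
#' objective attained, and the per-protein fold overexpression
#' \eqn{(p'_j + \epsilon_j)/p'_j}.
#' @slot epsilon named allowance vector over measured genes
#' @slot E total overexpression budget
#' @slot objectiveValue production flux at the optimum
#' @slot fold named fold-overexpression vector (Inf where pFit is 0)
#' @slot status solver status
#' @export
setClass("DebottleneckResult", representation(
  epsilon = "numeric", E = "numeric", objectiveValue = "numeric",
  fold = "numeric", status = "character"))

# ---- show methods -----------------------------------------------------------

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel", object@modelId, "\n")
  cat(" ", length(object@metaboliteIds), "metabolites x",
      length(object@reactionIds), "reactions,",
      length(object@geneIds), "genes\n")
  cat(" ", sum(nzchar(object@gpr)), "gene-associated reactions\n")
})

setMethod("show", "PCModel", function(object) {
  cat("PCModel on", object@model@modelId, "\n")
  cat(" ", length(object@complexes@complexIds), "complexes,",
      length(object@enzymes@rxnIds), "enzymatic reactions\n")
  cat("  proteome budget P =", object@P, "mg/gDW; keffAvg =",
      object@rates@keffAvg, "1/s (kappa =", object@rates@kappa, ")\n")
})

setMethod("show", "ContextModel", function(object) {
  cat("ContextModel (slack s =", object@slack, ")\n")
  cat(" ", sum(object@measured), "of", length(object@measured),
      "genes measured\n")
  show(object@pcm)
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult:", object@status, "| objective =",
      format(object@objective, digits = 6), "|",
      sum(object@measured), "measured genes\n")
})

setMethod("show", "ConsistencyReport", function(object) {
  cat("ConsistencyReport: R2 =", round(object@r2, 4),
      "R2* =", round(object@r2Star, 4), "\n")
  cat(" ", length(object@outliers), "outliers (>=3x),",
      length(object@farOutliers), "far outliers (>=10x) of",
      object@nPairs, "pairs\n")
})

setMethod("show", "DebottleneckResult", function(object) {
  cat("DebottleneckResult: objective =",
      format(object@objectiveValue, digits = 6),
      "| E =", object@E, "| sum(epsilon) =",
      format(sum(object@epsilon), digits = 6), "\n")
})

# ---- accessors --------------------------------------------------------------

#' Accessors for model objects
#'
#' @param object a \linkS4class{MetabolicModel}, \linkS4class{PCModel} or
#'   \linkS4class{ContextModel}
#' @return the requested component; \code{stoichiometry} returns the sparse
#'   S matrix, \code{fluxBounds} a two-column matrix (lb, ub).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))
#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))
#' @rdname accessors
#' @export
setGeneric("fluxBounds", function(object) standardGeneric("fluxBounds"))
#' @rdname accessors
#' @export
setGeneric("geneRules", function(object) standardGeneric("geneRules"))
#' @rdname accessors
#' @export
setGeneric("baseModel", function(object) standardGeneric("baseModel"))
#' @rdname accessors
#' @export
setGeneric("proteomeBudget", function(object) standardGeneric("proteomeBudget"))
#' @rdname accessors
#' @export
setGeneric("rateConstants", function(object) standardGeneric("rateConstants"))
#' @rdname accessors
#' @export
setGeneric("fittedProteome", function(object) standardGeneric("fittedProteome"))

setMethod("reactionIds", "MetabolicModel", function(object) object@reactionIds)
setMethod("metaboliteIds", "MetabolicModel", function(object) object@metaboliteIds)
setMethod("geneIds", "MetabolicModel", function(object) object@geneIds)
setMethod("stoichiometry", "MetabolicModel", function(object) object@S)
setMethod("fluxBounds", "MetabolicModel", function(object)
  cbind(lb = object@lb, ub = object@ub))
setMethod("geneRules", "MetabolicModel", function(object)
  stats::setNames(object@gpr, object@reactionIds))

setMethod("reactionIds", "PCModel", function(object) object@model@reactionIds)
setMethod("geneIds", "PCModel", function(object) object@model@geneIds)
setMethod("baseModel", "PCModel", function(object) object@model)
setMethod("proteomeBudget", "PCModel", function(object) object@P)
setMethod("rateConstants", "PCModel", function(object) object@rates)

setMethod("baseModel", "ContextModel", function(object) object@pcm@model)
setMethod("geneIds", "ContextModel", function(object) object@pcm@model@geneIds)
setMethod("fittedProteome", "ContextModel", function(object)
  stats::setNames(object@pFit, object@pcm@model@geneIds))
setMethod("fittedProteome", "FitResult", function(object) object@pFit)
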