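# JSON serialisation of PC-models and context models, so pipeline stages
# can be run separately and exchange intermediates as documented text files.
# Sparse matrices are stored as coordinate triplets.

.mat_to_triplets <- function(M) {
  s <- Matrix::summary(.as_dgc(M))
  list(dims = dim(M), i = s$i, j = s$j, x = s$x)
}

.triplets_to_mat <- function(tr) {
  Matrix::sparseMatrix(i = unlist(tr$i), j = unlist(tr$j),
                       x = unlist(tr$x),
                       dims = unlist(tr$dims))
}

#' Write / read a PCModel as JSON
#'
#' @param pcm a \linkS4class{PCModel}
#' @param path JSON file path
#' @return \code{writePCModel}: \code{path} invisibly;
#'   \code{readPCModel}: the \linkS4class{PCModel}
#' @export
writePCModel <- function(pcm, path) {
  m <- pcm@model
  out <- list(
    format = "pcflux/pcmodel-v1",
    model = list(modelId = m@modelId, reactionIds = m@reactionIds,
                 metaboliteIds = m@metaboliteIds, geneIds = m@geneIds,
                 S = .mat_to_triplets(m@S), lb = m@lb, ub = m@ub,
                 obj = m@obj, gpr = m@gpr, subsystem = m@subsystem),
    complexes = list(complexIds = pcm@complexes@complexIds,
                     C = .mat_to_triplets(pcm@complexes@C),
                     mw = pcm@complexes@mw),
    enzymes = list(rxnIds = pcm@enzymes@rxnIds,
                   B = .mat_to_triplets(pcm@enzymes@B)),
    rates = list(r = pcm@rates@r, rOri = pcm@rates@rOri,
                 keffAvg = pcm@rates@keffAvg, kappa = pcm@rates@kappa),
    d = unname(pcm@d), P = pcm@P, pUb = pcm@pUb)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePCModel
#' @export
readPCModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "pcflux/pcmodel-v1"))
    stop("not a pcflux PC-model file: ", path)
  m <- j$model
  model <- newMetabolicModel(m$reactionIds, m$metaboliteIds, m$geneIds,
                             .triplets_to_mat(m$S), m$lb, m$ub, m$obj,
                             m$gpr, m$subsystem, modelId = m$modelId)
  complexes <- .s4("ComplexSet",
    complexIds = as.character(j$complexes$complexIds),
    C = .as_dgc(.triplets_to_mat(j$complexes$C)),
    mw = as.numeric(j$complexes$mw))
  enzymes <- .s4("EnzymeSet",
    rxnIds = as.character(j$enzymes$rxnIds),
    B = .as_dgc(.triplets_to_mat(j$enzymes$B)))
  rates <- .s4("RateConstants", r = as.numeric(j$rates$r),
                        rOri = as.numeric(j$rates$rOri),
                        keffAvg = j$rates$keffAvg, kappa = j$rates$kappa)
  newPCModel(model, complexes, enzymes, rates, j$d, j$P, j$pUb)
}

#' Write / read a ContextModel as JSON
#' @param ctx a \linkS4class{ContextModel}
#' @param path JSON file path
#' @return \code{writeContextModel}: \code{path} invisibly;
#'   \code{readContextModel}: the \linkS4class{ContextModel}
#' @export
writeContextModel <- function(ctx, path) {
  tmp <- tempfile(fileext = ".json")
  writePCModel(ctx@pcm, tmp)
  pc <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  unlink(tmp)
  out <- list(format = "pcflux/context-v1", pcm = pc,
              pFit = ctx@pFit, slack = ctx@slack, measured = ctx@measured)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeContextModel
#' @export
readContextModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "pcflux/context-v1"))
    stop("not a pcflux context-model file: ", path)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(j$pcm, tmp, auto_unbox = TRUE, digits = NA)
  pcm <- readPCModel(tmp)
  unlink(tmp)
  .s4("ContextModel", pcm = pcm, pFit = as.numeric(j$pFit),
               slack = j$slack, measured = as.logical(j$measured))
}
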