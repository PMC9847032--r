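# Model, protein and transcript input/output.

#' Construct a MetabolicModel
#'
#' @param reactionIds,metaboliteIds,geneIds identifier vectors
#' @param S stoichiometric matrix (metabolites x reactions), dense or sparse
#' @param lb,ub flux bounds (mmol/gDW/h)
#' @param obj objective coefficients (default all 0)
#' @param gpr gene rules (default all spontaneous)
#' @param subsystem subsystem labels (default "")
#' @param modelId model identifier
#' @return a validated \linkS4class{MetabolicModel}
#' @export
newMetabolicModel <- function(reactionIds, metaboliteIds, geneIds, S,
                              lb, ub, obj = NULL, gpr = NULL,
                              subsystem = NULL, modelId = "model") {
  nr <- length(reactionIds)
  if (is.null(obj)) obj <- numeric(nr)
  if (is.null(gpr)) gpr <- character(nr) else gpr[is.na(gpr)] <- ""
  if (is.null(subsystem)) subsystem <- character(nr)
  S <- .as_dgc(S)
  dimnames(S) <- list(metaboliteIds, reactionIds)
  .s4("MetabolicModel", modelId = modelId,
               reactionIds = as.character(reactionIds),
               metaboliteIds = as.character(metaboliteIds),
               geneIds = as.character(geneIds), S = S,
               lb = as.numeric(lb), ub = as.numeric(ub),
               obj = as.numeric(obj), gpr = as.character(gpr),
               subsystem = as.character(subsystem))
}

# average residue masses (Da); protein mass = sum(residues) + one water
.aa_residue_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.aa_water <- 18.01524

#' Molecular mass of a protein sequence
#'
#' Sums average residue masses plus one water and converts to mg/nmol
#' (1 Da = 1e-6 mg/nmol), the unit of the PC-model mass vector d.
#' Unknown residue \code{X} contributes the mean standard residue mass;
#' selenocysteine \code{U} and pyrrolysine \code{O} are mapped to cysteine
#' and lysine with a warning.  Terminal \code{*} is ignored.
#'
#' @param sequence one-letter amino-acid string
#' @return molecular mass in mg/nmol
#' @examples
#' computeMolecularWeight("GG") * 1e6  # Da
#' @export
computeMolecularWeight <- function(sequence) {
  sequence <- gsub("\\*$", "", toupper(sequence))
  if (!nzchar(sequence)) stop("empty protein sequence")
  aa <- strsplit(sequence, "")[[1]]
  if (any(aa == "U")) { warning("selenocysteine (U) given cysteine mass"); aa[aa == "U"] <- "C" }
  if (any(aa == "O")) { warning("pyrrolysine (O) given lysine mass"); aa[aa == "O"] <- "K" }
  bad <- setdiff(unique(aa), c(names(.aa_residue_mass), "X"))
  if (length(bad))
    stop("invalid amino-acid code(s): ", paste(bad, collapse = ", "))
  m <- .aa_residue_mass[aa]
  m[aa == "X"] <- mean(.aa_residue_mass)
  (sum(m) + .aa_water) * 1e-6
}

#' Read protein sequences from FASTA
#'
#' The locus tag is the first whitespace-delimited token of each header.
#' Duplicate tags keep the first record with a warning.  Molecular masses
#' are computed with \code{\link{computeMolecularWeight}}.
#'
#' @param path FASTA file
#' @return a data.frame with columns \code{geneId}, \code{sequence},
#'   \code{mw} (mg/nmol)
#' @export
readProteinFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  tags <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(tags)) {
    warning("duplicate locus tags in ", basename(path), ": ",
            paste(unique(tags[duplicated(tags)]), collapse = ", "),
            " (keeping first)")
    keep <- !duplicated(tags)
    seqs <- seqs[keep]; tags <- tags[keep]
  }
  sq <- as.character(seqs)
  mw <- vapply(seq_along(sq), function(i)
    tryCatch(computeMolecularWeight(sq[i]),
             error = function(e) stop("record '", tags[i], "': ",
                                      conditionMessage(e), call. = FALSE)),
    numeric(1))
  data.frame(geneId = tags, sequence = unname(sq), mw = mw,
             stringsAsFactors = FALSE)
}

#' Read a transcript-abundance table
#'
#' Two-column TSV (gene id, abundance); missing measurements may be encoded
#' as empty fields, \code{NA} or \code{NaN}.  A header line is detected and
#' skipped if its second field is not numeric.
#'
#' @param path TSV file
#' @return a named numeric vector of abundances (NA = missing)
#' @export
readTranscripts <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character"))
  if (nrow(df) == 0L) stop("empty transcript file: ", path)
  suppressWarnings(first <- as.numeric(df[1, 2]))
  if (is.na(first) && !df[1, 2] %in% c("", "NA", "NaN")) df <- df[-1, , drop = FALSE]
  vals <- suppressWarnings(as.numeric(df[[2]]))
  stats::setNames(vals, df[[1]])
}

#' Align a transcript vector to model genes
#'
#' @param model a \linkS4class{MetabolicModel} or \linkS4class{PCModel}
#' @param t named abundance vector (e.g. from \code{\link{readTranscripts}})
#' @return numeric vector over model genes; genes absent from \code{t}
#'   become NA (treated as unmeasured downstream)
#' @export
alignTranscripts <- function(model, t) {
  genes <- if (methods::is(model, "PCModel")) model@model@geneIds else geneIds(model)
  out <- stats::setNames(rep(NA_real_, length(genes)), genes)
  hit <- intersect(genes, names(t))
  out[hit] <- unname(t[hit])
  if (any(!is.na(out) & out < 0)) stop("negative transcript abundance")
  out
}

#' Write a transcript table
#' @param t named abundance vector (NA allowed)
#' @param path output TSV path
#' @export
writeTranscripts <- function(t, path) {
  vals <- ifelse(is.na(t), "NA", format(t, digits = 12, trim = TRUE,
                                        scientific = FALSE))
  writeLines(paste(names(t), vals, sep = "\t"), path)
}

#' Merge two metabolic models
#'
#' Generic union merge used to combine a cellular model with an organelle
#' model: listed metabolites/reactions are first removed from \code{a}
#' (typically the organelle content being replaced), then the reaction and
#' metabolite sets are unioned by identifier.  A reaction present in both
#' models keeps the definition from \code{b}.
#'
#' @param a,b \linkS4class{MetabolicModel} objects
#' @param dropReactions,dropMetabolites ids to delete from \code{a} first
#' @return the merged \linkS4class{MetabolicModel}
#' @export
mergeModels <- function(a, b, dropReactions = character(0),
                        dropMetabolites = character(0)) {
  keepR <- !(a@reactionIds %in% c(dropReactions, b@reactionIds))
  keepM <- !(a@metaboliteIds %in% dropMetabolites)
  mets <- unique(c(a@metaboliteIds[keepM], b@metaboliteIds))
  rxns <- c(a@reactionIds[keepR], b@reactionIds)
  S <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(length(mets), length(rxns)),
                            dimnames = list(mets, rxns))
  Sa <- a@S[intersect(a@metaboliteIds, mets), a@reactionIds[keepR], drop = FALSE]
  S[rownames(Sa), colnames(Sa)] <- Sa
  Sb <- b@S[, , drop = FALSE]
  S[rownames(Sb), colnames(Sb)] <- Sb
  newMetabolicModel(
    reactionIds = rxns, metaboliteIds = mets,
    geneIds = unique(c(a@geneIds, b@geneIds)),
    S = S,
    lb = c(a@lb[keepR], b@lb), ub = c(a@ub[keepR], b@ub),
    obj = c(a@obj[keepR], b@obj),
    gpr = c(a@gpr[keepR], b@gpr),
    subsystem = c(a@subsystem[keepR], b@subsystem),
    modelId = paste0(a@modelId, "+", b@modelId))
}
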