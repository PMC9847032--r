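# SBML Level 3 + FBC v2 and COBRA-JSON model readers/writers.
#
# The SBML support targets the FBC subset that constraint-based models use:
# species, reactions with stoichiometry and fbc flux-bound parameters,
# gene-product associations, and a linear objective.  Identifier prefixes
# "R_"/"M_"/"G_" are applied on write and stripped on read, matching the
# common COBRA convention.

.sbml_core_ns <- "http://www.sbml.org/sbml/level3/version1/core"
.sbml_fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}
.sbml_id <- function(x, prefix) paste0(prefix, gsub("[^A-Za-z0-9_]", "__", x))

#' Read a metabolic model
#'
#' @param path model file
#' @param format \code{"sbml"} (Level 3 + FBC) or \code{"json"} (COBRA-JSON);
#'   by default inferred from the file extension
#' @return a \linkS4class{MetabolicModel}
#' @details SBML models must carry FBC flux bounds for every reaction; a file
#'   without them is rejected rather than silently defaulted.  GPR strings
#'   are normalised to lowercase \code{and}/\code{or}.
#' @export
readMetabolicModel <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  if (format == "json") .read_model_json(path) else .read_model_sbml(path)
}

#' Write a metabolic model
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param path output file
#' @param format \code{"sbml"} or \code{"json"}; by default from the extension
#' @return \code{path}, invisibly
#' @export
writeMetabolicModel <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  if (format == "json") .write_model_json(model, path) else .write_model_sbml(model, path)
  invisible(path)
}

# ---- COBRA-JSON -------------------------------------------------------------

.read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$reactions) || is.null(j$metabolites))
    stop("malformed COBRA-JSON: missing 'reactions' or 'metabolites' in ", path)
  mets <- vapply(j$metabolites, function(m) m$id, "")
  genes <- vapply(j$genes, function(g) g$id, "")
  nr <- length(j$reactions)
  rxn <- character(nr); lb <- numeric(nr); ub <- numeric(nr)
  obj <- numeric(nr); gpr <- character(nr); subsys <- character(nr)
  ii <- list(); jj <- list(); xx <- list()
  for (k in seq_len(nr)) {
    r <- j$reactions[[k]]
    if (is.null(r$id)) stop("malformed COBRA-JSON: reaction ", k, " has no id")
    rxn[k] <- r$id
    if (is.null(r$lower_bound) || is.null(r$upper_bound))
      stop("no flux bounds for reaction '", r$id, "'")
    lb[k] <- r$lower_bound; ub[k] <- r$upper_bound
    obj[k] <- if (!is.null(r$objective_coefficient)) r$objective_coefficient else 0
    gpr[k] <- .normalize_gpr(if (!is.null(r$gene_reaction_rule)) r$gene_reaction_rule else "")
    subsys[k] <- if (!is.null(r$subsystem)) r$subsystem else ""
    mm <- r$metabolites
    if (length(mm)) {
      idx <- match(names(mm), mets)
      if (anyNA(idx)) stop("reaction '", r$id, "' references unknown metabolite '",
                           names(mm)[is.na(idx)][1], "'")
      ii[[k]] <- idx; jj[[k]] <- rep(k, length(mm)); xx[[k]] <- as.numeric(unlist(mm))
    }
  }
  S <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(length(mets), nr))
  newMetabolicModel(rxn, mets, genes, S, lb, ub, obj, gpr, subsys,
                    modelId = if (!is.null(j$id)) j$id else "model")
}

.write_model_json <- function(model, path) {
  S <- model@S
  rx <- lapply(seq_along(model@reactionIds), function(k) {
    col <- S[, k]
    nz <- which(col != 0)
    list(id = model@reactionIds[k],
         metabolites = as.list(stats::setNames(col[nz], model@metaboliteIds[nz])),
         lower_bound = model@lb[k], upper_bound = model@ub[k],
         objective_coefficient = model@obj[k],
         gene_reaction_rule = model@gpr[k],
         subsystem = model@subsystem[k])
  })
  out <- list(id = model@modelId,
              metabolites = lapply(model@metaboliteIds, function(m)
                list(id = m, compartment = "c")),
              genes = lapply(model@geneIds, function(g) list(id = g)),
              reactions = rx)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.normalize_gpr <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return("")
  rule <- gsub("\\band\\b", "and", rule, ignore.case = TRUE)
  rule <- gsub("\\bor\\b", "or", rule, ignore.case = TRUE)
  trimws(gsub("\\s+", " ", rule))
}

# ---- SBML L3 + FBC ----------------------------------------------------------

.xml_local <- function(node, name) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
}
.attr_local <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", name, "$"), names(at))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

.read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  modelNode <- .xml_local(doc, "model")
  if (length(modelNode) == 0L) stop("malformed SBML: no <model> element in ", path)
  modelNode <- modelNode[[1]]
  modelId <- .attr_local(modelNode, "id")
  if (is.na(modelId)) modelId <- "model"

  sp <- .xml_local(modelNode, "species")
  mets <- .strip_prefix(vapply(sp, .attr_local, "", "id"), "M_")
  if (length(mets) == 0L) stop("malformed SBML: no species in ", path)

  params <- .xml_local(modelNode, "parameter")
  pvals <- stats::setNames(as.numeric(vapply(params, .attr_local, "", "value")),
                           vapply(params, .attr_local, "", "id"))

  gps <- .xml_local(modelNode, "geneProduct")
  gpid <- vapply(gps, .attr_local, "", "id")
  gplabel <- vapply(gps, .attr_local, "", "label")
  gplabel[is.na(gplabel)] <- .strip_prefix(gpid[is.na(gplabel)], "G_")
  gpmap <- stats::setNames(gplabel, gpid)

  rnodes <- .xml_local(modelNode, "reaction")
  nr <- length(rnodes)
  if (nr == 0L) stop("malformed SBML: no reactions in ", path)
  rxn <- character(nr); lb <- numeric(nr); ub <- numeric(nr)
  gpr <- character(nr); subsys <- character(nr)
  ii <- list(); jj <- list(); xx <- list()
  for (k in seq_len(nr)) {
    rn <- rnodes[[k]]
    rxn[k] <- .strip_prefix(.attr_local(rn, "id"), "R_")
    lbp <- .attr_local(rn, "lowerFluxBound")
    ubp <- .attr_local(rn, "upperFluxBound")
    if (is.na(lbp) || is.na(ubp))
      stop("no flux bounds for reaction '", rxn[k],
           "' (missing fbc lowerFluxBound/upperFluxBound)")
    if (is.na(pvals[lbp]) || is.na(pvals[ubp]))
      stop("flux-bound parameter '", if (is.na(pvals[lbp])) lbp else ubp,
           "' of reaction '", rxn[k], "' is undefined")
    lb[k] <- pvals[[lbp]]; ub[k] <- pvals[[ubp]]

    add_side <- function(tag, sign) {
      refs <- .xml_local(rn, tag)
      for (rf in refs) {
        srefs <- .xml_local(rf, "speciesReference")
        for (s in srefs) {
          met <- .strip_prefix(.attr_local(s, "species"), "M_")
          st <- as.numeric(.attr_local(s, "stoichiometry"))
          if (is.na(st)) st <- 1
          idx <- match(met, mets)
          if (is.na(idx)) stop("reaction '", rxn[k],
                               "' references unknown species '", met, "'")
          ii[[length(ii) + 1L]] <<- idx
          jj[[length(jj) + 1L]] <<- k
          xx[[length(xx) + 1L]] <<- sign * st
        }
      }
    }
    add_side("listOfReactants", -1)
    add_side("listOfProducts", 1)

    gpa <- .xml_local(rn, "geneProductAssociation")
    if (length(gpa)) {
      kids <- xml2::xml_children(gpa[[1]])
      if (length(kids)) gpr[k] <- .gpa_to_rule(kids[[1]], gpmap)
    }
    notes <- .xml_local(rn, "notes")
    if (length(notes)) {
      txt <- xml2::xml_text(notes[[1]])
      m <- regmatches(txt, regexpr("SUBSYSTEM: *[^\n<]*", txt))
      if (length(m)) subsys[k] <- trimws(sub("SUBSYSTEM: *", "", m))
    }
  }
  S <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(length(mets), nr))

  obj <- numeric(nr)
  fos <- .xml_local(modelNode, "fluxObjective")
  for (fo in fos) {
    rid <- .strip_prefix(.attr_local(fo, "reaction"), "R_")
    coef <- as.numeric(.attr_local(fo, "coefficient"))
    idx <- match(rid, rxn)
    if (!is.na(idx)) obj[idx] <- coef
  }
  newMetabolicModel(rxn, mets, unname(gplabel), S, lb, ub, obj,
                    vapply(gpr, .normalize_gpr, ""), subsys, modelId = modelId)
}

.gpa_to_rule <- function(node, gpmap) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- .attr_local(node, "geneProduct")
    g <- gpmap[ref]
    return(if (is.na(g)) .strip_prefix(ref, "G_") else unname(g))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, .gpa_to_rule, "", gpmap = gpmap)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

.write_model_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  gid <- function(g) .sbml_id(g, "G_")

  bvals <- sort(unique(c(model@lb, model@ub)))
  bids <- stats::setNames(sprintf("fb_%d", seq_along(bvals)), num(bvals))

  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w(sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), .sbml_core_ns, .sbml_fbc_ns))
  w(sprintf('  <model id="%s" fbc:strict="true">', esc(model@modelId)))
  w('    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>')
  w('    <listOfSpecies>')
  for (m in model@metaboliteIds)
    w(sprintf(paste0('      <species id="%s" compartment="c" constant="false" ',
                     'boundaryCondition="false" hasOnlySubstanceUnits="false"/>'),
              .sbml_id(m, "M_")))
  w('    </listOfSpecies>')
  w('    <listOfParameters>')
  for (i in seq_along(bvals))
    w(sprintf('      <parameter id="%s" value="%s" constant="true"/>',
              sprintf("fb_%d", i), num(bvals[i])))
  w('    </listOfParameters>')
  if (length(model@geneIds)) {
    w('    <fbc:listOfGeneProducts>')
    for (g in model@geneIds)
      w(sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                gid(g), esc(g)))
    w('    </fbc:listOfGeneProducts>')
  }
  w('    <listOfReactions>')
  S <- model@S
  for (k in seq_along(model@reactionIds)) {
    rid <- .sbml_id(model@reactionIds[k], "R_")
    w(sprintf(paste0('      <reaction id="%s" reversible="%s" fast="false" ',
                     'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
              rid, tolower(model@lb[k] < 0),
              bids[num(model@lb[k])], bids[num(model@ub[k])]))
    if (nzchar(model@subsystem[k]))
      w(sprintf('        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: %s</p></body></notes>',
                esc(model@subsystem[k])))
    col <- S[, k]; nz <- which(col != 0)
    reac <- nz[col[nz] < 0]; prod <- nz[col[nz] > 0]
    if (length(reac)) {
      w('        <listOfReactants>')
      for (i in reac)
        w(sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                  .sbml_id(model@metaboliteIds[i], "M_"), num(-col[i])))
      w('        </listOfReactants>')
    }
    if (length(prod)) {
      w('        <listOfProducts>')
      for (i in prod)
        w(sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                  .sbml_id(model@metaboliteIds[i], "M_"), num(col[i])))
      w('        </listOfProducts>')
    }
    if (nzchar(model@gpr[k]))
      w(paste0('        <fbc:geneProductAssociation>',
               .rule_to_gpa(model@gpr[k], gid),
               '</fbc:geneProductAssociation>'))
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  act <- which(model@obj != 0)
  w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  if (length(act)) {
    w('        <fbc:listOfFluxObjectives>')
    for (k in act)
      w(sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="%s"/>',
                .sbml_id(model@reactionIds[k], "R_"), num(model@obj[k])))
    w('        </fbc:listOfFluxObjectives>')
  }
  w('      </fbc:objective>')
  w('    </fbc:listOfObjectives>')
  w('  </model>')
  w('</sbml>')
}

# serialise a GPR string as nested fbc:and/fbc:or elements
.rule_to_gpa <- function(rule, gid) {
  tree <- .gpr_ast(rule)
  .ast_to_gpa(tree, gid)
}

.gpr_ast <- function(rule) {
  tk <- .gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$tokens <- tk$tokens; st$pos <- tk$pos; st$i <- 1L; st$end <- nchar(rule) + 1L
  expr <- function() {
    t1 <- term()
    parts <- list(t1)
    while (identical(.gpr_peek(st), "or")) { .gpr_next(st); parts <- c(parts, list(term())) }
    if (length(parts) == 1L) parts[[1]] else list(op = "or", args = parts)
  }
  term <- function() {
    f1 <- factor_()
    parts <- list(f1)
    while (identical(.gpr_peek(st), "and")) { .gpr_next(st); parts <- c(parts, list(factor_())) }
    if (length(parts) == 1L) parts[[1]] else list(op = "and", args = parts)
  }
  factor_ <- function() {
    tok <- .gpr_peek(st)
    if (identical(tok, "(")) {
      .gpr_next(st); inner <- expr()
      if (!identical(.gpr_peek(st), ")")) stop("GPR parse error: expected ')'")
      .gpr_next(st); return(inner)
    }
    .gpr_next(st); list(gene = tok)
  }
  out <- expr()
  if (!is.null(.gpr_peek(st))) stop("GPR parse error: trailing tokens")
  out
}

.ast_to_gpa <- function(node, gid) {
  if (!is.null(node$gene))
    return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>', gid(node$gene)))
  inner <- paste(vapply(node$args, .ast_to_gpa, "", gid = gid), collapse = "")
  sprintf('<fbc:%s>%s</fbc:%s>', node$op, inner, node$op)
}
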