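# End-to-end pipeline orchestration with a YAML/list configuration,
# file-based intermediates, provenance records and hash-based resumption.

.cfg_default <- list(
  P = NULL, keffAvg = 65, slack = 0.02, budget = NULL,
  fractions = c(0, 0.5, 0.9, 0.99), clusters = NULL,
  keffMethod = "alternating", seed = 1, pUb = NULL)

#' Run the full pipeline
#'
#' Executes build -> per-sample proteome fit -> optional rate-constant
#' calibration and refit -> optional debottlenecking -> flux variability
#' and expression-dependence classification, writing every intermediate to
#' \code{outDir} in documented formats (PC-model/context JSON, TSV tables)
#' together with a provenance record (configuration, package version,
#' seeds, input hashes).  A stage whose outputs already exist under the
#' same configuration hash is not recomputed.
#'
#' @param config path to a YAML file or a named list with entries:
#'   \code{model} (SBML/JSON path), \code{fasta} (protein FASTA),
#'   \code{transcripts} (character vector of TSV paths), \code{P}
#'   (proteome budget, required), and optionally \code{keffAvg},
#'   \code{slack}, \code{clusters} (enable calibration with this many
#'   sample groups), \code{keffMethod}, \code{objective} (production
#'   reaction for debottlenecking/FVA), \code{budget} (overexpression E),
#'   \code{fractions}, \code{seed}, \code{pUb}
#' @param outDir output directory
#' @return invisibly, a list with the main in-memory results
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.cfg_default, config)
  for (need in c("model", "fasta", "transcripts", "P"))
    if (is.null(cfg[[need]]))
      stop("pipeline configuration is missing required entry '", need, "'")
  for (f in c(cfg$model, cfg$fasta, cfg$transcripts))
    if (!file.exists(f)) stop("input file does not exist: ", f)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  cfgFile <- file.path(outDir, "config_used.yaml")
  yaml::write_yaml(cfg, cfgFile)
  cfgHash <- unname(tools::md5sum(cfgFile))
  prov <- list(tool = "pcflux",
               version = as.character(utils::packageVersion("pcflux")),
               solver = "pcflux interior-point",
               configHash = cfgHash, seed = cfg$seed,
               inputs = as.list(tools::md5sum(c(cfg$model, cfg$fasta,
                                                cfg$transcripts))))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  fresh <- function(path) {
    file.exists(path) && file.exists(file.path(outDir, "stamp")) &&
      identical(readLines(file.path(outDir, "stamp"))[1], cfgHash)
  }
  writeStamp <- function() writeLines(cfgHash, file.path(outDir, "stamp"))

  # build
  pcPath <- file.path(outDir, "pc_model.json")
  if (fresh(pcPath)) {
    pcm <- readPCModel(pcPath)
  } else {
    model <- readMetabolicModel(cfg$model)
    proteins <- readProteinFasta(cfg$fasta)
    pcm <- buildPCModel(model, proteins, P = cfg$P, keffAvg = cfg$keffAvg,
                        pUb = if (is.null(cfg$pUb)) NULL else cfg$pUb)
    writePCModel(pcm, pcPath)
  }
  samples <- lapply(cfg$transcripts, readTranscripts)
  names(samples) <- sub("\\.tsv$", "", basename(cfg$transcripts))
  Tmat <- t(vapply(samples, function(t) alignTranscripts(pcm, t),
                   numeric(length(pcm@model@geneIds))))

  # optional rate-constant calibration
  if (!is.null(cfg$clusters)) {
    cl <- clusterSamples(Tmat, cfg$clusters)
    fit <- solveKeffNCQP(pcm, cl$means, method = cfg$keffMethod,
                         seed = cfg$seed)
    pcm <- withRates(pcm, fit$r)
    writePCModel(pcm, file.path(outDir, "pc_model_calibrated.json"))
    jsonlite::write_json(
      list(r = fit$r, rOri = fit$rOri, freeMask = fit$freeMask,
           objective = fit$objective, objectiveInitial = fit$objectiveInitial,
           method = fit$method, heuristic = fit$heuristic,
           status = fit$status, seed = cfg$seed),
      file.path(outDir, "keff_fit.json"), auto_unbox = TRUE, digits = NA)
  }

  # per-sample fit + contextualisation
  ctxs <- list(); reports <- list(); tScaled <- list()
  for (s in seq_len(nrow(Tmat))) {
    t <- scaleTranscriptome(Tmat[s, ], pcm@d, pcm@P)
    ft <- fitProteome(pcm, t)
    ctx <- contextualize(pcm, ft, s = cfg$slack)
    writeContextModel(ctx, file.path(outDir,
      sprintf("context_%s.json", rownames(Tmat)[s])))
    ctxs[[s]] <- ctx
    tScaled[[s]] <- t
    reports[[s]] <- consistencyReport(ft@pFit, t)
  }
  consist <- data.frame(
    sample = rownames(Tmat),
    r2 = vapply(reports, function(r) r@r2, numeric(1)),
    r2Star = vapply(reports, function(r) r@r2Star, numeric(1)),
    outliers = vapply(reports, function(r) length(r@outliers), integer(1)),
    farOutliers = vapply(reports, function(r) length(r@farOutliers),
                         integer(1)))
  utils::write.table(consist, file.path(outDir, "consistency.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  results <- list(pcm = pcm, contexts = ctxs, consistency = consist)

  if (!is.null(cfg$objective)) {
    # debottleneck (optional) and FVA/classification per sample
    if (!is.null(cfg$budget)) {
      db <- lapply(ctxs, debottleneck, objective = cfg$objective,
                   E = cfg$budget)
      tab <- do.call(rbind, lapply(seq_along(db), function(s)
        data.frame(sample = rownames(Tmat)[s],
                   gene = names(db[[s]]@epsilon),
                   pFit = ctxs[[s]]@pFit[ctxs[[s]]@measured],
                   epsilon = unname(db[[s]]@epsilon),
                   fold = unname(db[[s]]@fold))))
      utils::write.table(tab[tab$epsilon > 0, ],
                         file.path(outDir, "debottleneck_targets.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      results$debottleneck <- db
    }
    fvas <- lapply(ctxs, pcFVA, objective = cfg$objective,
                   fractions = cfg$fractions)
    for (s in seq_along(fvas))
      utils::write.table(fvas[[s]],
        file.path(outDir, sprintf("fva_%s.tsv", rownames(Tmat)[s])),
        sep = "\t", row.names = FALSE, quote = FALSE)
    if (length(fvas) >= 3) {
      cls <- classifyReactions(fvas, lapply(seq_len(nrow(Tmat)),
                                            function(s) Tmat[s, ]),
                               pcm@model)
      utils::write.table(cls, file.path(outDir, "classification.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      results$classification <- cls
    }
    results$fva <- fvas
  }
  writeStamp()
  invisible(results)
}
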