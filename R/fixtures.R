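# Seeded synthetic fixtures: desk-scale metabolic networks, protein
# sequences and transcriptomes with known ground truth, so every pipeline
# stage is testable without external data.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.random_protein <- function(len) {
  paste(sample(names(.aa_residue_mass), len, replace = TRUE), collapse = "")
}

#' Generate a random toy metabolic model with proteins
#'
#' Builds a feasible linear/branched conversion network: a substrate source,
#' a chain of internal conversions with random branch reactions (some
#' reversible), and an export objective.  Gene rules mix single genes,
#' isozymes ("or"), complexes ("and") and nested forms according to the
#' requested fractions; protein sequences are random with lengths 100-600.
#' The seed fully determines the output.
#'
#' @param nMetabolites internal metabolites (chain length), default 8
#' @param nReactions internal (gene-associated candidate) reactions,
#'   default 12; must be at least \code{nMetabolites - 1}
#' @param nGenes gene pool size, default 10
#' @param isozymeFraction,complexFraction fraction of reactions with "or" /
#'   "and" rules, defaults 0.2 each
#' @param seed RNG seed
#' @return list with \code{model} (\linkS4class{MetabolicModel}, objective =
#'   export of the terminal metabolite) and \code{proteins} (data.frame as
#'   from \code{\link{readProteinFasta}})
#' @export
makeToyModel <- function(nMetabolites = 8, nReactions = 12, nGenes = 10,
                         isozymeFraction = 0.2, complexFraction = 0.2,
                         seed = 1) {
  stopifnot(nReactions >= nMetabolites - 1, nMetabolites >= 2)
  .with_seed(seed, {
    for (attempt in 1:10) {
      mets <- sprintf("m%02d", seq_len(nMetabolites))
      genes <- sprintf("g%02d", seq_len(nGenes))
      rid <- character(0); ii <- list(); jj <- list(); xx <- list()
      lb <- numeric(0); ub <- numeric(0)
      addRxn <- function(id, stoich, l, u) {
        rid <<- c(rid, id)
        k <- length(rid)
        ii[[k]] <<- match(names(stoich), mets)
        jj[[k]] <<- rep(k, length(stoich))
        xx[[k]] <<- unname(stoich)
        lb <<- c(lb, l); ub <<- c(ub, u)
      }
      addRxn("SRC", c(m01 = 1), 0, 10)
      for (q in seq_len(nMetabolites - 1L)) {
        st <- c(-1, 1); names(st) <- mets[c(q, q + 1L)]
        addRxn(sprintf("CHN%02d", q), st, 0, 1000)
      }
      nBranch <- nReactions - (nMetabolites - 1L)
      for (q in seq_len(nBranch)) {
        ab <- sort(sample(nMetabolites, 2))
        st <- c(-1, 1); names(st) <- mets[ab]
        rev <- stats::runif(1) < 0.3
        addRxn(sprintf("BRN%02d", q), st, if (rev) -1000 else 0, 1000)
      }
      st <- c(-1); names(st) <- mets[nMetabolites]
      addRxn("EX", st, 0, 1000)

      internal <- grep("^(CHN|BRN)", rid)
      gpr <- character(length(rid))
      for (k in internal) {
        u <- stats::runif(1)
        pick <- function(n) sample(genes, n)
        gpr[k] <- if (u < isozymeFraction / 2) {
          g <- pick(3); sprintf("(%s and %s) or %s", g[1], g[2], g[3])
        } else if (u < isozymeFraction) {
          g <- pick(2); sprintf("%s or %s", g[1], g[2])
        } else if (u < isozymeFraction + complexFraction) {
          g <- pick(2); sprintf("%s and %s", g[1], g[2])
        } else pick(1)
      }
      obj <- as.numeric(rid == "EX")
      S <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                x = unlist(xx),
                                dims = c(nMetabolites, length(rid)))
      used <- unique(unlist(lapply(gpr, .gpr_genes)))
      model <- newMetabolicModel(rid, mets, genes, S, lb, ub, obj, gpr,
                                 subsystem = ifelse(grepl("^BRN", rid),
                                                    "branch", "core"),
                                 modelId = sprintf("toy_s%d", seed))
      sq <- vapply(genes, function(g)
        .random_protein(sample(100:600, 1)), "")
      proteins <- data.frame(geneId = genes, sequence = unname(sq),
                             mw = vapply(sq, computeMolecularWeight,
                                         numeric(1), USE.NAMES = FALSE))
      if (fba(model)$objective > 1e-6)
        return(list(model = model, proteins = proteins))
    }
    stop("failed to draw a feasible toy model in 10 attempts")
  })
}

#' The canonical Calvin-Benson cycle fixture
#'
#' A 13-reaction Calvin-Benson stoichiometry (RuBisCO carboxylation,
#' phosphoglycerate kinase, glyceraldehyde-3-phosphate dehydrogenase,
#' triose-phosphate isomerase, two aldolases, FBPase, SBPase, two
#' transketolases, ribulose-phosphate epimerase and isomerase,
#' phosphoribulokinase) with CO2/phosphate/water sources, ATP- and
#' NADH-regeneration pseudo-reactions and a triose-phosphate export sink.
#' All internal reactions are carbon- and phosphate-balanced; exporting one
#' triose-phosphate requires fixing three CO2 and consumes 9 ATP and
#' 6 NADH.
#'
#' @return a \linkS4class{MetabolicModel}; the objective is triose-phosphate
#'   export (\code{EX_gap}); \code{ATPS}/\code{NADHS} fluxes measure ATP and
#'   NADH consumption
#' @export
makeCalvinFixture <- function() {
  mets <- c("co2", "rubp", "pga", "bpg", "gap", "dhap", "fbp", "f6p",
            "e4p", "sbp", "s7p", "x5p", "r5p", "ru5p",
            "atp", "adp", "pi", "nadh", "nad", "h2o")
  rx <- list(
    RBC    = c(rubp = -1, co2 = -1, h2o = -1, pga = 2),
    PGK    = c(pga = -1, atp = -1, bpg = 1, adp = 1),
    GAPDH  = c(bpg = -1, nadh = -1, gap = 1, nad = 1, pi = 1),
    TPI    = c(gap = -1, dhap = 1),
    FBA    = c(gap = -1, dhap = -1, fbp = 1),
    FBPase = c(fbp = -1, h2o = -1, f6p = 1, pi = 1),
    TKT1   = c(f6p = -1, gap = -1, x5p = 1, e4p = 1),
    SBA    = c(e4p = -1, dhap = -1, sbp = 1),
    SBPase = c(sbp = -1, h2o = -1, s7p = 1, pi = 1),
    TKT2   = c(s7p = -1, gap = -1, x5p = 1, r5p = 1),
    RPE    = c(x5p = -1, ru5p = 1),
    RPI    = c(r5p = -1, ru5p = 1),
    PRK    = c(ru5p = -1, atp = -1, rubp = 1, adp = 1),
    ATPS   = c(adp = -1, pi = -1, atp = 1, h2o = 1),
    NADHS  = c(nad = -1, nadh = 1),
    SRC_co2 = c(co2 = 1),
    SRC_pi  = c(pi = 1),
    EX_h2o  = c(h2o = -1),
    EX_gap  = c(gap = -1))
  rid <- names(rx)
  reversible <- c("TPI", "TKT1", "TKT2", "RPE", "RPI", "EX_h2o")
  lb <- ifelse(rid %in% reversible, -1000, 0)
  ub <- rep(1000, length(rid))
  ii <- list(); jj <- list(); xx <- list()
  for (k in seq_along(rx)) {
    ii[[k]] <- match(names(rx[[k]]), mets)
    jj[[k]] <- rep(k, length(rx[[k]]))
    xx[[k]] <- unname(rx[[k]])
  }
  S <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(length(mets), length(rid)))
  enzymatic <- rid[1:13]
  genes <- sprintf("cbb%02d", seq_along(enzymatic))
  gpr <- character(length(rid))
  gpr[1:13] <- genes
  newMetabolicModel(rid, mets, genes, S, lb, ub,
                    obj = as.numeric(rid == "EX_gap"), gpr = gpr,
                    subsystem = ifelse(rid %in% enzymatic,
                                       "Calvin cycle", "exchange"),
                    modelId = "calvin")
}

#' Deterministic protein records for the Calvin fixture
#' @return data.frame as from \code{\link{readProteinFasta}}; sequence
#'   lengths grow with gene index so complex masses (and initial rate
#'   ratios) differ
#' @export
makeCalvinProteins <- function() {
  genes <- sprintf("cbb%02d", 1:13)
  base <- "ACDEFGHIKLMNPQRSTVWY"
  sq <- vapply(seq_along(genes), function(i)
    paste(rep(base, 10 + i), collapse = ""), "")
  data.frame(geneId = genes, sequence = sq,
             mw = vapply(sq, computeMolecularWeight, numeric(1),
                         USE.NAMES = FALSE))
}

#' Generate synthetic transcriptomes from a PC-model
#'
#' Per sample, a feasible flux state is drawn by protein-constrained FBA
#' under random objective weights; its minimal-mass proteome is the ground
#' truth, and the emitted transcript vector is the truth under
#' multiplicative lognormal noise, \eqn{t = p_{true} e^{\sigma Z}}, with a
#' random fraction of genes set to missing.
#'
#' @param pcm a \linkS4class{PCModel}
#' @param nSamples number of samples
#' @param sigma lognormal noise scale, default 0.2
#' @param nanFraction fraction of genes reported missing, default 0.05
#' @param seed RNG seed
#' @param rTrue optional per-complex true rate ratios used while
#'   generating (for rate-constant recovery experiments)
#' @return list with \code{T} (samples x genes abundance matrix, NA =
#'   missing), \code{pTrue} (samples x genes ground-truth proteomes) and
#'   \code{rTrue}
#' @export
makeSyntheticTranscriptomes <- function(pcm, nSamples, sigma = 0.2,
                                        nanFraction = 0.05, seed = 1,
                                        rTrue = NULL) {
  if (!is.null(rTrue)) pcm <- withRates(pcm, rTrue)
  genes <- pcm@model@geneIds
  nr <- length(pcm@model@reactionIds)
  .with_seed(seed, {
    T <- matrix(NA_real_, nSamples, length(genes),
                dimnames = list(sprintf("s%02d", seq_len(nSamples)), genes))
    ptm <- T
    for (s in seq_len(nSamples)) {
      cc <- stats::runif(nr) * (pcm@model@ub > 0)
      sol <- .pc_fba_vector(pcm, cc)
      if (sol$status != "optimal") stop("sample ", s, ": PC-FBA failed")
      p <- pmax(sol$p, 0)
      ptm[s, ] <- p
      t <- p * exp(sigma * stats::rnorm(length(genes)))
      t[stats::runif(length(genes)) < nanFraction] <- NA
      T[s, ] <- t
    }
    list(T = T, pTrue = ptm, rTrue = if (is.null(rTrue)) pcm@rates@rOri
                                     else rTrue)
  })
}

# PC-FBA with an arbitrary flux-objective vector (max c'v, then min p'd)
.pc_fba_vector <- function(pcm, cc) {
  cons <- pcConstraints(pcm)
  c1 <- numeric(cons$ntot); c1[cons$iv] <- -cc
  c2 <- numeric(cons$ntot); c2[cons$ip] <- unname(pcm@d)
  sol <- ipSolveLex(list(list(c = c1), list(c = c2)),
                    A = cons$A, rlb = cons$rlb, rub = cons$rub,
                    lb = cons$lb, ub = cons$ub)
  .pc_solution(sol, cons, pcm,
               objValue = if (sol$status == "optimal") -sol$primary else NA)
}

#' Rate-constant recovery fixture
#'
#' A deterministic three-pathway network built for calibration experiments:
#' a substrate feeds three demanded product pathways, each catalysed by a
#' single-gene complex.  Two complexes (high-abundance subunits) are free
#' to calibrate; the third stays fixed.  Two noiseless "sample groups" with
#' different pathway demands are generated from the minimal proteome at a
#' known \code{rTrue} (mean 1, inside the 0.1-1.9 bounds), and the budget
#' equals the larger group's proteome mass so that group's transcripts pin
#' the rate constants exactly.
#'
#' @return list with \code{model}, \code{proteins}, \code{P},
#'   \code{rTrue} (named by complex), \code{groupMeans} (2 x genes matrix)
#'   and \code{demands} (the per-group demand bounds used)
#' @export
makeKeffFixture <- function() {
  mets <- c("a", "b1", "b2", "b3")
  rx <- list(SRC = c(a = 1),
             P1 = c(a = -1, b1 = 1), P2 = c(a = -1, b2 = 1),
             P3 = c(a = -1, b3 = 1),
             EX1 = c(b1 = -1), EX2 = c(b2 = -1), EX3 = c(b3 = -1))
  rid <- names(rx)
  ii <- list(); jj <- list(); xx <- list()
  for (k in seq_along(rx)) {
    ii[[k]] <- match(names(rx[[k]]), mets)
    jj[[k]] <- rep(k, length(rx[[k]])); xx[[k]] <- unname(rx[[k]])
  }
  S <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(length(mets), length(rid)))
  demands <- list(g1 = c(EX1 = 2, EX2 = 1, EX3 = 0.1),
                  g2 = c(EX1 = 1, EX2 = 2, EX3 = 0.1))
  lb <- c(0, 0, 0, 0, 0, 0, 0)   # per-group demand lbs set below
  ub <- c(10, 1000, 1000, 1000, 10, 10, 10)
  genes <- c("gA", "gB", "gC")
  gpr <- c("", "gA", "gB", "gC", "", "", "")
  model <- newMetabolicModel(rid, mets, genes, S, lb, ub,
                             obj = as.numeric(rid == "EX1"), gpr = gpr,
                             modelId = "keff_fixture")
  proteins <- data.frame(geneId = genes,
                         sequence = rep(paste(rep("ACDEFGHIKL", 45),
                                              collapse = ""), 3))
  proteins$mw <- vapply(proteins$sequence, computeMolecularWeight,
                        numeric(1), USE.NAMES = FALSE)
  kappa <- 65 * 3600e-6
  rTrue <- c(1.3, 0.7, 1.0)
  pTrue <- vapply(demands, function(q)
    c(gA = q[["EX1"]] / (kappa * rTrue[1]),
      gB = q[["EX2"]] / (kappa * rTrue[2]),
      gC = q[["EX3"]] / (kappa * rTrue[3])), c(gA = 0, gB = 0, gC = 0))
  d <- proteins$mw
  P <- max(colSums(pTrue * d))
  groupMeans <- t(pTrue)
  rownames(groupMeans) <- names(demands)
  list(model = model, proteins = proteins, P = P,
       rTrue = stats::setNames(rTrue, c("gA", "gB", "gC")),
       groupMeans = groupMeans, demands = demands)
}

#' Apply a demand set of the rate-constant fixture
#' @param model the fixture model
#' @param demand named vector of export lower bounds (one group of
#'   \code{makeKeffFixture()$demands})
#' @return the model with those demand lower bounds set
#' @export
applyDemands <- function(model, demand) {
  idx <- match(names(demand), model@reactionIds)
  stopifnot(!anyNA(idx))
  model@lb[idx] <- unname(demand)
  model
}

#' Write fixture files to a directory
#'
#' Serialises a toy fixture to the standard interchange formats so the
#' pipeline can be exercised end to end through the public readers: the
#' model as SBML and COBRA-JSON, proteins as FASTA, and transcriptome
#' samples as per-sample TSV files.
#'
#' @param dir output directory (created if needed)
#' @param kind \code{"toy"}, \code{"calvin"} or \code{"timecourse"} (a toy
#'   model plus synthetic transcriptome samples)
#' @param seed RNG seed
#' @param nSamples samples for \code{"timecourse"}, default 4
#' @param P proteome budget used when generating transcriptomes, default 10
#' @return invisibly, the paths written
#' @export
writeFixtures <- function(dir, kind = c("toy", "calvin", "timecourse"),
                          seed = 1, nSamples = 4, P = 10) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wfasta <- function(proteins, path) {
    writeLines(paste0(">", proteins$geneId, "\n", proteins$sequence), path)
    path
  }
  if (kind == "calvin") {
    model <- makeCalvinFixture()
    p <- file.path(dir, "calvin.xml")
    writeMetabolicModel(model, p)
    paths <- c(paths, p, wfasta(makeCalvinProteins(),
                                file.path(dir, "calvin.faa")))
  } else {
    fx <- makeToyModel(seed = seed)
    p1 <- file.path(dir, "toy.xml"); p2 <- file.path(dir, "toy.json")
    writeMetabolicModel(fx$model, p1); writeMetabolicModel(fx$model, p2)
    paths <- c(paths, p1, p2, wfasta(fx$proteins, file.path(dir, "toy.faa")))
    if (kind == "timecourse") {
      pcm <- buildPCModel(fx$model, fx$proteins, P = P)
      tr <- makeSyntheticTranscriptomes(pcm, nSamples, seed = seed)
      for (s in seq_len(nSamples)) {
        pt <- file.path(dir, sprintf("transcripts_s%02d.tsv", s))
        writeTranscripts(tr$T[s, ], pt)
        paths <- c(paths, pt)
      }
    }
  }
  invisible(paths)
}
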