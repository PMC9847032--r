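test_that("molecular weights match an independent peptide-mass oracle", {
  # reference values from a standard average-mass peptide calculator (Da)
  expect_equal(computeMolecularWeight("G") * 1e6, 75.0666, tolerance = 1e-5)
  expect_equal(computeMolecularWeight("GG") * 1e6, 132.1179, tolerance = 1e-5)
  expect_equal(computeMolecularWeight("ACDEFGHIKLMNPQRSTVWY") * 1e6,
               2395.7134, tolerance = 1e-5)
})

test_that("mass is composition-invariant and X gets the mean residue mass", {
  sq <- "MKVLAWGGTR"
  rev <- paste(rev(strsplit(sq, "")[[1]]), collapse = "")
  expect_equal(computeMolecularWeight(sq), computeMolecularWeight(rev))
  # X carries the mean of the 20 standard residue masses
  expect_equal(computeMolecularWeight("X") * 1e6,
               (2395.7134 - 18.0152) / 20 + 18.0152, tolerance = 1e-3)
  expect_error(computeMolecularWeight(""), "empty")
  expect_error(computeMolecularWeight("GZ"), "invalid")
  expect_warning(computeMolecularWeight("GU"), "selenocysteine")
})

test_that("protein FASTA parsing extracts locus tags and deduplicates", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">g1 some description", "GG", ">g2", "MKV"), f)
  p <- readProteinFasta(f)
  expect_identical(p$geneId, c("g1", "g2"))
  expect_identical(p$sequence[1], "GG")
  expect_equal(p$mw[1] * 1e6, 132.1179, tolerance = 1e-4)

  f2 <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">g1", "GG", ">g1", "MKV"), f2)
  expect_warning(p2 <- readProteinFasta(f2), "duplicate")
  expect_identical(nrow(p2), 1L)
  expect_identical(p2$sequence, "GG")

  f3 <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">g1", "GZ"), f3)
  expect_error(readProteinFasta(f3), "g1")
})

test_that("model round-trips through SBML and COBRA-JSON", {
  fx <- makeToyModel(seed = 3)
  m <- fx$model
  for (fmt in c("sbml", "json")) {
    path <- withr::local_tempfile(fileext = if (fmt == "json") ".json" else ".xml")
    writeMetabolicModel(m, path, format = fmt)
    m2 <- readMetabolicModel(path, format = fmt)
    expect_identical(m2@reactionIds, m@reactionIds)
    expect_identical(m2@metaboliteIds, m@metaboliteIds)
    expect_setequal(m2@geneIds, m@geneIds)
    expect_equal(as.matrix(m2@S), as.matrix(m@S), ignore_attr = TRUE)
    expect_equal(m2@lb, m@lb)
    expect_equal(m2@ub, m@ub)
    expect_equal(m2@obj, m@obj)
    expect_identical(lapply(m2@gpr, parseGeneRule), lapply(m@gpr, parseGeneRule))
    expect_identical(m2@subsystem, m@subsystem)
    # read -> write -> read is idempotent
    path2 <- withr::local_tempfile(fileext = if (fmt == "json") ".json" else ".xml")
    writeMetabolicModel(m2, path2, format = fmt)
    m3 <- readMetabolicModel(path2, format = fmt)
    expect_equal(as.matrix(m3@S), as.matrix(m2@S), ignore_attr = TRUE)
    expect_identical(m3@gpr, m2@gpr)
  }
})

test_that("written SBML is readable by an independent SBML implementation", {
  m <- makeCalvinFixture()
  path <- withr::local_tempfile(fileext = ".xml")
  writeMetabolicModel(m, path, format = "sbml")
  out <- system2("python", c("-c", shQuote(paste0(
    "import cobra; m = cobra.io.read_sbml_model('", path, "'); ",
    "print(len(m.reactions), len(m.metabolites), len(m.genes)); ",
    "print(round(m.optimize().objective_value, 6))"))),
    stdout = TRUE, stderr = FALSE)
  expect_identical(out[1], "19 20 13")
  # independent FBA optimum equals ours
  expect_equal(as.numeric(out[2]), fba(m)$objective, tolerance = 1e-5)
})

test_that("SBML without flux bounds is rejected", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeMetabolicModel(makeCalvinFixture(), path)
  txt <- readLines(path)
  txt <- gsub(' fbc:lowerFluxBound="[^"]*"', "", txt)
  txt <- gsub(' fbc:upperFluxBound="[^"]*"', "", txt)
  writeLines(txt, path)
  expect_error(readMetabolicModel(path), "no flux bounds")
})

test_that("transcript tables round-trip with missing values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTranscripts(c(g1 = 1.5, g2 = NA, g3 = 0), f)
  t <- readTranscripts(f)
  expect_equal(t, c(g1 = 1.5, g2 = NA, g3 = 0))
  m <- makeCalvinFixture()
  al <- alignTranscripts(m, c(cbb01 = 2, unrelated = 9))
  expect_equal(unname(al[c("cbb01", "cbb02")]), c(2, NA))
})

test_that("model merge unions reactions and drops replaced content", {
  fx <- makeToyModel(seed = 5)
  a <- fx$model
  S <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 2))
  S[1, 2] <- -1
  b <- newMetabolicModel(c("ORG1", "ORG2"), "om1", "gz1", S,
                         lb = c(0, 0), ub = c(10, 10),
                         gpr = c("gz1", ""), modelId = "organelle")
  mrg <- mergeModels(a, b, dropReactions = "BRN01")
  expect_true(all(c("ORG1", "ORG2") %in% mrg@reactionIds))
  expect_false("BRN01" %in% mrg@reactionIds)
  expect_true("om1" %in% mrg@metaboliteIds)
  expect_true("gz1" %in% mrg@geneIds)
  expect_identical(length(mrg@reactionIds),
                   length(a@reactionIds) - 1L + 2L)
})
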