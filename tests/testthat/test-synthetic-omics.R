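test_that("identical seed and parameters give bit-identical datasets", {
  d <- studyDesign(regions = c("M1", "S1"), nPerGroup = 4L,
                   sexSplit = c(M = 2L, F = 2L))
  a <- simulateAbundanceExperiment(d, nFeatures = 50, seed = 7)
  b <- simulateAbundanceExperiment(d, nFeatures = 50, seed = 7)
  expect_identical(lapply(a$experiments, assay), lapply(b$experiments, assay))
  expect_identical(a$truth, b$truth)
  c2 <- simulateAbundanceExperiment(d, nFeatures = 50, seed = 8)
  expect_false(identical(assay(a$experiments$M1), assay(c2$experiments$M1)))
})

test_that("noiseless planted effects reproduce exact grouped ratios", {
  d <- studyDesign(nPerGroup = 4L, sexSplit = c(M = 2L, F = 2L))
  sim <- simulateAbundanceExperiment(d, nFeatures = 20,
                                     fracDifferential = 0.2,
                                     effectLog2 = 1, sharedFrac = 0,
                                     noiseSd = 0,
                                     channelLoadingRange = c(1, 1),
                                     seed = 3)
  eff <- sim$truth$effectLog2
  diffFeat <- which(rowSums(eff != 0) > 0)
  expect_true(length(diffFeat) >= 1)
  for (r in colnames(eff)) {
    dt <- suppressWarnings(   # zero variance is intended in noiseless data
      differentialTable(sim$experiments[[r]], normalize = FALSE))
    expect_equal(dt@records$AR, 2^eff[, r], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("shared and unique effect masks are disjoint and consistent", {
  sim <- simulateAbundanceExperiment(nFeatures = 200,
                                     fracDifferential = 0.3,
                                     sharedFrac = 0.5, seed = 11)
  tr <- sim$truth
  expect_false(any(tr$sharedMask & tr$uniqueMask))
  ## shared features carry the same effect in every region
  sharedEff <- tr$effectLog2[tr$sharedMask, , drop = FALSE]
  expect_true(all(apply(sharedEff, 1, function(e) length(unique(e)) == 1)))
  ## unique features hit exactly one region
  uniqueEff <- tr$effectLog2[tr$uniqueMask, , drop = FALSE]
  expect_true(all(rowSums(uniqueEff != 0) == 1))
  ## non-differential features have zero effect everywhere
  nullEff <- tr$effectLog2[!(tr$sharedMask | tr$uniqueMask), , drop = FALSE]
  expect_true(all(nullEff == 0))
  expect_true(all(unlist(tr$channelLoading) > 0))
})

test_that("generator rejects invalid parameters", {
  expect_error(simulateAbundanceExperiment(nFeatures = 0), "positive")
  expect_error(simulateAbundanceExperiment(nFeatures = 10, noiseSd = -1),
               "non-negative")
  expect_error(simulateAbundanceExperiment(nFeatures = 10,
                                           fracDifferential = 1.5),
               "\\[0, 1\\]")
  expect_error(simulateAbundanceExperiment(nFeatures = 10,
                                           channelLoadingRange = c(-1, 2)),
               "positive")
})

test_that("total-amount normalization undoes channel loading exactly", {
  d <- studyDesign(regions = "M1")
  sim <- simulateAbundanceExperiment(d, nFeatures = 80,
                                     fracDifferential = 0, noiseSd = 0,
                                     channelLoadingRange = c(0.5, 2),
                                     seed = 5)
  ae <- sim$experiments$M1
  norm <- normalizeTotalAmount(ae)
  cs <- colSums(assay(norm))
  expect_equal(max(abs(cs / mean(cs) - 1)), 0, tolerance = 1e-9)
  ## loading-free profile restored: all columns proportional to 2^base
  a <- assay(norm)
  ratios <- a / a[, 1]
  expect_equal(max(abs(ratios - 1)), 0, tolerance = 1e-9)
})

test_that("kinase-substrate map generator respects its construction rules", {
  feats <- sprintf("P%03d_S%d", 1:50, 1:50)
  expect_equal(nrow(simulateKinaseSubstrateMap(0, 5, feats)), 0)
  m <- simulateKinaseSubstrateMap(2, 5, feats, seed = 4)
  expect_equal(nrow(m), 10)
  expect_true(all(m$substrate %in% feats))
  expect_true(all(m$networkin_score >= 0))
  expect_true(all(m$source %in% c("PSP", "NetworKIN")))
  expect_error(simulateKinaseSubstrateMap(2, 100, feats), "exceeds")
  expect_error(simulateKinaseSubstrateMap(2, 5, character(0)), "non-empty")
})

test_that("annotation db generator and GMT writer round-trip losslessly", {
  genes <- sprintf("Gene%04d", 1:200)
  db <- simulateAnnotationDb(10, genes, "Reactome", seed = 2)
  expect_true(all(lengths(db) >= 1))
  expect_identical(attr(db, "category"), "Reactome")
  path <- tempfile(fileext = ".gmt")
  writeGmt(db, path)
  back <- readGmt(path)
  expect_identical(back[names(db)], db[names(db)], ignore_attr = TRUE)
  expect_identical(attr(back, "category"), "Reactome")
  ## agreement with an independent GMT reader
  fg <- fgsea::gmtPathways(path)
  expect_identical(lapply(fg, unname), lapply(db, unname)[names(fg)])
  expect_error(simulateAnnotationDb(5, genes, "NotACategory"))
})

test_that("a universe term is never enriched and a planted term wins", {
  set.seed(42)
  genes <- sprintf("Gene%04d", 1:500)
  universeDb <- list(ALL = genes)
  attr(universeDb, "category") <- "KEGG"
  hits <- sample(genes, 40)
  er <- enrichTerms(hits, genes, universeDb, filter = FALSE)
  expect_equal(er$p_value, 1)   # observed always equals expected draw
  ## planted term = exactly the input list has the smallest p of all terms
  db <- simulateAnnotationDb(20, genes, "KEGG", seed = 9)
  db$PLANTED <- hits
  er2 <- enrichTerms(hits, genes, db, filter = FALSE)
  expect_equal(er2$term_id[which.min(er2$p_value)], "PLANTED")
  ## brute-force check: minimum p among all terms by direct phyper
  ps <- sapply(names(db), function(tm) {
    K <- length(intersect(db[[tm]], genes))
    obs <- length(intersect(hits, db[[tm]]))
    phyper(obs - 1, K, length(genes) - K, length(hits), lower.tail = FALSE)
  })
  expect_equal(min(er2$p_value), unname(min(ps)), tolerance = 1e-12)
})
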