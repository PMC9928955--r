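test_that("normalization equalizes column sums and inverts loadings", {
  set.seed(42)
  m <- matrix(rlnorm(50 * 16, 10, 1), 50, 16)
  ae <- toyExperiment(m)
  norm <- normalizeTotalAmount(ae)
  cs <- colSums(assay(norm))
  expect_equal(max(abs(cs / mean(cs) - 1)), 0, tolerance = 1e-9)
  ## matrices already equal in column sum pass through unchanged
  eq <- sweep(m, 2, colSums(m), `/`)
  aeEq <- toyExperiment(eq * 1000)
  expect_equal(assay(normalizeTotalAmount(aeEq)), assay(aeEq),
               tolerance = 1e-12)
  ## doubling one column is undone relative to the rest (up to the overall
  ## target scale, which is the mean input column sum)
  m2 <- m; m2[, 3] <- 2 * m2[, 3]
  n1 <- assay(normalizeTotalAmount(toyExperiment(m)))
  n2 <- assay(normalizeTotalAmount(toyExperiment(m2)))
  expect_equal(sweep(n1, 2, colSums(n1), `/`),
               sweep(n2, 2, colSums(n2), `/`), tolerance = 1e-12)
})

test_that("t-test p-values match independent references to 1e-12", {
  set.seed(7)
  m <- matrix(rlnorm(20 * 16, 8, 0.5), 20, 16)
  ae <- toyExperiment(m)
  for (tst in c("student", "welch")) {
    dt <- differentialTable(ae, test = tst, normalize = FALSE)
    lm2 <- log2(m)
    for (i in 1:20) {
      x <- lm2[i, 1:8]; y <- lm2[i, 9:16]
      ## textbook formula oracle
      orc <- oracleT(x, y, welch = tst == "welch")
      expect_equal(dt@records$p_value[i], orc$p, tolerance = 1e-12)
      ## base-R reference
      tr <- t.test(x, y, var.equal = tst == "student")
      expect_equal(dt@records$p_value[i], tr$p.value, tolerance = 1e-12)
    }
  }
})

test_that("grouped ratios follow the analytic limits", {
  ## identical PME and PSE values: AR = 1, t = 0, p = 1
  m <- matrix(5, 3, 8)
  dt <- differentialTable(toyExperiment(m), normalize = FALSE)
  expect_equal(dt@records$AR, rep(1, 3))
  expect_equal(dt@records$log2_ar, rep(0, 3))
  expect_equal(dt@records$p_value, rep(1, 3))
  ## PME = 4s, PSE = 2s with infinitesimal jitter: AR = 2, log2 = 1
  set.seed(1)
  m2 <- rbind(c(4, 4, 4, 4, 2, 2, 2, 2) +
              rnorm(8, 0, 1e-9))
  dt2 <- differentialTable(toyExperiment(m2), normalize = FALSE)
  expect_equal(dt2@records$AR, 2, tolerance = 1e-6)
  expect_equal(dt2@records$log2_ar, 1, tolerance = 1e-6)
  ## zero variance, unequal means: p adjacent to 0 with a warning
  m3 <- rbind(c(4, 4, 4, 4, 2, 2, 2, 2))
  expect_warning(dt3 <- differentialTable(toyExperiment(m3),
                                          normalize = FALSE),
                 "zero within-group variance")
  expect_lt(dt3@records$p_value, 1e-300)
})

test_that("significance counting matches a brute-force recount", {
  set.seed(13)
  m <- matrix(rlnorm(300 * 16, 9, 0.4), 300, 16)
  m[1:30, 1:8] <- m[1:30, 1:8] * 2      # planted up features
  dt <- differentialTable(toyExperiment(m), normalize = FALSE)
  fc <- filterAndCount(dt)
  r <- as.data.frame(dt@records)
  expect_equal(fc$n_significant, sum(r$p_value < 0.05))
  expect_equal(fc$n_up, sum(r$p_value < 0.05 & r$log2_ar > 0))
  expect_equal(fc$n_down, sum(r$p_value < 0.05 & r$log2_ar < 0))
  expect_equal(fc$n_up + fc$n_down, fc$n_significant)
  expect_identical(unname(diffCounts(dt)),
                   c(fc$n_significant, fc$n_up, fc$n_down))
  ## all p = 0.5 gives an empty subset
  dt@records$p_value <- rep(0.5, nrow(dt@records))
  dt@records$significant <- FALSE
  fc0 <- filterAndCount(dt)
  expect_equal(c(fc0$n_significant, fc0$n_up, fc0$n_down), c(0, 0, 0))
})

test_that("a table with 200 up and 1048 down significant records counts as such", {
  n <- 1400
  up <- c(rep(TRUE, 200), rep(FALSE, n - 200))
  sig <- c(rep(TRUE, 1248), rep(FALSE, n - 1248))
  rec <- S4Vectors::DataFrame(
    feature_id = sprintf("F%04d", 1:n), gene_id = sprintf("G%04d", 1:n),
    mean_pme = 2, mean_pse = 1,
    AR = ifelse(up, 2, 0.5), log2_ar = ifelse(up, 1, -1),
    p_value = ifelse(sig, 0.01, 0.5), significant = sig,
    direction = ifelse(up, "up", "down"))
  dt <- new("DifferentialTable", records = rec, alpha = 0.05,
            region = "M1", level = "proteome", test = "student")
  fc <- filterAndCount(dt)
  expect_equal(fc$n_up, 200)
  expect_equal(fc$n_down, 1048)
})

test_that("AR and p are invariant to per-feature rescaling", {
  set.seed(21)
  m <- matrix(rlnorm(10 * 16, 8, 0.5), 10, 16)
  dt1 <- differentialTable(toyExperiment(m), normalize = FALSE)
  m2 <- m; m2[4, ] <- m2[4, ] * 37.5
  dt2 <- differentialTable(toyExperiment(m2), normalize = FALSE)
  expect_equal(dt1@records$AR[4], dt2@records$AR[4], tolerance = 1e-12)
  expect_equal(dt1@records$p_value[4], dt2@records$p_value[4],
               tolerance = 1e-12)
})

test_that("average-linkage clustering orders features and samples sensibly", {
  ## two identical profiles merge first at distance 0
  set.seed(3)
  base <- rlnorm(8, 8, 0.3)
  m <- rbind(base, base, rlnorm(8, 8, 0.3), rlnorm(8, 8, 0.3))
  ae <- toyExperiment(m)
  cl <- clusterDifferential(ae, features = sprintf("F%03d", 1:4))
  h <- cl$featureDendrogram
  expect_equal(sort(-h$merge[1, ]), c(1, 2))
  expect_equal(h$height[1], 0, tolerance = 1e-9)
  ## correlated pair joins before the uncorrelated third profile
  t8 <- seq_len(8)
  m3 <- 2^rbind(10 + sin(t8), 10 + 0.95 * sin(t8) + 0.01 * cos(t8),
                10 + cos(2 * t8))
  cl3 <- clusterDifferential(toyExperiment(m3),
                             features = sprintf("F%03d", 1:3))
  expect_equal(sort(-cl3$featureDendrogram$merge[1, ]), c(1, 2))
  ## planted group effect separates PME from PSE at the top split
  d <- studyDesign(regions = "M1")
  sim <- simulateAbundanceExperiment(d, nFeatures = 100,
                                     fracDifferential = 0.4,
                                     effectLog2 = 2, noiseSd = 0.2,
                                     seed = 17)
  aeP <- sim$experiments$M1
  dtP <- differentialTable(aeP)
  clP <- clusterDifferential(aeP, significantFeatures(dtP))
  groups2 <- cutree(clP$sampleDendrogram, 2)
  expect_equal(length(unique(groups2[groupLabels(aeP) == "PME"])), 1)
  expect_equal(length(unique(groups2[groupLabels(aeP) == "PSE"])), 1)
  ## degenerate input
  expect_error(clusterDifferential(aeP, "F001"), "at least 2")
})
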