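kseaToySites <- function() {
  data.frame(
    feature_id = sprintf("S%02d", 1:12),
    log2_fc = rep(c(1, -1, 0), each = 4),
    localization_confirmed = TRUE)
}

test_that("the KSEA z-score matches the hand formula", {
  sites <- kseaToySites()
  ## kinase K hits the four +1 sites; p_bar = 0, delta = sqrt(2/3)
  map <- data.frame(kinase = "K", substrate = sprintf("S%02d", 1:4),
                    source = "PSP", networkin_score = 0)
  ks <- kseaScores(sites, map)
  s <- as.data.frame(kseaTable(ks))
  expect_equal(ks@globalMean, 0)
  expect_equal(ks@globalSd, sqrt(8 / 12), tolerance = 1e-12)
  expect_equal(s$m, 4L)
  expect_equal(s$z, (1 - 0) * 2 / sqrt(8 / 12), tolerance = 1e-12)
  expect_equal(s$z, oracleKseaZ(sites$log2_fc, rep(1, 4)),
               tolerance = 1e-12)
  expect_equal(s$p_value, 2 * pnorm(-abs(s$z)), tolerance = 1e-12)
  ## substrate mean equal to the global mean gives z = 0
  map0 <- data.frame(kinase = "K0", substrate = c("S01", "S05", "S09"),
                     source = "PSP", networkin_score = 0)
  ## substrates at {+1, -1, 0}: mean 0 = global mean
  expect_equal(as.data.frame(kseaTable(kseaScores(sites, map0)))$z, 0)
})

test_that("z is invariant to shifting every site by a constant", {
  set.seed(5)
  sites <- data.frame(feature_id = sprintf("S%03d", 1:100),
                      log2_fc = rnorm(100, 0, 0.4),
                      localization_confirmed = TRUE)
  map <- simulateKinaseSubstrateMap(5, 8, sites$feature_id, seed = 6)
  names(map)[names(map) == "substrate"] <- "substrate"
  z1 <- as.data.frame(kseaTable(kseaScores(sites, map)))$z
  sites2 <- sites; sites2$log2_fc <- sites2$log2_fc + 0.7
  z2 <- as.data.frame(kseaTable(kseaScores(sites2, map)))$z
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("global statistics depend on the site table, not the map", {
  set.seed(8)
  sites <- data.frame(feature_id = sprintf("S%03d", 1:80),
                      log2_fc = rnorm(80, 0, 0.3),
                      localization_confirmed = TRUE)
  map <- simulateKinaseSubstrateMap(4, 6, sites$feature_id, seed = 2)
  full <- kseaScores(sites, map)
  drop1 <- kseaScores(sites, map[map$kinase != "KIN01", ])
  expect_identical(full@globalMean, drop1@globalMean)
  expect_identical(full@globalSd, drop1@globalSd)
  a <- as.data.frame(kseaTable(full))
  b <- as.data.frame(kseaTable(drop1))
  expect_false("KIN01" %in% b$kinase)
  shared <- intersect(a$kinase, b$kinase)
  expect_equal(a$z[match(shared, a$kinase)], b$z[match(shared, b$kinase)])
})

test_that("filters and degenerate inputs behave as documented", {
  sites <- kseaToySites()
  ## NetworKIN rows below the cutoff are dropped; PSP rows are kept
  map <- data.frame(kinase = "K",
                    substrate = sprintf("S%02d", 1:4),
                    source = c("PSP", "NetworKIN", "NetworKIN", "PSP"),
                    networkin_score = c(0, 0.4, 3, 0))
  ks <- kseaScores(sites, map, networkinCutoff = 1)
  expect_equal(as.data.frame(kseaTable(ks))$m, 3L)
  ## duplicate (kinase, substrate) rows count once
  mapDup <- rbind(map, map)
  expect_equal(as.data.frame(kseaTable(kseaScores(sites, mapDup)))$m, 4L)
  ## unconfirmed sites are excluded (here: every mapped substrate)
  sitesU <- kseaToySites(); sitesU$localization_confirmed[1:4] <- FALSE
  expect_warning(ksU <- kseaScores(sitesU, map), "no usable")
  expect_equal(nrow(kseaTable(ksU)), 0)
  ## empty usable map warns and returns an empty result
  expect_warning(
    ks0 <- kseaScores(sites, data.frame(kinase = character(0),
                                        substrate = character(0),
                                        source = character(0),
                                        networkin_score = numeric(0))),
    "no usable")
  expect_equal(nrow(kseaTable(ks0)), 0)
  ## constant fold changes are degenerate
  cst <- data.frame(feature_id = c("A", "B"), log2_fc = c(0.2, 0.2),
                    localization_confirmed = TRUE)
  expect_error(kseaScores(cst, map), "degenerate")
})

test_that("a planted substrate shift yields a positive z", {
  set.seed(10)
  sites <- data.frame(feature_id = sprintf("S%04d", 1:1000),
                      log2_fc = rnorm(1000, 0, 0.3),
                      localization_confirmed = TRUE)
  planted <- sprintf("S%04d", 1:10)
  sites$log2_fc[1:10] <- sites$log2_fc[1:10] + 0.5
  map <- data.frame(kinase = "PLANTED", substrate = planted,
                    source = "PSP", networkin_score = 0)
  s <- as.data.frame(kseaTable(kseaScores(sites, map)))
  expect_gt(s$z, 0)
})

test_that("the kinome annotation export carries |z| as node size", {
  sites <- kseaToySites()
  map <- data.frame(kinase = c("KA", "KA", "KB", "KB"),
                    substrate = c("S05", "S06", "S01", "S09"),
                    source = "PSP", networkin_score = 0)
  ks <- kseaScores(sites, map)
  coral <- kinomeExport(ks)
  expect_named(coral, c("kinase", "branch_value", "node_color_value",
                        "node_size_value"))
  expect_equal(coral$node_size_value, abs(coral$node_color_value))
  expect_true(all(diff(coral$node_size_value) <= 0))  # |z| descending
  s <- as.data.frame(kseaTable(ks))
  expect_equal(coral$branch_value[match(s$kinase, coral$kinase)], s$fdr)
  ## numeric round-trip through TSV at full precision
  path <- tempfile(fileext = ".tsv")
  write.table(format(coral, digits = 17), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read.delim(path)
  expect_equal(back$node_color_value, coral$node_color_value,
               tolerance = 1e-15)
})

test_that("under the null, kinase p-values are calibrated and FDR is quiet", {
  set.seed(42)
  ps <- fdrHits <- NULL
  for (rep in 1:30) {
    sites <- data.frame(feature_id = sprintf("S%04d", 1:500),
                        log2_fc = rnorm(500, 0, 0.3),
                        localization_confirmed = TRUE)
    map <- simulateKinaseSubstrateMap(40, 10, sites$feature_id,
                                      seed = rep)
    s <- as.data.frame(kseaTable(kseaScores(sites, map)))
    ps <- c(ps, s$p_value)
    fdrHits <- c(fdrHits, sum(s$fdr < 0.05))
  }
  expect_gt(mean(ps < 0.05), 0.03)
  expect_lt(mean(ps < 0.05), 0.07)
  expect_lt(mean(fdrHits), 0.5)
})
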