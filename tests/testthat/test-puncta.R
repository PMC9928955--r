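smallTruth <- function(...) {
  simulateImageGroundTruth(stackShape = c(z = 40L, y = 120L, x = 120L), ...)
}

test_that("neuropil estimation excludes occluder volume geometrically", {
  ## nucleus sphere of radius r excludes close to (4/3) pi r^3
  tr <- smallTruth(nPairs = 20L, nUnpairedPre = 0L, nUnpairedPost = 0L,
                   nNuclei = 1L, nucleusRadius = 1.2, seed = 51)
  st <- simulateImageStack(tr, snr = 100, seed = 52)
  np <- estimateNeuropil(st)
  exclVol <- sum(np$exclusionMask) * prod(st@voxelSize)
  expect_lt(abs(exclVol - 4 / 3 * pi * 1.2^3) / (4 / 3 * pi * 1.2^3), 0.1)
  expect_lt(abs(np$neuropilVolume - tr$neuropilVolume) / tr$neuropilVolume,
            0.05)
  ## no occluders: neuropil covers the tissue-filled stack
  tr0 <- smallTruth(nPairs = 20L, seed = 53)
  st0 <- simulateImageStack(tr0, snr = 100, seed = 54)
  np0 <- estimateNeuropil(st0)
  expect_lt(abs(np0$neuropilVolume - tr0$neuropilVolume) /
            tr0$neuropilVolume, 0.02)
  ## growing the occluder monotonically shrinks the neuropil
  tr2 <- smallTruth(nPairs = 20L, nUnpairedPre = 0L, nUnpairedPost = 0L,
                    nNuclei = 2L, nucleusRadius = 1.2, seed = 51)
  st2 <- simulateImageStack(tr2, snr = 100, seed = 52)
  np2 <- estimateNeuropil(st2)
  expect_lt(np2$neuropilVolume, np$neuropilVolume)
  ## all-zero postsynaptic channel is degenerate
  stBad <- st
  stBad@post <- array(0, dim(st@post))
  expect_error(estimateNeuropil(stBad), "all zero")
})

test_that("spot detection recovers planted blobs and rejects blanks", {
  tr <- smallTruth(nPairs = 0L, nUnpairedPre = 50L, nUnpairedPost = 0L,
                   seed = 55)
  st <- simulateImageStack(tr, snr = 100, seed = 56)
  pre <- detectSpots(st@pre, st@voxelSize, 0.5)
  expect_gte(nrow(punctaCentroids(pre)), 48)
  expect_lte(nrow(punctaCentroids(pre)), 50)
  ## every detection sits within 0.15 um of a planted centroid
  dmat <- as.matrix(dist(rbind(punctaCentroids(pre), tr$preCentroids)))
  nd <- nrow(punctaCentroids(pre))
  nearest <- apply(dmat[seq_len(nd), -seq_len(nd), drop = FALSE], 1, min)
  expect_lt(max(nearest), 0.15)
  ## blank channel (noise only) yields nothing
  trB <- smallTruth(nPairs = 0L, nUnpairedPre = 0L, nUnpairedPost = 0L,
                    seed = 57)
  stB <- simulateImageStack(trB, snr = 100, seed = 58)
  expect_equal(nrow(punctaCentroids(detectSpots(stB@pre, stB@voxelSize,
                                                0.5))), 0)
  ## a spot inside the exclusion mask is dropped by the mask argument:
  ## mask a 0.3 um ball of voxels around the first planted centroid
  mask <- array(TRUE, dim(st@pre))
  vox <- round(tr$preCentroids[1, ] / st@voxelSize + 0.5)
  rad <- ceiling(0.3 / st@voxelSize)
  mask[max(1, vox[1] - rad[1]):min(dim(mask)[1], vox[1] + rad[1]),
       max(1, vox[2] - rad[2]):min(dim(mask)[2], vox[2] + rad[2]),
       max(1, vox[3] - rad[3]):min(dim(mask)[3], vox[3] + rad[3])] <- FALSE
  near1 <- sum(sqrt(colSums((t(punctaCentroids(pre)) -
                             tr$preCentroids[1, ])^2)) < 0.3)
  expect_equal(near1, 1)
  masked <- detectSpots(st@pre, st@voxelSize, 0.5, neuropilMask = mask)
  expect_equal(nrow(punctaCentroids(masked)),
               nrow(punctaCentroids(pre)) - 1)
  expect_error(detectSpots(st@pre, st@voxelSize, -0.5), "positive")
})

test_that("juxtaposition pairing respects the 0.5 um criterion one-to-one", {
  mkSet <- function(m, diameter)
    new("PunctaSet", centroids = m, diameter = diameter,
        intensities = rep(1, nrow(m)))
  at <- function(...) matrix(c(...), ncol = 3, byrow = TRUE,
                             dimnames = list(NULL, c("z", "y", "x")))
  ## 0.4 um apart: one synapse; 0.6 um apart: none
  pre1 <- mkSet(at(1, 1, 1), 0.5)
  expect_equal(pairSynapses(pre1, mkSet(at(1, 1, 1.4), 0.3),
                            neuropilVolume = 10)$record$n_synapses, 1)
  expect_equal(pairSynapses(pre1, mkSet(at(1, 1, 1.6), 0.3),
                            neuropilVolume = 10)$record$n_synapses, 0)
  ## three pre around one post: the one-to-one cap yields a single synapse
  pre3 <- mkSet(at(1, 1, 1, 1, 1, 1.2, 1, 1.2, 1), 0.5)
  post1 <- mkSet(at(1, 1.1, 1.1), 0.3)
  expect_equal(pairSynapses(pre3, post1,
                            neuropilVolume = 10)$record$n_synapses, 1)
  ## many-to-one mode counts each pre with a close partner
  expect_equal(pairSynapses(pre3, post1, neuropilVolume = 10,
                            mode = "many_to_one")$record$n_synapses, 3)
  expect_error(pairSynapses(pre3, post1, neuropilVolume = 0), "positive")
})

test_that("pairing counts are symmetric, capped and monotone in distance", {
  set.seed(61)
  mkSet <- function(m, diameter)
    new("PunctaSet", centroids = m, diameter = diameter,
        intensities = rep(1, nrow(m)))
  for (i in 1:10) {
    a <- matrix(runif(3 * sample(3:12, 1), 0, 3), ncol = 3,
                dimnames = list(NULL, c("z", "y", "x")))
    b <- matrix(runif(3 * sample(3:12, 1), 0, 3), ncol = 3,
                dimnames = list(NULL, c("z", "y", "x")))
    pre <- mkSet(a, 0.5); post <- mkSet(b, 0.3)
    n1 <- pairSynapses(pre, post, neuropilVolume = 27)$record$n_synapses
    expect_equal(n1, oraclePairCount(a, b, 0.5))
    ## symmetry under role swap
    n2 <- pairSynapses(mkSet(b, 0.5), mkSet(a, 0.3),
                       neuropilVolume = 27)$record$n_synapses
    expect_equal(n1, n2)
    expect_lte(n1, min(nrow(a), nrow(b)))
    ## shrinking max_dist never increases the count
    n3 <- pairSynapses(pre, post, maxDist = 0.3,
                       neuropilVolume = 27)$record$n_synapses
    expect_lte(n3, n1)
  }
})

test_that("group comparison matches the closed-form t-test and flags outliers", {
  recs <- data.frame(density = c(1, 2, 3, 4, 2, 3, 4, 5),
                     group = rep(c("PME", "PSE"), each = 4))
  cmp <- compareGroups(recs)
  orc <- oracleT(c(1, 2, 3, 4), c(2, 3, 4, 5), welch = cmp$welch)
  expect_equal(cmp$t, orc$t, tolerance = 1e-12)
  expect_equal(cmp$p_value, orc$p, tolerance = 1e-12)
  ## identical groups: t = 0
  recs0 <- data.frame(density = rep(c(1, 2, 3, 4), 2),
                      group = rep(c("PME", "PSE"), each = 4))
  expect_equal(compareGroups(recs0)$t, 0)
  ## quartile convention marks points outside [Q1, Q3]
  expect_true(any(cmp$outliers))
  cmpT <- compareGroups(recs, outlierRule = "tukey")
  expect_false(any(cmpT$outliers))
  expect_error(compareGroups(recs[c(1, 5, 6, 7), ]), "at least 2")
})

test_that("a planted density shift is detected with high power", {
  set.seed(63)
  hits <- replicate(200, {
    pme <- rnorm(8, 1.2, 0.1)   # shift of 2 pooled SDs
    pse <- rnorm(8, 1.0, 0.1)
    recs <- data.frame(density = c(pme, pse),
                       group = rep(c("PME", "PSE"), each = 8))
    compareGroups(recs)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})
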