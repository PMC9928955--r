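#' Simulate one omics level of the two-group multi-region study
#'
#' Generates feature-by-sample reporter abundances for every region of a
#' \linkS4class{StudyDesign} under a log-normal model around a per-feature
#' baseline: the log2 abundance of feature i in sample j of a region is
#' \deqn{b_i + e_{i,region} [group_j = PME] + \log_2 \ell_j +
#'       N(0, \sigma)}
#' with per-feature baseline \eqn{b_i}, planted log2 effect
#' \eqn{e_{i,region}}, per-channel loading factor \eqn{\ell_j} and noise SD
#' \eqn{\sigma}.  Differential features are split into a region-shared
#' block (the same effect in all regions) and region-unique blocks (effect
#' in one region only); effect signs are random.  The ground truth (effect
#' matrix, masks, loadings) is returned alongside.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param nFeatures number of features (> 0).
#' @param fracDifferential fraction of features with a planted effect, in
#'   [0, 1].
#' @param effectLog2 absolute planted log2(PME/PSE) effect size.
#' @param sharedFrac fraction of differential features whose effect is
#'   shared by all regions (the rest are unique to one region each).
#' @param noiseSd log2-scale noise SD (>= 0; 0 gives noiseless data).
#' @param channelLoadingRange range of per-sample multiplicative loading
#'   factors (must be positive).
#' @param level \code{"protein"} or \code{"phospho"} (phospho features get a
#'   site label and a confirmed-localization flag).
#' @param geneUniverse optional gene id pool; phospho features draw their
#'   gene from it, proteins map 1:1 onto its head.
#' @param seed integer seed; identical seed and parameters give
#'   bit-identical output.
#' @return list with \code{experiments} (named list region ->
#'   \linkS4class{AbundanceExperiment}) and \code{truth} (list with
#'   \code{effectLog2} feature x region matrix, \code{sharedMask},
#'   \code{uniqueMask}, \code{channelLoading}, \code{noiseSd},
#'   \code{seed}).
#' @export
simulateAbundanceExperiment <- function(design = studyDesign(),
                                        nFeatures = 1000L,
                                        fracDifferential = 0.1,
                                        effectLog2 = 1,
                                        sharedFrac = 0.5,
                                        noiseSd = 0.3,
                                        channelLoadingRange = c(0.5, 2),
                                        level = c("protein", "phospho"),
                                        geneUniverse = NULL,
                                        seed = 1L) {
  level <- match.arg(level)
  if (nFeatures <= 0) stop("nFeatures must be positive")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (fracDifferential < 0 || fracDifferential > 1)
    stop("fracDifferential must lie in [0, 1]")
  if (any(channelLoadingRange <= 0)) stop("channel loadings must be positive")
  regions <- design@regions
  .withSeed(seed, {
    if (is.null(geneUniverse))
      geneUniverse <- sprintf("Gene%05d", seq_len(max(nFeatures, 100L)))
    if (level == "protein") {
      featureId <- sprintf("P%05d", seq_len(nFeatures))
      geneId <- geneUniverse[((seq_len(nFeatures) - 1L) %%
                              length(geneUniverse)) + 1L]
      site <- NULL
      confirmed <- NULL
    } else {
      featureId <- sprintf("P%05d_%s%d", seq_len(nFeatures),
                           sample(c("S", "T", "Y"), nFeatures, TRUE),
                           sample(1:999, nFeatures, TRUE))
      geneId <- sample(geneUniverse, nFeatures, replace = TRUE)
      site <- sub("^P\\d+_", "", featureId)
      confirmed <- rep(TRUE, nFeatures)
    }
    nDiff <- round(nFeatures * fracDifferential)
    diffIdx <- if (nDiff) sample.int(nFeatures, nDiff) else integer(0)
    nShared <- round(nDiff * sharedFrac)
    sharedIdx <- diffIdx[seq_len(nShared)]
    uniqueIdx <- setdiff(diffIdx, sharedIdx)
    sharedMask <- seq_len(nFeatures) %in% sharedIdx
    uniqueMask <- seq_len(nFeatures) %in% uniqueIdx
    eff <- matrix(0, nFeatures, length(regions),
                  dimnames = list(featureId, regions))
    if (length(sharedIdx)) {
      sgn <- sample(c(-1, 1), length(sharedIdx), replace = TRUE)
      eff[sharedIdx, ] <- sgn * effectLog2
    }
    if (length(uniqueIdx)) {
      home <- rep_len(seq_along(regions), length(uniqueIdx))
      sgn <- sample(c(-1, 1), length(uniqueIdx), replace = TRUE)
      for (t in seq_along(uniqueIdx))
        eff[uniqueIdx[t], home[t]] <- sgn[t] * effectLog2
    }
    base <- stats::rnorm(nFeatures, mean = 18, sd = 1.5)
    loadings <- list()
    experiments <- list()
    for (r in regions) {
      meta <- designSamples(design, r)
      ns <- nrow(meta)
      loading <- stats::runif(ns, channelLoadingRange[1],
                              channelLoadingRange[2])
      names(loading) <- meta$sample
      isPme <- as.numeric(meta$group == "PME")
      lmat <- outer(base, rep(1, ns)) +
              outer(eff[, r], isPme) +
              outer(rep(1, nFeatures), log2(loading)) +
              matrix(stats::rnorm(nFeatures * ns, 0, noiseSd),
                     nFeatures, ns)
      values <- 2^lmat
      colnames(values) <- meta$sample
      experiments[[r]] <- AbundanceExperiment(
        values, featureId = featureId, geneId = geneId, site = site,
        sampleMeta = meta, localizationConfirmed = confirmed)
      loadings[[r]] <- loading
    }
    list(experiments = experiments,
         truth = list(effectLog2 = eff, sharedMask = sharedMask,
                      uniqueMask = uniqueMask, channelLoading = loadings,
                      noiseSd = noiseSd, fracDifferential = fracDifferential,
                      seed = seed))
  })
}

#' Simulate the full omics dataset (proteome + phosphoproteome)
#'
#' Convenience wrapper generating both omics levels for every region of the
#' design, with independent ground truths but a common gene universe so the
#' two levels overlap in GeneID space.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param nProtein,nPhospho feature counts per level.
#' @param seed integer seed; the two levels use distinct child seeds.
#' @param ... further arguments passed to
#'   \code{\link{simulateAbundanceExperiment}}.
#' @return list with elements \code{protein} and \code{phospho}, each as
#'   returned by \code{\link{simulateAbundanceExperiment}}, plus
#'   \code{geneUniverse}.
#' @export
simulateOmicsDataset <- function(design = studyDesign(),
                                 nProtein = 2000L, nPhospho = 1000L,
                                 seed = 1L, ...) {
  geneUniverse <- sprintf("Gene%05d", seq_len(max(nProtein, 100L)))
  list(protein = simulateAbundanceExperiment(
         design, nFeatures = nProtein, level = "protein",
         geneUniverse = geneUniverse, seed = childSeed(seed, 1L), ...),
       phospho = simulateAbundanceExperiment(
         design, nFeatures = nPhospho, level = "phospho",
         geneUniverse = geneUniverse, seed = childSeed(seed, 2L), ...),
       geneUniverse = geneUniverse)
}
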