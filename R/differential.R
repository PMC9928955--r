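#' Total-amount normalization
#'
#' Rescales every sample (column) so that all column sums equal the mean of
#' the input column sums, removing per-channel loading differences while
#' preserving within-column proportions.  This mirrors the "normalize by
#' total peptide amount, no scaling" convention of grouped-abundance
#' exports.
#'
#' @param x an \linkS4class{AbundanceExperiment}.
#' @return An \linkS4class{AbundanceExperiment} with equalized column sums.
#' @examples
#' ae <- simulateAbundanceExperiment(studyDesign(regions = "M1"),
#'                                   nFeatures = 50, seed = 1)$experiment
#' colSums(assay(normalizeTotalAmount(ae)))
#' @export
normalizeTotalAmount <- function(x) {
  stopifnot(is(x, "AbundanceExperiment"))
  a <- assay(x)
  cs <- colSums(a)
  if (any(cs <= 0)) stop("all column sums must be positive")
  target <- mean(cs)
  assay(x) <- sweep(a, 2L, cs / target, `/`)
  x
}

## closed-form two-sample t (Student pooled or Welch) on a pair of vectors
.tTwoSample <- function(x, y, welch = FALSE) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  d <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    if (d == 0) return(list(t = 0, df = nx + ny - 2, p = 1))
    warning("zero within-group variance with unequal means; p set adjacent to 0")
    return(list(t = sign(d) * Inf, df = nx + ny - 2,
                p = .Machine$double.xmin))
  }
  if (welch) {
    se2 <- vx / nx + vy / ny
    tt <- d / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    tt <- d / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Per-feature differential abundance table
#'
#' Computes, for every feature, the grouped PME and PSE means of the
#' normalized abundances, the abundance ratio AR = mean(PME)/mean(PSE), its
#' log2, and a two-sided two-sample t-test p-value.  The t-test is run on
#' log2-transformed abundances (variance-stabilized scale on which the
#' planted effects are additive); AR is always the ratio of arithmetic group
#' means on the natural scale.  No multiple-testing correction is applied:
#' features are flagged significant at raw p < \code{alpha}.
#'
#' @param x an \linkS4class{AbundanceExperiment} (normalized with
#'   \code{\link{normalizeTotalAmount}} first unless \code{normalize=FALSE}).
#' @param alpha significance level (default 0.05).
#' @param test \code{"student"} (pooled variance, the default) or
#'   \code{"welch"}.
#' @param normalize apply total-amount normalization first (default TRUE).
#' @param logScale run the t-test on log2 abundances (default TRUE) or on the
#'   natural scale.
#' @return A \linkS4class{DifferentialTable}.
#' @export
differentialTable <- function(x, alpha = 0.05,
                              test = c("student", "welch"),
                              normalize = TRUE, logScale = TRUE) {
  stopifnot(is(x, "AbundanceExperiment"))
  test <- match.arg(test)
  if (normalize) x <- normalizeTotalAmount(x)
  grp <- groupLabels(x)
  if (sum(grp == "PME") < 2L || sum(grp == "PSE") < 2L)
    stop("each group needs at least 2 samples")
  a <- assay(x)
  ta <- if (logScale) log2(a) else a
  pme <- grp == "PME"; pse <- grp == "PSE"
  meanPme <- unname(rowMeans(a[, pme, drop = FALSE]))
  meanPse <- unname(rowMeans(a[, pse, drop = FALSE]))
  ar <- meanPme / meanPse
  pv <- vapply(seq_len(nrow(a)), function(i)
    .tTwoSample(ta[i, pme], ta[i, pse], welch = test == "welch")$p,
    numeric(1))
  log2ar <- log2(ar)
  rec <- DataFrame(
    feature_id = rowData(x)$feature_id,
    gene_id = rowData(x)$gene_id,
    mean_pme = meanPme,
    mean_pse = meanPse,
    AR = ar,
    log2_ar = log2ar,
    p_value = pv,
    significant = pv < alpha,
    direction = ifelse(log2ar > 0, "up", ifelse(log2ar < 0, "down", "none"))
  )
  if ("site" %in% colnames(rowData(x))) rec$site <- rowData(x)$site
  new("DifferentialTable", records = rec, alpha = alpha,
      region = paste(regionLabel(x), collapse = "/"),
      level = if ("site" %in% colnames(rowData(x))) "phosphoproteome"
              else "proteome",
      test = test)
}

#' Filter the significant subset and count directions
#'
#' @param table a \linkS4class{DifferentialTable}.
#' @return list with \code{significant} (the significant records),
#'   \code{n_significant}, \code{n_up} (significant with log2_ar > 0) and
#'   \code{n_down}.
#' @export
filterAndCount <- function(table) {
  stopifnot(is(table, "DifferentialTable"))
  r <- table@records
  sig <- r[r$p_value < table@alpha, , drop = FALSE]
  list(significant = sig,
       n_significant = nrow(sig),
       n_up = sum(sig$log2_ar > 0),
       n_down = sum(sig$log2_ar < 0))
}

#' @rdname diffCounts
#' @param x a \linkS4class{DifferentialTable}.
#' @return \code{diffCounts}: named integer vector
#'   \code{c(n_significant=, n_up=, n_down=)}.
#' @export
setMethod("diffCounts", "DifferentialTable", function(x) {
  fc <- filterAndCount(x)
  c(n_significant = fc$n_significant, n_up = fc$n_up, n_down = fc$n_down)
})

#' @rdname significantFeatures
#' @param x a \linkS4class{DifferentialTable}.
#' @param what return \code{"feature_id"} (default) or \code{"gene_id"}.
#' @param ... unused.
#' @return \code{significantFeatures}: character vector of identifiers with
#'   p < alpha.
#' @export
setMethod("significantFeatures", "DifferentialTable",
  function(x, what = c("feature_id", "gene_id"), ...) {
    what <- match.arg(what)
    fc <- filterAndCount(x)
    unique(as.character(fc$significant[[what]]))
  })

setMethod("show", "DifferentialTable", function(object) {
  ct <- diffCounts(object)
  cat("DifferentialTable (", object@level, ", region ", object@region,
      "): ", nrow(object@records), " features, alpha = ", object@alpha,
      "\n  significant: ", ct["n_significant"], " (", ct["n_up"], " up, ",
      ct["n_down"], " down), ", object@test, " t-test\n", sep = "")
})

#' Hierarchical clustering of differential features
#'
#' Agglomerative average-linkage (group-average) clustering of the
#' significant features and of the samples, on correlation distance of
#' per-feature z-scored log2 abundances — the standard clustermap layout for
#' differential TMT features.
#'
#' @param x an \linkS4class{AbundanceExperiment}.
#' @param features feature ids to cluster (typically
#'   \code{significantFeatures(table)}).
#' @param distance \code{"correlation"} (default, 1 - Pearson r) or
#'   \code{"euclidean"}.
#' @return list with \code{featureDendrogram} and \code{sampleDendrogram}
#'   (\code{hclust} objects) and the corresponding leaf orders
#'   \code{featureOrder}, \code{sampleOrder}.
#' @export
clusterDifferential <- function(x, features,
                                distance = c("correlation", "euclidean")) {
  stopifnot(is(x, "AbundanceExperiment"))
  distance <- match.arg(distance)
  keep <- rowData(x)$feature_id %in% features
  if (sum(keep) < 2L) stop("need at least 2 significant features to cluster")
  m <- log2(assay(x)[keep, , drop = FALSE])
  z <- t(scale(t(m)))          # per-feature z-score across samples
  z[is.na(z)] <- 0             # constant features carry no profile
  dfun <- function(mm) {
    if (distance == "correlation") {
      cc <- suppressWarnings(stats::cor(t(mm)))
      cc[is.na(cc)] <- 0
      stats::as.dist(1 - cc)
    } else stats::dist(mm)
  }
  hf <- stats::hclust(dfun(z), method = "average")
  hs <- stats::hclust(dfun(t(z)), method = "average")
  list(featureDendrogram = hf, sampleDendrogram = hs,
       featureOrder = rownames(m)[hf$order],
       sampleOrder = colnames(m)[hs$order])
}
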