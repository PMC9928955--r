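#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData colData
NULL

#' Two-group multi-channel study design
#'
#' Describes the sampling layout of a two-group isobaric-labelling study:
#' a set of brain regions, the number of animals per exposure group
#' (\code{PME} = prenatal methadone exposure, \code{PSE} = prenatal saline
#' exposure) and the male/female split within each group.  The default is the
#' 16-sample design used throughout the package: four regions (M1, S1, DLS,
#' DMS), n = 8 per group, 4 males and 4 females per group.
#'
#' @slot regions character vector of region labels.
#' @slot nPerGroup integer, animals per exposure group and region.
#' @slot sexSplit named integer vector \code{c(M = , F = )} summing to
#'   \code{nPerGroup}.
#' @slot groups character, exactly \code{c("PME", "PSE")}.
#' @slot litterIds optional per-sample litter labels (metadata only; litter is
#'   not modelled as a variance component).
#'
#' @export
setClass("StudyDesign",
  representation(
    regions   = "character",
    nPerGroup = "integer",
    sexSplit  = "integer",
    groups    = "character",
    litterIds = "character"
  ),
  prototype(
    regions   = c("M1", "S1", "DLS", "DMS"),
    nPerGroup = 8L,
    sexSplit  = c(M = 4L, F = 4L),
    groups    = c("PME", "PSE"),
    litterIds = character(0)
  )
)

setValidity("StudyDesign", function(object) {
  msg <- character(0)
  if (!identical(sort(object@groups), c("PME", "PSE")))
    msg <- c(msg, "groups must be exactly {PME, PSE}")
  if (length(object@regions) < 1L || anyDuplicated(object@regions))
    msg <- c(msg, "regions must be a non-empty set of unique labels")
  if (object@nPerGroup < 1L)
    msg <- c(msg, "nPerGroup must be positive")
  if (sum(object@sexSplit) != object@nPerGroup)
    msg <- c(msg, "sex counts must sum to nPerGroup per group")
  if (length(msg)) msg else TRUE
})

#' Feature-by-sample reporter abundance container
#'
#' A \linkS4class{SummarizedExperiment} holding strictly positive reporter
#' abundances (features in rows, samples in columns) together with the
#' per-sample \code{group} (PME/PSE), \code{sex} and \code{region} metadata
#' and per-feature \code{feature_id}, \code{gene_id} and (for
#' phosphopeptides) \code{site} annotations.
#'
#' @export
setClass("AbundanceExperiment", contains = "SummarizedExperiment")

setValidity("AbundanceExperiment", function(object) {
  msg <- character(0)
  a <- assay(object)
  if (!is.numeric(a) || any(!is.finite(a)) || any(a <= 0))
    msg <- c(msg, "abundances must be finite and strictly positive")
  rd <- rowData(object)
  for (col in c("feature_id", "gene_id"))
    if (!col %in% colnames(rd)) msg <- c(msg, paste0("rowData lacks ", col))
  cd <- colData(object)
  for (col in c("group", "sex", "region"))
    if (!col %in% colnames(cd)) msg <- c(msg, paste0("colData lacks ", col))
  if ("group" %in% colnames(cd)) {
    lev <- unique(as.character(cd$group))
    if (!identical(sort(lev), c("PME", "PSE")))
      msg <- c(msg, "group must have exactly the two levels PME and PSE")
  }
  if (length(msg)) msg else TRUE
})

#' Per-feature differential abundance results
#'
#' One record per feature with grouped means, the PME/PSE abundance ratio
#' (AR), its log2, the two-sample t-test p-value, a significance flag at
#' \code{alpha} and the direction of change.
#'
#' @slot records a \code{DataFrame} with columns \code{feature_id},
#'   \code{gene_id}, \code{mean_pme}, \code{mean_pse}, \code{AR},
#'   \code{log2_ar}, \code{p_value}, \code{significant}, \code{direction}.
#' @slot alpha significance level (features with p < alpha are flagged).
#' @slot region region label the table was computed for.
#' @slot level \code{"proteome"} or \code{"phosphoproteome"}.
#' @slot test \code{"student"} or \code{"welch"}.
#'
#' @export
setClass("DifferentialTable",
  representation(
    records = "DataFrame",
    alpha   = "numeric",
    region  = "character",
    level   = "character",
    test    = "character"
  )
)

setValidity("DifferentialTable", function(object) {
  msg <- character(0)
  need <- c("feature_id", "gene_id", "mean_pme", "mean_pse", "AR",
            "log2_ar", "p_value", "significant", "direction")
  miss <- setdiff(need, colnames(object@records))
  if (length(miss))
    msg <- c(msg, paste("records lack columns:", paste(miss, collapse = ", ")))
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha > 1)
    msg <- c(msg, "alpha must be a single value in (0, 1]")
  if (!length(miss)) {
    r <- object@records
    if (any(r$AR <= 0)) msg <- c(msg, "AR must be positive")
    if (any(r$significant & !(r$p_value < object@alpha)))
      msg <- c(msg, "significant flag inconsistent with p < alpha")
    bad <- (r$log2_ar > 0 & r$direction != "up") |
           (r$log2_ar < 0 & r$direction != "down")
    if (any(bad)) msg <- c(msg, "direction inconsistent with sign of log2_ar")
  }
  if (length(msg)) msg else TRUE
})

#' Kinase-substrate enrichment scores
#'
#' Per-kinase KSEA results: substrate count m, substrate mean log2
#' fold change, the z-score \eqn{z = (\bar{s} - \bar{p})\sqrt{m} / \delta}
#' (where \eqn{\bar{p}} and \eqn{\delta} are the mean and SD of all site
#' log2 fold changes), its two-sided normal p-value and the
#' Benjamini-Hochberg FDR across kinases.
#'
#' @slot scores a \code{DataFrame} with columns \code{kinase}, \code{m},
#'   \code{s_bar}, \code{z}, \code{p_value}, \code{fdr}.
#' @slot globalMean mean of all usable site log2 fold changes (\eqn{\bar{p}}).
#' @slot globalSd SD of all usable site log2 fold changes (\eqn{\delta}).
#'
#' @export
setClass("KseaResults",
  representation(
    scores     = "DataFrame",
    globalMean = "numeric",
    globalSd   = "numeric"
  )
)

setValidity("KseaResults", function(object) {
  msg <- character(0)
  need <- c("kinase", "m", "s_bar", "z", "p_value", "fdr")
  miss <- setdiff(need, colnames(object@scores))
  if (length(miss))
    msg <- c(msg, paste("scores lack columns:", paste(miss, collapse = ", ")))
  if (!length(miss) && nrow(object@scores)) {
    s <- object@scores
    if (any(s$m < 1)) msg <- c(msg, "substrate count m must be >= 1")
    if (any(s$fdr < s$p_value - 1e-12)) msg <- c(msg, "fdr must be >= p_value")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-region set overlap and cosine similarity report
#'
#' Summarises how similar per-region significant term (or GeneID) sets are:
#' pairwise Jaccard overlap fractions, the all-region overlap
#' (|intersection| / |union|), the cosine similarity between a focal
#' region's set and the union of the remaining regions' sets, and Venn
#' counts for every region membership pattern.
#'
#' @slot regions region labels in set order.
#' @slot sets the input sets (list of character vectors, named by region).
#' @slot pairwise matrix of pairwise Jaccard fractions.
#' @slot allRegionOverlap |intersection over all regions| / |union|.
#' @slot focalRegion the region compared against the pooled rest (default M1).
#' @slot focalVsRestCosine cosine similarity of the focal set vs the union of
#'   the other regions' sets (0 when either side is empty).
#' @slot vennCounts named integer vector; names are membership patterns such
#'   as \code{"M1&S1"}, values count elements with exactly that pattern.
#' @slot uniqueCounts per-region count of elements found in no other region.
#' @slot uniquePct per-region unique count as a percentage of the all-region
#'   union.
#'
#' @export
setClass("SimilarityReport",
  representation(
    regions           = "character",
    sets              = "list",
    pairwise          = "matrix",
    allRegionOverlap  = "numeric",
    focalRegion       = "character",
    focalVsRestCosine = "numeric",
    vennCounts        = "integer",
    uniqueCounts      = "integer",
    uniquePct         = "numeric"
  )
)

setValidity("SimilarityReport", function(object) {
  msg <- character(0)
  if (!identical(names(object@sets), object@regions))
    msg <- c(msg, "sets must be named by region, in region order")
  if (length(object@vennCounts)) {
    u <- length(unique(unlist(object@sets)))
    if (sum(object@vennCounts) != u)
      msg <- c(msg, "venn counts must sum to |union of all sets|")
  }
  if (length(msg)) msg else TRUE
})

#' Network subcluster assignment
#'
#' Result of k-means subclustering of a confidence-filtered interaction
#' graph on its spectral embedding: a hard cluster index per retained node,
#' per-edge intra/inter-cluster flags, and (after labelling) the strongest
#' significant annotation term per cluster.
#'
#' @slot membership named integer vector, node -> cluster in 1..k.
#' @slot k number of clusters requested (reduced with a warning if some end
#'   up empty).
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{score},
#'   \code{intra}.
#' @slot labels per-cluster label (term id or \code{"unlabeled"}).
#' @slot labelStrength per-cluster enrichment strength of the labelling term.
#'
#' @export
setClass("SubclusterAssignment",
  representation(
    membership    = "integer",
    k             = "integer",
    edges         = "data.frame",
    labels        = "character",
    labelStrength = "numeric"
  )
)

setValidity("SubclusterAssignment", function(object) {
  msg <- character(0)
  if (is.null(names(object@membership)))
    msg <- c(msg, "membership must be named by node")
  if (length(object@membership) &&
      !all(object@membership %in% seq_len(object@k)))
    msg <- c(msg, "membership indices must lie in 1..k")
  if (length(msg)) msg else TRUE
})

#' Two-channel 3D image stack with physical voxel size
#'
#' Pre- and postsynaptic marker channels (plus an optional occluder channel
#' carrying nuclei/vasculature signal) as 3D arrays indexed \code{[z, y, x]},
#' with the voxel size in micrometres and acquisition metadata.
#'
#' @slot pre,post 3D numeric arrays, identical dimensions.
#' @slot occluder 3D numeric array of the same shape, or a 0-length array
#'   when no occluder channel was acquired.
#' @slot voxelSize named numeric \code{c(z = , y = , x = )} in micrometres.
#' @slot meta list of acquisition metadata (animal id, layer, marker pair,
#'   group, sex).
#'
#' @export
setClass("ImageStack",
  representation(
    pre       = "array",
    post      = "array",
    occluder  = "array",
    voxelSize = "numeric",
    meta      = "list"
  )
)

setValidity("ImageStack", function(object) {
  msg <- character(0)
  if (length(dim(object@pre)) != 3L || length(dim(object@post)) != 3L)
    msg <- c(msg, "pre and post channels must be 3D arrays")
  else if (!identical(dim(object@pre), dim(object@post)))
    msg <- c(msg, "channel shapes must be equal")
  if (length(object@occluder) &&
      !identical(dim(object@occluder), dim(object@pre)))
    msg <- c(msg, "occluder channel shape must match")
  vs <- object@voxelSize
  if (length(vs) != 3L || any(vs <= 0) ||
      !identical(names(vs), c("z", "y", "x")))
    msg <- c(msg, "voxelSize must be positive and named c(z=, y=, x=)")
  if (length(msg)) msg else TRUE
})

#' Detected puncta in physical coordinates
#'
#' Sub-voxel centroids of detected (or simulated) synaptic puncta in
#' micrometres, together with the expected marker diameter and the detection
#' response intensity per punctum.
#'
#' @slot centroids n x 3 matrix with columns \code{z}, \code{y}, \code{x}
#'   (micrometres).
#' @slot diameter expected punctum diameter in micrometres; synaptic puncta
#'   fall in the 0.25-0.8 micrometre band.
#' @slot intensities detection response per punctum.
#'
#' @export
setClass("PunctaSet",
  representation(
    centroids   = "matrix",
    diameter    = "numeric",
    intensities = "numeric"
  )
)

setValidity("PunctaSet", function(object) {
  msg <- character(0)
  if (ncol(object@centroids) != 3L)
    msg <- c(msg, "centroids must have 3 columns (z, y, x)")
  if (length(object@diameter) != 1L ||
      object@diameter < 0.25 || object@diameter > 0.8)
    msg <- c(msg, "diameter must lie in the [0.25, 0.8] micrometre band")
  if (nrow(object@centroids) != length(object@intensities))
    msg <- c(msg, "one intensity per centroid required")
  if (length(msg)) msg else TRUE
})

#' Machine-readable pipeline run report
#'
#' Aggregates the outputs of a full pipeline run: per-region differential
#' counts for both omics levels, KSEA summaries, the cross-region similarity
#' reports, network cluster summaries, puncta statistics, the configuration
#' used and its hash.
#'
#' @slot sections named list of report sections.
#'
#' @export
setClass("RunReport", representation(sections = "list"))
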