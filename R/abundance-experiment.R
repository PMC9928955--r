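#' Construct a StudyDesign
#'
#' @param regions character vector of region labels.
#' @param nPerGroup animals per exposure group per region.
#' @param sexSplit named integer vector \code{c(M=, F=)} per group.
#' @param litterIds optional per-sample litter labels (metadata only).
#'
#' @return A \linkS4class{StudyDesign}. The default reproduces the 16-sample
#'   design: 8 PME (4M:4F) vs 8 PSE (4M:4F) per region, regions M1, S1, DLS,
#'   DMS.
#' @examples
#' studyDesign()
#' studyDesign(regions = "M1", nPerGroup = 4L, sexSplit = c(M = 2L, F = 2L))
#' @export
studyDesign <- function(regions = c("M1", "S1", "DLS", "DMS"),
                        nPerGroup = 8L,
                        sexSplit = c(M = 4L, F = 4L),
                        litterIds = character(0)) {
  new("StudyDesign",
      regions = as.character(regions),
      nPerGroup = as.integer(nPerGroup),
      sexSplit = structure(as.integer(sexSplit), names = names(sexSplit)),
      groups = c("PME", "PSE"),
      litterIds = as.character(litterIds))
}

#' Per-region sample annotation implied by a design
#'
#' Expands a \linkS4class{StudyDesign} into one row per sample (channel) of a
#' single region's multiplex: group, sex and a sample name of the form
#' \code{<group>_<sex>_<replicate>}.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param region region label for all samples.
#' @return data.frame with columns \code{sample}, \code{group}, \code{sex},
#'   \code{region}.
#' @export
designSamples <- function(design, region) {
  stopifnot(is(design, "StudyDesign"))
  rows <- do.call(rbind, lapply(design@groups, function(g) {
    sex <- rep(names(design@sexSplit), design@sexSplit)
    data.frame(group = g, sex = sex, stringsAsFactors = FALSE)
  }))
  rows$region <- region
  rows$sample <- paste(rows$group, rows$sex,
                       stats::ave(seq_len(nrow(rows)),
                                  paste(rows$group, rows$sex),
                                  FUN = seq_along),
                       sep = "_")
  rows[c("sample", "group", "sex", "region")]
}

#' Construct an AbundanceExperiment
#'
#' @param values features x samples matrix of strictly positive reporter
#'   abundances.
#' @param featureId,geneId parallel per-feature identifiers.
#' @param site optional phosphosite labels (e.g. \code{"S123"}); NA for
#'   unmodified proteome features.
#' @param sampleMeta data.frame with one row per column of \code{values} and
#'   columns \code{group} (PME/PSE), \code{sex}, \code{region}.
#' @param localizationConfirmed optional logical per feature; phosphosites
#'   without confirmed localization are excluded from KSEA.
#'
#' @return An \linkS4class{AbundanceExperiment}.
#' @export
AbundanceExperiment <- function(values, featureId, geneId, site = NULL,
                                sampleMeta, localizationConfirmed = NULL) {
  values <- as.matrix(values)
  rd <- DataFrame(feature_id = as.character(featureId),
                  gene_id = as.character(geneId))
  if (!is.null(site)) rd$site <- as.character(site)
  if (!is.null(localizationConfirmed))
    rd$localization_confirmed <- as.logical(localizationConfirmed)
  rownames(values) <- rd$feature_id
  if (is.null(colnames(values)) && "sample" %in% colnames(sampleMeta))
    colnames(values) <- sampleMeta$sample
  cd <- DataFrame(sampleMeta[c("group", "sex", "region")])
  rownames(cd) <- colnames(values)
  new("AbundanceExperiment",
      SummarizedExperiment(assays = list(abundance = values),
                           rowData = rd, colData = cd))
}

#' @describeIn AbundanceExperiment group labels per sample.
#' @param x an AbundanceExperiment.
#' @export
groupLabels <- function(x) as.character(colData(x)$group)

#' @describeIn AbundanceExperiment the (single) region of the experiment.
#' @export
regionLabel <- function(x) unique(as.character(colData(x)$region))

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@regions), "region(s) [",
      paste(object@regions, collapse = ", "), "]\n")
  cat("  per region:", object@nPerGroup, "PME +", object@nPerGroup,
      "PSE samples (", paste(names(object@sexSplit), object@sexSplit,
                             sep = "=", collapse = ", "), "per group )\n")
})

setMethod("show", "AbundanceExperiment", function(object) {
  cat("AbundanceExperiment:", nrow(object), "features x", ncol(object),
      "samples, region", paste(regionLabel(object), collapse = "/"), "\n")
  tab <- table(groupLabels(object))
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  callNextMethod()
})
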