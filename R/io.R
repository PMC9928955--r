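#' Read and write GMT annotation databases
#'
#' Standard GMT: one term per line, tab-separated as
#' \code{term_id <tab> description <tab> gene1 <tab> gene2 ...}.  The
#' description field carries the annotation category so a database
#' round-trips losslessly.
#'
#' @param db named list term_id -> character vector of genes, optionally
#'   with attribute \code{category}.
#' @param path file path.
#' @return \code{readGmt}: the database (named list with \code{category}
#'   attribute when present); \code{writeGmt}: the path, invisibly.
#' @export
writeGmt <- function(db, path) {
  stopifnot(length(db) == 0L || !is.null(names(db)))
  cat2 <- attr(db, "category")
  if (is.null(cat2)) cat2 <- "na"
  lines <- vapply(names(db), function(tm)
    paste(c(tm, cat2, db[[tm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGmt
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  db <- lapply(parts, function(p) p[-(1:2)])
  names(db) <- vapply(parts, `[`, character(1), 1L)
  cats <- unique(vapply(parts, `[`, character(1), 2L))
  if (length(cats) == 1L && cats != "na") attr(db, "category") <- cats
  db
}

#' Write/read an abundance table as TSV
#'
#' One row per feature: \code{feature_id}, \code{gene_id}, optional
#' \code{site} and \code{localization_confirmed}, then one column per sample
#' named \code{<group>_<sex>_<replicate>}.  The region is stored on a
#' leading \code{## region=} header line.  The reader tolerates extra
#' annotation columns (as in grouped-abundance exports): any column that is
#' not a recognised annotation and does not match a \code{PME_}/\code{PSE_}
#' sample name is ignored.
#'
#' @param x an \linkS4class{AbundanceExperiment}.
#' @param path file path.
#' @return \code{readAbundanceTsv}: an \linkS4class{AbundanceExperiment};
#'   \code{writeAbundanceTsv}: the path, invisibly.
#' @export
writeAbundanceTsv <- function(x, path) {
  stopifnot(is(x, "AbundanceExperiment"))
  rd <- as.data.frame(rowData(x))
  df <- cbind(rd, as.data.frame(assay(x), check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("## region=", paste(regionLabel(x), collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAbundanceTsv
#' @export
readAbundanceTsv <- function(path) {
  first <- readLines(path, n = 1L)
  region <- if (startsWith(first, "## region="))
    sub("^## region=", "", first) else "NA"
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  annotCols <- intersect(c("feature_id", "gene_id", "site",
                           "localization_confirmed"), colnames(df))
  sampleCols <- grep("^(PME|PSE)_", colnames(df), value = TRUE)
  values <- as.matrix(df[sampleCols])
  parts <- strsplit(sampleCols, "_", fixed = TRUE)
  meta <- data.frame(sample = sampleCols,
                     group = vapply(parts, `[`, character(1), 1L),
                     sex = vapply(parts, `[`, character(1), 2L),
                     region = region, stringsAsFactors = FALSE)
  AbundanceExperiment(values, featureId = df$feature_id,
                      geneId = df$gene_id,
                      site = if ("site" %in% annotCols) df$site else NULL,
                      sampleMeta = meta,
                      localizationConfirmed =
                        if ("localization_confirmed" %in% annotCols)
                          df$localization_confirmed else NULL)
}

#' Write a differential table as TSV
#'
#' Columns: feature_id, gene_id, mean_pme, mean_pse, AR, log2_ar, p_value,
#' significant, direction (plus site for phosphopeptides).  A companion
#' volcano-coordinate table (log2_ar, -log10 p) can be written alongside.
#'
#' @param table a \linkS4class{DifferentialTable}.
#' @param path file path.
#' @param volcanoPath optional path for the volcano coordinates.
#' @return the path, invisibly.
#' @export
writeDifferentialTsv <- function(table, path, volcanoPath = NULL) {
  stopifnot(is(table, "DifferentialTable"))
  df <- as.data.frame(table@records)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(volcanoPath)) {
    vol <- data.frame(feature_id = df$feature_id, log2_ar = df$log2_ar,
                      neg_log10_p = -log10(df$p_value))
    utils::write.table(vol, volcanoPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write/read a kinase-substrate map as TSV
#'
#' Columns: kinase, substrate, source, networkin_score.
#'
#' @param map data.frame kinase-substrate map.
#' @param path file path.
#' @return \code{readKinaseMapTsv}: the map data.frame;
#'   \code{writeKinaseMapTsv}: the path, invisibly.
#' @export
writeKinaseMapTsv <- function(map, path) {
  utils::write.table(map[c("kinase", "substrate", "source",
                           "networkin_score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeKinaseMapTsv
#' @export
readKinaseMapTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write/read a two-channel image stack as multi-page TIFF + JSON sidecar
#'
#' Each channel goes to \code{<prefix>_<channel>.tif} (32-bit float pages,
#' one per z-plane, rescaled to [0, 1] with the scale factor recorded in the
#' sidecar).  The sidecar \code{<prefix>.json} stores the voxel size,
#' channel roles, scale factors and acquisition metadata, and optionally
#' the simulation ground truth.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param prefix path prefix (no extension).
#' @param groundTruth optional list to embed in the sidecar.
#' @return \code{readImageStack}: an \linkS4class{ImageStack} (ground truth,
#'   if present, in \code{meta$ground_truth}); \code{writeImageStack}: the
#'   sidecar path, invisibly.
#' @export
writeImageStack <- function(stack, prefix, groundTruth = NULL) {
  stopifnot(is(stack, "ImageStack"))
  channels <- list(pre = stack@pre, post = stack@post)
  if (length(stack@occluder)) channels$occluder <- stack@occluder
  scales <- list()
  for (ch in names(channels)) {
    arr <- channels[[ch]]
    mx <- max(arr, 1e-12)
    scales[[ch]] <- mx
    pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / mx)
    tiff::writeTIFF(pages, paste0(prefix, "_", ch, ".tif"),
                    bits.per.sample = 32L)
  }
  sidecar <- list(voxel_size_um = as.list(stack@voxelSize),
                  channels = names(channels), scales = scales,
                  meta = stack@meta)
  if (!is.null(groundTruth)) sidecar$ground_truth <- groundTruth
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"),
                                 simplifyVector = TRUE)
  readCh <- function(ch) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    arr * sidecar$scales[[ch]]
  }
  chans <- sidecar$channels
  meta <- as.list(sidecar$meta)
  if (!is.null(sidecar$ground_truth))
    meta$ground_truth <- sidecar$ground_truth
  vs <- unlist(sidecar$voxel_size_um)[c("z", "y", "x")]
  new("ImageStack",
      pre = readCh("pre"), post = readCh("post"),
      occluder = if ("occluder" %in% chans) readCh("occluder")
                 else array(0, c(0, 0, 0)),
      voxelSize = vs, meta = meta)
}
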