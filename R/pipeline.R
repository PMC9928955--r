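#' Default pipeline configuration
#'
#' Assembles the configuration consumed by \code{\link{runPipeline}}.  The
#' defaults reproduce the synthetic study conditions end to end: the
#' 16-sample two-group design over four regions, raw p < 0.05 significance,
#' KSEA with NetworKIN and substrate-count cutoffs of 0, enrichment over the
#' four annotation categories, network confidence 0.9 with k = 5 (proteome)
#' and k = 3 (phosphoproteome) subclusters, and 0.5 um juxtaposition
#' pairing for the optional imaging stage.
#'
#' @param seed global pipeline seed (fanned out per stage via
#'   \code{\link{childSeed}}).
#' @param alpha significance level for differential and enrichment filters.
#' @param design a \linkS4class{StudyDesign}.
#' @param omics list of synthetic omics parameters (\code{nProtein},
#'   \code{nPhospho}, \code{fracDifferential}, \code{effectLog2},
#'   \code{sharedFrac}, \code{noiseSd}).
#' @param ksea list with \code{nKinases}, \code{substratesPerKinase},
#'   \code{networkinCutoff}, \code{substrateCutoff}.
#' @param enrichment list with \code{categories}, \code{nTerms},
#'   \code{termSizeRange}.
#' @param network list with \code{minScore}, \code{kProteome},
#'   \code{kPhospho}.
#' @param puncta list with \code{enabled} plus generator/detection
#'   parameters (\code{nPairs}, \code{nPerGroup}, \code{effect},
#'   \code{snr}, \code{maxDist}).
#' @return a \code{PipelineConfig}-shaped named list.
#' @export
pipelineConfig <- function(seed = 1L, alpha = 0.05,
                           design = studyDesign(),
                           omics = list(nProtein = 800L, nPhospho = 400L,
                                        fracDifferential = 0.1,
                                        effectLog2 = 1, sharedFrac = 0.5,
                                        noiseSd = 0.3),
                           ksea = list(nKinases = 20L,
                                       substratesPerKinase = 10L,
                                       networkinCutoff = 0,
                                       substrateCutoff = 0),
                           enrichment = list(categories = c("GO Process",
                                                            "GO Function",
                                                            "KEGG",
                                                            "Reactome"),
                                             nTerms = 50L,
                                             termSizeRange = c(10L, 50L)),
                           network = list(minScore = 0.9, kProteome = 5L,
                                          kPhospho = 3L),
                           puncta = list(enabled = FALSE, nPairs = 80L,
                                         nPerGroup = 4L, effect = 20L,
                                         snr = 50, maxDist = 0.5,
                                         stackShape = c(z = 40L, y = 160L,
                                                        x = 160L))) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  list(seed = as.integer(seed), alpha = alpha, design = design,
       omics = omics, ksea = ksea, enrichment = enrichment,
       network = network, puncta = puncta)
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$design <- list(regions = config$design@regions,
                     nPerGroup = config$design@nPerGroup,
                     sexSplit = as.list(config$design@sexSplit))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes synthetic data generation, per-region differential analysis for
#' both omics levels, KSEA per region, over-representation analysis per
#' region and category, cross-region overlap/cosine similarity, interaction
#' network subclustering of the focal region's significant genes, and
#' (optionally) the synthetic imaging/puncta stage.  All tables are written
#' under \code{outDir}; identical configuration and seed give an identical
#' report.
#'
#' @param config a configuration from \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if missing).
#' @return A \linkS4class{RunReport}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  alpha <- config$alpha
  design <- config$design
  regions <- design@regions
  stage <- function(i) childSeed(seed, i)

  ## stage 1: synthetic omics
  om <- config$omics
  ds <- tryCatch(
    simulateOmicsDataset(design, nProtein = om$nProtein,
                         nPhospho = om$nPhospho,
                         fracDifferential = om$fracDifferential,
                         effectLog2 = om$effectLog2,
                         sharedFrac = om$sharedFrac, noiseSd = om$noiseSd,
                         seed = stage(1L)),
    error = function(e) stop("[simulate] ", conditionMessage(e)))

  ## stage 2: differential per level and region
  tables <- list(proteome = list(), phosphoproteome = list())
  diffSection <- list()
  for (lv in c("protein", "phospho")) {
    lvName <- if (lv == "protein") "proteome" else "phosphoproteome"
    for (r in regions) {
      dt <- tryCatch(
        differentialTable(ds[[lv]]$experiments[[r]], alpha = alpha),
        error = function(e) stop("[differential] ", conditionMessage(e)))
      tables[[lvName]][[r]] <- dt
      writeDifferentialTsv(dt, file.path(outDir,
        sprintf("differential_%s_%s.tsv", lvName, r)))
      diffSection[[lvName]][[r]] <- as.list(diffCounts(dt))
    }
  }

  ## stage 3: KSEA per region on the phosphoproteome fold changes
  phosphoFeatures <- rowData(
    ds$phospho$experiments[[1L]])$feature_id
  map <- simulateKinaseSubstrateMap(config$ksea$nKinases,
                                    config$ksea$substratesPerKinase,
                                    phosphoFeatures, seed = stage(3L))
  writeKinaseMapTsv(map, file.path(outDir, "kinase_substrate_map.tsv"))
  kseaSection <- list()
  for (r in regions) {
    rec <- tables$phosphoproteome[[r]]@records
    sites <- data.frame(feature_id = rec$feature_id,
                        log2_fc = rec$log2_ar,
                        localization_confirmed = TRUE)
    ks <- tryCatch(
      kseaScores(sites, map,
                 networkinCutoff = config$ksea$networkinCutoff,
                 substrateCutoff = config$ksea$substrateCutoff),
      error = function(e) stop("[ksea] ", conditionMessage(e)))
    path <- file.path(outDir, sprintf("ksea_%s.tsv", r))
    utils::write.table(as.data.frame(kseaTable(ks)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    coral <- kinomeExport(ks)
    utils::write.table(coral, file.path(outDir,
      sprintf("kinome_annotation_%s.tsv", r)), sep = "\t", quote = FALSE,
      row.names = FALSE)
    kseaSection[[r]] <- list(n_kinases = nrow(kseaTable(ks)),
                             n_fdr_significant =
                               sum(kseaTable(ks)$fdr < 0.05),
                             table = basename(path))
  }

  ## stage 4: enrichment per level, region and category
  dbs <- lapply(seq_along(config$enrichment$categories), function(i)
    simulateAnnotationDb(config$enrichment$nTerms, ds$geneUniverse,
                         category = config$enrichment$categories[i],
                         termSizeRange = config$enrichment$termSizeRange,
                         seed = stage(40L + i)))
  names(dbs) <- config$enrichment$categories
  termSets <- list()
  for (lvName in names(tables)) {
    for (categ in names(dbs)) {
      sets <- list()
      for (r in regions) {
        dt <- tables[[lvName]][[r]]
        genes <- significantFeatures(dt, what = "gene_id")
        background <- unique(as.character(dt@records$gene_id))
        er <- enrichTerms(genes, background, dbs[[categ]], alpha = alpha)
        utils::write.table(er, file.path(outDir,
          sprintf("enrichment_%s_%s_%s.tsv", lvName, gsub(" ", "", categ),
                  r)), sep = "\t", quote = FALSE, row.names = FALSE)
        sets[[r]] <- er$term_id
      }
      termSets[[lvName]][[categ]] <- sets
    }
  }

  ## stage 5: cross-region overlap / cosine similarity
  similarity <- list()
  for (lvName in names(tables)) {
    geneRep <- geneIdOverlap(tables[[lvName]])
    similarity[[lvName]]$gene_ids <- similarityAsList(geneRep)
    for (categ in names(dbs))
      similarity[[lvName]][[gsub(" ", "_", categ)]] <-
        similarityAsList(regionOverlap(termSets[[lvName]][[categ]]))
  }
  jsonlite::write_json(similarity,
                       file.path(outDir, "similarity_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## stage 6: interaction network subclustering (focal region, both levels)
  networkSection <- list()
  focal <- regions[1L]
  for (lvName in names(tables)) {
    dt <- tables[[lvName]][[focal]]
    sigGenes <- significantFeatures(dt, what = "gene_id")
    k <- if (lvName == "proteome") config$network$kProteome
         else config$network$kPhospho
    if (length(sigGenes) < max(10L, 2L * k)) {
      networkSection[[lvName]] <- list(skipped = "too few significant genes")
      next
    }
    sizes <- rep(length(sigGenes) %/% k, k)
    sizes[1L] <- sizes[1L] + length(sigGenes) %% k
    net <- simulateInteractionEdges(sizes, nodeNames = sigGenes,
                                    nDecoy = 50L,
                                    seed = stage(60L +
                                      match(lvName, names(tables))))
    g <- tryCatch(
      buildInteractionGraph(net$edges, minScore = config$network$minScore),
      error = function(e) stop("[network] ", conditionMessage(e)))
    assign2 <- kmeansSubcluster(g, k = min(k, igraph::vcount(g)),
                                seed = stage(65L))
    assign2 <- labelSubclusters(assign2, dbs[["KEGG"]], alpha = alpha)
    utils::write.table(
      data.frame(gene_id = names(assign2@membership),
                 cluster = assign2@membership,
                 label = assign2@labels[assign2@membership]),
      file.path(outDir, sprintf("network_clusters_%s.tsv", lvName)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    networkSection[[lvName]] <- list(
      n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
      k = assign2@k, cluster_sizes = as.list(clusterSizes(assign2)),
      labels = as.list(assign2@labels))
  }

  ## stage 7: optional synthetic imaging / puncta stage
  punctaSection <- NULL
  if (isTRUE(config$puncta$enabled)) {
    pc <- config$puncta
    recs <- list()
    i <- 0L
    for (grp in c("PME", "PSE")) for (a in seq_len(pc$nPerGroup)) {
      i <- i + 1L
      ## per-image synapse counts vary as Poisson draws around the group rate
      rate <- pc$nPairs + if (grp == "PME") pc$effect else 0L
      nPairs <- .withSeed(stage(110L + i), stats::rpois(1L, rate))
      shape <- pc$stackShape
      if (is.null(shape)) shape <- c(z = 40L, y = 160L, x = 160L)
      truth <- simulateImageGroundTruth(nPairs = nPairs,
                                        nUnpairedPre = 10L,
                                        nUnpairedPost = 10L,
                                        stackShape = shape,
                                        seed = stage(70L + i))
      stack <- simulateImageStack(truth, snr = pc$snr,
                                  meta = list(animal_id =
                                                paste0(grp, "_", a),
                                              group = grp),
                                  seed = stage(90L + i))
      np <- estimateNeuropil(stack)
      pre <- detectSpots(stack@pre, stack@voxelSize, 0.5,
                         neuropilMask = np$neuropilMask)
      post <- detectSpots(stack@post, stack@voxelSize, 0.3,
                          neuropilMask = np$neuropilMask)
      recs[[i]] <- pairSynapses(pre, post, maxDist = pc$maxDist,
                                neuropilVolume = np$neuropilVolume,
                                meta = list(animal_id = paste0(grp, "_", a),
                                            group = grp))$record
    }
    recs <- do.call(rbind, recs)
    utils::write.table(recs, file.path(outDir, "synapse_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cmp <- compareGroups(recs)
    punctaSection <- list(n_images = nrow(recs),
                          t = cmp$t, df = cmp$df, p_value = cmp$p_value,
                          welch = cmp$welch,
                          mean_density = as.list(stats::setNames(
                            cmp$descriptives$mean, cmp$descriptives$group)))
  }

  report <- new("RunReport", sections = list(
    differential = diffSection,
    ksea = kseaSection,
    similarity = similarity,
    network = networkSection,
    puncta = punctaSection,
    seed = seed,
    alpha = alpha,
    version = as.character(utils::packageVersion("proteoRegion")),
    config_hash = .configHash(config)))
  writeRunReport(report, outDir)
  report
}

#' @rdname reportSections
#' @param x a \linkS4class{RunReport}.
#' @return \code{reportSections}: the named list of report sections.
#' @export
setMethod("reportSections", "RunReport", function(x) x@sections)

setMethod("show", "RunReport", function(object) {
  s <- object@sections
  cat("RunReport (seed", s$seed, ", alpha", s$alpha, ")\n")
  for (lv in names(s$differential)) {
    ct <- vapply(s$differential[[lv]], function(x) x$n_significant,
                 numeric(1))
    cat(" ", lv, "significant per region:",
        paste(names(ct), ct, sep = "=", collapse = ", "), "\n")
  }
})

#' Write / read a run report
#'
#' JSON is the canonical machine-readable form (timestamps excluded, so
#' identical runs give byte-identical files); the TSV bundle additionally
#' flattens the differential counts into one row per level and region.
#'
#' @param report a \linkS4class{RunReport}.
#' @param dir output directory.
#' @param format \code{"json"} (always written) plus optionally
#'   \code{"tsv"}.
#' @return \code{writeRunReport}: the JSON path, invisibly;
#'   \code{readRunReport}: the report as a \linkS4class{RunReport}.
#' @export
writeRunReport <- function(report, dir, format = c("json", "tsv")) {
  stopifnot(is(report, "RunReport"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "run_report.json")
  jsonlite::write_json(report@sections, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  if ("tsv" %in% format) {
    rows <- list()
    for (lv in names(report@sections$differential))
      for (r in names(report@sections$differential[[lv]])) {
        ct <- report@sections$differential[[lv]][[r]]
        rows[[paste(lv, r)]] <- data.frame(level = lv, region = r,
                                           n_significant = ct$n_significant,
                                           n_up = ct$n_up,
                                           n_down = ct$n_down)
      }
    utils::write.table(do.call(rbind, rows),
                       file.path(dir, "differential_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeRunReport
#' @export
readRunReport <- function(dir) {
  new("RunReport",
      sections = jsonlite::read_json(file.path(dir, "run_report.json"),
                                     simplifyVector = FALSE))
}
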