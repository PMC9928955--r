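#' Over-representation analysis against a term database
#'
#' Hypergeometric upper-tail test per term: drawing |genes| from the
#' background, how surprising is the observed count of term members in the
#' input list?  The background (universe) is the set of genes quantified in
#' the experiment, not the genome.  Enrichment strength is
#' log10(observed/expected).  Benjamini-Hochberg FDR is computed across all
#' terms of the database (one annotation category per database) and
#' reported; the returned list is filtered at raw p < \code{alpha} by
#' default, matching the significance convention of the downstream overlap
#' analysis.
#'
#' @param genes character vector, the differential gene list.
#' @param background character vector, the quantified universe; must contain
#'   every element of \code{genes}.
#' @param db an annotation database: named list term_id -> character vector
#'   of member genes, with optional attribute \code{category}.
#' @param alpha raw-p significance filter (default 0.05).
#' @param filter return only significant terms (default TRUE).
#' @return data.frame with columns \code{term_id}, \code{category},
#'   \code{observed}, \code{expected}, \code{strength}, \code{p_value},
#'   \code{fdr}, sorted by strength descending.
#' @export
enrichTerms <- function(genes, background, db, alpha = 0.05, filter = TRUE) {
  genes <- unique(as.character(genes))
  background <- unique(as.character(background))
  offenders <- setdiff(genes, background)
  if (length(offenders))
    stop("genes not in background: ", paste(utils::head(offenders, 5),
                                            collapse = ", "))
  if (!length(db)) stop("annotation database is empty")
  N <- length(background)
  k <- length(genes)
  members <- lapply(db, function(g) intersect(unique(as.character(g)),
                                              background))
  K <- lengths(members)
  obs <- vapply(members, function(mm) length(intersect(genes, mm)),
                integer(1))
  expd <- k * K / N
  p <- stats::phyper(obs - 1L, K, N - K, k, lower.tail = FALSE)
  out <- data.frame(
    term_id = names(db),
    category = if (is.null(attr(db, "category"))) NA_character_
               else attr(db, "category"),
    observed = obs,
    expected = expd,
    strength = ifelse(obs > 0, log10(obs / expd), NA_real_),
    p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (filter) out <- out[out$p_value < alpha, , drop = FALSE]
  out[order(-out$strength, out$p_value, out$term_id), , drop = FALSE]
}

#' Cosine similarity between two identifier sets
#'
#' Treats each set as a binary vector over the union vocabulary, so
#' \eqn{\cos(a, b) = |a \cap b| / \sqrt{|a| |b|}}.  An empty set on either
#' side yields 0 (the convention for regions with no significant terms).
#'
#' @param a,b character vectors (duplicates ignored).
#' @return similarity in [0, 1].
#' @examples
#' cosineSetSimilarity(c("x", "y"), c("y", "z"))  # 0.5
#' @export
cosineSetSimilarity <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (!length(a) || !length(b)) return(0)
  length(intersect(a, b)) / sqrt(length(a) * length(b))
}

#' Venn membership-pattern counts
#'
#' @param sets named list of character vectors.
#' @return named integer vector; names are \code{&}-joined subset patterns
#'   (e.g. \code{"M1&DLS"}), values count elements belonging to exactly the
#'   named sets.  Counts sum to |union|.
#' @export
vennCounts <- function(sets) {
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  u <- unique(unlist(sets))
  if (!length(u)) return(structure(integer(0), names = character(0)))
  pattern <- vapply(u, function(el) {
    paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  tab <- table(pattern)
  structure(as.integer(tab), names = names(tab))
}

.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Cross-region overlap and cosine similarity
#'
#' Given per-region significant term (or GeneID) sets, computes the
#' pairwise Jaccard overlap fractions, the all-region overlap
#' (|intersection over all regions| / |union|), Venn membership counts, the
#' per-region unique counts (elements in no other region's set, as a count
#' and as a percentage of the all-region union), and the cosine similarity
#' between the focal region's set and the de-duplicated union of the other
#' regions' sets.
#'
#' @param sets named list (region -> character vector) of significant ids;
#'   at least 2 regions.
#' @param focalRegion region compared against the pooled rest (default
#'   \code{"M1"}; falls back to the first region if absent).
#' @return A \linkS4class{SimilarityReport}.
#' @export
regionOverlap <- function(sets, focalRegion = "M1") {
  if (length(sets) < 2L || is.null(names(sets)))
    stop("need named sets for at least 2 regions")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  regions <- names(sets)
  if (!focalRegion %in% regions) focalRegion <- regions[1L]
  pw <- matrix(0, length(sets), length(sets),
               dimnames = list(regions, regions))
  for (i in seq_along(sets)) for (j in seq_along(sets))
    pw[i, j] <- .jaccard(sets[[i]], sets[[j]])
  inter <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  allFrac <- if (length(uni)) length(inter) / length(uni) else 0
  rest <- unique(unlist(sets[setdiff(regions, focalRegion)]))
  uniqueCounts <- vapply(regions, function(r) {
    others <- unique(unlist(sets[setdiff(regions, r)]))
    length(setdiff(sets[[r]], others))
  }, integer(1))
  new("SimilarityReport",
      regions = regions, sets = sets, pairwise = pw,
      allRegionOverlap = allFrac,
      focalRegion = focalRegion,
      focalVsRestCosine = cosineSetSimilarity(sets[[focalRegion]], rest),
      vennCounts = vennCounts(sets),
      uniqueCounts = uniqueCounts,
      uniquePct = if (length(uni)) 100 * uniqueCounts / length(uni)
                  else uniqueCounts * 0)
}

#' GeneID overlap of differential tables across regions
#'
#' Extracts the significant GeneID set of every region's differential table
#' and summarises the cross-region sharing with
#' \code{\link{regionOverlap}}: how many GeneIDs recur in all regions, how
#' many are unique to each region, and how similar the focal region is to
#' the pooled rest.
#'
#' @param tables named list (region -> \linkS4class{DifferentialTable}); all
#'   of one omics level.
#' @param what overlap \code{"gene_id"} (default) or \code{"feature_id"}.
#' @param focalRegion see \code{\link{regionOverlap}}.
#' @return A \linkS4class{SimilarityReport} over the significant identifiers.
#' @export
geneIdOverlap <- function(tables, what = c("gene_id", "feature_id"),
                          focalRegion = "M1") {
  what <- match.arg(what)
  stopifnot(length(tables) >= 2L, !is.null(names(tables)))
  sets <- lapply(tables, significantFeatures, what = what)
  regionOverlap(sets, focalRegion = focalRegion)
}

setMethod("show", "SimilarityReport", function(object) {
  cat("SimilarityReport over", length(object@regions), "regions (",
      paste(object@regions, collapse = ", "), ")\n")
  cat("  all-region overlap:", signif(object@allRegionOverlap, 4),
      "|", object@focalRegion, "vs rest cosine:",
      signif(object@focalVsRestCosine, 4), "\n")
  cat("  unique counts:", paste(names(object@uniqueCounts),
                                object@uniqueCounts, sep = "=",
                                collapse = ", "), "\n")
})

#' Convert a SimilarityReport to a plain list (for JSON serialization)
#' @param report a \linkS4class{SimilarityReport}.
#' @return nested list of the report's statistics.
#' @export
similarityAsList <- function(report) {
  stopifnot(is(report, "SimilarityReport"))
  list(regions = report@regions,
       pairwise_jaccard = as.data.frame(report@pairwise),
       all_region_overlap = report@allRegionOverlap,
       focal_region = report@focalRegion,
       focal_vs_rest_cosine = report@focalVsRestCosine,
       venn_counts = as.list(report@vennCounts),
       unique_counts = as.list(report@uniqueCounts),
       unique_pct = as.list(report@uniquePct))
}
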