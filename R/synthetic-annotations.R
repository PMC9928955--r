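#' Simulate a kinase-substrate map
#'
#' Draws, for each synthetic kinase, a set of substrate phosphosites from
#' the quantified feature list, annotating every row with a source flag
#' (PSP or NetworKIN) and a NetworKIN-like score (0 for PSP rows, positive
#' for NetworKIN rows) — the shape of a PhosphoSitePlus + NetworKIN
#' kinase-substrate dataset.
#'
#' @param nKinases number of kinases (0 gives an empty map).
#' @param substratesPerKinase substrates drawn (without replacement) per
#'   kinase; must not exceed the number of available features.
#' @param phosphoFeatures non-empty character vector of quantified
#'   phosphosite feature ids.
#' @param seed integer seed.
#' @return data.frame with columns \code{kinase}, \code{substrate},
#'   \code{source}, \code{networkin_score}.
#' @export
simulateKinaseSubstrateMap <- function(nKinases, substratesPerKinase,
                                       phosphoFeatures, seed = 1L) {
  if (!length(phosphoFeatures)) stop("phospho feature list must be non-empty")
  if (nKinases == 0L)
    return(data.frame(kinase = character(0), substrate = character(0),
                      source = character(0), networkin_score = numeric(0),
                      stringsAsFactors = FALSE))
  if (substratesPerKinase > length(phosphoFeatures))
    stop("substratesPerKinase exceeds the number of available features")
  .withSeed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nKinases), function(i) {
      subs <- sample(phosphoFeatures, substratesPerKinase)
      src <- sample(c("PSP", "NetworKIN"), substratesPerKinase,
                    replace = TRUE)
      data.frame(kinase = sprintf("KIN%02d", i), substrate = subs,
                 source = src,
                 networkin_score = ifelse(src == "NetworKIN",
                                          round(stats::runif(
                                            substratesPerKinase, 0.5, 5), 3),
                                          0),
                 stringsAsFactors = FALSE)
    }))
    rownames(rows) <- NULL
    rows
  })
}

#' Simulate a term-annotation database
#'
#' Builds a named list of terms (term_id -> member genes) for one of the
#' four annotation categories, with term sizes drawn uniformly from a
#' range.  Every term has at least one member.
#'
#' @param nTerms number of terms.
#' @param genes non-empty gene universe to draw members from.
#' @param category one of \code{"GO Process"}, \code{"GO Function"},
#'   \code{"KEGG"}, \code{"Reactome"}; anything else is an error.
#' @param termSizeRange integer range of term sizes (capped at the universe
#'   size).
#' @param seed integer seed.
#' @return named list with attribute \code{category}; write with
#'   \code{\link{writeGmt}}.
#' @export
simulateAnnotationDb <- function(nTerms, genes,
                                 category = c("GO Process", "GO Function",
                                              "KEGG", "Reactome"),
                                 termSizeRange = c(10L, 50L), seed = 1L) {
  category <- match.arg(category)
  if (!length(genes)) stop("gene universe must be non-empty")
  prefix <- c("GO Process" = "GOP", "GO Function" = "GOF",
              "KEGG" = "KEGG", "Reactome" = "REACT")[category]
  .withSeed(seed, {
    lo <- max(1L, min(termSizeRange[1], length(genes)))
    hi <- min(termSizeRange[2], length(genes))
    db <- lapply(seq_len(nTerms), function(i)
      sample(genes, sample(lo:hi, 1L)))
    names(db) <- sprintf("%s:%04d", prefix, seq_len(nTerms))
    attr(db, "category") <- category
    db
  })
}

#' Simulate a STRING-dialect interaction edge list with planted communities
#'
#' Draws a planted-partition (stochastic block model) graph over a node set
#' split into communities: node pairs within a community are connected with
#' probability \code{withinP}, pairs across communities with
#' \code{betweenP}.  Planted edges receive high combined scores (drawn from
#' \code{scoreRange}); additional decoy edges with sub-threshold scores can
#' be added to exercise confidence filtering.
#'
#' @param communitySizes integer vector of community sizes.
#' @param withinP,betweenP edge probabilities within/between communities.
#' @param scoreRange combined-score range for planted edges (default within
#'   the highest-confidence band).
#' @param nDecoy number of extra low-score (0.15-0.4) decoy edges.
#' @param nodeNames optional node names (defaults to \code{GeneNNNNN}).
#' @param stringDialect emit integer scores 0-999 instead of [0, 1].
#' @param seed integer seed.
#' @return list with \code{edges} (data.frame \code{protein1},
#'   \code{protein2}, \code{combined_score}) and \code{membership} (named
#'   integer vector of true community labels).
#' @export
simulateInteractionEdges <- function(communitySizes = c(20L, 20L, 20L),
                                     withinP = 0.9, betweenP = 0.05,
                                     scoreRange = c(0.9, 0.999),
                                     nDecoy = 0L, nodeNames = NULL,
                                     stringDialect = FALSE, seed = 1L) {
  n <- sum(communitySizes)
  if (is.null(nodeNames)) nodeNames <- sprintf("Gene%05d", seq_len(n))
  stopifnot(length(nodeNames) == n)
  membership <- rep(seq_along(communitySizes), communitySizes)
  names(membership) <- nodeNames
  .withSeed(seed, {
    pairs <- utils::combn(n, 2L)
    same <- membership[pairs[1, ]] == membership[pairs[2, ]]
    p <- ifelse(same, withinP, betweenP)
    keep <- stats::runif(ncol(pairs)) < p
    e <- data.frame(
      protein1 = nodeNames[pairs[1, keep]],
      protein2 = nodeNames[pairs[2, keep]],
      combined_score = stats::runif(sum(keep), scoreRange[1], scoreRange[2]),
      stringsAsFactors = FALSE)
    if (nDecoy > 0L) {
      di <- replicate(nDecoy, sample.int(n, 2L))
      e <- rbind(e, data.frame(
        protein1 = nodeNames[di[1, ]], protein2 = nodeNames[di[2, ]],
        combined_score = stats::runif(nDecoy, 0.15, 0.4),
        stringsAsFactors = FALSE))
    }
    if (stringDialect) e$combined_score <- round(e$combined_score * 1000)
    list(edges = e, membership = membership)
  })
}
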