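#' Kinase-substrate enrichment analysis (KSEA) z-scores
#'
#' Scores each kinase by how far the mean log2 fold change of its quantified
#' substrates deviates from the global mean, normalized by the spread of all
#' site fold changes:
#' \deqn{z = \frac{(\bar{s} - \bar{p})\sqrt{m}}{\delta}}
#' where \eqn{\bar{s}} is the mean log2 fold change of the kinase's
#' \eqn{m} substrates, \eqn{\bar{p}} the mean over all usable sites and
#' \eqn{\delta} their standard deviation (population SD by default, the
#' KSEA App convention).  Two-sided normal p-values are Benjamini-Hochberg
#' corrected across kinases.
#'
#' Only localization-confirmed sites are used.  Map rows below the
#' NetworKIN score cutoff are dropped; a substrate mapped to the same kinase
#' by several sources counts once.  A substrate-count cutoff of 0 means no
#' minimum beyond m >= 1.
#'
#' @param sites data.frame of phosphosite records with columns
#'   \code{feature_id}, \code{log2_fc} and optionally
#'   \code{localization_confirmed} (missing means confirmed).
#' @param map kinase-substrate map: data.frame with columns \code{kinase},
#'   \code{substrate}, \code{source} (PSP or NetworKIN) and
#'   \code{networkin_score}.
#' @param networkinCutoff drop NetworKIN-sourced map rows with score below
#'   this (default 0 = keep all).
#' @param substrateCutoff minimum substrate count per kinase (default 0,
#'   i.e. m >= 1).
#' @param ddof degrees-of-freedom correction for \eqn{\delta}: 0 (population
#'   SD, default) or 1 (sample SD).
#' @return A \linkS4class{KseaResults}.
#' @export
kseaScores <- function(sites, map, networkinCutoff = 0, substrateCutoff = 0,
                       ddof = 0) {
  stopifnot(all(c("feature_id", "log2_fc") %in% colnames(sites)))
  if ("localization_confirmed" %in% colnames(sites))
    sites <- sites[as.logical(sites$localization_confirmed), , drop = FALSE]
  sites <- sites[is.finite(sites$log2_fc), , drop = FALSE]
  if (nrow(sites) < 2L) stop("need at least 2 usable phosphosites")
  fc <- sites$log2_fc
  names(fc) <- as.character(sites$feature_id)
  n <- length(fc)
  pBar <- mean(fc)
  delta <- sqrt(sum((fc - pBar)^2) / (n - ddof))
  if (delta == 0) stop("degenerate site table: all log2 fold changes equal")

  usable <- map
  if (nrow(usable)) {
    drop <- usable$source == "NetworKIN" &
            usable$networkin_score < networkinCutoff
    usable <- usable[!drop, , drop = FALSE]
    usable <- usable[as.character(usable$substrate) %in% names(fc), ,
                     drop = FALSE]
    usable <- unique(usable[c("kinase", "substrate")])
  }
  if (!nrow(usable)) {
    warning("no usable kinase-substrate map rows; returning empty result")
    return(new("KseaResults",
               scores = DataFrame(kinase = character(0), m = integer(0),
                                  s_bar = numeric(0), z = numeric(0),
                                  p_value = numeric(0), fdr = numeric(0)),
               globalMean = pBar, globalSd = delta))
  }
  bySub <- split(as.character(usable$substrate), as.character(usable$kinase))
  m <- lengths(bySub)
  keep <- m >= max(substrateCutoff, 1L)
  bySub <- bySub[keep]; m <- m[keep]
  sBar <- vapply(bySub, function(s) mean(fc[s]), numeric(1))
  z <- (sBar - pBar) * sqrt(m) / delta
  p <- 2 * stats::pnorm(-abs(z))
  new("KseaResults",
      scores = DataFrame(kinase = names(bySub), m = as.integer(m),
                         s_bar = unname(sBar), z = unname(z),
                         p_value = unname(p),
                         fdr = stats::p.adjust(p, method = "BH")),
      globalMean = pBar, globalSd = delta)
}

#' @rdname kseaTable
#' @param x a \linkS4class{KseaResults}.
#' @return \code{kseaTable}: the per-kinase score \code{DataFrame}.
#' @export
setMethod("kseaTable", "KseaResults", function(x) x@scores)

setMethod("show", "KseaResults", function(object) {
  s <- object@scores
  cat("KseaResults:", nrow(s), "kinases; global mean log2FC =",
      signif(object@globalMean, 4), ", delta =", signif(object@globalSd, 4),
      "\n  FDR < 0.05:", sum(s$fdr < 0.05), "kinases\n")
})

#' Kinome-tree annotation export
#'
#' Formats KSEA results as the annotation table consumed by kinome-tree
#' visualizers: branch colour carries the FDR, node colour the signed
#' z-score, node size the absolute z-score.  Rows are ordered by |z|
#' descending.
#'
#' @param scores a \linkS4class{KseaResults}.
#' @return data.frame with columns \code{kinase}, \code{branch_value} (fdr),
#'   \code{node_color_value} (z) and \code{node_size_value} (|z|).
#' @export
kinomeExport <- function(scores) {
  stopifnot(is(scores, "KseaResults"))
  s <- as.data.frame(scores@scores)
  if (!nrow(s)) stop("no kinase scores to export")
  out <- data.frame(kinase = s$kinase,
                    branch_value = s$fdr,
                    node_color_value = s$z,
                    node_size_value = abs(s$z),
                    stringsAsFactors = FALSE)
  out[order(-out$node_size_value, out$kinase), , drop = FALSE]
}
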