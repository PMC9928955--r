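#' Build a confidence-filtered interaction graph
#'
#' Consumes an interaction edge list (STRING-export dialect: integer
#' combined scores 0-999 are divided by 1,000), drops edges below the
#' confidence threshold (default 0.9, "highest confidence"), drops
#' self-loops, and hides disconnected nodes: only nodes with at least one
#' retained edge appear in the graph.
#'
#' @param edges data.frame with columns \code{protein1}, \code{protein2},
#'   \code{combined_score}; scores either in [0, 1] or STRING-dialect
#'   integers in 0-999.
#' @param minScore minimum combined score to retain an edge (default 0.9).
#' @param nodeAttrs optional data.frame with columns \code{gene_id} and
#'   \code{log2_ar}; matched attributes are attached to retained nodes.
#' @return an \code{igraph} undirected graph with edge attribute
#'   \code{score}.
#' @export
buildInteractionGraph <- function(edges, minScore = 0.9, nodeAttrs = NULL) {
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% colnames(edges)))
    stop("edge table must have columns ", paste(need, collapse = ", "))
  sc <- suppressWarnings(as.numeric(edges$combined_score))
  bad <- which(!is.finite(sc))
  if (length(bad))
    stop("malformed combined_score at edge row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(sc > 1)) sc <- sc / 1000       # STRING 0-999 dialect
  if (any(sc < 0 | sc > 1))
    stop("combined scores must lie in [0, 1] after dialect conversion")
  keep <- sc >= minScore &
          as.character(edges$protein1) != as.character(edges$protein2)
  e <- data.frame(from = as.character(edges$protein1)[keep],
                  to = as.character(edges$protein2)[keep],
                  score = sc[keep], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  if (!is.null(nodeAttrs)) {
    idx <- match(igraph::V(g)$name, as.character(nodeAttrs$gene_id))
    igraph::V(g)$log2_ar <- nodeAttrs$log2_ar[idx]
  }
  g
}

## deterministic spectral embedding: top-k eigenvectors of the
## symmetric-normalized adjacency, sign-fixed, row-normalized
.spectralEmbedding <- function(g, k) {
  ord <- order(igraph::V(g)$name)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)[ord, ord]
  d <- rowSums(A)
  dI <- 1 / sqrt(pmax(d, .Machine$double.eps))
  L <- A * (dI %o% dI)
  eg <- eigen(L, symmetric = TRUE)
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(U))) {              # fix sign ambiguity
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  rn <- sqrt(rowSums(U^2))
  U <- U / pmax(rn, .Machine$double.eps)
  rownames(U) <- rownames(A)
  U
}

#' k-means subclustering of an interaction graph
#'
#' Embeds the graph spectrally (top-k eigenvectors of the
#' symmetric-normalized adjacency, rows normalized to unit length) and runs
#' k-means with a fixed seed, giving a deterministic hard assignment that is
#' invariant to node input order (nodes are sorted by name internally and
#' cluster indices are canonicalized by first node appearance).  Defaults
#' used downstream: k = 5 for proteome graphs, k = 3 for phosphoproteome
#' graphs.
#'
#' @param graph an \code{igraph} graph from
#'   \code{\link{buildInteractionGraph}}.
#' @param k number of subclusters; must not exceed the node count.
#' @param seed integer seed for the k-means initialization.
#' @return A \linkS4class{SubclusterAssignment}; edges carry an
#'   \code{intra} flag (TRUE when both endpoints share a cluster).
#' @export
kmeansSubcluster <- function(graph, k, seed = 1L) {
  n <- igraph::vcount(graph)
  if (n < k) stop("graph has ", n, " nodes, fewer than k = ", k)
  U <- .spectralEmbedding(graph, k)
  km <- local({
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    stats::kmeans(U, centers = k, nstart = 25L, iter.max = 200L)
  })
  memb <- km$cluster
  ## canonical indices: cluster 1 is the one containing the first node, etc.
  canon <- match(memb, unique(memb))
  names(canon) <- rownames(U)
  kEff <- length(unique(canon))
  if (kEff < k) warning("only ", kEff, " non-empty clusters; k reduced")
  el <- igraph::as_data_frame(graph, what = "edges")
  edges <- data.frame(from = el$from, to = el$to, score = el$score,
                      intra = canon[el$from] == canon[el$to],
                      stringsAsFactors = FALSE, row.names = NULL)
  new("SubclusterAssignment",
      membership = structure(as.integer(canon), names = names(canon)),
      k = as.integer(kEff), edges = edges,
      labels = rep("unlabeled", kEff),
      labelStrength = rep(NA_real_, kEff))
}

#' @rdname clusterSizes
#' @param x a \linkS4class{SubclusterAssignment}.
#' @return \code{clusterSizes}: integer vector of cluster sizes, summing to
#'   the number of retained nodes.
#' @export
setMethod("clusterSizes", "SubclusterAssignment", function(x) {
  as.integer(table(factor(x@membership, levels = seq_len(x@k))))
})

setMethod("show", "SubclusterAssignment", function(object) {
  cat("SubclusterAssignment:", length(object@membership), "nodes in",
      object@k, "clusters (sizes:",
      paste(clusterSizes(object), collapse = ", "), ")\n")
  if (any(object@labels != "unlabeled"))
    cat("  labels:", paste(seq_len(object@k), object@labels, sep = ":",
                           collapse = "; "), "\n")
})

#' Label subclusters by their strongest annotation term
#'
#' Runs over-representation analysis per cluster against a KEGG or Reactome
#' database (background = all retained nodes) and labels each cluster with
#' its maximal-strength significant term; ties are broken by smaller
#' p-value, then lexicographic term id.  Clusters with no significant term
#' are labelled \code{"unlabeled"}.
#'
#' @param assignment a \linkS4class{SubclusterAssignment}.
#' @param db annotation database (named list term -> genes), typically with
#'   attribute \code{category} in \{KEGG, Reactome\}.
#' @param alpha significance filter for candidate terms (default 0.05).
#' @return the assignment with \code{labels} and \code{labelStrength}
#'   filled in.
#' @export
labelSubclusters <- function(assignment, db, alpha = 0.05) {
  stopifnot(is(assignment, "SubclusterAssignment"))
  background <- names(assignment@membership)
  labels <- rep("unlabeled", assignment@k)
  strength <- rep(NA_real_, assignment@k)
  if (length(db)) {
    for (cl in seq_len(assignment@k)) {
      members <- background[assignment@membership == cl]
      if (!length(members)) next
      er <- enrichTerms(members, background, db, alpha = alpha,
                        filter = TRUE)
      er <- er[!is.na(er$strength), , drop = FALSE]
      if (!nrow(er)) next
      er <- er[order(-er$strength, er$p_value, er$term_id), , drop = FALSE]
      labels[cl] <- er$term_id[1L]
      strength[cl] <- er$strength[1L]
    }
  }
  assignment@labels <- labels
  assignment@labelStrength <- strength
  assignment
}
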