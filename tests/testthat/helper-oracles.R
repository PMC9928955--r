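suppressMessages(library(SummarizedExperiment))

## Independent brute-force oracles used across the suite.  These are kept
## deliberately naive (textbook formulas, explicit loops) so they share no
## code path with the implementation they check.

## textbook two-sample t on a pair of vectors (pooled or Welch)
oracleT <- function(x, y, welch = FALSE) {
  nx <- length(x); ny <- length(y)
  mx <- sum(x) / nx; my <- sum(y) / ny
  vx <- sum((x - mx)^2) / (nx - 1); vy <- sum((y - my)^2) / (ny - 1)
  if (welch) {
    se2 <- vx / nx + vy / ny
    tt <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    tt <- (mx - my) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

## KSEA z from first principles (population SD)
oracleKseaZ <- function(allFc, substrateFc) {
  pBar <- mean(allFc)
  delta <- sqrt(mean((allFc - pBar)^2))
  (mean(substrateFc) - pBar) * sqrt(length(substrateFc)) / delta
}

## binary-vector cosine over the union vocabulary
oracleCosine <- function(a, b) {
  vocab <- union(unique(a), unique(b))
  if (!length(vocab)) return(0)
  va <- as.numeric(vocab %in% a)
  vb <- as.numeric(vocab %in% b)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  sum(va * vb) / (na * nb)
}

## membership-pattern tally by explicit enumeration
oracleVenn <- function(sets) {
  u <- unique(unlist(sets))
  out <- list()
  for (el in u) {
    members <- character(0)
    for (nm in names(sets)) if (el %in% sets[[nm]]) members <- c(members, nm)
    key <- paste(members, collapse = "&")
    out[[key]] <- c(out[[key]], el)
  }
  sapply(out, length)
}

## greedy one-to-one juxtaposition pairing, written independently
oraclePairCount <- function(pre, post, maxDist) {
  if (!nrow(pre) || !nrow(post)) return(0L)
  cand <- NULL
  for (i in seq_len(nrow(pre))) for (j in seq_len(nrow(post))) {
    dd <- sqrt(sum((pre[i, ] - post[j, ])^2))
    if (dd <= maxDist) cand <- rbind(cand, c(i, j, dd))
  }
  if (is.null(cand)) return(0L)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  usedI <- usedJ <- integer(0)
  n <- 0L
  for (r in seq_len(nrow(cand))) {
    if (cand[r, 1] %in% usedI || cand[r, 2] %in% usedJ) next
    usedI <- c(usedI, cand[r, 1]); usedJ <- c(usedJ, cand[r, 2])
    n <- n + 1L
  }
  n
}

## tiny deterministic toy matrix experiment builder
toyExperiment <- function(values, region = "M1", site = NULL) {
  n <- ncol(values)
  stopifnot(n %% 2 == 0)
  half <- n / 2
  meta <- data.frame(
    sample = paste(rep(c("PME", "PSE"), each = half),
                   rep(c("M", "F"), length.out = n),
                   rep(seq_len(half), 2), sep = "_"),
    group = rep(c("PME", "PSE"), each = half),
    sex = rep(c("M", "F"), length.out = n),
    region = region, stringsAsFactors = FALSE)
  colnames(values) <- meta$sample
  AbundanceExperiment(values,
                      featureId = sprintf("F%03d", seq_len(nrow(values))),
                      geneId = sprintf("G%03d", seq_len(nrow(values))),
                      site = site, sampleMeta = meta)
}
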