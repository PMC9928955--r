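## --- separable 3D Gaussian smoothing ---------------------------------------

## band convolution matrix with replicate-edge normalization: rows sum to 1
.convMatrix <- function(n, sigmaVox) {
  if (sigmaVox <= 0) return(diag(n))
  rad <- max(1L, ceiling(3 * sigmaVox))
  offs <- -rad:rad
  w <- exp(-offs^2 / (2 * sigmaVox^2))
  K <- matrix(0, n, n)
  for (t in seq_along(offs)) {
    j <- seq_len(n) + offs[t]
    ok <- j >= 1 & j <= n
    K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] + w[t]
  }
  K / rowSums(K)
}

## apply a matrix along one axis of a 3D array
.applyAxis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- K %*% matrix(a, nrow = da[1])
  out <- array(m, da)
  aperm(out, order(perm))
}

#' Separable 3D Gaussian smoothing with per-axis sigma (in voxels)
#' @param arr 3D array.
#' @param sigmaVox numeric length-3 sigma in voxels per axis (z, y, x).
#' @return smoothed array of the same shape.
#' @export
gaussianSmooth3d <- function(arr, sigmaVox) {
  stopifnot(length(dim(arr)) == 3L, length(sigmaVox) == 3L)
  for (ax in 1:3)
    if (sigmaVox[ax] > 0)
      arr <- .applyAxis(arr, .convMatrix(dim(arr)[ax], sigmaVox[ax]), ax)
  arr
}

## discrete Laplacian in physical units (replicate edges)
.laplacian3d <- function(arr, voxelSize) {
  d <- dim(arr)
  out <- array(0, d)
  shift <- function(a, axis, by) {
    idx <- lapply(d, seq_len)
    idx[[axis]] <- pmin(pmax(idx[[axis]] + by, 1L), d[axis])
    a[idx[[1]], idx[[2]], idx[[3]]]
  }
  for (ax in 1:3)
    out <- out + (shift(arr, ax, 1L) + shift(arr, ax, -1L) - 2 * arr) /
                 voxelSize[ax]^2
  out
}

## Otsu threshold on a numeric array (per-z-slice median via EBImage)
.otsuThreshold <- function(arr) {
  mx <- max(arr)
  if (mx <= 0) return(Inf)
  img <- EBImage::Image(aperm(pmax(arr, 0) / mx, c(3, 2, 1)))
  th <- EBImage::otsu(img, range = c(0, 1))
  stats::median(th) * mx
}

## --- neuropil / exclusion masking ------------------------------------------

#' Estimate exclusion and neuropil masks and the neuropil volume
#'
#' Rebuilds the volume denominator of synapse density: the occluder channel
#' (nuclei and vasculature signal) is smoothed, thresholded at half its
#' bright plateau (with a robust noise floor) and closed morphologically
#' into an exclusion mask; the postsynaptic channel,
#' smoothed at tissue scale and thresholded at a low fraction of its bright
#' level, gives the tissue (surface) mask; the neuropil is the tissue mask
#' minus the exclusion mask, and its volume is the voxel count times the
#' voxel volume.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param occluderSigma smoothing sigma (um) for the occluder channel.
#' @param tissueSigma smoothing sigma (um) for the postsynaptic channel.
#' @param tissueFraction tissue threshold as a fraction of the smoothed
#'   postsynaptic channel's 99th percentile.
#' @param closingRadius in-plane morphological closing radius (voxels).
#' @return list with \code{exclusionMask}, \code{neuropilMask} (logical
#'   arrays) and \code{neuropilVolume} (um^3).
#' @export
estimateNeuropil <- function(stack, occluderSigma = 0.15, tissueSigma = 0.4,
                             tissueFraction = 0.15, closingRadius = 2L) {
  stopifnot(is(stack, "ImageStack"))
  vs <- stack@voxelSize
  if (max(stack@post) <= 0)
    stop("postsynaptic channel is all zero; cannot build a neuropil surface")
  exclusion <- array(FALSE, dim(stack@post))
  if (length(stack@occluder)) {
    smOcc <- gaussianSmooth3d(stack@occluder, occluderSigma / vs)
    ## half the bright plateau recovers the occluder surface without radial
    ## bias; the robust floor keeps a signal-free (noise-only) occluder
    ## channel from excluding volume
    th <- max(0.5 * stats::quantile(smOcc, 0.999, names = FALSE),
              stats::median(smOcc) + 10 * stats::mad(smOcc))
    if (is.finite(th)) {
      exclusion <- smOcc > th
      if (closingRadius > 0L && any(exclusion)) {
        brush <- EBImage::makeBrush(2L * closingRadius + 1L, shape = "disc")
        for (z in seq_len(dim(exclusion)[1]))
          exclusion[z, , ] <- EBImage::closing(exclusion[z, , ],
                                               brush) > 0
      }
    }
  }
  smPost <- gaussianSmooth3d(stack@post, tissueSigma / vs)
  th <- tissueFraction * stats::quantile(smPost, 0.99, names = FALSE)
  tissue <- smPost > th
  neuropil <- tissue & !exclusion
  list(exclusionMask = exclusion, neuropilMask = neuropil,
       neuropilVolume = sum(neuropil) * prod(vs))
}

## --- spot detection ---------------------------------------------------------

#' Detect puncta by scale-matched Laplacian-of-Gaussian filtering
#'
#' Smooths the channel with a Gaussian matched to the expected punctum
#' diameter (sigma = diameter / (2 sqrt(3)), the scale at which the 3D LoG
#' response of a blob of that radius peaks), takes the scale-normalized
#' negative Laplacian in physical units, and keeps local maxima (26-voxel
#' neighbourhood) above the detection threshold.  Centroids are refined to
#' sub-voxel precision by an intensity-weighted mean over the 3x3x3
#' response neighbourhood and reported in micrometres; spots outside the
#' neuropil mask are discarded.
#'
#' @param channel 3D array.
#' @param voxelSize voxel size in um, \code{c(z=, y=, x=)}.
#' @param diameter expected punctum diameter in um (pre 0.5, post 0.3).
#' @param threshold detection threshold on the LoG response; \code{NULL}
#'   applies the automatic Otsu surrogate used for calibration images
#'   (per-animal manual thresholds are passed through the pipeline config).
#' @param neuropilMask optional logical array; detections outside it are
#'   dropped.
#' @return A \linkS4class{PunctaSet}.
#' @export
detectSpots <- function(channel, voxelSize, diameter, threshold = NULL,
                        neuropilMask = NULL) {
  if (diameter <= 0) stop("diameter must be positive")
  stopifnot(length(dim(channel)) == 3L)
  vs <- voxelSize[c("z", "y", "x")]
  sigmaUm <- diameter / (2 * sqrt(3))
  sm <- gaussianSmooth3d(channel, sigmaUm / vs)
  resp <- -sigmaUm^2 * .laplacian3d(sm, vs)
  if (is.null(threshold))   # Otsu surrogate with a robust noise floor
    threshold <- max(.otsuThreshold(resp),            # (median + 10 MAD)
                     stats::median(resp) + 10 * stats::mad(resp))
  d <- dim(resp)
  shift <- function(a, dz, dy, dx) {
    iz <- pmin(pmax(seq_len(d[1]) + dz, 1L), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    ix <- pmin(pmax(seq_len(d[3]) + dx, 1L), d[3])
    a[iz, iy, ix]
  }
  isMax <- resp > threshold
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    isMax <- isMax & (resp >= shift(resp, dz, dy, dx))
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx)) {                      # deduplicate plateau maxima
    ord <- order(idx[, 1], idx[, 2], idx[, 3])
    idx <- idx[ord, , drop = FALSE]
    keep <- !logical(nrow(idx))
    if (nrow(idx) > 1L)
      for (i in 2L:nrow(idx))
        if (any(abs(sweep(idx[seq_len(i - 1L), , drop = FALSE], 2,
                          idx[i, ])) <= 1 &
                rowSums(abs(sweep(idx[seq_len(i - 1L), , drop = FALSE], 2,
                                  idx[i, ])) <= 1) == 3 & keep[seq_len(i - 1L)]))
          keep[i] <- FALSE
    idx <- idx[keep, , drop = FALSE]
  }
  cent <- matrix(0, nrow(idx), 3, dimnames = list(NULL, c("z", "y", "x")))
  inten <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    v <- idx[i, ]
    nb <- lapply(1:3, function(ax)
      max(1L, v[ax] - 1L):min(d[ax], v[ax] + 1L))
    w <- pmax(resp[nb[[1]], nb[[2]], nb[[3]]], 0)
    tot <- sum(w)
    ctr <- if (tot > 0) {
      g <- expand.grid(z = nb[[1]], y = nb[[2]], x = nb[[3]])
      colSums(as.matrix(g) * as.vector(w)) / tot
    } else v
    cent[i, ] <- (ctr - 0.5) * vs
    inten[i] <- resp[v[1], v[2], v[3]]
  }
  if (!is.null(neuropilMask) && nrow(idx)) {
    keep <- neuropilMask[idx]
    cent <- cent[keep, , drop = FALSE]
    inten <- inten[keep]
  }
  new("PunctaSet", centroids = cent, diameter = diameter,
      intensities = inten)
}

#' @rdname punctaCentroids
#' @param x a \linkS4class{PunctaSet}.
#' @return \code{punctaCentroids}: the n x 3 centroid matrix in um.
#' @export
setMethod("punctaCentroids", "PunctaSet", function(x) x@centroids)

setMethod("show", "PunctaSet", function(object) {
  cat("PunctaSet:", nrow(object@centroids), "puncta, expected diameter",
      object@diameter, "um\n")
})

## --- juxtaposition pairing and group stats ----------------------------------

#' Pair pre- and postsynaptic puncta into anatomical synapses
#'
#' A presynaptic punctum directly apposed to a postsynaptic punctum —
#' centroid distance at most \code{maxDist} (0.5 um) — counts as one
#' anatomical synapse.  Matching is one-to-one: candidate pairs are
#' accepted greedily in ascending distance order and each punctum is used
#' at most once (a many-to-one mode that counts every pre punctum with any
#' close post partner is available).  Density is the synapse count over the
#' neuropil volume.
#'
#' @param pre,post \linkS4class{PunctaSet}s in the same physical frame.
#' @param maxDist juxtaposition distance in um (default 0.5).
#' @param neuropilVolume neuropil volume in um^3 (> 0).
#' @param mode \code{"one_to_one"} (default) or \code{"many_to_one"}.
#' @param meta list of image/animal metadata copied into the record.
#' @return list with \code{pairs} (data.frame \code{pre}, \code{post},
#'   \code{distance}) and \code{record} (one-row data.frame with
#'   \code{n_pre}, \code{n_post}, \code{n_synapses},
#'   \code{neuropil_volume}, \code{density} and the metadata).
#' @export
pairSynapses <- function(pre, post, maxDist = 0.5, neuropilVolume,
                         mode = c("one_to_one", "many_to_one"),
                         meta = list()) {
  stopifnot(is(pre, "PunctaSet"), is(post, "PunctaSet"))
  mode <- match.arg(mode)
  if (neuropilVolume <= 0) stop("neuropil volume must be positive")
  a <- pre@centroids; b <- post@centroids
  pairs <- data.frame(pre = integer(0), post = integer(0),
                      distance = numeric(0))
  if (nrow(a) && nrow(b)) {
    d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
          outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
    dd <- sqrt(pmax(d2, 0))
    cand <- which(dd <= maxDist, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(dd[cand]), , drop = FALSE]
      if (mode == "one_to_one") {
        usedA <- logical(nrow(a)); usedB <- logical(nrow(b))
        for (i in seq_len(nrow(cand))) {
          pi <- cand[i, 1]; qi <- cand[i, 2]
          if (!usedA[pi] && !usedB[qi]) {
            usedA[pi] <- TRUE; usedB[qi] <- TRUE
            pairs <- rbind(pairs, data.frame(pre = pi, post = qi,
                                             distance = dd[pi, qi]))
          }
        }
      } else {
        firstB <- cand[!duplicated(cand[, 1]), , drop = FALSE]
        pairs <- data.frame(pre = firstB[, 1], post = firstB[, 2],
                            distance = dd[firstB])
      }
    }
  }
  rec <- data.frame(n_pre = nrow(a), n_post = nrow(b),
                    n_synapses = nrow(pairs),
                    neuropil_volume = neuropilVolume,
                    density = nrow(pairs) / neuropilVolume)
  for (nm in names(meta)) rec[[nm]] <- meta[[nm]]
  list(pairs = pairs, record = rec)
}

#' Compare synapse density (or any per-image metric) between groups
#'
#' Two-sided two-sample t-test with Welch's correction applied when a
#' Levene pre-test (alpha 0.05) rejects equal variances.  The descriptive
#' table carries per-group quartiles and per-record outlier flags; the
#' default convention marks every point outside [Q1, Q3] of its group (a
#' Tukey 1.5 IQR alternative is available).
#'
#' @param records data.frame of per-image records (e.g. stacked
#'   \code{pairSynapses} records) with a \code{group} column.
#' @param metric name of the numeric column to compare (default
#'   \code{"density"}).
#' @param outlierRule \code{"quartile"} (flag outside [Q1, Q3]) or
#'   \code{"tukey"} (outside Q1 - 1.5 IQR, Q3 + 1.5 IQR).
#' @return list with \code{t}, \code{df}, \code{p_value}, \code{welch}
#'   (logical), \code{levene_p}, \code{descriptives} (per-group summary)
#'   and \code{outliers} (logical flag per record).
#' @export
compareGroups <- function(records, metric = "density",
                          outlierRule = c("quartile", "tukey")) {
  outlierRule <- match.arg(outlierRule)
  stopifnot(metric %in% colnames(records), "group" %in% colnames(records))
  y <- records[[metric]]
  g <- factor(records$group)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) < 2L)) stop("each group needs at least 2 records")
  lev <- suppressWarnings(car::leveneTest(y ~ g))  # pre-test only switches
                                                   # the t-test variant
  levP <- lev[1, "Pr(>F)"]
  welch <- is.finite(levP) && levP < 0.05
  ## degenerate-safe two-sample t (identical to t.test away from zero
  ## variance)
  tt <- .tTwoSample(y[g == levels(g)[1]], y[g == levels(g)[2]],
                    welch = welch)
  q <- tapply(y, g, stats::quantile, probs = c(0.25, 0.5, 0.75))
  desc <- do.call(rbind, lapply(levels(g), function(lv) {
    yy <- y[g == lv]
    data.frame(group = lv, n = length(yy), mean = mean(yy),
               sd = stats::sd(yy), q1 = q[[lv]][1], median = q[[lv]][2],
               q3 = q[[lv]][3], stringsAsFactors = FALSE)
  }))
  out <- vapply(seq_along(y), function(i) {
    qq <- q[[as.character(g[i])]]
    if (outlierRule == "quartile") y[i] < qq[1] || y[i] > qq[3]
    else {
      iqr <- qq[3] - qq[1]
      y[i] < qq[1] - 1.5 * iqr || y[i] > qq[3] + 1.5 * iqr
    }
  }, logical(1))
  list(t = tt$t, df = tt$df, p_value = tt$p, welch = welch,
       levene_p = levP, descriptives = desc, outliers = out)
}
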