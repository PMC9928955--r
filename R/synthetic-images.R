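## physical coordinates (um) of voxel centers along one axis
.axisCoords <- function(nVox, vox) (seq_len(nVox) - 0.5) * vox

## voxel mask of all occluders (nucleus spheres, x-aligned vessel tubes)
.occluderMask <- function(shape, voxelSize, nuclei, vessels) {
  cz <- .axisCoords(shape[1], voxelSize["z"])
  cy <- .axisCoords(shape[2], voxelSize["y"])
  cx <- .axisCoords(shape[3], voxelSize["x"])
  mask <- array(FALSE, shape)
  for (nu in nuclei) {
    dz2 <- (cz - nu$center[1])^2
    dy2 <- (cy - nu$center[2])^2
    dx2 <- (cx - nu$center[3])^2
    mask <- mask | (outer(outer(dz2, dy2, `+`), dx2, `+`) <= nu$radius^2)
  }
  for (ve in vessels) {           # tube along x at (z0, y0)
    dz2 <- (cz - ve$center[1])^2
    dy2 <- (cy - ve$center[2])^2
    inTube <- outer(dz2, dy2, `+`) <= ve$radius^2
    mask <- mask | outer(inTube, rep(TRUE, shape[3]), `&`)
  }
  mask
}

.insideOccluder <- function(pt, nuclei, vessels, pad = 0) {
  for (nu in nuclei)
    if (sqrt(sum((pt - nu$center)^2)) <= nu$radius + pad) return(TRUE)
  for (ve in vessels)
    if (sqrt(sum((pt[1:2] - ve$center)^2)) <= ve$radius + pad) return(TRUE)
  FALSE
}

#' Simulate ground-truth puncta geometry for a 3D stack
#'
#' Places presynaptic and postsynaptic punctum centroids inside the stack
#' (in micrometres), with \code{nPairs} of them forming true synapses:
#' pre/post pairs at separations drawn from \code{pairDistRange} (at most
#' the 0.5 um juxtaposition criterion).  Unpaired puncta are kept at least
#' 0.7 um away from every punctum of the opposite channel so they can never
#' be paired; same-channel puncta keep a minimum separation so detection
#' can resolve them.  Optional nucleus spheres and x-aligned vessel tubes
#' occlude volume; no centroid falls inside an occluder.
#'
#' @param nPairs number of true pre/post synapse pairs.
#' @param nUnpairedPre,nUnpairedPost isolated puncta per channel.
#' @param stackShape voxel counts \code{c(z=, y=, x=)}.
#' @param voxelSize voxel size in um, \code{c(z=, y=, x=)} (anisotropic
#'   allowed; all geometry is in physical units).
#' @param nNuclei,nucleusRadius number and radius (um) of nucleus spheres.
#' @param nVessels,vesselRadius number and radius (um) of vessel tubes.
#' @param pairDistRange range of true pair separations (um, max <= 0.5).
#' @param minSep minimum same-channel centroid separation (um).
#' @param seed integer seed.
#' @return list with \code{preCentroids}, \code{postCentroids} (n x 3
#'   matrices, um, columns z,y,x), \code{pairedIndices} (two-column matrix),
#'   \code{nuclei}, \code{vessels}, \code{stackShape}, \code{voxelSize},
#'   \code{occluderVolume} and \code{neuropilVolume} (um^3; stack volume
#'   minus occluded volume).
#' @export
simulateImageGroundTruth <- function(nPairs = 200L, nUnpairedPre = 20L,
                                     nUnpairedPost = 20L,
                                     stackShape = c(z = 40L, y = 160L,
                                                    x = 160L),
                                     voxelSize = c(z = 0.1, y = 0.05,
                                                   x = 0.05),
                                     nNuclei = 0L, nucleusRadius = 1.2,
                                     nVessels = 0L, vesselRadius = 0.8,
                                     pairDistRange = c(0.1, 0.4),
                                     minSep = 0.6, seed = 1L) {
  stopifnot(all(voxelSize > 0), max(pairDistRange) <= 0.5)
  extent <- stackShape * voxelSize[c("z", "y", "x")]
  margin <- 0.5
  if (any(extent <= 2 * margin)) stop("stack too small for the margin")
  if (nNuclei > 0L && any(extent <= 2 * (margin + nucleusRadius)))
    stop("nucleus occluders do not fit inside the stack")
  if (nVessels > 0L && any(extent[1:2] <= 2 * (margin + vesselRadius)))
    stop("vessel occluders do not fit inside the stack")
  .withSeed(seed, {
    nuclei <- lapply(seq_len(nNuclei), function(i)
      list(center = stats::runif(3, margin + nucleusRadius,
                                 extent - margin - nucleusRadius),
           radius = nucleusRadius))
    vessels <- lapply(seq_len(nVessels), function(i)
      list(center = stats::runif(2, margin + vesselRadius,
                                 extent[1:2] - margin - vesselRadius),
           radius = vesselRadius))
    drawPoint <- function(existing, minDist, avoid = NULL, avoidDist = 0) {
      for (try in 1:5000) {
        pt <- stats::runif(3, margin, extent - margin)
        if (.insideOccluder(pt, nuclei, vessels, pad = 0.2)) next
        ok <- TRUE
        if (length(existing) && minDist > 0) {
          dd <- sqrt(colSums((t(do.call(rbind, existing)) - pt)^2))
          if (any(dd < minDist)) ok <- FALSE
        }
        if (ok && length(avoid) && avoidDist > 0) {
          dd <- sqrt(colSums((t(do.call(rbind, avoid)) - pt)^2))
          if (any(dd < avoidDist)) ok <- FALSE
        }
        if (ok) return(pt)
      }
      stop("could not place a punctum; stack too crowded")
    }
    pre <- list(); post <- list()
    for (i in seq_len(nPairs)) {
      placed <- FALSE
      for (attempt in 1:200) {   # redraw the pre point if no partner fits
        p <- drawPoint(pre, minSep)
        q <- NULL
        for (try in 1:200) {
          dir <- stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          qq <- p + dir * stats::runif(1, pairDistRange[1],
                                       pairDistRange[2])
          if (all(qq > margin) && all(qq < extent - margin) &&
              !.insideOccluder(qq, nuclei, vessels, pad = 0.2) &&
              (!length(post) ||
               all(sqrt(colSums((t(do.call(rbind, post)) - qq)^2)) >=
                   minSep))) {
            q <- qq
            break
          }
        }
        if (!is.null(q)) {
          pre[[length(pre) + 1L]] <- p
          post[[length(post) + 1L]] <- q
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place a punctum pair; stack too crowded")
    }
    pairedIndices <- cbind(pre = seq_len(nPairs), post = seq_len(nPairs))
    for (i in seq_len(nUnpairedPre))
      pre[[length(pre) + 1L]] <- drawPoint(pre, minSep, avoid = post,
                                           avoidDist = minSep)
    for (i in seq_len(nUnpairedPost))
      post[[length(post) + 1L]] <- drawPoint(post, minSep, avoid = pre,
                                             avoidDist = minSep)
    toMat <- function(l) {
      m <- if (length(l)) do.call(rbind, l) else matrix(0, 0, 3)
      colnames(m) <- c("z", "y", "x")
      m
    }
    occ <- .occluderMask(stackShape, voxelSize, nuclei, vessels)
    voxVol <- prod(voxelSize)
    list(preCentroids = toMat(pre), postCentroids = toMat(post),
         pairedIndices = pairedIndices, nuclei = nuclei, vessels = vessels,
         stackShape = stackShape, voxelSize = voxelSize,
         occluderVolume = sum(occ) * voxVol,
         neuropilVolume = (length(occ) - sum(occ)) * voxVol)
  })
}

## add isotropic 3D Gaussian blobs (physical sigma, um) at centroids
.renderGaussians <- function(arr, voxelSize, centroids, sigmaUm,
                             amplitude = 1) {
  if (!nrow(centroids)) return(arr)
  shape <- dim(arr)
  coords <- list(.axisCoords(shape[1], voxelSize["z"]),
                 .axisCoords(shape[2], voxelSize["y"]),
                 .axisCoords(shape[3], voxelSize["x"]))
  halo <- 4 * sigmaUm
  for (i in seq_len(nrow(centroids))) {
    ct <- centroids[i, ]
    rng <- lapply(1:3, function(ax)
      which(abs(coords[[ax]] - ct[ax]) <= halo))
    if (any(lengths(rng) == 0L)) next
    gz <- exp(-(coords[[1]][rng[[1]]] - ct[1])^2 / (2 * sigmaUm^2))
    gy <- exp(-(coords[[2]][rng[[2]]] - ct[2])^2 / (2 * sigmaUm^2))
    gx <- exp(-(coords[[3]][rng[[3]]] - ct[3])^2 / (2 * sigmaUm^2))
    arr[rng[[1]], rng[[2]], rng[[3]]] <-
      arr[rng[[1]], rng[[2]], rng[[3]]] +
      amplitude * outer(outer(gz, gy), gx)
  }
  arr
}

#' Render a synthetic two-channel 3D image stack
#'
#' Renders the ground-truth puncta as isotropic 3D Gaussian blobs whose
#' full width at half maximum approximates the marker diameter (pre 0.5 um,
#' post 0.3 um), adds a diffuse tissue background to both channels (zeroed
#' inside occluders, which carry their own channel), and corrupts every
#' channel with Poisson noise whose photon budget scales with \code{snr}.
#'
#' @param truth as returned by \code{\link{simulateImageGroundTruth}}.
#' @param snr positive photon-budget scale: voxel values are
#'   \code{rpois(snr * clean) / snr}, so large snr approaches the clean
#'   image.
#' @param preDiameter,postDiameter rendered punctum FWHM in um.
#' @param background diffuse tissue background level (fraction of punctum
#'   amplitude) added to the pre and post channels outside occluders.
#' @param meta acquisition metadata list (animal id, layer, marker pair,
#'   group, sex).
#' @param seed integer seed for the noise.
#' @return an \linkS4class{ImageStack}; the ground truth is attached as
#'   \code{meta$ground_truth}.
#' @export
simulateImageStack <- function(truth, snr = 50,
                               preDiameter = 0.5, postDiameter = 0.3,
                               background = 0.1,
                               meta = list(animal_id = "A1", layer = "L2/3",
                                           marker_pair = "VGluT1/PSD95",
                                           group = "PME", sex = "M"),
                               seed = 1L) {
  if (snr <= 0) stop("snr must be positive")
  shape <- unname(truth$stackShape)
  vs <- truth$voxelSize
  occ <- .occluderMask(shape, vs, truth$nuclei, truth$vessels)
  fwhm2sigma <- 1 / (2 * sqrt(2 * log(2)))
  pre <- .renderGaussians(array(0, shape), vs, truth$preCentroids,
                          preDiameter * fwhm2sigma)
  post <- .renderGaussians(array(0, shape), vs, truth$postCentroids,
                           postDiameter * fwhm2sigma)
  tissue <- background * !occ
  pre <- (pre + tissue) * !occ
  post <- (post + tissue) * !occ
  occCh <- 0.8 * occ
  .withSeed(seed, {
    noisy <- function(cl)
      array(stats::rpois(length(cl), snr * (cl + 0.005)) / snr, dim(cl))
    meta$ground_truth <- truth[c("pairedIndices", "occluderVolume",
                                 "neuropilVolume")]
    new("ImageStack", pre = noisy(pre), post = noisy(post),
        occluder = noisy(occCh),
        voxelSize = vs[c("z", "y", "x")], meta = meta)
  })
}
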