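# Puncta detection: multi-scale Laplacian-of-Gaussian blob detection on the
# sum of the detection channels, local thresholding around each blob seed,
# and nearest-seed splitting of merged blobs (the watershed-style step).

#' Detection parameters
#'
#' @param minDiameter,maxDiameter accepted punctum equivalent-diameter range
#'   (um). The lesion module widens `maxDiameter` because PANTHOS pa-ALs can
#'   exceed the normal vesicle scale.
#' @param logThreshold minimum scale-normalized LoG response of a seed
#'   (intensity units; full scale ~1).
#' @param maskFraction fraction of the local peak-over-background at which
#'   the punctum mask is cut (0.5 = full width at half maximum).
#' @param detectionChannels channels summed for detection; `NULL` means all
#'   of mRFP, eGFP and CTSD that are present.
#' @return list of parameters for [detectPuncta()].
#' @export
detectionParams <- function(minDiameter = 0.2, maxDiameter = 3.0,
                            logThreshold = 0.04, maskFraction = 0.5,
                            detectionChannels = NULL) {
  list(minDiameter = minDiameter, maxDiameter = maxDiameter,
       logThreshold = logThreshold, maskFraction = maskFraction,
       detectionChannels = detectionChannels)
}

# geometric radius grid (um) covering the accepted diameter range
logScaleRadii <- function(minD, maxD) {
  lo <- max(0.25, minD / 2 * 1.2)
  hi <- max(lo, maxD / 2 * 0.85)
  r <- lo
  out <- c()
  while (r <= hi * 1.001) { out <- c(out, r); r <- r * 1.45 }
  out
}

#' Detect vesicular puncta
#'
#' @param x a [ChannelStack].
#' @param params from [detectionParams()].
#' @return a list with `puncta` (data.frame: id, x, y 0-based pixel centroid,
#'   area_px, area_um2, radius_um) and `labels` (integer matrix assigning
#'   each claimed pixel to a punctum id; 0 = background).
#' @export
detectPuncta <- function(x, params = detectionParams()) {
  px <- pixelSize(x)
  if (!is.finite(px) || px <= 0) stop("pixel size must be known and positive")
  chn <- params$detectionChannels %||%
    intersect(c("mRFP", "eGFP", "CTSD"), channelNames(x))
  chn <- intersect(chn, channelNames(x))
  if (!length(chn)) stop("no detection channels present in image")
  sumImg <- Reduce(`+`, lapply(chn, function(ch) getChannel(x, ch)))
  ny <- nrow(sumImg); nx <- ncol(sumImg)
  empty <- list(puncta = data.frame(id = integer(), x = numeric(),
                                    y = numeric(), area_px = integer(),
                                    area_um2 = numeric(),
                                    radius_um = numeric()),
                labels = matrix(0L, ny, nx))
  if (all(sumImg == sumImg[1])) return(empty)

  radii <- logScaleRadii(params$minDiameter, params$maxDiameter)
  cand <- NULL
  # incremental scale-space: blur by the sigma increment at each step
  sm0 <- sumImg
  sig0 <- 0
  for (r in radii) {
    sig <- max(0.8, r / sqrt(2) / px)
    sm0 <- gaussBlur(sm0, sqrt(max(sig^2 - sig0^2, 0)))
    sig0 <- sig
    resp <- -sig^2 * cpp_laplace(sm0)
    m <- cpp_local_max(resp, params$logThreshold)
    if (nrow(m)) {
      cand <- rbind(cand, cbind(m, r))
    }
  }
  if (is.null(cand) || nrow(cand) == 0) return(empty)
  colnames(cand) <- c("y", "x", "resp", "r")
  # non-maximum suppression across scales: strongest response wins within
  # 0.9 * max radius; deterministic tie-break by (y, x)
  ord <- order(-cand[, "resp"], cand[, "y"], cand[, "x"])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  ky <- kx <- kr <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(ky)) {
      d <- sqrt((ky - cand[i, "y"])^2 + (kx - cand[i, "x"])^2)
      if (any(d < 1.2 * pmax(kr, cand[i, "r"]) / px)) next
    }
    keep[i] <- TRUE
    ky <- c(ky, cand[i, "y"]); kx <- c(kx, cand[i, "x"])
    kr <- c(kr, cand[i, "r"])
  }
  cand <- cand[keep, , drop = FALSE]
  # deterministic processing order by (y, x)
  cand <- cand[order(cand[, "y"], cand[, "x"]), , drop = FALSE]

  sm <- gaussBlur(sumImg, 1)
  labels <- matrix(0L, ny, nx)
  # squared distance (px^2) from each claimed pixel to its seed, for
  # nearest-seed resolution of contested pixels
  claimD2 <- matrix(Inf, ny, nx)
  info <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cy <- cand[i, "y"]; cx <- cand[i, "x"]; r <- cand[i, "r"] / px
    d <- pixelDisk(ny, nx, cy, cx, max(3, 1.6 * r))
    win <- sm[d$ys, d$xs]
    ring <- d$d2 > (1.3 * r)^2
    bg <- if (any(ring)) stats::median(win[ring]) else min(win)
    peak <- sm[cy, cx]
    thr <- bg + params$maskFraction * (peak - bg)
    sel <- d$inside & win >= thr & d$d2 <= (1.5 * r)^2
    if (!any(sel)) next
    ys <- matrix(d$ys, length(d$ys), length(d$xs))[sel]
    xs <- matrix(d$xs, length(d$ys), length(d$xs), byrow = TRUE)[sel]
    d2 <- d$d2[sel]
    idx <- cbind(ys, xs)
    take <- d2 < claimD2[idx]
    labels[idx[take, , drop = FALSE]] <- i
    claimD2[idx[take, , drop = FALSE]] <- d2[take]
    info[[i]] <- TRUE
  }
  # collect puncta (centroids from the claimed pixels only)
  nz <- which(labels > 0L)
  lab <- labels[nz]
  npx <- tabulate(lab, nbins = nrow(cand))
  rows <- ((nz - 1L) %% ny) + 1L
  cols <- ((nz - 1L) %/% ny) + 1L
  keepId <- which(npx > 0)
  sumY <- rowsum(as.numeric(rows), lab)
  sumX <- rowsum(as.numeric(cols), lab)
  out <- data.frame(id = keepId,
                    y = sumY[, 1] / npx[keepId] - 1,
                    x = sumX[, 1] / npx[keepId] - 1,
                    area_px = npx[keepId])
  out$area_um2 <- out$area_px * px^2
  out$radius_um <- sqrt(out$area_um2 / pi)
  dia <- 2 * out$radius_um
  drop <- dia < params$minDiameter | dia > params$maxDiameter
  if (any(drop)) {
    labels[labels %in% out$id[drop]] <- 0L
    out <- out[!drop, , drop = FALSE]
  }
  out$id <- seq_len(nrow(out))
  # relabel consecutively
  if (nrow(out)) {
    map <- integer(nrow(cand))
    map[keepId[!drop]] <- out$id
    labels[labels > 0] <- map[labels[labels > 0]]
  } else {
    labels[] <- 0L
  }
  rownames(out) <- NULL
  list(puncta = out, labels = labels)
}

#' Measure background-subtracted per-channel punctum intensities
#'
#' The mean over the punctum mask minus a local background estimate (median
#' of an annulus around the punctum, excluding pixels claimed by any
#' punctum), clamped at zero.
#'
#' @param x a [ChannelStack].
#' @param detection the result of [detectPuncta()].
#' @return data.frame with one row per punctum and one background-subtracted
#'   mean-intensity column per channel.
#' @export
measureIntensities <- function(x, detection) {
  p <- detection$puncta
  labels <- detection$labels
  px <- pixelSize(x)
  chn <- channelNames(x)
  ny <- nrow(labels); nx <- ncol(labels)
  chData <- lapply(chn, function(ch) getChannel(x, ch))
  out <- matrix(0, nrow(p), length(chn),
                dimnames = list(NULL, chn))
  for (i in seq_len(nrow(p))) {
    id <- p$id[i]
    cy <- p$y[i] + 1; cx <- p$x[i] + 1
    rpx <- p$radius_um[i] / px
    d <- pixelDisk(ny, nx, cy, cx, rpx + 6)
    sub <- labels[d$ys, d$xs]
    inMask <- sub == id
    if (!any(inMask)) stop("empty mask for punctum ", id)
    ann <- d$d2 >= (rpx + 2)^2 & sub == 0L
    for (k in seq_along(chn)) {
      w <- chData[[k]][d$ys, d$xs]
      bg <- if (any(ann)) stats::median(w[ann]) else 0
      out[i, k] <- max(0, mean(w[inMask]) - bg)
    }
  }
  cbind(p, as.data.frame(out))
}

#' Assign puncta to neurons via a label image
#'
#' @param puncta punctum data.frame (needs 0-based `x`, `y` centroids).
#' @param labelImage integer matrix of neuron labels (0 = background).
#' @return `puncta` with a `neuron_id` column (`NA` for label 0).
#' @export
assignToNeurons <- function(puncta, labelImage) {
  if (nrow(puncta) == 0) {
    puncta$neuron_id <- integer(0)
    return(puncta)
  }
  ny <- nrow(labelImage); nx <- ncol(labelImage)
  ri <- pmin(ny, pmax(1, round(puncta$y) + 1))
  ci <- pmin(nx, pmax(1, round(puncta$x) + 1))
  lab <- labelImage[cbind(ri, ci)]
  puncta$neuron_id <- ifelse(lab == 0L, NA_integer_, lab)
  puncta
}
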