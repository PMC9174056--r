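# PANTHOS lesion detection, staging and lesion-level statistics: rosettes of
# AV-filled membrane blebs around an LC3-free nuclear remnant, their DAPI
# status, amyloid-plaque correspondence and marker co-occurrence.

#' PANTHOS detection parameters
#'
#' @param lc3SmoothUm Gaussian smoothing of the LC3 channel before
#'   thresholding (um).
#' @param threshFraction LC3 threshold as a fraction of the robust dynamic
#'   range (99.9th percentile over background) above background.
#' @param minAreaUm2 minimum candidate area. Operational definition - a
#'   candidate must be at least most-of-a-soma in size; the burden criterion
#'   does the specificity work.
#' @param burden minimum number of pa-AL calls inside the candidate mask.
#' @param closeUm morphological closing radius (um).
#' @param coreRadiusUm radius of the central core probed for the LC3-free
#'   nuclear remnant (um).
#' @param minBlebsStage3 bleb count at or above which (with a dark core) a
#'   lesion is called full-pattern stage iii.
#' @return parameter list for [detectPanthos()].
#' @export
panthosParams <- function(lc3SmoothUm = 1.0, threshFraction = 0.15,
                          minAreaUm2 = 250, burden = 20, closeUm = 1.0,
                          coreRadiusUm = 4.5, minBlebsStage3 = 6) {
  list(lc3SmoothUm = lc3SmoothUm, threshFraction = threshFraction,
       minAreaUm2 = minAreaUm2, burden = burden, closeUm = closeUm,
       coreRadiusUm = coreRadiusUm, minBlebsStage3 = minBlebsStage3)
}

# Count angular lobes (blebs) of a lesion mask from the radial-extent
# profile of its boundary around the centroid: blebs protrude radially
# beyond the perikaryal baseline, so they appear as circular runs of
# 5-degree bins whose outer mask radius exceeds the baseline (the 15th
# percentile of the profile) by a protrusion margin. A stage-i lesion is a
# disk - its boundary is circular and yields no runs.
countBlebs <- function(lc3, mask, cy, cx, px, protrusionUm = 2.2) {
  idx <- which(mask)
  ys <- ((idx - 1L) %% nrow(mask)) + 1L
  xs <- ((idx - 1L) %/% nrow(mask)) + 1L
  dy <- ys - cy; dx <- xs - cx
  r <- sqrt(dy^2 + dx^2)
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  nb <- 72L                               # 5-degree bins
  bins <- floor(ang / (360 / nb)) + 1
  rq <- vapply(seq_len(nb), function(b) {
    v <- r[bins == b]
    if (length(v)) stats::quantile(v, 0.98, names = FALSE) else 0
  }, 0)
  base <- stats::quantile(rq, 0.15, names = FALSE)
  hot <- rq > base + protrusionUm / px
  if (!any(hot)) return(0L)
  if (all(hot)) return(1L)
  # count circular runs of >= 2 consecutive hot bins
  rot <- which(!hot)[1]                  # start counting at a cold bin
  hotR <- hot[((seq_len(nb) + rot - 2L) %% nb) + 1L]
  runs <- rle(hotR)
  sum(runs$values & runs$lengths >= 2)
}

#' Detect and stage PANTHOS lesions
#'
#' A candidate lesion is a connected region of high tfLC3 (mRFP) signal,
#' morphologically closed and hole-filled, whose area exceeds a soma-scale
#' threshold and which carries at least `burden` pa-AL calls. Staging is by
#' morphology: angular lobe (bleb) counting around the centroid plus the
#' central-core LC3 level; a full rosette (>= `minBlebsStage3` blebs and an
#' LC3-free core) is stage iii, focal bulging (>= 1 bleb) stage ii,
#' otherwise stage i. Deterministic for fixed input and parameters.
#'
#' @param x a [ChannelStack] with the tfLC3 channels.
#' @param calls classified punctum table for the same field
#'   ([classifyField()] output); used for the pa-AL burden criterion.
#' @param params from [panthosParams()].
#' @return list with `lesions` (data.frame: lesion_id, x, y centroid (0-based
#'   px), area_um2, n_blebs, core_frac, n_paAL, stage) and `labels` (integer
#'   lesion mask image).
#' @export
detectPanthos <- function(x, calls, params = panthosParams()) {
  chn <- channelNames(x)
  if (!("mRFP" %in% chn)) stop("LC3 (mRFP) channel missing")
  px <- pixelSize(x)
  lc3 <- getChannel(x, "mRFP")
  sm <- gaussBlur(lc3, params$lc3SmoothUm / px)
  bg <- stats::median(sm)
  hi <- stats::quantile(sm, 0.999, names = FALSE)
  thr <- bg + params$threshFraction * max(hi - bg, 1e-6)
  mask <- sm > thr
  mask <- binaryClose(mask, round(params$closeUm / px))
  mask <- fillHoles(mask)
  lab <- cpp_label4(mask)
  ny <- nrow(lab); nx <- ncol(lab)
  nlab <- max(lab)
  outLab <- matrix(0L, ny, nx)
  rows <- NULL
  nextId <- 0L
  if (nlab > 0) {
    areas <- tabulate(lab[lab > 0], nbins = nlab) * px^2
    for (l in which(areas >= params$minAreaUm2)) {
      idx <- which(lab == l)
      ys <- ((idx - 1L) %% ny) + 1L
      xs <- ((idx - 1L) %/% ny) + 1L
      cy <- mean(ys); cx <- mean(xs)
      inMask <- rep(FALSE, nrow(calls))
      if (nrow(calls)) {
        ri <- pmin(ny, pmax(1, round(calls$y) + 1))
        ci <- pmin(nx, pmax(1, round(calls$x) + 1))
        inMask <- lab[cbind(ri, ci)] == l
      }
      nPa <- sum(inMask & calls$klass == "paAL")
      if (nPa < params$burden) next
      nextId <- nextId + 1L
      outLab[idx] <- nextId
      m <- lab == l
      nb <- countBlebs(sm, m, cy, cx, px)
      core <- pixelDisk(ny, nx, cy, cx, params$coreRadiusUm / px)
      coreVals <- sm[core$ys, core$xs][core$inside]
      lesionMean <- mean(sm[idx]) - bg
      coreFrac <- if (lesionMean > 0) (mean(coreVals) - bg) / lesionMean else 1
      stage <- if (nb >= params$minBlebsStage3 && coreFrac < 0.5) "iii"
               else if (nb >= 1) "ii" else "i"
      rows <- rbind(rows, data.frame(
        lesion_id = nextId, y = cy - 1, x = cx - 1,
        area_um2 = areas[l], n_blebs = nb, core_frac = coreFrac,
        n_paAL = nPa, stage = stage, stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(lesion_id = integer(), y = numeric(), x = numeric(),
                       area_um2 = numeric(), n_blebs = integer(),
                       core_frac = numeric(), n_paAL = integer(),
                       stage = character(), stringsAsFactors = FALSE)
  }
  list(lesions = rows, labels = outLab)
}

#' DAPI status of a PANTHOS lesion core
#'
#' DAPI-positive pixels inside the core disk (centroid +/- 1.5x the expected
#' nucleus radius) are those above background + kMAD * MAD. No positive
#' area (below `minAreaUm2`) is "absent"; a positive area below half the
#' expected nucleus area is "condensed"; otherwise "normal".
#'
#' @param lesion one row of the [detectPanthos()] lesion table.
#' @param x the [ChannelStack] (needs a DAPI channel).
#' @param nucleusRadiusUm expected nucleus radius (um).
#' @param kMAD positivity threshold multiplier.
#' @param minAreaUm2 minimum DAPI-positive area to count as detectable.
#' @return `"normal"`, `"condensed"` or `"absent"`.
#' @export
dapiStatus <- function(lesion, x, nucleusRadiusUm = 4, kMAD = 3,
                       minAreaUm2 = 1) {
  if (!("DAPI" %in% channelNames(x))) stop("DAPI channel missing")
  px <- pixelSize(x)
  ch <- getChannel(x, "DAPI")
  bgs <- robustBgStats(ch)
  d <- pixelDisk(nrow(ch), ncol(ch), lesion$y + 1, lesion$x + 1,
                 1.5 * nucleusRadiusUm / px)
  vals <- ch[d$ys, d$xs][d$inside]
  posArea <- sum(vals > bgs$median + kMAD * max(bgs$mad, 1e-6)) * px^2
  nucArea <- pi * nucleusRadiusUm^2
  if (posArea < minAreaUm2) "absent"
  else if (posArea < 0.5 * nucArea) "condensed"
  else "normal"
}

# background-subtracted positive signal of a channel (suppresses noise by
# requiring pixels above background + kMAD * MAD)
positiveSignal <- function(ch, kMAD = 3) {
  bgs <- robustBgStats(ch)
  thr <- bgs$median + kMAD * max(bgs$mad, 1e-6)
  out <- ch - bgs$median
  out[ch <= thr] <- 0
  out
}

#' Fraction of total amyloid signal inside PANTHOS lesions
#'
#' Integrated background-subtracted amyloid intensity within the union of
#' lesion masks, divided by the field total.
#'
#' @param x a [ChannelStack] with the amyloid channel.
#' @param panthos a [detectPanthos()] result (its `labels` give the masks),
#'   or an integer/logical lesion mask matrix.
#' @param channel amyloid channel name.
#' @param dilateUm lesion masks are dilated by this much before the overlap
#'   (tolerates boundary blur).
#' @return fraction in `[0, 1]`, or `NA` (flagged by a warning) when the
#'   field has no amyloid signal.
#' @export
amyloidSignalFraction <- function(x, panthos, channel = "Abeta",
                                  dilateUm = 1) {
  px <- pixelSize(x)
  masks <- if (is.list(panthos)) panthos$labels else panthos
  union <- masks > 0
  if (dilateUm > 0 && any(union)) {
    union <- cpp_dilate(union, as.integer(round(dilateUm / px)))
  }
  sig <- positiveSignal(getChannel(x, channel))
  tot <- sum(sig)
  if (tot <= 0) {
    warning("no amyloid signal in field; fraction undefined")
    return(NA_real_)
  }
  sum(sig[union]) / tot
}

#' Segment amyloid plaques
#'
#' Otsu threshold on the smoothed amyloid channel, hole filling and a
#' minimum-area filter.
#'
#' @param x a [ChannelStack].
#' @param channel amyloid channel name.
#' @param smoothUm Gaussian smoothing before thresholding (um).
#' @param minAreaUm2 minimum plaque area.
#' @return list with `plaques` (data.frame id, x, y, area_um2) and `labels`.
#' @export
segmentPlaques <- function(x, channel = "Abeta", smoothUm = 0.5,
                           minAreaUm2 = 20) {
  px <- pixelSize(x)
  sm <- gaussBlur(getChannel(x, channel), smoothUm / px)
  thr <- otsuThreshold(sm)
  bgs <- robustBgStats(sm)
  # Otsu needs a genuinely bimodal image; guard pure-noise fields
  thr <- max(thr, bgs$median + 6 * max(bgs$mad, 1e-6))
  mask <- fillHoles(sm > thr)
  lab <- cpp_label4(mask)
  ny <- nrow(lab)
  nlab <- max(lab)
  out <- NULL
  relab <- matrix(0L, ny, ncol(lab))
  nid <- 0L
  if (nlab > 0) {
    areas <- tabulate(lab[lab > 0], nbins = nlab) * px^2
    for (l in which(areas >= minAreaUm2)) {
      idx <- which(lab == l)
      nid <- nid + 1L
      relab[idx] <- nid
      out <- rbind(out, data.frame(
        id = nid, y = mean(((idx - 1L) %% ny) + 1L) - 1,
        x = mean(((idx - 1L) %/% ny) + 1L) - 1, area_um2 = areas[l]))
    }
  }
  if (is.null(out)) out <- data.frame(id = integer(), y = numeric(),
                                      x = numeric(), area_um2 = numeric())
  list(plaques = out, labels = relab)
}

#' Lesion-plaque correspondence
#'
#' A plaque "contains" a PANTHOS lesion (and vice versa) when their mask
#' overlap covers at least `minOverlap` of the smaller mask.
#'
#' @param panthos a [detectPanthos()] result.
#' @param plaques a [segmentPlaques()] result.
#' @param minOverlap overlap fraction of the smaller mask.
#' @return list with `fracPanthosAmyloidPos`, `fracPlaquesWithPanthos`, and
#'   the underlying counts.
#' @export
lesionPlaqueCorrespondence <- function(panthos, plaques, minOverlap = 0.5) {
  pl <- panthos$labels; ql <- plaques$labels
  nP <- max(pl); nQ <- max(ql)
  if (nP == 0 && nQ == 0) {
    return(list(fracPanthosAmyloidPos = NA_real_,
                fracPlaquesWithPanthos = NA_real_,
                nPanthos = 0L, nPlaques = 0L, nMatched = 0L))
  }
  areaP <- tabulate(pl[pl > 0], nbins = max(nP, 1))
  areaQ <- tabulate(ql[ql > 0], nbins = max(nQ, 1))
  both <- pl > 0 & ql > 0
  panMatched <- rep(FALSE, nP); plaMatched <- rep(FALSE, nQ)
  if (any(both)) {
    ov <- table(pl[both], ql[both])
    for (i in rownames(ov)) for (j in colnames(ov)) {
      o <- ov[i, j]
      if (o == 0) next
      ii <- as.integer(i); jj <- as.integer(j)
      if (o >= minOverlap * min(areaP[ii], areaQ[jj])) {
        panMatched[ii] <- TRUE
        plaMatched[jj] <- TRUE
      }
    }
  }
  list(fracPanthosAmyloidPos = if (nP > 0) mean(panMatched) else NA_real_,
       fracPlaquesWithPanthos = if (nQ > 0) mean(plaMatched) else NA_real_,
       nPanthos = nP, nPlaques = nQ, nMatched = sum(panMatched))
}

#' Marker co-occurrence within lesion confines
#'
#' A lesion is marker-positive when the marker-positive pixel area inside
#' its mask reaches `minAreaUm2` ("within the confines" operationalized).
#'
#' @param x a [ChannelStack].
#' @param panthos a [detectPanthos()] result.
#' @param channel marker channel (`"ThioS"`, `"GFAP"`, `"IbaI"`), or pass a
#'   logical `markerMask` directly.
#' @param markerMask optional precomputed logical matrix.
#' @param minAreaUm2 minimum marker-positive area inside the lesion.
#' @param kMAD positivity threshold for building the mask from a channel.
#' @return list with `percent` (of lesions marker-positive), `positive`
#'   logical per lesion, `n`. `NA` percent (flagged) when there are no
#'   lesions.
#' @export
cooccurrenceFraction <- function(x, panthos, channel = "ThioS",
                                 markerMask = NULL, minAreaUm2 = 5,
                                 kMAD = 3) {
  px <- pixelSize(x)
  if (is.null(markerMask)) {
    ch <- getChannel(x, channel)
    bgs <- robustBgStats(ch)
    markerMask <- ch > bgs$median + kMAD * max(bgs$mad, 1e-6)
  }
  lab <- panthos$labels
  n <- max(lab)
  if (n == 0) {
    warning("no lesions; co-occurrence undefined")
    return(list(percent = NA_real_, positive = logical(0), n = 0L))
  }
  pos <- vapply(seq_len(n), function(l) {
    sum(markerMask[lab == l]) * px^2 >= minAreaUm2
  }, TRUE)
  list(percent = 100 * mean(pos), positive = pos, n = n)
}

#' Intensity line profile across a field
#'
#' Bilinear-interpolated intensities of every channel along the segment from
#' `from` to `to` (micrometre coordinates), sampled every `step` um.
#'
#' @param x a [ChannelStack].
#' @param from,to numeric length-2 (x, y) endpoints in um.
#' @param step sampling step in um.
#' @return list with `t_um` (distance along the path), `x_um`, `y_um`, and
#'   `intensity` (matrix, one column per channel).
#' @export
lineProfile <- function(x, from, to, step = NULL) {
  px <- pixelSize(x)
  if (is.null(step)) step <- px
  d <- dim(x)
  lim <- c(d[2], d[1]) * px
  for (p in list(from, to)) {
    if (p[1] < 0 || p[2] < 0 || p[1] > lim[1] || p[2] > lim[2]) {
      stop("profile endpoints must lie inside the image")
    }
  }
  len <- sqrt(sum((to - from)^2))
  t <- seq(0, len, by = step)
  xs <- from[1] + t / max(len, 1e-12) * (to[1] - from[1])
  ys <- from[2] + t / max(len, 1e-12) * (to[2] - from[2])
  # bilinear interpolation at um coords (pixel centers at (i-0.5)*px)
  cx <- pmin(pmax(xs / px + 0.5, 1), d[2])
  cy <- pmin(pmax(ys / px + 0.5, 1), d[1])
  x0 <- pmin(floor(cx), d[2] - 1); y0 <- pmin(floor(cy), d[1] - 1)
  fx <- cx - x0; fy <- cy - y0
  inten <- sapply(channelNames(x), function(ch) {
    m <- getChannel(x, ch)
    m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
      m[cbind(y0, x0 + 1)] * fx * (1 - fy) +
      m[cbind(y0 + 1, x0)] * (1 - fx) * fy +
      m[cbind(y0 + 1, x0 + 1)] * fx * fy
  })
  if (is.null(dim(inten))) inten <- matrix(inten, nrow = length(t))
  colnames(inten) <- channelNames(x)
  list(t_um = t, x_um = xs, y_um = ys, intensity = inten, step_um = step)
}
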