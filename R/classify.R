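# Hue-angle / saturation computation and the multi-fluorophore decision
# table mapping each punctum to AP, AL, pa-AL, LY or unclassified.

#' Hue angle of an RGB intensity triple
#'
#' The spreadsheet-style hue used for vesicle identity:
#' \deqn{Hue = atan2(\sqrt{3}(G - B),\; 2R - G - B) \cdot 180/\pi \mod 360}
#' i.e. the angle of the point `(x, y) = (2R - G - B, sqrt(3) (G - B))`
#' mapped to `[0, 360)`. Note the spreadsheet two-argument arctangent takes
#' `(x, y)`; R's `atan2()` takes `(y, x)`, so the arguments are swapped here
#' on purpose. Pure red maps to 0, green to 120, blue to 240 degrees.
#' Invariant under positive scaling of the triple.
#'
#' @param R,G,B non-negative intensities (vectorized).
#' @return hue in degrees in `[0, 360)`.
#' @export
hueAngle <- function(R, G, B = 0) {
  n <- max(length(R), length(G), length(B))
  R <- rep_len(R, n); G <- rep_len(G, n); B <- rep_len(B, n)
  if (any(R == 0 & G == 0 & B == 0)) {
    stop("hue is undefined for an all-zero intensity triple")
  }
  h <- atan2(sqrt(3) * (G - B), 2 * R - G - B) * 180 / pi
  h %% 360
}

#' Saturation percentage of an RGB triple
#'
#' `(max - min) / (max + min) * 100` on channel intensities normalized to
#' `[0, 1]`; 0 for achromatic input (including all-zero, by convention).
#' Also reports whether lightness `(max + min)/2` is below 1, the validity
#' condition of the formula.
#'
#' @param R,G,B intensities normalized to `[0, 1]` (vectorized).
#' @return data.frame with `saturation` (percent) and `lightness_ok`.
#' @export
saturationPct <- function(R, G, B = 0) {
  n <- max(length(R), length(G), length(B))
  R <- rep_len(R, n); G <- rep_len(G, n); B <- rep_len(B, n)
  mx <- pmax(R, G, B); mn <- pmin(R, G, B)
  s <- ifelse(mx + mn > 0, (mx - mn) / (mx + mn) * 100, 0)
  data.frame(saturation = s, lightness_ok = (mx + mn) / 2 < 1 | (mx == 0))
}

#' Classification configuration
#'
#' Hue sector boundaries (degrees), the minimum saturation below which a
#' punctum is unclassified, and the robust-threshold multiplier used for
#' marker/LC3 positivity (background median + `kMAD` * MAD).
#'
#' @param redSector,yellowSector,greenSector numeric length-2 sectors;
#'   `redSector` wraps through 0.
#' @param sMin minimum saturation percent.
#' @param kMAD positivity threshold multiplier.
#' @return a config list for [classifyField()].
#' @export
classificationConfig <- function(redSector = c(315, 40),
                                 yellowSector = c(40, 90),
                                 greenSector = c(90, 150),
                                 sMin = 10, kMAD = 3) {
  list(redSector = redSector, yellowSector = yellowSector,
       greenSector = greenSector, sMin = sMin, kMAD = kMAD)
}

hueInSector <- function(hue, sector) {
  if (sector[1] <= sector[2]) hue >= sector[1] & hue < sector[2]
  else hue >= sector[1] | hue < sector[2]   # wraps through 0
}

hueCategory <- function(hue, config = classificationConfig()) {
  out <- rep("other", length(hue))
  out[hueInSector(hue, config$redSector)] <- "red"
  out[hue >= 15 & hue < config$yellowSector[1]] <- "orange-red"
  out[hueInSector(hue, config$yellowSector)] <- "yellow"
  out[hueInSector(hue, config$greenSector)] <- "green"
  out[hue >= 190 & hue < 270] <- "blue"
  out
}

#' Marker positivity of a measured punctum intensity
#'
#' A punctum is positive for a channel when its background-subtracted mean
#' intensity exceeds `kMAD` times the robust noise scale (MAD) of that
#' channel's background pixels.
#'
#' @param value background-subtracted mean intensity (vectorized).
#' @param bgStats list with `median` and `mad` of the channel background
#'   (from [robustBgStats()]); the median is already removed from `value`
#'   by the measurement step, so only the MAD enters.
#' @param kMAD threshold multiplier.
#' @return logical vector.
#' @export
markerPositive <- function(value, bgStats, kMAD = 3) {
  value > kMAD * max(bgStats$mad, 1e-6)
}

#' Classify one vesicle from its hue, saturation and marker status
#'
#' The decision table: an LC3-positive punctum with red-sector hue is an
#' acidified AL (purple when the lysosomal marker is also present, red
#' otherwise); yellow-sector hue splits into pa-AL (marker-positive, white
#' in the three-channel merge) versus AP (marker-negative, yellow); a
#' marker-positive punctum without LC3 is an LY; anything below the
#' saturation floor or outside the sectors is unclassified.
#'
#' @param hue hue angle in degrees (may be `NA` for marker-only puncta).
#' @param saturation saturation percent.
#' @param marker logical, lysosomal-marker positivity.
#' @param lc3 logical, tfLC3 (red or green channel) positivity.
#' @param config from [classificationConfig()].
#' @return one of `"AP"`, `"AL"`, `"paAL"`, `"LY"`, `"unclassified"`
#'   (vectorized).
#' @export
classifyVesicle <- function(hue, saturation, marker, lc3,
                            config = classificationConfig()) {
  n <- max(length(hue), length(marker), length(lc3), length(saturation))
  hue <- rep_len(hue, n); saturation <- rep_len(saturation, n)
  marker <- rep_len(marker, n); lc3 <- rep_len(lc3, n)
  out <- rep("unclassified", n)
  out[!lc3 & marker] <- "LY"
  ok <- lc3 & !is.na(hue) & saturation >= config$sMin
  red <- ok & hueInSector(hue, config$redSector)
  yel <- ok & hueInSector(hue, config$yellowSector)
  out[red] <- "AL"
  out[yel & marker] <- "paAL"
  out[yel & !marker] <- "AP"
  out
}

#' Classify every punctum of a field
#'
#' Applies [hueAngle()], [saturationPct()], [markerPositive()] and
#' [classifyVesicle()] to a measured punctum table. The hue used for the
#' red/yellow decision is computed from the two tfLC3 channels (the
#' lysosomal marker enters through its own positivity branch of the
#' decision table); saturation is computed on the per-channel
#' 99.9th-percentile-normalized triple. Positivity for any extra channels
#' (amyloid, PLA, ...) uses the same background + kMAD rule.
#'
#' @param x the [ChannelStack] the puncta were measured on.
#' @param measured output of [measureIntensities()] (optionally already
#'   carrying `neuron_id`).
#' @param detection the [detectPuncta()] result (for background statistics).
#' @param config from [classificationConfig()].
#' @param markerChannel name of the lysosomal-marker channel, or `NA` for
#'   two-channel mode (marker-dependent calls then fall back to
#'   "yellow, indeterminate" = unclassified for yellow+markerless logic).
#' @return `measured` with columns `hue_deg`, `saturation_pct`,
#'   `lightness_ok`, `lc3_pos`, `marker_pos`, `color_category`, `klass`,
#'   and `<channel>_pos` for extra channels.
#' @export
classifyField <- function(x, measured, detection,
                          config = classificationConfig(),
                          markerChannel = "CTSD") {
  chn <- channelNames(x)
  if (!all(c("mRFP", "eGFP") %in% chn)) {
    stop("classification requires mRFP and eGFP channels")
  }
  hasMarker <- !is.na(markerChannel) && markerChannel %in% chn
  if (!is.na(markerChannel) && !hasMarker) {
    stop("marker channel '", markerChannel, "' is not in the image; pass ",
         "markerChannel = NA to run in two-channel (mRFP/eGFP) mode")
  }
  fg <- detection$labels > 0
  bgStats <- lapply(chn, function(ch) robustBgStats(getChannel(x, ch), fg))
  names(bgStats) <- chn
  p999 <- vapply(chn, function(ch) {
    stats::quantile(getChannel(x, ch), 0.999, names = FALSE) -
      bgStats[[ch]]$median
  }, 0)
  p999 <- pmax(p999, 1e-6)

  n <- nrow(measured)
  R <- measured$mRFP; G <- measured$eGFP
  B <- if (hasMarker) measured[[markerChannel]] else rep(0, n)
  lc3 <- markerPositive(R, bgStats$mRFP, config$kMAD) |
    markerPositive(G, bgStats$eGFP, config$kMAD)
  marker <- if (hasMarker) {
    markerPositive(B, bgStats[[markerChannel]], config$kMAD)
  } else rep(FALSE, n)

  hue <- rep(NA_real_, n)
  okHue <- R > 0 | G > 0
  if (any(okHue)) hue[okHue] <- hueAngle(R[okHue], G[okHue], 0)
  Rn <- pmin(R / p999["mRFP"], 1); Gn <- pmin(G / p999["eGFP"], 1)
  # the classification gate uses the tfLC3 pair (B = 0), consistent with the
  # hue: a "white" pa-AL is achromatic in the three-channel triple by
  # definition, so the full-triple saturation cannot serve as the gate
  sat <- saturationPct(Rn, Gn, 0)

  klass <- classifyVesicle(hue, sat$saturation, marker, lc3, config)
  if (!hasMarker) {
    # two-channel mode cannot split yellow into AP vs pa-AL: indeterminate
    klass[klass == "AP"] <- "unclassified"
  }
  out <- measured
  out$hue_deg <- hue
  out$saturation_pct <- sat$saturation
  out$lightness_ok <- sat$lightness_ok
  out$lc3_pos <- lc3
  out$marker_pos <- marker
  out$color_category <- ifelse(is.na(hue), "other", hueCategory(hue, config))
  out$klass <- klass
  extras <- setdiff(chn, c("mRFP", "eGFP",
                           if (hasMarker) markerChannel, "DAPI"))
  for (ch in extras) {
    out[[paste0(tolower(ch), "_pos")]] <-
      markerPositive(measured[[ch]], bgStats[[ch]], config$kMAD)
  }
  out
}
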