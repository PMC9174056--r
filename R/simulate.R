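# Synthetic confocal-field generator. Every experimental condition the
# pipeline quantifies is stated as a preset (see inst/extdata/presets); the
# generator draws per-neuron vesicle complements, renders the pH-dependent
# tfLC3 photophysics plus marker channels, and keeps full ground truth.

truncNorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  for (i in 1:50) {
    if (!length(need)) break
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  if (length(need)) out[need] <- pmin(hi, pmax(lo, stats::rnorm(length(need), mean, sd)))
  out
}

# log-normal with given mean and coefficient of variation
rlnormMeanCV <- function(n, mean, cv) {
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Place n disks of the given radii inside an annulus [rIn, rOut] around the
# origin, without overlap (margin um between edges), by bounded rejection.
placeInAnnulus <- function(radii, rIn, rOut, margin = 0.35, maxTry = 4000,
                           existing = NULL) {
  n <- length(radii)
  dx <- numeric(n); dy <- numeric(n)
  ex <- existing  # data.frame(dx, dy, r) already placed
  for (i in seq_len(n)) {
    r <- radii[i]
    lo <- rIn + r; hi <- rOut - r
    if (hi <= lo) stop("vesicle of radius ", signif(r, 3),
                       " um does not fit in annulus [", rIn, ", ", rOut,
                       "] um (crowding: reduce counts or sizes)")
    placed <- FALSE
    for (t in seq_len(maxTry)) {
      rad <- sqrt(stats::runif(1, lo^2, hi^2))
      th <- stats::runif(1, 0, 2 * pi)
      x <- rad * cos(th); y <- rad * sin(th)
      ok <- TRUE
      if (i > 1) {
        d <- sqrt((dx[seq_len(i - 1)] - x)^2 + (dy[seq_len(i - 1)] - y)^2)
        ok <- all(d > radii[seq_len(i - 1)] + r + margin)
      }
      if (ok && !is.null(ex) && nrow(ex)) {
        d <- sqrt((ex$dx - x)^2 + (ex$dy - y)^2)
        ok <- all(d > ex$r + r + margin)
      }
      if (ok) { dx[i] <- x; dy[i] <- y; placed <- TRUE; break }
    }
    if (!placed) stop("failed to place vesicle ", i, " of ", n,
                      " after ", maxTry,
                      " tries (crowding: reduce counts or sizes)")
  }
  data.frame(dx = dx, dy = dy)
}

# Draw the class-dependent scalar attributes of nv vesicles of one class.
drawVesicleAttrs <- function(klass, nv, preset) {
  if (nv == 0) {
    return(data.frame(class = character(), pH = numeric(), radius = numeric(),
                      lc3_load = numeric(), marker_ctsd = logical(),
                      abeta_positive = logical(), pla_positive = logical(),
                      stringsAsFactors = FALSE))
  }
  b <- preset$pH_bounds[[klass]]
  area <- rlnormMeanCV(nv, preset$size_um2[[klass]], preset$size_cv)
  data.frame(
    class = rep(klass, nv),
    pH = truncNorm(nv, preset$pH_mean[[klass]], preset$pH_sd[[klass]],
                   b[1], b[2]),
    radius = sqrt(area / pi),
    lc3_load = if (klass == "LY") rep(0, nv) else rlnormMeanCV(nv, 1, 0.2),
    marker_ctsd = rep(klass != "AP", nv),
    abeta_positive = stats::runif(nv) < (preset$p_abeta[[klass]] %||% 0),
    pla_positive = stats::runif(nv) < (preset$p_pla[[klass]] %||% 0),
    stringsAsFactors = FALSE
  )
}

#' Sample one neuron from a preset
#'
#' Draws per-class vesicle counts (Poisson), sizes (log-normal), luminal pH
#' (truncated normal) and colocalization flags from the preset, and places
#' the vesicles without overlap in the perikaryon (soma annulus outside the
#' nucleus). For PANTHOS stages the geometry is delegated to
#' [makePanthosNeuron()].
#'
#' @param preset a preset from [getPreset()].
#' @param stage `"none"`, `"i"`, `"ii"` or `"iii"`; `NULL` draws from the
#'   preset's stage mix.
#' @return a neuron spec: list with `stage`, `soma_radius`, `nucleus_radius`,
#'   `dapi_state`, marker flags, `blebs` (data.frame) and `vesicles`
#'   (data.frame with offsets `dx`, `dy` in micrometres from the soma center).
#' @export
sampleNeuron <- function(preset, stage = NULL) {
  if (is.null(stage)) {
    sm <- unlist(preset$panthos$stage_mix)[c("none", "i", "ii", "iii")]
    sm[is.na(sm)] <- 0
    stage <- sample(c("none", "i", "ii", "iii"), 1, prob = sm)
  }
  stage <- match.arg(stage, c("none", "i", "ii", "iii"))
  if (stage != "none") return(makePanthosNeuron(stage, preset))

  g <- preset$geometry
  ves <- do.call(rbind, lapply(.vesicleClasses, function(k) {
    drawVesicleAttrs(k, stats::rpois(1, preset$counts[[k]]), preset)
  }))
  if (nrow(ves)) {
    pos <- placeInAnnulus(ves$radius, g$nucleus_radius + 0.2,
                          g$soma_radius - 0.2)
    ves <- cbind(ves, pos)
  } else {
    ves$dx <- numeric(0); ves$dy <- numeric(0)
  }
  list(stage = "none", soma_radius = g$soma_radius,
       nucleus_radius = g$nucleus_radius, dapi_state = "normal",
       amyloid = FALSE, thioS = FALSE, gfap = FALSE, ibai = FALSE,
       blebs = data.frame(angle = numeric(), neck = numeric(),
                          radius = numeric()),
       vesicles = ves)
}

#' Construct a PANTHOS-stage neuron
#'
#' Stage i: enlarged pa-ALs proliferate in a modestly expanded perikaryon,
#' no blebs. Stage ii: the same plus 1-2 focal plasma-membrane blebs. Stage
#' iii: the full rosette - at least 6 radially arranged AV-filled blebs, a
#' central LC3-free core holding the nuclear remnant, optional perinuclear
#' amyloid corona, and co-label flags (Thio-S, GFAP, IbaI, DAPI state) drawn
#' from the preset.
#'
#' @param stage `"i"`, `"ii"` or `"iii"`.
#' @param preset a preset from [getPreset()].
#' @return a neuron spec (see [sampleNeuron()]).
#' @export
makePanthosNeuron <- function(stage, preset) {
  stage <- match.arg(stage, c("i", "ii", "iii"))
  g <- preset$geometry
  pan <- preset$panthos
  # enlarging, proliferating pa-ALs expand the perikaryon at stages i-ii
  somaR <- if (stage %in% c("i", "ii")) g$soma_radius + 1.5 else g$soma_radius
  coreR <- g$nucleus_radius + 0.5

  nBlebs <- switch(stage,
    i = 0L,
    ii = 1L + stats::rbinom(1, 1, 0.5),
    iii = 6L + min(stats::rpois(1, 1.2), 2L))
  blebs <- if (nBlebs > 0) {
    spacing <- 2 * pi / nBlebs
    ang <- (stats::runif(1, 0, 2 * pi) +
            (seq_len(nBlebs) - 1) * spacing +
            stats::runif(nBlebs, -0.12 * spacing, 0.12 * spacing)) %% (2 * pi)
    data.frame(angle = ang,
               neck = stats::runif(nBlebs, 2.0, 3.5),
               radius = stats::runif(nBlebs, 3.0, 4.2))
  } else {
    data.frame(angle = numeric(), neck = numeric(), radius = numeric())
  }

  nSoma <- switch(stage, i = 22L + stats::rpois(1, 3),
                  ii = 22L + stats::rpois(1, 3), iii = 12L)
  somaVes <- drawVesicleAttrs("paAL", nSoma, preset)
  somaVes <- cbind(somaVes,
                   placeInAnnulus(somaVes$radius, coreR + 0.3, somaR - 0.2))
  extra <- drawVesicleAttrs("AL", stats::rpois(1, preset$counts$AL %||% 0),
                            preset)
  if (nrow(extra)) {
    extra <- cbind(extra, placeInAnnulus(
      extra$radius, coreR + 0.3, somaR - 0.2,
      existing = data.frame(dx = somaVes$dx, dy = somaVes$dy,
                            r = somaVes$radius)))
    somaVes <- rbind(somaVes, extra)
  }

  blebVes <- NULL
  if (nBlebs > 0) {
    for (b in seq_len(nBlebs)) {
      bc <- (somaR + blebs$neck[b] + blebs$radius[b] * 0.55) *
        c(cos(blebs$angle[b]), sin(blebs$angle[b]))
      usable <- blebs$radius[b] - 0.2
      nv <- max(2L, round(pi * (usable - 0.9)^2 / 7))
      v <- drawVesicleAttrs("paAL", nv, preset)
      pos <- placeInAnnulus(v$radius, 0, usable)
      v$dx <- pos$dx + bc[1]; v$dy <- pos$dy + bc[2]
      blebVes <- rbind(blebVes, v)
    }
  }
  ves <- rbind(somaVes, blebVes)

  dapiP <- unlist(pan$dapi)[c("normal", "condensed", "absent")]
  dapiP[is.na(dapiP)] <- 0
  dapi <- if (stage == "iii") {
    sample(c("normal", "condensed", "absent"), 1, prob = dapiP)
  } else "normal"

  list(stage = stage, soma_radius = somaR, nucleus_radius = g$nucleus_radius,
       dapi_state = dapi,
       amyloid = stage == "iii" && stats::runif(1) < (pan$p_amyloid %||% 0),
       thioS = stage == "iii" && stats::runif(1) < (pan$p_thioS %||% 0),
       gfap = stage == "iii" && stats::runif(1) < (pan$p_gfap %||% 0),
       ibai = stage == "iii" && stats::runif(1) < (pan$p_ibai %||% 0),
       blebs = blebs, vesicles = ves)
}

# ---- rendering ------------------------------------------------------------

stampDisk <- function(img, cx, cy, r, value, px) {
  d <- pixelDisk(nrow(img), ncol(img), cy / px + 0.5, cx / px + 0.5, r / px)
  img[d$ys, d$xs][d$inside] <- img[d$ys, d$xs][d$inside] + value
  img
}

maskDisk <- function(mask, cx, cy, r, px) {
  d <- pixelDisk(nrow(mask), ncol(mask), cy / px + 0.5, cx / px + 0.5, r / px)
  mask[d$ys, d$xs][d$inside] <- TRUE
  mask
}

maskAnnulus <- function(mask, cx, cy, rIn, rOut, px) {
  d <- pixelDisk(nrow(mask), ncol(mask), cy / px + 0.5, cx / px + 0.5, rOut / px)
  sel <- d$d2 <= (rOut / px)^2 & d$d2 >= (rIn / px)^2
  mask[d$ys, d$xs][sel] <- TRUE
  mask
}

# capsule (thick segment) mask between two um points
maskCapsule <- function(mask, p0, p1, halfwidth, px) {
  ny <- nrow(mask); nx <- ncol(mask)
  lo <- pmin(p0, p1) - halfwidth; hi <- pmax(p0, p1) + halfwidth
  xs <- max(1L, floor(lo[1] / px)):min(nx, ceiling(hi[1] / px))
  ys <- max(1L, floor(lo[2] / px)):min(ny, ceiling(hi[2] / px))
  if (!length(xs) || !length(ys)) return(mask)
  gx <- (xs - 0.5) * px; gy <- (ys - 0.5) * px
  v <- p1 - p0
  len2 <- sum(v^2)
  X <- matrix(gx, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(gy, length(ys), length(xs))
  tt <- if (len2 > 0) pmin(1, pmax(0, ((X - p0[1]) * v[1] + (Y - p0[2]) * v[2]) / len2)) else 0
  d2 <- (X - (p0[1] + tt * v[1]))^2 + (Y - (p0[2] + tt * v[2]))^2
  sub <- mask[ys, xs]
  sub[d2 <= halfwidth^2] <- TRUE
  mask[ys, xs] <- sub
  mask
}

# Support mask of a PANTHOS lesion (soma + necks + blebs), used both for
# diffuse tfLC3 rendering and for the ground-truth lesion label.
lesionSupport <- function(ny, nx, spec, cx, cy, px) {
  m <- matrix(FALSE, ny, nx)
  m <- maskDisk(m, cx, cy, spec$soma_radius, px)
  if (nrow(spec$blebs)) {
    for (b in seq_len(nrow(spec$blebs))) {
      a <- spec$blebs$angle[b]
      bc <- c(cx, cy) + (spec$soma_radius + spec$blebs$neck[b] +
                           spec$blebs$radius[b] * 0.55) * c(cos(a), sin(a))
      edge <- c(cx, cy) + (spec$soma_radius - 1) * c(cos(a), sin(a))
      m <- maskCapsule(m, edge, bc, 1.2, px)
      m <- maskDisk(m, bc[1], bc[2], spec$blebs$radius[b], px)
    }
  }
  m
}

#' Render a set of neuron specs into a multi-channel field
#'
#' Green-channel intensity of each vesicle is `lc3_load *`
#' [egfpQuenchFactor()] at its luminal pH; red is `lc3_load` (pH-resistant);
#' the lysosomal-marker channel renders `marker_ctsd` vesicles; amyloid,
#' PLA, DAPI, Thio-S and glial channels render from their flags. The
#' expected image is blurred with a Gaussian PSF, then Poisson shot noise
#' and Gaussian read noise are added (when enabled).
#'
#' @param preset a preset from [getPreset()].
#' @param specs list of neuron specs (from [sampleNeuron()]).
#' @param centers matrix/data.frame of soma centers (um), one row per spec.
#' @param fieldDim c(width, height) of the field in um.
#' @param noise,psf logical overrides of the preset's noise and PSF settings.
#' @param isolatedPlaques optional data.frame (x_um, y_um, radius_um) of
#'   extra-lesional amyloid plaques to render.
#' @return a [SimulatedField] (seed slot filled by the caller).
#' @export
renderField <- function(preset, specs, centers, fieldDim,
                        noise = NULL, psf = TRUE, isolatedPlaques = NULL) {
  px <- preset$pixel_size
  chn <- preset$channels
  nx <- round(fieldDim[1] / px); ny <- round(fieldDim[2] / px)
  if (is.null(noise)) noise <- isTRUE(preset$noise)
  egfp <- egfpModel()
  imgs <- lapply(chn, function(ch) matrix(0, ny, nx))
  names(imgs) <- chn
  neuronLab <- matrix(0L, ny, nx)
  lesionLab <- matrix(0L, ny, nx)
  vesTab <- NULL
  neuTab <- NULL
  lesionCount <- 0L

  for (i in seq_along(specs)) {
    s <- specs[[i]]
    cx <- centers[i, 1]; cy <- centers[i, 2]
    if (cx - s$soma_radius < 0 || cy - s$soma_radius < 0 ||
        cx + s$soma_radius > fieldDim[1] || cy + s$soma_radius > fieldDim[2]) {
      stop("neuron ", i, " soma does not fit inside the field")
    }
    isPan <- s$stage != "none"
    # diffuse cytosolic tfLC3 (neutral pH: equal eGFP and mRFP emission)
    if (isPan) {
      sup <- lesionSupport(ny, nx, s, cx, cy, px)
      core <- matrix(FALSE, ny, nx)
      core <- maskDisk(core, cx, cy, s$nucleus_radius + 0.5, px)
      dif <- sup & !core
      imgs$mRFP[dif] <- imgs$mRFP[dif] + 0.28
      imgs$eGFP[dif] <- imgs$eGFP[dif] + 0.28
      lesionCount <- lesionCount + 1L
      lesFill <- fillHoles(sup)
      lesionLab[lesFill & lesionLab == 0L] <- lesionCount
      neuronLab[lesFill & neuronLab == 0L] <- i
    } else {
      som <- matrix(FALSE, ny, nx)
      som <- maskAnnulus(som, cx, cy, s$nucleus_radius, s$soma_radius, px)
      imgs$mRFP[som] <- imgs$mRFP[som] + 0.05
      imgs$eGFP[som] <- imgs$eGFP[som] + 0.05
      lab <- matrix(FALSE, ny, nx)
      lab <- maskDisk(lab, cx, cy, s$soma_radius, px)
      neuronLab[lab & neuronLab == 0L] <- i
    }
    # vesicles
    v <- s$vesicles
    if (nrow(v)) {
      if (any(v$abeta_positive) && !("Abeta" %in% chn)) {
        stop("neuron carries Abeta-positive vesicles but the channel list ",
             "has no 'Abeta' channel")
      }
      if (any(v$pla_positive) && !("PLA" %in% chn)) {
        stop("neuron carries PLA-positive vesicles but the channel list ",
             "has no 'PLA' channel")
      }
      q <- egfpQuenchFactor(v$pH, egfp)
      for (j in seq_len(nrow(v))) {
        vx <- cx + v$dx[j]; vy <- cy + v$dy[j]
        if (v$lc3_load[j] > 0) {
          imgs$mRFP <- stampDisk(imgs$mRFP, vx, vy, v$radius[j],
                                 v$lc3_load[j], px)
          imgs$eGFP <- stampDisk(imgs$eGFP, vx, vy, v$radius[j],
                                 v$lc3_load[j] * q[j], px)
        }
        if (v$marker_ctsd[j] && "CTSD" %in% chn) {
          imgs$CTSD <- stampDisk(imgs$CTSD, vx, vy, v$radius[j], 0.9, px)
        }
        if (v$abeta_positive[j] && "Abeta" %in% chn) {
          imgs$Abeta <- stampDisk(imgs$Abeta, vx, vy, v$radius[j], 0.9, px)
        }
        if (v$pla_positive[j] && "PLA" %in% chn) {
          imgs$PLA <- stampDisk(imgs$PLA, vx, vy, v$radius[j], 0.9, px)
        }
      }
      vesTab <- rbind(vesTab, data.frame(
        neuron_id = i, class = v$class, pH = v$pH,
        x_um = cx + v$dx, y_um = cy + v$dy, radius_um = v$radius,
        lc3_load = v$lc3_load, marker_ctsd = v$marker_ctsd,
        abeta_positive = v$abeta_positive, pla_positive = v$pla_positive,
        stringsAsFactors = FALSE))
    }
    # nuclear / lesion-level channels
    if ("DAPI" %in% chn) {
      if (s$dapi_state == "normal") {
        imgs$DAPI <- stampDisk(imgs$DAPI, cx, cy, s$nucleus_radius, 0.9, px)
      } else if (s$dapi_state == "condensed") {
        imgs$DAPI <- stampDisk(imgs$DAPI, cx, cy, 0.45 * s$nucleus_radius,
                               1.2, px)
      }
    }
    if (isPan) {
      coreR <- s$nucleus_radius + 0.5
      if (s$amyloid && "Abeta" %in% chn) {
        am <- matrix(FALSE, ny, nx)
        am <- maskAnnulus(am, cx, cy, coreR, coreR + 3.5, px)
        imgs$Abeta[am] <- imgs$Abeta[am] + 0.8
      }
      if (s$thioS && "ThioS" %in% chn) {
        imgs$ThioS <- stampDisk(imgs$ThioS, cx, cy, 3.0, 0.9, px)
      }
      for (mk in c("gfap", "ibai")) {
        ch <- if (mk == "gfap") "GFAP" else "IbaI"
        if (s[[mk]] && ch %in% chn) {
          # reactive glia engage the lesion surface: patches straddle the
          # soma boundary so they reliably overlap the lesion confines
          for (k in 1:2) {
            a <- stats::runif(1, 0, 2 * pi)
            pc <- c(cx, cy) + 9.5 * c(cos(a), sin(a))
            imgs[[ch]] <- stampDisk(imgs[[ch]], pc[1], pc[2], 2.5, 0.8, px)
          }
        }
      }
    }
    neuTab <- rbind(neuTab, data.frame(
      neuron_id = i, x_um = cx, y_um = cy, soma_radius_um = s$soma_radius,
      nucleus_radius_um = s$nucleus_radius, panthos_stage = s$stage,
      lesion_id = if (isPan) lesionCount else 0L,
      n_blebs = nrow(s$blebs), dapi_state = s$dapi_state,
      amyloid = s$amyloid, thioS = s$thioS, gfap = s$gfap, ibai = s$ibai,
      stringsAsFactors = FALSE))
  }

  if (!is.null(isolatedPlaques) && nrow(isolatedPlaques) && "Abeta" %in% chn) {
    for (j in seq_len(nrow(isolatedPlaques))) {
      imgs$Abeta <- stampDisk(imgs$Abeta, isolatedPlaques$x_um[j],
                              isolatedPlaques$y_um[j],
                              isolatedPlaques$radius_um[j], 0.8, px)
    }
  }

  sig <- if (psf) preset$psf_sigma / px else 0
  arr <- array(0, c(ny, nx, length(chn)))
  for (k in seq_along(chn)) {
    im <- imgs[[k]] + preset$background
    if (sig > 0) im <- gaussBlur(im, sig)
    if (noise) {
      ph <- preset$photons_full_scale
      im <- matrix(stats::rpois(length(im), pmax(im, 0) * ph) / ph,
                   nrow(im), ncol(im))
      im <- im + matrix(stats::rnorm(length(im), 0, preset$read_noise_sd),
                        nrow(im), ncol(im))
      im <- pmax(im, 0)
    }
    arr[, , k] <- im
  }
  if (is.null(vesTab)) {
    vesTab <- data.frame(neuron_id = integer(), class = character(),
                         pH = numeric(), x_um = numeric(), y_um = numeric(),
                         radius_um = numeric(), lc3_load = numeric(),
                         marker_ctsd = logical(), abeta_positive = logical(),
                         pla_positive = logical(), stringsAsFactors = FALSE)
  }
  if (nrow(vesTab)) vesTab <- cbind(id = seq_len(nrow(vesTab)), vesTab)
  else vesTab$id <- integer(0)
  if (is.null(neuTab)) neuTab <- data.frame(neuron_id = integer())
  new("SimulatedField", data = arr, channels = chn, pixelSize = px,
      vesicles = vesTab, neurons = neuTab, neuronLabels = neuronLab,
      lesionLabels = lesionLab, seed = NA_integer_, preset = preset$name)
}

#' Simulate one field from a preset
#'
#' Lays `nNeurons` sampled neurons out on a tile grid (or, for lesion-style
#' presets that define a `geometry$field`, one lesion centered per field),
#' renders all channels and returns the field with full ground truth.
#'
#' @inheritParams renderField
#' @param nNeurons number of neurons in the field.
#' @param seed integer seed; fixes every output bit.
#' @param stage optional fixed PANTHOS stage passed to [sampleNeuron()].
#' @return a [SimulatedField].
#' @export
simulateField <- function(preset, nNeurons = NULL, seed = 1L, noise = NULL,
                          psf = TRUE, stage = NULL) {
  if (is.character(preset)) preset <- getPreset(preset)
  set.seed(as.integer(seed))
  g <- preset$geometry
  iso <- NULL
  if (!is.null(g$field)) {
    nNeurons <- nNeurons %||% 1L
    fieldDim <- c(g$field, g$field)
    centers <- matrix(rep(g$field / 2, 2), nNeurons, 2, byrow = TRUE) +
      matrix(stats::runif(2 * nNeurons, -2, 2), nNeurons, 2)
    specs <- lapply(seq_len(nNeurons), function(i) sampleNeuron(preset, stage))
    pIso <- preset$panthos$p_isolated_plaque %||% 0
    if (pIso > 0 && stats::runif(1) < pIso) {
      a <- stats::runif(1, 0, 2 * pi)
      iso <- data.frame(x_um = fieldDim[1] / 2 + 27 * cos(a),
                        y_um = fieldDim[2] / 2 + 27 * sin(a),
                        radius_um = 6.6)
    }
  } else {
    nNeurons <- nNeurons %||% 9L
    t <- g$tile
    ncols <- ceiling(sqrt(nNeurons))
    nrows <- ceiling(nNeurons / ncols)
    fieldDim <- c(ncols * t, nrows * t)
    idx <- seq_len(nNeurons) - 1L
    centers <- cbind((idx %% ncols) * t + t / 2,
                     (idx %/% ncols) * t + t / 2) +
      matrix(stats::runif(2 * nNeurons, -1.5, 1.5), nNeurons, 2)
    specs <- lapply(seq_len(nNeurons), function(i) sampleNeuron(preset, stage))
  }
  fld <- renderField(preset, specs, centers, fieldDim, noise = noise,
                     psf = psf, isolatedPlaques = iso)
  fld@seed <- as.integer(seed)
  fld
}

#' Simulate a cohort of fields
#'
#' Splits `nNeurons` across fields of `neuronsPerField` and renders each
#' field from its own child seed derived from the root seed, so the whole
#' cohort is reproducible bit-for-bit.
#'
#' @inheritParams simulateField
#' @param nNeurons total neurons (or lesions, for lesion-style presets).
#' @param neuronsPerField neurons rendered per field.
#' @return list of [SimulatedField]s.
#' @export
simulateCohort <- function(preset, nNeurons, neuronsPerField = 9L, seed = 1L,
                           noise = NULL, psf = TRUE, stage = NULL) {
  if (is.character(preset)) preset <- getPreset(preset)
  if (!is.null(preset$geometry$field)) neuronsPerField <- 1L
  nFields <- ceiling(nNeurons / neuronsPerField)
  sizes <- rep(neuronsPerField, nFields)
  sizes[nFields] <- nNeurons - neuronsPerField * (nFields - 1)
  set.seed(as.integer(seed))
  fieldSeeds <- sample.int(.Machine$integer.max - 1L, nFields)
  lapply(seq_len(nFields), function(i) {
    simulateField(preset, sizes[i], seed = fieldSeeds[i], noise = noise,
                  psf = psf, stage = stage)
  })
}
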