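# Pipeline glue: per-field detect -> measure -> classify, cohort-level
# aggregation, and the simulate / analyze / report entry points that the
# command-line wrapper (inst/cli/panthoscope.R) calls.

#' Pipeline configuration
#'
#' @param detection from [detectionParams()].
#' @param classification from [classificationConfig()].
#' @param markerChannel lysosomal-marker channel name (`NA` = two-channel
#'   mode).
#' @param panthos logical, run lesion detection.
#' @param panthosPar from [panthosParams()].
#' @return config list.
#' @export
pipelineConfig <- function(detection = detectionParams(),
                           classification = classificationConfig(),
                           markerChannel = "CTSD", panthos = FALSE,
                           panthosPar = panthosParams()) {
  list(detection = detection, classification = classification,
       markerChannel = markerChannel, panthos = panthos,
       panthosPar = panthosPar)
}

#' Analyze one field
#'
#' Runs puncta detection, intensity measurement, neuron assignment (when a
#' label image is available) and ratiometric classification; optionally
#' PANTHOS lesion detection.
#'
#' @param x a [ChannelStack] (a [SimulatedField] supplies its own neuron
#'   label image).
#' @param config from [pipelineConfig()].
#' @param neuronLabels optional integer label matrix (same shape as the
#'   image).
#' @return list with `calls` (classified punctum table), `detection`, and
#'   `panthos` (when enabled).
#' @export
analyzeField <- function(x, config = pipelineConfig(), neuronLabels = NULL) {
  if (is.null(neuronLabels) && is(x, "SimulatedField")) {
    neuronLabels <- x@neuronLabels
  }
  det <- detectPuncta(x, config$detection)
  measured <- measureIntensities(x, det)
  if (!is.null(neuronLabels)) {
    if (!identical(dim(neuronLabels), dim(det$labels))) {
      stop("neuron label image shape does not match the image")
    }
    measured <- assignToNeurons(measured, neuronLabels)
  } else {
    measured$neuron_id <- NA_integer_
  }
  calls <- classifyField(x, measured, det, config$classification,
                         config$markerChannel)
  out <- list(calls = calls, detection = det)
  if (isTRUE(config$panthos)) {
    out$panthos <- detectPanthos(x, calls, config$panthosPar)
  }
  out
}

#' Analyze a cohort of fields
#'
#' Applies [analyzeField()] to each field, offsets neuron ids so they are
#' unique across the cohort, and aggregates per-neuron metrics.
#'
#' @param fields list of [ChannelStack]s / [SimulatedField]s.
#' @param config from [pipelineConfig()].
#' @return list with `calls` (cohort punctum table with global neuron ids),
#'   `neuronMetrics` (one row per neuron, zero rows included for simulated
#'   fields), `results` (per-field results), and a `log` of stage counts.
#' @export
analyzeCohort <- function(fields, config = pipelineConfig()) {
  offset <- 0L
  allCalls <- NULL
  allIds <- integer(0)
  results <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    res <- analyzeField(fields[[i]], config)
    calls <- res$calls
    nNeu <- if (is(fields[[i]], "SimulatedField")) {
      nrow(fields[[i]]@neurons)
    } else {
      s <- calls$neuron_id[!is.na(calls$neuron_id)]
      if (length(s)) max(s) else 0L
    }
    calls$field <- i
    calls$neuron_id <- calls$neuron_id + offset
    allIds <- c(allIds, offset + seq_len(nNeu))
    offset <- offset + nNeu
    allCalls <- rbind(allCalls, calls)
    results[[i]] <- res
  }
  metrics <- perNeuronMetrics(allCalls, neuronIds = allIds)
  list(calls = allCalls, neuronMetrics = metrics, results = results,
       log = list(nFields = length(fields), nNeurons = length(allIds),
                  nPuncta = if (is.null(allCalls)) 0L else nrow(allCalls)))
}

#' Analyze a PANTHOS cohort
#'
#' Per field: detection + classification, lesion detection and staging,
#' DAPI status, plaque segmentation and correspondence, and marker
#' co-occurrence. Amyloid signal fractions are aggregated as total
#' inside-lesion signal over total field signal across the cohort.
#'
#' @param fields list of fields simulated with a lesion-style preset.
#' @param config from [pipelineConfig()] (panthos is forced on; the punctum
#'   diameter ceiling is widened to the enlarged pa-AL scale).
#' @return list with `lesions` (cohort lesion table with `dapi_status` and
#'   marker positivity), `amyloidFraction`, `plaque` correspondence counts,
#'   and marker co-occurrence percentages.
#' @export
analyzePanthosCohort <- function(fields, config = NULL) {
  if (is.null(config)) {
    config <- pipelineConfig(detection = detectionParams(maxDiameter = 4),
                             panthos = TRUE)
  }
  config$panthos <- TRUE
  lesions <- NULL
  sigIn <- sigTot <- 0
  nPlq <- nPlqWith <- nPan <- nPanAmy <- 0L
  cooc <- c(ThioS = 0L, GFAP = 0L, IbaI = 0L)
  nLes <- 0L
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    res <- analyzeField(f, config)
    pan <- res$panthos
    chn <- channelNames(f)
    if (nrow(pan$lesions)) {
      lt <- pan$lesions
      lt$field <- i
      if ("DAPI" %in% chn) {
        lt$dapi_status <- vapply(seq_len(nrow(lt)), function(j) {
          dapiStatus(lt[j, ], f)
        }, "")
      }
      for (mk in intersect(c("ThioS", "GFAP", "IbaI"), chn)) {
        cf <- cooccurrenceFraction(f, pan, channel = mk)
        lt[[paste0(tolower(mk), "_pos")]] <- cf$positive
        cooc[mk] <- cooc[mk] + sum(cf$positive)
      }
      nLes <- nLes + nrow(lt)
      lesions <- rbind(lesions, lt)
    }
    if ("Abeta" %in% chn) {
      sig <- positiveSignal(getChannel(f, "Abeta"))
      union <- pan$labels > 0
      if (any(union)) {
        union <- cpp_dilate(union, as.integer(round(1 / pixelSize(f))))
      }
      sigIn <- sigIn + sum(sig[union])
      sigTot <- sigTot + sum(sig)
      plq <- segmentPlaques(f)
      corr <- lesionPlaqueCorrespondence(pan, plq)
      pm <- plaqueMatched(pan, plq)
      nPlq <- nPlq + length(pm)
      nPlqWith <- nPlqWith + sum(pm)
      nPan <- nPan + corr$nPanthos
      nPanAmy <- nPanAmy + corr$nMatched
    }
  }
  list(lesions = lesions,
       amyloidFraction = if (sigTot > 0) sigIn / sigTot else NA_real_,
       plaque = list(nPlaques = nPlq, nWithPanthos = nPlqWith,
                     percentWithPanthos = if (nPlq > 0) 100 * nPlqWith / nPlq else NA_real_,
                     nPanthos = nPan,
                     percentPanthosAmyloidPos = if (nPan > 0) 100 * nPanAmy / nPan else NA_real_),
       cooccurrence = if (nLes > 0) 100 * cooc / nLes else cooc * NA_real_,
       nLesions = nLes)
}

# helper: logical per plaque, matched to a lesion at >= 50% of smaller mask
plaqueMatched <- function(pan, plq, minOverlap = 0.5) {
  nQ <- max(plq$labels)
  if (nQ == 0) return(logical(0))
  nP <- max(pan$labels)
  areaQ <- tabulate(plq$labels[plq$labels > 0], nbins = nQ)
  if (nP == 0) return(rep(FALSE, nQ))
  areaP <- tabulate(pan$labels[pan$labels > 0], nbins = nP)
  both <- pan$labels > 0 & plq$labels > 0
  out <- rep(FALSE, nQ)
  if (any(both)) {
    ov <- table(pan$labels[both], plq$labels[both])
    for (i in rownames(ov)) for (j in colnames(ov)) {
      o <- ov[i, j]
      if (o == 0) next
      ii <- as.integer(i); jj <- as.integer(j)
      if (o >= minOverlap * min(areaP[ii], areaQ[jj])) out[jj] <- TRUE
    }
  }
  out
}

# ---- disk-based entry points ----------------------------------------------

configHash <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Simulate a cohort and write it to disk
#'
#' Writes one multi-page TIFF per field plus 16-bit neuron-label and
#' lesion-mask TIFFs, per-vesicle and per-neuron ground-truth CSVs, and a
#' manifest JSON recording the preset, seed and config hash.
#'
#' @param preset preset name or path (see [getPreset()]).
#' @param nNeurons total neurons (or lesions) to simulate.
#' @param seed root seed.
#' @param outdir output directory (created).
#' @param neuronsPerField neurons per rendered field.
#' @param noise,psf optional overrides.
#' @return the manifest (invisibly).
#' @export
runSimulate <- function(preset, nNeurons, seed, outdir, neuronsPerField = 9L,
                        noise = NULL, psf = TRUE) {
  p <- if (is.character(preset)) getPreset(preset) else preset
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fields <- simulateCohort(p, nNeurons, neuronsPerField, seed, noise, psf)
  files <- character(0)
  vesAll <- NULL
  neuAll <- NULL
  offset <- 0L
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    img <- file.path(outdir, sprintf("field_%03d.tif", i))
    writeTiffStack(f, img)
    lab <- file.path(outdir, sprintf("field_%03d_neurons.tif", i))
    writeTiffStack(matrix(as.numeric(f@neuronLabels), nrow(f@neuronLabels)),
                   lab, channels = "neuron_labels", pixelSize = f@pixelSize,
                   dtype = "uint16")
    les <- file.path(outdir, sprintf("field_%03d_lesions.tif", i))
    writeTiffStack(matrix(as.numeric(f@lesionLabels), nrow(f@lesionLabels)),
                   les, channels = "lesion_labels", pixelSize = f@pixelSize,
                   dtype = "uint16")
    files <- c(files, basename(img))
    v <- f@vesicles; v$field <- i
    v$neuron_id <- v$neuron_id + offset
    n <- f@neurons; n$field <- i
    n$neuron_id <- n$neuron_id + offset
    offset <- offset + nrow(f@neurons)
    vesAll <- rbind(vesAll, v)
    neuAll <- rbind(neuAll, n)
  }
  write.csv(vesAll, file.path(outdir, "ground_truth_vesicles.csv"),
            row.names = FALSE)
  write.csv(neuAll, file.path(outdir, "ground_truth_neurons.csv"),
            row.names = FALSE)
  manifest <- list(preset = p$name, seed = as.integer(seed),
                   n_neurons = as.integer(nNeurons),
                   neurons_per_field = as.integer(neuronsPerField),
                   channels = p$channels, pixel_size_um = p$pixel_size,
                   fields = files, config_hash = configHash(p),
                   package_version = as.character(utils::packageVersion("panthoscope")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Analyze a simulated-cohort directory
#'
#' Reads the fields written by [runSimulate()], runs the detection /
#' classification / quantification pipeline (and lesion analysis when the
#' preset carries lesion channels), and writes punctum, vesicle-call and
#' per-neuron CSVs plus a summary JSON.
#'
#' @param indir directory produced by [runSimulate()].
#' @param outdir output directory (default `indir`).
#' @param config from [pipelineConfig()]; marker channel and panthos mode
#'   are defaulted from the manifest channels.
#' @return list with `calls`, `neuronMetrics` and (optionally) `panthos`
#'   summaries (invisibly).
#' @export
runAnalyze <- function(indir, outdir = indir, config = NULL) {
  mf <- file.path(indir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", indir)
  manifest <- jsonlite::fromJSON(mf)
  chn <- manifest$channels
  if (is.null(config)) {
    config <- pipelineConfig(
      markerChannel = if ("CTSD" %in% chn) "CTSD" else NA)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fields <- lapply(manifest$fields, function(fn) {
    x <- readTiffStack(file.path(indir, fn))
    labPath <- file.path(indir, sub("\\.tif$", "_neurons.tif", fn))
    lab <- readTiffStack(labPath, asArray = TRUE)
    gt <- new("SimulatedField", data = x@data, channels = x@channels,
              pixelSize = x@pixelSize,
              vesicles = data.frame(), neurons = data.frame(),
              neuronLabels = matrix(as.integer(round(lab[, , 1])),
                                    dim(lab)[1]),
              lesionLabels = matrix(0L, dim(lab)[1], dim(lab)[2]),
              seed = NA_integer_, preset = manifest$preset)
    nIds <- sort(unique(as.integer(gt@neuronLabels)))
    gt@neurons <- data.frame(neuron_id = nIds[nIds > 0])
    gt
  })
  res <- analyzeCohort(fields, config)
  write.csv(res$calls, file.path(outdir, "vesicle_calls.csv"),
            row.names = FALSE)
  write.csv(res$neuronMetrics, file.path(outdir, "neuron_metrics.csv"),
            row.names = FALSE)
  summary <- list(
    preset = manifest$preset, seed = manifest$seed,
    config_hash = configHash(config), log = res$log,
    mean_counts = lapply(.vesicleClasses, function(k) {
      groupSummary(res$neuronMetrics[[paste0("n_", k)]])
    })
  )
  names(summary$mean_counts) <- .vesicleClasses
  isLesion <- all(c("Abeta", "DAPI", "ThioS") %in% chn)
  if (isLesion || isTRUE(config$panthos)) {
    panRes <- analyzePanthosCohort(fields)
    if (!is.null(panRes$lesions)) {
      write.csv(panRes$lesions, file.path(outdir, "lesions.csv"),
                row.names = FALSE)
    }
    summary$panthos <- list(
      n_lesions = panRes$nLesions,
      amyloid_fraction = panRes$amyloidFraction,
      plaque = panRes$plaque,
      cooccurrence_pct = as.list(panRes$cooccurrence))
    res$panthos <- panRes
  }
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Pairwise condition comparison report
#'
#' Mean +/- s.e.m. per condition and two-tailed unpaired Student's t-tests
#' on per-neuron metrics (pa-AL/AL counts and sizes), for every pair of the
#' supplied conditions.
#'
#' @param metricsList named list of per-neuron metric data.frames (from
#'   [analyzeCohort()] or read from `neuron_metrics.csv`).
#' @param metrics metric columns to compare.
#' @param outdir optional directory to write `report.csv` / `report.json`.
#' @return data.frame of comparisons.
#' @export
runReport <- function(metricsList,
                      metrics = c("n_paAL", "n_AL", "area_paAL", "area_AL"),
                      outdir = NULL) {
  if (length(metricsList) < 2) stop("need at least two analyzed conditions")
  if (is.null(names(metricsList)) || any(names(metricsList) == "")) {
    names(metricsList) <- paste0("condition", seq_along(metricsList))
  }
  out <- NULL
  cmb <- utils::combn(names(metricsList), 2)
  for (j in seq_len(ncol(cmb))) {
    a <- cmb[1, j]; b <- cmb[2, j]
    for (m in metrics) {
      for (nm in c(a, b)) {
        if (!m %in% names(metricsList[[nm]])) {
          stop("metric column '", m, "' missing from condition '", nm, "'")
        }
      }
      tt <- unpairedTTest(metricsList[[a]][[m]], metricsList[[b]][[m]])
      out <- rbind(out, data.frame(
        metric = m, groupA = a, groupB = b,
        meanA = tt$meanA, semA = tt$semA, nA = tt$nA,
        meanB = tt$meanB, semB = tt$semB, nB = tt$nB,
        t = tt$t, df = tt$df, p = tt$p))
    }
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(outdir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(out, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
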