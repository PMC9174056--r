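panCfg <- function() {
  pipelineConfig(detection = detectionParams(maxDiameter = 4), panthos = TRUE)
}

test_that("a stage-iii rosette is detected, staged and bleb-counted", {
  f <- simulateField(getPreset("panthos-2.7mo"), 1, seed = 51, stage = "iii")
  res <- analyzeField(f, panCfg())
  les <- res$panthos$lesions
  expect_equal(nrow(les), 1)
  expect_equal(les$stage, "iii")
  expect_lte(abs(les$n_blebs - f@neurons$n_blebs[1]), 1)
  expect_gte(les$n_paAL, 20)
  expect_lt(les$core_frac, 0.5)
  # detection is deterministic and idempotent
  res2 <- analyzeField(f, panCfg())
  expect_identical(res$panthos$lesions, res2$panthos$lesions)
  expect_identical(res$panthos$labels, res2$panthos$labels)
})

test_that("healthy control fields yield zero lesion calls", {
  f <- simulateField(getPreset("trgl-ctrl"), nNeurons = 9, seed = 52)
  res <- analyzeField(f, pipelineConfig(panthos = TRUE))
  expect_equal(nrow(res$panthos$lesions), 0)
})

test_that("per-stage calls agree with ground truth on a mixed cohort", {
  p <- getPreset("panthos-2.7mo")
  stages <- rep(c("i", "ii", "iii"), times = c(5, 5, 8))
  got <- character(0)
  for (i in seq_along(stages)) {
    f <- simulateField(p, 1, seed = 700 + i, stage = stages[i])
    res <- analyzeField(f, panCfg())
    got <- c(got, if (nrow(res$panthos$lesions)) res$panthos$lesions$stage[1]
                  else "none")
  }
  expect_gte(mean(got == stages), 0.9)
})

test_that("DAPI status recovers the generated nuclear state", {
  p <- getPreset("panthos-2.7mo")
  for (state in c("normal", "condensed", "absent")) {
    p$panthos$dapi <- list(normal = 0, condensed = 0, absent = 0)
    p$panthos$dapi[[state]] <- 1
    f <- simulateField(p, 1, seed = 53, stage = "iii")
    res <- analyzeField(f, panCfg())
    expect_equal(dapiStatus(res$panthos$lesions[1, ], f), state)
  }
})

test_that("amyloid signal fraction has the documented extremes", {
  p <- getPreset("panthos-2.7mo")
  p$panthos$p_isolated_plaque <- 0
  f <- simulateField(p, 1, seed = 54, stage = "iii")
  res <- analyzeField(f, panCfg())
  # all amyloid rendered inside the single lesion
  expect_gt(amyloidSignalFraction(f, res$panthos), 0.97)
  expect_lte(amyloidSignalFraction(f, res$panthos), 1)
  # no lesions at all: fraction 0
  empty <- list(labels = matrix(0L, dim(f)[1], dim(f)[2]))
  expect_equal(amyloidSignalFraction(f, empty), 0)
  # no amyloid signal: undefined and flagged
  g <- f
  g@data[, , match("Abeta", channelNames(f))] <- 0
  expect_warning(out <- amyloidSignalFraction(g, res$panthos), "undefined")
  expect_true(is.na(out))
})

test_that("lesion-plaque correspondence matches construction", {
  p <- getPreset("panthos-2.7mo")
  p$panthos$p_isolated_plaque <- 0
  f <- simulateField(p, 1, seed = 55, stage = "iii")
  res <- analyzeField(f, panCfg())
  plq <- segmentPlaques(f)
  corr <- lesionPlaqueCorrespondence(res$panthos, plq)
  expect_equal(corr$fracPanthosAmyloidPos, 1)
  expect_equal(corr$fracPlaquesWithPanthos, 1)
  # plaques with no lesions: zero correspondence
  empty <- list(labels = matrix(0L, dim(f)[1], dim(f)[2]),
                lesions = data.frame())
  corr0 <- lesionPlaqueCorrespondence(empty, plq)
  expect_equal(corr0$fracPlaquesWithPanthos, 0)
})

test_that("marker co-occurrence is area-gated within lesion confines", {
  f <- simulateField(getPreset("panthos-6mo"), 1, seed = 56, stage = "iii")
  res <- analyzeField(f, panCfg())
  everywhere <- matrix(TRUE, dim(f)[1], dim(f)[2])
  expect_equal(cooccurrenceFraction(f, res$panthos,
                                    markerMask = everywhere)$percent, 100)
  nowhere <- matrix(FALSE, dim(f)[1], dim(f)[2])
  expect_equal(cooccurrenceFraction(f, res$panthos,
                                    markerMask = nowhere)$percent, 0)
  noLesions <- list(labels = matrix(0L, dim(f)[1], dim(f)[2]))
  expect_warning(out <- cooccurrenceFraction(f, noLesions,
                                             markerMask = everywhere),
                 "undefined")
  expect_true(is.na(out$percent))
})

test_that("lesion masks are disjoint and fractions bounded", {
  fields <- simulateCohort("panthos-2.7mo", 4, seed = 57)
  for (f in fields) {
    res <- analyzeField(f, panCfg())
    lab <- res$panthos$labels
    # one label per pixel by construction; check ids are consecutive
    expect_true(all(sort(unique(as.integer(lab))) %in%
                      0:nrow(res$panthos$lesions)))
    if ("Abeta" %in% channelNames(f)) {
      fr <- amyloidSignalFraction(f, res$panthos)
      expect_true(is.na(fr) || (fr >= 0 && fr <= 1))
    }
  }
})

test_that("line profiles interpolate bilinearly", {
  arr <- array(0.3, c(40, 40, 1))
  x <- new("ChannelStack", data = arr, channels = "mRFP", pixelSize = 0.5)
  lp <- lineProfile(x, c(2, 10), c(18, 10), step = 0.5)
  expect_true(all(abs(lp$intensity[, 1] - 0.3) < 1e-12))
  # horizontal gradient image: linear profile
  grad <- array(rep(seq(0, 1, length.out = 40), each = 40), c(40, 40, 1))
  g <- new("ChannelStack", data = grad, channels = "mRFP", pixelSize = 0.5)
  lp2 <- lineProfile(g, c(2, 10), c(18, 10), step = 0.5)
  d <- diff(lp2$intensity[, 1])
  expect_true(all(abs(d - d[1]) < 1e-9))
  expect_error(lineProfile(x, c(-5, 10), c(18, 10)), "inside")
})
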