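test_that("the decision table maps hue, marker and LC3 status to classes", {
  # purple (red hue + marker) and plain red are both acidified ALs
  expect_equal(classifyVesicle(10, 100, marker = TRUE, lc3 = TRUE), "AL")
  expect_equal(classifyVesicle(350, 100, marker = FALSE, lc3 = TRUE), "AL")
  # white (yellow hue + marker) is pa-AL; yellow without marker is AP
  expect_equal(classifyVesicle(60, 100, marker = TRUE, lc3 = TRUE), "paAL")
  expect_equal(classifyVesicle(60, 100, marker = FALSE, lc3 = TRUE), "AP")
  # marker without LC3 is a lysosome
  expect_equal(classifyVesicle(NA, 0, marker = TRUE, lc3 = FALSE), "LY")
  # outside any sector, low saturation, or nothing positive: unclassified
  expect_equal(classifyVesicle(120, 100, marker = FALSE, lc3 = TRUE),
               "unclassified")
  expect_equal(classifyVesicle(60, 5, marker = FALSE, lc3 = TRUE),
               "unclassified")
  expect_equal(classifyVesicle(NA, 0, marker = FALSE, lc3 = FALSE),
               "unclassified")
})

test_that("every punctum receives exactly one class over the whole hue wheel", {
  set.seed(12)
  hues <- runif(500, 0, 360)
  for (mk in c(TRUE, FALSE)) {
    k <- classifyVesicle(hues, 100, marker = mk, lc3 = TRUE)
    expect_true(all(k %in% c("AP", "AL", "paAL", "LY", "unclassified")))
    expect_equal(length(k), 500)
  }
})

test_that("an LY-only field yields no AP/AL/pa-AL calls", {
  p <- testPreset(counts = list(AP = 0, AL = 0, paAL = 0, LY = 4))
  f <- simulateField(p, nNeurons = 4, seed = 14, noise = FALSE)
  res <- analyzeField(f)
  expect_true(all(res$calls$klass %in% c("LY", "unclassified")))
  expect_gt(sum(res$calls$klass == "LY"), 0)
})

test_that("chloroquine de-acidification turns ALs into pa-AL calls", {
  f <- simulateField(getPreset("cq"), nNeurons = 9, seed = 15)
  res <- analyzeField(f)
  n <- table(factor(res$calls$klass, c("AP", "AL", "paAL", "LY",
                                       "unclassified")))
  expect_gt(n[["paAL"]], 3 * n[["AL"]])
})

test_that("marker-channel handling follows the two-channel contract", {
  f <- simulateField(testPreset(channels = c("mRFP", "eGFP")), nNeurons = 2,
                     seed = 16, noise = FALSE)
  # marker-dependent analysis on a two-channel image: clean error
  expect_error(analyzeField(f), "two-channel")
  # explicit two-channel mode: yellow puncta are indeterminate, red are AL
  res <- analyzeField(f, pipelineConfig(markerChannel = NA))
  expect_true(all(res$calls$klass %in% c("AL", "unclassified")))
})

test_that("noise-free class labels equal simulator ground truth field-wide", {
  p <- testPreset()
  f <- simulateField(p, nNeurons = 6, seed = 18, noise = FALSE, psf = FALSE)
  res <- analyzeField(f)
  gt <- groundTruth(f)
  m <- matchCalls(f, res$calls)
  expect_true(all(!is.na(m)))
  expect_equal(res$calls$klass[m], gt$class)
})
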