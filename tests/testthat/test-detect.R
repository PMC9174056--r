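test_that("noise-free fields give exactly k puncta with tight centroids and areas", {
  p <- testPreset()
  f <- simulateField(p, nNeurons = 4, seed = 31, noise = FALSE, psf = FALSE)
  det <- detectPuncta(f)
  gt <- groundTruth(f)
  expect_equal(nrow(det$puncta), nrow(gt))
  m <- matchCalls(f, det$puncta, tolUm = 0.5)
  expect_true(all(!is.na(m)))
  px <- pixelSize(f)
  dx <- (det$puncta$x[m] + 0.5) * px - gt$x_um
  dy <- (det$puncta$y[m] + 0.5) * px - gt$y_um
  expect_true(all(sqrt(dx^2 + dy^2) <= px * 1.001))  # within one pixel
  # measured area within the +/- 1-pixel-ring discretization bound of pi r^2
  ring <- 2 * pi * gt$radius_um * px + pi * px^2
  expect_true(all(abs(det$puncta$area_um2[m] - pi * gt$radius_um^2) <= ring))
})

test_that("blank and empty inputs behave as documented", {
  blank <- new("ChannelStack",
               data = array(0.5, c(60, 60, 2)),
               channels = c("mRFP", "eGFP"), pixelSize = 0.1)
  det <- detectPuncta(blank)
  expect_equal(nrow(det$puncta), 0)
  bad <- blank
  bad@pixelSize <- 0.1
  bad@pixelSize <- NaN
  expect_error(detectPuncta(bad), "pixel size")
})

test_that("two vesicles separated by more than one PSF sigma split into two puncta", {
  p <- testPreset(counts = list(AP = 0, AL = 0, paAL = 0, LY = 0))
  g <- p$geometry
  mk <- function(sep) {
    spec <- list(stage = "none", soma_radius = g$soma_radius,
                 nucleus_radius = g$nucleus_radius, dapi_state = "normal",
                 amyloid = FALSE, thioS = FALSE, gfap = FALSE, ibai = FALSE,
                 blebs = data.frame(angle = numeric(), neck = numeric(),
                                    radius = numeric()),
                 vesicles = data.frame(
                   class = c("AL", "AL"), pH = 4.8, radius = 0.45,
                   lc3_load = 1, marker_ctsd = TRUE, abeta_positive = FALSE,
                   pla_positive = FALSE, dx = c(-sep / 2, sep / 2), dy = 0))
    renderField(p, list(spec), cbind(12, 12), c(24, 24), noise = FALSE,
                psf = TRUE)
  }
  # gap between edges > 1 PSF sigma (0.15 um)
  f <- mk(2 * 0.45 + 0.35)
  expect_equal(nrow(detectPuncta(f)$puncta), 2)
})

test_that("detection is translation-equivariant for whole-pixel shifts", {
  p <- testPreset()
  f <- simulateField(p, nNeurons = 1, seed = 33, noise = FALSE)
  shift <- 7L
  arr <- f@data
  arr2 <- array(f@data[1, 1, 1], dim(arr))
  arr2[, (shift + 1):dim(arr)[2], ] <- arr[, 1:(dim(arr)[2] - shift), ]
  g <- new("ChannelStack", data = arr2, channels = f@channels,
           pixelSize = f@pixelSize)
  d1 <- detectPuncta(f)$puncta
  d2 <- detectPuncta(g)$puncta
  # drop any punctum too close to the pasted-in border
  keep <- d1$x < dim(arr)[2] - shift - 5
  expect_equal(nrow(d2), sum(keep))
  o1 <- order(d1$y[keep], d1$x[keep])
  o2 <- order(d2$y, d2$x)
  expect_equal(d2$x[o2], d1$x[keep][o1] + shift, tolerance = 1e-9)
  expect_equal(d2$y[o2], d1$y[keep][o1], tolerance = 1e-9)
})

test_that("intensity measurement subtracts the local background", {
  # uniform synthetic channel: mean over the mask minus annulus median
  arr <- array(0.2, c(50, 50, 2))
  arr[21:30, 21:30, 1] <- 0.9
  x <- new("ChannelStack", data = arr, channels = c("mRFP", "eGFP"),
           pixelSize = 0.1)
  det <- detectPuncta(x)
  expect_equal(nrow(det$puncta), 1)
  got <- measureIntensities(x, det)
  expect_equal(got$eGFP, 0, tolerance = 1e-9)           # background only
  expect_gt(got$mRFP, 0.6)                              # 0.9 - 0.2 ~ 0.7
  expect_lt(abs(got$mRFP - 0.7), 0.05)
})

test_that("neuron assignment uses the centroid label and validates shapes", {
  puncta <- data.frame(id = 1:2, x = c(10, 40), y = c(10, 40))
  lab <- matrix(0L, 50, 50)
  lab[5:15, 5:15] <- 7L
  out <- assignToNeurons(puncta, lab)
  expect_equal(out$neuron_id, c(7L, NA_integer_))
  f <- simulateField(testPreset(), nNeurons = 4, seed = 31, noise = FALSE)
  expect_error(analyzeField(f, neuronLabels = matrix(0L, 5, 5)), "shape")
  # per-neuron counts equal ground truth (noise off)
  res <- analyzeField(f)
  gt <- groundTruth(f)
  for (id in unique(gt$neuron_id)) {
    expect_equal(sum(res$calls$neuron_id == id, na.rm = TRUE),
                 sum(gt$neuron_id == id))
  }
})
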