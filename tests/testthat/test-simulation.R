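test_that("sampled neurons respect the class invariants", {
  set.seed(1)
  p <- testPreset()
  for (i in 1:20) {
    s <- sampleNeuron(p)
    v <- s$vesicles
    expect_true(all(!v$marker_ctsd[v$class == "AP"]))
    expect_true(all(v$marker_ctsd[v$class %in% c("AL", "paAL", "LY")]))
    expect_true(all(v$lc3_load[v$class == "LY"] == 0))
    expect_true(all(v$radius > 0))
    # placement: inside the soma annulus, pairwise non-overlapping
    r <- sqrt(v$dx^2 + v$dy^2)
    expect_true(all(r + v$radius <= s$soma_radius))
    expect_true(all(r - v$radius >= s$nucleus_radius))
    if (nrow(v) > 1) {
      d <- as.matrix(dist(cbind(v$dx, v$dy)))
      sep <- outer(v$radius, v$radius, "+")
      expect_true(all(d[upper.tri(d)] > sep[upper.tri(sep)]))
    }
  }
})

test_that("an all-zero preset yields an empty neuron and crowding errors name the cause", {
  set.seed(2)
  p0 <- testPreset(counts = list(AP = 0, AL = 0, paAL = 0, LY = 0))
  expect_equal(nrow(sampleNeuron(p0)$vesicles), 0)
  # overfull soma cannot be packed
  pBig <- testPreset(counts = list(AP = 0, AL = 200, paAL = 0, LY = 0))
  expect_error(sampleNeuron(pBig), "crowding")
})

test_that("Monte-Carlo class counts converge to the preset Poisson means", {
  set.seed(3)
  p <- testPreset()
  n <- 3000
  counts <- vapply(seq_len(n), function(i) {
    v <- sampleNeuron(p)$vesicles
    c(sum(v$class == "paAL"), sum(v$class == "AL"))
  }, numeric(2))
  for (k in 1:2) {
    mu <- c(p$counts$paAL, p$counts$AL)[k]
    se <- sd(counts[k, ]) / sqrt(n)
    expect_lt(abs(mean(counts[k, ]) - mu), 3 * se + 1e-9)
  }
})

test_that("rendered color is the closed-form quench ratio and monotone in pH", {
  p <- testPreset(counts = list(AP = 0, AL = 0, paAL = 0, LY = 0),
                  background = 0)
  g <- p$geometry
  mkField <- function(pH) {
    spec <- list(stage = "none", soma_radius = g$soma_radius,
                 nucleus_radius = g$nucleus_radius, dapi_state = "normal",
                 amyloid = FALSE, thioS = FALSE, gfap = FALSE, ibai = FALSE,
                 blebs = data.frame(angle = numeric(), neck = numeric(),
                                    radius = numeric()),
                 vesicles = data.frame(
                   class = "AL", pH = pH, radius = 0.7, lc3_load = 1,
                   marker_ctsd = TRUE, abeta_positive = FALSE,
                   pla_positive = FALSE, dx = 0, dy = 0))
    renderField(p, list(spec), cbind(12, 12), c(24, 24), noise = FALSE,
                psf = FALSE)
  }
  f <- mkField(4.8)
  ctr <- round(12 / p$pixel_size)
  ratio <- getChannel(f, "eGFP")[ctr, ctr] / getChannel(f, "mRFP")[ctr, ctr]
  expect_equal(ratio, 1 / (1 + 10^1.2), tolerance = 1e-6)
  # green/red ratio (hence hue) is monotone in luminal pH
  pHs <- seq(3.5, 7.5, by = 0.5)
  ratios <- vapply(pHs, function(ph) {
    f <- mkField(ph)
    getChannel(f, "eGFP")[ctr, ctr] / getChannel(f, "mRFP")[ctr, ctr]
  }, 0)
  expect_true(all(diff(ratios) > 0))
  hues <- vapply(ratios, function(r) hueAngle(1, r, 0), 0)
  expect_true(all(diff(hues) > 0) && all(hues >= 0 & hues <= 60))
})

test_that("a fixed seed fixes every output bit", {
  f1 <- simulateField(testPreset(), nNeurons = 2, seed = 99)
  f2 <- simulateField(testPreset(), nNeurons = 2, seed = 99)
  expect_identical(f1@data, f2@data)
  expect_identical(groundTruth(f1), groundTruth(f2))
  expect_identical(f1@neuronLabels, f2@neuronLabels)
  f3 <- simulateField(testPreset(), nNeurons = 2, seed = 100)
  expect_false(identical(f1@data, f3@data))
})

test_that("PANTHOS neurons have the staged geometry", {
  set.seed(5)
  p <- getPreset("panthos-2.7mo")
  s1 <- makePanthosNeuron("i", p)
  expect_equal(nrow(s1$blebs), 0)
  s2 <- makePanthosNeuron("ii", p)
  expect_true(nrow(s2$blebs) %in% 1:2)
  s3 <- makePanthosNeuron("iii", p)
  expect_gte(nrow(s3$blebs), 6)
  expect_true(all(s3$vesicles$class == "paAL" | s3$vesicles$class == "AL"))
  expect_gt(mean(s3$vesicles$class == "paAL"), 0.8)
  # rendered stage-iii core is LC3-free: no signal above background
  f <- simulateField(p, 1, seed = 41, stage = "iii", noise = FALSE)
  ctrX <- f@neurons$x_um[1]; ctrY <- f@neurons$y_um[1]
  px <- pixelSize(f)
  core <- getChannel(f, "mRFP")[
    round(ctrY / px) + (-10:10), round(ctrX / px) + (-10:10)]
  expect_lt(max(core), p$background + 0.05)
})

test_that("the amyloid corona flanks the DAPI peak on a diametric profile", {
  p <- getPreset("panthos-2.7mo")
  p$panthos$p_amyloid <- 1
  p$panthos$dapi <- list(normal = 1, condensed = 0, absent = 0)
  f <- simulateField(p, 1, seed = 17, stage = "iii", noise = FALSE)
  cx <- f@neurons$x_um[1]; cy <- f@neurons$y_um[1]
  lp <- lineProfile(f, c(cx - 12, cy), c(cx + 12, cy), step = 0.1)
  dapi <- lp$intensity[, "DAPI"]; ab <- lp$intensity[, "Abeta"]
  ctr <- which.min(abs(lp$t_um - 12))     # path midpoint = nucleus center
  expect_gt(dapi[ctr], 0.5)               # DAPI peak at the center
  # amyloid is bimodal: both flanks exceed the level at the DAPI peak
  left <- max(ab[lp$t_um < lp$t_um[ctr] - 2])
  right <- max(ab[lp$t_um > lp$t_um[ctr] + 2])
  expect_gt(left, ab[ctr] + 0.2)
  expect_gt(right, ab[ctr] + 0.2)
})

test_that("rendering rejects channel lists inconsistent with vesicle flags", {
  p <- testPreset(p_abeta = list(AP = 0, AL = 0, paAL = 1, LY = 0))
  set.seed(8)
  expect_error(simulateField(p, nNeurons = 1, seed = 8), "Abeta")
})
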