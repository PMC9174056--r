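test_that("hue angle hits the primary and secondary color anchors", {
  expect_equal(hueAngle(1, 0, 0), 0)
  expect_equal(hueAngle(0, 1, 0), 120)
  expect_equal(hueAngle(0, 0, 1), 240)
  expect_equal(hueAngle(1, 1, 0), 60)
  expect_equal(hueAngle(1, 0, 1), 300)
  expect_equal(hueAngle(0, 1, 1), 180)
})

test_that("hue angle matches the spreadsheet arctangent semantics", {
  # oracle: direct evaluation with the spreadsheet two-argument arctangent,
  # which takes (x, y) = (2R - G - B, sqrt(3) (G - B))
  sheetHue <- function(R, G, B) {
    h <- atan2(sqrt(3) * (G - B), 2 * R - G - B) * 180 / pi  # R atan2(y, x)
    if (h < 0) h + 360 else h
  }
  expect_equal(hueAngle(200, 100, 50), sheetHue(200, 100, 50), tolerance = 1e-12)
  expect_equal(hueAngle(200, 100, 50), 19.1066, tolerance = 1e-4)
  expect_equal(hueAngle(120, 240, 60), 100.8934, tolerance = 1e-4)
  expect_error(hueAngle(0, 0, 0), "undefined")
})

test_that("hue is scale-invariant and rotates by 120 degrees with channels", {
  set.seed(4)
  for (i in 1:200) {
    v <- runif(3, 0.01, 5)
    h <- hueAngle(v[1], v[2], v[3])
    for (c in c(0.1, 3, 1234)) {
      expect_equal(hueAngle(c * v[1], c * v[2], c * v[3]), h,
                   tolerance = 1e-9)
    }
    # (R,G,B) -> (B,R,G) moves every channel one slot: +120 degrees mod 360
    expect_equal(hueAngle(v[3], v[1], v[2]) %% 360, (h + 120) %% 360,
                 tolerance = 1e-9)
  }
})

test_that("saturation matches its printed definition", {
  expect_equal(saturationPct(1, 1, 0)$saturation, 100)
  expect_equal(saturationPct(0.3, 0.3, 0.3)$saturation, 0)
  expect_equal(saturationPct(0.8, 0.4, 0.2)$saturation, 60)
  s0 <- saturationPct(0, 0, 0)
  expect_equal(s0$saturation, 0)
  expect_true(s0$lightness_ok)
  # lightness flag: (max + min) / 2 must stay below 1
  expect_false(saturationPct(1, 1, 1)$lightness_ok)
  expect_true(saturationPct(0.9, 0.5, 0.1)$lightness_ok)
})

test_that("saturation agrees with a direct arithmetic oracle on random triples", {
  set.seed(11)
  n <- 1e5
  R <- runif(n); G <- runif(n); B <- runif(n)
  got <- saturationPct(R, G, B)$saturation
  # element-wise literal translation of the printed formula
  oracle <- vapply(seq_len(n), function(i) {
    v <- c(R[i], G[i], B[i])
    (max(v) - min(v)) / (max(v) + min(v)) * 100
  }, 0)
  expect_equal(got, oracle, tolerance = 1e-12)
})
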