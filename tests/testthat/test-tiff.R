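test_that("TIFF round-trip preserves images and channel metadata", {
  set.seed(6)
  arr <- array(runif(40 * 30 * 3), c(40, 30, 3))
  x <- new("ChannelStack", data = arr, channels = c("mRFP", "eGFP", "CTSD"),
           pixelSize = 0.1)
  tf <- withr::local_tempfile(fileext = ".tif")
  writeTiffStack(x, tf)
  y <- readTiffStack(tf)
  expect_s4_class(y, "ChannelStack")
  expect_equal(channelNames(y), channelNames(x))
  expect_equal(pixelSize(y), 0.1)
  expect_equal(y@data, arr, tolerance = 1e-6)  # float32 quantization

  # 16-bit label image round-trips exactly
  lab <- matrix(sample(0:500, 40 * 30, replace = TRUE), 40, 30)
  writeTiffStack(matrix(as.numeric(lab), 40), tf, channels = "labels",
                 pixelSize = 0.1, dtype = "uint16")
  z <- readTiffStack(tf, asArray = TRUE)
  expect_identical(matrix(as.integer(z[, , 1]), 40), lab)
})

test_that("reader rejects what it cannot parse", {
  tf <- withr::local_tempfile(fileext = ".tif")
  writeBin(c(charToRaw("MM"), as.raw(0L), as.raw(42L)), tf)  # big-endian magic
  expect_error(readTiffStack(tf), "little-endian")
})
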