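# Shared fixtures: a downscaled preset for fast unit tests and a matcher
# that pairs detected puncta with simulated ground-truth vesicles.

# small vesicle complement, same optics as the packaged presets
testPreset <- function(counts = list(AP = 1.5, AL = 3, paAL = 3, LY = 2),
                       channels = c("mRFP", "eGFP", "CTSD"), ...) {
  p <- getPreset("trgl-ctrl")
  p$counts <- counts
  p$channels <- channels
  extra <- list(...)
  for (nm in names(extra)) p[[nm]] <- extra[[nm]]
  validatePreset(p)
}

# For each ground-truth vesicle, the index of the nearest detected punctum
# within tolUm (NA when unmatched). One punctum can match only one vesicle.
matchCalls <- function(field, calls, tolUm = 0.5) {
  gt <- groundTruth(field)
  px <- pixelSize(field)
  cx <- (calls$x + 0.5) * px
  cy <- (calls$y + 0.5) * px
  used <- rep(FALSE, nrow(calls))
  m <- rep(NA_integer_, nrow(gt))
  for (i in seq_len(nrow(gt))) {
    d <- sqrt((cx - gt$x_um[i])^2 + (cy - gt$y_um[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] < tolUm) {
      m[i] <- j
      used[j] <- TRUE
    }
  }
  m
}
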