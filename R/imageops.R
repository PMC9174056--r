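# Low-level image helpers shared by the simulator, the puncta detector and
# the lesion detector. All operate on plain numeric matrices [y, x].

gaussKernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur of a 2D image
#'
#' Separable Gaussian convolution with reflect boundary handling; used as the
#' optical PSF in the simulator and as the smoothing step of the detectors.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns `img`.
#' @return blurred matrix of the same shape.
#' @export
gaussBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussKernel(sigma)
  cpp_conv_sep(img, k, k)
}

# Scale-normalized negative Laplacian-of-Gaussian response (bright blobs give
# positive peaks). sigma in pixels.
logResponse <- function(img, sigma) {
  -sigma^2 * cpp_laplace(gaussBlur(img, sigma))
}

# Fill holes of a binary mask: background components not touching the border
# are holes.
fillHoles <- function(mask) {
  lab <- cpp_label4(!mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  mask | (lab > 0 & !(lab %in% border))
}

# Morphological closing (dilate then erode) with a disk of radius r pixels.
binaryClose <- function(mask, r) {
  if (r <= 0) return(mask)
  cpp_erode(cpp_dilate(mask, as.integer(r)), as.integer(r))
}

# Otsu threshold on a numeric matrix (256-bin histogram between min and max).
otsuThreshold <- function(img) {
  v <- as.numeric(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(256L, 1L + floor(255 * (v - rng[1]) / diff(rng))), 256L)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(256) - 0.5) / 256 * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[256]
  between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Robust background statistics (median, MAD) of the pixels of a channel
# outside a foreground mask.
robustBgStats <- function(channel, fgMask = NULL) {
  v <- if (is.null(fgMask)) as.numeric(channel) else channel[!fgMask]
  if (length(v) == 0) v <- as.numeric(channel)
  list(median = stats::median(v), mad = stats::mad(v))
}

# Distance from each pixel of a [y, x] grid window to a point (in pixel
# coordinates, 1-based centers).
pixelDisk <- function(ny, nx, cy, cx, r) {
  ys <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r))
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  list(ys = ys, xs = xs, inside = d2 <= r^2, d2 = d2)
}
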