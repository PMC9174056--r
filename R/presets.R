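.vesicleClasses <- c("AP", "AL", "paAL", "LY")

# Per-class truncation bounds for luminal pH. pa-AL is by definition above
# the eGFP quench point (it fluoresces yellow/white), AL below it; the
# bounds keep the stated world consistent with the color-to-class mapping.
.defaultPHBounds <- list(
  AP   = c(6.5, 7.5),
  paAL = c(6.4, 7.5),
  AL   = c(3.5, 5.8),
  LY   = c(3.5, 5.8)
)

#' List packaged simulation presets
#'
#' @return character vector of preset names that [getPreset()] resolves.
#' @export
listPresets <- function() {
  dir <- system.file("extdata", "presets", package = "panthoscope")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

#' Load and validate a simulation preset
#'
#' Presets are YAML files describing the stated experimental world the
#' simulator renders: per-neuron class-count Poisson means, log-normal
#' vesicle sizes, per-class luminal pH distributions, colocalization
#' probabilities, PANTHOS stage mix and co-label probabilities, plus optics
#' (pixel size, PSF sigma, noise).
#'
#' @param name a packaged preset name (see [listPresets()]) or a path to a
#'   YAML file.
#' @return a validated preset (named list, class `"panthoscopePreset"`).
#' @export
getPreset <- function(name) {
  path <- if (file.exists(name)) name else {
    system.file("extdata", "presets", paste0(name, ".yaml"),
                package = "panthoscope")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown preset '", name, "'; packaged presets: ",
         paste(listPresets(), collapse = ", "))
  }
  p <- yaml::read_yaml(path)
  validatePreset(p)
}

#' @rdname getPreset
#' @param preset a preset list to validate.
#' @export
validatePreset <- function(preset) {
  need <- c("name", "channels", "pixel_size", "counts", "size_um2",
            "pH_mean", "pH_sd")
  miss <- setdiff(need, names(preset))
  if (length(miss)) stop("preset is missing fields: ", paste(miss, collapse = ", "))
  if (preset$pixel_size <= 0) stop("pixel_size must be positive")
  if (!all(c("mRFP", "eGFP") %in% preset$channels)) {
    stop("preset channels must include mRFP and eGFP")
  }
  for (k in .vesicleClasses) {
    if (is.null(preset$counts[[k]])) stop("counts missing class ", k)
    if (preset$counts[[k]] < 0) stop("counts must be >= 0")
    if (is.null(preset$size_um2[[k]]) || preset$size_um2[[k]] <= 0) {
      stop("size_um2 must be positive for class ", k)
    }
  }
  for (fld in c("p_abeta", "p_pla")) {
    if (is.null(preset[[fld]])) {
      preset[[fld]] <- as.list(stats::setNames(rep(0, 4), .vesicleClasses))
    }
    pr <- unlist(preset[[fld]])
    if (any(pr < 0 | pr > 1)) stop(fld, " probabilities must lie in [0, 1]")
  }
  # defaults
  preset$psf_sigma <- preset$psf_sigma %||% 0.15
  preset$noise <- preset$noise %||% TRUE
  preset$read_noise_sd <- preset$read_noise_sd %||% 0.02
  preset$photons_full_scale <- preset$photons_full_scale %||% 400
  preset$background <- preset$background %||% 0.02
  preset$size_cv <- preset$size_cv %||% 0.25
  preset$geometry <- preset$geometry %||% list()
  preset$geometry$soma_radius <- preset$geometry$soma_radius %||% 10
  preset$geometry$nucleus_radius <- preset$geometry$nucleus_radius %||% 4
  preset$geometry$tile <- preset$geometry$tile %||% 24
  if (preset$geometry$nucleus_radius >= preset$geometry$soma_radius) {
    stop("nucleus_radius must be smaller than soma_radius")
  }
  preset$panthos <- preset$panthos %||% list()
  preset$panthos$stage_mix <- preset$panthos$stage_mix %||%
    list(none = 1, i = 0, ii = 0, iii = 0)
  sm <- unlist(preset$panthos$stage_mix)
  if (any(sm < 0) || sum(sm) <= 0) stop("stage_mix must be non-negative")
  for (fld in c("p_amyloid", "p_thioS", "p_gfap", "p_ibai",
                "p_isolated_plaque")) {
    preset$panthos[[fld]] <- preset$panthos[[fld]] %||% 0
    if (preset$panthos[[fld]] < 0 || preset$panthos[[fld]] > 1) {
      stop(fld, " must lie in [0, 1]")
    }
  }
  preset$panthos$dapi <- preset$panthos$dapi %||%
    list(normal = 1, condensed = 0, absent = 0)
  # per-class pH truncation bounds
  bounds <- .defaultPHBounds
  for (k in .vesicleClasses) {
    if (!is.null(preset$pH_lo[[k]])) bounds[[k]][1] <- preset$pH_lo[[k]]
    if (!is.null(preset$pH_hi[[k]])) bounds[[k]][2] <- preset$pH_hi[[k]]
  }
  preset$pH_bounds <- bounds
  class(preset) <- c("panthoscopePreset", "list")
  preset
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.panthoscopePreset <- function(x, ...) {
  cat("panthoscope preset '", x$name, "'\n", sep = "")
  cat("  channels:", paste(x$channels, collapse = ", "),
      " pixel:", x$pixel_size, "um\n")
  cnt <- unlist(x$counts)
  cat("  class count means:",
      paste(names(cnt), signif(cnt, 3), sep = "=", collapse = ", "), "\n")
  sm <- unlist(x$panthos$stage_mix)
  cat("  stage mix:", paste(names(sm), sm, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
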