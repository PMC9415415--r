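#' Define a soil line
#'
#' The soil line is the linear relation between near-infrared (B8A) and red
#' (B4) reflectance of bare soil; its slope calibrates the weighted difference
#' vegetation index WDVI = B8A - a * B4, which is zero for bare soil and
#' positive under vegetation.
#'
#' @param slope_a Slope of the soil line (B8A per B4), positive.
#' @param intercept Reflectance intercept (default 0).
#' @return A list of class `"soil_line"`.
#' @export
soil_line <- function(slope_a, intercept = 0) {
  if (!is.numeric(slope_a) || length(slope_a) != 1 || slope_a <= 0) {
    stop("soil-line slope must be a single positive number")
  }
  structure(list(slope_a = slope_a, intercept = intercept), class = "soil_line")
}

#' @export
print.soil_line <- function(x, ...) {
  cat(sprintf("Soil line: B8A = %.4f * B4 + %.4f\n", x$slope_a, x$intercept))
  invisible(x)
}

#' Soil and vegetation endmember spectra
#'
#' The synthetic generator represents each pixel as a linear mixture of a
#' bare-soil spectrum and a green-vegetation spectrum, weighted by fractional
#' canopy cover, with additive Gaussian band noise. The default soil spectrum
#' lies exactly on the default soil line (slope 1.62: B8A = 0.324 = 1.62 x
#' 0.20), and the default vegetation spectrum has the strong red absorption /
#' NIR plateau of a healthy canopy (NDVI ~ 0.84).
#'
#' Canopies of different species differ spectrally (leaf structure, canopy
#' water, chlorophyll), which is what makes crops distinguishable at equal
#' cover; `vegetation_offsets` encodes those per-crop differences as additive
#' band offsets on the vegetation endmember, scaled by `class_separation`
#' (1 = the default species contrast, 0 = a single shared canopy spectrum).
#'
#' @param soil Named band vector of the bare-soil endmember.
#' @param vegetation Named band vector of the full-canopy endmember.
#' @param noise_sd Per-band Gaussian noise standard deviation (reflectance).
#' @param vegetation_offsets Named list (crop -> band offset vector) of
#'   per-crop deviations from the base vegetation endmember; see
#'   [default_vegetation_offsets()].
#' @param class_separation Multiplier on the offsets, >= 0.
#' @return A list of class `"endmember_spectra"`.
#' @export
endmember_spectra <- function(
    soil = c(B2 = 0.12, B3 = 0.16, B4 = 0.20, B5 = 0.23, B6 = 0.26,
             B7 = 0.28, B8A = 0.324, B11 = 0.40, B12 = 0.35),
    vegetation = c(B2 = 0.03, B3 = 0.06, B4 = 0.04, B5 = 0.08, B6 = 0.25,
                   B7 = 0.35, B8A = 0.45, B11 = 0.20, B12 = 0.10),
    noise_sd = 0.01,
    vegetation_offsets = default_vegetation_offsets(),
    class_separation = 1) {
  soil <- drop(as_band_matrix(soil))
  vegetation <- drop(as_band_matrix(vegetation))
  if (any(soil < 0 | soil > 1) || any(vegetation < 0 | vegetation > 1)) {
    stop("endmember reflectances must lie in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (class_separation < 0) stop("class_separation must be non-negative")
  structure(list(soil = soil, vegetation = vegetation, noise_sd = noise_sd,
                 vegetation_offsets = vegetation_offsets,
                 class_separation = class_separation),
            class = "endmember_spectra")
}

#' Default per-crop canopy spectral offsets
#'
#' Qualitative species contrasts at full cover: corn (a tall C4 grass) with a
#' brighter NIR plateau and higher shortwave infrared; alfalfa (a dense, dark
#' legume canopy with high water content) with depressed NIR and SWIR; bean a
#' lighter-green legume close to the base canopy. "Other" crops use the base
#' vegetation endmember unchanged.
#'
#' @return Named list of band offset vectors (reflectance units).
#' @export
default_vegetation_offsets <- function() {
  zero <- stats::setNames(rep(0, 9), band_names())
  off <- function(...) {
    v <- zero
    d <- c(...)
    v[names(d)] <- d
    v
  }
  list(
    corn = off(B5 = 0.010, B6 = 0.020, B7 = 0.020, B8A = 0.030,
               B11 = 0.020, B12 = 0.010),
    alfalfa = off(B2 = -0.005, B3 = -0.010, B4 = -0.005, B8A = -0.030,
                  B11 = -0.030, B12 = -0.020),
    bean = off(B3 = 0.010, B5 = 0.010, B11 = 0.010),
    other = zero
  )
}

#' Vegetation endmember for a given crop
#'
#' Applies the crop's spectral offset (scaled by `class_separation`) to the
#' base vegetation endmember, clipped to \[0, 1\]. Crops without an offset
#' entry use the base endmember.
#'
#' @param spectra An [endmember_spectra()].
#' @param crop Crop label.
#' @return Named band vector.
#' @export
crop_vegetation <- function(spectra, crop) {
  stopifnot(inherits(spectra, "endmember_spectra"))
  veg <- spectra$vegetation
  off <- spectra$vegetation_offsets[[crop]]
  if (!is.null(off)) {
    veg <- veg + spectra$class_separation * off[names(veg)]
  }
  pmin(pmax(veg, 0), 1)
}

#' Mix soil and vegetation spectra for a given canopy cover
#'
#' Per band, reflectance = (1 - cover) * soil + cover * vegetation plus
#' Gaussian noise (sd `spectra$noise_sd`), clipped to \[0, 1\]. With
#' `cover = 0` and zero noise this returns the soil endmember exactly; with
#' `cover = 1`, the vegetation endmember.
#'
#' @param cover Fractional canopy cover, vectorized, each value in \[0, 1\].
#' @param spectra An [endmember_spectra()].
#' @param seed Optional integer seed for the noise draw.
#' @param vegetation Optional vegetation endmember override (e.g. a
#'   [crop_vegetation()] result); defaults to the base endmember.
#' @return A matrix with one row per cover value and the nine band columns.
#' @export
mix_reflectance <- function(cover, spectra, seed = NULL, vegetation = NULL) {
  stopifnot(inherits(spectra, "endmember_spectra"))
  if (any(cover < 0 | cover > 1)) stop("cover must lie in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(cover)
  bn <- band_names()
  vegetation <- vegetation %||% spectra$vegetation
  refl <- outer(1 - cover, spectra$soil) + outer(cover, vegetation)
  if (spectra$noise_sd > 0) {
    refl <- refl + matrix(stats::rnorm(n * length(bn), 0, spectra$noise_sd),
                          nrow = n)
  }
  refl <- pmin(pmax(refl, 0), 1)
  colnames(refl) <- bn
  refl
}

#' Generate bare-soil plot spectra on a soil line
#'
#' Draws `n` bare-soil band vectors whose noiseless B8A/B4 ratio equals the
#' requested soil-line slope, with brightness varying between plots (a common
#' property of real soils: points slide along the soil line) and additive
#' Gaussian band noise. Used to exercise the soil-line slope estimator.
#'
#' @param n Number of plots.
#' @param line A [soil_line()] the noiseless spectra must satisfy.
#' @param spectra An [endmember_spectra()] supplying the base soil spectrum;
#'   its B8A value is replaced by `slope_a * B4` so the constraint holds.
#' @param noise_sd Gaussian noise sd added per band.
#' @param brightness_range Multiplicative brightness span (uniform).
#' @param seed Integer seed.
#' @return A matrix of `n` band vectors.
#' @export
simulate_bare_plots <- function(n, line = soil_line(1.62),
                                spectra = endmember_spectra(),
                                noise_sd = 0.005,
                                brightness_range = c(0.8, 1.2), seed = 1) {
  stopifnot(inherits(line, "soil_line"), n >= 1)
  base <- spectra$soil
  base["B8A"] <- line$slope_a * base["B4"]
  set.seed(as.integer(seed))
  bright <- stats::runif(n, brightness_range[1], brightness_range[2])
  refl <- outer(bright, base)
  if (noise_sd > 0) {
    refl <- refl + matrix(stats::rnorm(n * length(base), 0, noise_sd), nrow = n)
  }
  refl <- pmin(pmax(refl, 0), 1)
  colnames(refl) <- band_names()
  refl
}
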