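#' Zonal mean of pixel band vectors
#'
#' Averages the pixels of one sampling unit (a cluster of 8-10 pixels or a
#' whole plot polygon) band by band, producing the per-plot reflectance used
#' everywhere downstream.
#'
#' @param pixel_vectors A matrix or data.frame of pixel band vectors (one row
#'   per pixel, nine band columns), or a single named band vector.
#' @return Named numeric band vector of per-band arithmetic means.
#' @export
zonal_mean <- function(pixel_vectors) {
  m <- as_band_matrix(pixel_vectors)
  if (nrow(m) == 0) stop("empty sampling unit: no pixels to average")
  colMeans(m)
}

#' Normalized Difference Vegetation Index
#'
#' NDVI = (B8A - B4) / (B8A + B4), bounded in \[-1, 1\]. A zero denominator is
#' treated as corrupt input (physically impossible for atmospherically
#' corrected surface reflectance) and raises an error.
#'
#' @param b8a,b4 Near-infrared and red reflectance (vectorized), or `b8a` may
#'   be a named band vector / band table with `b4` missing.
#' @return NDVI value(s).
#' @export
compute_ndvi <- function(b8a, b4 = NULL) {
  if (is.null(b4)) {
    m <- as_band_matrix(b8a)
    b8a <- m[, "B8A"]
    b4 <- m[, "B4"]
  }
  s <- b8a + b4
  if (any(s == 0)) stop("undefined NDVI: B8A + B4 = 0")
  (b8a - b4) / s
}

#' Weighted Difference Vegetation Index
#'
#' WDVI = B8A - a * B4, with `a` the soil-line slope. Zero for bare soil on
#' the soil line, positive with vegetation cover; used as the emergence
#' indicator.
#'
#' @param b8a,b4 Reflectances (vectorized), or `b8a` a band vector/table with
#'   `b4` missing.
#' @param line A [soil_line()].
#' @return WDVI value(s).
#' @export
compute_wdvi <- function(b8a, b4 = NULL, line = soil_line(1.62)) {
  if (inherits(b4, "soil_line")) { # compute_wdvi(band_vector, line)
    line <- b4
    b4 <- NULL
  }
  stopifnot(inherits(line, "soil_line"))
  if (is.null(b4)) {
    m <- as_band_matrix(b8a)
    b8a <- m[, "B8A"]
    b4 <- m[, "B4"]
  }
  b8a - line$slope_a * b4
}

#' Estimate the soil-line slope from bare plots
#'
#' Ratio-of-sums estimator: a = sum(B8A_i) / sum(B4_i) over the plots without
#' crop. This is the printed form (not a per-plot average of ratios and not a
#' least-squares slope); it is exact whenever every plot lies on the line and
#' is scale-invariant under a common brightness factor.
#'
#' @param bare_plots Matrix/data.frame of bare-plot band vectors (or at least
#'   columns `B8A` and `B4`), or a single named band vector.
#' @return A [soil_line()] with the estimated slope.
#' @export
estimate_soil_line <- function(bare_plots) {
  if (is.data.frame(bare_plots)) bare_plots <- as.matrix(bare_plots)
  if (is.numeric(bare_plots) && !is.matrix(bare_plots)) {
    bare_plots <- matrix(bare_plots, nrow = 1,
                         dimnames = list(NULL, names(bare_plots)))
  }
  if (!all(c("B8A", "B4") %in% colnames(bare_plots))) {
    stop("bare_plots must provide columns B8A and B4")
  }
  if (nrow(bare_plots) == 0) stop("no bare plots supplied")
  s4 <- sum(bare_plots[, "B4"])
  if (s4 <= 0) stop("zero red-band sum: cannot estimate soil line")
  soil_line(sum(bare_plots[, "B8A"]) / s4)
}

#' Vegetation-emergence decision
#'
#' A plot counts as emerged when its WDVI is at or above the threshold;
#' strictly smaller values indicate no standing crop (bare, pre-emergence or
#' harvested) and the record is eliminated from the database. The default
#' threshold of 0.005 (unit reflectance scale) corresponds to the first days
#' after emergence.
#'
#' @param wdvi WDVI value(s).
#' @param threshold Emergence threshold (default 0.005).
#' @return Logical vector: `TRUE` when emerged.
#' @export
emergence_status <- function(wdvi, threshold = 0.005) {
  if (any(!is.finite(wdvi))) stop("WDVI must be finite")
  wdvi >= threshold
}

#' Attach vegetation indices and the emergence flag to a reflectance table
#'
#' @param reflectance Long-format data.frame with at least the nine band
#'   columns (plus any id columns, which are preserved).
#' @param line A [soil_line()].
#' @param threshold Emergence threshold passed to [emergence_status()].
#' @return The input with columns `NDVI`, `WDVI` and `emerged` appended.
#' @export
compute_features <- function(reflectance, line, threshold = 0.005) {
  stopifnot(is.data.frame(reflectance))
  m <- as_band_matrix(reflectance)
  reflectance$NDVI <- compute_ndvi(m[, "B8A"], m[, "B4"])
  reflectance$WDVI <- compute_wdvi(m[, "B8A"], m[, "B4"], line)
  reflectance$emerged <- emergence_status(reflectance$WDVI, threshold)
  reflectance
}
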