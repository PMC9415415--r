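#' Sentinel-2 20 m band names used throughout the package
#'
#' The nine surface-reflectance bands retained for analysis, in the fixed
#' order used for feature records: B2 (490 nm), B3 (560 nm), B4 (665 nm),
#' B5 (705 nm), B6 (740 nm), B7 (783 nm), B8A (865 nm), B11 (1610 nm),
#' B12 (2190 nm). All reflectances are on unit scale, i.e. L2A digital
#' numbers divided by 10^4, so values lie in [0, 1].
#'
#' @return Character vector of length nine.
#' @export
band_names <- function() {
  c("B2", "B3", "B4", "B5", "B6", "B7", "B8A", "B11", "B12")
}

#' Per-scene descriptor names (bands plus vegetation indices)
#'
#' @return Character vector of length eleven: the nine bands followed by
#'   "NDVI" and "WDVI".
#' @export
descriptor_names <- function() {
  c(band_names(), "NDVI", "WDVI")
}

# Derive a stage-specific seed from a root seed; kept below 2^31 so it is a
# valid R integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    labels = 11L, sowing = 23L, pixels = 37L, reflectance = 53L,
    split = 71L, folds = 89L, model = 107L, bare = 131L
  )
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

# Validate a named numeric band vector (or matrix/data.frame with the nine
# band columns). Returns band values as a numeric matrix with one row per
# observation, columns in canonical order.
as_band_matrix <- function(x) {
  bn <- band_names()
  if (is.numeric(x) && !is.matrix(x)) {
    if (is.null(names(x)) && length(x) == length(bn)) names(x) <- bn
    if (!all(bn %in% names(x))) stop("band vector must name all nine bands")
    x <- matrix(x[bn], nrow = 1, dimnames = list(NULL, bn))
    return(x)
  }
  if (is.data.frame(x)) x <- as.matrix(x[, intersect(colnames(x), bn), drop = FALSE])
  if (!is.matrix(x) || !all(bn %in% colnames(x))) {
    stop("expected a named band vector or a table with columns ", paste(bn, collapse = ", "))
  }
  x[, bn, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
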