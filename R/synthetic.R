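#' Crop-class priors of the 2019 cycle
#'
#' Shares of the main crops in the irrigation module during the 2019
#' Spring-Summer cycle: corn 67.2%, alfalfa 22.5%, bean 5.9%, other 4.4%.
#'
#' @return Named numeric vector summing to 1.
#' @export
crop_priors_2019 <- function() {
  c(corn = 0.672, alfalfa = 0.225, bean = 0.059, other = 0.044)
}

#' Sample a crop pattern from class priors
#'
#' Draws `n_plots` crop labels independently from the given priors,
#' reproducibly under a fixed seed.
#'
#' @param n_plots Number of plots (>= 1).
#' @param priors Named label -> fraction vector summing to 1.
#' @param seed Integer seed.
#' @return Character vector of `n_plots` crop labels.
#' @export
sample_crop_pattern <- function(n_plots, priors = crop_priors_2019(), seed = 1) {
  if (n_plots < 1) stop("n_plots must be at least 1")
  if (is.null(names(priors)) || any(!nzchar(names(priors)))) {
    stop("priors must be a named vector of class fractions")
  }
  if (abs(sum(priors) - 1) > 1e-9) stop("priors must sum to 1")
  if (any(priors < 0)) stop("priors must be non-negative")
  set.seed(as.integer(seed))
  sample(names(priors), n_plots, replace = TRUE, prob = priors)
}

#' Configure a synthetic irrigation-module scenario
#'
#' Two presets reproduce the study conditions: `"survey2019"` is the training
#' cycle (exactly 280 surveyed plots - 154 corn, 72 alfalfa, 54 bean - on the
#' 2019 cloud calendar, with a stratified 50/50 train/validation split of 140
#' plots each), and `"cycle2020"` is the next-cycle test set (895 plots - 590
#' corn, 264 alfalfa, 41 bean - on the 15-day 2020 calendar). Custom
#' scenarios give either exact `class_counts` or `priors` to sample from.
#'
#' @param preset `"survey2019"`, `"cycle2020"`, or `NULL` for a custom setup.
#' @param n_plots Number of plots (custom scenarios with `priors`).
#' @param class_counts Named integer vector of exact per-class plot counts.
#' @param priors Named class priors to sample labels from (alternative to
#'   `class_counts`).
#' @param calendar An [acquisition_calendar()].
#' @param crop_calendar Named list of [crop_calendar_entry()] objects.
#' @param spectra An [endmember_spectra()]; its `noise_sd` is the per-pixel,
#'   per-band reflectance noise.
#' @param split_fraction Fraction of plots assigned to training (stratified
#'   by class); `NA` for no split (test cycles).
#' @param include_other Keep "other" plots in the training pool (default
#'   drops them: the classifiers are trained on the three main crops).
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(preset = NULL, n_plots = NULL, class_counts = NULL,
                            priors = NULL, calendar = NULL,
                            crop_calendar = default_crop_calendar(),
                            spectra = endmember_spectra(),
                            split_fraction = NA, include_other = FALSE) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("survey2019", "cycle2020"))
    if (preset == "survey2019") {
      class_counts <- class_counts %||% c(corn = 154, alfalfa = 72, bean = 54)
      calendar <- calendar %||% calendar_2019()
      if (is.na(split_fraction)) split_fraction <- 0.5
    } else {
      class_counts <- class_counts %||% c(corn = 590, alfalfa = 264, bean = 41)
      calendar <- calendar %||% calendar_2020()
    }
  }
  if (is.null(class_counts) && is.null(priors)) {
    stop("provide a preset, class_counts, or priors")
  }
  if (is.null(calendar)) stop("a calendar is required for custom scenarios")
  if (!is.null(priors) && is.null(n_plots)) stop("n_plots is required with priors")
  structure(list(
    preset = preset, n_plots = n_plots, class_counts = class_counts,
    priors = priors, calendar = calendar, crop_calendar = crop_calendar,
    spectra = spectra, split_fraction = split_fraction,
    include_other = include_other
  ), class = "scenario_config")
}

#' Generate a synthetic irrigation-module dataset
#'
#' Simulates one crop cycle: crop labels (fixed counts or sampled from
#' priors), per-plot sowing dates drawn uniformly within each crop's sowing
#' window, plot sampling units of 8-10 pixels, and - for every plot and
#' cloud-free acquisition date - the zonal-mean band vector obtained by
#' mixing soil and vegetation endmembers at the plot's simulated canopy cover
#' with per-pixel Gaussian noise. All randomness is routed through stage
#' seeds derived from `seed`, so equal seeds give identical datasets.
#'
#' @param config A [scenario_config()] (or a preset name).
#' @param seed Integer root seed.
#' @return A list of class `"crop_scenario"` with elements
#'   \describe{
#'     \item{reflectance}{long data.frame: `plot_id`, `date`, nine bands,
#'       `true_cover`, `crop_label` - one row per plot per cloud-free date.}
#'     \item{calendar}{the [acquisition_calendar()] used.}
#'     \item{plots}{per-plot table: `plot_id`, `crop_label`, `sowing_date`,
#'       `pixel_count`, `split` ("train"/"validation"/`NA`).}
#'   }
#' @export
generate_dataset <- function(config, seed = 1) {
  if (is.character(config)) config <- scenario_config(preset = config)
  stopifnot(inherits(config, "scenario_config"))

  if (!is.null(config$class_counts)) {
    labels <- rep(names(config$class_counts), config$class_counts)
  } else {
    labels <- sample_crop_pattern(config$n_plots, config$priors,
                                  seed = derive_seed(seed, "labels"))
  }
  n <- length(labels)
  unknown <- setdiff(unique(labels), names(config$crop_calendar))
  if (length(unknown) > 0) {
    stop("no phenology entry for crop(s): ", paste(unknown, collapse = ", "))
  }
  plot_id <- sprintf("P%04d", seq_len(n))
  year <- as.integer(format(min(config$calendar$date), "%Y"))

  set.seed(derive_seed(seed, "sowing"))
  sowing <- vapply(labels, function(lbl) {
    w <- config$crop_calendar[[lbl]]$sowing_window
    round(stats::runif(1, w[1], w[2]))
  }, numeric(1))
  sowing_date <- as.Date(sowing - 1, origin = sprintf("%d-01-01", year))

  set.seed(derive_seed(seed, "pixels"))
  pixel_count <- sample(8:10, n, replace = TRUE)

  split <- rep(NA_character_, n)
  if (!is.na(config$split_fraction)) {
    set.seed(derive_seed(seed, "split"))
    pool <- if (config$include_other) unique(labels) else setdiff(unique(labels), "other")
    for (lbl in pool) {
      idx <- which(labels == lbl)
      n_train <- round(length(idx) * config$split_fraction)
      tr <- sample(idx, n_train)
      split[tr] <- "train"
      split[setdiff(idx, tr)] <- "validation"
    }
  }
  plots <- data.frame(plot_id = plot_id, crop_label = labels,
                      sowing_date = sowing_date, pixel_count = pixel_count,
                      split = split, stringsAsFactors = FALSE)

  dates <- cloudfree_dates(config$calendar)
  grid <- expand.grid(plot = seq_len(n), date_i = seq_along(dates))
  cover <- numeric(nrow(grid))
  for (lbl in unique(labels)) {
    rows <- labels[grid$plot] == lbl
    cover[rows] <- simulate_cover(config$crop_calendar[[lbl]],
                                  sowing_date[grid$plot[rows]],
                                  dates[grid$date_i[rows]])
  }

  # pixel-level mixing (crop-specific canopy spectrum), then the zonal mean
  # over each plot's sampling unit
  px_per_row <- pixel_count[grid$plot]
  row_of_px <- rep(seq_len(nrow(grid)), px_per_row)
  set.seed(derive_seed(seed, "reflectance"))
  px <- matrix(NA_real_, length(row_of_px), length(band_names()),
               dimnames = list(NULL, band_names()))
  for (lbl in unique(labels)) {
    sel <- labels[grid$plot[row_of_px]] == lbl
    px[sel, ] <- mix_reflectance(rep(cover, px_per_row)[sel], config$spectra,
                                 vegetation = crop_vegetation(config$spectra, lbl))
  }
  refl <- rowsum(px, row_of_px) / px_per_row

  reflectance <- data.frame(
    plot_id = plot_id[grid$plot], date = dates[grid$date_i],
    refl, true_cover = cover, crop_label = labels[grid$plot],
    stringsAsFactors = FALSE
  )
  reflectance <- reflectance[order(reflectance$plot_id, reflectance$date), ]
  rownames(reflectance) <- NULL

  structure(list(reflectance = reflectance, calendar = config$calendar,
                 plots = plots), class = "crop_scenario")
}

#' @export
print.crop_scenario <- function(x, ...) {
  cat(sprintf("Synthetic crop scenario: %d plots, %d cloud-free dates, %d records\n",
              nrow(x$plots), length(cloudfree_dates(x$calendar)),
              nrow(x$reflectance)))
  print(table(x$plots$crop_label))
  invisible(x)
}

#' Write plot polygons as GeoJSON
#'
#' Lays the synthetic plots out on a regular grid near the study area and
#' writes one rectangle per plot (EPSG:4326) with `plot_id` and `crop_label`
#' properties. Purely a fixture for GIS round-trips; no georeferenced raster
#' is synthesized.
#'
#' @param plots The `plots` table of a [generate_dataset()] result.
#' @param path Output file path.
#' @param origin Longitude/latitude of the grid origin.
#' @param cell_deg Grid cell size in degrees (default ~60 m).
#' @return `path`, invisibly.
#' @export
write_plot_polygons <- function(plots, path, origin = c(-99.10, 20.42),
                                cell_deg = 6e-4) {
  n <- nrow(plots)
  ncol_grid <- ceiling(sqrt(n))
  feats <- lapply(seq_len(n), function(i) {
    r <- (i - 1) %/% ncol_grid
    c0 <- (i - 1) %% ncol_grid
    x0 <- origin[1] + c0 * cell_deg
    y0 <- origin[2] + r * cell_deg
    ring <- list(c(x0, y0), c(x0 + cell_deg * 0.9, y0),
                 c(x0 + cell_deg * 0.9, y0 + cell_deg * 0.9),
                 c(x0, y0 + cell_deg * 0.9), c(x0, y0))
    list(type = "Feature",
         properties = list(plot_id = plots$plot_id[i],
                           crop_label = plots$crop_label[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
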