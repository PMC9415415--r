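#' Scene-combination schemes
#'
#' A combination pairs the current scene (lag 0) with scenes acquired a fixed
#' number of days earlier, forming one multitemporal record of 11 descriptors
#' per scene (nine bands, NDVI, WDVI). The four standard schemes are
#' C1 (0/30/60 days, 33 descriptors), C2 (0/30, 22), C3 (0/15/30, 33) and
#' C4 (0/15, 22).
#'
#' @param id One of "C1".."C4", or a custom id when `lags` is supplied.
#' @param lags Ordered day offsets; must start at 0 and increase. Defaults to
#'   the standard scheme for `id`.
#' @param tolerance Maximum days a matched scene may deviate from its lag
#'   target (default 5, one revisit period).
#' @return A list of class `"combination_spec"`.
#' @export
combination_spec <- function(id = c("C1", "C2", "C3", "C4"), lags = NULL,
                             tolerance = 5) {
  standard <- list(C1 = c(0, 30, 60), C2 = c(0, 30),
                   C3 = c(0, 15, 30), C4 = c(0, 15))
  if (is.null(lags)) {
    id <- match.arg(id)
    lags <- standard[[id]]
  } else {
    id <- id[1]
  }
  if (lags[1] != 0) stop("lag 0 (the current scene) must always be present")
  if (any(diff(lags) <= 0)) stop("lags must be strictly increasing")
  if (tolerance < 0) stop("tolerance must be non-negative")
  structure(list(id = id, lags = lags, tolerance = tolerance,
                 n_descriptors = 11L * length(lags)),
            class = "combination_spec")
}

#' All four standard combinations
#'
#' @param tolerance Matching tolerance in days, shared by all four.
#' @return Named list of [combination_spec()] objects C1..C4.
#' @export
standard_combinations <- function(tolerance = 5) {
  ids <- c("C1", "C2", "C3", "C4")
  stats::setNames(lapply(ids, combination_spec, tolerance = tolerance), ids)
}

#' Match lagged scenes to an analysis date
#'
#' For each lag of the combination, selects the cloud-free date nearest to
#' (analysis date - lag) within the tolerance, breaking ties toward the
#' earlier date. Returns `NULL` when any lag has no scene in range - the
#' combination cannot be formed on that date.
#'
#' @param cloudfree A `Date` vector of usable scene dates (any order), or an
#'   [acquisition_calendar()].
#' @param analysis_date The current date; must itself be a cloud-free scene
#'   date (classification only happens on scene dates).
#' @param spec A [combination_spec()].
#' @return A list of class `"scene_selection"` with `analysis_date`, `lags`,
#'   and `matched_dates` (one `Date` per lag, lag 0 first), or `NULL`.
#' @export
match_scenes <- function(cloudfree, analysis_date, spec) {
  stopifnot(inherits(spec, "combination_spec"))
  if (inherits(cloudfree, "acquisition_calendar") || is.data.frame(cloudfree)) {
    cloudfree <- cloudfree_dates(cloudfree)
  }
  dates <- sort(unique(as.Date(cloudfree)))
  analysis_date <- as.Date(analysis_date)
  if (!analysis_date %in% dates) {
    stop("analysis_date ", format(analysis_date), " is not a cloud-free scene date")
  }
  matched <- as.Date(rep(NA, length(spec$lags)))
  for (i in seq_along(spec$lags)) {
    target <- analysis_date - spec$lags[i]
    diffs <- abs(as.numeric(dates - target))
    ok <- which(diffs <= spec$tolerance)
    if (length(ok) == 0) return(NULL)
    best <- ok[diffs[ok] == min(diffs[ok])]
    matched[i] <- dates[best[1]] # ties: dates ascending, so first = earlier
  }
  structure(list(analysis_date = analysis_date, lags = spec$lags,
                 matched_dates = matched, combination = spec$id),
            class = "scene_selection")
}

#' @export
print.scene_selection <- function(x, ...) {
  cat(sprintf("%s @ %s: %s\n", x$combination, format(x$analysis_date),
              paste(sprintf("%s (lag %d)", format(x$matched_dates), x$lags),
                    collapse = ", ")))
  invisible(x)
}

#' Assemble one multitemporal feature record
#'
#' Concatenates the 11 per-scene descriptors scene-major (current scene
#' first, then progressively older scenes), each block ordered B2, B3, B4,
#' B5, B6, B7, B8A, B11, B12, NDVI, WDVI. Descriptor names carry the lag in
#' days, e.g. `B8A_30`.
#'
#' @param plot_id Plot identifier.
#' @param selection A [match_scenes()] result.
#' @param features Per-date feature table for the plot: columns `date` plus
#'   the eleven descriptors (see [compute_features()]).
#' @param label Crop label to attach (may be `NA` for unlabeled prediction).
#' @return A list with `plot_id`, `crop_label`, `analysis_date` and the named
#'   `descriptors` vector (length 11 x number of lags).
#' @export
build_record <- function(plot_id, selection, features, label = NA_character_) {
  stopifnot(inherits(selection, "scene_selection"))
  dn <- descriptor_names()
  if (!all(c("date", dn) %in% colnames(features))) {
    stop("features must provide a date column and all eleven descriptors")
  }
  fdates <- as.Date(features$date)
  desc <- numeric(0)
  for (i in seq_along(selection$lags)) {
    row <- which(fdates == selection$matched_dates[i])
    if (length(row) == 0) {
      stop("no features for matched date ", format(selection$matched_dates[i]))
    }
    block <- as.numeric(features[row[1], dn])
    names(block) <- paste0(dn, "_", selection$lags[i])
    desc <- c(desc, block)
  }
  if (anyNA(desc)) stop("missing descriptor values in feature table")
  list(plot_id = plot_id, crop_label = label,
       analysis_date = selection$analysis_date, descriptors = desc)
}

#' Remove records without a standing crop
#'
#' A record survives only if its WDVI is at or above the emergence threshold
#' on every scene it contains; a sub-threshold WDVI on any constituent scene
#' indicates the crop was absent (not yet emerged, bare, or harvested) and
#' the whole row is eliminated. `scenes = "lagged"` restricts the test to the
#' earlier scenes only, leaving the current scene unchecked.
#'
#' @param records A training table (see [assemble_training_table()]) or any
#'   data.frame with `WDVI_<lag>` columns.
#' @param threshold Emergence threshold (default 0.005).
#' @param scenes `"all"` (default) or `"lagged"`.
#' @return The surviving rows.
#' @export
apply_emergence_filter <- function(records, threshold = 0.005,
                                   scenes = c("all", "lagged")) {
  scenes <- match.arg(scenes)
  wcols <- grep("^WDVI_", colnames(records), value = TRUE)
  if (length(wcols) == 0) stop("records carry no WDVI descriptors")
  if (scenes == "lagged") wcols <- setdiff(wcols, "WDVI_0")
  if (length(wcols) == 0) return(records)
  w <- as.matrix(records[, wcols, drop = FALSE])
  keep <- rowSums(w < threshold) == 0
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the multitemporal training/prediction table
#'
#' The database of the method: one candidate record per (plot, feasible
#' analysis date), where a date is feasible when [match_scenes()] can supply
#' every lag of the combination; the emergence filter then removes records
#' without a standing crop on every constituent scene.
#'
#' @param dataset A `crop_scenario` from [generate_dataset()], or a list with
#'   a long `reflectance` table (plot_id, date, bands, crop_label) and a
#'   `calendar`.
#' @param spec A [combination_spec()].
#' @param line A [soil_line()] for the WDVI descriptors.
#' @param threshold Emergence threshold; `NA` skips the filter.
#' @param analysis_dates Candidate analysis dates (default: every cloud-free
#'   date of the calendar).
#' @param plot_ids Optional subset of plots (e.g. the training split).
#' @param filter_scenes Passed to [apply_emergence_filter()].
#' @return A data.frame of class `"training_table"`: `plot_id`, `crop_label`,
#'   `analysis_date`, then the 11 x k descriptor columns. Attributes
#'   `combination`, `lags`, `tolerance` and `descriptors` record the scheme.
#'   Empty (with a warning) when no analysis date is feasible.
#' @export
assemble_training_table <- function(dataset, spec, line,
                                    threshold = 0.005,
                                    analysis_dates = NULL, plot_ids = NULL,
                                    filter_scenes = "all") {
  stopifnot(inherits(spec, "combination_spec"), inherits(line, "soil_line"))
  refl <- dataset$reflectance
  if (!is.null(plot_ids)) refl <- refl[refl$plot_id %in% plot_ids, , drop = FALSE]
  feats <- compute_features(refl, line)
  dates <- cloudfree_dates(dataset$calendar)
  if (is.null(analysis_dates)) analysis_dates <- dates
  analysis_dates <- as.Date(analysis_dates)

  dn <- descriptor_names()
  pieces <- list()
  for (ad in as.list(analysis_dates)) {
    sel <- match_scenes(dates, ad, spec)
    if (is.null(sel)) next
    base <- unique(feats[, c("plot_id", "crop_label"), drop = FALSE])
    base$analysis_date <- ad
    complete <- rep(TRUE, nrow(base))
    for (i in seq_along(sel$lags)) {
      f <- feats[as.Date(feats$date) == sel$matched_dates[i], c("plot_id", dn)]
      colnames(f) <- c("plot_id", paste0(dn, "_", sel$lags[i]))
      base <- merge(base, f, by = "plot_id", all.x = TRUE, sort = FALSE)
    }
    desc_cols <- setdiff(colnames(base), c("plot_id", "crop_label", "analysis_date"))
    complete <- stats::complete.cases(base[, desc_cols, drop = FALSE])
    pieces[[length(pieces) + 1]] <- base[complete, , drop = FALSE]
  }

  desc_names <- as.vector(vapply(spec$lags,
                                 function(l) paste0(dn, "_", l),
                                 character(length(dn))))
  if (length(pieces) == 0) {
    warning("no feasible analysis date for combination ", spec$id)
    tab <- as.data.frame(c(
      list(plot_id = character(0), crop_label = character(0),
           analysis_date = as.Date(character(0))),
      stats::setNames(rep(list(numeric(0)), length(desc_names)), desc_names)
    ))
  } else {
    tab <- do.call(rbind, pieces)
    tab <- tab[, c("plot_id", "crop_label", "analysis_date", desc_names)]
    if (!is.na(threshold)) {
      tab <- apply_emergence_filter(tab, threshold, filter_scenes)
    }
    tab <- tab[order(tab$plot_id, tab$analysis_date), ]
    rownames(tab) <- NULL
  }
  structure(tab, class = c("training_table", "data.frame"),
            combination = spec$id, lags = spec$lags,
            tolerance = spec$tolerance, descriptors = desc_names)
}

#' Descriptor matrix of a training table
#'
#' @param table A `training_table`.
#' @return Numeric matrix of the descriptor columns.
#' @export
descriptor_matrix <- function(table) {
  desc <- attr(table, "descriptors") %||%
    setdiff(colnames(table), c("plot_id", "crop_label", "analysis_date"))
  as.matrix(as.data.frame(table)[, desc, drop = FALSE])
}
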