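#' Per-date within-cycle evaluation of trained models
#'
#' Emulates testing models trained on one crop cycle against the next cycle:
#' for each requested analysis date and each combination whose lagged scenes
#' can be matched on the test calendar, records are assembled from the test
#' dataset (whole-plot features, no retraining), predicted, and scored. Dates
#' early in the cycle typically admit only the short-lag combinations,
#' mirroring the varying combination availability of a real scene archive.
#'
#' @param models Named list of fitted `crop_model`s, one per combination id
#'   (e.g. the result of training on each of [standard_combinations()]).
#' @param test_dataset A `crop_scenario` (or list with `reflectance` and
#'   `calendar`) for the evaluation cycle.
#' @param line A [soil_line()] used for the WDVI descriptors.
#' @param dates Analysis dates to evaluate (default: all cloud-free dates of
#'   the test calendar).
#' @param combinations Named list of [combination_spec()]s keyed like
#'   `models` (default [standard_combinations()] restricted to the model
#'   names).
#' @param threshold Emergence threshold for record filtering.
#' @param vocabulary Class order for the confusion matrices (default: the
#'   first model's training classes).
#' @return A data.frame with one row per (date, combination) that could be
#'   evaluated: `date`, `combination`, `n_records`, `overall_accuracy`,
#'   `kappa`, `altman`, and per-class `PA_<class>` / `UA_<class>` columns.
#'   The full [accuracy_report()]s are attached as attribute `reports`.
#'   Empty (with a warning) when no date/combination is feasible.
#' @export
timeline_evaluate <- function(models, test_dataset, line, dates = NULL,
                              combinations = NULL, threshold = 0.005,
                              vocabulary = NULL) {
  stopifnot(is.list(models), length(models) > 0)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    stop("models must be a named list keyed by combination id")
  }
  if (is.null(combinations)) {
    combinations <- standard_combinations()[names(models)]
  }
  if (is.null(dates)) dates <- cloudfree_dates(test_dataset$calendar)
  dates <- as.Date(dates)
  vocabulary <- vocabulary %||% models[[1]]$classes

  rows <- list()
  reports <- list()
  for (cid in names(models)) {
    spec <- combinations[[cid]]
    if (is.null(spec)) stop("no combination spec for model ", cid)
    tab <- assemble_training_table(test_dataset, spec, line,
                                   threshold = threshold,
                                   analysis_dates = dates)
    if (nrow(tab) == 0) next
    for (ad in as.list(unique(tab$analysis_date))) {
      sub <- tab[tab$analysis_date == ad, , drop = FALSE]
      attr(sub, "descriptors") <- attr(tab, "descriptors")
      keep <- sub$crop_label %in% vocabulary
      sub <- sub[keep, , drop = FALSE]
      if (nrow(sub) == 0) next
      pred <- predict(models[[cid]], sub)
      rep <- accuracy_report(confusion_counts(sub$crop_label, pred, vocabulary))
      key <- paste(format(ad), cid, sep = "|")
      reports[[key]] <- rep
      row <- data.frame(date = ad, combination = cid, n_records = rep$n,
                        overall_accuracy = rep$overall_accuracy,
                        kappa = rep$kappa, altman = rep$altman,
                        stringsAsFactors = FALSE)
      for (cl in vocabulary) {
        row[[paste0("PA_", cl)]] <- rep$producers_accuracy[[cl]]
        row[[paste0("UA_", cl)]] <- rep$users_accuracy[[cl]]
      }
      rows[[key]] <- row
    }
  }
  if (length(rows) == 0) {
    warning("no feasible (date, combination) pair on the test calendar")
    out <- data.frame(date = as.Date(character(0)), combination = character(0),
                      n_records = integer(0), overall_accuracy = numeric(0),
                      kappa = numeric(0), altman = character(0))
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$date, out$combination), ]
    rownames(out) <- NULL
  }
  attr(out, "reports") <- reports
  out
}
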