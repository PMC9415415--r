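#' Confusion matrix from truth and prediction
#'
#' Rows are ground truth, columns predicted; the class order is the supplied
#' vocabulary (shared by both axes).
#'
#' @param truth,predicted Equal-length label vectors.
#' @param vocabulary Class order; defaults to the sorted union of labels.
#' @return Square integer matrix with the vocabulary as dimnames.
#' @export
confusion_counts <- function(truth, predicted,
                             vocabulary = sort(unique(c(truth, predicted)))) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  bad <- setdiff(unique(c(truth, predicted)), vocabulary)
  if (length(bad) > 0) stop("labels outside vocabulary: ", paste(bad, collapse = ", "))
  table(factor(truth, vocabulary), factor(predicted, vocabulary)) |>
    unclass() |> `dimnames<-`(list(truth = vocabulary, predicted = vocabulary))
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix counts must be non-negative")
  if (sum(cm) <= 0) stop("empty confusion matrix")
  cm
}

#' Overall accuracy (percent)
#'
#' Correctly classified sampling units divided by all units, times 100.
#'
#' @param cm Square confusion matrix (truth rows, predicted columns).
#' @return Percent in \[0, 100\].
#' @export
overall_accuracy <- function(cm) {
  cm <- check_cm(cm)
  100 * sum(diag(cm)) / sum(cm)
}

#' Producer's accuracy per class (percent)
#'
#' Fraction of each ground-truth class recovered by the classifier (recall).
#' Classes absent from the truth have no defined PA and are reported `NA`.
#'
#' @param cm Square confusion matrix.
#' @return Named percent vector.
#' @export
producers_accuracy <- function(cm) {
  cm <- check_cm(cm)
  rs <- rowSums(cm)
  out <- ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
  stats::setNames(out, rownames(cm))
}

#' User's accuracy per class (percent)
#'
#' Fraction of each predicted class that is correct (precision). Classes
#' never predicted have no defined UA and are reported `NA`.
#'
#' @param cm Square confusion matrix.
#' @return Named percent vector.
#' @export
users_accuracy <- function(cm) {
  cm <- check_cm(cm)
  cs <- colSums(cm)
  out <- ifelse(cs > 0, 100 * diag(cm) / cs, NA_real_)
  stats::setNames(out, colnames(cm))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e), with observed
#' agreement p_o the diagonal fraction and expected agreement p_e the sum of
#' row-total x column-total products over the squared grand total. Equals 1
#' only for a diagonal matrix, 0 under row/column independence, and is
#' undefined (error) when p_e = 1 (all mass in one row-and-column cell).
#'
#' @param cm Square confusion matrix.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(cm) {
  cm <- check_cm(cm)
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (1 - p_e < 1e-15) stop("undefined kappa: expected agreement is 1")
  (p_o - p_e) / (1 - p_e)
}

#' Qualitative rating of a kappa value (Altman bands)
#'
#' poor (<= 0.20), regular (0.20, 0.40], moderate (0.40, 0.60], good
#' (0.60, 0.80], particularly good (0.80, 1]. Negative kappas rate poor. The
#' boundaries are half-open so every value in \[-1, 1\] gets exactly one
#' rating.
#'
#' @param kappa_value Numeric in \[-1, 1\] (vectorized).
#' @return Character rating(s).
#' @export
altman_rating <- function(kappa_value) {
  if (any(kappa_value < -1 - 1e-12 | kappa_value > 1 + 1e-12)) {
    stop("kappa must lie in [-1, 1]")
  }
  cut(kappa_value, breaks = c(-1 - 1e-9, 0.2, 0.4, 0.6, 0.8, 1),
      labels = c("poor", "regular", "moderate", "good", "particularly good"),
      right = TRUE) |> as.character()
}

#' Full accuracy report from a confusion matrix
#'
#' @param cm Square confusion matrix (truth rows, predicted columns).
#' @return List of class `"accuracy_report"`: `overall_accuracy`, per-class
#'   `producers_accuracy` and `users_accuracy` (percent, `NA` where
#'   undefined), `kappa`, `altman`, `n` and the confusion matrix.
#' @export
accuracy_report <- function(cm) {
  cm <- check_cm(cm)
  k <- cohens_kappa(cm)
  structure(list(
    overall_accuracy = overall_accuracy(cm),
    producers_accuracy = producers_accuracy(cm),
    users_accuracy = users_accuracy(cm),
    kappa = k, altman = altman_rating(k), n = sum(cm), confusion = cm
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.1f%%  kappa: %.2f (%s)  n = %d\n",
              x$overall_accuracy, x$kappa, x$altman, x$n))
  tab <- rbind(`PA%` = x$producers_accuracy, `UA%` = x$users_accuracy)
  print(round(tab, 1))
  invisible(x)
}
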