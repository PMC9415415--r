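#' Specify a crop classifier
#'
#' Two algorithms are supported: `"svm_cubic"` - a one-vs-one support vector
#' machine with the cubic polynomial kernel k(x, xi) = ((x' xi) + 1)^3 on
#' standardized descriptors - and `"bagged_trees"` - a bootstrap-aggregated
#' ensemble of 100 fully grown classification trees voting by majority.
#'
#' @param algorithm `"svm_cubic"` or `"bagged_trees"`.
#' @param kernel_degree Polynomial order d (default 3).
#' @param kernel_offset Kernel offset c (default 1).
#' @param cost SVM box constraint C (default 1).
#' @param standardize Standardize descriptors to training mean 0 / sd 1
#'   (default `TRUE`).
#' @param n_trees Ensemble size for bagged trees (default 100).
#' @param cv_folds Default fold count for [cross_validate()] (default 5).
#' @param class_weights Optional named weights to counter class imbalance
#'   (off by default: the imbalance of the survey is part of the method's
#'   behavior).
#' @param seed Integer seed for tree bootstrap resampling.
#' @return A list of class `"classifier_spec"`.
#' @export
classifier_spec <- function(algorithm = c("svm_cubic", "bagged_trees"),
                            kernel_degree = 3, kernel_offset = 1, cost = 1,
                            standardize = TRUE, n_trees = 100, cv_folds = 5,
                            class_weights = NULL, seed = 1) {
  algorithm <- match.arg(algorithm)
  if (kernel_degree < 1) stop("kernel_degree must be >= 1")
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(algorithm = algorithm, kernel_degree = kernel_degree,
                 kernel_offset = kernel_offset, cost = cost,
                 standardize = standardize, n_trees = n_trees,
                 cv_folds = cv_folds, class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Cubic (or general polynomial) kernel
#'
#' k(x, xi) = ((x' xi) + c)^d, evaluated with the raw inner product - no
#' kernel-scale normalization; descriptor standardization provides scaling.
#'
#' @param x,xi Numeric vectors of equal length.
#' @param degree Polynomial order d.
#' @param offset Additive offset c.
#' @return Scalar kernel value.
#' @export
polynomial_kernel <- function(x, xi, degree = 3, offset = 1) {
  (sum(x * xi) + offset)^degree
}

fit_standardizer <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1 # constant columns pass through centered
  list(mean = mu, sd = sd)
}

apply_standardizer <- function(std, x) {
  if (is.null(std)) return(x)
  sweep(sweep(x, 2, std$mean, "-"), 2, std$sd, "/")
}

#' Train a crop recognition model
#'
#' Fits the model of a [classifier_spec()] on a training table. Descriptor
#' standardization parameters are estimated on the training data only and
#' stored with the model. The SVM trains one binary machine per class pair
#' (one-vs-one); the bagged ensemble draws `n_trees` bootstrap resamples with
#' all descriptors available at every split.
#'
#' @param table A `training_table` from [assemble_training_table()], or any
#'   data.frame with a `crop_label` column and numeric descriptor columns.
#' @param spec A [classifier_spec()].
#' @return A list of class `"crop_model"`: the fitted machinery, the class
#'   vocabulary, descriptor names, standardization parameters and the spec.
#' @export
train_classifier <- function(table, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- descriptor_matrix(table)
  y <- factor(table$crop_label)
  if (nrow(x) == 0) stop("empty training table")
  if (nlevels(y) < 2) stop("training requires at least two classes")
  if (anyNA(x)) stop("training descriptors contain missing values")

  std <- NULL
  if (spec$standardize) {
    std <- fit_standardizer(x)
    x <- apply_standardizer(std, x)
  }

  if (spec$algorithm == "svm_cubic") {
    fit <- e1071::svm(
      x = x, y = y, scale = FALSE, type = "C-classification",
      kernel = "polynomial", degree = spec$kernel_degree,
      gamma = 1, coef0 = spec$kernel_offset, cost = spec$cost,
      class.weights = spec$class_weights
    )
  } else {
    set.seed(derive_seed(spec$seed, "model"))
    cw <- spec$class_weights
    fit <- randomForest::randomForest(
      x = x, y = y, ntree = spec$n_trees, mtry = ncol(x), replace = TRUE,
      classwt = if (!is.null(cw)) cw[levels(y)]
    )
  }
  structure(list(fit = fit, spec = spec, classes = levels(y),
                 descriptors = colnames(x), standardizer = std,
                 n_train = nrow(x), version = "croprec-model-1"),
            class = "crop_model")
}

# One-vs-one aggregation from pairwise SVM decision values: majority vote,
# ties broken by summed decision values per class, then by class order.
aggregate_ovo <- function(decision_values, classes) {
  n <- nrow(decision_values)
  votes <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
  score <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (col in colnames(decision_values)) {
    pair <- strsplit(col, "/", fixed = TRUE)[[1]]
    v <- decision_values[, col]
    win_a <- v > 0
    votes[, pair[1]] <- votes[, pair[1]] + win_a
    votes[, pair[2]] <- votes[, pair[2]] + !win_a
    score[, pair[1]] <- score[, pair[1]] + v
    score[, pair[2]] <- score[, pair[2]] - v
  }
  vapply(seq_len(n), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) {
      s <- score[i, top]
      top <- top[s == max(s)]
    }
    classes[top[1]]
  }, character(1))
}

#' Predict crop labels
#'
#' @param object A [train_classifier()] model.
#' @param newdata A training table or descriptor matrix; descriptor columns
#'   must match the training descriptors.
#' @param ... Unused.
#' @return Character vector of predicted labels, one per record.
#' @export
predict.crop_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else descriptor_matrix(newdata)
  if (ncol(x) != length(object$descriptors)) {
    stop(sprintf("record length %d does not match training length %d",
                 ncol(x), length(object$descriptors)))
  }
  if (!is.null(colnames(x)) && !identical(colnames(x), object$descriptors)) {
    if (!all(object$descriptors %in% colnames(x))) {
      stop("descriptor names do not match the training descriptors")
    }
    x <- x[, object$descriptors, drop = FALSE]
  }
  if (nrow(x) == 0) return(character(0))
  x <- apply_standardizer(object$standardizer, x)
  if (object$spec$algorithm == "svm_cubic") {
    pred <- stats::predict(object$fit, x, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    aggregate_ovo(dv, object$classes)
  } else {
    as.character(stats::predict(object$fit, x))
  }
}

#' Stratified k-fold cross-validation
#'
#' Assigns records to folds stratified by class (seeded), trains on k-1
#' folds, predicts the held-out fold, and pools the held-out predictions into
#' one confusion matrix for overall accuracy and kappa; per-fold OA/kappa are
#' reported alongside.
#'
#' @param table A training table.
#' @param spec A [classifier_spec()].
#' @param folds Number of folds (default `spec$cv_folds`).
#' @param seed Seed for the fold assignment.
#' @return List with `per_fold` (data.frame fold/OA/kappa), `pooled` (an
#'   [accuracy_report()]), `confusion` and the fold assignment.
#' @export
cross_validate <- function(table, spec = classifier_spec(),
                           folds = spec$cv_folds, seed = 1) {
  y <- factor(table$crop_label)
  n <- length(y)
  if (folds > n) stop("more folds than records")
  set.seed(derive_seed(seed, "folds"))
  fold <- integer(n)
  for (lbl in levels(y)) {
    idx <- which(y == lbl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  truth <- character(0); pred <- character(0)
  per_fold <- data.frame(fold = seq_len(folds), oa = NA_real_, kappa = NA_real_)
  for (k in seq_len(folds)) {
    tr <- table[fold != k, , drop = FALSE]
    te <- table[fold == k, , drop = FALSE]
    attr(tr, "descriptors") <- attr(table, "descriptors")
    attr(te, "descriptors") <- attr(table, "descriptors")
    model <- train_classifier(tr, spec)
    p <- predict(model, te)
    cmk <- confusion_counts(te$crop_label, p, levels(y))
    per_fold$oa[k] <- overall_accuracy(cmk)
    per_fold$kappa[k] <- cohens_kappa(cmk)
    truth <- c(truth, te$crop_label); pred <- c(pred, p)
  }
  cm <- confusion_counts(truth, pred, levels(y))
  list(per_fold = per_fold, pooled = accuracy_report(cm), confusion = cm,
       fold = fold)
}

#' Save / load a fitted model
#'
#' Round-trips a [train_classifier()] model through a self-describing
#' versioned file; a reloaded model reproduces its predictions exactly.
#'
#' @param model A `crop_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "crop_model"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "crop_model") ||
      !identical(model$version, "croprec-model-1")) {
    stop("not a recognized crop model file")
  }
  model
}
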