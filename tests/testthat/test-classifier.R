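test_that("both algorithms fit a separable toy exactly", {
  tab <- separable_table(classes = c("corn", "alfalfa", "bean"))
  for (algo in c("svm_cubic", "bagged_trees")) {
    model <- train_classifier(tab, classifier_spec(algo))
    expect_identical(predict(model, tab), tab$crop_label)
  }
})

test_that("training contracts are enforced", {
  tab <- separable_table(classes = c("corn", "alfalfa"))
  single <- tab[tab$crop_label == "corn", ]
  attr(single, "descriptors") <- attr(tab, "descriptors")
  expect_error(train_classifier(single), "at least two classes")

  model <- train_classifier(tab)
  short <- descriptor_matrix(tab)[, 1:10]
  expect_error(predict(model, short), "does not match training length")
})

test_that("bagged-tree training is deterministic under a fixed seed", {
  tab <- separable_table(classes = c("corn", "alfalfa", "bean"), sep = 2)
  probe <- separable_table(classes = c("corn", "alfalfa", "bean"), sep = 2,
                           seed = 99)
  m1 <- train_classifier(tab, classifier_spec("bagged_trees", seed = 5))
  m2 <- train_classifier(tab, classifier_spec("bagged_trees", seed = 5))
  expect_identical(predict(m1, probe), predict(m2, probe))
})

test_that("standardization centers and scales on the training data only", {
  tab <- separable_table(classes = c("corn", "alfalfa"))
  model <- train_classifier(tab, classifier_spec("svm_cubic"))
  x <- descriptor_matrix(tab)
  z <- sweep(sweep(x, 2, model$standardizer$mean), 2, model$standardizer$sd, "/")
  expect_equal(unname(colMeans(z)), rep(0, ncol(z)), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, ncol(z)), tolerance = 1e-10)
  off <- train_classifier(tab, classifier_spec("svm_cubic", standardize = FALSE))
  expect_null(off$standardizer)
})

test_that("predictions are invariant under descriptor-wise affine rescaling", {
  tab <- separable_table(classes = c("corn", "alfalfa", "bean"), sep = 1.5)
  probe <- separable_table(classes = c("corn", "alfalfa", "bean"), sep = 1.5,
                           seed = 31)
  model <- train_classifier(tab, classifier_spec("svm_cubic"))
  base <- predict(model, probe)

  scale <- runif(ncol(descriptor_matrix(tab)), 0.5, 20)
  shift <- runif(length(scale), -3, 3)
  rescale <- function(t) {
    x <- descriptor_matrix(t)
    x2 <- sweep(sweep(x, 2, scale, "*"), 2, shift, "+")
    t[, colnames(x2)] <- x2
    t
  }
  model2 <- train_classifier(rescale(tab), classifier_spec("svm_cubic"))
  expect_identical(predict(model2, rescale(probe)), base)
})

test_that("the cubic kernel matches direct arithmetic and the SVM dual form", {
  set.seed(10)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    expect_identical(polynomial_kernel(x, y), (sum(x * y) + 1)^3)
  }

  # dual-form oracle: decision value recomputed from support vectors and
  # kernel arithmetic matches the fitted machine's decision value
  tab <- separable_table(classes = c("corn", "alfalfa"), sep = 1)
  model <- train_classifier(tab, classifier_spec("svm_cubic"))
  fit <- model$fit
  x <- apply_standardizer(model$standardizer, descriptor_matrix(tab))
  pred <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")[, 1]
  manual <- vapply(seq_len(nrow(x)), function(i) {
    k <- apply(fit$SV, 1, polynomial_kernel, xi = x[i, ])
    sum(fit$coefs[, 1] * k) - fit$rho[1]
  }, numeric(1))
  expect_equal(unname(manual), unname(dv), tolerance = 1e-8)
})

test_that("prediction is a pointwise map (no cross-record coupling)", {
  tab <- separable_table(classes = c("corn", "alfalfa", "bean"), sep = 1.5)
  model <- train_classifier(tab)
  one <- tab[3, , drop = FALSE]
  attr(one, "descriptors") <- attr(tab, "descriptors")
  dup <- tab[c(3, 3, 3), , drop = FALSE]
  attr(dup, "descriptors") <- attr(tab, "descriptors")
  expect_identical(predict(model, dup), rep(predict(model, one), 3))
})

test_that("cross-validation partitions records and scores sensibly", {
  tab <- separable_table(classes = c("corn", "alfalfa", "bean"),
                         n_per_class = 20)
  cv <- cross_validate(tab, classifier_spec("svm_cubic"), folds = 5, seed = 2)
  expect_equal(length(cv$fold), nrow(tab))
  expect_true(all(cv$fold %in% 1:5))
  expect_equal(sum(cv$confusion), nrow(tab)) # every record held out once
  expect_equal(cv$pooled$overall_accuracy, 100)

  expect_error(cross_validate(tab[1:3, ], folds = 5), "more folds than records")
})

test_that("random labels give chance-level cross-validated accuracy", {
  tab <- separable_table(classes = c("corn", "alfalfa", "bean"),
                         n_per_class = 100, sep = 1.5)
  set.seed(77)
  tab$crop_label <- sample(tab$crop_label) # break the label-feature link
  cv <- cross_validate(tab, classifier_spec("svm_cubic"), folds = 5, seed = 3)
  expect_lt(abs(cv$pooled$overall_accuracy - 100 / 3), 10)
  expect_lt(abs(cv$pooled$kappa), 0.1)
})

test_that("models round-trip through the versioned file format", {
  tab <- separable_table(classes = c("corn", "alfalfa", "bean"), sep = 1.5)
  probe <- separable_table(classes = c("corn", "alfalfa", "bean"), sep = 1.5,
                           seed = 12)
  model <- train_classifier(tab)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  reloaded <- load_model(path)
  expect_identical(predict(reloaded, probe), predict(model, probe))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_model(bad), "not a recognized crop model")
})

test_that("bagged-tree accuracy is stable across seeds on the default scenario", {
  ds <- generate_dataset(tiny_scenario(), seed = 14)
  line <- soil_line(1.62)
  tab <- assemble_training_table(ds, combination_spec("C4"), line,
                                 plot_ids = ds$plots$plot_id[ds$plots$split == "train"])
  val <- assemble_training_table(ds, combination_spec("C4"), line,
                                 plot_ids = ds$plots$plot_id[ds$plots$split == "validation"])
  oas <- vapply(1:10, function(s) {
    m <- train_classifier(tab, classifier_spec("bagged_trees", seed = s))
    overall_accuracy(confusion_counts(val$crop_label, predict(m, val),
                                      m$classes))
  }, numeric(1))
  expect_lt(sd(oas), 2)
})
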