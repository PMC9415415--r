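test_that("confusion matrices count truth rows against predicted columns", {
  truth <- c("corn", "corn", "bean", "alfalfa")
  expect_equal(diag(confusion_counts(truth, truth)), c(alfalfa = 1, bean = 1, corn = 2))
  cm <- confusion_counts(rep("corn", 5), rep("bean", 5), c("bean", "corn"))
  expect_equal(cm["corn", "bean"], 5)
  expect_equal(sum(cm), 5)
  expect_error(confusion_counts(truth, truth[-1]), "equal length")
  expect_error(confusion_counts(truth, c("corn", "corn", "oat", "alfalfa"),
                                c("corn", "bean", "alfalfa")),
               "outside vocabulary")
})

test_that("OA, PA and UA match hand arithmetic", {
  d <- diag(c(3, 4, 5))
  dimnames(d) <- list(truth = letters[1:3], predicted = letters[1:3])
  expect_equal(overall_accuracy(d), 100)
  expect_true(all(producers_accuracy(d) == 100, users_accuracy(d) == 100))

  cm <- matrix(c(45, 10, 5, 40), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(overall_accuracy(cm), 85.0)
  expect_equal(unname(producers_accuracy(cm)), c(90.0, 80.0))
  expect_equal(unname(users_accuracy(cm)), c(45 / 55, 40 / 45) * 100,
               tolerance = 1e-12)

  # empty truth row: PA undefined, reported NA
  cm2 <- matrix(c(10, 3, 0, 0), 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_true(is.na(producers_accuracy(cm2)[["b"]]))
  expect_false(is.na(users_accuracy(cm2)[["a"]]))
})

test_that("OA decomposes as the PA weighted by class prevalence", {
  set.seed(6)
  for (i in 1:20) {
    cm <- matrix(rpois(9, 8), 3, dimnames = list(letters[1:3], letters[1:3]))
    if (sum(cm) == 0) next
    pa <- producers_accuracy(cm)
    w <- rowSums(cm) / sum(cm)
    ok <- !is.na(pa)
    expect_equal(overall_accuracy(cm) / 100, sum(pa[ok] / 100 * w[ok]))
    # and OA is invariant under a simultaneous class permutation
    p <- sample(3)
    expect_equal(overall_accuracy(cm[p, p]), overall_accuracy(cm))
  }
})

test_that("kappa matches its closed form and its boundary cases", {
  perfect <- diag(c(5, 7, 9))
  dimnames(perfect) <- list(letters[1:3], letters[1:3])
  expect_equal(cohens_kappa(perfect), 1.0)

  indep <- matrix(25, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(cohens_kappa(indep), 0.0)

  cm <- matrix(c(45, 10, 5, 40), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(cohens_kappa(cm), 0.70)

  # independence in general: rows proportional to column totals
  outer_cm <- outer(c(30, 20, 10), c(3, 2, 1))
  dimnames(outer_cm) <- list(letters[1:3], letters[1:3])
  expect_equal(cohens_kappa(outer_cm), 0, tolerance = 1e-12)

  single <- matrix(c(9, 0, 0, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(cohens_kappa(single), "undefined kappa")
})

test_that("kappa agrees with a brute-force oracle on random matrices", {
  set.seed(123)
  for (i in 1:200) {
    cm <- matrix(sample(0:30, 9, replace = TRUE), 3,
                 dimnames = list(letters[1:3], letters[1:3]))
    if (sum(cm) == 0) next
    pe_num <- sum(rowSums(cm) * colSums(cm))
    if (pe_num == sum(cm)^2) next # degenerate
    expect_equal(cohens_kappa(cm), brute_force_kappa(cm), tolerance = 1e-12)
  }
})

test_that("Altman ratings follow the published bands", {
  expect_equal(altman_rating(0.53), "moderate")
  expect_equal(altman_rating(0.74), "good")
  expect_equal(altman_rating(0.91), "particularly good")
  expect_equal(altman_rating(c(-0.5, 0.1, 0.2)), rep("poor", 3))
  expect_equal(altman_rating(c(0.21, 0.40)), rep("regular", 2))
  expect_equal(altman_rating(c(0.41, 0.60)), rep("moderate", 2))
  expect_equal(altman_rating(c(0.61, 0.80)), rep("good", 2))
  expect_equal(altman_rating(1), "particularly good")
  expect_error(altman_rating(1.2), "\\[-1, 1\\]")
})

test_that("accuracy reports bundle all metrics coherently", {
  cm <- matrix(c(45, 10, 5, 40), 2, dimnames = list(c("a", "b"), c("a", "b")))
  rep <- accuracy_report(cm)
  expect_equal(rep$overall_accuracy, 85)
  expect_equal(rep$kappa, 0.70)
  expect_equal(rep$altman, "good")
  expect_equal(rep$n, 100)
})

test_that("timeline evaluation reduces to a direct evaluation on one date", {
  ds <- generate_dataset(tiny_scenario(), seed = 8)
  line <- soil_line(1.62)
  spec <- combination_spec("C4")
  train_ids <- ds$plots$plot_id[ds$plots$split == "train"]
  tab <- assemble_training_table(ds, spec, line, plot_ids = train_ids)
  model <- train_classifier(tab, classifier_spec("svm_cubic"))

  ad <- max(tab$analysis_date)
  tl <- timeline_evaluate(list(C4 = model), ds, line, dates = ad)
  expect_equal(nrow(tl), 1)

  direct <- assemble_training_table(ds, spec, line, analysis_dates = ad)
  pred <- predict(model, direct)
  rep <- accuracy_report(confusion_counts(direct$crop_label, pred, model$classes))
  expect_equal(tl$overall_accuracy, rep$overall_accuracy)
  expect_equal(tl$kappa, rep$kappa)
  expect_equal(tl$n_records, rep$n)
})

test_that("early test-cycle dates admit only the short-lag combination", {
  # on the 2020 calendar, 6 May can only be formed with the 15-day lag (C4)
  cf <- cloudfree_dates(calendar_2020())
  ad <- as.Date("2020-05-06")
  expect_null(match_scenes(cf, ad, combination_spec("C1")))
  expect_null(match_scenes(cf, ad, combination_spec("C2")))
  expect_null(match_scenes(cf, ad, combination_spec("C3")))
  expect_false(is.null(match_scenes(cf, ad, combination_spec("C4"))))
})
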