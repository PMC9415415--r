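test_that("combination schemes carry the standard lags and sizes", {
  expect_equal(combination_spec("C1")$lags, c(0, 30, 60))
  expect_equal(combination_spec("C2")$lags, c(0, 30))
  expect_equal(combination_spec("C3")$lags, c(0, 15, 30))
  expect_equal(combination_spec("C4")$lags, c(0, 15))
  expect_equal(combination_spec("C1")$n_descriptors, 33L)
  expect_equal(combination_spec("C4")$n_descriptors, 22L)
  expect_error(combination_spec("X", lags = c(15, 30)), "lag 0")
  expect_error(combination_spec("X", lags = c(0, 30, 30)), "increasing")
})

test_that("scene matching reproduces the 2019 worked example", {
  cf <- cloudfree_dates(calendar_2019())
  ad <- as.Date("2019-07-06")
  expect_equal(match_scenes(cf, ad, combination_spec("C1"))$matched_dates,
               as.Date(c("2019-07-06", "2019-06-06", "2019-05-07")))
  expect_equal(match_scenes(cf, ad, combination_spec("C2"))$matched_dates,
               as.Date(c("2019-07-06", "2019-06-06")))
  expect_equal(match_scenes(cf, ad, combination_spec("C3"))$matched_dates,
               as.Date(c("2019-07-06", "2019-06-21", "2019-06-06")))
  expect_equal(match_scenes(cf, ad, combination_spec("C4"))$matched_dates,
               as.Date(c("2019-07-06", "2019-06-21")))
})

test_that("scene matching handles edge cases deterministically", {
  # a calendar containing only the analysis date cannot form any lag
  expect_null(match_scenes(as.Date("2019-07-06"), as.Date("2019-07-06"),
                           combination_spec("C4")))
  # analysis must be on a scene date
  expect_error(match_scenes(cloudfree_dates(calendar_2019()),
                            as.Date("2019-07-07"), combination_spec("C4")),
               "not a cloud-free scene date")
  # equidistant candidates resolve toward the earlier date
  dates <- as.Date(c("2019-05-28", "2019-06-03", "2019-06-30"))
  sel <- match_scenes(dates, as.Date("2019-06-30"),
                      combination_spec("X", lags = c(0, 30), tolerance = 5))
  expect_equal(sel$matched_dates[2], as.Date("2019-05-28"))
  # order independence of the input date list
  cf <- cloudfree_dates(calendar_2019())
  shuffled <- cf[sample(length(cf))]
  expect_equal(match_scenes(shuffled, as.Date("2019-08-05"), combination_spec("C1")),
               match_scenes(cf, as.Date("2019-08-05"), combination_spec("C1")))
})

test_that("scene matching agrees with an exhaustive brute-force oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    dates <- sort(as.Date("2019-04-01") + sample(0:160, n))
    spec <- combination_spec(sample(c("C1", "C2", "C3", "C4"), 1))
    ad <- sample(dates, 1)
    got <- match_scenes(dates, ad, spec)
    want <- brute_force_match(dates, ad, spec)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$matched_dates, want)
    }
  }
})

test_that("records are scene-major with 11 descriptors per scene", {
  cf <- cloudfree_dates(calendar_2019())
  feats <- data.frame(date = cf)
  set.seed(3)
  for (d in descriptor_names()) feats[[d]] <- runif(nrow(feats))
  sel1 <- match_scenes(cf, as.Date("2019-07-06"), combination_spec("C1"))
  rec1 <- build_record("P1", sel1, feats, "corn")
  expect_length(rec1$descriptors, 33)
  expect_equal(names(rec1$descriptors)[1:11], paste0(descriptor_names(), "_0"))
  expect_equal(names(rec1$descriptors)[23:33], paste0(descriptor_names(), "_60"))
  # lag-0 block equals the feature row of the analysis date
  row0 <- feats[feats$date == as.Date("2019-07-06"), descriptor_names()]
  expect_equal(unname(rec1$descriptors[1:11]), as.numeric(row0))

  sel4 <- match_scenes(cf, as.Date("2019-07-06"), combination_spec("C4"))
  expect_length(build_record("P1", sel4, feats, "bean")$descriptors, 22)

  # a matched date absent from the feature table is an error
  expect_error(build_record("P1", sel1, feats[-which(feats$date == as.Date("2019-05-07")), ], "corn"),
               "no features for matched date")
})

test_that("emergence filter drops rows with any sub-threshold scene", {
  toy <- toy_filter_table()
  kept <- apply_emergence_filter(toy)
  expect_equal(nrow(kept), 4)
  expect_setequal(kept$plot_id, c("P1", "P3", "P4", "P6"))

  # monotonicity: survivors never increase as the threshold rises
  thresholds <- c(0, 0.005, 0.05, 0.1, 0.25, 0.5)
  survivors <- vapply(thresholds,
                      function(th) nrow(apply_emergence_filter(toy, th)),
                      numeric(1))
  expect_true(all(diff(survivors) <= 0))

  # lagged-only reading keeps a record whose current scene is bare
  lagged <- apply_emergence_filter(toy, scenes = "lagged")
  expect_true("P5" %in% lagged$plot_id)
  expect_false("P2" %in% lagged$plot_id)
})

test_that("training-table assembly enumerates plot x feasible-date records", {
  # 15-day cadence April-August: C1 (lags 30/60) is feasible from the fifth
  # scene onward; two always-emerged alfalfa plots give 2 x 7 = 14 records
  cal <- regular_calendar("2019-04-02", "2019-08-30", cadence_days = 15)
  cfg <- scenario_config(class_counts = c(alfalfa = 2), calendar = cal,
                         spectra = endmember_spectra(noise_sd = 0))
  ds <- generate_dataset(cfg, seed = 3)
  tab <- assemble_training_table(ds, combination_spec("C1"), soil_line(1.62))
  n_dates <- length(cloudfree_dates(cal))
  expect_equal(nrow(tab), 2 * (n_dates - 4))
  expect_equal(ncol(descriptor_matrix(tab)), 33)
  expect_equal(attr(tab, "descriptors")[12:22],
               paste0(descriptor_names(), "_30"))

  # a calendar with a single usable scene cannot form C2 anywhere
  cal1 <- acquisition_calendar(as.Date("2019-06-01") + c(0, 5, 10),
                               cloudy = c(FALSE, TRUE, TRUE))
  cfg1 <- scenario_config(class_counts = c(alfalfa = 2), calendar = cal1)
  ds1 <- generate_dataset(cfg1, seed = 3)
  expect_warning(tab1 <- assemble_training_table(ds1, combination_spec("C2"),
                                                 soil_line(1.62)),
                 "no feasible analysis date")
  expect_equal(nrow(tab1), 0)
})

test_that("the 2019 database mirrors the monthly worked-example rows", {
  # the four example analysis dates and their matched scenes
  cf <- cloudfree_dates(calendar_2019())
  expected <- list(
    "2019-06-06" = c("2019-06-06", "2019-05-07", "2019-04-07"),
    "2019-07-06" = c("2019-07-06", "2019-06-06", "2019-05-07"),
    "2019-08-05" = c("2019-08-05", "2019-07-06", "2019-06-06"),
    "2019-09-04" = c("2019-09-04", "2019-08-05", "2019-07-06")
  )
  for (ad in names(expected)) {
    sel <- match_scenes(cf, as.Date(ad), combination_spec("C1"))
    expect_equal(sel$matched_dates, as.Date(expected[[ad]]))
  }
})
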