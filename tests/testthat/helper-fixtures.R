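# Shared fixtures, built in code.

# A small custom scenario: 20 plots, short season, 15-day cloud-free cadence.
tiny_scenario <- function(noise_sd = 0.005) {
  scenario_config(
    class_counts = c(corn = 10, alfalfa = 6, bean = 4),
    calendar = regular_calendar("2019-04-02", "2019-08-30", cadence_days = 15),
    spectra = endmember_spectra(noise_sd = noise_sd),
    split_fraction = 0.5
  )
}

# A linearly separable toy training table: two (or three) well-separated
# Gaussian blobs in a 22-descriptor space named like a C4 record.
separable_table <- function(n_per_class = 15, classes = c("corn", "alfalfa"),
                            sep = 10, seed = 7) {
  set.seed(seed)
  dn <- as.vector(vapply(c(0, 15), function(l) paste0(descriptor_names(), "_", l),
                         character(11)))
  blocks <- lapply(seq_along(classes), function(i) {
    m <- matrix(stats::rnorm(n_per_class * length(dn), mean = i * sep),
                nrow = n_per_class, dimnames = list(NULL, dn))
    cbind(data.frame(plot_id = sprintf("%s%02d", classes[i], seq_len(n_per_class)),
                     crop_label = classes[i],
                     analysis_date = as.Date("2019-07-06")),
          as.data.frame(m))
  })
  tab <- do.call(rbind, blocks)
  structure(tab, class = c("training_table", "data.frame"),
            descriptors = dn, combination = "C4", lags = c(0, 15))
}

# Six-record toy table with WDVI descriptors for two scenes; records 2 and 5
# carry one sub-threshold scene each.
toy_filter_table <- function() {
  tab <- data.frame(
    plot_id = sprintf("P%d", 1:6),
    crop_label = c("corn", "corn", "bean", "alfalfa", "bean", "corn"),
    WDVI_0  = c(0.30, 0.25, 0.10, 0.40, 0.004, 0.08),
    WDVI_30 = c(0.20, 0.004, 0.09, 0.35, 0.200, 0.05)
  )
  tab
}

# Brute-force scene matcher: enumerate all per-lag candidates within tolerance
# and pick the assignment minimizing total absolute lag error, ties broken
# toward earlier dates lag by lag.
brute_force_match <- function(dates, analysis_date, spec) {
  dates <- sort(unique(as.Date(dates)))
  picks <- vector("list", length(spec$lags))
  for (i in seq_along(spec$lags)) {
    target <- analysis_date - spec$lags[i]
    err <- abs(as.numeric(dates - target))
    ok <- which(err <= spec$tolerance)
    if (length(ok) == 0) return(NULL)
    best <- ok[err[ok] == min(err[ok])]
    picks[[i]] <- dates[best[1]] # earliest among minimal-error candidates
  }
  as.Date(vapply(picks, as.character, character(1)))
}

# Independent kappa: explicit p_o / p_e arithmetic, no shared code path.
brute_force_kappa <- function(cm) {
  n <- sum(cm)
  p_o <- 0
  for (i in seq_len(nrow(cm))) p_o <- p_o + cm[i, i] / n
  p_e <- 0
  for (i in seq_len(nrow(cm))) {
    p_e <- p_e + (sum(cm[i, ]) / n) * (sum(cm[, i]) / n)
  }
  (p_o - p_e) / (1 - p_e)
}
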