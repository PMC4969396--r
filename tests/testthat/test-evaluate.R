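test_that("spike fractions count coverage directly", {
  tr <- spike_train(seq(0.5, 9.5, by = 1), duration = 10)
  none <- burst_set(method = "x")
  expect_equal(spikes_in_bursts_fraction(tr, none), 0)
  all_b <- burst_set(data.frame(first = 1L, last = 10L, begin = 0.5,
                                end = 9.5, n_spikes = 10L,
                                surprise = NA_real_), method = "x")
  expect_equal(spikes_in_bursts_fraction(tr, all_b), 1)
  part <- burst_set(data.frame(first = 1L, last = 8L, begin = 0.5,
                               end = 7.5, n_spikes = 8L,
                               surprise = NA_real_), method = "x")
  expect_equal(spikes_in_bursts_fraction(tr, part), 0.8)
  expect_equal(spikes_in_bursts_fraction(spike_train(numeric(0),
                                                     duration = 1), none), 0)
})

test_that("tp/fp fractions follow the set-intersection definitions", {
  # 20 spikes: first 10 form one ground-truth burst, last 10 are noise
  times <- c(1 + (0:9) * 0.05, seq(5, 27.5, by = 2.5))
  tr <- spike_train(times, duration = 30)
  truth <- burst_set(data.frame(first = 1L, last = 10L, begin = times[1],
                                end = times[10], n_spikes = 10L,
                                surprise = NA_real_), method = "truth")
  lab <- labeled_train(tr, truth, c(rep(TRUE, 10), rep(FALSE, 10)))
  # detected covers 5 burst spikes and 2 noise spikes
  det <- burst_set(data.frame(first = c(1L, 11L), last = c(5L, 12L),
                              begin = c(times[1], times[11]),
                              end = c(times[5], times[12]),
                              n_spikes = c(5L, 2L), surprise = NA_real_),
                   method = "x")
  expect_equal(tp_fp_spike_fractions(det, lab),
               c(tp_fraction = 0.5, fp_fraction = 0.2))
  expect_equal(tp_fp_spike_fractions(truth, lab),
               c(tp_fraction = 1, fp_fraction = 0))
  empty <- burst_set(method = "x")
  expect_equal(tp_fp_spike_fractions(empty, lab),
               c(tp_fraction = 0, fp_fraction = 0))
  # all-burst train: fp denominator empty -> NA, not 0
  lab2 <- sim_poisson_bursting(0.2, 5, 0.3, duration = 100, seed = 3)
  r <- tp_fp_spike_fractions(empty, lab2)
  expect_true(is.na(r[["fp_fraction"]]))
  expect_equal(r[["tp_fraction"]], 0)
})

test_that("sensitivity/specificity match a hand-counted toy train", {
  # 12 spikes; annotation covers spikes 1-6, detection covers 4-9
  times <- (1:12) / 2
  tr <- spike_train(times, duration = 7)
  mk <- function(f, l) {
    burst_set(data.frame(first = f, last = l, begin = times[f],
                         end = times[l], n_spikes = l - f + 1L,
                         surprise = NA_real_), method = "x")
  }
  ann <- mk(1L, 6L); det <- mk(4L, 9L)
  ss <- sensitivity_specificity(det, ann, tr)
  expect_equal(ss[["sensitivity"]], 3 / 6)   # spikes 4,5,6 of 6
  expect_equal(ss[["fpr"]], 3 / 6)           # spikes 7,8,9 of 6 outside
  expect_equal(sensitivity_specificity(ann, ann, tr),
               c(sensitivity = 1, fpr = 0))
  expect_equal(sensitivity_specificity(mk(1L, 12L), ann, tr),
               c(sensitivity = 1, fpr = 1))
  # tp/fp and sensitivity/fpr coincide when annotation is ground truth
  lab <- sim_noisy_bursting(duration = 150, seed = 8)
  det2 <- detect_max_interval(lab$train)
  expect_equal(unname(tp_fp_spike_fractions(det2, lab)),
               unname(sensitivity_specificity(det2, lab$truth, lab$train)))
})

test_that("hamming distance is a normalized metric on masks", {
  expect_equal(hamming_distance_fraction(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_equal(hamming_distance_fraction(c(0, 1, 0), c(1, 0, 1)), 1)
  m <- integer(6000); m2 <- m; m2[1:300] <- 1L
  expect_equal(hamming_distance_fraction(m, m2), 0.05)
  expect_error(hamming_distance_fraction(1:3, 1:4), "equal length")
  set.seed(66)
  for (i in 1:20) {
    a <- rbinom(400, 1, 0.3); b <- rbinom(400, 1, 0.3)
    cc <- rbinom(400, 1, 0.3)
    expect_equal(hamming_distance_fraction(a, b),
                 hamming_distance_fraction(b, a))
    expect_equal(hamming_distance_fraction(a, a), 0)
    expect_lte(hamming_distance_fraction(a, cc),
               hamming_distance_fraction(a, b) +
                 hamming_distance_fraction(b, cc))
  }
})

test_that("burst summaries report durations, counts and CV of IBI", {
  # periodic bursts: constant IBI, CV = 0
  times <- unlist(lapply(seq(0, 90, by = 10), function(o) o + c(0, 0.1, 0.2)))
  tr <- spike_train(times, duration = 100)
  det <- detect_max_interval(tr)
  s <- burst_summary(tr, det)
  expect_equal(s$burst_count, 10)
  expect_equal(s$cv_of_ibi, 0)
  expect_equal(s$mean_burst_duration, 0.2)
  expect_equal(s$fraction_spikes_in_bursts, 1)
  # toy durations average
  mk <- function(begin, end) {
    data.frame(first = NA_integer_, last = NA_integer_, begin = begin,
               end = end, n_spikes = 3L, surprise = NA_real_)
  }
  bs <- burst_set(mk(c(0, 1, 2, 3), c(0.1, 1.2, 2.3, 3.4)), method = "x")
  expect_equal(burst_summary(tr, bs)$mean_burst_duration, 0.25)
  # < 3 bursts: CV undefined
  one <- burst_set(mk(1, 1.5), method = "x")
  expect_true(is.na(burst_summary(tr, one)$cv_of_ibi))
  # start-to-start option
  s2 <- burst_summary(tr, det, ibi = "start_to_start")
  expect_equal(s2$cv_of_ibi, 0)
})

test_that("burst recovery counts intersected ground-truth bursts", {
  lab <- sim_poisson_bursting(0.2, 5, 0.3, duration = 120, seed = 5)
  expect_equal(burst_recovery_fraction(lab$truth, lab$truth), 1)
  expect_equal(burst_recovery_fraction(burst_set(method = "x"), lab$truth), 0)
  expect_true(is.na(burst_recovery_fraction(lab$truth,
                                            burst_set(method = "x"))))
})

test_that("roc_sweep averages per-train points and scores distance", {
  set.seed(41)
  labs <- lapply(1:3, function(i) {
    sim_noisy_bursting(duration = 120, seed = 100 + i)
  })
  trains <- lapply(labs, `[[`, "train")
  anns <- lapply(labs, `[[`, "truth")
  # CMA yields exactly one ROC point
  r_cma <- roc_sweep(trains, anns, "cma")
  expect_equal(nrow(r_cma$points), 1)
  # per-train averaging equals the arithmetic mean of per-train values
  grid <- list(detector_params("mi"))
  r_mi <- roc_sweep(trains, anns, "mi", grid = grid)
  per <- vapply(seq_along(trains), function(i) {
    sensitivity_specificity(detect_bursts(trains[[i]], "mi"),
                            anns[[i]], trains[[i]])
  }, numeric(2))
  expect_equal(r_mi$points$sensitivity, mean(per[1, ]))
  expect_equal(r_mi$points$fpr, mean(per[2, ]))
  expect_equal(r_mi$points$distance,
               sqrt(mean(per[2, ])^2 + (1 - mean(per[1, ]))^2))
  # a detector that reproduces the annotation has distance 0
  perfect <- function(train, params = NULL, ...) {
    anns[[which(vapply(trains, identical, logical(1), train))]]
  }
  register_detector("oracle_ann", perfect)
  r_p <- roc_sweep(trains, anns, "oracle_ann", grid = list(list()))
  expect_equal(r_p$best_distance, 0)
  expect_gte(r_mi$best_distance, 0)
})

test_that("property benchmark tables are reproducible and well-formed", {
  r1 <- run_property_benchmark("D7", methods = c("mi", "cma"),
                               n_trains = 3, duration = 60, seed = 2)
  r2 <- run_property_benchmark("D7", methods = c("mi", "cma"),
                               n_trains = 3, duration = 60, seed = 2)
  expect_identical(r1, r2)
  expect_setequal(unique(r1$method), c("truth", "mi", "cma"))
  expect_true(all(c("fraction_spikes_in_bursts", "tp_fraction",
                    "burst_recovery") %in% r1$metric))
  expect_error(run_property_benchmark("D1", "mi", 2, 60, 1),
               "unknown property")
  s <- summarize_benchmark(r1)
  expect_true(all(c("median", "q25", "q75") %in% names(s)))
  expect_true(all(s$q25 <= s$median & s$median <= s$q75))
})
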