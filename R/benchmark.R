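#' Simulate one benchmark train for a desirable-property scenario
#'
#' The benchmark scenarios describe spike-train regimes a burst
#' detector should handle: `D4` homogeneous Poisson at 1 Hz
#' (computational-load scenario), `D5` nonbursting (alternating
#' Poisson 0.5 Hz and gamma-ISI shape 1 rate 0.5/s trains, smallest
#' 10% of ISIs trimmed), `D6` nonstationary nonbursting (inhomogeneous
#' Poisson with intensity 1 + t/300 Hz, trimmed), `D7` regular short
#' bursts (burst rate 0.2 Hz, mean 5 spikes, 0.3-s spread), `D8`
#' nonstationary bursts (0.3 Hz, size ~ U(5,18), spread ~ U(0.3,3) s,
#' 5-Hz within-burst rate floor), `D9` long bursts (0.1 Hz, 18 spikes,
#' 3-s spread), `D10` high-frequency bursts (1 Hz, 10 spikes, 0.5-s
#' spread), `D11` noisy bursting (0.5 Hz, 8 spikes, 0.8-s spread plus
#' trimmed gamma noise and a 0.5-s exclusion margin).
#'
#' Nonbursting scenarios return a `labeled_train` with an empty
#' ground-truth burst set; bursting scenarios have every spike inside a
#' ground-truth burst (except D11, where noise spikes carry `FALSE`
#' membership).
#'
#' @param property scenario id, `"D4"` to `"D11"`.
#' @param index train index within the scenario (selects the
#'   deterministic substream, and for D5 whether the train is
#'   Poisson — odd index — or gamma).
#' @param duration recording duration in seconds.
#' @param seed master seed; the train's stream is derived from
#'   `(seed, property, index)` so any train is reproducible in
#'   isolation.
#' @return A [labeled_train].
#' @export
sim_property_train <- function(property, index = 1L, duration = 300,
                               seed = 1L) {
  props <- paste0("D", 4:11)
  if (!property %in% props) {
    stop("unknown property id: ", property,
         " (expected one of ", paste(props, collapse = ", "), ")",
         call. = FALSE)
  }
  s <- substream_seed(seed, match(property, props) * 100000L + index)
  id <- sprintf("%s_%03d", property, index)
  as_labeled <- function(train) {
    labeled_train(train, burst_set(method = "truth"),
                  rep(FALSE, length(train$times)))
  }
  switch(property,
    D4 = as_labeled(sim_poisson_train(1, duration, seed = s, id = id)),
    D5 = {
      tr <- if (index %% 2 == 1) {
        sim_poisson_train(0.5, duration, seed = s, id = id)
      } else {
        sim_gamma_train(1, 0.5, duration, seed = s, id = id)
      }
      as_labeled(trim_smallest_isis(tr, 0.1))
    },
    D6 = as_labeled(trim_smallest_isis(
      sim_inhomogeneous_poisson(1, 1 / duration, duration, seed = s,
                                id = id), 0.1)),
    D7 = sim_poisson_bursting(0.2, 5, 0.3, duration, seed = s, id = id),
    D8 = sim_nonstationary_bursting(0.3, c(5, 18), c(0.3, 3), duration,
                                    seed = s, id = id),
    D9 = sim_poisson_bursting(0.1, 18, 3, duration, seed = s, id = id),
    D10 = sim_poisson_bursting(1, 10, 0.5, duration, seed = s, id = id),
    D11 = sim_noisy_bursting(duration = duration, seed = s, id = id))
}

#' Run the synthetic-property benchmark
#'
#' Simulates `n_trains` spike trains for one benchmark scenario (see
#' [sim_property_train]), runs each requested detector on every train,
#' and scores the results against the ground truth. The output is a
#' tidy table with one row per (train, method, metric).
#'
#' Metrics reported per train and method:
#' `fraction_spikes_in_bursts` (always); `tp_fraction` and
#' `fp_fraction` where ground-truth burst and noise spikes exist
#' (D11; on pure-bursting scenarios `tp_fraction` equals the fraction
#' of spikes in bursts); `burst_count_ratio` (detected / true burst
#' count) and `burst_recovery` (fraction of true bursts intersected)
#' on bursting scenarios. Ground-truth rows are included under method
#' `"truth"`.
#'
#' @param property scenario id, `"D4"` to `"D11"`.
#' @param methods character vector of detector names.
#' @param n_trains number of simulated trains.
#' @param duration train duration in seconds.
#' @param seed master seed; the run is bitwise reproducible.
#' @param preset parameter preset passed to [detector_params].
#' @return data.frame with columns `property`, `train`, `method`,
#'   `metric`, `value`.
#' @examples
#' res <- run_property_benchmark("D7", methods = "mi", n_trains = 3,
#'                               duration = 60, seed = 1)
#' aggregate(value ~ metric, data = subset(res, method == "mi"), median)
#' @export
run_property_benchmark <- function(property,
                                   methods = c("mi", "logisi", "cma", "ps",
                                               "rs", "rgs", "irt"),
                                   n_trains = 100L, duration = 300,
                                   seed = 1L, preset = "standard") {
  rows <- list()
  add <- function(train_i, method, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      property = property, train = train_i, method = method,
      metric = metric, value = as.numeric(value))
  }
  for (i in seq_len(n_trains)) {
    lab <- sim_property_train(property, i, duration, seed)
    truth_frac <- if (length(lab$membership)) mean(lab$membership) else 0
    add(i, "truth", "fraction_spikes_in_bursts", truth_frac)
    add(i, "truth", "burst_count", nrow(lab$truth$bursts))
    for (m in methods) {
      det <- detect_bursts(lab$train, m, params = detector_params(m, preset))
      add(i, m, "fraction_spikes_in_bursts",
          spikes_in_bursts_fraction(lab$train, det))
      add(i, m, "burst_count", nrow(det$bursts))
      if (nrow(lab$truth$bursts)) {
        tpfp <- tp_fp_spike_fractions(det, lab)
        add(i, m, "tp_fraction", tpfp[["tp_fraction"]])
        if (!is.na(tpfp[["fp_fraction"]])) {
          add(i, m, "fp_fraction", tpfp[["fp_fraction"]])
        }
        add(i, m, "burst_count_ratio",
            nrow(det$bursts) / nrow(lab$truth$bursts))
        add(i, m, "burst_recovery",
            burst_recovery_fraction(det, lab$truth))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median and IQR summary of a benchmark table
#'
#' Aggregates a [run_property_benchmark] table across trains, matching
#' box-plot reporting: median and interquartile range per (method,
#' metric).
#'
#' @param results data.frame from [run_property_benchmark].
#' @return data.frame with `method`, `metric`, `median`, `q25`, `q75`,
#'   `n`.
#' @export
summarize_benchmark <- function(results) {
  sp <- split(results, list(results$method, results$metric), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    qs <- stats::quantile(d$value, c(0.25, 0.5, 0.75), na.rm = TRUE,
                          names = FALSE)
    data.frame(method = d$method[1], metric = d$metric[1],
               median = qs[2], q25 = qs[1], q75 = qs[3],
               n = sum(!is.na(d$value)))
  }))
  rownames(out) <- NULL
  out[order(out$metric, out$method), ]
}
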