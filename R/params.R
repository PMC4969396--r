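#' Detector parameter bundles
#'
#' Returns the parameter list for one detector, pre-filled with the
#' standard defaults used throughout the synthetic benchmark
#' (`preset = "standard"`), or with the alternative regime tuned for
#' sparse human iPSC-derived network recordings (`preset = "hipsc"`:
#' Poisson surprise threshold raised to -log(0.0025), MaxInterval
#' maximum beginning ISI 0.2 s, logISI maximum cutoff 150 ms, and CMA
#' post-hoc screening caps of 5 s mean burst duration / 50 spikes per
#' burst). Any field can be overridden through `...`.
#'
#' Default values by method (`"standard"`):
#' \describe{
#'   \item{mi}{`max_begin_isi` 0.17 s, `max_end_isi` 0.3 s, `min_ibi`
#'     0.2 s, `min_duration` 0.01 s, `min_spikes` 3.}
#'   \item{ps}{`s_min` = -log(0.01) (~4.6), surprise-maximization
#'     lookahead 10 spikes.}
#'   \item{rs}{`rs_min` = -log(0.01), `isi_limit_percentile` 0.75,
#'     exact rank-sum convolution up to `exact_max_q` = 12 ISIs.}
#'   \item{rgs}{`gs_min` = -log(0.01), `mad_multiplier` -2.58 applied to
#'     the Gaussian-consistent scaled MAD.}
#'   \item{irt}{rank threshold `theta_r` 0.5, spike-count cutoff at
#'     upper-tail level `count_tail_p` 0.05 of 1-s window counts.}
#'   \item{cma}{ISI histogram bin width `bin_width` 0.1 s; the
#'     skewness of the CMA curve selects `(alpha1, alpha2)` via
#'     [cma_alpha_from_skew].}
#'   \item{logisi}{`max_cutoff` 0.1 s, `void_threshold` 0.7, 10
#'     histogram bins per log10 decade, Gaussian smoothing sd
#'     `smooth_sd` = 2 bins.}
#' }
#'
#' All methods share a global minimum of `min_spikes = 3` spikes per
#' burst.
#'
#' @param method one of `"mi"`, `"ps"`, `"rs"`, `"rgs"`, `"irt"`,
#'   `"cma"`, `"logisi"`.
#' @param preset `"standard"` or `"hipsc"`.
#' @param ... named overrides of individual fields.
#' @return A named list of parameters with class `detector_params`.
#' @examples
#' detector_params("mi")
#' detector_params("ps", preset = "hipsc")
#' detector_params("logisi", max_cutoff = 0.15)
#' @export
detector_params <- function(method = c("mi", "ps", "rs", "rgs", "irt",
                                       "cma", "logisi"),
                            preset = c("standard", "hipsc"), ...) {
  method <- match.arg(method)
  preset <- match.arg(preset)
  p <- switch(method,
    mi = list(max_begin_isi = 0.17, max_end_isi = 0.3, min_ibi = 0.2,
              min_duration = 0.01, min_spikes = 3L),
    ps = list(s_min = -log(0.01), lookahead = 10L, min_spikes = 3L),
    rs = list(rs_min = -log(0.01), isi_limit_percentile = 0.75,
              exact_max_q = 12L, min_spikes = 3L),
    rgs = list(gs_min = -log(0.01), mad_multiplier = -2.58, min_spikes = 3L),
    irt = list(theta_r = 0.5, count_tail_p = 0.05, min_spikes = 3L),
    cma = list(bin_width = 0.1, min_spikes = 3L),
    logisi = list(max_cutoff = 0.1, void_threshold = 0.7,
                  bins_per_decade = 10L, smooth_sd = 2, min_spikes = 3L))
  if (preset == "hipsc") {
    p <- switch(method,
      ps = utils::modifyList(p, list(s_min = -log(0.0025))),
      mi = utils::modifyList(p, list(max_begin_isi = 0.2)),
      logisi = utils::modifyList(p, list(max_cutoff = 0.15)),
      cma = utils::modifyList(p, list(max_mean_burst_duration = 5,
                                      max_mean_spikes_per_burst = 50)),
      p)
  }
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), c(names(p), "max_mean_burst_duration",
                                  "max_mean_spikes_per_burst"))
    if (length(bad)) {
      stop("unknown parameter(s) for method '", method, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    p <- utils::modifyList(p, over)
  }
  structure(c(p, list(method = method, preset = preset)),
            class = "detector_params")
}

#' @export
print.detector_params <- function(x, ...) {
  cat(sprintf("<detector_params: %s (%s preset)>\n", x$method, x$preset))
  flds <- setdiff(names(x), c("method", "preset"))
  for (f in flds) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}
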