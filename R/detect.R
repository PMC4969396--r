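#' Detect bursts on a spike train
#'
#' Generic front end to the seven detectors. All detectors are
#' deterministic — identical input and parameters always give the same
#' bursts — and every returned burst contains at least three spikes,
#' with non-overlapping spike-index ranges ordered by begin time.
#'
#' Methods: `"mi"` MaxInterval ([detect_max_interval]), `"logisi"`
#' log-ISI histogram ([detect_logisi]), `"cma"` cumulative moving
#' average ([detect_cma]), `"ps"` Poisson surprise
#' ([detect_poisson_surprise]), `"rs"` rank surprise
#' ([detect_rank_surprise]), `"rgs"` robust Gaussian surprise
#' ([detect_rgs]), `"irt"` ISI rank threshold ([detect_irt]).
#' Additional detectors registered with [register_detector] are
#' addressed by their registered name.
#'
#' Note that RGS is defined on a whole recording: when called through
#' `detect_bursts` on one train, the central distribution is estimated
#' from that train alone. Use [detect_rgs] with a list of trains to
#' pool ISIs across electrodes.
#'
#' @param train a `spike_train`.
#' @param method detector name.
#' @param params a [detector_params]; defaults to the standard preset
#'   for `method`.
#' @param ... passed on to plugin detectors.
#' @return A `burst_set`.
#' @examples
#' lab <- sim_poisson_bursting(0.2, 5, 0.3, duration = 60, seed = 1)
#' detect_bursts(lab$train, "mi")
#' @export
detect_bursts <- function(train, method = c("mi", "logisi", "cma", "ps",
                                            "rs", "rgs", "irt"),
                          params = NULL, ...) {
  if (length(method) == 1 && !method %in% c("mi", "logisi", "cma", "ps",
                                            "rs", "rgs", "irt")) {
    fn <- .detector_registry[[method]]
    if (is.null(fn)) stop("unknown detector: ", method, call. = FALSE)
    return(fn(train, params = params, ...))
  }
  method <- match.arg(method)
  if (is.null(params)) params <- detector_params(method)
  if (!identical(params$method, method)) {
    stop(sprintf("params are for method '%s', not '%s'",
                 params$method, method), call. = FALSE)
  }
  switch(method,
         mi = detect_max_interval(train, params),
         logisi = detect_logisi(train, params),
         cma = detect_cma(train, params),
         ps = detect_poisson_surprise(train, params),
         rs = detect_rank_surprise(train, params),
         rgs = detect_rgs(train, params),
         irt = detect_irt(train, params))
}

.detector_registry <- new.env(parent = emptyenv())

#' Register a plugin burst detector
#'
#' External detectors (for example a wrapper around a hidden semi-Markov
#' model sampler) can be plugged in under the same contract as the
#' built-in methods: a function `f(train, params, ...)` returning a
#' `burst_set`. Once registered, the detector is reachable through
#' [detect_bursts] by name.
#'
#' @param name detector name (must not clash with a built-in method).
#' @param fn function of `(train, params, ...)` returning a `burst_set`.
#' @return Invisibly, `name`.
#' @export
register_detector <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  if (name %in% c("mi", "logisi", "cma", "ps", "rs", "rgs", "irt")) {
    stop("cannot override a built-in detector", call. = FALSE)
  }
  .detector_registry[[name]] <- fn
  invisible(name)
}
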