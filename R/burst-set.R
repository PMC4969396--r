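#' Burst set objects
#'
#' A `burst_set` is the universal detector output: an ordered collection
#' of non-overlapping bursts on one spike train. Each burst is a
#' contiguous run of spikes, stored with its 1-based inclusive spike
#' indices, begin/end times (seconds), spike count, duration and, for the
#' surprise-based detectors, the surprise score S = -log(p).
#'
#' @param bursts data.frame with columns `first`, `last` (1-based
#'   inclusive spike indices; may be NA for annotations read from file),
#'   `begin`, `end` (s), `n_spikes`, `surprise` (NA where not
#'   applicable). A `duration` column is derived. Zero-row input is a
#'   valid, empty burst set.
#' @param method character: name of the detector that produced the set
#'   (or `"annotation"`/`"truth"`).
#' @param params list of the detector parameters used, for provenance.
#'
#' @return An object of class `burst_set`.
#' @export
burst_set <- function(bursts = empty_bursts_df(), method = "unknown",
                      params = list()) {
  need <- c("first", "last", "begin", "end", "n_spikes", "surprise")
  for (col in setdiff(need, names(bursts))) {
    bursts[[col]] <- if (col == "surprise") NA_real_ else NA_integer_
  }
  bursts <- as.data.frame(bursts)[seq_len(nrow(bursts)), need, drop = FALSE]
  if (nrow(bursts)) {
    if (any(bursts$end < bursts$begin)) {
      stop("burst end time precedes begin time", call. = FALSE)
    }
    ord <- order(bursts$begin)
    bursts <- bursts[ord, , drop = FALSE]
    rownames(bursts) <- NULL
    ok_idx <- !is.na(bursts$first) & !is.na(bursts$last)
    if (any(ok_idx) && nrow(bursts) > 1) {
      f <- bursts$first[ok_idx]; l <- bursts$last[ok_idx]
      if (length(f) > 1 && any(f[-1] <= l[-length(l)])) {
        stop("bursts overlap in spike indices", call. = FALSE)
      }
    }
  }
  bursts$duration <- bursts$end - bursts$begin
  structure(list(bursts = bursts, method = method, params = params),
            class = "burst_set")
}

empty_bursts_df <- function() {
  data.frame(first = integer(0), last = integer(0),
             begin = numeric(0), end = numeric(0),
             n_spikes = integer(0), surprise = numeric(0))
}

# build a burst_set from first/last spike indices on a train
bursts_from_indices <- function(train, first, last, method, params = list(),
                                surprise = NULL) {
  first <- as.integer(first); last <- as.integer(last)
  if (is.null(surprise)) surprise <- rep(NA_real_, length(first))
  df <- data.frame(first = first, last = last,
                   begin = train$times[first], end = train$times[last],
                   n_spikes = last - first + 1L,
                   surprise = as.numeric(surprise))
  burst_set(df, method = method, params = params)
}

#' @export
print.burst_set <- function(x, ...) {
  b <- x$bursts
  cat(sprintf("<burst_set> %d bursts (method: %s)\n", nrow(b), x$method))
  if (nrow(b)) {
    cat(sprintf("  spikes/burst: median %g; duration: median %.4g s\n",
                stats::median(b$n_spikes), stats::median(x$bursts$duration)))
    print(utils::head(b, 10))
    if (nrow(b) > 10) cat(sprintf("  ... %d more\n", nrow(b) - 10))
  }
  invisible(x)
}

#' @export
as.data.frame.burst_set <- function(x, ...) x$bursts

#' Number of bursts in a set
#' @param bursts a `burst_set`.
#' @return integer count.
#' @export
n_bursts <- function(bursts) nrow(bursts$bursts)

#' Labeled spike train (simulator output)
#'
#' Couples a simulated `spike_train` with its ground-truth bursts and the
#' per-spike burst membership (`TRUE` for within-burst spikes, `FALSE`
#' for noise spikes). This is the reference object the benchmark scores
#' detectors against.
#'
#' @param train a `spike_train`.
#' @param truth a `burst_set` of ground-truth bursts.
#' @param membership logical vector, one entry per spike.
#' @return An object of class `labeled_train`.
#' @export
labeled_train <- function(train, truth, membership) {
  stopifnot(inherits(train, "spike_train"), inherits(truth, "burst_set"),
            length(membership) == length(train$times))
  b <- truth$bursts
  if (nrow(b) && any(b$n_spikes < 1)) {
    stop("every ground-truth burst must contain at least one spike",
         call. = FALSE)
  }
  in_truth <- rep(FALSE, length(train$times))
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) in_truth[b$first[k]:b$last[k]] <- TRUE
  }
  if (!identical(as.logical(membership), in_truth)) {
    stop("membership inconsistent with ground-truth burst intervals",
         call. = FALSE)
  }
  structure(list(train = train, truth = truth,
                 membership = as.logical(membership)),
            class = "labeled_train")
}

#' @export
print.labeled_train <- function(x, ...) {
  cat(sprintf(
    "<labeled_train '%s'> %d spikes, %d ground-truth bursts, %.1f%% in bursts\n",
    x$train$id, length(x$train$times), nrow(x$truth$bursts),
    100 * mean(x$membership)))
  invisible(x)
}

# spike indices covered by any burst of a set; falls back to time
# intervals when indices are absent (annotations read from file)
spikes_in_set <- function(train, bursts) {
  b <- bursts$bursts
  out <- logical(length(train$times))
  if (is.null(b) || !nrow(b)) return(out)
  for (k in seq_len(nrow(b))) {
    if (!is.na(b$first[k]) && !is.na(b$last[k])) {
      out[b$first[k]:b$last[k]] <- TRUE
    } else {
      out[train$times >= b$begin[k] & train$times <= b$end[k]] <- TRUE
    }
  }
  out
}
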