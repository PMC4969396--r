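#' Read spike trains from plain-text timestamp files
#'
#' Two formats are supported. `"timestamps"`: one spike time (seconds)
#' per line, one train per file — the form produced by exporting action
#' potential timestamps from acquisition software to text. `"multitrain_csv"`:
#' a CSV with header `train_id,time_s` holding any number of trains.
#'
#' Times must be numeric, non-negative and strictly increasing within a
#' train; duplicate times are rejected because downstream rank-based
#' detectors require strictly positive ISIs. Validation errors name the
#' offending line.
#'
#' @param path file to read.
#' @param format `"timestamps"` or `"multitrain_csv"`.
#' @param duration recording duration in seconds applied to every train;
#'   if `NULL`, each train's duration defaults to its last spike time
#'   rounded up to the next whole second.
#' @return A list of [spike_train] objects (length 1 for `"timestamps"`).
#' @export
read_spike_trains <- function(path, format = c("timestamps", "multitrain_csv"),
                              duration = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "timestamps") {
    lines <- readLines(path)
    keep <- nzchar(trimws(lines))
    vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
    if (anyNA(vals)) {
      bad <- which(keep)[which(is.na(vals))[1]]
      stop(sprintf("non-numeric spike time at line %d of %s: '%s'",
                   bad, path, trimws(lines[bad])), call. = FALSE)
    }
    list(.validate_times(vals, which(keep), path,
                         duration = duration,
                         id = sub("\\.[^.]*$", "", basename(path))))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("train_id", "time_s") %in% names(df))) {
      stop("multitrain CSV must have header train_id,time_s", call. = FALSE)
    }
    tm <- suppressWarnings(as.numeric(df$time_s))
    if (anyNA(tm)) {
      bad <- which(is.na(tm))[1] + 1L  # + header line
      stop(sprintf("non-numeric spike time at line %d of %s", bad, path),
           call. = FALSE)
    }
    ids <- unique(df$train_id)
    lapply(ids, function(i) {
      rows <- which(df$train_id == i)
      .validate_times(tm[rows], rows + 1L, path, duration = duration,
                      id = as.character(i))
    })
  }
}

.validate_times <- function(vals, lines, path, duration, id) {
  if (length(vals) && any(vals < 0)) {
    bad <- lines[which(vals < 0)[1]]
    stop(sprintf("negative spike time at line %d of %s", bad, path),
         call. = FALSE)
  }
  if (length(vals) > 1) {
    d <- diff(vals)
    if (any(d < 0)) {
      bad <- lines[which(d < 0)[1] + 1L]
      stop(sprintf("spike times not sorted at line %d of %s", bad, path),
           call. = FALSE)
    }
    if (any(d == 0)) {
      bad <- lines[which(d == 0)[1] + 1L]
      stop(sprintf("duplicate spike time at line %d of %s", bad, path),
           call. = FALSE)
    }
  }
  spike_train(vals, duration = duration, id = id)
}

#' Write and read burst-interval CSV files
#'
#' Burst intervals travel as CSV with header
#' `train_id,begin_s,end_s,n_spikes,method`. Times are written with
#' microsecond (6-decimal) precision; reading a file written by
#' [write_bursts] reproduces the burst times exactly at that precision.
#' The same format carries visually annotated bursts used as a
#' sensitivity/specificity reference.
#'
#' @param bursts a `burst_set`.
#' @param path output file.
#' @param train_id label written in the `train_id` column.
#' @return `write_bursts` invisibly returns `path`.
#' @export
write_bursts <- function(bursts, path, train_id = "train") {
  stopifnot(inherits(bursts, "burst_set"))
  b <- bursts$bursts
  df <- data.frame(train_id = rep(train_id, nrow(b)),
                   begin_s = sprintf("%.6f", b$begin),
                   end_s = sprintf("%.6f", b$end),
                   n_spikes = b$n_spikes,
                   method = rep(bursts$method, nrow(b)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bursts
#' @param train optional `spike_train`; when supplied, spike indices of
#'   each interval are reconstructed so the result can be scored against
#'   detector output.
#' @return `read_bursts` returns a `burst_set` (spike indices `NA` unless
#'   `train` is given).
#' @export
read_bursts <- function(path, train = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("train_id", "begin_s", "end_s", "n_spikes", "method")
  if (!all(need %in% names(df))) {
    stop("burst CSV must have header train_id,begin_s,end_s,n_spikes,method",
         call. = FALSE)
  }
  begin <- as.numeric(df$begin_s); end <- as.numeric(df$end_s)
  if (anyNA(begin) || anyNA(end)) {
    stop("non-numeric burst boundary in ", path, call. = FALSE)
  }
  if (any(end < begin)) {
    stop(sprintf("burst interval with end < begin at row %d of %s",
                 which(end < begin)[1], path), call. = FALSE)
  }
  first <- last <- rep(NA_integer_, nrow(df))
  if (!is.null(train) && nrow(df)) {
    eps <- 1e-6   # written precision: boundary spikes must not drop out
    for (k in seq_len(nrow(df))) {
      inside <- which(train$times >= begin[k] - eps &
                        train$times <= end[k] + eps)
      if (length(inside)) {
        first[k] <- inside[1]; last[k] <- inside[length(inside)]
      }
    }
  }
  method <- if (nrow(df)) df$method[1] else "unknown"
  burst_set(data.frame(first = first, last = last, begin = begin, end = end,
                       n_spikes = as.integer(df$n_spikes),
                       surprise = rep(NA_real_, nrow(df))),
            method = method)
}
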