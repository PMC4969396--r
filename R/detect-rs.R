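#' Rank-sum p-value of the discrete uniform sum distribution
#'
#' Probability that the sum of `q` independent draws from the discrete
#' uniform distribution on `{1, ..., n_isi}` is less than or equal to
#' `rank_sum`. This is the null distribution of the sum of ISI ranks on
#' a candidate bursting interval when ranks are exchangeable. The exact
#' distribution is computed by convolution for `q <= exact_max_q`; above
#' that, a Gaussian approximation with continuity correction is used
#' (mean `q*(n_isi+1)/2`, variance `q*(n_isi^2-1)/12`).
#'
#' @param rank_sum observed sum of ranks (mid-ranks allowed, so possibly
#'   half-integer); must lie in `[q, q*n_isi]`.
#' @param q number of ISIs in the candidate interval (>= 1).
#' @param n_isi total number of ISIs on the train.
#' @param exact_max_q largest `q` for which the exact convolution is
#'   used.
#' @return p-value in (0, 1].
#' @examples
#' rank_surprise_pvalue(1, 1, 10)   # 0.1
#' rank_surprise_pvalue(3, 2, 10)   # 0.03
#' @export
rank_surprise_pvalue <- function(rank_sum, q, n_isi, exact_max_q = 12L) {
  if (q < 1 || n_isi < 1) stop("q and n_isi must be >= 1", call. = FALSE)
  if (rank_sum < q || rank_sum > q * n_isi) {
    stop("rank_sum out of range [q, q*n_isi]", call. = FALSE)
  }
  if (q <= exact_max_q) {
    cdf <- .uniform_sum_cdf(q, n_isi)
    # support is q..q*n_isi; P(S <= rank_sum) with integer-valued S
    k <- floor(rank_sum) - q + 1L
    unname(cdf[max(1L, min(length(cdf), k))])
  } else {
    mu <- q * (n_isi + 1) / 2
    sigma <- sqrt(q * (n_isi^2 - 1) / 12)
    min(1, stats::pnorm(rank_sum + 0.5, mean = mu, sd = sigma))
  }
}

# CDF vector of the sum of q discrete uniforms on {1..n}, on support
# q..q*n. Cached per (q, n) within a session.
.uniform_sum_cdf <- local({
  cache <- new.env(parent = emptyenv())
  function(q, n) {
    key <- paste(q, n, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    pmf <- rep(1 / n, n)
    acc <- pmf
    if (q > 1) {
      for (i in seq_len(q - 1)) {
        acc <- .conv(acc, pmf)
      }
    }
    out <- pmin(1, cumsum(acc))
    cache[[key]] <- out
    out
  }
})

# open (polynomial) convolution; FFT above a size cutoff, direct below
.conv <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (as.double(la) * lb <= 4096) {
    out <- numeric(la + lb - 1)
    for (j in seq_len(lb)) {
      out[j:(j + la - 1)] <- out[j:(j + la - 1)] + a * b[j]
    }
    return(out)
  }
  out <- stats::convolve(a, rev(b), type = "open")
  pmax(out, 0)
}

#' Rank surprise burst detection
#'
#' ISIs are ranked across the whole train (mid-ranks on ties, smallest
#' ISI rank 1). Only ISIs at or below the `isi_limit_percentile`
#' quantile (default 75th percentile) may belong to a burst. Within
#' every maximal run of such ISIs, all sub-windows of at least two ISIs
#' are evaluated: the rank surprise RS = -log(p) with p from
#' [rank_surprise_pvalue]. Candidates are accepted greedily by
#' descending RS (ties: earlier start), excluding overlap in spike
#' indices, and candidates below `rs_min` are discarded.
#'
#' @param train a `spike_train`.
#' @param params a [detector_params] for method `"rs"`.
#' @return A `burst_set`; the `surprise` column holds each burst's RS.
#' @export
detect_rank_surprise <- function(train, params = detector_params("rs")) {
  stopifnot(inherits(train, "spike_train"))
  t <- train$times
  n <- length(t)
  out_empty <- burst_set(method = "rs", params = params)
  min_sp <- max(3L, params$min_spikes)
  if (n < min_sp) return(out_empty)
  iv <- diff(t)
  n_isi <- length(iv)
  rk <- rank(iv)                       # mid-ranks on ties
  limit <- stats::quantile(iv, params$isi_limit_percentile, names = FALSE)
  ok <- iv <= limit
  if (!any(ok)) return(out_empty)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_sp - 1L)
  if (!length(runs)) return(out_empty)
  crk <- c(0, cumsum(rk))
  cand_first <- integer(0); cand_last <- integer(0); cand_rs <- numeric(0)
  for (s in runs) {
    a <- starts[s]; b <- ends[s]
    for (u in a:(b - min_sp + 2L)) {
      for (v in (u + min_sp - 2L):b) {
        rsum <- crk[v + 1L] - crk[u]
        p <- rank_surprise_pvalue(rsum, v - u + 1L, n_isi,
                                  exact_max_q = params$exact_max_q)
        rs <- -log(p)
        if (rs >= params$rs_min) {
          cand_first <- c(cand_first, u)
          cand_last <- c(cand_last, v + 1L)   # spike index of window end
          cand_rs <- c(cand_rs, rs)
        }
      }
    }
  }
  if (!length(cand_first)) return(out_empty)
  ord <- order(-cand_rs, cand_first)
  taken <- logical(n)
  first <- integer(0); last <- integer(0); rs_v <- numeric(0)
  for (k in ord) {
    idx <- cand_first[k]:cand_last[k]
    if (!any(taken[idx])) {
      taken[idx] <- TRUE
      first <- c(first, cand_first[k]); last <- c(last, cand_last[k])
      rs_v <- c(rs_v, cand_rs[k])
    }
  }
  ord <- order(first)
  bursts_from_indices(train, first[ord], last[ord],
                      method = "rs", params = params,
                      surprise = rs_v[ord])
}
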