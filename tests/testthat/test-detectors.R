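test_that("MaxInterval applies its five thresholds as specified", {
  tr <- spike_train(c(0, 0.05, 0.10, 1.0, 1.05, 1.10, 5.0), duration = 6)
  out <- detect_max_interval(tr)
  expect_equal(nrow(out$bursts), 2)
  expect_equal(out$bursts$first, c(1L, 4L))
  expect_equal(out$bursts$last, c(3L, 6L))
  expect_equal(out$bursts$begin, c(0, 1.0))
  expect_equal(out$bursts$end, c(0.10, 1.10))
  # regular 1-Hz train: every ISI exceeds the beginning threshold
  expect_equal(n_bursts(detect_max_interval(regular_train(60))), 0)
  # merge rule: two 3-spike groups 0.2 s apart with min_ibi 0.3 merge
  tr2 <- spike_train(c(0, 0.05, 0.1, 0.3, 0.35, 0.4), duration = 1)
  p2 <- detector_params("mi", max_begin_isi = 0.1, max_end_isi = 0.1,
                        min_ibi = 0.3)
  m <- detect_max_interval(tr2, p2)
  expect_equal(nrow(m$bursts), 1)
  expect_equal(m$bursts$n_spikes, 6L)
  # min_duration and min_spikes filters
  p3 <- detector_params("mi", min_duration = 0.5)
  expect_equal(n_bursts(detect_max_interval(tr2, p3)), 0)
  expect_equal(n_bursts(detect_max_interval(spike_train(c(0, 0.05),
                                                        duration = 1))), 0)
})

test_that("poisson_surprise equals the log-space tail sum", {
  expect_equal(poisson_surprise(0, 1, 1), 0)
  # derived closed-form example: N = 5, lambda*T = 1
  expect_equal(poisson_surprise(5, 1, 1),
               -log(1 - exp(-1) * sum(1 / factorial(0:4))))
  # independent log-sum-exp oracle across a grid, to 1e-10 relative
  # (absolute for surprise values below 1)
  for (lt in c(0.1, 1, 7.5, 40)) {
    for (n in c(1, 2, 5, 20, 80, 200)) {
      s_o <- max(0, -oracle_log_poisson_tail(n, lt))
      expect_lt(abs(poisson_surprise(n, 1, lt) - s_o),
                1e-10 * max(1, s_o))
    }
  }
  # no underflow deep in the tail
  expect_gt(poisson_surprise(500, 1, 1), 700)
  expect_true(is.finite(poisson_surprise(500, 1, 1)))
  # monotone in N at fixed lambda*T
  s <- poisson_surprise(1:30, 1, 2.5)
  expect_true(all(diff(s) >= 0))
  expect_error(poisson_surprise(3, 1, 0), "positive")
  expect_error(poisson_surprise(3, 0, 1), "positive")
  expect_error(poisson_surprise(-1, 1, 1), "non-negative")
})

test_that("Poisson surprise detector returns locally maximal bursts", {
  # exactly periodic train: no interval is surprising
  expect_equal(n_bursts(detect_poisson_surprise(regular_train(100))), 0)
  # 10-spike 10-ms cluster in a sparse 0.1-Hz background
  bg <- seq(10, 290, by = 10)
  cl <- 150.005 + (0:9) * 0.01
  tr <- spike_train(sort(c(bg, cl)), duration = 300)
  out <- detect_poisson_surprise(tr)
  expect_equal(nrow(out$bursts), 1)
  idx <- which(tr$times %in% cl)
  expect_true(all(idx >= out$bursts$first & idx <= out$bursts$last))
  expect_gte(out$bursts$surprise, -log(0.01))
  # local maximality: no single-spike move improves S
  rate <- n_spikes(tr) / tr$duration
  f <- out$bursts$first; l <- out$bursts$last
  s_cur <- poisson_surprise(l - f + 1, tr$times[l] - tr$times[f], rate)
  moves <- list(c(f - 1, l), c(f + 1, l), c(f, l - 1), c(f, l + 1))
  for (mv in moves) {
    if (mv[1] >= 1 && mv[2] <= n_spikes(tr) && mv[2] - mv[1] + 1 >= 3) {
      s_mv <- poisson_surprise(mv[2] - mv[1] + 1,
                               tr$times[mv[2]] - tr$times[mv[1]], rate)
      expect_lte(s_mv, s_cur)
    }
  }
  # every returned surprise respects the threshold on simulated data
  lab <- sim_poisson_bursting(0.2, 5, 0.3, duration = 300, seed = 12)
  d <- detect_poisson_surprise(lab$train)
  expect_true(all(d$bursts$surprise >= -log(0.01)))
  expect_true(all(d$bursts$n_spikes >= 3))
})

test_that("rank_surprise_pvalue matches exhaustive enumeration", {
  expect_equal(rank_surprise_pvalue(1, 1, 10), 0.1)
  expect_equal(rank_surprise_pvalue(3, 2, 10), 0.03)
  # exhaustive enumeration for q <= 3, N <= 12
  for (N in c(4, 7, 12)) {
    for (q in 1:3) {
      grid <- do.call(expand.grid, rep(list(seq_len(N)), q))
      sums <- rowSums(grid)
      for (rs in unique(c(q, floor(quantile(sums, c(0.1, 0.5, 0.9)))))) {
        expect_equal(rank_surprise_pvalue(rs, q, N),
                     mean(sums <= rs), tolerance = 1e-12)
      }
    }
  }
  # Gaussian approximation agrees with the exact convolution for large q
  for (rs in c(1300, 1515, 1700)) {
    expect_equal(rank_surprise_pvalue(rs, 30, 100, exact_max_q = 40),
                 rank_surprise_pvalue(rs, 30, 100, exact_max_q = 10),
                 tolerance = 0.005)
  }
  expect_error(rank_surprise_pvalue(0, 1, 10), "out of range")
  expect_error(rank_surprise_pvalue(21, 2, 10), "out of range")
})

test_that("rank surprise detector honors the ISI limit and threshold", {
  # all ISIs equal: mid-ranks make every window unsurprising
  expect_equal(n_bursts(detect_rank_surprise(regular_train(50))), 0)
  # planted run of 8 fast spikes in a sparse train is found
  bg <- seq(5, 280, by = 5)
  run <- 100.01 + (0:7) * 0.01
  tr <- spike_train(sort(c(bg, run)), duration = 300)
  out <- detect_rank_surprise(tr)
  expect_gte(nrow(out$bursts), 1)
  idx <- which(tr$times %in% run)
  expect_true(any(out$bursts$first <= min(idx) & out$bursts$last >= max(idx)))
  expect_true(all(out$bursts$surprise >= -log(0.01)))
  # oracle check: recompute the reported RS of each burst from scratch
  iv <- isi(tr)
  rk <- rank(iv)
  for (k in seq_len(nrow(out$bursts))) {
    w <- out$bursts$first[k]:(out$bursts$last[k] - 1)
    p <- rank_surprise_pvalue(sum(rk[w]), length(w), length(iv))
    expect_equal(out$bursts$surprise[k], -log(p), tolerance = 1e-8)
  }
  # every burst ISI is below the percentile limit
  lim <- quantile(iv, 0.75, names = FALSE)
  for (k in seq_len(nrow(out$bursts))) {
    expect_true(all(iv[out$bursts$first[k]:(out$bursts$last[k] - 1)] <= lim))
  }
})

test_that("RGS central distribution is robust and pooling-invariant", {
  set.seed(8)
  x <- rnorm(5000, mean = -1.3, sd = 0.4)
  cd <- rgs_central_distribution(x)
  expect_equal(cd$center, -1.3, tolerance = 0.05)
  expect_equal(cd$spread, 0.4, tolerance = 0.05)
  expect_false(cd$degenerate)
  # constant input flagged degenerate
  expect_true(rgs_central_distribution(rep(2, 10))$degenerate)
  # 10% low contamination barely moves the center
  xc <- c(x, rnorm(500, mean = -5, sd = 0.1))
  expect_equal(rgs_central_distribution(xc)$center, median(x),
               tolerance = 0.05)
  # duplication invariance of the full detector
  lab <- sim_poisson_bursting(0.3, 8, 0.5, duration = 200, seed = 21)
  single <- detect_rgs(lab$train)
  dup <- detect_rgs(list(lab$train, lab$train))
  expect_equal(single$bursts, dup[[1]]$bursts)
  expect_equal(dup[[1]]$bursts, dup[[2]]$bursts)
})

test_that("RGS flags planted low-ISI outliers and honors the threshold", {
  # log-normal ISIs with a planted cluster far below the central body
  set.seed(14)
  iv <- exp(rnorm(300, mean = 0, sd = 0.3))
  iv[150:156] <- exp(-5 * mad(log(iv)) + log(median(iv)))
  tr <- spike_train(cumsum(c(0.5, iv)))
  out <- detect_rgs(tr)
  expect_gte(nrow(out$bursts), 1)
  hit <- any(out$bursts$first <= 150 & out$bursts$last >= 155)
  expect_true(hit)
  expect_true(all(out$bursts$surprise >= -log(0.01)))
  # a pure Gaussian log-ISI train yields few or no bursts
  set.seed(15)
  pure <- spike_train(cumsum(exp(rnorm(400, 0, 0.3))))
  few <- detect_rgs(pure)
  expect_lte(nrow(few$bursts), 3)
  # sub-2-spike trains give empty results, not errors
  expect_equal(n_bursts(detect_rgs(spike_train(1, duration = 2))), 0)
})

test_that("IRT applies the count and rank thresholds", {
  # constant-rate train: every 1-s window holds the same count, the
  # empirical tail cutoff exceeds it, so nothing is detected
  expect_equal(n_bursts(detect_irt(regular_train(120, period = 0.5))), 0)
  # dense 2-s burst in a sparse background
  bg <- seq(2, 118, by = 2)
  dense <- 60.05 + (0:19) * 0.1
  tr <- spike_train(sort(c(bg, dense)), duration = 120)
  out <- detect_irt(tr)
  expect_equal(nrow(out$bursts), 1)
  idx <- which(tr$times %in% dense)
  expect_true(out$bursts$first[1] >= min(idx) - 1)
  # sliding-window oracle for onset and offset
  theta_c <- burstlab:::irt_count_cutoff(tr, 0.05)
  fwd <- vapply(seq_along(tr$times), function(i) {
    sum(tr$times > tr$times[i] & tr$times <= tr$times[i] + 1)
  }, numeric(1))
  rk <- rank(isi(tr)) / length(isi(tr))
  onset_oracle <- which(fwd > theta_c &
                          c(rk, Inf) < 0.5)[1]
  expect_equal(out$bursts$first[1], onset_oracle)
  off <- which(seq_along(tr$times) > onset_oracle & fwd < theta_c / 2)[1]
  expect_equal(out$bursts$last[1], off)
})

test_that("CMA maps skewness to coefficients exactly", {
  expect_equal(cma_alpha_from_skew(0.5), c(alpha1 = 1.0, alpha2 = 0.5))
  expect_equal(cma_alpha_from_skew(1), c(alpha1 = 0.7, alpha2 = 0.5))
  expect_equal(cma_alpha_from_skew(5), c(alpha1 = 0.5, alpha2 = 0.9))
  expect_equal(cma_alpha_from_skew(9), c(alpha1 = 0.3, alpha2 = 0.1))
  expect_equal(cma_alpha_from_skew(10), c(alpha1 = 0.3, alpha2 = 0.1))
  expect_error(cma_alpha_from_skew(NaN), "finite")
})

test_that("CMA cutoff matches a brute-force scan from the curve peak", {
  tr <- bimodal_train(n_bursts = 30, size = 6, intra = 0.01, gap = 4)
  out <- detect_cma(tr)
  # recovers every dense run
  expect_equal(nrow(out$bursts), 30)
  expect_true(all(out$bursts$n_spikes == 6))
  # oracle: recompute maxISI by scanning all bins from the peak on
  iv <- isi(tr)
  cv <- burstlab:::cma_curve(iv, 0.1)
  a <- cma_alpha_from_skew(cv$skewness)[["alpha1"]]
  peak <- which.max(cv$cma)
  errs <- abs(cv$cma - a * cv$cma_max)
  errs[seq_len(peak - 1)] <- Inf
  max_isi <- cv$centers[which.min(errs)]
  ok <- iv < max_isi
  r <- rle(ok)
  expect_equal(nrow(out$bursts), sum(r$values & r$lengths >= 2))
  # tiny trains are empty, not errors
  expect_equal(n_bursts(detect_cma(spike_train(c(0, 1), duration = 2))), 0)
})

test_that("void parameter matches its closed form", {
  expect_equal(void_parameter(100, 50, 0), 1)
  expect_equal(void_parameter(30, 30, 30), 0)
  expect_equal(void_parameter(100, 25, 25), 0.5)
  expect_error(void_parameter(0, 10, 1), ">")
})

test_that("logISI finds bimodal cutoffs and falls back with extension", {
  # unimodal slow train: no intraburst peak at or below 100 ms
  slow <- spike_train(cumsum(runif(80, 0.8, 1.2)))
  expect_equal(n_bursts(detect_logisi(slow)), 0)
  # clean bimodal train: all planted burst spikes recovered
  tr <- bimodal_train(n_bursts = 25, size = 6, intra = 0.01, gap = 5)
  out <- detect_logisi(tr)
  expect_equal(nrow(out$bursts), 25)
  expect_true(all(out$bursts$n_spikes == 6))
  # fallback branch: intra spacings straddle 100 ms, so cores detected
  # at 100 ms must be extended by the (larger) void cutoff
  set.seed(33)
  onsets <- seq(1, by = 8, length.out = 30)
  times <- sort(unlist(lapply(onsets, function(o) {
    iv <- c(runif(5, 0.02, 0.08), runif(2, 0.12, 0.18))
    o + cumsum(c(0, sample(iv)))
  })))
  tr2 <- spike_train(times)
  out2 <- detect_logisi(tr2)
  expect_equal(nrow(out2$bursts), 30)
  # extension must capture nearly all burst spikes despite >100 ms gaps
  expect_gt(spikes_in_bursts_fraction(tr2, out2), 0.9)
  core_only <- burstlab:::.runs_below(tr2, isi(tr2), 0.1, 3, TRUE,
                                      "logisi", list())
  expect_gt(spikes_in_bursts_fraction(tr2, out2),
            spikes_in_bursts_fraction(tr2, core_only))
})

test_that("all detectors are deterministic with >= 3-spike bursts", {
  lab <- sim_noisy_bursting(duration = 200, seed = 17)
  for (m in all_methods) {
    a <- detect_bursts(lab$train, m)
    b <- detect_bursts(lab$train, m)
    expect_identical(a$bursts, b$bursts)
    if (nrow(a$bursts)) {
      expect_true(all(a$bursts$n_spikes >= 3))
      expect_true(all(diff(a$bursts$begin) > 0) || nrow(a$bursts) == 1)
      # non-overlapping index ranges
      if (nrow(a$bursts) > 1) {
        expect_true(all(a$bursts$first[-1] >
                          a$bursts$last[-nrow(a$bursts)]))
      }
    }
    # sub-3-spike input: empty result, never an error
    expect_equal(n_bursts(detect_bursts(spike_train(c(0.2, 0.4),
                                                    duration = 1), m)), 0)
  }
})

test_that("detector plugin registry accepts externally defined methods", {
  fake <- function(train, params = NULL, ...) {
    burst_set(method = "fake")
  }
  register_detector("fake", fake)
  out <- detect_bursts(regular_train(10), "fake")
  expect_s3_class(out, "burst_set")
  expect_equal(out$method, "fake")
  expect_error(register_detector("mi", fake), "built-in")
  expect_error(detect_bursts(regular_train(10), "nope"), "unknown detector")
})
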