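test_that("cumulative profiles count responders over all trials", {
  p <- profile_from_latencies(rep(NA_real_, 10))
  expect_equal(p$curve, rep(0, length(p$times)))

  p <- profile_from_latencies(c(1, 1, 3, NA))
  expect_equal(p$n_total, 4)
  at <- function(t) p$curve[which.min(abs(p$times - t))]
  expect_equal(at(0.9), 0)
  expect_equal(at(1), 0.5)
  expect_equal(at(2.9), 0.5)
  expect_equal(at(3), 0.75)
  expect_equal(at(10), 0.75)
  expect_true(all(diff(p$curve) >= 0))
  expect_error(cumulative_profile(list()), "no analyzable")
})

test_that("KS comparison is symmetric, null on identical input, monotone in D", {
  a <- profile_from_latencies(c(0.5, 1.2, 3, NA, NA))
  b <- profile_from_latencies(c(0.7, 2.2, NA, NA, NA))
  expect_equal(ks_compare(a, a)$D, 0)
  expect_equal(ks_compare(a, a)$p, 1)
  expect_equal(ks_compare(a, b)$D, ks_compare(b, a)$D)
  expect_equal(ks_compare(a, b)$p, ks_compare(b, a)$p)
  # p decreases as D grows at fixed n (vary separation)
  ps <- sapply(c(1, 2, 4, 6), function(shift) {
    g1 <- profile_from_latencies(rep(1, 10))
    g2 <- profile_from_latencies(c(rep(1, 10 - shift), rep(8, shift)))
    ks_compare(g1, g2)$p
  })
  expect_true(all(diff(ps) < 0))
  bad <- profile_from_latencies(c(1, 2), duration_s = 5)
  expect_error(ks_compare(a, bad), "mismatched")
})

test_that("fully separated two-point latency groups give D = 1 with an extreme p", {
  g1 <- profile_from_latencies(rep(c(1, 2), each = 4))
  g2 <- profile_from_latencies(rep(c(5, 6), each = 4))
  ks <- ks_compare(g1, g2)
  expect_equal(ks$D, 1)
  expect_lt(ks$p, 0.01)
  # exact enumeration oracle: how many of the C(16,8) equally likely group
  # assignments of the pooled latencies reach D = 1 (complete separation)
  pooled <- c(rep(c(1, 2), each = 4), rep(c(5, 6), each = 4))
  combos <- utils::combn(16, 8)
  d_of <- function(ix) {
    la <- pooled[ix]; lb <- pooled[-ix]
    grid <- seq(0, 10, by = 0.1)
    max(abs(sapply(grid, function(t) mean(la <= t) - mean(lb <= t))))
  }
  n_extreme <- sum(apply(combos, 2, function(ix) d_of(ix) >= 1 - 1e-9))
  p_exact <- n_extreme / ncol(combos)
  expect_equal(p_exact, 2 / choose(16, 8))
  # the asymptotic p is the same order of magnitude as the exact tail
  expect_lt(ks$p, 20 * p_exact)
  expect_gt(ks$p, p_exact / 20)
})

test_that("bootstrap lag of degenerate latency distributions is exact", {
  up <- profile_from_latencies(rep(1, 6))  # reuse builder for call lists
  both_at_1 <- rep(1, 6)
  lag0 <- bootstrap_lag(
    lapply(both_at_1, function(l) structure(list(responded = TRUE,
      latency_s = l, magnitude = NA), class = "response_call")),
    lapply(both_at_1, function(l) structure(list(responded = TRUE,
      latency_s = l, magnitude = NA), class = "response_call")),
    n_resamples = 200, seed = 4)
  expect_equal(lag0$lag_s, 0)
  expect_equal(lag0$sem_s, 0)
  mk <- function(lat) lapply(lat, function(l)
    structure(list(responded = !is.na(l), latency_s = l, magnitude = NA),
              class = "response_call"))
  lag2 <- bootstrap_lag(mk(rep(1, 5)), mk(rep(3, 5)),
                        n_resamples = 200, seed = 4)
  expect_equal(lag2$lag_s, 2)
  expect_equal(lag2$sem_s, 0)
  # a group that never reaches 50% response leaves the lag undefined
  und <- bootstrap_lag(mk(c(1, NA, NA, NA)), mk(rep(1, 4)),
                       n_resamples = 50, seed = 1)
  expect_true(und$undefined)
  expect_true(is.na(und$lag_s))
})

test_that("bootstrap lag SEM converges to the exhaustive resampling SD", {
  lat_u <- c(1.0, 2.0, 3.0)
  lat_d <- c(2.0, 3.0, 4.0, 5.0)
  mk <- function(lat) lapply(lat, function(l)
    structure(list(responded = TRUE, latency_s = l, magnitude = NA),
              class = "response_call"))
  t50_naive <- function(lat) {
    n <- length(lat); k <- ceiling(n / 2)
    sort(lat)[k]
  }
  enum_t50 <- function(lat) {
    n <- length(lat)
    grids <- expand.grid(rep(list(seq_len(n)), n))
    apply(grids, 1, function(ix) t50_naive(lat[ix]))
  }
  tu <- enum_t50(lat_u)          # 27 equally likely resamples
  td <- enum_t50(lat_d)          # 256 equally likely resamples
  lags <- as.vector(outer(td, tu, "-"))
  sd_pop <- sqrt(mean((lags - mean(lags))^2))
  bl <- bootstrap_lag(mk(lat_u), mk(lat_d), n_resamples = 50000, seed = 12)
  expect_equal(bl$lag_s, t50_naive(lat_d) - t50_naive(lat_u))
  expect_lt(abs(bl$sem_s - sd_pop) / sd_pop, 0.01)
})

test_that("response magnitudes follow the published window definitions", {
  expect_equal(magnitude_sensory(rep(0.3, 300), 100, 200), 0)
  x <- c(rep(0, 100), rep(0.8, 200))
  expect_equal(magnitude_sensory(x, 100, 200), 0.8)
  inh <- c(rep(0.5, 100), rep(-0.2, 200))
  expect_equal(magnitude_sensory(inh, 100, 200), -0.7)
  expect_error(magnitude_sensory(rep(0, 300), 5, 200), "unavailable")

  expect_equal(magnitude_peak(rep(0, 300), 100, 200), 0)
  tri <- numeric(300)
  tri[101:200] <- 1.4 * (1 - abs(seq(-1, 1, length.out = 100)))
  expect_equal(magnitude_peak(tri, 100, 200), 1.4, tolerance = 0.03)
})

test_that("rise time is the 33%-to-66% first-crossing interval", {
  ramp <- c(rep(0, 100), (0:99) / 100, rep(0.99, 100))
  call <- structure(list(responded = TRUE, onset_frame = 100L),
                    class = "response_call")
  expect_equal(rise_time(ramp, call, 100, 200), 3.3, tolerance = 0.10001)
  step <- c(rep(0, 100), rep(1, 200))
  expect_equal(rise_time(step, call, 100, 200), 0)
  # exponential rise, tau = 2 s, against a per-frame scan oracle
  t <- (0:299) / 10
  expo <- ifelse(t >= 10, 1 - exp(-(t - 10) / 2), 0)
  peak <- max(expo[101:200])
  scan <- function(q) (which(expo[101:200] >= q * peak)[1] - 1) / 10
  expect_equal(rise_time(expo, call, 100, 200), scan(0.66) - scan(0.33))
  noresp <- structure(list(responded = FALSE), class = "response_call")
  expect_error(rise_time(ramp, noresp, 100, 200), "non-responders")
})

test_that("pulse-pair statistics tabulate reliability and correlations", {
  mkdf <- function(n, r1, r2, m1, m2, l1, l2)
    data.frame(animal = rep(seq_len(n), each = 2),
               pulse = rep(c(1L, 2L), n),
               responded = as.vector(rbind(r1, r2)),
               magnitude = as.vector(rbind(m1, m2)),
               latency_s = as.vector(rbind(l1, l2)))
  # all double responders with identical magnitudes across pulses
  m <- seq(0.5, 1.4, length.out = 10)
  df <- mkdf(10, rep(TRUE, 10), rep(TRUE, 10), m, m,
             rep(1, 10), rep(1, 10))
  pp <- pulse_pair_stats(df)
  expect_equal(unname(pp$contingency["responded", "responded"]), 10)
  expect_equal(sum(pp$contingency), 10)
  expect_equal(pp$cor_magnitude, 1)
  # independent coin-flip responses land inside binomial 99% bounds
  set.seed(31)
  n <- 200
  r1 <- runif(n) < 0.5; r2 <- runif(n) < 0.5
  df <- mkdf(n, r1, r2, runif(n), runif(n), runif(n, 1, 3), runif(n, 1, 3))
  pp <- pulse_pair_stats(df)
  bounds <- qbinom(c(0.005, 0.995), n, 0.25)
  expect_true(all(pp$contingency >= bounds[1] & pp$contingency <= bounds[2]))
  expect_error(pulse_pair_stats(df[df$pulse == 1, ]), "no animals")
})

test_that("the profile comparison is never anti-conservative under the null", {
  # same latency law in both groups: the rejection rate at p < 0.05 must
  # not exceed the nominal level (the discrete frame grid and the modest
  # per-group n make the test conservative, not liberal)
  set.seed(808)
  n <- 40
  rej <- 0
  for (r in 1:400) {
    l1 <- ceiling((0.2 + rlnorm(n, 0, 0.5)) * 10) / 10
    l2 <- ceiling((0.2 + rlnorm(n, 0, 0.5)) * 10) / 10
    p1 <- profile_from_latencies(ifelse(l1 <= 10, l1, NA))
    p2 <- profile_from_latencies(ifelse(l2 <= 10, l2, NA))
    if (ks_compare(p1, p2)$p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / 400, 0.06)
})
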