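# PETHs, firing-rate gains, sleep trends, shock responses, censoring.

test_that("PETH peaks at zero lag for peak-locked spikes and stays flat for
           homogeneous firing", {
  peaks <- seq(10, 500, by = 10)
  peth <- peri_event_rate(peaks, peaks, kind = "SWR")
  expect_lt(abs(peth$lag_s[which.max(peth$mean_rate_hz)]), 0.03)
  set.seed(71)
  spk <- gen_poisson_train(4, 600)
  peth2 <- peri_event_rate(spk, peaks, kind = "SWR")
  expect_true(all(abs(peth2$mean_rate_hz - 4) < 1.5))
  expect_error(peri_event_rate(spk, numeric(0)), "at least one event")
})

test_that("per-event PETH bins equal brute-force counting", {
  set.seed(72)
  spk <- gen_poisson_train(5, 200)
  peaks <- c(50, 100, 150)
  peth <- peri_event_rate(spk, peaks, kind = "SWR")
  for (e in seq_along(peaks)) {
    for (b in c(1, 25, 50, 100)) {
      lo <- peaks[e] + peth$lag_s[b] - 0.005
      hi <- peaks[e] + peth$lag_s[b] + 0.005
      expect_equal(peth$rate_matrix[e, b], sum(spk >= lo & spk < hi) / 0.01)
    }
  }
})

test_that("fr_gain matches its definition and ground-truth injected gains", {
  set.seed(73)
  ev <- data.frame(start = seq(5, 995, 10), end = seq(5, 995, 10) + 0.2)
  ref <- intervals(0, 1000)
  spk <- gen_poisson_train(4, 1000)
  g <- fr_gain(spk, ev, ref)
  expect_equal(g$gain, 1, tolerance = 0.25)
  # no spikes inside events -> gain 0
  spk_out <- spk[!iv_contains(spk, ev)]
  expect_equal(fr_gain(spk_out, ev, ref)$gain, 0)
  # invariance to appending spike-free time outside the reference
  g2 <- fr_gain(spk, ev, ref)
  expect_equal(fr_gain(c(spk, 5000, 6000), ev, ref)$gain, g2$gain)
  # zero outside rate flagged
  spk_in <- spk[iv_contains(spk, ev)]
  gz <- fr_gain(spk_in, ev, ref)
  expect_true(is.na(gz$gain))
  expect_equal(gz$flag, "zero outside rate")
  # ground-truth recovery on a synthetic gain-5 unit
  base <- gen_poisson_train(3, 1000)
  spk5 <- sleeposc:::apply_event_gain(base, cbind(ev, center = NA), 5,
                                      function(t) 3)
  expect_equal(fr_gain(spk5, ev, ref)$gain, 5, tolerance = 0.15)
})

test_that("fixture-session event gains are recovered for high-gain units", {
  s <- fixture_session()
  hyp <- fixture_hypnogram()
  nrem <- select_state_time(hyp[hyp$usable, ], "NREM")
  tg <- s$truth_gains
  tg <- tg[tg$kind != "shock" & (tg$gain > 2 | tg$gain < 0.6), ]
  spl <- split(s$spikes$t, s$spikes$unit_id)
  err <- vapply(seq_len(nrow(tg)), function(i) {
    ev <- s$truth_events[s$truth_events$kind == tg$kind[i], ]
    g <- fr_gain(spl[[tg$unit_id[i]]], ev, nrem)
    if (is.na(g$gain)) return(NA_real_)
    (g$gain - tg$gain[i]) / tg$gain[i]
  }, numeric(1))
  expect_gt(sum(!is.na(err)), 2)
  expect_lt(median(abs(err), na.rm = TRUE), 0.35)
})

test_that("sleep firing trends recover injected decay and z-score correctly", {
  hyp <- normalize_hypnogram(hyp_from_runs(
    rep(c("NREM", "REM"), 6), rep(c(500, 100), 6)))
  ext <- find_extended_sleep(hyp)
  expect_equal(nrow(ext), 1)
  set.seed(74)
  # constant-rate units: rho near 0, delta near 0
  const <- list(u1 = gen_poisson_train(3, 3600), u2 = gen_poisson_train(1, 3600))
  tr <- sleep_fr_trend(const, ext, hyp)
  expect_true(all(abs(tr$delta$delta_z) < 3))
  expect_true(all(abs(tapply(tr$epochs$fr_z, tr$epochs$unit_id, mean)) < 1e-10))
  expect_true(all(abs(tapply(tr$epochs$fr_z, tr$epochs$unit_id, sd) - 1) < 1e-10))
  # linearly decaying unit: negative rho and negative delta
  rates <- seq(4, 1, length.out = nrow(hyp))
  dec <- list(d1 = sleeposc:::gen_poisson_piecewise(hyp, rates))
  tr2 <- sleep_fr_trend(dec, ext, hyp)
  expect_lt(tr2$trend$rho, 0)
  expect_lt(tr2$delta$delta_z, 0)
})

test_that("within-event firing change tracks first-to-last epoch differences", {
  ep <- data.frame(start = c(0, 100), end = c(50, 150))
  ev <- data.frame(start = c(10, 20, 110, 120), end = c(11, 21, 111, 121))
  # identical within-event rates -> 0
  spk <- c(10.1, 10.5, 20.1, 20.5, 110.1, 110.5, 120.1, 120.5)
  expect_equal(within_event_fr_change(spk, ev, ep)$delta_z, 0)
  # doubled rate in last epoch -> positive delta
  spk2 <- c(10.1, 10.5, 110.1, 110.2, 110.5, 120.3, 120.6, 120.9)
  expect_gt(within_event_fr_change(spk2, ev, ep)$delta_z, 0)
  # epoch without events -> flagged
  ev2 <- ev[ev$start < 100, ]
  out <- within_event_fr_change(spk, ev2, ep)
  expect_true(is.na(out$delta_z))
  # hand-computed two-step oracle on a random fixture
  set.seed(75)
  ep3 <- data.frame(start = c(0, 60, 120), end = c(50, 110, 170))
  ev3 <- data.frame(start = c(5, 25, 65, 85, 125, 145),
                    end = c(7, 27, 67, 87, 127, 147))
  spk3 <- gen_poisson_train(3, 170)
  per <- vapply(1:3, function(i) {
    e <- ev3[ev3$start >= ep3$start[i] & ev3$end <= ep3$end[i], ]
    sum(iv_count(spk3, e)) / sum(e$end - e$start)
  }, numeric(1))
  zz <- (per - mean(per)) / sd(per)
  expect_equal(within_event_fr_change(spk3, ev3, ep3)$delta_z, zz[3] - zz[1])
})

test_that("shock gain recovers transients and handles degenerate baselines", {
  set.seed(76)
  shocks <- data.frame(start = c(100, 200, 300), end = c(102, 202, 302))
  first_cs <- 69
  # regular 10 Hz firing: every 0.1-s bin holds one spike, so the PSTH peak
  # equals the baseline exactly and the gain is 1
  reg <- seq(0.05, 399.95, by = 0.1)
  expect_equal(shock_gain(reg, shocks, first_cs)$gain, 1)
  spk <- gen_poisson_train(5, 400)
  # known transient: rate x4 inside shocks
  spk2 <- sort(c(spk, unlist(lapply(shocks$start, function(s0)
    s0 + sort(runif(rpois(1, 2 * 15), 0, 2))))))
  g2 <- shock_gain(spk2, shocks, first_cs)
  expect_gt(g2$gain, 2)
  # silent baseline flagged without crashing
  spk3 <- spk[spk >= 90]
  g3 <- shock_gain(spk3, shocks, first_cs)
  expect_true(is.na(g3$gain))
  expect_equal(g3$flag, "zero baseline rate")
  expect_error(shock_gain(spk, shocks[0, ], first_cs), "at least one shock")
})

test_that("shock-pulse censoring removes exactly the artifact windows", {
  pulses <- data.frame(start = c(1.000, 2.000), end = c(1.002, 2.002))
  spk <- c(0.9999, 1.000, 1.0015, 1.0069, 1.0071, 2.0005, 2.0075)
  out <- censor_shock_artifacts(spk, pulses)
  # removed: [start - 0.1 ms, end + 5 ms) = [0.9999, 1.007) and [1.9999, 2.007)
  expect_equal(out, c(1.0071, 2.0075))
  # membership oracle on a random fixture
  set.seed(77)
  spk2 <- runif(2000, 0, 10)
  pulses2 <- data.frame(start = seq(0.5, 9.5, 0.5), end = seq(0.5, 9.5, 0.5) + 0.002)
  keep <- !vapply(spk2, function(s)
    any(s >= pulses2$start - 1e-4 & s < pulses2$end + 5e-3), logical(1))
  expect_equal(censor_shock_artifacts(spk2, pulses2), spk2[keep])
})
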