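# Band-power z traces, the threshold engine, the four detectors, summaries.

test_that("z trace has mean 0 and SD 1 over baseline by construction", {
  set.seed(51)
  fs <- 1250
  x <- rnorm(60 * fs)
  base <- intervals(c(0, 30), c(20, 50))
  pw <- band_rms_z(x, fs, c(100, 250), 13.3, base)
  mask <- iv_contains((seq_along(pw$z) - 1) / fs, base)
  expect_equal(mean(pw$z[mask]), 0, tolerance = 1e-10)
  expect_equal(sd(pw$z[mask]), 1, tolerance = 1e-10)
  # amplitude scale invariance
  pw2 <- band_rms_z(1000 * x, fs, c(100, 250), 13.3, base)
  expect_equal(pw$z, pw2$z, tolerance = 1e-8)
  expect_error(band_rms_z(x, fs, c(100, 250), 13.3, intervals(100, 110)),
               "empty baseline")
})

test_that("a pure in-band sinusoid yields the analytic RMS plateau", {
  fs <- 1250
  t <- (0:(40 * fs - 1)) / fs
  x <- rnorm(length(t), sd = 0.05)
  seg <- t >= 20 & t < 25
  A <- 4
  x[seg] <- x[seg] + A * sin(2 * pi * 150 * t[seg])
  bp <- sleeposc:::bandpass(x, fs, c(100, 250))
  rms <- sleeposc:::moving_rms(bp, round(0.0133 * fs))
  plateau <- median(rms[t > 21 & t < 24])
  expect_equal(plateau, A / sqrt(2), tolerance = 0.02)
})

test_that("threshold engine matches a brute-force run-length oracle", {
  oracle <- function(z, fs, pp) {
    # candidates: maximal runs strictly above enter_z
    ev <- list(); i <- 1; n <- length(z)
    while (i <= n) {
      if (z[i] > pp$enter_z) {
        j <- i
        while (j < n && z[j + 1] > pp$enter_z) j <- j + 1
        ev[[length(ev) + 1]] <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    if (length(ev) == 0) return(NULL)
    m <- do.call(rbind, ev)
    keep <- vapply(seq_len(nrow(m)), function(k) {
      seg <- z[m[k, 1]:m[k, 2]]
      dur <- (m[k, 2] - m[k, 1] + 1) / fs * 1000
      max(seg) >= pp$peak_z &
        (if (pp$min_dur_strict) dur > pp$min_dur_ms else dur >= pp$min_dur_ms)
    }, logical(1))
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    # merge gaps < merge_gap, then drop dur >= max_dur
    out <- list(m[1, ])
    for (k in seq_len(nrow(m))[-1]) {
      last <- out[[length(out)]]
      if ((m[k, 1] - 1 - last[2]) / fs * 1000 < pp$merge_gap_ms)
        out[[length(out)]][2] <- m[k, 2]
      else out[[length(out) + 1]] <- m[k, ]
    }
    m <- do.call(rbind, out)
    m <- m[(m[, 2] - m[, 1] + 1) / fs * 1000 < pp$max_dur_ms, , drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    data.frame(start = (m[, 1] - 1) / fs, end = m[, 2] / fs)
  }
  set.seed(52)
  fs <- 100
  pp <- detector_params(c(1, 2), 10, enter_z = 2, peak_z = 4, min_dur_ms = 30,
                        merge_gap_ms = 25, max_dur_ms = 400)
  for (r in 1:20) {
    z <- rep(rnorm(150, 1, 2), times = sample(2:6, 150, replace = TRUE))[1:300]
    got <- detect_threshold_events(list(z = z, fs = fs), pp)
    want <- oracle(z, fs, pp)
    if (is.null(want)) expect_equal(nrow(got), 0)
    else expect_equal(got[, c("start", "end")], want, ignore_attr = TRUE)
  }
})

test_that("threshold engine applies the confirmation, merge and duration rules", {
  fs <- 1000
  z <- rep(0, 1000)
  pp <- detector_params(c(1, 2), 10, 2, 4, 30, 20)
  # rectangular pulse z = 6, 100 ms -> one event spanning the pulse
  z1 <- z; z1[101:200] <- 6
  ev <- detect_threshold_events(list(z = z1, fs = fs), pp)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 0.1); expect_equal(ev$end, 0.2)
  expect_equal(ev$peak_z, 6)
  # two pulses 15 ms apart with merge gap 20 -> one merged event
  z2 <- z; z2[101:150] <- 6; z2[166:215] <- 6
  ev2 <- detect_threshold_events(list(z = z2, fs = fs), pp)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$end - ev2$start, 0.115)
  # same two pulses 25 ms apart -> two events
  z3 <- z; z3[101:150] <- 6; z3[176:225] <- 6
  expect_equal(nrow(detect_threshold_events(list(z = z3, fs = fs), pp)), 2)
  # peak below threshold dropped
  z4 <- z; z4[101:200] <- 3
  expect_equal(nrow(detect_threshold_events(list(z = z4, fs = fs), pp)), 0)
})

test_that("detectors recover injected events with state gating and SW conjunction", {
  s <- fixture_session()
  ev <- fixture_events()
  tr <- s$truth_events
  for (k in c("SWR", "HFO", "cRipple", "spindle")) {
    e_t <- tr[tr$kind == k, ]
    e_d <- ev[ev$kind == k, ]
    recall <- mean(vapply(seq_len(nrow(e_t)), function(i)
      any(e_d$start < e_t$end[i] & e_d$end > e_t$start[i]), logical(1)))
    precision <- mean(vapply(seq_len(nrow(e_d)), function(i)
      any(e_t$start < e_d$end[i] & e_t$end > e_d$start[i]), logical(1)))
    expect_gt(recall, 0.9)
    expect_gt(precision, 0.9)
    # peak times near injected centers
    derr <- vapply(seq_len(nrow(e_d)), function(i) {
      j <- which(e_t$start < e_d$end[i] & e_t$end > e_d$start[i])
      if (length(j) == 0) return(NA_real_)
      min(abs(e_d$peak_time[i] - e_t$center[j]))
    }, numeric(1))
    expect_lt(median(derr, na.rm = TRUE), 0.020)
  }
})

test_that("no SWR is reported during REM even with an injected ripple", {
  set.seed(53)
  fs <- 1250
  n <- 120 * fs
  hyp <- hyp_from_runs(c("NREM", "REM"), c(60, 60))
  hyp$usable <- TRUE
  data <- cbind(sleeposc:::one_over_f_noise(n), sleeposc:::one_over_f_noise(n))
  inject <- function(data, center) {
    seg <- sleeposc:::burst_segment(n, fs, center, 0.08, 150, 8)
    data[seg$idx, 1] <- data[seg$idx, 1] + seg$y
    data[seg$idx, 2] <- data[seg$idx, 2] + seg$y
    sw <- sleeposc:::deflection_segment(n, fs, center, 0.03, -8)
    data[sw$idx, 2] <- data[sw$idx, 2] + sw$y
    data
  }
  data <- inject(inject(data, 30), 90) # one in NREM, one in REM
  lfp <- make_lfp(data, fs, c("vCA1", "vCA1"), c("vCA1_s1", "vCA1_s1"), c(1, 2))
  swr <- detect_swr(lfp, hyp)
  expect_true(all(swr$peak_time < 60))
  expect_gt(nrow(swr), 0)
})

test_that("ripples without sharp-waves are not SWRs; shank without pair errors", {
  set.seed(54)
  fs <- 1250
  n <- 90 * fs
  hyp <- hyp_from_runs("NREM", 90); hyp$usable <- TRUE
  data <- cbind(sleeposc:::one_over_f_noise(n), sleeposc:::one_over_f_noise(n))
  for (cc in c(20, 45, 70)) {
    seg <- sleeposc:::burst_segment(n, fs, cc, 0.08, 150, 8)
    data[seg$idx, 1] <- data[seg$idx, 1] + seg$y
    data[seg$idx, 2] <- data[seg$idx, 2] + seg$y
  }
  lfp <- make_lfp(data, fs, c("vCA1", "vCA1"), c("vCA1_s1", "vCA1_s1"), c(1, 2))
  expect_equal(nrow(detect_swr(lfp, hyp)), 0)
  lfp1 <- make_lfp(data[, 1, drop = FALSE], fs, "vCA1", "vCA1_s1", 1)
  expect_error(detect_swr(lfp1, hyp), "lacks a superficial/deep")
})

test_that("spindle candidates respect the sustained-duration and state rules", {
  set.seed(55)
  fs <- 1250
  n <- 180 * fs
  hyp <- hyp_from_runs(c("NREM", "WAKE", "NREM"), c(60, 60, 60))
  hyp$usable <- TRUE
  x <- sleeposc:::one_over_f_noise(n)
  add <- function(x, center, dur) {
    seg <- sleeposc:::burst_segment(n, fs, center, dur, 12, 6)
    x[seg$idx] <- x[seg$idx] + seg$y
    x
  }
  x <- add(x, 30, 0.8)   # NREM, long enough
  x <- add(x, 90, 0.8)   # WAKE -> must be rejected
  x <- add(x, 150, 0.20) # NREM but too short even after wavelet smearing
  lfp <- make_lfp(matrix(x, ncol = 1), fs, "PL5")
  sp <- detect_spindles(lfp, hyp)
  overlaps <- function(lo, hi) any(sp$start < hi & sp$end > lo)
  expect_true(overlaps(29.6, 30.4))
  expect_false(overlaps(89.6, 90.4))
  expect_false(overlaps(149.8, 150.2))
})

test_that("stringent thresholds yield a subset of default events", {
  s <- fixture_session()
  hyp <- fixture_hypnogram()
  ev <- fixture_events()
  evs <- sleeposc:::detect_all_oscillations(
    s$lfp, hyp, params = default_detector_params(stringent = TRUE))
  for (i in seq_len(nrow(evs))) {
    same <- ev[ev$kind == evs$kind[i], ]
    expect_true(any(same$start <= evs$start[i] + 1e-9 &
                      same$end >= evs$end[i] - 1e-9))
  }
})

test_that("event summaries report quartiles and rates per the definitions", {
  ev <- data.frame(start = seq(0, 90, 10), end = seq(0, 90, 10) + 0.05)
  ss <- event_summary(ev, intervals(0, 100))
  expect_equal(ss$rate_hz, 0.1)
  expect_equal(ss$dur_median_ms, 50)
  # random fixture: quartiles equal the sorted-array oracle
  set.seed(56)
  durs <- runif(37, 0.02, 0.4)
  ev2 <- data.frame(start = seq_along(durs) * 10, end = seq_along(durs) * 10 + durs)
  ss2 <- event_summary(ev2, intervals(0, 1000))
  expect_equal(c(ss2$dur_q1_ms, ss2$dur_median_ms, ss2$dur_q3_ms),
               unname(quantile(durs * 1000, c(0.25, 0.5, 0.75))))
  # empty event list and zero state time
  ss3 <- event_summary(ev[0, ], intervals(0, 100))
  expect_equal(ss3$rate_hz, 0)
  expect_true(is.na(ss3$dur_median_ms))
  expect_true(is.na(event_summary(ev, intervals(0, 1)[0, ])$rate_hz))
})
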