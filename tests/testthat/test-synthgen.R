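# Synthetic-session generator: conservation, rate calibration, ground-truth
# consistency and byte-level determinism.

test_that("hypnogram partitions the session exactly and respects config", {
  cfg <- synth_config(duration_s = 7200, seed = 3)
  hyp <- generate_hypnogram(cfg, seed = 3)
  expect_equal(hyp$start[1], 0)
  expect_equal(hyp$end[nrow(hyp)], 7200)
  expect_equal(sum(hyp$end - hyp$start), 7200)
  expect_true(all(head(hyp$end, -1) == tail(hyp$start, -1)))
  dur <- hyp$end - hyp$start
  expect_true(any(hyp$state == "NREM" & dur > 50))
  expect_true(any(hyp$state == "REM" & dur > 50))
})

test_that("a degenerate all-NREM architecture yields one NREM interval", {
  arch <- default_sleep_arch()
  arch$trans <- matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE,
                       dimnames = dimnames(arch$trans))
  arch$init <- c(meanlog = log(1e-3), sdlog = 1e-6) # vanishing initial wake
  arch$dwell$NREM <- c(meanlog = log(1e6), sdlog = 1e-6)
  cfg <- synth_config(duration_s = 3600, sleep_arch = arch, seed = 5)
  hyp <- generate_hypnogram(cfg, seed = 5)
  hyp <- hyp[hyp$state == "NREM", ]
  expect_equal(nrow(hyp), 1)
  expect_equal(hyp$end - hyp$start, 3600, tolerance = 1e-2)
})

test_that("sessions shorter than 10 min are rejected", {
  cfg <- synth_config(duration_s = 650, seed = 1)
  cfg$duration_s <- 599
  expect_error(generate_hypnogram(cfg), "too short")
})

test_that("unit spike counts follow the configured Poisson state rates", {
  set.seed(101)
  # pure NREM timeline, 2 Hz for 1000 s: count within 3 SD of 2000
  hyp <- hyp_from_runs("NREM", 1000)
  spk <- sleeposc:::gen_poisson_piecewise(hyp, 2)
  expect_true(abs(length(spk) - 2000) < 3 * sqrt(2000))
  expect_true(all(diff(spk) > 0))
  # zero rate in all states -> empty train
  expect_length(sleeposc:::gen_poisson_piecewise(hyp, 0), 0)
  expect_error(sleeposc:::gen_poisson_piecewise(hyp, -1), "negative")
})

test_that("REM/NREM rate ratio is recovered by an independent bin-count oracle", {
  set.seed(102)
  hyp <- hyp_from_runs(rep(c("NREM", "REM"), 10), rep(c(300, 100), 10))
  rates <- c(NREM = 1, REM = 3)[hyp$state]
  spk <- sleeposc:::gen_poisson_piecewise(hyp, rates)
  # oracle: direct counts over each state's total time
  cnt <- function(st) {
    iv <- hyp[hyp$state == st, ]
    sum(iv_count(spk, iv)) / sum(iv$end - iv$start)
  }
  expect_equal(cnt("REM") / cnt("NREM"), 3, tolerance = 0.15)
})

test_that("generated spike trains are sorted, in range, with true-rate ground truth", {
  s <- fixture_session()
  cfg <- fixture_config()
  expect_true(all(s$spikes$t >= 0 & s$spikes$t < cfg$duration_s))
  for (u in split(s$spikes$t, s$spikes$unit_id))
    expect_true(all(diff(u) > 0))
  expect_true(all(c("rate_nrem", "rate_rem", "rate_wake") %in% names(s$units)))
})

test_that("injected events lie in eligible states and never overlap within kind", {
  s <- fixture_session()
  tr <- s$truth_events
  hyp <- s$hypnogram
  state_at <- function(t) hyp$state[findInterval(t, hyp$start)]
  for (k in unique(tr$kind)) {
    e <- tr[tr$kind == k, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1) expect_true(all(tail(e$start, -1) >= head(e$end, -1)))
    st <- vapply(e$center, state_at, character(1))
    if (k == "SWR") expect_true(all(st %in% c("NREM", "WAKE")))
    else expect_true(all(st == "NREM"))
  }
})

test_that("an injected ripple's band-power peak sits at the injection center", {
  # oracle: direct band-pass + argmax of the analytic envelope proxy (RMS)
  set.seed(103)
  fs <- 1250
  x <- sleeposc:::one_over_f_noise(60 * fs)
  seg <- sleeposc:::burst_segment(length(x), fs, center = 10, dur = 0.08,
                                  freq = 150, amp = 10)
  x[seg$idx] <- x[seg$idx] + seg$y
  pw <- band_rms_z(x, fs, c(100, 250), 13.3, intervals(0, 60))
  t_peak <- (which.max(pw$z) - 0.5) / fs
  expect_lt(abs(t_peak - 10), 0.015)
})

test_that("within-event spike gain is recovered by a Poisson thinning oracle", {
  set.seed(104)
  T <- 4000
  ev <- data.frame(start = seq(5, T - 10, by = 10), end = seq(5, T - 10, by = 10) + 1)
  ev$center <- (ev$start + ev$end) / 2
  base <- gen_poisson_train(5, T)
  for (g in c(0.4, 5)) {
    spk <- sleeposc:::apply_event_gain(base, ev, g, function(t) 5)
    fin <- sum(iv_contains(spk, ev)) / iv_duration(ev)
    fout <- sum(!iv_contains(spk, ev)) / (T - iv_duration(ev))
    expect_equal(fin / fout, g, tolerance = 0.15)
  }
})

test_that("with gain 1 the within/outside rates are statistically indistinguishable", {
  set.seed(105)
  ev <- data.frame(start = seq(5, 995, by = 10), end = seq(5, 995, by = 10) + 0.5)
  p <- replicate(30, {
    spk <- gen_poisson_train(4, 1000)
    n_in <- sum(iv_contains(spk, ev))
    d_in <- iv_duration(ev)
    stats::poisson.test(c(n_in, length(spk) - n_in),
                        c(d_in, 1000 - d_in))$p.value
  })
  expect_lt(mean(p < 0.05), 0.25) # near-nominal two-sided false-positive rate
  expect_gt(min(p), 0)
})

test_that("generate_session is byte-identical under the same seed and round-trips", {
  cfg <- synth_config(duration_s = 900, n_units_per_region = 3, seed = 77)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  s1 <- generate_session(cfg, d1)
  s2 <- generate_session(cfg, d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
  # manifest bookkeeping: row counts and LFP sample counts correct
  man <- jsonlite::fromJSON(file.path(d1, "manifest.json"))
  expect_equal(man$row_counts$spikes, nrow(s1$spikes))
  expect_equal(man$n_lfp_samples_per_channel, round(900 * cfg$fs_lfp))
  expect_equal(nrow(s1$lfp$data), round(900 * cfg$fs_lfp))
  # reload reproduces float32-stored LFP exactly
  s1b <- load_session(file.path(d1, "manifest.json"))
  expect_identical(s1$lfp$data, s1b$lfp$data)
})

test_that("extended-sleep frequency matches a direct dwell-process simulation", {
  # oracle: an independent re-implementation of the semi-Markov dwell process
  cfg <- synth_config(duration_s = 7200, seed = 1)
  arch <- cfg$sleep_arch
  sim_direct <- function() {
    st <- "WAKE"; t <- 0; first <- TRUE
    ss <- character(0); dd <- numeric(0)
    while (t < cfg$duration_s) {
      p <- if (first) arch$init else arch$dwell[[st]]
      first <- FALSE
      d <- rlnorm(1, p[["meanlog"]], p[["sdlog"]])
      ss <- c(ss, st); dd <- c(dd, d); t <- t + d
      st <- sample(colnames(arch$trans), 1, prob = arch$trans[st, ])
    }
    ends <- pmin(cumsum(dd), cfg$duration_s)
    h <- data.frame(start = c(0, head(ends, -1)), end = ends, state = ss)
    h <- h[h$end > h$start, ]
    # longest sleep span allowing wake gaps <= 60 s
    best <- 0; cur_start <- NA
    i <- 1
    while (i <= nrow(h)) {
      if (h$state[i] %in% c("NREM", "REM")) {
        if (is.na(cur_start)) cur_start <- h$start[i]
        best <- max(best, h$end[i] - cur_start)
      } else if (!is.na(cur_start) && h$end[i] - h$start[i] > 60) {
        cur_start <- NA
      }
      i <- i + 1
    }
    best > 1800
  }
  set.seed(106); frac_direct <- mean(replicate(120, sim_direct()))
  set.seed(107)
  frac_gen <- mean(replicate(120, {
    hyp <- normalize_hypnogram(generate_hypnogram(cfg))
    nrow(find_extended_sleep(hyp)) > 0
  }))
  expect_lt(abs(frac_gen - frac_direct), 0.15)
  expect_gt(frac_gen, 0.5) # 2-h sessions usually contain extended sleep
})
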