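# State rates, REM-preference index, shuffle-null classification, triplet
# profiles, cross-session correlations and bootstraps.

test_that("REM-preference index follows its closed form", {
  expect_equal(rem_preference_index(2, 0), 1)
  expect_equal(rem_preference_index(0, 2), -1)
  expect_equal(rem_preference_index(3, 3), 0)
  expect_equal(rem_preference_index(1, 3), -0.5)
  expect_true(is.na(rem_preference_index(0, 0)))
  # antisymmetry
  set.seed(61)
  a <- runif(20, 0, 5); b <- runif(20, 0, 5)
  expect_equal(rem_preference_index(a, b), -rem_preference_index(b, a))
})

test_that("state rates equal a direct count/duration oracle on whole-second epochs", {
  set.seed(62)
  hyp <- normalize_hypnogram(hyp_from_runs(
    c("WAKE", "NREM", "REM", "NREM", "REM", "WAKE"),
    c(60, 300, 100, 200, 80, 60)))
  spk <- gen_poisson_train(3, 800)
  sr <- state_rates(spk, hyp)
  for (st in c("NREM", "REM")) {
    iv <- hyp[hyp$state == st & hyp$usable, ]
    oracle <- sum(iv_count(spk, iv)) / sum(iv$end - iv$start)
    got <- if (st == "NREM") sr$fr_nrem else sr$fr_rem
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # 2 Hz homogeneous train: both rates near 2; empty train -> 0
  spk2 <- gen_poisson_train(2, 800)
  sr2 <- state_rates(spk2, hyp)
  expect_equal(sr2$fr_rem, 2, tolerance = 0.5)
  expect_equal(sr2$fr_nrem, 2, tolerance = 0.5)
  sr0 <- state_rates(numeric(0), hyp)
  expect_equal(sr0$fr_rem, 0)
  expect_equal(sr0$fr_nrem, 0)
})

test_that("shuffle classification is deterministic, conservative on ties, seeded", {
  cnt <- c(rep(1L, 40), rep(1L, 60)) # identical counts in every bin
  st <- c(rep("REM", 40), rep("NREM", 60))
  pr <- classify_preference(cnt, st, n_shuffles = 200, seed = 1)
  expect_equal(pr$index, 0)
  expect_equal(pr$label, "NS")
  # same seed, same data -> identical percentiles
  set.seed(2)
  cnt2 <- rpois(100, 2)
  a <- classify_preference(cnt2, st, 500, seed = 11)
  b <- classify_preference(cnt2, st, 500, seed = 11)
  expect_identical(a[c("null_lo", "null_hi", "label")],
                   b[c("null_lo", "null_hi", "label")])
  # all-zero counts flagged NS
  z <- classify_preference(rep(0L, 100), st, 100, seed = 1)
  expect_equal(z$label, "NS")
  expect_equal(z$flag, "all-zero counts")
  expect_error(classify_preference(1:5, rep("REM", 5)), "at least one")
})

test_that("strongly REM-modulated units are labeled REM and the null is exchangeable", {
  set.seed(63)
  st <- c(rep("REM", 600), rep("NREM", 1800))
  cnt <- c(rpois(600, 2), rpois(1800, 0.5))
  pr <- classify_preference(cnt, st, 1000, seed = 5)
  expect_equal(pr$label, "REM")
  # relabeling bin order leaves the classification unchanged
  perm <- sample(length(cnt))
  pr2 <- classify_preference(cnt[perm], st[perm], 1000, seed = 5)
  expect_equal(pr2$label, "REM")
  expect_equal(pr2$index, pr$index)
})

test_that("triplet profiles separate states and match a count oracle", {
  trip <- data.frame(n1_start = 0, n1_end = 90, rem_start = 90, rem_end = 150,
                     n2_start = 150, n2_end = 240)
  # constant-rate unit -> flat profile, z approximately 0
  spk <- seq(0.05, 239.95, by = 0.25)
  tp <- triplet_profile(spk, trip)
  expect_true(all(abs(tp$profile_hz - 4) < 0.1))
  # unit firing only in REM -> REM thirds strictly above NREM thirds
  spk2 <- seq(90.1, 149.9, by = 0.1)
  tp2 <- triplet_profile(spk2, trip)
  expect_true(min(tp2$profile_z[4:6]) > max(tp2$profile_z[c(1:3, 7:9)]))
  # random fixture vs direct interval counts
  set.seed(64)
  spk3 <- gen_poisson_train(2, 240)
  tp3 <- triplet_profile(spk3, trip)
  oracle <- c(vapply(0:2, function(k) sum(spk3 >= k * 30 & spk3 < (k + 1) * 30) / 30, numeric(1)),
              vapply(0:2, function(k) sum(spk3 >= 90 + k * 20 & spk3 < 90 + (k + 1) * 20) / 20, numeric(1)),
              vapply(0:2, function(k) sum(spk3 >= 150 + k * 30 & spk3 < 150 + (k + 1) * 30) / 30, numeric(1)))
  expect_equal(tp3$profile_hz, oracle)
  expect_error(triplet_profile(spk, trip[0, ]), "no triplets")
})

test_that("cross-session Spearman matrix handles ties like a rank oracle", {
  idx <- list(hc1 = c(0.1, 0.5, -0.2, 0.8, 0.3),
              hc2 = c(0.2, 0.4, -0.1, 0.9, 0.3),
              hc3 = c(-0.1, -0.5, 0.2, -0.8, -0.3))
  rho <- preference_correlation(idx)
  expect_equal(rho["hc1", "hc1"], 1)
  expect_equal(rho["hc1", "hc3"], -1)
  expect_equal(rho["hc1", "hc2"],
               cor(rank(idx$hc1), rank(idx$hc2))) # tie-aware oracle
  # too few shared neurons -> NA
  idx2 <- list(a = c(1, 2, NA, NA, NA), b = c(2, 1, NA, NA, NA))
  expect_true(is.na(preference_correlation(idx2)["a", "b"]))
})

test_that("bootstrap comparisons are seeded and symmetric for identical regions", {
  set.seed(65)
  m <- data.frame(hc1 = runif(40, -1, 1))
  m$hc2 <- m$hc1 + rnorm(40, 0, 0.3)
  m$hc3 <- m$hc1 + rnorm(40, 0, 0.3)
  regions <- list(A = m, B = m)
  expect_warning(
    bootstrap_correlation_compare(list(A = m[1:10, ]), n_resample = 92,
                                  n_boot = 10, seed = 1),
    "fewer than")
  bc <- suppressWarnings(
    bootstrap_correlation_compare(regions, n_resample = 92, n_boot = 300,
                                  seed = 7))
  # identical regions: between-region differences centered at 0
  expect_true(all(abs(bc$region_diff$diff_mean) < 0.05))
  expect_true(all(bc$region_diff$ci_lo <= 0 & bc$region_diff$ci_hi >= 0))
  # stable correlations: rho significantly above 0
  expect_true(all(bc$rho$rho_mean > 0))
  expect_true(all(bc$rho$p_boot < 0.05))
  suppressWarnings({
    b1 <- bootstrap_correlation_compare(regions, 92, 200, seed = 8)
    b2 <- bootstrap_correlation_compare(regions, 92, 200, seed = 8)
  })
  expect_identical(b1, b2)
})

test_that("false-positive rate of the shuffle classifier is near alpha", {
  # quick null calibration at reduced n (the acceptance suite runs the full
  # 1000-unit version)
  set.seed(66)
  st <- c(rep("REM", 500), rep("NREM", 1500))
  fp <- mean(replicate(200, {
    cnt <- rpois(2000, 1.5)
    classify_preference(cnt, st, 500)$label != "NS"
  }))
  expect_gt(fp, 0.005)
  expect_lt(fp, 0.11)
})
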