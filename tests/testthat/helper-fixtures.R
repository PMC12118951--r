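# Shared fixtures, built in code and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

# Homogeneous Poisson train on [0, T).
gen_poisson_train <- function(rate, T) {
  sort(runif(rpois(1, rate * T), 0, T))
}

# A 30-min synthetic session with ground truth, cached across test files.
fixture_session <- function() {
  if (is.null(.fixtures$session)) {
    dir <- file.path(tempdir(), "sleeposc-fixture-session")
    cfg <- synth_config(duration_s = 1800, n_units_per_region = 5,
                        shock_times = c(100, 200, 300),
                        cs_times = c(69, 169, 269), seed = 424242L)
    .fixtures$config <- cfg
    .fixtures$session <- generate_session(cfg, dir)
  }
  .fixtures$session
}

fixture_config <- function() {
  fixture_session()
  .fixtures$config
}

# Detected events on the fixture session (expensive; cached).
fixture_events <- function() {
  if (is.null(.fixtures$events)) {
    s <- fixture_session()
    hyp <- normalize_hypnogram(s$hypnogram)
    .fixtures$hyp <- hyp
    .fixtures$events <- sleeposc:::detect_all_oscillations(s$lfp, hyp)
  }
  .fixtures$events
}

fixture_hypnogram <- function() {
  fixture_events()
  .fixtures$hyp
}

# Simple hand-built hypnogram from state/duration pairs.
hyp_from_runs <- function(states, durs) {
  ends <- cumsum(durs)
  data.frame(start = c(0, head(ends, -1)), end = ends, state = states)
}

# A minimal lfp_set with given channel matrix.
make_lfp <- function(data, fs, regions, shanks = NULL, depth = NULL) {
  k <- ncol(data)
  structure(list(
    data = data, fs = fs,
    channels = data.frame(channel = seq_len(k),
                          name = paste0("ch", seq_len(k)),
                          region = regions,
                          shank = shanks %||% paste0(regions, "_s1"),
                          depth_order = depth %||% seq_len(k))),
    class = "lfp_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All permutations of 1..n (for exhaustive rank-test enumeration, small n).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) for (k in 0:(n - 1))
    out[[length(out) + 1]] <- append(p, n, after = k)
  out
}
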