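# Hypnogram post-processing: microarousal merging, short-epoch exclusion,
# extended-sleep periods and NREM-REM-NREM triplets.

#' Normalize a raw hypnogram
#'
#' Wake bouts shorter than 40 s that occur within NREM sleep (NREM on both
#' sides) or at a REM-to-NREM transition are microarousals: they are
#' relabeled NREM and merged with their neighbors. Wake at sleep onset or
#' offset is never merged. Afterwards, epochs lasting 50 s or less are kept
#' in the timeline but flagged unusable (`usable = FALSE`). `MA` labels in
#' the input are treated as wake. The operation is idempotent.
#'
#' @param raw hypnogram interval table (`start`, `end`, `state`), a partition.
#' @return normalized hypnogram with a `usable` column.
#' @export
normalize_hypnogram <- function(raw) {
  hyp <- raw[order(raw$start), , drop = FALSE]
  hyp$state[hyp$state == "MA"] <- "WAKE"
  repeat {
    dur <- hyp$end - hyp$start
    n <- nrow(hyp)
    prev <- c(NA, hyp$state[-n]); nxt <- c(hyp$state[-1], NA)
    ma <- which(hyp$state == "WAKE" & dur < 40 &
                  ((prev %in% "NREM" & nxt %in% "NREM") |
                     (prev %in% "REM" & nxt %in% "NREM")))
    if (length(ma) == 0) break
    hyp$state[ma[1]] <- "NREM"
    hyp <- merge_same_state(hyp)
  }
  hyp <- merge_same_state(hyp)
  hyp$usable <- (hyp$end - hyp$start) > 50
  rownames(hyp) <- NULL
  hyp
}

merge_same_state <- function(hyp) {
  n <- nrow(hyp)
  if (n <= 1) return(hyp[, c("start", "end", "state"), drop = FALSE])
  grp <- cumsum(c(TRUE, hyp$state[-1] != hyp$state[-n]))
  first <- which(!duplicated(grp))
  last <- c(first[-1] - 1L, n)
  data.frame(start = hyp$start[first], end = hyp$end[last],
             state = hyp$state[first])
}

#' Find extended-sleep periods
#'
#' Maximal periods of sleep (NREM/REM) spanning more than 30 min in which no
#' wake bout exceeds 60 s. A period starts at the first and ends at the last
#' sleep epoch it contains; internal wake bouts of up to 60 s are allowed.
#'
#' @param hypnogram normalized hypnogram (from [normalize_hypnogram()]).
#' @return interval table of extended-sleep periods.
#' @export
find_extended_sleep <- function(hypnogram) {
  sleep <- hypnogram$state %in% c("NREM", "REM")
  n <- nrow(hypnogram)
  out_s <- numeric(0); out_e <- numeric(0)
  i <- 1
  while (i <= n) {
    if (!sleep[i]) { i <- i + 1; next }
    j <- i
    while (j < n) {
      k <- j + 1
      if (sleep[k]) { j <- k; next }
      # wake bout: allowed if <= 60 s and followed by more sleep
      if (hypnogram$end[k] - hypnogram$start[k] <= 60 && k < n && sleep[k + 1]) {
        j <- k + 1
      } else break
    }
    if (hypnogram$end[j] - hypnogram$start[i] > 1800) {
      out_s <- c(out_s, hypnogram$start[i]); out_e <- c(out_e, hypnogram$end[j])
    }
    i <- j + 1
  }
  data.frame(start = out_s, end = out_e)
}

#' Find NREM-REM-NREM triplets
#'
#' All runs of consecutive NREM, REM, NREM epochs in which every member lasts
#' more than 50 s. Consecutive triplets may share epochs (N-R-N-R-N yields
#' two triplets). By default consecutiveness tolerates intervening excluded
#' (<= 50 s) epochs of any state, which are skipped over; set
#' `tolerate_excluded = FALSE` to require strict adjacency.
#'
#' @param hypnogram normalized hypnogram with `usable` column.
#' @param tolerate_excluded skip over unusable short epochs (default TRUE).
#' @return data.frame with one row per triplet: `n1_start`, `n1_end`,
#'   `rem_start`, `rem_end`, `n2_start`, `n2_end`.
#' @export
find_triplets <- function(hypnogram, tolerate_excluded = TRUE) {
  hp <- if (tolerate_excluded) hypnogram[hypnogram$usable, , drop = FALSE]
  else hypnogram
  ok <- (hp$end - hp$start) > 50
  n <- nrow(hp)
  rows <- list()
  if (n >= 3) for (i in 1:(n - 2)) {
    if (hp$state[i] == "NREM" && hp$state[i + 1] == "REM" &&
        hp$state[i + 2] == "NREM" && all(ok[i:(i + 2)])) {
      rows[[length(rows) + 1]] <- data.frame(
        n1_start = hp$start[i], n1_end = hp$end[i],
        rem_start = hp$start[i + 1], rem_end = hp$end[i + 1],
        n2_start = hp$start[i + 2], n2_end = hp$end[i + 2])
    }
  }
  if (length(rows) == 0)
    return(data.frame(n1_start = numeric(0), n1_end = numeric(0),
                      rem_start = numeric(0), rem_end = numeric(0),
                      n2_start = numeric(0), n2_end = numeric(0)))
  do.call(rbind, rows)
}
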