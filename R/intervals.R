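# Interval algebra on half-open [start, end) intervals, times in seconds from
# session start. All analysis epochs (hypnogram states, oscillatory events,
# session windows) are represented this way; half-open bounds mean a spike on
# a shared boundary is counted exactly once.

#' Construct an interval table
#'
#' @param start,end numeric vectors of equal length; each row is `[start, end)`.
#' @param label optional character vector of labels.
#' @return a `data.frame` with columns `start`, `end` (and `label` if given).
#' @export
intervals <- function(start, end, label = NULL) {
  if (length(start) != length(end)) stop("start and end lengths differ")
  if (any(end <= start)) stop("intervals must satisfy start < end")
  out <- data.frame(start = as.numeric(start), end = as.numeric(end))
  if (!is.null(label)) out$label <- as.character(label)
  out
}

#' Total duration of an interval set
#' @param iv interval table.
#' @return total duration in seconds.
#' @export
iv_duration <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(0)
  sum(iv$end - iv$start)
}

#' Sort and merge overlapping or abutting intervals
#' @param iv interval table.
#' @param merge_touching merge intervals that abut exactly (default TRUE).
#' @return merged interval table (labels dropped).
#' @export
iv_union <- function(iv, merge_touching = TRUE) {
  if (nrow(iv) == 0) return(intervals(numeric(0), numeric(0)))
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  s <- iv$start; e <- iv$end
  out_s <- s[1]; out_e <- e[1]; k <- 1
  for (i in seq_len(nrow(iv))[-1]) {
    joins <- if (merge_touching) s[i] <= out_e[k] else s[i] < out_e[k]
    if (joins) {
      out_e[k] <- max(out_e[k], e[i])
    } else {
      k <- k + 1; out_s[k] <- s[i]; out_e[k] <- e[i]
    }
  }
  data.frame(start = out_s, end = out_e)
}

#' Intersection of two interval sets
#' @param a,b interval tables.
#' @return interval table of pairwise overlaps (merged, unlabeled).
#' @export
iv_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(intervals(numeric(0), numeric(0)))
  a <- iv_union(a); b <- iv_union(b)
  out_s <- numeric(0); out_e <- numeric(0)
  j <- 1
  for (i in seq_len(nrow(a))) {
    while (j <= nrow(b) && b$end[j] <= a$start[i]) j <- j + 1
    jj <- j
    while (jj <= nrow(b) && b$start[jj] < a$end[i]) {
      s <- max(a$start[i], b$start[jj]); e <- min(a$end[i], b$end[jj])
      if (e > s) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
      jj <- jj + 1
    }
  }
  data.frame(start = out_s, end = out_e)
}

#' Set difference a \ b of interval sets
#' @param a,b interval tables.
#' @return interval table covering time in `a` but not in `b`.
#' @export
iv_setdiff <- function(a, b) {
  a <- iv_union(a)
  if (nrow(a) == 0) return(a)
  b <- iv_union(b)
  if (nrow(b) == 0) return(a)
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    cur <- a$start[i]
    ov <- b[b$end > a$start[i] & b$start < a$end[i], , drop = FALSE]
    if (nrow(ov) > 0) for (k in seq_len(nrow(ov))) {
      if (ov$start[k] > cur) { out_s <- c(out_s, cur); out_e <- c(out_e, ov$start[k]) }
      cur <- max(cur, ov$end[k])
    }
    if (cur < a$end[i]) { out_s <- c(out_s, cur); out_e <- c(out_e, a$end[i]) }
  }
  data.frame(start = out_s, end = out_e)
}

#' Count events (e.g. spikes) falling in each interval
#'
#' Membership is half-open: a time `t` belongs to `[start, end)`.
#'
#' @param times sorted numeric vector of event times.
#' @param iv interval table.
#' @return integer vector, one count per row of `iv`.
#' @export
iv_count <- function(times, iv) {
  if (nrow(iv) == 0) return(integer(0))
  n_before <- function(x) findInterval(x, times, left.open = TRUE)
  as.integer(n_before(iv$end) - n_before(iv$start))
}

#' Which events fall inside any interval of a set
#' @param times numeric vector (need not be sorted).
#' @param iv interval table (need not be disjoint).
#' @return logical vector along `times`.
#' @export
iv_contains <- function(times, iv) {
  if (nrow(iv) == 0) return(rep(FALSE, length(times)))
  u <- iv_union(iv)
  idx <- findInterval(times, u$start)
  idx > 0 & times < u$end[pmax(idx, 1)]
}

# Clip an interval table to [lo, hi), dropping empty results.
iv_clip <- function(iv, lo, hi) {
  s <- pmax(iv$start, lo); e <- pmin(iv$end, hi)
  keep <- e > s
  out <- iv[keep, , drop = FALSE]
  out$start <- s[keep]; out$end <- e[keep]
  out
}

# Convert a logical run-mask over a regular sample grid into intervals.
# Sample i covers [i-1, i)/fs shifted by t0.
mask_to_iv <- function(mask, fs, t0 = 0) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = t0 + starts[keep] / fs, end = t0 + ends[keep] / fs)
}
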