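# Independent brute-force oracles used by the unit and acceptance suites.

# Exhaustive two-sided Mann-Whitney p over all group assignments.
enum_mann_whitney <- function(x, y) {
  pool <- c(x, y); nx <- length(x)
  u_obs <- sum(rank(pool)[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * length(y) / 2
  combs <- utils::combn(length(pool), nx)
  us <- apply(combs, 2, function(ix) sum(rank(pool)[ix]) - nx * (nx + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Exhaustive two-sided Wilcoxon signed-rank p over all sign flips.
enum_signed_rank <- function(d) {
  d <- d[d != 0]; n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-12)
}

# Exhaustive two-sided Spearman p over all permutations of one margin.
enum_spearman <- function(x, y) {
  rho_obs <- stats::cor(rank(x), rank(y))
  perms <- combinat_perms(length(y))
  rhos <- vapply(perms, function(p) stats::cor(rank(x), rank(y[p])),
                 numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# Overlap-based recall/precision of detected vs injected event intervals.
match_events <- function(truth, detected) {
  recall <- if (nrow(truth) == 0) NA_real_ else
    mean(vapply(seq_len(nrow(truth)), function(i)
      any(detected$start < truth$end[i] & detected$end > truth$start[i]),
      logical(1)))
  precision <- if (nrow(detected) == 0) NA_real_ else
    mean(vapply(seq_len(nrow(detected)), function(i)
      any(truth$start < detected$end[i] & truth$end > detected$start[i]),
      logical(1)))
  list(recall = recall, precision = precision)
}
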