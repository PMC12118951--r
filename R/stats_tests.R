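# Nonparametric tests used throughout, including an in-package Steel-Dwass
# all-pairs post hoc (not available in the standard libraries). Standard
# tests delegate to the base-R routines; every result carries method and
# group sizes so reported p values are auditable.

test_result <- function(statistic, p_value, n, method, ties = FALSE) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n = n, method = method, ties = ties),
            class = "test_result")
}

has_ties <- function(x) any(duplicated(x))

#' Mann-Whitney U test (two-sided)
#'
#' Exact enumeration for combined samples of 12 or fewer without ties;
#' otherwise the tie-corrected normal approximation (no continuity
#' correction).
#'
#' @param x,y numeric samples.
#' @return a `test_result`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("empty group")
  ties <- has_ties(c(x, y))
  exact <- (length(x) + length(y) <= 12) && !ties
  w <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  test_result(w$statistic, w$p.value, c(length(x), length(y)),
              "Mann-Whitney U", ties)
}

#' Wilcoxon signed-rank test (two-sided)
#'
#' Zero differences are dropped; exact sign-flip enumeration for 12 or fewer
#' nonzero differences without ties, otherwise the tie-corrected normal
#' approximation.
#'
#' @param d numeric vector of paired differences.
#' @return a `test_result`.
#' @export
wilcoxon_signed_rank <- function(d) {
  d <- d[d != 0]
  if (length(d) < 1) stop("all differences are zero")
  ties <- has_ties(abs(d))
  exact <- length(d) <= 12 && !ties
  w <- suppressWarnings(wilcox.test(d, exact = exact, correct = FALSE))
  test_result(w$statistic, w$p.value, length(d), "Wilcoxon signed-rank", ties)
}

#' Spearman rank correlation (two-sided)
#'
#' Tie-aware rho (Pearson correlation of ranks). Exact p for n <= 7 without
#' ties; otherwise the t approximation on rho.
#'
#' @param x,y numeric vectors.
#' @return a `test_result` with `statistic` = rho.
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  ties <- has_ties(x) || has_ties(y)
  rho <- cor(rank(x), rank(y))
  p <- if (n <= 7 && !ties) {
    cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else if (abs(rho) >= 1) {
    tst <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    tst$p.value
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  test_result(rho, p, n, "Spearman rank correlation", ties)
}

# One Steel-Dwass pairwise comparison: joint ranks of the two groups,
# tie-corrected rank-sum variance, statistic referred to the Studentized
# range distribution with k groups (df = Inf).
steel_dwass_pair <- function(xi, xj, k) {
  ni <- length(xi); nj <- length(xj); N <- ni + nj
  r <- rank(c(xi, xj))
  Ri <- sum(r[seq_len(ni)])
  E <- ni * (N + 1) / 2
  # tie-corrected rank-sum variance via the empirical rank variance
  V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  z <- (Ri - E) / sqrt(V)
  p <- ptukey(sqrt(2) * abs(z), nmeans = k, df = Inf, lower.tail = FALSE)
  list(z = z, p = p, n = c(ni, nj))
}

#' Kruskal-Wallis omnibus with Steel-Dwass all-pairs post hoc
#'
#' Tie-corrected Kruskal-Wallis; when its p value falls below `gate`
#' (default 0.05), every group pair is compared with the Steel-Dwass
#' procedure: joint ranks of the two groups, tie-corrected variance, and the
#' studentized statistic `sqrt(2) |z|` referred to the Studentized range
#' distribution with `k` groups (df = Inf). With two groups this reduces to
#' the two-sided tie-corrected rank-sum z test.
#'
#' @param groups named list of numeric vectors (>= 2 each; >= 2 groups).
#' @param gate omnibus p threshold gating the post hoc (`Inf` runs it
#'   unconditionally).
#' @return list `omnibus` (a `test_result`) and `pairwise` (data.frame of
#'   pair, z, p, group sizes; `NULL` when gated out).
#' @export
kruskal_steel_dwass <- function(groups, gate = 0.05) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 observations")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- kruskal.test(groups)
  omnibus <- test_result(kw$statistic, kw$p.value, lengths(groups),
                         "Kruskal-Wallis", has_ties(unlist(groups)))
  pairwise <- NULL
  if (omnibus$p_value < gate) {
    k <- length(groups)
    cmb <- utils::combn(names(groups), 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(c1) {
      a <- cmb[1, c1]; b <- cmb[2, c1]
      sd_ <- steel_dwass_pair(groups[[a]], groups[[b]], k)
      data.frame(group_a = a, group_b = b, z = sd_$z, p = sd_$p,
                 n_a = sd_$n[1], n_b = sd_$n[2])
    }))
  }
  list(omnibus = omnibus, pairwise = pairwise)
}

# Pipeline stage: assemble the standard comparisons from upstream results.
pipeline_stats <- function(res) {
  rows <- list()
  add <- function(analysis, tr) {
    rows[[length(rows) + 1]] <<- data.frame(
      analysis = analysis, method = tr$method, statistic = tr$statistic,
      p_value = tr$p_value, n = paste(tr$n, collapse = ","))
  }
  pref <- res$preference
  if (!is.null(res$gains) && !is.null(pref)) {
    lab <- setNames(pref$label, pref$unit_id)
    for (kind in unique(res$gains$kind)) {
      g <- res$gains[res$gains$kind == kind, ]
      gn <- g$gain[lab[g$unit_id] %in% "NREM"]
      gr <- g$gain[lab[g$unit_id] %in% "REM"]
      gn <- gn[is.finite(gn)]; gr <- gr[is.finite(gr)]
      if (length(gn) >= 2 && length(gr) >= 2)
        add(paste0("fr_gain_", kind, "_NREMpref_vs_REMpref"),
            mann_whitney(gn, gr))
      idx <- setNames(pref$index, pref$unit_id)
      ok <- is.finite(g$gain) & is.finite(idx[g$unit_id])
      if (sum(ok) >= 4 && sd(g$gain[ok]) > 0 && sd(idx[g$unit_id][ok]) > 0)
        add(paste0("fr_gain_", kind, "_vs_index"),
            spearman(idx[g$unit_id][ok], g$gain[ok]))
    }
  }
  if (!is.null(res$coactivity)) {
    for (kind in unique(res$coactivity$kind)) {
      d <- res$coactivity[res$coactivity$kind == kind, ]
      ok <- is.finite(d$z) & is.finite(d$index_product)
      if (sum(ok) >= 4 && sd(d$z[ok]) > 0 && sd(d$index_product[ok]) > 0)
        add(paste0("coactivity_", kind, "_z_vs_index_product"),
            spearman(d$index_product[ok], d$z[ok]))
      grp <- split(d$z[ok], d$pair_type[ok])
      grp <- grp[names(grp) %in% c("NN", "RR", "NR", "RN")]
      grp <- grp[lengths(grp) >= 2]
      if (length(grp) >= 3) {
        ks <- kruskal_steel_dwass(grp)
        add(paste0("coactivity_", kind, "_kruskal"), ks$omnibus)
        if (!is.null(ks$pairwise)) for (i in seq_len(nrow(ks$pairwise)))
          rows[[length(rows) + 1]] <- data.frame(
            analysis = paste0("coactivity_", kind, "_steel_dwass_",
                              ks$pairwise$group_a[i], "_", ks$pairwise$group_b[i]),
            method = "Steel-Dwass", statistic = ks$pairwise$z[i],
            p_value = ks$pairwise$p[i],
            n = paste(ks$pairwise$n_a[i], ks$pairwise$n_b[i], sep = ","))
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(analysis = character(0), method = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      n = character(0)))
  do.call(rbind, rows)
}
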