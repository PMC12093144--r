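# Circularization enrichment by flanking-Alu pattern: log-odds differences
# with bootstrap uncertainty, Mann-Whitney comparisons, and downstream-Alu
# length distributions.

#' Cross-tabulate classified exons by pattern and circularization
#'
#' @param classified data.frame from [classify_exons()] with columns
#'   `pattern` and `circularizing`.
#' @return data.frame with one row per flank pattern (all five always
#'   present) and columns `pattern`, `n_circ`, `n_noncirc`.
#' @export
build_contingency <- function(classified) {
  if (nrow(classified) == 0) stop("no classified exons")
  pat <- factor(as.character(classified$pattern), levels = FLANK_PATTERNS)
  tab <- table(pattern = pat, circ = factor(classified$circularizing,
                                            levels = c(TRUE, FALSE)))
  data.frame(pattern = FLANK_PATTERNS,
             n_circ = as.integer(tab[, "TRUE"]),
             n_noncirc = as.integer(tab[, "FALSE"]),
             stringsAsFactors = FALSE)
}

.row_counts <- function(table, pattern) {
  i <- match(pattern, table$pattern)
  if (is.na(i)) stop(sprintf("pattern '%s' not present in table", pattern))
  c(circ = table$n_circ[i], noncirc = table$n_noncirc[i])
}

#' Difference in log odds of circularization between two flank patterns
#'
#' Computes `ln(odds_pattern) - ln(odds_baseline)` where
#' `odds = n_circ / n_noncirc`. When any of the four cells is zero the
#' Haldane-Anscombe correction adds `correction` (default 0.5) to all four
#' cells at once; otherwise counts are used untouched. Natural log.
#'
#' @param table contingency from [build_contingency()].
#' @param pattern,baseline flank-pattern names.
#' @param correction pseudo-count applied only when needed.
#' @return a single dimensionless log-odds difference.
#' @export
log_odds_difference <- function(table, pattern, baseline = "NONE",
                                correction = 0.5) {
  p <- .row_counts(table, pattern)
  b <- .row_counts(table, baseline)
  if (sum(p) == 0)
    stop(sprintf("pattern '%s' has no exons; log odds undefined", pattern))
  if (sum(b) == 0)
    stop(sprintf("baseline '%s' has no exons; log odds undefined", baseline))
  cells <- c(p, b)
  k <- if (any(cells == 0)) correction else 0
  unname(log((p["circ"] + k) / (p["noncirc"] + k)) -
         log((b["circ"] + k) / (b["noncirc"] + k)))
}

#' Case bootstrap of a log-odds difference
#'
#' Case resampling over exons: each replicate redraws all n exons with
#' replacement and recomputes the log-odds difference. Because the
#' statistic depends on an exon only through its (pattern, circularizing)
#' cell, resampling exons is carried out as multinomial resampling of the
#' ten contingency cells, which is exactly equivalent and vectorizable.
#' Degenerate replicates (an empty cell) are recomputed with the
#' Haldane-Anscombe pseudo-count rather than dropped.
#'
#' @param classified data.frame from [classify_exons()].
#' @param pattern,baseline flank-pattern names.
#' @param B number of bootstrap replicates.
#' @param seed integer seed (mandatory for reproducibility).
#' @param conf confidence level for the percentile interval.
#' @return list with elements `pattern`, `baseline`, `log_odds` (point
#'   log-odds of `pattern`), `diff_vs_baseline` (point estimate),
#'   `bootstrap_samples` (length B), `ci_low`, `ci_high`.
#' @export
bootstrap_log_odds <- function(classified, pattern, baseline = "NONE",
                               B = 1000, seed, conf = 0.95) {
  stopifnot(B >= 1)
  if (missing(seed)) stop("a seed is required for bootstrap reproducibility")
  tab <- build_contingency(classified)
  point <- log_odds_difference(tab, pattern, baseline)
  counts <- c(rbind(tab$n_circ, tab$n_noncirc))  # 10 cells
  n <- sum(counts)
  set.seed(seed)
  draws <- stats::rmultinom(B, size = n, prob = counts / n)
  ip <- match(pattern, tab$pattern); ib <- match(baseline, tab$pattern)
  pc <- draws[2 * ip - 1, ]; pn <- draws[2 * ip, ]
  bc <- draws[2 * ib - 1, ]; bn <- draws[2 * ib, ]
  k <- ifelse(pc == 0 | pn == 0 | bc == 0 | bn == 0, 0.5, 0)
  samples <- log((pc + k) / (pn + k)) - log((bc + k) / (bn + k))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(samples, c(alpha, 1 - alpha), names = FALSE))
  list(pattern = pattern, baseline = baseline,
       log_odds = .pattern_log_odds(tab, pattern),
       diff_vs_baseline = point,
       bootstrap_samples = samples,
       ci_low = ci[1], ci_high = ci[2])
}

.pattern_log_odds <- function(tab, pattern) {
  p <- .row_counts(tab, pattern)
  k <- if (any(p == 0)) 0.5 else 0
  unname(log((p["circ"] + k) / (p["noncirc"] + k)))
}

#' Mann-Whitney U test
#'
#' U counts the (x_i, y_j) pairs with x_i > y_j, plus 0.5 per tie. The
#' exact two-sided p-value enumerates every assignment of the pooled values
#' to the two groups (used when n + m <= 12 in `auto` mode); otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param x,y numeric samples (both nonempty).
#' @param mode `"exact"`, `"normal_approx"`, or `"auto"`.
#' @return list with `U` and two-sided `p`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n <- length(x); m <- length(y)
  u <- .u_statistic(x, y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both samples; test is degenerate")
    return(list(U = u, p = 1))
  }
  if (mode == "exact" || (mode == "auto" && n + m <= 12)) {
    p <- .mwu_exact_p(pooled, n, u)
  } else {
    p <- .mwu_normal_p(pooled, n, m, u)
  }
  list(U = unname(u), p = unname(min(p, 1)))
}

.u_statistic <- function(x, y) {
  # rank-sum form handles ties via midranks: U = R_x - n(n+1)/2
  n <- length(x)
  r <- rank(c(x, y), ties.method = "average")
  sum(r[seq_len(n)]) - n * (n + 1) / 2
}

.mwu_exact_p <- function(pooled, n, u) {
  N <- length(pooled)
  idx <- utils::combn(N, n)
  r <- rank(pooled, ties.method = "average")
  us <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
  eps <- 1e-9
  p_lo <- mean(us <= u + eps)
  p_hi <- mean(us >= u - eps)
  min(1, 2 * min(p_lo, p_hi))
}

.mwu_normal_p <- function(pooled, n, m, u) {
  N <- n + m
  ties <- table(pooled)
  mu <- n * m / 2
  sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  2 * stats::pnorm(-abs(z))
}

#' Downstream-Alu length distributions by circularization status
#'
#' Applies the flanking window criterion only -- no minimum-length filter --
#' and returns the lengths of all downstream Alus grouped by whether the
#' exon circularizes, for length-distribution comparisons.
#'
#' @param exons data.frame of exon intervals.
#' @param alus data.frame of Alu elements.
#' @param circs circRNA records for [mark_circularizing()] (or a logical
#'   vector of labels via `circularizing`).
#' @param window flanking window in nucleotides.
#' @param circularizing optional precomputed logical labels along `exons`.
#' @return list with numeric vectors `circ` and `noncirc` of Alu lengths.
#' @export
downstream_alu_lengths <- function(exons, alus, circs = NULL, window = 2000,
                                   circularizing = NULL) {
  if (is.null(circularizing))
    circularizing <- mark_circularizing(exons, circs)
  stopifnot(length(circularizing) == nrow(exons))
  if (nrow(exons) == 0) return(list(circ = numeric(0), noncirc = numeric(0)))
  pick <- function(side) {
    h <- .flank_side_pairs(exons, alus, window, 0, side)
    keep <- if (side == "right") exons$strand[h$exon] != "-" else
      exons$strand[h$exon] == "-"
    list(exon = h$exon[keep], alu = h$alu[keep])
  }
  p <- list(pick("left"), pick("right"))
  exon_idx <- c(p[[1]]$exon, p[[2]]$exon)
  alu_idx <- c(p[[1]]$alu, p[[2]]$alu)
  lens <- alus$end[alu_idx] - alus$start[alu_idx]
  list(circ = lens[circularizing[exon_idx]],
       noncirc = lens[!circularizing[exon_idx]])
}

#' Enrichment summary table across all flank patterns
#'
#' One shared set of case-bootstrap replicates (multinomial over the ten
#' contingency cells) yields, per pattern, bootstrap samples of its log
#' odds; differences are taken against the baseline within each replicate.
#' The Mann-Whitney column compares the bootstrap log-odds distribution of
#' each pattern with the baseline's, mirroring distribution-level
#' comparisons of enrichment violins; it is a descriptive contrast of
#' resampled estimates, not a calibrated test on independent units.
#'
#' @param classified data.frame from [classify_exons()].
#' @param baseline baseline pattern for differences.
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @return data.frame: pattern, n_circ, n_noncirc, log_odds, diff, ci_low,
#'   ci_high, mwu_p_vs_baseline.
#' @export
enrichment_table <- function(classified, baseline = "NONE", B = 1000, seed) {
  if (missing(seed)) stop("a seed is required for bootstrap reproducibility")
  tab <- build_contingency(classified)
  counts <- c(rbind(tab$n_circ, tab$n_noncirc))
  n <- sum(counts)
  set.seed(seed)
  draws <- stats::rmultinom(B, size = n, prob = counts / n)
  lo_samples <- function(p) {
    i <- match(p, tab$pattern)
    pc <- draws[2 * i - 1, ]; pn <- draws[2 * i, ]
    k <- ifelse(pc == 0 | pn == 0, 0.5, 0)
    log((pc + k) / (pn + k))
  }
  base_present <- sum(.row_counts(tab, baseline)) > 0
  base_s <- if (base_present) lo_samples(baseline) else NULL
  rows <- lapply(FLANK_PATTERNS, function(p) {
    row <- tab[tab$pattern == p, ]
    if (row$n_circ + row$n_noncirc == 0 || !base_present)
      return(data.frame(pattern = p, n_circ = row$n_circ,
                        n_noncirc = row$n_noncirc,
                        log_odds = NA_real_, diff = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        mwu_p_vs_baseline = NA_real_))
    s <- lo_samples(p)
    d <- s - base_s
    ci <- unname(stats::quantile(d, c(0.025, 0.975), names = FALSE))
    pval <- if (p == baseline) NA_real_ else
      suppressWarnings(mann_whitney_u(s, base_s, mode = "normal_approx"))$p
    data.frame(pattern = p, n_circ = row$n_circ, n_noncirc = row$n_noncirc,
               log_odds = .pattern_log_odds(tab, p),
               diff = log_odds_difference(tab, p, baseline),
               ci_low = ci[1], ci_high = ci[2], mwu_p_vs_baseline = pval)
  })
  do.call(rbind, rows)
}
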