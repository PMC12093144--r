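# Independent oracles used across tests. Deliberately naive and separate
# from the package's implementations.

# All-pairs flank classification for one exon: loops over every Alu,
# applies the window/length/side rules literally, then the pattern rule
# table.
naive_classify_exon <- function(exon, alus, window = 2000,
                                min_full_length = 250) {
  up <- list(); down <- list()
  for (k in seq_len(nrow(alus))) {
    a <- alus[k, ]
    if (a$chrom != exon$chrom) next
    if ((a$end - a$start) < min_full_length) next
    left <- a$end <= exon$start && (exon$start - a$end) <= window
    right <- a$start >= exon$end && (a$start - exon$end) <= window
    if (!left && !right) next
    side <- if (left) "L" else "R"
    if (exon$strand == "-") side <- if (side == "L") "R" else "L"
    if (side == "L") up <- c(up, list(a)) else down <- c(down, list(a))
  }
  up_s <- vapply(up, function(a) a$strand, "")
  down_s <- vapply(down, function(a) a$strand, "")
  if (!length(up) && !length(down)) return("NONE")
  if (length(up) && !length(down)) return("FIVE_PRIME_ONLY")
  if (!length(up) && length(down)) return("THREE_PRIME_ONLY")
  for (u in up_s) for (d in down_s) if (u != d) return("IR")
  "OTHER"
}

# Exhaustive Mann-Whitney two-sided p by bitmask enumeration of every
# subset of pooled positions assigned to x.
brute_mwu_p <- function(x, y) {
  n <- length(x); N <- n + length(y)
  pooled <- c(x, y)
  u_of <- function(xi, yi) {
    u <- 0
    for (a in xi) for (b in yi)
      u <- u + (a > b) + 0.5 * (a == b)
    u
  }
  u_obs <- u_of(x, y)
  us <- c()
  for (mask in 0:(2^N - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(N - 1))) > 0)
    if (length(sel) != n) next
    us <- c(us, u_of(pooled[sel], pooled[-sel]))
  }
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Character-level lift-over oracle: delete the spec's intervals from an
# indexed reference; the mutant->WT map is the vector of surviving
# indices.
alignment_liftover_oracle <- function(spec, wt_length) {
  deleted <- rep(FALSE, wt_length)
  for (k in seq_len(nrow(spec)))
    deleted[(spec$wt_start[k] + 1):spec$wt_end[k]] <- TRUE
  which(!deleted) - 1L  # oracle_map[mutant_pos + 1] == wt_pos
}

random_alus <- function(n, chrom_pool = c("chr1", "chr2"), span = 500000) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(50:400, n, replace = TRUE)
  data.frame(chrom = sample(chrom_pool, n, replace = TRUE),
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             name = "AluX", stringsAsFactors = FALSE)
}

random_exons <- function(n, chrom_pool = c("chr1", "chr2"), span = 500000) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(80:600, n, replace = TRUE)
  data.frame(chrom = sample(chrom_pool, n, replace = TRUE),
             start = start, end = start + len,
             name = sprintf("e%d", seq_len(n)), score = 0,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
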