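# Seeded synthetic-data generators. Every pipeline input can be produced
# here with known (planted) ground truth, so each analysis stage supports
# parameter-recovery testing without external downloads.
#
# The genome simulator plants flank patterns geometrically -- actual Alu
# coordinates respecting the window/strand rules -- not just labels, so the
# interval logic is exercised alongside the statistics.

#' Configuration for the synthetic genome generator
#'
#' Defaults describe a field-realistic toy genome: ~300-nt Alu elements
#' (sd 20, truncated at `min_full_length` so planted Alus always qualify),
#' Alu-exon gaps uniform in 50-1500 nt (inside the 2000-nt flanking
#' window), a pattern mix dominated by Alu-free exons, and a logistic
#' circularization model: log odds `beta0` for every exon plus `beta1` for
#' exons flanked by inverted repeats.
#'
#' @param n_exons number of exons.
#' @param alu_length_mean,alu_length_sd Alu length distribution (nt).
#' @param gap_range Alu-exon boundary gap range (nt), within the window.
#' @param exon_length_range exon length range (nt).
#' @param pattern_mix named probabilities over [FLANK_PATTERNS].
#' @param beta0 baseline log odds of circularization.
#' @param beta1 added log odds for IR-flanked exons.
#' @param window,min_full_length flanking criteria the geometry respects.
#' @param short_alu_prob probability of adding a decoy Alu shorter than
#'   `min_full_length` next to an exon (must not change its pattern).
#' @param multiblock_frac fraction of exons receiving a decoy multi-exon
#'   circRNA record (block_count 2; must be ignored by the intersection).
#' @param seed integer seed.
#' @return list of class `genome_sim_config`.
#' @export
genome_sim_config <- function(n_exons = 1000,
                              alu_length_mean = 300, alu_length_sd = 20,
                              gap_range = c(50, 1500),
                              exon_length_range = c(100, 500),
                              pattern_mix = c(IR = 0.20, FIVE_PRIME_ONLY = 0.15,
                                              THREE_PRIME_ONLY = 0.15,
                                              NONE = 0.40, OTHER = 0.10),
                              beta0 = -2.2, beta1 = 1.21,
                              window = 2000, min_full_length = 250,
                              short_alu_prob = 0.1, multiblock_frac = 0.02,
                              seed = 1) {
  stopifnot(n_exons >= 1,
            abs(sum(pattern_mix) - 1) < 1e-8,
            all(names(pattern_mix) %in% FLANK_PATTERNS),
            gap_range[1] > 0, gap_range[2] <= min(5000, window),
            gap_range[2] >= gap_range[1])
  structure(as.list(environment()), class = "genome_sim_config")
}

#' Generate synthetic genome annotations with planted circularization truth
#'
#' Each exon's flank pattern is drawn from `pattern_mix` and realized as
#' concrete Alu coordinates (one qualifying Alu per occupied side; strands
#' arranged to produce exactly the drawn pattern). The circularization
#' label is Bernoulli with log odds `beta0 + beta1 [pattern == IR]`;
#' circularizing exons receive a single-exon circRNA record. Exons sit in
#' well-separated slots so flanking assignments never leak between
#' neighbours. Deterministic given the config seed.
#'
#' @param cfg a [genome_sim_config()].
#' @return list: `exons`, `alus`, `circs` (BED-style data.frames) and
#'   `truth` (exon, pattern, circularizing).
#' @export
gen_genome_annotations <- function(cfg) {
  stopifnot(inherits(cfg, "genome_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_exons
  slot <- 2 * (cfg$window + cfg$gap_range[2] +
                 (cfg$alu_length_mean + 6 * cfg$alu_length_sd)) +
    cfg$exon_length_range[2] + 2000
  base <- (seq_len(n) - 1) * slot
  offset <- cfg$window + cfg$gap_range[2] +
    cfg$alu_length_mean + 6 * cfg$alu_length_sd + 500
  exon_len <- sample(seq(cfg$exon_length_range[1], cfg$exon_length_range[2]),
                     n, replace = TRUE)
  exon_start <- base + offset
  exon_end <- exon_start + exon_len
  exon_strand <- sample(c("+", "-"), n, replace = TRUE)
  pattern <- sample(names(cfg$pattern_mix), n, replace = TRUE,
                    prob = cfg$pattern_mix)

  has_up <- pattern %in% c("IR", "FIVE_PRIME_ONLY", "OTHER")
  has_down <- pattern %in% c("IR", "THREE_PRIME_ONLY", "OTHER")
  up_strand <- sample(c("+", "-"), n, replace = TRUE)
  down_strand <- ifelse(pattern == "IR",
                        ifelse(up_strand == "+", "-", "+"),
                        ifelse(pattern == "OTHER", up_strand,
                               sample(c("+", "-"), n, replace = TRUE)))
  # transcript-orientation sides -> genomic left/right
  minus <- exon_strand == "-"
  left_needed <- ifelse(minus, has_down, has_up)
  right_needed <- ifelse(minus, has_up, has_down)
  left_strand <- ifelse(minus, down_strand, up_strand)
  right_strand <- ifelse(minus, up_strand, down_strand)

  draw_len <- function(k) pmax(round(stats::rnorm(k, cfg$alu_length_mean,
                                                  cfg$alu_length_sd)),
                               cfg$min_full_length)
  draw_gap <- function(k) round(stats::runif(k, cfg$gap_range[1],
                                             cfg$gap_range[2]))
  fam <- c("AluSz", "AluSq2", "AluY", "AluSx", "AluJb")

  li <- which(left_needed)
  l_len <- draw_len(length(li)); l_gap <- draw_gap(length(li))
  l_end <- exon_start[li] - l_gap
  alus_l <- data.frame(chrom = "chrS", start = l_end - l_len, end = l_end,
                       strand = left_strand[li],
                       name = sample(fam, length(li), replace = TRUE))
  ri <- which(right_needed)
  r_len <- draw_len(length(ri)); r_gap <- draw_gap(length(ri))
  r_start <- exon_end[ri] + r_gap
  alus_r <- data.frame(chrom = "chrS", start = r_start, end = r_start + r_len,
                       strand = right_strand[ri],
                       name = sample(fam, length(ri), replace = TRUE))
  alus <- rbind(alus_l, alus_r)

  # short decoy Alus: below the full-length threshold, so they must not
  # change any pattern
  if (cfg$short_alu_prob > 0 && cfg$min_full_length > 60) {
    di <- which(stats::runif(n) < cfg$short_alu_prob)
    if (length(di)) {
      d_len <- sample(seq(50, cfg$min_full_length - 1), length(di),
                      replace = TRUE)
      d_gap <- draw_gap(length(di))
      d_side <- sample(c(-1, 1), length(di), replace = TRUE)
      d_start <- ifelse(d_side < 0, exon_start[di] - d_gap - d_len,
                        exon_end[di] + d_gap)
      alus <- rbind(alus, data.frame(
        chrom = "chrS", start = d_start, end = d_start + d_len,
        strand = sample(c("+", "-"), length(di), replace = TRUE),
        name = sample(fam, length(di), replace = TRUE)))
    }
  }
  alus <- alus[order(alus$start), ]
  alus$length <- alus$end - alus$start
  rownames(alus) <- NULL

  p_circ <- stats::plogis(cfg$beta0 + cfg$beta1 * (pattern == "IR"))
  circ_label <- stats::runif(n) < p_circ
  exons <- data.frame(chrom = "chrS", start = exon_start, end = exon_end,
                      name = sprintf("exon%05d", seq_len(n)), score = 0,
                      strand = exon_strand, stringsAsFactors = FALSE)
  ci <- which(circ_label)
  circs <- data.frame(chrom = "chrS", start = exon_start[ci],
                      end = exon_end[ci],
                      name = sprintf("circ%05d", seq_along(ci)), score = 0,
                      strand = exon_strand[ci], block_count = 1L,
                      stringsAsFactors = FALSE)
  mi <- sample(n, round(cfg$multiblock_frac * n))
  if (length(mi))
    circs <- rbind(circs, data.frame(
      chrom = "chrS", start = exon_start[mi], end = exon_end[mi] + 5000,
      name = sprintf("mbcirc%05d", seq_along(mi)), score = 0,
      strand = exon_strand[mi], block_count = 2L, stringsAsFactors = FALSE))
  truth <- data.frame(exon = exons$name, pattern = pattern,
                      circularizing = circ_label, stringsAsFactors = FALSE)
  list(exons = exons, alus = alus, circs = circs, truth = truth)
}

#' Write synthetic genome annotations as BED/BED12 files
#'
#' @param sim output of [gen_genome_annotations()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_genome_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_ex <- file.path(dir, "exons.bed")
  f_alu <- file.path(dir, "alus.bed")
  f_circ <- file.path(dir, "circs.bed12")
  f_truth <- file.path(dir, "truth.tsv")
  bed6 <- function(d) data.frame(d$chrom, d$start, d$end, d$name,
                                 if (is.null(d$score)) 0 else d$score, d$strand)
  utils::write.table(bed6(sim$exons), f_ex, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  a <- sim$alus
  utils::write.table(data.frame(a$chrom, a$start, a$end, a$name, 0, a$strand),
                     f_alu, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  cc <- sim$circs
  sizes <- cc$end - cc$start
  b12 <- data.frame(cc$chrom, cc$start, cc$end, cc$name, cc$score, cc$strand,
                    cc$start, cc$end, "0", cc$block_count,
                    paste0(sizes, ","), "0,")
  utils::write.table(b12, f_circ, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth, f_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(exons = f_ex, alus = f_alu, circs = f_circ, truth = f_truth)
}

#' Simulate mutation-rate profiles over a known structure
#'
#' Each position gets one latent modified mutation rate, exponential with
#' a low mean at paired positions and a higher mean at unpaired positions;
#' every replicate observes that shared latent rate under multiplicative
#' lognormal replicate noise plus exponential background (truncated to
#' \[0, 1\]). Untreated rates are independent exponential background. DMS
#' chemistry plants signal only at A/C (G/U positions carry background in
#' both channels). Depths are constant.
#'
#' @param structure a `secondary_structure` providing sequence and
#'   paired/unpaired truth.
#' @param chemistry `"SHAPE"` or `"DMS"`.
#' @param paired_mean,unpaired_mean mean modified mutation rate at
#'   paired/unpaired positions.
#' @param untreated_mean mean background mutation rate.
#' @param replicate_noise_sd sdlog of the per-replicate lognormal factor
#'   on the latent rate (0 = replicates differ only in background).
#' @param depth constant read depth.
#' @param n_replicates number of replicate profiles sharing the latent
#'   rates.
#' @param seed integer seed.
#' @return list of `mutation_rate_profile`s (length `n_replicates`).
#' @export
gen_reactivity_profiles <- function(structure, chemistry = c("SHAPE", "DMS"),
                                    paired_mean = 0.005, unpaired_mean = 0.05,
                                    untreated_mean = 0.001,
                                    replicate_noise_sd = 0.1, depth = 10000,
                                    n_replicates = 1, seed = 1) {
  chemistry <- match.arg(chemistry)
  stopifnot(paired_mean > 0, unpaired_mean > 0)
  set.seed(seed)
  n <- length(structure$sequence)
  paired <- !is.na(structure$pair_of)
  means <- ifelse(paired, paired_mean, unpaired_mean)
  if (chemistry == "DMS")
    means[!toupper(structure$sequence) %in% c("A", "C")] <- untreated_mean
  latent <- stats::rexp(n, 1 / means)
  lapply(seq_len(n_replicates), function(r) {
    noise <- if (replicate_noise_sd > 0)
      stats::rlnorm(n, 0, replicate_noise_sd) else 1
    mutation_rate_profile(
      sequence = structure$sequence,
      rate_modified = pmin(latent * noise +
                             stats::rexp(n, 1 / untreated_mean), 1),
      rate_untreated = pmin(stats::rexp(n, 1 / untreated_mean), 1),
      depth_modified = rep(depth, n),
      depth_untreated = rep(depth, n))
  })
}

#' Configuration for the JuMP simulator
#'
#' @param construct_length construct length (nt).
#' @param contacts data.frame of planted (i, j) crosslink pairs (0-based,
#'   i < j).
#' @param contact_rate per-read deletion probability at a planted contact.
#' @param background_rate per-read probability at background pairs.
#' @param depth informative reads per event site.
#' @param n_background number of random background pairs.
#' @param jitter crosslink position jitter (nt) applied to planted pairs.
#' @param seed integer seed.
#' @return list of class `jump_sim_config`.
#' @export
jump_sim_config <- function(construct_length = 3000, contacts,
                            contact_rate = 0.02, background_rate = 0.002,
                            depth = 5000, n_background = 200, jitter = 0,
                            seed = 1) {
  stopifnot(contact_rate >= 0, contact_rate <= 1,
            background_rate >= 0, background_rate <= 1,
            all(contacts$i < contacts$j),
            all(contacts$j <= construct_length))
  structure(as.list(environment()), class = "jump_sim_config")
}

#' Simulate treated/untreated JuMP datasets with planted contacts
#'
#' Treated counts are Binomial(depth, contact_rate) at each planted pair
#' (jittered by up to `jitter` nt) and Binomial(depth, background_rate) at
#' shared random background pairs; the untreated sample sees background
#' only. Deterministic given the config seed.
#'
#' @param cfg a [jump_sim_config()].
#' @return list: `treated`, `untreated` (`jump_dataset`s), `truth`
#'   (planted pairs as realized, post-jitter).
#' @export
gen_jump_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "jump_sim_config"))
  set.seed(cfg$seed)
  L <- cfg$construct_length
  ci <- cfg$contacts$i; cj <- cfg$contacts$j
  if (cfg$jitter > 0) {
    ci <- pmax(0, ci + sample(-cfg$jitter:cfg$jitter, length(ci), TRUE))
    cj <- pmin(L, cj + sample(-cfg$jitter:cfg$jitter, length(cj), TRUE))
  }
  # background pairs distinct from the planted ones
  bg_i <- bg_j <- numeric(0)
  while (length(bg_i) < cfg$n_background) {
    need <- cfg$n_background - length(bg_i)
    a <- sample.int(L, need, replace = TRUE) - 1L
    b <- sample.int(L, need, replace = TRUE) - 1L
    lo <- pmin(a, b); hi <- pmax(a, b)
    ok <- hi > lo & !(paste(lo, hi) %in% c(paste(ci, cj), paste(bg_i, bg_j)))
    lo <- lo[ok]; hi <- hi[ok]
    if (length(lo)) {
      d <- !duplicated(paste(lo, hi))
      bg_i <- c(bg_i, lo[d]); bg_j <- c(bg_j, hi[d])
    }
  }
  t_ev <- data.frame(
    start = c(ci, bg_i), stop = c(cj, bg_j),
    count = c(stats::rbinom(length(ci), cfg$depth, cfg$contact_rate),
              stats::rbinom(length(bg_i), cfg$depth, cfg$background_rate)),
    depth = cfg$depth)
  u_ev <- data.frame(
    start = bg_i, stop = bg_j,
    count = stats::rbinom(length(bg_i), cfg$depth, cfg$background_rate),
    depth = cfg$depth)
  list(treated = jump_dataset(t_ev[t_ev$count > 0, ], "sim", "treated"),
       untreated = jump_dataset(u_ev[u_ev$count > 0, ], "sim", "untreated"),
       truth = data.frame(i = ci, j = cj))
}

#' Simulate a replicate-summarized qPCR Ct table
#'
#' Ct values are generated so the analytic 2^(-dCt) ratio equals the
#' planted circularization ratio in expectation: reference Ct 20, pre-mRNA
#' Ct 24, circRNA Ct 24 - log2(ratio), each with Gaussian replicate noise.
#' A non-circularizing construct (ratio NA or 0) emits the circ target as
#' a no-amplification sentinel (NA Ct).
#'
#' @param true_ratios named numeric vector of planted efficiencies per
#'   construct (NA or 0 = does not circularize).
#' @param ct_noise_sd replicate Ct standard deviation (cycles).
#' @param n_replicates technical replicates per target.
#' @param seed integer seed.
#' @return data.frame in [read_qpcr_csv()] layout.
#' @export
gen_qpcr_table <- function(true_ratios, ct_noise_sd = 0.1, n_replicates = 3,
                           seed = 1) {
  set.seed(seed)
  rows <- lapply(names(true_ratios), function(cn) {
    r <- true_ratios[[cn]]
    mk <- function(target, mu) {
      if (is.na(mu))
        return(data.frame(construct = cn, target = target,
                          ct_mean = NA_real_, ct_sd = 0, n = n_replicates))
      reps <- stats::rnorm(n_replicates, mu, ct_noise_sd)
      data.frame(construct = cn, target = target, ct_mean = mean(reps),
                 ct_sd = stats::sd(reps), n = n_replicates)
    }
    circ_mu <- if (is.na(r) || r <= 0) NA_real_ else 24 - log2(r)
    rbind(mk("reference", 20), mk("pre_mrna", 24), mk("circ", circ_mu))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a random pseudoknot-free secondary structure
#'
#' A left-to-right stack process opens, closes, or skips at each position;
#' openings are only allowed while enough positions remain to close every
#' open bracket. Used for structure-metric and round-trip property
#' testing.
#'
#' @param n sequence length.
#' @param p_open,p_close move probabilities.
#' @param seed integer seed (NULL leaves the RNG state alone).
#' @return a `secondary_structure` with a random ACGU sequence.
#' @export
gen_random_structure <- function(n, p_open = 0.35, p_close = 0.35,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pair_of <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    remaining <- n - i  # positions after i
    can_open <- remaining > length(stack)
    u <- stats::runif(1)
    if (length(stack) && (u < p_close || remaining < length(stack) + 1)) {
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      pair_of[i] <- j - 1L; pair_of[j] <- i - 1L
    } else if (can_open && u < p_close + p_open) {
      stack <- c(stack, i)
    }
  }
  while (length(stack)) stack <- stack[-length(stack)]  # leave unpaired
  secondary_structure(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                      pair_of)
}
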