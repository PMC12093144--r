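mk_classified <- function(counts) {
  # counts: named list pattern -> c(circ, noncirc)
  rows <- lapply(names(counts), function(p) {
    k <- counts[[p]]
    data.frame(pattern = p,
               circularizing = rep(c(TRUE, FALSE), times = k))
  })
  do.call(rbind, rows)
}

test_that("contingency table counts exactly and ignores input order", {
  cl <- mk_classified(list(IR = c(3, 1), NONE = c(0, 2)))
  tab <- build_contingency(cl)
  expect_equal(tab$n_circ[tab$pattern == "IR"], 3L)
  expect_equal(tab$n_noncirc[tab$pattern == "IR"], 1L)
  expect_equal(tab$n_circ[tab$pattern == "NONE"], 0L)
  expect_equal(tab$n_noncirc[tab$pattern == "NONE"], 2L)
  # empty classes still get a (0, 0) row
  expect_true(all(FLANK_PATTERNS %in% tab$pattern))
  set.seed(1)
  tab2 <- build_contingency(cl[sample(nrow(cl)), ])
  expect_equal(tab2, tab)
  expect_equal(sum(tab$n_circ + tab$n_noncirc), nrow(cl))
})

test_that("log-odds difference matches closed-form arithmetic", {
  cl <- mk_classified(list(IR = c(15, 85), NONE = c(5, 95)))
  tab <- build_contingency(cl)
  expect_equal(log_odds_difference(tab, "IR", "NONE"),
               log((15 / 85) / (5 / 95)), tolerance = 1e-12)
  expect_equal(log_odds_difference(tab, "IR", "NONE"), 1.2098,
               tolerance = 1e-4)
  # identical rows -> 0
  cl2 <- mk_classified(list(IR = c(10, 40), NONE = c(10, 40)))
  expect_equal(log_odds_difference(build_contingency(cl2), "IR", "NONE"), 0)
})

test_that("log-odds difference is antisymmetric and scale-free", {
  cl <- mk_classified(list(IR = c(12, 30), NONE = c(7, 55)))
  tab <- build_contingency(cl)
  expect_equal(log_odds_difference(tab, "IR", "NONE"),
               -log_odds_difference(tab, "NONE", "IR"))
  tab2 <- tab
  tab2$n_circ <- tab2$n_circ * 2L
  tab2$n_noncirc <- tab2$n_noncirc * 2L
  expect_equal(log_odds_difference(tab2, "IR", "NONE"),
               log_odds_difference(tab, "IR", "NONE"))
})

test_that("zero cells trigger the Haldane-Anscombe correction, empty rows error", {
  cl <- mk_classified(list(IR = c(0, 10), NONE = c(5, 5)))
  tab <- build_contingency(cl)
  got <- log_odds_difference(tab, "IR", "NONE")
  expect_true(is.finite(got))
  expect_equal(got, log(0.5 / 10.5) - log(5.5 / 5.5), tolerance = 1e-12)
  expect_error(log_odds_difference(tab, "OTHER", "NONE"), "OTHER")
})

test_that("bootstrap is seed-deterministic with an ordered percentile CI", {
  set.seed(3)
  cl <- mk_classified(list(IR = c(40, 160), NONE = c(30, 370)))
  b1 <- bootstrap_log_odds(cl, "IR", "NONE", B = 300, seed = 11)
  b2 <- bootstrap_log_odds(cl, "IR", "NONE", B = 300, seed = 11)
  expect_identical(b1$bootstrap_samples, b2$bootstrap_samples)
  expect_length(b1$bootstrap_samples, 300)
  expect_true(all(is.finite(b1$bootstrap_samples)))
  expect_lte(b1$ci_low, b1$diff_vs_baseline)
  expect_gte(b1$ci_high, b1$diff_vs_baseline)
  b3 <- bootstrap_log_odds(cl, "IR", "NONE", B = 300, seed = 12)
  expect_false(identical(b1$bootstrap_samples, b3$bootstrap_samples))
  expect_error(bootstrap_log_odds(cl, "IR", "NONE", B = 300), "seed")
})

test_that("Mann-Whitney statistic and exact p match hand values", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 2 / 6, tolerance = 1e-12)
  # same multiset -> U = nm/2
  mw2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw2$U, 9 / 2)
  # degenerate data
  expect_warning(mw3 <- mann_whitney_u(c(2, 2), c(2, 2)), "identical")
  expect_equal(mw3$p, 1)
})

test_that("exact Mann-Whitney p equals brute-force enumeration with ties", {
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(2:4, 1); m <- sample(2:4, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, m, replace = TRUE)
    if (length(unique(c(x, y))) == 1) next
    expect_equal(mann_whitney_u(x, y, mode = "exact")$p, brute_mwu_p(x, y),
                 tolerance = 1e-12,
                 label = sprintf("x=%s y=%s", paste(x, collapse = ","),
                                 paste(y, collapse = ",")))
  }
})

test_that("normal approximation tracks the exact p and stats::wilcox.test", {
  set.seed(9)
  diffs <- replicate(20, {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    abs(mann_whitney_u(x, y, mode = "exact")$p -
          mann_whitney_u(x, y, mode = "normal_approx")$p)
  })
  expect_lt(max(diffs), 0.02)
  # independent cross-check of the exact route against R's implementation
  set.seed(10)
  for (rep in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    got <- mann_whitney_u(x, y, mode = "exact")
    expect_equal(got$U, sum(outer(x, y, ">")), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("downstream Alu lengths bypass the full-length filter and recover a planted shift", {
  # two exons, one circ, downstream Alus of known lengths incl. short ones
  exons <- genomic_intervals("chr1", c(1000, 50000), c(1500, 50500), "+")
  alus <- data.frame(chrom = "chr1",
                     start = c(2000, 2400, 51000),
                     end = c(2150, 2700, 51250),  # lengths 150, 300, 250
                     strand = "+", name = "Alu")
  lens <- downstream_alu_lengths(exons, alus,
                                 circularizing = c(TRUE, FALSE))
  expect_setequal(lens$circ, c(150, 300))   # 150 kept despite length rule
  expect_setequal(lens$noncirc, 250)
  # planted length shift of ~50 nt shows up in the medians
  set.seed(21)
  n <- 300
  starts <- seq(0, by = 20000, length.out = n)
  ex <- genomic_intervals("chr1", starts + 5000, starts + 5400, "+")
  circ <- rep(c(TRUE, FALSE), length.out = n)
  alen <- ifelse(circ, round(rnorm(n, 300, 20)), round(rnorm(n, 250, 20)))
  al <- data.frame(chrom = "chr1", start = starts + 5600,
                   end = starts + 5600 + alen, strand = "+", name = "Alu")
  got <- downstream_alu_lengths(ex, al, circularizing = circ)
  expect_equal(median(got$circ) - median(got$noncirc), 50, tolerance = 0.2)
})

test_that("enrichment table reports every pattern against the baseline", {
  set.seed(2)
  cl <- mk_classified(list(IR = c(40, 160), FIVE_PRIME_ONLY = c(12, 90),
                           THREE_PRIME_ONLY = c(9, 80), NONE = c(30, 370),
                           OTHER = c(5, 60)))
  et <- enrichment_table(cl, baseline = "NONE", B = 200, seed = 4)
  expect_equal(et$pattern, FLANK_PATTERNS)
  expect_equal(et$diff[et$pattern == "NONE"], 0)
  expect_true(all(et$ci_low <= et$diff & et$diff <= et$ci_high))
  ir <- et[et$pattern == "IR", ]
  expect_equal(ir$diff, log((40 / 160) / (30 / 370)), tolerance = 1e-12)
})
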