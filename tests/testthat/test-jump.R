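test_that("jump event reader maps fields, merges duplicates, validates counts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment line",
               "construct\tstart\tstop\tcount\tdepth",
               "wt\t10\t500\t45\t9000",
               "wt\t20\t600\t20\t9000",
               "wt\t20\t600\t25\t9000"), f)
  expect_warning(ds <- read_jump_events(f, "treated"), "duplicate")
  expect_s3_class(ds$events, "data.frame")
  expect_equal(nrow(ds$events), 2)
  merged <- ds$events[ds$events$start == 20, ]
  expect_equal(merged$count, 45)
  expect_equal(merged$depth, 18000)
  one <- ds$events[ds$events$start == 10, ]
  expect_equal(unlist(one), c(start = 10, stop = 500, count = 45, depth = 9000))

  writeLines(c("construct\tstart\tstop\tcount\tdepth",
               "wt\t10\t500\t50\t40"), f)
  expect_error(read_jump_events(f), "count exceeds depth")
  writeLines(c("construct\tstart\tstop\tcount\tdepth",
               "wt\t500\t10\t5\t40"), f)
  expect_error(read_jump_events(f), "stop > start")
})

test_that("frequencies divide count by depth and drop low-count events first", {
  ds <- jump_dataset(data.frame(start = c(0, 10, 20), stop = c(100, 110, 120),
                                count = c(50, 19, 20), depth = c(1000, 30, 30)),
                     "wt", "treated")
  fr <- jump_frequencies(ds, min_count = 20)
  expect_equal(nrow(fr$events), 2)       # count 19 omitted, count 20 kept
  expect_false(10 %in% fr$events$start)
  expect_equal(fr$events$frequency[fr$events$start == 0], 0.05)
  expect_equal(fr$events$frequency[fr$events$start == 20], 20 / 30)
  # filter-before-subtract is observable: a 19-count treated event never
  # reaches the output even with no untreated partner
  un <- jump_frequencies(jump_dataset(
    data.frame(start = 0, stop = 100, count = 30, depth = 3000),
    "wt", "untreated"))
  sub <- subtract_untreated(fr, un)
  expect_false(10 %in% sub$start)
})

test_that("background subtraction matches exactly and defaults missing partners to 0", {
  tr <- jump_frequencies(jump_dataset(
    data.frame(start = c(0, 50), stop = c(100, 150),
               count = c(50, 40), depth = 1000), "wt", "treated"))
  un <- jump_frequencies(jump_dataset(
    data.frame(start = 0, stop = 100, count = 20, depth = 2000),
    "wt", "untreated"))
  sub <- subtract_untreated(tr, un)
  expect_equal(sub$delta_frequency[sub$start == 0], 0.05 - 0.01)
  expect_equal(sub$delta_frequency[sub$start == 50], 0.04)  # no partner
  # equal frequencies cancel; negatives survive in the data
  un2 <- jump_frequencies(jump_dataset(
    data.frame(start = c(0, 50), stop = c(100, 150),
               count = c(100, 100), depth = 1000), "wt", "untreated"))
  sub2 <- subtract_untreated(tr, un2)
  expect_equal(sub2$delta_frequency, c(-0.05, -0.06))
  other <- jump_frequencies(jump_dataset(
    data.frame(start = 0, stop = 100, count = 30, depth = 1000),
    "mut", "untreated"))
  expect_error(subtract_untreated(tr, other), "construct mismatch")
})

test_that("rank distribution sorts descending with deterministic tie-breaks", {
  ev <- data.frame(start = c(5, 1, 3, 2), stop = c(50, 40, 30, 20),
                   delta_frequency = c(0.01, 0.04, 0.02, 0.02))
  rk <- rank_distribution(ev)
  expect_equal(rk$delta_frequency, c(0.04, 0.02, 0.02, 0.01))
  expect_equal(rk$start, c(1, 2, 3, 5))  # tie at 0.02 broken by start
  expect_equal(rank_distribution(ev[0, ])$rank, integer(0))
  # negatives are clipped for ranking
  ev$delta_frequency[1] <- -0.5
  rk2 <- rank_distribution(ev)
  expect_equal(min(rk2$delta_frequency), 0)
})

test_that("lift-over agrees with the character-level alignment oracle and round-trips", {
  set.seed(23)
  for (rep in 1:25) {
    L <- sample(500:3000, 1)
    k <- sample(1:3, 1)
    bounds <- sort(sample(seq(0, L), 2 * k))
    spec <- deletion_spec(bounds[seq(1, 2 * k, 2)], bounds[seq(2, 2 * k, 2)],
                          wt_length = L)
    oracle <- alignment_liftover_oracle(spec, L)
    mut_len <- length(oracle)
    if (mut_len == 0) next
    pos <- 0:(mut_len - 1)
    wt <- lift_to_reference(pos, spec)
    expect_equal(wt, oracle, label = sprintf("rep %d", rep))
    expect_true(all(diff(wt) > 0))                 # strictly increasing
    expect_equal(reference_to_mutant(wt, spec), pos)  # round trip
  }
  # WT positions inside a deletion have no mutant image
  spec <- deletion_spec(100, 257, wt_length = 1000)
  expect_true(is.na(reference_to_mutant(150, spec)))
  expect_equal(lift_to_reference(99, spec), 99)    # identity upstream
  expect_equal(lift_to_reference(100, spec), 257)  # +157 at the cut
  expect_error(lift_to_reference(900, spec), "out of range")
})

test_that("deletion specs validate geometry and read from YAML", {
  expect_error(deletion_spec(c(10, 15), c(20, 25)), "disjoint")
  expect_error(deletion_spec(10, 10), "end > start")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("wt_length: 2926", "deletions:", "  - [1500, 1657]"), f)
  sp <- read_deletion_spec_yaml(f)
  expect_equal(sp$wt_start, 1500)
  expect_equal(sp$wt_end, 1657)
  expect_equal(attr(sp, "wt_length"), 2926)
  # gap-run extraction from sequences reconstructs the mutant (deletion
  # boundaries are only defined up to runs of identical bases, so the
  # check is reconstruction, not interval identity)
  wt_seq <- paste(sample(c("A", "C", "G", "U"), 60, TRUE), collapse = "")
  spec2 <- deletion_spec(c(10, 40), c(20, 45), wt_length = 60)
  keep <- alignment_liftover_oracle(spec2, 60) + 1
  mut_seq <- paste(strsplit(wt_seq, "")[[1]][keep], collapse = "")
  inferred <- deletion_spec_from_sequences(wt_seq, mut_seq)
  keep2 <- alignment_liftover_oracle(inferred, 60) + 1
  expect_equal(paste(strsplit(wt_seq, "")[[1]][keep2], collapse = ""), mut_seq)
  expect_equal(sum(inferred$wt_end - inferred$wt_start), 15)
})

test_that("density matrix conserves clipped mass in midpoint/separation bins", {
  ev <- data.frame(start = c(100, 103, 500), stop = c(900, 905, 520),
                   delta_frequency = c(0.04, 0.02, -0.01))
  m <- jump_density(ev, bin = 10, length = 1000)
  expect_equal(sum(m), 0.06)  # negative clipped to zero
  # single event lands in one cell: midpoint 500 -> bin 51, sep 800 -> bin 81
  m1 <- jump_density(ev[1, ], bin = 10, length = 1000)
  expect_equal(m1[81, 51], 0.04)
  expect_equal(sum(m1 > 0), 1)
  # events 3 nt apart share a cell at bin 10
  m2 <- jump_density(ev[1:2, ], bin = 10, length = 1000)
  expect_equal(sum(m2 > 0), 1)
  expect_equal(m2[81, 51], 0.06)
  expect_error(jump_density(data.frame(start = 1, stop = 2000,
                                       delta_frequency = 1),
                            bin = 10, length = 1000), "exceed")
})

test_that("replicate combination sums counts before frequencies by default", {
  r1 <- jump_dataset(data.frame(start = 0, stop = 100, count = 15, depth = 1000),
                     "wt", "treated")
  r2 <- jump_dataset(data.frame(start = c(0, 5), stop = c(100, 200),
                                count = c(10, 30), depth = 1000),
                     "wt", "treated")
  comb <- suppressWarnings(combine_jump_replicates(r1, r2))
  ev <- comb$events[comb$events$start == 0, ]
  expect_equal(ev$count, 25)
  expect_equal(ev$depth, 2000)
  # a 15+10 event passes the count filter only after summation
  expect_equal(nrow(jump_frequencies(comb)$events), 2)
  avg <- suppressWarnings(combine_jump_replicates(r1, r2, mode = "average"))
  expect_equal(avg$events$frequency[avg$events$start == 0],
               mean(c(15 / 1000, 10 / 1000)))
  expect_equal(avg$events$frequency[avg$events$start == 5],
               mean(c(0, 30 / 1000)))
})
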