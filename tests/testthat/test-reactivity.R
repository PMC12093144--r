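mk_profile <- function(seq, mod, unt, dm = 5000, du = 5000) {
  n <- nchar(seq)
  mutation_rate_profile(seq, rep_len(mod, n), rep_len(unt, n),
                        rep_len(dm, n), rep_len(du, n))
}

test_that("raw reactivity is the treated-untreated rate difference with depth masking", {
  p <- mk_profile("ACGU", 0.05, 0.01)
  r <- compute_raw_reactivity(p, min_depth = 1000)
  expect_equal(r$reactivity, rep(0.04, 4), tolerance = 1e-12)
  # low depth invalidates a position
  p2 <- mutation_rate_profile("ACGU", rep(0.05, 4), rep(0.01, 4),
                              c(0, 5000, 5000, 5000), rep(5000, 4))
  r2 <- compute_raw_reactivity(p2, min_depth = 1000)
  expect_false(r2$valid[1])
  expect_true(all(r2$valid[2:4]))
  # negatives are retained pre-normalization
  p3 <- mk_profile("ACGU", 0.01, 0.05)
  expect_equal(compute_raw_reactivity(p3)$reactivity, rep(-0.04, 4))
  expect_error(mutation_rate_profile("ACGU", rep(0.5, 3), rep(0, 4),
                                     rep(1, 4), rep(1, 4)), "length")
})

test_that("normalization floors at -0.1 and self-normalizes flat profiles", {
  set.seed(14)
  n <- 200
  seqs <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
  vals <- rexp(n, 10)
  vals[5] <- -0.5
  prof <- reactivity_profile(seqs, vals)
  norm <- normalize_per_nucleotide(prof)
  expect_gte(min(norm$reactivity[norm$valid]), -0.1)
  expect_equal(norm$reactivity[5], -0.1)
  # all-equal positive values for every type -> all become 1
  flat <- reactivity_profile(seqs, rep(2.5, n))
  expect_equal(normalize_per_nucleotide(flat)$reactivity, rep(1, n))
})

test_that("per-type top-decile mean is 1 after boxplot normalization", {
  set.seed(15)
  n <- 400
  base <- sample(c("A", "C", "G", "U"), n, TRUE)
  prof <- reactivity_profile(base, rexp(n, 2))
  norm <- normalize_per_nucleotide(prof)
  for (nt in c("A", "C", "G", "U")) {
    v <- norm$reactivity[base == nt & norm$valid]
    q <- quantile(v, c(0.25, 0.75), names = FALSE)
    kept <- v[v <= q[2] + 1.5 * (q[2] - q[1])]
    top <- sort(kept, decreasing = TRUE)[seq_len(ceiling(length(kept) * 0.1))]
    expect_equal(mean(top), 1, tolerance = 1e-9)
  }
})

test_that("normalization is equivariant to per-type rescaling", {
  set.seed(16)
  n <- 300
  base <- sample(c("A", "C", "G", "U"), n, TRUE)
  vals <- rexp(n, 3)
  p1 <- normalize_per_nucleotide(reactivity_profile(base, vals))
  vals2 <- ifelse(base == "C", vals * 7, vals)
  p2 <- normalize_per_nucleotide(reactivity_profile(base, vals2))
  expect_equal(p2$reactivity, p1$reactivity, tolerance = 1e-12)
})

test_that("types with too few defined values are left unscaled with a warning", {
  base <- c(rep("A", 30), rep("C", 5))
  vals <- c(rexp(30, 1), rep(4, 5))
  expect_warning(norm <- normalize_per_nucleotide(
    reactivity_profile(paste(base, collapse = ""), vals)), "C")
  expect_equal(norm$reactivity[31:35], rep(4, 5))  # untouched
})

test_that("DMS mask keeps only A/C and is idempotent", {
  prof <- reactivity_profile("GACU", c(0.5, 0.6, 0.7, 0.8), chemistry = "DMS")
  m1 <- apply_dms_mask(prof)
  expect_equal(m1$valid, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(m1$reactivity[2:3], c(0.6, 0.7))
  m2 <- apply_dms_mask(m1)
  expect_identical(m2$valid, m1$valid)
  expect_identical(m2$reactivity, m1$reactivity)
  # lowercase (pre-masked) and all-G sequences give no defined positions
  allg <- apply_dms_mask(reactivity_profile("GGGG", rep(1, 4), chemistry = "DMS"))
  expect_equal(sum(allg$valid), 0)
  expect_error(apply_dms_mask(reactivity_profile("GACU", rep(1, 4))), "DMS")
})

test_that("region median uses valid positions only and flags empty regions", {
  prof <- reactivity_profile("AAAAA", c(0.1, 0.2, 0.9, NA, 0.5))
  expect_equal(region_median(prof, region("r", 0, 3)), 0.2)
  expect_equal(region_median(prof, region("one", 4, 5)), 0.5)
  expect_warning(got <- region_median(prof, region("gap", 3, 4)), "no valid")
  expect_true(is.na(got))
  expect_error(region_median(prof, region("oob", 2, 9)), "outside")
})

test_that("replicate correlation hits the closed-form attenuation target", {
  set.seed(18)
  n <- 1000
  x <- rexp(n, 1)
  # additive noise with var chosen for theoretical r = sqrt(1/(1+k)) pattern:
  # r = sd(x)/sqrt(sd(x)^2 + sigma^2) -> sigma for r = 0.8
  sigma <- sd(x) * sqrt(1 / 0.8^2 - 1)
  y <- x + rnorm(n, 0, sigma)
  p1 <- reactivity_profile(strrep("A", n), x)
  p2 <- reactivity_profile(strrep("A", n), y)
  expect_equal(replicate_correlation(p1, p2), 0.8, tolerance = 0.0625)
  expect_equal(replicate_correlation(p1, p1), 1)
  p3 <- reactivity_profile(strrep("A", n), -(x - mean(x)) + mean(x))
  expect_equal(replicate_correlation(p1, p3), -1)
  expect_error(replicate_correlation(p1, reactivity_profile(strrep("C", n), x)),
               "same sequence")
  few <- reactivity_profile("AAAA", c(1, 2, NA, NA))
  expect_error(replicate_correlation(few, few), "fewer than 3")
})

test_that("delta-SHAPE flags a planted bump and nothing on identical profiles", {
  set.seed(19)
  n <- 120
  base <- strrep("A", n)
  x <- rexp(n, 4)
  p1 <- reactivity_profile(base, x)
  d0 <- delta_shape(p1, p1)
  expect_equal(sum(d0$significant), 0)
  # +2.0 bump over 5 consecutive nt
  y <- x
  y[61:65] <- y[61:65] + 2
  p2 <- reactivity_profile(base, y)
  d <- delta_shape(p2, p1, window = 3)
  hits <- d$position[d$significant]
  expect_true(all(hits >= 59 & hits <= 65))   # bump +/- half window
  expect_true(all(61:63 %in% hits))           # fully-inside windows flagged
  # invalid positions poison their windows
  y[30] <- NA
  p3 <- reactivity_profile(base, y)
  d3 <- delta_shape(p3, p1, window = 3)
  expect_true(all(is.na(d3$diff[30:31 + 0])))
  expect_error(delta_shape(p1, p1, window = 999), "window")
})

test_that("profile TSV reader round-trips through the writer dialects", {
  set.seed(20)
  st <- gen_random_structure(60, seed = 20)
  prof <- gen_reactivity_profiles(st, "SHAPE", seed = 20)[[1]]
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(Nucleotide = seq_along(prof$sequence),
               Sequence = prof$sequence,
               Modified_rate = prof$rate_modified,
               Untreated_rate = prof$rate_untreated,
               Modified_effective_depth = prof$depth_modified,
               Untreated_effective_depth = prof$depth_untreated,
               Extra = 1),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_shapemapper_profile(f)
  expect_equal(back$rate_modified, prof$rate_modified, tolerance = 1e-9)
  expect_equal(back$sequence, prof$sequence)
  r <- compute_raw_reactivity(back)
  fs <- withr::local_tempfile(fileext = ".shape")
  write_shape_file(r, fs, "shape")
  sh <- utils::read.table(fs)
  expect_equal(nrow(sh), 60)
  expect_equal(sh$V2[r$valid], r$reactivity[r$valid], tolerance = 1e-6)
  expect_true(all(sh$V2[!r$valid] == -999))
})
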