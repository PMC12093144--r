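# Chemical-probing reactivity processing: raw mutation-rate differences,
# per-nucleotide-type boxplot normalization with the -0.1 floor, DMS A/C
# masking, regional medians, replicate correlation, and windowed profile
# differences (delta-SHAPE style).
#
# Undefined values are carried as explicit invalid positions (NA + mask),
# never as zeros.

#' Build a reactivity profile object
#'
#' @param sequence RNA sequence (single string or character vector of
#'   bases; case preserved -- lowercase marks pre-masked positions for DMS).
#' @param reactivity per-nucleotide numeric values (NA where undefined).
#' @param valid logical mask; defaults to `!is.na(reactivity)`.
#' @param chemistry `"SHAPE"` (all four nucleotides) or `"DMS"` (A/C only
#'   after masking).
#' @return object of class `reactivity_profile`.
#' @export
reactivity_profile <- function(sequence, reactivity, valid = NULL,
                               chemistry = c("SHAPE", "DMS")) {
  chemistry <- match.arg(chemistry)
  seqv <- .as_base_vector(sequence)
  n <- length(seqv)
  if (length(reactivity) != n)
    stop("reactivity length does not match sequence length")
  if (is.null(valid)) valid <- !is.na(reactivity)
  if (length(valid) != n) stop("valid mask length mismatch")
  reactivity[!valid] <- NA_real_
  structure(list(sequence = seqv, reactivity = as.numeric(reactivity),
                 valid = as.logical(valid) & !is.na(reactivity),
                 chemistry = chemistry),
            class = "reactivity_profile")
}

.as_base_vector <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    strsplit(sequence, "")[[1]] else as.character(sequence)
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat(sprintf("<reactivity_profile> %s, %d nt, %d defined (%.1f%%)\n",
              x$chemistry, length(x$sequence), sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' Read a ShapeMapper2-style per-nucleotide profile table
#'
#' Expects tab-separated columns `Nucleotide` (1-based position),
#' `Sequence`, `Modified_rate`, `Untreated_rate`,
#' `Modified_effective_depth`, `Untreated_effective_depth`; extra columns
#' are ignored.
#'
#' @param path profile TSV.
#' @return list (mutation-rate profile): sequence, rate_modified,
#'   rate_untreated, depth_modified, depth_untreated.
#' @export
read_shapemapper_profile <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("Nucleotide", "Sequence", "Modified_rate", "Untreated_rate",
            "Modified_effective_depth", "Untreated_effective_depth")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("profile is missing column(s): %s", paste(miss, collapse = ", ")))
  df <- df[order(df$Nucleotide), ]
  mutation_rate_profile(
    sequence = df$Sequence,
    rate_modified = df$Modified_rate,
    rate_untreated = df$Untreated_rate,
    depth_modified = df$Modified_effective_depth,
    depth_untreated = df$Untreated_effective_depth)
}

#' Assemble and validate a mutation-rate profile
#'
#' @param sequence bases (vector or single string).
#' @param rate_modified,rate_untreated per-nucleotide mutation fractions in
#'   \[0, 1\] (NA allowed).
#' @param depth_modified,depth_untreated per-nucleotide read depths.
#' @return list of class `mutation_rate_profile`.
#' @export
mutation_rate_profile <- function(sequence, rate_modified, rate_untreated,
                                  depth_modified, depth_untreated) {
  seqv <- .as_base_vector(sequence)
  n <- length(seqv)
  lens <- c(length(rate_modified), length(rate_untreated),
            length(depth_modified), length(depth_untreated))
  if (any(lens != n)) stop("all profile arrays must match the sequence length")
  for (r in list(rate_modified, rate_untreated))
    if (any(r < 0 | r > 1, na.rm = TRUE)) stop("mutation rates must lie in [0, 1]")
  if (any(depth_modified < 0, na.rm = TRUE) || any(depth_untreated < 0, na.rm = TRUE))
    stop("depths must be non-negative")
  structure(list(sequence = seqv,
                 rate_modified = as.numeric(rate_modified),
                 rate_untreated = as.numeric(rate_untreated),
                 depth_modified = as.numeric(depth_modified),
                 depth_untreated = as.numeric(depth_untreated)),
            class = "mutation_rate_profile")
}

#' Raw reactivity from treated/untreated mutation rates
#'
#' reactivity_i = modified rate - untreated rate. A position is invalid if
#' either depth falls below `min_depth` or either rate is missing.
#' Negative values are retained at this stage; the floor is applied during
#' normalization.
#'
#' @param profile a `mutation_rate_profile`.
#' @param min_depth minimum effective read depth in both samples.
#' @param chemistry passed to the resulting profile.
#' @return a `reactivity_profile`.
#' @export
compute_raw_reactivity <- function(profile, min_depth = 1000,
                                   chemistry = c("SHAPE", "DMS")) {
  chemistry <- match.arg(chemistry)
  stopifnot(inherits(profile, "mutation_rate_profile"))
  r <- profile$rate_modified - profile$rate_untreated
  ok <- !is.na(r) &
    !is.na(profile$depth_modified) & profile$depth_modified >= min_depth &
    !is.na(profile$depth_untreated) & profile$depth_untreated >= min_depth
  r[!ok] <- NA_real_
  reactivity_profile(profile$sequence, r, ok, chemistry)
}

#' Per-nucleotide-type boxplot normalization with a -0.1 floor
#'
#' For each nucleotide type (A, C, G, U) independently: values above
#' Q3 + 1.5 IQR are set aside as outliers, the remaining values' top decile
#' mean becomes the scaling factor, and every value of that type (outliers
#' included) is divided by it. Values below -0.1 are then set to -0.1;
#' treated-minus-untreated rates below zero carry no structural signal and
#' are functionally zero. Types with fewer than `min_defined` defined
#' values are left unscaled with a warning.
#'
#' @param profile a `reactivity_profile` of raw reactivities.
#' @param floor lower clamp applied after scaling.
#' @param min_defined minimum defined values per type to normalize it.
#' @return normalized `reactivity_profile`.
#' @export
normalize_per_nucleotide <- function(profile, floor = -0.1, min_defined = 20) {
  stopifnot(inherits(profile, "reactivity_profile"))
  vals <- profile$reactivity
  base <- toupper(profile$sequence)
  base[base == "T"] <- "U"
  for (nt in c("A", "C", "G", "U")) {
    sel <- which(base == nt & profile$valid)
    if (!length(sel)) next
    if (length(sel) < min_defined) {
      warning(sprintf("only %d defined %s values (< %d); type left unscaled",
                      length(sel), nt, min_defined))
      next
    }
    v <- vals[sel]
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    kept <- v[v <= q[2] + 1.5 * iqr]
    top <- sort(kept, decreasing = TRUE)[seq_len(max(1L, ceiling(length(kept) * 0.1)))]
    fac <- mean(top)
    if (!is.finite(fac) || fac <= 0)
      stop(sprintf("non-positive normalization factor for nucleotide %s", nt))
    vals[sel] <- v / fac
  }
  vals[profile$valid & vals < floor] <- floor
  reactivity_profile(profile$sequence, vals, profile$valid, profile$chemistry)
}

#' Mask non-A/C positions of a DMS profile
#'
#' DMS methylates accessible adenosine and cytidine; guanosine and uridine
#' (and any lowercase, i.e. pre-masked, position) are set invalid. A and C
#' are untouched. Idempotent.
#'
#' @param profile a `reactivity_profile` with chemistry `"DMS"`.
#' @return masked `reactivity_profile`.
#' @export
apply_dms_mask <- function(profile) {
  stopifnot(inherits(profile, "reactivity_profile"))
  if (profile$chemistry != "DMS")
    stop("apply_dms_mask expects a DMS-chemistry profile")
  keep <- profile$sequence %in% c("A", "C")
  r <- profile$reactivity
  r[!keep] <- NA_real_
  reactivity_profile(profile$sequence, r, profile$valid & keep, "DMS")
}

#' Define a named region on a construct
#'
#' @param name region label (e.g. an Alu element or the exon).
#' @param start,end 0-based half-open positions.
#' @return one-row data.frame (name, start, end).
#' @export
region <- function(name, start, end) {
  stopifnot(start >= 0, end > start)
  data.frame(name = as.character(name), start = as.numeric(start),
             end = as.numeric(end), stringsAsFactors = FALSE)
}

#' Read a YAML region file
#'
#' Expects a mapping of region name to `[start, end]` (0-based half-open)
#' or a list of `{name, start, end}` entries.
#'
#' @param path YAML file.
#' @return data.frame of regions.
#' @export
read_regions_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- lapply(seq_along(y), function(i) {
    el <- y[[i]]
    if (is.list(el) && !is.null(el$name))
      region(el$name, el$start, el$end)
    else
      region(names(y)[i], el[[1]], el[[2]])
  })
  do.call(rbind, rows)
}

.region_index <- function(reg, n) {
  if (reg$start < 0 || reg$end > n || reg$end <= reg$start)
    stop(sprintf("region '%s' [%g, %g) outside profile of length %d",
                 reg$name, reg$start, reg$end, n))
  seq.int(reg$start + 1, reg$end)
}

#' Median reactivity over a region
#'
#' Median over valid positions only (for DMS profiles these are A/C by
#' construction).
#'
#' @param profile a `reactivity_profile`.
#' @param reg one-row region data.frame.
#' @return median reactivity, or NA (with a warning) when no position in
#'   the region is valid.
#' @export
region_median <- function(profile, reg) {
  idx <- .region_index(reg, length(profile$sequence))
  v <- profile$reactivity[idx][profile$valid[idx]]
  if (!length(v)) {
    warning(sprintf("region '%s' has no valid positions; median undefined",
                    reg$name))
    return(NA_real_)
  }
  stats::median(v)
}

#' Pearson correlation between replicate profiles over selected regions
#'
#' Restricted to positions valid in both profiles within the union of the
#' supplied regions.
#'
#' @param p1,p2 `reactivity_profile`s over the same sequence.
#' @param regions data.frame of regions; `NULL` uses the whole molecule.
#' @return Pearson r.
#' @export
replicate_correlation <- function(p1, p2, regions = NULL) {
  n <- length(p1$sequence)
  if (length(p2$sequence) != n || !all(p1$sequence == p2$sequence))
    stop("profiles are not over the same sequence")
  sel <- rep(FALSE, n)
  if (is.null(regions)) sel[] <- TRUE else
    for (i in seq_len(nrow(regions)))
      sel[.region_index(regions[i, ], n)] <- TRUE
  use <- sel & p1$valid & p2$valid
  if (sum(use) < 3)
    stop("fewer than 3 positions valid in both profiles over the regions")
  stats::cor(p1$reactivity[use], p2$reactivity[use], method = "pearson")
}

#' Windowed reactivity difference with significance calls (delta-SHAPE)
#'
#' Each profile is smoothed with a centered window mean; the per-nucleotide
#' difference d_i = smooth(p1)_i - smooth(p2)_i is standardized
#' (s_i = (d_i - mean d)/sd d) and screened by a Z-factor
#' z_i = 1 - 1.96 (se1_i + se2_i)/|d_i| built from windowed standard
#' errors. A site is significant when z_i > `z_threshold` and
#' |s_i| >= `s_threshold`. Windows containing invalid positions yield
#' undefined differences.
#'
#' @param p1,p2 `reactivity_profile`s over the same sequence.
#' @param window odd window width in nucleotides.
#' @param z_threshold,s_threshold significance cutoffs.
#' @return data.frame: position (0-based), diff, z, s, significant.
#' @export
delta_shape <- function(p1, p2, window = 3, z_threshold = 0, s_threshold = 1) {
  n <- length(p1$sequence)
  if (length(p2$sequence) != n || !all(p1$sequence == p2$sequence))
    stop("profiles are not over the same sequence")
  if (window > n) stop("window larger than the sequence")
  if (window %% 2 == 0) stop("window must be odd")
  sm <- function(p) {
    m <- se <- rep(NA_real_, n)
    h <- (window - 1) / 2
    x <- ifelse(p$valid, p$reactivity, NA_real_)
    for (i in seq_len(n)) {
      lo <- i - h; hi <- i + h
      if (lo < 1 || hi > n) next
      w <- x[lo:hi]
      if (anyNA(w)) next
      m[i] <- mean(w)
      se[i] <- stats::sd(w) / sqrt(window)
    }
    list(m = m, se = se)
  }
  a <- sm(p1); b <- sm(p2)
  d <- a$m - b$m
  mu <- mean(d, na.rm = TRUE); sdd <- stats::sd(d, na.rm = TRUE)
  s <- if (is.na(sdd) || sdd == 0) rep(0, n) else (d - mu) / sdd
  z <- 1 - 1.96 * (a$se + b$se) / abs(d)
  z[is.na(d) | d == 0] <- -Inf
  sig <- !is.na(d) & z > z_threshold & abs(s) >= s_threshold
  data.frame(position = seq_len(n) - 1L, diff = d, z = z, s = s,
             significant = sig)
}

#' Write reactivities in .shape / .map dialects for folding tools
#'
#' The 2-column `.shape` dialect writes `position reactivity` with -999 for
#' undefined positions (1-based positions); the 4-column `.map` dialect
#' adds a standard-error column (0 here) and the base.
#'
#' @param profile a `reactivity_profile`.
#' @param path output file.
#' @param dialect `"shape"` or `"map"`.
#' @export
write_shape_file <- function(profile, path, dialect = c("shape", "map")) {
  dialect <- match.arg(dialect)
  n <- length(profile$sequence)
  val <- ifelse(profile$valid, profile$reactivity, -999)
  if (dialect == "shape") {
    utils::write.table(data.frame(seq_len(n), val), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(data.frame(seq_len(n), val, 0, profile$sequence), path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Write a normalized reactivity TSV
#'
#' @param profile a `reactivity_profile`.
#' @param path output file.
#' @export
write_reactivity_tsv <- function(profile, path) {
  n <- length(profile$sequence)
  utils::write.table(
    data.frame(position = seq_len(n) - 1L, base = profile$sequence,
               reactivity = profile$reactivity, valid = profile$valid),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
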