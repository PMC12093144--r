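# Genomic interval model and strand-aware classification of exons by the
# pattern of flanking Alu elements and their circularization status.
#
# Coordinates are 0-based half-open throughout (native BED); readers for
# 1-based formats (RepeatMasker .out) convert at the boundary.

#' Flanking-Alu pattern levels
#'
#' The five mutually exclusive categories an exon can fall into based on
#' qualifying Alu elements on its 5' and 3' sides (transcript orientation):
#' \describe{
#'   \item{IR}{at least one upstream/downstream Alu pair on opposite genomic
#'     strands (an inverted repeat able to base-pair in the transcript)}
#'   \item{FIVE_PRIME_ONLY}{qualifying Alus upstream only}
#'   \item{THREE_PRIME_ONLY}{qualifying Alus downstream only}
#'   \item{NONE}{no qualifying Alu on either side}
#'   \item{OTHER}{Alus on both sides but every upstream/downstream pair is
#'     same-strand (cannot form an inverted repeat)}
#' }
#' @export
FLANK_PATTERNS <- c("IR", "FIVE_PRIME_ONLY", "THREE_PRIME_ONLY", "NONE", "OTHER")

#' Construct a table of genomic intervals
#'
#' Validates and assembles 0-based half-open intervals.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, 0-based exclusive; must exceed `start`.
#' @param strand character vector in `+`, `-`, `.`.
#' @param name optional feature names.
#' @return data.frame with columns chrom, start, end, strand, name.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NA_character_) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  name <- rep_len(as.character(name), n)
  if (any(is.na(start)) || any(is.na(end)))
    stop("start/end must be numeric and non-missing")
  if (any(start < 0)) stop("start must be >= 0")
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("end <= start for interval(s): %s", paste(head(bad, 5), collapse = ", ")))
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, name = name, stringsAsFactors = FALSE)
}

#' Read a BED file (BED6 or BED12 dialect)
#'
#' BED coordinates are taken as-is (0-based half-open). For the bed12
#' dialect the block count (field 10) is returned as `block_count`, the
#' convention circRNA annotation files use to record the number of exons in
#' the circle.
#'
#' @param path path to a tab-separated BED file; `#` comment lines and track
#'   lines are skipped.
#' @param dialect `"bed6"` or `"bed12"`.
#' @return data.frame of intervals (chrom, start, end, name, score, strand,
#'   and block_count for bed12).
#' @export
read_bed <- function(path, dialect = c("bed6", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  need <- if (dialect == "bed6") 6L else 12L
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < need))
    stop(sprintf("malformed BED line %d: expected >= %d fields, found %d",
                 idx[which(nf < need)[1]], need, nf[which(nf < need)[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("malformed BED line %d: non-numeric coordinates",
                 idx[which(is.na(start) | is.na(end))[1]]))
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("invalid interval on line %d: end (%s) <= start (%s)",
                 idx[bad[1]], end[bad[1]], start[bad[1]]))
  out <- data.frame(
    chrom = chrom, start = start, end = end,
    name = vapply(fields, `[[`, "", 4L),
    score = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L))),
    strand = vapply(fields, `[[`, "", 6L),
    stringsAsFactors = FALSE)
  if (dialect == "bed12") {
    bc <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 10L)))
    if (anyNA(bc))
      stop(sprintf("malformed BED12 line %d: non-integer block count",
                   idx[which(is.na(bc))[1]]))
    if (any(bc < 1))
      stop(sprintf("invalid block count on line %d: %d", idx[which(bc < 1)[1]],
                   bc[which(bc < 1)[1]]))
    out$block_count <- bc
  }
  out
}

#' Read RepeatMasker .out annotations into Alu elements
#'
#' RepeatMasker query coordinates are 1-based inclusive; they are converted
#' to 0-based half-open here. Strand `C` (complement) becomes `-`. Rows are
#' optionally restricted to a repeat-name prefix (default `"Alu"`).
#'
#' @param path RepeatMasker .out file (3 header lines).
#' @param family_prefix keep repeats whose name starts with this prefix;
#'   `NULL` keeps everything.
#' @return data.frame of elements: chrom, start, end, strand, name, length.
#' @export
read_repeatmasker_out <- function(path, family_prefix = "Alu") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  chrom <- vapply(toks, `[[`, "", 5L)
  start1 <- as.numeric(vapply(toks, `[[`, "", 6L))
  end1 <- as.numeric(vapply(toks, `[[`, "", 7L))
  strand <- vapply(toks, `[[`, "", 9L)
  name <- vapply(toks, `[[`, "", 10L)
  strand <- ifelse(strand == "C", "-", strand)
  out <- data.frame(chrom = chrom, start = start1 - 1, end = end1,
                    strand = strand, name = name, stringsAsFactors = FALSE)
  if (!is.null(family_prefix))
    out <- out[startsWith(out$name, family_prefix), , drop = FALSE]
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out
}

.as_granges <- function(df, use_strand = FALSE) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = if (use_strand) df$strand else "*")
}

#' Mark exons that overlap a single-exon circRNA annotation
#'
#' circRNA records with `block_count != 1` are discarded first: only
#' annotations describing a single-exon circle identify which exon
#' circularizes. An exon is labelled circularizing when it shares at least
#' one base with any retained circRNA interval on the same chromosome.
#' Strand is ignored by default because circRNA-database and gene-annotation
#' strand conventions can disagree; set `strict_strand = TRUE` to require a
#' strand match.
#'
#' @param exons data.frame of exon intervals (chrom, start, end, strand).
#' @param circs data.frame of circRNA intervals with a `block_count` column
#'   (absent column is treated as all 1).
#' @param strict_strand require matching strand for an overlap to count.
#' @return logical vector along `exons`.
#' @export
mark_circularizing <- function(exons, circs, strict_strand = FALSE) {
  if (nrow(exons) == 0) return(logical(0))
  if (is.null(circs) || nrow(circs) == 0) return(rep(FALSE, nrow(exons)))
  bc <- if ("block_count" %in% names(circs)) circs$block_count else rep(1L, nrow(circs))
  circs <- circs[bc == 1L, , drop = FALSE]
  if (nrow(circs) == 0) return(rep(FALSE, nrow(exons)))
  # suppressed warning: disjoint seqlevel sets simply mean no overlap
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    .as_granges(exons, use_strand = strict_strand),
    .as_granges(circs, use_strand = strict_strand),
    minoverlap = 1L, ignore.strand = !strict_strand))
  out <- rep(FALSE, nrow(exons))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Find qualifying flanking Alu elements for one exon
#'
#' An Alu qualifies on a side when it lies on the exon's chromosome, does
#' not overlap the exon, the gap between the closest boundaries is at most
#' `window` nucleotides (0 for abutting features), and its length is at
#' least `min_full_length`. Sides are reported in transcript orientation:
#' for a `+` (or `.`) exon upstream means lower genomic coordinates; for a
#' `-` exon upstream means higher coordinates.
#'
#' @param exon single-row data.frame (chrom, start, end, strand).
#' @param alus data.frame of Alu elements (chrom, start, end, strand, name).
#' @param window maximum boundary-to-boundary gap in nucleotides.
#' @param min_full_length minimum Alu length to count as full length. The
#'   value 250 nt approximates a full-length ~300-nt Alu while tolerating
#'   truncation; set 0 to disable (used for length-distribution analyses).
#' @return list with data.frames `upstream` and `downstream`.
#' @export
find_flanking_alus <- function(exon, alus, window = 2000, min_full_length = 250) {
  stopifnot(nrow(exon) == 1, window > 0, min_full_length >= 0)
  same <- alus$chrom == exon$chrom
  len_ok <- (alus$end - alus$start) >= min_full_length
  left <- same & len_ok & (exon$start - alus$end) >= 0 &
    (exon$start - alus$end) <= window
  right <- same & len_ok & (alus$start - exon$end) >= 0 &
    (alus$start - exon$end) <= window
  if (identical(exon$strand, "-")) {
    up <- right; down <- left
  } else {
    up <- left; down <- right
  }
  list(upstream = alus[up, , drop = FALSE],
       downstream = alus[down, , drop = FALSE])
}

#' Classify one exon's flank pattern from its qualifying Alus
#'
#' IR requires at least one upstream/downstream pair on opposite genomic
#' strands (the most permissive reading: ANY opposite-strand pair). Both
#' sides occupied but all pairs same-strand yields OTHER.
#'
#' @param upstream,downstream data.frames of qualifying Alus as returned by
#'   [find_flanking_alus()].
#' @return one of [FLANK_PATTERNS].
#' @export
classify_flank_pattern <- function(upstream, downstream) {
  n_up <- if (is.null(upstream)) 0L else nrow(upstream)
  n_down <- if (is.null(downstream)) 0L else nrow(downstream)
  if (n_up == 0 && n_down == 0) return("NONE")
  if (n_up > 0 && n_down == 0) return("FIVE_PRIME_ONLY")
  if (n_up == 0 && n_down > 0) return("THREE_PRIME_ONLY")
  up_s <- unique(upstream$strand)
  down_s <- unique(downstream$strand)
  inverted <- ("+" %in% up_s && "-" %in% down_s) ||
    ("-" %in% up_s && "+" %in% down_s)
  if (inverted) "IR" else "OTHER"
}

# Indexed genome-wide flank detection. The qualifying rule on the genomic
# left side is 0 <= exon.start - alu.end <= window; on the right side it is
# 0 <= alu.start - exon.end <= window. Both reduce to an overlap of the
# Alu's exon-facing edge (a point) with the exon's side window, computed
# with an interval index.

# (exon index, alu index) pairs qualifying on one genomic side
.flank_side_pairs <- function(exons, alus, window, min_full_length, side) {
  len_ok <- which((alus$end - alus$start) >= min_full_length)
  a <- alus[len_ok, , drop = FALSE]
  if (nrow(a) == 0 || nrow(exons) == 0)
    return(list(exon = integer(0), alu = integer(0)))
  if (side == "left") {
    win <- GenomicRanges::GRanges(exons$chrom,
      IRanges::IRanges(start = pmax(exons$start - window, 0) + 1,
                       end = exons$start + 1))
    pts <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$end + 1, a$end + 1))
  } else {
    win <- GenomicRanges::GRanges(exons$chrom,
      IRanges::IRanges(start = exons$end + 1, end = exons$end + window + 1))
    pts <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1, a$start + 1))
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(win, pts,
                                                       ignore.strand = TRUE))
  list(exon = S4Vectors::queryHits(hits),
       alu = len_ok[S4Vectors::subjectHits(hits)])
}

# per-exon strand presence and counts on one genomic side
.flank_side_hits <- function(exons, alus, window, min_full_length, side) {
  n <- nrow(exons)
  res <- list(plus = logical(n), minus = logical(n), count = integer(n))
  h <- .flank_side_pairs(exons, alus, window, min_full_length, side)
  if (length(h$exon)) {
    strands <- alus$strand[h$alu]
    res$plus[unique(h$exon[strands == "+"])] <- TRUE
    res$minus[unique(h$exon[strands == "-"])] <- TRUE
    res$count <- tabulate(h$exon, nbins = n)
  }
  res
}

#' Classify all exons by flank pattern and circularization status
#'
#' Genome-wide, interval-indexed equivalent of running
#' [find_flanking_alus()] + [classify_flank_pattern()] +
#' [mark_circularizing()] per exon.
#'
#' @param exons data.frame of exon intervals.
#' @param alus data.frame of Alu elements.
#' @param circs data.frame of circRNA records (BED12-style, `block_count`);
#'   `NULL` marks every exon non-circularizing.
#' @param window,min_full_length flanking criteria, see
#'   [find_flanking_alus()].
#' @param strict_strand passed to [mark_circularizing()].
#' @return data.frame: the exon columns plus `circularizing`, `pattern`,
#'   `n_upstream`, `n_downstream`.
#' @export
classify_exons <- function(exons, alus, circs = NULL, window = 2000,
                           min_full_length = 250, strict_strand = FALSE) {
  stopifnot(window > 0, min_full_length >= 0)
  n <- nrow(exons)
  left <- .flank_side_hits(exons, alus, window, min_full_length, "left")
  right <- .flank_side_hits(exons, alus, window, min_full_length, "right")
  minus_exon <- exons$strand == "-"
  up_plus <- ifelse(minus_exon, right$plus, left$plus)
  up_minus <- ifelse(minus_exon, right$minus, left$minus)
  down_plus <- ifelse(minus_exon, left$plus, right$plus)
  down_minus <- ifelse(minus_exon, left$minus, right$minus)
  n_up <- ifelse(minus_exon, right$count, left$count)
  n_down <- ifelse(minus_exon, left$count, right$count)
  has_up <- up_plus | up_minus
  has_down <- down_plus | down_minus
  ir <- (up_plus & down_minus) | (up_minus & down_plus)
  pattern <- rep("NONE", n)
  pattern[has_up & !has_down] <- "FIVE_PRIME_ONLY"
  pattern[!has_up & has_down] <- "THREE_PRIME_ONLY"
  pattern[has_up & has_down] <- "OTHER"
  pattern[ir] <- "IR"
  circ <- if (is.null(circs)) rep(FALSE, n) else
    mark_circularizing(exons, circs, strict_strand = strict_strand)
  out <- exons
  out$circularizing <- circ
  out$pattern <- factor(pattern, levels = FLANK_PATTERNS)
  out$n_upstream <- as.integer(n_up)
  out$n_downstream <- as.integer(n_down)
  out
}

#' Write a classified-exon table to TSV
#'
#' @param classified output of [classify_exons()].
#' @param path output file.
#' @export
write_classified_tsv <- function(classified, path) {
  cols <- c("chrom", "start", "end", "strand", "circularizing", "pattern",
            "n_upstream", "n_downstream")
  utils::write.table(classified[, intersect(cols, names(classified))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
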