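# Secondary-structure file parsing (CT, dot-bracket, pairing-probability
# text) and region-level pairing metrics.
#
# Internally a structure is a sequence plus a 0-based pair table:
# pair_of[i+1] is the partner of position i, or NA when unpaired. The pair
# table must be an involution with no self-pairs; CT parsing accepts
# pseudoknots (the table is general), dot-bracket emission uses bracket
# tiers.

.BRACKET_OPEN <- c("(", "[", "{")
.BRACKET_CLOSE <- c(")", "]", "}")

#' Construct a secondary structure
#'
#' @param sequence RNA string or base vector.
#' @param pair_of 0-based partner indices (NA = unpaired), along the
#'   sequence.
#' @return object of class `secondary_structure`.
#' @export
secondary_structure <- function(sequence, pair_of) {
  seqv <- .as_base_vector(sequence)
  n <- length(seqv)
  if (length(pair_of) != n) stop("pair table length does not match sequence")
  pair_of <- as.integer(pair_of)
  idx <- which(!is.na(pair_of))
  if (any(pair_of[idx] < 0 | pair_of[idx] >= n))
    stop("partner index out of range")
  if (any(pair_of[idx] == idx - 1L))
    stop(sprintf("position %d pairs with itself", idx[pair_of[idx] == idx - 1L][1]))
  back <- pair_of[pair_of[idx] + 1L]
  bad <- idx[is.na(back) | back != idx - 1L]
  if (length(bad))
    stop(sprintf("pair table is not an involution at position(s) %s (0-based %s)",
                 paste(head(bad, 3), collapse = ", "),
                 paste(head(bad - 1L, 3), collapse = ", ")))
  structure(list(sequence = seqv, pair_of = pair_of),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d pairs\n",
              length(x$sequence), sum(!is.na(x$pair_of)) / 2))
  invisible(x)
}

#' Parse a connectivity-table (CT) file
#'
#' Standard CT: a header line starting with the sequence length, then one
#' row per nucleotide (index, base, prev, next, pair, natural index). The
#' 1-based pair column is converted to 0-based; 0 means unpaired. The pair
#' table is validated as an involution.
#'
#' @param path CT file.
#' @return a `secondary_structure`.
#' @export
parse_ct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  n <- suppressWarnings(as.integer(head_tok[1]))
  if (is.na(n) || n < 1) stop("CT header must begin with the sequence length")
  if (length(lines) < n + 1) stop("CT file truncated")
  toks <- strsplit(trimws(lines[2:(n + 1)]), "[[:space:]]+")
  idx <- as.integer(vapply(toks, `[[`, "", 1L))
  if (any(idx != seq_len(n))) stop("CT rows out of order")
  base <- vapply(toks, `[[`, "", 2L)
  pair1 <- as.integer(vapply(toks, `[[`, "", 5L))
  pair_of <- ifelse(pair1 == 0L, NA_integer_, pair1 - 1L)
  secondary_structure(base, pair_of)
}

#' Parse a dot-bracket string
#'
#' Supports nested brackets in the tiers `()`, `[]`, `{}` (tiers may
#' interleave, encoding pseudoknots). Unbalanced input errors with the
#' offending position.
#'
#' @param db dot-bracket string.
#' @param sequence optional sequence of the same length (defaults to "N").
#' @return a `secondary_structure`.
#' @export
parse_dotbracket <- function(db, sequence = NULL) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  pair_of <- rep(NA_integer_, n)
  for (t in seq_along(.BRACKET_OPEN)) {
    stack <- integer(0)
    for (i in seq_len(n)) {
      if (ch[i] == .BRACKET_OPEN[t]) stack <- c(stack, i)
      else if (ch[i] == .BRACKET_CLOSE[t]) {
        if (!length(stack))
          stop(sprintf("unbalanced '%s' at position %d", ch[i], i))
        j <- stack[length(stack)]; stack <- stack[-length(stack)]
        pair_of[i] <- j - 1L; pair_of[j] <- i - 1L
      }
    }
    if (length(stack))
      stop(sprintf("unbalanced '%s' at position %d", .BRACKET_OPEN[t],
                   stack[length(stack)]))
  }
  allowed <- c(".", "-", .BRACKET_OPEN, .BRACKET_CLOSE)
  if (any(!ch %in% allowed))
    stop(sprintf("unsupported character '%s' at position %d",
                 ch[!ch %in% allowed][1], which(!ch %in% allowed)[1]))
  if (is.null(sequence)) sequence <- rep("N", n)
  secondary_structure(sequence, pair_of)
}

#' Render a structure as dot-bracket
#'
#' Pairs are assigned greedily to the lowest bracket tier that keeps each
#' tier nested; more than three tiers (deeply crossing pseudoknots) is an
#' error.
#'
#' @param structure a `secondary_structure`.
#' @return dot-bracket string.
#' @export
format_dotbracket <- function(structure) {
  n <- length(structure$sequence)
  out <- rep(".", n)
  po <- structure$pair_of
  opens <- which(!is.na(po) & po + 1L > seq_len(n))
  tier_closed <- rep(0L, length(.BRACKET_OPEN))  # rightmost close per tier
  # process pairs ordered by opening position; a pair fits a tier if it is
  # nested or disjoint with everything already in the tier
  tiers <- vector("list", length(.BRACKET_OPEN))
  for (i in opens) {
    j <- po[i] + 1L
    placed <- FALSE
    for (t in seq_along(tiers)) {
      crossing <- any(vapply(tiers[[t]], function(p)
        (p[1] < i & i <= p[2] & p[2] < j), logical(1)))
      if (!crossing) {
        tiers[[t]] <- c(tiers[[t]], list(c(i, j)))
        out[i] <- .BRACKET_OPEN[t]; out[j] <- .BRACKET_CLOSE[t]
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("structure requires more than 3 bracket tiers to render")
  }
  paste(out, collapse = "")
}

#' Percentage of region nucleotides paired to any nucleotide
#'
#' 100 x (paired positions in the region) / (region length); the partner
#' may lie anywhere in the molecule, inside or outside the region.
#'
#' @param structure a `secondary_structure`.
#' @param reg one-row region data.frame (see [region()]); `NULL` uses the
#'   whole molecule.
#' @return percentage in \[0, 100\].
#' @export
percent_paired <- function(structure, reg = NULL) {
  n <- length(structure$sequence)
  if (is.null(reg)) reg <- region("all", 0, n)
  idx <- .region_index(reg, n)
  100 * sum(!is.na(structure$pair_of[idx])) / length(idx)
}

#' Fraction of one region's positions paired into another region
#'
#' Quantifies inter-region (e.g. Alu-Alu) pairing: the fraction of
#' `region_a` positions whose partner lies inside `region_b`. Regions must
#' be disjoint.
#'
#' @param structure a `secondary_structure`.
#' @param region_a,region_b disjoint one-row region data.frames.
#' @return fraction in \[0, 1\].
#' @export
inter_region_pair_fraction <- function(structure, region_a, region_b) {
  if (region_a$start < region_b$end && region_b$start < region_a$end)
    stop("regions overlap; inter-region pairing undefined")
  n <- length(structure$sequence)
  ia <- .region_index(region_a, n)
  partners <- structure$pair_of[ia]
  inside_b <- !is.na(partners) & partners >= region_b$start &
    partners < region_b$end
  sum(inside_b) / length(ia)
}

#' Parse a pairing-probability text file
#'
#' Dialect produced by partition-function probability plots: a length
#' line, a header line, then rows `i j -log10(probability)` (1-based i <
#' j). Probabilities are recovered as 10^(-value).
#'
#' @param path probability text file.
#' @return data.frame: i, j (0-based, i < j), prob.
#' @export
parse_probability_plot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("probability file truncated")
  toks <- strsplit(trimws(lines[-(1:2)]), "[[:space:]]+")
  if (!length(toks))
    return(data.frame(i = integer(0), j = integer(0), prob = numeric(0)))
  i1 <- as.integer(vapply(toks, `[[`, "", 1L))
  j1 <- as.integer(vapply(toks, `[[`, "", 2L))
  v <- as.numeric(vapply(toks, `[[`, "", 3L))
  if (any(v < 0))
    stop(sprintf("negative -log10 probability on data row %d", which(v < 0)[1]))
  if (any(j1 <= i1)) stop("probability rows must have i < j")
  data.frame(i = i1 - 1L, j = j1 - 1L, prob = 10^(-v))
}

#' Filter pairing-probability records by minimum probability
#'
#' @param records data.frame from [parse_probability_plot()].
#' @param min_prob keep records with `prob >= min_prob`.
#' @return filtered data.frame.
#' @export
filter_pairs <- function(records, min_prob) {
  records[records$prob >= min_prob, , drop = FALSE]
}

#' Region pairing metrics table
#'
#' percent-paired per region plus pairwise inter-region pairing fractions.
#'
#' @param structure a `secondary_structure`.
#' @param regions data.frame of regions.
#' @return list with data.frames `per_region` (name, length,
#'   percent_paired) and `between` (from, to, fraction).
#' @export
structure_region_metrics <- function(structure, regions) {
  per <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    data.frame(name = r$name, length = r$end - r$start,
               percent_paired = percent_paired(structure, r))
  }))
  pairs <- if (nrow(regions) > 1) utils::combn(nrow(regions), 2) else
    matrix(integer(0), nrow = 2)
  between <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- regions[pairs[1, k], ]; b <- regions[pairs[2, k], ]
    data.frame(from = c(a$name, b$name), to = c(b$name, a$name),
               fraction = c(inter_region_pair_fraction(structure, a, b),
                            inter_region_pair_fraction(structure, b, a)))
  }))
  list(per_region = per, between = between)
}
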