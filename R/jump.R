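# SHAPE-JuMP deletion-event quantification: frequencies with low-count
# filtering, treated-minus-untreated background subtraction, rank
# distributions, coordinate lift-over from deletion-mutant constructs to
# reference (WT) coordinates, and triangular density matrices.
#
# A JuMP event records one crosslink traversal: the processive reverse
# transcriptase jumps across the crosslinked nucleotides and leaves a
# deletion from `start` to `stop` (0-based, stop exclusive), seen in
# `count` of `depth` informative reads.

#' Assemble a JuMP dataset
#'
#' @param events data.frame with columns start, stop, count, depth.
#' @param construct construct name.
#' @param condition `"treated"` or `"untreated"`.
#' @return list of class `jump_dataset`.
#' @export
jump_dataset <- function(events, construct = "construct",
                         condition = c("treated", "untreated")) {
  condition <- match.arg(condition)
  need <- c("start", "stop", "count", "depth")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop(sprintf("events missing column(s): %s", paste(miss, collapse = ", ")))
  if (any(events$stop <= events$start))
    stop("every event must satisfy stop > start")
  if (any(events$count < 0) || any(events$depth < 0))
    stop("counts and depths must be non-negative")
  bad <- which(events$count > events$depth)
  if (length(bad))
    stop(sprintf("count exceeds depth for event(s) at row %s",
                 paste(head(bad, 5), collapse = ", ")))
  key <- paste(events$start, events$stop)
  if (anyDuplicated(key)) {
    warning("duplicate (start, stop) events; counts and depths summed")
    events <- stats::aggregate(cbind(count, depth) ~ start + stop,
                               data = events, FUN = sum)
  }
  events <- events[order(events$start, events$stop), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(construct = construct, condition = condition,
                 events = events), class = "jump_dataset")
}

#' Read a JuMP deletion-event TSV
#'
#' Columns: construct, start, stop, count, depth; `#` comment lines are
#' skipped. Duplicate (start, stop) rows are merged by summing counts and
#' depths (with a warning).
#'
#' @param path TSV file.
#' @param condition condition label for the dataset.
#' @return a `jump_dataset` (single-construct files) or a named list of
#'   them when the file holds several constructs.
#' @export
read_jump_events <- function(path, condition = c("treated", "untreated")) {
  condition <- match.arg(condition)
  df <- utils::read.delim(path, comment.char = "#")
  need <- c("construct", "start", "stop", "count", "depth")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("JuMP table missing column(s): %s", paste(miss, collapse = ", ")))
  split_df <- split(df, df$construct)
  out <- lapply(names(split_df), function(cn)
    jump_dataset(split_df[[cn]][c("start", "stop", "count", "depth")],
                 construct = cn, condition = condition))
  names(out) <- names(split_df)
  if (length(out) == 1L) out[[1]] else out
}

#' Combine replicate JuMP datasets
#'
#' Default mode sums counts and depths event-wise before any frequency is
#' computed; `"average"` instead averages per-replicate frequencies
#' (events absent from a replicate contribute frequency 0).
#'
#' @param ... `jump_dataset`s of the same construct and condition.
#' @param mode `"sum"` or `"average"`.
#' @return a `jump_dataset` (`"average"` mode returns frequency-bearing
#'   events with count/depth from the summed data).
#' @export
combine_jump_replicates <- function(..., mode = c("sum", "average")) {
  mode <- match.arg(mode)
  reps <- list(...)
  stopifnot(length(reps) >= 1)
  cons <- unique(vapply(reps, `[[`, "", "construct"))
  cond <- unique(vapply(reps, `[[`, "", "condition"))
  if (length(cons) != 1 || length(cond) != 1)
    stop("replicates must share construct and condition")
  all_ev <- do.call(rbind, lapply(reps, function(d) d$events))
  summed <- suppressWarnings(jump_dataset(all_ev, cons, cond))
  if (mode == "sum") return(summed)
  key_all <- paste(summed$events$start, summed$events$stop)
  freq <- sapply(seq_along(key_all), function(i) {
    fs <- vapply(reps, function(d) {
      j <- match(key_all[i], paste(d$events$start, d$events$stop))
      if (is.na(j)) 0 else d$events$count[j] / d$events$depth[j]
    }, numeric(1))
    mean(fs)
  })
  out <- summed
  out$events$frequency <- freq
  out
}

#' JuMP frequencies with low-count filtering
#'
#' frequency = count / depth. Events with `count < min_count` are removed
#' before any downstream step: low-count events can be artificially
#' high-frequency when both count and depth are small (one deletion in one
#' read is a 100% frequency).
#'
#' @param ds a `jump_dataset`.
#' @param min_count minimum deletion count to retain an event.
#' @param min_depth optional minimum depth floor (disabled by default).
#' @return the dataset with filtered events carrying a `frequency` column.
#' @export
jump_frequencies <- function(ds, min_count = 20, min_depth = 0) {
  stopifnot(inherits(ds, "jump_dataset"))
  ev <- ds$events
  ev <- ev[ev$count >= min_count & ev$depth >= min_depth, , drop = FALSE]
  if (nrow(ev) && any(ev$depth == 0))
    stop("retained event with zero depth; frequency undefined")
  ev$frequency <- if (nrow(ev)) ev$count / ev$depth else numeric(0)
  rownames(ev) <- NULL
  out <- ds
  out$events <- ev
  out
}

#' Subtract untreated (background) frequencies from treated
#'
#' Events are matched on exact (start, stop); a treated event with no
#' untreated partner gets untreated frequency 0. Negative differences are
#' retained in the output (clipping to zero happens only when rendering
#' densities or ranks).
#'
#' @param treated,untreated `jump_dataset`s with `frequency` columns (from
#'   [jump_frequencies()]), same construct.
#' @param fuzzy_nt match untreated partners within +/- this many nt on both
#'   coordinates (0 = exact; nearest match wins).
#' @return data.frame: start, stop, count, depth, frequency,
#'   untreated_frequency, delta_frequency.
#' @export
subtract_untreated <- function(treated, untreated, fuzzy_nt = 0) {
  stopifnot(inherits(treated, "jump_dataset"), inherits(untreated, "jump_dataset"))
  if (!identical(treated$construct, untreated$construct))
    stop(sprintf("construct mismatch: '%s' vs '%s'", treated$construct,
                 untreated$construct))
  te <- treated$events; ue <- untreated$events
  if (is.null(te$frequency) || (nrow(ue) > 0 && is.null(ue$frequency)))
    stop("run jump_frequencies() on both datasets first")
  uf <- numeric(nrow(te))
  if (nrow(ue)) {
    if (fuzzy_nt == 0) {
      j <- match(paste(te$start, te$stop), paste(ue$start, ue$stop))
      uf <- ifelse(is.na(j), 0, ue$frequency[j])
    } else {
      for (i in seq_len(nrow(te))) {
        d <- abs(ue$start - te$start[i]) + abs(ue$stop - te$stop[i])
        cand <- which(abs(ue$start - te$start[i]) <= fuzzy_nt &
                        abs(ue$stop - te$stop[i]) <= fuzzy_nt)
        uf[i] <- if (length(cand)) ue$frequency[cand[which.min(d[cand])]] else 0
      }
    }
  }
  te$untreated_frequency <- uf
  te$delta_frequency <- te$frequency - uf
  te
}

#' Rank distribution of JuMP differences
#'
#' Stable descending sort by `delta_frequency`; ties broken by (start,
#' stop) ascending. Negative differences are clipped at zero for the rank
#' values (they carry no signal above background).
#'
#' @param events data.frame from [subtract_untreated()] (or any frame with
#'   a `delta_frequency` column).
#' @return data.frame: rank, start, stop, delta_frequency.
#' @export
rank_distribution <- function(events) {
  if (nrow(events) == 0)
    return(data.frame(rank = integer(0), start = numeric(0),
                      stop = numeric(0), delta_frequency = numeric(0)))
  d <- pmax(events$delta_frequency, 0)
  o <- order(-d, events$start, events$stop)
  data.frame(rank = seq_along(o), start = events$start[o],
             stop = events$stop[o], delta_frequency = d[o])
}

#' Deletion specification for a mutant construct
#'
#' The ordered, disjoint half-open intervals removed from the reference
#' (WT) construct to form the mutant.
#'
#' @param wt_start,wt_end numeric vectors of deleted intervals (0-based
#'   half-open, WT coordinates).
#' @param wt_length optional WT length for bounds checking.
#' @return data.frame of class `deletion_spec`.
#' @export
deletion_spec <- function(wt_start, wt_end, wt_length = NULL) {
  stopifnot(length(wt_start) == length(wt_end))
  o <- order(wt_start)
  wt_start <- as.numeric(wt_start[o]); wt_end <- as.numeric(wt_end[o])
  if (any(wt_end <= wt_start)) stop("deleted intervals must have end > start")
  if (length(wt_start) > 1 && any(wt_start[-1] < wt_end[-length(wt_end)]))
    stop("deleted intervals must be disjoint")
  if (!is.null(wt_length) && any(wt_end > wt_length))
    stop("deleted interval extends beyond the WT construct")
  structure(data.frame(wt_start = wt_start, wt_end = wt_end),
            wt_length = wt_length,
            class = c("deletion_spec", "data.frame"))
}

#' Read a deletion spec from YAML
#'
#' Expects `deletions: [[start, end], ...]` (0-based half-open WT
#' intervals), optionally `wt_length`.
#'
#' @param path YAML file.
#' @return a `deletion_spec`.
#' @export
read_deletion_spec_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  dels <- y$deletions
  if (is.null(dels)) stop("YAML must contain a 'deletions' list")
  deletion_spec(vapply(dels, `[[`, numeric(1), 1L),
                vapply(dels, `[[`, numeric(1), 2L),
                wt_length = y$wt_length)
}

#' Infer a deletion spec from WT and mutant sequences
#'
#' Extracts gap runs from a simple anchored walk: mutant must equal WT with
#' whole blocks deleted (no substitutions), the construction used for
#' deletion-mutant constructs.
#'
#' @param wt,mutant sequences (strings).
#' @return a `deletion_spec`.
#' @export
deletion_spec_from_sequences <- function(wt, mutant) {
  w <- .as_base_vector(wt); m <- .as_base_vector(mutant)
  starts <- ends <- numeric(0)
  i <- 1L; j <- 1L
  while (j <= length(m)) {
    if (i > length(w)) stop("mutant is not a deletion derivative of WT")
    if (w[i] == m[j]) { i <- i + 1L; j <- j + 1L; next }
    # open a deletion: advance i until the remaining suffixes can align
    s <- i - 1L
    repeat {
      i <- i + 1L
      if (i > length(w)) stop("mutant is not a deletion derivative of WT")
      if (w[i] == m[j] && (length(w) - i) >= (length(m) - j)) break
    }
    starts <- c(starts, s); ends <- c(ends, i - 1L)
  }
  if (i <= length(w)) { starts <- c(starts, i - 1L); ends <- c(ends, length(w)) }
  deletion_spec(starts, ends, wt_length = length(w))
}

#' Lift mutant construct positions to reference (WT) coordinates
#'
#' A mutant position maps to the WT position shifted by the total deleted
#' length upstream of it; the map is strictly increasing and injective.
#'
#' @param pos 0-based mutant position(s).
#' @param spec a `deletion_spec`.
#' @return WT position(s).
#' @export
lift_to_reference <- function(pos, spec) {
  del_len <- spec$wt_end - spec$wt_start
  mut_len_before <- cumsum(c(0, del_len))
  # mutant coordinate at which each deletion sits:
  mut_break <- spec$wt_start - mut_len_before[seq_len(nrow(spec))]
  wt_length <- attr(spec, "wt_length")
  mut_length <- if (is.null(wt_length)) Inf else wt_length - sum(del_len)
  vapply(pos, function(p) {
    if (p < 0 || p > mut_length)
      stop(sprintf("mutant position %g out of range", p))
    p + sum(del_len[mut_break <= p])
  }, numeric(1))
}

#' Map reference (WT) positions onto the mutant construct
#'
#' Inverse of [lift_to_reference()]: WT positions inside a deleted interval
#' have no mutant image and return NA.
#'
#' @param wt_pos 0-based WT position(s).
#' @param spec a `deletion_spec`.
#' @return mutant position(s), NA where deleted.
#' @export
reference_to_mutant <- function(wt_pos, spec) {
  vapply(wt_pos, function(p) {
    if (p < 0) stop(sprintf("WT position %g out of range", p))
    if (any(p >= spec$wt_start & p < spec$wt_end)) return(NA_real_)
    p - sum((spec$wt_end - spec$wt_start)[spec$wt_end <= p])
  }, numeric(1))
}

#' Lift a JuMP event table to WT coordinates
#'
#' @param events data.frame with start/stop columns (mutant coordinates).
#' @param spec a `deletion_spec`.
#' @return the table with start/stop replaced by WT coordinates.
#' @export
lift_jump_events <- function(events, spec) {
  events$start <- lift_to_reference(events$start, spec)
  events$stop <- lift_to_reference(events$stop, spec)
  events
}

#' Triangular JuMP density matrix
#'
#' Each event deposits max(delta, 0) into the cell indexed by the bin of
#' its midpoint (start+stop)/2 and the bin of its separation stop-start:
#' the triangular-plot geometry with sequence position horizontal and pair
#' separation vertical, long-range contacts at the apex. Total matrix mass
#' equals the sum of clipped differences.
#'
#' @param events data.frame with start, stop, delta_frequency.
#' @param bin bin width in nucleotides.
#' @param length construct length in nucleotides.
#' @return matrix (separation bins x midpoint bins) with bin-start
#'   dimnames.
#' @export
jump_density <- function(events, bin = 10, length) {
  stopifnot(bin >= 1, length >= 1)
  if (nrow(events) && any(events$stop > length))
    stop("event coordinates exceed the construct length")
  # separation can reach the full construct length, hence the +1
  nb <- floor(length / bin) + 1
  mat <- matrix(0, nrow = nb, ncol = nb,
                dimnames = list(separation = (seq_len(nb) - 1) * bin,
                                midpoint = (seq_len(nb) - 1) * bin))
  if (nrow(events) == 0) return(mat)
  mid_bin <- floor(((events$start + events$stop) / 2) / bin) + 1
  sep_bin <- floor((events$stop - events$start) / bin) + 1
  w <- pmax(events$delta_frequency, 0)
  for (i in seq_along(w))
    mat[sep_bin[i], mid_bin[i]] <- mat[sep_bin[i], mid_bin[i]] + w[i]
  mat
}
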