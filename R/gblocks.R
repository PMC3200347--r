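# Gblocks-style selection of conserved alignment blocks, as used to strip
# regions of uncertain alignment from ribosomal (16S-like) loci before
# distance and character analyses.

#' Parameters for the conserved-block filter
#'
#' Defaults mirror the classic settings for moderately variable ribosomal
#' alignments: a conserved position needs the majority residue in at least
#' 50% of sequences, a flanking position in at least 90%, at most 3
#' contiguous non-conserved positions are tolerated inside a block, blocks
#' must span at least 5 retained columns, and columns with gaps in half or
#' more of the sequences are discarded ("half" gap allowance).
#'
#' Thresholds count sequences: a fraction f of n sequences means
#' `ceiling(f * n)` sequences.
#'
#' @param min_conserved_frac Fraction of sequences required for a conserved
#'   position (0 < f <= `min_flank_frac`).
#' @param min_flank_frac Fraction required for a highly conserved (flanking)
#'   position (<= 1).
#' @param max_contig_nonconserved Longest run of non-conserved columns that
#'   does not split a block.
#' @param min_block_len Minimum number of retained columns per block.
#' @param gap_allowance One of `"none"` (any gap disqualifies a column),
#'   `"half"` (gaps in >= 50% of sequences disqualify) or `"all"` (gaps
#'   never disqualify).
#' @return A list of validated parameters (class `gblocks_params`).
#' @export
gblocks_params <- function(min_conserved_frac = 0.5,
                           min_flank_frac = 0.9,
                           max_contig_nonconserved = 3,
                           min_block_len = 5,
                           gap_allowance = c("half", "none", "all")) {
  gap_allowance <- match.arg(gap_allowance)
  if (!(min_conserved_frac > 0 && min_conserved_frac <= min_flank_frac &&
        min_flank_frac <= 1)) {
    stop("need 0 < min_conserved_frac <= min_flank_frac <= 1")
  }
  if (max_contig_nonconserved < 0 || min_block_len < 1) {
    stop("max_contig_nonconserved must be >= 0 and min_block_len >= 1")
  }
  structure(list(min_conserved_frac = min_conserved_frac,
                 min_flank_frac = min_flank_frac,
                 max_contig_nonconserved = as.integer(max_contig_nonconserved),
                 min_block_len = as.integer(min_block_len),
                 gap_allowance = gap_allowance),
            class = "gblocks_params")
}

# Classify each column as "N" (non-conserved), "C" (conserved) or "H"
# (highly conserved).  The majority count ignores gaps and the ambiguity
# code N, which carries no state information.
classify_columns <- function(aln, params) {
  n <- nrow(aln)
  conserved_min <- ceiling(params$min_conserved_frac * n)
  flank_min <- ceiling(params$min_flank_frac * n)
  vapply(seq_len(ncol(aln)), function(j) {
    col <- aln[, j]
    n_gap <- sum(col == "-")
    gap_fail <- switch(params$gap_allowance,
                       none = n_gap > 0,
                       half = n_gap >= n / 2,
                       all = FALSE)
    states <- col[col != "-" & col != "N"]
    top <- if (length(states) == 0) 0L else max(tabulate(factor(states)))
    if (gap_fail || top < conserved_min) {
      "N"
    } else if (top < flank_min) {
      "C"
    } else {
      "H"
    }
  }, character(1))
}

#' Filter an alignment down to its conserved blocks
#'
#' Re-implements the classic conserved-block procedure: (1) columns are
#' classified as non-conserved, conserved or highly conserved from the
#' count of their most frequent residue; (2) runs of more than
#' `max_contig_nonconserved` contiguous non-conserved columns split the
#' alignment into candidate blocks, and every non-conserved column is
#' discarded; (3) each candidate block is trimmed until it starts and ends
#' on a highly conserved column; (4) blocks shorter than `min_block_len`
#' retained columns are discarded.  An empty result is legal, not an error.
#'
#' The filter is idempotent: applying it twice with the same parameters
#' changes nothing the second time.
#'
#' @param aln Alignment matrix (see [as_alignment()]).
#' @param params A [gblocks_params()] object.
#' @return A list with `alignment` (the surviving columns, in order),
#'   `blocks` (data.frame of 1-based closed intervals `start`, `end` of the
#'   kept columns in the input coordinate system) and `status` (the
#'   per-column classification of the input).
#' @export
gblocks_filter <- function(aln, params = gblocks_params()) {
  if (!is.matrix(aln) || nrow(aln) == 0 || ncol(aln) == 0) {
    stop("gblocks_filter needs a non-empty alignment matrix")
  }
  status <- classify_columns(aln, params)
  L <- length(status)

  # hard breakers: runs of non-conserved columns longer than the allowance
  r <- rle(status == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  breaker <- rep(FALSE, L)
  long <- which(r$values & r$lengths > params$max_contig_nonconserved)
  for (k in long) {
    breaker[starts[k]:ends[k]] <- TRUE
  }

  # candidate blocks = segments between breakers; keep non-"N" columns,
  # trim both ends to highly conserved columns, enforce the length floor
  seg_id <- cumsum(breaker)
  kept <- integer(0)
  for (seg in split(which(!breaker), seg_id[!breaker])) {
    cols <- seg[status[seg] != "N"]
    h <- which(status[cols] == "H")
    if (length(h) == 0) next
    cols <- cols[h[1]:h[length(h)]]
    if (length(cols) >= params$min_block_len) {
      kept <- c(kept, cols)
    }
  }

  blocks <- intervals_from_columns(kept)
  list(alignment = aln[, kept, drop = FALSE], blocks = blocks,
       status = status)
}

# 1-based closed intervals covering a sorted set of column indices
intervals_from_columns <- function(cols) {
  if (length(cols) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  brk <- c(0, which(diff(cols) > 1), length(cols))
  data.frame(start = cols[brk[-length(brk)] + 1],
             end = cols[brk[-1]])
}
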