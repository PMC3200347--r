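# Rank-stratified divergence summaries, barcoding-gap diagnostics, the
# 10x-rule threshold, species lumping and threshold-based identification.
#
# Every unordered pair of sequences falls in exactly one stratum:
# conspecific, congeneric (different species), confamilial (different
# genera) or different families.  Reports are rendered in percent
# (100 * d), the convention of barcode divergence tables.

RANK_LEVELS <- c("within_species",
                 "within_genus_between_species",
                 "within_family_between_genera",
                 "within_order_between_families")

pair_strata <- function(dm, tax) {
  tx <- tax[match(dm$ids, tax$id), , drop = FALSE]
  if (anyNA(tx$id)) {
    stop("distance-matrix id(s) missing from taxonomy: ",
         paste(setdiff(dm$ids, tax$id), collapse = ", "))
  }
  same_sp <- outer(tx$species, tx$species, `==`)
  same_gen <- outer(tx$genus, tx$genus, `==`)
  same_fam <- outer(tx$family, tx$family, `==`)
  stratum <- matrix(RANK_LEVELS[4], nrow(same_sp), ncol(same_sp))
  stratum[same_fam] <- RANK_LEVELS[3]
  stratum[same_gen] <- RANK_LEVELS[2]
  stratum[same_sp] <- RANK_LEVELS[1]
  stratum
}

#' Rank-stratified divergence summary
#'
#' Summarises pairwise K2P divergences by taxonomic stratum, the layout of
#' classic barcode divergence tables: mean, minimum, maximum and standard
#' error per comparison level, all in percent.  The SE is the sample
#' standard deviation of the pairwise distances divided by
#' `sqrt(n_pairs)`; pairwise distances are not independent, so treat it as
#' an indicative, not an inferential, quantity.  Flagged (undefined) pairs
#' are excluded from the statistics but still counted in `n_pairs`.
#'
#' @param dm A [distance_matrix()] result.
#' @param tax Taxonomy data.frame covering every id in `dm`.
#' @return data.frame with columns `comparison`, `n_pairs`, `average`,
#'   `minimum`, `maximum`, `se` (percent scale).
#' @export
rank_summary <- function(dm, tax) {
  stratum <- pair_strata(dm, tax)
  ut <- upper.tri(dm$d)
  pct <- dm$d * 100
  rows <- lapply(RANK_LEVELS, function(lv) {
    m <- ut & stratum == lv
    vals <- pct[m & !dm$undefined]
    if (length(vals) == 0) {
      data.frame(comparison = lv, n_pairs = sum(m), average = NA_real_,
                 minimum = NA_real_, maximum = NA_real_, se = NA_real_)
    } else {
      data.frame(comparison = lv, n_pairs = sum(m),
                 average = mean(vals), minimum = min(vals),
                 maximum = max(vals),
                 se = if (length(vals) > 1) {
                   stats::sd(vals) / sqrt(length(vals))
                 } else {
                   NA_real_
                 })
    }
  })
  do.call(rbind, rows)
}

#' Barcoding-gap report
#'
#' Pools conspecific distances (intra) against everything else (inter) and
#' asks whether a gap separates the two distributions, globally
#' (`min(inter) > max(intra)`) and per species (nearest heterospecific
#' individual vs own maximum conspecific distance).  Also returns a binned
#' histogram of both distributions (left-closed, right-open bins starting
#' at 0).
#'
#' @inheritParams rank_summary
#' @param bin_width Histogram bin width in percent.
#' @return List with `max_intra`, `min_inter`, `global_gap`, `per_species`
#'   (data.frame) and `histogram` (data.frame), distances in percent.
#' @export
gap_report <- function(dm, tax, bin_width = 1) {
  stratum <- pair_strata(dm, tax)
  ut <- upper.tri(dm$d)
  ok <- ut & !dm$undefined
  pct <- dm$d * 100
  intra <- pct[ok & stratum == RANK_LEVELS[1]]
  inter <- pct[ok & stratum != RANK_LEVELS[1]]
  max_intra <- if (length(intra)) max(intra) else NA_real_
  min_inter <- if (length(inter)) min(inter) else NA_real_
  global_gap <- if (length(intra) && length(inter)) {
    min_inter > max_intra
  } else {
    NA
  }

  tx <- tax[match(dm$ids, tax$id), , drop = FALSE]
  per_species <- do.call(rbind, lapply(unique(tx$species), function(sp) {
    mem <- which(tx$species == sp)
    oth <- which(tx$species != sp)
    dintra <- dm$d[mem, mem, drop = FALSE]
    dintra <- dintra[upper.tri(dintra)] * 100
    dinter <- dm$d[mem, oth, drop = FALSE] * 100
    mx <- if (length(mem) > 1 && any(!is.na(dintra))) {
      max(dintra, na.rm = TRUE)
    } else {
      NA_real_
    }
    nn <- if (length(oth) > 0 && any(!is.na(dinter))) {
      min(dinter, na.rm = TRUE)
    } else {
      NA_real_
    }
    data.frame(species = sp, n_individuals = length(mem),
               max_intra = mx, nearest_hetero = nn,
               local_gap = if (is.na(mx) || is.na(nn)) NA else nn > mx)
  }))

  all_d <- c(intra, inter)
  top <- if (length(all_d)) {
    max(bin_width, ceiling(max(all_d) / bin_width) * bin_width +
          bin_width)
  } else {
    bin_width
  }
  lo <- seq(0, top - bin_width, by = bin_width)
  bin_of <- function(x) findInterval(x, c(lo, top), rightmost.closed = FALSE)
  histogram <- data.frame(
    bin_low = lo, bin_high = lo + bin_width,
    intra_count = tabulate(bin_of(intra), nbins = length(lo)),
    inter_count = tabulate(bin_of(inter), nbins = length(lo)))

  list(max_intra = max_intra, min_inter = min_inter,
       global_gap = global_gap, per_species = per_species,
       histogram = histogram, bin_width = bin_width)
}

#' The 10x-rule identification threshold
#'
#' Ten times the mean conspecific pairwise divergence, in percent: the
#' classic threshold proposed for distance-based barcode identification.
#'
#' @inheritParams rank_summary
#' @return The threshold in percent (scalar).
#' @export
ten_x_threshold <- function(dm, tax) {
  stratum <- pair_strata(dm, tax)
  ok <- upper.tri(dm$d) & !dm$undefined & stratum == RANK_LEVELS[1]
  if (!any(ok)) {
    stop("no defined conspecific pairs: the 10x threshold is undefined")
  }
  10 * mean(dm$d[ok]) * 100
}

#' Species lumping under a distance threshold
#'
#' A species is "lumped" when the threshold fails to separate it from
#' another species.  The default criterion is the nearest-neighbour one: a
#' species is lumped iff its minimum distance to any heterospecific
#' individual falls below the threshold.  `criterion = "mean"` instead
#' compares the mean distance to heterospecific individuals.
#'
#' @inheritParams rank_summary
#' @param threshold Threshold in percent (e.g. from [ten_x_threshold()]).
#' @param criterion `"nearest"` (default) or `"mean"`.
#' @param rule Free-form tag recorded in the report (e.g. `"10x"`).
#' @return List with `threshold`, `rule`, `criterion`, `lumped_species`,
#'   `lumped_fraction`, `n_species` and `per_species` (data.frame).
#' @export
lumping <- function(dm, tax, threshold, criterion = c("nearest", "mean"),
                    rule = "user") {
  criterion <- match.arg(criterion)
  if (threshold < 0) stop("threshold must be >= 0")
  tx <- tax[match(dm$ids, tax$id), , drop = FALSE]
  species <- unique(tx$species)
  per_species <- do.call(rbind, lapply(species, function(sp) {
    mem <- which(tx$species == sp)
    oth <- which(tx$species != sp)
    dinter <- dm$d[mem, oth, drop = FALSE] * 100
    stat <- if (length(oth) == 0 || all(is.na(dinter))) {
      NA_real_
    } else if (criterion == "nearest") {
      min(dinter, na.rm = TRUE)
    } else {
      mean(dinter, na.rm = TRUE)
    }
    data.frame(species = sp, inter_stat = stat,
               lumped = !is.na(stat) && stat < threshold)
  }))
  lumped <- per_species$species[per_species$lumped]
  list(threshold = threshold, rule = rule, criterion = criterion,
       lumped_species = lumped,
       lumped_fraction = length(lumped) / length(species),
       n_species = length(species), per_species = per_species)
}

#' Identify a query sequence by nearest K2P distance
#'
#' Finds the reference individual nearest to the query (pairwise-deletion
#' K2P).  Below the threshold the query is assigned to that individual's
#' species; ties across species (to within numerical tolerance) are
#' reported as ambiguous; above the threshold the query is unassigned, a
#' putative new species.
#'
#' @param query Query sequence (string), aligned to the reference columns.
#' @param ref_aln Reference alignment matrix.
#' @param tax Taxonomy covering the reference ids.
#' @param threshold Assignment threshold in percent.
#' @param tol Absolute tie tolerance on the distance (substitutions/site).
#' @return List with `verdict` (`"assigned"`, `"ambiguous"` or
#'   `"unassigned"`), `species` (character vector), `distance` (percent)
#'   and `nearest_id`.
#' @export
identify_by_distance <- function(query, ref_aln, tax, threshold,
                                 tol = 1e-9) {
  ref_aln <- as_alignment(ref_aln)
  tx <- match_taxonomy(ref_aln, tax, allow_extra = TRUE)
  q <- if (length(query) == 1) strsplit(toupper(query), "")[[1]] else toupper(query)
  if (length(q) != ncol(ref_aln)) {
    stop("query length ", length(q), " does not match reference columns ",
         ncol(ref_aln))
  }
  d <- vapply(seq_len(nrow(ref_aln)),
              function(i) k2p(q, ref_aln[i, ])$d, numeric(1))
  if (all(is.na(d))) {
    stop("distance to every reference is undefined; cannot identify query")
  }
  dmin <- min(d, na.rm = TRUE)
  near <- which(!is.na(d) & d <= dmin + tol)
  sp <- unique(tx$species[near])
  if (dmin * 100 >= threshold) {
    list(verdict = "unassigned", species = character(0),
         distance = dmin * 100, nearest_id = rownames(ref_aln)[near[1]])
  } else if (length(sp) > 1) {
    list(verdict = "ambiguous", species = sort(sp), distance = dmin * 100,
         nearest_id = rownames(ref_aln)[near[1]])
  } else {
    list(verdict = "assigned", species = sp, distance = dmin * 100,
         nearest_id = rownames(ref_aln)[near[1]])
  }
}
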