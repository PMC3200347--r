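# Character-based (diagnostic-attribute) barcoding.
#
# A characteristic attribute (CA) is a nucleotide state at an alignment
# column found in one taxon and absent from every comparison taxon: "pure"
# when fixed in all members of the taxon, "private" when carried by only
# some members.  With species collapsed to flat one-vs-rest partitions,
# scanning every column against every taxon reproduces the CA discovery
# step of guide-tree diagnostic systems for species- and genus-level
# tables.  Gaps and N are treated as missing data, never as a fifth state.

IUPAC_PAIR <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Build a character matrix partitioned by taxon
#'
#' Restricts an alignment to the analysed individuals, partitions them by
#' the chosen rank, and drops columns consisting entirely of gaps
#' (recording the surviving original 1-based positions, which all reports
#' use).
#'
#' @param aln Alignment matrix.
#' @param tax Taxonomy data.frame covering the alignment.
#' @param rank Partitioning rank: `"species"` or `"genus"`.
#' @param taxa Optional subset of taxa to analyse (e.g. re-extracting
#'   barcodes for a small group of close congeners).
#' @return Object of class `character_matrix`: list with `mat` (character
#'   matrix), `positions` (original column numbers), `partition` (named
#'   list taxon -> ids) and `rank`.
#' @export
build_character_matrix <- function(aln, tax, rank = c("species", "genus"),
                                   taxa = NULL) {
  rank <- match.arg(rank)
  aln <- as_alignment(aln)
  tx <- match_taxonomy(aln, tax, allow_extra = TRUE)
  grp <- tx[[rank]]
  if (!is.null(taxa)) {
    keep <- grp %in% taxa
    if (!any(keep)) stop("no individuals left after subsetting to taxa")
    aln <- aln[keep, , drop = FALSE]
    grp <- grp[keep]
  }
  non_gap <- colSums(aln != "-") > 0
  mat <- aln[, non_gap, drop = FALSE]
  structure(list(mat = mat,
                 positions = which(non_gap),
                 partition = split(rownames(aln), grp),
                 rank = rank,
                 dropped_columns = which(!non_gap)),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character matrix: %d individuals, %d taxa (%s rank), %d columns\n",
              nrow(x$mat), length(x$partition), x$rank, ncol(x$mat)))
  invisible(x)
}

#' Find characteristic attributes
#'
#' Scans every column of the character matrix for diagnostic states.  At a
#' column, state s is a *pure* CA of taxon t when every member of t carries
#' s (a member gap/N therefore blocks purity) and no non-member carries s;
#' it is a *private* CA when at least one member carries s, no non-member
#' does, and it is not pure.  Absence is judged over observed states: a
#' gap or N in a non-member does not veto a CA.
#'
#' @param cm A [build_character_matrix()] object.
#' @param taxon Optional single taxon to restrict the result to.
#' @return data.frame with columns `taxon`, `position` (1-based, original
#'   alignment coordinates), `state`, `class` (`"pure"`/`"private"`).
#' @export
find_cas <- function(cm, taxon = NULL) {
  mat <- cm$mat
  taxa <- names(cm$partition)
  grp <- factor(rep(NA_character_, nrow(mat)), levels = taxa)
  for (t in taxa) grp[rownames(mat) %in% cm$partition[[t]]] <- t
  block_size <- as.vector(table(grp))

  res <- list()
  for (b in c("A", "C", "G", "T")) {
    hit <- (mat == b) * 1
    cnt <- rowsum(hit, grp)                 # taxon x column carrier counts
    tot <- colSums(hit)
    outside <- sweep(-cnt, 2, tot, `+`)     # carriers outside each taxon
    pure <- (cnt == block_size) & (outside == 0)
    priv <- (cnt >= 1) & (outside == 0) & !pure
    for (cls in c("pure", "private")) {
      w <- which(if (cls == "pure") pure else priv, arr.ind = TRUE)
      if (nrow(w) > 0) {
        res[[length(res) + 1]] <- data.frame(
          taxon = taxa[w[, 1]],
          position = cm$positions[w[, 2]],
          state = b, class = cls)
      }
    }
  }
  out <- if (length(res)) {
    do.call(rbind, res)
  } else {
    data.frame(taxon = character(0), position = integer(0),
               state = character(0), class = character(0))
  }
  out <- out[order(out$taxon, out$position, out$state), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(taxon)) {
    if (!taxon %in% taxa) stop("unknown taxon: ", taxon)
    out <- out[out$taxon == taxon, , drop = FALSE]
  }
  out
}

# Rendered state of a taxon at one matrix column: the shared nucleotide if
# members agree, an IUPAC code for two observed states, and a dash for
# three or more states (the non-significant convention of genus-level
# tables) or for all-missing.
render_state <- function(states) {
  s <- sort(unique(states[states != "-" & states != "N"]))
  if (length(s) == 0) {
    "-"
  } else if (length(s) == 1) {
    s
  } else if (length(s) == 2) {
    IUPAC_PAIR[[paste0(s[1], s[2])]]
  } else {
    "-"
  }
}

taxon_profile <- function(cm, cols) {
  taxa <- names(cm$partition)
  prof <- matrix("-", length(taxa), length(cols),
                 dimnames = list(taxa, cm$positions[cols]))
  for (t in taxa) {
    rows <- rownames(cm$mat) %in% cm$partition[[t]]
    for (k in seq_along(cols)) {
      prof[t, k] <- render_state(cm$mat[rows, cols[k]])
    }
  }
  prof
}

#' Select a diagnostic position set
#'
#' Greedy stand-in for the manual position choice of published character
#' barcode tables: (1) columns are ranked by their total pure-CA count
#' across taxa; (2) columns are added until every taxon has at least
#' `min_cas_per_taxon` pure CAs among the selected columns or has
#' exhausted its global CA supply; (3) if two taxa still share an
#' identical state vector, the column separating the most still-identical
#' pairs is added (ties to the lowest position) until all vectors are
#' unique or no separating column remains.  Shortfalls are reported, never
#' raised.
#'
#' @param cm A [build_character_matrix()] object.
#' @param min_cas_per_taxon Minimum pure CAs wanted per taxon (default 3).
#' @param max_positions Optional cap on the number of selected positions.
#' @return Object of class `diagnostic_profiles`: list with `rank`,
#'   `positions` (selected, ascending), `profile` (taxon x position state
#'   matrix), `cas` (CA table restricted to selected positions),
#'   `ca_counts` (pure CAs per taxon in the set), `shortfall`,
#'   `unique_combinations`, `min_cas`.
#' @export
select_diagnostics <- function(cm, min_cas_per_taxon = 3,
                               max_positions = Inf) {
  cas <- find_cas(cm)
  pure <- cas[cas$class == "pure", , drop = FALSE]
  taxa <- names(cm$partition)
  col_of <- match(pure$position, cm$positions)
  ncols <- ncol(cm$mat)

  # pure-CA count per column and per taxon x column
  col_score <- tabulate(col_of, nbins = ncols)
  supply <- table(factor(pure$taxon, levels = taxa))
  have <- stats::setNames(numeric(length(taxa)), taxa)

  selected <- integer(0)
  cas_in <- function(cols) {
    table(factor(pure$taxon[col_of %in% cols], levels = taxa))
  }
  repeat {
    if (length(selected) >= max_positions) break
    remaining <- pure[!(col_of %in% selected), , drop = FALSE]
    rem_supply <- table(factor(remaining$taxon, levels = taxa))
    short <- taxa[have < min_cas_per_taxon & rem_supply > 0]
    if (length(short) == 0) break
    cand <- sort(unique(match(remaining$position[remaining$taxon %in% short],
                              cm$positions)))
    best <- cand[order(-col_score[cand], cand)][1]
    selected <- c(selected, best)
    have <- cas_in(selected)
  }

  # ensure unique state vectors where possible
  repeat {
    if (length(selected) >= max_positions) break
    prof <- taxon_profile(cm, sort(selected))
    key <- if (length(selected) == 0) {
      rep("", length(taxa))
    } else {
      apply(prof, 1, paste0, collapse = "")
    }
    dup_groups <- split(seq_along(taxa), key)
    dup_groups <- dup_groups[lengths(dup_groups) > 1]
    if (length(dup_groups) == 0) break
    pairs <- do.call(rbind, lapply(dup_groups, function(g) {
      t(utils::combn(g, 2))
    }))
    cand <- setdiff(seq_len(ncols), selected)
    if (length(cand) == 0) break
    sep_count <- vapply(cand, function(j) {
      st <- vapply(taxa, function(t) {
        render_state(cm$mat[rownames(cm$mat) %in% cm$partition[[t]], j])
      }, character(1))
      sum(st[pairs[, 1]] != st[pairs[, 2]])
    }, numeric(1))
    if (max(sep_count) == 0) break
    best <- cand[order(-sep_count, cand)][1]
    selected <- c(selected, best)
  }

  selected <- sort(selected)
  prof <- taxon_profile(cm, selected)
  key <- if (length(selected) == 0) {
    rep("", length(taxa))
  } else {
    apply(prof, 1, paste0, collapse = "")
  }
  uniq <- length(selected) > 0 && !anyDuplicated(key)
  if (length(taxa) == 1) uniq <- TRUE
  counts <- cas_in(selected)
  sel_pos <- cm$positions[selected]
  structure(list(rank = cm$rank,
                 positions = sel_pos,
                 profile = prof,
                 cas = cas[cas$position %in% sel_pos, , drop = FALSE],
                 ca_counts = stats::setNames(as.integer(counts), taxa),
                 shortfall = stats::setNames(
                   pmax(0, min_cas_per_taxon - as.integer(counts)), taxa),
                 unique_combinations = uniq,
                 min_cas = min_cas_per_taxon),
            class = "diagnostic_profiles")
}

#' @export
print.diagnostic_profiles <- function(x, ...) {
  cat(sprintf("diagnostic profile set (%s rank): %d taxa, %d positions\n",
              x$rank, nrow(x$profile), length(x$positions)))
  cat(sprintf("  unique combinations: %s; min pure CAs per taxon: %d\n",
              x$unique_combinations, min(x$ca_counts)))
  invisible(x)
}

#' Diagnose a query against a diagnostic profile set
#'
#' Scores each taxon by the number of its pure CAs (at the selected
#' positions) whose state the query matches.  The top taxon is declared
#' only when its score reaches `min_cas` and strictly exceeds the
#' runner-up; otherwise the verdict is ambiguous with the tied taxa
#' listed.  Private CAs can be scored too, but pure CAs are the
#' identification currency by default.
#'
#' @param query Query sequence (string or character vector) in the same
#'   coordinate system as the original alignment.
#' @param profiles A [select_diagnostics()] object.
#' @param min_cas Score needed to declare an identification (defaults to
#'   the profile set's `min_cas`).
#' @param include_private Also score private CAs.
#' @return List with `verdict` (`"assigned"`/`"ambiguous"`), `taxon`,
#'   `tied` (taxa sharing the top score when ambiguous) and `scores`
#'   (data.frame, ranked).
#' @export
diagnose <- function(query, profiles, min_cas = profiles$min_cas,
                     include_private = FALSE) {
  q <- if (length(query) == 1) strsplit(toupper(query), "")[[1]] else toupper(query)
  if (length(profiles$positions) > 0 &&
      length(q) < max(profiles$positions)) {
    stop("query of length ", length(q),
         " is shorter than the largest diagnostic position ",
         max(profiles$positions))
  }
  cas <- profiles$cas
  if (!include_private) {
    cas <- cas[cas$class == "pure", , drop = FALSE]
  }
  taxa <- rownames(profiles$profile)
  hit <- cas[q[cas$position] == cas$state, , drop = FALSE]
  score <- table(factor(hit$taxon, levels = taxa))
  scores <- data.frame(taxon = taxa, score = as.integer(score))
  scores <- scores[order(-scores$score, scores$taxon), , drop = FALSE]
  rownames(scores) <- NULL
  top <- scores$score[1]
  runner <- if (nrow(scores) > 1) scores$score[2] else 0L
  if (top >= min_cas && top > runner) {
    list(verdict = "assigned", taxon = scores$taxon[1],
         tied = character(0), scores = scores)
  } else {
    list(verdict = "ambiguous", taxon = NA_character_,
         tied = scores$taxon[scores$score == top], scores = scores)
  }
}

#' Character-barcode table
#'
#' Renders a diagnostic profile set as the familiar barcode table: one row
#' per taxon, one column per selected 1-based position, cells holding the
#' taxon's state (IUPAC code for two observed states, dash for three or
#' more -- the non-significant convention -- or all-missing), a final
#' column of pure-CA counts, and a parallel flag matrix marking cells that
#' are CAs of their row taxon (`"pure"`/`"private"`).
#'
#' @param profiles A [select_diagnostics()] object.
#' @return List with `table` (data.frame ready for [write_table()]) and
#'   `flags` (character matrix).
#' @export
barcode_table <- function(profiles) {
  prof <- profiles$profile
  taxa <- rownames(prof)
  tab <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  for (k in seq_along(profiles$positions)) {
    tab[[paste0("p", profiles$positions[k])]] <- prof[, k]
  }
  tab$n_cas <- as.integer(profiles$ca_counts[taxa])
  flags <- matrix("", nrow(prof), ncol(prof), dimnames = dimnames(prof))
  cas <- profiles$cas
  for (i in seq_len(nrow(cas))) {
    k <- match(cas$position[i], profiles$positions)
    cur <- flags[cas$taxon[i], k]
    if (cur != "pure") {  # pure outranks private in the display
      flags[cas$taxon[i], k] <- cas$class[i]
    }
  }
  list(table = tab, flags = flags)
}
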