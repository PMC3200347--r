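# Orchestration of the three-method comparison on one barcode library.

#' Run the full three-method barcoding comparison
#'
#' Executes, on one aligned barcode library plus taxonomy: (1) the
#' distance analyses -- K2P matrix, rank-stratified divergence summary,
#' barcoding-gap report, 10x-rule threshold and species lumping under both
#' lumping criteria; (2) the tree analyses -- NJ with bootstrap supports,
#' outgroup rooting and species/genus monophyly assessment; (3) the
#' character analyses -- CA discovery and diagnostic position selection at
#' species and genus rank.  A 16S-like mode applies the conserved-block
#' filter first.
#'
#' Per-method species-resolution tallies use explicit denominators, since
#' the three methods count over different species subsets: distance
#' resolves a species when it is not lumped at the threshold
#' (nearest-neighbour criterion); monophyly resolves a species when it is
#' monophyletic, counted among species with at least two individuals;
#' character barcoding resolves a species when its state vector is unique
#' and it has at least `min_cas` pure CAs.
#'
#' @param aln Alignment matrix or named sequence vector (see
#'   [as_alignment()]).
#' @param tax Taxonomy data.frame covering every sequence.
#' @param outgroup Character vector of outgroup sequence ids (excluded
#'   from distance and character analyses, used to root the tree); `NULL`
#'   to skip rooting (monophyly is then read off the NJ tree as returned).
#' @param n_boot Bootstrap pseudoreplicates for node support (0 skips the
#'   bootstrap).
#' @param seed Seed for the bootstrap resampling stream.
#' @param threshold Identification threshold in percent; `NULL` applies
#'   the 10x rule.
#' @param min_cas Minimum pure CAs per species for the character method.
#' @param apply_gblocks Run [gblocks_filter()] first (16S-like loci).
#' @param gb_params Parameters for the block filter.
#' @param bin_width Histogram bin width (percent) for the gap report.
#' @return Object of class `barcode_comparison`: a list of all
#'   sub-reports plus `resolution` (the per-method tallies) and `meta`.
#' @export
run_comparison <- function(aln, tax, outgroup = NULL, n_boot = 100,
                           seed = 1, threshold = NULL, min_cas = 3,
                           apply_gblocks = FALSE,
                           gb_params = gblocks_params(), bin_width = 1) {
  aln <- as_alignment(aln)
  tax <- match_taxonomy(aln, tax)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  trimming <- NULL
  if (apply_gblocks) {
    trimming <- stage("gblocks", gblocks_filter(aln, gb_params))
    aln <- trimming$alignment
    if (ncol(aln) == 0) {
      stop("stage 'gblocks' removed every column; nothing to analyse")
    }
  }

  ingroup_ids <- setdiff(rownames(aln), outgroup)
  ing <- aln[ingroup_ids, , drop = FALSE]
  ing_tax <- tax[match(ingroup_ids, tax$id), , drop = FALSE]
  n_species <- length(unique(ing_tax$species))

  dm <- stage("distances", distance_matrix(ing))
  ranks <- stage("rank_summary", rank_summary(dm, ing_tax))
  gaps <- stage("gap_report", gap_report(dm, ing_tax, bin_width))
  thr <- if (is.null(threshold)) {
    stage("threshold", ten_x_threshold(dm, ing_tax))
  } else {
    threshold
  }
  rule <- if (is.null(threshold)) "10x" else "user"
  lump_nn <- stage("lumping",
                   lumping(dm, ing_tax, thr, criterion = "nearest",
                           rule = rule))
  lump_mean <- stage("lumping",
                     lumping(dm, ing_tax, thr, criterion = "mean",
                             rule = rule))

  tree <- NULL
  monophyly <- NULL
  monophyly_genus <- NULL
  if (nrow(aln) >= 3) {
    tree <- stage("tree", {
      if (n_boot > 0) {
        bootstrap_support(aln, n_reps = n_boot, seed = seed)
      } else {
        neighbor_joining(distance_matrix(aln))
      }
    })
    if (!is.null(outgroup)) {
      tree <- stage("rooting", root_with_outgroup(tree, outgroup))
    }
    monophyly <- stage("monophyly", assess_monophyly(tree, tax, "species"))
    monophyly_genus <- stage("monophyly",
                             assess_monophyly(tree, tax, "genus"))
  }

  cm <- stage("characters", build_character_matrix(ing, ing_tax, "species"))
  profiles <- stage("characters",
                    select_diagnostics(cm, min_cas_per_taxon = min_cas))
  cm_genus <- stage("characters",
                    build_character_matrix(ing, ing_tax, "genus"))
  profiles_genus <- stage("characters",
                          select_diagnostics(cm_genus,
                                             min_cas_per_taxon = min_cas))

  # per-method tallies over explicit denominators
  key <- apply(profiles$profile, 1, paste0, collapse = "")
  vec_unique <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  char_resolved <- sum(vec_unique & profiles$ca_counts >= min_cas)
  dist_resolved <- n_species - length(lump_nn$lumped_species)
  mono_sub <- if (is.null(monophyly)) {
    NULL
  } else {
    monophyly[monophyly$taxon %in% ing_tax$species &
                monophyly$status != "singleton", , drop = FALSE]
  }
  resolution <- data.frame(
    method = c("distance", "monophyly", "character"),
    resolved = c(dist_resolved,
                 if (is.null(mono_sub)) NA_integer_
                 else sum(mono_sub$status == "monophyletic"),
                 char_resolved),
    denominator = c(n_species,
                    if (is.null(mono_sub)) NA_integer_ else nrow(mono_sub),
                    n_species),
    denominator_def = c("all species",
                        "species with >= 2 individuals",
                        "all species"))

  structure(list(trimming = trimming,
                 distance = list(matrix = dm, rank_summary = ranks,
                                 gap = gaps, threshold = thr, rule = rule,
                                 lumping_nearest = lump_nn,
                                 lumping_mean = lump_mean),
                 tree = tree,
                 monophyly = monophyly,
                 monophyly_genus = monophyly_genus,
                 character = list(species = profiles,
                                  genus = profiles_genus),
                 resolution = resolution,
                 meta = list(seed = seed, n_boot = n_boot,
                             min_cas = min_cas, outgroup = outgroup,
                             n_sequences = nrow(aln),
                             n_species = n_species)),
            class = "barcode_comparison")
}

#' @export
print.barcode_comparison <- function(x, ...) {
  cat(sprintf("Barcode method comparison: %d sequences, %d species\n",
              x$meta$n_sequences, x$meta$n_species))
  ws <- x$distance$rank_summary[1, ]
  if (!is.na(ws$average)) {
    cat(sprintf("  mean intraspecific divergence: %.2f%% (max %.2f%%)\n",
                ws$average, ws$maximum))
  }
  cat(sprintf("  threshold (%s rule): %.2f%%; lumped species: %d/%d\n",
              x$distance$rule, x$distance$threshold,
              length(x$distance$lumping_nearest$lumped_species),
              x$meta$n_species))
  cat(sprintf("  global barcoding gap: %s\n", x$distance$gap$global_gap))
  for (i in seq_len(nrow(x$resolution))) {
    r <- x$resolution[i, ]
    cat(sprintf("  %-10s resolved %s / %s (%s)\n", r$method,
                r$resolved, r$denominator, r$denominator_def))
  }
  invisible(x)
}

#' Identify query sequences against a reference library
#'
#' Dispatches each query to the distance method
#' ([identify_by_distance()]) or the character method ([diagnose()]).
#' Queries must be aligned to the reference columns; a query of the wrong
#' length yields an error row, and the run continues.
#'
#' @param queries Named character vector of query sequences.
#' @param ref_aln Reference alignment matrix.
#' @param tax Reference taxonomy.
#' @param method `"distance"` or `"character"`.
#' @param threshold Distance threshold in percent (distance method).
#' @param profiles A [select_diagnostics()] object (character method);
#'   computed from the references when `NULL`.
#' @param min_cas Minimum score for a character assignment.
#' @return data.frame with one row per query: `query`, `verdict`,
#'   `taxon`, `evidence` (distance in percent or CA score), `detail`.
#' @export
identify_query <- function(queries, ref_aln, tax,
                           method = c("distance", "character"),
                           threshold = NULL, profiles = NULL,
                           min_cas = 3) {
  method <- match.arg(method)
  ref_aln <- as_alignment(ref_aln)
  if (length(queries) == 0) {
    return(data.frame(query = character(0), verdict = character(0),
                      taxon = character(0), evidence = numeric(0),
                      detail = character(0)))
  }
  if (method == "distance" && is.null(threshold)) {
    threshold <- ten_x_threshold(distance_matrix(ref_aln),
                                 match_taxonomy(ref_aln, tax,
                                                allow_extra = TRUE))
  }
  if (method == "character" && is.null(profiles)) {
    cm <- build_character_matrix(ref_aln,
                                 match_taxonomy(ref_aln, tax,
                                                allow_extra = TRUE),
                                 "species")
    profiles <- select_diagnostics(cm, min_cas_per_taxon = min_cas)
  }
  rows <- lapply(names(queries), function(qid) {
    res <- tryCatch({
      if (method == "distance") {
        r <- identify_by_distance(queries[[qid]], ref_aln, tax, threshold)
        data.frame(query = qid, verdict = r$verdict,
                   taxon = paste(r$species, collapse = ","),
                   evidence = r$distance,
                   detail = paste0("nearest=", r$nearest_id))
      } else {
        r <- diagnose(queries[[qid]], profiles, min_cas = min_cas)
        data.frame(query = qid, verdict = r$verdict,
                   taxon = if (is.na(r$taxon)) {
                     paste(r$tied, collapse = ",")
                   } else {
                     r$taxon
                   },
                   evidence = r$scores$score[1],
                   detail = paste0("runner_up=",
                                   if (nrow(r$scores) > 1) {
                                     r$scores$score[2]
                                   } else {
                                     0
                                   }))
      }
    }, error = function(e) {
      data.frame(query = qid, verdict = "error", taxon = NA_character_,
                 evidence = NA_real_, detail = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the comparison report to a directory
#'
#' Emits the TSV surfaces of a [run_comparison()] result: the rank
#' summary, gap histogram and per-species gap table, lumping report,
#' monophyly reports, species/genus barcode tables, the resolution tally
#' and a JSON manifest of run metadata.
#'
#' @param report A `barcode_comparison` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- report$distance
  write_table(d$rank_summary, file.path(dir, "rank_summary.tsv"))
  write_table(d$gap$per_species, file.path(dir, "gap_species.tsv"))
  write_table(d$gap$histogram, file.path(dir, "gap_histogram.tsv"))
  write_table(d$lumping_nearest$per_species,
              file.path(dir, "lumping.tsv"))
  if (!is.null(report$monophyly)) {
    write_table(report$monophyly, file.path(dir, "monophyly_species.tsv"))
    write_table(report$monophyly_genus,
                file.path(dir, "monophyly_genus.tsv"))
    ape::write.tree(report$tree, file.path(dir, "nj_tree.nwk"))
  }
  write_table(barcode_table(report$character$species)$table,
              file.path(dir, "barcode_species.tsv"))
  write_table(barcode_table(report$character$genus)$table,
              file.path(dir, "barcode_genus.tsv"))
  write_table(report$resolution, file.path(dir, "resolution.tsv"))
  jsonlite::write_json(
    c(report$meta,
      list(threshold = d$threshold, rule = d$rule,
           global_gap = d$gap$global_gap,
           lumped_fraction = d$lumping_nearest$lumped_fraction)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
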