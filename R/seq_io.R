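# Sequence, alignment and taxonomy input/output.
#
# Sequences live as named character strings over {A,C,G,T,N,-}; an alignment
# is a character matrix (rows = sequences, columns = positions, rownames =
# ids).  Column indices are 0-free here: everything user-facing is 1-based.

DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Read sequences from a FASTA file
#'
#' Parses a (possibly line-folded) FASTA file into a named character vector
#' of upper-cased sequences.  The id of each record is the header token
#' before the first whitespace.  The alphabet is restricted to
#' `A, C, G, T, N, -`; anything else is rejected with its position, so that
#' malformed input never propagates silently into a distance or character
#' analysis.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are record ids, values sequences.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "AC", "GT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("empty FASTA file: ", path)
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    stop("not a FASTA file (first non-blank line must start with '>'): ", path)
  }
  ids <- sub("^>\\s*", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) {
    stop("FASTA entry with an empty id in ", path)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  entry <- cumsum(is_hdr)
  body <- split(lines[!is_hdr], factor(entry[!is_hdr], levels = seq_along(ids)))
  seqs <- vapply(body, paste0, character(1), collapse = "")
  seqs <- toupper(gsub("[[:space:]]", "", seqs))
  names(seqs) <- ids
  empty <- ids[!nzchar(seqs)]
  if (length(empty) > 0) {
    stop("empty sequence for id(s): ", paste(empty, collapse = ", "))
  }
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN-]", seqs[[i]])
    if (bad != -1L) {
      stop(sprintf("illegal character '%s' in sequence '%s' at position %d",
                   substr(seqs[[i]], bad, bad), ids[i], bad))
    }
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' Accepts either a named character vector of sequences or an alignment
#' matrix (see [as_alignment()]).  `read_fasta(write_fasta(x))` round-trips.
#'
#' @param seqs Named character vector, or character matrix with rownames.
#' @param path Output path.
#' @param width Line width used to fold sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.matrix(seqs)) {
    seqs <- alignment_to_strings(seqs)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Convert sequences to an alignment matrix
#'
#' @param seqs Named character vector of equal-length sequences.
#' @return Character matrix, rows = sequences (rownames = ids), columns =
#'   alignment positions.
#' @export
as_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    return(seqs)
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named")
  }
  len <- nchar(seqs)
  if (length(unique(len)) != 1) {
    stop("sequences have unequal lengths (",
         paste(range(len), collapse = "-"),
         "); an alignment requires identical lengths")
  }
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

alignment_to_strings <- function(aln) {
  s <- apply(aln, 1, paste0, collapse = "")
  names(s) <- rownames(aln)
  s
}

#' Read a taxonomy table
#'
#' Reads a tab-separated table with columns `id`, `species`, `genus`,
#' `family`, `order` and validates the taxonomic hierarchy: a species must
#' map to exactly one genus and a genus to exactly one family.
#'
#' @param path Path to a TSV file with a header row.
#' @return A `data.frame` with the five required columns.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_taxonomy(tax)
}

#' @rdname read_taxonomy
#' @param tax A data.frame to validate in place of a file.
#' @export
validate_taxonomy <- function(tax) {
  required <- c("id", "species", "genus", "family", "order")
  missing <- setdiff(required, names(tax))
  if (length(missing) > 0) {
    stop("taxonomy table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  dup <- unique(tax$id[duplicated(tax$id)])
  if (length(dup) > 0) {
    stop("duplicate id(s) in taxonomy table: ", paste(dup, collapse = ", "))
  }
  check_one_parent(tax, "species", "genus")
  check_one_parent(tax, "genus", "family")
  tax[required]
}

check_one_parent <- function(tax, child, parent) {
  parents <- tapply(tax[[parent]], tax[[child]],
                    function(x) length(unique(x)))
  bad <- names(parents)[parents > 1]
  if (length(bad) > 0) {
    stop(sprintf("%s '%s' mapped to more than one %s",
                 child, paste(bad, collapse = "', '"), parent))
  }
  invisible(tax)
}

#' Join an alignment with its taxonomy
#'
#' Checks that every aligned record has a taxonomy row and (by default)
#' that the taxonomy has no orphan rows absent from the alignment.
#'
#' @param aln Alignment matrix.
#' @param tax Taxonomy data.frame (see [read_taxonomy()]).
#' @param allow_extra Allow taxonomy rows for ids not in the alignment.
#' @return The taxonomy rows reordered to match the alignment rows.
#' @export
match_taxonomy <- function(aln, tax, allow_extra = FALSE) {
  ids <- rownames(aln)
  absent <- setdiff(ids, tax$id)
  if (length(absent) > 0) {
    stop("aligned id(s) missing from taxonomy: ",
         paste(absent, collapse = ", "))
  }
  orphan <- setdiff(tax$id, ids)
  if (!allow_extra && length(orphan) > 0) {
    stop("taxonomy row(s) with no aligned sequence (orphans): ",
         paste(orphan, collapse = ", "))
  }
  tax[match(ids, tax$id), , drop = FALSE]
}

#' Write a report table as TSV
#'
#' @param report A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
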