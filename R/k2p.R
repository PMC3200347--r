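# Kimura 2-parameter distances.
#
# The K2P model separates transitions (A<->G, C<->T, proportion P of
# compared sites) from transversions (proportion Q) and corrects for
# multiple hits:
#
#   d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)
#
# Sites where either sequence carries a gap or N are excluded pair by pair
# (pairwise deletion), matching the MEGA convention for barcode datasets;
# complete deletion (drop every column with any missing state) is available
# as an option.

BASE_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L)
TRANSITION_PARTNER <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T

encode_alignment <- function(aln) {
  m <- matrix(BASE_CODES[aln], nrow = nrow(aln),
              dimnames = list(rownames(aln), NULL))
  m
}

k2p_from_counts <- function(n_sites, ts, tv) {
  if (n_sites == 0) {
    return(list(n_sites = 0L, P = NA_real_, Q = NA_real_, d = NA_real_,
                flag = "no_sites"))
  }
  P <- ts / n_sites
  Q <- tv / n_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(n_sites = n_sites, P = P, Q = Q, d = NA_real_,
                flag = "saturated"))
  }
  list(n_sites = n_sites, P = P, Q = Q,
       d = -0.5 * log(w1) - 0.25 * log(w2), flag = NA_character_)
}

#' Kimura 2-parameter distance between two sequences
#'
#' Compares two equal-length sequences under pairwise deletion (columns
#' where either sequence has `-` or `N` are skipped) and returns the
#' transition proportion `P`, transversion proportion `Q` and the K2P
#' distance `d` in substitutions per site.  When the log arguments are
#' non-positive the distance is undefined and flagged `"saturated"`; with
#' no comparable sites it is flagged `"no_sites"`.
#'
#' @param seq_a,seq_b Sequences as strings or character vectors of single
#'   characters over `A,C,G,T,N,-`.
#' @return List with `n_sites`, `P`, `Q`, `d` and `flag` (`NA` when `d` is
#'   defined).
#' @examples
#' k2p("AAAA", "GAAA")$d  # -0.5 * log(0.5)
#' @export
k2p <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1) strsplit(toupper(seq_a), "")[[1]] else toupper(seq_a)
  b <- if (length(seq_b) == 1) strsplit(toupper(seq_b), "")[[1]] else toupper(seq_b)
  if (length(a) != length(b)) {
    stop("sequences differ in length (", length(a), " vs ", length(b), ")")
  }
  ca <- BASE_CODES[a]
  cb <- BASE_CODES[b]
  ok <- !is.na(ca) & !is.na(cb)
  n_sites <- sum(ok)
  diff <- ok & ca != cb
  ts <- sum(diff & TRANSITION_PARTNER[ca] == cb, na.rm = TRUE)
  tv <- sum(diff) - ts
  k2p_from_counts(n_sites, ts, tv)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' Computes all unordered pairs of [k2p()] distances.  Undefined pairs
#' (saturated or no shared sites) are flagged, never silently replaced by a
#' number; downstream summaries exclude them and the tree builder refuses
#' them explicitly.
#'
#' @param aln Alignment matrix (see [as_alignment()]).
#' @param deletion `"pairwise"` (default) or `"complete"` (drop every
#'   column containing any gap or N before comparing).
#' @return An object of class `k2p_matrix`: list with `ids`, `d` (distance
#'   matrix, zero diagonal), `P`, `Q`, `n_sites`, `undefined` (logical
#'   matrix), `flag` (character matrix of reasons) and `deletion`.
#' @export
distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  aln <- as_alignment(aln)
  if (nrow(aln) < 2) {
    stop("distance_matrix needs at least 2 sequences")
  }
  enc <- encode_alignment(aln)
  if (deletion == "complete") {
    keep <- colSums(is.na(enc)) == 0
    enc <- enc[, keep, drop = FALSE]
  }
  n <- nrow(enc)
  ids <- rownames(aln)

  # one-hot crossproducts: counts of site patterns for every pair at once
  X <- lapply(1:4, function(b) {
    x <- (enc == b)
    x[is.na(x)] <- FALSE
    storage.mode(x) <- "double"
    x
  })
  V <- Reduce(`+`, X)                    # determinate-site indicator
  n_sites <- tcrossprod(V)               # shared determinate sites
  match_ct <- Reduce(`+`, lapply(X, tcrossprod))
  ts_ct <- tcrossprod(X[[1]], X[[3]]) + tcrossprod(X[[3]], X[[1]]) +
    tcrossprod(X[[2]], X[[4]]) + tcrossprod(X[[4]], X[[2]])
  tv_ct <- n_sites - match_ct - ts_ct

  P <- ifelse(n_sites > 0, ts_ct / n_sites, NA_real_)
  Q <- ifelse(n_sites > 0, tv_ct / n_sites, NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- ifelse(!is.na(w1) & w1 > 0 & w2 > 0,
              -0.5 * log(pmax(w1, 1e-300)) - 0.25 * log(pmax(w2, 1e-300)),
              NA_real_)
  flag <- matrix(NA_character_, n, n)
  flag[n_sites == 0] <- "no_sites"
  flag[is.na(d) & n_sites > 0] <- "saturated"
  diag(d) <- 0
  diag(P) <- 0
  diag(Q) <- 0
  diag(flag) <- NA_character_
  undefined <- is.na(d)
  dimnames(d) <- dimnames(P) <- dimnames(Q) <- dimnames(n_sites) <-
    dimnames(undefined) <- dimnames(flag) <- list(ids, ids)
  structure(list(ids = ids, d = d, P = P, Q = Q,
                 n_sites = n_sites, undefined = undefined, flag = flag,
                 deletion = deletion),
            class = "k2p_matrix")
}

#' @export
as.matrix.k2p_matrix <- function(x, ...) x$d

#' @export
print.k2p_matrix <- function(x, ...) {
  n <- length(x$ids)
  n_undef <- sum(x$undefined[upper.tri(x$undefined)])
  cat(sprintf("K2P distance matrix: %d sequences, %d pairs (%s deletion)\n",
              n, n * (n - 1) / 2, x$deletion))
  if (n_undef > 0) {
    cat(sprintf("  %d pair(s) undefined (saturated or no shared sites)\n",
                n_undef))
  }
  dd <- x$d[upper.tri(x$d)]
  if (any(!is.na(dd))) {
    cat(sprintf("  distances: min %.4f, mean %.4f, max %.4f\n",
                min(dd, na.rm = TRUE), mean(dd, na.rm = TRUE),
                max(dd, na.rm = TRUE)))
  }
  invisible(x)
}
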