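# Neighbour-joining trees, bootstrap supports and monophyly assessment.
#
# Trees are `ape::phylo` objects throughout, so they serialize to and from
# newick losslessly and interoperate with the rest of the R phylogenetics
# stack.  The NJ agglomeration is implemented here because its determinism
# contract (lexicographic tie-break, clamped negative limbs with a logged
# deficit, explicit refusal of undefined distances) is part of the method
# comparison; `ape::nj` serves as an independent cross-check in the test
# suite.

fmt_len <- function(x) sprintf("%.12g", x)

#' Neighbour-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step join the pair (i, j)
#' minimizing `Q(i,j) = (r - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`,
#' with limb lengths from the standard formulas.  Ties on Q are broken by
#' joining the pair whose (sorted) smallest member labels are
#' lexicographically smallest, so results are reproducible across
#' platforms.  Negative limb lengths are clamped to zero; the total clamped
#' deficit is attached as attribute `"clamped_total"`.  The result is
#' unrooted (trifurcating root) for >= 3 taxa.
#'
#' @param dm A [distance_matrix()] object or a symmetric numeric matrix
#'   with dimnames.  Undefined (flagged) entries are an error listing the
#'   offending pairs.
#' @return An `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "k2p_matrix")) {
    und <- which(dm$undefined & upper.tri(dm$undefined), arr.ind = TRUE)
    if (nrow(und) > 0) {
      pairs <- apply(und, 1, function(ij) {
        paste(dm$ids[ij[1]], dm$ids[ij[2]], sep = "/")
      })
      stop("undefined distance(s) for pair(s): ",
           paste(pairs, collapse = ", "))
    }
    D <- dm$d
    labels <- dm$ids
  } else {
    D <- as.matrix(dm)
    labels <- rownames(D)
    if (is.null(labels)) stop("distance matrix must have dimnames")
    if (anyNA(D)) stop("distance matrix contains NA entries")
  }
  m <- nrow(D)
  if (m < 2) stop("neighbor_joining needs at least 2 taxa")

  clamp <- function(x) {
    clamped_total <<- clamped_total + max(0, -x)
    max(x, 0)
  }
  clamped_total <- 0
  node_str <- labels   # newick fragment per active node
  min_lab <- labels    # smallest original label in each active cluster

  while (length(node_str) > 3) {
    mm <- nrow(D)
    r <- rowSums(D)
    Q <- (mm - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-10 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(min_lab[cand[, 1]], min_lab[cand[, 2]])
    key2 <- pmax(min_lab[cand[, 1]], min_lab[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]
    j <- cand[pick, 2]
    dij <- D[i, j]
    li <- clamp(dij / 2 + (r[i] - r[j]) / (2 * (mm - 2)))
    lj <- clamp(dij - (dij / 2 + (r[i] - r[j]) / (2 * (mm - 2))))
    new_d <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(mm), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_d[keep]),
               c(new_d[keep], 0))
    node_str <- c(node_str[keep],
                  sprintf("(%s:%s,%s:%s)", node_str[i], fmt_len(li),
                          node_str[j], fmt_len(lj)))
    min_lab <- c(min_lab[keep], min(min_lab[i], min_lab[j]))
  }

  if (length(node_str) == 3) {
    l1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
    l2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
    l3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                   node_str[1], fmt_len(l1), node_str[2], fmt_len(l2),
                   node_str[3], fmt_len(l3))
  } else {
    h <- clamp(D[1, 2] / 2)
    nwk <- sprintf("(%s:%s,%s:%s);",
                   node_str[1], fmt_len(h), node_str[2], fmt_len(h))
  }
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped_total") <- clamped_total
  tree
}

#' Bootstrap supports for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement (one draw of `ncol(aln)`
#' columns per pseudoreplicate, in replicate order from a single seeded
#' stream), recomputes the K2P + NJ tree per replicate, and attaches to
#' each internal node of the full-data tree the percentage of replicates
#' recovering its bipartition.  Replicates whose distance matrix contains
#' an undefined entry are dropped and counted; more than 50% dropped is an
#' error.  Supports are attached to bipartitions (internal node labels
#' survive rerooting via `edgelabel`).
#'
#' @param aln Alignment matrix.
#' @param n_reps Number of bootstrap pseudoreplicates (>= 1).
#' @param seed Optional integer seed; a seeded run is exactly reproducible.
#' @param deletion Passed to [distance_matrix()].
#' @return The NJ tree of the full alignment with `node.label` holding
#'   supports in percent (`NA` on the root, whose bipartition is trivial),
#'   and attributes `n_used`, `n_dropped`, `seed`.
#' @export
bootstrap_support <- function(aln, n_reps = 100, seed = NULL,
                              deletion = "pairwise") {
  if (n_reps < 1) stop("n_reps must be >= 1")
  aln <- as_alignment(aln)
  if (!is.null(seed)) set.seed(seed)
  dm <- distance_matrix(aln, deletion)
  tree0 <- neighbor_joining(dm)
  L <- ncol(aln)
  trees <- vector("list", n_reps)
  used <- 0
  dropped <- 0
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    dmb <- distance_matrix(aln[, cols, drop = FALSE], deletion)
    if (any(dmb$undefined[upper.tri(dmb$undefined)])) {
      dropped <- dropped + 1
      next
    }
    used <- used + 1
    trees[[used]] <- neighbor_joining(dmb)
  }
  if (dropped > n_reps / 2) {
    stop(dropped, " of ", n_reps,
         " bootstrap replicates had undefined distances (> 50%)")
  }
  trees <- trees[seq_len(used)]
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(tree0, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / used
  support[1] <- NA  # root: trivial bipartition
  tree0$node.label <- support
  attr(tree0, "n_used") <- used
  attr(tree0, "n_dropped") <- dropped
  attr(tree0, "seed") <- seed
  tree0
}

#' Root a tree on a designated outgroup
#'
#' Roots on the edge separating the outgroup leaves from the rest.  If the
#' outgroup does not form a bipartition of the unrooted tree the call fails
#' and names the intruding leaves.  Node labels (bootstrap supports) stay
#' attached to their bipartitions.
#'
#' @param tree An `ape::phylo` tree.
#' @param outgroup Character vector of outgroup leaf ids (proper subset of
#'   the leaves).
#' @return A rooted `ape::phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  tips <- tree$tip.label
  unknown <- setdiff(outgroup, tips)
  if (length(unknown) > 0) {
    stop("unknown outgroup id(s): ", paste(unknown, collapse = ", "))
  }
  if (length(outgroup) == 0) stop("empty outgroup")
  if (setequal(outgroup, tips)) {
    stop("outgroup cannot contain every leaf")
  }
  if (length(outgroup) > 1) {
    ingroup <- setdiff(tips, outgroup)
    rt <- ape::root(tree, outgroup = outgroup[1], resolve.root = TRUE)
    clade <- clade_tips(rt, ape::getMRCA(rt, ingroup))
    if (length(setdiff(clade, ingroup)) > 0) {
      rt2 <- ape::root(tree, outgroup = ingroup[1], resolve.root = TRUE)
      intr <- setdiff(clade_tips(rt2, ape::getMRCA(rt2, outgroup)),
                      outgroup)
      stop("outgroup is not monophyletic; intruding leaves: ",
           paste(intr, collapse = ", "))
    }
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
            edgelabel = TRUE)
}

clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    return(tree$tip.label[node])
  }
  ape::extract.clade(tree, node)$tip.label
}

#' Assess per-taxon monophyly on a rooted tree
#'
#' For every taxon at the chosen rank with at least two leaves, finds the
#' MRCA of its leaves and declares the taxon monophyletic iff the MRCA
#' clade contains no other leaves; otherwise the intruding leaf ids are
#' listed.  Single-leaf taxa are `singleton` (their monophyly and support
#' are undefined).  The reported support is the MRCA's node label where
#' one exists (see [bootstrap_support()]).
#'
#' @param tree Rooted `ape::phylo` tree.
#' @param tax Taxonomy data.frame covering every leaf.
#' @param rank Column of `tax` defining the taxa (`"species"`, `"genus"`,
#'   `"family"`).
#' @return data.frame with one row per taxon: `taxon`, `rank`,
#'   `n_individuals`, `status`, `support`, `intruders` (comma-separated).
#' @export
assess_monophyly <- function(tree, tax, rank = "species") {
  tips <- tree$tip.label
  tx <- tax[match(tips, tax$id), , drop = FALSE]
  if (anyNA(tx$id)) {
    stop("leaf id(s) missing from taxonomy: ",
         paste(setdiff(tips, tax$id), collapse = ", "))
  }
  groups <- split(tips, tx[[rank]])
  ntip <- length(tips)
  labels <- tree$node.label
  rows <- lapply(names(groups), function(taxon) {
    lv <- groups[[taxon]]
    if (length(lv) == 1) {
      return(data.frame(taxon = taxon, rank = rank, n_individuals = 1L,
                        status = "singleton", support = NA_real_,
                        intruders = ""))
    }
    mrca <- ape::getMRCA(tree, lv)
    clade <- clade_tips(tree, mrca)
    intr <- setdiff(clade, lv)
    supp <- if (is.null(labels)) {
      NA_real_
    } else {
      suppressWarnings(as.numeric(labels[mrca - ntip]))
    }
    data.frame(taxon = taxon, rank = rank, n_individuals = length(lv),
               status = if (length(intr) > 0) "non_monophyletic"
                        else "monophyletic",
               support = supp,
               intruders = paste(intr, collapse = ","))
  })
  do.call(rbind, rows)
}
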