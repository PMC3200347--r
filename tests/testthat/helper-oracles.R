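# Shared fixtures and independent brute-force oracles.

# three-species toy with two pure CAs: (Y, 1, T) and (X, 4, T)
toy_xyz <- function() {
  aln <- as_alignment(c(x1 = "ACGT", x2 = "ACGT",
                        y1 = "TCGA", y2 = "TCGA",
                        z1 = "ACGA", z2 = "ACGA"))
  tax <- data.frame(id = rownames(aln),
                    species = c("X", "X", "Y", "Y", "Z", "Z"),
                    genus = "G", family = "F", order = "O")
  list(aln = aln, tax = tax)
}

random_alignment <- function(n, L, chars = c("A", "C", "G", "T")) {
  m <- matrix(sample(chars, n * L, replace = TRUE), n, L)
  rownames(m) <- sprintf("s%02d", seq_len(n))
  m
}

# low-divergence alignment: mutated copies of one ancestor, far from the
# K2P saturation boundary (random uniform sequences sit on it)
similar_alignment <- function(n, L, mut = 0.08) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(base, n, L, byrow = TRUE)
  for (i in seq_len(n)) {
    k <- max(1, round(mut * L))
    at <- sample.int(L, k)
    m[i, at] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
  }
  rownames(m) <- sprintf("s%02d", seq_len(n))
  m
}

# hand-built k2p_matrix for tests that inject exact distances
fake_dm <- function(d) {
  ids <- rownames(d)
  und <- matrix(FALSE, nrow(d), ncol(d), dimnames = dimnames(d))
  structure(list(ids = ids, d = d, P = d, Q = d * 0,
                 n_sites = d * 0 + 100, undefined = und,
                 flag = matrix(NA_character_, nrow(d), ncol(d)),
                 deletion = "pairwise"),
            class = "k2p_matrix")
}

simple_tax <- function(ids, species, genus = "G1", family = "F1") {
  data.frame(id = ids, species = species, genus = genus, family = family,
             order = "O")
}

# direct definition scan: for every taxon, column and state, check the CA
# set conditions literally
brute_cas <- function(mat, partition) {
  rows <- list()
  for (taxon in names(partition)) {
    mem <- rownames(mat) %in% partition[[taxon]]
    for (j in seq_len(ncol(mat))) {
      mcol <- mat[mem, j]
      ocol <- mat[!mem, j]
      for (s in c("A", "C", "G", "T")) {
        if (any(ocol == s)) next
        cls <- if (all(mcol == s)) {
          "pure"
        } else if (any(mcol == s)) {
          "private"
        } else {
          next
        }
        rows[[length(rows) + 1]] <- data.frame(taxon = taxon, position = j,
                                               state = s, class = cls)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(0), position = integer(0),
               state = character(0), class = character(0))
  out[order(out$taxon, out$position, out$state), , drop = FALSE]
}

# tip set below every node, by direct recursion over the edge table
node_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  total <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  sets <- vector("list", total)
  getset <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    if (!is.null(sets[[v]])) return(sets[[v]])
    s <- unlist(lapply(kids[[as.character(v)]], getset))
    sets[[v]] <<- s
    s
  }
  for (v in seq(ntip + 1, total)) getset(v)
  sets
}

# brute-force monophyly: the minimal clade spanning the taxon's leaves
# must contain no outsider
brute_monophyly <- function(tree, leaves) {
  sets <- node_tipsets(tree)
  containing <- Filter(function(s) all(leaves %in% s), sets)
  minimal <- containing[[which.min(lengths(containing))]]
  length(setdiff(minimal, leaves)) == 0
}

# random tree whose cophenetic matrix is an additive distance matrix
random_additive <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
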