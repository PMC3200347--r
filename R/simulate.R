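# Seeded simulator of multi-species barcode reference libraries.
#
# The generator emulates the statistical structure every barcoding method
# assumes: a species tree with low intraspecific and much higher
# interspecific divergence, transition/transversion-biased substitution
# matching the K2P estimator's model exactly (so the estimator is the
# model's MLE), optional planted diagnostic sites (pure CAs by
# construction) and optional planted non-monophyly via grafted
# individuals.  All randomness flows from one seeded stream in a fixed
# draw order: species tree, individual placements, sequences, planted
# sites.

#' Simulation configuration
#'
#' @param n_species Number of ingroup species (>= 2).
#' @param individuals_per_species Single count or per-species integer
#'   vector (1 creates a singleton species).
#' @param seq_length Alignment length; 650 is a COI-like locus, 450 a
#'   16S-like one.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param inter_depth Root-to-tip depth of the ingroup species tree in
#'   expected substitutions/site; the scale of interspecific divergence.
#' @param intra_depth Expected conspecific pairwise divergence
#'   (substitutions/site); individual pendant branches are drawn
#'   Exponential with mean `intra_depth / 2`.
#' @param min_split_frac Species splits shallower than this fraction of
#'   `inter_depth` are pushed down to it, so the shallowest interspecific
#'   divergence stays bounded away from zero, as in real barcode
#'   libraries of distinct species (minimum congeneric divergences of
#'   about 2% at an 8% depth).
#' @param n_planted_diagnostics Diagnostic columns overwritten per species
#'   (each becomes a pure CA by construction).
#' @param grafts List of 2-vectors `c(a, b)`: move one individual of
#'   species `a` into species `b`'s cluster, planting non-monophyly of
#'   both.
#' @param outgroup Attach an outgroup individual below the ingroup root at
#'   1.5x depth (for rooting, as barcode studies do).
#' @param seed Integer seed recorded in the ground truth and manifest.
#' @return Validated configuration list (class `sim_config`).
#' @export
sim_config <- function(n_species = 40,
                       individuals_per_species = 3,
                       seq_length = 650,
                       kappa = 2,
                       inter_depth = 0.08,
                       intra_depth = 0.006,
                       min_split_frac = 0.125,
                       n_planted_diagnostics = 3,
                       grafts = NULL,
                       outgroup = TRUE,
                       seed = 1) {
  if (n_species < 2) stop("n_species must be >= 2")
  k <- individuals_per_species
  if (length(k) == 1) k <- rep(k, n_species)
  if (length(k) != n_species || any(k < 1)) {
    stop("individuals_per_species must be a count or a vector of ",
         n_species, " counts >= 1")
  }
  if (kappa <= 0) stop("kappa must be > 0")
  if (inter_depth <= 0 || intra_depth < 0) {
    stop("need inter_depth > 0 and intra_depth >= 0")
  }
  if (min_split_frac < 0 || min_split_frac >= 1) {
    stop("min_split_frac must be in [0, 1)")
  }
  if (n_planted_diagnostics < 0) stop("n_planted_diagnostics must be >= 0")
  if (!is.null(grafts)) {
    if (!is.list(grafts)) grafts <- list(grafts)
    for (g in grafts) {
      if (length(g) != 2) stop("each graft must be c(species_a, species_b)")
    }
  }
  structure(list(n_species = as.integer(n_species),
                 individuals_per_species = as.integer(k),
                 seq_length = as.integer(seq_length),
                 kappa = kappa,
                 inter_depth = inter_depth,
                 intra_depth = intra_depth,
                 min_split_frac = min_split_frac,
                 n_planted_diagnostics = as.integer(n_planted_diagnostics),
                 grafts = grafts,
                 outgroup = isTRUE(outgroup),
                 seed = as.integer(seed)),
            class = "sim_config")
}

species_name <- function(i) sprintf("Species_%02d", i)

#' Simulate a species tree
#'
#' Pure-birth (Yule) topology rescaled so that the root-to-tip depth
#' equals `inter_depth`, with internal node ages compressed affinely into
#' `[min_split_frac * inter_depth, inter_depth]` (see [sim_config()]).
#' Optionally attaches an outgroup leaf below the ingroup root with a
#' pendant edge of `1.5 * inter_depth`.
#'
#' @param n_species Number of ingroup species.
#' @param inter_depth Root-to-tip depth (substitutions/site).
#' @param min_split_frac Minimum split age as a fraction of the depth.
#' @param outgroup Attach an `"Outgroup"` leaf.
#' @param seed Optional seed (set only when given; [make_dataset()] seeds
#'   the whole stream once instead).
#' @return `ape::phylo` ultrametric species tree, tips
#'   `Species_01, ...` (plus `Outgroup`).
#' @export
simulate_species_tree <- function(n_species, inter_depth = 0.08,
                                  min_split_frac = 0.125,
                                  outgroup = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_species == 2) {
    ing <- ape::read.tree(text = sprintf("(%s:%s,%s:%s);",
                                         species_name(1),
                                         fmt_len(inter_depth),
                                         species_name(2),
                                         fmt_len(inter_depth)))
  } else {
    ing <- ape::rphylo(n_species, birth = 1, death = 0)
    ing$tip.label <- species_name(seq_len(n_species))
    depth <- max(ape::node.depth.edgelength(ing))
    ing$edge.length <- ing$edge.length * inter_depth / depth
    ing <- compress_node_ages(ing, inter_depth,
                              min_split_frac * inter_depth)
  }
  if (!outgroup) {
    return(ing)
  }
  nwk <- sub(";$", "", ape::write.tree(ing))
  ape::read.tree(text = sprintf("(%s:%s,Outgroup:%s);",
                                nwk, fmt_len(0.5 * inter_depth),
                                fmt_len(1.5 * inter_depth)))
}

# Affinely map internal node ages (time before the tips) from [0, depth]
# to [min_age, depth]; tips stay at age 0, so pendant edges absorb the
# compression and the tree stays ultrametric.
compress_node_ages <- function(tree, depth, min_age) {
  if (min_age <= 0) return(tree)
  ntip <- length(tree$tip.label)
  height <- ape::node.depth.edgelength(tree)   # distance from root
  age <- max(height) - height                  # time before tips
  new_age <- ifelse(seq_along(age) > ntip,
                    min_age + (depth - min_age) * age / depth,
                    0)
  tree$edge.length <- new_age[tree$edge[, 1]] - new_age[tree$edge[, 2]]
  tree
}

#' Expand species tips into individual-level clusters
#'
#' Replaces each ingroup species tip by a star of its individuals with
#' pendant lengths drawn Exponential(mean = `intra_depth / 2`); an
#' `intra_depth` of 0 gives identical placements.  Grafts then move the
#' last individual of species a into species b's star, planting
#' non-monophyly (of a, whose member now sits elsewhere, and of b, whose
#' cluster gains an intruder).
#'
#' @param species_tree Tree from [simulate_species_tree()].
#' @param config A [sim_config()].
#' @return List with `tree` (individual-level `ape::phylo`, tips
#'   `Species_01_1, ...`, `Outgroup_1`) and `expected_status` (data.frame
#'   of per-species planted monophyly statuses).
#' @export
simulate_individuals <- function(species_tree, config) {
  n <- config$n_species
  k <- config$individuals_per_species
  groups <- lapply(seq_len(n), function(i) {
    paste0(species_name(i), "_", seq_len(k[i]))
  })
  names(groups) <- species_name(seq_len(n))

  grafted <- character(0)
  for (g in config$grafts) {
    a <- g[1]
    b <- g[2]
    if (!a %in% names(groups) || !b %in% names(groups)) {
      stop("graft names unknown species: ", a, " -> ", b)
    }
    if (length(groups[[a]]) < 2) {
      stop("cannot graft from single-individual species ", a)
    }
    mover <- groups[[a]][length(groups[[a]])]
    groups[[a]] <- groups[[a]][-length(groups[[a]])]
    groups[[b]] <- c(groups[[b]], mover)
    grafted <- c(grafted, a, b)
  }

  nwk <- ape::write.tree(species_tree)
  mean_pend <- config$intra_depth / 2
  for (sp in names(groups)) {
    ids <- groups[[sp]]
    pend <- if (mean_pend > 0) {
      stats::rexp(length(ids), rate = 1 / mean_pend)
    } else {
      rep(0, length(ids))
    }
    star <- paste0("(", paste(sprintf("%s:%s", ids, fmt_len(pend)),
                              collapse = ","), ")")
    nwk <- sub(paste0(sp, ":"), paste0(star, ":"), nwk, fixed = TRUE)
  }
  if (config$outgroup) {
    nwk <- sub("Outgroup:", "Outgroup_1:", nwk, fixed = TRUE)
  }
  tree <- ape::collapse.singles(ape::read.tree(text = nwk))

  status <- vapply(species_name(seq_len(n)), function(sp) {
    if (sp %in% grafted) {
      "non_monophyletic"
    } else if (length(groups[[sp]]) == 1) {
      "singleton"
    } else {
      "monophyletic"
    }
  }, character(1))
  list(tree = tree,
       expected_status = data.frame(species = species_name(seq_len(n)),
                                    status = unname(status)))
}

# K2P transition probabilities after branch length t (expected
# substitutions/site), transition:transversion rate ratio kappa; the two
# transversions are equiprobable.  Rates scaled so alpha + 2 beta = 1.
k2p_branch_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  p_tv <- 0.25 - 0.25 * exp(-4 * beta * t)           # each transversion
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * t) -
    0.5 * exp(-2 * (alpha + beta) * t)
  c(ts = p_ts, tv = p_tv)
}

TV_TARGETS <- matrix(c(2L, 4L,   # A -> C or T
                       1L, 3L,   # C -> A or G
                       2L, 4L,   # G -> C or T
                       1L, 3L),  # T -> A or G
                     nrow = 4, byrow = TRUE)

mutate_along_branch <- function(seq_codes, t, kappa) {
  p <- k2p_branch_probs(t, kappa)
  u <- stats::runif(length(seq_codes))
  out <- seq_codes
  ts <- u < p["ts"]
  tv1 <- !ts & u < p["ts"] + p["tv"]
  tv2 <- !ts & !tv1 & u < p["ts"] + 2 * p["tv"]
  out[ts] <- TRANSITION_PARTNER[seq_codes[ts]]
  out[tv1] <- TV_TARGETS[seq_codes[tv1], 1]
  out[tv2] <- TV_TARGETS[seq_codes[tv2], 2]
  out
}

#' Evolve sequences along a tree under the K2P process
#'
#' The root sequence is uniform over `{A,C,G,T}`; along each branch of
#' length t every site substitutes under the Kimura 2-parameter process
#' (expected substitutions/site equal to t, transitions `kappa`-fold
#' faster than each transversion).  Afterwards, planted diagnostic
#' columns are overwritten: the owning species receives one fixed state
#' and every other individual a different fixed state, making each a pure
#' CA by construction.  No indels are simulated, so the sequence matrix is
#' the alignment.
#'
#' @param tree Individual-level tree (see [simulate_individuals()]).
#' @param config A [sim_config()].
#' @return List with `alignment` (character matrix) and `planted`
#'   (data.frame `species`, `position`, `state`, `other_state`).
#' @export
evolve_sequences <- function(tree, config) {
  L <- config$seq_length
  n_plant <- config$n_planted_diagnostics
  if (n_plant * config$n_species > L) {
    stop("planted diagnostic columns (", n_plant * config$n_species,
         ") exceed seq_length (", L, ")")
  }
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  seqs <- matrix(NA_integer_, ntip + nnode, L)
  root <- ntip + 1
  seqs[root, ] <- sample.int(4, L, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    seqs[child, ] <- mutate_along_branch(seqs[par, ], tree$edge.length[e],
                                         config$kappa)
  }
  aln <- matrix(c("A", "C", "G", "T")[seqs[seq_len(ntip), ]], ntip, L,
                dimnames = list(tree$tip.label, NULL))

  planted <- data.frame(species = character(0), position = integer(0),
                        state = character(0), other_state = character(0))
  if (n_plant > 0) {
    pos <- sample.int(L, n_plant * config$n_species)
    sp_of_row <- sub("_[0-9]+$", "", rownames(aln))
    for (i in seq_len(config$n_species)) {
      sp <- species_name(i)
      for (j in seq_len(n_plant)) {
        p <- pos[(i - 1) * n_plant + j]
        own <- sample(c("A", "C", "G", "T"), 1)
        other <- sample(setdiff(c("A", "C", "G", "T"), own), 1)
        aln[sp_of_row == sp, p] <- own
        aln[sp_of_row != sp, p] <- other
        planted <- rbind(planted,
                         data.frame(species = sp, position = p,
                                    state = own, other_state = other))
      }
    }
  }
  list(alignment = aln, planted = planted)
}

#' Generate a complete synthetic barcode dataset
#'
#' End-to-end composition: species tree, individual placements, K2P
#' sequence evolution, planted diagnostics, plus a taxonomy in which genus
#' and family labels come from cutting the species tree at fixed depths
#' (0.6 and 0.9 of the root-to-tip depth), so congeneric and confamilial
#' strata exist.  With a fixed seed the output is byte-identical across
#' runs.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, writes `alignment.fasta`,
#'   `taxonomy.tsv`, `species_tree.nwk`, `individual_tree.nwk`,
#'   `ground_truth.json` and `manifest.json` (seed and configuration).
#' @return List with `alignment`, `taxonomy`, `ground_truth` (list:
#'   trees as newick, planted sites, expected statuses, seed) and
#'   `config`.
#' @export
make_dataset <- function(config = sim_config(), dir = NULL) {
  set.seed(config$seed)
  sp_tree <- simulate_species_tree(config$n_species, config$inter_depth,
                                   config$min_split_frac, config$outgroup)
  ind <- simulate_individuals(sp_tree, config)
  ev <- evolve_sequences(ind$tree, config)

  taxonomy <- derive_taxonomy(sp_tree, config, rownames(ev$alignment))
  ground_truth <- list(
    species_tree = ape::write.tree(sp_tree),
    individual_tree = ape::write.tree(ind$tree),
    planted = ev$planted,
    expected_status = ind$expected_status,
    seed = config$seed)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(ev$alignment, file.path(dir, "alignment.fasta"))
    write_table(taxonomy, file.path(dir, "taxonomy.tsv"))
    writeLines(ground_truth$species_tree,
               file.path(dir, "species_tree.nwk"))
    writeLines(ground_truth$individual_tree,
               file.path(dir, "individual_tree.nwk"))
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(config), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(alignment = ev$alignment, taxonomy = taxonomy,
       ground_truth = ground_truth, config = config)
}

# Genus/family labels from single-linkage cuts of the ultrametric species
# tree: two species are congeneric when their MRCA is younger than
# 0.6 * depth, confamilial below 0.9 * depth.
derive_taxonomy <- function(sp_tree, config, ids) {
  ing <- if (config$outgroup) {
    ape::drop.tip(sp_tree, "Outgroup")
  } else {
    sp_tree
  }
  mrca_age <- ape::cophenetic.phylo(ing) / 2
  cl <- stats::hclust(stats::as.dist(mrca_age), method = "single")
  genus_id <- stats::cutree(cl, h = 0.6 * config$inter_depth)
  family_id <- stats::cutree(cl, h = 0.9 * config$inter_depth)
  sp <- ing$tip.label
  genus <- sprintf("Genus_%02d", genus_id[sp])
  family <- sprintf("Family_%02d", family_id[sp])
  lookup <- data.frame(species = sp, genus = genus, family = family)

  sp_of_id <- sub("_[0-9]+$", "", ids)
  tax <- data.frame(id = ids, species = sp_of_id,
                    genus = lookup$genus[match(sp_of_id, lookup$species)],
                    family = lookup$family[match(sp_of_id, lookup$species)],
                    order = "Simulordia")
  out <- sp_of_id == "Outgroup"
  tax$genus[out] <- "Outgenus"
  tax$family[out] <- "Outfamilia"
  tax$order[out] <- "Outordia"
  tax
}
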