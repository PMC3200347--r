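test_that("K2P handles identity, saturation and missing data", {
  id <- k2p("ACGTACGT", "ACGTACGT")
  expect_equal(id$d, 0)
  expect_equal(id$P, 0)
  expect_equal(id$Q, 0)

  # all-transversion pair: Q = 0.5 sits on the log-domain boundary
  sat <- k2p("AAAA", "CCAA")
  expect_true(is.na(sat$d))
  expect_equal(sat$flag, "saturated")

  none <- k2p("NN--", "AC-G")
  expect_equal(none$n_sites, 0L)
  expect_equal(none$flag, "no_sites")

  # pairwise deletion drops exactly the unshared sites
  pd <- k2p("ACGTA", "ACG-A")
  expect_equal(pd$n_sites, 4L)
})

test_that("K2P agrees with the independent K80 implementation in ape", {
  set.seed(11)
  aln <- similar_alignment(8, 300)
  aln[1, 5] <- "-"
  aln[2, 9] <- "N"
  dm <- distance_matrix(aln)
  oracle <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(aln)),
                                    model = "K80",
                                    pairwise.deletion = TRUE))
  expect_equal(dm$d, oracle[rownames(dm$d), colnames(dm$d)],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(isSymmetric(dm$d))
  expect_equal(diag(dm$d), stats::setNames(rep(0, 8), rownames(aln)))
})

test_that("K2P distance increases monotonically in P and in Q", {
  dval <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  grid <- seq(0, 0.3, by = 0.05)
  for (Q in grid) {
    ds <- vapply(grid[2 * grid + Q < 1], function(P) dval(P, Q), numeric(1))
    expect_true(all(diff(ds) > 0))
  }
  for (P in grid) {
    ds <- vapply(grid[2 * grid + P < 1 & grid < 0.5],
                 function(Q) dval(P, Q), numeric(1))
    expect_true(all(diff(ds) > 0))
  }
})

test_that("complete deletion removes every column with missing data", {
  aln <- as_alignment(c(a = "ACGTA", b = "ACG-A", c = "ACGTA"))
  dm <- distance_matrix(aln, deletion = "complete")
  expect_true(all(dm$n_sites == 4))
})

test_that("strata partition all pairs and summaries match hand arithmetic", {
  # 2 conspecific + 1 congeneric individual
  tax3 <- simple_tax(c("a", "b", "c"), c("S1", "S1", "S2"))
  d3 <- matrix(0.02, 3, 3, dimnames = list(tax3$id, tax3$id))
  d3["a", "b"] <- d3["b", "a"] <- 0.001
  diag(d3) <- 0
  rs <- rank_summary(fake_dm(d3), tax3)
  expect_equal(rs$n_pairs, c(1L, 2L, 0L, 0L))
  expect_equal(sum(rs$n_pairs), 3)

  # all conspecific: only the first stratum populated
  rs2 <- rank_summary(fake_dm(d3), simple_tax(tax3$id, rep("S1", 3)))
  expect_equal(rs2$n_pairs, c(3L, 0L, 0L, 0L))
  expect_true(all(is.na(rs2$average[-1])))

  # 4 individuals, 2 species: congeneric mean over {10,11,12,13}% is 11.5%
  tax4 <- simple_tax(c("a", "b", "c", "d"), c("S1", "S1", "S2", "S2"))
  d4 <- matrix(0, 4, 4, dimnames = list(tax4$id, tax4$id))
  d4["a", "b"] <- 0.01
  d4["c", "d"] <- 0.01
  d4["a", "c"] <- 0.10; d4["a", "d"] <- 0.11
  d4["b", "c"] <- 0.12; d4["b", "d"] <- 0.13
  d4 <- d4 + t(d4)
  rs4 <- rank_summary(fake_dm(d4), tax4)
  expect_equal(rs4$average[2], 11.5)
  expect_equal(rs4$minimum[2], 10)
  expect_equal(rs4$maximum[2], 13)
  expect_equal(rs4$se[1], stats::sd(c(1, 1)) / sqrt(2))
})

test_that("random strata counts always sum to n(n-1)/2", {
  set.seed(13)
  for (i in 1:5) {
    n <- sample(5:15, 1)
    ids <- sprintf("i%02d", 1:n)
    sp <- sample(sprintf("S%d", 1:4), n, replace = TRUE)
    gen <- c(S1 = "G1", S2 = "G1", S3 = "G2", S4 = "G2")[sp]
    fam <- c(G1 = "F1", G2 = "F2")[gen]
    tax <- data.frame(id = ids, species = sp, genus = gen, family = fam,
                      order = "O")
    d <- matrix(stats::runif(n * n), n, n, dimnames = list(ids, ids))
    d <- (d + t(d)) / 2; diag(d) <- 0
    rs <- rank_summary(fake_dm(d), tax)
    expect_equal(sum(rs$n_pairs), n * (n - 1) / 2)
  }
})

test_that("gap report detects separation and overlap correctly", {
  tax <- simple_tax(letters[1:4], c("S1", "S1", "S2", "S2"))
  gapped <- matrix(0.10, 4, 4, dimnames = list(tax$id, tax$id))
  gapped["a", "b"] <- gapped["b", "a"] <- 0.01
  gapped["c", "d"] <- gapped["d", "c"] <- 0.01
  diag(gapped) <- 0
  g <- gap_report(fake_dm(gapped), tax)
  expect_true(g$global_gap)
  expect_equal(g$max_intra, 1)
  expect_equal(g$min_inter, 10)
  expect_equal(sum(g$histogram$intra_count), 2)
  expect_equal(sum(g$histogram$inter_count), 4)

  # overlap in the style of a real barcode library: max intra 2.20%,
  # min inter 2.10% -> no gap
  overlap <- gapped
  overlap["a", "b"] <- overlap["b", "a"] <- 0.022
  overlap["a", "c"] <- overlap["c", "a"] <- 0.021
  g2 <- gap_report(fake_dm(overlap), tax)
  expect_false(g2$global_gap)
  expect_equal(g2$max_intra, 2.2)
  expect_equal(g2$min_inter, 2.1)
})

test_that("singleton species get null max-intra but a nearest neighbour", {
  tax <- simple_tax(c("a", "b", "c"), c("S1", "S2", "S2"))
  d <- matrix(0.05, 3, 3, dimnames = list(tax$id, tax$id))
  diag(d) <- 0
  g <- gap_report(fake_dm(d), tax)
  s1 <- g$per_species[g$per_species$species == "S1", ]
  expect_true(is.na(s1$max_intra))
  expect_equal(s1$nearest_hetero, 5)
})

test_that("the 10x rule is ten times the mean conspecific divergence", {
  tax <- simple_tax(letters[1:3], c("S1", "S1", "S2"))
  d <- matrix(0.05, 3, 3, dimnames = list(tax$id, tax$id))
  d["a", "b"] <- d["b", "a"] <- 0.0064
  diag(d) <- 0
  expect_equal(ten_x_threshold(fake_dm(d), tax), 6.4)
  d["a", "b"] <- d["b", "a"] <- 0.002
  expect_equal(ten_x_threshold(fake_dm(d), tax), 2.0)
  d["a", "b"] <- d["b", "a"] <- 0
  expect_equal(ten_x_threshold(fake_dm(d), tax), 0)
  # no conspecific pair at all: undefined
  expect_error(ten_x_threshold(fake_dm(d), simple_tax(letters[1:3],
                                                      c("S1", "S2", "S3"))),
               "undefined")
})

test_that("lumping follows the threshold monotonically", {
  tax <- simple_tax(letters[1:4], c("S1", "S1", "S2", "S3"))
  d <- matrix(0.10, 4, 4, dimnames = list(tax$id, tax$id))
  d["c", "a"] <- d["a", "c"] <- 0.021  # S1-S2 at 2.1%
  diag(d) <- 0
  dm <- fake_dm(d)
  expect_length(lumping(dm, tax, 0)$lumped_species, 0)
  l64 <- lumping(dm, tax, 6.4, rule = "10x")
  expect_setequal(l64$lumped_species, c("S1", "S2"))
  expect_equal(l64$lumped_fraction, 2 / 3)
  lall <- lumping(dm, tax, 99)
  expect_setequal(lall$lumped_species, c("S1", "S2", "S3"))
  # monotone: the lumped set only grows with the threshold
  thresholds <- c(0, 1, 2.2, 6.4, 12, 99)
  sets <- lapply(thresholds, function(t) lumping(dm, tax, t)$lumped_species)
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
})

test_that("distance identification assigns, abstains or flags ties", {
  toy <- toy_xyz()
  expect_equal(identify_by_distance("ACGT", toy$aln, toy$tax, 2)$verdict,
               "assigned")
  r <- identify_by_distance("ACGT", toy$aln, toy$tax, 2)
  expect_equal(r$species, "X")
  expect_equal(r$distance, 0)

  far <- identify_by_distance(paste(rep("A", 100), collapse = ""),
                              as_alignment(c(
                                a = paste(c(rep("G", 5), rep("A", 95)),
                                          collapse = ""),
                                b = paste(c(rep("G", 6), rep("A", 94)),
                                          collapse = ""))),
                              simple_tax(c("a", "b"), c("S1", "S2")), 2)
  expect_equal(far$verdict, "unassigned")

  # exact equidistance across two species below the threshold
  tie_aln <- as_alignment(c(a = "AAAAAAAAAA", b = "CCAAAAAAAA",
                            c = "AACCAAAAAA"))
  tie <- identify_by_distance("CCCCAAAAAA", tie_aln,
                              simple_tax(c("a", "b", "c"),
                                         c("S1", "S2", "S3")), 99)
  expect_equal(tie$verdict, "ambiguous")
  expect_length(tie$species, 2)
})
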