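test_that("the three-species toy yields exactly its two pure CAs", {
  toy <- toy_xyz()
  cm <- build_character_matrix(toy$aln, toy$tax, "species")
  cas <- find_cas(cm)
  expect_equal(cas,
               data.frame(taxon = c("X", "Y"), position = c(4L, 1L),
                          state = "T", class = "pure")[order(c("X", "Y")), ],
               ignore_attr = TRUE)
  expect_equal(nrow(find_cas(cm, "Z")), 0)
})

test_that("identical sequence sets across taxa yield no CAs", {
  aln <- as_alignment(c(a1 = "ACGT", a2 = "ACGT", b1 = "ACGT", b2 = "ACGT"))
  cm <- build_character_matrix(aln,
                               simple_tax(rownames(aln),
                                          c("A", "A", "B", "B")))
  expect_equal(nrow(find_cas(cm)), 0)
})

test_that("member gaps/N block pure CAs but can leave private ones", {
  # X fixed T at column 4 except one member with N: private, not pure
  aln <- as_alignment(c(x1 = "ACGT", x2 = "ACGN",
                        y1 = "TCGA", y2 = "TCGA"))
  cm <- build_character_matrix(aln, simple_tax(rownames(aln),
                                               c("X", "X", "Y", "Y")))
  cas <- find_cas(cm, "X")
  at4 <- cas[cas$position == 4, ]
  expect_equal(at4$class, "private")
  expect_equal(at4$state, "T")
  # a non-member N does not veto a pure CA
  aln2 <- as_alignment(c(x1 = "ACGT", x2 = "ACGT",
                         y1 = "TCGN", y2 = "TCGA"))
  cm2 <- build_character_matrix(aln2, simple_tax(rownames(aln2),
                                                 c("X", "X", "Y", "Y")))
  cas2 <- find_cas(cm2, "X")
  expect_true(any(cas2$position == 4 & cas2$class == "pure"))
})

test_that("CA discovery agrees with the brute-force definition scan", {
  set.seed(31)
  for (i in 1:8) {
    n_taxa <- sample(3:6, 1)
    sizes <- sample(1:3, n_taxa, replace = TRUE)
    ids <- sprintf("t%d_%d", rep(seq_len(n_taxa), sizes),
                   unlist(lapply(sizes, seq_len)))
    sp <- sprintf("T%d", rep(seq_len(n_taxa), sizes))
    aln <- random_alignment(length(ids), 40,
                            chars = c("A", "A", "C", "G", "T", "N"))
    rownames(aln) <- ids
    cm <- build_character_matrix(aln, simple_tax(ids, sp))
    got <- find_cas(cm)
    want <- brute_cas(aln, cm$partition)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("CAs never disappear when competitor taxa are removed", {
  set.seed(37)
  aln <- random_alignment(12, 60, chars = c("A", "A", "C", "G", "T"))
  sp <- rep(sprintf("T%d", 1:4), each = 3)
  tax <- simple_tax(rownames(aln), sp)
  full <- find_cas(build_character_matrix(aln, tax), "T1")
  sub <- find_cas(build_character_matrix(aln, tax, taxa = c("T1", "T2")),
                  "T1")
  full_pure <- full[full$class == "pure", c("position", "state")]
  sub_keys <- paste(sub$position, sub$state)
  expect_true(all(paste(full_pure$position, full_pure$state) %in% sub_keys))
  expect_true(nrow(sub) >= nrow(full))
})

test_that("diagnostic selection finds the minimal unique toy set", {
  toy <- toy_xyz()
  cm <- build_character_matrix(toy$aln, toy$tax, "species")
  prof <- select_diagnostics(cm, min_cas_per_taxon = 1)
  expect_equal(prof$positions, c(1L, 4L))
  expect_true(prof$unique_combinations)
  expect_equal(prof$profile["X", ], c(`1` = "A", `4` = "T"))
  expect_equal(prof$profile["Y", ], c(`1` = "T", `4` = "A"))
  expect_equal(prof$profile["Z", ], c(`1` = "A", `4` = "A"))
  # Z has no CA of its own: shortfall reported, uniqueness still achieved
  expect_equal(unname(prof$shortfall["Z"]), 1)
})

test_that("identical taxa are reported, not raised", {
  aln <- as_alignment(c(a1 = "ACGT", a2 = "ACGT", b1 = "ACGT"))
  cm <- build_character_matrix(aln, simple_tax(rownames(aln),
                                               c("A", "A", "B")))
  prof <- select_diagnostics(cm)
  expect_false(prof$unique_combinations)
  expect_true(all(prof$shortfall > 0))
})

test_that("a single separating column is forced into the selection", {
  # taxa A and B differ only at column 5, where C is polymorphic for both
  # states, so the column carries no pure CA for anyone: only the
  # separation step can pick it
  aln <- as_alignment(c(a1 = "ACGTA", a2 = "ACGTA",
                        b1 = "ACGTG", b2 = "ACGTG",
                        c1 = "TTTTA", c2 = "TTTTG"))
  cm <- build_character_matrix(aln, simple_tax(rownames(aln),
                                               c("A", "A", "B", "B",
                                                 "C", "C")))
  prof <- select_diagnostics(cm, min_cas_per_taxon = 1)
  expect_true(5 %in% prof$positions)
  expect_true(prof$unique_combinations)
})

test_that("every taxon with a pure CA implies unique combinations", {
  set.seed(43)
  for (i in 1:5) {
    n_taxa <- sample(3:6, 1)
    aln <- random_alignment(n_taxa * 2, 50)
    sp <- rep(sprintf("T%d", seq_len(n_taxa)), each = 2)
    rownames(aln) <- paste0(sp, "_", rep(1:2, n_taxa))
    # plant one pure CA per taxon in dedicated columns
    for (t in seq_len(n_taxa)) {
      aln[, t] <- "A"
      aln[sp == sprintf("T%d", t), t] <- "G"
    }
    cm <- build_character_matrix(aln, simple_tax(rownames(aln), sp))
    prof <- select_diagnostics(cm, min_cas_per_taxon = 1)
    expect_true(prof$unique_combinations)
  }
})

test_that("diagnosis scores pure CA matches and demands a clear winner", {
  toy <- toy_xyz()
  cm <- build_character_matrix(toy$aln, toy$tax, "species")
  prof <- select_diagnostics(cm, min_cas_per_taxon = 1)

  own <- diagnose("ACGT", prof, min_cas = 1)
  expect_equal(own$verdict, "assigned")
  expect_equal(own$taxon, "X")

  allN <- diagnose("NNNN", prof, min_cas = 1)
  expect_equal(allN$verdict, "ambiguous")
  expect_true(all(allN$scores$score == 0))

  chimera <- diagnose("TCGT", prof, min_cas = 1)
  expect_equal(chimera$verdict, "ambiguous")
  expect_setequal(chimera$tied, c("X", "Y"))

  expect_error(diagnose("AC", prof), "shorter")
})

test_that("training sequences score maximally for their own taxon", {
  set.seed(47)
  aln <- random_alignment(10, 80)
  sp <- rep(sprintf("T%d", 1:5), each = 2)
  rownames(aln) <- paste0(sp, "_", rep(1:2, 5))
  for (t in 1:5) {  # make every taxon diagnosable
    aln[, t] <- "C"
    aln[sp == sprintf("T%d", t), t] <- "A"
  }
  cm <- build_character_matrix(aln, simple_tax(rownames(aln), sp))
  prof <- select_diagnostics(cm, min_cas_per_taxon = 1)
  for (i in seq_len(nrow(aln))) {
    res <- diagnose(aln[i, ], prof, min_cas = 1)
    expect_equal(res$scores$taxon[1], sp[i])
  }
})

test_that("barcode tables render states, CA flags and the dash rule", {
  toy <- toy_xyz()
  cm <- build_character_matrix(toy$aln, toy$tax, "species")
  prof <- select_diagnostics(cm, min_cas_per_taxon = 1)
  bt <- barcode_table(prof)
  expect_equal(dim(bt$table), c(3L, 4L))  # taxon, p1, p4, n_cas
  expect_equal(sum(bt$flags == "pure"), 2)
  expect_equal(bt$table$n_cas, c(1L, 1L, 0L))

  # genus-level dash: three different nucleotides within one genus
  aln <- as_alignment(c(g1a = "AAAA", g1b = "CAAA", g1c = "GAAA",
                        g2a = "TTTT", g2b = "TTTT", g2c = "TTTT"))
  tax <- data.frame(id = rownames(aln),
                    species = c("s1", "s2", "s3", "s4", "s4", "s4"),
                    genus = rep(c("G1", "G2"), each = 3),
                    family = "F", order = "O")
  cmg <- build_character_matrix(aln, tax, rank = "genus")
  pg <- select_diagnostics(cmg, min_cas_per_taxon = 4)
  expect_true(1 %in% pg$positions)
  expect_equal(pg$profile["G1", "1"], "-")

  # empty selection renders a header-only table
  none <- select_diagnostics(
    build_character_matrix(as_alignment(c(a = "AA", b = "AA")),
                           simple_tax(c("a", "b"), c("A", "B"))))
  bt0 <- barcode_table(none)
  expect_equal(nrow(bt0$table), 2)
  expect_equal(ncol(bt0$table), 2)  # taxon + n_cas only
})

test_that("all-gap columns are dropped but positions stay 1-based original", {
  aln <- as_alignment(c(a1 = "A-CT", a2 = "A-CT", b1 = "G-CA", b2 = "G-CA"))
  cm <- build_character_matrix(aln, simple_tax(rownames(aln),
                                               c("A", "A", "B", "B")))
  expect_equal(cm$positions, c(1L, 3L, 4L))
  cas <- find_cas(cm)
  expect_setequal(unique(cas$position), c(1L, 4L))
})
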