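---
title: "Comparing distance, monophyly and character-based DNA barcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing distance, monophyly and character-based DNA barcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcomp)
```

# The problem

A DNA barcode library maps short standardized gene fragments (typically
mitochondrial COI, sometimes 16S rDNA) from identified voucher specimens to
species names, so that new specimens can be identified by sequence
comparison. Three identification paradigms dominate the literature, and
they can disagree on the same library:

* **Distance-based**: convert sequences to pairwise genetic distances and
  assign a query to the nearest species if the distance falls below a
  threshold. Its validity rests on a *barcoding gap* -- intraspecific
  divergences staying below interspecific ones -- which real libraries
  with closely related species often violate.
* **Monophyly-based**: build a phylogenetic tree (classically
  neighbour-joining on K2P distances) and require each species to come
  back as an exclusive clade, with bootstrap support measuring confidence.
* **Character-based**: characterize each species by a unique combination
  of diagnostic nucleotide states ("characteristic attributes", CAs) at
  specific alignment positions, independent of distances or trees.

`barcomp` implements all three on a common data model, plus a seeded
simulator that generates libraries with known answer keys, so the methods
can be compared under controlled divergence regimes.

# Models and procedures

## Kimura 2-parameter distances

For two aligned sequences, sites where either carries a gap or `N` are
dropped pair by pair (pairwise deletion, the convention of MEGA-style
barcode workflows; complete deletion is available via
`distance_matrix(..., deletion = "complete")`). With transition proportion
$P$ and transversion proportion $Q$ over the $n$ compared sites,

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$

When $1 - 2P - Q \le 0$ or $1 - 2Q \le 0$ the distance is undefined
(saturation) and is carried as an explicit flag, never as a silent
number; summaries exclude flagged pairs but still count them, and the
tree builder refuses them with the offending pairs named.

## Rank-stratified summaries, the gap, the 10x rule

Every unordered pair belongs to exactly one stratum: within species,
within genus between species, within family between genera, or between
families. `rank_summary()` reports mean/min/max/SE per stratum in
percent. The SE is the sample standard deviation of the pairwise
distances over $\sqrt{n_\mathrm{pairs}}$; pairwise distances share
individuals and are not independent, so the SE is indicative only --
documented here as a deliberate convention, matching how divergence
tables are usually presented.

`gap_report()` pools conspecific against all heterospecific distances;
the global gap is `min(inter) > max(intra)`, and per-species diagnostics
compare each species' maximum conspecific distance with its nearest
heterospecific individual. `ten_x_threshold()` returns ten times the mean
conspecific divergence. The published "lumping" notion is never formally
defined in the literature it comes from, so `lumping()` makes it
computable two ways and reports the choice: a species is lumped when its
*nearest* heterospecific distance (default) or its *mean* heterospecific
distance falls below the threshold. Lumping is monotone in the threshold
under either criterion.

## Neighbour joining, bootstrap, monophyly

`neighbor_joining()` is the classic Saitou-Nei agglomeration, joining the
pair minimizing $Q(i,j) = (r-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$.
Three numerical choices are fixed for reproducibility:

* ties on $Q$ are broken by the lexicographically smallest pair of
  cluster labels, so results are identical across platforms;
* negative limb lengths are clamped to zero (display convention of the
  common tree programs) with the total deficit logged as an attribute;
* trees are `ape::phylo` objects; for three or more taxa the result is
  unrooted with a trifurcating root node.

`bootstrap_support()` resamples alignment columns with replacement (one
draw per pseudoreplicate, in order, from a single seeded stream),
rebuilds the K2P + NJ tree each time, and attaches to each internal node
the percentage of replicates recovering its bipartition. Supports belong
to bipartitions, so rooting with `root_with_outgroup()` (which refuses a
non-monophyletic outgroup, naming the intruders) preserves them.
Replicates with saturated distances are dropped and counted; more than
half dropped is an error. Bootstrap percentages from other programs are
not expected to be reproduced bit for bit -- resampling streams differ --
only qualitatively (well-separated species near 100).

`assess_monophyly()` takes the MRCA of each taxon's leaves on the rooted
tree: monophyletic iff the MRCA clade adds no outsiders, with intruders
listed otherwise; single-individual taxa are `singleton`, with no
support, matching how published barcode trees annotate them.

## Characteristic attributes and diagnostic barcodes

With species collapsed to flat partitions (the one-vs-rest reduction of
guide-tree CA systems, which collapse species nodes to polytomies before
diagnosis), `find_cas()` scans every column: state $s$ at column $j$ is a
**pure** CA of taxon $t$ when every member of $t$ carries $s$ and no
non-member does, and **private** when some but not all members carry it
and no non-member does. Gaps and `N` are missing data, not a fifth
state: a member gap/N blocks purity at that column, a non-member gap/N
does not veto anything (absence is judged over observed states). A
guide-tree descent mode is deliberately out of scope.

Published diagnostic tables chose their positions by expert judgement;
`select_diagnostics()` is a declared greedy stand-in, not a claim of
identity: rank columns by total pure-CA count, add columns until every
taxon has `min_cas_per_taxon` (default 3) pure CAs or exhausts its
supply, then, if any two taxa still share a state vector, add the column
separating the most still-identical pairs (ties to the lowest position).
If every taxon owns at least one pure CA the resulting combinations are
always unique. Taxon states render as the shared nucleotide, an IUPAC
code for two observed states, or a dash for three or more (the
"non-significant position" convention of genus-level tables).
`diagnose()` scores a query by matched pure CAs and only declares a
species when the top score reaches `min_cas` and strictly beats the
runner-up; private CAs are reported but excluded from scoring by default,
since fixed states are the identification currency.

## Conserved-block filtering for ribosomal loci

`gblocks_filter()` reimplements the conserved-block procedure used to
strip uncertain alignment regions from 16S-like loci. Columns are
classified from the count of their most frequent residue (gaps and `N`
never count; thresholds are `ceiling(fraction * n)` sequences, so users
can match the original tool's counts): below 50% of sequences is
non-conserved, at least 90% is highly conserved. Under the default
"half" gap rule, a column gapped in at least half the sequences is
non-conserved outright. Runs of more than three contiguous non-conserved
columns split the alignment into candidate blocks; *all* non-conserved
columns are removed (short runs do not split a block -- the reading we
fixed where the original description is ambiguous); blocks are trimmed to
begin and end on highly conserved columns and must keep at least five
columns. Intervals are reported 1-based and closed because published
character tables count positions from 1. The filter is idempotent.

# The synthetic library generator

`make_dataset()` draws, from one seeded stream in a documented order
(species tree, individual placements, sequences, planted sites):

1. **Species tree**: a Yule topology rescaled to root-to-tip depth
   `inter_depth` (default 0.08 substitutions/site, a COI-like scale).
   Raw rescaled Yule trees contain arbitrarily recent splits, which no
   library of *distinct* species shows; node ages are therefore
   compressed affinely into `[min_split_frac * inter_depth, inter_depth]`
   with `min_split_frac = 0.125`, placing the shallowest interspecific
   divergence near 2% -- the regime real neogastropod libraries report as
   their minimum congeneric divergence. An outgroup leaf sits below the
   root at 1.5x depth for rooting.
2. **Individuals**: each species tip becomes a star of individuals with
   pendant lengths Exponential(mean `intra_depth / 2`), so the expected
   conspecific pairwise divergence is `intra_depth` (default 0.006, i.e.
   0.6%). Grafts move one individual of a donor species into a recipient
   star. In the *true* individual tree both donor and recipient are then
   non-monophyletic; note that NJ may resolve the recipient's star so
   that its own individuals regain exclusivity, so tests assert the
   donor, which cannot be rescued.
3. **Sequences**: the root sequence is uniform; each branch evolves every
   site under the exact K2P process (transitions `kappa`-fold faster than
   each transversion, `kappa = 2` by default), so the K2P estimator is
   the model's MLE and estimator consistency is testable. No rate
   heterogeneity across sites and no indels are simulated -- two
   documented limitations relative to real data.
4. **Planted diagnostics**: per species, dedicated columns are
   overwritten with one state in the species and a different state in
   everyone else -- pure CAs by construction, giving the character method
   a known answer key.
5. **Taxonomy**: genus and family labels come from single-linkage cuts of
   the species tree at 0.6 and 0.9 of its depth, so congeneric and
   confamilial strata exist with at least two genera per family under the
   defaults. The seed and full configuration are recorded in
   `manifest.json` / `ground_truth.json` (FASTA has no standard header
   field for them).

Because the generator matches the estimator's model exactly and bounds
the shallowest splits, passing tests demonstrate internal consistency of
the three methods under idealized barcode-like conditions; they do not
demonstrate robustness to rate variation, indels, incomplete lineage
sorting or contamination, which real libraries contain.

# Worked example

```{r example}
cfg <- sim_config(n_species = 8, individuals_per_species = 3,
                  seq_length = 650, seed = 42)
ds <- make_dataset(cfg)
rep <- run_comparison(ds$alignment, ds$taxonomy, outgroup = "Outgroup_1",
                      n_boot = 50, seed = 42)
rep
rep$distance$rank_summary
head(assess_monophyly(rep$tree, ds$taxonomy), 4)
barcode_table(rep$character$species)$table[1:4, 1:6]
```

Held-out identification with both assignment engines:

```{r identify}
held <- "Species_02_3"
ref <- ds$alignment[setdiff(rownames(ds$alignment), held), ]
tax <- ds$taxonomy[ds$taxonomy$id != held, ]
q <- setNames(paste(ds$alignment[held, ], collapse = ""), held)
identify_query(q, ref, tax, method = "distance")
identify_query(q, ref, tax, method = "character")
```

# Problem sizes and reproducibility

The package's reference configuration mirrors a realistic single-marker
study: 40 species with one to five individuals each (120 ingroup
sequences plus the outgroup), 650 bp, 100 bootstrap pseudoreplicates --
enough replication for stable support values while keeping a full
comparison under a minute on a laptop core. Examples and tests scale the
same generator down (5-8 species, a few hundred base pairs) where only
the mechanics are being exercised. Every stochastic step (tree, pendant
lengths, substitutions, planted sites, bootstrap resampling) flows from
user-supplied seeds, and reports regenerate byte-identically from the
same inputs and seeds.

# Known limitations

* The substitution simulator is exactly K2P: no among-site rate
  variation, no base-composition bias, no indels.
* Star-shaped intraspecific variation ignores within-species coalescent
  structure; planted non-monophyly via grafts is the only source of
  species para/polyphyly.
* The diagnostic-position selector is greedy and can select more columns
  than an expert would; it optimizes coverage and uniqueness, not table
  compactness.
* Bootstrap supports depend on the resampling stream and are comparable
  across runs of this package (seeded), not across programs.
* The one-vs-rest CA definition does not implement node-by-node
  guide-tree diagnosis; CAs are relative to the full analysed set, and
  re-extracting a small subset of close species (as with problem genera)
  can only gain CAs, never lose them.
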