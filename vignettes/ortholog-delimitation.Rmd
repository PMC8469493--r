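---
title: "Delimiting seed-mucilage toolbox orthologs across Brassicaceae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting seed-mucilage toolbox orthologs across Brassicaceae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoclade)
```

## The problem

Many Brassicaceae seeds extrude mucilage upon imbibition (myxospermy),
produced by specialised seed-coat epidermal cells (mucilage secretory
cells, MSCs). In *Arabidopsis thaliana* roughly a hundred genes — the
"MSC toolbox" — have characterised roles in this trait. A natural
comparative question is whether species that lost myxospermy also lost
(pseudogenized) toolbox-gene orthologs. Answering it requires, per
toolbox gene, a defensible ortholog set in each surveyed species, a
genes × species copy-number matrix contrasted with the phenotype, and a
way to compare expression of those orthologs across species whose
transcriptome datasets use heterogeneous units.

`orthoclade` implements the decision rules of that workflow on standard
file formats (newick, FASTA, BLAST outfmt-6 TSV, plain TSV tables). It
does **not** run aligners, BLAST or tree inference; it consumes their
outputs.

## The delimitation procedure

For each gene family the inputs are an (un)rooted gene tree and a leaf →
species map declaring three roles:

* **outgroup** species (here *Medicago truncatula* `Mtru` and *Linum
  usitatissimum* `Lusi`), non-Brassicaceae taxa used only for rooting;
* an **anchor** species (*Aethionema arabicum* `Aara`), the
  early-diverging Brassicaceae lineage that bounds the ortholog clade;
* the **focal** species (*A. thaliana* `Atha`) whose toolbox gene seeds
  the search.

The call is the composition of three steps:

1. **`root_on_outgroup`** — root on the branch separating the outgroup.
   When the outgroup leaves are not monophyletic (ancient duplications),
   the root goes on the edge maximising *(outgroup leaves on the outgroup
   side) − (ingroup leaves on that side)*; ties are broken by topological
   proximity to the first outgroup leaf in input order, so rooting is
   deterministic. A family without any outgroup leaf is reported
   unresolvable rather than guessed at.
2. **`extract_focal_clade`** — walk rootward from the focal leaf until
   the next step would pull in an outgroup leaf; the clade reached is the
   focal gene's side of the family, with paralogous ingroup sub-clades
   still attached.
3. **`delimit_ortholog_subclade`** — walk rootward again and stop at the
   *first* node whose leaf set contains an anchor-species sequence: the
   smallest clade containing the focal gene and an anchor sequence.
   Because clades containing a fixed leaf are nested, "smallest" and
   "first hit on the walk" coincide; the test suite nevertheless checks
   the walk against a brute-force enumeration of all clades. Anchor
   leaves are part of the returned ortholog set (the anchor is a scored
   species). If the clade contains no anchor sequence the whole clade is
   returned with `fallback_used = TRUE` — species without anchor
   co-orthologs are still scored.

"Closest anchor sequence" is interpreted *topologically* (shallowest
anchor-containing ancestor), the reading that makes the delimited set a
clade by construction. A patristic alternative (anchor at minimal
branch-length distance, then the MRCA clade) is exposed as
`anchor_choice = "patristic"` since the source phrasing does not fix the
metric. Bootstrap supports are carried through but not used: no support
threshold is part of the rule; families judged "insufficiently resolved"
are a curation decision upstream of this package, which only emits flags.

Multifurcations are accepted as-is: a multifurcating node's clade is its
full leaf set, never implicitly resolved.

## Filtering rules at the format boundaries

* `filter_blast_hits(hits, max_rank = 1000, evalue_cutoff = 1e-10)`
  keeps, per query, the hits with rank ≤ 1000 **or** e-value < 1e-10.
  The recovery phrasing ("the first 1000 hits, or all hits with e-value
  below 1e-10") is read as a union because the step exists to maximise
  recall of candidate homologs; `rule = "rank"` / `"evalue"` reproduce
  the single-criterion readings. Rank is order of appearance in the
  source file (BLAST emits by decreasing bit score); ties are never
  re-sorted. A filtered table keeps its original ranks, which makes the
  filter idempotent.
* `trim_gap_columns(aln, gap_fraction = 0.10)` removes every alignment
  column whose gap fraction is ≥ the threshold — inclusive, so 1 gap in
  10 sequences (exactly 10%) removes the column while 1 in 20 keeps it.
  Only `-` is a gap by default; `dots_as_gaps = TRUE` tolerates the `.`
  dialect.

## The presence matrix and phenotype contrast

`build_presence_matrix` is a pure tabulation of ortholog calls into a
genes × species copy-number matrix (0 = absence; presence is count ≥ 1,
matching a yellow/blue heatmap encoding with a copy-number gradient).
The species columns are caller-chosen: outgroup species never carry
ortholog copies, so analyses of the studied species normally pass the 32
ingroup codes. `contrast_by_phenotype` emits, per gene, the 2 × 2
presence × phenotype table over the phenotyped species (unknowns are
kept in the matrix but excluded from contrasts) and the difference in
presence proportions. No hypothesis test is attached — the upstream
finding this reproduces is a *qualitative* absence of correlation, and
the tables are emitted so any test can be applied downstream.
`group_by_category` summarises presence per functional category to ask
whether losses concentrate in any functional class.

## The expression summary

Within each species, per-gene expression is summed over all
seed-development kinetic samples (`kinetic_sum`), genes are ranked by
that SUM (ties broken lexicographically for determinism), and every SUM
is expressed as a percentage of the mean SUM of the ten most-expressed
genes (`relative_sum_percent`):

$$\mathrm{SUM\%}_g = 100 \cdot \frac{\mathrm{SUM}_g}{\tfrac{1}{10}\sum_{r=1}^{10}\mathrm{SUM}_{(r)}}$$

This makes values comparable across datasets with heterogeneous units:
SUM% is invariant under any global rescaling of a species' table, and
the mean SUM% of the ten reference genes is exactly 100. With fewer than
10 genes the reference falls back to the all-gene mean and the result is
flagged. In allopolyploids (e.g. *C. sativa*, *B. napus*) homeologous
copies of a reference gene are summed first (`sum_homeologs`); a map
homeolog missing from the table contributes zero with a warning by
default (`missing = "error"` to refuse). The display scale
(`heatmap_color`) is the published three-anchor scale — 0 blue, 1
yellow, 40 red — interpolated linearly *in the value* within each
segment (the source names only the anchors; linear-in-value is the
simplest monotone, continuous completion) and clamped to red above 40.

## The synthetic world

Everything above is testable offline against
ground truth generated by the package itself:

* `species_tree_fixture()` — a fixed ultrametric 34-species tree of
  depth 1.0: outgroup pair, *Aethionema*-like anchor pair diverging
  first within the ingroup, then three ladders of 10 species mirroring
  the major Brassicaceae lineages. The topology abstraction follows the
  study design; branch lengths are invented but fixed constants
  (divergences at 0.85/0.70/0.65 and 0.50-deep lineage ladders), chosen
  so that no branch is negligible relative to the event rates used in
  testing.
* `simulate_gene_family()` — one gene lineage enters the root;
  along every species-tree branch each lineage duplicates at rate
  λ and dies at rate μ (a linear birth–death process, simulated
  event-by-event with exponential waiting times), and speciates at every
  species-tree node. Node labels record `S`/`D` events; the expected
  copy number per species has the closed form $e^{(\lambda-\mu)t}$ with
  $t = 1$ on the fixture, which the suite checks against the empirical
  mean of 2,000 unconditioned replicates at (λ, μ) = (0.2, 0.1). The
  pipeline-facing default *conditions on focal-species survival* by
  resampling (the workflow is only defined for families that contain the
  focal gene); calibration tests disable that conditioning because the
  conditioned mean is biased upward by design.
* Ground truth: a leaf is a true ortholog of the focal copy iff their
  MRCA in the event-labelled tree is a speciation node — restricted to
  non-outgroup species, because the rooting taxa are a device, not
  scored species (otherwise the no-event limit could never reach
  recall 1, as delimited sets never contain outgroup leaves).
* `make_expression_fixture()` — log-normal magnitudes (heavy tail), ten
  designated genes rescaled to strictly dominate the ranking, optional
  homeolog splits whose parts sum bit-exactly to the parent row (the
  parent is redefined as the sequential floating-point sum of its
  parts, the same order of additions `sum_homeologs` performs).
* `make_cesa9_fixture()` — the study's striking loss pattern (*CESA9*
  retained only in the three *Arabidopsis* species plus the anchor) as a
  constructed tree the caller must reproduce exactly.

What a green suite does **not** establish: the simulator produces
topologically *congruent* gene trees (losses prune leaves but never
rearrange), so rooting and extraction are never stressed by inference
error unless `nni_moves > 0` is used; real gene trees carry estimation
noise, alignment artefacts and incomplete lineage sorting that the
generator does not emulate. A consequence worth knowing: under pure
duplication/loss noise, *recall* of the delimited set stays at 1.0 (the
anchor bound can only over-include paralogs, and congruent topologies
cannot misroot), so the degradation trend over increasing loss rates
holds as equality while *precision* is the quantity that visibly drops.

## Numerical and degenerate-input choices

* Rooting tie-breaks are fully deterministic (edge nearest the first
  outgroup leaf in input order); same seed ⇒ bit-identical simulator
  output, summaries and benchmark tables.
* A focal leaf sister to an outgroup leaf yields a single-leaf focal
  clade (`phylo_tip` stub), which delimits to the focal leaf alone with
  `fallback_used = TRUE`.
* An all-zero expression table has reference 0 and errors as degenerate;
  a single-phenotype species set makes the contrast degenerate and
  errors; an empty alignment is rejected at construction.
* Trimming can remove every column; the result is a valid zero-column
  alignment.
* Per-family pipeline failures (no outgroup leaf, missing focal gene)
  are logged per gene and surface as all-zero matrix rows — skip and
  log, never a silent drop.

## Limitations

* Only the clade rule is implemented — no reconciliation-based orthology,
  no ancestral-state reconstruction of myxospermy, no phylogenetically
  corrected association test.
* Expression comparisons inherit the source studies' units; SUM% is a
  within-species normalisation, not a cross-species expression model.
* The simulator is tree-level only; no sequences are generated, since no
  stage of the pipeline interprets sequence content.
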