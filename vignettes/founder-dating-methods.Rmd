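---
title: "Methods: motif-based haplogroup classification and rho-statistic founder dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-based haplogroup classification and rho-statistic founder dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofounder)
library(dplyr)
```

## The problem

Maternal lineages of founder populations — the European Romani being the
canonical example — leave a characteristic signature in mitochondrial DNA:
a handful of haplogroups at high frequency but very low internal diversity,
with star-like genealogies that radiate from a single founder haplotype.
Quantifying that signature requires four ingredients that this package
implements as one coherent pipeline:

1. parsing haplotypes reported in rCRS-relative variant notation
   (`T16298C`, `@16129`, `315+C`, ...), with hotspot masking;
2. allocating each haplotype to a named haplogroup via a diagnostic-variant
   tree, honouring what the record's sequenced range can and cannot show;
3. building a rooted maximum-parsimony tree for the members of a clade; and
4. converting the clade's average mutational depth into an age.

A synthetic-data layer simulates star and coalescent genealogies, Poisson
mutation accumulation and mixed databases with known truth, so every stage
is testable end to end without external downloads.

## Variant notation and the reference problem

All coordinates are 1-based rCRS positions (16,569 bp). A substitution is a
transition when reference and derived base form an A/G or C/T pair and a
transversion otherwise; `@`-prefixed tokens are reversions to the reference
state; insertions (`315+C`) and deletions (`16166d`) are carried but
excluded from the masked length-variation stretch; IUPAC-ambiguous derived
states are parsed as point heteroplasmies and excluded from all computation.
Annotation suffixes used in figure notation (`s`, `-t`, `-r`, `-nc`,
bracketed amino-acid changes, a leading `*`) are retained verbatim but never
affect identity.

The package does not bundle the complete reference genome. Instead it ships
a curated *base catalog*: the reference base at every position used by the
packaged haplogroup tree, the hotspots and the common control-region
nomenclature, assembled from the variant tokens themselves (a token
`T16298C` fixes the rCRS base at 16298). Token validation checks stated
reference bases against this catalog — strict by default, downgradable for
ref-free dialects such as `16223T`. Where a base is needed at *every*
position (aligned-sequence diffing, simulation), `synthetic_reference()`
provides a deterministic stand-in that carries the true base at every
cataloged position and pseudo-random bases elsewhere; it is labelled
synthetic, and any true reference FASTA can be supplied through
`read_reference_fasta()` instead.

## Hotspot masking

Phylogenetic reconstruction and dating exclude the three fastest point
hotspots (16182, 16183, 16519), indel variation in the 303–315
length-variation stretch, and point heteroplasmies. `hotspot_policy()`
makes the exclusions explicit and configurable; `mask_hotspots()` is
idempotent. The default clock rate (below) is calibrated on the same
masked mutation set, so masking and dating are consistent by construction.

## Haplogroup classification

A haplogroup tree is a rooted tree of named clades, each carrying the
diagnostic mutations of the branch leading to it; the cumulative motif of a
clade is the union of diagnostics from the root down, with back mutations
removing earlier variants at the same position. For a record with sequenced
ranges, each diagnostic is either *covered* (inside a range) or not.
The score of a node is `matched − missing_covered`: covered diagnostics
present minus covered diagnostics absent. Private variants are free — the
clades of interest are recognisable despite one or two extra mutations.
Uncovered diagnostics are neither credited nor penalised; if the winning
node has any, the assignment is flagged `candidate`, mirroring how a
control-region-only record can only ever be a candidate member of a clade
defined partly by coding variants.

Ties break by greatest depth, then name. One deliberate consequence: an
HVS-I-only record carrying exactly a clade's control-region motif is pushed
to the deepest nested node whose additional diagnostics are all uncovered —
as a flagged candidate, never as a confident call. The packaged mini-tree
covers the signature South Asian branches (M5a1b1a1, M35b2a1, M18), the
West Eurasian ones (U3/U3b1c, H5a2, H24, H88a), A2, M1/M1a1 and L2/L2c,
plus minimal macro-scaffolding; scaffold nodes whose defining variants were
not transcribed carry no diagnostics and are documented as such. The tree
file's alias table resolves the doubly-printed spelling of the U3 basal
landmark (16343 vs 16344): the M35b2a1 profile pins rCRS 16344 to C, so
A16343G is taken as canonical and the 16344 spelling is mapped onto it.

`search_motif()` implements range-aware database searches: a record is a
hit when its ranges cover every motif position, it carries every motif
variant, and (optionally) its classification does not fall under an
excluded clade — the "disregard compatible L branches / A2" style of
filter is configuration, not code. Records without full coverage are
reported separately as not evaluable rather than silently counted as
misses.

## Rooted maximum-parsimony trees

Clade trees are rooted at a designated basal motif — founder clades are
always dated from a named root haplotype — and each member reduces to its
variant set relative to that root (gains, plus `@`-marked losses).
Identical haplotypes collapse into one tip with a multiplicity before any
search. Construction is a recursive partition: candidate child clades at a
node are the carrier classes of the remaining variants; a clade's branch
takes every variant shared by all its members. Small instances (≤ 12
distinct non-root haplotypes, ≤ 25 segregating tokens) are solved by
exhaustive search over candidate clades, minimising total events; beyond
that a greedy rule splits on the most-carried variant, with ties preferring
to keep the less mutable site intact so that a four-gamete conflict
duplicates the event at the more mutable site (falling back to the site
with fewer carriers). Children are ordered by first mutation position and
then tip id, so output is deterministic.

The construction is guarded by an independent exact oracle:
`brute_force_min()` computes the true minimum number of mutation events as
a minimum Steiner tree in the `{0,1}^k` Hamming hypercube over the
segregating tokens (Dreyfus–Wagner dynamic programming, guarded to ≤ 7
distinct haplotypes and ≤ 12 sites). The test-suite checks equality of the
constructed tree's length with the oracle on hundreds of generator-drawn
instances. The oracle explores arbitrary Steiner topologies, including
ones that exploit reversions; the constructor does not propose reversions
below the root, which is the one known gap between the two — it has not
produced a discrepancy on generator-distributed instances, but is the
reason the oracle stays in the suite.

## Founder dating

For a rooted clade tree with branches carrying `m_b` mutations above
`n_b` of the `n` sampled haplotypes (multiplicities count),

- `rho = (1/n) * sum_b m_b * n_b` — the mean mutational distance of each
  sampled haplotype to the root, identical to the direct per-tip average;
- `sigma = sqrt( (1/n^2) * sum_b m_b * n_b^2 )` — the heuristic standard
  error computed from the genealogy estimate.

On a star of `n` tips with one private mutation each, `rho = 1` and
`sigma = 1/sqrt(n)` exactly; these closed forms are asserted in the tests.
`n` counts sampled haplotypes including multiplicities, matching rho's
definition as an average over individuals: five identical genomes plus one
a single transition away give `rho = sigma = 1/6` on a star of length one.

Ages convert through a clock model. The default is linear — one
substitution per 3,624 years over the whole molecule with hotspots masked,
the conventional corrected whole-molecule rate — and `clock_model()`
accepts any non-negative, non-decreasing `convert()` mapping with
`convert(0) = 0` for time-dependent corrections; the package deliberately
ships no hard-coded correction polynomial, since its coefficients belong to
the rate literature, not here. The 95% CI converts `rho ± 1.96 sigma`
through the clock and truncates at zero, which reproduces the
zero-truncated intervals customary for very young clades. Estimates are
monotone in rho for any valid clock. A scope tag (whole molecule vs
control region, inferred from the records' sequenced spans) must match the
clock's calibration scope unless explicitly overridden — dating
control-region-only data with a whole-molecule rate is a classic error and
is refused by default.

## Frequencies, diversity, ancestry partition

`frequency_table()` bins classified records into an ordered category scheme
(signature clades on their own, macro-bins, `other` for records that could
not be placed); fractions are asserted to sum to one and are reported both
raw and as one-decimal percentages. `diversity_summary()` counts distinct
haplotypes on a common sequenced window and the fraction equal to the basal
motif. `ancestry_partition()` implements the phylogeographic admixture
estimate: South Asian = fraction under M excluding M1; sub-Saharan = L
clades; West Eurasian = everything N-derived plus M1 (a toggle reads M1
lineages as African instead, reflecting the genuine ambiguity of
M1-candidate haplotypes); `other` = records left at the root with private
variants. The partition is invariant to record order and database
duplication, which the tests assert.

## The synthetic-data generator

The generator emulates exactly the regimes the analysis is meant to detect:

- **star genealogies** — founder expansions with every lineage radiating at
  the TMRCA (exact depths, by construction);
- **Kingman coalescent genealogies** — waiting times
  `Exp(choose(k,2)/ne_years)` while `k` lineages remain, optionally rescaled
  to a requested TMRCA; expected total branch length `2·Ne·H_{n−1}` is
  verified against that closed form in the tests;
- **Poisson mutation accumulation** — per-branch counts
  `Poisson(rate × years)` over a hotspot-weighted site spectrum
  (hotspots 20× by default, transition:transversion 22:1, both
  conventional orders of magnitude for the control region); a site is never
  hit twice within a lineage, so homoplasy arises only across lineages,
  and a `perfect` switch forces a perfect phylogeny for oracle tests;
- **mixed databases** — records drawn from a planted haplogroup
  composition (largest-remainder apportionment, so the planted fractions
  are recovered exactly), plus Poisson private mutations restricted to
  non-diagnostic, non-hotspot sites.

Every generator takes one explicit seed, draws everything from a single
stream, and restores the caller's RNG state; same seed means bit-identical
output.

What the generator does *not* emulate — heteroplasmy, within-lineage
recurrent mutation, rate variation beyond the hotspot weights, selection,
population structure, sequencing and transcription error — bounds what
passing tests show: they validate the estimators and the plumbing under the
stated models, not the models' adequacy for any particular real dataset.

### The parameter-recovery design

`simulate_founder_recovery()` runs the full pipeline — simulate star
genealogy, sprinkle mutations, rebuild the tree, re-estimate the age — with
`n = 20` lineages and an expected `mu·T = 2` mutations per lineage, the
regime of a young founder clade. The mutation spectrum for this experiment
excludes the hotspot positions, because the clock counts only non-hotspot
substitutions; simulating countable and uncountable mutations at one rate
and then masking would deflate rho by design, not by error. Across
replicates the mean recovered rho must sit within three Monte-Carlo
standard errors of 2 and the 95% CI must cover the true TMRCA between 90%
and 98% of the time. The suite runs 500 replicates (and 200 random
instances for the parsimony oracle; the module tests use smaller designs) —
sizes chosen to make the Monte-Carlo error small relative to the
tolerances being asserted.

## Numerical and degenerate-input choices

- Empty clade trees are errors; a clade whose members all equal the root
  has `rho = sigma = 0` and age 0 with CI starting at 0.
- Ranges are inclusive 1-based intervals; a record may carry several; every
  variant must fall inside one, enforced at construction.
- Duplicate substitution positions within one record are invalid;
  insertions may share a position.
- Tie-breaks everywhere are total orders (score, depth, name; carrier
  count, mutability, token), so all outputs are deterministic.
- The default HVS-I window is 16024–16400, wide enough for every packaged
  motif; the exact right edge differs between compiled studies, so it is
  an argument wherever records from heterogeneous sources are compared.

## Known limitations

- The classifier is combinatorial, not probabilistic: no likelihoods over
  mutation rates, no calibrated uncertainty on assignments beyond the
  candidate flag.
- The parsimony constructor commits to a tree; median-network-style
  reticulations are out of scope, and its reversion-free search below the
  root is heuristic, guarded (not replaced) by the exact oracle.
- The packaged haplogroup tree is a deliberately small excerpt, not a
  nomenclature mirror; real studies should load their own tree file.
- Dating full clades of real mitogenomes requires the sequences themselves;
  the package validates its estimators by simulation and worked structural
  examples instead of bundling third-party data.
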