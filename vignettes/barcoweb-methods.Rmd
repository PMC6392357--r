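---
title: "Methods: comparing observation- and barcoding-based plant-herbivore webs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing observation- and barcoding-based plant-herbivore webs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcoweb)
```

## The problem

Plant–herbivore interaction networks are usually built one of two ways.
The *observation* route records which tree a larva was collected from
(e.g. by insecticide fogging of a focal crown) and treats co-occurrence
as an interaction. The *molecular* route identifies the plants a larva
actually ate by amplifying plant barcode markers (rbcLa, trnL, ITS2)
from its gut contents and matching them against a local reference
library. The two routes disagree systematically: larvae drop or
disperse from neighbouring trees (false positives for observation), and
markers cannot always separate congeneric plants (resolution loss for
barcoding). `barcoweb` implements the full comparison: insect OTU
delimitation from COI, multi-marker diet identification with resolution
scoring, construction of both bipartite webs, node/link overlap,
spatially explicit mismatch attribution, a network-metric suite,
size-matched null comparison, and a logistic model of detection
probability — plus a seeded synthetic-data generator so that every
stage is testable end to end without any external data.

## Sequence handling and OTU delimitation

Gut and COI sequences are compared with the uncorrected *p*-distance
(mismatches over comparable sites) under pairwise deletion: positions
where either sequence carries a gap or `N` are excluded. No model
correction is applied; the divergence-threshold convention the package
follows is defined on raw distances. Sequences are assumed pre-aligned
or equal-length by construction (the generator produces ungapped
equal-length markers; an external aligner can be used for real data).

Quality control keeps a sequence iff its ungapped length is at least
80% of the marker's expected length, with the boundary inclusive.
Expected lengths are 540 bp (rbcLa), 500 bp (trnL) and 350 bp (ITS2 —
amplicons span roughly 350–400 bp, and the lower bound is used so the
80% rule is well defined); COI is configurable (658 bp default).

OTUs are delimited by agglomerative clustering of the distance matrix
cut at 2% divergence. The linkage is a flag (`average` default,
`single`, `complete`): the upstream tools this emulates do not document
their linkage, so the classic default of threshold-based OTU software
is used and the choice is exposed rather than hidden. Cluster labels
are assigned deterministically in order of each cluster's
lexicographically smallest member id. Taxonomy assignment follows
family-consistency rules: a best hit whose family agrees with the
morphological family (or with no morphological family available) gives
the species label; otherwise the highest-ranked top-5 hit in the
morphological family is used; OTUs with no top-5 hit in the
morphological family are discarded as cross-family conflicts, OTUs
hitting outside the target order are discarded outright, and best hits
below a species-level identity floor yield a family-level label.

## Diet identification

Each QC-passed gut sequence is scored against every reference sequence
for its marker by identity fraction (matches over comparable sites).
The candidate set is all taxa at the maximal identity; results below a
configurable identity floor (default 0.95 — no published floor exists,
so a conservative barcoding convention is used) are treated as
unidentified. Markers whose candidate sets intersect are merged into
one diet item resolved to the intersection, so an extra marker can only
sharpen a call; disjoint candidate sets are kept as *separate diet
items* and interpreted as multiple true food plants, not as errors —
caterpillars do eat several plants, and the output flags such larvae
for audit. An item's resolved level is species for a singleton, genus
when all members are congeneric, family when confamilial.

Resolution scoring assigns 1 when an item is unambiguous at a level
within the local library, 0 when ambiguous, and a conservative 0.5 at
species level for nontree taxa (bamboos, lianas, bryophytes, parasites)
that lack local plot references but are distinguishable from all local
sequences. Summaries average over *diet individuals* — a plant eaten by
ten larvae counts ten times — per marker and for the combination.

## Webs, overlap, and mismatch attribution

The observation web counts larvae of each insect on each collection
tree; the molecular web adds one count per diet item, with species
complexes (sets of indistinguishable congeners) forming single columns
that merge into their genus at genus level. Overlap tables report, for
plant nodes and for links (restricted to shared plant nodes, and over
all nodes), the counts and percentages found by both methods or by one
only. A complex matches an observation species when that species is a
member — the complex is the molecular method's best statement of the
same node. Percentages are rounded half-up to one decimal for table
parity.

Mismatch attribution classifies each larva with a non-empty diet call,
per item and in this order: unambiguous agreement with the collection
species is a **match**; a nontree diet is observation-method sampling
bias (**nontree**); an item ambiguous at species level is
**near-neighbour** bias when any member has a stem within 2 m of the
collection stem and **low-resolution** (molecular) bias otherwise; an
unambiguous non-matching species is **near** or **far** by the same
radius. "Within 2 m" is inclusive (the collection sheet is 2 × 2 m),
and distances are stem-to-stem Euclidean — crown extent is ignored
because no crown data exist in the designs this emulates. Multi-item
larvae take the most favourable category in the order match > near >
far > nontree > low-resolution; the source convention classifies each
larva once but does not state a multi-diet precedence, so this
documented rule is used. Method contributions are computed over
mismatched larvae only: near + far + nontree is observation bias,
low-resolution is molecular bias.

## The metric suite

All metrics treat webs smaller than 2 × 2 as degenerate and return
`NA`.

**H2′ specialization** standardizes the two-dimensional Shannon entropy
of the interaction proportions between its minimum and maximum over
matrices with the observed marginal totals. For small integer webs
(both dimensions ≤ 4 and a composition bound of ≤ 2 × 10^4^ candidate
tables) the bounds come from exhaustive enumeration of all integer
tables with those margins; otherwise H2max is the independence
(outer-product) entropy — the exact continuous maximum — and H2min
comes from a greedy mass-concentration heuristic (repeatedly place
`min(row remainder, column remainder)` in one cell, ties resolved
row-major). If enumeration returns degenerate bounds (margins that
force the table, e.g. 0/1 permutation webs), the continuous maximum is
used so forced perfectly specialized webs score 1. The result is
clamped to [0, 1].

**Interaction evenness** is the Shannon entropy of the cell proportions
over log(R × C) by default; the denominator is switchable to the log of
the number of realized links, since the source convention names only
"Shannon's evenness" and both conventions circulate.

**Generality and vulnerability** are mean partner counts per insect /
per plant: raw nonzero counts on the binary web (qualitative) or
effective partner numbers, exp of each node's interaction entropy,
weighted by the node's share of total interaction weight
(quantitative).

**NODF / weighted NODF** use paired overlap with decreasing fill over
all row and column pairs, averaged on the 0–100 scale, after sorting
rows and columns into the canonical order (decreasing fill; weighted
ties broken by decreasing marginal totals, then original index). A pair
contributes only when fill strictly decreases; the weighted score
counts cells where the poorer node's weight is positive but strictly
below the richer node's. This matches the canonical implementation of
the cited nestedness methods, and the test suite verifies exact
agreement with `vegan::nestednodf` on random webs.

**Barber bipartite modularity** Q = (1/F) Σᵢⱼ (Aᵢⱼ − kᵢdⱼ/F) δ(gᵢ, hⱼ)
is maximized by weighted label propagation with agglomerative
refinement: the first restart seeds one module per insect node with
greedy column attachment; subsequent restarts seed rows and columns
jointly from a random label pool so different basins are explored. Each
restart alternates single-node best-label sweeps (a node may open a
fresh module when every existing module scores negatively) until no
label changes, then greedily merges the module pair with the largest
positive modularity gain (tolerance 10⁻¹²), re-propagating after each
merge. The best partition over ten restarts is kept, and the
single-module partition (Q = 0) is the floor. The search is seeded and
reproducible; the test suite checks it against exhaustive partition
enumeration on webs up to 4 × 4.

## Null comparison

To control for network size, each observation-web metric is compared
with the distribution over randomized subwebs of the molecular web.
"Equal number of nodes" is implemented as separately matched insect and
plant node counts, because bipartite metrics depend on both dimensions.
Subwebs are uniform row/column subsets, rejection-resampled (cap
10,000) until no all-zero row or column remains, keeping node counts
exact; whether the source convention rejected or dropped empty nodes is
unstated, and rejection is the documented choice here. Note that a very
sparse molecular web may admit no induced subweb at the full
observation size — the pipeline then reports the condition and skips
the envelope rather than silently changing the target size. The
envelope reports the null mean and the percentile 95% interval
(percentile rather than normal-approximation, because metric
distributions are skewed at small sizes; interpolated type-7 quantiles,
which makes finite-draw coverage slightly below nominal — about 94%
with 1,000 draws in the package's own coverage check). Rare-link
pruning (counts ≤ 2 zeroed, empty nodes dropped) supports the
robustness variant of the comparison.

## Detection model

Each classified larva contributes one record: x is the total number of
observed occurrences of its insect species on its collection host
across the dataset, y = 1 iff its category is match. Records are per
larva, not per unique pair. The logistic fit is maximum likelihood via
IRLS (deviance tolerance 10⁻⁸) with Wald z and p per coefficient;
complete separation and single-class responses are rejected with
errors. An optional body-size covariate supports the null check that
size does not affect confirmation.

## The synthetic-data generator

The generator emulates the sampling design the analysis assumes, at the
study's own scale by default: a 1000 × 500 m (50 ha) mapped plot, 213
tree/shrub species of which 72 are fogged, 15 unsampled nontree taxa,
and 2,235 larvae. Stems follow a homogeneous Poisson process (a
clustered Thomas process is optional; Poisson is the default because it
has closed-form checks, e.g. mean nearest-neighbour distance
1/(2√λ)). Species are grouped into genera and families at the richness
ratios of a diverse subtropical plot (~1.65 species per genus, ~2.15
genera per family).

Each larva draws a true diet location class — focal tree / near
neighbour (≤ 2 m) / far neighbour / nontree — with probabilities
(0.25, 0.11, 0.52, 0.12) by default, a calibration that mirrors the
published mismatch composition with ambiguous-taxon larvae folded into
the far class. At the default stem density most stems have *no*
heterospecific neighbour within 2 m, so larvae in the near class draw
their collection stem among stems that have one, and far diets are
drawn among species whose nearest stem is beyond the radius; this keeps
the planted class exactly consistent with the realized stem geometry,
which is what lets the classifier's output be compared to the planted
proportions without bias. Insect loads are lognormal; the per-tree
larva count distribution is not fixed by any source and is therefore an
emergent property of total larva count and loads rather than a modelled
quantity.

Sequences are uniform-random ancestors per taxon per marker with
i.i.d. substitutions (intraspecific divergence 0.004 by default, within
the range reported for Lepidoptera COI; random ancestors give
heterospecific divergence far above any threshold), with no indels —
gap handling is exercised through truncated low-quality reads (trailing
gaps) and fixtures instead. Species flagged indistinguishable
(probability 0.12, matching the observed share of ambiguous larvae)
share byte-identical plant-marker sequences with one congener. Marker
amplification is independent Bernoulli per marker per larva — no
dependence structure is documented for the failures this emulates —
with defaults (0.19, 0.14, 0.075) chosen so per-marker sequence yields
keep the published rbcLa : trnL : ITS2 ratio and overall recovery lands
near 36% of larvae; 5% of amplified reads are truncated below the QC
threshold. Insect richness is scaled to 60 species (the study had 406):
larva count, not insect richness, drives every recovery statistic the
package validates. All randomness derives from one root seed through
fixed offsets, and identical parameters plus seed give byte-identical
outputs.

What the generator does *not* emulate: phylogenetically realistic
sequence evolution, seasonal/phenological structure, crown geometry,
abundance–body-size allometry, and PCR artefacts. Passing the
end-to-end tests therefore shows the pipeline's logic is correct under
the stated statistical structure, not that real gut-content data will
be as clean: real markers fail non-independently, real congeners
diverge continuously rather than being identical-or-separated, and
real larvae are collected with spatial and temporal correlation.

## Validation design and problem sizes

The test suite validates each stage against independent oracles:
clustering against a brute-force average-linkage merge scan (webs of up
to 8 sequences), distances against `ape::dist.dna`, NODF against
`vegan::nestednodf`, H2′ bounds against grid enumeration of integer
tables, and modularity against exhaustive partition enumeration on 200
random webs up to 4 × 4. Property checks use 1,000 random H2′ extreme
cases, 200-replicate null-envelope coverage with 1,000-draw envelopes
on a 16 × 16 web, logistic parameter recovery at n = 2,000, and one
full-scale end-to-end run (2,235 larvae, 213 + 15 taxa) in the
well-separated regime (`p_species_indistinguishable = 0`), whose
classifier output is compared with the planted four-way proportions at
3σ binomial error. These sizes were chosen so the whole validation runs
in minutes while keeping every statistical check adequately powered.

## Known limitations

* The overlap percentages follow the species-row convention
  (count/total); one published genus-row percentage set is internally
  inconsistent with its printed total and is deliberately not
  reconciled.
* Published resolution and structural-property tables cannot be
  reproduced without the original specimen-level data; the package
  validates the corresponding machinery on synthetic data with known
  truth instead.
* The rejection-sampled null keeps node counts exact but becomes
  infeasible for very sparse molecular webs at full observation size;
  the envelope is then skipped with a warning rather than approximated.
* Identity search is exact within the local reference library; there is
  no remote database search, chimera detection, or metabarcoding read
  processing.
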