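# barcoweb

Builds and compares bipartite plant–herbivore interaction networks
obtained by two routes: **field observation** (a larva is linked to the
tree it was collected from, e.g. by canopy fogging) and **DNA
barcoding of gut contents** (plant residues amplified with rbcLa, trnL
and ITS2 markers and matched against a local reference library). The
two routes disagree in characteristic ways — larvae drop or disperse
from neighbouring trees, and markers cannot always separate congeneric
plants — and this package quantifies each side of the disagreement.

It is aimed at community ecologists working with interaction networks
who want a tested, reproducible implementation of the whole chain:

* **OTU delimitation** of insect COI sequences by agglomerative
  clustering at 2% uncorrected *p*-distance (pairwise deletion), with
  family-consistency taxonomy rules and QC (ungapped length ≥ 80% of
  the marker's expected length);
* **diet identification** per larva from up to three plant markers:
  candidate sets at maximal identity, set-intersection combination
  across markers, species complexes for indistinguishable congeners,
  and resolution scores in {0, 0.5, 1} at family/genus/species levels;
* **web construction and overlap**: observation and molecular count
  matrices at species or genus level, with T+M+/T+M−/T−M+ node and
  link overlap tables;
* **mismatch attribution**: each larva classified as match /
  near-neighbour (≤ 2 m) / far-neighbour / nontree / low-resolution,
  splitting the disagreement into observation-method and
  molecular-method bias;
* a **network-metric suite**: H2′ specialization, interaction
  evenness, qualitative and quantitative generality/vulnerability,
  NODF and weighted NODF nestedness, and Barber bipartite modularity
  maximized by seeded weighted label propagation (LPAwb+-style);
* **size-matched null comparison**: metrics of the observation web
  against percentile envelopes from randomized subwebs of the
  molecular web, plus rare-link pruning;
* a **logistic detection model**: probability that the molecular
  method confirms an observed pairing as a function of how often the
  pairing was observed;
* a fully seeded **synthetic-data generator** (mapped plot, stems,
  larvae, toy barcode sequences with controlled divergences) so the
  pipeline is testable end to end with known truth.

## The statistics at the core

For a count web `A` with total `F`, row strengths `k_i`, column
strengths `d_j` and proportions `p_ij = A_ij / F`:

* **H2′** = (H2max − H2) / (H2max − H2min), where
  H2 = −Σ p_ij ln p_ij and the bounds are over matrices with the
  observed marginal totals (exhaustive for small integer webs, greedy
  heuristic plus the independence entropy otherwise). 1 = maximal
  specialization, 0 = the neutral expectation from the marginals.
* **Interaction evenness** = H2 / ln(R·C) (denominator switchable to
  realized links).
* **Quantitative generality/vulnerability** = Σ_i (A_i·/F) · exp(H_i),
  the abundance-weighted mean effective partner number; qualitative
  variants count realized partners on the binary web.
* **NODF / WNODF**: mean paired overlap with decreasing fill over all
  row and column pairs, 0–100 (weighted form counts cells where the
  poorer node's weight is positive but lower).
* **Barber modularity** Q = (1/F) Σ_ij (A_ij − k_i d_j / F) δ(g_i, h_j),
  maximized over bipartite module assignments.
* **Detection model**: y ~ Bernoulli(p), logit(p) = β0 + β1·x, with x
  the observed occurrence count of the insect–host pair.

## Worked example

Simulate a community and run the whole pipeline:

```r
library(barcoweb)

params <- community_params(
  n_tree_species = 60, n_sampled_species = 30, n_nontree_taxa = 8,
  stems_per_species = 30, n_insect_species = 15, n_larvae = 600,
  rng_seed = 42)
cfg <- pipeline_config(params, seed = 42, n_draws = 200)
result <- run_pipeline(cfg)
result
#> barcoweb pipeline result
#>   larvae: 600 (diet identified for 34.7%)
#>   insect OTUs: 15
#>   observation web: 14 insects x 30 plants
#>   molecular web:  14 insects x 62 plants
#>   mismatch percentages:
#>          match  near_neighbor   far_neighbor        nontree low_resolution
#>           20.7           14.9           51.0           13.5            0.0
```

Gut contents were identified for 34.7% of larvae; all 15 planted
insect species were recovered as OTUs; and only a fifth of larvae were
confirmed to feed on the tree they were collected from — the rest of
the disagreement is attributed spatially (nearly all of it to
observation-method bias here, since this run used well-separated
sequences and so has no low-resolution larvae).

```r
result$resolution_summary
#>     marker family_pct genus_pct species_pct n_sequences
#> 1    rbcLa        100       100        91.7         114
#> 2     trnL        100       100        95.0          80
#> 3     ITS2        100       100        95.5          44
#> 4 combined        100       100        93.3         208

round(result$metrics_obs, 3)
#>             h2_prime interaction_evenness      generality_qual
#>                0.355                0.797                9.857
#>   vulnerability_qual     generality_quant  vulnerability_quant
#>                4.600               13.890                4.743
#>            nodf_qual           nodf_quant         modularity_q
#>               49.361               16.313                0.279

result$envelope
#> Null envelope: 200 randomized subwebs (seed 83, 95% CI)
#>                metric observed null_mean ci_lower ci_upper outside_ci n_na
#>              h2_prime   0.3545    0.5175   0.4789   0.5578       TRUE    0
#>  interaction_evenness   0.7972    0.7276   0.7081   0.7464       TRUE    0
#>       generality_qual   9.8571    6.1257   5.4286   6.8571       TRUE    0
#>    vulnerability_qual   4.6000    2.8587   2.5333   3.2000       TRUE    0
#>      generality_quant  13.8903    9.6133   8.3238  11.0454       TRUE    0
#>   vulnerability_quant   4.7430    3.2811   3.0255   3.5652       TRUE    0
#>             nodf_qual  49.3610   32.2741  26.8358  38.1444       TRUE    0
#>            nodf_quant  16.3130    5.7787   3.7489   8.3250       TRUE    0
#>          modularity_q   0.2787    0.3933   0.3565   0.4305       TRUE    0
```

Every metric of the observation web falls outside the 95% envelope of
size-matched molecular subwebs: with most larvae planted as dispersers
from far neighbours, the observation web is less specialized (lower
H2′), more even, more nested and less modular than diet-based webs of
the same dimensions — the signature this analysis is designed to
detect.

Published-table arithmetic works directly on counts:

```r
s <- summarize_mismatch(c(match = 204, near_neighbor = 85,
                          far_neighbor = 319, nontree = 91,
                          low_resolution = 96))
s$percentages
#>          match  near_neighbor   far_neighbor        nontree low_resolution
#>           25.7           10.7           40.1           11.4           12.1
c(s$contrib_observation_pct, s$contrib_molecular_pct)
#> [1] 83.8 16.2

predict_probability(c(-2.11, 0.39), 20)
#> [1] 0.9966318
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/barcoweb.R`
(`Rscript barcoweb.R run --config cfg.json --seed 1 --outdir out/`).

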