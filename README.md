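# phyloprior

Regional phylogenetic conservation prioritization in R: EDGE2 scoring with
extinction-risk resampling on a dated phylogeny, phylogenetic-diversity
metrics, DNA-barcode discriminatory-power statistics, and trait–threat
tabulations and rank correlations.

## Who this is for

Conservation biologists and phylogeneticists prioritizing a regional flora
or fauna — the motivating case is a comprehensively assessed orchid flora
with Red List assessments at two scopes (a regional list and a national
list) and a time-calibrated phylogeny — who need reproducible, seedable
implementations of the whole workflow, from Newick/FASTA/CSV inputs to
ranked priority tables.

## The model at the core

EDGE2 scores each taxon by its expected contribution of unique
evolutionary history weighted by its extinction risk:

    EDGE2_i = ED2_i × GE2_i

    ED2_i = TBL_i + Σ_j ( L_{i,j} × Π_{k ∈ C_{i,j} \ i} p_k )

`ED2_i` is taxon *i*'s *expected unique phylogenetic diversity*: its
terminal branch length `TBL_i` plus each ancestral branch `L_{i,j}`
weighted by the probability that every other tip descending from that
branch (`C_{i,j} \ i`) goes extinct, with `p_k` the per-taxon extinction
probabilities.  `GE2_i` is a 50-year extinction probability drawn from a
category-specific pool whose median is pinned exactly to the stated risk
for that Red List category (CR 0.97, EN 0.485, VU 0.2425, NT 0.12125,
LC 0.060625) and whose support is the category's published interval.
Joint resampling (default 500 draws) yields per-taxon medians and
interquartile ranges, and a dense ranking by EDGE2 median.

Around the core: total PD and fair-proportion ED (with an ED ~ threat
OLS), Kimura-2-parameter barcoding-gap analysis with a within/between
diversity decomposition, Spearman trait–threat correlations with the
field's coding schemes, and seeded generators producing synthetic inputs
with the study's statistical structure.

## Worked example

Generate a study-shaped synthetic data set (134 taxa, 110-Myr ultrametric
tree, regional + national categories, four coded traits, one
multi-accession marker) and run the scoring:

```r
library(phyloprior)
bundle <- make_fixture(n_taxa = 134, seed = 42)
fit <- edge2(bundle$tree, bundle$assessments, scope = "hk",
             n_draws = 500, seed = 1)
fit
#> EDGE2 fit: 134 taxa, scope 'hk', 500 draws
#> total PD: 2879.43 Myr
#> top 5 by EDGE2 median:
#>  taxon category EDGE2_median EDGE2_IQR rank
#>  sp055       RE        53.58     8.802    1
#>  sp081       RE        47.89     8.158    2
#>  sp092       CR        44.15     6.376    3
#>  sp107       CR        38.04     5.758    4
#>  sp022       RE        33.39     5.482    5
```

The top ranks go to regionally extinct and critically endangered taxa on
long branches: the EDGE2 median is the typical number of million years of
unique evolutionary history expected to be lost with that taxon, and the
IQR is the resampling uncertainty from the extinction-risk draws.  The
score distribution peaks in the lowest class, as regional score
distributions do:

```r
head(edge2_bins(fit), 4)
#>   bin_low bin_high count
#> 1       0        5    74
#> 2       5       10    25
#> 3      10       15    17
#> 4      15       20     6
```

Barcode discriminatory power on the bundled marker — intraspecific
distances two orders of magnitude below interspecific, an unambiguous
barcoding gap:

```r
md <- partition_distances(bundle$alignment)
md
#> K2P distances, marker 'marker1': 80601 pairs (80601 defined)
#>   intra: n=402 mean=0.0030   inter: n=80199 mean=0.0791
#>   pi_total 0.0787  pi_within 0.0030  delta 0.0758  coefficient 0.9622
av <- barcoding_gap_anova(md)
#> F = 4143.5, p ~ 0
```

Trait–threat rank correlations recover the generating associations
(targets: habitat 0.529, mating 0.369, trade 0.119, habit −0.041):

```r
trait_threat_correlations(bundle$assessments, "hk")
#>                 trait scope   n       rho      p.value method  strength
#> 1               habit    hk 131 0.1446217 9.933564e-02      t very weak
#> 2 habitat_specificity    hk 131 0.5479198 1.258470e-11      t  moderate
#> 3              mating    hk  68 0.3485545 3.580777e-03      t      weak
#> 4               trade    hk 131 0.1538024 7.944268e-02      t very weak
```

And the diversity decomposition applied to a published marker's printed
means returns the printed between-species diversity exactly:

```r
diversity_decomposition(0.0480, 0.0038)
#> $pi_total 0.048; $pi_within 0.0038; $delta_between 0.0442; $coefficient 0.9208
```

A command-line wrapper (`inst/scripts/phyloprior`) exposes the same
pipeline as subcommands (`simulate`, `edge2`, `ed`, `barcode-gap`,
`traits`) with manifests for bit-exact replay.

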