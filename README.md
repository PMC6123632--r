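# metabias

Biodiversity estimates for benthic meiofauna — the small (< 1 mm)
invertebrates of 20+ animal phyla living between sediment grains — depend
strongly on how "species" are counted. Surveys based on individual
specimens yield morphotypes (comparative morphology), GMYC entities
(likelihood species delimitation on ultrametric 18S gene trees) or OTUs
(identity-threshold clustering of single-specimen amplicons); surveys
based on environmental DNA yield eOTUs or denoised sequence variants from
metabarcoding reads. Because detection efficiency differs between methods
*and* between phyla, richness, community structure and phylogenetic
diversity inferred from the same fauna can disagree systematically — some
phyla (e.g. Gastrotricha, Nemertea) can appear *less* diverse under
metabarcoding than under morphology.

`metabias` implements every step of this comparison as a tested R
package, for ecologists and bioinformaticians who want to delimit units,
attach taxonomy, compute the standard diversity descriptors, and quantify
cross-method bias — either on their own tables/trees/FASTA files or on
fully synthetic communities with known truth.

## What is inside

* **Delimitation** — `dereplicate_and_denoise()` (sequence variants via
  an abundance-ratio error rule), `cluster_greedy()` (99%-identity greedy
  centroid OTUs with reverse-strand matching), and
  `gmyc_single_threshold()`, a classed model fit of the generalized mixed
  Yule-coalescent: branching older than a threshold age *T* follows a
  Yule process with intensity λ·A(t), branching younger than *T* follows
  per-cluster coalescence with intensity λc·Σ k(k−1)/2; the
  log-likelihood Σ log b(tᵢ) − ∫ b(t) dt is maximised over (λ, λc) at
  every candidate threshold and tested against the nested
  single-process null (LR, χ² df = 2).
* **Taxonomy** — `filter_hits()` (top-five hits within 0.5 identity
  points of the top, span > 120 bp), `consensus_taxonomy()`
  (lowest-common-lineage prefix under the >97/>93/>90 species / family /
  phylum ceilings), `clade_rescue()` (phylum rescue inside a supported
  clade of ≥ 5 assigned same-phylum tips), and a self-contained
  `naive_search()`.
* **Diversity** — incidence-based `chao2()` (S + ((m−1)/m)·Q₁²/(2Q₂)) and
  `jack1()` (S + Q₁(m−1)/m); `faith_pd()`, `mpd()`, `mntd()` and their
  standardized effect sizes `ses()` under a tip-shuffling null.
* **Community structure** — `jaccard_matrix()`, a from-definition
  `permanova()` (sequential SS on the Gower-centered distance matrix,
  permutation p-values, exhaustive and stratified variants; agrees
  exactly with `vegan::adonis2`), and `compare_methods()`, a
  site-stratified permutation harness for per-phylum richness contrasts
  with Holm correction.
* **Marker regions** — `locate_primer_pair()` / `extract_regions()`
  (IUPAC-aware, both strands) and `region_identity_profile()` for the
  V1–V2 vs V9 divergence comparison.
* **Synthetic data** — `simulate_metacommunity()`: Yule species tree,
  Kingman coalescent tip clusters, Jukes–Cantor sequences over
  primer-flanked V1–V2/V9 regions, and a multi-site survey observed
  through a phylum × method detection model with read errors, plus a
  serialized truth object.

A thin command line (`inst/cli/metabias`) exposes the pipeline as
`metabias simulate | delimit | classify | diversity | compare | regions`.

## Worked example

Simulate a biased survey (28 species over 7 phyla at 12 sites; detection
0.95 everywhere except 0.3 for Gastrotricha under metabarcoding), denoise
each method's reads into sequence variants, and test the cross-method
richness contrasts:

```r
library(metabias)

det <- detection_model(0.95, read_depth_mean = 6, error_rate = 0.002)
det$prob["Gastrotricha", "metabarcoding"] <- 0.3
mc <- simulate_metacommunity(n_species = 28, within_species_n = 1,
                             n_sites = 12, occupancy_prob = 0.5,
                             detection = det, seed = 1)
cmp <- compare_methods(survey_unit_sets(mc$survey), n_perm = 399, seed = 1)
print(cmp)
#> Cross-method comparison of 2 unit sets
#>   summed per-site richness by method:
#>     metabarcoding  203
#>     specimen       208
#>   4 of 8 contrasts significant after Holm correction
#>        phylum method_a      method_b     delta      p p_holm flag
#>      Annelida specimen metabarcoding -1.000000 0.0025  0.020 TRUE
#>  Gastrotricha specimen metabarcoding  4.416667 0.0025  0.020 TRUE
#>      Mollusca specimen metabarcoding -3.250000 0.0025  0.020 TRUE
#>      Nematoda specimen metabarcoding  2.333333 0.0050  0.025 TRUE
```

`delta` is the mean per-site richness difference (specimen −
metabarcoding) within the phylum stratum: the engineered Gastrotricha
deficit appears as the large positive contrast (≈ 4.4 fewer Gastrotricha
variants per site under metabarcoding), flagged at the Holm-corrected 5%
level; the small contrasts in the other direction reflect error-split
variants inflating metabarcoding counts.

GMYC species delimitation on a simulated 5-species tree (4 tips each,
coalescent scale 1% of tree height):

```r
st <- simulate_yule_tree(5, 1, seed = 2)
fit <- gmyc_single_threshold(
  graft_coalescent_tips(st, 4, 0.01 * attr(st, "height"), seed = 3))
summary(fit)
#> GMYC single-threshold species delimitation
#>   tips: 20   entities: 5 (clusters: 5, singletons: 0)
#>   threshold age: 0.190751
#>   logL mixed: 76.7724   logL null: 47.1760
#>   LR = 59.1929, df = 2, p = 1.401e-13
#>   branching rates: lambda = 1.011  lambda_c = 75.07
#>   entity sizes: 4 4 4 4 4
```

All five species are recovered, with a decisive likelihood ratio against
the single-process null and a within-species rate (λc) two orders of
magnitude above the speciation rate (λ), as the 1% coalescent scale
implies.

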