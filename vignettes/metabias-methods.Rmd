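---
title: "Methods: taxonomic-unit definitions and method bias in metabarcoding surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxonomic-unit definitions and method bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabias)
```

## The problem

Benthic meiofauna — the small (< 1 mm) invertebrates of more than twenty
animal phyla living between sediment grains — can be surveyed either by
collecting and identifying individual specimens or by sequencing a marker
gene (here 18S rRNA) directly from environmental samples. Each route
defines its "species" differently: morphotypes from comparative
morphology, evolutionary entities from GMYC species delimitation on an
ultrametric gene tree, OTUs from identity-threshold clustering of
single-specimen amplicons, and eOTUs or denoised sequence variants from
environmental reads. Because detection efficiency differs between methods
and between phyla, richness, community structure and phylogenetic
diversity estimated from the same fauna can disagree systematically.

This package implements each unit definition, the classifier that attaches
taxonomy to anonymous sequences, the diversity descriptors used to compare
methods, and a synthetic-community generator that reproduces the
generative structure the comparison assumes, so that the whole pipeline is
testable end to end without access to survey data.

## Unit delimitation

**Sequence variants** (`dereplicate_and_denoise`). Equal-length reads are
dereplicated exactly; a unique sequence with abundance below
`min_abundance` lying within `max_err_links` substitutions of a unique
sequence at least ten times more abundant is merged into it as a putative
sequencing-error satellite, and remaining low-abundance uniques are
dropped. This abundance-ratio rule is a deliberately simple, fully
specified denoiser: it is not a learned error model, but it reproduces the
qualitative contrast that matters for the method comparison — denoised
variant counts do not exceed clustered OTU counts on noisy reads.
Defaults `min_abundance = 2`, `max_err_links = 1` treat only singletons
adjacent to a dominant sequence as errors.

**OTUs** (`cluster_greedy`). Greedy centroid clustering at 99% global
pairwise identity, processing sequences by decreasing abundance with
lexicographic id as the tie-break, assigning each sequence to the first
centroid reaching the threshold and allowing reverse-strand matches.
The tie-break makes the (order-dependent) greedy procedure reproducible.
Pairwise identity is pinned to a Needleman–Wunsch global alignment with
match +1, mismatch −1, linear gap −2, identity = matches / aligned
columns; without a pinned scoring scheme an identity threshold has no
fixed meaning.

**GMYC entities** (`gmyc_single_threshold`). The generalized mixed
Yule-coalescent model assumes that on an ultrametric gene tree, branching
older than a threshold age $T$ reflects speciation and branching younger
than $T$ reflects within-species coalescence. We model the two processes
as a superposition with total branching intensity

$$b(t) \;=\; \lambda\,A(t) \;+\; \lambda_c\,B(t),$$

where $A(t)$ is the number of species lineages (the crossing-lineage
count above $T$, constant at the entity count below it) and
$B(t)=\sum_j k_j(t)(k_j(t)-1)/2$ sums the coalescent weight over clusters
with $k_j$ lineages. The log-likelihood over the $n-2$ observed waiting
times (the root is a starting condition, not an event) is
$\sum_i \log b(t_i) - \int b(t)\,dt$, maximized numerically over
$(\lambda, \lambda_c)$ at every candidate threshold — the midpoints
between consecutive distinct node ages. We use the superposition form
rather than separate per-class waiting-time products because the
per-class form degenerates: a cluster's root event has zero forward
intensity in its own class, and crediting events with class-specific
backward intensities systematically favors interpreting the whole tree
as one coalescent.

The null model is the single branching process over the whole tree. It
coincides exactly with the mixed model at the youngest candidate
threshold, so it is nested and `logL_mixed >= logL_null` holds by
construction; the likelihood ratio is referred to $\chi^2_2$ (one extra
rate plus the threshold). Single rates are used throughout — no
per-cluster rates and no scaling exponents — which is the simplest form
of the single-threshold method. Exactly tied node ages are perturbed by a
seeded jitter below $10^{-9}$ of tree height before thresholds are
formed, and the fit is invariant to rescaling all branch lengths.

The fit is returned as a classed object with `print`, `summary`, `plot`,
`logLik` and `coef` methods, including the full threshold profile.

Single-threshold GMYC is conservative when speciation events approach the
coalescent time scale: replicate surveys in our own acceptance checks
show that with five species of four tips and coalescent scale 1% of tree
height, a noticeable fraction of replicates has no separating threshold
at all (the deepest within-species coalescence is older than the
shallowest speciation), and near-tie likelihood surfaces then merge or
split one species. Users should read `p_value` (and the profile), not
only `n_entities`.

## Taxonomic classification

`filter_hits` keeps at most five hits per query, drops alignments of
span ≤ 120 bp before determining the top hit, and then drops hits more
than 0.5 identity points below it (all comparisons strict).
`consensus_taxonomy` sets a ceiling rank from the best-hit identity
(> 97 species, > 93 family, > 90 phylum) and assigns the deepest rank at
or under the ceiling on which *all* retained hits agree — the lowest
common lineage prefix, which is the only order-independent reading of a
"best consensus". Raising thresholds or widening the window can therefore
never deepen an assignment; both properties are tested.

`clade_rescue` assigns a phylum to an otherwise unassigned tip when its
smallest supported clade (support ≥ 0.95 by default; nodes without a
numeric support value count as unsupported) contains at least five
*other* tips, all assigned, all to one phylum. Already-assigned tips are
never changed. The smallest-supported-clade rule resolves the ambiguity
of nested qualifying clades; 0.95 is a conventional posterior-support
cutoff and is configurable.

`naive_search` is a self-contained top-k similarity search against a
lineage-labelled reference (global alignment identity, ties by reference
id) so synthetic runs need no external search tool. When the reference
carries no family labels, the species label is reused as its own family
so the rank ladder stays consistent.

## Diversity descriptors

Incidence (presence/absence across sites) is the common currency; read
counts are never interpreted as abundance. With $Q_1, Q_2$ the numbers of
units found at exactly one or two of $m$ sites:

* `chao2`: $S_{obs} + \frac{m-1}{m}\,\frac{Q_1^2}{2Q_2}$, falling back to
  the bias-corrected $S_{obs} + \frac{m-1}{m}\,Q_1(Q_1-1)/2$ when
  $Q_2 = 0$ (logged); always ≥ $S_{obs}$.
* `jack1`: $S_{obs} + Q_1\,(m-1)/m$.

`faith_pd` sums the branch lengths of the minimal subtree spanning a tip
set. Conventions are pinned because SES comparisons are sensitive to
them: the edge above the set's MRCA is excluded and a single tip has
PD 0. `mpd` and `mntd` average patristic distances over unordered pairs
and nearest neighbours respectively. `ses` compares an observed metric
against `null_reps` uniform draws of equal-sized tip sets (unweighted
tip-label shuffling); a zero-variance null (e.g. the full tip set) yields
a flagged `NA`, never a silent 0.

## Community structure

`jaccard_matrix` computes $d(i,j) = 1 - |A_i \cap A_j|/|A_i \cup A_j|$
on per-site unit sets; a pair of empty sites gets distance 0 by
convention and is flagged. `permanova` partitions the Gower-centered
matrix of squared distances by sequential (Type-I) sums of squares in the
order terms are listed — term order matters and is the caller's choice —
with pseudo-F per term and $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$
under row-label permutation, so $p$ is never 0. A permutation matrix can
be supplied for exhaustive enumeration, and a `strata` factor restricts
permutations within groups. The implementation is validated against an
independent first-principles oracle and against `vegan::adonis2` (exact
agreement of F, $R^2$ and, given identical permutations, $p$).

`compare_methods` replaces mixed-model richness regression with a fully
specified permutation analog: per site and per phylum stratum it tests
each pairwise method contrast by independent per-site swaps of the two
method labels (sign flips of the per-site richness difference), with Holm
correction across all contrasts, and runs per-method Jaccard + PERMANOVA
when covariates are supplied. Swapping two method labels negates their
contrast exactly.

## The synthetic generator

`simulate_metacommunity` chains four stages, each bit-reproducible given
its seed:

1. **Species tree** — Yule pure-birth: while $k$ lineages exist the next
   speciation waits $\mathrm{Exp}(\lambda k)$, observed from the root
   split to the interval after the $n$-th lineage, so the expected root
   age is $\sum_{k=2}^{n} 1/(\lambda k)$ (used as an analytic test
   oracle).
2. **Within-species clusters** — Kingman coalescent per species with
   scale $\theta$ (rate $\binom{j}{2}/\theta$ while $j$ lineages),
   rejection-sampled so the subtree height stays inside the terminal
   branch; a species tree that cannot host the coalescent after bounded
   retries raises an error rather than silently distorting the model.
3. **Sequences** — Jukes–Cantor evolution along the tree with
   region-specific rates over primer-flanked variable regions; primers
   evolve at rate 0, and the emitted amplicon is
   forward-primer + region + reverse-complemented reverse primer, the
   form the region takes on the forward strand of a real amplicon. The
   JC identity expectation $1/4 + 3/4\,e^{-4rd/3}$ is the test oracle.
4. **Survey** — Bernoulli occupancy per species × site (every species
   kept in ≥ 1 site), observed through a phylum × method detection
   matrix; a detected occurrence yields a zero-truncated Poisson read
   count (so perfect detection with zero errors reproduces the true
   incidence exactly) with i.i.d. substitution errors per base.

Defaults mirror the study design the package addresses: 19 sites, 7
phyla (Annelida, Gastrotricha, Mollusca, Nematoda, Nemertea,
Platyhelminthes, Xenacoelomorpha), the published 18S primer pairs
(EukF/SR7 for V1–V2; Illumina_Euk_1391f/EukBr for V9), and a V9
substitution rate three times the V1–V2 rate, reflecting the faster
divergence of V9. Where no quantitative value exists we chose once:
35 species (5 per phylum), 3 sequenced individuals per species,
occupancy 0.35 (≈ 6–7 occupied sites per species), mean read depth 20,
read error rate 0.002/base, baseline detection 0.95 with metabarcoding
detection 0.3 for Gastrotricha and Nemertea — the deficit directions are
meaningful, the magnitudes are illustrative, since no study measures
per-phylum detection probabilities directly.

What the generator does *not* emulate: PCR amplification bias and primer
mismatch (detection is a single per-phylum probability), rRNA copy-number
variation, chimeras and indels (errors are i.i.d. substitutions), spatial
autocorrelation between sites, and real 18S secondary-structure rate
heterogeneity (Jukes–Cantor only, chosen for its closed-form oracle).
Passing tests therefore show the pipeline's internal correctness and its
qualitative behaviour under controlled bias, not calibration to any real
survey.

## Problem sizes used in the checks

The automated checks run at desk scale, chosen once: estimator oracles
enumerate all incidence matrices up to 4 units × 3 sites; phylogenetic
metrics are compared with a path-enumeration oracle on 200 random trees
of ≤ 8 tips; GMYC recovery uses 50 replicates of 5 species × 4 tips at
$\theta = 0.01$ × tree height; PERMANOVA calibration uses 1000 null data
sets of 8 sites × 15 units at 199 permutations (rejection at
$\alpha = 0.05$ must fall inside the exact binomial 99% interval); the
bias emulation uses 50 replicate surveys of 28 species over 7 phyla at
12 sites, mean depth 6, 399 permutations — a size at which the designed
Gastrotricha deficit (detection 0.3 vs 0.95) is comfortably detectable;
the region comparison uses 21 species over 7 phyla.

## Numerical choices

* Ultrametricity is judged relative to tree height (default tolerance
  $10^{-6} \times$ height): simulated trees are exact, time-calibrated
  trees from Bayesian samplers carry rounding.
* GMYC rate optimization uses Nelder–Mead on log-rates from three warm
  starts (event-count/exposure ratios and a Yule-only corner); the
  all-Yule threshold is evaluated in closed form, which also fixes the
  null exactly.
* Permutation p-values always include the observed statistic in
  numerator and denominator.
* Greedy clustering and denoising orders are fully deterministic
  (abundance, then lexicographic tie-breaks).
* 0-based half-open coordinates for primer/region intervals.

## A worked run

```{r example, eval = FALSE}
mc <- simulate_metacommunity(seed = 1)
units <- survey_unit_sets(mc$survey)
cmp <- compare_methods(units, covariates = mc$covariates,
                       n_perm = 199, seed = 1)
print(cmp)

fit <- gmyc_single_threshold(
  graft_coalescent_tips(simulate_yule_tree(5, 1, seed = 2), 4,
                        0.01 * attr(simulate_yule_tree(5, 1, seed = 2),
                                    "height"), seed = 3))
summary(fit)
```

## Known limitations

* The denoiser is an abundance-ratio rule, not an error-model learner;
  at very high error rates it under-merges and drops true low-abundance
  variants.
* Single-threshold GMYC under-splits when speciation and coalescent time
  scales overlap (see above); no multiple-threshold variant is provided.
* PERMANOVA uses sequential sums of squares only; marginal (Type-III)
  tests are out of scope.
* The classifier assumes three lineage ranks (phylum; family; species);
  deeper lineages are truncated on read.
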