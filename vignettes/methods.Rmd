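---
title: "Tracing island invasion routes from microsatellite genotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing island invasion routes from microsatellite genotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

guavapop implements the population-genetic machinery needed to reconstruct
the origin and island-to-island spread of an invasive plant from a panel of
co-dominant SSR (microsatellite) markers: diversity statistics that are
aware of null alleles, between-population distances and trees, a coalescent
simulator for colonization scenarios under stepwise mutation, and an
approximate Bayesian computation (ABC) engine for choosing among scenarios
and estimating their parameters.  This vignette records the models, the
numerical choices, and the design decisions behind each component, in the
package's own words.

## The data model

Genotypes live in a long tibble (`genotype_tbl`): one row per individual x
locus, two integer allele sizes per call on the locus's repeat scale, both
`NA` for a missing genotype.  A homozygote repeats the same size; a
half-recorded call is rejected at construction.  Population labels partition
individuals; mainland samples may additionally carry a region label obtained
by binning a precomputed distance from the northern end of the sampled
transect into three 240-km latitudinal bands crossed with three
physiographic axis labels (nine regions).  Bands are half-open, `[a, b)`:
a sample falling exactly on a 240-km boundary belongs to the southern band.
The choice is ours; the sampling design we emulate does not state how
boundary samples were assigned, and any fixed convention serves, as long as
it is deterministic.

Allele identity is the integer size itself.  We deliberately do not bin
sizes +/-1 into common alleles: the stepwise mutation model operates on an
integer repeat ladder and the simulator reports exact repeat counts.

## Null alleles

A null allele fails to amplify, so a visible/null heterozygote is scored as
a visible homozygote and a null/null genotype is scored as missing.  The
per-locus, per-population null frequency `beta` is estimated by
expectation-maximisation over the latent genotype classes under
Hardy-Weinberg proportions: apparent homozygote counts for allele *i* mix
true *i/i* with *i*/null, and (by default) blank genotypes mix null/null
with a co-estimated locus-wide technical failure rate.  A no-blank variant
(`include_blanks = FALSE`) instead truncates the likelihood on visibility
and imputes the hidden blank class during counting; both variants are gene
counting EMs whose observed-data log-likelihood is non-decreasing at every
iteration (asserted in the test suite).  Defaults: tolerance 1e-6 on the
largest frequency change, at most 1000 iterations, initialisation at the
raw visible frequencies scaled to `1 - beta0` with `beta0 = 0.1`.

Three corrected statistics are built on the estimates:

* **Corrected expected heterozygosity.**  We compute Nei's unbiased gene
  diversity from the EM frequencies with the null included as one extra
  allele class: `He = n/(n-1) * (1 - sum(p_vis^2) - beta^2)`.  The
  inclusion of the null class is deliberate.  Under the null-allele model
  the *raw* frequency estimates of the visible alleles already converge to
  the renormalised visible frequencies, so renormalising after removing
  `beta` would reproduce the uncorrected value and the correction would be
  vacuous; counting the null as an allele restores the heterozygosity that
  masking hides, which is why corrected He exceeds uncorrected He exactly
  when `beta > 0` (a property the tests assert on masked fixtures).  With
  `beta = 0` the statistic reduces to the uncorrected one.
* **ENA-corrected FST.**  Weir & Cockerham's theta with, per locus, the
  corrected visible allele frequencies in place of the raw ones, the null
  class excluded from the allele sums, and heterozygote frequencies taken
  at their Hardy-Weinberg expectations under the corrected frequencies
  (the uncorrected estimator uses the observed heterozygote counts).
  Loci are combined by the ratio of summed variance components, not by
  averaging per-locus ratios.  On data masked with a known null overlay,
  the corrected estimator is closer to the truth than the naive one in the
  large majority of replicates (asserted at >= 80%).
* **Chord distance with the INA correction.**  We pin one specific variant
  of the Cavalli-Sforza & Edwards distance, because the literature scales
  it several ways: per locus `(2/pi) * sqrt(2 * (1 - sum_a sqrt(x_a y_a)))`,
  averaged over shared loci.  The INA correction appends the two
  populations' null frequencies as one extra shared allele class before the
  square-root sum.

## Diversity statistics

Expected heterozygosity is Nei's unbiased gene diversity with the
`n/(n-1)` factor (`n` = gene copies); per-population values are means over
loci with data.  The multi-locus inbreeding coefficient is the ratio of
means, `Fis = 1 - mean(Ho)/mean(He)`, not the mean of per-locus ratios —
the two differ, the source tables we emulate are reproduced by the
ratio-of-means convention, and it is the stabler of the two under loci with
small He.  Allelic richness is rarefied exactly (hypergeometric, no Monte
Carlo) to a standard gene count — 160 genes for island-scale comparisons,
16 for region-scale ones; cells with fewer copies are excluded from the
mean rather than extrapolated.  Private alleles are counted over a stated
universe of populations, with a rarefied variant that applies the same
subsampling probability to the private-allele indicator; that variant is
approximate in that privacy is assessed on the full sample, and it is
documented as such.

Hardy-Weinberg tests use the chi-square statistic with a Monte-Carlo null
built by re-pairing shuffled gene copies (conditional on allele counts),
which scales to many alleles where the exact test's enumeration does not;
the test suite checks the Monte-Carlo p against an exact Levene enumeration
on a small two-allele table.  Linkage disequilibrium uses a genotypic
contingency chi-square with one locus's genotypes permuted across
individuals.  Multiple testing is controlled with the Benjamini-Yekutieli
step-up adjustment (valid under arbitrary dependence); note BY is not
idempotent — re-adjusting adjusted values inflates them further.  The He
permutation test permutes individuals between the two populations being
compared (the alternative, permuting loci, answers a different question
about locus exchangeability; individual permutation matches the
population-difference null we want).  Paired per-locus He vectors are
compared with the Wilcoxon signed-rank test or Mood's median test, both
delegated to standard routines.

The Evanno delta-K statistic post-processes a table of clustering
log-likelihoods: `deltaK = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))`,
undefined at the endpoints and wherever the replicate SD is zero.  The
clustering itself (admixture-model MCMC) is out of scope; only the model
selection statistic is provided.

## Distances, ordination, and hierarchical variance

Nei's (1972) standard distance sums the J identities over loci before
normalising.  Neighbor joining is delegated to `ape::nj`; negative branch
lengths, which NJ can produce on noisy matrices, are clamped to zero with
the negative length carried onto the adjacent descendant edges so that
tip-to-tip path lengths are conserved.  Node support comes from resampling
the loci (the 11 columns), not individuals, with replacement: each
bootstrap dataset rebuilds the distance matrix and tree, and support is the
percentage of replicates containing each bipartition of the reference tree.

PCoA is classical metric scaling on the double-centred `-D^2/2` matrix;
negative eigenvalues (non-Euclidean input) are reported, never silently
dropped, and explained proportions are relative to the positive spectrum.
The individual-level distance feeding it encodes each individual as its
within-individual allele frequency vector (0/0.5/1 per allele), with
missing loci mean-imputed within the individual's population; this keeps
the ordination defined under missingness at the cost of shrinking missing
individuals toward their population centroid.

AMOVA decomposes allele-level variance at three levels (among populations,
among individuals within populations, within individuals) from
sums of squares under the mismatch distance, computed per locus and summed,
with missing genotypes ignored locus-wise.  Components are obtained from
the expected mean squares with the usual unequal-sample-size coefficient;
significance is assessed by permuting individuals among populations (top
level) and allele copies among individuals within populations (middle
level).  A brute-force pair-loop oracle on a small toy pins the
implementation to 1e-10.

The Mantel test correlates two distance matrices by Spearman rank over
off-diagonal pairs, permuting one matrix's labels jointly (10,000
permutations by default), one-sided for positive association — the
direction of the isolation-by-distance hypothesis.  Geographic distances
are haversine great circles (Earth radius 6371 km) between group centroid
coordinates.

## The coalescent simulator

Histories are event lists in backward time over named populations: `merge`
(a daughter's lineages move to its source), `admix` (each lineage chooses
between two parents with probability `r`), and `resize`.  Within a
population of effective size `N`, `k` lineages coalesce at rate
`k(k-1)/2 / (2N)` per generation — the continuous-time approximation to the
Wright-Fisher model, standard and accurate when `N` is much larger than the
sample.  Times are generations throughout; scenario files carry absolute
`N` and `mu`, so compound quantities such as `2 N mu` are derived, never
primary.  A founder-flush colonization is encoded as a resize to the
founder size spanning the first fraction `d` of the time since
introduction, then the present size.

Mutations follow the strict stepwise model: Poisson(`mu` x branch length)
events per branch, each changing the repeat count by +/-1 with equal
probability, sizes never clipped.  We chose the single-step SMM over a
geometric multi-step variant to match the mutation model under which the
scenario comparisons we emulate were run; the cost is a known tendency to
underestimate divergence times when real loci take multi-repeat jumps.
The generative core is compiled (Rcpp), as is usual for coalescent
simulators, because the ABC layer calls it hundreds of thousands of times.
Closed-form checks pin it: pairwise coalescence times are Exp(mean `2N`),
tree height approaches `4N(1 - 1/n)`, between-population squared
mean-size difference grows as `2 mu t`, and equilibrium gene diversity
approaches `1 - 1/sqrt(1 + 8 N mu)`.

All randomness flows through R's RNG, so a single `set.seed()` makes any
simulation, test, or pipeline run exactly reproducible.

## ABC: scenario choice and parameter estimation

Summary statistics are declared by a `stat_design`: per population the mean
allele count, mean unbiased gene diversity and mean allele-size variance;
per pair the pooled versions of those three plus FST, the shared-allele
distance DAS, and Goldstein's `(delta mu)^2` (read as the squared
difference of mean allele sizes, averaged over loci); per designated trio a
least-squares admixture coefficient over pooled allele frequencies, clamped
to `[0, 1]`.  The origin analyses use the full per-population/per-pair grid
(57 statistics for six populations); the colonization analyses use the
allele-number/size-variance/FST/`(delta mu)^2` subset (26 statistics for
four populations).  The exact statistic sets of the study being emulated
are only partially enumerable from its text, so the design lists are
configurable and default to every statistic it names.

Rejection sampling draws a scenario uniformly, draws parameters from the
shared prior honouring structural constraints (ordering of introduction
times; per-scenario constraints are enforced by redrawing that scenario's
rows), simulates, and retains the closest 1% by Euclidean distance on
statistics standardised by the simulated pool's SD (zero-variance
statistics are dropped with a warning; SD rather than MAD because the pool
is large and the statistics are well-behaved).  Posterior probabilities per
scenario come from a multinomial logistic regression of the scenario label
on the retained, observed-centred statistics, reduced first to linear
discriminant axes — the observed point sits at the origin, so the fitted
intercepts carry its probabilities; the reduction is what keeps the
regression identified where a couple of hundred retained draws meet dozens
of statistics.  Confidence intervals map the coefficient covariance through
the softmax by Monte Carlo.  Under complete separation or a failed fit the
estimator falls back, flagged, to retained-set proportions with binomial
intervals.

Parameter posteriors use the standard local-linear adjustment on the best
scenario's retained draws: each parameter is regressed on the standardised
statistics and residual-shifted to the observed point, on a log scale for
times and sizes and a logit scale for proportions (chosen for regression
stability and range preservation), then back-transformed; draws violating
the scenario's time-ordering constraints are discarded.  Model checking
simulates from the posterior predictive and reports, per statistic, the
fraction of predictive values below the observed — a statistic fits when
that fraction is inside `[0.05, 0.95]` — plus a PCA of the predictive
statistics with the observed point projected and its squared Mahalanobis
distance in the retained component space.

Desk-scale defaults run 20,000 simulations per analysis.  The study-scale
analyses this package emulates used 0.9-1.6 million; the budget is
configurable upward, and every accuracy statement in the tests is made at
the desk scale.  One consequence of the smaller budget: a 1% retention cut
(the function default, matching full-scale practice) leaves only 200 draws
for a nine-class regression, so the shipped recovery experiments retain 5%
— about a thousand draws, closer to the absolute retained-sample sizes the
regression was designed around — and let the Epanechnikov distance weights
keep the estimate local to the observed point.

## The scenario library

Four shipped sets cover the emulated analyses: 15 origin scenarios per
island lineage (5 single mainland sources, 10 pairwise admixtures over a
star of five mainland lineages), 16 first-stage colonization scenarios over
{Mainland, San Cristobal, Isabela+Floreana, Santa Cruz}, 9 second-stage
scenarios separating Floreana and Isabela, and the final serial model
Mainland -> San Cristobal (t4) -> Floreana (t3) -> Isabela (t2) with the
late San Cristobal -> Santa Cruz branch (t1), `t4 > t3 > t2 > t1`, founder
bottlenecks at every introduction.  The staged sets' full topology lists
are not enumerable from the text we emulate, so beyond the named members
(the serial chain, the Santa Cruz admixture variant, the parallel and
Floreana-first second-stage variants) the sets are completed systematically
under the stated constraints — Santa Cruz is never ancestral to San
Cristobal or Isabela/Floreana — and each scenario carries a provenance note
saying whether it is named or reconstructed.  Sets round-trip losslessly
through a YAML schema for archiving and editing.

## The synthetic-data generator

`generate_study_like()` produces datasets with the study's shape — 376
diploids at 11 loci in five populations (96, 95, 80, 94, 11), the mainland
subdivided into nine regions — with full ground truth.  Its defaults are
the conditions the emulated study reports where stated, and one-time
choices where not:

* **Mainland structure.**  The simulator's event grammar has no migration,
  so a literal stepping-stone is out of reach; the monotone
  divergence-with-distance signature is instead produced by an admixture
  cline: two ancestral pools (N = 8000, diverged 4000 generations) mix
  into nine regional demes (N = 1500, formed 40 generations ago) with
  ancestry proportions set by each deme's position along the northwest -
  southeast diagonal of the sampled transect.  This reproduces the
  isolation-by-distance Mantel signal and leaves mainland gene diversity
  near 0.8, at the cost of not modelling ongoing gene flow; passing tests
  therefore show distance-decay detection, not stepping-stone inference.
* **Colonization.**  The final serial model with point times
  (34, 119, 211, 1710) generations, founder sizes 25/6/15/10 and island
  sizes 800 (SCY), 100 (FLO), 1000 (ISA), 2000 (SCZ) — island diversities
  then fall in the low-to-moderate range the study reports, below the
  mainland in essentially every draw, with island-island differentiation
  well above region-region differentiation.
* **Null alleles and missingness.**  Per-locus null frequencies drawn
  uniformly on `[0, 0.33]` (the study's reported range) and applied by
  masking: one null copy makes an apparent homozygote, two make a blank;
  2% of genotypes are then blanked at random as technical missingness.

What the generator does *not* emulate: per-locus allele-size distributions
of the real markers, mutation-rate heterogeneity across loci, selection,
and ongoing migration.  Recovery results on synthetic data bound what the
methods can do under the model's own assumptions, not under every
real-data pathology.

`generate_null_allele_benchmark()` is the EM validation harness:
single-population HWE datasets with known `beta`, used for the recovery
curve (bias within +/-0.05 at n = 500) and the consistency-in-n property.

## Problem sizes and determinism

The shipped tests and the acceptance script run everything at desk scale:
20,000 ABC simulations per analysis (20 scenario-recovery replicates),
thousands of coalescent replicates for the closed-form checks, and twenty
generator seeds for the fixture-pattern rates.  These sizes are the
package's own defaults, chosen so a full run completes on one CPU in
minutes while leaving the Monte-Carlo error comfortably inside every
stated tolerance; all of them are arguments, and scale up unchanged.
Every stochastic routine takes its randomness from R's global RNG so that
one seed fixes the entire analysis graph.

## Known limitations

* No migration events in the demographic grammar (splits, admixtures and
  size changes only), hence no true stepping-stone or continuous gene flow.
* No genotyping-error models beyond null alleles: stutter and large-allele
  dropout are not simulated or corrected.
* The rarefied private-allele count is approximate (privacy assessed on
  the full sample).
* ABC accuracy statements hold at the desk-scale simulation budget;
  separating closely related scenario topologies reliably needs the
  study-scale budgets.
* The logistic posterior-probability intervals are asymptotic; with very
  few retained draws the flagged proportion fallback is used instead.
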