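---
title: "Admixture-aware analysis of gene-diversity clines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture-aware analysis of gene-diversity clines: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

A decline of within-population genetic diversity with distance along a
colonisation route is the classic signature of a serial founder effect:
each new deme is founded by a subset of its predecessor, and every founding
sheds heterozygosity. But the same geographic pattern arises if recent
admixture from diverged source populations is itself geographically
patterned — admixture injects diversity, so regions with more of it look
more diverse regardless of their founding history. For Native American
microsatellite data the two explanations collide directly: European and
African admixture is strongest in the north (Canada) and in the Andes,
while the least admixed populations (Amazonia, Paraguay) are also the most
distant from Beringia and the least diverse.

`admixcline` implements the analysis that separates the hypotheses —
estimate individual ancestry, collapse it to a single non-native covariate,
and compare the raw correlation of gene diversity with distance against the
partial correlation controlling that covariate — together with a simulator
that generates data under each hypothesis in isolation, so every step of
the analysis can be validated against known truth.

## The admixture model and its estimator

For `K` clusters, individual `i`, locus `l` and observed gene copy carrying
allele `a`, the likelihood is the standard unsupervised admixture model

$$\log L(Q, P) = \sum_{i,l,c} \log \sum_{k=1}^{K} q_{ik}\, p_{k l a_{ilc}},$$

with `Q` row-stochastic over clusters and each `(k, l)` block of `P`
row-stochastic over alleles. We maximise by EM: responsibilities are exact
posteriors of the cluster label of each gene copy, and both M-step updates
are closed-form. The log-likelihood is non-decreasing at every iteration,
which the test suite asserts on every fitted trace.

Choices that matter:

* **ML instead of Bayesian MCMC.** The Dirichlet admixture prior of the
  original clustering programs mainly regularises small samples; the
  analyses here operate at the level of population means of `Q`, where the
  prior's influence is negligible. EM makes replicate runs cheap enough to
  compute ΔK from honest replicate variation. The admixture hyperparameter
  is deliberately not part of the model.
* **Initialisation.** `Q` from symmetric Dirichlet jitter, `P` from pooled
  allele frequencies with ±30% multiplicative jitter. `n_starts` (default
  5) independent starts per run, best final log-likelihood kept.
* **Convergence.** Relative log-likelihood change below `tol = 1e-6` or
  `max_iter = 2000`.
* **Frequency floor.** Cluster allele frequencies are floored at `1e-9`
  and renormalised, so a private allele never produces `log(0)`.
* **Missing data.** A missing gene copy simply contributes nothing to the
  likelihood; a heterozygote with one unreadable allele still contributes
  its observed copy.

Replicate runs are label-aligned greedily by the dot products of `Q`
columns; the greedy match is verified against the exhaustive permutation
oracle for small `K` in the tests. ΔK follows Evanno:
`|L''(K)|` of the across-run mean log-likelihood divided by the across-run
standard deviation; endpoints and zero-variance K are reported `NA` rather
than infinite. Clusters are annotated to continental sources when a source
group's mean membership exceeds 0.5 (ties broken by sample size), and
"non-native ancestry" is the summed membership of all source-annotated
clusters.

## Diversity, distances, geography

Gene diversity uses Nei's unbiased estimator per locus,
$\hat H = \frac{m}{m-1}(1 - \sum_a \hat p_a^2)$ with `m` observed gene
copies, averaged over loci with `m >= 2` (configurable). The unbiased
correction is kept because compiled data sets routinely contain populations
with a handful of sampled individuals. Loci are included pairwise for the
distance measures (defined in both populations), which maximises
information over complete-case filtering. We average over all defined loci;
no locus filtering is applied beyond the copy minimum.

Nei's minimum distance and `(δμ)²` share the same frequency machinery.
`(δμ)²` interprets allele labels as additive sizes (repeat counts or base
pairs) as the stepwise mutation model requires; it is therefore *not*
invariant to allele relabelling, while `Ĥ` and Nei's distance are — both
facts are asserted in tests.

Geographic distances are haversine great circles on a sphere of radius
6371.0088 km; the sub-half-percent sphericity error is immaterial to
correlations. Waypoint routes (north-coast Canada, Pacific coast, Amazon
river, a Mesoamerican detour for the Pima, an Atlantic path for the Ache)
live in an editable YAML library because the original best-fit waypoints
are not published; populations without a route fall back to the direct
great circle. The origin defaults to a Beringia analog at 66°N 167°W and is
explicitly an assumption, not an estimate.

## The gradient analysis

`gradient_analysis()` produces the raw Pearson correlation (two-sided p
from the t transform), the first-order partial correlation controlling the
single combined non-native covariate (p on `n − 3` df), residual pairs for
plotting, and drop-one jackknife tables at population and region level with
signed influence `Δr = r(without unit) − r(baseline)`. Two-sided p-values
are reported throughout. No multiple-testing correction is applied across
jackknife rows; the table is descriptive. The partial correlation equals
the correlation of the residuals from regressing each variable on the
covariate — an identity the tests verify to `1e-10` on a thousand random
triples, and the route by which the residual scatter plot is an honest
picture of the statistic. A nonparametric bootstrap over populations
provides interval statements about the partial correlation where a point
estimate would be over-read.

## The simulator: what it emulates, and what it does not

`simulate_genotypes()` is a forward Wright–Fisher simulation on allele-size
space with unlinked loci and random mating, so each gene copy at each locus
picks a uniform parent copy independently. Components:

* **Root at mutation–drift equilibrium**, reached by burn-in from a
  monomorphic start; burn-in stops when mean heterozygosity changes by
  less than 1% over 100 generations, capped at `10 × 2N` generations.
* **Stepwise mutation** at rate μ per copy per generation, ±1 with equal
  probability, the downward step at size 1 reflected upward.
* **Continental outgroups** that evolve independently from the root state
  for a configured number of generations (branch length, not calendar
  split: divergence longer than the chain is handled by pre-evolving the
  branch).
* **A serial founder chain** in which each founding is `founder_duration`
  generations at `founder_size` diploids before expansion to `deme_size`.
  The sustained phase is essential: a one-generation bottleneck removes
  only `1/(2N_f)` of heterozygosity, which mutation–drift balance erases
  almost immediately.
* **One admixture pulse**, replacing each gene copy of deme `d`
  independently with a draw from source `s` with probability `α_{ds}`
  (constant, linear, exponential-decay, or manual per-deme profiles).
  Ancestry labels attach to gene copies at the pulse and are transmitted
  with them, so realized per-individual ancestry is known exactly.
* **Language labels** on contiguous deme blocks, reassigned at random with
  a configurable decoupling probability — genes and languages moving
  independently.

The drift expectation used as the simulator's oracle composes the founding
phase with the post-expansion decay,
`H_t = H0 (1 − 1/(2N_f)) (1 − 1/(2N))^{t−1}` per founding generation, and
is exact at μ = 0; a 200-replicate Monte-Carlo comparison at `H0 = 0.8`,
`N = 50`, `t = 20` sits within three standard errors in the tests.

What the simulator does **not** model: linkage and LD, selection,
continuous migration between demes, overlapping generations, genotyping
error, and ascertainment. Passing tests therefore demonstrate that the
statistics behave correctly when their own assumptions hold — not that any
particular real data set satisfies those assumptions.

## Scenario presets: the study conditions

The presets fix the generative conditions for validation and are not tuned
per analysis. Sizes were chosen for desk-scale runs (demes of 100 diploids,
100–200 loci, 15–50 sampled individuals per deme); μ = 10⁻³ per copy per
generation is a standard microsatellite rate, and 4Nμ = 0.4 keeps
equilibrium heterozygosity near 0.25 so bottleneck and admixture effects
are visible against it.

* `scenario_true_k3()` — three demes drifted apart for 250-generation
  intervals, no admixture: ΔK should recover K = 3.
* `scenario_alpha_grid()` — per-deme European-analog admixture fractions
  0–0.5 on a chain with 8-generation founding intervals. The short chain
  is deliberate: the K = 2 admixture model has no term for native
  inter-deme drift, and long chains push that unmodelled structure into
  the source component, inflating estimates by roughly 20% relative. With
  a shared native background, deme-level recovery error (MAE) is
  comfortably below 0.05.
* `scenario_admixture_only()` — no bottlenecks; admixture decays
  exponentially with distance (α₀ = 0.35, λ = 3×10⁻⁴ per km over
  13,500 km). All demes share one drift history, so any diversity cline is
  admixture's shadow.
* `scenario_founder_only()` — sustained 12-founder bottlenecks at every
  founding, plus a small constant 5% admixture fraction that carries no
  geographic information (a constant covariate would make the partial
  correlation degenerate; an uninformative one is the honest control).
* `scenario_planted_region()` — nine demes in three regions; only deme 7
  passes through a severe founding bottleneck (4 founders), and demes 8–9
  inherit its loss. The far region is thereby planted as the sole driver
  of the global cline, which the regional jackknife should single out.

## Numerical and design choices

* Ordination scales allele-dosage columns to unit variance after mean
  imputation of missing entries (both configurable); zero-variance columns
  are dropped with a count. Axes are sign-fixed so the largest-magnitude
  loading (PCA) or score (MDS) is positive. The PCA entity is the
  individual, summarised per population for reporting.
* Classical (metric) scaling was chosen for the MDS step; the negative
  eigenvalue mass is reported as a Euclideanness diagnostic.
* The gene–language summary quantifies what is otherwise read off plots:
  the between-minus-within family distance contrast with a label
  permutation p-value `(1 + #{perm ≥ obs})/(n_perm + 1)`, and the
  nearest-neighbour same-family rate computed over populations that have at
  least one same-family partner (singleton families cannot score a hit by
  construction and would only dilute the rate).
* The packaged 29-population metadata table is a reconstruction from the
  published region census and standard language-classification references
  (ASCII-normalised names, alias table for diacritic variants); its
  coordinates are approximate published locations. It is versioned with
  the package so that the family census — 16 families, mean 1.8125
  populations per family, exactly two families larger than two — is
  auditable.
* Pipeline runs derive every stage seed from one master seed and write a
  manifest with md5 checksums, so a rerun is verifiably identical.

## Known limitations

* The ML estimator reports no uncertainty on `Q`; population means across
  replicate aligned runs are the intended unit of interpretation.
* ΔK is undefined at the endpoints of the K range and degenerates when
  across-run variance is zero; it guides, rather than decides, the choice
  of K — the K-sensitivity curves (`k_sensitivity()`) are the primary
  diagnostic for ancestry conclusions.
* Route distances are waypoint polylines, not least-cost paths over
  landmasses; they encode qualitative hypotheses.
* With ~10 populations the bootstrap interval of a partial correlation is
  wide; that width is the message, not a defect, in the admixture-only
  contrast.
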