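# admixcline

Did genetic diversity in the Americas decline southward because of a serial
founder effect during the initial peopling, or because post-contact
admixture is itself geographically patterned? `admixcline` packages the
statistical machinery needed to ask that question of diploid microsatellite
data — and, because the two hypotheses are observationally entangled in any
single real data set, a forward simulator that generates data under each
hypothesis separately so the machinery can be validated against known truth.

The package is aimed at population geneticists working with
STRUCTURE-format multi-allelic genotypes, population coordinates, and
language-family metadata.

## What it computes

**Ancestry.** Unsupervised admixture proportions by maximum likelihood: for
individual *i*, cluster *k*, locus *l* and allele *a*,

    log L = Σ_copies log Σ_k q_ik · p_kla

maximised by EM over the ancestry matrix *Q* and cluster allele frequencies
*P* (both row-stochastic; the log-likelihood is non-decreasing at every
iteration). Replicate runs are label-aligned by greedy column matching, and
the number of clusters is probed with Evanno's statistic

    ΔK = |mean L(K+1) − 2 mean L(K) + mean L(K−1)| / sd L(K).

**Diversity and distance.** Per-population gene diversity (Nei's unbiased
estimator, `Ĥ = m/(m−1)·(1 − Σ p̂²)` averaged over loci), Nei's minimum
distance `D = (J_X + J_Y)/2 − J_XY`, and Goldstein's `(δμ)² = (μ_X − μ_Y)²`
on frequency-weighted mean allele sizes.

**Geography.** Haversine great-circle distances on a spherical Earth
(R = 6371.0088 km), optionally constrained through waypoint routes (coastal,
riverine) read from a YAML library, accumulated from an origin such as
Beringia.

**The core inference.** Pearson correlation of gene diversity against
distance from the origin; the first-order partial correlation controlling
combined non-native ancestry,

    r_xy·z = (r_xy − r_xz·r_yz) / √((1 − r_xz²)(1 − r_yz²));

and drop-one jackknife tables at population and region level that attribute
the correlation to its drivers.

**Ordination and language.** PCA of scaled individual allele dosages,
classical (Torgerson) MDS of genetic distances, axis–covariate
correlations, and a permutation test of gene–language correspondence
(within- vs between-family distances, nearest-neighbour same-family rate).

**Simulation.** A forward Wright–Fisher simulator on allele-size space:
burn-in to mutation–drift equilibrium, continental outgroup analogs,
a serial chain of demes founded through sustained bottlenecks, symmetric
single-step (stepwise) mutation, a geographically patterned admixture pulse
with per-gene-copy ancestry tracking, and language labels assigned in
blocks then randomly decoupled. Every run returns a truth record
(realized admixture fractions, per-individual ancestry, expected and
realized heterozygosity) for parameter-recovery tests.

## A worked example

Simulate a pure admixture cline (no founder effect), then ask whether the
raw diversity–distance correlation survives controlling for admixture:

```r
library(admixcline)

sim <- simulate_genotypes(scenario_admixture_only(11))
inp <- sim_gradient_inputs(sim)
gradient_analysis(inp$diversity, inp$geotable, inp$covariate)
```

```
gradient_result: n = 10 populations
  r = -0.888 (p = 0.000597)
  r_partial = -0.193 (p = 0.619), controlling non-native ancestry
```

The raw correlation is strongly negative — gene diversity falls with
distance from the origin — yet the partial correlation controlling each
deme's true non-native ancestry collapses toward zero: in this scenario the
"cline" is entirely a shadow of geographically patterned admixture. Running
the same analysis on `scenario_founder_only()` data instead leaves the two
coefficients in agreement (both ≈ −0.85), which is the signature of a real
serial founder effect.

The packaged 29-population metadata reconstruction is available as
`american_populations()`; its language-family census
(`language_family_counts()`) has 16 families, a mean of 1.8125 populations
per family, and exactly two families (Chibchan, Tupi-Guarani) with more
than two representatives.

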