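---
title: "Methods: quantifying symbiont strain sharing in host-enemy-plant networks"
author: "symnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying symbiont strain sharing in host-enemy-plant networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(symnet)
```

# The question and the data

Defensive bacterial symbionts such as *Hamiltonella defensa* protect their
insect hosts against parasitoid wasps, and field surveys repeatedly find
each host species carrying only one or a few symbiont strains. Two
ecological routes could generate non-random strain distributions across a
host community: shared natural enemies (parasitoids select for — and can
physically transmit — protective strains) and shared food plants (plant
tissue can act as a transmission route). Disentangling them requires
community-level statistics, because host species are also phylogenetically
related, and related hosts carry related symbionts.

`symnet` works from a long-format observation table: one record per
sampled individual with its host (aphid) species, plant, parasitoid, and
symbiont strain. Two partner fields distinguish *screened-but-negative*
(the `"No Association"` sentinel) from *not screened* (`NA`); only the
former is evidence of absence, and both are removed when building the
matrix for the corresponding analysis.

# Filtering rules

`filter_observations()` applies two removals:

1. **Sentinel removal** — records without the partner of the downstream
   analysis (`"No Association"` or unscreened).
2. **Transient associations** — a record whose (host, plant) pair occurs
   exactly once in the whole table, unless that plant is declared a
   recognised host in the optional `host_list`. A single individual on an
   unusual plant is most plausibly a vagrant, not an ecological
   association. There is no canonical numeric rule for "transient"; the
   singleton rule is this package's operationalisation, and the
   recognised-host list is the escape hatch for known-but-rare hosts.

The sentinel rule runs first, deliberately: the singleton scan then sees
exactly the records that the analysis will use, and the filter is
idempotent (running it twice changes nothing), which makes pipelines
re-entrant. Every removal is logged on the returned object.

# Community matrices and similarity

`build_community_matrix()` tallies records into focal-species ×
partner-taxon counts. Rows and columns are sorted in byte order
(locale-independent), so every downstream artifact is byte-stable across
machines — important when result files are hashed and diffed.

Similarity between two species' partner profiles is `1 − BC` with
`BC(x, y) = Σ|xᵢ − yᵢ| / Σ(xᵢ + yᵢ)` (Bray–Curtis, computed through
`vegan`), so 1 means identical partner use and 0 means none shared. By
default the counts enter raw, matching the long-standing default of the
community-ecology tooling; `normalize = TRUE` first converts each row to
relative abundances, which is advisable when sampling effort differs
strongly between species and only compositional differences are of
interest.

# Host relatedness

Relatedness between host species is the site-count gene distance between
one representative marker sequence per species (`gene_distance_matrix()`,
computed through `ape::dist.gene`): the number of aligned positions at
which the representatives differ, with gap/`N` positions excluded pairwise
by default. The representative is the species' most abundant exact
haplotype, ties broken lexicographically.

A site-count distance *grows* with unrelatedness, so the sign of its MMRR
coefficient depends on the convention chosen. `relatedness_transform()`
offers three, and stamps the chosen mode on the matrix so reports can name
it:

* `raw_distance` (default) — the distance itself enters the model; a
  *negative* coefficient then means related hosts share strains.
* `one_minus_scaled` — `1 − D/max(D)`, a similarity in [0, 1].
* `negated_z` — `−(D − mean)/sd` over off-diagonal entries.

The default is the least manipulated form; because MMRR z-scores all
predictors anyway, the three modes differ only in sign and in how `max(D)`
enters, and the package's own outputs always carry the mode used. Readers
of any fitted model should check the mode before interpreting the sign of
the relatedness coefficient.

# Multiple matrix regression with randomization

`mmrr()` unfolds each square symmetric matrix into its `n(n−1)/2`
lower-triangle pairs, z-scores every unfolded vector, and fits OLS of the
dependent vector on the predictor block with intercept. Coefficients are
therefore standardized and comparable across predictors.

Pairs that share a species are not independent, so OLS p-values are
invalid; inference instead permutes the *species labels* of the dependent
matrix — rows and columns simultaneously — and refits, which preserves the
dependence structure under the null. Per coefficient,
`p = (#{|t*| ≥ |t|} + 1)/(nperm + 1)`, ties counting against rejection
(conservative); the overall F is treated identically. The default
`nperm = 9999` gives four-decimal p-value granularity; 999 is fine for
screening. Only the dependent matrix is permuted (the classic convention
for multi-predictor matrix regression); permuting predictors is not
offered. Fits are exact linear algebra (the permutation loop reuses the
fixed design's cross-products), so `nperm = 9999` on a 22-species problem
takes well under a second.

Degenerate inputs are refused loudly: constant unfolded predictors, label
mismatches, and asymmetry beyond `1e-9` are errors, not warnings.

# Bipartite specialisation, H2′

For an interaction matrix with grand total `m`, `H2` is the Shannon
entropy of the cell frequencies. Its achievable range depends on the
marginals: `H2max` is the entropy of the most even table with the observed
row/column totals, `H2min` of the most concentrated one, and

```
H2' = (H2max − H2) / (H2max − H2min)
```

is 1 for perfect specialisation and 0 when the table equals its
independence expectation.

Computing the constrained extremes exactly is a minimum-entropy-coupling
problem, NP-hard in general, so the bounds are computed at two levels:

* **Exact, small tables.** A dynamic programme over
  remaining-marginal states returns the true extremes whenever its state
  space is affordable (`min(Π(rᵢ+1), Π(cⱼ+1)) ≤ 2×10⁵` and `m ≤ 64`). The
  test suite verifies exactness against independent exhaustive enumeration
  over every marginal configuration up to 4×4 with totals up to 12.
* **Heuristic, field-sized tables.** `H2max`: largest-remainder rounding
  of the independence expectation `rᵢcⱼ/m`, unit top-ups restoring the
  marginals (largest outstanding remainder first, ties row-major), then an
  entropy-ascending local search over marginal-preserving 2×2 unit shifts.
  The local search matters: rounding alone can land measurably below the
  true maximum even on tiny tables. `H2min`: greedy concentration — place
  `min(remaining row, remaining column)` where that allocation is largest
  — run under two deterministic tie-break policies (plain row-major, and
  exact-fit-first, which prefers cells whose remaining row and column
  totals match), keeping the better table. Greedy concentration is the
  standard heuristic for this bound; it is not guaranteed optimal, which
  is precisely why small tables take the exact route.

`h2prime` is clamped to [0, 1] (the heuristic bracket can be overshot by a
hair), and a degenerate bracket (`H2max = H2min`) returns 0 with a
warning.

## Null model and SES

`h2_ses()` compares the observed H2′ with `n_null` (default 1000) random
tables drawn from the fixed-marginal (Patefield) null via
`stats::r2dtable`, reporting `SES = (obs − null mean)/null sd` with the
sample (n−1) standard deviation. Because every null draw shares the
observed marginals, the entropy bounds are computed once and reused for
all draws. SES values from stochastic nulls are reproducible only under a
fixed seed and comparable across implementations only approximately (their
scale depends on the null RNG stream); signs and orders of magnitude are
the robust content.

The projected parasitoid × strain network has fractional entries. Its
observed H2′ uses the continuous independence optimum for `H2max`; for the
null draws, the marginals are rounded to integers with a total-preserving
largest-remainder rule. This mirrors the common practice of rounding
projected networks before null-model analysis and is recorded here because
it is a choice, not a theorem.

# Projection through shared hosts

`project_parasitoid_symbiont()` computes
`B[p, s] = Σₐ S[a, s] · A[a, p] / Σₚ′ A[a, p′]`: each host's symbiont
individuals are assigned to its parasitoids proportionally to attack
frequency. Fractional weights are retained and the symbiont total over
retained hosts is conserved to numerical precision (a test pins this at
`1e-9`). Hosts lacking either record type are dropped and logged.

# Diversity screens

`diversity_indices()` reports richness, Shannon entropy (nats), and the
*Gini–Simpson* index `1 − Σpᵢ²` — "Simpson" is ambiguous in the
literature, and the complement form matches the default of the ecology
tooling this package leans on. `rarefy_indices()` equalises sampling
effort by repeated subsampling without replacement (default depth 7,
1000 draws, seeded); species with fewer individuals than the depth are
flagged for exclusion rather than resampled with replacement, which would
manufacture precision. The Monte-Carlo mean richness is checked in the
tests against the hypergeometric closed form
`Σᵢ [1 − C(N−Nᵢ, d)/C(N, d)]`.

`fit_diversity_model()` is an ordinary one-predictor OLS screen of strain
diversity against partner diversity. The reported R² is *adjusted*
(`1 − (1−R²)(n−1)/(n−2)`), which goes negative for uninformative
predictors — a feature, since it makes "no relationship" visible at a
glance. A constant response returns slope 0, F = 0, p = 1 by convention
rather than erroring, so screens over many index/dataset combinations
don't fall over on degenerate cells.

# The synthetic community generator

`simulate_community()` generates a field-survey-like dataset with known
ground truth, in four steps:

1. **Phylogeny and sequences.** A pure-birth (Yule) tree with unit
   speciation rate (`ape::rphylo`), one marker sequence per species
   evolved by Jukes–Cantor substitution along the branches
   (`phangorn::simSeq`), default 400 sites at rate 0.05 per site per unit
   branch — giving within-community divergences of a few percent, like a
   typical barcoding marker.
2. **Attack profiles.** Dominant parasitoids cycle through a random
   permutation of the parasitoid pool (default 10 parasitoids for 22
   species), so blocks of species share their main enemy; each species'
   dominant holds `dominance` (default 0.8, emulating communities where a
   single parasitoid accounts for more than three-quarters of attacks) of
   its attack profile, the rest spread over 1–3 minor parasitoids.
3. **Strain profiles.** Every parasitoid (and plant) carries a signature
   strain; a species' strain profile is the mixture
   `λ_par · (attack-weighted parasitoid signatures) + λ_phy · (nearest
   phylogenetic neighbour's profile) + λ_pla · (plant signature) +
   (1 − Σλ) · Dirichlet noise`. Defaults: `λ_par = 0.4`, `λ_phy = 0.3`,
   `λ_pla = 0` — a community where enemies and ancestry both structure the
   symbiosis and plants do not, the regime the method is designed to
   detect.
4. **Records.** Default 40 samples per species (≈880 records for 22
   species, the scale of a multi-year survey); per record, categorical
   draws from the profiles, with screening failure rates
   `p_no_parasitoid = 0.15` and `p_no_strain = 0.25` emitting the
   `"No Association"` sentinel. Records with an observed parasitoid are
   sourced `"mummy"`, others `"live"`.

The generator is a deterministic function of its config (byte-identical
tables under the same seed).

**What it emulates and what it does not.** It reproduces the statistical
structure the pipeline consumes — dominant enemies, parasitoid-linked
strain signatures, tunable couplings, uneven screening — via direct
mixture sampling, not mechanism: there is no transmission dynamics, no
within-host symbiont titre, no temporal turnover, and the phylogenetic
coupling borrows only from the single nearest neighbour rather than
following a Brownian trait model. Two consequences are worth knowing.
First, passing recovery tests shows the estimator detects the encoded
couplings, not that real communities behave like the generator. Second,
nearest-neighbour borrowing elevates similarity only for one pair per
species, so the fitted relatedness coefficient under `λ_phy` is
reliably signed but modest in magnitude — weaker than a fully
phylogenetically autocorrelated world would produce.

# Calibration and verification

The package's statistical guarantees are exercised by the test suite and
`scripts/acceptance.R` at these problem sizes (chosen to give tight Monte
Carlo error at interactive runtimes):

* MMRR exactness against an independent `lm()` oracle at `1e-9`, on random
  instances up to 15 species and 3 predictors.
* Type-I error of the permutation test on independent random matrices:
  500 replicates at 20 species, 999 permutations — the rejection rate at
  α = 0.05 must land in [0.03, 0.07].
* Power: with `λ_par = 0.8` and no other couplings, the parasitoid
  coefficient is positive and significant in ≥ 90% of 100 replicate
  communities, while the plant coefficient stays centred on zero.
* H2′ bounds exact over every marginal configuration up to 4×4, total
  ≤ 12, against exhaustive enumeration; Patefield draws keep exact
  marginals always, and match the enumerated two-table law on unit
  marginals within 3 standard errors over 10,000 draws.
* Rarefied richness within 3 Monte-Carlo standard errors of the
  hypergeometric expectation at 1000 draws.

# Known limitations

* H2′ entropy bounds on field-sized matrices are heuristic (exact only
  where the DP is affordable); H2′ is therefore comparable across
  implementations only to the extent their bounds agree. SES values
  additionally depend on the null RNG stream.
* The transient-association filter is an operationalisation (singleton
  pairs), not a community standard; use `host_list` to protect known rare
  associations.
* MMRR assumes a linear relationship between unfolded similarities;
  strongly nonlinear coupling would be under-detected.
* The generator's simplifications above bound what green tests prove
  about real data.
* Exact reproduction of any published field analysis requires the original
  deposited observation tables and alignments; without them the pipeline's
  correctness is established on synthetic ground truth only.
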