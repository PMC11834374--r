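# symnet

Network analysis of tripartite host–enemy–symbiont communities.

Many insects carry heritable *defensive symbionts* — bacteria such as
*Hamiltonella defensa* in aphids — that protect their hosts against
parasitoid wasps. In the field, each host species tends to carry only a few
symbiont strains, and why particular strains sit in particular hosts is a
central question: do hosts that share **natural enemies** carry the same
strains (selection by, or transmission via, parasitoids), or do hosts that
share **food plants** (plant-mediated transmission)?

`symnet` implements the statistical workflow for answering that question
from field survey data, for community ecologists working with long-format
observation tables (one row per sampled individual, linking a focal host
species to its plant, its parasitoid, and its symbiont strain):

* **Community matrices and similarity.** Focal-species × partner-taxon
  count matrices; pairwise community similarity as 1 − Bray–Curtis,
  `BC(x, y) = Σ|xᵢ − yᵢ| / Σ(xᵢ + yᵢ)`.
* **Multiple matrix regression with randomization (MMRR).** The unfolded
  symbiont-similarity matrix is regressed on partner-similarity and
  host-relatedness matrices; all unfolded vectors are z-scored, so the βs
  are standardized. Significance comes from permuting the rows *and*
  columns of the dependent matrix simultaneously
  (`p = (#{|t*| ≥ |t|} + 1)/(nperm + 1)`).
* **Bipartite specialisation (H2′).** The two-dimensional Shannon entropy
  of an interaction matrix rescaled between its marginal-constrained
  extremes, `H2′ = (H2max − H2)/(H2max − H2min)`, tested against Patefield
  fixed-marginal null models and summarised as a standardised effect size
  `SES = (obs − null mean)/null sd`.
* **Proportional projection.** A parasitoid × strain network obtained by
  assigning each host's symbiont individuals to its parasitoids in
  proportion to attack frequencies.
* **Diversity screens.** Richness, Shannon and Gini–Simpson indices, with
  rarefaction by repeated subsampling, and OLS screens of strain diversity
  against partner diversity.
* **Sequence utilities.** Greedy centroid OTU clustering at an identity
  threshold, exact-haplotype strain typing from concatenated MLST genes,
  and site-count gene-distance (relatedness) matrices.
* **A synthetic community generator** with known ground truth — dominant
  parasitoids, parasitoid-linked strain signatures, phylogeny and plant
  couplings with tunable strength — so the whole pipeline can be exercised
  and calibrated without field data.

## Worked example

Simulate a 22-species community in which strain sharing is coupled to
parasitoid sharing, then run the full pipeline:

```r
library(symnet)

sim <- simulate_community(synthetic_config(seed = 1))
bundle <- run_pipeline(pipeline_config(
  observations = sim$observations, sequences = sim$sequences,
  mmrr_nperm = 999, mmrr_seed = 2, h2_n_null = 200, h2_seed = 3,
  rarefaction_reps = 200))

bundle$mmrr$parasitoid
#> Multiple matrix regression with randomization
#>   22 species, 231 pairs, 999 permutations
#>   (Intercept)        beta =  -0.0000  t =   -0.000  p_perm = 0.9340
#>   parasitoid         beta =   0.4585  t =    7.695  p_perm = 0.0010
#>   relatedness        beta =   0.0528  t =    0.886  p_perm = 0.6410
#>   R2 = 0.2063, F = 29.625, F p_perm = 0.0010

bundle$h2$aphid_parasitoid
#> H2' specialisation: h2prime = 0.7880 (H2 = 3.6435 in [3.1834, 5.3535])
#>   null (n = 200): mean = 0.0686, sd = 0.00800, SES = 90.0

bundle$pairs$parasitoid
#> Pairwise sharing over 231 species pairs:
#>   strain-sharing pairs: 231
#>   of those, sharing partner use (> 0.00): 135 (58.4%)
#>   species linked via shared partner: 22 of 22 (100.0%)
#>   strains in >1 species: 12 of 12 (100.0%)
```

Reading the output: the standardized coefficient on parasitoid community
similarity (β = 0.46, permutation p = 0.001) says that host species
attacked by the same parasitoids carry significantly more similar strain
communities, after controlling for host relatedness — which is exactly the
coupling this synthetic community was generated with
(`coupling_parasitoid = 0.4`). The aphid–parasitoid network is strongly
specialised: its H2′ of 0.79 sits 90 null standard deviations above the
fixed-marginal expectation. With defaults, `run_pipeline()` also writes
every matrix, model and summary to `out_dir` as CSV/JSON.

Real data enter through `read_observations()` (CSV/TSV, configurable
column mapping) and `read_sequences()` (aligned FASTA), or through a YAML
file via `read_pipeline_config()`.

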