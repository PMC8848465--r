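# bincomm

Community phylogenetics of DNA-barcode BINs: does a local assemblage contain
species that are more closely related than a random draw from its regional
pool?

`bincomm` is built for analyses of barcode-defined communities such as the
Coleoptera of Churchill, Manitoba: specimen records are pulled as a
BOLD-style export (TSV metadata + FASTA sequences), species are proxied by
Barcode Index Numbers (BINs), each BIN is reduced to a centroid sequence,
per-group phylogenies are estimated, and the phylogenetic structure of the
local community is quantified against the regional pool. The package also
ships a synthetic-data generator with known assembly regimes so the entire
pipeline is testable without any database access.

## The statistics at the core

For a community of k BINs drawn from a regional pool with tip-to-tip
distance matrix d:

* **MPD** — mean pairwise distance, the average of d over all unordered
  pairs of community members.
* **MNTD** — mean nearest-taxon distance, the average over members of the
  distance to their nearest co-occurring relative (k directional terms).

Each observed metric is standardized against a null distribution of
`n_iter` random draws of the same richness from the pool (the tip-label
shuffling null):

    NRI = -(MPD_obs  - mean(MPD_null))  / sd(MPD_null)
    NTI = -(MNTD_obs - mean(MNTD_null)) / sd(MNTD_null)

Positive values indicate phylogenetic clustering (the signature of
environmental filtering), negative values overdispersion. The one-tailed
permutation p-value for clustering is `(r + 1) / (n_iter + 1)` where r is
the number of null values at or below the observed metric; with 1000
randomizations the smallest attainable p is 1/1001 ≈ .001. Families are
tested jointly with the Holm stepdown correction.

Trait analyses relate per-group structure to categories (habitat, diet):
one-way ANOVA, chi-square tests on BIN representation counts, paired
t-tests between analyses, and phylogenetic generalized least squares (PGLS)
under Brownian motion on a backbone tree, `β̂ = (XᵀV⁻¹X)⁻¹XᵀV⁻¹y` with
`V[i,j]` the shared root-to-MRCA path length.

## Worked example

```r
library(bincomm)

# simulate a BOLD-style export: 50-BIN regional pool, a 15-BIN local
# community assembled under environmental filtering
cfg <- sim_config(n_pool_tips = 50, community_richness = 15, n_per_bin = 3,
                  assembly_mode = "filtering", lambda = 5, seed = 11)
sim <- emit_bold_dataset(cfg)

run <- run_pipeline(sim$paths$metadata, sim$paths$fasta,
                    local_box = cfg$local_box, n_iter = 1000, seed = 99)
print(run$table[, c("group", "n_pool", "n_local", "pct_local",
                    "nri", "p_nri", "nti", "p_nti")], digits = 3)
#>   group n_pool n_local pct_local  nri    p_nri  nti p_nti
#> 1 Fam01     50      15        30 10.4 0.000999 3.05 0.003

# compare the published full-pool and restricted-pool family tables
full  <- load_family_metrics("full")
restr <- load_family_metrics("restricted")
paired_t(setNames(full$nri, full$family), setNames(restr$nri, restr$family))
#> Paired t-test: t = 0.1889 on 15 df, p = 0.8527 (n = 16 pairs)
#>   mean difference 0.03312 (sd 0.7013)
```

The synthetic community was assembled under strong environmental filtering
(`lambda = 5`), so the pipeline recovers a large positive NRI with the
smallest attainable permutation p-value (1/1001): the local BINs are far
more closely related than random draws from the pool. The paired t-test
shows that the published full-pool and restricted-pool NRI values for the
16 Churchill beetle families do not differ (t = 0.189).

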