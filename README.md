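# nichescape

Tools for studying climatic niche evolution across a clade: did closely
related lineages diverge into new environmental conditions, or did they
conserve their ancestral tolerances while speciating in allopatry? The
package was built around the six-clade *Tarentola mauritanica* (Moorish
gecko) species complex of the Mediterranean basin, but every stage is
generic.

The workflow:

1. **Seasonal predictors** — five monthly environmental variables (middle
   infra-red reflectance, day/night land-surface temperature, NDVI, EVI; 60
   layers) are condensed into 30 bioclim-style predictors (annual mean,
   seasonality, extremes, annual range, quarter means; diurnal range and
   isothermality for the temperature pair).
2. **Environmental space** — a correlation PCA (components with eigenvalue
   > 1 retained) and per-clade backgrounds: all cells within 100 km of a
   clade's records.
3. **Envelope SDMs** — boxcar (Bioclim) envelopes on the PC scores; the
   percentile score `1 − 2·|F(x) − ½|` per axis, aggregated by the minimum,
   zero outside the training box.
4. **Realized niche overlap** — occupancy-corrected kernel density grids
   (`z ∝ o/e`) on a 100×100 lattice over PCs 1–2, Schoener's
   `D = 1 − ½·Σ|z₁ − z₂|`, the niche **equivalency** randomization test
   (pool, re-split, 100×) and the **background similarity** test (random
   records from the other clade's available environment, both directions),
   with the standard qualitative overlap classification.
5. **Niche history** — predicted niche occupancy (PNO) profiles (suitability
   binned over each PC, 100 bins), and Brownian-motion/GLS reconstruction of
   ancestral tolerances on a calibrated ultrametric tree, with uncertainty
   propagated by 1000 Monte-Carlo draws from the PNOs (and, optionally, over
   a set of posterior trees); node summaries are means with 80% equal-tail
   central density intervals.

A synthetic-data module generates all inputs — seasonal raster stacks, clade
occurrences with controllable niche structure, and the calibrated six-clade
reference tree (root 5.88 Ma, youngest split 2.47 Ma) — so the entire
pipeline is testable offline.

## Worked example

Two clades with nested niches (one generalist, one specialist sharing the
same optimum):

```r
library(nichescape)

stacks     <- generate_monthly_stacks(extent = c(0, 10, 0, 10),
                                      resolution = 0.5, seed = 1)
occ        <- generate_clade_occurrences(stacks, canonical_scenario("nested"),
                                         seed = 2)
predictors <- build_predictor_set(stacks)

cmp <- pca_env_compare(predictors, occ, "A", "B", n_reps = 100, seed = 3)
cat("Schoener D =", round(cmp$d, 3), "->", cmp$class, "\n")
#> Schoener D = 0.558 -> moderate
cmp$equivalency
#> niche equivalency test
#>   observed D = 0.5581, 100 randomizations
#>   95% CI of simulated D: [0.8026, 0.9001]
#>   p = 0.0198 -> null REJECTED at the 95% level
```

The observed overlap (0.558, "moderate") sits far below every overlap
obtained by pooling and re-splitting the two clades' records (95% CI
0.80–0.90), so niche equivalency is rejected at the permutation floor
p = 2/101 ≈ 0.02: the specialist occupies a genuinely narrower niche than
exchangeability with the generalist would produce.

The full six-clade analysis, through ancestral reconstruction:

```r
occ6 <- generate_clade_occurrences(stacks, canonical_scenario("reference"),
                                   seed = 2)
cfg  <- pipeline_config(stacks, occ6, build_reference_tree(),
                        r = 60, n_reps = 50, n_samples = 500, seed = 9)
res  <- run_pipeline(cfg)
head(res$overlap_table, 4)
#>    pair    D    class equivalency_p similarity_p_2to1 similarity_p_1to2
#> 1  VI-V 0.34      low         0.039              0.67             0.471
#> 2  VI-I 0.67     high         0.549              0.20             0.078
#> 3 VI-IV 0.49 moderate         0.078              0.98             0.549
#> 4 VI-II 0.76     high         0.784              0.35             0.431
```

`res$ancestral$summary` holds, per internal node and PC, the mean inferred
ancestral tolerance with its 80% interval (e.g. the root at 5.88 Ma:
mean 3.39, interval 2.38–4.40 on PC1 in this run);
`plot(res$ancestral, axis = "PC1")` draws the age-vs-tolerance history
connecting ancestors to descendants.

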