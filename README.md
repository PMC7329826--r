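# dyadconn

Dyadic analysis of resting-state connectome similarity in sociometric
networks: does social closeness predict how similar two people's functional
brains are ("neural homophily at rest")?

`dyadconn` implements the complete analysis chain for studies that pair a
**roster-and-rating friendship survey** (every student rates every peer on a
five-point Likert scale) with **parcellated resting-state fMRI**:

1. **Social network** — binarised reciprocal friendship graphs at Likert
   threshold 4 or 5, geodesic social distance `d_ij`, Louvain community
   detection with seeded restarts, and the standard cohort summary
   (diameter, modularity, mean path length, reciprocity, density,
   eigenvector centrality).
2. **Connectome similarity** — per-subject P×P Pearson connectivity from
   parcel time series, Fisher z transform (clipped, diagonal masked),
   optional restriction to named resting-state networks (DMN, salience,
   lFPN, rFPN) via a label mask, and inter-subject similarity
   `r_ij = cor(vec(Z_i), vec(Z_j))` over the upper triangle.
3. **Dyadic inference** — the crossed-random-effects linear mixed model

   `y_ij = β0 + β1 x_ij + u_i + u_j + ε_ij`,  `u ~ N(0, σ²_u)`, `ε ~ N(0, σ²_ε)`

   fitted by exact one-dimensional REML, where `y_ij` is the standardized
   similarity of dyad (i, j) and `x_ij` is either social distance or binary
   community co-membership; per-cohort slopes are pooled with a
   random-effects meta-analysis (REML τ², inverse-variance weights).
   Because every subject sits in many dyads, OLS on dyadic data understates
   uncertainty; the shared member intercept restores calibration.
4. **Signed graph metrics** — nodal strength s±, nodal diversity h±
   (module-wise entropy), and signed Louvain modularity
   `Q* = Q⁺ − v⁻/(v⁺+v⁻) Q⁻`, compared across dyads by correlation or
   absolute difference.
5. **Distance prediction** — elastic-net regression of social distance on
   edgewise similarity features with subject-grouped nested
   cross-validation and a permutation test of predictability.
6. **Synthetic cohorts** — a generator that plants friendship groups in the
   roster and a homophily effect of size θ in the connectomes, so every
   stage has parameter-recovery, type-I and power tests with known ground
   truth.

## Worked example

Simulate a three-cohort study (23, 17 and 28 scanned students, 40 parcels)
with a planted homophily effect θ = 0.3, fit the social-distance model per
cohort, and pool:

```r
library(dyadconn)

study <- simulate_study(cohort_sizes = c(23, 17, 28), seed = 42,
                        theta = 0.3, n_parcels = 40)
res <- fit_study(study, predictor = "distance")
summary(res$fits$cohort1)
#> Dyadic linear mixed model (REML), crossed random member intercepts
#> Formula: similarity ~ distance
#> 231 dyads, 22 subjects (22 unreachable/incomplete dyads dropped)
#>
#> Fixed effects (Wald z tests):
#>              Estimate Std. Error   t value  df Pr(>|t|)
#> (Intercept)   1.45352    0.16159   8.99518 Inf   <2e-16 ***
#> distance     -0.45733    0.03291 -13.89533 Inf   <2e-16 ***
#>
#> Variance components: member sigma2_u = 0.07143 , residual sigma2_e = 0.512

res$meta
#> Random-effects meta-analysis (REML), k = 3 cohorts, coefficient 'distance'
#>   pooled beta = -0.5797  SE = 0.156  95% CI [-0.8854, -0.2741]
#>   tau2 = 0.07091, z = -3.717, p = 0.0002015
```

The negative pooled slope says similarity falls as social distance grows —
the planted homophily is recovered with a 95% CI excluding zero. With
`theta = 0` the same pipeline rejects at the nominal 5% rate (see the
acceptance script below).

Real data enter through `load_roster()` (roster CSV), `load_time_series()`
(manifest + per-subject TSV) and `run_pipeline()` / `read_run_config()`
(YAML-driven multi-cohort runs writing dyad tables, fit JSONs, a
forest-plot CSV and a hashed artifact manifest).

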