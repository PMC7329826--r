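---
title: "Dyadic models of connectome similarity in friendship networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyadic models of connectome similarity in friendship networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the data

Homophily — the tendency of similar people to become friends — is well
documented for demographic and behavioural traits. `dyadconn` implements
the analysis needed to ask whether it extends to *intrinsic brain
organisation*: do schoolmates who are socially close have more similar
resting-state functional connectomes than distant pairs?

Two instruments feed the analysis. A **roster-and-rating survey** gives
each student's rating of every peer ("How much time do you spend
interacting with this student?") on a five-point Likert scale anchored
"None", "A rare amount", "Some", "More than some", "Most", coded 1..5 in
that order. **Parcellated resting-state fMRI** gives each scanned student a
T×P matrix of BOLD time series (the study design this package mirrors uses
P = 272 parcels and a ~10-minute scan).

The unit of analysis is the *dyad*: an unordered pair of students. A cohort
of n students yields n(n−1)/2 dyads, which is why modest cohorts (23, 17,
28 scanned students) still produce hundreds of outcomes (253 + 136 + 378 =
767 dyads).

## From ratings to social structure

A directed tie i→j exists when i rated j at or above a threshold; the
default threshold 4 keeps "More than some" and "Most" (threshold 5, only
"Most", is the robustness variant). The primary graph is **reciprocal**:
an undirected edge requires both directed ratings to clear the threshold,
because mutually reported ties are more reliable indicators of friendship.
Students who did not take part in the survey are removed before graph
construction, as are their incident ties.

Social distance is the unweighted geodesic d_ij on the reciprocal graph:
d = 1 is mutual friendship, 2 a shared friend, and so on. Unreachable pairs
are carried as `Inf` and excluded from distance-based model fits with a
recorded count (`n_dropped`); the study networks this mirrors were fully
connected with diameter ≤ 4, so no exclusion rule is inherited from them.
Distance enters the models as a continuous predictor. Community
co-membership, the second predictor, is the binary indicator of sharing a
Louvain module; we run Louvain with resolution γ = 1 and 100 seeded
restarts, keeping the maximum-modularity partition (ties resolved by first
occurrence in seeded order), since the restart-to-restart variability of
greedy modularity optimisation is otherwise a hidden analysis input.

The direct-tie robustness variant aggregates a dyad's two directed ratings
by their mean (minimum and maximum are provided as options); the mean
respects exchangeability of the two members and uses both reports.

## From time series to similarity outcomes

Per subject, the connectome is the P×P Pearson correlation matrix of the
parcel time series. Before comparison, correlations are Fisher
z-transformed (variance stabilisation), with r clipped to ±(1 − 1e−7) so
that duplicated or degenerate series cannot produce infinities, and the
self-self diagonal masked. Network-restricted analyses subset the z matrix
by a parcel-label mask (DMN, salience, lFPN, rFPN); selection is keyed by
label, not position, and the mask is consumed as a plain table — voxel
overlap computation is out of scope.

Inter-subject similarity is the Pearson correlation of the two subjects'
vectorised upper triangles. The vectorisation order (row-major over pairs
p < q) does not affect the correlation; it is fixed anyway so intermediate
files are reproducible. Within each cohort **and each network scope**, the
similarity outcome is standardized to mean 0, SD 1 before modelling; the
per-scope choice keeps slopes comparable across scopes (the alternative, a
single global standardisation, would let the whole-brain scale leak into
network-level slopes).

## The dyadic mixed model

Dyadic outcomes are not independent: each student appears in n − 1 dyads.
Ordinary least squares ignores that and inflates type-I error. The model

y_ij = β0 + β1 x_ij + u_i + u_j + ε_ij,  u ~ N(0, σ²_u), ε ~ N(0, σ²_ε)

gives every student a random intercept shared by all their dyads. Because
dyads are unordered, the two member effects must share a single variance
component — separate variances are not identifiable — which is the
social-relations-model form of crossed random effects.

The fit is restricted maximum likelihood. With λ = σ²_u/σ²_ε the marginal
covariance is V = σ²_ε (I + λ ZZ′) for the two-ones-per-row membership
matrix Z, and the REML profile in λ is one-dimensional. We evaluate it
exactly through a thin eigendecomposition of Z′Z (n_subjects × n_subjects),
optimise log λ on [−15, 10], always evaluate the λ = 0 boundary, and flag
the fit singular when the boundary wins — in which case the fixed effects
equal OLS to machine precision, a reduction the tests verify. Inference on
β1 uses Wald z tests by default (dyad counts of 136–378 make the normal
approximation accurate); Satterthwaite degrees of freedom, computed from
the numerically differentiated REML information, are available via
`df = "satterthwaite"`. Covariate models add ethnicity match, boarding
match, and head-motion terms as fixed effects; for an unordered pair, the
two members' motion values enter as their mean and absolute difference, the
two exchangeable summaries.

Cohorts are fitted separately (their social networks are disjoint) and the
slope is pooled by random-effects meta-analysis: β_k ~ N(β̄, τ² + SE_k²),
τ² by REML (DerSimonian–Laird and fixed-effect available), inverse-variance
weights, normal 95% CI. This is delegated to `metafor::rma.uni`, with the
convergence threshold tightened to 1e−10 so the τ² estimate agrees with an
independent grid-search maximiser of the restricted likelihood to 1e−6.
Results are reported per network scope without multiplicity correction,
matching per-network forest-plot reporting; a Bonferroni adjustment can be
applied to the returned p-values by the caller.

## Signed graph metrics

The exploratory arm characterises each connectome as a signed weighted
graph. Nodal strength is the sum of positive (s⁺) or rectified negative
(s⁻) weights at a node. Modularity uses the asymmetric signed objective
Q* = Q⁺ − v⁻/(v⁺ + v⁻) Q⁻: positive within-module weight counts fully,
negative within-module weight is penalised only in proportion to its share
of total weight — the convention that treats positive connections as the
primary carriers of community structure. The symmetric variant (Q⁺ − Q⁻)
is exposed as an option. Since standard Louvain implementations reject
negative weights, the package optimises the signed objective directly with
a dense multi-level Louvain of its own (greedy local moves on the signed
modularity matrix, aggregation, seeded restarts); on all-positive input it
reproduces igraph's weighted modularity exactly, and on ≤ 6 nodes it
attains the exhaustively enumerated optimum in the tests. Nodal diversity
is the module-wise entropy of a node's strength distribution, normalised
by log m with 0·log 0 := 0, computed on the subject's own modularity
partition (recorded in the output, since the partition source is an
analysis choice). Dyadic comparison follows the outcome's shape: Pearson
correlation of per-node vectors for strength and diversity (positive and
negative parts concatenated; sign-separated variants available), absolute
difference for the scalar Q*.

## Predicting distance from edges

The whole-matrix correlation could miss signal carried by specific
connections, so the package also regresses social distance on the full
vector of edgewise similarities, feature (p, q) of dyad (i, j) being
−|z_i(p,q) − z_j(p,q)| (edge-product and edge-mean variants are options).
Elastic net handles P(P−1)/2 ≫ n_dyads. Cross-validation must respect the
dyadic dependence: outer folds hold out *subjects*, test dyads are pairs of
held-out subjects, and training dyads touch no held-out subject — plain
k-fold over dyads would leak members between sides. Inner folds (same
grouping) select the mixing parameter α over {0.1, 0.25, 0.5, 0.75, 1} and
λ over a 50-point path spanning four decades below the all-zero λ, by mean
squared error. Feature standardisation uses training-fold statistics only,
and the fold-wise means are returned for leakage audits. Predictive skill
is judged by a permutation test: distances shuffled across dyads, fold
structure intact, p = (1 + #{perm ≥ observed}) / (1 + n_perm) on the
out-of-fold prediction correlation.

## The synthetic cohort generator

Every stage above is tested against cohorts with known ground truth. The
generator plants `n_groups` friendship groups; each directed rating is
drawn independently (so reciprocity is *emergent*, matching independent
raters): "high" (Likert 5) with probability `p_in` within groups and
`p_out` between, "low" (Likert 1) otherwise, then jittered one step with
probability `likert_noise`. Connectomes mix three random factor-structure
correlation templates: a global template (weight η), the subject's group
template (weight θ — the homophily effect), and subject-unique noise
(weight 1 − θ − η). A convex combination of correlation matrices is itself
a correlation matrix, so the nearest-correlation projection
(`Matrix::nearPD`, Higham alternating projections, tolerance 1e−8) is a
numerical guard rather than a repair. BOLD series are multivariate normal
draws realising each subject's matrix via its symmetric eigen
factorisation.

Defaults are fixed once to emulate the study conditions: `p_in = 0.85`,
`p_out = 0.25` reproduce the scale of the observed cohort summaries at
n ≈ 59 (density ~0.2, mean path length ~2, diameter 3–4, connected,
moderate modularity); `n_timepoints = 250` stands in for a ~10-minute scan,
where only large-sample correlation stability matters downstream;
`n_groups = 4` matches the few friendship modules such cohorts show;
templates use k = 5 factors for realistic low-rank structure; `eta = 0.3`
keeps subjects positively similar overall (as real connectomes are) while
leaving headroom for θ. One root seed drives everything through labelled
child streams (`child_seed(seed, "cohort1/bold/S07")`), so enlarging a
simulation never perturbs existing draws.

What the generator does **not** emulate: haemodynamics, scanner noise,
head motion, atlas misregistration, heavy-tailed or non-stationary BOLD,
rating styles (acquiescence), or inter-year-group ties. Passing calibration
tests on these cohorts therefore shows the *statistical machinery* is
sound — calibrated type-I error, unbiased recovery, no CV leakage — not
that real data meet the model's assumptions.

## Numerical choices and degenerate inputs

- Fisher clipping constant 1e−7; synthetic duplicates can reach |r| = 1.
- Constant time-series columns, zero-variance similarity outcomes,
  constant predictors, mismatched parcel labels and out-of-range ratings
  are hard errors naming the offending parcel/cell, never silent NaNs.
- REML: λ optimised on log scale, boundary λ = 0 always evaluated;
  singular fits report σ²_u = 0 rather than failing.
- Louvain ties between equal-Q partitions: first found under seeded order.
- Geodesics: unreachable is `Inf`, never a large number.
- All CSV floats are written at 17 significant digits; JSON numbers are
  written unrounded.

## Problem sizes used in the shipped tests

Chosen as the package's own trade-off between Monte-Carlo resolution and a
test suite that runs in minutes: type-I calibration uses 200 replicate
three-cohort studies (23 + 17 + 28 subjects) at P = 40 parcels, T = 250;
slope recovery uses 200 replicates at 30 subjects; the elastic-net null
calibration uses 20 replicate cohorts (16 subjects, P = 20) with 19
permutations each; oracle equivalences run exhaustively at ≤ 8 nodes
(graphs) and ≤ 6 parcels (similarity). The acceptance script
(`scripts/acceptance.R`) re-runs the same computations from a single
command-line seed.

## Known limitations

- The shared-variance crossed random intercept is the minimal dyadic
  model; relationship-specific effects (SRM dyadic covariance) are not
  modelled.
- Social distance is treated as numeric; ordinal treatments are out of
  scope.
- The elastic-net feature construction is one defensible choice among
  several (hence the variants behind a flag); results should be read
  through the permutation test, not the raw CV score.
- The signed-Louvain optimiser is exact only in the sense of attaining
  local optima from many seeded starts; like all Louvain variants it
  carries no global guarantee.
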