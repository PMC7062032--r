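---
title: "Methods: models, procedures and design choices in palmvision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, procedures and design choices in palmvision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`palmvision` tests the frugivory hypothesis for primate colour vision at
two scales: macroecologically, by asking whether assemblages with a high
proportion of conspicuous-fruited palm species hold more trichromatic
primates once climate, forest structure and area are accounted for; and
macroevolutionarily, by asking whether trichromat and conspicuous-palm
lineages radiated in parallel and whether diversification rates depend on
the trait states. This vignette documents the models, their assumptions,
the tunable parameters, and the design decisions taken where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Fruit-colour classification and assemblage tables

Each palm species carries a set of fruit colours from a fixed 14-colour
vocabulary. Classification proceeds in two steps:

1. *Palatability*: a species whose description contains none of the six
   colours primates feed on (brown, green, orange, yellow, red, purple)
   is `excluded` and never enters any count or proportion.
2. *Conspicuousness*: among palatable species, any of orange, red,
   yellow or pink makes the species `conspicuous`; otherwise it is
   `non_conspicuous`.

For multi-colour species, palatability is tested against the union of
listed colours first and conspicuousness then triggers on *any*
conspicuous colour. This is the permissive reading: a fruit displaying
any reddish colour is detectable to a trichromat. A pink-only species is
excluded (pink is a conspicuous colour but not a primate-diet colour);
the rule table is verified in the tests by brute force over every colour
subset up to size three.

`build_assemblage()` counts, per spatial unit (botanical country or
equal-area grid cell), the species richness of each colour-vision class —
optionally restricted to day-active frugivores (frugivory rank 1–3).
Cathemeral/crepuscular species are *not* counted as day-active by
default (the conservative reading; `cathemeral_is_diurnal = TRUE`
toggles it). The proportion of conspicuous palm fruits is
`n_conspicuous / (n_conspicuous + n_nonconspicuous)`, undefined (and
flagged) where no palatable palm occurs.

`filter_units()` keeps units with at least one focal-class primate and
at least three palatable palm species. The palm floor counts *palatable*
species only, because excluded species never enter the proportion whose
stability the filter protects. `transform_variables()` applies sqrt to
richness (variance stabilisation for counts), natural log to area, and
then min–max rescaling of every model variable to [0, 1], in that order —
transforming first preserves the purpose of each transform on the
modelled scale. The scaling constants are recorded for inversion.
Standardized coefficients and the SEM χ² are invariant to these affine
rescalings, which the tests assert.

## Maximum-likelihood path analysis

Models are recursive (acyclic) systems over observed variables,
specified as `effect ~ cause1 + cause2` equations. Variables never
appearing on a left-hand side are exogenous; their covariances are
always free (the standard path-analysis convention, and the structure of
a fully connected exogenous block). Endogenous residuals are mutually
uncorrelated. Writing `B` for the coefficient matrix, `Φ` for the
exogenous covariance block and `ψ` for the residual variances, the
implied covariance is `Σ(θ) = (I−B)⁻¹ Ψ₀ (I−B)⁻ᵀ` and the fit minimises
the Wishart discrepancy

```
F(θ) = ln|Σ(θ)| − ln|S| + tr(S Σ(θ)⁻¹) − p ,    χ² = (n − 1) F
```

with `S` the unbiased sample covariance. The `(n−1)` convention is
stated explicitly because software differs. Optimisation is BFGS on the
free parameters (`Φ` via its Cholesky factor with log diagonal, `ψ` on
the log scale) from per-equation OLS starting values; for recursive
models with uncorrelated residuals the OLS start *is* the ML solution,
so iteration only polishes and convergence tolerance is `1e-12` on `F`.
This OLS equivalence is also the independent oracle in the tests: on
random recursive models the ML paths must match closed-form OLS to
`1e-6`. Standard errors come from the inverse observed information of
`(n−1)F/2`.

Fit adequacy uses χ² (`p > 0.05`), CFI (`> 0.90`) and the RMSEA,
`sqrt(max(χ²−df,0)/(df(n−1)))`, with confidence limits obtained by
numerically inverting the noncentral χ² distribution (verified against a
bisection oracle). The confidence level defaults to 90%, the
conventional choice. The RMSEA *criterion* is read as "CI lower bound
below 0.05", with the upper bound also reported so the stricter reading
can be audited — the two readings are printed side by side rather than
silently chosen between.

`backward_eliminate()` removes the least significant path (largest p;
ties by smallest |z|, then lexical edge order), refits, and stops when
all paths are significant at `alpha = 0.05`. The exogenous set of the
initial model is kept fixed throughout, making successive models nested
so χ² is non-decreasing (asserted in tests). `modification_indices()`
reports the *exact* χ² drop from refitting with a candidate edge freed,
not the Lagrange-multiplier approximation — exact refits are cheap at
these model sizes and remove an approximation from the audit trail.

## Permutation null and progressive delimitation

The permutation null reshuffles primate species across units: for a unit
with observed richness k, k distinct species are drawn uniformly from
the global pool, independently across units (species may occupy several
units, as in range data). This is the minimal scheme that preserves
per-unit total richness exactly, which it does by construction. Per
replicate the *full* pipeline runs again — rebuild, filter, transform,
fit, standardize — and the observed standardized coefficient is compared
to the null distribution; the test is one-sided ("greater") at the 95%
level, with a two-sided variant behind a flag. Replicates whose refit
fails are dropped; more than 5% failures aborts with diagnostics. The
loop is integer-coded internally (species and units as indices, the
covariance assembled directly) for speed; the tests verify it reproduces
the reference data-frame pipeline exactly.

One property worth knowing: conditionally on a single realised landscape
the null distribution's mean is not exactly zero — it inherits a small
offset (order `1/sqrt(n_units)`) from the finite-sample correlation
between total unit richness and the predictors. Marginally over
landscapes it centres at zero, and the test's type-I error is unaffected
because the observed coefficient is drawn from the same conditional
distribution; the calibration test (nominal 5% within its binomial
interval over 200 independent landscapes) checks exactly this.

`progressive_delimitation()` raises the minimum palatable palm richness
per unit from 2 to 16, one threshold at a time, refitting the SEM on
each nested subset — 15 fits in total, following the methods text
(thresholds 2..16 inclusive); where a figure caption elsewhere counts 16,
the methods text is followed and the discrepancy simply noted.
Thresholds retaining fewer than 30 units (configurable) are recorded as
skipped rather than fitted. The reported uncertainty is the standardized
coefficient's delta-method standard error (`se(b)·sd(cause)/sd(effect)`
at the implied variances); the dispersion of the sds themselves is
ignored, which is standard and conservative at these sample sizes.

## SAR error models and Moran's I

The spatial robustness check fits `y = Xβ + u`, `u = λWu + ε` — the SAR
*error* specification, matching the purpose of absorbing autocorrelation
in residuals rather than in the response. `W` defaults to rook adjacency,
row-standardized; this neighbourhood choice is an assumption (documented,
configurable to queen/binary) rather than a derived fact. The likelihood
is profiled over λ within its feasible interval `(1/ω_min, 1/ω_max)`
given the eigenvalues ω of `W`, with β and σ² concentrated out and
`ln|I−λW| = Σ ln(1−λω_i)` from the precomputed spectrum. At `λ = 0` the
fit reproduces OLS exactly (coefficients and log-likelihood), which the
tests assert to machine precision; estimates at the interval boundary
are flagged. Moran's I uses the analytic randomisation-assumption
moments (`E[I] = −1/(n−1)` and the classical variance with the kurtosis
correction).

## Mk models, stochastic mapping, diversity through time

Colour vision is coded as three states (routine trichromatic /
polymorphic / dichromatic-or-monochromatic) and fruit colour as two
(conspicuous / non-conspicuous); both are assumptions recorded here, not
facts derived from the machinery, which is k-state throughout.

The Mk likelihood is Felsenstein pruning with per-branch transition
matrices `P(t) = e^{Qt}` from the eigendecomposition of `Q` (with a
scaling-and-squaring fallback when the eigenvector matrix is
ill-conditioned), row-renormalised after clipping tiny negatives.
`fit_mk()` maximises over log rates under ER/SYM/ARD constraints; the
root prior defaults to the fitted stationary distribution (flat
available — the choice is stamped on the model object). Likelihood and
marginals are verified against exhaustive enumeration over all
internal-node state assignments on small trees, to `1e-10`.

Marginal ancestral reconstruction uses the two-pass
(re-rooting-equivalent) algorithm; the same machinery evaluates
marginals at arbitrary interior points of edges, which is what the
diversity-through-time estimator integrates over.

`stochastic_map()` samples node states root-to-tips from their joint
conditionals, then fills each branch with an endpoint-conditioned
history by uniformization — exact, with no rejection blow-up on long or
rate-free branches. Segment durations sum to branch lengths to `1e-9`
and map frequencies converge to the marginals (both asserted).

`state_diversity_through_time()` evaluates, just below each
internal-node time, the expected number of contemporaneous lineages in
the focal state. `method = "simulation"` (default) averages indicator
counts across stochastic maps; `method = "asr"` sums exact per-lineage
point marginals and is the fast deterministic alternative. Which mode a
published analysis used is often unstated, so both are provided and the
conservation identity — summing the curve over all states returns the
number of lineages alive — holds exactly for `asr` and by construction
per map for `simulation`.

## State-dependent diversification (MuSSE)

The per-branch extinction/data ODEs

```
E_i' = μ_i − (λ_i+μ_i+q_i·)E_i + λ_iE_i² + Σ_j q_ij E_j
D_i' = −(λ_i+μ_i+q_i·)D_i + 2λ_iE_iD_i + Σ_j q_ij D_j
```

are integrated tip-to-root with an adaptive Cash–Karp Runge–Kutta scheme
in compiled code (tolerances `rtol 1e-8`, `atol 1e-12` for likelihood
evaluation; relaxed to `1e-6`/`1e-9` inside optimisation loops where
only AIC differences matter). Branches combine at nodes with the node
state's λ; every internal node including the root contributes its
speciation factor and no survival conditioning is applied. The root uses
likelihood weighting (FitzJohn-style) by default; flat and equilibrium
treatments are selectable and the choice is stamped on results.

The module's strongest correctness anchor is the factorisation identity:
with state-independent λ and μ, the MuSSE log-likelihood equals the
constant-rate birth–death log-likelihood plus the Mk log-likelihood,
each computed by independent code (`bd_loglik()` is closed-form). The
tests require agreement to `1e-6` on random trees, plus agreement with a
brute-force fixed-step RK4 integrator and the Yule closed form.

`fit_sse()` compares the free model against `equal_lambda` and/or
`equal_lambda_mu` constraints by AIC, optimising log rates by
Nelder–Mead from a Yule-based heuristic start. A known limitation,
confirmed by this package's own simulations: at around 150 tips with a
two-fold speciation ratio, AIC preference for the true state-dependent
model occurs in only roughly two-thirds of replicates (rate-ordering
`λ̂_fast > λ̂_slow` is far more reliable), in line with the literature
on the low power of state-dependent diversification tests below a few
hundred tips. Making the trait more conserved does not help — fewer
independent origins carry less information.

## The synthetic-data generator

The generator defines the study conditions for every calibration and
recovery claim:

* *Landscapes*: units draw five covariates (annual mean temperature
  °C×10, annual precipitation mm, temperature seasonality, precipitation
  seasonality CV, canopy height m) from a multivariate normal with a
  climate-realistic default correlation (wet–warm 0.3, wet–tall-canopy
  0.55, warm–low-seasonality −0.45, …) and means/SDs chosen once to
  resemble tropical-subtropical WorldClim summaries (the
  specification of means plus a correlation matrix is completed with
  explicit SDs, a field the generator adds). Areas are log-normal.
  Non-negative variables are floored at 1% of their mean.
* *Palm floras*: each synthetic species has exactly one colour (real
  descriptions may list several; multi-colour handling is exercised
  through the classifier, not the generator). Half the palatable pool is
  conspicuous; per unit, palatable richness is Poisson (mean 8–10) and
  the conspicuous count is binomial with probability
  `plogis(intercept + slope·z(covariate))`, so the expected proportion
  conspicuous follows a logistic gradient with exactly the requested
  slope — recovered by logistic regression in the tests. A ~10% slice of
  the pool gets non-palatable colours to exercise the exclusion rule.
* *Primate assemblages*: the scenario fixes *standardized* path
  coefficients. Richness is generated on the sqrt scale
  (`ŷ = 3 + 0.6·y*`, Gaussian noise completing unit variance), squared
  and rounded — matching the analysis transform so that downstream
  standardized-coefficient recovery is unbiased (the tests recover 0.5
  to within ±0.05 over 50 replicates of 400 units). Species identities
  are nested uniform draws from global class pools (class shares 38/31/31
  per cent), which makes vision labels exchangeable in the null scenario —
  the assumption the permutation test leans on. A Poisson noise model is
  available as an alternative.
* *Trees and traits*: birth–death trees conditioned on tip count (via
  `ape::rphylo`) with CTMC traits simulated along branches; and forward
  Gillespie state-dependent birth–death simulation, pruned of extinct
  lineages, retried (bounded) on all-extinct realisations.

What the generator does *not* emulate: real geography (no range
cohesion, no spatial autocorrelation in occupancy beyond the covariate
gradient), phylogenetic signal in range placement, correlated
multi-colour descriptions, or observation error in traits. Passing tests
therefore demonstrate correctness of the machinery and calibration of
the procedures under the stated generative assumptions — not that real
data meet those assumptions.

## Problem sizes and seeds

The suite runs at: 100 random path models (n = 200) for the OLS oracle;
200 independent landscapes × 200 permutations for type-I calibration
(200 units each); 50 replicates of 400 units for effect recovery; 500
random ≤6-tip trees for the Mk enumeration oracle; 2000 stochastic maps
for marginal consistency; 20 random trees for the MuSSE identity and 20
simulated 150-tip trees for rate recovery; 30 replicates of a 20×20 grid
for SAR recovery. Every stochastic step takes an explicit seed, and
generators restore the caller's RNG state. These sizes are the package's
chosen study conditions; the acceptance script re-runs the same
computations from a single command-line seed.

## Known limitations

* Latent variables, mean structures, multi-group SEM, missing-data FIML
  and robust corrections are out of scope; the SEM engine is for
  complete observed-variable recursive systems.
* The SAR stage applies to single-equation response models, not to the
  full path system.
* Mk/MuSSE machinery assumes binary, rooted trees with branch lengths in
  time units; MuSSE additionally assumes ultrametry and (by default)
  complete sampling, with a per-state sampling fraction available.
* State-dependent diversification model *selection* is underpowered at
  ~150 tips (see above); treat AIC preference on small trees as
  suggestive only.
* Hidden-state models, fossil tips and divergence-time estimation are
  not provided.
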