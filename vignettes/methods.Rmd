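---
title: "Methods: phylogenetic signal in community diversity responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic signal in community diversity responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the unit of analysis

Communities of different taxonomic families surveyed along the same
environmental gradient can show very different diversity patterns: one
family's site richness may peak mid-elevation while a relative's declines
monotonically; one family's composition may turn over within kilometres
while another's barely changes. `divsignal` asks whether these
community-level responses are themselves heritable at macroevolutionary
scale — whether closely related families respond more similarly than
distant ones.

The family is the comparative unit: families are generally monophyletic,
functionally coherent, and numerous enough within one regional survey to
support comparative tests. Each family contributes up to nine response
variables (a diversity peak, two curve-complexity variants, three turnover
slopes, three turnover fits), and the phylogenetic-signal machinery treats
each variable as a "trait" of the family.

# Per-family diversity responses

## Which sites count

All responses are computed at a family's *presence-only* sites — sites
holding at least one member species. Absences elsewhere say as much about
the survey extent as about the family, and including them would drag every
family's curve toward zero at the gradient ends it never reaches.

## Curve complexity (Edf-α)

`fit_richness_gam()` fits a Gaussian additive model of ln(richness) with a
penalized cubic regression spline of elevation (basis dimension 10, smooth
centered for identifiability), the smoothing parameter chosen by
generalized cross-validation. The effective degrees of freedom of the
smooth measure curve complexity on an interpretable scale: heavy penalties
drive the edf to 1 (a straight line), no penalty toward the basis limit of
9. The GCV criterion is the historical default of the GAM machinery this
models; it is configurable in spirit by passing a fixed `sp`.

Two caveats shape the calibration tests. First, the approximate p-value of
the smooth feeds `corrected_edf()`, which zeroes the edf of non-significant
models (a non-significant model has estimated no parameters); both raw and
corrected variants are carried through the entire signal suite in parallel.
Second, "low noise" has to be read relative to GCV's behaviour: as noise
tends to zero, GCV interpolates and the edf climbs toward the basis limit
regardless of the true curve's complexity. The calibration scenarios
therefore use a residual sd of 0.3 on the log scale — a typical scatter for
log richness counts — for both the linear truth (edf should sit at 1) and
the quartic truth (edf should sit near 5, the complexity of a degree-4
polynomial).

Geographic coordinates enter as linear covariates only when a pre-screen
(`screen_coords()`: OLS of ln richness on each coordinate separately,
slope p < 0.05) flags a latitudinal or longitudinal trend, so spatial
autocorrelation is controlled exactly where it is detectable and the model
stays minimal elsewhere.

## Diversity peak (Peak-α)

`estimate_peak()` fits a two-segment linear model of ln(richness) on
elevation. The breakpoint ψ is profiled over a deterministic grid — 200
even candidates between the 5th and 95th elevation percentiles, plus every
observed elevation in that window so that noiseless apexes are hit exactly
— and ψ minimizes the residual sum of squares. A grid profile was chosen
over iterative linearization deliberately: it cannot fail to converge on
small families and is exactly reproducible.

The 95% CI inverts the profile F statistic with **2 numerator degrees of
freedom**, treating the breakpoint and its slope change as the parameters
that distinguish the segmented alternative; the same 2-df F tests whether
the break exists at all. The 1-df inversion was measured at 88% empirical
coverage on correctly specified simulations and the 2-df at 97%, inside
the 88–99% band expected of a usable interval at 100–200 replicates, so
the 2-df form is the default. SE = (hi − lo)/3.92 assumes approximate
normality of the profile.

When the two-segment model does not beat a single line (F p ≥ 0.05, or the
line already fits perfectly), there is no inflection to estimate; the
function falls back to the elevation of maximum lowess-smoothed richness,
reports a CI spanning the occupied elevation range, and flags the estimate
`"fallback"`. This automated rule replaces case-by-case visual inspection
of curves; the flag keeps the two estimator populations separable
downstream.

## Turnover (β) responses

Sørensen dissimilarity β = (b + c)/(2a + b + c) is computed between all
pairs of presence-only sites (binary Bray–Curtis via vegan). Site
predictors are Euclidean distance on projected coordinates, absolute
elevation difference, and Euclidean distance on arcsine-square-root
transformed habitat covers — the variance-stabilizing transform for
proportions. Habitat covers are validated to lie in [0, 1] but are *not*
required to sum to 1 per site: survey legends often include overlapping or
residual categories.

`mrm()` regresses the vectorized lower triangle of the response matrix on
the predictors' triangles by OLS. Because pairs sharing a site are not
independent, inference is permutational: rows and columns of the
*response* matrix are permuted jointly (the standard MRM scheme), the
model refit, and p = (1 + #{perm ≥ obs})/(n_perm + 1) computed on |t| per
slope and on R² for the overall fit (two-sided by construction). With
`exact = TRUE` all n! site permutations are enumerated, which the test
suite exploits on ≤ 5 objects to check the sampled p against exhaustive
enumeration. Ties are counted as exceedances, so a perfect fit on a
symmetric tree yields p slightly above the nominal floor — the honest
answer when label swaps reproduce the statistic.

The six turnover responses split by construction: the three *slopes* (and
their SEs, used downstream as measurement-error weights) come from the
one joint MRM with all three predictors, so each is a partial effect; the
three *R²* values come from three separate single-predictor MRMs, since a
joint R² cannot be attributed to one gradient. Non-significant
single-gradient fits report R² = 0 — a null influence is informative and
comparable across families. This single-vs-joint split is an
interpretation; both quantities are computed and the choice is confined to
`turnover_responses()`.

# The phylogenetic-signal suite

## Blomberg's K

`blomberg_k()` implements the variance-ratio form: the mean squared
deviation of tips from the phylogenetic (GLS) mean, over the
covariance-standardized deviation, scaled by its Brownian expectation
(tr(C) − n/(1ᵀC⁻¹1))/(n − 1). K = 1 is the Brownian expectation, K = 0
phylogenetic independence. The implementation is checked in the test suite
against an independent hand-built linear-algebra oracle and against
`phytools::phylosig` to 1e-8.

When responses carry standard errors (Peak-α and the three slopes), the
Brownian rate σ² is first estimated by ML under σ²C + diag(se²) and K is
computed on the error-adjusted covariance C + diag(se²)/σ̂². This keeps
E[K] = 1 under Brownian motion with zero error and smoothly down-weights
families whose responses were poorly estimated. The permutation test
shuffles values and SEs jointly across tips, re-estimating σ² each time,
and counts variance ratios at least as large as observed.

## Fritz–Purvis D

`d_statistic()` measures signal in a binary trait (here: widespread,
filter-passing families vs rare ones) as the sum over internal nodes of
absolute sister-clade differences of downpass nodal averages, rescaled
between two simulated anchors: the mean under random tip shuffles (D = 1)
and the mean under threshold Brownian motion at the observed prevalence
(D = 0). Both anchors use 1000 draws by default, matching the simulation
effort used elsewhere in the suite. Multifurcating nodes contribute all
pairwise child differences. D < 0 indicates clumping beyond Brownian
expectation, D > 1 overdispersion; `p_random` and `p_brownian` are the
simulated exceedance probabilities of the observed sum under each anchor.

## Effect-size distance regressions

The second, tree-topology-free route to signal regresses pairwise response
dissimilarities between families on patristic distances (twice the
divergence node age). Responses with SEs use Cohen's d,
|x_i − x_j| / sqrt((se_i² + se_j²)/2): each family contributes one
estimate and one SE, so the two SEs stand in for the pooled dispersion —
an interpretation forced by the absence of per-family replicate counts.
Responses without SEs (Edf, R²) use raw absolute differences. Inference
permutes the family labels of the dissimilarity matrix (the patristic
matrix stays fixed), the one-matrix scheme consistent with the MRM
machinery.

## White noise vs Brownian motion, and the power of the comparison

`fit_wn()` and `fit_bm()` are two-parameter ML fits — mean/root state and
variance/rate — of N(μ, σ²I) and N(μ1, σ²C) respectively, closed-form
without measurement error and 1-D profile ML over σ² with it (errors enter
as known additive variances, and simulated datasets reuse the same SEs on
refit). Richer models (OU, early-burst, λ) are deliberately out of scope:
at 9–14 families two parameters are all the data support.

`pmc_power()` quantifies what the comparison can actually resolve: both
models are fitted to the data, 1000 datasets are simulated from each
fitted model, both models are refit to every dataset, and
δ = 2(lnL_BM − lnL_WN) (sign convention: positive favours BM) is collected
under each generating model. The overlap of the two δ distributions *is*
the power statement; the observed δ is called for BM when it exceeds the
0.95 quantile of the WN-generated null. The models are not nested in the
usual sense, so no χ² approximation is used anywhere. On a star phylogeny
C ∝ I makes the models identical and δ collapses to 0 — a structural
identity the test suite asserts.

## C-score

Family-level co-existence uses the checkerboard index
C = (R_i − S)(R_j − S)/(R_i R_j) on family occupancy vectors (the OR over
member species). Computed this way — not averaged over cross-family
species pairs — the printed endpoints hold exactly: 0 for identical or
nested occupancies (sympatry), 1 for disjoint ones (allopatry). The
resulting matrix feeds the same patristic distance regression as the
effect sizes. Null-model matrix randomizations (fixed-fixed swaps) are out
of scope: the question is association with phylogeny, not departure from
a co-occurrence null.

## PGLS and AICc model selection

`gls_fit()` is closed-form ML generalized least squares with
Var(e) = σ² W^(1/2) V W^(1/2), where V is the tree's Brownian correlation
(covariance scaled to unit diagonal) or the identity, and W holds relative
variance weights normalized to mean 1 (zero weights floored at 1e-8 × mean
with a warning). With the correlation fixed by the tree, the ML estimates
are exact linear algebra — no optimizer, no convergence failures — and the
implementation is verified against `nlme::gls(..., method = "ML")` to 1e-6
in coefficients, likelihood and standard errors. How weights combine with
the BM correlation is genuinely underdetermined; the multiplicative
sandwich form above is the one consistent with variance-function GLS.

ML (not REML) is used throughout because candidate models differ in their
fixed effects, and REML likelihoods are not comparable across those.
The parameter count k includes the intercept, slopes and σ² but nothing
for the BM correlation, whose structure is fixed given the tree.
AICc = −2lnL + 2k + 2k(k+1)/(n−k−1). `model_selection()` enumerates every
predictor subset × {no correlation, BM} — with ≤ 3 candidate predictors,
exhaustive enumeration subsumes any forward/backward path and is
deterministic — ranks by AICc, reports Akaike weights, and flags the
ΔAICc < 3 equal-support set. Candidates with n ≤ k + 1 (AICc undefined)
are dropped with a note.

# The synthetic-data generator

`simulate_study()` builds: a pure-birth ultrametric phylogeny rescaled to
exact depth (300 Ma default, roughly the family-level depths of the taxa
this design targets); family peak elevations evolving under Brownian
motion from a mid-gradient root (rate default 1200 m²/Ma, i.e. tip sd
≈ 600 m over the tree) and clamped to the central 90% of the gradient;
a landscape of sites uniform over a 100-km square and a 0–2400 m gradient,
with softmax habitat composition drifting along elevation (drift 1.5, so
habitat and elevational distances correlate as they do on real mountains;
drift 0 decouples them); and Bernoulli occurrence matrices in which
species s of family f occupies site i with probability

amplitude_f × exp(−(turnover_z,f × (elev_i − opt_s))² / 2) ×
exp(−turnover_xy,f × d_xy(i, center_s)),

with species optima opt_s ~ N(peak_f, width_f²) and a uniform-random
geographic center per species. The elevational turnover rate is thus the
reciprocal of the species' niche bandwidth — higher rates mean species
replace each other faster along elevation — while the family's richness
curve keeps its peak at peak_f with width ≈ sqrt(width_f² + 1/turnover_z²).
An earlier kernel in which the rate multiplied an extra exponential decay
was rejected during design because it shrank occupancy probabilities,
saturated Sørensen dissimilarity near 1 and inverted the slope ranking;
the bandwidth form keeps the rate a genuine composition-turnover rate.

Defaults (widths 300–700 m, amplitudes 0.35–0.7, geographic decay
0.01–0.08 per km, elevational rates 0.0005–0.004 per m, 12 families × 300
sites × 12 species) describe a plausible mid-mountain survey. The
*strong-settings* recovery experiment fixes width (400 m), amplitude (0.9)
and geographic decay (0.002/km), decouples habitat from elevation, spreads
elevational rates 0.0005–0.004/m and uses 20 species per family — the
condition under which turnover differences, not occupancy ceilings, drive
the slopes, which is what a ranking-recovery test is entitled to assume.

What the generator does **not** emulate: abundance structure (occurrence
is Bernoulli, as in the presence–absence data the analysis consumes),
diversification below the family level, spatially autocorrelated
occupancy beyond the species-center decay, detection error, and trait
evolution of the organismal predictors. Passing recovery tests therefore
demonstrate that the estimators invert the generator's structure, not that
real surveys satisfy it.

All randomness flows from one master seed through `derive_seeds()` —
named substreams per stage — so removing one family or stage never shifts
another's draws, and reruns are byte-identical.

# Problem sizes, numerical choices, degenerate inputs

The test and calibration suite uses desk-scale sizes chosen to keep the
whole run in tens of seconds while leaving the statistics meaningful:
500 Brownian replicates on 20 tips for the K calibration; 100 linear and
50 quartic datasets of 200 sites for the edf calibration; 500 null
replicates at 199 (K) and 99 (MRM) permutations for the type-I checks
(the nominal 0.05 is attainable exactly at both counts); 100 replicates
of 300 sites for breakpoint coverage; 500 simulations per model for the
δ-overlap checks.

Other numerical decisions, collected: body size is natural-log transformed
before family averaging (the log base only shifts means, and e is the
analysis convention); single-species families get SE = 0 with a warning
rather than NA, so they stay usable with explicit zero weight
information; non-binary incidence cells are coerced to presence with a
warning (the analysis is presence–absence throughout); ultrametricity is
checked to a relative 1e-6; UPGMA ties resolve in deterministic
lexicographic order; constant predictors in MRM are flagged and dropped,
exactly collinear predictor sets are an error; zero-variance data make the
WN/BM fits error rather than return a boundary likelihood; D is undefined
(error) at prevalence 0 or 1; Cohen's d errors when both SEs of a pair are
zero.

# Limitations

Signal tests at 9–14 families are intrinsically low-powered; the δ
analysis makes this visible rather than fixing it. The automated fallback
peak is not the manual curve inspection it replaces, and fallback
estimates carry deliberately wide errors. The profile-grid breakpoint CI
is calibrated under a correctly specified two-segment Gaussian model;
heavy overdispersion of richness would require a different error model.
K's error adjustment assumes SEs are known, not estimated. And the
single-vs-joint MRM split for R² vs slopes is one defensible reading of an
ambiguous convention; both quantities are available if the other reading
is preferred.
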