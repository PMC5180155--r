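---
title: "Models and methods: chemical defence and extinction risk on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: chemical defence and extinction risk on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defrisk)
```

# The scientific problem

Chemically defended amphibians have been associated with elevated
macroevolutionary extinction rates, which raises the question of whether the
same trait also predicts *contemporary* extinction risk as measured by IUCN
Red List categories. defrisk implements the statistical machinery for that
question on any (tree, trait table) pair: regression-style models that treat
Red List status as a response with phylogenetically structured residuals,
explicitly evolutionary models that treat defence and threat as jointly
evolving binary characters, a descriptive contrast of terminal branch ages,
and forward birth–death simulations of lineage fates.

Species are never independent data points: close relatives share most of
their history. Every model here therefore carries the phylogeny, either
through the Brownian shared-path-length matrix $C$ ($C_{ij}$ = Myr of path
shared from the root to the MRCA of tips $i$ and $j$) or by evolving the
traits along the branches.

# Data coding

IUCN categories are coded two ways. The binary *threat* code groups LC and
NT as non-threatened (0) and VU, EN, CR, EW, EX as threatened (1); the
ordinal *status* code is 0 = LC, 1 = NT, 2 = VU, 3 = EN, 4 = CR, 5 = EW/EX,
so `threat == (status >= 2)` always holds and is asserted on every built
dataset. DD (data deficient) and NE (not evaluated) species carry no usable
response and are excluded; `build_dataset()` reports how many species were
dropped for each reason (not on the tree, unknown defence state, uncodable
category) so dataset attrition is fully auditable. Tip labels are matched
exactly and case-sensitively after converting spaces to underscores, the
dominant Newick convention; unmatched labels are only reported, never
guessed — taxonomy reconciliation is out of scope.

# Regression family

## Phylogenetic logistic regression

For binary threat $y_i$ with linear predictor $\eta_i = x_i^\top \beta$ and
$p_i = \mathrm{logit}^{-1}(\eta_i)$, coefficients solve the generalized
estimating equations
$X^\top \Delta V^{-1} (y - p) = 0$, with $\Delta = \mathrm{diag}(p_i(1-p_i))$
and working covariance $V = A^{1/2} R(s) A^{1/2}$,
$A = \mathrm{diag}(p_i(1-p_i))$. The working correlation is an attenuated
Brownian correlation

$$R(s) = I + s\,(C^{*} - I), \qquad s = e^{-\alpha} \in [0, 1],$$

where $C^{*}$ is $C$ normalized to unit diagonal. The signal parameter is
profiled: for each candidate $s$ on a log-spaced $\alpha$ grid (plus $s = 0$)
the GEE is solved and the Gaussian pseudo-log-likelihood of the Pearson
residuals, $-\tfrac12(\log|R| + n\log(r^\top R^{-1} r / n) + \text{const})$,
is evaluated; the best grid cell is refined by golden-section search. This
follows the single-signal-parameter spirit of the Ives–Garland estimating
equation method. We deliberately use the attenuation form rather than a
patristic-distance decay $e^{-\alpha d_{ij}}$: on a star tree $C^{*} = I$,
so the fit reduces *exactly* to ordinary logistic regression for every $s$
— the independence limit the test suite anchors on — whereas a distance
decay retains spurious correlation at finite depths. Standard errors are
naive model-based, $(\hat\beta) \sim (X^\top \Delta V^{-1} \Delta X)^{-1}$,
with two-sided normal p-values, the convention of this model family.

Complete separation (a predictor perfectly splitting the response) is
detected before fitting and raised as an error rather than returning a
divergent estimate.

`threat_probability_contrast()` back-transforms the fit:
$\hat p_0 = \mathrm{logit}^{-1}(\hat\beta_0)$,
$\hat p_1 = \mathrm{logit}^{-1}(\hat\beta_0 + \hat\beta_1)$, one-standard-
error bands on the linear-predictor scale mapped through the inverse logit,
and the relative increase $\hat p_1/\hat p_0 - 1$.

## Phylogenetic Poisson GEE

Ordinal status treated as a count: log link, Poisson variance, working
correlation fixed at $C^{*}$ (or the identity, which reproduces the ordinary
Poisson GLM to optimizer precision), Pearson-estimated dispersion. This is
the classical phylogenetic GEE construction; it is deliberately simpler than
the ordinal model below and is kept because the two bracket the status
response from opposite sides.

## Phylogenetic vs non-phylogenetic fits

`compare_phylo_vs_plain()` fits both variants and compares a pseudo-AIC,
$-2\,\text{pseudo-loglik} + 2k$, charging the phylogenetic variant one extra
parameter for the signal. AIC is this package's choice of criterion; nothing
deeper than "penalized fit" is claimed for it. Calibration is checked by
simulation in the test suite (plain wins on star-tree data; phylogenetic
wins under strong planted clustering).

# Ordinal threshold model

Status is modelled as a latent liability
$\ell = \beta_0 + \beta_1 d + u + e$ crossing ordered thresholds, with
$u \sim N(0, \sigma^2_{\text{phy}} C)$ and $e \sim N(0, 1)$. Identifiability
fixes the residual variance at 1 (probit scale) and the first threshold at
0; an intercept is estimated. The Gibbs sampler uses Albert–Chib updates:
truncated-normal liabilities, conjugate normal fixed effects (prior
$N(0, 10^8)$), the phylogenetic effect sampled in the eigenbasis of $C$
(where its full conditional is diagonal), $\sigma^2_{\text{phy}}$ from an
inverse-gamma full conditional (prior IG(0.01, 0.01)), and uniform
full-conditional draws for the free thresholds, which carry a bounded
uniform prior on $[0, 100]$ so that empty top categories stay proper.
Parameter expansion is not implemented; with near-zero variance the
$\sigma^2$ chain mixes slowly, which is flagged as a limitation rather than
hidden. With two categories the model is exactly a phylogenetic probit, and
the sampler is checked against the ML probit fit; threshold order is
asserted at every stored sample.

The reporting convention is posterior mean, equal-tailed 95% credible
interval, and pMCMC $= 2\min(P(\beta > 0), P(\beta < 0))$ floored at one
over the stored sample count. Default chain settings (1.1M iterations, 100k
burn-in, thinning 1000) mirror long-run practice for this model family;
tests and the acceptance script use desk-scale chains (thousands of
iterations on trees of 60–400 tips), which the coverage study shows are
adequate at those sizes.

# Evolutionary pathway models

Joint (defence, threat) evolution is a 4-state continuous-time Markov chain
on states $(d, t) \in \{00, 01, 10, 11\}$, indexed $2d + t$. Dual
transitions (both traits flipping at once) are structurally zero, leaving 8
permitted rates $q_{ij}$. Three model classes are fitted by maximum
likelihood:

* **independent** (4 free rates): each trait's gain and loss rate is the
  same regardless of the other trait's state;
* **dependent** (8 free rates): all permitted rates free;
* **constrained directional** (7 free rates): the dependent model with one
  constraint on the threat-gain rates.

The likelihood is Felsenstein's pruning algorithm with per-branch
$P(t) = e^{Qt}$, implemented in C++. Each likelihood evaluation
eigendecomposes the 4×4 generator once and reuses it across branches, with a
scaling-and-squaring (`arma::expmat`) fallback whenever the eigenvector
matrix fails a reconstruction check (near-defective generators); per-edge
partial likelihoods are rescaled to avoid underflow, so trees of hundreds of
tips are safe. Root state frequencies default to ¼ each (configurable to the
stationary distribution of the fitted generator); the equal-frequency
default is the common convention in this model family. Optimization is
multi-start L-BFGS-B on log rates bounded in $[10^{-8}, 100]$ per Myr,
starting from a parsimony-informed heuristic (changes per total tree length)
plus lognormal jitter; these surfaces are multi-modal, and the nested
model's MLE always seeds one start of the more general model so LRT
statistics are non-negative by construction.

**Pagel's correlation test** is the LRT of dependent vs independent,
$2\Delta\log L \sim \chi^2_4$. **The directional test** is the LRT of
dependent vs constrained-directional on 1 d.f. The default constraint is the
equality $q_{(0,0)\to(0,1)} = q_{(1,0)\to(1,1)}$ — threat gain does not
depend on defence state. This is the single-constraint, 1-d.f. construction
consistent with the parameter counts of the model family; rejecting it says
the threat-gain rate differs by defence state, and the test output therefore
always reports the fitted ordering of the two rates, interpreting rejection
as "defence first, then threat" only when $q_{(1,0)\to(1,1)} >
q_{(0,0)\to(0,1)}$. An alternative reading — forbidding threat gain before
defence, $q_{(0,0)\to(0,1)} = 0$ — is available via `constraint = "zero"`;
the report states which constraint was used and never conflates the two.
P-values use the central $\chi^2$ with no boundary correction, matching
standard practice; for the zero-rate variant this is a documented caveat
(the constraint sits on the parameter boundary).

`count_origins()` gives Sankoff-parsimony minimum change counts per trait,
used as an adequacy check: these tests need multiple independent origins of
each trait on the tree.

**Calibration regime.** The $\chi^2$ reference for these LRTs is asymptotic
in the amount of evolutionary information, not in the number of tips. Our
null simulations show the test holds its 5% size on 200-tip trees when every
rate class is informed by tens of expected transitions and tips have not
reached stationarity (null gain/loss rates 0.06/Myr for threat and 0.04/Myr
for defence on trees of ~50 Myr depth: mean null LR 4.5 on 4 d.f.,
rejection rate 0.05). Outside that window the test is *anticonservative*:
with sparser transitions (rates around 0.03/0.02) rejection rises to ~0.10,
and in the saturating regime (rates ≥ 0.1/Myr, tips near stationarity, so
the likelihood flattens in the rate magnitudes) to ~0.15. Users applying the
test to traits with very few origins, or to fast-evolving traits on deep
trees, should prefer a simulation-based null (the package's generators make
a parametric bootstrap straightforward) over the $\chi^2$ p-value.

# Terminal branch ages

Pendant edge lengths are binned in half-open 5-Myr bins $[5k, 5k+5)$ —
half-open so edge-boundary ages are assigned unambiguously — with per-group
densities (each group integrates to 1; a shared normalization is not used).
The young-tip excess is the difference in the proportion of tips younger
than 15 Myr (defended minus undefended). Because the histogram contrast is
descriptive, the package adds a label-permutation test of the excess
statistic (two-sided, +1-corrected); the output labels it as a package
addition. No correction is attempted for uneven sampling fractions across
clades, a known limitation of terminal-branch-age arguments.

# Birth–death fates

Starting from a single extant species, a Gillespie simulation evolves
lineage counts under constant $\lambda$ (birth) and $\mu$ (death); a
replicate is extinct at horizon $t$ if no lineage survives. The closed form

$$P_{\text{ext}}(t) = \frac{\mu(e^{rt} - 1)}{\lambda e^{rt} - \mu},
  \quad r = \lambda - \mu$$

(with $\mu t/(1+\mu t)$ when $\lambda = \mu$ and $1 - e^{-\mu t}$ when
$\lambda = 0$; computed in an overflow-safe rearrangement for $r > 0$) is
the module's oracle, checked on a $(\lambda, \mu, t)$ grid at 1000
replicates. Default horizons are 5–100 Myr in 5-Myr steps with 1000
replicates per horizon. Two modes exist because "run the simulations at each
time point" is ambiguous: independent replicate sets per horizon (the
default, the literal per-time-point reading) and one cohort tracked through
all horizons (exactly monotone); both estimate the same curve.
`compare_groups()` forms the per-horizon defended/undefended ratio with
delta-method standard errors and reports the horizon from which the ratio's
changes stay below a tolerance (default 0.05). The group rates are inputs:
published group-specific diversification estimates belong to their own
analyses and are deliberately not baked in as defaults.

# Synthetic data: what it does and does not emulate

The generators produce every input the pipeline consumes, with one
independent random stream per operation (the master seed is hashed with an
operation tag, so adding a stage never shifts another stage's draws):

* `simulate_tree()`: birth–death trees conditioned on tip count (via
  coalescent-style sampling) or run forward for a fixed age by a recursive
  single-lineage simulation in which whole-clade extinction is a reportable
  outcome, not an error.
* `simulate_joint_traits()`: exact event-driven CTMC simulation (competing
  exponentials per branch — no time discretization, exact at any rate
  magnitude), optionally recording realized transition counts and per-state
  occupancy times, which the parameter-recovery study uses to decide which
  rates were informed by enough expected events.
* `simulate_ordinal_status()`: the generative counterpart of the threshold
  model; `simulate_brownian_covariate()`: tip values $\sim N(\text{root},
  \text{rate}\cdot C)$.
* `simulate_study()` assembles a full trait table: defence evolves as a
  2-state Markov chain (gain 0.01/Myr, loss 0.005/Myr), status comes from
  the liability model (defence effect 1, phylogenetic variance 0.5, residual
  1, thresholds 0.8–4.0), and categories are the inverse of the status
  coding. Defaults: 400 tips, birth 0.1/Myr, death 0.03/Myr — rate
  magnitudes chosen once as realistic for amphibian-scale supertrees
  (tree depths of tens of Myr, a handful to dozens of trait origins).

What this synthetic world does *not* emulate: real taxonomic sampling bias,
Red List assessment error, correlated covariates, or the specific rate
estimates of any published dataset. Passing tests therefore demonstrate that
the estimators are correct and calibrated under their own assumptions, not
that any particular empirical conclusion is reproduced; empirical headline
numbers require the original deposited data and tree, which are external
downloads.

# Numerical choices and degenerate inputs

* Rate bounds $[10^{-8}, 100]$/Myr during optimization; optimizer tolerance
  `factr = 1e7` (about $10^{-9}$ relative) with a polishing second run.
* LRT statistics are clamped at 0; a restricted model out-fitting the
  general one by more than $10^{-4}$ log-units triggers a warning and, in
  the directional test, an automatic re-fit of the general model seeded from
  the constrained MLE.
* Working correlations get a $10^{-10}$ diagonal ridge; a singular
  correlation is ridge-regularized with a warning.
* Zero-length pendant edges are accepted but flagged in the validation
  report (they distort tip-age histograms); polytomies are accepted
  everywhere (the pruning code iterates over children, and parsimony uses
  Sankoff).
* Trees of one tip are legal throughout the likelihood machinery (the
  likelihood reduces to the root frequency of the observed state).
* Truncated-normal draws clamp liabilities to $\pm 38$ to avoid infinite
  quantiles in extreme tails.

# Problem sizes

The test suite and acceptance script run entirely on synthetic data at desk
scale, chosen to keep the full suite in the tens of minutes on one core
while leaving the Monte-Carlo checks well powered: oracle checks on 2–50-tip
trees (1000 two-tip draws at $10^{-10}$), type-I calibration of Pagel's test
on 100 null datasets of 200 tips, parameter recovery on 50 datasets of 500
tips, ordinal coverage on 50 datasets of 60 tips, pattern-frequency
validation at $10^5$ simulations, and the birth–death grid at 1000
replicates per cell. The pipeline defaults (400-tip studies, 1000 fate
replicates) match the scale typical of amphibian supertree analyses.

# Known limitations

* The pathway LRTs rely on the $\chi^2$ reference and are anticonservative
  when transition counts are sparse or saturated (see the calibration notes
  above).
* In the ordinal model, when the realized phylogenetic liability variance
  dwarfs the residual (clade-constant categories), $\sigma^2_{\text{phy}}$
  becomes nearly unidentified and the defence effect inflates with it —
  credible intervals widen accordingly. This is a property of threshold
  models with free variance on the probit scale, and it is the regime in
  which ordinal analyses of Red List status report extreme coefficients with
  very wide intervals.
* The logistic signal estimate can stick to the $s = 0$ boundary in small
  samples with weak signal; the comparison function reports ties to the
  plain model honestly rather than forcing a winner.
* The ordinal model's $\sigma^2_{\text{phy}}$ prior is weakly informative
  but not parameter-expanded; posteriors near zero variance mix slowly.
* With a five/six-category response and estimated thresholds the ordinal
  defence effect is weakly identified on small trees — wide credible
  intervals there are a property of the model, not a sampler failure.
* Directional inference from pathway models assumes Red List status can be
  treated as an evolving Markov character; the package surfaces the fitted
  rate ordering alongside the LRT so users can judge the strength of that
  assumption for their data.
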