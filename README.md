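# defrisk

Phylogenetic comparative analyses linking a binary chemical antipredator
defence to contemporary extinction risk, built for amphibian-style datasets:
a time-calibrated phylogeny (branch lengths in Myr) joined to a species table
of chemical-defence states and IUCN Red List categories. The package is aimed
at evolutionary ecologists who want to test whether a defence trait predicts
Red List status, whether the two traits coevolve, and what constant-rate
birth–death dynamics imply for the future of each trait group.

## What it computes

Extinction risk is coded two ways from the IUCN category: a binary **threat**
variable (LC, NT → 0; VU, EN, CR, EW, EX → 1) and an ordinal **status**
(0 = LC, 1 = NT, 2 = VU, 3 = EN, 4 = CR, 5 = EW/EX). DD and NE species are
excluded, with per-reason attrition counts reported. Around that coding the
package provides:

- **Phylogenetic logistic regression** (Ives–Garland model family) of threat
  on defence: the working correlation is an attenuated Brownian correlation
  R(α) = I + e^{−α}(C* − I), with C* the shared-path-length matrix scaled to
  unit diagonal and the signal α profiled on a log grid; β is estimated by
  generalized estimating equations. Back-transformed threat probabilities
  per defence group and the relative increase p̂₁/p̂₀ − 1 come from
  `threat_probability_contrast()`.
- **Phylogenetic Poisson GEE** of ordinal status (log link, working
  correlation C*), plus a phylogenetic-vs-ordinary model comparison by a
  pseudo-likelihood AIC.
- **Bayesian ordinal threshold model**: status arises from a latent liability
  β·defence + u + e with phylogenetic random effect u ~ N(0, σ²_phylo C),
  residual variance fixed at 1 and first threshold at 0; a Gibbs sampler
  returns the posterior of β with equal-tailed 95% CI and pMCMC.
- **Evolutionary pathway models**: 4-state Markov models of joint
  (defence, threat) evolution with states (00, 01, 10, 11) and no dual
  transitions. Pagel's correlation test compares the 8-rate dependent model
  against the 4-rate independent model (LRT, 4 d.f.); the directional test
  compares the dependent model against a 7-rate model with the single
  constraint q₍₀₀→₀₁₎ = q₍₁₀→₁₁₎ (1 d.f.), and reports the fitted ordering
  of the two threat-gain rates. Likelihoods use Felsenstein pruning with
  per-branch matrix exponentials (C++ backend; polytomies supported).
- **Terminal-branch-age contrast**: per-group density histograms of pendant
  edge lengths in 5-Myr bins and a young-tip excess statistic (difference in
  the proportion of tips younger than 15 Myr), with a label-permutation test.
- **Birth–death fate simulations**: Gillespie simulations of whole-lineage
  extinction from a single species, per defence group, with the closed-form
  oracle P(extinct by t) = μ(e^{rt}−1)/(λe^{rt}−μ), r = λ−μ.
- **Synthetic-data generators** for every input: birth–death trees, joint
  trait evolution under any 4-state generator, ordinal statuses from a
  phylogenetic liability, and Brownian covariates — so the full pipeline is
  testable with no external downloads.

## Worked example

```r
library(defrisk)

study <- simulate_study(study_config(n_tips = 250, beta_defence = 2, seed = 5))
ds <- build_dataset(study$traits, study$tree)
tt <- ds$traits

fit <- phylo_logistic(ds$tree,
                      setNames(tt$threat, tt$species),
                      data.frame(species = tt$species,
                                 defence = tt$chemical_defence))
print(fit)
#> Phylogenetic binomial regression (n = 250 )
#>                beta     se       z      p
#> (Intercept) -1.2502 0.7824 -1.5979 0.1101
#> defence      1.0419 0.3527  2.9539 0.0031
#> signal s = 0.7553 (alpha = 0.2806)

threat_probability_contrast(fit)$relative_increase
#> [1] 1.012549
```

The defence coefficient (here β = 1.04, p = 0.003) is the log-odds increase
in being threatened for chemically defended species; the contrast says
defended species are ~101% more likely to be threatened in this synthetic
draw, which planted a strong positive defence effect (liability β = 2). The
joint-evolution side of the analysis runs the same way:

```r
states <- setNames(joint_state_index(tt$chemical_defence, tt$threat),
                   tt$species)
pagel_correlation_test(ds$tree, states, n_starts = 5, seed = 1)
#> Likelihood ratio = 13.9113, d.f. = 4, p = 0.007583
directional_test(ds$tree, states, n_starts = 5, seed = 1)
```

`run_pipeline(pipeline_config(tree, traits, ...))` executes all stages from
one config and writes `report.json` / `report.txt`;
`inst/scripts/defrisk.R` is a thin command-line wrapper around it.

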