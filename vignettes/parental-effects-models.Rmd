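---
title: "Estimating vertical transmission and genetic nurture from transmitted and nontransmitted polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating vertical transmission and genetic nurture from transmitted and nontransmitted polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsnurture)
library(dplyr)
```

## The problem

Parents transmit half of their autosomal additive genetic effects to each
child, but they also shape the child's rearing environment. When the parental
traits that shape that environment are themselves heritable, the genes a
child inherits become correlated with the environment it is raised in. This
passive gene–environment covariance is called *genetic nurture*, and it is a
necessary consequence of *vertical transmission* (VT) — a direct causal
effect of a parental phenotype on the offspring phenotype.

Trio genotype data separate these signals. For each parent the polygenic
score (PGS) can be split into the haplotype transmitted to the offspring
(`T_p`, `T_m`) and the haplotype not transmitted (`NT_p`, `NT_m`). A
nontransmitted score can influence the offspring only through the
environment the parent provides, so the covariance between offspring
phenotype and the nontransmitted scores is a fingerprint of genetic nurture.
This package implements a structural-equation framework built on that idea:
path-traced equilibrium expectations, full-information maximum likelihood
(FIML) estimation, moment-based tests of assortative-mating mechanisms, and
a forward-time variant-level simulator that serves as the framework's oracle.

## The models

All three models are zero-mean covariance-structure models for the observed
family vector. Throughout, `delta` is the effect of one haplotypic PGS on
the phenotype, `f` the VT path from each parental phenotype to the offspring
familial environment `F_o = f Y_p + f Y_m`, `V_eps` the residual variance,
and `k` the base-population variance of a haplotypic PGS (a scaling
constant, not a parameter — see below).

**Model 0 (VT, no assortative mating).** Five observed variables
(`T_p, NT_p, T_m, NT_m, Y_o`). Writing `Omega = cov(Y_*, [N]T_*)` for the
covariance between a parent's phenotype and either of that parent's
haplotypic scores, the equilibrium expectations are mutually recursive:

- `Omega = (delta + w) / 2`, where `w = 2 f Omega` is genetic nurture (the
  covariance between the full PGS and `F`);
- `theta_NT = cov(Y_o, NT_p + NT_m) = 2 f Omega` — genetic nurture read off
  directly;
- `theta_T = delta + 2 f Omega`, so `theta_T - theta_NT = delta` is the
  direct PGS effect purged of nurture;
- `V_F = 2 f^2 V_Y` and `V_Y = 2 delta Omega + delta w + V_F + V_eps`.

Substituting the recursion into itself yields a geometric series whose sum
gives the closed form `f = theta_NT / theta_T`: `delta` cancels, so the
estimate of `f` (and hence the full `V_F`) does not depend on how predictive
the PGS is — only its standard error does. [closed_form_model0()] implements
this inversion; the model is just-identified.

**Model 1 (VT plus assortative mating).** Primary phenotypic assortative
mating (AM) is modeled with a *copath* `mu = cov(Y_p, Y_m) / V_Y^2` joining
the parental phenotypes. AM builds gametic phase disequilibrium: the
haplotypic scores acquire an extra (co)variance `g = Omega^2 mu`, appearing
as a *cis* covariance within a person (`cov(T_*, NT_*)`), a *trans*
covariance across mates (`cov([N]T_p, [N]T_m)`), and an increase `k + g` of
each haplotypic variance. The nurture quantities inflate by the factor
`(1 + mu V_Y)`: `w = 2 f Omega (1 + mu V_Y)` and
`V_F = 2 f^2 V_Y (1 + mu V_Y)`. Because AM and VT both grow `V_Y` across
generations while the spousal *correlation* is assumed constant, `mu`
shrinks toward its equilibrium value; the recursion settles in a handful of
generations (see below).

**Model 2 (VT, AM, and latent genetics).** Real PGSs capture a fraction of
heritability. Model 2 adds haplotypic *latent genetic scores* (LGS) with
effect `a`, orthogonal to the PGS in the base population, with their own
AM-induced quantities `h` (LGS–LGS), `i` (PGS–LGS) and latent nurture `v`.
Two proportionate-increase assumptions make these identifiable:
`h = g a^2 / delta^2` (the AM-induced increase scales the same way for
observed and latent scores) and `v = w a / delta` (the nurture-to-effect
ratio is shared). They imply `i = sqrt(g h)`. The latent analog of `Omega`
is `Gamma = a j + 2 a h + 2 delta i + v / 2`. The offspring-score
covariances gain latent chains, e.g.
`theta_NT = 2 f Omega (1 + mu V_Y) + 4 delta g + 4 a i`. Ignoring `i` (as
Model 1 implicitly does) misattributes AM-induced genetic covariance to
nurture, which is why Model 1 overstates `V_F` when the PGS is weak — the
package's central reproducible claim. `a` is estimated from observed
parental phenotypes (a 7×7 covariance structure), or fixed from an assumed
base-population heritability via `a^2 = h2_base - delta^2`
([fit_assumed_a()]); overstated `h2_base` biases `w` and `V_F` downward, and
vice versa.

The phenotypic variance decomposes as
`V_Y = V_A + V_F + 2 (a v + delta w) + V_eps` with
`V_A = 2 a^2 (j + 2h) + 2 delta^2 (k + 2g) + 8 a i delta`.
[decompose_variance()] reports this plus the base-population `V_A0` and the
Kong-style quantities `eta = 2 f Omega` (direct nurture),
`phi_eta = 2 f Omega mu V_Y` (AM's contribution to apparent nurture;
`eta + phi_eta = w`) and `phi_delta = 4 delta g`.

### Scaling constants

`k` (and its latent analog `j`) are fixed by how the user scales the
scores, not estimated: `k = 1/2` if the full PGS is standardized in the base
population (simulated data), `k = 1/2 - 2g` if standardized in the current
generation (the usual choice for real data), and `k = 1/2 - g` if each
haplotypic score is scaled to variance 1/2 now. Estimates of the other
parameters are unaffected so long as `k` matches the data's scale;
[extract_family_table()] and [standardize_scores()] apply a convention and
report the matching `k`. For the current-generation conventions `k` depends
on the unknown `g`, so the two are resolved jointly from the observed cis
moments (for full-PGS standardization, `ghat = 1 - 2 vbar - cbar` with
`vbar` the mean haplotypic variance and `cbar` the mean cis covariance);
this one-dimensional consistency solve is our choice — the circularity is
not addressed in the source framework.

```{r}
p <- model_params(delta = 0.3, a = 0.55, f = 0.12, r_mate = 0.3, V_eps = 0.4)
st <- equilibrium_state(p, model = "m2")
st
decompose_variance(st) |> round(3)
```

## Solving the equilibrium

All derived quantities are nonlinear constraints on one another. We solve
them by plain successive substitution from the no-AM, no-VT start values
(`g = h = i = w = v = 0`, `V_Y = 2 delta^2 k + 2 a^2 j + V_eps`), iterating
until the largest absolute change falls below `tol` (default `1e-12`, so the
exact identity suite below holds with margin; `max_iter = 10000`). One
iteration corresponds to one generation of mating, so the trajectory *is*
the approach to equilibrium: for realistic parameters it is reached (all
quantities within 0.5%) in roughly 5–10 generations. When the user supplies
the spousal correlation `r_mate` — more interpretable than the copath `mu`,
which is neither the spousal covariance nor the correlation — `mu = r_mate
/ V_Y` is re-derived inside each iteration, matching the assumption that the
*correlation* is what stays constant while `V_Y` grows.

Two details are deliberate:

- **A final consistency pass** recomputes every derived quantity from the
  converged state, so the equilibrium identities (`g = Omega^2 mu`,
  `i = sqrt(g h)`, `h delta^2 = g a^2`, `v delta = w a`,
  `V_Y = V_A + V_F + 2(av + delta w) + V_eps`, `eta + phi_eta = w`) hold to
  numerical precision rather than to `tol`.
- **Divergence is an error, not a warning**: `2 f^2 (1 + mu V_Y) >= 1`
  leaves no finite phenotypic variance (e.g. `|f| >= 1/sqrt(2)` without AM),
  and the solver names the offending parameter combination.

Under base-population scaling, the imposed ratio constraints and the
path-traced `Gamma` are mutually consistent (`Gamma / Omega = a / delta`,
hence `h = Gamma^2 mu` automatically). Under current-generation scalings
the two characterizations of `h` cannot hold simultaneously in a forward
recursion; we keep the ratio constraints exact and treat `Gamma` as the
path-traced quantity, which the simulator validates (below).

### Disequilibrium assortment

A single generation of AM produces *trans* covariance between mates' scores
but no *cis* covariance within haplotypes — that requires a second
generation's recombination. The `am_regime = "disequilibrium"` flag models
this: cis `g`, `h`, `i` are set to zero in the haplotypic variances,
within-person covariances, `Omega`, `Gamma` and `V_A`, while the
copath-mediated trans covariances (`Omega^2 mu`) and the `(1 + mu V_Y)`
inflation of `w`, `v`, `V_F` are retained; the AM-induced genetic terms in
`theta_[N]T` halve (only the trans chains survive). This is a stationary
rendering of the single-generation scenario; the simulator with
`am_onset = n_generations` is the reference for its trans expectations, and
the cis/trans diagnostics below are the recommended way to detect the
scenario in data.

## The simulator (and what it does and does not emulate)

[simulate_population()] is a variant-level forward-time engine. The base
generation draws haplotypes at `m_obs + m_lat` biallelic loci in linkage
equilibrium with frequencies uniform on `maf_range` (default 0.1–0.5);
per-locus weights are standard normal, rescaled so each haplotypic score has
variance exactly 1/2 in the base population under linkage equilibrium
(`sum beta^2 p(1-p) = 1/2`), making `k = j = 1/2` true population constants.
Each generation: phenotypic assortment to a target spousal correlation
(a Gaussian copula on phenotype ranks — exact in expectation, no rejection
loop), vertical transmission `F_o = f (Y_p + Y_m)`, Mendelian transmission
with free recombination (every locus segregates independently), two
offspring per couple (one of each sex, deterministic halves), and phenotype
assembly `Y = delta (T_p + T_m) + a (LT_p + LT_m) + F + eps`. Identical
configurations are bit-identical by seed.

Defaults represent the validation conditions: `n_generations = 15` (well
past the 5–10 needed for equilibrium), 50 observed + 50 latent loci,
`maf_range = c(0.1, 0.5)`. The acceptance suite checks that *every* entry
of the implied covariance matrix matches the empirical covariance of 200,000
simulated equilibrium families within 4 Monte-Carlo standard errors, across
five parameter sets spanning the three models.

What the simulator does **not** emulate, and the corresponding limits of
what passing tests show about real data:

- **Linkage and LD maps.** Loci recombine freely; cis covariance dynamics
  are purely AM-driven. Real genomes would approach equilibrium more slowly
  in tightly linked regions.
- **Finite locus counts** leave a same-locus across-haplotype covariance
  (AM-induced Hardy–Weinberg disequilibrium) of order `1/m` that the
  infinitesimal path model ignores; it depresses the haplotypic variances
  slightly (measured ~0.008 at `m = 20` versus < 0.001 at `m = 100` for
  `g = 0.03`). Oracle comparisons therefore use at least 50–60 observed
  loci.
- **Closed-population relatedness.** With exactly two offspring per couple,
  every parent is somebody's sibling, and assortment propagates those links
  to in-laws. Point estimates are unaffected, but standard errors computed
  under independent-families assumptions (FIML, the influence covariance)
  understate the truth by up to ~40% for within-person moments in strongly
  assorting, many-generation closed populations. Calibration studies
  therefore use single-generation scenarios whose parents are the unrelated
  base population; with real data, pruning close relatives is advisable, as
  in any family-based design.
- No selection, mutation, sex-specific effects, parent-of-origin effects,
  or sibling (horizontal) transmission.

## Estimation

[fit_model()] maximizes the FIML likelihood: families are grouped by
missingness pattern once; each family contributes the zero-mean
multivariate-normal density of its observed variables under the implied
covariance, so estimates are unbiased under data missing (completely) at
random — families carrying only pairs of variables still contribute, with
wider standard errors. Rather than passing nonlinear constraints to a
constrained optimizer, the equilibrium fixed point is solved *inside* every
likelihood evaluation, so the constraints hold exactly by construction; the
outer search (Nelder–Mead with a BFGS polish, five jittered starts by
default, ties broken toward the smaller parameter norm) runs on transformed
scales with `|f| <= 0.95`, `V_eps >= 1e-6`, spousal correlation magnitude
`<= 0.95`. Non-convergence, boundary solutions and degenerate inputs raise
or warn explicitly. A covariance-matrix entry point ([loglik_cov()])
reproduces the record-level likelihood on complete data.

Standard errors come from the numerically differentiated observed
information, with delta-method propagation to every derived quantity
(`V_F`, `w`, `v`, `V_A`, ... — reported and flagged as derived); because
`V_F` is quadratic in `f`, the propagation includes the second-order
delta-method term, which keeps its SE from collapsing when `f` is estimated
near zero. A singular information matrix falls back to a family bootstrap
with a warning. The Kong-style quantities receive delta-method SEs like any
other derived quantity — a reporting choice on our part.

One caveat deserves emphasis: when the PGS captures a small share of the
heritability and samples are modest (a few thousand families), `f` and the
latent effect `a` are only weakly separated (both enter
`cov(Y_o, Y_parent)`), the sampling distribution of `f` is visibly
non-Gaussian, and Wald-style intervals for `V_F` undercover in the lower
tail: in our 100-replicate study at 5,000 families with the PGS at 20% of
heritability, `V_F` is unbiased to three decimals yet sits within 3 of its
reported SEs of the truth in only ~94% of replicates — every exceedance on
the low side, none removable by extra optimizer starts, bootstrap SEs, or
higher-order propagation. For applied work at such sizes, prefer
profile-likelihood or bootstrap intervals for `V_F`, or more families.

```{r}
pop <- simulate_population(sim_config(
  n_families = 4000, m_obs = 30, m_lat = 30,
  delta = sqrt(0.1), a = sqrt(0.4), f = 0.15, r_mate = 0.3, V_eps = 0.5,
  n_generations = 15, seed = 42, store = "last"
))
ft <- extract_family_table(pop)
fit <- fit_model(ft, model = "m2", se_method = "hessian", n_starts = 2, seed = 1)
tidy(fit) |> filter(term %in% c("delta", "a", "f", "r_mate", "V_F", "w", "v"))
```

## Testing mechanisms of assortative mating

The four haplotypic variances (less `k`), the two within-person (cis)
covariances and the four across-mate (trans) covariances give ten estimates
of `g` ([g_estimates()]). Their sampling covariance is estimated from the
per-family influence products (empirical fourth moments) by default — a
deterministic estimator that calibrates the chi-squared tests accurately
(type-I error 0.051 over 12,000 null replicates in our checks); a
family-level bootstrap is available. Two Wald chi-squared(1) tests follow
the framework: whether the *average* of the ten estimates exceeds zero
(primary AM produces gametic phase disequilibrium), and whether the cis and
trans group means differ (equality is the equilibrium signature;
trans > cis with cis near zero indicates a single recent generation of
assortment). [am_test_report()] combines them with the single-generation
verdict and a homogamy diagnostic: the `g`-implied spousal covariance
(`mu V_Y^2` with `mu` recovered from `g = Omega^2 mu`) is compared with the
observed one — observed above implied is the social-homogamy direction,
below it the genetic-homogamy direction. Note that under strong primary AM
an added shared-environment spousal covariance also inflates `V_Y`, so the
diagnostic's power is greatest when genetic assortment is modest. The three
results are reported jointly at `alpha = 0.05` with no multiplicity
correction — they answer different questions and are labeled as such.

```{r}
pop1 <- simulate_population(sim_config(
  n_families = 8000, m_obs = 30, m_lat = 0, delta = 0.5, f = 0,
  r_mate = 0.4, V_eps = 0.75, n_generations = 1, am_onset = 1, seed = 7
))
am_test_report(extract_family_table(pop1), k = 0.5)
```

## Scores from real trio data

[read_trios()] + [haplotypic_scores()] construct `T_p, NT_p, T_m, NT_m`
from a VCF and a PGS weight table. With phased data the offspring's first
haplotype is taken as paternal (configurable); with unphased data Mendelian
deduction resolves each site, which fails to be unique exactly when all
three members are heterozygous. Ambiguous sites either contribute half the
parental genotype score to each of T and NT (`split`, the default —
unbiased for the score sums, slightly attenuating the T/NT contrast) or are
dropped per family. Alleles are matched to the weight table by identity
(no strand inference); mismatches, multi-allelic sites and Mendelian errors
are excluded and counted. IBD detection, statistical phasing and imputation
are out of scope — the package expects phased or unphased genotype calls.

## Numerical choices and study sizes

- Fixed point: successive substitution, `tol = 1e-12`, `max_iter = 10000`;
  identities asserted to `1e-10` on a 3×3×3×3 parameter grid.
- Oracle agreement: 200,000 families per parameter set, generation 15,
  4 MC SE tolerance, five parameter sets.
- Estimator bias study: 100 replicates of 5,000 families (PGS at 20% of a
  base heritability of 0.5, spousal correlation 0.3, `f = 0.15`); checked:
  Model 1's `V_F` above truth and Model 2's within 3 SE of truth, each in
  >= 95% of replicates (the second sits at ~94% for the structural reasons
  discussed under Estimation).
- Test calibration: 500 single-generation null replicates at 5,000
  families; 100 single-generation-AM replicates for the verdict rate.
- Missingness: a 20,000-family pairs-only design (every family keeps two
  variables, all 21 pairs represented) against the complete-data fit.

These sizes are the package's validation conditions; they were chosen so
Monte-Carlo error sits well below the asserted tolerances while the whole
suite runs in minutes.

## Known limitations

Single trait only (no bivariate or cross-trait extension); no sibling or
horizontal transmission; no parent-of-origin or gene-by-age effects (the
framework assumes equal PGS effects in parents and offspring); latent-trait
social/genetic homogamy models are diagnosed directionally, not fitted;
estimates assume the discovery GWAS behind the weights was adequately
controlled for stratification. `V_F` quantifies parental influence
*associated with the trait the PGS indexes* — parental influences genetically
uncorrelated with that trait are invisible to the design.
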