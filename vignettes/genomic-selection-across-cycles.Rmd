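---
title: "Genomic selection across breeding cycles: models, simulation design and validation schemes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection across breeding cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gscycles)
```

## The problem

A line-breeding program creates a new cohort of inbred candidates every year
(a *breeding cycle*) and tests it in multi-location trials. Genomic selection
promises to rank next year's candidates from their marker profiles alone, but
the usual way of measuring how well that works — random cross-validation
inside a single cohort — answers a different question than the one a breeder
faces. Within a cohort, training and validation lines are close relatives
tested in the same environments; a new cycle is neither. `gscycles`
implements the full chain needed to quantify that gap on multi-cycle data:
two-stage phenotypic analysis, marker quality control and imputation,
RR-BLUP/G-BLUP prediction, three cross-validation schemes (within-cycle,
between-cycle, cycles-as-folds), outlier diagnostics based on pairwise
prediction accuracies, independent-cohort validation with selection
proportions, and derived-trait prediction from component traits. Because
commercial trial data of this kind are typically proprietary, the package
ships a breeding-program simulator with known true breeding values so that
every claim the pipeline makes can be checked against truth.

## Two-stage phenotypic analysis

**Stage 1 (per trial).** Trials follow the usual early-generation layout:
unreplicated test lines plus replicated checks, which makes the error
variance estimable and allows spatial correction. With line as a fixed
effect, four candidate models are fitted by REML — a baseline, and versions
adding random row, column, or row+column effects — and the smallest AIC wins.
Candidates share the same fixed part, so the REML likelihoods are
comparable; the baseline is fitted with `nlme::gls()` and the spatial models
with `lme4::lmer()`, whose REML log-likelihoods coincide for a common model.
The trial is summarised by line BLUEs with standard errors, a genetic
variance from a companion fit with line random (same spatial terms), and the
entry-mean heritability

$$h^2 = \frac{\sigma^2_G}{\sigma^2_G + \tfrac{1}{2}\,\mathrm{MVD}},$$

where MVD is the mean variance of a difference between two line BLUEs,
computed from the full fixed-effect covariance matrix. Trials with
`h2 <= 0.3` are discarded by default (`select_trials()`, strict inequality).

**Stage 2 (per cycle and trait).** The retained trials' BLUEs enter

$$y_{ij} = \mu + g_i + t_j + gt_{ij} + e,$$

with fixed trial effects, random line and line-by-trial effects, and known
observation variances `c * se_ij^2` — the stage-1 precisions act as weights,
and the residual constant `c` is fixed per trait (1 for grain yield, 0.1 for
the protein traits), which is what makes the interaction variance separable
from the residual. Variance components come from `metafor::rma.mv()` (a
meta-analytic mixed model with known sampling variances — exactly this
structure); line BLUEs are then re-estimated with line fixed by generalised
least squares, which is diagonal here because the interaction has one
observation per line-by-trial cell. The across-trial heritability is
$h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GT}/t)$. Whether the stage-2
adjusted means should come from a fixed- or a random-line fit is genuinely
open; we default to the fixed-line refit (the downstream accuracies are
correlations with these means, and shrunken means would attenuate them
differentially by cycle size) and expose `blue_method = "random"` as the
alternative.

## Markers, imputation, kinship

QC removes markers with call rate below 0.90, minor allele frequency below
0.05 (heterozygotes count half), or more than 10% missing data. Remaining
gaps are filled by an EM algorithm under a multivariate-normal model over
*lines*: each marker column is a draw with line-by-line covariance
$\Sigma$; the E-step imputes missing entries from their conditional
expectation, the M-step re-estimates the marker means and $\Sigma$ (with the
conditional covariance in the sufficient statistics). Two numerical choices
matter. First, $\Sigma$ is shrunk towards its diagonal with intensity
`max(0.02, N/(N+M))`: the covariance of N lines estimated from M marker
columns is noisy when N approaches M, and without growing shrinkage the
iteration can diverge; the floor of 0.02 keeps near-duplicate line profiles
(covariance ≈ variance) recoverable to within a few hundredths. Second, the
marker means are re-estimated inside the loop — centring on observed-only
means conflicts with the sum-to-zero degeneracy of a column-centred line
covariance and visibly biases the conditional means. Imputed dosages are
continuous in [-1, 1]; observed calls are never altered.

The genomic relationship matrix is

$$K = \frac{WW^{\mathsf T}}{2\sum_k p_k(1-p_k)},$$

with $W$ the column-centred code matrix and $p_k$ the frequency of the
+1-coded allele. Centring by the column mean of the $\{-1,0,1\}$ codes is
the scale-consistent form of "subtract $2p_k$" on a dosage scale, and the
denominator is used in its positive form. Consequences used as tests: rows
of $K$ sum to zero, and for near-inbred material the mean diagonal is close
to $1+f \approx 2$.

## RR-BLUP, G-BLUP and reliabilities

Both predictors are fitted by exact REML on the spectral decomposition of
their kernel ($ZZ^{\mathsf T}$ or $K$) restricted to the orthogonal
complement of the fixed effects: with eigenvalues $\xi_i$ and rotated data
$\eta_i$, the profiled REML criterion in the variance ratio
$\lambda^2 = \sigma^2_e/\sigma^2_u$ is one-dimensional and is minimised by a
coarse grid (49 points on $\log\lambda \in [-12, 12]$) followed by golden
section refinement; a solution at the grid boundary is reported as "no
genetic signal". Marker effects and genetic values then come from the
mixed-model equations at the estimates; the two parameterisations give
identical genetic deviations (tested to 1e-6; the kinship ridge is
$10^{-8}I$, small enough not to break that identity). G-BLUP additionally
returns per-line prediction error variances
$\mathrm{PEV}_i = [\sigma^2_G K - \sigma^2_G K P K \sigma^2_G]_{ii}$ (with
$P$ the REML projection matrix, verified against the inverse coefficient
matrix of Henderson's equations on a hand-solved 3-line system) and the
reliability-type accuracy $r_{\mathrm{PEV}} = \sqrt{1 -
\mathrm{PEV}/(G_{ii}\sigma^2_G)}$.

When a training set spans several cycles, fixed cycle-indicator columns
absorb the year levels; predictions for a new cycle are genetic deviations
(the unknown new-year effect cancels in every correlation-based accuracy,
and for absolute predictions the mean of the training-cycle effects is the
documented fallback).

## Cross-validation schemes and diagnostics

*Within-cycle*: five near-equal random folds per replicate, trained on 4/5
of one cohort; the replicate value averages the per-fold correlations
between GEBV and BLUE (the pooled-prediction correlation is available behind
`pooling = "pooled"`). *Between-cycle*: the same training folds (bit-exact,
via indexed RNG substreams of one master seed) predict every other cohort in
full; the bias of the within-cycle estimate is
$(r_{within} - r_{between})/r_{between} \times 100$, with negative-
denominator cells flagged rather than reported. *Across-cycle*: cycles are
the folds; an equal number of lines is sampled from each remaining cycle
(remainders spread one per cycle) so that training size and cycle
composition are not confounded, with fixed year effects in the model.
The pairwise cycle matrix (train on all of cycle a, predict all of cycle b;
within-cycle means on the diagonal) approximates the genetic correlation
structure among years; a cycle whose row mean in the training role falls
more than one standard deviation below the overall mean is flagged as an
outlier, and trials with negative mean training accuracy likewise at the
trial level. The outlier-corrected scheme re-divides the sampling quota over
the remaining cycles so the training size stays constant; by default an
excluded cycle is dropped from both the training and the validation role
(a flag restores it as a validation fold).

Independent validation fits on complete training cycles, predicts a held-out
cohort, and reports — besides the accuracy — the proportion of correctly
selected best (or worst) lines over a grid of selection fractions (default
10/20/30%; the fractions are a reporting choice, not a model parameter),
with ties broken by line id so results are reproducible.

## What the simulator emulates — and what it does not

`simulate_genotypes()` builds founder inbreds at allele frequencies
Uniform(0.1, 0.9) (guaranteeing post-QC polymorphism at desk scale), crosses
parents drawn preferentially from the previous cohort into biparental
families (~8 lines each), and takes progeny to near-homozygosity by
simulated single-seed descent; the default of five selfing generations
mirrors F6-derived material and leaves residual heterozygosity near 1%, with
a DH switch for fully homozygous lines. This makes within-cycle kinship
exceed between-cycle kinship, the structural fact that drives every
within-versus-across contrast in the package. Trait architecture: one shared
QTL set with bivariate-normal effects gives grain yield and protein content
a configurable genetic correlation (default -0.3, the typical negative
yield-protein relation); protein yield is *derived per plot* as
`grain_yield * protein_content / 100` (dt/ha times % on the natural scale),
so its genetics, interactions and noise all emerge from the components, as
in the field.

`simulate_phenotypes()` adds year and trial main effects, genotype-by-trial
deviations, optional random row/column trends, plot residuals, and
replicated checks beside unreplicated test lines. The genotype-by-trial
variance is calibrated from the target entry-mean heritability as
$\sigma^2_{GT} = \mathrm{var(TBV)}\, t\, (1/h^2 - 1)$ — the stage-2
estimator excludes the plot residual (it is absorbed through the known
stage-1 weights), so this is the calibration that makes the pipeline's
estimate land on the target (defaults follow the 0.14–0.84 range observed
across five cycles of a commercial program; recovery to ±0.1 is an
acceptance test). Setting a target of 0 removes the genetic signal entirely,
giving the null traits used for calibration tests. Two structured
distortions are available: `outlier_trials` sign-flips the genetic effects
of designated trials (producing the negative phenotypic correlation with
sibling trials that characterises frost- or drought-damaged environments),
and `cycle_genetic_frac` adds a *marker-encoded, cycle-specific* genetic
deviation (fresh QTL effect draws per cycle, scaled to a fraction of the TBV
variance). The latter is what makes within-cycle cross-validation genuinely
optimistic: a marker model can learn this component inside a cycle, but it
does not transfer to other cycles. With iid interaction noise alone the bias
exists but is driven purely by relatedness, and the trait ordering of the
bias is not reproduced.

Deliberate omissions (they do not affect the contrasts under study, but
passing tests say nothing about them): no linkage map or LD decay — markers
segregate independently, so accuracy levels are driven by family structure
and the causal markers being genotyped, not by historical LD; no dominance
or epistasis; no reaction-norm G×E beyond the cycle/trial structure above;
family sizes and the crossing design are exposed as configuration without
claiming fidelity to any particular program.

## Numerical and design choices

- AR1×AR1 residual structures in stage 1 are out of scope; the candidate set
  is the four row/column random-effect models. The AIC selection, BLUE and
  weight flow are fully exercised without them; spatially autocorrelated
  residuals beyond row/column trends are a documented limitation.
- REML non-convergence in stage 1 flags the result rather than failing;
  negative variance iterates are clamped at zero by the fitting engines.
- Stage-2 standard errors use the known total variances
  $\sigma^2_{GT} + c\,se^2_{ij}$ directly (no residual rescaling);
  weights with missing stage-1 standard errors are floored at $10^{-6}$.
- The trait-specific residual constant (1 for grain yield, 0.1 for the
  protein traits) follows the field convention for these units. For the
  protein traits it understates the known observation variances, so a small
  share of residual noise is absorbed into $\sigma^2_{GT}$ and their
  heritabilities are estimated slightly conservatively (about 0.05–0.1 low
  in simulation); calibration properties are therefore asserted on grain
  yield.
- All randomness flows through indexed substreams
  (`scheme, replicate, fold/cycle`) of one master seed: every scheme is
  replay-exact, and the between-cycle scheme reuses the within-cycle folds
  bit-identically.
- Monte-Carlo problem sizes in the test-suite: five cycles of 40 lines with
  3 trials and 250 markers for the scheme-level properties, cohorts of
  50–100 lines and 120–500 markers for estimator recovery, chosen as the
  smallest sizes at which the studied contrasts are comfortably resolved.

## A worked example

```{r example, eval = FALSE}
cfg <- program_config(n_cycles = 3, lines_per_cycle = rep(60, 3),
                      n_markers = 300, trials_per_cycle = rep(3, 3),
                      target_h2 = 0.6, seed = 1)
pop <- simulate_genotypes(cfg)
plots <- simulate_phenotypes(pop)
analysis <- analyze_phenotypes(plots, min_h2 = 0.3)
variance_report(analysis)
d <- gs_data_from_analysis(pop, analysis)
within_cycle_cv(d, "C1", "grain_yield", reps = 20, seed = 1)
across_cycle_cv(d, "grain_yield", train_size_total = 80, reps = 20, seed = 1)
```

The same flow is available as a configuration-driven pipeline
(`run_pipeline()`, YAML or JSON) writing CSV artifacts plus a manifest, with
`make_report()` collecting them into summary tables.

## Known limitations

Accuracy *levels* from the simulator are not calibrated to any particular
crop or marker platform (no LD structure; causal loci genotyped), so only
orderings, contrasts and calibration properties — not absolute accuracies —
should be read off simulated runs. Stage 1 assumes the check-based error
variance applies to the unreplicated test lines. The derived-trait route
adds cohort means back before multiplying GEBVs; whether to use means or
pure deviations is not decidable from first principles, so the
deviation-product is available behind a flag.
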