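---
title: "Soft-sensor models for galactose-fed CHO cultures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft-sensor models for galactose-fed CHO cultures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chosensor compares three soft-sensor model families for predicting growth,
antibody titer, intracellular nucleotide sugar donors (NSDs) and N-glycan
galactosylation in galactose-fed CHO fed-batch cultures: a mechanistic
Michaelis--Menten/Monod kinetic model (MMK), an orthogonal partial least
squares (OPLS) regression, and a small penalized tanh feed-forward network
(NN). This vignette documents the models, the numerical choices, and the
design decisions a maintainer would want to know about. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The data model

All observations travel as a tidy long table — one row per
(batch, condition, replicate, time, channel) measurement — because the
channels are sampled on different cadences: extracellular metabolites every
12--24 h from inoculation, NSDs every 12 h from day 2.5, glycan fractions
roughly daily from day 3. A long table represents "not measured" as an
absent value without sentinel codes; a wide per-channel view
(`pivot_culture_wide()`) is derived, never stored. Missing values are
first-class (`NA`, an empty CSV field) and never coded as 0 or −1.

The fifteen channels split into the factor block used by the data-driven
models — the six extracellular metabolites (glucose, glutamine, glutamate,
lactate, ammonium, galactose) — and the response block (three glycan
fractions G0F/G1F/G2F, four NSDs, viable cell density, titer). Time is in
hours throughout; day-based statements convert as day d = 24·d h.

## The kinetic model (MMK)

The ODE state has 19 components: culture volume, viable cell density Xv,
six extracellular species, titer, three intracellular sugar pools, four NSD
pools, and the secreted antibody mass carried by each glycoform. The
default instantiation is:

* **Growth**: Monod on glucose, `mu = mu_max*Glc/(K_glc + Glc)`, with a
  constant death rate `k_d`. Byproduct (lactate/ammonium) toxicity is
  deliberately excluded; the model treats death as first-order.
* **Glucose**: consumed by growth and maintenance,
  `dGlc/dt = -(mu/Y_xglc + m_glc)*Xv`. Lactate is yielded from glucose
  consumption, ammonium and glutamate from glutamine consumption.
* **Galactose**: Michaelis--Menten uptake with an optional glucose
  inhibition factor `1/(1 + Glc/Ki_glc_gal)`; the default `Ki = Inf`
  disables it, since the observation motivating it (suppressed galactose
  uptake under glucose abundance) is a hypothesis, not part of the core
  model.
* **Intracellular pools** (culture-volume mM): membrane transport in by
  uni-uni Michaelis--Menten kinetics, synthesis consumption out, and a
  growth-dilution term `mu*S`. Whether such pools should be per-cell or
  per-volume quantities is genuinely open; we chose culture-volume mM with
  dilution, which keeps every flux in mM/h.
* **NSD synthesis**: UDP-Glc from intracellular glucose (uni-uni); UDP-Gal
  from UDP-Glc (epimerase, uni-uni) plus intracellular galactose (salvage,
  uni-uni) — the salvage route is what makes galactose feeding raise
  UDP-Gal; UDP-GlcNAc from intracellular glucose and glutamine (bi-ternary
  complex); UDP-GalNAc from UDP-GlcNAc (uni-uni). Each NSD loses a
  constant Golgi transport flux `f_n` (gated at zero) and growth dilution.
* **Glycan maturation**: sequential G0F → G1F → G2F galactosylation with
  pseudo-first-order rates saturating in UDP-Gal, applied over a fixed
  Golgi residence time `tau_G`. The closed form of the two-step
  first-order chain splits newly secreted antibody across glycoforms, so
  the three glycoform masses sum to titer *identically* — the conservation
  checked to 1e-8 in the tests. The degenerate equal-rate case switches to
  the analytic limit `kappa*tau*exp(-kappa*tau)` when the two rates agree
  within 1e-12 relative. A residence-time closed form was chosen over a
  spatially resolved Golgi model: with only three measured glycoforms the
  extra structure would be unidentifiable.

Each rate law is an isolated function (`monod_mu`, `mm_uni`,
`mm_bi_ternary`, `glycan_instantaneous_fractions`) so alternative forms can
be swapped without touching the integrator.

**Events.** Feeds are concentration increments by default ("fed 25 mM"
means +25 mM; the concentrated bolus volume is neglected); a stock-mixing
mode with explicit feed volume is available. Sampling removes volume and
leaves every intensive quantity unchanged. Both are applied instantaneously
between integration segments, sampling before feeding when they coincide.

**Numerics.** Integration uses `deSolve::lsoda` (adaptive,
stiff-capable), rtol 1e-8 / atol 1e-10 by default. Consumption fluxes are
multiplied by a smooth gate `S/(S + 1e-6 mM)` instead of hard clipping, so
the right-hand side stays continuous when a pool empties; 1 nM is far below
assay resolution for every species modeled, and the gate width keeps the
boundary layer at an emptied pool resolvable without excessive step
rejection. Output states are clipped at zero (any undershoot is at
integrator-tolerance scale). Glucose exhaustion late in a long culture is
the stiffest regime; the default fixture trajectories traverse it.

**Fixture parameter values.** No published parameter set exists for this
model, so the package defaults are fixture values chosen once to produce
study-like trajectories: peak VCD of order 1e7 cells/mL, titer of a few
hundred mg/L, sub-mM NSD pools, UDP-Gal rising from a ~0.15 mM baseline
toward ~0.6 mM after two 25 mM galactose boluses and declining afterwards,
G0F in the 70--85% range. They are documented as fixtures, not estimates.

## Parameter estimation

With Gaussian measurement error, maximizing the likelihood is minimizing a
weighted SSE; `fit_kinetics()` does multi-start bound-constrained
Levenberg--Marquardt (via `minpack.lm`) in log10 parameter space (all
parameters are positive scale quantities). Two residual modes:

* **free** — one forward simulation per evaluation, residuals at all
  observation times;
* **teacher forcing** — the simulated state is reset to the measured values
  of every *observed* channel at each observation time and integrated one
  segment ahead; unmeasured channels carry the simulated value over.
  Glycan fractions reset jointly (rescaling the glycoform masses at fixed
  total) and only when all three are measured. Resetting only measured
  channels is a choice: resetting unmeasured states would require inventing
  values for them.

Two weighting schemes: per-channel inverse-squared-mean weights (the
default; makes the objective invariant to unit changes) and per-observation
relative weighting `1/max(|obs|, 0.05*channel mean)` — the exact maximum
likelihood weighting when error is multiplicative with constant CV, which
is the generator's noise model. The relative mode is markedly better at
pinning `K_glc`, which is informed almost entirely by the brief
glucose-depletion bend where observations are small.

Numerical details that matter: the finite-difference Jacobian step
(`epsfcn = 1e-6`) must sit well above the squared ODE tolerance or the
Jacobian is integration noise; sampling events are dropped inside the fit
objective (they change only volume, which never feeds back into an
intensive state, and each event forces an integrator restart); a tight
`maxsteps` budget makes pathological parameter draws fail fast and take a
large penalty residual instead of stalling the optimizer. Only a
configurable subset of parameters is fitted (defaults: growth/substrate
constants); the K-constants of the NSD reactions stay fixed by default
because the full problem has more parameters than the data can constrain.

Parameter-recovery studies fit a **single replicate** with the initial
state taken from that replicate's own t = 0 observations. Pooling
replicates whose inoculation densities were perturbed by ±50% creates a
systematic mismatch exactly at the depletion bend, biasing `K_glc`; this is
a property of pooling, not of the estimator. The t0 convention mirrors the
study: extracellular states from t = 0 measurements, NSD and glycan states
from the earliest measured values (~72 h) of the same condition.

## OPLS

`fit_opls()` decomposes the autoscaled factor block into Y-predictive and
Y-orthogonal variation. Orthogonal components are extracted first, by a
two-tier rule. Whenever the cross-covariance X'Y has a numerical nullspace
(rank detected by pivoted QR), the orthogonal weight is the dominant
principal direction of X outside the span of X'Y, which makes the
orthogonal score's sample covariance with every response *exactly* zero —
the tests assert |corr| < 1e-6 on such data. When X'Y is numerically full
rank (the typical case with many noisy responses: no direction is exactly
Y-free), the classic construction is used instead — the part of the
current X-loading not spanned by the predictive weight — which yields the
small-but-nonzero correlations practical OPLS implementations produce.
After the orthogonal deflations, `A_pred` predictive PLS2 components are
fitted by NIPALS with standard deflation. With zero orthogonal components
the procedure reduces to plain PLS2 and is tested against an independent
per-component SVD oracle to 1e-8. When the NIPALS power iteration cycles
between two near-tied covariance directions (which can happen after
orthogonal deflation), the component is resolved deterministically from
the SVD of the zero-filled cross-covariance plus one skip-missing
refinement pass.

Missing cells are handled NIPALS-style: every inner product runs over
present cells only (a score is the least-squares projection of a row's
present entries on the weight vector). This is why no imputation step
exists anywhere in the package — with channels 30--87% incomplete,
imputation would dominate the signal. Deleting 10% of cells at random from
a strong-signal dataset moves predictions by under 5% RMS (tested).

Component count: the study convention reports a total (5); the split is
configurable with defaults `A_pred = 2`, `A_orth = 3`. One row per
observation time; observation time itself is included as a seventh factor
column (it anchors the data-driven models against extrapolation along the
culture clock). The variant with NSDs as factors can be built by passing a
different response set, but it is not a default. Cross-validated Q2 uses
7 folds assigned round-robin after a seeded shuffle; PRESS accumulates on
held-out rows in training-fold scaled units. VIP follows
`sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a)`, so mean squared VIP is 1.
Sign convention everywhere: the largest-magnitude element of a weight
vector is made positive.

## The neural network

A fixed 6--3--8 architecture: six extracellular metabolite inputs, three
tanh hidden units, eight outputs (the responses minus UDP-GlcNAc), and
6·3 + 3 + 3·8 + 8 = 53 trainable parameters. Inputs and outputs are
autoscaled (a 53-parameter network cannot span cells/mL to mM raw);
predictions are de-scaled and may legitimately be negative — they are
preserved, not clipped. Missing inputs impute to the training mean; rows
with all responses missing are dropped; rows missing some responses
contribute only their observed channels to the SSE. That skip-missing sum
is the mechanism that lets the 87%-missing UDP-GlcNAc channel be excluded
without touching anything else, and the tests verify the objective and
gradient for the remaining channels are bit-identical either way.

Training: normally distributed random starts (default seed 1234 — the
study's "1,234 points" is ambiguous between a seed and a restart count; we
read it as a seed and make the restart count configurable, default 16); an
initial fit at penalty zero; then a golden-section line search on the log
ridge penalty (squared weights, biases unpenalized), each candidate fitted
by BFGS with the analytic backpropagation gradient (verified against
central differences to 1e-6). During BFGS the validation likelihood is
monitored every 10 iterations and training stops when it no longer
improves (with no validation set, the training objective plateau is used).
Among line-search candidates the model with the best training likelihood
is reported. A `lambda` argument fixes the penalty and skips the search.
Overfit is assessed by comparing R² and RASE (`sqrt(SSE/n)`) between
training and validation data per response.

## The comparison harness

One-way ANOVA (via `stats::aov`) followed by Tukey's HSD. The Tukey table
uses the Tukey--Kramer standard error `sqrt(MSW(1/n_a + 1/n_b))` for
unequal group sizes, p-values from the studentized-range distribution, and
rows oriented non-negative and sorted by descending absolute difference —
the layout of the study's comparison tables. Two independent cross-checks
in the tests: the exact two-group identity with the pooled t-test
(q = √2·|t|), and a numeric double-integration oracle for the
studentized-range tail probability. "Whole culture duration" comparisons
treat timepoints as observations, which ignores autocorrelation — exactly
as the original analysis does; per-timepoint glycan comparisons run across
replicate draws. A model source that never reports a channel drops out of
that channel's comparison rather than blanking it for everyone.

Derived metrics: specific rates `qs = Δconc / ∫Xv dt` with a trapezoid
IVCD (negative = consumption); fold changes as ratios of magnitudes;
the feed-window trend metric — per window, the percent difference between
predicted and observed concentration *changes*, insensitive to constant
offsets; and the galactosylation index `GI = (0.5·G1F + G2F)/ΣG`, the
occupied-site fraction of a two-site biantennary glycan (the standard form;
config-overridable since the source formula is not printed).

## The synthetic-data generator

The generator defines the study conditions; it is not a tuning dial. Four
conditions: unfed control (144 h), one 25 mM galactose bolus at 72 h or at
120 h (216 h each), and a validation condition fed at both 72 and 120 h
(288 h). Sampling grids honor the stated cadences and counts (10/13/18
metabolite points; NSDs every 12 h from 60 h, with the maximum of each
stated count range; glycans daily from 72 h, with the validation condition
analysed at days 3, 4, 6, 7, 8). The exact grid times within the
"12--24 h" cadence are not pinned by the study text; one deterministic
choice is hard-coded. Two biological replicates by default, with the
inoculation density perturbed uniformly within ±0.15e6 cells/mL around
0.3e6.

Noise is multiplicative Gaussian with per-channel CV (default 5%; channels
span nine orders of magnitude, so additive noise would be meaningless),
applied to glycan *areas* before renormalization to 100%. Truncation at
zero is clip (default) or reject-resample. Missingness is
missing-completely-at-random per channel at the study's reported
fractions: 30% VCD, 75% titer, 30--40% extracellular metabolites, 55%
NSDs, 87% UDP-GlcNAc — the schedule-driven part of the real pattern is
already captured by the per-channel grids, and the Bernoulli layer adds
the remainder. What passing tests on this generator do **not** show:
real cultures have correlated (block) missingness, assay-specific error
structure, and model misspecification; the generator shares the kinetic
model family with the MMK being fitted, so recovery results speak to the
estimation machinery, not to the model's biological adequacy.

## The pipeline

`run_pipeline()` chains generate → fit MMK → fit OPLS → fit NN → predict
the validation condition → compare, writing CSV/JSON artifacts and a
manifest with seeds and file hashes. The kinetic model predicts the
validation condition by forward simulation from its observed t0; OPLS and
the network predict from the validation batch's factor measurements
timepoint by timepoint. One global seed fans out to per-stage seeds by
fixed offsets; two runs with the same configuration are byte-identical.
The default configuration runs at fixture scale (2 kinetic starts, 2--4
network starts, 60--100 BFGS iterations) so a full pipeline completes in a
few minutes on one CPU; these sizes are package defaults, and every fitting
function accepts larger budgets.

## Known limitations

* The kinetic model omits pH/DO/temperature effects, amino-acid dynamics,
  byproduct toxicity, high-mannose and afucosylated glycoforms.
* Intracellular pools are culture-volume concentrations; per-cell pools
  with a volume model would change the dilution structure.
* The OPLS batch-level unfolding of the original commercial workflow is
  not reproducible from its description; one row per observation time with
  time as a factor is this package's convention.
* Tukey comparisons over whole-culture trajectories inherit the
  autocorrelation blindness of the original design.
* The generator's missingness is MCAR; real missingness is partly
  systematic.
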