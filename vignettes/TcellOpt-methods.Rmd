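---
title: "Models and methods in TcellOpt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in TcellOpt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TcellOpt)
```

TcellOpt supports the computational side of engineering T-cell
differentiation from pluripotent stem cells: planning multi-cytokine
dose-response experiments, fitting response surfaces to the phenotype
cell counts they produce, turning those surfaces into a single
optimization objective, quantifying progenitor frequencies from
limiting-dilution assays, and scoring notch pathway activity in
single-cell RNA-seq data. This vignette describes each model, its
assumptions, the tunable parameters, and the numerical choices made
where the methods literature leaves the design open.

## Experimental design: the orthogonal central composite design

Cytokine screens at this scale (six factors per differentiation stage)
cannot afford full multi-level factorials, so `makeCCD()` builds a
central composite design (CCD): a two-level factorial core at coded
levels $\pm 1$, two axial runs per factor at $\pm\alpha$, and replicated
center runs at $0$. For six factors the core is the 32-run half
fraction with defining relation $I = ABCDEF$ — the highest-resolution
(VI) half fraction, under which no main effect, quadratic or two-factor
interaction is aliased with any other, so the full 28-term second-order
model is estimable. With $\alpha \notin \{0, 1\}$ every factor column
takes exactly five distinct levels, which is what makes quadratic
curvature identifiable.

Two parameters are deliberately inputs rather than derived quantities:

* **`alpha` (default 2.366).** The axial distance that keeps the
  six-factor design orthogonal depends on the exact orthogonality
  criterion and center-run count used by the generating software; we
  treat the published value as a constant of the design rather than
  re-deriving it, and the default carries over to the optimizer's
  feasibility radius (below).
* **`nCenter` (default 8).** Center replication is a free choice that
  trades runs for a pure-error estimate; 8 is a conventional choice for
  a 44-run six-factor CCD and is user-settable.

Concentrations map to coded units logarithmically
(`codedToConc()`): coded $x$ corresponds to
$10^{\log_{10}\sqrt{c_{\text{low}} c_{\text{high}}} + x\,
\log_{10}(c_{\text{high}}/c_{\text{low}})/2}$, so $-1/0/+1$ hit the low
end, the geometric midpoint and the high end. The log scale reflects
how cytokine potency spans orders of magnitude; it also means coded
levels can never produce a zero or negative concentration, which is why
factor ranges must be strictly positive.

Run order is deterministic (factorial core in standard order, axial by
factor, then center) so that designs are reproducible fixtures; a
seeded shuffle is available for physical randomization.

## Dose-response surfaces

`fitResponse()` models the (transformed) absolute cell count of one
phenotype as a polynomial in the coded concentrations, fit by ordinary
least squares. Counts may be fit as-is (`identity`) or as
$\log(X + 1)$ (`log1p`, natural log); `log1p` is the default for counts
because cell yields are typically log-normally dispersed and the
transform keeps zero counts finite. Which transform suits which
phenotype is a per-response user decision.

Third-order terms are not in the default basis; `selectThirdOrder()`
adds user-nominated degree-3 terms by greedy forward selection on
adjusted $R^2$ ("improves the fit" is operationalized as an adjusted
$R^2$ increase above a configurable threshold, default 0). Ties break
toward the earliest candidate in canonical term order, and a candidate
that becomes aliased with already-selected terms is treated as
non-improving — on small designs the axial runs carry only two distinct
magnitudes per axis, so distinct cubic monomials can be exactly
confounded (e.g. $x_1^2 x_2$ with $\{x_2, x_2^3\}$).

Back-transformed predictions are clipped at zero on the count scale,
since negative cell counts are not meaningful. Fitted models serialize
to a long-format coefficient CSV (`writeCoefCsv()`) with 17 significant
digits, so published coefficient tables can drive the optimizer with no
raw data and round trips are lossless.

## Desirability optimization

Each fitted response is mapped to $[0,1]$ by a maximize-type
Derringer desirability: 0 at or below $L$, 1 at or above $U$, a power
ramp (weight $w$, default 1) between. The anchors $L$ and $U$ are, by
default, the minimum and maximum predicted count over the experimental
design points — the least-arbitrary way to scale predictions into
$[0,1]$ — and both are overridable per response. Note the consequence:
with design-anchored $U$, every point predicting above the design
maximum scores exactly 1, creating a plateau; analyses that need a
unique interior optimum should set $U$ above the model's global
maximum.

The overall objective is the geometric mean of the individual
desirabilities, so any response at 0 annihilates the whole score and
balanced improvement is favoured over trading one phenotype off to
zero. `optimizeDesirability()` maximizes it with a basin-hopping-style
search: 25 random restarts (uniform in the feasibility ball, via
normalized Gaussian direction times $r\,u^{1/k}$), each alternating
Nelder-Mead local polish with Gaussian perturbation hops (5 hops of
step 0.5 coded units by default). The search is constrained to the
hypersphere $\lVert x\rVert_2 \le \alpha = 2.366$ so that reported
optima are never extrapolations beyond the tested concentration range;
constraint handling is radial projection of candidates onto the sphere
before evaluation, which preserves direction and is smooth enough for
the derivative-free local search. Inside the optimizer the geometric
mean uses desirabilities clipped to $[10^{-12}, 1]$ so the objective
remains informative where a response scores 0; reported scores are
unclipped, and a run in which every restart ends at $D = 0$ is flagged
degenerate rather than reported as an optimum.

The reported optimum is the arithmetic mean of the coded vectors of the
top 5 restart solutions (read as the 5 best restart outcomes, not 5
distinct basins), mapped back to concentrations. Averaging adjacent
near-optimal solutions buys robustness to the flat top of the
desirability surface at the cost of a small bias when the top solutions
straddle distinct basins; the full ranked solution list is retained so
users can detect that case.

## Limiting-dilution frequency estimation

`estimateFrequency()` fits the single-hit Poisson model: a well seeded
with $n$ cells remains negative with probability $e^{-fn}$, where $f$
is the per-cell frequency of cells competent to generate the readout
(here, CD7$^+$ NK/T lymphoid progenitors). The binomial log-likelihood

$$\ell(f) = \sum_i \left[\text{neg}_i\,(-f n_i) +
  (w_i - \text{neg}_i)\log(1 - e^{-f n_i})\right]$$

is maximized over $\log f$ (an unconstrained scale) by bracketed 1-D
search (`stats::optimize`, bracket $f \in [10^{-12},\,
-\log(10^{-12})/\min n_i]$) followed by up to three Newton steps using
the analytic score, which brings the optimum to near machine precision.
The reciprocal $1/\hat f$ — cells per progenitor — is exactly the dose
at which the fitted failure rate is $e^{-1} \approx 0.37$. Confidence
intervals are Wald on $\log f$ by default (cheap, and accurate at the
well counts used here); a profile-likelihood interval is available for
sparse designs. Datasets with no positive wells (or no negative wells)
pin $\hat f$ at a bracket boundary and return `converged = FALSE` with
an explicit flag instead of an infinite estimate. The MLE is used
rather than a regression-style estimator; on data consistent with the
model the two coincide.

The positivity rule that scored wells (e.g. ">25 viable CD7$^+$
cells") is upstream metadata — wells arrive pre-scored.

## Single-cell QC, normalization and the notch activity score

`applyQC()` applies the standard droplet scRNA-seq screen with strict
inequalities: cells with more than 36,000 total counts or more than
6000 detected genes are removed as likely doublets, cells with more
than 18% mitochondrial reads (gene-name prefix `MT-`) as dying, and
genes detected in fewer than 3 remaining cells are dropped ("expressed
in few cells ($n = 3$)" is read as *detected in fewer than 3 cells*;
the boundary matters only for genes in exactly 3 cells, which are
kept). The filter is idempotent, and the report itemizes removals per
rule. `normalizeLog()` scales each cell to $10^4$ counts and applies
the natural-log `log1p` transform.

`scoreSignature()` computes a per-cell activity score for a gene set
(default the notch targets *HES1, CD3D, HES4, DTX1, BCL11B, HEY2*)
normalized against control genes matched on expression level: genes are
ranked by mean normalized expression and cut into `nBins` equal-size
bins (default 25 — unstated in the methods this follows; 25 matches the
common practice of expression-bin scoring and is configurable), and
for each signature gene 50 control genes are drawn from its bin,
excluding all signature genes. The score is the mean over signature
genes minus the mean over the pooled controls. Subtraction (not
division) is the normalization because it makes the null exactly zero
and is translation-detecting — shifting every signature gene by
$\delta$ shifts the score by exactly $\delta$; a ratio mode is kept
behind a flag since the phrase "normalized to the average of reference
genes" admits either reading. Controls are pooled across signature
genes before averaging (variance-stabler than per-gene normalization;
both are linear, so the null-zero property is unaffected). Bins
smaller than 50 after exclusions fall back to sampling with replacement
and flag the result. Bin assignment and sampling order are resolved by
value and gene name, so results are invariant to the storage order of
genes at a fixed seed.

`compareConditions()` reports the fold change of mean scores (defined
only when both means are positive — a subtraction-based score can be
legitimately negative, in which case the fold change is flagged
undefined rather than reported with a misleading sign) and a two-sided
Mann-Whitney rank-sum $p$ value.

## The synthetic-data generators

Every stage has a generator with known ground truth, so the pipeline is
testable end to end without any external data. The generators aim to
emulate the *statistical structure* the estimators assume, plus
controlled violations:

* `genDoseResponse()` evaluates a true polynomial at the design points,
  adds Gaussian noise **on the transformed scale** (matching the
  fitting transform, so least squares is the true MLE and recovery
  tests are exact in expectation), back-transforms, clips at zero and
  rounds to integer counts. No noise model for cell counts is given in
  the methods this emulates; transformed-scale Gaussian noise is a
  stand-in chosen for its estimator-exactness property, and the
  integer rounding adds a small (±0.5 count) perturbation real data
  would not distinguish.
* `genLDAWells()` makes a well negative iff all $n$ seeded cells
  independently fail: probability $(1-p)^n$, the exact
  Bernoulli-per-cell model. The estimator assumes the Poisson form
  $e^{-fn}$, so the generator is deliberately the finer model and every
  recovery test quantifies the approximation gap
  ($\hat f \to -\log(1-p)$, under 1% at the frequencies probed here).
* `genExpression()` draws negative-binomial counts (dispersion 0.1 by
  default — overdispersed but near-Poisson, typical of UMI data) around
  per-gene baseline means, scales mitochondrial genes to carry a
  configured fraction of counts, multiplies signature-gene means by a
  per-condition effect, and appends QC-violating cells (high-count,
  high-gene, high-mito) flagged in the cell metadata. It does not
  emulate ambient RNA, doublet mixtures, batch effects or
  gene-gene correlation; tests passing on this generator therefore
  certify the scoring arithmetic and the QC contracts, not robustness
  to those real-data artifacts.

All generators are bit-reproducible given (truth, seed).

## Problem sizes and tolerances

The test suite exercises: noiseless OLS recovery at $10^{-8}$;
optimizer-vs-analytic optima at $10^{-3}$ in coded units with the norm
constraint checked at $+10^{-6}$ slack; limiting-dilution recovery over
200 simulated assays of 2000 wells (doses 10/30/100/300 at 500
wells each) requiring the median reciprocal within ±10% and ≥90% CI
coverage, plus dominance over a $10^6$-point likelihood grid;
signature-score null centring within 3 standard errors at 300 cells and
exact $\delta$-shift detection; and a two-condition simulation at 500
cells per condition for the Mann-Whitney comparison. These sizes were
chosen to keep Monte-Carlo error well below the tolerance being
checked while remaining quick on a laptop.

## Known limitations

* Desirability shapes are maximize-only; target-value or minimize
  goals, multi-objective Pareto analysis, and two-sided desirabilities
  are out of scope.
* The LDA module fits one sample at a time; it does not test frequency
  differences between groups.
* No lack-of-fit ANOVA beyond $R^2$/adjusted $R^2$; no Box-Cox
  transform search.
* The identities of the cytokines per stage, and which responses used
  which transform in the motivating experiments, are configuration
  decisions, not package defaults.
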