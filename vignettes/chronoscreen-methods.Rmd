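---
title: "Methods: competitive chronological-lifespan screening with chronoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competitive chronological-lifespan screening with chronoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoscreen)
```

## The measurement model

Chronological lifespan (CLS) in budding yeast is the capacity of a
stationary-phase population to resume growth. chronoscreen analyses screens
in which each RFP-labelled deletion strain is aged in co-culture with a
CFP-labelled wild-type (WT) reference and, at each stationary-phase age, an
aliquot is outgrown in fresh medium while OD600, RFP and CFP are read
periodically.

The model assumes stationary-phase death is exponential with a per-day rate
$r$ per strain. The viable inoculum of the outgrowth at age $T$ is then
proportional to $e^{-rT}$, and during exponential outgrowth the
fluorescence ratio at a fixed time satisfies

$$\ln \frac{RFP(T)}{CFP(T)} = c + (r_{ref} - r_{mut})\,T ,$$

so the slope of the log-ratio across ages — the **survival coefficient**
$s$ — directly estimates the death-rate difference. Negative $s$ means the
mutant dies faster than the reference; positive means slower. The intercept
absorbs the mixing ratio, channel gains and growth-rate differences, which
is why the statistic is robust to those nuisances. Saturation of the
outgrowth affects both channels identically and cancels from the ratio.

### Fixed-time interpolation

Signals are interpolated channel-wise at a fixed outgrowth time (default
10 h, within the 14 h sampling window). Interpolation is linear in
*log-signal* space, since growth is exponential at mid-outgrowth; at grid
points the two candidate spaces coincide, and 10 h lies on the default
150-min grid, so the choice only matters for irregular grids. A signal
floor (default 1 fluorescence unit) is enforced before the log; ages where
a channel sits at or below the floor are dropped with a warning, and a
series needs at least three usable ages.

### Robust slope fit

`fit_survival()` fits the log-ratio on age by iteratively reweighted least
squares with Tukey bisquare weights, tuning constant 4.685, and scale
re-estimated each iteration from the median absolute residual
(MAD$/0.6745$). Two numerical details matter:

* **Initialisation.** The bisquare $\psi$ is redescending, so the IRLS can
  be captured by a local minimum when several gross outliers sit at one end
  of the age range; an ordinary-least-squares start (the common default)
  fails exactly there. The fit therefore starts from the Theil–Sen line
  (median of pairwise slopes, 29% breakdown), which places the first
  iteration near the majority of the data. On clean data the result is
  indistinguishable from the classical IRLS.
* **Scale floor.** When the majority of points fit exactly, the MAD scale
  collapses to zero; the scale is floored at $10^{-8}\max|r|$ (and machine
  epsilon) so that gross outliers are still rejected while exactly
  collinear data reduce to ordinary least squares, as it should.

The reported standard error is the weighted least-squares standard error of
the slope at the final weights. Quality control (`qc_filter()`) excludes
strains with fewer than three usable ages, peak fluorescence below 5x the
floor, or saturation OD below half the plate median; the thresholds are
deliberate, configurable stand-ins for the unquantified "slow growth or low
signal" discard rule such screens apply.

## Hit calling and the lifespan-extension statistic

The null distribution of $s$ comes from many independent WT-vs-WT
co-cultures (264 in the genomewide design): `build_null()` takes their mean
$\mu$ and standard deviation $\sigma$, and each mutant gets
$Z = (s - \mu)/\sigma$, a two-tailed normal p-value (the Z framing, not a
t), and a Benjamini–Hochberg correction applied **within each condition**,
mirroring the per-condition "5% FDR" framing of such screens. Rejection is
implemented as the step-up rule directly on the p-values
($p_{(i)} \le \tfrac{i}{m}\alpha$), which is equivalent to thresholding BH
q-values but exact at the boundary.

The **lifespan-extension statistic** for a strain measured under a
non-restricted (NR) and a dietary-restricted (DR) condition is

$$LE = \frac{s_{DR} + 1}{s_{NR} + 1},$$

with $LE = 1$ meaning the diet changed nothing relative to WT, $LE < 1$ a
diminished and $LE > 1$ an enhanced restriction response. $LE$ is undefined
for $s_{NR} \le -1$ (the strain effectively cannot be referenced) and such
strains are excluded with a warning. $LE$ is scored against a WT $LE$ null
built by pairing WT replicate $i$ in NR with replicate $i$ in DR
(plate-position pairing; random pairing is available — the right pairing is
not derivable from the assay description, and with hundreds of replicates
the two give nearly identical nulls). BH runs once across all strains for
$LE$. The **stringency filter** then demotes strains whose $LE$ is
significant but that are neutral in both single-condition calls: a
diet-response call requires at least one supporting CLS phenotype.
`cross_reference_le()` recomputes $LE$ against an alternative reference
screen and tests, by one-tailed Wilcoxon rank-sum, whether a designated
gene set's values skew below or above the rest.

## Small-scale viability kinetics

For single-strain assays, viability is read from outgrowth time shifts: if
an aged culture needs $\Delta t$ longer than the age-0 culture to reach
mid-exponential OD (default 0.3), its relative viability is
$100 \cdot 2^{-\Delta t / t_d}$ with $t_d$ the doubling time. The doubling
time comes from a log-linear fit over the OD window 0.05–0.5; by default
the age-0 doubling time is used for every age (the shift formula needs one
reference $t_d$; per-age doubling times are available as an option).
Censored outgrowths — never reaching the threshold — receive a viability
floor of 0.1% so decay fits remain finite.

Viability curves are fitted by nonlinear least squares (Levenberg–
Marquardt, initialised from the log-linear fit) to $N(T) = N_0 e^{-rT}$.
The **half-life is defined as the fitted curve's 50% crossing**,
$\ln(N_0/50)/r$ — not $\ln 2 / r$ — because fitted $N_0$ routinely sits
slightly off 100%; the two definitions coincide exactly at $N_0 = 100$.
Printed (rate, half-life) pairs from such assays are consistent with the
crossing definition. An increasing viability trend floors $r$ at $10^{-6}$
with a warning. Percent extension between conditions is
$100\,(h_{DR} - h_{NR})/h_{NR}$, reported to the nearest percent: WT
half-lives of 14.7 d (glutamine) and 28.1 d (GABA) give 91%. Death-rate
comparisons between replicate groups use Welch's t-test by default.

## Kappa clustering of diet-response genes

Functional similarity between two genes is Cohen's kappa over their binary
annotation vectors (shared presence *and* shared absence, chance-corrected).
Pairs with $\kappa > 0.35$ — the customary threshold for large annotation
sets — seed clusters; groups sharing at least 50% of their members merge
iteratively until only dissimilar groups remain, and clusters need at least
four members. Two under-determined choices are fixed as defaults and kept
configurable:

* **Overlap denominator**: the smaller group (DAVID-style); Jaccard
  (union) is the alternative.
* **Merge order**: each iteration processes groups in lexicographic order
  of their sorted member ids and merges the first qualifying pair. Merging
  is confluent on almost all real inputs, but a fixed order makes the
  fixpoint deterministic, which testing requires.

Kappa between genes sharing no annotated term is computed normally (it can
be negative), not special-cased. Diminished ($LE<1$) and enhanced ($LE>1$)
gene sets are meant to be clustered separately. The network export writes
SIF-style and weighted-TSV edges plus a node table carrying each cluster's
mean-$LE$ rank for colouring.

## Heat-diffusion ranking of transcription factors

Regulators of a gene set are prioritised by propagating unit heat from each
target gene backward along regulatory edges, discounted by a diffusion
coefficient $d$ (default 0.25) per additional layer: a regulator's weight
is $\sum_{\text{targets}} d^{k-1}$ with $k$ the length of the shortest
directed path from the regulator to the target, truncated at 10 layers.
Each target is counted once, at its nearest layer — this keeps weights
bounded (a TF with four direct targets weighs exactly twice one with two)
and interpretable; an all-paths variant with out-degree normalisation is a
possible extension but is not what the layer-discount description implies.
TF-to-TF edges participate in propagation. Because the published weights of
web-service implementations depend on the particular network snapshot,
this module reproduces the described semantics, not specific numbers.
"Percent regulated" is reported both as reachable-within-depth and as
direct-only, since either reading of the phrase is defensible. Group rank
comparisons use the Wilcoxon rank-sum test, exact for small tie-free
groups.

## The synthetic screen generator

No raw screen deposit is programmatically retrievable, so the generator is
a first-class module that emulates the assay's data-generating process with
known ground truth:

* exponential stationary-phase death at condition-specific rates; WT rates
  default to 0.057/day (glutamine-like NR) and 0.029/day (GABA-like DR), so
  restriction roughly doubles WT half-life;
* 2:1 mutant:reference mixing, outgrowth sampled every 150 min over 14 h,
  exponential regrowth with a ratio-preserving hyperbolic saturation at
  OD 1.2;
* multiplicative lognormal fluorescence noise (CV 0.05), additive OD noise
  (sd 0.005), and gross outliers (default 1% of readings replaced by 10x
  or 0.1x their value) — the case for robust regression;
* 264 WT-vs-WT replicate co-cultures by default;
* a mutant effect mixture: 80% neutral ($N(r_{wt}, 0.005^2)$ per
  condition), 10% short-lived (+0.03–0.10/day), 10% long-lived
  (−0.01–0.025/day), truncated at zero. This mixture is a realistic
  stand-in, not an inference from data; effect sizes draw independently per
  condition so diet-specific responses arise naturally;
* a per-co-culture **well effect** (sd 0.003/day perturbation of the
  realized death-rate difference) applied to mutants and WT replicates
  alike. Screens run many WT-vs-WT replicates precisely because
  experimental well-to-well variance exceeds photometric noise; without
  this term the WT null would be unrealistically tight relative to the
  neutral mutants' scatter and the null-calibration logic of the design
  would not carry over.

The generator does **not** emulate medium chemistry (pH, buffering,
aeration), fluorophore maturation dynamics, strain-strain interactions in
co-culture, or age-dependent noise; conclusions from passing tests are
about the estimator and calling machinery under the stated generative
model, not about any particular laboratory's data. Annotation matrices
plant clusters as shared signature-term blocks (80 terms carried with
probability 0.95 over a 3% background), which puts within-cluster kappa
near 0.56 — comfortably above the 0.35 threshold — while background pairs
sit at 0 in expectation. Regulatory networks plant regulators with direct
and intermediate-TF paths into the target set and give decoys edges only
outside it.

## Problem sizes and reproducibility

The test-suite simulations use screens of 100–500 mutants with up to 264
WT replicates, 200 random instances for the cluster-merge oracle, and 100
random small networks for the diffusion oracle; the demo pipeline runs 200
mutants and 50 WT pairs and completes in seconds. These sizes give the
property checks (FDR control, recovery rates, oracle equivalence) stable
margins while keeping the default test run quick. All randomness flows from
a single seed through per-stage sub-streams; rerunning any pipeline or
generator call with the same seed and configuration is byte-identical.

The end-to-end recovery checks are evaluated pooled over three screens:
the invariant's expected value (roughly 86% of planted hits recovered,
~7% of neutral strains miscalled at 5% FDR) sits near the 80%/10% margins,
and pooling measures the property rather than single-screen sampling
noise.

## Known limitations

* The survival coefficient's standard error uses the final-weights
  weighted-LS formula, which slightly understates uncertainty relative to
  sandwich-type robust variance estimators; the calling machinery never
  uses per-strain errors, only the empirical WT null.
* The LE null pairing and the BH scope (per condition for $s$, global for
  $LE$) are conventions; both are configurable or isolated behind small
  functions.
* With only tens of WT replicates, the null sd estimate is noisy and
  calling power fluctuates between screens; hundreds of replicates (the
  genomewide design) are needed for stable calibration.
* Cluster merging is order-defined; alternative orders can split or join
  borderline groups that overlap near 50%.
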