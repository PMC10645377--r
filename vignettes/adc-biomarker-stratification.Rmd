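---
title: "Methods: biomarker stratification for PBD-payload ADCs in prostate cancer"
author: "adcstratify"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: biomarker stratification for PBD-payload ADCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcstratify)
```

# The problem

Antibody–drug conjugates (ADCs) that deliver a pyrrolobenzodiazepine (PBD)
payload through the B7H3/CD276 surface antigen kill metastatic prostate
cancer (mPC) cells by forming DNA interstrand crosslinks that arrest
replication forks. Target expression is necessary but not sufficient for
response: sensitivity tracks with vulnerabilities to replication stress —
RB1 loss, SLFN11 expression, and crosslink-repair lesions (ATR, CHD1).
`adcstratify` packages the quantitative machinery for this stratification:
dose–response summarization, expression and signature scoring, IHC
quantification, a composite decision engine, and a clinical funnel, plus a
synthetic-data generator that makes every stage testable without primary
data.

# Dose–response: the nAUC statistic

Each assay compares a targeted ADC with a non-binding isotype-control ADC
on the same model, doses ascending to 4 µg/mL, five replicate wells per
dose, two or more independent experiments. Replicates are averaged per
dose and the mean viability curve is integrated by the trapezoidal rule
over $\log_{10}$(dose), normalized by $100 \times$ the log-dose span:

$$\mathrm{AUC} = \frac{\int v(\log_{10} d)\, \mathrm{d}\log_{10} d}
                      {100 \,(\log_{10} d_{max} - \log_{10} d_{min})},
\qquad
\mathrm{nAUC} = \frac{\mathrm{AUC}_{targeted}}{\mathrm{AUC}_{control}}.$$

The AUC definition itself is a design choice (only the ratio is
prescribed by the analyses this package reproduces): integrating on the
log scale with span normalization makes the statistic dimensionless,
invariant to rescaling all doses (e.g. the ng/mL ↔ µg/mL unit change the
readers perform), robust to the dilution grid, and anchored so that a flat
100% curve scores exactly 1 — matching the observation that resistant
models sit near nAUC = 1. nAUC is computed per experiment (never pooled),
then summarized as the median with its IQR; the median drives everything
downstream.

IC50 and MaxR are companions, not drivers: IC50 is the relative
(curve-midpoint) four-parameter-logistic IC50 fitted by
Levenberg–Marquardt on mean viability vs $\log_{10}$(dose), reported only
when the optimizer converges and the estimate is bracketed by the tested
range; a flat curve returns `converged = FALSE` rather than an error or a
fabricated number. A small ladder of starting values guards against
unlucky initial Jacobians. MaxR is the viability at the top dose.
Viability values are used as supplied — no clipping at 100%, since percent
viability is relative to untreated control and can legitimately exceed it.

**Responder threshold.** The observed responder/nonresponder labels of a
model panel are ground truth wherever available. For label-free use,
`call_responder()` applies a strict `median nAUC < 0.75` rule
(configurable, recorded in provenance): published responder ranges
(≈0.2–0.6) and nonresponder ranges (→1) separate cleanly at 0.75, and a
tie is conservatively called a nonresponder.

# Expression normalization and SLFN11 calling

`tmm_normalize()` follows the canonical trimmed-mean-of-M-values recipe
(30% two-sided trim on M, 5% on A, inverse-asymptotic-variance weights,
reference sample at the most typical upper quartile, factors renormalized
to geometric mean 1), computed by edgeR — the implementation behind the
original analyses — and then converts to log2 CPM against the effective
library size with a 0.5 pseudo-count. The test suite holds the factors to
an independently hand-coded oracle at $10^{-10}$.

`ordered_quantile_normalize()` is the rank-based inverse-normal map
$\Phi^{-1}((r - 0.5)/n)$ with average ranks for ties: any strictly
monotone transform of the input yields identical output.

**SLFN11 status** is bimodal in prostate tumors (silenced vs expressed).
The default caller fits one- and two-component Gaussian mixtures
(BIC-selected, via mclust) and assigns positivity by posterior > 0.5 for
the higher-mean component. Two deliberate choices:

* The mixture is fit **on the values as supplied**, not on rank-normal
  scores. A rank-based inverse-normal transform maps *any* sample onto
  exact N(0,1) quantiles, which erases the very bimodality the mixture
  estimates; fitting after such a transform cannot recover an expressing
  fraction. The `quantile_normalize` switch exists but defaults to off.
* This mixture rule is the package's own pluggable operationalization of
  "expressor status" — the exact rule used in the original clinical
  analysis is not public — so every call records its method and
  parameters, a user threshold rule is available, and the funnel accepts
  any caller function.

Degenerate fits (one component preferred, or a component weight < 0.02)
fall back to the threshold rule when a cutoff was supplied, else all
samples are called negative, always with a warning.

# Signature scores and the correlation screen

`ssgsea_score()` implements the single-sample weighted running sum: per
sample, genes are ranked (average ranks for ties) and walked in decreasing
order; the enrichment score sums the difference between the in-set
empirical CDF weighted by $|r|^\alpha$ and the unweighted out-of-set CDF.
$\alpha = 0.25$ is the canonical default. Raw scores are rescaled by the
global max–min range across the whole score matrix (the cited method's
default; disable with `normalize = FALSE`). Scores depend only on
within-sample ranks, hence are invariant to any strictly increasing
per-sample transform — the property the tests exercise — and the
implementation is held to a brute-force gene-by-gene oracle at
$10^{-12}$ over 200 random matrices. The KDE-based variant of gene-set
variation analysis is deliberately not implemented; the running-sum
variant is used for model and clinical data alike, and real signature
gene lists are supplied by the user as GMT files (the shipped GMT is a
placeholder over synthetic gene identifiers, for testing only).

Z-scaling is per signature across the cohort with the sample (n−1) SD.
Phenotypes come from the AR/NE quadrant rule at z = 0 (strictly positive
means active): AR+/NE− ARPC, AR−/NE− DNPC, AR−/NE+ SCNPC, AR+/NE+
amphicrine; the exact published cutoffs are not public, so the thresholds
are configurable and recorded. The correlation screen tests each
signature's z-scores against median nAUC (Spearman by default, two-sided,
Benjamini–Hochberg across signatures, FDR ≤ 0.05), excluding constant
signatures from the ranking; pairwise group comparisons use two-sided
Wilcoxon rank-sum tests with Holm adjustment.

# IHC H-scores

$H = \sum_{i=1}^{3} pct_i \times i \in [0, 300]$; triplicate cores are
averaged over evaluable cores only, a tumor with none is flagged
not-analyzed rather than erroring, and B7H3 positivity is **strictly**
$H > 20$ (a score of exactly 20 is negative, taking the published ">"
literally). The percentage-sum check tolerates ±0.5 to absorb rounded
pathology tables.

# The composite classifier

Rules fire in a fixed order, exactly one per model; the rationale string
names the deciding biomarker:

1. B7H3-negative → ineligible (no target, no delivery);
2. RB1 biallelic loss **or** RepStress z > 1 → responder;
3. SLFN11 expressed → responder;
4. ATR or CHD1 loss of function → responder;
5. TP53 wild-type → nonresponder;
6. otherwise indeterminate.

Replication stress outranks SLFN11 because RB1-deficient models respond
independently of SLFN11 expression; repair lesions come after SLFN11 as
the rarer, rescue-class biomarker (the enumeration (a) replication
stress, (b) SLFN11, (c) repair mutations). The RepStress default of z > 1
is a conservative reading of "above average" for the two RB1-wild-type
responders with elevated scores; it is configurable and recorded. BRCA2
is carried but fires no rule — a BRCA2-deficient, TP53-wild-type model
was nonresponsive, so classical HRD is not presumed sufficient for PBD
response and the TP53 rule dominates. TP53-altered models with no
positive biomarker are left indeterminate rather than forced to
nonresponder, because that cell of the decision schematic is not
classified by the evidence. The rules are total and deterministic, and
flipping RB1 from wild-type to biallelic loss can never demote a
responder (a monotonicity the tests check exhaustively).

# The clinical funnel

`merge_unique()` unifies polyA and capture assays one-record-per-sample,
polyA winning duplicates (configurable; conflicting tumor contents > 0.05
apart warn). `filter_tumor_content()` keeps samples at **≥ 30%** tumor
content — inclusive, following the methods wording "at least 30%" over
the looser "over 30%" phrasing elsewhere. `run_funnel()` then partitions:
RB1 homozygous loss; SLFN11 status among RB1-intact (any caller);
ATR/CHD1 loss among the double-negative remainder; TP53 status last.
Eligibility is the union of the three positive-biomarker branches.
Counting is sample-level throughout, including the stage whose published
phrasing is per patient but whose denominator is samples. Branch counts
provably partition every stage input.

# The synthetic-data generator

The generators define the study conditions the tests run under, and each
draws from its own seed substream so streams do not perturb one another:

* **Counts**: gene means log-normal (log2 mean 5, SD 2), counts
  negative-binomial with dispersion 0.1 — the standard bulk RNA-seq noise
  model, chosen because no expression noise model is prescribed. Planted
  sets shift member-gene log2 means by δ in a labelled sample fraction,
  with the truth table returned.
* **Viability**: 4PL curves on a seven-point serial dilution to 4 µg/mL,
  5 replicates, 3 independent experiments, additive Gaussian noise
  (default 5%, a nominal value — replicate variance is not published —
  always configurable) truncated at 0 but not at 100; control flat at
  100%.
* **Cohort**: Beta(4, 3) tumor content (≈7% of samples below 0.30,
  matching the published 25/328 exclusion rate), independent Bernoulli
  genotypes (RB1 0.10, TP53 0.405, ATR/CHD1 0.02 each — the published
  marginal rates), SLFN11 from a two-component mixture (means 2 and 6, SD
  1, 40% expressing).
* **IHC**: three cores per tumor, Dirichlet-jittered around each
  configured intensity profile; zero-percentage intensities stay exactly
  zero and rows always sum to 100.

What passing tests on these data do **not** show: real RNA-seq has
gene-length and GC effects, correlated genes and batch structure; real
genotypes co-occur (RB1 and TP53 losses are correlated in SCNPC); real
SLFN11 distributions are skewed and assay-dependent. The generators make
the marginals right, not the dependence structure, so they validate the
pipeline's arithmetic and decision logic — not biological effect sizes.

The 26-row annotation panel (`synthetic_model_table()`) is likewise a
*synthetic reconstruction*: its rows are constructed so that every
published panel tally (8/8, 3/11, 7/8, 6/9, 19 + 7 phenotype split,
response-class nAUC ranges) holds simultaneously; it is not a
transcription of measured per-model data, which is not publicly printed.
`synthetic_hill_params()` maps each row's nAUC to a steep 4PL whose
computed nAUC lands on the annotation (verified in tests).

# Numerical choices and degenerate inputs

Ties use average ranks everywhere. The z two-sample convention is the
sample SD (two samples score ±1/√2). Flat dose–response curves are
non-converged, not errors; constant signature vectors are excluded from
FDR ranking; zero-variance signatures and all-identical
quantile-normalization inputs are errors naming the offender; zero-count
samples are errors naming the sample; empty cohorts produce all-zero
funnels. All writers are atomic (temp-then-rename), so failures leave no
partial files, and every pipeline output carries a provenance JSON with
versions, seed, thresholds and input digests.

Problem sizes used by the test and acceptance suites — 200 random 10×6
score matrices, 20 IC50 recovery seeds, 50 null-calibration seeds at 100
signatures × 20 models, cohorts of 10,000, rule-cohorts of 1,000 — were
chosen as the smallest sizes at which the Monte-Carlo error of each check
is comfortably below its tolerance.

# Interfaces

The package's interface is its functions, the `run_pipeline()` driver and
this vignette, in the mold of Bioconductor analysis packages; file
interchange uses plain TSV/CSV/GMT with declared scales and units
(ng/mL converts to µg/mL on read). No shell entry point is shipped:
`run_pipeline()` plus a four-line Rscript covers scripted use, and
`scripts/acceptance.R` is the worked example of exactly that.

# Known limitations

* The real signature gene lists (RepStress, PCa_IFN, RB1, AR, NE) are not
  public; shipped GMTs are placeholders over synthetic identifiers, and
  published correlations (e.g. nAUC vs RB1 score r = −0.64) can only be
  reproduced once the true lists and deposited expression data are
  supplied.
* The SLFN11 rule is this package's mixture default, not the original
  (non-public) rule; fractions near decision boundaries shift with the
  caller.
* The classifier's rule order between SLFN11 and repair lesions is an
  interpretation of a schematic; both orders agree on every profile
  carrying a single positive biomarker.
* Clinical funnel counts on the real cohort require the controlled-access
  tables; the package verifies the funnel's composition law on synthetic
  cohorts instead.
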