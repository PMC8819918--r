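---
title: "Comparing targeted qPCR and 16S amplicon sequencing: models and methods"
author: "ampliBias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing targeted qPCR and 16S amplicon sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliBias)
```

## The problem

High-throughput microfluidic qPCR (HT-qPCR) and 16S rRNA gene amplicon
sequencing measure the same microbial community on fundamentally
different scales. A targeted qPCR panel reports *absolute* abundances —
copies of a species-specific single-copy gene per microlitre of sample —
for the species its assays cover, subject to a detection limit set by
the nanolitre reaction volume. Amplicon sequencing reports *relative*
read counts for every taxon its primers amplify, distorted by
taxon-specific amplification efficiencies and by the variable number of
16S rRNA gene copies per genome (roughly 3–9 in the lactic acid
bacteria that dominate cheese). `ampliBias` implements the statistical
machinery needed to compare the two honestly: rule-based qPCR
quantification, detection classification, compositional bias estimation
with bootstrap uncertainty, taxon-group and gene copy-number
corrections, and dissimilarity/clustering agreement analysis — plus a
synthetic community generator with known ground truth to validate the
whole pipeline.

## qPCR quantification rules

Each assay is calibrated by a standard curve, the least-squares line of
quantification cycle on log10 known copies,

$$C_q = a \cdot \log_{10}(\text{copies}/\mu l) + b, \qquad a < 0,$$

fitted from serial dilutions spanning $10^3$–$10^7$ copies/µl
(`fitStandardCurve()`). The implied amplification efficiency is
$10^{-1/a} - 1$; a perfectly doubling assay has $a = -1/\log_{10} 2
\approx -3.3219$. Per-reaction quantification inverts the line
(`quantifyReaction()`); reactions flagged by the instrument, failing to
amplify, or quantifying below the 800 copies/µl cutoff are negative
calls. Technical triplicates are then combined by the 2-of-3 rule
(`aggregateTriplicates()`): a (sample, assay) result is positive only if
at least two reactions survive the cutoff, and the reported value is the
arithmetic mean *of the positive reactions only* — negative reactions
have no defined copies value, so they cannot enter the mean. Values
above the calibrated range are extrapolated with a warning: the cutoff
already guards the low end, and real communities routinely exceed
$10^5$ copies/µl.

Where the panel resolves subspecies that sequencing cannot (the
*Lactococcus lactis* subspecies), `poolSubspecies()` sums the assay
columns into one species group before comparison; a group is positive
if any member is.

## Harmonizing the sequencing table

`relativeAbundance()` closes each sample over the declared taxon set
(the last column absorbs floating-point rounding so rows sum to 1
exactly). Two corrections mirror the standard post-hoc fixes:

* **Taxon-group merge** (`mergePlantarumGroup()`). V1–V2 amplicons
  cannot distinguish *Lactiplantibacillus plantarum*, *L. pentosus* and
  *L. paraplantarum*; the sequencing side merges
  *pentosus* + *plantarum* and the qPCR side
  *plantarum* + *paraplantarum* into one common "L. plantarum group"
  column, making the two tables describe the same taxon.
* **Gene copy-number normalization** (`gcnNormalize()`). Read counts
  are divided by each taxon's mean 16S copies per genome, approximating
  genome-level abundance. Mean (not median) copy numbers are used, and
  the choice is configurable; a constant copy-number map is provably a
  no-op on proportions, which the tests exploit.

Taxon labels are matched case-sensitively after whitespace
normalization, with an optional synonym map for pre-reclassification
genus names (`normalizeTaxa()`).

## Detection classification and agreement

`classifyDetections()` partitions every (sample, taxon) cell into
`shared_positive`, `qpcr_only`, `ngs_only` (panel taxa),
`ngs_exclusive` (taxa outside the panel with reads) and `undetected`.
Positivity is operational: a non-missing qPCR value (the cutoff and
triplicate rules having been applied upstream) and at least one read.
`coverageStats()` reports the percentage of each sample's reads falling
on shared-positive taxa; `logLogR2()` / `linearR2()` give pooled
coefficients of determination between the paired measurements.

Profile-level agreement uses the Bray–Curtis dissimilarity
$\sum_i |x_i - y_i| \,/\, \sum_i (x_i + y_i)$ between each sample's two
method profiles, renormalized over the shared taxon set, and UPGMA
(average-linkage) clustering of all $2N$ profiles
(`clusterMethodProfiles()`). A sample "agrees" when its two profiles
end up as sibling leaves. Labels are sorted lexicographically before
clustering so equal-distance merges resolve deterministically across
platforms.

## The compositional bias model

The core estimator treats sequencing as a compositional measurement
with taxon-specific multiplicative efficiencies. If sample $i$ has true
(reference) proportions $p_{it}$ and the observed method measures
proportions $q_{it} \propto p_{it} B_t$, then the observed/reference
ratio satisfies

$$\log r_{it} = \log B_t + \log c_i + \varepsilon_{it},$$

with a free per-sample constant $c_i$ absorbing the compositional
closure. $B_t$ — the taxon's efficiency relative to the geometric mean
efficiency of all taxa — is identified only up to a constant, fixed by
the constraint $\sum_t \log B_t = 0$ (geometric mean 1). Because only
proportion *ratios* enter, the estimate is invariant to rescaling any
sample's vector: bias is independent of the sample's composition. This
invariance, and the reciprocality $B \to 1/B$ under swapping observed
and reference, are tested as properties on random instances.

`buildPairedCompositions()` prepares the input: per sample, the taxon
subset is the panel taxa the reference detected; observed zeros on that
subset receive a pseudocount of 1 read *before* renormalization (a
proportion-floor variant was considered and rejected — the pseudocount
is a count by construction); samples with fewer than two
reference-positive taxa are dropped with a warning, since a one-taxon
composition carries no ratio information. `estimateBias()` fits the
two-way model by least squares over all present cells, which handles
the ragged per-sample subsets of real panels; the co-occurrence graph
of taxa must be connected, otherwise components are reported in the
error. With complete data the fit reduces to the closed form

$$\hat B_t = \Big[\prod_i \frac{r_{it}}{(\prod_{t'} r_{it'})^{1/T}}\Big]^{1/n},$$

kept as `estimateBiasClosedForm()` purely as a cross-check oracle.

Uncertainty comes from resampling whole samples with replacement
(`bootstrapGSE()`, default 1000 replicates): the geometric standard
error of taxon $t$ is $\exp(\mathrm{sd}(\log \hat B_t))$ over the
replicates in which the taxon was estimable. Sample-level resampling
respects within-sample dependence. Two edge rules: replicates whose
resampled co-occurrence graph is disconnected are skipped entirely (the
joint estimate is unidentified there), and taxa informed by a single
sample get `NA` — a spread estimated from one observation is
undefined. Reported intervals are multiplicative,
$(\hat B/\mathrm{GSE}^2,\ \hat B \cdot \mathrm{GSE}^2)$
(`gseInterval()`). All geometric means are computed in log space.

## The synthetic community generator

`simulateTruth()` states a world resembling a 21-sample semi-hard
raw-milk cheese survey and makes no claim beyond it:

| parameter | default | why |
|---|---|---|
| samples × taxa | 21 × 20 | the study design being emulated |
| abundance | lognormal, meanlog $\log(2 \times 10^4)$, sdlog 2 (copies/µl) | spans $\sim 10^3$–$10^7$ copies/µl, the range targeted panels report |
| absence probability | 0.2 per cell | ragged detection around a shared core |
| efficiency | lognormal, sdlog 0.5, geometric mean 1 | order-of-magnitude efficiency spread |
| 16S copies | uniform on {3, …, 9} per taxon | the range typical of prevalent dairy species |
| depth | 471,184 reads/sample | a realistic mean amplicon depth |
| detection limit | 800 copies/µl | the microfluidic-chip recommendation |

Sequencing observation (`observeNGS()`) draws multinomial reads with
probabilities proportional to abundance × copy number × efficiency, so
the true sequencing bias relative to qPCR is copy number × efficiency
renormalized to geometric mean 1 (`trueBias()`). qPCR observation
(`observeQPCR()`) emits technical triplicates with multiplicative
lognormal noise of mean 1 and coefficient of variation `cv` on the
*copies* scale — noise on the Cq scale was rejected because it would
make the 800 copies/µl censoring threshold uninterpretable — converted
to Cq through a simulated curve (slope −3.3219, intercept 38,
overridable). Records are emitted even below the detection limit;
censoring is the quantification step's job. One root seed spawns child
streams per operation, so partial reruns reproduce.

What the generator does **not** emulate: sequence-level artefacts
(primer mismatches at base resolution, chimeras), taxonomic
misassignment, extraction bias, overdispersion beyond multinomial
sampling, and correlated absences (cells are zeroed independently). A
green recovery test therefore establishes that the estimator inverts
the *stated* measurement model under censoring and realistic noise —
not that real communities obey that model.

## Numerical choices and degenerate inputs

* Standard-curve fitting requires ≥ 3 points spanning ≥ 2 orders of
  magnitude; R² is computed directly from residuals (avoiding
  `summary.lm()`'s perfect-fit warning on exact standards).
* Cq values past the 30-cycle run length are no-amplification records.
* The triplicate rule errors on ≠ 3 replicates unless
  `allowIncomplete = TRUE`, which applies the ≥ 2-positive rule to
  however many exist.
* Bray–Curtis on two all-zero vectors is an error, not 0/0.
* UPGMA requires a symmetric, zero-diagonal, nonnegative matrix; leaf
  heights are half the cophenetic distance, so tip-to-tip path lengths
  reproduce the merge distances and ultrametric inputs are reproduced
  exactly.
* `relativeAbundance()` errors on zero-total rows, naming the sample.

## A small worked run

```{r example, eval = FALSE}
truth <- simulateTruth(nSamples = 21, nTaxa = 15,
                       efficiencyLogSd = 0.5, depth = 5e5, seed = 42)
ngs <- observeNGS(truth)
qpcr <- quantifyReactions(observeQPCR(truth, cv = 0.1),
                          defaultStandardCurve(), cutoff = 800)
report <- runPipeline(qpcr, ngs, copyNumbers = taxonCopyNumber(truth),
                      nBootstrap = 1000, seed = 43)
gseInterval(report$variants$raw$bias)
```

The package's test suite runs exactly this configuration and checks
that the estimated bias matches `trueBias(truth)` in rank order
(Spearman ρ > 0.9) and magnitude (max |log₂ error| < 0.5), with ±2 GSE
intervals covering the truth for most taxa.

## Known limitations

* The bias model assumes one multiplicative efficiency per taxon,
  constant across samples; efficiency–composition interactions are not
  modelled.
* qPCR is treated as the reference, but it carries its own biases; the
  estimate is strictly a *differential* bias of sequencing relative to
  qPCR.
* Taxa never co-detected with the rest of the panel are inestimable
  (disconnected graph), and single-sample taxa get point estimates
  without uncertainty.
* The packaged per-sample coverage table ships printed percentages at
  two decimals; summaries recomputed from it inherit that rounding.
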