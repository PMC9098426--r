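---
title: "Methods: circadian rhythmicity and alternative splicing from time-course transcript abundances"
author: "circasplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian rhythmicity and alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circasplice)
```

# Scope

`circasplice` analyses bulk time-course RNA-seq at the transcript level,
starting from abundance matrices (TPM and estimated counts) rather than
reads. It answers four questions about a circadian experiment with a
reference line and one or more clock-gene knockouts:

1. Which transcripts and genes oscillate with a ~24 h period?
2. Which local alternative-splicing events (A3, A5, AF, AL, MX, RI, SE) are
   actively used, and which are gained or lost in a knockout?
3. Which events change inclusion levels significantly between conditions?
4. Which within-gene isoform pairs are rhythmic with *different* rhythms —
   in particular, phase-shifted relative to each other?

A synthetic-data generator with complete ground truth stands in for the
sequencing experiments, so every stage is testable end to end.

# Normalization

Raw transcript counts are scaled with trimmed-mean-of-M-values (TMM)
factors (computed by edgeR behind `tmm_factors()`): per sample against a
reference column, log2 ratios are trimmed 30% on M and 5% on A and averaged
with inverse asymptotic-variance weights; factors are rescaled to geometric
mean one. CPM uses the effective library size `N_k * f_k`. Features with
mean CPM below 0.5 over all samples of a condition are removed and the
retained set is renormalized (`filter_low_expression()`; reusing the
original factors is available via `refresh_factors = FALSE`, but
recomputation is the default because the filtered composition is what later
stages see). Conditions are normalized separately, mirroring per-cell-line
analyses. Gene-level series are exact sums of transcript values
(`summarize_to_gene()`), the same summarization tximport applies.

Units are tracked on every matrix: rhythm detection accepts unlogged CPM
(or TPM) and refuses raw counts; PSI requires TPM.

# Rhythm detection

Each feature series $y(t)$ is tested for 24 h rhythmicity and then
parameterized by the cosinor model

$$y(t) = M + A\cos\left(\frac{2\pi (t-\phi)}{\tau}\right) + \varepsilon,$$

fitted by least squares via the linear form $a\cos\omega t + b\sin\omega t$.
$M$ is the mesor, $A = \sqrt{a^2+b^2}$ the amplitude, $\phi$ the acrophase
(time of fitted maximum, hours modulo the period, in sample-time
coordinates; no zeitgeber adjustment) and rAMP $= A/M$ the relative
amplitude on the linear scale. A constant series yields $A = 0$, rAMP 0 and
an `NA` acrophase.

The default significance test is nonparametric: sampling times are folded
modulo the period into phase groups, and a Mack–Wolfe umbrella rank
statistic — standardized by its exact null moments and maximized over all
circular placements of the umbrella peak — is referred to a seeded
permutation null (`rhythm_test(method = "rank_umbrella")`). This targets
the same alternative class as umbrella-based rhythm detectors (a rise to a
peak and fall within the cycle, with no waveform assumption) while keeping
the null distribution exactly testable: for eight or fewer samples the
permutation distribution is enumerated exhaustively, and an exactly
constant series gives $p = 1$ by convention. It is an approximation of that
family of detectors, not a re-implementation of any of them; a parametric
cosinor F-test (`method = "harmonic_F"`) is included for cross-checks. Ties
are handled with midranks; the permutation count defaults to 1000 (p-value
floor $1/(B+1)$), and the same seeded permutations are shared across the
features of a matrix.

A feature is called rhythmic when its Benjamini–Hochberg q-value (adjusted
across all features of the matrix, i.e. per condition and level) is below
0.05 **and** rAMP $\ge$ 0.1. The amplitude gate removes statistically
significant but biologically negligible oscillations.

`gene_transcript_discordance()` contrasts the two levels per gene:
`transcripts_only` captures, e.g., antiphase isoform pairs that cancel into
a flat gene signal, and `gene_only` the converse case where individually
sub-threshold transcripts sum to a detectable gene rhythm.

# Local splicing events and PSI

`extract_events()` enumerates the seven local event modes from exon/junction
coordinate signatures with strict boundary matching, per gene (overlapping
genes never mix). Any number of transcripts may support an event; the
inclusion and total transcript sets are unions over compatible transcripts.
Donor/acceptor and first/last semantics follow the direction of
transcription, so mirroring a gene's coordinates while flipping its strand
preserves event labels. Two junctions sharing an acceptor are classified as
alternative 5' sites when the alternative donor exons overlap, and as
alternative first exons when those exons are disjoint terminal exons (and
symmetrically for A3/AL); this disambiguation is a package convention, as is
the choice of inclusion form per mode: SE — the exon-containing form; RI —
the intron-retaining form; A5/A3 — the longer exonic extension (shorter
intron); MX — the transcription-direction upstream internal exon; AF/AL —
the more distal alternative terminal exon.

PSI of an event in a sample is the TPM of the inclusion transcripts over
the TPM of all event transcripts; it is undefined where the denominator is
zero, and mean PSI averages the defined samples of a condition. An event is
"spliced" when its mean PSI lies strictly in (0.1, 0.9); events defined in
fewer than half of a condition's samples are excluded from that condition's
gene sets (the data do not state how missingness was handled; this is the
package's choice). A gene is spliced by mode E if any of its type-E events
is spliced. Gain/loss between knockout and control compares these per-mode
gene sets; `shared`/`absent` complete the partition over genes testable in
either condition.

Differential splicing compares per-sample PSI vectors between conditions
with a two-sided Mann–Whitney test (midranks; exhaustive enumeration when
both sides have at most eight defined samples, normal approximation with
tie correction otherwise; no continuity correction) at p < 0.05. A
rank test across time-course samples replaces resampling-based ΔPSI nulls
designed for replicate pools, because the time-course design supplies 16
samples per condition and no replicate pool; the decision rule (p < 0.05)
is unchanged.

# Differential rhythmicity of isoform pairs

Within one condition, every unordered pair of rhythmic transcripts of the
same gene is tested. Both series are first standardized to unit mesor so
that pure expression-level offsets cannot register as rhythm differences
(raw-scale testing via `standardize = FALSE`); a joint harmonic regression
with series-indicator interaction terms is then fitted and the equality of
the two (cos, sin) coefficient pairs tested with a 2-df F-test. A single
well-defined test with the same decision rule (BH FDR < 0.05) replaces
ensemble meta-p constructions whose composition is not specified; this is
documented as an approximation. The circular phase difference
$\Delta\phi = \min(|\phi_a-\phi_b|,\, \tau - |\phi_a-\phi_b|) \in [0, \tau/2]$
and the amplitude ratio (rAMP of the lexicographically later transcript
over the earlier; the ordering convention fixes an otherwise
underdetermined axis) come from the separate cosinor fits. Pairs with
q < 0.05 and $\Delta\phi \ge 3$ h are "phase-shifted"; phase bins use 3-h
edges (`<3`, `[3,6)`, `[6,9)`, `>=9`, the last closed at 12 by the circular
bound), and each pair carries its unordered biotype pairing.

# Gene sets and enrichment

Splicing-factor and cancer-hallmark collections load from two-column TSV or
GMT files. `sf_rhythm_matrix()` reports, per SF gene and condition, whether
at least one transcript is rhythmic, plus the SFs losing rhythmicity in
every knockout. Over-representation uses the upper-tail hypergeometric
probability with BH adjustment across sets; the universe defaults to the
expressed genes after filtering (a common, but not unique, choice — it is
configurable by passing any universe).

# The synthetic generator

`simulation_design()` defaults to the study design the package targets: 16
timepoints every 3 h from t = 9 h (spanning 45 h), one replicate per
timepoint (replicates configurable; the sequencing depth of the emulated
experiments is one library per timepoint), conditions labelled with the
reference first. `generate_annotation()` builds two-transcript toy genes
realizing each requested event mode with randomized exon/intron lengths
(50–250 bp) on alternating strands. `simulate_timecourse()` evaluates each
transcript's cosinor expectation, applies condition effects (rhythm loss,
phase shift, amplitude scaling, expression knockout, isoform switches that
preserve the gene total), multiplies mean-preserving log-normal noise with
log-sd $\sqrt{\log(1+\mathrm{cv}^2)}$, and draws counts as Poisson with a
configurable library size (default $10^6$) allocated proportionally to
TPM × summed exon length. Transcript effective length is the summed exon
length — no fragment-length modelling at this scale.

The generator emulates rhythmic mean structure, multiplicative biological
noise, count sampling and programmed condition effects. It does **not**
emulate quantification uncertainty from read mapping, length biases beyond
TPM, batch effects, autocorrelated noise, or realistic isoform complexity
(toy genes have two isoforms). Passing tests therefore demonstrate the
correctness and calibration of the statistical machinery under the stated
noise model, not performance on real sequencing data.

# Numerical choices and problem sizes

- Amplitudes below `1e-10 * max(|M|, 1)` are snapped to zero and the
  acrophase set to `NA` (degenerate/constant series).
- Permutation p-values count ties at `>= obs - 1e-9` and use the add-one
  estimator $(1+b)/(B+1)$; exact enumeration divides by the number of
  permutations and includes the identity, so p = 1 for fully tied data.
- BH is applied once per matrix (per condition and feature level) and once
  per condition over isoform pairs.
- The test suite and the acceptance script exercise the pipeline at sizes
  chosen to make Monte-Carlo assertions stable while staying desk-scale:
  2000 features for the type-I error run, 500 + 500 features for rhythm
  recovery, 56 genes for event-extraction oracle equivalence, 40 genes for
  gain/loss recovery and 60 isoform pairs for differential rhythmicity.
- Under the recovery conditions (rAMP 0.3, noise CV 0.1, 16 timepoints)
  the acrophase standard error of a single fit is ≈ 0.45 h, so
  phase-difference estimates carry an irreducible ≈ 0.64 h standard error;
  accuracy assertions therefore bound the median error, not each pair.

# Known limitations

- The rhythm test assumes a single peak per period (umbrella alternative);
  multimodal waveforms lose power.
- Fixed known period (24 h by default); no period scanning.
- Event extraction uses strict boundary matching: alternative events whose
  flanking exon boundaries differ between transcripts are not merged.
- The Mann–Whitney differential-splicing test treats time-course samples as
  exchangeable replicates within condition; strong shared rhythmicity of
  PSI itself would violate independence.
- Enrichment assumes the supplied universe is the correct background;
  results shift with that choice.
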