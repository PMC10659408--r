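---
title: "recseq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{recseq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical models it
implements, the tunable parameters that matter, what the synthetic-data
generator does and does not emulate, and the design decisions taken
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The measurement model

A recruitment-sequencing experiment reads out 48S preinitiation
complexes (PICs) frozen on start codons of a whole-transcriptome mRNA
pool. After RNase digestion, each PIC protects a 25–34 nt fragment
whose 5' end lies, for the canonical geometry, 12 nt upstream of the
AUG in the P site. All analysis happens in transcript coordinates
(1-based, 5'→3'); signed positions relative to the main AUG use the
convention A-of-AUG = +1 with no position 0, so "−12" is the twelfth
nucleotide upstream.

P-site assignment adds a fixed offset (default 12, configurable per
footprint length via `psite_config()`) to the 5' end. Region counting
is pure closed-interval membership on the signed P-site:

| window | interval | count |
|---|---|---|
| main AUG | [−3, +6] | mRPF |
| upstream | [5' end, −5] | uRPF |
| internal | [+9, stop end] | iRPF |
| CDS | [−3, stop end] | cdsRPF |

Two deliberate gaps follow from taking the stated bounds literally:
position −4 belongs to neither uRPF nor mRPF, and +7/+8 to neither
mRPF nor iRPF. The CDS window starts at −3 rather than +1 so that
cdsRPF ⊇ mRPF ∪ iRPF and the occupancy ratio RRO = iRPF/cdsRPF is a
true fraction; a `cds_from` switch restores the narrower reading,
which differs only for reads at −3..−1.

## 2. Spike-in normalization

Each sample receives a constant amount of pre-formed 48S PICs on two
non-native luciferase mRNAs. Counting the same [−3, +6] window around
every spike AUG category gives a per-sample count vector; the
per-sample **geometric mean** of those counts, divided by the maximum
across samples, is the size factor (so the best-recovered sample has
factor 1 and all factors lie in (0, 1]; normalized = raw / factor).
The geometric mean matters because library construction distorts
categories multiplicatively (exponential amplification): for any
distortion of the form `count = true_k · loss_s · exp(g_s z_k)` with
zero-sum log biases `z_k`, the geometric mean cancels the distortion
exactly while the arithmetic mean does not — this is encoded as a
regression test. Zero spike categories are an experimental failure and
raise an error by default (`zero_policy = "strict"`); `"drop"` removes
the category symmetrically across samples for robustness analyses.

Spike factors enter the differential tests as *fixed* size factors and
are never re-estimated from transcriptome counts: with a limiting PIC
pool, most of the transcriptome can genuinely shift in one direction,
which is exactly the situation median-of-ratios normalization would
erase.

## 3. Differential recruitment

A deliberately owned, simplified DESeq2-style pipeline (DESeq2 itself
is not a dependency; Cook's filtering, independent filtering and LFC
shrinkage are omitted):

1. **Filtering** — transcripts with total raw reads above a threshold
   (strict `> t` or `>= t`, both used in practice: > 90 across 9
   samples for a 3-condition design, ≥ 8 across 4 for a 2-condition
   design).
2. **Dispersion** — per-gene method-of-moments estimates from pooled
   within-condition variances of normalized counts, kept *unclipped*
   (negative values included) for trend fitting; an `a0 + a1/mean`
   trend fitted by least squares on equal-size bin means; arithmetic
   shrinkage of per-gene values toward the trend with weight 0.7.
   The choices are calibration-driven: clipping before averaging
   inflates the trend, log-space averaging of a right-skewed estimator
   deflates it, and with 2–3 replicates the per-gene estimate carries
   so little information that strong shrinkage is what makes the Wald
   test hold its nominal size (the acceptance suite checks type-I
   error in [0.03, 0.07] at p < 0.05 on null simulations).
3. **Wald test** — per group, the NB mean `mu_i = s_i q` is fitted by
   Newton iteration on the score `sum (y_i − s_i q)/(1 + α s_i q)`,
   vectorized across genes; the statistic is `log(q_B/q_A)` over its
   expected-information standard error, two-sided normal. Genes with
   one all-zero group fall back to a score test at the null fit, so no
   pseudocount ever enters a test statistic; the 0.5 pseudocount on
   normalized counts affects only the *reported* log2 fold change of
   such genes. Genes zero everywhere get p = 1 and a flag.
4. **BH adjustment** (own step-up implementation, oracle-checked
   against `p.adjust`) and **classification**: up = FDR < 0.05 and
   FC > 2; down = FDR < 0.05 and FC < 0.5. Fold-change gating uses the
   unshrunken estimate, since thresholded raw ratios are what the
   downstream calls quote.

One stated invariant was weakened deliberately: multiplying one
sample's counts and its size factor by the same constant leaves every
normalized quantity identical, but cannot leave an NB Wald statistic
bit-identical — the rescaled sample genuinely carries more counts and
hence more Fisher information (DESeq2 behaves the same way). The test
asserts exact invariance of normalized outputs and agreement of the
thresholded calls.

## 4. Efficiencies and classifiers

* mRNA density = RNA-seq 5' ends inside [cds_start, cds_end] / CDS
  length; RE = normalized mRPF / density (transcripts with zero
  density are excluded, never infinite); RRO = iRPF/cdsRPF (NA when
  cdsRPF = 0; iRPF > cdsRPF is an internal error).
* Condition-level metrics are computed from replicate means of
  spike-normalized counts before ratioing (ΔRE, ΔRRO); per-replicate
  tables remain available. Whether the original workflow averaged
  before or after ratioing is not documented; ratio-of-means was chosen
  because it is the lower-variance estimator for small counts.
* The **leaky-scanning classifier** builds three nested sets from the
  mRPF and iRPF contrasts: significantly down in mRPF; additionally
  significantly up in iRPF; and additionally `ΔiRPF ≥ 0.5 · (−ΔmRPF)`
  in normalized read units — the reciprocity expected if internal
  footprints are PICs that scanned past the main AUG. The
  upstream-initiation classifier mirrors this (uRPF down, mRPF up,
  `−ΔuRPF ≥ 0.5 · ΔmRPF`). Reciprocity compares condition-level
  normalized count differences because the criterion is phrased in
  absolute read units.
* Translatome-wide uRPF/mRPF ratios exclude flagged outlier
  transcripts (a GCN4-like 5'UTR can carry half of all upstream
  footprints); the excluded transcripts' shares are reported
  separately.

## 5. Feature summaries

PARS-style per-nucleotide structure scores are summarised as: Total
(sum over the 5'UTR), Max30 (maximum 30-nt window sum within the
5'UTR; for 5'UTRs shorter than 30 nt the full-UTR sum — the truncated
window reading, configurable), Start30 (sum over −15..+15 around the
AUG, defined only for 5'UTRs ≥ 15 nt), and Plus15/30/45 (30-nt sums
starting at signed +15/+30/+45; the original anchoring is defined in
prior work not restated here, so the anchors are configurable).
Context scores are the geometric mean of position-specific
relative-adaptiveness weights at −6..−1 and +4..+6 around the AUG;
the bundled weight matrix is synthetic (built for testing, A-rich
consensus) and real-data use should supply a matrix derived from a
reference set of highly translated transcripts.

Equal-size binning sorts stably by (value, id) and cuts contiguous
blocks whose sizes differ by at most one, extras going to the lowest
bins — deterministic under ties by construction.

## 6. The synthetic world

The generator emulates the generative process the analysis assumes:

* ~10³ transcripts with log-normal 5'UTR lengths (median 50 nt,
  sdlog 0.7) and CDS lengths (median 1200 nt, multiple of 3), random
  sequences with guaranteed AUG/stop, upstream AUGs read off the 5'UTR
  sequence and internal AUGs enumerated in all frames at absolute
  positions ≥ cds_start + 9.
* Competition for a limiting PIC pool (default 2×10⁵ per sample):
  multinomial allocation with weight
  `abundance · exp(−α·Max30 − β·utr5_len) · (1 + S·c/(c+K))`,
  K = 100 nM (stimulation near-saturated at 100 nM). The amplitude S
  is structure-dependent (`S = 3 × penalty`, the Ded1-like world),
  uniform (the eIF4A-like world), or planted on a random 10% subset
  (S = 6, i.e. ≥ 4-fold at 500 nM) for recovery tests.
* Context-dependent leaky scanning `leak = 0.08·exp(−2·context)`
  (translatome average ≈ 3% at zero helicase), multiplied uniformly by
  condition (defaults 1 / 1.4 / 1.7 across 0 / 100 / 500 nM — the
  ~1.7× readthrough increase corresponds to a flat log₂ΔRRO curve of
  ~0.75). After readthrough the PIC lands on downstream internal AUGs
  under a geometric stop rule (p = 0.5 per AUG). Planted-leaky
  transcripts jump 0.15 → 0.75 at the top concentration: a clearly
  reciprocal main-to-internal conversion, chosen because a planted
  fold change sitting exactly on the 0.5 significance gate is
  undetectable in principle at desk-scale depth.
* Rare upstream initiation (2×10⁻³ per PIC where an upstream AUG
  exists) and one GCN4-like outlier with ~50× upstream activity,
  flagged for exclusion from translatome totals.
* Spike-ins as constant expected category counts scaled by per-sample
  recovery losses (log-uniform in [0.25, 1] by default), Poisson
  noise; transcript counts get two-stage gamma–Poisson noise
  (dispersion 0.05) applied per transcript after allocation — the
  mean–variance structure the NB tests assume — then binomial loss
  thinning.
* Footprint lengths 25–34 nt (mode 28–29) and 5'-end jitter −2..+2
  around −12 (72% mass at −12, slight downstream skew). The stated
  length spectrum is not published beyond the 25–34 range and −12
  mode; the defaults are free parameters fixed once here.
* RNA-seq as uniform fragment 5' ends at 2.3 expected reads/nt for a
  median-abundance transcript.
* `noise = "none"` switches every stage to exact expectations
  (fractional counts) for identity tests; one RNG stream per
  (sample, stage) keeps stages independently reproducible.

What it does **not** emulate: sequence realism (codon usage, GC),
rRNA/ncRNA contamination, 60S joining or elongation, 5'-truncated
mRNA isoforms, or genome-coordinate complications (spliced
transcripts, strands). A green test therefore establishes correctness
of the counting, normalization, testing and classification machinery
under the stated generative assumptions — not robustness to artefacts
these simplifications exclude.

## 7. Numerical choices and degenerate inputs

* Geometric means require strictly positive counts; zeros are handled
  by policy (strict error / symmetric drop), never by pseudocounts.
* The dispersion floor is 10⁻⁸; all-zero genes take the trend value at
  a nominal mean of 1.
* Newton iterations for the NB mean run to a 10⁻¹⁰ relative step with
  halving safeguards; expected (not observed) information is used for
  standard errors.
* Footprints that would extend beyond transcript bounds (5'UTRs
  shorter than ~12 nt) are dropped with a tallied warning, and the
  planted truth carries the same survival probability so expected and
  emitted counts agree.
* Equal-size bins, rank heat-maps and the wiggle writer break ties by
  transcript id; wiggle values round-trip at 10⁻⁶.
* Acceptance thresholds for "flat" curves were fixed from the
  generative math before measurement: a uniform readthrough multiplier
  bounds the per-bin ΔRRO spread at max/min ≤ 1.25 while the baseline
  RRO spans ≥ 1.5× across context bins; uniform stimulation bounds the
  ΔRE bin-median spread at 1.2× while structure-dependent stimulation
  must at least double from the first to the sixth PARS bin.

## 8. Known limitations

* The NB pipeline is intentionally simpler than DESeq2 (no outlier
  replacement, no independent filtering, no LFC shrinkage); exact
  numerical agreement with DESeq2 is not claimed anywhere.
* Wald calibration was tuned for 2–3 replicates per condition; designs
  with many replicates would warrant weaker shrinkage
  (`shrink_weight`).
* The context-score matrix is synthetic; scores on real data require a
  user-supplied model or precomputed values.
* Transcript-space wiggle tracks substitute for genome-coordinate
  (Watson/Crick) tracks; there is no strand or splicing logic.
* The CLI is a thin orchestration layer; multi-factor designs and
  workflow-engine integration are out of scope.
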