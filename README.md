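# recseq

Analysis of in vitro 48S preinitiation-complex (PIC) recruitment
sequencing data in transcript coordinates, together with a fully
parameterised synthetic-data generator that makes every stage of the
pipeline testable against planted truth.

## The problem

Recruitment sequencing monitors the earliest steps of translation
initiation: 48S PICs are assembled on a whole-transcriptome mRNA pool
in a reconstituted system, the unprotected mRNA is digested, and the
ribosome-protected fragments (25–34 nt) are sequenced in transcript
space. The questions the analysis answers are

* how many PICs sit on each start codon (main AUG, upstream AUGs in
  the 5'UTR, internal AUGs inside the CDS),
* how that changes when an RNA helicase (e.g. a Ded1- or eIF4A-like
  factor) is titrated into the reaction, and
* whether those changes track 5'UTR length, RNA structure, or start
  codon context.

The core quantities, in the field's notation:

* **P-site assignment** — the P-site codon of a footprint with 5' end
  at position *x* is at *x* + 12; footprints cluster with 5' ends 12 nt
  upstream of the AUG they initiate on.
* **Region counts** — per transcript, footprints with P-sites in
  [−3, +6] around the main AUG are **mRPF**s, in [+9, stop] **iRPF**s,
  in [5' end, −5] **uRPF**s, and in [−3, stop] **cdsRPF**s (signed
  coordinates with A of the AUG = +1, no position 0).
* **Size factors** — each sample carries constant spike-in 48S PICs on
  two luciferase mRNAs; the per-sample geometric mean of spike category
  counts, rescaled to the best-recovered sample, converts counts to a
  common absolute scale (`normalized = raw / size_factor`).
* **RE (recruitment efficiency)** — normalized mRPF divided by mRNA
  density (CDS RNA-seq reads per nt); the in vitro analogue of
  translational efficiency.
* **RRO (relative ribosome occupancy)** — iRPF/cdsRPF, the fraction of
  CDS-mapped PICs at internal AUGs; its change between conditions
  measures induced leaky scanning.
* **Differential recruitment** — per-region negative-binomial Wald
  tests with the spike factors as fixed size factors, BH-adjusted, with
  significance at FDR < 0.05 and fold change > 2 (or < 0.5).
* **Leaky-scanning calls** — transcripts whose mRPFs drop
  significantly, whose iRPFs rise significantly, and whose iRPF gain is
  at least 50% of the mRPF loss in normalized read units.

## Worked example

```r
library(recseq)

cfg <- synthetic_config(n_transcripts = 60, pic_pool = 5e4)
exp <- simulate_experiment(cfg, seed = 7)

ann    <- rbind(exp$tx$annotation, spike_annotation(cfg$spike_reference),
                fill = TRUE)
counts <- count_regions(exp$footprints, ann)
sf     <- compute_spike_size_factors(
            count_spike_categories(exp$footprints, cfg$spike_reference))
sf$table[1:3]
#>      sample_id geo_mean size_factor is_reference
#> 1:  ded1_0_rep1 724.7133   0.7916137        FALSE
#> 2:  ded1_0_rep2 402.6739   0.4398459        FALSE
#> 3:  ded1_0_rep3 915.4886   1.0000000         TRUE

m <- build_metagene(exp$footprints, ann)
metagene_modal_offset(m)
#> [1] -12
```

The size factors recover each sample's simulated recovery loss (the
reference sample, factor 1, is the best-recovered one), and the
metagene mode confirms the footprint geometry: the bulk of 5' ends sit
12 nt upstream of the main AUG, the position expected when the AUG
occupies the P site.

Continuing to efficiencies and differential calls:

```r
norm <- apply_size_factors(counts, sf)
dens <- compute_mrna_density(exp$rnaseq, ann)
eff  <- efficiency_table(norm, exp$samples, dens)
eff[1:2, .(condition, transcript_id, RE, RRO)]
#>    condition transcript_id        RE         RRO
#> 1:    ded1_0        TX0001  54.55397 0.019289486
#> 2:    ded1_0        TX0002 307.74790 0.024910331
```

A file-based end-to-end run (`run_pipeline()`) and a command line
(`inst/cli/recseq.R` with subcommands `simulate`, `count`, `normalize`,
`metagene`, `run`) wrap the same steps with validation, TSV outputs and
a hashed manifest.

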