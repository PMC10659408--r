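#' Configuration for the synthetic recruitment-sequencing world
#'
#' Builds the parameter set for the generative model that the analysis
#' pipeline assumes: a toy transcriptome whose transcripts compete for a
#' limiting pool of 43S/48S preinitiation complexes (PICs), with
#' helicase-concentration-dependent relief of 5'UTR length and structure
#' penalties (saturating near `ded1_K`), context-score-dependent leaky
#' scanning of the main AUG multiplied roughly uniformly by helicase,
#' rare upstream-AUG initiation, constant spike-in PICs scaled by
#' per-sample loss factors, footprints of 25-34 nt with 5' ends centred
#' 12 nt upstream of the P-site codon, and negative-binomial count noise.
#'
#' @param n_transcripts number of toy transcripts.
#' @param n_reps biological replicates per condition.
#' @param utr5_len_dist list(meanlog, sdlog) of the log-normal 5'UTR length
#'   (nt); lengths are rounded, minimum 0.
#' @param cds_len_dist list(meanlog, sdlog, min) of the log-normal CDS
#'   length (nt); rounded to a multiple of 3, at least `min`.
#' @param abundance_dist list(meanlog, sdlog) of per-transcript mRNA
#'   abundance (arbitrary units, median 1 by default).
#' @param structure_score_model list(rate, sd): per-transcript structure
#'   level s ~ Exponential(rate); per-nucleotide PARS-like score ~
#'   Normal(s, sd).  Higher score = more double-stranded.
#' @param pic_pool total 48S PICs formed per sample.
#' @param ded1_concs helicase concentrations (nM) defining the conditions.
#' @param ded1_K half-saturation concentration (nM).
#' @param penalty_alpha structure penalty weight (per Max30 PARS unit).
#' @param penalty_beta 5'UTR length penalty weight (per nt).
#' @param stim_mode how the stimulation amplitude S is assigned:
#'   `"structure"` (S = stim_scale x penalty, the helicase-specific world),
#'   `"uniform"` (S = stim_uniform_S for every transcript, the
#'   general-helicase / eIF4A-like world), or `"planted"` (a random
#'   fraction `stim_frac` gets S = stim_S, the rest 0).
#' @param stim_scale,stim_uniform_S,stim_frac,stim_S see `stim_mode`.
#' @param leak_base baseline main-AUG readthrough probability at context
#'   score 0.
#' @param leak_context_slope exponential decay of readthrough with context
#'   score: leak0 = leak_base * exp(-slope * context).
#' @param leak_ded1_mult multiplicative readthrough factor per condition
#'   (same length as `ded1_concs`).
#' @param leaky_frac fraction of transcripts planted as strongly leaky
#'   (readthrough jumps with helicase, reciprocally moving main-AUG
#'   footprints to internal AUGs); 0 disables planting.
#' @param leaky_leak0 baseline readthrough of planted leaky transcripts.
#' @param leaky_mult per-condition readthrough multiplier for planted
#'   leaky transcripts; the default plants a strong shift (0.15 -> 0.75
#'   at the top concentration), emulating the clearly reciprocal
#'   main-to-internal conversions seen for genuinely leaky mRNAs.
#' @param iaug_stop_prob geometric stop probability of the scanning PIC at
#'   successive downstream internal AUGs after readthrough.
#' @param uaug_init_prob per-PIC probability of initiating at an upstream
#'   start (when the transcript has one).
#' @param gcn4_like plant one transcript with an unusually active 5'UTR
#'   (flagged `excluded_from_uorf_totals`, mimicking a GCN4-style outlier).
#' @param spike_counts expected spike-in footprints per spike AUG category
#'   at loss 1; names must match the categories of `spike_reference`.
#' @param spike_reference spike-in annotation, see [default_spike_reference()].
#' @param sample_loss per-sample multiplicative recovery factor in (0, 1];
#'   NULL draws one per sample log-uniformly from [0.25, 1].
#' @param nb_dispersion negative-binomial dispersion of count noise.
#' @param noise `"nb"` (gamma-Poisson), `"poisson"`, or `"none"`
#'   (deterministic expectation mode; counts may be fractional).
#' @param footprint_len_probs probability vector over lengths 25..34.
#' @param offset_jitter_probs probability vector over 5'-end jitter
#'   -2..+2 nt around the canonical -12 position.
#' @param rna_reads_per_nt expected RNA-seq reads per nucleotide for a
#'   transcript of abundance 1.
#' @param context_model position weight model used both to score start
#'   contexts and to make scores sequence-derived; see
#'   [default_context_model()].
#'
#' @return a list of class `recseq_config`.
#' @export
synthetic_config <- function(n_transcripts = 1000L,
                             n_reps = 3L,
                             utr5_len_dist = list(meanlog = log(50), sdlog = 0.7),
                             cds_len_dist = list(meanlog = log(1200), sdlog = 0.45, min = 90L),
                             abundance_dist = list(meanlog = 0, sdlog = 1),
                             structure_score_model = list(rate = 1, sd = 1),
                             pic_pool = 2e5,
                             ded1_concs = c(0, 100, 500),
                             ded1_K = 100,
                             penalty_alpha = 0.02,
                             penalty_beta = 0.002,
                             stim_mode = c("structure", "uniform", "planted"),
                             stim_scale = 3,
                             stim_uniform_S = 2,
                             stim_frac = 0.1,
                             stim_S = 6,
                             leak_base = 0.08,
                             leak_context_slope = 2,
                             leak_ded1_mult = c(1, 1.4, 1.7),
                             leaky_frac = 0,
                             leaky_leak0 = 0.15,
                             leaky_mult = c(1, 3, 5),
                             iaug_stop_prob = 0.5,
                             uaug_init_prob = 0.002,
                             gcn4_like = TRUE,
                             spike_counts = NULL,
                             spike_reference = default_spike_reference(),
                             sample_loss = NULL,
                             nb_dispersion = 0.05,
                             noise = c("nb", "poisson", "none"),
                             footprint_len_probs = c(`25` = 0.02, `26` = 0.05, `27` = 0.10,
                                                     `28` = 0.22, `29` = 0.24, `30` = 0.16,
                                                     `31` = 0.10, `32` = 0.06, `33` = 0.03,
                                                     `34` = 0.02),
                             offset_jitter_probs = c(`-2` = 0.03, `-1` = 0.06, `0` = 0.72,
                                                     `1` = 0.13, `2` = 0.06),
                             rna_reads_per_nt = 2.3,
                             context_model = default_context_model()) {
  stim_mode <- match.arg(stim_mode)
  noise <- match.arg(noise)
  if (is.null(spike_counts)) {
    spike_counts <- c(FLUC_mAUG = 4000, FLUC_i150 = 1200, FLUC_i420 = 800,
                      FLUC_i780 = 500, RLUC_mAUG = 2400, RLUC_i200 = 900,
                      RLUC_i500 = 600)
  }
  cfg <- list(n_transcripts = as.integer(n_transcripts), n_reps = as.integer(n_reps),
              utr5_len_dist = utr5_len_dist, cds_len_dist = cds_len_dist,
              abundance_dist = abundance_dist,
              structure_score_model = structure_score_model,
              pic_pool = pic_pool, ded1_concs = ded1_concs, ded1_K = ded1_K,
              penalty_alpha = penalty_alpha, penalty_beta = penalty_beta,
              stim_mode = stim_mode, stim_scale = stim_scale,
              stim_uniform_S = stim_uniform_S, stim_frac = stim_frac,
              stim_S = stim_S,
              leak_base = leak_base, leak_context_slope = leak_context_slope,
              leak_ded1_mult = leak_ded1_mult,
              leaky_frac = leaky_frac, leaky_leak0 = leaky_leak0,
              leaky_mult = leaky_mult,
              iaug_stop_prob = iaug_stop_prob,
              uaug_init_prob = uaug_init_prob, gcn4_like = isTRUE(gcn4_like),
              spike_counts = spike_counts, spike_reference = spike_reference,
              sample_loss = sample_loss, nb_dispersion = nb_dispersion,
              noise = noise, footprint_len_probs = footprint_len_probs,
              offset_jitter_probs = offset_jitter_probs,
              rna_reads_per_nt = rna_reads_per_nt,
              context_model = context_model)
  class(cfg) <- "recseq_config"
  validate_config(cfg)
}

#' @rdname synthetic_config
#' @param cfg a `recseq_config`.
#' @export
validate_config <- function(cfg) {
  if (cfg$n_transcripts < 0) stop_recseq("config", "n_transcripts must be >= 0")
  if (cfg$pic_pool < 0) stop_recseq("config", "pic_pool must be >= 0")
  assert_prob_vector(cfg$footprint_len_probs, "footprint_len_probs")
  assert_prob_vector(cfg$offset_jitter_probs, "offset_jitter_probs")
  if (!identical(names(cfg$footprint_len_probs), as.character(25:34)))
    stop_recseq("config", "footprint_len_probs must be named 25..34")
  for (p in c(cfg$leak_base, cfg$uaug_init_prob, cfg$leaky_leak0))
    if (p < 0 || p > 1) stop_recseq("config", "leak probabilities must lie in [0,1]")
  if (length(cfg$leak_ded1_mult) != length(cfg$ded1_concs))
    stop_recseq("config", "leak_ded1_mult must match ded1_concs in length")
  if (length(cfg$leaky_mult) != length(cfg$ded1_concs))
    stop_recseq("config", "leaky_mult must match ded1_concs in length")
  if (any(cfg$ded1_concs < 0)) stop_recseq("config", "ded1_concs must be >= 0")
  if (is.null(cfg$utr5_len_dist$fixed)) {
    bad <- vapply(cfg$utr5_len_dist[c("meanlog", "sdlog")],
                  function(x) is.null(x) || !is.finite(x), logical(1))
    if (any(bad)) stop_recseq("config", "invalid utr5_len_dist parameters")
  } else if (cfg$utr5_len_dist$fixed < 0) {
    stop_recseq("config", "fixed 5'UTR length must be >= 0")
  }
  if (!is.null(cfg$sample_loss) &&
      (any(cfg$sample_loss <= 0) || any(cfg$sample_loss > 1)))
    stop_recseq("config", "sample_loss must lie in (0, 1]")
  if (!all(names(cfg$spike_counts) %in% cfg$spike_reference$category))
    stop_recseq("config", "spike_counts names must match spike_reference categories")
  cfg
}

#' Disable 5'-end jitter in a configuration
#'
#' Point mass at the canonical -12 offset, so every footprint 5' end falls
#' exactly 12 nt upstream of the AUG chosen by the scanning model.
#'
#' @param cfg a `recseq_config`.
#' @return the modified configuration.
#' @export
jitter_off <- function(cfg) {
  cfg$offset_jitter_probs <- c(`0` = 1)
  cfg
}
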