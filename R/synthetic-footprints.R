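#' Planted ground truth for a synthetic transcriptome
#'
#' Computes, per transcript, the recruitment base weight
#' `exp(-penalty_alpha * Max30 - penalty_beta * utr5_len)`, the
#' helicase-stimulation amplitude S (mode-dependent, see
#' [synthetic_config()]), the baseline main-AUG readthrough probability,
#' and per-condition derived quantities: the saturating stimulation
#' factor `1 + S * ded1 / (ded1 + K)`, the readthrough probability, and
#' the expected recruitment efficiency.  Used both to drive the
#' simulators and as ground truth for parameter-recovery tests.
#'
#' @param tx a `recseq_transcriptome`.
#' @param config the [synthetic_config()] used to build it.
#' @param seed master seed (planted stimulated/leaky sets are drawn from
#'   a stream derived from it).
#' @return list of class `recseq_truth` with `per_transcript` and
#'   `per_condition` data.tables.
#' @export
planted_truth <- function(tx, config, seed = 1L) {
  ann <- tx$annotation
  n <- nrow(ann)
  ps <- compute_pars_summaries(tx$pars, ann)
  max30 <- ps$max30_pars[match(ann$transcript_id, ps$transcript_id)]
  max30[is.na(max30)] <- 0
  penalty <- config$penalty_alpha * pmax(max30, 0) +
    config$penalty_beta * ann$utr5_len
  base_weight <- exp(-penalty)

  set.seed(derive_seed(seed, "truth"))
  is_leaky <- rep(FALSE, n)
  if (config$leaky_frac > 0 && n > 0) {
    k <- max(1L, round(config$leaky_frac * n))
    is_leaky[sample.int(n, k)] <- TRUE
  }
  S <- switch(config$stim_mode,
    structure = config$stim_scale * penalty,
    uniform   = rep(config$stim_uniform_S, n),
    planted   = {
      s <- rep(0, n)
      pool <- which(!is_leaky)
      k <- max(1L, round(config$stim_frac * n))
      s[sample(pool, min(k, length(pool)))] <- config$stim_S
      s
    })
  S[is_leaky] <- 0  # planted leaky transcripts must lose mRPFs cleanly

  ctx <- ann$context_score
  ctx[is.na(ctx)] <- 0.5  # short-5'UTR transcripts: generic context
  leak0 <- config$leak_base * exp(-config$leak_context_slope * ctx)
  leak0[is_leaky] <- config$leaky_leak0

  ua <- ifelse(ann$n_uaug > 0, config$uaug_init_prob, 0)
  ua[ann$excluded_from_uorf_totals] <- pmin(0.4, ua[ann$excluded_from_uorf_totals] * 50)

  f <- config$ded1_concs / (config$ded1_concs + config$ded1_K)
  f[config$ded1_concs == 0] <- 0

  per_tx <- data.table::data.table(
    transcript_id = ann$transcript_id, abundance = unname(tx$abundance),
    base_weight = base_weight, S = S, leak0 = leak0, uaug_prob = ua,
    max30_pars = max30,
    is_ded1_stimulated = (1 + S * max(f)) >= 2,
    is_leaky_planted = is_leaky)
  if (config$stim_mode == "planted") per_tx$is_ded1_stimulated <- S > 0

  # main-AUG footprints whose jittered 5' end would fall before position 1
  # (very short 5'UTRs) are dropped by the simulator; the expected counts
  # carry the same survival probability so the truth matches what is
  # actually emitted
  jit <- as.integer(names(config$offset_jitter_probs))
  p_keep <- vapply(ann$utr5_len, function(u)
    sum(config$offset_jitter_probs[jit >= 12L - u]), numeric(1))

  cond_list <- lapply(seq_along(config$ded1_concs), function(ci) {
    stim <- 1 + S * f[ci]
    mult <- ifelse(is_leaky, config$leaky_mult[ci], config$leak_ded1_mult[ci])
    leak <- pmin(0.95, leak0 * mult)
    w <- tx$abundance * base_weight * stim
    share <- if (sum(w) > 0) w / sum(w) else rep(0, n)
    e_mrpf <- config$pic_pool * share * (1 - ua) * (1 - leak) * p_keep
    dens <- tx$abundance * config$rna_reads_per_nt
    data.table::data.table(
      transcript_id = ann$transcript_id, ded1_conc = config$ded1_concs[ci],
      stim_factor = stim, leak_prob = leak, weight = w,
      expected_mrpf = e_mrpf,
      expected_re = ifelse(dens > 0, e_mrpf / dens, NA_real_))
  })
  out <- list(per_transcript = per_tx,
              per_condition = data.table::rbindlist(cond_list))
  class(out) <- "recseq_truth"
  out
}

#' Recruitment weights at a given helicase concentration
#'
#' `weight = abundance * base_weight * (1 + S * ded1 / (ded1 + K))`.
#' At `ded1_conc = 0` the weight reduces to `abundance * base_weight`;
#' weights are non-decreasing in concentration because S >= 0.
#'
#' @param truth a `recseq_truth` (its `per_transcript` table supplies
#'   abundance, base_weight and S).
#' @param ded1_conc helicase concentration in nM, scalar >= 0.
#' @param config the configuration (supplies `ded1_K`).
#' @return named numeric vector of weights.
#' @export
compute_recruitment_weights <- function(truth, ded1_conc, config) {
  if (!is.numeric(ded1_conc) || length(ded1_conc) != 1 || ded1_conc < 0)
    stop_recseq("weights", "ded1_conc must be a single non-negative number")
  pt <- truth$per_transcript
  f <- if (ded1_conc == 0) 0 else ded1_conc / (ded1_conc + config$ded1_K)
  setNames(pt$abundance * pt$base_weight * (1 + pt$S * f), pt$transcript_id)
}

# geometric stop rule over ordered downstream internal AUGs
iaug_probs <- function(k, stop_prob) {
  w <- stop_prob * (1 - stop_prob)^(seq_len(k) - 1)
  w / sum(w)
}

#' Simulate 48S footprints for one sample
#'
#' Allocates the PIC pool multinomially across transcripts by recruitment
#' weight, then per PIC chooses an upstream AUG (probability
#' `uaug_prob`), otherwise the main AUG unless readthrough occurs
#' (probability `leak_prob`), in which case a downstream internal AUG is
#' selected under a geometric stop rule.  Count noise (gamma-Poisson or
#' Poisson) is applied at the per-transcript level after allocation, and
#' per-sample recovery loss is applied by binomial thinning.  Each
#' footprint gets a length from `footprint_len_probs` and a 5'-end
#' placed `AUG - 12 + jitter` with jitter from `offset_jitter_probs`.
#' Events whose footprint would fall outside the transcript are dropped
#' (tallied in the `n_dropped` attribute, with a single warning).
#'
#' With `config$noise == "none"` the function returns expected
#' (fractional) counts instead of sampling.
#'
#' @param tx a `recseq_transcriptome`.
#' @param truth a `recseq_truth` from [planted_truth()].
#' @param config the configuration.
#' @param ded1_conc condition, must be one of `config$ded1_concs`.
#' @param sample_id sample label stored in the records.
#' @param seed master seed; the stream is derived from (seed, sample).
#' @param sample_loss recovery factor in (0, 1].
#' @return data.table (sample_id, transcript_id, five_prime_pos, length,
#'   count) with attributes `n_allocated` and `n_dropped`.
#' @export
simulate_footprints <- function(tx, truth, config, ded1_conc, sample_id,
                                seed = 1L, sample_loss = 1) {
  ann <- tx$annotation
  n <- nrow(ann)
  target_conc <- ded1_conc
  cond <- truth$per_condition[truth$per_condition$ded1_conc == target_conc]
  if (nrow(cond) != n) stop_recseq("simulate", "ded1_conc not in truth table")
  cond <- cond[match(ann$transcript_id, cond$transcript_id)]
  pt <- truth$per_transcript[match(ann$transcript_id,
                                   truth$per_transcript$transcript_id)]
  empty <- data.table::data.table(
    sample_id = character(), transcript_id = character(),
    five_prime_pos = integer(), length = integer(), count = numeric())

  if (n == 0L || config$pic_pool == 0) {
    data.table::setattr(empty, "n_allocated", 0)
    data.table::setattr(empty, "n_dropped", 0)
    return(empty)
  }

  lens <- as.integer(names(config$footprint_len_probs))
  jits <- as.integer(names(config$offset_jitter_probs))
  in_aug <- split(tx$internal_aug$pos, tx$internal_aug$transcript_id)
  up_aug <- split(tx$upstream_aug$pos, tx$upstream_aug$transcript_id)

  if (config$noise == "none") {
    share <- cond$weight / sum(cond$weight)
    alloc <- config$pic_pool * share * sample_loss
    sites <- vector("list", n)
    for (i in seq_len(n)) {
      if (alloc[i] <= 0) next
      id <- ann$transcript_id[i]
      ua <- pt$uaug_prob[i]; lk <- cond$leak_prob[i]
      up <- up_aug[[id]]; ia <- in_aug[[id]]
      if (is.null(up) || !length(up)) ua <- 0
      p_pos <- c(ann$cds_start[i],
                 if (length(up)) up else integer(),
                 if (length(ia)) ia else integer())
      p_w <- c((1 - ua) * (1 - lk),
               if (length(up)) rep(ua / length(up), length(up)) else numeric(),
               if (length(ia)) (1 - ua) * lk * iaug_probs(length(ia), config$iaug_stop_prob)
               else numeric())
      keep <- p_w > 0
      if (!any(keep)) next
      sites[[i]] <- data.table::data.table(
        transcript_id = id, aug_pos = p_pos[keep], n = alloc[i] * p_w[keep],
        tx_len = ann$tx_len[i])
    }
    st <- data.table::rbindlist(sites)
    if (nrow(st) == 0L) {
      data.table::setattr(empty, "n_allocated", sum(alloc))
      data.table::setattr(empty, "n_dropped", 0)
      return(empty)
    }
    grid <- data.table::CJ(len = lens, jit = jits)
    grid$p <- config$footprint_len_probs[as.character(grid$len)] *
      config$offset_jitter_probs[as.character(grid$jit)]
    grid <- grid[grid$p > 0]
    recs <- st[, {
      fp <- aug_pos - 12L + grid$jit
      data.table::data.table(five_prime_pos = fp, length = grid$len,
                             count = n * grid$p, tx_len = tx_len[1])
    }, by = c("transcript_id", "aug_pos")]
    dropped <- recs[five_prime_pos < 1L | five_prime_pos + length - 1L > tx_len]
    n_drop <- sum(dropped$count)
    recs <- recs[five_prime_pos >= 1L & five_prime_pos + length - 1L <= tx_len]
    out <- recs[, .(count = sum(count)),
                by = c("transcript_id", "five_prime_pos", "length")]
    out[, sample_id := sample_id]
    data.table::setcolorder(out, c("sample_id", "transcript_id",
                                   "five_prime_pos", "length", "count"))
    if (n_drop > 0)
      warning(sprintf("simulate_footprints: %.3g expected footprints fell outside transcript bounds and were dropped", n_drop))
    data.table::setattr(out, "n_allocated", sum(alloc))
    data.table::setattr(out, "n_dropped", n_drop)
    return(out[])
  }

  set.seed(derive_seed(seed, "footprints", sample_id))
  share <- cond$weight / sum(cond$weight)
  alloc <- as.vector(rmultinom(1, config$pic_pool, share))
  n_allocated <- sum(alloc)

  n1 <- if (config$noise == "nb" && config$nb_dispersion > 0) {
    g <- rgamma(n, shape = 1 / config$nb_dispersion,
                scale = config$nb_dispersion)
    rpois(n, alloc * g)
  } else {
    rpois(n, alloc)
  }
  n2 <- if (sample_loss < 1) rbinom(n, n1, sample_loss) else n1

  ua <- ifelse(ann$n_uaug > 0, pt$uaug_prob, 0)
  n_u <- rbinom(n, n2, ua)
  n_rest <- n2 - n_u
  n_leak <- rbinom(n, n_rest, cond$leak_prob)
  n_m <- n_rest - n_leak

  site_tx <- character(0); site_pos <- integer(0); site_n <- integer(0)
  add_sites <- function(ids, pos, cnt) {
    keep <- cnt > 0
    site_tx <<- c(site_tx, ids[keep])
    site_pos <<- c(site_pos, pos[keep])
    site_n <<- c(site_n, cnt[keep])
  }
  add_sites(ann$transcript_id, ann$cds_start, n_m)

  n_drop <- 0
  for (i in which(n_u > 0)) {
    up <- up_aug[[ann$transcript_id[i]]]
    if (is.null(up) || !length(up)) { n_drop <- n_drop + n_u[i]; next }
    cnt <- as.vector(rmultinom(1, n_u[i], rep(1, length(up))))
    add_sites(rep(ann$transcript_id[i], length(up)), up, cnt)
  }
  for (i in which(n_leak > 0)) {
    ia <- in_aug[[ann$transcript_id[i]]]
    if (is.null(ia) || !length(ia)) { n_drop <- n_drop + n_leak[i]; next }
    cnt <- as.vector(rmultinom(1, n_leak[i],
                               iaug_probs(length(ia), config$iaug_stop_prob)))
    add_sites(rep(ann$transcript_id[i], length(ia)), ia, cnt)
  }

  if (!length(site_n)) {
    data.table::setattr(empty, "n_allocated", n_allocated)
    data.table::setattr(empty, "n_dropped", n_drop)
    return(empty)
  }

  ev_tx <- rep(site_tx, site_n)
  ev_pos <- rep(site_pos, site_n)
  n_ev <- length(ev_tx)
  ev_len <- sample(lens, n_ev, replace = TRUE, prob = config$footprint_len_probs)
  ev_jit <- if (length(jits) == 1L) rep(jits, n_ev) else
    sample(jits, n_ev, replace = TRUE, prob = config$offset_jitter_probs)
  ev_fp <- ev_pos - 12L + ev_jit
  ev_txlen <- ann$tx_len[match(ev_tx, ann$transcript_id)]
  ok <- ev_fp >= 1L & ev_fp + ev_len - 1L <= ev_txlen
  n_drop <- n_drop + sum(!ok)
  if (n_drop > 0)
    warning(sprintf("simulate_footprints: %d initiation events dropped (footprint outside transcript bounds or no landing AUG)", n_drop))

  out <- data.table::data.table(
    sample_id = sample_id, transcript_id = ev_tx[ok],
    five_prime_pos = ev_fp[ok], length = ev_len[ok])[
      , .(count = .N),
      by = c("sample_id", "transcript_id", "five_prime_pos", "length")]
  data.table::setattr(out, "n_allocated", n_allocated)
  data.table::setattr(out, "n_dropped", n_drop)
  out[]
}

#' Simulate spike-in footprints for one sample
#'
#' A constant amount of pre-formed 48S PICs on the spike transcripts:
#' expected counts `spike_counts * sample_loss` per spike AUG category,
#' Poisson-sampled (exact in `"none"` noise mode), placed 12 nt upstream
#' of the category AUG with the configured length and jitter spectra.
#'
#' @inheritParams simulate_footprints
#' @return footprint data.table on spike transcript ids.
#' @export
simulate_spikeins <- function(config, sample_id, seed = 1L, sample_loss = 1) {
  ref <- config$spike_reference
  mu <- config$spike_counts[ref$category] * sample_loss
  lens <- as.integer(names(config$footprint_len_probs))
  jits <- as.integer(names(config$offset_jitter_probs))

  if (config$noise == "none") {
    grid <- data.table::CJ(k = seq_len(nrow(ref)), len = lens, jit = jits)
    grid$p <- config$footprint_len_probs[as.character(grid$len)] *
      config$offset_jitter_probs[as.character(grid$jit)]
    grid <- grid[grid$p > 0]
    out <- data.table::data.table(
      sample_id = sample_id,
      transcript_id = ref$spike_id[grid$k],
      five_prime_pos = ref$aug_pos[grid$k] - 12L + grid$jit,
      length = grid$len,
      count = mu[grid$k] * grid$p)
    return(out[count > 0][order(transcript_id, five_prime_pos, length)])
  }

  set.seed(derive_seed(seed, "spikes", sample_id))
  cnt <- rpois(nrow(ref), mu)
  ev_k <- rep(seq_len(nrow(ref)), cnt)
  n_ev <- length(ev_k)
  if (n_ev == 0L)
    return(data.table::data.table(sample_id = character(),
                                  transcript_id = character(),
                                  five_prime_pos = integer(),
                                  length = integer(), count = numeric()))
  ev_len <- sample(lens, n_ev, replace = TRUE, prob = config$footprint_len_probs)
  ev_jit <- if (length(jits) == 1L) rep(jits, n_ev) else
    sample(jits, n_ev, replace = TRUE, prob = config$offset_jitter_probs)
  data.table::data.table(
    sample_id = sample_id, transcript_id = ref$spike_id[ev_k],
    five_prime_pos = ref$aug_pos[ev_k] - 12L + ev_jit, length = ev_len)[
      , .(count = as.numeric(.N)),
      by = c("sample_id", "transcript_id", "five_prime_pos", "length")][]
}

#' Simulate input RNA-seq read positions
#'
#' Random fragmentation: fragment 5' ends uniform along each transcript,
#' total reads Poisson with mean `abundance * rna_reads_per_nt * length`,
#' so expected reads-per-nt is proportional to abundance everywhere,
#' including within the CDS.
#'
#' @inheritParams simulate_footprints
#' @param abundance per-transcript abundances; defaults to the ones
#'   generated with the transcriptome.
#' @return data.table (transcript_id, position, count).
#' @export
simulate_rnaseq <- function(tx, config, seed = 1L, abundance = tx$abundance) {
  ann <- tx$annotation
  if (nrow(ann) == 0L)
    return(data.table::data.table(transcript_id = character(),
                                  position = integer(), count = numeric()))
  lam <- abundance[ann$transcript_id] * config$rna_reads_per_nt
  if (config$noise == "none") {
    out <- data.table::data.table(
      transcript_id = rep(ann$transcript_id, ann$tx_len),
      position = unlist(lapply(ann$tx_len, seq_len)),
      count = rep(lam, ann$tx_len))
    return(out[count > 0])
  }
  set.seed(derive_seed(seed, "rnaseq"))
  n_reads <- rpois(nrow(ann), lam * ann$tx_len)
  ev_tx <- rep(ann$transcript_id, n_reads)
  ev_maxpos <- rep(ann$tx_len, n_reads)
  ev_pos <- 1L + as.integer(floor(runif(length(ev_tx)) * ev_maxpos))
  data.table::data.table(transcript_id = ev_tx, position = ev_pos)[
    , .(count = as.numeric(.N)), by = c("transcript_id", "position")][]
}

#' Simulate a complete multi-sample experiment
#'
#' Generates a transcriptome, planted truth, per-sample loss factors
#' (log-uniform in [0.25, 1] unless supplied), footprints plus spike-ins
#' for `n_reps` replicates of every condition in `ded1_concs`, and one
#' input RNA-seq dataset.
#'
#' @param config a [synthetic_config()].
#' @param seed master seed.
#' @return list of class `recseq_experiment`: `tx`, `truth`, `samples`
#'   (sample_id, condition, ded1_conc, rep, sample_loss), `footprints`
#'   (transcriptome + spikes), `rnaseq`, `config`.
#' @export
simulate_experiment <- function(config, seed = 1L) {
  tx <- generate_transcriptome(config, seed)
  truth <- planted_truth(tx, config, seed)
  concs <- config$ded1_concs
  samples <- data.table::CJ(rep = seq_len(config$n_reps), ded1_conc = concs,
                            sorted = FALSE)
  samples <- samples[order(match(ded1_conc, concs), rep)]
  samples[, condition := paste0("ded1_", ded1_conc)]
  samples[, sample_id := sprintf("%s_rep%d", condition, rep)]
  if (is.null(config$sample_loss)) {
    set.seed(derive_seed(seed, "loss"))
    samples[, sample_loss := exp(runif(.N, log(0.25), log(1)))]
  } else {
    samples[, sample_loss := rep_len(config$sample_loss, .N)]
  }
  data.table::setcolorder(samples, c("sample_id", "condition", "ded1_conc",
                                     "rep", "sample_loss"))
  fp <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i]
    rbind(
      simulate_footprints(tx, truth, config, s$ded1_conc, s$sample_id,
                          seed = seed, sample_loss = s$sample_loss),
      simulate_spikeins(config, s$sample_id, seed = seed,
                        sample_loss = s$sample_loss))
  })
  out <- list(tx = tx, truth = truth, samples = samples,
              footprints = data.table::rbindlist(fp),
              rnaseq = simulate_rnaseq(tx, config, seed),
              config = config)
  class(out) <- "recseq_experiment"
  out
}
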