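#' PARS-style structure summaries per transcript
#'
#' From a per-nucleotide structure score profile:
#' `total_pars` — sum over all 5'UTR nucleotides;
#' `max30_pars` — the highest cumulative score in any 30-nt window of
#' the 5'UTR (for 5'UTRs shorter than 30 nt the full 5'UTR sum, the
#' truncated-window behaviour);
#' `start30_pars` — sum over the 30 nt surrounding the main AUG
#' (signed -15..+15, i.e. 15 nt each side), defined only when the
#' 5'UTR is at least 15 nt;
#' `plus15/plus30/plus45_pars` — 30-nt sums starting at signed +15,
#' +30, +45 downstream of the main AUG.  Windows not fully covered by
#' the profile are NA (flagged).
#'
#' @param pars data.table (transcript_id, position, score).
#' @param annots annotation data.table.
#' @return data.table, one row per annotated non-spike transcript with
#'   a profile.
#' @export
compute_pars_summaries <- function(pars, annots) {
  ann <- data.table::as.data.table(annots)
  if ("is_spikein" %in% names(ann)) ann <- ann[is_spikein == FALSE]
  ps <- data.table::as.data.table(pars)
  out <- vector("list", nrow(ann))
  win_sum <- function(sc, lo, hi) {
    # closed window on a 1-based dense profile; NA if not covered
    if (lo < 1 || hi > base::length(sc)) return(NA_real_)
    sum(sc[lo:hi])
  }
  prof <- split(ps, by = "transcript_id")
  for (i in seq_len(nrow(ann))) {
    id <- ann$transcript_id[i]
    p <- prof[[id]]
    if (is.null(p)) next  # missing profile: excluded from PARS analyses
    sc <- numeric(max(p$position))
    sc[p$position] <- p$score
    covered <- logical(max(p$position)); covered[p$position] <- TRUE
    u <- ann$utr5_len[i]; cs <- ann$cds_start[i]
    total <- if (u > 0 && all(covered[1:u])) sum(sc[1:u]) else if (u == 0) 0 else NA_real_
    max30 <- if (u == 0) 0 else if (u <= 30) total else {
      csum <- cumsum(sc[1:u])
      max(csum[30:u] - c(0, csum)[(30:u) - 29])
    }
    start30 <- if (u >= 15) win_sum(sc, cs - 15L, cs + 14L) else NA_real_
    plus <- vapply(c(15L, 30L, 45L), function(k)
      win_sum(sc, cs + k - 1L, cs + k + 28L), numeric(1))
    out[[i]] <- data.table::data.table(
      transcript_id = id, total_pars = total, max30_pars = max30,
      start30_pars = start30, plus15_pars = plus[1], plus30_pars = plus[2],
      plus45_pars = plus[3])
  }
  data.table::rbindlist(out)
}

#' Equal-size bins of a feature
#'
#' Stable sort by (value, id), then contiguous blocks whose sizes
#' differ by at most one; when n is not a multiple of k the first
#' `n %% k` bins get the extra element.
#'
#' @param values finite numeric feature values.
#' @param k number of bins.
#' @param ids tie-breaking identifiers (default: input order).
#' @return integer bin assignment (1 = lowest values), same order as
#'   input.
#' @export
bin_equal_size <- function(values, k = 6L, ids = seq_along(values)) {
  n <- base::length(values)
  if (n < k) stop_recseq("bins", "need at least k values")
  if (any(!is.finite(values))) stop_recseq("bins", "values must be finite")
  o <- order(values, ids)
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  assign <- integer(n)
  assign[o] <- rep(seq_len(k), sizes)
  assign
}

#' Summarize a metric within feature bins
#'
#' @param feature feature values used for the bin ranges.
#' @param metric metric values (same length).
#' @param assignments bin assignment from [bin_equal_size()].
#' @return data.table (bin, feature_min, feature_max, n, mean, median,
#'   q25, q75).
#' @export
summarize_bins <- function(feature, metric, assignments) {
  dt <- data.table::data.table(bin = assignments, feature = feature,
                               metric = metric)
  dt[, .(feature_min = min(feature), feature_max = max(feature), n = .N,
         mean = mean(metric, na.rm = TRUE),
         median = median(metric, na.rm = TRUE),
         q25 = quantile(metric, 0.25, na.rm = TRUE, names = FALSE),
         q75 = quantile(metric, 0.75, na.rm = TRUE, names = FALSE)),
     by = "bin"][order(bin)]
}

check_universe <- function(a, b, stage) {
  if (!setequal(a$transcript_id, b$transcript_id))
    stop_recseq(stage, "differential results computed on mismatched transcript universes")
}

#' Leaky-scanning classification
#'
#' Nested sets built from two differential contrasts (condition B over
#' A) on the same transcript universe:
#' (1) main-AUG footprints significantly down;
#' (2) subset with internal footprints also significantly up;
#' (3) subset where the absolute increase in internal footprints is at
#' least 50% of the absolute decrease in main footprints, in
#' spike-normalized read units — the leaky-scanning calls, i.e. the
#' reciprocity expected if internal footprints arise from PICs that
#' scan past the main AUG.
#'
#' @param diff_mrpf,diff_irpf [nb_wald_test()] tables for the mRPF and
#'   iRPF contrasts.
#' @param cond_means data.table (transcript_id, mRPF_A, mRPF_B, iRPF_A,
#'   iRPF_B) of replicate-mean spike-normalized counts.
#' @param fdr_cut,fc_cut significance thresholds.
#' @param reciprocity_frac the "comparable magnitude" fraction (0.5).
#' @return list(m_down, m_down_i_up, leaky) of transcript id vectors.
#' @export
classify_leaky_scanning <- function(diff_mrpf, diff_irpf, cond_means,
                                    fdr_cut = 0.05, fc_cut = 2,
                                    reciprocity_frac = 0.5) {
  check_universe(diff_mrpf, diff_irpf, "leaky")
  m_down <- classify_significant(diff_mrpf, fdr_cut, fc_cut)$down
  i_up <- classify_significant(diff_irpf, fdr_cut, fc_cut)$up
  set2 <- intersect(m_down, i_up)
  cm <- data.table::as.data.table(cond_means)
  cm <- cm[transcript_id %in% set2]
  keep <- (cm$iRPF_B - cm$iRPF_A) >=
    reciprocity_frac * (cm$mRPF_A - cm$mRPF_B)
  list(m_down = m_down, m_down_i_up = set2, leaky = cm$transcript_id[keep])
}

#' Upstream-initiation reciprocity classification
#'
#' Transcripts whose upstream (5'UTR) footprints drop significantly
#' while main-AUG footprints rise significantly, with the upstream
#' decrease at least 50% of the main-AUG increase — the pattern
#' expected if relieved upstream initiation feeds the main AUG.
#'
#' @inheritParams classify_leaky_scanning
#' @param diff_urpf,diff_mrpf differential tables for uRPF and mRPF.
#' @param cond_means data.table (transcript_id, uRPF_A, uRPF_B, mRPF_A,
#'   mRPF_B).
#' @return list(u_down, u_down_m_up, reciprocal).
#' @export
classify_uaug_reciprocity <- function(diff_urpf, diff_mrpf, cond_means,
                                      fdr_cut = 0.05, fc_cut = 2,
                                      reciprocity_frac = 0.5) {
  check_universe(diff_urpf, diff_mrpf, "uaug")
  u_down <- classify_significant(diff_urpf, fdr_cut, fc_cut)$down
  m_up <- classify_significant(diff_mrpf, fdr_cut, fc_cut)$up
  set2 <- intersect(u_down, m_up)
  cm <- data.table::as.data.table(cond_means)[transcript_id %in% set2]
  keep <- (cm$uRPF_A - cm$uRPF_B) >=
    reciprocity_frac * (cm$mRPF_B - cm$mRPF_A)
  list(u_down = u_down, u_down_m_up = set2, reciprocal = cm$transcript_id[keep])
}

#' RRO and delta-RRO binned by start-context score
#'
#' Bins transcripts by context score into k equal-size bins and reports
#' the mean RRO per condition per bin plus the log2 ratio of bin mean
#' RROs between the two conditions (the delta-RRO curve; a planted
#' uniform readthrough multiplier m gives a flat curve at log2 m).
#'
#' @param eff an [efficiency_table()] covering both conditions.
#' @param context data.table (transcript_id, context_score).
#' @param condA,condB condition labels (delta is B over A).
#' @param k number of bins.
#' @return data.table (bin, context_min, context_max, n, rro_A, rro_B,
#'   log2_delta_rro).
#' @export
rro_by_context <- function(eff, context, condA, condB, k = 6L) {
  ctx <- data.table::as.data.table(context)
  a <- eff[condition == condA, .(transcript_id, rro_A = RRO)]
  b <- eff[condition == condB, .(transcript_id, rro_B = RRO)]
  dt <- ctx[a, on = "transcript_id", nomatch = NULL][b, on = "transcript_id",
                                                     nomatch = NULL]
  dt <- dt[!is.na(context_score) & !is.na(rro_A) & !is.na(rro_B)]
  dt[, bin := bin_equal_size(context_score, k, transcript_id)]
  dt[, .(context_min = min(context_score), context_max = max(context_score),
         n = .N, rro_A = mean(rro_A), rro_B = mean(rro_B),
         log2_delta_rro = log2(mean(rro_B) / mean(rro_A))),
     by = "bin"][order(bin)]
}

#' Rank-ordered delta matrix for heat-map display
#'
#' Rows are transcripts ordered by the log2 delta of one contrast, from
#' most increased to most decreased (ties broken by transcript id);
#' columns are the requested contrasts.
#'
#' @param deltas named list of [delta_between_conditions()] tables
#'   sharing a transcript universe.
#' @param order_by name of the contrast used for ordering.
#' @return numeric matrix of log2 deltas with transcript rownames.
#' @export
rank_heatmap_table <- function(deltas, order_by = names(deltas)[1]) {
  ids <- deltas[[1]]$transcript_id
  for (d in deltas)
    if (!setequal(d$transcript_id, ids))
      stop_recseq("heatmap", "delta tables on mismatched universes")
  key <- deltas[[order_by]]
  o <- order(-key$log2_delta, key$transcript_id)
  ordered_ids <- key$transcript_id[o]
  m <- sapply(deltas, function(d)
    d$log2_delta[match(ordered_ids, d$transcript_id)])
  rownames(m) <- ordered_ids
  m
}
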