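#' mRNA density from input RNA-seq positions
#'
#' Reads whose 5' end falls within the CDS (closed interval
#' `[cds_start, cds_end]`), divided by CDS length, in reads per
#' nucleotide.  Reads outside the CDS do not contribute.
#'
#' @param rnaseq data.table (transcript_id, position, count).
#' @param annots annotation data.table.
#' @return data.table (transcript_id, cds_reads, mrna_density,
#'   zero_flag).
#' @export
compute_mrna_density <- function(rnaseq, annots) {
  ann <- data.table::as.data.table(annots)[is_spikein == FALSE]
  rs <- data.table::as.data.table(rnaseq)
  j <- ann[, .(transcript_id, cds_start, cds_end)][rs, on = "transcript_id",
                                                   nomatch = NULL]
  agg <- j[position >= cds_start & position <= cds_end,
           .(cds_reads = sum(count)), by = "transcript_id"]
  out <- agg[ann[, .(transcript_id, cds_start, cds_end)], on = "transcript_id"]
  out[is.na(cds_reads), cds_reads := 0]
  out[, mrna_density := cds_reads / (cds_end - cds_start + 1)]
  out[, zero_flag := mrna_density == 0]
  out[, c("cds_start", "cds_end") := NULL]
  out[]
}

#' Recruitment efficiency
#'
#' RE = normalized main-AUG footprint count / mRNA density.  Transcripts
#' with zero density are excluded (NA with a flag), never infinite.
#'
#' @param norm_mrpf numeric vector of spike-normalized mRPF counts.
#' @param density matching mRNA densities (reads/nt).
#' @return numeric vector of REs, NA where density is zero.
#' @export
compute_re <- function(norm_mrpf, density) {
  ifelse(is.na(density) | density <= 0, NA_real_, norm_mrpf / density)
}

#' Relative ribosome occupancy
#'
#' RRO = iRPF / cdsRPF, the fraction of CDS-mapped 48S PICs at internal
#' AUGs.  Undefined (NA) when cdsRPF is zero; iRPF > cdsRPF is an
#' internal consistency error.
#'
#' @param irpf,cdsrpf numeric vectors of (normalized or raw) counts.
#' @return numeric vector in [0, 1] or NA.
#' @export
compute_rro <- function(irpf, cdsrpf) {
  if (any(irpf > cdsrpf + 1e-9, na.rm = TRUE))
    stop_recseq("rro", "iRPF exceeds cdsRPF: inconsistent counts")
  ifelse(cdsrpf > 0, irpf / cdsrpf, NA_real_)
}

#' Per-condition efficiency table
#'
#' Replicate means of spike-normalized region counts per condition,
#' with RE and RRO per transcript.
#'
#' @param norm_counts region count table with `norm_*` columns (from
#'   [apply_size_factors()]).
#' @param samples sample table (sample_id, condition).
#' @param density table from [compute_mrna_density()].
#' @return data.table (condition, transcript_id, mRPF, uRPF, iRPF,
#'   cdsRPF [replicate-mean normalized], mrna_density, RE, RRO).
#' @export
efficiency_table <- function(norm_counts, samples, density) {
  nc <- data.table::as.data.table(norm_counts)
  st <- data.table::as.data.table(samples)[, .(sample_id, condition)]
  j <- st[nc, on = "sample_id", nomatch = NULL]
  eff <- j[, .(mRPF = mean(norm_mRPF), uRPF = mean(norm_uRPF),
               iRPF = mean(norm_iRPF), cdsRPF = mean(norm_cdsRPF)),
           by = c("condition", "transcript_id")]
  eff <- density[, .(transcript_id, mrna_density)][eff, on = "transcript_id"]
  eff[, RE := compute_re(mRPF, mrna_density)]
  eff[, RRO := compute_rro(iRPF, cdsRPF)]
  data.table::setcolorder(eff, c("condition", "transcript_id"))
  eff[]
}

#' Between-condition change of a metric
#'
#' Delta = metric(condB) / metric(condA) per transcript, computed on
#' condition-level replicate-mean values; transcripts where the metric
#' is undefined (NA) or zero in the denominator are excluded (NA with a
#' flag).
#'
#' @param eff an [efficiency_table()].
#' @param condA,condB condition labels (A is the denominator/reference).
#' @param metric column name, e.g. `"RE"`, `"RRO"`, `"mRPF"`.
#' @return data.table (transcript_id, valueA, valueB, delta, log2_delta,
#'   excluded).
#' @export
delta_between_conditions <- function(eff, condA, condB, metric = "RE") {
  for (cn in c(condA, condB))
    if (!cn %in% eff$condition) stop_recseq("delta", "unknown condition ", cn)
  a <- eff[condition == condA, .(transcript_id, valueA = get(metric))]
  b <- eff[condition == condB, .(transcript_id, valueB = get(metric))]
  out <- a[b, on = "transcript_id"]
  out[, excluded := is.na(valueA) | is.na(valueB) | valueA == 0]
  out[, delta := ifelse(excluded, NA_real_, valueB / valueA)]
  out[, log2_delta := log2(delta)]
  out[]
}

#' Translatome-wide uRPF/mRPF ratio
#'
#' Sum of upstream footprints over sum of main-AUG footprints across
#' all transcripts not on the exclusion list (outlier transcripts whose
#' 5'UTRs dominate the upstream totals, e.g. a GCN4-like mRNA, are
#' excluded so the ratio reflects the translatome).  Also reports each
#' excluded transcript's share of the total upstream footprints.
#'
#' @param counts table with normalized (or raw) `uRPF`/`mRPF` columns;
#'   column names used are given by `u_col`/`m_col`.
#' @param exclude transcript ids to exclude from the totals.
#' @param u_col,m_col column names.
#' @return list(ratio, total_urpf, total_mrpf, excluded_shares).
#' @export
urpf_mrpf_ratio <- function(counts, exclude = character(),
                            u_col = "norm_uRPF", m_col = "norm_mRPF") {
  ct <- data.table::as.data.table(counts)
  all_u <- sum(ct[[u_col]])
  keep <- !ct$transcript_id %in% exclude
  tu <- sum(ct[[u_col]][keep]); tm <- sum(ct[[m_col]][keep])
  if (tm == 0) stop_recseq("urpf", "total mRPF is zero")
  shares <- if (base::length(exclude)) {
    ex <- ct[transcript_id %in% exclude,
             .(urpf = sum(get(u_col))), by = "transcript_id"]
    ex[, share_of_total_urpf := if (all_u > 0) urpf / all_u else 0]
    ex[]
  } else NULL
  list(ratio = tu / tm, total_urpf = tu, total_mrpf = tm,
       excluded_shares = shares)
}
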