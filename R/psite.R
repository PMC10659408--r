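#' P-site assignment configuration
#'
#' The predicted P-site of a 25-34 nt 48S footprint lies `offset` nt
#' downstream of its 5' end (default 12 for every length, the position
#' implied by the bulk of footprint 5' ends mapping 12 nt upstream of
#' the main AUG).  Region windows are closed intervals in signed
#' coordinates relative to the main AUG, where the A of the AUG is +1,
#' the nucleotide 5' of it is -1, and there is no position 0:
#' main footprints (mRPF) have P-sites in `[-3, +6]`, internal (iRPF) in
#' `[+9, stop end]`, CDS (cdsRPF) in `[cds_from, stop end]`, and
#' upstream (uRPF) from the transcript 5' end to `[-5]`.  Positions -4
#' and +7/+8 belong to no category, following the stated window bounds
#' literally.
#'
#' @param offset_by_length named integer vector, offset per footprint
#'   length; a single unnamed value is applied to all lengths.
#' @param min_len,max_len accepted footprint lengths (reads outside are
#'   rejected and tallied in a discard log).
#' @param mrpf_window signed closed interval for mRPFs.
#' @param irpf_from signed start of the internal window.
#' @param urpf_to signed end of the upstream window.
#' @param cds_from signed start of the CDS window (-3 so that
#'   cdsRPF covers mRPF and iRPF; +1 reproduces the narrower reading).
#' @return list of class `recseq_psite_config`.
#' @export
psite_config <- function(offset_by_length = 12L, min_len = 25L, max_len = 34L,
                         mrpf_window = c(-3L, 6L), irpf_from = 9L,
                         urpf_to = -5L, cds_from = -3L) {
  lens <- min_len:max_len
  off <- if (length(offset_by_length) == 1L && is.null(names(offset_by_length)))
    setNames(rep(as.integer(offset_by_length), length(lens)), lens)
  else {
    if (!all(as.character(lens) %in% names(offset_by_length)))
      stop_recseq("psite", "offset_by_length must cover every length in [min_len, max_len]")
    setNames(as.integer(offset_by_length[as.character(lens)]), lens)
  }
  if (any(off <= 0) || any(off >= min_len))
    stop_recseq("psite", "offsets must be positive and less than min_len")
  structure(list(offset_by_length = off, min_len = as.integer(min_len),
                 max_len = as.integer(max_len), mrpf_window = mrpf_window,
                 irpf_from = as.integer(irpf_from),
                 urpf_to = as.integer(urpf_to),
                 cds_from = as.integer(cds_from)),
            class = "recseq_psite_config")
}

# signed position relative to cds_start under the A-of-AUG = +1,
# skip-zero convention
signed_rel <- function(abs_pos, cds_start) {
  ifelse(abs_pos >= cds_start, abs_pos - cds_start + 1L, abs_pos - cds_start)
}

#' Assign P-sites to footprints
#'
#' Returns the signed P-site position of each footprint relative to the
#' main AUG (A = +1, no zero).  Footprints outside the accepted length
#' range get NA and are counted as rejected.
#'
#' @param five_prime_pos 1-based footprint 5'-end positions.
#' @param length footprint lengths.
#' @param cds_start 1-based main-AUG positions (recycled).
#' @param cfg a [psite_config()].
#' @return integer vector of signed positions, NA where rejected.
#' @export
assign_psite <- function(five_prime_pos, length, cds_start, cfg = psite_config()) {
  ok <- length >= cfg$min_len & length <= cfg$max_len
  off <- rep(NA_integer_, base::length(length))
  off[ok] <- cfg$offset_by_length[as.character(length[ok])]
  signed_rel(five_prime_pos + off, cds_start)
}

# join footprints to annotation, drop spikes, filter lengths, compute
# signed P-site; shared by counting functions
prepare_psites <- function(footprints, annots, cfg) {
  unknown <- setdiff(unique(footprints$transcript_id), annots$transcript_id)
  if (base::length(unknown))
    stop_recseq("count", "unknown transcript ids: ",
                paste(head(unknown, 5), collapse = ", "))
  fp <- data.table::as.data.table(footprints)
  ann <- data.table::as.data.table(annots)
  fp <- ann[, .(transcript_id, utr5_len, cds_start, cds_end, tx_len,
                is_spikein)][fp, on = "transcript_id"]
  fp <- fp[is_spikein == FALSE | is.na(is_spikein)]
  n_rej <- sum(fp$count[fp$length < cfg$min_len | fp$length > cfg$max_len])
  fp <- fp[length >= cfg$min_len & length <= cfg$max_len]
  fp[, psite := assign_psite(five_prime_pos, length, cds_start, cfg)]
  data.table::setattr(fp, "n_rejected", n_rej)
  fp
}

#' Count footprints in the main / upstream / internal / CDS windows
#'
#' Pure interval membership on signed P-site positions:
#' mRPF in `[-3, +6]`, uRPF in `[5' end, -5]`, iRPF in `[+9, stop end]`,
#' cdsRPF in `[-3, stop end]` (all closed; stop end is the last
#' nucleotide of the stop codon).  Every (sample, transcript) pair in
#' the cross of observed samples and annotated non-spike transcripts is
#' reported, zeros included.
#'
#' @param footprints data.table (sample_id, transcript_id,
#'   five_prime_pos, length, count).
#' @param annots annotation data.table.
#' @param cfg a [psite_config()].
#' @return data.table (sample_id, transcript_id, mRPF, uRPF, iRPF,
#'   cdsRPF); attribute `n_rejected` counts length-filtered reads.
#' @export
count_regions <- function(footprints, annots, cfg = psite_config()) {
  ann <- data.table::as.data.table(annots)[is_spikein == FALSE]
  samples <- unique(footprints$sample_id)
  grid <- data.table::CJ(sample_id = samples,
                         transcript_id = ann$transcript_id)
  if (nrow(footprints) == 0L) {
    out <- grid[, `:=`(mRPF = 0, uRPF = 0, iRPF = 0, cdsRPF = 0)]
    data.table::setattr(out, "n_rejected", 0)
    return(out[])
  }
  fp <- prepare_psites(footprints, annots, cfg)
  stop_end <- fp$cds_end - fp$cds_start + 1L
  fp[, `:=`(
    in_m = psite >= cfg$mrpf_window[1] & psite <= cfg$mrpf_window[2],
    in_u = psite <= cfg$urpf_to & psite >= -utr5_len,
    in_i = psite >= cfg$irpf_from & psite <= stop_end,
    in_c = psite >= cfg$cds_from & psite <= stop_end)]
  agg <- fp[, .(mRPF = sum(count * in_m), uRPF = sum(count * in_u),
                iRPF = sum(count * in_i), cdsRPF = sum(count * in_c)),
            by = c("sample_id", "transcript_id")]
  out <- agg[grid, on = c("sample_id", "transcript_id")]
  for (cn in c("mRPF", "uRPF", "iRPF", "cdsRPF"))
    data.table::set(out, which(is.na(out[[cn]])), cn, 0)
  data.table::setattr(out, "n_rejected", attr(fp, "n_rejected"))
  out[]
}

#' Metagene matrix of footprint 5' ends around the main AUG
#'
#' Rows are footprint lengths (25-34 by default), columns are signed
#' 5'-end positions in the requested window around the main AUG (A =
#' +1, no zero: the default (-50, +100) window has 150 columns).  Cell
#' (L, p) is the summed count of length-L footprints whose 5' end sits
#' at relative position p; transcripts shorter than the window simply
#' contribute the positions they cover.
#'
#' @param footprints footprint records.
#' @param annots annotation data.table.
#' @param window signed (from, to) bounds.
#' @param cfg a [psite_config()] (length bounds only).
#' @return numeric matrix with dimnames (length, position).
#' @export
build_metagene <- function(footprints, annots, window = c(-50L, 100L),
                           cfg = psite_config()) {
  if (window[1] >= window[2]) stop_recseq("metagene", "bad window bounds")
  positions <- setdiff(seq(window[1], window[2]), 0L)
  lens <- cfg$min_len:cfg$max_len
  m <- matrix(0, nrow = base::length(lens), ncol = base::length(positions),
              dimnames = list(length = as.character(lens),
                              position = as.character(positions)))
  if (nrow(footprints) == 0L) return(m)
  fp <- prepare_psites(footprints, annots, cfg)
  fp[, rel5 := signed_rel(five_prime_pos, cds_start)]
  fp <- fp[rel5 >= window[1] & rel5 <= window[2] & rel5 != 0L]
  if (nrow(fp) == 0L) return(m)
  agg <- fp[, .(count = sum(count)), by = c("length", "rel5")]
  m[cbind(as.character(agg$length), as.character(agg$rel5))] <- agg$count
  m
}

#' Modal 5'-end offset of a metagene matrix
#'
#' @param metagene matrix from [build_metagene()].
#' @return the signed position with maximal total density.
#' @export
metagene_modal_offset <- function(metagene) {
  totals <- colSums(metagene)
  as.integer(names(totals)[which.max(totals)])
}
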