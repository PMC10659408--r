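#' Default spike-in reference (synthetic)
#'
#' Annotation of the two spike-in luciferase mRNAs (FLUC, RLUC) carrying
#' pre-formed 48S PICs: for each spike AUG used as a counting category,
#' the transcript, the 1-based position of the A of the AUG, and whether
#' it is the main or an internal AUG.  Counting uses the same [-3, +6]
#' P-site window around every category AUG as main-AUG counting does.
#' Positions are synthetic stand-ins (no published spike sequence is
#' bundled); they are spaced so the expanded windows never overlap.
#'
#' @return a `data.table` with columns `spike_id`, `category`, `aug_pos`,
#'   `is_main`, `tx_len`.
#' @export
default_spike_reference <- function() {
  ref <- data.table::data.table(
    spike_id = c("FLUC", "FLUC", "FLUC", "FLUC", "RLUC", "RLUC", "RLUC"),
    category = c("FLUC_mAUG", "FLUC_i150", "FLUC_i420", "FLUC_i780",
                 "RLUC_mAUG", "RLUC_i200", "RLUC_i500"),
    aug_pos  = c(30L, 150L, 420L, 780L, 25L, 200L, 500L),
    is_main  = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    tx_len   = c(1650L, 1650L, 1650L, 1650L, 1100L, 1100L, 1100L))
  validate_spike_reference(ref)
}

validate_spike_reference <- function(ref) {
  if (nrow(ref) < 2) stop_recseq("spike", "need >= 2 spike categories")
  # [-3, +6] signed windows expand to [aug-3, aug+5] absolute
  by_tx <- split(ref$aug_pos, ref$spike_id)
  for (p in by_tx) {
    p <- sort(p)
    if (length(p) > 1 && any(diff(p) < 9))
      stop_recseq("spike", "spike category windows overlap after expansion")
  }
  ref
}

#' Spike annotation rows in transcript-annotation layout
#'
#' @param ref a spike reference table.
#' @return a `data.table` matching the transcript annotation schema, one
#'   row per spike transcript, flagged `is_spikein = TRUE`.
#' @export
spike_annotation <- function(ref = default_spike_reference()) {
  main <- ref[ref$is_main]
  data.table::data.table(
    transcript_id = main$spike_id,
    tx_len = main$tx_len,
    utr5_len = main$aug_pos - 1L,
    cds_start = main$aug_pos,
    cds_end = main$tx_len,    # nominal; spikes are never region-counted
    context_score = NA_real_,
    is_spikein = TRUE,
    excluded_from_uorf_totals = FALSE)
}
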