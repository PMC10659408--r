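#' Count spike-in footprints per AUG category
#'
#' Applies the same P-site rule and [-3, +6] window used for main-AUG
#' counting to every spike AUG category (main and internal AUGs of the
#' spike transcripts).  A sample with no spike reads at all is treated
#' as a failed spike-in and raises an error.
#'
#' @param footprints footprint records (spike and transcriptome reads
#'   may be mixed; only spike transcripts are used).
#' @param ref spike reference, see [default_spike_reference()].
#' @param cfg a [psite_config()].
#' @return data.table, one row per sample, one column per category.
#' @export
count_spike_categories <- function(footprints, ref = default_spike_reference(),
                                   cfg = psite_config()) {
  fp <- data.table::as.data.table(footprints)[transcript_id %in% ref$spike_id]
  samples <- unique(footprints$sample_id)
  missing <- setdiff(samples, unique(fp$sample_id))
  if (base::length(missing))
    stop_recseq("spike", "no spike-in reads for sample(s): ",
                paste(missing, collapse = ", "))
  if (nrow(fp) == 0L) stop_recseq("spike", "no spike-in reads present")
  fp <- fp[length >= cfg$min_len & length <= cfg$max_len]
  fp[, psite_abs := five_prime_pos + cfg$offset_by_length[as.character(length)]]
  res <- data.table::data.table(sample_id = samples)
  for (k in seq_len(nrow(ref))) {
    lo <- ref$aug_pos[k] + cfg$mrpf_window[1]          # signed -3 -> abs aug-3
    hi <- ref$aug_pos[k] + cfg$mrpf_window[2] - 1L     # signed +6 -> abs aug+5
    cnt <- fp[transcript_id == ref$spike_id[k] & psite_abs >= lo & psite_abs <= hi,
              .(n = sum(count)), by = "sample_id"]
    res[, (ref$category[k]) := 0]
    res[cnt, on = "sample_id", (ref$category[k]) := i.n]
  }
  res[]
}

#' Geometric-mean spike-in size factors
#'
#' Per sample, the geometric mean of the spike category counts; every
#' sample is normalized to the sample with the highest geometric mean
#' (whose factor is therefore 1), and a normalized count is the raw
#' count divided by the sample's factor.  The geometric mean (rather
#' than the arithmetic mean) makes the factors exact under
#' multiplicative per-sample losses such as those introduced by
#' exponential library amplification.
#'
#' @param category_counts table from [count_spike_categories()].
#' @param zero_policy `"strict"` errors on any zero category (a failed
#'   spike-in); `"drop"` removes zero-containing categories symmetrically
#'   across all samples.
#' @return list of class `recseq_size_factors` with `table` (sample_id,
#'   geo_mean, size_factor, is_reference), `reference_sample`, and
#'   `categories` used.
#' @export
compute_spike_size_factors <- function(category_counts,
                                       zero_policy = c("strict", "drop")) {
  zero_policy <- match.arg(zero_policy)
  cc <- data.table::as.data.table(category_counts)
  cats <- setdiff(names(cc), "sample_id")
  mat <- as.matrix(cc[, ..cats])
  rownames(mat) <- cc$sample_id
  if (any(mat == 0)) {
    if (zero_policy == "strict") {
      bad <- which(mat == 0, arr.ind = TRUE)[1, ]
      stop_recseq("spike", sprintf(
        "zero spike count for sample '%s', category '%s' (failed spike-in)",
        rownames(mat)[bad[1]], cats[bad[2]]))
    }
    keep <- colSums(mat == 0) == 0
    if (sum(keep) < 2) stop_recseq("spike", "fewer than 2 usable spike categories")
    mat <- mat[, keep, drop = FALSE]
    cats <- cats[keep]
  }
  gm <- apply(mat, 1, geometric_mean)
  ref <- names(gm)[which.max(gm)]
  tab <- data.table::data.table(sample_id = names(gm), geo_mean = unname(gm),
                                size_factor = unname(gm / gm[[ref]]),
                                is_reference = names(gm) == ref)
  structure(list(table = tab, reference_sample = ref, categories = cats),
            class = "recseq_size_factors")
}

#' Apply size factors to a region count table
#'
#' Adds `norm_*` columns (`raw / size_factor`); raw columns are left
#' untouched.  The reference sample's normalized counts equal its raw
#' counts.
#'
#' @param table region count table from [count_regions()].
#' @param sf a `recseq_size_factors`.
#' @return the table with `norm_mRPF`, `norm_uRPF`, `norm_iRPF`,
#'   `norm_cdsRPF` columns added.
#' @export
apply_size_factors <- function(table, sf) {
  tab <- data.table::as.data.table(table)
  fac <- setNames(sf$table$size_factor, sf$table$sample_id)
  missing <- setdiff(unique(tab$sample_id), names(fac))
  if (base::length(missing))
    stop_recseq("spike", "no size factor for sample(s): ",
                paste(missing, collapse = ", "))
  f <- fac[tab$sample_id]
  for (cn in intersect(c("mRPF", "uRPF", "iRPF", "cdsRPF"), names(tab)))
    tab[, (paste0("norm_", cn)) := get(cn) / f]
  tab[]
}
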