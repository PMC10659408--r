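# In-memory analysis chain shared by the acceptance tests: count ->
# normalize -> filter -> per-region NB Wald, mirroring run_pipeline()
# without the file round-trip.
analyse_experiment <- function(exp, condA, condB, min_total = 8,
                               strict = FALSE) {
  cfg <- exp$config
  ann <- rbind(exp$tx$annotation, spike_annotation(cfg$spike_reference),
               fill = TRUE)
  counts <- count_regions(exp$footprints, ann)
  sf <- compute_spike_size_factors(
    count_spike_categories(exp$footprints, cfg$spike_reference))
  norm <- apply_size_factors(counts, sf)
  st <- exp$samples[exp$samples$condition %in% c(condA, condB)]
  kept <- filter_min_counts(counts[sample_id %in% st$sample_id],
                            min_total, strict = strict, region = "mRPF")
  diff_region <- function(region) {
    mat <- data.table::dcast(
      counts[sample_id %in% st$sample_id & transcript_id %in% kept],
      transcript_id ~ sample_id, value.var = region)
    m <- as.matrix(mat[, -1])
    rownames(m) <- mat$transcript_id
    scond <- st$condition[match(colnames(m), st$sample_id)]
    sfv <- sf$table$size_factor[match(colnames(m), sf$table$sample_id)]
    disp <- estimate_dispersions(m, sfv, scond)
    nb_wald_test(m, sfv, factor(scond, levels = c(condA, condB)), disp)
  }
  cond_means <- function(regions = c("mRPF", "iRPF")) {
    j <- norm[st, on = "sample_id"]
    agg <- j[, lapply(.SD, mean), by = c("condition", "transcript_id"),
             .SDcols = paste0("norm_", regions)]
    wide <- data.table::dcast(
      agg, transcript_id ~ condition,
      value.var = paste0("norm_", regions))
    names(wide) <- sub(paste0("^norm_(", paste(regions, collapse = "|"),
                              ")_?", condA, "$"), "\\1_A", names(wide))
    names(wide) <- sub(paste0("^norm_(", paste(regions, collapse = "|"),
                              ")_?", condB, "$"), "\\1_B", names(wide))
    wide
  }
  list(ann = ann, counts = counts, sf = sf, norm = norm, st = st,
       kept = kept, diff_region = diff_region, cond_means = cond_means)
}
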