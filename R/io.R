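#' Write a synthetic experiment to plain-text files
#'
#' Emits the standard file set consumed by the pipeline: transcriptome
#' FASTA, annotation TSV (transcript_id, tx_len, utr5_len, cds_start,
#' cds_end, context_score, internal/upstream AUG positions
#' comma-joined, flags), footprint TSV (sample_id, transcript_id,
#' five_prime_pos, length, count), RNA-seq TSV, PARS profile TSV,
#' sample table, spike reference, planted-truth TSVs, and the
#' configuration as JSON.
#'
#' @param exp a `recseq_experiment` from [simulate_experiment()].
#' @param outdir output directory (created).
#' @return invisible named list of written paths.
#' @export
write_experiment <- function(exp, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  ann <- data.table::copy(exp$tx$annotation)
  ia <- exp$tx$internal_aug[, .(internal_augs = paste(pos, collapse = ",")),
                            by = "transcript_id"]
  ua <- exp$tx$upstream_aug[, .(upstream_augs = paste(pos, collapse = ",")),
                            by = "transcript_id"]
  ann <- ua[ia[ann, on = "transcript_id"], on = "transcript_id"]
  ann[is.na(internal_augs), internal_augs := ""]
  ann[is.na(upstream_augs), upstream_augs := ""]
  paths <- list(
    fasta = p("transcriptome.fasta"), annotation = p("annotation.tsv"),
    footprints = p("footprints.tsv"), rnaseq = p("rnaseq.tsv"),
    pars = p("pars.tsv"), samples = p("samples.tsv"),
    spike_ref = p("spike_reference.tsv"),
    truth_tx = p("truth_transcripts.tsv"),
    truth_cond = p("truth_conditions.tsv"), config = p("config.json"))
  write_fasta(exp$tx$sequences, paths$fasta)
  data.table::fwrite(ann, paths$annotation, sep = "\t")
  data.table::fwrite(exp$footprints, paths$footprints, sep = "\t")
  data.table::fwrite(exp$rnaseq, paths$rnaseq, sep = "\t")
  data.table::fwrite(exp$tx$pars, paths$pars, sep = "\t")
  data.table::fwrite(exp$samples, paths$samples, sep = "\t")
  data.table::fwrite(exp$config$spike_reference, paths$spike_ref, sep = "\t")
  data.table::fwrite(exp$truth$per_transcript, paths$truth_tx, sep = "\t")
  data.table::fwrite(exp$truth$per_condition, paths$truth_cond, sep = "\t")
  write_config(exp$config, paths$config)
  invisible(paths)
}

write_fasta <- function(sequences, path) {
  if (requireNamespace("Biostrings", quietly = TRUE) && base::length(sequences)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (id in names(sequences))
      writeLines(c(paste0(">", id), sequences[[id]]), con)
  }
  invisible(path)
}

#' Serialize / restore a synthetic configuration as JSON
#'
#' The context model matrix and the spike reference table are stored in
#' expanded form; [read_config()] rebuilds a validated
#' `recseq_config`.
#'
#' @param config a `recseq_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cm <- cfg$context_model
  cfg$context_model <- list(rows = rownames(cm), cols = colnames(cm),
                            values = as.vector(cm))
  cfg$spike_reference <- as.data.frame(cfg$spike_reference)
  # named atomic vectors must survive as JSON objects, not bare arrays
  for (nm in c("footprint_len_probs", "offset_jitter_probs", "spike_counts"))
    cfg[[nm]] <- as.list(cfg[[nm]])
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- matrix(j$context_model$values, nrow = base::length(j$context_model$rows),
               dimnames = list(j$context_model$rows, j$context_model$cols))
  for (nm in c("footprint_len_probs", "offset_jitter_probs", "spike_counts"))
    j[[nm]] <- unlist(j[[nm]])
  args <- j[intersect(names(j), names(formals(synthetic_config)))]
  args$context_model <- cm
  args$spike_reference <- data.table::as.data.table(j$spike_reference)
  args$sample_loss <- j$sample_loss
  do.call(synthetic_config, args)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_recseq("io", what, " file not found: ", path)
  dt <- data.table::fread(path, sep = "\t")
  miss <- setdiff(required, names(dt))
  if (base::length(miss))
    stop_recseq("io", what, " is missing column(s): ", paste(miss, collapse = ", "))
  dt
}

#' Readers for the pipeline's TSV inputs
#'
#' Thin `fread` wrappers with schema checks.
#'
#' @param path file path.
#' @return a data.table.
#' @export
read_annotation <- function(path) {
  ann <- read_tsv_checked(path, c("transcript_id", "utr5_len", "cds_start",
                                  "cds_end"), "annotation")
  if (!"tx_len" %in% names(ann)) ann[, tx_len := cds_end + 0L]
  if (!"is_spikein" %in% names(ann)) ann[, is_spikein := FALSE]
  if (!"excluded_from_uorf_totals" %in% names(ann))
    ann[, excluded_from_uorf_totals := FALSE]
  bad <- ann[utr5_len != cds_start - 1L]
  if (nrow(bad))
    stop_recseq("io", "annotation violates utr5_len = cds_start - 1 for: ",
                paste(head(bad$transcript_id, 5), collapse = ", "))
  ann
}

#' @rdname read_annotation
#' @export
read_footprints <- function(path) {
  read_tsv_checked(path, c("sample_id", "transcript_id", "five_prime_pos",
                           "length", "count"), "footprints")
}

#' @rdname read_annotation
#' @export
read_rnaseq <- function(path) {
  read_tsv_checked(path, c("transcript_id", "position", "count"), "rnaseq")
}

#' @rdname read_annotation
#' @export
read_pars <- function(path) {
  read_tsv_checked(path, c("transcript_id", "position", "score"), "pars")
}

#' @rdname read_annotation
#' @export
read_samples <- function(path) {
  read_tsv_checked(path, c("sample_id", "condition"), "samples")
}

#' @rdname read_annotation
#' @export
read_spike_reference <- function(path) {
  validate_spike_reference(
    read_tsv_checked(path, c("spike_id", "category", "aug_pos", "is_main",
                             "tx_len"), "spike reference"))
}
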