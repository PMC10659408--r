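#' Build a pipeline run configuration
#'
#' @param annotation,footprints,rnaseq,samples,spike_ref,pars input file
#'   paths (`pars` optional; `spike_ref` NULL uses the bundled default
#'   reference).
#' @param contrasts character vector of `"B:A"` contrasts (B over A) on
#'   condition labels from the sample table.
#' @param outdir output directory.
#' @param regions which region counts to test.
#' @param fdr,fc,min_total,strict_min significance and filtering
#'   thresholds; the defaults are FDR < 0.05, fold change > 2 (< 0.5),
#'   and a strict "> min_total reads across all samples" filter.
#' @param min_len,max_len,offset footprint length bounds and P-site
#'   offset.
#' @param exclude transcript ids excluded from translatome-wide
#'   upstream-footprint totals (added to any annotation flags).
#' @param seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return list of class `recseq_run_config`.
#' @export
run_config <- function(annotation, footprints, rnaseq, samples,
                       spike_ref = NULL, pars = NULL,
                       contrasts, outdir,
                       regions = c("mRPF", "uRPF", "iRPF"),
                       fdr = 0.05, fc = 2, min_total = 90, strict_min = TRUE,
                       min_len = 25L, max_len = 34L, offset = 12L,
                       exclude = character(), seed = 1L) {
  if (fdr <= 0 || fc <= 0 || min_total < 0)
    stop_recseq("config", "thresholds must be positive")
  structure(list(annotation = annotation, footprints = footprints,
                 rnaseq = rnaseq, samples = samples, spike_ref = spike_ref,
                 pars = pars, contrasts = contrasts, outdir = outdir,
                 regions = regions, fdr = fdr, fc = fc,
                 min_total = min_total, strict_min = strict_min,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 offset = as.integer(offset), exclude = exclude,
                 seed = as.integer(seed)),
            class = "recseq_run_config")
}

parse_contrast <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (base::length(parts) != 2) stop_recseq("config", "contrast must be 'B:A': ", x)
  list(B = parts[1], A = parts[2])
}

#' Validate pipeline inputs
#'
#' Schema checks on every input table, coordinate sanity (footprints
#' within transcript bounds), and sample/condition consistency.  Never
#' throws; failures are returned in the report.
#'
#' @param rc a [run_config()].
#' @return data.table (check, status, detail); zero `fail` rows means
#'   the inputs are usable.
#' @export
validate_inputs <- function(rc) {
  rep <- list()
  note <- function(check, status, detail = "")
    rep[[base::length(rep) + 1L]] <<- data.table::data.table(
      check = check, status = status, detail = detail)
  ann <- fp <- st <- NULL
  try_read <- function(check, fn, path) {
    out <- tryCatch(fn(path), error = function(e) {
      note(check, "fail", conditionMessage(e)); NULL
    })
    if (!is.null(out)) note(check, "ok")
    out
  }
  ann <- try_read("annotation", read_annotation, rc$annotation)
  fp <- try_read("footprints", read_footprints, rc$footprints)
  try_read("rnaseq", read_rnaseq, rc$rnaseq)
  st <- try_read("samples", read_samples, rc$samples)
  if (!is.null(rc$pars)) try_read("pars", read_pars, rc$pars)
  if (!is.null(rc$spike_ref)) try_read("spike_ref", read_spike_reference, rc$spike_ref)

  if (!is.null(ann) && !is.null(fp)) {
    ref <- if (is.null(rc$spike_ref)) default_spike_reference() else
      tryCatch(read_spike_reference(rc$spike_ref), error = function(e) NULL)
    full <- rbind(ann, if (!is.null(ref)) spike_annotation(ref), fill = TRUE)
    fp2 <- data.table::copy(fp)[, line := .I + 1L]
    j <- full[, .(transcript_id, tx_len)][fp2, on = "transcript_id"]
    unknown <- j[is.na(tx_len)]
    if (nrow(unknown))
      note("footprint transcripts", "fail",
           sprintf("unknown transcript '%s' (line %d)",
                   unknown$transcript_id[1], unknown$line[1]))
    else note("footprint transcripts", "ok")
    oob <- j[!is.na(tx_len) &
               (five_prime_pos < 1L | five_prime_pos + length - 1L > tx_len)]
    if (nrow(oob))
      note("footprint bounds", "fail",
           sprintf("footprint beyond transcript end on '%s' (line %d)",
                   oob$transcript_id[1], oob$line[1]))
    else note("footprint bounds", "ok")
  }
  if (!is.null(st)) {
    dup <- st[, .(n = data.table::uniqueN(condition)), by = "sample_id"][n > 1]
    if (nrow(dup))
      note("sample conditions", "fail",
           paste("sample in multiple conditions:",
                 paste(dup$sample_id, collapse = ", ")))
    else note("sample conditions", "ok")
    if (!is.null(fp)) {
      extra <- setdiff(unique(fp$sample_id), st$sample_id)
      if (base::length(extra))
        note("sample coverage", "fail",
             paste("footprint samples missing from sample table:",
                   paste(extra, collapse = ", ")))
      else note("sample coverage", "ok")
    }
  }
  data.table::rbindlist(rep)
}

#' Run the full analysis pipeline
#'
#' count -> normalize -> differential (per region, per contrast) ->
#' efficiency -> feature summaries, writing TSV outputs and a manifest
#' (file list with md5 hashes, thresholds, package version).
#' Idempotent for identical inputs and configuration.
#'
#' @param rc a [run_config()].
#' @return invisible manifest list (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(rc) {
  report <- validate_inputs(rc)
  if (any(report$status == "fail")) {
    bad <- report[status == "fail"][1]
    stop_recseq("validate", bad$check, ": ", bad$detail)
  }
  dir.create(rc$outdir, showWarnings = FALSE, recursive = TRUE)
  out_paths <- character(0)
  emit <- function(dt, name) {
    pth <- file.path(rc$outdir, name)
    data.table::fwrite(dt, pth, sep = "\t")
    out_paths <<- c(out_paths, pth)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_recseq(name, conditionMessage(e)))
  }

  ann <- read_annotation(rc$annotation)
  fp <- read_footprints(rc$footprints)
  rnaseq <- read_rnaseq(rc$rnaseq)
  st <- read_samples(rc$samples)
  spike_ref <- if (is.null(rc$spike_ref)) default_spike_reference() else
    read_spike_reference(rc$spike_ref)
  full_ann <- rbind(ann, spike_annotation(spike_ref), fill = TRUE)
  cfg <- psite_config(offset_by_length = rc$offset, min_len = rc$min_len,
                      max_len = rc$max_len)

  counts <- stage("count", count_regions(fp, full_ann, cfg))
  cat_counts <- stage("normalize", {
    if (!any(fp$transcript_id %in% spike_ref$spike_id))
      stop("missing spike reference reads: no footprints on spike transcripts")
    count_spike_categories(fp, spike_ref, cfg)
  })
  sf <- stage("normalize", compute_spike_size_factors(cat_counts))
  norm_counts <- apply_size_factors(counts, sf)
  emit(norm_counts, "region_counts.tsv")
  emit(cbind(cat_counts, sf$table[, .(geo_mean, size_factor, is_reference)]),
       "size_factors.tsv")

  dens <- stage("efficiency", compute_mrna_density(rnaseq, full_ann))
  eff <- stage("efficiency", efficiency_table(norm_counts, st, dens))
  emit(eff, "efficiency.tsv")

  contrasts <- lapply(rc$contrasts, parse_contrast)
  diffs <- list()
  for (ct in contrasts) {
    for (cn in c("A", "B"))
      if (!ct[[cn]] %in% st$condition)
        stop_recseq("diffexp", "unknown condition in contrast: ", ct[[cn]])
    sub <- st[condition %in% c(ct$A, ct$B)]
    kept <- filter_min_counts(
      counts[sample_id %in% sub$sample_id], rc$min_total,
      strict = rc$strict_min, region = "mRPF")
    for (region in rc$regions) {
      mat <- data.table::dcast(counts[sample_id %in% sub$sample_id &
                                        transcript_id %in% kept],
                               transcript_id ~ sample_id, value.var = region)
      m <- as.matrix(mat[, -1]); rownames(m) <- mat$transcript_id
      scond <- sub$condition[match(colnames(m), sub$sample_id)]
      sfv <- sf$table$size_factor[match(colnames(m), sf$table$sample_id)]
      disp <- stage("diffexp", estimate_dispersions(m, sfv, scond))
      res <- stage("diffexp", nb_wald_test(
        m, sfv, factor(scond, levels = c(ct$A, ct$B)), disp))
      res[, class := classify_class(padj, log2FC, rc$fdr, rc$fc)]
      tag <- sprintf("%s_%s_vs_%s", region, ct$B, ct$A)
      res[, `:=`(region = region, contrast = paste0(ct$B, ":", ct$A),
                 fdr_cut = rc$fdr, fc_cut = rc$fc, min_total = rc$min_total)]
      diffs[[tag]] <- res
      emit(res, paste0("diffexp_", tag, ".tsv"))
    }
    de <- stage("efficiency",
                delta_between_conditions(eff, ct$A, ct$B, "RE"))
    emit(de, sprintf("delta_re_%s_vs_%s.tsv", ct$B, ct$A))
  }

  excl <- union(rc$exclude,
                ann$transcript_id[ann$excluded_from_uorf_totals %in% TRUE])
  urpf <- stage("features", {
    per_cond <- eff[, .(ratio = urpf_mrpf_ratio(
      .SD, exclude = excl, u_col = "uRPF", m_col = "mRPF")$ratio),
      by = "condition"]
    per_cond
  })
  emit(urpf, "urpf_mrpf_ratio.tsv")

  manifest <- list(
    package = "recseq",
    version = as.character(utils::packageVersion("recseq")),
    seed = rc$seed,
    thresholds = list(fdr = rc$fdr, fc = rc$fc, min_total = rc$min_total,
                      strict_min = rc$strict_min, min_len = rc$min_len,
                      max_len = rc$max_len, offset = rc$offset),
    contrasts = rc$contrasts,
    inputs = lapply(list(annotation = rc$annotation, footprints = rc$footprints,
                         rnaseq = rc$rnaseq, samples = rc$samples),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    outputs = lapply(setNames(out_paths, basename(out_paths)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(rc$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
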