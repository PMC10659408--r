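#' Write a transcript-space wiggle track
#'
#' variableStep, 1-based; one declaration line per transcript.  Values
#' are written with six decimal places, so a round-trip through
#' [read_wiggle()] is exact to 1e-6.
#'
#' @param track data.table (transcript_id, position, value).
#' @param path output file.
#' @param name track name written in the header.
#' @export
write_wiggle <- function(track, path, name = "recseq") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s\"", name), con)
  tr <- data.table::as.data.table(track)[order(transcript_id, position)]
  for (id in unique(tr$transcript_id)) {
    sub <- tr[transcript_id == id]
    writeLines(sprintf("variableStep chrom=%s", id), con)
    writeLines(sprintf("%d %.6f", sub$position, sub$value), con)
  }
  invisible(path)
}

#' Read a transcript-space wiggle track
#'
#' @param path a file written by [write_wiggle()].
#' @return data.table (transcript_id, position, value).
#' @export
read_wiggle <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track")]
  chrom <- NA_character_
  out <- vector("list", base::length(lines))
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], "variableStep")) {
      chrom <- sub(".*chrom=([^ ]+).*", "\\1", lines[i])
    } else if (nzchar(lines[i])) {
      xs <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
      out[[i]] <- data.table::data.table(
        transcript_id = chrom, position = as.integer(xs[1]),
        value = as.numeric(xs[2]))
    }
  }
  data.table::rbindlist(out)
}

#' Export size-factor-normalized coverage tracks
#'
#' One transcript-space wiggle file per sample (and optionally one
#' averaged track per condition), with per-position density of either
#' predicted P-sites or raw 5' ends, divided by the sample's size
#' factor.
#'
#' @param footprints footprint records.
#' @param annots annotation (spikes are excluded from tracks).
#' @param dir output directory, created if needed.
#' @param size_factors a size-factor set from
#'   [compute_spike_size_factors()], or NULL for unnormalized tracks.
#' @param value `"psite"` or `"five_prime"`.
#' @param samples optional sample table (sample_id, condition); when
#'   given, condition-averaged tracks (arithmetic mean of the
#'   per-replicate normalized tracks) are also written.
#' @param cfg a [psite_config()].
#' @return invisible character vector of written paths.
#' @export
export_tracks <- function(footprints, annots, dir, size_factors = NULL,
                          value = c("psite", "five_prime"), samples = NULL,
                          cfg = psite_config()) {
  value <- match.arg(value)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- prepare_psites(footprints, annots, cfg)
  fp[, position := if (value == "psite") five_prime_pos +
        cfg$offset_by_length[as.character(length)] else five_prime_pos]
  sf <- if (is.null(size_factors)) NULL else
    setNames(size_factors$table$size_factor, size_factors$table$sample_id)
  paths <- character(0)
  per_sample <- list()
  for (sid in unique(fp$sample_id)) {
    tr <- fp[sample_id == sid, .(value = sum(count)),
             by = c("transcript_id", "position")]
    fac <- if (is.null(sf)) 1 else {
      if (!sid %in% names(sf)) stop_recseq("tracks", "no size factor for sample ", sid)
      sf[[sid]]
    }
    tr[, value := value / fac]
    per_sample[[sid]] <- tr
    p <- file.path(dir, paste0(sid, ".", value, ".wig"))
    write_wiggle(tr, p, name = sid)
    paths <- c(paths, p)
  }
  if (!is.null(samples)) {
    st <- data.table::as.data.table(samples)
    for (cond in unique(st$condition)) {
      ids <- intersect(st$sample_id[st$condition == cond], names(per_sample))
      if (!base::length(ids)) next
      avg <- average_tracks(per_sample[ids])
      p <- file.path(dir, paste0(cond, ".mean.", value, ".wig"))
      write_wiggle(avg, p, name = paste0(cond, "_mean"))
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Arithmetic mean of replicate tracks
#'
#' Positions absent from a replicate contribute zero.
#'
#' @param tracks list of track data.tables (transcript_id, position, value).
#' @return a track data.table.
#' @export
average_tracks <- function(tracks) {
  n <- base::length(tracks)
  all <- data.table::rbindlist(tracks)
  all[, .(value = sum(value) / n), by = c("transcript_id", "position")][
    order(transcript_id, position)]
}
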