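#' Generate a toy transcriptome
#'
#' Draws per-transcript geometry (5'UTR and CDS lengths), random
#' sequences with a guaranteed main AUG and terminal stop codon,
#' abundances, PARS-like per-nucleotide structure profiles, and
#' sequence-derived start-context scores.  Upstream AUGs are enumerated
#' from the 5'UTR sequence; internal AUGs are enumerated in all three
#' frames within the CDS at absolute positions >= cds_start + 9, the
#' region whose P-sites fall in the internal-footprint window.
#'
#' @param config a [synthetic_config()].
#' @param seed integer master seed.
#' @return a list of class `recseq_transcriptome`:
#'   `annotation` (data.table: transcript_id, tx_len, utr5_len, cds_start,
#'   cds_end, context_score, n_uaug, n_iaug, is_spikein,
#'   excluded_from_uorf_totals), `sequences` (named character),
#'   `abundance` (named numeric), `pars` (data.table: transcript_id,
#'   position, score), `upstream_aug` and `internal_aug`
#'   (data.tables: transcript_id, pos).
#' @export
generate_transcriptome <- function(config, seed = 1L) {
  validate_config(config)
  n <- config$n_transcripts
  empty <- function() {
    list(annotation = data.table::data.table(
           transcript_id = character(), tx_len = integer(),
           utr5_len = integer(), cds_start = integer(), cds_end = integer(),
           context_score = numeric(), n_uaug = integer(), n_iaug = integer(),
           is_spikein = logical(), excluded_from_uorf_totals = logical()),
         sequences = character(), abundance = numeric(),
         pars = data.table::data.table(transcript_id = character(),
                                       position = integer(), score = numeric()),
         upstream_aug = data.table::data.table(transcript_id = character(), pos = integer()),
         internal_aug = data.table::data.table(transcript_id = character(), pos = integer()))
  }
  if (n == 0L) {
    out <- empty()
    class(out) <- "recseq_transcriptome"
    return(out)
  }

  set.seed(derive_seed(seed, "transcriptome"))
  ids <- sprintf("TX%04d", seq_len(n))

  utr5 <- if (!is.null(config$utr5_len_dist$fixed)) {
    rep(as.integer(config$utr5_len_dist$fixed), n)
  } else {
    pmax(0L, as.integer(round(
      rlnorm(n, config$utr5_len_dist$meanlog, config$utr5_len_dist$sdlog))))
  }
  cds_min <- config$cds_len_dist$min %||% 90L
  cds <- as.integer(round(
    rlnorm(n, config$cds_len_dist$meanlog, config$cds_len_dist$sdlog)))
  cds <- pmax(cds_min, cds - cds %% 3L)
  utr3 <- 30L  # short fixed trailer; downstream analyses never touch it
  tx_len <- utr5 + cds + utr3

  abundance <- rlnorm(n, config$abundance_dist$meanlog, config$abundance_dist$sdlog)
  names(abundance) <- ids

  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- sample(bases, tx_len[i], replace = TRUE)
    cs <- utr5[i] + 1L
    s[cs:(cs + 2L)] <- c("A", "T", "G")
    stop_codon <- sample(stops, 1L)
    ce <- utr5[i] + cds[i]
    s[(ce - 2L):ce] <- strsplit(stop_codon, "")[[1]]
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- ids

  cds_start <- utr5 + 1L
  cds_end <- utr5 + cds

  # AUG enumeration straight from the sequence
  find_aug <- function(seq, from, to) {
    if (to - from < 2L) return(integer())
    hits <- gregexpr("ATG", substring(seq, from, to), fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(integer())
    as.integer(hits) + from - 1L
  }
  up_list <- vector("list", n)
  in_list <- vector("list", n)
  for (i in seq_len(n)) {
    up_list[[i]] <- find_aug(seqs[i], 1L, utr5[i])  # fully inside the 5'UTR
    ia <- find_aug(seqs[i], cds_start[i] + 9L, cds_end[i] - 2L)
    in_list[[i]] <- ia
  }

  # one GCN4-like outlier: an unusually uORF-active 5'UTR, excluded from
  # translatome-wide upstream-footprint totals
  excl <- rep(FALSE, n)
  if (config$gcn4_like && n >= 5L) {
    cand <- which(lengths(up_list) > 0)
    if (length(cand)) excl[cand[which.max(lengths(up_list)[cand])]] <- TRUE
  }

  ctx <- compute_context_score(seqs, cds_start, config$context_model)

  # PARS-like profile: transcript-level structure propensity + nt noise
  set.seed(derive_seed(seed, "pars"))
  s_level <- stats::rexp(n, rate = config$structure_score_model$rate)
  pars <- data.table::data.table(
    transcript_id = rep(ids, tx_len),
    position = unlist(lapply(tx_len, seq_len)),
    score = rnorm(sum(tx_len),
                  mean = rep(s_level, tx_len),
                  sd = config$structure_score_model$sd))

  annotation <- data.table::data.table(
    transcript_id = ids, tx_len = tx_len, utr5_len = utr5,
    cds_start = cds_start, cds_end = cds_end, context_score = ctx,
    n_uaug = lengths(up_list), n_iaug = lengths(in_list),
    is_spikein = FALSE, excluded_from_uorf_totals = excl)

  out <- list(
    annotation = annotation, sequences = seqs, abundance = abundance,
    pars = pars,
    upstream_aug = data.table::data.table(
      transcript_id = rep(ids, lengths(up_list)), pos = unlist(up_list)),
    internal_aug = data.table::data.table(
      transcript_id = rep(ids, lengths(in_list)), pos = unlist(in_list)))
  class(out) <- "recseq_transcriptome"
  out
}
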