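# Shared fixture builders: everything is generated in code, no data files.

# small default world for fast tests
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_transcripts = 40L, pic_pool = 2e4),
                            list(...))
  do.call(synthetic_config, args)
}

# hand-built annotation row(s) for counting tests
mk_ann <- function(id, utr5, cds_len, utr3 = 30L) {
  data.table::data.table(
    transcript_id = id, tx_len = utr5 + cds_len + utr3,
    utr5_len = as.integer(utr5), cds_start = as.integer(utr5 + 1L),
    cds_end = as.integer(utr5 + cds_len), context_score = 0.5,
    is_spikein = FALSE, excluded_from_uorf_totals = FALSE)
}

mk_fp <- function(sample, tx, pos, len = 28L, count = 1) {
  data.table::data.table(sample_id = sample, transcript_id = tx,
                         five_prime_pos = as.integer(pos),
                         length = as.integer(len), count = count)
}

# independent per-read interval-membership oracle for region counting:
# a plain double loop, no shared code with count_regions()
oracle_count_regions <- function(fp, ann, offset = 12L) {
  res <- list()
  for (s in unique(fp$sample_id)) for (t in ann$transcript_id) {
    a <- ann[ann$transcript_id == t, ]
    rows <- fp[fp$sample_id == s & fp$transcript_id == t, ]
    m <- u <- i <- cds <- 0
    if (nrow(rows)) for (r in seq_len(nrow(rows))) {
      if (rows$length[r] < 25 || rows$length[r] > 34) next
      abs_p <- rows$five_prime_pos[r] + offset
      rel <- if (abs_p >= a$cds_start) abs_p - a$cds_start + 1 else abs_p - a$cds_start
      stop_end <- a$cds_end - a$cds_start + 1
      cnt <- rows$count[r]
      if (rel >= -3 && rel <= 6) m <- m + cnt
      if (rel <= -5 && rel >= -a$utr5_len) u <- u + cnt
      if (rel >= 9 && rel <= stop_end) i <- i + cnt
      if (rel >= -3 && rel <= stop_end) cds <- cds + cnt
    }
    res[[length(res) + 1L]] <- data.table::data.table(
      sample_id = s, transcript_id = t, mRPF = m, uRPF = u, iRPF = i,
      cdsRPF = cds)
  }
  data.table::rbindlist(res)
}

# exact upper-tail hypergeometric by direct summation of the pmf
oracle_hyper_p <- function(k, nA, nB, N) {
  j <- max(k, max(0, nA + nB - N)):min(nA, nB)
  sum(choose(nA, j) * choose(N - nA, nB - j)) / choose(N, nB)
}

# random footprint instance on a small annotation set
random_instance <- function(seed, n_tx = 5L, n_reads = 50L) {
  set.seed(seed)
  ann <- data.table::rbindlist(lapply(seq_len(n_tx), function(i)
    mk_ann(sprintf("T%02d", i), sample(0:60, 1), 3L * sample(20:80, 1))))
  idx <- sample(n_tx, n_reads, replace = TRUE)
  pos <- pmax(1L, as.integer(round(runif(n_reads, 1, ann$tx_len[idx] - 34))))
  fp <- mk_fp(sample(c("s1", "s2"), n_reads, replace = TRUE),
              ann$transcript_id[idx], pos,
              len = sample(23:36, n_reads, replace = TRUE),
              count = sample(1:3, n_reads, replace = TRUE))[
                , .(count = sum(count)),
                by = c("sample_id", "transcript_id", "five_prime_pos", "length")]
  list(ann = ann, fp = fp)
}

# NB count matrix generator for differential tests
sim_nb_counts <- function(n_genes, n_per_group, mu, disp, fc = 1,
                          sf = NULL, seed = 1) {
  set.seed(seed)
  n <- 2L * n_per_group
  if (is.null(sf)) sf <- rep(1, n)
  muA <- if (length(mu) == 1) rep(mu, n_genes) else mu
  muB <- muA * fc
  m <- matrix(0L, n_genes, n)
  for (j in seq_len(n_per_group))
    m[, j] <- rnbinom(n_genes, mu = muA * sf[j], size = 1 / disp)
  for (j in seq_len(n_per_group))
    m[, n_per_group + j] <- rnbinom(n_genes, mu = muB * sf[n_per_group + j],
                                    size = 1 / disp)
  rownames(m) <- sprintf("G%05d", seq_len(n_genes))
  m
}
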