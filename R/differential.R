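#' Filter transcripts by total raw reads
#'
#' @param counts matrix (transcripts x samples) of raw counts, or a
#'   region count table plus `region`.
#' @param threshold total-read threshold across all samples.
#' @param strict TRUE keeps totals strictly greater than the threshold
#'   (the "> 90 in 9 samples" design); FALSE keeps totals >= threshold
#'   (the ">= 8 in 4 samples" design).
#' @param region when `counts` is a region table, which raw column to
#'   total.
#' @return character vector of retained transcript ids.
#' @export
filter_min_counts <- function(counts, threshold, strict = TRUE, region = "mRPF") {
  if (is.data.frame(counts)) {
    dt <- data.table::as.data.table(counts)
    totals <- dt[, .(total = sum(get(region))), by = "transcript_id"]
    tot <- setNames(totals$total, totals$transcript_id)
  } else {
    tot <- rowSums(counts)
  }
  names(tot)[if (strict) tot > threshold else tot >= threshold]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' NA p-values are propagated as NA and excluded from the ranking and
#' from m.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values (FDR), clipped to 1.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, base::length(p))
  ok <- which(!is.na(p))
  if (!base::length(ok)) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop_recseq("bh", "p-values must lie in [0, 1]")
  m <- base::length(pv)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  out[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out
}

#' Estimate negative-binomial dispersions
#'
#' Simplified DESeq2-style estimator with fixed (spike-derived) size
#' factors: per-gene method-of-moments dispersion from pooled
#' within-condition variances of normalized counts, an `a0 + a1/mean`
#' trend fitted by least squares on equal-size bin means of the
#' unclipped moment estimates (keeping negative estimates in the bin
#' averages keeps the trend unbiased; clipping first would inflate it,
#' log-averaging would deflate it), and arithmetic shrinkage of the
#' per-gene values toward the trend.  The strong default shrinkage
#' (0.7) reflects how little per-gene information 2-3 replicates carry
#' and is what calibrates the downstream Wald test at small n.
#' All-zero genes are assigned the trend dispersion.  Deterministic.
#'
#' @param counts matrix transcripts x samples of raw counts.
#' @param size_factors per-sample factors (same order as columns).
#' @param condition factor/character of length ncol(counts).
#' @param shrink_weight weight on the trend, in [0, 1].
#' @param floor dispersion floor.
#' @return list of class `recseq_dispersions`: `raw` (floored per-gene
#'   moment estimates), `trend` (function of mean), `trend_coef`
#'   (a0, a1), `shrunken`, `shrink_weight`.
#' @export
estimate_dispersions <- function(counts, size_factors, condition,
                                 shrink_weight = 0.7, floor = 1e-8) {
  condition <- as.character(condition)
  if (max(table(condition)) < 2)
    stop_recseq("dispersion", "need >= 2 replicates in at least one condition")
  norm <- sweep(counts, 2, size_factors, "/")
  mu <- rowMeans(norm)
  xi <- mean(1 / size_factors)
  groups <- unique(condition)
  ss <- 0; df <- 0
  for (g in groups) {
    idx <- which(condition == g)
    if (base::length(idx) < 2) next
    sub <- norm[, idx, drop = FALSE]
    gm <- rowMeans(sub)
    ss <- ss + rowSums((sub - gm)^2)
    df <- df + base::length(idx) - 1
  }
  v <- ss / df
  a_mom <- (v - xi * mu) / mu^2   # unclipped; negative values are kept
  a_mom[!is.finite(a_mom)] <- 0
  raw <- pmax(floor, a_mom)

  use <- which(mu > 0)
  if (base::length(use) >= 40) {
    nb <- min(20L, base::length(use) %/% 10L)
    bins <- cut(rank(mu[use], ties.method = "first"), nb)
    bm <- tapply(a_mom[use], bins, mean)
    bi <- tapply(1 / mu[use], bins, mean)
    a <- pmax(coef(lm(bm ~ bi)), 0)
  } else {
    a <- c(max(floor, median(raw[use])), 0)
  }
  trend_fun <- function(m) pmax(floor, a[1] + a[2] / pmax(m, 1e-8))
  tr <- trend_fun(mu)
  tr[mu == 0] <- trend_fun(1)  # all-zero genes: trend at a nominal mean of 1

  shr <- pmax(floor, (1 - shrink_weight) * pmax(a_mom, 0) + shrink_weight * tr)
  shr[mu == 0] <- tr[mu == 0]
  structure(list(raw = raw, trend = trend_fun,
                 trend_coef = setNames(as.numeric(a), c("a0", "a1")),
                 shrunken = shr, shrink_weight = shrink_weight, floor = floor),
            class = "recseq_dispersions")
}

# Newton solve of the per-group NB mean parameter q (mu_i = s_i * q),
# vectorized across genes; returns list(q, info) with the expected
# Fisher information for log q.
nb_group_fit <- function(y, s, alpha, iters = 30L) {
  # y: genes x samples (one group), s: size factors, alpha: per-gene
  tot_y <- rowSums(y); tot_s <- sum(s)
  q <- pmax(tot_y / tot_s, 1e-12)
  for (it in seq_len(iters)) {
    mu <- outer(q, s)
    denom <- 1 + alpha * mu
    f <- rowSums((y - mu) / denom)
    fp <- -rowSums(sweep(1 + alpha * y, 2, s, "*") / denom^2)
    step <- f / fp
    q_new <- q - step
    q_new[!is.finite(q_new) | q_new <= 0] <- q[!is.finite(q_new) | q_new <= 0] / 2
    if (max(abs(q_new - q) / pmax(q, 1e-12)) < 1e-10) { q <- q_new; break }
    q <- q_new
  }
  mu <- outer(q, s)
  info <- rowSums(mu / (1 + alpha * mu))
  list(q = q, info = info, zero = tot_y == 0)
}

#' Two-group negative-binomial Wald test
#'
#' For each transcript, fits the NB mean per group with fixed size
#' factors and known (shrunken) dispersion, and tests H0: equal group
#' means by a Wald test on the log fold change with standard error from
#' the expected information.  Genes where one group is all zero fall
#' back to a score test at the null fit; genes zero in both groups get
#' p = 1, log2FC = 0 and a flag.  The 0.5 pseudocount on normalized
#' counts enters the reported log2FC of zero-group genes only, never any
#' test statistic.
#'
#' @param counts matrix transcripts x samples of raw counts (rownames =
#'   transcript ids).
#' @param size_factors per-sample factors (column order).
#' @param condition two-level factor/character; the fold change is
#'   level 2 over level 1 (B over A, with levels in order of first
#'   appearance unless a factor is given).
#' @param dispersions a `recseq_dispersions` or numeric vector.
#' @param pseudocount reporting pseudocount for zero groups.
#' @return data.table (transcript_id, baseMean, log2FC, lfcSE, stat,
#'   pvalue, padj, class, zero_flag).  `class` is filled by
#'   [classify_significant()] defaults (fdr 0.05, fc 2).
#' @export
nb_wald_test <- function(counts, size_factors, condition, dispersions,
                         pseudocount = 0.5) {
  condition <- if (is.factor(condition)) condition else
    factor(condition, levels = unique(condition))
  lev <- levels(condition)
  if (base::length(lev) != 2) stop_recseq("wald", "exactly two conditions required")
  alpha <- if (inherits(dispersions, "recseq_dispersions"))
    dispersions$shrunken else dispersions
  alpha <- pmax(alpha, 1e-8)
  iA <- which(condition == lev[1]); iB <- which(condition == lev[2])
  yA <- counts[, iA, drop = FALSE]; yB <- counts[, iB, drop = FALSE]
  sA <- size_factors[iA]; sB <- size_factors[iB]

  fA <- nb_group_fit(yA, sA, alpha)
  fB <- nb_group_fit(yB, sB, alpha)

  beta <- log(fB$q) - log(fA$q)
  se <- sqrt(1 / fA$info + 1 / fB$info)
  stat <- beta / se
  pval <- 2 * pnorm(-abs(stat))
  log2fc <- beta / log(2)
  lfc_se <- se / log(2)

  norm <- sweep(counts, 2, size_factors, "/")
  base_mean <- rowMeans(norm)
  mA <- rowMeans(norm[, iA, drop = FALSE]); mB <- rowMeans(norm[, iB, drop = FALSE])

  one_zero <- xor(fA$zero, fB$zero)
  both_zero <- fA$zero & fB$zero
  if (any(one_zero)) {
    for (g in which(one_zero)) {
      y <- counts[g, ]; s <- size_factors
      q0 <- sum(y) / sum(s)
      mu0 <- s * q0
      d <- 1 + alpha[g] * mu0
      U <- sum((y[iB] - mu0[iB]) / d[iB])
      V <- sum(mu0[iB] / d[iB])
      stat[g] <- U / sqrt(V)
      pval[g] <- 2 * pnorm(-abs(stat[g]))
      log2fc[g] <- log2((mB[g] + pseudocount) / (mA[g] + pseudocount))
      lfc_se[g] <- NA_real_
    }
  }
  if (any(both_zero)) {
    stat[both_zero] <- 0; pval[both_zero] <- 1
    log2fc[both_zero] <- 0; lfc_se[both_zero] <- NA_real_
  }

  res <- data.table::data.table(
    transcript_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    baseMean = base_mean, log2FC = log2fc, lfcSE = lfc_se, stat = stat,
    pvalue = pval, padj = bh_adjust(pval),
    zero_flag = one_zero | both_zero)
  res[, class := classify_class(padj, log2fc)]
  res[]
}

classify_class <- function(padj, log2fc, fdr_cut = 0.05, fc_cut = 2) {
  fc <- 2^log2fc
  cls <- rep("ns", base::length(padj))
  cls[!is.na(padj) & padj < fdr_cut & fc > fc_cut] <- "up"
  cls[!is.na(padj) & padj < fdr_cut & fc < 1 / fc_cut] <- "down"
  cls
}

#' Classify significant transcripts
#'
#' up: FDR < `fdr_cut` and fold change > `fc_cut`; down: FDR < `fdr_cut`
#' and fold change < 1/`fc_cut`; everything else ns.
#'
#' @param results a [nb_wald_test()] table.
#' @param fdr_cut FDR threshold.
#' @param fc_cut fold-change threshold (> 1).
#' @return list(up = ids, down = ids, n_up, n_down).
#' @export
classify_significant <- function(results, fdr_cut = 0.05, fc_cut = 2) {
  cls <- classify_class(results$padj, results$log2FC, fdr_cut, fc_cut)
  list(up = results$transcript_id[cls == "up"],
       down = results$transcript_id[cls == "down"],
       n_up = sum(cls == "up"), n_down = sum(cls == "down"))
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability of observing at least the given overlap
#' between two subsets of a common universe.
#'
#' @param setA,setB character vectors of ids.
#' @param universe_size size of the common universe.
#' @return list(overlap, p).
#' @export
overlap_test <- function(setA, setB, universe_size) {
  setA <- unique(setA); setB <- unique(setB)
  if (base::length(setA) > universe_size || base::length(setB) > universe_size)
    stop_recseq("overlap", "set larger than the universe")
  k <- base::length(intersect(setA, setB))
  p <- phyper(k - 1, base::length(setA), universe_size - base::length(setA),
              base::length(setB), lower.tail = FALSE)
  list(overlap = k, p = p)
}

#' Spearman rank correlation
#'
#' Average ranks for ties; returns NaN (with a warning) for constant
#' input.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return rank correlation coefficient.
#' @export
spearman_corr <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (base::length(x) < 3) stop_recseq("spearman", "need >= 3 complete pairs")
  if (base::length(unique(x)) == 1 || base::length(unique(y)) == 1) {
    warning("spearman_corr: constant input, correlation undefined")
    return(NaN)
  }
  cor(rank(x), rank(y))
}
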