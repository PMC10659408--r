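#' Synthetic start-codon context model
#'
#' Position-specific relative-adaptiveness weights for the -6..-1 and
#' +4..+6 positions around a main AUG, in the style of codon-adaptation
#' indices for start contexts (AUG_CAI).  The consensus base of each
#' column has weight 1; a sequence matching the consensus at every scored
#' position therefore scores 1.  This matrix is synthetic (built for
#' testing, loosely imitating the A-rich preference of highly translated
#' yeast mRNAs); real-data use should supply a matrix derived from a
#' reference set of efficiently translated transcripts.
#'
#' @return a 4 x 9 numeric matrix, rows A/C/G/T, columns named
#'   -6..-1, +4..+6 (signed, no zero).
#' @export
default_context_model <- function() {
  pos <- c(-6:-1, 4:6)
  m <- matrix(0, nrow = 4, ncol = length(pos),
              dimnames = list(c("A", "C", "G", "T"), as.character(pos)))
  # consensus aAaAaA AUG UCu: A-rich upstream, U/C just downstream
  consensus <- c("A", "A", "A", "A", "A", "A", "T", "C", "T")
  others <- list(
    c(C = 0.45, G = 0.30, T = 0.55), c(C = 0.40, G = 0.25, T = 0.50),
    c(C = 0.35, G = 0.20, T = 0.45), c(C = 0.40, G = 0.25, T = 0.50),
    c(C = 0.45, G = 0.30, T = 0.55), c(C = 0.30, G = 0.16, T = 0.40),
    c(A = 0.60, C = 0.50, G = 0.35), c(A = 0.55, G = 0.30, T = 0.70),
    c(A = 0.65, C = 0.55, G = 0.45))
  for (j in seq_along(pos)) {
    m[consensus[j], j] <- 1
    m[names(others[[j]]), j] <- others[[j]]
  }
  m
}

#' Score a start-codon context
#'
#' Geometric mean of the position weights at -6..-1 and +4..+6 around the
#' main AUG (the AUG itself, +1..+3, is excluded).  Transcripts with a
#' 5'UTR shorter than 6 nt cannot provide the full upstream window and
#' are returned as NA (flagged), matching the usual ">5 nt 5'UTR"
#' restriction for context-score analyses.
#'
#' @param sequence transcript sequence(s), character vector.
#' @param cds_start 1-based position of the A of the main AUG, recycled.
#' @param model weight matrix from [default_context_model()] or
#'   user-supplied with identical layout.
#' @return numeric vector of scores in (0, 1], NA where undefined.
#' @export
compute_context_score <- function(sequence, cds_start, model = default_context_model()) {
  pos <- as.integer(colnames(model))
  n <- max(length(sequence), length(cds_start))
  sequence <- rep_len(sequence, n)
  cds_start <- rep_len(cds_start, n)
  vapply(seq_len(n), function(i) {
    cs <- cds_start[i]
    if (cs - 1 < 6) return(NA_real_)  # 5'UTR < 6 nt: upstream window missing
    abs_pos <- ifelse(pos < 0, cs + pos, cs + pos - 1)  # signed skip-zero
    if (max(abs_pos) > nchar(sequence[i])) return(NA_real_)
    bases <- strsplit(substring(sequence[i], abs_pos, abs_pos), "")
    w <- vapply(seq_along(pos), function(j) {
      b <- substring(sequence[i], abs_pos[j], abs_pos[j])
      if (!b %in% rownames(model)) return(NA_real_)
      model[b, j]
    }, numeric(1))
    if (anyNA(w)) return(NA_real_)
    exp(mean(log(w)))
  }, numeric(1))
}
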