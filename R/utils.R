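#' @import data.table
#' @importFrom stats rnorm rpois rbinom rmultinom runif rlnorm rgamma rexp
#'   pnorm phyper cor complete.cases lm coef mad median quantile setNames
#' @importFrom utils head tail packageVersion
NULL

# Deterministic 31-bit sub-seed derived from a master seed and a string tag.
# Keeps every (sample, stage) stream independently reproducible.
derive_seed <- function(master, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(tag)) h <- (h * 131 + cp) %% 2147483647
  as.integer((as.numeric(master) * 2654435761 + h) %% 2147483647)
}

#' Geometric mean of strictly positive values
#'
#' @param x numeric vector, all elements > 0.
#' @return exp(mean(log(x))).
#' @export
geometric_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_recseq <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

assert_prob_vector <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop_recseq("config", what, " must be non-negative and sum to 1")
  invisible(p)
}
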