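#' Two-sided Fisher exact test for 2x2 count tables
#'
#' Exact two-sided P computed by the standard point-probability rule: with
#' row margins fixed, the P value is the sum of hypergeometric
#' probabilities of every table sharing the observed margins whose
#' probability does not exceed that of the observed table. Because the
#' comparison of floating-point probabilities is delicate, "does not
#' exceed" is evaluated with a small relative tolerance
#' (`p_table <= p_observed * (1 + rel_tol)`), matching common practice.
#'
#' The table layout is rows = groups, columns = (methylated, unmethylated)
#' pooled read counts:
#' \preformatted{   a  b     group 1: methylated, unmethylated
#'    c  d     group 2: methylated, unmethylated}
#'
#' @param a,b,c,d Non-negative integer vectors (recycled to a common
#'   length) of cell counts.
#' @param rel_tol Relative tolerance for the probability comparison
#'   (default 1e-7).
#' @return Numeric vector of two-sided P values in \[0, 1\]. A table with
#'   an all-zero margin has P = 1.
#' @examples
#' fisher_exact_two_sided(2, 2, 2, 2) # 1
#' @export
fisher_exact_two_sided <- function(a, b, c, d, rel_tol = 1e-7) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0)) {
    abort("all counts must be non-negative and non-missing")
  }
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]          # row 1 margin
    nn <- c[i] + d[i]         # row 2 margin
    k <- a[i] + c[i]          # column 1 margin
    lo <- max(0, k - nn)
    hi <- min(k, m)
    if (hi < lo) return(1)
    probs <- dhyper(lo:hi, m, nn, k)
    p_obs <- probs[a[i] - lo + 1]
    min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
  }, numeric(1))
}
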