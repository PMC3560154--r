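# Between-lane normalisation factors. Simulated lanes are depth-matched by
# construction, so "unit" is the default; median-of-ratios and a simplified
# trimmed-mean-of-M-values (TMM) scheme are offered for real data.

#' Per-lane size factors
#'
#' Computes normalisation factors for a count matrix. `"unit"` returns 1 for
#' every lane. `"median-of-ratios"` takes, per lane, the median ratio of its
#' counts to the per-transcript geometric mean over lanes (computed on
#' transcripts with no zero count). `"tmm"` is a trimmed mean of per-transcript
#' log2 count ratios against a reference lane (the lane whose upper-quartile
#' expression is closest to the average), trimming the 30% most extreme
#' log-ratios on each side and 5% by average abundance, multiplied by the lane
#' total; no precision weighting is applied. All factors are normalised to
#' geometric mean 1.
#'
#' @param counts A [count_matrix()] or numeric matrix.
#' @param method One of `"unit"`, `"median-of-ratios"`, `"tmm"`.
#' @return Named numeric vector of positive per-lane factors.
#' @export
#' @examples
#' cm <- count_matrix(matrix(c(1:4, 2L * (1:4)), 4, 2))
#' compute_size_factors(cm, "median-of-ratios")
compute_size_factors <- function(counts,
                                 method = c("unit", "median-of-ratios", "tmm")) {
  x <- as_count_matrix(counts)
  method <- match.arg(method)
  k <- x$counts
  totals <- colSums(k)
  if (any(totals == 0)) stop_input("size factors undefined for an all-zero lane")
  sf <- switch(method,
    "unit" = rep(1, ncol(k)),
    "median-of-ratios" = {
      pos <- rowSums(k > 0) == ncol(k)
      if (!any(pos)) {
        stop_input("median-of-ratios needs transcripts observed in every lane")
      }
      loggeo <- rowMeans(log(k[pos, , drop = FALSE]))
      apply(log(k[pos, , drop = FALSE]), 2L,
            function(col) exp(median(col - loggeo)))
    },
    "tmm" = {
      cpm_uq <- vapply(seq_len(ncol(k)), function(j) {
        v <- k[, j] / totals[j]
        quantile(v[v > 0], 0.75, names = FALSE)
      }, numeric(1))
      ref <- which.min(abs(cpm_uq - mean(cpm_uq)))
      f <- vapply(seq_len(ncol(k)), function(j) {
        if (j == ref) return(1)
        use <- k[, j] > 0 & k[, ref] > 0
        pj <- k[use, j] / totals[j]
        pr <- k[use, ref] / totals[ref]
        m <- log2(pj / pr)
        a <- 0.5 * log2(pj * pr)
        keep <- m >= quantile(m, 0.30) & m <= quantile(m, 0.70) &
          a >= quantile(a, 0.05) & a <= quantile(a, 0.95)
        if (!any(keep)) keep <- rep(TRUE, length(m))
        2^mean(m[keep])
      }, numeric(1))
      f * totals
    }
  )
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(k)
  sf
}
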