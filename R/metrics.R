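# Evaluation statistics: false/true positive rates against the
# effectively-DE ground truth, call rates, abundance strata, p-value
# histograms and cross-strategy call overlap. All rates are quoted in
# percent; the decision rule at significance level alpha (percent) is
# 100 * p < alpha.

as_is_de <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  if (!all(labels %in% c("effectively-DE", "effectively-non-DE"))) {
    stop_input(paste0("labels must be logical or ",
                      "'effectively-DE' / 'effectively-non-DE'"))
  }
  labels == "effectively-DE"
}

check_pvalues <- function(p, name = "p") {
  if (length(p) == 0L) stop_input(sprintf("`%s` must be non-empty", name))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_input(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(p)
}

#' False positive rate under the null (raw p-values)
#'
#' With no DE simulated, every significant transcript is a false positive:
#' `100 * #\{100 * p < alpha\} / total`. For a correctly calibrated test this
#' should match the significance level.
#'
#' @param p_values Raw (unadjusted) p-values from null data.
#' @param alpha_percent Significance level in percent (default 1).
#' @return FPR in percent.
#' @export
fpr_null <- function(p_values, alpha_percent = 1) {
  check_pvalues(p_values, "p_values")
  check_scalar_number(alpha_percent, "alpha_percent", lower = 0, upper = 100)
  100 * mean(100 * p_values < alpha_percent)
}

#' False / true positive rates against effectively-DE labels
#'
#' `fpr()` is the percentage of effectively-non-DE transcripts with
#' `100 * p_adj < alpha`; `tpr()` the analogous percentage of effectively-DE
#' transcripts (sensitivity; `100 - fpr` is the specificity). When the
#' denominator class is empty the rate is undefined and `NA` is returned
#' with a warning.
#'
#' @param p_adj BH-adjusted p-values.
#' @param labels Effective-DE ground truth: logical, or the labels produced
#'   by [label_effective_de()].
#' @param alpha_percent Significance level in percent.
#' @return Rate in percent (possibly `NA`).
#' @export
fpr <- function(p_adj, labels, alpha_percent = 1) {
  check_pvalues(p_adj, "p_adj")
  is_de <- as_is_de(labels)
  stopifnot(length(is_de) == length(p_adj))
  check_scalar_number(alpha_percent, "alpha_percent", lower = 0, upper = 100)
  denom <- sum(!is_de)
  if (denom == 0L) {
    warning("no effectively-non-DE transcripts; FPR undefined")
    return(NA_real_)
  }
  100 * sum(!is_de & 100 * p_adj < alpha_percent) / denom
}

#' @rdname fpr
#' @export
tpr <- function(p_adj, labels, alpha_percent = 1) {
  check_pvalues(p_adj, "p_adj")
  is_de <- as_is_de(labels)
  stopifnot(length(is_de) == length(p_adj))
  check_scalar_number(alpha_percent, "alpha_percent", lower = 0, upper = 100)
  denom <- sum(is_de)
  if (denom == 0L) {
    warning("no effectively-DE transcripts; TPR undefined")
    return(NA_real_)
  }
  100 * sum(is_de & 100 * p_adj < alpha_percent) / denom
}

#' Overall DE call rate
#'
#' Percentage of all transcripts called DE at the adjusted-p criterion.
#'
#' @inheritParams fpr
#' @return Call rate in percent.
#' @export
call_rate <- function(p_adj, alpha_percent = 1) {
  check_pvalues(p_adj, "p_adj")
  check_scalar_number(alpha_percent, "alpha_percent", lower = 0, upper = 100)
  100 * mean(100 * p_adj < alpha_percent)
}

#' Split transcripts into high- and low-count strata
#'
#' A transcript is high-count when its mean count, averaged across the
#' biological replicates of the control condition (all lanes when no
#' condition is assigned), exceeds `threshold`; the boundary itself is
#' low-count. The two masks partition the transcript set.
#'
#' @param counts A [count_matrix()] or matrix.
#' @param condition Optional labels when `counts` is a bare matrix.
#' @param threshold Count threshold (default 100).
#' @return List with logical masks `high` and `low`.
#' @export
stratify_by_count <- function(counts, condition = NULL, threshold = 100) {
  x <- as_count_matrix(counts, condition = condition)
  check_scalar_number(threshold, "threshold", lower = 0)
  k <- x$counts
  if (!is.null(x$condition)) {
    k <- k[, x$condition == "control", drop = FALSE]
  }
  m <- rowMeans(k)
  list(high = m > threshold, low = m <= threshold)
}

#' Histogram of p-values as per-bin percentages
#'
#' Bins `[0, 1]` into `bins` right-closed intervals and reports the
#' percentage of p-values in each; the percentages sum to 100. Under a
#' well-calibrated continuous test the histogram is flat at `100 / bins`;
#' the discrete exact test additionally piles balanced low-count transcripts
#' into the right-most bin (p exactly 1).
#'
#' @param p_values P-values in `[0, 1]`.
#' @param bins Number of bins (default 100).
#' @return Data frame with `bin_lower`, `bin_upper`, `percent`.
#' @export
pvalue_histogram <- function(p_values, bins = 100) {
  check_pvalues(p_values, "p_values")
  check_scalar_number(bins, "bins", lower = 1)
  breaks <- seq(0, 1, length.out = bins + 1)
  counts <- graphics::hist(p_values, breaks = breaks, right = TRUE,
                           include.lowest = TRUE, plot = FALSE)$counts
  data.frame(bin_lower = breaks[-length(breaks)], bin_upper = breaks[-1],
             percent = 100 * counts / length(p_values))
}

#' Overlap of DE calls between two result tables
#'
#' Compares the adjusted-p calls of two strategies on the same transcripts
#' and counts transcripts called by only the first, only the second, or
#' both, split by the effective-DE ground truth. The three counts are
#' disjoint and sum to the union of the call sets.
#'
#' @param results_a,results_b `"de_result"` tables over the same transcripts
#'   (matching `transcript_id`).
#' @param labels Effective-DE ground truth (logical or labels).
#' @param alpha_percent Significance level in percent.
#' @return Data frame with one row per label class: `label`, `a_only`,
#'   `b_only`, `both`.
#' @export
call_overlap <- function(results_a, results_b, labels, alpha_percent = 1) {
  stopifnot(is.data.frame(results_a), is.data.frame(results_b))
  if (!identical(results_a$transcript_id, results_b$transcript_id)) {
    stop_input("result tables must cover the same transcripts in the same order")
  }
  is_de <- as_is_de(labels)
  stopifnot(length(is_de) == nrow(results_a))
  a <- 100 * results_a$p_adj < alpha_percent
  b <- 100 * results_b$p_adj < alpha_percent
  summarise <- function(mask) {
    c(a_only = sum(a & !b & mask), b_only = sum(!a & b & mask),
      both = sum(a & b & mask))
  }
  rbind(
    data.frame(label = "effectively-DE", t(summarise(is_de))),
    data.frame(label = "effectively-non-DE", t(summarise(!is_de)))
  )
}

# One tidy block of metrics for a DE result at a given stratum mask.
metrics_row <- function(result, is_de, mask, stratum, alpha_percent) {
  idx <- which(mask)
  n <- length(idx)
  n_de <- sum(is_de[idx])
  data.frame(
    stratum = stratum,
    call_rate_percent = if (n) call_rate(result$p_adj[idx], alpha_percent)
                        else NA_real_,
    fpr_percent = if (n && n_de < n) {
      fpr(result$p_adj[idx], is_de[idx], alpha_percent)
    } else NA_real_,
    tpr_percent = if (n_de) tpr(result$p_adj[idx], is_de[idx], alpha_percent)
                  else NA_real_,
    n_transcripts = n, n_effective_de = n_de, n_effective_nonde = n - n_de,
    stringsAsFactors = FALSE
  )
}

#' Summarise DE metrics overall and per count stratum
#'
#' Computes call rate, FPR and TPR (adjusted-p criterion) for a DE result
#' against the effective-DE ground truth, for all transcripts and for the
#' high- / low-count strata of [stratify_by_count()].
#'
#' @param result A `"de_result"` from [run_de_test()].
#' @param labels Effective-DE ground truth.
#' @param counts The [count_matrix()] the result was computed on (used for
#'   stratification).
#' @param alpha_percent Significance level in percent.
#' @param count_threshold Stratum boundary (default 100).
#' @return Data frame with one row per stratum (`all`, `high-count`,
#'   `low-count`).
#' @export
de_metrics <- function(result, labels, counts, alpha_percent = 1,
                       count_threshold = 100) {
  stopifnot(inherits(result, "de_result"))
  is_de <- as_is_de(labels)
  strata <- stratify_by_count(counts, threshold = count_threshold)
  out <- rbind(
    metrics_row(result, is_de, rep(TRUE, nrow(result)), "all", alpha_percent),
    metrics_row(result, is_de, strata$high, "high-count", alpha_percent),
    metrics_row(result, is_de, strata$low, "low-count", alpha_percent)
  )
  rownames(out) <- NULL
  out
}
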