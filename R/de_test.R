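# Composition of the DE pipeline: normalisation -> dispersion estimation ->
# exact test -> multiple-testing adjustment -> fold-change calling.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at 1),
#' applied over all tested transcripts.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues_bh <- function(p) {
  if (length(p) == 0L) stop_input("`p` must be non-empty")
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Fold-change DE calls
#'
#' Calls a transcript DE when its (pseudocount-damped) fold change between
#' condition means reaches `threshold` in either direction:
#' `max(fc, 1/fc) >= threshold` with
#' `fc = (pseudocount + mean_treatment) / (pseudocount + mean_control)`.
#' With `pseudocount = 0` a transcript observed in exactly one condition has
#' an infinite ratio and is called (the "spurious doubling or halving" that a
#' pseudocount of 1 suppresses); a transcript with zero counts in both
#' conditions has an undefined fold change and is not called.
#'
#' @param counts A [count_matrix()] with control/treatment lanes.
#' @param condition Optional labels when `counts` is a bare matrix.
#' @param threshold Fold-change call threshold (> 0), default 2.
#' @param pseudocount Non-negative count added to both means (default 0).
#' @param size_factors Optional per-lane normalisation factors.
#' @return Data frame with `transcript_id`, `fold_change` (treatment over
#'   control), and logical `call`.
#' @export
fold_change_detector <- function(counts, condition = NULL, threshold = 2,
                                 pseudocount = 0, size_factors = NULL) {
  x <- as_count_matrix(counts, condition = condition)
  require_two_conditions(x)
  check_scalar_number(threshold, "threshold", lower = 0,
                      allow_boundary = FALSE)
  check_scalar_number(pseudocount, "pseudocount", lower = 0)
  k <- x$counts
  if (!is.null(size_factors) && any(size_factors != 1)) {
    k <- sweep(k, 2L, size_factors, `/`)
  }
  mc <- rowMeans(k[, x$condition == "control", drop = FALSE])
  mt <- rowMeans(k[, x$condition == "treatment", drop = FALSE])
  fc <- (pseudocount + mt) / (pseudocount + mc)
  ratio <- pmax(fc, 1 / fc)
  call <- !is.nan(ratio) & ratio >= threshold
  data.frame(transcript_id = rownames(k), fold_change = fc, call = call,
             stringsAsFactors = FALSE)
}

#' Run the full two-group DE test
#'
#' Composes [compute_size_factors()], [estimate_dispersions()],
#' [exact_nb_test()], [adjust_pvalues_bh()] and [fold_change_detector()] into
#' one deterministic pipeline and returns a per-transcript result table.
#'
#' @param counts A [count_matrix()] with control/treatment lanes.
#' @param condition Optional labels when `counts` is a bare matrix.
#' @param strategy Dispersion strategy, see [estimate_dispersions()].
#' @param alpha_percent Significance level in percent for the adjusted-p DE
#'   call (default 1, i.e. `p_adj < 0.01`).
#' @param size_factor_method Normalisation method, see
#'   [compute_size_factors()]; default `"unit"` (simulated lanes are
#'   depth-matched by construction).
#' @param true_dispersions Ground-truth dispersions for the oracle strategy.
#' @param prior_df Squeeze prior for the tagwise strategy.
#' @param fold_threshold,pseudocount Passed to [fold_change_detector()].
#' @param s_max Passed to [exact_nb_test()].
#' @return A data frame of class `"de_result"`: `transcript_id`, `p_value`,
#'   `p_adj`, `fold_change`, `fold_call`, `de_call` (adjusted-p criterion),
#'   `dispersion_used`, `mean_control`, `mean_treatment`.
#' @export
#' @examples
#' pop <- build_parameter_population(generator_config(t = 60), seed = 1)
#' cm <- simulate_counts(pop, n_reps = 3, seed = 2)
#' head(run_de_test(cm, strategy = "oracle",
#'                  true_dispersions = pop$dispersion))
run_de_test <- function(counts, condition = NULL,
                        strategy = c("max-parametric", "tagwise-squeeze",
                                     "powerlaw", "oracle"),
                        alpha_percent = 1,
                        size_factor_method = "unit",
                        true_dispersions = NULL,
                        prior_df = 10,
                        fold_threshold = 2,
                        pseudocount = 0,
                        s_max = 1e5) {
  x <- as_count_matrix(counts, condition = condition)
  require_two_conditions(x)
  strategy <- match.arg(strategy)
  check_scalar_number(alpha_percent, "alpha_percent", lower = 0, upper = 100)
  sf <- compute_size_factors(x, size_factor_method)
  disp <- estimate_dispersions(x, strategy = strategy,
                               true_dispersions = true_dispersions,
                               prior_df = prior_df, size_factors = sf)
  p <- exact_nb_test(x, dispersions = disp, size_factors = sf, s_max = s_max)
  p_adj <- adjust_pvalues_bh(p)
  fc <- fold_change_detector(x, threshold = fold_threshold,
                             pseudocount = pseudocount, size_factors = sf)
  k <- sweep(x$counts, 2L, sf, `/`)
  res <- data.frame(
    transcript_id = rownames(x$counts),
    p_value = unname(p),
    p_adj = unname(p_adj),
    fold_change = fc$fold_change,
    fold_call = fc$call,
    de_call = unname(p_adj) < alpha_percent / 100,
    dispersion_used = as.numeric(disp),
    mean_control = rowMeans(k[, x$condition == "control", drop = FALSE]),
    mean_treatment = rowMeans(k[, x$condition == "treatment", drop = FALSE]),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "strategy") <- strategy
  attr(res, "alpha_percent") <- alpha_percent
  class(res) <- c("de_result", "data.frame")
  res
}

#' Write a DE result table as TSV
#' @param x A `"de_result"` data frame from [run_de_test()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de_result <- function(x, path) {
  stopifnot(inherits(x, "de_result"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
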