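# Experiment orchestration: null calibration runs, replication x depth power
# grids, and multiplex (barcoded lane-sharing) scenarios, each repeated over
# independently generated datasets and summarised by the median and a 90%
# interval (5th-95th percentile) across repetitions.
#
# Seeding: one root seed; every stage draws from a child stream derived via
# child_seed(seed, repetition, stage, ...), so any cell of any grid is
# individually reproducible and cells shared between experiment families
# (e.g. a multiplex scenario and the matching power-grid cell) coincide
# exactly for the same root seed.

rates_from_calls <- function(calls, is_de, strata) {
  one <- function(mask, stratum) {
    n <- sum(mask)
    n_de <- sum(is_de & mask)
    n_non <- n - n_de
    data.frame(
      stratum = stratum,
      call_rate_percent = if (n) 100 * sum(calls & mask) / n else NA_real_,
      fpr_percent = if (n_non) 100 * sum(calls & !is_de & mask) / n_non
                    else NA_real_,
      tpr_percent = if (n_de) 100 * sum(calls & is_de & mask) / n_de
                    else NA_real_,
      n_transcripts = n, n_effective_de = n_de, n_effective_nonde = n_non,
      stringsAsFactors = FALSE
    )
  }
  all_mask <- rep(TRUE, length(calls))
  out <- rbind(one(all_mask, "all"), one(strata$high, "high-count"),
               one(strata$low, "low-count"))
  rownames(out) <- NULL
  out
}

#' Summarise per-repetition metrics by median and 90% interval
#'
#' Aggregates a tidy per-repetition table over repetitions: for every group
#' and metric, the median and the 5th-95th percentile interval of the
#' repetition values.
#'
#' @param per_repetition Tidy data frame with a `repetition` column.
#' @param metric_cols Names of numeric metric columns to summarise.
#' @param group_cols Names of columns identifying a scenario cell.
#' @return Data frame with one row per (group, metric): the group columns
#'   plus `metric`, `median`, `lower90`, `upper90`, `n_repetitions`.
#' @export
summarize_repetitions <- function(per_repetition, metric_cols, group_cols) {
  stopifnot(all(c(metric_cols, group_cols) %in% names(per_repetition)))
  key <- interaction(per_repetition[group_cols], drop = TRUE, sep = "\r")
  out <- list()
  for (lev in levels(key)) {
    block <- per_repetition[key == lev, , drop = FALSE]
    for (m in metric_cols) {
      v <- block[[m]]
      v <- v[!is.na(v)]
      qs <- if (length(v)) {
        quantile(v, c(0.5, 0.05, 0.95), names = FALSE, type = 7)
      } else {
        rep(NA_real_, 3)
      }
      out[[length(out) + 1L]] <- cbind(
        block[1L, group_cols, drop = FALSE],
        data.frame(metric = m, median = qs[1], lower90 = qs[2],
                   upper90 = qs[3], n_repetitions = nrow(block),
                   stringsAsFactors = FALSE)
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Null-hypothesis calibration experiment
#'
#' For each repetition, generates a fresh parameter population with all
#' regulating factors at 1 (no DE), simulates `n` control vs `n` treatment
#' lanes for each requested `n`, applies each dispersion strategy followed by
#' the exact test, and records the raw-p false positive rate ([fpr_null()])
#' at `alpha_percent`, overall and within the high-/low-count strata.
#'
#' @param n_values Replicates per condition to test.
#' @param strategies Dispersion strategies (may include `"oracle"`).
#' @param repetitions Independent datasets per `n` (default 100).
#' @param alpha_percent Significance level in percent.
#' @param config A [generator_config()] describing the population.
#' @param prior_df Tagwise squeeze prior.
#' @param count_threshold High/low stratum boundary.
#' @param seed Root seed.
#' @param verbose Print per-cell progress?
#' @return List with `per_repetition` (tidy rows: repetition, n, strategy,
#'   stratum, fpr_percent, n_transcripts) and `summary`
#'   (via [summarize_repetitions()]).
#' @export
run_null_experiment <- function(n_values = c(2, 3, 4, 6, 8, 12),
                                strategies = c("tagwise-squeeze",
                                               "max-parametric", "powerlaw"),
                                repetitions = 100,
                                alpha_percent = 1,
                                config = generator_config(),
                                prior_df = 10,
                                count_threshold = 100,
                                seed = 1,
                                verbose = FALSE) {
  check_scalar_number(repetitions, "repetitions", lower = 1)
  stopifnot(inherits(config, "generator_config"))
  rows <- list()
  for (r in seq_len(repetitions)) {
    pop <- build_parameter_population(config, seed = child_seed(seed, r, 1))
    for (n in n_values) {
      cm <- simulate_counts(pop, n, seed = child_seed(seed, r, 3, n))
      strata <- stratify_by_count(cm, threshold = count_threshold)
      masks <- list(`all` = rep(TRUE, nrow(pop)),
                    `high-count` = strata$high, `low-count` = strata$low)
      for (strategy in strategies) {
        disp <- estimate_dispersions(
          cm, strategy = strategy,
          true_dispersions = if (strategy == "oracle") pop$dispersion,
          prior_df = prior_df
        )
        p <- exact_nb_test(cm, dispersions = disp)
        for (stratum in names(masks)) {
          mask <- masks[[stratum]]
          rows[[length(rows) + 1L]] <- data.frame(
            repetition = r, n = n, strategy = strategy, stratum = stratum,
            fpr_percent = if (any(mask)) fpr_null(p[mask], alpha_percent)
                          else NA_real_,
            n_transcripts = sum(mask), stringsAsFactors = FALSE
          )
        }
        if (verbose) {
          message(sprintf("null rep %d n=%d %s: FPR %.3f%%", r, n, strategy,
                          rows[[length(rows) - 2L]]$fpr_percent))
        }
      }
    }
  }
  per_repetition <- do.call(rbind, rows)
  list(per_repetition = per_repetition,
       summary = summarize_repetitions(per_repetition, "fpr_percent",
                                       c("n", "strategy", "stratum")))
}

# shared engine for power grids and multiplex scenarios: `cells` is a data
# frame of (n, depth) pairs; within a repetition each n is simulated once at
# full depth and every requested depth is a subsample of that same dataset,
# so depth comparisons are paired.
power_engine <- function(cells, strategy, repetitions, alpha_percent, config,
                         prior_df, fold_threshold, fold_pseudocounts,
                         count_threshold, seed, verbose) {
  rows <- list()
  for (r in seq_len(repetitions)) {
    pop <- build_parameter_population(config, seed = child_seed(seed, r, 1))
    pop <- draw_regulating_factors(pop, config$frac_up, config$frac_down,
                                   seed = child_seed(seed, r, 2))
    pop <- label_effective_de(pop)
    is_de <- as_is_de(pop$effective_label)
    for (n in unique(cells$n)) {
      full <- simulate_counts(pop, n, seed = child_seed(seed, r, 3, n))
      depths <- sort(unique(cells$depth[cells$n == n]), decreasing = TRUE)
      for (depth in depths) {
        cm <- if (depth == 1) {
          full
        } else {
          subsample_depth(full, depth,
                          seed = child_seed(seed, r, 4, n, round(1e4 * depth)))
        }
        res <- run_de_test(
          cm, strategy = strategy, alpha_percent = alpha_percent,
          true_dispersions = if (strategy == "oracle") pop$dispersion,
          prior_df = prior_df, fold_threshold = fold_threshold
        )
        base <- data.frame(repetition = r, n = n, depth_fraction = depth,
                           strategy = strategy, stringsAsFactors = FALSE)
        m <- de_metrics(res, pop$effective_label, cm, alpha_percent,
                        count_threshold)
        rows[[length(rows) + 1L]] <-
          cbind(base, criterion = "adjusted-p", m)
        strata <- stratify_by_count(cm, threshold = count_threshold)
        for (pc in fold_pseudocounts) {
          fc <- fold_change_detector(cm, threshold = fold_threshold,
                                     pseudocount = pc)
          rows[[length(rows) + 1L]] <-
            cbind(base, criterion = sprintf("fold-change-pseudo%g", pc),
                  rates_from_calls(fc$call, is_de, strata))
        }
        if (verbose) {
          message(sprintf("rep %d n=%d depth=%.2f: TPR %.2f%% FPR %.3f%%",
                          r, n, depth, m$tpr_percent[1], m$fpr_percent[1]))
        }
      }
    }
  }
  per_repetition <- do.call(rbind, rows)
  rownames(per_repetition) <- NULL
  per_repetition
}

power_summary <- function(per_repetition) {
  summarize_repetitions(
    per_repetition,
    c("call_rate_percent", "fpr_percent", "tpr_percent"),
    c("n", "depth_fraction", "strategy", "criterion", "stratum")
  )
}

#' Replication-by-depth power grid
#'
#' For every repetition, simulates a DE dataset (15% induced DE by default)
#' per value of `n` at full depth, subsamples the same dataset to each
#' requested depth fraction (paired comparisons), runs the DE test, and
#' records call rate, FPR and TPR at the adjusted-p criterion plus
#' fold-change criteria at the configured pseudocounts, overall and per
#' count stratum.
#'
#' @param n_values Replicates per condition.
#' @param depth_fractions Depth grid in `(0, 1]`.
#' @param strategy Dispersion strategy for the test.
#' @param repetitions Independent datasets per cell (default 10).
#' @param fold_pseudocounts Pseudocounts at which the fold-change criterion
#'   is also evaluated (default 0 and 1).
#' @inheritParams run_null_experiment
#' @param fold_threshold Fold-change call threshold.
#' @return List with tidy `per_repetition` rows and their `summary`.
#' @export
run_power_grid <- function(n_values = c(2, 3, 4, 6, 8, 12),
                           depth_fractions = c(1, 0.75, 0.5, 0.25, 0.15,
                                               0.1, 0.05, 0.01),
                           strategy = "max-parametric",
                           repetitions = 10,
                           alpha_percent = 1,
                           config = generator_config(),
                           prior_df = 10,
                           fold_threshold = 2,
                           fold_pseudocounts = c(0, 1),
                           count_threshold = 100,
                           seed = 1,
                           verbose = FALSE) {
  check_scalar_number(repetitions, "repetitions", lower = 1)
  stopifnot(inherits(config, "generator_config"))
  if (any(depth_fractions <= 0 | depth_fractions > 1)) {
    stop_input("`depth_fractions` must lie in (0, 1]")
  }
  cells <- expand.grid(n = n_values, depth = depth_fractions)
  per_repetition <- power_engine(cells, strategy, repetitions, alpha_percent,
                                 config, prior_df, fold_threshold,
                                 fold_pseudocounts, count_threshold, seed,
                                 verbose)
  list(per_repetition = per_repetition,
       summary = power_summary(per_repetition))
}

#' Multiplex experimental-design scenarios
#'
#' Evaluates designs that pack `n` barcoded samples per lane (two lanes for
#' an n-vs-n comparison), so each sample is sequenced at an average depth of
#' `1/n`: the scenario list pairs every `n` with depth `1/n` exactly. The
#' trajectory of TPR across these scenarios is the "multiplex line". Cells
#' coincide with the matching [run_power_grid()] cells for the same root
#' seed.
#'
#' @param n_values Replicates per condition (all >= 2); default
#'   `c(2, 3, 4, 6, 8, 12, 32, 96)`.
#' @inheritParams run_power_grid
#' @return List with tidy `per_repetition` rows and their `summary`.
#' @export
run_multiplex_scenarios <- function(n_values = c(2, 3, 4, 6, 8, 12, 32, 96),
                                    strategy = "max-parametric",
                                    repetitions = 10,
                                    alpha_percent = 1,
                                    config = generator_config(),
                                    prior_df = 10,
                                    fold_threshold = 2,
                                    fold_pseudocounts = c(0, 1),
                                    count_threshold = 100,
                                    seed = 1,
                                    verbose = FALSE) {
  if (any(n_values < 2)) stop_input("multiplex scenarios need n >= 2")
  stopifnot(inherits(config, "generator_config"))
  cells <- data.frame(n = n_values, depth = 1 / n_values)
  per_repetition <- power_engine(cells, strategy, repetitions, alpha_percent,
                                 config, prior_df, fold_threshold,
                                 fold_pseudocounts, count_threshold, seed,
                                 verbose)
  list(per_repetition = per_repetition,
       summary = power_summary(per_repetition))
}

#' Write experiment tables to disk
#'
#' Writes every table of a named list as `<name>.tsv` under `output_dir`
#' and a combined `report.json` holding all tables, for programmatic reuse.
#'
#' @param tables Named list of data frames (e.g. the `per_repetition` and
#'   `summary` components of a runner result).
#' @param output_dir Directory to create/write into.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(tables, output_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables),
            all(nzchar(names(tables))))
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_input(sprintf("cannot create `%s`", output_dir))
  }
  files <- character(0)
  for (nm in names(tables)) {
    stopifnot(is.data.frame(tables[[nm]]))
    f <- file.path(output_dir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  jf <- file.path(output_dir, "report.json")
  jsonlite::write_json(tables, jf, dataframe = "rows", digits = NA)
  invisible(c(files, jf))
}
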