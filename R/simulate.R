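# Count simulation and read-level resampling (lane equalisation, depth
# reduction). Reads are only ever removed without replacement, so per-lane
# subsamples follow a multivariate hypergeometric law over transcripts.

# Multivariate hypergeometric draw: subsample `n` reads without replacement
# from a lane whose reads are partitioned over transcripts as `x`.
# Sequential conditional method: category i is Hypergeometric given the
# reads remaining to draw and the reads remaining in categories i..t.
rmvhyper_counts <- function(x, n) {
  total <- sum(x)
  if (n > total) stop_input("cannot subsample more reads than the lane holds")
  if (n == total) return(x)
  out <- numeric(length(x))
  remaining <- total
  k <- n
  for (i in seq_along(x)) {
    if (k == 0) break
    xi <- x[i]
    remaining <- remaining - xi
    if (remaining == 0) { # all that is left to draw comes from this category
      out[i] <- k
      k <- 0
      break
    }
    drawn <- rhyper(1L, xi, remaining, k)
    out[i] <- drawn
    k <- k - drawn
  }
  out
}

#' Equalise lane sequencing depths to the shallowest lane
#'
#' Reduces every lane's total count to the minimum lane total by
#' without-replacement subsampling of reads, tracking the transcript each
#' read maps to (one multivariate hypergeometric draw per lane). Used to put
#' replicate lanes of unequal depth on a common footing before parameter
#' estimation. If all totals are already equal the matrix is returned
#' unchanged and the RNG is not consumed.
#'
#' @param counts A [count_matrix()] (or coercible matrix).
#' @param seed Optional seed.
#' @return A [count_matrix()] with equal lane totals.
#' @export
equalize_lane_depths <- function(counts, seed = NULL) {
  x <- as_count_matrix(counts)
  totals <- lane_totals(x)
  target <- min(totals)
  if (all(totals == target)) return(x)
  with_seed(seed, {
    for (j in which(totals > target)) {
      x$counts[, j] <- rmvhyper_counts(x$counts[, j], target)
    }
    x
  })
}

#' Remove transcripts with too few reads overall
#'
#' Drops transcripts whose total count across all lanes is below `min_total`
#' (the study design uses one count per lane on average, i.e. `min_total =`
#' number of lanes). Transcripts this shallow cannot support dispersion
#' estimation.
#'
#' @param counts A [count_matrix()].
#' @param min_total Minimum summed count to keep a transcript.
#' @return A [count_matrix()] restricted to the retained transcripts.
#' @export
cull_low_count_transcripts <- function(counts, min_total) {
  x <- as_count_matrix(counts)
  check_scalar_number(min_total, "min_total", lower = 0)
  keep <- rowSums(x$counts) >= min_total
  if (!any(keep)) {
    warning("all transcripts fall below `min_total`; returning empty matrix")
  }
  x$counts <- x$counts[keep, , drop = FALSE]
  x
}

#' Simulate paired control / treatment count matrices
#'
#' Draws `n_reps` control lanes per transcript from `NB(mu_i, phi_i)` and
#' `n_reps` treatment lanes from `NB(theta_i * mu_i, phi_i)` (regulating
#' factor applied to the mean, dispersion unchanged), independently across
#' transcripts and lanes. Transcripts with `phi = 0` are drawn Poisson.
#'
#' @param params A `"transcript_params"` data frame (no degenerate rows).
#' @param n_reps Biological replicates per condition (>= 1).
#' @param seed Optional seed.
#' @return A [count_matrix()] with `2 * n_reps` lanes and a condition factor.
#' @export
#' @examples
#' pop <- build_parameter_population(generator_config(t = 50), seed = 1)
#' simulate_counts(pop, n_reps = 3, seed = 2)
simulate_counts <- function(params, n_reps, seed = NULL) {
  stopifnot(inherits(params, "transcript_params"))
  check_scalar_number(n_reps, "n_reps", lower = 1)
  if (n_reps != round(n_reps)) stop_input("`n_reps` must be an integer")
  if (any(!is.finite(params$mean)) || any(params$mean <= 0)) {
    stop_input("all transcript means must be positive (drop degenerate rows)")
  }
  if (any(!is.finite(params$dispersion)) || any(params$dispersion < 0)) {
    stop_input("all dispersions must be non-negative")
  }
  t <- nrow(params)
  draw_block <- function(mu, phi, n) {
    m <- matrix(0, length(mu), n)
    pos <- phi > 0
    if (any(pos)) {
      m[pos, ] <- rnbinom(sum(pos) * n, size = 1 / phi[pos], mu = mu[pos])
    }
    if (any(!pos)) {
      m[!pos, ] <- rpois(sum(!pos) * n, lambda = mu[!pos])
    }
    m
  }
  with_seed(seed, {
    ctrl <- draw_block(params$mean, params$dispersion, n_reps)
    trt <- draw_block(params$theta * params$mean, params$dispersion, n_reps)
    counts <- cbind(ctrl, trt)
    rownames(counts) <- params$transcript_id
    colnames(counts) <- c(sprintf("control_%02d", seq_len(n_reps)),
                          sprintf("treatment_%02d", seq_len(n_reps)))
    count_matrix(counts,
                 condition = rep(c("control", "treatment"), each = n_reps))
  })
}

#' Reduce sequencing depth by without-replacement read subsampling
#'
#' Independently reduces every lane to `round(depth_fraction * lane total)`
#' reads (round-half-even) by sampling reads without replacement while
#' tracking their transcript of origin (multivariate hypergeometric per
#' lane). This emulates sequencing the same libraries at a lower depth, e.g.
#' under multiplexing; applied to control and treatment lanes alike.
#'
#' @param counts A [count_matrix()].
#' @param depth_fraction Fraction of reads to retain, in `(0, 1]`.
#' @param seed Optional seed.
#' @return A [count_matrix()] at reduced depth (identical at
#'   `depth_fraction = 1`).
#' @export
subsample_depth <- function(counts, depth_fraction, seed = NULL) {
  x <- as_count_matrix(counts)
  check_scalar_number(depth_fraction, "depth_fraction", lower = 0, upper = 1)
  if (depth_fraction == 0) stop_input("`depth_fraction` must be in (0, 1]")
  if (depth_fraction == 1) return(x)
  with_seed(seed, {
    totals <- lane_totals(x)
    targets <- round(depth_fraction * totals)
    for (j in seq_along(targets)) {
      if (targets[j] < totals[j]) {
        x$counts[, j] <- rmvhyper_counts(x$counts[, j], targets[j])
      }
    }
    x
  })
}
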