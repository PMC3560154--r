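# Transcriptome parameter populations: either estimated from a real count
# matrix (44-lane style single-condition replicates) or drawn from a built-in
# generator emulating the empirical abundance / dispersion landscape.

#' Configuration for the built-in parameter generator
#'
#' Describes a synthetic transcriptome: per-transcript abundances follow a
#' truncated log10-normal law and dispersions scatter around the power-law
#' trend \eqn{\phi = c\,\mu^{\alpha-2}} with log-normal noise. The defaults
#' are the study conditions used throughout: `c = 0.364`, `alpha = 1.700`
#' for the trend, `log10(mu) ~ N(0.9, 0.8)` truncated to `[1, 1e5]` spanning
#' four abundance decades, means rescaled so a lane totals `library_size`
#' expected reads, and 7.5% up- plus 7.5% down-regulated transcripts.
#'
#' @param t Number of transcripts.
#' @param mu_log10_mean,mu_log10_sd Location and scale of the log10-abundance
#'   normal law (before truncation and rescaling).
#' @param mu_range Truncation bounds for the raw abundance draw.
#' @param dispersion_c,dispersion_alpha Power-law trend parameters.
#' @param sigma_phi Standard deviation (log10 scale) of dispersion scatter
#'   around the trend.
#' @param phi_range Clamp bounds for generated dispersions.
#' @param frac_up,frac_down Fractions of transcripts induced up / down.
#' @param library_size Expected per-lane total after rescaling the means;
#'   `NULL` skips rescaling.
#' @param seed Optional default seed stored with the configuration.
#' @return An object of class `"generator_config"` (a validated list).
#' @export
#' @examples
#' generator_config(t = 1000)
generator_config <- function(t = 20000,
                             mu_log10_mean = 0.9,
                             mu_log10_sd = 0.8,
                             mu_range = c(1, 1e5),
                             dispersion_c = 0.364,
                             dispersion_alpha = 1.700,
                             sigma_phi = 0.35,
                             phi_range = c(1e-4, 10),
                             frac_up = 0.075,
                             frac_down = 0.075,
                             library_size = 1e6,
                             seed = NULL) {
  check_scalar_number(t, "t", lower = 1)
  check_scalar_number(mu_log10_mean, "mu_log10_mean")
  check_scalar_number(mu_log10_sd, "mu_log10_sd", lower = 0)
  stopifnot(length(mu_range) == 2L, mu_range[1] > 0, diff(mu_range) > 0)
  check_scalar_number(dispersion_c, "dispersion_c", lower = 0,
                      allow_boundary = FALSE)
  check_scalar_number(dispersion_alpha, "dispersion_alpha")
  check_scalar_number(sigma_phi, "sigma_phi", lower = 0)
  stopifnot(length(phi_range) == 2L, phi_range[1] > 0, diff(phi_range) > 0)
  check_scalar_number(frac_up, "frac_up", lower = 0, upper = 1)
  check_scalar_number(frac_down, "frac_down", lower = 0, upper = 1)
  if (frac_up + frac_down > 1) stop_input("frac_up + frac_down must be <= 1")
  if (!is.null(library_size)) {
    check_scalar_number(library_size, "library_size", lower = 1)
  }
  structure(list(t = as.integer(t),
                 mu_log10_mean = mu_log10_mean, mu_log10_sd = mu_log10_sd,
                 mu_range = as.numeric(mu_range),
                 dispersion_c = dispersion_c,
                 dispersion_alpha = dispersion_alpha,
                 sigma_phi = sigma_phi, phi_range = as.numeric(phi_range),
                 frac_up = frac_up, frac_down = frac_down,
                 library_size = library_size, seed = seed),
            class = "generator_config")
}

#' Full-scale preset of the generator configuration
#'
#' The transcriptome-scale conditions: 46,446 transcripts at a lane total of
#' 13 million reads (the midpoint of the 10-16 million range of the lanes the
#' parameter landscape emulates). Dot-dot-dot arguments override any field.
#'
#' @param ... Overrides passed to [generator_config()].
#' @return A `"generator_config"`.
#' @export
generator_config_full_scale <- function(...) {
  args <- list(...)
  defaults <- list(t = 46446, library_size = 13e6)
  do.call(generator_config, utils::modifyList(defaults, args))
}

#' Read / write a generator configuration (YAML or JSON)
#'
#' @param path File path; format chosen by extension (`.json` for JSON,
#'   anything else parsed as YAML).
#' @return For `read_generator_config` a `"generator_config"`;
#'   `write_generator_config` invisibly returns `path`.
#' @export
read_generator_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(generator_config, cfg)
}

#' @param config A `"generator_config"`.
#' @rdname read_generator_config
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

new_transcript_params <- function(transcript_id, mean, dispersion,
                                  theta = rep(1, length(mean)),
                                  effective_label =
                                    rep("effectively-non-DE", length(mean))) {
  structure(data.frame(transcript_id = as.character(transcript_id),
                       mean = mean, dispersion = dispersion, theta = theta,
                       effective_label = effective_label,
                       stringsAsFactors = FALSE),
            class = c("transcript_params", "data.frame"))
}

rnorm_truncated_log10 <- function(n, location, scale, range) {
  lo <- log10(range[1])
  hi <- log10(range[2])
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(n - length(out), location, scale)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  10^out
}

#' Build a per-transcript NB parameter population
#'
#' Produces the `(mu_i, phi_i)` landscape that seeds every simulation, by one
#' of two routes:
#' \itemize{
#'   \item from a [count_matrix()] of biological replicates of a single
#'     condition: lane totals are equalised to the smallest lane
#'     ([equalize_lane_depths()]), transcripts averaging under one count per
#'     lane are culled ([cull_low_count_transcripts()], `min_total` defaults
#'     to the number of lanes), and `NB(mu, phi)` is fitted per transcript by
#'     maximum likelihood ([estimate_nb_mle()]); degenerate (all-zero) fits
#'     are dropped;
#'   \item from a [generator_config()]: abundances from the truncated
#'     log10-normal law (rescaled to the configured lane total) and
#'     dispersions `c * mu^(alpha-2) * 10^eps` with `eps ~ N(0, sigma_phi)`,
#'     clamped to `phi_range`.
#' }
#' All regulating factors start at 1 (no DE).
#'
#' @param source A [count_matrix()] or a [generator_config()].
#' @param seed Optional seed for the equalisation subsampling / the generator
#'   draws (falls back to `source$seed` for configs).
#' @param min_total Culling threshold for the count-matrix route; default is
#'   the number of lanes.
#' @return A `"transcript_params"` data frame with columns `transcript_id`,
#'   `mean`, `dispersion`, `theta`, `effective_label`.
#' @export
#' @examples
#' pop <- build_parameter_population(generator_config(t = 100), seed = 1)
#' head(pop)
build_parameter_population <- function(source, seed = NULL, min_total = NULL) {
  if (inherits(source, "generator_config")) {
    seed <- seed %||% source$seed
    return(with_seed(seed, {
      mu <- rnorm_truncated_log10(source$t, source$mu_log10_mean,
                                  source$mu_log10_sd, source$mu_range)
      if (!is.null(source$library_size)) {
        mu <- mu * source$library_size / sum(mu)
      }
      eps <- if (source$sigma_phi > 0) rnorm(source$t, 0, source$sigma_phi) else 0
      phi <- source$dispersion_c * mu^(source$dispersion_alpha - 2) * 10^eps
      phi <- pmin(pmax(phi, source$phi_range[1]), source$phi_range[2])
      new_transcript_params(sprintf("tx%06d", seq_len(source$t)), mu, phi)
    }))
  }
  if (!inherits(source, "count_matrix")) {
    stop_input("`source` must be a count_matrix or a generator_config")
  }
  if (ncol(source$counts) < 2L) {
    stop_input("need >= 2 lanes (biological replicates) to estimate dispersion")
  }
  eq <- equalize_lane_depths(source, seed = seed)
  eq <- cull_low_count_transcripts(eq, min_total %||% ncol(eq$counts))
  if (nrow(eq$counts) == 0L) stop_input("no transcripts left after culling")
  fits <- apply(eq$counts, 1L, estimate_nb_mle)
  keep <- !vapply(fits, function(f) isTRUE(f$degenerate), logical(1))
  fits <- fits[keep]
  new_transcript_params(rownames(eq$counts)[keep],
                        vapply(fits, `[[`, numeric(1), "mean"),
                        vapply(fits, `[[`, numeric(1), "dispersion"))
}

#' Induce differential expression via exponential regulating factors
#'
#' Randomly selects disjoint subsets of `floor(frac_up * t)` transcripts to
#' up-regulate with factor `theta = 1 + X` and `floor(frac_down * t)` to
#' down-regulate with `theta = (1 + X)^(-1)`, where `X ~ Exponential(mean 1)`;
#' remaining transcripts keep `theta = 1`. The treatment-condition mean of a
#' transcript becomes `theta * mu` with unchanged dispersion. Labels are not
#' recomputed here; call [label_effective_de()] afterwards.
#'
#' @param params A `"transcript_params"` data frame.
#' @param frac_up,frac_down Fractions of transcripts regulated up / down
#'   (defaults 0.075 each, i.e. 15% induced in total).
#' @param seed Optional seed.
#' @return `params` with updated `theta`.
#' @export
#' @examples
#' pop <- build_parameter_population(generator_config(t = 200), seed = 1)
#' pop <- draw_regulating_factors(pop, seed = 2)
#' table(pop$theta != 1)
draw_regulating_factors <- function(params, frac_up = 0.075,
                                    frac_down = 0.075, seed = NULL) {
  stopifnot(inherits(params, "transcript_params"))
  check_scalar_number(frac_up, "frac_up", lower = 0, upper = 1)
  check_scalar_number(frac_down, "frac_down", lower = 0, upper = 1)
  if (frac_up + frac_down > 1) stop_input("frac_up + frac_down must be <= 1")
  t <- nrow(params)
  n_up <- floor(frac_up * t)
  n_down <- floor(frac_down * t)
  with_seed(seed, {
    params$theta <- rep(1, t)
    if (n_up + n_down > 0) {
      idx <- sample.int(t, n_up + n_down)
      if (n_up > 0) {
        params$theta[idx[seq_len(n_up)]] <- 1 + rexp(n_up, rate = 1)
      }
      if (n_down > 0) {
        params$theta[idx[n_up + seq_len(n_down)]] <-
          1 / (1 + rexp(n_down, rate = 1))
      }
    }
    params
  })
}

#' Label transcripts as effectively DE or effectively non-DE
#'
#' A regulated transcript only counts as a true positive when its fold change
#' is biologically meaningful: `theta <= lower` or `theta >= upper`
#' (boundaries inclusive) marks it `"effectively-DE"`, anything in between
#' (including unregulated transcripts) `"effectively-non-DE"`. These labels
#' are the ground truth used by [fpr()] and [tpr()].
#'
#' @param params A `"transcript_params"` data frame with `theta` assigned.
#' @param lower,upper Regulating-factor thresholds (defaults 0.83 and 1.20).
#' @return `params` with updated `effective_label`.
#' @export
label_effective_de <- function(params, lower = 0.83, upper = 1.20) {
  stopifnot(inherits(params, "transcript_params"))
  check_scalar_number(lower, "lower", lower = 0)
  check_scalar_number(upper, "upper", lower = lower)
  params$effective_label <-
    ifelse(params$theta <= lower | params$theta >= upper,
           "effectively-DE", "effectively-non-DE")
  params
}
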