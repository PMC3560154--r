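test_that("equalize_lane_depths contracts every lane to the minimum total", {
  cm <- count_matrix(matrix(c(30, 70, 60, 140), 2, 2))
  eq <- equalize_lane_depths(cm, seed = 1)
  expect_equal(unname(colSums(eq$counts)), c(100, 100))
  expect_true(all(eq$counts <= cm$counts))
  # already equal: returned unchanged
  cm2 <- count_matrix(matrix(c(10, 20, 15, 15), 2, 2))
  expect_identical(equalize_lane_depths(cm2), cm2)
  # degenerate hypergeometric: single transcript keeps everything
  cm3 <- count_matrix(matrix(c(100, 200), 1, 2))
  eq3 <- equalize_lane_depths(cm3, seed = 2)
  expect_equal(unname(eq3$counts[1, ]), c(100, 100))
})

test_that("cull_low_count_transcripts applies the one-count-per-lane rule", {
  counts <- matrix(1, 2, 44)
  counts[2, 44] <- 0 # total 43 over 44 lanes
  cm <- count_matrix(counts)
  culled <- cull_low_count_transcripts(cm, 44)
  expect_equal(nrow(culled$counts), 1L)
  expect_identical(cull_low_count_transcripts(cm, 0)$counts, cm$counts)
  expect_warning(cull_low_count_transcripts(cm, 1000), "all transcripts")
})

test_that("generator populations follow the configured abundance and dispersion laws", {
  cfg0 <- generator_config(t = 500, sigma_phi = 0)
  pop0 <- build_parameter_population(cfg0, seed = 11)
  expect_equal(nrow(pop0), 500L)
  expect_equal(pop0$dispersion, 0.364 * pop0$mean^(1.700 - 2),
               tolerance = 1e-12)
  expect_true(all(pop0$theta == 1))
  # lane total rescaling
  expect_equal(sum(pop0$mean), 1e6, tolerance = 1e-6)
  cfg <- generator_config(t = 5000)
  pop <- build_parameter_population(cfg, seed = 12)
  expect_equal(nrow(pop), 5000L)
  expect_true(all(pop$dispersion >= 1e-4 & pop$dispersion <= 10))
  # reproducibility
  expect_identical(pop, build_parameter_population(cfg, seed = 12))
})

test_that("parameter estimation pipeline recovers NB parameters from counts", {
  set.seed(13)
  counts <- matrix(rnbinom(300 * 44, size = 1 / 0.3, mu = 50), 300, 44)
  pop <- build_parameter_population(count_matrix(counts), seed = 14)
  expect_gt(nrow(pop), 290)
  expect_lt(abs(median(pop$dispersion) - 0.3) / 0.3, 0.25)
  expect_lt(abs(median(pop$mean) - 50) / 50, 0.1)
})

test_that("regulating factors hit the designed subset sizes and moments", {
  params <- make_params(rep(10, 1000), rep(0.1, 1000))
  # null configuration
  null <- draw_regulating_factors(params, 0, 0, seed = 15)
  expect_true(all(null$theta == 1))
  # floor-rounded subset sizes
  de <- draw_regulating_factors(params, seed = 16)
  expect_equal(sum(de$theta != 1), 2 * floor(0.075 * 1000))
  expect_equal(sum(de$theta > 1), floor(0.075 * 1000))
  # E(1 + X) = 2 for the up-regulated factors
  big <- make_params(rep(1, 2e5), rep(0.1, 2e5))
  up <- draw_regulating_factors(big, frac_up = 0.5, frac_down = 0, seed = 17)
  expect_lt(abs(mean(up$theta[up$theta > 1]) - 2), 0.02)
})

test_that("effective-DE labels follow the fold-change thresholds", {
  params <- make_params(rep(1, 3), rep(0.1, 3))
  params$theta <- c(1, 1.20, 0.83)
  lab <- label_effective_de(params)
  expect_equal(lab$effective_label,
               c("effectively-non-DE", "effectively-DE", "effectively-DE"))
  # closed form: P(theta outside (0.83, 1.20)) for the exponential factors
  big <- make_params(rep(1, 1e6), rep(0.1, 1e6))
  ind <- draw_regulating_factors(big, frac_up = 0.5, frac_down = 0.5,
                                 seed = 18)
  ind <- label_effective_de(ind)
  frac <- mean(ind$effective_label == "effectively-DE")
  analytic <- (exp(-0.2) + exp(-(1 / 0.83 - 1))) / 2
  expect_lt(abs(frac - analytic), 0.001)
})

test_that("simulate_counts reproduces the configured moments", {
  # null symmetry: control and treatment exchangeable
  pop <- build_parameter_population(generator_config(t = 2000), seed = 19)
  cm <- simulate_counts(pop, 3, seed = 20)
  ks <- suppressWarnings(ks.test(
    rowMeans(cm$counts[, cm$condition == "control"]),
    rowMeans(cm$counts[, cm$condition == "treatment"])
  ))
  expect_gt(ks$p.value, 0.001)
  # Poisson limit: per-lane variance equals the mean
  pois <- make_params(rep(10, 4000), rep(0, 4000))
  cmp <- simulate_counts(pois, 6, seed = 21)
  expect_lt(abs(mean(apply(cmp$counts, 1, var)) - 10), 0.5)
  # induced fold change scales the treatment mean
  reg <- make_params(rep(100, 10000), rep(0.1, 10000),
                     theta = rep(3, 10000))
  cmr <- simulate_counts(reg, 2, seed = 22)
  trt <- colMeans(cmr$counts[, cmr$condition == "treatment"])
  expect_true(all(abs(trt - 300) / 300 < 0.01))
  # determinism
  expect_identical(simulate_counts(pop, 3, seed = 20), cm)
  expect_error(simulate_counts(pop, 0), "lower|integer|\\[1")
})

test_that("subsample_depth is an exact multivariate hypergeometric thinning", {
  pop <- build_parameter_population(generator_config(t = 500), seed = 23)
  cm <- simulate_counts(pop, 2, seed = 24)
  expect_identical(subsample_depth(cm, 1), cm)
  sub <- subsample_depth(cm, 0.15, seed = 25)
  expect_equal(unname(colSums(sub$counts)),
               unname(round(0.15 * colSums(cm$counts))))
  expect_true(all(sub$counts <= cm$counts))
  expect_identical(subsample_depth(cm, 0.15, seed = 25), sub)
  expect_error(subsample_depth(cm, 0), "\\(0, 1\\]")
  expect_error(subsample_depth(cm, 1.2), "outside")
})

test_that("subsampled counts have the hypergeometric expectation", {
  lane <- count_matrix(matrix(c(10000, 990000), 2, 1))
  draws <- vapply(1:500, function(r) {
    subsample_depth(lane, 0.1, seed = 1000 + r)$counts[1, 1]
  }, numeric(1))
  se <- sqrt(1e5 * 0.01 * 0.99 * (1e6 - 1e5) / (1e6 - 1)) / sqrt(500)
  expect_lt(abs(mean(draws) - 1000), 4 * se)
})

test_that("two-stage 50% subsampling matches a single 25% subsample", {
  lane <- count_matrix(matrix(c(40, 30, 20, 10), 4, 1))
  one <- vapply(1:1500, function(r) {
    subsample_depth(lane, 0.25, seed = 2000 + r)$counts[1, 1]
  }, numeric(1))
  two <- vapply(1:1500, function(r) {
    half <- subsample_depth(lane, 0.5, seed = 4000 + r)
    subsample_depth(half, 0.5, seed = 6000 + r)$counts[1, 1]
  }, numeric(1))
  lev <- 0:13
  tab <- rbind(table(factor(pmin(one, 13), levels = lev)),
               table(factor(pmin(two, 13), levels = lev)))
  keep <- colSums(tab) >= 10
  expect_gt(suppressWarnings(chisq.test(tab[, keep]))$p.value, 0.001)
})

test_that("count matrices round-trip through TSV", {
  pop <- build_parameter_population(generator_config(t = 40), seed = 26)
  cm <- simulate_counts(pop, 2, seed = 27)
  tsv <- tempfile(fileext = ".tsv")
  cmap <- tempfile(fileext = ".tsv")
  write_count_matrix(cm, tsv, cmap)
  back <- read_count_matrix(tsv, cmap)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$condition, cm$condition)
})

test_that("generator configurations round-trip through YAML and JSON", {
  cfg <- generator_config(t = 123, sigma_phi = 0.2, library_size = 5e5)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_generator_config(cfg, f)
    expect_equal(read_generator_config(f), cfg)
  }
})
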