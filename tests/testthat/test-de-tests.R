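test_that("size factors behave for unit, median-of-ratios and TMM", {
  set.seed(501)
  base <- rnbinom(2000, size = 5, mu = 10^runif(2000, 0.5, 3))
  dup <- count_matrix(cbind(base, base))
  for (m in c("unit", "median-of-ratios", "tmm")) {
    expect_equal(unname(compute_size_factors(dup, m)), c(1, 1),
                 tolerance = 1e-12)
  }
  doubled <- count_matrix(cbind(base, 2 * base))
  mor <- compute_size_factors(doubled, "median-of-ratios")
  expect_equal(unname(mor[2] / mor[1]), 2, tolerance = 1e-9)
  expect_equal(prod(mor), 1, tolerance = 1e-9)
  # cross-method consistency without DE
  null4 <- count_matrix(vapply(1:4, function(j) {
    rnbinom(2000, size = 5, mu = 10^runif(2000, 0.5, 3))
  }, numeric(2000)))
  expect_lt(max(abs(compute_size_factors(null4, "tmm") /
                      compute_size_factors(null4, "median-of-ratios") - 1)),
            0.05)
  expect_error(compute_size_factors(count_matrix(matrix(0, 2, 1))),
               "all-zero")
})

test_that("tagwise squeezing recovers a constant common dispersion", {
  set.seed(502)
  mu <- 10^runif(5000, 0.5, 3.5)
  params <- make_params(mu, rep(0.3, 5000))
  cm <- simulate_counts(params, 12, seed = 503)
  d <- estimate_dispersions(cm, strategy = "tagwise-squeeze")
  common <- attr(d, "details")$common
  expect_lt(abs(common - 0.3) / 0.3, 0.10)
  # infinite prior squeezes every transcript onto the common value
  dInf <- estimate_dispersions(cm, strategy = "tagwise-squeeze",
                               prior_df = Inf)
  expect_true(all(abs(dInf - attr(dInf, "details")$common) < 1e-12))
  # finite prior: estimates lie between tagwise and common (weighted mean)
  expect_true(all(d >= pmin(dInf[1], estimate_dispersions(
    cm, strategy = "tagwise-squeeze", prior_df = 0)) - 1e-12))
})

test_that("max-parametric takes the elementwise maximum of estimate and trend", {
  pop <- build_parameter_population(generator_config(t = 1500), seed = 504)
  cm <- simulate_counts(pop, 4, seed = 505)
  d <- estimate_dispersions(cm, strategy = "max-parametric")
  fit <- attr(d, "details")$fit
  expect_s3_class(fit, "parametric_dispersion_fit")
  mu <- rowMeans(cm$counts)
  fitted <- predict(fit, pmax(mu, 1e-8))
  expect_true(all(d >= pmin(fitted, 50) - 1e-8))
  # a wildly overdispersed transcript keeps its own (higher) estimate
  set.seed(506)
  spiked <- rbind(cm$counts,
                  spike = rnbinom(8, size = 1 / 5, mu = 200))
  cms <- count_matrix(spiked, condition = as.character(cm$condition))
  ds <- estimate_dispersions(cms, strategy = "max-parametric")
  i <- nrow(spiked)
  expect_gt(ds[i], predict(attr(ds, "details")$fit, mean(spiked[i, ])))
  expect_gt(ds[i], 1)
})

test_that("powerlaw strategy puts every transcript on its fitted trend", {
  pop <- build_parameter_population(generator_config(t = 1500), seed = 507)
  cm <- simulate_counts(pop, 4, seed = 508)
  d <- estimate_dispersions(cm, strategy = "powerlaw")
  fit <- attr(d, "details")$fit
  expect_s3_class(fit, "powerlaw_dispersion_fit")
  mu <- rowMeans(cm$counts)
  pos <- mu > 0
  expect_equal(as.numeric(d)[pos],
               unname(pmin(pmax(predict(fit, mu[pos]), 1e-8), 50)),
               tolerance = 1e-10)
})

test_that("oracle strategy passes true dispersions through", {
  pop <- build_parameter_population(generator_config(t = 100), seed = 509)
  cm <- simulate_counts(pop, 2, seed = 510)
  d <- estimate_dispersions(cm, strategy = "oracle",
                            true_dispersions = pop$dispersion)
  expect_equal(as.numeric(d), pop$dispersion)
  expect_error(estimate_dispersions(cm, strategy = "oracle"), "oracle")
})

test_that("exact test equals brute-force enumeration for all totals S <= 200", {
  phis <- c(0, 0.05, 0.5, 2)
  for (design in list(c(2, 2), c(1, 1), c(1, 3))) {
    nA <- design[1]; nB <- design[2]
    S <- 0:200
    SA <- S %/% 3
    SB <- S - SA
    phi <- rep_len(phis, length(S))
    cm <- make_split_matrix(SA, SB, nA, nB)
    p <- exact_nb_test(cm, dispersions = phi)
    expected <- vapply(seq_along(S), function(i) {
      oracle_exact_p(SA[i], SB[i], nA, nB, phi[i])
    }, numeric(1))
    expect_equal(unname(p), expected, tolerance = 1e-10)
  }
})

test_that("balanced designs with equal condition sums give p exactly 1", {
  cm <- make_split_matrix(c(0, 7, 40), c(0, 7, 40), 3, 3)
  expect_identical(unname(exact_nb_test(cm, dispersions = c(0.2, 0.2, 1))),
                   c(1, 1, 1))
})

test_that("Poisson limit reduces to the conditional Binomial(S, 1/2) test", {
  cases <- list(c(0, 4), c(3, 9), c(10, 10), c(1, 15))
  for (cs in cases) {
    cm <- make_split_matrix(cs[1], cs[2], 1, 1)
    p <- unname(exact_nb_test(cm, dispersions = 0))
    S <- sum(cs)
    pr <- dbinom(0:S, S, 0.5)
    expect_equal(p, sum(pr[pr <= pr[cs[1] + 1] * (1 + 1e-12)]),
                 tolerance = 1e-10)
  }
})

test_that("small observed instance matches direct enumeration", {
  cm <- make_split_matrix(0, 4, 1, 1)
  p <- unname(exact_nb_test(cm, dispersions = 0.5))
  expect_equal(p, oracle_exact_p(0, 4, 1, 1, 0.5), tolerance = 1e-12)
})

test_that("central-region enumeration agrees with the full sum", {
  set.seed(511)
  counts <- matrix(rnbinom(50 * 6, size = 1 / 0.2, mu = 300), 50, 6)
  cm <- count_matrix(counts, condition = rep(c("control", "treatment"),
                                             each = 3))
  full <- exact_nb_test(cm, dispersions = rep(0.2, 50))
  truncated <- exact_nb_test(cm, dispersions = rep(0.2, 50), s_max = 500)
  expect_equal(truncated, full, tolerance = 1e-9)
})

test_that("null p-values with oracle dispersions are near-uniform below the spike", {
  params <- make_params(rep(200, 4000), rep(0.12, 4000))
  cm <- simulate_counts(params, 3, seed = 512)
  p <- exact_nb_test(cm, dispersions = params$dispersion)
  # raw FPR of a correctly specified test is near nominal at high counts
  expect_lt(abs(fpr_null(p, 1) - 1), 3 * sqrt(0.0099 / 4000) * 100)
  sub <- p[p < 0.9] / 0.9
  D <- max(abs(sort(sub) - seq_along(sub) / length(sub)))
  expect_lt(D, 0.06)
})

test_that("BH adjustment matches the step-up oracle and preserves the top rank", {
  expect_equal(adjust_pvalues_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues_bh(0.2), 0.2)
  expect_equal(adjust_pvalues_bh(rep(1, 5)), rep(1, 5))
  set.seed(513)
  for (i in 1:5) {
    p <- runif(200)^2
    adj <- adjust_pvalues_bh(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    # the smallest raw p-value attains the smallest adjusted value
    expect_equal(adj[which.min(p)], min(adj))
  }
  expect_error(adjust_pvalues_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold-change detector applies thresholds and pseudocount damping", {
  two <- count_matrix(matrix(c(10, 20), 1, 2),
                      condition = c("control", "treatment"))
  expect_true(fold_change_detector(two, threshold = 2)$call)
  zero_one <- count_matrix(matrix(c(0, 1), 1, 2),
                           condition = c("control", "treatment"))
  expect_true(fold_change_detector(zero_one, pseudocount = 1)$call)
  expect_false(fold_change_detector(zero_one, pseudocount = 10)$call)
  # raw ratio against zero counts as a spurious doubling
  expect_true(fold_change_detector(zero_one, pseudocount = 0)$call)
  both_zero <- count_matrix(matrix(c(0, 0), 1, 2),
                            condition = c("control", "treatment"))
  expect_false(fold_change_detector(both_zero, pseudocount = 0)$call)
})

test_that("run_de_test composes the pipeline deterministically", {
  pop <- build_parameter_population(generator_config(t = 400), seed = 514)
  cm <- simulate_counts(pop, 3, seed = 515)
  res <- run_de_test(cm, strategy = "oracle",
                     true_dispersions = pop$dispersion)
  expect_s3_class(res, "de_result")
  expect_equal(nrow(res), 400L)
  expect_true(all(res$p_adj >= res$p_value - 1e-12))
  expect_identical(res, run_de_test(cm, strategy = "oracle",
                                    true_dispersions = pop$dispersion))
  # duplicated lanes across conditions: no evidence, p = 1 everywhere
  dup <- count_matrix(cbind(cm$counts[, 1:2], cm$counts[, 1:2]),
                      condition = rep(c("control", "treatment"), each = 2))
  expect_true(all(run_de_test(dup, strategy = "oracle",
                              true_dispersions = pop$dispersion)$p_value == 1))
  # TSV export round trip
  f <- tempfile(fileext = ".tsv")
  write_de_result(res, f)
  back <- read.delim(f)
  expect_equal(back$p_value, res$p_value, tolerance = 1e-12)
})

test_that("null FPR ordering reproduces the strategies' documented behaviour", {
  pop <- build_parameter_population(generator_config(t = 6000), seed = 21)
  for (n in c(2, 3)) {
    cm <- simulate_counts(pop, n, seed = 30 + n)
    f <- vapply(c("max-parametric", "tagwise-squeeze", "powerlaw"),
                function(s) {
      d <- estimate_dispersions(cm, strategy = s)
      fpr_null(exact_nb_test(cm, dispersions = d), 1)
    }, numeric(1))
    expect_lte(f[["max-parametric"]], f[["tagwise-squeeze"]])
    expect_lte(f[["tagwise-squeeze"]], f[["powerlaw"]])
  }
})
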