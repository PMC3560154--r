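# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths: the NB pmf is
# written out via lgamma, the exact test by naive enumeration, and the BH
# adjustment by the textbook step-up recursion.

oracle_nb_pmf <- function(k, mu, phi) {
  if (phi == 0) {
    return(exp(-mu + k * log(mu) - lgamma(k + 1)))
  }
  r <- 1 / phi
  p <- r / (r + mu)
  exp(lgamma(k + r) - lgamma(r) - lgamma(k + 1) + r * log(p) + k * log1p(-p))
}

# brute-force exact conditional test on condition sums
oracle_exact_p <- function(SA, SB, nA, nB, phi, tie_tol = 1e-12) {
  S <- SA + SB
  if (S == 0) return(1)
  mu_lane <- S / (nA + nB)
  a <- 0:S
  P <- oracle_nb_pmf(a, nA * mu_lane, phi / nA) *
    oracle_nb_pmf(S - a, nB * mu_lane, phi / nB)
  min(sum(P[P <= P[SA + 1] * (1 + tie_tol)]) / sum(P), 1)
}

# textbook step-up BH: p_(i) * m / i, cumulative minimum from the largest
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(rev(cummin(rev(p[o] * m / seq_len(m)))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# transcript parameter table without going through a generator
make_params <- function(mean, dispersion, theta = rep(1, length(mean))) {
  structure(
    data.frame(transcript_id = sprintf("tx%06d", seq_along(mean)),
               mean = mean, dispersion = dispersion, theta = theta,
               effective_label = "effectively-non-DE",
               stringsAsFactors = FALSE),
    class = c("transcript_params", "data.frame")
  )
}

# matrix of synthetic exact-test instances: one transcript per row, counts
# split over nA + nB lanes so that the condition sums are (SA, SB)
make_split_matrix <- function(SA, SB, nA, nB) {
  split_n <- function(s, n) {
    base <- s %/% n
    extra <- s %% n
    base + c(rep(1, extra), rep(0, n - extra))
  }
  counts <- t(vapply(seq_along(SA), function(i) {
    c(split_n(SA[i], nA), split_n(SB[i], nB))
  }, numeric(nA + nB)))
  count_matrix(counts,
               condition = rep(c("control", "treatment"), c(nA, nB)))
}
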