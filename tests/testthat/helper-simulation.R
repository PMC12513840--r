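# shared simulation helpers for the test suite

sim_region <- simulate_region
sim_instruments <- simulate_mr_instruments

# brute-force coloc oracle: literal enumeration of causal configurations
coloc_oracle <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 5e-6,
                         W = 0.04) {
  shared <- intersect(stats1$variant_id, stats2$variant_id)
  d1 <- stats1[match(shared, stats1$variant_id), ]
  d2 <- stats2[match(shared, stats2$variant_id), ]
  a1 <- exp(wakefield_log_abf(d1$beta, d1$se, W))
  a2 <- exp(wakefield_log_abf(d2$beta, d2$se, W))
  m <- length(shared)
  h0 <- 1
  h1 <- p1 * sum(a1)
  h2 <- p2 * sum(a2)
  h3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) h3 <- h3 + p1 * p2 * a1[i] * a2[j]
  }
  h4 <- p12 * sum(a1 * a2)
  pp <- c(h0, h1, h2, h3, h4)
  pp / sum(pp)
}

# high-precision Wakefield ABF through the normal-density form,
# independent of the package's algebraic form
wakefield_oracle <- function(beta, se, W = 0.04) {
  V <- se^2
  stats::dnorm(beta, 0, sqrt(V + W), log = TRUE) -
    stats::dnorm(beta, 0, sqrt(V), log = TRUE)
}
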