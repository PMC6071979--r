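# Shared fixtures, all built in code.

# small balanced clustered sample with known ANOVA decomposition
balanced_toy <- function() {
  list(y = c(0, 2, 4, 6), stand = c("A", "A", "B", "B"))
}

# simulated clustered dataset for integration-style tests
sim_data <- function(icc = 0.5, J = 22, n = 10, seed = 1,
                     components = FALSE) {
  generate_dataset(sim_config(J = J, n = n,
                              tau2 = tau2_for_icc(icc),
                              components = components, seed = seed))
}

# random balanced response for oracle-equivalence checks
random_balanced <- function(J, n, tau2 = 0.5, sigma2 = 1) {
  u <- rnorm(J, 0, sqrt(tau2))
  list(y = rep(u, each = n) + rnorm(J * n, 0, sqrt(sigma2)) + 5,
       stand = rep(sprintf("g%02d", seq_len(J)), each = n))
}
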