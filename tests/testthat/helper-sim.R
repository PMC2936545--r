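# small configurations used across tests
small_config <- function(seed = 11, ...) {
  sim_config(n_samples = 80, n_probes = 150, n_modules = 2,
             module_sizes = c(20, 15), n_snps = 40, n_cis_eqtl = 3,
             seed = seed, ...)
}

# quartet generator for SEM / LEO tests: anchors explain a^2 of their node,
# topology edge (or confounder arms) with path b
sim_quartet <- function(n = 500, topology = "causal", a = sqrt(0.1),
                        b = 0.5) {
  MA <- rbinom(n, 2, 0.3); MB <- rbinom(n, 2, 0.3)
  ma <- as.numeric(scale(MA)); mb <- as.numeric(scale(MB))
  e <- sqrt(1 - a^2 - b^2)
  if (topology == "causal") {
    A <- a * ma + sqrt(1 - a^2) * rnorm(n)
    B <- b * A + a * mb + e * rnorm(n)
  } else if (topology == "reactive") {
    B <- a * mb + sqrt(1 - a^2) * rnorm(n)
    A <- b * B + a * ma + e * rnorm(n)
  } else if (topology == "confounded") {
    C <- rnorm(n)
    A <- a * ma + b * C + e * rnorm(n)
    B <- a * mb + b * C + e * rnorm(n)
  } else {
    A <- a * ma + sqrt(1 - a^2) * rnorm(n)
    B <- a * mb + sqrt(1 - a^2) * rnorm(n)
  }
  list(A = A, B = B, MA = MA, MB = MB)
}
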