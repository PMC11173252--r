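# Shared small fixtures for the test suite.  Everything is seeded and cheap;
# heavier runs live in test-acceptance.R.

toy_domain <- rbind(c(-1.5, 1.5), c(-1.5, 1.5))

# tiny network for derivative checks
tiny_mlp <- function(d = 3L, hidden = c(5L, 4L), dim_out = 1L, seed = 42L) {
  set.seed(seed)
  mlp_potential(d, hidden = hidden, dim_out = dim_out)
}

# finite-difference gradient of a scalar function of the parameter vector
fd_grad <- function(f, par, eps = 1e-6) {
  vapply(seq_along(par), function(i) {
    p1 <- par; p2 <- par
    p1[i] <- p1[i] + eps; p2[i] <- p2[i] - eps
    (f(p1) - f(p2)) / (2 * eps)
  }, numeric(1))
}

# small mutual-repression / self-activation gene network (2 genes)
toggle_network <- function() {
  gene_network_system(activators = list(1, 2), repressors = list(2, 1))
}
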