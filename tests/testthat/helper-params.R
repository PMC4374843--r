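# shared fixtures and small oracles, built in code

fig1_params <- function(y = 100, a1 = 25, b = 50, gamma_b = 1) {
  gene_params(a0 = 0.75, a1 = a1, kp = 500, b = b, y = y, kb = 1,
              gamma_b = gamma_b)
}

# random parameter sets away from the closed-form degeneracies
random_valid_params <- function(n) {
  draws <- list()
  while (length(draws) < n) {
    p <- gene_params(a0 = runif(1, 0.1, 3), a1 = runif(1, 0.1, 30),
                     kp = runif(1, 2, 1000), b = runif(1, 10, 100),
                     y = runif(1, 1, 200), kb = runif(1, 0.1, 10),
                     gamma_b = runif(1, 0.2, 2))
    if (q_exponents(p)$valid) draws[[length(draws) + 1L]] <- p
  }
  draws
}

# trapezoid integral, independent of the package internals
tt_trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# total mass of a density grid including the analytic origin panel
grid_mass <- function(g) tt_trapz(g$x, g$density) + g$origin_mass
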