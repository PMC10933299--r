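# Independent oracles used by the tests. These are deliberately written from
# the definitions, not by calling the package's own code paths.

# Efron-approximation Cox partial log-likelihood for a single numeric
# covariate, vectorized over a grid of beta values.
efron_loglik <- function(beta, time, event, x) {
  E <- exp(outer(x, beta))            # n x B
  ll <- numeric(length(beta))
  for (tt in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == tt)
    R <- which(time >= tt)
    sR <- colSums(E[R, , drop = FALSE])
    sD <- colSums(E[D, , drop = FALSE])
    d <- length(D)
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sR - (l / d) * sD)
    }
  }
  ll
}

# Brute-force maximization of the Efron partial likelihood over a fine grid.
grid_max_beta <- function(time, event, x, grid = seq(-5, 5, by = 1e-4)) {
  grid[which.max(efron_loglik(grid, time, event, x))]
}

# Toy survival fixtures, all with <= 10 records and a binary group.
cox_toy_fixtures <- function() {
  list(
    untied = data.frame(time = 1:6, event = c(1, 1, 1, 1, 1, 0),
                        group = c("A", "B", "A", "B", "A", "B")),
    tied_pairs = data.frame(time = c(1, 1, 2, 2, 3, 3),
                            event = c(1, 1, 1, 1, 1, 1),
                            group = c("A", "B", "A", "B", "A", "B")),
    tied_mixed = data.frame(time = c(2, 2, 2, 3, 3, 4, 5, 5),
                            event = c(1, 1, 0, 1, 1, 1, 1, 0),
                            group = c("A", "B", "A", "B", "B", "A", "B", "A")),
    ten = data.frame(time = c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7),
                     event = c(1, 1, 1, 0, 1, 1, 0, 1, 1, 0),
                     group = c("A", "B", "A", "B", "B", "A", "A", "B", "A", "B"))
  )
}

# Closed-form FRAP physics, hand-coded from the definitions.
oracle_diffusion <- function(radius_um, t_half_s) {
  0.88 * radius_um * radius_um / (4 * t_half_s)
}
oracle_viscosity <- function(D_um2_s, r_nm, T_K) {
  1.380649e-23 * T_K / (6 * pi * (D_um2_s * 1e-12) * (r_nm * 1e-9))
}
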