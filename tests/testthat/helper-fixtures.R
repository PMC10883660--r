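# Shared fixtures, all generated in code.

# Per-presentation responses for a direction-uniform (null) neuron:
# list of 8 vectors, one per direction.
uniformRepResponses <- function(mean = 0.3, sd = 0.1, n_rep = 3) {
  lapply(1:8, function(j) rnorm(n_rep, mean, sd))
}

# A small high-SNR population with the default topography.
smallPopulation <- function(n_fwd = 8, n_bwd = 8, n_ns = 4, seed = 11,
                            noise_sd = 2) {
  spec <- populationSpec(
    n_per_class = c(forward = n_fwd, backward = n_bwd,
                    cw_rotation = 0, ccw_rotation = 0,
                    nonselective = n_ns),
    tuning = tuningParams(amplitude = 0.8, kappa = 4, noise_sd = noise_sd,
                          w_contra = 1, w_ipsi = 0.6),
    seed = seed)
  generatePopulation(spec)
}

# One epoch row of the default binocular protocol.
defaultEpoch <- function(i = 1, seed = 1) {
  epochs(generateProtocol(seed = seed))[i, ]
}

# Direct double-loop KDE + min-integral oracle, independent of kde2d's
# separable evaluation.
msOracle <- function(P, Q, grid, sd) {
  dens <- function(pts) {
    z <- matrix(0, length(grid$x), length(grid$y))
    for (i in seq_along(grid$x)) for (j in seq_along(grid$y)) {
      s <- 0
      for (k in seq_len(nrow(pts)))
        s <- s + dnorm(grid$x[i] - pts[k, 1], sd = sd) *
          dnorm(grid$y[j] - pts[k, 2], sd = sd)
      z[i, j] <- s
    }
    z / (sum(z) * (grid$x[2] - grid$x[1]) * (grid$y[2] - grid$y[1]))
  }
  sum(pmin(dens(P), dens(Q))) * (grid$x[2] - grid$x[1]) *
    (grid$y[2] - grid$y[1])
}
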