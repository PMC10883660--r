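# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards; keeps all randomness explicit and local.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap angles in degrees to (-180, 180].
wrapAngle <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

deg2rad <- function(deg) deg * pi / 180

.gridCellArea <- function(x, y) {
  dx <- if (length(x) > 1) x[2] - x[1] else 1
  dy <- if (length(y) > 1) y[2] - y[1] else 1
  dx * dy
}

# Empirical quantile used throughout: linear interpolation of the empirical
# CDF (stats::quantile type 7), the package's documented convention.
empiricalQuantile <- function(x, prob) {
  stats::quantile(x, probs = prob, names = FALSE, type = 7)
}
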