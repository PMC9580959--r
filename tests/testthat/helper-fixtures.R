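# Shared fixtures, built in code.

# Render a pixel-integrated elliptical Gaussian directly from the closed
# form (independent of the package's renderer) on an n x n frame.
render_spot <- function(n, x0, y0, sx, sy, photons, background = 0) {
  xs <- 0:(n - 1)
  fx <- pnorm((xs + 0.5 - x0) / sx) - pnorm((xs - 0.5 - x0) / sx)
  fy <- pnorm((xs + 0.5 - y0) / sy) - pnorm((xs - 0.5 - y0) / sy)
  photons * outer(fy, fx) + background
}

# Poisson-noisy spot image with flat background, fixed seed.
noisy_spot <- function(n, x0, y0, sigma, photons, background = 10,
                      baseline = 100) {
  lambda <- render_spot(n, x0, y0, sigma, sigma, photons, background)
  matrix(rpois(n * n, lambda) + baseline, n, n)
}

# A small random cubic transform with visible but tame nonlinearity.
random_cubic_transform <- function(seed) {
  set.seed(seed)
  ax <- c(rnorm(4, 0, 1e-7), rnorm(2, 0, 1e-5), rnorm(1, 0, 1e-5),
          0.9 + rnorm(1, 0, 0.01), rnorm(1, 0, 0.01), rnorm(1, 0, 2))
  ay <- c(rnorm(4, 0, 1e-7), rnorm(2, 0, 1e-5), rnorm(1, 0, 1e-5),
          rnorm(1, 0, 0.01), 0.9 + rnorm(1, 0, 0.01), rnorm(1, 0, 2))
  field_transform(ax, ay)
}

# Greedy nearest-neighbour assignment cost (baseline for optimality tests).
greedy_cost <- function(cost) {
  total <- 0
  taken <- logical(ncol(cost))
  for (i in seq_len(nrow(cost))) {
    o <- order(cost[i, ])
    o <- o[!taken[o]]
    if (!length(o)) next
    total <- total + cost[i, o[1]]
    taken[o[1]] <- TRUE
  }
  total
}
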