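# Shared fixtures and independent reference implementations.

# Straightforward per-pixel HSI conversion used as an independent oracle for
# the vectorised layer: scalar arithmetic, explicit branching.
scalar_rgb_to_hsi <- function(R, G, B) {
  total <- R + G + B
  if (total <= 0) return(c(0, 0, 0))
  r <- R / total; g <- G / total; b <- B / total
  if (R == G && G == B) {
    h <- 0
  } else {
    num <- 0.5 * ((r - g) + (r - b))
    den <- sqrt(max((r - g)^2 + (r - b) * (g - b), 1e-24))
    arg <- num / den
    if (arg > 1) arg <- 1
    if (arg < -1) arg <- -1
    h <- acos(arg)
    if (b > g) h <- 2 * pi - h
  }
  s <- 1 - 3 * min(r, g, b)
  i <- total / (3 * 255)
  c(h * 180 / pi, s * 100, i * 255)
}

# One-pixel image helper.
pixel_image <- function(R, G, B) rgb_image(array(c(R, G, B), c(1, 1, 3)))

# A small configuration for fast end-to-end tests.
tiny_config <- function(seed = 0L, ...) {
  model_config(
    grid = 4L,
    efe = list(kernel_sizes = c(1L, 3L), channels_per_branch = 3L,
               mid_channels = 6L, out_channels = 6L, embed_dim = 4L),
    encoder = list(layers = 1L, width = 6L, n_heads = 2L,
                   aspp_rates = 1L, aspp_channels = 4L),
    decoder = list(fc_layers = 1L, dropout = 0),
    head = list(hidden = 12L, dropout = 0),
    seed = seed, ...
  )
}

random_preprocessed <- function(seed, side = 16L) {
  set.seed(seed)
  structure(array(stats::runif(side * side * 3), c(side, side, 3)),
            class = "preprocessed_image")
}

# Random probability vector.
random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}
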