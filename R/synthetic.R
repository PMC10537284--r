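# Synthetic food images with known latent nutrient vectors. Each "food" is
# an elliptical dish whose colour hue and sinusoidal texture frequency
# deterministically encode its nutrient fractions (the in-code linear rule
# below), composited over interchangeable background styles. Foreground
# appearance depends only on (food, seed), never on the background, so
# background-stability experiments are exact by construction.

#' Specify a synthetic food universe
#'
#' Builds the per-food palette (hue, texture frequency) and the nutrient map
#' tying appearance to composition: carbohydrate rises linearly with hue,
#' protein with texture frequency, fat with the food index; fiber and
#' minerals cycle at small positive levels; water is constant; the remainder
#' class absorbs the rest. All entries are strictly positive and the
#' food-to-nutrients map is injective.
#'
#' @param n_foods Number of distinct foods (>= 1).
#' @param image_size Native render side length in pixels.
#' @param backgrounds Background style pool, a subset of
#'   `c("solid", "gradient", "checker", "noise")`.
#' @param seed Integer seed folded into every render.
#' @return A list of class `synthetic_spec` with `palette` (tibble) and
#'   `nutrient_map` (matrix, foods x nutrient classes).
#' @export
synthetic_spec <- function(n_foods = 6L, image_size = 64L,
                           backgrounds = c("solid", "gradient", "checker", "noise"),
                           seed = 0L) {
  n_foods <- as.integer(n_foods)
  if (n_foods < 1L) config_error("n_foods must be at least 1")
  backgrounds <- match.arg(backgrounds, several.ok = TRUE)
  j <- seq_len(n_foods)
  hue <- (j - 1) * 360 / n_foods
  freq <- 2 + (j - 1)
  nm <- cbind(
    protein = 0.04 + 0.02 * freq,
    fat = 0.03 + 0.12 * (if (n_foods > 1) (j - 1) / (n_foods - 1) else 0),
    fiber = 0.01 + 0.02 * ((j - 1) %% 2),
    carbohydrate = 0.10 + 0.30 * hue / 360,
    minerals = 0.005 + 0.005 * (j %% 3),
    water = rep(0.25, n_foods)
  )
  nm <- cbind(nm, remainder = 1 - rowSums(nm))
  if (any(nm <= 0)) config_error("nutrient map left the simplex; reduce n_foods")
  rownames(nm) <- paste0("food_", j)
  structure(list(
    n_foods = n_foods,
    image_size = as.integer(image_size),
    backgrounds = backgrounds,
    seed = as.integer(seed),
    palette = tibble::tibble(food = j, name = rownames(nm), hue = hue, freq = freq),
    nutrient_map = nm
  ), class = "synthetic_spec")
}

# hue (degrees) -> RGB in [0,1] at full saturation, value v.
.hue_to_rgb <- function(hue, v = 0.85) {
  hp <- (hue %% 360) / 60
  x <- v * (1 - abs(hp %% 2 - 1))
  i <- floor(hp)
  rgb <- switch(as.character(i),
    "0" = c(v, x, 0), "1" = c(x, v, 0), "2" = c(0, v, x),
    "3" = c(0, x, v), "4" = c(x, 0, v), c(v, 0, x))
  rgb
}

.render_background <- function(style, size, rng_seed) {
  with_seed(rng_seed, {
    yy <- matrix(rep(seq_len(size), size), size)
    xx <- t(yy)
    img <- array(0, c(size, size, 3))
    if (style == "solid") {
      col <- stats::runif(3)
      for (c in 1:3) img[, , c] <- col[c]
    } else if (style == "gradient") {
      c1 <- stats::runif(3); c2 <- stats::runif(3)
      horiz <- stats::runif(1) < 0.5
      t_ <- (if (horiz) xx else yy) / size
      for (c in 1:3) img[, , c] <- c1[c] + (c2[c] - c1[c]) * t_
    } else if (style == "checker") {
      c1 <- stats::runif(3); c2 <- stats::runif(3)
      cell <- sample(4:12, 1)
      chk <- ((yy - 1) %/% cell + (xx - 1) %/% cell) %% 2
      for (c in 1:3) img[, , c] <- c1[c] * (1 - chk) + c2[c] * chk
    } else { # noise
      img <- array(stats::runif(size * size * 3), c(size, size, 3))
    }
    img
  })
}

.render_foreground <- function(spec, food, rng_seed) {
  size <- spec$image_size
  with_seed(rng_seed, {
    cx <- size / 2 + stats::runif(1, -0.1, 0.1) * size
    cy <- size / 2 + stats::runif(1, -0.1, 0.1) * size
    rx <- stats::runif(1, 0.26, 0.38) * size
    ry <- stats::runif(1, 0.26, 0.38) * size
    phase <- stats::runif(1, 0, 2 * pi)
    yy <- matrix(rep(seq_len(size), size), size)
    xx <- t(yy)
    mask <- ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
    hue <- spec$palette$hue[food]
    freq <- spec$palette$freq[food]
    base <- .hue_to_rgb(hue)
    tex <- 0.75 + 0.25 * sin(2 * pi * freq * (xx + yy) / (2 * size) + phase)
    fg <- array(0, c(size, size, 3))
    for (c in 1:3) fg[, , c] <- base[c] * tex
    list(fg = fg, mask = mask)
  })
}

#' Render one synthetic food sample
#'
#' Deterministic per `(spec, food, background_id, seed)`: the foreground dish
#' (position, size, texture phase) depends only on `(food, seed)`, and the
#' background only on `(background_id, seed)`.
#'
#' @param spec A [synthetic_spec()].
#' @param food Food index in `1:n_foods`.
#' @param background_id Index into the background style pool.
#' @param seed Per-sample seed.
#' @return A list: `image` (`rgb_image`), `label` (food index), `nutrients`
#'   (named vector), `background_id`, `mask` (logical foreground mask).
#' @export
generate_sample <- function(spec, food, background_id, seed = 0L) {
  if (food < 1L || food > spec$n_foods)
    .nn_error(sprintf("food index %d out of 1..%d", food, spec$n_foods), "nutrinet_index_error")
  if (background_id < 1L || background_id > length(spec$backgrounds))
    .nn_error(sprintf("background_id %d out of 1..%d", background_id,
                      length(spec$backgrounds)), "nutrinet_index_error")
  fgr <- .render_foreground(spec, food, derive_seed(spec$seed, "fg", food, seed))
  bg <- .render_background(spec$backgrounds[background_id], spec$image_size,
                           derive_seed(spec$seed, "bg", background_id, seed))
  img <- bg
  for (c in 1:3) {
    plane <- img[, , c]
    plane[fgr$mask] <- fgr$fg[, , c][fgr$mask]
    img[, , c] <- plane
  }
  list(
    image = rgb_image(round(img * 255)),
    label = as.integer(food),
    nutrients = stats::setNames(spec$nutrient_map[food, ], colnames(spec$nutrient_map)),
    background_id = as.integer(background_id),
    mask = fgr$mask
  )
}

#' Generate a synthetic dataset
#'
#' Draws foods and backgrounds uniformly, derives per-sample seeds from the
#' master seed, and (optionally) renders the images and writes them with a
#' CSV manifest and the nutrient table.
#'
#' @param spec A [synthetic_spec()].
#' @param n_samples Number of samples (>= 1).
#' @param seed Master seed for the draws.
#' @param dir Optional output directory; when given, PNG images,
#'   `manifest.csv` and `nutrient_table.csv` are written there.
#' @param render If `FALSE`, only the manifest (labels and backgrounds) is
#'   produced — useful for checking label statistics cheaply.
#' @return A list of class `synthetic_dataset`: `samples` (list, empty if
#'   `render = FALSE`), `manifest` (tibble: `image_path`, `label`,
#'   `background_id`), `nutrient_table` (tibble in the composition-table
#'   format), and `spec`.
#' @export
generate_dataset <- function(spec, n_samples, seed = 0L, dir = NULL, render = TRUE) {
  if (n_samples < 1L) config_error("n_samples must be at least 1")
  draws <- with_seed(derive_seed(seed, "draws"), {
    list(food = sample.int(spec$n_foods, n_samples, replace = TRUE),
         bg = sample.int(length(spec$backgrounds), n_samples, replace = TRUE))
  })
  paths <- sprintf("sample_%05d.png", seq_len(n_samples))
  manifest <- tibble::tibble(image_path = paths, label = draws$food,
                             background_id = draws$bg)
  samples <- list()
  if (render) {
    samples <- lapply(seq_len(n_samples), function(i)
      generate_sample(spec, draws$food[i], draws$bg[i], derive_seed(seed, "s", i)))
  }
  nt <- nutrient_map_table(spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      io_error(sprintf("cannot create output directory '%s'", dir))
    if (render) {
      for (i in seq_along(samples))
        write_image(samples[[i]]$image, file.path(dir, paths[i]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(nt, file.path(dir, "nutrient_table.csv"), row.names = FALSE)
  }
  structure(list(samples = samples, manifest = manifest,
                 nutrient_table = nt, spec = spec),
            class = "synthetic_dataset")
}

#' The spec's nutrient map in composition-table form
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with a `food` column and the tracked nutrient columns in
#'   percent units (remainder omitted, as in published tables).
#' @export
nutrient_map_table <- function(spec) {
  nm <- spec$nutrient_map
  tracked <- setdiff(colnames(nm), "remainder")
  out <- tibble::tibble(food = rownames(nm))
  for (cc in tracked) out[[cc]] <- 100 * nm[, cc]
  out
}

#' Load a dataset previously written to disk
#'
#' @param dir Directory holding `manifest.csv`, `nutrient_table.csv` and the
#'   PNG images.
#' @return A list with `samples` (images decoded, nutrients joined from the
#'   table) and `manifest`.
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) io_error(sprintf("no manifest.csv under '%s'", dir))
  manifest <- tibble::as_tibble(utils::read.csv(mf, stringsAsFactors = FALSE))
  table <- load_nutrient_table(file.path(dir, "nutrient_table.csv"))
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- load_image(file.path(dir, manifest$image_path[i]))
    lab <- manifest$label[i]
    list(image = img, label = lab,
         nutrients = map_label(lab, stats::setNames(as.list(table$food),
                                                    seq_len(nrow(table))), table),
         background_id = manifest$background_id[i])
  })
  list(samples = samples, manifest = manifest, nutrient_table = table)
}

#' Generate same-foreground / different-background pairs
#'
#' For the background-stability ablation: each pair shares one foreground
#' render (same food, position, texture) over two distinct background
#' styles.
#'
#' @param spec A [synthetic_spec()] with at least two background styles.
#' @param food Food index used for every pair.
#' @param n_pairs Number of pairs.
#' @param seed Master seed.
#' @return A flat list of `2 * n_pairs` samples, each carrying a `pair_id`.
#' @export
generate_background_pairs <- function(spec, food, n_pairs, seed = 0L) {
  if (length(spec$backgrounds) < 2L)
    config_error("background pairs need at least two background styles")
  out <- list()
  for (p in seq_len(n_pairs)) {
    bgs <- with_seed(derive_seed(seed, "pairbg", p),
                     sample.int(length(spec$backgrounds), 2L))
    fg_seed <- derive_seed(seed, "pairfg", p)
    for (b in bgs) {
      s <- generate_sample(spec, food, b, fg_seed)
      s$pair_id <- p
      out[[length(out) + 1L]] <- s
    }
  }
  out
}
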