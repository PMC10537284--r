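#' Convert an RGB image to the HSI colour space
#'
#' Converts per pixel via the chromaticity form: with
#' \eqn{r = R/(R+G+B)} (and likewise \eqn{g, b}), the hue angle is
#' \deqn{h = \cos^{-1}\frac{0.5[(r-g)+(r-b)]}{\sqrt{(r-g)^2+(r-b)(g-b)}}}
#' for \eqn{b \le g}, and \eqn{h = 2\pi - \cos^{-1}(\cdot)} for \eqn{b > g};
#' saturation is \eqn{s = 1 - 3\min(r,g,b)} and intensity
#' \eqn{i = (R+G+B)/(3\cdot 255)}. Outputs are rescaled to
#' \eqn{H = h \cdot 180/\pi \in [0,360)}, \eqn{S = 100 s \in [0,100]},
#' \eqn{I = 255 i \in [0,255]}.
#'
#' Conventions for degenerate pixels: achromatic pixels (R = G = B) take
#' H = 0 (S = 0 already marks them); a black pixel maps to (0, 0, 0). The
#' arccos argument is clamped to \eqn{[-1, 1]} and the squared denominator is
#' floored at 1e-24 before the square root, so the conversion is finite
#' everywhere and exact away from degeneracy.
#'
#' @param img An `rgb_image` (`[0, 255]`), a `preprocessed_image` (`[0, 1]`),
#'   or any `H x W x 3` array; unit-scale inputs are detected by their range.
#' @param max_value The white level of the input, or `NULL` to infer it
#'   (255 unless all values are at most 1).
#' @return An `H x W x 3` array of class `hsi_image`; planes are H, S, I.
#' @examples
#' hsi <- rgb_to_hsi(rgb_image(array(c(255, 0, 0), c(1, 1, 3))))
#' hsi[1, 1, ]  # 0 100 85
#' @export
rgb_to_hsi <- function(img, max_value = NULL) {
  x <- unclass(img)
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    validation_error("rgb_to_hsi() expects an H x W x 3 array")
  if (is.null(max_value)) max_value <- if (max(x) <= 1) 1 else 255
  x <- x / max_value * 255
  R <- x[, , 1]; G <- x[, , 2]; B <- x[, , 3]
  total <- R + G + B
  black <- total <= 0
  safe_total <- ifelse(black, 1, total)
  r <- R / safe_total; g <- G / safe_total; b <- B / safe_total
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt(pmax((r - g)^2 + (r - b) * (g - b), 1e-24))
  h <- acos(clamp(num / den, -1, 1))
  h <- ifelse(b > g, 2 * pi - h, h)
  achrom <- (R == G) & (G == B)
  h[achrom | black] <- 0
  s <- 1 - 3 * pmin(r, g, b)
  s[black] <- 0
  i <- total / (3 * 255)
  out <- array(c(h * 180 / pi, s * 100, i * 255), dim(x))
  out[, , 1][out[, , 1] >= 360] <- 0   # numerical wrap guard
  structure(out, class = "hsi_image")
}

# HSI planes rescaled to a common [0, 1] range for use as network input.
hsi_unit_scale <- function(hsi) {
  x <- unclass(hsi)
  x[, , 1] <- x[, , 1] / 360
  x[, , 2] <- x[, , 2] / 100
  x[, , 3] <- x[, , 3] / 255
  x
}
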