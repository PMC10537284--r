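#' Read a food photograph from disk
#'
#' Decodes a PNG or JPEG file into an integer RGB array. Greyscale images are
#' replicated to three channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a PNG or JPEG file.
#' @return An `H x W x 3` integer array with channel values in `[0, 255]`.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(0, c(2, 2, 3)), f)
#' img <- load_image(f)
#' dim(img)
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    decode_error(sprintf("image file not found: %s", paste(path, collapse = ", ")))
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    {
      if (ext == "png") png::readPNG(path)
      else EBImage::imageData(EBImage::transpose(EBImage::readImage(path)))
    },
    error = function(e) decode_error(sprintf("cannot decode '%s': %s", path, conditionMessage(e)))
  )
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  nc <- dim(px)[3]
  if (nc == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (nc %in% c(2L, 4L)) px <- px[, , seq_len(nc - 1L), drop = FALSE]  # drop alpha
  if (dim(px)[3] == 2L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3] != 3L)
    decode_error(sprintf("expected 1-4 channels, found %d in '%s'", nc, path))
  rgb_image(round(px * 255))
}

#' Construct and validate an RGB image
#'
#' @param pixels `H x W x 3` numeric array with values in `[0, 255]`.
#' @return The validated array with class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    validation_error("an RGB image must be an H x W x 3 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    validation_error("RGB channel values must lie in [0, 255]")
  structure(pixels, class = c("rgb_image", class(pixels)))
}

#' Resize and rescale an image to the model input form
#'
#' Bilinearly resizes any RGB image to `size x size` and maps pixel values
#' from `[0, 255]` to `[0, 1]`.
#'
#' @param img An `rgb_image` or any `H x W x 3` array in `[0, 255]`.
#' @param size Output side length in pixels (default 224).
#' @return A `size x size x 3` array in `[0, 1]` with class `preprocessed_image`.
#' @export
preprocess <- function(img, size = 224L) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    validation_error("preprocess() expects an H x W x 3 array")
  out <- resize_bilinear(unclass(img), size, size) / 255
  structure(clamp(out, 0, 1), class = "preprocessed_image")
}

#' Augmentation parameters
#'
#' @param p_flip Probability of a horizontal flip.
#' @param max_deg Rotation bound in degrees; the angle is uniform in
#'   `[-max_deg, max_deg]`.
#' @param crop_frac Area fraction retained by the random crop, in `(0, 1]`.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(p_flip = 0.5, max_deg = 15, crop_frac = 0.875) {
  if (!is.numeric(crop_frac) || crop_frac <= 0 || crop_frac > 1)
    config_error("crop_frac must lie in (0, 1]")
  if (p_flip < 0 || p_flip > 1) config_error("p_flip must lie in [0, 1]")
  if (max_deg < 0) config_error("max_deg must be nonnegative")
  structure(list(p_flip = p_flip, max_deg = max_deg, crop_frac = crop_frac),
            class = "augment_config")
}

#' Randomly augment a preprocessed image
#'
#' Applies, in order, a horizontal flip (with probability `p_flip`), a
#' rotation by a uniform angle in `[-max_deg, max_deg]` with reflect fill for
#' out-of-frame pixels, and a random crop to `crop_frac` of the area resized
#' back to the input size. Deterministic for a fixed seed.
#'
#' @param img A `preprocessed_image` (values in `[0, 1]`).
#' @param seed Integer seed controlling all random draws.
#' @param params An [augment_config()].
#' @return A `preprocessed_image` of the same size.
#' @export
augment <- function(img, seed, params = augment_config()) {
  if (!inherits(params, "augment_config")) params <- do.call(augment_config, params)
  x <- unclass(img)
  h <- dim(x)[1]; w <- dim(x)[2]
  with_seed(seed, {
    if (stats::runif(1) < params$p_flip) x <- x[, w:1, , drop = FALSE]
    ang <- stats::runif(1, -params$max_deg, params$max_deg)
    if (abs(ang) > 1e-12) x <- .rotate_reflect(x, ang)
    if (params$crop_frac < 1) {
      side_frac <- sqrt(params$crop_frac)
      ch <- max(1L, round(h * side_frac)); cw <- max(1L, round(w * side_frac))
      oy <- sample.int(h - ch + 1L, 1L); ox <- sample.int(w - cw + 1L, 1L)
      x <- x[oy:(oy + ch - 1L), ox:(ox + cw - 1L), , drop = FALSE]
      x <- resize_bilinear(x, h, w)
    }
  })
  structure(clamp(x, 0, 1), class = "preprocessed_image")
}

# Rotate about the image centre by `deg` degrees, sampling with reflect
# padding so no artificial background is injected.
.rotate_reflect <- function(x, deg) {
  h <- dim(x)[1]; w <- dim(x)[2]
  th <- deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- rep(seq_len(h), times = w) - cy
  xx <- rep(seq_len(w), each = h) - cx
  # inverse rotation of output coordinates into the source frame
  sy <- cos(th) * yy - sin(th) * xx + cy
  sx <- sin(th) * yy + cos(th) * xx + cx
  out <- sample_bilinear_reflect(x, sy, sx)
  array(out, dim(x))
}

#' Write an RGB image to a PNG file
#'
#' @param img An `rgb_image` (values `[0, 255]`) or `preprocessed_image`
#'   (values `[0, 1]`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  x <- unclass(img)
  if (max(x) > 1) x <- x / 255
  png::writePNG(clamp(x, 0, 1), path)
  invisible(path)
}
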