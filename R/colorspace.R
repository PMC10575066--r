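#' Image tensors in a declared color space
#'
#' An `image_tensor` is an `H x W x 3` array of real values in `[0, 1]`
#' tagged with the color space it lives in (`"rgb"` or `"hsv"`).  All images
#' inside the package are unit-range reals; 8-bit quantization only happens
#' at file I/O.  In HSV images the hue channel is stored as a fraction of a
#' full turn (degrees/360), so that all three channels share the `[0, 1]`
#' scale expected by the networks.
#'
#' @param pixels numeric `H x W x 3` array with values in `[0, 1]`.
#' @param space `"rgb"` or `"hsv"`.
#' @return An `image_tensor` object.
#' @examples
#' img <- image_tensor(array(runif(12), c(2, 2, 3)), "rgb")
#' image_space(img)
#' @export
image_tensor <- function(pixels, space = c("rgb", "hsv")) {
  space <- match.arg(tolower(space), c("rgb", "hsv"))
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop_input("`pixels` must be an H x W x 3 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop_input("pixel values must lie in [0, 1]")
  structure(pixels, space = space, class = "image_tensor")
}

#' @rdname image_tensor
#' @param x an `image_tensor`.
#' @export
image_space <- function(x) {
  sp <- attr(x, "space")
  if (is.null(sp)) stop_input("object carries no color-space tag")
  sp
}

#' @export
print.image_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_tensor> %d x %d, space = %s, range [%.4f, %.4f]\n",
              d[1], d[2], image_space(x), min(x), max(x)))
  invisible(x)
}

#' Normalize an integer image to the unit range
#'
#' Divides every raw pixel value by the highest representable value
#' (255 for 8-bit input), producing a unit-range RGB [image_tensor].
#'
#' @param raw integer-valued `H x W x 3` array with entries in
#'   `[0, max_value]`.
#' @param max_value the maximum representable raw value (default 255).
#' @return An RGB [image_tensor] with `pixels = raw / max_value`.
#' @examples
#' raw <- array(c(0L, 51L, 255L), c(1, 1, 3))
#' normalize_image(raw)[1, 1, ]
#' @export
normalize_image <- function(raw, max_value = 255) {
  if (!is_count(max_value, min = 1)) stop_input("`max_value` must be a positive integer")
  if (!is.array(raw) || length(dim(raw)) != 3 || dim(raw)[3] != 3)
    stop_input("`raw` must be an H x W x 3 array")
  if (anyNA(raw) || min(raw) < 0 || max(raw) > max_value)
    stop_input("raw pixel values must lie in [0, ", max_value, "]")
  image_tensor(raw / max_value, "rgb")
}

#' Convert between the RGB and HSV color spaces
#'
#' Exact hexcone conversion, vectorized over all pixels.  Hue is returned as
#' a turn-fraction in `[0, 1)`; for achromatic pixels (saturation 0) hue is
#' fixed at 0 by convention.  Value equals the channel-wise maximum of the
#' RGB pixel, exactly.  `hsv_to_rgb()` inverts the mapping; the round trip
#' is the identity to numerical tolerance.
#'
#' @param img an [image_tensor] in the source space (`rgb_to_hsv()` requires
#'   an RGB image, `hsv_to_rgb()` an HSV one; a wrong tag is an error).
#' @return An [image_tensor] in the target space.
#' @examples
#' red <- image_tensor(array(c(1, 0, 0), c(1, 1, 3)), "rgb")
#' rgb_to_hsv(red)[1, 1, ]   # (0, 1, 1)
#' @export
rgb_to_hsv <- function(img) {
  if (image_space(img) != "rgb")
    stop_input("rgb_to_hsv() expects an RGB image, got space = ", image_space(img))
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  v <- mx
  s <- ifelse(mx > 0, d / mx, 0)
  safe <- ifelse(d > 0, d, 1)          # avoid 0/0; overwritten below
  h <- ifelse(mx == r, ((g - b) / safe) %% 6,
       ifelse(mx == g, (b - r) / safe + 2,
                       (r - g) / safe + 4)) / 6
  h <- ifelse(d > 0, h %% 1, 0)
  out <- array(c(h, s, v), dim(img))
  image_tensor(out, "hsv")
}

#' @rdname rgb_to_hsv
#' @examples
#' hsv_to_rgb(rgb_to_hsv(red))[1, 1, ]   # back to (1, 0, 0)
#' @export
hsv_to_rgb <- function(img) {
  if (image_space(img) != "hsv")
    stop_input("hsv_to_rgb() expects an HSV image, got space = ", image_space(img))
  h <- img[, , 1]; s <- img[, , 2]; v <- img[, , 3]
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(c(r, g, b), dim(img))
  image_tensor(clamp01(out), "rgb")
}
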