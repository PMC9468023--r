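#' Rescale intensities linearly to [0, 1]
#'
#' @param image numeric matrix or [labeled_image()].
#' @return object of the same kind with pixels spanning `[0, 1]`; a constant
#'   input yields all zeros with a warning.
#' @export
normalize_intensity <- function(image) {
  px <- if (inherits(image, "labeled_image")) image$pixels else image
  stopifnot(all(is.finite(px)))
  rng <- range(px)
  if (diff(rng) == 0) {
    warning("constant image: normalized to all zeros")
    out <- matrix(0, nrow(px), ncol(px))
  } else {
    out <- (px - rng[1]) / diff(rng)
  }
  if (inherits(image, "labeled_image")) {
    image$pixels <- out
    image
  } else out
}

# nonflat structuring element: offsets within a disc of the given radius,
# with heights normalized so the sag at the rim equals `sag` intensity units
structuring_element <- function(radius, shape = c("ball", "paraboloid"),
                                sag = 0.1) {
  shape <- match.arg(shape)
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- g$dy^2 + g$dx^2
  keep <- d2 <= radius^2
  g <- g[keep, , drop = FALSE]
  d2 <- d2[keep]
  h <- switch(shape,
              ball = sag * (sqrt(pmax(radius^2 - d2, 0)) - radius) / radius,
              paraboloid = -sag * d2 / radius^2)
  list(dy = as.integer(g$dy), dx = as.integer(g$dx), h = h)
}

#' Rolling-ball / sliding-paraboloid background removal
#'
#' Estimates a local background for every pixel as the grayscale
#' morphological opening of the image by a ball (spherical cap) or
#' paraboloid structuring element of the given radius, and subtracts it.
#' The radius should be at least the size of the largest object that is not
#' part of the background.  Wherever no clipping occurred,
#' `corrected + background` reconstructs the input.
#'
#' @param image numeric matrix or [labeled_image()], finite values.
#' @param radius element radius in pixels (>= 1).
#' @param element `"ball"` (default) or `"paraboloid"`.
#' @param sag element depth at the rim, in intensity units; smaller values
#'   approach a flat-disc opening.
#' @return list with `background` and `corrected` rasters (`corrected`
#'   clipped at 0).
#' @export
rolling_ball_background <- function(image, radius = 50,
                                    element = c("ball", "paraboloid"),
                                    sag = 0.1) {
  px <- if (inherits(image, "labeled_image")) image$pixels else image
  if (!all(is.finite(px))) stop("non-finite pixel values")
  stopifnot(radius >= 1)
  if (radius > min(dim(px)) / 2)
    warning("radius exceeds half the smallest image dimension")
  se <- structuring_element(radius, match.arg(element), sag)
  eroded <- cpp_gray_morph_nf(px, se$dy, se$dx, se$h, TRUE)
  background <- cpp_gray_morph_nf(eroded, se$dy, se$dx, se$h, FALSE)
  list(background = background, corrected = pmax(px - background, 0))
}

#' Apply background removal and normalization to a labeled image
#'
#' Convenience stage used by the pipeline: rolling-ball correction followed
#' by linear intensity normalization.
#'
#' @inheritParams rolling_ball_background
#' @return the input [labeled_image()] with corrected, normalized pixels.
#' @export
preprocess_image <- function(image, radius = 50,
                             element = c("ball", "paraboloid"), sag = 0.1) {
  stopifnot(inherits(image, "labeled_image"))
  rb <- rolling_ball_background(image, radius, match.arg(element), sag)
  rng <- range(rb$corrected)
  image$pixels <- if (diff(rng) == 0) matrix(0, image$height, image$width) else
    (rb$corrected - rng[1]) / diff(rng)
  image
}
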