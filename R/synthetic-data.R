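#' Specification of a synthetic texture class
#'
#' Describes one synthetic droplet-deposit texture class.  The three
#' connectivity modes span the particle-scattering / particle-connectivity
#' axis seen in dried-droplet micrographs: isolated scattered particles,
#' branched diffusion-limited aggregates, and dilated random-walk skeletons.
#' `target_dimension` controls the realized local fractality of the texture
#' (via structure thickness and branching), so that classes generated with
#' different targets rank-order consistently under LCFD analysis.
#'
#' @param class_name label attached to generated images.
#' @param target_dimension nominal fractal dimension in (0, 2].
#' @param particle_density fraction of foreground pixels aimed for, in (0, 1).
#' @param connectivity_mode one of `"dla_aggregate"`, `"scattered_points"`,
#'   `"dilated_skeleton"`.
#' @param glare_count number of smooth glare blobs added to the background.
#' @param blank_margin_px width of the texture-free margin, in pixels.
#' @return an object of class `texture_class_spec`.
#' @export
texture_class_spec <- function(class_name, target_dimension, particle_density,
                               connectivity_mode = c("dla_aggregate",
                                                     "scattered_points",
                                                     "dilated_skeleton"),
                               glare_count = 2L, blank_margin_px = 0L) {
  connectivity_mode <- match.arg(connectivity_mode)
  stopifnot(is.character(class_name), length(class_name) == 1L,
            target_dimension > 0, target_dimension <= 2,
            particle_density > 0, particle_density < 1,
            glare_count >= 0, blank_margin_px >= 0)
  structure(list(class_name = class_name,
                 target_dimension = target_dimension,
                 particle_density = particle_density,
                 connectivity_mode = connectivity_mode,
                 glare_count = as.integer(glare_count),
                 blank_margin_px = as.integer(blank_margin_px)),
            class = "texture_class_spec")
}

#' Default three-class study specification
#'
#' Three texture classes with well-separated fractality (nominal local
#' dimensions 1.2, 1.5 and 1.8), emulating the scattered / intermediate /
#' connected deposit morphologies of dried-droplet preparations.
#'
#' @return list of three [texture_class_spec()] objects.
#' @export
default_texture_specs <- function() {
  list(texture_class_spec("low",  1.2, 0.025, "dilated_skeleton",
                          glare_count = 2L),
       texture_class_spec("mid",  1.5, 0.05, "dla_aggregate",
                          glare_count = 2L),
       texture_class_spec("high", 1.8, 0.45, "dilated_skeleton",
                          glare_count = 2L))
}

#' Grow a diffusion-limited aggregate
#'
#' Launches random walkers towards a seeded central pixel; a walker freezes
#' with probability `stickiness` when it becomes 8-connected to the
#' aggregate.  Growth stops early if the aggregate reaches the image border,
#' in which case the actual particle count is reported in attribute
#' `"particles"`.
#'
#' @param size image side in pixels (>= 64).
#' @param n_particles number of particles to attach (>= 1).
#' @param stickiness attachment probability in (0, 1].
#' @param seed integer seed; identical inputs give bit-identical output.
#' @return logical `size x size` matrix with attribute `particles`.
#' @export
generate_dla_texture <- function(size, n_particles, stickiness = 1, seed = 1) {
  stopifnot(size >= 64, n_particles >= 1, stickiness > 0, stickiness <= 1)
  set.seed(seed)
  g <- cpp_dla_grow(as.integer(size), as.integer(n_particles), stickiness)
  out <- g > 0L
  attr(out, "particles") <- attr(g, "particles")
  if (attr(g, "particles") < n_particles)
    warning("aggregate reached the border after ",
            attr(g, "particles"), " of ", n_particles, " particles")
  out
}

#' Sierpinski carpet
#'
#' Standard Sierpinski carpet at a given recursion level; an analytic
#' fixture with known fractal dimension log(8)/log(3).
#'
#' @param level recursion depth, integer in `[1, 6]`.
#' @return logical `3^level x 3^level` matrix.
#' @export
generate_sierpinski_carpet <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || level != round(level) ||
      level < 1 || level > 6)
    stop("`level` must be an integer in [1, 6]")
  base <- matrix(1L, 3L, 3L)
  base[2L, 2L] <- 0L
  m <- base
  for (k in seq_len(level - 1L)) m <- kronecker(m, base)
  m > 0L
}

# scattered particle field: small discs placed uniformly; dot radius grows
# mildly with target dimension
scattered_texture <- function(size, density, dot_radius = 1L) {
  area <- (2L * dot_radius + 1L)^2 * pi / 4
  n_dots <- max(1L, round(density * size^2 / area))
  out <- matrix(FALSE, size, size)
  ci <- sample.int(size, n_dots, replace = TRUE)
  cj <- sample.int(size, n_dots, replace = TRUE)
  off <- expand.grid(a = -dot_radius:dot_radius, b = -dot_radius:dot_radius)
  off <- off[off$a^2 + off$b^2 <= dot_radius^2 + 0.5, , drop = FALSE]
  for (k in seq_len(nrow(off))) {
    ii <- ci + off$a[k]
    jj <- cj + off$b[k]
    ok <- ii >= 1L & ii <= size & jj >= 1L & jj <= size
    out[cbind(ii[ok], jj[ok])] <- TRUE
  }
  out
}

# random-walk skeleton paths rasterized as pixels; walks wrap around the
# image torus so coverage is spatially stationary (no centre/edge bias)
skeleton_texture <- function(size, density) {
  out <- matrix(FALSE, size, size)
  target <- density * size^2
  drawn <- 0
  while (drawn < target) {
    i <- sample.int(size, 1L)
    j <- sample.int(size, 1L)
    len <- round(stats::runif(1, 0.5, 1.5) * size)
    # persistent random walk: heading changes slowly so paths look filament-like
    ang <- stats::runif(1, 0, 2 * pi)
    for (s in seq_len(len)) {
      ang <- ang + stats::rnorm(1, 0, 0.35)
      i <- ((i + round(sin(ang)) - 1L) %% size) + 1L
      j <- ((j + round(cos(ang)) - 1L) %% size) + 1L
      if (!out[i, j]) {
        out[i, j] <- TRUE
        drawn <- drawn + 1
      }
    }
  }
  out
}

# binary dilation by a disc of radius r (r = 0 is a no-op)
dilate_disc <- function(mask, r) {
  if (r <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0
}

#' Generate one class texture
#'
#' Renders the binary texture for a class specification.  Structure
#' thickness is derived from `target_dimension`: thicker, more connected
#' structures realize higher local fractal dimension.
#'
#' @param spec a [texture_class_spec()].
#' @param size image side in pixels.
#' @param seed integer seed.
#' @return logical `size x size` matrix.
#' @export
generate_class_texture <- function(spec, size, seed = 1) {
  stopifnot(inherits(spec, "texture_class_spec"))
  set.seed(seed)
  mask <- switch(spec$connectivity_mode,
    scattered_points = {
      dot_radius <- max(1L, round(spec$target_dimension))
      scattered_texture(size, spec$particle_density, dot_radius)
    },
    dilated_skeleton = {
      # thin filament tangles; realized local dimension grows with path
      # density and thickness, which only enters above ~1.3
      thick <- min(2L, max(0L, round((spec$target_dimension - 1.3) * 5)))
      # empirical overlap factor: realized foreground after disc dilation
      # per drawn skeleton pixel
      f <- c(1, 3.3, 4.7)[thick + 1L]
      dilate_disc(skeleton_texture(size, spec$particle_density / f), thick)
    },
    dla_aggregate = {
      # several aggregates on a jittered grid so texture covers the image;
      # branch thickness (disc dilation) raises the local dimension from
      # ~1.5 (thin arms at patch scale) towards 2
      thick <- min(2L, max(0L, round((spec$target_dimension - 1.55) * 8)))
      tile <- 120L
      k <- max(2L, round(size / 80))
      mult <- c(1, 4, 5.2)[thick + 1L]
      per <- round(spec$particle_density * size^2 / (k^2 * mult))
      out <- matrix(FALSE, size, size)
      centers <- seq(0L, k - 1L) * floor(size / k) + floor(size / (2L * k))
      for (a in centers) for (b in centers) {
        agg <- cpp_dla_grow(tile, as.integer(max(per, 50L)), 1.0) > 0L
        ji <- a - tile %/% 2L + round(stats::runif(1, -8, 8))
        jj <- b - tile %/% 2L + round(stats::runif(1, -8, 8))
        ii <- which(agg, arr.ind = TRUE)
        gi <- ii[, 1L] + ji
        gj <- ii[, 2L] + jj
        ok <- gi >= 1L & gi <= size & gj >= 1L & gj <= size
        out[cbind(gi[ok], gj[ok])] <- TRUE
      }
      dilate_disc(out, thick)
    })
  if (spec$blank_margin_px > 0L) {
    m <- spec$blank_margin_px
    if (2L * m >= size) stop("blank_margin_px incompatible with image size")
    mask[c(seq_len(m), (size - m + 1L):size), ] <- FALSE
    mask[, c(seq_len(m), (size - m + 1L):size)] <- FALSE
  }
  mask
}

# smooth additive background: tilted paraboloid, plus Gaussian glare blobs
background_field <- function(size, amplitude, glare_count) {
  if (amplitude <= 0 && glare_count == 0L) return(matrix(0, size, size))
  u <- (seq_len(size) - stats::runif(1, 0.3, 0.7) * size) / size
  v <- (seq_len(size) - stats::runif(1, 0.3, 0.7) * size) / size
  bg <- amplitude * (outer(u^2, rep(1, size)) + outer(rep(1, size), v^2)) +
    amplitude * 0.5 * (outer(u, rep(1, size)) + outer(rep(1, size), v))
  bg <- bg - min(bg)
  for (g in seq_len(glare_count)) {
    ci <- stats::runif(1, 0.15, 0.85) * size
    cj <- stats::runif(1, 0.15, 0.85) * size
    sg <- stats::runif(1, size / 12, size / 7)
    bg <- bg + 0.3 *
      exp(-(outer((seq_len(size) - ci)^2, rep(1, size)) +
              outer(rep(1, size), (seq_len(size) - cj)^2)) / (2 * sg^2))
  }
  bg
}

#' Labeled grayscale image
#'
#' @param pixels numeric matrix with finite values in `[0, 1]`.
#' @param image_id identifier string.
#' @param class_label source-class label.
#' @return object of class `labeled_image`.
#' @export
labeled_image <- function(pixels, image_id, class_label = NA_character_) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            min(pixels) >= 0, max(pixels) <= 1)
  structure(list(pixels = pixels, image_id = as.character(image_id),
                 class_label = as.character(class_label),
                 height = nrow(pixels), width = ncol(pixels)),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image %s  %dx%d  class=%s>\n",
              x$image_id, x$height, x$width, x$class_label))
  invisible(x)
}

#' Generate a labeled synthetic image set
#'
#' Each image is composed as class texture (foreground intensity 1) plus a
#' smooth additive background (tilted paraboloid and glare blobs) plus
#' pixel noise, clipped to `[0, 1]`.  With `background_amplitude = 0`,
#' `noise_sd = 0`, no glare and no margin, the image equals the pure binary
#' texture.  All randomness derives from `seed` through a counter-based
#' per-image stream split, so output is bit-identical for identical inputs.
#'
#' @param specs list of [texture_class_spec()]; at least two distinct classes.
#' @param n_per_class images generated per class.
#' @param size image side in pixels.
#' @param seed integer seed.
#' @param background_amplitude peak amplitude of the smooth background.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param blur_sigma Gaussian blur applied to the composed texture before
#'   noise, emulating the microscope point-spread function; `0` disables
#'   blurring (the texture then stays binary).
#' @return list of [labeled_image()] objects, `n_per_class` per class.
#' @export
generate_image_set <- function(specs, n_per_class, size = 320L, seed = 1,
                               background_amplitude = 0.25, noise_sd = 0.02,
                               blur_sigma = 2) {
  stopifnot(length(specs) >= 2L, n_per_class >= 1L)
  stopifnot(length(unique(vapply(specs, `[[`, "", "class_name"))) ==
              length(specs))
  images <- list()
  for (spec in specs) {
    if (2L * spec$blank_margin_px >= size)
      stop("blank_margin_px incompatible with image size")
    for (i in seq_len(n_per_class)) {
      s_img <- derive_seed(seed, spec$class_name, i)
      tex <- generate_class_texture(spec, size, seed = s_img)
      set.seed(derive_seed(seed, spec$class_name, i, "bg"))
      bg <- background_field(size, background_amplitude, spec$glare_count)
      fg <- matrix(as.numeric(tex), size, size)
      if (blur_sigma > 0)
        fg <- EBImage::imageData(EBImage::gblur(EBImage::Image(fg),
                                                blur_sigma))
      px <- fg + bg
      if (noise_sd > 0) px <- px + stats::rnorm(length(px), 0, noise_sd)
      px <- matrix(clamp01(px), size, size)
      images[[length(images) + 1L]] <-
        labeled_image(px, sprintf("%s_%03d", spec$class_name, i),
                      spec$class_name)
    }
  }
  images
}

#' Write an image set as 8-bit PNGs with a manifest
#'
#' @param images list of [labeled_image()].
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_image_set <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(image_id = vapply(images, `[[`, "", "image_id"),
                    class_name = vapply(images, `[[`, "", "class_label"),
                    height = vapply(images, `[[`, 1L, "height"),
                    width = vapply(images, `[[`, 1L, "width"),
                    file = paste0(vapply(images, `[[`, "", "image_id"), ".png"))
  for (img in images)
    EBImage::writeImage(EBImage::Image(t(img$pixels)),
                        file.path(dir, paste0(img$image_id, ".png")),
                        type = "png", bits.per.sample = 8L)
  write.table(man, file.path(dir, "images_manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(man)
}

#' Read a grayscale image from disk as a labeled image
#'
#' Accepts PNG/TIFF/JPEG; color input is converted to luminance, and
#' intensities are mapped into `[0, 1]`.
#'
#' @param path image file path.
#' @param class_label source-class label to attach.
#' @param image_id identifier; defaults to the file name without extension.
#' @return a [labeled_image()].
#' @export
read_labeled_image <- function(path, class_label = NA_character_,
                               image_id = NULL) {
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) != 0) img <- EBImage::channel(img, "gray")
  px <- t(EBImage::imageData(img))
  if (length(dim(px)) > 2L) px <- px[, , 1L]
  px <- clamp01(px)
  if (is.null(image_id))
    image_id <- sub("\\.[^.]+$", "", basename(path))
  labeled_image(px, image_id, class_label)
}
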