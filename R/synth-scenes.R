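#' Specification of a synthetic surgical scene
#'
#' Describes one synthetic video frame: up to seven instrument-part regions
#' (elongated capsules with distinct hues and shared specular noise) placed
#' on a textured background. Class ids follow the mask convention:
#' 1 = left-arm upper flexion, 2 = left-arm abduction, 3 = left
#' grasping/cutting, 4 = right-arm upper flexion, 5 = right-arm abduction,
#' 6 = right grasping/cutting, 7 = needle; 0 is background.
#'
#' @param image_height,image_width frame size in pixels (>= 32).
#' @param parts_present integer subset of \code{1:7}; empty generates a
#'   negative example (no instruments, all-background mask).
#' @param shape_params list with \code{len_range} and \code{width_range}
#'   (capsule half-length and radius ranges, pixels).
#' @param background_texture list with noise \code{amplitude} (intensity
#'   units on \[0,1\]) and \code{scale} (smoothing length, pixels).
#' @param seed integer; the same spec and seed reproduce the scene
#'   bit-for-bit.
#' @return object of class \code{scene_spec}.
#' @export
scene_spec <- function(image_height = 64, image_width = 64,
                       parts_present = 1:7,
                       shape_params = list(len_range = c(7, 14),
                                           width_range = c(2.2, 4)),
                       background_texture = list(amplitude = 0.1, scale = 6),
                       seed = 1L) {
  stopifnot(image_height >= 32, image_width >= 32)
  parts_present <- as.integer(parts_present)
  if (length(parts_present) && !all(parts_present %in% 1:7)) {
    stop("parts_present must be a subset of 1:7")
  }
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 parts_present = parts_present,
                 shape_params = shape_params,
                 background_texture = background_texture,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Distinct part-class colours: evenly spaced hues, high saturation.
part_colors <- function() {
  sapply(1:7, function(c) grDevices::col2rgb(
    grDevices::hsv((c - 1) / 7, 0.85, 0.92)) / 255)
}

# Smoothed Gaussian noise field (zero mean, unit sd) via circular running
# means along rows and columns.
smooth_noise <- function(H, W, scale) {
  n <- matrix(stats::rnorm(H * W), H, W)
  if (scale > 1) {
    kern <- rep(1 / scale, scale)
    n <- apply(n, 2, function(col) stats::filter(col, kern, circular = TRUE))
    n <- t(apply(n, 1, function(row) stats::filter(row, kern, circular = TRUE)))
    n <- (n - mean(n)) / stats::sd(n)
  }
  n
}

# Pixels within distance r of the segment (p1, p2); coordinates are 0-based
# (row-major) to match the feature extractor's convention.
capsule_pixels <- function(H, W, p1, p2, r) {
  rows <- matrix(rep(0:(H - 1), W), H, W)
  cols <- matrix(rep(0:(W - 1), each = H), H, W)
  d <- p2 - p1
  len2 <- sum(d * d)
  vx <- cols - p1[1]; vy <- rows - p1[2]
  t_ <- if (len2 > 0) pmin(pmax((vx * d[1] + vy * d[2]) / len2, 0), 1) else 0
  dx <- vx - t_ * d[1]; dy <- vy - t_ * d[2]
  which(dx * dx + dy * dy <= r * r)
}

#' Generate one synthetic frame with its ground-truth mask
#'
#' Draws each requested part class as an elongated capsule with a distinct
#' hue plus shared specular noise, on a smoothly textured background. Class
#' regions are mutually disjoint and each requested class occupies at least
#' one pixel; every pixel belonging to no part is background (label 0).
#'
#' @param spec a [scene_spec()].
#' @return list with \code{frame} (H x W x 3 array of intensities in
#'   \[0, 1\]) and \code{mask} (H x W integer matrix with values in 0..7).
#' @export
#' @examples
#' sc <- generate_scene(scene_spec(parts_present = c(1, 4), seed = 7))
#' sort(unique(as.vector(sc$mask)))  # 0 1 4
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$image_height; W <- spec$image_width
  with_seed(spec$seed, {
    base <- 0.35
    amp <- spec$background_texture$amplitude
    sc <- spec$background_texture$scale
    frame <- array(0, c(H, W, 3))
    for (ch in 1:3) frame[, , ch] <- base + amp * smooth_noise(H, W, sc)
    mask <- matrix(0L, H, W)
    cols <- part_colors()
    lr <- spec$shape_params$len_range
    wr <- spec$shape_params$width_range
    for (cl in spec$parts_present) {
      placed <- FALSE
      for (try in 1:200) {
        r <- stats::runif(1, wr[1], wr[2])
        half <- stats::runif(1, lr[1], lr[2]) / 2
        ang <- stats::runif(1, 0, pi)
        if (r + half >= (min(H, W) - 1) / 2) next   # cannot fit at this size
        cx <- stats::runif(1, r + half, W - 1 - r - half)
        cy <- stats::runif(1, r + half, H - 1 - r - half)
        p1 <- c(cx - half * cos(ang), cy - half * sin(ang))
        p2 <- c(cx + half * cos(ang), cy + half * sin(ang))
        px <- capsule_pixels(H, W, p1, p2, r)
        if (length(px) >= 1 && all(mask[px] == 0L)) {
          mask[px] <- cl
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("cannot place part class ", cl,
             ": no disjoint placement found at image size ", H, "x", W,
             " (enlarge the image or shrink the shapes)")
      }
    }
    # shared specular noise on instrument pixels, per-class hue
    spec_noise <- matrix(stats::rnorm(H * W, sd = 0.04), H, W)
    for (cl in sort(unique(mask[mask > 0L]))) {
      px <- which(mask == cl)
      for (ch in 1:3) {
        plane <- frame[, , ch]
        plane[px] <- cols[ch, cl] + spec_noise[px]
        frame[, , ch] <- plane
      }
    }
    frame[frame < 0] <- 0
    frame[frame > 1] <- 1
    list(frame = frame, mask = mask)
  })
}

#' Read and write frames and label masks as PNG
#'
#' Frames are 8-bit RGB PNG. Masks are single-channel 8-bit PNG holding the
#' raw label value (0-7) per pixel; the round trip is exact.
#'
#' @param frame H x W x 3 array in \[0, 1\].
#' @param mask H x W integer matrix with values in 0..7.
#' @param path file path.
#' @return \code{read_frame_png} returns the array; \code{read_mask_png} the
#'   integer matrix; writers return \code{path} invisibly.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(frame, path)
  invisible(path)
}

#' @rdname write_frame_png
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE] |> array(c(dim(img)[1:2], 3))
}

#' @rdname write_frame_png
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(all(mask %in% 0:255))
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_frame_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
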