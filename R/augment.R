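# --- individual transforms (pure, geometry supplied by the caller) ---------

flip_image <- function(img, horizontal = TRUE) {
  if (horizontal) img[, rev(seq_len(ncol(img))), , drop = FALSE]
  else img[rev(seq_len(nrow(img))), , , drop = FALSE]
}

# counter-clockwise rotation by a multiple of 90 degrees (square images)
rotate_image <- function(img, angle) {
  angle <- angle %% 360
  if (angle == 0) return(img)
  r <- aperm(img, c(2L, 1L, 3L))      # transpose
  if (angle == 90) r[rev(seq_len(nrow(r))), , , drop = FALSE]
  else if (angle == 270) r[, rev(seq_len(ncol(r))), , drop = FALSE]
  else rotate_image(rotate_image(img, 90), 90)  # 180
}

shift_hue <- function(img, delta) {
  d <- dim(img)
  m <- matrix(aperm(img, c(3L, 1L, 2L)), nrow = 3L)  # 3 x (H*W)
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  rgb <- hsv_to_rgb(hsv[1L, ] + delta, hsv[2L, ], hsv[3L, ])
  out <- rbind(rgb$r, rgb$g, rgb$b)
  aperm(array(out, dim = c(3L, d[1L], d[2L])), c(2L, 3L, 1L))
}

crop_resize <- function(img, area_frac, cx, cy) {
  h <- nrow(img); w <- ncol(img)
  s <- sqrt(area_frac)
  ch <- max(2L, round(h * s)); cw <- max(2L, round(w * s))
  y0 <- 1L + floor(cy * (h - ch)); x0 <- 1L + floor(cx * (w - cw))
  crop <- img[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L), , drop = FALSE]
  resize_image(crop, h, w)
}

erase_rect <- function(img, area_frac, aspect, cx, cy) {
  h <- nrow(img); w <- ncol(img)
  eh <- max(1L, round(sqrt(area_frac * h * w * aspect)))
  ew <- max(1L, round(sqrt(area_frac * h * w / aspect)))
  eh <- min(eh, h); ew <- min(ew, w)
  y0 <- 1L + floor(cy * (h - eh)); x0 <- 1L + floor(cx * (w - ew))
  img[y0:(y0 + eh - 1L), x0:(x0 + ew - 1L), ] <-
    stats::runif(eh * ew * 3L)
  img
}

#' Stochastic training-time augmentation of a tile
#'
#' Applies, each with independent probability `p`: horizontal flip, vertical
#' flip, rotation by an angle drawn from \{0, 90, 180, 270\} degrees, a hue
#' shift uniform in `+/- hue_delta`, a random crop of at least
#' `min_crop_area` of the area resized back to the input size, and random
#' erasing of a rectangle covering 2-20 percent of the area refilled with uniform
#' noise. Output shape and `[0, 1]` range equal the input's; the function is
#' pure given `seed`.
#'
#' @param patch `H x W x 3` array in `[0, 1]`.
#' @param seed integer seed making the draw deterministic.
#' @param p per-transform firing probability.
#' @param hue_delta maximum absolute hue shift on the `[0, 1]` hue scale.
#' @param min_crop_area lower bound of the crop area fraction.
#' @param erase_range area-fraction range of the erased rectangle.
#' @return augmented array, same dimensions as `patch`.
#' @export
augment_patch <- function(patch, seed = NULL, p = 0.5, hue_delta = 0.05,
                          min_crop_area = 0.8, erase_range = c(0.02, 0.2)) {
  stopifnot(length(dim(patch)) == 3L, dim(patch)[3L] == 3L)
  with_local_seed(seed, {
    gates <- stats::runif(6L) < p
    if (gates[1L]) patch <- flip_image(patch, horizontal = TRUE)
    if (gates[2L]) patch <- flip_image(patch, horizontal = FALSE)
    angle <- sample(c(0, 90, 180, 270), 1L)
    if (gates[3L]) patch <- rotate_image(patch, angle)
    delta <- stats::runif(1L, -hue_delta, hue_delta)
    if (gates[4L]) patch <- shift_hue(patch, delta)
    crop_par <- stats::runif(3L)  # area position, used only if gate fires
    if (gates[5L]) {
      af <- min_crop_area + crop_par[1L] * (1 - min_crop_area)
      patch <- crop_resize(patch, af, crop_par[2L], crop_par[3L])
    }
    erase_par <- stats::runif(4L)
    if (gates[6L]) {
      af <- erase_range[1L] + erase_par[1L] * diff(erase_range)
      aspect <- exp(stats::runif(1L, log(0.5), log(2)))
      patch <- erase_rect(patch, af, aspect, erase_par[2L], erase_par[3L])
    }
    clamp01(patch)
  })
}

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

#' ImageNet-statistics channel normalization
#'
#' Per channel `(value - mean_c) / sd_c` with the fixed constants
#' mean = (0.485, 0.456, 0.406) and sd = (0.229, 0.224, 0.225).
#'
#' @param patch `H x W x 3` array with values in `[0, 1]`.
#' @return real-valued array of the same shape.
#' @export
normalize_imagenet <- function(patch) {
  stopifnot(length(dim(patch)) == 3L, dim(patch)[3L] == 3L)
  if (min(patch) < -1e-9 || max(patch) > 1 + 1e-9) {
    stop_validation("normalize_imagenet expects pixel values in [0, 1]")
  }
  for (c in 1:3) patch[, , c] <- (patch[, , c] - IMAGENET_MEAN[c]) / IMAGENET_SD[c]
  patch
}
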