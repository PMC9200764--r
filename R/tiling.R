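#' Otsu tissue segmentation of a slide thumbnail
#'
#' Chooses the grayscale threshold that maximises the between-class variance
#' over a 256-bin histogram and marks as tissue every pixel *darker* than the
#' threshold (H&E-stained tissue is darker than the glass background).
#'
#' @param thumbnail grayscale matrix in `[0, 1]`, or an RGB array (converted
#'   by channel mean).
#' @param downsample downsample factor of the thumbnail relative to the
#'   working magnification (recorded in the result, used by
#'   [enumerate_rois()] to map tile boxes onto the mask).
#' @return object of class `tissue_mask`: list with logical `mask`, numeric
#'   `threshold` in `(0, 1)` and `downsample`.
#' @export
tissue_mask <- function(thumbnail, downsample = 1) {
  g <- rgb_to_gray(thumbnail)
  if (length(g) == 0L) stop_validation("empty thumbnail")
  thr <- otsu_threshold(g)
  structure(list(mask = g < thr, threshold = thr, downsample = downsample),
            class = "tissue_mask")
}

# 256-bin Otsu: maximise omega0*omega1*(mu0 - mu1)^2 over cut points; the
# threshold is returned on the [0,1] grayscale as the upper edge of the
# optimal background-free bin range.
otsu_threshold <- function(g, levels = 256L) {
  v <- pmin(pmax(as.vector(g), 0), 1)
  bin <- pmin(floor(v * levels), levels - 1L)  # 0 .. levels-1
  counts <- tabulate(bin + 1L, nbins = levels)
  if (sum(counts > 0L) < 2L) {
    stop_validation("degenerate histogram: image has a single gray level, no tissue/background separation")
  }
  p <- counts / sum(counts)
  mids <- (seq_len(levels) - 0.5) / levels
  w0 <- cumsum(p)[-levels]                 # class 0 = bins 1..k
  mu0 <- cumsum(p * mids)[-levels]
  mu_t <- sum(p * mids)
  w1 <- 1 - w0
  bcv <- ifelse(w0 > 0 & w1 > 0, (mu_t * w0 - mu0)^2 / (w0 * w1), 0)
  k <- which.max(bcv)
  k / levels
}

#' Enumerate overlapping tile (ROI) coordinates over tissue
#'
#' Produces the raster-order grid of half-open `size x size` boxes at the
#' working magnification, keeping boxes whose tissue fraction (from the Otsu
#' mask) reaches `min_tissue`. Coordinates are 0-based with x rightward and
#' y downward; a box `(x, y)` covers pixels `[x, x+size) x [y, y+size)`.
#'
#' @param mask a [tissue_mask].
#' @param size tile side in pixels at the working magnification (default 224).
#' @param stride grid stride in pixels; must satisfy `0 < stride <= size`
#'   (default `size / 2`, i.e. 50 percent maximum overlap).
#' @param min_tissue minimum tissue fraction for a box to be kept.
#' @param slide_id id copied into the output.
#' @return data.frame with columns `slide_id`, `x`, `y`, `size`; zero rows
#'   when the slide is smaller than `size`.
#' @export
enumerate_rois <- function(mask, size = 224L, stride = size %/% 2L,
                           min_tissue = 0.5, slide_id = "slide") {
  stopifnot(inherits(mask, "tissue_mask"))
  if (stride <= 0 || stride > size) stop_validation("stride must satisfy 0 < stride <= size")
  if (min_tissue < 0 || min_tissue > 1) stop_validation("min_tissue must be in [0, 1]")
  ds <- mask$downsample
  h <- nrow(mask$mask) * ds
  w <- ncol(mask$mask) * ds
  if (size > h || size > w) {
    return(data.frame(slide_id = character(), x = integer(), y = integer(), size = integer()))
  }
  xs <- seq.int(0L, w - size, by = stride)
  ys <- seq.int(0L, h - size, by = stride)
  grid <- expand.grid(x = xs, y = ys)  # x fastest -> raster order row by row
  # integral image of the mask for O(1) box tissue fractions
  m <- mask$mask * 1
  ii <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  ii[-1L, -1L] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  frac <- mapply(function(x, y) {
    r0 <- floor(y / ds); r1 <- ceiling((y + size) / ds)
    c0 <- floor(x / ds); c1 <- ceiling((x + size) / ds)
    r1 <- min(r1, nrow(m)); c1 <- min(c1, ncol(m))
    area <- (r1 - r0) * (c1 - c0)
    (ii[r1 + 1L, c1 + 1L] - ii[r0 + 1L, c1 + 1L] - ii[r1 + 1L, c0 + 1L] + ii[r0 + 1L, c0 + 1L]) / area
  }, grid$x, grid$y)
  keep <- frac >= min_tissue
  out <- data.frame(slide_id = rep(slide_id, sum(keep)), x = as.integer(grid$x[keep]),
                    y = as.integer(grid$y[keep]), size = rep(as.integer(size), sum(keep)))
  rownames(out) <- NULL
  out
}

#' Randomly sample tile coordinates
#'
#' Draws `n` boxes without replacement when `n` does not exceed the number
#' of available boxes; otherwise keeps every box once and tops up to `n` by
#' sampling with replacement, so every available box appears at least once.
#'
#' @param coords data.frame from [enumerate_rois()].
#' @param n number of tiles to draw (>= 1).
#' @param seed integer; sampling is deterministic given the seed.
#' @return data.frame of `n` rows.
#' @export
sample_rois <- function(coords, n, seed = 1) {
  if (nrow(coords) == 0L) stop_validation("no tissue ROIs to sample from")
  if (n < 1) stop_validation("n must be >= 1")
  idx <- with_local_seed(seed, {
    if (n <= nrow(coords)) {
      sample.int(nrow(coords), n)
    } else {
      c(sample.int(nrow(coords)), sample.int(nrow(coords), n - nrow(coords), replace = TRUE))
    }
  })
  out <- coords[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Crop a tile from a slide reader
#'
#' @param slide a `slide_reader` (see [open_slide()]).
#' @param x,y 0-based top-left corner at the working magnification.
#' @param size tile side in pixels.
#' @return `size x size x 3` array.
#' @export
read_roi <- function(slide, x, y, size) {
  slide$read_region(x, y, size, size)
}
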