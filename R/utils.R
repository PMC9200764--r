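#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed without clobbering the caller's
# RNG stream. `seed = NULL` leaves the current stream untouched.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Convert an RGB image array to grayscale
#'
#' @param img `H x W x 3` numeric array in `[0, 1]`, or an `H x W` matrix
#'   (returned unchanged).
#' @return `H x W` matrix of channel-mean intensities.
#' @export
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L)
  (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
}

# Block-mean downsample of a matrix by integer factor f (trailing remainder
# rows/cols are dropped). Used to emulate low-magnification reads of slides
# that ship without a pyramid.
block_mean <- function(m, f) {
  stopifnot(f >= 1, f == as.integer(f))
  f <- as.integer(f)
  if (f == 1L) return(m)
  h2 <- nrow(m) %/% f
  w2 <- ncol(m) %/% f
  m <- m[seq_len(h2 * f), seq_len(w2 * f), drop = FALSE]
  # collapse rows: (f, h2, w2*f) -> colMeans over the first axis
  a <- array(m, dim = c(f, h2, w2 * f))
  s <- colMeans(a)                       # h2 x (w2*f)
  a2 <- array(t(s), dim = c(f, w2, h2))  # columns fastest after transpose
  t(colMeans(a2))                        # h2 x w2
}

#' Average-pool downsample of an RGB image
#'
#' @param img `H x W x 3` array.
#' @param factor integer downsample factor.
#' @return downsampled `H' x W' x 3` array.
#' @export
downsample_image <- function(img, factor) {
  if (factor == 1) return(img)
  ch <- lapply(1:3, function(c) block_mean(img[, , c], factor))
  array(unlist(ch), dim = c(dim(ch[[1L]]), 3L))
}

# Bilinear resize of one channel matrix to (h2, w2).
resize_matrix <- function(m, h2, w2) {
  h <- nrow(m); w <- ncol(m)
  if (h == h2 && w == w2) return(m)
  # map output pixel centres into input coordinates
  ys <- if (h2 == 1L) rep((h + 1) / 2, 1L) else (seq_len(h2) - 0.5) * h / h2 + 0.5
  xs <- if (w2 == 1L) rep((w + 1) / 2, 1L) else (seq_len(w2) - 0.5) * w / w2 + 0.5
  ys <- pmin(pmax(ys, 1), h); xs <- pmin(pmax(xs, 1), w)
  y0 <- pmin(floor(ys), h - 1L); x0 <- pmin(floor(xs), w - 1L)
  if (h == 1L) y0 <- rep(1L, h2)
  if (w == 1L) x0 <- rep(1L, w2)
  fy <- ys - y0; fx <- xs - x0
  y1 <- pmin(y0 + 1L, h); x1 <- pmin(x0 + 1L, w)
  m00 <- m[y0, x0, drop = FALSE]; m01 <- m[y0, x1, drop = FALSE]
  m10 <- m[y1, x0, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  FY <- matrix(fy, h2, w2); FX <- matrix(fx, h2, w2, byrow = TRUE)
  m00 * (1 - FY) * (1 - FX) + m10 * FY * (1 - FX) +
    m01 * (1 - FY) * FX + m11 * FY * FX
}

resize_image <- function(img, h2, w2) {
  ch <- lapply(1:3, function(c) resize_matrix(img[, , c], h2, w2))
  array(unlist(ch), dim = c(h2, w2, 3L))
}

# Vectorised HSV -> RGB (h, s, v in [0,1]); inverse of grDevices::rgb2hsv
# up to hue wrap-around.
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Read a slide image from PNG or TIFF
#'
#' Returns an `H x W x 3` array in `[0, 1]`; alpha channels are dropped and
#' grayscale images replicated across channels.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return RGB array.
#' @export
read_slide_image <- function(path) {
  if (!file.exists(path)) stop_validation("slide image not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop_validation("reading TIFF slides requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop_validation("unsupported slide format '%s' (PNG/TIFF supported)", ext)
  )
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Open a slide through the pluggable reader contract
#'
#' The tiling functions only need `dims` (width, height in pixels at the
#' working magnification), `read_region(x, y, w, h)` with 0-based half-open
#' pixel coordinates, and `thumbnail(downsample)`. Pyramidal formats can be
#' supported by supplying an object with the same fields.
#'
#' @param path slide image path (PNG/TIFF).
#' @param downsample integer average-pooling factor applied on open, used to
#'   emulate a lower working magnification when the source has no pyramid.
#' @return an object of class `slide_reader`.
#' @export
open_slide <- function(path, downsample = 1) {
  img <- read_slide_image(path)
  if (downsample > 1) img <- downsample_image(img, downsample)
  slide_reader_from_array(img, slide_id = tools::file_path_sans_ext(basename(path)))
}

#' @rdname open_slide
#' @param img in-memory `H x W x 3` array.
#' @param slide_id identifier carried into risk tables.
#' @export
slide_reader_from_array <- function(img, slide_id = "slide") {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  structure(list(
    slide_id = slide_id,
    dims = c(width = w, height = h),
    image = img,
    read_region = function(x, y, rw, rh) {
      img[(y + 1):(y + rh), (x + 1):(x + rw), , drop = FALSE]
    },
    thumbnail = function(downsample = 1) {
      if (downsample == 1) img else downsample_image(img, downsample)
    }
  ), class = "slide_reader")
}
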