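#' Score every tissue tile of a slide
#'
#' Runs inference over the exhaustive half-stride grid of tissue tiles
#' (no augmentation) and returns one risk per tile.
#'
#' @param model a trained [risk_model].
#' @param slide a `slide_reader` (see [open_slide()] /
#'   [slide_reader_from_array()]).
#' @param size tile side in pixels (defaults to the model's input size).
#' @param stride grid stride (default `size / 2`).
#' @param min_tissue minimum tissue fraction of a kept tile.
#' @return data.frame of class `slide_risk_table` with columns `slide_id`,
#'   `x`, `y`, `size`, `risk`.
#' @export
score_slide <- function(model, slide, size = model$config$input_size,
                        stride = size %/% 2L, min_tissue = 0.5) {
  stopifnot(inherits(slide, "slide_reader"))
  mask <- tissue_mask(slide$thumbnail(1))
  coords <- enumerate_rois(mask, size = size, stride = stride,
                           min_tissue = min_tissue, slide_id = slide$slide_id)
  if (nrow(coords) == 0L) stop_validation("no tissue ROIs found on slide '%s'", slide$slide_id)
  tiles <- lapply(seq_len(nrow(coords)), function(i) {
    normalize_imagenet(read_roi(slide, coords$x[i], coords$y[i], size))
  })
  coords$risk <- predict_risk_batch(model, tiles)
  class(coords) <- c("slide_risk_table", "data.frame")
  coords
}

#' Aggregate tile risks to one patient-level risk
#'
#' The patient risk is the median of the pooled tile risks across all the
#' patient's slides (even counts average the central pair), which is robust
#' to outlier tiles.
#'
#' @param risks numeric vector of tile risks, a `slide_risk_table`, or a
#'   list of risk tables from the patient's slides.
#' @return scalar patient risk.
#' @export
aggregate_patient <- function(risks) {
  if (is.data.frame(risks)) risks <- risks$risk
  if (is.list(risks)) risks <- unlist(lapply(risks, function(t) if (is.data.frame(t)) t$risk else t))
  risks <- as.numeric(risks)
  if (length(risks) == 0L) stop_validation("aggregate_patient: no risks to aggregate")
  stats::median(risks)
}

#' Render a risk density map overlay
#'
#' Tile risks are min-max scaled per slide to `[0, 1]`, placed on the tiling
#' grid with overlapping contributions averaged, passed through a
#' blue-to-red diverging colormap (blue = relatively lower risk, red =
#' higher) and alpha-blended over the slide thumbnail. Background without
#' any scored tile is left unshaded. When all risks are equal the map is
#' uniform mid-scale rather than an error.
#'
#' @param table a `slide_risk_table` from [score_slide()].
#' @param thumbnail slide RGB array at the working magnification divided by
#'   `downsample`.
#' @param downsample factor between the risk-table coordinates and the
#'   thumbnail resolution.
#' @param alpha overlay opacity.
#' @param colormap_name name recorded in the result (`"blue-red"`).
#' @param scale `"slide"` (per-slide min-max, default) or `"absolute"`
#'   (risks are assumed already on a common `[0, 1]` scale across slides).
#' @return object of class `risk_map`: `grid` (2-D array of averaged scaled
#'   risks, `NA` where uncovered), `overlay` (RGB array, thumbnail dims),
#'   `colormap_name`.
#' @export
render_risk_map <- function(table, thumbnail, downsample = 1, alpha = 0.4,
                            colormap_name = "blue-red", scale = c("slide", "absolute")) {
  scale <- match.arg(scale)
  if (nrow(table) == 0L) stop_validation("render_risk_map: empty risk table")
  h <- dim(thumbnail)[1L]; w <- dim(thumbnail)[2L]
  r <- table$risk
  if (scale == "slide") {
    rng <- range(r)
    u <- if (diff(rng) < .Machine$double.eps) rep(0.5, length(r)) else (r - rng[1L]) / diff(rng)
  } else {
    u <- clamp01(r)
  }
  acc <- matrix(0, h, w)
  cnt <- matrix(0L, h, w)
  for (i in seq_len(nrow(table))) {
    y0 <- floor(table$y[i] / downsample) + 1L
    x0 <- floor(table$x[i] / downsample) + 1L
    y1 <- min(h, ceiling((table$y[i] + table$size[i]) / downsample))
    x1 <- min(w, ceiling((table$x[i] + table$size[i]) / downsample))
    acc[y0:y1, x0:x1] <- acc[y0:y1, x0:x1] + u[i]
    cnt[y0:y1, x0:x1] <- cnt[y0:y1, x0:x1] + 1L
  }
  grid <- acc / ifelse(cnt > 0L, cnt, NA_integer_)

  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  covered <- which(cnt > 0L)
  cols <- ramp(grid[covered]) / 255
  overlay <- thumbnail
  for (c in 1:3) {
    ch <- overlay[, , c]
    ch[covered] <- (1 - alpha) * ch[covered] + alpha * cols[, c]
    overlay[, , c] <- ch
  }
  structure(list(grid = grid, overlay = clamp01(overlay),
                 colormap_name = colormap_name, alpha = alpha),
            class = "risk_map")
}

#' Write a risk map overlay to PNG
#'
#' @param map a `risk_map`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_risk_map <- function(map, path) {
  png::writePNG(map$overlay, path)
  invisible(path)
}
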