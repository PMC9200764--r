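#' Extract a patient's training tile pool
#'
#' For each slide: Otsu tissue segmentation, half-stride tile enumeration,
#' and random sampling of `n_per_slide` tiles; pools are merged across a
#' patient's slides so the patient contributes one tile pool regardless of
#' slide count.
#'
#' @param slides list of `slide_reader` objects (or in-memory `synth_slide`
#'   objects, whose images are wrapped automatically).
#' @param n_per_slide tiles sampled per slide.
#' @param size tile side in pixels.
#' @param seed integer seed.
#' @param min_tissue minimum tissue fraction per tile.
#' @return list of raw `[0, 1]` tile arrays.
#' @export
extract_tile_pool <- function(slides, n_per_slide = 30L, size = 64L,
                              seed = 1L, min_tissue = 0.5) {
  tiles <- list()
  for (s in seq_along(slides)) {
    sl <- slides[[s]]
    if (inherits(sl, "synth_slide")) {
      sl <- slide_reader_from_array(sl$image, slide_id = sprintf("synth_%d", s))
    }
    mask <- tissue_mask(sl$thumbnail(1))
    coords <- enumerate_rois(mask, size = size, stride = size %/% 2L,
                             min_tissue = min_tissue, slide_id = sl$slide_id)
    if (nrow(coords) == 0L) next
    picks <- sample_rois(coords, n_per_slide, seed = seed + 17L * s)
    tiles <- c(tiles, lapply(seq_len(nrow(picks)), function(i) {
      read_roi(sl, picks$x[i], picks$y[i], size)
    }))
  }
  if (length(tiles) == 0L) stop_validation("no tissue tiles extracted")
  tiles
}

#' Tile pools for a whole cohort
#'
#' @param x a [cohort] whose `slide_ids` are readable image paths, or a
#'   named list of in-memory slides per patient (as produced by
#'   [generate_cohort()]).
#' @param n_per_slide,size,seed,min_tissue passed to [extract_tile_pool()].
#' @return named list: patient id -> list of tiles.
#' @export
cohort_tile_pools <- function(x, n_per_slide = 30L, size = 64L, seed = 1L,
                              min_tissue = 0.5) {
  if (inherits(x, "cohort")) {
    ids <- x$patients$patient_id
    pools <- lapply(seq_along(ids), function(i) {
      slides <- lapply(x$patients$slide_ids[[i]], open_slide)
      extract_tile_pool(slides, n_per_slide, size, seed + 1009L * i, min_tissue)
    })
  } else {
    ids <- names(x)
    pools <- lapply(seq_along(ids), function(i) {
      extract_tile_pool(x[[i]], n_per_slide, size, seed + 1009L * i, min_tissue)
    })
  }
  stats::setNames(pools, ids)
}
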