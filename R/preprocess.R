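#' Preprocessing configuration
#'
#' Target voxel geometry and CT display window used before habitat mapping
#' and texture extraction. The default window is level 35 HU / width 350 HU
#' (a conventional soft-tissue window). A width smaller than the absolute
#' level by an order of magnitude usually means level and width were swapped
#' when transcribing protocol settings; such configurations are accepted but
#' flagged loudly, because a very narrow window at high attenuation flattens
#' all soft-tissue contrast and makes every downstream texture degenerate.
#'
#' @param target_spacing_mm Positive length-3 target spacing (default 1 mm
#'   isotropic).
#' @param window_level_hu Window center in HU.
#' @param window_width_hu Positive window width in HU.
#' @param interpolation Only `"nearest"` is supported: nearest-neighbor
#'   preserves the original HU value set, which texture discretization relies
#'   on.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing_mm = c(1, 1, 1),
                              window_level_hu = 35,
                              window_width_hu = 350,
                              interpolation = c("nearest")) {
  interpolation <- match.arg(interpolation)
  target_spacing_mm <- as.numeric(target_spacing_mm)
  if (length(target_spacing_mm) != 3 || any(target_spacing_mm <= 0)) {
    abort("`target_spacing_mm` must be a positive length-3 vector.")
  }
  if (window_width_hu <= 0) abort("`window_width_hu` must be > 0.")
  if (window_width_hu < abs(window_level_hu) / 5) {
    warn(paste0(
      "Window width (", window_width_hu, " HU) is much smaller than the ",
      "window level magnitude (", window_level_hu, " HU); level and width ",
      "may be swapped. Texture contrast will be nearly degenerate."
    ))
  }
  structure(
    list(
      target_spacing_mm = target_spacing_mm,
      window_level_hu = window_level_hu,
      window_width_hu = window_width_hu,
      interpolation = interpolation
    ),
    class = "preprocess_config"
  )
}

# Nearest-neighbor index map from an output axis to an input axis.
# Output voxel centers at (i-1)*t are matched to the nearest input center
# (j-1)*s; exact midpoints resolve toward the lower input index.
nn_index_map <- function(n_in, s_in, s_out) {
  extent <- (n_in - 1) * s_in
  n_out <- floor(extent / s_out + 1e-9) + 1L
  q <- (seq_len(n_out) - 1) * s_out / s_in
  clamp(as.integer(ceiling(q - 0.5 - 1e-12)) + 1L, 1L, n_in)
}

#' Resample a volume/mask pair to a target isotropic spacing
#'
#' Nearest-neighbor resampling of both image and mask onto the target voxel
#' grid. Because each output voxel copies the value of its nearest input
#' voxel center, the output intensity value set is a subset of the input's
#' and the mask stays exactly binary. Midpoint ties resolve toward the lower
#' input index, which keeps the mapping deterministic and orientation-stable.
#'
#' @param volume An [image_volume()].
#' @param mask The paired [tumor_mask()].
#' @param config A [preprocess_config()].
#' @return A list with resampled `volume` and `mask`.
#' @export
resample_isotropic <- function(volume, mask, config = preprocess_config()) {
  check_aligned(volume, mask)
  s_in <- volume$spacing_mm
  s_out <- config$target_spacing_mm
  dm <- dim(volume$grid)
  ix <- nn_index_map(dm[1], s_in[1], s_out[1])
  iy <- nn_index_map(dm[2], s_in[2], s_out[2])
  iz <- nn_index_map(dm[3], s_in[3], s_out[3])
  vg <- volume$grid[ix, iy, iz, drop = FALSE]
  mg <- mask$grid[ix, iy, iz, drop = FALSE]
  if (!any(mg)) abort("mask is empty after resampling (degenerate case).")
  list(
    volume = image_volume(vg, spacing_mm = s_out, origin = volume$origin),
    mask = tumor_mask(mg, spacing_mm = s_out, origin = mask$origin)
  )
}

#' Clip intensities to a CT display window
#'
#' Intensities are clipped to `[level - width/2, level + width/2]`; values
#' already inside the window pass through unchanged, so the operation is
#' idempotent.
#'
#' @inheritParams resample_isotropic
#' @return A windowed [image_volume()].
#' @export
apply_window <- function(volume, config = preprocess_config()) {
  lo <- config$window_level_hu - config$window_width_hu / 2
  hi <- config$window_level_hu + config$window_width_hu / 2
  image_volume(clamp(volume$grid, lo, hi),
    spacing_mm = volume$spacing_mm, origin = volume$origin
  )
}
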