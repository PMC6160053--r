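#' Extract a cubic subvolume
#'
#' Cuts an axis-aligned cube of the requested physical edge length out of a
#' volume. The cube side in voxels is `floor(edge_length / voxel_size)`
#' (90 um at 3 um/voxel gives 30 voxels); the origin of the returned volume
#' is updated so physical coordinates are preserved.
#'
#' @param vol A [voxel_volume()].
#' @param corner Physical position (um) of the cube corner, relative to the
#'   volume origin.
#' @param edge_length Physical edge length of the cube in um.
#' @return A [voxel_volume()].
#' @export
extract_subvolume <- function(vol, corner, edge_length) {
  stopifnot(inherits(vol, "voxel_volume"))
  vs <- vol$voxel_size
  n <- floor(edge_length / vs)
  if (n < 1) abort("`edge_length` smaller than one voxel")
  i0 <- round(corner / vs) + 1L
  i1 <- i0 + n - 1L
  d <- dim(vol$data)
  if (any(i0 < 1L) || any(i1 > d)) {
    abort(sprintf(
      "requested cube [%s]..[%s] voxels exceeds volume bounds %s",
      paste(i0, collapse = ","), paste(i1, collapse = ","),
      paste(d, collapse = "x")
    ))
  }
  voxel_volume(
    vol$data[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE],
    voxel_size = vs,
    origin = vol$origin + (i0 - 1L) * vs
  )
}

#' Edge-preserving contrast enhancement (de-noise substitute)
#'
#' Sharpens the material/air contrast with a toggle-contrast operator: each
#' voxel is snapped to whichever of its neighborhood minimum or maximum
#' (centre excluded) is closer to its own value. On an already two-valued
#' volume the operator is idempotent; an isolated salt/pepper voxel is
#' replaced by its (constant) neighborhood value; thin one- to two-voxel
#' beams are preserved, which a plain median filter would erase. Set
#' `bypass = TRUE` to disable the step entirely so downstream results never
#' silently depend on it.
#'
#' @param vol A [voxel_volume()].
#' @param size_px Neighborhood box size in voxels (odd; default 3 as in the
#'   usual 3d de-noise setting).
#' @param neighborhood Neighborhood code: 6 (faces), 18 (faces + edges) or
#'   26 (full box).
#' @param bypass Return the input unchanged.
#' @return A [voxel_volume()] with intensities still in `[0, 255]`.
#' @export
denoise_contrast <- function(vol, size_px = 3, neighborhood = 26,
                             bypass = FALSE) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!is.numeric(size_px) || length(size_px) != 1L || size_px < 1) {
    abort("`size_px` must be a positive integer")
  }
  if (!neighborhood %in% c(6, 18, 26)) {
    abort("`neighborhood` must be one of 6, 18, 26")
  }
  if (bypass) return(vol)
  r <- max(1L, as.integer(size_px) %/% 2L)
  mm <- cpp_minmax_filter(as.vector(vol$data), dim(vol$data), r,
                          as.integer(neighborhood))
  v <- as.vector(vol$data)
  lo <- mm$min
  hi <- mm$max
  out <- ifelse(v - lo <= hi - v, lo, hi)
  out <- pmin(pmax(out, 0), 255)
  voxel_volume(array(out, dim(vol$data)), vol$voxel_size, vol$origin)
}

#' Binarize a volume with an inclusive intensity band
#'
#' Foreground is every voxel with `lo <= intensity <= hi`; both ends of the
#' band are inclusive (a stated convention, since interactive thresholding
#' tools leave it undocumented). Default band 76--172.
#'
#' @param vol A [voxel_volume()].
#' @param lo,hi Band limits, `0 <= lo <= hi <= 255`.
#' @return A [binary_volume()].
#' @export
threshold_band <- function(vol, lo = 76, hi = 172) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (lo > hi) abort("`lo` must not exceed `hi`")
  if (lo < 0 || hi > 255) abort("band must lie within [0, 255]")
  mask <- vol$data >= lo & vol$data <= hi
  binary_volume(mask, vol$voxel_size, vol$origin)
}

#' Remove small connected components from a mask
#'
#' Deletes every foreground component with fewer than `min_size_vox` voxels
#' under the stated connectivity. Components of exactly `min_size_vox`
#' voxels survive (inclusive boundary). Default 1000 voxels under
#' 26-connectivity, the usual small-spot removal setting.
#'
#' @param bin A [binary_volume()].
#' @param min_size_vox Minimum surviving component size in voxels (>= 1).
#' @param connectivity 6, 18 or 26.
#' @return A [binary_volume()] with total foreground never increased.
#' @export
remove_small_components <- function(bin, min_size_vox = 1000,
                                    connectivity = 26) {
  stopifnot(inherits(bin, "binary_volume"))
  if (!is.numeric(min_size_vox) || length(min_size_vox) != 1L ||
      min_size_vox < 1) {
    abort("`min_size_vox` must be >= 1")
  }
  if (!connectivity %in% c(6, 18, 26)) {
    abort("`connectivity` must be one of 6, 18, 26")
  }
  lab <- cpp_label(as.vector(bin$mask), dim(bin$mask),
                  as.integer(connectivity))
  if (max(lab) == 0L) return(bin)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_size_vox)
  mask <- array(lab %in% keep, dim(bin$mask))
  binary_volume(mask, bin$voxel_size, bin$origin)
}

#' Full preprocessing chain
#'
#' Convenience wrapper running contrast enhancement, band thresholding and
#' small-component removal with the standard defaults (band 76--172,
#' min size 1000 voxels, 26-connectivity). Errors if the result is entirely
#' foreground or entirely background, which indicates degenerate input or a
#' mis-set band.
#'
#' @param vol A [voxel_volume()].
#' @param band Length-2 inclusive threshold band.
#' @param min_size_vox,connectivity See [remove_small_components()].
#' @param denoise Apply [denoise_contrast()] first.
#' @param denoise_size,denoise_neighborhood Its parameters.
#' @return A [binary_volume()].
#' @export
preprocess_volume <- function(vol, band = c(76, 172), min_size_vox = 1000,
                              connectivity = 26, denoise = TRUE,
                              denoise_size = 3, denoise_neighborhood = 26) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (denoise) {
    vol <- denoise_contrast(vol, denoise_size, denoise_neighborhood)
  }
  bin <- threshold_band(vol, band[1], band[2])
  bin <- remove_small_components(bin, min_size_vox, connectivity)
  fg <- mean(bin$mask)
  if (fg <= 0 || fg >= 1) {
    abort(sprintf(
      "degenerate preprocessing result: foreground fraction %.3f", fg
    ))
  }
  bin
}
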