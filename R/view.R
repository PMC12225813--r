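## View processing: raw 90 x 360 panorama -> the network's 20 x 90 input.

check_panorama <- function(pano) {
  stopifnot(is.matrix(pano), nrow(pano) == 90L, ncol(pano) == 360L)
  invisible(pano)
}

#' Split a panorama into left and right visual fields
#'
#' Each visual field spans 180 degrees. With a frontal `overlap` of width o,
#' the left field is panorama columns covering relative azimuths
#' `[-180 + o/2, o/2)` and the right field `[-o/2, 180 - o/2)` (0-based
#' column ranges `[o/2, 180 + o/2)` and `[180 - o/2, 360 - o/2)`), so a
#' region of width o centred on the front is imaged by both fields and a
#' region of the same width at the rear by neither. The two fields are
#' stacked horizontally, left then right, into a 90 x 360 matrix.
#'
#' @param pano 90 x 360 panorama matrix.
#' @param overlap frontal overlap in degrees, `0 <= overlap < 180`;
#'   multiples of 8 keep field boundaries aligned with the 4-degree
#'   downsampling blocks (odd overlaps are cropped at the nearest degree).
#' @return 90 x 360 matrix, columns 1-180 the left field, 181-360 the right.
#' @export
split_visual_fields <- function(pano, overlap = 0) {
  check_panorama(pano)
  stopifnot(is.numeric(overlap), length(overlap) == 1L)
  if (overlap < 0 || overlap >= 180) stop("overlap must be in [0, 180)")
  o2 <- round(overlap / 2)
  left <- (o2 + 1L):(180L + o2)
  right <- (180L - o2 + 1L):(360L - o2)
  cbind(pano[, left, drop = FALSE], pano[, right, drop = FALSE])
}

#' Crop and mean-downsample a stacked view
#'
#' Removes the 10 highest-elevation pixel rows, then replaces each
#' non-overlapping 4 x 4 block of the 80 x 360 remainder by its arithmetic
#' mean, giving a 20 x 90 image at 4 degrees/pixel.
#'
#' @param stacked 90 x 360 matrix (a panorama or stacked visual fields).
#' @return 20 x 90 numeric matrix.
#' @export
crop_and_downsample <- function(stacked) {
  check_panorama(stacked)
  x <- stacked[11:90, , drop = FALSE]
  a <- array(x, dim = c(4L, 20L, 360L))
  s1 <- colMeans(a)                       # 20 x 360, row blocks pooled
  a2 <- array(t(s1), dim = c(4L, 90L, 20L))
  t(colMeans(a2))                         # 20 x 90
}

#' Process a panorama into the network input
#'
#' Composition of [split_visual_fields()] and [crop_and_downsample()]: the
#' 20 x 90 processed view whose columns 1-45 are the left visual field and
#' 46-90 the right. The overlap used is recorded as an attribute so that
#' training can detect mismatched views.
#'
#' @inheritParams split_visual_fields
#' @return 20 x 90 matrix with attribute `"overlap"`.
#' @export
process_view <- function(pano, overlap = 0) {
  out <- crop_and_downsample(split_visual_fields(pano, overlap))
  attr(out, "overlap") <- overlap
  out
}

#' Rotate a panorama to a new facing direction
#'
#' Circular shift of the panorama columns: `rotate_panorama(p, d)` equals the
#' panorama re-rendered at the same position with heading increased by `d`
#' degrees.
#'
#' @param pano 90 x 360 panorama matrix.
#' @param deg integer rotation in degrees.
#' @return 90 x 360 matrix.
#' @export
rotate_panorama <- function(pano, deg) {
  check_panorama(pano)
  stopifnot(length(deg) == 1L, deg == round(deg))
  idx <- ((seq_len(360L) - 1L + as.integer(deg)) %% 360L) + 1L
  pano[, idx, drop = FALSE]
}

#' Flatten a processed view to the vPN activity vector
#'
#' Visual projection neurons carry the greyscale pixel values of the
#' processed view, column-major: vPNs 1-900 are the left visual field
#' (columns 1-45), vPNs 901-1800 the right.
#'
#' @param view 20 x 90 processed view.
#' @return numeric vector of length 1800.
#' @export
as_vpn_vector <- function(view) {
  stopifnot(is.matrix(view), nrow(view) == 20L, ncol(view) == 90L)
  as.numeric(view)
}

## vPN vectors for all 360 facing directions of a panorama (one column per
## integer direction 0..359).
direction_views <- function(pano, overlap = 0) {
  vapply(0:359, function(d)
    as_vpn_vector(process_view(rotate_panorama(pano, d), overlap)),
    numeric(1800L))
}
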