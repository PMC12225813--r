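## Fractional position of mass (FPM) reference quantities, evaluated on the
## centre-of-arena view (where stimulus angles are the image coordinates).

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

## Sutherland-Hodgman clip of a polygon against the half-plane x <= xmax.
clip_left_of <- function(poly, xmax) {
  n <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    p <- poly[i, ]
    q <- poly[i %% n + 1L, ]
    pin <- p[1] <= xmax
    qin <- q[1] <= xmax
    if (pin) out <- rbind(out, p)
    if (xor(pin, qin)) {
      tt <- (xmax - p[1]) / (q[1] - p[1])
      out <- rbind(out, p + tt * (q - p))
    }
  }
  out
}

## Merge a set of [lo, hi] intervals into a disjoint union.
merge_intervals <- function(iv) {
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- nrow(out)
    if (iv[i, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

#' Fractional position of mass of a shape
#'
#' The FPM is the proportion L/(L+R) of a shape lying left of the facing
#' direction, evaluated from the arena centre. With `method = "width"` the
#' shape's "mass" is its horizontal (azimuthal) extent; with
#' `method = "area"` it is the black area in stimulus-angle coordinates.
#' The fraction clamps to 0/1 when the facing direction lies outside the
#' shape's azimuthal extent.
#'
#' @param shape a [shape_spec()].
#' @param facing_azimuth facing direction, degrees (world frame, i.e. same
#'   frame as the shape's vertex azimuths).
#' @param method `"width"` (default) or `"area"`.
#' @return fraction in `[0, 1]`.
#' @examples
#' compute_fpm(shape_library()$rect_160x38, 30)  # 0.1875
#' @export
compute_fpm <- function(shape, facing_azimuth, method = c("width", "area")) {
  method <- match.arg(method)
  stopifnot(inherits(shape, "shape_spec"))
  if (method == "width") {
    iv <- do.call(rbind, lapply(shape$components, function(m) range(m[, 1])))
    iv <- merge_intervals(iv)
    total <- sum(iv[, 2] - iv[, 1])
    if (total <= 0) stop("shape has zero azimuthal extent")
    left <- sum(pmax(0, pmin(iv[, 2], facing_azimuth) - iv[, 1]))
    left / total
  } else {
    total <- sum(vapply(shape$components, shoelace_area, 0))
    if (total <= 0) stop("shape has zero area")
    left <- sum(vapply(shape$components, function(p) {
      cl <- clip_left_of(p, facing_azimuth)
      if (nrow(cl) < 3L) 0 else shoelace_area(cl)
    }, 0))
    left / total
  }
}

#' Facing direction that reproduces an FPM value
#'
#' Inverse of [compute_fpm()]: the facing direction at the arena centre that
#' puts fraction `fpm` of the test shape left of centre. For non-rectangular
#' shapes under the area method the direction is found by monotone root
#' search on the cumulative area profile.
#'
#' @param fpm target fraction in `[0, 1]`.
#' @param test_shape a [shape_spec()].
#' @param method `"width"` or `"area"`.
#' @return degrees right of the test shape's left edge.
#' @examples
#' fpm_match_direction(0.1875, shape_library()$rect_80x38)  # 15
#' @export
fpm_match_direction <- function(fpm, test_shape,
                                method = c("width", "area")) {
  method <- match.arg(method)
  stopifnot(is.numeric(fpm), length(fpm) == 1L, fpm >= 0, fpm <= 1)
  ext <- azimuth_extent(test_shape)
  origin <- test_shape$left_edge_azimuth
  if (fpm <= 0) return(ext[1] - origin)
  if (fpm >= 1) return(ext[2] - origin)
  f <- function(d) compute_fpm(test_shape, d, method) - fpm
  root <- uniroot(f, interval = ext, tol = 1e-9)$root
  root - origin
}
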