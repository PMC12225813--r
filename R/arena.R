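#' Arena configuration
#'
#' Geometry of the cylindrical arena and of the training route. The agent is
#' trained on a straight path from the arena centre towards a feeder placed
#' `feeder_distance` metres from the centre at world azimuth `feeder_azimuth`.
#' World azimuth 0 is the direction of the reference point Z at the base of
#' the wall; by convention the training shape's left edge is placed there, so
#' plotted facing directions are measured from the shape's left edge.
#' Azimuths increase rightward (clockwise seen from above).
#'
#' @param radius arena radius R in metres.
#' @param feeder_distance distance r from centre to feeder in metres
#'   (`0 <= r < R`).
#' @param feeder_azimuth world azimuth of the feeder, degrees.
#' @return an object of class `arena_config`.
#' @examples
#' arena_config()
#' @export
arena_config <- function(radius = 1.5, feeder_distance = 0.6,
                         feeder_azimuth = 0) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0,
            is.numeric(feeder_distance), length(feeder_distance) == 1L,
            feeder_distance >= 0, feeder_distance < radius,
            is.numeric(feeder_azimuth), length(feeder_azimuth) == 1L)
  structure(list(radius = radius, feeder_distance = feeder_distance,
                 feeder_azimuth = feeder_azimuth,
                 n_rows = 90L, n_cols = 360L),
            class = "arena_config")
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("arena: R = %g m, feeder at r = %g m, azimuth %g deg\n",
              x$radius, x$feeder_distance, x$feeder_azimuth))
  invisible(x)
}

#' Agent pose inside the arena
#'
#' @param x,y position in metres from the arena centre.
#' @param heading world azimuth the agent faces, degrees.
#' @return an object of class `agent_pose`.
#' @export
agent_pose <- function(x = 0, y = 0, heading = 0) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(heading))
  structure(list(position = c(x, y), heading = heading), class = "agent_pose")
}

#' Shape on the arena wall
#'
#' A shape is one or more filled polygons given in stimulus-angle coordinates
#' as measured from the arena centre: each vertex is (azimuth, elevation) in
#' degrees, with elevations in `[0, 90)`. Composite shapes (e.g. two abutting
#' triangles) are passed as a list of polygon matrices. All shapes are
#' anchored with their base on the arena floor (elevation 0).
#'
#' @param components a two-column numeric matrix of vertices, or a list of
#'   such matrices (one per polygon component).
#' @param left_edge_azimuth azimuth of the shape's leftmost point, the
#'   plotting origin; defaults to the minimum vertex azimuth.
#' @param name optional label.
#' @return an object of class `shape_spec`.
#' @examples
#' rect <- shape_spec(cbind(c(0, 160, 160, 0), c(0, 0, 38, 38)))
#' @export
shape_spec <- function(components, left_edge_azimuth = NULL, name = NULL) {
  if (is.matrix(components)) components <- list(components)
  components <- lapply(components, function(v) {
    m <- as.matrix(v)
    storage.mode(m) <- "double"
    stopifnot(ncol(m) == 2L, nrow(m) >= 3L,
              all(is.finite(m)), all(m[, 2] >= 0), all(m[, 2] < 90))
    unname(m)
  })
  if (is.null(left_edge_azimuth))
    left_edge_azimuth <- min(vapply(components, function(m) min(m[, 1]), 0))
  structure(list(components = components,
                 left_edge_azimuth = left_edge_azimuth, name = name),
            class = "shape_spec")
}

#' @export
print.shape_spec <- function(x, ...) {
  ext <- azimuth_extent(x)
  cat(sprintf("shape%s: %d component(s), azimuths [%g, %g] deg, max elevation %g deg\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              length(x$components), ext[1], ext[2],
              max(vapply(x$components, function(m) max(m[, 2]), 0))))
  invisible(x)
}

azimuth_extent <- function(shape) {
  range(unlist(lapply(shape$components, function(m) range(m[, 1]))))
}

#' Transform stimulus angles to an arbitrary viewing location
#'
#' A wall point with stimulus angles (`theta`, `phi`) as measured from the
#' arena centre O is seen from a pose L inside the arena under transformed
#' angles: `theta' = acos(LZ.LP / (|LZ||LP|))` with the side resolved by the
#' sign of the planar cross product of LZ and LP (the arccos alone is
#' unsigned), and `phi' = atan(R tan(phi) / |LP|)`, where P is the point's
#' projection onto the wall base and Z marks world azimuth 0.
#'
#' @param theta azimuthal stimulus angle(s), degrees (vectorised).
#' @param phi polar (elevation) stimulus angle(s) in `[0, 90)`, degrees.
#' @param pose an [agent_pose()] strictly inside the arena.
#' @param arena an [arena_config()].
#' @return list with components `theta` and `phi`, the transformed angles in
#'   degrees; `theta` lies in `[0, 360)` and reduces to the input at the
#'   arena centre.
#' @examples
#' transform_point(37, 25, agent_pose(), arena_config())
#' @export
transform_point <- function(theta, phi, pose, arena = arena_config()) {
  stopifnot(all(phi >= 0), all(phi < 90))
  L <- pose$position
  R <- arena$radius
  if (sqrt(sum(L^2)) >= R)
    stop("pose must lie strictly inside the arena wall")
  P <- R * az_to_xy(theta)
  LZ <- c(R, 0) - L
  LPx <- P[, 1] - L[1]
  LPy <- P[, 2] - L[2]
  dotp <- LZ[1] * LPx + LZ[2] * LPy
  crs <- LZ[1] * LPy - LZ[2] * LPx
  theta_p <- (-rad2deg(atan2(crs, dotp))) %% 360
  d_xy <- sqrt(LPx^2 + LPy^2)
  phi_p <- rad2deg(atan(R * tan(deg2rad(phi)) / d_xy))
  list(theta = theta_p, phi = phi_p)
}

## Densely sample the closed outline of a polygon (in stimulus-angle space)
## at `step` degrees along each edge.
sample_outline <- function(poly, step = 0.1) {
  n <- nrow(poly)
  pts <- vector("list", n)
  for (i in seq_len(n)) {
    p <- poly[i, ]
    q <- poly[i %% n + 1L, ]
    m <- max(1L, ceiling(max(abs(q - p)) / step))
    tt <- seq(0, 1, length.out = m + 1L)[-(m + 1L)]
    pts[[i]] <- cbind(p[1] + tt * (q[1] - p[1]), p[2] + tt * (q[2] - p[2]))
  }
  do.call(rbind, pts)
}

## Even-odd scanline fill of one transformed outline into the raw image
## grid. `a` is the unwrapped (continuous) azimuth relative to the heading,
## `e` the elevation, both degrees. Pixel centres sit at half-degrees; for
## each image column the crossing elevations of the closed outline with the
## column's azimuth are paired off (even-odd rule) and the rows between each
## pair are set black.
fill_outline <- function(img, a, e) {
  row_c <- 90.5 - seq_len(90)          # row 1 = elevation 89
  col_c <- seq_len(360) - 180.5        # column 181 = relative azimuth 0.5
  x1 <- a; x2 <- c(a[-1L], a[1L])
  y1 <- e; y2 <- c(e[-1L], e[1L])
  kmin <- floor((min(a) + 180) / 360)
  kmax <- floor((max(a) + 180) / 360)
  for (k in kmin:kmax) {
    ac <- col_c + 360 * k
    cols <- which(ac >= min(a) & ac <= max(a))
    for (ci in cols) {
      xc <- ac[ci]
      hit <- (x1 <= xc & x2 > xc) | (x2 <= xc & x1 > xc)
      if (!any(hit)) next
      tt <- (xc - x1[hit]) / (x2[hit] - x1[hit])
      ys <- sort(y1[hit] + tt * (y2[hit] - y1[hit]))
      for (j in seq_len(length(ys) %/% 2L)) {
        inside <- row_c > ys[2L * j - 1L] & row_c < ys[2L * j]
        if (any(inside)) img[inside, ci] <- 1
      }
    }
  }
  img
}

#' Render a panoramic greyscale view
#'
#' Rasterises wall shapes into a 90 x 360 panoramic image (1 degree/pixel) as
#' seen from a pose. Row 1 is elevation 89 deg, row 90 the floor; column c
#' corresponds to azimuth `c - 181` relative to the heading (column 181 is
#' straight ahead, columns 1/360 the rear). Pixel value 1 is black
#' (shape), 0 is white. Each polygon outline is sampled at `outline_step`
#' degrees, transformed with [transform_point()], and filled by the even-odd
#' rule at pixel centres.
#'
#' @param shapes a [shape_spec()] or list of them.
#' @param pose an [agent_pose()].
#' @param arena an [arena_config()].
#' @param outline_step outline sampling density in degrees.
#' @return 90 x 360 numeric matrix in `[0, 1]`.
#' @examples
#' pano <- render_panorama(shape_library()$rect_160x38, agent_pose())
#' sum(pano)  # 160 x 38 pixels
#' @export
render_panorama <- function(shapes, pose = agent_pose(),
                            arena = arena_config(), outline_step = 0.1) {
  if (inherits(shapes, "shape_spec")) shapes <- list(shapes)
  img <- matrix(0, arena$n_rows, arena$n_cols)
  for (sh in shapes) {
    stopifnot(inherits(sh, "shape_spec"))
    for (poly in sh$components) {
      dense <- sample_outline(poly, outline_step)
      tp <- transform_point(dense[, 1], dense[, 2], pose, arena)
      rel <- ((tp$theta - pose$heading + 180) %% 360) - 180
      img <- fill_outline(img, unwrap_deg(rel), tp$phi)
    }
  }
  img
}

#' Poses along the training path
#'
#' The agent trains while moving in a straight line from the arena centre to
#' the feeder, facing straight ahead. Training views are taken at `n_train`
#' equally spaced distances from 0 to `feeder_distance` inclusive; with
#' `n_train = 1` only the centre view is used.
#'
#' @param arena an [arena_config()].
#' @param n_train number of training poses (>= 1).
#' @return list of [agent_pose()] objects, all heading `feeder_azimuth`.
#' @export
training_path_poses <- function(arena = arena_config(), n_train = 30) {
  stopifnot(is.numeric(n_train), length(n_train) == 1L, n_train >= 1)
  d <- seq(0, arena$feeder_distance, length.out = n_train)
  dir <- az_to_xy(arena$feeder_azimuth)
  lapply(d, function(di) agent_pose(di * dir[1], di * dir[2],
                                    heading = arena$feeder_azimuth))
}
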