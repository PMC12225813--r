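#' Standard train and test shapes
#'
#' The wall shapes used across the reference experiments, all anchored with
#' their base on the arena floor and their left edge at azimuth 0:
#' rectangles 160/120/80/40 x 38 deg and 140/80 x 35 deg; an 80 deg-wide
#' trapezoid with heights 10 (left) and 57 (right); a 160 deg-wide scalene
#' triangle of height 65 with its summit 50 deg right of the start, plus its
#' horizontal reflection; a 160 deg-wide trapezoid with heights 10 and 65; a
#' composite of two abutting isosceles triangles (base 70, height 35); and a
#' 140 deg-wide trapezoid whose top-left vertex sits 35 deg right of the
#' start.
#'
#' @return named list of [shape_spec()] objects.
#' @export
shape_library <- function() {
  rect <- function(w, h) cbind(c(0, w, w, 0), c(0, 0, h, h))
  lib <- list(
    rect_160x38 = rect(160, 38),
    rect_120x38 = rect(120, 38),
    rect_80x38 = rect(80, 38),
    rect_40x38 = rect(40, 38),
    trapezoid_80 = cbind(c(0, 80, 80, 0), c(0, 0, 57, 10)),
    triangle_160 = cbind(c(0, 160, 50), c(0, 0, 65)),
    triangle_160_reflected = cbind(c(0, 160, 110), c(0, 0, 65)),
    trapezoid_160 = cbind(c(0, 160, 160, 0), c(0, 0, 65, 10)),
    double_triangle = list(cbind(c(0, 70, 35), c(0, 0, 35)),
                           cbind(c(70, 140, 105), c(0, 0, 35))),
    rect_140x35 = rect(140, 35),
    trapezoid_140x35 = cbind(c(0, 140, 140, 35), c(0, 0, 35, 35)),
    rect_80x35 = rect(80, 35))
  Map(function(poly, nm) shape_spec(poly, name = nm), lib, names(lib))
}

#' Define a train/test experiment
#'
#' Bundles a training shape, its feeder placement, the number of training
#' views, and one or more test shapes. The arena is oriented so that world
#' azimuth 0 is the training shape's left edge; the feeder azimuth is given
#' in that frame (degrees right of the left edge).
#'
#' @param train a [shape_spec()], the training shape.
#' @param tests a named list of [shape_spec()] test shapes.
#' @param feeder_azimuth feeder direction, degrees right of the training
#'   shape's left edge.
#' @param n_train number of training views along the path.
#' @param arena an [arena_config()]; built from `feeder_azimuth` if omitted.
#' @param true_modes optional named numeric vector of reference (true) mode
#'   directions per test shape, degrees, for performance scoring.
#' @param name optional label.
#' @return object of class `nav_experiment`.
#' @export
nav_experiment <- function(train, tests, feeder_azimuth, n_train = 30,
                           arena = NULL, true_modes = NULL, name = NULL) {
  stopifnot(inherits(train, "shape_spec"))
  if (inherits(tests, "shape_spec")) tests <- list(tests)
  stopifnot(all(vapply(tests, inherits, TRUE, "shape_spec")))
  if (is.null(names(tests)))
    names(tests) <- vapply(seq_along(tests), function(i)
      tests[[i]]$name %||% paste0("test", i), "")
  if (is.null(arena)) arena <- arena_config(feeder_azimuth = feeder_azimuth)
  structure(list(train = train, tests = tests,
                 feeder_azimuth = feeder_azimuth, n_train = n_train,
                 arena = arena, true_modes = true_modes, name = name),
            class = "nav_experiment")
}

#' @export
print.nav_experiment <- function(x, ...) {
  cat(sprintf("experiment%s: train '%s', feeder at %g deg, %d training views\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$train$name %||% "?", x$feeder_azimuth, x$n_train))
  cat("  tests:", paste(names(x$tests), collapse = ", "), "\n")
  invisible(x)
}

#' Trained FPM and FPM-match directions of an experiment
#'
#' `trained_fpm()` is the FPM of the training shape at the feeder direction;
#' `match_directions()` maps it through [fpm_match_direction()] to the
#' facing direction on each test shape that reproduces it.
#'
#' @param experiment a [nav_experiment()].
#' @param method FPM method, `"width"` or `"area"`.
#' @return `trained_fpm()`: a fraction; `match_directions()`: named vector of
#'   directions in degrees (relative to each test shape's left edge).
#' @export
trained_fpm <- function(experiment, method = c("width", "area")) {
  compute_fpm(experiment$train, experiment$feeder_azimuth, method)
}

#' @rdname trained_fpm
#' @export
match_directions <- function(experiment, method = c("width", "area")) {
  f <- trained_fpm(experiment, method)
  vapply(experiment$tests, function(s) fpm_match_direction(f, s, method), 0)
}

#' Reference experiment fixtures
#'
#' The standard experiment sets: `rectangles` (train 160 x 38 rectangle,
#' feeder 30 deg right of the left edge; tests: the same rectangle, an
#' 80 x 38 rectangle, and the 80 deg trapezoid), `nested_rectangles` (same
#' training regime; tests 120/80/40 x 38 rectangles), `triangle` (scalene
#' triangle training shape; tests: itself, its reflection, and the 160 deg
#' trapezoid), and `composite_I/II/III` (two abutting triangles with the
#' feeder 25/35/55 deg right of the shape start; set II places the feeder at
#' the centre of the first triangle).
#'
#' The feeder azimuth of the `triangle` set is not independently documented
#' and is taken equal to the 30 deg inset of the rectangle set.
#'
#' @return named list of [nav_experiment()] objects.
#' @export
fpm_experiments <- function() {
  sh <- shape_library()
  list(
    rectangles = nav_experiment(
      sh$rect_160x38,
      list(rect_160x38 = sh$rect_160x38, rect_80x38 = sh$rect_80x38,
           trapezoid_80 = sh$trapezoid_80),
      feeder_azimuth = 30, name = "rectangles"),
    nested_rectangles = nav_experiment(
      sh$rect_160x38,
      list(rect_120x38 = sh$rect_120x38, rect_80x38 = sh$rect_80x38,
           rect_40x38 = sh$rect_40x38),
      feeder_azimuth = 30, name = "nested_rectangles"),
    triangle = nav_experiment(
      sh$triangle_160,
      list(triangle_160 = sh$triangle_160,
           triangle_160_reflected = sh$triangle_160_reflected,
           trapezoid_160 = sh$trapezoid_160),
      feeder_azimuth = 30, name = "triangle"),
    composite_I = nav_experiment(
      sh$double_triangle,
      list(double_triangle = sh$double_triangle,
           rect_140x35 = sh$rect_140x35,
           trapezoid_140x35 = sh$trapezoid_140x35),
      feeder_azimuth = 25, name = "composite_I"),
    composite_II = nav_experiment(
      sh$double_triangle,
      list(double_triangle = sh$double_triangle,
           rect_140x35 = sh$rect_140x35,
           trapezoid_140x35 = sh$trapezoid_140x35),
      feeder_azimuth = 35, name = "composite_II"),
    composite_III = nav_experiment(
      sh$double_triangle,
      list(double_triangle = sh$double_triangle,
           rect_140x35 = sh$rect_140x35, rect_80x35 = sh$rect_80x35),
      feeder_azimuth = 55, name = "composite_III"))
}
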