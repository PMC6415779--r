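#' Per-structure alignment transform
#'
#' Accumulates the full alignment state of one structure.  Application
#' order is fixed:
#' center subtraction, pre-rotation (ellipse de-rotation), anisotropic
#' scaling (circularization), tilt about the x axis, in-plane rotation,
#' translation.  Ellipse circularization populates `center`,
#' `pre_rotation` and the scales; rigid registration populates `tilt_phi`,
#' `theta` and `shift`.
#'
#' @param scale_x,scale_y Dimensionless deformation scales (`R/a`, `R/b`);
#'   must be positive.
#' @param pre_rotation Rotation in radians applied before scaling
#'   (`-phi` of the fitted ellipse).
#' @param tilt_phi Rotation about the x axis in degrees (3D alignment).
#' @param theta In-plane rotation in degrees, normalized to `[0, 360)`.
#' @param shift Final translation `(x, y)` in nm.
#' @param center Point `(x, y)` (or `(x, y, z)` for 3D alignment, where the
#'   axial centroid must be removed before tilting) in nm subtracted before
#'   any rotation (ellipse center or structure centroid).
#' @return A `structure_transform` object.
#' @export
structure_transform <- function(scale_x = 1, scale_y = 1, pre_rotation = 0,
                                tilt_phi = 0, theta = 0, shift = c(0, 0),
                                center = c(0, 0)) {
  stopifnot(scale_x > 0, scale_y > 0, length(shift) == 2,
            length(center) %in% c(2, 3))
  structure(list(scale_x = scale_x, scale_y = scale_y,
                 pre_rotation = pre_rotation, tilt_phi = tilt_phi,
                 theta = theta %% 360, shift = as.numeric(shift),
                 center = as.numeric(center)),
            class = "structure_transform")
}

#' @export
print.structure_transform <- function(x, ...) {
  cat(sprintf(paste0("<structure_transform> center (%.2f, %.2f) nm, ",
                     "pre-rot %.4f rad, scales (%.4f, %.4f), tilt %.2f deg, ",
                     "theta %.2f deg, shift (%.2f, %.2f) nm\n"),
              x$center[1], x$center[2], x$pre_rotation, x$scale_x,
              x$scale_y, x$tilt_phi, x$theta, x$shift[1], x$shift[2]))
  invisible(x)
}

rot2 <- function(theta_rad) {
  matrix(c(cos(theta_rad), sin(theta_rad),
           -sin(theta_rad), cos(theta_rad)), 2, 2)
}

#' Apply a structure transform to a molecule list
#'
#' Applies the documented composition order exactly.  A nonzero `tilt_phi`
#' requires 3D coordinates (the tilt mixes y and z).
#'
#' @param ml A [molecule_list()].
#' @param t A [structure_transform()].
#' @return The transformed molecule list.
#' @export
apply_transform <- function(ml, t) {
  stopifnot(inherits(ml, "molecule_list"), inherits(t, "structure_transform"))
  if (t$tilt_phi != 0 && !is_3d(ml))
    stop("tilt_phi != 0 requires z coordinates")
  x <- ml$x - t$center[1]
  y <- ml$y - t$center[2]
  z <- if (is_3d(ml)) ml$z else NULL
  if (length(t$center) == 3 && !is.null(z)) z <- z - t$center[3]
  if (t$pre_rotation != 0) {
    p <- rot2(t$pre_rotation) %*% rbind(x, y)
    x <- p[1, ]; y <- p[2, ]
  }
  x <- x * t$scale_x
  y <- y * t$scale_y
  if (t$tilt_phi != 0) {
    phi <- t$tilt_phi * pi / 180
    y2 <- cos(phi) * y - sin(phi) * z
    z <- sin(phi) * y + cos(phi) * z
    y <- y2
  }
  if (t$theta != 0) {
    p <- rot2(t$theta * pi / 180) %*% rbind(x, y)
    x <- p[1, ]; y <- p[2, ]
  }
  out <- ml
  out$x <- x + t$shift[1]
  out$y <- y + t$shift[2]
  if (!is.null(z)) out$z <- z
  out
}

#' Invert a structure transform
#'
#' The inverse is expressible in the same fixed-order parameterization
#' whenever the transform does not combine anisotropic scaling with a
#' nonzero tilt (scaling and x-tilt do not commute); every transform the
#' pipelines produce satisfies this (2D deformation has no tilt, 3D
#' alignment has unit scales).
#'
#' @param t A [structure_transform()].
#' @return The inverse `structure_transform`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "structure_transform"))
  aniso <- t$scale_x != 1 || t$scale_y != 1
  if (aniso && t$tilt_phi != 0)
    stop("cannot invert a transform combining scaling and tilt")
  if (length(t$center) == 3)
    stop("transforms with an axial center are not invertible in-form")
  theta_rad <- t$theta * pi / 180
  structure_transform(scale_x = 1 / t$scale_x, scale_y = 1 / t$scale_y,
                      pre_rotation = -theta_rad,
                      tilt_phi = -t$tilt_phi,
                      theta = -t$pre_rotation * 180 / pi,
                      shift = t$center, center = t$shift)
}

#' Rotate 3D localizations about the x axis
#'
#' Rotates `(x, y, z)` by `phi` degrees about an axis through the structure
#' centroid parallel to x, using the matrix
#' `[1 0 0; 0 cos(phi) -sin(phi); 0 sin(phi) cos(phi)]`.
#'
#' @param ml A 3D [molecule_list()].
#' @param phi Rotation angle in degrees.
#' @param about Rotation origin `(y, z)`; default the centroid.
#' @return The rotated molecule list; `x` is unchanged.
#' @export
rotate_about_x <- function(ml, phi, about = NULL) {
  stopifnot(inherits(ml, "molecule_list"))
  if (!is_3d(ml)) stop("rotate_about_x requires 3D coordinates")
  if (is.null(about)) about <- c(mean(ml$y), mean(ml$z))
  p <- phi * pi / 180
  y <- ml$y - about[1]
  z <- ml$z - about[2]
  out <- ml
  out$y <- cos(p) * y - sin(p) * z + about[1]
  out$z <- sin(p) * y + cos(p) * z + about[2]
  out
}
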