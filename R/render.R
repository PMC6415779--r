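#' Construct a pixel image
#'
#' @param values Non-negative numeric matrix (rows = y, columns = x).
#' @param pixel_size Pixel edge in nm.
#' @param origin `(x, y)` nm position of the center of pixel `[1, 1]`.
#' @return A `pixel_image` (matrix with `pixel_size` / `origin` attributes).
#' @export
pixel_image <- function(values, pixel_size, origin = c(0, 0)) {
  stopifnot(is.matrix(values), pixel_size > 0, length(origin) == 2)
  if (nrow(values) < 8 || ncol(values) < 8 ||
      nrow(values) %% 2 != 0 || ncol(values) %% 2 != 0)
    stop("image dimensions must be even and at least 8")
  structure(values, class = c("pixel_image", "matrix"),
            pixel_size = pixel_size, origin = as.numeric(origin))
}

#' @export
print.pixel_image <- function(x, ...) {
  cat(sprintf("<pixel_image> %d x %d, %.3g nm/px, origin (%.1f, %.1f) nm, sum %.4g\n",
              nrow(x), ncol(x), attr(x, "pixel_size"),
              attr(x, "origin")[1], attr(x, "origin")[2], sum(x)))
  invisible(x)
}

pixel_size_of <- function(img) attr(img, "pixel_size")

#' Render a molecule list to a pixel image
#'
#' Bins localizations into a 2D histogram on a square pixel grid centered at
#' `center`, then (optionally) smooths with a Gaussian kernel.  Before
#' smoothing the total intensity equals the number of in-field points;
#' points outside the field are dropped and their count recorded in the
#' `n_dropped` attribute.
#'
#' @param ml A [molecule_list()] (z, if present, is ignored: the rendering
#'   is the x-y projection).
#' @param pixel_size Pixel edge in nm (default 10).
#' @param field_size Field edge in nm; rounded to an even number of pixels.
#' @param blur_sigma Gaussian smoothing SD in nm (0 = none).  Typically set
#'   to the localization precision.
#' @param center `(x, y)` nm center of the field (default the origin, which
#'   is where circularized/simulated structures live; use the structure
#'   centroid for uncentered data).
#' @return A [pixel_image()].
#' @export
render_image <- function(ml, pixel_size = 10, field_size = 640,
                         blur_sigma = 0, center = c(0, 0)) {
  stopifnot(inherits(ml, "molecule_list"), pixel_size > 0, field_size > 0)
  n <- max(8L, 2L * ceiling(field_size / pixel_size / 2))
  # pixel centers: origin + (0:(n-1)) * pixel_size, symmetric about `center`
  origin <- center - (n / 2 - 0.5) * pixel_size
  ci <- round((ml$x - origin[1]) / pixel_size)
  ri <- round((ml$y - origin[2]) / pixel_size)
  keep <- ci >= 0 & ci < n & ri >= 0 & ri < n
  if (!any(keep)) stop("all points fall outside the rendering field")
  idx <- ri[keep] + 1 + n * ci[keep]
  counts <- matrix(tabulate(idx, nbins = n * n), n, n)
  img <- pixel_image(counts, pixel_size, origin)
  if (blur_sigma > 0) img <- gaussian_blur(img, blur_sigma)
  attr(img, "n_dropped") <- sum(!keep)
  img
}

gaussian_blur <- function(img, sigma_nm) {
  ps <- pixel_size_of(img)
  n <- nrow(img)
  d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j) * ps)
  k <- exp(-d^2 / (2 * sigma_nm^2))
  k <- k / sum(exp(-(seq(-n, n) * ps)^2 / (2 * sigma_nm^2)))  # unit mass
  out <- k %*% unclass(img) %*% k
  pixel_image(out, ps, attr(img, "origin"))
}

fftfreq_idx <- function(n) c(0:(n / 2 - 1), -(n / 2):-1)

#' Translate image content by a (possibly fractional) pixel shift
#'
#' Shifts via the Fourier phase ramp, i.e. circularly with band-limited
#' interpolation for fractional components.
#'
#' @param img A [pixel_image()] or plain matrix.
#' @param sx,sy Shift in pixels along x (columns) and y (rows).
#' @return The shifted image.
#' @export
fourier_shift <- function(img, sx, sy) {
  m <- unclass(img)
  nr <- nrow(m); nc <- ncol(m)
  fy <- fftfreq_idx(nr); fx <- fftfreq_idx(nc)
  ph <- exp(-2i * pi * (outer(fy * sy / nr, rep(1, nc)) +
                          outer(rep(1, nr), fx * sx / nc)))
  out <- Re(fft(fft(m) * ph, inverse = TRUE)) / (nr * nc)
  if (inherits(img, "pixel_image"))
    pixel_image(out, pixel_size_of(img), attr(img, "origin"))
  else out
}

#' Rotate image content about the raster center
#'
#' Bilinear interpolation; content rotates by `+theta` degrees in the
#' package's (x right, y down rows) frame, matching coordinate rotation by
#' [structure_transform()]'s `theta`.
#'
#' @param img A [pixel_image()] or matrix.
#' @param theta Angle in degrees.
#' @return The rotated image.
#' @export
rotate_image <- function(img, theta) {
  out <- .rotate_bilinear_cpp(unclass(img), theta * pi / 180)
  if (inherits(img, "pixel_image"))
    pixel_image(out, pixel_size_of(img), attr(img, "origin"))
  else out
}

transform_image <- function(img, theta, shift) {
  out <- rotate_image(img, theta)
  if (any(shift != 0)) out <- fourier_shift(out, shift[1], shift[2])
  out
}

# Raised-cosine edge taper: 1 in the interior, falling to 0 over the outer
# `frac` of each dimension.  Suppresses wrap-around correlation artifacts.
taper_window <- function(n, frac = 0.05) {
  w <- rep(1, n)
  m <- max(1L, floor(n * frac))
  ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 0.5) / m))
  w[seq_len(m)] <- ramp
  w[n + 1 - seq_len(m)] <- ramp
  w
}

preprocess_image <- function(img, taper = TRUE, frac = 0.05) {
  m <- unclass(img)
  m <- m - mean(m)
  if (taper) {
    w <- taper_window(nrow(m), frac)
    m <- m * outer(w, taper_window(ncol(m), frac))
  }
  m
}

#' Export a pixel image as 16-bit TIFF
#'
#' Intensities are scaled to the full 16-bit range for inspection in
#' standard viewers.  Requires the `tiff` package.
#'
#' @param img A [pixel_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  m <- unclass(img)
  rng <- range(m)
  scaled <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}
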