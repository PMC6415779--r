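bilinear_sample <- function(m, y, x) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  grab <- function(yy, xx) {
    v <- array(0, dim(yy))
    ok <- yy >= 0 & yy < nr & xx >= 0 & xx < nc
    v[ok] <- m[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  grab(y0, x0) * (1 - fx) * (1 - fy) + grab(y0, x0 + 1) * fx * (1 - fy) +
    grab(y0 + 1, x0) * (1 - fx) * fy + grab(y0 + 1, x0 + 1) * fx * fy
}

#' Rotational autocorrelation of an image
#'
#' Correlates the image with itself rotated about the raster center over a
#' grid of angles; an N-fold symmetric structure produces peaks at
#' multiples of 360/N degrees.  The image is resampled once onto a polar
#' grid over the inscribed disk, mean-subtracted (area-weighted), and
#' rotations are evaluated as integer circular shifts along the angular
#' axis, so every angle suffers identical interpolation; the curve is
#' normalized so the correlation at 0 degrees is 1.
#'
#' @param img A [pixel_image()].
#' @param angle_step Grid step in degrees; must divide 360.
#' @param prominence Minimum correlation for a reported peak, as a
#'   fraction of the zero-angle value (default 0.05).
#' @return An `autocorr_curve`: list with `angle`, `correlation` and
#'   `peaks` (data frame of local maxima in (0, 180], highest first).
#' @export
rotational_autocorrelation <- function(img, angle_step = 1,
                                       prominence = 0.05) {
  stopifnot(angle_step > 0, 360 %% angle_step == 0)
  m <- unclass(img)
  cy <- (nrow(m) - 1) / 2; cx <- (ncol(m) - 1) / 2
  radii <- seq(0.5, min(cx, cy), by = 0.5)
  nth <- as.integer(360 / angle_step)
  th <- (seq_len(nth) - 1) * angle_step * pi / 180
  pol <- bilinear_sample(m, outer(sin(th), radii) + cy,
                         outer(cos(th), radii) + cx)     # angle x radius
  w <- matrix(radii, nth, length(radii), byrow = TRUE)   # area element
  f <- (pol - sum(pol * w) / sum(w)) * sqrt(w)
  ff <- stats::mvfft(f)
  corr <- rowSums(Re(stats::mvfft(ff * Conj(ff), inverse = TRUE))) / nth
  if (corr[1] <= 1e-12 * sum(pol^2 * w))
    stop("flat image: autocorrelation undefined")
  corr <- corr / corr[1]
  angles <- (seq_len(nth) - 1) * angle_step
  k <- length(angles)
  nb1 <- corr[c(k, seq_len(k - 1))]
  nb2 <- corr[c(seq_len(k - 1) + 1, 1)]
  is_peak <- corr > nb1 & corr >= nb2 & angles > 0 & angles <= 180 &
    corr >= prominence
  peaks <- data.frame(angle = angles[is_peak], height = corr[is_peak])
  peaks <- peaks[order(-peaks$height), , drop = FALSE]
  structure(list(angle = angles, correlation = corr, peaks = peaks),
            class = "autocorr_curve")
}

#' @export
print.autocorr_curve <- function(x, ...) {
  cat(sprintf("<autocorr_curve> %d angles; top peaks: %s\n",
              length(x$angle),
              if (nrow(x$peaks)) paste(sprintf("%g deg (%.3f)",
                                               utils::head(x$peaks$angle, 3),
                                               utils::head(x$peaks$height, 3)),
                                       collapse = ", ") else "none"))
  invisible(x)
}

#' Dominant non-zero symmetry peak
#'
#' @param ac An `autocorr_curve`.
#' @return Angle (degrees) of the highest local maximum in (0, 180], or
#'   `NA` if there is none.
#' @export
dominant_peak <- function(ac) {
  if (nrow(ac$peaks) == 0) return(NA_real_)
  ac$peaks$angle[1]
}

#' Angular phase of an N-fold ring image
#'
#' Resamples the image to polar coordinates and returns the phase of the
#' N-th angular Fourier harmonic — the common angular offset of the N
#' clusters — in degrees in `[0, 360/nfold)`.  Used e.g. to measure the
#' angular offset between the two rings of a two-color structure.
#'
#' @param img A [pixel_image()] centered on the ring.
#' @param nfold Symmetry order (default 9).
#' @param r_range Optional `(min, max)` radius in nm restricting the
#'   analysis to one ring of a multi-ring image.
#' @return Phase angle in degrees.
#' @export
ring_phase <- function(img, nfold = 9, r_range = NULL) {
  m <- unclass(img)
  ps <- pixel_size_of(img)
  cy <- (nrow(m) - 1) / 2; cx <- (ncol(m) - 1) / 2
  radii <- seq(0.5, min(cx, cy), by = 0.5)
  if (!is.null(r_range))
    radii <- radii[radii * ps >= r_range[1] & radii * ps <= r_range[2]]
  nth <- 720L
  th <- (seq_len(nth) - 1) * 2 * pi / nth
  pol <- bilinear_sample(m, outer(sin(th), radii) + cy,
                         outer(cos(th), radii) + cx)
  prof <- as.numeric(pol %*% radii)
  z <- sum(prof * exp(-1i * nfold * th))
  (Arg(z) * 180 / pi / nfold) %% (360 / nfold)
}

#' Fourier ring correlation resolution of aligned localizations
#'
#' Randomly halves the pooled localizations, renders each half as an
#' unsmoothed histogram image, and correlates the two Fourier transforms
#' ring by ring.  The resolution is the inverse of the spatial frequency
#' at which the (lightly smoothed) curve first drops below the threshold;
#' the split is repeated `n_splits` times and the spread over splits gives
#' the reported uncertainty.
#'
#' @param aligned A [molecule_list()] or list of molecule lists (pooled).
#' @param pixel_size Rendering pixel size in nm (default 5).
#' @param field_size Field edge in nm.
#' @param threshold Correlation threshold (default 1/7).
#' @param n_splits Number of random halvings (default 20).
#' @param duplicate_halves Degenerate mode for sanity checks: correlate
#'   the full data with itself instead of splitting; the resolution is
#'   then reported as the Nyquist limit `2 * pixel_size` with a warning.
#' @param seed Optional seed for the random splits.
#' @return An `frc_curve`: list with `spatial_frequency` (1/nm),
#'   `correlation` (curve of the last split), `threshold`, `resolution`
#'   (mean over splits, nm; `NA` with status `"unresolved"` if the curve
#'   never crosses the threshold), `resolution_sd` and `resolutions`.
#' @export
frc_resolution <- function(aligned, pixel_size = 5, field_size = 640,
                           threshold = 1 / 7, n_splits = 20,
                           duplicate_halves = FALSE, seed = NULL) {
  if (inherits(aligned, "molecule_list")) aligned <- list(aligned)
  x <- unlist(lapply(aligned, `[[`, "x"))
  y <- unlist(lapply(aligned, `[[`, "y"))
  npts <- length(x)
  if (npts < 100) stop("too few localizations for a stable FRC split")
  if (!is.null(seed)) set.seed(seed)
  pool <- molecule_list(x, y)
  if (duplicate_halves) {
    curve <- frc_curve_once(pool, pool, pixel_size, field_size)
    warning("duplicate halves: correlation is 1 by construction; ",
            "reporting the Nyquist limit")
    return(structure(list(spatial_frequency = curve$freq,
                          correlation = curve$frc, threshold = threshold,
                          resolution = 2 * pixel_size, resolution_sd = 0,
                          resolutions = 2 * pixel_size,
                          status = "degenerate"),
                     class = "frc_curve"))
  }
  res <- numeric(n_splits)
  acc <- NULL
  curve <- NULL
  for (k in seq_len(n_splits)) {
    half <- sample.int(npts, npts %/% 2)
    curve <- frc_curve_once(pool[half, , drop = FALSE],
                            pool[-half, , drop = FALSE],
                            pixel_size, field_size)
    acc <- if (is.null(acc)) curve$frc else acc + curve$frc
    res[k] <- frc_crossing(curve$freq, curve$frc_smooth, threshold)
  }
  # the headline resolution comes from the split-averaged curve (much less
  # ring-level noise); the per-split crossings give the uncertainty
  mean_curve <- acc / n_splits
  sm <- stats::filter(mean_curve, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- mean_curve[is.na(sm)]
  resolution <- frc_crossing(curve$freq, as.numeric(sm), threshold)
  ok <- is.finite(res)
  structure(list(spatial_frequency = curve$freq, correlation = mean_curve,
                 threshold = threshold,
                 resolution = resolution,
                 resolution_sd = if (sum(ok) > 1) stats::sd(res[ok]) else
                   NA_real_,
                 resolutions = res,
                 status = if (is.finite(resolution)) "ok" else
                   "unresolved"),
            class = "frc_curve")
}

#' @export
print.frc_curve <- function(x, ...) {
  if (identical(x$status, "unresolved"))
    cat("<frc_curve> unresolved (no threshold crossing)\n")
  else
    cat(sprintf("<frc_curve> resolution %.1f nm (sd %.1f, threshold %.3f)\n",
                x$resolution, x$resolution_sd %||% NA, x$threshold))
  invisible(x)
}

frc_curve_once <- function(h1, h2, pixel_size, field_size) {
  i1 <- render_image(molecule_list(h1$x, h1$y), pixel_size = pixel_size,
                     field_size = field_size, blur_sigma = 0)
  i2 <- render_image(molecule_list(h2$x, h2$y), pixel_size = pixel_size,
                     field_size = field_size, blur_sigma = 0)
  f1 <- fft(unclass(i1)); f2 <- fft(unclass(i2))
  n <- nrow(f1)
  fr <- fftfreq_idx(n)
  ring <- round(sqrt(outer(fr^2, fr^2, `+`)))
  nb <- n %/% 2
  sel <- ring >= 1 & ring < nb   # ring 0 is the DC term, trivially 1
  num <- tapply(Re(f1 * Conj(f2))[sel], ring[sel], sum)
  d1 <- tapply(abs(f1)[sel]^2, ring[sel], sum)
  d2 <- tapply(abs(f2)[sel]^2, ring[sel], sum)
  frc <- as.numeric(num / sqrt(d1 * d2))
  freq <- as.numeric(names(num)) / (n * pixel_size)
  sm <- stats::filter(frc, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- frc[is.na(sm)]
  list(freq = freq, frc = frc, frc_smooth = as.numeric(sm))
}

# first crossing below the threshold from above, linearly interpolated;
# returns the resolution 1/freq in nm, or NA if the curve never crosses.
# A curve that does not start decisively above the threshold (low-frequency
# correlation < 0.5) carries no resolution information -> NA.
frc_crossing <- function(freq, frc, threshold) {
  if (frc[1] < max(0.5, threshold)) return(NA_real_)
  above <- frc >= threshold
  idx <- which(!above & c(TRUE, above[-length(above)]) & freq > 0)
  idx <- idx[idx > 1]
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  f0 <- freq[i - 1]; f1 <- freq[i]
  v0 <- frc[i - 1]; v1 <- frc[i]
  fc <- f0 + (threshold - v0) * (f1 - f0) / (v1 - v0)
  1 / fc
}
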