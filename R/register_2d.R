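registration_result <- function(theta, shift, peak, nrmse, alpha,
                                tilt_phi = 0) {
  structure(list(theta = theta %% 360, shift = as.numeric(shift),
                 peak = peak, nrmse = nrmse, alpha = alpha,
                 tilt_phi = tilt_phi),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(paste0("<registration_result> theta %.2f deg, shift ",
                     "(%.4f, %.4f) px, tilt %.1f deg, peak %.4g, ",
                     "NRMSE %.4f\n"),
              x$theta, x$shift[1], x$shift[2], x$tilt_phi, x$peak, x$nrmse))
  invisible(x)
}

check_pair <- function(moving, reference) {
  if (!all(dim(moving) == dim(reference)))
    stop("images must have identical dimensions")
  if (sum(abs(unclass(moving))) == 0 || sum(abs(unclass(reference))) == 0)
    stop("cannot register an all-zero image")
}

# Evaluate the cross-correlation r(shift) = sum_uv CP(u,v)
# exp(2 pi i (u sx / N + v sy / M)) on a fine grid around shift0 by
# matrix-multiply DFT, returning the refined shift and peak height on the
# same scale as Re(ifft2(CP)).
upsampled_peak <- function(CP, shift0, upsample, halfwidth = 0.75) {
  m <- nrow(CP); n <- ncol(CP)
  fy <- fftfreq_idx(m); fx <- fftfreq_idx(n)
  gy <- shift0[2] + seq(-halfwidth, halfwidth, by = 1 / upsample)
  gx <- shift0[1] + seq(-halfwidth, halfwidth, by = 1 / upsample)
  ey <- exp(2i * pi * outer(gy, fy) / m)          # |gy| x m
  ex <- exp(2i * pi * outer(fx, gx) / n)          # n x |gx|
  r <- Re(ey %*% CP %*% ex) / (m * n)
  best <- arrayInd(which.max(r), dim(r))
  list(shift = c(gx[best[2]], gy[best[1]]), peak = r[best[1], best[2]])
}

finish_registration <- function(moving, reference, theta, shift, peak) {
  f <- unclass(reference)
  g <- transform_image(unclass(moving), theta, shift)
  sfg <- sum(f * g); sgg <- sum(g * g); sff <- sum(f * f)
  alpha <- if (sgg > 0) sfg / sgg else 0
  e2 <- if (sgg > 0) 1 - sfg^2 / (sff * sgg) else 1
  registration_result(theta, shift, peak, sqrt(max(0, e2)), alpha)
}

#' Subpixel translation registration by upsampled DFT cross-correlation
#'
#' Finds the translation of `moving` that maximizes its cross-correlation
#' with `reference`: a coarse estimate from the integer-pixel FFT
#' cross-correlation peak, refined on a fine grid around that peak by a
#' matrix-multiply DFT sampled at `1/upsample` pixel.
#'
#' @param moving,reference [pixel_image()]s of identical dimensions and
#'   pixel size.
#' @param upsample Integer upsampling factor (default 100, i.e. 1/100 px).
#' @param taper Apply a raised-cosine edge taper (after mean subtraction)
#'   before the FFT to suppress wrap-around artifacts.
#' @return A `registration_result` with `theta = 0`; `shift` is the
#'   translation in pixels to apply to `moving` to align it to
#'   `reference`.
#' @export
dft_translation_register <- function(moving, reference, upsample = 100,
                                     taper = TRUE) {
  check_pair(moving, reference)
  stopifnot(upsample >= 1)
  res <- register_rotated(moving, reference, angles = 0, upsample = upsample,
                          taper = taper)
  finish_registration(moving, reference, 0, res$shift, res$peak)
}

# Shared coarse search + refinement.  `angles` in degrees; returns the best
# (theta, shift, peak) without computing NRMSE.
register_rotated <- function(moving, reference, angles, upsample, taper) {
  m <- unclass(moving)
  refp <- preprocess_image(reference, taper = taper)
  Fref <- fft(refp)
  w <- if (taper) {
    outer(taper_window(nrow(m)), taper_window(ncol(m)))
  } else {
    matrix(1, nrow(m), ncol(m))
  }
  cs <- .rot_search_cpp(m, Fref, w, angles * pi / 180)
  best <- which(cs$peak == max(cs$peak))[1]  # ties -> smallest angle
  theta <- angles[best]
  shift0 <- c(cs$sx[best], cs$sy[best])
  if (upsample > 1) {
    rot <- rotate_image(m, theta)
    rot <- rot - mean(rot)
    rot <- rot * w
    CP <- Fref * Conj(fft(rot))
    up <- upsampled_peak(CP, shift0, upsample)
    list(theta = theta, shift = up$shift, peak = up$peak)
  } else {
    # the C++ ifft2 already carries the 1/(MN) factor that upsampled_peak
    # applies, so the scales match
    list(theta = theta, shift = shift0, peak = cs$peak[best])
  }
}

#' Rigid registration with exhaustive in-plane rotation search
#'
#' Rotates `moving` through the full angle grid (default 0-359 deg in 1 deg
#' steps), computes the integer-pixel cross-correlation peak at each angle,
#' selects the angle with the highest peak (ties broken toward the smallest
#' angle), and refines the translation at that angle by upsampled DFT.
#' `theta` is the rotation to apply to `moving` (about the raster center)
#' to align it to `reference`.
#'
#' @inheritParams dft_translation_register
#' @param angle_step Angle grid step in degrees; must divide 360.
#' @return A `registration_result`.
#' @export
rotation_translation_register <- function(moving, reference, angle_step = 1,
                                          upsample = 100, taper = TRUE) {
  check_pair(moving, reference)
  stopifnot(angle_step > 0, 360 %% angle_step == 0)
  angles <- seq(0, 360 - angle_step, by = angle_step)
  res <- register_rotated(moving, reference, angles, upsample, taper)
  finish_registration(moving, reference, res$theta, res$shift, res$peak)
}

#' Normalized root-mean-square error between two images
#'
#' Evaluates `E^2 = min_alpha sum(|alpha g' - f|^2) / sum(|f|^2)` where
#' `g'` is `g` rotated by `theta` and shifted by `shift`, with the
#' intensity scaling `alpha` at its closed-form least-squares optimum.
#' Minimizing E over the transform is equivalent to maximizing the
#' cross-correlation.
#'
#' @param f Reference image.
#' @param g Image being transformed.
#' @param theta Rotation in degrees applied to `g`.
#' @param shift Translation in pixels applied to `g` after rotation.
#' @return E (non-negative scalar).
#' @export
nrmse <- function(f, g, theta = 0, shift = c(0, 0)) {
  if (!all(dim(f) == dim(g))) stop("images must have identical dimensions")
  if (sum(unclass(f)^2) == 0) stop("reference image is identically zero")
  finish_registration(g, f, theta, shift, NA_real_)$nrmse
}

#' Iterative template-free alignment of an image stack
#'
#' Implements the iterative averaging loop: the first reference is the
#' unweighted average of all input images; each iteration registers every
#' image to the current reference (full rotation search + subpixel
#' translation of the *original* image, so interpolation errors do not
#' accumulate) and the average of the aligned images becomes the next
#' reference.
#'
#' @param images List of >= 2 [pixel_image()]s with identical dimensions
#'   and pixel size.
#' @param n_iterations Number of iterations (default 10).
#' @inheritParams rotation_translation_register
#' @param verbose Print per-iteration mean NRMSE.
#' @return An `alignment_run`: list with `report` (one row per structure
#'   and iteration: `structure`, `iteration`, `phi_deg`, `theta_deg`,
#'   `shift_x_px`, `shift_y_px`, `peak`, `nrmse`), `transforms` (final
#'   per-image `registration_result`s), `reference` (final average image),
#'   `mean_nrmse` per iteration, and `n_iterations`.
#' @export
iterative_align <- function(images, n_iterations = 10, angle_step = 1,
                            upsample = 100, taper = TRUE, verbose = FALSE) {
  stopifnot(length(images) >= 2, n_iterations >= 1)
  d <- dim(images[[1]])
  if (!all(vapply(images, function(im) all(dim(im) == d), logical(1))))
    stop("all images must share the same dimensions")
  origin <- attr(images[[1]], "origin") %||% c(0, 0)
  ref <- Reduce(`+`, lapply(images, unclass)) / length(images)
  ref <- pixel_image(ref, pixel_size_of(images[[1]]), origin)
  report <- vector("list", n_iterations * length(images))
  results <- vector("list", length(images))
  mean_nrmse <- numeric(n_iterations)
  row <- 0L
  for (it in seq_len(n_iterations)) {
    aligned <- vector("list", length(images))
    for (i in seq_along(images)) {
      res <- rotation_translation_register(images[[i]], ref,
                                           angle_step = angle_step,
                                           upsample = upsample,
                                           taper = taper)
      results[[i]] <- res
      aligned[[i]] <- transform_image(unclass(images[[i]]), res$theta,
                                      res$shift)
      row <- row + 1L
      ps <- pixel_size_of(images[[1]])
      report[[row]] <- data.frame(structure = i, iteration = it,
                                  phi_deg = 0, theta_deg = res$theta,
                                  shift_x_px = res$shift[1],
                                  shift_y_px = res$shift[2],
                                  shift_x_nm = res$shift[1] * ps,
                                  shift_y_nm = res$shift[2] * ps,
                                  peak = res$peak, nrmse = res$nrmse)
    }
    ref <- pixel_image(Reduce(`+`, aligned) / length(aligned),
                       pixel_size_of(images[[1]]), origin)
    mean_nrmse[it] <- mean(vapply(results, function(r) r$nrmse, numeric(1)))
    if (verbose)
      message(sprintf("iteration %d: mean NRMSE %.4f", it, mean_nrmse[it]))
  }
  structure(list(report = do.call(rbind, report), transforms = results,
                 reference = ref, mean_nrmse = mean_nrmse,
                 n_iterations = n_iterations),
            class = "alignment_run")
}

#' @export
print.alignment_run <- function(x, ...) {
  cat(sprintf(paste0("<alignment_run> %d structures, %d iterations, ",
                     "final mean NRMSE %.4f\n"),
              length(x$transforms), x$n_iterations,
              x$mean_nrmse[x$n_iterations]))
  invisible(x)
}
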