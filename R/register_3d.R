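#' Tilt-search specification for 3D alignment
#'
#' @param phi_range Length-2 degrees `(min, max)` searched about the x
#'   axis; default symmetric `c(-90, 90)`.
#' @param phi_step Grid step in degrees (default 2).
#' @param n_iterations Alignment iterations (default 5).
#' @return A `tilt_search_spec` list.
#' @export
tilt_search_spec <- function(phi_range = c(-90, 90), phi_step = 2,
                             n_iterations = 5) {
  stopifnot(length(phi_range) == 2, phi_step > 0, n_iterations >= 1,
            phi_range[2] >= phi_range[1])
  structure(list(phi_range = phi_range, phi_step = phi_step,
                 n_iterations = n_iterations), class = "tilt_search_spec")
}

#' Align tilted flat structures in 3D
#'
#' Adds an exhaustive rotation about the x axis outside the 2D rotation and
#' translation search: for every structure and every trial tilt `phi` on
#' the grid, the coordinates are rotated about the structure centroid, the
#' x-y projection is rendered, and the 2D search is run against the
#' evolving reference (the average projection, initialized from the
#' untilted projections).  The `(phi, theta, shift)` with the highest
#' correlation peak wins; exact ties go to the smallest `|phi|`.  No
#' deformation is applied.
#'
#' @param structures List of >= 2 3D [molecule_list()]s.
#' @param spec A [tilt_search_spec()].
#' @param angle_step,upsample,taper As in
#'   [rotation_translation_register()].
#' @param pixel_size,field_size,blur_sigma Rendering parameters (see
#'   [render_image()]); set `blur_sigma` to the localization precision.
#' @param verbose Print per-iteration mean NRMSE.
#' @return List with `aligned` (3D molecule lists, centered in the common
#'   frame), `transforms` (per-structure [structure_transform()]s, where
#'   `center` is the structure centroid), `run` (an `alignment_run` whose
#'   report carries `phi_deg` and a `phi_boundary` flag marking best tilts
#'   on the grid edge), and `average_image` (final reference projection).
#' @export
align_3d <- function(structures, spec = tilt_search_spec(), angle_step = 1,
                     upsample = 100, taper = TRUE, pixel_size = 10,
                     field_size = 640, blur_sigma = 15, verbose = FALSE) {
  stopifnot(length(structures) >= 2, inherits(spec, "tilt_search_spec"))
  if (!all(vapply(structures, is_3d, logical(1))))
    stop("3D alignment requires z coordinates for every structure")
  phis <- seq(spec$phi_range[1], spec$phi_range[2], by = spec$phi_step)
  if (length(phis) == 0) stop("empty tilt grid")
  phi_order <- order(abs(phis), phis)   # tie-break: smallest |phi| first
  n <- length(structures)

  cents <- lapply(structures, centroid)
  centered <- lapply(seq_len(n), function(i) {
    ml <- structures[[i]]
    ml$x <- ml$x - cents[[i]]["x"]
    ml$y <- ml$y - cents[[i]]["y"]
    ml$z <- ml$z - cents[[i]]["z"]
    ml
  })
  render1 <- function(ml) render_image(ml, pixel_size = pixel_size,
                                       field_size = field_size,
                                       blur_sigma = blur_sigma)
  # tilt grid is fixed, so render every (structure, phi) projection once
  tilted_imgs <- lapply(centered, function(ml) {
    lapply(phis, function(p) render1(rotate_about_x(ml, p,
                                                    about = c(0, 0))))
  })
  proj0 <- lapply(centered, render1)
  origin <- attr(proj0[[1]], "origin")
  ref <- pixel_image(Reduce(`+`, lapply(proj0, unclass)) / n, pixel_size,
                     origin)

  d <- dim(ref)
  w <- if (taper) outer(taper_window(d[1]), taper_window(d[2])) else
    matrix(1, d[1], d[2])
  angles <- seq(0, 360 - angle_step, by = angle_step)

  report <- list(); row <- 0L
  results <- vector("list", n)
  best_phi_idx <- integer(n)
  mean_nrmse <- numeric(spec$n_iterations)
  for (it in seq_len(spec$n_iterations)) {
    Fref <- fft(preprocess_image(ref, taper = taper))
    aligned_imgs <- vector("list", n)
    for (i in seq_len(n)) {
      best <- NULL
      for (k in phi_order) {
        cs <- .rot_search_cpp(unclass(tilted_imgs[[i]][[k]]), Fref, w,
                              angles * pi / 180)
        pk <- max(cs$peak)
        if (is.null(best) || pk > best$peak) best <- list(peak = pk, k = k)
      }
      best_phi_idx[i] <- best$k
      res <- rotation_translation_register(tilted_imgs[[i]][[best$k]], ref,
                                           angle_step = angle_step,
                                           upsample = upsample,
                                           taper = taper)
      res$tilt_phi <- phis[best$k]
      results[[i]] <- res
      aligned_imgs[[i]] <- transform_image(
        unclass(tilted_imgs[[i]][[best$k]]), res$theta, res$shift)
      row <- row + 1L
      report[[row]] <- data.frame(
        structure = i, iteration = it, phi_deg = phis[best$k],
        theta_deg = res$theta, shift_x_px = res$shift[1],
        shift_y_px = res$shift[2],
        shift_x_nm = res$shift[1] * pixel_size,
        shift_y_nm = res$shift[2] * pixel_size,
        peak = res$peak, nrmse = res$nrmse,
        phi_boundary = length(phis) > 1 &&
          best$k %in% c(which.min(phis), which.max(phis)))
    }
    ref <- pixel_image(Reduce(`+`, aligned_imgs) / n, pixel_size, origin)
    mean_nrmse[it] <- mean(vapply(results, function(r) r$nrmse, numeric(1)))
    if (verbose)
      message(sprintf("3D iteration %d: mean NRMSE %.4f", it,
                      mean_nrmse[it]))
  }

  transforms <- lapply(seq_len(n), function(i) {
    res <- results[[i]]
    structure_transform(tilt_phi = res$tilt_phi, theta = res$theta,
                        shift = res$shift * pixel_size,
                        center = unname(c(cents[[i]]["x"], cents[[i]]["y"],
                                          cents[[i]]["z"])))
  })
  aligned <- lapply(seq_len(n), function(i)
    apply_transform(structures[[i]], transforms[[i]]))
  run <- structure(list(report = do.call(rbind, report),
                        transforms = results, reference = ref,
                        mean_nrmse = mean_nrmse,
                        n_iterations = spec$n_iterations),
                   class = "alignment_run")
  list(aligned = aligned, transforms = transforms, run = run,
       average_image = ref)
}
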