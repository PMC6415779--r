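#' Deformed 2D alignment workflow
#'
#' The full 2D pipeline: robustly fit each structure's localizations to an
#' ellipse, trim radial outliers, refit, circularize every structure to
#' the cohort's average radius, render the deformed coordinates, run the
#' iterative rotation + subpixel-translation alignment, and apply the
#' final transforms back to the coordinates.  With `deform = FALSE` the
#' ellipse stage is skipped entirely, giving the rigid-registration
#' baseline.
#'
#' @param structures List of >= 2 [molecule_list()]s (one per structure).
#' @param deform Circularize before registration (default `TRUE`).
#' @param n_iterations Alignment iterations (default 10).
#' @param angle_step,upsample,taper See
#'   [rotation_translation_register()].
#' @param pixel_size,field_size,blur_sigma Rendering parameters; set
#'   `blur_sigma` to the localization precision.
#' @param outlier_k SD multiplier for [remove_outliers()] (default 1.5).
#' @param R Target common radius in nm; default the cohort's
#'   [average_radius()].
#' @param verbose Report progress.
#' @return List with `aligned` (molecule lists in the common frame),
#'   `transforms` (full per-structure [structure_transform()]s:
#'   deformation + rotation + shift), `fits` (final ellipse fits, `NULL`
#'   when `deform = FALSE`), `R`, `run` (the `alignment_run`), and
#'   `average_image` (final reference).  Structures whose ellipse fit
#'   fails are dropped with a warning and listed in `failed`.
#' @export
run_align2d <- function(structures, deform = TRUE, n_iterations = 10,
                        angle_step = 1, upsample = 100, taper = TRUE,
                        pixel_size = 10, field_size = 640, blur_sigma = 15,
                        outlier_k = 1.5, R = NULL, verbose = FALSE) {
  stopifnot(length(structures) >= 2)
  n <- length(structures)
  fits <- NULL
  failed <- integer(0)
  if (deform) {
    fits <- vector("list", n)
    cleaned <- vector("list", n)
    for (i in seq_len(n)) {
      f <- try({
        fit0 <- fit_ellipse(structures[[i]], method = "robust")
        ml1 <- remove_outliers(structures[[i]], fit0, k = outlier_k)
        list(fit = fit_ellipse(ml1, method = "robust"), ml = ml1)
      }, silent = TRUE)
      if (inherits(f, "try-error")) {
        failed <- c(failed, i)
        warning("ellipse fit failed for structure ", i, ": ",
                attr(f, "condition")$message)
      } else {
        fits[[i]] <- f$fit
        cleaned[[i]] <- f$ml
      }
    }
    keep <- setdiff(seq_len(n), failed)
    if (length(keep) < 2) stop("fewer than 2 structures survive fitting")
    fits <- fits[keep]; cleaned <- cleaned[keep]
    if (is.null(R)) R <- average_radius(fits)
    circ <- lapply(seq_along(keep), function(j)
      circularize(cleaned[[j]], fits[[j]], R))
    work <- lapply(circ, `[[`, "ml")
    pre <- lapply(circ, `[[`, "transform")
    centers <- replicate(length(keep), c(0, 0), simplify = FALSE)
  } else {
    keep <- seq_len(n)
    work <- structures
    pre <- NULL
    centers <- lapply(structures, function(ml)
      unname(centroid(ml)[c("x", "y")]))
  }
  images <- lapply(seq_along(work), function(j)
    render_image(work[[j]], pixel_size = pixel_size,
                 field_size = field_size, blur_sigma = blur_sigma,
                 center = centers[[j]]))
  run <- iterative_align(images, n_iterations = n_iterations,
                         angle_step = angle_step, upsample = upsample,
                         taper = taper, verbose = verbose)
  transforms <- lapply(seq_along(keep), function(j) {
    res <- run$transforms[[j]]
    shift_nm <- res$shift * pixel_size
    if (deform) {
      t0 <- pre[[j]]
      structure_transform(scale_x = t0$scale_x, scale_y = t0$scale_y,
                          pre_rotation = t0$pre_rotation,
                          theta = res$theta, shift = shift_nm,
                          center = t0$center)
    } else {
      structure_transform(theta = res$theta, shift = shift_nm,
                          center = centers[[j]])
    }
  })
  aligned <- lapply(seq_along(keep), function(j)
    apply_transform(structures[[keep[j]]], transforms[[j]]))
  list(aligned = aligned, transforms = transforms, fits = fits, R = R,
       run = run, average_image = run$reference, kept = keep,
       failed = failed)
}

#' 3D alignment workflow
#'
#' Thin wrapper around [align_3d()] accepting the tilt-search parameters
#' directly.  No deformation is applied (flat structures tilted in 3D are
#' treated as rigid); heterogeneity of the x-y projection is absorbed by
#' the tilt search.
#'
#' @inheritParams run_align2d
#' @param phi_range,phi_step,n_iterations Tilt grid (degrees) and
#'   iteration count; see [tilt_search_spec()].
#' @return See [align_3d()].
#' @export
run_align3d <- function(structures, phi_range = c(-90, 90), phi_step = 2,
                        n_iterations = 5, angle_step = 1, upsample = 100,
                        taper = TRUE, pixel_size = 10, field_size = 640,
                        blur_sigma = 15, verbose = FALSE) {
  align_3d(structures,
           spec = tilt_search_spec(phi_range, phi_step, n_iterations),
           angle_step = angle_step, upsample = upsample, taper = taper,
           pixel_size = pixel_size, field_size = field_size,
           blur_sigma = blur_sigma, verbose = verbose)
}

#' Simulate structures and write them to disk
#'
#' Runs [simulate_structures()] and writes one molecule-list file per
#' structure (multi-channel structures get a combined file with a channel
#' column), a ground-truth table, and a JSON run manifest sufficient to
#' reproduce the outputs.
#'
#' @param cfg A [simulation_config()] or preset name for [sim_preset()].
#' @param out_dir Output directory (created if missing).
#' @param seed Optional seed override.
#' @return The simulated structures, invisibly (see
#'   [simulate_structures()]).
#' @export
run_simulate <- function(cfg, out_dir, seed = NULL) {
  if (is.character(cfg)) cfg <- sim_preset(cfg)
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sims <- simulate_structures(cfg)
  for (s in seq_along(sims)) {
    path <- file.path(out_dir, sprintf("structure_%03d.csv", s))
    if (inherits(sims[[s]], "molecule_list")) {
      write_molecule_list(sims[[s]], path)
    } else {
      chans <- sims[[s]]
      comb <- do.call(rbind, lapply(names(chans), function(ch) {
        df <- as.data.frame(chans[[ch]])
        df$channel <- as.integer(ch)
        df
      }))
      ml <- molecule_list(comb$x, comb$y, z = comb[["z"]])
      ml$channel <- comb$channel
      write_molecule_list(ml, path)
    }
  }
  utils::write.csv(attr(sims, "ground_truth"),
                   file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  manifest <- c(unclass(cfg)[setdiff(names(unclass(cfg)), "channels")],
                list(channels = cfg$channels,
                     n_files = length(sims),
                     package_version =
                       as.character(utils::packageVersion("ringalign"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sims)
}
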