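#' Multicolor alignment by reference-channel transform transfer
#'
#' Aligns the designated reference channel of every structure (2D deformed
#' alignment or 3D tilt-search alignment) and applies each structure's
#' recovered transform verbatim to its other channels, so inter-channel
#' geometry is preserved exactly (up to the shared deformation scales in
#' 2D mode).  Generalizes to any number of channels.
#'
#' @param structures List of structures, each a named list mapping channel
#'   id to a [molecule_list()]; all channels of a structure share one
#'   coordinate frame and dimensionality.
#' @param reference_channel Name (or index) of the channel to align on -
#'   conventionally the channel with the higher resolution.
#' @param mode `"2d"` (deformed, optional) or `"3d"` (tilt search, no
#'   deformation).
#' @param deform In 2D mode, circularize on the reference channel before
#'   registration (default `TRUE`).
#' @param ... Passed to [run_align2d()] or [align_3d()]
#'   (`spec`, `angle_step`, `upsample`, rendering parameters, ...).
#' @return List with `aligned` (per structure, named per-channel aligned
#'   molecule lists), `channel_average` (per-channel pooled aligned
#'   [molecule_list()]s), `transforms`, and `run`.
#' @export
align_multicolor <- function(structures, reference_channel,
                             mode = c("2d", "3d"), deform = TRUE, ...) {
  mode <- match.arg(mode)
  stopifnot(length(structures) >= 2)
  chans <- names(structures[[1]])
  if (is.null(chans)) stop("structures must be named per-channel lists")
  reference_channel <- as.character(reference_channel)
  for (i in seq_along(structures)) {
    if (!reference_channel %in% names(structures[[i]]))
      stop("structure ", i, " is missing the reference channel")
    dims <- vapply(structures[[i]], is_3d, logical(1))
    if (length(unique(dims)) != 1)
      stop("structure ", i, " mixes 2D and 3D channels")
  }
  refs <- lapply(structures, `[[`, reference_channel)
  fit <- if (mode == "2d") {
    run_align2d(refs, deform = deform, ...)
  } else {
    align_3d(refs, ...)
  }
  aligned <- lapply(seq_along(structures), function(i) {
    lapply(structures[[i]], apply_transform, t = fit$transforms[[i]])
  })
  names(aligned) <- names(structures)
  pooled <- lapply(chans, function(ch) {
    xs <- lapply(aligned, `[[`, ch)
    molecule_list(unlist(lapply(xs, `[[`, "x")),
                  unlist(lapply(xs, `[[`, "y")),
                  z = if (is_3d(xs[[1]]))
                    unlist(lapply(xs, `[[`, "z")),
                  channel = ch)
  })
  names(pooled) <- chans
  list(aligned = aligned, channel_average = pooled,
       transforms = fit$transforms, run = fit$run)
}
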