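# Shared fixture builders.  Everything is generated in code; sizes are kept
# small so the whole suite stays fast.

# points exactly on an ellipse (no noise)
ellipse_points <- function(n = 500, a = 200, b = 150, phi = 0,
                           center = c(0, 0), noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  p <- rbind(a * cos(t), b * sin(t))
  r <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  q <- r %*% p
  molecule_list(q[1, ] + center[1] + rnorm(n, 0, noise),
                q[2, ] + center[2] + rnorm(n, 0, noise))
}

# a small asymmetric two-blob image for registration tests
two_blob_image <- function(n = 64, ps = 10) {
  ml <- molecule_list(c(rep(-120, 60), rep(100, 25), rnorm(30, 0, 40)),
                      c(rep(-40, 60), rep(130, 25), rnorm(30, 0, 40)))
  render_image(ml, pixel_size = ps, field_size = n * ps, blur_sigma = 25)
}

# ideal noise-free N-fold ring image
nfold_ring_image <- function(nfold = 9, radius = 150, ps = 10, n = 64,
                             blur = 15) {
  ang <- seq(0, 360 - 360 / nfold, by = 360 / nfold) * pi / 180
  ml <- molecule_list(rep(radius * cos(ang), each = 50),
                      rep(radius * sin(ang), each = 50))
  render_image(ml, pixel_size = ps, field_size = n * ps, blur_sigma = blur)
}

# brute-force circular cross-correlation argmax over all integer shifts
# (spatial domain, independent of the FFT path)
brute_force_shift <- function(f, g) {
  f <- unclass(f); g <- unclass(g)
  nr <- nrow(f); nc <- ncol(f)
  best <- c(-Inf, 0, 0)
  for (sy in 0:(nr - 1)) {
    gi <- g[((seq_len(nr) - 1 - sy) %% nr) + 1, , drop = FALSE]
    for (sx in 0:(nc - 1)) {
      gs <- gi[, ((seq_len(nc) - 1 - sx) %% nc) + 1, drop = FALSE]
      v <- sum(f * gs)
      if (v > best[1]) best <- c(v, sx, sy)
    }
  }
  sx <- best[2]; sy <- best[3]
  if (sx > nc / 2) sx <- sx - nc
  if (sy > nr / 2) sy <- sy - nr
  list(peak = best[1], shift = c(sx, sy))
}

# brute-force (angle, shift) search sharing only the rotation primitive
brute_force_rot_shift <- function(moving, reference, angle_step = 1) {
  angles <- seq(0, 360 - angle_step, by = angle_step)
  best <- NULL
  mref <- unclass(reference) - mean(unclass(reference))
  for (a in angles) {
    rot <- rotate_image(unclass(moving), a)
    rot <- rot - mean(rot)
    bf <- brute_force_shift(mref, rot)
    if (is.null(best) || bf$peak > best$peak)
      best <- list(peak = bf$peak, theta = a, shift = bf$shift)
  }
  best
}
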