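#' @name fit_ellipse
#' @title Fit localizations to an ellipse
#'
#' @description Fits the general conic
#' `A x^2 + B xy + C y^2 + D x + E y + F = 0` with an ellipse constraint to
#' the (x, y) coordinates of a structure and converts the algebraic
#' coefficients to geometric parameters: center, semi-axes `a >= b` and
#' major-axis orientation `phi` in `[0, pi)`.
#'
#' `least_squares` is the direct constrained least-squares conic fit
#' (stable Halir-Flusser formulation of the Fitzgibbon estimator), which
#' always returns an ellipse when one exists.  `robust` approximates a
#' least-absolute-deviations fit of the algebraic residual by iteratively
#' reweighted least squares around the same constrained solver, which makes
#' it far less sensitive to stray localizations than the plain
#' least-squares fit.
#'
#' @param ml A [molecule_list()]; at least 6 non-collinear points.
#' @param method `"robust"` (default) or `"least_squares"`.
#' @param max_iter Maximum IRLS passes for the robust method.
#' @param tol Convergence tolerance on the relative change of the conic
#'   coefficient vector.
#' @return An `ellipse_fit`: list with `center`, `a`, `b`, `phi`, `conic`
#'   (named length-6 vector), `n_used` and `method`.
#' @export
fit_ellipse <- function(ml, method = c("robust", "least_squares"),
                        max_iter = 50, tol = 1e-8) {
  stopifnot(inherits(ml, "molecule_list"))
  method <- match.arg(method)
  x <- ml$x; y <- ml$y
  if (length(x) < 6) stop("ellipse fit needs at least 6 points (structure ",
                          attr(ml, "structure_id") %||% "?", ")")
  # condition the problem: center and scale the data
  mx <- mean(x); my <- mean(y)
  s <- mean(c(stats::sd(x), stats::sd(y)))
  if (!is.finite(s) || s <= 0)
    stop("degenerate point set for ellipse fit (structure ",
         attr(ml, "structure_id") %||% "?", ")")
  u <- (x - mx) / s; v <- (y - my) / s
  w <- rep(1, length(u))
  conic_u <- direct_ellipse_fit(u, v, w, attr(ml, "structure_id"))
  if (method == "robust") {
    for (it in seq_len(max_iter)) {
      r <- conic_residual(conic_u, u, v)
      w <- 1 / pmax(abs(r), 1e-6 * stats::median(abs(r)) + 1e-300)
      newc <- direct_ellipse_fit(u, v, w, attr(ml, "structure_id"))
      if (sum(newc * conic_u) < 0) newc <- -newc
      delta <- sqrt(sum((newc - conic_u)^2))
      conic_u <- newc
      if (delta < tol) break
    }
  }
  conic <- conic_uncenter(conic_u, mx, my, s)
  geom <- conic_to_geometry(conic)
  if (is.null(geom))
    stop("fit is not an ellipse (structure ",
         attr(ml, "structure_id") %||% "?", ")")
  structure(c(geom, list(conic = conic, n_used = length(x), method = method,
                         structure_id = attr(ml, "structure_id"))),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(paste0("<ellipse_fit> center (%.2f, %.2f) nm, a = %.2f, ",
                     "b = %.2f nm, phi = %.4f rad, n = %d (%s)\n"),
              x$center[1], x$center[2], x$a, x$b, x$phi, x$n_used,
              x$method))
  invisible(x)
}

# Weighted direct constrained ellipse fit (Halir & Flusser decomposition of
# the Fitzgibbon 4AC - B^2 = 1 estimator).  Returns (A,B,C,D,E,F).
direct_ellipse_fit <- function(x, y, w, sid = NULL) {
  d1 <- cbind(x^2, x * y, y^2) * sqrt(w)
  d2 <- cbind(x, y, 1) * sqrt(w)
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)
  t3 <- try(-solve(s3, t(s2)), silent = TRUE)
  if (inherits(t3, "try-error"))
    stop("degenerate point set for ellipse fit (structure ",
         sid %||% "?", ")")
  m <- s1 + s2 %*% t3
  m <- rbind(m[3, ] / 2, -m[2, ], m[1, ] / 2)
  ev <- eigen(m)
  vec <- Re(ev$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0)
    stop("fit did not yield an ellipse (structure ", sid %||% "?", ")")
  a1 <- vec[, ok[1]]
  cvec <- c(a1, t3 %*% a1)
  cvec / sqrt(sum(cvec^2))
}

conic_residual <- function(conic, x, y) {
  conic[1] * x^2 + conic[2] * x * y + conic[3] * y^2 +
    conic[4] * x + conic[5] * y + conic[6]
}

# map a conic fitted in u = (x - mx)/s, v = (y - my)/s back to (x, y)
conic_uncenter <- function(cc, mx, my, s) {
  A <- cc[1]; B <- cc[2]; C <- cc[3]; D <- cc[4] * s; E <- cc[5] * s
  F <- cc[6] * s^2
  out <- c(A = A, B = B, C = C,
           D = D - 2 * A * mx - B * my,
           E = E - B * mx - 2 * C * my,
           F = A * mx^2 + B * mx * my + C * my^2 - D * mx - E * my + F)
  out / sqrt(sum(out^2)) * sign(out[1] + out[3])
}

#' Convert conic coefficients to geometric ellipse parameters
#'
#' @param conic Length-6 vector `(A, B, C, D, E, F)` of
#'   `A x^2 + B xy + C y^2 + D x + E y + F = 0`.
#' @return List with `center`, semi-axes `a >= b` and major-axis angle
#'   `phi` in `[0, pi)`, or `NULL` if the conic is not a real ellipse.
#' @export
conic_to_geometry <- function(conic) {
  A <- conic[1]; B <- conic[2]; C <- conic[3]
  D <- conic[4]; E <- conic[5]; F <- conic[6]
  den <- B^2 - 4 * A * C
  if (!is.finite(den) || den >= 0) return(NULL)
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  root <- sqrt((A - C)^2 + B^2)
  q1 <- num * (A + C + root)
  q2 <- num * (A + C - root)
  if (q1 < 0 || q2 < 0) return(NULL)
  ax1 <- -sqrt(q1) / den   # major semi-axis (den < 0)
  ax2 <- -sqrt(q2) / den
  a <- max(ax1, ax2); b <- min(ax1, ax2)
  if (!is.finite(a) || b <= 0) return(NULL)
  phi <- if (abs(B) < .Machine$double.eps * (abs(A) + abs(C))) {
    if (A <= C) 0 else pi / 2
  } else {
    atan2(C - A - root, B)
  }
  phi <- phi %% pi
  list(center = c(x = unname(x0), y = unname(y0)),
       a = unname(a), b = unname(b), phi = unname(phi))
}

#' Build conic coefficients from geometric ellipse parameters
#'
#' Inverse of [conic_to_geometry()]; mainly used for validation.
#'
#' @param center `(x0, y0)`.
#' @param a,b Semi-axes.
#' @param phi Major-axis angle in radians.
#' @return Named length-6 conic vector, unit norm, `A + C > 0`.
#' @export
geometry_to_conic <- function(center, a, b, phi) {
  ct <- cos(phi); st <- sin(phi)
  A <- ct^2 / a^2 + st^2 / b^2
  C <- st^2 / a^2 + ct^2 / b^2
  B <- 2 * ct * st * (1 / a^2 - 1 / b^2)
  x0 <- center[1]; y0 <- center[2]
  D <- -2 * A * x0 - B * y0
  E <- -B * x0 - 2 * C * y0
  F <- A * x0^2 + B * x0 * y0 + C * y0^2 - 1
  out <- c(A = unname(A), B = unname(B), C = unname(C), D = unname(D),
           E = unname(E), F = unname(F))
  out / sqrt(sum(out^2)) * sign(out[1] + out[3])
}

# signed radial residual: distance from the ellipse center minus the
# ellipse radius at the point's polar angle (in the ellipse frame)
radial_residuals <- function(ml, fit) {
  q <- rot2(-fit$phi) %*% rbind(ml$x - fit$center[1], ml$y - fit$center[2])
  ang <- atan2(q[2, ], q[1, ])
  re <- fit$a * fit$b / sqrt((fit$b * cos(ang))^2 + (fit$a * sin(ang))^2)
  sqrt(q[1, ]^2 + q[2, ]^2) - re
}

#' Remove localizations far from the fitted ellipse
#'
#' Computes each point's signed radial residual (distance from the ellipse
#' center minus the ellipse radius along the point's polar angle) and
#' removes points whose residual deviates from the mean residual by more
#' than `k` standard deviations.
#'
#' @param ml A [molecule_list()].
#' @param fit An `ellipse_fit` for the same structure.
#' @param k SD multiplier (default 1.5).
#' @return The cleaned molecule list, with attribute `n_removed`.
#' @export
remove_outliers <- function(ml, fit, k = 1.5) {
  stopifnot(inherits(fit, "ellipse_fit"), k > 0)
  r <- radial_residuals(ml, fit)
  # the 1e-9 nm slack keeps numerically-on-the-ellipse points (sd ~ 1e-13)
  # from being culled by floating-point noise
  keep <- abs(r - mean(r)) <= k * stats::sd(r) + 1e-9
  if (sum(keep) < 6)
    stop("outlier removal would leave fewer than 6 points (structure ",
         attr(ml, "structure_id") %||% "?", ")")
  out <- ml[keep, , drop = FALSE]
  out <- as_molecule_list(out, channel = attr(ml, "channel"),
                          structure_id = attr(ml, "structure_id"))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Circularize a structure to a common radius
#'
#' Centers the structure on the fitted ellipse center, rotates the major
#' axis onto x, and scales x by `R/a` and y by `R/b` so every structure
#' becomes a ring of radius `R`.
#'
#' @param ml A [molecule_list()].
#' @param fit Its `ellipse_fit`.
#' @param R Target common radius in nm (typically [average_radius()] of the
#'   cohort).
#' @return List with the deformed molecule list (`ml`) and the recording
#'   [structure_transform()] (`transform`).
#' @export
circularize <- function(ml, fit, R) {
  stopifnot(inherits(fit, "ellipse_fit"), R > 0)
  t <- structure_transform(scale_x = R / fit$a, scale_y = R / fit$b,
                           pre_rotation = -fit$phi, center = fit$center)
  list(ml = apply_transform(ml, t), transform = t)
}

#' Average radius of a set of ellipse fits
#'
#' @param fits List of `ellipse_fit` objects.
#' @return Mean over structures of `(a + b) / 2`, in nm.
#' @export
average_radius <- function(fits) {
  if (length(fits) == 0) stop("no fits supplied")
  mean(vapply(fits, function(f) (f$a + f$b) / 2, numeric(1)))
}
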