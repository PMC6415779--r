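test_that("exact circles and noise-free ellipses are fitted exactly", {
  ml <- ellipse_points(500, a = 150, b = 150, center = c(10, -20),
                       seed = 1)
  f <- fit_ellipse(ml, "least_squares")
  expect_equal(unname(f$center), c(10, -20), tolerance = 1e-6)
  expect_equal(f$a, 150, tolerance = 1e-6)
  expect_equal(f$b, 150, tolerance = 1e-6)

  mle <- ellipse_points(400, a = 200, b = 120, phi = 1.1,
                        center = c(-5, 30))
  for (m in c("robust", "least_squares")) {
    fe <- fit_ellipse(mle, m)
    expect_equal(unname(fe$center), c(-5, 30), tolerance = 1e-6)
    expect_equal(fe$a, 200, tolerance = 1e-5)
    expect_equal(fe$b, 120, tolerance = 1e-5)
    expect_equal(fe$phi, 1.1, tolerance = 1e-6)
  }
  # noise-free data: the two methods agree to numerical precision
  fr <- fit_ellipse(mle, "robust")
  fl <- fit_ellipse(mle, "least_squares")
  expect_equal(fr$conic, fl$conic, tolerance = 1e-6)

  expect_error(fit_ellipse(molecule_list(1:5, 1:5 * 2)), "at least 6")
  expect_error(fit_ellipse(molecule_list(1:20, 1:20 * 2 + 3)),
               "degenerate|ellipse")
})

test_that("conic and geometric parameterizations are mutually consistent", {
  cases <- list(c(200, 150, 0.5), c(180, 179, 2.9), c(90, 30, 0))
  for (cs in cases) {
    conic <- geometry_to_conic(c(12, -8), cs[1], cs[2], cs[3])
    g <- conic_to_geometry(conic)
    expect_equal(unname(g$center), c(12, -8), tolerance = 1e-9)
    expect_equal(g$a, cs[1], tolerance = 1e-9)
    expect_equal(g$b, cs[2], tolerance = 1e-9)
    expect_equal(g$phi, cs[3], tolerance = 1e-9)
  }
  # a hyperbola is rejected
  expect_null(conic_to_geometry(c(1, 0, -1, 0, 0, -1)))
  # fitted conic round-trips through the geometry
  ml <- ellipse_points(300, a = 160, b = 110, phi = 0.8, noise = 5,
                       seed = 3)
  f <- fit_ellipse(ml)
  g <- conic_to_geometry(f$conic)
  expect_equal(g$a, f$a, tolerance = 1e-6)
  expect_equal(g$phi, f$phi, tolerance = 1e-6)
})

test_that("noisy ellipse parameters are recovered within Monte-Carlo error", {
  # oracle: Monte-Carlo SE of each parameter from replicate fits
  a <- 200; b <- 150; phi <- 30 * pi / 180
  reps <- 60
  est <- t(vapply(seq_len(reps), function(i) {
    ml <- ellipse_points(500, a, b, phi, noise = 10, seed = 1000 + i)
    f <- fit_ellipse(ml, "least_squares")
    c(f$center, f$a, f$b, f$phi)
  }, numeric(5)))
  se <- apply(est, 2, stats::sd)
  bias <- colMeans(est) - c(0, 0, a, b, phi)
  # the direct conic fit carries a small O(sigma^2) shrinkage bias; it must
  # stay well below 1% of the axis lengths at this noise level
  expect_lt(abs(bias[3]) / a, 0.01)
  expect_lt(abs(bias[4]) / b, 0.01)
  expect_lt(max(abs(bias[c(1, 2, 5)])), 0.5)
  # a fresh single fit lands within 3 SD of the Monte-Carlo distribution
  f1 <- fit_ellipse(ellipse_points(500, a, b, phi, noise = 10, seed = 77))
  err <- abs(c(f1$center, f1$a, f1$b, f1$phi) - colMeans(est))
  expect_true(all(err < 3 * se + 1e-6))
})

test_that("robust fitting beats least squares under outlier contamination", {
  a <- 200; b <- 150; phi <- 30 * pi / 180
  wins <- 0L
  nrep <- 60
  for (i in seq_len(nrep)) {
    set.seed(2000 + i)
    ml <- ellipse_points(450, a, b, phi, noise = 10)
    out <- molecule_list(c(ml$x, runif(50, -300, 300)),
                         c(ml$y, runif(50, -300, 300)))
    ang_err <- function(f) {
      d <- abs(f$phi - phi) %% pi
      min(d, pi - d)
    }
    er <- ang_err(fit_ellipse(out, "robust"))
    el <- ang_err(fit_ellipse(out, "least_squares"))
    wins <- wins + (er < el)
  }
  expect_gte(wins / nrep, 0.9)
})

test_that("outlier removal trims gross outliers and keeps the Gaussian core", {
  ml <- ellipse_points(500, a = 150, b = 150)
  f <- fit_ellipse(ml)
  clean <- remove_outliers(ml, f)
  expect_equal(attr(clean, "n_removed"), 0)

  one_out <- molecule_list(c(ml$x, 1500), c(ml$y, 0))
  f2 <- fit_ellipse(one_out, "robust")
  clean2 <- remove_outliers(one_out, f2)
  expect_equal(attr(clean2, "n_removed"), 1)
  expect_equal(nrow(clean2), 500)
  expect_lt(max(abs(clean2$x)), 200)

  # Gaussian radial noise: retained fraction ~ P(|Z| <= 1.5) = 86.6%
  set.seed(5)
  big <- ellipse_points(4000, a = 150, b = 150, noise = 0)
  big <- molecule_list(big$x * (1 + rnorm(4000, 0, 0.08)),
                       big$y * (1 + rnorm(4000, 0, 0.08)))
  f3 <- fit_ellipse(big)
  clean3 <- remove_outliers(big, f3, k = 1.5)
  frac <- nrow(clean3) / 4000
  expect_lt(abs(frac - (stats::pnorm(1.5) - stats::pnorm(-1.5))), 0.03)

  # a second pass re-estimates the residual SD on the truncated sample and
  # trims again; the truncated-normal prediction is ~15% at k = 1.5
  again <- remove_outliers(clean3, f3, k = 1.5)
  expect_lt(abs(attr(again, "n_removed") / nrow(clean3) - 0.152), 0.05)
})

test_that("circularization maps the ellipse onto the target circle", {
  circ0 <- ellipse_points(400, a = 150, b = 150)
  f0 <- fit_ellipse(circ0)
  out0 <- circularize(circ0, f0, R = 150)
  r0 <- sqrt(out0$ml$x^2 + out0$ml$y^2)
  expect_equal(r0, rep(150, 400), tolerance = 1e-6)

  mle <- ellipse_points(400, a = 200, b = 120, phi = 0.6,
                        center = c(40, -10))
  fe <- fit_ellipse(mle)
  oute <- circularize(mle, fe, R = 150)
  re <- sqrt(oute$ml$x^2 + oute$ml$y^2)
  expect_equal(re, rep(150, 400), tolerance = 1e-4)
  # the long-axis vertex lands on (R, 0)
  vertex <- molecule_list(40 + 200 * cos(0.6), -10 + 200 * sin(0.6))
  vt <- apply_transform(vertex, oute$transform)
  expect_equal(c(vt$x, vt$y), c(150, 0), tolerance = 1e-4)

  # refitting the circularized noisy structure gives a/b ~ 1
  noisy <- ellipse_points(600, a = 210, b = 160, phi = 1.2, noise = 8,
                          seed = 9)
  fn <- fit_ellipse(noisy)
  cn <- circularize(noisy, fn, R = 150)
  fn2 <- fit_ellipse(cn$ml)
  expect_lte(fn2$a / fn2$b, 1.02)
})

test_that("circularize is scale-equivariant and average_radius averages axes", {
  mle <- ellipse_points(200, a = 180, b = 140, phi = 0.3, noise = 4,
                        seed = 11)
  f1 <- fit_ellipse(mle)
  o1 <- circularize(mle, f1, R = 150)
  s <- 2.5
  scaled <- molecule_list(mle$x * s, mle$y * s)
  f2 <- fit_ellipse(scaled)
  o2 <- circularize(scaled, f2, R = 150 * s)
  expect_equal(o2$ml$x, o1$ml$x * s, tolerance = 1e-6)
  expect_equal(o2$ml$y, o1$ml$y * s, tolerance = 1e-6)

  mk <- function(a, b) structure(list(a = a, b = b), class = "ellipse_fit")
  expect_equal(average_radius(list(mk(200, 100))), 150)
  expect_equal(average_radius(list(mk(100, 100), mk(200, 200))), 150)
  expect_error(average_radius(list()), "no fits")
})
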