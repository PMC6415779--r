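test_that("self-registration returns the identity", {
  img <- two_blob_image()
  r <- dft_translation_register(img, img)
  expect_equal(r$shift, c(0, 0), tolerance = 1e-9)
  expect_lt(r$nrmse, 1e-9)
  expect_equal(r$alpha, 1, tolerance = 1e-9)

  rr <- rotation_translation_register(img, img, taper = FALSE)
  expect_equal(rr$theta, 0)
  expect_equal(rr$shift, c(0, 0), tolerance = 1e-9)

  # N-fold symmetric input: equal peaks at all symmetry angles resolve to
  # the smallest angle
  ring <- nfold_ring_image()
  rsym <- rotation_translation_register(ring, ring, taper = FALSE)
  expect_equal(rsym$theta, 0)
})

test_that("integer shifts are recovered exactly and match brute force", {
  img <- two_blob_image(n = 32)
  shifted <- pixel_image(
    unclass(img)[((seq_len(32) - 1 - (-3)) %% 32) + 1,
                 ((seq_len(32) - 1 - 5) %% 32) + 1],
    pixel_size_of(img))
  # `shifted` carries the content of img moved by (+5, -3); the result is
  # the translation that undoes it
  r <- dft_translation_register(shifted, img, upsample = 1, taper = FALSE)
  expect_equal(r$shift, c(-5, 3))
  bf <- brute_force_shift(preprocess_image(img, taper = FALSE),
                          preprocess_image(shifted, taper = FALSE))
  expect_equal(r$shift, bf$shift)
})

test_that("fractional shifts are recovered to 1/100 pixel", {
  img <- two_blob_image()
  sh <- fourier_shift(img, 3.37, -1.82)
  r <- dft_translation_register(sh, img, upsample = 100, taper = FALSE)
  expect_lt(abs(r$shift[1] - (-3.37)), 0.01)
  expect_lt(abs(r$shift[2] - 1.82), 0.01)
})

test_that("rotations are recovered at the grid resolution", {
  img <- two_blob_image()
  rot <- rotate_image(img, 25)
  r <- rotation_translation_register(rot, img, taper = FALSE)
  expect_equal(r$theta, 335)
  expect_lt(max(abs(r$shift)), 0.05)

  both <- fourier_shift(rotate_image(img, 90), 4, 4)
  r2 <- rotation_translation_register(both, img, taper = FALSE)
  expect_equal(r2$theta, 270)
  moved_back <- transform_image(both, r2$theta, r2$shift)
  expect_lt(nrmse(img, moved_back), 0.05)
})

test_that("coarse rotation search equals exhaustive brute force", {
  set.seed(31)
  for (case in 1:4) {
    ml <- molecule_list(rnorm(60, 0, 60), rnorm(60, 0, 60))
    ref <- render_image(ml, pixel_size = 10, field_size = 160,
                        blur_sigma = 18)
    mov <- fourier_shift(rotate_image(ref, sample(0:359, 1)),
                         sample(-3:3, 1), sample(-3:3, 1))
    mov <- pixel_image(pmax(unclass(mov), 0), 10)
    r <- rotation_translation_register(mov, ref, angle_step = 10,
                                       upsample = 1, taper = FALSE)
    bf <- brute_force_rot_shift(mov, ref, angle_step = 10)
    expect_equal(r$theta, bf$theta)
    expect_equal(r$shift, bf$shift)
  }
})

test_that("nrmse has the Eq-4 closed form and is minimized at the correlation peak", {
  img <- two_blob_image()
  expect_equal(nrmse(img, img), 0, tolerance = 1e-12)
  zero <- pixel_image(matrix(0, 64, 64), 10)
  expect_equal(nrmse(img, zero), 1)
  expect_error(nrmse(zero, img), "zero")

  # argmin of E over integer shifts equals argmax of the correlation
  sh <- fourier_shift(img, 2, -1)
  grid <- expand.grid(sx = -3:3, sy = -3:3)
  es <- mapply(function(sx, sy) nrmse(img, sh, 0, c(sx, sy)),
               grid$sx, grid$sy)
  best <- grid[which.min(es), ]
  r <- dft_translation_register(sh, img, upsample = 1, taper = FALSE)
  expect_equal(c(best$sx, best$sy), r$shift)
})

test_that("iterative alignment has the identity fixed point and recovers known transforms", {
  img <- nfold_ring_image(nfold = 3, blur = 20)
  run <- iterative_align(rep(list(img), 4), n_iterations = 3,
                         taper = FALSE)
  expect_true(all(run$report$theta_deg == 0))
  expect_true(all(abs(run$report[, c("shift_x_px", "shift_y_px")]) < 1e-9))
  expect_equal(as.numeric(run$reference), as.numeric(img),
               tolerance = 1e-12)

  # known random transforms of one 9-fold ring are recovered modulo 40 deg
  set.seed(17)
  base <- nfold_ring_image(nfold = 9, blur = 15)
  truth_th <- runif(8, 0, 360)
  truth_sh <- matrix(sample(seq(-2, 2, 0.5), 16, TRUE), ncol = 2)
  imgs <- lapply(seq_len(8), function(i)
    pixel_image(pmax(unclass(fourier_shift(rotate_image(base, truth_th[i]),
                                           truth_sh[i, 1], truth_sh[i, 2])),
                     0), 10))
  run2 <- iterative_align(imgs, n_iterations = 10)
  rec <- vapply(run2$transforms, `[[`, numeric(1), "theta")
  resid <- (rec + truth_th) %% 40
  gauge <- atan2(mean(sin(resid * pi / 20)), mean(cos(resid * pi / 20))) *
    20 / pi
  err <- abs((resid - gauge + 20) %% 40 - 20)
  expect_lt(max(err), 1)
  # mean NRMSE is non-increasing across iterations (within tolerance)
  expect_true(all(diff(run2$mean_nrmse) < 1e-3))
})

test_that("registration is inverse-consistent", {
  # needs an angularly sharp image: broad blobs leave the correlation
  # peak flat over a few degrees and the invariant only holds to the
  # resolution the data support
  a <- nfold_ring_image(nfold = 3, blur = 12)
  m <- unclass(a)
  m[10:14, 40:44] <- m[10:14, 40:44] + 2   # break the symmetry
  a <- pixel_image(m, 10)
  b <- pixel_image(pmax(unclass(fourier_shift(rotate_image(a, 30),
                                              1.5, -2.25)), 0), 10)
  rab <- rotation_translation_register(a, b, taper = FALSE)
  rba <- rotation_translation_register(b, a, taper = FALSE)
  delta <- (rab$theta + rba$theta) %% 360
  expect_lte(min(delta, 360 - delta), 2)
  # composed shifts cancel after rotating one into the other's frame
  th <- rab$theta * pi / 180
  rot_shift <- c(cos(th) * rba$shift[1] - sin(th) * rba$shift[2],
                 sin(th) * rba$shift[1] + cos(th) * rba$shift[2])
  expect_lt(max(abs(rab$shift + rot_shift)), 0.15)
})
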