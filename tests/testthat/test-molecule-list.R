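test_that("read/write round trip preserves coordinates and columns", {
  ml <- molecule_list(x = c(1.123456789, -250.5, 3e2),
                      y = c(-0.000001, 42, 17.25),
                      z = c(5, -5, 0.125), photons = c(100, 2000, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_molecule_list(ml, path)
  back <- read_molecule_list(path)
  expect_equal(back$x, ml$x, tolerance = 1e-12)
  expect_equal(back$y, ml$y, tolerance = 1e-12)
  expect_equal(back$z, ml$z, tolerance = 1e-12)
  expect_equal(back$photons, ml$photons)

  ml2d <- molecule_list(x = 1:3, y = 4:6)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_molecule_list(ml2d, path2)
  expect_false("z_nm" %in% names(utils::read.delim(path2)))
  expect_false(is_3d(read_molecule_list(path2)))
})

test_that("reader converts units and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm", "0.1,0.2", "0.3,0.4"), path)
  um <- read_molecule_list(path, format_spec = list(x = "x_nm", y = "y_nm",
                                                    units = "um"))
  expect_equal(um$x, c(100, 300))

  writeLines(c("x_nm,y_nm", "1,2", "3,NaN"), path)
  expect_error(read_molecule_list(path), "row 2")
  writeLines("x_nm,y_nm", path)
  expect_error(read_molecule_list(path), "empty")
})

test_that("rendering conserves mass and places points correctly", {
  one <- molecule_list(0, 0)
  img <- render_image(one, pixel_size = 10, field_size = 160,
                      blur_sigma = 0)
  expect_equal(sum(img), 1)
  expect_equal(dim(img), c(16, 16))
  # field center: pixel centers at -75, ..., -5, 5, ... so (0,0) rounds
  # into the pixel centered at (5, 5) -> index [9, 9]
  expect_equal(which(unclass(img) != 0), 8 * 16 + 9)

  k <- molecule_list(rep(2, 7), rep(-1, 7))
  imgk <- render_image(k, pixel_size = 10, field_size = 160, blur_sigma = 0)
  expect_equal(max(imgk), 7)
  expect_equal(sum(imgk), 7)

  # blur preserves mass away from edges
  imgb <- render_image(k, pixel_size = 10, field_size = 320,
                       blur_sigma = 12)
  expect_equal(sum(imgb), 7, tolerance = 1e-6)

  expect_error(render_image(molecule_list(1e6, 1e6), field_size = 640),
               "outside")
})

test_that("radial intensity profile of a rendered ring peaks at the ring radius", {
  set.seed(42)
  t <- runif(500, 0, 2 * pi)
  ml <- molecule_list(150 * cos(t), 150 * sin(t))
  img <- render_image(ml, pixel_size = 10, field_size = 640, blur_sigma = 0)
  n <- nrow(img)
  ctr <- (n - 1) / 2
  rad <- round(sqrt(outer((seq_len(n) - 1 - ctr)^2,
                          (seq_len(n) - 1 - ctr)^2, `+`)))
  prof <- tapply(as.numeric(img), as.numeric(rad), mean)
  peak_r <- as.numeric(names(prof))[which.max(prof)] * 10
  expect_lt(abs(peak_r - 150), 10 / 2 + 5)
})

test_that("apply_transform follows the documented rotation conventions", {
  ml <- molecule_list(100, 0)
  out <- apply_transform(ml, structure_transform(theta = 90))
  expect_equal(c(out$x, out$y), c(0, 100), tolerance = 1e-9)

  ml3 <- molecule_list(0, 100, z = 0)
  out3 <- apply_transform(ml3, structure_transform(tilt_phi = 90))
  expect_equal(c(out3$x, out3$y, out3$z), c(0, 0, 100), tolerance = 1e-9)

  ident <- apply_transform(ml3, structure_transform())
  expect_equal(as.data.frame(ident), as.data.frame(ml3))

  expect_error(apply_transform(ml, structure_transform(tilt_phi = 10)),
               "requires z")
})

test_that("transforms invert, preserve rigid distances, and scale distances", {
  set.seed(7)
  ml <- molecule_list(rnorm(40, 0, 100), rnorm(40, 0, 100),
                      z = rnorm(40, 0, 50))
  cases <- list(
    structure_transform(theta = 33, shift = c(12, -7), center = c(5, 5)),
    structure_transform(scale_x = 1.4, scale_y = 0.7, pre_rotation = 0.4,
                        theta = 290, shift = c(-30, 4), center = c(-10, 2)),
    structure_transform(pre_rotation = -1.1, tilt_phi = 25, theta = 110,
                        shift = c(3, 8))
  )
  for (t in cases) {
    rt <- apply_transform(apply_transform(ml, t), invert_transform(t))
    expect_equal(rt$x, ml$x, tolerance = 1e-9)
    expect_equal(rt$y, ml$y, tolerance = 1e-9)
    expect_equal(rt$z, ml$z, tolerance = 1e-9)
  }

  d0 <- dist(cbind(ml$x, ml$y))
  rigid <- apply_transform(ml, cases[[1]])
  expect_equal(as.numeric(dist(cbind(rigid$x, rigid$y))), as.numeric(d0),
               tolerance = 1e-9)
  sc <- apply_transform(ml, structure_transform(scale_x = 2, scale_y = 2))
  expect_equal(as.numeric(dist(cbind(sc$x, sc$y))), 2 * as.numeric(d0),
               tolerance = 1e-9)
})

test_that("rotate_about_x matches the x-axis rotation matrix", {
  ml <- molecule_list(c(0, 3), c(1, 0), z = c(0, 0))
  out <- rotate_about_x(ml, 90, about = c(0, 0))
  expect_equal(out$x, c(0, 3))
  expect_equal(out$y, c(0, 0), tolerance = 1e-12)
  expect_equal(out$z, c(1, 0), tolerance = 1e-12)

  half <- rotate_about_x(ml, 180, about = c(0, 0))
  expect_equal(half$y, -ml$y, tolerance = 1e-12)
  expect_equal(half$z, -ml$z, tolerance = 1e-12)

  expect_equal(as.data.frame(rotate_about_x(ml, 0)), as.data.frame(ml))
  expect_error(rotate_about_x(molecule_list(1, 2), 10), "3D")
})

test_that("channel splitting keeps per-channel coordinates together", {
  ml <- molecule_list(1:6, 6:1)
  ml$channel <- c(1, 2, 1, 2, 1, 2)
  sp <- split_channels(ml)
  expect_named(sp, c("1", "2"))
  expect_equal(sp[["1"]]$x, c(1, 3, 5))
  expect_equal(sp[["2"]]$y, c(5, 3, 1))
})
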