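# Log-radius discretisation, log-polar transform and polygon conversions.

test_that("radiusToBin matches its defining formula and constraints", {
  expect_identical(radiusToBin(50, 256, 50), 128L)   # r_init maps to M/2
  expect_identical(radiusToBin(1, 256, 50), 0L)
  expect_identical(radiusToBin(10, 256, 50), 75L)    # floor(128*ln10/ln50)
  expect_error(radiusToBin(0.5), "not representable")
  # monotone non-decreasing in r
  set.seed(11)
  r <- sort(runif(200, 1, 400))
  b <- radiusToBin(r, 256, 50)
  expect_true(all(diff(b) >= 0))
  expect_true(all(b >= 0 & b <= 255))
})

test_that("binToRadius inverts the discretisation", {
  expect_equal(binToRadius(128, 256, 50), 50)
  expect_equal(binToRadius(0, 256, 50), 1)
  expect_identical(radiusToBin(binToRadius(0:255, 256, 50), 256, 50), 0:255)
  expect_error(binToRadius(256, 256, 50), "out of range")
  # finer resolution at smaller radii: bin widths strictly increase
  w <- diff(binToRadius(0:255, 256, 50))
  expect_true(all(diff(w) > 0))
})

test_that("logPolarTransform samples constants, circles and boundaries", {
  f <- matrix(7, 64, 64)
  lp <- logPolarTransform(f, c(31.5, 31.5), 32, 64, 20)
  interior <- radiusToBin(25, 64, 20)            # columns within the frame
  expect_true(all(abs(lp[, 1:interior] - 7) < 1e-12))
  # bright circle of radius 50: every row peaks at bin 128
  size <- 161
  ctr <- c(80, 80)
  x <- matrix(rep(0:(size - 1), each = size), size, size)
  y <- matrix(rep(0:(size - 1), size), size, size)
  d <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
  img <- exp(-(d - 50)^2 / 2)                    # ridge at radius 50
  lp <- logPolarTransform(img, ctr, 128, 256, 50)
  peaks <- apply(lp, 1, which.max) - 1L
  expect_true(all(abs(peaks - 128) <= 1))
  # out-of-image samples take fill value 0
  lp0 <- logPolarTransform(matrix(3, 16, 16), c(0, 0), 8, 32, 10)
  expect_equal(lp0[5, 32], 0)                    # angle pi, far radius
  expect_error(logPolarTransform(f, c(-2, 5), 8, 32, 10), "outside")
})

test_that("contourToRadial recovers circles, ellipses and is rotation-proof", {
  # vertex angles aligned with the 16 ray angles so intersections are exact
  ang <- 2 * pi * (0:159) / 160
  circ <- cbind(50 * cos(ang), 50 * sin(ang))
  bins <- contourToRadial(circ, c(0, 0), 16, 256, 50)
  expect_true(all(bins == 128L))
  # cyclic rotation of the vertex list changes nothing
  rot <- circ[c(51:160, 1:50), ]
  expect_identical(contourToRadial(rot, c(0, 0), 16, 256, 50), bins)
  # axis-aligned ellipse: bins at angles 0 and pi/2 match the semi-axes
  ell <- cbind(60 * cos(ang), 40 * sin(ang))
  eb <- contourToRadial(ell, c(0, 0), 4, 256, 50)
  expect_identical(eb[1], radiusToBin(60, 256, 50))
  expect_identical(eb[2], radiusToBin(40, 256, 50))
  expect_error(contourToRadial(circ, c(200, 0), 8, 256, 50), "centre")
})

test_that("radialToCartesian closes the loop with contourToRadial", {
  v <- radialToCartesian(rep(128L, 4), c(0, 0), 256, 50)
  expect_equal(unname(v),
               rbind(c(50, 0), c(0, 50), c(-50, 0), c(0, -50)),
               tolerance = 1e-9)
  set.seed(4)
  # roundtrip identity on smooth-enough radial contours
  bins <- as.integer(round(120 + cumsum(rnorm(64, 0, 1))))
  bins <- pmin(pmax(bins, 0L), 255L)
  poly <- radialToCartesian(bins, c(10, -3), 256, 50)
  expect_identical(contourToRadial(poly, c(10, -3), 64, 256, 50), bins)
})

test_that("log-polar transform localises a rasterized annulus boundary", {
  size <- 121; ctr <- c(60, 60)
  x <- matrix(rep(0:(size - 1), each = size), size, size)
  y <- matrix(rep(0:(size - 1), size), size, size)
  d <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
  img <- (d <= 30) * 1 + (d > 30 & d <= 45) * 0.3   # annulus on empty field
  lp <- logPolarTransform(img, ctr, 64, 128, 30)
  edges <- apply(lp, 1, function(row) which.max(abs(diff(row))))
  truthBin <- radiusToBin(30, 128, 30)
  expect_true(mean(abs(edges - truthBin) <= 1) > 0.95)
})
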