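test_that("extract_faz finds a carved disc and errors on full fields", {
  expect_error(extract_faz(matrix(1L, 64, 64)), "no FAZ found")
  n <- 160
  m <- matrix(1L, n, n)
  m[disc_mask(n, 50) == 1L] <- 0L
  fz <- extract_faz(m, max_bridge_px = 0L)
  expect_lt(abs(fz$area_px - pi * 50^2) / (pi * 50^2), 0.02)
  expect_false(fz$touches_border)
})

test_that("a FAZ reaching the raster border is flagged unreliable", {
  n <- 64
  m <- matrix(1L, n, n)
  m[, 25:40] <- 0L  # open channel through the border
  fz <- extract_faz(m, max_bridge_px = 0L)
  expect_true(fz$touches_border)
})

test_that("closing seals capillary gaps before extraction", {
  n <- 120
  m <- matrix(1L, n, n)
  m[disc_mask(n, 30) == 1L] <- 0L
  # cut a 3-px corridor from the disc to the outside
  m[59:61, 1:90] <- 0L
  open <- extract_faz(m, max_bridge_px = 0L)
  sealed <- extract_faz(m, max_bridge_px = 2L)
  expect_true(open$touches_border)               # leaked out the corridor
  expect_gt(open$area_px, pi * 30^2 + 80)
  expect_false(sealed$touches_border)
  expect_lt(abs(sealed$area_px - pi * 30^2) / (pi * 30^2), 0.05)
})

test_that("extracted region overlaps the generator truth ellipse (Jaccard)", {
  for (s in c(2, 9)) {
    sim <- simulate_angiogram(size = 224, faz_semi_axes_px = c(30, 24),
                              seed = s)
    mask <- binarize(sim$angiogram)
    fz <- extract_faz(mask)
    tr <- sim$truth$faz_ellipse
    n <- nrow(mask$pixels)
    ell <- outer(1:n, 1:n, function(x, y)
      ((x - tr$center_px[1]) / tr$semi_axes_px[1])^2 +
        ((y - tr$center_px[2]) / tr$semi_axes_px[2])^2 < 1)
    jac <- sum(fz$region & ell) / sum(fz$region | ell)
    expect_gte(jac, 0.95)
  }
})

test_that("disc metrics match the analytic circle", {
  reg <- disc_mask(256, 100)
  fm <- faz_shape_metrics(reg, scale_um_per_px = 10)
  expect_lt(abs(fm$area_mm2 - pi * 1.0^2) / pi, 0.02)   # r = 1 mm
  expect_lt(abs(fm$perimeter_mm - 2 * pi) / (2 * pi), 0.02)
  expect_lt(abs(fm$acircularity - 1), 0.02)
  expect_lt(fm$eccentricity, 0.1)
  expect_lt(abs(fm$axis_ratio - 1), 0.02)
  expect_lt(abs(fm$diameter_max_mm - 2) / 2, 0.03)
  expect_lt(abs(fm$diameter_min_mm - 2) / 2, 0.03)
})

test_that("acircularity ~ 1 with eccentricity ~ 0 down to radius 30", {
  for (r in c(30, 60)) {
    fm <- faz_shape_metrics(disc_mask(2 * r + 40, r), 10)
    expect_lt(abs(fm$acircularity - 1), 0.02)
    expect_lt(fm$eccentricity, 0.15)
  }
})

test_that("a = 2b ellipse: axis ratio 2, eccentricity sqrt(3)/2", {
  reg <- ellipse_mask(256, 80, 40)
  fm <- faz_shape_metrics(reg, 10)
  expect_lt(abs(fm$axis_ratio - 2), 0.03)
  expect_lt(abs(fm$eccentricity - sqrt(3) / 2), 0.01)
  expect_lt(abs(fm$diameter_max_mm - 1.6) / 1.6, 0.03)
  expect_lt(abs(fm$diameter_min_mm - 0.8) / 0.8, 0.03)
})

test_that("random convex polygons match the vertex-geometry oracle", {
  set.seed(17)
  for (rep in 1:4) {
    n <- 220
    k <- sample(5:9, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    rad <- runif(k, 55, 95)
    vx <- cbind((n + 1) / 2 + rad * cos(ang), (n + 1) / 2 + rad * sin(ang))
    # rasterize by point-in-polygon test (crossing number)
    inpoly <- function(px, py) {
      cnt <- 0
      for (i in seq_len(k)) {
        j <- if (i == k) 1 else i + 1
        if ((vx[i, 2] > py) != (vx[j, 2] > py)) {
          xint <- vx[i, 1] + (py - vx[i, 2]) / (vx[j, 2] - vx[i, 2]) *
            (vx[j, 1] - vx[i, 1])
          if (px < xint) cnt <- cnt + 1
        }
      }
      cnt %% 2 == 1
    }
    reg <- matrix(0L, n, n)
    for (r in 1:n) for (c in 1:n) if (inpoly(r, c)) reg[r, c] <- 1L
    fm <- faz_shape_metrics(reg, 1000)  # 1 px = 1 mm for direct comparison
    expect_lt(abs(fm$area_mm2 - oracle_polygon_area(vx)) /
                oracle_polygon_area(vx), 0.03)
    expect_lt(abs(fm$perimeter_mm - oracle_polygon_perimeter(vx)) /
                oracle_polygon_perimeter(vx), 0.03)
    fer <- oracle_polygon_feret(vx)
    expect_lt(abs(fm$diameter_max_mm - fer["dmax"]) / fer["dmax"], 0.03)
    expect_lt(abs(fm$diameter_min_mm - fer["dmin"]) / fer["dmin"], 0.05)
  }
})

test_that("metrics scale linearly in the pixel scale", {
  reg <- ellipse_mask(128, 40, 25)
  a <- faz_shape_metrics(reg, 10)
  b <- faz_shape_metrics(reg, 20)
  expect_equal(b$area_mm2, 4 * a$area_mm2)
  expect_equal(b$perimeter_mm, 2 * a$perimeter_mm)
  expect_equal(b$diameter_max_mm, 2 * a$diameter_max_mm)
  expect_equal(b$diameter_min_mm, 2 * a$diameter_min_mm)
  expect_equal(b$axis_ratio, a$axis_ratio)
  expect_equal(b$eccentricity, a$eccentricity)
  expect_equal(b$acircularity, a$acircularity)
})

test_that("degenerate inputs error", {
  expect_error(faz_shape_metrics(matrix(0L, 10, 10), 10), "empty")
})
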