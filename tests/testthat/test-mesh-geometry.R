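# Surface area, enclosed volume, SA:V and their invariants.

test_that("area and volume match closed forms for cube, sphere, spheroid", {
  cb <- cubeMesh(1)
  expect_equal(surfaceArea(cb), 6)
  expect_equal(enclosedVolume(cb), 1)

  s <- icosphere(4, 1)
  expect_lt(abs(surfaceArea(s) - 4 * pi) / (4 * pi), 0.002)
  expect_lt(abs(enclosedVolume(s) - 4 * pi / 3) / (4 * pi / 3), 0.003)
  expect_lt(abs(saToV(icosphere(4, 2)) - 3 / 2) / (3 / 2), 0.005)

  # prolate spheroid a = b = 2, c = 4: analytic area from the closed form
  a <- 2; c <- 4; e <- sqrt(1 - (a / c)^2)
  analyticArea <- 2 * pi * a^2 * (1 + (c / (a * e)) * asin(e))
  v <- meshVertices(icosphere(4, 1))
  sp <- TriangleMesh(cbind(v[, 1] * a, v[, 2] * a, v[, 3] * c),
                     meshFaces(icosphere(4, 1)))
  expect_lt(abs(surfaceArea(sp) - analyticArea) / analyticArea, 0.005)
  expect_lt(abs(enclosedVolume(sp) - 4 / 3 * pi * a^2 * c) /
              (4 / 3 * pi * a^2 * c), 0.005)
})

test_that("scaling laws and rigid invariance hold on random meshes", {
  set.seed(7)
  for (i in 1:3) {
    m <- noisySphere(runif(1, 2, 4), 0.15, subdivisions = 3, seed = i)
    a0 <- surfaceArea(m); v0 <- enclosedVolume(m); r0 <- saToV(m)
    for (k in c(0.5, 2)) {
      mk <- scaleMesh(m, k)
      expect_equal(surfaceArea(mk), a0 * k^2, tolerance = 1e-9)
      expect_equal(enclosedVolume(mk), v0 * k^3, tolerance = 1e-9)
      expect_equal(saToV(mk), r0 / k, tolerance = 1e-9)
    }
    mt <- translateMesh(m, c(11.3, -42.7, 5.9))
    expect_equal(enclosedVolume(mt), v0, tolerance = 1e-9)
    expect_equal(surfaceArea(mt), a0, tolerance = 1e-9)
  }
})

test_that("broken meshes are rejected with diagnostics", {
  s <- icosphere(2, 1)
  # remove one face -> open surface
  open <- TriangleMesh(meshVertices(s), meshFaces(s)[-1, , drop = FALSE],
                       validate = FALSE)
  expect_error(surfaceArea(open), "watertight")
  # inward orientation -> instructs re-orientation, never silently fixed
  expect_error(enclosedVolume(reorientMesh(s)), "inward-oriented")
  # degenerate face: collapse one vertex onto another
  v <- meshVertices(s); f <- meshFaces(s)
  v[f[1, 2], ] <- v[f[1, 1], ]
  expect_error(surfaceArea(TriangleMesh(v, f, validate = FALSE)), "degenerate")
})

test_that("SA:V reproduces printed table rows and the sphere closed form", {
  # a mesh realizing the printed Pat1L row (V 135.5, SA 367.3) has
  # SA:V 2.71, consistent with the printed 2.7
  m <- spheroidMatching(135.5, 367.3, subdivisions = 3)
  expect_equal(saToV(m), 367.3 / 135.5, tolerance = 0.01)
  expect_equal(round(saToV(m), 1), 2.7)
  # ellipsoid row: 180.2 / 212.5 = 0.848
  expect_equal(saToV(spheroidMatching(212.5, 180.2)), 0.848, tolerance = 0.005)
  # sphere: SA:V = 3/r
  expect_lt(abs(saToV(icosphere(4, 2.5)) - 3 / 2.5) / (3 / 2.5), 0.005)
})

test_that("smoothing preserves volume, cannot inflate area, identity at 0", {
  cb <- cubeMesh(2)
  sm <- smoothMesh(cb, 20)
  expect_lte(surfaceArea(sm), 6 * 4 + 1e-6)
  expect_equal(enclosedVolume(sm), 8, tolerance = 1e-9)

  ns <- noisySphere(3, 0.1)
  smn <- smoothMesh(ns, 20)
  expect_lt(surfaceArea(smn), surfaceArea(ns))          # strictly decreases
  expect_lt(abs(surfaceArea(smn) - 4 * pi * 9) / (4 * pi * 9), 0.005)
  expect_equal(enclosedVolume(smn), enclosedVolume(ns), tolerance = 1e-6)

  expect_identical(meshVertices(smoothMesh(ns, 0)), meshVertices(ns))
  expect_error(smoothMesh(ns, 101), "strength")
})

test_that("spheroid matching reproduces printed (V, SA) and rejects infeasible", {
  m <- spheroidMatching(212.5, 180.2)
  expect_lt(abs(enclosedVolume(m) - 212.5) / 212.5, 0.005)
  expect_lt(abs(surfaceArea(m) - 180.2) / 180.2, 0.005)
  expect_equal(saToV(m), 0.848, tolerance = 0.005)

  # degenerate case: area of the sphere itself -> eccentricity ~ 0
  r <- 2
  sphere <- spheroidMatching(4 / 3 * pi * r^3, 4 * pi * r^2)
  v <- meshVertices(sphere)
  expect_lt(abs(max(abs(v[, 3])) / max(abs(v[, 1])) - 1), 0.02)

  # (36*pi*100^2)^(1/3) = 104.19: area 50 is infeasible
  expect_error(spheroidMatching(100, 50), "infeasible")
})

test_that("voxelization is exact for grid-aligned cubes and converges", {
  g <- voxelize(cubeMesh(1), spacing = 1, padding = 5)
  vals <- gridValues(g)
  expect_equal(sum(vals) * voxelVolumeMl(g), 1, tolerance = 1e-9)
  expect_true(all(vals %in% c(0, 1) | (vals > 1 - 1e-9) | (vals < 1e-9)))

  s <- icosphere(4, 3.7)
  truth <- enclosedVolume(s)
  g1 <- voxelize(s, spacing = 1, padding = 8)
  err1 <- abs(sum(gridValues(g1)) * voxelVolumeMl(g1) - truth) / truth
  expect_lt(err1, 0.005)
  expect_lt(abs(sum(gridValues(g1)) * voxelVolumeMl(g1) -
                  4 / 3 * pi * 3.7^3) / (4 / 3 * pi * 3.7^3), 0.005)
  # halving the spacing must not worsen the volume error
  g2 <- voxelize(s, spacing = 2, padding = 8)
  err2 <- abs(sum(gridValues(g2)) * voxelVolumeMl(g2) - truth) / truth
  expect_lte(err1, err2 + 1e-12)
  expect_error(voxelize(s, spacing = 0.1, padding = 200), "grid extent")
})
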