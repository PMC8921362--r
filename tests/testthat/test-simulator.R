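# Activity maps, PSF blurring and the count-noise surrogate.

test_that("activity maps have the published plateaus and conserve activity", {
  sp <- PhantomSpec("s", "ellipsoid", icosphere(3, 2.5))
  cfgInf <- acquisitionConfig(targetConc = 102.5, backgroundConc = 0)
  vol <- buildActivityMap(sp, cfgInf, padding = 12)
  vals <- gridValues(vol)
  expect_equal(max(vals), 102.5)
  expect_equal(min(vals), 0)
  expect_equal(vals[1, 1, 1], 0)                 # exterior exactly cold

  cfg10 <- acquisitionConfig(targetConc = 100.7, backgroundConc = 10.4,
                             tbrLabel = "10:1")
  v10 <- gridValues(buildActivityMap(sp, cfg10, padding = 12))
  expect_equal(max(v10), 100.7)
  expect_equal(v10[1, 1, 1], 10.4)
  expect_equal(max(v10) / v10[1, 1, 1], 9.68, tolerance = 0.001)

  # conservation by construction: target*V + background*(domain - V - wall);
  # the background share is read back from the map given the cavity occupancy
  occ <- voxelize(phantomMesh(sp), spacing = 1, padding = 12)
  vml <- voxelVolumeMl(occ)
  cavVol <- sum(gridValues(occ)) * vml
  bgfrac <- (v10 - 100.7 * gridValues(occ)) / 10.4
  wallVol <- prod(dim(v10)) * vml - cavVol - sum(bgfrac) * vml
  expect_lt(abs(sum(v10) * vml -
                  (100.7 * cavVol + 10.4 * (prod(dim(v10)) * vml - cavVol -
                                              wallVol))) /
              (sum(v10) * vml), 0.005)
  # the inactive wall is a ~1.2 mm skin of the cavity surface
  expect_equal(wallVol, surfaceArea(phantomMesh(sp)) * 0.12,
               tolerance = 0.2)
})

test_that("PSF blur conserves counts, is identity at fwhm 0, bounded", {
  sp <- PhantomSpec("s", "ellipsoid", icosphere(3, 2.5))
  cfg <- acquisitionConfig(psfFwhm = 9.5)
  vol <- buildActivityMap(sp, cfg, padding = 30)
  blurred <- applyPSF(vol, 9.5)
  expect_lt(abs(sum(gridValues(blurred)) - sum(gridValues(vol))) /
              sum(gridValues(vol)), 1e-6)
  expect_identical(applyPSF(vol, 0), vol)
  # blur cannot exceed the input extrema
  expect_lte(max(gridValues(blurred)), max(gridValues(vol)))
  expect_gte(min(gridValues(blurred)), 0)
  # strict spill-out: a cold-background phantom never reaches the plateau
  expect_lt(max(gridValues(blurred)), 102.5)
  # insufficient padding is rejected
  tight <- buildActivityMap(sp, cfg, padding = 4)
  expect_error(applyPSF(tight, 20), "padding")
})

test_that("blurred slab mean matches the numeric erf-profile oracle", {
  # 1-D oracle: mean over the slab of the blurred profile
  # f(z) = pnorm(z/s) + pnorm((T - z)/s) - 1, integrated numerically
  T <- 20; fwhm <- 9.5
  s <- fwhm / (2 * sqrt(2 * log(2)))
  oracle <- stats::integrate(function(z) pnorm(z / s) + pnorm((T - z) / s) - 1,
                             0, T, rel.tol = 1e-10)$value / T
  slab <- slabVolume(thickness = T, value = 100, n = c(15, 15, 121))
  blurred <- applyPSF(slab, fwhm)
  mid <- gridValues(blurred)[8, 8, ]
  inside <- gridValues(slab)[8, 8, ] > 0
  expect_equal(mean(mid[inside]) / 100, oracle, tolerance = 1e-3)
})

test_that("TBR superposition: noiseless image is linear in background fraction", {
  sp <- PhantomSpec("s", "ellipsoid", icosphere(3, 2), wallThickness = 0)
  mk <- function(bg, label) acquisitionConfig(psfFwhm = 8, voxel = 2,
                                              targetConc = 100,
                                              backgroundConc = bg,
                                              tbrLabel = label,
                                              wallEnabled = FALSE)
  cold <- simulateAcquisition(sp, mk(0, "infinity"), padding = 26)
  f <- 0.2
  mixed <- simulateAcquisition(sp, mk(20, "5:1"), padding = 26)
  uniform <- 100  # blurring preserves a uniform field
  lhs <- gridValues(mixed)
  rhs <- (1 - f) * gridValues(cold) + f * uniform
  expect_lt(max(abs(lhs - rhs)) / 100, 1e-6)
})

test_that("noise surrogate is seeded, unbiased, and off by default", {
  sp <- PhantomSpec("s", "ellipsoid", icosphere(2, 2))
  cfgOff <- acquisitionConfig(voxel = 2)
  vol <- simulateAcquisition(sp, cfgOff, padding = 30)
  expect_identical(addNoise(vol, cfgOff), vol)

  cfgOn <- acquisitionConfig(voxel = 2, noiseEnabled = TRUE,
                             countsPerKbqMlVoxel = 5, seed = 11L)
  n1 <- addNoise(vol, cfgOn)
  n2 <- addNoise(vol, cfgOn)
  expect_identical(gridValues(n1), gridValues(n2))

  # mean over repeated draws of a uniform volume returns the input level
  uni <- new("ActivityVolume", origin = c(0, 0, 0), spacing = c(2, 2, 2),
             values = array(100, c(10, 10, 10)))
  ms <- vapply(1:100, function(s) {
    cfg <- acquisitionConfig(voxel = 2, noiseEnabled = TRUE,
                             countsPerKbqMlVoxel = 5, seed = s)
    mean(gridValues(addNoise(uni, cfg)))
  }, numeric(1))
  expect_lt(abs(mean(ms) - 100), 3 * sqrt(var(ms) / 100) + 0.05)
})

test_that("simulation is bit-reproducible for identical config and seed", {
  sp <- PhantomSpec("s", "ellipsoid", icosphere(2, 2))
  cfg <- acquisitionConfig(voxel = 2, noiseEnabled = TRUE, seed = 3L)
  a <- simulateAcquisition(sp, cfg, padding = 30)
  b <- simulateAcquisition(sp, cfg, padding = 30)
  expect_identical(gridValues(a), gridValues(b))
})
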