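# Volume-matched isocontour VOIs and the recovery-coefficient statistic.

test_that("volume matching recovers a binary mask exactly", {
  g <- voxelize(cubeMesh(2), spacing = 1, padding = 5)
  voi <- volumeMatchedVOI(g, targetVolume = 8)
  expect_equal(sum(gridValues(voi)) * voxelVolumeMl(voi), 8, tolerance = 0.005)
  expect_error(volumeMatchedVOI(g, 10 * prod(dim(gridValues(g))) / 1000),
               "unattainable")
})

test_that("threshold for a blurred sphere sits near half the plateau", {
  s <- icosphere(4, 3.7)
  sp <- PhantomSpec("s", "ellipsoid", s)
  cfg <- acquisitionConfig(psfFwhm = 9.5)
  img <- simulateAcquisition(sp, cfg, padding = 30)
  voi <- volumeMatchedVOI(img, targetVolume = enclosedVolume(s))
  # erf radial profile: the 0.5-of-plateau level set lies at the true
  # radius (curvature and the sub-plateau maximum shift it slightly)
  expect_lt(abs(voi@threshold - 0.5), 0.06)
  expect_equal(sum(gridValues(voi)) * voxelVolumeMl(voi),
               enclosedVolume(s), tolerance = 0.005)
})

test_that("meanInVOI is an inclusion-weighted mean", {
  uni <- new("ActivityVolume", origin = c(0, 0, 0), spacing = c(1, 1, 1),
             values = array(42, c(8, 8, 8)))
  voi <- new("VOI", origin = c(0, 0, 0), spacing = c(1, 1, 1),
             values = array(1, c(8, 8, 8)))
  expect_equal(meanInVOI(uni, voi), 42)

  # half-domain VOI on a two-valued image picks out the right plateau
  two <- uni
  two@values[1:4, , ] <- 10
  half <- voi; half@values[5:8, , ] <- 0
  expect_equal(meanInVOI(two, half), 10)
  # full-domain VOI of a checker image gives the arithmetic mean
  chk <- uni
  chk@values[] <- rep(c(1, 3), length.out = length(chk@values))
  expect_equal(meanInVOI(chk, voi), 2)
  empty <- voi; empty@values[] <- 0
  expect_error(meanInVOI(uni, empty), "empty")
})

test_that("recovery coefficient is a plain ratio with guarded input", {
  expect_equal(recoveryCoefficient(102.5, 102.5), 100)
  expect_equal(recoveryCoefficient(76.3, 100), 76.3)
  expect_error(recoveryCoefficient(50, 0), "positive")
  # invariance under global rescaling of both concentrations
  expect_equal(recoveryCoefficient(37, 88), recoveryCoefficient(3.7, 8.8))
})

test_that("RC decreases with FWHM and approaches 100 as FWHM vanishes", {
  sp <- PhantomSpec("s", "ellipsoid", icosphere(3, 2.5))
  rcAt <- function(fwhm) {
    cfg <- acquisitionConfig(psfFwhm = fwhm, voxel = 1)
    res <- runExperiment(list(sp), list(cfg))
    res$rc_percent
  }
  rcs <- vapply(c(0.5, 5, 9.5, 15), rcAt, numeric(1))
  expect_true(all(diff(rcs) < 0))           # monotone in FWHM
  expect_gt(rcs[1], 98)                     # -> 100 up to voxel discretization
  expect_lt(rcs[3], 100)                    # strict spill-out
})

test_that("experiment runs one record per phantom and configuration", {
  sp1 <- PhantomSpec("a", "ellipsoid", icosphere(2, 2))
  sp2 <- PhantomSpec("b", "ellipsoid", icosphere(2, 2.4))
  cfgs <- tbrConfigs(psfFwhm = 8, voxel = 2)
  res <- runExperiment(list(sp1, sp2), cfgs)
  expect_equal(nrow(res), 6)
  expect_setequal(unique(res$tbr), c("infinity", "10:1", "5:1"))
  # spill-in from a warm background always raises RC over cold background
  w <- reshape(res[, c("phantom_id", "tbr", "rc_percent")],
               idvar = "phantom_id", timevar = "tbr", direction = "wide")
  expect_true(all(w[["rc_percent.5:1"]] > w[["rc_percent.infinity"]]))
})

test_that("RC superposition across TBR holds to 0.2 pp with the wall off", {
  sp <- PhantomSpec("s", "ellipsoid", icosphere(3, 2.2), wallThickness = 0)
  mk <- function(bg, lab) acquisitionConfig(psfFwhm = 9.5, voxel = 2,
                                            targetConc = 100,
                                            backgroundConc = bg, tbrLabel = lab,
                                            wallEnabled = FALSE)
  res <- runExperiment(list(sp), list(mk(0, "infinity"), mk(20, "5:1")))
  rc0 <- res$rc_percent[res$tbr == "infinity"]
  rcf <- res$rc_percent[res$tbr == "5:1"]
  f <- 0.2
  expect_lt(abs(rcf - (100 * f + (1 - f) * rc0)), 0.2)
})

test_that("cortex shells recover less and vary more than parenchyma shapes", {
  cohort <- list(generateParenchyma(21, 165, 1.40, subdivisions = 3),
                 generateParenchyma(22, 175, 1.48, subdivisions = 3),
                 generateCortex(23, 110, 2.8, subdivisions = 3),
                 generateCortex(24, 135, 3.6, subdivisions = 3))
  res <- runExperiment(cohort, tbrConfigs(psfFwhm = 9.5, voxel = 2)["infinity"])
  par <- res$rc_percent[res$kind == "whole-parenchyma"]
  cor <- res$rc_percent[res$kind == "cortex-only"]
  expect_gt(mean(par), mean(cor))
  expect_gt(var(cor), var(par))
})
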