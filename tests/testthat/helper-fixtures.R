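# Shared test fixtures, built in code.

# noisy icosphere: high-frequency radial perturbation of given amplitude (cm)
noisySphere <- function(radius = 3, amplitude = 0.1, subdivisions = 4,
                        seed = 1) {
  s <- icosphere(subdivisions, radius)
  v <- meshVertices(s)
  u <- v / sqrt(rowSums(v^2))
  set.seed(seed)
  TriangleMesh(u * (radius + amplitude * runif(nrow(u), -1, 1)), meshFaces(s))
}

# small activity volume built directly on a lattice
slabVolume <- function(thickness = 20, value = 100, n = c(21, 21, 81),
                       spacing = 1) {
  vals <- array(0, n)
  z0 <- (n[3] - thickness / spacing) / 2
  zidx <- seq_len(n[3])
  inside <- zidx > z0 & zidx <= z0 + thickness / spacing
  vals[, , inside] <- value
  new("ActivityVolume", origin = c(0, 0, 0), spacing = rep(spacing, 3),
      values = vals)
}

# independent brute-force oracles for the exact nonparametric tests,
# working on raw values / explicit sign patterns, not on rank formulas
bruteMW <- function(a, b) {
  pooled <- c(a, b); na <- length(a); n <- length(pooled)
  uOf <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  e <- na * length(b) / 2
  obs <- uOf(a, b)
  cmb <- utils::combn(n, na)
  us <- apply(cmb, 2, function(idx) uOf(pooled[idx], pooled[-idx]))
  mean(abs(us - e) >= abs(obs - e) - 1e-9)
}
bruteWilcoxon <- function(d) {
  n <- length(d); r <- rank(abs(d))
  e <- n * (n + 1) / 4
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  mean(abs(ws - e) >= abs(obs - e) - 1e-9)
}

# memoised heavy simulation shared by the acceptance tests: the default
# published-size cohort at the default acquisition conditions
.acceptanceCache <- new.env(parent = emptyenv())
acceptanceRun <- function() {
  if (!is.null(.acceptanceCache$run)) return(.acceptanceCache$run)
  cohort <- generateCohort(10, 9, TRUE, seed = 42)
  rc <- runExperiment(cohort, tbrConfigs(psfFwhm = 9.5, voxel = 1)["infinity"])
  fit <- fitRCvsSAV(rc$sav_cm1, rc$rc_percent)
  .acceptanceCache$run <- list(cohort = cohort, rc = rc, fit = fit)
  .acceptanceCache$run
}
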