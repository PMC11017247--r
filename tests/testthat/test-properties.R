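## Property estimators against generator ground truth and their degenerate
## limits.

test_that("compressibility estimator inverts the fluctuation formula", {
  ## constant series
  expect_identical(estimateValue(kappaT(rep(10, 1000), 298)), 0)
  ## doubling the fluctuation variance doubles kappa (same mean)
  set.seed(1)
  x <- rnorm(5000)
  x <- x - mean(x)
  v1 <- 10 + 0.01 * x
  v2 <- 10 + 0.01 * sqrt(2) * x
  expect_equal(estimateValue(kappaT(v2, 298, discard = 0)) /
               estimateValue(kappaT(v1, 298, discard = 0)), 2,
               tolerance = 1e-9)
  expect_error(kappaT(v1, -5), "positive")
  expect_warning(kappaT(rnorm(50, 10, 0.1), 298), "short")
})

test_that("estimators recover generator ground truth within 3 stderr", {
  ## seeded replicates per estimator; each inverts exactly the moments the
  ## generator prescribed
  zK <- zE <- zG <- zD <- numeric(0)
  for (seed in 1:20) {
    sv <- synthSeries("volume", list(mean = 10.4, T = 298, kappaT = 5e-4),
                      length = 8000, seed = seed)
    k <- kappaT(sv$series, 298)
    zK <- c(zK, (estimateValue(k) - sv$truth$kappaT) / estimateStderr(k))

    sd1 <- synthSeries("dipole", list(V = 26, T = 298, epsilonRaw = 44),
                       length = 8000, seed = seed)
    e <- dielectricConstant(sd1$series, 26, 298)
    zE <- c(zE, (e@settings$raw - 44) / e@settings$rawStderr)

    sp <- synthSeries("pressure_tensor",
                      list(gamma = 70, Lz = 10, Pbase = 1, sd = 60),
                      length = 6000, seed = seed)
    g <- surfaceTension(sp$series, 10)
    zG <- c(zG, (estimateValue(g) - 70) / estimateStderr(g))

    sw <- synthSeries("msd_walk", list(D = 1.89, nParticles = 12),
                      length = 600, dt = 0.1, seed = seed)
    d <- diffusionEinstein(sw$series, 0.1, fitWindow = c(2, 12))
    zD <- c(zD, (estimateValue(d) - 1.89) / estimateStderr(d))
  }
  expect_lt(max(abs(zK)), 3)
  expect_lt(max(abs(zE)), 3)
  expect_lt(max(abs(zG)), 3)
  expect_lt(max(abs(zD)), 3)
})

test_that("heat capacity finite difference is an exact quotient", {
  ## H linear in T with slope s per molecule
  N <- 100
  s <- 18 / 4184                      # kcal/mol/K per molecule
  h1 <- rep(-500, 100)
  h2 <- rep(-500 + s * N * 6, 100)
  cp <- heatCapacityFd(h1, 295, h2, 301, N, discard = 0)
  expect_equal(estimateValue(cp), 18, tolerance = 1e-9)
  ## swapped argument order gives the identical result
  cp2 <- heatCapacityFd(h2, 301, h1, 295, N, discard = 0)
  expect_identical(estimateValue(cp), estimateValue(cp2))
  expect_error(heatCapacityFd(h1, 298, h2, 298, N), "differ")
  ## synthetic series with known means: hand-computed quotient
  a <- synthSeries("enthalpy", list(mean = -2000, sd = 4), length = 4000,
                   seed = 3)
  b <- synthSeries("enthalpy", list(mean = -1991, sd = 4), length = 4000,
                   seed = 4)
  cp3 <- heatCapacityFd(a$series, 295, b$series, 301, 50)
  hand <- (mean(seriesValues(b$series)[401:4000]) -
           mean(seriesValues(a$series)[401:4000])) / 6 / 50 * 4184
  expect_equal(estimateValue(cp3), hand, tolerance = 1e-12)
})

test_that("heat of vaporization assembles its terms as stated", {
  ## noninteracting limit: <V_gas> = <V_liq>/N, no self energy -> RT
  RT <- physicalConstants$kB * 298 * 4.184
  d <- deltaHVap(rep(-100, 100), 10, rep(-10, 100), 298, dESelf = 0,
                 discard = 0)
  expect_equal(estimateValue(d), RT, tolerance = 1e-9)
  ## self-energy shifts the result exactly linearly
  d2 <- deltaHVap(rep(-100, 100), 10, rep(-10, 100), 298, dESelf = -1.5,
                  discard = 0)
  expect_equal(estimateValue(d2), RT - 1.5 * 4.184, tolerance = 1e-9)
  ## synthetic inputs with chosen means: hand-computed sum
  d3 <- deltaHVap(rep(-2100, 10), 216, rep(-0.7, 10), 298, dESelf = -0.62,
                  discard = 0)
  expect_equal(estimateValue(d3),
               (-0.7 + 2100 / 216 + physicalConstants$kB * 298 - 0.62) * 4.184,
               tolerance = 1e-9)
  expect_error(deltaHVap(rep(-100, 10), 10, NULL, 298), "gas")
  ## the model dipole and the polarization self-energy have sane magnitudes
  mu <- modelDipole(loadParameters("flexible"))
  expect_gt(mu, 2); expect_lt(mu, 2.5)
  expect_lt(deltaESelf(mu), 0)
})

test_that("dielectric estimator recovers the closed form and its limits", {
  ## zero fluctuation: the electronic-continuum baseline exactly
  M0 <- matrix(5, 100, 3)
  e0 <- dielectricConstant(M0, 26, 298)
  expect_equal(estimateValue(e0), 1.78, tolerance = 1e-12)
  expect_equal(e0@settings$raw, 1, tolerance = 1e-12)
  ## doubling the volume at fixed dipole variance halves (eps_raw - 1)
  set.seed(7)
  M <- matrix(rnorm(3000, 0, 2), 1000, 3)
  eA <- dielectricConstant(M, 20, 298, discard = 0)
  eB <- dielectricConstant(M, 40, 298, discard = 0)
  expect_equal((eB@settings$raw - 1) / (eA@settings$raw - 1), 0.5,
               tolerance = 1e-9)
  expect_error(dielectricConstant(M, -1, 298), "positive")
})

test_that("diffusion estimator handles frozen and drifting systems", {
  frozen <- array(rep(1:10, each = 50 * 4 * 3), c(50, 4, 3)) * 0 + 1
  d <- diffusionEinstein(frozen, 0.1, fitWindow = c(0.5, 3))
  expect_equal(estimateValue(d), 0, tolerance = 1e-12)
  ## linear drift grows quadratically: flagged as non-diffusive
  set.seed(8)
  drift <- array(rnorm(200 * 4 * 3, 0, 1e-4), c(200, 4, 3))
  for (f in 1:200) drift[f, , ] <- drift[f, , ] + (f - 1) * 0.05
  dd <- diffusionEinstein(drift, 0.1, fitWindow = c(1, 15))
  expect_true(dd@settings$nonDiffusive)
  ## wrapped input rejected
  wrapped <- array(0, c(50, 2, 3))
  wrapped[seq(2, 50, 2), , ] <- 1.8
  expect_error(diffusionEinstein(wrapped, 0.1, fitWindow = c(0.5, 2),
                                 box = rep(2, 3)), "unwrapped")
  ## the quantum annotation is a footnote, never applied
  sw <- synthSeries("msd_walk", list(D = 2, nParticles = 6), length = 300,
                    dt = 0.1, seed = 2)
  d2 <- diffusionEinstein(sw$series, 0.1, fitWindow = c(2, 10))
  expect_equal(d2@settings$quantumCorrected15pct,
               estimateValue(d2) * 1.15, tolerance = 1e-12)
})

test_that("surface tension is the stated pressure-tensor quadrature", {
  ## isotropic tensor: zero
  iso <- data.frame(Pxx = rep(3, 100), Pyy = rep(3, 100), Pzz = rep(3, 100))
  expect_equal(estimateValue(surfaceTension(iso, 10)), 0, tolerance = 1e-12)
  ## hand unit conversion: 100 bar anisotropy on a 10 nm box -> 50 mN/m
  an <- data.frame(Pxx = rep(0, 100), Pyy = rep(0, 100), Pzz = rep(100, 100))
  expect_equal(estimateValue(surfaceTension(an, 10)), 50, tolerance = 1e-12)
  ## doubling the anisotropy doubles gamma
  an2 <- data.frame(Pxx = 0, Pyy = 0, Pzz = rep(200, 100))
  expect_equal(estimateValue(surfaceTension(an2, 10)), 100,
               tolerance = 1e-12)
  expect_error(surfaceTension(data.frame(Pxx = 1), 10), "Pzz")
})

test_that("ensemble geometry derives the angle from mean distances", {
  ## <OH> = 1, <HH> = sqrt(2): right angle
  mk <- function(oh, hh) {
    half <- hh / 2
    z <- sqrt(oh^2 - half^2)
    pos <- rbind(c(0, 0, 0), c(half, 0, z), c(-half, 0, z)) / 10
    new("SystemState", box = c(3, 3, 3), positions = pos,
        velocities = matrix(0, 3, 3), molecule = rep(1L, 3),
        siteNames = c("OW", "HW1", "HW2"), time = 0, wrapped = FALSE,
        metadata = list())
  }
  g <- ensembleGeometry(list(mk(1, sqrt(2))))
  expect_equal(g$thetaE, 90, tolerance = 1e-9)
  ## the EG298 geometry round-trips through the inverse formula
  hh298 <- 2 * 0.9706 * sin(105.25 * pi / 360)
  g2 <- ensembleGeometry(list(mk(0.9706, hh298)))
  expect_equal(g2$re, 0.9706, tolerance = 1e-9)
  expect_equal(g2$thetaE, 105.25, tolerance = 1e-9)
  ## rigid trajectories are rejected
  expect_error(ensembleGeometry(list(mk(1, 1.4)),
                                params = loadParameters("EG273")), "rigid")
})

test_that("radial distribution function is normalized to the uniform fluid", {
  ## ideal-gas configurations: g = 1 within sampling error
  set.seed(3)
  snaps <- lapply(1:40, function(i) {
    n <- 60
    pos <- matrix(runif(9 * n, 0, 2.4), 3 * n, 3)
    new("SystemState", box = rep(2.4, 3), positions = pos,
        velocities = matrix(0, 3 * n, 3), molecule = rep(1:n, each = 3L),
        siteNames = rep(c("OW", "HW1", "HW2"), n), time = 0,
        wrapped = TRUE, metadata = list())
  })
  g <- rdfCalc(snaps, "OO", binWidth = 0.1, rMax = 1.2)
  expect_lt(max(abs(g$g[g$r > 0.2] - 1)), 0.15)
  expect_equal(mean(g$g[g$r > 0.2]), 1, tolerance = 0.02)
  ## hard-contact region of a dense structured state is empty
  st <- buildWaterBox(64, 997, seed = 2)
  g2 <- rdfCalc(list(st), "OO", binWidth = 0.01, rMax = 0.6)
  expect_true(all(g2$g[g2$r < 0.24] == 0))
  ## two fixed particles: single-bin peak integrating to one neighbor
  two <- new("SystemState", box = rep(3, 3),
             positions = rbind(c(0.1, 0.1, 0.1), c(0.2, 0.15, 0.1),
                               c(0.05, 0.2, 0.1),
                               c(1.1, 0.1, 0.1), c(1.2, 0.15, 0.1),
                               c(1.05, 0.2, 0.1)),
             velocities = matrix(0, 6, 3), molecule = rep(1:2, each = 3L),
             siteNames = rep(c("OW", "HW1", "HW2"), 2), time = 0,
             wrapped = TRUE, metadata = list())
  g3 <- rdfCalc(list(two), "OO", binWidth = 0.05, rMax = 1.4)
  ## counting oracle: integral of g rho_pair 4 pi r^2 dr = 1 neighbor,
  ## with the exact finite-N pair density (N-1)/V
  rho <- 1 / 27
  integral <- sum(g3$g * rho * 4 * pi * g3$r^2 * 0.05)
  expect_equal(integral, 1, tolerance = 0.05)
  expect_error(rdfCalc(list(two), "OO", rMax = 2), "half")
})
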