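## MD engine: Ewald electrostatics, energy/force consistency, integrators,
## thermostats/barostats, constraints, pressure routes.

test_that("Ewald reproduces the isolated Coulomb pair in the dilute limit", {
  pos <- rbind(c(0, 0, 0), c(0.3, 0, 0))   # nm
  q <- c(1, -1)
  res <- coulombEwald(pos, q, box = rep(12, 3), rCut = 5.9)
  exact <- -physicalConstants$coulomb / 3   # 1/r at 3 A
  expect_equal(res$energy, exact, tolerance = 1e-4 * abs(exact))
})

test_that("Ewald rejects non-neutral systems and undersized boxes", {
  pos <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  expect_error(coulombEwald(pos, c(1, -0.5), rep(6, 3)), "neutral")
  p <- loadParameters("EG298")
  st <- buildWaterBox(8, 500, seed = 1, params = p)
  expect_error(systemEnergyForces(st, p, cutoff = cutoffScheme(5)),
               "twice the cutoff")
})

test_that("rigid translation leaves energy unchanged and net force zero", {
  p <- loadParameters("EG273")
  st <- buildWaterBox(32, 997, seed = 3, params = p)
  cut <- cutoffScheme(0.45, TRUE, TRUE)
  e1 <- systemEnergyForces(st, p, cutoff = cut)
  st2 <- st
  st2@positions <- sweep(st@positions, 2, c(0.123, -0.456, 0.789), `+`)
  e2 <- systemEnergyForces(st2, p, cutoff = cut)
  expect_equal(e2$components$total, e1$components$total, tolerance = 1e-10)
  expect_lt(max(abs(colSums(e1$forces))), 1e-8)
})

test_that("virtual-site force redistribution preserves molecular force and torque", {
  ## the redistribution weights (1-2a, a, a) sum to 1 and place the
  ## transferred force at the M position, so molecular force and torque are
  ## conserved; verified against the numerical gradient of the energy with
  ## respect to a rigid molecular rotation
  p <- loadParameters("EG298")
  st <- buildWaterBox(32, 997, seed = 4, params = p)
  cut <- cutoffScheme(0.45, TRUE, TRUE)
  ef <- systemEnergyForces(st, p, cutoff = cut)
  ## torque on molecule 1 about its O from site forces
  f <- ef$forces                       # kcal/mol/A
  pA <- st@positions * 10
  tq <- colSums(do.call(rbind, lapply(1:3, function(s) {
    r <- pA[s, ] - pA[1, ]
    c(r[2] * f[s, 3] - r[3] * f[s, 2],
      r[3] * f[s, 1] - r[1] * f[s, 3],
      r[1] * f[s, 2] - r[2] * f[s, 1])
  })))
  ## numerical torque: rotate molecule 1 about each axis through its O
  h <- 1e-6
  num <- vapply(1:3, function(ax) {
    rot <- function(ang) {
      u <- c(0, 0, 0); u[ax] <- 1
      K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
                  byrow = TRUE)
      diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    }
    en <- function(ang) {
      s2 <- st
      rel <- sweep(pA[1:3, ], 2, pA[1, ])
      s2@positions[1:3, ] <- sweep(rel %*% t(rot(ang)), 2, pA[1, ], `+`) / 10
      systemEnergyForces(s2, p, cutoff = cut)$components$total
    }
    -(en(h) - en(-h)) / (2 * h)
  }, numeric(1))
  expect_equal(tq, num, tolerance = 1e-5 * max(1, max(abs(tq))))
})

test_that("analytic forces equal the numerical gradient for both variants", {
  set.seed(11)
  for (variant in c("flexible", "EG273")) {
    p <- loadParameters(variant)
    st <- buildWaterBox(32, 997, seed = 6, params = p)
    ew <- ewaldParams(tol = 1e-7)
    cut <- cutoffScheme(0.45, TRUE, TRUE)
    ef <- systemEnergyForces(st, p, ew, cut)
    probes <- sample(nrow(st@positions) * 3, 8)
    fd <- numericalForces(st, p, ew, cut, probes)
    an <- analyticForceAt(ef$forces, st, probes)
    expect_lt(max(abs(fd - an)) / max(abs(an)), 1e-6)
  }
})

test_that("a zero-force particle system moves linearly in NVE", {
  p <- loadParameters("flexible")
  st <- buildWaterBox(4, 100, seed = 2, params = p)
  st@velocities <- matrix(0.05, nrow(st@positions), 3)
  tr <- runMD(st, p, steps = 100, dt = 1e-3, integrator = "nve",
              cutoff = cutoffScheme(0.3, FALSE, FALSE),
              interactions = FALSE, sampleEvery = 100)
  expect_equal(sitePositions(finalState(tr)),
               st@positions + 0.05 * 0.1, tolerance = 1e-12)
})

test_that("molecular vibration conserves energy at a fine time step", {
  ## velocity-Verlet bound: a single flexible molecule integrated at
  ## roughly period/1000 shows no secular drift over ~20 stretch periods
  p <- loadParameters("flexible")
  st <- buildWaterBox(2, 30, seed = 1, params = p)
  tr <- runMD(st, p, steps = 20000, dt = 1e-5, integrator = "nve",
              cutoff = cutoffScheme(0.3, FALSE, FALSE),
              initTemperature = 300, seed = 4, sampleEvery = 100)
  s <- trajectorySeries(tr)
  scale <- mean(s$ekin)
  drift <- abs(coef(lm(s$etot ~ s$time))[2]) * diff(range(s$time))
  expect_lt(drift / scale, 1e-6)       # secular drift
  expect_lt((max(s$etot) - min(s$etot)) / scale, 1e-4)  # bounded fluctuation
})

test_that("a free rigid molecule conserves kinetic energy over 10 ps at 2 fs", {
  p <- loadParameters("EG273")
  st <- buildWaterBox(2, 30, seed = 1, params = p)
  tr <- runMD(st, p, steps = 5000, dt = 2e-3, integrator = "nve",
              cutoff = cutoffScheme(0.3, FALSE, FALSE),
              interactions = FALSE, initTemperature = 300, seed = 2,
              sampleEvery = 100)
  s <- trajectorySeries(tr)
  expect_lt((max(s$ekin) - min(s$ekin)) / mean(s$ekin), 1e-6)
})

test_that("constraint maintenance, momentum projection and convergence guard", {
  p <- loadParameters("EG273")
  st <- equilibratedBox(27, "EG273", 260, 0.4, seed = 8)
  res <- constraintResiduals(st, p)
  expect_lt(res$bond, 1e-8)
  expect_lt(res$angle, 1e-8)
  ## projection preserves linear momentum to 1e-10
  stv <- maxwellVelocities(st, 300, seed = 3)
  v0 <- siteVelocities(stv)
  stc <- constrainRigid(stv, p)
  m <- rep(c(physicalConstants$massO, physicalConstants$massH,
             physicalConstants$massH), nMolecules(st))
  expect_lt(max(abs(colSums(v0 * m) - colSums(siteVelocities(stc) * m))),
            1e-10)
  expect_error(constrainRigid(st, loadParameters("flexible")), "rigid")
})

test_that("Nose-Hoover NVT holds the target temperature within 1 percent", {
  p <- loadParameters("EG273")
  st <- equilibratedBox(64, "EG273", 260, 0.55, seed = 5)
  tr <- runMD(st, p, steps = 2500, dt = 2e-3, integrator = "nvt",
              thermostat = thermostatParams(260, 0.5),
              cutoff = cutoffScheme(0.55, TRUE, TRUE), sampleEvery = 5)
  s <- trajectorySeries(tr)
  s <- s[s$time > trajectorySeries(tr)$time[1] + 1, ]
  expect_lt(abs(mean(s$temperature) - 260) / 260, 0.01)
  ## volume is constant without a barostat
  expect_identical(length(unique(s$volume)), 1L)
  expect_error(runMD(st, p, steps = 1, dt = 1e-3, integrator = "nvt",
                     thermostat = thermostatParams(260, -1)), "positive")
})

test_that("Maxwell velocities are Gaussian at the target temperature", {
  p <- loadParameters("flexible")
  st <- buildWaterBox(343, 997, seed = 1, params = p)
  stv <- maxwellVelocities(st, 298, seed = 12)
  v <- siteVelocities(stv) * 10        # A/ps
  mass <- rep(c(physicalConstants$massO, physicalConstants$massH,
                physicalConstants$massH), 343)
  ## mass-scaled components are standard normal
  z <- sqrt(mass / (physicalConstants$kB * 298 *
                    physicalConstants$kcalToAmuA2ps2)) * v
  pv <- shapiro.test(sample(as.numeric(z), 3000))$p.value
  expect_gt(pv, 1e-3)
  expect_equal(sd(as.numeric(z)), 1, tolerance = 0.05)
})

test_that("the ideal-gas surrogate reproduces its equation of state", {
  p <- loadParameters("flexible")   # unconstrained surrogate
  st <- buildWaterBox(125, 200, seed = 4, params = p)
  tr <- runMD(st, p, steps = 6000, dt = 2e-3, integrator = "npt",
              thermostat = thermostatParams(300, 0.5),
              barostat = barostatParams(P = 200, tau = 1),
              cutoff = cutoffScheme(0.3, FALSE, FALSE),
              initTemperature = 300, seed = 5, interactions = FALSE,
              sampleEvery = 10)
  s <- trajectorySeries(tr)
  s <- s[s$time > 4, ]
  kBbar <- physicalConstants$kBSI / 1e-27 / 1e5
  rho <- 125 / mean(s$volume)
  expect_lt(abs(rho * kBbar * 300 - 200) / 200, 0.02)
  ## mean instantaneous pressure sits on the setpoint
  se <- sd(s$pressure) / sqrt(10)      # generous block-level error
  expect_lt(abs(mean(s$pressure) - 200), 4 * se)
  expect_error(runMD(st, p, steps = 1, dt = 1e-3, integrator = "npt",
                     barostat = barostatParams(200, -2)), "positive")
})

test_that("interacting NPT pressure relaxes to the setpoint within error bars", {
  p <- loadParameters("EG273")
  st <- equilibratedBox(64, "EG273", 260, 0.55, seed = 5)
  tr <- runMD(st, p, steps = 2500, dt = 2e-3, integrator = "npt",
              thermostat = thermostatParams(260, 0.5),
              barostat = barostatParams(P = 1, tau = 2),
              cutoff = cutoffScheme(0.55, TRUE, TRUE), sampleEvery = 5)
  s <- trajectorySeries(tr)
  s <- s[s$time > s$time[1] + 2, ]
  b <- tapply(s$pressure, floor(seq_along(s$pressure) * 8 /
                                (length(s$pressure) + 1)), mean)
  se <- sd(b) / sqrt(length(b))
  expect_lt(abs(mean(s$pressure) - 1), 5 * se)
})

test_that("pressure tensor: ideal-gas kinetic route and frozen-state virial route", {
  p <- loadParameters("EG298")
  st <- buildWaterBox(64, 500, seed = 9, params = p)
  st <- maxwellVelocities(st, 300, seed = 2)
  ## virial off (interactions untouched but state is a lattice): compare the
  ## FD volume-perturbation pressure with the virial pressure, LRC off so
  ## the two routes agree identically
  cut <- cutoffScheme(0.5, FALSE, FALSE)
  ef <- systemEnergyForces(st, p, cutoff = cut)
  V <- prod(st@box * 10)
  Pvir <- sum(diag(ef$virial)) / 3 / V * physicalConstants$pressureUnitBar
  scaleState <- function(s1) {
    st2 <- st
    n <- nMolecules(st)
    iO <- 3 * (1:n) - 2
    mO <- physicalConstants$massO; mH <- physicalConstants$massH
    com <- (mO * st@positions[iO, ] + mH * (st@positions[iO + 1, ] +
            st@positions[iO + 2, ])) / (mO + 2 * mH)
    for (k in 0:2)
      st2@positions[iO + k, ] <- st@positions[iO + k, ] + (s1 - 1) * com
    st2@box <- st@box * s1
    st2
  }
  eps <- 1e-5
  e1 <- systemEnergyForces(scaleState(1 + eps), p, cutoff = cut)$components$total
  e2 <- systemEnergyForces(scaleState(1 - eps), p, cutoff = cut)$components$total
  Pfd <- -(e1 - e2) / (V * ((1 + eps)^3 - (1 - eps)^3)) *
    physicalConstants$pressureUnitBar
  expect_equal(Pfd, Pvir, tolerance = 0.01 * abs(Pvir))
  ## full tensor is symmetric and kinetic part gives N kB T / V when frozen
  ## interactions are removed from the virial by construction
  pt <- pressureTensor(st, p, cutoff = cut)
  expect_equal(pt$tensor, t(pt$tensor))
  expect_equal(pt$pressure, sum(diag(pt$tensor)) / 3)
})

test_that("bulk equilibrium pressure is isotropic within error bars", {
  p <- loadParameters("EG273")
  st <- equilibratedBox(64, "EG273", 260, 0.55, seed = 5)
  tr <- runMD(st, p, steps = 1500, dt = 2e-3, integrator = "nvt",
              thermostat = thermostatParams(260, 0.5),
              cutoff = cutoffScheme(0.55, TRUE, TRUE), sampleEvery = 5)
  s <- trajectorySeries(tr)
  ses <- vapply(c("Pxx", "Pyy", "Pzz"), function(cn)
    sd(s[[cn]]) / sqrt(8), numeric(1))
  mns <- vapply(c("Pxx", "Pyy", "Pzz"), function(cn) mean(s[[cn]]),
                numeric(1))
  expect_lt(max(mns) - min(mns), 6 * max(ses))
})

test_that("identical seeds give identical trajectories", {
  p <- loadParameters("EG273")
  run <- function() {
    st <- buildWaterBox(32, 997, seed = 2, params = p)
    runMD(st, p, steps = 50, dt = 1e-3, integrator = "nvt",
          thermostat = thermostatParams(250, 0.5),
          cutoff = cutoffScheme(0.45, TRUE, TRUE),
          initTemperature = 250, seed = 9)
  }
  a <- run(); b <- run()
  expect_identical(sitePositions(finalState(a)),
                   sitePositions(finalState(b)))
  expect_identical(trajectorySeries(a), trajectorySeries(b))
})

test_that("a bulk-replicated control shows zero net surface tension", {
  ## no interface: the slab formula applied to a periodic bulk box must
  ## give zero within sampling error
  p <- loadParameters("EG273")
  st <- equilibratedBox(64, "EG273", 260, 0.55, seed = 5)
  tr <- runMD(st, p, steps = 1500, dt = 2e-3, integrator = "nvt",
              thermostat = thermostatParams(260, 0.5),
              cutoff = cutoffScheme(0.55, TRUE, TRUE), sampleEvery = 5)
  g <- surfaceTension(trajectorySeries(tr), Lz = st@box[3])
  expect_lt(abs(estimateValue(g)), 4 * estimateStderr(g) + 1)
})

test_that("the dispersion tail correction equals its analytic closed form", {
  p <- loadParameters("EG298")
  st <- buildWaterBox(64, 900, seed = 3, params = p)
  rc <- 0.5
  on <- systemEnergyForces(st, p, cutoff = cutoffScheme(rc, TRUE, TRUE))
  off <- systemEnergyForces(st, p, cutoff = cutoffScheme(rc, FALSE, FALSE))
  n <- 64
  V <- prod(st@box * 10)
  expect_equal(on$components$lrc,
               -2 * pi * n^2 * p@COO / (3 * V * (rc * 10)^3),
               tolerance = 1e-12)
  expect_identical(off$components$lrc, 0)
  ## two O sites at 5 A: direct arithmetic for the real-space pair terms
  A <- waterSites(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0), p)
  B <- waterSites(c(5, 0, 0), c(5.96, 0, 0), c(5 - 0.24, 0.93, 0), p)
  eb <- pairEnergy(A, B, p)
  expect_equal(eb@repulsion, p@AOO * exp(-5 * p@alpha), tolerance = 1e-12)
  expect_equal(eb@dispersion, -p@COO / 5^6, tolerance = 1e-12)
})
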