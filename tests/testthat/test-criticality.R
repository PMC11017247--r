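## Critical-phenomena machinery: phase densities, coexistence fits, vapor
## pressure, IAPWS-E surface-tension fit, LLCP localization, melting-point
## driver.

test_that("slab phase densities come from plateau regions", {
  z <- seq(0, 10, 0.02)
  prof <- data.frame(z = z, rho = 15 + (992 - 15) / 2 *
                       (tanh((z - 3) / 0.2) - tanh((z - 7) / 0.2)))
  out <- slabPhaseDensities(prof, exclusion = 1.0)
  expect_equal(out$rhoLiquid, 992, tolerance = 1e-3 * 992)
  expect_equal(out$rhoVapor, 15, tolerance = 1e-3 * 992)
  ## uniform profile: coexistence lost
  expect_error(slabPhaseDensities(data.frame(z = z, rho = 500 + 0 * z)),
               "uniform|supercritical")
  ## vacuum-only vapor region
  prof0 <- data.frame(z = z, rho = ifelse(z > 3 & z < 7, 990, 0))
  out0 <- slabPhaseDensities(prof0, exclusion = 0.5)
  expect_identical(out0$rhoVapor, 0)
})

test_that("Wegner fit recovers noiseless synthetic coexistence exactly", {
  truth <- list(Tc = 683, B0 = 500, B1 = 0.8, rhoc = 308, a1 = 420,
                a2 = 150)
  cw <- synthCurves("coexistence_wegner", truth,
                    Tgrid = seq(325, 625, length.out = 8), noise = 0)
  fit <- wegnerFit(cw$points, seed = 2)
  expect_true(fit@converged)
  expect_equal(fittedPar(fit)[["Tc"]], 683, tolerance = 683 * 1e-6)
  expect_equal(fittedPar(fit)[["B0"]], 500, tolerance = 500 * 1e-6)
  expect_equal(fittedPar(fit)[["B1"]], 0.8, tolerance = 1e-5)
  ## at T = T_c the fitted difference is exactly zero (tau = 0)
  p <- fittedPar(fit)
  del <- function(T) {
    tau <- pmax(0, 1 - T / p[["Tc"]])
    p[["B0"]] * tau^0.325 * (1 + p[["B1"]] * sqrt(tau))
  }
  expect_identical(del(p[["Tc"]]), 0)
  expect_error(wegnerFit(cw$points[1:3, ]), "4")
})

test_that("Wegner fit is unbiased on noisy data across seeds", {
  truth <- list(Tc = 683, B0 = 500, B1 = 0.8, rhoc = 308, a1 = 420,
                a2 = 150)
  Tgrid <- seq(325, 625, length.out = 8)
  ests <- ses <- numeric(0)
  for (seed in 1:20) {
    cw <- synthCurves("coexistence_wegner", truth, Tgrid,
                      noise = 0.01 * 500, seed = seed)
    fit <- wegnerFit(cw$points, seed = seed)
    ests <- c(ests, fittedPar(fit)[["Tc"]])
    ses <- c(ses, fit@stderr[["Tc"]])
  }
  bias <- mean(ests) - 683
  ci <- 2 * sd(ests) / sqrt(20)
  expect_lt(abs(bias), max(ci, mean(ses)))
})

test_that("critical density fit reproduces the diameter law", {
  ## symmetric coexistence: constant diameter equals rho_c
  pts <- data.frame(T = seq(400, 600, 50),
                    rhoLiquid = 300 + seq(250, 50, -50),
                    rhoVapor = 300 - seq(250, 50, -50))
  fit <- criticalDensityFit(pts, Tc = 650)
  expect_equal(fittedPar(fit)[["rhoc"]], 300, tolerance = 1e-9)
  ## exact recovery of a known singular diameter
  truth <- list(Tc = 683, B0 = 500, B1 = 0.8, rhoc = 308, a1 = 420,
                a2 = 150)
  cw <- synthCurves("coexistence_wegner", truth,
                    Tgrid = seq(325, 625, length.out = 8), noise = 0)
  fit2 <- criticalDensityFit(cw$points, Tc = 683)
  expect_equal(fittedPar(fit2)[["rhoc"]], 308, tolerance = 1e-8 * 308)
  expect_equal(fittedPar(fit2)[["a1"]], 420, tolerance = 1e-6 * 420)
  ## noisy recovery within CI across seeds
  ests <- numeric(0)
  for (seed in 1:20) {
    cwn <- synthCurves("coexistence_wegner", truth,
                       Tgrid = seq(325, 625, length.out = 8),
                       noise = 5, seed = seed)
    ests <- c(ests, fittedPar(criticalDensityFit(cwn$points, 683))[["rhoc"]])
  }
  expect_lt(abs(mean(ests) - 308), 2 * sd(ests) / sqrt(20) + 1)
})

test_that("Antoine fit solves the determined system exactly", {
  an <- synthCurves("antoine", list(A = 11.9, B = 3816.44, C = -46.13),
                    Tgrid = c(350, 450, 550), noise = 0)
  fit <- antoineFit(an$points, seed = 3)
  expect_equal(unname(fittedPar(fit)), c(11.9, 3816.44, -46.13),
               tolerance = 1e-6)
  ## P_c from the closed form at a given Tc
  expect_equal(antoinePc(fit, 683), exp(11.9 - 3816.44 / (683 - 46.13)),
               tolerance = 1e-5)
  ## B = 0: constant pressure at all temperatures
  an0 <- synthCurves("antoine", list(A = 2, B = 0, C = 10),
                     Tgrid = c(300, 400, 500, 600), noise = 0)
  expect_equal(var(an0$points$P), 0, tolerance = 1e-20)
  expect_error(antoineFit(data.frame(T = c(300, 400), P = c(1, -2))),
               "positive")
})

test_that("IAPWS-E fit recovers noiseless parameters and honors the T_e convention", {
  truth <- list(Tc = 683, B = 243.057, b = -0.727, c = 0.0872,
                Te = 237.653)
  Tgrid <- c(seq(230, 320, 10), seq(350, 650, 50))
  gi <- synthCurves("gamma_iapws_e", truth, Tgrid, noise = 0)
  fit <- iapwsEFit(gi$points, Tc = 683, seed = 4)
  p <- fittedPar(fit)
  expect_equal(p[["B"]], 243.057, tolerance = 243 * 1e-5)
  expect_equal(p[["b"]], -0.727, tolerance = 1e-4)
  expect_equal(p[["c"]], 0.0872, tolerance = 1e-4)
  expect_equal(p[["Te"]], 237.653, tolerance = 237 * 1e-5)
  ## definition of the emergence temperature: the fitted curve deviates
  ## from the classical term by exactly gamma_s at T_e
  dev <- iapwsEGamma(p[["Te"]], 683, p[["B"]], p[["b"]], p[["c"]],
                     p[["Te"]]) -
    iapwsClassicalGamma(p[["Te"]], 683, p[["B"]], p[["b"]])
  expect_equal(dev, 1, tolerance = 1e-10)
  expect_true(fit@info$emergenceDetected)
})

test_that("IAPWS-E fit is invariant to point order and weight rescaling", {
  truth <- list(Tc = 683, B = 243.057, b = -0.727, c = 0.0872,
                Te = 237.653)
  Tgrid <- c(seq(230, 320, 10), seq(350, 650, 50))
  gi <- synthCurves("gamma_iapws_e", truth, Tgrid, noise = 0.2, seed = 5)
  f1 <- iapwsEFit(gi$points, 683, seed = 4)
  perm <- sample(nrow(gi$points))
  f2 <- iapwsEFit(gi$points[perm, ], 683, seed = 4)
  expect_equal(fittedPar(f1), fittedPar(f2), tolerance = 1e-6)
  sc <- gi$points
  sc$stderr <- sc$stderr * 7.3
  f3 <- iapwsEFit(sc, 683, seed = 4)
  expect_equal(fittedPar(f1), fittedPar(f3), tolerance = 1e-6)
})

test_that("IAPWS-E fit reports identifiability failures explicitly", {
  truth <- list(Tc = 683, B = 243.057, b = -0.727, c = 0.0872,
                Te = 237.653)
  warm <- synthCurves("gamma_iapws_e", truth, seq(280, 650, 30), noise = 0)
  expect_error(iapwsEFit(warm$points, 683), "supercooled")
  ## zero emergence component: flagged as not detected
  null <- synthCurves("gamma_iapws_e",
                      list(Tc = 683, B = 243.057, b = -0.727, c = 0.5,
                           Te = 30), # component ~ exp(-100): numerically 0
                      Tgrid = c(seq(230, 320, 10), seq(350, 650, 50)),
                      noise = 0)
  fit <- iapwsEFit(null$points, 683, seed = 2)
  expect_false(fit@info$emergenceDetected)
})

test_that("LLCP locator recovers the analytic vdW critical point within the grid cell", {
  gr <- vdwGrids(seq(580, 700, 2), seq(160, 280, 20))
  est <- locateLLCP(gr$kappa, gr$density)
  expect_true(est$detected)
  expect_lt(abs(est$Pc - vdwOracle$Pc / 10), abs(diff(est$bracket)) + 1e-9)
  expect_lt(abs(est$Tc - vdwOracle$Tc), est$dT + 1e-9)
  ## uncertainties never below grid spacing
  expect_gte(est$dT, 2)
  expect_gte(est$dP, 1)
})

test_that("LLCP locator refuses featureless or one-sided grids", {
  Ts <- seq(580, 700, 5); Ps <- seq(16, 28, 2)
  fg <- expand.grid(T = Ts, P = Ps)
  fg$rho <- 900 - 0.5 * fg$T + 0.1 * fg$P
  fg$stderr <- 3
  fk <- fg[c("T", "P")]
  fk$kappa <- 1e-4 + 1e-7 * fk$T
  est <- locateLLCP(fk, fg)
  expect_false(est$detected)
  expect_match(est$reason, "no")
})

test_that("refining an already-bracketing grid only narrows the bracket", {
  ## refine the isobar grid at fixed temperature resolution
  coarse <- vdwGrids(seq(580, 700, 2), seq(160, 280, 20))
  fine <- vdwGrids(seq(580, 700, 2), seq(160, 280, 10))
  e1 <- locateLLCP(coarse$kappa, coarse$density)
  e2 <- locateLLCP(fine$kappa, fine$density)
  expect_true(e1$detected && e2$detected)
  expect_lte(abs(diff(e2$bracket)), abs(diff(e1$bracket)))
  ## the fine bracket stays inside the coarse one (orientation-agnostic)
  expect_gte(min(e2$bracket), min(e1$bracket) - 1e-9)
  expect_lte(max(e2$bracket), max(e1$bracket) + 1e-9)
})

test_that("phase classifier separates ice from liquid configurations", {
  ice <- buildIceIh(c(2, 2, 1), seed = 1)
  expect_identical(classifyPhase(ice), "ice")
  liq <- buildWaterBox(64, 997, seed = 7)
  expect_identical(classifyPhase(liq), "liquid")
  expect_gt(mean(tetrahedralOrder(ice)), 0.95)
})

test_that("melting-point driver bisects between the bracketing temperatures", {
  ice <- buildIceIh(c(2, 2, 1), seed = 1)
  ## deterministic mock runner with a sharp melting point at 271 K
  mockRunner <- function(state, T)
    if (T > 271) buildWaterBox(64, 997, seed = 3) else state
  out <- meltingPointThreePhase(ice, loadParameters("EG273"),
                                TH = 275, TL = 255, runner = mockRunner,
                                maxBisect = 5)
  expect_length(out$flags, 0)
  expect_lte(out$bracket[1], 271)
  expect_gte(out$bracket[2], 271)
  expect_lt(diff(out$bracket), 20 / 2^4)
  ## classifier sanity at the end points
  expect_identical(out$history[[1]]$endState, "liquid")
  expect_identical(out$history[[2]]$endState, "ice")
  ## ambiguous end states widen the bracket and are flagged
  half <- function(state, T) {
    mixed <- buildWaterBox(64, 997, seed = 3)
    if (T > 271) mixed else state
  }
  amb <- meltingPointThreePhase(ice, loadParameters("EG273"),
                                TH = 275, TL = 255,
                                runner = function(s, T) s,
                                maxBisect = 2)
  expect_gt(length(amb$flags), 0)
})
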