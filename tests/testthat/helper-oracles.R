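## Shared independent oracles and small fixtures for the test suite.

## van der Waals equation of state with water-like constants: an analytic
## stand-in for a fluid with a known critical point, used to exercise the
## critical-point locator.  Maxwell construction via chemical-potential
## comparison of the cubic's roots.
vdwOracle <- local({
  Rb <- 0.0831446                      # L bar / (mol K)
  a <- 5.536; b <- 0.03049             # L^2 bar / mol^2, L/mol
  M <- 18.015
  rho <- function(T, P) {              # stable density, g/L, P in bar
    r <- polyroot(rev(c(P, -(P * b + Rb * T), a, -a * b)))
    v <- Re(r[abs(Im(r)) < 1e-8]); v <- v[v > b]
    if (length(v) == 1) return(M / v)
    mu <- function(vv) -Rb * T * log(vv - b) + Rb * T * vv / (vv - b) -
      2 * a / vv + P * vv
    M / v[which.min(vapply(v, mu, numeric(1)))]
  }
  list(rho = rho,
       Tc = 8 * a / (27 * Rb * b),
       Pc = a / (27 * b^2),            # bar
       rhoc = M / (3 * b))
})

## (T, P) grids of density and compressibility from the vdW oracle, with a
## stated measurement error as a block-simulation would carry
vdwGrids <- function(Ts, PsBar, stderr = 3) {
  dens <- expand.grid(T = Ts, P = PsBar)
  dens$rho <- mapply(vdwOracle$rho, dens$T, dens$P)
  dens$stderr <- stderr
  kap <- dens[c("T", "P")]
  kap$kappa <- mapply(function(T, P) {
    h <- 0.05
    (vdwOracle$rho(T, P + h) - vdwOracle$rho(T, P - h)) / (2 * h) /
      vdwOracle$rho(T, P)
  }, kap$T, kap$P)
  dens$P <- dens$P / 10                # bar -> MPa
  kap$P <- kap$P / 10
  list(kappa = kap, density = dens)
}

## Evjen-style direct lattice sum for the rocksalt Madelung energy:
## fractional weights for sites on the faces/edges/corners of the summation
## cube make the partial sums charge-neutral, so the conditionally
## convergent series converges rapidly.  Independent of the Ewald path.
madelungDirect <- function(L = 14) {
  idx <- -L:L
  g <- expand.grid(i = idx, j = idx, k = idx)
  w <- function(v) ifelse(abs(v) == L, 0.5, 1)
  weight <- w(g$i) * w(g$j) * w(g$k)
  r <- sqrt(g$i^2 + g$j^2 + g$k^2)
  sel <- r > 0
  q <- (-1)^(g$i + g$j + g$k)
  -sum(weight[sel] * q[sel] / r[sel])   # Madelung constant (per ion, x q^2/a)
}

## small equilibrated boxes shared by engine tests (built once per run)
testBoxCache <- new.env()
equilibratedBox <- function(n = 64, variant = "EG273", T = 260,
                            rcut = 0.55, seed = 5) {
  key <- paste(n, variant, T, rcut, seed, sep = "_")
  if (!is.null(testBoxCache[[key]])) return(testBoxCache[[key]])
  p <- loadParameters(variant)
  st <- buildWaterBox(n, 997, seed = seed, params = p)
  dt <- if (variant == "flexible") 5e-4 else 1e-3
  tr <- runMD(st, p, steps = 400, dt = dt, integrator = "nvt",
              thermostat = thermostatParams(T, 0.1),
              cutoff = cutoffScheme(rcut, TRUE, TRUE),
              initTemperature = T, seed = seed, sampleEvery = 200)
  testBoxCache[[key]] <- finalState(tr)
  testBoxCache[[key]]
}

## independent numerical gradient of the system energy (nm input state)
numericalForces <- function(state, params, ewald, cutoff, probes,
                            h = 1e-6) {
  vapply(probes, function(k) {
    n <- nrow(state@positions)
    i <- (k - 1) %% n + 1
    d <- (k - 1) %/% n + 1
    sp <- state; sp@positions[i, d] <- state@positions[i, d] + h
    sm <- state; sm@positions[i, d] <- state@positions[i, d] - h
    ep <- systemEnergyForces(sp, params, ewald, cutoff)$components$total
    em <- systemEnergyForces(sm, params, ewald, cutoff)$components$total
    -(ep - em) / (2 * h * 10)          # kcal/mol/A
  }, numeric(1))
}

analyticForceAt <- function(forces, state, probes) {
  n <- nrow(state@positions)
  vapply(probes, function(k)
    forces[(k - 1) %% n + 1, (k - 1) %/% n + 1], numeric(1))
}
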