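## Deterministic generators: water boxes, slabs, proton-disordered ice Ih,
## and synthetic time series / curves with known ground truth.  Every
## generator is a pure function of (parameters, seed).

waterTemplate <- function(params) {
  ## one molecule in Angstrom: O at origin, HOH bisector along +z
  th <- params@thetaE * pi / 180
  re <- params@re
  rbind(O  = c(0, 0, 0),
        H1 = re * c(sin(th / 2), 0, cos(th / 2)),
        H2 = re * c(-sin(th / 2), 0, cos(th / 2)))
}

randomRotations <- function(n) {
  ## uniform rotations via normalized quaternions
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) {
    w <- q[i, 1]; x <- q[i, 2]; y <- q[i, 3]; z <- q[i, 4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
}

assembleState <- function(oPositionsA, rots, params, boxA, meta) {
  tmpl <- waterTemplate(params)
  n <- nrow(oPositionsA)
  pos <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    mol <- tmpl %*% t(rots[[i]])
    pos[(3 * i - 2):(3 * i), ] <- sweep(mol, 2, oPositionsA[i, ], `+`)
  }
  new("SystemState", box = boxA / 10, positions = pos / 10,
      velocities = matrix(0, 3 * n, 3),
      molecule = rep(seq_len(n), each = 3L),
      siteNames = rep(c("OW", "HW1", "HW2"), n),
      time = 0, wrapped = TRUE, metadata = meta)
}

#' Build a bulk water box on a jittered lattice
#'
#' Molecules are placed on a cubic lattice with small positional jitter and
#' uniformly random orientations, at the box size implied by the target
#' mass density.  The construction guarantees a minimum intermolecular O-O
#' distance; it is deterministic per seed.
#'
#' @param n number of molecules (>= 2); protocol sizes are 216, 343, 1728
#' @param density target mass density (kg/m^3)
#' @param seed RNG seed
#' @param params \code{ForceFieldParameters} (sets the molecular geometry)
#' @param minOO minimum acceptable O-O distance (Angstrom)
#' @return a \code{SystemState} (wrapped positions, zero velocities)
#' @examples
#' st <- buildWaterBox(32, 997, seed = 1)
#' boxLengths(st)   # cube edge from the density formula
#' @export
buildWaterBox <- function(n, density = 997, seed = 1,
                          params = loadParameters("EG298"), minOO = 2.4) {
  stopifnot(n >= 2, density > 0)
  set.seed(seed)
  pc <- physicalConstants
  vA <- n * pc$waterMolarMass / (density * 1e3) / pc$avogadro * 1e30  # A^3
  L <- vA^(1 / 3)
  ## bcc lattice (two sites per cell): nearest neighbor sqrt(3)/2 * a
  m <- ceiling((n / 2)^(1 / 3))
  a <- L / m
  nn <- sqrt(3) / 2 * a
  if (nn < minOO + 0.2)
    stop(sprintf(
      "density %.4g kg/m^3 geometrically unattainable for the lattice builder (nearest neighbor %.3g A < %.3g A)",
      density, nn, minOO + 0.2))
  corner <- as.matrix(expand.grid(x = seq_len(m), y = seq_len(m),
                                  z = seq_len(m))) - 1
  grid <- rbind(corner, sweep(corner, 2, 0.5, `+`)) + 0.25
  idx <- sample(nrow(grid), n)
  jitterAmp <- min(0.08 * a, (nn - minOO) / 4)
  oPos <- grid[idx, , drop = FALSE] * a +
    matrix(stats::runif(3 * n, -jitterAmp, jitterAmp), n, 3)
  st <- assembleState(oPos, randomRotations(n), params, rep(L, 3),
                      list(generator = "buildWaterBox", seed = seed,
                           density = density, variant = params@variant))
  st
}

#' Build a liquid slab with vacuum
#'
#' A slab of the stated lateral dimensions centered in a taller box; the
#' slab thickness follows from the target density, leaving vacuum above and
#' below.  Defaults reproduce the 2139-molecule supercooled-slab geometry
#' (3.999 x 3.999 x 10 nm^3); the ambient protocol uses
#' \code{buildSlab(1728, lateral = 3.58)}.
#'
#' @param n number of molecules
#' @param lateral lateral box edge (nm)
#' @param lz total box height (nm)
#' @param density liquid density used to size the slab (kg/m^3)
#' @param seed RNG seed
#' @param params \code{ForceFieldParameters}
#' @param rCut cutoff (nm) used only to warn when the vacuum gap is too thin
#' @return a \code{SystemState}
#' @export
buildSlab <- function(n = 2139, lateral = 3.999, lz = 10, density = 997,
                      seed = 1, params = loadParameters("EG273"),
                      rCut = 1.75) {
  pc <- physicalConstants
  set.seed(seed)
  vNm <- n * pc$waterMolarMass / (density * 1e3) / pc$avogadro * 1e27
  thick <- vNm / lateral^2
  vacuum <- lz - thick
  if (vacuum <= 0) stop("slab does not fit: vacuum gap would be negative")
  if (vacuum < 2 * rCut)
    warning(sprintf("vacuum gap %.3g nm is below twice the cutoff %.3g nm",
                    vacuum, rCut))
  ## lattice inside lateral x lateral x thick, centered in z
  aspect <- c(lateral, lateral, thick)
  m <- ceiling((n / prod(aspect))^(1 / 3) * aspect)
  while (prod(m) < n) m[which.min(m / aspect)] <- m[which.min(m / aspect)] + 1
  spacing <- aspect / m * 10   # A
  grid <- as.matrix(expand.grid(x = seq_len(m[1]), y = seq_len(m[2]),
                                z = seq_len(m[3]))) - 0.5
  idx <- sample(nrow(grid), n)
  oPos <- sweep(grid[idx, , drop = FALSE], 2, spacing, `*`)
  jitterAmp <- 0.08 * min(spacing)
  oPos <- oPos + matrix(stats::runif(3 * n, -jitterAmp, jitterAmp), n, 3)
  oPos[, 3] <- oPos[, 3] + (lz - thick) / 2 * 10
  assembleState(oPos, randomRotations(n), params,
                c(lateral, lateral, lz) * 10,
                list(generator = "buildSlab", seed = seed, density = density,
                     thickness = thick, vacuum = vacuum))
}

## ---------------------------------------------------------------------------
## Ice Ih

iceOxygenLattice <- function(nx, ny, nz, a = 4.5, c = 7.32) {
  ax <- a; ay <- a * sqrt(3); az <- c
  base <- rbind(
    c(0,       a * sqrt(3) / 3,     3 / 16 * c),
    c(0,       a * sqrt(3) / 3,    13 / 16 * c),
    c(a / 2,   a * sqrt(3) / 6,     5 / 16 * c),
    c(a / 2,   a * sqrt(3) / 6,    11 / 16 * c))
  base <- rbind(base, sweep(base, 2, c(ax / 2, ay / 2, 0), `+`))
  cells <- as.matrix(expand.grid(ix = 0:(nx - 1), iy = 0:(ny - 1),
                                 iz = 0:(nz - 1)))
  pos <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k)
    sweep(base, 2, cells[k, ] * c(ax, ay, az), `+`)))
  list(pos = pos, box = c(nx * ax, ny * ay, nz * az))
}

iceNeighbors <- function(posA, boxA, rmax = 3.2) {
  n <- nrow(posA)
  out <- list()
  k <- 0
  for (i in seq_len(n - 1)) {
    dd <- sweep(posA[(i + 1):n, , drop = FALSE], 2, posA[i, ])
    dd <- dd - sweep(round(sweep(dd, 2, boxA, `/`)), 2, boxA, `*`)
    r <- sqrt(rowSums(dd^2))
    js <- which(r < rmax)
    for (j in js) {
      k <- k + 1
      out[[k]] <- c(i, i + j)
    }
  }
  do.call(rbind, out)
}

#' Build proton-disordered hexagonal ice (ice Ih)
#'
#' Oxygens are placed on the lonsdaleite (hexagonal-diamond) lattice of ice
#' Ih in an orthorhombic supercell (8 molecules per cell, lattice constants
#' a = 4.5 Angstrom, c = 7.32 Angstrom by default, giving the familiar
#' ~0.92 g/cm^3).  A seeded stochastic assignment places one hydrogen on
#' every O-O bond and repairs violations until the Bernal-Fowler ice rules
#' hold: every oxygen donates exactly two hydrogens and every bond carries
#' exactly one.
#'
#' @param cells integer length-3: unit-cell counts (nx >= 2 so that
#'   nearest-neighbor images are unambiguous)
#' @param seed RNG seed (different seeds give different proton topologies
#'   on the same oxygen lattice)
#' @param params \code{ForceFieldParameters}: sets the OH length used to
#'   place hydrogens along the accepted bonds
#' @param a,c lattice constants (Angstrom)
#' @param maxRestarts internal re-seeds of the repair sweep before erroring
#' @return a \code{SystemState}; metadata records the lattice constants,
#'   seed and donor assignment
#' @export
buildIceIh <- function(cells = c(2, 2, 2), seed = 1,
                       params = loadParameters("EG273"),
                       a = 4.5, c = 7.32, maxRestarts = 10) {
  stopifnot(length(cells) == 3, all(cells >= 1), cells[1] >= 2)
  lat <- iceOxygenLattice(cells[1], cells[2], cells[3], a, c)
  nb <- iceNeighbors(lat$pos, lat$box)
  n <- nrow(lat$pos)
  if (nrow(nb) != 2 * n)
    stop("internal error: oxygen lattice is not 4-coordinated")
  set.seed(seed)
  for (restart in seq_len(maxRestarts)) {
    donor <- sample(c(TRUE, FALSE), nrow(nb), replace = TRUE)
    ## donor[k] TRUE: H on bond k sits with nb[k,1]
    nH <- function() {
      h <- tabulate(nb[, 1][donor], n) + tabulate(nb[, 2][!donor], n)
      h
    }
    h <- nH()
    cost <- sum((h - 2)^2)
    maxSweep <- 400 * nrow(nb)
    it <- 0
    while (cost > 0 && it < maxSweep) {
      it <- it + 1
      k <- sample.int(nrow(nb), 1)
      i <- nb[k, 1]; j <- nb[k, 2]
      from <- if (donor[k]) i else j
      to <- if (donor[k]) j else i
      dcost <- ((h[from] - 1 - 2)^2 + (h[to] + 1 - 2)^2) -
        ((h[from] - 2)^2 + (h[to] - 2)^2)
      if (dcost < 0 || (dcost == 0 && stats::runif(1) < 0.5)) {
        donor[k] <- !donor[k]
        h[from] <- h[from] - 1
        h[to] <- h[to] + 1
        cost <- cost + dcost
      }
    }
    if (cost == 0) break
    if (restart == maxRestarts)
      stop("proton-disorder assignment did not converge; try another seed")
  }
  ## place hydrogens at r_e along the two accepted bonds of each oxygen
  pos <- matrix(0, 3 * n, 3)
  boxA <- lat$box
  for (i in seq_len(n)) {
    ks <- which((nb[, 1] == i & donor) | (nb[, 2] == i & !donor))
    stopifnot(length(ks) == 2)
    pos[3 * i - 2, ] <- lat$pos[i, ]
    for (s in 1:2) {
      k <- ks[s]
      other <- if (nb[k, 1] == i) nb[k, 2] else nb[k, 1]
      d <- lat$pos[other, ] - lat$pos[i, ]
      d <- d - round(d / boxA) * boxA
      pos[3 * i - 2 + s, ] <- lat$pos[i, ] + params@re * d / sqrt(sum(d^2))
    }
  }
  new("SystemState", box = boxA / 10, positions = pos / 10,
      velocities = matrix(0, 3 * n, 3),
      molecule = rep(seq_len(n), each = 3L),
      siteNames = rep(c("OW", "HW1", "HW2"), n),
      time = 0, wrapped = TRUE,
      metadata = list(generator = "buildIceIh", seed = seed, a = a, c = c,
                      cells = cells, donor = donor, bonds = nb))
}

## ---------------------------------------------------------------------------
## Synthetic series and curves with known ground truth

ar1Series <- function(n, mean, sd, phi = 0) {
  x <- stats::rnorm(n)
  if (phi > 0) x <- as.numeric(stats::filter(x, phi, "recursive")) *
      sqrt(1 - phi^2)
  mean + sd * x
}

#' Synthetic observable series with known ground truth
#'
#' Stationary Gaussian (optionally AR(1)-correlated) or random-walk
#' processes whose moments are chosen by inverting the target estimator's
#' formula at generation time, so each estimator can be checked against an
#' exact known answer.
#'
#' Kinds and their \code{trueParams}:
#' \describe{
#'   \item{volume}{\code{mean} (nm^3), \code{T} (K) and either \code{sd}
#'     (nm^3) or \code{kappaT} (MPa^-1, inverted to the implied sd).}
#'   \item{enthalpy}{\code{mean}, \code{sd} (kcal/mol).}
#'   \item{dipole}{\code{V} (nm^3), \code{T} (K), \code{epsilonRaw}
#'     (fluctuation-route dielectric constant; inverted to the implied
#'     per-component dipole sd in e nm).}
#'   \item{pressure_tensor}{\code{gamma} (mN/m), \code{Lz} (nm),
#'     \code{Pbase}, \code{sd} (bar).}
#'   \item{msd_walk}{\code{D} (1e-5 cm^2/s), \code{nParticles}.}
#' }
#'
#' @param kind one of the kinds above
#' @param trueParams named list, see Details
#' @param length number of samples (frames)
#' @param dt sampling interval (ps)
#' @param seed RNG seed
#' @param phi AR(1) coefficient to exercise block averaging (default 0)
#' @return list with \code{series} (a \code{TimeSeries}, or a data.frame for
#'   tensor/dipole kinds, or an array frames x particles x 3 for
#'   \code{msd_walk}) and \code{truth} (generator name, true values, seed)
#' @export
synthSeries <- function(kind = c("volume", "enthalpy", "dipole",
                                 "pressure_tensor", "msd_walk"),
                        trueParams = list(), length = 1000, dt = 1,
                        seed = 1, phi = 0) {
  kind <- match.arg(kind)
  if (length <= 0) stop("series length must be positive")
  set.seed(seed)
  pc <- physicalConstants
  tp <- trueParams
  truth <- list(generator = paste0("synthSeries:", kind), seed = seed)
  if (kind == "volume") {
    if (is.null(tp$sd)) {
      ## invert the fluctuation formula: var(V) = kappa kB T <V>
      kPa <- tp$kappaT * 1e-6                       # 1/Pa
      varSI <- kPa * pc$kBSI * tp$T * (tp$mean * 1e-27)
      tp$sd <- sqrt(varSI) * 1e27                   # nm^3
    }
    truth$kappaT <- tp$kappaT %||%
      ((tp$sd * 1e-27)^2 / (pc$kBSI * tp$T * tp$mean * 1e-27) * 1e6)
    truth$mean <- tp$mean; truth$T <- tp$T
    ser <- newTimeSeries(ar1Series(length, tp$mean, tp$sd, phi),
                         "volume", "nm^3", dt)
  } else if (kind == "enthalpy") {
    truth$mean <- tp$mean; truth$sd <- tp$sd
    ser <- newTimeSeries(ar1Series(length, tp$mean, tp$sd, phi),
                         "enthalpy", "kcal/mol", dt)
  } else if (kind == "dipole") {
    varTot <- (tp$epsilonRaw - 1) * 3 * pc$eps0 * (tp$V * 1e-27) *
      pc$kBSI * tp$T                                # (C m)^2
    sdComp <- sqrt(varTot / 3) / (pc$eCharge * 1e-9) # e nm
    truth$epsilonRaw <- tp$epsilonRaw; truth$V <- tp$V; truth$T <- tp$T
    ser <- data.frame(Mx = ar1Series(length, 0, sdComp, phi),
                      My = ar1Series(length, 0, sdComp, phi),
                      Mz = ar1Series(length, 0, sdComp, phi))
    attr(ser, "dt") <- dt
  } else if (kind == "pressure_tensor") {
    dP <- tp$gamma / (0.1 * tp$Lz / 2)              # bar
    truth$gamma <- tp$gamma; truth$Lz <- tp$Lz
    ser <- data.frame(
      Pxx = ar1Series(length, tp$Pbase, tp$sd, phi),
      Pyy = ar1Series(length, tp$Pbase, tp$sd, phi),
      Pzz = ar1Series(length, tp$Pbase + dP, tp$sd, phi))
    attr(ser, "dt") <- dt
  } else { # msd_walk
    Dnm <- tp$D * 1e-3                              # nm^2/ps
    np <- tp$nParticles %||% 16
    stepSd <- sqrt(2 * Dnm * dt)
    ser <- array(0, c(length, np, 3))
    for (p in seq_len(np))
      for (d in 1:3)
        ser[, p, d] <- cumsum(c(0, stats::rnorm(length - 1, 0, stepSd)))
    truth$D <- tp$D
    attr(ser, "dt") <- dt
  }
  list(series = ser, truth = truth)
}

## closed forms shared by the curve generators and the fitters -------------

#' Extended IAPWS surface-tension correlation
#'
#' gamma(T) = B tau^mu (1 + b tau) + gamma_s exp(c (T_e - T)), tau = 1-T/T_c:
#' the classical IAPWS term plus an exponential component that emerges in
#' the supercooled regime; by construction the deviation from the classical
#' term equals gamma_s at T = T_e.
#'
#' @param T temperatures (K)
#' @param Tc critical temperature (K, fixed from coexistence fits)
#' @param B,b classical-term amplitude (mN/m) and correction
#' @param c exponential rate (1/K)
#' @param Te emergence temperature (K)
#' @param gammaS emergence amplitude convention (1 mN/m)
#' @param mu critical exponent (11/9)
#' @return surface tension (mN/m)
#' @export
iapwsEGamma <- function(T, Tc, B, b, c, Te, gammaS = 1, mu = 11 / 9) {
  tau <- 1 - T / Tc
  B * tau^mu * (1 + b * tau) + gammaS * exp(c * (Te - T))
}

#' @rdname iapwsEGamma
#' @export
iapwsClassicalGamma <- function(T, Tc, B, b, mu = 11 / 9) {
  tau <- 1 - T / Tc
  B * tau^mu * (1 + b * tau)
}

wegnerDelta <- function(T, Tc, B, beta = 0.325, Delta = 0.5) {
  ## B = c(B0, B1, ...): leading amplitude plus correction amplitudes
  tau <- 1 - T / Tc
  corr <- rep(1, length(T))
  if (length(B) > 1)
    for (i in seq_along(B[-1])) corr <- corr + B[i + 1] * tau^(i * Delta)
  B[1] * tau^beta * corr
}

coexDiameter <- function(T, Tc, rhoc, a1, a2, alphaPrime = 0.11) {
  tau <- 1 - T / Tc
  rhoc + a1 * tau^(1 - alphaPrime) + a2 * tau
}

antoineP <- function(T, A, B, C) exp(A - B / (T + C))

#' Synthetic analysis curves with known ground truth
#'
#' Evaluates the closed form of the target fitter on a temperature grid and
#' adds seeded Gaussian noise.
#'
#' Kinds and their \code{trueParams}:
#' \describe{
#'   \item{gamma_iapws_e}{\code{Tc, B, b, c, Te} (and optional
#'     \code{gammaS}, \code{mu}); noise is absolute (mN/m).}
#'   \item{coexistence_wegner}{\code{Tc, B0, B1, rhoc, a1, a2}; noise is
#'     absolute (kg/m^3) on both branches.}
#'   \item{antoine}{\code{A, B, C}; noise is relative on P (applied to
#'     ln P).}
#' }
#'
#' @param kind curve family
#' @param trueParams named list (see Details)
#' @param Tgrid temperatures (K); coexistence/gamma grids must stay below Tc
#' @param noise noise scale (0 for exact curves)
#' @param seed RNG seed
#' @return list with \code{points} (data.frame) and \code{truth}
#' @export
synthCurves <- function(kind = c("gamma_iapws_e", "coexistence_wegner",
                                 "antoine"),
                        trueParams = list(), Tgrid, noise = 0, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  tp <- trueParams
  truth <- c(list(generator = paste0("synthCurves:", kind), seed = seed), tp)
  if (kind == "gamma_iapws_e") {
    if (any(Tgrid >= tp$Tc)) stop("temperature grid must stay below T_c")
    g <- iapwsEGamma(Tgrid, tp$Tc, tp$B, tp$b, tp$c, tp$Te,
                     tp$gammaS %||% 1, tp$mu %||% (11 / 9))
    pts <- data.frame(T = Tgrid, gamma = g + stats::rnorm(length(Tgrid), 0, noise),
                      stderr = if (noise > 0) noise else 1e-6)
  } else if (kind == "coexistence_wegner") {
    if (any(Tgrid >= tp$Tc)) stop("coexistence grid must stay below T_c")
    del <- wegnerDelta(Tgrid, tp$Tc, c(tp$B0, tp$B1))
    dia <- coexDiameter(Tgrid, tp$Tc, tp$rhoc, tp$a1, tp$a2)
    pts <- data.frame(
      T = Tgrid,
      rhoLiquid = dia + del / 2 + stats::rnorm(length(Tgrid), 0, noise),
      rhoVapor = dia - del / 2 + stats::rnorm(length(Tgrid), 0, noise))
  } else {
    p <- antoineP(Tgrid, tp$A, tp$B, tp$C)
    pts <- data.frame(T = Tgrid,
                      P = exp(log(p) + stats::rnorm(length(Tgrid), 0, noise)))
  }
  list(points = pts, truth = truth)
}
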