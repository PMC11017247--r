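## Property estimators: RDF, isothermal compressibility, heat capacity,
## heat of vaporization, dielectric constant, self-diffusion, surface
## tension, and ensemble-geometry extraction for the EG variants.
##
## Conventions shared by all estimators: an explicit equilibration discard
## fraction (default 10%), block averaging for error bars (default 10
## blocks), SI conversion at this boundary, and pure-function behavior
## (same input, same output).

discardValues <- function(x, discard) {
  n0 <- length(x)
  keep <- seq.int(floor(discard * n0) + 1, n0)
  x[keep]
}

blockMeans <- function(x, blocks) {
  n <- length(x)
  b <- max(2, min(blocks, n))
  idx <- floor((seq_len(n) - 1) * b / n) + 1
  as.numeric(tapply(x, idx, mean))
}

blockStderrOf <- function(x, blocks, stat = mean) {
  n <- length(x)
  b <- max(2, min(blocks, n %/% 2))
  idx <- floor((seq_len(n) - 1) * b / n) + 1
  vals <- as.numeric(tapply(x, idx, stat))
  stats::sd(vals) / sqrt(length(vals))
}

seriesIn <- function(x) if (methods::is(x, "TimeSeries")) x@values else as.numeric(x)

#' Isothermal compressibility from volume fluctuations
#'
#' kappa_T = var(V) / (k_B T <V>) on an equilibrated NPT volume series,
#' SI-converted to 1/MPa.  Uncertainty from block averaging (per-block
#' kappa estimates).
#'
#' @param volumes \code{TimeSeries} or numeric, nm^3
#' @param T temperature (K)
#' @param discard equilibration fraction discarded from the front
#' @param blocks number of blocks for the error bar
#' @return a \code{PropertyEstimate} (MPa^-1)
#' @export
kappaT <- function(volumes, T, discard = 0.1, blocks = 10) {
  if (T <= 0) stop("temperature must be positive")
  v <- discardValues(seriesIn(volumes), discard)
  if (length(v) < 10 * blocks)
    warning("volume series is short (fewer than 10 samples per block); ",
            "the error bar is unreliable")
  pc <- physicalConstants
  kap <- function(x) {
    vm <- mean(x) * 1e-27                       # m^3
    stats::var(x) * 1e-54 / (pc$kBSI * T * vm) * 1e6   # 1/MPa
  }
  value <- kap(v)
  n <- length(v)
  b <- max(2, min(blocks, n %/% 2))
  idx <- floor((seq_len(n) - 1) * b / n) + 1
  bk <- as.numeric(tapply(v, idx, kap))
  se <- stats::sd(bk) / sqrt(length(bk))
  new("PropertyEstimate", value = value, units = "1/MPa",
      stderr = if (is.finite(se)) se else 0,
      settings = list(T = T, discard = discard, blocks = blocks),
      provenance = "NPT volume fluctuation formula")
}

#' Heat capacity by finite differences of the enthalpy
#'
#' C_p = (<H(T2)> - <H(T1)>) / (T2 - T1) / N, converted to J/(mol K).
#' The protocol pair is (295, 301) K for a 298 K estimate.  The result is
#' invariant under swapping the two series.
#'
#' @param h1,h2 enthalpy series (\code{TimeSeries} or numeric, kcal/mol for
#'   the whole box) at temperatures \code{T1}, \code{T2}
#' @param T1,T2 the two temperatures (K); must differ
#' @param N number of molecules
#' @param discard,blocks see \code{\link{kappaT}}
#' @return a \code{PropertyEstimate} (J/(mol K))
#' @export
heatCapacityFd <- function(h1, T1, h2, T2, N, discard = 0.1, blocks = 10) {
  if (T1 == T2) stop("the two temperatures must differ")
  a <- discardValues(seriesIn(h1), discard)
  b <- discardValues(seriesIn(h2), discard)
  cp <- (mean(b) - mean(a)) / (T2 - T1) / N * 4184
  se <- sqrt(blockStderrOf(a, blocks)^2 + blockStderrOf(b, blocks)^2) /
    abs(T2 - T1) / N * 4184
  new("PropertyEstimate", value = cp, units = "J/(mol K)", stderr = se,
      settings = list(T1 = T1, T2 = T2, N = N, discard = discard,
                      blocks = blocks),
      provenance = "finite-difference enthalpy quotient")
}

#' Polarization self-energy correction for the heat of vaporization
#'
#' The energetic cost of the condensed-phase dipole enhancement of an
#' effective pair potential: -(mu_model - mu_gas)^2 / (2 alpha), evaluated
#' with the gas-phase dipole and isotropic polarizability of the water
#' monomer.  Negative: it reduces the classical heat of vaporization.
#'
#' @param muModel the model's molecular dipole (Debye); see
#'   \code{\link{modelDipole}}
#' @param muGas gas-phase monomer dipole (Debye)
#' @param alphaPol isotropic polarizability (Angstrom^3)
#' @return energy (kcal/mol)
#' @export
deltaESelf <- function(muModel, muGas = 1.855, alphaPol = 1.47) {
  pc <- physicalConstants
  dmu <- (muModel - muGas) * pc$debye           # C m
  eJ <- -dmu^2 / (2 * alphaPol * 1e-30) / (4 * pi * pc$eps0)
  eJ * pc$avogadro / 4184                       # kcal/mol
}

#' Dipole moment of one model molecule at its equilibrium geometry
#'
#' @param params a \code{ForceFieldParameters}
#' @return dipole (Debye)
#' @export
modelDipole <- function(params) {
  th <- params@thetaE * pi / 180
  dM <- params@a * 2 * params@re * cos(th / 2)
  mu <- 2 * params@qH * params@re * cos(th / 2) + params@qM * dM  # e A
  pc <- physicalConstants
  mu * pc$eCharge * 1e-10 / pc$debye
}

#' Heat of vaporization
#'
#' Delta H_vap = <V_gas> - <V_liq>/N + RT + Delta E_self, where <V> are
#' mean potential energies of the respective phases, the gas series comes
#' from a single-molecule run, and Delta E_self is the polarization
#' self-energy correction (reported separately; see
#' \code{\link{deltaESelf}}).  Path-integral studies place the missing
#' nuclear-quantum correction near -6 kJ/mol; it is attached as an
#' annotation, never applied.
#'
#' @param vLiquid liquid potential-energy series (kcal/mol, whole box of N)
#' @param N molecules in the liquid box
#' @param vGas gas (single-molecule) potential-energy series (kcal/mol)
#' @param T temperature (K)
#' @param dESelf self-energy correction (kcal/mol), e.g.
#'   \code{deltaESelf(modelDipole(params))}
#' @param discard,blocks see \code{\link{kappaT}}
#' @return a \code{PropertyEstimate} (kJ/mol); \code{settings} carries each
#'   term (kJ/mol) and the quantum-correction annotation
#' @export
deltaHVap <- function(vLiquid, N, vGas, T, dESelf = 0, discard = 0.1,
                      blocks = 10) {
  if (missing(vGas) || is.null(vGas))
    stop("gas-phase potential-energy series is required")
  liq <- discardValues(seriesIn(vLiquid), discard)
  gas <- discardValues(seriesIn(vGas), discard)
  pc <- physicalConstants
  RT <- pc$kB * T
  terms <- c(gas = mean(gas), liquidPerMol = -mean(liq) / N, RT = RT,
             dESelf = dESelf)
  dh <- sum(terms) * 4.184
  se <- sqrt(blockStderrOf(gas, blocks)^2 +
             (blockStderrOf(liq, blocks) / N)^2) * 4.184
  new("PropertyEstimate", value = dh, units = "kJ/mol", stderr = se,
      settings = list(terms_kJ = terms * 4.184, T = T,
                      quantumCorrection_kJ = -6,
                      quantumCorrected = dh - 6),
      provenance = "phase-energy difference with self-energy correction")
}

#' Static dielectric constant from dipole fluctuations
#'
#' Fluctuation-dissipation route
#' eps_raw = 1 + (<M^2> - <M>^2) / (3 eps0 V k_B T), followed by the
#' electronic-continuum scaling by the high-frequency dielectric constant,
#' eps = eps_inf * eps_raw with eps_inf = 1.78.  Both the raw and the
#' scaled values are always reported.
#'
#' @param M total-dipole series: matrix/data.frame with 3 columns (e nm)
#' @param V mean box volume (nm^3)
#' @param T temperature (K)
#' @param epsInf high-frequency dielectric constant
#' @param discard,blocks see \code{\link{kappaT}}
#' @return a \code{PropertyEstimate}; \code{value} is the scaled constant,
#'   \code{settings$raw} the unscaled fluctuation result
#' @export
dielectricConstant <- function(M, V, T, epsInf = 1.78, discard = 0.1,
                               blocks = 10) {
  if (V <= 0 || T <= 0) stop("volume and temperature must be positive")
  M <- as.matrix(as.data.frame(M)[, 1:3])
  keep <- seq.int(floor(discard * nrow(M)) + 1, nrow(M))
  M <- M[keep, , drop = FALSE]
  pc <- physicalConstants
  unit2 <- (pc$eCharge * 1e-9)^2                 # (e nm)^2 -> (C m)^2
  denom <- 3 * pc$eps0 * (V * 1e-27) * pc$kBSI * T
  epsOf <- function(rows) {
    varM <- sum(apply(M[rows, , drop = FALSE], 2, stats::var))
    1 + varM * unit2 / denom
  }
  raw <- epsOf(seq_len(nrow(M)))
  n <- nrow(M)
  b <- max(2, min(blocks, n %/% 2))
  idx <- floor((seq_len(n) - 1) * b / n) + 1
  bk <- vapply(split(seq_len(n), idx), epsOf, numeric(1))
  seRaw <- stats::sd(bk) / sqrt(length(bk))
  new("PropertyEstimate", value = epsInf * raw, units = "",
      stderr = epsInf * (if (is.finite(seRaw)) seRaw else 0),
      settings = list(raw = raw, rawStderr = seRaw, epsInf = epsInf,
                      V = V, T = T, blocks = blocks),
      provenance = "dipole fluctuation-dissipation with eps_inf scaling")
}

#' Self-diffusion constant by the Einstein relation
#'
#' D = slope(MSD)/6 over a fit window chosen to exclude the ballistic
#' regime.  Requires unwrapped coordinates; wrapped input (single-step
#' jumps beyond half a box length) is rejected.  A quadratic term is fitted
#' alongside the linear one as a diagnostic: significant curvature flags a
#' non-diffusive (e.g. drifting) regime.  The +15% nuclear-quantum
#' annotation is attached in \code{settings}, never applied.
#'
#' @param positions array frames x particles x 3 of unwrapped positions
#'   (nm), typically oxygen trajectories
#' @param dt frame interval (ps)
#' @param fitWindow lag-time window (ps) for the linear fit
#' @param box optional box lengths (nm) used for the wrap check
#' @return a \code{PropertyEstimate} (1e-5 cm^2/s)
#' @export
diffusionEinstein <- function(positions, dt,
                              fitWindow = c(2, 10) * dt * 10, box = NULL) {
  stopifnot(length(dim(positions)) == 3)
  nf <- dim(positions)[1]
  if (!is.null(box)) {
    jump <- apply(abs(positions[-1, , , drop = FALSE] -
                      positions[-nf, , , drop = FALSE]), 3, max)
    if (any(jump > box / 2))
      stop("wrapped coordinates detected (single-step jump beyond half a ",
           "box length); diffusion needs unwrapped input")
  }
  maxLag <- min(nf - 1, ceiling(fitWindow[2] / dt))
  lags <- seq_len(maxLag)
  np <- dim(positions)[2]
  msdP <- vapply(lags, function(l) {
    d <- positions[-(1:l), , , drop = FALSE] -
      positions[seq_len(nf - l), , , drop = FALSE]
    colMeans(apply(d^2, c(1, 2), sum))
  }, numeric(np))                               # np x nlag
  msdP <- matrix(msdP, nrow = np)
  msd <- colMeans(msdP)
  tl <- lags * dt
  sel <- tl >= fitWindow[1] & tl <= fitWindow[2]
  if (sum(sel) < 3) stop("fit window contains fewer than 3 lag times")
  fit <- stats::lm(msd[sel] ~ tl[sel])
  slope <- stats::coef(fit)[2]                  # nm^2/ps
  ## error bar from the dispersion of independent per-particle slopes
  ## (residuals of a single pooled MSD fit are strongly correlated)
  slopesP <- apply(msdP[, sel, drop = FALSE], 1, function(y)
    stats::coef(stats::lm(y ~ tl[sel]))[2])
  seSlope <- stats::sd(slopesP) / sqrt(np)
  fit2 <- stats::lm(msd[sel] ~ tl[sel] + I(tl[sel]^2))
  quad <- summary(fit2)$coefficients
  nonDiffusive <- nrow(quad) >= 3 && quad[3, 4] < 0.01 &&
    abs(quad[3, 1]) * max(tl[sel]) > 0.5 * abs(quad[2, 1])
  D5 <- slope / 6 * 1e3                         # 1e-5 cm^2/s
  new("PropertyEstimate", value = unname(D5), units = "1e-5 cm^2/s",
      stderr = unname(seSlope / 6 * 1e3),
      settings = list(fitWindow = fitWindow, dt = dt,
                      nonDiffusive = nonDiffusive,
                      quantumCorrected15pct = unname(D5 * 1.15)),
      provenance = "Einstein MSD slope / 6")
}

#' Surface tension from the pressure-tensor anisotropy of a slab
#'
#' gamma = (L_Z / 2) (<P_Z> - (<P_X> + <P_Y>)/2), converted from bar nm to
#' mN/m (1 bar nm = 0.1 mN/m).  The factor 1/2 accounts for the two
#' interfaces of a periodic slab.
#'
#' @param tensor data.frame with columns \code{Pxx}, \code{Pyy}, \code{Pzz}
#'   (bar), e.g. \code{trajectorySeries(traj)}
#' @param Lz box length normal to the interfaces (nm)
#' @param discard,blocks see \code{\link{kappaT}}
#' @return a \code{PropertyEstimate} (mN/m)
#' @export
surfaceTension <- function(tensor, Lz, discard = 0.1, blocks = 10) {
  need <- c("Pxx", "Pyy", "Pzz")
  if (!all(need %in% names(tensor)))
    stop("pressure-tensor input must provide columns ",
         paste(need, collapse = ", "))
  aniso <- tensor$Pzz - (tensor$Pxx + tensor$Pyy) / 2
  aniso <- discardValues(aniso, discard)
  gam <- 0.1 * Lz / 2 * mean(aniso)
  se <- 0.1 * Lz / 2 * blockStderrOf(aniso, blocks)
  new("PropertyEstimate", value = gam, units = "mN/m",
      stderr = if (is.finite(se)) se else 0,
      settings = list(Lz = Lz, discard = discard, blocks = blocks),
      provenance = "slab pressure-tensor anisotropy")
}

#' Ensemble geometry of a flexible trajectory
#'
#' The rigid EG variants are constructed from thermal averages of the
#' intramolecular distances: r_e = <OH> over all bonds and frames, and
#' theta_e = 2 arcsin(<HH> / (2 <OH>)).  The angle is derived from the mean
#' distances (not the mean angle; the two differ).
#'
#' @param traj a \code{Trajectory} with snapshots from a flexible run, or a
#'   list of \code{SystemState} snapshots
#' @param params optional \code{ForceFieldParameters}; when the trajectory
#'   carries rigid parameters the call errors
#' @return list with \code{re} (Angstrom), \code{thetaE} (degrees),
#'   \code{meanOH}, \code{meanHH} (Angstrom) and the frame count
#' @export
ensembleGeometry <- function(traj, params = NULL) {
  if (methods::is(traj, "Trajectory")) {
    if (is.null(params)) params <- traj@params
    snaps <- traj@snapshots
    if (!length(snaps)) snaps <- list(traj@finalState)
  } else snaps <- traj
  if (!is.null(params) && isRigid(params))
    stop("ensemble geometry is extracted from flexible trajectories; '",
         params@variant, "' is rigid")
  ohs <- hhs <- numeric(0)
  for (st in snaps) {
    p <- st@positions * 10
    n <- nMolecules(st)
    iO <- 3 * (seq_len(n) - 1) + 1
    ohs <- c(ohs,
             sqrt(rowSums((p[iO + 1, , drop = FALSE] - p[iO, , drop = FALSE])^2)),
             sqrt(rowSums((p[iO + 2, , drop = FALSE] - p[iO, , drop = FALSE])^2)))
    hhs <- c(hhs,
             sqrt(rowSums((p[iO + 2, , drop = FALSE] - p[iO + 1, , drop = FALSE])^2)))
  }
  mOH <- mean(ohs); mHH <- mean(hhs)
  list(re = mOH, thetaE = 2 * asin(mHH / (2 * mOH)) * 180 / pi,
       meanOH = mOH, meanHH = mHH, frames = length(snaps))
}

#' Radial distribution function
#'
#' Site-site g(r) over trajectory snapshots, normalized so that an ideal
#' uniform fluid gives g = 1 at all r.
#'
#' @param snapshots list of \code{SystemState} (or a \code{Trajectory})
#' @param pair "OO", "OH" or "HH"
#' @param binWidth bin width (nm)
#' @param rMax maximum distance (nm); must not exceed half the minimum box
#'   length
#' @return data.frame with bin centers \code{r} (nm) and \code{g}
#' @export
rdfCalc <- function(snapshots, pair = c("OO", "OH", "HH"), binWidth = 0.005,
                    rMax = NULL) {
  pair <- match.arg(pair)
  if (methods::is(snapshots, "Trajectory")) {
    tr <- snapshots
    snapshots <- tr@snapshots
    if (!length(snapshots)) snapshots <- list(tr@finalState)
  }
  box <- snapshots[[1]]@box
  if (is.null(rMax)) rMax <- min(box) / 2
  if (rMax > min(box) / 2 + 1e-9)
    stop("rMax exceeds half the minimum box length")
  edges <- seq(0, rMax, by = binWidth)
  counts <- numeric(length(edges) - 1)
  nPairsIdeal <- 0
  V <- prod(box)
  for (st in snapshots) {
    p <- st@positions
    n <- nMolecules(st)
    iO <- 3 * (seq_len(n) - 1) + 1
    iH <- c(rbind(iO + 1, iO + 2))
    ## intermolecular pairs only (bonded OH / geminal HH excluded)
    sel <- switch(pair,
      OO = list(p[iO, , drop = FALSE], NULL, seq_len(n), NULL),
      OH = list(p[iO, , drop = FALSE], p[iH, , drop = FALSE],
                seq_len(n), rep(seq_len(n), each = 2)),
      HH = list(p[iH, , drop = FALSE], NULL, rep(seq_len(n), each = 2), NULL))
    a <- sel[[1]]; bm <- sel[[2]]; molA <- sel[[3]]; molB <- sel[[4]]
    dists <- function(x, y, mx, my) {
      same <- is.null(y)
      if (same) { y <- x; my <- mx }
      out <- numeric(0)
      for (i in seq_len(nrow(x))) {
        js <- (if (same) seq_len(nrow(y)) > i else rep(TRUE, nrow(y))) &
          my != mx[i]
        if (!any(js)) next
        d <- sweep(y[js, , drop = FALSE], 2, x[i, ])
        d <- d - sweep(round(sweep(d, 2, box, `/`)), 2, box, `*`)
        out <- c(out, sqrt(rowSums(d^2)))
      }
      out
    }
    dd <- dists(a, bm, molA, molB)
    counts <- counts + graphics::hist(dd[dd < max(edges)], breaks = edges,
                                      plot = FALSE)$counts
    nPairsIdeal <- nPairsIdeal + switch(pair,
      OO = n * (n - 1) / 2, OH = n * (n - 1) * 2, HH = 2 * n * (2 * n - 2) / 2)
  }
  centers <- edges[-1] - binWidth / 2
  shellV <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  gg <- counts / (nPairsIdeal * shellV / V)
  data.frame(r = centers, g = gg)
}
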