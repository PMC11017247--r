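#!/usr/bin/env Rscript
## Ambient-condition property battery:
##  - kappa_T at 298 K / 1 bar from NPT volume fluctuations (1728 box)
##  - dielectric constant from 5 ns of dipole fluctuations (EG298)
##  - C_p by finite difference between NPT runs at 295 and 301 K (15 ns each)
##  - Delta H_vap of the flexible model (liquid box vs single molecule)
##    with the polarization self-energy correction
##  - ensemble geometry of a 5 ns flexible run at the reference
##    temperature (the EG-model constructor)
suppressMessages(library(rwail))
args <- commandArgs(TRUE)
get <- function(flag, default) {
  v <- sub(paste0(flag, "="), "", grep(flag, args, value = TRUE)[1])
  if (is.na(v)) default else as.numeric(v)
}
seed <- as.integer(get("--seed", 1))
scale <- get("--scale", 1)
res <- list(seed = seed)

pE <- loadParameters("EG298")
n <- max(125, round(1728 * scale))
st <- buildWaterBox(n, 997, seed = seed, params = pE)
npt <- function(T, steps, seed2, params = pE, state = st)
  runMD(state, params, steps = steps, dt = 2e-3, integrator = "npt",
        thermostat = thermostatParams(T, 2), barostat = barostatParams(1, 5),
        initTemperature = T, seed = seed2, sampleEvery = 25)

tr298 <- npt(298, round(2.5e6 * scale), seed)
s <- trajectorySeries(tr298)
s <- s[s$time > max(s$time) * 0.2, ]
res$kappaT_1e4_MPa <- estimateValue(kappaT(s$volume, 298, discard = 0)) * 1e4
eps <- dielectricConstant(s[c("Mx", "My", "Mz")], mean(s$volume), 298)
res$epsilon <- estimateValue(eps)
res$epsilon_raw <- eps@settings$raw

t295 <- npt(295, round(7.5e6 * scale), seed + 1)
t301 <- npt(301, round(7.5e6 * scale), seed + 2)
res$Cp_J_molK <- estimateValue(heatCapacityFd(
  trajectoryObservable(t295, "enthalpy"), 295,
  trajectoryObservable(t301, "enthalpy"), 301, n))

pF <- loadParameters("flexible")
liq <- runMD(buildWaterBox(n, 997, seed = seed, params = pF), pF,
             steps = round(1e7 * scale), dt = 5e-4, integrator = "npt",
             thermostat = thermostatParams(298, 2),
             barostat = barostatParams(1, 5), initTemperature = 298,
             seed = seed + 3, sampleEvery = 100,
             snapshotEvery = round(2e5 * scale))
gas <- runMD(buildWaterBox(2, 20, seed = seed, params = pF), pF,
             steps = round(1e7 * scale), dt = 5e-4, integrator = "nvt",
             thermostat = thermostatParams(298, 5e-4),
             cutoff = cutoffScheme(0.3, FALSE, FALSE),
             initTemperature = 298, seed = seed + 4, sampleEvery = 100)
dh <- deltaHVap(trajectoryObservable(liq, "epot"), n,
                newTimeSeries(trajectorySeries(gas)$epot / 2, "epot",
                              "kcal/mol"),
                298, dESelf = deltaESelf(modelDipole(pF)))
res$dHvap_kJ_mol <- estimateValue(dh)
res$dHvap_terms <- as.list(dh@settings$terms_kJ)

eg <- ensembleGeometry(liq)
res$eg_re_A <- eg$re
res$eg_theta_deg <- eg$thetaE
str(res)
out <- sub("--out=", "", grep("--out", args, value = TRUE)[1])
if (!is.na(out)) jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
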