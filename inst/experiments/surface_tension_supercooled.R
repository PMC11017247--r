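#!/usr/bin/env Rscript
## Surface tension across the supercooled and normal regimes with EG273:
## 2139-molecule slab (3.999 x 3.999 x 10 nm^3, 6 nm vacuum), 1.75 nm vdW
## cutoff, no tail corrections, Nose-Hoover at 2 ps; >= 10 ns
## equilibration and >= 15 ns of production per temperature.  The gamma(T)
## points are then fitted to the extended IAPWS correlation with T_c fixed
## from the coexistence analysis, yielding the emergence temperature T_e.
suppressMessages(library(rwail))
args <- commandArgs(TRUE)
get <- function(flag, default) {
  v <- sub(paste0(flag, "="), "", grep(flag, args, value = TRUE)[1])
  if (is.na(v)) default else as.numeric(v)
}
seed <- as.integer(get("--seed", 1))
scale <- get("--scale", 1)
Tc <- get("--tc", 683)                 # from the coexistence experiment

Ts <- c(230, 240, 250, 260, 273, 298, 325, 350)
pts <- NULL
p <- loadParameters("EG273")
for (T in Ts) {
  st <- buildSlab(2139, seed = seed, params = p)
  eq <- runMD(st, p, steps = round(5e6 * scale), dt = 2e-3,
              integrator = "nvt", thermostat = thermostatParams(T, 2),
              cutoff = slabCutoff(), initTemperature = T,
              seed = seed + T, sampleEvery = 500)
  pr <- runMD(finalState(eq), p, steps = round(7.5e6 * scale), dt = 2e-3,
              integrator = "nvt", thermostat = thermostatParams(T, 2),
              cutoff = slabCutoff(), seed = seed + T, sampleEvery = 50)
  g <- surfaceTension(trajectorySeries(pr), Lz = 10)
  pts <- rbind(pts, data.frame(T = T, gamma = estimateValue(g),
                               stderr = estimateStderr(g)))
  message(sprintf("T=%3.0f K gamma=%6.2f +/- %.2f mN/m", T,
                  estimateValue(g), estimateStderr(g)))
}
fit <- iapwsEFit(pts, Tc = Tc, seed = seed)
print(fit)
out <- sub("--out=", "", grep("--out", args, value = TRUE)[1])
if (!is.na(out))
  jsonlite::write_json(list(points = pts, par = as.list(fittedPar(fit)),
                            Te_K = fittedPar(fit)[["Te"]], Tc = Tc,
                            seed = seed),
                       out, auto_unbox = TRUE, digits = NA)
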