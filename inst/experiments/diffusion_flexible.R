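#!/usr/bin/env Rscript
## Self-diffusion of the flexible model at 298 K: 1728-molecule box,
## 0.5 fs steps, 5 ns NVT (Nose-Hoover, tau 5 ps), Einstein MSD slope.
## Expected headline value ~1.9e-5 cm^2/s; +15% quantum annotation is
## reported separately by the estimator.
suppressMessages(library(rwail))
args <- commandArgs(TRUE)
get <- function(flag, default) {
  v <- sub(paste0(flag, "="), "", grep(flag, args, value = TRUE)[1])
  if (is.na(v)) default else as.numeric(v)
}
seed <- as.integer(get("--seed", 1))
scale <- get("--scale", 1)

p <- loadParameters("flexible")
n <- max(64, round(1728 * scale))
st <- buildWaterBox(n, 997, seed = seed, params = p)
eq <- runMD(st, p, steps = round(200000 * scale), dt = 5e-4,
            integrator = "npt", thermostat = thermostatParams(298, 2),
            barostat = barostatParams(1, 5), initTemperature = 298,
            seed = seed, sampleEvery = 1000)
pr <- runMD(finalState(eq), p, steps = round(1e7 * scale), dt = 5e-4,
            integrator = "nvt", thermostat = thermostatParams(298, 5),
            seed = seed + 1, sampleEvery = 2000, snapshotEvery = 2000)
snaps <- pr@snapshots
iO <- 3 * (seq_len(n) - 1) + 1
pos <- array(0, c(length(snaps), n, 3))
for (f in seq_along(snaps)) pos[f, , ] <- sitePositions(snaps[[f]])[iO, ]
D <- diffusionEinstein(pos, dt = 1, fitWindow = c(20, 200) * max(scale, 0.05))
print(D)
out <- sub("--out=", "", grep("--out", args, value = TRUE)[1])
if (!is.na(out))
  jsonlite::write_json(list(D_1e5_cm2_s = estimateValue(D),
                            stderr = estimateStderr(D),
                            quantum15pct = D@settings$quantumCorrected15pct,
                            n = n, seed = seed),
                       out, auto_unbox = TRUE, digits = NA)
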