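#!/usr/bin/env Rscript
## Liquid-liquid critical point scan with the EG273 variant: NPT runs of a
## 343-molecule cubic box on a (T, P) grid from 190 K upward and up to
## 1000 bar; isothermal compressibility from volume fluctuations and
## density from the same runs; the locator brackets the critical point
## between the last continuous (Widom-peak) and first discontinuous
## (density-jump) isobar.  Multi-nanosecond sampling per state point.
suppressMessages(library(rwail))
args <- commandArgs(TRUE)
get <- function(flag, default) {
  v <- sub(paste0(flag, "="), "", grep(flag, args, value = TRUE)[1])
  if (is.na(v)) default else as.numeric(v)
}
seed <- as.integer(get("--seed", 1))
scale <- get("--scale", 1)

p <- loadParameters("EG273")
Ts <- seq(190, 250, 5)
Ps <- c(200, 400, 600, 800, 900, 1000)           # bar
steps <- round(5e6 * scale)                      # 10 ns per point at 2 fs
kap <- den <- NULL
for (P in Ps) {
  st <- buildWaterBox(343, 1000, seed = seed, params = p)
  for (T in Ts) {
    tr <- runMD(st, p, steps = steps, dt = 2e-3, integrator = "npt",
                thermostat = thermostatParams(T, 2),
                barostat = barostatParams(P, 5),
                initTemperature = T, seed = seed + P + T, sampleEvery = 50)
    st <- finalState(tr)                         # anneal along the isobar
    s <- trajectorySeries(tr)
    s <- s[s$time > max(s$time) * 0.3, ]
    k <- kappaT(s$volume, T, discard = 0)
    rho <- 343 * 18.015 / (6.02214076e23 * mean(s$volume) * 1e-21) * 1e3
    kap <- rbind(kap, data.frame(T = T, P = P / 10, kappa = estimateValue(k)))
    den <- rbind(den, data.frame(T = T, P = P / 10, rho = rho,
                                 stderr = sd(s$volume) / sqrt(10) /
                                   mean(s$volume) * rho))
    message(sprintf("P=%4.0f bar T=%3.0f K rho=%7.1f kappa=%.3g", P, T,
                    rho, estimateValue(k)))
  }
}
est <- locateLLCP(kap, den)
print(est)
out <- sub("--out=", "", grep("--out", args, value = TRUE)[1])
if (!is.na(out))
  jsonlite::write_json(c(est[setdiff(names(est), "classification")],
                         list(seed = seed)), out, auto_unbox = TRUE,
                       digits = NA)
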