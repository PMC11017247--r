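#!/usr/bin/env Rscript
## Liquid-vapor critical properties with EG273: a 2139-molecule slab at 8
## temperatures spanning 325-625 K; bulk phase densities from the slab
## density profiles, T_c from the Wegner expansion (3D-Ising exponents
## fixed), rho_c from the singular-diameter law (alpha' = 0.11), vapor
## pressure from the slab normal pressure fitted to Antoine's equation and
## evaluated at T_c.
suppressMessages(library(rwail))
args <- commandArgs(TRUE)
get <- function(flag, default) {
  v <- sub(paste0(flag, "="), "", grep(flag, args, value = TRUE)[1])
  if (is.na(v)) default else as.numeric(v)
}
seed <- as.integer(get("--seed", 1))
scale <- get("--scale", 1)

Ts <- seq(325, 625, length.out = 8)
p <- loadParameters("EG273")
coex <- vap <- NULL
for (T in Ts) {
  st <- buildSlab(2139, seed = seed, params = p)
  tr <- runMD(st, p, steps = round(7.5e6 * scale), dt = 2e-3,
              integrator = "nvt", thermostat = thermostatParams(T, 2),
              cutoff = slabCutoff(), initTemperature = T, seed = seed + T,
              sampleEvery = 200, snapshotEvery = round(5e4 * scale))
  ## density profile along z, averaged over snapshots
  edges <- seq(0, 10, 0.1)
  prof <- rep(0, length(edges) - 1)
  for (sn in tr@snapshots) {
    z <- sitePositions(sn)[3 * (1:2139) - 2, 3] %% 10
    prof <- prof + hist(z, breaks = edges, plot = FALSE)$counts
  }
  vol <- 3.999^2 * 0.1 * length(tr@snapshots)
  rhoZ <- prof * 18.015 / (6.02214076e23 * vol * 1e-21) * 1e3
  ph <- slabPhaseDensities(data.frame(z = edges[-1] - 0.05, rho = rhoZ))
  s <- trajectorySeries(tr)
  coex <- rbind(coex, data.frame(T = T, rhoLiquid = ph$rhoLiquid,
                                 rhoVapor = ph$rhoVapor))
  vap <- rbind(vap, data.frame(T = T, P = mean(tail(s$Pzz, 500))))
  message(sprintf("T=%3.0f rho_l=%6.1f rho_v=%6.2f Pvap=%.3g bar", T,
                  ph$rhoLiquid, ph$rhoVapor, tail(vap$P, 1)))
}
wf <- wegnerFit(coex, seed = seed)
Tc <- fittedPar(wf)[["Tc"]]
rc <- fittedPar(criticalDensityFit(coex, Tc))[["rhoc"]]
af <- antoineFit(vap[vap$P > 0, ], seed = seed)
Pc <- antoinePc(af, Tc)
message(sprintf("Tc=%.1f K  Pc=%.1f bar  rhoc=%.1f kg/m^3", Tc, Pc, rc))
out <- sub("--out=", "", grep("--out", args, value = TRUE)[1])
if (!is.na(out))
  jsonlite::write_json(list(Tc_K = Tc, Pc_bar = Pc, rhoc_kg_m3 = rc,
                            points = coex, seed = seed),
                       out, auto_unbox = TRUE, digits = NA)
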