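#!/usr/bin/env Rscript
## Melting point by NVE three-phase coexistence: an ice-Ih slab joined to
## liquid with vacuum above, evolved at 0.5 fs from bracketing initial
## temperatures (flexible: 280/260 K; EG273: 275/255 K); the end state is
## classified by the tetrahedral order parameter and the bracket bisected.
suppressMessages(library(rwail))
args <- commandArgs(TRUE)
get <- function(flag, default) {
  v <- sub(paste0(flag, "="), "", grep(flag, args, value = TRUE)[1])
  if (is.na(v)) default else as.numeric(v)
}
seed <- as.integer(get("--seed", 1))
scale <- get("--scale", 1)
variant <- if (any(grepl("--flexible", args))) "flexible" else "EG273"
p <- loadParameters(variant)
brackets <- if (variant == "flexible") c(260, 280) else c(255, 275)

## three-phase cell: ice block + liquid block stacked in z, vacuum above
ice <- buildIceIh(c(3, 2, 2), seed = seed, params = p)
liq <- buildWaterBox(nMolecules(ice), 997, seed = seed + 1, params = p)
lbox <- boxLengths(ice)
posL <- sitePositions(liq) * lbox[1] / boxLengths(liq)[1]
posL[, 3] <- posL[, 3] * 0.9 + lbox[3] + 0.1
cell <- new("SystemState", box = c(lbox[1], lbox[2], lbox[3] * 2.6),
            positions = rbind(sitePositions(ice), posL),
            velocities = matrix(0, 2 * nrow(sitePositions(ice)), 3),
            molecule = rep(seq_len(2 * nMolecules(ice)), each = 3L),
            siteNames = rep(c("OW", "HW1", "HW2"), 2 * nMolecules(ice)),
            time = 0, wrapped = TRUE,
            metadata = list(generator = "three-phase cell", seed = seed))

out <- meltingPointThreePhase(cell, p, TH = brackets[2], TL = brackets[1],
                              steps = round(4e6 * scale), dt = 5e-4,
                              maxBisect = 3, seed = seed,
                              cutoff = cutoffScheme(0.9, FALSE, FALSE))
print(out$bracket)
dest <- sub("--out=", "", grep("--out", args, value = TRUE)[1])
if (!is.na(dest))
  jsonlite::write_json(list(variant = variant, TM_K = out$TM,
                            bracket = out$bracket, flags = out$flags,
                            seed = seed), dest, auto_unbox = TRUE,
                       digits = NA)
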