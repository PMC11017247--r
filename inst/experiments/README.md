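# Cluster-scale experiment scripts

These scripts encode the full production protocols behind the model's
headline numbers (diffusion constant, ambient properties, liquid-vapor
critical point, supercooled surface tension and its emergence temperature,
liquid-liquid critical point scan, melting points).  They are *not* part
of the test suite: each needs multi-nanosecond trajectories of 343-2139
molecules and hours-to-days of wall time on a multicore node.  Every
script takes `--seed` and writes a JSON report; problem sizes and run
lengths are the protocol values and can be scaled down with the
`--scale` option for a smoke run.

Run from the repository root, e.g.

    Rscript inst/experiments/diffusion_flexible.R --seed 1 --out D.json
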