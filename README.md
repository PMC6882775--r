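# tidalRD

Breath-by-breath quantification of cyclic tidal recruitment and
derecruitment (R/D) from dynamic lung CT during assisted spontaneous
breathing over a PEEP ramp.

## Who this is for

Respiratory physiology and intensive-care imaging groups who acquire
continuous (e.g. 20 Hz) CT of a fixed transverse lung slice while a
subject breathes spontaneously with EAdi-proportional assist (NAVA), and
who need the full analysis chain from raw tracings and HU slices to the
statistical tables of a PEEP-response study — plus a simulator and
dynamic lung phantom to validate every step against known ground truth.

## What it computes

- **Aeration compartments** of masked HU slices: non-inflated
  (−100 … +100 HU), poorly (−500 … −100), normally (−900 … −500) and
  hyperinflated (−1000 … −900) volumes, tissue weights (density
  `(HU + 1000)/1000` g/ml) and gas volumes (gas fraction `−HU/1000`).
- **Per-breath mechanics**: breath detection from flow zero crossings,
  flow integration with per-breath drift correction, multiple linear
  regression of the single-compartment equation of motion
  `P(t) = P0 + Rrs·V̇ + Ers·V` on the transpulmonary channel, and the
  resistive-corrected maximal transpulmonary pressure

  `P_TP,max = (Pao − Peso)_max − Rrs · F_peak`

  together with breath-by-breath EAdi,max / EAdi,min.
- **CT–spirometry synchronization** by normalized cross-correlation of
  the CT gas-volume series against spirometric volume, and selection of
  each breath's end-inspiratory and end-expiratory frames.
- **Tidal R/D** per breath: non-aerated lung at end-expiration minus
  end-inspiration of the same cycle, in ml, g, %eeLV and %eeLW, with
  end-expiratory atelectasis, aggregated by PEEP and ramp direction.
- **The hypothesis battery**: pooled and per-subject regressions of RR
  and TV on PEEP; Wilcoxon comparisons of compartments between PEEP
  extremes; Kruskal–Wallis across PEEP with Dunn–Šidák post hoc
  (including ascending-vs-descending couples); one-tailed ("lower PEEP
  more dispersed") and two-tailed Ansari–Bradley dispersion tests with
  exact small-sample enumeration; linear/quadratic/cubic regressions of
  `P_TP,max` on PEEP.
- **A synthetic study**: a deterministic breathing simulator
  (equation-of-motion waveforms, PEEP-dependent drive, EAdi channel) and
  a dynamic CT phantom whose regions open and close via per-region
  opening/closing pressures with hysteresis, emitting ground truth for
  every downstream quantity.

See `vignettes/tidal-rd-methods.Rmd` for the models, parameter meanings
and design decisions.

## Worked example

```r
library(tidalRD)

cfg   <- sim_config(seed = 7)                       # breathing + drive model
pcfg  <- phantom_config(grid_shape = c(64L, 64L),   # reduced-size phantom
                        duration = 25, seed = 7)
study <- run_study(cfg, pcfg, settle_time = 3)
print(study)
```

```
<rd_study> 11 protocol steps, 273 breaths (236 kept), 214 R/D measures
  pooled R/D %eeLV by PEEP:
 peep rd_pct_eelv_mean rd_pct_eelv_sd  n
    0        6.7644209     1.73245437 68
    3        4.4573643     0.48981111 56
    6        2.0979451     0.20514568 42
    9        0.9377692     0.09349177 30
   12        0.3633721     0.04491097 16
   15        0.2745478     0.02283937  2
<q_report>
  Q1 RR~PEEP slope -5.800 (R2 0.999), TV~PEEP slope 0.01988 (R2 0.834)
  Q3 KW pooled: H = 185.02, p = 4.52e-38
  Q4 one-tailed AB pairs: 15 (rejections: 12)
  Q5 cubic R2 = 0.982
```

Reading the output: pooled mean tidal R/D falls monotonically from 6.8%
of end-expiratory lung volume at PEEP 0 to 0.3% at PEEP 15, and its
breath-to-breath dispersion shrinks alongside (the one-tailed
Ansari–Bradley battery rejects equal dispersion for 12 of the 15 PEEP
pairs).  The pooled respiratory-rate regression recovers the simulator's
drive slope (−5.8 breaths/min per cmH2O), tidal volume rises by
~0.02 L per cmH2O, Kruskal–Wallis confirms that R/D depends on PEEP,
and the cubic fit of `P_TP,max` on PEEP explains 98% of the variance.
`study$breaths`, `study$rd`, `study$aggregates` and `study$report` hold
the full tables; `out_dir =` writes them as CSV/JSON with a provenance
block.

A thin CLI over the same functions lives at `inst/cli/tidalrd.R`
(`simulate`, `analyze`, `full` subcommands; YAML config; `--seed`;
`--out`).  `simulate_study()` writes raw acquisitions (waveform CSVs,
16-bit multi-page TIFF frames, YAML sidecars) that `analyze_study()` —
or the CLI `analyze` mode — reproduces identically to an in-memory run.

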