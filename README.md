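# gqfret

Single-molecule FRET analysis of G-quadruplex (GQ) folding: conformer
populations, three-state folding kinetics, initial folding rates, and
conformation-selective ligand/protein binding — with a ground-truth
trajectory simulator so that every analysis stage is verifiable by
parameter recovery.

## The scientific problem

G-rich DNA obeying the motif **G₃₊ N₁–₇ G₃₊ N₁–₇ G₃₊ N₁–₇ G₃₊** folds
into G-quadruplexes whose topology — parallel (P), antiparallel (AP) or
unfolded (UF) — depends on the length and sequence of the three loops
(N). In an smFRET assay with a donor at the 3′ end of the GQ overhang
and an acceptor on the stem, the three conformations separate by FRET
efficiency

```
E = I_acceptor / (I_acceptor + I_donor)
```

with E ≈ 0.55 for parallel, ≈ 0.70–0.75 for antiparallel, and a
length-dependent 0.2–0.4 for unfolded molecules. The package implements
the full quantitative workflow used by single-molecule labs studying
this system:

- **constructs** — the panel of loop-variant DNA constructs ("133",
  "233", ..., "TTA", "TAA", telomere-like repeats, a T25 non-GQ
  control), loop-descriptor parsing, and a greedy G-run motif scanner.
- **simulate** — exact (Gillespie) sampling of the three-state
  continuous-time Markov chain with the six transition rates
  {P_AP, P_U, AP_P, AP_U, U_P, U_AP}, majority-occupancy frame binning,
  Gaussian channel noise, single-step photobleaching, buffer-flow
  folding-initiation experiments, snapshot populations, and Hill-model
  quenching curves.
- **traces** — FRET computation, photobleach detection, analysis-window
  selection, lossless TSV+JSON trace I/O.
- **populations** — FRET histograms, chi-square-weighted unrestrained
  Gaussian mixture fits, component-count selection, P/AP/UF labelling
  and area fractions.
- **kinetics** — threshold state assignment with noise despiking,
  dwell-time collection with flank censoring, the six rates via
  truncation-corrected inverse mean dwells, change-point flow-onset
  detection, and the initial folding rate `1 / mean(latency)`.
- **binding** — percent quenching `100 (1 − F/F0)`, T25 background
  subtraction, Hill fits `y = Vmax xⁿ/(xⁿ + kⁿ)` (k ≡ Kd),
  double-exponential saturation, EMSA bound fractions
  `100·shifted/(shifted+unshifted)`, and correlation of binding with
  the parallel fraction.
- **cli_and_reporting** — a seeded, fully reproducible pipeline with a
  JSON report and a command-line interface
  (`inst/cli/gqfret.R`, subcommands `simulate`, `fret`, `populations`,
  `kinetics`, `flowrate`, `binding`, `correlate`, `report`).

## Worked example

```r
library(gqfret)

cfg <- run_config(constructs = c("cMyc", "333", "TTA"), n_molecules = 3000,
                  dynamic_molecules = 100, dynamic_frames = 600,
                  flow_molecules = 100, seed = 7)
bundle <- run_pipeline(cfg)
cat(render_report(bundle), sep = "\n")
```

prints (exact output, seed 7):

```
gqfret report (schema v1, package 0.1.0, config 4d26ea749a2f7f8205db936002116e47)
construct cMyc:
  populations  P 100.0%  AP   0.0%  UF   0.0%  (n=3000)
  rates (1/s)  P_AP=0.0502  P_U=0.0548  AP_P=0.0236  AP_U=0.0344  U_P=0.0361  U_AP=0.0279
  initial fold 2.05 1/s (se 0.21; 100 folded, 0 censored)
  binding      Kd 0.1 uM, saturation 77.2%
construct 333:
  populations  P  55.2%  AP  44.8%  UF   0.0%  (n=3000)
  rates (1/s)  P_AP=0.167  P_U=0.112  AP_P=0.154  AP_U=0.125  U_P=0.517  U_AP=0.385
  initial fold 0.714 1/s (se 0.071; 100 folded, 0 censored)
  binding      Kd 9.62 uM, saturation 44.3%
construct TTA:
  populations  P  34.3%  AP  45.2%  UF  20.5%  (n=3000)
  rates (1/s)  P_AP=0.186  P_U=0.109  AP_P=0.152  AP_U=0.118  U_P=0.482  U_AP=0.35
  initial fold 0.548 1/s (se 0.055; 100 folded, 0 censored)
  binding      Kd 123 uM, saturation 23.2%
correlation (% parallel vs max quench): pearson 0.997, spearman 1.000 (n=3)
```

Reading the numbers: the simulator was parameterised with the registry
values for each construct, and the analysis pipeline recovers them —
c-Myc is a pure parallel folder (P ≈ 100%, single 0.55-FRET peak), 333
is the 56/44 parallel/antiparallel mixture, and TTA splits ≈ 35/45/20
across P/AP/UF. The 333 rates come back near their generating values
(e.g. U_P 0.52 vs 0.50 1/s), the initial folding rates reproduce the
loop-length ordering (c-Myc/short loops ≈ 2 s⁻¹, 9-nt loops
0.5–0.7 s⁻¹), and the NMM dissociation constant rises from 0.1 µM for
the highly parallel construct to >100 µM for the least parallel one,
giving the characteristic binding-vs-parallel correlation. The printed
rates for *stable* constructs (c-Myc: true exchange ≈ 0.01 s⁻¹) are
window-limited — their dwells rarely complete inside a 60 s trace — and
should be read as upper bounds, mirroring the practical difficulty of
dwell collection for static molecules.

Per-construct parameters and their provenance (`"paper"` for values the
registry takes from the printed analysis of this system, `"assumed"`
for plausible defaults) live in `gq_registry()`.

## Layout

```
R/                     implementation (constructs, registry, simulate,
                       traces, populations, kinetics, binding,
                       acceptance, pipeline)
inst/extdata/          construct table fixture (TSV)
inst/cli/gqfret.R      command-line interface
tests/testthat/        unit, property and acceptance tests (+ oracles)
scripts/acceptance.R   acceptance report generator
vignettes/             methods vignette (model, assumptions, choices)
```
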