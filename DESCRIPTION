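Package: gqfret
Title: Single-Molecule FRET Analysis of G-Quadruplex Folding and Ligand Binding
Version: 0.1.0
Authors@R:
    person("gqfret", "maintainers", email = "gqfret@example.org", role = c("aut", "cre"))
Description: Tools for quantifying G-quadruplex (GQ) folding from
    single-molecule FRET trajectories. Provides a packaged table of GQ DNA
    constructs with loop-length/sequence annotations and a G3+N(1-7) motif
    scanner; an exact (Gillespie) three-state continuous-time Markov chain
    simulator of donor/acceptor intensity trajectories with photobleaching
    and buffer-flow folding-initiation experiments; FRET-efficiency
    computation and photobleach-aware window selection; Gaussian-mixture
    quantification of parallel/antiparallel/unfolded conformer populations
    from FRET histograms; dwell-time based estimation of the six
    inter-conversion rates and of initial folding rates; Hill-equation and
    double-exponential fitting of ligand quenching curves, EMSA bound
    fractions, and conformation-binding correlation; and a reproducible
    pipeline with a command-line interface and JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
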