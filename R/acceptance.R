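#' Parameter-recovery acceptance targets
#'
#' The source study's figure-level numbers are measurements on microscope
#' data that was never deposited, so validation is by parameter recovery:
#' the simulator is parameterised with the registry values and the
#' analysis pipeline must recover them.  Each target re-runs the full
#' relevant pipeline stage from scratch.
#'
#' Targets: `t1`-`t4` recovered parallel percentage for 233 / 333 / TTA /
#' TAA snapshot populations (n = 3000); `t5` fitted mid-FRET component
#' mean for a cMyc-style population (n = 2000); `t6` fitted high-FRET
#' component mean for a 233-style mixture; `t7` initial folding rate for
#' 133 from 200 buffer-flow traces; `t8` Hill Kd recovered from a noisy
#' NMM quenching curve at the registry Kd for cMyc.
#'
#' @param seed integer master seed; all per-target seeds derive from it.
#' @return named list, one entry per target id, each a list with `value`
#'   (on the scale the field reports: percent, FRET, 1/s, uM) and `n`
#'   (problem size used).
#' @export
acceptance_targets <- function(seed = 1L) {
  sub_seed <- function(i) as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
  out <- list()

  # t1-t4: parallel percentage from Gaussian-mixture fits of snapshot
  # populations (two components for the P/AP constructs, three when an
  # unfolded population is present)
  pop_targets <- list(t1 = "233", t2 = "333", t3 = "TTA", t4 = "TAA")
  for (i in seq_along(pop_targets)) {
    cname <- pop_targets[[i]]
    params <- construct_params(cname)
    k <- sum(params$fractions > 0)
    snap <- simulate_snapshot_fret(params, 3000, seed = sub_seed(i))
    fit <- suppressWarnings(quantify_populations(snap$fret, params, k = k))
    out[[names(pop_targets)[i]]] <- list(
      value = 100 * unname(fit$fractions["P"]), n = 3000L)
  }

  # t5: fitted mean of the single component for a parallel-only construct
  p_myc <- construct_params("cMyc")
  snap <- simulate_snapshot_fret(p_myc, 2000, seed = sub_seed(5))
  fit5 <- fit_gaussian_mixture(build_histogram(snap$fret), k = 1)
  out$t5 <- list(value = fit5$components$mean[1], n = 2000L)

  # t6: fitted mean of the emergent high-FRET (antiparallel) component
  p233 <- construct_params("233")
  snap <- simulate_snapshot_fret(p233, 3000, seed = sub_seed(6))
  fit6 <- fit_gaussian_mixture(build_histogram(snap$fret), k = 2)
  out$t6 <- list(value = fit6$components$mean[2], n = 3000L)

  # t7: initial folding rate from 200 flow traces for 133 (onset frame 50)
  p133 <- construct_params("133")
  set.seed(sub_seed(7))
  flow <- lapply(seq_len(200), function(i) {
    simulate_flow_experiment(p133, pre_frames = 49, duration = 25, dt = 0.1,
                             id = sprintf("flow_%03d", i))
  })
  fr <- initial_folding_rate(flow, p133)
  out$t7 <- list(value = fr$rate, n = 200L)

  # t8: Hill Kd recovered from a noisy quenching curve at the registry Kd
  qp <- quench_curve_params(vmax = 80, k = p_myc$kd_nmm, n = 1, noise_sd = 2,
                            concentrations = 10^seq(-2, 1, length.out = 12))
  curve <- simulate_quench_curve(qp, seed = sub_seed(8))
  out$t8 <- list(value = fit_hill(curve)$k, n = 12L)

  out
}
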