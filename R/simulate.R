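#' Synthetic smFRET trajectory generation
#'
#' The generative model is a three-state continuous-time Markov chain
#' (UF, P, AP) sampled exactly with the Gillespie algorithm and binned to
#' camera frames by majority occupancy.  Per frame, the acceptor channel
#' reads `total_intensity * E` and the donor `total_intensity * (1 - E)`
#' where E is the FRET center of the occupied state (plus a per-molecule
#' center offset), with additive Gaussian channel noise whose sd is
#' `noise_scale * sqrt(channel mean) + noise_floor`.  Photobleaching is a
#' single simultaneous exponential step after which both channels drop to
#' background.
#'
#' @name simulate
NULL

# build the 3x3 generator matrix (rows = from state, order UF, P, AP)
ctmc_generator <- function(rates) {
  stopifnot(setequal(names(rates), gq_rate_labels()))
  if (any(rates < 0)) stopf("rates must be non-negative")
  st <- gq_states()
  Q <- matrix(0, 3, 3, dimnames = list(st, st))
  for (lab in gq_rate_labels()) {
    ft <- rate_label_states(lab)
    Q[ft["from"], ft["to"]] <- rates[[lab]]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of the three-state folding chain
#'
#' Solves the null space of the generator (pi Q = 0, sum pi = 1) by a
#' constrained linear solve.  The chain must be irreducible: every state
#' reachable from every other through positive-rate transitions.
#'
#' @param rates named numeric with the six rates `P_AP, P_U, AP_P, AP_U,
#'   U_P, U_AP` (1/s).
#' @return named numeric `c(P=, AP=, UF=)` summing to 1.
#' @export
#' @examples
#' ctmc_equilibrium(c(P_AP = 1, P_U = 1, AP_P = 1, AP_U = 1, U_P = 1, U_AP = 1))
ctmc_equilibrium <- function(rates) {
  Q <- ctmc_generator(rates)
  st <- gq_states()
  # the stationary distribution is unique iff exactly one closed
  # communicating class exists on the positive-rate digraph
  reach <- (Q > 0) | diag(TRUE, 3)
  for (k in 1:3) reach <- reach | (reach[, k] %o% reach[k, ])
  class_id <- integer(3)
  for (i in 1:3) class_id[i] <- min(which(reach[i, ] & reach[, i]))
  closed <- vapply(unique(class_id), function(cl) {
    members <- which(class_id == cl)
    all(reach[members, , drop = FALSE][, -members, drop = FALSE] == FALSE) ||
      length(members) == 3L
  }, logical(1))
  if (sum(closed) != 1L) {
    classes <- unique(class_id)[closed]
    bad <- st[class_id %in% classes]
    stopf("chain has no unique stationary distribution: states {%s} form %d disjoint absorbing set(s)",
          paste(bad, collapse = ", "), sum(closed))
  }
  A <- rbind(t(Q), rep(1, 3))
  b <- c(0, 0, 0, 1)
  pi_hat <- qr.solve(A, b)
  names(pi_hat) <- st
  pi_hat <- pmax(pi_hat, 0)        # clamp solver noise at exact zeros
  pi_hat <- pi_hat / sum(pi_hat)
  c(P = unname(pi_hat["P"]), AP = unname(pi_hat["AP"]),
    UF = unname(pi_hat["UF"]))
}

# exact Gillespie sampling of the state path over [0, duration]
# start_state: one of "UF","P","AP"; returns list(states, durations)
gillespie_path <- function(rates, duration, start_state) {
  Q <- ctmc_generator(rates)
  st <- gq_states()
  s <- match(start_state, st)
  if (is.na(s)) stopf("unknown start state '%s'", start_state)
  states <- integer(0); durs <- numeric(0)
  t_now <- 0
  while (t_now < duration) {
    lam <- -Q[s, s]
    if (lam <= 0) {             # absorbing state
      states <- c(states, s); durs <- c(durs, duration - t_now)
      break
    }
    dwell <- stats::rexp(1L, lam)
    if (t_now + dwell >= duration) {
      states <- c(states, s); durs <- c(durs, duration - t_now)
      break
    }
    states <- c(states, s); durs <- c(durs, dwell)
    p_next <- Q[s, ]; p_next[s] <- 0
    s <- sample.int(3L, 1L, prob = p_next)
    t_now <- t_now + dwell
  }
  list(states = st[states], durations = durs)
}

# majority-occupancy binning of a piecewise-constant path to frames;
# within-frame mixtures take the state occupying most of the frame
# (ties to the earlier state in UF < P < AP order)
bin_path_to_frames <- function(states, durations, n_frames, dt) {
  st <- gq_states()
  occ <- matrix(0, 3L, n_frames)
  t0 <- 0
  for (i in seq_along(states)) {
    t1 <- t0 + durations[i]
    f0 <- max(1L, floor(t0 / dt + 1e-12) + 1L)
    f1 <- min(n_frames, ceiling(t1 / dt - 1e-12))
    if (f0 <= f1) {
      fr <- f0:f1
      ov <- pmin(t1, fr * dt) - pmax(t0, (fr - 1) * dt)
      idx <- match(states[i], st)
      occ[idx, fr] <- occ[idx, fr] + ov
    }
    t0 <- t1
    if (t0 >= n_frames * dt) break
  }
  st[max.col(t(occ), ties.method = "first")]
}

# render per-frame donor/acceptor intensities for a FRET series
render_channels <- function(fret_true, total_intensity, noise_scale, noise_floor) {
  a_mean <- total_intensity * fret_true
  d_mean <- total_intensity * (1 - fret_true)
  a_sd <- noise_scale * sqrt(pmax(a_mean, 0)) + noise_floor
  d_sd <- noise_scale * sqrt(pmax(d_mean, 0)) + noise_floor
  n <- length(fret_true)
  acceptor <- pmax(0, a_mean + stats::rnorm(n, 0, a_sd))
  donor <- pmax(0, d_mean + stats::rnorm(n, 0, d_sd))
  list(donor = donor, acceptor = acceptor)
}

new_gq_trace <- function(id, dt, donor, acceptor, truth = NULL,
                         bleach_frame = NA_integer_,
                         flow_onset_frame = NA_integer_,
                         construct = NA_character_) {
  stopifnot(length(donor) == length(acceptor), dt > 0)
  structure(list(id = id, dt = dt, donor = donor, acceptor = acceptor,
                 truth = truth, bleach_frame = bleach_frame,
                 flow_onset_frame = flow_onset_frame, construct = construct),
            class = "gq_trace")
}

#' @export
print.gq_trace <- function(x, ...) {
  cat(sprintf("<gq_trace> %s (%s): %d frames @ %.3g s", x$id,
              x$construct %||% "?", length(x$donor), x$dt))
  if (!is.na(x$bleach_frame)) cat(sprintf(", bleach @ %d", x$bleach_frame))
  if (!is.na(x$flow_onset_frame)) cat(sprintf(", flow onset @ %d", x$flow_onset_frame))
  cat("\n")
  invisible(x)
}

#' Simulate one equilibrium smFRET trajectory
#'
#' @param params a `gq_construct_params` (see [construct_params()]).
#' @param duration trace length in seconds.
#' @param dt frame time in seconds (camera resolution 0.1-0.2 s).
#' @param seed integer seed; identical `(params, seed)` give identical
#'   traces. `NULL` uses the current RNG stream.
#' @param total_intensity summed channel intensity, arbitrary units.
#' @param bleach_rate single-step photobleach rate (1/s); 0 disables.
#' @param start_state optional fixed start state (`"UF"/"P"/"AP"`); by
#'   default the start is drawn from the chain's stationary distribution
#'   (falling back to the registry fractions for reducible chains).
#' @param noise_scale,noise_floor channel noise model parameters; the
#'   defaults give a FRET sd of about 0.05 at `total_intensity = 1000`.
#' @param center_jitter_sd sd of the per-molecule FRET center offset
#'   (static molecule-to-molecule heterogeneity); 0 disables.
#' @param id molecule identifier.
#' @return a `gq_trace` with ground truth (`truth$states`,
#'   `truth$durations`, `truth$frame_states`, `truth$center_offset`).
#' @export
simulate_trajectory <- function(params, duration, dt = 0.1, seed = NULL,
                                total_intensity = 1000, bleach_rate = 0.01,
                                start_state = NULL, noise_scale = 3,
                                noise_floor = 5, center_jitter_sd = 0,
                                id = "mol_1") {
  stopifnot(inherits(params, "gq_construct_params"))
  if (!(dt > 0) || !(duration >= dt)) stopf("need duration >= dt > 0")
  if (!is.null(seed)) set.seed(seed)

  if (is.null(start_state)) {
    eq <- tryCatch(ctmc_equilibrium(params$rates), error = function(e) NULL)
    probs <- if (is.null(eq)) params$fractions else eq
    start_state <- c("P", "AP", "UF")[sample.int(3L, 1L, prob = pmax(probs, 0))]
  }
  n_frames <- floor(duration / dt + 1e-9)
  path <- gillespie_path(params$rates, duration, start_state)
  frame_states <- bin_path_to_frames(path$states, path$durations, n_frames, dt)

  offset <- if (center_jitter_sd > 0) stats::rnorm(1L, 0, center_jitter_sd) else 0
  fret_true <- pmin(1, pmax(0, params$centers[frame_states] + offset))

  bleach_frame <- NA_integer_
  if (bleach_rate > 0) {
    tb <- stats::rexp(1L, bleach_rate)
    if (tb < duration) bleach_frame <- as.integer(floor(tb / dt) + 1L)
  }

  ch <- render_channels(fret_true, total_intensity, noise_scale, noise_floor)
  if (!is.na(bleach_frame)) {
    post <- bleach_frame:n_frames
    ch$donor[post] <- pmax(0, stats::rnorm(length(post), 0, noise_floor))
    ch$acceptor[post] <- pmax(0, stats::rnorm(length(post), 0, noise_floor))
  }
  new_gq_trace(id, dt, ch$donor, ch$acceptor,
               truth = list(states = path$states, durations = path$durations,
                            frame_states = frame_states,
                            center_offset = offset),
               bleach_frame = bleach_frame, construct = params$name)
}

#' Simulate a molecule population
#'
#' In `"snapshot"` mode each molecule's conformational state is drawn
#' once from the registry equilibrium fractions and held fixed (the
#' histogramming experiments pool molecules regardless of dynamics); in
#' `"dynamic"` mode each molecule runs the full state chain.
#'
#' @inheritParams simulate_trajectory
#' @param n_molecules number of molecules (>= 1).
#' @param frames_per_molecule trace length in frames.
#' @param mode `"snapshot"` or `"dynamic"`.
#' @param center_jitter_sd per-molecule FRET center sd; defaults to the
#'   registry `fret_sd` in snapshot mode (it sets the population peak
#'   width) and 0 in dynamic mode.
#' @param ... further arguments (e.g. `noise_scale`, `noise_floor`)
#'   passed to [simulate_trajectory()].
#' @return list of `gq_trace` objects.
#' @export
simulate_population <- function(params, n_molecules, frames_per_molecule = 30,
                                dt = 0.1, seed = NULL,
                                mode = c("snapshot", "dynamic"),
                                total_intensity = 1000, bleach_rate = 0.01,
                                center_jitter_sd = NULL, ...) {
  stopifnot(inherits(params, "gq_construct_params"), n_molecules >= 1)
  mode <- match.arg(mode)
  if (abs(sum(params$fractions) - 1) > 1e-9) stopf("fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(center_jitter_sd)) {
    center_jitter_sd <- if (mode == "snapshot") params$fret_sd else 0
  }
  duration <- frames_per_molecule * dt
  lapply(seq_len(n_molecules), function(i) {
    if (mode == "snapshot") {
      s <- c("P", "AP", "UF")[sample.int(3L, 1L, prob = pmax(params$fractions, 0))]
      frozen <- params
      frozen$rates[] <- 0    # hold the drawn state for the whole snapshot
      simulate_trajectory(frozen, duration, dt, seed = NULL,
                          total_intensity = total_intensity,
                          bleach_rate = bleach_rate, start_state = s,
                          center_jitter_sd = center_jitter_sd,
                          id = sprintf("mol_%04d", i), ...)
    } else {
      simulate_trajectory(params, duration, dt, seed = NULL,
                          total_intensity = total_intensity,
                          bleach_rate = bleach_rate,
                          center_jitter_sd = center_jitter_sd,
                          id = sprintf("mol_%04d", i), ...)
    }
  })
}

#' Draw per-molecule snapshot FRET values
#'
#' Fast path for histogram experiments: each molecule contributes one
#' FRET value, drawn as its state's center plus Gaussian scatter of sd
#' `fret_sd`.  This is the distribution the Gaussian-mixture population
#' analysis assumes.
#'
#' @inheritParams simulate_trajectory
#' @param n number of molecules.
#' @param fret_sd per-molecule FRET sd (defaults to the registry value).
#' @return data frame with columns `state` and `fret` (clipped to
#'   \[-0.2, 1.2\]).
#' @export
simulate_snapshot_fret <- function(params, n, seed = NULL,
                                   fret_sd = params$fret_sd) {
  stopifnot(inherits(params, "gq_construct_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  states <- c("P", "AP", "UF")[sample.int(3L, n, replace = TRUE,
                                          prob = pmax(params$fractions, 0))]
  fret <- params$centers[states] + stats::rnorm(n, 0, fret_sd)
  data.frame(state = states,
             fret = pmin(1.2, pmax(-0.2, unname(fret))),
             stringsAsFactors = FALSE)
}

#' Simulate a buffer-flow folding-initiation experiment
#'
#' The molecule sits unfolded in cation-free buffer for `pre_frames`
#' frames; K+ buffer arrives at the flow onset, after which the first
#' folding latency is exponential with the construct's initial folding
#' rate.  Constructs with a single-nt loop fold directly into the
#' parallel state; the 2-5 nt first-loop constructs fold first into the
#' antiparallel state.  Subsequent dynamics follow the six-rate chain.
#'
#' @inheritParams simulate_trajectory
#' @param pre_frames frames of unfolded baseline before the flow onset.
#' @param bleach_rate default 0: flow experiments are short and analysed
#'   from onset, so bleaching is disabled unless requested.
#' @return a `gq_trace` with `flow_onset_frame` set (first frame at/after
#'   the K+ arrival) and ground-truth `truth$latency` in seconds.
#' @export
simulate_flow_experiment <- function(params, pre_frames = 50, duration = 30,
                                     dt = 0.1, seed = NULL,
                                     total_intensity = 1000, bleach_rate = 0,
                                     noise_scale = 3, noise_floor = 5,
                                     id = "mol_1") {
  stopifnot(inherits(params, "gq_construct_params"))
  if (!(dt > 0) || !(duration >= dt)) stopf("need duration >= dt > 0")
  if (is.na(params$initial_folding_rate)) {
    stopf("construct '%s' has no initial_folding_rate configured", params$name)
  }
  if (!is.null(seed)) set.seed(seed)

  n_frames <- floor(duration / dt + 1e-9)
  onset_frame <- pre_frames + 1L
  t_onset <- pre_frames * dt
  if (onset_frame > n_frames) stopf("pre_frames exceeds trace length")

  latency <- stats::rexp(1L, params$initial_folding_rate)
  first_state <- params$first_folded_state
  t_fold <- t_onset + latency
  if (t_fold >= duration) {
    states <- "UF"; durs <- duration
  } else {
    post <- gillespie_path(params$rates, duration - t_fold, first_state)
    states <- c("UF", post$states)
    durs <- c(t_fold, post$durations)
  }
  frame_states <- bin_path_to_frames(states, durs, n_frames, dt)
  fret_true <- pmin(1, pmax(0, params$centers[frame_states]))

  bleach_frame <- NA_integer_
  if (bleach_rate > 0) {
    tb <- stats::rexp(1L, bleach_rate)
    if (tb < duration) bleach_frame <- as.integer(floor(tb / dt) + 1L)
  }
  ch <- render_channels(fret_true, total_intensity, noise_scale, noise_floor)
  if (!is.na(bleach_frame)) {
    post_idx <- bleach_frame:n_frames
    ch$donor[post_idx] <- pmax(0, stats::rnorm(length(post_idx), 0, noise_floor))
    ch$acceptor[post_idx] <- pmax(0, stats::rnorm(length(post_idx), 0, noise_floor))
  }
  new_gq_trace(id, dt, ch$donor, ch$acceptor,
               truth = list(states = states, durations = durs,
                            frame_states = frame_states,
                            latency = latency, first_folded_state = first_state),
               bleach_frame = bleach_frame,
               flow_onset_frame = as.integer(onset_frame),
               construct = params$name)
}

#' Quenching-curve parameters
#'
#' @param vmax maximal percent quenching, in (0, 100].
#' @param k apparent dissociation constant Kd (uM), > 0.
#' @param n Hill coefficient, > 0.
#' @param noise_sd Gaussian noise sd as percent of `vmax` (e.g. 2 = 2%).
#' @param concentrations ligand concentration grid (uM), non-negative.
#' @return a `gq_quench_params` list.
#' @export
quench_curve_params <- function(vmax = 80, k = 0.1, n = 1, noise_sd = 2,
                                concentrations = 10^seq(-2, 1, length.out = 12)) {
  if (!(vmax > 0 && vmax <= 100)) stopf("vmax must be in (0, 100]")
  if (!(k > 0)) stopf("k (Kd) must be positive")
  if (!(n > 0)) stopf("Hill coefficient must be positive")
  if (any(concentrations < 0)) stopf("concentrations must be non-negative")
  structure(list(vmax = vmax, k = k, n = n, noise_sd = noise_sd,
                 concentrations = sort(concentrations)),
            class = "gq_quench_params")
}

#' Hill dose-response curve
#'
#' `y = vmax * x^n / (x^n + k^n)`.
#'
#' @param x concentration (uM).
#' @param vmax,k,n Hill parameters.
#' @return response at `x`.
#' @export
hill_curve <- function(x, vmax, k, n) {
  vmax * x^n / (x^n + k^n)
}

#' Simulate a ligand quenching curve
#'
#' @param params a [quench_curve_params()] object.
#' @param seed integer seed.
#' @return data frame with `concentration` (uM) and `quench` (percent,
#'   clipped to \[0, 100\]).
#' @export
simulate_quench_curve <- function(params, seed = NULL) {
  stopifnot(inherits(params, "gq_quench_params"))
  if (!is.null(seed)) set.seed(seed)
  x <- params$concentrations
  y <- hill_curve(x, params$vmax, params$k, params$n)
  noise_abs <- params$noise_sd / 100 * params$vmax
  if (noise_abs > 0) y <- y + stats::rnorm(length(x), 0, noise_abs)
  data.frame(concentration = x, quench = pmin(100, pmax(0, y)))
}
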