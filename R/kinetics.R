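#' Dwell-time kinetics and initial folding rates
#'
#' State paths are assigned by fixed thresholds at the midpoints between
#' adjacent FRET centers (per-frame nearest state).  Short sojourns
#' flanked by the *same* state on both sides (noise spikes) are merged
#' away; short sojourns between *different* states are genuine transits
#' whose transitions are kept even though their durations are below the
#' resolution.  The six inter-conversion rates are estimated as inverse
#' mean dwell times (the maximum-likelihood estimator for exponential
#' dwells) computed over resolvable dwells only, with a truncation-aware
#' discretisation correction `(min_frames - 1/2) * dt` (the plain `dt/2`
#' correction is its `min_frames = 1` special case), branch-split by the
#' transition counts of all completed sojourns.  First and last sojourns
#' of each trace are censored.
#'
#' @name kinetics
NULL

#' Assign conformational states to a FRET series
#'
#' @param series a `gq_fret_series` (or plain numeric vector of FRET
#'   values, in which case `dt` must be given).
#' @param centers named numeric `c(UF=, P=, AP=)`, strictly increasing.
#' @param min_dwell noise-spike width in frames, default 2: sojourns of
#'   at most this many frames whose two flanking sojourns are the same
#'   state are merged into that state.  Short sojourns between two
#'   different states are retained (they are real transits; their
#'   durations are handled by the truncation correction downstream).
#' @param dt frame time; taken from `series` when it is a series object.
#' @return object of class `gq_state_path`: `id`, `dt`, `states`
#'   (character per frame, `"invalid"` where FRET is `NA`).
#' @export
assign_states <- function(series, centers, min_dwell = 2L, dt = NULL) {
  if (inherits(series, "gq_fret_series")) {
    fret <- series$fret
    dt <- series$dt
    id <- series$id
  } else {
    fret <- as.numeric(series)
    if (is.null(dt)) stopf("dt must be supplied for a bare FRET vector")
    id <- "mol_1"
  }
  stopifnot(all(c("UF", "P", "AP") %in% names(centers)))
  centers <- centers[c("UF", "P", "AP")]
  if (!(centers["UF"] < centers["P"] && centers["P"] < centers["AP"])) {
    stopf("FRET centers must be strictly ordered UF < P < AP")
  }
  thr_up <- (centers["UF"] + centers["P"]) / 2   # UF/P midpoint
  thr_pa <- (centers["P"] + centers["AP"]) / 2   # P/AP midpoint
  st <- ifelse(is.na(fret), "invalid",
               ifelse(fret < thr_up, "UF", ifelse(fret < thr_pa, "P", "AP")))
  st <- merge_short_sojourns(st, min_dwell)
  structure(list(id = id, dt = dt, states = st), class = "gq_state_path")
}

# iteratively merge noise spikes: real-state runs of <= min_dwell frames
# whose two real neighbours are the same state collapse into that state.
# "invalid" runs act as hard boundaries and are never merged across.
merge_short_sojourns <- function(states, min_dwell) {
  if (min_dwell < 1L) return(states)
  repeat {
    r <- rle(states)
    n <- length(r$values)
    cand <- which(r$values != "invalid" & r$lengths <= min_dwell)
    cand <- cand[vapply(cand, function(i) {
      i > 1L && i < n && r$values[i - 1L] == r$values[i + 1L] &&
        r$values[i - 1L] != "invalid"
    }, logical(1))]
    if (!length(cand)) return(inverse.rle(r))
    r$values[cand[1L]] <- r$values[cand[1L] - 1L]
    states <- inverse.rle(r)
  }
}

#' @export
print.gq_state_path <- function(x, ...) {
  tab <- table(factor(x$states, levels = c(gq_states(), "invalid")))
  cat(sprintf("<gq_state_path> %s: %d frames @ %.3g s (UF %d, P %d, AP %d, invalid %d)\n",
              x$id, length(x$states), x$dt, tab["UF"], tab["P"], tab["AP"],
              tab["invalid"]))
  invisible(x)
}

# dwell records from one run-length encoded path; durations in seconds.
# flanking sojourns (and sojourns bordering invalid stretches) are censored.
dwells_from_runs <- function(states, durations, molecule) {
  keep <- states != "invalid"
  if (!any(keep)) {
    return(data.frame(molecule = character(0), state = character(0),
                      duration = numeric(0), transition = character(0),
                      censored = logical(0), stringsAsFactors = FALSE))
  }
  # split into contiguous blocks of real states at invalid boundaries
  blocks <- split(seq_along(states), cumsum(!keep))
  recs <- list()
  for (b in blocks) {
    b <- b[states[b] != "invalid"]
    if (!length(b)) next
    m <- length(b)
    for (j in seq_len(m)) {
      i <- b[j]
      censored <- j == 1L || j == m
      transition <- NA_character_
      if (!censored) {
        nxt <- states[b[j + 1L]]
        from <- if (states[i] == "UF") "U" else states[i]
        to <- if (nxt == "UF") "U" else nxt
        transition <- paste0(from, "_", to)
      }
      recs[[length(recs) + 1L]] <- data.frame(
        molecule = molecule, state = states[i], duration = durations[i],
        transition = transition, censored = censored,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, recs)
}

#' Collect dwell records from state paths
#'
#' One record per sojourn; completed (interior) sojourns carry their exit
#' transition label, the first and last sojourn of each trace are marked
#' censored and carry none.
#'
#' @param paths a `gq_state_path` or list of them.
#' @return data frame with columns `molecule`, `state`, `duration` (s),
#'   `transition` (one of the six labels or `NA`), `censored`.
#' @export
collect_dwells <- function(paths) {
  if (inherits(paths, "gq_state_path")) paths <- list(paths)
  out <- lapply(paths, function(p) {
    r <- rle(p$states)
    dwells_from_runs(r$values, r$lengths * p$dt, p$id)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(molecule = character(0), state = character(0),
                      duration = numeric(0), transition = character(0),
                      censored = logical(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Ground-truth dwell records from simulated traces
#'
#' Extracts the continuous-time sojourns recorded by the simulator, with
#' the same flank-censoring convention as [collect_dwells()]; used for
#' validating estimators against the generative chain.
#'
#' @param traces list of simulated `gq_trace` objects with ground truth.
#' @return dwell record data frame.
#' @export
truth_dwells <- function(traces) {
  if (inherits(traces, "gq_trace")) traces <- list(traces)
  out <- lapply(traces, function(tr) {
    if (is.null(tr$truth)) stopf("trace '%s' has no ground truth", tr$id)
    dwells_from_runs(tr$truth$states, tr$truth$durations, tr$id)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Estimate the six inter-conversion rates from dwell records
#'
#' For each state the total exit rate is `1 / (mean resolvable dwell -
#' (min_frames - 1/2) * dt)`.  Only dwells of at least `min_frames`
#' frames enter the mean: shorter sojourns are below the camera
#' resolution and their exclusion truncates the exponential, which by
#' memorylessness shifts the surviving mean up by exactly the truncation
#' point `(min_frames - 1/2) * dt` (the frame count of a dwell is its
#' duration rounded to frames, so a dwell survives when its true length
#' exceeds `(min_frames - 1/2) * dt`).  With `min_frames = 1` this
#' reduces to the classic `dt/2` discretisation correction.  The exit
#' rate is split across the two exit transitions by the counts of *all*
#' completed sojourns (short transits carry real transitions).
#' Transitions with fewer than `min_dwells` completed dwells are
#' reported as missing.  Standard errors follow the delta method for
#' exponential dwells with a binomial branch split.
#'
#' @param dwells dwell record data frame from [collect_dwells()].
#' @param dt frame time in seconds (0 for continuous-time dwells: no
#'   truncation, no correction).
#' @param min_dwells minimum completed dwells per transition, default 5.
#' @param min_frames minimum resolvable dwell length in frames entering
#'   the duration mean, default 3 (one more than the default despike
#'   width of [assign_states()], so that selective spike removal cannot
#'   distort the duration sample).
#' @return object of class `gq_rate_estimates`: data frame `rates` with
#'   one row per transition label (`rate`, `se`, `n`), plus `state_summary`.
#' @export
estimate_rates <- function(dwells, dt = 0.1, min_dwells = 5L, min_frames = 3L) {
  stopifnot(is.data.frame(dwells))
  done <- dwells[!dwells$censored & !is.na(dwells$transition), , drop = FALSE]
  labels <- gq_rate_labels()
  rates <- data.frame(transition = labels, rate = NA_real_, se = NA_real_,
                      n = 0L, stringsAsFactors = FALSE)
  state_summary <- data.frame(state = gq_states(), n_dwells = 0L,
                              n_resolvable = 0L, mean_dwell = NA_real_,
                              exit_rate = NA_real_, stringsAsFactors = FALSE)
  trunc_at <- if (dt > 0) (min_frames - 0.5) * dt else 0
  for (s in gq_states()) {
    ds <- done[done$state == s, , drop = FALSE]
    n_s <- nrow(ds)
    row <- state_summary$state == s
    state_summary$n_dwells[row] <- n_s
    if (n_s == 0L) next
    surv <- ds$duration[ds$duration > trunc_at]
    n_surv <- length(surv)
    state_summary$n_resolvable[row] <- n_surv
    if (n_surv == 0L) next
    mean_dwell <- mean(surv)
    corrected <- max(mean_dwell - trunc_at, dt / 2, .Machine$double.eps)
    exit_rate <- 1 / corrected
    state_summary$mean_dwell[row] <- mean_dwell
    state_summary$exit_rate[row] <- exit_rate
    s_lab <- if (s == "UF") "U" else s
    for (lab in labels[startsWith(labels, paste0(s_lab, "_"))]) {
      n_t <- sum(ds$transition == lab)
      i <- which(rates$transition == lab)
      rates$n[i] <- n_t
      if (n_t >= min_dwells) {
        p <- n_t / n_s
        rates$rate[i] <- exit_rate * p
        rates$se[i] <- rates$rate[i] * sqrt(1 / n_surv + (1 - p) / (n_s * p))
      }
    }
  }
  structure(list(rates = rates, state_summary = state_summary, dt = dt),
            class = "gq_rate_estimates")
}

#' @export
print.gq_rate_estimates <- function(x, ...) {
  cat("<gq_rate_estimates> (1/s)\n")
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Detect the buffer-flow onset frame of a trace
#'
#' Simulated flow traces carry the onset in their manifest
#' (`flow_onset_frame`), which is returned directly.  Otherwise a
#' two-segment change-point on the FRET series is used: the split
#' minimising the summed within-segment squared deviations, accepted only
#' if it reduces the single-segment RSS by at least `min_reduction`.
#'
#' @param trace a `gq_trace`.
#' @param min_reduction fractional RSS reduction required, default 0.3.
#' @return integer frame index of the first post-onset frame.
#' @export
detect_flow_onset <- function(trace, min_reduction = 0.3) {
  stopifnot(inherits(trace, "gq_trace"))
  if (!is.na(trace$flow_onset_frame)) return(as.integer(trace$flow_onset_frame))
  fs <- compute_fret(trace$donor, trace$acceptor, dt = trace$dt, id = trace$id)
  y <- fs$fret[fs$valid]
  n <- length(y)
  if (n < 10L) stopf("trace '%s': too few valid frames for onset detection", trace$id)
  rss1 <- sum((y - mean(y))^2)
  # cumulative sums give O(n) two-segment RSS
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  t_cand <- 3L:(n - 3L)
  rss_left <- cs2[t_cand] - cs[t_cand]^2 / t_cand
  nr <- n - t_cand
  rss_right <- (cs2[n] - cs2[t_cand]) - (cs[n] - cs[t_cand])^2 / nr
  rss2 <- rss_left + rss_right
  best <- which.min(rss2)
  if (rss1 <= 0 || (rss1 - rss2[best]) / rss1 < min_reduction) {
    stopf("trace '%s': no flow onset found (no change point)", trace$id)
  }
  # map back through the valid-frame index to the original frame grid
  as.integer(which(fs$valid)[t_cand[best] + 1L])
}

#' Initial folding rate from buffer-flow experiments
#'
#' Per molecule, the folding latency is the time between the flow onset
#' and the first sustained FRET rise above the UF/P midpoint (at least
#' `sustained` consecutive frames, guarding against noise spikes).  The
#' rate is the inverse mean latency; molecules that never fold are
#' reported as censored, not dropped silently.  The first folded state
#' (P vs AP, by the nearest center over the event frames) is tallied.
#'
#' @param traces list of flow-experiment `gq_trace` objects.
#' @param params construct registry parameters (for centers).
#' @param sustained consecutive supra-threshold frames required, default 3.
#' @param min_molecules minimum detected molecules, default 20 (a warning
#'   is emitted below this).
#' @return object of class `gq_folding_rate`: `rate` (1/s), `se`,
#'   `n_folded`, `n_censored`, `first_state_tally` (named counts),
#'   `latencies` (s).
#' @export
initial_folding_rate <- function(traces, params, sustained = 3L,
                                 min_molecules = 20L) {
  stopifnot(is.list(traces), inherits(params, "gq_construct_params"))
  centers <- params$centers
  thr <- (centers["UF"] + centers["P"]) / 2
  latencies <- numeric(0)
  first_states <- character(0)
  n_censored <- 0L
  for (tr in traces) {
    onset <- detect_flow_onset(tr)
    fs <- compute_fret(tr$donor, tr$acceptor, dt = tr$dt, id = tr$id)
    fret <- fs$fret
    n <- length(fret)
    above <- !is.na(fret) & fret > thr
    # first frame >= onset starting a run of `sustained` above-threshold frames
    ev <- NA_integer_
    run <- 0L
    for (f in seq(onset, n)) {
      run <- if (above[f]) run + 1L else 0L
      if (run == sustained) { ev <- f - sustained + 1L; break }
    }
    if (is.na(ev)) {
      n_censored <- n_censored + 1L
      next
    }
    latencies <- c(latencies, (ev - onset) * tr$dt)
    med <- stats::median(fret[ev:min(n, ev + sustained - 1L)], na.rm = TRUE)
    first_states <- c(first_states,
                      if (abs(med - centers["P"]) <= abs(med - centers["AP"]))
                        "P" else "AP")
  }
  n_folded <- length(latencies)
  if (n_folded == 0L) {
    warnf("no folding events detected; rate is missing")
    rate <- NA_real_; se <- NA_real_
  } else {
    if (n_folded < min_molecules) {
      warnf("only %d molecules with folding events (< %d)", n_folded,
            min_molecules)
    }
    rate <- 1 / mean(latencies)
    se <- rate / sqrt(n_folded)
  }
  structure(list(rate = rate, se = se, n_folded = n_folded,
                 n_censored = n_censored,
                 first_state_tally = table(factor(first_states,
                                                  levels = c("P", "AP"))),
                 latencies = latencies),
            class = "gq_folding_rate")
}

#' @export
print.gq_folding_rate <- function(x, ...) {
  cat(sprintf("<gq_folding_rate> %.3g 1/s (se %.2g), %d folded / %d censored; first state P:%d AP:%d\n",
              x$rate, x$se, x$n_folded, x$n_censored,
              x$first_state_tally["P"], x$first_state_tally["AP"]))
  invisible(x)
}
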