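#' FRET efficiency and trace preprocessing
#'
#' FRET efficiency is computed as E = A / (A + D), the acceptor intensity
#' divided by the summed donor and acceptor intensities.  Frames whose
#' total intensity falls below a floor (default 10% of the molecule's
#' median total) are marked invalid rather than divided; the usable
#' analysis window ends at the photobleach step.
#'
#' @name traces
NULL

#' Compute the FRET efficiency series of one molecule
#'
#' @param donor,acceptor intensity series (equal length, >= 1 frame).
#' @param floor_fraction frames with `donor + acceptor` below this
#'   fraction of the median total are marked invalid (`NA` FRET).
#' @param dt frame time, carried through for downstream dwell analysis.
#' @param id molecule identifier.
#' @return object of class `gq_fret_series`: list with `id`, `dt`,
#'   `fret` (numeric, `NA` where invalid), `valid` (logical),
#'   `window` (`c(start, end)` frame indices) and `excluded` flag.
#' @export
#' @examples
#' compute_fret(donor = c(500, 450), acceptor = c(500, 550))$fret
compute_fret <- function(donor, acceptor, floor_fraction = 0.1,
                         dt = 0.1, id = "mol_1") {
  if (length(donor) != length(acceptor)) {
    stopf("donor and acceptor series have different lengths (%d vs %d)",
          length(donor), length(acceptor))
  }
  if (length(donor) == 0L) stopf("empty intensity series")
  total <- donor + acceptor
  floor_level <- floor_fraction * stats::median(total)
  valid <- total >= floor_level & total > 0
  fret <- rep(NA_real_, length(total))
  fret[valid] <- acceptor[valid] / total[valid]
  structure(list(id = id, dt = dt, fret = fret, valid = valid,
                 window = c(start = 1L, end = length(fret)),
                 excluded = FALSE),
            class = "gq_fret_series")
}

#' @export
print.gq_fret_series <- function(x, ...) {
  cat(sprintf("<gq_fret_series> %s: %d frames @ %.3g s, window %d..%d%s\n",
              x$id, length(x$fret), x$dt, x$window["start"], x$window["end"],
              if (x$excluded) " [excluded]" else ""))
  invisible(x)
}

#' Detect the photobleach frame of a trace
#'
#' Returns the first frame where the total intensity drops below
#' `threshold_fraction` times the molecule's reference level and stays
#' below for at least `min_below` consecutive frames.  The reference
#' level is the median of the brightest frames (top `ref_frames`), which
#' is robust to traces that spend most of their length bleached.
#'
#' @param trace a `gq_trace`.
#' @param threshold_fraction fraction of the reference total, default 0.5.
#' @param min_below consecutive sub-threshold frames required, default 5.
#' @return integer frame index, or `NA_integer_` if no bleach step found.
#' @details The reference level is the median of the frames above the
#'   total-intensity midrange, which stays anchored to the bright
#'   (pre-bleach) cluster even when a molecule bleaches very early.
#' @export
detect_bleach <- function(trace, threshold_fraction = 0.5, min_below = 5L) {
  stopifnot(inherits(trace, "gq_trace"))
  total <- trace$donor + trace$acceptor
  n <- length(total)
  if (n == 0L) return(NA_integer_)
  mid <- (max(total) + min(total)) / 2
  bright <- total[total >= mid]
  ref <- stats::median(bright)
  below <- total < threshold_fraction * ref
  if (!any(below)) return(NA_integer_)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & (r$lengths >= min_below)
  if (!any(ok)) return(NA_integer_)
  as.integer(starts[which(ok)[1]])
}

#' Select the usable analysis window of a trace
#'
#' Computes FRET on pre-bleach frames only and flags molecules with fewer
#' than `min_frames` usable (valid, pre-bleach) frames as excluded.
#'
#' @param trace a `gq_trace`.
#' @param min_frames minimum usable frames, default 20.
#' @param floor_fraction passed to [compute_fret()].
#' @param threshold_fraction passed to [detect_bleach()].
#' @return a `gq_fret_series` whose `window` ends before the bleach and
#'   whose `fret` is `NA` outside the window.
#' @export
select_window <- function(trace, min_frames = 20L, floor_fraction = 0.1,
                          threshold_fraction = 0.5) {
  stopifnot(inherits(trace, "gq_trace"))
  n <- length(trace$donor)
  bleach <- detect_bleach(trace, threshold_fraction = threshold_fraction)
  end <- if (is.na(bleach)) n else max(0L, bleach - 1L)
  fs <- compute_fret(trace$donor, trace$acceptor,
                     floor_fraction = floor_fraction, dt = trace$dt,
                     id = trace$id)
  if (end < n) {
    fs$fret[(end + 1L):n] <- NA_real_
    fs$valid[(end + 1L):n] <- FALSE
  }
  fs$window <- c(start = 1L, end = as.integer(end))
  usable <- sum(fs$valid)
  fs$excluded <- usable < min_frames
  fs
}

#' Per-molecule FRET value for histogramming
#'
#' The snapshot convention: the mean FRET over the first `n_frames`
#' usable frames of the molecule's analysis window.
#'
#' @param trace a `gq_trace`.
#' @param n_frames number of leading valid frames to average, default 10.
#' @param ... passed to [select_window()].
#' @return a single FRET value, or `NA` for excluded molecules.
#' @export
molecule_fret <- function(trace, n_frames = 10L, ...) {
  fs <- select_window(trace, ...)
  if (fs$excluded) return(NA_real_)
  vals <- fs$fret[fs$valid]
  mean(utils::head(vals, n_frames))
}

#' Per-molecule FRET values for a population of traces
#'
#' @param traces list of `gq_trace`.
#' @inheritParams molecule_fret
#' @return numeric vector (NA for excluded molecules).
#' @export
population_fret <- function(traces, n_frames = 10L, ...) {
  vapply(traces, molecule_fret, numeric(1), n_frames = n_frames, ...)
}

# run-length encode a ground-truth path for the JSON manifest
encode_truth <- function(truth) {
  if (is.null(truth)) return(NULL)
  out <- list(states = truth$states, durations = truth$durations)
  extra <- setdiff(names(truth), c("states", "durations", "frame_states"))
  out <- c(out, truth[extra])
  out
}

#' Write traces to a directory (TSV + JSON manifest dialect)
#'
#' Each molecule becomes one TSV (`frame`, `time_s`, `donor`, `acceptor`,
#' full double precision) and the manifest records `dt`, seeds, construct,
#' per-molecule bleach/flow-onset frames and the run-length encoded
#' ground-truth path, making the round trip lossless.
#'
#' @param traces list of `gq_trace`.
#' @param path output directory (created if needed).
#' @param seed optional seed to record in the manifest.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, seed = NULL) {
  stopifnot(is.list(traces), length(traces) >= 1)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    stopifnot(inherits(tr, "gq_trace"))
    file_i <- sprintf("trace_%05d.tsv", i)
    n <- length(tr$donor)
    lines <- c("frame\ttime_s\tdonor\tacceptor",
               sprintf("%d\t%s\t%s\t%s", seq_len(n),
                       formatC((seq_len(n) - 1L) * tr$dt, format = "g", digits = 17),
                       formatC(tr$donor, format = "g", digits = 17),
                       formatC(tr$acceptor, format = "g", digits = 17)))
    writeLines(lines, file.path(path, file_i))
    entries[[i]] <- list(id = tr$id, file = file_i,
                         construct = tr$construct,
                         bleach_frame = tr$bleach_frame,
                         flow_onset_frame = tr$flow_onset_frame,
                         truth = encode_truth(tr$truth))
  }
  manifest <- list(format = "gqfret-traces", version = 1L,
                   dt = traces[[1]]$dt, n_molecules = length(traces),
                   seed = seed, molecules = entries)
  # digits = I(17): 17 significant digits, the minimum that round-trips
  # IEEE doubles exactly through decimal text
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read traces written by [write_traces()]
#'
#' @param path directory containing `manifest.json` and per-molecule TSVs.
#' @return list of `gq_trace`.
#' @export
read_traces <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stopf("no manifest.json under '%s'", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  for (key in c("format", "dt", "molecules")) {
    if (is.null(mf[[key]])) stopf("manifest '%s' missing field '%s'", mf_path, key)
  }
  if (!identical(mf$format, "gqfret-traces")) {
    stopf("manifest '%s' has unknown format '%s'", mf_path, mf$format)
  }
  dt <- as.numeric(mf$dt)
  lapply(mf$molecules, function(m) {
    f <- file.path(path, m$file)
    if (!file.exists(f)) stopf("trace file missing: '%s'", f)
    tab <- utils::read.delim(f, colClasses = "numeric")
    need <- c("frame", "time_s", "donor", "acceptor")
    if (!all(need %in% names(tab))) {
      stopf("trace file '%s' missing columns: %s", f,
            paste(setdiff(need, names(tab)), collapse = ", "))
    }
    truth <- m$truth
    if (!is.null(truth)) {
      truth$states <- unlist(truth$states)
      truth$durations <- as.numeric(unlist(truth$durations))
      if (!is.null(truth$center_offset)) {
        truth$center_offset <- as.numeric(truth$center_offset)
      }
      if (!is.null(truth$latency)) truth$latency <- as.numeric(truth$latency)
      truth$frame_states <- bin_path_to_frames(truth$states, truth$durations,
                                               nrow(tab), dt)
    }
    new_gq_trace(m$id %||% basename(f), dt, tab$donor, tab$acceptor,
                 truth = truth,
                 bleach_frame = as.integer(m$bleach_frame %||% NA_integer_),
                 flow_onset_frame = as.integer(m$flow_onset_frame %||% NA_integer_),
                 construct = m$construct %||% NA_character_)
  })
}
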