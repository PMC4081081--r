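# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that internal randomised routines
#' (e.g. multi-start restarts) do not perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# state bookkeeping: internal order UF, P, AP everywhere
gq_states <- function() c("UF", "P", "AP")

# the six transition labels; "U" is the unfolded state in rate notation
gq_rate_labels <- function() c("P_AP", "P_U", "AP_P", "AP_U", "U_P", "U_AP")

# map a rate label to (from, to) in UF/P/AP state names
rate_label_states <- function(label) {
  parts <- strsplit(label, "_", fixed = TRUE)[[1]]
  map <- c(U = "UF", P = "P", AP = "AP")
  c(from = unname(map[parts[1]]), to = unname(map[parts[2]]))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
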