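#' Per-construct generative and kinetic parameter registry
#'
#' Each construct carries the FRET centers of its three conformational
#' states (UF = unfolded, P = parallel, AP = antiparallel), the width of
#' the per-molecule FRET distribution, its equilibrium conformer
#' fractions, the six inter-conversion rates, the initial folding rate
#' measured in buffer-flow experiments, the state it folds into first
#' after K+ is introduced, and ligand-binding parameters for quenching
#' simulations.  Every scalar is provenance-tagged `"paper"` (printed in
#' the source study) or `"assumed"` (chosen here as a realistic default);
#' tests only treat `"paper"`-tagged values as external facts.
#'
#' @name registry
NULL

#' Construct a ConstructParams object
#'
#' @param name construct label.
#' @param centers named numeric `c(UF=, P=, AP=)` FRET centers, strictly
#'   increasing UF < P < AP, each in \[0, 1\].
#' @param fractions named numeric `c(P=, AP=, UF=)` equilibrium conformer
#'   fractions summing to 1.
#' @param rates named numeric with the six transition rates (1/s), names
#'   `P_AP, P_U, AP_P, AP_U, U_P, U_AP`; all >= 0.
#' @param initial_folding_rate 1/s; latency scale of the first folding
#'   event after buffer flow.
#' @param first_folded_state `"P"` or `"AP"`.
#' @param fret_sd per-molecule FRET standard deviation (population peak
#'   width), default 0.05.
#' @param kd_nmm apparent dissociation constant (uM) for NMM quenching.
#' @param quench_vmax maximal percent quenching for NMM.
#' @param provenance named character tagging fields `"paper"`/`"assumed"`.
#' @return object of class `gq_construct_params`.
#' @export
construct_params_new <- function(name, centers, fractions, rates,
                                 initial_folding_rate = NA_real_,
                                 first_folded_state = NA_character_,
                                 fret_sd = 0.05,
                                 kd_nmm = NA_real_, quench_vmax = NA_real_,
                                 provenance = character()) {
  stopifnot(all(c("UF", "P", "AP") %in% names(centers)))
  centers <- centers[c("UF", "P", "AP")]
  if (!(centers["UF"] < centers["P"] && centers["P"] < centers["AP"])) {
    stopf("FRET centers must be ordered UF < P < AP for '%s'", name)
  }
  if (any(centers < 0 | centers > 1)) stopf("FRET centers must lie in [0,1]")
  stopifnot(all(c("P", "AP", "UF") %in% names(fractions)))
  fractions <- fractions[c("P", "AP", "UF")]
  if (abs(sum(fractions) - 1) > 1e-9) {
    stopf("fractions must sum to 1 for '%s' (got %.12f)", name, sum(fractions))
  }
  if (any(fractions < 0)) stopf("fractions must be non-negative")
  stopifnot(setequal(names(rates), gq_rate_labels()))
  rates <- rates[gq_rate_labels()]
  if (any(rates < 0)) stopf("rates must be non-negative for '%s'", name)
  structure(list(name = name, centers = centers, fractions = fractions,
                 rates = rates, initial_folding_rate = initial_folding_rate,
                 first_folded_state = first_folded_state, fret_sd = fret_sd,
                 kd_nmm = kd_nmm, quench_vmax = quench_vmax,
                 provenance = provenance),
            class = "gq_construct_params")
}

#' @export
print.gq_construct_params <- function(x, ...) {
  cat(sprintf("<gq_construct_params> %s\n", x$name))
  cat(sprintf("  centers   UF=%.2f P=%.2f AP=%.2f (fret sd %.3f)\n",
              x$centers["UF"], x$centers["P"], x$centers["AP"], x$fret_sd))
  cat(sprintf("  fractions P=%.2f AP=%.2f UF=%.2f\n",
              x$fractions["P"], x$fractions["AP"], x$fractions["UF"]))
  cat("  rates     ", paste(sprintf("%s=%.3g", names(x$rates), x$rates),
                            collapse = " "), "\n")
  cat(sprintf("  initial folding %.3g 1/s -> %s\n",
              x$initial_folding_rate, x$first_folded_state))
  invisible(x)
}

# shorthand for a symmetric rare-exchange rate set (stable constructs:
# mid/high-FRET interconversion is too infrequent for dwell collection)
.slow_rates <- function(r = 0.01) {
  stats::setNames(rep(r, 6L), gq_rate_labels())
}

.rates <- function(P_AP, P_U, AP_P, AP_U, U_P, U_AP) {
  c(P_AP = P_AP, P_U = P_U, AP_P = AP_P, AP_U = AP_U, U_P = U_P, U_AP = U_AP)
}

#' The packaged parameter registry
#'
#' @return named list of [construct_params_new()] objects keyed by
#'   construct name; `"TTT"` is an alias of `"333"`.
#' @export
#' @examples
#' gq_registry()[["233"]]
gq_registry <- function() {
  reg <- list(
    cMyc = construct_params_new(
      "cMyc",
      centers = c(UF = 0.35, P = 0.55, AP = 0.75),
      fractions = c(P = 1, AP = 0, UF = 0),
      rates = .slow_rates(),
      initial_folding_rate = 2, first_folded_state = "P",
      kd_nmm = 0.1, quench_vmax = 80,
      provenance = c(center_P = "paper", center_AP = "paper",
                     center_UF = "assumed", fractions = "paper",
                     rates = "assumed", initial_folding_rate = "assumed",
                     first_folded_state = "assumed",
                     kd_nmm = "paper", quench_vmax = "assumed")),
    `133` = construct_params_new(
      "133",
      centers = c(UF = 0.30, P = 0.55, AP = 0.75),
      fractions = c(P = 1, AP = 0, UF = 0),
      rates = .slow_rates(),
      initial_folding_rate = 2, first_folded_state = "P",
      kd_nmm = 0.1, quench_vmax = 75,
      provenance = c(center_P = "paper", center_AP = "paper",
                     center_UF = "assumed", fractions = "paper",
                     rates = "assumed", initial_folding_rate = "paper",
                     first_folded_state = "paper",
                     kd_nmm = "assumed", quench_vmax = "assumed")),
    `144` = construct_params_new(
      "144",
      centers = c(UF = 0.28, P = 0.55, AP = 0.75),
      fractions = c(P = 1, AP = 0, UF = 0),
      rates = .slow_rates(),
      initial_folding_rate = 0.8, first_folded_state = "P",
      kd_nmm = 0.3, quench_vmax = 70,
      provenance = c(center_P = "paper", fractions = "paper",
                     initial_folding_rate = "paper",
                     first_folded_state = "paper", rates = "assumed",
                     center_UF = "assumed", center_AP = "paper",
                     kd_nmm = "assumed", quench_vmax = "assumed")),
    `155` = construct_params_new(
      "155",
      centers = c(UF = 0.25, P = 0.55, AP = 0.75),
      fractions = c(P = 0.95, AP = 0, UF = 0.05),
      rates = .slow_rates(),
      initial_folding_rate = 0.3, first_folded_state = "P",
      kd_nmm = 0.5, quench_vmax = 65,
      provenance = c(center_P = "paper", center_AP = "paper",
                     center_UF = "assumed", fractions = "assumed",
                     rates = "assumed", initial_folding_rate = "assumed",
                     first_folded_state = "paper",
                     kd_nmm = "assumed", quench_vmax = "assumed")),
    `177` = construct_params_new(
      "177",
      centers = c(UF = 0.20, P = 0.55, AP = 0.75),
      fractions = c(P = 0.85, AP = 0, UF = 0.15),
      rates = .slow_rates(),
      initial_folding_rate = 0.08, first_folded_state = "P",
      kd_nmm = 1, quench_vmax = 60,
      provenance = c(center_P = "paper", center_AP = "paper",
                     center_UF = "paper", fractions = "assumed",
                     rates = "assumed", initial_folding_rate = "paper",
                     first_folded_state = "paper",
                     kd_nmm = "assumed", quench_vmax = "assumed")),
    `199` = construct_params_new(
      "199",
      centers = c(UF = 0.20, P = 0.55, AP = 0.75),
      fractions = c(P = 0.75, AP = 0, UF = 0.25),
      rates = .slow_rates(),
      initial_folding_rate = 0.05, first_folded_state = "P",
      kd_nmm = 2, quench_vmax = 55,
      provenance = c(center_P = "paper", center_AP = "paper",
                     center_UF = "paper", fractions = "assumed",
                     rates = "assumed", initial_folding_rate = "paper",
                     first_folded_state = "paper",
                     kd_nmm = "assumed", quench_vmax = "assumed")),
    `233` = construct_params_new(
      "233",
      centers = c(UF = 0.30, P = 0.55, AP = 0.75),
      fractions = c(P = 0.91, AP = 0.09, UF = 0),
      rates = .slow_rates(),
      initial_folding_rate = 2, first_folded_state = "AP",
      kd_nmm = 0.15, quench_vmax = 70,
      provenance = c(center_P = "paper", center_AP = "paper",
                     center_UF = "assumed", fractions = "paper",
                     rates = "assumed", initial_folding_rate = "paper",
                     first_folded_state = "paper",
                     kd_nmm = "assumed", quench_vmax = "assumed")),
    `333` = construct_params_new(
      "333",
      centers = c(UF = 0.30, P = 0.55, AP = 0.75),
      fractions = c(P = 0.56, AP = 0.44, UF = 0),
      rates = .rates(P_AP = 0.15, P_U = 0.12, AP_P = 0.15, AP_U = 0.12,
                     U_P = 0.50, U_AP = 0.40),
      initial_folding_rate = 0.7, first_folded_state = "AP",
      kd_nmm = 10, quench_vmax = 45,
      provenance = c(center_P = "paper", center_AP = "paper",
                     center_UF = "assumed", fractions = "paper",
                     rates = "assumed", initial_folding_rate = "paper",
                     first_folded_state = "paper",
                     kd_nmm = "assumed", quench_vmax = "assumed")),
    `433` = construct_params_new(
      "433",
      centers = c(UF = 0.30, P = 0.55, AP = 0.75),
      fractions = c(P = 0.45, AP = 0.35, UF = 0.20),
      rates = .rates(P_AP = 0.12, P_U = 0.15, AP_P = 0.10, AP_U = 0.12,
                     U_P = 0.15, U_AP = 0.13),
      initial_folding_rate = 0.5, first_folded_state = "AP",
      kd_nmm = 50, quench_vmax = 35,
      provenance = c(center_P = "paper", center_AP = "paper",
                     center_UF = "paper", fractions = "assumed",
                     rates = "assumed", initial_folding_rate = "paper",
                     first_folded_state = "paper",
                     kd_nmm = "assumed", quench_vmax = "assumed")),
    `533` = construct_params_new(
      "533",
      centers = c(UF = 0.30, P = 0.55, AP = 0.75),
      fractions = c(P = 0.35, AP = 0.35, UF = 0.30),
      rates = .rates(P_AP = 0.12, P_U = 0.15, AP_P = 0.10, AP_U = 0.15,
                     U_P = 0.12, U_AP = 0.12),
      initial_folding_rate = 0.3, first_folded_state = "AP",
      kd_nmm = 100, quench_vmax = 30,
      provenance = c(center_P = "paper", center_AP = "paper",
                     center_UF = "paper", fractions = "assumed",
                     rates = "assumed", initial_folding_rate = "assumed",
                     first_folded_state = "paper",
                     kd_nmm = "assumed", quench_vmax = "assumed")),
    TTA = construct_params_new(
      "TTA",
      centers = c(UF = 0.30, P = 0.55, AP = 0.70),
      fractions = c(P = 0.35, AP = 0.45, UF = 0.20),
      rates = .rates(P_AP = 0.15, P_U = 0.12, AP_P = 0.12, AP_U = 0.12,
                     U_P = 0.45, U_AP = 0.40),
      initial_folding_rate = 0.6, first_folded_state = "AP",
      kd_nmm = 100, quench_vmax = 25,
      provenance = c(center_P = "paper", center_AP = "paper",
                     center_UF = "assumed", fraction_P = "paper",
                     fraction_AP = "assumed", fraction_UF = "assumed",
                     rates = "assumed", initial_folding_rate = "assumed",
                     first_folded_state = "paper",
                     kd_nmm = "assumed", quench_vmax = "assumed")),
    TAA = construct_params_new(
      "TAA",
      centers = c(UF = 0.30, P = 0.55, AP = 0.75),
      fractions = c(P = 0.16, AP = 0.50, UF = 0.34),
      rates = .rates(P_AP = 0.15, P_U = 0.15, AP_P = 0.10, AP_U = 0.12,
                     U_P = 0.09, U_AP = 0.15),
      initial_folding_rate = 0.55, first_folded_state = "AP",
      kd_nmm = 300, quench_vmax = 15,
      provenance = c(center_P = "paper", center_AP = "paper",
                     center_UF = "assumed", fraction_P = "paper",
                     fraction_AP = "assumed", fraction_UF = "assumed",
                     rates = "assumed", initial_folding_rate = "assumed",
                     first_folded_state = "paper",
                     kd_nmm = "assumed", quench_vmax = "assumed")),
    AAA = construct_params_new(
      "AAA",
      centers = c(UF = 0.40, P = 0.55, AP = 0.75),
      fractions = c(P = 0.10, AP = 0.10, UF = 0.80),
      rates = .rates(P_AP = 0.12, P_U = 0.20, AP_P = 0.10, AP_U = 0.20,
                     U_P = 0.04, U_AP = 0.04),
      initial_folding_rate = 0.3, first_folded_state = "AP",
      kd_nmm = 500, quench_vmax = 10,
      provenance = c(center_UF = "paper", center_P = "paper",
                     center_AP = "paper", fractions = "assumed",
                     rates = "assumed", initial_folding_rate = "assumed",
                     first_folded_state = "assumed",
                     kd_nmm = "assumed", quench_vmax = "assumed")),
    T25 = construct_params_new(
      "T25",
      centers = c(UF = 0.25, P = 0.55, AP = 0.75),
      fractions = c(P = 0, AP = 0, UF = 1),
      rates = stats::setNames(rep(0, 6L), gq_rate_labels()),
      initial_folding_rate = NA_real_, first_folded_state = NA_character_,
      kd_nmm = NA_real_, quench_vmax = 5,
      provenance = c(centers = "assumed", fractions = "paper",
                     rates = "assumed", quench_vmax = "assumed"))
  )
  reg
}

#' Look up registry parameters for a construct
#'
#' @param name construct label; `"TTT"` resolves to `"333"`.
#' @param registry optionally a pre-built registry list.
#' @return a `gq_construct_params` object.
#' @export
construct_params <- function(name, registry = gq_registry()) {
  if (identical(name, "TTT")) name <- "333"
  p <- registry[[name]]
  if (is.null(p)) stopf("no registry parameters for construct '%s'", name)
  p
}
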