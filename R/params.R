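#' Rate-law parameters for the compartmentalised PEN DNA model
#'
#' Bundles the lumped rate constants of the minimal PEN (polymerase,
#' exonuclease, nickase) reaction model used by [simulate_bulk_reaction()]
#' and [simulate_compartment_network()]. Production follows a saturating
#' template-occupancy law with product inhibition,
#' `v_prod = k_pol * P * T * s/(K_m + s) * 1/(1 + s/K_i)`,
#' and exonuclease degradation is Michaelis-type,
#' `v_deg = k_exo * E * s/(K_exo + s)`,
#' with all strand concentrations in nM and time in minutes.
#'
#' The defaults are a reference set chosen to reproduce the qualitative
#' behaviour of proteinosome-hosted autocatalysis: sigmoidal growth at the
#' reference exonuclease level with 0.12 uM internal template, switch-off of
#' compartmentalised reactions at high (9.6 nM) exonuclease, and unimpeded
#' growth in bulk at micromolar template. They are not fitted to any
#' experimental trace.
#'
#' @param k_pol Production rate constant (min^-1 per nM template at full
#'   occupancy, at reference polymerase activity `P = 1`).
#' @param K_m Primer half-saturation constant for template binding (nM).
#' @param K_i Product-inhibition constant (nM); primer occupying both
#'   template ends suppresses production at high primer levels.
#' @param k_exo Exonuclease degradation rate constant (min^-1 nM^-1 of
#'   exonuclease).
#' @param K_exo Degradation half-saturation constant (nM).
#' @param k_ex Membrane exchange rate between a compartment and the bulk
#'   phase (min^-1).
#' @param P Polymerase activity level (dimensionless; 1 = reference
#'   12.8 U mL^-1).
#' @param E Exonuclease concentration (nM).
#' @param alpha Fluorescence gain (RFU per nM of duplex equivalent).
#' @param F0 Baseline fluorescence (RFU).
#' @param ext_coef Weight of free extended strand in the duplex-proportional
#'   fluorescence proxy (dimensionless).
#' @return An object of class `pen_params` (a validated named list).
#' @examples
#' p <- pen_params()
#' p$k_pol
#' @export
pen_params <- function(k_pol = 10, K_m = 200, K_i = 200,
                       k_exo = 1.0, K_exo = 100, k_ex = 10,
                       P = 1, E = 0.6, alpha = 1, F0 = 100,
                       ext_coef = 0.1) {
  p <- list(k_pol = k_pol, K_m = K_m, K_i = K_i, k_exo = k_exo,
            K_exo = K_exo, k_ex = k_ex, P = P, E = E, alpha = alpha,
            F0 = F0, ext_coef = ext_coef)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("pen_params: '", nm, "' must be a single finite number")
    if (v < 0) stop("pen_params: '", nm, "' must be >= 0")
  }
  if (K_m <= 0) stop("pen_params: 'K_m' must be > 0")
  if (K_exo <= 0) stop("pen_params: 'K_exo' must be > 0")
  structure(p, class = "pen_params")
}

#' @export
print.pen_params <- function(x, ...) {
  cat("PEN reaction parameters (nM, min):\n")
  for (nm in names(x)) cat(sprintf("  %-8s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Proteinosome network layout
#'
#' Describes a dispersion of template-loaded proteinosome populations: for
#' each population the node kind (autocatalytic template T2 or linear trigger
#' template T1), the internal template concentration, the number of
#' compartments and their radius. `volume_fraction` is the total compartment
#' volume divided by the total sample volume and sets the dilution the
#' compartments experience through membrane exchange.
#'
#' @param populations List of population descriptions; each element is a list
#'   with fields `node_kind` ("autocatalytic" or "linear"), `T_in` (internal
#'   template concentration, uM; default 0.12), `n_compartments` (count) and
#'   `radius_um` (compartment radius, um).
#' @param volume_fraction Total compartment volume / total sample volume
#'   (dimensionless, strictly between 0 and 1).
#' @return An object of class `network_layout`.
#' @examples
#' network_layout(list(list(node_kind = "autocatalytic", T_in = 0.12,
#'                          n_compartments = 5, radius_um = 12.1)),
#'                volume_fraction = 0.005)
#' @export
network_layout <- function(populations, volume_fraction) {
  if (!is.numeric(volume_fraction) || length(volume_fraction) != 1L ||
      !is.finite(volume_fraction) ||
      volume_fraction <= 0 || volume_fraction >= 1)
    stop("network_layout: 'volume_fraction' must lie strictly in (0, 1)")
  if (!is.list(populations) || length(populations) == 0L)
    stop("network_layout: 'populations' must be a non-empty list")
  populations <- lapply(populations, function(pp) {
    pp <- utils::modifyList(list(T_in = 0.12), pp)
    if (is.null(pp$node_kind) ||
        !pp$node_kind %in% c("autocatalytic", "linear"))
      stop("network_layout: node_kind must be 'autocatalytic' or 'linear'")
    if (!is.numeric(pp$T_in) || pp$T_in < 0)
      stop("network_layout: T_in must be >= 0")
    if (!is.numeric(pp$n_compartments) || pp$n_compartments < 1)
      stop("network_layout: n_compartments must be >= 1")
    if (!is.numeric(pp$radius_um) || pp$radius_um <= 0)
      stop("network_layout: radius_um must be > 0")
    pp$n_compartments <- as.integer(pp$n_compartments)
    pp
  })
  structure(list(populations = populations,
                 volume_fraction = volume_fraction),
            class = "network_layout")
}

#' @export
print.network_layout <- function(x, ...) {
  cat("Proteinosome layout, volume fraction", x$volume_fraction, "\n")
  for (pp in x$populations)
    cat(sprintf("  %-13s n=%d  T_in=%g uM  r=%g um\n", pp$node_kind,
                pp$n_compartments, pp$T_in, pp$radius_um))
  invisible(x)
}
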