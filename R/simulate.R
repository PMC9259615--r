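# Mechanistic two-compartment PEN DNA reaction simulator.
# Concentration unit is nM throughout the state vector; time is minutes.

# production at an autocatalytic template: saturating occupancy with
# product inhibition (primer binding both template ends at high s).
.v_prod <- function(s, T_nM, p)
  p$k_pol * p$P * T_nM * (s / (p$K_m + s)) / (1 + s / p$K_i)

# production of the downstream substrate at a linear (trigger) template;
# the input strand is templated, not consumed.
.v_lin <- function(s_in, T_nM, p)
  p$k_pol * p$P * T_nM * (s_in / (p$K_m + s_in))

# Michaelis-type exonuclease degradation.
.v_deg <- function(s, p) p$k_exo * p$E * s / (p$K_exo + s)

# duplex-proportional fluorescence proxy: template-bound strand plus a small
# free-strand contribution (EvaGreen reports duplex non-specifically).
.duplex <- function(s_bound, T_nM, s_free, p)
  T_nM * s_bound / (p$K_m + s_bound) + p$ext_coef * s_free

# Fixed-step classical RK4 with a post-step clamp: components in
# (-1e-12, 0) are set to 0; larger negatives or non-finite states abort.
# Each recorded interval is integrated in n_sub equal substeps so the
# recording grid (frame interval) can be much coarser than the stability
# limit of the fastest rate (membrane exchange).
.integrate_rk4 <- function(deriv, y0, times, n_sub = 1L) {
  n <- length(times)
  out <- matrix(NA_real_, n, length(y0))
  out[1L, ] <- y0
  y <- y0
  for (i in seq_len(n - 1L)) {
    h <- (times[i + 1L] - times[i]) / n_sub
    for (j in seq_len(n_sub)) {
      t0 <- times[i] + (j - 1L) * h
      k1 <- deriv(t0, y)
      k2 <- deriv(t0 + h / 2, y + h / 2 * k1)
      k3 <- deriv(t0 + h / 2, y + h / 2 * k2)
      k4 <- deriv(t0 + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(y)))
        stop(sprintf("integration failure: non-finite state at t = %g",
                     t0 + h))
      tiny <- y < 0 & y > -1e-12
      y[tiny] <- 0
      if (any(y < 0))
        stop(sprintf("integration failure: negative state at t = %g",
                     t0 + h))
    }
    out[i + 1L, ] <- y
  }
  out
}

# substep count keeping the RK4 step well below the stability limit of the
# fastest linearised rate in the model.
.n_substeps <- function(params, T_nM_max, dt) {
  rate_scale <- params$k_ex +
    params$k_pol * params$P * T_nM_max / params$K_m +
    params$k_exo * params$E / params$K_exo
  max(1L, as.integer(ceiling(dt * rate_scale / 1.0)))
}

.check_grid <- function(duration, dt) {
  if (!is.numeric(duration) || duration <= 0) stop("'duration' must be > 0")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  if (dt > duration / 10) stop("'dt' must be <= duration/10")
  seq(0, duration, by = dt)
}

#' Simulate a bulk (buffer) autocatalytic PEN reaction
#'
#' Single-compartment reduction of the compartment model: one well-mixed
#' volume holding template at `template_conc`, primer at `primer0`,
#' polymerase and exonuclease. Integrates
#' `ds/dt = v_prod(s) - v_deg(s)` with classical fixed-step RK4 and reports
#' fluorescence `F(t) = F0 + alpha * duplex(s(t))`.
#'
#' @param params A [pen_params()] object.
#' @param template_conc Template concentration (uM).
#' @param primer0 Initial primer concentration (nM).
#' @param duration Simulated time (min).
#' @param dt Integration and sampling step (min); must be `<= duration/10`.
#' @return A [kinetic_trace()].
#' @examples
#' tr <- simulate_bulk_reaction(pen_params(), template_conc = 1,
#'                              primer0 = 1, duration = 120, dt = 1)
#' @export
simulate_bulk_reaction <- function(params, template_conc, primer0,
                                   duration, dt) {
  stopifnot(inherits(params, "pen_params"))
  if (template_conc < 0) stop("'template_conc' must be >= 0")
  if (primer0 < 0) stop("'primer0' must be >= 0")
  times <- .check_grid(duration, dt)
  T_nM <- template_conc * 1000
  deriv <- function(t, y) .v_prod(y, T_nM, params) - .v_deg(y, params)
  n_sub <- max(1L, as.integer(ceiling(
    dt * (params$k_pol * params$P * T_nM / params$K_m +
            params$k_exo * params$E / params$K_exo))))
  s <- .integrate_rk4(deriv, primer0, times, n_sub)[, 1L]
  A <- params$F0 + params$alpha * .duplex(s, T_nM, s, params)
  kinetic_trace(times, A, compartment_id = "bulk",
                template_conc = template_conc, template_units = "uM",
                exonuclease_nM = params$E)
}

#' Simulate a dispersion of template-loaded proteinosomes
#'
#' Couples every compartment to the shared bulk phase through first-order
#' membrane exchange at rate `k_ex`. Two diffusible strand species are
#' tracked: `s1`, the substrate of the linear (trigger) node, and `s2`, the
#' autocatalytic substrate. Inside an autocatalytic compartment `s2` is
#' amplified on its template; inside a linear compartment `s2` is produced
#' from template T1 at a rate proportional to the T1 occupancy by `s1`,
#' while `s1` itself is only degraded (templated catalysis). The bulk phase
#' only degrades and exchanges, with compartment-to-bulk volume weights
#' `V_j / V_out`.
#'
#' The primer is taken to be equilibrated across the membrane at t = 0
#' (uniform initial concentration): small DNA exchanges across the membrane
#' in seconds, faster than one frame interval.
#'
#' @param params A [pen_params()] object.
#' @param layout A [network_layout()].
#' @param primer0_outside Initial primer concentration (nM), uniform.
#' @param duration,dt Time span and step (min); `dt <= duration/10`.
#' @param seed Integer seed for the measurement noise (unused when
#'   `noise_sd = 0`).
#' @param noise_sd Additive Gaussian measurement noise on the reported
#'   fluorescence (RFU); the underlying state stays noiseless.
#' @param primer_node Which species the supplied primer is: `"auto"` picks
#'   `"s1"` when a linear population is present and `"s2"` otherwise;
#'   override to `"s1"` for trigger-substrate-only controls.
#' @return A [trace_set()] with one trace per compartment plus a `"bulk"`
#'   trace; `truth` carries the free-strand state matrices.
#' @examples
#' lay <- network_layout(list(list(node_kind = "autocatalytic",
#'                                 n_compartments = 3, radius_um = 12.1)),
#'                       volume_fraction = 0.005)
#' ts <- simulate_compartment_network(pen_params(), lay, primer0_outside = 1,
#'                                    duration = 300, dt = 1)
#' @export
simulate_compartment_network <- function(params, layout, primer0_outside,
                                         duration, dt, seed = NULL,
                                         noise_sd = 0,
                                         primer_node = c("auto", "s1", "s2")) {
  stopifnot(inherits(params, "pen_params"), inherits(layout, "network_layout"))
  primer_node <- match.arg(primer_node)
  if (primer0_outside < 0) stop("'primer0_outside' must be >= 0")
  times <- .check_grid(duration, dt)

  comp <- do.call(rbind, lapply(seq_along(layout$populations), function(ip) {
    pp <- layout$populations[[ip]]
    data.frame(pop = ip, kind = pp$node_kind, T_nM = pp$T_in * 1000,
               radius = pp$radius_um,
               idx = seq_len(pp$n_compartments))
  }))
  nc <- nrow(comp)
  V <- (4 / 3) * pi * comp$radius^3
  V_out <- sum(V) * (1 - layout$volume_fraction) / layout$volume_fraction
  w <- V / V_out
  is_lin <- comp$kind == "linear"
  has_linear <- any(is_lin)
  if (primer_node == "auto") primer_node <- if (has_linear) "s1" else "s2"

  # state: s1[1..nc], s2[1..nc], s1_out, s2_out
  y0 <- numeric(2 * nc + 2)
  if (primer_node == "s1") y0[c(seq_len(nc), 2 * nc + 1)] <- primer0_outside
  else y0[c(nc + seq_len(nc), 2 * nc + 2)] <- primer0_outside

  kx <- params$k_ex
  deriv <- function(t, y) {
    s1 <- y[seq_len(nc)]; s2 <- y[nc + seq_len(nc)]
    s1o <- y[2 * nc + 1]; s2o <- y[2 * nc + 2]
    ds1 <- -.v_deg(s1, params) + kx * (s1o - s1)
    prod2 <- ifelse(is_lin,
                    .v_lin(s1, comp$T_nM, params),
                    .v_prod(s2, comp$T_nM, params))
    ds2 <- prod2 - .v_deg(s2, params) + kx * (s2o - s2)
    ds1o <- -.v_deg(s1o, params) + sum(w * kx * (s1 - s1o))
    ds2o <- -.v_deg(s2o, params) + sum(w * kx * (s2 - s2o))
    c(ds1, ds2, ds1o, ds2o)
  }
  st <- .integrate_rk4(deriv, y0, times,
                       .n_substeps(params, max(comp$T_nM), dt))
  s1m <- st[, seq_len(nc), drop = FALSE]
  s2m <- st[, nc + seq_len(nc), drop = FALSE]

  if (!is.null(seed)) set.seed(seed)
  noise <- function(n) if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0

  traces <- vector("list", nc + 1L)
  for (j in seq_len(nc)) {
    bound <- if (is_lin[j]) s1m[, j] else s2m[, j]
    dup <- .duplex(bound, comp$T_nM[j], s1m[, j] + s2m[, j], params)
    A <- pmax(0, params$F0 + params$alpha * dup + noise(length(times)))
    traces[[j]] <- kinetic_trace(
      times, A,
      compartment_id = sprintf("p%d_c%d", comp$pop[j], comp$idx[j]),
      population = paste0("population", comp$pop[j]),
      template_conc = comp$T_nM[j] / 1000, template_units = "uM",
      exonuclease_nM = params$E)
  }
  dup_out <- .duplex(0, 0, st[, 2 * nc + 1] + st[, 2 * nc + 2], params)
  traces[[nc + 1L]] <- kinetic_trace(
    times, pmax(0, params$F0 + params$alpha * dup_out + noise(length(times))),
    compartment_id = "bulk", population = "bulk",
    template_conc = 0, template_units = "uM",
    exonuclease_nM = params$E)

  trace_set(traces, times, seed = if (is.null(seed)) NA_integer_ else seed,
            truth = list(params = params, layout = layout,
                         compartments = comp, s1 = s1m, s2 = s2m,
                         s1_out = st[, 2 * nc + 1], s2_out = st[, 2 * nc + 2],
                         primer_node = primer_node))
}
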