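# Independent oracles and fixture builders used across the suite.

# forward-Euler integrator, independent of the package's RK4 path
euler_bulk <- function(params, template_uM, primer0, duration, dt) {
  T_nM <- template_uM * 1000
  n <- ceiling(duration / dt)
  s <- numeric(n + 1)
  s[1] <- primer0
  for (i in seq_len(n)) {
    v_prod <- params$k_pol * params$P * T_nM *
      (s[i] / (params$K_m + s[i])) / (1 + s[i] / params$K_i)
    v_deg <- params$k_exo * params$E * s[i] / (params$K_exo + s[i])
    s[i + 1] <- max(0, s[i] + dt * (v_prod - v_deg))
  }
  s
}

# fluorescence map matching the generator's duplex proxy
fluor_of <- function(s, T_uM, params) {
  T_nM <- T_uM * 1000
  params$F0 + params$alpha *
    (T_nM * s / (params$K_m + s) + params$ext_coef * s)
}

# exact logistic samples in the printed parameterisation (k < 0 grows)
logistic_trace <- function(k, L = 1, x0, t, noise_sd = 0) {
  A <- L / (1 + exp(k * (t - x0)))
  if (noise_sd > 0) A <- A + rnorm(length(t), 0, noise_sd)
  kinetic_trace(t, pmax(A, 0), normalized = (L == 1))
}

# render a frame of disks and rotated ellipses directly (independent of
# synthesize_image_stack); shapes: list of (type, cx, cy, ... um units)
render_frame <- function(shapes, nx = 256, ny = 256, pixel_size = 0.65,
                         noise_sd = 0) {
  xs <- (seq_len(nx) - 0.5) * pixel_size
  ys <- (seq_len(ny) - 0.5) * pixel_size
  frame <- matrix(0, nx, ny)
  for (sh in shapes) {
    if (sh$type == "disk") {
      m <- outer((xs - sh$cx)^2, (ys - sh$cy)^2, "+") <= sh$r^2
    } else {
      th <- if (is.null(sh$theta)) 0 else sh$theta
      xr <- outer(xs - sh$cx, ys - sh$cy,
                  function(dx, dy) dx * cos(th) + dy * sin(th))
      yr <- outer(xs - sh$cx, ys - sh$cy,
                  function(dx, dy) -dx * sin(th) + dy * cos(th))
      m <- (xr / sh$a)^2 + (yr / sh$b)^2 <= 1
    }
    frame[m] <- sh$intensity
  }
  if (noise_sd > 0) frame <- frame + matrix(rnorm(nx * ny, 0, noise_sd), nx, ny)
  frame
}

# standard single-population layout at a given total template (nM)
autocat_layout <- function(total_nM, n = 4, radius = 12.1, T_in = 0.12)
  network_layout(list(list(node_kind = "autocatalytic", T_in = T_in,
                           n_compartments = n, radius_um = radius)),
                 volume_fraction = total_nM / (T_in * 1000))

# two-population trigger/amplifier layout; T2 total fixed at 0.068 nM
twonode_layout <- function(n1, n2 = 24, radius = 12.1) {
  vf1 <- (0.068 / 120) / n2
  network_layout(list(
    list(node_kind = "linear", T_in = 0.12, n_compartments = n1,
         radius_um = radius),
    list(node_kind = "autocatalytic", T_in = 0.12, n_compartments = n2,
         radius_um = radius)),
    volume_fraction = vf1 * (n1 + n2))
}

traces_of_pop <- function(ts, pop)
  Filter(function(tr) tr$population == pop, ts$traces)
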