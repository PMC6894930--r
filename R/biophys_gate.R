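#' Conductance-based bistable interneuron membrane model
#'
#' The intrinsic steady-state current is the sum of a linear leak, a
#' non-inactivating voltage-gated inward (calcium-like) current and a
#' voltage-gated outward (potassium-like) current,
#' `I_ss(V) = g_leak (V - E_leak) + g_ca m_inf(V) (V - E_ca) +
#' g_k n_inf(V) (V - E_k)`,
#' with Boltzmann activations `m_inf`, `n_inf`. With the default
#' calibration this I-V curve is N-shaped with stable zeros near -80 mV
#' (rest) and exactly -20 mV (plateau), an unstable zero between them, a
#' saddle-node ("knee") current of about 2.2 pA on the resting branch, and
#' a stiff depolarized branch (~3.5 nS) so that suprathreshold steps all
#' settle near -20 mV. `g_ca` is solved at construction so the depolarized
#' zero sits exactly at `v_dep_target` (pass `g_ca` explicitly to
#' override).
#'
#' Synaptic elements: a glutamate-gated chloride shunt of conductance
#' `g_cl` (gate state `s_cl` in 0..1) reversing at `e_cl = -80` mV near
#' rest, so an open shunt mainly lowers input resistance rather than
#' hyperpolarizing; and a gap junction of conductance `g_gap` to a
#' presynaptic command potential (`v_awa_rest` when the partner is silent,
#' `v_awa_on` when optogenetically driven). `g_cl` defaults above the
#' magnitude of the steepest negative slope of the intrinsic I-V, so the
#' fully open shunt makes the cell monostable near rest - the AND-gate
#' precondition. Membrane dynamics:
#' `C dV/dt = -I_ss(V) - g_cl s_cl (V - e_cl) + g_gap (v_awa - V) + I_inj`.
#'
#' A sigmoid of V serves as a normalized calcium-indicator proxy.
#'
#' @param capacitance_pf membrane capacitance in pF.
#' @param g_leak,e_leak leak conductance (nS) and reversal (mV).
#' @param g_ca,e_ca,ca_vhalf,ca_k inward current parameters; `g_ca = NULL`
#'   calibrates it from `v_dep_target`.
#' @param g_k,e_k,k_vhalf,k_k outward current parameters.
#' @param g_cl,e_cl chloride shunt conductance (nS) and reversal (mV).
#' @param g_gap gap-junction conductance (nS).
#' @param v_awa_rest,v_awa_on presynaptic command potentials (mV).
#' @param v_dep_target voltage (mV) at which the depolarized stable zero
#'   is placed during calibration.
#' @param ca_proxy_vhalf,ca_proxy_k calcium-proxy sigmoid parameters.
#' @return an object of class `membrane_model`.
#' @export
membrane_model <- function(capacitance_pf = 1,
                           g_leak = 0.25, e_leak = -80,
                           g_ca = NULL, e_ca = 60,
                           ca_vhalf = -45, ca_k = 5,
                           g_k = 0.8, e_k = -90,
                           k_vhalf = -25, k_k = 5,
                           g_cl = 3.5, e_cl = -80,
                           g_gap = 0.1,
                           v_awa_rest = -75, v_awa_on = -15,
                           v_dep_target = -20,
                           ca_proxy_vhalf = -45, ca_proxy_k = 8) {
  minf <- function(v) 1 / (1 + exp(-(v - ca_vhalf) / ca_k))
  ninf <- function(v) 1 / (1 + exp(-(v - k_vhalf) / k_k))
  if (is.null(g_ca)) {
    vd <- v_dep_target
    g_ca <- -(g_leak * (vd - e_leak) + g_k * ninf(vd) * (vd - e_k)) /
      (minf(vd) * (vd - e_ca))
  }
  m <- list(capacitance_pf = capacitance_pf,
            g_leak = g_leak, e_leak = e_leak,
            g_ca = g_ca, e_ca = e_ca, ca_vhalf = ca_vhalf, ca_k = ca_k,
            g_k = g_k, e_k = e_k, k_vhalf = k_vhalf, k_k = k_k,
            g_cl = g_cl, e_cl = e_cl, g_gap = g_gap,
            v_awa_rest = v_awa_rest, v_awa_on = v_awa_on,
            v_dep_target = v_dep_target,
            ca_proxy_vhalf = ca_proxy_vhalf, ca_proxy_k = ca_proxy_k)
  class(m) <- "membrane_model"
  m
}

#' @export
print.membrane_model <- function(x, ...) {
  fp <- find_fixed_points(x)
  cat("<membrane_model> C = ", x$capacitance_pf, " pF; fixed points at ",
      "0 pA (shunt closed, uncoupled):\n", sep = "")
  print(fp, row.names = FALSE)
  invisible(x)
}

#' Intrinsic steady-state current
#'
#' @param model a `membrane_model`.
#' @param v membrane potential(s), mV.
#' @return current in pA (positive = outward).
#' @export
intrinsic_current <- function(model, v) {
  minf <- 1 / (1 + exp(-(v - model$ca_vhalf) / model$ca_k))
  ninf <- 1 / (1 + exp(-(v - model$k_vhalf) / model$k_k))
  model$g_leak * (v - model$e_leak) +
    model$g_ca * minf * (v - model$e_ca) +
    model$g_k * ninf * (v - model$e_k)
}

# Net outward steady-state current; zero at a fixed point. v_awa = NULL
# means the gap junction is disconnected (isolated cell).
.net_current <- function(model, v, i_inj = 0, s_cl = 0, v_awa = NULL) {
  i <- intrinsic_current(model, v) +
    model$g_cl * s_cl * (v - model$e_cl) - i_inj
  if (!is.null(v_awa)) i <- i - model$g_gap * (v_awa - v)
  i
}

#' Fixed points of the membrane equation
#'
#' Locates every zero of the net steady-state current over
#' `[-120, 20]` mV by a sign-change scan (0.05 mV grid) refined with
#' bisection to |I| < 1e-6 pA, and classifies stability from the local
#' slope (a positive net-outward-current slope is stable). With the
#' default model, closed shunt and no input this yields the bistable
#' configuration: stable points near -80 and at -20 mV separated by an
#' unstable point.
#'
#' @param model a `membrane_model`.
#' @param i_inj injected current, pA.
#' @param s_cl chloride gate state in 0..1.
#' @param v_awa presynaptic potential (mV) or `NULL` for an uncoupled
#'   cell.
#' @param v_range search interval, mV.
#' @return data frame with columns `v` (mV), `stable` (logical), `current`
#'   (residual pA).
#' @export
find_fixed_points <- function(model, i_inj = 0, s_cl = 0, v_awa = NULL,
                              v_range = c(-120, 20)) {
  f <- function(v) .net_current(model, v, i_inj, s_cl, v_awa)
  grid <- seq(v_range[1], v_range[2], by = 0.05)
  fv <- f(grid)
  roots <- numeric(0)
  exact <- which(fv == 0)
  roots <- c(roots, grid[exact])
  flip <- which(fv[-1] * fv[-length(fv)] < 0)
  for (j in flip) {
    lo <- grid[j]; hi <- grid[j + 1]
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (abs(f(mid)) < 1e-6 || (hi - lo) < 1e-12) break
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    roots <- c(roots, mid)
  }
  roots <- sort(unique(roots))
  if (length(roots) == 0L)
    return(data.frame(v = numeric(0), stable = logical(0),
                      current = numeric(0)))
  eps <- 1e-4
  slope <- (f(roots + eps) - f(roots - eps)) / (2 * eps)
  data.frame(v = roots, stable = slope > 0, current = f(roots))
}

#' Stimulus protocols
#'
#' `protocol_steps()` builds a series of square current steps, each
#' preceded by a hyperpolarizing reset pre-pulse (the published series:
#' 5 s steps from -1 to 8 pA in 1 pA increments with a -10 pA pre-pulse).
#' `protocol_ramp()` builds a linear current ramp from `i_start` to
#' `i_end` over `duration_s` seconds.
#'
#' @param levels_pa step currents, pA.
#' @param step_s step duration, s.
#' @param pre_pulse_pa,pre_pulse_s reset pre-pulse amplitude and duration.
#' @return an object of class `stimulus_protocol`: a data frame of
#'   segments with `duration_s`, `i_start`, `i_end`.
#' @export
protocol_steps <- function(levels_pa = -1:8, step_s = 5,
                           pre_pulse_pa = -10, pre_pulse_s = 1) {
  seg <- do.call(rbind, lapply(levels_pa, function(lv)
    data.frame(duration_s = c(pre_pulse_s, step_s),
               i_start = c(pre_pulse_pa, lv), i_end = c(pre_pulse_pa, lv))))
  structure(seg, class = c("stimulus_protocol", "data.frame"))
}

#' @rdname protocol_steps
#' @param i_start,i_end ramp endpoints, pA.
#' @param duration_s ramp duration, s.
#' @export
protocol_ramp <- function(i_start = 0, i_end = 5, duration_s = 15) {
  structure(data.frame(duration_s = duration_s, i_start = i_start,
                       i_end = i_end),
            class = c("stimulus_protocol", "data.frame"))
}

# Injected current at arbitrary times for a segment protocol.
.protocol_current <- function(protocol, t_s) {
  ends <- cumsum(protocol$duration_s)
  starts <- c(0, ends[-length(ends)])
  i <- numeric(length(t_s))
  seg_idx <- findInterval(pmin(t_s, ends[length(ends)] - 1e-12), starts)
  seg_idx[seg_idx < 1L] <- 1L
  for (k in seq_len(nrow(protocol))) {
    sel <- seg_idx == k
    if (!any(sel)) next
    frac <- (t_s[sel] - starts[k]) / protocol$duration_s[k]
    i[sel] <- protocol$i_start[k] +
      (protocol$i_end[k] - protocol$i_start[k]) * pmin(pmax(frac, 0), 1)
  }
  i
}

#' Integrate the membrane equation under a stimulus protocol
#'
#' Fixed-step fourth-order Runge-Kutta integration of
#' `C dV/dt = -I_ss(V) - g_cl s_cl (V - e_cl) + g_gap (v_awa - V) +
#' I_inj(t)` at `dt_ms` (default 0.1 ms; the membrane time constants are
#' 0.3-4 ms, so halving dt moves reported transition times by less than
#' one step). Returns the voltage trajectory, the injected current and a
#' sigmoidal calcium-indicator proxy of V.
#'
#' @param model a `membrane_model`.
#' @param protocol a `stimulus_protocol`.
#' @param dt_ms integration step, ms.
#' @param v0 initial potential; default is the resting (most hyperpolarized
#'   stable) fixed point under the same conductances.
#' @param s_cl chloride gate state.
#' @param v_awa presynaptic potential or `NULL` (uncoupled).
#' @param record_every store every k-th step (default 10, i.e. 1 ms
#'   resolution).
#' @return an object of class `membrane_sim`: list with `t_s`, `v_mv`,
#'   `i_pa`, `ca_proxy`, `dt_ms` and the simulation settings.
#' @export
simulate_membrane <- function(model, protocol, dt_ms = 0.1, v0 = NULL,
                              s_cl = 0, v_awa = NULL, record_every = 10L) {
  stopifnot(inherits(model, "membrane_model"))
  if (is.null(v0)) {
    fp <- find_fixed_points(model, 0, s_cl, v_awa)
    st <- fp$v[fp$stable]
    if (length(st) == 0L) stop("no stable resting point found", call. = FALSE)
    v0 <- min(st)
  }
  total_s <- sum(protocol$duration_s)
  n_steps <- ceiling(total_s * 1000 / dt_ms)
  dt_s <- dt_ms / 1000
  # injected current at full and half steps, precomputed
  t_full <- (0:n_steps) * dt_s
  i_full <- .protocol_current(protocol, t_full)
  i_half <- .protocol_current(protocol, t_full + dt_s / 2)
  Cpf <- model$capacitance_pf
  gl <- model$g_leak; el <- model$e_leak
  gca <- model$g_ca; eca <- model$e_ca; cvh <- model$ca_vhalf; cak <- model$ca_k
  gk <- model$g_k; ek <- model$e_k; kvh <- model$k_vhalf; kk <- model$k_k
  gcl <- model$g_cl * s_cl; ecl <- model$e_cl
  ggap <- if (is.null(v_awa)) 0 else model$g_gap
  vawa <- if (is.null(v_awa)) 0 else v_awa
  dvdt <- function(v, i_inj) {
    iss <- gl * (v - el) +
      gca / (1 + exp(-(v - cvh) / cak)) * (v - eca) +
      gk / (1 + exp(-(v - kvh) / kk)) * (v - ek)
    (-iss - gcl * (v - ecl) + ggap * (vawa - v) + i_inj) / Cpf
  }
  keep <- seq(1L, n_steps + 1L, by = record_every)
  out_v <- numeric(length(keep))
  out_v[1] <- v0
  v <- v0
  ki <- 2L
  for (s in seq_len(n_steps)) {
    k1 <- dvdt(v, i_full[s])
    k2 <- dvdt(v + dt_ms / 2 * k1, i_half[s])
    k3 <- dvdt(v + dt_ms / 2 * k2, i_half[s])
    k4 <- dvdt(v + dt_ms * k3, i_full[s + 1L])
    v <- v + dt_ms / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(v))
      stop("integration diverged at t = ", s * dt_s,
           " s (dt too large or model degenerate)", call. = FALSE)
    if (ki <= length(keep) && s + 1L == keep[ki]) {
      out_v[ki] <- v
      ki <- ki + 1L
    }
  }
  t_rec <- t_full[keep]
  structure(list(t_s = t_rec, v_mv = out_v,
                 i_pa = i_full[keep],
                 ca_proxy = 1 / (1 + exp(-(out_v - model$ca_proxy_vhalf) /
                                           model$ca_proxy_k)),
                 dt_ms = dt_ms, s_cl = s_cl, v_awa = v_awa),
            class = "membrane_sim")
}

# Unstable fixed point separating the two stable branches of the isolated,
# shunt-closed model at zero input.
.v_unstable <- function(model) {
  fp <- find_fixed_points(model)
  vu <- fp$v[!fp$stable]
  if (length(vu) == 0L)
    stop("model has no unstable fixed point at rest", call. = FALSE)
  vu[1]
}

# Most depolarized stable fixed point under the given conductances.
.v_depolarized <- function(model, i_inj = 0, s_cl = 0, v_awa = NULL) {
  fp <- find_fixed_points(model, i_inj, s_cl, v_awa)
  st <- fp$v[fp$stable]
  if (length(st) == 0L) return(NA_real_)
  max(st)
}

#' Smallest current step that switches the membrane to the plateau
#'
#' Simulates each step of the protocol independently from rest (each
#' preceded by the hyperpolarizing reset pre-pulse) and reports the
#' smallest step current after which the membrane has crossed the unstable
#' fixed point and settled within 5 mV of the depolarized stable state.
#'
#' @param model a `membrane_model`.
#' @param levels_pa candidate step currents (default -1..8 pA).
#' @param step_s step duration (default 5 s).
#' @param pre_pulse_pa,pre_pulse_s reset pre-pulse.
#' @param s_cl,v_awa synaptic state during the whole protocol.
#' @param dt_ms integration step.
#' @return smallest switching current in pA, or `NA` if no step switches.
#' @export
step_threshold <- function(model, levels_pa = -1:8, step_s = 5,
                           pre_pulse_pa = -10, pre_pulse_s = 1,
                           s_cl = 0, v_awa = NULL, dt_ms = 0.1) {
  v_dep <- .v_depolarized(model)
  for (lv in sort(levels_pa)) {
    pr <- protocol_steps(lv, step_s, pre_pulse_pa, pre_pulse_s)
    sim <- simulate_membrane(model, pr, dt_ms = dt_ms, s_cl = s_cl,
                             v_awa = v_awa)
    if (!is.na(v_dep) && abs(sim$v_mv[length(sim$v_mv)] - v_dep) < 5)
      return(lv)
  }
  NA_real_
}

#' Instantaneous current at the ramp-evoked state transition
#'
#' Simulates a linear current ramp and reports the injected current at the
#' moment the membrane potential first crosses the unstable fixed point of
#' the resting configuration. Because the membrane time constants are
#' milliseconds while the ramps span seconds, the crossing current is
#' essentially the saddle-node (knee) current and is insensitive to the
#' ramp slope.
#'
#' @param model a `membrane_model`.
#' @param i_end ramp end current, pA.
#' @param duration_s ramp duration, s.
#' @param i_start ramp start current, pA.
#' @param s_cl,v_awa synaptic state.
#' @param dt_ms integration step.
#' @return current in pA at the transition, or `NA` if none occurs.
#' @export
ramp_threshold <- function(model, i_end = 5, duration_s = 15, i_start = 0,
                           s_cl = 0, v_awa = NULL, dt_ms = 0.1) {
  vu <- .v_unstable(model)
  sim <- simulate_membrane(model, protocol_ramp(i_start, i_end, duration_s),
                           dt_ms = dt_ms, s_cl = s_cl, v_awa = v_awa)
  hit <- which(sim$v_mv > vu)
  if (length(hit) == 0L) return(NA_real_)
  sim$i_pa[hit[1]]
}

#' AND-gate truth table of the two-input circuit
#'
#' Evaluates the four combinations of gap-junction drive (presynaptic
#' command at `v_awa_on` versus `v_awa_rest`) and glutamate release from
#' upstream sensory neurons (release keeps the chloride shunt open,
#' `s_cl = 1`; odor-evoked inhibition of those neurons closes it,
#' `s_cl = 0`). Each combination is simulated for `t_settle_s` seconds
#' from rest; the plateau flag records whether the final potential lies
#' within 5 mV of the depolarized stable state of the shunt-closed model.
#' With the default calibration only coincident drive and disinhibition
#' reach the plateau.
#'
#' @param model a `membrane_model`.
#' @param t_settle_s simulated duration per combination (default 10 s).
#' @param dt_ms integration step.
#' @return data frame with `awa_drive`, `glut_release_off`, `final_v_mv`,
#'   `plateau`.
#' @export
and_gate_truth_table <- function(model, t_settle_s = 10, dt_ms = 0.1) {
  v_dep <- .v_depolarized(model)
  combos <- expand.grid(awa_drive = c(FALSE, TRUE),
                        glut_release_off = c(FALSE, TRUE))
  res <- lapply(seq_len(nrow(combos)), function(r) {
    drive <- combos$awa_drive[r]
    released <- combos$glut_release_off[r]   # TRUE = shunt closed
    s_cl <- if (released) 0 else 1
    v_awa <- if (drive) model$v_awa_on else model$v_awa_rest
    rest <- find_fixed_points(model, 0, 1, model$v_awa_rest)
    v0 <- min(rest$v[rest$stable])
    sim <- simulate_membrane(model, protocol_ramp(0, 0, t_settle_s),
                             dt_ms = dt_ms, v0 = v0, s_cl = s_cl,
                             v_awa = v_awa)
    vf <- sim$v_mv[length(sim$v_mv)]
    data.frame(awa_drive = drive, glut_release_off = released,
               final_v_mv = vf, plateau = abs(vf - v_dep) < 5)
  })
  do.call(rbind, res)
}

#' Report whether the calibration produces hysteresis
#'
#' After a suprathreshold step returns to zero injected current the
#' membrane stays on the depolarized branch exactly when that branch is
#' still a stable fixed point at 0 pA. This helper reports which regime
#' the model's calibration is in, and verifies it by simulation.
#'
#' @param model a `membrane_model`.
#' @param step_pa suprathreshold test step (default 5 pA).
#' @param dt_ms integration step.
#' @return list with `bistable_at_zero` (fixed-point analysis) and
#'   `persists_after_step` (simulated), which must agree.
#' @export
hysteresis_report <- function(model, step_pa = 5, dt_ms = 0.1) {
  fp0 <- find_fixed_points(model)
  dep_stable <- any(fp0$stable & fp0$v > .v_unstable(model))
  pr <- structure(data.frame(duration_s = c(5, 5),
                             i_start = c(step_pa, 0), i_end = c(step_pa, 0)),
                  class = c("stimulus_protocol", "data.frame"))
  sim <- simulate_membrane(model, pr, dt_ms = dt_ms)
  vf <- sim$v_mv[length(sim$v_mv)]
  list(bistable_at_zero = dep_stable,
       persists_after_step = vf > .v_unstable(model),
       final_v_mv = vf)
}
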