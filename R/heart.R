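# Normalized double-Hill activation shape constants (rise/decay time
# fractions and Hill exponents); s is dimensionless activation time.
HILL_SHAPE <- c(t1 = 0.269, n1 = 1.32, t2 = 0.452, n2 = 21.9)

#' @noRd
hill_shape <- function(s, shape = HILL_SHAPE) {
  a <- (s / shape[["t1"]])^shape[["n1"]]
  (a / (1 + a)) / (1 + (s / shape[["t2"]])^shape[["n2"]])
}

# peak location and value of the raw shape, found numerically and memoized
.hill_cache <- new.env(parent = emptyenv())
#' @noRd
hill_peak <- function(shape = HILL_SHAPE) {
  key <- paste(signif(shape, 10), collapse = "|")
  hit <- .hill_cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- seq(0.02, 1.5, by = 1e-4)
  v <- hill_shape(s, shape)
  i <- which.max(v)
  res <- list(s = s[i], value = v[i])
  .hill_cache[[key]] <- res
  res
}

#' Lumped left-ventricle parameters
#'
#' Parameter set of the time-varying-elastance ventricle: pressure is
#' \eqn{p_{lv}(t) = E(t)\,(V - V_0)} with \eqn{E(t)} sweeping between
#' `E_min` (diastole) and `E_max` (end systole), pressure-gated aortic and
#' mitral valves modelled as diodes with linear resistance (aortic inertance
#' optional), and a constant-pressure atrial preload source.
#'
#' @param E_max peak elastance (mmHg/mL), > `E_min`.
#' @param E_min baseline (diastolic) elastance (mmHg/mL), > 0.
#' @param period cardiac period T = 60/HR (s).
#' @param V0 unstressed ventricular volume (mL).
#' @param activation_time time to peak elastance (s), in (0, T); the default
#'   0.3 sqrt(T) reproduces the physiological shortening of systole with
#'   increasing heart rate.
#' @param preload_pressure constant atrial filling pressure (mmHg).
#' @param valve_resistance aortic valve resistance (mmHg s/mL).
#' @param valve_inertance aortic valve inertance (mmHg s^2/mL), may be 0.
#' @param mitral_resistance mitral valve resistance (mmHg s/mL).
#' @param shape double-Hill shape constants, a named numeric vector
#'   `c(t1, n1, t2, n2)` (rise/decay time fractions and Hill exponents of
#'   the normalized activation waveform).
#' @return object of class `cardiac_params`.
#' @export
cardiac_params <- function(E_max, E_min, period,
                           V0 = 10,
                           activation_time = 0.3 * sqrt(period),
                           preload_pressure = 8,
                           valve_resistance = 0.005,
                           valve_inertance = 0,
                           mitral_resistance = 0.005,
                           shape = HILL_SHAPE) {
  if (period <= 0) stop_invalid("cardiac_params: period must be > 0")
  if (!(E_max > E_min && E_min > 0)) {
    stop_invalid("cardiac_params: need E_max > E_min > 0")
  }
  if (!(activation_time > 0 && activation_time < period)) {
    stop_invalid("cardiac_params: activation_time must lie in (0, period)")
  }
  if (valve_resistance <= 0 || mitral_resistance <= 0 || valve_inertance < 0) {
    stop_invalid("cardiac_params: invalid valve parameters")
  }
  structure(list(E_max = E_max, E_min = E_min, V0 = V0, period = period,
                 activation_time = activation_time,
                 preload_pressure = preload_pressure,
                 valve_resistance = valve_resistance,
                 valve_inertance = valve_inertance,
                 mitral_resistance = mitral_resistance,
                 shape = shape),
            class = "cardiac_params")
}

#' @export
print.cardiac_params <- function(x, ...) {
  cat("Lumped LV parameters:\n")
  cat(sprintf("  E_max %.3f, E_min %.4f mmHg/mL, V0 %.1f mL\n",
              x$E_max, x$E_min, x$V0))
  cat(sprintf("  period %.3f s (HR %.1f bpm), activation time %.3f s\n",
              x$period, 60 / x$period, x$activation_time))
  cat(sprintf("  preload %.1f mmHg, valve R %.3f mmHg s/mL\n",
              x$preload_pressure, x$valve_resistance))
  invisible(x)
}

#' Time-varying ventricular elastance
#'
#' Periodic double-Hill elastance waveform normalized so that its minimum
#' over a cycle is `E_min`, its maximum is `E_max`, and the maximum is
#' attained at `activation_time`.
#'
#' @param t time (s), >= 0; vectorized. Times beyond one period wrap.
#' @param params a [cardiac_params()] object.
#' @return elastance E(t) (mmHg/mL).
#' @export
elastance <- function(t, params) {
  if (any(t < 0)) stop_invalid("elastance: negative time")
  shape <- if (is.null(params$shape)) HILL_SHAPE else params$shape
  pk <- hill_peak(shape)
  tc <- t %% params$period
  s <- tc * (pk$s / params$activation_time)
  params$E_min + (params$E_max - params$E_min) *
    hill_shape(s, shape) / pk$value
}

#' Instantaneous ventricular pressure
#'
#' Elastance pressure--volume relation \eqn{p = E(t)(V - V_0)}.
#'
#' @param state list with `volume` (mL) and `time_in_cycle` (s); optional
#'   valve flags `aortic_valve_open`, `mitral_valve_open`.
#' @param params a [cardiac_params()] object.
#' @return ventricular pressure (mmHg).
#' @export
ventricle_pressure <- function(state, params) {
  if (is.null(state$volume) || state$volume <= 0) {
    stop_invalid("ventricle_pressure: state$volume must be > 0")
  }
  if (state$volume <= params$V0) {
    warning("ventricular volume at or below unstressed volume V0 ",
            "(allowed transiently)", call. = FALSE)
  }
  elastance(state$time_in_cycle, params) * (state$volume - params$V0)
}

#' Advance the lumped heart by one time step
#'
#' Explicit update of the ventricle against a given aortic root pressure:
#' the aortic valve passes flow only while ventricular pressure exceeds root
#' pressure (diode with linear resistance, optional inertance), the mitral
#' valve fills from the constant preload while ventricular pressure is below
#' it, and the volume obeys the discrete mass balance
#' \eqn{\Delta V = (Q_{in} - Q_{out})\,dt} exactly.
#'
#' @param state list with `volume` (mL), `time_in_cycle` (s) and, when
#'   inertance is used, `aortic_flow` (mL/s).
#' @param aortic_root_pressure pressure opposing the aortic valve (mmHg).
#' @param dt time step (s).
#' @param params a [cardiac_params()] object.
#' @return list with the new `state` (volume, time_in_cycle, valve flags,
#'   aortic_flow) and the aortic inflow `Q` (mL/s) over the step.
#' @export
step_heart <- function(state, aortic_root_pressure, dt, params) {
  p_lv <- elastance(state$time_in_cycle, params) * (state$volume - params$V0)
  if (params$valve_inertance > 0) {
    q_prev <- if (is.null(state$aortic_flow)) 0 else state$aortic_flow
    q_av <- q_prev + dt * (p_lv - aortic_root_pressure -
                             params$valve_resistance * q_prev) /
      params$valve_inertance
    q_av <- max(0, q_av)
    if (p_lv <= aortic_root_pressure && q_prev <= 0) q_av <- 0
  } else {
    q_av <- max(0, (p_lv - aortic_root_pressure) / params$valve_resistance)
  }
  q_mit <- max(0, (params$preload_pressure - p_lv) / params$mitral_resistance)
  new_state <- list(
    volume = state$volume + dt * (q_mit - q_av),
    time_in_cycle = (state$time_in_cycle + dt) %% params$period,
    aortic_valve_open = q_av > 0,
    mitral_valve_open = q_mit > 0,
    aortic_flow = q_av
  )
  list(state = new_state, Q = q_av)
}

# Pure-0D harness: heart ejecting into a two-element Windkessel afterload.
# Used in tests to exercise valve logic and volume conservation without the
# 1D network.
simulate_heart_0d <- function(params, R_art = 1.0, C_art = 1.5,
                              cycles = 8, dt = 1e-4, p_art0 = 70,
                              p_ven = 5) {
  state <- list(volume = params$V0 + params$preload_pressure / params$E_min,
                time_in_cycle = 0, aortic_flow = 0)
  p_art <- p_art0
  n <- round(cycles * params$period / dt)
  keep <- round(params$period / dt)
  vol <- q_av <- q_mit <- p_lv <- p_a <- both_open <- numeric(0)
  for (i in seq_len(n)) {
    st <- step_heart(state, p_art, dt, params)
    p_art <- p_art + dt * (st$Q - (p_art - p_ven) / R_art) / C_art
    if (i > n - keep) {
      vol <- c(vol, st$state$volume)
      q_av <- c(q_av, st$Q)
      q_mit <- c(q_mit, (st$state$volume - state$volume) / dt + st$Q)
      p_a <- c(p_a, p_art)
      both_open <- c(both_open,
                     st$state$aortic_valve_open && st$state$mitral_valve_open)
    }
    state <- st$state
  }
  list(volume = vol, q_aortic = q_av, q_mitral = q_mit, p_art = p_a,
       both_valves_open = as.logical(both_open), dt = dt)
}
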