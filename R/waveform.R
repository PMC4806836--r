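#' Central pressure indices from a one-cycle waveform
#'
#' Systolic pressure is the cycle maximum, diastolic the minimum, pulse
#' pressure their difference and MAP the time-weighted cycle mean.
#'
#' @param waveform a `site_waveform` (data.frame with `time` and `pressure`)
#'   or any data.frame with those columns spanning one cycle.
#' @param id subject identifier to attach.
#' @param source `"model"` or `"reference_device"`.
#' @return object of class `central_pressure_estimate`: a one-row
#'   data.frame with `id`, `cSBP`, `cDBP`, `cPP`, `MAP`, `source`.
#' @export
extract_pressures <- function(waveform, id = NA_character_,
                              source = c("model", "reference_device")) {
  source <- match.arg(source)
  p <- waveform$pressure
  t <- waveform$time
  if (is.null(p) || is.null(t) || anyNA(p) || anyNA(t)) {
    stop_invalid("extract_pressures: waveform must carry finite time and ",
                 "pressure columns")
  }
  if (length(p) < 50) stop_invalid("extract_pressures: need >= 50 samples")
  sbp <- max(p)
  dbp <- min(p)
  if (sbp - dbp < 1e-9) {
    stop_invalid("extract_pressures: degenerate (flat) waveform, ",
                 "no pulse to measure")
  }
  # time-weighted mean (trapezoid), robust to non-uniform sampling
  map <- sum(diff(t) * (head(p, -1) + tail(p, -1)) / 2) / (max(t) - min(t))
  out <- data.frame(id = as.character(id), cSBP = sbp, cDBP = dbp,
                    cPP = sbp - dbp, MAP = map, source = source,
                    stringsAsFactors = FALSE)
  class(out) <- c("central_pressure_estimate", "data.frame")
  out
}

#' Locate the foot of a pressure waveform
#'
#' Intersecting-tangent construction: the foot is the intersection of the
#' horizontal line through the cycle minimum with the tangent drawn at the
#' point of maximum upstroke slope. This is the convention used by
#' foot-to-foot transit-time devices.
#'
#' @param waveform a `site_waveform` or data.frame with `time`, `pressure`.
#' @return foot time (s).
#' @export
diastolic_foot <- function(waveform) {
  t <- waveform$time
  p <- waveform$pressure
  if (max(p) - min(p) < 1e-9) stop_invalid("diastolic_foot: flat waveform")
  dp <- diff(p) / diff(t)
  if (max(dp) <= 0) stop_invalid("diastolic_foot: no rising edge found")
  # To make the construction robust to where the cycle window cuts the
  # upstroke, rotate the cycle so it starts at the pressure minimum.
  i_min <- which.min(p)
  rot <- c(i_min:length(p), seq_len(i_min - 1))
  pr <- p[rot]
  dtv <- diff(t)
  tr <- cumsum(c(0, dtv[c(i_min:(length(p) - 1), seq_len(i_min - 1))]))
  dpr <- diff(pr) / diff(tr)
  i_up <- which.max(dpr)
  slope <- dpr[i_up]
  t_tan <- (tr[i_up] + tr[i_up + 1]) / 2
  p_tan <- (pr[i_up] + pr[i_up + 1]) / 2
  p_min <- min(p)
  t_foot_rot <- t_tan - (p_tan - p_min) / slope
  # map back to the original cycle's clock
  t_foot <- t[i_min] + t_foot_rot
  period <- max(t) - min(t) + mean(dtv)
  if (t_foot > max(t)) t_foot <- t_foot - period
  t_foot
}

#' Foot-to-foot pulse wave velocity
#'
#' Transit-time PWV: path distance divided by the delay between the
#' diastolic feet of a proximal and a distal waveform,
#' \eqn{PWV = \Delta x / (t_{foot,distal} - t_{foot,proximal})}.
#' A non-positive delay (allowing for cycle wrap) is an ordering error.
#'
#' @param proximal,distal `site_waveform`s over the same cycle.
#' @param path_distance path length between the sites (m).
#' @return PWV (m/s).
#' @export
foot_to_foot_pwv <- function(proximal, distal, path_distance) {
  if (path_distance <= 0) stop_invalid("foot_to_foot_pwv: distance must be > 0")
  tp <- diastolic_foot(proximal)
  td <- diastolic_foot(distal)
  delay <- td - tp
  period <- max(proximal$time) - min(proximal$time) +
    mean(diff(proximal$time))
  # feet are defined modulo the cycle; wrap into (-T/2, T/2]
  if (delay <= -period / 2) delay <- delay + period
  if (delay > period / 2) delay <- delay - period
  if (delay <= 0) {
    stop_invalid("foot_to_foot_pwv: non-positive delay; sites swapped or ",
                 "path distance wrong")
  }
  path_distance / delay
}

#' Pulse pressure amplification
#'
#' Ratio of peripheral to central pulse pressure; values above 1 are the
#' norm in young subjects (the pulse steepens and grows travelling
#' distally).
#'
#' @param central,peripheral `central_pressure_estimate`s for the same
#'   subject and source.
#' @return the ratio peripheral cPP / central cPP.
#' @export
amplification <- function(central, peripheral) {
  peripheral$cPP / central$cPP
}

#' In-silico carotid-femoral PWV of a simulated subject
#'
#' Applies the clinical foot-to-foot method to the simulated carotid and
#' femoral waveforms, with the path distance taken along the network
#' (carotid site to femoral site through the aortic arch).
#'
#' @param sim a `centralbp_sim` containing carotid and femoral waveforms.
#' @param network the (tailored) network the simulation used.
#' @return measured cfPWV (m/s).
#' @export
measure_cfpwv <- function(sim, network) {
  wf <- sim$waveforms
  if (is.null(wf$carotid) || is.null(wf$femoral)) {
    stop_invalid("measure_cfpwv: simulation lacks carotid/femoral outputs")
  }
  d_cm <- site_path_distance(network, "carotid", "femoral")
  foot_to_foot_pwv(wf$carotid, wf$femoral, d_cm / 100)
}
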