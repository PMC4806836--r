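# Unit conventions at all user-facing interfaces:
#   pressure mmHg, length cm, area cm^2, volume mL, flow mL/s, time s,
#   PWV m/s, wall stiffness Pa*cm, wall viscosity Pa*s*cm,
#   resistance mmHg*s/mL, compliance mL/mmHg,
#   blood density kg/m^3, blood viscosity Pa*s.
# The numerical core works in CGS (dyn, cm, s, g); conversions live here only.

MMHG_TO_DYNCM2 <- 1333.22387415
PA_TO_DYNCM2 <- 10
MS_TO_CMS <- 100 # m/s -> cm/s

#' @noRd
mmHg_to_cgs <- function(p) p * MMHG_TO_DYNCM2
#' @noRd
cgs_to_mmHg <- function(p) p / MMHG_TO_DYNCM2
#' @noRd
beta_to_cgs <- function(beta) beta * PA_TO_DYNCM2 # Pa*cm -> dyn/cm
#' @noRd
gamma_to_cgs <- function(gamma) gamma * PA_TO_DYNCM2 # Pa*s*cm -> dyn*s/cm
#' @noRd
rho_to_cgs <- function(rho) rho / 1000 # kg/m^3 -> g/cm^3
#' @noRd
mu_to_cgs <- function(mu) mu * 10 # Pa*s -> poise
#' @noRd
res_to_cgs <- function(r) r * MMHG_TO_DYNCM2 # mmHg*s/mL -> dyn*s/cm^5
#' @noRd
cap_to_cgs <- function(c) c / MMHG_TO_DYNCM2 # mL/mmHg -> cm^5/dyn

stop_invalid <- function(...) {
  stop(structure(
    class = c("centralbp_invalid_input", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
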