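#' Transmural pressure from the arterial tube law
#'
#' Constitutive relation of a compliant vessel: an elastic Laplace-law term
#' plus an optional Kelvin--Voigt viscous term,
#' \deqn{p = p_{ext} + \beta\,\frac{\sqrt{A}-\sqrt{A_0}}{A_0}
#'       + \frac{\gamma}{A_0\sqrt{A}}\frac{dA}{dt}.}
#' The elastic branch yields the closed-form wave speed used by
#' [wave_speed()], which is what makes the pulse-wave-velocity based
#' stiffness setting invertible.
#'
#' @param A cross-sectional area (cm^2), > 0.
#' @param A0 reference (zero transmural pressure) area (cm^2), > 0.
#' @param beta elastic wall coefficient (Pa cm), > 0.
#' @param gamma Kelvin--Voigt wall-viscosity coefficient (Pa s cm), >= 0.
#' @param dA_dt rate of change of area (cm^2/s).
#' @param p_ext external pressure (mmHg).
#' @return transmural pressure (mmHg).
#' @seealso [wave_speed()], [stiffness_from_pwv()]
#' @export
#' @examples
#' tube_law(A = 3.3, A0 = 3.0, beta = 100)
tube_law <- function(A, A0, beta, gamma = 0, dA_dt = 0, p_ext = 0) {
  if (any(A <= 0) || any(A0 <= 0)) {
    stop_invalid("tube_law: areas must be strictly positive")
  }
  if (any(beta <= 0)) stop_invalid("tube_law: beta must be strictly positive")
  if (any(gamma < 0)) stop_invalid("tube_law: gamma must be non-negative")
  b <- beta_to_cgs(beta)
  g <- gamma_to_cgs(gamma)
  p <- b * (sqrt(A) - sqrt(A0)) / A0 + g / (A0 * sqrt(A)) * dA_dt
  p_ext + cgs_to_mmHg(p)
}

#' Pulse wave speed of the elastic tube law
#'
#' Wave speed \eqn{c = \sqrt{(A/\rho)\,\partial p/\partial A}} of the elastic
#' branch of [tube_law()]; in closed form
#' \eqn{c^2 = \beta \sqrt{A} / (2 \rho A_0)}.
#'
#' @inheritParams tube_law
#' @param rho blood density (kg/m^3).
#' @return wave speed (m/s).
#' @export
wave_speed <- function(A, A0, beta, rho = 1060) {
  if (any(A <= 0) || any(A0 <= 0) || any(beta <= 0) || any(rho <= 0)) {
    stop_invalid("wave_speed: all inputs must be strictly positive")
  }
  c_cgs <- sqrt(beta_to_cgs(beta) * sqrt(A) / (2 * rho_to_cgs(rho) * A0))
  c_cgs / MS_TO_CMS
}

#' Wall stiffness that realises a target pulse wave velocity
#'
#' Exact algebraic inverse of [wave_speed()]. With the default
#' `at_pressure = 0` the inversion is taken at \eqn{A = A_0}:
#' \eqn{\beta = 2 \rho c^2 \sqrt{A_0}}, so
#' `wave_speed(A0, A0, stiffness_from_pwv(v, A0))` returns `v` to machine
#' precision. Because the tube law stiffens with distension
#' (\eqn{c^2 = \beta/(2\rho\sqrt{A_0}) + p/(2\rho)} exactly, for transmural
#' pressure \eqn{p}), a PWV measured in vivo reflects the vessel's working
#' pressure; passing that pressure as `at_pressure` makes the *distended*
#' wave speed match the target instead:
#' \eqn{\beta = \sqrt{A_0}\,(2 \rho c^2 - p)}.
#'
#' @param target_pwv target wave speed (m/s), > 0.
#' @param A0 reference area (cm^2), > 0.
#' @param rho blood density (kg/m^3).
#' @param at_pressure transmural pressure (mmHg) at which the target wave
#'   speed should hold (0 = at reference area).
#' @return elastic wall coefficient beta (Pa cm).
#' @export
#' @examples
#' b <- stiffness_from_pwv(5.86, A0 = 3.0)
#' wave_speed(3.0, 3.0, b) # 5.86
stiffness_from_pwv <- function(target_pwv, A0, rho = 1060, at_pressure = 0) {
  if (any(target_pwv <= 0) || any(A0 <= 0) || any(rho <= 0)) {
    stop_invalid("stiffness_from_pwv: all inputs must be strictly positive")
  }
  rho_c <- rho_to_cgs(rho)
  b_cgs <- sqrt(A0) * (2 * rho_c * (target_pwv * MS_TO_CMS)^2 -
                         mmHg_to_cgs(at_pressure))
  if (any(b_cgs <= 0)) {
    stop_invalid("stiffness_from_pwv: target wave speed is below the ",
                 "pressure-induced floor sqrt(p / (2 rho))")
  }
  b_cgs / PA_TO_DYNCM2
}

VESSEL_REGIONS <- c("aortic", "upper-limb", "lower-limb", "cerebral", "visceral")
NAMED_SITES <- c("aortic_root", "carotid", "brachial", "radial", "femoral", "tibial")

#' Assemble and validate an arterial network
#'
#' Container for the large-artery tree: tapered elastic segments, RCR
#' (three-element Windkessel) terminal loads on every leaf, the six named
#' measurement sites, the blood constants, and the reference-subject scalars
#' used by the subject-specific setting procedure.
#'
#' @param segments data.frame with columns `id`, `name`, `length` (cm),
#'   `proximal_radius`, `distal_radius` (cm), `wall_stiffness` (Pa cm),
#'   `viscoelastic_coeff` (Pa s cm), `region` (one of aortic, upper-limb,
#'   lower-limb, cerebral, visceral), `parent` (id or NA for the root).
#' @param terminals data.frame with columns `segment`, `R1`, `R2`
#'   (mmHg s/mL), `C` (mL/mmHg), `venous_pressure` (mmHg); one row per leaf.
#' @param named_sites data.frame with columns `site`, `segment`, `position`
#'   (fractional position in \[0, 1\]); must cover aortic_root, carotid,
#'   brachial, radial, femoral, tibial.
#' @param fluid list with `blood_density` (kg/m^3) and `blood_viscosity`
#'   (Pa s).
#' @param reference list of reference-subject scalars: `height` (cm), `bsa`
#'   (m^2), `map` (mmHg), `mean_flow` (mL/s), `ratio` (mmHg s/mL, =
#'   map/mean_flow) and `regional_pwv` (named list, m/s per region).
#' @return object of class `arterial_network`.
#' @export
arterial_network <- function(segments, terminals, named_sites,
                             fluid = list(blood_density = 1060,
                                          blood_viscosity = 0.004),
                             reference = NULL) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  terminals <- as.data.frame(terminals, stringsAsFactors = FALSE)
  named_sites <- as.data.frame(named_sites, stringsAsFactors = FALSE)
  net <- structure(
    list(segments = segments, terminals = terminals,
         named_sites = named_sites, fluid = fluid, reference = reference),
    class = "arterial_network"
  )
  validate_network(net)
  net
}

#' Validate arterial-network invariants
#'
#' Checks the schema and the topological invariants: strictly positive
#' geometry and stiffness, a single rooted tree without cycles, at most two
#' children per segment, exactly one Windkessel terminal on every leaf (and
#' none elsewhere), and resolvable named sites. Errors name the offending
#' element.
#'
#' @param net an `arterial_network`.
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  s <- net$segments
  need <- c("id", "name", "length", "proximal_radius", "distal_radius",
            "wall_stiffness", "viscoelastic_coeff", "region", "parent")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop_invalid("network schema: missing segment columns: ",
                                 paste(miss, collapse = ", "))
  if (anyDuplicated(s$id)) {
    stop_invalid("network schema: duplicated segment id: ",
                 s$id[duplicated(s$id)][1])
  }
  bad <- s$id[s$length <= 0 | s$proximal_radius <= 0 | s$distal_radius <= 0 |
                s$wall_stiffness <= 0]
  if (length(bad)) stop_invalid("segment ", bad[1],
                                ": length, radii and wall_stiffness must be > 0")
  bad <- s$id[s$viscoelastic_coeff < 0]
  if (length(bad)) stop_invalid("segment ", bad[1],
                                ": viscoelastic_coeff must be >= 0")
  bad <- s$id[!s$region %in% VESSEL_REGIONS]
  if (length(bad)) stop_invalid("segment ", bad[1], ": unknown region '",
                                s$region[s$id == bad[1]], "'")
  roots <- s$id[is.na(s$parent)]
  if (length(roots) != 1) {
    stop_invalid("network topology: expected exactly one root, found ",
                 length(roots))
  }
  orphan <- setdiff(s$parent[!is.na(s$parent)], s$id)
  if (length(orphan)) stop_invalid("network topology: unknown parent id '",
                                   orphan[1], "'")
  # cycle / reachability check by walking up from every segment
  idx <- match(s$parent, s$id)
  for (i in seq_len(nrow(s))) {
    seen <- integer(0)
    j <- i
    while (!is.na(idx[j])) {
      if (j %in% seen) stop_invalid("network topology: cycle through segment '",
                                    s$id[j], "'")
      seen <- c(seen, j)
      j <- idx[j]
    }
    if (s$id[j] != roots) stop_invalid("network topology: segment '", s$id[i],
                                       "' not connected to the root")
  }
  nchild <- table(factor(s$parent, levels = s$id))
  if (any(nchild > 2)) {
    stop_invalid("network topology: segment '",
                 names(nchild)[which(nchild > 2)[1]],
                 "' has more than two children")
  }
  leaves <- s$id[nchild[s$id] == 0]
  tr <- net$terminals
  need_t <- c("segment", "R1", "R2", "C", "venous_pressure")
  miss <- setdiff(need_t, names(tr))
  if (length(miss)) stop_invalid("network schema: missing terminal columns: ",
                                 paste(miss, collapse = ", "))
  if (anyDuplicated(tr$segment)) {
    stop_invalid("terminal duplicated on segment '",
                 tr$segment[duplicated(tr$segment)][1], "'")
  }
  no_term <- setdiff(leaves, tr$segment)
  if (length(no_term)) stop_invalid("leaf segment '", no_term[1],
                                    "' has no Windkessel terminal")
  not_leaf <- setdiff(tr$segment, leaves)
  if (length(not_leaf)) stop_invalid("terminal attached to non-leaf segment '",
                                     not_leaf[1], "'")
  bad <- tr$segment[tr$R1 <= 0 | tr$R2 <= 0 | tr$C <= 0]
  if (length(bad)) stop_invalid("terminal on '", bad[1],
                                "': R1, R2 and C must be > 0")
  ns <- net$named_sites
  miss <- setdiff(NAMED_SITES, ns$site)
  if (length(miss)) stop_invalid("named sites missing: ",
                                 paste(miss, collapse = ", "))
  bad <- ns$site[!ns$segment %in% s$id]
  if (length(bad)) stop_invalid("named site '", bad[1],
                                "' refers to unknown segment")
  bad <- ns$site[ns$position < 0 | ns$position > 1]
  if (length(bad)) stop_invalid("named site '", bad[1],
                                "' position outside [0, 1]")
  if (is.null(net$fluid$blood_density) || net$fluid$blood_density <= 0 ||
      is.null(net$fluid$blood_viscosity) || net$fluid$blood_viscosity <= 0) {
    stop_invalid("fluid constants must be positive")
  }
  invisible(net)
}

#' @export
print.arterial_network <- function(x, ...) {
  s <- x$segments
  cat("Arterial network:", nrow(s), "segments,", nrow(x$terminals),
      "Windkessel terminals\n")
  cat("  root:", network_root(x), " total length:",
      format(sum(s$length), digits = 4), "cm\n")
  cat("  regions:", paste(sprintf("%s (%d)", names(table(s$region)),
                                  as.integer(table(s$region))),
                          collapse = ", "), "\n")
  cat("  sites:", paste(x$named_sites$site, collapse = ", "), "\n")
  if (!is.null(x$reference)) {
    cat("  reference subject: height", x$reference$height, "cm, BSA",
        x$reference$bsa, "m^2, MAP/flow ratio",
        format(x$reference$ratio, digits = 4), "mmHg s/mL\n")
  }
  invisible(x)
}

#' @noRd
network_root <- function(net) net$segments$id[is.na(net$segments$parent)]

#' @noRd
network_children <- function(net, id) {
  net$segments$id[!is.na(net$segments$parent) & net$segments$parent == id]
}

#' @noRd
network_leaves <- function(net) {
  setdiff(net$segments$id, net$segments$parent[!is.na(net$segments$parent)])
}

#' Reference area profile of a segment
#'
#' Linear taper of radius between the proximal and distal ends gives
#' \eqn{A_0(x) = \pi r(x)^2}.
#'
#' @param seg one-row segment data.frame.
#' @param frac fractional positions along the segment in \[0, 1\].
#' @return reference areas (cm^2).
#' @export
segment_area0 <- function(seg, frac) {
  r <- seg$proximal_radius + (seg$distal_radius - seg$proximal_radius) * frac
  pi * r^2
}

#' Path length between two named sites
#'
#' Sum of segment lengths along the (unique) tree path between two named
#' sites, the in-silico analogue of the clinical transit distance used for
#' foot-to-foot PWV.
#'
#' @param net an `arterial_network`.
#' @param from,to site labels present in `net$named_sites`.
#' @return distance in cm.
#' @export
site_path_distance <- function(net, from, to) {
  ns <- net$named_sites
  a <- ns[ns$site == from, ]
  b <- ns[ns$site == to, ]
  if (nrow(a) != 1 || nrow(b) != 1) stop_invalid("unknown site label")
  s <- net$segments
  lineage <- function(id) {
    path <- id
    while (!is.na(s$parent[s$id == id])) {
      id <- s$parent[s$id == id]
      path <- c(path, id)
    }
    path
  }
  la <- lineage(a$segment)
  lb <- lineage(b$segment)
  common <- intersect(la, lb)
  anc <- common[1] # lineages are ordered leaf -> root
  up_a <- la[seq_len(match(anc, la))]
  up_b <- lb[seq_len(match(anc, lb))]
  seg_len <- function(id) s$length[s$id == id]
  dist_to_anc <- function(up, site_row) {
    if (length(up) == 1) return(NA_real_) # site lies on the ancestor itself
    d <- site_row$position * seg_len(site_row$segment)
    if (length(up) > 2) d <- d + sum(vapply(up[2:(length(up) - 1)], seg_len, 0))
    d
  }
  if (a$segment == anc && b$segment == anc) {
    return(abs(a$position - b$position) * seg_len(anc))
  }
  if (a$segment == anc) {
    return(dist_to_anc(up_b, b) + (1 - a$position) * seg_len(anc))
  }
  if (b$segment == anc) {
    return(dist_to_anc(up_a, a) + (1 - b$position) * seg_len(anc))
  }
  dist_to_anc(up_a, a) + dist_to_anc(up_b, b)
}

NETWORK_FORMAT <- "centralbp-arterial-network/1"

#' Read an arterial network from its structured-text (JSON) description
#'
#' The on-disk schema is versioned JSON holding fluid constants, the
#' reference-subject scalars, segment geometry/wall parameters, terminal
#' Windkessel parameters and the named sites. All [validate_network()]
#' invariants are enforced on load; a round trip through [save_network()]
#' is lossless.
#'
#' @param path file path.
#' @return an `arterial_network`.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop_invalid("network file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$format) || raw$format != NETWORK_FORMAT) {
    stop_invalid("unrecognized network file format header: ",
                 if (is.null(raw$format)) "<missing>" else raw$format)
  }
  seg <- raw$segments
  seg$parent[seg$parent == ""] <- NA_character_
  ref <- raw$reference
  if (!is.null(ref)) ref$regional_pwv <- as.list(ref$regional_pwv)
  arterial_network(seg, raw$terminals, raw$named_sites,
                   fluid = as.list(raw$fluid), reference = ref)
}

#' Write an arterial network to its structured-text (JSON) description
#'
#' @param net an `arterial_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @rdname load_network
#' @export
save_network <- function(net, path) {
  validate_network(net)
  seg <- net$segments
  seg$parent[is.na(seg$parent)] <- ""
  payload <- list(
    format = NETWORK_FORMAT,
    fluid = net$fluid,
    reference = net$reference,
    segments = seg,
    terminals = net$terminals,
    named_sites = net$named_sites
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' The shipped averaged-adult reference network
#'
#' Loads the package's default 56-segment large-artery tree (a classic
#' averaged-adult topology: aorta, arm, head and leg paths plus the main
#' visceral branches), with wall stiffness set from region-wise reference
#' pulse wave velocities and Windkessel terminals calibrated to a reference
#' mean pressure/flow working point. This tree is the package's own
#' representative description of a healthy young adult, and it is the
#' starting point the subject-specific setting procedure rescales.
#'
#' @return an `arterial_network`.
#' @export
default_network <- function() {
  load_network(system.file("extdata", "adult_reference_network.json",
                           package = "centralbp", mustWork = TRUE))
}
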