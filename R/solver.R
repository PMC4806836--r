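#' Simulation configuration
#'
#' Numerical settings for [simulate_network()].
#'
#' @param cfl_number Courant number of the explicit two-step Lax--Wendroff
#'   scheme, in (0, 1).
#' @param max_cycles maximum number of cardiac cycles to run while seeking
#'   periodic steady state.
#' @param convergence_tol cycle-to-cycle convergence tolerance (mmHg): the
#'   maximum absolute difference between consecutive cycles' aortic-root
#'   pressure traces.
#' @param spatial_resolution target grid spacing (cm); every segment gets at
#'   least 4 nodes.
#' @param output_sites site labels to record (default: all six named sites).
#' @param output_sampling output sampling rate (Hz) for returned waveforms.
#' @param init_pressure initial pressure everywhere (mmHg); flow starts at
#'   zero and the run proceeds to periodicity, so this only affects how many
#'   cycles convergence takes.
#' @return a `sim_config` list.
#' @export
sim_config <- function(cfl_number = 0.9, max_cycles = 20,
                       convergence_tol = 0.5, spatial_resolution = 0.25,
                       output_sites = NAMED_SITES, output_sampling = 1000,
                       init_pressure = 70) {
  if (!(cfl_number > 0 && cfl_number < 1)) {
    stop_invalid("sim_config: cfl_number must be in (0, 1)")
  }
  if (convergence_tol <= 0) stop_invalid("sim_config: convergence_tol must be > 0")
  if (spatial_resolution <= 0) stop_invalid("sim_config: spatial_resolution must be > 0")
  structure(list(cfl_number = cfl_number, max_cycles = max_cycles,
                 convergence_tol = convergence_tol,
                 spatial_resolution = spatial_resolution,
                 output_sites = output_sites,
                 output_sampling = output_sampling,
                 init_pressure = init_pressure),
            class = "sim_config")
}

# Topologically ordered segment indices (root first, parents before children)
#' @noRd
topo_order <- function(net) {
  s <- net$segments
  order_ids <- character(0)
  queue <- network_root(net)
  while (length(queue)) {
    id <- queue[1]
    queue <- queue[-1]
    order_ids <- c(order_ids, id)
    queue <- c(queue, network_children(net, id))
  }
  match(order_ids, s$id)
}

# Discretize the network into the CGS arrays the C++ core consumes.
#' @noRd
compile_model <- function(net, dx_target) {
  ord <- topo_order(net)
  s <- net$segments[ord, , drop = FALSE]
  idx_of <- stats::setNames(seq_len(nrow(s)), s$id)
  rho <- rho_to_cgs(net$fluid$blood_density)
  mu <- mu_to_cgs(net$fluid$blood_viscosity)
  segs <- vector("list", nrow(s))
  for (k in seq_len(nrow(s))) {
    L <- s$length[k]
    n <- max(4L, as.integer(round(L / dx_target)) + 1L)
    dx <- L / (n - 1)
    fr <- seq(0, 1, length.out = n)
    frh <- (fr[-n] + fr[-1]) / 2
    rp <- s$proximal_radius[k]
    rd <- s$distal_radius[k]
    drdx <- (rd - rp) / L
    r <- rp + (rd - rp) * fr
    rh <- rp + (rd - rp) * frh
    segs[[k]] <- list(
      n = n, dx = dx,
      beta = beta_to_cgs(s$wall_stiffness[k]),
      gamma = gamma_to_cgs(s$viscoelastic_coeff[k]),
      A0 = pi * r^2, dA0 = 2 * pi * r * drdx,
      A0h = pi * rh^2, dA0h = 2 * pi * rh * drdx,
      parent = if (is.na(s$parent[k])) -1L else idx_of[[s$parent[k]]] - 1L
    )
  }
  juncs <- list()
  for (k in seq_len(nrow(s))) {
    ch <- network_children(net, s$id[k])
    if (length(ch)) {
      juncs[[length(juncs) + 1L]] <-
        as.integer(c(k - 1L, idx_of[ch[1]] - 1L,
                     if (length(ch) > 1) idx_of[ch[2]] - 1L else -1L))
    }
  }
  tr <- net$terminals
  terms <- lapply(seq_len(nrow(tr)), function(i) {
    c(idx_of[[tr$segment[i]]] - 1L,
      res_to_cgs(tr$R1[i]), res_to_cgs(tr$R2[i]),
      cap_to_cgs(tr$C[i]), mmHg_to_cgs(tr$venous_pressure[i]))
  })
  list(model = list(segments = segs, junctions = juncs, terminals = terms,
                    rho = rho, mu = mu),
       idx_of = idx_of, seg_n = vapply(segs, function(x) x$n, 0L))
}

#' @noRd
site_nodes <- function(net, compiled, sites) {
  ns <- net$named_sites
  seg <- integer(length(sites))
  node <- integer(length(sites))
  for (i in seq_along(sites)) {
    row <- ns[ns$site == sites[i], ]
    if (nrow(row) != 1) stop_invalid("unknown output site '", sites[i], "'")
    k <- compiled$idx_of[[row$segment]]
    n <- compiled$seg_n[k]
    seg[i] <- k - 1L
    node[i] <- as.integer(round(row$position * (n - 1)))
  }
  list(seg = seg, node = node)
}

#' Simulate pulse propagation over an arterial network
#'
#' Solves the 1D blood-flow equations over the whole tree, coupled at the
#' root either to the lumped elastance heart (`cardiac`) or to a prescribed
#' inflow waveform (`inflow`), and at every leaf to its RCR Windkessel load.
#' With a heart the run repeats cardiac cycles until the aortic-root
#' pressure trace is periodic to within `convergence_tol` (or `max_cycles`
#' is hit); the returned waveforms are the last full cycle.
#'
#' @param network an [arterial_network()].
#' @param cardiac a [cardiac_params()] object (heart-driven inlet).
#' @param config a [sim_config()].
#' @param inflow optional prescribed inlet flow instead of the heart: a list
#'   with `flow` (mL/s samples), `dt` (s between samples) and `duration`
#'   (s, total simulated time).
#' @return object of class `centralbp_sim`: per-site one-cycle waveforms
#'   (`$waveforms`, each a data.frame with time/pressure/flow/area),
#'   convergence info, simulated EDV/ESV/SV, and mass-balance diagnostics.
#' @export
simulate_network <- function(network, cardiac = NULL, config = sim_config(),
                             inflow = NULL) {
  validate_network(network)
  compiled <- compile_model(network, config$spatial_resolution)
  sn <- site_nodes(network, compiled, config$output_sites)
  if (!is.null(inflow)) {
    inlet <- list(mode = 1L, period = inflow$duration,
                  flow = inflow$flow, flow_dt = inflow$dt)
    max_cycles <- 1L
  } else {
    if (is.null(cardiac)) stop_invalid("either cardiac or inflow is required")
    inlet <- list(
      mode = 0L, period = cardiac$period,
      Emax = mmHg_to_cgs(cardiac$E_max), Emin = mmHg_to_cgs(cardiac$E_min),
      V0 = cardiac$V0, tact = cardiac$activation_time,
      ppre = mmHg_to_cgs(cardiac$preload_pressure),
      Rav = res_to_cgs(cardiac$valve_resistance),
      Lav = res_to_cgs(cardiac$valve_inertance),
      Rmit = res_to_cgs(cardiac$mitral_resistance),
      h_t1 = cardiac$shape[["t1"]], h_n1 = cardiac$shape[["n1"]],
      h_t2 = cardiac$shape[["t2"]], h_n2 = cardiac$shape[["n2"]]
    )
    max_cycles <- config$max_cycles
  }
  raw <- run_simulation_cpp(
    compiled$model, inlet,
    list(cfl = config$cfl_number, max_cycles = as.integer(max_cycles),
         tol = mmHg_to_cgs(config$convergence_tol),
         p_init = mmHg_to_cgs(config$init_pressure),
         site_seg = as.integer(sn$seg), site_node = as.integer(sn$node))
  )
  period <- inlet$period
  n_out <- max(50L, as.integer(round(config$output_sampling * period)))
  t_out <- seq(period / n_out, period, length.out = n_out)
  waveforms <- stats::setNames(vector("list", length(config$output_sites)),
                               config$output_sites)
  for (j in seq_along(config$output_sites)) {
    wf <- data.frame(
      time = t_out,
      pressure = stats::approx(raw$time, raw$pressure[, j], t_out, rule = 2)$y,
      flow = stats::approx(raw$time, raw$flow[, j], t_out, rule = 2)$y,
      area = stats::approx(raw$time, raw$area[, j], t_out, rule = 2)$y
    )
    attr(wf, "site") <- config$output_sites[j]
    class(wf) <- c("site_waveform", "data.frame")
    waveforms[[j]] <- wf
  }
  structure(list(
    waveforms = waveforms,
    cycles_run = raw$cycles,
    converged = isTRUE(raw$converged),
    cycle_residual = raw$residual,
    residual_history = raw$residual_history,
    edv = raw$edv, esv = raw$esv,
    sv = if (!is.null(raw$edv) && is.finite(raw$edv)) raw$edv - raw$esv else NA_real_,
    inlet_volume = raw$inlet_volume,
    terminal_volumes = raw$terminal_volumes,
    junction_residual = raw$junction_residual,
    courant_max = raw$courant_max,
    dt = raw$dt,
    period = period,
    root_pressure = data.frame(time = raw$time, pressure = raw$root_pressure),
    volume_trace = raw$volume_trace,
    inflow_trace = raw$inflow_trace,
    config = config
  ), class = "centralbp_sim")
}

#' @export
print.centralbp_sim <- function(x, ...) {
  cat("1D haemodynamic simulation:", x$cycles_run, "cycles,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(cycle residual %.3g mmHg, tol %.3g)\n",
              x$cycle_residual, x$config$convergence_tol))
  if (is.finite(x$edv)) {
    cat(sprintf("  LV: EDV %.1f mL, ESV %.1f mL, SV %.1f mL\n",
                x$edv, x$esv, x$sv))
  }
  root <- x$waveforms[["aortic_root"]]
  if (!is.null(root)) {
    cat(sprintf("  aortic root: %.1f/%.1f mmHg (mean %.1f)\n",
                max(root$pressure), min(root$pressure), mean(root$pressure)))
  }
  invisible(x)
}

#' @export
plot.centralbp_sim <- function(x, sites = names(x$waveforms), ...) {
  cols <- grDevices::hcl.colors(length(sites), "Dark 3")
  rng <- range(unlist(lapply(x$waveforms[sites], function(w) w$pressure)))
  graphics::plot(NA, xlim = c(0, x$period), ylim = rng,
                 xlab = "time (s)", ylab = "pressure (mmHg)", ...)
  for (i in seq_along(sites)) {
    w <- x$waveforms[[sites[i]]]
    graphics::lines(w$time, w$pressure, col = cols[i])
  }
  graphics::legend("topright", legend = sites, col = cols, lty = 1, cex = 0.7,
                   bty = "n")
  invisible(x)
}

#' Cycle-to-cycle convergence check
#'
#' Residual between consecutive cycles of aligned aortic-root pressure
#' traces: the maximum absolute pointwise difference between the last two
#' cycles, compared against a tolerance.
#'
#' @param history a matrix (cycles in rows) or list of equal-length numeric
#'   vectors of per-cycle root-pressure traces (mmHg).
#' @param tol tolerance (mmHg).
#' @return list with `converged` flag and `residual` (mmHg).
#' @export
check_convergence <- function(history, tol) {
  if (is.list(history)) history <- do.call(rbind, history)
  if (!is.matrix(history) || nrow(history) < 2) {
    stop_invalid("check_convergence: need at least 2 cycles")
  }
  m <- nrow(history)
  residual <- max(abs(history[m, ] - history[m - 1, ]))
  list(converged = residual <= tol, residual = residual)
}

#' Write a site waveform to CSV
#'
#' Plain CSV with columns time (s), pressure (mmHg), flow (mL/s),
#' area (cm^2) and a comment header naming the site.
#'
#' @param waveform a `site_waveform` (one entry of a simulation's
#'   `$waveforms`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# site: %s", attr(waveform, "site")), con)
  writeLines("# columns: time_s,pressure_mmHg,flow_mL_s,area_cm2", con)
  utils::write.table(as.data.frame(waveform), con, sep = ",",
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}
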