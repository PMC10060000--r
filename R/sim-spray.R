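#' Spray and solvent-film model
#'
#' Parameters of the DESI spray plume and of the solvent film it maintains on
#' the tissue surface. The film volume density `V` (arbitrary volume units
#' per unit area) obeys `dV/dt = solvent_in - k_removal * V`: solvent is
#' delivered by the primary spray and carried off in secondary droplets.
#' Dissolution only proceeds once the film exceeds the wetting threshold
#' `v_wet` (tissue rehydration), with Michaelis-type enhancement
#' `s(V) = max(0, V - v_wet) / (k_sat + max(0, V - v_wet))`.
#'
#' Defaults were calibrated once, jointly with the class-default dissolution
#' rates, so that a dry tissue spot wets after about 0.5 s and the fast- and
#' slow-dissolving analyte classes peak in the published 1-2 s and 2-3 s
#' windows; they are frozen constants of the package.
#'
#' @param footprint_um Effective spray footprint diameter (um).
#' @param solvent_in Solvent delivery flux (volume units / s).
#' @param k_removal Removal rate into secondary droplets (1/s).
#' @param v_wet Wetting threshold (volume units).
#' @param k_sat Half-saturation of the dissolution enhancement (volume units).
#' @return An object of class `spray_model`.
#' @export
#' @examples
#' spray_model()
spray_model <- function(footprint_um = 150, solvent_in = 1.0,
                        k_removal = 0.25, v_wet = 0.5, k_sat = 1.6) {
  for (nm in c("footprint_um", "solvent_in", "k_removal", "v_wet", "k_sat")) {
    assert_scalar_num(get(nm), nm, positive = TRUE)
  }
  structure(list(footprint_um = footprint_um, solvent_in = solvent_in,
                 k_removal = k_removal, v_wet = v_wet, k_sat = k_sat),
            class = "spray_model")
}

#' @export
print.spray_model <- function(x, ...) {
  cat(sprintf(
    "<spray_model> footprint %g um | in %g /s, removal %g /s | wet %g, sat %g\n",
    x$footprint_um, x$solvent_in, x$k_removal, x$v_wet, x$k_sat))
  invisible(x)
}

# film volume at time t after spray-on over dry tissue (V(0) = 0)
solvent_film <- function(spray, t) {
  vinf <- spray$solvent_in / spray$k_removal
  vinf * (1 - exp(-spray$k_removal * t))
}

# dissolution enhancement s(V) in [0, 1)
dissolution_s <- function(spray, v) {
  u <- pmax(0, v - spray$v_wet)
  u / (spray$k_sat + u)
}

#' Per-analyte desorption/ionization kinetics
#'
#' One row per transition: the dissolution rate constant `k_diss` (1/s, how
#' fast surface analyte enters the solvent film once the film is wet), the
#' droplet transfer rate `k_des` (1/s, dissolved analyte carried into
#' secondary droplets), the ionization efficiency `eta` (detected counts per
#' amount desorbed) and the charge-competition weight `w_charge`.
#'
#' Class defaults encode the published contrast between fast "drug-like" and
#' slow "lipid-like" dissolution: `k_diss` 3.0/s for drugs, 0.8/s for lipids,
#' 1.5/s otherwise. These constants are frozen (see [spray_model()]).
#'
#' @param transitions A transition tibble ([transition_table()]).
#' @param k_diss Optional vector overriding the class-default dissolution
#'   rates (1/s).
#' @param k_des Droplet transfer rate (1/s).
#' @param eta Ionization efficiency (counts per amount).
#' @param w_charge Charge-competition weight.
#' @return A tibble with one kinetics row per transition.
#' @export
#' @examples
#' kinetics_table(demo_transitions())
kinetics_table <- function(transitions, k_diss = NULL, k_des = 5,
                           eta = 1e4, w_charge = 1) {
  tr <- validate_transitions(transitions)
  if (is.null(k_diss)) {
    k_diss <- c(drug = 3.0, lipid = 0.8, other = 1.5)[tr$analyte_class]
  }
  kt <- tibble(
    transition_id = tr$id, analyte = tr$analyte,
    analyte_class = tr$analyte_class,
    k_diss = as.numeric(k_diss), k_des = as.numeric(k_des),
    eta = as.numeric(eta), w_charge = as.numeric(w_charge)
  )
  if (any(!is.finite(kt$k_diss)) || any(kt$k_diss <= 0) ||
      any(kt$k_des <= 0)) {
    abort("kinetic rates must be finite and > 0")
  }
  if (any(kt$eta < 0) || any(!is.finite(kt$eta))) abort("eta must be >= 0")
  kt
}

# default integration step: 1 ms, refined if dwell windows are shorter
default_dt <- function(config, dt_s) {
  min_dwell <- min(config$transitions$dwell_ms) / 1000
  if (is.null(dt_s)) return(min(0.001, min_dwell / 4))
  assert_scalar_num(dt_s, "dt_s", positive = TRUE)
  if (dt_s > min_dwell / 4) {
    warn(sprintf(
      "integration step %.4g s is coarser than dwell/4 = %.4g s", dt_s,
      min_dwell / 4))
  }
  dt_s
}

# dwell-window start offsets (s) of each transition within a scan cycle
cycle_offsets <- function(config) {
  dw <- config$transitions$dwell_ms / 1000
  it <- config$inter_transition_ms / 1000
  c(0, cumsum(dw + it))[seq_along(dw)]
}

# Exponential operator-splitting recursion for the dissolved pools.
# delta_a: n_steps x n_analytes matrix of per-step dissolved amounts.
# Returns list(out = per-step droplet outflow, d_end = pool at end).
droplet_transfer <- function(delta_a, k_des, dt) {
  a <- exp(-k_des * dt)
  out <- matrix(0, nrow(delta_a), ncol(delta_a))
  for (j in seq_len(ncol(delta_a))) {
    e <- stats::filter(delta_a[, j], a[j], method = "recursive")
    out[, j] <- as.numeric(e) * (1 - a[j])
  }
  list(out = out,
       d_end = colSums(delta_a) - colSums(out))
}

# charge competition: shared ion budget i_max (counts/s); detected_i =
# raw_i * min(1, i_max / sum_j w_j raw_j)
apply_competition <- function(raw, w, i_max) {
  if (!is.finite(i_max)) return(raw)
  tot <- as.numeric(raw %*% w)
  f <- ifelse(tot > 0, pmin(1, i_max / tot), 1)
  raw * f
}

# integrate per-step detected rates (counts/s) into per-scan counts over the
# dwell windows of each transition; returns list(counts = n_scans x n_tr,
# times = scan-relative times of window centers)
bin_scans <- function(rate, t_mid, dt, config, n_scans) {
  period <- scan_period_s(config)
  offs <- cycle_offsets(config)
  dw <- config$transitions$dwell_ms / 1000
  cyc <- floor(t_mid / period)
  tau <- t_mid - cyc * period
  n_tr <- nrow(config$transitions)
  counts <- matrix(0, n_scans, n_tr)
  keep <- cyc >= 0 & cyc < n_scans
  for (i in seq_len(n_tr)) {
    m <- keep & tau >= offs[i] & tau < offs[i] + dw[i]
    if (any(m)) {
      agg <- rowsum(rate[m, i] * dt, group = cyc[m])
      counts[as.integer(rownames(agg)) + 1L, i] <- agg[, 1]
    }
  }
  times <- outer(seq_len(n_scans) - 1L, offs + dw / 2,
                 function(c, o) c * period + o)
  list(counts = counts, times = times)
}

#' Simulate a static-spray desorption kinetics experiment
#'
#' Holds the spray over one tissue spot and records MRM chronograms, as in a
#' desorption-kinetics experiment: the trace shows a wetting delay, a rise
#' with slope set by the analyte's dissolution rate, a plateau, and a decline
#' as the spot depletes. The solvent film, surface amounts and dissolved
#' pools are advanced with a fixed-step (default 1 ms) exponential
#' operator-splitting scheme whose sub-steps are exact, so mass is conserved
#' to machine precision.
#'
#' @param spray A [spray_model()].
#' @param kinetics A [kinetics_table()] matching `config`'s transitions.
#' @param config An [acquisition_config()]; supplies the scan cycle timing.
#' @param duration_s Length of the experiment (s).
#' @param amounts Initial surface amount per analyte (single value or vector
#'   named by transition id).
#' @param noise If `TRUE`, per-scan counts are Poisson draws.
#' @param i_max Shared ion budget for charge competition (counts/s);
#'   `Inf` disables competition.
#' @param seed Master seed; only the `"noise"` substream is consumed here.
#' @param dt_s Integration step (s); default `min(1 ms, dwell/4)`.
#' @return A [line_scan_set()] with a single line (index 0) and, in attribute
#'   `"sim_state"`, the dense per-step state (film, amounts, pools, rates)
#'   for diagnostics.
#' @export
#' @examples
#' cfg <- acquisition_config(demo_transitions(dwell_ms = 3),
#'                           inter_transition_ms = 3.25)
#' sim <- simulate_static(spray_model(), kinetics_table(cfg$transitions), cfg,
#'                        duration_s = 6)
#' head(as_tibble(sim))
simulate_static <- function(spray, kinetics, config, duration_s = 10,
                            amounts = 1, noise = FALSE, i_max = Inf,
                            seed = 1L, dt_s = NULL) {
  stopifnot(inherits(spray, "spray_model"), inherits(config, "acq_config"))
  kin <- check_kinetics(kinetics, config)
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  dt <- default_dt(config, dt_s)
  a0 <- analyte_amounts(amounts, kin$transition_id)

  n <- max(1L, ceiling(duration_s / dt))
  t_mid <- (seq_len(n) - 0.5) * dt
  s_mid <- dissolution_s(spray, solvent_film(spray, t_mid))
  s_cum <- c(0, cumsum(s_mid * dt))

  # remaining surface amount: A_i(t) = A0 * exp(-k_diss * integral of s)
  a_rem <- outer(s_cum, kin$k_diss, function(s, k) exp(-k * s))
  a_rem <- sweep(a_rem, 2, a0, `*`)
  delta_a <- a_rem[-nrow(a_rem), , drop = FALSE] -
    a_rem[-1, , drop = FALSE]

  tr <- droplet_transfer(delta_a, kin$k_des, dt)
  raw <- sweep(tr$out / dt, 2, kin$eta, `*`)
  detected <- apply_competition(raw, kin$w_charge, i_max)

  n_scans <- max(1L, floor(duration_s / scan_period_s(config)))
  sc <- bin_scans(detected, t_mid, dt, config, n_scans)
  counts <- sc$counts
  if (noise) {
    counts <- with_substream(seed, "noise", {
      matrix(rpois(length(counts), counts), nrow(counts), ncol(counts))
    })
  }

  data <- tibble(
    line_index = 0L,
    transition_id = rep(kin$transition_id, each = n_scans),
    scan_index = rep(seq_len(n_scans) - 1L, times = nrow(kin)),
    time_s = as.numeric(sc$times),
    intensity = as.numeric(counts)
  )
  out <- line_scan_set(config, data,
                       metadata = list(mode = "static", seed = seed))
  attr(out, "sim_state") <- list(
    time_s = t_mid, film = solvent_film(spray, t_mid), s = s_mid,
    a_rem = a_rem[-1, , drop = FALSE], detected_rate = detected,
    desorbed = apply(tr$out, 2, cumsum),
    dissolved = apply(delta_a - tr$out, 2, cumsum),
    initial = a0, transition_id = kin$transition_id)
  out
}

check_kinetics <- function(kinetics, config) {
  kin <- as_tibble(kinetics)
  need <- c("transition_id", "k_diss", "k_des", "eta", "w_charge")
  miss <- setdiff(need, names(kin))
  if (length(miss)) abort(paste("kinetics table missing columns:",
                                paste(miss, collapse = ", ")))
  if (!all(is.finite(kin$k_diss)) || !all(is.finite(kin$k_des)) ||
      !all(is.finite(kin$eta))) {
    abort("kinetic parameters must be finite")
  }
  ids <- config$transitions$id
  if (!setequal(kin$transition_id, ids)) {
    abort("kinetics table must cover exactly the config's transitions")
  }
  kin[match(ids, kin$transition_id), ]
}

analyte_amounts <- function(amounts, ids) {
  if (length(amounts) == 1L && is.null(names(amounts))) {
    a0 <- rep(as.numeric(amounts), length(ids))
  } else {
    if (is.null(names(amounts)) || !all(ids %in% names(amounts))) {
      abort("`amounts` must be a single value or named by transition id")
    }
    a0 <- as.numeric(amounts[ids])
  }
  if (any(a0 < 0)) abort("amounts must be non-negative")
  a0
}
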