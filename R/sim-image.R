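#' Simulate a line-scan DESI-MRM imaging acquisition
#'
#' Moves the spray footprint (uniform disc) along each line at the stage
#' speed. The solvent film builds from dry tissue at every line start and is
#' carried with the sprayer; tissue cells under the disc lose surface analyte
#' at `k_diss * s(V)`, feeding per-analyte dissolved pools that transfer into
#' secondary droplets at `k_des`. Depletion persists across lines, so a
#' footprint wider than the line spacing re-samples partially exhausted
#' tissue (cross-line bleed). Detected rates are integrated over each
#' transition's dwell window to per-scan counts.
#'
#' Line-to-line jitter is modelled as a de-synchronization between stage
#' motion and acquisition start: each line's recorded scan window is shifted
#' by an integer pixel offset drawn uniformly from
#' `{-jitter_px_max, ..., +jitter_px_max}`. Ground-truth images record the
#' noiseless, jitter-free expected signal (counts/s).
#'
#' @inheritParams simulate_static
#' @param tissue A [tissue_model()]; `surface_amount` entries are matched to
#'   transition ids by name (unmatched transitions see zero amount).
#' @param config An [acquisition_config()]; geometry and timing of the run.
#' @param jitter_px_max Maximum absolute line-start jitter (pixels).
#' @return An object of class `sim_result`: `lineset` ([line_scan_set()]),
#'   `truth_images` (named list of [ion_image()]), `injected_jitter_px`,
#'   `labels` (region label matrix at pixel resolution), `mass`
#'   (per-analyte balance tibble) and `seed`.
#' @export
#' @examples
#' ph <- make_phantom("tumor_stroma",
#'                    params = list(width_um = 1200, height_um = 500),
#'                    seed = 1)
#' tr <- transition_table(id = c("pc341", "pc364"),
#'                        analyte_class = "lipid",
#'                        precursor_mz = c(760.6, 782.6), product_mz = 184.1,
#'                        dwell_ms = 9)
#' cfg <- acquisition_config(tr, stage_speed_um_s = 500,
#'                           line_spacing_um = 100, line_length_um = 1200,
#'                           n_lines = 5)
#' res <- simulate_image(spray_model(), kinetics_table(tr), ph, cfg,
#'                       jitter_px_max = 2, seed = 3)
#' res$injected_jitter_px
simulate_image <- function(spray, kinetics, tissue, config,
                           jitter_px_max = 0, noise = FALSE, i_max = Inf,
                           seed = 1L, dt_s = NULL) {
  stopifnot(inherits(spray, "spray_model"), inherits(tissue, "tissue_model"),
            inherits(config, "acq_config"))
  kin <- check_kinetics(kinetics, config)
  jpm <- as.integer(jitter_px_max)
  if (jpm < 0) abort("jitter_px_max must be >= 0")
  dt <- default_dt(config, dt_s)

  g <- tissue$grid_um
  dims <- dim(tissue$tissue_mask)
  if (dims[1] * g < config$n_lines * config$line_spacing_um ||
      dims[2] * g < config$line_length_um) {
    abort(sprintf(
      "tissue too small: %g x %g um for %d lines x %g um at %g um spacing",
      dims[2] * g, dims[1] * g, config$n_lines, config$line_length_um,
      config$line_spacing_um))
  }
  if (spray$footprint_um > config$line_spacing_um) {
    warn("spray footprint exceeds line spacing; cross-line bleed simulated")
  }

  ids <- kin$transition_id
  n_k <- length(ids)
  cell_area <- g^2
  # amount per cell, depleted in place as lines are scanned
  amt <- lapply(ids, function(id) {
    m <- tissue$surface_amount[[id]]
    if (is.null(m)) matrix(0, dims[1], dims[2]) else m * cell_area
  })
  names(amt) <- ids
  initial <- vapply(amt, sum, numeric(1))

  r <- spray$footprint_um / 2
  v <- config$stage_speed_um_s
  period <- scan_period_s(config)
  pw <- pixel_width_um(config)
  n_px <- scans_per_line(config)
  n_ext <- n_px + 2L * jpm
  t_line <- n_ext * period
  n_steps <- ceiling(t_line / dt)
  t_mid <- (seq_len(n_steps) - 0.5) * dt
  s_mid <- dissolution_s(spray, solvent_film(spray, t_mid))
  s_cum <- c(0, cumsum(s_mid * dt))
  x0 <- -jpm * pw
  xc_cells <- (seq_len(dims[2]) - 0.5) * g
  yc_cells <- (seq_len(dims[1]) - 0.5) * g

  offsets <- if (jpm > 0) {
    with_substream(seed, "jitter",
                   sample(seq(-jpm, jpm), config$n_lines, replace = TRUE))
  } else rep(0L, config$n_lines)

  truth <- lapply(ids, function(id) matrix(NA_real_, config$n_lines, n_px))
  names(truth) <- ids
  rows_out <- vector("list", config$n_lines)
  desorbed <- numeric(n_k)
  residual <- numeric(n_k)
  dw_s <- config$transitions$dwell_ms / 1000

  for (l in seq_len(config$n_lines)) {
    y_l <- (l - 0.5) * config$line_spacing_um
    band <- which(abs(yc_cells - y_l) <= r)
    delta_a <- matrix(0, n_steps, n_k)
    for (i in band) {
      hw <- sqrt(max(0, r^2 - (yc_cells[i] - y_l)^2))
      t_in <- (xc_cells - hw - x0) / v
      t_out <- (xc_cells + hw - x0) / v
      cols <- which(t_out > 0 & t_in < t_line)
      for (j in cols) {
        b1 <- max(1L, floor(max(0, t_in[j]) / dt) + 1L)
        b2 <- min(n_steps, ceiling(min(t_line, t_out[j]) / dt))
        if (b2 < b1) next
        seg <- b1:b2
        s0 <- s_cum[b1]
        ds <- s_cum[seg + 1L] - s0
        for (k in seq_len(n_k)) {
          a_c <- amt[[k]][i, j]
          if (a_c <= 0) next
          rem <- exp(-kin$k_diss[k] * ds)
          prev <- c(1, rem[-length(rem)])
          delta_a[seg, k] <- delta_a[seg, k] + a_c * (prev - rem)
          amt[[k]][i, j] <- a_c * rem[length(rem)]
        }
      }
    }
    tr <- droplet_transfer(delta_a, kin$k_des, dt)
    raw <- sweep(tr$out / dt, 2, kin$eta, `*`)
    detected <- apply_competition(raw, kin$w_charge, i_max)
    sc <- bin_scans(detected, t_mid, dt, config, n_ext)
    desorbed <- desorbed + colSums(tr$out)
    residual <- residual + tr$d_end

    central <- jpm + seq_len(n_px)
    for (k in seq_len(n_k)) {
      truth[[k]][l, ] <- sc$counts[central, k] / dw_s[k]
    }
    rec_idx <- central - offsets[l]
    counts_rec <- sc$counts[rec_idx, , drop = FALSE]
    rows_out[[l]] <- tibble(
      line_index = l - 1L,
      transition_id = rep(ids, each = n_px),
      scan_index = rep(seq_len(n_px) - 1L, times = n_k),
      time_s = as.numeric(outer(seq_len(n_px) - 1L,
                                cycle_offsets(config) + dw_s / 2,
                                function(c, o) c * period + o)),
      intensity = as.numeric(counts_rec)
    )
  }

  data <- bind_rows(rows_out)
  if (noise) {
    data$intensity <- with_substream(seed, "noise",
                                     rpois(nrow(data), data$intensity))
  }
  lineset <- line_scan_set(config, data,
                           metadata = list(mode = "image", seed = seed))

  truth_images <- lapply(ids, function(id) {
    ion_image(id, truth[[id]], pixel_w_um = pw,
              pixel_h_um = config$line_spacing_um)
  })
  names(truth_images) <- ids

  labels <- matrix(0L, config$n_lines, n_px)
  for (l in seq_len(config$n_lines)) {
    ri <- pmin(dims[1], pmax(1L, ceiling((l - 0.5) *
                                           config$line_spacing_um / g)))
    ci <- pmin(dims[2], pmax(1L, ceiling(((seq_len(n_px) - 0.5) * pw) / g)))
    labels[l, ] <- tissue$region_labels[ri, ci]
  }

  remaining <- vapply(amt, sum, numeric(1))
  mass <- tibble(transition_id = ids, initial = initial,
                 remaining = remaining, desorbed = desorbed,
                 dissolved_residual = residual)

  structure(list(lineset = lineset, truth_images = truth_images,
                 injected_jitter_px = as.integer(offsets), labels = labels,
                 mass = mass, seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %d lines x %d px, %d transitions | jitter in [%d, %d] px\n",
    nrow(x$labels), ncol(x$labels), length(x$truth_images),
    min(x$injected_jitter_px), max(x$injected_jitter_px)))
  invisible(x)
}
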