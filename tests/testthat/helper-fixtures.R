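# shared fixture builders; everything is generated in code

# two-transition (one drug-like, one lipid-like) method cycling at 10 scans/s
two_transition_config <- function(dwell_ms = 3, speed = 100, n_lines = 2,
                                  line_length_um = 1000,
                                  line_spacing_um = 100) {
  tr <- transition_table(
    id = c("drug", "lip"), analyte_class = c("drug", "lipid"),
    precursor_mz = c(472.3, 760.6), product_mz = c(436.3, 184.1),
    dwell_ms = dwell_ms)
  acquisition_config(tr, inter_transition_ms = (100 - 2 * dwell_ms) / 2,
                     stage_speed_um_s = speed, n_lines = n_lines,
                     line_length_um = line_length_um,
                     line_spacing_um = line_spacing_um)
}

# a small valid line-scan set with deterministic pseudo-data
toy_lineset <- function(config = two_transition_config(), n_scans = 8) {
  period <- scan_period_s(config)
  grid <- expand.grid(line_index = seq_len(config$n_lines) - 1L,
                      transition_id = config$transitions$id,
                      scan_index = seq_len(n_scans) - 1L,
                      stringsAsFactors = FALSE)
  grid$time_s <- grid$scan_index * period +
    ifelse(grid$transition_id == "drug", 0.001, 0.005)
  grid$intensity <- round(100 * abs(sin(seq_len(nrow(grid)))), 3)
  line_scan_set(config, grid)
}

# uniform rectangular tissue with the given per-transition densities
flat_tissue <- function(height_um, width_um, grid_um, densities) {
  nr <- round(height_um / grid_um); nc <- round(width_um / grid_um)
  tissue_model(grid_um,
               lapply(densities, function(d) matrix(d, nr, nc)),
               matrix(TRUE, nr, nc))
}

# mean on-tissue truth signal over a quasi-steady interior window
interior_mean <- function(res, id, config, x_min, x_max) {
  g <- res$truth_images[[id]]$grid[1, ]
  x <- (seq_along(g) - 0.5) * pixel_width_um(config)
  mean(g[x > x_min & x < x_max])
}
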