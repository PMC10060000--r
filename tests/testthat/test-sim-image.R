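test_that("jitter-free noise-free reconstruction equals the truth exactly", {
  ph <- make_phantom("tumor_stroma",
                     params = list(width_um = 1200, height_um = 500,
                                   grid_um = 50), seed = 1)
  tr <- transition_table(id = c("pc341", "pc364"), analyte_class = "lipid",
                         precursor_mz = c(760.6, 782.6), product_mz = 184.1,
                         dwell_ms = 9)
  cfg <- acquisition_config(tr, stage_speed_um_s = 500,
                            line_spacing_um = 100, line_length_um = 1200,
                            n_lines = 5)
  res <- suppressWarnings(
    simulate_image(spray_model(), kinetics_table(tr), ph, cfg, seed = 2))
  imgs <- reconstruct(res$lineset)
  for (id in names(imgs)) {
    expect_identical(dim(imgs[[id]]$grid), dim(res$truth_images[[id]]$grid))
    expect_equal(imgs[[id]]$grid, res$truth_images[[id]]$grid)
  }
  expect_true(all(res$injected_jitter_px == 0L))
})

test_that("undersized tissue and wide footprints are flagged", {
  tr <- transition_table(id = "pc341", analyte_class = "lipid",
                         precursor_mz = 760.6, product_mz = 184.1,
                         dwell_ms = 9)
  cfg <- acquisition_config(tr, stage_speed_um_s = 500,
                            line_spacing_um = 100, line_length_um = 2000,
                            n_lines = 10)
  small <- flat_tissue(200, 500, 50, list(pc341 = 1))
  expect_error(
    simulate_image(spray_model(), kinetics_table(tr), small, cfg),
    "tissue too small")
  ok <- flat_tissue(1000, 2000, 50, list(pc341 = 1))
  expect_warning(
    simulate_image(spray_model(footprint_um = 300), kinetics_table(tr), ok,
                   cfg, seed = 1),
    "bleed")
})

test_that("doubling the stage speed doubles the depletion-limited signal", {
  run_speed <- function(speed) {
    tr <- transition_table(id = "drug", analyte_class = "drug",
                           precursor_mz = 472.3, product_mz = 436.3,
                           dwell_ms = 9)
    cfg <- acquisition_config(tr, stage_speed_um_s = speed,
                              line_spacing_um = 700,
                              line_length_um = 4000, n_lines = 1)
    ti <- flat_tissue(700, 4000, 100, list(drug = 1))
    res <- simulate_image(spray_model(footprint_um = 600),
                          kinetics_table(tr), ti, cfg, seed = 1,
                          dt_s = 0.002)
    interior_mean(res, "drug", cfg, 1200, 3600)
  }
  ratio <- run_speed(200) / run_speed(100)
  expect_equal(ratio, 2, tolerance = 0.02)
})

test_that("at high speed lipids lose signal to fast-dissolving drugs", {
  run <- function(speed) {
    tr <- transition_table(
      id = c("drugA", "drugB", "lip"),
      analyte_class = c("drug", "drug", "lipid"),
      precursor_mz = c(472.3, 394.2, 760.6),
      product_mz = c(436.3, 278.1, 184.1), dwell_ms = 9)
    cfg <- acquisition_config(tr, stage_speed_um_s = speed,
                              line_spacing_um = 700,
                              line_length_um = 25000, n_lines = 1)
    ti <- flat_tissue(700, 25000, 100,
                      list(drugA = 1, drugB = 1, lip = 1))
    res <- simulate_image(spray_model(), kinetics_table(tr), ti, cfg,
                          seed = 1, dt_s = 0.002, i_max = 1e8)
    c(drug = interior_mean(res, "drugA", cfg, 18000, 24000),
      lip = interior_mean(res, "lip", cfg, 18000, 24000))
  }
  slow <- run(500); fast <- run(1000)
  expect_lt(fast[["lip"]], slow[["lip"]])      # lipid decreases
  expect_gte(fast[["drug"]], slow[["drug"]])   # drug does not
})

test_that("charge competition anticorrelates anti-phase analytes", {
  tr <- transition_table(id = c("a", "b"), analyte_class = "drug",
                         precursor_mz = c(472.3, 394.2),
                         product_mz = c(436.3, 278.1), dwell_ms = 9)
  cfg <- acquisition_config(tr, stage_speed_um_s = 500,
                            line_spacing_um = 700, line_length_um = 8000,
                            n_lines = 1)
  nr <- 7; nc <- 80
  stripe <- 0.5 + 0.45 * sin(2 * pi * (seq_len(nc) - 0.5) * 100 / 800)
  a <- matrix(rep(stripe, each = nr), nr, nc)
  ti <- tissue_model(100, list(a = a, b = max(a) - a + min(a)),
                     matrix(TRUE, nr, nc))
  res <- simulate_image(spray_model(), kinetics_table(tr), ti, cfg,
                        seed = 1, dt_s = 0.002, i_max = 5e7)
  ga <- res$truth_images$a$grid[1, ]
  gb <- res$truth_images$b$grid[1, ]
  x <- (seq_along(ga) - 0.5) * pixel_width_um(cfg)
  keep <- x > 3000 & x < 7500
  expect_lt(cor(ga[keep], gb[keep]), 0)
})

test_that("runs are reproducible and substreams are independent", {
  ph <- make_phantom("tumor_stroma",
                     params = list(width_um = 1000, height_um = 400,
                                   grid_um = 50), seed = 3)
  tr <- transition_table(id = c("pc341", "pc364"), analyte_class = "lipid",
                         precursor_mz = c(760.6, 782.6), product_mz = 184.1,
                         dwell_ms = 9)
  cfg <- acquisition_config(tr, stage_speed_um_s = 500,
                            line_spacing_um = 100, line_length_um = 1000,
                            n_lines = 4)
  kin <- kinetics_table(tr)
  r1 <- suppressWarnings(simulate_image(spray_model(), kin, ph, cfg,
                                        jitter_px_max = 3, noise = TRUE,
                                        seed = 5))
  r2 <- suppressWarnings(simulate_image(spray_model(), kin, ph, cfg,
                                        jitter_px_max = 3, noise = TRUE,
                                        seed = 5))
  expect_identical(r1$lineset$data, r2$lineset$data)
  expect_identical(r1$injected_jitter_px, r2$injected_jitter_px)
  # toggling noise must not shift the jitter draws
  r3 <- suppressWarnings(simulate_image(spray_model(), kin, ph, cfg,
                                        jitter_px_max = 3, noise = FALSE,
                                        seed = 5))
  expect_identical(r3$injected_jitter_px, r1$injected_jitter_px)
})

test_that("dynamic-mode mass accounting balances", {
  tr <- transition_table(id = "pc341", analyte_class = "lipid",
                         precursor_mz = 760.6, product_mz = 184.1,
                         dwell_ms = 9)
  cfg <- acquisition_config(tr, stage_speed_um_s = 500,
                            line_spacing_um = 150, line_length_um = 1500,
                            n_lines = 3)
  ti <- flat_tissue(450, 1500, 50, list(pc341 = 2))
  res <- simulate_image(spray_model(), kinetics_table(tr), ti, cfg,
                        seed = 1)
  m <- res$mass
  expect_equal(m$remaining + m$desorbed + m$dissolved_residual, m$initial,
               tolerance = 1e-9)
})

test_that("liver phantom keeps drug signal periportal end to end", {
  ph <- make_phantom("zonated_liver",
                     params = list(width_um = 2000, height_um = 1000,
                                   grid_um = 50, lobule_um = 500), seed = 4)
  tr <- transition_table(id = c("drugA", "lipB"),
                         analyte_class = c("drug", "lipid"),
                         precursor_mz = c(472.3, 786.6),
                         product_mz = c(436.3, 184.1), dwell_ms = 9)
  cfg <- acquisition_config(tr, stage_speed_um_s = 500,
                            line_spacing_um = 100, line_length_um = 2000,
                            n_lines = 10)
  res <- suppressWarnings(
    simulate_image(spray_model(), kinetics_table(tr), ph, cfg,
                   jitter_px_max = 2, noise = TRUE, seed = 6))
  al <- realign_lines(reconstruct(res$lineset))
  g <- al$images$drugA$grid
  expect_gt(mean(g[res$labels == 1], na.rm = TRUE),
            mean(g[res$labels == 3], na.rm = TRUE))
})
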