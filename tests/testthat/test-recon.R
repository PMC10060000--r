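test_that("reconstruction maps scans to pixels and normalizes dwell", {
  cfg <- two_transition_config(n_lines = 3)
  set <- toy_lineset(cfg, n_scans = 8)
  imgs <- reconstruct(set)
  expect_named(imgs, cfg$transitions$id)
  expect_identical(dim(imgs$drug$grid), c(3L, 8L))
  raw <- set$data
  v <- raw$intensity[raw$line_index == 1 & raw$transition_id == "drug" &
                       raw$scan_index == 4]
  expect_equal(imgs$drug$grid[2, 5], v / 0.003)
  expect_equal(imgs$drug$pixel_h_um, cfg$line_spacing_um)
  expect_equal(imgs$drug$pixel_w_um, pixel_width_um(cfg))
})

test_that("already-normalized sets are not normalized twice", {
  set <- normalize_dwell(toy_lineset())
  imgs <- reconstruct(set)
  v <- set$data$intensity[set$data$line_index == 0 &
                            set$data$transition_id == "lip" &
                            set$data$scan_index == 2]
  expect_equal(imgs$lip$grid[1, 3], v)
})

test_that("ragged lines pad with NA and missing transitions warn", {
  cfg <- two_transition_config(n_lines = 2)
  d <- toy_lineset(cfg, n_scans = 6)$data
  d <- d[!(d$line_index == 1 & d$scan_index >= 4), ]
  set <- line_scan_set(cfg, d)
  imgs <- reconstruct(set)
  expect_true(all(is.na(imgs$drug$grid[2, 5:6])))
  expect_false(anyNA(imgs$drug$grid[1, ]))

  d2 <- d[!(d$transition_id == "lip" & d$line_index == 1), ]
  expect_warning(imgs2 <- reconstruct(line_scan_set(cfg, d2)),
                 "missing on line")
  expect_true(all(is.na(imgs2$lip$grid[2, ])))
})

test_that("empty line scan sets are rejected", {
  cfg <- two_transition_config()
  empty <- structure(list(config = cfg,
                          data = toy_lineset(cfg)$data[0, ],
                          normalized = FALSE, metadata = list()),
                     class = "line_scan_set")
  expect_error(reconstruct(empty), "empty")
})

test_that("relative scaling records its scale and clamps hotspots", {
  g <- matrix(1, 10, 10)
  g[5, 5] <- 100
  im <- ion_image("x", g, 10, 10)
  mx <- scale_relative(im, method = "max")
  expect_equal(max(mx$grid), 1)
  expect_equal(attr(mx, "scaling")$scale, 100)

  pc <- scale_relative(im, method = "percentile", q = 99)
  sc <- attr(pc, "scaling")$scale
  expect_equal(sc, as.numeric(quantile(as.numeric(g), 0.99)))
  expect_equal(pc$grid[5, 5], 1)          # hotspot clamped
  expect_equal(pc$grid[1, 1], 1 / sc)     # background structure survives

  z <- scale_relative(ion_image("z", matrix(0, 3, 3), 1, 1))
  expect_true(all(z$grid == 0))
  expect_equal(attr(z, "scaling")$scale, 1)

  # idempotence on already-scaled input
  expect_equal(scale_relative(mx, method = "max")$grid, mx$grid)
})

test_that("overlays compose additively with missing pixels black", {
  r <- matrix(0, 2, 2); r[1, 1] <- 1; r[2, 2] <- 1
  g <- matrix(0, 2, 2); g[1, 2] <- 1; g[2, 2] <- 1
  r[2, 1] <- NA
  ov <- overlay(list(a = ion_image("a", r, 1, 1),
                     b = ion_image("b", g, 1, 1)),
                colors = c(a = "red", b = "green"))
  expect_equal(ov$rgb[1, 1, ], c(1, 0, 0))      # red only
  expect_equal(ov$rgb[1, 2, ], c(0, 1, 0))      # green only
  expect_equal(ov$rgb[2, 2, ], c(1, 1, 0))      # overlap -> yellow
  expect_equal(ov$rgb[2, 1, ], c(0, 1, 0) * 0)  # NA -> black
  expect_error(overlay(list(a = ion_image("a", r, 1, 1),
                            b = ion_image("b", matrix(0, 3, 3), 1, 1))),
               "share one grid")
})

test_that("single-channel overlay is grayscale in that color", {
  g <- matrix(seq(0, 1, length.out = 9), 3, 3)
  ov <- overlay(list(a = ion_image("a", g, 1, 1)), colors = c(a = "red"))
  expect_equal(ov$rgb[, , 1], g)
  expect_true(all(ov$rgb[, , 2:3] == 0))
})

test_that("ion images round-trip through their CSV form", {
  g <- matrix(rnorm(20), 4, 5)
  g[2, 3] <- NA
  im <- ion_image("pc341", g, 12.25, 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ion_image_csv(im, path)
  back <- read_ion_image_csv(path)
  expect_identical(back$grid, g)
  expect_equal(back$pixel_w_um, 12.25)
  expect_equal(back$transition_id, "pc341")
})
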