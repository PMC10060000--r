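test_that("write -> read round-trips a line scan set losslessly", {
  set.seed(7)
  cfg <- two_transition_config()
  n <- 10
  grid <- expand.grid(line_index = 0:1,
                      transition_id = cfg$transitions$id,
                      scan_index = seq_len(n) - 1L,
                      stringsAsFactors = FALSE)
  grid$time_s <- grid$scan_index * scan_period_s(cfg) +
    ifelse(grid$transition_id == "drug", 0.0015, 0.0515)
  grid$intensity <- rpois(nrow(grid), 40) + runif(nrow(grid))
  set <- line_scan_set(cfg, grid)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chronograms(set, path)
  back <- read_chronograms(path, cfg)
  expect_identical(back$data$intensity, set$data$intensity)
  expect_equal(back$data$time_s, set$data$time_s, tolerance = 1e-6)
  expect_identical(back$data$transition_id, set$data$transition_id)
  expect_false(back$normalized)
})

test_that("row order in the file does not matter", {
  set <- toy_lineset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_chronograms(set, path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  colrow <- max(hdr) + 1L
  body <- lines[(colrow + 1L):length(lines)]
  writeLines(c(lines[hdr], lines[colrow], rev(body)), path)
  back <- read_chronograms(path, set$config)
  expect_equal(back$data, set$data)
})

test_that("malformed files raise named parse errors with line numbers", {
  set <- toy_lineset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_chronograms(set, path)
  lines <- readLines(path)
  body_start <- max(grep("^#", lines)) + 2L

  dup <- c(lines, lines[body_start])
  writeLines(dup, path)
  expect_error(read_chronograms(path, set$config), "duplicate")

  bad_id <- lines
  bad_id[body_start] <- sub("drug", "nope", bad_id[body_start])
  writeLines(bad_id, path)
  expect_error(read_chronograms(path, set$config), "unknown transition")

  writeLines(c("#x=1", "line_index,transition_id,scan_index,time_s"), path)
  expect_error(read_chronograms(path, set$config), "missing columns")
})

test_that("duplicate keys are rejected at construction too", {
  cfg <- two_transition_config()
  d <- toy_lineset(cfg)$data
  expect_error(line_scan_set(cfg, rbind(d, d[1, ])), "duplicate")
})

test_that("dwell normalization converts counts to counts/s once", {
  cfg <- acquisition_config(
    transition_table(id = "m", precursor_mz = 402.2, product_mz = 384.2,
                     dwell_ms = 59))
  set <- line_scan_set(cfg, tibble::tibble(
    line_index = 0L, transition_id = "m", scan_index = 0:1,
    time_s = c(0.01, 1.01), intensity = c(190, 0)))
  norm <- normalize_dwell(set)
  expect_equal(norm$data$intensity, c(190 / 0.059, 0), tolerance = 1e-6)
  expect_equal(round(norm$data$intensity[1], 1), 3220.3)
  expect_error(normalize_dwell(norm), "already")
})

test_that("dwell normalization is linear and the identity at 1 s", {
  cfg <- acquisition_config(
    transition_table(id = "m", precursor_mz = 100, product_mz = 50,
                     dwell_ms = 1000))
  mk <- function(v) line_scan_set(cfg, tibble::tibble(
    line_index = 0L, transition_id = "m",
    scan_index = seq_along(v) - 1L, time_s = seq_along(v), intensity = v))
  v <- c(3, 14, 159)
  expect_equal(normalize_dwell(mk(v))$data$intensity, v)
  a <- 7.5
  expect_equal(normalize_dwell(mk(a * v))$data$intensity,
               a * normalize_dwell(mk(v))$data$intensity)
})

test_that("transition tables round-trip through CSV", {
  tr <- demo_transitions()
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_table(tr, path)
  back <- read_transition_table(path)
  expect_equal(back, tr)
})
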