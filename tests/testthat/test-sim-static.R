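# dense per-step trace of one analyte from the simulator state
static_trace <- function(sim, id = "drug") {
  st <- attr(sim, "sim_state")
  k <- match(id, st$transition_id)
  list(t = st$time_s, rate = st$detected_rate[, k],
       a_rem = st$a_rem[, k], dissolved = st$dissolved[, k],
       desorbed = st$desorbed[, k], initial = st$initial[k])
}

test_that("static traces show delay, rise, plateau and decline in order", {
  cfg <- two_transition_config()
  sim <- simulate_static(spray_model(), kinetics_table(cfg$transitions),
                         cfg, duration_s = 12)
  for (id in c("drug", "lip")) {
    tr <- static_trace(sim, id)
    i_first <- min(which(tr$rate > 0))
    expect_gt(tr$t[i_first], 0.3)   # wetting delay, no signal before
    expect_true(all(tr$rate[seq_len(i_first - 1)] == 0))
    i_pk <- which.max(tr$rate)
    expect_gt(i_pk, i_first)
    # monotone rise to the peak (smoothed slope stays non-negative)
    rise <- tr$rate[seq(i_first, i_pk, by = 25)]
    expect_true(all(diff(rise) > -1e-9))
    # plateau: a contiguous stretch around the peak where the slope is
    # below 5% of the peak slope, lasting at least 15 ms
    slope <- diff(tr$rate) / diff(tr$t)
    low <- abs(slope) < 0.05 * max(abs(slope))
    runs <- rle(low)
    ends <- cumsum(runs$lengths)
    hit <- which(runs$values & ends >= i_pk - 1 &
                   ends - runs$lengths + 1 <= i_pk)
    expect_length(hit, 1)
    dt_step <- diff(tr$t[1:2])
    expect_gte(runs$lengths[hit] * dt_step, 0.015)
    # decline once depleted
    expect_lt(tr$rate[length(tr$rate)], 0.35 * tr$rate[i_pk])
  }
})

test_that("class-default kinetics peak in the published windows", {
  cfg <- two_transition_config()  # 10 scans/s
  sim <- simulate_static(spray_model(), kinetics_table(cfg$transitions),
                         cfg, duration_s = 10)
  pk <- as_tibble(sim) |>
    dplyr::group_by(transition_id) |>
    dplyr::summarise(tmax = time_s[which.max(intensity)])
  t_drug <- pk$tmax[pk$transition_id == "drug"]
  t_lip <- pk$tmax[pk$transition_id == "lip"]
  expect_lte(t_drug, 2)
  expect_gte(t_lip, 2)
  expect_lte(t_lip, 3)
  expect_lt(t_drug, t_lip)  # fast drug before slow structural lipid
})

test_that("zero ionization efficiency yields an all-zero trace", {
  cfg <- two_transition_config()
  kin <- kinetics_table(cfg$transitions)
  kin$eta[kin$transition_id == "drug"] <- 0
  sim <- simulate_static(spray_model(), kin, cfg, duration_s = 5)
  d <- as_tibble(sim)
  expect_true(all(d$intensity[d$transition_id == "drug"] == 0))
  expect_gt(max(d$intensity[d$transition_id == "lip"]), 0)
})

test_that("mass is conserved at every step and depletion is complete", {
  cfg <- two_transition_config()
  sim <- simulate_static(spray_model(), kinetics_table(cfg$transitions),
                         cfg, duration_s = 30)
  for (id in c("drug", "lip")) {
    tr <- static_trace(sim, id)
    bal <- tr$a_rem + tr$dissolved + tr$desorbed
    expect_lt(max(abs(bal - tr$initial)) / tr$initial, 1e-6)
    # long horizon: cumulative desorbed approaches the initial amount
    expect_equal(tr$desorbed[length(tr$desorbed)], tr$initial,
                 tolerance = 0.01)
  }
})

test_that("splitting integrator matches a deSolve RK4 oracle", {
  skip_if_not_installed("deSolve")
  sp <- spray_model()
  k_diss <- 3.0; k_des <- 5
  rhs <- function(t, y, parms) {
    u <- max(0, y[1] - sp$v_wet)
    s <- u / (sp$k_sat + u)
    list(c(sp$solvent_in - sp$k_removal * y[1],
           -k_diss * y[2] * s,
           k_diss * y[2] * s - k_des * y[3]))
  }
  times <- seq(0, 6, by = 0.001)
  ode <- deSolve::ode(c(V = 0, A = 1, D = 0), times, rhs, NULL,
                      method = "rk4")
  cfg <- two_transition_config()
  sim <- simulate_static(spray_model(), kinetics_table(cfg$transitions),
                         cfg, duration_s = 6)
  tr <- static_trace(sim, "drug")
  idx <- findInterval(c(1, 2, 3, 5), tr$t)
  for (i in idx) {
    j <- which.min(abs(times - tr$t[i]))
    expect_equal(tr$a_rem[i], unname(ode[j, "A"]), tolerance = 1e-3)
    expect_equal(tr$dissolved[i], unname(ode[j, "D"]), tolerance = 5e-3)
  }
})

test_that("Poisson counting noise has variance close to the mean", {
  cfg <- two_transition_config()
  kin <- kinetics_table(cfg$transitions)
  reps <- vapply(1:150, function(s) {
    sim <- simulate_static(spray_model(), kin, cfg, duration_s = 2.2,
                           noise = TRUE, seed = s)
    d <- as_tibble(sim)
    d$intensity[d$transition_id == "drug" & d$scan_index == 17]
  }, numeric(1))
  expect_gt(mean(reps), 5)  # enough counts for the ratio to be meaningful
  expect_equal(var(reps) / mean(reps), 1, tolerance = 0.35)
})

test_that("a too-coarse integration step warns", {
  cfg <- two_transition_config(dwell_ms = 3)
  expect_warning(
    simulate_static(spray_model(), kinetics_table(cfg$transitions), cfg,
                    duration_s = 1, dt_s = 0.002),
    "coarser")
})

test_that("noise toggling does not change underlying expected counts", {
  cfg <- two_transition_config()
  kin <- kinetics_table(cfg$transitions)
  a <- simulate_static(spray_model(), kin, cfg, duration_s = 3, seed = 1)
  b <- simulate_static(spray_model(), kin, cfg, duration_s = 3, seed = 99)
  expect_identical(as_tibble(a)$intensity, as_tibble(b)$intensity)
})
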