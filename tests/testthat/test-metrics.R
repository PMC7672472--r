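test_that("trapezoid AUC matches elementary areas and tracks metadata", {
  rect <- auc(data.frame(time_min = c(0, 45, 90),
                         fluorescence_au = c(5, 5, 5)))
  expect_equal(rect$value, 450)
  expect_equal(rect$t_span, 90)
  expect_equal(rect$n_points, 3)
  tri <- auc(c(0, 10), c(10, 0))
  expect_equal(tri$value, 50)
  # irregular grid, piecewise-linear exact
  expect_equal(auc(c(0, 1, 4, 10), c(0, 2, 2, 0))$value,
               1 + 6 + 6)
  expect_error(auc(c(0), c(1)), "2 time points")
  expect_error(auc(c(0, 0, 10), c(1, 1, 1)), "increasing")
})

test_that("trapezoid AUC converges quadratically to the exact integral", {
  A <- 100; k <- 0.05; T <- 90
  exact <- (A / k) * (1 - exp(-k * T))
  err <- function(h) {
    tt <- seq(0, T, by = h)
    abs(auc(tt, A * exp(-k * tt))$value - exact)
  }
  expect_lt(err(5) / exact, 0.01)          # within 1% on the 5-min grid
  ratio <- err(5) / err(2.5)               # halving the step ~quarters error
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("the t0-exclusion flag drops the first read", {
  tt <- seq(0, 60, by = 15)
  ff <- c(100, 80, 60, 40, 20)
  full <- auc(tt, ff)$value
  tail_only <- auc(tt, ff, include_t0 = FALSE)$value
  expect_equal(tail_only, auc(tt[-1], ff[-1])$value)
  expect_lt(tail_only, full)
})

test_that("resistance value implements (AUC1 - AUC0)/AUC0", {
  expect_equal(resistance_value(450, 450), 0)
  expect_equal(resistance_value(900, 450), 1)
  expect_equal(resistance_value(300, 450), -1 / 3)  # negative, not clipped
  expect_error(resistance_value(100, 0), "control AUC")
  expect_error(resistance_value(100, -5), "control AUC")
})

test_that("simulated strong binder matches the closed-form AUC oracle", {
  p <- digestion_params(k_unprotected = 0.05, k_leak = 0, amplitude = 100,
                        background = 0, noise_cv = 0)
  theta <- 0.93
  omega <- 42 / 73
  # oracle: analytic integration of both noiseless model curves
  r_exact <- model_resistance_cf(theta, p, omega, 240)
  # implementation: simulate on a fine grid, integrate, form R
  fine <- sampling_schedule(seq(0, 240, by = 0.25))
  f1 <- expected_fluorescence(fine$times, theta, apt73, p)
  f0 <- expected_fluorescence(fine$times, 0, apt73, p)
  r_num <- resistance_value(auc(fine$times, f1), auc(fine$times, f0))
  expect_equal(r_num, r_exact, tolerance = 1e-4)
})

test_that("cross-reactivity follows the shared-control identity", {
  expect_equal(cross_reactivity(900, 900, 450), 100)  # L = T
  expect_equal(cross_reactivity(450, 900, 450), 0)    # no protection
  # CR = 100 * R_L / R_T with a shared control: R_L 0.25, R_T 0.5
  a0 <- 400
  expect_equal(cross_reactivity(a0 * 1.25, a0 * 1.5, a0), 50)
  expect_error(cross_reactivity(500, 400, 450), "AUC_T > AUC_0")
})

test_that("CR identities hold on random AUC triples", {
  set.seed(11)
  for (i in 1:100) {
    a0 <- runif(1, 50, 500)
    aT <- a0 * runif(1, 1.05, 3)
    aL <- a0 * runif(1, 0.2, 3)
    r_L <- resistance_value(aL, a0)
    r_T <- resistance_value(aT, a0)
    expect_equal(cross_reactivity(aT, aT, a0), 100, tolerance = 1e-12)
    expect_equal(cross_reactivity(aL, aT, a0), 100 * r_L / r_T,
                 tolerance = 1e-12)
  }
})

test_that("signal gain and SD cross-reactivity follow their definitions", {
  expect_equal(signal_gain(100, 100), 0)
  expect_equal(signal_gain(130, 100), 0.3)
  expect_equal(signal_gain(10, 100), -0.9)
  expect_error(signal_gain(100, 0), "f0")
  expect_equal(sd_cross_reactivity(0.5, 0.5), 100)
  expect_equal(sd_cross_reactivity(0, 0.5), 0)
  expect_equal(sd_cross_reactivity(-0.45, 0.5), -90)  # artifact-suspect
  expect_error(sd_cross_reactivity(0.2, 0), "positive")
})

test_that("noiseless resistance rises monotonically with occupancy", {
  f0 <- expected_fluorescence(sched240$times, 0, apt73, noiseless)
  a0 <- auc(sched240$times, f0)
  r <- vapply(seq(0, 1, by = 0.2), function(th) {
    f <- expected_fluorescence(sched240$times, th, apt73, noiseless)
    resistance_value(auc(sched240$times, f), a0)
  }, numeric(1))
  expect_equal(r[1], 0)
  expect_true(all(diff(r) > 0))
})

test_that("resistance table aggregates replicates with a common control", {
  panel <- mephedrone_screen_panel()
  plate <- simulate_panel(panel$aptamers[1:2],
                          list(ligand_condition("mephedrone", 200)),
                          panel$binding_table, n_replicates = 3,
                          params = noiseless, seed = 3)
  rt <- resistance_table(plate)
  expect_equal(nrow(rt), 2)
  expect_equal(rt$n_replicates, c(3L, 3L))
  # noiseless replicates are identical, so SD is exactly 0
  expect_equal(rt$resistance_sd, c(0, 0))
  # MMC1 (Kd 15) and MMC2 (Kd 6.6): both near-saturated binders
  expect_true(all(rt$resistance_mean > 0.8 & rt$resistance_mean < 1))
  expect_true(all(rt$flag == "ok"))
})

test_that("control wells on a different grid are interpolated", {
  sch_l <- sampling_schedule(seq(0, 240, by = 15))
  sch_c <- sampling_schedule(seq(0, 300, by = 10))
  bind <- binding_params("MMC1", "mephedrone", 15)
  lig <- simulate_timecourse(apt73, ligand_condition("mephedrone", 200),
                             bind, noiseless, sch_l, seed = 1)
  ctl <- simulate_timecourse(apt73, make_control_condition(), NULL,
                             noiseless, sch_c, seed = 2)
  plate <- plate_experiment(dplyr::bind_rows(lig, ctl))
  rt <- resistance_table(plate)
  # oracle: both curves integrated on the ligand grid (the overlap)
  f1 <- expected_fluorescence(sch_l$times, 200 / 215, apt73, noiseless)
  f0 <- expected_fluorescence(sch_l$times, 0, apt73, noiseless)
  r_direct <- resistance_value(auc(sch_l$times, f1), auc(sch_l$times, f0))
  # linear interpolation of the convex control on its 10-min grid biases
  # its AUC up by at most k^2 h^2 / 8 ~ 3%, so R agrees to within that
  expect_equal(rt$resistance_mean, r_direct, tolerance = 0.05)
})

test_that("null panels give mean resistance consistent with zero", {
  panel <- mephedrone_screen_panel()
  bt <- panel$binding_table
  bt$kd_app <- Inf
  p <- digestion_params(noise_cv = 0.02)
  rs <- vapply(1:100, function(i) {
    plate <- simulate_panel(panel$aptamers[1],
                            list(ligand_condition("mephedrone", 200)),
                            bt, n_replicates = 3, params = p, seed = i)
    resistance_table(plate)$resistance_mean
  }, numeric(1))
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 3 * se + 1e-4)
})
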