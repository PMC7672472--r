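test_that("fraction bound follows the single-site isotherm", {
  expect_equal(fraction_bound(0, 15), 0)
  expect_equal(fraction_bound(15, 15), 0.5)
  expect_equal(fraction_bound(200, 15), 200 / 215)
  # non-binder sentinel binds nothing at any concentration
  expect_equal(fraction_bound(c(0, 25, 800), Inf), c(0, 0, 0))
  expect_error(fraction_bound(-1, 15), "concentration")
  expect_error(fraction_bound(10, 0), "kd_app")
  expect_error(fraction_bound(10, -3), "kd_app")
})

test_that("expected fluorescence matches closed-form limits", {
  p <- digestion_params(k_unprotected = 0.05, k_leak = 0, amplitude = 100,
                        background = 5, noise_cv = 0)
  # nothing digested at t = 0, for any occupancy
  for (th in c(0, 0.3, 1)) {
    expect_equal(expected_fluorescence(0, th, apt73, p), 105)
  }
  # free aptamer: single exponential, F(1/k) = B + A/e
  expect_equal(expected_fluorescence(1 / 0.05, 0, apt73, p),
               5 + 100 / exp(1))
  # fully bound, no leak: plateau at the protected-length fraction
  omega <- 42 / 73
  expect_equal(expected_fluorescence(1e6, 1, apt73, p), 5 + 100 * omega,
               tolerance = 1e-12)
})

test_that("exchange modes agree at zero occupancy and model is monotone", {
  slow <- digestion_params(noise_cv = 0, exchange_mode = "slow")
  fast <- digestion_params(noise_cv = 0, exchange_mode = "fast")
  tt <- seq(0, 300, by = 5)
  expect_equal(expected_fluorescence(tt, 0, apt73, slow),
               expected_fluorescence(tt, 0, apt73, fast))
  # non-increasing in time and non-decreasing in occupancy, both modes
  for (p in list(slow, fast)) {
    prev <- NULL
    for (th in seq(0, 1, by = 0.2)) {
      f <- expected_fluorescence(tt, th, apt73, p)
      expect_true(all(diff(f) <= 1e-12), info = p$exchange_mode)
      if (!is.null(prev)) {
        expect_true(all(f[-1] >= prev[-1] - 1e-12), info = p$exchange_mode)
      }
      prev <- f
    }
  }
})

test_that("unknown exchange mode is a configuration error", {
  p <- digestion_params(noise_cv = 0)
  p$exchange_mode <- "oscillating"
  expect_error(expected_fluorescence(10, 0.5, apt73, p), "exchange_mode")
})

test_that("single time courses are noiseless-exact, seeded, and physical", {
  cond <- ligand_condition("mephedrone", 200)
  bind <- binding_params("MMC1", "mephedrone", 15)
  tc <- simulate_timecourse(apt73, cond, bind, noiseless, sched240, seed = 42)
  theta <- 200 / 215
  expect_equal(tc$fluorescence_au,
               expected_fluorescence(sched240$times, theta, apt73, noiseless))
  # determinism: identical seed and inputs give identical trajectories
  noisy <- digestion_params(noise_cv = 0.05)
  t1 <- simulate_timecourse(apt73, cond, bind, noisy, sched240, seed = 7)
  t2 <- simulate_timecourse(apt73, cond, bind, noisy, sched240, seed = 7)
  expect_identical(t1, t2)
  t3 <- simulate_timecourse(apt73, cond, bind, noisy, sched240, seed = 8)
  expect_false(identical(t1$fluorescence_au, t3$fluorescence_au))
  # huge noise never drives fluorescence negative
  wild <- digestion_params(noise_cv = 2)
  t4 <- simulate_timecourse(apt73, cond, bind, wild, sched240, seed = 1)
  expect_true(all(t4$fluorescence_au >= 0))
})

test_that("final/initial expected ratio matches the model closed form", {
  p <- digestion_params(k_unprotected = 0.05, k_leak = 0.002, noise_cv = 0)
  bind <- binding_params("MMC1", "mephedrone", 15)
  tc <- simulate_timecourse(apt73, ligand_condition("mephedrone", 200), bind,
                            p, sched240, seed = 1)
  theta <- 200 / 215
  omega <- 42 / 73
  f_of <- function(t) {
    5 + 100 * ((1 - theta) * exp(-0.05 * t) +
               theta * (omega + (1 - omega) * exp(-0.05 * t)) *
                 exp(-0.002 * t))
  }
  expect_equal(tc$fluorescence_au[length(tc$fluorescence_au)] /
                 tc$fluorescence_au[1],
               f_of(240) / f_of(0), tolerance = 1e-12)
})

test_that("ligand-excess validity warning fires below 10x aptamer conc", {
  bind <- binding_params("MMC1", "mephedrone", 15)
  expect_warning(
    simulate_timecourse(apt73, ligand_condition("mephedrone", 5), bind,
                        noiseless, sched240, seed = 1),
    "ligand-excess")
  expect_silent(
    simulate_timecourse(apt73, ligand_condition("mephedrone", 25), bind,
                        noiseless, sched240, seed = 1))
})

test_that("panel simulation counts wells and auto-adds controls", {
  bt <- data.frame(aptamer_id = "MMC1", ligand_id = "mephedrone",
                   kd_app = 15)
  plate <- simulate_panel(list(apt73),
                          list(ligand_condition("mephedrone", 200)),
                          bt, n_replicates = 3, seed = 1)
  wells <- dplyr::distinct(tibble::as_tibble(plate), aptamer_id, ligand_id,
                           concentration_uM, replicate)
  expect_equal(nrow(wells), 6)  # (control + target) x 3 replicates
  expect_setequal(unique(wells$ligand_id), c("none", "mephedrone"))

  panel <- mephedrone_screen_panel()
  plate29 <- simulate_panel(panel$aptamers,
                            list(ligand_condition("mephedrone", 200)),
                            panel$binding_table, n_replicates = 2, seed = 1)
  wells29 <- dplyr::distinct(tibble::as_tibble(plate29), aptamer_id,
                             ligand_id, concentration_uM, replicate)
  expect_equal(nrow(wells29), 116)  # 29 x (control + target) x 2
})

test_that("missing binding entries become logged non-binders", {
  bt <- data.frame(aptamer_id = character(0), ligand_id = character(0),
                   kd_app = numeric(0))
  expect_message(
    plate <- simulate_panel(list(apt73),
                            list(ligand_condition("mephedrone", 200)),
                            bt, n_replicates = 2,
                            params = noiseless, seed = 1),
    "non-binder")
  df <- tibble::as_tibble(plate)
  lig <- df[df$ligand_id == "mephedrone" & df$replicate == 1, ]
  ctl <- df[df$ligand_id == "none" & df$replicate == 1, ]
  expect_equal(lig$fluorescence_au, ctl$fluorescence_au)
})

test_that("all-non-binder panels are indistinguishable from controls", {
  panel <- mephedrone_screen_panel()
  bt <- panel$binding_table
  bt$kd_app <- Inf
  plate <- simulate_panel(panel$aptamers[1:3],
                          list(ligand_condition("mephedrone", 200)),
                          bt, n_replicates = 1, params = noiseless, seed = 1)
  df <- tibble::as_tibble(plate)
  for (id in unique(df$aptamer_id)) {
    expect_equal(df$fluorescence_au[df$aptamer_id == id &
                                    df$ligand_id == "mephedrone"],
                 df$fluorescence_au[df$aptamer_id == id &
                                    df$ligand_id == "none"])
  }
})

test_that("panel generation is bit-reproducible for a fixed master seed", {
  panel <- mephedrone_screen_panel()
  p1 <- simulate_panel(panel$aptamers[1:5],
                       list(ligand_condition("mephedrone", 200)),
                       panel$binding_table, n_replicates = 2, seed = 99)
  p2 <- simulate_panel(panel$aptamers[1:5],
                       list(ligand_condition("mephedrone", 200)),
                       panel$binding_table, n_replicates = 2, seed = 99)
  expect_identical(tibble::as_tibble(p1), tibble::as_tibble(p2))
})

test_that("replicate means converge to the noiseless curve", {
  p <- digestion_params(noise_cv = 0.05)
  bind <- binding_params("MMC1", "mephedrone", 15)
  cond <- ligand_condition("mephedrone", 200)
  n <- 200
  mat <- vapply(seq_len(n), function(i) {
    simulate_timecourse(apt73, cond, bind, p, sched240,
                        seed = i)$fluorescence_au
  }, numeric(length(sched240$times)))
  mu <- expected_fluorescence(sched240$times, 200 / 215, apt73, p)
  se <- mu * 0.05 / sqrt(n)
  expect_true(all(abs(rowMeans(mat) - mu) <= 3 * se))
})

test_that("strand-displacement readout reproduces artifact failure modes", {
  sd0 <- sd_params(f_max = 100, quench_efficiency = 0.92, kd_sd = 0.6,
                   max_displacement = 0.6)
  # no ligand, no artifact: F = F0 = quenched baseline
  r0 <- simulate_sd_readout(ligand_condition("x", 0),
                            binding_params("A", "x", 0.6), sd0)
  expect_equal(r0$f, r0$f0)
  expect_equal(r0$f0, (1 - 0.92) * 100)
  # strong binder whose ligand attenuates the fluorophore: false negative
  r_fn <- simulate_sd_readout(
    ligand_condition("chlorpromazine", 50, dye_artifact_factor = 0.1),
    binding_params("A", "chlorpromazine", 0.6), sd0)
  delta <- 0.6 * 50 / (0.6 + 50)
  f_true <- 8 + (100 - 8) * delta
  expect_equal(r_fn$f, 0.1 * f_true)
  expect_lt(r_fn$f, r_fn$f0)
  # non-binder whose ligand enhances the fluorophore: false positive
  r_fp <- simulate_sd_readout(
    ligand_condition("acetyl_fentanyl", 200, dye_artifact_factor = 1.3),
    binding_params("A", "acetyl_fentanyl", Inf),
    sd_params(quench_efficiency = 0.92))
  expect_equal(r_fp$f, 1.3 * r_fp$f0)
  expect_gt(signal_gain(r_fp$f, r_fp$f0), 0)
})
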