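#' Fraction of aptamer bound at a given ligand concentration
#'
#' Single-site binding isotherm under ligand excess: the assay uses ~1 uM
#' aptamer against >= 25 uM ligand, so free ligand is taken equal to total
#' ligand and the bound fraction is `c / (kd_app + c)`. A non-binder
#' (`kd_app = Inf`) is bound at fraction 0 at every concentration.
#'
#' @param concentration Ligand concentration(s), uM (>= 0); vectorised.
#' @param kd_app Apparent Kd, uM (> 0), or `Inf` for a non-binder.
#' @return Fraction(s) bound in \[0, 1\].
#' @examples
#' fraction_bound(200, 15)   # ~0.93: near-saturation of a 15-uM binder
#' fraction_bound(15, 15)    # 0.5 at c = Kd
#' fraction_bound(800, Inf)  # 0: non-binder
#' @export
fraction_bound <- function(concentration, kd_app) {
  if (!is.numeric(concentration) || any(is.na(concentration)) ||
      any(concentration < 0)) {
    stop("`concentration` must be numeric and >= 0", call. = FALSE)
  }
  if (!is.numeric(kd_app) || length(kd_app) != 1L || is.na(kd_app) ||
      kd_app <= 0) {
    stop("`kd_app` must be positive (uM) or Inf for a non-binder",
         call. = FALSE)
  }
  if (is.infinite(kd_app)) {
    return(rep(0, length(concentration)))
  }
  concentration / (kd_app + concentration)
}

#' Expected (noiseless) digestion fluorescence
#'
#' The ligand-free aptamer is digested at first-order rate `k_u`, so its
#' stainable fluorescence decays as a single exponential. A ligand-bound
#' aptamer is digested down to its protected product, which retains a
#' fraction `omega = P / N` of the dye signal (signal taken proportional to
#' retained nucleotides) and is itself degraded slowly at `k_leak`.
#'
#' Under slow exchange (bound/free states frozen over the digestion):
#' \deqn{F(t) = B + A\,[(1-\theta)e^{-k_u t} +
#'   \theta\,(\omega + (1-\omega)e^{-k_u t})\,e^{-k_{leak} t}]}
#' where the bound channel decays from full length to the protected plateau
#' at `k_u` and leaks away at `k_leak`. Under fast exchange the two states
#' average into one effective rate:
#' \deqn{F(t) = B + A\,e^{-k_{eff} t},\quad
#'   k_{eff} = (1-\theta)k_u + \theta k_{leak}.}
#'
#' @param t Time(s) since enzyme addition, minutes (>= 0); vectorised.
#' @param theta Fraction of aptamer in the ligand-bound state, in \[0, 1\].
#' @param aptamer An [aptamer_spec()].
#' @param params A [digestion_params()]; `exchange_mode` selects the model.
#' @return Expected fluorescence, a.u., same length as `t`.
#' @examples
#' apt <- aptamer_spec("MMC1", 73, 42)
#' par <- digestion_params(noise_cv = 0)
#' expected_fluorescence(0, 0.5, apt, par)          # B + A at t = 0
#' expected_fluorescence(c(0, 60, 240), 0.93, apt, par)
#' @export
expected_fluorescence <- function(t, theta, aptamer, params) {
  stopifnot(inherits(aptamer, "aptamer_spec"),
            inherits(params, "digestion_params"))
  if (!is.numeric(t) || any(is.na(t)) || any(t < 0)) {
    stop("`t` must be numeric and >= 0", call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 1) {
    stop("`theta` must be a single value in [0, 1]", call. = FALSE)
  }
  A <- params$amplitude
  B <- params$background
  ku <- params$k_unprotected
  kl <- params$k_leak
  omega <- aptamer$protected_length_nt / aptamer$full_length_nt
  switch(params$exchange_mode,
    slow = B + A * ((1 - theta) * exp(-ku * t) +
                    theta * (omega + (1 - omega) * exp(-ku * t)) * exp(-kl * t)),
    fast = {
      keff <- (1 - theta) * ku + theta * kl
      B + A * exp(-keff * t)
    },
    stop("unknown `exchange_mode`: ", params$exchange_mode, call. = FALSE)
  )
}

# Deterministic master-seed -> per-well sub-seed derivation. Wells are
# numbered in generation order (aptamer, then condition, then replicate);
# well i gets seed (master + i * 10007) mod (2^31 - 1), so any single well
# is reproducible in isolation from (master seed, well index).
well_seed <- function(master_seed, well_index) {
  as.integer((as.numeric(master_seed) + as.numeric(well_index) * 10007) %%
               2147483647)
}

#' Simulate one digestion fluorescence time course
#'
#' Evaluates the noiseless model at the scheduled times, applies
#' multiplicative Gaussian noise `y = F(t) * (1 + eps)`,
#' `eps ~ N(0, noise_cv)`, independently per read (each time point is a
#' destructively sampled aliquot), and clips at 0 so fluorescence stays
#' physical. With the same seed and inputs the output is identical.
#'
#' Free ligand is approximated by total ligand; a warning is issued when the
#' ligand concentration is positive but less than 10x the aptamer
#' concentration, outside the validity of that approximation.
#'
#' @param aptamer An [aptamer_spec()].
#' @param condition A [ligand_condition()].
#' @param binding A [binding_params()] whose ids match `aptamer`/`condition`
#'   (the control condition `"none"` needs no match).
#' @param params A [digestion_params()].
#' @param schedule A [sampling_schedule()].
#' @param seed Integer seed for the noise draws.
#' @param replicate Replicate index recorded in the output (default 1).
#' @param aptamer_conc_uM Aptamer assay concentration used for the
#'   ligand-excess validity check (default 1 uM).
#' @return A tibble with columns `aptamer_id`, `ligand_id`,
#'   `concentration_uM`, `replicate`, `time_min`, `fluorescence_au`.
#' @export
simulate_timecourse <- function(aptamer, condition, binding, params, schedule,
                                seed, replicate = 1L, aptamer_conc_uM = 1) {
  stopifnot(inherits(aptamer, "aptamer_spec"),
            inherits(condition, "ligand_condition"),
            inherits(params, "digestion_params"),
            inherits(schedule, "sampling_schedule"))
  is_control <- condition$concentration == 0
  if (!is_control) {
    stopifnot(inherits(binding, "binding_params"))
    if (binding$aptamer_id != aptamer$aptamer_id ||
        binding$ligand_id != condition$ligand_id) {
      stop("binding entry (", binding$aptamer_id, ", ", binding$ligand_id,
           ") does not match aptamer/condition (", aptamer$aptamer_id, ", ",
           condition$ligand_id, ")", call. = FALSE)
    }
    if (is.finite(binding$kd_app) &&
        condition$concentration < 10 * aptamer_conc_uM) {
      warning("ligand concentration ", condition$concentration,
              " uM is < 10x the aptamer concentration (", aptamer_conc_uM,
              " uM); the ligand-excess approximation may be poor",
              call. = FALSE)
    }
    theta <- fraction_bound(condition$concentration, binding$kd_app)
  } else {
    theta <- 0
  }
  mu <- expected_fluorescence(schedule$times, theta, aptamer, params)
  if (params$noise_cv > 0) {
    set.seed(as.integer(seed))
    y <- mu * (1 + stats::rnorm(length(mu), 0, params$noise_cv))
    y <- pmax(y, 0)
  } else {
    y <- mu
  }
  tibble::tibble(
    aptamer_id = aptamer$aptamer_id,
    ligand_id = if (is_control) "none" else condition$ligand_id,
    concentration_uM = condition$concentration,
    replicate = as.integer(replicate),
    time_min = schedule$times,
    fluorescence_au = y
  )
}

#' Simulate a full plate of digestion time courses
#'
#' Generates one time course per (aptamer, condition, replicate). A
#' ligand-free control condition is added automatically for every aptamer if
#' not already present. A missing (aptamer, ligand) entry in the binding
#' table is treated as a non-binder and reported via a message, not an
#' error. Per-well noise uses deterministic sub-seeds derived from the
#' master seed, so the full panel is bit-reproducible and any single well
#' can be re-simulated in isolation.
#'
#' @param aptamers List of [aptamer_spec()] objects.
#' @param conditions List of [ligand_condition()] objects (shared across
#'   aptamers).
#' @param binding_table Data frame with columns `aptamer_id`, `ligand_id`,
#'   `kd_app` (uM; `Inf` = non-binder).
#' @param n_replicates Replicates per well (>= 1).
#' @param params A [digestion_params()].
#' @param schedule A [sampling_schedule()].
#' @param seed Master integer seed.
#' @return A [plate_experiment()] (long tibble with provenance attribute).
#' @examples
#' apt <- aptamer_spec("MMC1", 73, 42)
#' bt <- data.frame(aptamer_id = "MMC1", ligand_id = "mephedrone", kd_app = 15)
#' plate <- simulate_panel(list(apt), list(ligand_condition("mephedrone", 200)),
#'                         bt, n_replicates = 3,
#'                         params = digestion_params(),
#'                         schedule = sampling_schedule(), seed = 1)
#' dplyr::count(plate, ligand_id)
#' @export
simulate_panel <- function(aptamers, conditions, binding_table,
                           n_replicates = 3L, params = digestion_params(),
                           schedule = sampling_schedule(), seed = 1L) {
  if (inherits(aptamers, "aptamer_spec")) aptamers <- list(aptamers)
  if (inherits(conditions, "ligand_condition")) conditions <- list(conditions)
  stopifnot(length(aptamers) >= 1L, length(conditions) >= 1L,
            n_replicates >= 1L)
  ids <- vapply(aptamers, `[[`, character(1), "aptamer_id")
  if (anyDuplicated(ids)) {
    stop("duplicate aptamer ids in panel: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  binding_table <- as.data.frame(binding_table)
  # every aptamer gets a ligand-free control
  has_control <- any(vapply(conditions, function(cc) cc$concentration == 0,
                            logical(1)))
  if (!has_control) {
    conditions <- c(list(ligand_condition("none", 0)), conditions)
  }
  missing_pairs <- character(0)
  out <- vector("list", length(aptamers) * length(conditions) * n_replicates)
  i <- 0L
  for (apt in aptamers) {
    for (cond in conditions) {
      if (cond$concentration == 0) {
        bind <- NULL
      } else {
        hit <- binding_table$aptamer_id == apt$aptamer_id &
               binding_table$ligand_id == cond$ligand_id
        if (any(hit)) {
          row <- binding_table[which(hit)[1], ]
          bind <- binding_params(apt$aptamer_id, cond$ligand_id,
                                 kd_app = row$kd_app)
        } else {
          missing_pairs <- c(missing_pairs,
                             paste0(apt$aptamer_id, "/", cond$ligand_id))
          bind <- binding_params(apt$aptamer_id, cond$ligand_id, kd_app = Inf)
        }
      }
      for (rep_i in seq_len(n_replicates)) {
        i <- i + 1L
        out[[i]] <- simulate_timecourse(
          apt, cond, bind, params, schedule,
          seed = well_seed(seed, i), replicate = rep_i
        )
      }
    }
  }
  if (length(missing_pairs) > 0) {
    message("no binding entry for ", length(unique(missing_pairs)),
            " (aptamer, ligand) pair(s); treated as non-binders: ",
            paste(unique(missing_pairs), collapse = ", "))
  }
  plate_experiment(
    dplyr::bind_rows(out),
    provenance = list(
      generator = "exoprofiler::simulate_panel",
      seed = as.integer(seed),
      n_replicates = as.integer(n_replicates),
      exchange_mode = params$exchange_mode,
      noise_cv = params$noise_cv
    )
  )
}

#' Simulate a strand-displacement readout
#'
#' Models the fluorophore-quencher displacement assay. The quenched baseline
#' is `F_q = (1 - quench_efficiency) * F_max`; ligand displaces a fraction
#' `delta = max_displacement * c / (kd_sd + c)` of complexes, giving a true
#' signal `F_true = F_q + (F_max - F_q) * delta`. The observed signal is
#' `dye_artifact_factor * F_true * (1 + eps)`: ligand-fluorophore artifacts
#' scale the whole readout, which is how a strong binder whose ligand
#' quenches the dye can read below baseline (false negative) and a
#' non-binder whose ligand enhances it can read above (false positive).
#' The ligand-free reference `F0` always uses `c = 0` and factor 1.
#'
#' @param condition A [ligand_condition()] (carries concentration and
#'   `dye_artifact_factor`).
#' @param binding A [binding_params()]; a non-binder (`kd_app = Inf`)
#'   displaces nothing.
#' @param sd A [sd_params()].
#' @param seed Integer seed for the noise draws.
#' @param noise_cv Multiplicative noise CV (default 0, noiseless).
#' @return Named list with elements `f` (observed signal) and `f0`
#'   (ligand-free reference), both a.u.
#' @examples
#' cond <- ligand_condition("chlorpromazine", 50, dye_artifact_factor = 0.1)
#' bind <- binding_params("MA-46", "chlorpromazine", kd_app = 0.6)
#' simulate_sd_readout(cond, bind, sd_params(kd_sd = 0.6))
#' @export
simulate_sd_readout <- function(condition, binding, sd, seed = 1L,
                                noise_cv = 0) {
  stopifnot(inherits(condition, "ligand_condition"),
            inherits(binding, "binding_params"),
            inherits(sd, "sd_params"))
  f_q <- (1 - sd$quench_efficiency) * sd$f_max
  # displacement tracks occupancy of the displacement-competent state; a
  # non-binding aptamer-ligand pair displaces nothing regardless of kd_sd
  if (is.infinite(binding$kd_app) || condition$concentration == 0) {
    delta <- 0
  } else {
    delta <- sd$max_displacement *
      condition$concentration / (sd$kd_sd + condition$concentration)
  }
  f_true <- f_q + (sd$f_max - f_q) * delta
  if (noise_cv > 0) {
    set.seed(as.integer(seed))
    eps <- stats::rnorm(2, 0, noise_cv)
  } else {
    eps <- c(0, 0)
  }
  list(
    f = max(condition$dye_artifact_factor * f_true * (1 + eps[1]), 0),
    f0 = max(f_q * (1 + eps[2]), 0)
  )
}
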