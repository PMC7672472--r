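#' Synthetic 29-candidate mephedrone screening panel
#'
#' Constructs the canonical screening scenario this package's analyses are
#' exercised on: 29 aptamer candidates from a selection against mephedrone,
#' of which the four most abundant (MMC1-MMC4) are true binders with
#' apparent Kd values spanning the moderate-affinity range (6.6-40 uM) and
#' the remaining 25 are non-binders. All candidates are 73-nt sequences
#' whose ligand-protected major product is 42 nt. Screened at 200 uM
#' mephedrone with the default digestion parameters, the binders' noiseless
#' resistance values fall in [0.8, 1.0] and the non-binders' at 0.
#'
#' @return A list with `aptamers` (list of [aptamer_spec()]) and
#'   `binding_table` (tibble: `aptamer_id`, `ligand_id`, `kd_app`).
#' @examples
#' panel <- mephedrone_screen_panel()
#' length(panel$aptamers)          # 29 candidates
#' sum(is.finite(panel$binding_table$kd_app))  # 4 binders
#' @export
mephedrone_screen_panel <- function() {
  ids <- paste0("MMC", 1:29)
  kd <- rep(Inf, 29)
  kd[1:4] <- c(15, 6.6, 30, 40)
  list(
    aptamers = lapply(ids, aptamer_spec, full_length_nt = 73L,
                      protected_length_nt = 42L),
    binding_table = tibble::tibble(
      aptamer_id = ids, ligand_id = "mephedrone", kd_app = kd)
  )
}

#' Synthetic ligand panel for cross-reactivity profiling
#'
#' One high-affinity aptamer profiled against a panel of ligands: its main
#' target (mephedrone, apparent Kd 15 uM), a close structural analog
#' (methedrone) with 10-fold lower affinity, and a set of non-binding
#' compounds. Two of the non-binders carry fluorophore artifacts for the
#' strand-displacement comparison: a chlorpromazine-like strong binder that
#' attenuates the fluorophore to 10% and an acetyl-fentanyl-like non-binder
#' that enhances it by 30%.
#'
#' @param aptamer_id Id of the profiled aptamer (default `"MMC1"`).
#' @return A list with `aptamer` ([aptamer_spec()]), `binding_table`
#'   (tibble), and `conditions` (list of [ligand_condition()] at 200 uM).
#' @export
profile_ligand_panel <- function(aptamer_id = "MMC1") {
  binding <- tibble::tibble(
    aptamer_id = aptamer_id,
    ligand_id = c("mephedrone", "methedrone", "chlorpromazine",
                  "acetyl_fentanyl", "morphine", "lidocaine"),
    kd_app = c(15, 150, 0.6, Inf, Inf, Inf)
  )
  artifact <- c(mephedrone = 1, methedrone = 1, chlorpromazine = 0.1,
                acetyl_fentanyl = 1.3, morphine = 1, lidocaine = 1)
  conditions <- lapply(names(artifact), function(lg) {
    ligand_condition(lg, 200, dye_artifact_factor = unname(artifact[lg]))
  })
  list(
    aptamer = aptamer_spec(aptamer_id, full_length_nt = 73L,
                           protected_length_nt = 42L),
    binding_table = binding,
    conditions = conditions
  )
}

#' Standard calibration concentration series
#'
#' The seven-point ligand concentration series used for dose-response
#' calibration: 0, 25, 50, 100, 200, 400 and 800 uM.
#'
#' @return Numeric vector of concentrations in uM.
#' @export
calibration_concentrations <- function() {
  c(0, 25, 50, 100, 200, 400, 800)
}

#' Simulate a resistance dose-response series
#'
#' Runs the digestion simulator across a concentration series for one
#' aptamer-ligand pair and returns the resistance table (one row per
#' concentration), ready for [fit_dose_response()].
#'
#' @param aptamer An [aptamer_spec()].
#' @param binding A [binding_params()] carrying the true apparent Kd.
#' @param concentrations Concentration series, uM; must include 0 (the
#'   control). Defaults to [calibration_concentrations()].
#' @param n_replicates Replicates per concentration (default 3).
#' @param params,schedule Simulator settings.
#' @param seed Master seed.
#' @return A tibble as returned by [resistance_table()].
#' @export
simulate_dose_response <- function(aptamer, binding,
                                   concentrations = calibration_concentrations(),
                                   n_replicates = 3L,
                                   params = digestion_params(),
                                   schedule = sampling_schedule(),
                                   seed = 1L) {
  stopifnot(inherits(binding, "binding_params"))
  conc_pos <- setdiff(concentrations, 0)
  conditions <- lapply(conc_pos, function(cc) {
    ligand_condition(binding$ligand_id, cc)
  })
  bt <- tibble::tibble(aptamer_id = binding$aptamer_id,
                       ligand_id = binding$ligand_id,
                       kd_app = binding$kd_app)
  plate <- simulate_panel(list(aptamer), conditions, bt,
                          n_replicates = n_replicates, params = params,
                          schedule = schedule, seed = seed)
  rt <- resistance_table(plate)
  # the ligand-free control anchors the series at (0, 0): each control
  # replicate's resistance against the common (mean) denominator averages
  # to zero by construction, with the replicate scatter as its SD
  df <- tibble::as_tibble(plate)
  ctl <- df[df$concentration_uM == 0, ]
  auc0_reps <- vapply(split(ctl, ctl$replicate), function(w) {
    auc(w$time_min, w$fluorescence_au)$value
  }, numeric(1))
  r0 <- auc0_reps / mean(auc0_reps) - 1
  zero_row <- tibble::tibble(
    aptamer_id = aptamer$aptamer_id, ligand_id = binding$ligand_id,
    concentration_uM = 0, resistance_mean = 0,
    resistance_sd = if (length(r0) >= 2) stats::sd(r0) else NA_real_,
    n_replicates = length(r0), auc_control = mean(auc0_reps), flag = "ok")
  dplyr::bind_rows(zero_row, rt)
}
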