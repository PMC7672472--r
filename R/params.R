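#' Describe one aptamer candidate
#'
#' An aptamer spec records the identity, optional sequence, full length and
#' the length of the exonuclease-protected major product of one candidate.
#' Ligand binding stalls digestion at an internal site, leaving a truncated
#' product (e.g. a 41-nt product from a 46-nt aptamer); the ratio
#' `protected_length_nt / full_length_nt` sets the fluorescence plateau of a
#' fully protected well, because the intercalating dye signal scales with the
#' amount of retained DNA.
#'
#' @param aptamer_id Character scalar, unique within a panel.
#' @param full_length_nt Positive integer, full aptamer length N in
#'   nucleotides. If `sequence` is given, defaults to `nchar(sequence)`.
#' @param protected_length_nt Integer P with `0 < P <= N`: length of the
#'   ligand-protected digestion product.
#' @param sequence Optional IUPAC DNA string of length `full_length_nt`.
#' @return A list of class `aptamer_spec`.
#' @examples
#' aptamer_spec("MMC1", full_length_nt = 73, protected_length_nt = 42)
#' @export
aptamer_spec <- function(aptamer_id, full_length_nt = NULL,
                         protected_length_nt, sequence = NULL) {
  if (!is.character(aptamer_id) || length(aptamer_id) != 1L || is.na(aptamer_id) ||
      !nzchar(aptamer_id)) {
    stop("`aptamer_id` must be a non-empty character scalar", call. = FALSE)
  }
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (grepl("[^ACGTURYSWKMBDHVN]", sequence)) {
      stop("`sequence` contains non-IUPAC characters", call. = FALSE)
    }
    if (is.null(full_length_nt)) full_length_nt <- nchar(sequence)
    if (nchar(sequence) != full_length_nt) {
      stop("sequence length (", nchar(sequence), ") does not equal `full_length_nt` (",
           full_length_nt, ")", call. = FALSE)
    }
  }
  if (is.null(full_length_nt)) {
    stop("`full_length_nt` is required when no sequence is given", call. = FALSE)
  }
  full_length_nt <- as.integer(full_length_nt)
  protected_length_nt <- as.integer(protected_length_nt)
  if (is.na(full_length_nt) || full_length_nt <= 0L) {
    stop("`full_length_nt` must be a positive integer", call. = FALSE)
  }
  if (is.na(protected_length_nt) || protected_length_nt <= 0L ||
      protected_length_nt > full_length_nt) {
    stop("`protected_length_nt` must satisfy 0 < P <= N (got P = ",
         protected_length_nt, ", N = ", full_length_nt, ")", call. = FALSE)
  }
  structure(
    list(aptamer_id = aptamer_id, sequence = sequence,
         full_length_nt = full_length_nt,
         protected_length_nt = protected_length_nt),
    class = "aptamer_spec"
  )
}

#' @export
print.aptamer_spec <- function(x, ...) {
  cat("<aptamer_spec> ", x$aptamer_id, ": N = ", x$full_length_nt,
      " nt, protected product P = ", x$protected_length_nt, " nt\n", sep = "")
  invisible(x)
}

#' Phenomenological digestion-kinetics parameters
#'
#' The simulator treats exonucleolytic digestion of the unbound aptamer as a
#' first-order decay of stainable fluorescence at rate `k_unprotected`
#' (per minute), matching the exponential loss of signal seen for ligand-free
#' controls. The ligand-protected product is degraded much more slowly, at
#' `k_leak`. `amplitude` is the fluorescence of intact aptamer above
#' `background`; `noise_cv` is the multiplicative (constant-CV) plate-reader
#' noise. `exchange_mode` selects whether bound and free aptamer interconvert
#' slowly ("slow", default: each molecule keeps its initial bound/free state
#' through the digestion, which reproduces persistent protected products) or
#' fast ("fast": a single effective rate, the occupancy-weighted mean).
#'
#' Defaults are calibrated so that a ligand-free control digests to baseline
#' within ~1.5 h and a saturated binder's resistance value over a 4-h window
#' is ~1, the range reported for true binders in candidate screens.
#'
#' @param k_unprotected Digestion rate of unprotected DNA, per minute (> 0).
#' @param k_leak Slow digestion rate of the protected product, per minute
#'   (`0 <= k_leak < k_unprotected`).
#' @param amplitude Fluorescence amplitude of intact aptamer, a.u. (> 0).
#' @param background Constant background fluorescence, a.u. (>= 0).
#' @param noise_cv Coefficient of variation of multiplicative noise (>= 0).
#' @param exchange_mode `"slow"` or `"fast"`.
#' @return A list of class `digestion_params`.
#' @examples
#' digestion_params()
#' digestion_params(k_unprotected = 0.1, noise_cv = 0)
#' @export
digestion_params <- function(k_unprotected = 0.05, k_leak = 0.012,
                             amplitude = 100, background = 5,
                             noise_cv = 0.02, exchange_mode = c("slow", "fast")) {
  exchange_mode <- match.arg(exchange_mode)
  stopifnot(is.numeric(k_unprotected), length(k_unprotected) == 1L,
            is.numeric(k_leak), length(k_leak) == 1L,
            is.numeric(amplitude), length(amplitude) == 1L,
            is.numeric(background), length(background) == 1L,
            is.numeric(noise_cv), length(noise_cv) == 1L)
  if (!is.finite(k_unprotected) || k_unprotected <= 0) {
    stop("`k_unprotected` must be a positive finite rate", call. = FALSE)
  }
  if (!is.finite(k_leak) || k_leak < 0 || k_leak >= k_unprotected) {
    stop("`k_leak` must satisfy 0 <= k_leak < k_unprotected", call. = FALSE)
  }
  if (amplitude <= 0) stop("`amplitude` must be > 0", call. = FALSE)
  if (background < 0) stop("`background` must be >= 0", call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  structure(
    list(k_unprotected = k_unprotected, k_leak = k_leak,
         amplitude = amplitude, background = background,
         noise_cv = noise_cv, exchange_mode = exchange_mode),
    class = "digestion_params"
  )
}

#' One ligand condition of a digestion experiment
#'
#' `concentration = 0` denotes the ligand-free control well.
#' `dye_artifact_factor` models ligand-fluorophore interference in the
#' strand-displacement comparison: some compounds attenuate the fluorophore
#' (factor < 1, e.g. ~0.1 for a chlorpromazine-like quench) or enhance it
#' (factor > 1, e.g. ~1.3); 1 means no artifact. The exonuclease assay reads
#' an intercalating dye added after quenching the reaction, so the artifact
#' applies only to the strand-displacement readout.
#'
#' @param ligand_id Character scalar; use `"none"` for the ligand-free control.
#' @param concentration Ligand concentration in uM (>= 0).
#' @param dye_artifact_factor Positive multiplier on the strand-displacement
#'   fluorescence (default 1).
#' @return A list of class `ligand_condition`.
#' @export
ligand_condition <- function(ligand_id, concentration,
                             dye_artifact_factor = 1) {
  stopifnot(is.character(ligand_id), length(ligand_id) == 1L,
            is.numeric(concentration), length(concentration) == 1L,
            is.numeric(dye_artifact_factor), length(dye_artifact_factor) == 1L)
  if (!is.finite(concentration) || concentration < 0) {
    stop("`concentration` must be a finite value >= 0 (uM)", call. = FALSE)
  }
  if (!is.finite(dye_artifact_factor) || dye_artifact_factor <= 0) {
    stop("`dye_artifact_factor` must be > 0", call. = FALSE)
  }
  structure(
    list(ligand_id = ligand_id, concentration = concentration,
         dye_artifact_factor = dye_artifact_factor),
    class = "ligand_condition"
  )
}

#' Apparent binding affinity of one aptamer-ligand pair
#'
#' `kd_app = Inf` is the non-binder sentinel: no binding at any tested
#' concentration. Finite values are apparent dissociation constants in uM.
#'
#' @param aptamer_id,ligand_id Character scalars identifying the pair.
#' @param kd_app Apparent Kd in uM (> 0), or `Inf` for a non-binder.
#' @return A list of class `binding_params`.
#' @examples
#' binding_params("MMC1", "mephedrone", kd_app = 15)
#' binding_params("MMC7", "mephedrone", kd_app = Inf)  # non-binder
#' @export
binding_params <- function(aptamer_id, ligand_id, kd_app) {
  stopifnot(is.character(aptamer_id), length(aptamer_id) == 1L,
            is.character(ligand_id), length(ligand_id) == 1L,
            is.numeric(kd_app), length(kd_app) == 1L)
  if (is.na(kd_app) || kd_app <= 0) {
    stop("`kd_app` must be positive (finite uM) or Inf for a non-binder",
         call. = FALSE)
  }
  structure(
    list(aptamer_id = aptamer_id, ligand_id = ligand_id, kd_app = kd_app),
    class = "binding_params"
  )
}

#' Sampling schedule of a digestion time course
#'
#' Times are minutes since addition of the exonuclease mix; the first read is
#' at t = 0. `incubation_min` records the aptamer-ligand pre-incubation
#' (metadata only; it does not enter the kinetics).
#'
#' @param times Strictly increasing numeric vector of minutes, starting at 0,
#'   at least 4 points.
#' @param incubation_min Pre-digestion incubation, minutes (default 60).
#' @return A list of class `sampling_schedule`.
#' @examples
#' sampling_schedule(seq(0, 240, by = 15))
#' @export
sampling_schedule <- function(times = seq(0, 240, by = 15),
                              incubation_min = 60) {
  stopifnot(is.numeric(times), is.numeric(incubation_min),
            length(incubation_min) == 1L)
  if (length(times) < 4L) {
    stop("`times` must contain at least 4 points", call. = FALSE)
  }
  if (times[1] != 0) stop("first sampling time must be 0", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(times = as.numeric(times), incubation_min = incubation_min),
    class = "sampling_schedule"
  )
}

#' Strand-displacement assay parameters
#'
#' A fluorophore-labelled aptamer is pre-hybridised to a quencher-labelled
#' complementary strand; ligand binding displaces the complement and restores
#' fluorescence. `f_max` is the unquenched signal, `quench_efficiency` the
#' fraction of it suppressed in the duplex (optimised to > 0.9 in practice),
#' `kd_sd` the apparent half-saturation of displacement and
#' `max_displacement` the fraction of complexes displaceable at saturation
#' (typically well below 1 because displacement requires out-competing the
#' duplex).
#'
#' @param f_max Unquenched fluorescence, a.u. (> 0).
#' @param quench_efficiency Fraction in \[0, 1\]; default fixtures keep it
#'   >= 0.9.
#' @param kd_sd Apparent displacement half-saturation, uM (> 0, may be Inf
#'   for a non-responder).
#' @param max_displacement Fraction in \[0, 1\] displaced at saturating ligand.
#' @return A list of class `sd_params`.
#' @export
sd_params <- function(f_max = 100, quench_efficiency = 0.92,
                      kd_sd = 15, max_displacement = 0.6) {
  stopifnot(is.numeric(f_max), length(f_max) == 1L,
            is.numeric(quench_efficiency), length(quench_efficiency) == 1L,
            is.numeric(kd_sd), length(kd_sd) == 1L,
            is.numeric(max_displacement), length(max_displacement) == 1L)
  if (!is.finite(f_max) || f_max <= 0) stop("`f_max` must be > 0", call. = FALSE)
  if (quench_efficiency < 0 || quench_efficiency > 1) {
    stop("`quench_efficiency` must lie in [0, 1]", call. = FALSE)
  }
  if (is.na(kd_sd) || kd_sd <= 0) {
    stop("`kd_sd` must be > 0 (uM) or Inf", call. = FALSE)
  }
  if (max_displacement < 0 || max_displacement > 1) {
    stop("`max_displacement` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(f_max = f_max, quench_efficiency = quench_efficiency,
         kd_sd = kd_sd, max_displacement = max_displacement),
    class = "sd_params"
  )
}
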