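#' Area under a fluorescence time course
#'
#' Composite trapezoid over the recorded grid, from the first to the last
#' time point; irregular grids are supported. The AUC of the fluorescence
#' time course is the primitive underlying the resistance value: a protected
#' (slowly digested) well retains fluorescence longer and accumulates a
#' larger area than its ligand-free control.
#'
#' @param tc A time-course data frame with columns `time_min` and
#'   `fluorescence_au`, or a numeric vector of times (with `fluorescence`
#'   supplied).
#' @param fluorescence Numeric fluorescence values when `tc` is a time
#'   vector.
#' @param include_t0 Keep the t = 0 read (default). Set `FALSE` to start
#'   integration at the second time point.
#' @return An object of class `auc_value`: list with `value` (a.u. x min),
#'   `n_points`, `t_span` (minutes).
#' @examples
#' auc(data.frame(time_min = c(0, 45, 90), fluorescence_au = c(5, 5, 5)))
#' auc(c(0, 10), c(10, 0))  # triangle: 50
#' @export
auc <- function(tc, fluorescence = NULL, include_t0 = TRUE) {
  if (is.data.frame(tc)) {
    times <- tc$time_min
    values <- tc$fluorescence_au
    if (is.null(times) || is.null(values)) {
      stop("`tc` must have columns `time_min` and `fluorescence_au`",
           call. = FALSE)
    }
  } else {
    times <- tc
    values <- fluorescence
    if (is.null(values)) {
      stop("supply `fluorescence` when `tc` is a time vector", call. = FALSE)
    }
  }
  stopifnot(length(times) == length(values))
  if (!include_t0) {
    times <- times[-1]
    values <- values[-1]
  }
  if (length(times) < 2L) {
    stop("at least 2 time points are required to integrate", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(
    list(value = pracma::trapz(times, values),
         n_points = length(times),
         t_span = times[length(times)] - times[1]),
    class = "auc_value"
  )
}

#' @export
print.auc_value <- function(x, ...) {
  cat("<auc_value> ", format(x$value), " a.u.*min over ", x$t_span,
      " min (", x$n_points, " points)\n", sep = "")
  invisible(x)
}

auc_num <- function(x) {
  if (inherits(x, "auc_value")) x$value else as.numeric(x)
}

#' Resistance value of an aptamer under ligand
#'
#' The resistance value quantifies ligand-conferred protection from
#' exonuclease digestion:
#' \deqn{R = (AUC_1 - AUC_0) / AUC_0}
#' where AUC_1 and AUC_0 are the areas under the fluorescence time course
#' with and without ligand. R = 0 means digestion is unchanged by ligand;
#' higher values mean stronger protection, hence tighter binding. Negative
#' values are reported raw (not clipped) so that artifact-like behaviour
#' stays visible.
#'
#' @param auc_ligand AUC with ligand ([auc()] result or a number).
#' @param auc_control AUC of the ligand-free control (> 0).
#' @return The resistance value, dimensionless.
#' @examples
#' resistance_value(900, 450)  # 1: area doubled by protection
#' @export
resistance_value <- function(auc_ligand, auc_control) {
  a1 <- auc_num(auc_ligand)
  a0 <- auc_num(auc_control)
  if (!is.finite(a0) || a0 <= 0) {
    stop("control AUC must be positive and finite (got ", a0, ")",
         call. = FALSE)
  }
  (a1 - a0) / a0
}

#' Exonuclease-assay cross-reactivity
#'
#' Protection conferred by a test ligand relative to the reference target:
#' \deqn{CR = 100 (AUC_L - AUC_0) / (AUC_T - AUC_0)}
#' With a shared control AUC this equals `100 * R_L / R_T`. The reference
#' ligand's own cross-reactivity is 100 by construction.
#'
#' @param auc_L AUC with the test ligand.
#' @param auc_T AUC with the reference (main) target; must exceed `auc_0`.
#' @param auc_0 AUC of the shared ligand-free control.
#' @return Cross-reactivity in percent (may be negative; reported raw).
#' @examples
#' cross_reactivity(675, 900, 450)  # 50%
#' @export
cross_reactivity <- function(auc_L, auc_T, auc_0) {
  aL <- auc_num(auc_L)
  aT <- auc_num(auc_T)
  a0 <- auc_num(auc_0)
  if (!is.finite(aT) || aT <= a0) {
    stop("reference target must protect: need AUC_T > AUC_0 (got ",
         aT, " <= ", a0, ")", call. = FALSE)
  }
  100 * (aL - a0) / (aT - a0)
}

#' Strand-displacement signal gain
#'
#' \deqn{S = (F - F_0) / F_0}
#' where F and F_0 are the fluorescence with and without ligand. Negative
#' gains are allowed: ligands that attenuate the fluorophore produce
#' negative apparent gains even when they bind.
#'
#' @param f Fluorescence with ligand, a.u.
#' @param f0 Ligand-free fluorescence, a.u. (> 0).
#' @return Signal gain, dimensionless.
#' @examples
#' signal_gain(130, 100)  # 0.3
#' signal_gain(10, 100)   # -0.9
#' @export
signal_gain <- function(f, f0) {
  if (!is.numeric(f0) || any(!is.finite(f0)) || any(f0 <= 0)) {
    stop("`f0` must be positive and finite", call. = FALSE)
  }
  (f - f0) / f0
}

#' Strand-displacement cross-reactivity
#'
#' \deqn{CR = 100 S_L / S_T}
#' the signal gain of a test ligand relative to that of the main target. A
#' negative test gain yields a negative CR, reported raw; such entries are
#' artifact-suspect (a true binder whose ligand quenches the fluorophore
#' shows exactly this signature).
#'
#' @param s_L Signal gain of the test ligand.
#' @param s_T Signal gain of the main target (> 0).
#' @return Cross-reactivity in percent.
#' @export
sd_cross_reactivity <- function(s_L, s_T) {
  if (!is.numeric(s_T) || any(!is.finite(s_T)) || any(s_T <= 0)) {
    stop("reference signal gain must be positive (got ", s_T, ")",
         call. = FALSE)
  }
  100 * s_L / s_T
}

# Per-replicate AUC of every ligand well, against the mean control AUC of
# the same aptamer evaluated on the overlap of the two time grids (control
# linearly interpolated onto the ligand grid; no extrapolation).
well_aucs <- function(plate) {
  stopifnot(inherits(plate, "plate_experiment"))
  df <- tibble::as_tibble(plate)
  dplyr::summarise(
    dplyr::group_by(df, .data$aptamer_id, .data$ligand_id,
                    .data$concentration_uM, .data$replicate),
    times = list(.data$time_min), values = list(.data$fluorescence_au),
    .groups = "drop"
  )
}

#' Resistance values for every aptamer-ligand-concentration condition
#'
#' Computes AUCs per replicate, aggregates controls into a common
#' denominator, and reports the replicate mean and SD of the resistance
#' value for each condition. When ligand and control wells were read on
#' different time grids, the control curve is linearly interpolated onto the
#' ligand grid and both areas are taken over the overlap of the two grids
#' only (no extrapolation). `AUC_0` is the mean over control replicates;
#' each ligand replicate's resistance uses that common denominator.
#'
#' @param plate A [plate_experiment()].
#' @param include_t0 Include the t = 0 read in the AUCs (default `TRUE`).
#' @return A tibble with one row per (aptamer, ligand, concentration):
#'   `resistance_mean`, `resistance_sd` (NA when n < 2), `n_replicates`,
#'   `auc_control`, and `flag` (`"negative"` for R < 0, else `"ok"`).
#' @examples
#' apt <- aptamer_spec("MMC1", 73, 42)
#' bt <- data.frame(aptamer_id = "MMC1", ligand_id = "mephedrone", kd_app = 15)
#' plate <- simulate_panel(list(apt), list(ligand_condition("mephedrone", 200)),
#'                         bt, n_replicates = 3, seed = 7)
#' resistance_table(plate)
#' @export
resistance_table <- function(plate, include_t0 = TRUE) {
  wells <- well_aucs(plate)
  controls <- wells[wells$concentration_uM == 0, ]
  ligands <- wells[wells$concentration_uM > 0, ]
  if (nrow(ligands) == 0) {
    return(tibble::tibble(
      aptamer_id = character(0), ligand_id = character(0),
      concentration_uM = numeric(0), resistance_mean = numeric(0),
      resistance_sd = numeric(0), n_replicates = integer(0),
      auc_control = numeric(0), flag = character(0)))
  }
  conds <- dplyr::distinct(ligands, .data$aptamer_id, .data$ligand_id,
                           .data$concentration_uM)
  out <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    cond <- conds[i, ]
    lw <- ligands[ligands$aptamer_id == cond$aptamer_id &
                  ligands$ligand_id == cond$ligand_id &
                  ligands$concentration_uM == cond$concentration_uM, ]
    cw <- controls[controls$aptamer_id == cond$aptamer_id, ]
    if (nrow(cw) == 0) {
      stop("no ligand-free control for aptamer ", cond$aptamer_id,
           call. = FALSE)
    }
    # overlap of the ligand grid with the control span
    lt <- lw$times[[1]]
    ct_range <- range(unlist(cw$times))
    span <- c(max(min(lt), ct_range[1]), min(max(lt), ct_range[2]))
    if (span[2] <= span[1]) {
      stop("no time-grid overlap between ligand and control wells for ",
           cond$aptamer_id, "/", cond$ligand_id, call. = FALSE)
    }
    grid <- lt[lt >= span[1] & lt <= span[2]]
    auc0_reps <- vapply(seq_len(nrow(cw)), function(j) {
      y <- stats::approx(cw$times[[j]], cw$values[[j]], xout = grid)$y
      auc(grid, y, include_t0 = include_t0)$value
    }, numeric(1))
    auc0 <- mean(auc0_reps)
    r_reps <- vapply(seq_len(nrow(lw)), function(j) {
      keep <- lw$times[[j]] >= span[1] & lw$times[[j]] <= span[2]
      a1 <- auc(lw$times[[j]][keep], lw$values[[j]][keep],
                include_t0 = include_t0)$value
      resistance_value(a1, auc0)
    }, numeric(1))
    out[[i]] <- tibble::tibble(
      aptamer_id = cond$aptamer_id, ligand_id = cond$ligand_id,
      concentration_uM = cond$concentration_uM,
      resistance_mean = mean(r_reps),
      resistance_sd = if (length(r_reps) >= 2) stats::sd(r_reps) else NA_real_,
      n_replicates = length(r_reps),
      auc_control = auc0,
      flag = if (mean(r_reps) < 0) "negative" else "ok"
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$aptamer_id, .data$ligand_id,
                 .data$concentration_uM)
}
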