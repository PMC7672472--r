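#' Call binders in a candidate screen
#'
#' Thresholds the replicate-mean resistance values of a candidate panel
#' screened at one shared ligand concentration. True binders in such screens
#' show resistance values near 1 while non-binders sit near zero, so the
#' default threshold 0.1 lies far from both clusters. Ties (R equal to the
#' threshold) are called binders. A companion z-score criterion
#' (`resistance_mean / resistance_sd >= 3`) is reported as `z_pass` but does
#' not change the call.
#'
#' @param results Resistance table (one row per candidate) as returned by
#'   [resistance_table()]; all rows must share one screening concentration.
#' @param threshold Resistance threshold for a binder call (default 0.1).
#' @return A tibble sorted by resistance descending with columns
#'   `aptamer_id`, `resistance_mean`, `resistance_sd`, `call`,
#'   `threshold_used`, `z_pass`.
#' @export
call_binders <- function(results, threshold = 0.1) {
  stopifnot(is.data.frame(results),
            all(c("aptamer_id", "resistance_mean") %in% names(results)))
  if (anyDuplicated(results$aptamer_id)) {
    stop("duplicate aptamer ids in screen: ",
         paste(unique(results$aptamer_id[duplicated(results$aptamer_id)]),
               collapse = ", "), call. = FALSE)
  }
  if ("concentration_uM" %in% names(results) &&
      length(unique(results$concentration_uM)) > 1) {
    stop("mixed screening concentrations (",
         paste(sort(unique(results$concentration_uM)), collapse = ", "),
         " uM); screen candidates at a single shared concentration",
         call. = FALSE)
  }
  sd_col <- if ("resistance_sd" %in% names(results)) {
    results$resistance_sd
  } else {
    rep(NA_real_, nrow(results))
  }
  out <- tibble::tibble(
    aptamer_id = results$aptamer_id,
    resistance_mean = results$resistance_mean,
    resistance_sd = sd_col,
    call = ifelse(results$resistance_mean >= threshold, "binder",
                  "non-binder"),
    threshold_used = threshold,
    z_pass = !is.na(sd_col) & sd_col > 0 &
      results$resistance_mean / sd_col >= 3
  )
  dplyr::arrange(out, dplyr::desc(.data$resistance_mean), .data$aptamer_id)
}

#' Build a cross-reactivity profile for one aptamer
#'
#' Converts per-ligand resistance values into cross-reactivity percentages
#' relative to a reference (main) target, using the shared ligand-free
#' control. Because all ligands of one aptamer share the control AUC,
#' `CR = 100 * R_L / R_T`. Entries below 10% are annotated
#' `"not significant"`, the conventional reporting bound for negligible
#' cross-reactivity; negative entries are flagged.
#'
#' @param results Resistance table for a single aptamer (one row per
#'   ligand), as returned by [resistance_table()].
#' @param reference_ligand Ligand id of the main target; its resistance
#'   must be positive.
#' @param significance_bound CR percentage below which an entry is
#'   annotated not significant (default 10).
#' @return A tibble with `ligand_id`, `cr_percent`, `reference_ligand_id`,
#'   `annotation` (`"reference"`, `"significant"`, `"not significant"`),
#'   `flag`. The reference entry is exactly 100.
#' @export
build_profile <- function(results, reference_ligand,
                          significance_bound = 10) {
  stopifnot(is.data.frame(results),
            all(c("ligand_id", "resistance_mean") %in% names(results)))
  if ("aptamer_id" %in% names(results) &&
      length(unique(results$aptamer_id)) > 1) {
    stop("profile must cover a single aptamer", call. = FALSE)
  }
  ref <- results[results$ligand_id == reference_ligand, ]
  if (nrow(ref) == 0) {
    stop("reference ligand '", reference_ligand, "' absent from results",
         call. = FALSE)
  }
  r_t <- ref$resistance_mean[1]
  if (!is.finite(r_t) || r_t <= 0) {
    stop("reference ligand must protect (R_T > 0; got ", r_t, ")",
         call. = FALSE)
  }
  cr <- 100 * results$resistance_mean / r_t
  cr[results$ligand_id == reference_ligand] <- 100  # analytic identity
  out <- tibble::tibble(
    ligand_id = results$ligand_id,
    cr_percent = cr,
    reference_ligand_id = reference_ligand,
    annotation = dplyr::case_when(
      results$ligand_id == reference_ligand ~ "reference",
      cr < significance_bound ~ "not significant",
      TRUE ~ "significant"
    ),
    flag = ifelse(cr < 0, "negative", "ok")
  )
  dplyr::arrange(out, dplyr::desc(.data$cr_percent), .data$ligand_id)
}

#' Fit a resistance dose-response curve
#'
#' Fits the rectangular hyperbola
#' \deqn{R(c) = R_{max} \, c / (k_{half} + c)}
#' to resistance values measured over a ligand concentration series, by
#' constrained least squares (Levenberg-Marquardt with non-negativity
#' bounds). This is the minimal model consistent with fraction-bound
#' occupancy driving protection; `k_half` is an apparent half-saturation
#' constant, not an ITC dissociation constant. Initial values: `r_max` from
#' the maximal observed resistance and `k_half` from the concentration at
#' half-maximum (linear interpolation). A bootstrap over concentration-level
#' residual resampling gives a percentile confidence interval for `k_half`.
#'
#' An all-zero (or all-non-positive) resistance vector returns the
#' non-binder sentinel: `converged = FALSE`, `k_half = Inf`, `r_max = 0`.
#'
#' @param concentrations Ligand concentrations, uM; at least 4 distinct
#'   values including 0.
#' @param resistances Resistance values, same length.
#' @param n_boot Bootstrap resamples for the CI (default 200; 0 disables).
#' @param seed Integer seed for the bootstrap.
#' @return A list of class `dose_response_fit`: `k_half`, `r_max`, `rss`,
#'   `converged`, `ci_k_half` (length-2 numeric, NA when disabled or
#'   degenerate), `n_obs`.
#' @examples
#' conc <- c(0, 25, 50, 100, 200, 400, 800)
#' fit_dose_response(conc, 1 * conc / (100 + conc), n_boot = 0)
#' @export
fit_dose_response <- function(concentrations, resistances, n_boot = 200,
                              seed = 1L) {
  stopifnot(is.numeric(concentrations), is.numeric(resistances),
            length(concentrations) == length(resistances))
  if (any(!is.finite(resistances)) || any(!is.finite(concentrations))) {
    stop("concentrations and resistances must be finite", call. = FALSE)
  }
  if (length(unique(concentrations)) < 4L || !any(concentrations == 0)) {
    stop("need >= 4 distinct concentrations including 0", call. = FALSE)
  }
  df <- data.frame(c = concentrations, r = resistances)
  if (all(df$r <= 0)) {
    return(structure(
      list(k_half = Inf, r_max = 0, rss = sum(df$r^2), converged = FALSE,
           ci_k_half = c(NA_real_, NA_real_), n_obs = nrow(df)),
      class = "dose_response_fit"))
  }
  fit1 <- fit_hyperbola(df)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    # resample residuals within the fitted curve, refit per resample
    set.seed(as.integer(seed))
    pred <- fit1$r_max * df$c / (fit1$k_half + df$c)
    resid <- df$r - pred
    ks <- vapply(seq_len(n_boot), function(b) {
      db <- data.frame(c = df$c, r = pred + sample(resid, replace = TRUE))
      fb <- tryCatch(fit_hyperbola(db), error = function(e) NULL)
      if (is.null(fb) || !fb$converged) NA_real_ else fb$k_half
    }, numeric(1))
    ks <- ks[is.finite(ks)]
    if (length(ks) >= 20) {
      ci <- unname(stats::quantile(ks, c(0.025, 0.975)))
    }
  }
  structure(
    list(k_half = fit1$k_half, r_max = fit1$r_max, rss = fit1$rss,
         converged = fit1$converged, ci_k_half = ci, n_obs = nrow(df)),
    class = "dose_response_fit")
}

# Constrained LM fit of r ~ r_max * c / (k_half + c)
fit_hyperbola <- function(df) {
  r_max0 <- max(df$r)
  half <- r_max0 / 2
  ord <- order(df$c)
  cs <- df$c[ord]; rs <- df$r[ord]
  # first concentration where the (monotone-smoothed) response crosses half-max
  rs_mono <- cummax(rs)
  idx <- which(rs_mono >= half)[1]
  k0 <- if (is.na(idx) || idx == 1L) {
    max(cs[cs > 0][1], 1e-6)
  } else {
    stats::approx(rs_mono[c(idx - 1L, idx)], cs[c(idx - 1L, idx)],
                  xout = half, ties = "ordered")$y
  }
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(cs[cs > 0])
  fit <- minpack.lm::nlsLM(
    r ~ r_max * c / (k_half + c), data = df,
    start = list(r_max = max(r_max0, 1e-6), k_half = k0),
    lower = c(r_max = 0, k_half = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  est <- stats::coef(fit)
  list(r_max = unname(est["r_max"]), k_half = unname(est["k_half"]),
       rss = sum(stats::resid(fit)^2),
       converged = fit$convInfo$isConv %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged && is.infinite(x$k_half)) {
    cat("<dose_response_fit> non-binder (no positive resistance)\n")
  } else {
    cat("<dose_response_fit> k_half = ", format(x$k_half, digits = 4),
        " uM, r_max = ", format(x$r_max, digits = 4),
        ", rss = ", format(x$rss, digits = 3), "\n", sep = "")
    if (all(is.finite(x$ci_k_half))) {
      cat("  bootstrap 95% CI for k_half: [",
          format(x$ci_k_half[1], digits = 4), ", ",
          format(x$ci_k_half[2], digits = 4), "] uM\n", sep = "")
    }
  }
  invisible(x)
}
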