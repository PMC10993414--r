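# Concentration-response fitting and effect-concentration derivation.
#
# A constrained four-parameter log-logistic model is used for cytotoxicity
# and MMP (bottom fixed at 0 because effects are control-normalised, top in
# (0, 100], hill > 0), fitted by least squares on the log10-dose axis with
# a deterministic multistart over ec50. The oxidative-stress endpoint uses
# a linear induction-ratio model with forced intercept 1 on the low-effect
# region below cytotoxic concentrations.

#' Forward four-parameter log-logistic curve
#'
#' effect(c) = bottom + (top - bottom) / (1 + (ec50/c)^hill)
#'
#' @param conc dose vector (same units as ec50)
#' @param bottom,top asymptotes in percent effect
#' @param ec50 dose of half-maximal effect
#' @param hill slope parameter (> 0)
#' @return percent effect at each dose
#' @export
loglogistic_effect <- function(conc, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
}

#' Fit a constrained log-logistic concentration-response curve
#'
#' Pools all measurements for one treatment and endpoint (across runs and
#' technical replicates) and fits effect(c) = top / (1 + (ec50/c)^hill)
#' by least squares, with top constrained to (0, 100] and hill > 0. The
#' bottom asymptote is fixed at 0: effects are defined relative to the
#' plate's solvent controls, so the zero-dose asymptote is 0 by
#' construction. Optimisation is deterministic: L-BFGS-B started from a
#' grid of 5 ec50 values spanning the tested dose range.
#'
#' A treatment is called active when the fit converged, the fitted top
#' reaches `effect_level`, and the derived effect concentration lies
#' between one tenth of the lowest tested dose and the highest tested dose
#' (no far extrapolation).
#'
#' @param data data.frame with columns `dose` (> 0) and `value` (percent
#'   effect) for one treatment and endpoint
#' @param treatment_id,endpoint identifiers carried into the result
#' @param effect_level percent effect at which the effect concentration is
#'   derived (default 10, i.e. IC10/EC10)
#' @param mask optional vector of doses to exclude before fitting, with
#'   `mask_reason` recorded in the result
#' @param mask_reason reason string stored alongside masked doses
#' @return object of class `mitotox_fit`: model `"loglogistic4"`, `params`
#'   (bottom, top, ec50, hill), `effect_conc`, `active`, `reason`,
#'   `mask_info`, `n_points`, `runs_used`, `converged`, `sse`
#' @export
fit_loglogistic <- function(data, treatment_id = "", endpoint = "",
                            effect_level = 10, mask = NULL,
                            mask_reason = NULL) {
  data <- data[is.finite(data$dose) & data$dose > 0 & is.finite(data$value), ]
  mask_info <- list(excluded_doses = numeric(0), reason = NA_character_)
  if (!is.null(mask) && length(mask)) {
    drop <- data$dose %in% mask
    mask_info <- list(excluded_doses = sort(unique(data$dose[drop])),
                      reason = mask_reason %||% "masked")
    data <- data[!drop, , drop = FALSE]
  }
  doses <- sort(unique(data$dose))
  runs_used <- if ("run_id" %in% names(data)) length(unique(data$run_id)) else 1L
  base <- fit_skeleton(treatment_id, endpoint, "loglogistic4", mask_info,
                       nrow(data), runs_used)
  if (length(doses) < 5)
    stop(sprintf("fit_loglogistic: %d distinct dose(s), need >= 5",
                 length(doses)), call. = FALSE)

  lc <- log10(data$dose)
  sse_fun <- function(par) {
    pred <- par[1] / (1 + 10^((par[2] - lc) * par[3]))
    sum((data$value - pred)^2)
  }
  lo <- c(1e-6, min(lc) - 3, 0.05)
  hi <- c(100, max(lc) + 3, 15)
  top0 <- min(100, max(10, max(stats::quantile(data$value, 0.95), 10)))
  starts <- seq(min(lc), max(lc), length.out = 5)
  trials <- lapply(starts, function(s) tryCatch(
    stats::optim(c(top0, s, 1), sse_fun, method = "L-BFGS-B",
                 lower = lo, upper = hi,
                 control = list(factr = 1e4, maxit = 500)),
    error = function(e) NULL))
  trials <- Filter(Negate(is.null), trials)
  # prefer starts that converged cleanly; fall back to the best overall
  converged <- Filter(function(f) f$convergence == 0, trials)
  pool <- if (length(converged)) converged else trials
  if (!length(pool)) {
    base$active <- FALSE
    base$reason <- "optimisation failed to converge"
    return(base)
  }
  best <- pool[[which.min(vapply(pool, `[[`, 0, "value"))]]
  top <- best$par[1]; ec50 <- 10^best$par[2]; hill <- best$par[3]
  base$params <- c(bottom = 0, top = top, ec50 = ec50, hill = hill)
  base$converged <- length(converged) > 0
  base$sse <- best$value
  if (top < effect_level) {
    base$active <- FALSE
    base$reason <- sprintf("fitted top below %g%% effect", effect_level)
    return(base)
  }
  if (!base$converged) {
    base$active <- FALSE
    base$reason <- "optimisation failed to converge"
    return(base)
  }
  ec <- effect_conc_at(base, effect_level)
  base$effect_conc <- ec
  if (!is.finite(ec) || ec < min(doses) / 10 || ec > max(doses)) {
    base$active <- FALSE
    base$reason <- "effect concentration outside tested range"
  } else {
    base$active <- TRUE
  }
  base
}

fit_skeleton <- function(treatment_id, endpoint, model, mask_info,
                         n_points, runs_used) {
  structure(list(treatment_id = treatment_id, endpoint = endpoint,
                 model = model,
                 params = c(bottom = NA_real_, top = NA_real_,
                            ec50 = NA_real_, hill = NA_real_),
                 effect_conc = NA_real_, active = NA, reason = NA_character_,
                 mask_info = mask_info, n_points = n_points,
                 runs_used = runs_used, converged = NA, sse = NA_real_),
            class = "mitotox_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Invert a fitted log-logistic curve at a given effect level
#'
#' Closed-form inversion c = ec50 * ((level - bottom) / (top - level))^(1/hill).
#' At level 10 this is the IC10 (cytotoxicity) or EC10 (MMP). Returns NA
#' when the fitted top does not reach the requested level (the effect is
#' not attained within the model).
#'
#' @param fit a `mitotox_fit` with model `"loglogistic4"`
#' @param level percent effect in (bottom, top)
#' @return the dose producing `level` percent effect, or NA
#' @export
effect_conc_at <- function(fit, level) {
  stopifnot(inherits(fit, "mitotox_fit"), fit$model == "loglogistic4")
  p <- fit$params
  if (anyNA(p)) return(NA_real_)
  if (level <= p[["bottom"]] || p[["top"]] <= level) return(NA_real_)
  unname(p[["ec50"]] *
           ((level - p[["bottom"]]) / (p[["top"]] - level))^(1 / p[["hill"]]))
}

#' Fit the linear induction-ratio model and derive EC_IR1.5
#'
#' Doses above the cytotoxicity IC10 are excluded before fitting: the
#' cytotoxicity burst inflates reporter signals, so only the low-effect
#' region is informative. On the retained doses a straight line
#' IR = 1 + slope * c is fitted by least squares with the intercept forced
#' to 1 (the induction ratio of a solvent control is 1 by definition).
#' EC_IR1.5 = 0.5 / slope. The fit is inactive when fewer than 3 distinct
#' doses survive masking ("over-masked"), when the slope is not positive,
#' or when EC_IR1.5 exceeds the highest retained dose.
#'
#' @param data data.frame with `dose` and `value` (induction ratio) for one
#'   treatment
#' @param ic10 cytotoxicity IC10 used as the masking cutoff, or NA/NULL to
#'   skip masking
#' @param treatment_id identifier carried into the result
#' @param ir_threshold induction ratio defining the effect concentration
#'   (default 1.5, i.e. EC_IR1.5 = 0.5/slope)
#' @return a `mitotox_fit` with model `"linear_low_effect"`, `params`
#'   containing `slope` (IR per unit dose), and `effect_conc` = EC_IR1.5
#' @export
fit_ecir15 <- function(data, ic10 = NULL, treatment_id = "",
                       ir_threshold = 1.5) {
  stopifnot(ir_threshold > 1)
  data <- data[is.finite(data$dose) & data$dose > 0 & is.finite(data$value), ]
  mask_info <- list(excluded_doses = numeric(0), reason = NA_character_)
  if (!is.null(ic10) && is.finite(ic10)) {
    drop <- data$dose > ic10
    if (any(drop))
      mask_info <- list(excluded_doses = sort(unique(data$dose[drop])),
                        reason = "above cytotoxicity IC10")
    data <- data[!drop, , drop = FALSE]
  }
  runs_used <- if ("run_id" %in% names(data)) length(unique(data$run_id)) else 1L
  base <- fit_skeleton(treatment_id, "oxidative_stress", "linear_low_effect",
                       mask_info, nrow(data), runs_used)
  base$params <- c(slope = NA_real_)
  doses <- unique(data$dose)
  if (length(doses) < 3) {
    base$active <- FALSE
    base$reason <- "over-masked"
    return(base)
  }
  # least squares for IR - 1 = slope * c through the origin
  slope <- sum(data$dose * (data$value - 1)) / sum(data$dose^2)
  base$params <- c(slope = slope)
  base$converged <- TRUE
  if (slope <= 0) {
    base$active <- FALSE
    base$reason <- "non-positive slope"
    return(base)
  }
  ec <- (ir_threshold - 1) / slope
  base$effect_conc <- ec
  if (ec > max(doses)) {
    base$active <- FALSE
    base$reason <- "EC_IR1.5 beyond highest retained dose"
  } else {
    base$active <- TRUE
  }
  base
}

#' Apply the 10 x IC10 secondary-cytotoxicity rule to an MMP fit
#'
#' When the EC10 for MMP loss lies more than 10-fold above the
#' cytotoxicity IC10, the apparent MMP effect occurs only at doses that
#' are already strongly cytotoxic and is treated as a secondary
#' consequence of cell death: the fit is marked inactive with reason
#' "secondary to cytotoxicity" and no EC10 is reported. The boundary is
#' inclusive: EC10 equal to exactly `multiplier * IC10` is retained.
#'
#' @param fit_mmp a `mitotox_fit` for the MMP endpoint
#' @param ic10 cytotoxicity IC10 (same units), or NA/NULL when cytotoxicity
#'   was not reached (rule not applied)
#' @param multiplier cutoff multiplier (default 10)
#' @return the (possibly deactivated) `mitotox_fit`
#' @export
derive_ec10_mmp <- function(fit_mmp, ic10 = NULL, multiplier = 10) {
  stopifnot(inherits(fit_mmp, "mitotox_fit"))
  if (isTRUE(fit_mmp$active) && !is.null(ic10) && is.finite(ic10) &&
      fit_mmp$effect_conc > multiplier * ic10) {
    fit_mmp$active <- FALSE
    fit_mmp$reason <- "secondary to cytotoxicity"
  }
  fit_mmp
}

#' @export
print.mitotox_fit <- function(x, ...) {
  cat(sprintf("<mitotox_fit> %s / %s [%s]\n", x$treatment_id, x$endpoint,
              x$model))
  p <- x$params[!is.na(x$params)]
  if (length(p))
    cat("  params:", paste(sprintf("%s=%.4g", names(p), p), collapse = ", "),
        "\n")
  cat(sprintf("  effect_conc: %s  active: %s%s\n",
              format(x$effect_conc, digits = 4), x$active,
              if (!is.na(x$reason)) paste0("  (", x$reason, ")") else ""))
  if (length(x$mask_info$excluded_doses))
    cat(sprintf("  masked %d dose(s): %s\n",
                length(x$mask_info$excluded_doses), x$mask_info$reason))
  invisible(x)
}

#' Flatten a list of fits to a tidy table
#'
#' @param fits list of `mitotox_fit` objects
#' @return data.frame with one row per fit (treatment, endpoint, model,
#'   parameters, effect_conc, active, reason, bookkeeping counts)
#' @export
fits_to_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    data.frame(treatment_id = f$treatment_id, endpoint = f$endpoint,
               model = f$model,
               bottom = if ("bottom" %in% names(f$params)) f$params[["bottom"]] else NA_real_,
               top = if ("top" %in% names(f$params)) f$params[["top"]] else NA_real_,
               ec50 = if ("ec50" %in% names(f$params)) f$params[["ec50"]] else NA_real_,
               hill = if ("hill" %in% names(f$params)) f$params[["hill"]] else NA_real_,
               slope = if ("slope" %in% names(f$params)) f$params[["slope"]] else NA_real_,
               effect_conc = f$effect_conc, active = f$active,
               reason = f$reason, n_points = f$n_points,
               runs_used = f$runs_used, stringsAsFactors = FALSE)
  })
  reset_rows(do.call(rbind, rows))
}
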