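#' Predict clinical tumor response from mouse PD and human PK
#'
#' Simulates a clinical dosing regimen by driving the
#' tumor-growth-inhibition model (mouse-fitted PD parameters carried over
#' unchanged, including the initial tumor volume) with the free-ADC plasma
#' concentration predicted by the shed-target TMDD model, and classifies
#' the outcome from the terminal-to-initial volume ratio.
#'
#' Because clinical tumors grow far more slowly than mouse xenografts,
#' stasis under mouse growth parameters is a conservative readout:
#' predictions achieving stasis are interpreted as at least stable
#' disease in patients.
#'
#' @param pd A [tgi_params()] object (mouse-fitted PD; `pd$v0` is carried
#'   over as the clinical initial volume unless `v0` is given).
#' @param human_pk A [tmdd_params()] object (predicted human PK).
#' @param regimen A [dosing_regimen()] (e.g. Q3W x 4, 1-h infusions).
#' @param horizon Evaluation time (day); default last dose + 21 days.
#' @param v0 Initial tumor volume (mm^3).
#' @param thresholds Named vector `c(regression = 0.8, regrowth = 1.2)`:
#'   the outcome is `regression` if `TV(horizon)/v0` falls below the
#'   first value, `regrowth` above the second, `stasis` between.
#' @param model_id Optional label.
#' @param dt Output/forcing grid step (day).
#' @return An object of class `clinical_prediction`: list with
#'   `model_id`, `outcome`, `tv_ratio_end`, `trajectory` (data frame
#'   `time_day`, `TV`, `conc_ugml`), `regimen`, `thresholds`,
#'   `interpretation`.
#' @export
#' @examples
#' n87 <- tgi_params(0.068, 26.8, 4600, 2.54, 0.15, 1.24, 1, v0 = 200)
#' pk <- two_cpt_params(38.1, 5.52, 20.2, 14.9)
#' human <- tmdd_params(pk, KD = 0.1, kon = 61.3, kshed = 6.65,
#'                      kdeg = 33.3, kel_complex = 32.6)
#' pred <- predict_clinical(n87, human,
#'                          dosing_regimen_q(1, 21, 4, infusion_h = 1))
#' pred$outcome
predict_clinical <- function(pd, human_pk, regimen, horizon = NULL,
                             v0 = pd$v0,
                             thresholds = c(regression = 0.8,
                                            regrowth = 1.2),
                             model_id = NULL, dt = 0.05) {
  stopifnot(inherits(pd, "tgi_params"), inherits(human_pk, "tmdd_params"),
            inherits(regimen, "dosing_regimen"))
  if (!all(c("regression", "regrowth") %in% names(thresholds)) ||
      thresholds[["regression"]] > thresholds[["regrowth"]]) {
    stop_invalid("predict_clinical: thresholds must contain regression <= ",
                 "regrowth")
  }
  if (is.null(horizon)) {
    horizon <- max(regimen$time_day + regimen$infusion_day) + 21
  }
  last_event <- max(regimen$time_day + regimen$infusion_day)
  if (horizon < last_event) {
    stop_invalid("predict_clinical: horizon precedes the last dose")
  }
  grid <- seq(0, horizon, by = dt)
  if (grid[length(grid)] < horizon) grid <- c(grid, horizon)
  tm <- simulate_tmdd(human_pk, regimen, times = grid)
  free <- concentration_profile(tm$time_day, tm$free_ugml,
                                unit = "ug/mL", analyte = "free")
  tgi_times <- unique(c(seq(0, horizon, by = max(dt, 0.25)), horizon))
  traj <- simulate_tgi(pd, conc = free, times = tgi_times, v0 = v0)
  tv_end <- traj$TV[nrow(traj)]
  ratio <- tv_end / v0
  outcome <- if (ratio < thresholds[["regression"]]) "regression"
             else if (ratio > thresholds[["regrowth"]]) "regrowth"
             else "stasis"
  structure(list(model_id = model_id, outcome = outcome,
                 tv_ratio_end = ratio,
                 trajectory = data.frame(time_day = traj$time_day,
                                         TV = traj$TV,
                                         conc_ugml = traj$conc),
                 regimen = regimen, horizon = horizon, v0 = v0,
                 thresholds = thresholds,
                 interpretation = paste(
                   "stasis under mouse growth parameters is interpreted",
                   "as at least stable disease in patients")),
            class = "clinical_prediction")
}

#' @export
print.clinical_prediction <- function(x, ...) {
  cat(sprintf("Clinical prediction%s: %s (TV(end)/v0 = %.3g at day %g)\n",
              if (is.null(x$model_id)) "" else paste0(" [", x$model_id, "]"),
              x$outcome, x$tv_ratio_end, x$horizon))
  invisible(x)
}

#' Dose achieving tumor stasis
#'
#' Bisection on the dose level until the terminal volume ratio
#' `TV(horizon)/v0` crosses 1, i.e. the boundary between net growth and
#' net regression over the simulated regimen.
#'
#' @param pd A [tgi_params()] object (mouse-fitted PD).
#' @param human_pk A [tmdd_params()] object.
#' @param interval_day Dosing interval (day), default 21.
#' @param n_doses Number of doses, default 4.
#' @param bracket Length-2 dose bracket (mg/kg) straddling the stasis
#'   boundary.
#' @param infusion_h Infusion duration (hours).
#' @param tol Convergence tolerance on `|TV(horizon)/v0 - 1|`.
#' @param ... Passed to [predict_clinical()] (e.g. `horizon`, `v0`).
#' @return The stasis dose (mg/kg).
#' @export
dose_for_stasis <- function(pd, human_pk, interval_day = 21, n_doses = 4,
                            bracket = c(0.05, 10), infusion_h = 1,
                            tol = 0.01, ...) {
  stopifnot(inherits(pd, "tgi_params"))
  if (pd$kkmax <= pd$kgEx) {
    stop_invalid("dose_for_stasis: kkmax <= kgEx - the drug cannot hold ",
                 "this tumor static at any concentration")
  }
  ratio_at <- function(dose) {
    reg <- dosing_regimen_q(dose, interval_day, n_doses,
                            infusion_h = infusion_h)
    predict_clinical(pd, human_pk, reg, ...)$tv_ratio_end
  }
  r_lo <- ratio_at(bracket[1])
  r_hi <- ratio_at(bracket[2])
  if ((r_lo - 1) * (r_hi - 1) > 0) {
    stop_invalid("dose_for_stasis: bracket [", bracket[1], ", ", bracket[2],
                 "] mg/kg does not straddle the stasis boundary ",
                 "(ratios ", signif(r_lo, 3), ", ", signif(r_hi, 3), ")")
  }
  lo <- bracket[1]; hi <- bracket[2]
  for (i in 1:60) {
    mid <- sqrt(lo * hi) # bisection in log-dose
    r <- ratio_at(mid)
    if (abs(r - 1) < tol) return(mid)
    if ((r - 1) * (r_lo - 1) > 0) {
      lo <- mid; r_lo <- r
    } else {
      hi <- mid
    }
    if (hi / lo < 1 + 1e-4) break
  }
  sqrt(lo * hi)
}
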