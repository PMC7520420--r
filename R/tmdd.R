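#' Shed-target TMDD model parameters
#'
#' Parameters of the target-mediated drug disposition model for clinical
#' ADC PK: a linear two-compartment backbone plus binding of free drug to
#' the circulating shed target (HER2 extracellular domain), zero-order
#' target production (`kshed`), first-order target degradation (`kdeg`),
#' and first-order elimination of the drug-target complex.
#'
#' The dissociation rate is tied as `koff = KD * kon`. By default the
#' baseline target concentration is tied to the turnover steady state
#' `ECD0 = kshed / kdeg`, so an undosed system stays at baseline; pass an
#' explicit `ECD0` (with `tie_ecd0 = FALSE`) to start off steady state.
#'
#' @param linear A [two_cpt_params()] object (mL/kg, mL/day/kg).
#' @param KD Binding affinity (nM).
#' @param kon Association rate constant (1/nM/day).
#' @param kshed Target production (shedding) rate (nM/day).
#' @param kdeg Target degradation rate (1/day).
#' @param kel_complex Elimination rate of the drug-target complex (1/day).
#' @param ECD0 Baseline shed-target concentration (nM); default
#'   `kshed/kdeg`.
#' @param tie_ecd0 If `TRUE` (default) and `ECD0` is supplied, `kshed` is
#'   re-tied to `kdeg * ECD0` so the baseline is a steady state; if
#'   `FALSE`, `ECD0` is used as-is (off-steady-state start).
#' @return An object of class `tmdd_params`.
#' @export
#' @examples
#' human_pk <- two_cpt_params(38.1, 5.52, 20.2, 14.9)
#' tmdd_params(human_pk, KD = 0.1, kon = 61.3, kshed = 6.65,
#'             kdeg = 33.3, kel_complex = 32.6)
tmdd_params <- function(linear, KD, kon, kshed, kdeg, kel_complex,
                        ECD0 = NULL, tie_ecd0 = TRUE) {
  stopifnot(inherits(linear, "two_cpt_params"))
  vals <- c(KD = KD, kshed = kshed, kdeg = kdeg,
            kel_complex = kel_complex)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_invalid("tmdd_params: KD, kshed, kdeg and kel_complex must ",
                 "be strictly positive")
  }
  if (!is.finite(kon) || kon < 0) {
    stop_invalid("tmdd_params: kon must be >= 0 (0 switches binding off)")
  }
  if (is.null(ECD0)) {
    ECD0 <- kshed / kdeg
  } else {
    if (!is.finite(ECD0) || ECD0 <= 0) {
      stop_invalid("tmdd_params: ECD0 must be strictly positive")
    }
    if (tie_ecd0) kshed <- kdeg * ECD0
  }
  structure(list(linear = linear, KD = KD, kon = kon, koff = KD * kon,
                 kshed = kshed, kdeg = kdeg, kel_complex = kel_complex,
                 ECD0 = ECD0),
            class = "tmdd_params")
}

#' @export
print.tmdd_params <- function(x, ...) {
  cat("Shed-target TMDD model parameters:\n")
  print(x$linear)
  cat(sprintf("  binding:  KD = %g nM, kon = %g /nM/day, koff = %g /day\n",
              x$KD, x$kon, x$koff))
  cat(sprintf("  target:   kshed = %g nM/day, kdeg = %g /day, ECD0 = %.4g nM\n",
              x$kshed, x$kdeg, x$ECD0))
  cat(sprintf("  complex:  kel = %g /day\n", x$kel_complex))
  invisible(x)
}

# Update ECD0 (and re-tie kshed) on an existing parameter set.
set_ecd0 <- function(p, ecd0_nM, tie = TRUE) {
  tmdd_params(p$linear, KD = p$KD, kon = p$kon,
              kshed = if (tie) p$kdeg * ecd0_nM else p$kshed,
              kdeg = p$kdeg, kel_complex = p$kel_complex,
              ECD0 = ecd0_nM, tie_ecd0 = FALSE)
}

#' Simulate the shed-target TMDD model
#'
#' Integrates the four-state system (free drug central, drug peripheral,
#' free shed target, drug-target complex; all nM) under an IV
#' bolus/infusion regimen. Infusions enter as a zero-order rate
#' `dose / (Vc * T_inf)` in nM/day; doses in mg/kg are converted to
#' nmol/kg with the 150 kDa ADC molecular weight. A fifth bookkeeping
#' state accumulates eliminated drug (linear clearance plus complex
#' elimination, nmol/kg) for mass-balance checks.
#'
#' @param p A [tmdd_params()] object.
#' @param regimen A [dosing_regimen()].
#' @param times Output times (day), strictly increasing.
#' @param rtol,atol Solver tolerances.
#' @return A data frame with columns `time_day`, `C_ADC`, `C_ADC_per`,
#'   `C_ECD`, `C_ADC_ECD` (nM), `free_ugml`, `total_ugml`, and
#'   `cum_elim_nmolkg`.
#' @export
#' @examples
#' pk <- two_cpt_params(38.1, 5.52, 20.2, 14.9)
#' p <- tmdd_params(pk, KD = 0.1, kon = 61.3, kshed = 6.65, kdeg = 33.3,
#'                  kel_complex = 32.6)
#' sim <- simulate_tmdd(p, dosing_regimen(0, 3, infusion_day = 1 / 24),
#'                      times = seq(0, 21, 0.25))
simulate_tmdd <- function(p, regimen, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "tmdd_params"), inherits(regimen, "dosing_regimen"))
  times <- as.numeric(times)
  if (any(times < 0)) stop_invalid("simulate_tmdd: negative times not allowed")
  if (is.unsorted(times, strictly = TRUE)) {
    stop_invalid("simulate_tmdd: times must be strictly increasing")
  }
  lin <- p$linear
  parms <- numeric(TMDD_MAXP)
  parms[1:9] <- c(lin$CL, lin$Vc, lin$Vp, lin$Q, p$kon, p$koff,
                  p$kshed, p$kdeg, p$kel_complex)

  inf <- regimen[regimen$infusion_day > 0 & regimen$dose_mg_per_kg > 0, ]
  bol <- regimen[regimen$infusion_day == 0 & regimen$dose_mg_per_kg > 0, ]
  if (nrow(inf) > TMDD_MAXEV) {
    stop_invalid("simulate_tmdd: at most ", TMDD_MAXEV,
                 " infusion events supported")
  }
  parms[10] <- nrow(inf)
  if (nrow(inf)) {
    conc_nM <- dose_mgkg_to_nmolkg(inf$dose_mg_per_kg) / (lin$Vc / 1000)
    ev <- as.numeric(t(cbind(inf$time_day, conc_nM / inf$infusion_day,
                             inf$infusion_day)))
    parms[TMDD_EVOFF + seq_along(ev)] <- ev
  }
  boluses <- NULL
  if (nrow(bol)) {
    boluses <- data.frame(time = bol$time_day, state = 1L,
                          amount = dose_mgkg_to_nmolkg(bol$dose_mg_per_kg) /
                            (lin$Vc / 1000))
  }

  # the model's initial condition is defined at t = 0: integrate from 0
  # even when the first requested output time is later
  prepend <- times[1] > 0
  t_int <- if (prepend) c(0, times) else times
  y0 <- c(0, 0, p$ECD0, 0, 0)
  sol <- piecewise_ode(y0 = y0, times = t_int, parms = parms,
                       func = "tmdd_derivs", initfunc = "tmdd_init",
                       boundaries = regimen_boundaries(regimen),
                       boluses = boluses, rtol = rtol, atol = atol)
  if (prepend) sol <- sol[-1, , drop = FALSE]
  st <- sol[, -1, drop = FALSE]
  st[st < 0 & st > -1e6 * atol] <- 0
  free <- st[, 1]
  total <- st[, 1] + st[, 4]
  data.frame(time_day = sol[, 1],
             C_ADC = st[, 1], C_ADC_per = st[, 2],
             C_ECD = st[, 3], C_ADC_ECD = st[, 4],
             free_ugml = nm_to_ugml(free),
             total_ugml = nm_to_ugml(total),
             cum_elim_nmolkg = st[, 5])
}

#' Extract a concentration profile from a TMDD simulation
#'
#' @param sim A data frame from [simulate_tmdd()].
#' @param analyte `"free"` or `"total"` (free plus complexed drug).
#' @param unit `"ug/mL"` or `"nM"`.
#' @param dose_mg_per_kg,regimen Optional metadata to attach.
#' @return A [concentration_profile()].
#' @export
tmdd_profile <- function(sim, analyte = c("free", "total"),
                         unit = c("ug/mL", "nM"),
                         dose_mg_per_kg = NA_real_, regimen = NULL) {
  analyte <- match.arg(analyte)
  unit <- match.arg(unit)
  conc_nM <- if (analyte == "free") sim$C_ADC else sim$C_ADC + sim$C_ADC_ECD
  conc <- if (unit == "nM") conc_nM else nm_to_ugml(conc_nM)
  concentration_profile(sim$time_day, conc, unit = unit, analyte = analyte,
                        dose_mg_per_kg = dose_mg_per_kg, regimen = regimen)
}

#' Non-compartmental PK metrics
#'
#' Computes AUC(0 to infinity) by linear trapezoid over the sampled grid
#' plus log-linear tail extrapolation (`C_last / lambda_z`), clearance as
#' `dose / AUC`, and terminal half-life as `ln(2) / lambda_z`, where
#' `lambda_z` is the negative slope of `ln(conc)` regressed on time over
#' the terminal window.
#'
#' @param profile A [concentration_profile()] (nM profiles are converted
#'   to ug/mL using the ADC molecular weight).
#' @param dose Administered dose (mg/kg); defaults to the profile's
#'   `dose_mg_per_kg` attribute.
#' @param terminal_window Length-2 numeric `(start_day, end_day)` of the
#'   log-linear regression window. If `NULL` (default) the window is
#'   selected automatically as the most log-linear post-peak segment
#'   spanning at least `min_window_frac` of the profile (maximum adjusted
#'   R-squared of the log-linear fit over a grid of candidate windows) —
#'   the segment a modeler would draw a ruler through on a semilog plot.
#'   For profiles with target-mediated elimination this reads the
#'   elimination phase rather than the accelerated low-concentration tail.
#' @param min_window_frac Minimum automatic-window span as a fraction of
#'   the post-peak time span (default 0.25).
#' @return A list with `CL` (mL/day/kg), `half_life` (day), `AUC_inf` and
#'   `AUC_last` (ug/mL * day), `lambda_z` (1/day), and the window used.
#' @export
nca_metrics <- function(profile, dose = attr(profile, "dose_mg_per_kg"),
                        terminal_window = NULL, min_window_frac = 0.25) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (is.null(dose) || is.na(dose) || dose <= 0) {
    stop_invalid("nca_metrics: a positive dose (mg/kg) is required")
  }
  profile <- profile_as_ugml(profile)
  tt <- profile$time_day
  cc <- profile$conc
  if (length(tt) < 4) stop_invalid("nca_metrics: at least 4 samples required")

  if (is.null(terminal_window)) {
    terminal_window <- select_loglinear_window(tt, cc, min_window_frac)
  }
  win <- tt >= terminal_window[1] - 1e-9 & tt <= terminal_window[2] + 1e-9
  if (sum(win) < 3) {
    stop_invalid("nca_metrics: fewer than 3 samples in the terminal window")
  }
  if (any(cc[win] <= 0)) {
    stop_invalid("nca_metrics: non-positive concentrations in the terminal ",
                 "window; choose a later or shorter window")
  }
  fit <- lm(log(cc[win]) ~ tt[win])
  lambda_z <- -coef(fit)[[2]]
  if (lambda_z <= 0) {
    stop_invalid("nca_metrics: terminal phase is not monotonically ",
                 "declining in the window; try a later window")
  }
  auc_last <- sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2)
  auc_inf <- auc_last + cc[length(cc)] / lambda_z
  list(CL = dose * 1000 / auc_inf,       # (ug/kg) / (ug/mL*day) = mL/day/kg
       half_life = log(2) / lambda_z,
       AUC_inf = auc_inf, AUC_last = auc_last, lambda_z = lambda_z,
       terminal_window = terminal_window)
}

# Automatic terminal-window selection: among contiguous post-peak windows
# spanning at least `min_frac` of the post-peak time range (and >= 5
# samples), pick the one whose log-linear fit has the highest adjusted
# R-squared with a negative slope.
select_loglinear_window <- function(tt, cc, min_frac = 0.25, n_edges = 30) {
  i_peak <- which.max(cc)
  t0 <- tt[i_peak]
  tend <- tt[length(tt)]
  span <- tend - t0
  if (span <= 0) stop_invalid("nca_metrics: profile has no post-peak phase")
  edges <- seq(t0, tend, length.out = n_edges)
  best <- NULL
  best_r2 <- -Inf
  for (i in seq_len(n_edges - 1)) {
    for (j in seq(i + 1, n_edges)) {
      if (edges[j] - edges[i] < min_frac * span) next
      w <- tt >= edges[i] - 1e-9 & tt <= edges[j] + 1e-9
      if (sum(w) < 5 || any(cc[w] <= 0)) next
      fit <- lm(log(cc[w]) ~ tt[w])
      if (coef(fit)[[2]] >= 0) next
      y <- log(cc[w])
      nw <- length(y)
      r2 <- 1 - (sum(fit$residuals^2) / (nw - 2)) /
        (sum((y - mean(y))^2) / (nw - 1))
      if (r2 > best_r2 + 1e-12) {
        best_r2 <- r2
        best <- c(edges[i], edges[j])
      }
    }
  }
  if (is.null(best)) {
    stop_invalid("nca_metrics: no declining log-linear window found; ",
                 "supply terminal_window explicitly")
  }
  best
}

#' Fit the baseline shed-target concentration to an observed profile
#'
#' One-dimensional least-squares fit of `ECD0` (with `kshed` re-tied to
#' `kdeg * ECD0`) minimizing log-scale residuals between an observed
#' concentration profile and the TMDD model prediction.
#'
#' @param observed A [concentration_profile()] with its `regimen`
#'   attribute set (or pass `regimen`).
#' @param p A [tmdd_params()] object (all parameters except `ECD0` fixed).
#' @param ecd_bounds Length-2 positive bounds on `ECD0` (nM).
#' @param regimen Optional [dosing_regimen()] overriding the profile's.
#' @return Fitted `ECD0` (nM). Warns if the optimum lies at a bound.
#' @export
fit_ecd_to_profile <- function(observed, p, ecd_bounds = c(0.16, 0.28),
                               regimen = attr(observed, "regimen")) {
  stopifnot(inherits(observed, "concentration_profile"),
            inherits(p, "tmdd_params"))
  if (is.null(regimen)) {
    stop_invalid("fit_ecd_to_profile: a dosing regimen is required ",
                 "(profile attribute or argument)")
  }
  if (any(ecd_bounds <= 0) || ecd_bounds[1] >= ecd_bounds[2]) {
    stop_invalid("fit_ecd_to_profile: bounds must be positive and ordered")
  }
  analyte <- attr(observed, "analyte")
  obs <- profile_as_ugml(observed)
  keep <- obs$conc > 0
  sse <- function(log_ecd0) {
    pe <- set_ecd0(p, exp(log_ecd0))
    sim <- simulate_tmdd(pe, regimen, times = obs$time_day, rtol = 1e-8,
                         atol = 1e-10)
    pred <- if (analyte == "free") sim$free_ugml else sim$total_ugml
    sum((log(pmax(pred[keep], 1e-12)) - log(obs$conc[keep]))^2)
  }
  opt <- optimize(sse, interval = log(ecd_bounds), tol = 1e-8)
  ecd <- exp(opt$minimum)
  if (min(abs(log(ecd) - log(ecd_bounds))) < 1e-3) {
    warning("fit_ecd_to_profile: optimum is at a bound (",
            signif(ecd, 4), " nM); consider widening ecd_bounds",
            call. = FALSE)
  }
  ecd
}
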