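#' Two-compartment IV PK parameters (per kg)
#'
#' Macro-constants of a linear two-compartment model with elimination from
#' the central compartment. All values are body-weight normalized.
#'
#' @param Vc Central compartment volume (mL/kg).
#' @param CL Linear clearance (mL/day/kg).
#' @param Vp Peripheral compartment volume (mL/kg).
#' @param Q Inter-compartmental clearance (mL/day/kg).
#' @return An object of class `two_cpt_params`.
#' @export
#' @examples
#' two_cpt_params(Vc = 61.0, CL = 22.8, Vp = 56.2, Q = 35.0) # mouse
two_cpt_params <- function(Vc, CL, Vp, Q) {
  vals <- c(Vc = Vc, CL = CL, Vp = Vp, Q = Q)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_invalid("two_cpt_params: Vc, CL, Vp and Q must all be strictly ",
                 "positive and finite (got ",
                 paste(names(vals), signif(vals, 4), sep = "=",
                       collapse = ", "), ")")
  }
  structure(as.list(vals), class = "two_cpt_params")
}

#' @export
print.two_cpt_params <- function(x, ...) {
  cat("Two-compartment IV PK parameters (per kg):\n")
  cat(sprintf("  Vc = %g mL/kg, CL = %g mL/day/kg, Vp = %g mL/kg, Q = %g mL/day/kg\n",
              x$Vc, x$CL, x$Vp, x$Q))
  invisible(x)
}

#' Convert macro- to micro-constants
#'
#' `kel = CL/Vc`, `k12 = Q/Vc`, `k21 = Q/Vp`.
#'
#' @param p A [two_cpt_params()] object.
#' @return An object of class `micro_constants` with elements `kel`, `k12`,
#'   `k21` (1/day).
#' @export
#' @examples
#' macro_to_micro(two_cpt_params(38.1, 7.2, 20.2, 19.2)) # monkey
macro_to_micro <- function(p) {
  stopifnot(inherits(p, "two_cpt_params"))
  structure(list(kel = p$CL / p$Vc, k12 = p$Q / p$Vc, k21 = p$Q / p$Vp),
            class = "micro_constants")
}

#' @export
print.micro_constants <- function(x, ...) {
  cat(sprintf("Micro-constants: kel = %.4g, k12 = %.4g, k21 = %.4g (1/day)\n",
              x$kel, x$k12, x$k21))
  invisible(x)
}

# Reconstruct macro constants; inverse of macro_to_micro given Vc.
micro_to_macro <- function(m, Vc) {
  two_cpt_params(Vc = Vc, CL = m$kel * Vc, Vp = m$k12 * Vc / m$k21,
                 Q = m$k12 * Vc)
}

# Hybrid disposition exponents alpha (fast) and beta (slow), 1/day.
disposition_exponents <- function(p) {
  m <- macro_to_micro(p)
  s <- m$kel + m$k12 + m$k21
  disc <- sqrt(s^2 - 4 * m$kel * m$k21)
  list(alpha = (s + disc) / 2, beta = (s - disc) / 2, k21 = m$k21)
}

#' Distribution and terminal half-lives of a two-compartment model
#'
#' Half-lives derived from the eigenvalues of the 2x2 disposition rate
#' matrix.
#'
#' @param p A [two_cpt_params()] object.
#' @return List with `t_half_alpha` and `t_half_beta` (days); the terminal
#'   half-life is `t_half_beta`.
#' @export
pk_half_lives <- function(p) {
  e <- disposition_exponents(p)
  list(t_half_alpha = log(2) / e$alpha, t_half_beta = log(2) / e$beta)
}

#' IV dosing regimen
#'
#' An ordered set of IV dose events. `infusion_day = 0` means bolus;
#' positive values give the zero-order infusion duration in days
#' (a 1-h infusion is `1/24`).
#'
#' @param time_day Event start times (day), strictly increasing.
#' @param dose_mg_per_kg Dose levels (mg/kg), non-negative.
#' @param infusion_day Infusion durations (day), non-negative; recycled.
#' @return An object of class `dosing_regimen` (a data frame).
#' @export
#' @examples
#' dosing_regimen(c(0, 4, 8, 12), 3)                # Q4d x 4 bolus
#' dosing_regimen_q(3.6, interval_day = 21, n_doses = 4, infusion_h = 1)
dosing_regimen <- function(time_day, dose_mg_per_kg, infusion_day = 0) {
  n <- length(time_day)
  if (n < 1) stop_invalid("dosing_regimen: at least one event is required")
  dose_mg_per_kg <- rep_len(dose_mg_per_kg, n)
  infusion_day <- rep_len(infusion_day, n)
  if (any(!is.finite(time_day)) || any(time_day < 0)) {
    stop_invalid("dosing_regimen: event times must be finite and >= 0")
  }
  if (is.unsorted(time_day, strictly = TRUE)) {
    stop_invalid("dosing_regimen: event times must be strictly increasing")
  }
  if (any(dose_mg_per_kg < 0)) {
    stop_invalid("dosing_regimen: doses must be >= 0")
  }
  if (any(infusion_day < 0)) {
    stop_invalid("dosing_regimen: infusion durations must be >= 0")
  }
  structure(data.frame(time_day = time_day,
                       dose_mg_per_kg = dose_mg_per_kg,
                       infusion_day = infusion_day),
            class = c("dosing_regimen", "data.frame"))
}

#' @param dose Dose level (mg/kg) shared by all events.
#' @param interval_day Inter-dose interval (day).
#' @param n_doses Number of doses.
#' @param infusion_h Infusion duration in hours (0 = bolus).
#' @param start_day First dose time (day).
#' @rdname dosing_regimen
#' @export
dosing_regimen_q <- function(dose, interval_day, n_doses, infusion_h = 0,
                             start_day = 0) {
  dosing_regimen(time_day = start_day + interval_day * (seq_len(n_doses) - 1),
                 dose_mg_per_kg = dose,
                 infusion_day = infusion_h / 24)
}

#' Concentration-time profile
#'
#' A tagged concentration-time trace. The unit and analyte (free vs total
#' drug) travel with the data so downstream steps can enforce consistency.
#'
#' @param time_day Sampling times (day), non-decreasing.
#' @param conc Concentrations, non-negative.
#' @param unit `"ug/mL"` or `"nM"`.
#' @param analyte `"free"` or `"total"`.
#' @param subject_id Optional subject label.
#' @param dose_mg_per_kg Optional administered dose, carried as metadata.
#' @param regimen Optional [dosing_regimen()], carried as metadata.
#' @return A data frame of class `concentration_profile` with columns
#'   `time_day` and `conc` and attributes `unit`, `analyte`, `subject_id`,
#'   `dose_mg_per_kg`, `regimen`.
#' @export
concentration_profile <- function(time_day, conc, unit = c("ug/mL", "nM"),
                                  analyte = c("free", "total"),
                                  subject_id = NA_character_,
                                  dose_mg_per_kg = NA_real_,
                                  regimen = NULL) {
  unit <- match.arg(unit)
  analyte <- match.arg(analyte)
  if (length(time_day) != length(conc)) {
    stop_invalid("concentration_profile: time and concentration lengths differ")
  }
  if (is.unsorted(time_day)) {
    stop_invalid("concentration_profile: times must be non-decreasing")
  }
  if (any(conc < 0)) {
    stop_invalid("concentration_profile: concentrations must be >= 0")
  }
  structure(data.frame(time_day = time_day, conc = conc),
            unit = unit, analyte = analyte, subject_id = subject_id,
            dose_mg_per_kg = dose_mg_per_kg, regimen = regimen,
            class = c("concentration_profile", "data.frame"))
}

# Convert a profile to ug/mL (ADC molecular weight).
profile_as_ugml <- function(profile) {
  if (attr(profile, "unit") == "nM") {
    profile$conc <- nm_to_ugml(profile$conc)
    attr(profile, "unit") <- "ug/mL"
  }
  profile
}

# Vectorized closed-form central concentration (ug/mL) of the linear
# two-compartment model under bolus/infusion event superposition.
conc_2cpt_closed_form <- function(p, regimen, times) {
  e <- disposition_exponents(p)
  a <- e$alpha; b <- e$beta; k21 <- e$k21
  conc <- numeric(length(times))
  for (i in seq_len(nrow(regimen))) {
    t0 <- regimen$time_day[i]
    dose <- regimen$dose_mg_per_kg[i]
    dur <- regimen$infusion_day[i]
    if (dose <= 0) next
    s <- times - t0
    on <- s >= 0
    D <- dose * 1000 / p$Vc # ug/mL
    if (dur <= 0) {
      conc[on] <- conc[on] + D * ((a - k21) * exp(-a * s[on]) +
                                  (k21 - b) * exp(-b * s[on])) / (a - b)
    } else {
      R <- D / dur
      Fa <- (a - k21) / (a * (a - b))
      Fb <- (k21 - b) / (b * (a - b))
      f <- function(u) R * (Fa * (1 - exp(-a * u)) + Fb * (1 - exp(-b * u)))
      conc[on] <- conc[on] + f(s[on])
      off <- s - dur > 0
      conc[off] <- conc[off] - f(s[off] - dur)
    }
  }
  pmax(conc, 0)
}

#' Simulate a linear two-compartment IV PK model
#'
#' Central-compartment concentration under an arbitrary bolus/infusion
#' regimen, from the analytic bi-exponential solution with event
#' superposition (the model is linear, so doses superpose exactly).
#'
#' @param p A [two_cpt_params()] object.
#' @param regimen A [dosing_regimen()].
#' @param times Output times (day), non-negative.
#' @return A [concentration_profile()] in ug/mL, analyte `"free"`.
#' @export
#' @examples
#' mouse <- two_cpt_params(61.0, 22.8, 56.2, 35.0)
#' sim <- simulate_2cpt(mouse, dosing_regimen(0, 3), times = 0:14)
#' head(sim)
simulate_2cpt <- function(p, regimen, times) {
  stopifnot(inherits(p, "two_cpt_params"), inherits(regimen, "dosing_regimen"))
  if (any(times < 0)) stop_invalid("simulate_2cpt: negative times not allowed")
  times <- as.numeric(times)
  concentration_profile(time_day = times,
                        conc = conc_2cpt_closed_form(p, regimen, times),
                        unit = "ug/mL", analyte = "free")
}

#' Allometric interspecies scaling of per-kg PK parameters
#'
#' Per-kg volumes scale as `(BW_target/BW_source)^(exp_volume - 1)` and
#' per-kg clearances as `(BW_target/BW_source)^(exp_clearance - 1)`; the
#' conventional exponents for antibody-sized drugs are 1 for volumes and
#' 0.9 for clearances.
#'
#' @param p A [two_cpt_params()] object for the source species.
#' @param bw_source,bw_target Body weights (kg), positive.
#' @param exp_volume,exp_clearance Allometric exponents.
#' @return A [two_cpt_params()] object for the target species.
#' @export
#' @examples
#' monkey <- two_cpt_params(38.1, 7.2, 20.2, 19.2)
#' scale_allometric(monkey, bw_source = 5, bw_target = 70)
scale_allometric <- function(p, bw_source, bw_target,
                             exp_volume = 1, exp_clearance = 0.9) {
  stopifnot(inherits(p, "two_cpt_params"))
  if (bw_source <= 0 || bw_target <= 0) {
    stop_invalid("scale_allometric: body weights must be positive")
  }
  r <- bw_target / bw_source
  two_cpt_params(Vc = p$Vc * r^(exp_volume - 1),
                 CL = p$CL * r^(exp_clearance - 1),
                 Vp = p$Vp * r^(exp_volume - 1),
                 Q = p$Q * r^(exp_clearance - 1))
}

#' Write / read concentration tables
#'
#' Delimited-text serialization of concentration profiles with columns
#' `subject_id`, `time_day`, `conc`, `unit`, `analyte`.
#'
#' @param profiles A single [concentration_profile()] or a list of them.
#' @param path Output file path.
#' @return `write_concentration_table()` returns `path` invisibly.
#' @export
write_concentration_table <- function(profiles, path) {
  if (inherits(profiles, "concentration_profile")) profiles <- list(profiles)
  rows <- lapply(seq_along(profiles), function(i) {
    pr <- profiles[[i]]
    sid <- attr(pr, "subject_id")
    if (is.na(sid)) sid <- paste0("S", i)
    data.frame(subject_id = sid, time_day = pr$time_day, conc = pr$conc,
               unit = attr(pr, "unit"), analyte = attr(pr, "analyte"))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
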