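#' Tumor-growth-inhibition model parameters
#'
#' Parameters of the transit-compartment tumor-growth-inhibition (TGI)
#' model: a logistic growth law that switches smoothly from exponential to
#' linear growth, coupled to a concentration-driven Hill kill rate feeding
#' three transduction (delay) compartments.
#'
#' @param kgEx Exponential growth rate (1/day).
#' @param kg Linear growth rate (mm^3/day).
#' @param Vmax Maximum tumor volume (mm^3).
#' @param tau Transduction time of each delay compartment (day).
#' @param kkmax Maximum kill rate (1/day).
#' @param kc50 Plasma concentration at half-maximal kill (ug/mL).
#' @param n Hill coefficient (dimensionless).
#' @param psi Exponential-to-linear switching constant (dimensionless,
#'   conventionally fixed at 20).
#' @param v0 Initial tumor volume (mm^3).
#' @return An object of class `tgi_params`.
#' @export
#' @examples
#' tgi_params(kgEx = 0.0883, kg = 47.5, Vmax = 4080, tau = 2.23,
#'            kkmax = 0.703, kc50 = 10.6, n = 2.4, v0 = 200)
tgi_params <- function(kgEx, kg, Vmax, tau, kkmax, kc50, n, psi = 20,
                       v0 = 200) {
  vals <- c(kgEx = kgEx, kg = kg, Vmax = Vmax, tau = tau, kkmax = kkmax,
            kc50 = kc50, n = n, psi = psi, v0 = v0)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_invalid("tgi_params: all parameters must be strictly positive ",
                 "and finite (got ",
                 paste(names(vals), signif(vals, 4), sep = "=",
                       collapse = ", "), ")")
  }
  structure(as.list(vals), class = "tgi_params")
}

#' @export
print.tgi_params <- function(x, ...) {
  cat("TGI model parameters:\n")
  cat(sprintf("  growth: kgEx = %g /day, kg = %g mm3/day, Vmax = %g mm3 (psi = %g)\n",
              x$kgEx, x$kg, x$Vmax, x$psi))
  cat(sprintf("  drug:   kkmax = %g /day, kc50 = %g ug/mL, n = %g, tau = %g day\n",
              x$kkmax, x$kc50, x$n, x$tau))
  cat(sprintf("  v0 = %g mm3\n", x$v0))
  invisible(x)
}

#' Hill kill rate
#'
#' `kkill(C) = kkmax * C^n / (kc50^n + C^n)`: the first-order tumor cell
#' kill rate induced by plasma ADC concentration `C`.
#'
#' @param conc Plasma ADC concentration (ug/mL), non-negative; vectorized.
#' @param p A [tgi_params()] object.
#' @return Kill rate(s) (1/day), in `[0, kkmax)`.
#' @export
#' @examples
#' p <- tgi_params(0.0883, 47.5, 4080, 2.23, 0.703, 10.6, 2.4)
#' kill_rate(p$kc50, p) # kkmax / 2
kill_rate <- function(conc, p) {
  stopifnot(inherits(p, "tgi_params"))
  if (any(conc < 0)) stop_invalid("kill_rate: concentration must be >= 0")
  cn <- conc^p$n
  ifelse(conc == 0, 0, p$kkmax * cn / (p$kc50^p$n + cn))
}

#' Per-volume tumor growth factor
#'
#' `G(TV) = kgEx * (1 - TV/Vmax) / (1 + ((kgEx/kg) * TV)^psi)^(1/psi)`:
#' the specific growth rate applied to the proliferating compartment. It
#' equals `kgEx` for small tumors, transitions to linear growth at
#' `TV ~ kg/kgEx`, and vanishes at `TV = Vmax`. The `psi`-th power is
#' evaluated in log space to avoid overflow.
#'
#' @param tv Total tumor volume (mm^3), non-negative; vectorized.
#' @param p A [tgi_params()] object.
#' @return Growth factor(s) (1/day).
#' @export
growth_rate <- function(tv, p) {
  stopifnot(inherits(p, "tgi_params"))
  if (any(tv < 0)) stop_invalid("growth_rate: tumor volume must be >= 0")
  growth_factor_vec(p$kgEx, p$kg, p$Vmax, p$psi, tv)
}

# Vectorized growth factor over parameters and/or volumes; the psi-th
# power is evaluated in log space (x^20 overflows for moderate x).
growth_factor_vec <- function(kgEx, kg, Vmax, psi, tv) {
  x <- (kgEx / kg) * tv
  den <- rep(1, length(x))
  pos <- which(x > 0)
  if (length(pos)) {
    z <- psi * log(x[pos])
    den[pos] <- ifelse(z > 30, x[pos], exp(log1p(exp(pmin(z, 30))) / psi))
  }
  kgEx * (1 - tv / Vmax) / den
}

#' Simulate the tumor-growth-inhibition ODE system
#'
#' Integrates the four-compartment TGI system (proliferating volume plus
#' three transduction compartments) with a stiff-capable solver, driven by
#' one of: a linear two-compartment PK model plus dosing regimen, a fixed
#' concentration-time profile, or a constant concentration. Integration is
#' restarted at dose-event boundaries.
#'
#' @param p A [tgi_params()] object.
#' @param pk Optional [two_cpt_params()] driving free plasma ADC.
#' @param regimen Optional [dosing_regimen()] (required with `pk`).
#' @param conc Optional driver instead of `pk`: a single number (constant
#'   concentration, ug/mL) or a [concentration_profile()] (linearly
#'   interpolated; nM profiles are converted to ug/mL).
#' @param times Output times (day), starting at 0.
#' @param v0 Initial tumor volume (mm^3); defaults to `p$v0`.
#' @param rtol,atol Solver tolerances.
#' @return A data frame with columns `time_day`, `V1`..`V4`, `TV`, `conc`,
#'   `kkill`.
#' @export
#' @examples
#' p <- tgi_params(0.0883, 47.5, 4080, 2.23, 0.703, 10.6, 2.4, v0 = 200)
#' mouse <- two_cpt_params(61.0, 22.8, 56.2, 35.0)
#' sim <- simulate_tgi(p, pk = mouse,
#'                     regimen = dosing_regimen_q(1, 4, 4), times = 0:28)
#' tail(sim[, c("time_day", "TV")])
simulate_tgi <- function(p, pk = NULL, regimen = NULL, conc = NULL,
                         times, v0 = p$v0, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "tgi_params"))
  out <- simulate_tgi_multi(p, growth = matrix(c(p$kgEx, p$kg), nrow = 1),
                            v0 = v0, pk = pk, regimen = regimen, conc = conc,
                            times = times, rtol = rtol, atol = atol,
                            full_state = TRUE)
  out
}

# Multi-animal TGI integration. growth: matrix [n_anim x 2] (kgEx, kg);
# v0: vector of initial volumes. Shared drug-effect parameters from `p`.
# Returns: if full_state, a data.frame for a single animal; otherwise a
# matrix [length(times) x n_anim] of total volumes.
simulate_tgi_multi <- function(p, growth, v0, pk = NULL, regimen = NULL,
                               conc = NULL, times, rtol = 1e-8, atol = 1e-10,
                               full_state = FALSE, restart = TRUE) {
  times <- as.numeric(times)
  if (any(times < 0)) stop_invalid("simulate_tgi: negative times not allowed")
  if (is.unsorted(times, strictly = TRUE)) {
    stop_invalid("simulate_tgi: times must be strictly increasing")
  }
  n_anim <- nrow(growth)
  v0 <- rep_len(v0, n_anim)

  forced <- is.null(pk)
  if (forced && is.null(conc)) {
    stop_invalid("simulate_tgi: supply either pk + regimen or conc")
  }
  if (!forced && is.null(regimen)) {
    stop_invalid("simulate_tgi: a dosing regimen is required with pk")
  }

  boundaries <- numeric(0)
  forcings <- cbind(range(times), 0) # dummy; compiled model requires one
  conc_fun <- NULL
  if (!forced) {
    boundaries <- regimen_boundaries(regimen)
    conc_fun <- function(t) conc_2cpt_closed_form(pk, regimen, t)
  } else if (inherits(conc, "concentration_profile")) {
    conc <- profile_as_ugml(conc)
    if (max(times) > max(conc$time_day) + 1e-9) {
      stop_invalid("simulate_tgi: concentration profile does not cover ",
                   "the simulation horizon")
    }
    forcings <- cbind(conc$time_day, conc$conc)
    conc_fun <- function(t) approx(conc$time_day, conc$conc, t,
                                   rule = 2)$y
  } else {
    if (!is.numeric(conc) || length(conc) != 1 || conc < 0) {
      stop_invalid("simulate_tgi: constant conc must be a single ",
                   "non-negative number")
    }
    forcings <- cbind(range(times), conc)
    conc_fun <- function(t) rep(conc, length(t))
  }

  parms <- pack_tgi_parms(p, growth, pk = pk, regimen = regimen,
                          forced = forced)
  y0 <- as.numeric(rbind(v0, 0, 0, 0))
  # initial conditions hold at t = 0; integrate from 0 if times start later
  prepend <- times[1] > 0
  t_int <- if (prepend) c(0, times) else times
  sol <- piecewise_ode(y0 = y0, times = t_int, parms = parms,
                       func = "tgi_derivs", initfunc = "tgi_init",
                       boundaries = boundaries,
                       forcings = forcings, initforc = "tgi_forcinit",
                       rtol = rtol, atol = atol, restart = restart)
  if (prepend) sol <- sol[-1, , drop = FALSE]
  states <- sol[, -1, drop = FALSE]
  states[states < 0 & states > -1e6 * atol] <- 0
  if (any(states < 0)) {
    stop_invalid("simulate_tgi: solver returned negative compartment ",
                 "volumes beyond tolerance; tighten rtol/atol")
  }
  if (!full_state) {
    tv <- sapply(seq_len(n_anim), function(ia) {
      rowSums(states[, 4 * (ia - 1) + 1:4, drop = FALSE])
    })
    return(matrix(tv, nrow = length(times)))
  }
  cc <- conc_fun(times)
  data.frame(time_day = times,
             V1 = states[, 1], V2 = states[, 2],
             V3 = states[, 3], V4 = states[, 4],
             TV = rowSums(states[, 1:4, drop = FALSE]),
             conc = cc, kkill = kill_rate(pmax(cc, 0), p))
}

#' Write a tumor trajectory table
#'
#' @param trajectory A data frame from [simulate_tgi()].
#' @param path Output file path.
#' @param animal_id Optional animal label column value.
#' @return `path`, invisibly.
#' @export
write_tumor_trajectory <- function(trajectory, path, animal_id = NULL) {
  out <- trajectory[, c("time_day", "V1", "V2", "V3", "V4", "TV")]
  if (!is.null(animal_id)) out <- cbind(animal_id = animal_id, out)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
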