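#' Residual error model
#'
#' Combined additive-plus-proportional observation noise: the residual
#' standard deviation at prediction `f` is `additive + proportional * f`,
#' on the observation scale (mm^3 for tumor volumes).
#'
#' @param additive Additive SD component (observation units), >= 0.
#' @param proportional Proportional SD component (fraction), >= 0.
#' @return An object of class `residual_error_model`.
#' @export
residual_error_model <- function(additive = 0, proportional = 0) {
  if (additive < 0 || proportional < 0) {
    stop_invalid("residual_error_model: components must be >= 0")
  }
  structure(list(additive = additive, proportional = proportional),
            class = "residual_error_model")
}

#' Inter-individual variability specification
#'
#' Log-normal between-animal variability of the growth parameters; the
#' omegas are log-scale standard deviations.
#'
#' @param omega_kgEx,omega_kg Log-scale SDs, >= 0.
#' @return An object of class `iiv_spec`.
#' @export
iiv_spec <- function(omega_kgEx = 0, omega_kg = 0) {
  if (omega_kgEx < 0 || omega_kg < 0) {
    stop_invalid("iiv_spec: omegas must be >= 0")
  }
  structure(list(omega_kgEx = omega_kgEx, omega_kg = omega_kg),
            class = "iiv_spec")
}

#' Condition number of an information matrix
#'
#' Ratio of the largest to smallest absolute eigenvalue; 1 for the
#' identity, large for ill-conditioned (poorly identified) fits.
#'
#' @param H A symmetric matrix (Hessian / information matrix).
#' @return The condition number (>= 1), or `NA` if not computable.
#' @export
condition_number <- function(H) {
  ev <- tryCatch(abs(eigen(H, symmetric = TRUE, only.values = TRUE)$values),
                 error = function(e) NULL)
  if (is.null(ev) || any(!is.finite(ev)) || min(ev) <= 0) return(NA_real_)
  max(ev) / min(ev)
}

new_fit_result <- function(estimates, cv_percent, objective, hessian,
                           convergence, residuals, error_model = NULL,
                           flags = character(0), predict_fn = NULL,
                           simulate_fn = NULL) {
  structure(list(estimates = estimates, cv_percent = cv_percent,
                 objective = objective,
                 condition_number = if (is.null(hessian)) NA_real_
                                    else condition_number(hessian),
                 hessian = hessian, convergence = convergence,
                 residuals = residuals, error_model = error_model,
                 flags = flags, predict_fn = predict_fn,
                 simulate_fn = simulate_fn),
            class = "adc_fit")
}

#' @export
print.adc_fit <- function(x, ...) {
  cat("Model fit:\n")
  est <- data.frame(estimate = signif(unlist(x$estimates), 4),
                    cv_percent = signif(x$cv_percent[names(x$estimates)], 3))
  print(est)
  cat(sprintf("objective (-2LL or SSQ): %.4g | condition number: %.3g | converged: %s\n",
              x$objective, x$condition_number, x$convergence))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# Times/volumes for one animal, sorted, with the day-0 volume used as v0.
animal_series <- function(study, id) {
  rows <- study[study$animal_id == id, ]
  rows <- rows[order(rows$time_day), ]
  i0 <- which(rows$time_day == 0)
  if (!length(i0)) {
    stop_invalid("animal ", id, " has no day-0 measurement (needed for v0)")
  }
  list(times = rows$time_day, obs = rows$tumor_volume_mm3,
       v0 = rows$tumor_volume_mm3[i0[1]], dose = rows$dose_mg_per_kg[1],
       arm = rows$arm_id[1])
}

#' Fit unperturbed tumor growth to the vehicle arm
#'
#' Stage one of the two-stage analysis: a hierarchical fit of the
#' logistic switching growth model to the vehicle-control animals.
#' Each animal's `(kgEx, kg)` are individual log-normal random effects
#' around the population values; `Vmax` - a property of the tumor model
#' rather than the individual animal, and weakly identified from any
#' single trajectory - is a single shared value. Residuals are log-scale.
#' The population values, the between-animal variability (omegas) and the
#' individual parameters are estimated by a Laplace
#' expectation-maximization scheme: individual MAP fits given the current
#' population/omega values, then moment updates `omega^2 =
#' mean((log g_i - mu)^2 + posterior variance)`, iterated to convergence.
#' When the data carry no real between-animal variability the omegas
#' shrink toward zero and the fit approaches a pooled one; naive
#' per-animal fitting would instead absorb residual noise into spurious
#' variability.
#'
#' @param study A tumor-study data frame (see [read_tumor_study()]) with a
#'   zero-dose arm of at least 3 animals with at least 4 time points each.
#' @param psi Switching constant of the growth law (default 20).
#' @return A list with elements `fit` (an `adc_fit` with population
#'   estimates), `iiv` (an [iiv_spec()]), and `individual` (per-animal
#'   estimates).
#' @export
fit_vehicle_growth <- function(study, psi = 20) {
  study <- as_tumor_study(study)
  veh <- study[study$dose_mg_per_kg == 0, ]
  if (!nrow(veh)) {
    stop_invalid("fit_vehicle_growth: no vehicle (dose 0) arm in the study")
  }
  ids <- unique(veh$animal_id)
  arm <- veh$arm_id[1]
  if (length(ids) < 3) {
    stop_invalid("fit_vehicle_growth: vehicle arm '", arm, "' has only ",
                 length(ids), " animal(s); at least 3 are required")
  }
  counts <- table(veh$animal_id)
  if (any(counts < 4)) {
    stop_invalid("fit_vehicle_growth: animal(s) ",
                 paste(names(counts)[counts < 4], collapse = ", "),
                 " in vehicle arm '", arm, "' have fewer than 4 time points")
  }

  series <- lapply(ids, function(id) animal_series(veh, id))
  names(series) <- ids

  # per-animal (kgEx, kg) fit conditional on a shared Vmax; residuals on
  # the log scale so early (small) and late (large) volumes weigh alike.
  # Starts are data-driven: early log-slope for kgEx, volume increments
  # for kg.
  fit_one <- function(s, vmax, maxit = 200) {
    n_half <- max(3, ceiling(length(s$times) / 2))
    sl <- coef(lm(log(pmax(s$obs[1:n_half], 1)) ~ s$times[1:n_half]))[[2]]
    kgEx0 <- min(max(sl, 0.005), 0.5)
    dv <- diff(s$obs) / diff(s$times)
    kg0 <- min(max(max(dv), 5), 1000)
    lower <- log(c(1e-4, 0.5))
    upper <- log(c(2, 5e3))
    start <- pmin(pmax(log(c(kgEx0, kg0)), lower), upper)
    obj <- function(theta) {
      pp <- tgi_params(kgEx = exp(theta[1]), kg = exp(theta[2]),
                       Vmax = vmax, tau = 1, kkmax = 1, kc50 = 1,
                       n = 1, psi = psi, v0 = s$v0)
      tv <- simulate_tgi_multi(pp, matrix(exp(theta), 1), v0 = s$v0,
                               conc = 0, times = s$times,
                               rtol = 1e-7, atol = 1e-8,
                               restart = FALSE)
      sum((log(s$obs) - log(pmax(tv[, 1], 1e-6)))^2)
    }
    opt <- optim(start, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = maxit))
    c(exp(opt$par), sse = opt$value, conv = opt$convergence, v0 = s$v0)
  }

  # log-scale SSE of one animal at given growth parameters
  animal_sse <- function(s, g, vmax) {
    pp <- tgi_params(kgEx = g[1], kg = g[2], Vmax = vmax, tau = 1,
                     kkmax = 1, kc50 = 1, n = 1, psi = psi, v0 = s$v0)
    tv <- simulate_tgi_multi(pp, matrix(g, 1), v0 = s$v0, conc = 0,
                             times = s$times, rtol = 1e-7, atol = 1e-8,
                             restart = FALSE)
    sum((log(s$obs) - log(pmax(tv[, 1], 1e-6)))^2)
  }

  # initialization: free per-animal fits at a generous provisional Vmax;
  # the shared Vmax is then refined inside the EM loop
  vmax_lo <- max(veh$tumor_volume_mm3) * 1.05
  vmax_hat <- max(veh$tumor_volume_mm3) * 3
  free_fits <- t(vapply(series, fit_one, numeric(5), vmax = vmax_hat,
                        maxit = 60))
  colnames(free_fits) <- c("kgEx", "kg", "sse", "conv", "v0")

  n_obs_veh <- sum(vapply(series, function(s) length(s$obs), numeric(1)))
  gmat <- log(free_fits[, c("kgEx", "kg"), drop = FALSE])
  mu <- colMeans(gmat)
  omega <- pmax(apply(gmat, 2, sd), 0.05)
  if (length(ids) == 1) omega <- c(0, 0)
  sig2 <- sum(free_fits[, "sse"]) / n_obs_veh
  vpost <- matrix(0, length(ids), 2)

  # Laplace-EM rounds (skipped for a single animal)
  if (length(ids) > 1) {
    for (iter in 1:6) {
      sse_i <- numeric(length(ids))
      for (k in seq_along(series)) {
        s <- series[[k]]
        map_obj <- function(g) {
          val <- animal_sse(s, exp(g), vmax_hat) / sig2 +
            sum(((g - mu) / omega)^2)
          if (!is.finite(val)) 1e10 else val
        }
        opt <- optim(gmat[k, ], map_obj, method = "L-BFGS-B",
                     lower = mu - 4 * omega - 0.1,
                     upper = mu + 4 * omega + 0.1,
                     control = list(maxit = 80))
        gmat[k, ] <- opt$par
        sse_i[k] <- animal_sse(s, exp(opt$par), vmax_hat)
        H <- tryCatch(optimHess(opt$par, map_obj), error = function(e) NULL)
        vc <- if (is.null(H)) NULL else tryCatch(2 * solve(H),
                                                 error = function(e) NULL)
        vpost[k, ] <- if (is.null(vc) || any(diag(vc) <= 0)) 0
                      else pmin(diag(vc), 4)
      }
      mu_new <- colMeans(gmat)
      omega_new <- sqrt(pmax(colMeans((gmat - rep(mu_new, each =
                                        nrow(gmat)))^2 + vpost), 1e-3))
      sig2 <- sum(sse_i) / n_obs_veh
      done <- max(abs(omega_new - omega)) < 0.02 &&
        max(abs(mu_new - mu)) < 0.005
      mu <- mu_new
      omega <- pmin(omega_new, 3)
      # refresh the shared Vmax at the current individual parameters
      ov <- optimize(function(lv) {
        sum(vapply(seq_along(series), function(k) {
          animal_sse(series[[k]], exp(gmat[k, ]), exp(lv))
        }, numeric(1)))
      }, interval = log(c(vmax_lo, 1e5)), tol = 0.05)
      vmax_hat <- exp(ov$minimum)
      if (done) break
    }
  }

  individual <- data.frame(animal_id = ids, kgEx = exp(gmat[, 1]),
                           kg = exp(gmat[, 2]),
                           sse = vapply(seq_along(series), function(k) {
                             animal_sse(series[[k]], exp(gmat[k, ]),
                                        vmax_hat)
                           }, numeric(1)),
                           conv = free_fits[, "conv"],
                           v0 = free_fits[, "v0"], Vmax = vmax_hat,
                           row.names = NULL)

  logm <- as.data.frame(gmat)
  names(logm) <- c("kgEx", "kg")
  logm$Vmax <- log(vmax_hat)
  est <- list(kgEx = exp(mu[[1]]), kg = exp(mu[[2]]), Vmax = vmax_hat)
  flags <- character(0)
  if (length(ids) == 1) {
    iiv <- iiv_spec(0, 0)
    flags <- "single animal: population equals individual, omegas undefined"
    cvp <- setNames(rep(NA_real_, 3), names(est))
  } else {
    iiv <- iiv_spec(omega_kgEx = omega[[1]], omega_kg = omega[[2]])
    cvp <- 100 * c(omega / sqrt(length(ids)), Vmax = NA)
    names(cvp) <- names(est)
  }

  resid_tab <- do.call(rbind, lapply(seq_along(ids), function(k) {
    s <- animal_series(veh, ids[k])
    pp <- tgi_params(kgEx = individual$kgEx[k], kg = individual$kg[k],
                     Vmax = individual$Vmax[k], tau = 1, kkmax = 1,
                     kc50 = 1, n = 1, psi = psi, v0 = s$v0)
    pred <- simulate_tgi_multi(pp, matrix(c(pp$kgEx, pp$kg), 1), v0 = s$v0,
                               conc = 0, times = s$times,
                               rtol = 1e-7, atol = 1e-8,
                               restart = FALSE)[, 1]
    data.frame(animal_id = ids[k], time_day = s$times, observed = s$obs,
               predicted = pred, residual = s$obs - pred)
  }))

  H <- tryCatch(optimHess(colMeans(logm), function(theta) {
    sum(vapply(seq_along(ids), function(k) {
      s <- animal_series(veh, ids[k])
      pp <- tgi_params(kgEx = exp(theta[1]), kg = exp(theta[2]),
                       Vmax = exp(theta[3]), tau = 1, kkmax = 1, kc50 = 1,
                       n = 1, psi = psi, v0 = s$v0)
      tv <- simulate_tgi_multi(pp, matrix(exp(theta[1:2]), 1), v0 = s$v0,
                               conc = 0, times = s$times,
                               rtol = 1e-7, atol = 1e-8,
                               restart = FALSE)
      sum((log(s$obs) - log(pmax(tv[, 1], 1e-6)))^2)
    }, numeric(1)))
  }), error = function(e) NULL)

  fit <- new_fit_result(estimates = est, cv_percent = cvp,
                        objective = sum(individual$sse), hessian = H,
                        convergence = all(individual$conv == 0),
                        residuals = resid_tab, flags = flags)
  list(fit = fit, iiv = iiv, individual = individual)
}

# Resolve the per-arm dosing regimen for a study.
study_regimen_fn <- function(study, regimen_fn = NULL) {
  if (!is.null(regimen_fn)) return(regimen_fn)
  design <- attr(study, "design")
  if (!is.null(design)) {
    return(function(dose) dosing_regimen_q(dose, design$interval_day,
                                           design$n_doses,
                                           design$infusion_h,
                                           design$start_day))
  }
  function(dose) dosing_regimen_q(dose, interval_day = 4, n_doses = 4)
}

#' Fit drug-effect parameters to a full tumor-growth-inhibition study
#'
#' Stage two of the two-stage analysis: with the population growth
#' parameters, `Vmax`, and the between-animal variability (omegas) fixed
#' from the vehicle stage, the drug-effect parameters `(tau, kkmax, kc50,
#' n)` and the combined residual error `(additive, proportional)` are
#' estimated by pooled maximum likelihood over all animals. Vehicle
#' animals keep their stage-one individual growth estimates; each dosed
#' animal's `(kgEx, kg)` are treated as empirical-Bayes (MAP) random
#' effects, estimated jointly with the shared parameters under a
#' log-normal penalty toward the population values weighted by the
#' vehicle-stage omegas. The joint objective is minimized by coordinate
#' descent, alternating the shared-parameter and per-animal blocks.
#'
#' @param study A tumor-study data frame; dosed arms required.
#' @param pk A [two_cpt_params()] object (mouse PK, fixed).
#' @param growth_fix Result of [fit_vehicle_growth()].
#' @param regimen_fn Function mapping a dose (mg/kg) to a
#'   [dosing_regimen()]; defaults to the study's design attribute, else
#'   Q4d x 4 IV bolus.
#' @param fix Named list of parameters to hold fixed, e.g. `list(n = 1)`.
#' @param n_starts Number of multi-start optimizations (log-uniform within
#'   a factor of 10 around the data-driven start).
#' @param seed Seed for the multi-start draws.
#' @param psi Switching constant (default 20).
#' @return An `adc_fit` with estimates, CV%, objective (-2 log-likelihood),
#'   condition number, residual table, and prediction/simulation closures
#'   used by [diagnostics()]. Fits with any CV > 100% carry a
#'   low-confidence flag.
#' @export
fit_tgi <- function(study, pk, growth_fix, regimen_fn = NULL, fix = list(),
                    n_starts = 5, seed = 1, psi = 20) {
  study <- as_tumor_study(study)
  stopifnot(inherits(pk, "two_cpt_params"))
  if (!any(study$dose_mg_per_kg > 0)) {
    stop_invalid("fit_tgi: no dosed arms in the study")
  }
  regimen_fn <- study_regimen_fn(study, regimen_fn)

  pop <- growth_fix$fit$estimates
  ind <- growth_fix$individual

  omegas <- c(growth_fix$iiv$omega_kgEx, growth_fix$iiv$omega_kg)

  # per-arm blocks: shared regimen, per-animal growth parameters and v0.
  # Vehicle animals carry their stage-one estimates (held fixed); dosed
  # animals start at the population values and are refined as MAP random
  # effects when the omegas are positive.
  arms <- split(study, study$dose_mg_per_kg)
  blocks <- lapply(arms, function(arm_df) {
    ids <- unique(arm_df$animal_id)
    series <- lapply(ids, function(id) animal_series(arm_df, id))
    times <- sort(unique(arm_df$time_day))
    growth <- t(vapply(ids, function(id) {
      j <- match(id, ind$animal_id)
      if (!is.na(j)) c(ind$kgEx[j], ind$kg[j]) else c(pop$kgEx, pop$kg)
    }, numeric(2)))
    v0 <- vapply(series, `[[`, numeric(1), "v0")
    idx <- lapply(series, function(s) match(s$times, times))
    dose <- arm_df$dose_mg_per_kg[1]
    list(dose = dose, ids = ids, series = series, times = times,
         growth = growth, v0 = v0, idx = idx,
         eb = (dose > 0) & !(ids %in% ind$animal_id),
         regimen = if (dose > 0) regimen_fn(dose) else NULL)
  })
  n_obs <- sum(vapply(blocks, function(b) {
    sum(lengths(lapply(b$series, `[[`, "obs")))
  }, numeric(1)))

  par_names <- c("tau", "kkmax", "kc50", "n", "additive", "proportional")
  fixed <- unlist(fix)
  if (length(fixed) && !all(names(fixed) %in% par_names)) {
    stop_invalid("fit_tgi: unknown fixed parameter(s): ",
                 paste(setdiff(names(fixed), par_names), collapse = ", "))
  }
  free_names <- setdiff(par_names, names(fixed))

  # data-driven starting values (no access to generating truth)
  cmax <- max(vapply(blocks, function(b) {
    if (is.null(b$regimen)) 0
    else max(conc_2cpt_closed_form(pk, b$regimen,
                                   seq(0, max(b$times), 0.25)))
  }, numeric(1)))
  vol_scale <- median(study$tumor_volume_mm3)
  start_full <- c(tau = 2, kkmax = max(3 * pop$kgEx, 0.2),
                  kc50 = max(cmax / 4, 0.5), n = 1.5,
                  additive = 0.05 * vol_scale, proportional = 0.15)
  lower_full <- c(tau = 0.1, kkmax = 1e-3, kc50 = 1e-2, n = 0.3,
                  additive = 1e-3, proportional = 1e-4)
  upper_full <- c(tau = 50, kkmax = 10, kc50 = 1e4, n = 6,
                  additive = 1e3, proportional = 1)

  assemble <- function(theta_free) {
    full <- c(exp(theta_free)[free_names], fixed)[par_names]
    names(full) <- par_names
    full
  }

  make_params <- function(th) {
    tgi_params(kgEx = pop$kgEx, kg = pop$kg, Vmax = pop$Vmax,
               tau = th[["tau"]], kkmax = th[["kkmax"]],
               kc50 = th[["kc50"]], n = th[["n"]], psi = psi, v0 = 200)
  }
  block_pred <- function(b, pp, growth) {
    if (is.null(b$regimen)) {
      simulate_tgi_multi(pp, growth, b$v0, conc = 0, times = b$times,
                         rtol = 1e-7, atol = 1e-8, restart = FALSE)
    } else {
      simulate_tgi_multi(pp, growth, b$v0, pk = pk, regimen = b$regimen,
                         times = b$times, rtol = 1e-7, atol = 1e-8,
                         restart = FALSE)
    }
  }
  # MAP penalty for a growth matrix relative to the population values
  # (-2 log of the log-normal random-effect density, up to a constant)
  map_penalty <- function(b) {
    if (!any(b$eb) || any(omegas <= 0)) return(0)
    d1 <- log(b$growth[b$eb, 1] / pop$kgEx) / omegas[1]
    d2 <- log(b$growth[b$eb, 2] / pop$kg) / omegas[2]
    sum(d1^2) + sum(d2^2)
  }

  # -2 log-likelihood of the data given shared parameters th and the
  # current per-animal growth matrices (penalty added separately)
  neg2ll_data <- function(theta_free) {
    th <- assemble(theta_free)
    pp <- make_params(th)
    tot <- 0
    for (b in blocks) {
      tv <- block_pred(b, pp, b$growth)
      for (k in seq_along(b$series)) {
        pred <- tv[b$idx[[k]], k]
        sdv <- th[["additive"]] + th[["proportional"]] * pmax(pred, 0)
        tot <- tot + sum(log(2 * pi * sdv^2) +
                         ((b$series[[k]]$obs - pred) / sdv)^2)
      }
    }
    if (!is.finite(tot)) tot <- 1e10
    tot
  }
  total_penalty <- function() sum(vapply(blocks, map_penalty, numeric(1)))

  # per-animal empirical-Bayes refinement of (kgEx, kg) for dosed animals
  refine_animals <- function(th) {
    pp <- make_params(th)
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      if (!any(b$eb) || any(omegas <= 0)) next
      for (k in which(b$eb)) {
        s <- b$series[[k]]
        obj_k <- function(g) {
          tv <- simulate_tgi_multi(pp, matrix(exp(g), 1), b$v0[k],
                                   pk = pk, regimen = b$regimen,
                                   times = s$times,
                                   rtol = 1e-7, atol = 1e-8,
                                   restart = FALSE)
          pred <- tv[, 1]
          sdv <- th[["additive"]] + th[["proportional"]] * pmax(pred, 0)
          val <- sum(log(2 * pi * sdv^2) + ((s$obs - pred) / sdv)^2) +
            ((g[1] - log(pop$kgEx)) / omegas[1])^2 +
            ((g[2] - log(pop$kg)) / omegas[2])^2
          if (!is.finite(val)) 1e10 else val
        }
        g0 <- log(b$growth[k, ])
        opt <- tryCatch(
          optim(g0, obj_k, method = "L-BFGS-B",
                lower = log(c(pop$kgEx, pop$kg)) - 4 * omegas,
                upper = log(c(pop$kgEx, pop$kg)) + 4 * omegas,
                control = list(maxit = 40)),
          error = function(e) NULL)
        if (!is.null(opt)) blocks[[bi]]$growth[k, ] <<- exp(opt$par)
      }
    }
    invisible(NULL)
  }

  lower <- log(lower_full[free_names])
  upper <- log(upper_full[free_names])
  opt_shared <- function(start, maxit = 200) {
    tryCatch(
      optim(pmin(pmax(start, lower), upper), neg2ll_data,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit, factr = 1e9)),
      error = function(e) NULL)
  }

  # round 1: multi-start on the shared parameters at population growth
  set.seed(as.integer(seed))
  starts <- list(log(start_full[free_names]))
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1)) {
      starts[[s + 1]] <- log(start_full[free_names]) +
        log(10) * runif(length(free_names), -1, 1)
    }
  }
  best <- NULL
  for (st in starts) {
    opt <- opt_shared(st, maxit = 80)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) stop_invalid("fit_tgi: all optimization starts failed")

  # coordinate descent: alternate per-animal MAP refinement with the
  # shared-parameter fit until the joint objective stops improving
  joint_prev <- best$value + total_penalty()
  for (round in 1:3) {
    refine_animals(assemble(best$par))
    opt <- opt_shared(best$par, maxit = 150)
    if (!is.null(opt)) best <- opt
    joint <- best$value + total_penalty()
    if (joint_prev - joint < 1) break
    joint_prev <- joint
  }

  th <- assemble(best$par)
  neg2ll <- neg2ll_data # observed-information Hessian of the data term
  H <- tryCatch(optimHess(best$par, neg2ll), error = function(e) NULL)
  cvp <- setNames(rep(NA_real_, length(par_names)), par_names)
  flags <- character(0)
  if (!is.null(H)) {
    vc <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) {
      cvp[free_names] <- 100 * sqrt(diag(vc))
    } else {
      flags <- c(flags, paste("information matrix singular: at least one",
                              "parameter (often n) is not identified;",
                              "consider fix = list(n = 1)"))
      warning("fit_tgi: information matrix is singular; Hill coefficient ",
              "n may be non-identifiable - consider fixing it ",
              "(fix = list(n = 1))", call. = FALSE)
    }
  }
  cvp[names(fixed)] <- 0
  if (any(is.finite(cvp) & cvp > 100)) {
    flags <- c(flags, paste0("low confidence: CV% > 100 for ",
                             paste(par_names[is.finite(cvp) & cvp > 100],
                                   collapse = ", ")))
  }

  resid_tab <- do.call(rbind, lapply(blocks, function(b) {
    pp <- tgi_params(kgEx = pop$kgEx, kg = pop$kg, Vmax = pop$Vmax,
                     tau = th[["tau"]], kkmax = th[["kkmax"]],
                     kc50 = th[["kc50"]], n = th[["n"]], psi = psi, v0 = 200)
    tv <- if (is.null(b$regimen)) {
      simulate_tgi_multi(pp, b$growth, b$v0, conc = 0, times = b$times,
                         rtol = 1e-7, atol = 1e-8, restart = FALSE)
    } else {
      simulate_tgi_multi(pp, b$growth, b$v0, pk = pk, regimen = b$regimen,
                         times = b$times, rtol = 1e-7, atol = 1e-8,
                         restart = FALSE)
    }
    do.call(rbind, lapply(seq_along(b$series), function(k) {
      pred <- tv[b$idx[[k]], k]
      sdv <- th[["additive"]] + th[["proportional"]] * pmax(pred, 0)
      data.frame(animal_id = b$ids[k], dose_mg_per_kg = b$dose,
                 time_day = b$series[[k]]$times,
                 observed = b$series[[k]]$obs, predicted = pred,
                 residual = b$series[[k]]$obs - pred,
                 wres = (b$series[[k]]$obs - pred) / sdv)
    }))
  }))
  row.names(resid_tab) <- NULL

  err <- residual_error_model(th[["additive"]], th[["proportional"]])
  iiv <- growth_fix$iiv
  simulate_fn <- function(sim_seed) {
    set.seed(as.integer(sim_seed))
    do.call(rbind, lapply(blocks, function(b) {
      growth <- cbind(pop$kgEx * exp(rnorm(length(b$ids)) * iiv$omega_kgEx),
                      pop$kg * exp(rnorm(length(b$ids)) * iiv$omega_kg))
      pp <- tgi_params(kgEx = pop$kgEx, kg = pop$kg, Vmax = pop$Vmax,
                       tau = th[["tau"]], kkmax = th[["kkmax"]],
                       kc50 = th[["kc50"]], n = th[["n"]], psi = psi,
                       v0 = 200)
      tv <- if (is.null(b$regimen)) {
        simulate_tgi_multi(pp, growth, b$v0, conc = 0, times = b$times,
                           rtol = 1e-7, atol = 1e-8)
      } else {
        simulate_tgi_multi(pp, growth, b$v0, pk = pk, regimen = b$regimen,
                           times = b$times, rtol = 1e-7, atol = 1e-8)
      }
      do.call(rbind, lapply(seq_along(b$ids), function(k) {
        pred <- tv[b$idx[[k]], k]
        sdv <- err$additive + err$proportional * pmax(pred, 0)
        data.frame(animal_id = b$ids[k], dose_mg_per_kg = b$dose,
                   time_day = b$series[[k]]$times,
                   simulated = pmax(pred + rnorm(length(pred)) * sdv, 1))
      }))
    }))
  }

  new_fit_result(estimates = as.list(th[free_names]),
                 cv_percent = cvp, objective = best$value, hessian = H,
                 convergence = best$convergence == 0,
                 residuals = resid_tab, error_model = err, flags = flags,
                 simulate_fn = simulate_fn)
}

#' Fit shed-target turnover parameters to clinical PK profiles
#'
#' Estimates `(kshed, kdeg, kel_complex)` of the TMDD model from observed
#' concentration profiles across dose levels, with the binding constants
#' and linear PK fixed. Residuals are proportional on the log scale;
#' `kshed` and `ECD0` stay tied (`ECD0 = kshed / kdeg`).
#'
#' @param profiles List of [concentration_profile()] objects, each with
#'   `dose_mg_per_kg` and `regimen` attributes.
#' @param p_init A [tmdd_params()] object: initial values for the
#'   estimated parameters and fixed values for the rest.
#' @param estimate_ecd0 If `TRUE`, additionally fit a per-profile baseline
#'   target concentration within `ecd_bounds` after the pooled fit.
#' @param ecd_bounds Bounds (nM) for the per-profile ECD0 refinement.
#' @param n_starts,seed Multi-start control, as in [fit_tgi()].
#' @return An `adc_fit`; estimates on the original scale, CV% from the
#'   observed information. A warning is issued when fewer than 2 dose
#'   levels are supplied (weak identifiability).
#' @export
fit_tmdd_clinical <- function(profiles, p_init, estimate_ecd0 = FALSE,
                              ecd_bounds = c(0.16, 0.28), n_starts = 3,
                              seed = 1) {
  stopifnot(inherits(p_init, "tmdd_params"))
  if (!length(profiles)) stop_invalid("fit_tmdd_clinical: no profiles")
  doses <- vapply(profiles, function(pr) attr(pr, "dose_mg_per_kg"),
                  numeric(1))
  if (any(is.na(doses))) {
    stop_invalid("fit_tmdd_clinical: every profile needs a dose attribute")
  }
  if (length(unique(doses)) < 2) {
    warning("fit_tmdd_clinical: fewer than 2 dose levels - kshed/kdeg/",
            "kel_complex are weakly identified from a single dose level",
            call. = FALSE)
  }
  prep <- lapply(profiles, function(pr) {
    reg <- attr(pr, "regimen")
    if (is.null(reg)) {
      reg <- dosing_regimen(0, attr(pr, "dose_mg_per_kg"),
                            infusion_day = 1 / 24)
    }
    pr2 <- profile_as_ugml(pr)
    keep <- pr2$conc > 0
    list(times = pr2$time_day[keep], obs = pr2$conc[keep],
         analyte = attr(pr, "analyte"), regimen = reg)
  })
  n_obs <- sum(lengths(lapply(prep, `[[`, "obs")))

  sse_fn <- function(theta) {
    kshed <- exp(theta[1]); kdeg <- exp(theta[2]); kelc <- exp(theta[3])
    p <- tmdd_params(p_init$linear, KD = p_init$KD, kon = p_init$kon,
                     kshed = kshed, kdeg = kdeg, kel_complex = kelc)
    tot <- 0
    for (pr in prep) {
      # wild parameter proposals can defeat the integrator; treat partial
      # or failed integrations as a rejected proposal
      sim <- tryCatch(suppressWarnings(
        simulate_tmdd(p, pr$regimen, times = pr$times,
                      rtol = 1e-8, atol = 1e-10)),
        error = function(e) NULL)
      if (is.null(sim) || nrow(sim) != length(pr$times)) return(1e10)
      pred <- if (pr$analyte == "free") sim$free_ugml else sim$total_ugml
      tot <- tot + sum((log(pmax(pred, 1e-12)) - log(pr$obs))^2)
    }
    tot
  }
  # -2 log-likelihood with the log-scale residual SD profiled out
  obj <- function(theta) {
    s <- sse_fn(theta)
    n_obs * log(s / n_obs) + n_obs * (1 + log(2 * pi))
  }

  start0 <- log(c(p_init$kshed, p_init$kdeg, p_init$kel_complex))
  lower <- start0 - log(100)
  upper <- start0 + log(100)
  set.seed(as.integer(seed))
  starts <- list(start0)
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1)) {
      starts[[s + 1]] <- start0 + log(10) * runif(3, -1, 1)
    }
  }
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(optim(st, obj, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(maxit = 300)),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) stop_invalid("fit_tmdd_clinical: optimization failed")
  # polish the winning start at a tight tolerance (the kdeg/kel_complex
  # direction is shallow and coarse stops can strand the fit on it)
  polish <- tryCatch(optim(best$par, obj, method = "L-BFGS-B",
                           lower = lower, upper = upper,
                           control = list(maxit = 500, factr = 1e6)),
                     error = function(e) NULL)
  if (!is.null(polish) && polish$value < best$value) best <- polish

  est <- setNames(as.list(exp(best$par)), c("kshed", "kdeg", "kel_complex"))
  p_hat <- tmdd_params(p_init$linear, KD = p_init$KD, kon = p_init$kon,
                       kshed = est$kshed, kdeg = est$kdeg,
                       kel_complex = est$kel_complex)
  H <- tryCatch(optimHess(best$par, obj), error = function(e) NULL)
  cvp <- setNames(rep(NA_real_, 3), names(est))
  flags <- character(0)
  if (!is.null(H)) {
    vc <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) cvp[] <- 100 * sqrt(diag(vc))
  }
  if (any(is.finite(cvp) & cvp > 100)) {
    flags <- c(flags, "low confidence: CV% > 100 for at least one parameter")
  }

  ecd0_fit <- NULL
  if (estimate_ecd0) {
    ecd0_fit <- vapply(seq_along(profiles), function(i) {
      fit_ecd_to_profile(profiles[[i]], p_hat, ecd_bounds = ecd_bounds,
                         regimen = prep[[i]]$regimen)
    }, numeric(1))
  }

  resid_tab <- do.call(rbind, lapply(seq_along(prep), function(i) {
    pr <- prep[[i]]
    sim <- simulate_tmdd(p_hat, pr$regimen, times = pr$times,
                         rtol = 1e-8, atol = 1e-10)
    pred <- if (pr$analyte == "free") sim$free_ugml else sim$total_ugml
    data.frame(profile = i, time_day = pr$times, observed = pr$obs,
               predicted = pred,
               residual = log(pr$obs) - log(pmax(pred, 1e-12)))
  }))
  sigma <- sqrt(sse_fn(best$par) / n_obs)
  resid_tab$wres <- resid_tab$residual / sigma

  fit <- new_fit_result(estimates = est, cv_percent = cvp,
                        objective = best$value, hessian = H,
                        convergence = best$convergence == 0,
                        residuals = resid_tab,
                        error_model = residual_error_model(0, sigma),
                        flags = flags)
  fit$params <- p_hat
  fit$ecd0_per_profile <- ecd0_fit
  fit
}

#' Fit diagnostics: observation-prediction tables, residuals, VPC
#'
#' Emits the standard goodness-of-fit material for a fitted model:
#' observation-versus-prediction pairs, weighted residuals versus time, a
#' visual-predictive-check table (simulation percentiles per time point
#' with the observed coverage of the 10-90% band), and the condition
#' number of the information matrix.
#'
#' @param fit An `adc_fit` from [fit_tgi()] (VPC available when the fit
#'   carries a simulation closure) or another fit function.
#' @param n_sim Number of VPC simulation replicates (default 500).
#' @param seed Seed for the VPC simulations.
#' @return A list of class `adc_diagnostics` with `obs_pred`, `vpc`
#'   (or `NULL`), `coverage_10_90` and `condition_number`.
#' @export
diagnostics <- function(fit, n_sim = 500, seed = 1) {
  stopifnot(inherits(fit, "adc_fit"))
  obs_pred <- fit$residuals
  vpc <- NULL
  coverage <- NA_real_
  if (!is.null(fit$simulate_fn)) {
    sims <- lapply(seq_len(n_sim), function(i) fit$simulate_fn(seed + i))
    key <- interaction(obs_pred$animal_id, obs_pred$time_day, drop = FALSE)
    simmat <- vapply(sims, function(s) s$simulated, numeric(nrow(sims[[1]])))
    q <- t(apply(simmat, 1, quantile, probs = c(0.1, 0.5, 0.9)))
    s1 <- sims[[1]]
    vpc <- data.frame(animal_id = s1$animal_id,
                      dose_mg_per_kg = s1$dose_mg_per_kg,
                      time_day = s1$time_day,
                      q10 = q[, 1], q50 = q[, 2], q90 = q[, 3])
    m <- match(paste(obs_pred$animal_id, obs_pred$time_day),
               paste(vpc$animal_id, vpc$time_day))
    inside <- obs_pred$observed >= vpc$q10[m] & obs_pred$observed <= vpc$q90[m]
    coverage <- mean(inside, na.rm = TRUE)
  }
  structure(list(obs_pred = obs_pred, vpc = vpc,
                 coverage_10_90 = coverage,
                 condition_number = fit$condition_number),
            class = "adc_diagnostics")
}

#' @export
print.adc_diagnostics <- function(x, ...) {
  cat(sprintf("Diagnostics: %d observations, condition number %.3g\n",
              nrow(x$obs_pred), x$condition_number))
  if (!is.na(x$coverage_10_90)) {
    cat(sprintf("VPC: %.1f%% of observations inside the 10-90%% band\n",
                100 * x$coverage_10_90))
  }
  invisible(x)
}
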