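#' Xenograft study design
#'
#' Describes a mouse efficacy study: parallel dose arms (0 = vehicle)
#' dosed on a repeating IV schedule, tumor volumes measured on a common
#' grid, animals randomized at an initial-volume window.
#'
#' @param n_animals_per_arm Animals per arm.
#' @param dose_arms Dose levels (mg/kg); must include 0 (vehicle).
#' @param interval_day,n_doses,infusion_h,start_day Dosing schedule
#'   (default Q4d x 4 IV bolus from day 0).
#' @param measurement_days Measurement times (day); must include 0 and lie
#'   within the study horizon.
#' @param v0_range Randomization window for initial volumes (mm^3).
#' @param v0_dist `"uniform"` (default) or `"lognormal"` (median at the
#'   window midpoint, log-SD a quarter of the log window width).
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_animals_per_arm = 8,
                         dose_arms = c(0, 0.25, 0.5, 1),
                         interval_day = 4, n_doses = 4, infusion_h = 0,
                         start_day = 0,
                         measurement_days = seq(0, 42, by = 3.5),
                         v0_range = c(150, 300),
                         v0_dist = c("uniform", "lognormal")) {
  v0_dist <- match.arg(v0_dist)
  if (!any(dose_arms == 0)) {
    stop_invalid("study_design: at least one vehicle arm (dose 0) is ",
                 "required for growth fitting")
  }
  if (n_animals_per_arm < 1) {
    stop_invalid("study_design: n_animals_per_arm must be >= 1")
  }
  if (!0 %in% measurement_days) {
    stop_invalid("study_design: a day-0 measurement is required")
  }
  if (is.unsorted(measurement_days, strictly = TRUE) ||
      any(measurement_days < 0)) {
    stop_invalid("study_design: measurement days must be non-negative and ",
                 "strictly increasing")
  }
  last_dose <- start_day + interval_day * (n_doses - 1) + infusion_h / 24
  if (max(measurement_days) < last_dose) {
    stop_invalid("study_design: measurement horizon ends before the last ",
                 "dose")
  }
  if (length(v0_range) != 2 || any(v0_range <= 0) ||
      v0_range[1] >= v0_range[2]) {
    stop_invalid("study_design: v0_range must be positive and increasing")
  }
  structure(list(n_animals_per_arm = n_animals_per_arm,
                 dose_arms = dose_arms, interval_day = interval_day,
                 n_doses = n_doses, infusion_h = infusion_h,
                 start_day = start_day,
                 measurement_days = measurement_days,
                 v0_range = v0_range, v0_dist = v0_dist),
            class = "study_design")
}

# Independent per-animal (or per-subject) PRNG stream seeds, so adding
# animals does not perturb the draws of existing ones.
stream_seed <- function(seed, arm_idx, unit_idx) {
  as.integer((as.numeric(seed) + 100003 * arm_idx + 7919 * unit_idx) %%
               2147483629)
}

#' Generate a synthetic xenograft efficacy study
#'
#' Simulates animal-level tumor-volume data with the statistical structure
#' the two-stage analysis assumes: per-animal growth rates drawn
#' log-normally around the population values (median = population,
#' log-SD = omega), initial volumes drawn from the randomization window,
#' trajectories from the TGI model driven by the two-compartment mouse
#' PK, and combined additive-plus-proportional residual noise truncated
#' at a 1 mm^3 floor. Each animal has its own PRNG stream.
#'
#' @param design A [study_design()].
#' @param p A [tgi_params()] object (population values).
#' @param iiv An [iiv_spec()].
#' @param err A [residual_error_model()].
#' @param pk A [two_cpt_params()] object (mouse PK).
#' @param seed Integer seed.
#' @return A `tumor_study` data frame with columns `animal_id`, `arm_id`,
#'   `dose_mg_per_kg`, `time_day`, `tumor_volume_mm3`; the generating
#'   per-animal parameters are attached as attribute `truth` and the
#'   design as attribute `design`.
#' @export
#' @examples
#' p <- tgi_params(0.0883, 47.5, 4080, 2.23, 0.703, 10.6, 2.4)
#' study <- generate_xenograft_study(study_design(n_animals_per_arm = 3),
#'                                   p, iiv_spec(0.4, 1.2),
#'                                   residual_error_model(13.4, 0.118),
#'                                   two_cpt_params(61, 22.8, 56.2, 35),
#'                                   seed = 7)
#' head(study)
generate_xenograft_study <- function(design, p, iiv, err, pk, seed) {
  stopifnot(inherits(design, "study_design"), inherits(p, "tgi_params"),
            inherits(iiv, "iiv_spec"),
            inherits(err, "residual_error_model"),
            inherits(pk, "two_cpt_params"))
  times <- design$measurement_days
  n_t <- length(times)
  rows <- list()
  truth <- list()
  for (a in seq_along(design$dose_arms)) {
    dose <- design$dose_arms[a]
    arm_id <- if (dose == 0) "vehicle" else paste0("arm_", dose, "mgkg")
    # per-animal draws first (one stream each), then one batched
    # trajectory solve for the whole arm
    draws <- lapply(seq_len(design$n_animals_per_arm), function(i) {
      set.seed(stream_seed(seed, a, i))
      kgEx_i <- p$kgEx * exp(rnorm(1) * iiv$omega_kgEx)
      kg_i <- p$kg * exp(rnorm(1) * iiv$omega_kg)
      v0_i <- if (design$v0_dist == "uniform") {
        runif(1, design$v0_range[1], design$v0_range[2])
      } else {
        exp(rnorm(1, mean = mean(log(design$v0_range)),
                  sd = diff(log(design$v0_range)) / 4))
      }
      list(kgEx = kgEx_i, kg = kg_i, v0 = v0_i, z = rnorm(n_t))
    })
    growth <- t(vapply(draws, function(d) c(d$kgEx, d$kg), numeric(2)))
    v0 <- vapply(draws, `[[`, numeric(1), "v0")
    reg <- if (dose > 0) {
      dosing_regimen_q(dose, design$interval_day, design$n_doses,
                       design$infusion_h, design$start_day)
    } else NULL
    # the batched solver handles ~100 animals per call; chunk large arms
    chunks <- split(seq_len(design$n_animals_per_arm),
                    ceiling(seq_len(design$n_animals_per_arm) / 100))
    tv <- do.call(cbind, lapply(chunks, function(ix) {
      if (dose > 0) {
        simulate_tgi_multi(p, growth[ix, , drop = FALSE], v0[ix], pk = pk,
                           regimen = reg, times = times)
      } else {
        simulate_tgi_multi(p, growth[ix, , drop = FALSE], v0[ix],
                           conc = 0, times = times)
      }
    }))
    for (i in seq_len(design$n_animals_per_arm)) {
      pred <- tv[, i]
      sdv <- err$additive + err$proportional * pred
      obs <- pmax(pred + draws[[i]]$z * sdv, 1)
      id <- sprintf("%s_%02d", arm_id, i)
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = id, arm_id = arm_id, dose_mg_per_kg = dose,
        time_day = times, tumor_volume_mm3 = obs)
      truth[[length(truth) + 1]] <- data.frame(
        animal_id = id, arm_id = arm_id, dose_mg_per_kg = dose,
        kgEx = draws[[i]]$kgEx, kg = draws[[i]]$kg, v0 = v0[i])
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  structure(out,
            truth = do.call(rbind, truth), design = design,
            params = p, class = c("tumor_study", "data.frame"))
}

#' Generate synthetic clinical PK profiles from the TMDD model
#'
#' Simulates subject-level concentration profiles under 1-h IV infusions,
#' optionally drawing each subject's baseline shed-target concentration
#' from a stated range, with log-normal proportional observation noise.
#' Each subject has its own PRNG stream.
#'
#' @param p A [tmdd_params()] object.
#' @param doses Dose levels (mg/kg), one arm per dose.
#' @param sampling_days Sampling times (day).
#' @param prop_error Log-scale SD of the observation noise (0 =
#'   noise-free).
#' @param n_per_dose Subjects per dose level.
#' @param seed Integer seed.
#' @param ecd_range_ngml Optional length-2 range (ng/mL); each subject's
#'   ECD0 is drawn uniformly inside it (kshed re-tied).
#' @param analyte `"free"` or `"total"` observed analyte.
#' @param interval_day,n_doses Dosing schedule (default: a single dose).
#' @param infusion_h Infusion duration (hours).
#' @return A list of [concentration_profile()] objects with `subject_id`,
#'   `dose_mg_per_kg` and `regimen` attributes; the generating ECD0
#'   values are attached as attribute `truth_ecd0_nM`.
#' @export
generate_clinical_pk <- function(p, doses, sampling_days, prop_error = 0,
                                 n_per_dose = 1, seed = 1,
                                 ecd_range_ngml = NULL,
                                 analyte = c("free", "total"),
                                 interval_day = 21, n_doses = 1,
                                 infusion_h = 1) {
  stopifnot(inherits(p, "tmdd_params"))
  analyte <- match.arg(analyte)
  if (any(sampling_days < 0) || is.unsorted(sampling_days, strictly = TRUE)) {
    stop_invalid("generate_clinical_pk: sampling days must be ",
                 "non-negative and strictly increasing")
  }
  profiles <- list()
  ecd_used <- numeric(0)
  for (a in seq_along(doses)) {
    reg <- dosing_regimen_q(doses[a], interval_day, n_doses,
                            infusion_h = infusion_h)
    for (i in seq_len(n_per_dose)) {
      set.seed(stream_seed(seed, a, i))
      pi_sub <- p
      if (!is.null(ecd_range_ngml)) {
        ecd0 <- ecd_ngml_to_nm(runif(1, ecd_range_ngml[1],
                                     ecd_range_ngml[2]))
        pi_sub <- set_ecd0(p, ecd0)
      }
      z <- rnorm(length(sampling_days))
      sim <- simulate_tmdd(pi_sub, reg, times = sampling_days)
      pred <- if (analyte == "free") sim$free_ugml else sim$total_ugml
      obs <- pred * exp(z * prop_error)
      sid <- sprintf("dose%g_%02d", doses[a], i)
      profiles[[length(profiles) + 1]] <-
        concentration_profile(sampling_days, obs, unit = "ug/mL",
                              analyte = analyte, subject_id = sid,
                              dose_mg_per_kg = doses[a], regimen = reg)
      ecd_used <- c(ecd_used, pi_sub$ECD0)
    }
  }
  attr(profiles, "truth_ecd0_nM") <- ecd_used
  profiles
}
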