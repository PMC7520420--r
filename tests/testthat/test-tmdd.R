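test_that("with binding switched off the TMDD model reduces to linear two-compartment PK", {
  lin <- two_cpt_params(38.1, 5.52, 20.2, 14.9)
  p <- tmdd_params(lin, KD = 0.1, kon = 0, kshed = 6.65, kdeg = 33.3,
                   kel_complex = 32.6)
  reg <- dosing_regimen(0, 1, infusion_day = 1 / 24)
  tt <- seq(0, 21, by = 0.25)
  sim <- simulate_tmdd(p, reg, tt)
  ref <- simulate_2cpt(lin, reg, tt)
  expect_lt(max(abs(sim$free_ugml[-1] / ref$conc[-1] - 1)), 1e-6)
})

test_that("without dosing the shed target sits at its turnover steady state", {
  p <- fx_human_tmdd()
  expect_equal(p$ECD0, 6.65 / 33.3, tolerance = 1e-12)
  sim <- simulate_tmdd(p, dosing_regimen(0, 0), times = c(0, 5, 10, 21))
  expect_equal(sim$C_ECD, rep(6.65 / 33.3, 4), tolerance = 1e-9)
  expect_true(all(sim$C_ADC == 0))
})

test_that("TMDD trajectory matches an independent RK4 oracle", {
  p <- fx_human_tmdd()
  dose <- 1
  dur <- 1 / 24
  rate <- adcpkpd:::dose_mgkg_to_nmolkg(dose) / (p$linear$Vc / 1000) / dur
  infusion <- function(t) if (t >= 0 && t < dur) rate else 0
  # binding makes the system stiff (kon * C_ADC ~ 1e4/day), so the
  # fixed-step oracle needs a small step and a short horizon
  tt <- c(0, dur, 0.2, 0.5, 1, 2, 3)
  oracle <- rk4_integrate(tmdd_rhs(p, infusion), c(0, 0, p$ECD0, 0), tt,
                          dt = 2.5e-5, breaks = dur)
  sim <- simulate_tmdd(p, dosing_regimen(0, dose, infusion_day = dur), tt)
  expect_lt(max(abs(sim$C_ADC[-1] / oracle[-1, 1] - 1)), 1e-4)
  expect_lt(max(abs(sim$C_ECD / oracle[, 3] - 1)), 1e-4)
})

test_that("drug mass balances: input equals remaining plus eliminated", {
  p <- fx_human_tmdd()
  reg <- dosing_regimen_q(1, 21, 2, infusion_h = 1)
  tt <- seq(0, 42, by = 0.5)
  sim <- simulate_tmdd(p, reg, tt)
  lin <- p$linear
  input <- adcpkpd:::dose_mgkg_to_nmolkg(1) *
    vapply(tt, function(t) sum(t >= reg$time_day + reg$infusion_day) +
             sum(pmax(pmin((t - reg$time_day) / reg$infusion_day, 1), 0) *
                   (t < reg$time_day + reg$infusion_day)), numeric(1))
  remaining <- sim$C_ADC * lin$Vc / 1000 + sim$C_ADC_per * lin$Vp / 1000 +
    sim$C_ADC_ECD * lin$Vc / 1000
  balance <- remaining + sim$cum_elim_nmolkg
  idx <- tt > 0.1
  expect_lt(max(abs(balance[idx] / input[idx] - 1)), 1e-6)
})

test_that("all four state variables stay non-negative under multiple infusions and boluses", {
  p <- fx_human_tmdd()
  reg <- dosing_regimen(c(0, 10, 21), c(3, 0.15, 1),
                        infusion_day = c(1 / 24, 0, 1 / 24))
  sim <- simulate_tmdd(p, reg, seq(0, 40, 0.25))
  expect_true(all(sim[, c("C_ADC", "C_ADC_per", "C_ECD", "C_ADC_ECD")] >= 0))
})

test_that("dose-normalized exposure rises with dose (saturable elimination)", {
  p <- fx_human_tmdd()
  tt <- seq(0, 21, by = 0.05)
  auc_per_dose <- vapply(c(0.15, 0.5, 1, 3), function(d) {
    sim <- simulate_tmdd(p, dosing_regimen(0, d, infusion_day = 1 / 24), tt)
    sum(diff(tt) * (head(sim$free_ugml, -1) + tail(sim$free_ugml, -1)) / 2) / d
  }, numeric(1))
  expect_true(all(diff(auc_per_dose) > 0))
})

test_that("NCA recovers the clearance of a linear profile within 0.5%", {
  lin <- two_cpt_params(38.1, 5.52, 20.2, 14.9)
  tt <- seq(0, 120, by = 0.1)
  prof <- simulate_2cpt(lin, dosing_regimen(0, 1), tt)
  attr(prof, "dose_mg_per_kg") <- 1
  m <- nca_metrics(prof)
  expect_equal(m$CL, 5.52, tolerance = 0.005)
  expect_gt(m$half_life, 0)
})

test_that("NCA rejects windows with a rising terminal phase", {
  p <- fx_human_tmdd()
  tt <- seq(0, 42, 0.25)
  sim <- simulate_tmdd(p, dosing_regimen_q(1, 21, 2, infusion_h = 1), tt)
  prof <- tmdd_profile(sim, dose_mg_per_kg = 1)
  # window spanning the second infusion: concentrations rise into it
  expect_error(nca_metrics(prof, terminal_window = c(18, 23)),
               "later window|declining")
})

test_that("total analyte dominates free and ECD0 fitting is self-consistent", {
  p <- fx_human_tmdd()
  reg <- dosing_regimen(0, 1, infusion_day = 1 / 24)
  tt <- seq(0.25, 21, by = 0.75)
  sim <- simulate_tmdd(p, reg, tt)
  expect_true(all(sim$total_ugml >= sim$free_ugml - 1e-12))

  obs <- concentration_profile(tt, sim$free_ugml, unit = "ug/mL",
                               analyte = "free", regimen = reg)
  fit <- fit_ecd_to_profile(obs, p, ecd_bounds = c(0.05, 0.8))
  expect_equal(fit, p$ECD0, tolerance = 1e-3)
})

test_that("higher baseline shed target lowers free-drug exposure", {
  p <- fx_human_tmdd()
  reg <- dosing_regimen_q(1, 21, 4, infusion_h = 1)
  tt <- seq(0, 84, by = 0.25)
  low <- simulate_tmdd(adcpkpd:::set_ecd0(p, ecd_ngml_to_nm(2)), reg, tt)
  high <- simulate_tmdd(adcpkpd:::set_ecd0(p, ecd_ngml_to_nm(750)), reg, tt)
  idx <- tt > 0.2
  expect_true(all(high$free_ugml[idx] <= low$free_ugml[idx] + 1e-9))
  # troughs just before each later dose are strictly ordered
  troughs <- c(20.9, 41.9, 62.9, 83.9)
  i <- vapply(troughs, function(x) which.min(abs(tt - x)), integer(1))
  expect_true(all(high$free_ugml[i] < low$free_ugml[i]))
})
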