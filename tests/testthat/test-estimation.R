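# A small noise-free study, its stage-one and stage-two fits, are shared
# across the blocks below (the fits are the expensive part).
make_noisefree_study <- function() {
  design <- study_design(n_animals_per_arm = 4, dose_arms = c(0, 0.5, 1),
                         measurement_days = seq(0, 35, by = 3.5))
  generate_xenograft_study(design, fx_jimt1(), iiv_spec(0, 0),
                           residual_error_model(0, 0), fx_mouse_pk(),
                           seed = 9)
}
nf_study <- make_noisefree_study()
nf_growth <- fit_vehicle_growth(nf_study)
nf_fit <- suppressWarnings(fit_tgi(nf_study, fx_mouse_pk(), nf_growth,
                                   n_starts = 1, seed = 1))

test_that("vehicle growth fitting recovers the generating parameters from clean data", {
  g <- nf_growth
  expect_equal(g$fit$estimates$kgEx, 0.0883, tolerance = 0.02)
  expect_equal(g$fit$estimates$kg, 47.5, tolerance = 0.05)
  expect_equal(g$fit$estimates$Vmax, 4080, tolerance = 0.25)
  expect_lt(g$iiv$omega_kgEx, 0.1)
  expect_gte(g$fit$condition_number, 1)
})

test_that("vehicle fitting demands enough animals and time points", {
  st <- make_noisefree_study()
  dosed_only <- st[st$dose_mg_per_kg > 0, ]
  expect_error(fit_vehicle_growth(dosed_only), "no vehicle")
  two <- st[st$animal_id %in% unique(st$animal_id)[1:2] |
              st$dose_mg_per_kg > 0, ]
  expect_error(fit_vehicle_growth(two), "at least 3")
  sparse <- st[st$time_day %in% c(0, 3.5, 7) | st$dose_mg_per_kg > 0, ]
  expect_error(fit_vehicle_growth(sparse), "fewer than 4 time points")
})

test_that("drug-effect fitting is self-consistent on noise-free data", {
  f <- nf_fit
  expect_equal(f$estimates$kkmax, 0.703, tolerance = 0.05)
  expect_equal(f$estimates$kc50, 10.6, tolerance = 0.05)
  expect_equal(f$estimates$tau, 2.23, tolerance = 0.05)
  # residuals essentially zero relative to the volume scale
  expect_lt(max(abs(f$residuals$residual)) / 200, 0.025)
})

test_that("fit results expose CVs, flags and a reorder-invariant likelihood", {
  design <- study_design(n_animals_per_arm = 4, dose_arms = c(0, 0.5, 1),
                         measurement_days = seq(0, 35, by = 3.5))
  st <- generate_xenograft_study(design, fx_jimt1(), iiv_spec(0, 0),
                                 residual_error_model(13.4, 0.118),
                                 fx_mouse_pk(), seed = 21)
  g <- fit_vehicle_growth(st)
  f <- suppressWarnings(fit_tgi(st, fx_mouse_pk(), g,
                                fix = list(n = 2.4), n_starts = 1,
                                seed = 2))
  expect_equal(f$cv_percent[["n"]], 0) # fixed parameters carry zero CV
  expect_true(all(c("tau", "kkmax", "kc50") %in% names(f$estimates) |
                    c("tau", "kkmax", "kc50") %in%
                      names(f$cv_percent)))
  # permuting rows leaves the fit unchanged
  set.seed(1)
  st2 <- st[sample(nrow(st)), ]
  g2 <- fit_vehicle_growth(st2)
  f2 <- suppressWarnings(fit_tgi(st2, fx_mouse_pk(), g2,
                                 fix = list(n = 2.4), n_starts = 1,
                                 seed = 2))
  expect_equal(f2$objective, f$objective, tolerance = 1e-6)
  # solver state ordering differs, so estimates agree to optimizer
  # precision rather than machine precision
  expect_equal(unlist(f2$estimates), unlist(f$estimates),
               tolerance = 1e-2)
})

test_that("TMDD turnover parameters are recovered from clean multi-dose profiles", {
  truth <- fx_human_tmdd()
  tt <- c(0.1, 0.25, 0.5, 1, 2, 4, 7, 10, 14, 21)
  profiles <- generate_clinical_pk(truth, doses = c(0.3, 1.2, 4.8),
                                   sampling_days = tt, prop_error = 0,
                                   seed = 5)
  init <- tmdd_params(truth$linear, KD = 0.1, kon = 61.3, kshed = 3,
                      kdeg = 15, kel_complex = 60)
  f <- fit_tmdd_clinical(profiles, init, n_starts = 6, seed = 4)
  expect_equal(f$estimates$kshed, 6.65, tolerance = 0.1)
  expect_equal(f$estimates$kdeg, 33.3, tolerance = 0.1)
  expect_equal(f$estimates$kel_complex, 32.6, tolerance = 0.15)
  expect_true(all(is.finite(unlist(f$cv_percent))))
})

test_that("a single dose level triggers an identifiability warning", {
  truth <- fx_human_tmdd()
  profiles <- generate_clinical_pk(truth, doses = 1,
                                   sampling_days = c(0.5, 1, 3, 7, 14),
                                   prop_error = 0, seed = 5)
  expect_warning(
    fit_tmdd_clinical(profiles, truth, n_starts = 1, seed = 1),
    "dose level")
})

test_that("condition number equals 1 for the identity and matches analytic eigenvalue ratios", {
  expect_equal(condition_number(diag(3)), 1)
  H <- diag(c(9, 1))
  expect_equal(condition_number(H), 9)
  # rotated quadratic form keeps its spectrum
  th <- 0.6
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  expect_equal(condition_number(R %*% H %*% t(R)), 9, tolerance = 1e-10)
})

test_that("diagnostics: zero weighted residuals on clean data, calibrated VPC on noisy data", {
  d0 <- diagnostics(nf_fit, n_sim = 10, seed = 1)
  expect_lt(max(abs(d0$obs_pred$residual)), 5)

  design <- study_design(n_animals_per_arm = 6, dose_arms = c(0, 0.5, 1),
                         measurement_days = seq(0, 35, by = 3.5))
  stn <- generate_xenograft_study(design, fx_jimt1(), iiv_spec(0.2, 0.3),
                                  residual_error_model(13.4, 0.118),
                                  fx_mouse_pk(), seed = 31)
  gn <- fit_vehicle_growth(stn)
  fn <- suppressWarnings(fit_tgi(stn, fx_mouse_pk(), gn, n_starts = 1,
                                 seed = 3))
  dn <- diagnostics(fn, n_sim = 200, seed = 2)
  expect_true(!is.null(dn$vpc))
  expect_gt(dn$coverage_10_90, 0.6)
  expect_lt(dn$coverage_10_90, 0.97)
})
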