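test_that("macro-to-micro conversion follows kel = CL/Vc, k12 = Q/Vc, k21 = Q/Vp", {
  m <- macro_to_micro(fx_monkey_pk())
  expect_equal(m$kel, 7.2 / 38.1, tolerance = 1e-12)
  expect_equal(m$k12, 19.2 / 38.1, tolerance = 1e-12)
  expect_equal(m$k21, 19.2 / 20.2, tolerance = 1e-12)
  expect_equal(round(c(m$kel, m$k12, m$k21), 4), c(0.1890, 0.5039, 0.9505))

  unitp <- two_cpt_params(1, 1, 1, 1)
  expect_equal(unlist(macro_to_micro(unitp)), c(kel = 1, k12 = 1, k21 = 1))

  expect_equal(macro_to_micro(fx_mouse_pk())$kel, 22.8 / 61.0)

  # reconstruction is the identity
  p <- fx_monkey_pk()
  back <- adcpkpd:::micro_to_macro(macro_to_micro(p), Vc = p$Vc)
  expect_equal(unlist(back[c("Vc", "CL", "Vp", "Q")]),
               unlist(p[c("Vc", "CL", "Vp", "Q")]), tolerance = 1e-12)

  expect_error(two_cpt_params(-1, 2, 3, 4), "positive")
})

test_that("bolus concentration starts at dose/Vc and the profile is linear in dose", {
  mouse <- fx_mouse_pk()
  tt <- c(0, 0.5, 1, 2, 4, 7, 14)
  s3 <- simulate_2cpt(mouse, dosing_regimen(0, 3), tt)
  expect_equal(s3$conc[1], 3 * 1000 / 61.0, tolerance = 1e-10) # 49.2 ug/mL
  s6 <- simulate_2cpt(mouse, dosing_regimen(0, 6), tt)
  expect_equal(s6$conc, 2 * s3$conc, tolerance = 1e-12)
  expect_error(simulate_2cpt(mouse, dosing_regimen(0, 3), c(-1, 0)),
               "negative")
})

test_that("multi-dose profile is the superposition of shifted single doses", {
  p <- fx_monkey_pk()
  tt <- seq(0, 30, by = 0.5)
  multi <- simulate_2cpt(p, dosing_regimen(c(0, 4, 8), c(1, 2, 0.5),
                                           infusion_day = c(0, 1 / 24, 0)),
                         tt)
  parts <- Map(function(t0, d, dur) {
    shifted <- simulate_2cpt(p, dosing_regimen(0, d, dur), pmax(tt - t0, 0))
    ifelse(tt >= t0, shifted$conc, 0)
  }, c(0, 4, 8), c(1, 2, 0.5), c(0, 1 / 24, 0))
  expect_equal(multi$conc, Reduce(`+`, parts), tolerance = 1e-10)
})

test_that("closed-form solution matches an independent RK4 integration of the micro-constant system", {
  p <- fx_monkey_pk()
  m <- macro_to_micro(p)
  dose <- 3
  tt <- c(0, 0.5, 1, 2, 5, 10, 20)
  f <- function(t, y) {
    c(-(m$kel + m$k12) * y[1] + m$k21 * y[2],
      m$k12 * y[1] - m$k21 * y[2])
  }
  oracle <- rk4_integrate(f, y0 = c(dose * 1000 / p$Vc, 0), tt, dt = 0.002)
  sim <- simulate_2cpt(p, dosing_regimen(0, dose), tt)
  expect_equal(sim$conc, oracle[, 1], tolerance = 1e-8)
})

test_that("single-bolus AUC(0 to infinity) equals dose/CL", {
  p <- fx_mouse_pk()
  dose <- 3
  tt <- seq(0, 120, by = 0.02)
  s <- simulate_2cpt(p, dosing_regimen(0, dose), tt)
  auc <- sum(diff(tt) * (head(s$conc, -1) + tail(s$conc, -1)) / 2)
  expect_equal(auc, dose * 1000 / p$CL, tolerance = 1e-4)
})

test_that("monkey terminal half-life follows the slow eigenvalue of the rate matrix", {
  m <- macro_to_micro(fx_monkey_pk())
  A <- matrix(c(-(m$kel + m$k12), m$k21, m$k12, -m$k21), 2, 2, byrow = TRUE)
  slow <- min(abs(eigen(A)$values))
  expect_equal(pk_half_lives(fx_monkey_pk())$t_half_beta, log(2) / slow,
               tolerance = 1e-10)
  # approximately 5.9 days from the published monkey parameters
  expect_equal(log(2) / slow, 5.9, tolerance = 0.01)
})

test_that("allometric scaling uses exponent-minus-one on per-kg parameters", {
  monkey <- fx_monkey_pk()
  human <- scale_allometric(monkey, bw_source = 5, bw_target = 70)
  expect_equal(human$Vc, 38.1)                       # exponent 1: unchanged
  expect_equal(human$Vp, 20.2)
  expect_equal(human$CL, 7.2 * (70 / 5)^(-0.1), tolerance = 1e-12)
  expect_equal(human$CL, 5.52, tolerance = 0.005)    # published human value
  expect_equal(human$Q, 14.9, tolerance = 0.015)

  same <- scale_allometric(monkey, 5, 70, exp_clearance = 1)
  expect_equal(same$CL, monkey$CL)
  expect_error(scale_allometric(monkey, -5, 70), "positive")
})

test_that("dosing regimens validate ordering and signs", {
  expect_error(dosing_regimen(c(0, 0), 1), "strictly increasing")
  expect_error(dosing_regimen(c(4, 0), 1), "strictly increasing")
  expect_error(dosing_regimen(0, -1), ">= 0")
  reg <- dosing_regimen_q(3.6, 21, 4, infusion_h = 1)
  expect_equal(reg$time_day, c(0, 21, 42, 63))
  expect_equal(reg$infusion_day, rep(1 / 24, 4))
})
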