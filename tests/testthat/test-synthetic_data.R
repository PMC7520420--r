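small_design <- function(n = 3) {
  study_design(n_animals_per_arm = n, dose_arms = c(0, 1),
               measurement_days = seq(0, 21, by = 3.5))
}

test_that("generation is deterministic under a fixed seed", {
  p <- fx_jimt1()
  args <- list(small_design(), p, iiv_spec(0.4, 1.2),
               residual_error_model(13.4, 0.118), fx_mouse_pk())
  a <- do.call(generate_xenograft_study, c(args, seed = 7))
  b <- do.call(generate_xenograft_study, c(args, seed = 7))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- do.call(generate_xenograft_study, c(args, seed = 8))
  expect_false(identical(a$tumor_volume_mm3, c2$tumor_volume_mm3))
})

test_that("per-animal streams: adding animals leaves existing ones untouched", {
  p <- fx_jimt1()
  args <- function(n) list(small_design(n), p, iiv_spec(0.4, 1.2),
                           residual_error_model(13.4, 0.118),
                           fx_mouse_pk())
  small <- do.call(generate_xenograft_study, c(args(3), seed = 7))
  big <- do.call(generate_xenograft_study, c(args(5), seed = 7))
  shared <- big[big$animal_id %in% unique(small$animal_id), ]
  expect_equal(shared$tumor_volume_mm3, small$tumor_volume_mm3)
})

test_that("zero residual error reproduces the model trajectories exactly", {
  p <- fx_jimt1()
  st <- generate_xenograft_study(small_design(), p, iiv_spec(0, 0),
                                 residual_error_model(0, 0),
                                 fx_mouse_pk(), seed = 3)
  tr <- attr(st, "truth")
  a1 <- tr$animal_id[tr$dose_mg_per_kg == 1][1]
  obs <- st$tumor_volume_mm3[st$animal_id == a1]
  sim <- simulate_tgi(p, pk = fx_mouse_pk(),
                      regimen = dosing_regimen_q(1, 4, 4),
                      times = seq(0, 21, 3.5),
                      v0 = tr$v0[tr$animal_id == a1])
  expect_equal(obs, sim$TV, tolerance = 1e-8)
})

test_that("volumes respect the 1 mm^3 floor under heavy additive noise", {
  p <- fx_jimt1()
  st <- generate_xenograft_study(small_design(4), p, iiv_spec(0, 0),
                                 residual_error_model(500, 0),
                                 fx_mouse_pk(), seed = 12)
  expect_true(all(st$tumor_volume_mm3 >= 1))
})

test_that("the drawn growth rates reproduce the requested log-normal spread", {
  p <- fx_jimt1()
  design <- study_design(n_animals_per_arm = 10000, dose_arms = c(0),
                         n_doses = 1,
                         measurement_days = c(0, 7, 14))
  st <- generate_xenograft_study(design, p, iiv_spec(0.401, 1.23),
                                 residual_error_model(0, 0),
                                 fx_mouse_pk(), seed = 99)
  tr <- attr(st, "truth")
  expect_equal(sd(log(tr$kgEx)), 0.401, tolerance = 0.02)
  expect_equal(sd(log(tr$kg)), 1.23, tolerance = 0.02)
  expect_equal(median(log(tr$kgEx)), log(0.0883), tolerance = 0.02)
  expect_true(all(tr$v0 >= 150 & tr$v0 <= 300))
})

test_that("generated studies round-trip through the table readers", {
  p <- fx_jimt1()
  st <- generate_xenograft_study(small_design(), p, iiv_spec(0.4, 1.2),
                                 residual_error_model(13.4, 0.118),
                                 fx_mouse_pk(), seed = 7)
  path <- tempfile(fileext = ".csv")
  write_tumor_study(st, path)
  back <- read_tumor_study(path)
  expect_equal(as.data.frame(back)[, 1:5],
               as.data.frame(st)[, 1:5], tolerance = 1e-12)
})

test_that("clinical PK generation: noise-free curves, analyte ordering and ECD effect", {
  p <- fx_human_tmdd()
  tt <- c(0.25, 1, 3, 7, 14, 21)
  clean <- generate_clinical_pk(p, doses = 1, sampling_days = tt,
                                prop_error = 0, seed = 2)
  sim <- simulate_tmdd(p, dosing_regimen(0, 1, infusion_day = 1 / 24), tt)
  expect_equal(clean[[1]]$conc, sim$free_ugml, tolerance = 1e-9)

  tot <- generate_clinical_pk(p, doses = 1, sampling_days = tt,
                              prop_error = 0, seed = 2, analyte = "total")
  expect_true(all(tot[[1]]$conc >= clean[[1]]$conc - 1e-12))

  noisy <- generate_clinical_pk(p, doses = 1, sampling_days = tt,
                                prop_error = 0.2, seed = 2)
  expect_false(identical(noisy[[1]]$conc, clean[[1]]$conc))

  lohi <- lapply(c(2, 750), function(e) {
    generate_clinical_pk(adcpkpd:::set_ecd0(p, ecd_ngml_to_nm(e)),
                         doses = 1, sampling_days = tt, prop_error = 0,
                         seed = 2)[[1]]$conc
  })
  expect_true(all(lohi[[2]] <= lohi[[1]] + 1e-12))
})
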