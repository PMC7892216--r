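test_that("zero dose with zero noise leaves the film untouched", {
  lot <- lot_profile()
  pv <- simulate_pv(0, "R", lot, shelf_age_months = 0, sigma = 0)
  expect_equal(pv$post, pv$pre)
  expect_equal(pv$pre, lot$base_pv[1])
})

test_that("the postscan value decreases strictly with dose in every channel", {
  lot <- lot_profile()
  dose <- seq(0, 500, by = 5)
  for (ch in c("R", "G", "B")) {
    pv <- simulate_pv(dose, ch, lot, sigma = 0)
    expect_true(all(diff(pv$post) < 0))
  }
})

test_that("the generator round-trips exactly through the optical-density features", {
  lot <- lot_profile()
  dose <- c(20, 70, 150, 300, 400)
  for (age in c(0, 10)) {
    for (i in 1:3) {
      ch <- c("R", "G", "B")[i]
      pv <- simulate_pv(dose, ch, lot, shelf_age_months = age, sigma = 0)
      want <- lot$s_l * (1 + lot$drift_sens * age) *
        (lot$alpha[i] * dose / (dose + lot$beta[i]) + lot$gamma[i] * dose)
      expect_equal(net_optical_density(pv$pre, pv$post), want)
      expect_equal(inverse_transmittance(pv$post), 65535 / pv$post)
    }
  }
})

test_that("film simulation is reproducible from its seed and config", {
  cfg <- sim_config()
  f1 <- with_seed_for_tests(12, simulate_film(224, lot_profile(), 5, cfg, 3))
  f2 <- with_seed_for_tests(12, simulate_film(224, lot_profile(), 5, cfg, 3))
  expect_identical(f1, f2)
  f3 <- with_seed_for_tests(13, simulate_film(224, lot_profile(), 5, cfg, 3))
  expect_false(identical(f1, f3))
})

test_that("doses follow the depth-dose geometry: build-up then exponential fall-off", {
  cfg <- sim_config(noise_sigma = 0)
  film <- simulate_film(300, lot_profile(), 0, cfg)
  past <- film$position_mm > cfg$buildup_mm
  expect_true(all(diff(film$dose_cGy[past]) < 0))
  expect_equal(max(film$dose_cGy), 300, tolerance = 0.05)
  # and the tabulated PDD agrees with the dose mapping used by the generator
  pdd <- synthetic_pdd(cfg)
  expect_equal(dose_at_position(300, pdd, film$position_mm[10]),
               film$dose_cGy[10], tolerance = 1e-6)
})

test_that("shelf aging darkens the background and boosts the response monotonically", {
  lot <- lot_profile()
  ages <- 0:20
  pre <- vapply(ages, function(t) simulate_pv(100, "R", lot, t, 0)$pre, numeric(1))
  nods <- vapply(ages, function(t) {
    pv <- simulate_pv(100, "R", lot, t, 0)
    net_optical_density(pv$pre, pv$post)
  }, numeric(1))
  expect_true(all(diff(pre) < 0))
  expect_true(all(diff(nods) > 0))
})

test_that("channel sensitivity ordering R > G > B is enforced", {
  lot <- lot_profile()
  s <- lot$alpha / lot$beta
  expect_true(s[1] > s[2] && s[2] > s[3])
  expect_error(lot_profile(alpha = c(0.2, 0.4, 0.22)), "ordered",
               class = "filmhnn_input_error")
})

test_that("lots differing only in sensitivity are linked by a smooth monotone response map", {
  cfg <- sim_config(noise_sigma = 0)
  base <- lot_profile("C", s_l = 1)
  shifted <- lot_profile("X", s_l = 1.07)
  dose <- seq(20, 400, by = 5)
  pc <- simulate_pv(dose, "R", base, 0, 0)$post
  px <- simulate_pv(dose, "R", shifted, 0, 0)$post
  # same dose ordering, and the map pc -> px is strictly increasing
  o <- order(pc)
  expect_true(all(diff(px[o]) > 0))
})

test_that("the full study has the expected shape and is deterministic", {
  st <- fixture_study()
  expect_equal(nrow(st$portion1), 11 * 220)
  expect_equal(nrow(st$portion2), 16 * 220)
  expect_equal(nrow(st$aging_test), 220)
  expect_equal(nrow(st$lota_rest), 6 * 220)
  expect_equal(nrow(st$lotb_rest), 2 * 220)
  expect_equal(unique(st$aging_test$shelf_age_months), 20)
  expect_equal(max(st$portion2$shelf_age_months), 16)
  expect_equal(range(round(st$portion2$dose_cGy)), c(20, 399))
  # individual films are independently reproducible
  again <- generate_study()
  expect_identical(st$portion2, again$portion2)
  expect_identical(st$aging_test, again$aging_test)
})
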