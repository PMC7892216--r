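test_that("per-subnet and total parameter counts match the analytic formula", {
  spec <- hnn_spec()
  counts <- vapply(names(spec), function(nm) count_params(spec[nm]), integer(1))
  expect_equal(unname(counts),
               c(335L, 126L, 115L, 115L, 180L, 125L, 213L))
  expect_identical(count_params(spec), 1209L)
  # a trivial 1-1 linear net has one weight and one bias
  expect_identical(count_params(list(list(layer_sizes = c(1, 1)))), 2L)
})

test_that("the architecture is validated: topology, activations, linear outputs", {
  expect_error(hnn_spec(activations = list(O3 = c("relu", "tanh", "linear"))),
               "unknown activation", class = "filmhnn_input_error")
  expect_error(hnn_spec(activations = list(O3 = c("relu", "relu", "relu"))),
               "linear output", class = "filmhnn_input_error")
  bad <- hnn_spec()
  bad$O5$layer_sizes <- c(3, 16, 7, 1)
  expect_error(filmhnn:::validate_hnn_spec(bad), "layer sizes",
               class = "filmhnn_input_error")
})

test_that("seeded builds are reproducible and seeds differentiate", {
  w1 <- filmhnn:::hnn_init_weights(hnn_spec(), 435)
  w2 <- filmhnn:::hnn_init_weights(hnn_spec(), 435)
  w3 <- filmhnn:::hnn_init_weights(hnn_spec(), 436)
  expect_identical(w1, w2)
  expect_false(identical(w1, w3))
  # uniform range respected, biases start at zero
  allw <- unlist(lapply(w1, function(sn) lapply(sn, `[[`, "W")))
  expect_true(all(abs(allw) <= 0.05))
  expect_true(all(unlist(lapply(w1, function(sn) lapply(sn, `[[`, "b"))) == 0))
})

test_that("backpropagated gradients match central finite differences", {
  net <- filmhnn:::hnn_init_weights(hnn_spec(), 7, init_range = c(-0.6, 0.6))
  set.seed(8)
  for (sn in names(net)) for (l in seq_along(net[[sn]])) {
    net[[sn]][[l]]$b <- runif(length(net[[sn]][[l]]$b), -0.3, 0.3)
  }
  X <- matrix(runif(40, 0.5, 2), 4, 10)
  y <- runif(4, 0.5, 3)
  fw <- filmhnn:::hnn_forward(net, X, cache = TRUE)
  g <- filmhnn:::hnn_backward(net, fw, 2 * (fw$out - y) / length(y))
  loss <- function(n) mean((filmhnn:::hnn_forward(n, X) - y)^2)
  eps <- 1e-5
  for (sn in names(net)) for (l in seq_along(net[[sn]])) {
    W <- net[[sn]][[l]]$W
    for (k in sample(length(W), min(3, length(W)))) {
      n2 <- net
      n2[[sn]][[l]]$W[k] <- W[k] + eps; up <- loss(n2)
      n2[[sn]][[l]]$W[k] <- W[k] - eps; dn <- loss(n2)
      expect_equal(g[[sn]]$gW[[l]][k], (up - dn) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("training is deterministic under a fixed seed", {
  dat <- fixture_quiet_study()$portion1
  dat <- dat[seq(1, nrow(dat), by = 6), ]
  ctl <- hnn_control(epochs = 8, seed = 435)
  m1 <- hnn_fit(dat, control = ctl)
  m2 <- hnn_fit(dat, control = ctl)
  expect_identical(m1$subnets, m2$subnets)
  m3 <- hnn_fit(dat, control = hnn_control(epochs = 8, seed = 1))
  expect_false(identical(m1$subnets, m3$subnets))
})

test_that("a constant-dose dataset regresses to the constant", {
  set.seed(5)
  pre <- matrix(runif(360, 39000, 43000), ncol = 3)
  post <- pre * 10^(-0.2 * matrix(runif(360, 0.95, 1.05), ncol = 3))
  dat <- cbind(build_features(pre, post), dose_cGy = 200)
  m <- hnn_fit(dat, control = hnn_control(epochs = 400, seed = 435))
  p <- predict(m, dat)
  expect_lt(mean(abs(p - 200)), 3)
  expect_true(all(abs(p - 200) < 200 * 0.05))
})

test_that("training converges on noiseless synthetic data at protocol settings", {
  cfg <- sim_config(noise_sigma = 0, n_positions = 125, seed = 91)
  study <- generate_study(cfg)
  dat <- study$portion2
  expect_equal(nrow(dat), 2000L)
  m <- hnn_fit(dat)  # default control: batch 20, 500 epochs, split 0.45
  h <- m$history
  expect_lte(h$mae[nrow(h)], 3)
  # the 50-epoch-smoothed training loss trends monotonically downward:
  # non-increasing between checkpoints up to transient optimizer spikes,
  # with orders-of-magnitude overall decrease
  sm <- stats::filter(h$mse, rep(1 / 50, 50), sides = 1)
  sm <- sm[!is.na(sm)]
  ck <- sm[seq(1, length(sm), by = 50)]
  expect_true(all(diff(log(ck)) < log(1.3)))
  expect_lt(sm[length(sm)], 1e-3 * sm[1])
  assign("noiseless_protocol_model", m, envir = .fixtures)
  assign("noiseless_protocol_study", study, envir = .fixtures)
})

test_that("predictions increase monotonically with dose on a noiseless single-lot grid", {
  m <- get("noiseless_protocol_model", envir = .fixtures)
  study <- get("noiseless_protocol_study", envir = .fixtures)
  # dose grid spanning the training range at a training-age film
  cfg <- sim_config(noise_sigma = 0, n_positions = 125, seed = 91)
  film <- simulate_film(400, study$lots$C, 8, cfg)
  film <- film[order(film$dose_cGy), ]
  film <- film[c(TRUE, diff(film$dose_cGy) > 2), ]  # drop near-duplicate doses
  p <- predict(m, film)
  expect_true(all(diff(p) > 0))
})

test_that("background-PV inputs drive the shelf-age compensation", {
  # depriving the model of the aged background (replacing the prescan PVs
  # with fresh-film values) must worsen the late-age verification error
  m <- fixture_portion2_model()
  test <- fixture_study()$aging_test
  base <- lot_profile("C")$base_pv
  honest <- run_aging_test(m, test)
  blinded <- test
  blinded$R_bpv <- base[1]; blinded$G_bpv <- base[2]; blinded$B_bpv <- base[3]
  blind <- run_aging_test(m, blinded)
  expect_gt(blind$mean_abs_pct, honest$mean_abs_pct)
})

test_that("a model survives the JSON serialization round trip", {
  dat <- fixture_quiet_study()$portion1
  dat <- dat[seq(1, nrow(dat), by = 12), ]
  m <- hnn_fit(dat, control = hnn_control(epochs = 5, seed = 2))
  path <- tempfile(fileext = ".json")
  write_hnn(m, path)
  m2 <- read_hnn(path)
  expect_equal(predict(m2, dat), predict(m, dat), tolerance = 1e-12)
  expect_equal(m2$control$seed, m$control$seed)
})
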