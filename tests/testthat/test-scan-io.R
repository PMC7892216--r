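test_that("TIFF scans round-trip onto the 16-bit scale, promoting 8-bit input", {
  p16 <- write_constant_tiff(c(40000, 42000, 41000), bits = 16L)
  s16 <- read_scan(p16, "prescan", dpi = 127)
  expect_equal(dim(s16$pixels), c(20L, 15L, 3L))
  expect_true(all(s16$pixels[, , 1] == 40000))
  expect_true(all(s16$pixels[, , 2] == 42000))
  expect_true(all(s16$pixels[, , 3] == 41000))

  p8 <- write_constant_tiff(c(100, 100, 100), bits = 8L)
  s8 <- read_scan(p8, "postscan", dpi = 127)
  expect_true(all(s8$pixels == 100 * 257))
  expect_identical(s8$bits, 8L)

  expect_error(read_scan(tempfile(), "prescan", dpi = 127), "not found")
  expect_error(read_scan(p16, "prescan"), "resolution",
               class = "filmhnn_input_error")
})

test_that("synthetic scans read back with the written pixel grid", {
  film <- with_seed_for_tests(1, simulate_film(200, lot_profile(), 0,
                                               sim_config(noise_sigma = 0, n_positions = 50)))
  paths <- write_synthetic_scans(film, sim_config(), tempdir(), width_px = 15,
                                 basename = "roundtrip")
  sc <- read_scan(paths$post, "postscan", dpi = 127)
  rows_mm <- seq(min(film$position_mm), max(film$position_mm), by = 25.4 / 127)
  want <- round(stats::approx(film$position_mm, film$R_ipv, xout = rows_mm, rule = 2)$y)
  expect_equal(as.numeric(sc$pixels[, 8, 1]), want)
})

test_that("midline profile reproduces per-row window means", {
  # red channel decreasing linearly down the rows, G/B constant
  h <- 40; w <- 21
  px <- array(0, dim = c(h, w, 3))
  px[, , 1] <- matrix(seq(50000, 30000, length.out = h), h, w)
  px[, , 2] <- 42000
  px[, , 3] <- 41000
  # add lateral structure so the window actually averages something
  px[, , 1] <- px[, , 1] + outer(rep(1, h), seq(-50, 50, length.out = w))
  sc <- as_film_scan(px)

  prof <- extract_midline_profile(sc, window_px = 3, step_px = 2)
  rows <- seq(1, h, by = 2)
  mid <- floor(w / 2) + 1
  brute <- sapply(rows, function(r) mean(px[r, (mid - 3):(mid + 3), 1]))
  expect_equal(prof$R_pv, brute)
  expect_true(all(prof$G_pv == 42000))
  expect_equal(prof$position_mm, (rows - 1) * 25.4 / 127)

  # step of 5 px at 127 dpi is a 1.0 mm sampling step
  prof5 <- extract_midline_profile(sc, window_px = 3, step_px = 5)
  expect_equal(diff(prof5$position_mm), rep(1.0, length(prof5$position_mm) - 1))

  # constant image gives a constant profile for any window
  pc <- array(12345, dim = c(10, 11, 3))
  profc <- extract_midline_profile(as_film_scan(pc), window_px = 5, step_px = 1)
  expect_true(all(profc$R_pv == 12345))
})

test_that("midline extraction is invariant to a left-right flip", {
  set.seed(42)
  px <- array(runif(30 * 21 * 3, 1000, 60000), dim = c(30, 21, 3))
  # make the window symmetric content-wise irrelevant: flip means mirrored cols
  flipped <- px[, 21:1, , drop = FALSE]
  p1 <- extract_midline_profile(as_film_scan(px), window_px = 4, step_px = 3)
  p2 <- extract_midline_profile(as_film_scan(flipped), window_px = 4, step_px = 3)
  expect_equal(p1, p2)
})

test_that("window wider than the image is an error", {
  px <- array(100, dim = c(10, 7, 3))
  expect_error(extract_midline_profile(as_film_scan(px), window_px = 5),
               "exceeds", class = "filmhnn_input_error")
})

test_that("profile pairing matches on position and drops the rest", {
  pre <- data.frame(position_mm = c(0, 1, 2, 3), R_pv = 1:4 * 100,
                    G_pv = 1:4 * 100, B_pv = 1:4 * 100)
  post <- data.frame(position_mm = c(1, 2, 5), R_pv = c(90, 80, 70),
                     G_pv = c(90, 80, 70), B_pv = c(90, 80, 70))
  paired <- pair_profiles(pre, post)
  expect_equal(paired$position_mm, c(1, 2))
  expect_equal(paired$R_bpv, c(200, 300))
  expect_equal(paired$R_ipv, c(90, 80))
  expect_identical(attr(paired, "n_pairs"), 2L)

  post_far <- transform(post, position_mm = position_mm + 100)
  expect_error(pair_profiles(pre, post_far), "overlap",
               class = "filmhnn_input_error")
})
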