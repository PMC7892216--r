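# Shared fixtures. Expensive objects (the full synthetic study, trained
# networks) are built once per test run and cached; everything is generated
# in code from fixed seeds.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# The full default study at protocol scale (seed 435, noise 0.003).
fixture_study <- function() cached("study", generate_study())

# Networks trained at the full verification protocol.
fixture_portion2_model <- function() cached("m_portion2", {
  hnn_fit(fixture_study()$portion2)
})
fixture_portion1_model <- function() cached("m_portion1", {
  hnn_fit(fixture_study()$portion1)
})

# A small noiseless single-lot study and a quickly trained network on it,
# for qualitative model checks (monotonicity, self-consistency).
fixture_quiet_config <- function() {
  sim_config(noise_sigma = 0, n_positions = 60, seed = 20260901)
}

fixture_quiet_study <- function() cached("quiet_study", {
  generate_study(fixture_quiet_config())
})

fixture_quiet_model <- function() cached("quiet_model", {
  hnn_fit(fixture_quiet_study()$portion2,
          control = hnn_control(epochs = 150, seed = 435))
})

# Write a constant-valued RGB TIFF and return its path.
write_constant_tiff <- function(rgb, nrow = 20, ncol = 15, bits = 16L,
                                path = tempfile(fileext = ".tif")) {
  denom <- if (bits == 8L) 255 else 65535
  px <- array(rep(rgb / denom, each = nrow * ncol), dim = c(nrow, ncol, 3L))
  tiff::writeTIFF(px, path, bits.per.sample = bits, compression = "none")
  path
}

# Build a film_scan object directly from a pixel array (16-bit scale).
as_film_scan <- function(px, dpi = 127, role = "prescan") {
  structure(list(pixels = px, dpi = dpi, orientation = "portrait",
                 role = role, bits = 16L),
            class = "film_scan")
}

with_seed_for_tests <- function(seed, code) filmhnn:::with_seed(seed, code)

hnn_feature_names_for_tests <- function() filmhnn:::hnn_feature_names()
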