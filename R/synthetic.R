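#' Synthetic film lot description
#'
#' Parameters of the synthetic EBT3-like dose response of one film lot. The
#' net optical density of channel W at dose D (cGy) and shelf age t (months)
#' is modelled as a saturating term plus a linear term,
#' \deqn{\mathrm{netOD}_W = s_L (1 + r_s t)\left(\frac{\alpha_W D}{D + \beta_W} + \gamma_W D\right),}
#' the standard radiochromic phenomenology: `alpha` is the saturating netOD
#' amplitude, `beta` the half-saturation dose (cGy), `gamma` a linear slope
#' (per cGy), `s_l` the lot sensitivity factor and `r_s = drift_sens` the
#' fractional sensitivity gain per month of shelf age. The prescan
#' (background) pixel value decays with age as
#' `basePV_W * (1 - drift_bg * t)`, and the postscan value follows
#' `pv_post = pv_pre * 10^(-netOD)`.
#'
#' Defaults make red the most sensitive channel at clinical doses
#' (`alpha/beta` strictly decreasing from R to G to B, which is enforced) and
#' reproduce, over a 4-month shelf gap, conventional-calibration errors of
#' several percent.
#'
#' @param lot_id lot label.
#' @param alpha,beta,gamma length-3 numeric (R, G, B) response parameters.
#' @param s_l lot sensitivity factor (dimensionless, > 0).
#' @param drift_sens fractional sensitivity drift per month of shelf age.
#' @param drift_bg fractional background-PV loss per month of shelf age.
#' @param base_pv length-3 prescan pixel values at age 0 (16-bit scale).
#' @return an object of class `lot_profile`.
#' @export
lot_profile <- function(lot_id = "C",
                        alpha = c(R = 0.55, G = 0.40, B = 0.22),
                        beta = c(R = 300, G = 550, B = 800),
                        gamma = c(R = 2e-4, G = 1.5e-4, B = 1e-4),
                        s_l = 1,
                        drift_sens = 0.008,
                        drift_bg = 0.0015,
                        base_pv = c(R = 42000, G = 43500, B = 41000)) {
  alpha <- unname(alpha); beta <- unname(beta); gamma <- unname(gamma)
  base_pv <- unname(base_pv)
  if (any(alpha < 0) || any(beta < 0) || any(gamma < 0)) {
    stop_input("alpha, beta and gamma must be non-negative")
  }
  if (s_l <= 0) stop_input("sensitivity factor s_l must be > 0")
  if (any(base_pv <= 0) || any(base_pv > 65535)) stop_input("base_pv must lie in (0, 65535]")
  sens <- alpha / beta
  if (!(sens[1L] > sens[2L] && sens[2L] > sens[3L])) {
    stop_input("low-dose sensitivity must be ordered R > G > B (alpha/beta decreasing)")
  }
  structure(list(lot_id = lot_id, alpha = alpha, beta = beta, gamma = gamma,
                 s_l = s_l, drift_sens = drift_sens, drift_bg = drift_bg,
                 base_pv = base_pv),
            class = "lot_profile")
}

#' @export
print.lot_profile <- function(x, ...) {
  cat(sprintf("synthetic film lot '%s': s_L = %.3f, drift %.2f%%/mo (sens) %.2f%%/mo (bg)\n",
              x$lot_id, x$s_l, 100 * x$drift_sens, -100 * x$drift_bg))
  m <- rbind(alpha = x$alpha, beta = x$beta, gamma = x$gamma, base_pv = x$base_pv)
  colnames(m) <- c("R", "G", "B")
  print(m)
  invisible(x)
}

#' Configuration of the synthetic calibration study
#'
#' Geometry, dose schedule and noise of the synthetic study. One calibration
#' session exposes one film edge-on in a phantom, so a single film yields one
#' (depth, dose) sample per midline position with the dose set by the
#' delivered monitor units and the percentage depth dose (PDD). The synthetic
#' PDD rises linearly from `100 * surface_frac` % at the surface to 100 % at
#' `buildup_mm`, then decays as `exp(-atten_per_mm * (d - buildup_mm))`
#' (6 MV-like attenuation).
#'
#' The default monitor-unit schedule cycles four levels (56, 112, 224,
#' 400 MU) across the training sessions so the training doses span
#' 20–400 cGy; verification films are delivered `verification_mu` (default
#' 400 MU, the top of the calibrated range, putting their midline doses at
#' roughly 145–400 cGy where the film signal-to-noise supports per-sample
#' relative-error statistics).
#'
#' @param mu_schedule monitor units of the training-lot sessions (recycled to
#'   the number of sessions).
#' @param verification_mu monitor units of verification films (the held-back
#'   training-lot session and every session of non-training lots).
#' @param noise_sigma standard deviation of the multiplicative Gaussian
#'   scanner noise applied independently to every emitted pre and post PV.
#' @param seed base seed; every film derives its own child seed from it.
#' @param depth_range sampled midline depth range in mm.
#' @param n_positions number of midline samples per film.
#' @param buildup_mm depth of the PDD maximum (mm).
#' @param surface_frac PDD at the surface as a fraction of the maximum.
#' @param atten_per_mm exponential attenuation coefficient beyond the
#'   build-up region (per mm).
#' @param dpi scan resolution used when rendering synthetic scans.
#' @param cal_factor machine calibration, cGy per MU at the reference depth.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(mu_schedule = c(56, 112, 224, 400),
                       verification_mu = 400,
                       noise_sigma = 0.003,
                       seed = 435,
                       depth_range = c(2, 200),
                       n_positions = 220,
                       buildup_mm = 15,
                       surface_frac = 0.5,
                       atten_per_mm = 0.0055,
                       dpi = 127,
                       cal_factor = 1) {
  if (noise_sigma < 0) stop_input("noise_sigma must be >= 0")
  if (any(mu_schedule <= 0) || verification_mu <= 0) stop_input("monitor units must be > 0")
  if (depth_range[1L] < 0 || diff(depth_range) <= 0) stop_input("invalid depth_range")
  structure(list(mu_schedule = mu_schedule, verification_mu = verification_mu,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 depth_range = depth_range, n_positions = as.integer(n_positions),
                 buildup_mm = buildup_mm, surface_frac = surface_frac,
                 atten_per_mm = atten_per_mm, dpi = dpi, cal_factor = cal_factor),
            class = "sim_config")
}

# PDD value (percent) at depth d (mm) for a sim_config.
pdd_value <- function(config, depth_mm) {
  b <- config$buildup_mm
  ifelse(depth_mm < b,
         100 * (config$surface_frac + (1 - config$surface_frac) * depth_mm / b),
         100 * exp(-config$atten_per_mm * (depth_mm - b)))
}

#' Tabulated synthetic percentage depth dose
#'
#' @param config a [sim_config()].
#' @param step_mm tabulation step in mm.
#' @return `data.frame` with columns `depth_mm`, `pdd_percent`, covering the
#'   configured depth range (extended to depth 0).
#' @export
synthetic_pdd <- function(config = sim_config(), step_mm = 1) {
  depth <- seq(0, ceiling(config$depth_range[2L]) + step_mm, by = step_mm)
  data.frame(depth_mm = depth, pdd_percent = pdd_value(config, depth))
}

#' Simulate paired pre/post pixel values for one channel
#'
#' Applies the lot's dose response (see [lot_profile()]): the prescan value
#' is the aged background, the postscan value attenuates it by
#' `10^(-netOD)`, and both are multiplied by independent Gaussian noise
#' factors `N(1, sigma)` drawn from the current RNG stream. Values are kept
#' real-valued (profile-table convention); quantisation to the integer pixel
#' grid happens only when rendering scan images.
#'
#' @param dose delivered dose(s), cGy, >= 0.
#' @param channel `"R"`, `"G"` or `"B"`.
#' @param lot a [lot_profile()].
#' @param shelf_age_months film shelf age at exposure, months.
#' @param sigma multiplicative noise standard deviation (0 = noiseless).
#' @return list with numeric vectors `pre` and `post`, clipped to
#'   \[1, 65535\].
#' @export
simulate_pv <- function(dose, channel = c("R", "G", "B"), lot,
                        shelf_age_months = 0, sigma = 0) {
  channel <- match.arg(channel)
  if (any(dose < 0)) stop_input("dose must be >= 0")
  if (!inherits(lot, "lot_profile")) stop_input("lot must be a lot_profile")
  i <- match(channel, c("R", "G", "B"))
  netod <- lot$s_l * (1 + lot$drift_sens * shelf_age_months) *
    (lot$alpha[i] * dose / (dose + lot$beta[i]) + lot$gamma[i] * dose)
  pre <- rep(lot$base_pv[i] * (1 - lot$drift_bg * shelf_age_months), length(dose))
  post <- pre * 10^(-netod)
  if (sigma > 0) {
    pre <- pre * stats::rnorm(length(pre), 1, sigma)
    post <- post * stats::rnorm(length(post), 1, sigma)
  }
  list(pre = pmin(pmax(pre, 1), 65535), post = pmin(pmax(post, 1), 65535))
}

#' Simulate one calibration film
#'
#' One film exposed edge-on: midline positions across the configured depth
#' range, delivered dose `mu * cal_factor * pdd(depth) / 100` at each
#' position, and noisy paired pre/post pixel values for all three channels.
#' Randomness is drawn from the current RNG stream; seed externally (or via
#' [generate_study()], which derives a child seed per film) for
#' reproducibility.
#'
#' @param mu delivered monitor units.
#' @param lot a [lot_profile()].
#' @param shelf_age_months shelf age at exposure, months.
#' @param config a [sim_config()].
#' @param calibration_index session number recorded in the table.
#' @return a sample-table `data.frame` with columns `lot_id`,
#'   `calibration_index`, `shelf_age_months`, `position_mm`, `R_bpv`,
#'   `G_bpv`, `B_bpv`, `R_ipv`, `G_ipv`, `B_ipv`, `dose_cGy`.
#' @export
simulate_film <- function(mu, lot, shelf_age_months = 0, config = sim_config(),
                          calibration_index = 1L) {
  pos <- seq(config$depth_range[1L], config$depth_range[2L],
             length.out = config$n_positions)
  dose <- mu * config$cal_factor * pdd_value(config, pos) / 100
  ch <- lapply(c("R", "G", "B"), function(w) {
    simulate_pv(dose, w, lot, shelf_age_months, config$noise_sigma)
  })
  data.frame(lot_id = lot$lot_id,
             calibration_index = as.integer(calibration_index),
             shelf_age_months = shelf_age_months,
             position_mm = pos,
             R_bpv = ch[[1L]]$pre, G_bpv = ch[[2L]]$pre, B_bpv = ch[[3L]]$pre,
             R_ipv = ch[[1L]]$post, G_ipv = ch[[2L]]$post, B_ipv = ch[[3L]]$post,
             dose_cGy = dose)
}

#' Generate the full synthetic calibration study
#'
#' Emulates the study design: a training lot (C) exposed 17 times within 20
#' months — sessions 1–16 at ages evenly spaced over 0–16 months cycling the
#' training MU schedule, and a 17th verification session 4 months after the
#' 16th (age 20 months) — plus two held-out lots with shifted sensitivity
#' factors: lot A (7 sessions, monthly) and lot B (3 sessions, monthly), all
#' delivered `verification_mu`. Each film draws its own child seed from
#' `config$seed`, so any table is reproducible in isolation.
#'
#' @param config a [sim_config()].
#' @param lot_c,lot_a,lot_b [lot_profile()] objects; the defaults give lot A
#'   +7 % and lot B -5 % sensitivity relative to the training lot.
#' @return a list of sample tables: `portion1` (training sessions 1–11),
#'   `portion2` (sessions 1–16), `aging_test` (session 17), `lota_first` /
#'   `lota_rest` (lot A session 1 / sessions 2–7), `lotb_first` /
#'   `lotb_rest` (lot B session 1 / sessions 2–3), plus `pdd` (tabulated
#'   depth dose), `config` and `lots`.
#' @export
generate_study <- function(config = sim_config(),
                           lot_c = lot_profile("C", s_l = 1),
                           lot_a = lot_profile("A", s_l = 1.07),
                           lot_b = lot_profile("B", s_l = 0.95)) {
  film <- function(lot, session, mu, age) {
    with_seed(derive_seed(config$seed, paste0("lot-", lot$lot_id, "-session-", session)),
              simulate_film(mu, lot, age, config, session))
  }
  sessions <- function(lot, mus, ages) {
    do.call(rbind, lapply(seq_along(mus), function(i) film(lot, i, mus[i], ages[i])))
  }
  mus_c <- c(rep_len(config$mu_schedule, 16L), config$verification_mu)
  ages_c <- c(seq(0, 16, length.out = 16L), 20)
  lotc <- sessions(lot_c, mus_c, ages_c)
  lota <- sessions(lot_a, rep(config$verification_mu, 7L), 0:6)
  lotb <- sessions(lot_b, rep(config$verification_mu, 3L), 0:2)
  list(portion1 = lotc[lotc$calibration_index <= 11L, ],
       portion2 = lotc[lotc$calibration_index <= 16L, ],
       aging_test = lotc[lotc$calibration_index == 17L, ],
       lota_first = lota[lota$calibration_index == 1L, ],
       lota_rest = lota[lota$calibration_index > 1L, ],
       lotb_first = lotb[lotb$calibration_index == 1L, ],
       lotb_rest = lotb[lotb$calibration_index > 1L, ],
       pdd = synthetic_pdd(config),
       config = config,
       lots = list(C = lot_c, A = lot_a, B = lot_b))
}

#' Render a film sample table as a prescan/postscan TIFF pair
#'
#' Writes 16-bit RGB TIFF images whose midline reproduces the film table's
#' pixel values: image rows sit on the dpi grid covering the film's sampled
#' positions, each row carries the (linearly interpolated) profile PV
#' constant across all columns, and values are rounded to the integer pixel
#' grid. Together with [read_scan()] and [extract_midline_profile()] this
#' closes the loop from simulated physics to image analysis.
#'
#' @param film a one-session sample table from [simulate_film()].
#' @param config the [sim_config()] used to generate it (supplies dpi).
#' @param out_dir output directory (created if needed).
#' @param width_px image width in pixels.
#' @param basename file-name stem; files are `<stem>_prescan.tif` and
#'   `<stem>_postscan.tif`.
#' @return list with `pre` and `post` file paths and `origin_mm`, the film
#'   position of the first image row (profile positions read back from the
#'   scans are relative to this origin).
#' @export
write_synthetic_scans <- function(film, config = sim_config(), out_dir = tempdir(),
                                  width_px = 41, basename = "film") {
  need <- c("position_mm", "R_bpv", "G_bpv", "B_bpv", "R_ipv", "G_ipv", "B_ipv")
  if (!all(need %in% names(film))) stop_input("film table lacks columns: ",
                                              paste(setdiff(need, names(film)), collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pos <- film$position_mm
  rows_mm <- seq(min(pos), max(pos), by = 25.4 / config$dpi)
  render <- function(cols) {
    px <- array(0, dim = c(length(rows_mm), width_px, 3L))
    for (ch in 1:3) {
      v <- stats::approx(pos, film[[cols[ch]]], xout = rows_mm, rule = 2)$y
      px[, , ch] <- matrix(round(v), length(rows_mm), width_px)
    }
    px / 65535
  }
  pre_path <- file.path(out_dir, paste0(basename, "_prescan.tif"))
  post_path <- file.path(out_dir, paste0(basename, "_postscan.tif"))
  tiff::writeTIFF(render(c("R_bpv", "G_bpv", "B_bpv")), pre_path,
                  bits.per.sample = 16L, compression = "none")
  tiff::writeTIFF(render(c("R_ipv", "G_ipv", "B_ipv")), post_path,
                  bits.per.sample = 16L, compression = "none")
  list(pre = pre_path, post = post_path, origin_mm = min(pos))
}
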