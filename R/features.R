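#' Net optical density of a colour channel
#'
#' The net optical density (NOD) of a film channel is the base-10 logarithm of
#' the ratio of the unirradiated (prescan, background) pixel value to the
#' irradiated (postscan) pixel value, `log10(pv_pre / pv_post)`. Film darkens
#' with dose, so the postscan value drops and NOD rises.
#'
#' @param pv_pre prescan (background) pixel value(s), > 0.
#' @param pv_post postscan (irradiated) pixel value(s), > 0.
#' @return dimensionless NOD, vectorised over the inputs.
#' @examples
#' net_optical_density(40000, 20000) # log10(2)
#' @export
net_optical_density <- function(pv_pre, pv_post) {
  if (any(!is.finite(pv_pre)) || any(!is.finite(pv_post)) ||
      any(pv_pre <= 0) || any(pv_post <= 0)) {
    stop_input("pixel values must be finite and > 0 to form an optical density")
  }
  log10(pv_pre / pv_post)
}

#' Inverse transmittance of a pixel value
#'
#' Inverse transmittance on the 16-bit scanner scale: `(2^16 - 1) / pv`.
#' A fully transparent film reads the scanner's full scale (65535) and has
#' inverse transmittance 1; darker film gives larger values.
#'
#' @param pv pixel value(s), > 0, on the 16-bit scale.
#' @return dimensionless inverse transmittance, vectorised.
#' @examples
#' inverse_transmittance(13107) # 5
#' @export
inverse_transmittance <- function(pv) {
  if (any(!is.finite(pv)) || any(pv <= 0)) {
    stop_input("pixel values must be finite and > 0 to form an inverse transmittance")
  }
  65535 / pv
}

#' Build the ten network input features from paired pixel values
#'
#' Expands paired prescan/postscan RGB pixel values into the ten features the
#' hierarchical network consumes, organised as five groups:
#' (1) red-channel net optical density, (2) red irradiated + background PV,
#' (3) green irradiated + background PV, (4) blue irradiated + background PV,
#' (5) red/green/blue inverse transmittances of the postscan values.
#'
#' @param pre prescan RGB pixel values: a length-3 vector, or a matrix /
#'   data.frame with three columns (R, G, B order), one row per sample.
#' @param post postscan RGB pixel values, same shape as `pre`.
#' @return a `data.frame` with columns `r_nod`, `r_ipv`, `r_bpv`, `g_ipv`,
#'   `g_bpv`, `b_ipv`, `b_bpv`, `r_it`, `g_it`, `b_it`.
#' @examples
#' build_features(c(40000, 42000, 41000), c(20000, 30000, 35000))
#' @export
build_features <- function(pre, post) {
  as_rgb <- function(x, what) {
    if (is.null(dim(x))) {
      if (length(x) != 3L) stop_input(what, " must have 3 channels (R, G, B)")
      x <- matrix(as.numeric(x), nrow = 1L)
    } else {
      x <- as.matrix(x)
      if (ncol(x) != 3L) stop_input(what, " must have 3 columns (R, G, B)")
      storage.mode(x) <- "double"
    }
    x
  }
  pre <- as_rgb(pre, "pre")
  post <- as_rgb(post, "post")
  if (nrow(pre) != nrow(post)) stop_input("pre and post must have the same number of samples")
  if (any(pre <= 0) || any(post <= 0)) stop_input("all pixel values must be > 0")
  out <- data.frame(
    r_nod = net_optical_density(pre[, 1L], post[, 1L]),
    r_ipv = post[, 1L], r_bpv = pre[, 1L],
    g_ipv = post[, 2L], g_bpv = pre[, 2L],
    b_ipv = post[, 3L], b_bpv = pre[, 3L],
    r_it = inverse_transmittance(post[, 1L]),
    g_it = inverse_transmittance(post[, 2L]),
    b_it = inverse_transmittance(post[, 3L])
  )
  out
}

#' Delivered dose at a midline position from MU and a depth-dose table
#'
#' With the film parallel to the beam axis, the dose at a midline position is
#' the delivered monitor units times the machine calibration factor times the
#' percentage depth dose (PDD) at that depth:
#' `dose = mu * cal_factor * pdd(position) / 100`.
#' The PDD table is interpolated linearly between tabulated depths; positions
#' outside the tabulated range are an error.
#'
#' @param mu delivered monitor units, > 0.
#' @param pdd a `data.frame` with columns `depth_mm` and `pdd_percent`.
#' @param position_mm depth(s) along the midline, in mm.
#' @param cal_factor machine calibration in cGy per MU under reference
#'   conditions (default 1, i.e. 1 MU delivers 1 cGy at the reference depth).
#' @return delivered dose(s) in cGy.
#' @examples
#' pdd <- data.frame(depth_mm = c(0, 50, 100), pdd_percent = c(60, 100, 75))
#' dose_at_position(200, pdd, c(50, 75))
#' @export
dose_at_position <- function(mu, pdd, position_mm, cal_factor = 1) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) stop_input("mu must be a single value > 0")
  if (!is.data.frame(pdd) || !all(c("depth_mm", "pdd_percent") %in% names(pdd))) {
    stop_input("pdd must be a data.frame with columns depth_mm and pdd_percent")
  }
  p <- stats::approx(pdd$depth_mm, pdd$pdd_percent, xout = position_mm,
                     method = "linear", rule = 1, ties = "ordered")$y
  if (any(is.na(p))) {
    stop_input("position(s) outside the tabulated PDD depth range [",
               min(pdd$depth_mm), ", ", max(pdd$depth_mm), "] mm")
  }
  mu * cal_factor * p / 100
}

#' Signed percentage dose error
#'
#' `(calculated - delivered) / delivered * 100`. Used both for the
#' conventional power-law calibration and for the network's dose estimates.
#'
#' @param calculated calculated dose(s), cGy.
#' @param delivered delivered dose(s), cGy, > 0.
#' @return signed percentage error(s).
#' @export
percent_error <- function(calculated, delivered) {
  if (any(!is.finite(delivered)) || any(delivered <= 0)) {
    stop_input("delivered dose must be finite and > 0")
  }
  (calculated - delivered) / delivered * 100
}

# Extract the 10-feature matrix (canonical column order) from a sample table
# that carries the CSV schema columns R_bpv..B_ipv, or already-built feature
# columns. Used by the model-fitting front ends.
sample_features <- function(samples) {
  fn <- hnn_feature_names()
  if (all(fn %in% names(samples))) {
    m <- as.matrix(samples[, fn, drop = FALSE])
  } else {
    need <- c("R_bpv", "G_bpv", "B_bpv", "R_ipv", "G_ipv", "B_ipv")
    if (!all(need %in% names(samples))) {
      stop_input("samples must contain either the ten feature columns or the raw PV columns ",
                 paste(need, collapse = ", "))
    }
    m <- as.matrix(build_features(samples[, c("R_bpv", "G_bpv", "B_bpv")],
                                  samples[, c("R_ipv", "G_ipv", "B_ipv")]))
  }
  storage.mode(m) <- "double"
  m
}
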