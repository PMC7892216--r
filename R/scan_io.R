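#' Read a film scan from a TIFF file
#'
#' Reads an RGB TIFF film scan (8 or 16 bits per channel) into a `film_scan`
#' object on the common 16-bit scale. 8-bit images are promoted by
#' multiplication with 257 so a full-scale 8-bit pixel maps to 65535. The
#' scan resolution is taken from the TIFF metadata when present; otherwise
#' `dpi` must be supplied.
#'
#' @param path path to an RGB TIFF file.
#' @param role `"prescan"` (background, before irradiation) or `"postscan"`.
#' @param dpi dots-per-inch override; required when the file metadata carries
#'   no resolution.
#' @param orientation `"portrait"` (long axis = depth axis, the scanning
#'   convention assumed throughout) or `"landscape"`.
#' @return a `film_scan` object: list with `pixels` (h x w x 3 array of
#'   values in \[0, 65535\]), `dpi`, `orientation`, `role`, `bits`.
#' @seealso [extract_midline_profile()]
#' @export
read_scan <- function(path, role = c("prescan", "postscan"), dpi = NULL,
                      orientation = c("portrait", "landscape")) {
  role <- match.arg(role)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_input("file not found: ", path)
  img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e) stop_input("cannot decode TIFF: ", conditionMessage(e)))
  if (length(dim(img)) != 3L || dim(img)[3L] < 3L) {
    stop_input("scan must be an RGB image; got ", length(dim(img)), "-d data")
  }
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  if (!bits %in% c(8L, 16L)) stop_input("only 8- or 16-bit scans are supported (got ", bits, ")")
  # readTIFF normalises to [0,1]; rescale to the integer 16-bit grid.
  # 8-bit: v/255 * 65535 == v * 257, the promotion convention.
  px <- round(img[, , 1:3, drop = FALSE] * 65535)
  if (is.null(dpi)) {
    xres <- attr(img, "x.resolution")
    unit <- attr(img, "resolution.unit")
    if (!is.null(xres) && is.finite(xres) && xres > 0 &&
        (is.null(unit) || unit %in% c("inch", 2))) {
      dpi <- xres
    } else {
      stop_input("scan carries no resolution metadata; supply dpi explicitly")
    }
  }
  if (dpi <= 0) stop_input("dpi must be > 0")
  structure(list(pixels = px, dpi = dpi, orientation = orientation,
                 role = role, bits = bits),
            class = "film_scan")
}

#' @export
print.film_scan <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("film scan (%s, %s): %d x %d px, %d-bit source, %g dpi\n",
              x$role, x$orientation, d[1L], d[2L], x$bits, x$dpi))
  invisible(x)
}

#' Extract the midline depth profile of a film scan
#'
#' With the film irradiated edge-on (plane parallel to the beam axis, midline
#' on the central axis), depth runs along the scan's long axis and the
#' midline is the central pixel column. At every `step_px`-th row the RGB
#' pixel values are averaged over the columns within `window_px` of the
#' central column, and the row index is converted to a depth in mm through
#' the scan dpi (25.4 mm per inch). Position 0 is the first sampled row.
#'
#' @param scan a [read_scan()] object.
#' @param window_px lateral half-width of the averaging window, in pixels
#'   (the window spans `2 * window_px + 1` columns).
#' @param step_px row sampling step in pixels (5 px at 127 dpi is 1 mm).
#' @param transpose set `TRUE` when the depth axis runs along the scan rows
#'   (landscape convention); the image is transposed before extraction.
#' @return a `data.frame` of class `midline_profile` with columns
#'   `position_mm`, `R_pv`, `G_pv`, `B_pv`, and attributes `window_px`,
#'   `step_px`, `dpi`, `role`.
#' @export
extract_midline_profile <- function(scan, window_px = 5, step_px = 5,
                                    transpose = FALSE) {
  if (!inherits(scan, "film_scan")) stop_input("scan must be a film_scan object")
  if (window_px < 1 || step_px < 1) stop_input("window_px and step_px must be >= 1")
  px <- scan$pixels
  if (transpose) px <- aperm(px, c(2L, 1L, 3L))
  h <- dim(px)[1L]; w <- dim(px)[2L]
  mid <- floor(w / 2) + 1L  # central column, 0-based floor(w/2)
  cols <- (mid - window_px):(mid + window_px)
  if (cols[1L] < 1L || cols[length(cols)] > w) {
    stop_input("averaging window (+/-", window_px, " px around column ", mid,
               ") exceeds the image width ", w)
  }
  rows <- seq.int(1L, h, by = as.integer(step_px))
  pv <- vapply(1:3, function(ch) rowMeans(px[rows, cols, ch, drop = FALSE]),
               numeric(length(rows)))
  out <- data.frame(position_mm = (rows - 1L) * 25.4 / scan$dpi,
                    R_pv = pv[, 1L], G_pv = pv[, 2L], B_pv = pv[, 3L])
  attr(out, "window_px") <- window_px
  attr(out, "step_px") <- step_px
  attr(out, "dpi") <- scan$dpi
  attr(out, "role") <- scan$role
  class(out) <- c("midline_profile", "data.frame")
  out
}

#' Pair prescan and postscan midline profiles by position
#'
#' Matches the two profiles on `position_mm` (to sub-micrometre tolerance);
#' positions present in only one profile are dropped.
#'
#' @param pre prescan [extract_midline_profile()] profile.
#' @param post postscan profile sampled with the same window and step.
#' @return a `data.frame` with columns `position_mm`, `R_bpv`, `G_bpv`,
#'   `B_bpv` (prescan) and `R_ipv`, `G_ipv`, `B_ipv` (postscan), and an
#'   `n_pairs` attribute.
#' @export
pair_profiles <- function(pre, post) {
  for (p in list(pre, post)) {
    if (!all(c("position_mm", "R_pv", "G_pv", "B_pv") %in% names(p))) {
      stop_input("profiles must have columns position_mm, R_pv, G_pv, B_pv")
    }
  }
  wp <- c(attr(pre, "window_px"), attr(post, "window_px"))
  sp <- c(attr(pre, "step_px"), attr(post, "step_px"))
  if (length(wp) == 2L && wp[1L] != wp[2L]) stop_input("profiles use different averaging windows")
  if (length(sp) == 2L && sp[1L] != sp[2L]) stop_input("profiles use different sampling steps")
  key_pre <- round(pre$position_mm, 6)
  key_post <- round(post$position_mm, 6)
  m <- match(key_pre, key_post)
  keep <- which(!is.na(m))
  if (!length(keep)) stop_input("no overlapping positions between the two profiles")
  out <- data.frame(position_mm = pre$position_mm[keep],
                    R_bpv = pre$R_pv[keep], G_bpv = pre$G_pv[keep], B_bpv = pre$B_pv[keep],
                    R_ipv = post$R_pv[m[keep]], G_ipv = post$G_pv[m[keep]], B_ipv = post$B_pv[m[keep]])
  attr(out, "n_pairs") <- nrow(out)
  out
}
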