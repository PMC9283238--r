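#' Generate a synthetic bone Raman spectrum with known ground truth
#'
#' Builds a spectrum on the 800-1800 cm^-1 grid (1 cm^-1 step) from three
#' Gaussian bands - nu1-phosphate at 959 cm^-1, nu1-carbonate at 1073 cm^-1
#' (FWHM 16) and Amide I at 1660 cm^-1 (FWHM 24); the fixed centres and
#' widths keep the carbonate and Amide bands more than three standard
#' deviations inside the default integration windows, so windowed
#' trapezoidal areas are unbiased - whose areas realise the requested
#' mineral-to-matrix ratio and carbonate substitution exactly and whose
#' phosphate width equals the requested FWHM. A smooth cubic
#' fluorescence-like background, optional cosmic-ray spikes and
#' multiplicative Gaussian noise emulate the raw instrument signal.
#'
#' @param mmr true mineral-to-matrix ratio (phosphate/Amide I area).
#' @param carbonate true carbonate substitution (carbonate/phosphate area).
#' @param fwhm true phosphate FWHM in cm^-1, in (5, 60).
#' @param noise multiplicative noise fraction (0 for noiseless).
#' @param baseline baseline amplitude relative to the phosphate peak height
#'   (0 disables the background).
#' @param n_spikes number of cosmic-ray spikes to inject.
#' @param seed RNG seed (noise, spike positions); required when
#'   \code{noise > 0} for reproducibility.
#' @param amide_area Amide I band area in arbitrary units (sets the overall
#'   intensity scale).
#' @param meta metadata list attached to the spectrum.
#' @return a \code{raw} \code{raman_spectrum}; the ground truth is attached
#'   as attribute \code{"truth"}.
#' @export
generate_spectrum <- function(mmr, carbonate, fwhm, noise = 0.01,
                              baseline = 0.5, n_spikes = 0L, seed = NULL,
                              amide_area = 100, meta = list()) {
  stopifnot(mmr > 0, carbonate > 0, fwhm > 5, fwhm < 60, noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  x <- seq(800, 1800, by = 1)
  sig_p <- fwhm / (2 * sqrt(2 * log(2)))
  gauss <- function(center, sigma, area) {
    area / (sigma * sqrt(2 * pi)) * exp(-(x - center)^2 / (2 * sigma^2))
  }
  a_po4 <- mmr * amide_area
  a_co3 <- carbonate * a_po4
  y <- gauss(959, sig_p, a_po4) +
    gauss(1073, 16 / (2 * sqrt(2 * log(2))), a_co3) +
    gauss(1660, 24 / (2 * sqrt(2 * log(2))), amide_area)
  peak <- max(y)
  if (baseline > 0) {
    u <- (x - 800) / 1000
    y <- y + baseline * peak * (0.8 - 0.9 * u + 0.6 * u^2 - 0.3 * u^3)
  }
  if (noise > 0) {
    y <- y * (1 + noise * stats::rnorm(length(y)))
  }
  if (n_spikes > 0L) {
    pos <- sample(seq(10, length(x) - 10), n_spikes)
    y[pos] <- y[pos] + (20 + 30 * stats::runif(n_spikes)) * peak
  }
  y <- pmax(y, 0)
  s <- raman_spectrum(x, y, state = "raw", meta = meta)
  attr(s, "truth") <- list(mmr = mmr, carbonate = carbonate, fwhm = fwhm)
  s
}

#' Generate a synthetic load-controlled indentation curve
#'
#' Forward model consistent with the Oliver-Pharr equations. From the
#' targets (Er_true, H_true) and the probe geometry the model derives the
#' contact area A = Pmax / H, the contact depth from the spherical area
#' function, the stiffness S from the reduced-modulus equation, and the
#' peak displacement from the contact-depth correction. The loading branch
#' is a Hertz-type 3/2-power law scaled through the peak point (a pure
#' elastic Hertz constant would be inconsistent with a contact whose
#' hardness fixes a larger plastic depth), the hold creeps logarithmically
#' at constant load, and the unloading branch is the power law
#' \eqn{P = \alpha (h - h_f)^m} whose derivative at the peak equals S, so
#' the Oliver-Pharr analysis recovers the targets exactly in the noiseless
#' limit.
#'
#' @param Er_true target reduced modulus, GPa.
#' @param H_true target hardness, GPa.
#' @param probe a \code{probe_geometry}.
#' @param noise displacement noise fraction (Gaussian, sd =
#'   \code{noise * h_max}).
#' @param seed RNG seed.
#' @param Pmax peak load in uN (default 1000, the standard protocol).
#' @param hold_s hold duration in seconds (default 45).
#' @param ramp_s load/unload ramp duration in seconds.
#' @param dt sample interval in seconds (default 0.01, i.e. the ~100 Hz
#'   acquisition rate of load-controlled nanoindenters).
#' @param creep_nm total creep displacement during the hold.
#' @param m unloading power-law exponent.
#' @param meta metadata list.
#' @return an \code{indent_curve}; ground truth attached as attribute
#'   \code{"truth"}.
#' @export
generate_indent_curve <- function(Er_true, H_true, probe = probe_geometry(),
                                  noise = 0, seed = NULL, Pmax = 1000,
                                  hold_s = 45, ramp_s = 10, dt = 0.01,
                                  creep_nm = 2, m = 1.5, meta = list()) {
  stopifnot(Er_true > 0, H_true > 0, Pmax > 0, noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  R <- probe$radius_um
  A <- Pmax / (H_true * 1000)                  # um^2 so that H A = Pmax
  if (A / pi >= R^2) {
    stop("requested hardness needs a contact deeper than the probe radius",
         call. = FALSE)
  }
  hc_um <- R - sqrt(R^2 - A / pi)              # invert A = pi(2R hc - hc^2)
  if (hc_um >= 2 * R) {
    stop("inconsistent property pair: contact depth exceeds probe diameter",
         call. = FALSE)
  }
  hc <- hc_um * 1000                            # nm
  S <- Er_true * probe$beta * 2 / sqrt(pi) * sqrt(A)   # uN/nm
  h_max <- hc + probe$epsilon * Pmax / S
  # unloading power law anchored at (h_max, Pmax) with dP/dh = S there
  h_f <- h_max - m * Pmax / S
  alpha <- Pmax / (h_max - h_f)^m

  t_load <- seq(0, ramp_s, by = dt)
  P_load <- Pmax * t_load / ramp_s
  h_top <- h_max - creep_nm
  h_load <- h_top * (P_load / Pmax)^(2 / 3)    # P ~ h^(3/2) loading shape

  t_hold <- seq(dt, hold_s, by = dt)
  tau <- 5
  h_hold <- h_top + creep_nm * log(1 + t_hold / tau) / log(1 + hold_s / tau)
  P_hold <- rep(Pmax, length(t_hold))

  t_unl <- seq(dt, ramp_s, by = dt)
  P_unl <- Pmax * (1 - t_unl / ramp_s)
  h_unl <- h_f + (pmax(P_unl, 0) / alpha)^(1 / m)

  time <- c(t_load, ramp_s + t_hold, ramp_s + hold_s + t_unl)
  P <- c(P_load, P_hold, P_unl)
  h <- c(h_load, h_hold, h_unl)
  if (noise > 0) {
    h <- h + noise * h_max * stats::rnorm(length(h))
  }
  cv <- indent_curve(time, P, h, meta = meta)
  attr(cv, "truth") <- list(Er = Er_true, H = H_true, S = S, hc = hc,
                            A = A, h_max = h_max, h_f = h_f, m = m)
  cv
}

#' Generate a synthetic backscatter-electron image
#'
#' A Gaussian calcium field is mapped to 8-bit gray levels through the
#' inverse calibration and quantised. The mineralised tissue occupies a
#' horizontal band (the synthetic "newly formed bone" region, returned as
#' the ROI mask); the surrounding pixels emulate embedding resin at a low
#' gray level.
#'
#' @param ca_mean,ca_sd mean and SD of the calcium field, wt\%.
#' @param cal a \code{gray_calibration}.
#' @param shape image dimensions \code{c(rows, cols)}.
#' @param seed RNG seed.
#' @param meta metadata list.
#' @return a \code{bse_image}; attribute \code{"truth"} carries the field
#'   parameters.
#' @export
generate_bse_image <- function(ca_mean, ca_sd, cal = gray_calibration(),
                               shape = c(400, 400), seed = NULL,
                               meta = list()) {
  stopifnot(ca_sd >= 0, length(shape) == 2L)
  if (!is.null(seed)) set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  band <- seq(floor(nr / 4) + 1L, floor(3 * nr / 4))
  ca <- matrix(ca_mean, nr, nc)
  if (ca_sd > 0) {
    ca[band, ] <- ca_mean + ca_sd * stats::rnorm(length(band) * nc)
  }
  g <- (ca - cal$intercept) / cal$slope
  clipped <- g < 0 | g > 255
  if (mean(clipped[band, ]) > 0.001) {
    stop("calcium field clips more than 0.1% of ROI pixels at 8 bits",
         call. = FALSE)
  }
  g <- round(pmin(pmax(g, 0), 255))
  px <- matrix(10, nr, nc)                     # resin background
  px[band, ] <- g[band, ]
  mask <- matrix(FALSE, nr, nc)
  mask[band, ] <- TRUE
  img <- bse_image(px, mask, meta = meta)
  attr(img, "truth") <- list(ca_mean = ca_mean, ca_sd = ca_sd)
  img
}
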