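#' Construct a nanoindentation load-displacement record
#'
#' @param time time in seconds, strictly increasing.
#' @param load load P in micronewtons.
#' @param displacement displacement h in nanometres.
#' @param segments optional integer vector \code{c(load_end, hold_end)} of
#'   segment boundary indices (set by \code{\link{segment_curve}}).
#' @param meta named metadata list (sample, group, region, distance_um).
#' @return an object of class \code{indent_curve}.
#' @export
indent_curve <- function(time, load, displacement, segments = NULL,
                         meta = list()) {
  time <- as.numeric(time)
  load <- as.numeric(load)
  displacement <- as.numeric(displacement)
  n <- length(time)
  if (length(load) != n || length(displacement) != n) {
    stop("time, load and displacement must have equal length", call. = FALSE)
  }
  if (n < 30L) stop("an indent record needs at least 30 points", call. = FALSE)
  if (any(diff(time) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (!is.null(segments)) {
    segments <- as.integer(segments)
    stopifnot(length(segments) == 2L,
              segments[1] >= 1L, segments[1] < segments[2], segments[2] < n)
  }
  structure(list(time = time, load = load, displacement = displacement,
                 segments = segments, meta = meta),
            class = "indent_curve")
}

#' @export
print.indent_curve <- function(x, ...) {
  cat(sprintf("<indent_curve> %d points, Pmax %.1f uN, hmax %.1f nm%s\n",
              length(x$time), max(x$load), max(x$displacement),
              if (is.null(x$segments)) " (unsegmented)" else
                sprintf(", segments at %d/%d", x$segments[1], x$segments[2])))
  invisible(x)
}

#' Spherical probe geometry
#'
#' Geometry of the indenter tip used in the Oliver-Pharr analysis. The
#' default radius matches a 1.03-um spherical diamond probe; \code{beta} is
#' the geometric correction factor of the reduced-modulus equation and
#' \code{epsilon} the intercept factor of the contact-depth correction
#' (0.75, the standard value for spherical/paraboloid contact).
#'
#' @param radius_um probe radius in micrometres.
#' @param beta geometric factor (> 0).
#' @param epsilon intercept factor in (0, 1].
#' @return a \code{probe_geometry} object.
#' @export
probe_geometry <- function(radius_um = 1.03, beta = 1, epsilon = 0.75) {
  stopifnot(radius_um > 0, beta > 0, epsilon > 0, epsilon <= 1)
  structure(list(shape = "sphere", radius_um = radius_um,
                 beta = beta, epsilon = epsilon),
            class = "probe_geometry")
}

#' Segment an indent record into load / hold / unload phases
#'
#' Boundaries follow the load-control protocol (ramp to peak, constant-load
#' hold, unload): the load segment ends at the first sample reaching
#' \code{(1 - hold_tolerance) * Pmax}, and the hold segment ends at the last
#' sample still at the plateau, i.e. the last sample before the load drops
#' by more than \code{hold_tolerance * Pmax} below the peak for good.
#'
#' @param curve an \code{indent_curve}.
#' @param hold_tolerance load plateau tolerance as a fraction of the peak
#'   load.
#' @return the curve with \code{segments} set.
#' @export
segment_curve <- function(curve, hold_tolerance = 0.02) {
  stopifnot(inherits(curve, "indent_curve"),
            hold_tolerance > 0, hold_tolerance < 0.5)
  P <- curve$load
  n <- length(P)
  pmax <- max(P)
  at_peak <- which(P >= (1 - hold_tolerance) * pmax)
  load_end <- at_peak[1]
  hold_end <- at_peak[length(at_peak)]
  if (hold_end >= n) {
    stop("no unloading branch found after the hold", call. = FALSE)
  }
  if (hold_end <= load_end) {
    stop("no hold plateau detected between loading and unloading",
         call. = FALSE)
  }
  curve$segments <- c(load_end, hold_end)
  curve
}

#' Unloading stiffness from a power-law fit
#'
#' Fits the Oliver-Pharr power law \eqn{P = \alpha (h - h_f)^m} to the
#' portion of the unloading branch with load between \code{lower} and
#' \code{upper} fractions of the peak load (default the 95\%-40\% region),
#' and evaluates the contact stiffness \eqn{S = dP/dh} at the peak
#' displacement. The regression is performed in the form
#' \eqn{h = h_f + (P/\alpha)^{1/m}} because in a load-controlled indent the
#' measurement noise lives in the displacement channel; regressing the
#' noisy displacement as the predictor would attenuate the fitted slope
#' (a classical errors-in-variables bias). The peak displacement used for
#' the derivative is the fitted curve evaluated at the peak load, which
#' coincides with the observed maximum for noiseless data but is robust to
#' displacement noise. A \code{method = "secant"} alternative reports the
#' straight-line slope over the same region.
#'
#' @param curve a segmented \code{indent_curve}.
#' @param upper,lower fit range as fractions of the peak load.
#' @param method \code{"power_law"} (derivative at the peak, default) or
#'   \code{"secant"}.
#' @return list with \code{S} (uN/nm), \code{h_max} (nm), \code{P_max} (uN),
#'   the fitted \code{alpha}, \code{h_f}, \code{m}, and a logical
#'   \code{m_flag} set when the fitted exponent leaves the physical
#'   range [1, 3].
#' @export
unloading_stiffness <- function(curve, upper = 0.95, lower = 0.40,
                                method = c("power_law", "secant")) {
  stopifnot(inherits(curve, "indent_curve"))
  method <- match.arg(method)
  if (is.null(curve$segments)) curve <- segment_curve(curve)
  n <- length(curve$load)
  unl <- seq(curve$segments[2] + 1L, n)   # first post-hold sample onward
  P <- curve$load[unl]
  h <- curve$displacement[unl]
  pmax <- max(curve$load)
  h_max <- max(curve$displacement)
  if (min(P) > lower * pmax) {
    stop("unloading branch does not span below the lower fit bound",
         call. = FALSE)
  }
  sel <- P >= lower * pmax & P <= upper * pmax
  if (sum(sel) < 8L) {
    stop(sprintf("only %d unloading points in the %.0f%%-%.0f%% range",
                 sum(sel), 100 * upper, 100 * lower), call. = FALSE)
  }
  dd <- data.frame(P = P[sel], h = h[sel])
  hf_0 <- min(dd$h) - 0.25 * (max(dd$h) - min(dd$h))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      h ~ hf + (P / alpha)^(1 / m),
      data = dd,
      start = list(alpha = pmax / (h_max - hf_0)^1.5, hf = hf_0, m = 1.5),
      lower = c(alpha = 1e-12, hf = -Inf, m = 0.5),
      upper = c(alpha = Inf, hf = Inf, m = 5),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
    ),
    error = function(e) {
      stop("unloading power-law fit failed: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  cf <- as.list(stats::coef(fit))
  h_peak <- cf$hf + (pmax / cf$alpha)^(1 / cf$m)  # fitted peak displacement
  S <- switch(method,
    power_law = cf$alpha * cf$m * (h_peak - cf$hf)^(cf$m - 1),
    secant = {
      hi <- which.max(dd$P); lo <- which.min(dd$P)
      (dd$P[hi] - dd$P[lo]) / (dd$h[hi] - dd$h[lo])
    })
  if (S <= 0) stop("non-positive unloading stiffness", call. = FALSE)
  list(S = S, h_max = h_peak, P_max = pmax,
       alpha = cf$alpha, h_f = cf$hf, m = cf$m,
       m_flag = cf$m < 1 || cf$m > 3)
}

#' Spherical contact area
#'
#' Projected contact area of a spherical probe at contact depth \code{hc}:
#' \eqn{A = \pi (2 R h_c - h_c^2)}.
#'
#' @param hc contact depth in nanometres.
#' @param probe a \code{probe_geometry}.
#' @return contact area in um^2.
#' @export
contact_area <- function(hc, probe = probe_geometry()) {
  stopifnot(inherits(probe, "probe_geometry"))
  hc_um <- hc / 1000
  if (any(hc_um <= 0)) stop("contact depth must be positive", call. = FALSE)
  if (any(hc_um >= 2 * probe$radius_um)) {
    stop("contact depth exceeds the probe diameter", call. = FALSE)
  }
  pi * (2 * probe$radius_um * hc_um - hc_um^2)
}

#' Reduced elastic modulus
#'
#' \eqn{E_r = \frac{1}{\beta} \frac{\sqrt{\pi}}{2} \frac{S}{\sqrt{A}}},
#' with S in uN/nm and A in um^2, returned in GPa
#' (1 uN/nm/um^{1} = 1 GPa when divided by sqrt(um^2)).
#'
#' @param S unloading stiffness in uN/nm.
#' @param A contact area in um^2.
#' @param probe a \code{probe_geometry} (supplies beta).
#' @return reduced modulus in GPa.
#' @export
reduced_modulus <- function(S, A, probe = probe_geometry()) {
  if (any(S <= 0) || any(A <= 0)) {
    stop("stiffness and area must be positive", call. = FALSE)
  }
  (1 / probe$beta) * (sqrt(pi) / 2) * S / sqrt(A)
}

#' Indentation hardness
#'
#' \eqn{H = P_{max} / A}; with load in uN and area in um^2 the ratio is in
#' MPa, converted to GPa.
#'
#' @param Pmax peak load in uN.
#' @param A contact area in um^2.
#' @return hardness in GPa.
#' @export
hardness <- function(Pmax, A) {
  if (any(Pmax <= 0)) stop("peak load must be positive", call. = FALSE)
  if (any(A <= 0)) stop("contact area must be positive", call. = FALSE)
  (Pmax / A) / 1000
}

#' Oliver-Pharr analysis of an indent record
#'
#' Chains segmentation, the 95\%-40\% power-law unloading fit, the
#' contact-depth correction \eqn{h_c = h_{max} - \epsilon P_{max} / S}, the
#' spherical contact area, and the reduced-modulus and hardness equations.
#'
#' @param curve an \code{indent_curve} (segmented automatically if needed).
#' @param probe a \code{probe_geometry}.
#' @param upper,lower unloading fit range (fractions of peak load).
#' @return an object of class \code{indent_result}: list with \code{S}
#'   (uN/nm), \code{hc} (nm), \code{A} (um^2), \code{Er} (GPa), \code{H}
#'   (GPa), \code{Pmax} (uN), \code{h_max} (nm) and \code{m_flag}.
#' @export
analyze_indent <- function(curve, probe = probe_geometry(),
                           upper = 0.95, lower = 0.40) {
  stopifnot(inherits(curve, "indent_curve"),
            inherits(probe, "probe_geometry"))
  if (is.null(curve$segments)) {
    curve <- tryCatch(segment_curve(curve),
                  error = function(e) stop("segmentation: ",
                                           conditionMessage(e), call. = FALSE))
  }
  u <- tryCatch(unloading_stiffness(curve, upper = upper, lower = lower),
                error = function(e) stop("stiffness: ",
                                         conditionMessage(e), call. = FALSE))
  hc <- u$h_max - probe$epsilon * u$P_max / u$S
  if (hc <= 0) stop("contact depth came out non-positive", call. = FALSE)
  A <- tryCatch(contact_area(hc, probe),
                error = function(e) stop("contact area: ",
                                         conditionMessage(e), call. = FALSE))
  structure(
    list(S = u$S, hc = hc, A = A,
         Er = reduced_modulus(u$S, A, probe),
         H = hardness(u$P_max, A),
         Pmax = u$P_max, h_max = u$h_max, m = u$m, m_flag = u$m_flag),
    class = "indent_result"
  )
}

#' @export
print.indent_result <- function(x, ...) {
  cat(sprintf(
    "<indent_result> Er %.2f GPa | H %.3f GPa | S %.3f uN/nm | hc %.1f nm | A %.4f um^2\n",
    x$Er, x$H, x$S, x$hc, x$A))
  invisible(x)
}

#' Read an indent record from delimited text
#'
#' Expects a header naming columns \code{time_s}, \code{load_uN},
#' \code{disp_nm} (any delimiter that \code{read.table} autodetects; the
#' package writes tab-separated files).
#'
#' @param path file path.
#' @param meta metadata list attached to the curve.
#' @return an \code{indent_curve}.
#' @export
read_indent_curve <- function(path, meta = list()) {
  d <- utils::read.table(path, header = TRUE)
  need <- c("time_s", "load_uN", "disp_nm")
  if (!all(need %in% names(d))) {
    stop("indent file must have columns time_s, load_uN, disp_nm",
         call. = FALSE)
  }
  indent_curve(d$time_s, d$load_uN, d$disp_nm, meta = meta)
}

#' Write an indent record as tab-separated text
#'
#' @param curve an \code{indent_curve}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_indent_curve <- function(curve, path) {
  stopifnot(inherits(curve, "indent_curve"))
  d <- data.frame(time_s = curve$time, load_uN = curve$load,
                  disp_nm = curve$displacement)
  utils::write.table(format(d, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
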