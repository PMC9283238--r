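# shared fixtures: all synthetic, built in code at test time

grid_800_1800 <- seq(800, 1800, by = 1)

gauss_profile <- function(x, center, sigma, area) {
  area / (sigma * sqrt(2 * pi)) * exp(-(x - center)^2 / (2 * sigma^2))
}

# a spectrum already in a given processing state (bypasses the pipeline for
# tests that target one stage in isolation)
spectrum_in_state <- function(intensity, state, wavenumber = grid_800_1800) {
  s <- raman_spectrum(wavenumber, pmax(intensity, 0), state = "raw")
  s$intensity <- intensity          # later states may be negative
  s$state <- state
  s
}

# independent oracle: KS distance as an explicit maximum of the ECDF gap
# over every pooled evaluation point
brute_force_ks <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(p) mean(x <= p), numeric(1))
  fy <- vapply(pts, function(p) mean(y <= p), numeric(1))
  max(abs(fx - fy))
}

# trapezoid-and-hold indent load profile with known corner indices
trapezoid_curve <- function(n_ramp = 50, n_hold = 30, pmax = 100) {
  P <- c(seq_len(n_ramp) / n_ramp * pmax, rep(pmax, n_hold),
         rev(seq_len(n_ramp) - 1) / n_ramp * pmax)
  n <- length(P)
  indent_curve(seq_len(n), P, seq_len(n))
}
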