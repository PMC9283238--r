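#' Construct a Raman spectrum
#'
#' A \code{raman_spectrum} holds a single spectrum as paired
#' wavenumber/intensity vectors together with a processing-state marker and
#' measurement metadata. Processing functions advance the state strictly
#' forward through \code{raw -> baselined -> despiked -> smoothed}; each stage
#' refuses input that has not passed through the preceding one, so a pipeline
#' cannot silently skip baseline correction or despiking.
#'
#' @param wavenumber numeric vector of Raman shifts in cm^-1, strictly
#'   increasing, length >= 64.
#' @param intensity numeric vector of intensities (arbitrary counts), same
#'   length as \code{wavenumber}. Raw spectra must be non-negative; later
#'   states may contain negative values from baseline subtraction.
#' @param state processing state, one of \code{"raw"}, \code{"baselined"},
#'   \code{"despiked"}, \code{"smoothed"}.
#' @param meta named list of measurement metadata. Recognised fields:
#'   \code{sample}, \code{group}, \code{region} (\code{"periosteal"} or
#'   \code{"perilacunar"}), \code{distance_um} (perilacunar only).
#'
#' @return an object of class \code{raman_spectrum}.
#' @export
raman_spectrum <- function(wavenumber, intensity, state = "raw", meta = list()) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  state <- match.arg(state, spectrum_states())
  if (length(wavenumber) != length(intensity)) {
    stop("wavenumber and intensity must have equal length", call. = FALSE)
  }
  if (length(wavenumber) < 64L) {
    stop("a spectrum needs at least 64 points", call. = FALSE)
  }
  if (anyNA(wavenumber) || anyNA(intensity)) {
    stop("NA values are not allowed in a spectrum", call. = FALSE)
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("wavenumber must be strictly increasing", call. = FALSE)
  }
  if (state == "raw" && any(intensity < 0)) {
    stop("raw intensities must be non-negative", call. = FALSE)
  }
  structure(
    list(wavenumber = wavenumber, intensity = intensity,
         state = state, meta = meta),
    class = "raman_spectrum"
  )
}

spectrum_states <- function() c("raw", "baselined", "despiked", "smoothed")

# enforce the forward-only state machine; `from` is the state the operation
# consumes, the returned spectrum carries `to`
advance_state <- function(s, from, to) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (s$state != from) {
    stop(sprintf("spectrum must be in state '%s' (got '%s')", from, s$state),
         call. = FALSE)
  }
  states <- spectrum_states()
  if (match(to, states) != match(from, states) + 1L) {
    stop("spectrum states may only advance forward", call. = FALSE)
  }
  s$state <- to
  s
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$wavenumber)
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm^-1, state '%s'\n",
              length(x$wavenumber), rng[1], rng[2], x$state))
  if (length(x$meta)) {
    kv <- vapply(names(x$meta), function(k) {
      sprintf("%s=%s", k, format(x$meta[[k]]))
    }, character(1))
    cat("  meta:", paste(kv, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Average replicate accumulations of a spectrum
#'
#' Spectrographs acquired as repeated accumulations on an identical
#' wavenumber grid are reduced to their pointwise mean before any further
#' processing, which lowers the noise standard deviation by 1/sqrt(n).
#'
#' @param spectra list of \code{raman_spectrum} objects, all \code{raw} and
#'   on the same grid.
#' @return a single \code{raw} \code{raman_spectrum}; metadata are taken from
#'   the first accumulation.
#' @export
average_accumulations <- function(spectra) {
  if (length(spectra) == 0L) {
    stop("no spectra supplied", call. = FALSE)
  }
  stopifnot(all(vapply(spectra, inherits, logical(1), "raman_spectrum")))
  if (any(vapply(spectra, function(s) s$state, character(1)) != "raw")) {
    stop("accumulations must be raw spectra", call. = FALSE)
  }
  grid <- spectra[[1]]$wavenumber
  same <- vapply(spectra, function(s) {
    length(s$wavenumber) == length(grid) && all(s$wavenumber == grid)
  }, logical(1))
  if (!all(same)) {
    stop("accumulations are not on a common wavenumber grid", call. = FALSE)
  }
  m <- rowMeans(vapply(spectra, function(s) s$intensity,
                       numeric(length(grid))))
  raman_spectrum(grid, m, state = "raw", meta = spectra[[1]]$meta)
}

#' Read spectra from a two-column text file
#'
#' The on-disk format is delimited text with two columns (wavenumber in
#' cm^-1, intensity), \code{#} comment lines, and multiple accumulations
#' stored as blocks separated by one or more blank lines.
#'
#' @param path file path.
#' @param meta metadata list attached to every spectrum read.
#' @return a list of \code{raman_spectrum} objects, one per block.
#' @export
read_spectrum <- function(path, meta = list()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  blank <- grepl("^\\s*$", lines)
  block_id <- cumsum(c(TRUE, diff(blank) == -1L))[!blank]
  lines <- lines[!blank]
  if (!length(lines)) stop("no data in ", path, call. = FALSE)
  blocks <- split(lines, block_id)
  lapply(blocks, function(b) {
    m <- utils::read.table(text = b, header = FALSE,
                           colClasses = "numeric", col.names = c("wn", "it"))
    raman_spectrum(m$wn, m$it, state = "raw", meta = meta)
  })
}

#' Write spectra to a two-column text file
#'
#' @param spectra a \code{raman_spectrum} or list of them (written as
#'   blank-line-separated accumulation blocks).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(spectra, path) {
  if (inherits(spectra, "raman_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# wavenumber_cm-1\tintensity", con)
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    writeLines(sprintf("%.6g\t%.10g", s$wavenumber, s$intensity), con)
    if (i < length(spectra)) writeLines("", con)
  }
  invisible(path)
}
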