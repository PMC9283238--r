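#' Define a Raman band window
#'
#' @param name band identifier; one of \code{"nu1_phosphate"},
#'   \code{"nu1_carbonate"}, \code{"amide_I"}.
#' @param low,high integration window limits in cm^-1, \code{low < high}.
#' @return a \code{band_definition} object.
#' @export
band_definition <- function(name = c("nu1_phosphate", "nu1_carbonate", "amide_I"),
                            low, high) {
  name <- match.arg(name)
  low <- as.numeric(low)
  high <- as.numeric(high)
  if (!(is.finite(low) && is.finite(high) && low < high)) {
    stop("band window requires low < high", call. = FALSE)
  }
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' Default bone Raman band windows
#'
#' Windows for the nu1-phosphate (930-980 cm^-1), nu1-carbonate
#' (1050-1100 cm^-1) and Amide I (1620-1700 cm^-1) bands, the standard
#' bone-Raman literature choices. All three are configurable per analysis.
#'
#' @return named list of \code{band_definition} objects.
#' @export
default_bands <- function() {
  bands <- list(
    nu1_phosphate = band_definition("nu1_phosphate", 930, 980),
    nu1_carbonate = band_definition("nu1_carbonate", 1050, 1100),
    amide_I       = band_definition("amide_I", 1620, 1700)
  )
  check_band_overlap(bands)
  bands
}

check_band_overlap <- function(bands) {
  n <- length(bands)
  if (n < 2L) return(invisible(bands))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      a <- bands[[i]]; b <- bands[[j]]
      if (a$low < b$high && b$low < a$high) {
        stop(sprintf("band windows '%s' and '%s' overlap", a$name, b$name),
             call. = FALSE)
      }
    }
  }
  invisible(bands)
}
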