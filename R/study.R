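#' Configuration of a synthetic three-group bone-quality study
#'
#' Encodes the study design being emulated: three animal groups (control,
#' chronic kidney disease, and calcimimetic-treated CKD), periosteal
#' measurements at eight points per animal in twelve animals per group, and
#' perilacunar measurements in a subset of six animals per group at six
#' lacunae per animal, four directions per lacuna, and distances of 1, 3, 5
#' and 7 um from the lacunar wall - i.e. 6 x 6 x 4 = 144 measurements per
#' group per distance.
#'
#' Ground-truth group means and SDs are configuration parameters: the study
#' being emulated reports group differences only graphically, so the
#' defaults encode its qualitative effect directions (CKD: lower carbonate
#' substitution and lower mechanical properties; treated CKD: higher
#' crystallinity and mineral-to-matrix ratio, lower carbonate, mechanics
#' restored toward control) at plausible magnitudes for rat cortical bone,
#' and are labelled as placeholders in the ground-truth output.
#'
#' @param groups group labels (first label is the reference group).
#' @param n_periosteal_animals animals per group with periosteal data.
#' @param n_perilacunar_animals animals per group with perilacunar data.
#' @param periosteal_points measurement points per animal between the
#'   fluorochrome labels.
#' @param lacunae lacunae per animal.
#' @param directions sampling directions per lacuna.
#' @param distances_um distances from the lacunar wall, um, ascending.
#' @param truth data.frame of ground-truth means/SDs with columns
#'   \code{group}, \code{parameter}, \code{mean}, \code{sd}; defaults as
#'   described above. Parameters: \code{mmr}, \code{carbonate},
#'   \code{crystallinity} (cm), \code{Er} (GPa), \code{H} (GPa),
#'   \code{ca_mean} (wt\%).
#' @param distance_effect named list mapping a parameter to a vector of
#'   per-distance mean offsets (same length as \code{distances_um});
#'   defaults to no distance dependence.
#' @param spectrum_noise,indent_noise,image_ca_sd measurement noise levels
#'   for the three raw-data generators.
#' @param seed master RNG seed.
#' @return a \code{study_config} object.
#' @export
study_config <- function(groups = c("CTRL", "CKD", "CKD_KP"),
                         n_periosteal_animals = 12L,
                         n_perilacunar_animals = 6L,
                         periosteal_points = 8L,
                         lacunae = 6L,
                         directions = 4L,
                         distances_um = c(1, 3, 5, 7),
                         truth = default_truth(groups),
                         distance_effect = list(),
                         spectrum_noise = 0.01,
                         indent_noise = 0.005,
                         image_ca_sd = 2,
                         seed = 1L) {
  stopifnot(length(groups) >= 2L, !anyDuplicated(groups),
            all(distances_um > 0), !is.unsorted(distances_um, strictly = TRUE),
            all(c("group", "parameter", "mean", "sd") %in% names(truth)),
            all(truth$sd >= 0))
  for (pe in names(distance_effect)) {
    if (length(distance_effect[[pe]]) != length(distances_um)) {
      stop("distance_effect entries must match the number of distances",
           call. = FALSE)
    }
  }
  structure(
    list(groups = groups,
         n_periosteal_animals = as.integer(n_periosteal_animals),
         n_perilacunar_animals = as.integer(n_perilacunar_animals),
         periosteal_points = as.integer(periosteal_points),
         lacunae = as.integer(lacunae),
         directions = as.integer(directions),
         distances_um = distances_um,
         truth = truth,
         distance_effect = distance_effect,
         spectrum_noise = spectrum_noise,
         indent_noise = indent_noise,
         image_ca_sd = image_ca_sd,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Default ground-truth table for the three study groups
#'
#' @param groups group labels; effect offsets are applied to the second
#'   (disease) and third (treated) labels when present.
#' @param zero_effects logical; if TRUE all groups share the reference
#'   means (the null configuration used for level checks).
#' @return data.frame with columns group, parameter, mean, sd.
#' @export
default_truth <- function(groups = c("CTRL", "CKD", "CKD_KP"),
                          zero_effects = FALSE) {
  base <- data.frame(
    parameter = c("mmr", "carbonate", "crystallinity", "Er", "H", "ca_mean"),
    mean = c(3.0, 0.170, 0.0550, 20.0, 0.70, 22.0),
    sd   = c(0.35, 0.020, 0.0040, 2.5, 0.10, 1.0)
  )
  out <- do.call(rbind, lapply(groups, function(g) {
    cbind(group = g, base)
  }))
  if (!zero_effects) {
    bump <- function(df, g, p, k_sd) {
      i <- df$group == g & df$parameter == p
      df$mean[i] <- df$mean[i] + k_sd * df$sd[i]
      df
    }
    if (length(groups) >= 2) {
      g2 <- groups[2]                       # disease group
      out <- bump(out, g2, "carbonate", -0.5)
      out <- bump(out, g2, "Er", -1.0)
      out <- bump(out, g2, "H", -0.75)
      out <- bump(out, g2, "ca_mean", -0.5)
    }
    if (length(groups) >= 3) {
      g3 <- groups[3]                       # treated group
      out <- bump(out, g3, "crystallinity", 1.0)
      out <- bump(out, g3, "carbonate", -1.0)
      out <- bump(out, g3, "mmr", 0.75)
      out <- bump(out, g3, "Er", -0.25)
      out <- bump(out, g3, "H", -0.25)
    }
  }
  rownames(out) <- NULL
  out
}

truth_lookup <- function(cfg, group, parameter) {
  i <- cfg$truth$group == group & cfg$truth$parameter == parameter
  if (!any(i)) stop("no ground truth for ", group, "/", parameter,
                    call. = FALSE)
  c(mean = cfg$truth$mean[i][1], sd = cfg$truth$sd[i][1])
}

dist_offset <- function(cfg, parameter, distance) {
  de <- cfg$distance_effect[[parameter]]
  if (is.null(de)) return(0)
  de[match(distance, cfg$distances_um)]
}

# draw per-measurement parameter truths for one group/region; returns a
# data.frame with one row per measurement (uses the current RNG stream)
draw_measurements <- function(cfg, group, region, distance = NA_real_, n) {
  params <- c("mmr", "carbonate", "crystallinity", "Er", "H")
  out <- data.frame(row.names = seq_len(n))
  for (p in params) {
    tr <- truth_lookup(cfg, group, p)
    off <- if (region == "perilacunar") dist_offset(cfg, p, distance) else 0
    out[[p]] <- stats::rnorm(n, tr["mean"] + off, tr["sd"])
  }
  # keep draws inside the physical domains of the generators
  out$mmr <- pmax(out$mmr, 0.2)
  out$carbonate <- pmax(out$carbonate, 0.01)
  out$crystallinity <- pmin(pmax(out$crystallinity, 1 / 55), 1 / 6)
  out$Er <- pmax(out$Er, 2)
  out$H <- pmax(out$H, 0.05)
  out$fwhm <- 1 / out$crystallinity
  out
}

#' Generate a complete synthetic study
#'
#' Produces the full three-group dataset with known ground truth. Two
#' fidelity levels are available:
#' \describe{
#'   \item{\code{"raw"}}{writes raw signals to \code{dir} - Raman spectra
#'     (\code{spectra/*.txt}), indent records (\code{indents/*.tsv}), one
#'     backscatter image and ROI mask per perilacunar animal
#'     (\code{images/*.png}) - plus \code{manifest.csv} and
#'     \code{truth.csv}, in the exact formats the package readers consume.}
#'   \item{\code{"parameters"}}{skips raw-signal synthesis and returns the
#'     per-measurement parameter draws directly (group truth plus
#'     between-measurement variation). This level exercises the study
#'     design and statistical layers at full size without the per-spectrum
#'     processing cost and is the one used for large Monte-Carlo designs.}
#' }
#' Generation consumes a single RNG stream seeded from \code{cfg$seed}, so
#' a study is bit-reproducible given its configuration.
#'
#' @param cfg a \code{study_config}.
#' @param dir output directory (required for \code{level = "raw"}).
#' @param level \code{"raw"} or \code{"parameters"}.
#' @return a list with \code{manifest} (data.frame; NULL at parameter
#'   level), \code{periosteal} and \code{perilacunar} per-measurement
#'   ground-truth/parameter tables, \code{images} (per-animal calcium field
#'   truth), and \code{config}.
#' @export
generate_study <- function(cfg = study_config(), dir = NULL,
                           level = c("parameters", "raw")) {
  stopifnot(inherits(cfg, "study_config"))
  level <- match.arg(level)
  if (level == "raw") {
    if (is.null(dir)) stop("raw-level generation needs an output directory",
                           call. = FALSE)
    for (d in file.path(dir, c("spectra", "indents", "images", "masks"))) {
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
    }
  }
  set.seed(cfg$seed)
  cal <- gray_calibration()
  manifest <- list()
  peri <- list()
  lac <- list()
  imgs <- list()

  for (g in cfg$groups) {
    # periosteal: n animals x 8 points, colocalized spectrum + indent
    for (a in seq_len(cfg$n_periosteal_animals)) {
      sample_id <- sprintf("%s_%02d", g, a)
      mm <- draw_measurements(cfg, g, "periosteal",
                              n = cfg$periosteal_points)
      mm <- cbind(sample = sample_id, group = g, region = "periosteal",
                  distance_um = NA_real_, point = seq_len(nrow(mm)), mm)
      peri[[length(peri) + 1L]] <- mm
      if (level == "raw") {
        manifest <- c(manifest,
                      write_measurement_files(mm, cfg, dir))
      }
    }
    # perilacunar: subset of animals, 6 lacunae x 4 directions x distances
    for (a in seq_len(cfg$n_perilacunar_animals)) {
      sample_id <- sprintf("%s_P%02d", g, a)
      for (d_um in cfg$distances_um) {
        n_pts <- cfg$lacunae * cfg$directions
        mm <- draw_measurements(cfg, g, "perilacunar", distance = d_um,
                                n = n_pts)
        mm <- cbind(sample = sample_id, group = g, region = "perilacunar",
                    distance_um = d_um, point = seq_len(nrow(mm)), mm)
        lac[[length(lac) + 1L]] <- mm
        if (level == "raw") {
          manifest <- c(manifest,
                        write_measurement_files(mm, cfg, dir))
        }
      }
      # one backscatter image per perilacunar animal
      tr <- truth_lookup(cfg, g, "ca_mean")
      ca_m <- stats::rnorm(1, tr["mean"], tr["sd"])
      imgs[[length(imgs) + 1L]] <- data.frame(
        sample = sample_id, group = g, ca_mean = ca_m,
        ca_sd = cfg$image_ca_sd)
      if (level == "raw") {
        img <- generate_bse_image(ca_m, cfg$image_ca_sd, cal,
                                  shape = c(200, 200))
        ipath <- file.path("images", paste0(sample_id, ".png"))
        mpath <- file.path("masks", paste0(sample_id, ".png"))
        write_bse_image(img$pixels, file.path(dir, ipath))
        write_bse_image(img$roi_mask * 255, file.path(dir, mpath))
        manifest[[length(manifest) + 1L]] <- data.frame(
          file = ipath, mask = mpath, kind = "image", sample = sample_id,
          group = g, region = "perilacunar", distance_um = NA_real_,
          calibration = "default")
      }
    }
  }

  peri <- do.call(rbind, peri)
  lac <- do.call(rbind, lac)
  imgs <- do.call(rbind, imgs)
  manifest <- if (length(manifest)) do.call(rbind, manifest) else NULL
  if (level == "raw") {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    truth_all <- rbind(peri, lac)
    utils::write.csv(truth_all, file.path(dir, "truth.csv"),
                     row.names = FALSE)
    writeLines(c("# ground-truth group means/SDs are configuration",
                 "# placeholders, not literature values"),
               file.path(dir, "truth_README.txt"))
  }
  list(manifest = manifest, periosteal = peri, perilacunar = lac,
       images = imgs, config = cfg)
}

# write the raw spectrum + indent files for a block of measurements and
# return their manifest rows
write_measurement_files <- function(mm, cfg, dir) {
  rows <- vector("list", 2L * nrow(mm))
  for (i in seq_len(nrow(mm))) {
    tag <- if (mm$region[i] == "perilacunar") {
      sprintf("%s_d%g_%02d", mm$sample[i], mm$distance_um[i], mm$point[i])
    } else {
      sprintf("%s_%02d", mm$sample[i], mm$point[i])
    }
    sp <- generate_spectrum(mm$mmr[i], mm$carbonate[i], mm$fwhm[i],
                            noise = cfg$spectrum_noise)
    spath <- file.path("spectra", paste0(tag, ".txt"))
    write_spectrum(sp, file.path(dir, spath))
    cv <- generate_indent_curve(mm$Er[i], mm$H[i],
                                noise = cfg$indent_noise)
    cpath <- file.path("indents", paste0(tag, ".tsv"))
    write_indent_curve(cv, file.path(dir, cpath))
    base <- data.frame(sample = mm$sample[i], group = mm$group[i],
                       region = mm$region[i],
                       distance_um = mm$distance_um[i],
                       calibration = "default")
    rows[[2L * i - 1L]] <- cbind(file = spath, mask = NA_character_,
                                 kind = "spectrum", base)
    rows[[2L * i]] <- cbind(file = cpath, mask = NA_character_,
                            kind = "indent", base)
  }
  rows
}
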