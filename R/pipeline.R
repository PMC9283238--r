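#' Per-specimen group comparisons for periosteal parameters
#'
#' Implements the periosteal statistical layer: measurement values are first
#' averaged to one value per specimen per parameter, each parameter is
#' routed through the Shapiro-Wilk normality gate, and group differences are
#' then tested by one-way ANOVA with Tukey HSD (parametric route) or
#' Kruskal-Wallis (nonparametric route).
#'
#' @param df data.frame with columns \code{sample}, \code{group}, and one
#'   column per parameter in \code{parameters}. Multiple rows per sample
#'   are averaged per specimen first; pass per-specimen data to skip
#'   averaging.
#' @param parameters character vector of parameter column names to test.
#' @param alpha omnibus/gate level.
#' @return a tidy data.frame with one row per parameter x pair:
#'   \code{parameter}, \code{route}, \code{omnibus_stat}, \code{omnibus_p},
#'   \code{pair}, \code{diff}, \code{p_adj}.
#' @export
periosteal_tests <- function(df, parameters, alpha = 0.05) {
  stopifnot(all(c("sample", "group", parameters) %in% names(df)))
  out <- list()
  for (p in parameters) {
    per_spec <- stats::aggregate(df[[p]],
                                 by = list(sample = df$sample,
                                           group = df$group),
                                 FUN = mean)
    groups <- split(per_spec$x, per_spec$group)
    gate <- normality_gate(groups, alpha = alpha)
    if (gate$route == "parametric") {
      om <- omnibus_and_posthoc(groups, alpha = alpha)
      rows <- data.frame(parameter = p, route = "parametric",
                         omnibus_stat = om$F, omnibus_p = om$p,
                         pair = om$pairs$pair, diff = om$pairs$diff,
                         p_adj = om$pairs$p_adj)
    } else {
      om <- kruskal_omnibus(groups)
      cmb <- utils::combn(names(groups), 2)
      rows <- data.frame(parameter = p, route = "nonparametric",
                         omnibus_stat = om$statistic, omnibus_p = om$p,
                         pair = paste(cmb[2, ], cmb[1, ], sep = "-"),
                         diff = NA_real_, p_adj = NA_real_)
    }
    out[[p]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pooled perilacunar distribution-shift table
#'
#' Implements the perilacunar statistical layer: for every parameter and
#' lacunar distance, the pooled per-group samples are compared pairwise
#' with the joint Kolmogorov-Smirnov / Anderson-Darling shift call at the
#' Bonferroni-adjusted level (0.05 divided by the number of group pairs).
#'
#' @param df data.frame with columns \code{group}, \code{distance_um}, and
#'   one column per parameter.
#' @param parameters parameter column names to test.
#' @param rule decision rule passed to \code{\link{shift_call}}.
#' @param alpha family-wise level before Bonferroni correction.
#' @return tidy data.frame: \code{parameter}, \code{distance_um},
#'   \code{group_a}, \code{group_b}, \code{ks_statistic}, \code{ks_p},
#'   \code{ad_statistic}, \code{ad_p}, \code{adjusted_alpha},
#'   \code{significant}, \code{direction} (group label or \code{"none"}),
#'   \code{tie}.
#' @export
perilacunar_shifts <- function(df, parameters, rule = "both", alpha = 0.05) {
  stopifnot(all(c("group", "distance_um", parameters) %in% names(df)))
  groups <- unique(df$group)
  cmb <- utils::combn(groups, 2)
  m <- ncol(cmb)
  out <- list()
  for (p in parameters) {
    for (d in sort(unique(df$distance_um))) {
      sub <- df[df$distance_um == d, ]
      for (j in seq_len(m)) {
        ga <- cmb[1, j]; gb <- cmb[2, j]
        sc <- shift_call(sub[[p]][sub$group == ga],
                         sub[[p]][sub$group == gb],
                         m_comparisons = m, labels = c(ga, gb),
                         alpha = alpha, rule = rule)
        out[[length(out) + 1L]] <- data.frame(
          parameter = p, distance_um = d, group_a = ga, group_b = gb,
          ks_statistic = sc$ks_statistic, ks_p = sc$ks_p,
          ad_statistic = sc$ad_statistic, ad_p = sc$ad_p,
          adjusted_alpha = sc$adjusted_alpha,
          significant = sc$significant,
          direction = switch(sc$direction,
                             right_shifted_A = ga,
                             right_shifted_B = gb,
                             "none"),
          tie = sc$tie)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full colocalized bone-quality pipeline on a study directory
#'
#' Reads \code{manifest.csv} from \code{input_dir}, processes every record
#' according to its kind (spectrum -> compositional parameters, indent ->
#' Oliver-Pharr mechanics, image -> BMDD metrics), and runs both
#' statistical layers. Per-record failures are logged and skipped; the run
#' log also echoes every configurable default in force so a run is fully
#' auditable. Outputs are deterministic for identical inputs.
#'
#' @param input_dir directory containing \code{manifest.csv} and the data
#'   files it references (as produced by \code{\link{generate_study}} at
#'   raw level).
#' @param out_dir output directory; created if missing.
#' @param bands Raman band definitions.
#' @param probe indenter geometry.
#' @param cal gray calibration.
#' @param baseline_order,window,polyorder Raman processing settings.
#' @param shift_rule decision rule for the perilacunar shift calls.
#' @return invisibly, a list with the result tables (\code{raman},
#'   \code{indent}, \code{bmdd}, \code{periosteal_tests},
#'   \code{perilacunar_shifts}) and the number of skipped records.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         bands = default_bands(),
                         probe = probe_geometry(),
                         cal = gray_calibration(),
                         baseline_order = 11L, window = 11L, polyorder = 4L,
                         shift_rule = "both") {
  manifest_path <- file.path(input_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("no manifest.csv in ", input_dir, call. = FALSE)
  }
  manifest <- utils::read.csv(manifest_path)
  need <- c("file", "kind", "sample", "group", "region", "distance_um")
  if (!all(need %in% names(manifest))) {
    stop("manifest.csv lacks required columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    "bonequal pipeline run",
    sprintf("records: %d", nrow(manifest)),
    "defaults in force:",
    sprintf("  bands: PO4 [%g,%g] CO3 [%g,%g] AmideI [%g,%g] cm-1",
            bands$nu1_phosphate$low, bands$nu1_phosphate$high,
            bands$nu1_carbonate$low, bands$nu1_carbonate$high,
            bands$amide_I$low, bands$amide_I$high),
    sprintf("  baseline order %d, SG window %d poly %d",
            baseline_order, window, polyorder),
    sprintf("  probe R=%g um beta=%g epsilon=%g; unload fit 95-40%%",
            probe$radius_um, probe$beta, probe$epsilon),
    sprintf("  gray cal: C %g -> %g wt%%, Al %g -> %g wt%% (tol %g)",
            cal$gray_carbon, cal$ca_carbon, cal$gray_aluminum,
            cal$ca_aluminum, cal$tolerance),
    sprintf("  shift rule '%s', Bonferroni over group pairs", shift_rule))

  skipped <- 0L
  raman_rows <- list(); indent_rows <- list(); bmdd_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    path <- file.path(input_dir, rec$file)
    res <- tryCatch({
      switch(as.character(rec$kind),
        spectrum = {
          acc <- read_spectrum(path)
          pars <- process_spectrum(acc, bands = bands,
                                   baseline_order = baseline_order,
                                   window = window, polyorder = polyorder)
          data.frame(sample = rec$sample, group = rec$group,
                     region = rec$region, distance_um = rec$distance_um,
                     mmr = pars$mmr,
                     carbonate = pars$carbonate_substitution,
                     crystallinity = pars$crystallinity,
                     fwhm = pars$fwhm_phosphate)
        },
        indent = {
          cv <- read_indent_curve(path)
          r <- analyze_indent(cv, probe)
          data.frame(sample = rec$sample, group = rec$group,
                     region = rec$region, distance_um = rec$distance_um,
                     S = r$S, hc = r$hc, A = r$A,
                     Er_GPa = r$Er, H_GPa = r$H)
        },
        image = {
          img <- read_bse_image(path,
                                mask_path = if (!is.na(rec$mask))
                                  file.path(input_dir, rec$mask) else NULL)
          b <- compute_bmdd(img, cal)
          data.frame(sample = rec$sample, group = rec$group,
                     ca_mean = b$ca_mean, ca_peak = b$ca_peak,
                     ca_width = b$ca_width)
        },
        stop("unknown record kind '", rec$kind, "'"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- skipped + 1L
      log_lines <- c(log_lines,
                     sprintf("SKIP %s (%s): %s", rec$file, rec$kind,
                             conditionMessage(res)))
      next
    }
    slot <- switch(as.character(rec$kind), spectrum = "raman",
                   indent = "indent", image = "bmdd")
    if (slot == "raman") raman_rows[[length(raman_rows) + 1L]] <- res
    if (slot == "indent") indent_rows[[length(indent_rows) + 1L]] <- res
    if (slot == "bmdd") bmdd_rows[[length(bmdd_rows) + 1L]] <- res
  }

  raman <- if (length(raman_rows)) do.call(rbind, raman_rows) else NULL
  indent <- if (length(indent_rows)) do.call(rbind, indent_rows) else NULL
  bmdd <- if (length(bmdd_rows)) do.call(rbind, bmdd_rows) else NULL
  write_out <- function(d, f) {
    if (!is.null(d)) utils::write.csv(d, file.path(out_dir, f),
                                      row.names = FALSE)
  }
  write_out(raman, "raman.csv")
  write_out(indent, "indent.csv")
  write_out(bmdd, "bmdd.csv")

  # periosteal layer: colocalized parameters, one averaged value/specimen
  peri_tests <- NULL
  peri <- merge_colocalized(raman, indent, region = "periosteal")
  if (!is.null(peri) && length(unique(peri$group)) >= 2) {
    pars <- intersect(c("mmr", "carbonate", "crystallinity",
                        "Er_GPa", "H_GPa"), names(peri))
    peri_tests <- tryCatch(periosteal_tests(peri, pars),
                           error = function(e) {
                             log_lines <<- c(log_lines,
                               paste("periosteal tests failed:",
                                     conditionMessage(e)))
                             NULL
                           })
    write_out(peri_tests, "periosteal_tests.csv")
  }

  # perilacunar layer: pooled distributions per distance
  lac_shifts <- NULL
  lac <- merge_colocalized(raman, indent, region = "perilacunar")
  if (!is.null(lac) && length(unique(lac$group)) >= 2 &&
      all(!is.na(lac$distance_um))) {
    pars <- intersect(c("mmr", "carbonate", "crystallinity",
                        "Er_GPa", "H_GPa"), names(lac))
    lac_shifts <- tryCatch(perilacunar_shifts(lac, pars, rule = shift_rule),
                           error = function(e) {
                             log_lines <<- c(log_lines,
                               paste("perilacunar shifts failed:",
                                     conditionMessage(e)))
                             NULL
                           })
    write_out(lac_shifts, "perilacunar_shifts.csv")
  }

  log_lines <- c(log_lines, sprintf("skipped records: %d", skipped))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(raman = raman, indent = indent, bmdd = bmdd,
                 periosteal_tests = peri_tests,
                 perilacunar_shifts = lac_shifts,
                 skipped = skipped))
}

# join the colocalized Raman and indent tables measurement-by-measurement
# within a region; rows are paired by order within sample x distance
merge_colocalized <- function(raman, indent, region) {
  take <- function(d) {
    if (is.null(d)) return(NULL)
    d <- d[d$region == region, , drop = FALSE]
    if (!nrow(d)) NULL else d
  }
  r <- take(raman); i <- take(indent)
  if (is.null(r) && is.null(i)) return(NULL)
  if (is.null(i)) return(r)
  if (is.null(r)) return(i)
  key <- function(d) paste(d$sample, d$distance_um)
  r$._k <- stats::ave(seq_len(nrow(r)), key(r), FUN = seq_along)
  i$._k <- stats::ave(seq_len(nrow(i)), key(i), FUN = seq_along)
  m <- merge(r, i[, c("sample", "distance_um", "._k", "S", "hc", "A",
                      "Er_GPa", "H_GPa")],
             by = c("sample", "distance_um", "._k"))
  m$._k <- NULL
  m
}
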