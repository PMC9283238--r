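#' Normality gate for group comparisons
#'
#' Routes a parameter to the parametric (ANOVA + Tukey) or nonparametric
#' (Kruskal-Wallis) analysis: parametric only when a Shapiro-Wilk test fails
#' to reject normality (p >= alpha) in every group. Constant groups, on
#' which the Shapiro-Wilk statistic is undefined, are routed nonparametric
#' with a degeneracy flag.
#'
#' @param groups named list of numeric vectors (one per animal group), each
#'   of length >= 3.
#' @param alpha per-group Shapiro-Wilk level (default 0.05).
#' @return list with \code{route} (\code{"parametric"} or
#'   \code{"nonparametric"}), the per-group \code{shapiro_p} values, and
#'   \code{degenerate}.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  check_group_list(groups, min_n = 3L)
  degenerate <- vapply(groups, function(g) stats::var(g) == 0, logical(1))
  if (any(degenerate)) {
    return(list(route = "nonparametric",
                shapiro_p = stats::setNames(rep(NA_real_, length(groups)),
                                            names(groups)),
                degenerate = TRUE))
  }
  p <- vapply(groups, function(g) stats::shapiro.test(g)$p.value, numeric(1))
  list(route = if (all(p >= alpha)) "parametric" else "nonparametric",
       shapiro_p = p, degenerate = FALSE)
}

check_group_list <- function(groups, min_n = 3L) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups))) {
    stop("groups must be a named list of at least two numeric vectors",
         call. = FALSE)
  }
  n <- vapply(groups, length, integer(1))
  if (any(n < min_n)) {
    stop(sprintf("every group needs at least %d observations", min_n),
         call. = FALSE)
  }
  invisible(n)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Omnibus one-way ANOVA across the groups; when the omnibus test rejects
#' at \code{alpha}, pairwise differences are assessed with Tukey's honestly
#' significant difference test (studentized-range distribution with the
#' pooled error variance). When the omnibus test does not reject, the pairs
#' are reported untested (NA p-values).
#'
#' @param groups named list of numeric vectors.
#' @param alpha omnibus level gating the post hoc tests (default 0.05).
#' @return list with \code{F}, \code{p}, \code{df} (numerator/denominator),
#'   and \code{pairs}: data.frame of \code{pair}, \code{diff},
#'   \code{p_adj}.
#' @export
omnibus_and_posthoc <- function(groups, alpha = 0.05) {
  check_group_list(groups, min_n = 2L)
  if (all(vapply(groups, function(g) stats::var(g) == 0, logical(1)))) {
    stop("zero within-group variance in every group", call. = FALSE)
  }
  d <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = d)
  tab <- summary(fit)[[1]]
  Fv <- tab["group", "F value"]
  pv <- tab["group", "Pr(>F)"]

  cmb <- utils::combn(names(groups), 2)
  pair_names <- paste(cmb[2, ], cmb[1, ], sep = "-")
  if (pv < alpha) {
    tk <- stats::TukeyHSD(fit)$group
    pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        p_adj = tk[, "p adj"], row.names = NULL)
  } else {
    pairs <- data.frame(pair = pair_names, diff = NA_real_, p_adj = NA_real_)
  }
  list(F = Fv, p = pv, df = unname(tab$Df), pairs = pairs)
}

#' Kruskal-Wallis omnibus test on a group list
#'
#' @param groups named list of numeric vectors.
#' @return list with \code{statistic} (chi-squared), \code{p}, \code{df}.
#' @export
kruskal_omnibus <- function(groups) {
  check_group_list(groups, min_n = 2L)
  k <- stats::kruskal.test(groups)
  list(statistic = unname(k$statistic), p = k$p.value,
       df = unname(k$parameter))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic Kolmogorov distribution (the regime of the pooled
#' perilacunar samples, n = 144 per group).
#'
#' @param x,y numeric samples, each of length >= 8.
#' @return list with \code{statistic} (D) and \code{p}.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 8L || length(y) < 8L) {
    stop("each sample needs at least 8 observations", call. = FALSE)
  }
  k <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(k$statistic), p = k$p.value)
}

#' Two-sample Anderson-Darling test
#'
#' Rank-form two-sample Anderson-Darling statistic with midrank tie
#' adjustment, standardised and converted to a p-value with the standard
#' k-sample interpolation of the statistic's null critical surface
#' (Scholz-Stephens). The Anderson-Darling statistic weights the ECDF
#' discrepancy by the inverse variance of the pooled ECDF and is therefore
#' more sensitive to tail differences than Kolmogorov-Smirnov. An exact
#' permutation p-value is available as a cross-check.
#'
#' @param x,y numeric samples, each of length >= 8.
#' @param method \code{"asymptotic"} (default) or \code{"permutation"}.
#' @param n_perm number of permutations for \code{method = "permutation"}.
#' @param seed RNG seed for the permutation method.
#' @return list with \code{statistic} (the tie-adjusted A2), \code{T}
#'   (standardised statistic) and \code{p}.
#' @export
ad_two_sample <- function(x, y, method = c("asymptotic", "permutation"),
                          n_perm = 2000L, seed = 1L) {
  method <- match.arg(method)
  if (length(x) < 8L || length(y) < 8L) {
    stop("each sample needs at least 8 observations", call. = FALSE)
  }
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    stop("all observations are tied; the test is degenerate", call. = FALSE)
  }
  a2 <- ad_statistic(x, y)
  sig <- ad_null_sd(c(length(x), length(y)))
  Tobs <- (a2 - 1) / sig       # k - 1 = 1 for two samples
  p <- if (method == "asymptotic") {
    ad_pvalue(Tobs)
  } else {
    n1 <- length(x)
    rng <- local({
      set.seed(seed)
      replicate(n_perm, sample.int(length(pooled), n1))
    })
    perm <- apply(rng, 2, function(idx) {
      ad_statistic(pooled[idx], pooled[-idx])
    })
    (1 + sum(perm >= a2)) / (n_perm + 1)
  }
  list(statistic = a2, T = Tobs, p = p)
}

# tie-adjusted (midrank) two-sample Anderson-Darling statistic
ad_statistic <- function(x, y) {
  N <- length(x) + length(y)
  z <- sort(unique(c(x, y)))
  L <- length(z)
  l <- tabulate(match(c(x, y), z), nbins = L)
  Ba <- cumsum(l) - l / 2
  denom <- Ba * (N - Ba) - N * l / 4
  ok <- denom > 0
  w <- (l / N)[ok] / denom[ok]
  inner <- 0
  for (s in list(x, y)) {
    f <- tabulate(match(s, z), nbins = L)
    Ma <- cumsum(f) - f / 2
    inner <- inner + sum(w * (N * Ma[ok] - length(s) * Ba[ok])^2) / length(s)
  }
  (N - 1) / N * inner
}

# exact null standard deviation of the k-sample AD statistic
ad_null_sd <- function(n) {
  k <- length(n)
  N <- sum(n)
  H <- sum(1 / n)
  h <- sum(1 / seq_len(N - 1))
  i <- seq_len(N - 2)
  # g = sum_{i<j} 1 / ((N - i) j) over 1 <= i < j <= N - 1
  tail_inv <- rev(cumsum(1 / rev(seq_len(N - 1))))  # sum_{j=i}^{N-1} 1/j
  g <- sum((1 / (N - i)) * (tail_inv[i + 1]))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k +
    (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k +
    (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  v <- (a * N^3 + b * N^2 + cc * N + d) /
    ((N - 1) * (N - 2) * (N - 3))
  sqrt(v)
}

# p-value for the standardised two-sample AD statistic: monotone
# interpolation of logit(alpha) against the critical values t_1(alpha)
# reconstructed from the published critical-surface coefficients
ad_pvalue <- function(Tobs) {
  alpha <- c(0.25, 0.10, 0.05, 0.025, 0.01)
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396)
  tm <- b0 + b1 + b2                      # m = k - 1 = 1
  lg <- log(alpha / (1 - alpha))
  f <- stats::splinefun(tm, lg, method = "monoH.FC")
  if (Tobs < tm[1]) {
    # below the table: extend linearly along the first segment, capped
    slope <- (lg[2] - lg[1]) / (tm[2] - tm[1])
    p <- stats::plogis(lg[1] + slope * (Tobs - tm[1]))
    return(min(p, 1))
  }
  if (Tobs > tm[length(tm)]) {
    slope <- (lg[5] - lg[4]) / (tm[5] - tm[4])
    return(stats::plogis(lg[5] + slope * (Tobs - tm[5])))
  }
  stats::plogis(f(Tobs))
}

#' Distribution-shift call for one group pair
#'
#' Runs the two-sample Kolmogorov-Smirnov and Anderson-Darling tests with a
#' Bonferroni-adjusted level \code{alpha / m_comparisons} (0.05 / 3 = 0.0167
#' for the three group pairs) and combines them. The default decision rule
#' requires BOTH tests to reject (a conservative conjunction); \code{rule =
#' "either"} reports either-test significance instead. A significant call is
#' directed: the sample with the greater median is the right-shifted one.
#'
#' @param x,y numeric samples.
#' @param m_comparisons Bonferroni divisor (number of pairwise comparisons).
#' @param labels length-2 character vector naming x and y.
#' @param alpha family-wise level before correction.
#' @param rule \code{"both"} (default) or \code{"either"}.
#' @return an object of class \code{shift_result}: list with the pair
#'   labels, both statistics and p-values, \code{adjusted_alpha},
#'   \code{significant}, \code{direction} (\code{"right_shifted_A"},
#'   \code{"right_shifted_B"} or \code{"none"}) and \code{tie}.
#' @export
shift_call <- function(x, y, m_comparisons = 3, labels = c("A", "B"),
                       alpha = 0.05, rule = c("both", "either")) {
  rule <- match.arg(rule)
  adjusted_alpha <- alpha / m_comparisons
  ks <- ks_two_sample(x, y)
  ad <- ad_two_sample(x, y)
  significant <- switch(rule,
    both = ks$p < adjusted_alpha && ad$p < adjusted_alpha,
    either = ks$p < adjusted_alpha || ad$p < adjusted_alpha)
  tie <- FALSE
  direction <- "none"
  if (significant) {
    mx <- stats::median(x); my <- stats::median(y)
    if (mx == my) {
      tie <- TRUE
    } else {
      direction <- if (mx > my) "right_shifted_A" else "right_shifted_B"
    }
  }
  structure(
    list(pair = labels,
         ks_statistic = ks$statistic, ks_p = ks$p,
         ad_statistic = ad$statistic, ad_p = ad$p,
         adjusted_alpha = adjusted_alpha,
         significant = significant, direction = direction, tie = tie),
    class = "shift_result"
  )
}

#' @export
print.shift_result <- function(x, ...) {
  dir <- switch(x$direction,
                right_shifted_A = paste(x$pair[1], "right-shifted"),
                right_shifted_B = paste(x$pair[2], "right-shifted"),
                "no shift")
  cat(sprintf(
    "<shift_result> %s vs %s: KS D=%.3f p=%.4g | AD A2=%.3f p=%.4g | %s (alpha=%.4f)\n",
    x$pair[1], x$pair[2], x$ks_statistic, x$ks_p, x$ad_statistic, x$ad_p,
    if (x$significant) dir else "not significant", x$adjusted_alpha))
  invisible(x)
}
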