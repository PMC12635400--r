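#' Extract a time-locked voltage window around an event
#'
#' Per-channel slice covering `pre` seconds before to `post` seconds after
#' the event time, with exactly `(pre + post) * fs` samples.
#'
#' @param session A `recording_session`.
#' @param event_time Event time, seconds.
#' @param pre,post Window extent before / after the event, seconds
#'   (`pre + post > 0`).
#' @return Channels x samples matrix with attributes `fs` and `t0` (time of
#'   the first sample).
#' @export
extract_event_window <- function(session, event_time, pre, post) {
  stopifnot(inherits(session, "recording_session"))
  if (pre < 0 || post < 0 || pre + post <= 0) {
    stop("window must have positive length")
  }
  fs <- session$fs
  n <- ncol(session$voltages)
  n_out <- round((pre + post) * fs)
  start <- round((event_time - pre) * fs) + 1L
  if (start < 1 || start + n_out - 1L > n) {
    stop("event window exceeds the session bounds")
  }
  out <- session$voltages[, start:(start + n_out - 1L), drop = FALSE]
  attr(out, "fs") <- fs
  attr(out, "t0") <- event_time - pre
  out
}

#' Trapezoidal area under the positive part of a trace
#'
#' The distension response statistic: rectifies the trace at zero
#' (`max(x, 0)`) and integrates by the trapezoidal rule, giving
#' microvolt-seconds.
#'
#' @param trace Numeric voltage series, microvolts.
#' @param fs Sampling rate, Hz.
#' @return Scalar area, uV*s (0 for an everywhere-negative trace).
#' @export
positive_auc <- function(trace, fs) {
  if (!all(is.finite(trace))) stop("trace must be finite")
  pracma::trapz(seq_along(trace) / fs, pmax(trace, 0))
}

#' Min-max normalize AUC values within one experiment
#'
#' `(x - min) / (max - min)`: the weakest distension maps to 0 and the
#' strongest to 1, making responses comparable across animals regardless
#' of absolute signal scale. Invariant under positive affine transforms of
#' the input and idempotent.
#'
#' @param aucs Numeric vector (length >= 2) of raw AUC values from one
#'   experiment.
#' @return Vector of nAUC values in [0, 1].
#' @export
normalize_auc <- function(aucs) {
  if (length(aucs) < 2) stop("need at least 2 AUC values")
  rng <- max(aucs) - min(aucs)
  if (rng == 0) stop("degenerate experiment: zero AUC range")
  (aucs - min(aucs)) / rng
}

#' Assumption-gated two-group comparison
#'
#' The statistical chain applied to nAUC groups: Shapiro-Wilk normality on
#' each group and Levene's test (median-centered) for homogeneity of
#' variance; if all pass at `alpha`, an unpaired two-sided pooled-variance
#' t-test (df = n1 + n2 - 2) with Cohen's d (mean difference / pooled SD)
#' and a 95% CI of the mean difference; otherwise a two-sided Mann-Whitney
#' U test (exact when n1*n2 <= 400 and there are no ties, normal
#' approximation with tie correction otherwise). U is reported for the
#' first group, so U1 + U2 = n1*n2.
#'
#' @param a,b Numeric vectors, >= 3 values each.
#' @param alpha Gate level for the assumption tests (default 0.05).
#' @return A list of class `stat_result`: `test_name`, `statistic`,
#'   `p_value`, `df`, `cohens_d`, `ci_low`, `ci_high`, `normality_p`
#'   (length 2), `variance_homogeneity_p`.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs at least 3 values")
  }
  sw_a <- stats::shapiro.test(a)$p.value
  sw_b <- stats::shapiro.test(b)$p.value
  grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
  lev <- car::leveneTest(c(a, b), grp)
  lev_p <- lev[1, "Pr(>F)"]
  n1 <- length(a); n2 <- length(b)
  d <- cohens_d(a, b)
  if (sw_a > alpha && sw_b > alpha && lev_p > alpha) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(test_name = "t", statistic = unname(tt$statistic),
                p_value = tt$p.value, df = unname(tt$parameter),
                cohens_d = d, ci_low = tt$conf.int[1],
                ci_high = tt$conf.int[2],
                normality_p = c(sw_a, sw_b),
                variance_homogeneity_p = lev_p)
  } else {
    wt <- stats::wilcox.test(a, b, exact = (n1 * n2 <= 400) &&
                               !any(duplicated(c(a, b))),
                             correct = TRUE)
    res <- list(test_name = "mann-whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value, df = NA_real_,
                cohens_d = d, ci_low = NA_real_, ci_high = NA_real_,
                normality_p = c(sw_a, sw_b),
                variance_homogeneity_p = lev_p)
  }
  structure(res, class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g, d = %.3g\n",
              x$test_name, x$statistic, x$p_value, x$cohens_d))
  invisible(x)
}

#' Cohen's d with pooled standard deviation
#' @noRd
cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
               (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Recover the pooled t statistic from Cohen's d
#'
#' For two equal-sized groups compared with a pooled-variance t-test,
#' `t = d * sqrt(n/2)` where `n` is the per-group size. With the reported
#' effect size d = 1.77 at n = 8 per group this returns t = 3.54.
#'
#' @param d Cohen's d.
#' @param n_per_group Per-group sample size (>= 2).
#' @return The t statistic.
#' @export
t_from_cohens_d <- function(d, n_per_group) {
  if (n_per_group < 2) stop("`n_per_group` must be at least 2")
  d * sqrt(n_per_group / 2)
}

#' Tukey boxplot summary statistics
#'
#' Quartiles by linear interpolation (quantile type 7) and Tukey whisker
#' bounds `Q1 - 1.5*IQR` / `Q3 + 1.5*IQR` reported as bounds (not clipped
#' to the data), plus the 5/10/50/90/95th percentiles.
#'
#' @param values Numeric vector (>= 1 value).
#' @return List with `minima`, `maxima`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `percentiles`.
#' @export
boxplot_summary <- function(values) {
  if (length(values) < 1) stop("need at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  list(
    minima = min(values), maxima = max(values),
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = q[1] - 1.5 * iqr,
    whisker_high = q[3] + 1.5 * iqr,
    percentiles = stats::quantile(values, c(0.05, 0.10, 0.50, 0.90, 0.95),
                                  type = 7)
  )
}

#' Smoothed Hilbert amplitude envelope of a contraction trace
#'
#' Magnitude of the analytic signal (Hilbert transform) of a 300-2000 Hz
#' band-passed trace, smoothed with a 1 s moving-average kernel
#' (reflection padding at the edges), tracking how high-frequency activity
#' swells and fades through a contraction.
#'
#' @param trace Band-passed voltage series.
#' @param fs Sampling rate, Hz.
#' @param smooth_s Moving-average window, seconds (default 1).
#' @return Object of class `envelope_trace`: data.frame `time_s`,
#'   `amplitude` (uV, >= 0) with attribute `smooth_s`.
#' @export
contraction_envelope <- function(trace, fs, smooth_s = 1) {
  env <- Mod(analytic_signal(trace))
  n <- length(env)
  k <- min(max(1L, round(smooth_s * fs)), n)
  pad <- min(k, n - 1)
  ext <- c(env[pad:1], env, env[n:(n - pad + 1)])
  kern <- rep(1 / k, k)
  sm <- stats::filter(ext, kern, sides = 2)
  sm <- as.numeric(sm)[(pad + 1):(pad + n)]
  # fall back to the raw envelope where the kernel ran off the extension
  sm[is.na(sm)] <- env[is.na(sm)]
  structure(data.frame(time_s = (seq_len(n) - 1) / fs, amplitude = sm),
            smooth_s = smooth_s,
            class = c("envelope_trace", "data.frame"))
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Zeroes negative frequencies and doubles positive ones, so the magnitude
#' of the result is the instantaneous amplitude envelope.
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Desensitization across repeated drug additions
#'
#' For repeated additions of one agonist, compares the chosen response
#' metric between addition indices with two-sided Mann-Whitney U tests
#' across animals, and summarizes the monotone trend as the Spearman
#' correlation between addition index and the across-animal mean response.
#'
#' @param metric_matrix Numeric matrix, animals x additions: one response
#'   metric value per animal per addition (column order = addition order).
#' @param comparisons List of length-2 integer vectors of addition indices
#'   to compare (default: 1st vs each later addition).
#' @return List with `comparisons` (data.frame: i, j, U, p) and
#'   `spearman_rho` (trend of the mean response over additions).
#' @export
desensitization_profile <- function(metric_matrix, comparisons = NULL) {
  m <- as.matrix(metric_matrix)
  if (ncol(m) < 2) stop("need at least 2 additions")
  if (any(!is.finite(m))) stop("metric matrix must be finite (equal animal counts per addition)")
  if (is.null(comparisons)) {
    comparisons <- lapply(2:ncol(m), function(j) c(1L, j))
  }
  rows <- lapply(comparisons, function(cp) {
    stopifnot(length(cp) == 2)
    a <- m[, cp[1]]; b <- m[, cp[2]]
    wt <- stats::wilcox.test(a, b, exact = !any(duplicated(c(a, b))))
    data.frame(i = cp[1], j = cp[2], U = unname(wt$statistic),
               p = wt$p.value)
  })
  means <- colMeans(m)
  rho <- suppressWarnings(
    stats::cor(seq_len(ncol(m)), means, method = "spearman"))
  list(comparisons = do.call(rbind, rows), spearman_rho = rho)
}
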