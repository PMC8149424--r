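#' Enamel-content metric of an en-face image
#'
#' Runs the structural-connectivity pipeline (binarize, components, opening,
#' closing) on an en-face image and sums the source intensities over the
#' closed connected mask — the total pixel intensities in continuity. The
#' sum is scaled to µm by `calibration_scale`.
#'
#' @param enface matrix from [extract_enface()] (or any grayscale image).
#' @param params a [connectivity_params()].
#' @param calibration_scale µm per summed-intensity unit. The mapping from
#'   intensity sums to µm is instrument- and normalization-specific; when
#'   left `NULL` a scale of 1 is used and a warning notes that the metric is
#'   in raw intensity units.
#' @return One-row tibble: connected_intensity_sum, connected_px, metric_um.
#'   An empty foreground yields a zero metric with a warning.
#' @export
enamel_metric <- function(enface, params = connectivity_params(),
                          calibration_scale = NULL) {
  m <- as_pixel_matrix(enface)
  if (is.null(calibration_scale)) {
    warning("no calibration_scale supplied: metric_um is in raw intensity units",
            call. = FALSE)
    calibration_scale <- 1
  }
  bin <- suppressWarnings(binarize_otsu(m))
  if (!any(bin$mask) && max(m) > 0 && diff(range(m)) == 0) {
    # a uniform positive field has no threshold to find: it is all signal
    bin$mask <- m > 0
  }
  if (!any(bin$mask)) {
    warning("empty foreground: enamel metric is 0", call. = FALSE)
    return(tibble::tibble(connected_intensity_sum = 0, connected_px = 0L,
                          metric_um = 0))
  }
  comp <- trace_components(bin$mask, params, img = m)
  opened <- open_mask(comp$labels > 0, radius = params$se_radius,
                      shape = params$se_shape)
  acct <- close_and_account(m, opened, params)
  tibble::tibble(connected_intensity_sum = acct$total_enamel_intensity,
                 connected_px = as.integer(acct$total_enamel_px),
                 metric_um = acct$total_enamel_intensity * calibration_scale)
}

# coerce a subjects x stages input (matrix or long/wide tibble) to a matrix
as_stage_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(colnames(x)) && ncol(x) == 4L)
      colnames(x) <- treatment_stage_labels()
    return(x)
  }
  df <- as.data.frame(x)
  if (all(c("subject", "metric_um") %in% names(df))) {
    stage_col <- if ("stage_label" %in% names(df)) "stage_label" else "stage"
    wide <- tidyr::pivot_wider(df[, c("subject", stage_col, "metric_um")],
                               names_from = dplyr::all_of(stage_col),
                               values_from = "metric_um")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$subject
    return(m)
  }
  as.matrix(df)
}

#' Pairwise differences of stage means
#'
#' @param means numeric vector of per-stage means.
#' @param labels stage labels (default the four treatment-group labels when
#'   four means are given).
#' @return Tibble of all ordered pairs i < j with
#'   `mean_difference = mean_i - mean_j` (so a positive value is a loss from
#'   the earlier to the later stage).
#' @export
mean_differences <- function(means, labels = NULL) {
  k <- length(means)
  if (is.null(labels))
    labels <- if (k == 4L) treatment_stage_labels() else
      names(means) %||% paste("stage", seq_len(k))
  pairs <- utils::combn(k, 2)
  tibble::tibble(stage_a = labels[pairs[1, ]], stage_b = labels[pairs[2, ]],
                 mean_a = means[pairs[1, ]], mean_b = means[pairs[2, ]],
                 mean_difference = means[pairs[1, ]] - means[pairs[2, ]])
}

#' Per-stage summary and pairwise mean differences
#'
#' @param x subjects x stages matrix, or a long tibble with columns subject,
#'   stage (or stage_label), metric_um.
#' @return An object of class `group_summary`: `summary` tibble (stage,
#'   mean, sd, min, max, n; SD is the sample SD, n-1) and `differences` from
#'   [mean_differences()]. Requires at least 2 subjects (SD undefined
#'   otherwise).
#' @export
group_summary <- function(x) {
  m <- as_stage_matrix(x)
  if (nrow(m) < 2L)
    stop("SD undefined: need at least 2 subjects", call. = FALSE)
  labs <- colnames(m) %||% paste("stage", seq_len(ncol(m)))
  summ <- tibble::tibble(
    stage = labs,
    mean = apply(m, 2, mean), sd = apply(m, 2, stats::sd),
    min = apply(m, 2, min), max = apply(m, 2, max),
    n = nrow(m))
  structure(list(summary = summ,
                 differences = mean_differences(summ$mean, labs),
                 matrix = m),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' @method tidy group_summary
#' @export
tidy.group_summary <- function(x, ...) x$summary

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Lilliefors-style: the reference normal uses the sample mean and SD
#' (plug-in), and `D = sup |ECDF - CDF|` is evaluated on both sides of every
#' jump point. The p-value uses the asymptotic Kolmogorov distribution,
#' which is conservative when parameters are estimated; treat it as a
#' screening value.
#'
#' @param values numeric vector, length >= 3, non-degenerate.
#' @return One-row tibble: statistic (D), p_value, n.
#' @export
ks_normality <- function(values) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 3L) stop("need at least 3 values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate sample: zero variance", call. = FALSE)
  cdf <- stats::pnorm(x, mean = mean(x), sd = s)
  d_plus <- max(seq_len(n) / n - cdf)
  d_minus <- max(cdf - (seq_len(n) - 1) / n)
  D <- max(d_plus, d_minus)
  # asymptotic Kolmogorov tail: Q(t) = 2 sum_{j>=1} (-1)^{j-1} exp(-2 j^2 t^2)
  t <- sqrt(n) * D
  j <- seq_len(100)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  tibble::tibble(statistic = D, p_value = min(max(p, 0), 1), n = n)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA across stages: the subject effect is removed from
#' the error term, `F = MS_treatment / MS_error` with
#' `df_treatment = stages - 1` and `df_error = (stages - 1)(subjects - 1)`.
#' No sphericity correction is applied.
#'
#' @param x subjects x stages matrix (complete; no missing cells) or a long
#'   tibble as in [group_summary()].
#' @return An object of class `rm_anova` with fields statistic (F), df_treatment,
#'   df_error, p_value, and the sums-of-squares table. A degenerate fit
#'   (zero error mean square) reports `p_value = 0` bounded below machine
#'   precision, or `p_value = 1` when the treatment effect is also zero.
#' @export
rm_anova <- function(x) {
  m <- as_stage_matrix(x)
  if (anyNA(m)) stop("complete matrix required: missing cells", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("need >= 2 subjects and >= 2 stages", call. = FALSE)
  grand <- mean(m)
  ss_treat <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_treat - ss_subj
  df_t <- k - 1L
  df_e <- (k - 1L) * (n - 1L)
  ms_t <- ss_treat / df_t
  ms_e <- ss_err / df_e
  if (ms_e <= .Machine$double.eps * max(1, ms_t)) {
    Fstat <- if (ms_t <= .Machine$double.eps) 0 else Inf
    p <- if (Fstat == 0) 1 else .Machine$double.xmin
  } else {
    Fstat <- ms_t / ms_e
    p <- stats::pf(Fstat, df_t, df_e, lower.tail = FALSE)
  }
  structure(list(statistic = Fstat, df_treatment = df_t, df_error = df_e,
                 p_value = p,
                 ss = tibble::tibble(term = c("treatment", "subject", "error"),
                                     ss = c(ss_treat, ss_subj, ss_err),
                                     df = c(df_t, n - 1L, df_e)),
                 n_subjects = n, n_stages = k),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_treatment, x$df_error, x$statistic, x$p_value))
  invisible(x)
}

#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) x$ss

#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df_treatment = x$df_treatment,
                 df_error = x$df_error, p_value = x$p_value,
                 n_subjects = x$n_subjects, n_stages = x$n_stages)
}

#' Bonferroni-corrected pairwise paired t-tests
#'
#' Paired t-test for every stage pair; adjusted p-values follow the
#' Bonferroni rule `min(1, m * p)` with `m` the number of pairs (6 for four
#' stages).
#'
#' @param x subjects x stages matrix or long tibble as in [group_summary()].
#' @param alpha significance level for the Sig/NS flag (default 0.05).
#' @return Tibble: stage_a, stage_b, mean_difference, t, df, p_raw, p_adj,
#'   significant.
#' @export
bonferroni_pairs <- function(x, alpha = 0.05) {
  m <- as_stage_matrix(x)
  if (anyNA(m)) stop("complete matrix required: missing cells", call. = FALSE)
  if (nrow(m) < 2L) stop("need >= 2 subjects", call. = FALSE)
  labs <- colnames(m) %||% paste("stage", seq_len(ncol(m)))
  pairs <- utils::combn(ncol(m), 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- m[, a] - m[, b]
    if (stats::sd(d) == 0) {
      tt <- list(statistic = c(t = if (mean(d) == 0) 0 else Inf),
                 parameter = c(df = nrow(m) - 1L),
                 p.value = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(m[, a], m[, b], paired = TRUE)
    }
    tibble::tibble(stage_a = labs[a], stage_b = labs[b],
                   mean_difference = mean(d),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value,
                   p_adj = min(1, n_pairs * tt$p.value))
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p_adj < alpha
  out
}

#' Full group statistics report
#'
#' Combines the per-stage summary, per-stage KS normality checks, the
#' repeated-measures ANOVA, and the Bonferroni post-hoc pairwise
#' comparisons.
#'
#' @param x subjects x stages matrix or long tibble as in [group_summary()].
#' @param alpha significance level (default 0.05).
#' @return An object of class `group_stats` with fields `summary`
#'   (group_summary), `normality` (tibble per stage), `anova` (rm_anova),
#'   `pairs` (tibble).
#' @export
run_group_stats <- function(x, alpha = 0.05) {
  m <- as_stage_matrix(x)
  gs <- group_summary(m)
  labs <- gs$summary$stage
  norm <- dplyr::bind_rows(lapply(seq_len(ncol(m)), function(j) {
    ks <- ks_normality(m[, j])
    tibble::tibble(stage = labs[j], statistic = ks$statistic,
                   p_value = ks$p_value)
  }))
  structure(list(summary = gs, normality = norm, anova = rm_anova(m),
                 pairs = bonferroni_pairs(m, alpha), alpha = alpha,
                 matrix = m),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  print(x$summary$summary)
  print(x$anova)
  print(x$pairs[, c("stage_a", "stage_b", "p_adj", "significant")])
  invisible(x)
}

#' @method tidy group_stats
#' @export
tidy.group_stats <- function(x, ...) x$pairs

#' @method glance group_stats
#' @export
glance.group_stats <- function(x, ...) glance(x$anova)

#' Serialize a group-stats report to a list (for JSON output)
#' @param x a `group_stats` object.
#' @return Nested list mirroring the summary/normality/ANOVA/post-hoc tables.
#' @export
group_stats_report <- function(x) {
  stopifnot(inherits(x, "group_stats"))
  list(summary = as.data.frame(x$summary$summary),
       mean_differences = as.data.frame(x$summary$differences),
       normality = as.data.frame(x$normality),
       rm_anova = list(F = x$anova$statistic,
                       df_treatment = x$anova$df_treatment,
                       df_error = x$anova$df_error,
                       p_value = x$anova$p_value),
       bonferroni = as.data.frame(x$pairs),
       alpha = x$alpha)
}
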