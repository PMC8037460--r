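#' Percent endothelial cell loss
#'
#' `100 * loss / pre`, the post-operative cell loss as a percentage of the
#' pre-operative endothelial cell density.  The value is returned at full
#' precision; clinical reports round it to one decimal (e.g. a mean loss of
#' 122.2 on a pre-operative 2307 cells/mm^2 prints as 5.3%).
#'
#' @param pre_mean pre-operative mean ECD, cells/mm^2 (> 0).
#' @param loss_mean mean cell loss, cells/mm^2.
#' @return percent loss (numeric, full precision).
#' @examples
#' percent_cell_loss(2307, 122.2)  # 5.297...
#' @export
percent_cell_loss <- function(pre_mean, loss_mean) {
  if (!is.finite(pre_mean) || pre_mean <= 0)
    stop("pre_mean must be a positive cell density")
  100 * loss_mean / pre_mean
}

#' Endothelial morphometry summary
#'
#' From per-cell areas (and optionally per-cell vertex counts), computes the
#' standard specular-microscopy indices: mean cell area AVE (um^2), the
#' polymegathism index CV = 100 * SD(area) / AVE (%), the pleomorphism
#' index 6A (percent hexagonal cells), and the implied cell density
#' ECD = 1e6 / AVE (cells/mm^2).
#'
#' @param cell_areas per-cell areas, um^2.
#' @param shapes per-cell vertex counts (6 = hexagonal); optional.
#' @return object of class `morphometry_summary`.
#' @examples
#' morphometry_summary(c(400, 500), c(6, 5))
#' @export
morphometry_summary <- function(cell_areas, shapes = NULL) {
  if (length(cell_areas) == 0) stop("cell_areas must be non-empty")
  if (!is.null(shapes) && length(shapes) != length(cell_areas))
    stop("cell_areas and shapes must have equal length")
  if (any(cell_areas <= 0)) stop("cell areas must be positive")
  ave <- mean(cell_areas)
  s <- if (length(cell_areas) > 1) stats::sd(cell_areas) else 0
  structure(list(
    ecd = 1e6 / ave, ave = ave, sd = s, cv = 100 * s / ave,
    hex_pct = if (is.null(shapes)) NA_real_ else 100 * mean(shapes == 6),
    min_area = min(cell_areas), max_area = max(cell_areas),
    n = length(cell_areas)), class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf(
    "<morphometry> n=%d  ECD %.0f cells/mm^2  AVE %.1f um^2  CV %.1f%%  6A %s\n",
    x$n, x$ecd, x$ave, x$cv,
    if (is.na(x$hex_pct)) "NA" else sprintf("%.1f%%", x$hex_pct)))
  invisible(x)
}

#' Normality screen (Kolmogorov-Smirnov + Shapiro-Wilk)
#'
#' A sample is routed to parametric tests only if both the Shapiro-Wilk test
#' and the Kolmogorov-Smirnov test against a normal with the sample moments
#' give p > `alpha`.  Degenerate (constant) samples are routed to
#' non-parametric handling with a warning.
#'
#' @param x numeric sample, n >= 3.
#' @param alpha screening level.
#' @return list of class `normality_screen`: `route`
#'   (`"parametric"`/`"nonparametric"`), `parametric` flag, p-values.
#' @export
normality_screen <- function(x, alpha = 0.05) {
  if (length(x) < 3) stop("normality screen needs n >= 3")
  if (stats::sd(x) == 0) {
    warning("constant sample: routed to non-parametric tests")
    return(structure(list(route = "nonparametric", parametric = FALSE,
                          p_shapiro = NA_real_, p_ks = NA_real_),
                     class = "normality_screen"))
  }
  p_sw <- stats::shapiro.test(x)$p.value
  p_ks <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  ok <- p_sw > alpha && p_ks > alpha
  structure(list(route = if (ok) "parametric" else "nonparametric",
                 parametric = ok, p_shapiro = p_sw, p_ks = p_ks),
            class = "normality_screen")
}

.test_result <- function(endpoint, test, statistic, p, alpha, screens = NULL) {
  structure(list(endpoint = endpoint, test = test,
                 statistic = unname(statistic), p_value = unname(p),
                 significant = is.finite(p) && p < alpha, alpha = alpha,
                 screens = screens),
            class = "endpoint_test")
}

#' @export
print.endpoint_test <- function(x, ...) {
  cat(sprintf("<endpoint_test> %s: %s, statistic %.4g, p = %.4g (%s)\n",
              x$endpoint, x$test, x$statistic, x$p_value,
              if (x$significant) "significant" else "n.s."))
  invisible(x)
}

#' Two-group endpoint comparison
#'
#' Screens both samples for normality, then compares them with a two-sided
#' two-sample t-test (Welch by default, classical Student with
#' `var_equal = TRUE`) when both screens pass, or a rank-based alternative
#' otherwise (Wilcoxon rank-sum / signed-rank).  `paper_compat = TRUE`
#' reproduces the source study's routing, which sent paired non-parametric
#' two-group comparisons to the Friedman test.
#'
#' @param a,b numeric samples.
#' @param paired logical.
#' @param var_equal classical Student's t instead of Welch.
#' @param paper_compat route paired non-parametric comparisons to Friedman.
#' @param alpha significance level.
#' @param endpoint label carried into the result.
#' @return an `endpoint_test`.
#' @export
compare_groups <- function(a, b, paired = FALSE, var_equal = FALSE,
                           paper_compat = FALSE, alpha = 0.05,
                           endpoint = "endpoint") {
  if (paired && length(a) != length(b))
    stop("paired comparison needs samples of equal length")
  sa <- withCallingHandlers(normality_screen(a),
                            warning = function(w) invokeRestart("muffleWarning"))
  sb <- withCallingHandlers(normality_screen(b),
                            warning = function(w) invokeRestart("muffleWarning"))
  screens <- list(a = sa, b = sb)
  if (sa$parametric && sb$parametric) {
    tt <- stats::t.test(a, b, paired = paired, var.equal = var_equal)
    nm <- if (paired) "paired t" else if (var_equal) "Student t" else "Welch t"
    return(.test_result(endpoint, nm, tt$statistic, tt$p.value, alpha, screens))
  }
  if (paper_compat && paired) {
    fr <- stats::friedman.test(cbind(a, b))
    return(.test_result(endpoint, "Friedman", fr$statistic, fr$p.value,
                        alpha, screens))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired))
  nm <- if (paired) "Wilcoxon signed-rank" else "Wilcoxon rank-sum"
  .test_result(endpoint, nm, wt$statistic, wt$p.value, alpha, screens)
}

#' Longitudinal course of an endpoint
#'
#' Tests for a change of an endpoint across timepoints within a cohort (or
#' one of its groups): repeated-measures ANOVA when every timepoint passes
#' the normality screen, the Friedman test otherwise.
#'
#' @param cohort a `cohort_table`.
#' @param endpoint column prefix, e.g. `"ecd"`.
#' @param timepoints character timepoint suffixes (>= 3), e.g.
#'   `c("pre", "1d", "1w", "1m")`.
#' @param group optional group label to subset.
#' @param alpha significance level.
#' @return an `endpoint_test`.
#' @export
longitudinal_course <- function(cohort, endpoint, timepoints,
                                group = NULL, alpha = 0.05) {
  if (length(timepoints) < 3) stop("need at least 3 timepoints")
  if (!is.null(group)) cohort <- cohort[cohort$group == group, ]
  cols <- paste(endpoint, timepoints, sep = "_")
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    stop("missing endpoint columns: ", paste(missing, collapse = ", "))
  Y <- as.matrix(cohort[, cols])
  screens <- apply(Y, 2, function(col)
    withCallingHandlers(normality_screen(col),
                        warning = function(w) invokeRestart("muffleWarning")),
    simplify = FALSE)
  lbl <- paste0(endpoint, if (!is.null(group)) paste0(" [", group, "]"))
  if (all(vapply(screens, `[[`, TRUE, "parametric"))) {
    long <- data.frame(
      y = as.vector(Y),
      time = factor(rep(timepoints, each = nrow(Y)), levels = timepoints),
      patient = factor(rep(seq_len(nrow(Y)), length(timepoints))))
    fit <- stats::aov(y ~ time + Error(patient), data = long)
    s <- summary(fit)[["Error: Within"]][[1]]
    return(.test_result(lbl, "RM-ANOVA", s[["F value"]][1],
                        s[["Pr(>F)"]][1], alpha, screens))
  }
  fr <- stats::friedman.test(Y)
  .test_result(lbl, "Friedman", fr$statistic, fr$p.value, alpha, screens)
}

#' Count transient IOP peaks above a threshold
#'
#' Number of patients whose intraocular pressure is strictly above
#' `threshold` at the given timepoint; reported per group when the table
#' has a `group` column.
#'
#' @param cohort a data.frame with an `iop_<timepoint>` column.
#' @param threshold mmHg.
#' @param timepoint timepoint suffix (default `"6h"`).
#' @return integer count, or a named vector of per-group counts plus
#'   `total` when a `group` column is present.
#' @examples
#' iop_peak_count(data.frame(iop_6h = c(18, 21, 25, 20, 19)))  # 2
#' @export
iop_peak_count <- function(cohort, threshold = 20, timepoint = "6h") {
  col <- paste0("iop_", timepoint)
  if (!col %in% names(cohort))
    stop("missing IOP column '", col, "'")
  hit <- cohort[[col]] > threshold
  if ("group" %in% names(cohort)) {
    by <- tapply(hit, cohort$group, sum)
    return(c(by, total = sum(hit)))
  }
  sum(hit)
}

#' Full endpoint report for a cohort
#'
#' Runs the study's endpoint battery on a cohort table: between-group
#' comparisons of age, ECD, IOP, BCVA and morphometry at each timepoint,
#' the within-group longitudinal ECD course, percent cell loss per group,
#' and the 6-h IOP peak counts.
#'
#' @param cohort a `cohort_table`.
#' @param alpha significance level.
#' @return list with `comparisons` (data.frame), `longitudinal`,
#'   `cell_loss_pct`, and `iop_peaks`.
#' @export
cohort_endpoint_report <- function(cohort, alpha = 0.05) {
  g1 <- cohort[cohort$group == "BSS", ]
  g2 <- cohort[cohort$group == "Healon", ]
  vars <- c("age", "ecd_pre", "ecd_1d", "ecd_1w", "ecd_1m",
            "iop_pre", "iop_6h", "iop_1d", "iop_1w", "iop_1m",
            "bcva_pre", "bcva_1d", "bcva_1w", "bcva_1m",
            "ave_pre", "cv_pre", "hex_pre")
  cmp <- do.call(rbind, lapply(vars, function(v) {
    r <- compare_groups(g1[[v]], g2[[v]], endpoint = v, alpha = alpha)
    data.frame(endpoint = v, test = r$test, statistic = r$statistic,
               p_value = r$p_value, significant = r$significant)
  }))
  tps <- c("pre", "1d", "1w", "1m")
  long <- lapply(c(BSS = "BSS", Healon = "Healon"), function(g)
    longitudinal_course(cohort, "ecd", tps, group = g, alpha = alpha))
  loss <- vapply(list(BSS = g1, Healon = g2), function(d)
    percent_cell_loss(mean(d$ecd_pre), mean(d$ecd_pre - d$ecd_1m)), 0)
  list(comparisons = cmp, longitudinal = long,
       cell_loss_pct = loss, iop_peaks = iop_peak_count(cohort))
}
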