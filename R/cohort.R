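#' Specification of the synthetic clinical cohort
#'
#' Describes the two surgical groups of the study — 47 eyes irrigated with
#' balanced salt solution (BSS) and 45 eyes operated under the Healon
#' viscoelastic — through the group-level means and standard deviations of
#' their measured endpoints: endothelial cell density (ECD, cells/mm^2) at
#' four timepoints, intraocular pressure (IOP, mmHg) at five, best-corrected
#' visual acuity (BCVA, decimal) at four, endothelial morphometry (mean cell
#' area AVE, coefficient of variation CV, percent hexagonal cells 6A) pre-op
#' and at day 1, and the surgical covariates (phaco time, effective phaco
#' time, LOCS III grade, surgery duration).
#'
#' Longitudinal endpoints are modeled per patient as correlated multivariate
#' normals with a common within-patient correlation `rho_w` across
#' timepoints (default 0.85, close to the value implied by the reported
#' one-month cell-loss SD; see [calibrate_rho()]).  Post-operative IOP
#' means/SDs are not tabulated in the source (figure only) and are chosen so
#' that a transient pressure peak above 20 mmHg occurs in roughly 9 of 47
#' BSS and 5 of 45 Healon eyes at 6 h and normalizes by day 1.  The
#' `age_ecl_slope` knob adds extra post-operative cell loss per year of age
#' above the group mean (older patients lose more cells).
#'
#' @param n group sizes, `c(BSS, Healon)`.
#' @param rho_w within-patient correlation across timepoints, in `[0, 1)`.
#' @param age_ecl_slope additional one-month ECD loss per year of age above
#'   the group mean (cells/mm^2/year); 0 disables the age association.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(BSS = 47, Healon = 45), rho_w = 0.85,
                        age_ecl_slope = 2) {
  if (any(n < 2)) stop("group sizes must be >= 2")
  if (rho_w < 0 || rho_w >= 1) stop("rho_w must lie in [0, 1)")
  grp <- c("BSS", "Healon")
  tp4 <- c("pre", "1d", "1w", "1m")
  tp5 <- c("pre", "6h", "1d", "1w", "1m")
  mk <- function(bss, healon, tp) {
    m <- rbind(BSS = bss, Healon = healon)
    colnames(m) <- tp
    m
  }
  spec <- list(
    n = stats::setNames(as.integer(n), grp),
    n_female = stats::setNames(c(32L, 30L), grp),
    rho_w = rho_w, age_ecl_slope = age_ecl_slope,
    age_mean = c(BSS = 71.2, Healon = 71.2),
    age_sd = c(BSS = 9.7, Healon = 10.6),
    age_range = list(BSS = c(44, 88), Healon = c(40, 91)),
    ecd_mean = mk(c(2334, 2250, 2211, 2228), c(2307, 2243, 2195, 2185), tp4),
    ecd_sd   = mk(c(436, 472, 485, 471),    c(427, 435, 452, 389),    tp4),
    iop_mean = mk(c(15.2, 16.5, 15.0, 14.8, 14.9),
                  c(13.9, 15.5, 14.2, 14.0, 13.9), tp5),
    iop_sd   = mk(c(3.8, 4.5, 3.5, 3.2, 3.0),
                  c(2.7, 3.7, 3.0, 2.8, 2.7), tp5),
    bcva_mean = mk(c(0.30, 0.72, 0.74, 0.88), c(0.39, 0.68, 0.88, 0.92), tp4),
    bcva_sd   = mk(c(0.14, 0.18, 0.18, 0.18), c(0.14, 0.19, 0.17, 0.22), tp4),
    ave_mean = mk(c(457.7, 481.8), c(452.3, 467.0), c("pre", "1d")),
    ave_sd   = mk(c(252, 211), c(126, 116), c("pre", "1d")),
    cv_mean  = mk(c(34.7, 36.7), c(34.9, 35.5), c("pre", "1d")),
    cv_sd    = mk(c(5.9, 6.0), c(5.1, 5.2), c("pre", "1d")),
    hex_mean = mk(c(60.4, 57.9), c(58.8, 57.1), c("pre", "1d")),
    hex_sd   = mk(c(8, 8), c(8, 8), c("pre", "1d")),
    phaco_time = rbind(BSS = c(1.62, 0.60), Healon = c(1.75, 0.89)),
    ept        = rbind(BSS = c(1.31, 0.49), Healon = c(1.40, 0.71)),
    locs3      = rbind(BSS = c(2.40, 0.81), Healon = c(2.16, 0.95)),
    surgery_time = rbind(BSS = c(6.54, 1.87), Healon = c(7.69, 1.32)))
  for (nm in grep("_sd$", names(spec), value = TRUE))
    if (any(spec[[nm]] < 0)) stop("standard deviations must be >= 0")
  class(spec) <- "cohort_spec"
  spec
}

#' Within-patient correlation implied by a paired-change SD
#'
#' For two timepoints with cross-sectional SDs `sd_pre` and `sd_post` and a
#' reported SD of the paired change `sd_loss`,
#' `Var(pre - post) = sd_pre^2 + sd_post^2 - 2 rho sd_pre sd_post` solves to
#' `rho = (sd_pre^2 + sd_post^2 - sd_loss^2) / (2 sd_pre sd_post)`.  With
#' the reported one-month figures (436, 471, 226) this gives ~0.88.
#'
#' @param sd_pre,sd_post cross-sectional SDs.
#' @param sd_loss SD of the paired difference.
#' @return correlation in `[0, 1)`; error if the triple is infeasible.
#' @export
calibrate_rho <- function(sd_pre, sd_post, sd_loss) {
  rho <- (sd_pre^2 + sd_post^2 - sd_loss^2) / (2 * sd_pre * sd_post)
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stop("infeasible correlation (", signif(rho, 3),
         ") implied by the given SDs")
  rho
}

# draws n rows from N(mu, diag(sd) R diag(sd)) with equicorrelation rho;
# exact means when sd = 0
.mvn_equicorr <- function(n, mu, sd, rho) {
  k <- length(mu)
  R <- matrix(rho, k, k); diag(R) <- 1
  Lc <- tryCatch(chol(R), error = function(e)
    stop("infeasible correlation matrix (rho_w = ", rho, ")"))
  z <- matrix(stats::rnorm(n * k), n, k) %*% Lc
  sweep(sweep(z, 2, sd, `*`), 2, mu, `+`)
}

#' Generate a synthetic patient cohort
#'
#' Draws a per-patient table with the statistical structure of
#' [cohort_spec()]: longitudinal endpoints are correlated within patient
#' (equicorrelation `rho_w`), truncated to physical ranges, with an optional
#' age dependence of post-operative cell loss.  The same seed always yields
#' the identical table.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed.
#' @return data.frame of class `cohort_table`, one row per patient.
#' @examples
#' co <- generate_cohort(cohort_spec(), seed = 1)
#' nrow(co)  # 92
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- list()
  for (g in names(spec$n)) {
    n <- spec$n[[g]]
    # truncated-normal ages within the reported range
    rng <- spec$age_range[[g]]
    age <- numeric(0)
    while (length(age) < n) {
      a <- stats::rnorm(2L * n, spec$age_mean[[g]], spec$age_sd[[g]])
      age <- c(age, a[a >= rng[1] & a <= rng[2]])
    }
    age <- age[seq_len(n)]
    nf <- min(spec$n_female[[g]], n)
    sex <- sample(c(rep("F", nf), rep("M", n - nf)))
    ecd <- .mvn_equicorr(n, spec$ecd_mean[g, ], spec$ecd_sd[g, ], spec$rho_w)
    # older patients lose more cells post-operatively
    if (spec$age_ecl_slope != 0) {
      fac <- c(0, 0.8, 0.9, 1)
      dl <- spec$age_ecl_slope * (age - spec$age_mean[[g]])
      ecd <- ecd - outer(dl, fac)
    }
    ecd <- pmax(ecd, 1)
    iop <- pmax(.mvn_equicorr(n, spec$iop_mean[g, ], spec$iop_sd[g, ],
                              spec$rho_w), 1)
    bcva <- pmin(pmax(.mvn_equicorr(n, spec$bcva_mean[g, ], spec$bcva_sd[g, ],
                                    spec$rho_w), 0.05), 1.5)
    ave <- pmax(.mvn_equicorr(n, spec$ave_mean[g, ], spec$ave_sd[g, ],
                              spec$rho_w), 150)
    cv <- pmax(.mvn_equicorr(n, spec$cv_mean[g, ], spec$cv_sd[g, ],
                             spec$rho_w), 5)
    hex <- pmin(pmax(.mvn_equicorr(n, spec$hex_mean[g, ], spec$hex_sd[g, ],
                                   spec$rho_w), 0), 100)
    pos <- function(m) pmax(stats::rnorm(n, m[1], m[2]), 0.05)
    df <- data.frame(
      patient_id = sprintf("%s%03d", substr(g, 1, 1), seq_len(n)),
      group = g, age = age, sex = sex,
      ecd_pre = ecd[, 1], ecd_1d = ecd[, 2], ecd_1w = ecd[, 3],
      ecd_1m = ecd[, 4],
      iop_pre = iop[, 1], iop_6h = iop[, 2], iop_1d = iop[, 3],
      iop_1w = iop[, 4], iop_1m = iop[, 5],
      bcva_pre = bcva[, 1], bcva_1d = bcva[, 2], bcva_1w = bcva[, 3],
      bcva_1m = bcva[, 4],
      ave_pre = ave[, 1], ave_1d = ave[, 2],
      cv_pre = cv[, 1], cv_1d = cv[, 2],
      hex_pre = hex[, 1], hex_1d = hex[, 2],
      phaco_time_s = pos(spec$phaco_time[g, ]),
      ept_s = pos(spec$ept[g, ]),
      locs3 = pos(spec$locs3[g, ]),
      surgery_time_min = pos(spec$surgery_time[g, ]),
      stringsAsFactors = FALSE)
    out[[g]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cohort_table", class(res))
  res
}
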