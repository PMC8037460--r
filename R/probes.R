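#' Sample a field time series at a point
#'
#' Barycentric (P1) interpolation of the stored fields at an arbitrary
#' point, one value per stored step.
#'
#' @param series a [run_transient()] result.
#' @param point numeric `c(x, y)` in mm, or a probe name known to the
#'   series' geometry.
#' @param field `"T"` (temperature, C) or `"speed"` (velocity magnitude,
#'   mm/s).
#' @return object of class `probe_trace`: `times`, `values`, `reference`
#'   (value in the initial steady state), `name`.
#' @export
sample_point <- function(series, point, field = c("T", "speed")) {
  field <- match.arg(field)
  stopifnot(inherits(series, "field_series"))
  if (is.character(point)) {
    nm <- point
    i <- match(nm, series$probes$name)
    if (is.na(i)) stop("unknown probe name '", nm, "'")
    point <- c(series$probes$x[i], series$probes$y[i])
  } else nm <- sprintf("point(%g, %g)", point[1], point[2])
  w <- interp_weights(series$mesh,
                      data.frame(x = point[1], y = point[2]))[[1]]
  at <- function(vec) sum(vec[w$nodes] * w$w)
  if (field == "T") {
    vals <- apply(series$stored_T, 2, at)
    ref <- at(series$steady$T)
  } else {
    vals <- vapply(series$stored_u,
                   function(u) at(sqrt(rowSums(u^2)) * 1e3), 0)
    ref <- at(sqrt(rowSums(series$steady$u^2)) * 1e3)
  }
  structure(list(name = nm, times = series$stored_times, values = vals,
                 reference = ref), class = "probe_trace")
}

#' Fine-resolution temperature trace at a named probe
#'
#' The named probes (`endothelium_center`, `probe_tip_center`,
#' `corneal_wall_interior`) are recorded at every time step during
#' [run_transient()]; this accessor returns that per-step trace.
#'
#' @param series a `field_series`.
#' @param name probe name.
#' @return a `probe_trace`.
#' @export
point_probe <- function(series, name = "endothelium_center") {
  stopifnot(inherits(series, "field_series"))
  if (!name %in% colnames(series$probe_traces))
    stop("unknown probe name '", name, "'")
  i <- match(name, series$probes$name)
  w <- interp_weights(series$mesh, series$probes[i, c("x", "y")])[[1]]
  ref <- sum(series$steady$T[w$nodes] * w$w)
  structure(list(name = name, times = series$times,
                 values = series$probe_traces[, name], reference = ref),
            class = "probe_trace")
}

#' Trace extrema and rise above reference
#'
#' @param trace a `probe_trace`.
#' @return list with `time_of_max`, `max_value`, and `max_rise`
#'   (`max_value - reference`).
#' @export
trace_extrema <- function(trace) {
  stopifnot(inherits(trace, "probe_trace"), length(trace$values) > 0)
  i <- which.max(trace$values)
  list(time_of_max = trace$times[i], max_value = trace$values[i],
       max_rise = trace$values[i] - trace$reference)
}

#' Relaxation time after the impulse
#'
#' First time after the end of the impulse at which the solution has
#' returned to the initial steady state and stays there: the field-wide
#' criterion requires `max|T - T_ref| < tol_T` over all nodes and a relative
#' velocity deviation below `tol_u` (relative to the maximum steady speed);
#' the probe criterion applies `tol_T` to the reference point-probe trace.
#' Returned as seconds elapsed since the end of the impulse; `NA` if the
#' criterion is never met within the horizon ("not relaxed").
#'
#' @param series a `field_series`.
#' @param reference a `field_state` (the initial steady state by default).
#' @param tol_T temperature tolerance, C.
#' @param tol_u relative velocity tolerance.
#' @param criterion `"field"` (stored full fields) or `"probe"` (per-step
#'   point-probe trace).
#' @export
relaxation_time <- function(series, reference = series$steady, tol_T = 0.5,
                            tol_u = 0.05, criterion = c("field", "probe")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(series, "field_series"))
  if (!is.null(reference$mesh) &&
      nrow(reference$mesh$nodes) != nrow(series$mesh$nodes))
    stop("reference state was computed on a different mesh")
  t0 <- series$source$duration
  if (max(series$times) <= t0)
    stop("series does not extend beyond the impulse end")
  if (criterion == "field") {
    dT <- apply(abs(series$stored_T - reference$T), 2, max)
    uref <- max(sqrt(rowSums(reference$u^2)))
    du <- vapply(series$stored_u, function(u)
      max(sqrt(rowSums((u - reference$u)^2))), 0)
    ok <- dT < tol_T & (uref < 1e-12 | du / max(uref, 1e-12) < tol_u)
    tt <- series$stored_times
  } else {
    tr <- point_probe(series)
    ok <- abs(tr$values - tr$reference) < tol_T
    tt <- tr$times
  }
  ok[tt < t0] <- FALSE
  sustained <- rev(cumprod(rev(ok))) == 1
  i <- which(sustained & tt >= t0)
  if (length(i) == 0L) return(NA_real_)
  tt[i[1]] - t0
}

#' Velocity magnitude extrema over a time window
#'
#' Extrema of the interior fluid speed (mm/s), excluding a two-element band
#' around the inlets and outlets where nodal velocities are
#' resolution-limited.  The maximum uses the per-flow-update statistics when
#' available (finer in time than the stored fields).
#'
#' @param series a `field_series`.
#' @param window `c(t0, t1)` in s.
#' @return named numeric `c(min, max)` in mm/s.
#' @export
velocity_range <- function(series, window = range(series$stored_times)) {
  stopifnot(inherits(series, "field_series"), length(window) == 2)
  sel <- series$stored_times >= window[1] - 1e-9 &
    series$stored_times <= window[2] + 1e-9
  if (!any(sel)) stop("empty window: no stored fields in [",
                      window[1], ", ", window[2], "]")
  ins <- if (!is.null(series$interior)) series$interior
         else seq_len(nrow(series$mesh$nodes))
  spd <- vapply(series$stored_u[sel],
                function(u) range(sqrt(rowSums(u[ins, , drop = FALSE]^2))) * 1e3,
                numeric(2))
  lo <- min(spd[1, ]); hi <- max(spd[2, ])
  vs <- series$vel_stats
  if (!is.null(vs) && nrow(vs)) {
    vsel <- vs$time >= window[1] - 1e-9 & vs$time <= window[2] + 1e-9
    if (any(vsel)) hi <- max(hi, vs$max_speed_interior[vsel])
  }
  c(min = lo, max = hi)
}

#' @export
print.probe_trace <- function(x, ...) {
  ex <- trace_extrema(x)
  cat("<probe_trace> ", x$name, ": ", length(x$values), " samples, ",
      "reference ", format(x$reference, digits = 4), ", max ",
      format(ex$max_value, digits = 4), " at t = ", ex$time_of_max,
      " s (rise ", format(ex$max_rise, digits = 3), ")\n", sep = "")
  invisible(x)
}
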