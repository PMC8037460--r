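#' Unit conversion helpers
#'
#' Small converters used at the interfaces of the simulation stage.  Geometry
#' is handled in millimetres, material constants and the solver in SI units,
#' clinical pressures in mmHg, and the aqueous production rate in uL/min.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * 133.322387415

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / 133.322387415

#' @rdname units
#' @export
uL_min_to_m3_s <- function(x) x * 1e-9 / 60

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3
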