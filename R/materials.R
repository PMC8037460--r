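#' Fluid property sets for the anterior-chamber model
#'
#' The chamber can be filled with aqueous humor (`"AH"`), balanced salt
#' solution (`"BSS"`) or a 1% sodium-hyaluronate viscoelastic (`"Healon"`).
#' Each preset carries the constants needed by the coupled flow/heat solver:
#' dynamic viscosity `mu` (Pa s), density `rho` (kg m^-3), thermal
#' conductivity `k` (W m^-1 K^-1), heat capacity `cp` (J kg^-1 K^-1) and the
#' thermal expansion coefficient `alpha` (K^-1).
#'
#' Density and thermal expansion are tabulated in the source literature for
#' aqueous humor only; BSS and Healon are near-water fluids and reuse the
#' aqueous values.  Heat capacities are stored in J kg^-1 K^-1 (4200 for
#' aqueous humor, 2500 for BSS/Healon); the literal per-gram numerals from
#' which they derive are available via `literal_cp = TRUE`, but they imply
#' unphysical thermal diffusivities and are kept only for traceability.
#'
#' @param mu,rho,k,cp,alpha fluid constants, see above.
#' @param name preset or registered fluid identifier.
#' @param literal_cp logical; if `TRUE` return the literal per-gram heat
#'   capacity numerals (4.2 / 2.5 J kg^-1 K^-1) instead of the physical
#'   kJ-interpreted values.
#' @return An object of class `fluid_properties` (a named list).
#' @examples
#' get_fluid("Healon")$mu   # 200 Pa s
#' get_fluid("BSS")$k      # 0.65 W m^-1 K^-1
#' @export
fluid_properties <- function(mu, rho, k, cp, alpha) {
  vals <- c(mu = mu, rho = rho, k = k, cp = cp, alpha = alpha)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all fluid properties must be finite and strictly positive: ",
         paste(names(vals)[!is.finite(vals) | vals <= 0], collapse = ", "))
  }
  pr <- mu * cp / k
  if (!is.finite(pr)) stop("Prandtl number mu*cp/k must be finite")
  structure(list(mu = mu, rho = rho, k = k, cp = cp, alpha = alpha),
            class = "fluid_properties")
}

# preset table; cp in J kg^-1 K^-1 under the kJ reading of the printed values
.fluid_presets <- function(literal_cp = FALSE) {
  cp_scale <- if (literal_cp) 1e-3 else 1
  list(
    AH     = fluid_properties(mu = 7.5e-4,  rho = 998, k = 0.58,
                              cp = 4200 * cp_scale, alpha = 3e-4),
    BSS    = fluid_properties(mu = 1.02e-3, rho = 998, k = 0.65,
                              cp = 2500 * cp_scale, alpha = 3e-4),
    Healon = fluid_properties(mu = 200,     rho = 998, k = 0.47,
                              cp = 2500 * cp_scale, alpha = 3e-4)
  )
}

.fluid_registry <- new.env(parent = emptyenv())

#' @rdname fluid_properties
#' @export
get_fluid <- function(name, literal_cp = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  presets <- .fluid_presets(literal_cp)
  if (name %in% names(presets)) return(presets[[name]])
  if (!is.null(.fluid_registry[[name]])) return(.fluid_registry[[name]])
  stop("unknown fluid '", name, "'; available: ",
       paste(c(names(presets), ls(.fluid_registry)), collapse = ", "))
}

#' Register a user-defined fluid preset
#'
#' @param name identifier under which the fluid becomes retrievable.
#' @param props a [fluid_properties()] object.
#' @return `props`, invisibly.
#' @export
register_fluid <- function(name, props) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(props, "fluid_properties"))
  assign(name, props, envir = .fluid_registry)
  invisible(props)
}

#' Porous-medium constants for the trabecular meshwork
#'
#' The trabecular meshwork is modeled as a Brinkman porous block with
#' porosity `eps_p` = 0.1 and permeability `kappa` = 5e-15 m^2.  The
#' Forchheimer coefficient `beta_f` and the mass source `q_m` default to
#' zero, so the corresponding momentum and continuity terms vanish.
#'
#' @param eps_p porosity in (0, 1].
#' @param kappa permeability, m^2, > 0.
#' @param beta_f Forchheimer coefficient (kg m^-4); 0 disables the term.
#' @param q_m volumetric mass source (kg m^-3 s^-1); 0 disables the term.
#' @return An object of class `porous_properties`.
#' @examples
#' get_porous()$kappa  # 5e-15 m^2
#' @export
porous_properties <- function(eps_p = 0.1, kappa = 5e-15,
                              beta_f = 0, q_m = 0) {
  if (!is.finite(eps_p) || eps_p <= 0 || eps_p > 1)
    stop("eps_p must lie in (0, 1]")
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (beta_f < 0) stop("beta_f must be >= 0")
  structure(list(eps_p = eps_p, kappa = kappa, beta_f = beta_f, q_m = q_m),
            class = "porous_properties")
}

#' @rdname porous_properties
#' @export
get_porous <- function() porous_properties()

#' @export
print.fluid_properties <- function(x, ...) {
  cat("<fluid_properties>\n")
  cat(sprintf("  mu    = %g Pa s\n  rho   = %g kg/m^3\n  k     = %g W/m/K\n",
              x$mu, x$rho, x$k))
  cat(sprintf("  cp    = %g J/kg/K\n  alpha = %g 1/K\n", x$cp, x$alpha))
  cat(sprintf("  (thermal diffusivity %.3g m^2/s)\n", x$k / (x$rho * x$cp)))
  invisible(x)
}
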