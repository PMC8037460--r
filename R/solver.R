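#' Boundary conditions of the chamber model
#'
#' Defaults follow the modeled surgical situation: the outer corneal wall is
#' held at 27 C (exposed, irrigated surface), every other border at the core
#' body temperature of 36.5 C; aqueous enters at the two pupil-border inlets
#' at the physiological production rate of 2.4 uL/min in total and leaves
#' through the Schlemm's-canal outlets held at the episcleral venous
#' pressure of 10.5 mmHg.
#'
#' For non-chamber meshes (e.g. [rectangle_mesh()]) the tag maps can be set
#' explicitly: `dirichlet_temp` is a named vector tag -> temperature (tags
#' without an entry get an insulating natural condition), `inlet_tags` and
#' `outlet_tags` name the velocity-inflow and pressure-outflow tags, and all
#' remaining boundary tags are no-slip walls.
#'
#' @param corneal_temp outer corneal wall temperature, C.
#' @param core_temp temperature of all other walls and of the inflow, C.
#' @param outlet_pressure Schlemm's-canal outlet pressure, mmHg.
#' @param inflow total aqueous inflow rate, uL/min (split over the inlets).
#' @param dirichlet_temp optional named tag -> temperature map overriding
#'   the chamber defaults.
#' @param inlet_tags,outlet_tags optional tag overrides.
#' @return object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(corneal_temp = 27, core_temp = 36.5,
                                outlet_pressure = 10.5, inflow = 2.4,
                                dirichlet_temp = NULL,
                                inlet_tags = NULL, outlet_tags = NULL) {
  if (!is.finite(corneal_temp) || !is.finite(core_temp))
    stop("boundary temperatures must be finite")
  if (outlet_pressure < 0) stop("outlet pressure must be >= 0")
  if (inflow <= 0) stop("inflow rate must be > 0")
  structure(list(corneal_temp = corneal_temp, core_temp = core_temp,
                 outlet_pressure = outlet_pressure, inflow = inflow,
                 dirichlet_temp = dirichlet_temp,
                 inlet_tags = inlet_tags, outlet_tags = outlet_tags),
            class = "boundary_conditions")
}

#' Heat impulse of the phaco tip
#'
#' The ultrasound impulse is modeled as a boundary heat flux on the immersed
#' tip segment, active for `t` in `[0, duration)`.  The total power (radiant
#' plus frictional, 0.66 / 1.2 / 2.4 / 3 W in the study grid) is spread over
#' the heated tip surface, giving a flux
#' `total_power / (tip_length * d_eff)` in W/m^2 imposed as
#' `-k dT/dn = flux` on the immersed segment.  The effective heated width
#' `d_eff` defaults to `pi` times the 2.2 mm tip diameter: the tip is a
#' cylinder, and its lateral surface per unit length is `pi * d`, so this is
#' the areal conversion consistent with a power "spread out over the tip".
#'
#' @param total_power impulse power, W (>= 0).
#' @param duration impulse duration, s.
#' @param tip_length heated segment length, mm.
#' @param d_eff effective heated out-of-plane width, mm
#'   (`pi * tip diameter` by default).
#' @return object of class `heat_source`.
#' @examples
#' s <- heat_source(1.2)
#' apply_heat_flux_bc(s, 2)  # ~7.89e4 W/m^2
#' apply_heat_flux_bc(s, 6)  # 0 after the 5-s impulse
#' @export
heat_source <- function(total_power, duration = 5,
                        tip_length = 2.2, d_eff = pi * 2.2) {
  if (!is.finite(total_power) || total_power < 0)
    stop("total_power must be a non-negative number of watts")
  if (duration <= 0) stop("duration must be > 0")
  flux <- total_power / (tip_length * 1e-3 * d_eff * 1e-3)
  structure(list(total_power = total_power, duration = duration,
                 tip_length = tip_length, d_eff = d_eff, flux = flux),
            class = "heat_source")
}

#' @rdname heat_source
#' @param source a `heat_source` object.
#' @param t time since impulse onset, s.
#' @return boundary flux in W/m^2 (0 outside the impulse window).
#' @export
apply_heat_flux_bc <- function(source, t) {
  stopifnot(inherits(source, "heat_source"), t >= 0)
  if (t < source$duration) source$flux else 0
}

#' Solver configuration
#'
#' @param dt transient time step, s (0.02 in the reference runs).
#' @param t_end simulation horizon, s (15 s, or 30 s at the higher powers).
#' @param steady_tol relative tolerance of the stationary solve.
#' @param store_dt interval at which full fields are retained, s.
#' @param flow_stride number of heat steps between flow updates; the flow
#'   field evolves on the buoyancy time scale (seconds), so re-solving the
#'   momentum system every `flow_stride * dt` = 0.1 s is a quasi-steady
#'   refresh, while temperature advances every `dt`.
#' @param buoyancy logical: include the Boussinesq body force.
#' @param gravity gravitational acceleration vector (m/s^2); the default
#'   points from cornea to lens (supine surgical position).
#' @param t_ref Boussinesq reference temperature, C (`NULL`: core temp).
#' @param stab_delta pressure-stabilization coefficient of the equal-order
#'   velocity/pressure pair.
#' @param stokes_mu_threshold viscosity (Pa s) above which the fluid is
#'   treated as non-convecting (flow solve skipped, pure conduction); the
#'   viscoelastic at 200 Pa s falls in this regime.
#' @param max_picard,picard_relax stationary Picard iteration controls.
#' @param qp,qvd include pressure-work / viscous-dissipation heat terms
#'   (negligible at mm/s velocities; off by default).
#' @return object of class `solver_config`.
#' @export
solver_config <- function(dt = 0.02, t_end = 15, steady_tol = 1e-3,
                          store_dt = 0.5, flow_stride = 5L, buoyancy = TRUE,
                          gravity = c(0, -9.81), t_ref = NULL,
                          stab_delta = 0.1, stokes_mu_threshold = 1,
                          max_picard = 80L, picard_relax = 0.6,
                          qp = FALSE, qvd = FALSE) {
  if (dt <= 0) stop("dt must be > 0")
  if (t_end <= 0) stop("t_end must be > 0")
  if (steady_tol <= 0 || steady_tol >= 1) stop("steady_tol must lie in (0, 1)")
  if (store_dt < dt) store_dt <- dt
  stopifnot(length(gravity) == 2, is.finite(gravity))
  structure(list(dt = dt, t_end = t_end, steady_tol = steady_tol,
                 store_dt = store_dt, flow_stride = as.integer(flow_stride),
                 buoyancy = isTRUE(buoyancy), gravity = gravity,
                 t_ref = t_ref, stab_delta = stab_delta,
                 stokes_mu_threshold = stokes_mu_threshold,
                 max_picard = as.integer(max_picard),
                 picard_relax = picard_relax, qp = isTRUE(qp),
                 qvd = isTRUE(qvd)),
            class = "solver_config")
}

#' Boussinesq buoyancy body force
#'
#' `F = rho * alpha * g * (T_ref - T)`, the temperature-linear volumetric
#' force of the Boussinesq approximation, oriented along the gravity vector.
#'
#' @param temp nodal temperature, C.
#' @param fluid a [fluid_properties()] object.
#' @param t_ref reference temperature, C.
#' @param gravity gravity vector, m/s^2.
#' @return n x 2 matrix of volumetric force (N/m^3).
#' @examples
#' f <- boussinesq_body_force(35.5, get_fluid("AH"), t_ref = 36.5,
#'                            gravity = c(0, -9.81))
#' sqrt(sum(f^2))  # 2.937 N/m^3 for a 1 K deficit
#' @export
boussinesq_body_force <- function(temp, fluid, t_ref,
                                  gravity = c(0, -9.81)) {
  stopifnot(all(is.finite(temp)))
  d <- fluid$rho * fluid$alpha * (t_ref - temp)
  cbind(d * gravity[1], d * gravity[2])
}

## ---------------------------------------------------------------------------
## internal solver context

# tag -> temperature Dirichlet map for a mesh
.temp_tag_map <- function(mesh, bc) {
  if (!is.null(bc$dirichlet_temp)) return(bc$dirichlet_temp)
  tags <- unique(mesh$boundary$tag)
  v <- stats::setNames(rep(bc$core_temp, length(tags)), tags)
  v["cornea"] <- bc$corneal_temp
  v
}

.inlet_outlet_tags <- function(mesh, bc) {
  tags <- unique(mesh$boundary$tag)
  inl <- if (!is.null(bc$inlet_tags)) bc$inlet_tags
         else intersect(c("inlet_left", "inlet_right"), tags)
  out <- if (!is.null(bc$outlet_tags)) bc$outlet_tags
         else intersect(c("sc_outlet_left", "sc_outlet_right"), tags)
  list(inlet = inl, outlet = out)
}

# flux-consistent nodal inflow speed for one inlet tag (m/s, +y)
.inlet_speed <- function(mesh, tag, q2d) {
  b <- mesh$boundary
  ie <- b[b$tag == tag, ]
  if (nrow(ie) == 0L) return(0)
  inodes <- unique(c(ie$n1, ie$n2))
  L_in <- sum(ie$length) * 1e-3
  adj <- b[b$tag != tag & (b$n1 %in% inodes | b$n2 %in% inodes), ]
  horiz <- abs(mesh$nodes[adj$n1, 2] - mesh$nodes[adj$n2, 2]) <
    1e-7 * (1 + adj$length)
  L_adj <- sum(adj$length[horiz]) * 1e-3
  q2d / (L_in + L_adj / 2)
}

# build everything that does not change during a simulation
.solver_ctx <- function(mesh, fluid, porous, bc, config) {
  fp <- fem_precompute(mesh)
  n <- fp$n
  d_eff <- if (!is.null(mesh$geom)) mesh$geom$params$probe_tip_diameter else 2.2
  eps_p <- ifelse(fp$porous, porous$eps_p, 1)
  mu_e <- fluid$mu / eps_p
  rho_adv <- fluid$rho / eps_p^2
  rho_t <- fluid$rho / eps_p

  Kvisc <- fem_stiffness(fp, mu_e)
  Mdarcy <- fem_mass(fp, ifelse(fp$porous, fluid$mu / porous$kappa, 0))
  Mrho <- fem_mass(fp, rho_t)
  Mcp <- fem_mass(fp, fluid$rho * fluid$cp)
  M1 <- fem_mass(fp, 1)
  Kt <- fem_stiffness(fp, fluid$k)
  grad <- fem_gradient_ops(fp)
  h2 <- 2 * fp$A
  # pressure-stabilization scale: viscous h^2/mu in the bulk, Darcy kappa/mu
  # in the porous block (harmonic combination)
  tau <- config$stab_delta /
    (fluid$mu / h2 + ifelse(fp$porous, fluid$mu / porous$kappa, 0))
  S <- fem_stiffness(fp, tau)
  tauA <- tau * fp$A

  tmap <- .temp_tag_map(mesh, bc)
  tdir_nodes <- integer(0); tdir_vals <- numeric(0)
  for (tg in names(tmap)) {
    nd <- boundary_nodes(mesh, tg)
    tdir_nodes <- c(tdir_nodes, nd)
    tdir_vals <- c(tdir_vals, rep(tmap[[tg]], length(nd)))
  }
  keep <- !duplicated(tdir_nodes)
  tdir_nodes <- tdir_nodes[keep]; tdir_vals <- tdir_vals[keep]

  io <- .inlet_outlet_tags(mesh, bc)
  q_total <- uL_min_to_m3_s(bc$inflow)
  n_inl <- max(1L, length(io$inlet))
  q2d <- (q_total / n_inl) / (d_eff * 1e-3)
  u_dir_nodes <- integer(0); u_dir_uy <- numeric(0)
  for (tg in io$inlet) {
    v <- .inlet_speed(mesh, tg, q2d)
    nd <- boundary_nodes(mesh, tg)
    u_dir_nodes <- c(u_dir_nodes, nd)
    u_dir_uy <- c(u_dir_uy, rep(v, length(nd)))
  }
  wall_tags <- setdiff(unique(mesh$boundary$tag), c(io$inlet, io$outlet))
  wn <- boundary_nodes(mesh, wall_tags)
  wn <- setdiff(wn, u_dir_nodes)        # inlet assignment wins at corners
  u_dir_nodes <- c(u_dir_nodes, wn)
  u_dir_uy <- c(u_dir_uy, rep(0, length(wn)))
  p_dir_nodes <- boundary_nodes(mesh, io$outlet)
  p_out <- mmHg_to_Pa(bc$outlet_pressure)
  if (length(p_dir_nodes) == 0L) { p_dir_nodes <- 1L; p_out <- 0 }

  # Dirichlet machinery for the 3n x 3n flow block system
  dir_rows <- c(u_dir_nodes, n + u_dir_nodes, 2L * n + p_dir_nodes)
  dir_vals <- c(rep(0, length(u_dir_nodes)), u_dir_uy,
                rep(p_out, length(p_dir_nodes)))
  mask <- rep(1, 3L * n); mask[dir_rows] <- 0
  Dmask <- Matrix::Diagonal(3L * n, mask)
  Ddir <- Matrix::Diagonal(3L * n, 1 - mask)

  maskT <- rep(1, n); maskT[tdir_nodes] <- 0
  DmaskT <- Matrix::Diagonal(n, maskT)
  DdirT <- Matrix::Diagonal(n, 1 - maskT)
  tdirvec <- numeric(n); tdirvec[tdir_nodes] <- tdir_vals

  tip_load <- Matrix::rowSums(fem_edge_mass(fp, mesh$tip_edges))

  t_ref <- if (is.null(config$t_ref)) bc$core_temp else config$t_ref

  list(mesh = mesh, fp = fp, n = n, fluid = fluid, porous = porous, bc = bc,
       config = config, d_eff = d_eff,
       Kvisc = Kvisc, Mdarcy = Mdarcy, Mrho = Mrho, Mcp = Mcp, M1 = M1,
       Kt = Kt, Dx = grad$Dx, Dy = grad$Dy, S = S, tauA = tauA,
       rho_adv = rho_adv, eps_p = eps_p,
       Dmask = Dmask, Ddir = Ddir, dir_rows = dir_rows, dir_vals = dir_vals,
       DmaskT = DmaskT, DdirT = DdirT, tdir_nodes = tdir_nodes,
       tdirvec = tdirvec, tip_load = tip_load, t_ref = t_ref,
       conduction_only = fluid$mu > config$stokes_mu_threshold)
}

# one linearized flow solve; u_adv: n x 2 advecting field; temp for buoyancy
.flow_solve <- function(ctx, u_adv, temp, dt = NULL, u_prev = NULL) {
  n <- ctx$n; fp <- ctx$fp
  C <- fem_advection(fp, u_adv[, 1], u_adv[, 2], ctx$rho_adv)
  A11 <- ctx$Kvisc + ctx$Mdarcy + C
  rhs_u <- numeric(2L * n)
  if (!is.null(dt)) {
    A11 <- A11 + ctx$Mrho / dt
    rhs_u <- c(as.numeric(ctx$Mrho %*% u_prev[, 1]),
               as.numeric(ctx$Mrho %*% u_prev[, 2])) / dt
  }
  rhs_p <- numeric(n)
  if (ctx$config$buoyancy) {
    F <- boussinesq_body_force(temp, ctx$fluid, ctx$t_ref, ctx$config$gravity)
    rhs_u <- rhs_u + c(as.numeric(ctx$M1 %*% F[, 1]),
                       as.numeric(ctx$M1 %*% F[, 2]))
    # consistent (PSPG) stabilization: keep the body force in the perturbed
    # continuity residual so that hydrostatic balance is exact
    tri <- fp$tri
    Fxe <- (F[tri[, 1], 1] + F[tri[, 2], 1] + F[tri[, 3], 1]) / 3
    Fye <- (F[tri[, 1], 2] + F[tri[, 2], 2] + F[tri[, 3], 2]) / 3
    for (i in 1:3)
      rhs_p <- rhs_p + tabulate_add(n, tri[, i],
                                    ctx$tauA * (fp$b[, i] * Fxe +
                                                fp$c[, i] * Fye))
  }
  Z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, n))
  A <- rbind(cbind(A11, Z, ctx$Dx),
             cbind(Z, A11, ctx$Dy),
             cbind(ctx$Dx, ctx$Dy, ctx$S))
  b <- c(rhs_u, rhs_p)
  A <- ctx$Dmask %*% A + ctx$Ddir
  b <- b * (Matrix::diag(ctx$Dmask)); b[ctx$dir_rows] <- ctx$dir_vals
  sol <- as.numeric(Matrix::solve(A, b))
  list(u = cbind(sol[1:n], sol[n + 1:n]), p = sol[2L * n + 1:n])
}

# temperature system matrix for a given advecting field (NULL dt = steady)
.temp_matrix <- function(ctx, u, dt = NULL) {
  C <- fem_advection(ctx$fp, u[, 1], u[, 2], ctx$fluid$rho * ctx$fluid$cp)
  A <- ctx$Kt + C
  if (!is.null(dt)) A <- A + ctx$Mcp / dt
  ctx$DmaskT %*% A + ctx$DdirT
}

.temp_rhs <- function(ctx, load) {
  b <- load
  b[ctx$tdir_nodes] <- 0
  b[ctx$tdir_nodes] <- ctx$tdirvec[ctx$tdir_nodes]
  b
}

# auxiliary heat terms (off by default): viscous dissipation and pressure work
.aux_heat_load <- function(ctx, u, p) {
  fp <- ctx$fp; load <- numeric(ctx$n)
  tri <- fp$tri
  if (ctx$config$qvd) {
    dux_dx <- fem_divergence(fp, u[, 1], numeric(ctx$n) + 0 * u[, 1])
    # full velocity-gradient tensor per element
    gx <- function(v) rowSums(fp$b * cbind(v[tri[, 1]], v[tri[, 2]], v[tri[, 3]]))
    gy <- function(v) rowSums(fp$c * cbind(v[tri[, 1]], v[tri[, 2]], v[tri[, 3]]))
    e11 <- gx(u[, 1]); e22 <- gy(u[, 2])
    e12 <- 0.5 * (gy(u[, 1]) + gx(u[, 2]))
    phi <- 2 * ctx$fluid$mu * (e11^2 + e22^2 + 2 * e12^2)
    contrib <- phi * fp$A / 3
    for (i in 1:3) load <- load + tabulate_add(ctx$n, tri[, i], contrib)
  }
  if (ctx$config$qp) {
    gx <- function(v) rowSums(fp$b * cbind(v[tri[, 1]], v[tri[, 2]], v[tri[, 3]]))
    gy <- function(v) rowSums(fp$c * cbind(v[tri[, 1]], v[tri[, 2]], v[tri[, 3]]))
    ue <- (u[tri[, 1], 1] + u[tri[, 2], 1] + u[tri[, 3], 1]) / 3
    ve <- (u[tri[, 1], 2] + u[tri[, 2], 2] + u[tri[, 3], 2]) / 3
    wp <- ue * gx(p) + ve * gy(p)
    contrib <- wp * fp$A / 3
    for (i in 1:3) load <- load + tabulate_add(ctx$n, tri[, i], contrib)
  }
  load
}

tabulate_add <- function(n, idx, val) {
  out <- numeric(n)
  t <- tapply(val, idx, sum)
  out[as.integer(names(t))] <- t
  out
}

#' Stationary coupled flow/temperature solution
#'
#' Computes the natural-convection baseline: the steady solution of the
#' coupled momentum (with Brinkman drag in the porous trabecular meshwork),
#' continuity and heat-transport equations under the Boussinesq body force,
#' by damped Picard iteration to the configured relative tolerance.  Fluids
#' above the viscosity threshold (the viscoelastic) are solved in
#' conduction-only mode with a quiescent velocity field.
#'
#' @param mesh an `ac_mesh` from [generate_mesh()] or [rectangle_mesh()].
#' @param fluid a [fluid_properties()] object (or preset name).
#' @param porous [porous_properties()] of the trabecular meshwork.
#' @param bc [boundary_conditions()].
#' @param config [solver_config()].
#' @return object of class `field_state`: nodal `u` (m/s), `p` (Pa),
#'   `T` (C), plus the solver context for restarts.
#' @export
solve_steady <- function(mesh, fluid = "AH", porous = get_porous(),
                         bc = boundary_conditions(),
                         config = solver_config()) {
  if (is.character(fluid)) fluid <- get_fluid(fluid)
  ctx <- .solver_ctx(mesh, fluid, porous, bc, config)
  n <- ctx$n
  u <- matrix(0, n, 2)
  A0 <- .temp_matrix(ctx, u)
  temp <- as.numeric(Matrix::solve(A0, .temp_rhs(ctx, numeric(n))))
  if (ctx$conduction_only) {
    st <- structure(list(u = u, p = numeric(n), T = temp, mesh = mesh,
                         fluid = fluid, porous = porous, bc = bc,
                         config = config, ctx = ctx,
                         converged = TRUE, iterations = 0L,
                         residual_history = numeric(0)),
                    class = "field_state")
    return(st)
  }
  relax <- config$picard_relax
  hist <- numeric(0)
  trange <- max(abs(diff(range(temp))), 1)
  converged <- FALSE
  for (it in seq_len(config$max_picard)) {
    fs <- .flow_solve(ctx, u, temp)
    u_new <- fs$u
    uscale <- max(max(abs(u_new)), 1e-12)
    du <- max(abs(u_new - u)) / uscale
    u <- relax * u_new + (1 - relax) * u
    At <- .temp_matrix(ctx, u)
    t_new <- as.numeric(Matrix::solve(At, .temp_rhs(ctx, numeric(n))))
    dT <- max(abs(t_new - temp)) / trange
    temp <- relax * t_new + (1 - relax) * temp
    hist <- c(hist, max(du, dT))
    if (max(du, dT) < config$steady_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    # pseudo-transient fallback: march the coupled system to steadiness
    dtp <- 0.25
    for (it in seq_len(200L)) {
      fs <- .flow_solve(ctx, u, temp, dt = dtp, u_prev = u)
      du <- max(abs(fs$u - u)) / max(max(abs(fs$u)), 1e-12)
      u <- fs$u
      At <- .temp_matrix(ctx, u, dt = dtp)
      rhs <- .temp_rhs(ctx, as.numeric(ctx$Mcp %*% temp) / dtp)
      t_new <- as.numeric(Matrix::solve(At, rhs))
      dT <- max(abs(t_new - temp)) / trange
      temp <- t_new
      hist <- c(hist, max(du, dT))
      if (max(du, dT) < config$steady_tol * dtp) { converged <- TRUE; break }
    }
  }
  if (!converged)
    stop("steady solver did not converge; residual history: ",
         paste(signif(utils::tail(hist, 8), 3), collapse = ", "))
  fs <- .flow_solve(ctx, u, temp)
  structure(list(u = u, p = fs$p, T = temp, mesh = mesh, fluid = fluid,
                 porous = porous, bc = bc, config = config, ctx = ctx,
                 converged = TRUE, iterations = length(hist),
                 residual_history = hist),
            class = "field_state")
}

#' Transient simulation of the heat impulse
#'
#' Starting from a converged steady state, advances the coupled system with
#' implicit-Euler steps of `dt`: the momentum system is refreshed every
#' `flow_stride` steps (Picard linearization about the previous velocity,
#' buoyancy from the current temperature), the heat equation every step.
#' The tip impulse is applied as a line source on the immersed tip edges
#' for the first `duration` seconds.
#'
#' @param initial a converged [solve_steady()] state.
#' @param source a [heat_source()].
#' @param config optional [solver_config()] override (defaults to the one
#'   of the steady solve, whose `t_end` governs the horizon).
#' @return object of class `field_series`: probe traces at every step,
#'   strided full fields, and run metadata.
#' @export
run_transient <- function(initial, source, config = NULL) {
  stopifnot(inherits(initial, "field_state"), inherits(source, "heat_source"))
  ctx <- initial$ctx
  if (!is.null(config)) {
    ctx$config <- config
  }
  cfg <- ctx$config
  if (cfg$t_end < source$duration)
    stop("t_end must be at least the impulse duration")
  dt <- cfg$dt
  nt <- as.integer(round(cfg$t_end / dt))
  store_every <- max(1L, as.integer(round(cfg$store_dt / dt)))
  n <- ctx$n
  mesh <- ctx$mesh

  probes <- if (!is.null(mesh$geom)) locate_probes(mesh$geom) else
    data.frame(name = character(0), x = numeric(0), y = numeric(0))
  pw <- if (nrow(probes)) interp_weights(mesh, probes) else list()
  probe_val <- function(vec) vapply(pw, function(w) sum(vec[w$nodes] * w$w), 0)

  inodes <- interior_nodes(mesh)
  u <- initial$u; temp <- initial$T; p <- initial$p
  LU <- NULL
  flux_scale <- ctx$tip_load                       # per-node line-source load
  trace <- matrix(NA_real_, nt, nrow(probes),
                  dimnames = list(NULL, probes$name))
  times <- dt * seq_len(nt)
  ns <- length(seq(store_every, nt, by = store_every)) + 1L
  stored_T <- matrix(NA_real_, n, ns)
  stored_u <- vector("list", ns)
  stored_times <- numeric(ns)
  stored_T[, 1] <- temp; stored_u[[1]] <- u; stored_times[1] <- 0
  si <- 1L
  vel_stats <- list()
  impulse_steps <- ceiling(source$duration / dt - 1e-9)

  for (k in seq_len(nt)) {
    t_mid <- (k - 0.5) * dt
    new_block <- ((k - 1L) %% cfg$flow_stride == 0L) ||
      (k == impulse_steps + 1L)
    if (new_block) {
      if (!ctx$conduction_only) {
        fs <- .flow_solve(ctx, u, temp, dt = cfg$flow_stride * dt, u_prev = u)
        u <- fs$u; p <- fs$p
      }
      LU <- Matrix::lu(.temp_matrix(ctx, u, dt = dt))
      spd <- sqrt(rowSums(u^2)) * 1e3            # mm/s
      vel_stats[[length(vel_stats) + 1L]] <-
        c(time = k * dt, max_speed = max(spd),
          max_speed_interior = max(spd[inodes]))
    }
    q <- apply_heat_flux_bc(source, t_mid)
    load <- as.numeric(ctx$Mcp %*% temp) / dt + q * flux_scale
    if (cfg$qvd || cfg$qp) load <- load + .aux_heat_load(ctx, u, p)
    temp <- as.numeric(Matrix::solve(LU, .temp_rhs(ctx, load)))
    if (nrow(probes)) trace[k, ] <- probe_val(temp)
    if (k %% store_every == 0L) {
      si <- si + 1L
      stored_T[, si] <- temp; stored_u[[si]] <- u; stored_times[si] <- k * dt
    }
  }
  vs <- as.data.frame(do.call(rbind, vel_stats))
  structure(list(mesh = mesh, fluid = initial$fluid, source = source,
                 config = cfg, steady = initial,
                 times = times, probe_traces = trace, probes = probes,
                 stored_times = stored_times[seq_len(si)],
                 stored_T = stored_T[, seq_len(si), drop = FALSE],
                 stored_u = stored_u[seq_len(si)],
                 vel_stats = vs, interior = inodes),
            class = "field_series")
}

#' Steady-state energy budget
#'
#' Boundary-integrated conductive fluxes (consistent nodal residuals at the
#' Dirichlet nodes) and the net advective transport, per boundary tag.  At a
#' converged steady state the total must balance to a small fraction of the
#' largest single flux.
#'
#' @param state a [solve_steady()] result.
#' @return list with per-tag conductive fluxes (W per metre of out-of-plane
#'   depth), the advective net, and the relative imbalance.
#' @export
energy_budget <- function(state) {
  ctx <- state$ctx
  Rcond <- as.numeric(ctx$Kt %*% state$T)
  Cadv <- fem_advection(ctx$fp, state$u[, 1], state$u[, 2],
                        ctx$fluid$rho * ctx$fluid$cp)
  Radv <- as.numeric(Cadv %*% state$T)
  tags <- unique(ctx$mesh$boundary$tag)
  cond <- stats::setNames(numeric(length(tags)), tags)
  for (tg in tags) cond[tg] <- sum(Rcond[boundary_nodes(ctx$mesh, tg)])
  total <- sum(Rcond) + sum(Radv)
  scale <- max(abs(cond), abs(sum(Radv)), 1e-12)
  list(conductive = cond, advective_net = sum(Radv),
       imbalance = total, relative_imbalance = abs(total) / scale)
}

#' @export
print.field_state <- function(x, ...) {
  cat("<field_state> ", length(x$T), " nodes; T in [",
      format(min(x$T), digits = 4), ", ", format(max(x$T), digits = 4),
      "] C; max |u| ", format(max(sqrt(rowSums(x$u^2))) * 1e3, digits = 3),
      " mm/s; ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' @export
print.field_series <- function(x, ...) {
  cat("<field_series> ", x$fluid$mu, " Pa s fluid, ",
      x$source$total_power, " W impulse, t_end ", x$config$t_end, " s, ",
      length(x$times), " steps, ", length(x$stored_times),
      " stored fields\n", sep = "")
  invisible(x)
}
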