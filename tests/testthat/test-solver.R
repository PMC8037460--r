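test_that("Boussinesq body force follows the linear law", {
  ah <- get_fluid("AH")
  # arithmetic oracle: 998 * 3e-4 * 9.81 * 1 K = 2.937114 N/m^3
  f <- boussinesq_body_force(35.5, ah, t_ref = 36.5, gravity = c(0, -9.81))
  expect_equal(sqrt(sum(f^2)), 2.937114, tolerance = 1e-6)
  expect_lt(f[2], 0)                      # deficit w.r.t. reference sinks
  # zero at the reference temperature, exact sign flip
  expect_equal(boussinesq_body_force(36.5, ah, 36.5)[1, ], c(0, 0))
  expect_equal(boussinesq_body_force(37.5, ah, 36.5),
               -boussinesq_body_force(35.5, ah, 36.5))
})

test_that("tip heat flux follows P/(L*d_eff) and the impulse window", {
  # spec arithmetic with the flat-projection width d_eff = 2.2 mm
  s22 <- heat_source(1.2, d_eff = 2.2)
  expect_equal(apply_heat_flux_bc(s22, 2), 1.2 / (2.2e-3 * 2.2e-3),
               tolerance = 1e-12)
  # package default: cylindrical tip surface, d_eff = pi * 2.2 mm
  s <- heat_source(1.2)
  expect_equal(apply_heat_flux_bc(s, 2), 1.2 / (2.2e-3 * pi * 2.2e-3),
               tolerance = 1e-12)
  expect_identical(apply_heat_flux_bc(s, 6), 0)     # after the 5-s impulse
  expect_identical(apply_heat_flux_bc(heat_source(0), 1), 0)
  expect_error(heat_source(-1), "non-negative")
})

test_that("no thermal gradient means no flow", {
  m <- rectangle_mesh(1, 3.2, 4, 24)
  bc <- boundary_conditions(
    dirichlet_temp = c(bottom = 30, top = 30, left = 30, right = 30),
    inlet_tags = character(0), outlet_tags = character(0))
  st <- solve_steady(m, "AH", bc = bc, config = solver_config())
  expect_lt(max(abs(st$u)), 1e-9)
  expect_lt(diff(range(st$T)), 1e-9)
})

test_that("pure conduction matches the 1-D closed-form profile within 2%", {
  m <- rectangle_mesh(1, 3.2, 4, 32)
  bc <- boundary_conditions(dirichlet_temp = c(bottom = 36.5, top = 27),
                            inlet_tags = character(0),
                            outlet_tags = character(0))
  st <- solve_steady(m, "AH", bc = bc, config = solver_config(buoyancy = FALSE))
  Texact <- 36.5 + (27 - 36.5) * m$nodes[, 2] / 3.2
  expect_lt(max(abs(st$T - Texact)) / 9.5, 0.02)
  expect_lt(max(abs(st$u)), 1e-9)
})

test_that("chamber baseline respects the maximum principle and symmetry", {
  st <- pt_steady("AH")
  expect_gte(min(st$T), 27 - 1e-6)
  expect_lte(max(st$T), 36.5 + 0.1)       # Galerkin tolerance
  m <- st$mesh
  key <- paste(round(m$nodes[, 1], 9), round(m$nodes[, 2], 9))
  mir <- match(paste(round(-m$nodes[, 1], 9), round(m$nodes[, 2], 9)), key)
  expect_false(anyNA(mir))
  expect_lt(max(abs(st$T - st$T[mir])), 0.05)
  # mirror antisymmetry of u_x, symmetry of u_y
  expect_lt(max(abs(st$u[, 1] + st$u[mir, 1])), 1e-5 + 0.05 * max(abs(st$u)))
  expect_lt(max(abs(st$u[, 2] - st$u[mir, 2])), 1e-5 + 0.05 * max(abs(st$u)))
})

test_that("baseline flow is divergence-free and mass-conserving", {
  st <- pt_steady("AH")
  fp <- fem_precompute(st$mesh)
  dv <- fem_divergence(fp, st$u[, 1], st$u[, 2])
  gx <- function(v) rowSums(fp$b * matrix(v[fp$tri], ncol = 3))
  gy <- function(v) rowSums(fp$c * matrix(v[fp$tri], ncol = 3))
  gradnorm <- sqrt(sum(fp$A * (gx(st$u[, 1])^2 + gy(st$u[, 1])^2 +
                               gx(st$u[, 2])^2 + gy(st$u[, 2])^2)))
  expect_lt(sqrt(sum(fp$A * dv^2)) / gradnorm, 0.1)
  # net inflow equals net outflow within 0.1% (edge flux integrals)
  b <- st$mesh$boundary
  flux <- function(tags, comp, sgn) {
    e <- b[b$tag %in% tags, ]
    sum(sgn * (st$u[e$n1, comp] + st$u[e$n2, comp]) / 2 * e$length * 1e-3)
  }
  qin <- flux(c("inlet_left", "inlet_right"), 2, +1)       # upward inflow
  qout <- flux("sc_outlet_right", 1, +1) + flux("sc_outlet_left", 1, -1)
  expect_equal(qout, qin, tolerance = 1e-3)
  # and the rate matches the configured 2.4 uL/min over d_eff = 2.2 mm
  q_expect <- uL_min_to_m3_s(2.4) / 2.2e-3
  expect_equal(qin, q_expect, tolerance = 0.01)
})

test_that("steady-state energy budget balances below 1%", {
  eb <- energy_budget(pt_steady("AH"))
  expect_lt(eb$relative_imbalance, 0.01)
  # heat enters through the warm walls and leaves through the cornea
  expect_lt(eb$conductive[["cornea"]], 0)
  expect_gt(eb$conductive[["iris"]], 0)
})

test_that("zero-power transient preserves the steady state", {
  m <- pt_mesh()
  st <- pt_steady("AH")
  ser <- run_transient(st, heat_source(0, tip_length = sum(m$tip_edges$length)),
                       config = solver_config(t_end = 5))
  expect_lt(max(abs(ser$stored_T - st$T)), 0.05)
})

test_that("impulse heats monotonically at the probe, then decays", {
  ser <- pt_ah12()
  tr <- point_probe(ser)
  during <- tr$values[tr$times <= 5]
  # rising phase: the end-of-impulse value dominates the first second
  expect_gt(during[250], during[50])
  expect_gt(during[50], during[1])
  # decay after the impulse
  expect_lt(tr$values[length(tr$values)], max(during))
  expect_lt(tr$values[length(tr$values)] - tr$reference, 1)
})

test_that("relaxation to the baseline lands in the reported 10-25 s window", {
  ser <- pt_ah12()
  rp <- relaxation_time(ser, criterion = "probe")
  rf <- relaxation_time(ser, criterion = "field")
  expect_gte(rp, 5); expect_lte(rp, 25)
  expect_gte(rf, 5); expect_lte(rf, 25)
})

test_that("the Brinkman block recovers bulk flow as kappa grows", {
  # buoyant cavity with a nominal porous band; at eps_p = 1 and huge kappa
  # the porous elements must behave as ordinary fluid
  bc <- boundary_conditions(
    dirichlet_temp = c(bottom = 36.5, top = 27, left = 32, right = 32),
    inlet_tags = character(0), outlet_tags = character(0))
  m1 <- rectangle_mesh(2, 1, 20, 10)
  m2 <- rectangle_mesh(2, 1, 20, 10, porous_x = c(0.8, 1.2))
  cfg <- solver_config()
  st1 <- solve_steady(m1, "AH", bc = bc, config = cfg)
  st2 <- solve_steady(m2, "AH", porous = porous_properties(eps_p = 1,
                                                           kappa = 1e6),
                      bc = bc, config = cfg)
  expect_gt(max(abs(st1$u)), 1e-6)   # the cavity actually convects
  expect_lt(max(abs(st1$u - st2$u)) / max(abs(st1$u)), 0.01)
  # and a tight porous band throttles the flow inside it
  st3 <- solve_steady(m2, "AH", porous = get_porous(), bc = bc, config = cfg)
  inband <- unique(as.vector(m2$tri[m2$subdomain == "porous", ]))
  expect_lt(max(abs(st3$u[inband, ])), 0.01 * max(abs(st3$u)))
})
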