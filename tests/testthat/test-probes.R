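# small synthetic series on a rectangle for the post-processing oracles
.mk_series <- function() {
  m <- rectangle_mesh(2, 1, 4, 2)
  n <- nrow(m$nodes)
  Tlin <- 2 * m$nodes[, 1] + 3 * m$nodes[, 2] + 30
  u0 <- cbind(rep(0, n), rep(0, n))
  times <- seq(0, 3, by = 0.5)
  stored_T <- matrix(rep(Tlin, length(times)), n)
  stored_u <- rep(list(u0), length(times))
  pt_synthetic_series(m, stored_T, stored_u, times, Tlin, u0)
}

test_that("sample_point interpolates stored fields exactly", {
  s <- .mk_series()
  m <- s$mesh
  # constant-in-time series: constant trace
  tr <- sample_point(s, c(0.7, 0.4))
  expect_equal(diff(range(tr$values)), 0)
  # node-coincident point equals nodal values
  tr2 <- sample_point(s, m$nodes[5, ])
  expect_equal(unname(tr2$values[1]), unname(s$stored_T[5, 1]))
  # mid-edge point on a linear field: mean of the endpoints
  p <- (m$nodes[1, ] + m$nodes[2, ]) / 2
  tr3 <- sample_point(s, p)
  expect_equal(unname(tr3$values[1]),
               (s$stored_T[1, 1] + s$stored_T[2, 1]) / 2)
  expect_error(sample_point(s, c(10, 10)), "outside")
})

test_that("trace extrema and rises", {
  tr <- structure(list(name = "x", times = c(0, 1, 2),
                       values = c(36.5, 40, 38), reference = 36.5),
                  class = "probe_trace")
  ex <- trace_extrema(tr)
  expect_equal(ex$max_rise, 3.5)
  expect_equal(ex$time_of_max, 1)
  # monotone trace peaks at the final time
  tr$values <- c(1, 2, 3)
  expect_equal(trace_extrema(tr)$time_of_max, 2)
})

test_that("relaxation time: identity, closed-form decay, monotonicity", {
  s <- .mk_series()
  expect_equal(relaxation_time(s, criterion = "field"), 0)
  # uniform exponential decay T = Tref + A exp(-t/tau):
  # crossing of |T - Tref| = tol at t = tau*log(A/tol)
  m <- s$mesh; n <- nrow(m$nodes)
  A <- 4; tau <- 2; tol <- 0.5
  times <- seq(0, 12, by = 0.1)
  dec <- vapply(times, function(t) A * exp(-t / tau), 0)
  stored_T <- outer(rep(1, n), dec) + 30
  sd2 <- pt_synthetic_series(m, stored_T, rep(list(s$steady$u), length(times)),
                             times, rep(30, n), s$steady$u)
  t_hat <- relaxation_time(sd2, tol_T = tol, criterion = "field")
  expect_lt(abs(t_hat - tau * log(A / tol)), 0.1 + 1e-9)
  # monotone non-increasing in tol_T
  tols <- c(0.2, 0.5, 1, 2)
  rts <- vapply(tols, function(tl)
    relaxation_time(sd2, tol_T = tl, criterion = "field"), 0)
  expect_true(all(diff(rts) <= 1e-12))
  # never-relaxing series: NA marker
  sd3 <- pt_synthetic_series(m, stored_T + 100,
                             rep(list(s$steady$u), length(times)),
                             times, rep(30, n), s$steady$u)
  expect_true(is.na(relaxation_time(sd3, criterion = "field")))
})

test_that("velocity range: zero field and rigid rotation", {
  s <- .mk_series()
  vr <- velocity_range(s)
  expect_equal(unname(vr), c(0, 0))
  # rigid rotation about the rectangle centre: max speed = omega * r_max
  m <- s$mesh
  ctr <- c(1, 0.5); omega <- 2
  u <- cbind(-omega * (m$nodes[, 2] - ctr[2]),
             omega * (m$nodes[, 1] - ctr[1])) * 1e-3   # mm -> m/s
  s$stored_u <- rep(list(u), length(s$stored_times))
  r_max <- max(sqrt((m$nodes[, 1] - ctr[1])^2 + (m$nodes[, 2] - ctr[2])^2))
  expect_equal(unname(velocity_range(s)["max"]), omega * r_max,
               tolerance = 1e-9)
  expect_error(velocity_range(s, c(100, 200)), "empty window")
})
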