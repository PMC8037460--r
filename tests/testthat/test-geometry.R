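test_that("default geometry reproduces the model dimensions", {
  g <- build_ac_geometry(geometry_params())
  # corneal arc: circle through (+-5, 0) with apex (0, 3.2)
  R <- g$arc$R; cy <- g$arc$cy
  expect_equal(cy + sqrt(R^2 - 25), 0, tolerance = 1e-12)
  expect_equal(cy + R, 3.2, tolerance = 1e-12)
  expect_true(any(abs(g$vertices[, 1]) < 1e-12 &
                    abs(g$vertices[, 2] - 3.2) < 1e-12))  # apex on outline
  # pupil gap and iris thickness realized in the outline
  lens <- g$vertices[abs(g$vertices[, 2] + 0.45) < 1e-12, 1]
  expect_equal(sort(lens), c(-1.49, 1.49))
  # TM blocks: 85 um x 300 um each side
  for (r in g$tm_rects) {
    expect_equal(r[2] - r[1], 0.085, tolerance = 1e-12)
    expect_equal(r[4] - r[3], 0.3, tolerance = 1e-12)
  }
  expect_equal(diff(g$y_sc), 0.163, tolerance = 1e-12)
})

test_that("parameter invariants are enforced with the field named", {
  expect_error(geometry_params(pupil_length = 10), "pupil_length")
  expect_error(geometry_params(ac_depth = -1), "ac_depth")
  expect_error(geometry_params(probe_offset_above_lens = 4),
               "probe_offset_above_lens")
  expect_error(geometry_params(iris_thickness = 0.2),
               "probe_offset_above_lens")
  expect_error(geometry_params(sc_length = 400), "sc_length")
})

test_that("outline area matches an independent shoelace computation", {
  g <- build_ac_geometry(geometry_params())
  v <- g$vertices
  # independent oracle: cross-product accumulation around the polygon
  n <- nrow(v); acc <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    acc <- acc + (v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2])
  }
  expect_equal(geometry_area(g), unname(acc / 2), tolerance = 1e-10)
  expect_gt(geometry_area(g), 0)
})

test_that("outline is mirror symmetric with mirrored boundary tags", {
  g <- build_ac_geometry(geometry_params())
  v <- g$vertices; tg <- g$edge_tags
  n <- nrow(v)
  mirror_tag <- function(t)
    ifelse(grepl("_left$", t), sub("_left$", "_right", t),
           sub("_right$", "_left", t))
  key <- function(x1, y1, x2, y2, t)
    paste(round(sort(c(x1, x2)), 9)[1], round(sort(c(x1, x2)), 9)[2],
          round(y1 + y2, 9), t)
  e1 <- character(n); e2 <- character(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e1[i] <- key(v[i, 1], v[i, 2], v[j, 1], v[j, 2], tg[i])
    e2[i] <- key(-v[i, 1], v[i, 2], -v[j, 1], v[j, 2], mirror_tag(tg[i]))
  }
  expect_setequal(e1, e2)
})

test_that("probe points are located on the axis, inside the domain", {
  g <- build_ac_geometry(geometry_params())
  pr <- locate_probes(g)
  ec <- pr[pr$name == "endothelium_center", ]
  # oracle: apex minus the stated depth along the symmetry axis
  expect_equal(ec$x, 0)
  expect_equal(ec$y, 3.2 - 0.6)
  expect_true(all(vapply(seq_len(nrow(pr)), function(i)
    point_in_geometry(g, pr$x[i], pr$y[i]), TRUE)))
  tip <- pr[pr$name == "probe_tip_center", ]
  expect_equal(tip$y, -0.45 + 0.25)
  g2 <- build_ac_geometry(geometry_params())
  g2$params$point_probe_depth_below_cornea <- 5
  expect_error(locate_probes(g2), "outside the domain|exceeds")
})
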