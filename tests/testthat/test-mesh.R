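test_that("reference mesh hits the element target and is valid", {
  m <- pt_mesh()
  expect_gte(nrow(m$tri), 3736)   # 4981 - 25%
  expect_lte(nrow(m$tri), 6226)   # 4981 + 25%
  # orientation and validity: recompute signed areas independently
  P <- m$nodes; tri <- m$tri
  a2 <- (P[tri[, 2], 1] - P[tri[, 1], 1]) * (P[tri[, 3], 2] - P[tri[, 1], 2]) -
        (P[tri[, 3], 1] - P[tri[, 1], 1]) * (P[tri[, 2], 2] - P[tri[, 1], 2])
  expect_true(all(a2 > 0))
  expect_equal(m$area, a2 / 2, tolerance = 1e-12)
})

test_that("meshed area equals the outline area to 1e-8 relative", {
  m <- pt_mesh()
  expect_equal(sum(m$area), geometry_area(m$geom), tolerance = 1e-8)
})

test_that("porous elements exactly tile the two TM blocks", {
  m <- pt_mesh()
  ap <- sum(m$area[m$subdomain == "porous"])
  expect_equal(ap, 2 * 0.085 * 0.3, tolerance = 0.01)
  # porous centroids all inside the TM rectangles
  P <- m$nodes; tri <- m$tri[m$subdomain == "porous", , drop = FALSE]
  cx <- abs(rowMeans(matrix(P[tri, 1], ncol = 3)))
  cy <- rowMeans(matrix(P[tri, 2], ncol = 3))
  expect_true(all(cx > m$geom$x_rim & cx < m$geom$x_out))
  expect_true(all(cy > 0 & cy < m$geom$y_tm))
})

test_that("boundary edges carry exactly one tag and features are exact", {
  m <- pt_mesh()
  expect_false(any(is.na(m$boundary$tag)))
  len_by_tag <- tapply(m$boundary$length, m$boundary$tag, sum)
  expect_equal(unname(len_by_tag["inlet_left"]), 0.020, tolerance = 1e-9)
  expect_equal(unname(len_by_tag["inlet_right"]), 0.020, tolerance = 1e-9)
  expect_equal(unname(len_by_tag["sc_outlet_left"]), 0.163, tolerance = 1e-9)
  expect_equal(unname(len_by_tag["sc_outlet_right"]), 0.163, tolerance = 1e-9)
  expect_equal(unname(len_by_tag["lens"]), 2.98, tolerance = 1e-9)
  # immersed heated segment spans the full 2.2 mm tip
  expect_equal(sum(m$tip_edges$length), 2.2, tolerance = 1e-9)
  # cornea edges lie on the outline polygon
  arc <- m$geom$arc
  ce <- m$boundary[m$boundary$tag == "cornea", ]
  yexp <- approx(arc$x, arc$y, xout = ce$mx)$y
  expect_equal(ce$my, yexp, tolerance = 1e-9)
})

test_that("element doubling leaves the domain area representation fixed", {
  g <- build_ac_geometry(geometry_params())
  a1 <- sum(generate_mesh(g, 4981)$area)
  a2 <- sum(generate_mesh(g, 9962)$area)
  expect_lt(abs(a2 - a1) / a1, 1e-6)
})

test_that("mesh is mirror symmetric about the pupil axis", {
  m <- pt_mesh()
  key <- paste(round(m$nodes[, 1], 9), round(m$nodes[, 2], 9))
  mkey <- paste(round(-m$nodes[, 1], 9), round(m$nodes[, 2], 9))
  expect_true(all(mkey %in% key))
})

test_that("unreachable targets raise a meshing error", {
  g <- build_ac_geometry(geometry_params())
  expect_error(generate_mesh(g, 100), "meshing error")
  expect_error(generate_mesh(g, 50), "target_elements")
})
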