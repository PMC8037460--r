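#' Geometry parameters of the anterior-chamber cross-section
#'
#' All lengths describing the 2-D model domain.  Linear dimensions are in
#' millimetres except for the outflow-pathway features (`tm_length`,
#' `tm_width`, `sc_length`, `inlet_length`), which are in micrometres.
#' Defaults are the dimensions of the modeled eye: chamber chord 10 mm,
#' depth 3.2 mm, pupil 2.98 mm, iris thickness 0.45 mm, trabecular meshwork
#' 85 um x 300 um, Schlemm's canal outlet 163 um, inlets 20 um, probe tip
#' diameter 2.2 mm placed 0.25 mm above the lens, and a reference point probe
#' 0.6 mm below the corneal apex.
#'
#' @param ac_length chamber chord length, mm.
#' @param ac_depth chamber sagittal depth at the apex, mm.
#' @param pupil_length pupil opening, mm; must be smaller than `ac_length`.
#' @param iris_thickness iris thickness (depth of the lens recess), mm.
#' @param tm_length trabecular-meshwork flow-path length, um.
#' @param tm_width trabecular-meshwork extent along the rim, um.
#' @param sc_length Schlemm's-canal outlet length on the outer face, um.
#' @param inlet_length length of each pupil-border inlet segment, um.
#' @param probe_tip_diameter phaco-tip diameter (heated segment length), mm.
#' @param probe_offset_above_lens tip height above the lens surface, mm; must
#'   be below both `ac_depth` and `iris_thickness` (the tip sits in the
#'   pupillary recess).
#' @param point_probe_depth_below_cornea depth of the reference point probe
#'   below the corneal apex, mm.
#' @return A validated list of class `geometry_params`.
#' @export
geometry_params <- function(ac_length = 10, ac_depth = 3.2,
                            pupil_length = 2.98, iris_thickness = 0.45,
                            tm_length = 85, tm_width = 300, sc_length = 163,
                            inlet_length = 20, probe_tip_diameter = 2.2,
                            probe_offset_above_lens = 0.25,
                            point_probe_depth_below_cornea = 0.6) {
  p <- list(ac_length = ac_length, ac_depth = ac_depth,
            pupil_length = pupil_length, iris_thickness = iris_thickness,
            tm_length = tm_length, tm_width = tm_width, sc_length = sc_length,
            inlet_length = inlet_length,
            probe_tip_diameter = probe_tip_diameter,
            probe_offset_above_lens = probe_offset_above_lens,
            point_probe_depth_below_cornea = point_probe_depth_below_cornea)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("geometry parameter '", nm, "' must be a single positive number")
  }
  if (p$pupil_length >= p$ac_length)
    stop("geometry parameter 'pupil_length' must be smaller than 'ac_length'")
  if (p$probe_offset_above_lens >= p$ac_depth)
    stop("geometry parameter 'probe_offset_above_lens' must be smaller than 'ac_depth'")
  if (p$probe_offset_above_lens >= p$iris_thickness)
    stop("geometry parameter 'probe_offset_above_lens' must be smaller than ",
         "'iris_thickness' (the heated tip segment lies in the lens recess)")
  if (p$probe_tip_diameter >= p$pupil_length)
    stop("geometry parameter 'probe_tip_diameter' must be smaller than 'pupil_length'")
  if (p$sc_length * 1e-3 >= p$tm_width * 1e-3)
    stop("geometry parameter 'sc_length' must be smaller than 'tm_width'")
  class(p) <- "geometry_params"
  p
}

# circular-arc helper: circle through (+-L/2, 0) with apex (0, D)
.arc_circle <- function(L, D) {
  R <- ((L / 2)^2 + D^2) / (2 * D)
  list(R = R, cy = D - R)
}

#' Build the anterior-chamber domain geometry
#'
#' Constructs the closed planar outline of the model chamber: a circular
#' corneal arc (chord `ac_length`, sagittal depth `ac_depth`), a flat iris
#' floor with a lens recess of depth `iris_thickness` spanning the pupil,
#' and, at each rim, a rectangular trabecular-meshwork (TM) porous block
#' with a Schlemm's-canal (SC) pressure outlet centred on its outer face.
#' The lower tips of the corneal arc are truncated at the TM height
#' (`tm_width`) where the outflow blocks attach, so that the porous flow
#' path runs horizontally through the iridocorneal angle.  Aqueous inlets
#' are two `inlet_length` segments of the iris floor bordering the pupil.
#' The heated phaco-tip segment is an immersed horizontal segment of length
#' `probe_tip_diameter` centred on the axis, `probe_offset_above_lens` above
#' the lens surface.
#'
#' The corneal arc is discretised once, at geometry-build time, into
#' `n_arc` chords; the mesh generator later places its boundary nodes on
#' this fixed polygon, so that meshed area and outline area agree exactly
#' at any refinement level.
#'
#' @param params a [geometry_params()] object.
#' @param n_arc even number of chords used to discretise the corneal arc.
#' @return An object of class `ac_geometry` with the outline polygon
#'   (`vertices`, `edge_tags`), TM rectangles, inlet/outlet segments, the
#'   tip segment, the analytic arc, and named probe points.
#' @examples
#' geom <- build_ac_geometry(geometry_params())
#' geometry_area(geom)
#' @export
build_ac_geometry <- function(params = geometry_params(), n_arc = 128) {
  if (!inherits(params, "geometry_params")) params <- do.call(geometry_params, params)
  stopifnot(n_arc >= 8, n_arc %% 2 == 0)
  L <- params$ac_length; D <- params$ac_depth
  pl <- params$pupil_length / 2
  it <- params$iris_thickness
  tmL <- params$tm_length * 1e-3
  tmW <- params$tm_width * 1e-3
  scL <- params$sc_length * 1e-3
  inl <- params$inlet_length * 1e-3
  circ <- .arc_circle(L, D)
  if (tmW >= D)
    stop("geometry parameter 'tm_width' must be smaller than the chamber depth")
  # rim abscissa where the arc is truncated at the TM height
  x_rim <- sqrt(circ$R^2 - (tmW - circ$cy)^2)
  if (x_rim <= pl + 2 * inl)
    stop("geometry parameter 'pupil_length' leaves no room for the iris and inlets")
  arc_y <- function(x) circ$cy + sqrt(pmax(circ$R^2 - x^2, 0))
  x_out <- x_rim + tmL
  y_sc <- c((tmW - scL) / 2, (tmW + scL) / 2)
  y_tip <- -it + params$probe_offset_above_lens
  tip_half <- params$probe_tip_diameter / 2

  # arc stations, uniform in x, mirror-symmetric, apex included
  xs_arc <- seq(-x_rim, x_rim, length.out = n_arc + 1)
  xs_arc[(n_arc / 2) + 1] <- 0

  v <- list(); tg <- character(0)
  add <- function(x, y, tag) {
    # appends vertices 2..n of a polyline whose edges all carry `tag`
    n <- length(x)
    v[[length(v) + 1L]] <<- cbind(x, y)
    tg <<- c(tg, rep(tag, n))
  }
  # counter-clockwise outline, starting at the left TM block's outer floor
  add(c(-x_out, -x_rim), c(0, 0), "wall_tm")
  add(c(-pl - inl), 0, "iris")
  add(c(-pl), 0, "inlet_left")
  add(c(-pl), -it, "pupil_wall")
  add(c(pl), -it, "lens")
  add(c(pl), 0, "pupil_wall")
  add(c(pl + inl), 0, "inlet_right")
  add(c(x_rim), 0, "iris")
  add(c(x_out), 0, "wall_tm")
  add(c(x_out), y_sc[1], "wall_tm")
  add(c(x_out), y_sc[2], "sc_outlet_right")
  add(c(x_out), tmW, "wall_tm")
  add(c(x_rim), tmW, "wall_tm")
  add(rev(xs_arc)[-1], arc_y(rev(xs_arc)[-1]), "cornea")
  add(c(-x_out), tmW, "wall_tm")
  add(c(-x_out), y_sc[2], "wall_tm")
  add(c(-x_out), y_sc[1], "sc_outlet_left")
  add(c(-x_out), 0, "wall_tm")
  verts <- do.call(rbind, v)
  # edge i joins vertex i to i+1 (cyclic); tags were recorded per target vertex,
  # shift so that tag i describes edge i
  tags <- c(tg[-1], tg[1])
  verts <- verts[-nrow(verts), , drop = FALSE]  # drop duplicated closing vertex
  tags <- tags[-length(tags)]
  colnames(verts) <- c("x", "y")

  probes <- data.frame(
    name = c("endothelium_center", "probe_tip_center", "corneal_wall_interior"),
    x = c(0, 0, 0),
    y = c(D - params$point_probe_depth_below_cornea, y_tip, D - 0.1),
    stringsAsFactors = FALSE)

  geom <- structure(list(
    params = params,
    vertices = verts, edge_tags = tags,
    arc = list(R = circ$R, cy = circ$cy, x = xs_arc, y = arc_y(xs_arc)),
    x_rim = x_rim, x_out = x_out, x_pupil = pl, x_inlet_end = pl + inl,
    y_floor = 0, y_lens = -it, y_tm = tmW, y_sc = y_sc,
    tip = list(y = y_tip, x0 = -tip_half, x1 = tip_half),
    tm_rects = list(right = c(x_rim, x_out, 0, tmW),
                    left = c(-x_out, -x_rim, 0, tmW)),
    probes = probes), class = "ac_geometry")
  geom
}

#' Polygon area of a geometry outline
#'
#' Shoelace area of the (counter-clockwise) outline polygon, in mm^2.
#'
#' @param geom an `ac_geometry` object.
#' @return area in mm^2.
#' @export
geometry_area <- function(geom) {
  stopifnot(inherits(geom, "ac_geometry"))
  x <- geom$vertices[, 1]; y <- geom$vertices[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Named probe points of the model
#'
#' Returns the three named probe points: `endothelium_center`
#' (`point_probe_depth_below_cornea` below the corneal apex on the symmetry
#' axis; the reference point probe of the simulations),
#' `probe_tip_center` (centre of the heated tip segment), and
#' `corneal_wall_interior` (an interior sampling point 0.1 mm below the
#' corneal apex, for the near-wall reading).
#'
#' @param geom an `ac_geometry` object.
#' @return data.frame with columns `name`, `x`, `y` (mm).
#' @export
locate_probes <- function(geom) {
  stopifnot(inherits(geom, "ac_geometry"))
  p <- geom$params
  if (p$point_probe_depth_below_cornea >= p$ac_depth)
    stop("point probe lies outside the domain: ",
         "'point_probe_depth_below_cornea' exceeds the chamber depth")
  pr <- geom$probes
  for (i in seq_len(nrow(pr))) {
    if (!point_in_geometry(geom, pr$x[i], pr$y[i]))
      stop("probe point '", pr$name[i], "' lies outside the domain")
  }
  pr
}

#' Test whether a point lies inside the chamber outline
#'
#' @param geom an `ac_geometry` object.
#' @param x,y point coordinates, mm.
#' @return logical.
#' @export
point_in_geometry <- function(geom, x, y) {
  vx <- geom$vertices[, 1]; vy <- geom$vertices[, 2]
  n <- length(vx); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > y) != (vy[j] > y)) {
      xint <- vx[i] + (y - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' @export
print.ac_geometry <- function(x, ...) {
  p <- x$params
  cat("<ac_geometry>\n")
  cat(sprintf("  chord %.3g mm, depth %.3g mm, pupil %.3g mm, iris %.3g mm\n",
              p$ac_length, p$ac_depth, p$pupil_length, p$iris_thickness))
  cat(sprintf("  TM %g x %g um, SC outlet %g um, inlets %g um\n",
              p$tm_length, p$tm_width, p$sc_length, p$inlet_length))
  cat(sprintf("  outline: %d vertices, area %.4f mm^2\n",
              nrow(x$vertices), geometry_area(x)))
  invisible(x)
}
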