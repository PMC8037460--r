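#' Generate a triangular mesh of the anterior-chamber geometry
#'
#' Builds a mapped, mirror-symmetric triangulation: vertical node columns are
#' placed at the fixed corneal-arc stations of the geometry outline plus the
#' feature abscissae (pupil edges, inlet ends, tip ends), each column is
#' filled with nodes from the floor (or lens recess) up to the outline, and
#' quadrilateral cells are split into triangles with mirrored diagonals.  The
#' trabecular-meshwork blocks are meshed conformingly with the rim columns,
#' one interior level is snapped to the Schlemm's-canal outlet endpoints and
#' one recess level to the heated tip segment, so that all boundary-condition
#' segments are exact unions of mesh edges.
#'
#' Because every boundary node lies on the outline polygon and every outline
#' vertex is a mesh node, the summed element area equals the outline area to
#' machine precision at any refinement level.
#'
#' @param geom an [build_ac_geometry()] geometry.  Its `n_arc` outline
#'   resolution bounds the coarsest achievable mesh.
#' @param target_elements requested number of triangles (achieved within
#'   +-25%); the reference resolution of the model is 4981.
#' @return An object of class `ac_mesh`: `nodes` (mm), `tri` (triangle
#'   connectivity, counter-clockwise), `area`, `subdomain` (`"bulk"` or
#'   `"porous"`), `boundary` (tagged boundary edges), `tip_edges` (immersed
#'   heated segment), and the generating geometry.
#' @examples
#' mesh <- generate_mesh(build_ac_geometry(geometry_params()), 4981)
#' nrow(mesh$tri)
#' @export
generate_mesh <- function(geom, target_elements = 4981) {
  stopifnot(inherits(geom, "ac_geometry"))
  if (target_elements < 100) stop("target_elements must be >= 100")
  p <- geom$params
  pl <- geom$x_pupil; inl <- geom$x_inlet_end - geom$x_pupil
  it <- p$iris_thickness
  tmW <- geom$y_tm; tmL <- geom$x_out - geom$x_rim
  tol <- 1e-9

  ## -- column abscissae ----------------------------------------------------
  mand <- c(0, geom$tip$x1, pl, geom$x_inlet_end, pl + 3 * inl)
  mand <- sort(unique(c(-mand, mand)))
  arc_x <- geom$arc$x
  near_mand <- vapply(arc_x, function(x) any(abs(x - mand) < 1e-7), logical(1))
  xs <- sort(c(arc_x[!near_mand], mand))
  xs <- xs[c(TRUE, diff(xs) > 1e-7)]
  arc_top <- function(x) stats::approx(geom$arc$x, geom$arc$y, xout = x,
                                       rule = 2)$y

  ## -- resolution selection -----------------------------------------------
  ntmx <- 2L
  count_for <- function(xs_use, ny, nr) {
    mids <- (xs_use[-1] + xs_use[-length(xs_use)]) / 2
    nseg <- length(mids)
    nrec <- sum(abs(mids) < pl - tol)
    2L * (nseg * ny + nrec * nr + 2L * ntmx * ny)
  }
  split_intervals <- function(xs_use, s) {
    if (s <= 1L) return(xs_use)
    w <- diff(xs_use)
    keep <- w > 0.5 * stats::median(w)
    out <- lapply(seq_along(w), function(i) {
      if (keep[i]) seq(xs_use[i], xs_use[i + 1], length.out = s + 1L)[-(s + 1L)]
      else xs_use[i]
    })
    c(unlist(out), xs_use[length(xs_use)])
  }
  Hbar <- mean(arc_top(( xs[-1] + xs[-length(xs)]) / 2))
  best <- NULL
  for (s in 1:4) {
    xs_s <- split_intervals(xs, s)
    for (ny in 4:150) {
      nr <- max(2L, as.integer(round(it * ny / Hbar)))
      cnt <- count_for(xs_s, ny, nr)
      d <- abs(cnt - target_elements)
      if (is.null(best) || d < best$d) best <- list(s = s, ny = ny, nr = nr,
                                                    cnt = cnt, d = d, xs = xs_s)
      if (cnt > 2 * target_elements) break
    }
    if (best$d / target_elements <= 0.05) break
  }
  if (best$d / target_elements > 0.25)
    stop("meshing error: cannot reach ", target_elements,
         " elements within 25% (closest ", best$cnt, "); the outline ",
         "resolution n_arc of the geometry bounds the coarsest mesh")
  xs <- best$xs; ny <- best$ny; nr <- best$nr

  ## -- vertical levels -----------------------------------------------------
  f <- seq(0, 1, length.out = ny + 1)
  for (fs in geom$y_sc / tmW) {       # snap interior fractions to SC endpoints
    i <- which.min(abs(f[2:ny] - fs)) + 1L
    f[i] <- fs
  }
  f <- sort(f)
  lev_rec <- seq(-it, 0, length.out = nr + 1)
  i <- which.min(abs(lev_rec[2:nr] - geom$tip$y)) + 1L
  lev_rec[i] <- geom$tip$y             # snap one recess level to the tip
  lev_rec <- sort(lev_rec)

  ## -- nodes ---------------------------------------------------------------
  nc <- length(xs)
  coords <- vector("list", nc + 2L * ntmx)
  upper <- vector("list", nc)   # node ids, floor -> outline
  lower <- vector("list", nc)   # recess ids, lens -> just below floor
  nid <- 0L
  is_rec <- abs(xs) < pl + tol
  for (i in seq_len(nc)) {
    ytop <- arc_top(xs[i])
    yu <- f * ytop
    if (is_rec[i]) {
      yr <- lev_rec[-(nr + 1)]            # lens floor up to just below y = 0
      lower[[i]] <- nid + seq_along(yr)
      upper[[i]] <- nid + length(yr) + seq_along(yu)
      coords[[i]] <- cbind(xs[i], c(yr, yu))
      nid <- nid + length(yr) + length(yu)
    } else {
      upper[[i]] <- nid + seq_along(yu)
      coords[[i]] <- cbind(xs[i], yu)
      nid <- nid + length(yu)
    }
  }
  # TM block columns (right then left)
  tm_right <- vector("list", ntmx); tm_left <- vector("list", ntmx)
  for (k in seq_len(ntmx)) {
    xk <- geom$x_rim + tmL * k / ntmx
    ids <- nid + seq_len(ny + 1); nid <- nid + ny + 1
    tm_right[[k]] <- ids
    coords[[nc + k]] <- cbind(xk, f * tmW)
  }
  for (k in seq_len(ntmx)) {
    xk <- -(geom$x_rim + tmL * k / ntmx)
    ids <- nid + seq_len(ny + 1); nid <- nid + ny + 1
    tm_left[[k]] <- ids
    coords[[nc + ntmx + k]] <- cbind(xk, f * tmW)
  }
  nodes <- do.call(rbind, coords)
  colnames(nodes) <- c("x", "y")

  ## -- triangles -----------------------------------------------------------
  tris <- vector("list", 0)
  quad_split <- function(A, B, C, D, right) {
    # quad with A bottom-left, B bottom-right, C top-right, D top-left
    if (right) rbind(cbind(A, B, C), cbind(A, C, D))
    else       rbind(cbind(A, B, D), cbind(B, C, D))
  }
  for (i in seq_len(nc - 1L)) {
    xc <- (xs[i] + xs[i + 1]) / 2
    L <- upper[[i]]; R <- upper[[i + 1]]
    j <- seq_len(length(f) - 1L)
    tris[[length(tris) + 1L]] <-
      quad_split(L[j], R[j], R[j + 1], L[j + 1], xc > 0)
    if (is_rec[i] && is_rec[i + 1] && xc > -pl && xc < pl) {
      Lr <- c(lower[[i]], L[1]); Rr <- c(lower[[i + 1]], R[1])
      jr <- seq_len(nr)
      tris[[length(tris) + 1L]] <-
        quad_split(Lr[jr], Rr[jr], Rr[jr + 1], Lr[jr + 1], xc > 0)
    }
  }
  rimR <- upper[[nc]]; rimL <- upper[[1]]
  colsR <- c(list(rimR), tm_right)
  colsL <- c(list(rimL), tm_left)
  j <- seq_len(length(f) - 1L)
  for (k in seq_len(ntmx)) {
    tris[[length(tris) + 1L]] <-
      quad_split(colsR[[k]][j], colsR[[k + 1]][j],
                 colsR[[k + 1]][j + 1], colsR[[k]][j + 1], TRUE)
    tris[[length(tris) + 1L]] <-
      quad_split(colsL[[k + 1]][j], colsL[[k]][j],
                 colsL[[k]][j + 1], colsL[[k + 1]][j + 1], FALSE)
  }
  tri <- do.call(rbind, tris)

  ## -- orientation & validity ----------------------------------------------
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  a2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  flip <- a2 < 0
  if (any(flip)) tri[flip, 2:3] <- tri[flip, 3:2]
  area <- abs(a2) / 2
  if (any(area <= 1e-14))
    stop("meshing error: degenerate triangle produced; geometry: ",
         paste(utils::capture.output(print(geom)), collapse = " "))

  cx <- (x1 + x2 + x3) / 3
  subdomain <- ifelse(abs(cx) > geom$x_rim + tol, "porous", "bulk")

  ## -- boundary edges -------------------------------------------------------
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(ekey)
  bnd <- e[ekey %in% names(cnt)[cnt == 1L], , drop = FALSE]
  bnd <- unique(cbind(pmin(bnd[, 1], bnd[, 2]), pmax(bnd[, 1], bnd[, 2])))
  mx <- (nodes[bnd[, 1], 1] + nodes[bnd[, 2], 1]) / 2
  my <- (nodes[bnd[, 1], 2] + nodes[bnd[, 2], 2]) / 2
  len <- sqrt((nodes[bnd[, 1], 1] - nodes[bnd[, 2], 1])^2 +
              (nodes[bnd[, 1], 2] - nodes[bnd[, 2], 2])^2)
  eps <- 1e-7
  tag <- rep(NA_character_, nrow(bnd))
  tag[abs(my + it) < eps & abs(mx) < pl] <- "lens"
  tag[abs(abs(mx) - pl) < eps & my < -eps] <- "pupil_wall"
  on_floor <- abs(my) < eps
  tag[on_floor & mx >=  pl - eps & mx <=  pl + inl + eps] <- "inlet_right"
  tag[on_floor & mx <= -pl + eps & mx >= -pl - inl - eps] <- "inlet_left"
  tag[on_floor & abs(mx) > pl + inl + eps & abs(mx) < geom$x_rim - eps] <- "iris"
  tag[(on_floor | abs(my - tmW) < eps) & abs(mx) > geom$x_rim - eps] <- "wall_tm"
  outface <- abs(abs(mx) - geom$x_out) < eps
  insc <- outface & my > geom$y_sc[1] - eps & my < geom$y_sc[2] + eps
  tag[outface & !insc] <- "wall_tm"
  tag[insc & mx > 0] <- "sc_outlet_right"
  tag[insc & mx < 0] <- "sc_outlet_left"
  tag[is.na(tag)] <- "cornea"
  boundary <- data.frame(n1 = bnd[, 1], n2 = bnd[, 2], tag = tag,
                         length = len, mx = mx, my = my,
                         stringsAsFactors = FALSE)

  ## -- immersed heated tip edges -------------------------------------------
  inte <- e[ekey %in% names(cnt)[cnt == 2L], , drop = FALSE]
  inte <- unique(cbind(pmin(inte[, 1], inte[, 2]), pmax(inte[, 1], inte[, 2])))
  ty1 <- nodes[inte[, 1], 2]; ty2 <- nodes[inte[, 2], 2]
  tx <- (nodes[inte[, 1], 1] + nodes[inte[, 2], 1]) / 2
  on_tip <- abs(ty1 - geom$tip$y) < eps & abs(ty2 - geom$tip$y) < eps &
    tx > geom$tip$x0 - eps & tx < geom$tip$x1 + eps
  tipe <- inte[on_tip, , drop = FALSE]
  tip_edges <- data.frame(
    n1 = tipe[, 1], n2 = tipe[, 2],
    length = abs(nodes[tipe[, 1], 1] - nodes[tipe[, 2], 1]))

  structure(list(nodes = nodes, tri = tri, area = area,
                 subdomain = subdomain, boundary = boundary,
                 tip_edges = tip_edges, geom = geom,
                 h = sqrt(2 * mean(area)),
                 levels = list(f = f, recess = lev_rec, xs = xs)),
            class = "ac_mesh")
}

#' Structured rectangle mesh (testing and 1-D oracle harness)
#'
#' A simple structured triangulation of `[0, width] x [0, height]` with
#' boundary tags `left`, `right`, `bottom`, `top`.  Used for closed-form
#' verification problems (plane conduction, channel flow) and for the
#' Brinkman-limit checks via the optional porous band.
#'
#' @param width,height rectangle dimensions, mm.
#' @param nx,ny number of cells in each direction.
#' @param porous_x optional `c(x0, x1)`: elements whose centroid falls in
#'   this x-range are tagged `"porous"`.
#' @return an `ac_mesh` object (without anterior-chamber geometry features).
#' @export
rectangle_mesh <- function(width, height, nx, ny, porous_x = NULL) {
  xs <- seq(0, width, length.out = nx + 1)
  ys <- seq(0, height, length.out = ny + 1)
  nodes <- cbind(x = rep(xs, each = ny + 1), y = rep(ys, nx + 1))
  id <- function(i, j) (i - 1L) * (ny + 1L) + j
  tris <- vector("list", nx)
  for (i in seq_len(nx)) {
    j <- seq_len(ny)
    A <- id(i, j); B <- id(i + 1L, j); C <- id(i + 1L, j + 1L); D <- id(i, j + 1L)
    tris[[i]] <- rbind(cbind(A, B, C), cbind(A, C, D))
  }
  tri <- do.call(rbind, tris)
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  area <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  cx <- (x1 + x2 + x3) / 3
  subdomain <- rep("bulk", nrow(tri))
  if (!is.null(porous_x))
    subdomain[cx >= porous_x[1] & cx <= porous_x[2]] <- "porous"
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(ekey)
  bnd <- e[ekey %in% names(cnt)[cnt == 1L], , drop = FALSE]
  bnd <- unique(cbind(pmin(bnd[, 1], bnd[, 2]), pmax(bnd[, 1], bnd[, 2])))
  mx <- (nodes[bnd[, 1], 1] + nodes[bnd[, 2], 1]) / 2
  my <- (nodes[bnd[, 1], 2] + nodes[bnd[, 2], 2]) / 2
  eps <- 1e-9
  tag <- rep(NA_character_, nrow(bnd))
  tag[abs(my) < eps] <- "bottom"; tag[abs(my - height) < eps] <- "top"
  tag[abs(mx) < eps] <- "left";   tag[abs(mx - width) < eps] <- "right"
  len <- sqrt((nodes[bnd[, 1], 1] - nodes[bnd[, 2], 1])^2 +
              (nodes[bnd[, 1], 2] - nodes[bnd[, 2], 2])^2)
  structure(list(nodes = nodes, tri = tri, area = area,
                 subdomain = subdomain,
                 boundary = data.frame(n1 = bnd[, 1], n2 = bnd[, 2], tag = tag,
                                       length = len, mx = mx, my = my,
                                       stringsAsFactors = FALSE),
                 tip_edges = data.frame(n1 = integer(0), n2 = integer(0),
                                        length = numeric(0)),
                 geom = NULL, h = sqrt(2 * mean(area)),
                 levels = NULL),
            class = "ac_mesh")
}

#' Nodes lying on boundary edges with given tags
#'
#' @param mesh an `ac_mesh`.
#' @param tags character vector of boundary tags.
#' @return sorted integer node indices.
#' @export
boundary_nodes <- function(mesh, tags) {
  b <- mesh$boundary[mesh$boundary$tag %in% tags, ]
  sort(unique(c(b$n1, b$n2)))
}

#' @export
print.ac_mesh <- function(x, ...) {
  cat("<ac_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$tri), " triangles (",
      sum(x$subdomain == "porous"), " porous), area ",
      format(sum(x$area), digits = 8), " mm^2\n", sep = "")
  invisible(x)
}
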