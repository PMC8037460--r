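## Linear (P1) finite-element operators on a triangular mesh.
## All operators work in SI units: the mesh stores millimetres, so element
## geometry is converted to metres once in fem_precompute().

#' Precompute P1 element geometry
#'
#' Computes element areas and basis-function gradients in SI units (metres)
#' for repeated assembly.
#'
#' @param mesh an `ac_mesh`.
#' @return list with `n` (nodes), `tri`, `A` (areas, m^2), `b`, `c`
#'   (gradient components of the three local basis functions, 1/m), and the
#'   porous-element mask.
#' @keywords internal
#' @export
fem_precompute <- function(mesh) {
  tri <- mesh$tri
  P <- mesh$nodes * 1e-3                       # mm -> m
  x1 <- P[tri[, 1], 1]; y1 <- P[tri[, 1], 2]
  x2 <- P[tri[, 2], 1]; y2 <- P[tri[, 2], 2]
  x3 <- P[tri[, 3], 1]; y3 <- P[tri[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  A <- det / 2
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / det
  list(n = nrow(P), tri = tri, A = A, b = b, c = cc,
       porous = mesh$subdomain == "porous", nodes_m = P)
}

# assemble a sparse matrix from 3x3 element blocks given as a function
# val(i, j) returning the per-element value vector
.fem_assemble <- function(fp, val) {
  m <- length(fp$A)
  I <- J <- X <- vector("list", 9L)
  k <- 0L
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1L
    I[[k]] <- fp$tri[, i]; J[[k]] <- fp$tri[, j]; X[[k]] <- val(i, j)
  }
  Matrix::sparseMatrix(i = unlist(I), j = unlist(J), x = unlist(X),
                       dims = c(fp$n, fp$n))
}

#' @rdname fem_precompute
#' @param coef per-element coefficient vector (recycled if scalar).
#' @export
fem_stiffness <- function(fp, coef = 1) {
  cA <- coef * fp$A
  .fem_assemble(fp, function(i, j)
    cA * (fp$b[, i] * fp$b[, j] + fp$c[, i] * fp$c[, j]))
}

#' @rdname fem_precompute
#' @export
fem_mass <- function(fp, coef = 1) {
  cA <- coef * fp$A / 12
  .fem_assemble(fp, function(i, j) cA * (1 + (i == j)))
}

#' @rdname fem_precompute
#' @param ux,uy nodal velocity components (m/s).
#' @export
fem_advection <- function(fp, ux, uy, coef = 1) {
  # C_ij = coef * int phi_i (u . grad phi_j), u interpolated linearly
  tri <- fp$tri
  uxe <- cbind(ux[tri[, 1]], ux[tri[, 2]], ux[tri[, 3]])
  uye <- cbind(uy[tri[, 1]], uy[tri[, 2]], uy[tri[, 3]])
  sx <- uxe[, 1] + uxe[, 2] + uxe[, 3]
  sy <- uye[, 1] + uye[, 2] + uye[, 3]
  cA <- coef * fp$A / 12
  .fem_assemble(fp, function(i, j)
    cA * ((sx + uxe[, i]) * fp$b[, j] + (sy + uye[, i]) * fp$c[, j]))
}

#' @rdname fem_precompute
#' @export
fem_gradient_ops <- function(fp) {
  # Dx_ij = int phi_i (d phi_j / dx); likewise Dy.  Used both for the
  # pressure-gradient term and (same matrices) the divergence rows.
  A3 <- fp$A / 3
  Dx <- .fem_assemble(fp, function(i, j) A3 * fp$b[, j])
  Dy <- .fem_assemble(fp, function(i, j) A3 * fp$c[, j])
  list(Dx = Dx, Dy = Dy)
}

#' Boundary/segment mass matrix for P1 edges
#'
#' Assembles `int phi_i phi_j ds` over the given edges (lengths taken from
#' the mesh in mm, converted to m).  Multiplying a constant flux by the row
#' sums of this matrix yields the consistent nodal load of a line source.
#'
#' @param fp output of [fem_precompute()].
#' @param edges data.frame with columns `n1`, `n2`, `length` (mm).
#' @export
fem_edge_mass <- function(fp, edges) {
  if (nrow(edges) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(fp$n, fp$n)))
  L <- edges$length * 1e-3
  I <- c(edges$n1, edges$n2, edges$n1, edges$n2)
  J <- c(edges$n1, edges$n2, edges$n2, edges$n1)
  X <- c(L / 3, L / 3, L / 6, L / 6)
  Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(fp$n, fp$n))
}

#' Element-wise divergence of a nodal velocity field
#'
#' @param fp output of [fem_precompute()].
#' @param ux,uy nodal velocity components (m/s).
#' @return per-element divergence (1/s), constant on each P1 element.
#' @export
fem_divergence <- function(fp, ux, uy) {
  tri <- fp$tri
  rowSums(fp$b * cbind(ux[tri[, 1]], ux[tri[, 2]], ux[tri[, 3]])) +
    rowSums(fp$c * cbind(uy[tri[, 1]], uy[tri[, 2]], uy[tri[, 3]]))
}

#' Barycentric interpolation weights for points in a mesh
#'
#' @param mesh an `ac_mesh`.
#' @param pts matrix or data.frame with columns `x`, `y` (mm).
#' @return list per point: `tri` (element index) and `w` (weights on the
#'   element's three nodes); error if a point lies outside the mesh.
#' @export
interp_weights <- function(mesh, pts) {
  pts <- as.matrix(pts[, c("x", "y"), drop = FALSE])
  tri <- mesh$tri; P <- mesh$nodes
  x1 <- P[tri[, 1], 1]; y1 <- P[tri[, 1], 2]
  x2 <- P[tri[, 2], 1]; y2 <- P[tri[, 2], 2]
  x3 <- P[tri[, 3], 1]; y3 <- P[tri[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  out <- vector("list", nrow(pts))
  for (k in seq_len(nrow(pts))) {
    px <- pts[k, 1]; py <- pts[k, 2]
    w2 <- ((px - x1) * (y3 - y1) - (x3 - x1) * (py - y1)) / det
    w3 <- ((x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)) / det
    w1 <- 1 - w2 - w3
    ok <- which(w1 >= -1e-9 & w2 >= -1e-9 & w3 >= -1e-9)
    if (length(ok) == 0L)
      stop("point (", px, ", ", py, ") lies outside the mesh")
    e <- ok[1]
    out[[k]] <- list(tri = e, nodes = tri[e, ],
                     w = pmax(c(w1[e], w2[e], w3[e]), 0))
  }
  out
}

#' Interior-node mask away from inlet/outlet boundary layers
#'
#' Returns the node indices at graph distance greater than `rings` element
#' edges from any node on the given boundary tags.  Used to exclude the
#' near-singular inlet/outlet corners from velocity extrema.
#'
#' @param mesh an `ac_mesh`.
#' @param tags boundary tags whose neighbourhood is excluded.
#' @param rings number of element rings to exclude.
#' @export
interior_nodes <- function(mesh,
                           tags = c("inlet_left", "inlet_right",
                                    "sc_outlet_left", "sc_outlet_right"),
                           rings = 2L) {
  seed <- boundary_nodes(mesh, tags)
  if (length(seed) == 0L) return(seq_len(nrow(mesh$nodes)))
  tri <- mesh$tri
  excl <- rep(FALSE, nrow(mesh$nodes))
  excl[seed] <- TRUE
  for (r in seq_len(rings)) {
    hit <- excl[tri[, 1]] | excl[tri[, 2]] | excl[tri[, 3]]
    excl[tri[hit, ]] <- TRUE
  }
  which(!excl)
}
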