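#' Construct a closed triangulated surface
#'
#' Builds the `tri_mesh` container used throughout the package: a closed,
#' orientable, genus-0 triangle mesh representing the vesicle membrane.
#' Edges and counts are derived from the triangle list; the constructor
#' verifies that every edge borders exactly two triangles, that the Euler
#' relation \eqn{N_v - N_l + N_t = 2} holds, and that the signed enclosed
#' volume is positive (consistent outward orientation).  Degenerate
#' triangles are rejected.
#'
#' @param positions Numeric matrix (N_v x 3) of vertex coordinates, in units
#'   of the bead diameter \eqn{\sigma}.
#' @param triangles Integer matrix (N_t x 3) of 1-based vertex indices with
#'   consistent outward orientation.
#' @return An object of class `tri_mesh`: a list with `positions`,
#'   `triangles`, `edges`, and counts `n_vertices`, `n_edges`,
#'   `n_triangles`.
#' @export
tri_mesh <- function(positions, triangles) {
  positions <- as.matrix(positions)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3) stop("positions must have 3 columns")
  if (any(!is.finite(positions))) stop("non-finite vertex coordinate")
  nv <- nrow(positions)
  if (any(triangles < 1L) || any(triangles > nv))
    stop("triangle index out of range")
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 2] == triangles[, 3] |
          triangles[, 1] == triangles[, 3]))
    stop("degenerate triangle: repeated vertex index")
  topo <- cpp_build_topology(triangles, nv)
  nl <- topo$n_edges
  nt <- nrow(triangles)
  if (nv - nl + nt != 2L)
    stop("Euler relation violated: mesh is not a closed genus-0 surface")
  # orientation consistency: every directed edge must appear exactly once
  # (each undirected edge is then traversed once in each direction)
  de <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  if (anyDuplicated((de[, 1] - 1) * as.double(nv) + de[, 2] - 1) ||
      nrow(de) != 2L * nl)
    stop("inconsistent triangle orientation: a directed edge appears twice")
  props <- cpp_mesh_props(positions, triangles)
  if (any(props$tri_areas <= 1e-12))
    stop("invalid mesh: degenerate (zero-area) triangle")
  if (props$volume <= 0)
    stop("signed volume is not positive: triangles are not consistently outward-oriented")
  structure(
    list(positions = positions, triangles = triangles, edges = topo$edges,
         n_vertices = nv, n_edges = nl, n_triangles = nt),
    class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d edges, %d triangles\n",
              x$n_vertices, x$n_edges, x$n_triangles))
  cat(sprintf("  area %.4f, volume %.4f, reduced volume %.4f\n",
              mesh_area(x), mesh_volume(x), reduced_volume(x)))
  invisible(x)
}

#' @export
summary.tri_mesh <- function(object, ...) {
  cf <- vertex_curvature(object)
  out <- list(n_vertices = object$n_vertices, n_edges = object$n_edges,
              n_triangles = object$n_triangles, area = mesh_area(object),
              volume = mesh_volume(object),
              reduced_volume = reduced_volume(object),
              asymmetry = membrane_asymmetry(object),
              mean_curvature = mean(cf$M),
              edge_length = mean(edge_lengths(object)))
  class(out) <- "summary.tri_mesh"
  out
}

#' @export
print.summary.tri_mesh <- function(x, ...) {
  cat(sprintf("closed triangulated surface: N_v = %d, N_l = %d, N_t = %d\n",
              x$n_vertices, x$n_edges, x$n_triangles))
  cat(sprintf("  A = %.4f  V = %.4f  v = %.4f  da = %.4f\n",
              x$area, x$volume, x$reduced_volume, x$asymmetry))
  cat(sprintf("  <M> = %.4f  <edge length> = %.4f\n",
              x$mean_curvature, x$edge_length))
  invisible(x)
}

#' Icosphere generator
#'
#' Subdivided icosahedron projected onto a sphere: the standard initial
#' condition for the vesicle membrane.  Each subdivision splits every
#' triangle into four, giving \eqn{10 \cdot 4^s + 2} vertices and
#' \eqn{20 \cdot 4^s} triangles at subdivision level `s`.
#'
#' @param subdivisions Non-negative integer subdivision level.
#' @param radius Sphere radius (units of \eqn{\sigma}).
#' @return A `tri_mesh`.
#' @export
#' @examples
#' m <- build_icosphere(2)
#' m$n_vertices          # 162
build_icosphere <- function(subdivisions = 3, radius = 1) {
  stopifnot(length(subdivisions) == 1, subdivisions >= 0,
            subdivisions == round(subdivisions), radius > 0)
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(1 + phi^2)
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midpoint <- new.env(hash = TRUE)
    verts <- lapply(seq_len(nrow(V)), function(i) V[i, ])
    get_mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- midpoint[[key]]
      if (!is.null(id)) return(id)
      m <- (verts[[a]] + verts[[b]]) / 2
      m <- m / sqrt(sum(m^2))
      verts[[length(verts) + 1]] <<- m
      id <- length(verts)
      midpoint[[key]] <- id
      id
    }
    newF <- matrix(0L, nrow(F) * 4, 3)
    for (t in seq_len(nrow(F))) {
      a <- F[t, 1]; b <- F[t, 2]; c <- F[t, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
      newF[4 * t - 3, ] <- c(a, ab, ca)
      newF[4 * t - 2, ] <- c(b, bc, ab)
      newF[4 * t - 1, ] <- c(c, ca, bc)
      newF[4 * t, ] <- c(ab, bc, ca)
    }
    F <- newF
    V <- do.call(rbind, verts)
  }
  tri_mesh(V * radius, F)
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas, in \eqn{\sigma^2}.
#' @param mesh A `tri_mesh`.
#' @return Positive scalar area.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  cpp_mesh_props(mesh$positions, mesh$triangles)$area
}

#' Enclosed volume of a closed mesh
#'
#' Signed sum of origin tetrahedra; positive for outward orientation and
#' invariant under translation for a closed surface.  In \eqn{\sigma^3}.
#' @param mesh A `tri_mesh`.
#' @return Scalar volume.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  cpp_mesh_props(mesh$positions, mesh$triangles)$volume
}

#' Reduced volume
#'
#' The dimensionless volume-to-area ratio \eqn{v = 6\sqrt{\pi}\, V / A^{3/2}}:
#' 1 for a sphere, smaller for deflated shapes.
#' @param mesh A `tri_mesh`.
#' @return Scalar in (0, 1] up to mesh-discretization tolerance.
#' @export
reduced_volume <- function(mesh) {
  A <- mesh_area(mesh)
  V <- mesh_volume(mesh)
  6 * sqrt(pi) * V / A^1.5
}

#' Per-vertex mean curvature and mixed areas
#'
#' Discrete mean curvature from the cotangent Laplace-Beltrami operator with
#' Meyer mixed Voronoi areas: \eqn{M_i = \mathrm{sign}\,|K_i|/2} with
#' \eqn{K_i = \sum_j (\cot\alpha_{ij}+\cot\beta_{ij})(x_i - x_j)/(2A_i)} and
#' the sign taken from the outward vertex normal.  The mixed-area rule keeps
#' \eqn{A_i > 0} on obtuse triangles and the \eqn{A_i} sum to the total mesh
#' area, so \eqn{2\kappa\sum_i M_i^2 A_i} is a Riemann sum of the Helfrich
#' bending energy.
#'
#' @param mesh A `tri_mesh`.
#' @return A list of class `curvature_field` with per-vertex `M` (1/\eqn{\sigma})
#'   and `A_mixed` (\eqn{\sigma^2}).
#' @export
vertex_curvature <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  out <- cpp_vertex_curvature(mesh$positions, mesh$triangles)
  structure(list(M = out$M, A_mixed = out$A_mixed), class = "curvature_field")
}

#' Membrane asymmetry
#'
#' The area integral of mean curvature normalized so a sphere gives exactly
#' one: \eqn{\Delta a = \oint M\,dA / (2\sqrt{\pi A})}, evaluated as
#' \eqn{\sum_i M_i A_i / (2\sqrt{\pi \sum_i A_i})}.  At fixed reduced volume
#' it separates cups, sheets and tubes.
#'
#' @param mesh A `tri_mesh`.
#' @return Scalar asymmetry.
#' @export
membrane_asymmetry <- function(mesh) {
  cf <- vertex_curvature(mesh)
  sum(cf$M * cf$A_mixed) / (2 * sqrt(pi * sum(cf$A_mixed)))
}

#' Edge lengths of a mesh
#' @param mesh A `tri_mesh`.
#' @return Numeric vector of edge lengths, ordered as `mesh$edges`.
#' @export
edge_lengths <- function(mesh) {
  d <- mesh$positions[mesh$edges[, 1], , drop = FALSE] -
    mesh$positions[mesh$edges[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Reference edge length of a triangulation
#'
#' The side \eqn{l_0} of identical equilateral triangles whose total area
#' equals the reference area: \eqn{A_0 = N_t \sqrt{3}\, l_0^2 / 4}.
#' @param A_0 Reference area.
#' @param n_triangles Number of triangles.
#' @return Scalar \eqn{l_0}.
#' @export
reference_edge_length <- function(A_0, n_triangles) {
  sqrt(4 * A_0 / (sqrt(3) * n_triangles))
}

#' Icosphere radius giving a prescribed reference edge length
#'
#' Inverts \eqn{4\pi R^2 = N_t \sqrt{3} l_0^2/4} for the icosphere at a given
#' subdivision level, so that the mesh spacing matches the bead diameter.
#' @param subdivisions Icosphere subdivision level.
#' @param l_0 Target reference edge length (default 1 \eqn{\sigma}).
#' @return Radius R.
#' @export
icosphere_radius_for_edge <- function(subdivisions, l_0 = 1) {
  nt <- 20 * 4^subdivisions
  sqrt(sqrt(3) * nt * l_0^2 / (16 * pi))
}
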