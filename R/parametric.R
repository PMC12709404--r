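#' Surface of revolution mesh
#'
#' Revolves a meridian contour (rho_i, z_i) around the z axis and
#' triangulates it into a closed mesh.  The contour must start and end on
#' the axis (rho = 0) at the two poles; interior points must have rho > 0.
#' Used to build the capped-cylinder tube and toroidal sheet reference
#' meshes whose closed-form reduced volume and asymmetry serve as oracles
#' for the discrete geometry.
#'
#' @param rho,z Numeric vectors of meridian coordinates (same length,
#'   `rho[1] = rho[m] = 0`).
#' @param n_seg Number of azimuthal segments (>= 3).
#' @return A `tri_mesh` with outward orientation when the contour runs from
#'   the top pole (largest z) to the bottom pole.
#' @export
revolve_mesh <- function(rho, z, n_seg) {
  m <- length(rho)
  stopifnot(m == length(z), m >= 3, n_seg >= 3,
            abs(rho[1]) < 1e-12, abs(rho[m]) < 1e-12,
            all(rho[2:(m - 1)] > 0))
  phi <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  V <- matrix(0, 2 + (m - 2) * n_seg, 3)
  V[1, ] <- c(0, 0, z[1])
  ring_id <- function(i, k) as.integer(1 + (i - 2) * n_seg + k)   # i in 2..m-1, k in 1..n_seg
  for (i in 2:(m - 1))
    V[ring_id(i, seq_len(n_seg)), ] <- cbind(rho[i] * cos(phi),
                                             rho[i] * sin(phi), z[i])
  V[nrow(V), ] <- c(0, 0, z[m])
  tris <- vector("list", m - 1)
  nk <- function(k) if (k == n_seg) 1L else k + 1L
  # top fan (pole at z[1]); orientation chosen for outward normals when
  # z[1] > z[m]
  tris[[1]] <- t(vapply(seq_len(n_seg), function(k)
    c(1L, ring_id(2, k), ring_id(2, nk(k))), integer(3)))
  if (m > 3) {
    for (i in 2:(m - 2)) {
      quads <- t(vapply(seq_len(n_seg), function(k) {
        a <- ring_id(i, k); b <- ring_id(i, nk(k))
        c2 <- ring_id(i + 1, k); d <- ring_id(i + 1, nk(k))
        c(a, c2, d, a, d, b)
      }, integer(6)))
      tris[[i]] <- rbind(quads[, 1:3], quads[, 4:6])
    }
  }
  tris[[m - 1]] <- t(vapply(seq_len(n_seg), function(k)
    c(nrow(V), ring_id(m - 1, nk(k)), ring_id(m - 1, k)), integer(3)))
  F <- do.call(rbind, tris)
  mesh <- tri_mesh(V, F)
  if (mesh_volume(mesh) < 0) mesh <- tri_mesh(V, F[, c(1, 3, 2)])
  mesh
}

#' Triangulated capped-cylinder tube
#'
#' Meshes the analytic tube reference shape (cylinder of radius `r_T`,
#' length `b * r_T`, hemispherical caps) for cross-checking the discrete
#' area, volume, reduced volume and membrane asymmetry against the closed
#' forms of [tube_model()].
#'
#' @param b Tube aspect ratio.
#' @param r_T Tube radius.
#' @param h Target mesh edge length (controls resolution).
#' @return A `tri_mesh`.
#' @export
capped_cylinder_mesh <- function(b, r_T = 1, h = r_T / 6) {
  stopifnot(b >= 0, r_T > 0, h > 0)
  L <- b * r_T
  n_th <- max(4L, ceiling((pi / 2) * r_T / h))     # polar steps per cap
  n_z <- max(1L, ceiling(L / h))
  th <- seq(0, pi / 2, length.out = n_th + 1)
  # top cap: from pole down to equator of the cap
  rho_top <- r_T * sin(th)
  z_top <- L / 2 + r_T * cos(th)
  zc <- if (n_z > 1) seq(L / 2, -L / 2, length.out = n_z + 1) else c(L / 2, -L / 2)
  rho_cyl <- rep(r_T, length(zc) - 2)
  z_cyl <- zc[2:(length(zc) - 1)]
  rho_bot <- rev(rho_top)
  z_bot <- -L / 2 - r_T * rev(cos(th))
  rho <- c(rho_top, rho_cyl, rho_bot)
  z <- c(z_top, z_cyl, z_bot)
  if (b == 0) {  # pure sphere: drop duplicated equator point
    keep <- !duplicated(round(cbind(rho, z), 12))
    rho <- rho[keep]; z <- z[keep]
  }
  n_seg <- max(6L, ceiling(2 * pi * r_T / h))
  revolve_mesh(rho, z, n_seg)
}

#' Triangulated toroidal sheet
#'
#' Meshes the analytic sheet reference shape: two parallel discs of radius
#' `c_aspect * r_2` joined by a half-torus rim of tube radius `r_2`, for
#' cross-checking against [sheet_model()].
#'
#' @param c_aspect Sheet aspect ratio (disc radius over rim radius).
#' @param r_2 Rim radius of curvature.
#' @param h Target mesh edge length.
#' @return A `tri_mesh`.
#' @export
toroidal_sheet_mesh <- function(c_aspect, r_2 = 1, h = r_2 / 6) {
  stopifnot(c_aspect > 0, r_2 > 0, h > 0)
  r_1 <- c_aspect * r_2
  n_d <- max(2L, ceiling(r_1 / h))                  # radial steps on each disc
  n_psi <- max(6L, ceiling(pi * r_2 / h))           # rim steps
  rr <- seq(0, r_1, length.out = n_d + 1)
  rho_top <- rr[-(n_d + 1)]
  z_top <- rep(r_2, n_d)
  psi <- seq(0, pi, length.out = n_psi + 1)
  rho_rim <- r_1 + r_2 * sin(psi)
  z_rim <- r_2 * cos(psi)
  rho_bot <- rev(rr[-(n_d + 1)])
  z_bot <- rep(-r_2, n_d)
  rho <- c(rho_top, rho_rim, rho_bot)
  z <- c(z_top, z_rim, z_bot)
  n_seg <- max(8L, ceiling(2 * pi * (r_1 + r_2) / h))
  revolve_mesh(rho, z, n_seg)
}

#' Synthetic tube-network fixtures (Y and H shapes)
#'
#' Builds a triangle soup of capped tubes arranged as a Y (one three-way
#' junction) or an H (two junctions joined by a crossbar), used to validate
#' the junction-counting skeleton.  The pieces are individually closed tubes
#' that interpenetrate at the joints, so the result is a `tri_soup` (not a
#' single closed surface); [count_junctions()] handles it through its
#' proximity-linking mode.
#'
#' @param shape `"Y"`, `"H"`, or `"I"` (a single straight tube, no junction).
#' @param radius Tube radius.
#' @param arm_length Length of each arm measured from its junction.
#' @param h Target mesh edge length.
#' @return A `tri_soup`: list with `positions`, `triangles`, `radius`.
#' @export
tube_network_mesh <- function(shape = c("Y", "H", "I"), radius = 1,
                              arm_length = 8, h = radius / 4) {
  shape <- match.arg(shape)
  seg <- function(p0, p1) list(p0 = p0, p1 = p1)
  L <- arm_length
  segs <- switch(shape,
    I = list(seg(c(0, -L, 0), c(0, L, 0))),
    Y = {
      dirs <- rbind(c(0, 1, 0),
                    c(sin(2 * pi / 3), cos(2 * pi / 3), 0),
                    c(-sin(2 * pi / 3), cos(2 * pi / 3), 0))
      lapply(seq_len(3), function(i) seg(c(0, 0, 0), L * dirs[i, ]))
    },
    H = {
      d <- L / 2
      list(seg(c(-d, -L, 0), c(-d, L, 0)),
           seg(c(d, -L, 0), c(d, L, 0)),
           seg(c(-d, 0, 0), c(d, 0, 0)))
    })
  pieces <- lapply(segs, function(s) {
    axis <- s$p1 - s$p0
    len <- sqrt(sum(axis^2))
    m <- capped_cylinder_mesh(b = len / radius, r_T = radius, h = h)
    # rotate z axis onto the segment axis, translate midpoint
    zhat <- c(0, 0, 1)
    a <- axis / len
    vcr <- c(zhat[2] * a[3] - zhat[3] * a[2],
             zhat[3] * a[1] - zhat[1] * a[3],
             zhat[1] * a[2] - zhat[2] * a[1])
    s_ <- sqrt(sum(vcr^2)); c_ <- sum(zhat * a)
    R <- diag(3)
    if (s_ > 1e-12) {
      K <- matrix(c(0, -vcr[3], vcr[2], vcr[3], 0, -vcr[1],
                    -vcr[2], vcr[1], 0), 3, 3, byrow = TRUE)
      R <- diag(3) + K + K %*% K * ((1 - c_) / s_^2)
    } else if (c_ < 0) {
      R <- diag(c(1, -1, -1))
    }
    mid <- (s$p0 + s$p1) / 2
    V <- sweep(m$positions %*% t(R), 2, mid, "+")
    list(V = V, F = m$triangles)
  })
  offs <- cumsum(c(0, vapply(pieces, function(p) nrow(p$V), numeric(1))))
  V <- do.call(rbind, lapply(pieces, `[[`, "V"))
  F <- do.call(rbind, lapply(seq_along(pieces),
                             function(i) pieces[[i]]$F + offs[i]))
  structure(list(positions = V, triangles = F, radius = radius),
            class = "tri_soup")
}

#' @export
print.tri_soup <- function(x, ...) {
  cat(sprintf("tri_soup: %d vertices, %d triangles (tube radius %.3g)\n",
              nrow(x$positions), nrow(x$triangles), x$radius))
  invisible(x)
}
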