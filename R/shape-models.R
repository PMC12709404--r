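#' Analytic capped-cylinder tube model
#'
#' Axisymmetric reference shape used to anchor vesicle shape classification:
#' a cylinder of radius \eqn{r_T} and length \eqn{L_T = b r_T}, closed by two
#' hemispherical caps.  Its area, volume, reduced volume and membrane
#' asymmetry have closed forms in the aspect ratio \eqn{b}:
#' \deqn{v_T = \frac{3(b + 4/3)}{\sqrt{2}\,(b+2)^{3/2}}, \qquad
#'       \Delta a_T = \frac{b + 4}{\sqrt{8 (b + 2)}}.}
#' The mean curvature is \eqn{1/r_T} on the caps and \eqn{1/(2 r_T)} on the
#' cylindrical section.  \eqn{b = 0} recovers the sphere
#' (\eqn{v_T = \Delta a_T = 1}); \eqn{v_T} decreases and \eqn{\Delta a_T}
#' increases monotonically with \eqn{b}.
#'
#' @param b Non-negative tube aspect ratio(s), \eqn{L_T / r_T}.
#' @param r_T Tube radius (only scales the dimensional outputs).
#' @return A data frame with columns `b`, `r_T`, `A_T`, `V_T`, `v_T`,
#'   `da_T` (one row per element of `b`).
#' @seealso [sheet_model()], [reference_asymmetries()]
#' @export
#' @examples
#' tube_model(0)            # sphere limit: v_T = 1, da_T = 1
#' tube_model(10)$v_T       # ~0.578
tube_model <- function(b, r_T = 1) {
  stopifnot(is.numeric(b), all(is.finite(b)), all(b >= 0), r_T > 0)
  A_T <- 2 * pi * r_T^2 * (b + 2)
  V_T <- pi * r_T^3 * (b + 4 / 3)
  data.frame(
    b = b, r_T = r_T, A_T = A_T, V_T = V_T,
    v_T = 3 * (b + 4 / 3) / (sqrt(2) * (b + 2)^1.5),
    da_T = (b + 4) / sqrt(8 * (b + 2))
  )
}

#' Analytic toroidal sheet model
#'
#' Axisymmetric reference disc ("sheet"): two parallel circular planes of
#' radius \eqn{r_1 = c\,r_2} joined by a half-torus rim of tube radius
#' \eqn{r_2}.  Closed forms in the aspect ratio \eqn{c}:
#' \deqn{v_S = \frac{6(2c^2 + \pi c + 4/3)}{(2c^2 + 2\pi c + 4)^{3/2}}, \qquad
#'       \Delta a_S = \frac{\pi c + 4}{2\sqrt{2c^2 + 2\pi c + 4}}.}
#' \eqn{c = 0} recovers the sphere.  The planar faces have zero mean
#' curvature; on the rim \eqn{M = 1/(2 r_2) + \sin\psi/(2 X)} with
#' \eqn{X = r_1 + r_2 \sin\psi} the distance from the symmetry axis.
#'
#' @param c_aspect Non-negative sheet aspect ratio(s), \eqn{r_1 / r_2}.
#' @param r_2 Rim radius of curvature (scales dimensional outputs).
#' @return A data frame with columns `c`, `r_2`, `A_S`, `V_S`, `v_S`, `da_S`.
#' @export
#' @examples
#' sheet_model(0)          # sphere limit
#' sheet_model(5)$da_S
sheet_model <- function(c_aspect, r_2 = 1) {
  stopifnot(is.numeric(c_aspect), all(is.finite(c_aspect)),
            all(c_aspect >= 0), r_2 > 0)
  cc <- c_aspect
  A_S <- pi * r_2^2 * (2 * cc^2 + 2 * pi * cc + 4)
  V_S <- pi * r_2^3 * (2 * cc^2 + pi * cc + 4 / 3)
  data.frame(
    c = cc, r_2 = r_2, A_S = A_S, V_S = V_S,
    v_S = 6 * (2 * cc^2 + pi * cc + 4 / 3) / (2 * cc^2 + 2 * pi * cc + 4)^1.5,
    da_S = (pi * cc + 4) / (2 * sqrt(2 * cc^2 + 2 * pi * cc + 4))
  )
}

#' Reference membrane asymmetries at a given reduced volume
#'
#' Inverts the monotone maps \eqn{v_T(b)} and \eqn{v_S(c)} by bracketed
#' root-finding and evaluates the corresponding tube and sheet asymmetries.
#' These two curves partition the \eqn{(v, \Delta a)} plane: vesicles near
#' the sheet curve are disc-like, vesicles near the tube curve are tubular,
#' and intermediate values indicate hybrid sheet-tube shapes.
#'
#' @param v Reduced volume(s) in (0, 1].
#' @param tol Root-finding tolerance on `v` (default 1e-10).
#' @return A data frame with columns `v`, `b`, `c`, `da_T`, `da_S`.
#' @export
#' @examples
#' reference_asymmetries(c(0.25, 0.5, 0.8))
reference_asymmetries <- function(v, tol = 1e-10) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  if (any(v <= 0 | v > 1 + 1e-12))
    stop("reduced volume must lie in (0, 1]")
  v <- pmin(v, 1)
  solve_one <- function(vi, fun) {
    if (vi >= 1) return(0)
    f <- function(x) fun(x) - vi
    upper <- 1
    while (f(upper) > 0) upper <- upper * 2
    stats::uniroot(f, c(0, upper), tol = tol)$root
  }
  vT_of_b <- function(b) 3 * (b + 4 / 3) / (sqrt(2) * (b + 2)^1.5)
  vS_of_c <- function(cc) 6 * (2 * cc^2 + pi * cc + 4 / 3) /
    (2 * cc^2 + 2 * pi * cc + 4)^1.5
  b <- vapply(v, solve_one, numeric(1), fun = vT_of_b)
  cc <- vapply(v, solve_one, numeric(1), fun = vS_of_c)
  data.frame(
    v = v, b = b, c = cc,
    da_T = tube_model(b)$da_T,
    da_S = sheet_model(cc)$da_S
  )
}

#' Vesicle shape index
#'
#' The dimensionless index \eqn{\alpha = \Delta a / \Delta a_T(v)}: membrane
#' asymmetry normalized by the asymmetry of the reference capped-cylinder
#' tube at the same reduced volume.  \eqn{\alpha \approx 1} for tubes and
#' branched tubes, \eqn{\alpha > 1} for pearled tubes, intermediate values
#' for sheets and \eqn{\alpha \ll 1} for cups.
#'
#' @param da Membrane asymmetry (see [membrane_asymmetry()]), or a
#'   `tri_mesh` from which both `da` and `v` are computed.
#' @param v Reduced volume in (0, 1]; ignored when `da` is a mesh.
#' @return Numeric shape index.
#' @export
shape_index <- function(da, v = NULL) {
  if (inherits(da, "tri_mesh")) {
    mesh <- da
    v <- reduced_volume(mesh)
    da <- membrane_asymmetry(mesh)
  }
  stopifnot(is.numeric(da), is.numeric(v))
  da / reference_asymmetries(pmin(v, 1))$da_T
}

#' Classify a vesicle shape from (membrane asymmetry, reduced volume)
#'
#' Banded thresholds anchored on the analytic sheet and tube curves: at the
#' vesicle's reduced volume the sheet asymmetry \eqn{\Delta a_S(v)} and tube
#' asymmetry \eqn{\Delta a_T(v)} are computed, and the measured
#' \eqn{\Delta a} is placed relative to them with a relative half-width
#' `delta`.  Below the sheet band: cup.  Above the tube band
#' (\eqn{\alpha > 1 + \delta}): pearled/compartmentalized.  Between the
#' bands: sheet-tube hybrid.
#'
#' @param da Membrane asymmetry, or a `tri_mesh`.
#' @param v Reduced volume; ignored when `da` is a mesh.
#' @param delta Relative band half-width (default 0.05).
#' @return Character label, one of `"cup"`, `"sheet"`, `"sheet-tube"`,
#'   `"tube"`, `"compartmentalized"`, `"unclassified"`.
#' @export
classify_shape <- function(da, v = NULL, delta = 0.05) {
  if (inherits(da, "tri_mesh")) {
    mesh <- da
    v <- reduced_volume(mesh)
    da <- membrane_asymmetry(mesh)
  }
  stopifnot(length(da) == length(v))
  ref <- reference_asymmetries(pmin(v, 1))
  lab <- function(dai, daS, daT) {
    if (!is.finite(dai)) return("unclassified")
    if (dai > daT * (1 + delta)) return("compartmentalized")
    if (dai >= daT * (1 - delta)) return("tube")
    if (dai > daS * (1 + delta)) return("sheet-tube")
    if (dai >= daS * (1 - delta)) return("sheet")
    "cup"
  }
  mapply(lab, da, ref$da_S, ref$da_T, USE.NAMES = FALSE)
}

#' Tabulate reference asymmetries over a grid of reduced volumes
#'
#' Convenience wrapper producing the sheet/tube asymmetry table used to
#' interpret shape diagrams.
#'
#' @param v Reduced volumes (default the grid 0.25--0.8 used throughout the
#'   shape analysis).
#' @return Data frame with `v`, `da_S`, `da_T`.
#' @export
reference_table <- function(v = c(0.25, 0.3, 0.35, 0.4, 0.45, 0.5, 0.6, 0.7, 0.8)) {
  ref <- reference_asymmetries(v)
  data.frame(v = ref$v, da_S = ref$da_S, da_T = ref$da_T)
}
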