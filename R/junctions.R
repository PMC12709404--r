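#' Count tubular junctions via a clustered curve skeleton
#'
#' Reduces a tubular mesh to a coarse centerline graph by greedy vertex
#' clustering at a spacing proportional to the local tube radius, then
#' counts three-way branch points.  Clusters become skeleton nodes at their
#' centroids; nodes are linked either through the mesh edges that span two
#' clusters (`connect = "mesh"`) or, for fixture soups assembled from
#' disjoint tube pieces, by point-set proximity (`connect = "proximity"`).
#' A node of degree \eqn{d \ge 3} contributes \eqn{d - 2} junctions, so a
#' four-way crossing counts as two three-way junctions.
#'
#' @param mesh A `tri_mesh`, a `tri_soup`, or a numeric position matrix.
#' @param radius Local tube radius.  Defaults to `2 V / A` for a closed
#'   `tri_mesh` (exact for a long cylinder) and to the stored radius for a
#'   `tri_soup`.
#' @param spacing Skeleton node spacing; default `2.4 * radius`, just above
#'   the tube diameter so that no cross-section ring can host two nodes and
#'   each cluster centroid falls on the centerline.
#' @param connect Cluster-graph linking rule; `"auto"` uses mesh edges when
#'   they connect the skeleton and falls back to proximity.
#' @return Integer junction count, with attributes `nodes` (cluster
#'   centroids), `degree`, and `low_confidence` (TRUE when the skeleton
#'   graph is disconnected or cyclic, e.g. on a non-tubular mesh).
#' @export
count_junctions <- function(mesh, radius = NULL,
                            spacing = NULL,
                            connect = c("auto", "mesh", "proximity")) {
  connect <- match.arg(connect)
  if (inherits(mesh, "tri_mesh")) {
    P <- mesh$positions
    E <- mesh$edges
    if (is.null(radius))
      radius <- 2 * mesh_volume(mesh) / mesh_area(mesh)
  } else if (inherits(mesh, "tri_soup")) {
    P <- mesh$positions
    E <- edges_of_triangles(mesh$triangles)
    if (is.null(radius)) radius <- mesh$radius
    if (connect == "auto") connect <- "proximity"
  } else {
    P <- as.matrix(mesh)
    E <- NULL
    if (connect %in% c("auto", "mesh")) connect <- "proximity"
    if (is.null(radius)) stop("radius must be given for a bare point set")
  }
  if (is.null(spacing)) spacing <- 2.4 * radius
  n <- nrow(P)

  # Poisson-disk seed selection: accept a vertex as a seed when it is at
  # least `spacing` from every previous seed, then assign every vertex to
  # its nearest seed (a surface Voronoi partition).  A ball of diameter
  # 2 * radius spans the tube cross-section, so each partition cell covers
  # a full ring of the tube and its centroid falls on the centerline.
  seeds <- integer(0)
  for (i in seq_len(n)) {
    if (length(seeds) == 0) { seeds <- i; next }
    d2 <- rowSums((P[seeds, , drop = FALSE] -
                     matrix(P[i, ], length(seeds), 3, byrow = TRUE))^2)
    if (min(d2) >= spacing^2) seeds <- c(seeds, i)
  }
  cen <- P[seeds, , drop = FALSE]
  # Lloyd iterations with node merging: assigning vertices to the nearest
  # node and re-centering pulls the nodes from the surface onto the tube
  # centerline (a full ring averages to an axis point); nodes that approach
  # within the spacing are merged so each cross-section keeps one node.
  for (iter in seq_len(30)) {
    d2s <- outer(rowSums(P^2), rowSums(cen^2), "+") - 2 * P %*% t(cen)
    cl <- max.col(-d2s)
    keep <- sort(unique(cl))
    cl <- match(cl, keep)
    new_cen <- do.call(rbind, lapply(seq_along(keep), function(i)
      colMeans(P[cl == i, , drop = FALSE])))
    merged <- FALSE
    if (nrow(new_cen) > 1) {
      dd <- as.matrix(dist(new_cen))
      diag(dd) <- Inf
      hit <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      if (min(dd) < 0.9 * spacing) {
        i <- min(hit); j <- max(hit)
        wi <- sum(cl == i); wj <- sum(cl == j)
        new_cen[i, ] <- (wi * new_cen[i, ] + wj * new_cen[j, ]) / (wi + wj)
        new_cen <- new_cen[-j, , drop = FALSE]
        merged <- TRUE
      }
    }
    moved <- if (nrow(new_cen) == nrow(cen) && !merged)
      max(rowSums((new_cen - cen)^2)) else Inf
    cen <- new_cen
    if (!merged && moved < (1e-4 * spacing)^2) break
  }
  d2s <- outer(rowSums(P^2), rowSums(cen^2), "+") - 2 * P %*% t(cen)
  cl <- max.col(-d2s)
  k <- nrow(cen)

  link <- NULL
  if (connect %in% c("auto", "mesh") && !is.null(E)) {
    a <- cl[E[, 1]]; b <- cl[E[, 2]]
    keep <- a != b
    link <- unique(cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep])))
  }
  need_prox <- connect == "proximity" ||
    (connect == "auto" && (is.null(link) ||
       igraph::components(igraph::graph_from_edgelist(link, directed = FALSE))$no > 1))
  if (need_prox) {
    # link clusters whose point sets approach within a fraction of the spacing
    thr <- 0.35 * spacing
    pairs <- list()
    for (i in seq_len(k - 1)) {
      Pi <- P[cl == i, , drop = FALSE]
      ceni <- cen[i, ]
      for (j in (i + 1):k) {
        if (sum((ceni - cen[j, ])^2) > (2.5 * spacing)^2) next
        Pj <- P[cl == j, , drop = FALSE]
        dmin <- min(proxy_min_dist(Pi, Pj))
        if (dmin < thr) pairs[[length(pairs) + 1]] <- c(i, j)
      }
    }
    link <- if (length(pairs)) do.call(rbind, pairs) else matrix(0L, 0, 2)
  }

  g <- igraph::graph_from_edgelist(link, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, k - igraph::vcount(g)))
  g <- igraph::simplify(g)
  deg <- igraph::degree(g)
  J <- sum(pmax(deg - 2L, 0L)[deg >= 3])
  comp <- igraph::components(g)
  cyc <- igraph::ecount(g) - igraph::vcount(g) + comp$no
  out <- as.integer(J)
  attr(out, "nodes") <- cen
  attr(out, "degree") <- deg
  attr(out, "low_confidence") <- comp$no > 1 || cyc > 0
  out
}

# minimum pairwise distance between two point sets (small sets only)
proxy_min_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

# undirected edge list of a triangle matrix
edges_of_triangles <- function(F) {
  E <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  E <- cbind(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
  unique(E)
}

#' Junction turnover rates from a junction-count time series
#'
#' Smooths the series with a persistence filter (a level change must
#' survive at least `window` consecutive frames to count) and reports the
#' emergence rate `r_e` (upward events per unit time), retraction rate
#' `r_r` (downward events), and the total turnover rate `r = r_e + r_r`.
#'
#' @param J Integer vector of junction counts per frame.
#' @param times Frame times (uniform sampling), or a scalar total duration.
#' @param window Persistence window in frames (default 1: every change
#'   counts).  With trajectory input use roughly 0.5 time units worth of
#'   frames to suppress single-frame flicker.
#' @return A list of class `turnover_stats` with `r_e`, `r_r`, `r`,
#'   `emergence_fraction`, `n_up`, `n_down`, `duration`.
#' @export
#' @examples
#' J <- c(0, 1, 1, 2, 2, 1, 3, 3, 2, 2, 3)
#' turnover_rates(J, times = seq(0, 10, length.out = 11))
turnover_rates <- function(J, times, window = 1L) {
  stopifnot(length(J) >= 2, window >= 1)
  if (length(times) == 1) {
    duration <- times
  } else {
    stopifnot(length(times) == length(J))
    duration <- times[length(times)] - times[1]
  }
  if (length(J) < window) stop("series shorter than persistence window")
  # persistence filter: accept a new level only once it has lasted >= window
  lev <- J[1]
  events_up <- 0L
  events_down <- 0L
  i <- 2L
  n <- length(J)
  while (i <= n) {
    if (J[i] != lev) {
      run_end <- i
      while (run_end < n && J[run_end + 1] == J[i]) run_end <- run_end + 1L
      if (run_end - i + 1L >= window) {
        if (J[i] > lev) events_up <- events_up + (J[i] - lev)
        else events_down <- events_down + (lev - J[i])
        lev <- J[i]
      }
      i <- run_end + 1L
    } else {
      i <- i + 1L
    }
  }
  r_e <- events_up / duration
  r_r <- events_down / duration
  structure(list(r_e = r_e, r_r = r_r, r = r_e + r_r,
                 emergence_fraction = if (r_e + r_r > 0) r_e / (r_e + r_r) else NA_real_,
                 n_up = events_up, n_down = events_down, duration = duration),
            class = "turnover_stats")
}

#' @export
print.turnover_stats <- function(x, ...) {
  cat(sprintf("junction turnover: r_e = %.3g, r_r = %.3g, r = %.3g per unit time\n",
              x$r_e, x$r_r, x$r))
  cat(sprintf("  %d emergence / %d retraction events over %.3g time units (r_e/r = %.3g)\n",
              x$n_up, x$n_down, x$duration, x$emergence_fraction))
  invisible(x)
}
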