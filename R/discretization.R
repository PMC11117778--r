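#' Build a regular nodal cloud
#'
#' Discretises a square tissue domain with an equally spaced grid of nodes.
#' The default study domain is a 5 x 5 mm square with 51 nodes per side
#' (2601 nodes, 0.1 mm internodal spacing).
#'
#' @param side_length Domain side length in mm.
#' @param nodes_per_side Number of nodes along each side (>= 2).
#' @param duplicate_tol Minimum distance between two distinct nodes in mm;
#'   positions closer than this to an existing node are treated as that
#'   node.  Defaults to a tenth of the internodal spacing, which keeps the
#'   radial moment matrices of inserted tip-cell nodes well conditioned.
#' @return An object of class `nodal_cloud`: a list with `coords` (N x 2
#'   matrix, mm), `spacing`, `bounds` (xmin, ymin, xmax, ymax),
#'   `nodes_per_side`, `n_base` (number of grid nodes) and `duplicate_tol`.
#' @export
build_regular_nodal_cloud <- function(side_length, nodes_per_side,
                                      duplicate_tol = NULL) {
  if (!is.numeric(side_length) || side_length <= 0)
    amech_stop("side_length must be positive", "invalid_argument")
  if (!is.numeric(nodes_per_side) || nodes_per_side < 2)
    amech_stop("nodes_per_side must be at least 2", "invalid_argument")
  nodes_per_side <- as.integer(nodes_per_side)
  ax <- seq(0, side_length, length.out = nodes_per_side)
  coords <- cbind(x = rep(ax, times = nodes_per_side),
                  y = rep(ax, each = nodes_per_side))
  spacing <- side_length / (nodes_per_side - 1)
  if (is.null(duplicate_tol)) duplicate_tol <- spacing / 10
  structure(list(coords = coords,
                 spacing = spacing,
                 bounds = c(xmin = 0, ymin = 0,
                            xmax = side_length, ymax = side_length),
                 nodes_per_side = nodes_per_side,
                 n_base = nrow(coords),
                 duplicate_tol = duplicate_tol),
            class = "nodal_cloud")
}

#' @exportS3Method base::print
print.nodal_cloud <- function(x, ...) {
  cat(sprintf("<nodal_cloud> %d nodes, spacing %.4g mm, bounds [%g, %g] x [%g, %g]\n",
              nrow(x$coords), x$spacing,
              x$bounds[1], x$bounds[3], x$bounds[2], x$bounds[4]))
  invisible(x)
}

n_nodes <- function(cloud) nrow(cloud$coords)

is_regular_grid <- function(cloud) {
  !is.null(cloud$nodes_per_side) && nrow(cloud$coords) == cloud$n_base
}

#' Build the background Gauss-Legendre integration mesh
#'
#' One background cell per nodal grid cell, each carrying a tensor-product
#' Gauss-Legendre rule.  Quadrature weights are scaled by the cell Jacobian
#' so that they sum to the domain area.
#'
#' @param cloud A regular [build_regular_nodal_cloud()] cloud.  The
#'   background mesh is anchored to the initial grid, so clouds that have
#'   grown by node insertion are integrated on their original cells.
#' @param gauss_order Gauss-Legendre order per direction (1 to 5);
#'   `gauss_order^2` points per cell.
#' @return An object of class `integration_mesh`: `points` (m x 2, mm),
#'   `weights` (mm^2), `cells` (cell index per point), `gauss_order`,
#'   `cell_size`.
#' @export
build_integration_mesh <- function(cloud, gauss_order = 3L) {
  if (!inherits(cloud, "nodal_cloud") || is.null(cloud$nodes_per_side))
    amech_stop("integration mesh needs a regular grid cloud",
               "unsupported_layout")
  if (!gauss_order %in% 1:5)
    amech_stop("gauss_order must be in 1..5", "invalid_argument")
  gauss_order <- as.integer(gauss_order)
  nps <- cloud$nodes_per_side
  h <- cloud$spacing
  gl <- gauss_legendre(gauss_order)
  # per-cell offsets of the tensor rule, cell-local coords in [0, h]
  off <- expand.grid(a = seq_len(gauss_order), b = seq_len(gauss_order))
  ox <- h * (gl$x[off$a] + 1) / 2
  oy <- h * (gl$x[off$b] + 1) / 2
  ow <- gl$w[off$a] * gl$w[off$b] * h^2 / 4
  ncell <- nps - 1L
  cell <- expand.grid(i = seq_len(ncell), j = seq_len(ncell))
  x0 <- (cell$i - 1) * h
  y0 <- (cell$j - 1) * h
  npc <- gauss_order^2
  pts <- cbind(x = rep(x0, each = npc) + rep(ox, times = nrow(cell)),
               y = rep(y0, each = npc) + rep(oy, times = nrow(cell)))
  structure(list(points = pts,
                 weights = rep(ow, times = nrow(cell)),
                 cells = rep(seq_len(nrow(cell)), each = npc),
                 gauss_order = gauss_order,
                 cell_size = h),
            class = "integration_mesh")
}

#' Gauss-Legendre quadrature along domain edges
#'
#' Builds 1D boundary quadrature (one segment per boundary cell edge) used
#' for traction force integration and for the variationally consistent
#' treatment of essential boundaries.
#'
#' @param cloud A regular nodal cloud.
#' @param edges Character vector among `"bottom"`, `"top"`, `"left"`,
#'   `"right"`.
#' @param gauss_order Gauss-Legendre order per edge segment.
#' @return List with `points` (m x 2), `weights` (mm), `normals` (m x 2,
#'   outward unit normals) and `edge` (factor).
#' @export
build_edge_quadrature <- function(cloud, edges, gauss_order = 3L) {
  if (!is_regular_grid(cloud) && is.null(cloud$nodes_per_side))
    amech_stop("edge quadrature needs a regular grid cloud",
               "unsupported_layout")
  side <- cloud$bounds["xmax"]
  h <- cloud$spacing
  nseg <- cloud$nodes_per_side - 1L
  gl <- gauss_legendre(as.integer(gauss_order))
  t0 <- (seq_len(nseg) - 1) * h
  tq <- rep(t0, each = gauss_order) + rep(h * (gl$x + 1) / 2, times = nseg)
  wq <- rep(gl$w * h / 2, times = nseg)
  geom <- list(
    bottom = function(t) list(p = cbind(t, 0),    n = c(0, -1)),
    top    = function(t) list(p = cbind(t, side), n = c(0, 1)),
    left   = function(t) list(p = cbind(0, t),    n = c(-1, 0)),
    right  = function(t) list(p = cbind(side, t), n = c(1, 0)))
  bad <- setdiff(edges, names(geom))
  if (length(bad))
    amech_stop(paste("unknown edge:", paste(bad, collapse = ", ")),
               "invalid_argument")
  pts <- NULL; wts <- NULL; nrm <- NULL; lab <- NULL
  for (e in edges) {
    g <- geom[[e]](tq)
    pts <- rbind(pts, g$p)
    wts <- c(wts, wq)
    nrm <- rbind(nrm, matrix(g$n, nrow = length(tq), ncol = 2, byrow = TRUE))
    lab <- c(lab, rep(e, length(tq)))
  }
  list(points = pts, weights = wts, normals = nrm, edge = factor(lab))
}

#' Find the influence domain of an evaluation point
#'
#' Returns the `n` nearest nodes under Euclidean distance; ties are broken
#' by ascending node id.
#'
#' @param point Numeric length-2 position (mm).
#' @param cloud A `nodal_cloud`.
#' @param n Number of nodes requested.
#' @return Object of class `influence_domain` with `node_indices` (ordered
#'   by ascending distance), `n` and `point`.
#' @export
find_influence_domain <- function(point, cloud, n = 16L) {
  N <- n_nodes(cloud)
  if (N == 0L) amech_stop("empty nodal cloud", "invalid_argument")
  if (n > N)
    amech_stop(sprintf("requested %d nodes but cloud has %d", n, N),
               "insufficient_nodes")
  kn <- cpp_knn(matrix(as.numeric(point), 1, 2), cloud$coords, as.integer(n))
  structure(list(point = as.numeric(point),
                 node_indices = as.integer(kn$idx[, 1]),
                 distances = as.numeric(kn$dist[, 1]),
                 n = as.integer(n)),
            class = "influence_domain")
}

# Batch influence domains: k x m index matrix plus k-th distance per point.
influence_domains <- function(points, cloud, n = 16L) {
  kn <- cpp_knn(points, cloud$coords, as.integer(n))
  list(idx = kn$idx, dist = kn$dist, rk = kn$dist[n, ])
}

#' Insert a node into the cloud
#'
#' Appends a node at `position` unless an existing node lies within the
#' duplicate tolerance, in which case the existing node id is returned and
#' the cloud is unchanged.  Used by the growth engine when a tip cell moves
#' to an unoccupied position.
#'
#' @param cloud A `nodal_cloud`.
#' @param position Numeric length-2 position (mm), inside the bounds.
#' @return List with `cloud` (possibly enlarged), `id` (node id of the
#'   position) and `inserted` (logical).
#' @export
insert_node <- function(cloud, position) {
  position <- as.numeric(position)
  b <- cloud$bounds
  if (position[1] < b["xmin"] || position[1] > b["xmax"] ||
      position[2] < b["ymin"] || position[2] > b["ymax"])
    amech_stop("position outside domain bounds", "out_of_domain")
  d2 <- (cloud$coords[, 1] - position[1])^2 +
        (cloud$coords[, 2] - position[2])^2
  jmin <- which.min(d2)
  if (sqrt(d2[jmin]) < cloud$duplicate_tol)
    return(list(cloud = cloud, id = jmin, inserted = FALSE))
  cloud$coords <- rbind(cloud$coords, position, deparse.level = 0)
  list(cloud = cloud, id = nrow(cloud$coords), inserted = TRUE)
}
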