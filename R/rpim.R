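#' Multiquadric RBF parameters
#'
#' The multiquadric radial basis function is R(d) = (d^2 + c^2)^p.  The
#' defaults c = 0.0001 and p = 0.9999 are the optimised values established
#' for RPIM with a linear polynomial basis; distances are in mm and the
#' constants are applied verbatim.
#'
#' @param c Shape parameter, >= 0.
#' @param p Exponent, != 0.
#' @return Object of class `mq_params`.
#' @export
mq_params <- function(c = 1e-4, p = 0.9999) {
  if (!is.numeric(c) || c < 0)
    amech_stop("c must be >= 0", "invalid_argument")
  if (!is.numeric(p) || p == 0)
    amech_stop("p must be nonzero", "invalid_argument")
  structure(list(c = c, p = p), class = "mq_params")
}

#' Evaluate the multiquadric radial basis function
#'
#' @param d Distance (mm), vectorised, >= 0.
#' @param params [mq_params()].
#' @return (d^2 + c^2)^p.
#' @export
mq_rbf <- function(d, params = mq_params()) {
  (d^2 + params$c^2)^params$p
}

#' Assemble the RPIM moment matrices for one evaluation point
#'
#' Builds the radial moment matrix R (R_ij = MQ(||x_i - x_j||)), the
#' polynomial moment matrix P (rows [1, x, y]) and the blocked system
#' matrix G = [R P; P' 0].  Diagnostic / reference path; batched assembly
#' uses the compiled kernel.
#'
#' @param point Numeric length-2 evaluation position (unused by R and P,
#'   kept for interface symmetry).
#' @param nodes n x 2 matrix of influence-domain node coordinates (n >= 3,
#'   not all collinear).
#' @param params [mq_params()].
#' @param cond_limit Condition-number limit above which the node geometry
#'   is treated as degenerate.
#' @return List with `R`, `P`, `G`.
#' @export
assemble_moment_matrices <- function(point, nodes, params = mq_params(),
                                     cond_limit = 1e12) {
  nodes <- as.matrix(nodes)
  n <- nrow(nodes)
  if (n < 3) amech_stop("need at least 3 nodes", "invalid_argument")
  D <- as.matrix(stats::dist(nodes))
  R <- mq_rbf(D, params)
  P <- cbind(1, nodes[, 1], nodes[, 2])
  G <- rbind(cbind(R, P), cbind(t(P), matrix(0, 3, 3)))
  kap <- kappa(G, exact = FALSE)
  if (!is.finite(kap) || kap > cond_limit)
    amech_stop(sprintf(
      "degenerate influence-domain geometry (condition number %.3g)", kap),
      "degenerate_geometry")
  list(R = R, P = P, G = G)
}

#' RPIM shape functions at an evaluation point
#'
#' Computes the shape-function vector phi and its analytic x/y derivatives
#' for the nodes of an influence domain.  phi is the first n entries of
#' [R(x)', p(x)'] G^-1; the trailing three entries form the residual vector
#' Psi, exposed for diagnostics.  phi has the Kronecker-delta property and
#' partitions unity; its derivatives sum to zero.
#'
#' @param point Numeric length-2 position (mm).
#' @param domain [find_influence_domain()] result.
#' @param cloud The `nodal_cloud` the domain indexes into.
#' @param params [mq_params()].
#' @return Object of class `shape_function_set`: `point`, `node_indices`,
#'   `phi`, `dphi_dx`, `dphi_dy` (1/mm), `psi`.
#' @export
shape_functions_at <- function(point, domain, cloud, params = mq_params()) {
  ids <- domain$node_indices
  nodes <- cloud$coords[ids, , drop = FALSE]
  mm <- assemble_moment_matrices(point, nodes, params)
  n <- length(ids)
  px <- point[1]; py <- point[2]
  d2 <- (nodes[, 1] - px)^2 + (nodes[, 2] - py)^2
  c2 <- params$c^2; p <- params$p
  rx <- (d2 + c2)^p
  tt <- 2 * p * (d2 + c2)^(p - 1)
  B <- cbind(c(rx, 1, px, py),
             c(tt * (px - nodes[, 1]), 0, 1, 0),
             c(tt * (py - nodes[, 2]), 0, 0, 1))
  S <- solve(mm$G, B)
  structure(list(point = as.numeric(point),
                 node_indices = ids,
                 phi = S[seq_len(n), 1],
                 dphi_dx = S[seq_len(n), 2],
                 dphi_dy = S[seq_len(n), 3],
                 psi = S[n + 1:3, 1]),
            class = "shape_function_set")
}

# Batched shape functions through the compiled kernel.
# pts: m x 2; neigh: k x m 1-based ids; ncnt: nodes used per point.
rpim_batch <- function(pts, coords, neigh, ncnt = NULL, params = mq_params(),
                       deriv = TRUE) {
  if (is.null(ncnt)) ncnt <- rep(nrow(neigh), ncol(neigh))
  cpp_rpim_batch(pts, coords, neigh, as.integer(ncnt),
                 params$c, params$p, deriv)
}
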