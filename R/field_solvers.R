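# Steady-state VEGF diffusion and plane-stress elastostatics assembled on
# the shared RPIM discretisation.

# Expand a k x m matrix pair (dx, dy) of shape-function derivatives into
# COO triplets of the local diffusion stiffness  w * D * (dx dx' + dy dy').
diffusion_triplets <- function(neigh, dxm, dym, wD) {
  k <- nrow(neigh)
  a <- rep(seq_len(k), times = k)
  b <- rep(seq_len(k), each = k)
  V <- dxm[a, , drop = FALSE] * dxm[b, , drop = FALSE] +
       dym[a, , drop = FALSE] * dym[b, , drop = FALSE]
  list(i = as.vector(neigh[a, , drop = FALSE]),
       j = as.vector(neigh[b, , drop = FALSE]),
       x = as.vector(V) * rep(wD, each = k * k))
}

# Consistency (boundary-flux) triplets along essential domain edges:
#  -w * D * phi_i * (n . grad phi_j).  Restores the variational
# consistency that strong nodal imposition alone leaves behind, so that
# patch tests are passed to quadrature precision.
edge_consistency_triplets <- function(eq, cloud, n_influence, params, Dedge) {
  dom <- influence_domains(eq$points, cloud,
                           min(n_influence, n_nodes(cloud)))
  sh <- rpim_batch(eq$points, cloud$coords, dom$idx, params = params)
  k <- nrow(dom$idx)
  dn <- sh$dx * rep(eq$normals[, 1], each = k) +
        sh$dy * rep(eq$normals[, 2], each = k)
  a <- rep(seq_len(k), times = k)
  b <- rep(seq_len(k), each = k)
  V <- sh$phi[a, , drop = FALSE] * dn[b, , drop = FALSE]
  list(i = as.vector(dom$idx[a, , drop = FALSE]),
       j = as.vector(dom$idx[b, , drop = FALSE]),
       x = as.vector(V) * rep(-eq$weights * Dedge, each = k * k))
}

resolve_diffusivity <- function(diffusivity, int_mesh) {
  m <- nrow(int_mesh$points)
  if (inherits(diffusivity, "diffusivity_map")) {
    if (!diffusivity$valid) {
      bad <- which(diffusivity$values < 0)
      amech_stop(sprintf(
        "diffusivity map is invalid: %d integration points have negative values (e.g. points %s); the pressure coupling is outside its stable regime",
        length(bad), paste(utils::head(bad, 5), collapse = ", ")),
        "instability")
    }
    vals <- diffusivity$values
    floor_D <- 1e-3 * diffusivity$base
    nlow <- sum(vals < floor_D)
    if (nlow > 0) {
      warning(sprintf(
        "clamping %d integration-point diffusivities below the floor %.3g to keep the system non-singular",
        nlow, floor_D), call. = FALSE)
      vals[vals < floor_D] <- floor_D
    }
    return(vals)
  }
  vals <- rep_len(as.numeric(diffusivity), m)
  if (any(vals < 0)) {
    bad <- which(vals < 0)
    amech_stop(sprintf("negative diffusivity at integration points %s",
                       paste(utils::head(bad, 5), collapse = ", ")),
               "instability")
  }
  vals
}

#' Assemble the steady-state VEGF diffusion system
#'
#' Galerkin assembly of the Helmholtz-type diffusion operator
#' K = sum_q B' D B w (+ the reaction term when `g` is nonzero) with the
#' discrete release-rate vector fq, on the background integration mesh
#' with RPIM shape functions.  Diffusion is isotropic (Dx = Dy).
#'
#' @param cloud A `nodal_cloud`.
#' @param int_mesh A [build_integration_mesh()] mesh.
#' @param diffusivity Scalar, per-integration-point vector (mm^2/s), or a
#'   [modified_diffusion_map()] object.  Values below a floor of 1e-3 of
#'   the base diffusivity are clamped (with a warning); negative values
#'   are rejected.
#' @param g Reaction (chemical) coefficient; 0 in the study conditions.
#' @param Q VEGF release rate, scalar or per-point; 0 by default (the
#'   essential concentrations at lumen and release region already set the
#'   gradient).
#' @param n_influence Influence-domain size (nodes per evaluation point).
#' @param params [mq_params()].
#' @param consistency_edges Optional character vector of domain edges that
#'   will carry essential values; adds the boundary-flux consistency term
#'   along them (makes K mildly non-symmetric).
#' @return Object of class `scalar_field_system` with `K` (sparse N x N),
#'   `fq`, and bookkeeping for boundary conditions.
#' @export
assemble_diffusion <- function(cloud, int_mesh, diffusivity, g = 0, Q = 0,
                               n_influence = 16L, params = mq_params(),
                               consistency_edges = NULL) {
  Dv <- resolve_diffusivity(diffusivity, int_mesh)
  N <- n_nodes(cloud)
  k <- min(n_influence, N)
  dom <- influence_domains(int_mesh$points, cloud, k)
  sh <- rpim_batch(int_mesh$points, cloud$coords, dom$idx, params = params)
  w <- int_mesh$weights
  tr <- diffusion_triplets(dom$idx, sh$dx, sh$dy, w * Dv)
  if (any(g != 0)) {
    gq <- rep_len(as.numeric(g), length(w))
    a <- rep(seq_len(k), times = k)
    b <- rep(seq_len(k), each = k)
    V <- sh$phi[a, , drop = FALSE] * sh$phi[b, , drop = FALSE]
    tr$i <- c(tr$i, as.vector(dom$idx[a, , drop = FALSE]))
    tr$j <- c(tr$j, as.vector(dom$idx[b, , drop = FALSE]))
    tr$x <- c(tr$x, as.vector(V) * rep(w * gq, each = k * k))
  }
  if (!is.null(consistency_edges)) {
    eq <- build_edge_quadrature(cloud, consistency_edges,
                                int_mesh$gauss_order)
    base_D <- if (inherits(diffusivity, "diffusivity_map"))
      evaluate_diffusivity(diffusivity, eq$points) else
      rep_len(as.numeric(diffusivity), nrow(eq$points))
    trc <- edge_consistency_triplets(eq, cloud, n_influence, params, base_D)
    tr$i <- c(tr$i, trc$i); tr$j <- c(tr$j, trc$j); tr$x <- c(tr$x, trc$x)
  }
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(N, N))
  fq <- numeric(N)
  if (any(Q != 0)) {
    Qq <- rep_len(as.numeric(Q), length(w))
    vals <- as.vector(sh$phi) * rep(w * Qq, each = k)
    agg <- rowsum(vals, group = as.vector(dom$idx))
    fq[as.integer(rownames(agg))] <- agg[, 1]
  }
  structure(list(K = K, fq = fq, N = N,
                 cloud = cloud, n_influence = n_influence, params = params,
                 essential = NULL, periodic = NULL,
                 phi_field = NULL),
            class = "scalar_field_system")
}

#' Impose essential (Dirichlet) concentrations
#'
#' Thanks to the Kronecker-delta property of RPIM shape functions the
#' prescribed nodal values are imposed directly: at solve time each
#' constrained row is replaced by an identity row with the prescribed
#' value on the right-hand side.
#'
#' @param system A `scalar_field_system`.
#' @param bcs Data frame (or 2-column matrix) with columns `node`, `value`.
#' @return The system with the constraints recorded.
#' @export
apply_essential_bc <- function(system, bcs) {
  bcs <- as.data.frame(bcs)
  names(bcs)[1:2] <- c("node", "value")
  bcs$node <- as.integer(bcs$node)
  if (any(bcs$node < 1 | bcs$node > system$N))
    amech_stop("essential bc node id out of range", "invalid_argument")
  all_bc <- rbind(system$essential, bcs)
  dup <- duplicated(all_bc$node) | duplicated(all_bc$node, fromLast = TRUE)
  if (any(dup)) {
    conf <- stats::aggregate(value ~ node, all_bc[dup, ],
                             function(v) length(unique(v)))
    if (any(conf$value > 1))
      amech_stop(sprintf("conflicting essential values on node(s) %s",
                         paste(conf$node[conf$value > 1], collapse = ", ")),
                 "conflict")
    all_bc <- all_bc[!duplicated(all_bc$node), ]
  }
  if (!is.null(system$periodic) &&
      any(unlist(system$periodic) %in% all_bc$node))
    amech_stop("node is both essential-constrained and in a periodic pair",
               "conflict")
  system$essential <- all_bc
  system
}

#' Impose periodic boundary conditions
#'
#' Realises the intent of tying paired boundary nodes to a common value by
#' master-slave elimination: each slave degree of freedom is folded into
#' its master, which keeps the reduced system well posed (replacing both
#' paired rows by the same two-term constraint would make the matrix
#' singular).
#'
#' @param system A `scalar_field_system`.
#' @param pairs Two-column matrix or data frame of (master, slave) node ids.
#' @return The system with the pairs recorded.
#' @export
apply_periodic_bc <- function(system, pairs) {
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  if (any(pairs[, 1] == pairs[, 2]))
    amech_stop("periodic pair members must be distinct", "invalid_argument")
  if (!is.null(system$essential) &&
      any(pairs %in% system$essential$node))
    amech_stop("periodic pair member is essential-constrained", "conflict")
  system$periodic <- rbind(system$periodic, pairs)
  system
}

# Direct sparse solve through an explicit LU factorisation (much faster
# than the generic solve() dispatch for dgCMatrix with a vector rhs).
sparse_lu_solve <- function(K, f) {
  as.numeric(Matrix::solve(Matrix::lu(K), f))
}

# Row replacement for essential values on a sparse matrix: zero the rows,
# put 1 on the diagonal.  O(nnz).
impose_rows <- function(K, idx) {
  N <- nrow(K)
  d <- rep(1, N); d[idx] <- 0
  Matrix::Diagonal(N, d) %*% K +
    Matrix::sparseMatrix(i = idx, j = idx, x = 1, dims = c(N, N))
}

#' Solve the assembled diffusion system
#'
#' @param system A `scalar_field_system` with essential conditions applied.
#' @return Numeric vector of nodal VEGF concentrations (g/mm^3) with a
#'   `residual` attribute (relative solver residual).
#' @export
solve_diffusion <- function(system) {
  if (is.null(system$essential) || nrow(system$essential) == 0L)
    amech_stop("no essential boundary conditions anywhere; the diffusion system is underdetermined",
               "underdetermined")
  N <- system$N
  K <- system$K
  f <- system$fq
  Tmap <- NULL
  if (!is.null(system$periodic)) {
    keep <- setdiff(seq_len(N), system$periodic[, 2])
    colof <- integer(N)
    colof[keep] <- seq_along(keep)
    colof[system$periodic[, 2]] <- colof[system$periodic[, 1]]
    Tmap <- Matrix::sparseMatrix(i = seq_len(N), j = colof, x = 1,
                                 dims = c(N, length(keep)))
    K <- Matrix::t(Tmap) %*% K %*% Tmap
    f <- as.numeric(Matrix::t(Tmap) %*% f)
    bc_idx <- colof[system$essential$node]
  } else {
    bc_idx <- system$essential$node
  }
  Kbc <- impose_rows(K, bc_idx)
  f[bc_idx] <- system$essential$value
  sol <- tryCatch(sparse_lu_solve(Kbc, f),
                  error = function(e) amech_stop(
                    paste("diffusion solve failed:", conditionMessage(e)),
                    "underdetermined"))
  phi <- if (is.null(Tmap)) sol else as.numeric(Tmap %*% sol)
  res <- sqrt(sum((as.numeric(Kbc %*% sol) - f)^2)) /
    max(sqrt(sum(f^2)), max(abs(system$essential$value)), 1e-300)
  attr(phi, "residual") <- res
  phi
}

plane_constitutive <- function(E, nu, plane = c("stress", "strain")) {
  plane <- match.arg(plane)
  if (plane == "stress") {
    E / (1 - nu^2) * matrix(c(1, nu, 0,
                              nu, 1, 0,
                              0, 0, (1 - nu) / 2), 3, 3)
  } else {
    E / ((1 + nu) * (1 - 2 * nu)) *
      matrix(c(1 - nu, nu, 0,
               nu, 1 - nu, 0,
               0, 0, (1 - 2 * nu) / 2), 3, 3)
  }
}

#' Assemble the linear elastostatic stiffness
#'
#' Plane-stress (default) Galerkin assembly K = sum_q B' c B w with the
#' RPIM strain matrix B built from the shape-function derivatives at each
#' integration point.  Degrees of freedom are interleaved (x1, y1, x2,
#' y2, ...).
#'
#' @param cloud A `nodal_cloud`.
#' @param int_mesh Background integration mesh.
#' @param E Young's modulus (MPa).
#' @param nu Poisson coefficient, in [0, 0.5).
#' @param plane `"stress"` (the printed constitutive form) or `"strain"`.
#' @param n_influence Influence-domain size.
#' @param params [mq_params()].
#' @return Object of class `elastic_system`.
#' @export
assemble_elasticity <- function(cloud, int_mesh, E, nu,
                                plane = c("stress", "strain"),
                                n_influence = 16L, params = mq_params()) {
  plane <- match.arg(plane)
  if (!is.numeric(E) || E <= 0)
    amech_stop("E must be positive", "invalid_argument")
  if (!is.numeric(nu) || nu < 0 || nu >= 0.5)
    amech_stop("nu must lie in [0, 0.5); nu >= 0.5 is incompressible",
               "incompressibility")
  cm <- plane_constitutive(E, nu, plane)
  N <- n_nodes(cloud)
  k <- min(n_influence, N)
  dom <- influence_domains(int_mesh$points, cloud, k)
  sh <- rpim_batch(int_mesh$points, cloud$coords, dom$idx, params = params)
  w <- int_mesh$weights
  a <- rep(seq_len(k), times = k)
  b <- rep(seq_len(k), each = k)
  DXa <- sh$dx[a, , drop = FALSE]; DXb <- sh$dx[b, , drop = FALSE]
  DYa <- sh$dy[a, , drop = FALSE]; DYb <- sh$dy[b, , drop = FALSE]
  wk <- rep(w, each = k * k)
  Ia <- dom$idx[a, , drop = FALSE]; Ib <- dom$idx[b, , drop = FALSE]
  # dof blocks: xx, xy, yx, yy
  Vxx <- (cm[1, 1] * DXa * DXb + cm[3, 3] * DYa * DYb) * wk
  Vxy <- (cm[1, 2] * DXa * DYb + cm[3, 3] * DYa * DXb) * wk
  Vyx <- (cm[1, 2] * DYa * DXb + cm[3, 3] * DXa * DYb) * wk
  Vyy <- (cm[2, 2] * DYa * DYb + cm[3, 3] * DXa * DXb) * wk
  ii <- c(2 * Ia - 1, 2 * Ia - 1, 2 * Ia, 2 * Ia)
  jj <- c(2 * Ib - 1, 2 * Ib,     2 * Ib - 1, 2 * Ib)
  xx <- c(Vxx, Vxy, Vyx, Vyy)
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(xx), dims = c(2 * N, 2 * N))
  structure(list(K = K, E = E, nu = nu, plane = plane, cmat = cm,
                 cloud = cloud, int_mesh = int_mesh,
                 neigh = dom$idx, dxm = sh$dx, dym = sh$dy,
                 n_influence = n_influence, params = params,
                 u_field = NULL),
            class = "elastic_system")
}

#' Solve the elastostatic problem
#'
#' @param system An `elastic_system`.
#' @param fixed_dofs Data frame with columns `node`, `dof` (1 = x, 2 = y)
#'   and optionally `value` (default 0): prescribed displacements.
#' @param tractions List of boundary loads, each
#'   `list(edge = "right", t = c(tx, ty))` in MPa; integrated with the
#'   shape-function values along the edge quadrature.
#' @return N x 2 matrix of nodal displacements (mm).
#' @export
solve_elasticity <- function(system, fixed_dofs, tractions = list()) {
  N <- n_nodes(system$cloud)
  fixed_dofs <- as.data.frame(fixed_dofs)
  if (is.null(fixed_dofs$value)) fixed_dofs$value <- 0
  gd <- 2L * fixed_dofs$node - 2L + as.integer(fixed_dofs$dof)
  f <- numeric(2 * N)
  for (tr in tractions) {
    eq <- build_edge_quadrature(system$cloud, tr$edge,
                                system$int_mesh$gauss_order)
    dom <- influence_domains(eq$points, system$cloud,
                             min(system$n_influence, N))
    sh <- rpim_batch(eq$points, system$cloud$coords, dom$idx,
                     params = system$params, deriv = FALSE)
    k <- nrow(dom$idx)
    vx <- as.vector(sh$phi) * rep(eq$weights * tr$t[1], each = k)
    vy <- as.vector(sh$phi) * rep(eq$weights * tr$t[2], each = k)
    ids <- as.vector(dom$idx)
    agg <- rowsum(cbind(vx, vy), group = ids)
    nid <- as.integer(rownames(agg))
    f[2 * nid - 1] <- f[2 * nid - 1] + agg[, 1]
    f[2 * nid]     <- f[2 * nid]     + agg[, 2]
  }
  Kbc <- impose_rows(system$K, gd)
  f[gd] <- fixed_dofs$value
  u <- tryCatch(sparse_lu_solve(Kbc, f),
                error = function(e) amech_stop(
                  "elasticity solve failed; constraints likely insufficient to remove rigid-body modes",
                  "rigid_body"))
  if (any(!is.finite(u)))
    amech_stop("non-finite displacements; insufficient constraints",
               "rigid_body")
  matrix(u, ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("ux", "uy")))
}

#' Recover stress and hydrostatic pressure at integration points
#'
#' Evaluates sigma = c B u at every integration point and the 2D
#' hydrostatic (mean in-plane) pressure (sigma_xx + sigma_yy) / 2,
#' positive in tension.
#'
#' @param system An `elastic_system`.
#' @param u_field N x 2 displacement matrix from [solve_elasticity()].
#' @return List with `stress` (m x 3: sxx, syy, sxy, MPa) and `pressure`
#'   (length m, MPa).
#' @export
recover_stress_and_pressure <- function(system, u_field) {
  k <- nrow(system$neigh); m <- ncol(system$neigh)
  Ux <- matrix(u_field[system$neigh, 1], k, m)
  Uy <- matrix(u_field[system$neigh, 2], k, m)
  ex <- colSums(system$dxm * Ux)
  ey <- colSums(system$dym * Uy)
  gxy <- colSums(system$dym * Ux + system$dxm * Uy)
  eps <- rbind(ex, ey, gxy)
  sig <- t(system$cmat %*% eps)
  colnames(sig) <- c("sxx", "syy", "sxy")
  list(stress = sig, pressure = (sig[, 1] + sig[, 2]) / 2)
}
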