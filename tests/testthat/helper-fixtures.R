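# Shared fixtures and independent oracles, built in code at test time.

# small regular cloud + mesh
small_setup <- function(nps = 6, side = 5, gauss = 3) {
  cloud <- build_regular_nodal_cloud(side, nps)
  mesh <- build_integration_mesh(cloud, gauss)
  list(cloud = cloud, mesh = mesh)
}

# brute-force k-nearest-neighbour oracle with the (distance, id) tie rule
knn_oracle <- function(point, coords, k) {
  d <- sqrt((coords[, 1] - point[1])^2 + (coords[, 2] - point[2])^2)
  order(d, seq_len(nrow(coords)))[seq_len(k)]
}

# 5-point finite-difference Laplace solve on the same regular grid with
# Dirichlet values on all boundary nodes (independent oracle for the
# uniform-diffusivity steady state)
fd_laplace_oracle <- function(cloud, boundary_values) {
  nps <- cloud$nodes_per_side
  N <- nps^2
  idx <- function(i, j) (j - 1L) * nps + i  # column-major like the cloud
  bnd <- which(!is.na(boundary_values))
  A <- matrix(0, N, N)
  b <- numeric(N)
  for (j in seq_len(nps)) for (i in seq_len(nps)) {
    n <- idx(i, j)
    if (n %in% bnd) {
      A[n, n] <- 1; b[n] <- boundary_values[n]
    } else {
      A[n, n] <- -4
      A[n, idx(i - 1L, j)] <- 1
      A[n, idx(i + 1L, j)] <- 1
      A[n, idx(i, j - 1L)] <- 1
      A[n, idx(i, j + 1L)] <- 1
    }
  }
  solve(A, b)
}

# bilinear 4-node (Q4) finite-element stiffness for one square cell,
# 2 x 2 Gauss, plane stress; node order (0,0), (h,0), (0,h), (h,h) with
# interleaved dofs -- an independent hand-assembled oracle
q4_stiffness <- function(h, E, nu) {
  cm <- E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2),
                                3, 3)
  gp <- c(-1, 1) / sqrt(3)
  K <- matrix(0, 8, 8)
  for (xi in gp) for (eta in gp) {
    # shape function derivatives on [-1,1]^2, node order (-,-),(+,-),(-,+),(+,+)
    dNdxi <- c(-(1 - eta), (1 - eta), -(1 + eta), (1 + eta)) / 4
    dNdeta <- c(-(1 - xi), -(1 + xi), (1 - xi), (1 + xi)) / 4
    dNdx <- dNdxi * 2 / h
    dNdy <- dNdeta * 2 / h
    B <- matrix(0, 3, 8)
    for (a in 1:4) {
      B[1, 2 * a - 1] <- dNdx[a]
      B[2, 2 * a] <- dNdy[a]
      B[3, 2 * a - 1] <- dNdy[a]
      B[3, 2 * a] <- dNdx[a]
    }
    K <- K + t(B) %*% cm %*% B * (h / 2)^2
  }
  K
}

# evaluate the RPIM interpolant of nodal values at arbitrary points
interp_at <- function(points, cloud, values, n = 16) {
  vapply(seq_len(nrow(points)), function(q) {
    dom <- find_influence_domain(points[q, ], cloud,
                                 min(n, nrow(cloud$coords)))
    sh <- shape_functions_at(points[q, ], dom, cloud)
    sum(sh$phi * values[dom$node_indices])
  }, numeric(1))
}

# fast scenario override for engine unit tests (coarser cloud)
coarse_example1 <- function(...) {
  scenario_factory("example1", nodes_per_side = 21L, ...)
}
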