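test_that("diffusion stiffness is symmetric with zero row sums", {
  s <- small_setup(11)
  sys <- assemble_diffusion(s$cloud, s$mesh, 1.0)
  expect_lt(max(abs(sys$K - Matrix::t(sys$K))) / max(abs(sys$K)), 1e-10)
  # constant field in the null space before boundary conditions
  expect_lt(max(abs(sys$K %*% rep(1, sys$N))) / max(abs(sys$K)), 1e-8)
  # D = 0 gives a zero operator
  sys0 <- assemble_diffusion(s$cloud, s$mesh, 0)
  expect_equal(max(abs(sys0$K)), 0)
  expect_error(assemble_diffusion(s$cloud, s$mesh, -1),
               class = "instability")
})

test_that("solved field matches a finite-difference oracle on a coarse grid", {
  s <- small_setup(6)
  cl <- s$cloud
  # x^2 - y^2 is harmonic and the 5-point stencil is exact for quadratics,
  # so the FD oracle returns the exact steady state
  harm <- cl$coords[, 1]^2 - cl$coords[, 2]^2
  onb <- cl$coords[, 1] %in% c(0, 5) | cl$coords[, 2] %in% c(0, 5)
  bvals <- ifelse(onb, harm, NA)
  oracle <- fd_laplace_oracle(cl, bvals)
  sys <- assemble_diffusion(cl, s$mesh, 1.0)
  sys <- apply_essential_bc(sys, data.frame(node = which(onb),
                                            value = harm[onb]))
  phi <- solve_diffusion(sys)
  rms <- sqrt(mean((phi - oracle)^2)) / diff(range(oracle))
  expect_lt(rms, 0.02)
})

test_that("essential values are attained exactly and obey the maximum principle", {
  s <- small_setup(11)
  sys <- assemble_diffusion(s$cloud, s$mesh, 1.16e-6)
  onb <- which(s$cloud$coords[, 2] %in% c(0, 5))
  lum <- onb[s$cloud$coords[onb, 2] == 0]
  rel <- onb[s$cloud$coords[onb, 2] == 5]
  sys <- apply_essential_bc(sys, data.frame(
    node = c(lum, rel),
    value = c(rep(2.35e-13, length(lum)), rep(6.43e-13, length(rel)))))
  phi <- solve_diffusion(sys)
  expect_equal(unname(phi[lum]), rep(2.35e-13, length(lum)))
  expect_equal(unname(phi[rel]), rep(6.43e-13, length(rel)))
  expect_true(all(phi >= 2.35e-13 - 1e-20 & phi <= 6.43e-13 + 1e-20))

  # constant prescriptions give the constant solution
  sysc <- assemble_diffusion(s$cloud, s$mesh, 1.0)
  allb <- which(s$cloud$coords[, 1] %in% c(0, 5) |
                s$cloud$coords[, 2] %in% c(0, 5))
  sysc <- apply_essential_bc(sysc, data.frame(node = allb, value = 2.35e-13))
  expect_equal(as.vector(solve_diffusion(sysc)), rep(2.35e-13, sysc$N),
               tolerance = 1e-10)

  expect_error(apply_essential_bc(sys, data.frame(node = lum[1], value = 1)),
               class = "conflict")
  expect_error(solve_diffusion(assemble_diffusion(s$cloud, s$mesh, 1.0)),
               class = "underdetermined")
})

test_that("a linear gradient between two faces halves at the centre", {
  s <- small_setup(11)
  left <- which(s$cloud$coords[, 1] == 0)
  right <- which(s$cloud$coords[, 1] == 5)
  sys <- assemble_diffusion(s$cloud, s$mesh, 1.0)
  sys <- apply_essential_bc(sys, data.frame(
    node = c(left, right), value = c(rep(0, length(left)),
                                     rep(1, length(right)))))
  phi <- solve_diffusion(sys)
  ctr <- which(s$cloud$coords[, 1] == 2.5 & s$cloud$coords[, 2] == 2.5)
  expect_equal(unname(phi[ctr]), 0.5, tolerance = 1e-3)
})

test_that("a two-region diffusivity splits the drop like series resistances", {
  s <- small_setup(11)
  Dq <- ifelse(s$mesh$points[, 1] < 2.5, 1, 2)
  left <- which(s$cloud$coords[, 1] == 0)
  right <- which(s$cloud$coords[, 1] == 5)
  sys <- assemble_diffusion(s$cloud, s$mesh, Dq)
  sys <- apply_essential_bc(sys, data.frame(
    node = c(left, right), value = c(rep(0, length(left)),
                                     rep(1, length(right)))))
  phi <- solve_diffusion(sys)
  mid <- which(s$cloud$coords[, 1] == 2.5 & s$cloud$coords[, 2] == 2.5)
  expect_equal(unname(phi[mid]), 2 / 3, tolerance = 0.02)
})

test_that("halving the spacing reduces the two-region error", {
  err <- sapply(c(6, 11), function(nps) {
    s <- small_setup(nps)
    Dq <- ifelse(s$mesh$points[, 1] < 2.5, 1, 2)
    left <- which(s$cloud$coords[, 1] == 0)
    right <- which(s$cloud$coords[, 1] == 5)
    sys <- assemble_diffusion(s$cloud, s$mesh, Dq)
    sys <- apply_essential_bc(sys, data.frame(
      node = c(left, right), value = c(rep(0, length(left)),
                                       rep(1, length(right)))))
    phi <- solve_diffusion(sys)
    # analytic: piecewise linear, phi(2.5) = 2/3
    x <- s$cloud$coords[, 1]
    exact <- ifelse(x <= 2.5, x / 2.5 * 2 / 3, 2 / 3 + (x - 2.5) / 2.5 / 3)
    sqrt(mean((phi - exact)^2))
  })
  expect_lt(err[2], err[1])
})

test_that("periodic pairs equalise the solution and match a Lagrange oracle", {
  s <- small_setup(6)
  cl <- s$cloud
  bottom <- which(cl$coords[, 2] == 0)
  top <- which(cl$coords[, 2] == 5)
  lefts <- which(cl$coords[, 1] == 0 & !cl$coords[, 2] %in% c(0, 5))
  rights <- which(cl$coords[, 1] == 5 & !cl$coords[, 2] %in% c(0, 5))
  sys <- assemble_diffusion(cl, s$mesh, 1.0)
  sys <- apply_essential_bc(sys, data.frame(
    node = c(bottom, top), value = c(rep(0, length(bottom)),
                                     rep(1, length(top)))))
  sys <- apply_periodic_bc(sys, cbind(lefts, rights))
  phi <- solve_diffusion(sys)
  expect_equal(unname(phi[lefts]), unname(phi[rights]), tolerance = 1e-10)

  # single pair in an asymmetric problem: equality plus Lagrange oracle
  sys2 <- assemble_diffusion(cl, s$mesh, 1.0)
  corner <- which(cl$coords[, 1] == 0 & cl$coords[, 2] == 0)
  farc <- which(cl$coords[, 1] == 5 & cl$coords[, 2] == 5)
  othr <- which(cl$coords[, 1] == 5 & cl$coords[, 2] == 0)
  sys2 <- apply_essential_bc(sys2, data.frame(node = c(corner, farc),
                                              value = c(0, 1)))
  i <- which(cl$coords[, 1] == 0 & cl$coords[, 2] == 2)
  j <- which(cl$coords[, 1] == 5 & cl$coords[, 2] == 3)
  sys2p <- apply_periodic_bc(sys2, cbind(i, j))
  phi2 <- solve_diffusion(sys2p)
  expect_equal(unname(phi2[i]), unname(phi2[j]), tolerance = 1e-12)
  # Lagrange-multiplier formulation of the same constraint
  N <- sys2$N
  Kd <- as.matrix(sys2$K)
  bcn <- c(corner, farc); bcv <- c(0, 1)
  Kd[bcn, ] <- 0; Kd[cbind(bcn, bcn)] <- 1
  C <- rep(0, N); C[i] <- 1; C[j] <- -1
  A <- rbind(cbind(Kd, c(rep(0, N))), c(C, 0))
  A[seq_len(N), N + 1] <- C
  b <- c(rep(0, N), 0); b[bcn] <- bcv
  lag <- solve(A, b)[seq_len(N)]
  expect_equal(as.vector(phi2), unname(lag), tolerance = 1e-8)

  expect_error(apply_periodic_bc(sys2, cbind(corner, j)),
               class = "conflict")
  expect_error(apply_periodic_bc(sys2, cbind(i, i)),
               class = "invalid_argument")
})

test_that("mirror-symmetric inputs give mirror-symmetric fields", {
  s <- small_setup(11)
  cl <- s$cloud
  bottom <- which(cl$coords[, 2] == 0)
  top <- which(cl$coords[, 2] == 5)
  sys <- assemble_diffusion(cl, s$mesh, 1.0)
  sys <- apply_essential_bc(sys, data.frame(
    node = c(bottom, top), value = c(rep(0, length(bottom)),
                                     rep(1, length(top)))))
  lefts <- which(cl$coords[, 1] == 0 & !cl$coords[, 2] %in% c(0, 5))
  rights <- which(cl$coords[, 1] == 5 & !cl$coords[, 2] %in% c(0, 5))
  sys <- apply_periodic_bc(sys, cbind(lefts, rights))
  phi <- solve_diffusion(sys)
  # mirror symmetry holds up to the influence-domain tie rule (ties are
  # broken by ascending node id, which is not mirror-invariant)
  mirror <- function(p) c(5 - p[1], p[2])
  for (n in sample(seq_len(nrow(cl$coords)), 20)) {
    mcoord <- mirror(cl$coords[n, ])
    mn <- which(abs(cl$coords[, 1] - mcoord[1]) < 1e-12 &
                abs(cl$coords[, 2] - mcoord[2]) < 1e-12)
    expect_equal(unname(phi[n]), unname(phi[mn]), tolerance = 1e-3)
  }
})

test_that("elastic stiffness is symmetric with energy-free rigid modes", {
  s <- small_setup(6)
  es <- assemble_elasticity(s$cloud, s$mesh, E = 1, nu = 0.3)
  expect_lt(max(abs(es$K - Matrix::t(es$K))) / max(abs(es$K)), 1e-10)
  for (tr in list(c(1, 0), c(0, 1), c(0.7, -0.2))) {
    u <- rep(tr, nrow(s$cloud$coords))
    expect_lt(abs(sum(u * as.numeric(es$K %*% u))), 1e-10)
  }
  expect_error(assemble_elasticity(s$cloud, s$mesh, E = 1, nu = 0.5),
               class = "incompressibility")
  expect_error(assemble_elasticity(s$cloud, s$mesh, E = -1, nu = 0.3),
               class = "invalid_argument")
})

test_that("uniaxial traction passes the elasticity patch test", {
  s <- small_setup(6)
  cl <- s$cloud
  E <- 0.01; nu <- 0.45; t <- 0.002
  es <- assemble_elasticity(cl, s$mesh, E, nu)
  left <- which(cl$coords[, 1] == 0)
  fixed <- data.frame(node = left, dof = 1, value = 0)
  bl <- which(cl$coords[, 1] == 0 & cl$coords[, 2] == 0)
  fixed <- rbind(fixed, data.frame(node = bl, dof = 2, value = 0))
  u <- solve_elasticity(es, fixed, list(list(edge = "right", t = c(t, 0))))
  rec <- recover_stress_and_pressure(es, u)
  expect_equal(mean(rec$stress[, "sxx"]), t, tolerance = 0.01)
  # pointwise stress carries a boundary layer from the essential-edge
  # nonconformity of the meshless test space; interior of the patch is flat
  expect_lt(max(abs(rec$stress[, "sxx"] - t)) / t, 0.05)
  # Hooke's law end displacement u_x(L) = t L / E
  right <- which(cl$coords[, 1] == 5)
  expect_equal(mean(u[right, 1]), t * 5 / E, tolerance = 0.01)
  # hydrostatic pressure of the uniaxial state is t/2
  expect_equal(mean(rec$pressure), t / 2, tolerance = 0.01)

  expect_error(solve_elasticity(es, fixed[1, ]), class = "rigid_body")
})

test_that("equibiaxial traction produces a uniform hydrostatic pressure", {
  s <- small_setup(6)
  cl <- s$cloud
  E <- 0.01; nu <- 0.45; t <- 0.0067
  es <- assemble_elasticity(cl, s$mesh, E, nu)
  fixed <- rbind(
    data.frame(node = which(cl$coords[, 1] == 0), dof = 1, value = 0),
    data.frame(node = which(cl$coords[, 2] == 0), dof = 2, value = 0))
  u <- solve_elasticity(es, fixed,
                        list(list(edge = "right", t = c(t, 0)),
                             list(edge = "top", t = c(0, t))))
  rec <- recover_stress_and_pressure(es, u)
  expect_equal(mean(rec$pressure), t, tolerance = 0.01)
  expect_lt(max(abs(rec$pressure - t)) / t, 0.05)
})

test_that("pure shear has zero hydrostatic pressure", {
  s <- small_setup(6)
  es <- assemble_elasticity(s$cloud, s$mesh, E = 1, nu = 0.3)
  gam <- 0.01
  u <- cbind(gam * s$cloud$coords[, 2], 0)
  rec <- recover_stress_and_pressure(es, u)
  expect_lt(max(abs(rec$pressure)), 1e-12)
  expect_equal(unname(rec$stress[, "sxy"]),
               rep(gam * 1 / (2 * (1 + 0.3)), nrow(s$mesh$points)),
               tolerance = 1e-6)
})

test_that("single-cell strain energy matches a hand-assembled Q4 element", {
  cl <- build_regular_nodal_cloud(1, 2)
  im <- build_integration_mesh(cl, 2)
  E <- 2.0; nu <- 0.25
  es <- assemble_elasticity(cl, im, E, nu, n_influence = 4)
  Kq4 <- q4_stiffness(1, E, nu)
  # cloud node order (0,0),(1,0),(0,1),(1,1) equals the oracle's
  for (r in 1:5) {
    set.seed(r)
    ab <- runif(6, -1, 1)
    ux <- ab[1] + ab[2] * cl$coords[, 1] + ab[3] * cl$coords[, 2]
    uy <- ab[4] + ab[5] * cl$coords[, 1] + ab[6] * cl$coords[, 2]
    u <- as.vector(rbind(ux, uy))
    e_rpim <- sum(u * as.numeric(es$K %*% u))
    e_fem <- sum(u * (Kq4 %*% u))
    expect_equal(e_rpim, e_fem, tolerance = 1e-6)
  }
})
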