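# Capillary network growth: endothelial tip cells migrate up the VEGF
# gradient, branch according to an order-dependent phenomenological law
# (halved threshold inside a compressed region), and stop at the domain
# boundary, the VEGF release region, or on close approach to another
# capillary (anastomosis).

# clockwise rotation by theta, matching the printed migration matrix
# [cos  sin; -sin  cos]
rotate2 <- function(v, theta) {
  c(cos(theta) * v[1] + sin(theta) * v[2],
    -sin(theta) * v[1] + cos(theta) * v[2])
}

#' Order-dependent branching law
#'
#' Threshold distance between consecutive branches:
#' `threshold(order) = base_distance * 2^(1 - order)`, strictly decreasing
#' with capillary order (first-order, large-calibre vessels branch least
#' often).  Inside a compressed region the effective threshold is
#' multiplied by `compression_factor`.
#'
#' @param base_distance d0 in mm.
#' @param compression_factor Multiplier applied under compression (0.5:
#'   the branching distance is halved).
#' @return Object of class `branching_law` with a `threshold(order)`
#'   function.
#' @export
branching_law <- function(base_distance = 1.0, compression_factor = 0.5) {
  structure(list(base_distance = base_distance,
                 compression_factor = compression_factor,
                 threshold = function(order) base_distance * 2^(1 - order)),
            class = "branching_law")
}

#' VEGF concentration gradient at a position
#'
#' Evaluates grad(Phi) through the RPIM shape-function derivatives at an
#' arbitrary position; for any field increasing toward the VEGF source the
#' gradient points toward the source.
#'
#' @param position Length-2 position (mm).
#' @param phi_field Nodal concentration vector.
#' @param cloud The `nodal_cloud` carrying `phi_field`.
#' @param n_influence Influence-domain size.
#' @param params [mq_params()].
#' @return `c(gx, gy)` in (g/mm^3)/mm.  Signals a classed
#'   `stalled_gradient` error when the gradient norm falls below 1e-30.
#' @export
vegf_gradient_at <- function(position, phi_field, cloud, n_influence = 16L,
                             params = mq_params()) {
  dom <- find_influence_domain(position, cloud,
                               min(n_influence, n_nodes(cloud)))
  sh <- shape_functions_at(position, dom, cloud, params)
  g <- c(sum(sh$dphi_dx * phi_field[dom$node_indices]),
         sum(sh$dphi_dy * phi_field[dom$node_indices]))
  if (sqrt(sum(g^2)) < stall_floor(phi_field[dom$node_indices]))
    amech_stop("VEGF gradient vanished at the tip position",
               "stalled_gradient")
  g
}

# A gradient is treated as vanished below an absolute floor of 1e-30
# plus a relative floor tied to the roundoff of the interpolant (a
# numerically constant field differentiates to ~1e-12 of its magnitude
# per mm, not to exact zero).
stall_floor <- function(phi_local) {
  1e-30 + 1e-10 * max(abs(phi_local))
}

#' Advance a tip cell one migration step
#'
#' The gradient direction is rotated by `theta` (clockwise for positive
#' theta), normalised, and the tip moves one step of `step_length` (the
#' average cell-to-cell distance) along it.
#'
#' @param position Current tip position.
#' @param gradient VEGF gradient at the tip.
#' @param theta Rotation angle in radians.
#' @param step_length Step length in mm, > 0.
#' @return The new position.
#' @export
migration_step <- function(position, gradient, theta = 0,
                           step_length = 0.1) {
  if (step_length <= 0)
    amech_stop("step_length must be positive", "invalid_argument")
  if (sqrt(sum(gradient^2)) < 1e-30)
    amech_stop("cannot step on a vanished gradient", "stalled_gradient")
  nmod <- rotate2(gradient, theta)
  u <- nmod / sqrt(sum(nmod^2))
  as.numeric(position) + step_length * u
}

#' Branching decision for a tip cell
#'
#' A branch occurs when the distance travelled since the previous branch
#' exceeds the order-dependent threshold; inside the compressed region the
#' threshold is reduced by the law's compression factor.
#'
#' @param tip List with `position`, `order`, `distance_since_branch`.
#' @param law A [branching_law()].
#' @param region A [loaded_region()] or `NULL`.
#' @param compression_active Whether compressive loading is applied.
#' @return `TRUE` when the tip should branch.
#' @export
check_branching <- function(tip, law, region = NULL,
                            compression_active = FALSE) {
  thr <- law$threshold(tip$order)
  if (compression_active && !is.null(region)) {
    d2 <- sum((as.numeric(tip$position) - region$center)^2)
    if (d2 <= region$radius^2) thr <- thr * law$compression_factor
  }
  tip$distance_since_branch > thr
}

point_in_rects <- function(pos, rects) {
  for (r in rects)
    if (pos[1] >= r[1] && pos[1] <= r[3] &&
        pos[2] >= r[2] && pos[2] <= r[4]) return(TRUE)
  FALSE
}

#' Stop criteria for a migrating tip cell
#'
#' A tip stops when it reaches the domain boundary, enters the VEGF
#' release region, or comes within half the internodal distance of
#' another endothelial (capillary) node -- anastomosis.  The tip's own
#' trailing nodes within one step are excluded from the anastomosis test.
#'
#' @param position Candidate tip position.
#' @param capillary_nodes m x 2 matrix of traced capillary node positions.
#' @param bounds Domain bounds (xmin, ymin, xmax, ymax).
#' @param release_rects List of release-region rectangles
#'   (xmin, ymin, xmax, ymax).
#' @param internodal Internodal distance (mm).
#' @param exclude Row indices of `capillary_nodes` to ignore (the tip's
#'   own trailing segment endpoints).
#' @return List with `stop` (logical) and `reason` (`"boundary"`,
#'   `"release_region"`, `"anastomosis"` or `NA`).
#' @export
check_stop <- function(position, capillary_nodes, bounds, release_rects,
                       internodal = 0.1, exclude = integer(0)) {
  if (point_in_rects(position, release_rects))
    return(list(stop = TRUE, reason = "release_region"))
  if (position[1] <= bounds[1] || position[1] >= bounds[3] ||
      position[2] <= bounds[2] || position[2] >= bounds[4])
    return(list(stop = TRUE, reason = "boundary"))
  if (!is.null(capillary_nodes) && nrow(capillary_nodes) > 0) {
    d2 <- (capillary_nodes[, 1] - position[1])^2 +
          (capillary_nodes[, 2] - position[2])^2
    if (length(exclude)) d2[exclude] <- Inf
    if (any(d2 < (internodal / 2)^2))
      return(list(stop = TRUE, reason = "anastomosis"))
  }
  list(stop = FALSE, reason = NA_character_)
}

# pad a square dgCMatrix with empty rows/columns up to dimension N
pad_sparse <- function(K, N) {
  n0 <- nrow(K)
  if (n0 == N) return(K)
  methods::new("dgCMatrix", i = K@i,
               p = c(K@p, rep(K@p[length(K@p)], N - n0)),
               x = K@x, Dim = c(N, N))
}

# Solver context: everything about the discretisation and the loaded
# scenario that does not change while the network grows.  Building it once
# per experiment arm and reusing it across seeds avoids re-assembling the
# base stiffness for every run.
sim_context <- function(config) {
  cloud <- build_regular_nodal_cloud(config$side, config$nodes_per_side)
  mesh <- build_integration_mesh(cloud, config$gauss_order)
  region <- NULL
  alpha_signed <- 0
  if (config$loading != "none") {
    alpha_signed <- if (config$loading == "compression")
      -abs(config$alpha) else abs(config$alpha)
    region <- loaded_region(config$region_center, config$region_radius,
                            pressure = if (config$loading == "compression")
                              -abs(config$pressure) else abs(config$pressure),
                            alpha = alpha_signed, allow_any_alpha = TRUE)
    check_region_inside(region, cloud)
    dmap <- modified_diffusion_map(config$D_base, region, alpha_signed,
                                   int_mesh = mesh)
  } else {
    dmap <- config$D_base
  }
  Dv <- withCallingHandlers(
    resolve_diffusivity(dmap, mesh),
    warning = function(w) invokeRestart("muffleWarning"))
  k <- config$n_influence
  params <- config$mq
  vol <- influence_domains(mesh$points, cloud, k)
  sh <- rpim_batch(mesh$points, cloud$coords, vol$idx, params = params)
  tr <- diffusion_triplets(vol$idx, sh$dx, sh$dy, mesh$weights * Dv)
  N <- n_nodes(cloud)
  K0 <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(N, N))
  # essential concentrations: lumen and release region nodes
  lum <- which(apply(cloud$coords, 1, point_in_rects, config$lumen_rects))
  rel <- which(apply(cloud$coords, 1, point_in_rects, config$release_rects))
  bc <- data.frame(node = c(lum, rel),
                   value = c(rep(config$conc_lumen, length(lum)),
                             rep(config$conc_release, length(rel))))
  bc <- bc[!duplicated(bc$node), ]
  list(config = config, cloud = cloud, mesh = mesh, region = region,
       alpha_signed = alpha_signed, dmap = dmap, Dv = Dv,
       vol = list(idx = vol$idx, rk = vol$rk),
       K0 = K0, bc = bc, params = params, k = k)
}

# recompute the diffusion (and edge-consistency) contributions of a set of
# integration points against the current cloud, returning the triplet
# delta (new minus old) and the updated neighbourhoods
stale_delta <- function(pts, wfac, old_idx, coords, k, params) {
  kn <- cpp_knn(pts, coords, k)
  old_sh <- rpim_batch(pts, coords, old_idx, params = params)
  new_sh <- rpim_batch(pts, coords, kn$idx, params = params)
  tro <- diffusion_triplets(old_idx, old_sh$dx, old_sh$dy, -wfac)
  trn <- diffusion_triplets(kn$idx, new_sh$dx, new_sh$dy, wfac)
  list(i = c(tro$i, trn$i), j = c(tro$j, trn$j), x = c(tro$x, trn$x),
       idx = kn$idx, rk = kn$dist[k, ])
}

#' Grow a capillary network
#'
#' Iterative mechano-chemical growth loop: at every iteration the VEGF
#' concentration field is solved on the current nodal cloud (with the
#' pressure-modified diffusivity map), every active tip cell advances one
#' step up the concentration gradient (optionally randomly rotated), new
#' tip positions are inserted as nodes, the branching and stop rules are
#' applied, and the boundary concentrations are re-imposed.  The loop ends
#' when no tips remain active or `max_iter` is reached (partial network
#' with a warning).  Fully deterministic for a given seed.
#'
#' @param config A [scenario_config()] (or preset from
#'   [scenario_factory()]).
#' @param context Optional pre-built solver context (reused across seeds
#'   by [run_experiment()]).
#' @return List with `network` (a `capillary_network`) and `fields`
#'   (final nodal concentrations, the cloud they live on, and the
#'   diffusivity map).
#' @export
run_simulation <- function(config, context = NULL) {
  if (is.null(context)) context <- sim_context(config)
  set.seed(config$seed)
  cfg <- config
  cloud0 <- context$cloud
  bounds <- cloud0$bounds
  coords <- cloud0$coords
  dup_tol <- cloud0$duplicate_tol
  K <- context$K0
  vol_idx <- context$vol$idx
  vol_rk <- context$vol$rk
  bc_nodes <- context$bc$node
  bc_vals <- context$bc$value
  k <- context$k
  params <- context$params
  law <- branching_law(cfg$d0, cfg$compression_factor)
  compression <- identical(cfg$loading, "compression")
  step <- cfg$step_length
  theta_fun <- if (identical(cfg$theta_mode, "uniform"))
    function() stats::runif(1, -cfg$theta_range, cfg$theta_range)
  else function() 0

  ns <- nrow(cfg$sprouts)
  tips <- vector("list", 2 * ns)
  cap_pos <- matrix(NA_real_, 4096, 2)
  cap_owner <- integer(4096); cap_step <- integer(4096); ncap <- 0L
  push_cap <- function(pos, owner, it) {
    if (ncap + 1L > nrow(cap_pos)) {
      cap_pos <<- rbind(cap_pos, matrix(NA_real_, nrow(cap_pos), 2))
      cap_owner <<- c(cap_owner, integer(length(cap_owner)))
      cap_step <<- c(cap_step, integer(length(cap_step)))
    }
    ncap <<- ncap + 1L
    cap_pos[ncap, ] <<- pos; cap_owner[ncap] <<- owner
    cap_step[ncap] <<- it
  }
  for (s in seq_len(ns)) {
    tips[[s]] <- list(id = s, position = as.numeric(cfg$sprouts[s, ]),
                      order = 1L, dist = 0, active = TRUE,
                      pending_dir = NULL, stop_reason = NA_character_,
                      parent_segment = NA_integer_)
    push_cap(cfg$sprouts[s, ], s, 0L)
  }
  ntips <- ns
  segs <- list(); nseg <- 0L
  branches <- list(); nbr <- 0L
  new_nodes <- NULL

  it <- 0L
  phi <- NULL
  while (any(vapply(tips[seq_len(ntips)], `[[`, TRUE, "active")) &&
         it < cfg$max_iter) {
    it <- it + 1L
    N <- nrow(coords)
    # --- solve the VEGF field on the current cloud ---
    free <- seq_len(N)[-bc_nodes]
    rhs <- -as.numeric(K[free, bc_nodes, drop = FALSE] %*% bc_vals)
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(K[free, free]),
                           LDL = FALSE, super = TRUE)
    phi <- numeric(N)
    phi[bc_nodes] <- bc_vals
    phi[free] <- as.numeric(Matrix::solve(ch, rhs))
    # --- advance tips ---
    act <- which(vapply(tips[seq_len(ntips)], `[[`, TRUE, "active"))
    tippos <- do.call(rbind, lapply(tips[act], `[[`, "position"))
    kn <- cpp_knn(tippos, coords, min(k, N))
    sh <- rpim_batch(tippos, coords, kn$idx, params = params)
    inserted <- NULL
    for (ii in seq_along(act)) {
      tid <- act[ii]
      tip <- tips[[tid]]
      g <- c(sum(sh$dx[, ii] * phi[kn$idx[, ii]]),
             sum(sh$dy[, ii] * phi[kn$idx[, ii]]))
      if (!is.null(tip$pending_dir)) {
        u <- tip$pending_dir / sqrt(sum(tip$pending_dir^2))
        tip$pending_dir <- NULL
      } else if (sqrt(sum(g^2)) < stall_floor(phi[kn$idx[, ii]])) {
        tip$active <- FALSE; tip$stop_reason <- "stalled"
        tips[[tid]] <- tip
        next
      } else {
        nmod <- rotate2(g, theta_fun())
        u <- nmod / sqrt(sum(nmod^2))
      }
      newp <- tip$position + step * u
      newp <- pmin(pmax(newp, bounds[c(1, 2)]), bounds[c(3, 4)])
      own <- which(cap_owner[seq_len(ncap)] == tip$id)
      excl <- own[cap_step[own] >= it - 1L]
      st <- check_stop(newp, cap_pos[seq_len(ncap), , drop = FALSE],
                       bounds, cfg$release_rects, cloud0$spacing,
                       exclude = excl)
      nseg <- nseg + 1L
      segs[[nseg]] <- c(tip$position, newp, tip$order, it)
      push_cap(newp, tip$id, it)
      # insert the new position as a node unless occupied
      d2n <- (coords[, 1] - newp[1])^2 + (coords[, 2] - newp[2])^2
      if (min(d2n) >= dup_tol^2) {
        coords <- rbind(coords, newp, deparse.level = 0)
        inserted <- rbind(inserted, newp)
      }
      tip$position <- newp
      tip$dist <- tip$dist + step
      tip$last_dir <- u
      if (st$stop) {
        tip$active <- FALSE; tip$stop_reason <- st$reason
        tips[[tid]] <- tip
        next
      }
      if (check_branching(list(position = newp, order = tip$order,
                               distance_since_branch = tip$dist),
                          law, context$region, compression)) {
        nbr <- nbr + 1L
        branches[[nbr]] <- c(newp, it)
        tip$active <- FALSE; tip$stop_reason <- "branched"
        corder <- min(tip$order + 1L, 3L)
        for (sgn in c(-1, 1)) {
          ntips <- ntips + 1L
          if (ntips > length(tips)) tips <- c(tips, vector("list", ntips))
          tips[[ntips]] <- list(
            id = ntips, position = newp, order = corder, dist = 0,
            active = TRUE,
            pending_dir = rotate2(u, sgn * cfg$branch_angle),
            stop_reason = NA_character_, parent_segment = nseg)
          push_cap(newp, ntips, it)
        }
      }
      tips[[tid]] <- tip
    }
    # --- incremental stiffness update for inserted nodes ---
    if (!is.null(inserted) && nrow(inserted) > 0) {
      N <- nrow(coords)
      K <- pad_sparse(K, N)
      stale_v <- rep(FALSE, ncol(vol_idx))
      for (r in seq_len(nrow(inserted))) {
        d <- sqrt((context$mesh$points[, 1] - inserted[r, 1])^2 +
                  (context$mesh$points[, 2] - inserted[r, 2])^2)
        stale_v <- stale_v | (d < vol_rk)
      }
      tr_i <- integer(0); tr_j <- integer(0); tr_x <- numeric(0)
      if (any(stale_v)) {
        svi <- which(stale_v)
        sd <- stale_delta(context$mesh$points[svi, , drop = FALSE],
                          context$mesh$weights[svi] * context$Dv[svi],
                          vol_idx[, svi, drop = FALSE], coords, k, params)
        vol_idx[, svi] <- sd$idx
        vol_rk[svi] <- sd$rk
        tr_i <- c(tr_i, sd$i); tr_j <- c(tr_j, sd$j); tr_x <- c(tr_x, sd$x)
      }
      if (length(tr_i))
        K <- K + Matrix::sparseMatrix(i = tr_i, j = tr_j, x = tr_x,
                                      dims = c(N, N))
    }
  }
  # final field on the final cloud (the loop solves before inserting the
  # last nodes)
  if (nrow(coords) > length(phi)) {
    N <- nrow(coords)
    free <- seq_len(N)[-bc_nodes]
    rhs <- -as.numeric(K[free, bc_nodes, drop = FALSE] %*% bc_vals)
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(K[free, free]),
                           LDL = FALSE, super = TRUE)
    phi <- numeric(N)
    phi[bc_nodes] <- bc_vals
    phi[free] <- as.numeric(Matrix::solve(ch, rhs))
  }
  hit_cap <- it >= cfg$max_iter &&
    any(vapply(tips[seq_len(ntips)], `[[`, TRUE, "active"))
  if (hit_cap)
    warning(sprintf("max_iter (%d) reached with active tips; returning the partial network",
                    cfg$max_iter), call. = FALSE)
  seg_m <- if (nseg) do.call(rbind, segs[seq_len(nseg)]) else
    matrix(numeric(0), 0, 6)
  segments <- as.data.frame(seg_m)
  names(segments) <- c("x1", "y1", "x2", "y2", "order", "step")
  br_m <- if (nbr) do.call(rbind, branches[seq_len(nbr)]) else
    matrix(numeric(0), 0, 3)
  branch_points <- as.data.frame(br_m)
  names(branch_points) <- c("x", "y", "step")
  tip_df <- do.call(rbind, lapply(tips[seq_len(ntips)], function(t)
    data.frame(id = t$id, x = t$position[1], y = t$position[2],
               order = t$order, active = t$active,
               stop_reason = if (is.null(t$stop_reason)) NA_character_
               else t$stop_reason)))
  network <- structure(list(segments = segments,
                            branch_points = branch_points,
                            tips = tip_df,
                            rng_seed = cfg$seed,
                            bounds = bounds,
                            iterations = it,
                            truncated = hit_cap),
                       class = "capillary_network")
  cloud_out <- cloud0
  cloud_out$coords <- coords
  list(network = network,
       fields = list(phi = phi, cloud = cloud_out,
                     diffusivity = context$dmap,
                     region = context$region))
}

#' @exportS3Method base::print
print.capillary_network <- function(x, ...) {
  cat(sprintf("<capillary_network> %d segments, %d branch points, %d tips, %d iterations%s\n",
              nrow(x$segments), nrow(x$branch_points), nrow(x$tips),
              x$iterations, if (x$truncated) " (truncated)" else ""))
  invisible(x)
}
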