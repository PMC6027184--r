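# Internal fast paths for the forward-dynamics inner loop: matrix-based
# force evaluation without per-step data frames. The exported
# apply_ligament_forces()/apply_muscle_forces() remain the reference
# implementations; tests assert the two paths agree.

# rows of a (n x 3) cross b (n x 3)
rowcross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# transform local points grouped by owning body; pts n x 3, body chr vector
transform_grouped <- function(pts, body, poses) {
  out <- matrix(0, nrow(pts), 3L)
  for (b in unique(body)) {
    i <- which(body == b)
    ps <- poses[[b]]
    out[i, ] <- pts[i, , drop = FALSE] %*% t(.pose_R(ps)) +
      matrix(ps$p, length(i), 3L, byrow = TRUE)
  }
  out
}

build_engine_cache <- function(model) {
  cache <- list()
  # --- ligaments: split straight (no via, no wrap) from complex bundles ---
  if (!is.null(model$ligaments)) {
    bundles <- model$ligaments$bundles
    straight <- vapply(bundles, function(b)
      length(b$via_points) == 0L && length(b$wrap_obstacles) == 0L, TRUE)
    si <- which(straight)
    cache$lig <- list(
      n = length(bundles),
      straight_idx = si,
      complex_idx = which(!straight),
      bundles = bundles,
      o_body = vapply(bundles[si], function(b) b$origin$body, ""),
      o_pts = do.call(rbind, lapply(bundles[si], function(b)
        as.numeric(b$origin$point))),
      i_body = vapply(bundles[si], function(b) b$insertion$body, ""),
      i_pts = do.call(rbind, lapply(bundles[si], function(b)
        as.numeric(b$insertion$point))),
      k = vapply(bundles, `[[`, 0, "k"),
      eps_l = vapply(bundles, `[[`, 0, "eps_l"),
      l0 = vapply(bundles, `[[`, 0, "l0"))
  }
  # --- muscles: stacked polyline points ---
  if (length(model$muscles)) {
    pts <- list(); body <- character(); mid <- integer()
    for (j in seq_along(model$muscles)) {
      m <- model$muscles[[j]]
      att <- c(list(m$origin), m$via_points, list(m$insertion))
      for (a in att) {
        pts[[length(pts) + 1L]] <- as.numeric(a$point)
        body <- c(body, a$body)
        mid <- c(mid, j)
      }
    }
    cache$mus <- list(pts = do.call(rbind, pts), body = body, mid = mid,
                      n = length(model$muscles))
  }
  # --- contact pairs ---
  cache$pairs <- lapply(model$contact_pairs, function(cp) {
    if (identical(cp$type, "point_sphere_cup")) return(cp)
    e <- cp$grid$elements
    list(name = cp$name, grid = cp$grid,
         parent = cp$grid$parent_body,
         E = as.matrix(e[, c("cx", "cy", "cz")]),
         N = as.matrix(e[, c("nx", "ny", "nz")]),
         area = e$area,
         opposing = cp$opposing)
  })
  cache
}

# tensions and free-body force applications of the ligament complex;
# returns list(tensions, body, P, F) with P/F k x 3 matrices
ligament_forces_fast <- function(lig, poses) {
  tensions <- numeric(lig$n)
  names(tensions) <- vapply(lig$bundles, `[[`, "", "name")
  body <- character(); P <- NULL; F <- NULL
  si <- lig$straight_idx
  if (length(si)) {
    O <- transform_grouped(lig$o_pts, lig$o_body, poses)
    I <- transform_grouped(lig$i_pts, lig$i_body, poses)
    d <- I - O
    len <- sqrt(rowSums(d * d))
    eps <- (len - lig$l0[si]) / lig$l0[si]
    tns <- bundle_force(eps, lig$k[si], lig$eps_l[si])
    tensions[si] <- tns
    taut <- which(tns > 0)
    if (length(taut)) {
      dir <- d[taut, , drop = FALSE] / len[taut]
      Fv <- dir * tns[taut]
      body <- c(lig$o_body[taut], lig$i_body[taut])
      P <- rbind(O[taut, , drop = FALSE], I[taut, , drop = FALSE])
      F <- rbind(Fv, -Fv)
    }
  }
  for (b in lig$complex_idx) {
    bd <- lig$bundles[[b]]
    pg <- path_geometry(bd$origin, bd$via_points, bd$insertion, poses,
                        bd$wrap_obstacles)
    tension <- bundle_force(bundle_strain(pg$length, bd$l0), bd$k, bd$eps_l)
    tensions[b] <- tension
    if (tension <= 0) next
    ap <- path_force_app_list(bd$origin, bd$via_points, bd$insertion,
                              poses, pg, tension)
    body <- c(body, ap$body)
    P <- rbind(P, ap$P); F <- rbind(F, ap$F)
  }
  list(tensions = tensions, body = body, P = P, F = F)
}

# lengths of all muscle polylines plus, given forces, the applications
muscle_eval_fast <- function(mus, poses, forces = NULL) {
  W <- transform_grouped(mus$pts, mus$body, poses)
  n_pts <- nrow(W)
  segs <- which(mus$mid[-n_pts] == mus$mid[-1L])  # segment start indices
  d <- W[segs + 1L, , drop = FALSE] - W[segs, , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  lengths <- as.numeric(rowsum(len, mus$mid[segs]))
  if (is.null(forces)) return(list(lengths = lengths))
  dirs <- d / len
  body <- character(); P <- NULL; F <- NULL
  for (j in which(forces > 0)) {
    pt_i <- which(mus$mid == j)
    sg_i <- which(mus$mid[segs] == j)
    k <- length(pt_i)
    dj <- dirs[sg_i, , drop = FALSE]
    rowsF <- matrix(0, k, 3L)
    rowsF[1L, ] <- forces[j] * dj[1L, ]
    if (k > 2L) for (v in 2:(k - 1L))
      rowsF[v, ] <- forces[j] * (dj[v, ] - dj[v - 1L, ])
    rowsF[k, ] <- -forces[j] * dj[k - 1L, ]
    body <- c(body, mus$body[pt_i])
    P <- rbind(P, W[pt_i, , drop = FALSE])
    F <- rbind(F, rowsF)
  }
  list(lengths = lengths, body = body, P = P, F = F)
}

# accumulate force applications into per-free-body wrenches about the COM
accumulate_wrench <- function(app, free, state, Facc, Tacc) {
  if (is.null(app$body) || !length(app$body)) return(list(F = Facc, tau = Tacc))
  for (b in intersect(unique(app$body), free)) {
    i <- which(app$body == b)
    Fi <- app$F[i, , drop = FALSE]
    Pi <- app$P[i, , drop = FALSE]
    r <- Pi - matrix(state[[b]]$xc, length(i), 3L, byrow = TRUE)
    Facc[[b]] <- Facc[[b]] + colSums(Fi)
    Tacc[[b]] <- Tacc[[b]] + colSums(rowcross(r, Fi))
  }
  list(F = Facc, tau = Tacc)
}

# fast grid-pair contact evaluation against an analytic opposing surface
grid_pair_fast <- function(pc, params, poses, twists, state, free) {
  ps_g <- poses[[pc$parent]]
  Rg <- .pose_R(ps_g)
  X <- pc$E %*% t(Rg) + matrix(ps_g$p, nrow(pc$E), 3L, byrow = TRUE)
  Nw <- pc$N %*% t(Rg)
  surf <- pc$opposing
  if (inherits(surf, "surface_mesh")) {
    ob <- surf$body_name
    delta <- mesh_penetration_depths(X, Nw, surf, poses[[ob]])
  } else {
    ob <- surf$body
    delta <- analytic_penetration_depths(X, surf, poses[[ob]])
  }
  active <- which(delta > 0)
  nel <- length(delta)
  if (!length(active))
    return(list(F = list(), tau = list(), D = list(),
                summary = list(total_force = 0, area = 0, peak_pressure = 0,
                               n_loaded = 0L),
                element_force = numeric(nel)))
  if (max(delta) > 5)
    stop("solver error: contact penetration exceeds 5 mm (divergence)")
  dlt <- delta[active]
  Xa <- X[active, , drop = FALSE]
  Na <- Nw[active, , drop = FALSE]
  f_el <- params$kc * dlt^params$n
  ci <- smooth_step(dlt / params$d_max) * params$c_max
  gb <- pc$parent
  v_g <- point_velocity(poses[[gb]], twists[[gb]], Xa)
  v_o <- point_velocity(poses[[ob]], twists[[ob]], Xa)
  ddot <- rowSums((v_g - v_o) * Na)
  f_tot <- pmax(f_el + ci * ddot, 0)
  res <- list(F = list(), tau = list(), D = list(), summary = NULL,
              element_force = numeric(nel))
  res$element_force[active] <- f_tot
  for (b in intersect(c(gb, ob), free)) {
    sgn <- if (b == ob) 1 else -1
    r <- Xa - matrix(state[[b]]$xc, length(active), 3L, byrow = TRUE)
    rxn <- rowcross(r, Na)
    other_v <- if (b == ob) v_g else v_o
    b_term <- rowSums(other_v * Na) * sgn
    f_expl <- f_el + ci * b_term
    res$F[[b]] <- sgn * colSums(Na * f_expl)
    res$tau[[b]] <- sgn * colSums(rxn * f_expl)
    res$D[[b]] <- crossprod(cbind(Na, rxn) * sqrt(ci))
  }
  e_area <- pc$area[active]
  res$summary <- list(total_force = sum(f_tot),
                      area = sum(e_area[f_tot > 0]),
                      peak_pressure = if (any(f_tot > 0))
                        max(f_tot / e_area) else 0,
                      n_loaded = sum(f_tot > 0))
  res
}
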