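# Discretization of an articular cartilage surface into contact elements of
# approximately target_size x target_size (default 3 x 3 mm, the printed
# element size). The mesh is parameterized by a developable/equal-area chart
# (plane, unrolled cylinder, or Lambert azimuthal projection for spheres),
# tiled by a regular cell grid in chart coordinates, and each triangle's true
# 3D area is distributed over the cells it overlaps by exact polygon
# clipping, so the summed element area equals the mesh area to rounding.

#' Discretize an articular surface into contact elements
#'
#' @param mesh an open `surface_mesh` shell representing the outer cartilage
#'   surface, oriented so triangle normals point outward (away from the bone).
#' @param target_size nominal element edge length in mm (default 3, giving
#'   the 3 x 3 mm cross-section used for the humeral cartilage).
#' @param thickness constant element thickness in mm, stored for reporting
#'   only (the contact law does not use it).
#' @param parent_body body label the element coordinates refer to; defaults
#'   to the mesh's `body_name`.
#' @return a `cartilage_grid`: list with `parent_body`, `elements` (data frame
#'   with centroid `cx,cy,cz`, unit outward normal `nx,ny,nz`, true `area`
#'   in mm^2, chart cell indices `u_idx,v_idx` and `thickness`), the chart
#'   description `param`, and `target_size`.
#' @export
discretize_cartilage <- function(mesh, target_size = 3, thickness = 2,
                                 parent_body = NULL) {
  if (target_size <= 0) stop("target_size must be > 0")
  if (is.null(parent_body)) parent_body <- mesh$body_name
  par <- fit_surface_chart(mesh)
  uv <- chart_coords(par, mesh$vertices)
  f <- mesh$faces
  A3 <- triangle_areas(mesh)
  N3 <- triangle_normals(mesh)

  ur <- range(uv[, 1L]); vr <- range(uv[, 2L])
  span_u <- max(ur[2L] - ur[1L], 1e-9)
  span_v <- max(vr[2L] - vr[1L], 1e-9)
  n_u <- max(1L, round(span_u / target_size))
  n_v <- max(1L, round(span_v / target_size))
  if (span_u < target_size && span_v < target_size)
    warning("surface smaller than one element; returning a single-element grid")
  du <- span_u / n_u; dv <- span_v / n_v
  u0 <- ur[1L] - 1e-9; v0 <- vr[1L] - 1e-9
  du <- (span_u + 2e-9) / n_u; dv <- (span_v + 2e-9) / n_v

  acc_area <- matrix(0, n_u, n_v)
  acc_cx <- matrix(0, n_u, n_v); acc_cy <- matrix(0, n_u, n_v)
  acc_cz <- matrix(0, n_u, n_v)
  acc_nx <- matrix(0, n_u, n_v); acc_ny <- matrix(0, n_u, n_v)
  acc_nz <- matrix(0, n_u, n_v)

  for (t in seq_len(nrow(f))) {
    vid <- f[t, ]
    tp <- uv[vid, , drop = FALSE]        # 3 x 2 chart triangle
    t3 <- mesh$vertices[vid, , drop = FALSE]
    ap <- abs(poly_area(tp))
    if (ap < 1e-12) {
      # chart-degenerate triangle (e.g. straddling the chart pole): assign
      # wholesale to the cell under its chart centroid
      cc <- colMeans(tp)
      iu <- min(n_u, max(1L, 1L + floor((cc[1L] - u0) / du)))
      iv <- min(n_v, max(1L, 1L + floor((cc[2L] - v0) / dv)))
      c3 <- colMeans(t3)
      acc_area[iu, iv] <- acc_area[iu, iv] + A3[t]
      acc_cx[iu, iv] <- acc_cx[iu, iv] + A3[t] * c3[1L]
      acc_cy[iu, iv] <- acc_cy[iu, iv] + A3[t] * c3[2L]
      acc_cz[iu, iv] <- acc_cz[iu, iv] + A3[t] * c3[3L]
      acc_nx[iu, iv] <- acc_nx[iu, iv] + A3[t] * N3[t, 1L]
      acc_ny[iu, iv] <- acc_ny[iu, iv] + A3[t] * N3[t, 2L]
      acc_nz[iu, iv] <- acc_nz[iu, iv] + A3[t] * N3[t, 3L]
      next
    }
    ratio <- A3[t] / ap
    iu_lo <- max(1L, 1L + floor((min(tp[, 1L]) - u0) / du))
    iu_hi <- min(n_u, 1L + floor((max(tp[, 1L]) - u0) / du))
    iv_lo <- max(1L, 1L + floor((min(tp[, 2L]) - v0) / dv))
    iv_hi <- min(n_v, 1L + floor((max(tp[, 2L]) - v0) / dv))
    for (iu in iu_lo:iu_hi) for (iv in iv_lo:iv_hi) {
      poly <- clip_poly_rect(tp,
                             u0 + (iu - 1L) * du, u0 + iu * du,
                             v0 + (iv - 1L) * dv, v0 + iv * dv)
      if (is.null(poly) || nrow(poly) < 3L) next
      a_piece <- abs(poly_area(poly))
      if (a_piece < 1e-12) next
      cp <- poly_centroid(poly)
      bary <- barycentric_coords(tp, cp)
      c3 <- as.numeric(bary %*% t3)
      w <- ratio * a_piece
      acc_area[iu, iv] <- acc_area[iu, iv] + w
      acc_cx[iu, iv] <- acc_cx[iu, iv] + w * c3[1L]
      acc_cy[iu, iv] <- acc_cy[iu, iv] + w * c3[2L]
      acc_cz[iu, iv] <- acc_cz[iu, iv] + w * c3[3L]
      acc_nx[iu, iv] <- acc_nx[iu, iv] + w * N3[t, 1L]
      acc_ny[iu, iv] <- acc_ny[iu, iv] + w * N3[t, 2L]
      acc_nz[iu, iv] <- acc_nz[iu, iv] + w * N3[t, 3L]
    }
  }

  keep <- which(acc_area > 1e-9, arr.ind = TRUE)
  ord <- order(keep[, 1L], keep[, 2L])
  keep <- keep[ord, , drop = FALSE]
  a <- acc_area[keep]
  nm <- cbind(acc_nx[keep], acc_ny[keep], acc_nz[keep])
  nm <- nm / sqrt(rowSums(nm * nm))
  elements <- data.frame(
    id = seq_len(nrow(keep)),
    cx = acc_cx[keep] / a, cy = acc_cy[keep] / a, cz = acc_cz[keep] / a,
    nx = nm[, 1L], ny = nm[, 2L], nz = nm[, 3L],
    area = a,
    u_idx = keep[, 1L], v_idx = keep[, 2L],
    thickness = thickness)
  structure(list(parent_body = parent_body, elements = elements,
                 param = c(par, list(u_breaks = u0 + (0:n_u) * du,
                                     v_breaks = v0 + (0:n_v) * dv)),
                 target_size = target_size),
            class = "cartilage_grid")
}

#' @export
print.cartilage_grid <- function(x, ...) {
  e <- x$elements
  cat(sprintf("cartilage_grid on '%s': %d elements (~%.0f x %.0f mm), total area %.2f mm^2\n",
              x$parent_body, nrow(e), x$target_size, x$target_size, sum(e$area)))
  cat(sprintf("  chart: %s; median element area %.2f mm^2\n",
              x$param$type, stats::median(e$area)))
  invisible(x)
}

# ---- chart fitting -----------------------------------------------------------

# Decide whether the shell is planar, cylindrical or spherical and return the
# chart parameters. Falls back to a best-fit plane with a warning.
fit_surface_chart <- function(mesh, tol = 1e-6) {
  N <- triangle_normals(mesh)
  A <- triangle_areas(mesh)
  w <- A / sum(A)
  nbar <- colSums(N * w)
  nbar_len <- sqrt(sum(nbar^2))
  if (nbar_len > 1 - 1e-9 ||
      max(1 - abs(N %*% vhat(nbar))) < tol) {
    # planar: in-plane axes from vertex PCA
    n <- vhat(nbar)
    V <- sweep(mesh$vertices, 2L, colMeans(mesh$vertices))
    P <- V - (V %*% n) %*% t(n)
    ev <- eigen(crossprod(P), symmetric = TRUE)$vectors
    return(list(type = "plane", normal = n,
                origin = colMeans(mesh$vertices),
                e1 = ev[, 1L], e2 = vcross(n, ev[, 1L])))
  }
  # cylinder: normals are perpendicular to the axis
  M <- crossprod(N * sqrt(w))
  eg <- eigen(M, symmetric = TRUE)
  axis <- eg$vectors[, 3L]
  if (max(abs(N %*% axis)) < 1e-3) {
    ctr <- fit_circle_2d(mesh, axis)
    return(c(list(type = "cylinder"), ctr))
  }
  # sphere: algebraic (Kasa) fit
  V <- mesh$vertices
  b <- rowSums(V * V)
  X <- cbind(2 * V, 1)
  sol <- qr.solve(X, b)
  cen <- sol[1:3]
  R <- sqrt(sol[4L] + sum(cen^2))
  r <- sqrt(rowSums(sweep(V, 2L, cen)^2))
  if (max(abs(r - R)) < 1e-3 * R) {
    d <- vhat(colMeans(V) - cen)
    e1 <- vhat(vcross(d, if (abs(d[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    return(list(type = "sphere", center = cen, radius = R,
                axis = d, e1 = e1, e2 = vcross(d, e1)))
  }
  warning("surface is neither planar, cylindrical nor spherical; ",
          "falling back to a best-fit plane chart")
  n <- vhat(nbar)
  V <- sweep(mesh$vertices, 2L, colMeans(mesh$vertices))
  P <- V - (V %*% n) %*% t(n)
  ev <- eigen(crossprod(P), symmetric = TRUE)$vectors
  list(type = "plane", normal = n, origin = colMeans(mesh$vertices),
       e1 = ev[, 1L], e2 = vcross(n, ev[, 1L]))
}

# least-squares circle fit of vertices projected perpendicular to `axis`
fit_circle_2d <- function(mesh, axis) {
  e1 <- vhat(vcross(axis, if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  e2 <- vcross(axis, e1)
  x <- mesh$vertices %*% e1
  y <- mesh$vertices %*% e2
  X <- cbind(2 * x, 2 * y, 1)
  sol <- qr.solve(X, x^2 + y^2)
  c2 <- sol[1:2]
  r <- sqrt(sol[3L] + sum(c2^2))
  origin <- as.numeric(c2[1L] * e1 + c2[2L] * e2)
  # reference direction: from axis to the surface centroid
  cen <- colMeans(mesh$vertices)
  rad <- cen - origin - as.numeric((cen - origin) %*% axis) * axis
  list(axis = as.numeric(axis), origin = origin, radius = r,
       d0 = vhat(rad), e1 = e1, e2 = e2)
}

# chart coordinates for a point set (n x 3) under a fitted chart
chart_coords <- function(par, V) {
  if (par$type == "plane") {
    Vc <- sweep(V, 2L, par$origin)
    cbind(as.numeric(Vc %*% par$e1), as.numeric(Vc %*% par$e2))
  } else if (par$type == "cylinder") {
    Vc <- sweep(V, 2L, par$origin)
    u <- as.numeric(Vc %*% par$axis)
    rad <- Vc - u %*% t(par$axis)
    d0 <- par$d0
    dperp <- vcross(par$axis, d0)
    theta <- atan2(as.numeric(rad %*% dperp), as.numeric(rad %*% d0))
    cbind(u, par$radius * theta)
  } else if (par$type == "sphere") {
    P <- sweep(V, 2L, par$center)
    p <- P / sqrt(rowSums(P * P))
    cosphi <- pmin(1, pmax(-1, as.numeric(p %*% par$axis)))
    phi <- acos(cosphi)
    lam <- atan2(as.numeric(p %*% par$e2), as.numeric(p %*% par$e1))
    rho <- 2 * par$radius * sin(phi / 2)     # Lambert equal-area radius
    cbind(rho * cos(lam), rho * sin(lam))
  } else stop("unknown chart type")
}

# ---- polygon helpers (2D, counter-clockwise or clockwise alike) -------------

poly_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  n <- nrow(p)
  j <- c(2:n, 1L)
  0.5 * sum(x * y[j] - x[j] * y)
}

poly_centroid <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  n <- nrow(p)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-14) return(colMeans(p))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Sutherland-Hodgman clip of polygon `p` to an axis-aligned rectangle
clip_poly_rect <- function(p, xlo, xhi, ylo, yhi) {
  clip_half <- function(poly, keep_fun, cross_fun) {
    n <- nrow(poly)
    if (n == 0L) return(poly)
    out <- matrix(0, 2L * n + 4L, 2L)
    k <- 0L
    inside <- keep_fun(poly)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (inside[i]) { k <- k + 1L; out[k, ] <- poly[i, ] }
      if (inside[i] != inside[j]) {
        k <- k + 1L
        out[k, ] <- cross_fun(poly[i, ], poly[j, ])
      }
    }
    out[seq_len(k), , drop = FALSE]
  }
  lerp_x <- function(a, b, x) {
    t <- (x - a[1L]) / (b[1L] - a[1L])
    c(x, a[2L] + t * (b[2L] - a[2L]))
  }
  lerp_y <- function(a, b, y) {
    t <- (y - a[2L]) / (b[2L] - a[2L])
    c(a[1L] + t * (b[1L] - a[1L]), y)
  }
  p <- clip_half(p, function(q) q[, 1L] >= xlo, function(a, b) lerp_x(a, b, xlo))
  if (nrow(p) == 0L) return(NULL)
  p <- clip_half(p, function(q) q[, 1L] <= xhi, function(a, b) lerp_x(a, b, xhi))
  if (nrow(p) == 0L) return(NULL)
  p <- clip_half(p, function(q) q[, 2L] >= ylo, function(a, b) lerp_y(a, b, ylo))
  if (nrow(p) == 0L) return(NULL)
  p <- clip_half(p, function(q) q[, 2L] <= yhi, function(a, b) lerp_y(a, b, yhi))
  if (nrow(p) == 0L) return(NULL)
  p
}

barycentric_coords <- function(tri, pt) {
  d <- (tri[2L, 2L] - tri[3L, 2L]) * (tri[1L, 1L] - tri[3L, 1L]) +
    (tri[3L, 1L] - tri[2L, 1L]) * (tri[1L, 2L] - tri[3L, 2L])
  a <- ((tri[2L, 2L] - tri[3L, 2L]) * (pt[1L] - tri[3L, 1L]) +
          (tri[3L, 1L] - tri[2L, 1L]) * (pt[2L] - tri[3L, 2L])) / d
  b <- ((tri[3L, 2L] - tri[1L, 2L]) * (pt[1L] - tri[3L, 1L]) +
          (tri[1L, 1L] - tri[3L, 1L]) * (pt[2L] - tri[3L, 2L])) / d
  c(a, b, 1 - a - b)
}

# ---- pressure map ------------------------------------------------------------

#' Unfold a per-element scalar field onto the 2D cartilage chart
#'
#' Reproduces the "unrolled cartilage" style of contact pressure map: the
#' chart coordinates are arc lengths on the articular surface (mm), so cell
#' positions are metric.
#'
#' @param grid a `cartilage_grid`.
#' @param values one scalar per grid element (e.g. contact pressure in MPa).
#' @return a `pressure_map`: list with cell-centre coordinate vectors `u`,
#'   `v` (mm) and a `values` matrix (`NA` where the chart cell holds no
#'   surface).
#' @export
unfold_pressure_map <- function(grid, values) {
  e <- grid$elements
  if (length(values) != nrow(e))
    stop("shape error: need one value per element (", nrow(e), "), got ",
         length(values))
  ub <- grid$param$u_breaks; vb <- grid$param$v_breaks
  m <- matrix(NA_real_, length(ub) - 1L, length(vb) - 1L)
  m[cbind(e$u_idx, e$v_idx)] <- values
  structure(list(u = (ub[-1L] + ub[-length(ub)]) / 2,
                 v = (vb[-1L] + vb[-length(vb)]) / 2,
                 values = m),
            class = "pressure_map")
}

#' Export a cartilage grid as CSV
#' @param grid a `cartilage_grid`.
#' @param path output CSV path.
#' @export
export_grid_csv <- function(grid, path) {
  e <- grid$elements
  utils::write.csv(data.frame(element_id = e$id, cx = e$cx, cy = e$cy,
                              cz = e$cz, nx = e$nx, ny = e$ny, nz = e$nz,
                              area_mm2 = e$area),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a pressure map as CSV (long format) and optionally a PNG heatmap
#' @param map a `pressure_map`.
#' @param csv_path output CSV path (cell u, v, value rows).
#' @param png_path optional PNG heatmap path.
#' @export
export_pressure_map <- function(map, csv_path, png_path = NULL) {
  df <- expand.grid(u_mm = map$u, v_mm = map$v)
  df$value <- as.vector(map$values)
  utils::write.csv(df[!is.na(df$value), ], csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 700, height = 500)
    on.exit(grDevices::dev.off())
    vals <- map$values
    vals[is.na(vals)] <- 0
    graphics::image(map$u, map$v, vals, xlab = "axial arc length (mm)",
                    ylab = "medial-lateral arc length (mm)",
                    main = "contact pressure (MPa)",
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
  }
  invisible(csv_path)
}
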