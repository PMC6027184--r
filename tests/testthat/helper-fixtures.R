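# shared fixtures built in code

# flat rectangular patch in the z = 0 plane, triangulated on a grid
flat_patch_mesh <- function(w = 30, h = 30, nx = 7L, ny = 7L, z = 0) {
  mesh_from_param_test(function(u, v) c(u, v, z),
                       seq(0, w, length.out = nx),
                       seq(0, h, length.out = ny))
}

# open cylinder band around the x axis
cylinder_band_mesh <- function(radius = 10, x0 = 0, x1 = 12,
                               ang = c(-2, 2), nu = 5L, nv = 41L) {
  mesh_from_param_test(function(u, v) c(u, radius * sin(v), -radius * cos(v)),
                       seq(x0, x1, length.out = nu),
                       seq(ang[1L], ang[2L], length.out = nv))
}

# spherical cap of half-angle `half` about the -z direction
sphere_cap_mesh <- function(radius = 9, half = pi / 3, nu = 10L, nv = 25L,
                            center = c(0, 0, 0)) {
  mesh_from_param_test(function(u, v) center +
                         radius * c(sin(u) * cos(v), sin(u) * sin(v), -cos(u)),
                       seq(1e-3, half, length.out = nu),
                       seq(0, 2 * pi, length.out = nv))
}

# closed axis-aligned box mesh (12 triangles)
box_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1), body_name = "box") {
  v <- as.matrix(expand.grid(x = c(lo[1L], hi[1L]), y = c(lo[2L], hi[2L]),
                             z = c(lo[3L], hi[3L])))
  # faces with outward orientation (1-based indices into the 8 corners)
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = lo
             c(5, 6, 7), c(6, 8, 7),   # z = hi
             c(1, 2, 5), c(2, 6, 5),   # y = lo
             c(3, 7, 4), c(4, 7, 8),   # y = hi
             c(1, 5, 3), c(3, 5, 7),   # x = lo
             c(2, 4, 6), c(4, 8, 6))   # x = hi
  surface_mesh(v, f, body_name)
}

# minimal parametric-grid mesh builder local to the tests (independent of
# the package-internal generator)
mesh_from_param_test <- function(fx, u, v, body_name = "test") {
  nu <- length(u); nv <- length(v)
  verts <- matrix(0, nu * nv, 3L)
  for (i in seq_len(nu)) for (j in seq_len(nv))
    verts[(i - 1L) * nv + j, ] <- fx(u[i], v[j])
  id <- function(i, j) (i - 1L) * nv + j
  faces <- list()
  for (i in seq_len(nu - 1L)) for (j in seq_len(nv - 1L)) {
    faces[[length(faces) + 1L]] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
    faces[[length(faces) + 1L]] <- c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
  }
  f <- do.call(rbind, faces)
  key <- apply(round(verts, 9L), 1L, paste, collapse = ",")
  uid <- !duplicated(key)
  map <- match(key, key[uid])
  f2 <- matrix(map[f], ncol = 3L)
  keep <- f2[, 1L] != f2[, 2L] & f2[, 2L] != f2[, 3L] & f2[, 1L] != f2[, 3L]
  surface_mesh(verts[uid, , drop = FALSE], f2[keep, , drop = FALSE], body_name)
}

# cached default synthetic subject shared across test files (uncalibrated)
default_subject <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_subject()
    val
  }
})

# cached calibrated model + laxity trial
calibrated_model <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      sub <- default_subject()
      model <- sub$model
      lax <- generate_trial(model, trial_spec("laxity", seed = 7L))
      model$ligaments <- estimate_zero_load_lengths(model$ligaments, lax)
      val <<- list(model = model, laxity = lax)
    }
    val
  }
})
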