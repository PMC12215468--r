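# Shared geometric fixtures, all built in code.

# binary sphere mask centred in its grid
sphere_grid <- function(r = 10, spacing = c(0.5, 0.5, 0.5), pad = 3) {
  n <- ceiling(2 * (r + pad) / spacing)
  ctr <- (n - 1) / 2
  xs <- (seq_len(n[1]) - 1 - ctr[1]) * spacing[1]
  ys <- (seq_len(n[2]) - 1 - ctr[2]) * spacing[2]
  zs <- (seq_len(n[3]) - 1 - ctr[3]) * spacing[3]
  m <- array(0L, n)
  for (k in seq_len(n[3]))
    m[, , k] <- as.integer(outer(xs^2, ys^2, "+") + zs[k]^2 < r^2)
  voxel_grid(m, spacing, -ctr * spacing)
}

# analytic closed UV-sphere mesh (inscribed polyhedron of radius r)
uv_sphere_mesh <- function(r = 10, n_theta = 24, n_phi = 48) {
  th <- seq(0, pi, length.out = n_theta + 1)[2:n_theta]
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  ring <- function(t) cbind(r * sin(t) * cos(ph), r * sin(t) * sin(ph), r * cos(t))
  V <- rbind(c(0, 0, r), do.call(rbind, lapply(th, ring)), c(0, 0, -r))
  top <- 1L
  bot <- nrow(V)
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  faces <- list()
  for (j in seq_len(n_phi))
    faces[[length(faces) + 1L]] <- c(top, idx(1, j), idx(1, j + 1))
  for (i in seq_len(length(th) - 1)) for (j in seq_len(n_phi)) {
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  ni <- length(th)
  for (j in seq_len(n_phi))
    faces[[length(faces) + 1L]] <- c(bot, idx(ni, j + 1), idx(ni, j))
  orient_outward(triangle_mesh(V, do.call(rbind, faces)))
}

# axis-aligned box mesh (12 triangles)
box_mesh <- function(lo = c(-5, -5, -5), hi = c(5, 5, 5)) {
  V <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]), c(lo[3], hi[3])))
  Fc <- rbind(
    c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
    c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
    c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  orient_outward(triangle_mesh(V, Fc))
}

# moderate-resolution phantom bone mesh (cached across tests)
.shape_cache <- new.env(parent = emptyenv())
bone_mesh <- function(bone = "femur", scale = 0.4, spacing = 0.7, seed = 1,
                      smooth = 1) {
  key <- paste(bone, scale, spacing, seed, smooth, sep = "_")
  if (!is.null(.shape_cache[[key]])) return(.shape_cache[[key]])
  sz <- c(femur = 60, tibia = 55, fibula = 40, patella = 24)[[bone]] * scale
  shape <- generate_bone_shape(bone, sz, seed = seed)
  fov <- rbind(shape$bbox[1, ] - 3, shape$bbox[2, ] + 3)
  g <- voxelize_shape(shape, rep(spacing, 3), fov)
  m <- extract_isosurface(g, smooth_sigma = smooth)
  .shape_cache[[key]] <- m
  m
}
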