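# FROI restriction, signed distances and per-bone summaries.

test_that("FROI keeps everything for identical full meshes and for the patella", {
  sph <- uv_sphere_mesh(10)
  froi <- define_froi(sph, sph, froi_spec(margin = 0))
  expect_true(all(froi$source_mask))
  expect_true(all(froi$target_mask))
  # patella exemption: clipped meshes still compared in full
  clipped <- triangle_mesh(sph$vertices[sph$vertices[, 3] > -2, , drop = FALSE],
                           matrix(integer(0), 0, 3))
  froi2 <- define_froi(clipped, sph, froi_spec(), bone = "patella")
  expect_true(all(froi2$source_mask))
  expect_true(all(froi2$target_mask))
})

test_that("FROI margin removes a spherical zone of the analytic area", {
  # source: upper half of a sphere (cut at z = 0); target: full sphere.
  # margin 2 at the cut end retains the zone z in [2, 10], area 2*pi*r*h
  g <- sphere_grid(10, c(0.4, 0.4, 0.4))
  full <- extract_isosurface(g, smooth_sigma = 1)
  half_mask <- g$mask
  zs <- g$origin[3] + (seq_len(dim(g$mask)[3]) - 1) * g$spacing[3]
  half_mask[, , zs < 0] <- 0L
  half <- extract_isosurface(voxel_grid(half_mask, g$spacing, g$origin),
                             smooth_sigma = 1)
  froi <- define_froi(half, full, froi_spec(margin = 2))
  V <- half$vertices[froi$source_mask, ]
  Fc <- half$faces
  keepf <- froi$source_mask[Fc[, 1]] & froi$source_mask[Fc[, 2]] &
    froi$source_mask[Fc[, 3]]
  sub <- triangle_mesh(half$vertices, Fc[keepf, , drop = FALSE])
  area <- mesh_measures(sub)$area
  # retained piece includes the flat cut cap of the half-sphere above z=2?
  # no: the cap sits at z ~ 0 and is excluded; analytic zone area for
  # heights [2, 10] on r = 10:
  expect_lt(abs(area - 2 * pi * 10 * 8) / (2 * pi * 10 * 8), 0.05)
})

test_that("FROI margin growth never increases the retained count", {
  g <- sphere_grid(8, c(0.5, 0.5, 0.5))
  full <- extract_isosurface(g)
  half_mask <- g$mask
  zs <- g$origin[3] + (seq_len(dim(g$mask)[3]) - 1) * g$spacing[3]
  half_mask[, , zs < 0] <- 0L
  half <- extract_isosurface(voxel_grid(half_mask, g$spacing, g$origin))
  counts <- vapply(c(0, 1, 2, 3, 4), function(m)
    sum(define_froi(half, full, froi_spec(margin = m))$source_mask), 0)
  expect_true(all(diff(counts) <= 0))
  expect_error(define_froi(half, full, froi_spec(margin = 50)), "empty FROI")
})

test_that("signed distance is zero on self and +/-0.30 for concentric spheres", {
  g10 <- sphere_grid(10, c(0.4, 0.4, 0.4))
  m10 <- extract_isosurface(g10, smooth_sigma = 1)
  self <- signed_distance(m10, m10)
  expect_lt(max(abs(self$distance)), 1e-9)
  m103 <- extract_isosurface(sphere_grid(10.3, c(0.4, 0.4, 0.4)), smooth_sigma = 1)
  m97 <- extract_isosurface(sphere_grid(9.7, c(0.4, 0.4, 0.4)), smooth_sigma = 1)
  d_out <- mean(signed_distance(m103, m10)$distance)
  d_in <- mean(signed_distance(m97, m10)$distance)
  expect_lt(abs(d_out - 0.30), 0.03)
  expect_lt(abs(d_in + 0.30), 0.03)
  # antisymmetry when swapping source and target
  d_swap <- mean(signed_distance(m10, m103)$distance)
  expect_lt(abs(d_swap + d_out), 0.03)
})

test_that("open targets need the pseudo-normal fallback and then sign correctly", {
  sph <- uv_sphere_mesh(10, 20, 40)
  # open target: drop the top cap faces
  open_faces <- sph$faces[apply(matrix(sph$vertices[sph$faces, 3], ncol = 3), 1, max) < 9.5, ]
  open_mesh <- suppressWarnings(orient_outward(triangle_mesh(sph$vertices, open_faces)))
  src <- uv_sphere_mesh(10.5, 12, 24)
  expect_error(signed_distance(src, open_mesh), "watertight")
  d <- signed_distance(src, open_mesh, allow_open = TRUE)
  expect_gt(mean(d$distance > 0), 0.95)
  src_in <- uv_sphere_mesh(9.5, 12, 24)
  d_in <- signed_distance(src_in, open_mesh, allow_open = TRUE)
  expect_gt(mean(d_in$distance < 0), 0.9)
})

test_that("summarize_bone follows the population-sd interval convention", {
  s <- summarize_bone(rep(0.25, 10), bone = "patella")
  expect_equal(s$mean, 0.25)
  expect_equal(s$sd, 0)
  expect_equal(c(s$lower, s$upper), c(0.25, 0.25))
  s2 <- summarize_bone(c(-1, 1))
  expect_equal(s2$mean, 0)
  expect_equal(s2$sd, 1)
  expect_equal(c(s2$lower, s2$upper), c(-1.96, 1.96))
  expect_error(summarize_bone(0.1), "at least 2")
})

test_that("the full pipeline recovers identity, offset and misaligned pairs", {
  # identity pair
  spec0 <- phantom_spec("patella", scale = 0.6, delta = 0, sigma_noise = 0, seed = 41)
  p0 <- generate_bone_pair(spec0)
  r0 <- compare_bone_pair(p0$grid_a, p0$grid_b, bone = "patella")
  expect_lt(abs(r0$summary$mean), 0.05)
  vox_diag <- sqrt(sum(p0$grid_b$spacing^2))
  expect_lt(r0$summary$sd, vox_diag / 4)
  # offset pair, identity transform
  spec1 <- phantom_spec("patella", scale = 0.6, delta = 0.30, sigma_noise = 0, seed = 42)
  p1 <- generate_bone_pair(spec1)
  r1 <- compare_bone_pair(p1$grid_a, p1$grid_b, bone = "patella")
  expect_lt(abs(r1$summary$mean - 0.30), 0.05)
  # zero offset under a 5 degree / (2, -1, 3) mm misalignment: the
  # registration must remove the transform
  spec2 <- phantom_spec("tibia", scale = 0.6, delta = 0, sigma_noise = 0,
                        transform = rigid_axis_rotation(2, 5, c(2, -1, 3)),
                        seed = 43)
  p2 <- generate_bone_pair(spec2)
  r2 <- compare_bone_pair(p2$grid_a, p2$grid_b, bone = "tibia")
  expect_lt(abs(r2$summary$mean), 0.05)
})
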