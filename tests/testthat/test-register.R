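# Kabsch superposition and ICP alignment.

test_that("kabsch recovers identity and constructed transforms", {
  set.seed(21)
  pts <- matrix(rnorm(18, sd = 5), ncol = 3)
  id <- kabsch(pts, pts)
  expect_lt(sqrt(sum(id$translation^2)), 1e-12)
  expect_lt(rotation_angle(id) * pi / 180, 1e-12)
  tr <- rigid_axis_rotation(3, 30, c(1, 2, 3))
  moved <- transform_points(tr, pts)
  rec <- kabsch(pts, moved)
  expect_lt(max(abs(rec$rotation - tr$rotation)), 1e-9)
  expect_lt(max(abs(rec$translation - tr$translation)), 1e-9)
  # weighted: duplicate of a point with weight 2 equals the point twice
  w <- c(2, 1, 1, 1, 1, 1)
  rec_w <- kabsch(pts, moved, weights = w)
  rec_d <- kabsch(pts[c(1, 1:6), ], moved[c(1, 1:6), ])
  expect_equal(rec_w$rotation, rec_d$rotation, tolerance = 1e-9)
})

test_that("kabsch excludes reflections and rejects degenerate input", {
  set.seed(22)
  pts <- matrix(rnorm(15, sd = 4), ncol = 3)
  mirrored <- pts %*% diag(c(-1, 1, 1))
  rec <- kabsch(pts, mirrored)
  expect_equal(det(rec$rotation), 1, tolerance = 1e-9)
  resid <- sqrt(mean(rowSums((transform_points(rec, pts) - mirrored)^2)))
  expect_gt(resid, 0.1)
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(line, line + 1), "collinear|degenerate")
  expect_error(kabsch(pts[1:2, ], pts[1:2, ]), "at least 3")
})

test_that("kabsch agrees with a brute-force rotation grid search", {
  # coarse 1-degree grid over z-rotations: planar problem so the optimum is
  # a pure z-rotation; kabsch must match the grid optimum to grid resolution
  set.seed(23)
  pts <- cbind(matrix(rnorm(10, sd = 3), ncol = 2), 0)
  true_ang <- 37.3
  target <- transform_points(rigid_axis_rotation(3, true_ang), pts)
  angles <- seq(0, 359, by = 1)
  cost <- vapply(angles, function(a) {
    m <- transform_points(rigid_axis_rotation(3, a), pts)
    sum((m - target)^2)
  }, 0)
  best <- angles[which.min(cost)]
  rec <- kabsch(pts, target)
  expect_lt(abs(rotation_angle(rec) - best), 1.0)
  expect_lt(abs(rotation_angle(rec) - true_ang), 1e-6)
})

test_that("apply_rigid maps vertices exactly and composes with its inverse", {
  m <- bone_mesh("patella", scale = 0.4, spacing = 0.8)
  expect_equal(apply_rigid(m, rigid_identity())$vertices, m$vertices)
  tr <- rigid_axis_rotation(1, 12, c(0, 0, 5))
  fwd <- apply_rigid(m, tr)
  expect_equal(colMeans(apply_rigid(m, rigid_transform(diag(3), c(0, 0, 5)))$vertices),
               colMeans(m$vertices) + c(0, 0, 5), tolerance = 1e-12)
  back <- apply_rigid(fwd, invert_rigid(tr))
  expect_lt(max(abs(back$vertices - m$vertices)), 1e-9)
  expect_identical(back$faces, m$faces)
})

test_that("ICP on identical meshes returns the identity", {
  m <- bone_mesh("femur", scale = 0.4, spacing = 0.8)
  res <- icp_align(m, m, icp_params(sample = 2000))
  expect_true(res$converged)
  expect_lt(rotation_angle(res$transform), 0.01)
  expect_lt(sqrt(sum(res$transform$translation^2)), 0.01)
  expect_lt(tail(res$rms_trace, 1), 1e-3)
})

test_that("ICP recovers a 5 degree / (2, -1, 3) mm misalignment", {
  m <- bone_mesh("femur", scale = 0.5, spacing = 0.5)
  tr <- rigid_axis_rotation(2, 5, c(2, -1, 3))
  moved <- apply_rigid(m, tr)
  res <- icp_align(moved, m, icp_params(sample = 4000))
  err <- compose_rigid(tr, res$transform) # should be identity
  expect_lt(rotation_angle(err), 0.5)
  expect_lt(sqrt(sum(err$translation^2)), 0.1)
})

test_that("ICP residual matches the noise floor for jittered vertices", {
  m <- bone_mesh("tibia", scale = 0.4, spacing = 0.8)
  sigma <- 0.2
  set.seed(31)
  noisy <- triangle_mesh(m$vertices + matrix(rnorm(length(m$vertices), sd = sigma),
                                             ncol = 3), m$faces)
  res <- icp_align(noisy, m, icp_params(sample = 3000))
  rms <- tail(res$rms_trace, 1)
  # per-axis noise sigma against a surface: residual is the distance of a
  # 3D Gaussian displacement to the plane, sd ~ sigma
  expect_gt(rms, 0.5 * sigma)
  expect_lt(rms, 1.5 * sigma)
})

test_that("every ICP transform satisfies the rigidity invariants and RMS decreases", {
  m <- bone_mesh("fibula", scale = 0.5, spacing = 0.6)
  tr <- rigid_axis_rotation(1, 8, c(3, 2, -4))
  res <- icp_align(apply_rigid(m, tr), m, icp_params(sample = 2000))
  Rm <- res$transform$rotation
  expect_lt(max(abs(crossprod(Rm) - diag(3))), 1e-9)
  expect_equal(det(Rm), 1, tolerance = 1e-9)
  expect_true(all(diff(res$rms_trace) < 1e-8))
})

test_that("ICP converges within 100 iterations for moderate misalignments", {
  # 50 seeded trials, misalignment up to 15 degrees / 10 mm
  bones <- c("femur", "tibia", "fibula", "patella")
  n_conv <- 0L
  n_trials <- 50L
  for (i in seq_len(n_trials)) {
    bone <- bones[1 + (i - 1) %% 4]
    m <- bone_mesh(bone, scale = 0.4, spacing = 0.7, seed = 1 + (i %% 3))
    tr <- bonequiv:::with_seed(900 + i, bonequiv:::random_rigid(15, 10))
    res <- icp_align(apply_rigid(m, tr), m,
                     icp_params(sample = 1500, max_iter = 100))
    n_conv <- n_conv + res$converged
  }
  expect_gte(n_conv / n_trials, 0.95)
})

test_that("ICP rejects degenerate meshes", {
  degen <- triangle_mesh(matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE),
                         matrix(integer(0), 0, 3))
  m <- bone_mesh("patella", scale = 0.4, spacing = 0.8)
  expect_error(icp_align(degen, m), "degenerate|empty")
})
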