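# Synthetic knee-bone phantoms. Shapes are smooth blends of analytic
# primitives (ellipsoids, capsules) represented by signed-distance functions
# (negative inside), so every downstream stage can be checked against
# analytic or Monte-Carlo oracles. Anatomical realism is a non-goal: only
# closedness, asymmetry (so rigid registration is well-posed) and scale
# matter.

PHANTOM_BONES <- c("femur", "tibia", "fibula", "patella")

new_implicit_shape <- function(sdf, label, bbox, feature_radius, parts = NULL) {
  structure(list(sdf = sdf, label = label, bbox = bbox,
                 feature_radius = feature_radius, parts = parts),
            class = "implicit_shape")
}

#' @export
print.implicit_shape <- function(x, ...) {
  cat("<implicit_shape> ", x$label, ", bbox [",
      paste(sprintf("%.1f..%.1f", x$bbox[1, ], x$bbox[2, ]), collapse = ", "),
      "] mm\n", sep = "")
  invisible(x)
}

# --- analytic primitives ----------------------------------------------------

# near-exact ellipsoid signed distance (first-order scaled estimate)
sdf_ellipsoid <- function(p, center, radii) {
  q <- sweep(p, 2, center)
  k0 <- sqrt((q[, 1] / radii[1])^2 + (q[, 2] / radii[2])^2 + (q[, 3] / radii[3])^2)
  k1 <- sqrt((q[, 1] / radii[1]^2)^2 + (q[, 2] / radii[2]^2)^2 + (q[, 3] / radii[3]^2)^2)
  d <- k0 * (k0 - 1) / k1
  d[k1 == 0] <- -min(radii)
  d
}

# exact capsule (line segment a-b swept by radius r) signed distance
sdf_capsule <- function(p, a, b, r) {
  ab <- b - a
  len2 <- sum(ab^2)
  q <- sweep(p, 2, a)
  h <- pmin(pmax((q %*% ab) / len2, 0), 1)
  dx <- q[, 1] - h * ab[1]
  dy <- q[, 2] - h * ab[2]
  dz <- q[, 3] - h * ab[3]
  sqrt(dx^2 + dy^2 + dz^2) - r
}

sdf_sphere <- function(p, center, r) {
  q <- sweep(p, 2, center)
  sqrt(rowSums(q^2)) - r
}

# polynomial smooth minimum (smooth union of signed distances); equals the
# exact min outside the |d1 - d2| < k band, so the field stays a true
# distance almost everywhere and level-set offsets displace the surface by
# the offset itself
smin <- function(d1, d2, k) {
  h <- pmin(pmax(0.5 + 0.5 * (d2 - d1) / k, 0), 1)
  d2 * (1 - h) + d1 * h - k * h * (1 - h)
}

eval_parts <- function(parts, p, blend_k) {
  d <- NULL
  for (pr in parts) {
    dp <- switch(pr$type,
      ellipsoid = sdf_ellipsoid(p, pr$center, pr$radii),
      capsule = sdf_capsule(p, pr$a, pr$b, pr$r),
      sphere = sdf_sphere(p, pr$center, pr$r),
      stop("unknown primitive type: ", pr$type))
    d <- if (is.null(d)) dp else smin(d, dp, blend_k)
  }
  d
}

part_bbox <- function(pr) {
  switch(pr$type,
    ellipsoid = rbind(pr$center - pr$radii, pr$center + pr$radii),
    capsule = rbind(pmin(pr$a, pr$b) - pr$r, pmax(pr$a, pr$b) + pr$r),
    sphere = rbind(pr$center - pr$r, pr$center + pr$r))
}

part_min_radius <- function(pr) {
  switch(pr$type, ellipsoid = min(pr$radii), capsule = pr$r, sphere = pr$r)
}

shape_from_parts <- function(parts, label, blend_k, pad = 0) {
  bb <- Reduce(function(a, b) rbind(pmin(a[1, ], b[1, ]), pmax(a[2, ], b[2, ])),
               lapply(parts, part_bbox))
  bb[1, ] <- bb[1, ] - pad
  bb[2, ] <- bb[2, ] + pad
  new_implicit_shape(function(p) eval_parts(parts, p, blend_k), label, bb,
                     feature_radius = min(vapply(parts, part_min_radius, 0)),
                     parts = parts)
}

# small seeded bumps welded onto a shape so that rotations are identifiable
bump_parts <- function(base_parts, size, n, rmin, rmax) {
  anchors <- base_parts[vapply(base_parts, function(p) p$type != "capsule", TRUE)]
  if (length(anchors) == 0L) anchors <- base_parts
  lapply(seq_len(n), function(i) {
    an <- anchors[[1 + (i - 1) %% length(anchors)]]
    ctr <- if (an$type == "capsule") (an$a + an$b) / 2 else an$center
    rad <- if (an$type == "ellipsoid") an$radii else rep(an$r, 3)
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    r <- runif(1, rmin, rmax) * size
    list(type = "sphere", center = ctr + dir * rad * 0.95, r = r)
  })
}

#' Generate a synthetic bone shape
#'
#' Builds a closed implicit surface loosely evoking the named knee bone:
#' a shaft with condylar bulges for the femur, a shaft with a flared plateau
#' for the tibia, a thin rod with a small head for the fibula, and a lens
#' for the patella. Each shape carries a few seeded asymmetric surface bumps
#' so that rigid registration has a unique solution. Deterministic per
#' (label, size, seed).
#'
#' The joint region sits near z = 0; femoral shaft extends towards +z,
#' tibial and fibular shafts towards -z, mimicking how an axial scan window
#' centred on the joint truncates the long bones but never the patella.
#'
#' @param label one of `"femur"`, `"tibia"`, `"fibula"`, `"patella"`.
#' @param size characteristic bone scale in mm (e.g. condylar width).
#' @param seed integer seed for bump placement.
#' @return an `implicit_shape`.
#' @export
generate_bone_shape <- function(label, size, seed = 1L) {
  label <- match.arg(label, PHANTOM_BONES)
  if (!is.finite(size) || size <= 0) stop("size must be > 0")
  s <- size
  with_seed(seed * 8L + match(label, PHANTOM_BONES), {
    parts <- switch(label,
      femur = c(
        list(list(type = "capsule", a = c(0, 0, 0.25 * s), b = c(0, 0, 1.15 * s), r = 0.15 * s),
             list(type = "ellipsoid", center = c(-0.17 * s, 0.02 * s, 0), radii = c(0.17, 0.20, 0.17) * s),
             list(type = "ellipsoid", center = c(0.15 * s, 0.04 * s, 0.01 * s), radii = c(0.15, 0.18, 0.16) * s)),
        bump_parts(list(list(type = "ellipsoid", center = c(-0.17 * s, 0.02 * s, 0), radii = c(0.17, 0.20, 0.17) * s)),
                   s, 3L, 0.05, 0.08)),
      tibia = c(
        list(list(type = "capsule", a = c(0, 0, -1.15 * s), b = c(0, 0, -0.22 * s), r = 0.13 * s),
             list(type = "ellipsoid", center = c(0, 0.01 * s, -0.09 * s), radii = c(0.21, 0.17, 0.11) * s),
             list(type = "sphere", center = c(0.06 * s, 0.17 * s, -0.18 * s), r = 0.06 * s)),
        bump_parts(list(list(type = "ellipsoid", center = c(0, 0.01 * s, -0.09 * s), radii = c(0.21, 0.17, 0.11) * s)),
                   s, 2L, 0.05, 0.08)),
      fibula = c(
        list(list(type = "capsule", a = c(0, 0, -1.7 * s), b = c(0, 0, -0.22 * s), r = 0.09 * s),
             list(type = "ellipsoid", center = c(0.01 * s, -0.02 * s, -0.16 * s), radii = c(0.14, 0.12, 0.15) * s)),
        bump_parts(list(list(type = "ellipsoid", center = c(0.01 * s, -0.02 * s, -0.16 * s), radii = c(0.14, 0.12, 0.15) * s)),
                   s, 2L, 0.05, 0.07)),
      patella = c(
        list(list(type = "ellipsoid", center = c(0, 0, 0), radii = c(0.42, 0.30, 0.26) * s)),
        bump_parts(list(list(type = "ellipsoid", center = c(0, 0, 0), radii = c(0.42, 0.30, 0.26) * s)),
                   s, 3L, 0.06, 0.10)))
    shape_from_parts(parts, label, blend_k = 0.05 * s)
  })
}

#' Displace an implicit surface along its normal
#'
#' Positive `delta` dilates the shape (surface moves outward by `delta` mm),
#' negative erodes it; implemented by shifting the signed-distance level set.
#' Emulates a uniform systematic size difference between modalities.
#'
#' @param shape an `implicit_shape`.
#' @param delta signed offset in mm; |delta| must stay below the shape's
#'   minimal feature radius.
#' @return an `implicit_shape`.
#' @export
offset_surface <- function(shape, delta) {
  stopifnot(inherits(shape, "implicit_shape"))
  if (abs(delta) >= shape$feature_radius)
    stop("|delta| must be smaller than the minimal feature radius (",
         format(shape$feature_radius), " mm)")
  sdf <- shape$sdf
  bb <- shape$bbox
  bb[1, ] <- bb[1, ] - max(delta, 0)
  bb[2, ] <- bb[2, ] + max(delta, 0)
  new_implicit_shape(function(p) sdf(p) - delta, shape$label, bb,
                     shape$feature_radius - abs(delta), shape$parts)
}

#' Add band-limited smooth surface noise
#'
#' Adds a fixed-seed field of Gaussian lobes to the signed-distance value,
#' emulating vertex-scale surface noise while keeping the surface closed and
#' smooth. Lobe signs are balanced so the surface-averaged perturbation is
#' near zero and the expected mean surface distance stays at the systematic
#' offset. The field is bounded by `sigma` (the amplitude).
#'
#' @param shape an `implicit_shape`.
#' @param sigma noise amplitude in mm (>= 0).
#' @param seed integer seed for lobe placement.
#' @param n_lobes number of Gaussian lobes.
#' @return an `implicit_shape`.
#' @export
add_surface_noise <- function(shape, sigma, seed = 1L, n_lobes = 48L) {
  stopifnot(inherits(shape, "implicit_shape"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(shape)
  bb <- shape$bbox
  width <- sqrt(sum((bb[2, ] - bb[1, ])^2)) / 14
  with_seed(seed * 16L + 7L, {
    centers <- cbind(runif(n_lobes, bb[1, 1], bb[2, 1]),
                     runif(n_lobes, bb[1, 2], bb[2, 2]),
                     runif(n_lobes, bb[1, 3], bb[2, 3]))
  })
  signs <- rep(c(1, -1), length.out = n_lobes)
  sdf <- shape$sdf
  noisy <- function(p) {
    f <- numeric(nrow(p))
    for (i in seq_len(n_lobes)) {
      q2 <- (p[, 1] - centers[i, 1])^2 + (p[, 2] - centers[i, 2])^2 +
        (p[, 3] - centers[i, 3])^2
      f <- f + signs[i] * exp(-q2 / (2 * width^2))
    }
    sdf(p) + sigma * tanh(f)
  }
  new_implicit_shape(noisy, shape$label, bb, shape$feature_radius, shape$parts)
}

# rigidly move a shape: sdf'(p) = sdf(R^T (p - t)) (isometry preserves
# signed distance exactly)
transform_shape <- function(shape, transform) {
  stopifnot(inherits(shape, "implicit_shape"), inherits(transform, "rigid_transform"))
  Rm <- transform$rotation
  tv <- transform$translation
  sdf <- shape$sdf
  corners <- as.matrix(expand.grid(shape$bbox[, 1], shape$bbox[, 2], shape$bbox[, 3]))
  tc <- t(Rm %*% t(corners) + tv)
  bb <- rbind(apply(tc, 2, min), apply(tc, 2, max))
  new_implicit_shape(function(p) {
    q <- sweep(p, 2, tv) %*% Rm  # = R^T (p - t) rowwise
    sdf(q)
  }, shape$label, bb, shape$feature_radius, NULL)
}

#' Rasterize an implicit shape onto a voxel grid
#'
#' Voxel-centre classification: a voxel is foreground iff the signed
#' distance at its centre is negative. The grid records its spacing and
#' origin (centre of the first voxel) in mm.
#'
#' @param shape an `implicit_shape`.
#' @param spacing voxel spacing in mm, length 3.
#' @param fov 2 x 3 matrix: physical field of view, rows = (lo, hi) mm.
#' @return a [voxel_grid].
#' @export
voxelize_shape <- function(shape, spacing, fov) {
  stopifnot(inherits(shape, "implicit_shape"))
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  fov <- rbind(pmin(fov[1, ], fov[2, ]), pmax(fov[1, ], fov[2, ]))
  n <- pmax(1L, as.integer(floor((fov[2, ] - fov[1, ]) / spacing + 1e-9)))
  origin <- fov[1, ] + spacing / 2
  xs <- origin[1] + (seq_len(n[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(n[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(n[3]) - 1) * spacing[3]
  mask <- array(0L, n)
  slab <- cbind(rep(xs, times = n[2]), rep(ys, each = n[1]), 0)
  for (k in seq_len(n[3])) {
    slab[, 3] <- zs[k]
    mask[, , k] <- as.integer(shape$sdf(slab) < 0)
  }
  if (sum(mask) == 0L)
    stop("empty mask: the field of view does not intersect the shape")
  voxel_grid(mask, spacing, origin)
}

# --- study generation -------------------------------------------------------

#' Specification of one phantom bone pair
#'
#' Defaults follow the study conditions this package emulates: modality-A
#' (cone-beam) spacing 0.30 x 0.30 x 0.60 mm against modality-B
#' (multidetector) spacing 0.49 x 0.49 x 0.625 mm, and an axial scan-height
#' ratio of 200/376 so that femur, tibia and fibula are truncated in the
#' shorter scan while the patella is always fully covered.
#'
#' @param bone bone label.
#' @param size characteristic bone scale (mm); defaults per bone
#'   (femur 60, tibia 55, fibula 40, patella 24, times `scale`).
#' @param scale overall subject scale factor.
#' @param transform true rigid misalignment between modalities
#'   (a [rigid_transform]); identity by default.
#' @param delta uniform surface offset of modality A relative to B (mm).
#' @param sigma_noise surface noise amplitude (mm).
#' @param spacing_a,spacing_b voxel spacing of the two grids (mm).
#' @param fov_height_a,fov_height_b axial (z) scan heights in mm, centred on
#'   the joint at z = 0; defaults scale the 200/376 mm ratio by `scale`.
#' @param seed integer seed.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(bone, size = NULL, scale = 1,
                         transform = rigid_identity(),
                         delta = 0, sigma_noise = 0.1,
                         spacing_a = c(0.30, 0.30, 0.60),
                         spacing_b = c(0.49, 0.49, 0.625),
                         fov_height_a = 60 * scale,
                         fov_height_b = 112.8 * scale,
                         seed = 1L) {
  bone <- match.arg(bone, PHANTOM_BONES)
  if (is.null(size))
    size <- c(femur = 60, tibia = 55, fibula = 40, patella = 24)[[bone]] * scale
  stopifnot(size > 0, sigma_noise >= 0, all(spacing_a > 0), all(spacing_b > 0),
            fov_height_a > 0, fov_height_b > 0)
  structure(list(bone = bone, size = size, transform = transform,
                 delta = delta, sigma_noise = sigma_noise,
                 spacing_a = as.numeric(spacing_a),
                 spacing_b = as.numeric(spacing_b),
                 fov_height_a = fov_height_a, fov_height_b = fov_height_b,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_fov <- function(bbox, spacing, fov_height, pad = 3) {
  lo <- bbox[1, ] - pad
  hi <- bbox[2, ] + pad
  lo[3] <- max(lo[3], -fov_height / 2)
  hi[3] <- min(hi[3], fov_height / 2)
  if (hi[3] <= lo[3]) stop("axial field of view does not intersect the bone")
  rbind(lo, hi)
}

#' Generate one phantom bone pair with ground truth
#'
#' Grid A is the voxelized base shape; grid B is the same bone with the
#' surface offset `delta` applied, surface noise added, and the true rigid
#' transform applied, rasterized on the B grid. Note the sign convention:
#' the offset makes the *A* model larger than B by `delta`, matching a
#' signed A-to-B surface distance whose expected mean is `delta`.
#'
#' @param spec a [phantom_spec].
#' @return list with `grid_a`, `grid_b` ([voxel_grid]s) and `truth`
#'   (true transform, delta, sigma_noise, seed, expected mean distance).
#' @export
generate_bone_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  base <- generate_bone_shape(spec$bone, spec$size, spec$seed)
  shape_a <- base
  shape_b <- offset_surface(base, -spec$delta)
  shape_b <- add_surface_noise(shape_b, spec$sigma_noise, spec$seed)
  shape_b <- transform_shape(shape_b, spec$transform)
  grid_a <- voxelize_shape(shape_a, spec$spacing_a,
                           phantom_fov(shape_a$bbox, spec$spacing_a, spec$fov_height_a))
  grid_b <- voxelize_shape(shape_b, spec$spacing_b,
                           phantom_fov(shape_b$bbox, spec$spacing_b, spec$fov_height_b))
  truth <- list(transform = spec$transform, delta = spec$delta,
                sigma_noise = spec$sigma_noise, seed = spec$seed,
                expected_mean = spec$delta)
  list(bone = spec$bone, grid_a = grid_a, grid_b = grid_b, truth = truth)
}

#' Build the specs of a multi-subject phantom study
#'
#' One spec per subject x bone. Each subject carries a seeded random rigid
#' misalignment between the modalities (rotation up to `max_angle` degrees,
#' translation up to `max_shift` mm per axis), the systematic offset `delta`
#' and noise `sigma_noise`.
#'
#' @param n_subjects number of subjects.
#' @param bones bone labels to include.
#' @param delta surface offset (mm); scalar or one per subject.
#' @param sigma_noise noise amplitude (mm).
#' @param scale subject scale factor (scalar or per subject).
#' @param max_angle,max_shift bounds of the random misalignment.
#' @param seed study seed.
#' @param ... further arguments passed to [phantom_spec()].
#' @return list of `phantom_spec`.
#' @export
knee_study_specs <- function(n_subjects = 4L, bones = PHANTOM_BONES,
                             delta = 0, sigma_noise = 0.1, scale = 1,
                             max_angle = 5, max_shift = 3, seed = 1L, ...) {
  delta <- rep_len(delta, n_subjects)
  scale <- rep_len(scale, n_subjects)
  specs <- list()
  for (s in seq_len(n_subjects)) {
    tr <- with_seed(seed * 1000L + s, random_rigid(max_angle, max_shift))
    for (b in bones) {
      sp <- phantom_spec(
        bone = b, scale = scale[s], transform = tr, delta = delta[s],
        sigma_noise = sigma_noise, seed = seed * 100L + s, ...)
      sp$subject <- s
      specs[[length(specs) + 1L]] <- sp
    }
  }
  specs
}

#' Generate a full phantom study
#'
#' @param specs list of [phantom_spec] (e.g. from [knee_study_specs()]).
#' @return list of bone pairs as returned by [generate_bone_pair()], with a
#'   `subject` index attached per spec order.
#' @export
generate_study <- function(specs) {
  if (length(specs) < 1L) stop("need at least one phantom spec")
  pairs <- lapply(specs, generate_bone_pair)
  for (i in seq_along(pairs)) pairs[[i]]$spec_index <- i
  pairs
}

#' Export a phantom ground-truth record as JSON
#'
#' @param truth a ground-truth record from [generate_bone_pair()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(rotation = unclass(truth$transform$rotation),
              translation = truth$transform$translation,
              delta = truth$delta, sigma_noise = truth$sigma_noise,
              seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
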