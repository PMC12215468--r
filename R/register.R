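# Rigid registration: Kabsch least-squares superposition and iterative
# closest point with exact closest-point-on-surface correspondences.

#' Rigid transform (proper rotation + translation)
#'
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @param translation length-3 numeric (mm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal (tolerance 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1)")
  if (length(translation) != 3L) stop("translation must have length 3")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rigid_identity <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> angle ", format(rotation_angle(x), digits = 4),
      " deg, translation (", paste(format(x$translation, digits = 4), collapse = ", "),
      ") mm\n", sep = "")
  invisible(x)
}

#' Rotation about a coordinate axis
#'
#' @param axis 1, 2 or 3 (x, y, z).
#' @param angle_deg angle in degrees.
#' @param translation optional translation (mm).
#' @return a [rigid_transform].
#' @export
rigid_axis_rotation <- function(axis, angle_deg, translation = c(0, 0, 0)) {
  a <- angle_deg * pi / 180
  R2 <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
  Rm <- diag(3)
  ix <- setdiff(1:3, axis)
  Rm[ix, ix] <- R2
  rigid_transform(Rm, translation)
}

# seeded random rigid transform with bounded angle (deg) and shift (mm)
random_rigid <- function(max_angle, max_shift) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0.2, 1) * max_angle * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  rigid_transform(Rm, runif(3, -max_shift, max_shift))
}

#' Compose, invert and apply rigid transforms
#'
#' `compose_rigid(a, b)` returns the transform "apply b, then a";
#' `invert_rigid` the inverse; `transform_points` maps an n x 3 matrix;
#' `rotation_angle` gives the rotation angle in degrees.
#'
#' @param a,b,transform [rigid_transform] objects.
#' @param points n x 3 matrix (mm).
#' @return a transform, matrix or scalar as appropriate.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -as.vector(t(transform$rotation) %*% transform$translation))
}

#' @rdname compose_rigid
#' @export
transform_points <- function(transform, points) {
  points <- rbind(points)
  t(transform$rotation %*% t(points) + transform$translation)
}

#' @rdname compose_rigid
#' @export
rotation_angle <- function(transform) {
  ct <- (sum(diag(transform$rotation)) - 1) / 2
  acos(pmin(pmax(ct, -1), 1)) * 180 / pi
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a [triangle_mesh].
#' @param transform a [rigid_transform].
#' @return the transformed mesh (topology unchanged).
#' @export
apply_rigid <- function(mesh, transform) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(transform, "rigid_transform"))
  out <- triangle_mesh(transform_points(transform, mesh$vertices), mesh$faces,
                       mesh$scalar)
  attr(out, "watertight") <- attr(mesh, "watertight")
  out
}

#' Least-squares rigid superposition (Kabsch / SVD)
#'
#' Finds the proper rotation R and translation t minimizing the weighted
#' sum of squared distances between `R source + t` and `target`. A
#' reflection solution is excluded by sign-correcting the smallest singular
#' direction.
#'
#' @param source,target n x 3 matrices of paired points (n >= 3).
#' @param weights optional non-negative weights.
#' @return a [rigid_transform] mapping source onto target.
#' @export
kabsch <- function(source, target, weights = NULL) {
  source <- rbind(source)
  target <- rbind(target)
  n <- nrow(source)
  if (nrow(target) != n) stop("source and target must have equal point counts")
  if (n < 3L) stop("need at least 3 point pairs")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop("weights must be non-negative")
  w <- weights / sum(weights)
  mu_s <- colSums(source * w)
  mu_t <- colSums(target * w)
  S <- sweep(source, 2, mu_s)
  T2 <- sweep(target, 2, mu_t)
  H <- t(S * w) %*% T2
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate geometry: points are (near-)collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(Rm, mu_t - as.vector(Rm %*% mu_s))
}

#' ICP parameters
#'
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the RMS change between iterations
#'   (mm).
#' @param trim fraction of worst correspondences discarded per iteration
#'   (in `[0, 0.5)`).
#' @param init initialization: `"identity"` starts from the current pose
#'   (for scans that already share a world frame; centroid matching would
#'   inject a gross axial error when the two fields of view truncate the
#'   bone differently); `"centroid"` aligns centroids;
#'   `"principal"` additionally aligns principal axes with 4-way axis-sign
#'   disambiguation by lowest RMS.
#' @param sample number of moving vertices to subsample (NULL = all).
#' @param seed seed for the subsampling draw.
#' @return an `icp_params` object.
#' @export
icp_params <- function(max_iter = 100L, tol = 1e-6, trim = 0,
                       init = c("centroid", "identity", "principal"), sample = NULL,
                       seed = 1L) {
  init <- match.arg(init)
  if (tol <= 0) stop("tol must be > 0")
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  structure(list(max_iter = as.integer(max_iter), tol = tol, trim = trim,
                 init = init, sample = sample, seed = as.integer(seed)),
            class = "icp_params")
}

# rotation matrix <-> rotation vector (axis * angle, Rodrigues)
rot_to_vec <- function(Rm) {
  ct <- (sum(diag(Rm)) - 1) / 2
  ang <- acos(pmin(pmax(ct, -1), 1))
  if (ang < 1e-12) return(c(0, 0, 0))
  ax <- c(Rm[3, 2] - Rm[2, 3], Rm[1, 3] - Rm[3, 1], Rm[2, 1] - Rm[1, 2])
  n <- sqrt(sum(ax^2))
  if (n < 1e-12) { # angle ~ pi: extract axis from R + I
    M <- (Rm + diag(3)) / 2
    ax <- sqrt(pmax(diag(M), 0))
    k <- which.max(ax)
    ax <- M[, k] / max(ax[k], 1e-12)
    return(ax / sqrt(sum(ax^2)) * ang)
  }
  ax / n * ang
}

vec_to_rot <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-12) return(diag(3))
  ax <- v / ang
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

icp_init_transforms <- function(mov, fix, init) {
  cm <- colMeans(mov)
  cf <- colMeans(fix)
  if (init == "identity") return(list(rigid_identity()))
  if (init == "centroid")
    return(list(rigid_transform(diag(3), cf - cm)))
  em <- eigen(stats::cov(mov), symmetric = TRUE)$vectors
  ef <- eigen(stats::cov(fix), symmetric = TRUE)$vectors
  out <- list()
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    S <- diag(c(s1, s2, s1 * s2)) # keeps det(R) = +1
    Rm <- ef %*% S %*% t(em)
    if (det(Rm) < 0) Rm <- ef %*% (S * -1) %*% t(em)
    out[[length(out) + 1L]] <- rigid_transform(Rm, cf - as.vector(Rm %*% cm))
  }
  out
}

#' Iterative closest point rigid alignment
#'
#' Aligns the moving mesh to the fixed mesh. Correspondences are exact
#' closest points on the fixed *surface* (closest point on triangle via a
#' bounding-volume hierarchy), not nearest vertices, so residuals below
#' the voxel size remain meaningful. Each iteration re-estimates the full
#' transform from the original moving points via [kabsch()]; iteration
#' stops when the RMS residual changes by less than `tol` or after
#' `max_iter` iterations.
#'
#' @param moving,fixed [triangle_mesh] objects.
#' @param params an [icp_params].
#' @return list with `transform` (moving -> fixed), `rms_trace` (mm per
#'   iteration), `iterations`, `converged`.
#' @export
icp_align <- function(moving, fixed, params = icp_params()) {
  stopifnot(inherits(moving, "triangle_mesh"), inherits(fixed, "triangle_mesh"))
  if (nrow(moving$vertices) == 0L || nrow(fixed$vertices) == 0L)
    stop("empty mesh")
  if (nrow(unique(moving$vertices)) <= 2L)
    stop("degenerate moving mesh (<= 2 distinct vertices)")
  pts <- moving$vertices
  if (!is.null(params$sample) && params$sample < nrow(pts)) {
    idx <- with_seed(params$seed, sample.int(nrow(pts), params$sample))
    pts <- pts[idx, , drop = FALSE]
  }
  tree <- .bvh_build(fixed$vertices, fixed$faces)

  rms_of <- function(tr) {
    cp <- .bvh_closest(tree, transform_points(tr, pts))
    sqrt(mean(cp$distance^2))
  }
  cands <- icp_init_transforms(pts, fixed$vertices, params$init)
  tr <- cands[[which.min(vapply(cands, rms_of, 0))]]

  tr_param <- function(tr) c(rot_to_vec(tr$rotation), tr$translation)
  param_tr <- function(p) rigid_transform(vec_to_rot(p[1:3]), p[4:6])
  rms_at <- function(tr) {
    d <- .bvh_closest(tree, transform_points(tr, pts))$distance
    if (params$trim > 0) {
      k <- max(3L, floor(length(d) * (1 - params$trim)))
      d <- sort(d)[seq_len(k)]
    }
    sqrt(mean(d^2))
  }

  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  iter <- 0L
  p_hist <- list()
  while (iter < params$max_iter) {
    iter <- iter + 1L
    moved <- transform_points(tr, pts)
    cp <- .bvh_closest(tree, moved)
    keep <- seq_len(nrow(pts))
    if (params$trim > 0) {
      k <- max(3L, floor(length(keep) * (1 - params$trim)))
      keep <- order(cp$distance)[seq_len(k)]
    }
    tr <- kabsch(pts[keep, , drop = FALSE], cp$point[keep, , drop = FALSE])
    rms <- rms_at(tr)
    # accelerate slow geometric tails by extrapolating the transform
    # sequence when successive updates are nearly parallel (classic
    # accelerated ICP); the jump is kept only if it lowers the RMS
    p_hist <- c(p_hist, list(tr_param(tr)))
    nh <- length(p_hist)
    if (nh >= 3L) {
      d1 <- p_hist[[nh]] - p_hist[[nh - 1L]]
      d0 <- p_hist[[nh - 1L]] - p_hist[[nh - 2L]]
      n1 <- sqrt(sum(d1^2))
      n0 <- sqrt(sum(d0^2))
      if (n1 > 0 && n0 > 0 && sum(d1 * d0) / (n1 * n0) > 0.95 && n1 < n0) {
        r <- min(n1 / n0, 0.98)
        fac <- min(r / (1 - r), 25)
        cand <- param_tr(p_hist[[nh]] + d1 * fac)
        rms_c <- rms_at(cand)
        if (rms_c < rms) {
          tr <- cand
          rms <- rms_c
          p_hist <- c(p_hist, list(tr_param(tr)))
        }
      }
    }
    trace <- c(trace, rms)
    if (is.finite(prev) && abs(prev - rms) < params$tol) {
      converged <- TRUE
      break
    }
    prev <- rms
  }
  list(transform = tr, rms_trace = trace, iterations = iter,
       converged = converged)
}
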