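#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Format a distance in mm the way the summary tables print it
#'
#' Two decimal places, extended to three when |x| < 0.01 and to four when
#' |x| < 0.001, so near-zero means and bounds keep a significant digit
#' (e.g. 0.00575 prints as "0.006", -0.00042 as "-0.0004").
#'
#' @param x numeric vector (mm).
#' @return character vector.
#' @export
#' @examples
#' fmt_mm(c(0.00575, -0.0004, 0.128, -0.036))
fmt_mm <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(NA_character_)
    digits <- if (abs(v) < 0.001 && v != 0) 4L else if (abs(v) < 0.01 && v != 0) 3L else 2L
    formatC(v, format = "f", digits = digits)
  }, character(1))
}

# round to the printed precision used by fmt_mm, returning a number
round_mm <- function(x) as.numeric(fmt_mm(x))

#' Separable Gaussian smoothing of a 3D array
#'
#' Zero-padded separable convolution with a Gaussian kernel, used as the
#' optional pre-smoothing step before isosurface extraction.
#'
#' @param a 3D numeric array.
#' @param sigma kernel standard deviation in voxels; scalar or length-3.
#' @return smoothed array of the same dimension.
#' @keywords internal
gaussian_smooth3 <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    m <- max(1L, ceiling(3 * s))
    k <- exp(-((-m:m)^2) / (2 * s^2))
    k <- k / sum(k)
    out <- array(0, dim(a))
    n <- dim(a)[axis]
    for (o in -m:m) {
      src <- seq_len(n) + o
      keep <- src >= 1 & src <= n
      if (!any(keep)) next
      idx_dst <- which(keep)
      idx_src <- src[keep]
      if (axis == 1) out[idx_dst, , ] <- out[idx_dst, , ] + k[o + m + 1] * a[idx_src, , ]
      else if (axis == 2) out[, idx_dst, ] <- out[, idx_dst, ] + k[o + m + 1] * a[, idx_src, ]
      else out[, , idx_dst] <- out[, , idx_dst] + k[o + m + 1] * a[, , idx_src]
    }
    a <- out
  }
  a
}
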