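`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a named, isolated RNG stream
#'
#' Each stochastic component of the package (label jitter, uptake noise,
#' calibration cohorts, paired tracer data) draws from its own stream so that
#' regenerating one fixture never shifts another. Streams are derived from the
#' user seed by a fixed per-component offset and applied with `set.seed()`
#' (Mersenne-Twister); the global RNG state is restored afterwards.
#'
#' @param seed integer base seed (kept well below 2^31).
#' @param stream stream name.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_stream <- function(seed, stream, expr) {
  offsets <- c(labels = 101L, uptake = 211L, noise = 307L,
               cohort = 401L, pairs = 503L, misc = 601L)
  if (!stream %in% names(offsets)) stopf("unknown RNG stream '%s'", stream)
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > .Machine$integer.max - 1000L)
    stopf("seed must be an integer below 2^31 - 1000")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed + offsets[[stream]])
  expr
}

read_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

pkg_extdata <- function(file) {
  p <- system.file("extdata", file, package = "atnquant")
  if (!nzchar(p)) stopf("bundled data file '%s' not found", file)
  p
}

#' Separable 3-D Gaussian blur
#'
#' Convolves a 3-D array with an axis-aligned Gaussian kernel, one axis at a
#' time, using dense band-matrix multiplication. Boundaries are zero-padded
#' (signal near the edge leaks out, as with a physical point-spread function).
#' A kernel whose sigma is below 0.01 voxel on an axis is treated as identity.
#'
#' @param arr 3-D numeric array.
#' @param fwhm_mm full width at half maximum of the PSF, in mm (scalar).
#' @param voxel_size length-3 voxel dimensions in mm.
#' @return blurred array, same dimensions.
#' @export
gaussian_blur <- function(arr, fwhm_mm, voxel_size) {
  stopifnot(length(dim(arr)) == 3, fwhm_mm >= 0, length(voxel_size) == 3)
  if (fwhm_mm == 0) return(arr)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_size
  out <- arr
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 0.01) next
    n <- dim(out)[ax]
    half <- max(1L, ceiling(3 * s))
    x <- (-half):half
    k <- exp(-x^2 / (2 * s^2))
    k <- k / sum(k)
    # band matrix K[i, j] = k[j - i + half + 1]
    K <- matrix(0, n, n)
    idx <- outer(seq_len(n), seq_len(n), function(i, j) j - i)
    sel <- abs(idx) <= half
    K[sel] <- k[idx[sel] + half + 1L]
    out <- apply_along_axis1(out, ax, K)
  }
  out
}

# multiply matrix K (n_ax x n_ax) along axis `ax` of 3-D array
apply_along_axis1 <- function(arr, ax, K) {
  d <- dim(arr)
  if (ax == 1) {
    array(K %*% matrix(arr, d[1], d[2] * d[3]), d)
  } else if (ax == 2) {
    perm <- aperm(arr, c(2, 1, 3))
    res <- array(K %*% matrix(perm, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    aperm(res, c(2, 1, 3))
  } else {
    perm <- aperm(arr, c(3, 1, 2))
    res <- array(K %*% matrix(perm, d[3], d[1] * d[2]), c(d[3], d[1], d[2]))
    aperm(res, c(2, 3, 1))
  }
}

# 3 x N matrix of 0-based voxel indices for a grid shape
voxel_grid <- function(shape) {
  i <- rep.int(0:(shape[1] - 1L), shape[2] * shape[3])
  j <- rep.int(rep(0:(shape[2] - 1L), each = shape[1]), shape[3])
  k <- rep(0:(shape[3] - 1L), each = shape[1] * shape[2])
  rbind(i, j, k, deparse.level = 0)
}
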