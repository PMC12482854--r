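#' Registration settings
#'
#' Controls the rigid registration: similarity metric, joint-histogram size,
#' multi-resolution schedule and optimizer budget. The defaults (normalized
#' mutual information, 48 bins, coarse-to-fine levels at downsampling factors
#' 4 and 2, derivative-free Nelder-Mead with an enlarged initial simplex) give
#' sub-0.1 mm / 0.1 degree recovery on noiseless phantoms with a capture range
#' of roughly +/-10 mm and +/-10 degrees after centre-of-mass initialization.
#'
#' @param metric `"nmi"` (normalized mutual information, suitable for
#'   multi-modal pairs) or `"mse"` (mean squared error, mono-modal only).
#' @param bins histogram bins per axis for NMI.
#' @param levels integer downsampling factors, coarse to fine. Each pyramid
#'   level is Gaussian-smoothed before decimation (plain decimation aliases
#'   and riddles the metric with local optima).
#' @param maxit optimizer iteration budget per level (recycled).
#' @param simplex_scale initial Nelder-Mead step per level, in mm/degrees
#'   (recycled).
#' @param restarts maximum simplex restarts per level; the optimizer is
#'   restarted from its own solution with a fresh simplex until the metric
#'   stops improving (Nelder-Mead is prone to premature convergence in 6-D).
#' @param reltol optimizer relative convergence tolerance.
#' @return a `register_config` list.
#' @export
register_config <- function(metric = c("nmi", "mse"), bins = 48L,
                            levels = c(4L, 2L), maxit = c(600L, 400L),
                            simplex_scale = c(0.8, 0.2), restarts = 10L,
                            reltol = 1e-10) {
  metric <- match.arg(metric)
  stopifnot(bins >= 8, length(levels) >= 1, all(levels >= 1), restarts >= 1)
  structure(list(metric = metric, bins = as.integer(bins),
                 levels = as.integer(levels),
                 maxit = as.integer(rep_len(maxit, length(levels))),
                 simplex_scale = rep_len(simplex_scale, length(levels)),
                 restarts = as.integer(restarts), reltol = reltol),
            class = "register_config")
}

world_centroid <- function(vol) {
  w <- as.vector(vol$data) - min(vol$data)
  s <- sum(w)
  if (s <= 0) stopf("degenerate image: constant intensity")
  w <- w / s
  pts <- vol$affine[1:3, 1:3] %*% voxel_grid(dim(vol$data)) + vol$affine[1:3, 4]
  as.vector(pts %*% w)
}

# anti-aliased pyramid level: Gaussian pre-smoothing, then decimation
downsample_volume <- function(vol, factor) {
  if (factor == 1L) return(vol)
  vs <- voxel_size(vol$affine)
  sm <- image_volume(gaussian_blur(vol$data, factor * mean(vs), vs),
                     vol$affine, space = vol$space)
  sh <- dim(vol$data)
  nsh <- pmax(8L, as.integer(floor(sh / factor)))
  naff <- vol$affine
  naff[1:3, 1:3] <- vol$affine[1:3, 1:3] * factor
  resample_once(sm, identity_transform(), space_spec(nsh, naff),
                interpolation = "trilinear")
}

nmi_metric <- function(fixed_vals, moving_vals, inside, bins, frange, mrange) {
  f <- fixed_vals[inside]
  m <- moving_vals[inside]
  bf <- pmin(pmax(1L, 1L + as.integer(bins * (f - frange[1]) /
                                        (frange[2] - frange[1] + 1e-12))), bins)
  bm <- pmin(pmax(1L, 1L + as.integer(bins * (m - mrange[1]) /
                                        (mrange[2] - mrange[1] + 1e-12))), bins)
  jt <- tabulate(bf + bins * (bm - 1L), bins * bins)
  p <- jt / sum(jt)
  pm <- matrix(p, bins)
  px <- rowSums(pm); py <- colSums(pm)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hxy <- -sum(p[p > 0] * log(p[p > 0]))
  (hx + hy) / hxy
}

#' Rigid PET-to-anatomy registration
#'
#' Estimates the 6-parameter rigid map from the moving volume's world frame to
#' the fixed volume's world frame by maximizing the configured similarity
#' metric over a coarse-to-fine pyramid, after intensity centre-of-mass
#' initialization of the translation. Rotation is parameterized about the
#' fixed volume's grid centre. Fully deterministic for a given configuration.
#'
#' @param moving,fixed [image_volume()]s overlapping in world space.
#' @param config a [register_config()].
#' @return a [rigid_transform()] with attributes `metric_value` (final
#'   similarity) and `converged`.
#' @export
rigid_register <- function(moving, fixed, config = register_config()) {
  stopifnot(inherits(moving, "image_volume"), inherits(fixed, "image_volume"))
  if (stats::sd(moving$data) == 0) stopf("degenerate image: constant moving image")
  if (stats::sd(fixed$data) == 0) stopf("degenerate image: constant fixed image")
  center <- as.vector(
    fixed$affine[1:3, 1:3] %*% ((dim(fixed$data) - 1) / 2) + fixed$affine[1:3, 4])
  t0 <- world_centroid(fixed) - world_centroid(moving)
  p_init <- c(0, 0, 0, t0)
  p <- p_init
  vs <- voxel_size(moving$affine)
  value <- NA_real_
  conv <- TRUE
  objective <- NULL
  for (li in seq_along(config$levels)) {
    f <- config$levels[li]
    fx <- downsample_volume(fixed, f)
    # smooth the moving image to the matching scale so the two histograms see
    # comparable frequency content
    mv <- if (f > 1L) gaussian_blur(moving$data, f * mean(vs), vs)
          else moving$data
    gvox <- voxel_grid(dim(fx$data))
    fvals <- as.vector(fx$data)
    frange <- range(fvals)
    mrange <- range(mv)
    Ainv <- solve(moving$affine)
    objective <- function(par) {
      Tm <- rigid_matrix(par[1:3], par[4:6], center)
      M <- Ainv %*% solve(Tm) %*% fx$affine
      vox <- M[1:3, 1:3] %*% gvox + M[1:3, 4]
      smp <- trilinear_sample(mv, vox)
      if (sum(smp$inside) < 64) return(0)
      if (config$metric == "nmi")
        -nmi_metric(fvals, smp$values, smp$inside, config$bins, frange, mrange)
      else
        mean((fvals[smp$inside] - smp$values[smp$inside])^2) /
          diff(frange + c(0, 1e-12))^2
    }
    # parscale enlarges the initial simplex (0.1 * parscale per coordinate);
    # with the default 0.1 mm/deg steps Nelder-Mead stalls on the flat,
    # binning-granular metric surface, and a fresh-simplex restart rescues
    # its frequent premature convergence in 6-D
    best <- Inf
    last_gain <- Inf
    for (r in seq_len(config$restarts)) {
      o <- stats::optim(p, objective, method = "Nelder-Mead",
                        control = list(maxit = config$maxit[li],
                                       reltol = config$reltol,
                                       parscale = rep(config$simplex_scale[li] * 10, 6)))
      p <- o$par
      last_gain <- best - o$value
      best <- min(best, o$value)
      if (last_gain <= 1e-7) break
    }
    value <- -best
    # not converged only if the level exhausted its restarts while the metric
    # was still moving appreciably
    conv <- conv && last_gain <= 1e-4
  }
  # never return something worse than the initialization (guards against
  # plateau drift when the start already sits at the optimum)
  init_val <- objective(p_init)
  if (init_val < -value) {
    p <- p_init
    value <- -init_val
  }
  if (!conv)
    warning(sprintf(
      "optimizer did not fully converge within its iteration/restart budget (final %s = %.6f)",
      config$metric, value), call. = FALSE)
  out <- rigid_transform(p[1:3], p[4:6], center)
  attr(out, "metric_value") <- value
  attr(out, "converged") <- conv
  out
}
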