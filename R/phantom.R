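#' Phantom generation settings
#'
#' The defaults define the package's standing test conditions: a 64^3 grid at
#' 2 mm isotropic (desk-scale; the full 181x217x181 1 mm template grid is
#' available via `grid = template_space()`), no PSF blur, no noise. Every
#' stochastic component draws from its own named RNG stream derived from
#' `seed`, so regenerating one fixture never shifts another.
#'
#' @param grid a [space_spec()] (default [phantom_space()]).
#' @param psf_fwhm Gaussian PSF full width at half maximum, mm.
#' @param noise_sd additive Gaussian noise SD, uptake units.
#' @param jitter blob-centre jitter as a fraction of the lattice cell (0-0.4).
#' @param seed integer seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid = phantom_space(), psf_fwhm = 0, noise_sd = 0,
                         jitter = 0.15, seed = 1L) {
  stopifnot(inherits(grid, "space_spec"), psf_fwhm >= 0, noise_sd >= 0,
            jitter >= 0, jitter <= 0.4)
  structure(list(grid = grid, psf_fwhm = psf_fwhm, noise_sd = noise_sd,
                 jitter = jitter, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Synthetic label phantom containing every dictionary structure
#'
#' Places each structure as a compact ellipsoid blob on a jittered 3-D lattice
#' (deterministic for a fixed seed, `labels` RNG stream). All dictionary
#' structures are representable so a full run yields 132 labels, of which the
#' 122 grey-matter ones feed the SUVr table.
#'
#' @param spec a [phantom_spec()].
#' @param dictionary a [label_dictionary()].
#' @return a [label_volume()] on `spec$grid`.
#' @export
make_label_phantom <- function(spec = phantom_spec(),
                               dictionary = load_label_dictionary()) {
  dictionary <- as_label_dictionary(dictionary)
  shape <- spec$grid$shape
  n_lab <- nrow(dictionary)
  # lattice with at least n_lab cells, as cubic as the grid allows
  cells <- ceiling(n_lab^(1 / 3))
  dims <- c(cells, cells, cells)
  while (prod(dims) < n_lab) dims[which.min(dims)] <- dims[which.min(dims)] + 1L
  cell_vox <- shape / dims
  if (any(cell_vox < 3))
    stopf("grid %s too small for %d labels (cells of %s voxels)",
          paste(shape, collapse = "x"), n_lab,
          paste(signif(cell_vox, 2), collapse = "x"))
  with_stream(spec$seed, "labels", {
    lab <- integer(prod(shape))
    g <- voxel_grid(shape)
    ids <- sort(dictionary$id)
    # cell index for each structure, row-major over the lattice
    cell <- arrayInd(seq_len(n_lab), dims) - 1L
    for (s in seq_len(n_lab)) {
      centre <- (cell[s, ] + 0.5) * cell_vox +
        stats::runif(3, -spec$jitter, spec$jitter) * cell_vox
      radii <- cell_vox / 2 * stats::runif(3, 0.70, 0.92)
      d2 <- ((g[1, ] - centre[1]) / radii[1])^2 +
            ((g[2, ] - centre[2]) / radii[2])^2 +
            ((g[3, ] - centre[3]) / radii[3])^2
      lab[d2 <= 1] <- ids[s]
    }
    label_volume(array(lab, shape), spec$grid$affine, dictionary)
  })
}

#' Synthetic PET phantom from a label volume
#'
#' Builds the piecewise-constant uptake image defined by `uptake_map`, blurs it
#' with an isotropic Gaussian PSF and adds Gaussian noise (`noise` RNG stream).
#' With zero PSF and zero noise the image is exactly piecewise constant, so
#' downstream SUVr values are known by construction.
#'
#' @param labels a [label_volume()].
#' @param uptake_map named numeric vector: structure id -> mean uptake
#'   (non-negative); must cover every label present. Background is 0.
#' @param psf_fwhm PSF FWHM in mm.
#' @param noise_sd additive noise SD in uptake units.
#' @param seed integer seed (used for the noise stream).
#' @return an [image_volume()] on the label grid.
#' @export
make_pet_phantom <- function(labels, uptake_map, psf_fwhm = 0, noise_sd = 0,
                             seed = 1L) {
  stopifnot(inherits(labels, "label_volume"))
  if (any(!is.finite(uptake_map)) || any(uptake_map < 0))
    stopf("uptake values must be non-negative")
  present <- setdiff(unique(as.integer(labels$labels)), 0L)
  ids <- as.integer(names(uptake_map))
  if (anyNA(ids)) stopf("uptake_map must be named by integer structure id")
  missing <- setdiff(present, ids)
  if (length(missing))
    stopf("uptake_map misses label(s): %s", paste(missing, collapse = ", "))
  lut <- numeric(max(c(ids, present)) + 1L)  # index = id + 1; background 0
  lut[ids + 1L] <- uptake_map
  img <- array(lut[as.integer(labels$labels) + 1L], dim(labels$labels))
  if (psf_fwhm > 0)
    img <- gaussian_blur(img, psf_fwhm, voxel_size(labels$affine))
  if (noise_sd > 0)
    img <- img + with_stream(seed, "noise",
                             array(stats::rnorm(length(img), 0, noise_sd),
                                   dim(img)))
  image_volume(img, labels$affine, space = "native")
}

#' Default phantom uptake maps per modality
#'
#' Convenience uptake patterns for demonstrations and tests: an
#' amyloid-positive pattern (cortical GM above the whole-cerebellum reference,
#' high white matter as for amyloid tracers), and a tau-positive pattern
#' (meta-temporal uptake above the cerebellar-GM reference).
#'
#' @param dictionary a [label_dictionary()].
#' @param modality `"amyloid"` or `"tau"`.
#' @param target_suvr uptake assigned to the target-mask structures, with the
#'   reference at 1 (so the noiseless composite SUVr equals this value by
#'   construction).
#' @param masks composite masks from [load_composite_masks()].
#' @return named numeric uptake map covering all dictionary ids.
#' @export
phantom_uptake_map <- function(dictionary = load_label_dictionary(),
                               modality = c("amyloid", "tau"),
                               target_suvr = if (modality == "amyloid") 1.8 else 1.6,
                               masks = load_composite_masks(dictionary)) {
  modality <- match.arg(modality)
  dictionary <- as_label_dictionary(dictionary)
  u <- numeric(nrow(dictionary))
  names(u) <- dictionary$id
  if (modality == "amyloid") {
    u[dictionary$tissue == "GM"] <- 1.3
    u[dictionary$tissue == "WM"] <- 2.0   # high non-specific WM binding
    u[dictionary$tissue == "CSF"] <- 0.2
    ref <- masks$whole_cerebellum
    tgt <- masks$centiloid_cortical
  } else {
    u[dictionary$tissue == "GM"] <- 1.1
    u[dictionary$tissue == "WM"] <- 1.3
    u[dictionary$tissue == "CSF"] <- 0.2
    ref <- masks$cerebellar_gm
    tgt <- masks$centaur_metatemporal
  }
  u[as.character(ref$structure_ids)] <- 1.0
  u[as.character(tgt$structure_ids)] <- target_suvr
  if (modality == "amyloid") {
    # keep the whole-cerebellum pooled mean at 1 regardless of GM/WM split
    u[as.character(masks$whole_cerebellum$structure_ids)] <- 1.0
  }
  u
}

#' Cohort settings for the two-point calibration
#'
#' Defaults are the study anchor conditions: group mean SUVr 0.9659 for the
#' young-CN group and 1.8972 for the AD group, with cohort sizes on the scale
#' of the PiB calibration samples (77 young CN, 152 dementia).
#'
#' @param n_ycn,n_ad group sizes (>= 2).
#' @param m_ycn,m_ad group mean SUVr.
#' @param sd within-group SD (>= 0).
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_ycn = 77L, n_ad = 152L, m_ycn = 0.9659,
                        m_ad = 1.8972, sd = 0.15, seed = 1L) {
  if (n_ycn < 2 || n_ad < 2) stopf("need n >= 2 per group")
  if (sd < 0) stopf("sd must be non-negative")
  if (m_ad <= m_ycn) stopf("AD mean must exceed yCN mean")
  structure(list(n_ycn = as.integer(n_ycn), n_ad = as.integer(n_ad),
                 m_ycn = m_ycn, m_ad = m_ad, sd = sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a two-group calibration cohort
#'
#' Gaussian SUVr draws per group (`cohort` RNG stream); with `sd = 0` every
#' draw equals its group anchor, so the sample means are exactly the anchors.
#'
#' @param spec a [cohort_spec()].
#' @return list with numeric vectors `ycn_suvrs` and `ad_suvrs`.
#' @export
make_calibration_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_stream(spec$seed, "cohort", {
    list(ycn_suvrs = stats::rnorm(spec$n_ycn, spec$m_ycn, spec$sd),
         ad_suvrs = stats::rnorm(spec$n_ad, spec$m_ad, spec$sd))
  })
}

#' Simulate paired SUVr data for cross-tracer regression
#'
#' Tracer SUVr is drawn uniformly over `range`; the paired PiB-like response is
#' `true_slope * x + true_intercept` plus Gaussian noise (`pairs` RNG stream).
#' With zero noise an OLS fit recovers the generating line to machine
#' precision.
#'
#' @param true_slope,true_intercept generating line.
#' @param n number of pairs (>= 3).
#' @param noise_sd response noise SD.
#' @param seed integer seed.
#' @param range tracer SUVr sampling range.
#' @return list with `tracer_suvrs` and `pib_suvrs`.
#' @export
make_paired_tracer_data <- function(true_slope, true_intercept, n = 46L,
                                    noise_sd = 0, seed = 1L,
                                    range = c(0.8, 2.5)) {
  if (n < 3) stopf("need at least 3 pairs, got %d", n)
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  with_stream(seed, "pairs", {
    x <- stats::runif(n, range[1], range[2])
    y <- true_slope * x + true_intercept + stats::rnorm(n, 0, noise_sd)
    list(tracer_suvrs = x, pib_suvrs = y)
  })
}
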