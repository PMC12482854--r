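#' Per-region uptake statistics
#'
#' Mean uptake, voxel count and volume for every structure of the label
#' volume's dictionary. Voxels with NaN or negative uptake are excluded from
#' the means and reported separately per region (robustness to reconstruction
#' artifacts). Dictionary structures absent from the volume are kept as
#' zero-count rows (mean `NA`), never silently dropped.
#'
#' @param pet an [image_volume()] on the same grid as `labels`.
#' @param labels a [label_volume()].
#' @param affine_tol maximum absolute affine discrepancy tolerated.
#' @return data frame of class `region_stats` with columns `id`, `name`,
#'   `tissue`, `mean`, `voxels` (all voxels of the label), `valid_voxels`
#'   (voxels entering the mean), `excluded_voxels`, `volume_mm3`; attribute
#'   `voxel_volume_mm3`.
#' @export
region_stats <- function(pet, labels, affine_tol = 1e-4) {
  stopifnot(inherits(pet, "image_volume"), inherits(labels, "label_volume"))
  if (!identical(dim(pet$data), dim(labels$labels)))
    stopf("grid mismatch: PET is %s, labels are %s",
          paste(dim(pet$data), collapse = "x"),
          paste(dim(labels$labels), collapse = "x"))
  if (max(abs(pet$affine - labels$affine)) > affine_tol)
    stopf("grid mismatch: affines differ by more than %g", affine_tol)
  dict <- labels$dictionary
  lab <- as.integer(labels$labels)
  up <- as.numeric(pet$data)
  valid <- is.finite(up) & up >= 0
  nmax <- max(dict$id)
  n_all <- tabulate(lab, nbins = nmax)
  n_valid <- tabulate(lab[valid], nbins = nmax)
  sums <- numeric(nmax)
  sel <- valid & lab > 0L
  if (any(sel)) {
    s <- rowsum(up[sel], lab[sel])
    sums[as.integer(rownames(s))] <- s[, 1]
  }
  vv <- voxel_volume(labels$affine)
  out <- data.frame(
    id = dict$id, name = dict$name, tissue = dict$tissue,
    mean = ifelse(n_valid[dict$id] > 0, sums[dict$id] / n_valid[dict$id], NA_real_),
    voxels = n_all[dict$id],
    valid_voxels = n_valid[dict$id],
    excluded_voxels = n_all[dict$id] - n_valid[dict$id],
    volume_mm3 = n_all[dict$id] * vv,
    stringsAsFactors = FALSE
  )
  attr(out, "voxel_volume_mm3") <- vv
  class(out) <- c("region_stats", "data.frame")
  out
}

#' Composite region of named structures
#'
#' @param name mask name.
#' @param structure_ids non-empty set of structure ids.
#' @param dictionary optional [label_dictionary()]; if given, every id must
#'   exist in it.
#' @return object of class `composite_mask`.
#' @export
composite_mask <- function(name, structure_ids, dictionary = NULL) {
  structure_ids <- unique(as.integer(structure_ids))
  if (length(structure_ids) == 0) stopf("composite mask '%s' is empty", name)
  if (any(is.na(structure_ids)) || any(structure_ids <= 0))
    stopf("composite mask ids must be positive integers")
  if (!is.null(dictionary)) {
    dictionary <- as_label_dictionary(dictionary)
    missing <- setdiff(structure_ids, dictionary$id)
    if (length(missing))
      stopf("mask '%s': id(s) absent from dictionary: %s", name,
            paste(missing, collapse = ", "))
  }
  structure(list(name = as.character(name), structure_ids = structure_ids),
            class = "composite_mask")
}

#' Build a composite mask from structure names
#' @param dictionary a [label_dictionary()].
#' @param name mask name.
#' @param structure_names character vector of dictionary structure names.
#' @return a [composite_mask()].
#' @export
mask_from_names <- function(dictionary, name, structure_names) {
  dictionary <- as_label_dictionary(dictionary)
  idx <- match(structure_names, dictionary$name)
  if (anyNA(idx))
    stopf("mask '%s': unknown structure name(s): %s", name,
          paste(structure_names[is.na(idx)], collapse = "; "))
  composite_mask(name, dictionary$id[idx], dictionary)
}

#' Load composite mask definitions (bundled defaults or a JSON file)
#'
#' The bundled file defines `whole_cerebellum` (amyloid reference),
#' `cerebellar_gm` (tau reference), `centaur_metatemporal` (meta-temporal tau
#' target) and a default `centiloid_cortical` target; masks are stored by
#' structure name and resolved against the dictionary.
#'
#' @param dictionary a [label_dictionary()].
#' @param path JSON file with a `masks` object of name -> structure-name
#'   arrays; `NULL` loads the bundled definitions.
#' @return named list of [composite_mask()]s.
#' @export
load_composite_masks <- function(dictionary = load_label_dictionary(),
                                 path = NULL) {
  path <- path %||% pkg_extdata("composite_masks.json")
  if (!file.exists(path)) stopf("mask file not found: %s", path)
  defs <- read_json(path)$masks
  if (is.null(defs)) stopf("mask file %s has no 'masks' object", path)
  out <- lapply(names(defs), function(nm)
    mask_from_names(dictionary, nm, unlist(defs[[nm]])))
  names(out) <- names(defs)
  out
}

#' Pooled-voxel mean uptake of a composite reference region
#'
#' The volume-weighted mean of the member-region means, i.e. the plain mean
#' over the pooled voxels of the union mask (the convention used for
#' mask-based SUVr).
#'
#' @param stats a [region_stats()] table.
#' @param reference a [composite_mask()].
#' @return scalar mean uptake.
#' @export
reference_uptake <- function(stats, reference) {
  stopifnot(inherits(stats, "region_stats"), inherits(reference, "composite_mask"))
  rows <- stats[stats$id %in% reference$structure_ids, ]
  rows <- rows[rows$valid_voxels > 0, ]
  if (nrow(rows) == 0)
    stopf("reference '%s' has no voxels in the volume", reference$name)
  sum(rows$mean * rows$valid_voxels) / sum(rows$valid_voxels)
}

#' Regional SUVr table
#'
#' Divides each grey-matter region mean by the reference uptake. Only GM
#' structures present in the volume are tabulated (a full 132-structure
#' parcellation yields 122 rows); absent GM ids are recorded in the
#' `missing_ids` attribute.
#'
#' @param stats a [region_stats()] table.
#' @param reference a [composite_mask()] (e.g. whole cerebellum for amyloid,
#'   cerebellar GM for tau).
#' @param dictionary the [label_dictionary()] (defaults to the one implied by
#'   `stats`).
#' @return data frame of class `suvr_table` with columns `id`, `name`,
#'   `tissue`, `mean`, `voxels`, `volume_mm3`, `suvr`; attributes
#'   `reference_region`, `reference_uptake`, `missing_ids`.
#' @export
suvr_table <- function(stats, reference, dictionary = NULL) {
  stopifnot(inherits(stats, "region_stats"))
  ref <- reference_uptake(stats, reference)
  if (!is.finite(ref) || ref <= 0)
    stopf("reference uptake must be positive, got %g", ref)
  gm <- stats[stats$tissue == "GM", ]
  missing <- gm$id[gm$valid_voxels == 0]
  gm <- gm[gm$valid_voxels > 0, ]
  out <- data.frame(id = gm$id, name = gm$name, tissue = gm$tissue,
                    mean = gm$mean, voxels = gm$voxels,
                    volume_mm3 = gm$volume_mm3,
                    suvr = gm$mean / ref, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "reference_region") <- reference$name
  attr(out, "reference_uptake") <- ref
  attr(out, "missing_ids") <- missing
  class(out) <- c("suvr_table", "data.frame")
  out
}

#' Composite-mask SUVr
#'
#' Pooled-voxel mean over the union of the mask structures, divided by the
#' reference uptake — the global value that feeds the Centiloid / CenTauRz
#' conversions.
#'
#' @param stats a [region_stats()] table.
#' @param mask,reference [composite_mask()]s.
#' @return scalar SUVr.
#' @export
composite_suvr <- function(stats, mask, reference) {
  stopifnot(inherits(mask, "composite_mask"))
  rows <- stats[stats$id %in% mask$structure_ids, ]
  rows <- rows[rows$valid_voxels > 0, ]
  if (nrow(rows) == 0)
    stopf("mask '%s' has no voxels in the volume", mask$name)
  pooled <- sum(rows$mean * rows$valid_voxels) / sum(rows$valid_voxels)
  pooled / reference_uptake(stats, reference)
}

#' Rank structures by between-group discrimination
#'
#' Ranks shared structures by how well their SUVr separates two subject groups
#' (e.g. young amyloid-negative controls vs amyloid-positive dementia), the
#' procedure used to derive a data-driven cortical target mask. The default
#' criterion is the absolute standardized mean difference (Cohen's d with
#' pooled SD); `"auc"` uses the Mann-Whitney area under the curve, folded
#' around 0.5.
#'
#' @param group_a,group_b lists of [suvr_table()]s (one per subject), sharing
#'   label sets; at least 2 subjects per group.
#' @param criterion `"effect_size"` or `"auc"`.
#' @param top_k number of structures for the returned mask.
#' @return list with `mask` (a [composite_mask()] of the top_k ids), `ranking`
#'   (data frame `id`, `name`, `criterion`, ordered), `criterion`, `unstable`
#'   (TRUE when the groups are essentially indistinguishable or the k-th
#'   boundary is tied).
#' @export
select_discriminative_structures <- function(group_a, group_b,
                                             criterion = c("effect_size", "auc"),
                                             top_k = 10L) {
  criterion <- match.arg(criterion)
  if (length(group_a) < 2 || length(group_b) < 2)
    stopf("need at least 2 subjects per group")
  as_mat <- function(tabs) {
    ids <- tabs[[1]]$id
    for (t in tabs)
      if (!identical(t$id, ids)) stopf("subjects have mismatched label sets")
    do.call(rbind, lapply(tabs, function(t) t$suvr))
  }
  A <- as_mat(group_a)
  B <- as_mat(group_b)
  if (!identical(group_a[[1]]$id, group_b[[1]]$id))
    stopf("groups have mismatched label sets")
  ids <- group_a[[1]]$id
  nms <- group_a[[1]]$name
  if (criterion == "effect_size") {
    ma <- colMeans(A); mb <- colMeans(B)
    va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
    sp <- sqrt(((nrow(A) - 1) * va + (nrow(B) - 1) * vb) /
                 (nrow(A) + nrow(B) - 2))
    crit <- ifelse(sp > 0, abs(ma - mb) / sp, ifelse(ma == mb, 0, Inf))
  } else {
    crit <- vapply(seq_along(ids), function(j) {
      auc <- mean(outer(B[, j], A[, j], ">") + 0.5 * outer(B[, j], A[, j], "=="))
      abs(auc - 0.5) * 2
    }, numeric(1))
  }
  ord <- order(-crit, ids)
  top_k <- min(as.integer(top_k), length(ids))
  sel <- ord[seq_len(top_k)]
  unstable <- all(crit < 1e-8) ||
    (top_k < length(ids) &&
       abs(crit[ord[top_k]] - crit[ord[top_k + 1]]) < 1e-12)
  list(mask = composite_mask("discriminative", ids[sel]),
       ranking = data.frame(id = ids[ord], name = nms[ord],
                            criterion = crit[ord], stringsAsFactors = FALSE),
       criterion = criterion, unstable = unstable)
}

#' Native and ICV-normalized structure volumes
#'
#' @param labels a [label_volume()].
#' @param icv intracranial volume in mm^3 (positive).
#' @return data frame of class `volume_table` with columns `id`, `name`,
#'   `tissue`, `voxels`, `native_mm3`, `icv_fraction`.
#' @export
volume_table <- function(labels, icv) {
  stopifnot(inherits(labels, "label_volume"))
  if (!is.finite(icv) || icv <= 0) stopf("icv must be positive, got %g", icv)
  dict <- labels$dictionary
  n <- tabulate(as.integer(labels$labels), nbins = max(dict$id))
  vv <- voxel_volume(labels$affine)
  out <- data.frame(id = dict$id, name = dict$name, tissue = dict$tissue,
                    voxels = n[dict$id],
                    native_mm3 = n[dict$id] * vv,
                    icv_fraction = n[dict$id] * vv / icv,
                    stringsAsFactors = FALSE)
  attr(out, "icv_mm3") <- icv
  class(out) <- c("volume_table", "data.frame")
  out
}

#' Iterative region-based partial-volume correction
#'
#' A clearly labelled substitute for resolution-recovery PVC, off by default in
#' the quantification pipeline: the iterative-Yang scheme. Each pass builds a
#' piecewise-constant synthetic image from the current region means (background
#' included), blurs it with the Gaussian PSF, and multiplies the observed image
#' by the ratio synthetic / blurred; region means are then re-estimated from
#' the corrected image.
#'
#' @param pet an [image_volume()].
#' @param labels a [label_volume()] on the same grid.
#' @param psf_fwhm PSF full width at half maximum, mm (> 0); a vanishing FWHM
#'   returns the input unchanged.
#' @param iterations number of correction passes (>= 1).
#' @return corrected [image_volume()].
#' @export
pvc_region_based <- function(pet, labels, psf_fwhm, iterations = 5L) {
  stopifnot(inherits(pet, "image_volume"), inherits(labels, "label_volume"))
  if (!is.finite(psf_fwhm) || psf_fwhm <= 0)
    stopf("psf_fwhm must be positive, got %g", psf_fwhm)
  if (iterations < 1) stopf("iterations must be >= 1")
  if (!identical(dim(pet$data), dim(labels$labels)))
    stopf("grid mismatch between PET and labels")
  vs <- voxel_size(pet$affine)
  sigma_vox <- (psf_fwhm / (2 * sqrt(2 * log(2)))) / vs
  if (all(sigma_vox < 0.01)) return(pet)
  lab <- as.integer(labels$labels) + 1L  # background -> group 1
  ngrp <- max(lab)
  corrected <- pet$data
  eps <- 1e-8 * max(abs(pet$data))
  for (it in seq_len(iterations)) {
    means <- vapply(split(as.numeric(corrected), lab), mean, numeric(1))
    mvec <- numeric(ngrp)
    mvec[as.integer(names(means))] <- means
    synth <- array(mvec[lab], dim(pet$data))
    blurred <- gaussian_blur(synth, psf_fwhm, vs)
    ratio <- synth / pmax(blurred, eps)
    ratio[synth == 0] <- 0
    corrected <- pet$data * ratio
  }
  image_volume(corrected, pet$affine, space = pet$space)
}
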