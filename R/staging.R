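#' Staging thresholds
#'
#' Cut-points mapping continuous biomarkers to categorical A/T2/N statuses.
#' Defaults: AMYPAD-recommended Centiloid bands (A- below 10 CL, intermediate
#' in the closed interval \[10, 30\], A+ above 30), the 24.1 CL binary
#' threshold, CTRz cut of 2 and neurodegeneration probability cut of 0.5.
#'
#' @param cl_low,cl_high AMYPAD band edges (CL).
#' @param cl_binary binary-mode Centiloid threshold (CL).
#' @param ctrz_cut CenTauRz threshold.
#' @param havas_cut neurodegeneration probability threshold.
#' @return object of class `staging_thresholds`.
#' @export
staging_thresholds <- function(cl_low = 10, cl_high = 30, cl_binary = 24.1,
                               ctrz_cut = 2, havas_cut = 0.5) {
  vals <- c(cl_low, cl_high, cl_binary, ctrz_cut, havas_cut)
  if (any(!is.finite(vals))) stopf("all thresholds must be finite")
  if (cl_low >= cl_high) stopf("cl_low must be below cl_high")
  structure(list(cl_low = cl_low, cl_high = cl_high, cl_binary = cl_binary,
                 ctrz_cut = ctrz_cut, havas_cut = havas_cut),
            class = "staging_thresholds")
}

#' Amyloid status from a Centiloid value
#'
#' In `"amypad"` mode, values below `cl_low` are `A-`, values in the closed
#' interval \[`cl_low`, `cl_high`\] are `A_inter` (both band edges belong to
#' the intermediate band), values above are `A+`. In `"binary"` mode the single
#' threshold assigns its boundary to `A+` (a value equal to 24.1 CL is
#' positive).
#'
#' @param cl Centiloid value (finite).
#' @param mode `"amypad"` or `"binary"`.
#' @param thresholds a [staging_thresholds()].
#' @return one of `"A-"`, `"A_inter"`, `"A+"`.
#' @export
a_status <- function(cl, mode = c("amypad", "binary"),
                     thresholds = staging_thresholds()) {
  mode <- match.arg(mode)
  if (length(cl) != 1 || !is.finite(cl)) stopf("cl must be a finite scalar")
  if (mode == "amypad") {
    if (cl < thresholds$cl_low) "A-"
    else if (cl <= thresholds$cl_high) "A_inter"
    else "A+"
  } else {
    if (cl >= thresholds$cl_binary) "A+" else "A-"
  }
}

#' Tau status from a CenTauRz value
#'
#' Values below the cut are `T2-`; the boundary and above are `T2+` (the
#' published wording is "below 2 is negative", so exactly 2 is positive).
#'
#' @param ctrz CenTauRz value (finite).
#' @param thresholds a [staging_thresholds()].
#' @return `"T2-"` or `"T2+"`.
#' @export
t2_status <- function(ctrz, thresholds = staging_thresholds()) {
  if (length(ctrz) != 1 || !is.finite(ctrz)) stopf("ctrz must be a finite scalar")
  if (ctrz < thresholds$ctrz_cut) "T2-" else "T2+"
}

#' Neurodegeneration status from an atrophy probability
#'
#' Strictly above the cut is `N+`; a probability of exactly 0.5 is `N-` (the
#' published wording is "higher than 0.5").
#'
#' @param havas probability in \[0, 1\].
#' @param thresholds a [staging_thresholds()].
#' @return `"N-"` or `"N+"`.
#' @export
n_status <- function(havas, thresholds = staging_thresholds()) {
  if (length(havas) != 1 || !is.finite(havas) || havas < 0 || havas > 1)
    stopf("havas must be a probability in [0, 1]")
  if (havas > thresholds$havas_cut) "N+" else "N-"
}

#' Load a neurodegeneration (HAVAs-style) model file
#'
#' The bundled default is a SYNTHETIC surrogate (`model_id` "surrogate-v1"):
#' age-linear normative means and SDs for the ICV fractions of hippocampus,
#' amygdala and inferior lateral ventricle, combined through a logistic link on
#' the mean pathological z-score. It is not the published HAVAs lifespan
#' model; users reproduce that axis by supplying their own file with the same
#' schema.
#'
#' @param path JSON model file; `NULL` loads the bundled surrogate.
#' @return model list.
#' @export
load_havas_model <- function(path = NULL) {
  path <- path %||% pkg_extdata("havas_surrogate_v1_synthetic.json")
  if (!file.exists(path)) stopf("neurodegeneration model file not found: %s", path)
  model <- read_json(path)
  need <- c("hippocampus", "amygdala", "inferior_lateral_ventricle")
  if (is.null(model$structures) || !all(need %in% names(model$structures)))
    stopf("model file %s must define structures: %s", path,
          paste(need, collapse = ", "))
  model
}

#' Atrophy probability from three structure volumes
#'
#' Evaluates the (surrogate by default) neurodegeneration model: each ICV
#' fraction is z-scored against the model's age-dependent normative mean and
#' SD, z-scores are signed toward pathology (atrophy for hippocampus and
#' amygdala, expansion for the inferior lateral ventricle), and their mean is
#' passed through a logistic link. Volumes exactly at the normative means give
#' 0.5; the score increases as the hippocampus or amygdala shrink and as the
#' ventricle enlarges.
#'
#' @param hippocampus_icv_frac,amygdala_icv_frac,inferior_lateral_ventricle_icv_frac
#'   structure volumes as fractions of intracranial volume, in (0, 1).
#' @param age subject age in years, within \[18, 110\].
#' @param model model list from [load_havas_model()].
#' @return probability in \[0, 1\], with attribute `model_id`.
#' @export
havas_probability <- function(hippocampus_icv_frac, amygdala_icv_frac,
                              inferior_lateral_ventricle_icv_frac, age,
                              model = load_havas_model()) {
  fr <- c(hippocampus = hippocampus_icv_frac,
          amygdala = amygdala_icv_frac,
          inferior_lateral_ventricle = inferior_lateral_ventricle_icv_frac)
  if (any(!is.finite(fr)) || any(fr <= 0) || any(fr >= 1))
    stopf("ICV fractions must lie strictly in (0, 1)")
  if (!is.finite(age) || age < 18 || age > 110)
    stopf("age must lie in [18, 110], got %g", age)
  z <- vapply(names(fr), function(s) {
    st <- model$structures[[s]]
    mu <- st$mean_at_reference + st$slope_per_year * (age - model$age_reference)
    st$direction * (fr[[s]] - mu) / st$sd
  }, numeric(1))
  p <- stats::plogis((model$logistic_scale %||% 1) * mean(z))
  attr(p, "model_id") <- model$model_id %||% "unknown"
  p
}

#' Assemble an A/T2/N biomarker panel
#'
#' Combines the continuous biomarkers with their categorical statuses. A
#' missing modality (`NULL` value, e.g. no amyloid PET supplied) yields the
#' status `"not_assessed"` for that axis while the others are still computed.
#'
#' @param cl Centiloid value or `NULL`.
#' @param ctrz CenTauRz value or `NULL`.
#' @param havas neurodegeneration probability or `NULL`.
#' @param mode amyloid staging mode, `"amypad"` or `"binary"`.
#' @param thresholds a [staging_thresholds()].
#' @param tracers optional named list/character of tracer ids used.
#' @param model_ids optional named list of model identifiers (e.g. the
#'   neurodegeneration model id).
#' @return object of class `biomarker_panel`.
#' @export
atn_panel <- function(cl = NULL, ctrz = NULL, havas = NULL,
                      mode = c("amypad", "binary"),
                      thresholds = staging_thresholds(),
                      tracers = NULL, model_ids = NULL) {
  mode <- match.arg(mode)
  structure(list(
    cl = if (is.null(cl)) NULL else as.numeric(cl),
    ctrz = if (is.null(ctrz)) NULL else as.numeric(ctrz),
    havas = if (is.null(havas)) NULL else as.numeric(havas),
    a_status = if (is.null(cl)) "not_assessed" else a_status(cl, mode, thresholds),
    t2_status = if (is.null(ctrz)) "not_assessed" else t2_status(ctrz, thresholds),
    n_status = if (is.null(havas)) "not_assessed" else n_status(havas, thresholds),
    mode = mode,
    thresholds = unclass(thresholds),
    tracers = tracers,
    model_ids = model_ids
  ), class = "biomarker_panel")
}

#' Serialize / restore a biomarker panel as JSON
#'
#' Round-trips losslessly: numeric values are written at full precision.
#'
#' @param panel a [atn_panel()].
#' @param path JSON file path.
#' @return `path` (write) or the restored `biomarker_panel` (read).
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "biomarker_panel"))
  write_json_file(unclass(panel), path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  x <- read_json(path)
  x$thresholds <- do.call(staging_thresholds, x$thresholds)
  panel <- atn_panel(cl = x$cl, ctrz = x$ctrz, havas = x$havas,
                     mode = x$mode, thresholds = x$thresholds,
                     tracers = x$tracers, model_ids = x$model_ids)
  panel
}

#' @export
print.biomarker_panel <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "not assessed" else sprintf("%.4f", v)
  cat("<biomarker_panel>\n")
  cat(sprintf("  A  (CL)    %-12s -> %s [%s mode]\n", fmt(x$cl), x$a_status, x$mode))
  cat(sprintf("  T2 (CTRz)  %-12s -> %s\n", fmt(x$ctrz), x$t2_status))
  cat(sprintf("  N  (prob)  %-12s -> %s\n", fmt(x$havas), x$n_status))
  invisible(x)
}
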